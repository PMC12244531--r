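#' Differential contact map between two conditions
#'
#' Per-pair log2((kd + p) / (ctrl + p)) of balanced values after scaling
#' both matrices to equal total signal. The pseudocount p defaults to 1e-3
#' of the pooled mean nonzero contact value, shared between both
#' directions so the map is exactly antisymmetric under swapping
#' conditions.
#'
#' @param kd,ctrl balanced `ContactMatrix` objects on the same bin table.
#' @param pseudocount pseudocount; NULL for the default.
#' @return data.frame (bin1, bin2, log2fc) with attribute `pseudocount`.
#' @export
differential_map <- function(kd, ctrl, pseudocount = NULL) {
  if (!identical(kd$bins[, c("chrom", "start", "end")],
                 ctrl$bins[, c("chrom", "start", "end")]))
    stop("matrices are not on the same bin table")
  kd <- scale_total(kd, 1)
  ctrl <- scale_total(ctrl, 1)
  if (is.null(pseudocount)) {
    pool <- c(kd$triplets$value, ctrl$triplets$value)
    pseudocount <- 1e-3 * mean(pool)
  }
  n <- nrow(kd$bins)
  key_k <- kd$triplets$bin1 * n + kd$triplets$bin2
  key_c <- ctrl$triplets$bin1 * n + ctrl$triplets$bin2
  keys <- sort(union(key_k, key_c))
  vk <- rep(0, length(keys)); vc <- rep(0, length(keys))
  vk[match(key_k, keys)] <- kd$triplets$value
  vc[match(key_c, keys)] <- ctrl$triplets$value
  out <- data.frame(bin1 = keys %/% n, bin2 = keys %% n,
                    log2fc = log2((vk + pseudocount) / (vc + pseudocount)))
  attr(out, "pseudocount") <- pseudocount
  attr(out, "bins") <- kd$bins
  out
}

# Simple prominence of local minima of a signal: depth of the minimum
# below the lower of the highest points reachable on each side before a
# deeper minimum is met.
local_minima_prominence <- function(x) {
  n <- length(x)
  is_min <- rep(FALSE, n)
  for (i in 2:(n - 1))
    is_min[i] <- x[i] <= x[i - 1] & x[i] <= x[i + 1] &
      (x[i] < x[i - 1] | x[i] < x[i + 1])
  mins <- which(is_min)
  # collapse plateaus: adjacent minima of equal depth are one boundary
  if (length(mins) > 1) {
    grp <- cumsum(c(1, diff(mins) > 1 | diff(x[mins]) != 0))
    mins <- vapply(split(mins, grp), function(g)
      g[ceiling(length(g) / 2)], numeric(1))
    names(mins) <- NULL
  }
  prom <- vapply(mins, function(i) {
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    lmax <- -Inf; v <- -Inf
    for (xx in rev(left)) { if (xx < x[i]) break; v <- max(v, xx) }
    lmax <- v
    v <- -Inf
    for (xx in right) { if (xx < x[i]) break; v <- max(v, xx) }
    rmax <- v
    min(lmax, rmax) - x[i]
  }, numeric(1))
  data.frame(pos = mins, prominence = prom)
}

#' TAD boundaries from diamond insulation-score minima
#'
#' For each bin, the insulation score is the mean balanced contact in the
#' diamond window of `window` bp upstream x `window` bp downstream,
#' log2-normalized to the chromosome mean. Boundaries are local minima of
#' this score whose prominence exceeds `prominence` (in log2 units).
#' Domains are the intervals between consecutive boundaries.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param arm chromosome name or list(chrom, start, end).
#' @param window diamond window in bp (default 100 kb); must span >= 3
#'   bins.
#' @param prominence minimum log2-space prominence (default 0.1).
#' @return list of class `TadBoundarySet`: `boundaries` (data.frame chrom,
#'   pos, insulation, prominence), `domains` (chrom, start, end, size),
#'   `insulation` per-bin track.
#' @export
insulation_boundaries <- function(matrix, arm, window = 1e5,
                                  prominence = 0.1) {
  res <- bin_resolution(matrix$bins)
  w <- as.integer(window / res)
  if (w < 3) stop("window must span at least 3 bins")
  ids <- arm_bin_ids(matrix$bins, arm)
  n <- length(ids)
  S <- cm_sparse(matrix)
  idx <- ids + 1L
  M <- as.matrix(S[idx, idx, drop = FALSE])
  ins <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - w; hi <- i + w
    if (lo < 1 || hi > n) next
    ins[i] <- mean(M[seq(lo, i - 1), seq(i + 1, hi)])
  }
  ok <- !is.na(ins) & ins > 0
  li <- rep(NA_real_, n)
  li[ok] <- log2(ins[ok] / mean(ins[ok]))
  valid <- which(!is.na(li))
  bins <- matrix$bins[matrix$bins$bin_id %in% ids, ]
  boundaries <- data.frame(chrom = character(), pos = numeric(),
                           insulation = numeric(), prominence = numeric())
  if (length(valid) >= 3) {
    lp <- local_minima_prominence(li[valid])
    keep <- lp$prominence >= prominence
    pos_bins <- valid[lp$pos[keep]]
    boundaries <- data.frame(chrom = bins$chrom[pos_bins],
                             pos = (bins$start[pos_bins] +
                                      bins$end[pos_bins]) / 2,
                             insulation = li[valid][lp$pos[keep]],
                             prominence = lp$prominence[keep])
  }
  domains <- NULL
  if (nrow(boundaries) >= 2) {
    b <- sort(boundaries$pos)
    domains <- data.frame(chrom = boundaries$chrom[1],
                          start = b[-length(b)], end = b[-1])
    domains$size <- domains$end - domains$start
  } else {
    domains <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), size = numeric())
  }
  structure(list(boundaries = boundaries, domains = domains,
                 insulation = data.frame(bins, score = li),
                 window = window, prominence = prominence),
            class = "TadBoundarySet")
}

#' Classify TAD-boundary changes between control and knockdown
#'
#' Control and knockdown boundaries are matched one-to-one by greedy
#' nearest-neighbor genomic distance. Matches shifted <= 10 kb are "Same";
#' 15-70 kb are "Shift"; matches falling in the 10-15 kb gap are reported
#' as "Unclassified" rather than silently binned; matches beyond 70 kb are
#' dissolved into Lost + Gained. Unmatched control boundaries are "Lost",
#' unmatched knockdown boundaries "Gained". A control domain containing
#' >= 2 whole knockdown domains is a "Split"; >= 2 whole control domains
#' inside one knockdown domain is a "Merge".
#'
#' @param ctrl,kd `TadBoundarySet` objects on the same genome.
#' @param same_max,shift_min,shift_max class thresholds in bp.
#' @return list of class `BoundaryComparison`: `matches` (ctrl_pos,
#'   kd_pos, dist, category), `counts`, `splits`, `merges`.
#' @export
classify_boundaries <- function(ctrl, kd, same_max = 1e4, shift_min = 1.5e4,
                                shift_max = 7e4) {
  cb <- sort(ctrl$boundaries$pos)
  kb <- sort(kd$boundaries$pos)
  matches <- data.frame(ctrl_pos = numeric(), kd_pos = numeric(),
                        dist = numeric(), category = character())
  if (length(cb) > 0 && length(kb) > 0) {
    dmat <- abs(outer(cb, kb, "-"))
    ord <- order(dmat)
    used_c <- rep(FALSE, length(cb)); used_k <- rep(FALSE, length(kb))
    for (o in ord) {
      i <- (o - 1) %% length(cb) + 1
      j <- (o - 1) %/% length(cb) + 1
      if (used_c[i] || used_k[j]) next
      if (dmat[i, j] > shift_max) break
      used_c[i] <- TRUE; used_k[j] <- TRUE
      d <- dmat[i, j]
      cat <- if (d <= same_max) "Same"
             else if (d >= shift_min && d <= shift_max) "Shift"
             else "Unclassified"
      matches <- rbind(matches,
                       data.frame(ctrl_pos = cb[i], kd_pos = kb[j],
                                  dist = d, category = cat))
    }
    lost <- cb[!used_c]; gained <- kb[!used_k]
  } else {
    lost <- cb; gained <- kb
  }
  counts <- c(Same = sum(matches$category == "Same"),
              Shift = sum(matches$category == "Shift"),
              Unclassified = sum(matches$category == "Unclassified"),
              Lost = length(lost), Gained = length(gained))
  whole_within <- function(inner, outer_dom) {
    vapply(seq_len(nrow(outer_dom)), function(i)
      sum(inner$start >= outer_dom$start[i] & inner$end <= outer_dom$end[i]),
      numeric(1))
  }
  splits <- merges <- 0L
  if (nrow(ctrl$domains) > 0 && nrow(kd$domains) > 0) {
    splits <- sum(whole_within(kd$domains, ctrl$domains) >= 2)
    merges <- sum(whole_within(ctrl$domains, kd$domains) >= 2)
  }
  structure(list(matches = matches, lost = lost, gained = gained,
                 counts = counts, splits = splits, merges = merges,
                 n_ctrl = length(cb), n_kd = length(kb)),
            class = "BoundaryComparison")
}

#' Virtual 4C: interaction profile from an anchor region
#'
#' For every unmasked bin of the target region, the mean balanced contact
#' between that bin and all unmasked anchor bins (implicit zeros
#' included). Bins inside the anchor are flagged.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param anchor interval set: data.frame (chrom, start, end) or a single
#'   list(chrom, start, end).
#' @param target region to profile (chromosome name or list(chrom, start,
#'   end)); defaults to the whole genome.
#' @return data.frame of class `Virtual4CProfile`: bin coordinates,
#'   `score`, `in_anchor`.
#' @export
virtual_4c <- function(matrix, anchor, target = NULL) {
  if (!is.data.frame(anchor)) anchor <- as.data.frame(anchor)
  bins <- matrix$bins
  in_anchor <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(anchor)))
    in_anchor <- in_anchor | (bins$chrom == anchor$chrom[i] &
                                bins$start >= anchor$start[i] &
                                bins$end <= anchor$end[i])
  unmask <- if (is.null(matrix$weights)) rep(TRUE, nrow(bins)) else
    !is.na(matrix$weights)
  aidx <- which(in_anchor & unmask)
  if (length(aidx) == 0) stop("anchor contains no unmasked bins")
  tids <- if (is.null(target)) bins$bin_id else
    arm_bin_ids(bins, target)
  S <- cm_sparse(matrix)
  col_sums <- as.numeric(Matrix::colSums(S[aidx, , drop = FALSE]))
  # diagonal entries are counted once in the symmetric store; the mean
  # over anchor bins is the sum of contacts to the anchor divided by the
  # number of anchor bins
  score <- col_sums[tids + 1L] / length(aidx)
  out <- data.frame(bins[bins$bin_id %in% tids,
                         c("chrom", "start", "end", "bin_id")],
                    score = score,
                    in_anchor = in_anchor[tids + 1L])
  out$score[!unmask[tids + 1L]] <- NA_real_
  rownames(out) <- NULL
  class(out) <- c("Virtual4CProfile", class(out))
  attr(out, "anchor") <- anchor
  out
}

#' Randomly placed size-matched control anchors
#'
#' Draws `n_controls` intervals of exactly the anchor's length, uniformly
#' over bin-aligned positions of the arm, overlapping neither the anchor
#' nor any exclusion interval.
#'
#' @param anchor list or one-row data.frame (chrom, start, end).
#' @param arm list(chrom, start, end) defining the placement range.
#' @param n_controls number of control intervals.
#' @param exclusions data.frame (chrom, start, end) of forbidden regions.
#' @param seed RNG seed.
#' @param resolution placement grid in bp.
#' @return data.frame (chrom, start, end).
#' @export
size_matched_controls <- function(anchor, arm, n_controls = 3,
                                  exclusions = NULL, seed = 1L,
                                  resolution = 5e3) {
  if (is.data.frame(anchor)) anchor <- as.list(anchor[1, ])
  len <- anchor$end - anchor$start
  starts <- seq(arm$start, arm$end - len, by = resolution)
  forbid <- rbind(data.frame(start = anchor$start, end = anchor$end),
                  if (!is.null(exclusions))
                    exclusions[exclusions$chrom == arm$chrom,
                               c("start", "end")])
  ok <- rep(TRUE, length(starts))
  for (i in seq_len(nrow(forbid)))
    ok <- ok & (starts + len <= forbid$start[i] | starts >= forbid$end[i])
  feasible <- starts[ok]
  if (length(feasible) < n_controls)
    stop("not enough feasible placements for size-matched controls")
  set.seed(seed)
  s <- sample(feasible, n_controls)
  data.frame(chrom = arm$chrom, start = s, end = s + len)
}

#' Mean and sd of the per-bin difference of two virtual-4C profiles
#'
#' Differences are taken over unmasked bins outside either profile's
#' anchor; the per-bin vector is retained.
#'
#' @return list(mean, sd, per_bin).
#' @export
v4c_difference <- function(a, b) {
  if (!identical(a$bin_id, b$bin_id))
    stop("profiles are not on the same bins")
  keep <- !a$in_anchor & !b$in_anchor & !is.na(a$score) & !is.na(b$score)
  d <- a$score[keep] - b$score[keep]
  list(mean = mean(d), sd = stats::sd(d),
       per_bin = data.frame(a[keep, c("chrom", "start", "end", "bin_id")],
                            diff = d))
}
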