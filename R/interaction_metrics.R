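#' Contact probability versus genomic separation, P(s)
#'
#' Mean balanced cis contact per log-spaced separation shell on one arm.
#' Shell means count every unmasked bin pair of the shell (implicit zeros
#' included); the curve is normalized to unit mass over the reported shells
#' and the normalization constant recorded. Shells with no unmasked pairs
#' are flagged missing, never zero-filled.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param arm chromosome name or list(chrom, start, end).
#' @param shells_per_decade number of log-spaced shells per decade of
#'   separation (default 8).
#' @return data.frame of class `PsCurve`: `sep` (geometric shell center,
#'   bp), `sep_lo`, `sep_hi`, `mean` (normalized), `raw_mean`, `n_pairs`,
#'   `missing`; attribute `norm` holds the normalization constant.
#' @export
ps_curve <- function(matrix, arm, shells_per_decade = 8) {
  ids <- arm_bin_ids(matrix$bins, arm)
  if (length(ids) < 2) stop("arm is empty or has a single bin")
  res <- bin_resolution(matrix$bins)
  n_arm <- length(ids)
  unmask <- if (is.null(matrix$weights)) rep(TRUE, n_arm) else
    !is.na(matrix$weights[ids + 1L])
  t <- matrix$triplets
  t <- t[t$bin1 %in% ids & t$bin2 %in% ids & t$bin1 != t$bin2, , drop = FALSE]
  d <- match(t$bin2, ids) - match(t$bin1, ids)
  # per-diagonal sums and unmasked pair counts
  dsum <- rep(0, n_arm - 1)
  if (nrow(t) > 0) {
    ag <- rowsum(t$value, d)
    dsum[as.integer(rownames(ag))] <- as.numeric(ag)
  }
  dcnt <- vapply(seq_len(n_arm - 1), function(dd) {
    i <- seq_len(n_arm - dd)
    sum(unmask[i] & unmask[i + dd])
  }, numeric(1))
  max_sep <- (n_arm - 1) * res
  edges <- 10^seq(log10(res), log10(max_sep * (1 + 1e-9)),
                  by = 1 / shells_per_decade)
  if (max(edges) < max_sep) edges <- c(edges, max_sep * (1 + 1e-9))
  edges[1] <- res - 0.5  # guard against 10^log10 rounding above res
  seps <- seq_len(n_arm - 1) * res
  shell <- findInterval(seps, edges, rightmost.closed = TRUE)
  ssum <- rowsum(dsum, shell)
  scnt <- rowsum(dcnt, shell)
  sh <- as.integer(rownames(ssum))
  out <- data.frame(sep = sqrt(edges[sh] * edges[sh + 1]),
                    sep_lo = edges[sh], sep_hi = edges[sh + 1],
                    raw_mean = ifelse(scnt > 0, ssum / scnt, NA_real_),
                    n_pairs = as.numeric(scnt))
  out$missing <- out$n_pairs == 0 | is.na(out$raw_mean)
  norm <- sum(out$raw_mean[!out$missing])
  out$mean <- out$raw_mean / norm
  attr(out, "norm") <- norm
  class(out) <- c("PsCurve", class(out))
  out
}

#' Log-log slope of a P(s) curve over a separation range
#'
#' @param curve a `PsCurve`.
#' @param fit_range separations (bp) to include in the least-squares fit.
#' @return list(slope, intercept, se) from `lm(log(mean) ~ log(sep))`.
#' @export
ps_slope <- function(curve, fit_range = c(1e5, 5e6)) {
  ok <- !curve$missing & curve$sep >= fit_range[1] &
    curve$sep <= fit_range[2] & curve$mean > 0
  if (sum(ok) < 3) stop("fewer than 3 usable shells in the fit range")
  fit <- stats::lm(log(curve$mean[ok]) ~ log(curve$sep[ok]))
  sm <- suppressWarnings(summary(fit))  # a perfect fit warns harmlessly
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       se = sm$coefficients[2, 2])
}

#' Separation at which two P(s) curves cross
#'
#' Finds sign changes of the log-ratio of two curves sharing shells,
#' linearly interpolated in log-log space. The smallest crossing is
#' returned; all crossings are listed. No sign change is a none-result
#' (`NA`), not an error — identical curves or curves differing by a
#' constant factor never cross.
#'
#' @return list(crossover = bp or NA, all = numeric vector of crossings).
#' @export
curve_crossover <- function(a, b) {
  if (!isTRUE(all.equal(a$sep, b$sep)))
    stop("curves do not share separation shells")
  ok <- !a$missing & !b$missing & a$mean > 0 & b$mean > 0
  ls <- log(a$sep[ok])
  ld <- log(a$mean[ok]) - log(b$mean[ok])
  crossings <- numeric(0)
  for (i in seq_len(length(ld) - 1)) {
    if (ld[i] == 0 && ld[i + 1] != 0) next
    if (ld[i] * ld[i + 1] < 0) {
      f <- ld[i] / (ld[i] - ld[i + 1])
      crossings <- c(crossings, exp(ls[i] + f * (ls[i + 1] - ls[i])))
    }
  }
  list(crossover = if (length(crossings)) min(crossings) else NA_real_,
       all = crossings)
}

#' Ratio of short-range to long-range cis contacts
#'
#' Sum of cis contact values at separation below `cutoff` (self-pairs
#' excluded) over the sum at or above `cutoff`; a pair at exactly the
#' cutoff counts as long-range.
#'
#' @param cutoff distance cutoff in bp (default 1 Mb).
#' @export
short_long_ratio <- function(matrix, arm, cutoff = 1e6) {
  ids <- arm_bin_ids(matrix$bins, arm)
  res <- bin_resolution(matrix$bins)
  t <- matrix$triplets
  t <- t[t$bin1 %in% ids & t$bin2 %in% ids & t$bin1 != t$bin2, , drop = FALSE]
  sep <- (t$bin2 - t$bin1) * res
  short <- sum(t$value[sep < cutoff])
  long <- sum(t$value[sep >= cutoff])
  if (long == 0)
    stop(sprintf("no long-range signal on %s at cutoff %g bp",
                 paste(unique(matrix$bins$chrom[matrix$bins$bin_id %in% ids]),
                       collapse = ","), cutoff))
  short / long
}

#' Per-chromosome-pair contact proportions
#'
#' For every source chromosome, the proportion of its total signal going to
#' each target chromosome (itself included); rows sum to 1 exactly.
#' Intended for raw (non-balanced) matrices at coarse resolution.
#'
#' @return data.frame (source, target, signal, proportion).
#' @export
trans_proportion_matrix <- function(matrix) {
  chroms <- unique(matrix$bins$chrom)
  if (length(chroms) < 2) stop("need at least two chromosomes")
  bc <- matrix$bins$chrom[match(matrix$triplets$bin1, matrix$bins$bin_id)]
  bc2 <- matrix$bins$chrom[match(matrix$triplets$bin2, matrix$bins$bin_id)]
  out <- expand.grid(source = chroms, target = chroms,
                     stringsAsFactors = FALSE)
  out$signal <- mapply(function(a, b) {
    sum(matrix$triplets$value[(bc == a & bc2 == b) | (bc == b & bc2 == a)])
  }, out$source, out$target)
  # total per source = cis + all trans (cis counted once)
  totals <- vapply(chroms, function(a)
    sum(out$signal[out$source == a]), numeric(1))
  out$proportion <- out$signal / totals[match(out$source, chroms)]
  out
}

#' Proportion of one chromosome's signal contacting another
#'
#' `trans_proportion(m, "chr2L", "chr2R")` is (total signal chr2L to
#' chr2R) / (total signal chr2L to all).
#' @export
trans_proportion <- function(matrix, chromA, chromB) {
  tp <- trans_proportion_matrix(matrix)
  v <- tp$proportion[tp$source == chromA & tp$target == chromB]
  if (length(v) != 1) stop("chromosome not found in bin table")
  v
}

#' Interaction strength per chromatin state at a fixed separation
#'
#' For each state, the distribution of balanced contact values over cis bin
#' pairs at exactly `separation` where both bins carry that state
#' (mixed-state pairs are excluded; implicit zeros on unmasked bins are
#' included).
#'
#' @param states per-bin state vector aligned to the matrix bins, or an
#'   interval track (chrom, start, end, state).
#' @param separation genomic separation in bp; must be a multiple of the
#'   bin resolution.
#' @return list with `values` (named list of numeric vectors per state) and
#'   `summary` (data.frame state, n, mean, median).
#' @export
state_interaction_strength <- function(matrix, states, separation) {
  res <- bin_resolution(matrix$bins)
  if (separation %% res != 0)
    stop("separation must be a multiple of the bin resolution")
  d <- as.integer(separation / res)
  st <- if (is.data.frame(states)) states_per_bin(matrix$bins, states)
        else states
  stopifnot(length(st) == nrow(matrix$bins))
  unmask <- if (is.null(matrix$weights)) rep(TRUE, nrow(matrix$bins)) else
    !is.na(matrix$weights)
  S <- cm_sparse(matrix)
  n <- nrow(matrix$bins)
  i <- seq_len(n - d)
  j <- i + d
  same_chrom <- matrix$bins$chrom[i] == matrix$bins$chrom[j]
  vals <- list()
  for (s in sort(unique(stats::na.omit(st)))) {
    sel <- same_chrom & !is.na(st[i]) & !is.na(st[j]) &
      st[i] == s & st[j] == s & unmask[i] & unmask[j]
    vals[[s]] <- as.numeric(S[cbind(i[sel], j[sel])])
  }
  summary <- data.frame(state = names(vals),
                        n = vapply(vals, length, numeric(1)),
                        mean = vapply(vals, function(v)
                          if (length(v)) mean(v) else NA_real_, numeric(1)),
                        median = vapply(vals, function(v)
                          if (length(v)) stats::median(v) else NA_real_,
                          numeric(1)))
  rownames(summary) <- NULL
  list(values = vals, summary = summary)
}

#' Mean interaction score for each pair of numbered compartments
#'
#' For every eligible compartment pair (i < j, same chromosome, midpoint
#' separation within [min_sep, max_sep]), the mean balanced contact over
#' all unmasked bin pairs (one bin from each compartment), implicit zeros
#' included. Compartment annotation comes from the CONTROL segmentation so
#' scores are comparable across conditions.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param seg a `CompartmentSegmentation` (from the control condition).
#' @param min_sep,max_sep midpoint-separation window in bp (defaults
#'   500 kb and 5 Mb).
#' @return data.frame (comp_i, type_i, comp_j, type_j, sep, mean, n_pairs).
#' @export
compartment_pair_scores <- function(matrix, seg, min_sep = 5e5,
                                    max_sep = 5e6) {
  stopifnot(min_sep < max_sep)
  # member bins of each compartment, as matrix bin ids
  members <- lapply(seq_len(nrow(seg)), function(i) {
    sel <- matrix$bins$chrom == seg$chrom[i] &
      matrix$bins$start >= seg$start[i] & matrix$bins$end <= seg$end[i]
    ids <- matrix$bins$bin_id[sel]
    if (!is.null(matrix$weights))
      ids <- ids[!is.na(matrix$weights[ids + 1L])]
    ids
  })
  mid <- (seg$start + seg$end) / 2
  S <- cm_sparse(matrix)
  out <- list()
  for (i in seq_len(nrow(seg) - 1)) {
    for (j in seq((i + 1), nrow(seg))) {
      if (seg$chrom[i] != seg$chrom[j]) next
      sep <- abs(mid[j] - mid[i])
      if (sep < min_sep || sep > max_sep) next
      bi <- members[[i]]; bj <- members[[j]]
      if (length(bi) == 0 || length(bj) == 0) {
        message(sprintf("compartment pair %d-%d skipped: empty compartment",
                        seg$number[i], seg$number[j]))
        next
      }
      tot <- sum(S[bi + 1L, bj + 1L, drop = FALSE])
      out[[length(out) + 1]] <- data.frame(
        comp_i = seg$number[i], type_i = seg$type[i],
        comp_j = seg$number[j], type_j = seg$type[j],
        sep = sep, mean = tot / (length(bi) * length(bj)),
        n_pairs = length(bi) * length(bj))
    }
  }
  if (length(out) == 0)
    return(data.frame(comp_i = integer(), type_i = character(),
                      comp_j = integer(), type_j = character(),
                      sep = numeric(), mean = numeric(),
                      n_pairs = numeric()))
  do.call(rbind, out)
}

#' Fold change of compartment-pair scores between conditions
#'
#' Per-pair knockdown/control score ratio and percent change
#' ((fold - 1) * 100); pairs with zero control mean are flagged undefined.
#'
#' @export
fold_change <- function(scores_kd, scores_ctrl) {
  m <- merge(scores_kd, scores_ctrl, by = c("comp_i", "comp_j"),
             suffixes = c("_kd", "_ctrl"))
  if (nrow(m) != nrow(scores_kd) || nrow(m) != nrow(scores_ctrl))
    stop("score tables do not share the same compartment pairs")
  m$undefined <- m$mean_ctrl == 0
  m$fold <- ifelse(m$undefined, NA_real_, m$mean_kd / m$mean_ctrl)
  m$percent_change <- (m$fold - 1) * 100
  m[, c("comp_i", "type_i_kd", "comp_j", "type_j_kd", "sep_kd",
        "mean_kd", "mean_ctrl", "fold", "percent_change", "undefined")] |>
    stats::setNames(c("comp_i", "type_i", "comp_j", "type_j", "sep",
                      "mean_kd", "mean_ctrl", "fold", "percent_change",
                      "undefined"))
}

# In-bounds box mean filter with half-window h (separable).
box_smooth <- function(M, h) {
  if (h == 0) return(M)
  run <- function(V) {
    n <- nrow(V)
    cs <- rbind(0, apply(V, 2, cumsum))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  t(run(t(run(M))))
}

#' Stratum-adjusted correlation coefficient (SCC) of two contact maps
#'
#' Per chromosome: both cis maps are smoothed with a 2D mean filter of
#' half-window `h` bins, then per-separation-stratum Pearson correlations
#' are combined with weights `N_d * sqrt(var(rank(x)) * var(rank(y)))`
#' (variance-stabilized rank weighting). `h = 0` reduces to the unsmoothed
#' stratum correlation. Identical maps give exactly 1.
#'
#' @param a,b `ContactMatrix` objects on the same bin table.
#' @param h smoothing half-window in bins (default 20).
#' @param max_sep maximum separation in bp (default 20 Mb).
#' @return list(per_chrom = data.frame(chrom, scc), aggregate, h, max_sep).
#' @export
scc <- function(a, b, h = 20, max_sep = 2e7) {
  if (!identical(a$bins[, c("chrom", "start", "end")],
                 b$bins[, c("chrom", "start", "end")]))
    stop("matrices are not on the same bin table")
  res <- bin_resolution(a$bins)
  Da <- cm_dense(a); Db <- cm_dense(b)
  per <- lapply(unique(a$bins$chrom), function(cn) {
    idx <- which(a$bins$chrom == cn)
    Ma <- box_smooth(Da[idx, idx, drop = FALSE], h)
    Mb <- box_smooth(Db[idx, idx, drop = FALSE], h)
    n <- length(idx)
    dmax <- min(n - 1, floor(max_sep / res))
    num <- 0; den <- 0
    for (d in seq_len(dmax)) {
      i <- seq_len(n - d)
      x <- Ma[cbind(i, i + d)]
      y <- Mb[cbind(i, i + d)]
      if (length(x) < 2) next
      if (!isTRUE(stats::var(x) > 0) || !isTRUE(stats::var(y) > 0)) next
      w <- length(x) * sqrt(stats::var(rank(x)) * stats::var(rank(y)))
      num <- num + w * stats::cor(x, y)
      den <- den + w
    }
    data.frame(chrom = cn, scc = if (den > 0) num / den else NA_real_)
  })
  per <- do.call(rbind, per)
  list(per_chrom = per, aggregate = mean(per$scc, na.rm = TRUE),
       h = h, max_sep = max_sep)
}
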