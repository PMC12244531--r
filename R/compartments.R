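#' Arm-wise eigenvector analysis of the observed/expected map
#'
#' Computes the first `n` principal components of the Pearson correlation
#' matrix of the arm's observed/expected cis map. Bins with degenerate
#' (constant or empty) correlation rows are masked. PC1 is oriented so that
#' bins overlapping active-state intervals have positive mean PC1 — under
#' this convention positive PC1 marks the A compartment.
#'
#' @param matrix balanced `ContactMatrix`.
#' @param arm chromosome name or list(chrom, start, end).
#' @param n number of components (>= 1).
#' @param states orientation reference: per-bin state vector aligned to the
#'   arm's bins, or a data.frame track (chrom, start, end, state) with
#'   states in {active, repressed, null}; NULL leaves PC1 unoriented.
#' @param centromere_end which end of the arm abuts the centromere
#'   ("left"/"right"); recorded for downstream P-compartment designation.
#' @param smooth_h half-window (bins) of a 2D mean filter applied to the
#'   O/E map before the correlation step, emulating super-resolution
#'   smoothing (a window twice the bin size); 0 disables.
#' @return object of class `EigenResult`: arm bin table, `pc` matrix
#'   (bins x n, NA on masked bins), `explained` variance fractions,
#'   `flipped` orientation flag.
#' @export
compute_eigenvectors <- function(matrix, arm, n = 3, states = NULL,
                                 centromere_end = "right", smooth_h = 2) {
  oe <- observed_expected(matrix, arm)
  bins <- oe$oe$bins
  nb <- nrow(bins)
  if (nb < 20) stop("arm has fewer than 20 bins")
  D <- cm_dense(oe$oe)
  if (smooth_h > 0) D <- box_smooth(D, smooth_h)
  unmask <- if (is.null(oe$oe$weights)) rep(TRUE, nb) else
    !is.na(oe$oe$weights)
  D[!unmask, ] <- NA
  D[, !unmask] <- NA
  sds <- apply(D, 2, stats::sd, na.rm = TRUE)
  good <- unmask & !is.na(sds) & sds > 0
  if (sum(good) < n)
    stop("fewer informative bins than requested components")
  C <- stats::cor(D[good, good])
  C[is.na(C)] <- 0
  eg <- eigen(C, symmetric = TRUE)
  if (sum(eg$values > 0) < n)
    stop("fewer than n informative dimensions in the correlation matrix")
  pc <- matrix(NA_real_, nb, n)
  pc[good, ] <- eg$vectors[, seq_len(n), drop = FALSE]
  explained <- eg$values[seq_len(n)] / sum(pmax(eg$values, 0))
  flipped <- NA
  if (!is.null(states)) {
    st <- if (is.data.frame(states)) states_per_bin(bins, states) else states
    act <- which(st == "active" & !is.na(pc[, 1]))
    if (length(act) > 0) {
      flipped <- mean(pc[act, 1]) < 0
      if (flipped) pc[, 1] <- -pc[, 1]
    }
  }
  structure(list(bins = bins, pc = pc, explained = explained,
                 flipped = flipped, arm = unique(bins$chrom),
                 centromere_end = centromere_end,
                 resolution = bin_resolution(bins)),
            class = "EigenResult")
}

#' Majority chromatin state per bin from an interval track
#'
#' A bin takes the state covering the majority of its bases.
#' @export
states_per_bin <- function(bins, track) {
  out <- rep(NA_character_, nrow(bins))
  for (i in seq_len(nrow(bins))) {
    tr <- track[track$chrom == bins$chrom[i] &
                  track$end > bins$start[i] & track$start < bins$end[i], ,
                drop = FALSE]
    if (nrow(tr) == 0) next
    cover <- pmin(tr$end, bins$end[i]) - pmax(tr$start, bins$start[i])
    agg <- rowsum(cover, tr$state)
    out[i] <- rownames(agg)[which.max(agg)]
  }
  out
}

# Fill NA entries with the nearest preceding value (head NAs take the
# first non-NA).
fill_na_prev <- function(x) {
  if (all(is.na(x))) return(x)
  first <- which(!is.na(x))[1]
  x[seq_len(first - 1)] <- x[first]
  for (i in seq_along(x)) if (is.na(x[i])) x[i] <- x[i - 1]
  x
}

#' Call A/B compartments from oriented PC1
#'
#' Maximal runs of same-sign PC1 spanning at least `min_len` become
#' compartments (positive = A, negative = B). Shorter runs are absorbed
#' into the larger flanking run (ties upstream) so the calls partition the
#' arm; compartments are numbered consecutively along the genome.
#'
#' @param eig an `EigenResult` with oriented PC1.
#' @param min_len minimum compartment span in bp (default 20 kb).
#' @return data.frame (number, type, chrom, start, end, n_bins) of class
#'   `CompartmentSegmentation`, with a `bin_type` attribute giving the
#'   per-bin call.
#' @export
call_compartments <- function(eig, min_len = 20000) {
  pc1 <- fill_na_prev(eig$pc[, 1])
  if (all(is.na(pc1))) {
    out <- data.frame(number = integer(), type = character(),
                      chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer())
    class(out) <- c("CompartmentSegmentation", class(out))
    return(out)
  }
  sgn <- ifelse(pc1 >= 0, 1L, -1L)
  res <- eig$resolution
  r <- rle(sgn)
  min_bins <- ceiling(min_len / res)
  # absorb runs shorter than min_len into the larger flank (ties upstream)
  repeat {
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_bins)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    up <- if (i > 1) r$lengths[i - 1] else -Inf
    down <- if (i < length(r$lengths)) r$lengths[i + 1] else -Inf
    r$values[i] <- if (up >= down) r$values[i - 1] else r$values[i + 1]
    v <- inverse.rle(r)
    r <- rle(v)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  bins <- eig$bins
  out <- data.frame(number = seq_along(r$values),
                    type = ifelse(r$values > 0, "A", "B"),
                    chrom = bins$chrom[starts],
                    start = bins$start[starts],
                    end = bins$end[ends],
                    n_bins = r$lengths)
  attr(out, "bin_type") <- ifelse(inverse.rle(r) > 0, "A", "B")
  attr(out, "bin_number") <- rep(out$number, r$lengths)
  attr(out, "bins") <- bins
  class(out) <- c("CompartmentSegmentation", class(out))
  out
}

#' Define P compartments by k-means on the first three eigenvectors
#'
#' Clusters bins in PC1-3 space with k-means (`restarts` random starts,
#' seeded). Clustering is performed arm-wise because eigenvector sign and
#' component order are arbitrary per arm; within each arm the cluster
#' whose bins lie closest, on average, to the declared centromeric end is
#' designated P, and the arm's P interval is the largest consecutive run
#' of P-cluster bins. An inertia-vs-k table (summed over arms) is attached
#' for scree inspection.
#'
#' @param eigs an `EigenResult` or list of them (one per arm).
#' @param k number of clusters (default 3: A, B, P).
#' @param seed RNG seed; identical seed and restarts give identical labels.
#' @param restarts number of k-means restarts.
#' @param scree_k_max largest k for the inertia table.
#' @return list of class `PCompartmentCall`: `assignments` (per-bin arm,
#'   coordinates, cluster, is_p), `p_cluster`, `p_intervals`, `scree`.
#' @export
kmeans_p_compartments <- function(eigs, k = 3, seed = 1L, restarts = 20,
                                  scree_k_max = 6) {
  if (inherits(eigs, "EigenResult")) eigs <- list(eigs)
  if (k == 1) warning("k = 1: single cluster, no P compartment designated")
  meta <- list()
  scree_tot <- rep(0, scree_k_max)
  p_clusters <- integer(0)
  for (ei in seq_along(eigs)) {
    e <- eigs[[ei]]
    ok <- rowSums(is.na(e$pc)) == 0
    # standardize components: eigenvector entries have arbitrary scale and
    # a noise-only component would otherwise dominate the distance metric
    X <- scale(e$pc[ok, , drop = FALSE])
    X[, attr(X, "scaled:scale") == 0] <- 0
    if (k > nrow(X)) stop("k exceeds the number of informative bins")
    arm_len <- max(e$bins$end)
    mid <- (e$bins$start + e$bins$end) / 2
    cen_dist <- if (e$centromere_end == "right") arm_len - mid else mid
    m <- data.frame(chrom = e$bins$chrom[ok], start = e$bins$start[ok],
                    end = e$bins$end[ok],
                    cen_prox = 1 - cen_dist[ok] / arm_len)
    set.seed(stage_seed(seed, paste0("kmeans_", ei)))
    km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100)
    kk_max <- min(scree_k_max, nrow(X) - 1)
    for (kk in seq_len(kk_max)) {
      set.seed(stage_seed(seed, paste0("kmeans_", ei)))
      scree_tot[kk] <- scree_tot[kk] +
        stats::kmeans(X, centers = kk, nstart = restarts,
                      iter.max = 100)$tot.withinss
    }
    if (k == 1) {
      p_cl <- NA_integer_
    } else {
      prox <- tapply(m$cen_prox, km$cluster, mean)
      p_cl <- as.integer(names(prox)[which.max(prox)])
    }
    m$cluster <- km$cluster
    m$is_p <- !is.na(p_cl) & km$cluster == p_cl
    meta[[ei]] <- m
    p_clusters <- c(p_clusters, p_cl)
  }
  meta <- do.call(rbind, meta)
  p_intervals <- NULL
  if (any(meta$is_p)) {
    p_intervals <- do.call(rbind, lapply(split(meta, meta$chrom), function(m) {
      m <- m[order(m$start), ]
      r <- rle(m$is_p)
      if (!any(r$values)) return(NULL)
      ends <- cumsum(r$lengths); starts <- c(1, head(ends, -1) + 1)
      runs <- which(r$values)
      best <- runs[which.max(r$lengths[runs])]
      data.frame(chrom = m$chrom[1], start = m$start[starts[best]],
                 end = m$end[ends[best]])
    }))
    rownames(p_intervals) <- NULL
  }
  structure(list(assignments = meta, p_cluster = p_clusters,
                 p_intervals = p_intervals,
                 scree = data.frame(k = seq_len(scree_k_max),
                                    inertia = scree_tot),
                 k = k, seed = seed, restarts = restarts),
            class = "PCompartmentCall")
}
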