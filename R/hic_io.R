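#' Build a uniform bin table over a genome
#'
#' Tiles each chromosome with consecutive bins of width `resolution`
#' (0-based half-open coordinates); the last bin of a chromosome may be
#' shorter. Bin ids are dense integers `0..N-1` over the whole genome in
#' the order the chromosomes are given.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param resolution bin width in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `bin_id` and a
#'   `resolution` attribute.
#' @export
bin_table <- function(chrom_lengths, resolution) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            resolution >= 1)
  rows <- lapply(names(chrom_lengths), function(cn) {
    len <- chrom_lengths[[cn]]
    starts <- seq(0, len - 1, by = resolution)
    data.frame(chrom = cn, start = starts,
               end = pmin(starts + resolution, len))
  })
  bins <- do.call(rbind, rows)
  bins$bin_id <- seq_len(nrow(bins)) - 1L
  rownames(bins) <- NULL
  attr(bins, "resolution") <- resolution
  bins
}

#' @export
bin_resolution <- function(bins) attr(bins, "resolution")

validate_bins <- function(bins) {
  stopifnot(all(c("chrom", "start", "end", "bin_id") %in% names(bins)))
  stopifnot(identical(as.integer(bins$bin_id), seq_len(nrow(bins)) - 1L))
  for (cn in unique(bins$chrom)) {
    b <- bins[bins$chrom == cn, ]
    stopifnot(all(b$end > b$start))
    if (nrow(b) > 1) stopifnot(all(b$start[-1] == b$end[-nrow(b)]))
  }
  invisible(bins)
}

#' Construct a sparse symmetric contact matrix
#'
#' Only the upper triangle (`bin1 <= bin2`) is stored; entries with
#' `bin1 > bin2` are folded and duplicate pairs are summed, which tolerates
#' dialects that emit both triangles.
#'
#' @param bins bin table from [bin_table()] or read from disk.
#' @param triplets data.frame with columns `bin1`, `bin2`, `value`.
#' @param normalization `"raw"` or `"balanced"`.
#' @param weights per-bin balancing weights (`NA` = masked), or NULL.
#' @return object of class `ContactMatrix`.
#' @export
contact_matrix <- function(bins, triplets, normalization = "raw",
                           weights = NULL) {
  validate_bins(bins)
  n <- nrow(bins)
  stopifnot(all(c("bin1", "bin2", "value") %in% names(triplets)))
  if (nrow(triplets) > 0) {
    if (any(triplets$bin1 < 0 | triplets$bin1 >= n |
            triplets$bin2 < 0 | triplets$bin2 >= n))
      stop("triplet references a bin id outside the bin table")
    if (any(triplets$value < 0))
      stop("negative contact value")
    swap <- triplets$bin1 > triplets$bin2
    if (any(swap)) {
      tmp <- triplets$bin1[swap]
      triplets$bin1[swap] <- triplets$bin2[swap]
      triplets$bin2[swap] <- tmp
    }
    key <- triplets$bin1 * n + triplets$bin2
    if (anyDuplicated(key)) {
      agg <- rowsum(triplets$value, key, reorder = TRUE)
      k <- as.numeric(rownames(agg))
      triplets <- data.frame(bin1 = k %/% n, bin2 = k %% n,
                             value = as.numeric(agg))
    }
    triplets <- triplets[order(triplets$bin1, triplets$bin2), , drop = FALSE]
    triplets <- triplets[triplets$value != 0, , drop = FALSE]
  }
  rownames(triplets) <- NULL
  structure(list(bins = bins, triplets = triplets,
                 normalization = normalization, weights = weights),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins (%s), %d nonzero pairs, %s\n",
              nrow(x$bins), paste(unique(x$bins$chrom), collapse = ","),
              nrow(x$triplets), x$normalization))
  invisible(x)
}

#' Read a contact matrix from bin-table and triplet text files
#'
#' The bin table is BED3+1 (`chrom start end bin_id`, tab-separated); the
#' triplet file has three whitespace-separated columns `bin_i bin_j value`.
#' Lower-triangle entries are folded into the upper triangle (summed when
#' the same pair occurs twice).
#'
#' @param bins_path path to the bin table.
#' @param triplets_path path to the triplet file.
#' @return a `ContactMatrix` with `normalization = "raw"`.
#' @export
read_contacts <- function(bins_path, triplets_path) {
  stopifnot(file.exists(bins_path), file.exists(triplets_path))
  bins <- utils::read.table(bins_path, sep = "\t",
                            col.names = c("chrom", "start", "end", "bin_id"),
                            colClasses = c("character", "numeric", "numeric",
                                           "integer"))
  widths <- bins$end - bins$start
  attr(bins, "resolution") <- max(widths)
  tri <- utils::read.table(triplets_path,
                           col.names = c("bin1", "bin2", "value"))
  contact_matrix(bins, tri, normalization = "raw")
}

#' Write a contact matrix to bin-table and triplet text files
#' @export
write_contacts <- function(matrix, bins_path, triplets_path) {
  utils::write.table(matrix$bins[, c("chrom", "start", "end", "bin_id")],
                     bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(matrix$triplets, triplets_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(matrix)
}

#' Write a per-bin track as bedGraph
#' @export
write_bedgraph <- function(bins, values, path) {
  keep <- is.finite(values)
  utils::write.table(cbind(bins[keep, c("chrom", "start", "end")],
                           value = values[keep]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Full symmetric sparse representation (diagonal stored once).
cm_sparse <- function(matrix) {
  n <- nrow(matrix$bins)
  t <- matrix$triplets
  Matrix::sparseMatrix(i = t$bin1 + 1L, j = t$bin2 + 1L, x = t$value,
                       dims = c(n, n), symmetric = TRUE)
}

# Dense symmetric matrix; masked bins become NA rows/columns if requested.
cm_dense <- function(matrix, na_masked = FALSE) {
  m <- as.matrix(cm_sparse(matrix))
  if (na_masked && !is.null(matrix$weights)) {
    bad <- which(is.na(matrix$weights))
    m[bad, ] <- NA_real_
    m[, bad] <- NA_real_
  }
  m
}

#' Balance a contact matrix by iterative correction
#'
#' Enforces the balanced-marginal property: every unmasked bin's genome-wide
#' marginal (row sum of the symmetric matrix) equals 1 within `tol` after
#' convergence. Bins with zero raw marginal, or whose nonzero-entry count is
#' below `mask_frac` of the densest bin's, are masked and carry no triplets
#' afterwards.
#'
#' @param matrix a raw `ContactMatrix`.
#' @param tol maximum relative marginal deviation at convergence.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   last deviation.
#' @param mask_frac sparsity floor relative to the densest bin.
#' @return a `ContactMatrix` with `normalization = "balanced"` and per-bin
#'   `weights` (`NA` for masked bins); balanced value = raw * w_i * w_j.
#' @export
balance <- function(matrix, tol = 1e-8, max_iter = 2000, mask_frac = 0.02) {
  stopifnot(matrix$normalization == "raw", tol > 0)
  n <- nrow(matrix$bins)
  S <- cm_sparse(matrix)
  nnz <- Matrix::rowSums(S != 0)
  masked <- nnz == 0 | nnz < mask_frac * max(nnz)
  w <- ifelse(masked, 0, 1)
  dev <- Inf
  for (it in seq_len(max_iter)) {
    m <- w * as.numeric(S %*% w)
    mu <- mean(m[!masked])
    if (mu == 0) stop("matrix has no signal on unmasked bins")
    dev <- max(abs(m[!masked] / mu - 1))
    if (dev < tol) break
    adj <- ifelse(masked, 1, m / mu)
    adj[adj == 0] <- 1
    w <- w / sqrt(adj)
  }
  if (dev >= tol)
    stop(sprintf(
      "balancing did not converge in %d iterations (max marginal deviation %.3g)",
      max_iter, dev))
  # rescale so marginals are exactly ~1
  m <- w * as.numeric(S %*% w)
  w <- w / sqrt(mean(m[!masked]))
  t <- matrix$triplets
  keep <- !masked[t$bin1 + 1L] & !masked[t$bin2 + 1L]
  t <- t[keep, , drop = FALSE]
  t$value <- t$value * w[t$bin1 + 1L] * w[t$bin2 + 1L]
  weights <- ifelse(masked, NA_real_, w)
  contact_matrix(matrix$bins, t, normalization = "balanced",
                 weights = weights)
}

# Bins of an arm: a list/row with chrom, start, end (or just chrom).
arm_bin_ids <- function(bins, arm) {
  if (is.character(arm)) arm <- list(chrom = arm, start = 0, end = Inf)
  sel <- bins$chrom == arm$chrom & bins$start >= arm$start &
    bins$end <= arm$end
  if (!any(sel)) stop("arm overlaps no bins in the bin table")
  bins$bin_id[sel]
}

#' Observed/expected transform of the cis map of one arm
#'
#' Divides each cis entry by the mean balanced contact of its diagonal
#' within the arm. Diagonal means count every unmasked bin pair of the
#' diagonal (implicit zeros included); diagonals with no unmasked pairs or
#' no signal are flagged missing, never zero-filled.
#'
#' @param matrix a balanced `ContactMatrix`.
#' @param arm chromosome name or list(chrom, start, end) within one
#'   chromosome.
#' @return list with `oe` (a `ContactMatrix` restricted to the arm) and
#'   `expected` (data.frame `sep`, `mean`, `n_pairs`, `missing`).
#' @export
observed_expected <- function(matrix, arm) {
  ids <- arm_bin_ids(matrix$bins, arm)
  n_arm <- length(ids)
  res <- bin_resolution(matrix$bins)
  unmask <- if (is.null(matrix$weights)) rep(TRUE, n_arm) else
    !is.na(matrix$weights[ids + 1L])
  t <- matrix$triplets
  t <- t[t$bin1 %in% ids & t$bin2 %in% ids, , drop = FALSE]
  pos <- match(t$bin1, ids)  # 1-based position within the arm
  pos2 <- match(t$bin2, ids)
  d <- pos2 - pos
  sums <- rep(0, n_arm)
  sl <- rowsum(t$value, d)
  sums[as.integer(rownames(sl)) + 1L] <- as.numeric(sl)
  # unmasked pair count per diagonal
  npairs <- vapply(0:(n_arm - 1), function(dd) {
    i <- seq_len(n_arm - dd)
    sum(unmask[i] & unmask[i + dd])
  }, numeric(1))
  mean_d <- ifelse(npairs > 0, sums / npairs, NA_real_)
  missing <- npairs == 0 | mean_d == 0 | is.na(mean_d)
  ed <- mean_d[d + 1L]
  keep <- !missing[d + 1L]
  oe_t <- data.frame(bin1 = t$bin1[keep], bin2 = t$bin2[keep],
                     value = t$value[keep] / ed[keep])
  arm_bins <- matrix$bins[matrix$bins$bin_id %in% ids, , drop = FALSE]
  arm_bins$bin_id <- seq_len(nrow(arm_bins)) - 1L
  attr(arm_bins, "resolution") <- res
  oe_t$bin1 <- match(t$bin1[keep], ids) - 1L
  oe_t$bin2 <- match(t$bin2[keep], ids) - 1L
  w <- if (is.null(matrix$weights)) NULL else matrix$weights[ids + 1L]
  oe <- contact_matrix(arm_bins, oe_t, normalization = matrix$normalization,
                       weights = w)
  expected <- data.frame(sep = (0:(n_arm - 1)) * res, mean = mean_d,
                         n_pairs = npairs, missing = missing)
  list(oe = oe, expected = expected)
}

#' Coarsen a contact matrix by an integer factor
#'
#' Groups `factor` consecutive bins per chromosome into one bin and sums
#' their contact values; total genome-wide signal is conserved exactly.
#'
#' @export
coarsen <- function(matrix, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(matrix)
  bins <- matrix$bins
  res <- bin_resolution(bins)
  map <- integer(nrow(bins))
  new_rows <- list()
  off <- 0L
  for (cn in unique(bins$chrom)) {
    b <- bins[bins$chrom == cn, ]
    grp <- (seq_len(nrow(b)) - 1L) %/% factor
    map[b$bin_id + 1L] <- grp + off
    starts <- tapply(b$start, grp, min)
    ends <- tapply(b$end, grp, max)
    new_rows[[cn]] <- data.frame(chrom = cn, start = as.numeric(starts),
                                 end = as.numeric(ends))
    off <- off + max(grp) + 1L
  }
  nb <- do.call(rbind, new_rows)
  nb$bin_id <- seq_len(nrow(nb)) - 1L
  rownames(nb) <- NULL
  attr(nb, "resolution") <- res * factor
  t <- matrix$triplets
  t$bin1 <- map[t$bin1 + 1L]
  t$bin2 <- map[t$bin2 + 1L]
  contact_matrix(nb, t, normalization = matrix$normalization)
}

#' Total contact signal of a matrix
#' @export
total_signal <- function(matrix) sum(matrix$triplets$value)

#' Rescale contact values so the genome-wide total equals `target`
#' @export
scale_total <- function(matrix, target = 1) {
  tot <- total_signal(matrix)
  if (tot == 0) stop("matrix has no signal")
  matrix$triplets$value <- matrix$triplets$value * (target / tot)
  matrix
}
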