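# Shared fixtures: everything is built in code at test time.

# tiny bin table over one or two chromosomes
toy_bins <- function(n = 4, resolution = 5000, chroms = "chr1") {
  lens <- stats::setNames(rep(n * resolution / length(chroms), length(chroms)),
                          chroms)
  bin_table(lens, resolution)
}

# dense symmetric matrix -> ContactMatrix
cm_from_dense <- function(M, bins, normalization = "raw", weights = NULL) {
  ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(bins,
                 data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                            value = M[ut]),
                 normalization = normalization, weights = weights)
}

dense_of <- function(cm) {
  n <- nrow(cm$bins)
  M <- matrix(0, n, n)
  for (r in seq_len(nrow(cm$triplets))) {
    i <- cm$triplets$bin1[r] + 1; j <- cm$triplets$bin2[r] + 1
    M[i, j] <- M[i, j] + cm$triplets$value[r]
    if (i != j) M[j, i] <- M[j, i] + cm$triplets$value[r]
  }
  M
}

# small synthetic genome (two 2 Mb arms, 20 kb bins -> 200 bins total)
small_spec <- function() {
  synthetic_genome_spec(
    arms = data.frame(name = c("aL", "aR"), length = c(2e6, 2e6),
                      centromere_end = c("right", "left")),
    resolution = 2e4, block_size = 2e5, p_len = 4e5)
}

# independent iterative proportional fitting oracle on a dense matrix;
# returns the balanced dense matrix with unit mean marginal
ipf_oracle <- function(M, iters = 500) {
  w <- rep(1, nrow(M))
  for (it in seq_len(iters)) {
    m <- w * as.numeric(M %*% w)
    w <- w / sqrt(m / mean(m))
  }
  m <- w * as.numeric(M %*% w)
  w <- w / sqrt(mean(m))
  M * outer(w, w)
}

sample_and_balance <- function(expected, depth, seed) {
  balance(sample_contacts(expected, depth, seed = seed))
}

# minimal TadBoundarySet for classification tests
boundary_set <- function(pos, chrom = "chr1") {
  pos <- sort(pos)
  domains <- if (length(pos) >= 2)
    data.frame(chrom = chrom, start = pos[-length(pos)], end = pos[-1],
               size = diff(pos))
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  size = numeric())
  structure(list(boundaries = data.frame(chrom = chrom, pos = pos),
                 domains = domains),
            class = "TadBoundarySet")
}

# minimal EigenResult carrying an oriented PC1
make_eig <- function(pc1, resolution = 5000, chrom = "chr1") {
  n <- length(pc1)
  bins <- bin_table(stats::setNames(n * resolution, chrom), resolution)
  pc <- cbind(pc1, 0, 0)
  structure(list(bins = bins, pc = pc, explained = c(NA, NA, NA),
                 flipped = FALSE, arm = chrom, centromere_end = "right",
                 resolution = resolution),
            class = "EigenResult")
}
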