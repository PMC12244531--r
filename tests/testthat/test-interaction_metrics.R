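test_that("P(s) slope recovers a planted decay exponent", {
  sp <- small_spec()
  em <- expected_map(sp, generator_model(), 1)
  body <- list(chrom = "aL", start = 0, end = 1.6e6)
  curve <- ps_curve(em, body)
  fit <- ps_slope(curve, fit_range = c(4e4, 8e5))
  expect_equal(fit$slope, -1, tolerance = 0.05)
  # per-shell pair counts account for every cis pair
  n_arm <- sum(em$bins$chrom == "aL" & em$bins$end <= 1.6e6)
  full <- ps_curve(em, body)
  expect_equal(sum(full$n_pairs), n_arm * (n_arm - 1) / 2)
})

test_that("a constant matrix gives a flat P(s) curve", {
  bins <- toy_bins(50)
  M <- matrix(1, 50, 50)
  cm <- cm_from_dense(M, bins, normalization = "balanced")
  fit <- ps_slope(ps_curve(cm, "chr1"), fit_range = c(5e3, 3e5))
  expect_equal(fit$slope, 0, tolerance = 1e-10)
})

test_that("curve crossover locates the closed-form crossing", {
  bins <- toy_bins(400, resolution = 5000)
  s_star <- 1e5
  # two exact power laws crossing at s*: a = s^-0.8, b = (s*/s)^0.4 * s^-0.8...
  # construct directly on shell values from one template curve
  M <- outer(1:400, 1:400, function(i, j)
    ifelse(i == j, 1, (abs(i - j) * 5000)^(-0.8)))
  ca <- ps_curve(cm_from_dense(M, bins, "balanced"), "chr1")
  cb <- ca
  # scale b so log b = -1.2 log s + c with equality at s*
  cb$mean <- cb$mean * (cb$sep / s_star)^(-0.4) * 1
  cr <- curve_crossover(ca, cb)
  expect_equal(cr$crossover, s_star, tolerance = 0.02)
  # identical curves and constant offsets never cross
  expect_true(is.na(curve_crossover(ca, ca)$crossover))
  off <- ca; off$mean <- off$mean * 3
  expect_true(is.na(curve_crossover(ca, off)$crossover))
})

test_that("short/long ratio uses the >= 1 Mb convention", {
  bins <- toy_bins(300, resolution = 1e4)
  t <- data.frame(bin1 = c(0L, 0L), bin2 = c(50L, 200L),
                  value = c(30, 10))  # separations 0.5 Mb and 2 Mb
  cm <- contact_matrix(bins, t, "balanced")
  expect_equal(short_long_ratio(cm, "chr1"), 3)
  # a pair at exactly the cutoff counts as long-range
  t2 <- data.frame(bin1 = c(0L, 0L), bin2 = c(50L, 100L), value = c(30, 10))
  expect_equal(short_long_ratio(contact_matrix(bins, t2, "balanced"), "chr1"), 3)
  t3 <- data.frame(bin1 = 0L, bin2 = 10L, value = 5)
  expect_error(short_long_ratio(contact_matrix(bins, t3, "balanced"), "chr1"),
               "long-range")
})

test_that("short/long ratio decreases strictly with condensin level", {
  sp <- small_spec()
  m <- generator_model()
  r <- vapply(c(0.5, 1, 2), function(l)
    short_long_ratio(expected_map(sp, m, l), "aL"), numeric(1))
  expect_true(all(diff(r) < 0))
})

test_that("trans proportions are normalized per source chromosome", {
  bins <- toy_bins(8, resolution = 5e5, chroms = c("cA", "cB"))
  t <- data.frame(bin1 = c(0L, 1L, 4L, 5L, 0L, 1L),
                  bin2 = c(1L, 2L, 5L, 6L, 4L, 6L),
                  value = c(60, 40, 70, 30, 25, 25))
  cm <- contact_matrix(bins, t)
  expect_equal(trans_proportion(cm, "cA", "cB"), 50 / 150)
  tp <- trans_proportion_matrix(cm)
  for (src in c("cA", "cB"))
    expect_equal(sum(tp$proportion[tp$source == src]), 1)
  one <- contact_matrix(toy_bins(4), data.frame(bin1 = 0L, bin2 = 1L, value = 1))
  expect_error(trans_proportion_matrix(one), "two chromosomes")
})

test_that("trans proportion decreases strictly with condensin level", {
  sp <- small_spec()
  m <- generator_model()
  tp <- vapply(c(0.5, 1, 2), function(l) {
    em <- expected_map(sp, m, l)
    trans_proportion(coarsen(contact_matrix(em$bins, em$triplets), 25),
                     "aL", "aR")
  }, numeric(1))
  expect_true(all(diff(tp) < 0))
})

test_that("state-stratified strengths keep only same-state pairs", {
  bins <- toy_bins(6, resolution = 1e5)
  st <- c("active", "active", "null", "null", "null", "active")
  M <- matrix(0, 6, 6)
  M[1, 2] <- 4; M[3, 4] <- 7; M[2, 3] <- 9  # last pair is mixed-state
  M <- M + t(M)
  cm <- cm_from_dense(M, bins, "balanced")
  res <- state_interaction_strength(cm, st, 1e5)
  expect_equal(res$values$active, 4)
  expect_equal(res$values$null, c(7, 0))  # includes the implicit zero pair
  expect_false(9 %in% unlist(res$values))
  expect_error(state_interaction_strength(cm, st, 1.5e5), "multiple")
})

test_that("same-compartment pairs beat mixed pairs on synthetic maps", {
  sp <- small_spec()
  gt <- ground_truth(sp)
  em <- expected_map(sp, generator_model(), 1)
  out <- state_interaction_strength(em, gt$states, 4e4)
  # generator oracle: A-A affinity 1.5 vs A-B 0.7 at equal separation
  D <- dense_of(em)
  lab <- as.character(gt$labels)
  d <- 4e4 / sp$resolution
  i <- seq_len(nrow(gt$bins) - d); j <- i + d
  cis <- gt$bins$chrom[i] == gt$bins$chrom[j]
  mixed <- cis & ((lab[i] == "A" & lab[j] == "B") |
                    (lab[i] == "B" & lab[j] == "A"))
  expect_gt(out$summary$mean[out$summary$state == "active"],
            mean(D[cbind(i[mixed], j[mixed])]))
})

test_that("compartment-pair scores match exhaustive enumeration", {
  bins <- toy_bins(30, resolution = 1e5)
  set.seed(13)
  M <- matrix(runif(900, 0, 2), 30, 30); M <- (M + t(M)) / 2
  cm <- cm_from_dense(M, bins, "balanced")
  seg <- data.frame(number = 1:3, type = c("A", "B", "A"),
                    chrom = "chr1",
                    start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6))
  sc <- compartment_pair_scores(cm, seg, min_sep = 5e5, max_sep = 5e6)
  # brute-force oracle over dense matrix
  for (r in seq_len(nrow(sc))) {
    bi <- which(bins$start >= seg$start[sc$comp_i[r]] &
                  bins$end <= seg$end[sc$comp_i[r]])
    bj <- which(bins$start >= seg$start[sc$comp_j[r]] &
                  bins$end <= seg$end[sc$comp_j[r]])
    expect_equal(sc$mean[r], mean(M[bi, bj]), tolerance = 1e-10)
  }
  # midpoint-separation window: pairs beyond max_sep excluded
  seg2 <- rbind(seg, data.frame(number = 4, type = "B", chrom = "chr1",
                                start = 2.9e6, end = 3e6))
  sc2 <- compartment_pair_scores(cm, seg2, min_sep = 5e5, max_sep = 1.5e6)
  expect_false(any(sc2$comp_i == 1 & sc2$comp_j == 4))
  expect_true(all(sc2$sep >= 5e5 & sc2$sep <= 1.5e6))
})

test_that("fold changes are 1 for identical conditions and track the planted direction", {
  bins <- toy_bins(30, resolution = 1e5)
  set.seed(14)
  M <- matrix(runif(900, 0, 2), 30, 30); M <- (M + t(M)) / 2
  cm <- cm_from_dense(M, bins, "balanced")
  seg <- data.frame(number = 1:3, type = c("A", "B", "A"), chrom = "chr1",
                    start = c(0, 1e6, 2e6), end = c(1e6, 2e6, 3e6))
  sc <- compartment_pair_scores(cm, seg, 5e5, 5e6)
  fc <- fold_change(sc, sc)
  expect_true(all(fc$fold == 1))
  expect_true(all(fc$percent_change == 0))
  cm2 <- cm; cm2$triplets$value <- cm2$triplets$value * 2
  fc2 <- fold_change(compartment_pair_scores(cm2, seg, 5e5, 5e6), sc)
  expect_true(all(abs(fc2$fold - 2) < 1e-12))
  expect_true(all(abs(fc2$percent_change - 100) < 1e-9))
})

test_that("long-range compartment fold change follows condensin level", {
  sp <- small_spec()
  m <- generator_model()
  gt <- ground_truth(sp)
  ems <- lapply(c(0.5, 1, 2), function(l)
    scale_total(expected_map(sp, m, l), 1e6))
  eig <- compute_eigenvectors(ems[[2]], "aL",
                              states = gt$states[gt$bins$chrom == "aL"],
                              centromere_end = "right")
  seg <- call_compartments(eig)
  sc <- lapply(ems, function(e)
    compartment_pair_scores(e, seg, min_sep = 4e5, max_sep = 1.6e6))
  fc_hi <- fold_change(sc[[3]], sc[[2]])
  fc_lo <- fold_change(sc[[1]], sc[[2]])
  long <- fc_hi$sep >= 1e6
  expect_gt(mean(fc_hi$fold[long]), 1)
  expect_lt(mean(fc_lo$fold[fc_lo$sep >= 1e6]), 1)
})

test_that("SCC is exact on identities and reduces to stratum correlation at h=0", {
  bins <- toy_bins(60, resolution = 1e4)
  set.seed(15)
  M <- matrix(rpois(3600, 4) * exp(-abs(row(matrix(0, 60, 60)) -
                                          col(matrix(0, 60, 60))) / 20), 60, 60)
  M <- (M + t(M)) / 2
  a <- cm_from_dense(M, bins, "balanced")
  expect_equal(scc(a, a, h = 5)$aggregate, 1, tolerance = 1e-12)
  # symmetry and bounds
  set.seed(16)
  M2 <- M * matrix(runif(3600, 0.5, 1.5), 60, 60)
  M2 <- (M2 + t(M2)) / 2
  b <- cm_from_dense(M2, bins, "balanced")
  s_ab <- scc(a, b, h = 3)$aggregate
  expect_equal(s_ab, scc(b, a, h = 3)$aggregate)
  expect_lte(abs(s_ab), 1)
  # h = 0 equals a direct per-diagonal weighted correlation oracle
  s0 <- scc(a, b, h = 0, max_sep = 3e5)$aggregate
  num <- 0; den <- 0
  for (d in 1:30) {
    i <- seq_len(60 - d)
    x <- M[cbind(i, i + d)]; y <- M2[cbind(i, i + d)]
    if (var(x) == 0 || var(y) == 0) next
    w <- length(x) * sqrt(var(rank(x)) * var(rank(y)))
    num <- num + w * cor(x, y); den <- den + w
  }
  expect_equal(s0, num / den, tolerance = 1e-12)
})

test_that("SCC of a shuffled map is near zero", {
  bins <- toy_bins(500, resolution = 1e4)
  set.seed(17)
  M <- outer(1:500, 1:500, function(i, j) 1 / (1 + abs(i - j))) *
    matrix(rpois(250000, 10), 500, 500)
  M <- (M + t(M)) / 2
  a <- cm_from_dense(M, bins, "balanced")
  perm <- sample(500)
  b <- cm_from_dense(M[perm, perm], bins, "balanced")
  expect_lt(abs(scc(a, b, h = 0, max_sep = 2e6)$aggregate), 0.1)
})
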