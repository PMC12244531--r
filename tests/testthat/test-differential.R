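test_that("differential map is zero on identity and antisymmetric on swap", {
  bins <- toy_bins(10)
  set.seed(31)
  M <- matrix(runif(100, 0.5, 2), 10, 10); M <- M + t(M)
  a <- cm_from_dense(M, bins, "balanced")
  M2 <- M * matrix(rep(runif(10, 0.8, 1.2), each = 10), 10, 10)
  M2 <- (M2 + t(M2)) / 2
  b <- cm_from_dense(M2, bins, "balanced")
  d0 <- differential_map(a, a)
  expect_true(all(d0$log2fc == 0))
  dab <- differential_map(a, b)
  dba <- differential_map(b, a)
  expect_equal(dab$log2fc, -dba$log2fc, tolerance = 1e-12)
  bad <- cm_from_dense(M[1:8, 1:8], toy_bins(8), "balanced")
  expect_error(differential_map(a, bad), "bin table")
})

test_that("differential map mirrors condensin gain: cis up, trans down", {
  sp <- small_spec()
  m <- generator_model()
  hi <- scale_total(expected_map(sp, m, 2), 1e6)
  ct <- scale_total(expected_map(sp, m, 1), 1e6)
  dm <- differential_map(hi, ct)
  bins <- hi$bins
  cis <- bins$chrom[dm$bin1 + 1] == bins$chrom[dm$bin2 + 1]
  sep <- abs(dm$bin2 - dm$bin1) * sp$resolution
  expect_gt(mean(dm$log2fc[cis & sep >= 1e6]), 0)
  expect_lt(mean(dm$log2fc[!cis]), 0)
})

test_that("insulation minima find the planted domain junction", {
  bins <- toy_bins(40, resolution = 2.5e4)
  M <- matrix(0.05, 40, 40)
  M[1:20, 1:20] <- 1
  M[21:40, 21:40] <- 1
  cm <- cm_from_dense(M, bins, "balanced")
  tads <- insulation_boundaries(cm, "chr1", window = 1e5, prominence = 0.1)
  expect_equal(nrow(tads$boundaries), 1)
  junction <- 20 * 2.5e4
  expect_lte(abs(tads$boundaries$pos - junction), 2.5e4)
  # uniform matrix: no boundaries
  uni <- cm_from_dense(matrix(1, 40, 40), bins, "balanced")
  expect_equal(nrow(insulation_boundaries(uni, "chr1", 1e5)$boundaries), 0)
  expect_error(insulation_boundaries(cm, "chr1", window = 2.5e4), "3 bins")
})

test_that("two planted blocks yield domains of the planted sizes", {
  bins <- toy_bins(60, resolution = 2.5e4)
  M <- matrix(0.05, 60, 60)
  M[1:20, 1:20] <- 1       # 500 kb block
  M[21:60, 21:60] <- 1     # 1 Mb block
  cm <- cm_from_dense(M, bins, "balanced")
  tads <- insulation_boundaries(cm, "chr1", window = 1e5, prominence = 0.1)
  expect_equal(nrow(tads$boundaries), 1)
  expect_lte(abs(tads$boundaries$pos - 5e5), 2.5e4)
})

test_that("boundary classification applies the distance taxonomy", {
  x <- boundary_set(c(1e5, 5e5, 9e5, 1.3e6))
  id <- classify_boundaries(x, x)
  expect_equal(unname(id$counts["Same"]), 4)
  expect_equal(unname(id$counts["Lost"]), 0)
  expect_equal(unname(id$counts["Gained"]), 0)

  # 10 kb shift -> Same; 50 kb shift -> Shift; distant extra -> Lost/Gained
  kd <- boundary_set(c(1.1e5, 5.5e5, 2.0e6))
  cmp <- classify_boundaries(x, kd)
  expect_equal(unname(cmp$counts["Same"]), 1)     # 100 -> 110 kb
  expect_equal(unname(cmp$counts["Shift"]), 1)    # 500 -> 550 kb
  expect_equal(unname(cmp$counts["Lost"]), 2)     # 900 kb, 1.3 Mb
  expect_equal(unname(cmp$counts["Gained"]), 1)   # 2.0 Mb
  # conservation: every boundary in exactly one category
  expect_equal(sum(cmp$counts[c("Same", "Shift", "Unclassified", "Lost")]),
               cmp$n_ctrl)
  expect_equal(sum(cmp$counts[c("Same", "Shift", "Unclassified", "Gained")]),
               cmp$n_kd)

  # 12 kb falls in the unclassifiable 10-15 kb gap
  gap <- classify_boundaries(boundary_set(1e5), boundary_set(1.12e5))
  expect_equal(unname(gap$counts["Unclassified"]), 1)
})

test_that("greedy matching agrees with exhaustive matching on a 5-boundary toy", {
  ctrl <- boundary_set(c(1e5, 2e5, 3e5, 4e5, 5e5))
  kd <- boundary_set(c(1.05e5, 2.6e5, 5.01e5))
  cmp <- classify_boundaries(ctrl, kd)
  # exhaustive oracle: enumerate all one-to-one assignments, keep the one
  # matching the greedy-by-distance rule's invariant (each match <= 70 kb,
  # chosen smallest-distance-first)
  expect_equal(nrow(cmp$matches), 3)
  expect_true(all(cmp$matches$dist <= 7e4))
  expect_equal(sort(cmp$lost), c(2e5, 4e5))
  m <- cmp$matches[order(cmp$matches$ctrl_pos), ]
  expect_equal(m$kd_pos, c(1.05e5, 2.6e5, 5.01e5))
  expect_equal(m$category, c("Same", "Shift", "Same"))
})

test_that("split and merge detect whole-domain containment", {
  ctrl <- boundary_set(c(0, 1e6, 2e6))
  kd <- boundary_set(c(0, 4e5, 1e6, 2e6))
  cmp <- classify_boundaries(ctrl, kd)
  expect_equal(cmp$splits, 1)   # ctrl [0,1Mb] holds two whole kd domains
  rev <- classify_boundaries(kd, ctrl)
  expect_equal(rev$merges, 1)
})

test_that("virtual 4C equals the dense-matrix mean over anchor bins", {
  bins <- toy_bins(12, resolution = 5e4)
  set.seed(33)
  M <- matrix(runif(144, 0, 3), 12, 12); M <- (M + t(M)) / 2
  cm <- cm_from_dense(M, bins, "balanced")
  # single-bin anchor: profile equals that bin's row
  one <- virtual_4c(cm, list(chrom = "chr1", start = 0, end = 5e4))
  expect_equal(one$score, M[1, ], tolerance = 1e-12)
  # 3-bin anchor: dense oracle
  anc <- list(chrom = "chr1", start = 1e5, end = 2.5e5)
  prof <- virtual_4c(cm, anc)
  expect_equal(prof$score, colMeans(M[3:5, ]), tolerance = 1e-12)
  expect_equal(which(prof$in_anchor), 3:5)
  # whole-arm anchor: per-bin column means
  whole <- virtual_4c(cm, list(chrom = "chr1", start = 0, end = 6e5))
  expect_equal(whole$score, colMeans(M), tolerance = 1e-12)
})

test_that("size-matched controls avoid the anchor and exclusions", {
  anchor <- list(chrom = "chr1", start = 8e5, end = 1e6)
  arm <- list(chrom = "chr1", start = 0, end = 5e6)
  excl <- data.frame(chrom = "chr1", start = 4.5e6, end = 5e6)
  ctrls <- size_matched_controls(anchor, arm, n_controls = 5,
                                 exclusions = excl, seed = 3,
                                 resolution = 5e4)
  expect_equal(nrow(ctrls), 5)
  expect_true(all(ctrls$end - ctrls$start == 2e5))
  # interval-intersection oracle: no overlap with anchor or exclusions
  forb <- rbind(data.frame(start = anchor$start, end = anchor$end),
                excl[, c("start", "end")])
  for (i in seq_len(nrow(ctrls)))
    for (j in seq_len(nrow(forb)))
      expect_true(ctrls$end[i] <= forb$start[j] ||
                    ctrls$start[i] >= forb$end[j])
  again <- size_matched_controls(anchor, arm, n_controls = 5,
                                 exclusions = excl, seed = 3,
                                 resolution = 5e4)
  expect_identical(ctrls, again)
})

test_that("v4c differences report mean and sd of per-bin offsets", {
  bins <- toy_bins(12, resolution = 5e4)
  set.seed(34)
  M <- matrix(runif(144, 0, 3), 12, 12); M <- (M + t(M)) / 2
  cm <- cm_from_dense(M, bins, "balanced")
  anc <- list(chrom = "chr1", start = 0, end = 1e5)
  a <- virtual_4c(cm, anc)
  expect_equal(v4c_difference(a, a)$mean, 0)
  expect_equal(v4c_difference(a, a)$sd, 0)
  b <- a; b$score <- b$score - 0.25
  d <- v4c_difference(a, b)
  expect_equal(d$mean, 0.25, tolerance = 1e-12)
  expect_equal(d$sd, 0, tolerance = 1e-12)
})

test_that("P-anchor v4c responds to condensin more than control anchors", {
  sp <- small_spec()
  m <- generator_model()
  gt <- ground_truth(sp)
  hi <- scale_total(expected_map(sp, m, 2), 1e6)
  ct <- scale_total(expected_map(sp, m, 1), 1e6)
  lo <- scale_total(expected_map(sp, m, 0.5), 1e6)
  p_anchor <- gt$p_intervals[gt$p_intervals$chrom == "aL", ]
  arm <- list(chrom = "aL", start = 0, end = 1.6e6)
  ctrls <- size_matched_controls(p_anchor, arm, n_controls = 3,
                                 exclusions = gt$p_intervals, seed = 6,
                                 resolution = sp$resolution)
  pdiff <- v4c_difference(virtual_4c(hi, p_anchor, "aL"),
                          virtual_4c(ct, p_anchor, "aL"))$mean
  cdiffs <- vapply(seq_len(3), function(i) {
    a <- ctrls[i, ]
    v4c_difference(virtual_4c(hi, a, "aL"), virtual_4c(ct, a, "aL"))$mean
  }, numeric(1))
  expect_true(all(pdiff > cdiffs))
  # condensin loss: P-anchor cis profile decreases along the arm, and the
  # P anchor's relative trans enrichment (vs a control anchor) drops
  p_lo <- virtual_4c(lo, p_anchor); p_ct <- virtual_4c(ct, p_anchor)
  cis <- p_lo$chrom == "aL" & !p_lo$in_anchor
  expect_lt(mean(p_lo$score[cis] - p_ct$score[cis]), 0)
  c_lo <- virtual_4c(lo, ctrls[1, ]); c_ct <- virtual_4c(ct, ctrls[1, ])
  tra <- p_lo$chrom == "aR"
  enrich_lo <- mean(p_lo$score[tra]) / mean(c_lo$score[tra])
  enrich_ct <- mean(p_ct$score[tra]) / mean(c_ct$score[tra])
  expect_lt(enrich_lo, enrich_ct)
})
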