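#' Specification of a synthetic genome with planted compartments
#'
#' Defines chromosome arms tiled by alternating A/B compartment blocks with
#' a terminal pericentric P domain at the centromeric end of each arm, and a
#' chromatin-state track aligned to the compartments (A blocks are active;
#' B blocks alternate repressed/null; the P domain is repressed). The
#' defaults describe two 10 Mb arms flanking a centromere (left arm with the
#' centromere at its right end, right arm mirrored) binned at 10 kb —
#' 2,000 bins genome wide.
#'
#' @param arms data.frame with columns `name`, `length` (bp) and
#'   `centromere_end` (`"left"` or `"right"`).
#' @param resolution bin size in bp.
#' @param block_size A/B compartment block length in bp.
#' @param p_len length of the pericentric P domain per arm in bp.
#' @return object of class `SyntheticGenomeSpec`.
#' @export
synthetic_genome_spec <- function(
    arms = data.frame(name = c("chr2L", "chr2R"),
                      length = c(1e7, 1e7),
                      centromere_end = c("right", "left")),
    resolution = 1e4, block_size = 5e5, p_len = 1e6) {
  stopifnot(all(arms$length > p_len), block_size >= resolution,
            all(arms$centromere_end %in% c("left", "right")))
  blocks <- list()
  for (i in seq_len(nrow(arms))) {
    L <- arms$length[i]
    body <- L - p_len
    n_blk <- ceiling(body / block_size)
    lens <- rep(block_size, n_blk)
    lens[n_blk] <- body - (n_blk - 1) * block_size
    lab <- rep(c("A", "B"), length.out = n_blk)
    state <- ifelse(lab == "A", "active",
                    ifelse(cumsum(lab == "B") %% 2 == 1, "repressed", "null"))
    if (arms$centromere_end[i] == "right") {
      starts <- c(0, cumsum(lens))[seq_len(n_blk)]
      blk <- data.frame(start = starts, end = starts + lens,
                        label = lab, state = state)
      blk <- rbind(blk, data.frame(start = body, end = L,
                                   label = "P", state = "repressed"))
    } else {
      starts <- p_len + c(0, cumsum(lens))[seq_len(n_blk)]
      blk <- data.frame(start = starts, end = starts + lens,
                        label = lab, state = state)
      blk <- rbind(data.frame(start = 0, end = p_len,
                              label = "P", state = "repressed"), blk)
    }
    blk <- blk[order(blk$start), ]
    blk$arm <- arms$name[i]
    blocks[[i]] <- blk
  }
  structure(list(arms = arms, resolution = resolution,
                 block_size = block_size, p_len = p_len,
                 blocks = do.call(rbind, blocks)),
            class = "SyntheticGenomeSpec")
}

#' Forward-model parameters for the contact-map generator
#'
#' `lambda` (passed at generation time) is the condensin II activity level:
#' 1 = control, >1 emulates SLMB knockdown (elevated condensin II), <1
#' emulates Cap-H2 knockdown. The cis decay exponent responds as
#' `alpha(lambda) = alpha0 - kappa * log2(lambda)`; the pericentric stripe
#' factor is `1 + sigma * (lambda - 1)` on pairs with one end in P; the
#' trans background away from P scales as `lambda^-gamma`.
#'
#' @param alpha0 baseline cis decay exponent.
#' @param kappa sensitivity of the decay exponent to condensin level.
#' @param sigma pericentric stripe amplitude coefficient.
#' @param tau0 trans background level; default 5% of the cis level at 1 Mb.
#' @param gamma trans-depletion sensitivity to condensin level.
#' @param affinity symmetric 3x3 compartment affinity matrix over A, B, P.
#' @param depth default sampling depth (total contacts).
#' @param fish_amp,fish_beta0,fish_kappa,fish_noise_sd power-law scaling of
#'   FISH 3D distance with genomic separation: amplitude (µm), baseline
#'   exponent, exponent sensitivity to condensin, lognormal noise sd.
#' @return object of class `GeneratorModel`.
#' @export
generator_model <- function(alpha0 = 1.0, kappa = 0.3, sigma = 1.0,
                            tau0 = 0.05 * (1e6)^(-alpha0), gamma = 1,
                            affinity = matrix(c(1.5, 0.7, 1.0,
                                                0.7, 1.5, 1.0,
                                                1.0, 1.0, 3.0), 3, 3,
                                              dimnames = list(c("A", "B", "P"),
                                                              c("A", "B", "P"))),
                            depth = 1e6,
                            fish_amp = 4.2e-3, fish_beta0 = 0.33,
                            fish_kappa = 0.05, fish_noise_sd = 0.3) {
  stopifnot(all(affinity > 0), isTRUE(all.equal(affinity, t(affinity))),
            tau0 > 0)
  structure(list(alpha0 = alpha0, kappa = kappa, sigma = sigma, tau0 = tau0,
                 gamma = gamma, affinity = affinity, depth = depth,
                 fish_amp = fish_amp, fish_beta0 = fish_beta0,
                 fish_kappa = fish_kappa, fish_noise_sd = fish_noise_sd),
            class = "GeneratorModel")
}

#' Decay exponent at a given condensin level
#' @export
alpha_at <- function(model, lambda) {
  stopifnot(lambda > 0)
  a <- model$alpha0 - model$kappa * log2(lambda)
  if (a <= 0.2 || a >= 2.5)
    stop(sprintf("decay exponent %.3f outside the admissible range", a))
  a
}

#' Ground-truth labels of a synthetic genome
#'
#' @return list with `bins` (bin table), `labels` (per-bin factor A/B/P),
#'   `states` (per-bin chromatin state), `p_intervals` (data.frame of the P
#'   domain per arm) and `track` (the block intervals).
#' @export
ground_truth <- function(spec) {
  lens <- stats::setNames(spec$arms$length, spec$arms$name)
  bins <- bin_table(lens, spec$resolution)
  mid <- (bins$start + bins$end) / 2
  labels <- character(nrow(bins))
  states <- character(nrow(bins))
  for (arm in spec$arms$name) {
    blk <- spec$blocks[spec$blocks$arm == arm, ]
    sel <- bins$chrom == arm
    idx <- findInterval(mid[sel], blk$start)
    labels[sel] <- blk$label[idx]
    states[sel] <- blk$state[idx]
  }
  p_int <- spec$blocks[spec$blocks$label == "P",
                       c("arm", "start", "end")]
  names(p_int)[1] <- "chrom"
  rownames(p_int) <- NULL
  list(bins = bins, labels = factor(labels, levels = c("A", "B", "P")),
       states = states, p_intervals = p_int, track = spec$blocks)
}

#' Deterministic expected contact map at a condensin level
#'
#' Cis pairs at separation s receive `affinity[c_i,c_j] * s^-alpha(lambda)`;
#' any pair (cis or trans) with at least one end in the P domain is further
#' multiplied by the stripe factor `1 + sigma*(lambda-1)` when exactly one
#' end is in P (trans P-P pairs, across the centromere, carry the stripe
#' factor too, reflecting centromere clustering remodelled by condensin);
#' trans pairs with no P end receive the background
#' `tau0 * lambda^-gamma * affinity[c_i,c_j]`. Rows are then jointly
#' rescaled (symmetric iterative proportional fitting) so the expected
#' per-bin coverage is constant, and entries are returned as a balanced-form
#' matrix with planted truth attached.
#'
#' @param spec a `SyntheticGenomeSpec`.
#' @param model a `GeneratorModel`.
#' @param lambda condensin activity (> 0; 1 = control).
#' @param row_scale if FALSE, skip the constant-coverage rescaling (useful
#'   for formula-level checks).
#' @return a `ContactMatrix` (normalization `"balanced"`, all bins
#'   unmasked) with attribute `ground_truth` holding the planted labels,
#'   `alpha` and `lambda`.
#' @export
expected_map <- function(spec, model, lambda, row_scale = TRUE) {
  gt <- ground_truth(spec)
  bins <- gt$bins
  n <- nrow(bins)
  alpha <- alpha_at(model, lambda)
  stripe <- 1 + model$sigma * (lambda - 1)
  if (stripe <= 0)
    stop("stripe factor is non-positive for this sigma/lambda combination")
  lab <- as.integer(gt$labels)          # 1=A, 2=B, 3=P
  B <- model$affinity
  aff <- B[cbind(rep(lab, times = n), rep(lab, each = n))]
  dim(aff) <- c(n, n)
  same <- outer(bins$chrom, bins$chrom, "==")
  mid <- (bins$start + bins$end) / 2
  s <- abs(outer(mid, mid, "-"))
  s[s < spec$resolution] <- spec$resolution   # floor at one bin
  inP <- lab == 3L
  oneP <- outer(inP, inP, "xor")
  bothP <- outer(inP, inP, "&")
  M <- matrix(0, n, n)
  cis <- same
  M[cis] <- (aff * s^(-alpha))[cis]
  M[cis & oneP] <- M[cis & oneP] * stripe
  tr <- !same
  M[tr] <- (model$tau0 * aff)[tr]
  M[tr & (oneP | bothP)] <- M[tr & (oneP | bothP)] * stripe
  M[tr & !(oneP | bothP)] <- M[tr & !(oneP | bothP)] * lambda^(-model$gamma)
  if (row_scale) {
    w <- rep(1, n)
    for (it in 1:100) {
      m <- w * as.numeric(M %*% w)
      dev <- max(abs(m / mean(m) - 1))
      if (dev < 1e-10) break
      w <- w / sqrt(m / mean(m))
    }
    M <- M * outer(w, w)
  }
  ut <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  t <- data.frame(bin1 = ut[, 1] - 1L, bin2 = ut[, 2] - 1L,
                  value = M[ut])
  cm <- contact_matrix(bins, t, normalization = "balanced",
                       weights = rep(1, n))
  attr(cm, "ground_truth") <- list(labels = gt$labels, alpha = alpha,
                                   lambda = lambda,
                                   p_intervals = gt$p_intervals,
                                   states = gt$states)
  cm
}

#' Sample integer contact counts from an expected map
#'
#' Independent Poisson noise per pair with expectation proportional to the
#' expected map, scaled to total `depth`.
#'
#' @export
sample_contacts <- function(expected, depth = 1e6, seed = 1L) {
  stopifnot(depth > 0)
  set.seed(seed)
  t <- expected$triplets
  mu <- t$value / sum(t$value) * depth
  t$value <- stats::rpois(length(mu), mu)
  cm <- contact_matrix(expected$bins, t, normalization = "raw")
  attr(cm, "ground_truth") <- attr(expected, "ground_truth")
  cm
}

#' Simulate FISH probe-pair observations
#'
#' The 3D distance for a pair at genomic separation s is drawn as
#' `d = fish_amp * s^beta(lambda) * exp(eps)` with zero-mean Gaussian noise
#' on the log scale; `beta(lambda) = fish_beta0 - fish_kappa * log2(lambda)`
#' decreases with condensin level (more condensin, more compact). Probe
#' centroids are emitted so that spot-level metrics can be exercised:
#' probe 1 at the nucleus origin, probe 2 displaced by d in a uniformly
#' random direction.
#'
#' @return data.frame (nucleus, pair, sep_bp, x1..z2, dist_um) with planted
#'   `amp` and `beta` attributes.
#' @export
simulate_fish_pairs <- function(spec, model, lambda, separations,
                                n_nuclei = 50, seed = 1L,
                                noise_sd = model$fish_noise_sd) {
  stopifnot(all(separations > 0),
            all(separations <= max(spec$arms$length)))
  set.seed(seed)
  beta <- model$fish_beta0 - model$fish_kappa * log2(lambda)
  rows <- expand.grid(nucleus = seq_len(n_nuclei),
                      pair = seq_along(separations))
  s <- separations[rows$pair]
  d <- model$fish_amp * s^beta * exp(stats::rnorm(nrow(rows), 0, noise_sd))
  u <- matrix(stats::rnorm(3 * nrow(rows)), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  out <- data.frame(nucleus = rows$nucleus, pair = rows$pair, sep_bp = s,
                    x1 = 0, y1 = 0, z1 = 0,
                    x2 = u[, 1] * d, y2 = u[, 2] * d, z2 = u[, 3] * d,
                    dist_um = d)
  attr(out, "amp") <- model$fish_amp
  attr(out, "beta") <- beta
  out
}
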