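#' A multi-channel 3D label volume for one nucleus
#'
#' @param channels named list of 3D integer/logical arrays sharing one
#'   shape (nonzero = labeled voxel).
#' @param voxel_size numeric c(x, y, z) voxel edge lengths in µm.
#' @param nucleus_id identifier.
#' @export
nucleus_volume <- function(channels, voxel_size = c(0.1, 0.1, 0.3),
                           nucleus_id = 1L) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0),
            length(channels) >= 1)
  shp <- dim(channels[[1]])
  stopifnot(length(shp) == 3)
  for (ch in channels) stopifnot(identical(dim(ch), shp))
  structure(list(channels = channels, voxel_size = voxel_size,
                 nucleus_id = nucleus_id),
            class = "NucleusLabelVolume")
}

# 26- or 6-connectivity neighbor offsets
conn_offsets <- function(connectivity = 26) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6)
    g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1, ]
  else if (connectivity != 26)
    stop("connectivity must be 6 or 26")
  as.matrix(g)
}

#' Count 3D connected components in a channel
#'
#' Flood-fill labeling of nonzero voxels under 26-connectivity (voxels
#' touching at faces, edges or corners belong to one domain); an empty
#' channel counts zero domains.
#'
#' @param volume `NucleusLabelVolume`.
#' @param channel channel name or index.
#' @param connectivity 26 (default) or 6.
#' @export
count_domains <- function(volume, channel, connectivity = 26) {
  A <- volume$channels[[channel]] != 0
  if (!any(A)) return(0L)
  dims <- dim(A)
  offs <- conn_offsets(connectivity)
  lab <- array(0L, dims)
  ncomp <- 0L
  todo <- which(A & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(v, dims)
      nb <- sweep(offs, 2, ai, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1) * dims[1] +
        (nb[, 3] - 1) * dims[1] * dims[2]
      new <- lin[A[lin] & lab[lin] == 0L]
      if (length(new) > 0) {
        lab[new] <- ncomp
        queue <- c(queue, new)
      }
    }
  }
  ncomp
}

#' Surface area of a labeled structure by exposed voxel faces
#'
#' Sums the areas of voxel faces adjacent to background (or the array
#' boundary); anisotropic voxels are respected — an x-facing face has area
#' dy*dz, and so on.
#'
#' @return surface area in µm².
#' @export
surface_area <- function(volume, channel) {
  A <- volume$channels[[channel]] != 0
  vs <- volume$voxel_size
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  dims <- dim(A)
  total <- 0
  for (ax in 1:3) {
    # a face between positions k and k+1 along axis ax is exposed iff
    # exactly one side is labeled; outermost slices face the boundary
    n <- dims[ax]
    sl <- function(a, k) {
      idx <- lapply(dims, seq_len)
      idx[[ax]] <- k
      do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    }
    inner <- xor(sl(A, seq_len(n - 1)), sl(A, seq(2, n)))
    exposed <- sum(inner) + sum(sl(A, 1)) + sum(sl(A, n))
    total <- total + exposed * face_area[ax]
  }
  total
}

#' Fraction of one channel's volume overlapping another
#'
#' Directional: (voxels in a that are also in b) / (voxels in a). An empty
#' channel a yields an undefined result (NA with a flag).
#'
#' @export
overlap_fraction <- function(volume, channel_a, channel_b) {
  A <- volume$channels[[channel_a]] != 0
  B <- volume$channels[[channel_b]] != 0
  na <- sum(A)
  if (na == 0) return(structure(NA_real_, undefined = TRUE))
  sum(A & B) / na
}

#' Is a probe pair in contact?
#'
#' Overlap mode: contact iff the probes' segmented volumes overlap by at
#' least one voxel. Distance mode: contact iff the centroid distance is at
#' most `threshold` µm.
#'
#' @param obs one observation row with `overlap_voxels` (overlap mode) or
#'   x1..z2 centroids (distance mode).
#' @param mode "overlap" (default) or "distance".
#' @param threshold distance threshold in µm (distance mode).
#' @export
pair_contact <- function(obs, mode = c("overlap", "distance"),
                         threshold = 0.25) {
  mode <- match.arg(mode)
  if (mode == "overlap") {
    if (is.null(obs$overlap_voxels) || is.na(obs$overlap_voxels))
      stop("overlap mode requires an overlap_voxels field")
    return(obs$overlap_voxels >= 1)
  }
  need <- c("x1", "y1", "z1", "x2", "y2", "z2")
  if (!all(need %in% names(obs)) || any(is.na(unlist(obs[need]))))
    stop("distance mode requires both probe centroids")
  d <- sqrt((obs$x2 - obs$x1)^2 + (obs$y2 - obs$y1)^2 +
              (obs$z2 - obs$z1)^2)
  d <= threshold
}

#' Minimum pairwise distance between two probes' foci
#'
#' Multiple foci per probe (diploid homologs) are allowed; the global
#' minimum over all focus combinations is returned.
#'
#' @param foci_a,foci_b matrices (n x 3) of focus centroids in µm.
#' @return minimum Euclidean distance in µm.
#' @export
min_distance <- function(foci_a, foci_b) {
  foci_a <- rbind(foci_a); foci_b <- rbind(foci_b)
  if (nrow(foci_a) == 0 || nrow(foci_b) == 0)
    stop("each probe needs at least one focus")
  dmin <- Inf
  for (i in seq_len(nrow(foci_a)))
    for (j in seq_len(nrow(foci_b)))
      dmin <- min(dmin, sqrt(sum((foci_a[i, ] - foci_b[j, ])^2)))
  dmin
}

#' Power-law fit of 3D distance versus genomic separation
#'
#' Least squares of log(distance) on log(separation), giving
#' d = amp * s^beta. When multiple nuclei share a separation the per-pair
#' median is fitted by default (`aggregate = "median"`); `"none"` fits all
#' observations. Non-positive distances or separations are excluded with a
#' log entry.
#'
#' @param observations data.frame with `sep_bp` and `dist_um` columns.
#' @return list of class `PowerLawFit`: amp, beta, se_amp, se_beta,
#'   n_points, aggregate, residuals.
#' @export
power_law_fit <- function(observations, aggregate = c("median", "none")) {
  aggregate <- match.arg(aggregate)
  obs <- observations[, c("sep_bp", "dist_um")]
  bad <- obs$sep_bp <= 0 | obs$dist_um <= 0 | is.na(obs$sep_bp) |
    is.na(obs$dist_um)
  if (any(bad)) {
    message(sprintf("power_law_fit: excluded %d non-positive records",
                    sum(bad)))
    obs <- obs[!bad, ]
  }
  if (aggregate == "median") {
    med <- tapply(obs$dist_um, obs$sep_bp, stats::median)
    obs <- data.frame(sep_bp = as.numeric(names(med)),
                      dist_um = as.numeric(med))
  }
  if (length(unique(obs$sep_bp)) < 3)
    stop("need at least 3 distinct separations")
  fit <- stats::lm(log(dist_um) ~ log(sep_bp), data = obs)
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  structure(list(amp = exp(co[1, 1]), beta = co[2, 1],
                 se_log_amp = co[1, 2], se_beta = co[2, 2],
                 n_points = nrow(obs), aggregate = aggregate,
                 residuals = stats::residuals(fit),
                 fit_domain = range(obs$sep_bp)),
            class = "PowerLawFit")
}
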