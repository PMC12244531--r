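#' Deterministic per-stage seed derived from a global seed
#'
#' Hashes the stage name onto the global seed so adding a stage does not
#' shift the randomness of the others. Result stays below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Configuration for the end-to-end synthetic workflow
#'
#' @param lambdas condensin activity levels to simulate (1 = control).
#' @param seed global seed; per-stage seeds derive from it.
#' @param spec synthetic genome specification.
#' @param model generator model.
#' @param depth sampling depth per condition.
#' @param out_dir output directory.
#' @export
workflow_config <- function(lambdas = c(0.5, 1, 2), seed = 1L,
                            spec = synthetic_genome_spec(),
                            model = generator_model(),
                            depth = 1e6, out_dir = tempfile("hicrun")) {
  stopifnot(1 %in% lambdas, all(lambdas > 0))
  list(lambdas = lambdas, seed = seed, spec = spec, model = model,
       depth = depth, out_dir = out_dir)
}

#' Run the synthetic analysis workflow end-to-end
#'
#' simulate -> sample -> balance -> compartments (control) -> distance and
#' compartment-pair metrics -> virtual 4C with size-matched controls.
#' All randomness derives from the config seed; re-running with an
#' identical config reproduces identical output digests.
#'
#' @param config from [workflow_config()].
#' @return invisible manifest data.frame (stage, file, md5).
#' @export
run_workflow <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, sprintf(...))
  files <- character(0)
  spec <- config$spec; model <- config$model
  gt <- ground_truth(spec)
  arms <- spec$arms$name
  maps <- list(); raw <- list()
  for (lam in config$lambdas) {
    key <- sprintf("lambda_%g", lam)
    maps[[key]] <- expected_map(spec, model, lam)
    raw[[key]] <- sample_contacts(maps[[key]], config$depth,
                                  seed = stage_seed(config$seed, key))
    write_contacts(raw[[key]], out("%s.bins.bed", key),
                   out("%s.matrix.tsv", key))
    files <- c(files, out("%s.bins.bed", key), out("%s.matrix.tsv", key))
  }
  ctrl_key <- "lambda_1"
  bal <- lapply(raw, balance)
  track <- gt$track
  names(track)[names(track) == "label"] <- "compartment"
  utils::write.table(track, out("state_track.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("state_track.tsv"))

  # compartments on the control condition
  segs <- list()
  for (arm in arms) {
    ce <- spec$arms$centromere_end[spec$arms$name == arm]
    st <- gt$states[gt$bins$chrom == arm]
    eig <- compute_eigenvectors(bal[[ctrl_key]], arm, states = st,
                                centromere_end = ce)
    segs[[arm]] <- call_compartments(eig)
    write_bedgraph(eig$bins, eig$pc[, 1], out("pc1_%s.bedgraph", arm))
    files <- c(files, out("pc1_%s.bedgraph", arm))
  }
  seg_all <- do.call(rbind, segs)
  seg_all$number <- seq_len(nrow(seg_all))
  utils::write.table(seg_all, out("compartments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, out("compartments.tsv"))

  # distance metrics per condition
  met <- do.call(rbind, lapply(names(bal), function(key) {
    data.frame(condition = key,
               short_long = short_long_ratio(bal[[key]], arms[1]),
               trans_prop = trans_proportion(
                 coarsen(raw[[key]], max(1L, as.integer(5e5 / spec$resolution))),
                 arms[1], arms[2]),
               ps_slope = ps_slope(ps_curve(bal[[key]], arms[1]))$slope)
  }))
  utils::write.table(met, out("metrics.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, out("metrics.tsv"))

  # compartment-pair fold changes vs control
  seg1 <- segs[[arms[1]]]
  ctrl_scores <- compartment_pair_scores(bal[[ctrl_key]], seg1)
  for (key in setdiff(names(bal), ctrl_key)) {
    fc <- fold_change(compartment_pair_scores(bal[[key]], seg1), ctrl_scores)
    utils::write.table(fc, out("pair_fold_%s.tsv", key), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, out("pair_fold_%s.tsv", key))
  }

  # virtual 4C from the P anchor and size-matched controls
  p_anchor <- gt$p_intervals[gt$p_intervals$chrom == arms[1], ]
  arm1 <- list(chrom = arms[1], start = 0,
               end = spec$arms$length[spec$arms$name == arms[1]])
  ctrls <- size_matched_controls(p_anchor, arm1, n_controls = 3,
                                 exclusions = gt$p_intervals,
                                 seed = stage_seed(config$seed, "v4c"),
                                 resolution = spec$resolution)
  for (key in names(bal)) {
    prof <- virtual_4c(bal[[key]], p_anchor, arms[1])
    write_bedgraph(prof[, c("chrom", "start", "end")], prof$score,
                   out("v4c_p_%s.bedgraph", key))
    files <- c(files, out("v4c_p_%s.bedgraph", key))
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
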