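#' Percentage share of ChIP peaks per chromatin state
#'
#' Given per-category peak counts (e.g. condensin II ChIP peaks assigned
#' to active, repressed and null chromatin types), returns each category's
#' percentage of the total. A bundled count table is used by default.
#'
#' @param counts data.frame with `category` and `count` columns, or NULL
#'   to use the packaged table.
#' @return data.frame (category, count, percent).
#' @export
peak_state_shares <- function(counts = NULL) {
  if (is.null(counts)) {
    path <- system.file("extdata", "chip_peak_counts.tsv",
                        package = "condensinhic")
    counts <- utils::read.table(path, header = TRUE, sep = "\t")
  }
  stopifnot(all(c("category", "count") %in% names(counts)),
            all(counts$count >= 0))
  counts$percent <- 100 * counts$count / sum(counts$count)
  counts
}
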