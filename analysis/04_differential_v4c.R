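#!/usr/bin/env Rscript
# Condition comparisons: compartment-pair fold changes, differential
# maps, TAD-boundary classification, and virtual 4C from the pericentric
# anchor with size-matched controls. Requires 01_simulate.R.

library(condensinhic)

sim <- "results/sim"
out <- "results/differential"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_genome_spec()
gt <- ground_truth(spec)

bals <- list()
for (lam in c(0.5, 1, 2)) {
  key <- sprintf("lambda_%g", lam)
  raw <- read_contacts(file.path(sim, paste0(key, ".bins.bed")),
                       file.path(sim, paste0(key, ".matrix.tsv")))
  bals[[key]] <- scale_total(balance(raw), 1e6)
}
ctrl <- bals[["lambda_1"]]

# compartment-pair fold changes against the control segmentation
seg <- call_compartments(
  compute_eigenvectors(ctrl, "chr2L",
                       states = gt$states[gt$bins$chrom == "chr2L"],
                       centromere_end = "right"))
sc_ctrl <- compartment_pair_scores(ctrl, seg, 5e5, 5e6)
for (key in c("lambda_0.5", "lambda_2")) {
  fc <- fold_change(compartment_pair_scores(bals[[key]], seg, 5e5, 5e6),
                    sc_ctrl)
  long <- fc$sep >= 1e6
  cat(sprintf("%s: mean compartment-pair fold change >=1Mb = %.2f (%d pairs)\n",
              key, mean(fc$fold[long]), sum(long)))
  write.table(fc, file.path(out, paste0("pair_fold_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# differential map direction, lambda=2 vs control
dm <- differential_map(bals[["lambda_2"]], ctrl)
bins <- ctrl$bins
cis <- bins$chrom[dm$bin1 + 1] == bins$chrom[dm$bin2 + 1]
sep <- abs(dm$bin2 - dm$bin1) * spec$resolution
cat(sprintf("differential lambda=2: mean log2FC cis>=1Mb %.2f, trans %.2f\n",
            mean(dm$log2fc[cis & sep >= 1e6]), mean(dm$log2fc[!cis])))

# TAD boundaries and the boundary-change taxonomy
tads <- lapply(bals, function(b)
  insulation_boundaries(b, "chr2L", window = 1e5, prominence = 0.1))
for (key in c("lambda_0.5", "lambda_2")) {
  cmp <- classify_boundaries(tads[["lambda_1"]], tads[[key]])
  cat(sprintf("%s boundaries vs control: %s; splits %d, merges %d\n", key,
              paste(names(cmp$counts), cmp$counts, collapse = ", "),
              cmp$splits, cmp$merges))
}

# virtual 4C from the P anchor vs size-matched controls
p_anchor <- gt$p_intervals[gt$p_intervals$chrom == "chr2L", ]
arm <- list(chrom = "chr2L", start = 0, end = 1e7)
ctrl_anchors <- size_matched_controls(p_anchor, arm, n_controls = 3,
                                      exclusions = gt$p_intervals,
                                      seed = 1, resolution = spec$resolution)
pdiff <- v4c_difference(virtual_4c(bals[["lambda_2"]], p_anchor, "chr2L"),
                        virtual_4c(ctrl, p_anchor, "chr2L"))
cat(sprintf("v4c P-anchor differential (lambda=2 - control): %.3f +- %.3f\n",
            pdiff$mean, pdiff$sd))
for (i in seq_len(nrow(ctrl_anchors))) {
  cd <- v4c_difference(
    virtual_4c(bals[["lambda_2"]], ctrl_anchors[i, ], "chr2L"),
    virtual_4c(ctrl, ctrl_anchors[i, ], "chr2L"))
  cat(sprintf("  control anchor %d: %.3f +- %.3f\n", i, cd$mean, cd$sd))
}
for (key in names(bals)) {
  prof <- virtual_4c(bals[[key]], p_anchor)
  write_bedgraph(prof[, c("chrom", "start", "end")], prof$score,
                 file.path(out, paste0("v4c_p_", key, ".bedgraph")))
}
cat("wrote", out, "\n")
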