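#!/usr/bin/env Rscript
# Balance the simulated control map, call A/B compartments from the O/E
# eigenvectors, and define P compartments by k-means on the first three
# components. Requires 01_simulate.R output.

library(condensinhic)

sim <- "results/sim"
out <- "results/compartments"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_genome_spec()
gt <- ground_truth(spec)
raw <- read_contacts(file.path(sim, "lambda_1.bins.bed"),
                     file.path(sim, "lambda_1.matrix.tsv"))
bal <- balance(raw)
cat(sprintf("balanced control map: %d/%d bins unmasked\n",
            sum(!is.na(bal$weights)), nrow(bal$bins)))

eigs <- list(); segs <- list()
for (arm in spec$arms$name) {
  ce <- spec$arms$centromere_end[spec$arms$name == arm]
  eig <- compute_eigenvectors(bal, arm,
                              states = gt$states[gt$bins$chrom == arm],
                              centromere_end = ce)
  eigs[[arm]] <- eig
  segs[[arm]] <- call_compartments(eig)
  write_bedgraph(eig$bins, eig$pc[, 1],
                 file.path(out, paste0("pc1_", arm, ".bedgraph")))
  lab <- gt$labels[gt$bins$chrom == arm]
  ab <- lab %in% c("A", "B") & !is.na(eig$pc[, 1])
  cat(sprintf("%s: %d compartments, A/B sign agreement with truth %.1f%%\n",
              arm, nrow(segs[[arm]]),
              100 * mean((eig$pc[ab, 1] >= 0) == (lab[ab] == "A"))))
}
seg <- do.call(rbind, segs)
seg$number <- seq_len(nrow(seg))
write.table(seg, file.path(out, "compartments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

km <- kmeans_p_compartments(eigs, k = 3, seed = 1, restarts = 20)
truth <- gt$labels[match(paste(km$assignments$chrom, km$assignments$start),
                         paste(gt$bins$chrom, gt$bins$start))]
cat(sprintf("k-means P cluster: purity %.1f%%, recall %.1f%%\n",
            100 * mean(truth[km$assignments$is_p] == "P"),
            100 * mean(km$assignments$is_p[truth == "P"])))
print(km$p_intervals)
write.table(km$assignments, file.path(out, "kmeans_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(km$scree, file.path(out, "kmeans_scree.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote", out, "\n")
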