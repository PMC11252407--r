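#!/usr/bin/env Rscript
# Simulate the pooled barcoded osmotic-stress screen: 1,000 genes x 5
# insertional alleles, 20 genes planted with a fitness defect (s = 0.5
# per doubling over 4 doublings, expected phi = 0.25), two replicate
# control/treatment pairs sequenced to 1e7 reads each. Writes the count
# table, ground truth and screen design under results/screen/.

library(osmoscreen)

out_dir <- "results/screen"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_screen(n_genes = 1000, alleles_per_gene = 5,
                       n_hit_genes = 20, selection_coefficient = 0.5,
                       doublings = 4, read_depth = 1e7, replicates = 2,
                       seed = 1)

write_counts_tsv(sim$counts, sim$annotation,
                 file.path(out_dir, "counts.tsv"))
write.table(sim$truth, file.path(out_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
yaml::write_yaml(
  setNames(lapply(seq_len(nrow(sim$design)), function(i)
    as.list(sim$design[i, ])),
    sprintf("screen_%d", seq_len(nrow(sim$design)))),
  file.path(out_dir, "design.yaml"))

message(sprintf(
  "Simulated %d barcodes (%d genes x 5 alleles + unmapped sink), %d samples.",
  nrow(sim$counts), nrow(sim$truth), ncol(sim$counts)))
message(sprintf("Planted %d hit genes with expected phi = %.2f.",
                sum(sim$truth$s > 0), 2^(-4 * 0.5)))
message("Wrote counts.tsv, truth.tsv, design.yaml to ", out_dir)
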