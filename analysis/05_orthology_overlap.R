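#!/usr/bin/env Rscript
# Reciprocal-best-BLAST-hit orthology and cross-list statistics: build an
# ortholog map from a generated two-proteome tabular BLAST result
# (e-value <= 1e-10), then compute the overlap between a functional-
# genomics hit list and a transcriptomic differentially-expressed set,
# and a category enrichment test on the DE set.

library(osmoscreen)

out_dir <- "results/orthology"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# two synthetic proteomes: 200 A-genes; 120 of them with a true ortholog
# (strong mutual hit), the rest only spurious weak hits
set.seed(5)
mk <- function(q, s, e, b) data.frame(qseqid = q, sseqid = s, pident = 90,
                                      length = 150, mismatch = 2, gapopen = 0,
                                      qstart = 1, qend = 150, sstart = 1,
                                      send = 150, evalue = e, bitscore = b)
n <- 200
with_ortho <- sort(sample(n, 120))
ab <- do.call(rbind, lapply(seq_len(n), function(i) {
  rows <- mk(sprintf("crA_%03d", i), sprintf("atB_%03d", sample(n, 2)),
             10^-runif(2, 2, 9), runif(2, 30, 80))
  if (i %in% with_ortho)
    rows <- rbind(rows, mk(sprintf("crA_%03d", i), sprintf("atB_%03d", i),
                           10^-runif(1, 15, 60), runif(1, 150, 400)))
  rows
}))
ab_path <- file.path(out_dir, "a_vs_b.blast.tsv")
write.table(ab, ab_path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
ba <- ab; names(ba)[1:2] <- c("sseqid", "qseqid"); ba <- ba[, names(ab)]
ba_path <- file.path(out_dir, "b_vs_a.blast.tsv")
write.table(ba, ba_path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

pairs <- rbh(best_hits(parse_blast_tab(ab_path)),
             best_hits(parse_blast_tab(ba_path)))
write.table(pairs, file.path(out_dir, "rbh_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("RBH map: %d pairs from %d true orthologs (%.0f%% recovered).",
                nrow(pairs), length(with_ortho),
                100 * mean(sprintf("crA_%03d", with_ortho) %in% pairs$gene_a)))

# overlap of a hit list with a DE reference set (the worked example
# proportion: 5 shared genes over a 1456-gene reference is 0.34%)
de_set <- sprintf("deg_%04d", seq_len(1456))
hit_list <- c(de_set[seq_len(5)], sprintf("fg_%02d", seq_len(71)))
ov <- overlap_stats(hit_list, de_set)
message(sprintf("Overlap: %d of %d hits are in the %d-gene DE set (%.2f%% of the reference).",
                ov$n_overlap, ov$n_query, ov$n_reference, ov$percentage))

# enrichment of a 40-gene category in a 150-gene DE list, 2000-gene universe
uni <- sprintf("g%04d", seq_len(2000))
category <- uni[seq_len(40)]
de_list <- c(uni[seq_len(18)], uni[200 + seq_len(132)])  # 18/40 in category
enr <- fisher_enrichment(de_list, category, uni)
message(sprintf("Category enrichment: %d/%d in list, OR = %.1f, Fisher p = %.2g.",
                enr$table[1, 1], length(category), enr$odds_ratio, enr$p))
write.table(data.frame(stat = c("overlap_pct", "enrichment_p", "rbh_pairs"),
                       value = c(ov$percentage, enr$p, nrow(pairs))),
            file.path(out_dir, "summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Wrote rbh_pairs.tsv, summary.tsv to ", out_dir)
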