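#!/usr/bin/env Rscript
# Secondary plate screen: render a scanned 96-well plate image for a
# layout with wild-type wells and 2 replicate wells per mutant, quantify
# mean well intensities on the grayscale image, and express mutant
# growth as Z-scores against the same-plate wild-type wells.

library(osmoscreen)

out_dir <- "results/secondary"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# 8 x 12 plate: 12 wild-type wells, 40 mutants x 2 replicate wells,
# 2 excluded wells (bubbles), remainder empty-vector controls
set.seed(3)
lay <- expand.grid(row = 1:8, col = 1:12)
genotype <- c(rep("wt", 12), rep(sprintf("mut%02d", 1:40), each = 2),
              rep("blank", 4))
lay$genotype <- sample(genotype)
lay$is_wt <- lay$genotype == "wt"
lay$excluded <- FALSE
lay$excluded[sample(which(!lay$is_wt), 2)] <- TRUE

growth <- c(wt = 150, blank = 20,
            setNames(150 * c(runif(30, 0.98, 1.02),     # mostly wt-like
                             runif(10, 0.3, 0.6)),       # 10 slow growers
                     sprintf("mut%02d", 1:40)))
plate <- simulate_plate(lay, growth, noise_sd = 4, seed = 11, render = TRUE)

wq <- quantify_wells(plate$image, lay, plate$geometry)
z <- growth_z_scores(wq)
write.table(z, file.path(out_dir, "plate_z.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

slow <- z$genotype[z$z < -3 & grepl("^mut", z$genotype)]
planted <- sprintf("mut%02d", 31:40)
message(sprintf("Quantified %d wells (%d excluded).", nrow(wq),
                sum(lay$excluded)))
message(sprintf("%d of 10 planted slow growers score Z < -3 (%d other mutants do).",
                sum(planted %in% slow), sum(!slow %in% planted)))
message("Wrote plate_z.tsv to ", out_dir)
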