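#!/usr/bin/env Rscript
# Stage 5: consolidate overlapping peptides into core epitopes (minimum
# length 9 for MHC-I, 9 and 13 for MHC-II), impute missing per-sample values
# with the sample minimum, and test differential presentation
# (p < 0.05, |log2fc| > 1, with BH-corrected calls alongside).

suppressPackageStartupMessages(library(ligandomics))

dir <- "results/simdata"
out <- "results/05_core_epitopes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

obs <- read_tsv(file.path(dir, "peptide_observations.tsv"))
sample_cols <- c(paste0("control_", 1:3), paste0("treated_", 1:3))
cond_of_col <- rep(c("control", "treated"), each = 3)

for (run in list(c("I", 9), c("II", 9), c("II", 13))) {
  cls <- run[1]; ml <- as.integer(run[2])
  sub <- obs[obs$mhc_class == cls, ]
  consistent <- unlist(lapply(c("control", "treated"), function(cond)
    replicate_consistent_set(sub[sub$condition == cond, ])$peptides$sequence))
  agg <- stats::aggregate(ms1_area ~ sequence + condition + bio_rep, sub,
                          mean)
  meta <- sub[!duplicated(sub$sequence),
              c("sequence", "protein", "start", "end")]
  wide <- meta[meta$sequence %in% consistent, ]
  for (cn in sample_cols) wide[[cn]] <- NA_real_
  key <- paste0(agg$condition, "_", agg$bio_rep)
  hit <- agg$sequence %in% wide$sequence
  wide[cbind(match(agg$sequence[hit], wide$sequence),
             match(key[hit], sample_cols) + 4L)] <- agg$ms1_area[hit]

  ce <- infer_core_epitopes(wide, ml, sample_cols)
  imp <- impute_missing(ce$cores[, sample_cols])
  dp <- differential_presentation(imp$matrix, cond_of_col)
  res <- cbind(ce$cores, dp)
  write_tsv(res, file.path(out, sprintf("core_epitopes_%s_min%d.tsv",
                                        cls, ml)))
  cat(sprintf("MHC-%s (min %d): %d cores from %d peptides (%d unresolvable)\n",
              cls, ml, nrow(res), nrow(wide), nrow(ce$unresolvable)))
  cat(sprintf("  raw p<0.05 & |log2fc|>1: %d up-treated, %d up-control; after BH: %d / %d\n",
              sum(dp$direction == "up_treated"),
              sum(dp$direction == "up_control"),
              sum(dp$direction_bh == "up_treated"),
              sum(dp$direction_bh == "up_control")))
}
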