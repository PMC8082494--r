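#!/usr/bin/env Rscript
# Stage 6: allele assignment with percentile-rank thresholds (strong < 0.500,
# weak < 2.000 for class I; binder < 10 for class II), HLA locus bias test,
# class-I carry-over flags in the class II table, and Gibbs motif clustering
# of 9-mer core epitopes scored by Kullback-Leibler divergence.

suppressPackageStartupMessages(library(ligandomics))

dir <- "results/simdata"
out <- "results/06_binding"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 42

reference <- read_fasta(file.path(dir, "reference.fasta"))
obs <- read_tsv(file.path(dir, "peptide_observations.tsv"))
truth <- read_tsv(file.path(dir, "truth_peptides.tsv"))

load_models <- function(cls) {
  files <- sort(list.files(dir, sprintf("^motif_%s_", cls),
                           full.names = TRUE))
  lapply(seq_along(files), function(i) {
    df <- read_tsv(files[i])
    build_allele_model(df$allele[1], as.matrix(df[, AA20]), reference,
                       n_background = 10000, seed = child_seed(seed, 500 + i))
  })
}
models1 <- load_models("I")
models2 <- load_models("II")

pep1 <- unique(obs$sequence[obs$mhc_class == "I"])
calls <- assign_alleles(pep1, models1, "I")
write_tsv(calls, file.path(out, "binder_calls_I.tsv"))
cat(sprintf("MHC-I binder calls: %d strong, %d weak, %d non-binder\n",
            sum(calls$binder_class == "strong"),
            sum(calls$binder_class == "weak"),
            sum(calls$binder_class == "non_binder")))

# locus bias of treated-exclusive binders vs the all-peptide locus mix
tr1 <- truth[truth$mhc_class == "I", ]
binders <- calls[calls$binder_class != "non_binder", ]
binders$locus <- hla_locus(sub(",.*$", "", binders$best_alleles))
ref_prop <- prop.table(table(binders$locus))
excl <- tr1$sequence[tr1$mode == "processing_shifted"]
obs_counts <- table(binders$locus[binders$peptide %in% excl])
if (length(obs_counts) > 1) {
  lb <- locus_bias_test(c(obs_counts), ref_prop[names(obs_counts)] /
                          sum(ref_prop[names(obs_counts)]))
  cat(sprintf("Locus bias of treated-exclusive binders: chi2=%.2f (df=%d), p=%.3g\n",
              lb$statistic, lb$df, lb$p_value))
}

pep2 <- unique(obs$sequence[obs$mhc_class == "II"])
contam <- flag_class_crosscontamination(pep2, models1, models2)
write_tsv(data.frame(sequence = pep2, class1_contaminant = contam),
          file.path(out, "class2_contamination.tsv"))
tr2 <- truth[truth$mhc_class == "II", ]
inj <- tr2$sequence[tr2$contaminant]
cat(sprintf("Class-II 9-mers flagged as class-I carry-over: %d (recall on injected: %.2f)\n",
            sum(contam),
            mean(contam[match(inj, pep2)])))

# motif clustering of 9-long MHC-I cores
sub <- obs[obs$mhc_class == "I", ]
sample_cols <- c(paste0("control_", 1:3), paste0("treated_", 1:3))
consistent <- unlist(lapply(c("control", "treated"), function(cond)
  replicate_consistent_set(sub[sub$condition == cond, ])$peptides$sequence))
agg <- stats::aggregate(ms1_area ~ sequence + condition + bio_rep, sub, mean)
meta <- sub[!duplicated(sub$sequence),
            c("sequence", "protein", "start", "end")]
wide <- meta[meta$sequence %in% consistent, ]
for (cn in sample_cols) wide[[cn]] <- NA_real_
key <- paste0(agg$condition, "_", agg$bio_rep)
hit <- agg$sequence %in% wide$sequence
wide[cbind(match(agg$sequence[hit], wide$sequence),
           match(key[hit], sample_cols) + 4L)] <- agg$ms1_area[hit]
cores <- infer_core_epitopes(wide, 9L, sample_cols)$cores
cores9 <- cores$core_sequence[nchar(cores$core_sequence) == 9]
cl <- gibbs_cluster(cores9, k = 3, seed = child_seed(seed, 600),
                    restarts = 5)
cat(sprintf("Gibbs clustering of %d 9-mer cores (k=3):\n", length(cores9)))
for (i in seq_len(cl$k)) {
  cat(sprintf("  cluster %d: n=%d, KLD=%.2f bits\n", i,
              cl$clusters[[i]]$size, cl$clusters[[i]]$kld))
  if (cl$clusters[[i]]$size > 0)
    write_pssm(cl$clusters[[i]]$pssm,
               file.path(out, sprintf("motif_cluster_%d_pssm.tsv", i)))
}
write_tsv(data.frame(core = cores9, cluster = cl$assignments),
          file.path(out, "motif_clusters_I.tsv"))
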