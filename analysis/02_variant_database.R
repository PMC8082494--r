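#!/usr/bin/env Rscript
# Stage 2: construct the proteogenomic target-decoy search database and flag
# variant-bearing (SNP/neoantigen-candidate) peptides.

suppressPackageStartupMessages(library(ligandomics))

dir <- "results/simdata"
out <- "results/02_variant_database"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

reference <- read_fasta(file.path(dir, "reference.fasta"))
variants <- read_tsv(file.path(dir, "variants.tsv"))

vfa <- vapply(split(variants, variants$protein), function(vv)
  apply_variants(reference[[vv$protein[1]]], vv), character(1))
names(vfa) <- paste0(names(vfa), "_var")
db <- build_search_database(reference, vfa)
write_tsv(db$entries, file.path(out, "search_database.tsv"))
cat(sprintf("Database: %d targets + %d decoys (%d variant proteins)\n",
            sum(!db$entries$decoy), sum(db$entries$decoy), length(vfa)))
if (length(db$warnings))
  cat("Palindromic targets flagged:", paste(db$warnings, collapse = ", "), "\n")

truth <- read_tsv(file.path(dir, "truth_peptides.tsv"))
pep <- truth[truth$mhc_class == "I",
             c("sequence", "protein", "start", "end", "variant")]
ann <- annotate_variant_peptides(pep, db, variants)
write_tsv(ann, file.path(out, "variant_peptide_flags.tsv"))
cat(sprintf("MHC-I peptides spanning a variant: %d; variant-exclusive: %d\n",
            sum(ann$spans_variant), sum(ann$variant_exclusive)))
cat(sprintf("Generator truth: %d variant peptides; all recovered: %s\n",
            sum(pep$variant), all(ann$spans_variant[pep$variant])))
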