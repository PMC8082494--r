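#!/usr/bin/env Rscript
# Stage 3: differential protein expression between control and treated
# reporter-channel groups (log2 t-test, p < 0.01, fold >= 1.2, BH q-values).

suppressPackageStartupMessages(library(ligandomics))

dir <- "results/simdata"
out <- "results/03_proteome"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

quant <- read_tsv(file.path(dir, "protein_quant.tsv"))
filt <- filter_quant_peptides(quant)
cat(sprintf("Channel filter (>=4 of 6 observed): %d of %d rows retained\n",
            attr(filt, "retention")["retained"],
            attr(filt, "retention")["input"]))

de <- differential_expression(filt, p_thresh = 0.01, fc_thresh = 1.2)
write_tsv(de, file.path(out, "differential_expression.tsv"))
cat(sprintf("Differentially expressed: %d of %d (%.1f%%), max q among DE: %.3f\n",
            sum(de$is_de), nrow(de), 100 * mean(de$is_de),
            max(de$q_value[de$is_de])))

truth_de <- read_tsv(file.path(dir, "truth_de_proteins.tsv"))
called <- de$accession[de$is_de]
cat(sprintf("Planted DE recovered: %d / %d; false positives: %d\n",
            sum(truth_de$accession %in% called), nrow(truth_de),
            sum(!(called %in% truth_de$accession))))
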