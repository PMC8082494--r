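---
title: "Interpreting MHC ligandome changes against the proteome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting MHC ligandome changes against the proteome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligandomics)
```

# The analytical problem

Interferon-gamma reshapes the set of peptides presented by MHC class I and
class II molecules in two distinct ways: by changing the expression of the
source proteins (more protein, more peptide) and by changing the antigen
processing machinery itself (immunoproteasome induction, peptidase and
transporter shifts), which can surface entirely new peptides from unchanged
proteins. Telling these modes apart requires measuring the proteome and the
immunopeptidome from the same cells and asking, for every presented peptide,
whether its abundance behavior across conditions is explained by its source
protein.

`ligandomics` implements that comparison as a pipeline of testable stages:

1. **Variant proteome** — variant protein sequences are built by replacing
   wild-type residues with annotated alternate residues (missense
   substitutions only), and a target-decoy search database (full-sequence
   reversal) is assembled from wild-type, variant and contaminant entries.
   Peptides are flagged when they span a variant position carrying the
   alternate residue, and as variant-exclusive when, in addition, their
   sequence occurs in no wild-type entry — the SNP/neoantigen candidates.
2. **Proteome differential expression** — reporter intensities from six TMT
   channels (3 control, 3 treated) are filtered to rows with at least four
   observed channels, log2-transformed, tested with an unpaired Welch
   t-test, and corrected with Benjamini-Hochberg. A protein is called
   differentially expressed at p < 0.01 and an absolute fold-change of at
   least 1.2.
3. **Repertoires** — a peptide enters a condition's repertoire only when
   observed in all three biological replicates (at least one of three
   injections each); condition-exclusive and shared sets follow by set
   algebra. Short class II peptides whose best class-I percentile rank beats
   their best class-II rank are flagged as carry-over from the serial
   class-I immunoprecipitation.
4. **Core epitopes** — overlapping quantified peptides on one protein are
   consolidated into core epitopes (interval intersection of an
   overlap-connected component), missing per-sample values are imputed with
   the sample minimum, and differential presentation is called at p < 0.05
   and |log2 fold-change| > 1, with BH-corrected calls alongside.
5. **Binding motifs** — peptides are scored against allele-specific 9-mer
   position-weight matrices; scores become percentile ranks against a
   background of random proteome 9-mers (strong binder < 0.500, weak
   < 2.000 for class I, binder < 10 for class II; exact sub-threshold rank
   ties are reported for all tied alleles). A Gibbs sampler clusters
   fixed-length cores into motifs scored by Kullback-Leibler divergence.
6. **Integration** (the core of the package) — each peptide is categorized
   by comparing its change status with its protein's (details below).
7. **Targeted quantification** — endogenous SNP/neoantigen peptides are
   quantified as `(light area / heavy area) x spike amount` against
   isotopically labeled standards and tested for differential presentation.

# The categorization model

Within every sample (condition x biological replicate), peptides are ranked
by descending MS1 area; the *fractional rank* is rank divided by the number
of peptides quantified in that sample (ties receive the average rank), so
values lie in (0, 1] and small means abundant. Rank scales are robust to
sample-to-sample loading and ionization differences, which is why the
comparison runs on ranks rather than raw areas.

Only peptides observed in at least 2 biological replicates of some
condition, with a maximum pairwise fractional-rank difference below 0.2
within every condition where they appear, are categorized; the rest are
reported separately as unstable measurements.

A peptide is **changed** when it is exclusive to one condition or when its
mean fractional rank moves by at least 0.2 between conditions. A protein is
**changed** when it is differentially expressed. The category is then:

| condition | category |
|---|---|
| protein absent from the proteome matrix | `protein_unmapped` |
| peptide and protein both unchanged, or both changed with the same sign | `mirrored` |
| any mismatch (including opposite signs) | `independent` |

Sub-categories refine the qualitative behavior: condition-exclusive peptides
are `nested_overlap` when a different-sequence peptide of the other
condition shares at least one residue position on the same protein, and
`novel` otherwise; peptides present in both conditions are
`abundance_shift` when changed and `unchanged` otherwise.

Two thresholds here were genuinely open design choices:

* **The between-condition change threshold.** The replicate-variance filter
  (< 0.2 fractional-rank difference) is stated by the source analysis, but
  the between-condition criterion is not. We reuse 0.2 as the
  between-condition mean-rank delta so that a single coherent rank scale
  governs both filters; it is exposed as `rank_delta_thresh` and recorded in
  every output header.
* **Direction matching.** A peptide and protein that both changed but in
  opposite directions are classified `independent`, since "mirroring"
  implies concordance. Both-changed-same-sign is `mirrored`.
* **Binary protein change.** Protein change status is the binary
  differential-expression call plus the sign of its log2 fold-change; an
  alternative would place proteins on their own rank scale. The binary form
  matches how the upstream differential analysis reports proteins and keeps
  the decision table enumerable (it is pinned by an 8-case oracle test).

# The synthetic world

No raw mass-spectrometry data is required anywhere: `sim_config()` +
`simulate_world()` generate every input with ground-truth labels.

* **Proteins**: random sequences from human-proteome residue frequencies;
  log-normal abundances (log2 mean 20, sd 2 — a typical MS dynamic range).
  2000 proteins by default; 10% are withheld from the quantification matrix
  ("undetected") to supply `protein_unmapped` peptides, echoing the green
  wedge of the source analysis (~9–13%).
* **Differential expression**: 40 of 2000 proteins (2%, the proportion the
  source study reports) receive a planted mean log2 shift of 2 with random
  sign; reporter noise is i.i.d. log2 sd 0.3.
* **Peptides**: substrings of their source proteins, sampled through
  allele-specific PWMs (strong anchors at core positions 2 and 9 for class
  I, milder anchors for class II), class I lengths 8–12 with mode 9, class
  II 13–25. Expression-coupled peptides track their protein's per-replicate
  reporter intensity; processing-shifted peptides (10% of the treated
  repertoire) are treated-exclusive draws under a chymotrypsin-like
  C-terminal cleavage preference from non-differential proteins — a minimal
  stand-in for immunoproteasome induction; protein-undetected peptides come
  from the withheld proteins and do not change. 2% of the class II table is
  injected class-I-motif 9-mers (the serial-immunoprecipitation carry-over
  fixture). Per-injection dropout is 2%.
* **Variants**: 50 single-residue substitutions at uniform positions; ~30%
  are covered by a planted class-I 9-mer carrying the alternate residue.
* **AQUA panel**: 25 class-I standards (23 SNP + 2 neoantigen candidates)
  and 5 class-II, spiked at 250 fmol into 2 conditions x 2 biological
  replicates x 3 injections; by default one neoantigen carries a 10-fold
  drop and three SNP peptides 4-fold changes, mirroring the four
  differential panel members of the source design.

All randomness derives from one master seed through fixed child streams, so
every table is a pure function of the configuration.

**What the generator does not emulate** — and hence what a green test does
not establish: spectrum-level identification errors (no decoy hits, no
search-engine score distributions), retention-time structure, TMT ratio
compression, correlated replicate noise, shared peptides between proteins,
post-translational modifications, and realistic linkage between protein
abundance and presentation efficiency. Recovery rates on synthetic data are
upper bounds on what real data would give.

# Numerical and algorithmic choices

* **t-tests**: Welch by default (the equal-variance form is config-exposed);
  zero variance in both groups is defined as p = 1 for equal means and p = 0
  otherwise, so degenerate rows never produce NaN.
* **Benjamini-Hochberg** is authored in-package (step-up, capped at 1) and
  is verified against both a brute-force oracle and `stats::p.adjust`.
* **Core-epitope splitting**: a component whose interval intersection is
  shorter than the minimum epitope length is split at the leftmost position
  of minimal coverage; peptides covering the split position follow the side
  holding their larger share (ties left). Components that cannot progress,
  and lone peptides shorter than the minimum, are listed as unresolvable
  with their areas retained, so summed MS1 area is conserved exactly —
  asserted on every oracle instance.
* **Percentile ranks** use strict inequality (fraction of background scores
  strictly greater), so rank 0 is attainable and ranks are monotone
  non-increasing in score. Background: 10,000 proteome 9-mers by default.
* **Class-I length handling**: longer peptides score as their best 9-mer
  window minus `gap_penalty * (L - 9)`; 8-mers as the best one-deletion
  alignment minus one penalty (default 1 log2-odds unit).
* **Gibbs clustering** maximizes the size-weighted total KLD
  (`sum_c n_c * KLD_c`, bits, pseudocount 0.05 per residue per position)
  with single-sequence reassignment moves at fixed temperature, best of 50
  restarts. Purely random initializations can freeze into symmetric mixed
  local optima that no single-sequence move escapes; the first restart is
  therefore seeded with k-means on one-hot residue encodings (deterministic
  given the seed), which reliably lands in the basin of the planted
  partition while leaving the stated move set untouched.
* **Ties and determinism**: split positions leftmost; set outputs sorted
  lexicographically; every pipeline output carries the configuration
  fingerprint and seed, and reruns are byte-identical.

# Known limitations

* The consolidation algorithm is a documented reimplementation of the
  landscape-consolidation idea, not a line-for-line port of the published
  utility; the oracle tests pin *this package's* stated semantics.
* The internal PWM scorer replaces neural-network binding predictors; ranks
  are calibrated against the simulated proteome only. Externally computed
  rank tables in the same schema can be substituted without code change.
* The targeted-quantification test inherits the source design's n = 2
  biological replicates per condition; its power is low and the output says
  so.
* With three replicates per group, the proteome t-test has limited power at
  fold 1.2; the defaults recover planted effects at log2 fold 2 but weaker
  effects will be missed.
* Overlapping variants on one transcript are emitted as one variant
  sequence per protein carrying all its substitutions; one-sequence-per-
  variant is a noted alternative.
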