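#' Replicate-consistent peptide repertoire
#'
#' Builds the set of unique peptide sequences observed in at least `min_bio`
#' biological replicates, each supported by at least `min_tech` technical
#' injections, for one condition and one MHC class (the paper's strict rule:
#' all three biological replicates, at least one of three injections).
#'
#' @param observations data.frame of peptide observations (columns
#'   `sequence`, `protein`, `start`, `end`, `condition`, `bio_rep`,
#'   `tech_rep`, `ms1_area`, `mhc_class`) from a single condition and class.
#' @param min_bio minimum biological replicates (default 3).
#' @param min_tech minimum injections per supporting replicate (default 1).
#' @return Object of class `repertoire_set`: data.frame `peptides` (sequence,
#'   protein, start, end, n_bio, mean_area) plus `condition` / `mhc_class`
#'   attributes; one row per unique sequence.
#' @export
replicate_consistent_set <- function(observations, min_bio = 3L,
                                     min_tech = 1L) {
  cond <- unique(observations$condition)
  cls <- unique(observations$mhc_class)
  if (length(cond) > 1L || length(cls) > 1L)
    stop("observations must come from one condition and one MHC class",
         call. = FALSE)
  n_reps <- length(unique(observations$bio_rep))
  if (nrow(observations) && min_bio > max(3L, n_reps))
    stop("config error: min_bio exceeds the replicates present",
         call. = FALSE)
  if (!nrow(observations)) {
    out <- data.frame(sequence = character(0), protein = character(0),
                      start = integer(0), end = integer(0),
                      n_bio = integer(0), mean_area = numeric(0),
                      stringsAsFactors = FALSE)
    return(structure(list(peptides = out,
                          condition = if (length(cond)) cond else NA_character_,
                          mhc_class = if (length(cls)) cls else NA_character_),
                     class = "repertoire_set"))
  }
  inj <- stats::aggregate(tech_rep ~ sequence + bio_rep, observations, length)
  supported <- inj[inj$tech_rep >= min_tech, ]
  n_bio <- table(supported$sequence)
  keep <- names(n_bio)[n_bio >= min_bio]
  sub <- observations[observations$sequence %in% keep, , drop = FALSE]
  mean_area <- tapply(sub$ms1_area, sub$sequence, mean)
  meta <- sub[!duplicated(sub$sequence),
              c("sequence", "protein", "start", "end")]
  meta$n_bio <- as.integer(n_bio[meta$sequence])
  meta$mean_area <- as.numeric(mean_area[meta$sequence])
  meta <- meta[order(meta$sequence), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(peptides = meta, condition = cond, mhc_class = cls),
            class = "repertoire_set")
}

#' @export
print.repertoire_set <- function(x, ...) {
  cat(sprintf("repertoire_set: %d unique peptides (MHC-%s, %s)\n",
              nrow(x$peptides), x$mhc_class, x$condition))
  invisible(x)
}

#' Exclusive and shared repertoires between two conditions
#'
#' @param control,treated `repertoire_set` objects of the same MHC class.
#' @return List of sorted sequence vectors: `control_only`, `treated_only`,
#'   `shared` (disjoint; union equals the union of the inputs).
#' @export
exclusive_sets <- function(control, treated) {
  stopifnot(inherits(control, "repertoire_set"),
            inherits(treated, "repertoire_set"))
  if (!identical(control$mhc_class, treated$mhc_class))
    stop("MHC class mismatch between repertoires", call. = FALSE)
  a <- control$peptides$sequence
  b <- treated$peptides$sequence
  list(control_only = sort(setdiff(a, b)),
       treated_only = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}

#' Flag class-I carry-over peptides in a class II table
#'
#' In serially performed MHC-I then MHC-II immunoprecipitations, short class
#' II peptides that score as class I binders are likely carry-over. A peptide
#' is flagged when its length is at most 9 residues and its best class-I
#' percentile rank is strictly better (lower) than its best class-II rank.
#'
#' @param class2_peptides character vector of peptides from the class II
#'   table.
#' @param class1_models,class2_models lists of [allele_model()] objects.
#' @return Logical vector of flags, one per peptide.
#' @export
flag_class_crosscontamination <- function(class2_peptides, class1_models,
                                          class2_models) {
  if (!length(class1_models) || !length(class2_models))
    stop("config error: no alleles configured", call. = FALSE)
  flags <- logical(length(class2_peptides))
  short <- nchar(class2_peptides) <= 9L
  if (!any(short)) return(flags)
  peps <- class2_peptides[short]
  best1 <- do.call(pmin, lapply(class1_models, function(m)
    percentile_rank(score_peptides(m, peps), m)))
  best2 <- do.call(pmin, lapply(class2_models, function(m)
    percentile_rank(score_peptides(m, peps, penalize_length = FALSE), m)))
  flags[short] <- best1 < best2
  flags
}

#' Chi-squared test for HLA locus bias
#'
#' Goodness-of-fit of observed per-locus binder counts against reference
#' proportions (e.g. the locus proportions of the full pMHC repertoire),
#' with `df = loci - 1`.
#'
#' @param locus_counts named integer vector of observed counts per locus
#'   (e.g. A/B/C).
#' @param reference_proportions named numeric vector over the same loci,
#'   summing to 1.
#' @return List: `statistic`, `p_value`, `df`, `expected`, and a
#'   `construction` label recording the test formulation.
#' @export
locus_bias_test <- function(locus_counts, reference_proportions) {
  loci <- names(locus_counts)
  if (is.null(loci) || !all(loci %in% names(reference_proportions)))
    stop("reference proportions must cover all observed loci", call. = FALSE)
  pr <- reference_proportions[loci]
  if (abs(sum(reference_proportions) - 1) > 1e-8)
    stop("reference proportions must sum to 1", call. = FALSE)
  expected <- sum(locus_counts) * pr
  if (any(expected == 0 & locus_counts > 0))
    stop("degenerate expectation: zero expected count for an observed locus",
         call. = FALSE)
  stat <- sum((locus_counts - expected)^2 / expected)
  df <- length(loci) - 1L
  list(statistic = stat,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df, expected = expected,
       construction = "goodness-of-fit vs reference proportions")
}

#' HLA locus of an allele name
#' @param allele character vector like `"HLA-A*02:01"` or `"SIM-B*03"`.
#' @return Character vector of locus letters (`"A"`, `"B"`, `"C"`, ...).
#' @export
hla_locus <- function(allele) {
  sub("^[^-]*-([A-Za-z]+).*$", "\\1", sub("\\*.*$", "", allele))
}
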