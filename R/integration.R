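#' Fractional abundance ranks per sample
#'
#' Within each (condition, biological replicate) sample, peptides are ranked
#' by descending MS1 area (most abundant = rank 1, ties receive the average
#' rank) and divided by the number of peptides quantified in that sample, so
#' the fractional rank lies in (0, 1] with small values = abundant.
#'
#' @param abundance_table data.frame: `sequence`, `condition`, `bio_rep`,
#'   `abundance` (one row per peptide per sample, e.g. mean over technical
#'   injections).
#' @return data.frame: `sequence`, `condition`, `bio_rep`, `frac_rank`.
#' @export
fractional_ranks <- function(abundance_table) {
  stopifnot(all(c("sequence", "condition", "bio_rep", "abundance") %in%
                  names(abundance_table)))
  if (any(abundance_table$abundance <= 0))
    stop("domain error: non-positive abundance", call. = FALSE)
  key <- interaction(abundance_table$condition, abundance_table$bio_rep,
                     drop = TRUE)
  fr <- numeric(nrow(abundance_table))
  for (idx in split(seq_len(nrow(abundance_table)), key)) {
    r <- rank(-abundance_table$abundance[idx], ties.method = "average")
    fr[idx] <- r / length(idx)
  }
  out <- abundance_table[, c("sequence", "condition", "bio_rep")]
  out$frac_rank <- fr
  rownames(out) <- NULL
  out
}

#' Per-peptide rank profile across conditions
#'
#' Summarizes [fractional_ranks()] output: per condition, the number of
#' biological replicates a peptide was observed in, the mean fractional rank
#' over those replicates, and the maximum pairwise rank difference between
#' them.
#'
#' @param ranks data.frame from [fractional_ranks()].
#' @return data.frame, one row per sequence: `n_bio_control`,
#'   `n_bio_treated`, `mean_rank_control`, `mean_rank_treated` (NA where
#'   absent), `maxdiff_control`, `maxdiff_treated`.
#' @export
rank_profiles <- function(ranks) {
  seqs <- sort(unique(ranks$sequence))
  stat <- function(cond, f, default) {
    sub <- ranks[ranks$condition == cond, ]
    v <- tapply(sub$frac_rank, sub$sequence, f)
    out <- rep(default, length(seqs))
    out[match(names(v), seqs)] <- as.numeric(v)
    out
  }
  data.frame(
    sequence = seqs,
    n_bio_control = stat("control", length, 0),
    n_bio_treated = stat("treated", length, 0),
    mean_rank_control = stat("control", mean, NA_real_),
    mean_rank_treated = stat("treated", mean, NA_real_),
    maxdiff_control = stat("control", function(x) diff(range(x)), NA_real_),
    maxdiff_treated = stat("treated", function(x) diff(range(x)), NA_real_),
    stringsAsFactors = FALSE)
}

#' Low-variance filter on rank profiles
#'
#' A peptide is retained when (a) in every condition where it is present its
#' maximum pairwise fractional-rank difference across biological replicates
#' is below `threshold`, and (b) it is present in at least `min_bio`
#' biological replicates of at least one condition.
#'
#' @param profiles data.frame from [rank_profiles()].
#' @param threshold fractional-rank difference threshold (default 0.2).
#' @param min_bio minimum biological replicates in some condition (default 2).
#' @return The retained rows of `profiles`; dropped rows in
#'   `attr(, "dropped")`.
#' @export
low_variance_filter <- function(profiles, threshold = 0.2, min_bio = 2L) {
  ok_var <- (profiles$n_bio_control == 0 |
               profiles$maxdiff_control < threshold) &
            (profiles$n_bio_treated == 0 |
               profiles$maxdiff_treated < threshold)
  ok_var[is.na(ok_var)] <- FALSE
  ok_bio <- pmax(profiles$n_bio_control, profiles$n_bio_treated) >= min_bio
  keep <- ok_var & ok_bio
  out <- profiles[keep, , drop = FALSE]
  attr(out, "dropped") <- profiles[!keep, , drop = FALSE]
  out
}

#' Categorize peptides against the underlying proteome
#'
#' The classification of each peptide's presentation behavior:
#' \enumerate{
#'   \item `protein_unmapped` - the source protein was not measured in the
#'     proteome analysis;
#'   \item `mirrored` - the peptide's change status matches the protein's
#'     (changed with the same direction, or both unchanged);
#'   \item `independent` - any mismatch (peptide changed while the protein
#'     did not, vice versa, or opposite directions).
#' }
#' A peptide counts as changed when it is exclusive to one condition
#' (present in at least `min_bio_presence` biological replicates of exactly
#' one condition) or when the absolute difference of its mean fractional
#' ranks between conditions is at least `rank_delta_thresh`. A protein
#' counts as changed when it is differentially expressed (`is_de`), with
#' direction from the sign of its log2 fold-change. Sub-categories per
#' [overlap_subcategory()].
#'
#' @param profiles filtered rank profiles ([low_variance_filter()] output).
#' @param peptide_meta data.frame mapping `sequence` to `protein`, `start`,
#'   `end` (first match used).
#' @param de_results [differential_expression()] output.
#' @param proteome_accessions accessions present in the proteome matrix.
#' @param rank_delta_thresh between-condition mean fractional-rank change
#'   threshold (default 0.2, mirroring the replicate-variance filter).
#' @param min_bio_presence replicates needed to count as present in a
#'   condition (default 2).
#' @return data.frame: sequence, protein, top_category, sub_category,
#'   peptide_changed, peptide_direction, protein_detected, protein_de,
#'   protein_log2fc, rank_delta, exclusive_to.
#' @export
categorize_pmhc <- function(profiles, peptide_meta, de_results,
                            proteome_accessions, rank_delta_thresh = 0.2,
                            min_bio_presence = 2L) {
  mi <- match(profiles$sequence, peptide_meta$sequence)
  if (anyNA(mi))
    stop("unmapped peptide error: no protein mapping for ",
         profiles$sequence[which(is.na(mi))[1]], call. = FALSE)
  protein <- peptide_meta$protein[mi]

  present_c <- profiles$n_bio_control >= min_bio_presence
  present_t <- profiles$n_bio_treated >= min_bio_presence
  exclusive_to <- ifelse(present_c & !present_t, "control",
                         ifelse(present_t & !present_c, "treated", "none"))
  rank_delta <- profiles$mean_rank_control - profiles$mean_rank_treated
  both <- exclusive_to == "none"
  changed <- !both | (abs(rank_delta) >= rank_delta_thresh &
                        !is.na(rank_delta))
  # lower fractional rank = more abundant: positive delta means up in treated
  pep_dir <- ifelse(exclusive_to == "treated", 1,
                    ifelse(exclusive_to == "control", -1,
                           ifelse(changed, sign(rank_delta), 0)))

  di <- match(protein, de_results$accession)
  prot_detected <- protein %in% proteome_accessions
  prot_de <- !is.na(di) & de_results$is_de[di]
  prot_dir <- ifelse(prot_de, sign(de_results$log2fc[di]), 0)

  top <- ifelse(!prot_detected, "protein_unmapped",
                ifelse(changed == prot_de &
                         (!changed | pep_dir == prot_dir),
                       "mirrored", "independent"))
  out <- data.frame(sequence = profiles$sequence, protein = protein,
                    top_category = top,
                    peptide_changed = changed,
                    peptide_direction = pep_dir,
                    protein_detected = prot_detected,
                    protein_de = prot_de,
                    protein_log2fc = de_results$log2fc[di],
                    rank_delta = rank_delta,
                    exclusive_to = exclusive_to,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sub-categorize a peptide's qualitative behavior
#'
#' Condition-exclusive peptides are `nested_overlap` when some peptide of
#' the other condition on the same protein shares at least one residue
#' position (a different sequence spanning the same region), else `novel`.
#' Peptides present in both conditions are `abundance_shift` when changed,
#' else `unchanged`.
#'
#' @param categories [categorize_pmhc()] output.
#' @param peptide_meta data.frame: `sequence`, `protein`, `start`, `end`.
#' @param repertoires list with `control` and `treated` character vectors of
#'   sequences present per condition (used to find overlap partners).
#' @return `categories` with `sub_category` and `overlap_partner` appended.
#' @export
overlap_subcategory <- function(categories, peptide_meta, repertoires) {
  meta <- peptide_meta[!duplicated(peptide_meta$sequence), ]
  sub <- character(nrow(categories))
  partner <- rep(NA_character_, nrow(categories))
  for (i in seq_len(nrow(categories))) {
    excl <- categories$exclusive_to[i]
    if (excl == "none") {
      sub[i] <- if (categories$peptide_changed[i]) "abundance_shift"
                else "unchanged"
      next
    }
    other <- if (excl == "treated") "control" else "treated"
    mine <- meta[meta$sequence == categories$sequence[i], ][1, ]
    cand <- meta[meta$sequence %in% repertoires[[other]] &
                   meta$protein == mine$protein &
                   meta$sequence != mine$sequence, , drop = FALSE]
    hit <- which(cand$start <= mine$end & cand$end >= mine$start)
    if (length(hit)) {
      sub[i] <- "nested_overlap"
      partner[i] <- cand$sequence[hit[1]]
    } else {
      sub[i] <- "novel"
    }
  }
  categories$sub_category <- sub
  categories$overlap_partner <- partner
  categories
}
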