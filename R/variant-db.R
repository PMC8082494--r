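#' Apply single-residue substitutions to a protein sequence
#'
#' Constructs the variant sequence by replacing the wild-type residue with
#' the alternate residue at each annotated position (1-based). Only
#' substitutions are supported: the output has the same length as the input.
#'
#' @param sequence wild-type protein sequence (single string).
#' @param variants data.frame with columns `pos` (1-based), `ref_aa`,
#'   `alt_aa`, and optionally `protein` (used in error messages).
#' @param check_ref verify that the sequence carries `ref_aa` at each
#'   position (default TRUE); with checks disabled, re-application against an
#'   already-varied sequence is an idempotent overwrite.
#' @return The variant sequence.
#' @export
apply_variants <- function(sequence, variants, check_ref = TRUE) {
  if (!nrow(variants)) return(sequence)
  stopifnot(all(c("pos", "ref_aa", "alt_aa") %in% names(variants)))
  prot <- if ("protein" %in% names(variants)) variants$protein[1] else "?"
  if (any(variants$ref_aa == variants$alt_aa))
    stop("invalid variant: ref_aa equals alt_aa", call. = FALSE)
  if (any(variants$pos < 1L) || any(variants$pos > nchar(sequence)))
    stop("bounds error: variant position outside sequence ", prot,
         " (length ", nchar(sequence), ")", call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (check_ref) {
    found <- chars[variants$pos]
    bad <- which(found != variants$ref_aa)
    if (length(bad))
      stop("reference inconsistency: ", prot, " position ",
           variants$pos[bad[1]], " carries ", found[bad[1]],
           ", annotation says ", variants$ref_aa[bad[1]], call. = FALSE)
  }
  chars[variants$pos] <- variants$alt_aa
  paste(chars, collapse = "")
}

#' Assemble a target-decoy search database
#'
#' Targets are the wild-type proteins, the variant sequences and the common
#' contaminants; decoys are the full reversals of every target, tagged with a
#' `rev_` accession prefix. Palindromic targets (decoy identical to target)
#' are flagged in the `warnings` element.
#'
#' @param wildtype named character vector of wild-type sequences.
#' @param variant_sequences named character vector of variant sequences
#'   (accessions must not collide with wild-type accessions).
#' @param contaminants named character vector (possibly empty).
#' @return Object of class `search_database`: data.frame `entries` with
#'   columns `accession`, `sequence`, `class` (wildtype / variant /
#'   contaminant), `decoy` (logical), plus a `warnings` attribute listing
#'   palindromic accessions.
#' @export
build_search_database <- function(wildtype, variant_sequences = character(0),
                                  contaminants = character(0)) {
  targets <- data.frame(
    accession = c(names(wildtype), names(variant_sequences),
                  names(contaminants)),
    sequence = c(unname(wildtype), unname(variant_sequences),
                 unname(contaminants)),
    class = c(rep("wildtype", length(wildtype)),
              rep("variant", length(variant_sequences)),
              rep("contaminant", length(contaminants))),
    decoy = FALSE, stringsAsFactors = FALSE)
  decoys <- targets
  decoys$accession <- paste0("rev_", targets$accession)
  decoys$sequence <- reverse_sequences(targets$sequence)
  decoys$decoy <- TRUE
  entries <- rbind(targets, decoys)
  if (anyDuplicated(entries$accession))
    stop("collision error: duplicate accession after decoy tagging: ",
         entries$accession[duplicated(entries$accession)][1], call. = FALSE)
  palindromic <- targets$accession[targets$sequence == decoys$sequence]
  structure(list(entries = entries, warnings = palindromic),
            class = "search_database")
}

reverse_sequences <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' @export
print.search_database <- function(x, ...) {
  tb <- table(x$entries$class[!x$entries$decoy])
  cat(sprintf("search_database: %d entries (%d targets + %d decoys)\n",
              nrow(x$entries), sum(!x$entries$decoy), sum(x$entries$decoy)))
  cat("  targets:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  if (length(x$warnings))
    cat("  warning: palindromic target(s):",
        paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}

#' Flag variant-spanning and variant-exclusive peptides
#'
#' `spans_variant` is TRUE when the peptide's protein interval covers an
#' annotated variant position and the peptide carries the alternate residue
#' there; `variant_exclusive` additionally requires that the peptide sequence
#' is a substring of no wild-type target entry (a SNP/neoantigen candidate).
#'
#' @param peptides data.frame with `sequence`, `protein`, `start`, `end`
#'   (1-based inclusive protein coordinates).
#' @param database a [build_search_database()] result.
#' @param variants variant table (columns `protein`, `pos`, `alt_aa`).
#' @return `peptides` with logical columns `spans_variant` and
#'   `variant_exclusive` appended.
#' @export
annotate_variant_peptides <- function(peptides, database, variants) {
  stopifnot(inherits(database, "search_database"))
  entries <- database$entries
  known <- unique(c(sub("^rev_", "", entries$accession),
                    sub("_var$", "", sub("^rev_", "", entries$accession))))
  unmapped <- !(peptides$protein %in% known)
  if (any(unmapped))
    stop("unmapped peptide error: protein(s) not in database: ",
         paste(unique(peptides$protein[unmapped]), collapse = ", "),
         call. = FALSE)
  wt <- entries$sequence[entries$class == "wildtype" & !entries$decoy]

  spans <- logical(nrow(peptides))
  if (nrow(variants)) {
    vmap <- split(variants, variants$protein)
    for (i in seq_len(nrow(peptides))) {
      vv <- vmap[[peptides$protein[i]]]
      if (is.null(vv)) next
      inside <- vv$pos >= peptides$start[i] & vv$pos <= peptides$end[i]
      if (any(inside)) {
        off <- vv$pos[inside] - peptides$start[i] + 1L
        carried <- substring(peptides$sequence[i], off, off) ==
          vv$alt_aa[inside]
        spans[i] <- any(carried)
      }
    }
  }
  # substring scan only needed where a variant is actually carried
  in_wildtype <- logical(nrow(peptides))
  in_wildtype[spans] <- vapply(peptides$sequence[spans], function(s)
    any(grepl(s, wt, fixed = TRUE)), logical(1), USE.NAMES = FALSE)
  peptides$spans_variant <- spans
  peptides$variant_exclusive <- spans & !in_wildtype
  peptides
}

#' Read / write FASTA (thin wrappers over Biostrings)
#' @param x named character vector of sequences.
#' @param path file path.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(x), path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}
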