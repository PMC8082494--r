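#' Simulate single-residue protein variants
#'
#' Plants `n_variants` missense substitutions at distinct positions across
#' the reference proteins (at most one variant per position; positions drawn
#' uniformly), with random provenance (exome / rna / both) and dbSNP/COSMIC
#' style boolean flags. Variant protein sequences carry all substitutions of
#' their protein (one emitted sequence per mutated protein).
#'
#' @param config a [sim_config()].
#' @param reference named character vector of wild-type protein sequences.
#' @return List with `variants` (data.frame: protein, pos, ref_aa, alt_aa,
#'   provenance, known_snp, cosmic_flag), `variant_fasta` (named character
#'   vector of variant protein sequences, accessions suffixed `_var`), and
#'   `truth` (the same variant table, the generator's ground truth).
#' @export
simulate_variants <- function(config, reference) {
  validate_sim_config(config)
  nv <- config$n_variants
  total_positions <- sum(nchar(reference))
  if (nv > total_positions)
    stop("invalid config: n_variants exceeds total mutable positions",
         call. = FALSE)
  if (nv == 0) {
    empty <- data.frame(protein = character(0), pos = integer(0),
                        ref_aa = character(0), alt_aa = character(0),
                        provenance = character(0), known_snp = logical(0),
                        cosmic_flag = logical(0), stringsAsFactors = FALSE)
    return(list(variants = empty, variant_fasta = character(0), truth = empty))
  }
  set.seed(child_seed(config$seed, 9))
  lens <- nchar(reference)
  # sample global positions without replacement, then map to (protein, pos)
  gpos <- sort(sample.int(total_positions, nv))
  cum <- cumsum(lens)
  prot_idx <- findInterval(gpos - 1L, c(0L, cum), rightmost.closed = FALSE)
  pos <- gpos - c(0L, cum)[prot_idx]
  prot <- names(reference)[prot_idx]
  ref_aa <- substr(reference[prot_idx], pos, pos)
  alt_aa <- vapply(ref_aa, function(r) sample(setdiff(AA20, r), 1L),
                   character(1), USE.NAMES = FALSE)
  variants <- data.frame(
    protein = prot, pos = as.integer(pos), ref_aa = ref_aa, alt_aa = alt_aa,
    provenance = sample(c("exome", "rna", "both"), nv, replace = TRUE,
                        prob = c(0.6, 0.2, 0.2)),
    known_snp = stats::runif(nv) < 0.9,
    cosmic_flag = stats::runif(nv) < 0.1,
    stringsAsFactors = FALSE)

  variant_fasta <- vapply(split(variants, variants$protein), function(vv) {
    apply_variants(reference[[vv$protein[1]]], vv)
  }, character(1))
  names(variant_fasta) <- paste0(names(variant_fasta), "_var")

  list(variants = variants, variant_fasta = variant_fasta, truth = variants)
}
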