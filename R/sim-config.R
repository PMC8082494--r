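#' Simulation configuration
#'
#' Parameters of the synthetic world emitted by the data generator. Defaults
#' emulate the design of a 6-channel TMT proteome (3 control vs 3
#' interferon-gamma-treated biological replicates) measured alongside MHC
#' class I and class II ligandomes (3 biological replicates x 3 technical
#' injections per condition), with a small differentially expressed protein
#' set (~2% of quantified proteins), a fraction of treated-exclusive peptides
#' produced by an altered processing (immunoproteasome-like) cleavage
#' preference, a fraction of peptides from proteins undetected in the
#' proteome, and planted single-residue variants.
#'
#' @param n_proteins number of simulated proteins.
#' @param protein_length_range integer (min, max) protein lengths in residues.
#' @param n_de_proteins number of proteins with a planted expression change.
#' @param de_log2fc magnitude of the planted mean log2 fold-change (>= 0);
#'   sign is drawn per protein.
#' @param channel_noise_sd standard deviation of reporter-channel log2 noise.
#' @param n_alleles number of class-I allele models in the simulated host.
#' @param peptides_per_condition unique peptides emitted per MHC class in the
#'   treated condition (the control repertoire is the shared subset).
#' @param frac_processing_shift fraction of the treated repertoire generated
#'   by the altered cleavage preference (treated-exclusive, no protein-level
#'   change).
#' @param frac_protein_undetected fraction of peptides drawn from proteins
#'   absent from the proteome quantification.
#' @param missingness per-injection dropout probability.
#' @param n_variants number of planted single-residue substitutions.
#' @param seed master random seed (all child streams derive from it).
#' @param frac_class1_contamination fraction of the class-II table injected as
#'   class-I-motif 9-mers (serial-immunoprecipitation carry-over fixture).
#' @param peptide_effect_sd sd of the per-peptide log2 ionization efficiency.
#' @param bio_noise_sd sd of per-biological-replicate peptide log2 noise.
#' @param tech_noise_sd sd of per-injection peptide log2 noise.
#' @param abundance_log2_mean,abundance_log2_sd log-normal protein abundance
#'   parameters (log2 scale).
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_proteins = 2000,
                       protein_length_range = c(200L, 600L),
                       n_de_proteins = 40,
                       de_log2fc = 2,
                       channel_noise_sd = 0.3,
                       n_alleles = 6,
                       peptides_per_condition = 5000,
                       frac_processing_shift = 0.10,
                       frac_protein_undetected = 0.10,
                       missingness = 0.02,
                       n_variants = 50,
                       seed = 42,
                       frac_class1_contamination = 0.02,
                       peptide_effect_sd = 1.5,
                       bio_noise_sd = 0.2,
                       tech_noise_sd = 0.15,
                       abundance_log2_mean = 20,
                       abundance_log2_sd = 2) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              protein_length_range = as.integer(protein_length_range),
              n_de_proteins = as.integer(n_de_proteins),
              de_log2fc = de_log2fc,
              channel_noise_sd = channel_noise_sd,
              n_alleles = as.integer(n_alleles),
              peptides_per_condition = as.integer(peptides_per_condition),
              frac_processing_shift = frac_processing_shift,
              frac_protein_undetected = frac_protein_undetected,
              missingness = missingness,
              n_variants = as.integer(n_variants),
              seed = as.integer(seed),
              frac_class1_contamination = frac_class1_contamination,
              peptide_effect_sd = peptide_effect_sd,
              bio_noise_sd = bio_noise_sd,
              tech_noise_sd = tech_noise_sd,
              abundance_log2_mean = abundance_log2_mean,
              abundance_log2_sd = abundance_log2_sd)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_proteins", "n_alleles", "peptides_per_condition")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 1)
      stop("invalid config: ", f, " must be a positive count", call. = FALSE)
  }
  fracs <- c("frac_processing_shift", "frac_protein_undetected",
             "missingness", "frac_class1_contamination")
  for (f in fracs) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("invalid config: ", f, " must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_de_proteins < 0 || cfg$n_de_proteins > cfg$n_proteins)
    stop("invalid config: n_de_proteins must lie in [0, n_proteins]",
         call. = FALSE)
  if (cfg$de_log2fc < 0)
    stop("invalid config: de_log2fc must be >= 0", call. = FALSE)
  if (cfg$n_variants < 0)
    stop("invalid config: n_variants must be >= 0", call. = FALSE)
  if (length(cfg$protein_length_range) != 2L ||
      cfg$protein_length_range[1] < 30L ||
      diff(cfg$protein_length_range) < 0)
    stop("invalid config: protein_length_range must be (min >= 30, max >= min)",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}
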