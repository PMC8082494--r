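#' Simulate a 6-channel TMT protein quantification matrix
#'
#' Draws `n_proteins` random protein sequences and log-normal abundances
#' (log2 mean/sd from the config), plants `n_de_proteins` with a mean log2
#' group difference of exactly `de_log2fc` (random sign), and emits reporter
#' intensities for six channels (three control, three treated) with i.i.d.
#' log2 noise. A configured fraction of proteins is held out of the
#' quantification matrix ("undetected") to supply peptides without a
#' proteome-level measurement downstream.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{quant}{data.frame: `accession` plus six channel columns; the
#'       channel-to-group map is in `attr(quant, "channel_groups")`.}
#'     \item{reference}{named character vector of all protein sequences
#'       (detected and undetected).}
#'     \item{truth}{list with `de_proteins` (accession + signed log2fc),
#'       `undetected` accessions, and the latent per-condition log2
#'       abundances.}
#'   }
#' @export
simulate_proteome <- function(config) {
  validate_sim_config(config)
  n <- config$n_proteins
  acc <- sprintf("P%05d", seq_len(n))
  reference <- random_proteins(n, config$protein_length_range,
                               child_seed(config$seed, 1))
  names(reference) <- acc

  set.seed(child_seed(config$seed, 2))
  mu <- stats::rnorm(n, config$abundance_log2_mean, config$abundance_log2_sd)

  de_idx <- if (config$n_de_proteins > 0)
    sort(sample.int(n, config$n_de_proteins)) else integer(0)
  de_sign <- if (length(de_idx))
    sample(c(-1, 1), length(de_idx), replace = TRUE) else numeric(0)

  shift <- numeric(n)
  shift[de_idx] <- de_sign * config$de_log2fc
  mu_control <- mu
  mu_treated <- mu + shift

  n_undet <- round(config$frac_protein_undetected * n)
  undet_idx <- if (n_undet > 0)
    sort(sample(setdiff(seq_len(n), de_idx), n_undet)) else integer(0)

  channels <- c("TMT126", "TMT127N", "TMT128C", "TMT129N", "TMT130C", "TMT131")
  groups <- c(rep("control", 3), rep("treated", 3))
  names(groups) <- channels

  det_idx <- setdiff(seq_len(n), undet_idx)
  m <- length(det_idx)
  vals <- matrix(NA_real_, m, 6, dimnames = list(NULL, channels))
  for (j in 1:3)
    vals[, j] <- 2^(mu_control[det_idx] + stats::rnorm(m, 0, config$channel_noise_sd))
  for (j in 4:6)
    vals[, j] <- 2^(mu_treated[det_idx] + stats::rnorm(m, 0, config$channel_noise_sd))

  quant <- data.frame(accession = acc[det_idx], vals,
                      check.names = FALSE, stringsAsFactors = FALSE)
  attr(quant, "channel_groups") <- groups

  truth <- list(
    de_proteins = data.frame(accession = acc[de_idx],
                             log2fc = de_sign * config$de_log2fc,
                             stringsAsFactors = FALSE),
    undetected = acc[undet_idx],
    abundance = data.frame(accession = acc,
                           log2_control = mu_control,
                           log2_treated = mu_treated,
                           stringsAsFactors = FALSE)
  )
  list(quant = quant, reference = reference, truth = truth)
}

#' Channel-to-group map of a simulated quantification matrix
#' @param quant a quant data.frame from [simulate_proteome()] or a TSV reread.
#' @return Named character vector mapping channel column to group.
#' @export
channel_groups <- function(quant) {
  g <- attr(quant, "channel_groups")
  if (!is.null(g)) return(g)
  channels <- setdiff(names(quant), "accession")
  if (length(channels) != 6L)
    stop("schema error: expected 6 channel columns, found ", length(channels),
         call. = FALSE)
  stats::setNames(c(rep("control", 3), rep("treated", 3)), channels)
}
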