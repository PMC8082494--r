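#' Absolute quantification against a spiked heavy standard
#'
#' `amount = (light_area / heavy_area) * spike_amount` (fmol): the
#' endogenous (light) MS1 area is scaled by the known amount of the
#' co-eluting isotopically labeled standard.
#'
#' @param light_area endogenous MS1 area (>= 0).
#' @param heavy_area standard MS1 area (> 0).
#' @param spike_amount spiked standard amount in fmol (> 0).
#' @return Endogenous amount in fmol (vectorized).
#' @export
quantify_against_standard <- function(light_area, heavy_area, spike_amount) {
  if (any(heavy_area <= 0))
    stop("standard not detected: heavy_area must be > 0", call. = FALSE)
  if (any(spike_amount <= 0))
    stop("spike_amount must be > 0", call. = FALSE)
  (light_area / heavy_area) * spike_amount
}

#' Differential presentation of targeted (AQUA) peptides
#'
#' Technical injections are averaged per biological replicate; a two-sample
#' t-test compares the biological-replicate mean amounts between conditions
#' (the study design has n = 2 spiked replicates per condition - low power,
#' flagged in the output); Benjamini-Hochberg q-values are computed across
#' the peptide panel; per-peptide z-scores standardize the per-condition
#' replicate means (population convention: they sum to 0 with unit
#' variance). Significance: `p < p_thresh` and `q < q_thresh`.
#'
#' @param measurements data.frame: `peptide`, `condition`, `bio_rep`,
#'   `tech_rep`, `light_area`, `heavy_area`, `spike_amount`.
#' @param p_thresh p-value threshold (default 0.05).
#' @param q_thresh q-value threshold (default 0.49).
#' @return List: `results` (peptide, log2fc, p_value, q_value, direction,
#'   significant, low_power) and `z_matrix` (peptide x replicate-mean
#'   z-scores, heatmap-ready).
#' @export
differential_targets <- function(measurements, p_thresh = 0.05,
                                 q_thresh = 0.49) {
  m <- measurements
  m$amount <- quantify_against_standard(m$light_area, m$heavy_area,
                                        m$spike_amount)
  agg <- stats::aggregate(amount ~ peptide + condition + bio_rep, m, mean)
  peptides <- sort(unique(agg$peptide))

  rows <- vector("list", length(peptides))
  zrows <- list()
  for (i in seq_along(peptides)) {
    sub <- agg[agg$peptide == peptides[i], ]
    xc <- sub$amount[sub$condition == "control"]
    xt <- sub$amount[sub$condition == "treated"]
    if (length(xc) < 2 || length(xt) < 2)
      stop("insufficient replicates: ", peptides[i],
           " needs >= 2 biological replicates per condition", call. = FALSE)
    p <- log2_t_test(log2(pmax(xc, .Machine$double.xmin)),
                     log2(pmax(xt, .Machine$double.xmin)))
    log2fc <- mean(log2(pmax(xt, .Machine$double.xmin))) -
      mean(log2(pmax(xc, .Machine$double.xmin)))
    means <- c(xc, xt)
    mz <- (means - mean(means)) /
      sqrt(mean((means - mean(means))^2))  # population sd
    zrows[[peptides[i]]] <- mz
    rows[[i]] <- data.frame(peptide = peptides[i], log2fc = log2fc,
                            p_value = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$q_value <- benjamini_hochberg(res$p_value)
  res$direction <- ifelse(res$log2fc > 0, "up_treated", "up_control")
  res$significant <- res$p_value < p_thresh & res$q_value < q_thresh
  res$direction[!res$significant] <- "unchanged"
  res$low_power <- TRUE  # n=2 per condition by design
  z <- do.call(rbind, zrows[res$peptide])
  colnames(z) <- c(paste0("control_", seq_len(ncol(z) / 2)),
                   paste0("treated_", seq_len(ncol(z) / 2)))
  list(results = res, z_matrix = z)
}

#' Simulate an AQUA targeted-quantification panel
#'
#' Emits the study's panel structure by default: 25 class-I standards (23
#' SNP peptides + 2 neoantigen candidates) and 5 class-II standards, spiked
#' at a known amount into 2 conditions x 2 biological replicates x 3
#' technical injections. A configurable subset of peptides carries a
#' planted fold-change in the treated condition (default: one neoantigen
#' with a 10-fold drop and three SNP peptides with 4-fold changes,
#' mirroring the study's four differential panel members).
#'
#' @param seed integer seed.
#' @param n_class1,n_class2 panel sizes (default 25 / 5).
#' @param spike_amount fmol spiked per sample (default 250).
#' @param planted named numeric vector: log2 fold-changes (treated vs
#'   control) for a subset of peptide indices `"pep_01"`, ... Defaults to
#'   `c(pep_01 = -log2(10), pep_03 = 2, pep_07 = 2, pep_12 = -2)`.
#' @param noise_sd log2 noise sd of replicate means (default 0.25).
#' @param tech_sd log2 noise sd of injections (default 0.1).
#' @return List: `measurements` (long data.frame) and `truth` (peptide,
#'   planted_log2fc, is_neoantigen).
#' @export
simulate_aqua <- function(seed = 42, n_class1 = 25L, n_class2 = 5L,
                          spike_amount = 250,
                          planted = c(pep_01 = -log2(10), pep_03 = 2,
                                      pep_07 = 2, pep_12 = -2),
                          noise_sd = 0.25, tech_sd = 0.1) {
  set.seed(child_seed(seed, 12))
  n <- n_class1 + n_class2
  peptide <- sprintf("pep_%02d", seq_len(n))
  is_neo <- peptide %in% c("pep_01", "pep_02")
  base_log2 <- stats::rnorm(n, 10, 1.5)
  lfc <- stats::setNames(rep(0, n), peptide)
  lfc[names(planted)[names(planted) %in% peptide]] <-
    planted[names(planted) %in% peptide]

  grid <- expand.grid(peptide = peptide,
                      condition = c("control", "treated"),
                      bio_rep = 1:2, tech_rep = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pi <- match(grid$peptide, peptide)
  bio_key <- paste(grid$peptide, grid$condition, grid$bio_rep)
  ukey <- unique(bio_key)
  bio_noise <- stats::setNames(stats::rnorm(length(ukey), 0, noise_sd), ukey)
  mu <- base_log2[pi] + ifelse(grid$condition == "treated", lfc[pi], 0) +
    bio_noise[bio_key]
  light <- 2^(mu + stats::rnorm(nrow(grid), 0, tech_sd))
  heavy <- 2^(stats::rnorm(nrow(grid), 12, 0.2))
  meas <- data.frame(grid,
                     light_area = light, heavy_area = heavy,
                     spike_amount = spike_amount,
                     mhc_class = ifelse(pi <= n_class1, "I", "II"),
                     stringsAsFactors = FALSE)
  truth <- data.frame(peptide = peptide, planted_log2fc = unname(lfc),
                      is_neoantigen = is_neo, stringsAsFactors = FALSE)
  list(measurements = meas, truth = truth)
}
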