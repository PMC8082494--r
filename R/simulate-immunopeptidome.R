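#' Simulated allele binding motifs
#'
#' Draws allele-specific positional frequency matrices. Class I motifs carry
#' strong anchors at positions 2 and 9 of the 9-mer core (primary anchor
#' weight 0.6, secondary 0.15); class II motifs carry milder anchors at core
#' positions 1, 4, 6 and 9 (weight 0.35). Anchor residues are drawn
#' deterministically from the config seed. When `n_alleles == 6` the class I
#' models are named after a typical HLA-A/-B/-C six-allele host so that locus
#' level summaries (A/B/C) are meaningful; otherwise synthetic names are used.
#'
#' @param config a [sim_config()].
#' @return List with `I` and `II`: named lists of 9 x 20 frequency matrices.
#' @export
simulate_allele_motifs <- function(config) {
  validate_sim_config(config)
  bg <- aa_background()
  anchor_pool <- c("L", "V", "I", "F", "Y", "M", "K", "R", "P", "A", "E", "D")

  class1_names <- if (config$n_alleles == 6L) {
    c("HLA-A*02:01", "HLA-A*02:05", "HLA-B*07:02",
      "HLA-B*50:01", "HLA-C*06:02", "HLA-C*07:02")
  } else {
    sprintf("SIM-%s*%02d", rep(c("A", "B", "C"), length.out = config$n_alleles),
            seq_len(config$n_alleles))
  }
  class2_names <- c("HLA-DRB1*11:03", "HLA-DRB1*15:01", "HLA-DRB5*01:01")

  anchored_motif <- function(anchors, weights) {
    freqs <- matrix(bg, 9, 20, byrow = TRUE, dimnames = list(NULL, AA20))
    for (j in seq_along(anchors)) {
      pos <- as.integer(names(anchors)[j])
      w <- weights[[j]]
      row <- bg * (1 - sum(w))
      row[anchors[[j]]] <- row[anchors[[j]]] + w
      freqs[pos, ] <- row / sum(row)
    }
    freqs
  }

  set.seed(child_seed(config$seed, 3))
  class1 <- lapply(seq_along(class1_names), function(a) {
    a2 <- sample(anchor_pool, 2)   # primary + secondary anchor, position 2
    a9 <- sample(anchor_pool, 2)   # primary + secondary anchor, position 9
    anchored_motif(stats::setNames(list(a2, a9), c("2", "9")),
                   list(c(0.60, 0.15), c(0.60, 0.15)))
  })
  names(class1) <- class1_names

  set.seed(child_seed(config$seed, 4))
  class2 <- lapply(seq_along(class2_names), function(a) {
    anchors <- lapply(1:4, function(i) sample(anchor_pool, 1))
    anchored_motif(stats::setNames(anchors, c("1", "4", "6", "9")),
                   rep(list(0.35), 4))
  })
  names(class2) <- class2_names

  list(I = class1, II = class2)
}

# integer-coded protein cache
protein_int_cache <- function(reference) {
  env <- new.env(parent = emptyenv())
  function(acc) {
    v <- env[[acc]]
    if (is.null(v)) {
      v <- match(strsplit(reference[[acc]], "", fixed = TRUE)[[1]], AA20)
      env[[acc]] <- v
    }
    v
  }
}

# scores of all 9-mer windows of an integer-coded protein under a log-odds pwm
window_scores_int <- function(pwm, x) {
  nw <- length(x) - 8L
  s <- numeric(nw)
  for (p in 1:9) s <- s + pwm[p, x[p:(p + nw - 1L)]]
  s
}

# sample one peptide: allele-motif-biased core window + length extension
sample_one_peptide <- function(acc, x, pwm, mhc_class) {
  nw <- length(x) - 8L
  sc <- window_scores_int(pwm, x)
  pr <- exp(sc - max(sc))
  t0 <- sample.int(nw, 1L, prob = pr)      # core window [t0, t0+8]
  if (mhc_class == "I") {
    L <- sample(8:12, 1L, prob = c(0.10, 0.60, 0.15, 0.10, 0.05))
    if (L == 8L) {
      drop_first <- stats::runif(1) < 0.5
      start <- t0 + as.integer(drop_first)
      end <- start + 7L
    } else {
      ext <- L - 9L
      left <- if (ext > 0) sample(0:ext, 1L) else 0L
      start <- max(1L, t0 - left)
      end <- min(length(x), start + L - 1L)
      start <- max(1L, end - L + 1L)
    }
  } else {
    L <- sample(13:25, 1L, prob = stats::dnorm(13:25, 16, 3))
    ext <- L - 9L
    left <- sample(0:ext, 1L)
    start <- max(1L, t0 - left)
    end <- min(length(x), start + L - 1L)
    start <- max(1L, end - L + 1L)
  }
  c(start = start, end = end)
}

# immunoproteasome-like cleavage preference: replace the C-terminal core row
processing_shift_pwm <- function(pwm) {
  bonus <- stats::setNames(rep(0, 20), AA20)
  bonus[c("F", "W", "Y", "L")] <- 3   # chymotrypsin-like C-termini (log2 odds)
  pwm[9, ] <- bonus
  pwm
}

#' Simulate MHC class I and II peptide observation tables
#'
#' Emits unique peptides as substrings of the simulated proteins, sampled
#' under allele-specific motif preferences, for two conditions x 3 biological
#' replicates x 3 technical injections per MHC class. Peptide modes:
#' \describe{
#'   \item{expression_coupled}{present in both conditions; MS1 areas track
#'     the source protein's per-replicate reporter intensity.}
#'   \item{processing_shifted}{treated-exclusive, drawn under an altered
#'     (immunoproteasome-like) C-terminal cleavage preference from detected,
#'     non-differentially-expressed proteins; areas independent of any
#'     protein change.}
#'   \item{protein_undetected}{from proteins held out of the proteome matrix;
#'     unchanged across conditions.}
#' }
#' A configured fraction of class-I-motif 9-mers is additionally injected
#' into the class II table (treated condition) as a serial-immunoprecipitation
#' carry-over fixture. If a variant table is supplied, a subset of variants
#' is covered by class-I 9-mers carrying the alternate residue.
#'
#' @param config a [sim_config()].
#' @param proteome result of [simulate_proteome()] (its truth is required).
#' @param variants optional variant table from [simulate_variants()].
#' @return List with `observations` (long data.frame: sequence, protein,
#'   start, end, condition, bio_rep, tech_rep, ms1_area, mhc_class), `truth`
#'   (one row per unique sequence: mode, allele, mhc_class, contaminant,
#'   variant flags) and `motifs` (from [simulate_allele_motifs()]).
#' @export
simulate_immunopeptidome <- function(config, proteome, variants = NULL) {
  validate_sim_config(config)
  if (is.null(proteome$truth))
    stop("dependency error: simulate the proteome first", call. = FALSE)
  reference <- proteome$reference
  truth_p <- proteome$truth
  motifs <- simulate_allele_motifs(config)
  bg <- aa_background()
  pwms <- lapply(motifs, function(cls)
    lapply(cls, function(fr) log2(sweep(pmax(fr, 1e-6), 2, bg, "/"))))

  detected <- setdiff(names(reference), truth_p$undetected)
  de_acc <- truth_p$de_proteins$accession
  nonde_detected <- setdiff(detected, de_acc)
  undetected <- truth_p$undetected

  get_int <- protein_int_cache(reference)

  N <- config$peptides_per_condition
  n_ps <- round(config$frac_processing_shift * N)
  n_ud <- round(config$frac_protein_undetected * N)
  if (length(undetected) == 0) n_ud <- 0
  n_ec <- N - n_ps - n_ud

  seen <- new.env(parent = emptyenv())
  draw_set <- function(n, mhc_class, mode, pool, pwm_set, shift = FALSE) {
    if (n <= 0 || !length(pool))
      return(data.frame(sequence = character(0), protein = character(0),
                        start = integer(0), end = integer(0),
                        allele = character(0), stringsAsFactors = FALSE))
    out <- vector("list", n)
    got <- 0L
    attempts <- 0L
    while (got < n && attempts < 60L * n) {
      attempts <- attempts + 1L
      acc <- pool[sample.int(length(pool), 1L)]
      al <- sample(names(pwm_set), 1L)
      pwm <- pwm_set[[al]]
      if (shift) pwm <- processing_shift_pwm(pwm)
      x <- get_int(acc)
      if (length(x) < 26L) next
      se <- sample_one_peptide(acc, x, pwm, mhc_class)
      seqc <- substr(reference[[acc]], se["start"], se["end"])
      if (!is.null(seen[[seqc]])) next
      seen[[seqc]] <- TRUE
      got <- got + 1L
      out[[got]] <- data.frame(sequence = seqc, protein = acc,
                               start = unname(se["start"]),
                               end = unname(se["end"]),
                               allele = al, stringsAsFactors = FALSE)
    }
    do.call(rbind, out[seq_len(got)])
  }

  set.seed(child_seed(config$seed, 5))
  cl1_ec <- draw_set(n_ec, "I", "expression_coupled", detected, pwms$I)
  cl1_ud <- draw_set(n_ud, "I", "protein_undetected", undetected, pwms$I)
  cl1_ps <- draw_set(n_ps, "I", "processing_shifted", nonde_detected, pwms$I,
                     shift = TRUE)

  set.seed(child_seed(config$seed, 6))
  cl2_ec <- draw_set(n_ec, "II", "expression_coupled", detected, pwms$II)
  cl2_ud <- draw_set(n_ud, "II", "protein_undetected", undetected, pwms$II)
  cl2_ps <- draw_set(n_ps, "II", "processing_shifted", nonde_detected, pwms$II,
                     shift = TRUE)

  # class-I carry-over 9-mers injected into the class II table (treated only)
  set.seed(child_seed(config$seed, 11))
  n_ct <- round(config$frac_class1_contamination * N)
  contam <- draw_set(n_ct, "I", "processing_shifted", nonde_detected, pwms$I,
                     shift = FALSE)
  if (nrow(contam)) {
    keep <- (contam$end - contam$start + 1L) == 9L
    contam <- contam[keep, , drop = FALSE]
  }

  # variant-bearing class-I 9-mers (sequence carries the alternate residue)
  var_pep <- NULL
  if (!is.null(variants) && nrow(variants)) {
    set.seed(child_seed(config$seed, 10))
    pick <- which(stats::runif(nrow(variants)) < 0.3)
    if (length(pick)) {
      rows <- lapply(pick, function(i) {
        v <- variants[i, ]
        plen <- nchar(reference[[v$protein]])
        offs <- sample(0:8, 9)  # variant position offset within the 9-mer
        for (o in offs) {
          start <- v$pos - o
          end <- start + 8L
          if (start >= 1L && end <= plen) {
            wt <- reference[[v$protein]]
            seqc <- substr(wt, start, end)
            substr(seqc, o + 1L, o + 1L) <- v$alt_aa
            if (is.null(seen[[seqc]])) {
              seen[[seqc]] <- TRUE
              return(data.frame(sequence = seqc, protein = v$protein,
                                start = start, end = end,
                                allele = names(pwms$I)[1],
                                stringsAsFactors = FALSE))
            }
          }
        }
        NULL
      })
      var_pep <- do.call(rbind, rows)
    }
  }

  assemble <- function(df, mode, mhc_class, contaminant = FALSE,
                       variant = FALSE) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df$mode <- mode
    df$mhc_class <- mhc_class
    df$contaminant <- contaminant
    df$variant <- variant
    df
  }
  var_mode <- if (!is.null(var_pep))
    ifelse(var_pep$protein %in% detected, "expression_coupled",
           "protein_undetected") else character(0)
  peptides <- rbind(
    assemble(cl1_ec, "expression_coupled", "I"),
    assemble(cl1_ud, "protein_undetected", "I"),
    assemble(cl1_ps, "processing_shifted", "I"),
    assemble(cl2_ec, "expression_coupled", "II"),
    assemble(cl2_ud, "protein_undetected", "II"),
    assemble(cl2_ps, "processing_shifted", "II"),
    assemble(contam, "processing_shifted", "II", contaminant = TRUE),
    if (!is.null(var_pep)) {
      v <- assemble(var_pep, "expression_coupled", "I", variant = TRUE)
      v$mode <- var_mode
      v
    })
  rownames(peptides) <- NULL

  # latent per-condition log2 abundance of each peptide's source protein
  ab <- truth_p$abundance
  ab_ctrl <- stats::setNames(ab$log2_control, ab$accession)
  ab_trt <- stats::setNames(ab$log2_treated, ab$accession)
  channels <- names(channel_groups(proteome$quant))
  qm <- as.matrix(proteome$quant[, channels])
  rownames(qm) <- proteome$quant$accession

  set.seed(child_seed(config$seed, 7))
  np <- nrow(peptides)
  eff <- stats::rnorm(np, 0, config$peptide_effect_sd)

  # biological-replicate grid (processing-shifted peptides are treated-only)
  grid <- data.frame(
    idx = rep(seq_len(np), each = 6L),
    condition = rep(rep(c("control", "treated"), each = 3L), np),
    bio_rep = rep(rep(1:3, 2L), np),
    stringsAsFactors = FALSE)
  drop_ctrl <- peptides$mode[grid$idx] == "processing_shifted" &
    grid$condition == "control"
  grid <- grid[!drop_ctrl, , drop = FALSE]
  ng <- nrow(grid)

  mode_g <- peptides$mode[grid$idx]
  prot_g <- peptides$protein[grid$idx]
  coupled <- mode_g == "expression_coupled" & prot_g %in% rownames(qm)
  base <- numeric(ng)
  if (any(coupled)) {
    ch_idx <- ifelse(grid$condition[coupled] == "control",
                     grid$bio_rep[coupled], grid$bio_rep[coupled] + 3L)
    base[coupled] <- log2(qm[cbind(match(prot_g[coupled], rownames(qm)),
                                   ch_idx)])
  }
  if (any(!coupled)) {
    mu <- ifelse(grid$condition[!coupled] == "treated" &
                   mode_g[!coupled] != "processing_shifted",
                 ab_trt[prot_g[!coupled]], ab_ctrl[prot_g[!coupled]])
    base[!coupled] <- mu + stats::rnorm(sum(!coupled), 0,
                                        config$channel_noise_sd)
  }
  log2_bio <- base + eff[grid$idx] + stats::rnorm(ng, 0, config$bio_noise_sd)

  gi <- rep(seq_len(ng), each = 3L)
  obs <- data.frame(
    sequence = peptides$sequence[grid$idx][gi],
    protein = prot_g[gi],
    start = peptides$start[grid$idx][gi],
    end = peptides$end[grid$idx][gi],
    condition = grid$condition[gi],
    bio_rep = grid$bio_rep[gi],
    tech_rep = rep(1:3, ng),
    ms1_area = 2^(log2_bio[gi] + stats::rnorm(3L * ng, 0,
                                              config$tech_noise_sd)),
    mhc_class = peptides$mhc_class[grid$idx][gi],
    stringsAsFactors = FALSE)

  set.seed(child_seed(config$seed, 8))
  if (config$missingness > 0) {
    obs <- obs[stats::runif(nrow(obs)) >= config$missingness, , drop = FALSE]
    rownames(obs) <- NULL
  }

  truth <- peptides[, c("sequence", "protein", "start", "end", "mhc_class",
                        "mode", "allele", "contaminant", "variant")]
  names(truth)[names(truth) == "allele"] <- "allele_of_origin"
  list(observations = obs, truth = truth, motifs = motifs)
}
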