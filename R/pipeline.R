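#' Default pipeline thresholds
#'
#' All stage parameters in one list: differential expression (p < 0.01,
#' fold >= 1.2), core-epitope differential presentation (p < 0.05,
#' log2fc > 1), minimum epitope lengths (9 for MHC-I; 9 and 13 for MHC-II),
#' binder rank thresholds (strong < 0.500, weak < 2.000 class I; < 10 class
#' II), the 0.2 fractional-rank thresholds, and the targeted-panel
#' significance rule (p < 0.05, q < 0.49).
#'
#' @param ... overrides by name.
#' @return Named list of parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(p_de = 0.01, fc_de = 1.2, fc_scale = "fold",
              min_channels = 4L,
              p_epitope = 0.05, lfc_epitope = 1,
              min_epitope_I = 9L, min_epitope_II = c(9L, 13L),
              strong_thresh = 0.500, weak_thresh = 2.000,
              class2_thresh = 10,
              rank_delta = 0.2, lowvar_thresh = 0.2, min_bio_presence = 2L,
              p_aqua = 0.05, q_aqua = 0.49,
              n_background = 10000L, gibbs_k = 3L, gibbs_restarts = 10L,
              seed = 42L)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Simulate the full synthetic study
#'
#' Runs the generator end to end: proteome, variants, immunopeptidome and
#' targeted AQUA panel, all derived from the one master seed in the config.
#'
#' @param config a [sim_config()].
#' @return List: `proteome`, `variants`, `peptidome`, `aqua`.
#' @export
simulate_world <- function(config) {
  proteome <- simulate_proteome(config)
  variants <- simulate_variants(config, proteome$reference)
  peptidome <- simulate_immunopeptidome(config, proteome, variants$variants)
  aqua <- simulate_aqua(config$seed)
  list(proteome = proteome, variants = variants, peptidome = peptidome,
       aqua = aqua)
}

#' Write a ready-to-run synthetic input directory
#'
#' Invokes the generator with defaults plus overrides and writes every input
#' the pipeline reads (reference and variant FASTA, variant table, protein
#' quantification matrix, peptide observations, AQUA measurements, allele
#' motif matrices) along with the ground-truth label tables and the flat
#' key=value simulation config.
#'
#' @param dir output directory (created).
#' @param overrides named list of [sim_config()] overrides.
#' @return The directory path, invisibly; truth tables are written alongside
#'   the inputs (files prefixed `truth_`).
#' @export
make_demo <- function(dir, overrides = list()) {
  cfg <- do.call(sim_config, overrides)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  world <- simulate_world(cfg)

  write_fasta(world$proteome$reference, file.path(dir, "reference.fasta"))
  if (length(world$variants$variant_fasta))
    write_fasta(world$variants$variant_fasta, file.path(dir, "variant.fasta"))
  write_tsv(world$variants$variants, file.path(dir, "variants.tsv"))

  quant <- world$proteome$quant
  write_tsv(quant, file.path(dir, "protein_quant.tsv"))
  write_tsv(world$peptidome$observations,
            file.path(dir, "peptide_observations.tsv"))
  write_tsv(world$peptidome$truth, file.path(dir, "truth_peptides.tsv"))
  write_tsv(world$proteome$truth$de_proteins,
            file.path(dir, "truth_de_proteins.tsv"))
  writeLines(world$proteome$truth$undetected,
             file.path(dir, "truth_undetected.txt"))
  write_tsv(world$aqua$measurements, file.path(dir, "aqua_measurements.tsv"))
  write_tsv(world$aqua$truth, file.path(dir, "truth_aqua.tsv"))

  for (cls in c("I", "II")) {
    for (al in names(world$peptidome$motifs[[cls]])) {
      fn <- sprintf("motif_%s_%s.tsv", cls, gsub("[*:]", "", al))
      mat <- world$peptidome$motifs[[cls]][[al]]
      df <- data.frame(allele = al, position = seq_len(nrow(mat)), mat,
                       check.names = FALSE)
      write_tsv(df, file.path(dir, fn))
    }
  }
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(v, collapse = ","), character(1)), sep = "="),
    file.path(dir, "sim_config.txt"))
  invisible(dir)
}

#' Read a flat key=value pipeline/simulation config file
#' @param path file with one `key=value` line per entry (comma-separated
#'   vectors; numerics auto-coerced).
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(x) {
    vals <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    if (!anyNA(num)) num else vals
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

load_allele_models <- function(input_dir, cls, reference, n_background,
                               seed) {
  files <- sort(list.files(input_dir, sprintf("^motif_%s_", cls),
                           full.names = TRUE))
  if (cls == "I") files <- files[!grepl("^motif_II_", basename(files))]
  models <- list()
  for (i in seq_along(files)) {
    df <- read_tsv(files[i])
    mat <- as.matrix(df[, AA20])
    models[[i]] <- build_allele_model(df$allele[1], mat, reference,
                                      n_background,
                                      child_seed(seed, 500L + i))
  }
  models
}

# mean MS1 area per (sequence, condition, bio_rep), wide 6-column layout
sample_abundance_matrix <- function(obs, sequences) {
  sub <- obs[obs$sequence %in% sequences, , drop = FALSE]
  agg <- stats::aggregate(ms1_area ~ sequence + condition + bio_rep, sub,
                          mean)
  cols <- c(paste0("control_", 1:3), paste0("treated_", 1:3))
  wide <- data.frame(sequence = sort(unique(agg$sequence)),
                     stringsAsFactors = FALSE)
  for (cn in cols) wide[[cn]] <- NA_real_
  key <- paste0(agg$condition, "_", agg$bio_rep)
  idx <- cbind(match(agg$sequence, wide$sequence), match(key, cols) + 1L)
  wide[idx] <- agg$ms1_area
  wide
}

stage_log <- function(report, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  report$log <- c(report$log, sprintf("[%s] %s", stage, msg))
  report
}

#' Run the integrated pipeline end to end
#'
#' Executes, in order: variant database construction, proteome differential
#' expression, repertoire analysis, core-epitope landscapes, binding-motif
#' analysis, proteome-integration categorization, and targeted AQUA
#' quantification, reading the inputs written by [make_demo()] (or
#' identically shaped real exports) and writing one TSV bundle per stage.
#' Every output carries the config fingerprint and seed in header comments;
#' identical config and inputs give byte-identical outputs.
#'
#' @param input_dir directory of input tables (see [make_demo()]).
#' @param out_dir output directory (created).
#' @param config a [pipeline_config()] list.
#' @return Report list (per-stage summaries and output paths), invisibly.
#' @export
run_pipeline <- function(input_dir, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- fingerprint(config)
  hdr <- c(sprintf("config_fingerprint: %s", fp),
           sprintf("seed: %d", as.integer(config$seed)))
  report <- list(log = character(0), fingerprint = fp)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## 1. variant proteome -----------------------------------------------------
  reference <- read_fasta(file.path(input_dir, "reference.fasta"))
  variants <- read_tsv(file.path(input_dir, "variants.tsv"))
  db <- stage("variants", {
    vfa <- vapply(split(variants, variants$protein), function(vv)
      apply_variants(reference[[vv$protein[1]]], vv), character(1))
    names(vfa) <- paste0(names(vfa), "_var")
    build_search_database(reference, vfa)
  })
  write_tsv(db$entries, file.path(out_dir, "search_database.tsv"), hdr)
  report <- stage_log(report, "variants",
                      "%d variants -> %d database entries (%d decoys)",
                      nrow(variants), nrow(db$entries),
                      sum(db$entries$decoy))

  ## 2. proteome differential expression -------------------------------------
  quant <- read_tsv(file.path(input_dir, "protein_quant.tsv"))
  de <- stage("proteome", {
    filt <- filter_quant_peptides(quant, config$min_channels)
    differential_expression(filt, config$p_de, config$fc_de,
                            config$fc_scale)
  })
  write_tsv(de, file.path(out_dir, "differential_expression.tsv"), hdr)
  report <- stage_log(report, "proteome",
                      "%d proteins tested, %d differentially expressed",
                      nrow(de), sum(de$is_de))
  report$de <- de

  ## 3. repertoires -----------------------------------------------------------
  obs <- read_tsv(file.path(input_dir, "peptide_observations.tsv"))
  reps <- list(); excl <- list()
  for (cls in c("I", "II")) {
    for (cond in c("control", "treated")) {
      sub <- obs[obs$mhc_class == cls & obs$condition == cond, , drop = FALSE]
      reps[[paste(cls, cond)]] <- stage("repertoire",
                                        replicate_consistent_set(sub))
    }
    excl[[cls]] <- exclusive_sets(reps[[paste(cls, "control")]],
                                  reps[[paste(cls, "treated")]])
    ex <- excl[[cls]]
    write_tsv(data.frame(
      set = rep(c("control_only", "treated_only", "shared"),
                lengths(ex)),
      sequence = unlist(ex, use.names = FALSE)),
      file.path(out_dir, sprintf("repertoire_%s.tsv", cls)), hdr)
    report <- stage_log(report, "repertoire",
                        "MHC-%s: %d control-only / %d treated-only / %d shared",
                        cls, length(ex$control_only),
                        length(ex$treated_only), length(ex$shared))
  }
  report$repertoires <- reps
  report$exclusive <- excl

  ## 4. core-epitope landscapes ------------------------------------------------
  sample_cols <- c(paste0("control_", 1:3), paste0("treated_", 1:3))
  cond_of_col <- rep(c("control", "treated"), each = 3)
  meta_all <- obs[!duplicated(obs$sequence),
                  c("sequence", "protein", "start", "end", "mhc_class")]
  epitopes <- list()
  runs <- list(list(cls = "I", ml = config$min_epitope_I))
  for (ml in config$min_epitope_II)
    runs <- c(runs, list(list(cls = "II", ml = ml)))
  for (r in runs) {
    cls <- r$cls; ml <- as.integer(r$ml)
    consistent <- union(reps[[paste(cls, "control")]]$peptides$sequence,
                        reps[[paste(cls, "treated")]]$peptides$sequence)
    wide <- sample_abundance_matrix(obs[obs$mhc_class == cls, ], consistent)
    peps <- merge(meta_all[meta_all$mhc_class == cls,
                           c("sequence", "protein", "start", "end")],
                  wide, by = "sequence", sort = TRUE)
    ce <- stage("epitopes",
                infer_core_epitopes(peps, ml, sample_cols))
    imp <- stage("epitopes", impute_missing(ce$cores[, sample_cols]))
    dp <- stage("epitopes",
                differential_presentation(imp$matrix, cond_of_col,
                                          config$p_epitope,
                                          config$lfc_epitope))
    out <- cbind(ce$cores, dp)
    tag <- sprintf("%s_min%d", cls, ml)
    write_tsv(out, file.path(out_dir, sprintf("core_epitopes_%s.tsv", tag)),
              hdr)
    epitopes[[tag]] <- list(cores = out, unresolvable = ce$unresolvable)
    report <- stage_log(report, "epitopes",
                        "MHC-%s (min %d): %d cores from %d peptides; %d up-treated / %d up-control (raw p)",
                        cls, ml, nrow(out), nrow(peps),
                        sum(dp$direction == "up_treated"),
                        sum(dp$direction == "up_control"))
  }
  report$epitopes <- epitopes

  ## 5. binding motifs ----------------------------------------------------------
  models1 <- stage("binding",
                   load_allele_models(input_dir, "I", reference,
                                      config$n_background, config$seed))
  models2 <- stage("binding",
                   load_allele_models(input_dir, "II", reference,
                                      config$n_background, config$seed))
  pep1 <- union(reps[["I control"]]$peptides$sequence,
                reps[["I treated"]]$peptides$sequence)
  calls <- stage("binding",
                 assign_alleles(pep1, models1, "I", config$strong_thresh,
                                config$weak_thresh))
  write_tsv(calls, file.path(out_dir, "binder_calls_I.tsv"), hdr)
  pep2 <- union(reps[["II control"]]$peptides$sequence,
                reps[["II treated"]]$peptides$sequence)
  contam <- stage("binding",
                  flag_class_crosscontamination(pep2, models1, models2))
  write_tsv(data.frame(sequence = pep2, class1_contaminant = contam),
            file.path(out_dir, "class2_contamination.tsv"), hdr)

  cores9 <- epitopes[[sprintf("I_min%d", config$min_epitope_I)]]$cores
  cores9 <- cores9$core_sequence[nchar(cores9$core_sequence) == 9]
  clusters <- NULL
  if (length(cores9) >= 5L * config$gibbs_k) {
    clusters <- stage("binding",
                      gibbs_cluster(cores9, config$gibbs_k,
                                    child_seed(config$seed, 600),
                                    restarts = config$gibbs_restarts))
    cl_df <- data.frame(core = cores9, cluster = clusters$assignments)
    write_tsv(cl_df, file.path(out_dir, "motif_clusters_I.tsv"), hdr)
    for (ci in seq_len(clusters$k))
      if (clusters$clusters[[ci]]$size > 0)
        write_pssm(clusters$clusters[[ci]]$pssm,
                   file.path(out_dir, sprintf("motif_cluster_I_%d_pssm.tsv",
                                              ci)))
  }
  report <- stage_log(report, "binding",
                      "MHC-I: %d binder calls (%d strong, %d weak); %d class-II peptides flagged as class-I carry-over",
                      nrow(calls), sum(calls$binder_class == "strong"),
                      sum(calls$binder_class == "weak"), sum(contam))
  report$binder_calls <- calls
  report$contamination <- stats::setNames(contam, pep2)
  report$clusters <- clusters

  ## 6. integration -------------------------------------------------------------
  categories <- list()
  for (cls in c("I", "II")) {
    sub <- obs[obs$mhc_class == cls, , drop = FALSE]
    agg <- stats::aggregate(ms1_area ~ sequence + condition + bio_rep, sub,
                            mean)
    names(agg)[names(agg) == "ms1_area"] <- "abundance"
    fr <- stage("integration", fractional_ranks(agg))
    prof <- stage("integration", rank_profiles(fr))
    filt <- stage("integration",
                  low_variance_filter(prof, config$lowvar_thresh,
                                      config$min_bio_presence))
    meta <- meta_all[meta_all$mhc_class == cls, ]
    cats <- stage("integration",
                  categorize_pmhc(filt, meta, de, quant$accession,
                                  config$rank_delta,
                                  config$min_bio_presence))
    repertoire_seqs <- list(
      control = filt$sequence[filt$n_bio_control >= config$min_bio_presence],
      treated = filt$sequence[filt$n_bio_treated >= config$min_bio_presence])
    cats <- stage("integration",
                  overlap_subcategory(cats, meta, repertoire_seqs))
    if (cls == "II")
      cats$class1_contaminant <- as.logical(
        report$contamination[cats$sequence])
    write_tsv(cats, file.path(out_dir, sprintf("categories_%s.tsv", cls)),
              c(hdr, sprintf("rank_delta_thresh: %s", config$rank_delta)))
    tb <- table(cats$top_category)
    write_tsv(data.frame(top_category = names(tb),
                         n = as.integer(tb),
                         fraction = as.numeric(tb) / nrow(cats)),
              file.path(out_dir, sprintf("category_summary_%s.tsv", cls)),
              hdr)
    report <- stage_log(report, "integration",
                        "MHC-%s: %d categorized (%s); %d dropped by the low-variance filter",
                        cls, nrow(cats),
                        paste(names(tb), as.integer(tb), sep = "=",
                              collapse = ", "),
                        nrow(attr(filt, "dropped")))
    categories[[cls]] <- cats
  }
  report$categories <- categories

  ## 7. targeted quantification ---------------------------------------------------
  aqua <- read_tsv(file.path(input_dir, "aqua_measurements.tsv"))
  tq <- stage("aqua", differential_targets(aqua, config$p_aqua,
                                           config$q_aqua))
  write_tsv(tq$results, file.path(out_dir, "aqua_differential.tsv"), hdr)
  write_tsv(data.frame(peptide = rownames(tq$z_matrix), tq$z_matrix,
                       check.names = FALSE),
            file.path(out_dir, "aqua_zscores.tsv"), hdr)
  report <- stage_log(report, "aqua",
                      "%d panel peptides, %d significant (p<%.2f, q<%.2f)",
                      nrow(tq$results), sum(tq$results$significant),
                      config$p_aqua, config$q_aqua)
  report$aqua <- tq

  writeLines(report$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(report)
}
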