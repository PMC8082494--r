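#' Allele-specific position-weight binding model
#'
#' Internal stand-in for external MHC binding predictors: a 9 x 20 log-odds
#' matrix over the standard residues plus an empirical background score
#' distribution from random proteome 9-mers, from which percentile ranks are
#' computed (lower rank = stronger predicted binding).
#'
#' @param allele allele name, e.g. `"HLA-A*02:01"`.
#' @param pwm 9 x 20 numeric matrix of log2 odds versus background; columns
#'   must be named by the 20 standard residues.
#' @param background_scores numeric vector of scores of random proteome
#'   9-mers under `pwm` (sorted internally).
#' @param core_length binding-core length (9).
#' @return An `allele_model` object.
#' @export
allele_model <- function(allele, pwm, background_scores, core_length = 9L) {
  stopifnot(is.matrix(pwm), nrow(pwm) == core_length)
  if (is.null(colnames(pwm)) || !setequal(colnames(pwm), AA20))
    stop("pwm columns must be named by the 20 standard residues", call. = FALSE)
  pwm <- pwm[, AA20, drop = FALSE]
  if (length(background_scores) < 1)
    stop("config error: empty background score distribution", call. = FALSE)
  structure(list(allele = allele,
                 core_length = as.integer(core_length),
                 pwm = pwm,
                 background_scores = sort(as.numeric(background_scores))),
            class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat(sprintf("allele_model %s (core %d, background n=%d)\n",
              x$allele, x$core_length, length(x$background_scores)))
  invisible(x)
}

#' Build an allele model from positional residue frequencies
#'
#' Converts a position x residue frequency matrix to log2 odds against the
#' background composition and calibrates the background score distribution by
#' scoring `n_background` 9-mers sampled uniformly from the supplied proteome.
#'
#' @param allele allele name.
#' @param freqs 9 x 20 positional probability matrix (rows sum to 1).
#' @param reference named character vector of protein sequences.
#' @param n_background number of background 9-mers (default 10000).
#' @param seed integer seed for background sampling.
#' @return An [allele_model()].
#' @export
build_allele_model <- function(allele, freqs, reference,
                               n_background = 10000L, seed = 1L) {
  bg <- aa_background()
  freqs <- freqs[, AA20, drop = FALSE]
  pwm <- log2(sweep(pmax(freqs, 1e-6), 2, bg, "/"))
  kmers <- sample_kmers(reference, 9L, n_background, seed)
  scores <- pwm_window_scores(pwm, kmers)
  allele_model(allele, pwm, scores)
}

#' Sample k-mers uniformly from a set of protein sequences
#' @param reference named character vector of sequences.
#' @param k k-mer length.
#' @param n number of k-mers.
#' @param seed integer seed.
#' @return Character vector of `n` k-mers.
#' @export
sample_kmers <- function(reference, k, n, seed) {
  eligible <- reference[nchar(reference) >= k]
  if (!length(eligible)) stop("no sequence of length >= ", k, call. = FALSE)
  set.seed(seed)
  idx <- sample.int(length(eligible), n, replace = TRUE)
  starts <- vapply(nchar(eligible)[idx] - k + 1L,
                   function(m) sample.int(m, 1L), integer(1))
  substr(rep(eligible[idx], 1L), starts, starts + k - 1L)
}

# peptides -> integer matrix of residue indices (rows = peptides), one length
peptide_int_matrix <- function(peptides) {
  sp <- strsplit(peptides, "", fixed = TRUE)
  m <- matrix(match(unlist(sp), AA20), nrow = length(peptides), byrow = TRUE)
  if (anyNA(m)) {
    bad <- unique(setdiff(unlist(sp), AA20))
    stop("alphabet error: residue(s) outside the 20-letter alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m
}

# score exact 9-mers against a pwm (vectorized)
pwm_window_scores <- function(pwm, kmers) {
  m <- peptide_int_matrix(kmers)
  stopifnot(ncol(m) == nrow(pwm))
  s <- numeric(nrow(m))
  for (p in seq_len(nrow(pwm))) s <- s + pwm[p, m[, p]]
  s
}

#' Score peptides against an allele model
#'
#' The score is the best 9-residue core window: peptides of length 9 are
#' scored directly; longer peptides take the maximum over all sliding 9-mer
#' windows minus `gap_penalty * (L - 9)` when `penalize_length = TRUE`
#' (class I convention) or with no penalty (class II core scan); 8-mers are
#' scored as the best alignment skipping one PWM position, minus one
#' `gap_penalty`.
#'
#' @param model an [allele_model()].
#' @param peptides character vector of peptide sequences.
#' @param gap_penalty log2-odds units subtracted per residue of length
#'   deviation from the 9-mer core (default 1).
#' @param penalize_length apply the length-gap penalty (class I default).
#' @return Numeric vector of log-odds scores.
#' @export
score_peptides <- function(model, peptides, gap_penalty = 1,
                           penalize_length = TRUE) {
  stopifnot(inherits(model, "allele_model"))
  pwm <- model$pwm
  K <- model$core_length
  out <- numeric(length(peptides))
  lens <- nchar(peptides)
  if (any(lens < K - 1L))
    stop("peptide shorter than ", K - 1L, " residues cannot be scored",
         call. = FALSE)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    m <- peptide_int_matrix(peptides[idx])
    if (L == K - 1L) {
      # one deletion relative to the core: skip each PWM row in turn
      best <- rep(-Inf, length(idx))
      for (d in seq_len(K)) {
        rows <- setdiff(seq_len(K), d)
        s <- numeric(length(idx))
        for (j in seq_along(rows)) s <- s + pwm[rows[j], m[, j]]
        best <- pmax(best, s)
      }
      out[idx] <- best - if (penalize_length) gap_penalty else 0
    } else {
      best <- rep(-Inf, length(idx))
      for (t in seq_len(L - K + 1L)) {
        s <- numeric(length(idx))
        for (p in seq_len(K)) s <- s + pwm[p, m[, t + p - 1L]]
        best <- pmax(best, s)
      }
      pen <- if (penalize_length) gap_penalty * (L - K) else 0
      out[idx] <- best - pen
    }
  }
  out
}

#' @rdname score_peptides
#' @param peptide single peptide sequence.
#' @export
score_peptide <- function(model, peptide, gap_penalty = 1,
                          penalize_length = TRUE) {
  score_peptides(model, peptide, gap_penalty, penalize_length)[1]
}

#' Percentile rank of scores under an allele model
#'
#' `rank = 100 * (fraction of background scores strictly greater than the
#' score)`; 0 is the strongest possible binder, 100 the weakest.
#'
#' @param score numeric vector of log-odds scores.
#' @param model an [allele_model()].
#' @return Numeric vector of ranks in \[0, 100\].
#' @export
percentile_rank <- function(score, model) {
  stopifnot(inherits(model, "allele_model"))
  bg <- model$background_scores
  if (!length(bg)) stop("config error: empty background", call. = FALSE)
  n <- length(bg)
  100 * (n - findInterval(score, bg)) / n
}

#' Assign peptides to alleles with binder-class thresholds
#'
#' For each peptide the best (lowest) percentile rank across the supplied
#' allele models is taken. Class I: strong binder at rank < 0.500, weak at
#' rank < 2.000; class II: binder at rank < 10. Exact rank ties below the
#' reporting threshold are reported as binders for all tied alleles.
#'
#' @param peptides character vector.
#' @param models list of [allele_model()] objects.
#' @param mhc_class `"I"` or `"II"`.
#' @param strong_thresh,weak_thresh class-I rank thresholds (0.500 / 2.000).
#' @param class2_thresh class-II binder rank threshold (10).
#' @param gap_penalty passed to [score_peptides()] for class I.
#' @return data.frame: `peptide`, `best_rank`, `best_alleles` (comma-joined
#'   on exact ties), `binder_class`.
#' @export
assign_alleles <- function(peptides, models, mhc_class = c("I", "II"),
                           strong_thresh = 0.500, weak_thresh = 2.000,
                           class2_thresh = 10, gap_penalty = 1) {
  mhc_class <- match.arg(mhc_class)
  if (!length(models)) stop("config error: no allele models", call. = FALSE)
  ranks <- sapply(models, function(m) {
    percentile_rank(score_peptides(m, peptides, gap_penalty,
                                   penalize_length = (mhc_class == "I")), m)
  })
  ranks <- matrix(ranks, nrow = length(peptides))
  colnames(ranks) <- vapply(models, `[[`, character(1), "allele")
  best <- apply(ranks, 1, min)
  best_alleles <- vapply(seq_along(peptides), function(i) {
    paste(colnames(ranks)[ranks[i, ] == best[i]], collapse = ",")
  }, character(1))
  binder_class <- if (mhc_class == "I") {
    ifelse(best < strong_thresh, "strong",
           ifelse(best < weak_thresh, "weak", "non_binder"))
  } else {
    ifelse(best < class2_thresh, "binder", "non_binder")
  }
  data.frame(peptide = peptides, best_rank = best,
             best_alleles = best_alleles, binder_class = binder_class,
             stringsAsFactors = FALSE)
}

# position x residue counts of equal-length sequences (integer matrix input)
motif_counts <- function(m) {
  L <- ncol(m)
  counts <- matrix(0L, L, 20, dimnames = list(NULL, AA20))
  for (p in seq_len(L)) {
    tb <- tabulate(m[, p], nbins = 20L)
    counts[p, ] <- tb
  }
  counts
}

# one-hot residue encoding (n x 20L), used for the k-means restart seed
onehot_encode <- function(m) {
  L <- ncol(m)
  oh <- matrix(0, nrow(m), 20L * L)
  for (p in seq_len(L)) oh[cbind(seq_len(nrow(m)), (p - 1L) * 20L + m[, p])] <- 1
  oh
}

# summed positional KLD (bits) of a pseudocount-regularized count matrix
counts_kld <- function(counts, pseudocount, qmat) {
  n <- sum(counts[1, ])
  p <- (counts + pseudocount) / (n + 20 * pseudocount)
  sum(p * log2(p / qmat))
}

#' Kullback-Leibler divergence of a motif from background
#'
#' Positional residue distributions are estimated with a +`pseudocount` per
#' residue per position; the reported value is the sum over positions of
#' `sum_r p log2(p/q)` in bits, where `q` is the background composition.
#'
#' @param sequences equal-length peptide cores.
#' @param pseudocount added per residue per position before normalization.
#' @param background named residue frequency vector.
#' @return List with `kld` (numeric), `pssm` (position x residue probability
#'   matrix) and `counts`.
#' @export
motif_kld <- function(sequences, pseudocount = 0.05,
                      background = aa_background()) {
  m <- peptide_int_matrix(sequences)
  counts <- motif_counts(m)
  L <- nrow(counts)
  qmat <- matrix(background[AA20], L, 20, byrow = TRUE)
  p <- (counts + pseudocount) / (length(sequences) + 20 * pseudocount)
  colnames(p) <- AA20
  list(kld = sum(p * log2(p / qmat)), pssm = p, counts = counts)
}

#' Cluster fixed-length peptide cores into sequence motifs by Gibbs sampling
#'
#' A simplified Gibbs clusterer: cluster assignments are sampled to maximize
#' the size-weighted total Kullback-Leibler divergence
#' `sum_c n_c * KLD_c` (bits) of the pseudocount-regularized cluster motifs
#' from the background composition. Moves are single-sequence reassignments
#' sampled from a fixed-temperature softmax over the objective; the
#' best-scoring partition over all restarts and sweeps is returned.
#' Deterministic for a fixed seed.
#'
#' Random 50/50 initializations can freeze into symmetric mixed local optima
#' that single-sequence moves cannot escape, so the first restart is seeded
#' with k-means on one-hot residue encodings (deterministic given the seed);
#' the remaining restarts are random.
#'
#' @param cores character vector of equal-length peptides (>= 5 per cluster).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts independent random initializations (default 50).
#' @param sweeps full reassignment passes per restart (default 30).
#' @param temperature softmax temperature in objective units (default 1).
#' @param pseudocount motif pseudocount (default 0.05).
#' @param background named residue frequency vector.
#' @return Object of class `motif_clusters`: list with `assignments`
#'   (integer vector), `clusters` (per cluster: `members`, `pssm`, `kld`,
#'   `size`), `objective`, `k`.
#' @export
gibbs_cluster <- function(cores, k, seed, restarts = 50L, sweeps = 30L,
                          temperature = 1, pseudocount = 0.05,
                          background = aa_background()) {
  if (k < 1) stop("config error: k must be >= 1", call. = FALSE)
  n <- length(cores)
  if (n < 5L * k)
    stop("config error: need at least 5 cores per cluster", call. = FALSE)
  if (length(unique(nchar(cores))) != 1L)
    stop("all cores must have equal length", call. = FALSE)
  m <- peptide_int_matrix(cores)
  L <- ncol(m)
  qmat <- matrix(background[AA20], L, 20, byrow = TRUE)
  f <- function(counts) {
    nc <- sum(counts[1, ])
    if (nc == 0) return(0)
    nc * counts_kld(counts, pseudocount, qmat)
  }

  best_obj <- -Inf
  best_z <- NULL
  for (r in seq_len(restarts)) {
    set.seed(child_seed(seed, 1000L + r))
    if (r == 1L && k > 1L) {
      z <- tryCatch(stats::kmeans(onehot_encode(m), centers = k,
                                  nstart = 5L)$cluster,
                    error = function(e) sample.int(k, n, replace = TRUE))
    } else {
      z <- sample.int(k, n, replace = TRUE)
      if (k > 1) z[seq_len(k)] <- seq_len(k)  # no empty start clusters
    }
    counts <- lapply(seq_len(k), function(c) motif_counts(m[z == c, , drop = FALSE]))
    fvals <- vapply(counts, f, numeric(1))
    obj <- sum(fvals)
    if (obj > best_obj) { best_obj <- obj; best_z <- z }
    for (s in seq_len(sweeps)) {
      for (i in seq_len(n)) {
        ci <- z[i]
        idx <- cbind(seq_len(L), m[i, ])
        counts[[ci]][idx] <- counts[[ci]][idx] - 1L
        f_wo <- f(counts[[ci]])
        base <- obj - fvals[ci] + f_wo
        cand <- numeric(k)
        for (c in seq_len(k)) {
          counts[[c]][idx] <- counts[[c]][idx] + 1L
          f_w <- f(counts[[c]])
          cand[c] <- if (c == ci) base - f_wo + f_w else base - fvals[c] + f_w
          counts[[c]][idx] <- counts[[c]][idx] - 1L
        }
        pr <- exp((cand - max(cand)) / temperature)
        cnew <- sample.int(k, 1L, prob = pr)
        counts[[cnew]][idx] <- counts[[cnew]][idx] + 1L
        if (cnew != ci) fvals[ci] <- f_wo
        fvals[cnew] <- f(counts[[cnew]])
        z[i] <- cnew
        obj <- sum(fvals)
        if (obj > best_obj) { best_obj <- obj; best_z <- z }
      }
    }
  }

  clusters <- lapply(seq_len(k), function(c) {
    members <- cores[best_z == c]
    if (length(members)) {
      mk <- motif_kld(members, pseudocount, background)
      list(members = members, pssm = mk$pssm, kld = mk$kld,
           size = length(members))
    } else {
      list(members = character(0), pssm = NULL, kld = 0, size = 0L)
    }
  })
  structure(list(assignments = best_z, clusters = clusters,
                 objective = best_obj, k = k),
            class = "motif_clusters")
}

#' @export
print.motif_clusters <- function(x, ...) {
  cat(sprintf("motif_clusters: k=%d, objective=%.2f\n", x$k, x$objective))
  for (i in seq_len(x$k))
    cat(sprintf("  cluster %d: n=%d, KLD=%.3f bits\n",
                i, x$clusters[[i]]$size, x$clusters[[i]]$kld))
  invisible(x)
}

#' Write allele model PSSMs / cluster frequency matrices as TSV
#' @param mat position x residue numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(mat, path) {
  df <- data.frame(position = seq_len(nrow(mat)), mat, check.names = FALSE)
  write_tsv(df, path)
}
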