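#' ligandomics: integrated immunopeptidome and proteome analysis
#'
#' Tools to simulate, filter, consolidate and classify MHC-presented peptide
#' repertoires measured alongside a TMT proteome, including the rank-based
#' categorization of peptides into expression-driven versus processing-driven
#' presentation changes.
#'
#' @keywords internal
"_PACKAGE"

#' The 20 standard amino-acid one-letter codes
#'
#' Alphabetical one-letter codes; the column order of every PWM / PSSM /
#' frequency matrix in the package.
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Background amino-acid frequencies
#'
#' Approximate human proteome residue frequencies, normalized to sum to 1.
#' Used as the background distribution for protein simulation, PWM log-odds
#' and Kullback-Leibler divergences.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
aa_background <- function() {
  f <- c(A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365,
         G = 0.0657, H = 0.0263, I = 0.0433, K = 0.0572, L = 0.0996,
         M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
         S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0267)
  f <- f[AA20]
  f / sum(f)
}

#' Derive a deterministic child seed from a master seed
#'
#' One master seed drives the whole pipeline; each randomized sub-step draws
#' its own stream so that reordering or skipping stages does not perturb the
#' others. Values stay below 2^31 - 1.
#'
#' @param seed master seed (integer-valued).
#' @param stream small integer identifying the consumer.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((abs(as.numeric(seed)) * 7919 + 104729 * as.numeric(stream)) %%
               2147483563) + 1L
}

#' 32-bit FNV-1a fingerprint of an R object
#'
#' Stable content hash used to stamp pipeline outputs with their generating
#' configuration (no external digest dependency).
#'
#' @param x any R object; hashed via its deparsed form.
#' @return Character scalar, 8 hex digits.
#' @export
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay inside 2^53
    lo16 <- h %% 65536
    hi16 <- h %/% 65536
    h <- (lo16 * 16777619 + ((hi16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a table as plain TSV (deterministic formatting)
#' @param x data.frame.
#' @param path output file.
#' @param comment optional character vector written as leading '# ' lines.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate random protein sequences from the background composition
#' @param n number of proteins.
#' @param length_range integer (min, max) residue lengths, sampled uniformly.
#' @param seed integer seed.
#' @return Named character vector of sequences.
#' @keywords internal
random_proteins <- function(n, length_range, seed) {
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  bg <- aa_background()
  vapply(lens, function(L) {
    paste(sample(AA20, L, replace = TRUE, prob = bg), collapse = "")
  }, character(1))
}
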