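# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# literal Benjamini-Hochberg step-up: sort, multiply by m/rank, cumulative
# minimum from the largest p, cap at 1, restore input order
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- sorted * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# union-find connected components of intervals under pairwise overlap
components_oracle <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && start[i] <= end[j] && start[j] <= end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# a tiny deterministic world shared by slower tests
tiny_config <- function(seed = 11, ...) {
  sim_config(n_proteins = 150, peptides_per_condition = 300,
             n_de_proteins = 6, n_variants = 8, seed = seed, ...)
}

random_peptide <- function(n, len = 9) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y"), len, replace = TRUE),
          collapse = ""), character(1))
}
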