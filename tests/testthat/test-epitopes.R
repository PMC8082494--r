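pep_df <- function(seqs, starts, samples = NULL, protein = "P1") {
  df <- data.frame(sequence = seqs, protein = protein, start = starts,
                   end = starts + nchar(seqs) - 1L, stringsAsFactors = FALSE)
  if (!is.null(samples)) df <- cbind(df, samples)
  df
}

test_that("simple consolidation cases match the interval-intersection rule", {
  s1 <- data.frame(s1 = c(10, 20))
  # a lone 9-mer is its own core
  one <- infer_core_epitopes(pep_df("AAAAAAAAA", 5L, data.frame(s1 = 10)),
                             9L, "s1")
  expect_equal(nrow(one$cores), 1)
  expect_equal(one$cores$core_start, 5)
  expect_equal(one$cores$core_end, 13)
  expect_identical(one$cores$core_sequence, "AAAAAAAAA")
  expect_equal(one$cores$s1, 10)

  # a 9-mer nested in an 11-mer sharing the span -> core = the 9-mer,
  # abundance = sum of both areas
  nested <- infer_core_epitopes(
    pep_df(c("CCCCCCCCC", "ACCCCCCCCCA"), c(6L, 5L), s1), 9L, "s1")
  expect_equal(nrow(nested$cores), 1)
  expect_equal(nested$cores$core_start, 6)
  expect_equal(nested$cores$core_end, 14)
  expect_identical(nested$cores$core_sequence, "CCCCCCCCC")
  expect_equal(nested$cores$s1, 30)

  # no shared position -> two cores
  two <- infer_core_epitopes(
    pep_df(c("AAAAAAAAA", "CCCCCCCCC"), c(1L, 50L), s1), 9L, "s1")
  expect_equal(nrow(two$cores), 2)

  # adjacent but non-overlapping intervals do not merge
  adj <- infer_core_epitopes(
    pep_df(c("AAAAAAAAA", "CCCCCCCCC"), c(1L, 10L), s1), 9L, "s1")
  expect_equal(nrow(adj$cores), 2)

  expect_error(infer_core_epitopes(
    data.frame(sequence = "AAAA", protein = "P1", start = 1L, end = 9L,
               s1 = 1), 9L, "s1"), "coordinate error")
})

test_that("component structure equals a union-find oracle and area is conserved", {
  set.seed(77)
  for (inst in 1:120) {
    n <- sample(2:12, 1)
    starts <- sample(1:50, n, replace = TRUE)
    lens <- sample(5:12, n, replace = TRUE)
    repeat {
      seqs <- vapply(lens, function(L)
        paste(sample(c("A", "C", "D", "E", "F", "G", "H", "K"), L,
                     replace = TRUE), collapse = ""), character(1))
      if (!anyDuplicated(seqs)) break
    }
    samples <- data.frame(s1 = runif(n, 1, 100), s2 = runif(n, 1, 100))
    samples$s2[runif(n) < 0.2] <- NA
    peps <- pep_df(seqs, as.integer(starts), samples)
    res <- infer_core_epitopes(peps, 5L, c("s1", "s2"))

    comp <- components_oracle(peps$start, peps$end)
    # components whose intersection is long enough must appear verbatim
    seq_to_core <- integer(nrow(peps))
    for (ci in seq_len(nrow(res$cores))) {
      members <- strsplit(res$cores$members[ci], ",")[[1]]
      idx <- which(peps$sequence %in% members)
      # containment: the core lies inside every member interval
      expect_true(all(peps$start[idx] <= res$cores$core_start[ci]))
      expect_true(all(peps$end[idx] >= res$cores$core_end[ci]))
      expect_gte(res$cores$core_end[ci] - res$cores$core_start[ci] + 1, 5)
    }
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      cs <- max(peps$start[idx]); ce <- min(peps$end[idx])
      if (ce - cs + 1 >= 5) {
        hit <- which(res$cores$core_start == cs & res$cores$core_end == ce &
                       res$cores$n_members == length(idx))
        expect_length(hit, 1)
        for (sc in c("s1", "s2")) {
          vals <- peps[idx, sc]
          oracle_sum <- if (all(is.na(vals))) NA_real_
                        else sum(vals, na.rm = TRUE)
          expect_equal(res$cores[hit, sc], oracle_sum)
        }
      }
    }
    # conservation: cores + unresolvable account for all input area
    for (sc in c("s1", "s2")) {
      total <- sum(peps[[sc]], na.rm = TRUE)
      got <- sum(res$cores[[sc]], na.rm = TRUE) +
        sum(res$unresolvable[[sc]], na.rm = TRUE)
      expect_equal(got, total)
    }
    # every peptide lands in exactly one core or the unresolvable list
    n_in_cores <- sum(res$cores$n_members)
    expect_equal(n_in_cores + nrow(res$unresolvable), nrow(peps))
  }
})

test_that("minimum-value imputation follows the per-sample rule", {
  m <- rbind(c(4, 10, NA), c(8, NA, 7), c(NA, 12, 9))
  colnames(m) <- c("a", "b", "c")
  out <- impute_missing(m)
  expect_equal(unname(out$matrix[3, "a"]), 4)    # column minimum
  expect_equal(unname(out$matrix[2, "b"]), 10)
  expect_equal(unname(out$matrix[1, "c"]), 7)
  expect_equal(out$matrix[!out$imputed], m[!is.na(m)])  # measured untouched
  # no missing cells -> unchanged; identical column -> that value
  full <- matrix(1:4, 2)
  expect_equal(impute_missing(full)$matrix, full)
  same <- matrix(c(5, 5, NA), 3)
  expect_equal(impute_missing(same)$matrix[3, 1], 5)
  expect_error(impute_missing(matrix(NA_real_, 2, 1)), "imputation impossible")
})

test_that("differential presentation calls direction at p<0.05 and |log2fc|>1", {
  set.seed(41)
  flat <- 2^matrix(rnorm(6, 10, 0.1), 1)
  m <- rbind(flat,
             flat * c(1, 1, 1, 16, 16, 16),    # strong treated increase
             flat * c(16, 16, 16, 1, 1, 1))    # strong control increase
  cond <- rep(c("control", "treated"), each = 3)
  dp <- differential_presentation(m, cond)
  expect_identical(dp$direction, c("unchanged", "up_treated", "up_control"))
  expect_equal(dp$q_value, benjamini_hochberg(dp$p_value))
  expect_error(differential_presentation(m[, c(1, 4, 5, 6)],
                                         cond[c(1, 4, 5, 6)]),
               "insufficient replicates")
  m0 <- m; m0[1, 1] <- 0
  expect_error(differential_presentation(m0, cond), "log-domain")
})

test_that("null core matrices are called at the matched Monte-Carlo rate", {
  # stated world: per-sample log2 noise 0.4 around a log-normal core mean
  n <- 500
  set.seed(52)
  m <- 2^(matrix(rnorm(6 * n, 0, 0.4), n) + rnorm(n, 18, 2))
  dp <- differential_presentation(m, rep(c("control", "treated"), each = 3))
  rate <- mean(dp$direction != "unchanged")
  set.seed(53)
  B <- 20000
  om <- matrix(rnorm(6 * B, 0, 0.4), B)
  op <- vapply(seq_len(B), function(i)
    t.test(om[i, 1:3], om[i, 4:6])$p.value, numeric(1))
  ofc <- rowMeans(om[, 4:6]) - rowMeans(om[, 1:3])
  oracle_rate <- mean(op < 0.05 & abs(ofc) > 1)
  tol <- 3 * sqrt(oracle_rate * (1 - oracle_rate) / n)
  expect_lt(abs(rate - oracle_rate), tol + 1e-12)
})
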