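uniform_model <- function(n_bg = 100) {
  pwm <- matrix(0, 9, 20, dimnames = list(NULL, AA20))
  allele_model("uniform", pwm, rep(0, n_bg))
}

anchored_freqs <- function(p2, p9, w = 0.8) {
  bg <- aa_background()
  f <- matrix(bg, 9, 20, byrow = TRUE, dimnames = list(NULL, AA20))
  for (pw in list(c(2, p2), c(9, p9))) {
    pos <- as.integer(pw[1])
    row <- bg * (1 - w); row[pw[2]] <- row[pw[2]] + w
    f[pos, ] <- row / sum(row)
  }
  f
}

test_that("PWM scoring equals a brute-force positional sum", {
  set.seed(101)
  pwm <- matrix(rnorm(180), 9, 20, dimnames = list(NULL, AA20))
  model <- allele_model("test", pwm, rnorm(100))
  for (pep in random_peptide(10, 9)) {
    chars <- strsplit(pep, "")[[1]]
    oracle <- sum(vapply(1:9, function(p) pwm[p, chars[p]], numeric(1)))
    expect_equal(score_peptide(model, pep), oracle)
  }
  # uniform (all-zero) pwm scores 0 for any length via best-window logic
  expect_equal(score_peptides(uniform_model(), random_peptide(5, 9)),
               rep(0, 5))
  # consensus peptide achieves the maximal attainable score
  consensus <- paste(AA20[apply(pwm, 1, which.max)], collapse = "")
  expect_equal(score_peptide(model, consensus), sum(apply(pwm, 1, max)))
  expect_gte(score_peptide(model, consensus),
             max(score_peptides(model, random_peptide(50, 9))))
  expect_error(score_peptide(model, "AAAAAAAAB"), "alphabet error")
})

test_that("longer and shorter peptides use best windows with length penalties", {
  set.seed(102)
  pwm <- matrix(rnorm(180), 9, 20, dimnames = list(NULL, AA20))
  model <- allele_model("test", pwm, rnorm(100))
  pep11 <- random_peptide(1, 11)
  chars <- strsplit(pep11, "")[[1]]
  windows <- vapply(1:3, function(t)
    sum(vapply(1:9, function(p) pwm[p, chars[t + p - 1]], numeric(1))),
    numeric(1))
  expect_equal(score_peptide(model, pep11), max(windows) - 2)
  expect_equal(score_peptide(model, pep11, penalize_length = FALSE),
               max(windows))
  pep8 <- random_peptide(1, 8)
  ch8 <- strsplit(pep8, "")[[1]]
  dels <- vapply(1:9, function(d) {
    rows <- setdiff(1:9, d)
    sum(vapply(seq_along(rows), function(j) pwm[rows[j], ch8[j]],
               numeric(1)))
  }, numeric(1))
  expect_equal(score_peptide(model, pep8), max(dels) - 1)
})

test_that("percentile ranks match brute-force counting and are monotone", {
  set.seed(103)
  bg <- rnorm(1000)
  model <- allele_model("test",
                        matrix(0, 9, 20, dimnames = list(NULL, AA20)), bg)
  for (s in c(-3, -0.5, 0, 0.7, 2.5, max(bg), min(bg))) {
    expect_equal(percentile_rank(s, model), 100 * mean(bg > s))
  }
  expect_equal(percentile_rank(max(bg) + 1, model), 0)
  expect_equal(percentile_rank(stats::median(bg), model), 50, tolerance = 0.2)
  s <- sort(rnorm(50))
  r <- percentile_rank(s, model)
  expect_true(all(diff(r) <= 0))  # rank non-increasing in score
})

test_that("allele assignment applies the printed thresholds and tie rule", {
  # constructed background distributions give exact rank control:
  # rank = 100 * fraction of bg strictly greater than score
  mk <- function(name, rank_for_zero) {
    bg <- c(rep(1, rank_for_zero * 10), rep(-1, 1000 - rank_for_zero * 10))
    allele_model(name, matrix(0, 9, 20, dimnames = list(NULL, AA20)), bg)
  }
  pep <- random_peptide(1, 9)
  # strong call with the best allele reported
  res <- assign_alleles(pep, list(mk("A1", 0.3), mk("B1", 5)), "I")
  expect_identical(res$binder_class, "strong")
  expect_identical(res$best_alleles, "A1")
  expect_equal(res$best_rank, 0.3)
  # weak window [0.5, 2)
  expect_identical(assign_alleles(pep, list(mk("A1", 0.5)), "I")$binder_class,
                   "weak")
  expect_identical(assign_alleles(pep, list(mk("A1", 1.9)), "I")$binder_class,
                   "weak")
  # all ranks >= 2 -> non-binder
  expect_identical(assign_alleles(pep, list(mk("A1", 2), mk("B1", 60)),
                                  "I")$binder_class, "non_binder")
  # exact ties below threshold report every tied allele
  tie <- assign_alleles(pep, list(mk("A1", 1), mk("B1", 1), mk("C1", 8)),
                        "I")
  expect_identical(tie$best_alleles, "A1,B1")
  # allele order does not change the call
  tie_rev <- assign_alleles(pep, list(mk("C1", 8), mk("B1", 1), mk("A1", 1)),
                            "I")
  expect_equal(tie_rev$best_rank, tie$best_rank)
  expect_setequal(strsplit(tie_rev$best_alleles, ",")[[1]],
                  strsplit(tie$best_alleles, ",")[[1]])
  # class II: binder strictly below rank 10
  expect_identical(assign_alleles(pep, list(mk("DR1", 9.9)),
                                  "II")$binder_class, "binder")
  expect_identical(assign_alleles(pep, list(mk("DR1", 10)),
                                  "II")$binder_class, "non_binder")
  expect_error(assign_alleles(pep, list(), "I"), "config error")
})

test_that("k=1 Gibbs clustering reproduces the direct KLD formula", {
  set.seed(104)
  cores <- random_peptide(30, 9)
  direct <- motif_kld(cores)
  cl <- gibbs_cluster(cores, k = 1, seed = 5, restarts = 2, sweeps = 2)
  expect_equal(cl$clusters[[1]]$kld, direct$kld)
  expect_equal(cl$clusters[[1]]$size, 30)
  expect_equal(cl$objective, 30 * direct$kld)
  # background-composition cluster has near-zero KLD
  set.seed(105)
  bg_cores <- vapply(1:400, function(i)
    paste(sample(AA20, 9, TRUE, prob = aa_background()), collapse = ""),
    character(1))
  expect_lt(motif_kld(bg_cores)$kld, 0.5)
  expect_error(gibbs_cluster(cores, k = 0, seed = 1), "config error")
  expect_error(gibbs_cluster(cores[1:8], k = 2, seed = 1), "config error")
})

test_that("two planted anchor motifs are separated with high purity", {
  set.seed(106)
  gen <- function(freqs, n) vapply(seq_len(n), function(i)
    paste(vapply(1:9, function(p)
      sample(AA20, 1, prob = freqs[p, ]), character(1)), collapse = ""),
    character(1))
  fa <- anchored_freqs("L", "V")
  fb <- anchored_freqs("P", "F")
  cores <- c(gen(fa, 100), gen(fb, 100))
  labels <- rep(1:2, each = 100)
  cl <- gibbs_cluster(cores, k = 2, seed = 9, restarts = 5, sweeps = 15)
  tab <- table(cl$assignments, labels)
  purity <- sum(apply(tab, 2, max)) / length(cores)
  expect_gte(purity, 0.9)
  # determinism: same seed, same partition
  cl2 <- gibbs_cluster(cores, k = 2, seed = 9, restarts = 5, sweeps = 15)
  expect_identical(cl$assignments, cl2$assignments)
  expect_true(all(vapply(cl$clusters, `[[`, numeric(1), "kld") >= 0))
})
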