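test_that("apply_variants replaces exactly the annotated residues", {
  # tapasin-like neoantigen context: P->L at peptide position 2
  ctx <- "MKSLAPGPPPFGLSDE"        # contains APGPPPFGL at positions 5..13
  v <- data.frame(protein = "TAPBP", pos = 6L, ref_aa = "P", alt_aa = "L")
  out <- apply_variants(ctx, v)
  expect_identical(substr(out, 5, 13), "ALGPPPFGL")
  expect_identical(substr(ctx, 5, 13), "APGPPPFGL")
  expect_equal(nchar(out), nchar(ctx))

  # identity on an empty variant list
  empty <- data.frame(pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0))
  expect_identical(apply_variants(ctx, empty), ctx)
})

test_that("apply_variants equals a per-position replacement oracle on random fixtures", {
  set.seed(71)
  for (rep in 1:20) {
    seq50 <- paste(sample(AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          50, replace = TRUE), collapse = "")
    pos <- sample(50, 5)
    chars <- strsplit(seq50, "")[[1]]
    alt <- vapply(chars[pos], function(r) sample(setdiff(AA, r), 1),
                  character(1), USE.NAMES = FALSE)
    v <- data.frame(pos = pos, ref_aa = chars[pos], alt_aa = alt)
    oracle <- chars
    for (i in seq_along(pos)) oracle[pos[i]] <- alt[i]
    expect_identical(apply_variants(seq50, v), paste(oracle, collapse = ""))
  }
})

test_that("reference checks gate re-application; disabling them makes it idempotent", {
  seq0 <- "AAAAAAAAAA"
  v <- data.frame(protein = "p1", pos = 3L, ref_aa = "A", alt_aa = "W")
  varied <- apply_variants(seq0, v)
  expect_error(apply_variants(varied, v), "reference inconsistency.*p1.*3")
  expect_identical(apply_variants(varied, v, check_ref = FALSE), varied)
  expect_error(apply_variants(seq0, data.frame(protein = "p1", pos = 99L,
                                               ref_aa = "A", alt_aa = "W")),
               "bounds error")
})

test_that("variant application round-trips through a sequence diff", {
  set.seed(72)
  for (rep in 1:10) {
    chars <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                    replace = TRUE)
    seq0 <- paste(chars, collapse = "")
    pos <- sort(sample(40, 4))
    alt <- vapply(chars[pos], function(r)
      sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], r), 1),
      character(1), USE.NAMES = FALSE)
    v <- data.frame(pos = pos, ref_aa = chars[pos], alt_aa = alt)
    out <- strsplit(apply_variants(seq0, v), "")[[1]]
    diffs <- which(out != chars)
    expect_identical(diffs, pos)
    expect_identical(out[diffs], alt)
  }
})

test_that("the target-decoy database doubles the targets and reverses exactly", {
  wt <- c(p1 = "ACDEFGHIK", p2 = "LMNPQRSTV", p3 = "WYACDEFGH")
  var <- c(p1_var = "ACWEFGHIK", p2_var = "LMNPQRSTW")
  cont <- c(keratin = "GGGSSSGGG")
  db <- build_search_database(wt, var, cont)
  expect_equal(nrow(db$entries), 2 * (3 + 2 + 1))
  tg <- db$entries[!db$entries$decoy, ]
  dc <- db$entries[db$entries$decoy, ]
  expect_equal(nrow(tg), nrow(dc))
  # reversal is an involution: reversing decoys reproduces the targets
  rerev <- vapply(strsplit(dc$sequence, ""), function(x)
    paste(rev(x), collapse = ""), character(1))
  expect_identical(rerev, tg$sequence)
  expect_true(all(grepl("^rev_", dc$accession)))
})

test_that("palindromic targets are flagged and empty variant sets are allowed", {
  db <- build_search_database(c(p1 = "AGA", p2 = "ACD"))
  expect_identical(db$warnings, "p1")
  expect_equal(nrow(db$entries), 4)
  expect_setequal(unique(db$entries$class), "wildtype")
  expect_error(build_search_database(c(p1 = "ACD"), c(p1 = "ACW")),
               "collision")
})

test_that("variant peptide flags match paper examples and a substring oracle", {
  wt <- c(TAPBP = "MKSLAPGPPPFGLSDEAAKENVPSHLPAA",
          SKA = "GGKENVPSHLPGG")
  variants <- data.frame(protein = c("TAPBP", "TAPBP"),
                         pos = c(6L, 22L), ref_aa = c("P", "V"),
                         alt_aa = c("L", "I"), stringsAsFactors = FALSE)
  vfa <- c(TAPBP_var = apply_variants(wt[["TAPBP"]], variants))
  db <- build_search_database(wt, vfa)
  peptides <- data.frame(
    sequence = c("ALGPPPFGL",   # carries P->L, absent from all wild types
                 "KENIPSHLP",   # carries V->I at an annotated position
                 "MKSLAPGPP"),  # unmutated region
    protein = "TAPBP",
    start = c(5L, 19L, 1L), end = c(13L, 27L, 9L),
    stringsAsFactors = FALSE)
  ann <- annotate_variant_peptides(peptides, db, variants)
  expect_identical(ann$spans_variant, c(TRUE, TRUE, FALSE))
  # KENIPSHLP carries the variant but KENVPSHLP-like context exists only in
  # wild type; the variant form is in no wild-type entry -> exclusive
  expect_identical(ann$variant_exclusive, c(TRUE, TRUE, FALSE))
  expect_error(annotate_variant_peptides(
    data.frame(sequence = "AAA", protein = "nope", start = 1L, end = 3L),
    db, variants), "unmapped peptide")
})

test_that("variant flags equal an exhaustive substring scan on a random fixture", {
  cfg <- tiny_config(seed = 51)
  w <- simulate_world(cfg)
  db <- build_search_database(w$proteome$reference,
                              w$variants$variant_fasta)
  tr <- w$peptidome$truth[w$peptidome$truth$mhc_class == "I", ]
  tr <- tr[seq_len(min(nrow(tr), 120)), ]
  ann <- annotate_variant_peptides(
    tr[, c("sequence", "protein", "start", "end")], db,
    w$variants$variants)
  wt_seqs <- w$proteome$reference
  va <- w$variants$variants
  for (i in seq_len(nrow(ann))) {
    vv <- va[va$protein == ann$protein[i] & va$pos >= ann$start[i] &
               va$pos <= ann$end[i], , drop = FALSE]
    carries <- FALSE
    if (nrow(vv)) {
      off <- vv$pos - ann$start[i] + 1
      carries <- any(substring(ann$sequence[i], off, off) == vv$alt_aa)
    }
    expect_identical(ann$spans_variant[i], carries)
    oracle_excl <- carries &&
      !any(vapply(wt_seqs, function(s)
        grepl(ann$sequence[i], s, fixed = TRUE), logical(1)))
    expect_identical(ann$variant_exclusive[i], oracle_excl)
  }
})
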