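#' Consolidate overlapping quantified peptides into core epitopes
#'
#' Peptides mapped to the same protein are grouped into connected components
#' by interval overlap (sharing at least one residue position). A component
#' whose interval intersection is at least `min_epitope_length` long yields
#' one core epitope spanning that intersection; otherwise the component is
#' split greedily at the leftmost position of minimal peptide coverage and
#' the two sides are re-processed (peptides covering the split position
#' follow the side holding their larger share; ties go left). Components
#' that cannot be resolved (including lone peptides shorter than the minimum
#' length) are reported in the `unresolvable` element with their abundance
#' retained, so that summed MS1 area is conserved.
#'
#' @param peptides data.frame: `sequence`, `protein`, `start`, `end`
#'   (1-based inclusive) plus one abundance column per sample (names given
#'   by `sample_cols`), NA where unobserved.
#' @param min_epitope_length minimum core length (9 for MHC-I; the paper
#'   runs MHC-II at both 9 and 13).
#' @param sample_cols character vector of per-sample abundance column names.
#' @return List: `cores` (data.frame: protein, core_start, core_end,
#'   core_sequence, n_members, members (comma-joined sequences) and the
#'   summed per-sample abundance columns) and `unresolvable` (the input rows
#'   that joined no core).
#' @export
infer_core_epitopes <- function(peptides, min_epitope_length = 9L,
                                sample_cols) {
  stopifnot(all(c("sequence", "protein", "start", "end") %in% names(peptides)))
  if (any(peptides$end - peptides$start + 1L != nchar(peptides$sequence)))
    stop("coordinate error: interval length does not match sequence length",
         call. = FALSE)
  core_rows <- list()
  unres_idx <- integer(0)

  resolve <- function(idx) {
    # idx: row indices of peptides on one protein, overlap-connected or not;
    # regroup into overlap components with IRanges, then emit or split
    ir <- IRanges::IRanges(start = peptides$start[idx],
                           end = peptides$end[idx])
    comp_ranges <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, comp_ranges, minoverlap = 1L)
    comp_of <- integer(length(idx))
    comp_of[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    for (c in seq_along(comp_ranges)) {
      members <- idx[comp_of == c]
      if (!length(members)) next
      cs <- max(peptides$start[members])
      ce <- min(peptides$end[members])
      if (ce - cs + 1L >= min_epitope_length) {
        core_rows[[length(core_rows) + 1L]] <<- list(members = members,
                                                     core_start = cs,
                                                     core_end = ce)
      } else if (length(members) == 1L) {
        unres_idx <<- c(unres_idx, members)
      } else {
        span <- min(peptides$start[members]):max(peptides$end[members])
        cov <- vapply(span, function(pos)
          sum(peptides$start[members] <= pos & peptides$end[members] >= pos),
          integer(1))
        s <- span[which.min(cov)]  # leftmost minimal coverage
        left <- members[peptides$end[members] < s]
        right <- members[peptides$start[members] > s]
        covering <- setdiff(members, c(left, right))
        go_left <- (s - peptides$start[covering]) >=
          (peptides$end[covering] - s)
        left <- c(left, covering[go_left])
        right <- c(right, covering[!go_left])
        if (!length(left) || !length(right)) {
          unres_idx <<- c(unres_idx, members)  # no progress possible
        } else {
          resolve(left)
          resolve(right)
        }
      }
    }
  }

  for (prot in unique(peptides$protein))
    resolve(which(peptides$protein == prot))

  cores <- do.call(rbind, lapply(core_rows, function(cr) {
    m <- cr$members
    first <- m[1]
    core_seq <- substr(peptides$sequence[first],
                       cr$core_start - peptides$start[first] + 1L,
                       cr$core_end - peptides$start[first] + 1L)
    ab <- if (length(sample_cols)) {
      vals <- peptides[m, sample_cols, drop = FALSE]
      sums <- colSums(vals, na.rm = TRUE)
      sums[colSums(!is.na(vals)) == 0] <- NA_real_
      as.data.frame(as.list(sums))
    } else NULL
    out <- data.frame(protein = peptides$protein[first],
                      core_start = cr$core_start, core_end = cr$core_end,
                      core_sequence = core_seq,
                      n_members = length(m),
                      members = paste(sort(peptides$sequence[m]),
                                      collapse = ","),
                      stringsAsFactors = FALSE)
    if (!is.null(ab)) { names(ab) <- sample_cols; out <- cbind(out, ab) }
    out
  }))
  if (is.null(cores)) {
    cores <- data.frame(protein = character(0), core_start = integer(0),
                        core_end = integer(0), core_sequence = character(0),
                        n_members = integer(0), members = character(0),
                        stringsAsFactors = FALSE)
    for (sc in sample_cols) cores[[sc]] <- numeric(0)
  }
  rownames(cores) <- NULL
  list(cores = cores,
       unresolvable = peptides[sort(unres_idx), , drop = FALSE])
}

#' Impute missing core abundances with the per-sample minimum
#'
#' Each missing cell receives the lowest measured value of its sample column
#' (the "impute with lowest measured value in each run" rule). Measured
#' cells are never altered.
#'
#' @param mat numeric matrix or data.frame of core x sample abundances.
#' @return List: `matrix` (completed, same shape) and `imputed` (logical
#'   matrix flagging filled cells).
#' @export
impute_missing <- function(mat) {
  m <- as.matrix(mat)
  if (any(colSums(!is.na(m)) == 0))
    stop("imputation impossible: sample column with no measured value",
         call. = FALSE)
  imputed <- is.na(m)
  mins <- apply(m, 2, min, na.rm = TRUE)
  for (j in seq_len(ncol(m))) m[imputed[, j], j] <- mins[j]
  list(matrix = m, imputed = imputed)
}

#' Differential presentation of core epitopes
#'
#' Two-sample t-test (Welch) on log2 consolidated abundances between the
#' condition groups, Benjamini-Hochberg correction across cores, and a
#' direction call at `p < p_thresh` and `|log2fc| > log2fc_thresh` (raw-p
#' calls; the BH-corrected call is reported alongside).
#'
#' @param core_matrix numeric matrix of core x sample abundances (complete,
#'   e.g. after [impute_missing()]); column-to-condition mapping via
#'   `condition`.
#' @param condition character vector, one of `"control"`/`"treated"` per
#'   column.
#' @param p_thresh raw p-value threshold (default 0.05).
#' @param log2fc_thresh log2 fold-change threshold (default 1).
#' @return data.frame: `log2fc`, `p_value`, `q_value`, `direction`
#'   (up_treated / up_control / unchanged, raw-p call) and `direction_bh`
#'   (same rule with q in place of p).
#' @export
differential_presentation <- function(core_matrix, condition,
                                      p_thresh = 0.05, log2fc_thresh = 1) {
  m <- as.matrix(core_matrix)
  stopifnot(length(condition) == ncol(m))
  ctrl <- m[, condition == "control", drop = FALSE]
  trt <- m[, condition == "treated", drop = FALSE]
  if (ncol(ctrl) < 2 || ncol(trt) < 2)
    stop("insufficient replicates: need >= 2 samples per condition",
         call. = FALSE)
  if (any(m <= 0)) stop("log-domain error: non-positive abundance",
                        call. = FALSE)
  lc <- log2(ctrl); lt <- log2(trt)
  log2fc <- rowMeans(lt) - rowMeans(lc)
  p <- vapply(seq_len(nrow(m)), function(i) log2_t_test(lc[i, ], lt[i, ]),
              numeric(1))
  q <- benjamini_hochberg(p)
  call_dir <- function(pv) ifelse(pv < p_thresh &
                                    abs(log2fc) > log2fc_thresh,
                                  ifelse(log2fc > 0, "up_treated",
                                         "up_control"),
                                  "unchanged")
  data.frame(log2fc = log2fc, p_value = p, q_value = q,
             direction = call_dir(p), direction_bh = call_dir(q),
             stringsAsFactors = FALSE)
}
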