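#' Filter peptide/protein rows on reporter-channel completeness
#'
#' Retains rows with observed (non-missing, positive) signal in at least
#' `min_observed` of the six reporter channels; the paper's rule is four of
#' six.
#'
#' @param tab data.frame with an identifier column followed by six channel
#'   columns (NA or non-positive = not observed).
#' @param min_observed minimum observed channels (default 4).
#' @param id_col identifier column name (default `"accession"`).
#' @return The retained rows; retention counts in `attr(, "retention")`.
#' @export
filter_quant_peptides <- function(tab, min_observed = 4L,
                                  id_col = "accession") {
  channels <- setdiff(names(tab), id_col)
  if (length(channels) != 6L)
    stop("schema error: expected 6 channel columns, found ",
         length(channels), call. = FALSE)
  vals <- as.matrix(tab[, channels])
  observed <- rowSums(!is.na(vals) & vals > 0)
  keep <- observed >= min_observed
  out <- tab[keep, , drop = FALSE]
  attr(out, "retention") <- c(input = nrow(tab), retained = sum(keep),
                              dropped = sum(!keep))
  attr(out, "channel_groups") <- attr(tab, "channel_groups")
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' The standard step-up construction: sort the m p-values increasingly,
#' multiply by m/rank, take the cumulative minimum from the largest, cap at
#' 1, and return in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("domain error: p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q[order(o)]
}

# two-sample t on log2 values with the zero-variance conventions:
# equal means & no variance -> p = 1; unequal means & no variance -> p = 0
log2_t_test <- function(x, y, var_equal = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Differential protein expression between control and treated channels
#'
#' Log2-transforms the reporter intensities, runs an unpaired two-sample
#' t-test per protein (Welch by default), adjusts with Benjamini-Hochberg
#' over all tested proteins, and calls a protein differentially expressed at
#' `p < p_thresh` and an absolute fold-change of at least `fc_thresh`
#' (linear scale by default: |log2fc| >= log2(fc_thresh)).
#'
#' @param quant data.frame: `accession` + six channel columns; channel
#'   grouping read via [channel_groups()]. NA channels are ignored; proteins
#'   with fewer than 2 observations in a group are excluded (counted in
#'   `attr(, "excluded")`).
#' @param p_thresh p-value threshold (default 0.01).
#' @param fc_thresh fold-change threshold (default 1.2).
#' @param fc_scale `"fold"` (default; |2^log2fc| >= fc_thresh) or `"log2"`
#'   (|log2fc| >= fc_thresh).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame: `accession`, `log2fc` (treated over control group
#'   means), `p_value`, `q_value`, `is_de`.
#' @export
differential_expression <- function(quant, p_thresh = 0.01, fc_thresh = 1.2,
                                    fc_scale = c("fold", "log2"),
                                    var_equal = FALSE) {
  fc_scale <- match.arg(fc_scale)
  groups <- channel_groups(quant)
  channels <- names(groups)
  vals <- as.matrix(quant[, channels])
  if (any(vals <= 0, na.rm = TRUE))
    stop("log-domain error: non-positive intensity", call. = FALSE)
  lv <- log2(vals)
  ctrl <- lv[, groups == "control", drop = FALSE]
  trt <- lv[, groups == "treated", drop = FALSE]
  n_ctrl <- rowSums(!is.na(ctrl))
  n_trt <- rowSums(!is.na(trt))
  testable <- n_ctrl >= 2 & n_trt >= 2

  log2fc <- rowMeans(trt, na.rm = TRUE) - rowMeans(ctrl, na.rm = TRUE)
  p <- rep(NA_real_, nrow(lv))
  for (i in which(testable)) {
    p[i] <- log2_t_test(ctrl[i, !is.na(ctrl[i, ])],
                        trt[i, !is.na(trt[i, ])], var_equal)
  }
  q <- rep(NA_real_, nrow(lv))
  q[testable] <- benjamini_hochberg(p[testable])
  fc_pass <- if (fc_scale == "fold") abs(log2fc) >= log2(fc_thresh)
             else abs(log2fc) >= fc_thresh
  res <- data.frame(accession = quant$accession, log2fc = log2fc,
                    p_value = p, q_value = q,
                    is_de = testable & !is.na(p) & p < p_thresh & fc_pass,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "excluded") <- sum(!testable)
  res
}
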