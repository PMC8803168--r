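# Nested-model adjusted-R^2 comparison: does elncRNA splicing add
# explanatory value for target expression beyond elncRNA expression?

#' Adjusted-R^2 gain from adding elncRNA splicing to the model
#'
#' Fits the nested ordinary-least-squares models
#' target ~ elncRNA expression and
#' target ~ elncRNA expression + elncRNA splicing
#' on identical complete cases and reports the difference in adjusted
#' R^2 (which can be negative: the adjustment penalizes an uninformative
#' predictor). Near-collinear predictors (|r| > 0.999) flag the gain as
#' unstable.
#'
#' @param target Target-gene expression vector.
#' @param elnc_expr elncRNA expression vector.
#' @param elnc_psi elncRNA splicing (PSI) vector.
#' @param min_n Minimum complete cases (default 30).
#' @param elncrna,partner,partner_kind Optional identifiers stored in
#'   the record.
#' @return One-row data frame of class `model_gain`: `elncrna`,
#'   `partner`, `partner_kind`, `n`, `adj_r2_expr`, `adj_r2_full`,
#'   `gain`, `unstable`.
#' @export
fit_gain <- function(target, elnc_expr, elnc_psi, min_n = 30L,
                     elncrna = NA_character_, partner = NA_character_,
                     partner_kind = c("target", "non_target")) {
  partner_kind <- match.arg(partner_kind)
  ok <- stats::complete.cases(target, elnc_expr, elnc_psi)
  if (sum(ok) < min_n)
    stop(sprintf("only %d complete cases (< %d)", sum(ok), min_n),
         call. = FALSE)
  y <- target[ok]; x1 <- elnc_expr[ok]; x2 <- elnc_psi[ok]
  unstable <- stats::sd(x2) == 0 || abs(stats::cor(x1, x2)) > 0.999
  m1 <- stats::lm(y ~ x1)
  m2 <- stats::lm(y ~ x1 + x2)
  a1 <- summary(m1)$adj.r.squared
  a2 <- summary(m2)$adj.r.squared
  out <- data.frame(elncrna = elncrna, partner = partner,
                    partner_kind = partner_kind, n = sum(ok),
                    adj_r2_expr = a1, adj_r2_full = a2, gain = a2 - a1,
                    unstable = unstable)
  class(out) <- c("model_gain", "data.frame")
  out
}

#' Compare gain distributions between targets and non-targets
#'
#' Two-tailed Mann-Whitney U test (with tie correction) of the
#' adjusted-R^2 gains of target partners against non-target partners.
#'
#' @param target_gains,non_target_gains Numeric gain vectors, or
#'   `model_gain` data frames (their `gain` columns are used).
#' @return List with `p`, `statistic`, `median_target`,
#'   `median_non_target`.
#' @export
compare_gain_distributions <- function(target_gains, non_target_gains) {
  g1 <- if (is.data.frame(target_gains)) target_gains$gain else target_gains
  g2 <- if (is.data.frame(non_target_gains)) non_target_gains$gain
        else non_target_gains
  if (length(g1) == 0L || length(g2) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(g1, g2,
                                            alternative = "two.sided"))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       median_target = stats::median(g1),
       median_non_target = stats::median(g2))
}

#' Pick the splicing predictor for a multi-intron elncRNA
#'
#' When an elncRNA has several intron PSIs the most variable one (by
#' variance across samples, missing values removed) enters the nested
#' models.
#'
#' @param psi Matrix of PSI values, introns x samples.
#' @return The selected intron's PSI vector (named by its row key).
#' @export
select_splicing_predictor <- function(psi) {
  psi <- as.matrix(psi)
  v <- apply(psi, 1, stats::var, na.rm = TRUE)
  if (all(is.na(v))) stop("no intron with defined PSI variance", call. = FALSE)
  pick <- which.max(v)
  out <- psi[pick, ]
  attr(out, "intron") <- rownames(psi)[pick]
  out
}
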