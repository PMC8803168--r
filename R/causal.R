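# Four-model mediation classification of joint QTL triplets (E, A, B):
# independent / causal / reactive / undecided, decided by composite
# partial-correlation z-scores against permutation nulls with an
# empirical-null local false discovery rate.

fisher_z <- function(r, k, n) {
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  atanh(r) * sqrt(n - k - 3)
}

partial_r <- function(r_xy, r_xz, r_yz) {
  den <- sqrt(pmax((1 - r_xz^2) * (1 - r_yz^2), .Machine$double.eps))
  (r_xy - r_xz * r_yz) / den
}

#' Correlation and partial-correlation statistics for one triplet
#'
#' Pearson correlations r(E,A), r(E,B), r(A,B) and the first-order
#' partials r(E,B|A), r(E,A|B), r(A,B|E), each with its Fisher
#' z-transform z = atanh(r) * sqrt(n - k - 3) (k conditioned variables).
#' Collinear inputs (|r| ~ 1) yield a `collinear` flag and the partials
#' are reported as 0 by convention.
#'
#' @param E,A,B Numeric vectors (genotype dosage, mediator, outcome);
#'   complete cases >= 20 required.
#' @return List of class `triplet_stats` with the correlations,
#'   z-statistics, `n`, and `collinear`.
#' @export
triplet_stats <- function(E, A, B) {
  ok <- stats::complete.cases(E, A, B)
  if (sum(ok) < 20L) stop("need >= 20 complete cases", call. = FALSE)
  E <- E[ok]; A <- A[ok]; B <- B[ok]
  for (nm in c("E", "A", "B"))
    if (stats::sd(get(nm)) == 0)
      stop(sprintf("zero variance in %s", nm), call. = FALSE)
  n <- length(E)
  r_EA <- stats::cor(E, A); r_EB <- stats::cor(E, B); r_AB <- stats::cor(A, B)
  collinear <- any(abs(c(r_EA, r_EB, r_AB)) > 0.999)
  if (collinear) {
    r_EB_A <- r_EA_B <- r_AB_E <- 0
  } else {
    r_EB_A <- partial_r(r_EB, r_EA, r_AB)
    r_EA_B <- partial_r(r_EA, r_EB, r_AB)
    r_AB_E <- partial_r(r_AB, r_EA, r_EB)
  }
  structure(list(
    n = n, collinear = collinear,
    r_EA = r_EA, r_EB = r_EB, r_AB = r_AB,
    r_EB_A = r_EB_A, r_EA_B = r_EA_B, r_AB_E = r_AB_E,
    z_EA = fisher_z(r_EA, 0, n), z_EB = fisher_z(r_EB, 0, n),
    z_AB = fisher_z(r_AB, 0, n),
    z_EB_A = fisher_z(r_EB_A, 1, n), z_EA_B = fisher_z(r_EA_B, 1, n),
    z_AB_E = fisher_z(r_AB_E, 1, n)),
    class = "triplet_stats")
}

#' @export
print.triplet_stats <- function(x, ...) {
  cat(sprintf("triplet_stats (n = %d%s):\n", x$n,
              if (x$collinear) ", collinear" else ""))
  cat(sprintf("  r(E,A) = %.3f  r(E,B) = %.3f  r(A,B) = %.3f\n",
              x$r_EA, x$r_EB, x$r_AB))
  cat(sprintf("  r(E,B|A) = %.3f  r(E,A|B) = %.3f  r(A,B|E) = %.3f\n",
              x$r_EB_A, x$r_EA_B, x$r_AB_E))
  invisible(x)
}

# Vectorized composite model scores for standardized sample matrices
# (samples x triplets). Returns a T x 3 matrix (causal, reactive,
# independent).
#
# causal:      needs E-B association and A-B given E, with E-B vanishing
#              given A:        min(|z(E,B)|, |z(A,B|E)|) - |z(E,B|A)|
# reactive:    the A<->B mirror: min(|z(E,A)|, |z(A,B|E)|) - |z(E,A|B)|
# independent: needs both marginal associations with A-B vanishing
#              given E:        min(|z(E,A)|, |z(E,B)|) - |z(A,B|E)|
# The independent score uses both marginals (not just E-B) so the whole
# classifier is exactly invariant under exchanging A and B.
triplet_scores <- function(Es, As, Bs) {
  n <- nrow(Es)
  cvec <- function(X, Y) colSums(X * Y) / (n - 1)
  r_EA <- cvec(Es, As); r_EB <- cvec(Es, Bs); r_AB <- cvec(As, Bs)
  z_EA <- abs(fisher_z(r_EA, 0, n))
  z_EB <- abs(fisher_z(r_EB, 0, n))
  z_EB_A <- abs(fisher_z(partial_r(r_EB, r_EA, r_AB), 1, n))
  z_EA_B <- abs(fisher_z(partial_r(r_EA, r_EB, r_AB), 1, n))
  z_AB_E <- abs(fisher_z(partial_r(r_AB, r_EA, r_EB), 1, n))
  cbind(causal = pmin(z_EB, z_AB_E) - z_EB_A,
        reactive = pmin(z_EA, z_AB_E) - z_EA_B,
        independent = pmin(z_EA, z_EB) - z_AB_E)
}

# Exact Gaussian-KDE log-density of `sample` evaluated at `at`
# (log-sum-exp over kernels, so far tails stay finite and ordered
# instead of underflowing).
kde_log_density <- function(sample, at, bw) {
  vapply(at, function(s) {
    lt <- stats::dnorm(s, mean = sample, sd = bw, log = TRUE)
    m <- max(lt)
    if (!is.finite(m)) return(-Inf)
    m + log(mean(exp(lt - m)))
  }, 0)
}

# Log-scale lfdr with isotonic adjustment; the log scale keeps
# far-tail scores ordered (no underflow ties) when several models all
# sit beyond their nulls.
local_fdr_log <- function(scores, null_scores) {
  if (length(scores) < 50L || length(null_scores) < 500L)
    warning("small score ensembles make the lfdr estimate unstable",
            call. = FALSE)
  if (stats::sd(scores) == 0 || stats::sd(null_scores) == 0)
    return(rep(0, length(scores)))  # log(1)
  pi0 <- min(1, 2 * mean(scores <= stats::median(null_scores)))
  pi0 <- max(pi0, 1 / (length(scores) + 1))  # keep log(pi0) finite
  bw0 <- stats::bw.nrd0(null_scores)
  bw1 <- stats::bw.nrd0(scores)
  log_f0 <- kde_log_density(null_scores, scores, bw0)
  log_f <- kde_log_density(scores, scores, bw1)
  log_lfdr <- pmin(log(pi0) + log_f0 - log_f, 0)
  # one-sided: only high scores are evidence FOR a model; at or below
  # the null median the density ratio would also vanish in the left
  # tail and misread contradicting scores as support
  log_lfdr[scores <= stats::median(null_scores)] <- 0
  ord <- order(scores)
  fit <- stats::isoreg(seq_along(ord), -log_lfdr[ord])
  out <- numeric(length(scores))
  out[ord] <- pmin(-fit$yf, 0)
  out
}

#' Local false discovery rate against an empirical null
#'
#' Two-group mixture estimate lfdr(s) = pi0 * f0(s) / f(s), with f0 and
#' f Gaussian-kernel density estimates (Silverman's bandwidth rule) of
#' the null and observed scores evaluated exactly in log space, pi0 =
#' min(1, 2 * fraction of observed scores at or below the null median),
#' the ratio clipped to `[0, 1]`, and the result made monotone
#' non-increasing in the score by isotonic adjustment. The test is
#' one-sided: scores at or below the null median get lfdr 1 (only high
#' scores support a model). Degenerate ensembles (all scores equal)
#' give lfdr = 1 everywhere.
#'
#' @param scores Observed composite scores (>= 50 recommended).
#' @param null_scores Null-score ensemble (>= 500 recommended).
#' @return Numeric vector of lfdr values aligned with `scores`.
#' @export
local_fdr <- function(scores, null_scores) {
  exp(local_fdr_log(scores, null_scores))
}

#' Classify joint triplets into the four mediation models
#'
#' For every triplet, composite scores for the causal, reactive and
#' independent models are computed from Fisher-z partial-correlation
#' statistics (see `triplet_scores` internals) and compared with
#' permutation nulls: the causal null permutes B across samples
#' (preserving the E-A association that triplet construction
#' guarantees), the reactive null permutes A, and the independent null
#' pools both, keeping the procedure exactly symmetric under exchanging
#' A and B. Each model's local FDR is estimated with [local_fdr()]; a
#' triplet is labelled with the lowest-lfdr model among those below
#' `lfdr_threshold`, ties or no qualifying model giving `undecided`.
#'
#' @param E,A,B Numeric matrices (samples x triplets), or pass a
#'   `mediation_triplets` object as `E`.
#' @param lfdr_threshold Decision threshold (default 0.1).
#' @param n_perm Permutations per null (default 200; null ensembles pool
#'   `n_perm * n_triplets` scores).
#' @param seed Integer RNG seed for the permutations.
#' @param min_triplets Minimum ensemble size (default 50); fewer
#'   triplets raise an error advising pooled analysis.
#' @return Data frame of class `triplet_calls`: `triplet`, the three
#'   scores, the three lfdrs, and `label`.
#' @examples
#' trip <- simulate_mediation_triplets(60, mediation_scenario("causal"),
#'                                     cohort_config(n_samples = 150))
#' calls <- classify_triplets(trip, n_perm = 100)
#' table(calls$label)
#' @export
classify_triplets <- function(E, A = NULL, B = NULL, lfdr_threshold = 0.1,
                              n_perm = 200L, seed = 1L, min_triplets = 50L) {
  if (inherits(E, "mediation_triplets")) {
    A <- E$A; B <- E$B; E <- E$E
  }
  E <- as.matrix(E); A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(E); n_trip <- ncol(E)
  if (n_trip < min_triplets)
    stop(sprintf(paste0("only %d triplets (< %d): the empirical-null lfdr ",
                        "needs an ensemble; pool analyses or lower ",
                        "min_triplets"), n_trip, min_triplets), call. = FALSE)
  for (nm in c("E", "A", "B")) {
    s <- apply(get(nm), 2, stats::sd)
    if (any(s == 0))
      stop(sprintf("zero variance in %s (triplet %d)", nm, which(s == 0)[1]),
           call. = FALSE)
  }
  Es <- scale(E); As <- scale(A); Bs <- scale(B)
  obs <- triplet_scores(Es, As, Bs)
  null_causal <- matrix(0, n_trip, n_perm)
  null_reactive <- matrix(0, n_trip, n_perm)
  null_ind <- matrix(0, n_trip, 2L * n_perm)
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      perm <- sample.int(n)
      sB <- triplet_scores(Es, As, Bs[perm, , drop = FALSE])
      sA <- triplet_scores(Es, As[perm, , drop = FALSE], Bs)
      null_causal[, k] <- sB[, "causal"]
      null_reactive[, k] <- sA[, "reactive"]
      null_ind[, k] <- sB[, "independent"]
      null_ind[, n_perm + k] <- sA[, "independent"]
    }
  })
  log_lfdr <- cbind(
    causal = local_fdr_log(obs[, "causal"], as.vector(null_causal)),
    reactive = local_fdr_log(obs[, "reactive"], as.vector(null_reactive)),
    independent = local_fdr_log(obs[, "independent"], as.vector(null_ind)))
  lfdr <- exp(log_lfdr)
  # argmin on the log scale: far-tail lfdrs stay ordered instead of
  # collapsing to ties at 0
  label <- apply(log_lfdr, 1, function(v) {
    below <- which(v < log(lfdr_threshold))
    if (length(below) == 0L) return("undecided")
    best <- which(v == min(v[below]))
    if (length(best) > 1L) return("undecided")
    colnames(log_lfdr)[best]
  })
  out <- data.frame(
    triplet = if (!is.null(colnames(E))) colnames(E)
              else sprintf("trip%04d", seq_len(n_trip)),
    score_causal = obs[, "causal"], score_reactive = obs[, "reactive"],
    score_independent = obs[, "independent"],
    lfdr_causal = lfdr[, "causal"], lfdr_reactive = lfdr[, "reactive"],
    lfdr_independent = lfdr[, "independent"],
    label = label)
  class(out) <- c("triplet_calls", "data.frame")
  attr(out, "lfdr_threshold") <- lfdr_threshold
  out
}

#' @export
summary.triplet_calls <- function(object, ...) {
  tab <- table(factor(object$label,
                      c("causal", "reactive", "independent", "undecided")))
  data.frame(model = names(tab), n = as.integer(tab),
             proportion = as.numeric(tab) / nrow(object))
}

#' @export
print.triplet_calls <- function(x, ...) {
  cat(sprintf("triplet_calls: %d triplets at lfdr < %.2g\n",
              nrow(x), attr(x, "lfdr_threshold")))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Summarize mediation calls per model and per elncRNA
#'
#' Tabulates model proportions; with a triplet-to-elncRNA map, reports
#' the fraction of elncRNAs with at least one causal triplet (an
#' elncRNA is "causal" when any of its triplets is); with junction end
#' positions, tests the 5'/3' junction split between causal and
#' non-causal triplets by a two-tailed Fisher's exact test.
#'
#' @param calls A `triplet_calls` data frame.
#' @param triplet_map Optional data frame `triplet`, `elncrna`.
#' @param junction_pos Optional data frame `triplet`, `end`
#'   (`"5prime"`/`"3prime"`, from [junction_end_position()]).
#' @return List of class `causal_summary`: `by_model`, and when
#'   available `elncrna_causal_fraction`, `by_elncrna`,
#'   `junction_table`, `junction_fisher_p`.
#' @export
summarize_calls <- function(calls, triplet_map = NULL, junction_pos = NULL) {
  out <- list(by_model = summary(calls))
  if (!is.null(triplet_map)) {
    m <- merge(calls[, c("triplet", "label")], triplet_map, by = "triplet")
    per <- tapply(m$label == "causal", m$elncrna, any)
    out$by_elncrna <- data.frame(elncrna = names(per),
                                 causal = as.logical(per))
    out$elncrna_causal_fraction <- mean(per)
  }
  if (!is.null(junction_pos)) {
    j <- merge(calls[, c("triplet", "label")], junction_pos, by = "triplet")
    tab <- table(factor(j$end, c("5prime", "3prime")),
                 factor(j$label == "causal", c(TRUE, FALSE),
                        labels = c("causal", "non_causal")))
    out$junction_table <- tab
    out$junction_fisher_p <- stats::fisher.test(tab)$p.value
  }
  structure(out, class = "causal_summary")
}

#' @export
print.causal_summary <- function(x, ...) {
  cat("mediation-call summary\n")
  print(x$by_model, row.names = FALSE)
  if (!is.null(x$elncrna_causal_fraction))
    cat(sprintf("elncRNAs with >= 1 causal triplet: %.1f%%\n",
                100 * x$elncrna_causal_fraction))
  if (!is.null(x$junction_fisher_p))
    cat(sprintf("5'/3' junction split Fisher p = %.3g\n",
                x$junction_fisher_p))
  invisible(x)
}
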