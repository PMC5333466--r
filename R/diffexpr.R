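# Differential expression: quantile normalization, per-comparison two-group
# fits, empirical-Bayes variance moderation, Benjamini-Hochberg adjustment,
# and the consistent-overlap consensus across the two resistant-vs-parental
# comparisons.

#' Quantile normalization
#'
#' Forces every sample column onto the identical value multiset — the mean of
#' the input order statistics — with tied positions averaged. Delegates to
#' [limma::normalizeQuantiles()], the standard microarray implementation.
#'
#' @param expr an `ExpressionMatrix` or a numeric matrix with >= 2 columns.
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(expr) {
  m <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (!is.matrix(m) || ncol(m) < 2)
    ct_validation_error("quantile normalization needs >= 2 sample columns")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (inherits(expr, "ExpressionMatrix")) expression_matrix(qn, expr$group_of) else qn
}

#' Per-gene two-group fit
#'
#' For the comparison (A, B), computes per gene the mean log2 difference
#' `beta = mean(B) - mean(A)`, the pooled within-group variance `s2`, and the
#' residual degrees of freedom `d = nA + nB - 2`.
#'
#' @param expr an `ExpressionMatrix` (intensity scale) or a numeric matrix
#'   already on the log scale (then `groups` must be given).
#' @param comparison length-2 character vector `c(groupA, groupB)`; the fold
#'   change is B relative to A.
#' @param groups named group vector when `expr` is a bare matrix.
#' @param log2_transform log2-transform intensities before fitting (default
#'   TRUE for an `ExpressionMatrix`, FALSE for a bare matrix).
#' @return data frame with columns `gene`, `beta`, `s2`, `df`; attributes
#'   `n_A`, `n_B`, `comparison`.
#' @export
fit_group_model <- function(expr, comparison, groups = NULL,
                            log2_transform = inherits(expr, "ExpressionMatrix")) {
  if (inherits(expr, "ExpressionMatrix")) {
    m <- expr$values
    groups <- expr$group_of
  } else {
    m <- expr
    if (is.null(groups)) ct_validation_error("groups required for a bare matrix")
  }
  if (length(comparison) != 2)
    ct_validation_error("comparison must name exactly two groups")
  for (g in comparison) {
    n <- sum(groups == g)
    if (n == 0) ct_validation_error("group absent from data: '%s'", g)
    if (n < 2) ct_validation_error("group '%s' has < 2 replicates", g)
  }
  if (log2_transform) {
    if (any(m <= 0))
      ct_validation_error("non-positive intensity; cannot log2-transform")
    m <- log2(m)
  }
  a <- m[, groups[colnames(m)] == comparison[1], drop = FALSE]
  b <- m[, groups[colnames(m)] == comparison[2], drop = FALSE]
  nA <- ncol(a); nB <- ncol(b)
  beta <- rowMeans(b) - rowMeans(a)
  ssa <- rowSums((a - rowMeans(a))^2)
  ssb <- rowSums((b - rowMeans(b))^2)
  d <- nA + nB - 2
  out <- data.frame(gene = rownames(m), beta = beta, s2 = (ssa + ssb) / d,
                    df = d, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_A") <- nA
  attr(out, "n_B") <- nB
  attr(out, "comparison") <- comparison
  out
}

# Invert the trigamma function by Newton iteration (solve trigamma(y) = x).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates a scaled-F prior (d0, s0^2) for the per-gene variances by
#' matching the first two moments of log s2 (digamma/trigamma inversion),
#' then shrinks each variance to
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)` and tests
#' `t = beta / sqrt(s2_post * (1/nA + 1/nB))` against a t distribution with
#' `d + d0` degrees of freedom. When the log-variances are under-dispersed
#' relative to the chi-square expectation the prior degrees of freedom are
#' infinite and every posterior variance equals s0^2 (a warning is logged).
#'
#' @param fit output of [fit_group_model()] over >= 10 genes.
#' @param d0,s02 optional prior overrides: `d0 = 0` reproduces the ordinary
#'   pooled t-test; a finite or infinite `d0` with `s02` fixes the prior
#'   instead of estimating it.
#' @return data frame of class `DEResult` with columns `gene`, `logFC`, `s2`,
#'   `df`, `s2_post`, `t`, `P.Value`, `adj.P.Val`; attributes `d0`, `s02`.
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s02 = NULL) {
  need <- c("gene", "beta", "s2", "df")
  if (!all(need %in% names(fit)))
    ct_validation_error("fit must come from fit_group_model()")
  nA <- attr(fit, "n_A"); nB <- attr(fit, "n_B")
  if (is.null(nA) || is.null(nB))
    ct_validation_error("fit lost its replicate-count attributes")
  s2 <- fit$s2; d <- fit$df
  if (all(s2 == 0)) ct_numeric_error("all residual variances are zero")

  if (is.null(d0)) {
    if (nrow(fit) < 10)
      ct_validation_error("hyperparameter estimation needs >= 10 genes")
    pos <- s2 > 0
    if (!all(pos))
      warning(sprintf("%d zero variance(s) excluded from prior estimation", sum(!pos)))
    z <- log(s2[pos]); dd <- d[pos]
    e <- z - digamma(dd / 2) + log(dd / 2)
    emean <- mean(e)
    evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(dd / 2))
    if (evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      warning("log-variances under-dispersed; setting prior df to Inf")
      d0 <- Inf
      s02 <- exp(emean)
    }
  } else {
    if (d0 < 0) ct_validation_error("d0 must be >= 0")
    if (d0 > 0 && is.null(s02))
      ct_validation_error("s02 must be supplied with a fixed d0 > 0")
  }

  s2_post <- if (d0 == 0) s2
  else if (is.infinite(d0)) rep(s02, length(s2))
  else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  t <- ifelse(se > 0, fit$beta / se, ifelse(fit$beta == 0, 0, sign(fit$beta) * Inf))
  df_total <- d + d0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  out <- data.frame(gene = fit$gene, logFC = fit$beta, s2 = s2, df = d,
                    s2_post = s2_post, t = t, P.Value = p,
                    adj.P.Val = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02 %||% NA_real_
  attr(out, "comparison") <- attr(fit, "comparison")
  attr(out, "n_A") <- nA
  attr(out, "n_B") <- nB
  class(out) <- c("DEResult", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric P-values in \[0, 1\].
#' @return adjusted P-values (monotone, capped at 1), in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    ct_validation_error("P-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Consistent overlap of two differential-expression results
#'
#' The consensus gene list: genes significant (adjusted P < cutoff) in both
#' resistant-vs-parental comparisons and, by default, with the same
#' fold-change direction in both. Output is partitioned into up- and
#' down-regulated sets.
#'
#' @param deA,deB `DEResult` objects over the same gene universe.
#' @param cutoff adjusted-P cutoff (default 0.01).
#' @param require_sign demand concordant log fold-change sign (default TRUE;
#'   FALSE keeps joint significance only).
#' @return list with `up`, `down` (gene id vectors), and `table` (per
#'   retained gene: both logFCs and adjusted Ps, direction).
#' @export
consistent_overlap <- function(deA, deB, cutoff = 0.01, require_sign = TRUE) {
  if (!setequal(deA$gene, deB$gene))
    ct_validation_error("the two comparisons cover different gene sets")
  deB <- deB[match(deA$gene, deB$gene), ]
  sel <- deA$adj.P.Val < cutoff & deB$adj.P.Val < cutoff
  if (require_sign) sel <- sel & sign(deA$logFC) == sign(deB$logFC) & deA$logFC != 0
  tab <- data.frame(gene = deA$gene[sel],
                    logFC_A = deA$logFC[sel], adjP_A = deA$adj.P.Val[sel],
                    logFC_B = deB$logFC[sel], adjP_B = deB$adj.P.Val[sel],
                    stringsAsFactors = FALSE)
  tab$direction <- ifelse(tab$logFC_A > 0, "up", "down")
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  list(up = tab$gene[tab$direction == "up"],
       down = tab$gene[tab$direction == "down"],
       table = tab)
}
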