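# Empirical-Bayes moderated t machinery for two-group comparisons.
#
# Per feature g with groups of sizes n1, n2 and pooled residual variance
# s2_g on d = n1 + n2 - 2 degrees of freedom, the residual variances are
# modeled as scaled inverse chi-square draws around a prior variance s0^2
# with d0 prior degrees of freedom. The posterior (shrunk) variance is
#   s~2_g = (d0 * s0^2 + d * s2_g) / (d0 + d)
# and the moderated t-statistic
#   t_g = (mean1_g - mean2_g) / (s~_g * sqrt(1/n1 + 1/n2))
# is referred to a t distribution on d0 + d degrees of freedom. The
# hyperparameters (d0, s0^2) are estimated by the method of moments on
# log s2_g, using the digamma/trigamma moments of the log chi-square
# distribution (Smyth 2004), with a Newton inversion of the trigamma
# function.

#' Moderated two-group t-test engine
#'
#' @param m Numeric features-by-samples matrix with feature row names.
#' @param groups Two-group sample labels (`sample`/`group` data frame or
#'   named vector); each group needs at least 2 samples.
#' @param d0_override Optional prior degrees of freedom forcing: `0` gives
#'   the ordinary pooled-variance t-test, `Inf` complete shrinkage to the
#'   prior variance.
#' @return A tibble with one row per feature: `feature`, `effect`
#'   (`mean(group1) - mean(group2)`, group1 = first sorted label), `t`,
#'   `df_total`, `p`, plus attributes `d0` and `s0_sq` with the estimated
#'   prior.
#' @export
moderated_t_engine <- function(m, groups, d0_override = NULL) {
  if (!is.matrix(m)) m <- expr_matrix(m)
  g <- group_vector(groups, colnames(m))
  if (length(g) < ncol(m)) m <- m[, names(g), drop = FALSE]
  levels <- sort_genes(unique(g))
  if (length(levels) != 2) abort("moderated test needs exactly two groups")
  idx1 <- which(g == levels[1])
  idx2 <- which(g == levels[2])
  n1 <- length(idx1)
  n2 <- length(idx2)
  if (n1 < 2 || n2 < 2) {
    abort(paste0("each group needs >= 2 samples (got ", n1, " and ", n2, ")"))
  }
  m1 <- rowMeans(m[, idx1, drop = FALSE])
  m2 <- rowMeans(m[, idx2, drop = FALSE])
  ss1 <- rowSums((m[, idx1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((m[, idx2, drop = FALSE] - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  if (is.null(d0_override)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    prior <- list(
      d0 = d0_override,
      s0_sq = if (is.infinite(d0_override)) fit_variance_prior(s2, d)$s0_sq else NA_real_
    )
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  s2_shrunk <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  effect <- m1 - m2
  t <- effect / se
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) {
    2 * pnorm(-abs(t))
  } else {
    2 * pt(-abs(t), df = df_total)
  }
  out <- tibble::tibble(
    feature = rownames(m) %||% as.character(seq_len(nrow(m))),
    effect = unname(effect), t = unname(t),
    df_total = df_total, p = unname(p)
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "groups") <- levels
  out
}

# method-of-moments fit of (d0, s0^2) from residual variances s2 on d df:
# z = log(s2); e = z - digamma(d/2) + log(d/2); then
# E[e] = log(s0^2) + digamma(d0/2) - log(d0/2) and
# Var[e] = trigamma(d/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    # degenerate: no spread to estimate from; shrink completely
    return(list(d0 = Inf, s0_sq = mean(s2[is.finite(s2)])))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of trigamma on (0, Inf); trigamma is decreasing and convex
trigamma_inverse <- function(y) {
  stopifnot(length(y) == 1, is.finite(y), y > 0)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment preserving input order (wrapper around
#' `p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
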