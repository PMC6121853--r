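#' Mixed-model fit wrapper
#'
#' Internal constructor for the classed result returned by the package's
#' mixed-model analyses ([adjacency_lmm()], [outcome_lmm()], [mis_lmm()]).
#' Bundles the underlying `lme4` fit with term-wise F-tests (containment
#' denominator degrees of freedom), variance components, an optional
#' sequential variance partition, and a Shapiro-Wilk residual-normality check.
#'
#' @name mixed_model_fit
#' @keywords internal
NULL

new_mixed_model_fit <- function(fit, anova_table, varpart = NULL,
                                shapiro_p = NA_real_, response = "",
                                transform = "identity") {
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, anova_table = anova_table, varpart = varpart,
                 variance_components = vc[, c("grp", "vcov")],
                 shapiro_p = shapiro_p, response = response,
                 transform = transform),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s (%s response), REML\n", x$response,
              x$transform))
  at <- x$anova_table
  at$p <- format.pval(at$p, digits = 3)
  print(at, row.names = FALSE, digits = 4)
  cat("Random-effect variances:\n")
  print(x$variance_components, row.names = FALSE, digits = 4)
  if (!is.na(x$shapiro_p))
    cat(sprintf("Shapiro-Wilk residual normality: p = %.3g\n", x$shapiro_p))
  if (!is.null(x$varpart)) {
    cat("Variance explained (sequential SS, % of total):\n")
    print(x$varpart, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.mixed_model_fit <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  print(lme4::fixef(object$fit), digits = 4)
  invisible(object)
}

#' @export
coef.mixed_model_fit <- function(object, ...) lme4::fixef(object$fit)

# Wald F-tests for each fixed-effect term of an lmer/glmer fit with
# denominator df by the containment method relative to one grouping factor:
# terms constant within every group ("between") get ddf = g - rank(between
# design); terms varying within groups get ddf = N - g - rank(within part).
# This reproduces the df pattern of classical nested ANOVA (e.g. denominator
# 9 for 10 subjects with one within-subject factor).
containment_anova <- function(fit, group) {
  X <- lme4::getME(fit, "X")
  asgn <- attr(X, "assign")
  tl <- attr(stats::terms(fit), "term.labels")
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  g <- length(unique(group))
  N <- nrow(X)

  is_between_col <- vapply(seq_len(ncol(X)), function(j) {
    all(tapply(X[, j], group, function(v) max(v) - min(v)) < 1e-8)
  }, logical(1))
  Xb <- X[, is_between_col, drop = FALSE]
  p_b <- 0
  if (ncol(Xb)) {
    # rank of the between design evaluated at the group level
    Xb_grp <- unique(data.frame(grp = group, Xb, check.names = FALSE))
    p_b <- qr(as.matrix(Xb_grp[, -1, drop = FALSE]))$rank
  }
  p_w <- qr(X)$rank - p_b

  rows <- lapply(seq_along(tl), function(k) {
    idx <- which(asgn == k)
    bk <- b[idx]
    Vk <- V[idx, idx, drop = FALSE]
    Fval <- as.numeric(t(bk) %*% solve(Vk, bk)) / length(idx)
    between <- all(is_between_col[idx])
    ddf <- if (between) g - p_b else N - g - p_w
    data.frame(term = tl[k], F = Fval, ndf = length(idx), ddf = ddf,
               p = stats::pf(Fval, length(idx), max(ddf, 1),
                             lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

# Sequential (type-I) sum-of-squares decomposition of the fixed-effect design
# on the (transformed) response; percentages of the total sum of squares.
sequential_varpart <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]
  terms <- rownames(av)
  total <- sum(ss)
  pct <- 100 * ss / total
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], percent = pct[keep],
             total_explained = sum(pct[keep]))
}

# set sum-to-zero contrasts on every factor column so that the per-term Wald
# F-tests are main-effect tests (not simple effects at a reference level)
use_sum_contrasts <- function(dat) {
  for (nm in names(dat))
    if (is.factor(dat[[nm]]) && nlevels(dat[[nm]]) > 1)
      stats::contrasts(dat[[nm]]) <- stats::contr.sum(nlevels(dat[[nm]]))
  dat
}

#' Adjusted difference between two factor levels
#'
#' Estimated fixed-effect difference `level_hi - level_lo` of a factor in a
#' [mixed_model_fit], averaged over the observed distribution of the other
#' model factors, with its standard error and a Wald confidence interval.
#'
#' @param fit a [mixed_model_fit] (must carry its model frame).
#' @param factor_name name of the factor in the model.
#' @param level_hi,level_lo the two levels to difference.
#' @param conf confidence level (default 0.95).
#' @return list with `estimate`, `se`, `ci_lo`, `ci_hi`.
#' @export
effect_of <- function(fit, factor_name, level_hi, level_lo, conf = 0.95) {
  stopifnot(inherits(fit, "mixed_model_fit"), !is.null(fit$data))
  X <- lme4::getME(fit$fit, "X")
  f <- fit$data[[factor_name]]
  if (is.null(f)) stop("no factor '", factor_name, "' in the fit",
                       call. = FALSE)
  L <- colMeans(X[f == level_hi, , drop = FALSE]) -
    colMeans(X[f == level_lo, , drop = FALSE])
  b <- lme4::fixef(fit$fit)
  V <- as.matrix(stats::vcov(fit$fit))
  est <- sum(L * b)
  se <- sqrt(as.numeric(t(L) %*% V %*% L))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  list(estimate = est, se = se, ci_lo = est - zq * se, ci_hi = est + zq * se)
}

#' Bias-reduced (Firth) logistic regression
#'
#' Fixed-effects logistic fit with Firth's penalized score correction
#' (score adjusted by the hat diagonal), which yields finite estimates under
#' complete separation. Used as the fallback when a binomial mixed model
#' cannot be trusted because the outcome is perfectly separated.
#'
#' @param X model matrix (with intercept column).
#' @param y 0/1 response.
#' @param max_iter,tol IRLS controls.
#' @return list with `coefficients` and `converged`.
#' @keywords internal
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    h <- diag(XW %*% solve(I, t(XW)))
    U <- as.numeric(t(X) %*% (y - p + h * (0.5 - p)))
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < tol)
      return(list(coefficients = stats::setNames(beta, colnames(X)),
                  converged = TRUE))
  }
  list(coefficients = stats::setNames(beta, colnames(X)), converged = FALSE)
}
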