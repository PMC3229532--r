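#' Correlation test with p-value
#'
#' Pearson or Spearman correlation with the two-sided p-value from the
#' t transform t = r sqrt((n-2)/(1-r^2)), as in \code{stats::cor.test}.
#'
#' @param x,y numeric vectors, n >= 4.
#' @param method "pearson" or "spearman".
#' @return list(r, p, n).
#' @export
correlationTest <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Power of a correlation test via the Fisher z approximation
#'
#' Power of the two-sided test of rho = 0 at level alpha when the true
#' correlation is r with n observations, using the Fisher z transform
#' with its standard small-sample mean correction
#' E z(rhat) = z(r) + r / (2 (n - 1)):
#' power = Phi(sqrt(n-3) m - z_{1-alpha/2}) +
#'         Phi(-sqrt(n-3) m - z_{1-alpha/2}),
#' where m = atanh(r) + r / (2 (n - 1)). At r = 0 this reduces to alpha
#' (the size of the test); the correction matters only at small n, where
#' the uncorrected approximation visibly underestimates simulated power.
#'
#' @param r true correlation, |r| < 1.
#' @param n sample size, > 3.
#' @param alpha significance level (default 0.05).
#' @return power in [0, 1].
#' @export
correlationPower <- function(r, n, alpha = 0.05) {
  stopifnot(abs(r) < 1, n > 3)
  zr <- atanh(r) + r / (2 * (n - 1))
  za <- stats::qnorm(1 - alpha / 2)
  s <- sqrt(n - 3)
  stats::pnorm(s * zr - za) + stats::pnorm(-s * zr - za)
}

#' Linear regression of expression divergence on Ks and/or WGD code
#'
#' Ordinary least squares for the three model forms d ~ Ks, d ~ W and
#' d ~ Ks + W, where W is the integer polyploidy-event code (1 for the
#' most recent event, increasing with age: alpha/beta/gamma -> 1/2/3,
#' rho/sigma -> 1/2). Rows with an invalid (NA) Ks or d are excluded.
#' AIC uses the full Gaussian log-likelihood with the error variance
#' counted as a parameter (the standard \code{stats::AIC} convention),
#' so AIC = n log(2 pi RSS/n) + n + 2 (k + 2) for k slopes.
#'
#' @param data data.frame with columns \code{d} and the needed
#'   predictors \code{Ks}, \code{W}.
#' @param model one of "ks", "w", "ks+w".
#' @return list: \code{coefficients} (data.frame term, estimate, p),
#'   \code{adj_r_squared}, \code{r_squared}, \code{aic}, \code{n},
#'   \code{fit} (the lm object).
#' @export
regressDivergence <- function(data, model = c("ks+w", "ks", "w")) {
  model <- match.arg(model)
  form <- switch(model, "ks" = d ~ Ks, "w" = d ~ W, "ks+w" = d ~ Ks + W)
  vars <- all.vars(form)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  dat <- data[keep, , drop = FALSE]
  fit <- stats::lm(form, data = dat)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  sm <- summary(fit)
  co <- data.frame(term = rownames(sm$coefficients),
                   estimate = sm$coefficients[, 1],
                   p = sm$coefficients[, 4], row.names = NULL)
  list(coefficients = co, adj_r_squared = sm$adj.r.squared,
       r_squared = sm$r.squared, aic = stats::AIC(fit),
       n = nrow(dat), fit = fit)
}

#' Map polyploidy event labels to integer codes
#'
#' The most recent event is coded 1, older events get larger codes:
#' alpha/beta/gamma -> 1/2/3 (Arabidopsis-like), rho/sigma -> 1/2
#' (rice-like). Custom mappings may be supplied.
#'
#' @param event character vector of event labels.
#' @param mapping named integer vector; default covers both label sets.
#' @return integer codes (NA for unmapped labels).
#' @export
wgdCode <- function(event,
                    mapping = c("alpha" = 1L, "beta" = 2L, "gamma" = 3L,
                                "α" = 1L, "β" = 2L,
                                "γ" = 3L,
                                "rho" = 1L, "sigma" = 2L,
                                "ρ" = 1L, "σ" = 2L)) {
  unname(mapping[event])
}

#' One-way ANOVA with Tukey HSD post-hoc contrasts
#'
#' @param values numeric vector.
#' @param groups grouping factor/character of the same length; at least 2
#'   groups of size >= 2.
#' @param alpha level for the Tukey decisions (default 0.05).
#' @return list: \code{F}, \code{p}, \code{tukey} (data.frame contrast,
#'   diff, p_adj, significant).
#' @export
anovaTukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(F = sm$`F value`[1], p = sm$`Pr(>F)`[1], tukey = tukey)
}

#' Smoothing-spline trend fit
#'
#' Cubic smoothing spline whose penalty is chosen so that the effective
#' degrees of freedom (trace of the smoother matrix) equal \code{df}, the
#' convention of \code{stats::smooth.spline}; df = 10 is the default used
#' for divergence-versus-Ks trend curves.
#'
#' @param x,y numeric vectors.
#' @param df target effective degrees of freedom (default 10).
#' @return list: \code{fitted} (at the input x), \code{predict} (function
#'   of new x), \code{df} (achieved effective df), \code{fit}.
#' @export
splineTrend <- function(x, y, df = 10) {
  nx <- length(unique(x))
  if (nx < df + 2)
    stop("only ", nx, " distinct x values; use df < ", nx - 1)
  fit <- stats::smooth.spline(x, y, df = df, cv = FALSE)
  list(fitted = stats::predict(fit, x)$y,
       predict = function(newx) stats::predict(fit, newx)$y,
       df = fit$df, fit = fit)
}
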