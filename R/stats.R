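test_result <- function(test, statistic, df, p, p_adjusted = NA_real_,
                        correction = "none", effect = NA_character_,
                        note = NA_character_) {
  data.frame(test = test, effect = effect, statistic = statistic,
             df = I(list(df)), p = p, p_adjusted = p_adjusted,
             correction = correction, note = note,
             stringsAsFactors = FALSE)
}

#' Paired-samples t-test
#'
#' Two-tailed Student's paired t-test on measurements paired by subject.
#' Degenerate inputs are handled explicitly: identical vectors give t = 0,
#' p = 1; a constant non-zero difference gives an infinite t, p reported
#' as 0 with a note.
#'
#' @param a,b equal-length numeric vectors (n >= 2), paired by subject.
#' @return A one-row test-result data frame (`statistic` = t).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (stats::sd(d) < .Machine$double.eps * max(1, abs(mean(d)))) {
    if (abs(mean(d)) < .Machine$double.eps)
      return(test_result("paired t", 0, n - 1, 1))
    return(test_result("paired t", sign(mean(d)) * Inf, n - 1, 0,
                       note = "zero variance of differences"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  test_result("paired t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value)
}

# Greenhouse-Geisser epsilon from the subject x level response matrix.
gg_epsilon <- function(Y) {
  k <- ncol(Y)
  C <- stats::contr.helmert(k)
  C <- qr.Q(qr(C))                           # orthonormal contrasts
  M <- t(C) %*% stats::cov(Y) %*% C
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' One-way: within-subject F-test via the multivariate linear model, with
#' Mauchly's sphericity test; when sphericity is rejected (default at
#' alpha 0.05) the Greenhouse-Geisser epsilon-corrected degrees of freedom
#' and p-value are reported. Two within factors: univariate mixed-design
#' tables via `car::Anova` (type III), GG-corrected per effect on the same
#' rule. With `repeated = FALSE` an ordinary (non-repeated) two-way ANOVA
#' is fitted instead — the fallback used when missing cells break the
#' within-subject design.
#'
#' @param data long-format data frame.
#' @param dv name of the value column.
#' @param subject name of the subject column.
#' @param within character vector of one or two within-subject factor
#'   columns.
#' @param repeated set FALSE for the non-repeated two-way fallback.
#' @param sphericity_alpha level of Mauchly's test triggering the GG
#'   correction.
#' @return A test-result data frame, one row per effect; `statistic` is
#'   F, `df` holds `c(df1, df2)` (GG-corrected when applied), and
#'   `correction` records "GG" or "none".
#' @export
rm_anova <- function(data, dv = "value", subject = "rat",
                     within = "condition", repeated = TRUE,
                     sphericity_alpha = 0.05) {
  data[within] <- lapply(data[within], factor)
  if (!repeated) {
    if (length(within) != 2) stop("the fallback needs two factors")
    f <- stats::as.formula(paste(dv, "~", within[1], "*", within[2]))
    aa <- car::Anova(stats::lm(f, data = data), type = 2)
    eff <- rownames(aa)[!rownames(aa) %in% "Residuals"]
    res <- lapply(eff, function(e) {
      test_result("two-way ANOVA", aa[e, "F value"],
                  c(aa[e, "Df"], aa["Residuals", "Df"]),
                  aa[e, "Pr(>F)"], effect = e)
    })
    return(do.call(rbind, res))
  }
  if (length(within) == 1) {
    w <- within
    if (nlevels(data[[w]]) < 2)
      stop("need at least two within-factor levels")
    cells <- tapply(data[[dv]], list(data[[subject]], data[[w]]), mean)
    if (anyNA(cells)) stop("incomplete within-subject design")
    Y <- unclass(cells)
    mod <- stats::lm(Y ~ 1)
    id <- data.frame(f = factor(colnames(cells)))
    names(id) <- w
    av <- anova(mod, M = stats::as.formula(paste("~", w)), X = ~1,
                idata = id, test = "Spherical")
    mau <- stats::mauchly.test(mod, M = stats::as.formula(paste("~", w)),
                               X = ~1, idata = id)
    eps <- gg_epsilon(Y)
    F_ <- av$F[1]; df1 <- av[["num Df"]][1]; df2 <- av[["den Df"]][1]
    p_raw <- av[["Pr(>F)"]][1]
    use_gg <- ncol(Y) > 2 && is.finite(mau$p.value) &&
      mau$p.value < sphericity_alpha
    if (use_gg) {
      out <- test_result("one-way rANOVA", F_, c(eps * df1, eps * df2),
                         av[["G-G Pr"]][1], correction = "GG", effect = w)
    } else {
      out <- test_result("one-way rANOVA", F_, c(df1, df2), p_raw,
                         effect = w)
    }
    out$gg_epsilon <- eps
    out$sphericity_p <- mau$p.value
    return(out)
  }
  # two within-subject factors
  w1 <- within[1]; w2 <- within[2]
  cells <- tapply(data[[dv]], list(data[[subject]],
                                   data[[w1]], data[[w2]]), mean)
  if (anyNA(cells)) stop("incomplete within-subject design")
  l1 <- dimnames(cells)[[2]]; l2 <- dimnames(cells)[[3]]
  Y <- matrix(cells, nrow = dim(cells)[1])
  id <- expand.grid(a = factor(l1), b = factor(l2))
  names(id) <- c(w1, w2)
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = id,
                   idesign = stats::as.formula(paste("~", w1, "*", w2)),
                   type = 3)
  sm <- summary(av, multivariate = FALSE)
  ut <- sm$univariate.tests
  adj <- sm$pval.adjustments
  sph <- sm$sphericity.tests
  eff <- setdiff(rownames(ut), "(Intercept)")
  res <- lapply(eff, function(e) {
    F_ <- ut[e, "F value"]; df1 <- ut[e, "num Df"]; df2 <- ut[e, "den Df"]
    p_raw <- ut[e, "Pr(>F)"]
    sp <- if (!is.null(sph) && e %in% rownames(sph)) sph[e, "p-value"] else NA
    if (is.finite(sp) && sp < sphericity_alpha && e %in% rownames(adj)) {
      eps <- adj[e, "GG eps"]
      r <- test_result("two-way rANOVA", F_, c(eps * df1, eps * df2),
                       adj[e, "Pr(>F[GG])"], correction = "GG", effect = e)
      r$gg_epsilon <- eps
    } else {
      r <- test_result("two-way rANOVA", F_, c(df1, df2), p_raw, effect = e)
      r$gg_epsilon <- NA_real_
    }
    r$sphericity_p <- sp
    r
  })
  do.call(rbind, res)
}

#' Holm-Bonferroni step-down correction
#'
#' Step-down adjusted p-values plus the fixed Bonferroni-corrected alpha
#' (`alpha / m`) that applies to the smallest p-value — both conventions
#' are reported so either can be checked. Adjusted p-values are monotone
#' in the raw ones.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha family-wise level.
#' @return list: `p_adjusted`, `reject` (logical, Holm at `alpha`),
#'   `fixed_alpha` (`alpha / m`), `reject_fixed` (each raw p against the
#'   fixed corrected alpha).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "holm")
  list(p_adjusted = adj,
       reject = adj <= alpha,
       fixed_alpha = alpha / length(p),
       reject_fixed = p < alpha / length(p))
}

#' Linear fit with R-squared and slope t-test
#'
#' Least-squares regression of `y` on `x`; reports the slope, coefficient
#' of determination and the two-tailed t-test of slope = 0 on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list: `slope`, `intercept`, `r2`, `t`, `df`, `p`, `n`.
#' @export
linfit_r2_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  list(slope = co["x", "Estimate"],
       intercept = co["(Intercept)", "Estimate"],
       r2 = sm$r.squared,
       t = co["x", "t value"], df = fit$df.residual,
       p = co["x", "Pr(>|t|)"], n = length(x))
}
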