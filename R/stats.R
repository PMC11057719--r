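#' Welch's unpaired two-sample t test
#'
#' Thin wrapper over [stats::t.test()] (unequal variances, Satterthwaite
#' degrees of freedom) with explicit conventions for degenerate inputs:
#' when both groups have zero variance, equal means give `p = 1`
#' (`t = 0`) and unequal means give `p = 0` with `degenerate = TRUE` and a
#' warning.
#'
#' @param x,y numeric vectors, each of length >= 2, finite.
#' @return list with `t`, `df`, `p` (two-sided) and `degenerate`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (!all(is.finite(c(x, y))))
    stop("values must be finite", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  degenerate = FALSE))
    warning("zero variance in both groups with unequal means; p -> 0",
            call. = FALSE)
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Wrapper over [stats::wilcox.test()] with the conventions fixed for this
#' pipeline: zero differences are dropped before ranking; an exact p value
#' is used for n <= 25 non-zero untied differences, the normal
#' approximation with continuity correction otherwise; all-zero differences
#' give `p = 1` with a warning.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `W` (sum of positive ranks), `p` (two-sided),
#'   `n_used` (non-zero pairs) and `exact`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired vectors of equal length >= 2",
         call. = FALSE)
  d <- x - y
  nz <- d != 0
  if (!any(nz)) {
    warning("all paired differences are zero; p = 1", call. = FALSE)
    return(list(W = 0, p = 1, n_used = 0L, exact = TRUE))
  }
  d <- d[nz]
  n <- length(d)
  exact <- n <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value, n_used = n, exact = exact)
}

#' Factorial ANOVA over a per-sample proportion table
#'
#' Fits the full factorial linear model `response ~ f1 * f2 * ...` and
#' returns F tests for every main effect and interaction.  Balanced designs
#' use the conventional sequential decomposition; unbalanced designs use
#' marginal (Type-III-style) sums of squares with sum-to-zero contrasts,
#' and the choice is recorded in the result's `ss_type` attribute.
#' Proportions are analysed untransformed.
#'
#' @param data long-format `data.frame` of per-sample values.
#' @param response name of the (finite numeric) response column.
#' @param factors character vector of 1-3 categorical column names, each
#'   with >= 2 levels and every cell populated.
#' @return `data.frame` with columns `effect`, `df1`, `df2`, `F`, `p` and
#'   `p_label` (p values below 1e-15 print as `"< 1e-15"`); attributes
#'   `ss_type` and `fit` (the underlying `lm`).  A saturated design (one
#'   observation per cell) leaves the highest interaction untestable and
#'   warns.
#' @export
factorial_anova <- function(data, response, factors) {
  if (length(factors) < 1 || length(factors) > 3)
    stop("between 1 and 3 factors are supported", call. = FALSE)
  if (!all(c(response, factors) %in% names(data)))
    stop("response/factor columns missing from data", call. = FALSE)
  y <- data[[response]]
  if (!is.numeric(y) || !all(is.finite(y)))
    stop("response must be finite numeric", call. = FALSE)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2)
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
  }
  cell <- interaction(data[factors], drop = FALSE)
  cnt <- table(cell)
  if (any(cnt == 0))
    stop("every factor-level cell needs at least one observation",
         call. = FALSE)
  balanced <- length(unique(cnt)) == 1L
  form <- stats::as.formula(paste(response, "~",
                                  paste(factors, collapse = " * ")))
  if (balanced) {
    fit <- stats::lm(form, data = data)
    tab <- stats::anova(fit)
    eff <- setdiff(rownames(tab), "Residuals")
    out <- data.frame(effect = eff, df1 = tab[eff, "Df"],
                      df2 = tab["Residuals", "Df"],
                      F = tab[eff, "F value"], p = tab[eff, "Pr(>F)"],
                      stringsAsFactors = FALSE)
    ss_type <- "sequential (Type I; balanced design)"
  } else {
    contr <- stats::setNames(rep(list("contr.sum"), length(factors)),
                             factors)
    fit <- stats::lm(form, data = data, contrasts = contr)
    tab <- car::Anova(fit, type = 3)
    eff <- setdiff(rownames(tab), c("(Intercept)", "Residuals"))
    out <- data.frame(effect = eff, df1 = tab[eff, "Df"],
                      df2 = tab["Residuals", "Df"],
                      F = tab[eff, "F value"], p = tab[eff, "Pr(>F)"],
                      stringsAsFactors = FALSE)
    ss_type <- "marginal (Type III; sum-to-zero contrasts)"
  }
  if (any(out$df2 == 0)) {
    warning("saturated design: no residual degrees of freedom, ",
            "interaction untestable", call. = FALSE)
    out$F[out$df2 == 0] <- NA_real_
    out$p[out$df2 == 0] <- NA_real_
  }
  out$p_label <- ifelse(is.na(out$p), NA_character_,
                        ifelse(out$p < 1e-15, "< 1e-15",
                               format(out$p, digits = 4)))
  rownames(out) <- NULL
  attr(out, "ss_type") <- ss_type
  attr(out, "fit") <- fit
  out
}

#' Tukey HSD multiple comparisons
#'
#' All pairwise comparisons among the levels of one factor (or the cells of
#' an interaction) after a factorial ANOVA, via [stats::TukeyHSD()] on the
#' corresponding `aov` fit; unbalanced groups use the Tukey-Kramer form.
#' The studentized-range statistic `q` is recomputed from the fit's error
#' mean square for reporting.
#'
#' @inheritParams factorial_anova
#' @param effect the factor name, or an interaction term such as
#'   `"tissue:sex"`, whose levels/cells are compared; defaults to the full
#'   interaction of `factors`.
#' @return `data.frame` with `comparison`, `diff`, `lwr`, `upr` (95%
#'   family-wise CI), `q` and `p_adj`; empty for a single group.
#' @export
tukey_hsd <- function(data, response, factors, effect = NULL) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  if (is.null(effect)) effect <- paste(factors, collapse = ":")
  parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
  groups <- interaction(data[parts], drop = TRUE, sep = ":")
  if (nlevels(groups) < 2)
    return(data.frame(comparison = character(0), diff = numeric(0),
                      lwr = numeric(0), upr = numeric(0), q = numeric(0),
                      p_adj = numeric(0)))
  form <- stats::as.formula(paste(response, "~",
                                  paste(factors, collapse = " * ")))
  fit <- stats::aov(form, data = data)
  th <- stats::TukeyHSD(fit, which = effect)[[effect]]
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  ns <- table(groups)
  means <- tapply(data[[response]], groups, mean)
  q <- vapply(seq_len(nrow(th)), function(i) {
    ab <- match_pair(rownames(th)[i], names(means))
    se <- sqrt(mse / 2 * (1 / ns[[ab[1]]] + 1 / ns[[ab[2]]]))
    abs(th[i, "diff"]) / se
  }, numeric(1))
  data.frame(comparison = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"], q = q,
             p_adj = th[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

# split a TukeyHSD row name "a-b" into its two group labels, robust to "-"
# inside labels
match_pair <- function(rowname, labels) {
  for (a in labels) for (b in labels) {
    if (identical(rowname, paste0(a, "-", b))) return(c(a, b))
  }
  stop("cannot parse comparison '", rowname, "'", call. = FALSE)
}
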