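#' Standardize a sequence of values
#'
#' Centres to mean 0 and rescales to sample standard deviation 1 (ddof 1).
#' Used to put clustering coefficients of different languages on a common
#' scale before cross-language comparison.
#'
#' @param values numeric vector (length >= 2, not all equal).
#' @return Standardized numeric vector with attributes `mean` and `sd`
#'   recording the reference distribution.
#' @export
zscore <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma == 0) stop("constant input: cannot standardize")
  out <- (values - mu) / sigma
  attr(out, "mean") <- mu
  attr(out, "sd") <- sigma
  out
}

#' Residualize one variable against another
#'
#' Ordinary least-squares residuals of `y ~ intercept + x`: the part of `y`
#' linearly unexplained by `x`. Residuals sum to zero and are orthogonal to
#' the predictor. Used to remove the linear frequency effect from clustering
#' coefficients (and vice versa) before paired comparisons.
#'
#' @param y response vector.
#' @param x predictor vector (same length as `y`, not constant, length >= 3).
#' @return Numeric vector of residuals.
#' @export
residualize <- function(y, x) {
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("constant predictor")
  unname(stats::.lm.fit(cbind(1, x), y)$residuals)
}

.cs_test <- function(method, statistic, df, p, effect = NULL, estimate = NULL,
                     extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df, p = p,
                   effect = effect, estimate = estimate), extra),
            class = "cs_test")
}

#' @export
print.cs_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g",
              x$method, x$statistic, dfs, x$p))
  if (!is.null(x$effect)) cat(sprintf(", effect = %.4f", x$effect))
  cat("\n")
  invisible(x)
}

#' Pearson correlation with significance test
#'
#' Correlation coefficient r with the usual t transform on n - 2 degrees of
#' freedom for the two-sided p-value.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A `cs_test` with `estimate` (r), `statistic` (t), `df`, `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  .cs_test("Pearson correlation", statistic = unname(ct$statistic),
           df = unname(ct$parameter), p = ct$p.value,
           estimate = unname(ct$estimate))
}

#' Construct a paired CS/TE sample
#'
#' One row per item (a CS word paired with its translation equivalent), with
#' the measured value for each member of the pair and the between-item
#' switch-direction label.
#'
#' @param value_cs,value_te numeric vectors (finite, equal length).
#' @param direction character/factor vector of direction labels per item.
#' @return Data frame of class `paired_sample`.
#' @export
paired_sample <- function(value_cs, value_te, direction) {
  stopifnot(length(value_cs) == length(value_te),
            length(direction) == length(value_cs))
  if (any(!is.finite(value_cs)) || any(!is.finite(value_te))) {
    stop("values must be finite")
  }
  df <- data.frame(item = seq_along(value_cs), value_cs = value_cs,
                   value_te = value_te,
                   direction = as.character(direction),
                   stringsAsFactors = FALSE)
  class(df) <- c("paired_sample", "data.frame")
  df
}

#' Paired-sample t test on CS - TE differences
#'
#' Tests whether CS words differ from their translation equivalents within
#' one switch direction. The difference is `value_cs - value_te`; the
#' statistic is `mean(d) / (sd(d)/sqrt(n))` on `n - 1` degrees of freedom,
#' and the standardized effect size is Cohen's d = `mean(d)/sd(d)`.
#'
#' @param sample a [paired_sample()].
#' @param direction optional direction label; default uses all items.
#' @return A `cs_test` with `statistic` (t), `df`, `p`, `effect` (Cohen's
#'   d), and `estimate` (mean difference).
#' @export
paired_t <- function(sample, direction = NULL) {
  stopifnot(inherits(sample, "paired_sample"))
  if (!is.null(direction)) sample <- sample[sample$direction == direction, ]
  n <- nrow(sample)
  if (n < 2) stop("need at least 2 items")
  d <- sample$value_cs - sample$value_te
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0) stop("zero-variance differences")
  tt <- stats::t.test(sample$value_cs, sample$value_te, paired = TRUE)
  .cs_test("Paired t", statistic = unname(tt$statistic),
           df = unname(tt$parameter), p = tt$p.value,
           effect = mean(d) / sdd, estimate = mean(d))
}

#' Mixed-design (split-plot) 2 x 2 ANOVA
#'
#' The item (a CS-TE pair) is the random unit; switching (CS word versus TE)
#' is the within-item factor and switch direction the between-item factor.
#' The classical split-plot decomposition is used: the between-item sum of
#' squares splits into direction and item-within-direction error, the
#' within-item sum of squares into switching, switching x direction, and
#' residual. With direction group sizes n1 and n2 the interaction has
#' `(1, n1 + n2 - 2)` degrees of freedom, and the interaction F equals the
#' square of the pooled two-sample t comparing per-item CS - TE differences
#' across the two directions.
#'
#' @param sample a [paired_sample()] with exactly two direction labels and
#'   at least two items per direction.
#' @return Named list of `cs_test` objects: `direction` (between-item),
#'   `switching` and `interaction` (within-item strata).
#' @export
mixed_anova_2x2 <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  dirs <- unique(sample$direction)
  if (length(dirs) != 2) stop("exactly 2 directions required")
  if (any(table(sample$direction) < 2)) {
    stop("need at least 2 items per direction")
  }
  long <- data.frame(
    item = factor(rep(sample$item, 2)),
    direction = factor(rep(sample$direction, 2)),
    switching = factor(rep(c("cs", "te"), each = nrow(sample)),
                       levels = c("te", "cs")),
    value = c(sample$value_cs, sample$value_te)
  )
  fit <- stats::aov(value ~ direction * switching + Error(item), data = long)
  sm <- summary(fit)
  tab_b <- sm[["Error: item"]][[1]]
  tab_w <- sm[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    r <- match("Residuals", trimws(rownames(tab)))
    .cs_test(paste0("Split-plot ANOVA: ", term),
             statistic = tab[i, "F value"],
             df = c(tab[i, "Df"], tab[r, "Df"]),
             p = tab[i, "Pr(>F)"])
  }
  list(direction = pick(tab_b, "direction"),
       switching = pick(tab_w, "switching"),
       interaction = pick(tab_w, "direction:switching"))
}

#' Sign test for paired comparisons
#'
#' Two-cell goodness-of-fit chi-square on the counts of pairs in which the
#' CS word's value is lower (`a`) versus higher (`b`) than its translation
#' equivalent's, without continuity correction:
#' \deqn{\chi^2 = (a - b)^2 / (a + b)} on 1 degree of freedom. Ties must be
#' excluded by the caller.
#'
#' @param a count of pairs with the CS value lower.
#' @param b count of pairs with the CS value higher.
#' @return A `cs_test` with `statistic` (chi-square), `df` = 1, `p`.
#' @export
sign_test <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1, a >= 0, b >= 0)
  if (a + b < 1) stop("a + b must be at least 1")
  chisq <- (a - b)^2 / (a + b)
  .cs_test("Sign test (chi-square)", statistic = chisq, df = 1,
           p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
           extra = list(n_lower = a, n_higher = b))
}

#' Logistic regression of a binary outcome on one predictor
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' `glm`). Reports the slope B, its standard error, the Wald statistic
#' `(B/SE)^2` with its two-sided p-value, and the Cox-Snell
#' \eqn{R^2 = 1 - (L_0/L_1)^{2/n}} (Nagelkerke's rescaling is also
#' returned). Perfect separation is flagged as non-convergence rather than
#' silently returning a divergent slope.
#'
#' @param y binary outcome (logical, 0/1, or two-level factor), both classes
#'   present.
#' @param x numeric predictor, same length as `y`, length >= 4.
#' @return A `cs_test` with `statistic` (Wald), `df`, `p`, `estimate` (B),
#'   and extra fields `se`, `intercept`, `r2_coxsnell`, `r2_nagelkerke`,
#'   `converged`.
#' @export
logistic_fit <- function(y, x) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 4) stop("need at least 4 observations")
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  if (length(unique(y)) < 2) stop("both classes must be present")
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  converged <- fit$converged && !separation
  B <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  wald <- (B / se)^2
  n <- length(y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(y ~ 1, family = stats::binomial())))
  r2cs <- 1 - exp((2 / n) * (ll0 - ll1))
  r2max <- 1 - exp((2 / n) * ll0)
  .cs_test("Logistic regression (Wald)", statistic = wald, df = 1,
           p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
           estimate = B,
           extra = list(se = se, intercept = unname(stats::coef(fit)[1]),
                        r2_coxsnell = r2cs, r2_nagelkerke = r2cs / r2max,
                        converged = converged))
}
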