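# build the (intercept + covariates) design matrix from a covariate
# data.frame; errors on rank deficiency naming the collinear columns
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cv <- as.data.frame(covariates)
  stopifnot(nrow(cv) == n)
  X <- cbind("(Intercept)" = 1, as.matrix(cv))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("covariate design is rank deficient; collinear columns: %s",
                 paste(bad, collapse = ", ")))
  }
  X
}

#' Remove covariate effects by ordinary least squares
#'
#' Regresses `y` on an intercept plus the covariate columns and returns the
#' residuals, which are orthogonal to every covariate column. With no
#' covariates this reduces to centering.
#'
#' @param y numeric vector (or subjects x variables matrix) of responses.
#' @param covariates data.frame/matrix of per-subject covariates (e.g. age,
#'   sex, education), or `NULL` for intercept-only.
#' @return residuals with the shape of `y`.
#' @export
residualize <- function(y, covariates = NULL) {
  ymat <- as.matrix(y)
  X <- covariate_design(covariates, nrow(ymat))
  if (nrow(ymat) <= ncol(X)) stop("need more subjects than covariates")
  res <- stats::lm.fit(X, ymat)$residuals
  if (is.vector(y)) as.numeric(res) else res
}

#' Covariate-adjusted omnibus group test (ANCOVA)
#'
#' F-test comparing the linear model `{group indicators + covariates}` against
#' `{covariates only}`. With no covariates this is exactly the classical
#' one-way ANOVA. Also reports covariate-adjusted group means ("fitted
#' values": group means of the covariate residuals, shifted back by the grand
#' mean) with their dispersions.
#'
#' @param y numeric response vector.
#' @param groups factor or character vector of group labels.
#' @param covariates data.frame of covariates or `NULL`.
#' @return a `group_comparison` list: `F`, `p`, `df` (between, within),
#'   `adjusted_means` data.frame, and the inputs' group levels.
#' @export
ancova_omnibus <- function(y, groups, covariates = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 subjects")
  dat <- data.frame(y = y, group = groups)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  covnames <- setdiff(names(dat), c("y", "group"))
  rhs0 <- if (length(covnames)) paste(covnames, collapse = " + ") else "1"
  fit0 <- lm(stats::as.formula(paste("y ~", rhs0)), data = dat)
  fit1 <- lm(stats::as.formula(paste("y ~ group +", rhs0)), data = dat)
  an <- anova(fit0, fit1)
  resid_adj <- residualize(y, covariates) + mean(y)
  adj <- data.frame(group = levels(groups),
                    adjusted_mean = tapply(resid_adj, groups, mean),
                    sd = tapply(resid_adj, groups, sd),
                    n = as.integer(table(groups)))
  rownames(adj) <- NULL
  structure(list(F = an$F[2], p = an$`Pr(>F)`[2],
                 df = c(between = an$Df[2], within = an$Res.Df[2]),
                 adjusted_means = adj),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("ANCOVA omnibus: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p))
  print(x$adjusted_means, row.names = FALSE)
  invisible(x)
}

#' Covariate-adjusted pairwise group contrast (GLM t-test)
#'
#' t statistic for the group indicator in a two-group linear model with
#' covariates; two-sided p. With no covariates this equals the classical
#' pooled-variance two-sample t-test. The sign convention is
#' `mean(first) - mean(second)` for `pair = c(first, second)`.
#'
#' @param y numeric response vector (all subjects).
#' @param groups group labels aligned with `y`.
#' @param pair character vector of the two group labels to compare.
#' @param covariates data.frame of covariates or `NULL`.
#' @return list with `t`, `p`, `df`, `pair`.
#' @export
posthoc_pairwise <- function(y, groups, pair, covariates = NULL) {
  stopifnot(length(pair) == 2)
  keep <- groups %in% pair
  if (sum(groups == pair[1]) < 2 || sum(groups == pair[2]) < 2) {
    stop("both groups need at least 2 subjects")
  }
  yk <- y[keep]
  # indicator = 1 for the first-named group, so t > 0 means first > second
  ind <- as.numeric(groups[keep] == pair[1])
  dat <- data.frame(y = yk, g = ind)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates)[keep, , drop = FALSE])
  covnames <- setdiff(names(dat), c("y", "g"))
  rhs <- if (length(covnames)) paste(c("g", covnames), collapse = " + ") else "g"
  fit <- lm(stats::as.formula(paste("y ~", rhs)), data = dat)
  sm <- summary(fit)$coefficients
  list(t = sm["g", "t value"], p = sm["g", "Pr(>|t|)"],
       df = fit$df.residual, pair = pair)
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure: reject all p-values at or below p_(k) where k is the
#' largest i with p_(i) <= i q / m. Implemented through the standard
#' `p.adjust(method = "BH")` adjusted values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q target false discovery rate in `(0, 1)` (default 0.05).
#' @return logical rejection mask the length of `p`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1), q > 0, q < 1)
  p.adjust(p, method = "BH") <= q
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the two covariate-residualized vectors, with the
#' p-value from the t transform on `n - k - 2` degrees of freedom (`k`
#' covariates). With no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of covariates or `NULL`.
#' @return list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- if (is.null(covariates)) 0 else ncol(as.data.frame(covariates))
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- residualize(x, covariates)
  ry <- residualize(y, covariates)
  # relative tolerance: OLS leaves O(eps) residuals on perfectly fit inputs
  degenerate <- function(r, v) sd(r) < 1e-10 * max(1, abs(mean(v)), sd(v))
  if (degenerate(rx, x) || degenerate(ry, y)) {
    stop("undefined correlation: zero-variance residuals")
  }
  r <- cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' Group comparison of a metrics table
#'
#' Runs the covariate-adjusted omnibus test and all pairwise contrasts for
#' each metric column, with optional BH-FDR correction of the omnibus
#' p-values across metrics (used for nodal metrics, where the correction runs
#' across the 90 regions per metric family).
#'
#' @param metrics data.frame holding `group`, covariate columns and metric
#'   columns.
#' @param metric_cols character vector of metric column names.
#' @param covariate_cols character vector of covariate column names
#'   (default `c("age", "sex", "education")`).
#' @param fdr_q FDR level for the omnibus p-values across `metric_cols`, or
#'   `NULL` for no correction (the convention for a handful of global
#'   metrics).
#' @return data.frame with one row per metric: omnibus F, p, (optional FDR
#'   rejection), and t/p per group pair.
#' @export
compare_metrics <- function(metrics, metric_cols,
                            covariate_cols = c("age", "sex", "education"),
                            fdr_q = NULL) {
  stopifnot(all(metric_cols %in% names(metrics)),
            all(covariate_cols %in% names(metrics)))
  covs <- if (length(covariate_cols)) metrics[covariate_cols] else NULL
  groups <- factor(metrics$group)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  rows <- lapply(metric_cols, function(mc) {
    y <- metrics[[mc]]
    om <- ancova_omnibus(y, groups, covs)
    row <- data.frame(metric = mc, F = om$F, p = om$p,
                      df1 = om$df[["between"]], df2 = om$df[["within"]])
    for (pr in pairs) {
      ph <- posthoc_pairwise(y, groups, pr, covs)
      nm <- paste(pr, collapse = "_vs_")
      row[[paste0("t_", nm)]] <- ph$t
      row[[paste0("p_", nm)]] <- ph$p
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(fdr_q)) out$fdr_significant <- fdr_correct(out$p, fdr_q)
  out
}
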