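#' Two-way ANOVA with partial eta-squared
#'
#' Fits `metric ~ treatment * sex` (or any two crossed factors) by ordinary
#' least squares and tests each term with Type III (marginal) sums of squares
#' under sum-to-zero factor coding — the appropriate decomposition when cell
#' sizes are unbalanced, and the one commercial ANOVA software reports by
#' default. The effect size for each term is partial eta-squared,
#' `SS_term / (SS_term + SS_residual)`.
#'
#' @param data `data.frame` holding the response and both factors.
#' @param metric name of the response column.
#' @param factors character vector of two factor column names
#'   (default `c("treatment", "sex")`).
#' @return `data.frame` of class `syntax_anova` with one row per term
#'   (`factors[1]`, `factors[2]`, interaction): `term`, `df`, `df_residual`,
#'   `F`, `p`, `partial_eta_sq`. Rows with a missing response are dropped
#'   first; an empty factor cell is an error naming the cell; a constant
#'   response yields `NA` statistics with a warning.
#' @export
two_way_anova <- function(data, metric, factors = c("treatment", "sex")) {
  stopifnot(length(factors) == 2L)
  miss <- setdiff(c(metric, factors), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[!is.na(data[[metric]]), c(metric, factors)]
  d[[factors[1L]]] <- factor(d[[factors[1L]]])
  d[[factors[2L]]] <- factor(d[[factors[2L]]])
  cells <- table(d[[factors[1L]]], d[[factors[2L]]])
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: %s = %s, %s = %s",
                 factors[1L], rownames(cells)[empty[1L]],
                 factors[2L], colnames(cells)[empty[2L]]), call. = FALSE)
  }
  term_names <- c(factors, paste(factors, collapse = ":"))
  if (var(d[[metric]]) == 0) {
    warning("constant response '", metric, "': F undefined", call. = FALSE)
    return(anova_frame(term_names, NA, NA, NA, NA, NA))
  }
  fml <- reformulate(paste(factors, collapse = " * "), response = metric)
  ctr <- setNames(rep(list("contr.sum"), 2L), factors)
  fit <- lm(fml, data = d, contrasts = ctr)
  a3 <- car::Anova(fit, type = 3)
  ss <- setNames(a3[["Sum Sq"]], rownames(a3))
  dfs <- setNames(a3[["Df"]], rownames(a3))
  Fs <- setNames(a3[["F value"]], rownames(a3))
  ps <- setNames(a3[["Pr(>F)"]], rownames(a3))
  res <- "Residuals"
  out <- anova_frame(term_names,
                     df = dfs[term_names],
                     df_residual = rep(dfs[res], 3L),
                     F = Fs[term_names],
                     p = ps[term_names],
                     partial_eta_sq = ss[term_names] / (ss[term_names] + ss[res]))
  out
}

anova_frame <- function(terms, df, df_residual, F, p, partial_eta_sq) {
  out <- data.frame(term = terms, df = as.numeric(df),
                    df_residual = as.numeric(df_residual), F = as.numeric(F),
                    p = as.numeric(p),
                    partial_eta_sq = as.numeric(partial_eta_sq),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("syntax_anova", "data.frame")
  out
}

#' @export
print.syntax_anova <- function(x, digits = 4, ...) {
  cat("Two-way ANOVA (Type III SS, sum-to-zero coding)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA table over many metrics
#'
#' Runs [two_way_anova()] for each metric and stacks the results into the
#' familiar one-row-per-metric-and-term summary table.
#'
#' @param data per-bird metrics `data.frame` with `sex` and `treatment`
#'   columns.
#' @param metrics character vector of metric column names (defaults to the
#'   eight diversity metrics plus the two network metrics, where present).
#' @param factors passed to [two_way_anova()].
#' @return `data.frame` with columns `metric`, `term`, `df`, `df_residual`,
#'   `F`, `p`, `partial_eta_sq`.
#' @export
anova_table <- function(data, metrics = NULL, factors = c("treatment", "sex")) {
  if (is.null(metrics))
    metrics <- intersect(c(DIVERSITY_METRICS, NETWORK_METRICS), names(data))
  rows <- lapply(metrics, function(m) {
    a <- two_way_anova(data, m, factors)
    cbind(metric = m, as.data.frame(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3), neither constant.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 complete paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant input", call. = FALSE)
  cor(x, y, method = "pearson")
}

#' Unrotated principal component analysis of standardized metrics
#'
#' Standardizes each variable to mean 0 and standard deviation 1 and
#' eigendecomposes the resulting correlation matrix (via `prcomp`), with no
#' rotation. Components are ordered by decreasing eigenvalue; the eigenvalues
#' sum to the number of variables. Each component's sign is fixed so that its
#' largest-magnitude loading is positive, making loadings reproducible across
#' platforms. Rows with missing values are dropped (and recorded) so that
#' scores stay aligned with complete cases.
#'
#' @param x numeric `data.frame` or matrix, observations in rows, variables
#'   in columns.
#' @return list of class `syntax_pca`: `eigenvalues`,
#'   `proportion_explained` (sums to 1), `cumulative_proportion`, `loadings`
#'   (variable x component), `scores` (row x component, variance equal to the
#'   eigenvalues), `dropped_rows` (row names/indices removed as incomplete).
#' @export
pca_unrotated <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) stop("PCA needs at least 2 variables", call. = FALSE)
  keep <- complete.cases(x)
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < 3L) stop("PCA needs at least 3 complete rows", call. = FALSE)
  sds <- vapply(x, sd, numeric(1))
  if (any(sds == 0))
    stop("constant variable(s): ", paste(names(x)[sds == 0], collapse = ", "),
         call. = FALSE)
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pr$sdev^2
  loadings <- pr$rotation
  scores <- pr$x
  for (j in seq_along(eig)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(eigenvalues = eig,
                 proportion_explained = eig / sum(eig),
                 cumulative_proportion = cumsum(eig) / sum(eig),
                 loadings = loadings, scores = scores,
                 dropped_rows = dropped),
            class = "syntax_pca")
}

#' @export
print.syntax_pca <- function(x, digits = 3, ...) {
  cat(sprintf("Unrotated PCA of %d standardized variables (%d observations",
              nrow(x$loadings), nrow(x$scores)))
  if (length(x$dropped_rows))
    cat(sprintf(", %d incomplete rows dropped", length(x$dropped_rows)))
  cat(")\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               proportion = x$proportion_explained,
               cumulative = x$cumulative_proportion)
  colnames(tab) <- colnames(x$loadings)
  print(round(tab, digits))
  invisible(x)
}

#' Multiple linear regression of a response on morphological predictors
#'
#' Ordinary least squares with intercept, as used to relate principal
#' component scores to vocal-control-nucleus volumes with body mass as a
#' covariate. Reports per-coefficient estimates, standard errors, t and p
#' values, plus the model F test and R-squared.
#'
#' @param data `data.frame` holding response and predictors.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @return list of class `syntax_ols`: `coefficients` (`data.frame` with
#'   `term`, `estimate`, `se`, `t`, `p`; intercept last), `F`, `df`,
#'   `df_residual`, `r_squared`, `p`, `n`, and the underlying `lm` fit.
#' @export
ols_regression <- function(data, response, predictors) {
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[, c(response, predictors), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(predictors) + 2L)
    stop("need at least ", length(predictors) + 2L, " complete rows",
         call. = FALSE)
  fml <- if (length(predictors)) reformulate(predictors, response = response)
         else as.formula(paste(response, "~ 1"))
  fit <- lm(fml, data = d)
  X <- model.matrix(fit)
  if (qr(X)$rank < ncol(X)) {
    al <- alias(fit)$Complete
    stop("rank-deficient design; collinear column(s): ",
         paste(rownames(al), collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)
  ct <- s$coefficients
  ord <- c(setdiff(rownames(ct), "(Intercept)"), "(Intercept)")
  ct <- ct[ord, , drop = FALSE]
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1L], se = ct[, 2L],
                      t = ct[, 3L], p = ct[, 4L], row.names = NULL,
                      stringsAsFactors = FALSE)
  fstat <- s$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  structure(list(coefficients = coefs,
                 F = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
                 df = if (is.null(fstat)) NA_real_ else unname(fstat[2L]),
                 df_residual = fit$df.residual,
                 r_squared = s$r.squared, p = unname(model_p), n = nrow(d),
                 fit = fit),
            class = "syntax_ols")
}

#' @export
print.syntax_ols <- function(x, digits = 3, ...) {
  cat(sprintf("OLS: F(%g, %g) = %.3f, R^2 = %.3f, p = %.3g, n = %d\n",
              x$df, x$df_residual, x$F, x$r_squared, x$p, x$n))
  print.data.frame(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}
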