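# Regression stage: variable transforms, MLR partial correlations, Pearson
# matrices, and principal component regression with a variance decomposition.
# Missing data are handled listwise over the exact variable set of each
# analysis; the significance threshold is 0.05 throughout and no
# multiple-testing correction is applied.

#' Transform a recombination rate for regression
#'
#' `log10(rate + 1)`: reduces the right skew of window recombination rates
#' while keeping 0 at 0.
#'
#' @param rate Rate(s) in cM/Mb (>= 0).
#' @return Transformed value(s).
#' @examples
#' transform_recombination(9)  # 1
#' @export
transform_recombination <- function(rate) {
  if (any(rate < 0, na.rm = TRUE)) stop("recombination rate must be >= 0", call. = FALSE)
  log10(rate + 1)
}

#' Z-transform a vector
#'
#' Standardises to mean 0 and standard deviation 1 (denominator n - 1).
#'
#' @param x Numeric vector with positive variance (`NA`s ignored in the
#'   moments, preserved in the output).
#' @return Standardised vector.
#' @export
z_transform <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("cannot Z-transform a constant vector", call. = FALSE)
  (x - mean(x, na.rm = TRUE)) / s
}

.as_predictor_matrix <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  X
}

#' Multiple linear regression with partial correlations
#'
#' Ordinary least squares of `y` on the columns of `X` (listwise-complete
#' rows). The per-predictor partial correlation is
#' `sign(b) * sqrt(t^2 / (t^2 + df))` with `df = n - p - 1`, which equals the
#' Pearson correlation of the residuals of `y` and of that predictor after
#' regressing both on the remaining predictors; two-sided p-values come from
#' the t distribution.
#'
#' @param X Predictor matrix or data frame (n x p, named columns).
#' @param y Response vector.
#' @return An object of class `mlr_partial`: data frame `partial` (predictor,
#'   partial correlation, p-value), `r.squared`, `n`, and the underlying
#'   [stats::lm()] fit.
#' @export
mlr_partial <- function(X, y) {
  X <- .as_predictor_matrix(X)
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 complete rows", call. = FALSE)
  if (qr(cbind(1, X))$rank < p + 1) {
    stop("rank-deficient predictor matrix (collinear columns: ",
         paste(colnames(X), collapse = ", "), ")", call. = FALSE)
  }
  df <- as.data.frame(X)
  df$.y <- y
  fit <- lm(.y ~ ., data = df)
  sm <- summary(fit)
  tt <- sm$coefficients[-1L, "t value"]
  dof <- n - p - 1
  partial <- sign(tt) * sqrt(tt^2 / (tt^2 + dof))
  pval <- 2 * pt(abs(tt), dof, lower.tail = FALSE)
  structure(list(
    partial = data.frame(predictor = colnames(X), partial_correlation = unname(partial),
                         p_value = unname(pval), stringsAsFactors = FALSE),
    r.squared = sm$r.squared, n = n, fit = fit
  ), class = "mlr_partial")
}

#' @export
print.mlr_partial <- function(x, ...) {
  cat(sprintf("MLR partial correlations (n = %d, R^2 = %.3f)\n", x$n, x$r.squared))
  df <- x$partial
  df$sig <- ifelse(df$p_value < 0.05, "*", "")
  print(df, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson r and two-sided p-values for every column pair, each pair computed
#' on its own complete rows. Constant columns give `NA` for their pairs.
#'
#' @param X Matrix or data frame (>= 3 complete rows per pair).
#' @return List with matrices `r`, `p` and `n` (pairwise sample sizes).
#' @export
pearson_matrix <- function(X) {
  X <- .as_predictor_matrix(X)
  p <- ncol(X)
  r <- pmat <- nmat <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  diag(r) <- 1
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(X[, c(i, j)])
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    if (n < 3 || sd(X[ok, i]) == 0 || sd(X[ok, j]) == 0) next
    ct <- stats::cor.test(X[ok, i], X[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
  }
  list(r = r, p = pmat, n = nmat)
}

#' Principal component regression with variance decomposition
#'
#' Z-transforms the predictors (idempotent if already standardised), extracts
#' principal components of their correlation matrix ordered by eigenvalue,
#' and regresses `y` jointly on all PC scores. Because the scores are
#' orthogonal, the share of response variance carried by each PC equals its
#' squared correlation with `y`, and the shares sum to the R^2 of the
#' full-predictor regression. The contribution of each variable within a PC
#' is its squared loading (summing to 1 per PC). Per-PC p-values are the
#' coefficient t-tests of the joint regression.
#'
#' @param X Predictor matrix or data frame.
#' @param y Response vector.
#' @return An object of class `pcr_fit`: `loadings` (p x p, orthonormal
#'   columns), `eigenvalues`, `variance_share` (per PC, of the response),
#'   `p_value` (per PC), `contribution` (squared loadings), `r.squared`,
#'   `n`.
#' @export
pcr <- function(X, y) {
  X <- .as_predictor_matrix(X)
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need n > p complete rows", call. = FALSE)
  Z <- apply(X, 2, z_transform)
  eg <- eigen(cor(Z), symmetric = TRUE)
  L <- eg$vectors
  # fix signs for reproducibility: largest |loading| positive
  for (k in seq_len(p)) if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  dimnames(L) <- list(colnames(X), paste0("PC", seq_len(p)))
  scores <- Z %*% L
  fit <- lm(y ~ scores)
  sm <- summary(fit)
  share <- as.numeric(cor(y, scores))^2   # orthogonal scores: squared correlations
  pv <- sm$coefficients[-1L, "Pr(>|t|)"]
  structure(list(
    loadings = L,
    eigenvalues = eg$values,
    variance_share = setNames(share, colnames(L)),
    p_value = setNames(unname(pv), colnames(L)),
    contribution = L^2,
    r.squared = sm$r.squared,
    n = n, fit = fit
  ), class = "pcr_fit")
}

#' @export
print.pcr_fit <- function(x, ...) {
  cat(sprintf("Principal component regression (n = %d, total R^2 = %.3f)\n",
              x$n, x$r.squared))
  df <- data.frame(eigenvalue = x$eigenvalues,
                   variance_share = x$variance_share,
                   p_value = x$p_value)
  print(df, digits = 3)
  cat("\nVariable contributions within each PC (squared loadings):\n")
  print(round(x$contribution, 3))
  invisible(x)
}

#' Bar-chart of the PCR variance decomposition
#'
#' One bar per principal component, height = share of response variance,
#' subdivided by the contribution of each predictor within the component.
#'
#' @param x A `pcr_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix (predictors x PCs).
#' @export
plot.pcr_fit <- function(x, ...) {
  m <- x$contribution * rep(x$variance_share, each = nrow(x$contribution))
  graphics::barplot(m, legend.text = rownames(m),
                    ylab = "share of response variance",
                    xlab = "principal component", ...)
  invisible(m)
}
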