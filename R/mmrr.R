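#' Unfold a square symmetric matrix into its lower-triangle vector
#'
#' Returns the strictly-lower-triangle entries in fixed column-major order
#' (`(2,1), (3,1), ..., (n,1), (3,2), ...`), the standard vectorisation used
#' by Mantel-family matrix regression.  Length `n (n - 1) / 2`.
#'
#' @param M Square matrix, symmetric within `tol`.
#' @param tol Symmetry tolerance (default `1e-9`).
#' @return Numeric vector of the `n (n - 1) / 2` off-diagonal pairs.
#' @export
unfold <- function(M, tol = 1e-9) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (max(abs(M - t(M))) > tol)
    stop("matrix is asymmetric beyond tolerance ", tol)
  M[lower.tri(M)]
}

.zscore <- function(v) (v - mean(v)) / stats::sd(v)

#' Multiple matrix regression with randomization (MMRR)
#'
#' Regresses an unfolded dependent distance/similarity matrix on one or more
#' unfolded predictor matrices.  All unfolded vectors are z-scored (mean 0,
#' sd 1 over the pairs), so the coefficients are standardized and comparable
#' across predictors.  Significance is assessed by permutation: the rows and
#' columns of `Y` are permuted \emph{simultaneously} by a random species
#' permutation (the predictors stay fixed), the model is refitted, and each
#' coefficient's p-value is `(#\{|t_perm| >= |t_obs|\} + 1) / (nperm + 1)`;
#' the overall F statistic is treated the same way.  Ties count towards
#' significance-destroying permutations (conservative).
#'
#' @param Y Square symmetric dependent matrix (e.g. symbiont community
#'   similarity), with row/column labels.
#' @param Xs Named list of square symmetric predictor matrices sharing `Y`'s
#'   labels and order.
#' @param nperm Number of permutations (default 9999, giving 4-decimal
#'   p-value granularity; 0 disables inference).
#' @param seed Optional integer seed.
#' @return An object of class `"mmrr"`: `coefficients` data.frame
#'   (`predictor`, `beta`, `t`, `p_perm`), `r2`, `F`, `F_p_perm`, `nperm`,
#'   `seed`, `n_species`, `n_pairs`.
#' @export
mmrr <- function(Y, Xs, nperm = 9999, seed = NULL) {
  stopifnot(is.list(Xs), length(Xs) >= 1L, nperm == 0 || nperm >= 99)
  if (is.null(names(Xs)) || any(!nzchar(names(Xs))))
    names(Xs) <- paste0("X", seq_along(Xs))
  labs <- rownames(Y)
  for (nm in names(Xs)) {
    if (!identical(dim(Xs[[nm]]), dim(Y)))
      stop("predictor '", nm, "' does not match Y's dimensions")
    if (!is.null(labs) && !identical(rownames(Xs[[nm]]), labs))
      stop("predictor '", nm, "' has mismatched species labels")
  }
  n <- nrow(Y)
  y_raw <- unfold(Y)
  X_raw <- vapply(Xs, unfold, numeric(length(y_raw)))
  if (stats::sd(y_raw) == 0) stop("unfolded Y is constant")
  const <- apply(X_raw, 2, stats::sd) == 0
  if (any(const))
    stop("constant unfolded predictor(s): ",
         paste(names(Xs)[const], collapse = ", "))

  y <- .zscore(y_raw)
  X <- cbind(`(Intercept)` = 1, apply(X_raw, 2, .zscore))
  k <- ncol(X)
  npairs <- length(y)
  df <- npairs - k

  XtX_inv <- solve(crossprod(X))
  yty <- sum(y^2)
  fit_t <- function(yv) {
    Xty <- crossprod(X, yv)                   # k x 1
    b <- XtX_inv %*% Xty
    rss <- max(sum(yv^2) - sum(b * Xty), 0)
    se <- sqrt(pmax(diag(XtX_inv) * rss / df, 0))
    t <- as.numeric(b) / se
    t[se == 0] <- sign(as.numeric(b))[se == 0] * Inf
    t[se == 0 & as.numeric(b) == 0] <- 0
    tss <- sum(yv^2)                          # z-scored: mean 0
    r2 <- 1 - rss / tss
    Fv <- if (rss == 0) Inf else (r2 / (k - 1)) / ((1 - r2) / df)
    list(beta = as.numeric(b), t = t, r2 = r2, F = Fv)
  }
  obs <- fit_t(y)

  p_perm <- rep(NA_real_, k)
  F_p <- NA_real_
  if (nperm > 0) {
    if (!is.null(seed)) set.seed(seed)
    ## pair-index bookkeeping: PI[i, j] = position of pair {i, j} in unfold()
    PI <- matrix(0L, n, n)
    PI[lower.tri(PI)] <- seq_len(npairs)
    PI <- PI + t(PI)
    ij <- which(lower.tri(PI), arr.ind = TRUE)  # column-major, unfold order
    ge_t <- numeric(k)
    ge_F <- 0
    for (p in seq_len(nperm)) {
      pm <- sample.int(n)
      yp <- y[PI[cbind(pm[ij[, 1]], pm[ij[, 2]])]]
      per <- fit_t(yp)
      ge_t <- ge_t + (abs(per$t) >= abs(obs$t))
      ge_F <- ge_F + (per$F >= obs$F)
    }
    p_perm <- (ge_t + 1) / (nperm + 1)
    F_p <- (ge_F + 1) / (nperm + 1)
  }

  structure(list(
    coefficients = data.frame(predictor = colnames(X), beta = obs$beta,
                              t = obs$t, p_perm = p_perm,
                              stringsAsFactors = FALSE),
    r2 = obs$r2, F = obs$F, F_p_perm = F_p,
    nperm = nperm, seed = seed, n_species = n, n_pairs = npairs
  ), class = "mmrr")
}

#' Extract one coefficient row from an MMRR fit
#'
#' @param fit An `"mmrr"` object.
#' @param predictor Predictor name as given in `Xs`.
#' @return One-row data.frame (`predictor`, `beta`, `t`, `p_perm`).
#' @export
mmrr_coef <- function(fit, predictor) {
  stopifnot(inherits(fit, "mmrr"))
  row <- fit$coefficients[fit$coefficients$predictor == predictor, ]
  if (nrow(row) == 0L) stop("no such predictor: ", predictor)
  row
}

#' @export
print.mmrr <- function(x, ...) {
  cat("Multiple matrix regression with randomization\n")
  cat(sprintf("  %d species, %d pairs, %d permutations\n",
              x$n_species, x$n_pairs, x$nperm))
  cf <- x$coefficients
  cat(sprintf("  %-18s beta = %8.4f  t = %8.3f  p_perm = %s\n",
              cf$predictor, cf$beta, cf$t,
              ifelse(is.na(cf$p_perm), "NA", sprintf("%.4f", cf$p_perm))),
      sep = "")
  cat(sprintf("  R2 = %.4f, F = %.3f, F p_perm = %s\n", x$r2, x$F,
              ifelse(is.na(x$F_p_perm), "NA", sprintf("%.4f", x$F_p_perm))))
  invisible(x)
}
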