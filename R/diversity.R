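#' Richness, Shannon and Gini-Simpson indices of one count vector
#'
#' With `p_i = count_i / sum(counts)`: richness is the number of nonzero
#' entries, Shannon is `-sum(p_i * log(p_i))` in nats (with `0 log 0 = 0`),
#' and Simpson is the Gini-Simpson index `1 - sum(p_i^2)` ("Simpson" is
#' ambiguous in the literature; the complement form is used here, matching
#' the default of the standard community-ecology tooling).
#'
#' @param counts Non-negative count vector, not all zero.
#' @return Named numeric vector `c(richness, shannon, simpson)`.
#' @export
diversity_indices <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) stop("diversity undefined for an all-zero vector")
  c(richness = as.numeric(vegan::specnumber(counts)),
    shannon  = as.numeric(vegan::diversity(counts, index = "shannon")),
    simpson  = as.numeric(vegan::diversity(counts, index = "simpson")))
}

#' Mean diversity indices under rarefaction by repeated subsampling
#'
#' Draws `reps` subsamples of `depth` individuals without replacement from
#' the community (the expanded multiset of individuals) and returns the mean
#' of each diversity index across draws, removing the effect of unequal
#' sample sizes.  A community with fewer than `depth` individuals is not an
#' error: it is flagged for exclusion (`excluded = TRUE`) so callers can
#' drop and log it.
#'
#' @param counts Non-negative integer count vector.
#' @param depth Rarefaction depth (individuals per draw).  Default 7.
#' @param reps Number of random subsamples.  Default 1000.
#' @param seed Optional integer seed for reproducibility.
#' @return A list: `excluded` (logical), and when not excluded `richness`,
#'   `shannon`, `simpson` (means over draws), their standard deviations
#'   (`sd_richness`, ...), `depth`, `reps`, `n` (community size).
#' @export
rarefy_indices <- function(counts, depth = 7, reps = 1000, seed = NULL) {
  stopifnot(all(counts >= 0), depth >= 1, reps >= 1)
  n <- sum(counts)
  if (n < depth)
    return(list(excluded = TRUE, n = n, depth = depth))
  if (!is.null(seed)) set.seed(seed)
  draws <- matrix(0, nrow = reps, ncol = 3,
                  dimnames = list(NULL, c("richness", "shannon", "simpson")))
  counts <- round(counts)
  for (r in seq_len(reps)) {
    ## rrarefy's "smallest count is > 1" heuristic warning is spurious here:
    ## depth and integerness are validated above
    sub <- suppressWarnings(vegan::rrarefy(counts, depth))
    draws[r, ] <- diversity_indices(as.numeric(sub))
  }
  mu <- colMeans(draws)
  sdv <- apply(draws, 2, stats::sd)
  list(excluded = FALSE,
       richness = mu[["richness"]], shannon = mu[["shannon"]],
       simpson = mu[["simpson"]],
       sd_richness = sdv[["richness"]], sd_shannon = sdv[["shannon"]],
       sd_simpson = sdv[["simpson"]],
       depth = depth, reps = reps, n = n)
}

#' Expected rarefied richness under the hypergeometric model
#'
#' Closed form for the expected number of taxa in a subsample of `depth`
#' individuals drawn without replacement:
#' `sum_i 1 - choose(N - N_i, depth) / choose(N, depth)`.
#'
#' @param counts Non-negative integer count vector with `sum >= depth`.
#' @param depth Subsample size.
#' @return Expected richness.
#' @export
expected_rarefied_richness <- function(counts, depth) {
  N <- sum(counts)
  stopifnot(N >= depth)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Ordinary least squares screen of one diversity response on one predictor
#'
#' Fits `y = a + b x` and reports the single-predictor F test, mirroring a
#' GLM screen of symbiont strain diversity against partner diversity.  The
#' reported R-squared is \emph{adjusted} (`1 - (1 - R2)(n - 1)/(n - 2)`),
#' which can be negative for uninformative predictors.
#'
#' @param x,y Numeric vectors per species (length >= 3, finite).
#' @return A list of class `"linear_fit"`: `slope`, `intercept`,
#'   `r2_adjusted`, `F`, `p`, `n`.
#' @export
fit_diversity_model <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 species with finite values")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  if (stats::var(y) == 0) {
    fit <- list(slope = 0, intercept = y[1],
                r2_adjusted = 1 - (n - 1) / (n - 2), F = 0, p = 1, n = n)
    class(fit) <- "linear_fit"
    return(fit)
  }
  m <- stats::lm(y ~ x)
  s <- summary(m)
  Fv <- unname(s$fstatistic[1])
  fit <- list(slope = unname(stats::coef(m)[2]),
              intercept = unname(stats::coef(m)[1]),
              r2_adjusted = s$adj.r.squared,
              F = Fv,
              p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE),
              n = n)
  class(fit) <- "linear_fit"
  fit
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf(
    "Linear fit (n = %d): slope = %.4f, adj. R2 = %.3f, F = %.3f, p = %.3f\n",
    x$n, x$slope, x$r2_adjusted, x$F, x$p))
  invisible(x)
}

#' Per-species diversity table for a community matrix
#'
#' One row per focal species: sample size, raw indices, and (optionally)
#' rarefied indices.  Species below the rarefaction depth get `NA` rarefied
#' values and `rarefied_excluded = TRUE`.
#'
#' @param M Community matrix (focal species as rows).
#' @param depth,reps,seed Rarefaction controls; `depth = NULL` skips
#'   rarefaction.
#' @return A data.frame.
#' @export
diversity_table <- function(M, depth = 7, reps = 1000, seed = NULL) {
  stopifnot(is.matrix(M))
  rows <- lapply(rownames(M), function(sp) {
    cnt <- M[sp, ]
    idx <- diversity_indices(cnt)
    out <- data.frame(species = sp, n_samples = sum(cnt),
                      richness = idx[["richness"]],
                      shannon = idx[["shannon"]],
                      simpson = idx[["simpson"]],
                      stringsAsFactors = FALSE)
    if (!is.null(depth)) {
      rr <- rarefy_indices(cnt, depth = depth, reps = reps, seed = seed)
      out$rarefied_excluded <- rr$excluded
      out$rarefied_richness <- if (rr$excluded) NA_real_ else rr$richness
      out$rarefied_shannon <- if (rr$excluded) NA_real_ else rr$shannon
      out$rarefied_simpson <- if (rr$excluded) NA_real_ else rr$simpson
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
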