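## Shannon entropy (nats) of a non-negative table with grand total m
.table_entropy <- function(tab, m = sum(tab)) {
  q <- tab[tab > 0] / m
  -sum(q * log(q))
}

## row-major rank of linear (column-major) cell indices of an nr x nc matrix
.row_major_rank <- function(cells, nr, nc) {
  ((cells - 1L) %% nr) * nc + ((cells - 1L) %/% nr) + 1L
}

## Most even integer table with the given marginals, three stages:
## (1) largest-remainder rounding of the independence expectation
##     r_i c_j / m; (2) unit allocations to the admissible cell (row and
##     column still short) with the largest outstanding remainder, ties
##     row-major, until the marginals are restored; (3) entropy-ascending
##     local search over marginal-preserving 2x2 unit shifts
##     (a_ij+1, a_il-1, a_kj-1, a_kl+1), run to a local optimum.  Stage (3)
## is needed because rounding alone can land measurably below the true
## constrained maximum even on tiny tables.
.h2max_table <- function(r, cs) {
  m <- sum(r)
  E <- outer(r, cs) / m
  T <- floor(E)
  rem <- E - T
  rdef <- r - rowSums(T)
  cdef <- cs - colSums(T)
  nr <- length(r); nc <- length(cs)
  while (sum(rdef) > 1e-9) {
    adm <- which(outer(rdef > 1e-9, cdef > 1e-9, "&"))
    best <- adm[order(-rem[adm], .row_major_rank(adm, nr, nc))][1]
    T[best] <- T[best] + 1
    i <- (best - 1L) %% nr + 1L
    j <- (best - 1L) %/% nr + 1L
    rdef[i] <- rdef[i] - 1
    cdef[j] <- cdef[j] - 1
    rem[best] <- rem[best] - 1   # deprioritise a cell already topped up
  }
  ## stage (3): xlogx is separable, so a shift's entropy gain decomposes
  ## over the four touched cells; repeat the best strictly-improving shift
  xlx <- function(a) ifelse(a > 0, a * log(a), 0)
  repeat {
    best_gain <- 1e-12
    best_move <- NULL
    for (i in seq_len(nr)) for (k in seq_len(nr)) {
      if (i == k) next
      for (j in seq_len(nc)) for (l in seq_len(nc)) {
        if (j == l || T[i, l] == 0 || T[k, j] == 0) next
        ## gain in -sum(a log a) from T[i,j]+1, T[i,l]-1, T[k,j]-1, T[k,l]+1
        gain <- (xlx(T[i, j]) + xlx(T[i, l]) + xlx(T[k, j]) + xlx(T[k, l])) -
          (xlx(T[i, j] + 1) + xlx(T[i, l] - 1) +
           xlx(T[k, j] - 1) + xlx(T[k, l] + 1))
        if (gain > best_gain) {
          best_gain <- gain
          best_move <- c(i, j, k, l)
        }
      }
    }
    if (is.null(best_move)) break
    i <- best_move[1]; j <- best_move[2]; k <- best_move[3]; l <- best_move[4]
    T[i, j] <- T[i, j] + 1; T[i, l] <- T[i, l] - 1
    T[k, j] <- T[k, j] - 1; T[k, l] <- T[k, l] + 1
  }
  T
}

## Most concentrated table with the given marginals: repeatedly place
## min(remaining row, remaining column) in the admissible cell where that
## allocation is largest.  Two deterministic tie-break policies are tried --
## plain row-major, and "exact fit first" (prefer cells whose remaining row
## and column totals are closest, so allocations that exhaust both at once
## win) -- and the lower-entropy table is kept.  Works for fractional
## marginals.
.h2min_greedy <- function(r, cs, exact_fit) {
  nr <- length(r); nc <- length(cs)
  T <- matrix(0, nr, nc)
  rr <- r; cc <- cs
  while (sum(rr) > 1e-9) {
    A <- outer(rr, cc, pmin)
    adm <- which(outer(rr > 1e-9, cc > 1e-9, "&"))
    rmr <- .row_major_rank(adm, nr, nc)
    o <- if (exact_fit) {
      D <- abs(outer(rr, cc, "-"))
      order(-A[adm], D[adm], rmr)
    } else {
      order(-A[adm], rmr)
    }
    best <- adm[o][1]
    a <- A[best]
    T[best] <- T[best] + a
    i <- (best - 1L) %% nr + 1L
    j <- (best - 1L) %/% nr + 1L
    rr[i] <- rr[i] - a
    cc[j] <- cc[j] - a
  }
  T
}

.h2min_table <- function(r, cs) {
  A <- .h2min_greedy(r, cs, exact_fit = FALSE)
  B <- .h2min_greedy(r, cs, exact_fit = TRUE)
  if (.table_entropy(B) < .table_entropy(A)) B else A
}

## Exact entropy extremes over all integer tables with the given marginals,
## by dynamic programming over remaining-column-sum states (level-by-level,
## one row at a time).  Finding the constrained entropy minimum is a
## minimum-entropy-coupling problem and NP-hard in general, so exactness is
## only affordable while the state space stays small; callers must check
## .dp_affordable() first and otherwise use the heuristic bounds.
.dp_affordable <- function(r, cs, limit = 2e5) {
  min(prod(r + 1), prod(cs + 1)) <= limit && sum(r) <= 64
}

.dp_extreme_entropy <- function(r, cs) {
  if (prod(r + 1) < prod(cs + 1)) { tmp <- r; r <- cs; cs <- tmp }
  m <- sum(r)
  xlx <- function(a) ifelse(a > 0, a * log(a), 0)
  ## rows of 'comp': every way to split s over length(caps) cells, capped
  row_splits <- function(s, caps) {
    k <- length(caps)
    grid <- list(0:min(s, caps[1]))
    if (k > 1) for (j in 2:k) grid[[j]] <- 0:min(s, caps[j])
    comp <- as.matrix(expand.grid(grid))
    comp[rowSums(comp) == s, , drop = FALSE]
  }
  ## states: named vectors remaining-col-sums -> c(min, max) of sum a*log(a)
  states <- new.env(hash = TRUE)
  assign(paste(cs, collapse = ","), c(0, 0), envir = states)
  for (i in seq_along(r)) {
    nxt <- new.env(hash = TRUE)
    for (key in ls(states)) {
      rem <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
      acc <- get(key, envir = states)
      sp <- row_splits(r[i], rem)
      if (nrow(sp) == 0) next
      contrib <- rowSums(matrix(xlx(sp), nrow = nrow(sp)))
      for (q in seq_len(nrow(sp))) {
        k2 <- paste(rem - sp[q, ], collapse = ",")
        cand <- c(acc[1] + contrib[q], acc[2] + contrib[q])
        old <- nxt[[k2]]
        if (is.null(old)) nxt[[k2]] <- cand
        else nxt[[k2]] <- c(min(old[1], cand[1]), max(old[2], cand[2]))
      }
    }
    states <- nxt
  }
  final <- states[[paste(rep(0L, length(cs)), collapse = ",")]]
  ## max sum a*log(a) <-> min entropy, and vice versa
  c(H2min = log(m) - final[2] / m, H2max = log(m) - final[1] / m)
}

## Entropy bounds for fixed marginals: exact by DP when affordable,
## heuristic tables otherwise.  'integerish' marginals only; fractional
## marginals get the continuous independence optimum and the greedy
## concentration directly in the callers.
.h2_bounds <- function(r, cs) {
  m <- sum(r)
  integerish <- max(abs(c(r, cs) - round(c(r, cs)))) < 1e-9
  if (integerish) {
    ri <- round(r); ci <- round(cs)
    if (.dp_affordable(ri, ci)) return(.dp_extreme_entropy(ri, ci))
    c(H2min = .table_entropy(.h2min_table(ri, ci), m),
      H2max = .table_entropy(.h2max_table(ri, ci), m))
  } else {
    c(H2min = .table_entropy(.h2min_table(r, cs), m),
      H2max = .table_entropy(outer(r, cs) / m, m))
  }
}

#' Entropy components of the H2' network specialisation index
#'
#' H2' measures how specialised a bipartite interaction network is, as the
#' two-dimensional Shannon entropy `H2` of the interaction frequencies
#' rescaled between the least (`H2max`) and most (`H2min`) even tables
#' achievable under the observed row and column totals:
#' `h2prime = (H2max - H2) / (H2max - H2min)`, 1 for perfect specialisation
#' and 0 when the table equals its independence expectation.
#'
#' Finding the marginal-constrained extremes exactly is a minimum-entropy
#' coupling problem (NP-hard in general), so the bounds are computed at two
#' levels.  While the dynamic-programming state space over remaining
#' marginals stays affordable -- small tables -- the extremes are exact.
#' Beyond that the standard heuristics are used: `H2max` by
#' largest-remainder rounding of the independence expectation, unit
#' allocations restoring the marginals, and an entropy-ascending local
#' search over marginal-preserving 2x2 shifts; `H2min` by greedy
#' concentration (always place the largest feasible allocation), run under
#' two deterministic tie-break policies with the better result kept.  For
#' matrices with fractional marginals (e.g. a proportional projection) the
#' continuous optimum `r_i c_j / m` replaces the rounded table.
#'
#' @param M Non-negative interaction matrix with at least 2 rows, 2 columns,
#'   and a grand total of at least 2.
#' @return A list: `H2`, `H2min`, `H2max` (nats) and `h2prime` (clamped to
#'   \[0, 1\]; 0 with a warning when `H2max = H2min`).
#' @export
h2_components <- function(M) {
  stopifnot(is.matrix(M), all(M >= 0))
  if (nrow(M) < 2L || ncol(M) < 2L)
    stop("H2' undefined: need at least 2 rows and 2 columns")
  m <- sum(M)
  if (m < 2) stop("H2' undefined: grand total below 2")
  r <- rowSums(M); cs <- colSums(M)
  H2 <- .table_entropy(M, m)
  bounds <- .h2_bounds(r, cs)
  H2min <- bounds[["H2min"]]
  H2max <- bounds[["H2max"]]
  if (H2max - H2min < 1e-12) {
    warning("H2max equals H2min; returning h2prime = 0")
    h2p <- 0
  } else {
    h2p <- min(max((H2max - H2) / (H2max - H2min), 0), 1)
  }
  list(H2 = H2, H2min = H2min, H2max = H2max, h2prime = h2p)
}

#' One random contingency table with fixed marginals (Patefield null)
#'
#' Draws a table uniformly from the multivariate hypergeometric null that
#' preserves both row and column totals exactly (equivalently: shuffle the
#' `m` column-labelled interaction tokens against the `m` row-labelled ones
#' and tally).  Uses Patefield's algorithm.
#'
#' @param row_sums,col_sums Non-negative integer marginals with equal sums.
#' @param seed Optional integer seed.
#' @return An integer matrix with exactly the given marginals.
#' @export
patefield_sample <- function(row_sums, col_sums, seed = NULL) {
  stopifnot(all(row_sums >= 0), all(col_sums >= 0))
  if (sum(row_sums) != sum(col_sums))
    stop("marginal sums differ: ", sum(row_sums), " vs ", sum(col_sums))
  if (sum(row_sums) == 0) stop("empty marginals")
  if (!is.null(seed)) set.seed(seed)
  ## degenerate shapes are deterministic; r2dtable needs >= 2 of each
  if (length(row_sums) == 1L) return(matrix(round(col_sums), nrow = 1))
  if (length(col_sums) == 1L) return(matrix(round(row_sums), ncol = 1))
  stats::r2dtable(1, round(row_sums), round(col_sums))[[1]]
}

## round a non-negative vector to integers preserving its (integer) total,
## by largest remainder
.round_preserve_sum <- function(x) {
  tot <- round(sum(x))
  f <- floor(x)
  short <- tot - sum(f)
  if (short > 0) {
    bump <- order(-(x - f))[seq_len(short)]
    f[bump] <- f[bump] + 1
  }
  f
}

#' H2' specialisation with a fixed-marginal null model and SES
#'
#' Computes the observed H2' of an interaction matrix and compares it with
#' `n_null` Patefield random tables sharing its marginals, summarising the
#' departure as a standardised effect size
#' `ses = (observed - null mean) / null sd` (sample sd, n - 1).  Because the
#' null preserves the marginals exactly, the entropy bounds `H2min`/`H2max`
#' are shared by every null draw and are computed once.
#'
#' Fractional matrices (e.g. proportional projections) are handled by
#' rounding the marginals to integers with a total-preserving
#' largest-remainder rule before drawing nulls; the observed H2' is still
#' computed from the fractional matrix.
#'
#' @param M Non-negative interaction matrix (see [h2_components()]).
#' @param n_null Number of null randomisations (default 1000).
#' @param seed Optional integer seed.
#' @return An object of class `"h2_ses"`: `H2`, `H2min`, `H2max`,
#'   `h2prime`, `null_mean`, `null_sd`, `ses`, `n_null`, `seed`.
#' @export
h2_ses <- function(M, n_null = 1000, seed = NULL) {
  obs <- h2_components(M)
  r <- .round_preserve_sum(rowSums(M))
  cs <- .round_preserve_sum(colSums(M))
  if (!is.null(seed)) set.seed(seed)
  tabs <- stats::r2dtable(n_null, r, cs)
  m <- sum(r)
  bounds <- .h2_bounds(r, cs)
  H2min_n <- bounds[["H2min"]]
  H2max_n <- bounds[["H2max"]]
  denom <- H2max_n - H2min_n
  null_h2p <- vapply(tabs, function(tb) {
    if (denom < 1e-12) return(0)
    min(max((H2max_n - .table_entropy(tb, m)) / denom, 0), 1)
  }, numeric(1))
  null_mean <- mean(null_h2p)
  null_sd <- stats::sd(null_h2p)
  ses <- if (null_sd > 0) (obs$h2prime - null_mean) / null_sd else {
    warning("null distribution has zero spread; SES undefined")
    NA_real_
  }
  structure(list(H2 = obs$H2, H2min = obs$H2min, H2max = obs$H2max,
                 h2prime = obs$h2prime, null_mean = null_mean,
                 null_sd = null_sd, ses = ses, n_null = n_null, seed = seed),
            class = "h2_ses")
}

#' @export
print.h2_ses <- function(x, ...) {
  cat(sprintf(
    "H2' specialisation: h2prime = %.4f (H2 = %.4f in [%.4f, %.4f])\n",
    x$h2prime, x$H2, x$H2min, x$H2max))
  cat(sprintf("  null (n = %d): mean = %.4f, sd = %.5f, SES = %s\n",
              x$n_null, x$null_mean, x$null_sd,
              ifelse(is.na(x$ses), "NA", sprintf("%.1f", x$ses))))
  invisible(x)
}

#' Project a parasitoid-symbiont network through shared aphid hosts
#'
#' Assigns the symbiont "individuals" observed in each aphid species to the
#' parasitoids attacking that species, proportionally to attack frequency:
#' `B[p, s] = sum_a S[a, s] * A[a, p] / sum_p' A[a, p']`.  Fractional
#' weights are retained, and the total symbiont count over retained aphids
#' is conserved.
#'
#' @param A Aphid x parasitoid count matrix.
#' @param S Aphid x strain count matrix (rows matched to `A` by name).
#' @return Parasitoid x strain weighted matrix; attribute `dropped_aphids`
#'   lists aphids without parasitoid records (dropped with a message).
#' @export
project_parasitoid_symbiont <- function(A, S) {
  stopifnot(is.matrix(A), is.matrix(S))
  common <- intersect(rownames(A), rownames(S))
  usable <- common[rowSums(A[common, , drop = FALSE]) > 0 &
                   rowSums(S[common, , drop = FALSE]) > 0]
  dropped <- setdiff(union(rownames(A), rownames(S)), usable)
  if (length(usable) == 0L)
    stop("no aphid species with both parasitoid and strain records")
  if (length(dropped))
    message("projection dropped ", length(dropped),
            " aphid(s) without both record types: ",
            paste(.lex_sort(dropped), collapse = ", "))
  Au <- A[usable, , drop = FALSE]
  Su <- S[usable, , drop = FALSE]
  W <- Au / rowSums(Au)
  B <- t(W) %*% Su
  attr(B, "dropped_aphids") <- .lex_sort(dropped)
  B
}

#' Summarise pairwise sharing of symbiont strains and ecological partners
#'
#' Enumerates all unordered pairs of focal species and asks, for each pair,
#' whether they share any symbiont strain (strain community similarity
#' greater than 0) and whether they overlap in partner (parasitoid or plant)
#' use (partner similarity greater than `threshold`).  Also reports
#' species-level linkage (among species that share strains with at least one
#' other species, how many also share a partner with at least one of their
#' strain-sharing counterparts) and, when `strain_counts` is supplied,
#' strain-level spread (strains observed in more than one species).
#'
#' @param sim_strain Symbiont community similarity matrix.
#' @param sim_partner Partner community similarity matrix over the same
#'   species labels.
#' @param threshold Partner-similarity threshold for "sharing" (default 0,
#'   i.e. any overlap; raise to highlight strong overlaps).
#' @param strain_counts Optional aphid x strain count matrix for the spread
#'   summary.
#' @return An object of class `"pair_summary"`: `pairs` (one row per
#'   unordered pair) and `summary` (aggregate counts and percentages).
#' @export
shared_pair_summary <- function(sim_strain, sim_partner, threshold = 0,
                                strain_counts = NULL) {
  if (!identical(rownames(sim_strain), rownames(sim_partner)))
    stop("similarity matrices have mismatched species labels")
  sp <- rownames(sim_strain)
  n <- length(sp)
  stopifnot(n >= 2L)
  idx <- utils::combn(n, 2)
  pairs <- data.frame(
    species1 = sp[idx[1, ]], species2 = sp[idx[2, ]],
    strain_similarity = sim_strain[t(idx)],
    partner_similarity = sim_partner[t(idx)],
    stringsAsFactors = FALSE)
  pairs$shares_strain <- pairs$strain_similarity > 0
  pairs$shares_partner <- pairs$partner_similarity > threshold

  n_share_strain <- sum(pairs$shares_strain)
  n_both <- sum(pairs$shares_strain & pairs$shares_partner)
  sharing_sp <- unique(c(pairs$species1[pairs$shares_strain],
                         pairs$species2[pairs$shares_strain]))
  linked <- vapply(sharing_sp, function(s) {
    rows <- pairs$shares_strain &
      (pairs$species1 == s | pairs$species2 == s)
    any(pairs$shares_partner[rows])
  }, logical(1))

  summary <- list(
    n_pairs = ncol(idx),
    n_pairs_sharing_strain = n_share_strain,
    n_pairs_sharing_both = n_both,
    pct_pairs_sharing_both = if (n_share_strain > 0)
      100 * n_both / n_share_strain else NA_real_,
    n_species_sharing_strain = length(sharing_sp),
    n_species_linked_by_partner = sum(linked),
    pct_species_linked_by_partner = if (length(sharing_sp) > 0)
      100 * sum(linked) / length(sharing_sp) else NA_real_,
    threshold = threshold)
  if (!is.null(strain_counts)) {
    spread <- colSums(strain_counts > 0) > 1
    summary$n_strains <- ncol(strain_counts)
    summary$n_strains_multi_species <- sum(spread)
    summary$pct_strains_multi_species <- 100 * mean(spread)
  }
  structure(list(pairs = pairs, summary = summary), class = "pair_summary")
}

#' @export
print.pair_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Pairwise sharing over %d species pairs:\n", s$n_pairs))
  cat(sprintf("  strain-sharing pairs: %d\n", s$n_pairs_sharing_strain))
  cat(sprintf("  of those, sharing partner use (> %.2f): %d (%.1f%%)\n",
              s$threshold, s$n_pairs_sharing_both, s$pct_pairs_sharing_both))
  cat(sprintf("  species linked via shared partner: %d of %d (%.1f%%)\n",
              s$n_species_linked_by_partner, s$n_species_sharing_strain,
              s$pct_species_linked_by_partner))
  if (!is.null(s$n_strains))
    cat(sprintf("  strains in >1 species: %d of %d (%.1f%%)\n",
                s$n_strains_multi_species, s$n_strains,
                s$pct_strains_multi_species))
  invisible(x)
}

#' Export a weighted bipartite matrix as an edge list
#'
#' @param B Weighted matrix (e.g. from [project_parasitoid_symbiont()]).
#' @param drop_zero Drop zero-weight edges (default `TRUE`).
#' @return data.frame with `source`, `target`, `weight`.
#' @export
edge_list <- function(B, drop_zero = TRUE) {
  df <- data.frame(
    source = rep(rownames(B), times = ncol(B)),
    target = rep(colnames(B), each = nrow(B)),
    weight = as.vector(B),
    stringsAsFactors = FALSE)
  if (drop_zero) df <- df[df$weight > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
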