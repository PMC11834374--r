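# Independent oracles and small fixtures shared across the suite.
# Everything here is deliberately brute-force / closed-form, written without
# reference to the package internals it checks.

# --- fixed-marginal table enumeration ---------------------------------------

# All integer tables with the given row/column sums, as a list of matrices.
# Literal recursive generation, no memoisation: the reference for every
# entropy-bound check.
enumerate_tables <- function(r, cs) {
  nr <- length(r)
  row_options <- function(s, caps) {
    k <- length(caps)
    if (k == 1L) return(if (s <= caps[1]) list(s) else list())
    out <- list()
    for (v in 0:min(s, caps[1]))
      for (rest in row_options(s - v, caps[-1]))
        out[[length(out) + 1L]] <- c(v, rest)
    out
  }
  rec <- function(i, rem, acc) {
    if (i > nr) return(list(do.call(rbind, acc)))
    out <- list()
    for (row in row_options(r[i], rem))
      out <- c(out, rec(i + 1L, rem - row, c(acc, list(row))))
    out
  }
  rec(1L, cs, list())
}

shannon_entropy <- function(tab) {
  m <- sum(tab)
  q <- tab[tab > 0] / m
  -sum(q * log(q))
}

# Exact (min, max) entropy over all fixed-marginal tables, by recursive
# search with memoisation on the remaining column sums.  Independent of the
# package's level-by-level implementation.
extreme_entropy_oracle <- function(r, cs) {
  memo <- new.env(hash = TRUE)
  nlogn <- function(a) sum(a[a > 0] * log(a[a > 0]))
  row_options <- function(s, caps) {
    k <- length(caps)
    if (k == 1L) return(if (s <= caps[1]) list(s) else list())
    out <- list()
    for (v in 0:min(s, caps[1]))
      for (rest in row_options(s - v, caps[-1]))
        out[[length(out) + 1L]] <- c(v, rest)
    out
  }
  rec <- function(i, rem) {
    if (i > length(r)) return(c(0, 0))
    key <- paste(i, paste(rem, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- c(Inf, -Inf)
    for (row in row_options(r[i], rem)) {
      sub <- rec(i + 1L, rem - row)
      if (!is.finite(sub[1])) next
      v <- nlogn(row)
      best[1] <- min(best[1], v + sub[1])
      best[2] <- max(best[2], v + sub[2])
    }
    memo[[key]] <- best
    best
  }
  res <- rec(1L, cs)
  m <- sum(r)
  c(Hmin = log(m) - res[2] / m, Hmax = log(m) - res[1] / m)
}

# Integer partitions of m into kmin..kmax positive parts (non-increasing).
partitions_between <- function(m, kmin, kmax) {
  rec <- function(m, k, maxp) {
    if (m == 0) return(list(integer()))
    if (k == 0) return(list())
    out <- list()
    for (p in min(m, maxp):1)
      for (rest in rec(m - p, k - 1L, p))
        out[[length(out) + 1L]] <- c(p, rest)
    out
  }
  Filter(function(x) length(x) >= kmin, rec(m, kmax, m))
}

# A feasible table with the given marginals (north-west corner rule).
nw_corner_table <- function(r, cs) {
  T <- matrix(0, length(r), length(cs))
  rr <- r; cc <- cs; i <- 1L; j <- 1L
  while (i <= length(r) && j <= length(cs)) {
    a <- min(rr[i], cc[j])
    T[i, j] <- a; rr[i] <- rr[i] - a; cc[j] <- cc[j] - a
    if (rr[i] == 0) i <- i + 1L else j <- j + 1L
  }
  T
}

# --- random symmetric matrices for matrix-regression checks ----------------

random_sym_matrix <- function(n, labels = sprintf("s%02d", seq_len(n))) {
  M <- matrix(stats::runif(n * n), n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(labels, labels)
  M
}

# OLS via lm() on z-scored unfolded vectors: the reference for mmrr().
mmrr_lm_oracle <- function(Y, Xs) {
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  y <- zs(Y[lower.tri(Y)])
  X <- vapply(Xs, function(M) zs(M[lower.tri(M)]), numeric(length(y)))
  df <- as.data.frame(X)
  fit <- stats::lm(y ~ ., data = df)
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)), t = unname(s$coefficients[, "t value"]),
       r2 = s$r.squared)
}

# --- observation-table fixture ---------------------------------------------

toy_observations <- function() {
  as_observations(data.frame(
    sample_id = sprintf("s%02d", 1:10),
    year = 2021L,
    location = "L01",
    aphid_species = c("aphA", "aphA", "aphA", "aphB", "aphB",
                      "aphC", "aphC", "aphC", "aphD", "aphD"),
    plant_species = c("p1", "p1", "p2", "p2", "p2",
                      "p3", "p3", "p3", "p1", "p1"),
    parasitoid_species = c("w1", "w1", "w2", "w2", NA,
                           "w3", "No Association", "w3", "w1", "w2"),
    strain_id = c("ST1", "ST1", "ST2", "ST2", "ST1",
                  "ST3", "ST3", NA, "No Association", "ST1"),
    source = c(rep("mummy", 4), "live", "mummy", "live", "mummy",
               "live", "mummy"),
    stringsAsFactors = FALSE))
}

write_temp_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}
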