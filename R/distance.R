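#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`: 0 for identical
#' compositions, 1 for completely disjoint ones.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0), all(y >= 0))
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("Bray-Curtis undefined: both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Pairwise community similarity (1 - Bray-Curtis) over matrix rows
#'
#' For network interpretation the Bray-Curtis dissimilarities between the
#' partner-count profiles of each pair of focal species are converted to
#' similarities, `1 - BC`, where 1 is most similar and 0 is no shared
#' partner use.
#'
#' @param M Community matrix (focal species as rows) with at least 2 rows.
#' @param normalize If `TRUE`, rows are first scaled to relative abundances
#'   (row sum 1), removing differences in sampling effort.  Default `FALSE`
#'   (raw counts).
#' @return Square symmetric similarity matrix with unit diagonal.
#' @export
community_similarity <- function(M, normalize = FALSE) {
  stopifnot(is.matrix(M), nrow(M) >= 2L)
  zero <- rowSums(M) == 0
  if (any(zero))
    stop("all-zero row(s) in community matrix: ",
         paste(rownames(M)[zero], collapse = ", "))
  if (normalize) M <- M / rowSums(M)
  S <- 1 - as.matrix(vegan::vegdist(M, method = "bray"))
  diag(S) <- 1
  S
}

#' Pairwise gene distance between species representative sequences
#'
#' `d(i, j)` is the number of compared alignment positions at which the
#' representative sequences of species `i` and `j` differ.  With
#' `gap_mode = "pairwise_deletion"` (default) positions where either
#' sequence carries `-` or `N` are excluded for that pair.  This site-count
#' distance grows with divergence and is the package's raw "relatedness"
#' currency; see [relatedness_transform()] for sign/scale conversions.
#'
#' @param seqs Named character vector (or `DNAbin`) of aligned sequences.
#' @param one_per_species Named character vector: species -> sequence id
#'   (e.g. from [choose_representatives()]).
#' @param gap_mode `"pairwise_deletion"` or `"count_gaps"`.
#' @return Square symmetric integer matrix over species (units: sites).
#' @export
gene_distance_matrix <- function(seqs, one_per_species,
                                 gap_mode = c("pairwise_deletion",
                                              "count_gaps")) {
  gap_mode <- match.arg(gap_mode)
  seqs <- .as_seq_vector(seqs)
  missing_rep <- setdiff(names(one_per_species), character(0))[
    !(one_per_species %in% names(seqs))]
  if (length(missing_rep))
    stop("species without representative sequence: ",
         paste(missing_rep, collapse = ", "))
  species <- .lex_sort(names(one_per_species))
  reps <- seqs[one_per_species[species]]
  .check_aligned(reps)
  chars <- do.call(rbind, strsplit(reps, ""))
  rownames(chars) <- species
  if (gap_mode == "pairwise_deletion") chars[chars %in% c("-", "N")] <- NA
  D <- as.matrix(ape::dist.gene(chars, method = "pairwise",
                                pairwise.deletion =
                                  gap_mode == "pairwise_deletion"))
  D <- D[species, species]
  diag(D) <- 0
  D
}

#' Convert a distance matrix into an MMRR predictor
#'
#' A site-count gene distance grows with \emph{un}relatedness, so the sign
#' of a regression coefficient depends on how the matrix enters the model.
#' Three conventions are supported and the chosen one is recorded on the
#' result so downstream reports can name it:
#' \describe{
#'   \item{`raw_distance`}{identity pass-through; coefficients then refer to
#'     phylogenetic \emph{distance}.}
#'   \item{`one_minus_scaled`}{`1 - D / max(D)`: a similarity in \[0, 1\].}
#'   \item{`negated_z`}{`-(D - mean) / sd` over off-diagonal entries: a
#'     standardized relatedness (mean 0, sd 1 off-diagonal).}
#' }
#'
#' @param D Square symmetric distance matrix (zero diagonal).
#' @param mode One of `"raw_distance"`, `"one_minus_scaled"`, `"negated_z"`.
#' @return Transformed matrix with attribute `relatedness_mode`.
#' @export
relatedness_transform <- function(D, mode = c("raw_distance",
                                              "one_minus_scaled",
                                              "negated_z")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  out <- switch(mode,
    raw_distance = D,
    one_minus_scaled = {
      mx <- max(D)
      if (mx == 0) {
        warning("max(D) = 0: one_minus_scaled yields an all-ones matrix")
        array(1, dim(D), dimnames(D))
      } else {
        S <- 1 - D / mx
        diag(S) <- 1
        S
      }
    },
    negated_z = {
      off <- D[lower.tri(D)]
      Z <- -(D - mean(off)) / stats::sd(off)
      diag(Z) <- 0
      Z
    })
  attr(out, "relatedness_mode") <- mode
  out
}

#' Write a labelled square matrix as CSV
#'
#' @param M Matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.csv(as.data.frame(M), path)
  invisible(path)
}

#' Read a labelled square matrix from CSV, validating symmetry
#'
#' @param path CSV written by [write_matrix_csv()] (first column = row
#'   labels).
#' @param tol Symmetry tolerance.
#' @return A square symmetric matrix.
#' @export
read_matrix_csv <- function(path, tol = 1e-9) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M)))
    stop("not a labelled square matrix: ", path)
  if (max(abs(M - t(M))) > tol)
    stop("matrix is not symmetric within tolerance ", tol, ": ", path)
  M
}
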