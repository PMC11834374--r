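.as_seq_vector <- function(seqs) {
  if (inherits(seqs, "DNAbin")) {
    seqs <- vapply(as.character(as.list(seqs)),
                   function(s) paste(s, collapse = ""), character(1))
  }
  stopifnot(is.character(seqs))
  if (length(seqs) == 0L) return(character())
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  toupper(seqs)
}

.check_aligned <- function(seqs) {
  if (length(unique(nchar(seqs))) > 1L)
    stop("sequences are not aligned: unequal lengths")
  invisible(seqs)
}

#' Read aligned sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  .as_seq_vector(ape::read.FASTA(path))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @export
write_sequences <- function(seqs, path) {
  seqs <- .as_seq_vector(seqs)
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Fraction of identical positions between two aligned sequences
#'
#' With `gap_mode = "pairwise_deletion"` (default) any position where either
#' sequence carries a gap (`-`) or an ambiguous base (`N`) is excluded from
#' both numerator and denominator.  With `"count_gaps"` every position is
#' compared and any position involving `-`/`N` counts as a mismatch.
#'
#' @param a,b Aligned sequences (equal-length character strings).
#' @param gap_mode `"pairwise_deletion"` or `"count_gaps"`.
#' @return Identity as a fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b,
                              gap_mode = c("pairwise_deletion", "count_gaps")) {
  gap_mode <- match.arg(gap_mode)
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  if (length(A) != length(B))
    stop("sequences have unequal lengths (", length(A), " vs ", length(B), ")")
  amb <- c("-", "N")
  if (gap_mode == "pairwise_deletion") {
    keep <- !(A %in% amb | B %in% amb)
    if (!any(keep)) stop("no comparable positions after pairwise deletion")
    mean(A[keep] == B[keep])
  } else {
    if (length(A) == 0L) stop("no comparable positions")
    mean(A == B & !(A %in% amb))
  }
}

#' Greedy centroid clustering of aligned sequences into OTUs
#'
#' Sequences are processed in order of decreasing abundance, ties broken by
#' ascending id (byte order).  Each sequence joins the first existing OTU
#' whose \emph{representative} (founder) it matches with identity strictly
#' greater than `threshold`; otherwise it founds a new OTU with itself as
#' representative.  Deterministic given the input.
#'
#' @param seqs Named character vector (or `DNAbin`) of aligned sequences.
#' @param threshold Identity threshold in (0, 1); membership requires
#'   identity `> threshold`.  Default 0.99 ("over 99% similarity").
#' @param abundance Optional named numeric vector of per-sequence abundances;
#'   defaults to 1 for every sequence.
#' @param gap_mode Passed to [pairwise_identity()].
#' @return A list of class `"otu_assignment"`: `otu` (named character vector
#'   id -> OTU label), `representatives` (OTU label -> sequence id),
#'   `threshold`.
#' @export
cluster_otus <- function(seqs, threshold = 0.99, abundance = NULL,
                         gap_mode = "pairwise_deletion") {
  seqs <- .as_seq_vector(seqs)
  stopifnot(threshold > 0, threshold < 1)
  if (length(seqs) == 0L)
    return(structure(list(otu = character(), representatives = character(),
                          threshold = threshold), class = "otu_assignment"))
  .check_aligned(seqs)
  if (is.null(abundance)) abundance <- stats::setNames(
    rep(1, length(seqs)), names(seqs))
  ids <- names(seqs)
  ord <- order(-abundance[ids], ids, method = "radix")
  ids <- ids[ord]

  reps <- character()   # OTU label -> representative id
  otu <- stats::setNames(character(length(seqs)), names(seqs))
  for (id in ids) {
    hit <- NA_character_
    for (lab in names(reps)) {
      if (pairwise_identity(seqs[[id]], seqs[[reps[[lab]]]],
                            gap_mode = gap_mode) > threshold) {
        hit <- lab
        break
      }
    }
    if (is.na(hit)) {
      hit <- sprintf("OTU%d", length(reps) + 1L)
      reps[[hit]] <- id
    }
    otu[[id]] <- hit
  }
  structure(list(otu = otu, representatives = reps, threshold = threshold),
            class = "otu_assignment")
}

#' Assign strain labels from concatenated MLST haplotypes
#'
#' Each distinct concatenated multilocus haplotype is its own strain
#' (exact-sequence equivalence classes, i.e. clustering at identity 1).
#' Labels are deterministic: ids are sorted, and strains are numbered by the
#' first occurrence of each distinct sequence along that order.
#'
#' @param mlst Named character vector (or `DNAbin`) of aligned, concatenated
#'   haplotypes; unequal lengths signal a concatenation mismatch and are an
#'   error.
#' @return Named character vector mapping each input id to a strain label.
#' @export
assign_strains <- function(mlst) {
  mlst <- .as_seq_vector(mlst)
  if (length(mlst) == 0L) return(character())
  if (length(unique(nchar(mlst))) > 1L)
    stop("concatenation mismatch: haplotypes have unequal lengths")
  ids <- .lex_sort(names(mlst))
  first <- !duplicated(mlst[ids])
  labels <- stats::setNames(sprintf("ST%02d", seq_len(sum(first))),
                            mlst[ids][first])
  stats::setNames(labels[mlst[ids]], ids)
}

#' Pick one representative sequence per species
#'
#' The representative haplotype of a species is its most abundant exact
#' haplotype; ties are broken by the lexicographically smallest sequence,
#' then the smallest sequence id.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param species Named character vector mapping sequence id -> species.
#' @return Named character vector: species -> representative sequence id.
#' @export
choose_representatives <- function(seqs, species) {
  seqs <- .as_seq_vector(seqs)
  stopifnot(all(names(seqs) %in% names(species)))
  sp <- species[names(seqs)]
  out <- vapply(.lex_sort(unique(sp)), function(s) {
    ids <- names(seqs)[sp == s]
    hap <- seqs[ids]
    cnt <- table(hap)
    best_hap <- .lex_sort(names(cnt)[cnt == max(cnt)])[1]
    .lex_sort(ids[hap == best_hap])[1]
  }, character(1))
  out
}
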