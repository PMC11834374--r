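#' Sentinel for screened-but-negative partner records
#'
#' Field samples that were screened for a parasitoid or a symbiont and found
#' without one are scored `"No Association"`.  This is distinct from a missing
#' value (`NA`), which means the sample was never screened for that partner.
#'
#' @format A length-one character constant.
#' @export
NO_ASSOCIATION <- "No Association"

.obs_fields <- c("sample_id", "year", "location", "aphid_species",
                 "plant_species", "parasitoid_species", "strain_id", "source")

.partner_column <- function(partner_kind) {
  partner_kind <- match.arg(partner_kind, c("parasitoid", "plant", "strain"))
  c(parasitoid = "parasitoid_species",
    plant      = "plant_species",
    strain     = "strain_id")[[partner_kind]]
}

## locale-independent lexicographic sort, so outputs are byte-stable
.lex_sort <- function(x) sort(x, method = "radix")

.blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Read a long-format observation table
#'
#' Reads one row per sampled aphid individual from a delimited text file and
#' validates it.  Column names are matched case-insensitively against the
#' canonical field names (`sample_id`, `year`, `location`, `aphid_species`,
#' `plant_species`, `parasitoid_species`, `strain_id`, `source`); a
#' `column_map` can rename arbitrary file headers onto those fields.
#' Partner fields may carry the [NO_ASSOCIATION] sentinel, meaning the sample
#' was screened and no partner was found, which is kept distinct from `NA`
#' (not screened).
#'
#' Rows whose mandatory fields cannot be parsed (empty `aphid_species`, or no
#' partner information at all) are rejected with their row numbers reported
#' in a warning and in the table's provenance attribute.
#'
#' @param path Path to a CSV or TSV file.  The delimiter is auto-detected
#'   from the header line unless `delimiter` is given.
#' @param delimiter Optional field delimiter, e.g. `","` or `"\t"`.
#' @param column_map Optional named character vector mapping canonical field
#'   names to the column names used in the file, e.g.
#'   `c(aphid_species = "Aphid")`.
#' @return A `data.frame` of class `"obs_table"` with the canonical columns,
#'   and attributes `provenance` (file, delimiter, rejected row numbers).
#' @export
read_observations <- function(path, delimiter = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delimiter)) delimiter <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character")
  nms <- names(raw)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), nms)
    if (length(bad))
      stop("column_map refers to columns absent from the file: ",
           paste(bad, collapse = ", "))
    for (canon in names(column_map)) nms[nms == column_map[[canon]]] <- canon
  }
  names(raw) <- tolower(nms)

  mandatory <- c("sample_id", "aphid_species")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("configuration error: mandatory column(s) missing: ",
         paste(missing_cols, collapse = ", "))

  tab <- as.data.frame(
    lapply(stats::setNames(.obs_fields, .obs_fields), function(f) {
      if (f %in% names(raw)) .blank_to_na(raw[[f]]) else
        rep(NA_character_, nrow(raw))
    }),
    stringsAsFactors = FALSE
  )
  tab$year <- suppressWarnings(as.integer(tab$year))

  as_observations(tab, provenance = list(path = path, delimiter = delimiter))
}

#' Validate a data frame of observation records
#'
#' Applies the record- and table-level invariants to an in-memory data frame:
#' unique `sample_id`, non-empty `aphid_species`, and at least one of
#' `plant_species`, `parasitoid_species`, `strain_id` present per record.
#' Rows violating record-level invariants are rejected (with row numbers);
#' duplicated sample ids are an error.
#'
#' @param x A data.frame carrying at least `sample_id` and `aphid_species`.
#' @param provenance Optional list of free-text metadata kept with the table.
#' @return An `"obs_table"` data.frame.
#' @export
as_observations <- function(x, provenance = list()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (f in setdiff(.obs_fields, names(x))) x[[f]] <- NA_character_
  x <- x[.obs_fields]
  for (f in setdiff(.obs_fields, "year")) x[[f]] <- .blank_to_na(x[[f]])
  x$year <- suppressWarnings(as.integer(x$year))

  has_partner <- !is.na(x$plant_species) | !is.na(x$parasitoid_species) |
    !is.na(x$strain_id)
  bad <- which(is.na(x$sample_id) | is.na(x$aphid_species) | !has_partner)
  if (length(bad)) {
    warning("rejected ", length(bad), " record(s) violating invariants ",
            "(rows: ", paste(bad, collapse = ", "), ")")
    x <- x[-bad, , drop = FALSE]
  }
  dup <- unique(x$sample_id[duplicated(x$sample_id)])
  if (length(dup))
    stop("validation error: duplicate sample_id value(s): ",
         paste(dup, collapse = ", "))
  rownames(x) <- NULL
  provenance$rejected_rows <- bad
  attr(x, "provenance") <- provenance
  class(x) <- c("obs_table", "data.frame")
  x
}

#' Filter observation records for a downstream analysis
#'
#' Two removal rules, applied in this order:
#' \enumerate{
#'   \item records scored [NO_ASSOCIATION] (or unscreened, `NA`) for the
#'     partner of the downstream analysis (`partner_kind`), if one is given;
#'   \item \emph{transient associations}: records whose (aphid, plant) pair
#'     occurs exactly once across the table and whose plant is not listed as
#'     a recognised host for that aphid in `host_list`.
#' }
#' Sentinel removal runs first so that the function is idempotent: the
#' singleton rule is evaluated on the table actually carried forward, and
#' removing a whole singleton pair never creates new singletons.
#'
#' @param table An `"obs_table"`.
#' @param partner_kind Optional; one of `"parasitoid"`, `"plant"`,
#'   `"strain"`.  When given, records without that partner are removed.
#' @param host_list Optional named list: aphid species -> character vector of
#'   recognised host plants.  Singleton (aphid, plant) records on a
#'   recognised host are kept.
#' @return The filtered `"obs_table"`; attribute `removal_log` holds a
#'   character vector describing every removal.
#' @export
filter_observations <- function(table, partner_kind = NULL, host_list = NULL) {
  stopifnot(inherits(table, "obs_table"))
  log <- character()

  if (!is.null(partner_kind)) {
    col <- .partner_column(partner_kind)
    drop <- is.na(table[[col]]) | table[[col]] == NO_ASSOCIATION
    if (any(drop)) {
      log <- c(log, sprintf(
        "removed %d record(s) without a %s partner ('%s' or unscreened)",
        sum(drop), partner_kind, NO_ASSOCIATION))
      table <- table[!drop, , drop = FALSE]
    }
  }

  has_plant <- !is.na(table$plant_species)
  key <- paste(table$aphid_species, table$plant_species, sep = "\r")
  n_pair <- table(key[has_plant])
  singleton <- has_plant & n_pair[key] == 1L
  if (!is.null(host_list)) {
    recognised <- mapply(function(a, p) {
      !is.na(p) && a %in% names(host_list) && p %in% host_list[[a]]
    }, table$aphid_species, table$plant_species, USE.NAMES = FALSE)
    singleton <- singleton & !recognised
  }
  singleton[is.na(singleton)] <- FALSE
  if (any(singleton)) {
    pairs <- unique(paste0("(", table$aphid_species[singleton], ", ",
                           table$plant_species[singleton], ")"))
    log <- c(log, sprintf(
      "removed %d transient record(s): singleton (aphid,plant) pair(s) %s",
      sum(singleton), paste(pairs, collapse = "; ")))
    table <- table[!singleton, , drop = FALSE]
  }

  if (nrow(table) == 0L)
    warning("all records removed by filtering", call. = FALSE)
  rownames(table) <- NULL
  attr(table, "removal_log") <- log
  table
}

#' Build a focal-species by partner-taxon count matrix
#'
#' Tallies filtered observation records into a community matrix:
#' `counts[i, j]` is the number of records pairing aphid species `i` with
#' partner taxon `j`.  Rows and columns are sorted lexicographically
#' (byte order), so the output is stable across runs and locales.
#'
#' @param table An `"obs_table"`, already filtered for `partner_kind`.
#' @param partner_kind One of `"parasitoid"`, `"plant"`, `"strain"`.
#' @return An integer matrix with aphid species as rows and partner taxa as
#'   columns; attribute `partner_kind` records the partner type.
#' @export
build_community_matrix <- function(table, partner_kind) {
  stopifnot(inherits(table, "obs_table"))
  col <- .partner_column(partner_kind)
  use <- !is.na(table$aphid_species) & !is.na(table[[col]]) &
    table[[col]] != NO_ASSOCIATION
  if (!any(use))
    stop("no usable records for partner_kind = '", partner_kind, "'")
  aphid <- table$aphid_species[use]
  partner <- table[[col]][use]
  m <- table(factor(aphid, levels = .lex_sort(unique(aphid))),
             factor(partner, levels = .lex_sort(unique(partner))))
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  names(dimnames(m)) <- NULL
  attr(m, "partner_kind") <- partner_kind
  m
}

#' Restrict community matrices and a relatedness matrix to common species
#'
#' Matrix-regression models need every input indexed by the same species in
#' the same order.  Species lacking data in any input (absent, or an all-zero
#' row) are dropped; every returned matrix shares one common, lexicographic
#' row order.
#'
#' @param matrices Named list of community matrices (aphid species as rows).
#' @param relatedness Optional square species x species distance/similarity
#'   matrix to restrict alongside.
#' @return A list with `matrices` (same names, aligned), `relatedness`
#'   (aligned, or `NULL`), `species` (common order), and `dropped`.
#' @export
align_species <- function(matrices, relatedness = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  present <- lapply(matrices, function(m) rownames(m)[rowSums(m) > 0])
  if (!is.null(relatedness)) present <- c(present, list(rownames(relatedness)))
  common <- .lex_sort(Reduce(intersect, present))
  if (length(common) < 3L)
    stop("only ", length(common), " species are shared across all inputs; ",
         "matrix regression needs at least 3")
  dropped <- .lex_sort(setdiff(unique(unlist(present)), common))
  out <- lapply(matrices, function(m) m[common, , drop = FALSE])
  rel <- if (!is.null(relatedness)) relatedness[common, common] else NULL
  list(matrices = out, relatedness = rel, species = common, dropped = dropped)
}
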