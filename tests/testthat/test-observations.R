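test_that("read_observations parses delimited files, maps columns, and keeps the sentinel distinct from missing", {
  df <- data.frame(Sample = c("a1", "a2", "a3"),
                   Aphid = c("aphA", "aphA", "aphB"),
                   parasitoid_species = c("w1", "No Association", "w2"),
                   plant_species = c("p1", "p1", NA),
                   year = c(2021, 2022, 2021),
                   stringsAsFactors = FALSE)
  path <- write_temp_csv(df)
  tab <- read_observations(path, column_map = c(sample_id = "Sample",
                                                aphid_species = "Aphid"))
  expect_s3_class(tab, "obs_table")
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$parasitoid_species[2], NO_ASSOCIATION)
  expect_true(is.na(tab$strain_id[1]))         # never screened
  expect_false(is.na(tab$parasitoid_species[2]))  # screened, negative
  expect_equal(tab$year, c(2021L, 2022L, 2021L))

  # TSV autodetection gives the same table
  tsv <- write_temp_csv(df, sep = "\t")
  tab2 <- read_observations(tsv, column_map = c(sample_id = "Sample",
                                                aphid_species = "Aphid"))
  expect_equal(tab2$aphid_species, tab$aphid_species)
})

test_that("read_observations enforces mandatory columns and unique sample ids", {
  df <- data.frame(sample_id = c("a1", "a2"), plant_species = c("p1", "p2"))
  path <- write_temp_csv(df)
  expect_error(read_observations(path), "aphid_species")

  dup <- data.frame(sample_id = c("a1", "a1", "a2"),
                    aphid_species = c("x", "x", "y"),
                    plant_species = c("p1", "p1", "p2"))
  expect_error(read_observations(write_temp_csv(dup)), "a1")
})

test_that("record invariants reject rows without species or any partner, reporting row numbers", {
  df <- data.frame(sample_id = c("a1", "a2", "a3"),
                   aphid_species = c("aphA", "", "aphB"),
                   plant_species = c("p1", "p2", NA),
                   parasitoid_species = c(NA, NA, NA),
                   strain_id = c(NA, NA, NA),
                   stringsAsFactors = FALSE)
  expect_warning(tab <- as_observations(df), "rows: 2, 3")
  expect_equal(tab$sample_id, "a1")
})

test_that("filter_observations removes singleton (aphid,plant) transients as found by brute-force pair counting", {
  tab <- toy_observations()
  # oracle: enumerate (aphid, plant) frequencies directly
  freq <- table(paste(tab$aphid_species, tab$plant_species))
  single <- names(freq)[freq == 1]
  expect_equal(single, "aphA p2")   # the only transient in the fixture

  out <- filter_observations(tab)
  expect_false(any(paste(out$aphid_species, out$plant_species) %in% single))
  expect_equal(nrow(out), nrow(tab) - 1L)
  expect_match(paste(attr(out, "removal_log"), collapse = " "), "aphA, p2",
               fixed = TRUE)

  # a recognised-host list shields the pair from removal
  kept <- filter_observations(tab, host_list = list(aphA = c("p1", "p2")))
  expect_equal(nrow(kept), nrow(tab))
})

test_that("filter_observations drops sentinel/unscreened records for the requested partner and can empty a table", {
  tab <- toy_observations()
  out <- filter_observations(tab, partner_kind = "strain")
  expect_false(any(is.na(out$strain_id)))
  expect_false(any(out$strain_id == NO_ASSOCIATION))

  allna <- as_observations(data.frame(
    sample_id = c("x1", "x2"), aphid_species = "aphA",
    plant_species = c("p1", "p1"),
    strain_id = c(NO_ASSOCIATION, NO_ASSOCIATION)))
  expect_warning(empty <- filter_observations(allna, partner_kind = "strain"),
                 "all records removed")
  expect_equal(nrow(empty), 0L)
})

test_that("filter_observations is idempotent and a no-op on clean tables", {
  tab <- toy_observations()
  once <- filter_observations(tab, partner_kind = "strain")
  twice <- filter_observations(once, partner_kind = "strain")
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)

  clean <- as_observations(data.frame(
    sample_id = c("c1", "c2", "c3", "c4"),
    aphid_species = c("A", "A", "B", "B"),
    plant_species = c("p1", "p1", "p2", "p2"),
    strain_id = c("ST1", "ST2", "ST1", "ST1")))
  expect_equal(as.data.frame(filter_observations(clean)),
               as.data.frame(clean), ignore_attr = TRUE)
})

test_that("build_community_matrix tallies records with lexicographic, byte-stable ordering", {
  tab <- as_observations(data.frame(
    sample_id = sprintf("r%d", 1:4),
    aphid_species = c("aphA", "aphA", "aphA", "aphB"),
    parasitoid_species = c("p1", "p1", "p2", "p2")))
  M <- build_community_matrix(tab, "parasitoid")
  expect_identical(M, structure(matrix(c(2L, 0L, 1L, 1L), 2,
                                       dimnames = list(c("aphA", "aphB"),
                                                       c("p1", "p2"))),
                                partner_kind = "parasitoid"))

  single <- as_observations(data.frame(sample_id = "r1",
                                       aphid_species = "aphA",
                                       parasitoid_species = "p1"))
  expect_equal(unname(build_community_matrix(single, "parasitoid")[1, 1]), 1L)

  # conservation: total count equals the number of records with a partner
  tab2 <- toy_observations()
  filt <- filter_observations(tab2, partner_kind = "strain")
  M2 <- build_community_matrix(filt, "strain")
  expect_equal(sum(M2), sum(!is.na(filt$strain_id) &
                              filt$strain_id != NO_ASSOCIATION))

  none <- as_observations(data.frame(sample_id = "r1",
                                     aphid_species = "aphA",
                                     plant_species = "p1"))
  expect_error(build_community_matrix(none, "strain"), "strain")
})

test_that("align_species restricts all inputs to common non-zero species in one shared order", {
  mk <- function(sp) matrix(1L, length(sp), 2,
                            dimnames = list(sp, c("x", "y")))
  expect_error(align_species(list(a = mk(c("A", "B", "C")),
                                  b = mk(c("B", "C", "D")))),
               "at least 3")

  sp <- c("C", "A", "B", "D")
  rel <- diag(0, 4); dimnames(rel) <- list(sp, sp)
  al <- align_species(list(a = mk(sp), b = mk(rev(sp))), relatedness = rel)
  expect_equal(al$species, c("A", "B", "C", "D"))
  expect_equal(rownames(al$matrices$a), rownames(al$matrices$b))
  expect_equal(rownames(al$relatedness), al$species)
  expect_equal(al$dropped, character(0))

  # an all-zero row counts as missing data for that species
  m1 <- mk(c("A", "B", "C", "D")); m1["D", ] <- 0L
  al2 <- align_species(list(a = m1, b = mk(c("A", "B", "C", "D"))))
  expect_equal(al2$species, c("A", "B", "C"))
  expect_equal(al2$dropped, "D")
})
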