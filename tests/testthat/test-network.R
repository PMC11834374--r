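test_that("h2_components reproduces the hand-enumerated 2x2 worked example", {
  # all tables with marginals (4,4)/(4,4): the concentrated diagonal gives
  # the entropy minimum, the even table the maximum
  tabs <- enumerate_tables(c(4, 4), c(4, 4))
  ents <- vapply(tabs, shannon_entropy, numeric(1))
  h <- h2_components(matrix(c(3, 1, 1, 3), 2))
  expect_equal(h$H2, -sum(rep(c(3, 1), 2) / 8 * log(rep(c(3, 1), 2) / 8)))
  expect_equal(h$H2min, min(ents), tolerance = 1e-12)
  expect_equal(h$H2max, max(ents), tolerance = 1e-12)
  expect_equal(h$H2min, log(2), tolerance = 1e-12)
  expect_equal(h$H2max, log(4), tolerance = 1e-12)
  expect_equal(round(h$h2prime, 3), 0.189)
})

test_that("h2prime hits its endpoints on diagonal and independence tables", {
  expect_equal(h2_components(diag(c(5, 5, 5)))$h2prime, 1)
  expect_equal(h2_components(matrix(2, 2, 2))$h2prime, 0)
  # unequal marginals whose independence expectation is itself integer
  M <- matrix(c(2, 4, 2, 4), 2)   # equals outer((4,8),(6,6))/12
  expect_equal(h2_components(M)$h2prime, 0)
  expect_error(h2_components(matrix(1:3, 1)), "2 rows")
  expect_error(h2_components(matrix(0, 2, 2)), "total")
})

test_that("entropy bounds bracket every enumerated table on random small matrices", {
  set.seed(51)
  for (i in 1:15) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    M <- matrix(rpois(nr * nc, 1), nr, nc)
    if (sum(M) < 2 || any(rowSums(M) == 0) || any(colSums(M) == 0)) next
    h <- suppressWarnings(h2_components(M))
    ents <- vapply(enumerate_tables(rowSums(M), colSums(M)),
                   shannon_entropy, numeric(1))
    expect_lte(h$H2min, min(ents) + 1e-9)
    expect_gte(h$H2max, max(ents) - 1e-9)
    # observed entropy itself must sit inside the bracket
    expect_gte(h$H2, h$H2min - 1e-9)
    expect_lte(h$H2, h$H2max + 1e-9)
  }
})

test_that("patefield_sample preserves marginals exactly and validates input", {
  set.seed(52)
  for (i in 1:10) {
    r <- rpois(4, 5) + 1
    cs <- as.vector(stats::rmultinom(1, sum(r), rep(1, 5)))
    tab <- patefield_sample(r, cs)
    expect_equal(rowSums(tab), r)
    expect_equal(colSums(tab), cs)
  }
  expect_equal(patefield_sample(5, c(2, 3)), matrix(c(2, 3), 1))
  expect_error(patefield_sample(c(2, 2), c(1, 1)), "differ")
})

test_that("h2_ses flags strong diagonal structure and is centred under the null", {
  # strongly specialised network: huge positive standardised effect
  D <- diag(10L) * 10L
  h <- h2_ses(D, n_null = 200, seed = 53)
  expect_equal(h$h2prime, 1)
  expect_gt(h$ses, 10)

  # self-consistency: matrices drawn from the null itself give SES ~ 0
  set.seed(54)
  r <- c(8, 6, 4, 2); cs <- c(7, 6, 4, 3)
  ses <- vapply(stats::r2dtable(200, r, cs), function(tab) {
    h2_ses(tab, n_null = 99, seed = sample.int(1e6, 1))$ses
  }, numeric(1))
  se <- sd(ses) / sqrt(length(ses))
  expect_lt(abs(mean(ses)), 3 * se + 0.05)

  # degenerate marginals leave no null spread
  ws <- capture_warnings(flat <- h2_ses(matrix(c(1, 0, 0, 1), 2),
                                        n_null = 20, seed = 1))
  expect_true(any(grepl("zero spread", ws)))
  expect_true(is.na(flat$ses))
})

test_that("h2_ses results are reproducible under a seed", {
  M <- matrix(c(6, 1, 0, 1, 5, 1, 0, 2, 4), 3)
  a <- h2_ses(M, n_null = 100, seed = 11)
  b <- h2_ses(M, n_null = 100, seed = 11)
  expect_identical(a, b)
})

test_that("proportional projection splits symbiont counts by attack frequency and conserves totals", {
  # one aphid, one parasitoid: everything transfers
  A1 <- matrix(3, 1, 1, dimnames = list("aphA", "w1"))
  S1 <- matrix(c(4, 2), 1, dimnames = list("aphA", c("ST1", "ST2")))
  B1 <- project_parasitoid_symbiont(A1, S1)
  expect_equal(unname(B1["w1", ]), c(4, 2))

  # equal attacks split the strains evenly
  A2 <- matrix(c(1, 1), 1, dimnames = list("aphA", c("w1", "w2")))
  B2 <- project_parasitoid_symbiont(A2, S1)
  expect_equal(B2, matrix(c(2, 1, 2, 1), 2, byrow = TRUE),
               ignore_attr = TRUE)

  # conservation over retained aphids on a random instance
  set.seed(55)
  sp <- sprintf("a%02d", 1:8)
  A <- matrix(rpois(8 * 4, 2), 8, dimnames = list(sp, sprintf("w%d", 1:4)))
  S <- matrix(rpois(8 * 5, 3), 8, dimnames = list(sp, sprintf("ST%d", 1:5)))
  A[3, ] <- 0   # aphid without parasitoid records is dropped
  expect_message(B <- project_parasitoid_symbiont(A, S), "a03")
  kept <- setdiff(sp, attr(B, "dropped_aphids"))
  expect_equal(sum(B), sum(S[kept, ]), tolerance = 1e-9)

  expect_error(project_parasitoid_symbiont(A1 * 0, S1), "no aphid")
})

test_that("shared_pair_summary matches exhaustive enumeration on a hand-built community", {
  sp <- c("aphA", "aphB", "aphC", "aphD")
  strain <- matrix(c(2, 1, 0, 0,
                     1, 2, 0, 0,
                     0, 0, 3, 0,
                     0, 0, 2, 1), 4, byrow = TRUE,
                   dimnames = list(sp, sprintf("ST%d", 1:4)))
  partner <- matrix(c(3, 0, 0,
                      0, 3, 0,
                      1, 2, 0,
                      0, 0, 3), 4, byrow = TRUE,
                    dimnames = list(sp, sprintf("w%d", 1:3)))
  sim_s <- community_similarity(strain)
  sim_p <- community_similarity(partner)
  ps <- shared_pair_summary(sim_s, sim_p, strain_counts = strain)

  # oracle: loop over all C(4,2) pairs directly
  brute_share <- 0; brute_both <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    shares <- sum(pmin(strain[i, ], strain[j, ])) > 0
    overlap <- sum(pmin(partner[i, ], partner[j, ])) > 0
    if (shares) {
      brute_share <- brute_share + 1
      if (overlap) brute_both <- brute_both + 1
    }
  }
  expect_equal(ps$summary$n_pairs, 6)
  expect_equal(ps$summary$n_pairs_sharing_strain, brute_share)
  expect_equal(ps$summary$n_pairs_sharing_both, brute_both)
  expect_equal(ps$summary$pct_pairs_sharing_both,
               100 * brute_both / brute_share)
  # strains seen in more than one species: ST1, ST2 (A,B) and ST3 (C,D)
  expect_equal(ps$summary$n_strains_multi_species, 3)

  # all strain communities disjoint: nothing shared
  disj <- diag(c(2, 3, 4, 5)); dimnames(disj) <- dimnames(strain)
  ps0 <- shared_pair_summary(community_similarity(disj), sim_p)
  expect_equal(ps0$summary$n_pairs_sharing_strain, 0)

  expect_error(shared_pair_summary(sim_s, sim_p[c(2, 1, 3, 4), ]),
               "mismatch")
})

test_that("a similarity threshold restricts which pairs count as partner-sharing", {
  sp <- c("a", "b", "c")
  sim_s <- matrix(1, 3, 3, dimnames = list(sp, sp))
  sim_p <- matrix(c(1, 0.05, 0.5,
                    0.05, 1, 0,
                    0.5, 0, 1), 3, dimnames = list(sp, sp))
  loose <- shared_pair_summary(sim_s, sim_p, threshold = 0)
  strict <- shared_pair_summary(sim_s, sim_p, threshold = 0.1)
  expect_equal(loose$summary$n_pairs_sharing_both, 2)
  expect_equal(strict$summary$n_pairs_sharing_both, 1)
})

test_that("edge_list flattens weighted matrices and drops empty edges", {
  B <- matrix(c(1.5, 0, 0, 2), 2,
              dimnames = list(c("w1", "w2"), c("ST1", "ST2")))
  el <- edge_list(B)
  expect_equal(nrow(el), 2)
  expect_equal(el$weight, c(1.5, 2))
  expect_equal(el$source, c("w1", "w2"))
})
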