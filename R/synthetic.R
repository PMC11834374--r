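#' Configuration for the synthetic tripartite community generator
#'
#' Bundles the knobs of [simulate_community()] with defaults emulating a
#' field survey of an aphid community: a couple of dozen focal species, each
#' attacked by one dominant parasitoid carrying most of the attacks, one
#' dominant food plant, and a handful of symbiont strains whose distribution
#' can be coupled, with tunable strength, to parasitoid sharing, host
#' phylogeny, and/or plant sharing.
#'
#' @param n_species Number of focal (aphid) species.  Default 22.
#' @param seq_len Marker alignment length (sites).  Default 400.
#' @param mutation_rate Per-site substitution rate per unit branch length of
#'   the species tree.  Default 0.05.
#' @param n_parasitoids,n_strains,n_plants Partner pool sizes.
#' @param dominance Expected share of attacks taken by a species' dominant
#'   parasitoid (default 0.8, i.e. "> 75% of parasitism").
#' @param coupling_parasitoid,coupling_phylo,coupling_plant Mixture weights
#'   in \[0, 1\] tying a species' strain profile to its parasitoids'
#'   signature strains, its nearest phylogenetic neighbour's profile, and
#'   its plant's strain pool; their sum must not exceed 1, the residual mass
#'   being independent Dirichlet noise.  Defaults 0.4 / 0.3 / 0.
#' @param samples_per_species Records emitted per species; an integer or a
#'   length-2 range sampled uniformly.  Default 40.
#' @param noise Dirichlet concentration of the residual strain noise.
#' @param plant_fidelity Probability a record sits on the species' dominant
#'   plant.  Default 0.9.
#' @param p_no_parasitoid,p_no_strain Probability that a record is scored
#'   `"No Association"` for the parasitoid / the symbiont (screened but
#'   negative).  Defaults 0.15 / 0.25.
#' @param seed Integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_species = 22, seq_len = 400,
                             mutation_rate = 0.05,
                             n_parasitoids = 10, n_strains = 12,
                             n_plants = 8, dominance = 0.8,
                             coupling_parasitoid = 0.4,
                             coupling_phylo = 0.3,
                             coupling_plant = 0,
                             samples_per_species = 40, noise = 1,
                             plant_fidelity = 0.9,
                             p_no_parasitoid = 0.15, p_no_strain = 0.25,
                             seed = 1L) {
  cfg <- list(n_species = n_species, seq_len = seq_len,
              mutation_rate = mutation_rate,
              n_parasitoids = n_parasitoids, n_strains = n_strains,
              n_plants = n_plants, dominance = dominance,
              coupling_parasitoid = coupling_parasitoid,
              coupling_phylo = coupling_phylo,
              coupling_plant = coupling_plant,
              samples_per_species = samples_per_species, noise = noise,
              plant_fidelity = plant_fidelity,
              p_no_parasitoid = p_no_parasitoid, p_no_strain = p_no_strain,
              seed = as.integer(seed))
  stopifnot(cfg$n_species >= 3, cfg$seq_len >= 1, cfg$mutation_rate >= 0,
            cfg$n_parasitoids >= 1, cfg$n_strains >= 1, cfg$n_plants >= 1,
            cfg$dominance > 0, cfg$dominance <= 1,
            cfg$coupling_parasitoid >= 0, cfg$coupling_phylo >= 0,
            cfg$coupling_plant >= 0,
            length(cfg$samples_per_species) %in% 1:2,
            all(cfg$samples_per_species >= 1),
            cfg$noise > 0, cfg$plant_fidelity >= 0, cfg$plant_fidelity <= 1,
            cfg$p_no_parasitoid >= 0, cfg$p_no_parasitoid < 1,
            cfg$p_no_strain >= 0, cfg$p_no_strain < 1)
  lam <- cfg$coupling_parasitoid + cfg$coupling_phylo + cfg$coupling_plant
  if (lam > 1 + 1e-12)
    stop("coupling weights sum to ", lam, "; must be <= 1")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Simulate marker sequences for the focal species on a random Yule tree
#'
#' Grows a pure-birth (Yule) tree with unit speciation rate and evolves one
#' marker sequence per species from a random root sequence by
#' Jukes-Cantor substitution along the branches.
#'
#' @param n_species Number of tips (at least 3).
#' @param seq_len Alignment length in sites.
#' @param mutation_rate Expected substitutions per site per unit branch
#'   length; 0 yields identical sequences.
#' @param seed Optional integer seed.
#' @return A list: `sequences` (named character vector, species sorted),
#'   `tree` (an `ape` phylo), `newick` (newick string).
#' @export
simulate_sequences <- function(n_species, seq_len = 400,
                               mutation_rate = 0.05, seed = NULL) {
  stopifnot(n_species >= 3, seq_len >= 1, mutation_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  if (mutation_rate == 0) {
    root <- paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
                  collapse = "")
    seqs <- stats::setNames(rep(root, n_species), tree$tip.label)
  } else {
    dat <- phangorn::simSeq(tree, l = seq_len, rate = mutation_rate)
    chr <- toupper(as.character(dat))
    seqs <- stats::setNames(apply(chr, 1, paste, collapse = ""),
                            rownames(chr))
  }
  seqs <- seqs[.lex_sort(names(seqs))]
  list(sequences = seqs, tree = tree, newick = ape::write.tree(tree))
}

## symmetric Dirichlet draw via normalised gammas
.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Simulate a tripartite observation table with known ground truth
#'
#' Generates a field-survey-like dataset in four steps: (1) species marker
#' sequences on a Yule tree ([simulate_sequences()]); (2) each species gets
#' a dominant parasitoid (drawn from a shared pool, so blocks of species
#' share enemies) holding `dominance` of its attack profile, the remainder
#' spread over 1-3 minor parasitoids; (3) every parasitoid (and plant)
#' carries a signature strain, and each species' strain profile is the
#' mixture `coupling_parasitoid * (attack-weighted parasitoid signatures) +
#' coupling_phylo * (nearest phylogenetic neighbour's profile) +
#' coupling_plant * (plant signature) + residual * Dirichlet(noise)`;
#' (4) per-record categorical draws emit the observation table, with a
#' configurable fraction of records scored `"No Association"` for the
#' parasitoid or the symbiont.  Records with an observed parasitoid are
#' sourced `"mummy"`, the rest `"live"`.
#'
#' The generator is a deterministic function of the config (including its
#' seed): identical configs give byte-identical tables.
#'
#' @param config A [synthetic_config()].
#' @return A list: `observations` (an `"obs_table"`), `truth` (tree newick,
#'   couplings, per-species dominant parasitoid/plant, attack and strain
#'   profiles, parasitoid/plant signature strains), `sequences`, `tree`.
#' @export
simulate_community <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_species

  sim <- simulate_sequences(n, config$seq_len, config$mutation_rate)
  species <- names(sim$sequences)
  pd <- stats::cophenetic(sim$tree)[species, species]

  parasitoids <- sprintf("P%02d", seq_len(config$n_parasitoids))
  plants <- sprintf("plant%02d", seq_len(config$n_plants))
  strains <- sprintf("ST%02d", seq_len(config$n_strains))

  ## (2) attack profiles: dominant + 1-3 minors.  Dominants cycle through a
  ## random permutation of the parasitoid pool, so when there are fewer
  ## parasitoids than species, blocks of species share their main enemy
  ## (and with a pool at least as large as the species set each species has
  ## its own).
  attack <- matrix(0, n, config$n_parasitoids,
                   dimnames = list(species, parasitoids))
  dom_par <- stats::setNames(
    rep(sample(parasitoids), length.out = n)[sample.int(n)], species)
  for (sp in species) {
    attack[sp, dom_par[[sp]]] <- config$dominance
    others <- setdiff(parasitoids, dom_par[[sp]])
    if (length(others) && config$dominance < 1) {
      k <- sample(seq_len(min(3L, length(others))), 1)
      minors <- sample(others, k)
      w <- .rdirichlet1(k, 1)
      attack[sp, minors] <- (1 - config$dominance) * w
    } else {
      attack[sp, dom_par[[sp]]] <- 1
    }
    attack[sp, ] <- attack[sp, ] / sum(attack[sp, ])
  }

  ## (3) signature strains and strain profiles
  sig_par <- stats::setNames(
    if (config$n_strains >= config$n_parasitoids)
      sample(strains, config$n_parasitoids)
    else sample(strains, config$n_parasitoids, replace = TRUE),
    parasitoids)
  sig_pla <- stats::setNames(sample(strains, config$n_plants,
                                    replace = TRUE), plants)
  dom_plant <- stats::setNames(sample(plants, n, replace = TRUE), species)

  lam_par <- config$coupling_parasitoid
  lam_phy <- config$coupling_phylo
  lam_pla <- config$coupling_plant
  resid <- 1 - lam_par - lam_phy - lam_pla

  base <- matrix(0, n, config$n_strains, dimnames = list(species, strains))
  for (sp in species) {
    par_mix <- stats::setNames(numeric(config$n_strains), strains)
    for (p in parasitoids)
      par_mix[sig_par[[p]]] <- par_mix[sig_par[[p]]] + attack[sp, p]
    pla_vec <- stats::setNames(numeric(config$n_strains), strains)
    pla_vec[sig_pla[[dom_plant[[sp]]]]] <- 1
    noise_vec <- .rdirichlet1(config$n_strains, config$noise)
    b <- lam_par * par_mix + lam_pla * pla_vec + resid * noise_vec
    base[sp, ] <- b / sum(b)
  }
  profile <- base
  if (lam_phy > 0) {
    for (sp in species) {
      d <- pd[sp, ]; d[sp] <- Inf
      nn <- names(d)[order(d, names(d), method = "radix")][1]
      profile[sp, ] <- (1 - lam_phy) * base[sp, ] + lam_phy * base[nn, ]
    }
  }

  ## (4) emit records
  nsamp <- if (length(config$samples_per_species) == 2L)
    sample(config$samples_per_species[1]:config$samples_per_species[2],
           n, replace = TRUE)
  else rep(config$samples_per_species, n)
  names(nsamp) <- species

  recs <- vector("list", n)
  for (si in seq_along(species)) {
    sp <- species[si]
    k <- nsamp[[sp]]
    par_obs <- sample(parasitoids, k, replace = TRUE, prob = attack[sp, ])
    par_na <- stats::runif(k) < config$p_no_parasitoid
    par_obs[par_na] <- NO_ASSOCIATION
    str_obs <- sample(strains, k, replace = TRUE, prob = profile[sp, ])
    str_obs[stats::runif(k) < config$p_no_strain] <- NO_ASSOCIATION
    on_dom <- stats::runif(k) < config$plant_fidelity
    pla_obs <- ifelse(on_dom, dom_plant[[sp]],
                      sample(plants, k, replace = TRUE))
    recs[[si]] <- data.frame(
      sample_id = sprintf("%s_%04d", sp, seq_len(k)),
      year = sample(2021:2022, k, replace = TRUE),
      location = sample(sprintf("L%02d", 1:6), k, replace = TRUE),
      aphid_species = sp,
      plant_species = pla_obs,
      parasitoid_species = par_obs,
      strain_id = str_obs,
      source = ifelse(par_obs == NO_ASSOCIATION, "live", "mummy"),
      stringsAsFactors = FALSE)
  }
  obs <- as_observations(do.call(rbind, recs),
                         provenance = list(generator = "simulate_community",
                                           seed = config$seed))

  truth <- list(newick = sim$newick,
                couplings = c(parasitoid = lam_par, phylo = lam_phy,
                              plant = lam_pla),
                dominant_parasitoid = dom_par,
                dominant_plant = dom_plant,
                attack_profiles = attack,
                strain_profiles = profile,
                parasitoid_signature = sig_par,
                plant_signature = sig_pla)
  list(observations = obs, truth = truth,
       sequences = sim$sequences, tree = sim$tree)
}
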