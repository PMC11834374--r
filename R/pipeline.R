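#' Assemble and validate a pipeline configuration
#'
#' The full analysis is driven by one configuration: where the inputs live
#' (or in-memory objects), how to filter, and the seeds and replication
#' counts of every stochastic stage.  All seeds are recorded in the outputs
#' and an MD5 hash of the configuration is embedded in every result file,
#' so a result bundle is a pure function of (inputs, config).
#'
#' @param observations Path to a delimited observation table, or an
#'   `"obs_table"` / data.frame.
#' @param sequences Path to a FASTA of aligned marker sequences (one per
#'   focal species, named by species), or a named character vector.
#' @param species_map Optional named vector sequence id -> species, when
#'   `sequences` holds several haplotypes per species.
#' @param column_map,delimiter Passed to [read_observations()].
#' @param host_list Optional recognised-host list for
#'   [filter_observations()].
#' @param normalize Normalise community matrices to relative abundances
#'   before Bray-Curtis (default `FALSE`).
#' @param relatedness_mode Passed to [relatedness_transform()]; default
#'   `"raw_distance"`.
#' @param rarefaction_depth,rarefaction_reps Diversity-screen rarefaction
#'   controls (defaults 7 and 1000).
#' @param mmrr_nperm,mmrr_seed MMRR permutation controls (defaults 9999, 42).
#' @param h2_n_null,h2_seed H2' null-model controls (defaults 1000, 42).
#' @param pair_threshold Partner-similarity threshold of
#'   [shared_pair_summary()] (default 0).
#' @param out_dir Optional output directory; when given, all result files
#'   are written there.
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(observations, sequences, species_map = NULL,
                            column_map = NULL, delimiter = NULL,
                            host_list = NULL, normalize = FALSE,
                            relatedness_mode = "raw_distance",
                            rarefaction_depth = 7, rarefaction_reps = 1000,
                            mmrr_nperm = 9999, mmrr_seed = 42,
                            h2_n_null = 1000, h2_seed = 42,
                            pair_threshold = 0, out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$rarefaction_depth >= 1, cfg$rarefaction_reps >= 1,
            cfg$mmrr_nperm == 0 || cfg$mmrr_nperm >= 99,
            cfg$h2_n_null >= 2, cfg$pair_threshold >= 0)
  cfg$relatedness_mode <- match.arg(cfg$relatedness_mode,
                                    c("raw_distance", "one_minus_scaled",
                                      "negated_z"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys are the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (key in c("observations", "sequences")) {
    if (is.character(raw[[key]]) && !file.exists(raw[[key]]))
      raw[[key]] <- file.path(dirname(path), raw[[key]])
  }
  do.call(pipeline_config, raw)
}

.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL   # where results land does not change what they are
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

.table1_screen <- function(M_strain, M_partner, group, depth, reps, seed) {
  common <- intersect(rownames(M_strain), rownames(M_partner))
  variants <- list()
  if (length(common) >= 3) {
    dx <- diversity_table(M_partner[common, , drop = FALSE],
                          depth = depth, reps = reps, seed = seed)
    dy <- diversity_table(M_strain[common, , drop = FALSE],
                          depth = depth, reps = reps, seed = seed)
    for (variant in c("full", "rarefied")) {
      for (index in c("richness", "shannon", "simpson")) {
        col <- if (variant == "rarefied") paste0("rarefied_", index) else index
        fit <- tryCatch(fit_diversity_model(dx[[col]], dy[[col]]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        variants[[length(variants) + 1L]] <- data.frame(
          group = group, dataset = variant, index = index,
          r2_adjusted = fit$r2_adjusted, F = fit$F, p = fit$p, n = fit$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(variants)) do.call(rbind, variants) else NULL
}

#' Run the full tripartite community analysis
#'
#' Orchestrates every stage from one configuration: read and validate the
#' observation table; filter per partner; build the three community
#' matrices; compute Bray-Curtis similarity and the gene-distance
#' relatedness matrix; screen diversity relationships (raw, rarefied, and
#' mummies-only variants); fit the two MMRR models (symbiont similarity
#' against parasitoid similarity + relatedness on the species shared by all
#' three matrices, and against plant similarity + relatedness likewise);
#' test H2' specialisation with Patefield nulls for the aphid-parasitoid,
#' aphid-symbiont, and projected parasitoid-symbiont networks; and
#' summarise pairwise sharing.  A run log records the species dropped at
#' every stage.
#'
#' @param config A [pipeline_config()] (or path to a YAML accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, the result bundle: `matrices`, `similarity`,
#'   `relatedness`, `diversity`, `diversity_models`, `mmrr` (parasitoid and
#'   plant models), `h2` (three networks), `projection`, `pairs`, `log`,
#'   `config_hash`, `seeds`.  Files are written when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  obs <- config$observations
  if (is.character(obs))
    obs <- read_observations(obs, delimiter = config$delimiter,
                             column_map = config$column_map)
  else if (!inherits(obs, "obs_table")) obs <- as_observations(obs)
  note("read %d observation records", nrow(obs))

  seqs <- config$sequences
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_sequences(seqs)
  seqs <- .as_seq_vector(seqs)

  ## community matrices, one per partner kind
  kinds <- c("parasitoid", "plant", "strain")
  mats <- lapply(stats::setNames(kinds, kinds), function(kind) {
    filt <- filter_observations(obs, partner_kind = kind,
                                host_list = config$host_list)
    note("%s: %d records after filtering (%s)", kind, nrow(filt),
         paste(attr(filt, "removal_log"), collapse = "; "))
    build_community_matrix(filt, kind)
  })

  ## relatedness over species with sequences
  reps <- if (!is.null(config$species_map))
    choose_representatives(seqs, config$species_map)
  else stats::setNames(names(seqs), names(seqs))
  D_gene <- gene_distance_matrix(seqs, reps)
  relate <- relatedness_transform(D_gene, config$relatedness_mode)

  ## the two matrix-regression models
  fit_model <- function(partner_kind) {
    al <- align_species(list(strain = mats$strain,
                             partner = mats[[partner_kind]]),
                        relatedness = relate)
    note("%s model: %d species retained, dropped: %s", partner_kind,
         length(al$species),
         if (length(al$dropped)) paste(al$dropped, collapse = ", ")
         else "none")
    sim_strain <- community_similarity(al$matrices$strain,
                                       normalize = config$normalize)
    sim_partner <- community_similarity(al$matrices$partner,
                                        normalize = config$normalize)
    Xs <- list(partner = sim_partner, relatedness = al$relatedness)
    names(Xs)[1] <- partner_kind
    list(fit = mmrr(sim_strain, Xs, nperm = config$mmrr_nperm,
                    seed = config$mmrr_seed),
         sim_strain = sim_strain, sim_partner = sim_partner,
         species = al$species)
  }
  par_model <- fit_model("parasitoid")
  pla_model <- fit_model("plant")

  ## diversity screens: full + rarefied, and mummies-only variant
  div_tab <- diversity_table(mats$strain, depth = config$rarefaction_depth,
                             reps = config$rarefaction_reps,
                             seed = config$mmrr_seed)
  screens <- list(
    .table1_screen(mats$strain, mats$parasitoid, "parasitoid",
                   config$rarefaction_depth, config$rarefaction_reps,
                   config$mmrr_seed),
    .table1_screen(mats$strain, mats$plant, "plant",
                   config$rarefaction_depth, config$rarefaction_reps,
                   config$mmrr_seed))
  mum <- obs[!is.na(obs$source) & obs$source == "mummy", , drop = FALSE]
  if (nrow(mum)) {
    mum <- as_observations(mum)
    mum_mats <- lapply(stats::setNames(kinds, kinds), function(kind) {
      filt <- filter_observations(mum, partner_kind = kind,
                                  host_list = config$host_list)
      if (nrow(filt) == 0) return(NULL)
      build_community_matrix(filt, kind)
    })
    for (kind in c("parasitoid", "plant")) {
      if (is.null(mum_mats$strain) || is.null(mum_mats[[kind]])) next
      sc <- .table1_screen(mum_mats$strain, mum_mats[[kind]], kind,
                           config$rarefaction_depth,
                           config$rarefaction_reps, config$mmrr_seed)
      if (!is.null(sc)) {
        sc$dataset <- "mummies_only"
        sc <- sc[sc$index %in% c("richness", "shannon", "simpson") &
                   !duplicated(paste(sc$group, sc$index)), ]
        screens[[length(screens) + 1L]] <- sc
      }
    }
  }
  div_models <- do.call(rbind, Filter(Negate(is.null), screens))

  ## specialisation of the three networks
  proj <- project_parasitoid_symbiont(mats$parasitoid, mats$strain)
  h2 <- list(
    aphid_parasitoid = h2_ses(mats$parasitoid, n_null = config$h2_n_null,
                              seed = config$h2_seed),
    aphid_strain = h2_ses(mats$strain, n_null = config$h2_n_null,
                          seed = config$h2_seed),
    parasitoid_strain = h2_ses(proj, n_null = config$h2_n_null,
                               seed = config$h2_seed))

  ## pairwise sharing summaries
  pairs_par <- shared_pair_summary(par_model$sim_strain,
                                   par_model$sim_partner,
                                   threshold = config$pair_threshold,
                                   strain_counts =
                                     mats$strain[par_model$species, ,
                                                 drop = FALSE])
  pairs_pla <- shared_pair_summary(pla_model$sim_strain,
                                   pla_model$sim_partner,
                                   threshold = config$pair_threshold,
                                   strain_counts =
                                     mats$strain[pla_model$species, ,
                                                 drop = FALSE])

  bundle <- list(
    matrices = mats,
    similarity = list(parasitoid = par_model$sim_partner,
                      plant = pla_model$sim_partner,
                      strain_parasitoid_model = par_model$sim_strain,
                      strain_plant_model = pla_model$sim_strain),
    relatedness = relate,
    diversity = div_tab,
    diversity_models = div_models,
    mmrr = list(parasitoid = par_model$fit, plant = pla_model$fit),
    h2 = h2,
    projection = proj,
    pairs = list(parasitoid = pairs_par, plant = pairs_pla),
    log = log,
    config_hash = .config_hash(config),
    seeds = list(mmrr = config$mmrr_seed, h2 = config$h2_seed))

  if (!is.null(config$out_dir)) .write_bundle(bundle, config)
  invisible(bundle)
}

.mmrr_json <- function(fit, hash) {
  list(coefficients = fit$coefficients, r2 = fit$r2, F = fit$F,
       F_p_perm = fit$F_p_perm, nperm = fit$nperm, seed = fit$seed,
       n_species = fit$n_species, n_pairs = fit$n_pairs,
       config_hash = hash)
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  for (kind in names(bundle$matrices))
    write_matrix_csv(bundle$matrices[[kind]],
                     out(sprintf("matrix_%s.csv", kind)))
  for (nm in names(bundle$similarity))
    write_matrix_csv(bundle$similarity[[nm]],
                     out(sprintf("similarity_%s.csv", nm)))
  write_matrix_csv(bundle$relatedness, out("relatedness.csv"))
  utils::write.csv(bundle$diversity, out("diversity.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$diversity_models))
    utils::write.csv(bundle$diversity_models, out("diversity_models.csv"),
                     row.names = FALSE)
  for (nm in names(bundle$mmrr))
    jsonlite::write_json(.mmrr_json(bundle$mmrr[[nm]], bundle$config_hash),
                         out(sprintf("mmrr_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (nm in names(bundle$h2)) {
    h <- unclass(bundle$h2[[nm]])
    h$config_hash <- bundle$config_hash
    h <- lapply(h, function(v) if (is.null(v)) NA else v)
    jsonlite::write_json(h, out(sprintf("h2_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(edge_list(bundle$projection),
                   out("projection_edges.csv"), row.names = FALSE)
  for (nm in names(bundle$pairs))
    utils::write.csv(bundle$pairs[[nm]]$pairs,
                     out(sprintf("pairs_%s.csv", nm)), row.names = FALSE)
  writeLines(c(sprintf("config_hash: %s", bundle$config_hash), bundle$log),
             out("run_log.txt"))
  invisible(config$out_dir)
}
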