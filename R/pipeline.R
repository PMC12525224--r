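#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis.  The defaults are the
#' study constants: herbs need at least 3 target-bearing ingredients, herb
#' target sets are capped at the top 50 by simple pathway count, candidate
#' herbs must reach overlap p < 0.05 and carry at least 5 active compounds,
#' the ranking keeps the top 10, and mechanism subnetworks use k = 20.
#'
#' @param min_ingredients Ingredient-count floor for herbs (default 3).
#' @param top_targets Per-herb target cap by path count (default 50).
#' @param p_threshold Overlap significance cut-off (default 0.05).
#' @param min_active_compounds Active-compound floor for ranked herbs
#'   (default 5).
#' @param top_n Herb-ranking length (default 10).
#' @param k Top-k cut-off for mechanism subnetworks (default 20).
#' @param walk A [walk_params()] object.
#' @param active_rule Active-compound rule, see [count_active_compounds()].
#' @param n_random_enrich Random queries for the enrichment z-score.
#' @param seed Seed for the stochastic stages (enrichment z background).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_ingredients = 3, top_targets = 50,
                            p_threshold = 0.05, min_active_compounds = 5,
                            top_n = 10, k = 20, walk = walk_params(),
                            active_rule = "network_mapped",
                            n_random_enrich = 200, seed = 1) {
  stopifnot(inherits(walk, "walk_params"))
  structure(
    list(
      min_ingredients = min_ingredients, top_targets = top_targets,
      p_threshold = p_threshold,
      min_active_compounds = min_active_compounds,
      top_n = top_n, k = k, walk = walk, active_rule = active_rule,
      n_random_enrich = n_random_enrich, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file with optional top-level blocks `walk:`
#' (`restart_prob`, `class_weights`, `tol`, `max_iter`) and `prioritize:`
#' (the remaining [pipeline_config()] fields); missing fields keep their
#' defaults.  `as_yaml()`/`read_pipeline_config()` round-trip unchanged.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  wp <- y$walk %||% list()
  walk <- walk_params(
    restart_prob = wp$restart_prob %||% 0.5,
    class_weights = unlist(wp$class_weights),
    tol = wp$tol %||% 1e-10,
    max_iter = wp$max_iter %||% 500
  )
  pr <- y$prioritize %||% list()
  pipeline_config(
    min_ingredients = pr$min_ingredients %||% 3,
    top_targets = pr$top_targets %||% 50,
    p_threshold = pr$p_threshold %||% 0.05,
    min_active_compounds = pr$min_active_compounds %||% 5,
    top_n = pr$top_n %||% 10,
    k = pr$k %||% 20,
    walk = walk,
    active_rule = pr$active_rule %||% "network_mapped",
    n_random_enrich = pr$n_random_enrich %||% 200,
    seed = y$seed %||% 1
  )
}

#' Serialise a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Optional output file; omitted, the YAML string is returned.
#' @return The YAML string (invisibly when written to `path`).
#' @export
config_as_yaml <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(
    walk = list(
      restart_prob = config$walk$restart_prob,
      class_weights = as.list(config$walk$class_weights),
      tol = config$walk$tol,
      max_iter = config$walk$max_iter
    ),
    prioritize = config[c(
      "min_ingredients", "top_targets", "p_threshold",
      "min_active_compounds", "top_n", "k", "active_rule",
      "n_random_enrich"
    )],
    seed = config$seed
  )
  txt <- yaml::as.yaml(y)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Run the full analysis pipeline
#'
#' Orchestrates build -> diffuse -> prioritize -> enrich -> mechanisms on
#' one input bundle and writes all result files: `herb_ranking.tsv`,
#' `compounds_<herb>.tsv` per ranked herb, `enrichment.tsv`,
#' `mechanism_<compound>.graphml` / `.sif` for every passing compound of
#' the top herb, plus `manifest.json` (config hash, seed, versions) and
#' `run.log`.  Re-running with the same inputs and config reproduces
#' identical result files.
#'
#' @param world A `synthetic_world`, or a directory containing the standard
#'   input bundle written by [write_world()].
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param gmt Optional path to (or named list of) gene sets for the
#'   enrichment stage; by default the function layer's protein annotations
#'   serve as the library.
#' @return A list with `herb_ranking`, `compound_rankings` (named list),
#'   `enrichment`, `mechanisms` (named list), and `manifest`, invisibly
#'   written under `out_dir`.
#' @export
run_pipeline <- function(world, out_dir, config = pipeline_config(),
                         gmt = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  if (is.character(world)) {
    note("stage build: reading input bundle from %s", world)
    net <- assemble_network(
      read_edge_list(file.path(world, "ppi.tsv"), "ppi", quiet = TRUE),
      read_edge_list(file.path(world, "protein_function.tsv"),
                     "protein_function", quiet = TRUE),
      read_edge_list(file.path(world, "function_hierarchy.tsv"),
                     "function_hierarchy", quiet = TRUE),
      quiet = TRUE
    )
    catalog <- suppressMessages(read_herb_catalog(
      file.path(world, "herb_compound.tsv"),
      file.path(world, "compound_target.tsv")
    ))
    disease <- read_disease_genes(file.path(world, "disease.gmt"))
  } else {
    stopifnot(inherits(world, "synthetic_world"))
    note("stage build: using in-memory synthetic world (seed %d)",
         world$config$seed)
    net <- world$network
    catalog <- world$catalog
    disease <- world$disease
  }

  note("stage filter: ingredient floor %d", config$min_ingredients)
  catalog <- suppressMessages(
    filter_herbs_min_ingredients(catalog, config$min_ingredients)
  )
  targets <- herb_target_sets(catalog, limit = config$top_targets)

  note("stage diffuse/prioritize: %d herb(s), restart %.3f",
       length(targets), config$walk$restart_prob)
  scores <- suppressMessages(
    score_entities(net, targets, "herb", disease, params = config$walk)
  )
  active <- count_active_compounds(catalog, net,
                                   disease_genes = disease$genes,
                                   active_rule = config$active_rule)
  scores <- left_join(scores, active, by = "entity")
  scores$n_active_compounds[is.na(scores$n_active_compounds)] <- 0L
  ranking <- suppressWarnings(rank_herbs(
    scores,
    p_threshold = config$p_threshold,
    min_active_compounds = config$min_active_compounds,
    top_n = config$top_n
  ))
  readr::write_tsv(as_tibble(ranking), file.path(out_dir, "herb_ranking.tsv"),
                   progress = FALSE)
  note("stage prioritize: %d herb(s) ranked", nrow(ranking))

  compound_rankings <- list()
  for (h in ranking$entity) {
    cr <- suppressMessages(suppressWarnings(rank_compounds(
      net, catalog, h, disease,
      params = config$walk, p_threshold = config$p_threshold
    )))
    compound_rankings[[h]] <- cr
    readr::write_tsv(as_tibble(cr),
                     file.path(out_dir, paste0("compounds_", h, ".tsv")),
                     progress = FALSE)
  }
  note("stage compounds: rankings for %d herb(s)", length(compound_rankings))

  # enrichment of the ranked herbs' pooled target sets
  enr <- NULL
  query <- unique(unlist(targets[ranking$entity]))
  lib <- enrichment_library(gmt, net)
  if (length(query) > 0 && length(lib) > 0) {
    enr <- suppressMessages(enrich_sets(
      query, lib,
      background = nodes_of_class(net, "protein"),
      n_random = config$n_random_enrich, seed = config$seed
    ))
    readr::write_tsv(as_tibble(enr), file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    note("stage enrich: %d term(s) scored on %d-gene query",
         nrow(enr), length(query))
  } else {
    note("stage enrich: skipped (empty query or library)")
  }

  # mechanism subnetworks for the passing compounds of the top herb
  mechanisms <- list()
  if (nrow(ranking) > 0) {
    top_herb <- ranking$entity[1]
    cr <- compound_rankings[[top_herb]]
    model <- attr(cr, "model")
    dprof <- attr(cr, "disease_profile")
    if (!is.null(model) && nrow(cr) > 0) {
      mech_net <- mechanism_parent_network(net, catalog, cr$entity, disease)
      mech_model <- transition_model(mech_net, config$walk)
      dprof2 <- diffusion_profile(mech_model, disease$id, config$walk)
      for (cp in cr$entity) {
        cprof <- diffusion_profile(mech_model, cp, config$walk)
        sub <- mechanism_subnetwork(mech_net, cprof, dprof2, k = config$k)
        mechanisms[[cp]] <- sub
        write_subnetwork(sub, file.path(out_dir, paste0("mechanism_", cp, ".graphml")),
                         "graphml")
        write_subnetwork(sub, file.path(out_dir, paste0("mechanism_", cp, ".sif")),
                         "sif")
      }
      note("stage mechanism: %d subnetwork(s) for %s", length(mechanisms),
           top_herb)
    }
  }

  manifest <- list(
    package = "herbwalk",
    version = as.character(utils::packageVersion("herbwalk")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = yaml::yaml.load(config_as_yaml(config)),
    config_hash = rlang::hash(config_as_yaml(config)),
    n_herbs_ranked = nrow(ranking)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)

  invisible(list(
    herb_ranking = ranking, compound_rankings = compound_rankings,
    enrichment = enr, mechanisms = mechanisms, manifest = manifest
  ))
}

# default enrichment library: one set per annotated function node
enrichment_library <- function(gmt, net) {
  if (is.list(gmt)) return(gmt)
  if (is.character(gmt)) return(read_gmt(gmt))
  pf <- filter(net$edges, .data$edge_class == "protein_function")
  if (nrow(pf) == 0) return(list())
  # edges are stored in canonical order, so pick endpoints by class
  cls <- setNames(net$nodes$class, net$nodes$node)
  protein_side <- ifelse(cls[pf$from] == "protein", pf$from, pf$to)
  function_side <- ifelse(cls[pf$from] == "protein", pf$to, pf$from)
  split(protein_side, function_side)
}

# the parent network used for mechanism extraction: disease plus the
# passing compounds attached
mechanism_parent_network <- function(net, catalog, compounds, disease) {
  proteins <- nodes_of_class(net, "protein")
  full <- attach_entity(net, disease$id, "disease",
                        intersect(toupper(disease$genes), proteins))
  ct <- filter(catalog$compound_target, .data$compound %in% compounds)
  tsets <- split(ct$target, ct$compound)
  attach_entities(full, tsets, "compound", quiet = TRUE)
}
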