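#' Configuration for a synthetic multiscale world
#'
#' Describes a self-contained toy world with the structure the analysis
#' assumes: a scale-free PPI layer, a rooted function hierarchy with sparse
#' leaf annotations, herbs with variable ingredient counts (some below the
#' 3-ingredient filter), compounds with small target sets, a connected
#' disease module, and one planted herb whose compound targets concentrate
#' on the disease module and its 1-hop neighborhood.
#'
#' @param n_proteins Number of protein nodes (default 200).
#' @param n_functions Number of function nodes (default 50).
#' @param ppi_attachment Edges added per new protein in the preferential-
#'   attachment PPI layer (default 2).
#' @param annotation_rate Mean protein-function annotations per protein
#'   (Poisson; default 1).
#' @param n_herbs Herb count, planted herb included (default 10).
#' @param compounds_per_herb Inclusive range of compounds per decoy herb
#'   (default `c(2, 8)`, so some herbs fall below the 3-ingredient floor);
#'   the planted herb always draws from `pmax(compounds_per_herb, 5)`, so it
#'   emulates a genuinely active herb that is eligible under both the
#'   3-ingredient floor and the 5-active-compound selection rule.
#' @param targets_per_compound Inclusive range of targets per compound
#'   (default `c(1, 5)`).
#' @param disease_size Disease-module size (default 20).
#' @param planted_herb_proximity Fraction of the planted herb's target draws
#'   taken from the disease module and its 1-hop neighborhood (default 0.9);
#'   within that pool, half the mass sits on the module itself.
#' @param seed RNG seed; generation is a pure function of config + seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 200, n_functions = 50,
                             ppi_attachment = 2, annotation_rate = 1,
                             n_herbs = 10, compounds_per_herb = c(2, 8),
                             targets_per_compound = c(1, 5),
                             disease_size = 20,
                             planted_herb_proximity = 0.9, seed = 1) {
  cfg <- list(
    n_proteins = n_proteins, n_functions = n_functions,
    ppi_attachment = ppi_attachment, annotation_rate = annotation_rate,
    n_herbs = n_herbs, compounds_per_herb = compounds_per_herb,
    targets_per_compound = targets_per_compound,
    disease_size = disease_size,
    planted_herb_proximity = planted_herb_proximity, seed = seed
  )
  with(cfg, {
    if (disease_size > n_proteins) {
      abort("disease_size cannot exceed n_proteins", class = "herbwalk_config_error")
    }
    stopifnot(
      n_proteins >= 10, n_functions >= 3, ppi_attachment >= 1,
      annotation_rate > 0, n_herbs >= 2,
      length(compounds_per_herb) == 2, compounds_per_herb[1] >= 1,
      diff(compounds_per_herb) >= 0,
      length(targets_per_compound) == 2, targets_per_compound[1] >= 1,
      diff(targets_per_compound) >= 0,
      disease_size >= 3,
      planted_herb_proximity >= 0, planted_herb_proximity <= 1
    )
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic multiscale world
#'
#' Builds the full input bundle for the pipeline from a
#' [synthetic_config()]: network layers, herb catalog, disease gene set, and
#' the ground-truth record of the planted herb and its compounds.  The PPI
#' layer is a preferential-attachment graph; the function hierarchy is a
#' random rooted tree whose leaves receive protein annotations; the disease
#' module is a breadth-first ball around the highest-degree protein; decoy
#' herbs draw targets uniformly from non-disease proteins, while the planted
#' herb draws a `planted_herb_proximity` fraction from the disease module
#' and its 1-hop ring.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_world`: list with `network` (a
#'   `multiscale_network`), `catalog` (`herb_catalog`), `disease` (list
#'   `id`, `genes`), `planted_herb`, `planted_compounds`, layer tibbles
#'   (`ppi`, `protein_function`, `function_hierarchy`), and `config`.
#' @export
generate_world <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  functions <- sprintf("F%03d", seq_len(cfg$n_functions))

  g <- igraph::sample_pa(cfg$n_proteins, m = cfg$ppi_attachment,
                         directed = FALSE)
  igraph::V(g)$name <- proteins
  ed <- igraph::as_data_frame(g, what = "edges")
  ppi <- tibble(from = ed$from, to = ed$to)

  # rooted random tree: node i > 1 attaches to a uniform earlier node
  parent <- vapply(2:cfg$n_functions, function(i) sample.int(i - 1, 1), 1L)
  hierarchy <- tibble(from = functions[parent], to = functions[2:cfg$n_functions])
  leaves <- setdiff(functions, functions[parent])

  n_annot <- pmin(rpois(cfg$n_proteins, cfg$annotation_rate), length(leaves))
  pf <- purrr::map2(proteins, n_annot, function(p, k) {
    if (k == 0) return(NULL)
    tibble(from = p, to = sample(leaves, k))
  }) |> bind_rows()
  if (nrow(pf) == 0) pf <- tibble(from = proteins[1], to = leaves[1])

  net <- assemble_network(ppi, pf, hierarchy, quiet = TRUE)

  # disease module: breadth-first ball around the top-degree protein
  deg <- igraph::degree(g)
  center <- proteins[which.max(deg)]
  bfs_order <- igraph::as_ids(igraph::bfs(g, root = center)$order)
  disease_genes <- bfs_order[seq_len(cfg$disease_size)]
  ring <- setdiff(
    unique(unlist(igraph::adjacent_vertices(g, disease_genes) |>
                    map(igraph::as_ids))),
    disease_genes
  )
  non_disease <- setdiff(proteins, disease_genes)

  herbs <- sprintf("H%02d", seq_len(cfg$n_herbs))
  planted <- herbs[1]
  cmp_counter <- 0L
  hc_rows <- list()
  ct_rows <- list()
  planted_compounds <- character()

  for (h in herbs) {
    rng <- cfg$compounds_per_herb
    if (h == planted) rng <- pmax(rng, 5)
    n_cmp <- sample(seq(rng[1], rng[2]), 1)
    for (ci in seq_len(n_cmp)) {
      cmp_counter <- cmp_counter + 1L
      cp <- sprintf("C%04d", cmp_counter)
      trng <- cfg$targets_per_compound
      n_t <- sample(seq(trng[1], trng[2]), 1)
      targets <- if (h == planted) {
        draw_planted_targets(n_t, cfg$planted_herb_proximity,
                             disease_genes, ring, proteins)
      } else {
        sample(non_disease, min(n_t, length(non_disease)))
      }
      hc_rows[[length(hc_rows) + 1L]] <- tibble(herb = h, compound = cp)
      ct_rows[[length(ct_rows) + 1L]] <- tibble(compound = cp, target = targets)
      if (h == planted) planted_compounds <- c(planted_compounds, cp)
    }
  }

  catalog <- herb_catalog(bind_rows(hc_rows), bind_rows(ct_rows))
  structure(
    list(
      network = net, catalog = catalog,
      disease = list(id = "DISEASE", genes = disease_genes),
      planted_herb = planted, planted_compounds = planted_compounds,
      ppi = ppi, protein_function = pf, function_hierarchy = hierarchy,
      config = cfg
    ),
    class = "synthetic_world"
  )
}

# planted draws: with prob `proximity` a proximal draw (half mass on the
# disease module, half on its 1-hop ring), else uniform over all proteins
draw_planted_targets <- function(n, proximity, module, ring, proteins) {
  pool_draw <- function() {
    if (stats::runif(1) < proximity) {
      if (length(ring) == 0 || stats::runif(1) < 0.5) {
        sample(module, 1)
      } else {
        sample(ring, 1)
      }
    } else {
      sample(proteins, 1)
    }
  }
  out <- character()
  tries <- 0
  while (length(out) < n && tries < 50 * n) {
    out <- unique(c(out, pool_draw()))
    tries <- tries + 1
  }
  out
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> seed %d: %d protein(s), %d function(s), %d herb(s) (planted: %s), disease module %d\n",
    x$config$seed, x$config$n_proteins, x$config$n_functions,
    x$config$n_herbs, x$planted_herb, x$config$disease_size
  ))
  invisible(x)
}

#' Write a synthetic world as the standard input bundle
#'
#' Emits `ppi.tsv`, `protein_function.tsv`, `function_hierarchy.tsv`,
#' `herb_compound.tsv`, `compound_target.tsv`, `disease.gmt`, and
#' `truth.json` into a directory.  Output is byte-deterministic for a fixed
#' config + seed.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w_tsv <- function(df, name) {
    readr::write_tsv(df, file.path(dir, name), col_names = FALSE,
                     progress = FALSE)
  }
  w_tsv(world$ppi, "ppi.tsv")
  w_tsv(world$protein_function, "protein_function.tsv")
  w_tsv(world$function_hierarchy, "function_hierarchy.tsv")
  w_tsv(world$catalog$herb_compound, "herb_compound.tsv")
  w_tsv(world$catalog$compound_target, "compound_target.tsv")
  write_gmt(setNames(list(world$disease$genes), world$disease$id),
            file.path(dir, "disease.gmt"))
  jsonlite::write_json(
    list(planted_herb = world$planted_herb,
         planted_compounds = world$planted_compounds,
         config = unclass(world$config)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' Deterministic overlap micro-fixture
#'
#' A tiny deterministic bundle of ten herb target sets with fixed overlap
#' counts `k` out of `n` targets against a configurable background, used to
#' exercise the overlap and fold-enrichment statistics on the exact (k, n)
#' patterns of the candidate-herb table: (2/50), (5/50), (2/27), (2/26),
#' (2/38), (1/11), (4/50) x 3, (3/50).
#'
#' @param background_size Universe size N (default 4227).
#' @param disease_size Disease-set size K (default 10), so the default
#'   background fraction K/N is exactly 10/4227.
#' @return List with `background`, `disease_genes`, `herb_targets` (named
#'   list), and a `table` tibble (`herb`, `k`, `n`).
#' @export
overlap_toy <- function(background_size = 4227, disease_size = 10) {
  stopifnot(disease_size < background_size)
  pattern <- tibble(
    herb = sprintf("H%02d", 1:10),
    k = c(2L, 5L, 2L, 2L, 2L, 1L, 4L, 4L, 4L, 3L),
    n = c(50L, 50L, 27L, 26L, 38L, 11L, 50L, 50L, 50L, 50L)
  )
  stopifnot(max(pattern$k) <= disease_size,
            sum(pattern$n - pattern$k) <= background_size - disease_size)
  background <- sprintf("G%05d", seq_len(background_size))
  disease_genes <- background[seq_len(disease_size)]
  offset <- disease_size
  herb_targets <- vector("list", nrow(pattern))
  for (i in seq_len(nrow(pattern))) {
    n_out <- pattern$n[i] - pattern$k[i]
    herb_targets[[i]] <- c(
      disease_genes[seq_len(pattern$k[i])],
      background[offset + seq_len(n_out)]
    )
    offset <- offset + n_out
  }
  names(herb_targets) <- pattern$herb
  list(
    background = background, disease_genes = disease_genes,
    herb_targets = herb_targets, table = pattern
  )
}
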