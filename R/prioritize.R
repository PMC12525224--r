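#' Correlation score between two diffusion profiles
#'
#' Entity-disease similarity is the correlation of the two visitation-
#' frequency vectors over the shared protein and function nodes.  All
#' entity-class nodes (herb, compound, disease) are excluded so that an
#' entity's own seed mass cannot inflate similarity.
#'
#' @param p,q `diffusion_profile`s computed on the same network.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_freq Correlate `log10(frequency + 1e-12)` instead of raw
#'   frequencies.
#' @return A single correlation in \[-1, 1\].
#' @export
correlation_score <- function(p, q, method = c("pearson", "spearman"),
                              log_freq = FALSE) {
  method <- rlang::arg_match(method)
  stopifnot(inherits(p, "diffusion_profile"), inherits(q, "diffusion_profile"))
  keep <- !(p$classes %in% ENTITY_CLASSES)
  common <- names(p$frequency)[keep]
  if (!setequal(names(p$frequency)[keep],
                names(q$frequency)[!(q$classes %in% ENTITY_CLASSES)])) {
    abort("profiles are not over the same network",
          class = "herbwalk_consistency_error")
  }
  x <- p$frequency[common]
  y <- q$frequency[common]
  if (log_freq) {
    x <- log10(x + 1e-12)
    y <- log10(y + 1e-12)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero-variance profile: correlation undefined",
          class = "herbwalk_degenerate_error")
  }
  unname(cor(x, y, method = method))
}

#' One-sided hypergeometric overlap test
#'
#' Tests whether an entity's target set overlaps a disease target set more
#' than expected when drawing from a background universe: with
#' `N = |background|`, `K = |disease|`, `n = |entity|` and `k` the observed
#' overlap, the p-value is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`.  Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param entity_targets,disease_targets Character vectors of gene symbols;
#'   must be subsets of `background`.
#' @param background Character vector: the target universe.
#' @return A one-row tibble: `k`, `n`, `K`, `N`, `p_value`, `enrichment`.
#' @export
#' @examples
#' hypergeom_overlap(c("A", "B", "C"), c("B", "C", "D"), LETTERS[1:10])
hypergeom_overlap <- function(entity_targets, disease_targets, background) {
  entity_targets <- unique(entity_targets)
  disease_targets <- unique(disease_targets)
  background <- unique(background)
  if (length(entity_targets) == 0 || length(disease_targets) == 0) {
    abort("target sets must be nonempty", class = "herbwalk_empty_input")
  }
  out <- setdiff(c(entity_targets, disease_targets), background)
  if (length(out) > 0) {
    abort(paste0("target(s) outside the background universe: ",
                 paste(head(out, 5), collapse = ", ")),
          class = "herbwalk_domain_error")
  }
  k <- length(intersect(entity_targets, disease_targets))
  n <- length(entity_targets)
  K <- length(disease_targets)
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(
    k = k, n = n, K = K, N = N,
    p_value = p,
    enrichment = fold_enrichment(k, n, K / N)
  )
}

#' Fold enrichment of an overlap against a background rate
#'
#' Ratio of the observed overlap rate `k / n` to the background fraction of
#' disease targets.
#'
#' @param k Overlap count.
#' @param n Entity target-set size (> 0).
#' @param background_fraction Background disease-target rate in (0, 1).
#' @return `(k / n) / background_fraction`.
#' @export
#' @examples
#' fold_enrichment(5, 50, 10 / 4227)
fold_enrichment <- function(k, n, background_fraction) {
  stopifnot(n > 0, k >= 0, k <= n,
            background_fraction > 0, background_fraction < 1)
  (k / n) / background_fraction
}

#' Score entities against a disease diffusion profile
#'
#' Attaches the disease and every entity to one copy of the network, runs
#' the biased walk from each node, and reports per entity the correlation
#' score against the disease profile plus the hypergeometric overlap
#' statistics of its target set.  Entities with no network-mapped target are
#' excluded (reported via the `skipped` attribute).
#'
#' @param net A `multiscale_network` *without* entities attached.
#' @param entity_targets Named list: entity id -> target gene symbols.
#' @param entity_class `"herb"` or `"compound"`.
#' @param disease List with `id` and `genes` (see [read_disease_genes()]).
#' @param params A [walk_params()] object.
#' @param background Background universe for the overlap test; default: all
#'   proteins of the network.
#' @param method Correlation method, passed to [correlation_score()].
#' @return A tibble (`entity`, `correlation_score`, `k`, `n`, `K`, `N`,
#'   `p_value`, `enrichment`), one row per linked entity, unsorted.
#' @export
score_entities <- function(net, entity_targets, entity_class, disease,
                           params = walk_params(), background = NULL,
                           method = "pearson") {
  stopifnot(inherits(net, "multiscale_network"))
  proteins <- nodes_of_class(net, "protein")
  background <- background %||% proteins
  disease_mapped <- intersect(disease$genes, proteins)
  if (length(disease_mapped) == 0) {
    abort("no disease gene maps onto the network", class = "herbwalk_unlinked")
  }

  full <- attach_entity(net, disease$id, "disease", disease_mapped)
  full <- attach_entities(full, entity_targets, entity_class, quiet = TRUE)
  skipped <- attr(full, "skipped")
  kept <- setdiff(names(entity_targets), skipped)
  if (length(kept) == 0) {
    warn("no entity could be linked to the network")
    return(structure(empty_score_tbl(), skipped = skipped))
  }

  model <- transition_model(full, params)
  dprof <- diffusion_profile(model, disease$id, params)
  bg_disease <- intersect(disease_mapped, background)

  rows <- map(kept, function(id) {
    prof <- diffusion_profile(model, id, params)
    targs <- intersect(unique(entity_targets[[id]]), background)
    ov <- hypergeom_overlap(targs, bg_disease, background)
    mutate(ov,
      entity = id,
      correlation_score = correlation_score(prof, dprof, method = method),
      .before = 1
    )
  })
  out <- bind_rows(rows)
  attr(out, "skipped") <- skipped
  attr(out, "disease_profile") <- dprof
  attr(out, "model") <- model
  out
}

empty_score_tbl <- function() {
  tibble(
    entity = character(), correlation_score = numeric(),
    k = integer(), n = integer(), K = integer(), N = integer(),
    p_value = numeric(), enrichment = numeric()
  )
}

#' Rank herbs against the disease
#'
#' Applies the selection rule for candidate herbs: keep herbs with a
#' significant target overlap (`p_value < p_threshold`) and at least
#' `min_active_compounds` active compounds, sort by correlation score
#' (descending; ties by ascending p-value then herb id), and truncate at
#' `top_n`.
#'
#' @param scores Tibble from [score_entities()] (herb mode), with an
#'   `n_active_compounds` column added (see [count_active_compounds()]).
#' @param p_threshold Overlap significance cut-off (default 0.05).
#' @param min_active_compounds Minimum active-compound count (default 5).
#' @param top_n Table length (default 10).
#' @return A `herb_ranking` tibble with `rank` and `passes_filters` columns;
#'   rows failing a filter are dropped.
#' @export
rank_herbs <- function(scores, p_threshold = 0.05, min_active_compounds = 5,
                       top_n = 10) {
  stopifnot(is.data.frame(scores))
  if (!"n_active_compounds" %in% names(scores)) {
    abort("scores must carry n_active_compounds; see count_active_compounds()",
          class = "herbwalk_param_error")
  }
  kept <- scores |>
    mutate(passes_filters = .data$p_value < p_threshold &
             .data$n_active_compounds >= min_active_compounds) |>
    filter(.data$passes_filters) |>
    arrange(desc(.data$correlation_score), .data$p_value, .data$entity) |>
    slice_head(n = top_n) |>
    mutate(rank = row_number(), .before = 1)
  if (nrow(kept) == 0) warn("no herb passes the selection filters")
  class(kept) <- c("herb_ranking", class(kept))
  kept
}

#' Count active compounds per herb
#'
#' An "active" compound under the default rule (`"network_mapped"`) is one
#' with at least one target mapped into the network; under
#' `"disease_target"` it must hit the disease gene set directly.
#'
#' @param catalog A `herb_catalog`.
#' @param net A `multiscale_network`.
#' @param disease_genes Needed for the `"disease_target"` rule.
#' @param active_rule `"network_mapped"` (default) or `"disease_target"`.
#' @return Tibble (`entity`, `n_active_compounds`) over all herbs in the
#'   catalog.
#' @export
count_active_compounds <- function(catalog, net, disease_genes = NULL,
                                   active_rule = c("network_mapped",
                                                   "disease_target")) {
  active_rule <- rlang::arg_match(active_rule)
  proteins <- nodes_of_class(net, "protein")
  pool <- if (active_rule == "network_mapped") {
    proteins
  } else {
    if (is.null(disease_genes)) {
      abort("disease_genes required for the disease_target rule",
            class = "herbwalk_param_error")
    }
    intersect(disease_genes, proteins)
  }
  active <- catalog$compound_target |>
    filter(.data$target %in% pool) |>
    pull("compound") |>
    unique()
  catalog$herb_compound |>
    group_by(entity = .data$herb) |>
    summarise(n_active_compounds = sum(unique(.data$compound) %in% active),
              .groups = "drop")
}

#' Rank a herb's compounds against the disease
#'
#' Computes a diffusion profile for each of the herb's compounds (attached to
#' the same network copy as the disease), correlates it with the disease
#' profile, tests target overlap, drops compounds failing
#' `p_value < p_threshold`, and sorts like [rank_herbs()].  Compounds with no
#' network-mapped target are excluded and reported.
#'
#' @param net A `multiscale_network` without entities.
#' @param catalog A `herb_catalog`.
#' @param herb Herb id (must be present in the catalog).
#' @param disease List with `id` and `genes`.
#' @param params A [walk_params()] object.
#' @param p_threshold Overlap significance cut-off (default 0.05).
#' @param background Overlap background; default all network proteins.
#' @param method Correlation method.
#' @return A `compound_ranking` tibble (possibly empty when no compound
#'   passes).
#' @export
rank_compounds <- function(net, catalog, herb, disease,
                           params = walk_params(), p_threshold = 0.05,
                           background = NULL, method = "pearson") {
  targets <- compound_target_sets(catalog, herb)
  targets <- keep(targets, ~ length(.x) > 0)
  if (length(targets) == 0) {
    warn(paste0("herb ", herb, " has no target-annotated compound"))
    out <- empty_score_tbl()
  } else {
    out <- score_entities(net, targets, "compound", disease,
                          params = params, background = background,
                          method = method)
  }
  ranked <- out |>
    mutate(passes_filters = .data$p_value < p_threshold) |>
    filter(.data$passes_filters) |>
    arrange(desc(.data$correlation_score), .data$p_value, .data$entity) |>
    mutate(rank = row_number(), .before = 1)
  if (nrow(ranked) == 0) {
    warn(paste0("no compound of ", herb, " passes the overlap threshold"))
  }
  attr(ranked, "skipped") <- attr(out, "skipped")
  attr(ranked, "disease_profile") <- attr(out, "disease_profile")
  attr(ranked, "model") <- attr(out, "model")
  class(ranked) <- c("compound_ranking", class(ranked))
  ranked
}

#' @method autoplot herb_ranking
#' @export
autoplot.herb_ranking <- function(object, ...) ranking_plot(object, "herb")

#' @method autoplot compound_ranking
#' @export
autoplot.compound_ranking <- function(object, ...) ranking_plot(object, "compound")

ranking_plot <- function(df, what) {
  df <- as_tibble(df)
  df$entity <- factor(df$entity, levels = rev(df$entity))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$correlation_score,
                                   y = .data$entity)) +
    ggplot2::geom_col(ggplot2::aes(fill = -log10(.data$p_value))) +
    ggplot2::scale_fill_viridis_c(name = "-log10 p") +
    ggplot2::labs(
      x = "correlation with disease profile", y = NULL,
      title = paste0("Ranked ", what, "s")
    ) +
    ggplot2::theme_minimal()
}
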