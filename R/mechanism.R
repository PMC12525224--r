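#' Extract a compound-disease mechanism subnetwork
#'
#' Collects the top-`k` protein/function nodes of the compound profile and
#' of the disease profile, adds both entity nodes, and induces the parent
#' network's edges over this set.  If the result is disconnected, unweighted
#' shortest paths through the parent network are added until it is
#' connected; interior path nodes are tagged `"connector"`.  Provenance per
#' node is one of `compound_topk`, `disease_topk`, `both`, `connector`, or
#' `entity` for the two seeds.
#'
#' @param net The `multiscale_network` the profiles were computed on (with
#'   the compound and disease entities attached).
#' @param compound_profile,disease_profile `diffusion_profile`s seeded at
#'   the compound and disease nodes.
#' @param k Top-k cut-off per profile (default 20).
#' @return A `mechanism_subnetwork`: list with `compound`, `disease`, a
#'   `nodes` tibble (`node`, `class`, `provenance`, `freq_compound`,
#'   `freq_disease`), an `edges` tibble, and the induced `igraph` graph.
#' @export
mechanism_subnetwork <- function(net, compound_profile, disease_profile, k = 20) {
  stopifnot(inherits(net, "multiscale_network"),
            inherits(compound_profile, "diffusion_profile"),
            inherits(disease_profile, "diffusion_profile"), k >= 1)
  cid <- compound_profile$seed
  did <- disease_profile$seed
  if (!all(c(cid, did) %in% net$nodes$node)) {
    abort("profile seeds must be nodes of the network",
          class = "herbwalk_consistency_error")
  }
  if (igraph::degree(net$graph, cid) == 0) {
    abort(paste0("excluded ingredient: ", cid,
                 " is not linked to any disease-related protein or function"),
          class = "herbwalk_unlinked")
  }

  ctop <- profile_top(compound_profile, k = k, classes = c("protein", "function"))$node
  dtop <- profile_top(disease_profile, k = k, classes = c("protein", "function"))$node
  sel <- unique(c(cid, did, ctop, dtop))
  provenance <- dplyr::case_when(
    sel %in% c(cid, did) ~ "entity",
    sel %in% ctop & sel %in% dtop ~ "both",
    sel %in% ctop ~ "compound_topk",
    TRUE ~ "disease_topk"
  )
  names(provenance) <- sel

  g <- igraph::induced_subgraph(net$graph, sel)
  # stitch components together with shortest paths through the full network
  comp <- igraph::components(g)
  while (comp$no > 1) {
    anchor <- names(comp$membership)[comp$membership == comp$membership[[cid]]]
    rest <- setdiff(names(comp$membership), anchor)
    dists <- igraph::distances(net$graph, v = anchor, to = rest)
    if (all(!is.finite(dists))) {
      warn("subnetwork cannot be connected through the parent network")
      break
    }
    hit <- which(dists == min(dists), arr.ind = TRUE)[1, ]
    path <- igraph::shortest_paths(
      net$graph, from = anchor[hit[1]], to = rest[hit[2]]
    )$vpath[[1]]
    path <- igraph::as_ids(path)
    new_nodes <- setdiff(path, names(provenance))
    provenance[new_nodes] <- "connector"
    sel <- unique(c(sel, new_nodes))
    g <- igraph::induced_subgraph(net$graph, sel)
    comp <- igraph::components(g)
  }

  node_cls <- setNames(net$nodes$class, net$nodes$node)
  nodes <- tibble(
    node = sel,
    class = unname(node_cls[sel]),
    provenance = unname(provenance[sel]),
    freq_compound = unname(compound_profile$frequency[sel]),
    freq_disease = unname(disease_profile$frequency[sel])
  )
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- tibble(from = ed$from, to = ed$to, edge_class = ed$edge_class)
  structure(
    list(compound = cid, disease = did, k = k,
         nodes = nodes, edges = edges, graph = g),
    class = "mechanism_subnetwork"
  )
}

#' @export
print.mechanism_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<mechanism_subnetwork> %s ~ %s (k = %d): %d node(s), %d edge(s), %d connector(s)\n",
    x$compound, x$disease, x$k, nrow(x$nodes), nrow(x$edges),
    sum(x$nodes$provenance == "connector")
  ))
  invisible(x)
}

#' @method tidy mechanism_subnetwork
#' @export
tidy.mechanism_subnetwork <- function(x, ...) x$nodes

#' Write a mechanism subnetwork to GraphML or SIF
#'
#' GraphML keeps node `class` and `provenance` attributes plus both
#' visitation frequencies and the typed edges; SIF writes one
#' `source<TAB>edge_class<TAB>target` line per edge.
#'
#' @param sub A `mechanism_subnetwork`.
#' @param path Output file path.
#' @param format `"graphml"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_subnetwork <- function(sub, path, format = c("graphml", "sif")) {
  stopifnot(inherits(sub, "mechanism_subnetwork"))
  format <- rlang::arg_match(format)
  if (format == "graphml") {
    g <- sub$graph
    ord <- match(igraph::V(g)$name, sub$nodes$node)
    igraph::V(g)$provenance <- sub$nodes$provenance[ord]
    igraph::V(g)$freq_compound <- sub$nodes$freq_compound[ord]
    igraph::V(g)$freq_disease <- sub$nodes$freq_disease[ord]
    igraph::write_graph(g, path, format = "graphml")
  } else {
    writeLines(
      sprintf("%s\t%s\t%s", sub$edges$from, sub$edges$edge_class, sub$edges$to),
      path
    )
  }
  invisible(path)
}

#' Read a GraphML subnetwork back
#'
#' Round-trip companion of [write_subnetwork()]: recovers the attributed
#' graph written in GraphML.
#'
#' @param path GraphML file.
#' @return An `igraph` graph with `class`, `provenance` and frequency
#'   attributes.
#' @export
read_subnetwork_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @method autoplot mechanism_subnetwork
#' @export
autoplot.mechanism_subnetwork <- function(object, ...) {
  set_layout <- igraph::layout_with_fr(object$graph)
  lay <- tibble(
    node = igraph::V(object$graph)$name,
    x = set_layout[, 1], y = set_layout[, 2]
  ) |>
    left_join(object$nodes, by = "node")
  seg <- object$edges |>
    left_join(select(lay, "node", "x", "y"), by = c(from = "node")) |>
    left_join(select(lay, "node", "x", "y"), by = c(to = "node"),
              suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$class,
                   shape = .data$provenance),
      size = 3
    ) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = 2.5
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(title = paste0(object$compound, " ~ ", object$disease,
                                 " mechanism subnetwork"))
}
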