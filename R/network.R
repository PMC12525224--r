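#' Assemble the multiscale network
#'
#' Joins the protein-protein interaction layer, the protein-to-function
#' annotation layer, and the function hierarchy into one typed, undirected,
#' unweighted graph.  Node classes (`protein` / `function`) are inferred from
#' layer membership; an id appearing as both a protein and a function is a
#' consistency error.  Isolated proteins or functions (possible after later
#' manipulation) are retained and reported, never dropped.
#'
#' @param ppi Tibble of protein-protein edges (`from`, `to`; an `edge_class`
#'   column, if present, is overwritten).
#' @param protein_function Tibble of protein-function annotation edges; the
#'   `from` column must hold the protein, `to` the function.
#' @param function_hierarchy Tibble of function-function hierarchy edges.
#' @param quiet Suppress assembly messages.
#'
#' @return A `multiscale_network`: a list carrying the `igraph` graph (vertex
#'   attribute `class`, edge attribute `edge_class`) plus tibble views
#'   `nodes` and `edges`.
#' @export
#' @examples
#' net <- assemble_network(
#'   ppi = tibble::tibble(from = "A", to = "B"),
#'   protein_function = tibble::tibble(from = "A", to = "F1"),
#'   function_hierarchy = tibble::tibble(from = "F1", to = "F2")
#' )
#' net$nodes
assemble_network <- function(ppi, protein_function, function_hierarchy,
                             quiet = FALSE) {
  ppi_raw <- as_tibble(ppi)
  pf_raw <- as_tibble(protein_function)
  fh_raw <- as_tibble(function_hierarchy)
  ppi <- as_edge_tbl(ppi_raw, "ppi")
  pf <- as_edge_tbl(pf_raw, "protein_function")
  fh <- as_edge_tbl(fh_raw, "function_hierarchy")
  if (nrow(ppi) == 0 || nrow(pf) == 0 || nrow(fh) == 0) {
    abort("all three layers must be nonempty", class = "herbwalk_empty_input")
  }

  # layer membership comes from the raw orientation (annotation edges list
  # the protein first), before edges are canonicalized for storage
  proteins <- unique(c(ppi_raw$from, ppi_raw$to, pf_raw$from))
  functions <- unique(c(pf_raw$to, fh_raw$from, fh_raw$to))
  clash <- intersect(proteins, functions)
  if (length(clash) > 0) {
    abort(
      paste0(
        "node id(s) used as both protein and function: ",
        paste(head(clash, 5), collapse = ", ")
      ),
      class = "herbwalk_class_conflict"
    )
  }

  nodes <- tibble(
    node = c(proteins, functions),
    class = c(rep("protein", length(proteins)), rep("function", length(functions)))
  )
  edges <- bind_rows(ppi, pf, fh)
  net <- new_msnet(nodes, edges)

  deg <- igraph::degree(net$graph)
  isolated <- names(deg)[deg == 0]
  if (!quiet) {
    inform(sprintf(
      "assembled network: %d protein(s), %d function(s), %d edge(s)%s",
      length(proteins), length(functions), nrow(edges),
      if (length(isolated) > 0) {
        sprintf("; %d isolated node(s): %s",
                length(isolated), paste(head(isolated, 5), collapse = ", "))
      } else ""
    ))
  }
  net$isolated <- isolated
  net
}

#' Construct a multiscale network from node and edge tables
#'
#' Low-level constructor used when the layer-wise [assemble_network()] entry
#' point is too coarse (e.g. hand-built micro-networks).  Validates id
#' uniqueness, endpoint existence, and edge-class/node-class compatibility.
#'
#' @param nodes Tibble with columns `node`, `class`.
#' @param edges Tibble with columns `from`, `to`, `edge_class`.
#' @return A `multiscale_network`.
#' @export
multiscale_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)[, c("node", "class")]
  stopifnot(all(nodes$class %in% NODE_CLASSES))
  edges <- normalize_edges(as_tibble(edges)[, c("from", "to", "edge_class")])
  stopifnot(all(edges$edge_class %in% EDGE_CLASSES))
  new_msnet(nodes, edges)
}

as_edge_tbl <- function(x, edge_class) {
  x <- as_tibble(x)
  stopifnot(all(c("from", "to") %in% names(x)))
  x$edge_class <- edge_class
  normalize_edges(x[, c("from", "to", "edge_class")])
}

new_msnet <- function(nodes, edges) {
  stopifnot(!anyDuplicated(nodes$node))
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$node)
  if (length(missing_ep) > 0) {
    abort(paste0("edge endpoint(s) not in node table: ",
                 paste(head(missing_ep, 5), collapse = ", ")),
          class = "herbwalk_consistency_error")
  }
  check_edge_endpoints(nodes, edges)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = as.data.frame(nodes)
  )
  structure(
    list(graph = g, nodes = nodes, edges = edges, isolated = character()),
    class = "multiscale_network"
  )
}

check_edge_endpoints <- function(nodes, edges) {
  cls <- setNames(nodes$class, nodes$node)
  for (ec in unique(edges$edge_class)) {
    want <- EDGE_ENDPOINTS[[ec]]
    e <- edges[edges$edge_class == ec, ]
    got <- cbind(cls[e$from], cls[e$to])
    ok <- (got[, 1] == want[1] & got[, 2] == want[2]) |
      (got[, 1] == want[2] & got[, 2] == want[1])
    if (!all(ok)) {
      i <- which(!ok)[1]
      abort(
        sprintf(
          "edge class %s cannot join a %s to a %s (%s -- %s)",
          ec, got[i, 1], got[i, 2], e$from[i], e$to[i]
        ),
        class = "herbwalk_consistency_error"
      )
    }
  }
  invisible(TRUE)
}

#' @export
print.multiscale_network <- function(x, ...) {
  tab <- table(x$nodes$class)
  cat("<multiscale_network>",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
      "|", nrow(x$edges), "edge(s)\n")
  invisible(x)
}

#' Attach an entity node to the network
#'
#' Adds one herb, compound, or disease node wired by a typed edge to each of
#' its target proteins that exists in the network.  An entity none of whose
#' targets map signals an `"entity unlinked"` condition, mirroring the
#' exclusion of ingredients with no network-mapped targets.
#'
#' @param net A `multiscale_network`.
#' @param id Entity node id (must not collide with an existing node).
#' @param entity_class `"herb"`, `"compound"`, or `"disease"`.
#' @param targets Character vector of gene symbols; ids are matched verbatim
#'   (file readers normalize symbols to uppercase at the I/O boundary).
#' @return The augmented network; the number of unmapped symbols is recorded
#'   in `attr(net, "unmapped")[[id]]`.
#' @export
attach_entity <- function(net, id, entity_class, targets) {
  stopifnot(inherits(net, "multiscale_network"))
  entity_class <- rlang::arg_match(entity_class, ENTITY_CLASSES)
  targets <- unique(targets)
  if (length(targets) == 0) {
    abort("targets must be nonempty", class = "herbwalk_empty_input")
  }
  if (id %in% net$nodes$node) {
    abort(paste0("node id already present: ", id),
          class = "herbwalk_consistency_error")
  }
  proteins <- net$nodes$node[net$nodes$class == "protein"]
  mapped <- intersect(targets, proteins)
  if (length(mapped) == 0) {
    abort(
      paste0("entity unlinked: no targets of ", id, " map onto the network"),
      class = "herbwalk_unlinked"
    )
  }
  ec <- switch(entity_class,
    herb = "herb_target", compound = "compound_target", disease = "disease_gene"
  )
  nodes <- bind_rows(net$nodes, tibble(node = id, class = entity_class))
  edges <- bind_rows(
    net$edges,
    normalize_edges(tibble(from = id, to = mapped, edge_class = ec))
  )
  out <- new_msnet(nodes, edges)
  out$isolated <- net$isolated
  unmapped <- attr(net, "unmapped") %||% list()
  unmapped[[id]] <- length(targets) - length(mapped)
  attr(out, "unmapped") <- unmapped
  out
}

#' Attach a batch of entities
#'
#' Convenience wrapper around [attach_entity()]: attaches every entity in a
#' named list of target vectors, silently skipping (but reporting) entities
#' with no mapped target.
#'
#' @param net A `multiscale_network`.
#' @param targets Named list: entity id -> character vector of targets.
#' @param entity_class Class for all attached entities.
#' @param quiet Suppress the skip report.
#' @return The augmented network, with attribute `"skipped"` listing unlinked
#'   entity ids.
#' @export
attach_entities <- function(net, targets, entity_class, quiet = FALSE) {
  skipped <- character()
  for (id in names(targets)) {
    out <- tryCatch(
      attach_entity(net, id, entity_class, targets[[id]]),
      herbwalk_unlinked = function(e) NULL,
      herbwalk_empty_input = function(e) NULL
    )
    if (is.null(out)) skipped <- c(skipped, id) else net <- out
  }
  if (length(skipped) > 0 && !quiet) {
    inform(sprintf(
      "skipped %d unlinked %s entit(ies): %s",
      length(skipped), entity_class, paste(head(skipped, 5), collapse = ", ")
    ))
  }
  attr(net, "skipped") <- skipped
  net
}

#' Node ids of a given class
#'
#' @param net A `multiscale_network`.
#' @param classes Character vector of node classes.
#' @return Character vector of node ids.
#' @export
nodes_of_class <- function(net, classes) {
  net$nodes$node[net$nodes$class %in% classes]
}
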