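#' Random-walk parameters
#'
#' Bundles the tunables of the class-biased random walk with restart.  At
#' every step the walker restarts at its seed with probability
#' `restart_prob`; otherwise it moves to a neighbor with probability
#' proportional to the weight of the joining edge's class.  Larger
#' `class_weights["protein_function"]` biases the walk toward
#' biological-function nodes.
#'
#' @param restart_prob Restart probability in (0, 1].
#' @param class_weights Named positive multipliers per edge class; classes
#'   not named keep weight 1.
#' @param tol L1 convergence threshold for power iteration.
#' @param max_iter Iteration cap.
#' @return A `walk_params` list.
#' @export
walk_params <- function(restart_prob = 0.5, class_weights = NULL,
                        tol = 1e-10, max_iter = 500) {
  w <- setNames(rep(1, length(EDGE_CLASSES)), EDGE_CLASSES)
  if (!is.null(class_weights)) {
    bad <- setdiff(names(class_weights), EDGE_CLASSES)
    if (length(bad) > 0) {
      abort(paste0("unknown edge class in weights: ", paste(bad, collapse = ", ")),
            class = "herbwalk_param_error")
    }
    w[names(class_weights)] <- class_weights
  }
  if (!(restart_prob > 0 && restart_prob <= 1)) {
    abort("restart_prob must lie in (0, 1]", class = "herbwalk_param_error")
  }
  if (any(w <= 0)) {
    abort("class weights must be positive", class = "herbwalk_param_error")
  }
  if (tol <= 0 || max_iter < 1) {
    abort("tol must be > 0 and max_iter >= 1", class = "herbwalk_param_error")
  }
  structure(
    list(restart_prob = restart_prob, class_weights = w,
         tol = tol, max_iter = as.integer(max_iter)),
    class = "walk_params"
  )
}

#' Build the class-biased transition operator
#'
#' Converts the network into a sparse column-stochastic matrix: entry (v, u)
#' is the probability of stepping from u to v, i.e. the class weight of the
#' u--v edge normalised by the total class weight over u's neighbors.
#' Isolated nodes get a self-loop so the operator stays stochastic.
#'
#' @param net A `multiscale_network`.
#' @param params A [walk_params()] object.
#' @return A `transition_model`: list with the sparse matrix `M` (columns are
#'   source nodes), `nodes` (id vector) and `classes` (node class vector).
#' @export
transition_model <- function(net, params = walk_params()) {
  stopifnot(inherits(net, "multiscale_network"), inherits(params, "walk_params"))
  nodes <- net$nodes$node
  if (length(nodes) == 0) abort("empty network", class = "herbwalk_empty_input")
  idx <- setNames(seq_along(nodes), nodes)
  e <- net$edges
  w <- params$class_weights[e$edge_class]
  # undirected: each edge contributes u->v and v->u
  i <- c(idx[e$to], idx[e$from])
  j <- c(idx[e$from], idx[e$to])
  x <- c(w, w)
  W <- Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(nodes), length(nodes)), dimnames = list(nodes, nodes)
  )
  colsum <- Matrix::colSums(W)
  iso <- which(colsum == 0)
  if (length(iso) > 0) {
    W <- W + Matrix::sparseMatrix(
      i = iso, j = iso, x = rep(1, length(iso)),
      dims = dim(W), dimnames = dimnames(W)
    )
    colsum[iso] <- 1
  }
  M <- W %*% Matrix::Diagonal(x = 1 / colsum)
  dimnames(M) <- list(nodes, nodes)
  structure(
    list(M = M, nodes = nodes, classes = net$nodes$class),
    class = "transition_model"
  )
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d node(s), %d nonzero transition(s)\n",
              length(x$nodes), length(x$M@x)))
  invisible(x)
}

#' Compute a diffusion profile by power iteration
#'
#' Solves `r = a * e_seed + (1 - a) * M r` (restart probability `a`,
#' transition operator `M`) by fixed-point iteration from the seed indicator
#' vector, stopping when the L1 change drops below `params$tol`.  The result
#' is the stationary visitation-frequency vector of the biased walk with
#' restart seeded at `seed`.
#'
#' @param model A [transition_model()].
#' @param seed Seed node id (usually an attached entity node).
#' @param params A [walk_params()] object; `restart_prob`, `tol` and
#'   `max_iter` are used here.
#' @return A `diffusion_profile`: list with `seed`, named numeric
#'   `frequency` (sums to 1), `iterations`, `converged`, and the node
#'   `classes`.
#' @export
diffusion_profile <- function(model, seed, params = walk_params()) {
  stopifnot(inherits(model, "transition_model"), inherits(params, "walk_params"))
  if (!seed %in% model$nodes) {
    abort(paste0("seed node not in network: ", seed),
          class = "herbwalk_lookup_error")
  }
  a <- params$restart_prob
  n <- length(model$nodes)
  e <- numeric(n)
  e[match(seed, model$nodes)] <- 1
  r <- e
  converged <- FALSE
  iter <- 0L
  if (a == 1) {
    converged <- TRUE
  } else {
    for (iter in seq_len(params$max_iter)) {
      r_new <- a * e + (1 - a) * as.numeric(model$M %*% r)
      delta <- sum(abs(r_new - r))
      r <- r_new
      if (delta < params$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warn(sprintf("diffusion from %s did not converge in %d iterations",
                 seed, params$max_iter))
  }
  r <- r / sum(r)
  new_diffusion_profile(seed, setNames(r, model$nodes), model$classes,
                        iterations = iter, converged = converged)
}

new_diffusion_profile <- function(seed, frequency, classes,
                                  iterations = NA_integer_, converged = TRUE) {
  structure(
    list(seed = seed, frequency = frequency, classes = classes,
         iterations = iterations, converged = converged),
    class = "diffusion_profile"
  )
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf(
    "<diffusion_profile> seed %s over %d node(s); %s after %s iteration(s)\n",
    x$seed, length(x$frequency),
    if (x$converged) "converged" else "NOT converged", x$iterations
  ))
  invisible(x)
}

#' Exact diffusion profile by dense linear solve
#'
#' Verification oracle for [diffusion_profile()]: solves
#' `(I - (1 - a) M) r = a e_seed` directly.  Refuses networks above
#' `max_nodes` nodes, since the solve is dense.
#'
#' @inheritParams diffusion_profile
#' @param restart_prob Restart probability in (0, 1].
#' @param max_nodes Dense-solve size guard (default 2000).
#' @return A `diffusion_profile` with `iterations = NA`.
#' @export
diffusion_profile_exact <- function(model, seed, restart_prob = 0.5,
                                    max_nodes = 2000) {
  stopifnot(inherits(model, "transition_model"))
  n <- length(model$nodes)
  if (n > max_nodes) {
    abort(sprintf("network too large for dense solve (%d > %d nodes)",
                  n, max_nodes),
          class = "herbwalk_size_error")
  }
  if (!seed %in% model$nodes) {
    abort(paste0("seed node not in network: ", seed),
          class = "herbwalk_lookup_error")
  }
  if (!(restart_prob > 0 && restart_prob <= 1)) {
    abort("restart_prob must lie in (0, 1]", class = "herbwalk_param_error")
  }
  e <- numeric(n)
  e[match(seed, model$nodes)] <- 1
  A <- diag(n) - (1 - restart_prob) * as.matrix(model$M)
  r <- solve(A, restart_prob * e)
  r <- r / sum(r)
  new_diffusion_profile(seed, setNames(r, model$nodes), model$classes)
}

#' Top-k nodes of a diffusion profile
#'
#' Returns the `k` most-visited nodes, optionally restricted to given node
#' classes, excluding the seed node itself.  Ties are broken
#' lexicographically on node id for reproducibility.
#'
#' @param profile A `diffusion_profile`.
#' @param k Number of nodes (default 20); if fewer are available all are
#'   returned.
#' @param classes Optional node-class filter, e.g. `c("protein", "function")`.
#' @return A tibble (`node`, `class`, `frequency`) in rank order.
#' @export
profile_top <- function(profile, k = 20, classes = NULL) {
  stopifnot(inherits(profile, "diffusion_profile"), k >= 1)
  df <- tidy(profile)
  df <- filter(df, .data$node != profile$seed)
  if (!is.null(classes)) df <- filter(df, .data$class %in% classes)
  df |>
    arrange(desc(.data$frequency), .data$node) |>
    slice_head(n = k)
}

#' @describeIn diffusion_profile Tidy a profile into a tibble
#'   (`node`, `class`, `frequency`).
#' @param x A `diffusion_profile`.
#' @param ... Unused.
#' @method tidy diffusion_profile
#' @export
tidy.diffusion_profile <- function(x, ...) {
  tibble(node = names(x$frequency), class = x$classes,
         frequency = unname(x$frequency))
}

#' @describeIn diffusion_profile One-row summary (seed, node count, top-k
#'   visitation share at k = 20, iterations, convergence flag).
#' @method glance diffusion_profile
#' @export
glance.diffusion_profile <- function(x, ...) {
  top <- profile_top(x, k = 20)
  tibble(
    seed = x$seed,
    n_nodes = length(x$frequency),
    top20_share = sum(top$frequency),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @describeIn diffusion_profile Lollipop plot of the top-k visitation
#'   frequencies.
#' @param object A `diffusion_profile`.
#' @param k Nodes to show.
#' @method autoplot diffusion_profile
#' @export
autoplot.diffusion_profile <- function(object, k = 20, ...) {
  df <- profile_top(object, k = k)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$node,
                                   colour = .data$class)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$frequency,
                                       yend = .data$node)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "visitation frequency", y = NULL,
      title = paste0("Diffusion profile: ", object$seed)
    ) +
    ggplot2::theme_minimal()
}
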