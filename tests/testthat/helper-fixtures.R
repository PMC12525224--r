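# shared fixtures and independent oracles ------------------------------------

# exact 3-node path graph a-b-c (all proteins, ppi edges)
path_net <- function() {
  multiscale_network(
    nodes = tibble::tibble(node = c("a", "b", "c"), class = "protein"),
    edges = tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                           edge_class = "ppi")
  )
}

# small three-layer network used across modules
toy_net <- function() {
  assemble_network(
    ppi = tibble::tibble(from = c("A", "B", "A"), to = c("B", "C", "D")),
    protein_function = tibble::tibble(from = c("A", "C"), to = c("F1", "F2")),
    function_hierarchy = tibble::tibble(from = c("F1", "F1"), to = c("F2", "F3")),
    quiet = TRUE
  )
}

# random typed multiscale network; proteins in a connected Erdos-Renyi-ish
# layer, functions in a random tree, sparse annotations
random_net <- function(n_protein = 12, n_function = 5, p_edge = 0.3) {
  proteins <- sprintf("p%02d", seq_len(n_protein))
  functions <- sprintf("f%02d", seq_len(n_function))
  # spanning path keeps the ppi layer connected, extra random edges on top
  ppi <- tibble::tibble(from = proteins[-n_protein], to = proteins[-1])
  pairs <- t(utils::combn(proteins, 2))
  extra <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  if (nrow(extra) > 0) {
    ppi <- dplyr::bind_rows(ppi, tibble::tibble(from = extra[, 1], to = extra[, 2]))
  }
  parent <- vapply(2:n_function, function(i) sample.int(i - 1, 1), 1L)
  fh <- tibble::tibble(from = functions[parent], to = functions[-1])
  pf <- tibble::tibble(
    from = sample(proteins, n_function, replace = TRUE),
    to = functions
  )
  assemble_network(ppi, pf, fh, quiet = TRUE)
}

# independent RWR oracle: dense solve written from the definition, not via
# the package's transition_model internals
rwr_oracle <- function(adj_weights, seed_idx, restart) {
  n <- nrow(adj_weights)
  M <- adj_weights
  for (j in seq_len(n)) {
    s <- sum(M[, j])
    if (s == 0) M[j, j] <- 1 else M[, j] <- M[, j] / s
  }
  e <- numeric(n)
  e[seed_idx] <- 1
  solve(diag(n) - (1 - restart) * M, restart * e)
}

# exhaustive hypergeometric tail by enumeration over all n-subsets
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# hypergeometric tail from the counting formula, independent of phyper
hyper_tail_choose <- function(N, K, n, k) {
  i <- max(k, max(0, n - (N - K))):min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

expect_no_error <- function(expr) expect_error(expr, NA)
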