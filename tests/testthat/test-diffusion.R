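test_that("transition probabilities follow class-weight normalization", {
  # hub protein A: 2 ppi neighbors (B, C) + 2 function neighbors (F1, F2)
  net <- multiscale_network(
    nodes = tibble::tibble(
      node = c("A", "B", "C", "F1", "F2"),
      class = c("protein", "protein", "protein", "function", "function")
    ),
    edges = tibble::tibble(
      from = c("A", "A", "A", "A", "F1"),
      to = c("B", "C", "F1", "F2", "F2"),
      edge_class = c("ppi", "ppi", "protein_function", "protein_function",
                     "function_hierarchy")
    )
  )
  m <- transition_model(net, walk_params(class_weights = c(protein_function = 3)))
  colA <- as.numeric(m$M[, "A"])
  names(colA) <- m$nodes
  expect_equal(colA[c("B", "C", "F1", "F2")],
               c(B = 0.125, C = 0.125, F1 = 0.375, F2 = 0.375))

  # all weights equal -> uniform over neighbors
  m2 <- transition_model(net, walk_params())
  expect_equal(as.numeric(m2$M[, "A"])[m2$nodes != "A"], rep(0.25, 4))
})

test_that("columns are stochastic and isolated nodes self-loop", {
  withr::local_seed(21)
  for (i in 1:5) {
    net <- random_net(n_protein = 15, n_function = 5)
    m <- transition_model(net, walk_params(class_weights = c(ppi = 2)))
    expect_lt(max(abs(Matrix::colSums(m$M) - 1)), 1e-12)
  }
  expect_error(walk_params(class_weights = c(ppi = -1)),
               class = "herbwalk_param_error")
})

test_that("path-graph profile matches the closed form (7/12, 1/3, 1/12)", {
  model <- transition_model(path_net(), walk_params(restart_prob = 0.5))
  prof <- diffusion_profile(model, "a", walk_params(restart_prob = 0.5))
  expect_true(prof$converged)
  expect_equal(unname(prof$frequency[c("a", "b", "c")]),
               c(7 / 12, 1 / 3, 1 / 12), tolerance = 1e-10)
  exact <- diffusion_profile_exact(model, "a", 0.5)
  expect_equal(unname(exact$frequency[c("a", "b", "c")]),
               c(7 / 12, 1 / 3, 1 / 12), tolerance = 1e-12)
})

test_that("restart probability 1 returns the seed indicator", {
  model <- transition_model(toy_net(), walk_params())
  prof <- diffusion_profile(model, "A", walk_params(restart_prob = 1))
  expect_equal(unname(prof$frequency["A"]), 1)
  expect_equal(sum(prof$frequency), 1)
})

test_that("iterative profiles agree with dense solves and with an external oracle", {
  withr::local_seed(42)
  params <- walk_params(restart_prob = 0.4,
                        class_weights = c(protein_function = 2))
  worst <- 0
  for (i in 1:10) {
    net <- random_net(n_protein = sample(8:20, 1), n_function = sample(3:6, 1))
    model <- transition_model(net, params)
    seed <- sample(nodes_of_class(net, "protein"), 1)
    it <- diffusion_profile(model, seed, params)
    ex <- diffusion_profile_exact(model, seed, params$restart_prob)
    worst <- max(worst, max(abs(it$frequency - ex$frequency)))
    expect_equal(sum(it$frequency), 1, tolerance = 1e-9)
    expect_true(all(it$frequency >= 0))

    # independent oracle built from the weighted adjacency definition
    cls <- setNames(net$nodes$class, net$nodes$node)
    n <- nrow(net$nodes)
    W <- matrix(0, n, n, dimnames = list(net$nodes$node, net$nodes$node))
    for (r in seq_len(nrow(net$edges))) {
      e <- net$edges[r, ]
      w <- params$class_weights[[e$edge_class]]
      W[e$from, e$to] <- w
      W[e$to, e$from] <- w
    }
    oracle <- rwr_oracle(W, match(seed, net$nodes$node), params$restart_prob)
    expect_equal(unname(it$frequency[net$nodes$node]), unname(oracle),
                 tolerance = 1e-8)
  }
  expect_lt(worst, 1e-8)
})

test_that("dense solver refuses oversized networks and handles one node", {
  model <- transition_model(path_net(), walk_params())
  expect_error(diffusion_profile_exact(model, "a", 0.5, max_nodes = 2),
               class = "herbwalk_size_error")

  solo <- multiscale_network(
    nodes = tibble::tibble(node = "only", class = "protein"),
    edges = tibble::tibble(from = character(), to = character(),
                           edge_class = character())
  )
  m1 <- transition_model(solo, walk_params())
  expect_equal(unname(diffusion_profile_exact(m1, "only", 0.5)$frequency), 1)
})

test_that("seed visitation is non-decreasing in restart probability", {
  withr::local_seed(13)
  net <- random_net(n_protein = 15, n_function = 5)
  model <- transition_model(net, walk_params())
  seed <- nodes_of_class(net, "protein")[1]
  freqs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(a) {
    diffusion_profile(model, seed, walk_params(restart_prob = a))$frequency[[seed]]
  }, 0)
  expect_true(all(diff(freqs) >= 0))
})

test_that("upweighting annotation edges shifts mass onto function nodes", {
  withr::local_seed(31)
  net <- random_net(n_protein = 15, n_function = 6)
  seed <- nodes_of_class(net, "protein")[1]
  mass_on_functions <- function(w) {
    params <- walk_params(class_weights = c(protein_function = w))
    prof <- diffusion_profile(transition_model(net, params), seed, params)
    sum(prof$frequency[net$nodes$class == "function"])
  }
  masses <- vapply(c(0.5, 1, 2, 4), mass_on_functions, 0)
  expect_true(all(diff(masses) > 0))
})

test_that("profiles are deterministic for identical inputs", {
  net <- toy_net()
  params <- walk_params(restart_prob = 0.35, class_weights = c(ppi = 1.7))
  p1 <- diffusion_profile(transition_model(net, params), "A", params)
  p2 <- diffusion_profile(transition_model(net, params), "A", params)
  expect_identical(p1$frequency, p2$frequency)
})

test_that("top-k extraction filters by class, excludes the seed, breaks ties", {
  model <- transition_model(path_net(), walk_params())
  prof <- diffusion_profile(model, "a", walk_params(restart_prob = 0.5))
  expect_equal(profile_top(prof, k = 2)$node, c("b", "c"))
  expect_equal(profile_top(prof, k = 10)$node, c("b", "c"))

  # ties broken lexicographically: symmetric star around the seed
  star <- multiscale_network(
    nodes = tibble::tibble(node = c("s", "z", "y", "x"), class = "protein"),
    edges = tibble::tibble(from = "s", to = c("z", "y", "x"),
                           edge_class = "ppi")
  )
  sp <- diffusion_profile(transition_model(star, walk_params()), "s",
                          walk_params())
  expect_equal(profile_top(sp, k = 3)$node, c("x", "y", "z"))

  # class filter drops entity nodes
  net <- attach_entity(toy_net(), "H1", "herb", c("A", "B"))
  hp <- diffusion_profile(transition_model(net, walk_params()), "H1",
                          walk_params())
  top <- profile_top(hp, k = 50, classes = c("protein", "function"))
  expect_false("H1" %in% top$node)
  expect_true(all(top$class %in% c("protein", "function")))
})

test_that("non-convergence is flagged and the tidiers report it", {
  model <- transition_model(path_net(), walk_params())
  expect_warning(
    prof <- diffusion_profile(model, "a",
                              walk_params(restart_prob = 0.01,
                                          tol = 1e-16, max_iter = 3)),
    "did not converge"
  )
  expect_false(prof$converged)
  expect_equal(sum(prof$frequency), 1, tolerance = 1e-12)
  g <- glance(prof)
  expect_false(g$converged)
  td <- tidy(prof)
  expect_equal(nrow(td), 3)
  expect_named(td, c("node", "class", "frequency"))
})
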