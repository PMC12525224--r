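make_profile <- function(freq, classes = NULL) {
  herbwalk:::new_diffusion_profile(
    "seed", freq, classes %||% rep("protein", length(freq))
  )
}

test_that("correlation score handles identity, anti-order, and excludes entities", {
  f <- setNames(c(0.4, 0.3, 0.2, 0.1), c("n1", "n2", "n3", "n4"))
  p <- make_profile(f)
  expect_equal(correlation_score(p, p), 1.0)

  q <- make_profile(setNames(rev(unname(f)), names(f)))
  expect_equal(correlation_score(p, q), -1.0)
  expect_equal(correlation_score(q, p), correlation_score(p, q))

  # an entity node with wildly different mass must not affect the score
  f2 <- c(f, E1 = 0.9)
  p2 <- make_profile(f2 / sum(f2), c(rep("protein", 4), "herb"))
  q2e <- c(rev(unname(f)), 0.0001)
  q2 <- make_profile(setNames(q2e / sum(q2e), names(f2)),
                     c(rep("protein", 4), "herb"))
  expect_equal(correlation_score(p2, q2), -1.0)

  flat <- make_profile(setNames(rep(0.25, 4), names(f)))
  expect_error(correlation_score(p, flat), class = "herbwalk_degenerate_error")
})

test_that("correlation matches a hand-coded covariance computation", {
  withr::local_seed(3)
  nodes <- sprintf("n%03d", 1:100)
  x <- stats::runif(100); x <- x / sum(x)
  y <- stats::runif(100); y <- y / sum(y)
  p <- make_profile(setNames(x, nodes))
  q <- make_profile(setNames(y, nodes))
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlation_score(p, q), hand, tolerance = 1e-12)
  # spearman variant agrees with rank-transformed pearson
  expect_equal(correlation_score(p, q, method = "spearman"),
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  bg <- sprintf("g%02d", 1:10)
  # N=10, K=3, n=4, k=2 -> enumerated p = 1/3
  ov <- hypergeom_overlap(bg[c(1, 2, 4, 5)], bg[1:3], bg)
  expect_equal(ov$k, 2)
  expect_equal(ov$p_value, hyper_tail_enum(10, 3, 4, 2))
  expect_equal(ov$p_value, 1 / 3, tolerance = 1e-12)

  # k = 0 -> tail at zero is 1
  ov0 <- hypergeom_overlap(bg[4:6], bg[1:3], bg)
  expect_equal(ov0$p_value, 1.0)

  # N=20, K=5, n=4, k=4 -> single term 5/4845
  bg20 <- sprintf("g%02d", 1:20)
  ov4 <- hypergeom_overlap(bg20[1:4], bg20[1:5], bg20)
  expect_equal(ov4$p_value, 5 / 4845, tolerance = 1e-12)
  expect_equal(ov4$p_value, hyper_tail_enum(20, 5, 4, 4), tolerance = 1e-12)

  expect_error(hypergeom_overlap(c("zz"), bg[1:3], bg),
               class = "herbwalk_domain_error")
})

test_that("tail probabilities equal the counting formula over a full sweep", {
  # every (N <= 25, K, n, k) instance against an independent choose() sum
  for (N in c(5, 10, 17, 25)) {
    for (K in 1:N) {
      for (n in 1:N) {
        for (k in 0:min(n, K)) {
          expect_equal(
            stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            hyper_tail_choose(N, K, n, k),
            tolerance = 1e-10,
            label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k)
          )
        }
      }
    }
  }
  # and spot-check the package path against full enumeration on a small N
  bg <- sprintf("g%02d", 1:12)
  for (K in c(2, 5)) {
    for (n in c(3, 6)) {
      for (k in 0:min(n, K)) {
        ent <- c(bg[seq_len(k)], bg[K + seq_len(n - k)])
        ov <- hypergeom_overlap(ent, bg[1:K], bg)
        expect_equal(ov$p_value, hyper_tail_enum(12, K, n, k),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value is non-increasing in the overlap count", {
  for (N in c(12, 25)) {
    K <- 6; n <- 8
    p <- vapply(0:min(n, K), function(k) {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    }, 0)
    expect_true(all(diff(p) <= 0))
  }
})

test_that("fold enrichment is the overlap rate over the background rate", {
  expect_equal(fold_enrichment(5, 50, 0.1), 1.0)
  # linear in k
  bf <- 0.013
  expect_equal(fold_enrichment(4, 50, bf), 2 * fold_enrichment(2, 50, bf))
  expect_error(fold_enrichment(2, 0, 0.1))
  expect_error(fold_enrichment(2, 5, 0))
})

test_that("candidate-table rows share one background calibration", {
  # calibrate the background fraction from the (5/50 -> 42.27) row; every
  # other row's printed enrichment must be reproduced to 2 decimals
  toy <- overlap_toy()
  bf <- (5 / 50) / 42.27
  expected <- c(16.91, 42.27, 31.31, 32.52, 22.25, 38.43, 33.82, 33.82,
                33.82, 25.36)
  got <- with(toy$table, round(fold_enrichment(k, n, bf), 2))
  expect_equal(got, expected)
  # the toy's own background realises that fraction exactly
  expect_equal(length(toy$disease_genes) / length(toy$background), bf,
               tolerance = 1e-12)
  # and the full overlap statistics agree when computed from the gene sets
  stats_tbl <- purrr::imap_dfr(toy$herb_targets, function(tg, h) {
    hypergeom_overlap(tg, toy$disease_genes, toy$background)
  })
  expect_equal(stats_tbl$k, toy$table$k)
  expect_equal(stats_tbl$n, toy$table$n)
  expect_equal(round(stats_tbl$enrichment, 2), expected)
})

test_that("herb ranking applies thresholds, tie rules, and stays stable", {
  scores <- tibble::tibble(
    entity = c("Hp06", "Hlo", "Hhi", "Htie", "Hfew"),
    correlation_score = c(0.9, 0.2, 0.5, 0.5, 0.8),
    k = 2L, n = 10L, K = 5L, N = 100L,
    p_value = c(0.06, 0.01, 0.02, 0.01, 0.001),
    enrichment = 4,
    n_active_compounds = c(9L, 6L, 7L, 8L, 2L)
  )
  rk <- rank_herbs(scores)
  # p = 0.06 excluded regardless of correlation; < 5 active compounds excluded
  expect_false(any(c("Hp06", "Hfew") %in% rk$entity))
  # equal correlation -> lower p first
  expect_equal(rk$entity, c("Htie", "Hhi", "Hlo"))
  expect_equal(rk$rank, 1:3)
  # permutation invariance
  rk2 <- rank_herbs(scores[sample(nrow(scores)), ])
  expect_equal(rk2$entity, rk$entity)
  # top_n truncation and threshold saturation
  expect_equal(nrow(rank_herbs(scores, top_n = 2)), 2)
  expect_equal(nrow(suppressWarnings(
    rank_herbs(scores, p_threshold = 1, min_active_compounds = 0)
  )), 5)
})

test_that("active-compound counting supports both rules", {
  net <- toy_net()  # proteins A, B, C, D
  cat <- herb_catalog(
    tibble::tibble(herb = "H", compound = c("c1", "c2", "c3")),
    tibble::tibble(compound = c("c1", "c2", "c3"),
                   target = c("A", "D", "ZZZ"))
  )
  by_net <- count_active_compounds(cat, net)
  expect_equal(by_net$n_active_compounds, 2)  # c3 unmapped
  by_dis <- count_active_compounds(cat, net, disease_genes = "A",
                                   active_rule = "disease_target")
  expect_equal(by_dis$n_active_compounds, 1)
})

test_that("planted herb is recovered by correlation rank and overlap p", {
  n_top <- 0; n_sig <- 0; seeds <- 1:6
  for (s in seeds) {
    w <- generate_world(synthetic_config(seed = s))
    catalog <- suppressMessages(filter_herbs_min_ingredients(w$catalog, 3))
    sc <- suppressMessages(score_entities(
      w$network, herb_target_sets(catalog), "herb", w$disease
    ))
    best <- sc$entity[order(-sc$correlation_score, sc$p_value, sc$entity)][1]
    n_top <- n_top + (best == w$planted_herb)
    n_sig <- n_sig + (sc$p_value[sc$entity == w$planted_herb] < 0.05)
  }
  expect_gte(n_top, length(seeds) - 1)
  expect_gte(n_sig, length(seeds) - 1)
})

test_that("compound ranking excludes failing compounds and recovers a planted one", {
  withr::local_seed(77)
  hits <- 0
  for (rep in 1:8) {
    net <- random_net(n_protein = 30, n_function = 6)
    proteins <- nodes_of_class(net, "protein")
    disease <- list(id = "DIS", genes = proteins[1:8])
    # planted compound targets sit inside the disease set; 5 decoys outside
    targets <- c(
      list(planted = proteins[1:5]),
      setNames(purrr::map(1:5, ~ sample(proteins[9:30], 4)),
               paste0("decoy", 1:5))
    )
    cat <- herb_catalog(
      tibble::tibble(herb = "H", compound = names(targets)),
      tibble::tibble(
        compound = rep(names(targets), lengths(targets)),
        target = unlist(targets)
      )
    )
    cr <- suppressMessages(suppressWarnings(
      rank_compounds(net, cat, "H", disease)
    ))
    expect_true(all(cr$p_value < 0.05))
    if (nrow(cr) > 0 && cr$entity[1] == "planted") hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("single passing compound yields a one-row table; none yields empty", {
  proteins <- sprintf("P%02d", 1:20)
  net <- assemble_network(
    ppi = tibble::tibble(from = proteins[-20], to = proteins[-1]),
    protein_function = tibble::tibble(from = proteins[1], to = "F1"),
    function_hierarchy = tibble::tibble(from = "F1", to = "F2"),
    quiet = TRUE
  )
  disease <- list(id = "DIS", genes = proteins[1:3])
  cat1 <- herb_catalog(
    tibble::tibble(herb = "H", compound = "c1"),
    tibble::tibble(compound = "c1", target = proteins[1:3])
  )
  cr1 <- suppressMessages(rank_compounds(net, cat1, "H", disease))
  expect_equal(nrow(cr1), 1)  # p = 1 / choose(20, 3), well under 0.05
  expect_equal(cr1$rank, 1)

  cat2 <- herb_catalog(
    tibble::tibble(herb = "H", compound = "c2"),
    tibble::tibble(compound = "c2", target = proteins[10])
  )
  cr2 <- suppressWarnings(suppressMessages(
    rank_compounds(net, cat2, "H", disease)
  ))
  expect_equal(nrow(cr2), 0)
})
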