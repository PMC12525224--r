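#' Gene-set over-representation analysis
#'
#' Tests a query gene list against every set of a GMT-style library with the
#' one-sided hypergeometric test on the 2x2 overlap table, Benjamini-
#' Hochberg adjustment across the library, an odds ratio (Haldane +0.5
#' correction when any cell is zero), a rank-based z-score against random
#' same-size queries, and the combined score `|z * ln(p)|`.
#'
#' The z-score follows the rank-deviation idea: `n_random` random queries of
#' the query's size are drawn from the background, each term's rank (by
#' p-value, average ties) is recorded, and `z = (expected rank - observed
#' rank) / sd(rank)`, so terms ranking far better than chance get large
#' positive z.
#'
#' @param query Character vector of gene symbols; must be a subset of
#'   `background`.
#' @param library Named list of gene sets (see [read_gmt()]).
#' @param background Gene universe; default: union of all library genes plus
#'   the query.
#' @param n_random Random queries for the z-score background (default 200);
#'   `0` skips the z-score (z = 0, combined = 0).
#' @param seed Integer seed for the random-query draw (default 1); the draw
#'   is isolated from the caller's RNG state.
#' @return An `enrichment_result` tibble: `term`, `overlap_count`,
#'   `term_size`, `query_size`, `background_size`, `p_value`, `adjusted_p`,
#'   `odds_ratio`, `z_score`, `combined_score`, `genes` (overlap members,
#'   `;`-separated), sorted by p-value.
#' @export
enrich_sets <- function(query, library, background = NULL, n_random = 200,
                        seed = 1) {
  query <- unique(query)
  if (length(query) == 0) abort("empty query", class = "herbwalk_empty_input")
  if (length(library) == 0 || is.null(names(library))) {
    abort("library must be a nonempty named list", class = "herbwalk_empty_input")
  }
  library <- map(library, unique)
  background <- unique(background %||% c(unlist(library), query))
  if (!all(query %in% background)) {
    abort("query must be a subset of the background",
          class = "herbwalk_domain_error")
  }

  # terms with no background member are skipped, not silently scored
  in_bg <- map(library, ~ intersect(.x, background))
  empty <- names(in_bg)[lengths(in_bg) == 0]
  if (length(empty) > 0) {
    inform(sprintf("skipping %d term(s) with no background member: %s",
                   length(empty), paste(head(empty, 5), collapse = ", ")))
    in_bg <- in_bg[lengths(in_bg) > 0]
  }
  if (length(in_bg) == 0) abort("no scorable term", class = "herbwalk_empty_input")

  N <- length(background)
  res <- term_table(query, in_bg, N)
  res$adjusted_p <- p.adjust(res$p_value, method = "BH")

  if (n_random > 0) {
    obs_rank <- rank(res$p_value, ties.method = "average")
    ranks <- withr::with_seed(seed, {
      vapply(seq_len(n_random), function(b) {
        rq <- sample(background, length(query))
        rank(term_table(rq, in_bg, N)$p_value, ties.method = "average")
      }, numeric(nrow(res)))
    })
    mu <- rowMeans(ranks)
    sdev <- apply(ranks, 1, sd)
    res$z_score <- ifelse(sdev > 0, (mu - obs_rank) / sdev, 0)
  } else {
    res$z_score <- 0
  }
  res$combined_score <- abs(res$z_score * log(res$p_value))
  res <- arrange(res, .data$p_value, .data$term)
  class(res) <- c("enrichment_result", class(res))
  res
}

# per-term 2x2 statistics for a given query (shared with the random draws)
term_table <- function(query, sets, N) {
  q <- length(query)
  rows <- imap(sets, function(members, nm) {
    m <- length(members)
    hits <- intersect(query, members)
    a <- length(hits)
    b <- q - a
    cc <- m - a
    d <- N - m - b
    or <- if (a == 0 || b == 0 || cc == 0 || d == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      (a * d) / (b * cc)
    }
    tibble(
      term = nm, overlap_count = a, term_size = m, query_size = q,
      background_size = N,
      p_value = stats::phyper(a - 1, m, N - m, q, lower.tail = FALSE),
      odds_ratio = or,
      genes = paste(sort(hits), collapse = ";")
    )
  })
  bind_rows(rows)
}

#' Disease-pathway whitelist for hyperthyroidism
#'
#' The nine KEGG signalling pathways taken as hyperthyroidism-associated.
#'
#' @return Character vector of pathway names.
#' @export
hyperthyroidism_pathways <- function() {
  c(
    "MAPK signaling pathway",
    "Thyroid hormone signaling pathway",
    "Calcium signaling pathway",
    "HIF-1 signaling pathway",
    "p53 signaling pathway",
    "mTOR signaling pathway",
    "PI3K-Akt signaling pathway",
    "Wnt signaling pathway",
    "Parathyroid hormone synthesis, secretion and action"
  )
}

#' Restrict enrichment results to a pathway whitelist
#'
#' Keeps exactly the terms whose names match the whitelist
#' (case-insensitive exact match).
#'
#' @param results An `enrichment_result` tibble.
#' @param whitelist Character vector of term names; defaults to
#'   [hyperthyroidism_pathways()].
#' @return The filtered tibble.
#' @export
filter_disease_pathways <- function(results, whitelist = hyperthyroidism_pathways()) {
  stopifnot(is.data.frame(results))
  filter(results, tolower(.data$term) %in% tolower(whitelist))
}

#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- head(as_tibble(object), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combined_score, y = .data$term)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$odds_ratio,
                                     colour = -log10(.data$adjusted_p))) +
    ggplot2::scale_colour_viridis_c(name = "-log10 adj. p") +
    ggplot2::scale_size_continuous(name = "odds ratio") +
    ggplot2::labs(x = "combined score", y = NULL,
                  title = "Gene-set over-representation") +
    ggplot2::theme_minimal()
}
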