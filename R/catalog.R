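#' Filter herbs by target-bearing ingredient count
#'
#' Retains herbs with at least `min_count` compounds that each carry at least
#' one target annotation.  Herbs below the floor are excluded and reported;
#' the operation is idempotent.
#'
#' @param catalog A `herb_catalog`.
#' @param min_count Minimum number of target-bearing compounds (default 3).
#' @param quiet Suppress the exclusion report.
#' @return A filtered `herb_catalog`.
#' @export
filter_herbs_min_ingredients <- function(catalog, min_count = 3, quiet = FALSE) {
  stopifnot(inherits(catalog, "herb_catalog"), min_count >= 1)
  targeted <- unique(catalog$compound_target$compound)
  counts <- catalog$herb_compound |>
    filter(.data$compound %in% targeted) |>
    count(.data$herb, name = "n_targeted")
  keep <- counts$herb[counts$n_targeted >= min_count]
  dropped <- setdiff(unique(catalog$herb_compound$herb), keep)
  if (length(dropped) > 0 && !quiet) {
    inform(sprintf(
      "excluded %d herb(s) with fewer than %d target-bearing compound(s): %s",
      length(dropped), min_count, paste(head(dropped, 10), collapse = ", ")
    ))
  }
  hc <- filter(catalog$herb_compound, .data$herb %in% keep)
  ct <- filter(catalog$compound_target, .data$compound %in% hc$compound)
  if (nrow(hc) == 0) warn("no herb survives the ingredient-count filter")
  out <- herb_catalog(hc, ct)
  out
}

#' Herb-to-target simple pathway counts
#'
#' For one herb, counts the herb -> compound -> target paths landing on each
#' target: the number of the herb's compounds annotated to that target.
#' Multiple compounds hitting one target accumulate.
#'
#' @param catalog A `herb_catalog`.
#' @param herb Herb id.
#' @return A tibble (`target`, `n_paths`) sorted by descending count then
#'   target symbol.
#' @export
#' @examples
#' cat <- herb_catalog(
#'   tibble::tibble(herb = "H", compound = c("c1", "c2")),
#'   tibble::tibble(compound = c("c1", "c1", "c2"), target = c("A", "B", "B"))
#' )
#' simple_path_counts(cat, "H")
simple_path_counts <- function(catalog, herb) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (!herb %in% catalog$herb_compound$herb) {
    abort(paste0("unknown herb: ", herb), class = "herbwalk_lookup_error")
  }
  compounds <- catalog$herb_compound$compound[catalog$herb_compound$herb == herb]
  catalog$compound_target |>
    filter(.data$compound %in% compounds) |>
    count(.data$target, name = "n_paths") |>
    arrange(desc(.data$n_paths), .data$target)
}

#' Select the top targets of a herb by path count
#'
#' @param path_counts Tibble from [simple_path_counts()].
#' @param limit Maximum number of targets to keep (default 50).
#' @return Character vector of target symbols, sorted by descending path
#'   count with lexicographic tie-break, truncated at `limit`.
#' @export
select_top_targets <- function(path_counts, limit = 50) {
  stopifnot(nrow(path_counts) > 0, limit >= 1)
  ord <- path_counts |> arrange(desc(.data$n_paths), .data$target)
  head(ord$target, limit)
}

#' Target sets for every herb in a catalog
#'
#' The default herb target set is the union of its compounds' targets capped
#' at `limit` by simple pathway count (descending, lexicographic tie-break);
#' `limit = Inf` gives the full union.
#'
#' @param catalog A `herb_catalog`.
#' @param limit Per-herb target cap (default 50).
#' @return Named list: herb id -> character vector of targets.
#' @export
herb_target_sets <- function(catalog, limit = 50) {
  herbs <- unique(catalog$herb_compound$herb)
  setNames(
    map(herbs, function(h) {
      pc <- simple_path_counts(catalog, h)
      if (nrow(pc) == 0) character() else select_top_targets(pc, min(limit, nrow(pc)))
    }),
    herbs
  )
}

#' Target sets for a herb's compounds
#'
#' @param catalog A `herb_catalog`.
#' @param herb Herb id.
#' @return Named list: compound id -> character vector of targets (compounds
#'   with no target annotation get an empty vector).
#' @export
compound_target_sets <- function(catalog, herb) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (!herb %in% catalog$herb_compound$herb) {
    abort(paste0("unknown herb: ", herb), class = "herbwalk_lookup_error")
  }
  compounds <- catalog$herb_compound$compound[catalog$herb_compound$herb == herb]
  setNames(
    map(compounds, function(cp) {
      catalog$compound_target$target[catalog$compound_target$compound == cp]
    }),
    compounds
  )
}
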