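#' Read a typed edge list
#'
#' Parses a tab-separated edge-list file into a tibble of typed, undirected
#' edges.  Lines starting with `#` are comments; the first two columns are the
#' endpoint node ids and any further columns are ignored.  Duplicate edges
#' (as unordered pairs) and self-loops are removed; the counts are reported
#' via a message so nothing is dropped silently.
#'
#' @param path Path to a TSV file.
#' @param edge_class One of `"ppi"`, `"protein_function"`,
#'   `"function_hierarchy"`, `"herb_target"`, `"compound_target"`,
#'   `"disease_gene"`.
#' @param quiet Suppress the line/edge count message.
#'
#' @return A tibble with columns `from`, `to`, `edge_class`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("A\tB", "B\tC"), tf)
#' read_edge_list(tf, "ppi")
read_edge_list <- function(path, edge_class, quiet = FALSE) {
  edge_class <- rlang::arg_match(edge_class, EDGE_CLASSES)
  if (!file.exists(path)) {
    abort(paste0("edge-list file not found: ", path), class = "herbwalk_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep_idx) == 0) {
    abort(paste0("empty edge-list file: ", path), class = "herbwalk_empty_input")
  }
  fields <- strsplit(lines[keep_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "malformed edge-list line %d in %s: fewer than 2 tab-separated columns",
        keep_idx[bad[1]], path
      ),
      class = "herbwalk_parse_error"
    )
  }
  edges <- tibble(
    from = trimws(map_chr(fields, 1)),
    to   = trimws(map_chr(fields, 2)),
    edge_class = edge_class
  )
  edges <- normalize_edges(edges)
  if (!quiet) {
    inform(sprintf(
      "read %d line(s) from %s: %d distinct %s edge(s)",
      length(keep_idx), basename(path), nrow(edges), edge_class
    ))
  }
  edges
}

# dedup as unordered pairs (keeping first-seen orientation) + drop self-loops
normalize_edges <- function(edges) {
  edges |>
    mutate(
      .u = pmin(.data$from, .data$to),
      .v = pmax(.data$from, .data$to)
    ) |>
    filter(.data$.u != .data$.v) |>
    distinct(.data$.u, .data$.v, .data$edge_class, .keep_all = TRUE) |>
    select("from", "to", "edge_class")
}

#' Read a GMT gene-set library
#'
#' GMT is the tab-separated gene-set format: each line holds a set name, a
#' description, then the member genes.  Member symbols are uppercased and
#' deduplicated.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GMT file not found: ", path), class = "herbwalk_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    abort(paste0("empty GMT file: ", path), class = "herbwalk_empty_input")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(
      sprintf("malformed GMT line %d: need name, description, >=1 member", bad[1]),
      class = "herbwalk_parse_error"
    )
  }
  sets <- map(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- map_chr(fields, 1)
  sets
}

#' Write a GMT gene-set library
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- imap(sets, function(members, nm) {
    paste(c(nm, description, members), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read herb and compound annotation tables
#'
#' Builds a herb catalog from two TSV files: `herb_compound.tsv`
#' (columns herb id, compound id) and `compound_target.tsv` (columns compound
#' id, target gene symbol).  Duplicate records collapse to one; target gene
#' symbols are uppercased.
#'
#' @param herb_compound_path,compound_target_path Paths to the two TSVs
#'   (tab-separated, `#` comments).
#' @param quiet Suppress record-count messages.
#' @return A herb catalog: list with tibbles `herb_compound`
#'   (`herb`, `compound`) and `compound_target` (`compound`, `target`).
#' @export
read_herb_catalog <- function(herb_compound_path, compound_target_path,
                              quiet = FALSE) {
  hc <- read_two_col(herb_compound_path, c("herb", "compound"))
  ct <- read_two_col(compound_target_path, c("compound", "target"))
  ct$target <- toupper(ct$target)
  ct <- distinct(ct)
  if (!quiet) {
    inform(sprintf(
      "catalog: %d herb-compound and %d compound-target record(s) after dedup",
      nrow(hc), nrow(ct)
    ))
  }
  herb_catalog(hc, ct)
}

read_two_col <- function(path, col_names) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "herbwalk_io_error")
  }
  df <- readr::read_tsv(
    path,
    col_names = col_names, col_types = readr::cols(.default = "c"),
    comment = "#", progress = FALSE
  )
  if (nrow(df) == 0) {
    abort(paste0("empty file: ", path), class = "herbwalk_empty_input")
  }
  distinct(as_tibble(df[, seq_along(col_names)]))
}

#' Construct a herb catalog from tibbles
#'
#' @param herb_compound Tibble with columns `herb`, `compound`.
#' @param compound_target Tibble with columns `compound`, `target`.
#' @return An object of class `herb_catalog`.
#' @export
herb_catalog <- function(herb_compound, compound_target) {
  herb_compound <- distinct(as_tibble(herb_compound)[, c("herb", "compound")])
  compound_target <- distinct(as_tibble(compound_target)[, c("compound", "target")])
  no_target <- setdiff(herb_compound$compound, compound_target$compound)
  if (length(no_target) > 0) {
    inform(sprintf(
      "catalog: %d compound(s) carry no target annotation", length(no_target)
    ))
  }
  structure(
    list(
      herb_compound = herb_compound,
      compound_target = compound_target,
      untargeted_compounds = no_target
    ),
    class = "herb_catalog"
  )
}

#' @export
print.herb_catalog <- function(x, ...) {
  cat(sprintf(
    "<herb_catalog> %d herb(s), %d compound(s), %d compound-target record(s)\n",
    dplyr::n_distinct(x$herb_compound$herb),
    dplyr::n_distinct(x$herb_compound$compound),
    nrow(x$compound_target)
  ))
  invisible(x)
}

#' Read a disease gene set
#'
#' Accepts either a plain list (one gene symbol per line, `#` comments) or a
#' GMT file, in which case the first set is used (or the set named by
#' `set_name`).
#'
#' @param path Path to the gene list or GMT file.
#' @param disease_id Identifier for the disease node; defaults to the file
#'   stem or the GMT set name.
#' @param set_name For GMT input, which set to take.
#' @return A list with elements `id` and `genes` (uppercase symbols).
#' @export
read_disease_genes <- function(path, disease_id = NULL, set_name = NULL) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- read_gmt(path)
    nm <- set_name %||% names(sets)[1]
    if (!nm %in% names(sets)) {
      abort(paste0("gene set not found in GMT: ", nm), class = "herbwalk_io_error")
    }
    genes <- sets[[nm]]
    id <- disease_id %||% nm
  } else {
    lines <- readLines(path, warn = FALSE)
    genes <- toupper(trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]))
    genes <- unique(genes)
    id <- disease_id %||% sub("\\.[^.]*$", "", basename(path))
  }
  if (length(genes) == 0) {
    abort("disease gene set is empty", class = "herbwalk_empty_input")
  }
  list(id = id, genes = genes)
}
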