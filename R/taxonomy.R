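#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join bind_rows n distinct across count rename slice pull
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Closed rank vocabulary, root-most first. "no rank" nodes are transparent to
# rank resolution; "strain"/"subspecies" sit below "species".
.tv_ranks <- c(
  "no rank", "superkingdom", "kingdom", "phylum", "class", "order",
  "family", "genus", "species", "subspecies", "strain"
)

#' Rank vocabulary for taxonomies
#'
#' @return Character vector of the rank strings accepted by [taxonomy()],
#'   ordered from root-most ("superkingdom") to leaf-most ("strain"), with
#'   "no rank" first.
#' @export
taxonomy_ranks <- function() .tv_ranks

#' Construct a taxonomy from a node table
#'
#' A taxonomy is a rooted tree of taxa. Each node has an integer `tax_id`, a
#' `parent_id` pointing at its parent (the root points at itself), a `rank`
#' drawn from [taxonomy_ranks()], and a scientific `name`.
#'
#' @param nodes A data frame with columns `tax_id`, `parent_id`, `rank`,
#'   `name`.
#' @return An object of class `taxonomy`: the validated node tibble plus
#'   internal lookup tables used by [resolve_at_rank()] and friends.
#' @examples
#' tax <- taxonomy(tibble::tibble(
#'   tax_id = c(1L, 2L, 562L),
#'   parent_id = c(1L, 1L, 2L),
#'   rank = c("no rank", "superkingdom", "species"),
#'   name = c("root", "Bacteria", "Escherichia coli")
#' ))
#' resolve_at_rank(tax, 562, "species")
#' @export
taxonomy <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  required <- c("tax_id", "parent_id", "rank", "name")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    abort(paste0("taxonomy(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  nodes <- as_tibble(nodes)[required]
  nodes$tax_id <- as.integer(nodes$tax_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  if (anyNA(nodes$tax_id) || anyNA(nodes$parent_id)) {
    abort("taxonomy(): tax_id/parent_id must be integers without NA")
  }
  if (any(nodes$tax_id <= 0L)) abort("taxonomy(): tax_id must be positive")
  if (anyDuplicated(nodes$tax_id)) {
    abort("taxonomy(): duplicated tax_id in node table")
  }
  bad_rank <- setdiff(unique(nodes$rank), .tv_ranks)
  if (length(bad_rank) > 0) {
    abort(paste0("taxonomy(): unknown rank(s): ",
                 paste(bad_rank, collapse = ", ")))
  }
  roots <- nodes$tax_id[nodes$tax_id == nodes$parent_id]
  if (length(roots) != 1L) {
    abort(paste0("taxonomy(): expected exactly one root (its own parent), found ",
                 length(roots)))
  }
  orphan <- setdiff(nodes$parent_id, nodes$tax_id)
  if (length(orphan) > 0) {
    abort(paste0("taxonomy(): parent_id not present in table: ",
                 paste(orphan, collapse = ", ")))
  }

  key <- as.character(nodes$tax_id)
  parent <- stats::setNames(nodes$parent_id, key)
  rank <- stats::setNames(nodes$rank, key)
  name <- stats::setNames(nodes$name, key)

  # acyclicity: every lineage must reach the root in <= n steps
  root <- roots[[1L]]
  n <- nrow(nodes)
  for (id in nodes$tax_id) {
    cur <- id
    steps <- 0L
    while (cur != root) {
      cur <- parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) {
        abort(paste0("taxonomy(): cycle detected following parents of tax_id ", id))
      }
    }
  }

  structure(
    list(nodes = nodes, root = root, parent = parent, rank = rank, name = name),
    class = "taxonomy"
  )
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes), " nodes, root tax_id ", x$root, "\n", sep = "")
  print(dplyr::count(x$nodes, .data$rank, sort = TRUE), ...)
  invisible(x)
}

#' @method tidy taxonomy
#' @export
tidy.taxonomy <- function(x, ...) x$nodes

.tv_check_ids <- function(tax, ids, what = "tax_id") {
  unknown <- setdiff(unique(ids), tax$nodes$tax_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown ", what, ": ", paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Lineage of a taxon
#'
#' Walks parent links from `tax_id` to the root.
#'
#' @param tax A [taxonomy()].
#' @param tax_id A single taxon id present in `tax`.
#' @return A tibble (tax_id, rank, name) ordered leaf to root.
#' @export
lineage <- function(tax, tax_id) {
  stopifnot(inherits(tax, "taxonomy"), length(tax_id) == 1L)
  tax_id <- as.integer(tax_id)
  .tv_check_ids(tax, tax_id)
  ids <- integer(0)
  cur <- tax_id
  repeat {
    ids <- c(ids, cur)
    if (cur == tax$root) break
    cur <- tax$parent[[as.character(cur)]]
  }
  key <- as.character(ids)
  tibble(tax_id = ids, rank = unname(tax$rank[key]), name = unname(tax$name[key]))
}

#' Resolve taxa at a target rank
#'
#' For each id, returns the ancestor (or the id itself) whose rank equals
#' `rank`, or `NA` if the lineage has no node of that rank. Lineages with rank
#' gaps resolve to `NA` rather than erroring, so downstream agreement tests
#' treat them as non-agreeing.
#'
#' @param tax A [taxonomy()].
#' @param tax_id Integer vector of taxon ids, all present in `tax`.
#' @param rank Target rank string (see [taxonomy_ranks()]).
#' @return Integer vector the same length as `tax_id` (`NA` where unresolved).
#' @export
resolve_at_rank <- function(tax, tax_id, rank = "species") {
  stopifnot(inherits(tax, "taxonomy"), length(rank) == 1L)
  if (!rank %in% .tv_ranks) abort(paste0("unknown rank: ", rank))
  tax_id <- as.integer(tax_id)
  .tv_check_ids(tax, tax_id)
  resolve_one <- function(id) {
    cur <- id
    repeat {
      if (identical(tax$rank[[as.character(cur)]], rank)) return(cur)
      if (cur == tax$root) return(NA_integer_)
      cur <- tax$parent[[as.character(cur)]]
    }
  }
  vapply(tax_id, resolve_one, integer(1))
}

#' Do two taxa agree at a rank?
#'
#' `TRUE` iff both ids resolve at `rank` (via [resolve_at_rank()]) and resolve
#' to the same node. Ids whose lineage lacks the rank never agree (not even
#' with themselves), reflecting that no statement at that rank can be made.
#'
#' @inheritParams resolve_at_rank
#' @param a,b Taxon ids (vectors recycled to common length).
#' @return Logical vector.
#' @export
same_taxon <- function(tax, a, b, rank = "species") {
  ra <- resolve_at_rank(tax, a, rank)
  rb <- resolve_at_rank(tax, b, rank)
  !is.na(ra) & !is.na(rb) & ra == rb
}

# ---- NCBI-style dump files ---------------------------------------------------

.tv_split_dmp <- function(lines, path) {
  # NCBI taxdump dialect: fields separated by "\t|\t", line terminated "\t|"
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Read a taxonomy from NCBI-style dump files
#'
#' Parses the pipe-and-tab delimited `nodes.dmp`/`names.dmp` dialect. Only
#' "scientific name" rows of the names file are used; nodes without one get an
#' empty name.
#'
#' @param nodes_path Path to a nodes dump (tax_id | parent | rank | ...).
#' @param names_path Path to a names dump (tax_id | name | unique | class).
#' @return A [taxonomy()].
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  node_lines <- readr::read_lines(nodes_path)
  node_lines <- node_lines[nzchar(node_lines)]
  fields <- .tv_split_dmp(node_lines, nodes_path)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0("load_taxonomy(): malformed node row at line ",
                 which(nf < 3L)[1], " of ", nodes_path))
  }
  tax_id <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  parent_id <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  rank <- vapply(fields, `[[`, "", 3L)
  if (anyNA(tax_id) || anyNA(parent_id)) {
    bad <- which(is.na(tax_id) | is.na(parent_id))[1]
    abort(paste0("load_taxonomy(): non-integer tax_id/parent at line ", bad,
                 " of ", nodes_path))
  }

  name_lines <- readr::read_lines(names_path)
  name_lines <- name_lines[nzchar(name_lines)]
  nfields <- .tv_split_dmp(name_lines, names_path)
  nn <- lengths(nfields)
  if (any(nn < 4L)) {
    abort(paste0("load_taxonomy(): malformed name row at line ",
                 which(nn < 4L)[1], " of ", names_path))
  }
  ntab <- tibble(
    tax_id = suppressWarnings(as.integer(vapply(nfields, `[[`, "", 1L))),
    name = vapply(nfields, `[[`, "", 2L),
    class = vapply(nfields, `[[`, "", 4L)
  )
  sci <- ntab[ntab$class == "scientific name", c("tax_id", "name")]
  sci <- sci[!duplicated(sci$tax_id), ]

  nodes <- tibble(tax_id = tax_id, parent_id = parent_id, rank = rank)
  nodes <- left_join(nodes, sci, by = "tax_id")
  nodes$name[is.na(nodes$name)] <- ""
  taxonomy(nodes)
}

#' Write a taxonomy as NCBI-style dump files
#'
#' Inverse of [load_taxonomy()]: writes `nodes.dmp` and `names.dmp` (scientific
#' names only) into `dir`.
#'
#' @param tax A [taxonomy()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the two file paths.
#' @export
write_taxdump <- function(tax, dir) {
  stopifnot(inherits(tax, "taxonomy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  n <- tax$nodes
  readr::write_lines(
    paste0(paste(n$tax_id, n$parent_id, n$rank, sep = "\t|\t"), "\t|"),
    nodes_path
  )
  readr::write_lines(
    paste0(paste(n$tax_id, n$name, "", "scientific name", sep = "\t|\t"), "\t|"),
    names_path
  )
  invisible(c(nodes = nodes_path, names = names_path))
}
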