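# Community profiles: aggregate accepted read assignments at a taxonomic
# rank, compute relative abundances, rarefy, and summarise richness.

#' Build a community profile from read assignments
#'
#' Counts reads per taxon after resolving every included read's taxon at
#' `rank`. Reads whose lineage lacks the rank are dropped and reported in the
#' `n_unresolved` attribute.
#'
#' @param assignments Read-assignment tibble ([filter_reads()] shape).
#' @param tax A [taxonomy()].
#' @param rank Aggregation rank (default `"species"`).
#' @param include Statuses whose reads enter the profile (default
#'   `"verified"`; use `c("verified", "classifier_only")` for an unverified
#'   profile).
#' @return A `community_profile`: a tibble (`tax_id`, `name`, `count`) sorted
#'   by decreasing count, with attributes `rank`, `total_reads` and
#'   `n_unresolved`.
#' @export
build_profile <- function(assignments, tax, rank = "species",
                          include = "verified") {
  stopifnot(inherits(tax, "taxonomy"))
  bad <- setdiff(include, .tv_statuses)
  if (length(bad) > 0) {
    abort(paste0("build_profile(): unknown status(es): ",
                 paste(bad, collapse = ", ")))
  }
  kept <- assignments[assignments$status %in% include & !is.na(assignments$tax_id), ]
  .tv_check_ids(tax, kept$tax_id)
  at_rank <- resolve_at_rank(tax, kept$tax_id, rank)
  n_unresolved <- sum(is.na(at_rank))
  counts <- table(at_rank[!is.na(at_rank)])
  ids <- as.integer(names(counts))
  out <- tibble(
    tax_id = ids,
    name = unname(tax$name[as.character(ids)]),
    count = as.integer(counts)
  )
  out <- arrange(out, dplyr::desc(.data$count), .data$tax_id)
  new_profile(out, rank = rank, n_unresolved = n_unresolved)
}

new_profile <- function(tbl, rank, n_unresolved = 0L) {
  tbl <- as_tibble(tbl)
  structure(tbl, rank = rank, total_reads = sum(tbl$count),
            n_unresolved = as.integer(n_unresolved),
            class = c("community_profile", class(tibble())))
}

#' Make a community profile from explicit counts
#'
#' @param counts Data frame with columns `tax_id` and `count` (optionally
#'   `name`).
#' @param rank Rank of the taxa.
#' @return A `community_profile`.
#' @export
community_profile <- function(counts, rank = "species") {
  stopifnot(is.data.frame(counts), all(c("tax_id", "count") %in% names(counts)))
  tbl <- as_tibble(counts)
  if (!"name" %in% names(tbl)) tbl$name <- NA_character_
  tbl <- tbl[c("tax_id", "name", "count")]
  tbl$tax_id <- as.integer(tbl$tax_id)
  tbl$count <- as.integer(tbl$count)
  if (any(tbl$count < 0)) abort("community_profile(): negative counts")
  new_profile(tbl[tbl$count > 0L, ], rank = rank)
}

#' @export
print.community_profile <- function(x, ...) {
  cat("<community_profile> rank ", attr(x, "rank"), ", ",
      nrow(x), " taxa, ", attr(x, "total_reads"), " reads",
      if (attr(x, "n_unresolved") > 0)
        paste0(" (+", attr(x, "n_unresolved"), " unresolved at rank)"),
      "\n", sep = "")
  NextMethod()
}

#' Relative abundances of a profile
#'
#' @param profile A `community_profile`.
#' @return A tibble (`tax_id`, `name`, `count`, `fraction`); fractions sum
#'   to 1.
#' @export
relative_abundance <- function(profile) {
  total <- attr(profile, "total_reads") %||% sum(profile$count)
  out <- as_tibble(profile)
  out$fraction <- if (total > 0) out$count / total else rep(NA_real_, nrow(out))
  out
}

#' Collapse rare taxa into "others"
#'
#' Display helper mirroring the common composition-plot rule of folding every
#' taxon below an abundance cutoff (default 2%) into a single "others" row.
#'
#' @param abundance A tibble from [relative_abundance()].
#' @param cutoff Fraction below-or-at which taxa are folded (default `0.02`;
#'   taxa must exceed it to keep their own row).
#' @return A tibble of the same shape; the folded row has `tax_id = NA` and
#'   `name = "others"`.
#' @export
collapse_others <- function(abundance, cutoff = 0.02) {
  keep <- abundance$fraction > cutoff
  if (all(keep)) return(abundance)
  folded <- abundance[!keep, ]
  dplyr::bind_rows(
    abundance[keep, ],
    tibble(tax_id = NA_integer_, name = "others",
           count = sum(folded$count), fraction = sum(folded$fraction))
  )
}

#' Rarefy a profile to a fixed depth
#'
#' Subsamples reads without replacement (a multivariate hypergeometric draw)
#' to exactly `depth` reads, the ecological convention for normalising
#' sequencing effort across samples.
#'
#' @param profile A `community_profile`.
#' @param depth Target read count; must not exceed the profile total. A
#'   sample below the target depth is refused (it would be dropped from an
#'   analysis, not padded).
#' @param seed Integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @return A rarefied `community_profile` with exactly `depth` reads.
#' @export
rarefy <- function(profile, depth, seed = NULL) {
  total <- attr(profile, "total_reads") %||% sum(profile$count)
  depth <- as.integer(depth)
  if (depth > total) {
    abort(paste0("rarefy(): depth ", depth, " exceeds profile total ", total,
                 "; sample would be dropped"))
  }
  draw <- function() {
    pool <- rep.int(seq_len(nrow(profile)), profile$count)
    picked <- sample(pool, depth, replace = FALSE)
    tabulate(picked, nbins = nrow(profile))
  }
  counts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble(tax_id = profile$tax_id, name = profile$name,
                count = as.integer(counts))
  out <- arrange(out[out$count > 0L, ], dplyr::desc(.data$count), .data$tax_id)
  new_profile(out, rank = attr(profile, "rank"))
}

#' Observed species richness
#'
#' Number of taxa whose relative abundance exceeds `floor` (default 0: every
#' taxon with at least one read counts).
#'
#' @param profile A `community_profile`.
#' @param floor Minimum relative abundance (fraction) a taxon must exceed.
#' @return Integer count of taxa.
#' @export
observed_species <- function(profile, floor = 0) {
  if (nrow(profile) == 0) return(0L)
  ra <- relative_abundance(profile)
  sum(ra$fraction > floor)
}

#' Fraction of classifiable reads retained per parameter setting
#'
#' Given one assignment table per parameter setting, reports the percentage
#' of classifiable reads (everything except `unclassified`) that survive with
#' an included status. Along a ladder of nested (tightening) thresholds the
#' retained percentage is non-increasing.
#'
#' @param assignment_sets Named list of read-assignment tibbles, one per
#'   setting.
#' @param include Statuses counted as retained (default `"verified"`).
#' @return A tibble (`setting`, `retained`, `classifiable`, `retained_pct`).
#' @export
retained_fraction <- function(assignment_sets, include = "verified") {
  stopifnot(is.list(assignment_sets), length(assignment_sets) > 0)
  nm <- names(assignment_sets) %||% as.character(seq_along(assignment_sets))
  purrr::map2(assignment_sets, nm, function(a, label) {
    classifiable <- sum(a$status != "unclassified")
    retained <- sum(a$status %in% include)
    tibble(
      setting = label, retained = retained, classifiable = classifiable,
      retained_pct = if (classifiable > 0) 100 * retained / classifiable
                     else NA_real_
    )
  }) |> dplyr::bind_rows()
}

#' Minimum-prevalence filter across samples
#'
#' Simple stand-in for heavier prevalence-filtering procedures: keeps taxa
#' present (count > 0) in at least `min_samples` of the supplied profiles.
#'
#' @param profiles List of `community_profile`s at a common rank.
#' @param min_samples Minimum number of profiles a taxon must appear in.
#' @return The list of profiles with non-prevalent taxa removed.
#' @export
prevalence_filter <- function(profiles, min_samples = 2L) {
  stopifnot(length(profiles) >= 1)
  prev <- table(unlist(lapply(profiles, function(p) unique(p$tax_id))))
  keep <- as.integer(names(prev)[prev >= min_samples])
  lapply(profiles, function(p) {
    new_profile(p[p$tax_id %in% keep, , drop = FALSE],
                rank = attr(p, "rank"))
  })
}
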