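# Read-level filtering and alignment verification.
#
# Stage 1 (classifier_filter): per-read quality-score and multi-match cutoffs
# on the classifier hit table, keeping the best-scoring candidate taxon.
# Stage 2 (verify_assignments): each surviving read->taxon call is checked
# against reference alignments; it is accepted only if an alignment to the
# same taxon (at the agreement rank) passes both the alignment-score (AS) and
# query-coverage (Cov) thresholds.

.tv_statuses <- c(
  "verified", "classifier_only", "rejected_low_score", "rejected_multimatch",
  "rejected_no_alignment", "rejected_low_coverage", "rejected_low_AS",
  "rejected_disagreement", "unclassified"
)

#' Filtering and verification parameters
#'
#' Bundles the thresholds of the two-stage read filter. Defaults are the
#' operating point selected on a gut mock community: classifier quality score
#' >= 150, at most 50 candidate taxa per read, alignment score (AS) >= 1500
#' and query coverage (Cov) >= 50%.
#'
#' @param min_score Minimum classifier quality score for the best hit.
#' @param max_matches Maximum number of distinct candidate taxa a read may
#'   have; reads exceeding it are discarded as low-information.
#' @param min_alignment_score Minimum AS for verification.
#' @param min_coverage_pct Minimum query coverage (percent, 0-100) for
#'   verification.
#' @param agreement_rank Rank at which classifier and alignment taxa must
#'   agree (default `"species"`).
#' @param min_hit_ratio Optional minimum clamped hit-length/query-length
#'   ratio; candidate hits below it are ignored before best-hit selection.
#'   Default `NULL` (the ratio is diagnostic only).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_score = 150L, max_matches = 50L,
                          min_alignment_score = 1500L,
                          min_coverage_pct = 50, agreement_rank = "species",
                          min_hit_ratio = NULL) {
  stopifnot(min_score >= 0, max_matches >= 0, min_alignment_score >= 0,
            min_coverage_pct >= 0, min_coverage_pct <= 100)
  if (!agreement_rank %in% .tv_ranks) {
    abort(paste0("filter_params(): unknown rank: ", agreement_rank))
  }
  if (!is.null(min_hit_ratio)) {
    stopifnot(min_hit_ratio >= 0, min_hit_ratio <= 1)
  }
  structure(
    list(min_score = as.integer(min_score),
         max_matches = as.numeric(max_matches),
         min_alignment_score = as.integer(min_alignment_score),
         min_coverage_pct = as.numeric(min_coverage_pct),
         agreement_rank = agreement_rank,
         min_hit_ratio = min_hit_ratio),
    class = "filter_params"
  )
}

#' Query coverage of an alignment
#'
#' Percentage of the read covered by the alignment on the query side:
#' `100 * (query_end - query_start) / query_length`.
#'
#' @param alns A tibble with columns `query_start`, `query_end`,
#'   `query_length` (e.g. from [read_paf()]).
#' @return Numeric vector of coverages in `[0, 100]`.
#' @export
coverage_of <- function(alns) {
  100 * (alns$query_end - alns$query_start) / alns$query_length
}

.tv_hit_ratio <- function(hit_length, query_length) {
  pmin(1, pmax(0, hit_length / query_length))
}

#' Best classifier hit per read
#'
#' The candidate with the highest quality score wins; ties are broken by file
#' order (first row wins), matching the convention that the classifier prints
#' its preferred hit first.
#'
#' @param hits Hit-table tibble ([read_hit_table()] shape) for one or many
#'   reads.
#' @return One row per `read_id`, in order of first appearance.
#' @export
best_classifier_hit <- function(hits) {
  if (nrow(hits) == 0) abort("best_classifier_hit(): empty hit table")
  hits |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$read_id) |>
    filter(.data$score == max(.data$score)) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$.row) |>
    select(-".row")
}

#' Classifier-stage filter
#'
#' Reduces a multi-candidate hit table to one verdict per read, before
#' alignment verification. Per read: `unclassified` if only `tax_id == 0`
#' rows are present; `rejected_low_score` if the best score falls below
#' `min_score`; `rejected_multimatch` if the read's `num_matches` exceeds
#' `max_matches`; otherwise `classifier_only` carrying the best hit's taxon.
#' If `min_hit_ratio` is set, candidate hits whose clamped
#' hit-length/query-length ratio falls below it are ignored before best-hit
#' selection (a read losing all candidates this way is `unclassified`).
#'
#' @param hits Hit-table tibble ([read_hit_table()] shape).
#' @param params A [filter_params()].
#' @return A read-assignment tibble: one row per read (`read_id`, `tax_id`
#'   (`NA` unless assigned), `status`, `best_score`, `num_matches`,
#'   `coverage_pct`, `alignment_score`), in order of first appearance.
#' @export
classifier_filter <- function(hits, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  empty <- tibble(
    read_id = character(), tax_id = integer(), status = character(),
    best_score = integer(), num_matches = integer(),
    coverage_pct = double(), alignment_score = integer()
  )
  if (nrow(hits) == 0) return(empty)

  hits <- mutate(hits, .row = dplyr::row_number())
  reads <- distinct(hits, .data$read_id)   # order of first appearance

  usable <- filter(hits, .data$tax_id != 0L)
  if (!is.null(params$min_hit_ratio)) {
    usable <- filter(
      usable,
      .tv_hit_ratio(.data$hit_length, .data$query_length) >= params$min_hit_ratio
    )
  }

  best <- usable |>
    group_by(.data$read_id) |>
    filter(.data$score == max(.data$score)) |>
    slice(1L) |>
    ungroup()

  out <- reads |>
    left_join(select(best, "read_id", "tax_id", "score", "num_matches"),
              by = "read_id") |>
    mutate(
      status = dplyr::case_when(
        is.na(.data$tax_id) ~ "unclassified",
        .data$score < params$min_score ~ "rejected_low_score",
        .data$num_matches > params$max_matches ~ "rejected_multimatch",
        TRUE ~ "classifier_only"
      ),
      tax_id = ifelse(.data$status == "classifier_only", .data$tax_id,
                      NA_integer_),
      best_score = dplyr::coalesce(.data$score, NA_integer_),
      coverage_pct = NA_real_,
      alignment_score = NA_integer_
    ) |>
    select("read_id", "tax_id", "status", "best_score", "num_matches",
           "coverage_pct", "alignment_score")
  out
}

#' Verify classifier assignments against alignments
#'
#' For every `classifier_only` read, its alignments are mapped to taxa through
#' the catalog and checked for agreement with the classifier taxon at
#' `agreement_rank`. Among agreeing alignments the best one wins (highest AS,
#' then largest query span, then first occurrence). The read becomes
#' `verified` if that alignment has AS >= `min_alignment_score` and coverage
#' >= `min_coverage_pct`; otherwise it is rejected with a reason:
#' `rejected_low_AS` / `rejected_low_coverage` (AS is tested first so the
#' label is deterministic; the accept/reject verdict is order-independent),
#' `rejected_disagreement` when alignments exist but none agree at rank, and
#' `rejected_no_alignment` when the read has no (scored) alignment at all.
#' Alignments without an AS tag are excluded from verification. Reads already
#' rejected by the classifier stage pass through unchanged.
#'
#' @param assignments Output of [classifier_filter()].
#' @param alns Alignment tibble ([read_paf()] shape).
#' @param catalog Catalog tibble (`seq_id`, `tax_id`) mapping alignment
#'   targets to taxa; every aligned target must be present.
#' @param tax A [taxonomy()].
#' @param params A [filter_params()].
#' @return A read-assignment tibble (same shape and read order as
#'   `assignments`).
#' @export
verify_assignments <- function(assignments, alns, catalog, tax,
                               params = filter_params()) {
  stopifnot(inherits(params, "filter_params"), inherits(tax, "taxonomy"))

  candidates <- filter(assignments, .data$status == "classifier_only")
  if (nrow(candidates) == 0) return(assignments)

  alns <- filter(alns, .data$read_id %in% candidates$read_id)
  missing_targets <- setdiff(unique(alns$target_id), catalog$seq_id)
  if (length(missing_targets) > 0) {
    abort(paste0("verify_assignments(): alignment target(s) absent from ",
                 "catalog: ", paste(missing_targets, collapse = ", ")))
  }
  alns <- filter(alns, !is.na(.data$alignment_score))

  aln_tax <- alns |>
    left_join(catalog, by = c(target_id = "seq_id")) |>
    mutate(coverage_pct = coverage_of(alns),
           span = .data$query_end - .data$query_start)

  # classifier taxon for each read, resolved once at the agreement rank
  cand <- candidates |>
    mutate(cls_rank = resolve_at_rank(tax, .data$tax_id, params$agreement_rank))

  aln_tax <- aln_tax |>
    mutate(tgt_rank = resolve_at_rank(tax, .data$tax_id, params$agreement_rank)) |>
    select("read_id", "coverage_pct", "span", "alignment_score", "tgt_rank")

  joined <- left_join(
    select(cand, "read_id", "cls_rank"),
    aln_tax, by = "read_id", relationship = "one-to-many"
  )

  verdicts <- joined |>
    mutate(
      has_aln = !is.na(.data$alignment_score),
      agrees = .data$has_aln & !is.na(.data$cls_rank) &
        !is.na(.data$tgt_rank) & .data$cls_rank == .data$tgt_rank,
      .ord = dplyr::row_number()
    ) |>
    group_by(.data$read_id) |>
    summarise(
      n_aln = sum(.data$has_aln),
      n_agree = sum(.data$agrees),
      best = list({
        ag <- dplyr::pick(dplyr::everything())
        ag <- ag[ag$agrees, , drop = FALSE]
        if (nrow(ag) == 0) NULL else {
          ag <- ag[order(-ag$alignment_score, -ag$span, ag$.ord), ,
                   drop = FALSE]
          ag[1L, ]
        }
      }),
      .groups = "drop"
    ) |>
    mutate(
      best_as = vapply(.data$best, function(b) {
        if (is.null(b)) NA_integer_ else as.integer(b$alignment_score)
      }, integer(1)),
      best_cov = vapply(.data$best, function(b) {
        if (is.null(b)) NA_real_ else b$coverage_pct
      }, double(1)),
      new_status = dplyr::case_when(
        .data$n_aln == 0L ~ "rejected_no_alignment",
        .data$n_agree == 0L ~ "rejected_disagreement",
        .data$best_as < params$min_alignment_score ~ "rejected_low_AS",
        .data$best_cov < params$min_coverage_pct ~ "rejected_low_coverage",
        TRUE ~ "verified"
      )
    ) |>
    select("read_id", "new_status", "best_as", "best_cov")

  assignments |>
    left_join(verdicts, by = "read_id") |>
    mutate(
      status = ifelse(.data$status == "classifier_only", .data$new_status,
                      .data$status),
      tax_id = ifelse(.data$status %in% c("verified", "classifier_only"),
                      .data$tax_id, NA_integer_),
      alignment_score = ifelse(.data$status == "verified", .data$best_as,
                               NA_integer_),
      coverage_pct = ifelse(.data$status == "verified", .data$best_cov,
                            NA_real_)
    ) |>
    select("read_id", "tax_id", "status", "best_score", "num_matches",
           "coverage_pct", "alignment_score")
}

#' Run the full two-stage filter
#'
#' Convenience wrapper: [classifier_filter()] followed by
#' [verify_assignments()].
#'
#' @inheritParams verify_assignments
#' @param hits Hit-table tibble.
#' @return A read-assignment tibble.
#' @export
filter_reads <- function(hits, alns, catalog, tax, params = filter_params()) {
  verify_assignments(classifier_filter(hits, params), alns, catalog, tax,
                     params)
}

#' Overlap between two assignment sets
#'
#' Compares two read->taxon assignment tables (typically classifier-only vs
#' alignment-verified) as sets of (read, taxon-at-rank) pairs, the Venn logic
#' used to quantify how many classifications survive alignment control.
#'
#' @param classifier,verified Read-assignment tibbles covering the same read
#'   ids; rows whose `tax_id` is `NA` contribute no pair.
#' @param tax A [taxonomy()].
#' @param rank Rank at which taxa are compared.
#' @return A one-row tibble: `both`, `classifier_only_set`,
#'   `verified_only_set` (pair counts), plus the corresponding fractions of
#'   the pair union (summing to 1 when the union is non-empty).
#' @export
assignment_overlap <- function(classifier, verified, tax, rank = "species") {
  if (!setequal(classifier$read_id, verified$read_id)) {
    abort("assignment_overlap(): the two sets must cover the same read ids")
  }
  pairs <- function(a) {
    a <- a[!is.na(a$tax_id), c("read_id", "tax_id")]
    a$at_rank <- resolve_at_rank(tax, a$tax_id, rank)
    a[!is.na(a$at_rank), c("read_id", "at_rank")]
  }
  pa <- pairs(classifier)
  pb <- pairs(verified)
  key_a <- paste(pa$read_id, pa$at_rank)
  key_b <- paste(pb$read_id, pb$at_rank)
  both <- length(intersect(key_a, key_b))
  a_only <- length(setdiff(key_a, key_b))
  b_only <- length(setdiff(key_b, key_a))
  union_n <- both + a_only + b_only
  tibble(
    both = both, classifier_only_set = a_only, verified_only_set = b_only,
    frac_both = if (union_n > 0) both / union_n else NA_real_,
    frac_classifier_only = if (union_n > 0) a_only / union_n else NA_real_,
    frac_verified_only = if (union_n > 0) b_only / union_n else NA_real_
  )
}

#' Sweep the classifier score threshold
#'
#' Re-runs the filter over an ascending ladder of minimum classifier scores
#' and reports, for each threshold, how many reads survive the classifier
#' stage alone and how many survive verification, together with the
#' difference quotient `g = delta(retained) / delta(threshold)` between
#' consecutive thresholds (the discrete slope of each retention curve).
#'
#' @inheritParams verify_assignments
#' @param hits Hit-table tibble.
#' @param thresholds Ascending integer vector of `min_score` values
#'   (length >= 2).
#' @return A tibble (`threshold`, `retained_classifier`, `retained_verified`,
#'   `g_classifier`, `g_verified`); `g_*` is `NA` on the first row.
#' @export
score_threshold_sweep <- function(hits, alns, catalog, tax,
                                  params = filter_params(),
                                  thresholds = c(0L, 150L, 300L, 450L, 600L)) {
  if (length(thresholds) < 2L) {
    abort("score_threshold_sweep(): need at least two thresholds")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("score_threshold_sweep(): thresholds must be strictly ascending")
  }
  rows <- purrr::map(thresholds, function(th) {
    p <- params
    p$min_score <- as.integer(th)
    pre <- classifier_filter(hits, p)
    post <- verify_assignments(pre, alns, catalog, tax, p)
    tibble(
      threshold = as.integer(th),
      retained_classifier = sum(pre$status == "classifier_only"),
      retained_verified = sum(post$status == "verified")
    )
  })
  out <- dplyr::bind_rows(rows)
  out$g_classifier <- c(NA, diff(out$retained_classifier) / diff(out$threshold))
  out$g_verified <- c(NA, diff(out$retained_verified) / diff(out$threshold))
  out
}

#' Per-read hit-ratio diagnostics
#'
#' Computes, for the best candidate of each read, the clamped
#' hit-length/query-length ratio (the fraction of the read supporting the
#' assignment) alongside the score and the read's candidate count, plus a
#' quartile summary stratified by whether the read exceeds `max_matches`.
#' Reads reporting more candidates than `max_matches` typically sit below the
#' first quartile of both ratio and score, which is the rationale for
#' discarding them.
#'
#' @param hits Hit-table tibble.
#' @param max_matches Stratification cutoff on `num_matches`.
#' @return A list with `reads` (tibble: `read_id`, `num_matches`,
#'   `hit_ratio`, `score`) and `summary` (quartiles of ratio and score per
#'   stratum).
#' @export
hit_ratio_diagnostics <- function(hits, max_matches = 50L) {
  if (nrow(hits) == 0) abort("hit_ratio_diagnostics(): empty hit table")
  reads <- hits |>
    filter(.data$tax_id != 0L) |>
    best_classifier_hit() |>
    mutate(hit_ratio = .tv_hit_ratio(.data$hit_length, .data$query_length)) |>
    select("read_id", "num_matches", "hit_ratio", "score")
  summary <- reads |>
    mutate(stratum = ifelse(.data$num_matches > max_matches,
                            "above_max_matches", "at_or_below_max_matches")) |>
    group_by(.data$stratum) |>
    summarise(
      n = n(),
      ratio_q1 = stats::quantile(.data$hit_ratio, 0.25),
      ratio_median = stats::median(.data$hit_ratio),
      ratio_q3 = stats::quantile(.data$hit_ratio, 0.75),
      score_q1 = stats::quantile(.data$score, 0.25),
      score_median = stats::median(.data$score),
      score_q3 = stats::quantile(.data$score, 0.75),
      .groups = "drop"
    )
  list(reads = reads, summary = summary)
}
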