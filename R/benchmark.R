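# Benchmarking predicted community profiles against a known (mock-community)
# composition: set-based precision/recall under a relative-abundance floor,
# and the area under the precision-recall curve (AUPR) obtained by sweeping a
# detection threshold down the abundance-ranked predictions.

#' Ground-truth community composition
#'
#' @param abundances Data frame with columns `tax_id` and `fraction`
#'   (optionally `name`); fractions must sum to 1.
#' @param rank Rank of the taxa.
#' @return A `ground_truth` tibble.
#' @export
ground_truth <- function(abundances, rank = "species") {
  stopifnot(is.data.frame(abundances),
            all(c("tax_id", "fraction") %in% names(abundances)))
  tbl <- as_tibble(abundances)
  if (!"name" %in% names(tbl)) tbl$name <- NA_character_
  tbl <- tbl[c("tax_id", "name", "fraction")]
  tbl$tax_id <- as.integer(tbl$tax_id)
  if (abs(sum(tbl$fraction) - 1) > 1e-9) {
    abort("ground_truth(): fractions must sum to 1")
  }
  if (anyDuplicated(tbl$tax_id)) abort("ground_truth(): duplicated tax_id")
  structure(tbl, rank = rank, class = c("ground_truth", class(tibble())))
}

# default abundance floor: 1e-5 percent, i.e. 1e-7 as a fraction
.tv_default_floor <- 1e-7

.tv_profile_fractions <- function(pred) {
  if (inherits(pred, "community_profile")) {
    relative_abundance(pred)
  } else {
    as_tibble(pred)
  }
}

#' Precision and recall of a predicted profile
#'
#' The predicted taxon set is every taxon whose relative abundance is at
#' least `floor` (default 1e-7, i.e. 1e-5 percent — the floor keeps
#' vanishingly rare, usually spurious, detections out of the comparison).
#' The floor applies to predictions only: all ground-truth taxa count,
#' however rare. Precision = TP/(TP+FP); recall = TP/(TP+FN). When nothing
#' is predicted, precision is 1 if the truth is also empty and 0 otherwise by
#' convention.
#'
#' @param pred A `community_profile` (or a tibble with `tax_id` and
#'   `fraction`).
#' @param truth A [ground_truth()].
#' @param floor Minimum predicted relative abundance (fraction).
#' @return A one-row tibble (`precision`, `recall`, `tp`, `fp`, `fn`,
#'   `floor`).
#' @export
precision_recall <- function(pred, truth, floor = .tv_default_floor) {
  stopifnot(inherits(truth, "ground_truth"))
  if (inherits(pred, "community_profile") &&
      !identical(attr(pred, "rank"), attr(truth, "rank"))) {
    abort(paste0("precision_recall(): rank mismatch (prediction at ",
                 attr(pred, "rank"), ", truth at ", attr(truth, "rank"), ")"))
  }
  ra <- .tv_profile_fractions(pred)
  predicted <- unique(ra$tax_id[!is.na(ra$fraction) & ra$fraction >= floor])
  truth_set <- unique(truth$tax_id)
  tp <- length(intersect(predicted, truth_set))
  fp <- length(setdiff(predicted, truth_set))
  fn <- length(setdiff(truth_set, predicted))
  precision <- if (tp + fp > 0) tp / (tp + fp) else as.numeric(fn == 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 1
  tibble(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn,
         floor = floor)
}

#' Area under the precision-recall curve
#'
#' Ranks predicted taxa by relative abundance (descending) and sweeps a
#' detection cutoff through every distinct abundance value; at each cutoff
#' the taxa at or above it form the predicted set and a (precision, recall)
#' point is computed against the truth set. The area is integrated over
#' recall by the trapezoidal rule, anchored at recall 0 with the first
#' point's precision.
#'
#' @inheritParams precision_recall
#' @param floor Taxa below this relative abundance are discarded before
#'   ranking (default 0: rank everything).
#' @return A list with `aupr` (number) and `curve` (tibble `threshold`,
#'   `precision`, `recall`, ordered by descending threshold / ascending
#'   recall).
#' @export
aupr <- function(pred, truth, floor = 0) {
  stopifnot(inherits(truth, "ground_truth"))
  if (nrow(truth) == 0) abort("aupr(): empty truth")
  ra <- .tv_profile_fractions(pred)
  ra <- ra[!is.na(ra$fraction) & ra$fraction >= floor & ra$fraction > 0, ]
  truth_set <- unique(truth$tax_id)
  if (nrow(ra) == 0) {
    return(list(aupr = 0,
                curve = tibble(threshold = double(), precision = double(),
                               recall = double())))
  }
  thresholds <- sort(unique(ra$fraction), decreasing = TRUE)
  curve <- purrr::map(thresholds, function(th) {
    predicted <- ra$tax_id[ra$fraction >= th]
    tp <- length(intersect(predicted, truth_set))
    tibble(
      threshold = th,
      precision = tp / length(predicted),
      recall = tp / length(truth_set)
    )
  }) |> dplyr::bind_rows()
  rec <- c(0, curve$recall)
  prec <- c(curve$precision[1], curve$precision)
  area <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  list(aupr = area, curve = curve)
}

#' Benchmark one predicted profile
#'
#' Bundles [precision_recall()] and [aupr()] (both using the same prediction
#' floor) into a single result object with broom-style [generics::tidy()] and
#' [generics::glance()] methods.
#'
#' @inheritParams precision_recall
#' @return A `benchmark_result`: list with `precision`, `recall`, `aupr`,
#'   `tp`, `fp`, `fn`, `abundance_floor` and the PR `curve`.
#' @export
benchmark_profile <- function(pred, truth, floor = .tv_default_floor) {
  pr <- precision_recall(pred, truth, floor)
  au <- aupr(pred, truth, floor)
  structure(
    list(precision = pr$precision, recall = pr$recall, aupr = au$aupr,
         tp = pr$tp, fp = pr$fp, fn = pr$fn, abundance_floor = floor,
         curve = au$curve),
    class = "benchmark_result"
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf(
    "<benchmark_result> precision %.3f, recall %.3f, AUPR %.3f (TP %d, FP %d, FN %d; floor %g)\n",
    x$precision, x$recall, x$aupr, x$tp, x$fp, x$fn, x$abundance_floor))
  invisible(x)
}

#' Tidy a benchmark result
#'
#' `tidy()` returns the precision-recall curve, one row per detection
#' threshold; `glance()` returns a one-row summary of the headline metrics.
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) x$curve

#' @rdname tidy.benchmark_result
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  tibble(precision = x$precision, recall = x$recall, aupr = x$aupr,
         tp = x$tp, fp = x$fp, fn = x$fn, abundance_floor = x$abundance_floor)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Sweep alignment-score and coverage thresholds
#'
#' Evaluates the full Cartesian grid of alignment-score (AS) and coverage
#' (Cov) thresholds: for each combination the two-stage filter is re-run, a
#' profile is built from verified reads, and precision / recall / AUPR are
#' computed against the truth. Used to pick the verification operating point.
#'
#' @inheritParams verify_assignments
#' @param hits Hit-table tibble.
#' @param truth A [ground_truth()].
#' @param as_values,cov_values Threshold grids (non-empty numeric vectors).
#' @param floor Prediction abundance floor.
#' @return A tibble (`min_alignment_score`, `min_coverage_pct`, `precision`,
#'   `recall`, `aupr`, `tp`, `fp`, `fn`, `n_verified`).
#' @export
grid_sweep <- function(hits, alns, catalog, tax, truth,
                       params = filter_params(),
                       as_values = c(0L, 500L, 1000L, 1500L, 2000L),
                       cov_values = c(0, 10, 50, 80),
                       floor = .tv_default_floor) {
  stopifnot(length(as_values) > 0, length(cov_values) > 0)
  pre <- classifier_filter(hits, params)
  grid <- tidyr::expand_grid(as_th = as_values, cov_th = cov_values)
  purrr::pmap(grid, function(as_th, cov_th) {
    p <- params
    p$min_alignment_score <- as.integer(as_th)
    p$min_coverage_pct <- cov_th
    post <- verify_assignments(pre, alns, catalog, tax, p)
    prof <- build_profile(post, tax, rank = attr(truth, "rank"))
    res <- benchmark_profile(prof, truth, floor)
    tibble(
      min_alignment_score = as.integer(as_th), min_coverage_pct = cov_th,
      precision = res$precision, recall = res$recall, aupr = res$aupr,
      tp = res$tp, fp = res$fp, fn = res$fn,
      n_verified = sum(post$status == "verified")
    )
  }) |> dplyr::bind_rows()
}

#' Benchmark several classifiers' read tables
#'
#' Adapts any classifier's per-read output (a table of `read_id`, `tax_id`)
#' to a species-rank profile and benchmarks each against the same truth, so
#' different tools can be compared on precision, recall and AUPR.
#'
#' @param pred_tables Named list of tibbles, each with columns `read_id` and
#'   `tax_id` (one assignment per read).
#' @param truth A [ground_truth()].
#' @param tax A [taxonomy()].
#' @param floor Prediction abundance floor.
#' @return A tibble, one row per method (`method`, `precision`, `recall`,
#'   `aupr`, `tp`, `fp`, `fn`, `n_reads`), plus the per-method
#'   `benchmark_result`s in the `results` attribute.
#' @export
compare_profiles <- function(pred_tables, truth, tax,
                             floor = .tv_default_floor) {
  stopifnot(is.list(pred_tables), length(pred_tables) > 0)
  nm <- names(pred_tables) %||% as.character(seq_along(pred_tables))
  results <- purrr::map(pred_tables, function(tbl) {
    stopifnot(all(c("read_id", "tax_id") %in% names(tbl)))
    tbl <- tbl[!is.na(tbl$tax_id) & tbl$tax_id != 0L, ]
    .tv_check_ids(tax, tbl$tax_id)
    assignments <- tibble(read_id = tbl$read_id, tax_id = as.integer(tbl$tax_id),
                          status = "classifier_only")
    prof <- build_profile(assignments, tax, rank = attr(truth, "rank"),
                          include = "classifier_only")
    benchmark_profile(prof, truth, floor)
  })
  out <- purrr::map2(results, nm, function(r, label) {
    dplyr::bind_cols(tibble(method = label), glance(r)[
      c("precision", "recall", "aupr", "tp", "fp", "fn")])
  }) |> dplyr::bind_rows()
  out$n_reads <- vapply(pred_tables, nrow, integer(1))
  attr(out, "results") <- results
  out
}
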