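test_that("coverage is the query-span percentage of read length", {
  alns <- dplyr::bind_rows(
    aln_row("r1", 11L, 1600L, query_length = 1000L, query_start = 100L,
            query_end = 900L),
    aln_row("r2", 11L, 1600L, query_length = 1000L, query_start = 0L,
            query_end = 1000L),
    aln_row("r3", 11L, 1600L, query_length = 1000L, query_start = 0L,
            query_end = 450L)
  )
  expect_equal(coverage_of(alns), c(80, 100, 45))
  # a 45% span fails the default 50% coverage threshold
  expect_true(coverage_of(alns)[3] < filter_params()$min_coverage_pct)
})

test_that("best hit takes the maximum score, first row on ties", {
  hits <- dplyr::bind_rows(
    hit_row("r1", 11L, 300L),
    hit_row("r1", 12L, 150L),
    hit_row("r2", 21L, 200L),
    hit_row("r2", 12L, 200L)   # tie: first row must win
  )
  best <- best_classifier_hit(hits)
  expect_equal(best$tax_id[best$read_id == "r1"], 11L)
  expect_equal(best$tax_id[best$read_id == "r2"], 21L)
  expect_error(best_classifier_hit(hits[0, ]), "empty")
})

test_that("best hit equals the (score desc, row asc) winner on permutations", {
  set.seed(42)
  base <- dplyr::bind_rows(
    hit_row("rA", 11L, 200L), hit_row("rA", 12L, 200L),
    hit_row("rA", 21L, 180L), hit_row("rB", 12L, 90L),
    hit_row("rB", 11L, 95L)
  )
  for (i in 1:20) {
    perm <- base[sample.int(nrow(base)), ]
    best <- best_classifier_hit(perm)
    # oracle: scan rows in order keeping the first maximum per read
    for (rid in unique(perm$read_id)) {
      rows <- perm[perm$read_id == rid, ]
      want <- rows[which.max(rows$score), ]
      got <- best[best$read_id == rid, ]
      expect_equal(got$tax_id, want$tax_id)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("classifier filter applies score and multi-match cutoffs", {
  hits <- dplyr::bind_rows(
    hit_row("r_low", 11L, 140L),                      # below score 150
    hit_row("r_multi", 11L, 300L, num_matches = 60L), # above 50 matches
    hit_row("r_ok", 12L, 300L, num_matches = 3L),
    hit_row("r_uncl", 0L, 0L)                         # tax_id 0 only
  )
  out <- classifier_filter(hits, filter_params())
  expect_equal(nrow(out), 4)
  st <- setNames(out$status, out$read_id)
  expect_equal(st[["r_low"]], "rejected_low_score")
  expect_equal(st[["r_multi"]], "rejected_multimatch")
  expect_equal(st[["r_ok"]], "classifier_only")
  expect_equal(st[["r_uncl"]], "unclassified")
  expect_equal(out$tax_id[out$read_id == "r_ok"], 12L)
  expect_true(all(is.na(out$tax_id[out$read_id != "r_ok"])))

  # min_hit_ratio drops low-ratio candidates before best-hit selection
  hits2 <- dplyr::bind_rows(
    hit_row("q", 11L, 400L, hit_length = 100L, query_length = 1000L),
    hit_row("q", 12L, 200L, hit_length = 800L, query_length = 1000L)
  )
  out2 <- classifier_filter(hits2, filter_params(min_hit_ratio = 0.3))
  expect_equal(out2$tax_id, 12L)   # the 0.1-ratio 400-score row is ignored
})

test_that("verification accepts agreeing alignments passing AS and Cov", {
  tax <- toy_tax()
  cat_tbl <- catalog_for(tax)
  p <- filter_params()   # AS 1500, Cov 50, species rank
  pre <- classifier_filter(hit_row("r1", 11L, 300L), p)

  # agreeing alignment AS 1600, coverage 80% -> verified
  ok <- verify_assignments(pre, aln_row("r1", 11L, 1600L), cat_tbl, tax, p)
  expect_equal(ok$status, "verified")
  expect_equal(ok$tax_id, 11L)
  expect_equal(ok$coverage_pct, 80)
  expect_equal(ok$alignment_score, 1600L)

  # strain-level alignment target agrees at species rank
  ok2 <- verify_assignments(pre, aln_row("r1", 13L, 1600L), cat_tbl, tax, p)
  expect_equal(ok2$status, "verified")

  # coverage 45% -> rejected_low_coverage
  low_cov <- verify_assignments(
    pre, aln_row("r1", 11L, 1600L, query_end = 450L), cat_tbl, tax, p)
  expect_equal(low_cov$status, "rejected_low_coverage")

  # AS 1400 -> rejected_low_AS (AS is checked before coverage)
  low_as <- verify_assignments(
    pre, aln_row("r1", 11L, 1400L, query_end = 450L), cat_tbl, tax, p)
  expect_equal(low_as$status, "rejected_low_AS")

  # alignments only to a different species -> rejected_disagreement
  dis <- verify_assignments(pre, aln_row("r1", 12L, 1600L), cat_tbl, tax, p)
  expect_equal(dis$status, "rejected_disagreement")

  # no alignment at all -> rejected_no_alignment
  none <- verify_assignments(pre, aln_row("zzz", 11L, 1600L), cat_tbl, tax, p)
  expect_equal(none$status, "rejected_no_alignment")

  # AS-less alignments are excluded from verification
  no_as <- aln_row("r1", 11L, 1600L)
  no_as$alignment_score <- NA_integer_
  expect_equal(verify_assignments(pre, no_as, cat_tbl, tax, p)$status,
               "rejected_no_alignment")

  # unknown alignment target -> configuration error naming the seq_id
  bad <- aln_row("r1", 999L, 1600L)
  expect_error(verify_assignments(pre, bad, cat_tbl, tax, p), "ref_999")

  # already-rejected reads pass through unchanged
  pre_low <- classifier_filter(hit_row("r1", 11L, 100L), p)
  through <- verify_assignments(pre_low, aln_row("r1", 11L, 1600L),
                                cat_tbl, tax, p)
  expect_equal(through$status, "rejected_low_score")
})

test_that("among agreeing alignments the best AS wins, ties by span", {
  tax <- toy_tax()
  cat_tbl <- catalog_for(tax)
  p <- filter_params()
  pre <- classifier_filter(hit_row("r1", 11L, 300L), p)
  alns <- dplyr::bind_rows(
    aln_row("r1", 11L, 1700L, query_end = 600L),  # best AS, cov 60
    aln_row("r1", 11L, 1600L, query_end = 900L),  # higher cov, lower AS
    aln_row("r1", 13L, 1700L, query_end = 550L)   # tie AS, smaller span
  )
  out <- verify_assignments(pre, alns, cat_tbl, tax, p)
  expect_equal(out$alignment_score, 1700L)
  expect_equal(out$coverage_pct, 60)
})

test_that("verification verdicts match the brute-force oracle on random fixtures", {
  spec <- community_preset("ten_taxa")
  cfg <- sim_config(n_reads = 150, seed = 99, fp_read_fraction = 0.15,
                    multimatch_fraction = 0.1, low_score_fraction = 0.15,
                    missing_alignment_fraction = 0.1, low_as_fraction = 0.15,
                    low_cov_fraction = 0.15, disagreement_fraction = 0.1)
  sim <- simulate_community(spec, cfg, n_decoys = 3L, genome_length = 2000L)
  p <- filter_params()
  pre <- classifier_filter(sim$hits, p)
  got <- verify_assignments(pre, sim$alns, sim$ref$catalog, sim$ref$tax, p)
  want <- oracle_verify(pre, sim$alns, sim$ref$catalog, sim$ref$tax, p)
  expect_equal(got, want)
  # conservation: every input read exactly once, with one status each
  expect_setequal(got$read_id, unique(sim$hits$read_id))
  expect_equal(anyDuplicated(got$read_id), 0L)
  expect_true(all(got$status %in% c(
    "verified", "classifier_only", "rejected_low_score",
    "rejected_multimatch", "rejected_no_alignment", "rejected_low_coverage",
    "rejected_low_AS", "rejected_disagreement", "unclassified")))
  # tax_id present iff accepted
  expect_equal(!is.na(got$tax_id),
               got$status %in% c("verified", "classifier_only"))
})

test_that("filtering is deterministic and monotone in the thresholds", {
  sim <- simulate_community("ten_taxa",
                            sim_config(n_reads = 120, seed = 12,
                                       low_as_fraction = 0.2,
                                       low_cov_fraction = 0.2,
                                       low_score_fraction = 0.2))
  p <- filter_params()
  run <- function(p) filter_reads(sim$hits, sim$alns, sim$ref$catalog,
                                  sim$ref$tax, p)
  expect_identical(run(p), run(p))   # byte-identical on identical inputs

  n_verified <- function(...) sum(run(filter_params(...))$status == "verified")
  base <- n_verified()
  expect_lte(n_verified(min_score = 500L), base)
  expect_lte(n_verified(max_matches = 10L), base)
  expect_lte(n_verified(min_alignment_score = 2000L), base)
  expect_lte(n_verified(min_coverage_pct = 80), base)
})

test_that("assignment overlap counts read-taxon pairs at rank", {
  tax <- toy_tax()
  a <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                      tax_id = c(11L, 12L, 21L),
                      status = "classifier_only")
  # identical maps -> 100% overlap
  ov <- assignment_overlap(a, a, tax)
  expect_equal(ov$both, 3)
  expect_equal(ov$frac_both, 1)

  # strain vs species agree at species rank
  b <- a
  b$tax_id[1] <- 13L
  ov2 <- assignment_overlap(a, b, tax)
  expect_equal(ov2$both, 3)

  # disjoint taxa per read -> 0% overlap
  c_ <- a
  c_$tax_id <- c(12L, 11L, 11L)
  ov3 <- assignment_overlap(a, c_, tax)
  expect_equal(ov3$both, 0)
  expect_equal(ov3$frac_both, 0)
  expect_equal(ov3$frac_classifier_only + ov3$frac_verified_only, 1)

  expect_error(assignment_overlap(a, b[-1, ], tax), "same read ids")
})

test_that("injected disagreements shift the overlap by about their rate", {
  cfg <- sim_config(n_reads = 600, seed = 21, disagreement_fraction = 0.3)
  sim <- simulate_community("ten_taxa", cfg)
  p <- filter_params()
  pre <- classifier_filter(sim$hits, p)
  post <- verify_assignments(pre, sim$alns, sim$ref$catalog, sim$ref$tax, p)
  ov <- assignment_overlap(pre, post, sim$ref$tax)
  # verified pairs are a subset of classifier pairs, so the overlap fraction
  # among classifier pairs ~ 1 - 0.3, within binomial error (3 sigma)
  frac_kept <- ov$both / (ov$both + ov$classifier_only_set)
  se <- sqrt(0.3 * 0.7 / 600)
  expect_lt(abs(frac_kept - 0.7), 3 * se)
  expect_equal(ov$verified_only_set, 0)
})

test_that("score sweep reports difference quotients per series", {
  tax <- toy_tax()
  cat_tbl <- catalog_for(tax)
  # 10 reads with scores 100..1000; alignments all verify
  hits <- dplyr::bind_rows(lapply(1:10, function(i) {
    hit_row(paste0("r", i), 11L, 100L * i)
  }))
  alns <- dplyr::bind_rows(lapply(1:10, function(i) {
    aln_row(paste0("r", i), 11L, 1600L)
  }))
  sw <- score_threshold_sweep(hits, alns, cat_tbl, toy_tax(),
                              thresholds = c(150L, 250L, 350L))
  # retained counts: scores >= 150 -> 9, >= 250 -> 8, >= 350 -> 7
  expect_equal(sw$retained_classifier, c(9L, 8L, 7L))
  expect_equal(sw$retained_verified, c(9L, 8L, 7L))
  expect_equal(sw$g_classifier, c(NA, -0.01, -0.01))
  # retained counts non-increasing in the threshold
  expect_true(all(diff(sw$retained_classifier) <= 0))
  expect_true(all(diff(sw$retained_verified) <= 0))
  # constant retention -> g = 0
  sw2 <- score_threshold_sweep(hits, alns, cat_tbl, toy_tax(),
                               thresholds = c(0L, 50L))
  expect_equal(sw2$g_classifier[2], 0)
  expect_error(score_threshold_sweep(hits, alns, cat_tbl, toy_tax(),
                                     thresholds = c(300L, 100L)),
               "ascending")
  expect_error(score_threshold_sweep(hits, alns, cat_tbl, toy_tax(),
                                     thresholds = 150L), "two thresholds")
})

test_that("verification flattens the retention slope at high score thresholds", {
  # verification already removes low-AS/low-Cov reads, which tend to be the
  # ones a higher classifier score would also drop; emulate that coupling by
  # degrading alignments of low-score reads
  set.seed(31)
  n <- 200
  scores <- sample(100:1500, n, replace = TRUE)
  hits <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    hit_row(paste0("r", i), 11L, scores[i])
  }))
  alns <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    # low-score reads get weak alignments
    as_val <- if (scores[i] < 600) 1000L else 1600L
    aln_row(paste0("r", i), 11L, as_val)
  }))
  sw <- score_threshold_sweep(hits, alns, catalog_for(toy_tax()), toy_tax(),
                              thresholds = c(300L, 600L, 900L))
  # between 300 and 600 the verified series loses nothing it still had
  expect_lte(abs(sw$g_verified[2]), abs(sw$g_classifier[2]))
})

test_that("hit-ratio diagnostics clamp ratios and stratify by match count", {
  hits <- dplyr::bind_rows(
    hit_row("r1", 11L, 400L, hit_length = 400L, query_length = 1000L),
    hit_row("r2", 12L, 500L, hit_length = 1200L, query_length = 1000L),
    hit_row("r3", 11L, 350L, hit_length = 800L, query_length = 1000L),
    hit_row("r4", 12L, 160L, num_matches = 60L, hit_length = 100L,
            query_length = 1000L)
  )
  d <- hit_ratio_diagnostics(hits, max_matches = 50L)
  r <- setNames(d$reads$hit_ratio, d$reads$read_id)
  expect_equal(r[["r1"]], 0.40)
  expect_equal(r[["r2"]], 1.0)    # clamped
  expect_equal(nrow(d$summary), 2)
  expect_error(hit_ratio_diagnostics(hits[0, ]), "empty")
})

test_that("multimatch reads sit below the first quartile of the hit ratio", {
  cfg <- sim_config(n_reads = 400, seed = 8, multimatch_fraction = 0.25)
  sim <- simulate_community("ten_taxa", cfg)
  d <- hit_ratio_diagnostics(sim$hits, max_matches = 50L)
  overall_q1 <- stats::quantile(d$reads$hit_ratio, 0.25)
  mm <- d$summary[d$summary$stratum == "above_max_matches", ]
  expect_lt(mm$ratio_median, overall_q1)
})
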