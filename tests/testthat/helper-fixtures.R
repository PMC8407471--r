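# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops over data frames, without reusing the
# package's vectorized code paths.

# A small hand-built taxonomy: two bacterial species (one with a strain),
# one archaeon, and a genus-level node with no species in its lineage (a
# rank gap).
toy_tax <- function() {
  taxonomy(tibble::tribble(
    ~tax_id, ~parent_id, ~rank,          ~name,
    1L,      1L,         "no rank",      "root",
    2L,      1L,         "superkingdom", "Bacteria",
    3L,      1L,         "superkingdom", "Archaea",
    10L,     2L,         "genus",        "Examplea",
    11L,     10L,        "species",      "Examplea prima",
    12L,     10L,        "species",      "Examplea secunda",
    13L,     11L,        "strain",       "Examplea prima str. X1",
    20L,     3L,         "genus",        "Archaeon genus",
    21L,     20L,        "species",      "Archaeon unum",
    30L,     2L,         "genus",        "Gapia"   # no species below
  ))
}

# one hit-table row with overridable fields
hit_row <- function(read_id, tax_id, score, num_matches = 1L,
                    hit_length = 500L, query_length = 1000L,
                    seq_id = paste0("ref_", tax_id),
                    second_best_score = 0L) {
  tibble::tibble(
    read_id = read_id, seq_id = seq_id, tax_id = as.integer(tax_id),
    score = as.integer(score), second_best_score = as.integer(second_best_score),
    hit_length = as.integer(hit_length), query_length = as.integer(query_length),
    num_matches = as.integer(num_matches)
  )
}

# one PAF-shaped alignment row
aln_row <- function(read_id, target_tax, alignment_score,
                    query_length = 1000L, query_start = 0L,
                    query_end = 800L, mapq = 60L) {
  tibble::tibble(
    read_id = read_id, query_length = as.integer(query_length),
    query_start = as.integer(query_start), query_end = as.integer(query_end),
    strand = "+", target_id = paste0("ref_", target_tax),
    target_length = 20000L, target_start = 0L,
    target_end = as.integer(query_end - query_start),
    n_match = as.integer(0.9 * (query_end - query_start)),
    block_len = as.integer(query_end - query_start), mapq = as.integer(mapq),
    alignment_score = as.integer(alignment_score)
  )
}

catalog_for <- function(tax, ids = NULL) {
  ids <- ids %||% tax$nodes$tax_id
  tibble::tibble(seq_id = paste0("ref_", ids), tax_id = as.integer(ids))
}

# --- independent rank resolution (loop over the node table) -----------------

oracle_resolve <- function(tax, id, rank) {
  nodes <- as.data.frame(tax$nodes)
  repeat {
    row <- nodes[nodes$tax_id == id, ]
    if (row$rank == rank) return(id)
    if (row$parent_id == id) return(NA_integer_)
    id <- row$parent_id
  }
}

# --- brute-force verification oracle -----------------------------------------
# Quadratic reference: for every classifier_only read, loop over every
# alignment row, resolve taxa by walking the node table, and re-derive the
# verdict from first principles.
oracle_verify <- function(assignments, alns, catalog, tax, params) {
  out <- as.data.frame(assignments)
  cat_df <- as.data.frame(catalog)
  aln_df <- as.data.frame(alns)
  for (i in seq_len(nrow(out))) {
    if (out$status[i] != "classifier_only") next
    rid <- out$read_id[i]
    cls <- oracle_resolve(tax, out$tax_id[i], params$agreement_rank)
    rows <- aln_df[aln_df$read_id == rid & !is.na(aln_df$alignment_score), ,
                   drop = FALSE]
    if (nrow(rows) == 0) {
      out$status[i] <- "rejected_no_alignment"; out$tax_id[i] <- NA; next
    }
    best <- NULL
    for (j in seq_len(nrow(rows))) {
      tgt_tax <- cat_df$tax_id[cat_df$seq_id == rows$target_id[j]]
      tgt <- oracle_resolve(tax, tgt_tax, params$agreement_rank)
      if (is.na(cls) || is.na(tgt) || cls != tgt) next
      cand <- list(
        as = rows$alignment_score[j],
        span = rows$query_end[j] - rows$query_start[j],
        cov = 100 * (rows$query_end[j] - rows$query_start[j]) /
          rows$query_length[j]
      )
      if (is.null(best) || cand$as > best$as ||
          (cand$as == best$as && cand$span > best$span)) {
        best <- cand
      }
    }
    if (is.null(best)) {
      out$status[i] <- "rejected_disagreement"; out$tax_id[i] <- NA
    } else if (best$as < params$min_alignment_score) {
      out$status[i] <- "rejected_low_AS"; out$tax_id[i] <- NA
    } else if (best$cov < params$min_coverage_pct) {
      out$status[i] <- "rejected_low_coverage"; out$tax_id[i] <- NA
    } else {
      out$status[i] <- "verified"
      out$coverage_pct[i] <- best$cov
      out$alignment_score[i] <- best$as
    }
  }
  tibble::as_tibble(out)
}

# --- brute-force AUPR oracle --------------------------------------------------
# Walks the distinct abundance thresholds with explicit loops and sums
# trapezoids one by one.
oracle_aupr <- function(fracs, tax_ids, truth_ids) {
  keep <- fracs > 0
  fracs <- fracs[keep]; tax_ids <- tax_ids[keep]
  if (length(fracs) == 0) return(0)
  ths <- sort(unique(fracs), decreasing = TRUE)
  prec <- numeric(0); rec <- numeric(0)
  for (th in ths) {
    pred <- tax_ids[fracs >= th]
    tp <- 0
    for (p in pred) if (p %in% truth_ids) tp <- tp + 1
    prec <- c(prec, tp / length(pred))
    rec <- c(rec, tp / length(truth_ids))
  }
  area <- 0
  prev_r <- 0; prev_p <- prec[1]
  for (k in seq_along(ths)) {
    area <- area + (rec[k] - prev_r) * (prec[k] + prev_p) / 2
    prev_r <- rec[k]; prev_p <- prec[k]
  }
  area
}

`%||%` <- rlang::`%||%`
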