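# Readers/writers for the tabular and sequence formats the pipeline consumes:
# the 8-column classifier hit table, PAF alignments, FASTA/FASTQ, and the
# 2-column reference catalog. All readers return tibbles; row order is
# preserved everywhere because the hit table encodes classifier ranking.

.tv_hit_cols <- c("readID", "seqID", "taxID", "score", "2ndBestScore",
                  "hitLength", "queryLength", "numMatches")

#' Read a classifier hit table
#'
#' Reads the tab-separated per-read classifier output dialect: a header line
#' naming the eight fields `readID seqID taxID score 2ndBestScore hitLength
#' queryLength numMatches`, then one candidate assignment per row. A read may
#' occupy several consecutive rows (one per candidate taxon); rows are kept in
#' file order, which encodes the classifier's own ranking. Rows with
#' `taxID == 0` are the classifier's "unclassified" verdict and are retained.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `read_id`, `seq_id`, `tax_id`, `score`,
#'   `second_best_score`, `hit_length`, `query_length`, `num_matches`.
#' @export
read_hit_table <- function(path) {
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) != 8L) {
    abort(paste0("read_hit_table(): expected 8 header columns, found ",
                 length(header), " in ", path))
  }
  tab <- suppressWarnings(readr::read_tsv(
    path,
    col_types = readr::cols(
      readr::col_character(), readr::col_character(), readr::col_integer(),
      readr::col_integer(), readr::col_integer(), readr::col_integer(),
      readr::col_integer(), readr::col_integer()
    ),
    progress = FALSE
  ))   # malformed cells surface as parse errors below, not readr warnings
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0("read_hit_table(): parse error at line ", probs$row[1] + 1L,
                 " of ", path, " (", probs$expected[1], ")"))
  }
  names(tab) <- c("read_id", "seq_id", "tax_id", "score", "second_best_score",
                  "hit_length", "query_length", "num_matches")
  if (any(tab$num_matches < 1L)) {
    abort("read_hit_table(): num_matches must be >= 1")
  }
  if (any(tab$query_length < 1L)) {
    abort("read_hit_table(): query_length must be >= 1")
  }
  tab
}

#' Write a classifier hit table
#'
#' @param hits Tibble in the shape returned by [read_hit_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[c("read_id", "seq_id", "tax_id", "score", "second_best_score",
                "hit_length", "query_length", "num_matches")]
  names(out) <- .tv_hit_cols
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read PAF alignments
#'
#' Parses standard 12+-column PAF. The query interval is 0-based half-open.
#' The `AS:i` alignment-score tag is looked up among the optional fields;
#' records without it are retained with `alignment_score = NA` (verification
#' ignores them).
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `read_id`, `query_length`, `query_start`,
#'   `query_end`, `strand`, `target_id`, `target_length`, `target_start`,
#'   `target_end`, `n_match`, `block_len`, `mapq`, `alignment_score`.
#' @export
read_paf <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      read_id = character(), query_length = integer(), query_start = integer(),
      query_end = integer(), strand = character(), target_id = character(),
      target_length = integer(), target_start = integer(),
      target_end = integer(), n_match = integer(), block_len = integer(),
      mapq = integer(), alignment_score = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(paste0("read_paf(): fewer than 12 columns at line ",
                 which(nf < 12L)[1], " of ", path))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  int <- function(i) {
    v <- suppressWarnings(as.integer(col(i)))
    if (anyNA(v)) {
      abort(paste0("read_paf(): non-integer value in column ", i, " at line ",
                   which(is.na(v))[1], " of ", path))
    }
    v
  }
  as_score <- vapply(fields, function(f) {
    tags <- f[-seq_len(12L)]
    hit <- tags[startsWith(tags, "AS:i:")]
    if (length(hit) == 0) NA_integer_ else as.integer(substring(hit[[1]], 6L))
  }, integer(1))
  out <- tibble(
    read_id = col(1), query_length = int(2), query_start = int(3),
    query_end = int(4), strand = col(5), target_id = col(6),
    target_length = int(7), target_start = int(8), target_end = int(9),
    n_match = int(10), block_len = int(11), mapq = int(12),
    alignment_score = as_score
  )
  bad <- which(!(out$query_start >= 0L & out$query_start < out$query_end &
                   out$query_end <= out$query_length))
  if (length(bad) > 0) {
    abort(paste0("read_paf(): invalid query interval at line ", bad[1],
                 " of ", path,
                 " (need 0 <= start < end <= query_length)"))
  }
  out
}

#' Write PAF alignments
#'
#' @param alns Tibble in the shape returned by [read_paf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_paf <- function(alns, path) {
  base <- paste(alns$read_id, alns$query_length, alns$query_start,
                alns$query_end, alns$strand, alns$target_id,
                alns$target_length, alns$target_start, alns$target_end,
                alns$n_match, alns$block_len, alns$mapq, sep = "\t")
  tag <- ifelse(is.na(alns$alignment_score), "",
                paste0("\tAS:i:", alns$alignment_score))
  readr::write_lines(paste0(base, tag), path)
  invisible(path)
}

#' Read and write a reference catalog
#'
#' The catalog links alignment targets to taxa: a 2-column TSV with header
#' `seqID taxID`, one reference sequence per row.
#'
#' @param path Path to the TSV file.
#' @return `read_catalog()`: a tibble (`seq_id`, `tax_id`).
#' @export
read_catalog <- function(path) {
  tab <- readr::read_tsv(path,
    col_types = readr::cols(readr::col_character(), readr::col_integer()),
    progress = FALSE)
  names(tab) <- c("seq_id", "tax_id")
  if (anyDuplicated(tab$seq_id)) {
    abort("read_catalog(): duplicated seq_id")
  }
  tab
}

#' @rdname read_catalog
#' @param catalog Tibble (`seq_id`, `tax_id`).
#' @export
write_catalog <- function(catalog, path) {
  out <- catalog[c("seq_id", "tax_id")]
  names(out) <- c("seqID", "taxID")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---- sequences ---------------------------------------------------------------

#' Read and write FASTA/FASTQ
#'
#' Thin tibble-returning wrappers around Biostrings. FASTQ quality strings are
#' carried verbatim.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble (`seq_id`, `seq`); `read_fastq()`: tibble
#'   (`read_id`, `seq`, `qual`).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(seq_id = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs For `write_fasta()` a tibble (`seq_id`, `seq`); for
#'   `write_fastq()` a tibble (`read_id`, `seq`, `qual`).
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs$seq)
  names(x) <- seqs$seq_id
  Biostrings::writeXStringSet(x, path, format = "fasta", width = 80L)
  invisible(path)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- unname(as.character(S4Vectors::mcols(x)$qualities))
  seqs <- unname(as.character(x))
  short <- which(nchar(qual) != nchar(seqs))
  if (length(short) > 0) {
    abort(paste0("read_fastq(): truncated record '",
                 names(x)[short[1]], "' in ", path,
                 " (quality string shorter than sequence)"))
  }
  tibble(read_id = sub("\\s.*$", "", names(x)), seq = seqs, qual = qual)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(seqs, path) {
  lines <- rbind(paste0("@", seqs$read_id), seqs$seq, "+", seqs$qual)
  readr::write_lines(as.vector(lines), path)
  invisible(path)
}
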