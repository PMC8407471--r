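# Synthetic-data generator: toy taxonomies and genomes, noisy long reads,
# classifier hit tables and PAF alignments, all with exact ground truth. Four
# presets reproduce standard simulated community designs (a uniform 10-taxon
# panel, a 17-member gut mock with abundances spanning five orders of
# magnitude, a host-dominated tumor community, and a 77-bacteria panel).
# Everything is driven by a single seed so whole runs are reproducible.

#' Simulation configuration
#'
#' Collects the knobs of the read/hit/alignment generator. The default error
#' rates total ~10% per base (substitution 4%, insertion 3%, deletion 3%),
#' the characteristic error profile of long-read nanopore sequencing. The
#' contamination fractions control how many reads receive a deliberately
#' corrupted hit or alignment; they all default to 0 (a clean run).
#'
#' @param n_reads Number of reads to simulate.
#' @param read_length_mean,read_length_sd Read length distribution (bases);
#'   lengths are drawn normal and truncated to `[200, genome length]`.
#' @param error_sub,error_ins,error_del Per-base substitution / insertion /
#'   deletion rates.
#' @param fp_read_fraction Fraction of reads whose hit-table taxon is wrong
#'   (drawn from decoy taxa when available, otherwise another member).
#' @param multimatch_fraction Fraction of reads reported with more candidate
#'   taxa than the multi-match cutoff allows, with depressed
#'   hit-length/query-length ratios and low scores.
#' @param low_score_fraction Fraction of reads whose best hit scores below
#'   the classifier score threshold.
#' @param missing_alignment_fraction Fraction of reads absent from the
#'   alignment file.
#' @param low_as_fraction,low_cov_fraction Fractions of reads whose alignment
#'   fails the alignment-score / coverage threshold.
#' @param disagreement_fraction Fraction of reads aligned to a different
#'   species than their hit-table taxon.
#' @param min_reads_per_taxon Guaranteed minimum read count per community
#'   member (zero-count members are topped up from the most abundant member
#'   after the multinomial draw), so every ground-truth taxon is observable.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_reads = 10000L, read_length_mean = 2000,
                       read_length_sd = 500, error_sub = 0.04,
                       error_ins = 0.03, error_del = 0.03,
                       fp_read_fraction = 0, multimatch_fraction = 0,
                       low_score_fraction = 0,
                       missing_alignment_fraction = 0, low_as_fraction = 0,
                       low_cov_fraction = 0, disagreement_fraction = 0,
                       min_reads_per_taxon = 1L, seed = NULL) {
  fracs <- c(fp_read_fraction, multimatch_fraction, low_score_fraction,
             missing_alignment_fraction, low_as_fraction, low_cov_fraction,
             disagreement_fraction)
  stopifnot(all(fracs >= 0), all(fracs <= 1), n_reads >= 1,
            error_sub >= 0, error_ins >= 0, error_del >= 0)
  if (fp_read_fraction + multimatch_fraction + low_score_fraction > 1) {
    abort("sim_config(): hit-table contamination fractions exceed 1")
  }
  if (missing_alignment_fraction + low_as_fraction + low_cov_fraction +
        disagreement_fraction > 1) {
    abort("sim_config(): alignment contamination fractions exceed 1")
  }
  structure(
    list(n_reads = as.integer(n_reads),
         read_length_mean = read_length_mean,
         read_length_sd = read_length_sd,
         error_sub = error_sub, error_ins = error_ins, error_del = error_del,
         fp_read_fraction = fp_read_fraction,
         multimatch_fraction = multimatch_fraction,
         low_score_fraction = low_score_fraction,
         missing_alignment_fraction = missing_alignment_fraction,
         low_as_fraction = low_as_fraction,
         low_cov_fraction = low_cov_fraction,
         disagreement_fraction = disagreement_fraction,
         min_reads_per_taxon = as.integer(min_reads_per_taxon),
         seed = seed),
    class = "sim_config"
  )
}

# Gut-mock abundance ladder (percent): 17 members spanning 14% down to
# 1e-4%, tiered like commercial gut-standard mixtures; sums to exactly 100.
.tv_gut_pct <- c(14, 14, 14, 14, 13.9889, 6, 6, 6, 6, 1.5, 1.5,
                 0.01, 0.001, 0.0001,   # 14 bacteria
                 0.1,                   # 1 archaeon
                 1.5, 1.4)              # 2 fungi

#' Community composition presets
#'
#' Four fixed community designs with synthetic member names:
#' \describe{
#'   \item{`ten_taxa`}{8 bacteria + 2 fungi, 10% abundance each.}
#'   \item{`gut`}{14 bacteria + 1 archaeon + 2 fungi with highly divergent
#'     abundances, 14% down to 1e-4% (fraction 1e-6).}
#'   \item{`tumor`}{A host genome at 99.9% plus 8 bacteria sharing the
#'     remaining 0.1% equally.}
#'   \item{`metamaps`}{77 bacteria, uniform by default.}
#' }
#'
#' @param name Preset name.
#' @param abundances Optional replacement abundance vector (fractions, summing
#'   to 1, one per member) for the `metamaps` preset.
#' @return A `community_spec` tibble (`tax_id`, `name`, `domain`,
#'   `abundance`), abundances summing to 1, with a `preset` attribute.
#' @export
community_preset <- function(name = c("ten_taxa", "gut", "tumor", "metamaps"),
                             abundances = NULL) {
  name <- match.arg(name)
  make <- function(domains, abundance, labels = NULL) {
    n <- length(domains)
    tibble(
      tax_id = 1000L + seq_len(n),
      name = labels %||% paste0(
        c(bacteria = "Bacterium", archaea = "Archaeon", fungi = "Fungus",
          host = "Host")[domains],
        " sp. ", seq_len(n)),
      domain = domains,
      abundance = abundance
    )
  }
  spec <- switch(name,
    ten_taxa = make(c(rep("bacteria", 8), rep("fungi", 2)), rep(0.10, 10)),
    gut = make(c(rep("bacteria", 14), "archaea", rep("fungi", 2)),
               .tv_gut_pct / 100),
    tumor = make(c("host", rep("bacteria", 8)),
                 c(0.999, rep(0.001 / 8, 8))),
    metamaps = make(rep("bacteria", 77),
                    abundances %||% rep(1 / 77, 77))
  )
  if (abs(sum(spec$abundance) - 1) > 1e-9) {
    abort("community_preset(): abundances must sum to 1")
  }
  structure(spec, preset = name,
            class = c("community_spec", class(tibble())))
}

.tv_random_seq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# superkingdom node ids used by the toy taxonomy
.tv_domains <- c(bacteria = 2L, archaea = 3L, fungi = 4L, host = 5L)

#' Build toy references and a matching taxonomy for a community
#'
#' Generates one pseudo-random genome per community member (plus optional
#' decoy species that carry zero true abundance but can receive wrong
#' classifier hits), a catalog mapping each reference name to its taxon, and
#' a small taxonomy with full root-superkingdom-genus-species lineages.
#'
#' @param spec A [community_preset()] (or any tibble with `tax_id`, `name`,
#'   `domain`, `abundance`).
#' @param genome_length Genome length per member (bases).
#' @param gc GC content of the generated genomes.
#' @param n_decoys Number of extra decoy species (bacteria) to add to the
#'   reference set and taxonomy.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list of class `toy_reference`: `refs` (tibble `seq_id`, `seq`),
#'   `catalog` (`seq_id`, `tax_id`), `tax` (a [taxonomy()]), `decoys`
#'   (integer tax ids), `genome_length`.
#' @export
make_toy_reference <- function(spec, genome_length = 20000L, gc = 0.5,
                               n_decoys = 0L, seed = NULL) {
  build <- function() {
    decoys <- if (n_decoys > 0) {
      tibble(
        tax_id = 9000L + seq_len(n_decoys),
        name = paste0("Decoy bacterium sp. ", seq_len(n_decoys)),
        domain = "bacteria",
        abundance = 0
      )
    } else {
      tibble(tax_id = integer(), name = character(), domain = character(),
             abundance = double())
    }
    members <- dplyr::bind_rows(as_tibble(spec)[names(decoys)], decoys)

    genus_id <- 100L + seq_len(nrow(members))
    nodes <- dplyr::bind_rows(
      tibble(tax_id = 1L, parent_id = 1L, rank = "no rank", name = "root"),
      tibble(tax_id = unname(.tv_domains),
             parent_id = 1L, rank = "superkingdom",
             name = c("Bacteria", "Archaea", "Eukaryota fungi",
                      "Eukaryota host")),
      tibble(tax_id = genus_id,
             parent_id = unname(.tv_domains[members$domain]),
             rank = "genus",
             name = paste0("Genus of ", members$name)),
      tibble(tax_id = members$tax_id, parent_id = genus_id,
             rank = "species", name = members$name)
    )
    tax <- taxonomy(nodes)

    refs <- tibble(
      seq_id = paste0("ref_", members$tax_id),
      seq = vapply(seq_len(nrow(members)),
                   function(i) .tv_random_seq(genome_length, gc), "")
    )
    catalog <- tibble(seq_id = refs$seq_id, tax_id = members$tax_id)
    structure(
      list(refs = refs, catalog = catalog, tax = tax,
           decoys = decoys$tax_id, genome_length = as.integer(genome_length)),
      class = "toy_reference"
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# apply substitution/insertion/deletion errors to one sequence string
.tv_bases <- c("A", "C", "G", "T")

.tv_mutate_seq <- function(seq, p_sub, p_ins, p_del) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  ndel <- stats::rbinom(1L, n, p_del)
  if (ndel > 0) chars <- chars[-sample.int(length(chars), ndel)]
  n <- length(chars)
  if (n == 0L) return("")
  nsub <- stats::rbinom(1L, n, p_sub)
  if (nsub > 0) {
    pos <- sample.int(n, nsub)
    # substitute with one of the three other bases (cyclic offset)
    idx <- match(chars[pos], .tv_bases)
    off <- sample.int(3L, nsub, replace = TRUE)
    chars[pos] <- .tv_bases[((idx - 1L + off) %% 4L) + 1L]
  }
  nins <- stats::rbinom(1L, n, p_ins)
  if (nins > 0) {
    gap <- sample.int(n + 1L, nins, replace = TRUE) - 0.5
    ins <- sample(.tv_bases, nins, replace = TRUE)
    chars <- c(chars, ins)[order(c(seq_len(n), gap))]
  }
  paste(chars, collapse = "")
}

# sample one wrong taxon per row, vectorized, never equal to the true taxon
.tv_sample_wrong <- function(true_tax, pool) {
  out <- pool[sample.int(length(pool), length(true_tax), replace = TRUE)]
  clash <- which(out == true_tax)
  for (i in clash) {
    alt <- pool[pool != true_tax[i]]
    out[i] <- alt[sample.int(length(alt), 1L)]
  }
  out
}

#' Simulate noisy long reads from a community
#'
#' Reads are allocated to members by a multinomial draw over the spec
#' abundances (topped up so every member gets at least
#' `min_reads_per_taxon`), each read is an error-free substring of its source
#' genome, and substitution/insertion/deletion errors are applied at the
#' configured per-base rates. The ground-truth table records each read's
#' source taxon and final (post-error) length.
#'
#' @param spec A [community_preset()].
#' @param ref A [make_toy_reference()] for the same spec.
#' @param config A [sim_config()]; its `seed` (if set) makes the draw
#'   reproducible.
#' @return A list: `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (tibble `read_id`, `tax_id`, `query_length`, `clean_seq` — the
#'   error-free origin of the read).
#' @export
simulate_reads <- function(spec, ref, config = sim_config()) {
  stopifnot(inherits(ref, "toy_reference"))
  build <- function() {
    n_members <- nrow(spec)
    counts <- as.integer(stats::rmultinom(1L, config$n_reads,
                                          spec$abundance))
    # top up members below the guaranteed minimum from the largest member
    need <- pmax(config$min_reads_per_taxon - counts, 0L)
    while (sum(need) > 0L) {
      donor <- which.max(counts - config$min_reads_per_taxon)
      take <- which(need > 0L)[1L]
      counts[donor] <- counts[donor] - need[take]
      counts[take] <- counts[take] + need[take]
      need <- pmax(config$min_reads_per_taxon - counts, 0L)
    }
    src <- rep.int(seq_len(n_members), counts)
    src <- src[sample.int(length(src))]   # shuffle read order
    glen <- ref$genome_length
    genome <- stats::setNames(ref$refs$seq,
                              sub("^ref_", "", ref$refs$seq_id))
    rl <- pmin(pmax(round(stats::rnorm(length(src), config$read_length_mean,
                                       config$read_length_sd)), 200L), glen)
    start <- vapply(rl, function(l) sample.int(glen - l + 1L, 1L), integer(1))
    clean <- unname(substring(genome[as.character(spec$tax_id[src])], start,
                              start + rl - 1L))
    seqs <- vapply(clean, .tv_mutate_seq, "", p_sub = config$error_sub,
                   p_ins = config$error_ins, p_del = config$error_del,
                   USE.NAMES = FALSE)
    read_id <- sprintf("read_%06d", seq_along(src))
    qual <- vapply(nchar(seqs), function(n) {
      strrep(intToUtf8(33L + sample(10:15, 1L)), n)
    }, "")
    list(
      reads = tibble(read_id = read_id, seq = seqs, qual = qual),
      # clean_seq is the error-free origin of each read, kept so realized
      # error rates can be measured against it
      truth = tibble(read_id = read_id, tax_id = spec$tax_id[src],
                     query_length = nchar(seqs), clean_seq = clean)
    )
  }
  if (is.null(config$seed)) build() else withr::with_seed(config$seed, build())
}

#' Emulate a classifier's hit table
#'
#' Stands in for the classification stage of the pipeline: each read in the
#' truth table receives candidate taxon rows with controlled contamination.
#' Clean reads get their true taxon with a score in `[min_score,
#' 10 * min_score]` and a hit-length ratio in `[0.4, 1]`; the configured
#' fractions instead get a wrong taxon (a decoy species where available),
#' a sub-threshold score in `[0, min_score)`, or more candidate taxa than
#' `max_matches` with depressed hit ratios and low scores.
#'
#' @param truth Truth tibble from [simulate_reads()] (`read_id`, `tax_id`,
#'   `query_length`).
#' @param ref A [make_toy_reference()].
#' @param config A [sim_config()].
#' @param params A [filter_params()] supplying `min_score` / `max_matches`
#'   conventions.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `hits` (hit-table tibble) and `categories` (tibble
#'   `read_id`, `hit_category` in clean/fp/multimatch/low_score).
#' @export
emulate_classifier <- function(truth, ref, config = sim_config(),
                               params = filter_params(), seed = NULL) {
  stopifnot(inherits(ref, "toy_reference"))
  build <- function() {
    n <- nrow(truth)
    cat_levels <- c("fp", "multimatch", "low_score", "clean")
    probs <- c(config$fp_read_fraction, config$multimatch_fraction,
               config$low_score_fraction, 0)
    probs[4] <- 1 - sum(probs)
    category <- sample(cat_levels, n, replace = TRUE, prob = probs)

    min_s <- params$min_score
    hi_s <- 10L * max(min_s, 1L)
    wrong_pool <- if (length(ref$decoys) > 0) ref$decoys else
      ref$catalog$tax_id

    # single-row reads (clean / fp / low_score), fully vectorized
    single <- category != "multimatch"
    tid <- truth$tax_id[single]
    qlen <- truth$query_length[single]
    cat1 <- category[single]
    tid_out <- tid
    if (any(cat1 == "fp")) {
      tid_out[cat1 == "fp"] <- .tv_sample_wrong(tid[cat1 == "fp"], wrong_pool)
    }
    score <- integer(sum(single))
    is_low <- cat1 == "low_score"
    score[!is_low] <- sample(min_s:hi_s, sum(!is_low), replace = TRUE)
    if (any(is_low)) {
      score[is_low] <- sample(0:max(min_s - 1L, 0L), sum(is_low),
                              replace = TRUE)
    }
    single_rows <- tibble(
      read_id = truth$read_id[single], seq_id = paste0("ref_", tid_out),
      tax_id = tid_out, score = score,
      second_best_score = as.integer(floor(score * stats::runif(sum(single), 0, 0.9))),
      hit_length = pmax(1L, as.integer(round(stats::runif(sum(single), 0.4, 1) * qlen))),
      query_length = qlen,
      num_matches = sample(1:5, sum(single), replace = TRUE)
    )

    # multimatch reads: a handful of visible candidate rows each, with a
    # num_matches field above the cutoff and depressed ratios/scores
    mm <- which(!single)
    mm_rows <- purrr::map(mm, function(i) {
      tid_i <- truth$tax_id[i]
      qlen_i <- truth$query_length[i]
      nm <- as.integer(params$max_matches) + sample.int(250L, 1L)
      others <- setdiff(ref$catalog$tax_id, tid_i)
      k <- min(2L, length(others))
      taxa <- c(tid_i, others[sample.int(length(others), k)])
      ratio <- stats::runif(length(taxa), 0.05, 0.30)
      tibble(
        read_id = truth$read_id[i], seq_id = paste0("ref_", taxa),
        tax_id = taxa,
        score = sort(sample(min_s:(min_s + 250L), length(taxa),
                            replace = TRUE), decreasing = TRUE),
        second_best_score = 0L,
        hit_length = pmax(1L, as.integer(round(ratio * qlen_i))),
        query_length = qlen_i, num_matches = nm
      )
    })
    hits <- dplyr::bind_rows(c(list(single_rows), mm_rows))
    # restore per-read file order (reads interleaved as in the truth table)
    hits <- hits[order(match(hits$read_id, truth$read_id)), ]
    list(
      hits = hits,
      categories = tibble(read_id = truth$read_id, hit_category = category)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Emulate reference alignments as PAF
#'
#' Stands in for the alignment-control stage: each read receives one
#' alignment to its true source reference (so reads whose hit-table taxon is
#' wrong naturally disagree with their alignment), with alignment score and
#' query coverage sampled above the verification thresholds. The configured
#' fractions instead get a sub-threshold alignment score, sub-threshold
#' coverage, a deliberately different target species, or no alignment at all.
#'
#' @inheritParams emulate_classifier
#' @return A list: `alns` (PAF-shaped tibble, [read_paf()] columns) and
#'   `categories` (tibble `read_id`, `aln_category` in
#'   clean/low_as/low_cov/disagree/missing).
#' @export
emulate_alignments <- function(truth, ref, config = sim_config(),
                               params = filter_params(), seed = NULL) {
  stopifnot(inherits(ref, "toy_reference"))
  build <- function() {
    n <- nrow(truth)
    cat_levels <- c("missing", "low_as", "low_cov", "disagree", "clean")
    probs <- c(config$missing_alignment_fraction, config$low_as_fraction,
               config$low_cov_fraction, config$disagreement_fraction, 0)
    probs[5] <- 1 - sum(probs)
    category <- sample(cat_levels, n, replace = TRUE, prob = probs)

    min_as <- params$min_alignment_score
    min_cov <- params$min_coverage_pct
    glen <- ref$genome_length

    keep <- category != "missing"
    m <- sum(keep)
    tid <- truth$tax_id[keep]
    qlen <- truth$query_length[keep]
    catk <- category[keep]

    target_tax <- tid
    if (any(catk == "disagree")) {
      target_tax[catk == "disagree"] <-
        .tv_sample_wrong(tid[catk == "disagree"], ref$catalog$tax_id)
    }
    as_score <- integer(m)
    lo <- catk == "low_as"
    as_score[!lo] <- sample(min_as:(2L * max(min_as, 1L)), sum(!lo),
                            replace = TRUE)
    if (any(lo)) {
      as_score[lo] <- sample(0:max(min_as - 1L, 0L), sum(lo), replace = TRUE)
    }
    cov <- numeric(m)
    lc <- catk == "low_cov"
    cov[!lc] <- stats::runif(sum(!lc), min_cov, 100)
    cov[lc] <- stats::runif(sum(lc), 5, max(min_cov - 5, 5))
    span <- integer(m)
    span[lc] <- pmax(1L, as.integer(floor(cov[lc] / 100 * qlen[lc])))
    span[!lc] <- pmin(qlen[!lc], as.integer(ceiling(cov[!lc] / 100 * qlen[!lc])))
    qstart <- as.integer(floor(stats::runif(m) * (qlen - span + 1L)))
    tspan <- pmin(span, glen)
    tstart <- as.integer(floor(stats::runif(m) * (glen - tspan + 1L)))

    alns <- tibble(
      read_id = truth$read_id[keep], query_length = qlen,
      query_start = qstart, query_end = qstart + span,
      strand = sample(c("+", "-"), m, replace = TRUE),
      target_id = paste0("ref_", target_tax), target_length = glen,
      target_start = tstart, target_end = tstart + tspan,
      n_match = as.integer(round(0.9 * span)), block_len = span,
      mapq = 60L, alignment_score = as_score
    )
    list(
      alns = alns,
      categories = tibble(read_id = truth$read_id, aln_category = category)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Ground truth of a community spec
#'
#' @param spec A [community_preset()].
#' @return A [ground_truth()] at species rank.
#' @export
spec_truth <- function(spec) {
  ground_truth(tibble(tax_id = spec$tax_id, name = spec$name,
                      fraction = spec$abundance))
}

#' Run the whole generator for one community
#'
#' Convenience wrapper producing everything the pipeline consumes: toy
#' references and taxonomy, noisy reads, a hit table and alignments, plus the
#' read-level and community-level ground truth. All randomness flows from
#' `config$seed`.
#'
#' @param spec A [community_preset()] (or preset name).
#' @param config A [sim_config()].
#' @param params A [filter_params()] (threshold conventions for the
#'   emulators).
#' @param genome_length,gc,n_decoys Passed to [make_toy_reference()].
#' @return A list of class `community_sim`: `spec`, `ref`, `reads`, `truth`,
#'   `hits`, `alns`, `categories` (per-read hit and alignment categories)
#'   and `truth_profile` (a [ground_truth()]).
#' @export
simulate_community <- function(spec, config = sim_config(),
                               params = filter_params(),
                               genome_length = 20000L, gc = 0.5,
                               n_decoys = 0L) {
  if (is.character(spec)) spec <- community_preset(spec)
  build <- function() {
    ref <- make_toy_reference(spec, genome_length = genome_length, gc = gc,
                              n_decoys = n_decoys)
    cfg <- config
    cfg$seed <- NULL   # already inside the seeded scope
    sim <- simulate_reads(spec, ref, cfg)
    cls <- emulate_classifier(sim$truth, ref, cfg, params)
    aln <- emulate_alignments(sim$truth, ref, cfg, params)
    structure(
      list(spec = spec, ref = ref, reads = sim$reads, truth = sim$truth,
           hits = cls$hits, alns = aln$alns,
           categories = left_join(cls$categories, aln$categories,
                                  by = "read_id"),
           truth_profile = spec_truth(spec)),
      class = "community_sim"
    )
  }
  if (is.null(config$seed)) build() else withr::with_seed(config$seed, build())
}

#' Write a simulation to disk
#'
#' Writes every artifact of a [simulate_community()] run in plain-text
#' formats: reference FASTA, reads FASTQ, hit-table TSV, alignment PAF,
#' catalog TSV, taxonomy dump files, and the read-level and community-level
#' truth TSVs.
#'
#' @param sim A `community_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "community_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    refs = file.path(dir, "references.fasta"),
    reads = file.path(dir, "reads.fastq"),
    hits = file.path(dir, "hits.tsv"),
    paf = file.path(dir, "alignments.paf"),
    catalog = file.path(dir, "catalog.tsv"),
    truth_reads = file.path(dir, "truth_reads.tsv"),
    truth_profile = file.path(dir, "truth_profile.tsv")
  )
  write_fasta(sim$ref$refs, paths[["refs"]])
  write_fastq(sim$reads, paths[["reads"]])
  write_hit_table(sim$hits, paths[["hits"]])
  write_paf(sim$alns, paths[["paf"]])
  write_catalog(sim$ref$catalog, paths[["catalog"]])
  readr::write_tsv(sim$truth, paths[["truth_reads"]], progress = FALSE)
  readr::write_tsv(as_tibble(sim$truth_profile), paths[["truth_profile"]],
                   progress = FALSE)
  tp <- write_taxdump(sim$ref$tax, dir)
  invisible(c(paths, nodes = unname(tp[["nodes"]]),
              names = unname(tp[["names"]])))
}
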