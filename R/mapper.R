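# k-mer read mapping with ConClave template sorting.
#
# Scoring model: a read's match score against a template is the number of
# its k-mers (restricted to those carrying the index prefix) found in the
# template at offsets consistent with a single ungapped placement — the
# mode of the diagonal (template offset minus read offset). Both
# orientations are scored and the better one kept. The ConClave pass then
# accumulates every read's score onto every candidate template, ranks
# templates by total score, and gives each read to its highest-ranked
# candidate.

#' Build a k-mer index over reference templates
#'
#' Indexes every overlapping k-mer of every template, optionally retaining
#' only k-mers that start with a fixed nucleotide prefix. A two-letter
#' prefix keeps on average one k-mer in 16 — roughly the density of
#' non-overlapping k-mers — trading sensitivity for index size and speed
#' the way large-database mappers do.
#'
#' Template headers must carry a taxid token (`taxid|<int>|` or
#' `taxid=<int>`; see [parse_taxid()]). k-mers containing `N` are never
#' indexed; templates shorter than `k` are skipped with a warning.
#'
#' @param templates a named character vector of DNA sequences, a
#'   `DNAStringSet`, or the path to a (optionally gzipped) FASTA file.
#' @param k k-mer length, between 4 and 31 (default 16).
#' @param prefix nucleotide prefix filter; `""` (default) indexes all
#'   overlapping k-mers.
#' @return an object of class `kmer_index` holding the compiled index and
#'   per-template metadata (`template_id`, `template_length`, `taxid`).
#'   The index lives in native memory and is valid for the current R
#'   session only; rebuild rather than serialize it.
#' @export
build_index <- function(templates, k = 16L, prefix = "") {
  if (is.character(templates) && length(templates) == 1L &&
      file.exists(templates) && is.null(names(templates))) {
    templates <- read_seqs(templates)
  }
  if (methods::is(templates, "DNAStringSet")) {
    templates <- stats::setNames(as.character(templates), names(templates))
  }
  stopifnot(is.character(templates), !is.null(names(templates)))
  k <- as.integer(k)
  if (k < 4L || k > 31L) stop("k must be between 4 and 31")
  if (nchar(prefix) >= k) stop("prefix must be shorter than k")
  templates <- toupper(templates)
  short <- nchar(templates) < k
  if (any(short)) {
    warning(sum(short), " template(s) shorter than k skipped: ",
            paste(utils::head(names(templates)[short], 5L), collapse = ", "))
    templates <- templates[!short]
  }
  if (!length(templates)) stop("no templates of length >= k")
  ptr <- cpp_build_index(unname(templates), k, toupper(prefix))
  structure(
    list(ptr = ptr, k = k, prefix = toupper(prefix),
         template_id = names(templates),
         template_length = unname(nchar(templates)),
         template_seq = unname(templates),
         taxid = parse_taxid(names(templates))),
    class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("kmer_index: k =", x$k,
      if (nzchar(x$prefix)) paste0("(prefix '", x$prefix, "')") else "",
      "\n ", length(x$template_id), "templates,",
      format(info$n_postings, big.mark = ","), "indexed k-mer positions\n")
  invisible(x)
}

# Number of indexed k-mer positions (used by tests).
index_size <- function(index) cpp_index_info(index$ptr)$n_postings

#' Score one read against all templates
#'
#' @param read a single DNA string of length >= `k`.
#' @param index a [build_index()] result.
#' @return a data.frame with one row per candidate template (score > 0):
#'   `template_id`, `score` (shared prefix-bearing k-mers on the best
#'   diagonal), `start` (0-based template position implied for the read's
#'   first base), `strand` (+1 forward / -1 reverse complement). Zero rows
#'   when the read has no hits.
#' @export
score_read <- function(read, index) {
  stopifnot(is.character(read), length(read) == 1L)
  hits <- score_read_batch(index, read)
  data.frame(template_id = index$template_id[hits$template],
             score = hits$score, start = hits$start, strand = hits$strand,
             stringsAsFactors = FALSE)
}

# Batch scoring; returns the raw hit table with integer template indices.
# Reads shorter than k get no hits (counted unmapped downstream).
score_read_batch <- function(index, reads) {
  cpp_score_reads(index$ptr, toupper(unname(reads)))
}

#' Restrict a hit table to each read's best-scoring templates
#'
#' A read's ConClave candidates are the templates it maps best to: all
#' templates achieving its maximum match score (ties kept — these are the
#' "possible mappings" that are indistinguishable at read level and that
#' the global template ranking must resolve). Lower-scoring placements
#' are genuine mismatches, not shared-read ambiguity, and do not
#' contribute.
#'
#' @param hits hit table (columns `read`, `template`, `score`).
#' @return the rows achieving each read's maximum score.
#' @export
best_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  best <- tapply(hits$score, hits$read, max)
  out <- hits[hits$score == best[as.character(hits$read)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ConClave template selection
#'
#' First ConClave pass: accumulate every read's match score onto each of
#' its candidate templates (pass the [best_hits()] table: a read counts
#' for every template it maps best to, so shared reads are counted for
#' all the templates they could belong to) and rank templates by total
#' score. Ties are broken deterministically by shorter template length,
#' then lexicographic template id.
#'
#' @param hits candidate hit table, normally [best_hits()] of the raw
#'   scores: columns `read`, `template` (integer index), `score`.
#' @param index the `kmer_index` the hits were computed against.
#' @return a data.frame ordered by rank: `template` (integer index),
#'   `template_id`, `total_score`, `rank`.
#' @export
conclave_select <- function(hits, index) {
  n <- length(index$template_id)
  total <- numeric(n)
  if (nrow(hits)) {
    agg <- rowsum(hits$score, hits$template)
    total[as.integer(rownames(agg))] <- agg[, 1L]
  }
  ord <- order(-total, index$template_length, index$template_id)
  data.frame(template = ord,
             template_id = index$template_id[ord],
             total_score = total[ord],
             rank = seq_len(n),
             stringsAsFactors = FALSE)
}

#' ConClave read reassignment
#'
#' Second ConClave pass: each read goes to the template, among its own
#' candidates, with the best global rank from [conclave_select()]. Reads
#' with no candidates stay unmapped.
#'
#' @param hits hit table (columns `read`, `template`, `score`).
#' @param ranking result of [conclave_select()].
#' @param n_reads total number of read units scored.
#' @return integer vector of length `n_reads`: winning template index per
#'   read, `NA` for unmapped reads.
#' @export
reassign_reads <- function(hits, ranking, n_reads) {
  assignment <- rep(NA_integer_, n_reads)
  if (!nrow(hits)) return(assignment)
  rank_of <- integer(max(ranking$template))
  rank_of[ranking$template] <- ranking$rank
  ord <- order(hits$read, rank_of[hits$template])
  first <- !duplicated(hits$read[ord])
  assignment[hits$read[ord][first]] <- hits$template[ord][first]
  assignment
}

#' Map reads to templates with ConClave assignment
#'
#' Runs the full mapping pass: batch k-mer scoring of every read (and
#' mate), ConClave template selection and read reassignment, then
#' per-template consensus statistics. Paired-end mates are scored
#' separately and their per-template scores summed, so a pair is assigned
#' as a unit; each mate is placed at its own best diagonal for the
#' consensus.
#'
#' @param index a [build_index()] result.
#' @param reads named character vector / `DNAStringSet` of reads, or path
#'   to a FASTA/FASTQ(.gz) file.
#' @param reads2 optional second mates, same length and order as `reads`.
#' @return a list of class `conclave_mapping`:
#'   `res` — data.frame of [template_stats()] results (the `.res` table);
#'   `assignments` — per read unit, the winning `template_id` or `NA`;
#'   `ranking` — the [conclave_select()] table;
#'   `n_reads`, `n_unmapped` — read-unit accounting (a pair is one unit).
#' @export
map_reads <- function(index, reads, reads2 = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      is.null(names(reads))) reads <- read_seqs(reads)
  if (methods::is(reads, "DNAStringSet"))
    reads <- stats::setNames(as.character(reads), names(reads))
  if (!is.null(reads2)) {
    if (is.character(reads2) && length(reads2) == 1L &&
        file.exists(reads2) && is.null(names(reads2)))
      reads2 <- read_seqs(reads2)
    if (methods::is(reads2, "DNAStringSet"))
      reads2 <- stats::setNames(as.character(reads2), names(reads2))
    stopifnot(length(reads2) == length(reads))
  }
  n_units <- length(reads)

  h1 <- score_read_batch(index, reads)
  h1$mate <- rep(1L, nrow(h1))
  if (!is.null(reads2)) {
    h2 <- score_read_batch(index, reads2)
    h2$mate <- rep(2L, nrow(h2))
    hits <- rbind(h1, h2)
  } else {
    hits <- h1
  }

  # Pair-level score per (read unit, template) for selection/assignment.
  if (nrow(hits)) {
    key <- paste(hits$read, hits$template)
    unit_score <- rowsum(hits$score, key)
    uk <- strsplit(rownames(unit_score), " ", fixed = TRUE)
    unit_hits <- data.frame(
      read = as.integer(vapply(uk, `[`, "", 1L)),
      template = as.integer(vapply(uk, `[`, "", 2L)),
      score = unit_score[, 1L])
  } else {
    unit_hits <- data.frame(read = integer(), template = integer(),
                            score = integer())
  }

  candidates <- best_hits(unit_hits)
  ranking <- conclave_select(candidates, index)
  assignment <- reassign_reads(candidates, ranking, n_units)

  res <- template_stats(hits, assignment, index,
                        reads = unname(toupper(reads)),
                        reads2 = if (is.null(reads2)) NULL
                                 else unname(toupper(reads2)))
  structure(
    list(res = res,
         assignments = ifelse(is.na(assignment), NA_character_,
                              index$template_id[assignment]),
         ranking = ranking,
         n_reads = n_units,
         n_unmapped = sum(is.na(assignment))),
    class = "conclave_mapping")
}

#' @export
print.conclave_mapping <- function(x, ...) {
  cat("conclave_mapping:", x$n_reads, "read units,",
      x$n_reads - x$n_unmapped, "assigned,",
      nrow(x$res), "templates with reads\n")
  invisible(x)
}

#' Per-template consensus statistics
#'
#' For every template that won at least one read, places each winning
#' read (mate) at its best diagonal, builds the per-position majority-vote
#' consensus, and derives the `.res`-dialect quantities:
#' * `depth` — aligned bases (clipped to the template) / template length;
#' * `template_coverage` — % of template positions covered >= 1x (capped
#'   at 100; `query_coverage` equals it under ungapped placement);
#' * `query_identity` — % of covered positions whose consensus base equals
#'   the template base;
#' * `template_identity` — % of all template positions matched by the
#'   consensus (uncovered positions count as unmatched);
#' * `conclave_score` — sum of the match scores of the reads won;
#' * `expected_score` — the score mass the template would receive under
#'   random assignment proportional to template length;
#' * `p_value` — two-tailed normal approximation to the binomial test of
#'   `conclave_score` against `expected_score`; `q_value` — the matching
#'   chi-square-style statistic `(s - e)^2 / (s + e)`.
#'
#' @param hits per-mate hit table (columns `read`, `template`, `score`,
#'   `start`, `strand`, `mate`).
#' @param assignment integer template index per read unit (`NA` =
#'   unmapped), from [reassign_reads()].
#' @param index the `kmer_index`.
#' @param reads,reads2 the read (and mate) sequences, uppercase.
#' @return data.frame with one row per template with `conclave_score > 0`,
#'   ordered by ConClave rank: `template_id`, `taxid`, `conclave_score`,
#'   `expected_score`, `template_length`, `template_identity`,
#'   `template_coverage`, `query_identity`, `query_coverage`, `depth`,
#'   `q_value`, `p_value`, `n_reads`.
#' @export
template_stats <- function(hits, assignment, index, reads, reads2 = NULL) {
  if (is.null(hits$mate)) hits$mate <- rep(1L, nrow(hits))
  won <- hits[!is.na(assignment[hits$read]) &
                hits$template == assignment[hits$read], , drop = FALSE]
  tpl_ids <- sort(unique(won$template))
  rows <- vector("list", length(tpl_ids))
  for (i in seq_along(tpl_ids)) {
    t <- tpl_ids[i]
    w <- won[won$template == t, , drop = FALSE]
    seqs <- ifelse(w$mate == 1L, reads[w$read],
                   if (is.null(reads2)) reads[w$read] else reads2[w$read])
    L <- index$template_length[t]
    counts <- cpp_pileup(L, seqs, w$start, w$strand)
    cov_vec <- counts[5L, ]
    covered <- cov_vec > 0L
    tseq <- strsplit(index$template_seq[t], "")[[1]]
    tcode <- match(tseq, c("A", "C", "G", "T"))  # NA for N etc.
    base_counts <- counts[1:4, , drop = FALSE]
    max_count <- apply(base_counts, 2L, max)
    # consensus: majority base; template base where uncovered or where the
    # template base ties for the maximum
    tpl_count <- ifelse(is.na(tcode), 0L,
                        base_counts[cbind(pmax(tcode, 1L),
                                          seq_len(L))])
    cons_idx <- max.col(t(base_counts), ties.method = "first")
    match_pos <- covered & !is.na(tcode) &
      (tpl_count == max_count | cons_idx == tcode)
    n_cov <- sum(covered)
    n_match <- sum(match_pos)
    rows[[i]] <- data.frame(
      template = t,
      template_id = index$template_id[t],
      taxid = index$taxid[t],
      conclave_score = sum(w$score),
      template_length = L,
      template_identity = 100 * n_match / L,
      template_coverage = min(100, 100 * n_cov / L),
      query_identity = if (n_cov > 0) 100 * n_match / n_cov else 0,
      query_coverage = min(100, 100 * n_cov / L),
      depth = sum(cov_vec) / L,
      n_reads = length(unique(w$read)),
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(template = integer(), template_id = character(),
               taxid = integer(), conclave_score = integer(),
               template_length = integer(), template_identity = numeric(),
               template_coverage = numeric(), query_identity = numeric(),
               query_coverage = numeric(), depth = numeric(),
               n_reads = integer(), stringsAsFactors = FALSE)

  # score-mass statistics vs length-proportional random assignment
  total_mass <- sum(res$conclave_score)
  total_len <- sum(as.numeric(index$template_length))
  p <- res$template_length / total_len
  res$expected_score <- total_mass * p
  s <- res$conclave_score; e <- res$expected_score
  res$q_value <- ifelse(s + e > 0, (s - e)^2 / (s + e), 0)
  var <- total_mass * p * (1 - p)
  z <- ifelse(var > 0, (s - e) / sqrt(var), 0)
  res$p_value <- ifelse(var > 0, 2 * pnorm(-abs(z)), 1)

  # order by ConClave rank criteria on the final (won-read) scores
  ord <- order(-res$conclave_score, res$template_length, res$template_id)
  res <- res[ord, c("template_id", "taxid", "conclave_score",
                    "expected_score", "template_length",
                    "template_identity", "template_coverage",
                    "query_identity", "query_coverage", "depth",
                    "q_value", "p_value", "n_reads")]
  rownames(res) <- NULL
  res
}

# ---------------------------------------------------------------------------

RES_HEADER <- c("#Template", "Score", "Expected", "Template_length",
                "Template_Identity", "Template_Coverage", "Query_Identity",
                "Query_Coverage", "Depth", "q_value", "p_value")

#' Write a template-result table in the `.res` tabular dialect
#'
#' Tab-separated with the fixed 11-column header used by KMA-style
#' mappers, so real mapper output and this package's output are
#' interchangeable at the file level. Floats are written with 2 decimals
#' (p-values with 4 significant digits, as mapper p-values underflow 2
#' decimals routinely).
#'
#' @param results a [template_stats()] data.frame (rows with score > 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_res <- function(results, path) {
  fmt2 <- function(x) sprintf("%.2f", x)
  lines <- paste(RES_HEADER, collapse = "\t")
  if (nrow(results)) {
    keep <- results$conclave_score > 0
    r <- results[keep, , drop = FALSE]
    body <- paste(r$template_id, r$conclave_score, fmt2(r$expected_score),
                  r$template_length, fmt2(r$template_identity),
                  fmt2(r$template_coverage), fmt2(r$query_identity),
                  fmt2(r$query_coverage), fmt2(r$depth), fmt2(r$q_value),
                  sprintf("%.4g", r$p_value), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
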