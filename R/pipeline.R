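# End-to-end convenience wrapper: map -> quality filter -> ranked
# classification, the sequence a user runs per sample.

#' Run the full classification pipeline on one sample
#'
#' Builds (or reuses) the k-mer index, maps the reads with ConClave
#' assignment, quality-filters the template table and classifies each
#' surviving template at the rank its identity supports.
#'
#' @param templates reference FASTA path / named character vector /
#'   `DNAStringSet`, or an existing [build_index()] object.
#' @param reads1,reads2 reads (paths or named character vectors);
#'   `reads2 = NULL` for single-end.
#' @param db a [load_taxonomy()] / [taxonomy_db()] database.
#' @param k,prefix index parameters (see [build_index()]).
#' @param quality a [quality_thresholds()] object.
#' @param thresholds a [rank_thresholds()] vector.
#' @param identity_source see [classify_sample()].
#' @return list with `mapping` (the [map_reads()] result), `res` (the
#'   quality-filtered template table) and `classification` (the
#'   [classify_sample()] table; RPM uses the reads given to the mapper).
#' @export
run_pipeline <- function(templates, reads1, reads2 = NULL, db,
                         k = 16L, prefix = "",
                         quality = quality_thresholds(),
                         thresholds = rank_thresholds(),
                         identity_source = "query_identity") {
  index <- if (inherits(templates, "kmer_index")) templates
           else build_index(templates, k = k, prefix = prefix)
  mapping <- map_reads(index, reads1, reads2)
  total_reads <- mapping$n_reads * (if (is.null(reads2)) 1L else 2L)
  res <- quality_filter(mapping$res, quality)
  classification <- classify_sample(res, db, thresholds = thresholds,
                                    identity_source = identity_source,
                                    total_reads = total_reads)
  list(mapping = mapping, res = res, classification = classification)
}

#' Per-read best-hit baseline assignment
#'
#' The naive strategy ConClave replaces: each read goes to its own
#' best-scoring template, ties resolved uniformly at random. Used to
#' demonstrate how shared reads inflate false positives under per-read
#' assignment.
#'
#' @param hits hit table (columns `read`, `template`, `score`).
#' @param n_reads number of read units.
#' @return integer vector: template index per read, `NA` if unmapped.
#' @export
naive_best_hit <- function(hits, n_reads) {
  assignment <- rep(NA_integer_, n_reads)
  if (!nrow(hits)) return(assignment)
  for (r in unique(hits$read)) {
    h <- hits[hits$read == r, , drop = FALSE]
    best <- h$template[h$score == max(h$score)]
    assignment[r] <- if (length(best) == 1L) best
                     else best[sample.int(length(best), 1L)]
  }
  assignment
}
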