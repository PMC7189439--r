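# Ranked taxonomic classification of a `.res` template table: quality
# filtering on depth/coverage/score/p-value, then truncation of each
# template's lineage at the deepest rank its sequence identity supports.

#' Quality thresholds for accepting a template match
#'
#' The filter dimensions are sequence depth, template coverage, ConClave
#' score and mapping p-value. Defaults are deliberately permissive
#' (low-abundance taxa at fractional depth are a normal signal in
#' metagenomes) and every value is a plain argument on the command line
#' and API.
#'
#' @param min_coverage minimum template coverage, percent (default 20).
#' @param min_depth minimum depth, fold (default 0.2).
#' @param min_score minimum ConClave score (default 0).
#' @param max_p_value maximum mapping p-value (default 0.05).
#' @return a `quality_thresholds` list.
#' @export
quality_thresholds <- function(min_coverage = 20, min_depth = 0.2,
                               min_score = 0, max_p_value = 0.05) {
  stopifnot(min_coverage >= 0, min_depth >= 0, min_score >= 0,
            max_p_value >= 0)
  structure(list(min_coverage = min_coverage, min_depth = min_depth,
                 min_score = min_score, max_p_value = max_p_value),
            class = "quality_thresholds")
}

#' Per-rank sequence-identity thresholds
#'
#' One percent-identity cutoff per assignable rank, weakly decreasing from
#' species to phylum; a value of 0 disables that rank's filter. The
#' defaults follow the similarity cutoffs established by large-scale
#' fungal barcoding analyses; they are configuration, not constants, and
#' can be changed per rank or all set to 0 to disable identity-based
#' truncation entirely.
#'
#' @param species,genus,family,order,class,phylum percent-identity cutoffs.
#' @return a `rank_thresholds` named numeric vector (species first).
#' @export
rank_thresholds <- function(species = 98.41, genus = 96.31, family = 88.51,
                            order = 81.21, class = 80.91, phylum = 0) {
  t <- c(species = species, genus = genus, family = family,
         order = order, class = class, phylum = phylum)
  if (any(t < 0 | t > 100)) stop("thresholds must lie in [0, 100]")
  nz <- t[t > 0]
  if (length(nz) > 1 && any(diff(nz) > 0))
    warning("non-zero thresholds should decrease from species to phylum")
  structure(t, class = "rank_thresholds")
}

#' Most specific rank supported by a sequence identity
#'
#' Walks ranks from species towards phylum and returns the first whose
#' threshold is 0 (disabled) or less than or equal to `identity`
#' (thresholds are inclusive: identity equal to the cutoff passes). If no
#' rank passes, returns `"unclassified"`.
#'
#' @param identity percent identity in \[0, 100\] (vectorized).
#' @param thresholds a [rank_thresholds()] vector.
#' @return character vector of rank labels (or `"unclassified"`).
#' @export
rank_from_identity <- function(identity, thresholds = rank_thresholds()) {
  stopifnot(all(identity >= 0 & identity <= 100))
  vapply(identity, function(id) {
    for (r in names(thresholds)) {
      if (thresholds[[r]] == 0 || id >= thresholds[[r]]) return(r)
    }
    "unclassified"
  }, "")
}

#' Parse a `.res`-dialect template table
#'
#' Accepts files written by [write_res()] or by a real KMA-style mapper:
#' tab-separated, 11 fixed columns, header starting `#Template`. The
#' template taxid is parsed from the template name; rows without a
#' parseable taxid or with non-numeric quality fields are skipped with a
#' warning.
#'
#' @param path path to a `.res` file.
#' @return data.frame in [template_stats()] layout (without `n_reads`).
#' @export
parse_res <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty .res file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(RES_HEADER, header)
  if (length(missing))
    stop(".res header is missing column(s): ",
         paste(missing, collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  empty <- data.frame(template_id = character(), taxid = integer(),
                      conclave_score = numeric(), expected_score = numeric(),
                      template_length = integer(),
                      template_identity = numeric(),
                      template_coverage = numeric(),
                      query_identity = numeric(), query_coverage = numeric(),
                      depth = numeric(), q_value = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (!length(body)) return(empty)
  f <- strsplit(body, "\t", fixed = TRUE)
  bad_len <- lengths(f) != length(header)
  if (any(bad_len)) {
    warning(sum(bad_len), " malformed .res row(s) skipped")
    f <- f[!bad_len]
  }
  if (!length(f)) return(empty)
  col <- function(name) vapply(f, `[`, "", match(name, header))
  num <- function(name) suppressWarnings(as.numeric(col(name)))
  out <- data.frame(
    template_id = col("#Template"),
    taxid = parse_taxid(col("#Template")),
    conclave_score = num("Score"),
    expected_score = num("Expected"),
    template_length = suppressWarnings(as.integer(num("Template_length"))),
    template_identity = num("Template_Identity"),
    template_coverage = num("Template_Coverage"),
    query_identity = num("Query_Identity"),
    query_coverage = num("Query_Coverage"),
    depth = num("Depth"),
    q_value = num("q_value"),
    p_value = num("p_value"),
    stringsAsFactors = FALSE)
  bad <- is.na(out$conclave_score) | is.na(out$depth) |
    is.na(out$template_coverage) | is.na(out$query_identity) |
    is.na(out$p_value)
  if (any(bad)) {
    warning(sum(bad), " .res row(s) with non-numeric fields skipped")
    out <- out[!bad, , drop = FALSE]
  }
  no_taxid <- is.na(out$taxid)
  if (any(no_taxid)) {
    warning(sum(no_taxid), " .res row(s) without a parseable taxid skipped")
    out <- out[!no_taxid, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Filter template matches on quality
#'
#' Pure predicate over [template_stats()] / [parse_res()] rows: keeps rows
#' with `template_coverage >= min_coverage`, `depth >= min_depth`,
#' `conclave_score >= min_score` and `p_value <= max_p_value`
#' (all boundaries inclusive); row order is preserved.
#'
#' @param results a template-result data.frame.
#' @param q a [quality_thresholds()] object.
#' @return the surviving rows, original order.
#' @export
quality_filter <- function(results, q = quality_thresholds()) {
  keep <- results$template_coverage >= q$min_coverage &
    results$depth >= q$min_depth &
    results$conclave_score >= q$min_score &
    results$p_value <= q$max_p_value
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert read counts to reads per million
#'
#' @param count read count(s) attributed to a taxon.
#' @param total_reads total reads given to the mapper for the sample.
#' @return `count / total_reads * 1e6`.
#' @export
to_rpm <- function(count, total_reads) {
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads <= 0)
    stop("total_reads must be a single positive number")
  count / total_reads * 1e6
}

#' Classify quality-filtered template matches at identity-supported ranks
#'
#' The pipeline core: for each surviving template row, the taxid is
#' updated against the merged-taxid table, its eight-rank lineage is
#' resolved, and the lineage is truncated at the deepest rank whose
#' identity threshold the match satisfies ([rank_from_identity()]).
#' Templates whose taxid is unknown to the taxonomy are reported as
#' `"unclassified"` with a warning rather than silently dropped.
#'
#' @param results quality-filtered rows ([quality_filter()]).
#' @param db a [load_taxonomy()] database.
#' @param thresholds a [rank_thresholds()] vector.
#' @param identity_source which identity drives the truncation:
#'   `"query_identity"` (consensus-vs-template identity, the default) or
#'   `"template_identity"`.
#' @param total_reads optional total read count of the sample, enabling
#'   the RPM column.
#' @return data.frame with one row per input row: `template_id`,
#'   `final_taxid`, `assigned_rank`, the eight rank-name columns
#'   (truncated, `NA` below the assigned rank, `unk_<rank>` placeholders
#'   within), `identity`, `depth`, `read_count`, `rpm`.
#' @export
classify_sample <- function(results, db, thresholds = rank_thresholds(),
                            identity_source = c("query_identity",
                                                "template_identity"),
                            total_reads = NULL) {
  identity_source <- match.arg(identity_source)
  n <- nrow(results)
  rank_cols <- matrix(NA_character_, n, 8L,
                      dimnames = list(NULL, CANONICAL_RANKS))
  final_taxid <- rep(NA_integer_, n)
  assigned <- rep("unclassified", n)
  identity <- results[[identity_source]]
  for (i in seq_len(n)) {
    tid <- suppressWarnings(update_taxid(db, results$taxid[i]))
    if (is.na(tid)) {
      warning("template ", results$template_id[i],
              " has a taxid unknown to the taxonomy; reported unclassified")
      next
    }
    final_taxid[i] <- tid
    lin <- resolve_lineage(db, tid)
    r <- rank_from_identity(identity[i], thresholds)
    # never assign deeper than the input taxid's own deepest known rank
    if (r != "unclassified") {
      deepest <- which(!is.na(lin$name))
      if (length(deepest)) {
        r_idx <- min(match(r, CANONICAL_RANKS), max(deepest))
        r <- CANONICAL_RANKS[r_idx]
      }
      assigned[i] <- r
      rank_cols[i, ] <- lineage_names(lin, to_rank = r)
    }
  }
  read_count <- if (!is.null(results$n_reads)) results$n_reads
                else rep(NA_integer_, n)
  out <- data.frame(template_id = results$template_id,
                    final_taxid = final_taxid,
                    assigned_rank = assigned,
                    rank_cols,
                    identity = identity,
                    depth = results$depth,
                    read_count = read_count,
                    stringsAsFactors = FALSE)
  out$rpm <- if (!is.null(total_reads)) to_rpm(out$read_count, total_reads)
             else NA_real_
  rownames(out) <- NULL
  out
}

#' Write a per-sample ranked classification CSV
#'
#' @param classification a [classify_sample()] data.frame.
#' @param path output path (RFC-4180 CSV, UTF-8).
#' @return `path`, invisibly.
#' @export
write_classification <- function(classification, path) {
  write.csv(classification, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-sample ranked classification CSV
#'
#' @param path a CSV written by [write_classification()].
#' @return the classification data.frame (empty strings back to `NA`).
#' @export
read_classification <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  for (r in CANONICAL_RANKS) out[[r]][out[[r]] == ""] <- NA_character_
  out
}
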