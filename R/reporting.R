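# Reporting: Krona-importable text and OTU-style merged abundance tables.

# Lineage path of each classification row, truncated at its assigned rank
# (or at merge_rank if given), with unk_<rank> placeholders inside the
# kept range. Returns a character vector of ";"-joined paths;
# "Unclassified" for rows with nothing to report.
classification_paths <- function(classification, merge_rank = NULL) {
  n <- nrow(classification)
  out <- character(n)
  for (i in seq_len(n)) {
    r <- classification$assigned_rank[i]
    if (!is.null(merge_rank)) {
      if (r == "unclassified" ||
          match(r, CANONICAL_RANKS) < match(merge_rank, CANONICAL_RANKS)) {
        # not classified down to the merge rank
        out[i] <- "Unclassified"
        next
      }
      r <- merge_rank
    }
    if (r == "unclassified") { out[i] <- "Unclassified"; next }
    cut <- match(r, CANONICAL_RANKS)
    nm <- unlist(classification[i, CANONICAL_RANKS[seq_len(cut)]],
                 use.names = FALSE)
    gap <- is.na(nm)
    nm[gap] <- paste0("unk_", CANONICAL_RANKS[seq_len(cut)][gap])
    out[i] <- paste(nm, collapse = ";")
  }
  out
}

#' Write classifications as Krona-importable text
#'
#' One tab-separated line per distinct (truncated) lineage:
#' `abundance<TAB>superkingdom<TAB>...<TAB>deepest-assigned-name`, with no
#' empty trailing fields, ready for `ktImportText`. Rows collapsing to the
#' same lineage are summed. Unclassified rows are emitted as a single
#' `Unclassified` line.
#'
#' @param classification a [classify_sample()] data.frame.
#' @param path output path.
#' @param unit abundance column to report: `"depth"` (default),
#'   `"read_count"` or `"rpm"`.
#' @return `path`, invisibly.
#' @export
write_krona_text <- function(classification, path, unit = "depth") {
  stopifnot(unit %in% c("depth", "read_count", "rpm"))
  paths <- classification_paths(classification)
  ab <- rowsum(classification[[unit]], paths)
  lines <- paste0(format_abundance(ab[, 1L]), "\t",
                  gsub(";", "\t", rownames(ab), fixed = TRUE))
  writeLines(lines, path)
  invisible(path)
}

format_abundance <- function(x) {
  ifelse(x == round(x), format(x, trim = TRUE, scientific = FALSE),
         format(x, trim = TRUE, scientific = FALSE, digits = 15))
}

#' Merge per-sample classifications into an OTU-style abundance table
#'
#' Aggregates each sample's classifications at `merge_rank` (lineage
#' truncated to that rank; taxa not classified down to it pooled into a
#' single `Unclassified` row) and joins samples as columns, absent cells
#' as 0 — the taxa-by-samples matrix shape community-analysis software
#' imports directly. Include/exclude filters match taxon names at any
#' rank of the full (untruncated) lineage and are applied before
#' aggregation.
#'
#' @param per_sample named list of [classify_sample()] data.frames (names
#'   become sample columns).
#' @param merge_rank rank to aggregate at (default `"species"`).
#' @param unit abundance unit: `"depth"` (default), `"read_count"` or
#'   `"rpm"`; all samples must carry it.
#' @param include optional character vector: keep only rows whose lineage
#'   contains at least one of these names.
#' @param exclude optional character vector: drop rows whose lineage
#'   contains any of these names (e.g. host reads via `"Chordata"`).
#' @return an `abundance_table` data.frame: `taxon_path` (names joined
#'   with `;`), `rank`, then one numeric column per sample.
#' @export
merge_samples <- function(per_sample, merge_rank = "species",
                          unit = "depth", include = NULL, exclude = NULL) {
  stopifnot(is.list(per_sample), length(per_sample) > 0)
  if (is.null(names(per_sample)) || any(!nzchar(names(per_sample))))
    names(per_sample) <- paste0("sample", seq_along(per_sample))
  stopifnot(unit %in% c("depth", "read_count", "rpm"),
            merge_rank %in% CANONICAL_RANKS)
  for (s in names(per_sample)) {
    if (is.null(per_sample[[s]][[unit]]) ||
        all(is.na(per_sample[[s]][[unit]])))
      stop("sample '", s, "' does not carry abundance unit '", unit, "'")
  }
  agg <- lapply(per_sample, function(cl) {
    if (!is.null(include) || !is.null(exclude)) {
      lin <- as.matrix(cl[, CANONICAL_RANKS])
      has_name <- function(names_vec)
        apply(lin, 1L, function(x) any(x %in% names_vec))
      keep <- rep(TRUE, nrow(cl))
      if (!is.null(include)) keep <- keep & has_name(include)
      if (!is.null(exclude)) keep <- keep & !has_name(exclude)
      cl <- cl[keep, , drop = FALSE]
    }
    if (!nrow(cl))
      return(stats::setNames(numeric(0), character(0)))
    paths <- classification_paths(cl, merge_rank = merge_rank)
    ab <- rowsum(cl[[unit]], paths)
    stats::setNames(ab[, 1L], rownames(ab))
  })
  all_paths <- sort(unique(unlist(lapply(agg, names))))
  # keep Unclassified last for readability
  if ("Unclassified" %in% all_paths)
    all_paths <- c(setdiff(all_paths, "Unclassified"), "Unclassified")
  mat <- sapply(names(agg), function(s) {
    v <- agg[[s]][all_paths]
    v[is.na(v)] <- 0
    v
  })
  mat <- matrix(mat, nrow = length(all_paths),
                dimnames = list(all_paths, names(agg)))
  out <- data.frame(taxon_path = all_paths,
                    rank = ifelse(all_paths == "Unclassified",
                                  "unclassified", merge_rank),
                    mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unit") <- unit
  attr(out, "merge_rank") <- merge_rank
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Write a merged abundance table as CSV
#'
#' RFC-4180 CSV, UTF-8, header `taxon_path,rank,<sample1>,<sample2>,...`.
#'
#' @param table an [merge_samples()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
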