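# Benchmarking: per-rank confusion counts between predicted and truth
# taxon sets, and precision/recall/F1.

#' Per-rank confusion counts between truth and prediction
#'
#' Both taxid sets are first updated against the merged-taxid table;
#' taxids unknown to the taxonomy are dropped with a warning (only matches
#' to valid taxids enter the statistics). Each surviving taxid is then
#' projected to `rank` via its lineage — using taxids, not names, so
#' homonyms cannot collide — and taxa with no ancestor at that rank are
#' dropped from both sides. True positives are the intersection, false
#' positives the prediction-only taxa, false negatives the truth-only
#' taxa.
#'
#' @param truth integer vector of truth taxids.
#' @param predicted integer vector of predicted taxids.
#' @param db a [load_taxonomy()] database.
#' @param rank rank to evaluate at (one of the eight canonical ranks).
#' @return a `confusion_counts` list: `rank`, `tp`, `fp`, `fn` (counts)
#'   and `tp_taxa`, `fp_taxa`, `fn_taxa` (taxid sets at `rank`).
#' @export
taxon_confusion <- function(truth, predicted, db, rank = "species") {
  stopifnot(rank %in% CANONICAL_RANKS)
  project <- function(taxids) {
    taxids <- update_taxid(db, taxids)
    taxids <- unique(taxids[!is.na(taxids)])
    at_rank <- vapply(taxids, function(t)
      resolve_lineage(db, t)$taxid[[rank]], integer(1))
    unique(at_rank[!is.na(at_rank)])
  }
  t_set <- project(truth)
  p_set <- project(predicted)
  tp <- intersect(p_set, t_set)
  fp <- setdiff(p_set, t_set)
  fn <- setdiff(t_set, p_set)
  structure(list(rank = rank, tp = length(tp), fp = length(fp),
                 fn = length(fn), tp_taxa = tp, fp_taxa = fp,
                 fn_taxa = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion_counts [%s]: TP %d, FP %d, FN %d\n",
              x$rank, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision of a confusion count, in percent
#'
#' `100 * TP / (TP + FP)`; when nothing was predicted (`TP + FP == 0`)
#' returns 0 carrying attribute `undefined = TRUE`.
#'
#' @param counts a [taxon_confusion()] result (or any list with `tp`,
#'   `fp`).
#' @return percent precision.
#' @export
precision <- function(counts) {
  denom <- counts$tp + counts$fp
  if (denom == 0) return(structure(0, undefined = TRUE))
  100 * counts$tp / denom
}

#' Recall of a confusion count, in percent
#'
#' `100 * TP / (TP + FN)`. An empty truth set (`TP + FN == 0`) leaves
#' recall undefined and is an error.
#'
#' @param counts a [taxon_confusion()] result (or any list with `tp`,
#'   `fn`).
#' @return percent recall.
#' @export
recall <- function(counts) {
  denom <- counts$tp + counts$fn
  if (denom == 0) stop("recall is undefined for an empty truth set")
  100 * counts$tp / denom
}

#' F1 score from percent precision and recall
#'
#' The harmonic average `2 * P * R / (P + R)`, 0 when both are 0.
#'
#' @param precision,recall percent values in \[0, 100\].
#' @return percent F1.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Benchmark a classification against a truth set across ranks
#'
#' Evaluates predicted taxids against truth taxids at each requested rank
#' (species through phylum, as classifier benchmarks conventionally
#' report).
#'
#' @param predicted integer vector of predicted taxids (e.g. the
#'   `final_taxid` column of [classify_sample()], optionally restricted to
#'   rows whose `assigned_rank` reaches the rank of interest — see
#'   `honor_assigned_rank`).
#' @param truth integer vector of truth taxids.
#' @param db a [load_taxonomy()] database.
#' @param ranks ranks to evaluate (default species, genus, family, order,
#'   class, phylum).
#' @param classification optional [classify_sample()] data.frame; when
#'   given, `predicted` is ignored and per-rank predictions honor each
#'   row's `assigned_rank` (a genus-level classification does not predict
#'   a species).
#' @return data.frame with one row per rank: `rank`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
benchmark_classification <- function(predicted = NULL, truth, db,
                                     ranks = c("species", "genus", "family",
                                               "order", "class", "phylum"),
                                     classification = NULL) {
  rows <- lapply(ranks, function(r) {
    pred_r <- if (!is.null(classification)) {
      ok <- classification$assigned_rank != "unclassified" &
        match(classification$assigned_rank, CANONICAL_RANKS) >=
          match(r, CANONICAL_RANKS)
      classification$final_taxid[ok & !is.na(classification$final_taxid)]
    } else predicted
    cc <- taxon_confusion(truth, pred_r, db, rank = r)
    p <- precision(cc)
    rec <- recall(cc)
    data.frame(rank = r, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               precision = as.numeric(p), recall = rec,
               f1 = f1_score(as.numeric(p), rec),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a truth-set TSV (taxid per line, optional abundance column)
#'
#' @param path truth TSV; lines starting with `#` are comments.
#' @return data.frame with `taxid` and (if present) `abundance`.
#' @export
read_truth <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    fill = TRUE, stringsAsFactors = FALSE)
  out <- data.frame(taxid = as.integer(tab[[1]]))
  if (ncol(tab) >= 2) out$abundance <- suppressWarnings(as.numeric(tab[[2]]))
  out
}

#' Write a per-rank benchmark report TSV
#'
#' @param report a [benchmark_classification()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
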