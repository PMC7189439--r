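# Taxonomy handling: NCBI-taxdump-style node/name/merged tables, obsolete
# taxid remapping, and fixed eight-rank lineage resolution.

# Canonical rank vocabulary, most inclusive first. "domain"/"realm" are
# accepted as synonyms of "superkingdom" when loading.
CANONICAL_RANKS <- c("superkingdom", "kingdom", "phylum", "class",
                     "order", "family", "genus", "species")

RANK_ALIASES <- c(domain = "superkingdom", realm = "superkingdom",
                  superkingdom = "superkingdom")

canonical_rank <- function(rank) {
  rank <- tolower(rank)
  ifelse(rank %in% names(RANK_ALIASES), RANK_ALIASES[rank], rank)
}

# ---------------------------------------------------------------------------

#' Load a taxonomy database
#'
#' Reads an NCBI-taxdump-style taxonomy into a lookup structure. Two file
#' dialects are accepted and auto-detected per file:
#' * classic pipe-delimited `.dmp` (`nodes.dmp` with taxid | parent | rank,
#'   `names.dmp` with taxid | name | unique name | name class, of which only
#'   `scientific name` rows are used, and `merged.dmp` with old | new), and
#' * a hand-writable 4-column TSV (`taxid  parent  rank  name`), in which
#'   case `names_table` is not needed; a merged table may then be a 2-column
#'   TSV (`old  new`).
#'
#' The root node is the (single) node that is its own parent. Every other
#' node's parent chain must terminate at the root; unknown parents and
#' cycles are load errors.
#'
#' @param nodes_table path to the nodes file (`.dmp` or 4-column TSV).
#' @param names_table path to `names.dmp`; ignored for the TSV dialect.
#' @param merged_table optional path to a merged-taxid remap file.
#' @return an object of class `taxonomy_db` with elements `parent`, `rank`
#'   and `name` (vectors named by taxid), `merged` (named integer vector,
#'   old taxid -> current taxid) and `root` (the root taxid).
#' @export
load_taxonomy <- function(nodes_table, names_table = NULL,
                          merged_table = NULL) {
  stopifnot(file.exists(nodes_table))
  lines <- readLines(nodes_table)
  lines <- lines[nzchar(lines)]
  is_dmp <- any(grepl("\t\\|", lines[seq_len(min(5, length(lines)))]))
  if (is_dmp) {
    fields <- strsplit(lines, "\t\\|\t?")
    taxid <- as.integer(vapply(fields, `[`, "", 1L))
    parent <- as.integer(vapply(fields, `[`, "", 2L))
    rank <- trimws(vapply(fields, `[`, "", 3L))
    name <- rep(NA_character_, length(taxid))
    if (!is.null(names_table)) {
      nl <- readLines(names_table)
      nl <- nl[nzchar(nl)]
      nf <- strsplit(nl, "\t\\|\t?")
      cls <- trimws(sub("\t?\\|\\s*$", "", vapply(nf, `[`, "", 4L)))
      sci <- cls == "scientific name"
      nm_id <- as.integer(vapply(nf, `[`, "", 1L))[sci]
      nm <- trimws(vapply(nf, `[`, "", 2L))[sci]
      name[match(nm_id, taxid)] <- nm
    }
    name[is.na(name)] <- paste0("taxid_", taxid[is.na(name)])
  } else {
    tab <- read.table(nodes_table, sep = "\t", header = FALSE,
                      quote = "", comment.char = "",
                      col.names = c("taxid", "parent", "rank", "name"),
                      colClasses = c("integer", "integer", "character",
                                     "character"))
    taxid <- tab$taxid; parent <- tab$parent
    rank <- tab$rank; name <- tab$name
  }
  if (anyDuplicated(taxid))
    stop("duplicate taxid in nodes table: ",
         taxid[duplicated(taxid)][1L])

  merged <- integer(0)
  if (!is.null(merged_table) && file.exists(merged_table)) {
    ml <- readLines(merged_table)
    ml <- ml[nzchar(ml)]
    if (length(ml)) {
      mf <- strsplit(ml, if (any(grepl("\t\\|", ml))) "\t\\|\t?" else "\t")
      old <- as.integer(vapply(mf, `[`, "", 1L))
      new <- as.integer(vapply(mf, `[`, "", 2L))
      merged <- stats::setNames(new, old)
    }
  }
  taxonomy_db(data.frame(taxid = taxid, parent = parent, rank = rank,
                         name = name, stringsAsFactors = FALSE),
              merged = merged)
}

#' Construct a taxonomy database in memory
#'
#' Programmatic counterpart of [load_taxonomy()], used e.g. by the
#' community simulator. Performs the same structural validation: a single
#' root (its own parent), no undefined parents, no cycles, and merged
#' taxids disjoint from node taxids.
#'
#' @param nodes data.frame with columns `taxid`, `parent`, `rank`, `name`.
#' @param merged named integer vector (names are old taxids, values the
#'   current ones).
#' @return a `taxonomy_db`.
#' @export
taxonomy_db <- function(nodes, merged = integer(0)) {
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(nodes)))
  taxid <- as.integer(nodes$taxid)
  parent <- as.integer(nodes$parent)
  if (anyDuplicated(taxid))
    stop("duplicate taxid in nodes table: ", taxid[duplicated(taxid)][1L])
  db <- structure(
    list(parent = stats::setNames(parent, taxid),
         rank = stats::setNames(canonical_rank(nodes$rank), taxid),
         name = stats::setNames(as.character(nodes$name), taxid),
         merged = merged,
         root = NA_integer_),
    class = "taxonomy_db")

  roots <- taxid[taxid == parent]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root (a node that is its own ",
         "parent); found ", length(roots))
  db$root <- roots

  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent))
    stop("parent taxid not defined in nodes table: ",
         paste(missing_parent, collapse = ", "))
  if (any(names(db$merged) %in% as.character(taxid)))
    stop("merged taxids must not also be node taxids")
  validate_acyclic(db)
  db
}

#' Write a taxonomy as the 4-column TSV dialect
#'
#' @param db a `taxonomy_db`.
#' @param nodes_path output path for the node TSV
#'   (`taxid  parent  rank  name`).
#' @param merged_path optional output path for the merged-taxid TSV
#'   (`old  new`); written only when the database has remaps.
#' @return `nodes_path`, invisibly.
#' @export
write_taxonomy_tsv <- function(db, nodes_path, merged_path = NULL) {
  tab <- data.frame(taxid = names(db$parent), parent = unname(db$parent),
                    rank = unname(db$rank), name = unname(db$name))
  utils::write.table(tab, nodes_path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(merged_path) && length(db$merged)) {
    utils::write.table(
      data.frame(old = names(db$merged), new = unname(db$merged)),
      merged_path, sep = "\t", row.names = FALSE, col.names = FALSE,
      quote = FALSE)
  }
  invisible(nodes_path)
}

# Walk each node to the root; a chain longer than the node count is a cycle.
validate_acyclic <- function(db) {
  n <- length(db$parent)
  for (tid in names(db$parent)) {
    cur <- tid
    steps <- 0L
    while (cur != as.character(db$root)) {
      cur <- as.character(db$parent[[cur]])
      steps <- steps + 1L
      if (steps > n)
        stop("cycle detected in taxonomy at taxid ", tid)
    }
  }
  invisible(TRUE)
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat("taxonomy_db:", length(x$parent), "nodes,",
      length(x$merged), "merged remaps, root taxid", x$root, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------

#' Remap obsolete taxids to their current identifier
#'
#' Taxids altered by nomenclature changes are carried in the taxonomy's
#' merged-taxid table; this resolves any taxid to its current form so that
#' e.g. a teleomorph and anamorph deposited under different historical ids
#' compare equal. Taxids known to neither the node nor the merged table are
#' returned as `NA` with a warning (callers such as the benchmark drop
#' them).
#'
#' @param db a `taxonomy_db`.
#' @param taxid integer vector of taxids.
#' @return integer vector of current taxids, `NA` where unknown.
#' @export
update_taxid <- function(db, taxid) {
  taxid <- as.integer(taxid)
  key <- as.character(taxid)
  out <- taxid
  is_merged <- key %in% names(db$merged)
  out[is_merged] <- db$merged[key[is_merged]]
  known <- is_merged | key %in% names(db$parent)
  if (any(!known & !is.na(taxid))) {
    warning("unknown taxid(s): ",
            paste(unique(taxid[!known & !is.na(taxid)]), collapse = ", "))
  }
  out[!known] <- NA_integer_
  out
}

#' Resolve a taxid to a fixed eight-rank lineage
#'
#' Walks the parent chain from `taxid` to the root, filling one slot per
#' canonical rank (superkingdom, kingdom, phylum, class, order, family,
#' genus, species). Nodes with non-canonical ranks ("no rank", subspecies,
#' strain, ...) are skipped, so a subspecies-level taxid reports its
#' species-level ancestor in the species slot. Ranks absent from the chain
#' are left `NA`; [lineage_names()] renders them as `unk_<rank>`
#' placeholders for rectangular output.
#'
#' @param db a `taxonomy_db`.
#' @param taxid a single taxid known to `db` (after [update_taxid()]).
#' @return an object of class `ranked_lineage`: list with `name` and
#'   `taxid`, each a vector with one element per canonical rank.
#' @export
resolve_lineage <- function(db, taxid) {
  key <- as.character(suppressWarnings(update_taxid(db, taxid)))
  if (is.na(key) || !key %in% names(db$parent))
    stop("unknown taxid: ", taxid)
  nm <- stats::setNames(rep(NA_character_, 8L), CANONICAL_RANKS)
  id <- stats::setNames(rep(NA_integer_, 8L), CANONICAL_RANKS)
  cur <- key
  repeat {
    r <- db$rank[[cur]]
    if (r %in% CANONICAL_RANKS && is.na(id[[r]])) {
      id[[r]] <- as.integer(cur)
      nm[[r]] <- db$name[[cur]]
    }
    if (cur == as.character(db$root)) break
    cur <- as.character(db$parent[[cur]])
  }
  structure(list(name = nm, taxid = id), class = "ranked_lineage")
}

#' Render lineage names with placeholders and optional truncation
#'
#' @param lineage a `ranked_lineage`.
#' @param to_rank deepest rank to keep (`"species"` keeps all eight slots;
#'   `"unclassified"` empties every slot). Slots below `to_rank` are `NA`.
#' @param placeholder if `TRUE`, ranks missing above the deepest retained
#'   filled slot are rendered as `"unk_<rank>"` so output stays
#'   rectangular.
#' @return named character vector over the eight canonical ranks.
#' @export
lineage_names <- function(lineage, to_rank = "species", placeholder = TRUE) {
  nm <- lineage$name
  if (identical(to_rank, "unclassified")) {
    nm[] <- NA_character_
    return(nm)
  }
  cut <- match(to_rank, CANONICAL_RANKS)
  if (is.na(cut)) stop("unknown rank: ", to_rank)
  if (cut < 8L) nm[(cut + 1L):8L] <- NA_character_
  if (placeholder) {
    kept <- seq_len(cut)
    deepest <- if (any(!is.na(nm[kept]))) max(which(!is.na(nm[kept]))) else 0L
    if (deepest > 0L) {
      gap <- which(is.na(nm[seq_len(deepest)]))
      nm[gap] <- paste0("unk_", CANONICAL_RANKS[gap])
    }
  }
  nm
}

#' @export
print.ranked_lineage <- function(x, ...) {
  shown <- ifelse(is.na(x$name), ".", x$name)
  cat(paste0(CANONICAL_RANKS, ": ", shown), sep = "\n")
  invisible(x)
}
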