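# Independent brute-force oracles and fixture builders for the test
# suite. These deliberately avoid the package's k-mer index and C++ code:
# scoring is done by exhaustive substring comparison over every
# (read k-mer, template position) pair.

# reverse complement without touching package/Biostrings code
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# all k-mers of a sequence as a character vector (NA-free positions only)
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# Brute-force count of indexable k-mer positions over a template set:
# every k-mer that starts with `prefix` and contains no N.
oracle_index_size <- function(templates, k, prefix = "") {
  sum(vapply(templates, function(tpl) {
    km <- seq_kmers(tpl, k)
    ok <- !grepl("N", km, fixed = TRUE)
    if (nzchar(prefix)) ok <- ok & startsWith(km, prefix)
    sum(ok)
  }, 0))
}

# Brute-force mode-of-diagonal match score of one oriented read against
# one template: tally template_pos - read_pos over all exact k-mer
# matches, return the largest tally.
oracle_score_oriented <- function(read, template, k, prefix = "") {
  rk <- seq_kmers(read, k)
  if (!length(rk)) return(0L)
  keep <- !grepl("N", rk, fixed = TRUE)
  if (nzchar(prefix)) keep <- keep & startsWith(rk, prefix)
  tk <- seq_kmers(template, k)
  if (!length(tk)) return(0L)
  diags <- integer(0)
  for (i in which(keep)) {
    j <- which(tk == rk[i])
    if (length(j)) diags <- c(diags, j - i)
  }
  if (!length(diags)) return(0L)
  max(tabulate(match(diags, unique(diags))))
}

# better orientation of the two
oracle_score <- function(read, template, k, prefix = "") {
  max(oracle_score_oriented(read, template, k, prefix),
      oracle_score_oriented(rc_chr(read), template, k, prefix))
}

# Full exhaustive (read x template) score matrix.
oracle_score_matrix <- function(reads, templates, k, prefix = "") {
  m <- matrix(0L, length(reads), length(templates))
  for (r in seq_along(reads))
    for (t in seq_along(templates))
      m[r, t] <- oracle_score(reads[r], templates[t], k, prefix)
  m
}

# ConClave totals and assignments recomputed from an exhaustive score
# matrix: candidates are each read's maximum-score templates; totals are
# candidate scores summed per template; each read goes to its candidate
# with the best (total, shorter length, lexicographic id) ordering.
oracle_conclave <- function(score_matrix, template_length, template_id) {
  n_t <- ncol(score_matrix)
  totals <- numeric(n_t)
  cand <- vector("list", nrow(score_matrix))
  for (r in seq_len(nrow(score_matrix))) {
    s <- score_matrix[r, ]
    if (max(s) == 0) next
    cand[[r]] <- which(s == max(s))
    totals[cand[[r]]] <- totals[cand[[r]]] + max(s)
  }
  ord <- order(-totals, template_length, template_id)
  rank_pos <- match(seq_len(n_t), ord)
  assignment <- rep(NA_integer_, nrow(score_matrix))
  for (r in seq_len(nrow(score_matrix))) {
    if (is.null(cand[[r]])) next
    assignment[r] <- cand[[r]][which.min(rank_pos[cand[[r]]])]
  }
  list(totals = totals, assignment = assignment)
}

# hand-writable toy taxonomy used across test files:
# root(1) > Eukaryota(2, superkingdom) > Fungi(3, kingdom) >
# Phylum_A(4) > Class_A(5) > Order_A(6) > Family_A(7) >
# Genus_A(8) > Species_A1(10), Species_A2(11); Species_A1 has
# subspecies(12); Genus_B(9) under Family_A.
toy_taxonomy <- function(merged = integer(0)) {
  nodes <- data.frame(
    taxid = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L),
    parent = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 7L, 8L, 8L, 10L),
    rank = c("no rank", "superkingdom", "kingdom", "phylum", "class",
             "order", "family", "genus", "genus", "species", "species",
             "subspecies"),
    name = c("root", "Eukaryota", "Fungi", "Phylum_A", "Class_A",
             "Order_A", "Family_A", "Genus_A", "Genus_B", "Species_A1",
             "Species_A2", "Species_A1 subsp. x"),
    stringsAsFactors = FALSE)
  taxonomy_db(nodes, merged = merged)
}

# Shared-segment fixture: template B equals template A except for one
# internal segment replaced by random bases; reads are drawn only from A.
# Returns templates plus reads split into shared (fully inside a region
# identical in both templates) and private (overlapping A's own segment).
shared_segment_fixture <- function(total_len = 300L, seg = c(101L, 200L),
                                   read_len = 40L, n_shared = 6L,
                                   n_private = 4L) {
  a <- rand_dna(total_len)
  b <- paste0(substr(a, 1, seg[1] - 1), rand_dna(seg[2] - seg[1] + 1),
              substr(a, seg[2] + 1, total_len))
  shared_starts <- c(
    sample(seq_len(seg[1] - read_len), ceiling(n_shared / 2), replace = TRUE),
    sample(seq(seg[2] + 1, total_len - read_len + 1), floor(n_shared / 2),
           replace = TRUE))
  private_starts <- sample(seq(seg[1] - 5, seg[2] - read_len + 5),
                           n_private, replace = TRUE)
  starts <- c(shared_starts, private_starts)
  reads <- substring(a, starts, starts + read_len - 1L)
  names(reads) <- sprintf("r%02d", seq_along(reads))
  list(templates = c("refA taxid=10" = a, "refB taxid=11" = b),
       reads = reads, n_shared = length(shared_starts))
}
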