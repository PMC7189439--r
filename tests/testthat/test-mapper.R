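# k-mer index, read scoring, ConClave selection/reassignment, template
# statistics and the .res writer.

test_that("index size equals the k-mer count, with and without prefix", {
  idx <- build_index(c("t taxid=1" = "ACGTACGT"), k = 4)
  expect_equal(conclaveR:::index_size(idx), 5)  # L - k + 1
  idx_pref <- build_index(c("t taxid=1" = "ACGTACGT"), k = 4,
                          prefix = "AC")
  expect_equal(conclaveR:::index_size(idx_pref), 2)  # positions 0 and 4

  set.seed(11)
  tpls <- vapply(sample(60:200, 40, replace = TRUE), rand_dna, "")
  names(tpls) <- sprintf("t%02d taxid=%d", seq_along(tpls),
                         seq_along(tpls))
  idx_at <- build_index(tpls, k = 6, prefix = "AT")
  expect_equal(conclaveR:::index_size(idx_at),
               oracle_index_size(tpls, 6, "AT"))
  # N-containing k-mers are never indexed
  idxN <- build_index(c("t taxid=1" = "ACGTNACGT"), k = 4)
  expect_equal(conclaveR:::index_size(idxN), 2)
})

test_that("templates shorter than k are skipped with a warning", {
  expect_warning(
    idx <- build_index(c("a taxid=1" = "ACGTACGTACGT", "b taxid=2" = "ACG"),
                       k = 8),
    "shorter than k")
  expect_equal(idx$template_id, "a taxid=1")
})

test_that("score_read matches perfect, symmetric and mismatch cases", {
  set.seed(21)
  tpl <- rand_dna(120)
  idx <- build_index(c("t taxid=1" = tpl), k = 8)
  read <- substr(tpl, 31, 70)  # exact 40 bp substring
  h <- score_read(read, idx)
  expect_equal(h$score, 40 - 8 + 1)
  expect_equal(h$start, 30)  # 0-based
  expect_equal(h$strand, 1)

  # reverse-complement orientation scores the same placement
  h_rc <- score_read(rc_chr(read), idx)
  expect_equal(h_rc$score, 33)
  expect_equal(h_rc$strand, -1)

  # two identical templates: equal scores on both
  idx2 <- build_index(c("a taxid=1" = tpl, "b taxid=2" = tpl), k = 8)
  h2 <- score_read(read, idx2)
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$score[1], h2$score[2])

  # one central mismatch: score equals the brute-force diagonal oracle
  read_mm <- read
  substr(read_mm, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                     substr(read_mm, 20, 20))[1]
  h_mm <- score_read(read_mm, idx)
  expect_equal(h_mm$score, oracle_score(read_mm, tpl, 8))
  expect_lt(h_mm$score, 33)
})

test_that("prefix-restricted scoring counts only prefix-bearing k-mers", {
  set.seed(31)
  tpl <- rand_dna(200)
  idx <- build_index(c("t taxid=1" = tpl), k = 6, prefix = "A")
  read <- substr(tpl, 51, 110)
  h <- score_read(read, idx)
  expect_equal(h$score, oracle_score(read, tpl, 6, prefix = "A"))
})

test_that("scores agree with the exhaustive oracle on random instances", {
  set.seed(41)
  for (rep in 1:10) {
    tpls <- vapply(sample(80:150, 3), rand_dna, "")
    names(tpls) <- sprintf("t%d taxid=%d", 1:3, 1:3)
    idx <- build_index(tpls, k = 8)
    reads <- c(
      # substrings with up to 3 mutations
      vapply(1:6, function(i) {
        t <- sample(3, 1)
        s <- sample(nchar(tpls[t]) - 39, 1)
        rd <- substr(tpls[t], s, s + 39)
        for (p in sample(40, sample(0:3, 1)))
          substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1)
        rd
      }, ""),
      vapply(rep(40, 2), rand_dna, ""))
    m <- oracle_score_matrix(reads, tpls, 8)
    for (r in seq_along(reads)) {
      h <- score_read(reads[r], idx)
      got <- rep(0L, 3)
      got[match(h$template_id, names(tpls))] <- h$score
      expect_equal(got, unname(m[r, ]))
    }
  }
})

test_that("ConClave gives shared reads to the globally dominant template", {
  set.seed(51)
  fx <- shared_segment_fixture()
  idx <- build_index(fx$templates, k = 8)
  mp <- map_reads(idx, fx$reads)
  # the true template wins every read; the near-identical decoy gets none
  expect_equal(unique(mp$assignments), "refA taxid=10")
  expect_equal(nrow(mp$res), 1L)
  expect_equal(mp$res$template_id, "refA taxid=10")
  expect_equal(mp$res$n_reads, length(fx$reads))
  expect_equal(mp$n_unmapped, 0L)
})

test_that("single-candidate reads keep their template; identical templates collapse deterministically", {
  set.seed(61)
  tpl <- rand_dna(200)
  # read hitting only the globally-second template is still assigned to it
  other <- rand_dna(200)
  idx <- build_index(c("big taxid=1" = tpl, "small taxid=2" = other), k = 8)
  reads <- c(substring(tpl, c(1, 51, 101), c(60, 110, 160)),
             substr(other, 21, 80))
  names(reads) <- paste0("r", 1:4)
  mp <- map_reads(idx, reads)
  expect_equal(mp$assignments,
               c(rep("big taxid=1", 3), "small taxid=2"))

  # two identical templates: all shared reads to the deterministically
  # first one; the lineages are not separately detectable
  idx_dup <- build_index(c("dupB taxid=3" = tpl, "dupA taxid=4" = tpl),
                         k = 8)
  mp_dup <- map_reads(idx_dup, reads[1:3])
  expect_equal(nrow(mp_dup$res), 1L)
  expect_equal(mp_dup$res$template_id, "dupA taxid=4")  # lexicographic tie
})

test_that("conclave totals and assignments equal the exhaustive double loop", {
  set.seed(71)
  tpls <- vapply(sample(80:160, 4), rand_dna, "")
  names(tpls) <- sprintf("t%d taxid=%d", 1:4, 1:4)
  idx <- build_index(tpls, k = 8)
  reads <- vapply(1:40, function(i) {
    t <- sample(4, 1)
    s <- sample(nchar(tpls[t]) - 29, 1)
    substr(tpls[t], s, s + 29)
  }, "")
  names(reads) <- paste0("r", 1:40)
  mp <- map_reads(idx, reads)

  m <- oracle_score_matrix(reads, tpls, 8)
  orc <- oracle_conclave(m, nchar(tpls), names(tpls))
  got_totals <- numeric(4)
  got_totals[match(mp$ranking$template_id, names(tpls))] <-
    mp$ranking$total_score
  expect_equal(got_totals, orc$totals)
  expect_equal(match(mp$assignments, names(tpls)),
               orc$assignment)
  # conservation: every read is assigned or unmapped
  expect_equal(sum(mp$res$n_reads) + mp$n_unmapped, length(reads))
})

test_that("template statistics recover depth, coverage and identity", {
  set.seed(81)
  tpl <- rand_dna(200)
  idx <- build_index(c("t taxid=1" = tpl), k = 8)
  # 10 reads of 20 bp tiling the template exactly once
  starts <- seq(1, 181, by = 20)
  reads <- substring(tpl, starts, starts + 19)
  names(reads) <- paste0("r", seq_along(reads))
  mp <- map_reads(idx, reads)
  expect_equal(mp$res$depth, 1.0)
  expect_equal(mp$res$template_coverage, 100)
  expect_equal(mp$res$query_identity, 100)
  expect_equal(mp$res$template_identity, 100)

  # reads covering half the template twice: depth 1, coverage 50
  half <- substring(tpl, c(1, 1, 21, 21, 41, 41, 61, 61, 81, 81),
                    c(20, 20, 40, 40, 60, 60, 80, 80, 100, 100))
  names(half) <- paste0("h", seq_along(half))
  mp2 <- map_reads(idx, half)
  expect_equal(mp2$res$depth, 1.0)
  expect_equal(mp2$res$template_coverage, 50)

  # a fixed SNP carried by every read: consensus disagrees at 1 of 200
  tpl100 <- rand_dna(100)
  idx100 <- build_index(c("t taxid=1" = tpl100), k = 8)
  snp_read <- tpl100
  substr(snp_read, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                      substr(tpl100, 50, 50))[1]
  snp_reads <- stats::setNames(rep(snp_read, 5), paste0("s", 1:5))
  mp3 <- map_reads(idx100, snp_reads)
  expect_equal(mp3$res$query_identity, 99.0)
  expect_equal(mp3$res$template_coverage, 100)
})

test_that("paired mates are assigned as a unit with summed scores", {
  set.seed(91)
  tpl <- rand_dna(400)
  idx <- build_index(c("t taxid=1" = tpl), k = 8)
  r1 <- stats::setNames(substring(tpl, c(1, 101), c(50, 150)), c("p1", "p2"))
  r2 <- stats::setNames(rc_chr(substring(tpl, c(151, 251), c(200, 300))),
                        c("p1", "p2"))
  mp <- map_reads(idx, r1, r2)
  expect_equal(mp$n_reads, 2L)
  expect_equal(mp$res$n_reads, 2L)
  # both mates contribute aligned bases: 4 x 50 bp over 400 bp
  expect_equal(mp$res$depth, 0.5)
  expect_equal(mp$res$conclave_score, 4 * (50 - 8 + 1))
})

test_that(".res files round-trip and are byte-deterministic", {
  set.seed(101)
  tpls <- stats::setNames(vapply(c(150, 150, 150), rand_dna, ""),
                          sprintf("t%d taxid=%d", 1:3, 1:3))
  idx <- build_index(tpls, k = 8)
  reads <- vapply(1:30, function(i) {
    t <- sample(3, 1); s <- sample(120, 1)
    substr(tpls[t], s, s + 29)
  }, "")
  names(reads) <- paste0("r", 1:30)
  mp <- map_reads(idx, reads)

  p1 <- tempfile(fileext = ".res"); p2 <- tempfile(fileext = ".res")
  write_res(mp$res, p1)
  lines <- readLines(p1)
  expect_equal(strsplit(lines[1], "\t")[[1]][1], "#Template")
  expect_equal(length(strsplit(lines[2], "\t")[[1]]), 11L)

  parsed <- parse_res(p1)
  expect_equal(parsed$template_id, mp$res$template_id)
  expect_equal(parsed$taxid, mp$res$taxid)
  expect_equal(parsed$conclave_score, mp$res$conclave_score)
  for (cn in c("expected_score", "template_identity", "template_coverage",
               "query_identity", "query_coverage", "depth", "q_value"))
    expect_equal(parsed[[cn]], mp$res[[cn]], tolerance = 0.006)

  # identical input => byte-identical output
  mp_again <- map_reads(idx, reads)
  write_res(mp_again$res, p2)
  expect_identical(readLines(p1), readLines(p2))

  # header-only file parses to an empty table
  p3 <- tempfile(fileext = ".res")
  write_res(mp$res[0, ], p3)
  expect_equal(length(readLines(p3)), 1L)
  expect_equal(nrow(parse_res(p3)), 0L)
})

test_that("malformed .res rows are rejected with warnings", {
  p <- tempfile(fileext = ".res")
  hdr <- paste(c("#Template", "Score", "Expected", "Template_length",
                 "Template_Identity", "Template_Coverage", "Query_Identity",
                 "Query_Coverage", "Depth", "q_value", "p_value"),
               collapse = "\t")
  good <- paste(c("t1 taxid=7", "10", "1.00", "100", "99.00", "80.00",
                  "99.50", "80.00", "1.20", "3.00", "0.01"),
                collapse = "\t")
  bad_depth <- paste(c("t2 taxid=8", "10", "1.00", "100", "99.00", "80.00",
                       "99.50", "80.00", "not_a_number", "3.00", "0.01"),
                     collapse = "\t")
  no_taxid <- paste(c("t3", "10", "1.00", "100", "99.00", "80.00",
                      "99.50", "80.00", "1.00", "3.00", "0.01"),
                    collapse = "\t")
  writeLines(c(hdr, good, bad_depth, no_taxid), p)
  expect_warning(expect_warning(res <- parse_res(p), "non-numeric"),
                 "taxid")
  expect_equal(res$template_id, "t1 taxid=7")
  expect_equal(res$taxid, 7L)

  writeLines(sub("Depth", "Deep", c(hdr, good)), p)
  expect_error(parse_res(p), "Depth")
})
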