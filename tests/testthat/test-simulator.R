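# Synthetic community generator: references, taxonomy, reads, truth.

small_spec <- function(...) {
  community_spec(n_species = 4, genome_length = 5000,
                 divergence = c(0, 0.05, 0.08, 0.12),
                 coverage = c(2, 2, 2, 2), read_length = 100,
                 insert_mean = 300, insert_sd = 30, ...)
}

test_that("references realize the requested divergence", {
  spec <- small_spec()
  refs <- simulate_references(spec, seed = 5)
  expect_length(refs$templates, 4L)
  expect_s3_class(refs$db, "taxonomy_db")
  # zero divergence: identical to ancestor
  expect_equal(refs$truth$identity_to_ancestor[1], 100)
  # 5% divergence on 5 kb: identity == 95% by construction (exact count)
  expect_equal(refs$truth$identity_to_ancestor[2], 95)
  # headers carry parseable taxids matching the truth table
  expect_equal(parse_taxid(names(refs$templates)), refs$truth$taxid)
  # every species taxid resolves to a full species-level lineage
  lin <- resolve_lineage(refs$db, refs$truth$taxid[3])
  expect_false(anyNA(lin$name))
})

test_that("reference simulation is seed-deterministic", {
  spec <- small_spec()
  r1 <- simulate_references(spec, seed = 9)
  r2 <- simulate_references(spec, seed = 9)
  expect_identical(r1$templates, r2$templates)
  g1 <- simulate_reads(r1, spec, seed = 4)
  g2 <- simulate_reads(r2, spec, seed = 4)
  expect_identical(g1$reads1, g2$reads1)
  expect_identical(g1$reads2, g2$reads2)

  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_community(r1, g1, d1)
  p2 <- write_community(r2, g2, d2)
  for (f in names(p1))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("read counts follow coverage arithmetic, with dropout", {
  # coverage 1.0 on 10 kb with single-end 100 bp reads: exactly 100 reads
  spec_se <- community_spec(n_species = 2, genome_length = 10000,
                            divergence = c(0, 0.1), coverage = c(1, 0.001),
                            read_length = 100, paired = FALSE,
                            error_rate = 0)
  refs <- simulate_references(spec_se, seed = 2)
  rds <- simulate_reads(refs, spec_se, seed = 2)
  expect_equal(rds$truth$n_reads, c(100L, 0L))
  expect_equal(rds$truth$present, c(TRUE, FALSE))
  expect_length(rds$reads1, 100L)
  expect_null(rds$reads2)

  # paired: coverage * L / (2 * read_length) fragments
  spec_pe <- small_spec()
  rds_pe <- simulate_reads(simulate_references(spec_pe, seed = 2),
                           spec_pe, seed = 2)
  expect_equal(rds_pe$truth$n_fragments, rep(50L, 4))
  expect_equal(length(rds_pe$reads1), sum(rds_pe$truth$n_fragments))
  expect_equal(names(rds_pe$reads2),
               sub("/1$", "/2", names(rds_pe$reads1)))
})

test_that("error-free reads are exact substrings of their template", {
  spec <- community_spec(n_species = 2, genome_length = 3000,
                         divergence = c(0.02, 0.1), coverage = 1,
                         read_length = 60, error_rate = 0,
                         insert_mean = 200, insert_sd = 20)
  refs <- simulate_references(spec, seed = 8)
  rds <- simulate_reads(refs, spec, seed = 8)
  sp <- as.integer(sub("^sp(\\d+)_.*", "\\1", names(rds$reads1)))
  for (i in seq_along(rds$reads1)) {
    tpl <- unname(refs$templates[sp[i]])
    r <- rds$reads1[[i]]
    expect_true(grepl(r, tpl, fixed = TRUE) ||
                  grepl(revcomp(r), tpl, fixed = TRUE))
  }
})

test_that("the substitution error rate is realized within sampling error", {
  spec_err <- community_spec(n_species = 1, genome_length = 10000,
                             divergence = 0, coverage = 10,
                             read_length = 100, paired = FALSE,
                             error_rate = 0.01)
  spec_0 <- spec_err; spec_0$error_rate <- 0
  refs <- simulate_references(spec_err, seed = 3)
  rds <- simulate_reads(refs, spec_0, seed = 3)       # pristine fragments
  rds_err <- simulate_reads(refs, spec_err, seed = 3) # same fragments + errors
  expect_equal(names(rds_err$reads1), names(rds$reads1))
  n_bases <- sum(nchar(rds$reads1))
  expect_gte(n_bases, 1e5)
  mism <- sum(mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, rds$reads1, rds_err$reads1))
  p_hat <- mism / n_bases
  sigma <- sqrt(0.01 * 0.99 / n_bases)
  expect_lt(abs(p_hat - 0.01), 3 * sigma + 1e-4)
})

test_that("transcript simulation respects gene windows and expression", {
  spec <- community_spec(n_species = 2, genome_length = 20000,
                         divergence = c(0.02, 0.1),
                         mode = "metatranscriptome",
                         genes_per_species = 10, gene_length = 1000,
                         expression_mean = 3, expression_sd = 0,
                         regulated_fraction = 0.2, regulation_factor = 1,
                         read_length = 100, insert_mean = 300,
                         insert_sd = 0, error_rate = 0)
  refs <- simulate_references(spec, seed = 6)
  tx <- simulate_transcripts(refs, spec, seed = 6)
  genes <- attr(tx$truth, "genes")
  expect_equal(nrow(genes), 20L)
  # factor 1 regulation reduces to the unperturbed model: every gene at
  # fold 3 => 1000 * 3 / 200 = 15 fragments each
  expect_equal(unique(genes$n_fragments), 15L)
  expect_equal(unique(genes$expression), 3)
  expect_equal(tx$truth$n_reads, rep(2L * 10L * 15L, 2))

  # a single unregulated 1 kb gene at fold 1 with SE 100 bp reads: 10 reads
  spec1 <- community_spec(n_species = 1, genome_length = 2000,
                          divergence = 0, mode = "metatranscriptome",
                          genes_per_species = 1, gene_length = 1000,
                          expression_mean = 1, expression_sd = 0,
                          regulated_fraction = 0, regulation_factor = 1,
                          read_length = 100, paired = FALSE,
                          error_rate = 0)
  refs1 <- simulate_references(spec1, seed = 6)
  tx1 <- simulate_transcripts(refs1, spec1, seed = 6)
  expect_equal(tx1$truth$n_reads, 10L)

  # template too short for the requested gene windows
  spec_bad <- community_spec(n_species = 1, genome_length = 2000,
                             mode = "metatranscriptome",
                             genes_per_species = 10, gene_length = 1000)
  refs_bad <- simulate_references(spec_bad, seed = 6)
  expect_error(simulate_transcripts(refs_bad, spec_bad, seed = 6),
               "too short")
})

test_that("realized per-gene coverage tracks the expression mean", {
  spec <- community_spec(n_species = 1, genome_length = 50000,
                         divergence = 0, mode = "metatranscriptome",
                         genes_per_species = 50, gene_length = 1000,
                         expression_mean = 3, expression_sd = 1,
                         regulated_fraction = 0, read_length = 100,
                         insert_mean = 300, insert_sd = 30,
                         error_rate = 0)
  refs <- simulate_references(spec, seed = 12)
  folds <- numeric(0)
  for (s in 1:4) {
    tx <- simulate_transcripts(refs, spec, seed = s)
    genes <- attr(tx$truth, "genes")
    folds <- c(folds, genes$n_fragments * 200 / 1000)
  }
  # 200 genes; mean realized coverage within 3 sigma of the target
  # (folds truncated at 0, slight upward bias tolerated in the band)
  expect_length(folds, 200L)
  expect_lt(abs(mean(folds) - 3), 3 * 1 / sqrt(200) + 0.1)
})
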