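# Synthetic community simulator: reference templates diverged from a
# common ancestor, a toy multi-rank taxonomy, Illumina-like reads with a
# substitution error model, and ground-truth tables for benchmarking.
#
# The generator emulates the design of published classifier test sets —
# a community of species at controlled pairwise identity, per-species
# coverage, paired-end reads with a normal insert-size distribution and
# per-base substitution errors — scaled to desk size.

#' Specify a synthetic community
#'
#' Defaults describe the package's desk-scale metagenome preset: 20
#' species of 50 kb diverged 3–12% from a common ancestor (so every
#' species pair is at most ~95% identical), per-species coverage drawn
#' uniformly between 5x and 15x (about 50,000 read pairs in total),
#' 2 x 100 bp paired reads with a normal(500, 50) insert and a 0.5%
#' per-base substitution error rate. Metatranscriptome mode samples
#' non-overlapping gene windows per genome and draws per-gene expression
#' from a normal distribution of mean 3x, with 20% of genes up- and 20%
#' down-regulated by a fixed factor.
#'
#' @param n_species number of species.
#' @param genome_length template length in bases.
#' @param divergence per-species substitution fraction from the common
#'   ancestor; default evenly spaced from 0.03 to 0.12.
#' @param coverage optional explicit per-species fold-coverage plan
#'   (recycled); overrides `coverage_range`. Coverages below the
#'   detection floor (read count rounding to 0) are legitimate and yield
#'   dropout species.
#' @param coverage_range fold-coverage interval for uniform per-species
#'   draws when `coverage` is not given.
#' @param read_length read length in bases.
#' @param paired simulate read pairs (insert drawn from a truncated
#'   normal) or single-end reads.
#' @param insert_mean,insert_sd insert-size distribution in bases.
#' @param error_rate per-base substitution probability in \[0, 0.1\].
#' @param mode `"metagenome"` or `"metatranscriptome"`.
#' @param genes_per_species gene windows per genome (metatranscriptome).
#' @param gene_length gene window length in bases.
#' @param expression_mean,expression_sd per-gene expression fold
#'   distribution (metatranscriptome).
#' @param regulated_fraction fraction of genes up- and (separately)
#'   down-regulated.
#' @param regulation_factor multiplicative fold change applied to
#'   regulated genes.
#' @param genus_size,family_size round-robin fan-out of the toy taxonomy
#'   (species per genus, genera per family).
#' @return a `community_spec` list.
#' @export
community_spec <- function(n_species = 20L, genome_length = 50000L,
                           divergence = NULL, coverage = NULL,
                           coverage_range = c(5, 15),
                           read_length = 100L, paired = TRUE,
                           insert_mean = 500, insert_sd = 50,
                           error_rate = 0.005,
                           mode = c("metagenome", "metatranscriptome"),
                           genes_per_species = 40L, gene_length = 1000L,
                           expression_mean = 3, expression_sd = 1,
                           regulated_fraction = 0.2,
                           regulation_factor = 2,
                           genus_size = 2L, family_size = 2L) {
  mode <- match.arg(mode)
  if (is.null(divergence))
    divergence <- seq(0.03, 0.12, length.out = n_species)
  divergence <- rep_len(divergence, n_species)
  stopifnot(n_species > 0, genome_length > 0, read_length > 0,
            error_rate >= 0, error_rate <= 0.1,
            all(coverage_range > 0), all(coverage_range <= 1e3),
            all(divergence >= 0), all(divergence < 1))
  if (!is.null(coverage)) coverage <- rep_len(coverage, n_species)
  structure(
    list(n_species = as.integer(n_species),
         genome_length = as.integer(genome_length),
         divergence = divergence, coverage = coverage,
         coverage_range = coverage_range,
         read_length = as.integer(read_length), paired = paired,
         insert_mean = insert_mean, insert_sd = insert_sd,
         error_rate = error_rate, mode = mode,
         genes_per_species = as.integer(genes_per_species),
         gene_length = as.integer(gene_length),
         expression_mean = expression_mean,
         expression_sd = expression_sd,
         regulated_fraction = regulated_fraction,
         regulation_factor = regulation_factor,
         genus_size = as.integer(genus_size),
         family_size = as.integer(family_size)),
    class = "community_spec")
}

DNA_BASES <- c("A", "C", "G", "T")

# Toy taxonomy: species grouped round-robin into genera, genera into
# families, then a single order/class/phylum/kingdom/superkingdom chain.
build_toy_taxonomy <- function(n_species, genus_size = 2L,
                               family_size = 2L) {
  n_genus <- ceiling(n_species / genus_size)
  n_family <- ceiling(n_genus / family_size)
  sp_id <- 1000L + seq_len(n_species)
  gen_id <- 200L + seq_len(n_genus)
  fam_id <- 100L + seq_len(n_family)
  sp_genus <- gen_id[((seq_len(n_species) - 1L) %% n_genus) + 1L]
  gen_family <- fam_id[((seq_len(n_genus) - 1L) %% n_family) + 1L]
  nodes <- rbind(
    data.frame(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
    data.frame(taxid = 2L, parent = 1L, rank = "superkingdom",
               name = "Eukaryota"),
    data.frame(taxid = 3L, parent = 2L, rank = "kingdom", name = "Fungi"),
    data.frame(taxid = 4L, parent = 3L, rank = "phylum",
               name = "Simulomycota"),
    data.frame(taxid = 5L, parent = 4L, rank = "class",
               name = "Simulomycetes"),
    data.frame(taxid = 6L, parent = 5L, rank = "order",
               name = "Simulales"),
    data.frame(taxid = fam_id, parent = 6L, rank = "family",
               name = paste0("Simulaceae_", seq_len(n_family))),
    data.frame(taxid = gen_id, parent = gen_family, rank = "genus",
               name = paste0("Simulomyces_", seq_len(n_genus))),
    data.frame(taxid = sp_id, parent = sp_genus, rank = "species",
               name = paste0("Simulomyces_",
                             match(sp_genus, gen_id), " species_",
                             seq_len(n_species))))
  list(db = taxonomy_db(nodes), species_taxid = sp_id)
}

#' Simulate reference templates, taxonomy and truth skeleton
#'
#' Draws one random ancestor sequence and mutates it independently per
#' species: a fraction `divergence[i]` of uniformly chosen positions is
#' substituted with a different base, so the realized identity of species
#' i to the ancestor is `100 * (1 - divergence[i])` and two species are
#' roughly `100 * (1 - d_i - d_j)` percent identical. A star-shaped toy
#' taxonomy groups species into genera and families round-robin.
#'
#' @param spec a [community_spec()].
#' @param seed RNG seed; equal seeds give identical output.
#' @return a `community_references` list: `templates` (named character
#'   vector; headers carry `taxid=<int>` tokens), `db` (the toy
#'   `taxonomy_db`), and `truth` (data.frame with `species`, `taxid`,
#'   `template_id`, `divergence`, `identity_to_ancestor`).
#' @export
simulate_references <- function(spec = community_spec(), seed = 1L) {
  set.seed(seed)
  L <- spec$genome_length
  n <- spec$n_species
  ancestor <- sample(DNA_BASES, L, replace = TRUE)
  tax <- build_toy_taxonomy(n, spec$genus_size, spec$family_size)
  ids <- sprintf("SP%02d_genome taxid=%d", seq_len(n), tax$species_taxid)
  templates <- character(n)
  realized <- numeric(n)
  for (i in seq_len(n)) {
    seq_i <- ancestor
    n_mut <- round(spec$divergence[i] * L)
    if (n_mut > 0) {
      pos <- sample.int(L, n_mut)
      seq_i[pos] <- vapply(seq_i[pos], function(b)
        sample(setdiff(DNA_BASES, b), 1L), "")
    }
    realized[i] <- 100 * sum(seq_i == ancestor) / L
    templates[i] <- paste(seq_i, collapse = "")
  }
  names(templates) <- ids
  structure(
    list(templates = templates, db = tax$db,
         truth = data.frame(species = seq_len(n),
                            taxid = tax$species_taxid,
                            template_id = ids,
                            divergence = spec$divergence,
                            identity_to_ancestor = realized,
                            stringsAsFactors = FALSE)),
    class = "community_references")
}

# Draw fragments from one sequence and return reads with substitution
# errors. Fragments come from either strand with equal probability.
sample_fragments <- function(seqtext, n_frag, spec, id_prefix) {
  rl <- spec$read_length
  L <- nchar(seqtext)
  if (n_frag == 0L) {
    empty <- stats::setNames(character(0), character(0))
    return(list(r1 = empty, r2 = if (spec$paired) empty else NULL))
  }
  if (spec$paired) {
    insert <- round(rnorm(n_frag, spec$insert_mean, spec$insert_sd))
    insert <- pmin(pmax(insert, rl), L)
  } else {
    insert <- rep(rl, n_frag)
  }
  start <- floor(runif(n_frag, 1, L - insert + 1 + 1))
  frag_strand <- runif(n_frag) < 0.5
  r1 <- substr(rep(seqtext, n_frag), start, start + rl - 1L)
  if (spec$paired) {
    r2 <- revcomp(substr(rep(seqtext, n_frag),
                         start + insert - rl, start + insert - 1L))
    flip <- frag_strand
    tmp <- r1[flip]; r1[flip] <- r2[flip]; r2[flip] <- tmp
  } else {
    r1[frag_strand] <- revcomp(r1[frag_strand])
    r2 <- NULL
  }
  names(r1) <- sprintf("%s_frag%d/1", id_prefix, seq_len(n_frag))
  r1 <- add_substitution_errors(r1, spec$error_rate)
  if (!is.null(r2)) {
    names(r2) <- sprintf("%s_frag%d/2", id_prefix, seq_len(n_frag))
    r2 <- add_substitution_errors(r2, spec$error_rate)
  }
  list(r1 = r1, r2 = r2)
}

# Per-base substitution errors: each base replaced with a different base
# with probability `rate`.
add_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  n_err <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  reads
}

#' Simulate metagenome reads from community references
#'
#' Per species, the number of fragments is
#' `round(coverage * genome_length / (read_length * (2 if paired else 1)))`
#' — i.e. total sequenced bases match the requested fold coverage.
#' Fragment starts are uniform, strands random, inserts normal (truncated
#' to at least one read length) and each base is substituted with
#' probability `error_rate`. Species whose read count rounds to 0 are
#' flagged absent in the truth table (the ultra-low-coverage dropout
#' regime).
#'
#' @param refs a [simulate_references()] result.
#' @param spec the [community_spec()] used for the references.
#' @param seed RNG seed; equal seeds give byte-identical reads.
#' @return a `community_reads` list: `reads1`, `reads2` (named character
#'   vectors; `reads2` is `NULL` for single-end), and `truth`
#'   (per-species data.frame with `taxid`, `template_id`, `coverage`,
#'   `n_fragments`, `n_reads`, `present`).
#' @export
simulate_reads <- function(refs, spec = community_spec(), seed = 1L) {
  set.seed(seed)
  n <- spec$n_species
  cov <- if (!is.null(spec$coverage)) spec$coverage
         else runif(n, spec$coverage_range[1], spec$coverage_range[2])
  per_read <- spec$read_length * (if (spec$paired) 2L else 1L)
  n_frag <- as.integer(round(cov * spec$genome_length / per_read))
  r1 <- vector("list", n); r2 <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- sample_fragments(unname(refs$templates[i]), n_frag[i], spec,
                           sprintf("sp%02d", i))
    r1[[i]] <- fr$r1; r2[[i]] <- fr$r2
  }
  truth <- data.frame(
    species = seq_len(n),
    taxid = refs$truth$taxid,
    template_id = refs$truth$template_id,
    coverage = cov,
    n_fragments = n_frag,
    n_reads = n_frag * (if (spec$paired) 2L else 1L),
    present = n_frag > 0L,
    stringsAsFactors = FALSE)
  structure(
    list(reads1 = do.call(c, r1),
         reads2 = if (spec$paired) do.call(c, r2) else NULL,
         truth = truth),
    class = "community_reads")
}

#' Simulate metatranscriptome reads from community references
#'
#' Samples `genes_per_species` non-overlapping gene windows from each
#' genome, draws a per-gene expression fold from
#' `normal(expression_mean, expression_sd)` (truncated at 0), multiplies
#' a `regulated_fraction` of genes up and another `regulated_fraction`
#' down by `regulation_factor`, and generates reads from each gene
#' window at its expression fold exactly as [simulate_reads()] does from
#' genomes.
#'
#' @param refs a [simulate_references()] result.
#' @param spec a [community_spec()] with `mode = "metatranscriptome"`.
#' @param seed RNG seed.
#' @return a `community_reads` list as in [simulate_reads()]; its `truth`
#'   has per-species totals and carries the per-gene table (window,
#'   expression fold, regulation, read count) as attribute `genes`.
#' @export
simulate_transcripts <- function(refs, spec, seed = 1L) {
  stopifnot(spec$mode == "metatranscriptome")
  set.seed(seed)
  n <- spec$n_species
  g <- spec$genes_per_species
  slot <- spec$genome_length %/% g
  if (slot < spec$gene_length)
    stop("template too short for ", g, " non-overlapping genes of ",
         spec$gene_length, " bases")
  per_read <- spec$read_length * (if (spec$paired) 2L else 1L)
  r1 <- list(); r2 <- list(); gene_rows <- list()
  for (i in seq_len(n)) {
    gene_start <- (seq_len(g) - 1L) * slot + 1L
    fold <- pmax(rnorm(g, spec$expression_mean, spec$expression_sd), 0)
    n_reg <- floor(spec$regulated_fraction * g)
    reg <- rep("none", g)
    if (n_reg > 0) {
      pick <- sample.int(g, 2L * n_reg)
      up <- pick[seq_len(n_reg)]
      down <- pick[n_reg + seq_len(n_reg)]
      fold[up] <- fold[up] * spec$regulation_factor
      fold[down] <- fold[down] / spec$regulation_factor
      reg[up] <- "up"; reg[down] <- "down"
    }
    tpl <- unname(refs$templates[i])
    for (j in seq_len(g)) {
      gene_seq <- substr(tpl, gene_start[j], gene_start[j] +
                           spec$gene_length - 1L)
      gspec <- spec
      gspec$insert_mean <- min(spec$insert_mean, spec$gene_length)
      n_frag <- as.integer(round(fold[j] * spec$gene_length / per_read))
      fr <- sample_fragments(gene_seq, n_frag, gspec,
                             sprintf("sp%02d_g%03d", i, j))
      r1 <- c(r1, list(fr$r1)); r2 <- c(r2, list(fr$r2))
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        species = i, taxid = refs$truth$taxid[i], gene = j,
        start = gene_start[j], expression = fold[j], regulation = reg[j],
        n_fragments = n_frag, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  agg <- rowsum(genes$n_fragments, genes$species)
  truth <- data.frame(
    species = seq_len(n),
    taxid = refs$truth$taxid,
    template_id = refs$truth$template_id,
    coverage = NA_real_,
    n_fragments = agg[, 1L],
    n_reads = agg[, 1L] * (if (spec$paired) 2L else 1L),
    present = agg[, 1L] > 0L,
    stringsAsFactors = FALSE)
  out <- structure(
    list(reads1 = do.call(c, r1),
         reads2 = if (spec$paired) do.call(c, r2) else NULL,
         truth = truth),
    class = "community_reads")
  attr(out$truth, "genes") <- genes
  out
}

#' Write a simulated community to disk
#'
#' Writes the reference FASTA (taxid-tagged headers), the taxonomy TSV,
#' the reads as FASTQ (gzipped when `gz = TRUE`) and the truth TSV into
#' `outdir`.
#'
#' @param refs a [simulate_references()] result.
#' @param reads a [simulate_reads()] / [simulate_transcripts()] result.
#' @param outdir output directory (created if needed).
#' @param gz gzip the FASTQ files.
#' @return named character vector of the paths written.
#' @export
write_community <- function(refs, reads, outdir, gz = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- c(templates = file.path(outdir, "templates.fa"),
         taxonomy = file.path(outdir, "taxonomy.tsv"),
         reads1 = file.path(outdir, paste0("reads_1.fq", if (gz) ".gz")),
         truth = file.path(outdir, "truth.tsv"))
  write_fasta(refs$templates, p[["templates"]])
  write_taxonomy_tsv(refs$db, p[["taxonomy"]])
  write_fastq(reads$reads1, p[["reads1"]])
  if (!is.null(reads$reads2)) {
    p[["reads2"]] <- file.path(outdir, paste0("reads_2.fq", if (gz) ".gz"))
    write_fastq(reads$reads2, p[["reads2"]])
  }
  utils::write.table(reads$truth, p[["truth"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  p
}
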