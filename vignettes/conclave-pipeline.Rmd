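---
title: "The ConClave classification pipeline: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ConClave classification pipeline: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conclaveR)
```

# The classification model

## Read scoring

A read's match score against a reference template is defined as the
number of its k-mers found in that template at offsets consistent with
one ungapped placement: all exact (read k-mer, template position)
matches are tallied by diagonal (template offset minus read offset) and
the best diagonal's tally is the score. Both the read and its reverse
complement are scored and the better orientation kept (forward wins
ties). With an index prefix set, only k-mers beginning with that prefix
participate on both sides.

This is deliberately an *ungapped, exact-k-mer* model. It makes the
score exactly reproducible by a brute-force enumeration over every
(read k-mer, template position) pair — the oracle the test suite and
acceptance script exercise — while preserving the semantics that
matter for classification: a read from a template present in the
sample scores near its maximum on that template and strictly lower on
diverged relatives, degrading smoothly with sequence divergence
(roughly by a factor \((1-d)^k\) for divergence \(d\)).

## ConClave template sorting

Let \(s_{rt}\) be read \(r\)'s score on template \(t\). Read \(r\)'s
*candidates* are the templates achieving \(\max_t s_{rt}\) — ties
included, since those placements cannot be distinguished from the read
alone. The two passes are:

1. every read adds its best score to **each** of its candidates, and
   templates are ranked by the accumulated total;
2. every read is assigned to its highest-ranked candidate.

Restricting candidacy to best-score ties (rather than to every
template with a non-zero score) is essential: in a community of
related genomes, the globally top template shares at least one k-mer
with almost every read, and unrestricted candidacy would hand it the
entire data set. With the best-tie rule, only reads that genuinely
cannot tell templates apart are steered by the global ranking — which
is precisely the shared-read problem the scheme exists to solve.

Ties in the template ranking are broken deterministically: higher
total score, then shorter template, then lexicographic template
identifier. Two identical templates therefore collapse onto one of
them reproducibly — two lineages with no detectable consensus
difference are reported as one taxon, which is the intended behavior,
not an error.

## Template statistics

For each template that won reads, every winning read (each mate
separately, at its own best diagonal, clipped to the template):

* **depth** — aligned bases / template length (fold);
* **template coverage** — % of positions covered at least once
  (query coverage equals it under ungapped placement);
* **consensus** — per-position majority base over the aligned reads;
  the template base where uncovered, and on ties the template base is
  retained;
* **query identity** — % of covered positions whose consensus equals
  the template: the quantity that drives rank truncation. Because the
  consensus votes out independent sequencing errors, query identity
  reflects biological divergence between the sampled organism and the
  reference, not the raw error rate;
* **template identity** — % of *all* template positions matched
  (uncovered positions count against it);
* **expected score** — the template's share of the total score mass
  under assignment proportional to template length,
  \(E_t = M \cdot L_t / \sum_u L_u\); the **p-value** is a two-tailed
  normal approximation to the binomial \((M, L_t/\sum L_u)\) at the
  observed score, and the q-value column carries the matching
  \((s-e)^2/(s+e)\) statistic. These are deliberately simple screening
  statistics — the classifier uses the p-value only as a filter
  dimension.

Results are written as the tab-separated `.res` dialect (11 fixed
columns), so tables from a real KMA-style mapper can be consumed by
`parse_res()` interchangeably; interchange happens at file level, not
at score level, and no attempt is made to reproduce another mapper's
numeric scores.

## Ranked classification

Surviving rows (coverage, depth, score, p-value filters; all
boundaries inclusive, so a value exactly at a threshold passes) are
classified by walking the rank ladder species → genus → family →
order → class → phylum and stopping at the first rank whose identity
cutoff is disabled (0) or satisfied. The template's lineage — resolved
against an NCBI-taxdump-style taxonomy with obsolete taxids remapped —
is truncated at that rank; ranks missing from the taxonomy inside the
kept range render as explicit `unk_<rank>` placeholders so merged
tables stay rectangular. A match whose identity passes species level
but whose taxid is only known to genus level is reported at the
taxid's own deepest rank: identity can never conjure resolution the
reference annotation lacks.

Default identity cutoffs (species 98.41, genus 96.31, family 88.51,
order 81.21, class 80.91, phylum 0) follow thresholds established for
fungal sequences in large-scale barcoding work; no universal threshold
suits all genes and organisms, so they are exposed as plain
configuration and can be altered per rank or all set to 0 (reporting
everything at its deepest known rank). Quality-filter defaults
(coverage ≥ 20%, depth ≥ 0.2×, score ≥ 0, p ≤ 0.05) are permissive on
purpose — fractional depth is a normal signal for low-abundance taxa
in metagenomes — and are likewise plain arguments.

# The synthetic community generator

The simulator provides the controlled conditions under which the
pipeline's claims are testable: `n` species mutated independently from
one random ancestor (divergence `d_i` gives pairwise identity close to
\(1 - d_i - d_j\)), a star-shaped taxonomy grouping species
round-robin into genera and families beneath a fixed
order/class/phylum/kingdom/superkingdom chain, and Illumina-like reads:
uniform fragment starts on either strand, paired ends with a
normal(500, 50) insert (truncated to at least one read length),
constant-quality FASTQ, and independent per-base substitutions.

The desk-scale default — 20 species × 50 kb, divergence 3–12%,
per-species coverage uniform in 5–15× (≈50,000 read pairs), 2×100 bp,
0.5% error — emulates the *shape* of published fungal-community test
sets (tens of species spanning a wide coverage range, millions of
pairs) at roughly 1/100 scale so that the full pipeline runs in tens
of seconds; coverage can also be pinned per species, e.g. to the
0.001× regime where a species' read count rounds to zero and it must
surface as a false negative.

What the generator does **not** model: indels (the mapper is ungapped
by design, so substitution-only errors keep the simulation aligned
with the method's assumptions), quality-score decay, GC or
amplification bias, chimeras, strain mixtures within a species, and
real taxonomies' irregular depth. Passing tests therefore demonstrate
the correctness of the sorting, filtering, classification and
accounting machinery under the stated error model — not classifier
performance on real libraries against real databases, which depends
overwhelmingly on database completeness and read quality.

Determinism is part of the contract: a seed fixes references, reads
and therefore every downstream byte (`.res` files compare identical
across runs).

# Numerical and design choices

* **k defaults to 16** with an empty index prefix. A two-letter prefix
  (e.g. `"AC"`) keeps ~1/16 of k-mers — on average the density of
  non-overlapping k-mers — trading sensitivity for index size the way
  large-database mappers do; with short prefixes the loss is modest.
  `k` is capped at 31 to keep 2-bit-packed k-mers in one 64-bit word.
* **N bases never match**; k-mers containing them are neither indexed
  nor queried. Reads shorter than `k` are unmapped. Templates shorter
  than `k` are skipped with a warning.
* **Paired ends** are scored per mate and summed per template before
  the ConClave passes, so a pair is assigned as one unit; each mate is
  placed at its own diagonal for consensus building.
* **RPM** uses the reads given to the mapper as its denominator (not
  the post-filter count), so abundances remain comparable across
  filter settings.
* **Names** are taken from `scientific name` rows when loading
  NCBI-dialect name tables; synonyms are ignored. The `q_value` column
  is parsed and written but not used as a filter.
* **Benchmarking** projects both truth and prediction to the evaluated
  rank *by taxid* (names would collide on homonyms); taxa unknown to
  the taxonomy are dropped from the statistics after a warning, and
  taxa with no ancestor at the evaluated rank are dropped from both
  sides. Per-rank predictions honor each classification's assigned
  rank: a genus-level call does not claim a species.

# Problem sizes used in validation

The test suite validates the ConClave pass against an exhaustive
(read × template × diagonal) oracle on 200 random instances of up to 5
templates × 50 reads at k = 8, exercises the shared-segment dominance
fixture over 100 seeded trials against the naive best-hit baseline,
and runs the full pipeline on the 20-species default community
(~50,000 read pairs) — sizes chosen so the complete suite runs in
about a minute while the oracle remains tractable.

# Known limitations

* Ungapped placement: indel-rich divergence degrades scores faster
  than the \((1-d)^k\) substitution model suggests, and identities are
  computed on substitution columns only.
* The p-value is a screening approximation, not a calibrated mapping
  statistic; at large score masses it saturates near 0 for any
  detected template and the coverage/depth filters do the real work.
* The in-memory k-mer index lives in native memory for the session; it
  is rebuilt rather than serialized.
* Abundance accuracy (as opposed to presence/absence) is reported but
  not benchmarked; no correction for genome size or copy number is
  applied.
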