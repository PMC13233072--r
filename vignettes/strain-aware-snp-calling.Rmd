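---
title: "Strain-aware SNP calling from long reads: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-aware SNP calling from long reads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsnp)
```

## The problem

A metagenome usually contains several closely related strains of the same
species at arbitrary, unequal abundances. When long, error-prone reads
(Oxford Nanopore, older PacBio) from such a community are mapped to a
reference or metagenome-assembled genome, true strain variants and
sequencing errors can occur at similar per-column frequencies: a strain at
10% abundance and a 5–10% error rate produce indistinguishable *marginal*
pileup counts. What separates them is correlation across loci: errors are
(approximately) independent across positions, while the variants of one
strain are carried by the same physical reads across an entire window.
Long reads make this signal usable, because a single read spans thousands
of positions.

`strainsnp` implements a windowed multi-locus caller built on that
observation, together with a deterministic multi-strain read simulator so
that every statistical property of the caller can be tested without any
external data.

## From alignments to binary matrices

Only the best alignment of each read is kept (maximal alignment score,
ties broken by lexicographically smallest `(contig, start)`). Each contig
is tiled with fixed, non-overlapping windows of half the median read
length — long enough to cover many loci, short enough that many reads span
a window end to end; the floor is 500 bp and an even-count median is the
mean of the two middle values. Within a window, the reads that span it
completely form a binary matrix \(M\) with \(n\) rows (reads) and one
column per reference position: \(M_{ij} = 1\) when read \(i\) shows the
reference base at position \(j\), and 0 for a substitution or a deletion
mark. Deletions count as coverage but are never emitted as calls (this is
a SNP caller; insertions are ignored entirely). The observed base behind
every cell is retained for allele reporting.

Columns where alternative alleles appear in **strictly more than 5%** of
covering reads are the *candidate loci*; their count is the \(m\) of the
significance bound below. The strict inequality and the per-column
denominator (reads covering the column) are deliberate: at \(n = 100\), a
column needs at least 6 non-reference reads.

Reads that do not span the window still matter twice: groups of at least
five reads sharing **exactly** the same `(start, end)` mapping coordinates
are analysed as their own matrices over their common span (strains with
structural differences produce exactly such groups), and all residual
partial reads contribute to the per-position coverage used by the
binomial test below.

## The error model

The error rate is measured per window as the divergence of the reads to
the reference (non-reference bases over aligned bases) and deliberately
over-estimated three-fold:

\[ s = \min(\max(3 \times \text{divergence}, 0.01), 0.95). \]

The inflation keeps \(s\) above the true local error rate in error-prone
contexts such as homopolymers; every test below treats \(s\) as an upper
bound on the per-base error probability, so over-estimating it only makes
the caller more conservative. Note that the measured divergence includes
true variants, which inflates \(s\) further in highly diverged mixtures —
again a conservative bias. With 31 non-reference bases among 336 aligned,
\(s = 3 \times 31/336 = 0.28\); with divergence 0.05, \(s = 0.15\).

## The multi-locus test

Candidate columns are compared all-against-all with Pearson chi-square
tests (1 d.f., no continuity correction) on the 2×2 table of
reference/alternative states over the reads covering both columns. A pair
with any zero marginal, or fewer than 10 shared reads, gets p = 1: these
p-values serve as a permissive dissimilarity for grouping, not as the
final decision. The columns are then clustered by complete-linkage
agglomeration with the p-value as distance, cutting the tree at 0.05 —
complete linkage guarantees every intra-group pair correlates at
p ≤ 0.05. Groups of one column fall through to the isolated-SNP path.

For a group of \(b\) loci, the *variant pattern* is the set of \(a\) reads
showing a non-reference state at **every** member locus. Under the null
hypothesis that all these cells are independent errors at rate at most
\(s\), any fixed \(a \times b\) submatrix is all-error with probability at
most \(s^{ab}\), and there are \(\binom{n}{a}\binom{m}{b}\) submatrices to
try, so by the union bound

\[ p \le s^{ab} \binom{n}{a} \binom{m}{b}. \]

The null is rejected at \(p \le 0.001\), and each member locus becomes a
`MULTILOCUS` call whose reported alternative allele is the majority
observed base among the pattern's reads (ties alphabetical). The bound is
evaluated in log space through `lchoose`, so no configuration overflows;
for the canonical configuration \(n = 100\), \(m = 500\), \(a = 5\),
\(b = 10\), \(s = 0.15\) the exact value is
\(10^{-12.9281} \approx 1.2 \times 10^{-13}\), which the test suite pins
against an arbitrary-precision oracle to \(10^{-9}\) relative in log
space. An exhaustive enumeration over all error configurations of every
matrix with \(n, m \le 4\) confirms the bound dominates the exact
existence probability for every \((a, b)\).

Two behavioural consequences are worth knowing. First, the chi-square
dissimilarity is two-sided, so perfectly *anti*-correlated columns
(complementary strain partitions with few reference-agreeing reads) can
merge into one group; with a reference-like strain present the
anti-correlation is diluted and this is rare. Second, when strains are
highly diverged, *all* their variant columns in a window correlate and
complete linkage produces one large group; the probability that a read is
non-reference at every one of \(b \approx 100\) loci is small (each locus
reverts to the reference with probability about \(e/3\) under error rate
\(e\)), so \(a\) collapses and the pattern legitimately fails the bound.
Those loci are then recovered by the per-position binomial test below —
the division of labour between the two paths shifts with divergence, and
the tests assert the union of the paths, not the share of each.

## Rescue paths

**Obvious SNPs.** Independently of the matrix machinery, every position of
the window pileup is tested per allele: if one alternative base occurs
\(k\) times among the \(c\) reads covering the position (spanning or
not), and the exact binomial upper tail \(P(X \ge k)\),
\(X \sim \mathrm{Bin}(c, s)\), is strictly below 0.001, the position is an
`OBVIOUS` SNP. Each alternative base is tested on its own count — the
model describes one allele's recurrence, and pooling across alternatives
would conflate multi-allelic noise.

**Correlated-locus rescue.** Every pileup column not yet called —
including those that failed the 5% filter — is chi-square-tested against
each confirmed column of the same matrix; a best p-value strictly below
\(10^{-6}\) yields a `RESCUED` call. The rescue runs before masking within
each round, because masking (next paragraph) erases the confirmed
column's signal.

**Iterative masking.** At multi-allelic sites the dominant alternative
allele shadows the rest: the matrix treats all alternatives as one class,
and the majority rule reports only the most frequent base. After each
round, every called (position, allele) is masked — cells carrying that
base become reference-like in the matrix, and its pileup count moves onto
the reference row — and the whole per-window pipeline re-runs, up to 5
rounds or until a round adds nothing. Masking strictly decreases the
count of non-reference cells whenever calls are emitted, so termination
is structural; a masked (position, allele) can never be re-emitted.
Well-supported secondary alleles are typically caught by the per-allele
binomial test already in round 1; the masking loop matters when the
dominant allele's group has claimed the column and the secondary allele
is below the binomial threshold but shares partner loci.

Calls at the same (position, allele) from different paths keep the
strongest-evidence status, in the order `MULTILOCUS` > `OBVIOUS` >
`RESCUED`.

## The simulator and what a green test establishes

`simulate_haplotypes()` draws a random ancestor over A/C/G/T and mutates
each base independently per strain with the configured divergence
(uniformly to one of the three other bases); strain 1 is the reference,
and the truth set is every (position, alternative base) at which another
strain differs from it. `simulate_reads()` samples fixed-length reads
uniformly along each haplotype to the target per-strain depth and flips
each base with the configured error probability. Because the simulation is
substitution-only, reads align exactly at their true coordinates, so they
are emitted pre-aligned (single match-run CIGARs) and the whole pipeline
is testable hermetically; an optional partial-read mode emits
identical-coordinate read groups to exercise coordinate clustering.

Defaults mirror a routine nanopore metagenome experiment: 10 kb reads,
5% error, 1% strain divergence, 20× per-strain depth. Two deliberate
omissions: no indels (alignment would stop being trivial, and the caller
is SNP-only) and no context-dependent error profile (homopolymer
artefacts, quality strings). A green test therefore establishes the
statistics of the caller under independent errors — the null model the
method itself assumes — not robustness to structured ONT noise. Two
consequences of uniform read sampling on a linear contig are visible in
every evaluation: positions near contig ends are covered by few reads
(no read can start before coordinate 0), and only about half the reads
covering a position span its whole window. Recall therefore dips within
roughly one read length of each contig end.

Scoring is exact-match on (position, alternative base): recall is matched
truth variants over all truth variants, precision is matched calls over
all calls, and an empty call set reports precision 1.0 with an explicit
`precision_defined = FALSE` flag.

## Numerical and design choices

* Chi-square statistics use the closed 2×2 form
  \(N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))\); for the all-pairs step
  this collapses to two rank-1 products
  (\(ad-bc = n\,n_{00} - c_u c_v\), denominator
  \(c_u(n-c_u)\,c_v(n-c_v)\)). Tail probabilities are evaluated only for
  pairs at or below the clustering cutoff; any larger value is
  interchangeable with 1.0 for a tree cut at that cutoff, so the
  partition is provably unchanged.
* The binomial tail is `pbinom(k-1, c, s, lower.tail = FALSE)`, exact via
  the regularised incomplete beta function; the suite verifies agreement
  with direct log-space pmf summation to \(10^{-12}\) for all
  \(c \le 200\).
* Thresholds follow their definitions exactly: the union bound rejects at
  \(p \le 0.001\), the binomial and rescue tests at strict
  \(p < 0.001\) and \(p < 10^{-6}\) respectively, and the candidate
  filter at strictly more than 5%.
* Agglomeration ties are resolved deterministically (fixed input order,
  groups sorted by lowest member index); the whole pipeline is
  deterministic for identical inputs, and windows are independent work
  units processed in genomic order.
* Degenerate inputs: an empty window yields an empty matrix and is
  skipped by the matrix path (the pileup scan still runs); a window with
  zero aligned bases yields no error model and no calls; an empty BAM
  produces zero windows and a warning.
* Coordinates are 0-based half-open internally and 1-based in VCF;
  co-located alternative alleles merge into one VCF record with
  comma-separated ALT in alphabetical order and per-allele INFO fields
  (`DP`, `SR`, `LP`, `ST`, `IT`).

## Known limitations

* **Low-coverage strains.** A strain at 5× contributes on average only
  ~2.5 rows to a window's spanning matrix (about half its reads span any
  given window). With 5% error the candidate filter also admits many
  error columns at typical \(n\), inflating \(m\); the bound
  \(s^{ab}\binom{n}{a}\binom{m}{b} \le 0.001\) then needs more supporting
  reads than such a strain can supply, and its private variants are
  recovered only in the minority of windows where a pattern happens to
  confirm (measured ~10% private-SNP recall at 5× in a four-strain, 5%
  error mixture — reported honestly by the corresponding red acceptance
  test). Deeper sequencing, lower error rates or longer reads all lift
  this directly.
* Calls are site-level: no genotype likelihoods, no strain haplotyping or
  phasing, no indels.
* The per-window error estimate conflates divergence with error, so
  highly diverged mixtures run with a more conservative \(s\) than
  necessary.

```{r example, eval = FALSE}
tr <- simulate_haplotypes(50000, strain_count = 2, divergence = 0.01, seed = 1)
reads <- simulate_reads(tr, coverages = c(20, 20), read_length = 10000,
                        error_rate = 0.05, seed = 2)
paths <- write_sim_bam(reads, tr, tempfile("demo"), "demo")
res <- snp_call(paths[["bam"]], paths[["fasta"]])
glance(res)
evaluate_calls(res, tr)
autoplot(res)
```
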