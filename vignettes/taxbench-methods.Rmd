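---
title: "Benchmarking metagenome classifiers with simulated communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking metagenome classifiers with simulated communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxbench)
library(dplyr)
```

## The problem

Shotgun metagenome classifiers disagree wildly about which species are in a
sample, especially for the rare non-bacterial fraction — the viruses and
eukaryotes of a fecal metagenome that may matter most clinically. Judging a
classifier needs a sample whose composition is known exactly. taxbench builds
such samples and the machinery around them: a per-read community simulator
with truth labels, an NCBI-style taxonomy with lowest-common-ancestor (LCA)
resolution, an ordered sequential-classification harness, and a species-set
evaluation layer (recall, precision, detection probability, depth trends).

Everything runs self-contained: a toy taxonomy and toy genome generator stand
in for a reference database, and a built-in exact k-mer classifier stands in
for the external programs, so full pipelines execute in tests without
downloads or third-party binaries. External classifiers plug in through two
adapter formats — 12-column BLAST tabular (b6) alignments post-processed by
`lca_count()`, and per-read assignment tables (`read_assignment_table()`,
taxid 0 = unclassified).

## The community model

Observed fecal rank-abundance data is well described by a power-law decay of
relative abundance with species rank,

$$a(r) = (s \cdot r)^{-e}, \qquad s = 1.5,\; e = 2,$$

so the most abundant species takes $4/9$ of its group and abundance falls
four-fold with every doubling of rank. `build_profile()` applies this decay
*within* each taxonomic group — ranks restart at 1 for bacteria, viruses and
eukaryotes — normalising each group to its weight so the full profile sums
to one:

```{r profile}
toy <- make_toy_taxonomy(300, 100, 100, seed = 1)
profile <- build_profile(split(toy$groups$taxid, toy$groups$group))
profile |> group_by(group) |> summarise(species = n(), weight = sum(expected_abundance))
```

The default group weights 0.97 / 0.02 / 0.01 (bacteria / viruses /
eukaryotes) encode a bacteria-dominant gut community in which non-bacterial
reads are a small minority; no published per-group read fractions exist for
this design, so the weights are an explicit, configurable parameter rather
than a fitted quantity.

`fit_decay_model()` inverts the model: ordinary least squares of
log-abundance on log-rank, so the slope estimates $-e$ and the intercept
$-e\log s$. $R^2$ is reported **in log–log space**; that convention is
declared rather than inferred, because a least-squares power-law fit is only
linear (and its $R^2$ unambiguous) on that scale. Fitting a *normalised*
profile shifts the intercept by the normalisation constant: the exponent and
the curve shape return exactly, while the reported scale absorbs the
constant (`scale_hat = s · C^{-1/e}`). The fit therefore recovers $(s, e)$
exactly only from unnormalised decay data.

## The read simulator

`simulate_reads()` works **per read**: species from the profile by exact
multinomial sampling, source contig within the species proportional to
contig length, start uniform over valid positions, strand uniform,
then i.i.d. per-base substitutions. Choices worth knowing:

* **Error model** — flat substitution rate, default 0.0024/base (a published
  Illumina estimate), substituted base uniform over the three alternatives;
  no indels. The classifiers this toolkit benchmarks are
  substitution-tolerant, and an indel model would add parameters with no
  counterpart in the evaluation.
* **Coordinates** — truth records 0-based half-open `[start, start + L)` on
  the forward strand, with strand stored separately; minus-strand reads are
  the reverse complement of that window.
* **Stochastic targets** — because sampling is per read, the realized number
  of distinct species per group is random. `realized_deviation()` reports
  `|realized − target| / target` against the conventional ±10% simulation
  tolerance. At 10 M reads the tolerance holds comfortably; at a scaled-down
  1 M reads the rarest eukaryotes expect under one read each
  (rank-100 eukaryote: $0.01 \cdot a(100)/\sum a \approx 6\times10^{-7}$,
  i.e. ~0.6 reads), so the eukaryote species count realizes around 85/100
  and the ±10% band is not attainable for that group at that depth — a
  property of the sampling model, visible in the package's own checks.
* **Quality strings** — FASTQ output carries a constant
  $Q = \mathrm{round}(-10\log_{10} \mathrm{rate})$; the benchmarked tools
  ignore quality.
* Contigs shorter than the read length are excluded from sampling with a
  warning; read headers encode `read_id|taxid|group` so truth survives
  round-trips through plain FASTA.

The toy genomes are i.i.d. uniform sequences with per-group lengths 20 kb
(virus), 200 kb (bacteria), 2 Mb (eukaryote) — the real three-orders size
asymmetry, scaled down. Uniform sequences have no repeats, no GC skew, no
shared evolutionary history: classification on them is *easier* than on real
genomes, so passing tests demonstrate the machinery's correctness, not
real-world classifier accuracy. `inject_shared_segment()` restores the one
confound this study design needs — bacterial sequence embedded in a
eukaryote assembly, the documented cause of cross-group misclassification.

## LCA counting and the built-in classifier

`lca_count()` reproduces the post-processing an all-hits aligner needs to
become a classifier: per read, keep hits within `top_margin` (default 1%,
configurable — tie windows differ between tools) of the best bit score and
assign the LCA of their taxids. Species-level counts project every
assignment to species rank; an assignment that resolves *above* species
(e.g. a genus-level LCA of sibling species) projects to the "unranked"
sentinel and counts as unclassified at species level — the same treatment
that species-level benchmarks apply to programs reporting correct genera but
unclassified species.

The built-in classifier (`build_kmer_index()` / `classify_kmer()`) is an
exact canonical k-mer voter: all matching k-mers vote for the species
containing them, the top-voted species wins, vote ties resolve to the LCA of
the tied species, and reads with fewer than `min_hits` matching k-mers stay
unclassified. Default $k = 31$ (odd to make canonical forms unique, capped
at 31 so a k-mer packs into a 64-bit word; the index is an open-addressing
hash table in C++). It is a deliberately simple test double standing behind
the classifier contract — not a reimplementation of any production tool.

## Ordered sequential classification

`order_recipe()` fixes the seven canonical orders: labels `a`–`f` are the
six permutations of virus/bacteria/eukaryote applied sequentially with reads
classified at earlier steps removed (`extract_unclassified()`), and `g` is
unordered (each group classifies the full read set). The step log records
input/classified/carried-forward counts, which must reconcile exactly: in an
ordered run no read can be claimed by two groups, while in unordered mode
multiple claims are permitted — that is precisely the mechanism by which
embedded bacterial sequence inflates eukaryote false positives, and why
bacteria-first orders improve eukaryote precision.

## Evaluation

Recall = correctly identified species / expected species; precision =
correctly identified species / all species reported. Both operate on
species *sets*, with `min_count` as the practitioner's low-abundance filter
(e.g. the conventional cut-off of 100 reads). Precision with an empty
reported set is **missing, not zero**, so replicate means are not dragged
down by degenerate steps.

Detection probability bins every (replicate × expected species) instance by
the species' profile abundance and reports the detected fraction per bin.
Two conventions are deliberate:

* The six default bins use boundaries 0.01, 0.002, 4×10⁻⁴, 10⁻⁴, 5×10⁻⁵.
  Published bin ladders of this shape contain typographical inconsistencies
  (a bin printed as "0.02–4×10⁻⁴" beside "0.01–0.002", and a gap between
  5×10⁻⁵ and a "<10⁻⁵" floor); the bins here are the contiguous tiling
  consistent with those boundaries, with the final bin "< 5×10⁻⁵".
* Replicates are **pooled** (instances summed across replicates) by default;
  `per_replicate = TRUE` gives per-replicate probabilities instead. Pooling
  keeps sparse high-abundance bins (≈5 species per simulation) estimable.
* What counts as "expected" is the caller's choice of input: passing each
  replicate's *sampled* species asks "of the species that made it into the
  reads, how many did the classifier recover", while passing the *community*
  (profile) species additionally charges the sampling floor — a species
  expecting under one read at a given depth is undetectable regardless of
  classifier. The depth analyses here use the community convention.

`depth_trend()` regresses a metric on $\log_{10}(\text{depth})$ — depth
series span 0.1–50 M reads, so the log scale is the natural covariate — and
returns the OLS slope, $R^2$ and slope t-test p-value; a constant series is
reported as slope 0, $R^2$ 0. Cross-program ANOVA is out of scope;
`summarise_eval()` produces the mean ± SD tables used to compare conditions.

## Problem sizes used in the test suite

The package's own checks run at sizes chosen to exercise every code path at
desk scale: the simulator-fidelity replicate uses the full
(300, 100, 100)-species community at 1 M reads with default genome lengths;
the ordered-analysis experiment uses 20 k reads over a 12/4/4-species
community with a 5 kb injected segment, five seeds; the detection-probability
ladder uses depths 10⁵ and 10⁶ over the 500-species community with reduced
genome lengths (20 kb / 5 kb / 50 kb for bacteria / viruses / eukaryotes),
five seeds. Oracle tests (LCA, lineage, counting) run against brute-force
reimplementations on random 200-node trees.

## Limitations

* Single-end reads only; no paired-end simulation, no platform quality
  profiles, no indels.
* The toy genomes share no homology beyond what is injected; real databases
  produce k-mer collisions, chimeric assignments and database-incompleteness
  effects that no test here measures.
* The built-in classifier is exact-match: its accuracy numbers say nothing
  about production classifiers; it exists so pipeline logic is testable.
* Merged/deleted taxid remapping (merged.dmp) is unsupported: unknown taxids
  are hard errors, because in a fully simulated benchmark a silent remap
  would mask bugs.
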