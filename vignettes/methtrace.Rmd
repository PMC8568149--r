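---
title: "Working with long-read methylation calls in methtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with long-read methylation calls in methtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtrace)
library(data.table)
```

## The problem

Nanopore sequencers read native DNA, so a methylation caller (nanopolish,
f5c, Megalodon) can assign every CpG on every read a log-likelihood ratio
(LLR) of 5-methylcytosine versus unmethylated cytosine. A single PromethION
flow cell yields hundreds of millions of such calls — too many to hold in
memory on a laptop, and too many to smooth naively when plotting a gene. At
the same time the per-read resolution is precisely what makes long reads
valuable: it lets you see haplotype-specific methylation, imprinting, and
X-inactivation on single molecules.

methtrace addresses the plumbing between callers and analysis: it normalises
the caller dialects into one minimal record, stores records in a
position-indexed compressed file that supports region queries without loading
the dataset, summarises calls into the count matrices that
differential-methylation tools consume, and computes the sample embeddings,
aggregate profiles and per-read views used to explore the data.

## The intermediate record and the sigmoid transform

Every call becomes one record: `(sample_id, chromosome, position, statistic,
read_id)`, with `position` the 1-based coordinate of the CpG cytosine and
`statistic` a natural-log likelihood ratio (positive favours methylation).
The nanopolish statistic is used as-is; Megalodon reports log-probabilities
for the modified and canonical base and the record statistic is their
difference, so in both cases the methylation probability is recovered by the
sigmoid transform

$$p = \frac{1}{1 + e^{-\mathrm{LLR}}}.$$

nanopolish groups CpGs closer than its window into one call covering
`num_motifs` sites with a single shared LLR. `split_grouped_call()` places
each motif at its own nucleotide using the CG offsets of the reported
sequence context; every motif inherits the group LLR unchanged. We considered
dividing the LLR among the motifs, but an LLR is not additive across sites in
any principled way, and keeping it unchanged preserves the caller's
per-call evidence; the choice is visible and documented rather than silently
baked in.

Coordinate conventions are a permanent source of off-by-one bugs, so they
are fixed once: caller output positions are 0-based and gain `+1` on import;
store queries and feature tables are 1-based, fully closed. Minus-strand
Megalodon calls are left where the caller put them by default; an optional
`collapse_strand` shifts them 1 bp to the forward-strand cytosine so both
strands of a CpG stack.

```{r ingest-example}
f <- tempfile()
writeLines(c(
  paste(c("chromosome", "strand", "start", "end", "read_name",
          "log_lik_ratio", "log_lik_methylated", "log_lik_unmethylated",
          "num_calling_strands", "num_motifs", "sequence"), collapse = "\t"),
  "chr1\t+\t1000\t1005\tread1\t3.1\t3.1\t0\t1\t2\tAACGTACGTA"), f)
parse_nanopolish(f, sample_id = "sampleA")
```

Parsing is streaming: files are read in blocks (default 50,000 lines) and a
callback can consume each block, so conversion memory is bounded by the
block size, not the file. Malformed lines — real caller output is routinely
truncated mid-write — are skipped and counted by default; `strict = TRUE`
turns them into errors with line numbers.

## The store

Records are persisted as a 5-column TSV, sorted by chromosome then position,
bgzip-compressed and tabix-indexed (sequence column 2, begin/end column 3,
1-based). bgzip compresses in independently decompressible blocks and tabix
maps genomic ranges to blocks, so `query_region()` touches only the blocks
that overlap the query. Sorting uses an external merge: blocks of at most
`chunk_size` rows (default $10^6$) are sorted in memory, spilled to disk,
and k-way merged under a per-file row budget, so arbitrarily large inputs
sort in bounded memory.

Three deliberate conventions:

* **Chromosome collation is plain byte order** (`chr10 < chr2`). tabix only
  requires that chromosomes be grouped; byte order is locale-independent and
  reproducible. All comparisons during the merge are pinned to the C locale
  for the same reason.
* **Statistics are serialised at 6 significant digits** — compact, and far
  below the noise floor of any caller's LLR.
* **The sample sheet is a sidecar file** (`<store>.samples.tsv`, columns
  `sample_id`, `group`); the indexed data file itself stays minimal.

The store is ordinary bgzip/tabix output (written via Rsamtools, i.e.
htslib): the command-line `tabix` queries it directly, which the test suite
verifies.

## Count matrices and the log-methylation-ratio

Downstream differential-methylation tools want per-site counts, not
per-read LLRs. `count_sites()` calls a record methylated if
`statistic > t`, unmethylated if `statistic < -t`, and discards it when
`|statistic| <= t`. The default `t = 0` is the minimal-assumption rule —
the sign of the evidence; `t = 2` reproduces the common nanopolish practice
of dropping ambiguous calls. Exact zeros are always discarded: they carry no
direction.

`write_dmr_tables()` emits the three standard layouts (bsseq-style
coverage/methylation matrices, DSS-style per-sample `(chr, pos, N, X)`
files, edgeR-style paired `Me_*`/`Un_*` columns), and `read_dss_tables()`
inverts the DSS layout exactly.

For sample-level embeddings the counts are converted to moderated log
ratios

$$\mathrm{LMR}_{ij} = \log_2 \frac{\mathrm{Me}_{ij} + c}{\mathrm{Un}_{ij} + c},$$

with prior count $c = 2$ by default, following the edgeR workflow convention
for log-ratios of small counts. Sites with zero total coverage are dropped
by default (`min_coverage = 1`): their rows are pure pseudocount and only
dilute variance-based site selection.

## Embeddings

`mds_embedding()` uses the root-mean-square difference of log ratios over
the retained sites as the pairwise sample distance and embeds with classical
(Torgerson) scaling; `pca_embedding()` runs site-centred PCA via SVD and
reports variance-explained fractions. Site selection
(`select_top_variable_sites()`, default `k = 500`) is *common* — one set of
most-variable sites shared by all pairs — rather than per-pair, which keeps
the distance matrix a true configuration of one fixed feature space and
makes results deterministic. Each dimension's sign is fixed so its
largest-magnitude coordinate is positive; embeddings are therefore
byte-reproducible across runs and machines.

## Profiles: per-site means, relative axes, binned means, lowess

Smoothing millions of raw calls is infeasible and unnecessary. The plotting
stack always reduces first:

1. **Per-site means.** For each site and group, the unweighted mean of the
   per-read probabilities. Note the mean *confounds biological and technical
   noise*: two reads confidently called 0.99 and 0.01 average to 0.5 exactly
   like two ambiguous 0.5 calls. The per-read spaghetti and heatmap views
   exist precisely to let you tell these cases apart by eye; no
   de-confounding statistic is attempted.
2. **Relative coordinates.** For aggregate profiles each feature body maps
   linearly to $[0, 1]$ and fixed-width flanks (default 2000 bp) map to
   $[-f, 0)$ and $(1, 1+f]$ with display fraction $f = 1/3$ — flanks occupy
   the same axis width for every feature regardless of its length.
   Minus-strand features are mirrored so 0 is always the 5' end. Both
   $f$ and the flank width are arguments, since the right display ratio is a
   judgement call.
3. **Binned means** (default 100 bins) equalise point density along the
   relative axis. Feature bodies are far denser in CpGs than flanks; a local
   smoother fed raw points would draw most of its neighbourhood from the
   body at every boundary. Empty bins are omitted, never interpolated — no
   signal is invented in sparse flanks.
4. **The aggregate is a two-stage average**: binned means within each
   feature, then an unweighted mean across features per bin. Every feature
   gets equal weight, so a single deeply covered gene cannot dominate the
   class profile. (The test suite verifies that duplicating all reads of one
   feature leaves the aggregate unchanged to $10^{-12}$, while a pooled
   read-weighted mean moves.)
5. **Smoothing** is degree-1 lowess with a tricube kernel and no robustness
   iterations, clamped to $[0, 1]$; spans default to 0.2 for region trends
   and 0.3 for aggregates — chosen by eye, exposed as arguments. Inputs
   with fewer than 5 points pass through unsmoothed and flagged: a local
   line through 3 points is noise. Per-read spaghetti lines are smoothed
   independently per read under the same rule.

Region box plots (`region_summary()`) pool per-site means by region class
(e.g. promoter vs non-promoter); regions of one class must not overlap so
no site is double-counted, and sites outside every region contribute only
when an explicit complement class is requested.

## Figures

`plot_spaghetti()` layers thin per-read smoothed lines, a thick per-group
trend, a tick mark at every called site, merged exon boxes below the axis,
and light-grey shading over the `top_n` (default 500) highest-ranked DMRs
from a user-supplied table. `plot_heatmap()` shows unsmoothed per-call
probabilities, one row per read, with reads packed into lanes by greedy
first-fit in start order — optimal on interval graphs, so the panel height
equals the maximum read overlap depth. Heatmap cells default to a fixed
fraction of the window width (bp-proportional cells vanish at typical CpG
spacing); pass `cell_width` for bp-proportional tiles. Groups with no data
in a window are dropped with a warning rather than an error. All figure
functions return ggplot objects.

## The synthetic-data generator

`methyl_landscape()` + `simulate_reads()` exist so that every operation is
testable against known truth with no downloads. The generator emulates the
statistical structure the visualisations assume:

* CpG sites at regular spacing (default 100 bp);
* a per-group methylation surface: a background level plus interval
  overrides (TSS-like dips, group-specific DMRs);
* reads with lognormal lengths (median 3000 bp, sdlog 0.35) placed
  uniformly, at a configurable mean coverage;
* one Bernoulli state per (read, site) — molecule-consistent, so per-read
  spaghetti lines are meaningful — and an emitted LLR drawn from
  $N(+m, s)$ for methylated and $N(-m, s)$ for unmethylated states, with
  defaults $m = 4$, $s = 1.5$: most calls confident, a realistic tail near
  $p = 0.5$;
* a configurable fraction of nanopolish-dialect calls grouped over two
  adjacent CpGs, with sequence contexts whose CG offsets match the genomic
  spacing.

It writes both caller dialects plus a truth table, byte-identically for a
given seed. What it does **not** emulate: sequence content and basecalling
error, CpG-density heterogeneity (real islands), correlated methylation
along molecules beyond the per-site state, strand asymmetry, or
coverage biases. Passing tests therefore demonstrate the correctness of the
data path and the statistics on their stated model — not caller accuracy on
real flow cells.

Default test problem sizes were chosen as the smallest that exercise the
machinery honestly: stores of $10^5$ records for query/oracle equivalence,
coverage 50 with a 0.4 methylation difference for the two-group embedding
study (3 + 3 samples, 100 seeded replicates), and coverage 50 over a
500-site truth surface for end-to-end recovery, where estimated per-site
methylation fractions correlate with truth at $r > 0.95$.

## Numerical and degenerate-input choices

* `sigmoid()`/`logit()` delegate to `plogis()`/`qlogis()` — exact in the
  tails where `1/(1+exp(-x))` overflows.
* Binned means use half-open bins with the last bin closed, so the domain
  endpoints are never dropped; ties at bin edges go right.
* `count_sites()` on an empty or fully-discarded input returns a 0-site
  matrix, not an error; queries on chromosomes absent from the index return
  empty results with a warning.
* An all-identical-sample matrix embeds to all-zero coordinates with a
  `degenerate` flag rather than erroring inside the eigensolver.
* Lane packing breaks start ties by read id, so plots are deterministic
  under input reordering.

## Limitations

methtrace does not call methylation, align reads, or test for differential
methylation — it feeds and visualises the tools that do. Per-read views
confound low caller confidence with genuine cell-to-cell heterogeneity, as
discussed above. The store is rebuild-only (no incremental updates), and
figures are static.
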