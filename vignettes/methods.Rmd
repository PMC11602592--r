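---
title: "Models and methods behind spliceshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spliceshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spliceshift analyses interferon-style stimulation experiments at the
transcript-isoform level: which isoforms of a gene are used, how usage
shifts after stimulation, and what those shifts do to the encoded
protein. This vignette explains the models, the parameters that matter,
and the design choices behind the implementation; it is the package's
reference for *why* things are computed the way they are. Nothing here
states a number that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinates and data model

All internal coordinates are 0-based, half-open intervals; GTF input and
output use the external 1-based closed convention and are converted at
the boundary. A transcript is an ordered exon chain on one chromosome
and strand (`transcript_model()`); its splice junctions are the gaps
between consecutive exons, stored genomically. The 5'/3' roles of a
junction's two ends depend on the strand, so donor/acceptor semantics
live in accessors (`junction_donor_sites()`), not in storage — a single
convention that confines strand bugs to a handful of functions.

## Structural classification

A query isoform is compared against a reference annotation within the
gene of maximal same-strand exonic overlap:

* **FSM** — the query's junction chain equals a reference chain;
* **ISM** — the chain is a *consecutive* sub-chain of a reference chain
  (an arbitrary subset is not an ISM: dropping an internal junction
  changes the transcript structure rather than truncating it, and such
  chains fall through to NIC);
* **NNC** — at least one donor or acceptor coordinate is unknown to the
  gene;
* **NIC** — all sites are known but the chain is new.

Mono-exonic queries are FSM when a mono-exonic reference contains them
with 50 nt of slack at each end, and `other` otherwise; `other` also
absorbs antisense/intergenic queries, which downstream stages never
consume. FSM matching is exact on coordinates — no fuzz is applied at
internal junctions because no tolerance is defined for one, and the
synthetic data plant exact matches.

Two quality filters mirror long-read curation practice:

* **Intra-priming** — an isoform is dropped when the 20 nt genomic
  window immediately downstream of its 3' end (read in the transcript
  sense) is ≥ 60% adenine, the signature of oligo-dT mispriming on
  A-rich genomic stretches. The 60% threshold is the filter's defining
  constant; the 20 nt window is the established convention and is
  configurable.
* **Junction support** — a novel, non-canonical junction (terminal
  dinucleotides outside GT..AG / GC..AG / AT..AC) must be supported by
  ≥ 3 uniquely mapped short reads in at least one sample. Novel
  *canonical* junctions are deliberately not support-filtered.
  Isoforms whose chain fully matches the reference (FSM) are always
  retained — the rescue rule — but the report records when the support
  rule would have removed them (`rescue_applied`). For FSM isoforms the
  would-be-removal condition is evaluated on any non-canonical
  unsupported junction, annotated or not, because an FSM by definition
  contains no novel junction; this is the only reading under which a
  rescue can ever trigger, and it matches the curation intent of
  retaining reference-matching isoforms regardless of short-read
  evidence.

## AS-event typing

Events between two isoforms of a gene are typed pairwise on genomic
coordinates: intron retention (an exon of one isoform contains an
intron of the other with ≥ 1 exonic bp on both flanks — the flank
requirement separates retention from alternative ends), exon skipping
(an intron contains ≥ 1 internal exon of the partner; one event per
skipped exon, the finest unit that makes event counts well defined),
alternative donor/acceptor (junction pairs sharing one site), and
alternative start/end (strand-resolved ends differing by ≥ 50 nt;
smaller differences are treated as collapse jitter). A junction pair
consumed by IR or ES is not re-reported as an alternative site
(precedence IR > ES > A5/A3). Mutually exclusive exons are not a
distinct type; they surface as two ES events.

## Isoform fractions and the switch test

The isoform fraction IF is an isoform's count divided by its gene's
total count in a sample; dIF is the difference of mean IFs between two
conditions, and the per-gene dIFs sum to zero whenever all isoforms are
kept. Significance is assessed per isoform by a Welch t test on
logit-transformed per-replicate fractions, `logit(x) = log((x + 0.01) /
(1 - x + 0.01))`, with BH correction across all tested isoforms; an
isoform switches when |dIF| > 0.05 and q < 0.05. The logit-Welch test
is a deliberate stand-in for a full GLM of isoform usage: it is
deterministic, has no convergence failures on small simplex-valued
data, and its type-I error on the null simulation is checked directly
by the test suite (nominal 0.05, accepted band 0.03–0.07). The test
function is isolated so a beta-binomial likelihood-ratio test can be
slotted in without touching the interface. dIF is reported as the
difference of mean IFs rather than a model-fitted effect — the
descriptive quantity stays interpretable whatever the test behind the
p value.

Expression inclusion uses gene TPM > 0.1, with an isoform prefilter of
TPM > 0.1 in at least 10% of samples.

## Consequences: ORF, NMD, 3'UTR, domains

Coding potential is approximated by the longest ATG-initiated ORF
(ties to the most 5' start; minimum 30 nt): a transparent, deterministic
stand-in for dedicated coding-potential predictors, adequate for
synthetic data whose ORFs are planted unambiguously. NMD sensitivity
follows the canonical 50-nt rule — a stop codon more than 50 nt
(strictly) upstream of the last exon–exon junction recruits decay.
3'UTR changes below 50 nt are not reported, again to ignore collapse
jitter. Domain gain/loss compares copy counts by domain name between
the up- and down-switching isoform.

## Domain-loss attribution

Within a gene, every ordered isoform pair is compared: a domain copy
present in the bearer but missing from the loser is one loss event,
with multi-copy domains matched greedily by genomic overlap (ties to
the leftmost copy). A loss is attributed to the AS event types whose
spans overlap the lost region by ≥ 1 bp. The lost region is the
*genomic hull* of the lost copy's mapped intervals: a domain that
straddles a spliced-out intron maps, in the bearer, to two exon pieces
that merely flank the intron, so a piece-wise overlap test could never
attribute an intron-retention loss — the hull, which contains the
excised intron, can. For single-interval domains the hull and the
pieces coincide, so nothing changes for ES/A5/A3/end-driven losses.
Losses attributed to both IR and a non-IR type count once in the IR row
of the 2×2 contrast (IR vs non-IR × loser dIF increased vs decreased),
which is tested with the uncorrected Pearson chi-square; no continuity
correction is applied because the classical statistic is what the
hand-checkable oracle computes. Losses whose loser sits inside the dIF
band, and unattributed losses, are excluded from the table.

## Aggregated IR dynamics

Counts of IR-labeled isoforms (those retaining at least one companion
intron) are aggregated per gene; the IR fraction and its complement sum
to one wherever the gene is expressed. Differential IR usage reuses the
logit-Welch engine on the two-feature aggregate, after filters
translated from common DTU practice: gene count ≥ 10 in ≥ 3 samples and
an IR proportion > 0.01 in at least one sample. Gene-set contrasts
(stimulated gene sets vs housekeeping controls) use the one-sided
rank-sum test on aggregated dIFs; gene sets are user-supplied lists,
none are bundled.

Splicing-factor screening correlates factor expression with IR-isoform
expression across samples (Spearman, on log2(CPM+1) — a simple
variance-stabilizing stand-in chosen over a model-based transform to
keep the pipeline dependency-light and deterministic). Pairs with rho ≤
−0.9 are flagged; factors that themselves carry IR isoforms are
excluded, since self-correlation would be circular. The 0.9 threshold
is configurable — reported strong-correlation cutoffs in this
literature hover there, but the sign and magnitude semantics are the
meaningful contract.

## Motif-density binning

Motifs are IUPAC consensus strings scanned exactly (all overlapping
matches, sense strand only, `N` in the sequence never matches).
Regions — exons and introns pooled over a gene's isoforms,
deduplicated — are classed by IR involvement: an intron equal to a
retained-intron span is an IR intron, and the exons immediately
flanking it in the spliced isoform are IR exons (the mechanistically
relevant neighbours; "IR exon" has no standard definition). Each region
is divided into 10 equal-width bins (last bin absorbs the remainder), a
match counts in the bin holding its start (unambiguous for matches
straddling boundaries), and densities are sites per bp, ordered 5' to
3'. Per bin, a one-sided rank-sum test compares the two classes, with
BH across the 10 bins of one motif — the smallest coherent correction
family. Consensus scanning rather than weighted-matrix scoring is a
deliberate scope decision: the analysis contribution is the binning and
per-bin testing, not the motif model, and motif definitions are inputs.

## The synthetic generator

The generator is first-class, tested code: it produces an annotation,
genome, counts, junction support, domains, motifs and factor expression
with planted ground truth, so that every analysis stage closes the loop
against known answers. Its defaults encode the study conditions the
analyses assume:

* 200 genes, each with a 6–9 exon backbone, exons of 90–250 bp and
  introns of 150–400 bp; one reference transcript per gene; query
  isoforms built *by rule* to realise each structural category (FSM
  copy; ISM dropping the 5'-most exon; NIC skipping internal exon 4;
  NNC shifting one donor 6 nt; IR merging intron 2 into its flanking
  exons).
* A 0/24/72 h time course with 4 replicates per condition and a library
  of 3×10^5 reads per sample. Isoform counts are
  Dirichlet-multinomial around the planted condition fractions with
  concentration 100 — fraction noise of roughly ±0.05 per sample at
  typical gene depths, which is what the calibration and recovery
  checks exercise.
* 30% of genes carry a planted switch with |dIF| drawn from
  [0.2, 0.35]; 30% carry an IR isoform whose aggregated fraction
  follows 0.19 / 0.27 / 0.34 over the time course (the package's
  model of a strongly IR-regulated stimulated gene), flat for
  housekeeping-like genes, reversed for a decreasing minority
  (proportions 0.6 / 0.3 / 0.1).
* Domains are planted so losses are attributable by construction: a
  60 nt domain straddling the retained intron's junction in every
  spliced isoform (lost by the IR isoform, hull covering the intron)
  and a domain inside the skipped exon (lost by the NIC isoform).
* Motif occurrences are written into the genome at 0.02 sites/bp in IR
  introns versus 0.01 in other introns (ratio 2), and 0.005 versus
  0.01 in IR versus non-IR exons — SRSF-like motifs depleted in exons
  flanking retained introns and enriched in the introns themselves.
* Splicing-factor expression is generated by a Gaussian copula against
  the IR isoform's log2(CPM+1) profile with rank correlation −0.95,
  using the normal-score correlation `2·sin(π·rho/6)` and an exact
  sample-correlation construction so the planted value is what a
  screen at n = 12 samples actually sees; independent null factors
  accompany them.
* Junction support is Poisson with mean 30 unique reads, with planted
  exceptions forced below 3 in every sample: the non-canonical NNC
  junctions of a configurable gene subset (removed by the filter) and
  one reference junction in "rescue" genes, written non-canonical so
  the FSM rescue path is exercised.

Everything is seeded; identical configuration and seed give
byte-identical fixture files. What the generator does *not* emulate:
read-level noise (no alignment or coverage model — counts are drawn
directly), genomic sequence composition (uniform random background),
overlapping genes, and isoform structures more complex than one planted
deviation per category. Passing the closed-loop tests therefore
demonstrates the correctness and calibration of the analysis logic
under the stated statistical model, not performance on real long-read
data.

## Problem sizes used by the checks

The test suite and acceptance script choose problem sizes that make the
statistical checks well-powered while staying desk-scale: 10,000 random
queries for the classification oracle; a 500-gene / 2,000-isoform null
at n = 5/group for calibration; 200 planted switch genes at n =
10/group for recovery; 100 seeded 40-gene replicates for the IR
domain-loss contrast; 600 genes for the IR time-course and gene-set
checks (≥ 150 genes per set); and 220 mostly-IR genes for the motif
contrast (≥ 200 regions per class). Each size is stated where it is
used.

## Known limitations

* The switch and IR-usage tests are per-isoform/per-gene Welch tests,
  not a joint usage model; strong count correlation between isoforms of
  one gene is handled only through the fraction transform.
* The longest-ORF rule can miss genuine short upstream ORFs and never
  models non-AUG initiation.
* Attribution by genomic-hull overlap can, in principle, attribute a
  loss to an event that overlaps the hull but not the encoded pieces;
  with one planted deviation per isoform this cannot occur in the
  generator, and the closed-loop accuracy check would surface it.
* Event typing assumes collapsed, full-length isoform models; it does
  not estimate PSI from reads and has no concept of partial intron
  retention.
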