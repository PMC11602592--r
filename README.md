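# spliceshift

Isoform-level analysis of stimulated transcriptomes in R: what happens
to a gene's *isoform usage* — not just its expression — when cells
respond to a stimulus such as type I interferon, and what those usage
shifts do to the encoded proteins.

Stimulation experiments are usually read gene by gene, but much of the
response plays out between isoforms of the same gene: a full-length
isoform declining while an intron-retaining isoform rises leaves the
gene's expression flat and its protein output crippled. spliceshift is
for transcriptomicists who have transcript models (long-read or
assembled), an isoform-level count matrix over conditions or a time
course, and want the complete chain of analysis from isoform curation
to mechanistic readouts.

## What it computes

* **Structural classification** of query isoforms against a reference
  annotation into FSM / ISM / NIC / NNC (full / incomplete splice
  match, novel in/not-in catalog) by comparing splice-junction chains,
  with intra-priming (≥ 60% downstream adenine) and junction-support
  (≥ 3 unique reads for novel non-canonical junctions) filters and an
  FSM rescue rule.
* **Isoform switching.** With isoform fraction IF = isoform count /
  gene total, the switch statistic is dIF = mean IF(stimulated) − mean
  IF(reference); significance comes from a Welch t test on
  logit-transformed per-replicate fractions with Benjamini–Hochberg
  correction (significant: |dIF| > 0.05, FDR < 0.05).
* **AS-event typing** between isoform pairs: exon skipping (ES),
  alternative donor/acceptor (A5/A3), intron retention (IR),
  alternative start/end (aTSS/aTTS), plus gain/loss enrichment across
  switching pairs (exact binomial vs 0.5).
* **Functional consequences** of a switch: 3'UTR length change,
  NMD sensitivity by the 50-nt exon-junction rule, protein-domain
  gain/loss.
* **Domain-loss attribution**: losses are tied to the AS events whose
  genomic spans overlap the lost domain region, and the IR vs non-IR
  contrast across increased/decreased isoforms is tested by chi-square.
* **Aggregated IR dynamics**: per-gene IR-isoform fractions over a time
  course, differential IR usage, gene-set contrasts (rank-sum), and a
  Spearman screen for splicing factors anti-correlated with IR
  isoforms.
* **Motif-density binning**: IUPAC motif occurrences per region, 10
  relative bins, one-sided rank-sum per bin between IR and non-IR
  exons/introns.
* A **seeded synthetic-data generator** that plants all of the above as
  ground truth, so the entire pipeline is testable end to end.

## Worked example

Everything below runs on synthetic data with planted truth — swap in
`read_gtf()`, `read_counts_tsv()`, `read_design_tsv()` etc. for real
files.

```r
library(spliceshift)

cfg <- generator_config(seed = 42, n_genes = 50)
ann <- generate_annotation(cfg)     # reference + query GTF models, genome
sim <- simulate_counts(ann)         # counts over 0/24/72 h, 4 replicates

# 1. classify query isoforms against the reference
idx <- build_reference_index(ann$reference)
queries <- classify_transcripts(ann$queries, idx)
table(vapply(queries, `[[`, "", "category"))
#> FSM ISM NIC NNC
#>  50  50  65  50

# 2. isoform switch test between 0 h and 72 h
gene_map <- setNames(ann$truth$isoforms$gene_id,
                     ann$truth$isoforms$transcript_id)
sw <- test_switch(sim$counts, sim$design, gene_map, c("h0", "h72"))
head(sw[sw$significant, ], 3)
#>   isoform_id gene_id    dIF  p_value q_value significant
#> 1  G0001.FSM   G0001  0.278 0.000744 0.00800        TRUE
#> 3  G0001.NIC   G0001 -0.267 0.000798 0.00817        TRUE
#> 5  G0002.FSM   G0002 -0.288 0.000626 0.00709        TRUE

# 3. aggregated IR fraction of one IR-regulated gene over the time course
irl <- setNames(ann$truth$isoforms$ir_label, ann$truth$isoforms$transcript_id)
agg <- aggregate_ir_fraction(sim$counts, sim$design, gene_map, irl)
cond <- sim$design$condition[match(colnames(agg$ir_fraction),
                                   sim$design$sample_id)]
round(tapply(agg$ir_fraction["G0016", ], cond, mean)[c("h0", "h24", "h72")], 3)
#>    h0   h24   h72
#> 0.204 0.276 0.336
```

The first block says 215 query isoforms fall into the four structural
categories exactly as planted. The switch table reads: in gene G0001
the FSM isoform's fraction rose by 0.278 while the skipping (NIC)
isoform fell by 0.267 — a significant usage switch at FDR below 0.01
with no change required in gene-level expression. The last line shows a
gene whose intron-retaining isoforms climb from ~20% to ~34% of the
gene's output over 72 h — the IR-driven attenuation pattern the
aggregated analysis is built to detect and test (`test_ir_usage()`,
`compare_genesets()`).

See `vignettes/methods.Rmd` for the models, defaults, and design
decisions, including what the synthetic generator does and does not
emulate.

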