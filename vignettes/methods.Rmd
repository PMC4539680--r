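---
title: "Harmful somatic AAS analysis: models, parameters and design choices"
author: "somaticAAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmful somatic AAS analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticAAS)
```

## The analysis in one paragraph

Tumour genomes accumulate far more somatic single-nucleotide variants
(SNVs) than are functionally relevant.  This package implements a
pipeline that (1) maps SNVs onto the coding sequence of the **longest
transcript** of each gene and classifies them as synonymous, missense
(amino acid substitution, AAS), nonsense or stop-loss; (2) filters AASs
by the probability that an external predictor assigns to their being
functionally harmful, keeping only confidently harmful calls;
(3) characterises the harmful landscape per cancer type: trinucleotide
substitution spectra, amino-acid substitution matrices and
length-normalised domain mutation densities; (4) prioritises the
proteins most recurrently affected by harmful AASs; (5) tests GO terms
and pathways for over-representation of the affected genes; and (6)
quantifies how centrally the affected proteins sit in a
functional-interaction network and how strongly cancer types overlap at
the pathway level.

## Stage models and the parameters that matter

### Variant annotation

Each gene is represented by the transcript encoding its longest
protein; equal lengths are broken by the lexicographically smallest
transcript id so the choice is deterministic.  Coordinates are 1-based
and inclusive throughout (genomic and protein), matching GFF3.  A
variant inside a CDS exon is projected to a CDS position by summing
exon widths in coding order; on minus-strand transcripts both alleles
and the flanking context are complemented.  Positions up to **2 nt
inside an intron** at a CDS exon boundary are classified `splice_site`
and excluded from spectra; the 2-nt width is the canonical donor or
acceptor dinucleotide.  Consequence calling compares the translations
of the reference and alternate codon (standard genetic code): equal
residues are synonymous, a gained stop is nonsense, a lost stop is
stop-loss, anything else is missense.  Stop-loss is recorded but routed
out of the AAS statistics, which cover missense (and, where stated,
stop-gain) changes only.

The nonsynonymous/synonymous ratio defaults to *missense /
synonymous*; stop-gains can be added to the numerator through the
`nonsynClasses` argument.  With genome-wide totals of 824,336 missense
and 308,896 synonymous changes this yields 2.7 at one decimal, which is
how the published overall ratio is reproduced — including stop-gains
would give 2.9 instead, so the missense-only reading is the one
consistent with the printed value.

### Harmfulness filtering

The harmfulness predictor is consumed as a file: one probability in
[0, 1] and a three-class call (`harmful` / `neutral` / `unknown`) per
substitution.  The predictor itself is external machine learning and is
deliberately **not** reimplemented.  When a prediction file carries no
class column, probabilities are mapped with thresholds `>= 0.95`
harmful and `<= 0.05` neutral; this threshold rule is a declared
approximation of the predictor's confidence-based classification (a
confidence level is not a plain probability cutoff), and a file's own
class column always takes precedence.  Unknown-class AASs are excluded
from every downstream harmful-AAS statistic because those predictions
are not considered reliable; they still count in class-fraction
denominators, which is why a benign set of 454 substitutions with 87
harmful calls has a false positive rate of 19.2 % regardless of how
many of the rest were unclassified.

### Mutational landscape

Substitution spectra use the standard 96-channel convention: six
pyrimidine-centred classes (C>A, C>G, C>T, T>A, T>C, T>G) by 16
combinations of the immediate 5' and 3' bases.  The context is read
from the **plus strand of the reference** and then canonicalized —
not from the coding strand — matching mutational-signature practice.
Channel totals always equal the number of included SNVs.  Amino-acid
substitution matrices are masked by reachability: a (reference,
alternate) residue pair is only attainable if some codon pair differs
at exactly one base, so for example R>H is reachable and M>W is not.
AAS matrices count occurrences by default; a `uniqueSubstitutions`
flag collapses recurrent identical substitutions, since either reading
of published per-residue counts is defensible.  Rendering is a flat
96-bar chart; the tested artifact is the matrix, the plot is cosmetic.

### Domain mutation density

A *domain* aggregates all instances sharing one accession across
proteins; an *instance* is one (protein, start, end) interval.  The
density of a domain is the number of AASs inside its instances divided
by the **cumulative length of only those instances that contain at
least one AAS** — an unmutated instance contributes nothing to the
denominator.  Domains with one or no AAS are dropped.  This literal
reading of the cumulative-length definition is what reproduces the
published formula; note it makes the density non-monotone in instance
count by design.  The `> 1 AAS` filter counts occurrences by default,
with the same unique-substitution flag as above.

### Protein prioritisation

Per cancer type: (1) proteins with harmful AASs in fewer than 2
distinct samples are eliminated; (2) the **nearest-rank 95th
percentile** (the value at position `ceiling(0.95 n)` of the sorted
per-protein sample counts) sets a threshold and proteins with strictly
more affected samples are selected — approximately the top 5 %;
(3) when more than 100 samples contain harmful AASs, proteins carrying
one identical substitution (same protein, position, reference and
alternate residue) in more than 2 % of **all** samples of the cancer
type are admitted as well, with the reason recorded.  Design choices
worth flagging: nearest-rank was chosen because no interpolation rule
is standard for this statistic; the percentile is computed *after* the
two-sample filter (the survivors are what gets sorted); and the 2 %
denominator is all samples of the cancer type, not only mutated ones.
The monotonicity guarantee is threshold-conditional: at a fixed
threshold, adding harmful AASs can only grow the selection, but
recomputing the threshold after adding data may legitimately move it
across a tied count.

### Enrichment

Over-representation is the classic one-sided hypergeometric test per
term — `P[X >= k]` for an overlap of `k` query genes with a term of
size `K`, query size `n`, universe size `N` — with Benjamini-Hochberg
adjustment applied within each (cancer, collection) family.  This is a
deliberate substitution for GO-graph-aware algorithms (elim/weight
style), which are out of scope; on real data the q-values of
dependency-aware methods would differ.  The universe is all genes in
the annotation collection, matching the defaults of the usual tools.
The query policy has two tiers: cancers with fewer than 20 selected
proteins are queried with *all* genes containing at least one harmful
AAS at GO FDR 0.01; the rest with the selected genes at GO FDR 0.001.
Pathway significance is always FDR 0.05.  Exactly 20 selected proteins
is *not* below the cutoff.

### Network statistics

The average degree of a node set is `D_n = (2 E_n + E_other) / n`,
where `E_n` counts edges within the set (each contributes to two
member degrees, hence the factor 2) and `E_other` edges with exactly
one endpoint in the set.  For a whole network `E_other = 0` and
`D = 2|E|/|V|`; the published full-network size (10,706 nodes, 171,449
edges) gives 32.0.  Degree comparisons are evaluated against the
**full** network even when a reduced subnetwork (selected proteins,
harmful proteins and their first neighbours) is used for display and
clustering.  Module detection is greedy modularity maximisation
(`igraph::cluster_fast_greedy`) under a fixed seed — a documented,
pluggable stand-in for unspecified plugin clustering; module
identities on real data would not be comparable across tools.
Cross-cancer overlap networks split cancers at more than 20 selected
proteins; nodes carry the number of significant pathways and selected
proteins, edges exist whenever two cancers share a significant pathway
and are weighted by the shared-pathway and shared-protein counts.

## The synthetic cohort generator

Every pipeline input can be generated with known planted structure, so
each stage has a recovery-based test without any external download.
The generator emulates: per-sample somatic SNV tables, gene models
(GFF3 + FASTA), harmfulness prediction tables, domain interval tables,
GO and pathway GMT collections, an interaction edge list (SIF), and a
cancer-gene list.  The planted truth (drivers, driver pathways,
channel weights, per-record consequence labels) is written to a
sidecar JSON that no pipeline stage ever reads.

Genes sit on one linear chromosome, non-overlapping, on both strands,
with multi-exon structure.  Isoforms are built by skipping
codon-aligned internal exons, so every transcript starts with ATG,
ends with a stop codon, has CDS length divisible by three and no
internal stop, while isoform protein lengths differ — exactly the
structure longest-transcript selection needs.  Background SNVs are
placed by first drawing a 96-channel from the cancer's spectrum
weights and then a uniformly random genomic position whose canonical
trinucleotide context matches that channel, so the generated channel
distribution equals the planted weights by construction.  Driver
genes additionally receive missense-only SNVs, channel-faithfully, at
`driver_boost` times their background missense rate.

### Default study conditions and why

* 3 cancer types x 100 samples; 560 genes of 200-500 codons;
  ~145 background SNVs per sample over gene loci.  This matches the
  order of magnitude of coding mutation burdens in exome cohorts
  (roughly a hundred coding SNVs per tumour) at a size a laptop
  simulates in seconds.
* A 40-gene driver pool in 5 blocks of 8; each cancer plants 3 blocks
  (24 drivers).  Blocks shared between cancers create the pathway-level
  overlap the cross-cancer analysis looks for, and each planted pathway
  is one block plus 4 filler genes.
* `driver_boost = 20` with a per-driver U(0.4, 1) multiplier.  The
  jitter gives drivers heterogeneous per-sample hit probabilities
  (~0.7-0.96), which spreads their sample counts and avoids massive
  ties at the selection threshold — real driver genes differ widely in
  mutation frequency.
* `harm_high = Beta(50, 1)` puts 92 % of driver missense AASs above
  the 0.95 cutoff; `harm_low = Beta(0.25, 0.30)` puts ~20 % of
  passenger AASs above it.  The passenger tail is deliberately not
  near zero: published benign-set evaluations of harmfulness
  predictors report false positive rates of 9-19 %, and the
  prioritisation rules *depend* on a broad background of
  spuriously-harmful proteins — the 95th-percentile rule selects the
  top ~5 % of surviving proteins, so several hundred background
  proteins must survive the two-sample filter for two dozen planted
  drivers to be the top 5 %.
* Pathway partition of all genes; network as a stochastic block model
  over that partition (within-pathway edge probability 0.6, cross
  0.004), dense enough for greedy modularity to recover the planted
  communities.
* Domains: 1-3 random instances per protein plus a hotspot accession
  covering the central 40 % of every driver-pool protein.

What the generator does **not** emulate: realistic human coordinates,
indels and copy-number events, sequencing error, transcript-level
expression, subclonal structure, or correlated mutational processes
within a sample.  Passing recovery tests therefore demonstrate that
the statistics implement their definitions and can recover planted
signal of realistic magnitude — not that the pipeline's biological
conclusions on real cohorts are correct.

### Numerical and degenerate-input choices

Exact hypergeometric tails come from `phyper` (log-space stable);
independent tests cross-check them against direct log-binomial
summation, Monte-Carlo sampling and a second over-representation
implementation.  Ties are always broken lexicographically (transcript
ids, domain accessions) so every ranking is deterministic.  Empty
inputs return empty, well-typed results rather than errors wherever
the empty case is meaningful (no surviving proteins, no overlapping
terms, zero-sample cohorts); genuinely contradictory inputs (ref equal
to alt, inconsistent hypergeometric counts, probabilities outside
[0, 1]) are errors that name the offending field, file line or bases.
A single master seed drives per-stage substreams, so any stage can be
regenerated independently and identical seeds give byte-identical
output files.  Test-suite simulations use reduced cohorts (typically
2 cancers x 12 samples x 40 genes) for unit-level checks and the full
default configuration, averaged over 10 seeds, for the recovery
claims; those sizes are the package's reference conditions, chosen
once.

## Known limitations

* The harmfulness threshold stub is an approximation; real prediction
  files should carry their own class column, which wins.
* Classic hypergeometric GO results will not match GO-graph-aware
  algorithms on real annotations.
* Module identities from greedy modularity are not comparable to other
  clustering tools; only the recovery of planted communities is
  guaranteed.
* A variant overlapping two genes is annotated once per gene; the
  conservation identity between summary counts and input rows holds
  exactly only for non-overlapping gene models (always true for
  synthetic data), with the multi-gene surplus reported alongside.
* One published EGFR domain statistic is internally inconsistent in
  its source (56.6 % vs 86/148 = 58.1 %); the density machinery here
  makes no attempt to resolve it.
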