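---
title: "Quantifying alternative-splicing rates and the drift barrier on splicing accuracy"
author: "splicedrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative-splicing rates and the drift barrier on splicing accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

Most splice variants detected in bulk RNA-seq are rare, and a long-standing
question is how much of this variation is functional regulation and how much
is molecular noise — errors of the spliceosome that selection cannot purge
when effective population sizes (*Ne*) are small (the drift barrier:
selection is powerless against deleterious effects with |*Ne·s*| ≪ 1).
`splicedrift` implements, on top of standard Bioconductor infrastructure, the
measurement layer needed to ask that question from spliced alignments, and a
small generative model to interpret the answer:

1. **Junction extraction.** Candidate introns are read off `N` operations in
   CIGAR strings of uniquely mapping reads with mismatch ratio ≤ 0.02.
   Detection requires ≥ 8 aligned bases on each flanking exon (anchors);
   quantification relaxes this to 5 bp. Introns longer than 2,000,000 bp are
   discarded; the first and last two intronic bases must spell GT–AG, GC–AG
   or AT–AC on one strand, which also assigns the strand. Introns are
   attached to the unique gene with an annotated exon coordinate within 1 bp
   of either intron boundary (ambiguous or unassigned introns are dropped)
   and restricted to the span between the transcription-wise first start
   codon and last stop codon across isoforms.

2. **AS quantification.** For a focal intron, `Ns` counts spliced reads
   excising exactly that intron, `Na` spliced reads sharing exactly one
   boundary, and `Nu` unspliced reads co-linear with the genome covering
   ≥ 10 bp on each side of a boundary (summed over both boundaries). The
   ratios RAS = Ns/(Ns+Na) and RANS = Ns/(Ns+Nu/2) — retention is seen at
   two sites, hence the factor 2 — are computed only when their denominator
   reaches 10 reads. Major-isoform introns have both ratios > 0.5;
   minor-isoform introns have at least one defined ratio ≤ 0.5. For a major
   intron with spliced reads `NM` and linked minor-variant reads
   `Nm = Σ Nim`, the AS rate is `Nm/(NM+Nm)` and each variant's MIRA is
   `Nim/(NM+Nm)`, so MIRAs sum exactly to AS. The per-gene AS rate pools a
   gene's major introns and assumes independent events:
   `ASg = 1 − (1 − ΣNm/Σ(NM+Nm))^Ni`.

3. **Variant-level analyses.** A minor boundary within 30 bp of its major
   boundary (shorter than the smallest metazoan introns, so no exon can hide
   between the two sites) is frame-preserving iff the offset is a multiple
   of 3; the random expectation is 1/3. Variants are called abundant when
   MIRA > 5%. SNP density at splice-site dinucleotides is contrasted with
   control AG/GT dinucleotides found 20–60 bp from the major splice sites,
   AG near the donor and GT near the acceptor so that controls cannot be
   unrecognised splice sites; proportions carry Wilson 95% intervals.

4. **Drift-barrier mixture (generative model).** Per-intron AS rates are a
   mixture: with probability 5% an intron hosts a functional variant with
   AS ~ Normal(25%, 5%); otherwise its rate is a splicing error
   ~ Gamma(shape 1) with mean 0.2%, 0.6% or 1.2% for a high-, medium- or
   low-*Ne* species. Two thirds of errors shift the reading frame;
   functional variants never do. Every summary the simulator reports is also
   available in closed form (`analytic_expectations()`), which serves as the
   simulator's oracle in the test suite.

5. **Comparative layer.** Cross-species relations between AS summaries and
   *Ne* proxies (longevity, body length, dN/dS — all supplied as given
   covariates) are fitted by phylogenetic generalized least squares under a
   Brownian-motion covariance (shared root-to-tip path lengths), with a
   two-sided *t*-test on *n* − 2 degrees of freedom for the slope.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| detection / quantification anchor | 8 / 5 | bp | discriminating junction placement vs counting power |
| mismatch ratio ceiling | 0.02 | — | removes poorly aligned reads |
| max intron length | 2,000,000 | bp | upper bound of credible metazoan introns |
| ratio denominator | 10 | reads | below this, RAS/RANS are too noisy to classify |
| retention overlap | 10 | bp | an unspliced read must straddle the boundary convincingly |
| frame window | 30 | bp (inclusive) | smaller than the smallest introns; excludes skipped exons |
| abundance threshold | 5% | MIRA | separates splice variants plausibly enriched in function |
| control window | 20–60 | bp | near enough to share base composition, far enough from real sites |
| functional fraction / mean / sd | 5% / 25% / 5% | — | the model's functional component |
| error shape / means | 1 / 0.2–1.2% | — | exponential-tailed error rates across the *Ne* range |
| frameshifting error fraction | 2/3 | — | random offsets preserve frame 1/3 of the time |

## What the synthetic generator emulates — and what it does not

`generate_annotation()` builds one chromosome of spaced genes (3–7 introns
each, exons 120–250 bp, introns 150–500 bp), plants splice signals (98%
GT–AG), start/stop codons, and for every intron one minor splice variant
with a recorded shared side, exonic/intronic location and boundary offset.
True AS rates come from the drift-barrier mixture; gene expression is
log-normal, optionally coupled to the error rate through a power exponent
(negative exponent = highly expressed genes spliced more accurately).
`simulate_reads()` realises Poisson junction coverage proportional to
expression, splits reads binomially between major and minor junctions at the
true AS rate, adds retention reads at a configured fraction of junction
depth, and can inject reads violating the anchor, mismatch or uniqueness
filters to exercise the extraction layer. `simulate_snps()` plants SNPs
per-base at a background density with multiplicative reductions at splice
dinucleotides (purifying-selection caricature). `simulate_clade()` grows a
pure-birth tree, evolves log-longevity by Brownian motion and couples each
species' error mean log-linearly to longevity.

Deliberate simplifications: uniform base composition and no splicing-motif
model beyond the planted dinucleotides; one isoform and one minor variant
per intron; no quality scores, no soft-clipped realignment artifacts, no
multi-sample structure; SNPs are independent Bernoulli events without
frequency spectra. Passing tests therefore demonstrate the correctness of
the measurement and inference layers under a controlled truth, not the
biological realism of real transcriptomes.

Two generator choices deserve a note:

* **Minor-variant offsets.** Error-variant offsets are uniform on 4–33 bp.
  Offsets below ~3 bp would make the planted minor splice dinucleotide
  collide with the major one in the sequence, and the 4–33 range keeps the
  frame-preserving fraction at exactly 1/3 both overall (10/30 multiples of
  3) and within the 30-bp evaluation window (9/27 on 4–30). Functional
  variants draw offsets from multiples of 3 up to 30 bp, mirroring the model
  assumption that they preserve frame.
* **Per-species summary size.** `simulate_clade()` summarises each species
  from 20,000 simulated introns. A metazoan transcriptome contributes tens
  of thousands of measured major introns to a genome-wide mean, so this
  restores realistic summary precision; far smaller per-species samples
  would let finite-sampling noise, an artifact of down-scaling, dominate
  the cross-species regression.

## Numerical and design choices

* `Nu/2` enters ratios and the denominator threshold as an exact real value
  (Ns = 0, Nu = 19 fails the RANS threshold; Nu = 20 passes).
* Ties at the classification boundary (ratio exactly 0.5) are minor, and
  `Na` is defined per focal intron — a read sharing one boundary counts
  toward every focal intron it contradicts.
* Retention reads must be free of `N` operations entirely; a read spliced at
  another intron is not counted as co-linear evidence.
* Anchors count M-op bases only; insertions, deletions and soft clips
  within a flank contribute nothing.
* Control dinucleotide distance is the boundary-shift convention also used
  for minor-variant offsets (a control at distance *k* sits where a minor
  boundary with offset *k* would place its dinucleotide); the candidate
  nearest the splice site wins, and candidates overlapping known splice
  dinucleotides can be excluded.
* CpG flagging inspects one flanking base on each side of the dinucleotide
  (any CG in the 4-mer context); a strict "dinucleotide is CG" rule is
  available via `strict = TRUE`.
* Frame-preservation enrichment of abundant vs rare variants is a ratio of
  proportions by default, with an odds-ratio alternative.
* MIRA profiles use 20 fixed-width 5% bins spanning (0, 1]; an equal-count
  (quantile) mode is available. Expression bins are always equal-count.
* PGLS is pure Brownian (Pagel's λ fixed at 1), fitted by Cholesky
  whitening; on a star phylogeny it reproduces OLS to machine precision and
  it is invariant to uniform rescaling of the covariance.
* Model truncation: functional draws outside [0, 1] are redrawn, gamma draws
  above 1 are clamped; at the default parameters both events have
  probability < 10⁻⁶ and the analytic oracle accounts for them exactly.
* Degenerate inputs: empty coverage vectors, all-zero depths, singular
  covariance matrices, offset-0 links and genes lacking start/stop codons
  raise errors or flagged `NA`s rather than silent results.

## Problem sizes used by the test suite

The suite validates the simulator against its closed form at 10⁶ introns per
*Ne* setting, recovers per-intron AS end-to-end from ~250,000 simulated
reads (1000 reads per intron over ~150 introns), and checks PGLS sign
recovery over 30 simulated 40-taxon clades; these sizes keep the full run
under a minute while leaving Monte-Carlo standard errors far below the
tested tolerances.

## Worked example

```{r example}
library(splicedrift)

cfg <- synthetic_config(n_genes = 12)
sim <- generate_annotation(cfg, seed = 61)
reads <- simulate_reads(sim, depth = 400, seed = 62)

introns <- detect_introns(reads$alignments, sim$genome, sim$annotation)
quant <- quantify_introns(introns, reads$alignments)
majors <- quantify_major_introns(quant)
head(majors$majors[, c("gene_id", "intron_start", "intron_end", "NM",
                       "Nm", "AS")])

links <- link_and_offset(majors$links)
mira_profile(links)
per_gene_as_rate(majors$majors)

# drift-barrier model vs its closed form
p <- model_params(n_introns = 1e6, error_mean = 0.012)
summarize_model(simulate_species(p, seed = 1))
analytic_expectations(p)
```

## Known limitations

* Only single-end-style co-linear evidence is modelled; paired-end mates and
  split mappers' secondary alignments are out of scope.
* Expression values (FPKM) are inputs, never computed from reads.
* The per-gene AS formula assumes a uniform rate and independence across a
  gene's major introns; genes violating independence will have biased `ASg`.
* PGLS offers no correlation-structure refinements (no Pagel's λ estimation,
  no Ornstein-Uhlenbeck alternatives).
* The drift-barrier model is illustrative: it is not fitted to data and does
  not estimate *Ne*.
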