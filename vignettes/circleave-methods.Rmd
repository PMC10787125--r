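---
title: "circleave: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circleave: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circleave)
```

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing (exonic ecircRNAs) or intron-lariat stabilization (ciRNAs).
Because they have no free ends, their decay routes differ from linear
mRNAs; in plants one candidate route is miRNA-guided endonucleolytic
slicing. Degradome (PARE) sequencing captures uncapped 5′-monophosphate
ends, so a miRNA cleavage event leaves a sharp pile of read 5′ ends at the
slice position. `circleave` implements the computational side of such a
study end to end: weighted 5′-end pileups, windowed peak calling with a
binomial significance filter, duplex-energy-based miRNA target matching at
peaks, detection of decay reads spanning the back-splice junction,
rolling-circle ORF prediction, circRNA typing/quantification, and a
permutation test for feature enrichment in circRNA transcribed regions —
all exercisable on deterministic synthetic data with planted ground truth.

## Degradome peak calling

Each mapped degradome read contributes `1/n` at its 5′-most mapped base,
where `n` is its number of reported loci (NH tag, or the record count per
read id), so one sequenced read always carries unit weight. Pileups are
strand-separated; soft-clipped bases are excluded (the monophosphate end is
the *mapped* 5′ base).

A position `i` with weight `w_i` is a cleavage peak when

1. `w_i / W ≥ 0.5`, where `W` sums the centred 21-nt window (10 nt each
   side, truncated at reference ends with the denominator restricted to
   existing positions — zero-padding would inflate edge fractions); and
2. the upper-tail binomial probability `P(X ≥ k)` is at most 0.05.

The binomial null is not fully pinned down by the cutoff alone, so two
modes are exposed. In the default *transcript* mode the null is uniform
decay over the reference: `p0 = 1/L`, `N` = the rounded total reference
weight. In *window* mode `p0 = 1/21` with `N` the rounded window total.
Weights stay fractional for the window-fraction rule; `k` and `N` are
rounded half-up only at the test boundary so the `1/n` bookkeeping is never
coarsened. No multiple-testing correction is applied by default (the raw
0.05 cutoff is the published procedure); `fdr = TRUE` switches to BH.

A property worth knowing: under transcript mode, a reference whose total
read count satisfies `N/L < ~0.05` makes even singleton 5′ ends nominally
significant (`P(X ≥ 1) ≈ N/L`). Such background "peaks" are real output of
the stated procedure; in the full pipeline they are eliminated by the
duplex and slice-position filters downstream.

## miRNA slice-site matching

For each peak, 25 nt of context on each side (51 nt total) is extracted;
circular transcripts wrap across the back-splice junction (periodic
sequence) and never truncate. Each mature miRNA is aligned antiparallel to
the window under a deliberately simplified duplex energy model:

* pair energies G:C = −3, A:T = −2, G:U wobble = −1 (all sequences held in
  the T alphabet internally);
* +2 per unpaired base inside the duplex (bulge/internal loop);
* +1 per opposed non-pairing position (mismatch);
* bases outside the first/last pair are free ("ends open").

The minimum energy `E` over all such duplexes (never above 0) is divided by
the energy `E*` of the miRNA bound to its exact complement, giving an MFE
ratio in [0, 1] with ratio 1 exactly when the window contains the perfect
complement. This is *not* a Turner-parameter thermodynamic engine and is
documented as a substitution: the downstream decision is a ratio threshold,
for which a monotone, exactly testable model suffices — the dynamic program
is verified against exhaustive co-pairing enumeration in the test suite.
The published threshold reads "MFE ratio 0.7 or less", which under the
standard convention would admit *unstable* duplexes; the default here is
the conventional reading (accept ratio ≥ 0.7), with `ratio_sense = "le"`
available to flip it.

Plant slicing cuts the target opposite miRNA positions 10–11; the predicted
slice is the target base paired with position 10 (a call is rejected if
position 10 sits in a bulge). A cleavage call requires ratio ≥ 0.7 and
predicted slice within ±1 nt of the peak (circular distance on circles).

## Junction-spanning decay reads

For a circle of spliced length `L`, the junction reference is the last `f`
nt followed by the first `f` nt with `f = min(50, floor(L/2))`; the cap
prevents the same circle base appearing twice in one reference. Reads are
scanned ungapped against each reference and hit when they have at most 1
mismatch and at least 5 nt on each side of the junction (leftmost placement
among equally good offsets). The paper is silent on these two thresholds
(its aligner defaults applied); 5 nt / 1 mismatch are this package's
defaults and both are exposed. With a 5-nt overhang a random linear read
has a per-offset false-hit probability of order 1%, which is why the
simulated linear control draws reads uniformly over the locus rather than
forcing minimal overhangs.

## Rolling-circle ORFs

The spliced circle sequence is concatenated four times and scanned on the
sense strand, all three frames, strict ATG starts, stops TAA/TAG/TGA.
ORFs longer than 10 aa (strictly, i.e. ≥ 11) are kept; start positions are
taken in the first copy, which deduplicates repeats across copies, and an
ORF whose coding span crosses a multiple of `L` spans the back-splice
junction. A frame with no stop anywhere in its periodic cycle is a rolling
ORF, reported once with the peptide truncated at four copies (the
truncation tail therefore depends on the rotation in which the circle is
written — a bookkeeping artefact, not a biological claim). uORFs and dORFs
on linear transcripts must lie entirely within the 5′/3′ UTR; CDS-
overlapping ORFs are excluded and counted, and the annotated CDS is emitted
as the primary ORF. Peptide support follows the published rule exactly:
peptides matching any number of ORFs other than one are dropped, and an ORF
is retained only with at least one surviving peptide.

## Quantification and differential expression

circRNA abundance is junction reads per million mapped reads
(`count / (total/1e6)`). Differential expression replaces the original
DEGseq call (external, non-reimplementable) with an exact two-proportion
binomial test: for counts `(k1, k2)` under totals `(N1, N2)`, the p-value
is the two-sided exact binomial test of `k1` in `k1 + k2` trials at
`p0 = N1/(N1+N2)`; FDR is Benjamini–Hochberg; calls require fold change
≥ 2 (or ≤ 0.5), p < 0.01 and FDR ≤ 0.01 simultaneously. Fold change is
computed on RPM with a 0.5 pseudocount added to *both* sides *only when
either side is zero*: an unconditional pseudocount would contradict exact
ratios for condition-specific-free cases, while the conditional form keeps
zeros finite and preserves `fc(a,b)·fc(b,a) = 1` to machine precision.
Replicates are pooled by summation before testing.

## Alternative back-splicing and internal splicing

The circle's 3′ (donor) boundary is the genomic end on "+" and the genomic
start on "−". Pairs of same-gene circRNAs sharing the donor but not the
acceptor are A5BS; sharing the acceptor but not the donor, A3BS; partially
overlapping intervals (neither containing the other) with mutually
exclusive exons are MIC, with A5BS/A3BS taking precedence so every pair
receives at most one label. Isoforms sharing both back-splice sites are
compared exon chain against exon chain: wholly absent exons are exon
skipping, an exon continuous across the other chain's intron is intron
retention, and boundary shifts on exons in 1:1 correspondence are A3SS or
A5SS by splice-site side and strand. The 1:1 restriction stops a retention
event from also surfacing as two spurious splice-site shifts.

## Permutation enrichment

To ask whether a feature class (AS events, R-loops) is enriched in circRNA
transcribed regions, the observed overlap count is compared with counts in
`n_perm` draws of equally many random transcript segments. The published
procedure matches only the *number* of segments; because count statistics
are length-confounded, the default here also samples segment lengths from
the observed pool (`fixed_length` reproduces the literal scheme).
Transcripts overlapping the target regions are excluded from the null
universe by default ("transcribed regions without circRNAs"). The report
includes permutation mean/SD (as published), an auxiliary z score with a
guarded `sd = 0` degenerate case, and the add-one empirical p-value
`(1 + #{perm ≥ obs})/(n_perm + 1)`, which is never smaller than its floor
`1/(n_perm+1)`. Calibration is tested: under a null in which targets and
features are exchangeable, empirical p-values are uniform (KS test) and the
mean z sits within ±0.2.

## The synthetic world

The generators state one fixed world rather than tunable difficulty:
a single random chromosome; genes of 2–5 exons, exons 80–300 nt, introns
60–200 nt; 21-nt miRNAs; planted slice sites built by embedding a miRNA's
reverse complement so the base paired with miRNA position 10 falls exactly
on the site; 200 signal reads per site; uniform background of 0.05 reads
per nt with 10% of background reads multi-mapping at 2–4 loci (NH-tagged);
30-nt reads. Every stage seeds the RNG as `seed + stage offset`, so outputs
are byte-identical per seed regardless of call order.

What the synthetic data does **not** emulate: sequencing errors and quality
scores, RNase R enrichment biochemistry, 3′-biased degradation gradients,
isoform mixtures, and genome-space alignment ambiguity (reads are emitted
already aligned, in transcript space). A green planted-truth test therefore
establishes that the *decision rules* are implemented correctly and
recover ideal signal over uniform noise — not that the pipeline is robust
to real library artefacts.

## Numerical choices and degenerate inputs

* Half-up rounding (`floor(x + 0.5)`) at the binomial test boundary, never
  banker's rounding, so weights like 0.5 behave predictably.
* Duplex DP ties are broken deterministically (smallest miRNA index, then
  smallest reversed-window index); junction hits take the leftmost best
  placement.
* Empty pileups, zero-length libraries, constant correlation profiles,
  CDS lengths not divisible by 3 (strict mode), unmappable windows and
  exhausted permutation universes all raise classed errors
  (`EmptyPileup`, `ZeroLibrary`, `ConstantVector`, `CoordinateError`,
  `WindowTooShort`, `UniverseExhausted`) rather than returning silent NAs.
* All internal coordinates are 0-based half-open; GFF3/GTF (1-based
  inclusive) and SAM (1-based) are converted at the boundary only.

## Known limitations

* The duplex model is a nearest-pair approximation; absolute energies are
  not comparable to RNAplex/RNAduplex values, only the ratio-threshold
  behaviour is preserved.
* Peak calling assumes one reference per transcript; peaks on overlapping
  transcripts of one locus are not deduplicated (the original study is
  silent on this too).
* The DE test has no dispersion component; replicate variability beyond
  pooled counts is not modelled.
* Junction-read mapping is ungapped by design; indel-bearing junction reads
  are not recovered.
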