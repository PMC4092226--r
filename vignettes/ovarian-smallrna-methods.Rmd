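---
title: "Methods: ovarian small-RNA annotation, hairpin prediction and target analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ovarian small-RNA annotation, hairpin prediction and target analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovamir)
```

ovamir reimplements, as a tested and reusable pipeline, the computational
workflow of an ovarian small-RNA sequencing study in a non-model crustacean:
read cleanup and collapsing into unique tags, classification of tags against
miRNA references and a surrogate genome, hairpin-based prediction of novel
miRNA precursors, seed- and duplex-energy-based discovery of miRNA binding
sites in a 3'-UTR, and the relative-expression statistics used to validate
candidate regulators (qPCR 2^-ddCt and dual-luciferase reporter assays).
Because raw libraries of this kind are often not deposited, the package ships
a seeded synthetic-data generator that plants every signal the pipeline is
supposed to find; all quantitative claims about the pipeline are made, and
tested, against that planted ground truth.

## Read preprocessing

Raw FASTQ reads pass through a fixed filter chain:

1. **quality** — mean PHRED+33 quality >= 20; reads containing N are removed
   here as unresolvable. The quality cutoff is a stand-in for the vendor
   pipelines' unquantified "low resolution" removal and is configurable.
2. **adaptor** — the 3' adaptor is located as the best prefix-of-adaptor /
   suffix-of-read overlap of at least 6 nt with at most 1 mismatch,
   preferring fewer mismatches, then the longest overlap. A best overlap at
   insert length 0 is an adaptor–adaptor ligation artifact; reads with no
   detectable adaptor are discarded rather than kept untrimmed, because in a
   small-RNA library an undetectable adaptor implies an insert at least as
   long as the read, outside the 15–30 nt window anyway. The
   fewest-mismatches-first rule makes recovery of error-free inserts exact:
   the default adaptor has no exact self-overlap, so the true trimming
   position is the unique zero-mismatch solution.
3. **contaminant** — full-length matching (<= 1 mismatch) against
   user-supplied reference sets standing in for mRNA, structural-RNA and
   repeat databases, with per-class removal counts. Matching is a hashed
   substring join using the split-in-half pigeonhole, so it is exact, not
   heuristic.
4. **length** — 15–30 nt inclusive.
5. **collapse** — unique tags with copy numbers, ordered by count then
   sequence, with stable ids.
6. **copy** — tags with fewer than 3 copies are dropped ("more than two
   copies"); the filter necessarily follows collapsing.

Contaminant matching runs at the read level (before collapsing) so the
per-class accounting is available in reads as well as unique sequences. The
filter order itself is a design choice: the source workflow lists its filters
without an order.

## Mapping and five-group classification

Unique tags are matched ungapped against species-level mature/precursor
references, broader-clade references, and a genome (for a species without its
own assembly, a related surrogate genome). Against miRNA references a tag may
have at most 2 mismatches but positions 2–8 — the seed — must match exactly;
against the genome matching is exact by default (both strands). Genome hits
are flagged when they overlap a known precursor locus, found by locating the
species precursors in the genome.

Tags are then assigned to one of five groups, in fixed order with the first
match winning:

1. known miRNA hit and a genome hit at a known precursor locus;
2. known miRNA hit plus an additional genome locus whose extended sequence
   folds into a hairpin (a putative additional precursor);
3. clade miRNA hit with a hit in a user-supplied secondary genome but not in
   the primary genome (unreachable when no secondary genome is configured;
   such tags fall through to group 4);
4. miRNA hit but no genome hit;
5. no miRNA hit, but a genome hit whose extended locus has hairpin
   propensity — the novel-miRNA candidates.

Tags hitting nothing, and genome-only tags whose loci do not fold into
hairpins (the piRNA-like bulk of an ovarian library), remain unclassified.
Two reading choices were genuinely open and are resolved as follows: a tag
matching a known reference *and* a new hairpin-forming locus is assigned
group 2 rather than group 1 (the extra locus is the more specific
observation); and "known" in groups 1–2 means a hit in either reference tier,
with the species tier preferred for naming (best hit by mismatches, then
alphabetically — a deterministic tie-break).

Known miRNAs are grouped into families by their seed (positions 2–8,
the standard convention for the "7–8 nt section at the 5' end";
configurable). A tag is called a star (passenger) strand when it maps inside
a known precursor on the arm opposite the annotated mature with at least 60%
of its bases paired to the mature arm in the precursor's fold.

## The folding engine

`mfe_fold()` computes minimum-free-energy nested secondary structures under a
deliberately compact nearest-neighbour model: a symmetric 6x6 stacking table
over AU/UA/GC/CG/GU/UG, affine hairpin, bulge and internal-loop penalties,
and a linear multiloop score; no dangling ends, coaxial stacking or
pseudoknots; hairpin loops of at least 3 nt; internal loops capped at 30
unpaired bases. The constants are bundled in `energy_params()` and shared by
every scorer in the package. The model is *not* the full Turner
parameterisation — the original analysis used an external folding server, so
numeric fidelity to any particular server is out of reach by construction.
Instead, correctness is defined internally: `structure_energy()` scores a
fixed structure by explicit loop decomposition, `fold_exhaustive()`
enumerates every admissible structure of a short sequence and takes the
optimum, and the dynamic program must agree with that optimum exactly. The
same contract holds for the intermolecular duplex program
(`duplex_mfe()` vs `duplex_exhaustive()`), which forbids intramolecular
pairs, has no initiation term (a lone pair scores 0, so duplex energies are
never positive) and uses the same stacking table.

Co-optimal structures are resolved by a fixed traceback order (helix
continuations before multiloops before hairpins, scanning candidates in a
fixed index order), which makes output deterministic without the cost of a
provably lexicographic-minimal traceback.

Two properties worth knowing: the optimal energy is reverse-complement
symmetric only when G:U wobbles are disabled (`energy_params(gu = FALSE)`) —
wobble pairs do not map to valid pairs under reverse complement — and
appending unpairable bases never lowers the optimum.

### Hairpin calls at genome loci

A candidate locus is extended 60 nt in both directions; the full window and
the two single-sided windows are folded. A verdict requires exactly one
terminal loop (bulges and internal loops allowed; multiloops and independent
stems not), energy at most -18 kcal/mol, and the mapped sequence entirely on
one arm with at least 60% of its bases paired. Both thresholds are declared
stand-ins — the source workflow never quantifies "propensity of forming
hairpins" — and stay configurable. Because a 140-nt window of real (or
realistic synthetic) sequence usually folds into more than one stem, the
checker excises the stem-loop branch containing the mapped sequence from the
window's fold, refolds it in isolation, and applies the criteria to that —
the same excision idea used by hairpin-based miRNA discovery tools.

## Target-site discovery

`scan_seed_sites()` reports every UTR span that is the exact Watson–Crick
reverse complement of miRNA positions 2–8; G:U is excluded within the seed
but allowed elsewhere in duplex scoring. Spans are labelled with the GY-box /
Brd-box / K-box motifs when they match; the motif sequences are
literature-derived configuration (Drosophila E(spl)/Brd work), shipped as an
editable table, and the labels are decorative — never a filter. Each site is
scored by hybridising the full miRNA against the site plus 15 nt of context
on each side (the exact context width used by duplex-scanning web tools is
unstated; 15 nt is declared, not inferred). Ranking is by the smallest duplex
energy per miRNA, ties broken by UTR coordinate. `pcr_product()` provides the
in-silico PCR used to check cloning primers against a template.

## Relative-expression statistics

`ddct()` implements Livak's 2^-ddCt: technical replicates are averaged per
sample; dCt is target minus normaliser (U6) for the same sample; ddCt
subtracts the mean reference-stage dCt; stages are compared by a paired
t-test on dCt over matched individuals (Welch fallback, flagged, when no
complete pairs exist), two-sided at alpha = 0.05. The arithmetic itself is a
design choice — the source describes only "normalized against U6" and the
test used — and Livak is the standard reading.

`luciferase_ratios()` normalises per-well firefly/renilla ratios to the
negative-control mean within each construct. Reporter noise is
multiplicative, so the model is fitted on log-ratios — on the raw ratio scale
a strong knockdown group has proportionally smaller variance, which deflates
the pooled ANOVA error and inflates the false-positive rate of the
control comparisons; the log scale removes that artifact. Estimates are
reported back on the ratio scale as geometric means. Group structure is
tested by one-way ANOVA per construct followed by two-sided comparisons
against the negative control. The default post-hoc is Dunnett contrasts on
the ANOVA fit — the canonical "ANOVA followed by comparison with a control"
procedure, available here through multcomp — with Holm-adjusted or unadjusted
Welch t-tests behind a flag, since the original report does not say how (or
whether) its asterisks were multiplicity-adjusted.

## The synthetic-data generator

`sim_config()` defaults define the study conditions used throughout the
tests: a 20 kb single-contig genome; 30 planted pre-miRNA hairpins, 20 of
them listed in the species reference (the "known" miRNAs) and 10 absent from
all references (discoverable only via group 5); 30 piRNA-like loci; 200,000
reads of 36 cycles; log-normal expression weights (sigma 1.5, emulating the
heavy abundance skew seen in real libraries); 60% of small-RNA reads from the
piRNA-like loci (the longer mode dominates ovarian libraries) with lengths
24–27 nt versus 21–23 nt for matures; 5% contaminant reads; 2%
adaptor–adaptor artifacts; 10% low-quality reads; 1% per-base substitution
errors; a 10% star-arm share. Where the emulated study states a condition
(the bimodal 15–30 nt length profile with those two modes, the abundance
skew, the artifact and contaminant classes, 3–4 individuals with technical
triplicates in qPCR, triplicate transfections), the defaults follow it;
everything else — read depth, error and contamination rates, the exact mode
shares — is a free parameter set once to values typical of Illumina small-RNA
data.

Planted precursors are built to satisfy the package's own hairpin criteria: a
6-nt closing stem, the mature arm, a 9–13 nt A/C loop (unpairable with
itself), and a star arm that is the reverse complement of the mature with
0–2 designed mismatches placed away from the stem ends so the terminal loop
is never widened. Mature and star never overlap, precursors are 60–120 nt,
and loci never overlap (packing failures are an explicit error, not a silent
retry).

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: position-dependent sequencing error profiles,
ligation bias, isomiR end-heterogeneity, genuine piRNA sequence biology
(ping-pong signatures, clustering), paralogous miRNA families sharing seeds,
and cross-mapping between near-identical loci. Recovery rates measured here
are upper bounds on real-data performance.

## Numerical and scale choices

The folding oracle is checked on 200 random sequences of length 10–18 and the
duplex oracle on 100 strand pairs of length 8–12 — small enough for complete
enumeration, large enough to cover every loop type. The planted-recovery,
ddCt-calibration (500 simulated datasets each for the fold-change envelope
and the null rejection rate) and luciferase-pattern (500 seeded plates)
checks run at the full default scale above; the whole suite completes in a
few minutes on one core. Energy comparisons use an absolute tolerance of
1e-9 kcal/mol (sums of identical constants in different orders). Degenerate
statistical inputs (zero-variance Ct or ratio data) yield NA test results
rather than errors, and are never flagged significant.

## Known limitations

The mapping engine is exact/near-exact hashing, not a seeded aligner: it is
complete within its declared mismatch ceilings but does not model indels. The
energy model is a teaching-grade nearest-neighbour subset; absolute kcal/mol
values are not comparable to Turner-parameter folders, only the internal
optimum is meaningful. Group 3 of the classification is reachable only when a
secondary genome is configured. piRNA-like tags are deliberately left
unclassified rather than annotated — piRNA biology is out of scope. The
worked example against the real crab cyclin B 3'-UTR (GenBank EU622123)
requires that sequence to be supplied by the user; it is not redistributed
with the package.
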