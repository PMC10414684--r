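---
title: "Methods: computational discovery of AMP-like peptides in helminth proteomes"
author: "helminthAMP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: computational discovery of AMP-like peptides in helminth proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helminthAMP)
```

# The problem

Parasitic nematodes and flatworms live in microbe-rich niches and are
expected to deploy antimicrobial peptides (AMPs), yet most helminth AMPs
cannot be found by homology because they diverge from the characterised
families of other invertebrates. This package implements a
prediction-first alternative: excise every plausible secreted peptide
from a predicted proteome, ask an ensemble of AMP predictors to vote on
each one, and then curate the surviving candidates — called AMP-like
peptides (AMP-LPs) — by conservation, annotation and physicochemistry,
down to a prioritised set suitable for synthesis and MIC screening, with
LC-MS/MS support for validating candidates detected in worm biofluid.

# Pipeline model and assumptions

The pipeline assumes the classical prepropeptide architecture of secreted
peptides: an N-terminal signal peptide, one or more propeptide regions
separated by dibasic convertase sites (KR, RR, KK, RK), and the mature
peptide(s) released between cleavage points. Stages run strictly in
order; every stage is a pure predicate over its input, so per-stage
removal counts fully describe a run.

1. **Precursor filters.** Exact duplicates are removed within each genome
   (first occurrence kept; duplicates between assemblies of related
   species are biologically meaningful and retained unless
   `scope = "global"`), sequences containing `X` or `*` are dropped, and
   precursors longer than 150 aa are discarded — known AMP precursors are
   almost always shorter.
2. **Excision.** Cleavage boundaries are the signal-peptide end, every
   propeptide site, and the C-terminus. Because convertase processing is
   unreliable to predict, *every* ordered boundary pair becomes a
   candidate (`all_pairs`, m(m−1)/2 candidates for m boundaries); the
   `segments` mode (consecutive pairs only) is provided for sensitivity
   analysis. Candidates outside 10–99 aa are gated out — the working
   range of the predictor ensemble.
3. **Ensemble consensus.** A candidate is an AMP-LP when *strictly more
   than half* of the contributing tools call it antimicrobial; with an
   even tool count an exact tie is negative. The overall score is the
   positive fraction as a half-up-rounded integer percentage, so an
   11-tool ensemble can only produce
   {0, 9, 18, 27, 36, 45, 55, 64, 73, 82, 91, 100} and the lowest
   AMP-LP score is 55%. Missing tool output is treated as abstention
   (that tool leaves the peptide's denominator) unless strict mode is on.
4. **Known-AMP exclusion.** Candidates scoring ≥ 50 bits against a
   library of already-characterised AMPs are removed so the pipeline
   reports novelty (threshold configurable; 50 bits on short peptides is
   near-identity).
5. **Sequelog grouping.** All-vs-all Smith–Waterman (BLOSUM62, gap open
   11, extend 1) with Karlin–Altschul bit scoring
   (bits = (λS − ln K)/ln 2, λ = 0.267, K = 0.041 — the standard gapped
   BLOSUM62 constants). Pairs at ≥ 100 bits become edges; connected
   components are sequelog groups. Singleton groups and groups confined
   to one genome are discarded: conservation across assemblies is the
   pipeline's main evidence of function.
6. **Curation.** Groups carrying blocklisted GO terms (signalling,
   protease inhibition, hormone activity, …) are removed — any annotated
   member suffices by default, because a single confident non-AMP
   annotation usually explains the whole group; an all-members mode is
   available. Unannotated groups are retained. Groups whose strict
   majority of members exceed 60 aa are removed (ties at exactly 50%
   retain). Peptides are triaged by cysteine count — linear (≤ 1),
   two-cysteine (= 2), cysteine-rich (> 2); only linear peptides are
   synthesis-friendly, and the two-cysteine class is kept separate
   because it belongs to neither published definition. Expression is
   flagged when TPM > 2 (strictly) in any sample; genes absent from the
   table are *unknown*, never unexpressed.

## Why grouping runs on precursors

Under λ = 0.267, K = 0.041, 100 bits requires a raw score of 248. A
peptide shorter than ~45 residues cannot reach that even against itself
(typical BLOSUM62 diagonal ≈ 5/residue), so a 100-bit criterion can only
have operated on sequences longer than the mature peptides. Grouping
therefore defaults to the full precursor (≤ 150 aa); a mature-peptide
mode (`groupingColumn = "sequence"`) with a user-chosen lower threshold
is available. "Overall bit score" is read as the best single local
alignment per pair; HSP-sum aggregation is out of scope.

## Consensus and representative

Each group's consensus is built from a center-star multiple alignment
(center = member with the highest summed pairwise bit score): per-column
modal residue, ties broken alphabetically, gap-majority columns dropped,
so the consensus is reported gap-free. The representative is the member
with the highest percent identity to that consensus; ties prefer the
longer sequence, then the lexicographically smallest id. With same-length
members this reduces to the member at minimal Hamming distance from the
column-mode sequence, which is how the tests verify it.

# Deterministic stand-ins for external predictors

Three components replace web services so that fixtures and examples run
self-contained. They are labelled heuristics — nothing in the package
claims they reproduce the external tools, and user-supplied annotations
always take precedence.

* `heuristicSignalEnd()`: the first 8-residue window starting within
  positions 3–30 whose mean Kyte–Doolittle hydropathy is ≥ 1.6 marks the
  h-region; the signal end is the window end + 5 (a typical c-region),
  capped at 35.
* `dibasicSites()`: positions of the second residue of each KR/RR/KK/RK
  occurrence, overlaps included.
* `referencePredictors()`: three physicochemical rules — net charge
  ≥ +2, hydrophobic fraction within [0.3, 0.6], Eisenberg hydrophobic
  moment ≥ 0.2 on an ideal α-helix (100°/residue). Cationic amphipathic
  helices trip at least two; neutral sequences trip none.

# Physicochemistry and mass spectrometry

Monoisotopic masses are residue sums plus one water, with deltas
pyro-Glu −17.026549, Met oxidation +15.994915, Tyr sulfation +79.956815
and C-terminal amide −0.984016 Da, reported to 4 decimals and tested at
±0.001 Da against independently computed values. Average masses drive
the µg/ml → µM MIC conversion, `round_half_up(1000·MIC/MW)`, matching
the convention of reporting integer micromolar values; a peptide counts
as active at MIC < 100 µg/ml. A candidate ending in glycine is
synthesised amidated without the glycine (the glycine is the biological
amide donor), and `synthesisForm()` encodes exactly that.

The simple net-charge model (+1 K/R, −1 D/E, +0.5 H, +1 free N-terminus,
−1 free C-terminus, suppressed by pyro-Glu/amide respectively) is the
default because it is reproducible and assumption-free; a
Henderson–Hasselbalch model at pH 7 is available. Published calculators
differ in pKa sets, so charges quoted from other software may differ by
a unit or two — the package never uses an external charge value as a
test oracle.

PSM confidence tiers follow the usual −10lgP bands — high ≥ 47.4 (1%
FDR), medium [20, 47.4), low [13, 20), rejected < 13 — with boundary
scores falling into the *higher* tier. Fragment ladders are singly
charged b/y series (CID, parent charges 2–4; a/c/z ions out of scope);
modifications travel with the fragment that contains them, and
b_i + y_(n−i) equals the neutral mass + 2 protons by construction.
Manual validation requires ≥ 3 consecutive ions within one series.
Sequence coverage is the interval union of accepted PSMs over the *full*
prepropeptide (signal included), half-up rounded; it is monotone
non-decreasing as the tier requirement is relaxed.

# The synthetic fixture generator

`generateFixtures()` plants prepropeptides with known truth: a
16-residue signal peptide whose h-region the heuristic always finds
within ±3 residues, a neutral pro-region, dibasic sites flanking the
mature peptide, and an acidic tail. Default study conditions: 8 AMP
families and 6 decoy families, each copied into 4 pseudo-genomes with
5% i.i.d. per-residue substitution; 3 planted copies of a known AMP for
the exclusion screen. AMP matures are cationic-amphipathic
(KLAKLAK-style template with family-specific divergence), chosen so the
three reference rules flag them with wide margins; half the decoys are
*GO decoys* — AMP-like sequences carrying a blocklisted GO term, the
protease-inhibitor-style false positive the GO stage exists to remove —
and the rest are neutral sequences the ensemble itself should reject.
Substitutions never touch the h-region or the dibasic motifs, so truth
coordinates stay valid. Tool-call tables are synthesised from the
reference rules with an 8% per-tool label flip, giving controllable
consensus outcomes. Bundles are byte-identical for a given seed.

What the generator does *not* emulate: indels and phylogenetic
correlation between copies (substitutions are i.i.d.), compositional
biases of real proteomes, multi-peptide precursors with heterogeneous
mature peptides, and realistic GO/TPM sparsity. Passing tests therefore
demonstrate the machinery is correct under the planted model, not that
the heuristics match neural-network predictors on real proteomes.

# Numerical choices

* Half-up rounding (`floor(x + 0.5)`) for all reported percentages and
  integer µM values; R's default banker's rounding would map 6/11 to
  54.5 → 54 and break the published score lattice.
* Boundary inclusivity: 150 aa precursors, 10 and 99 aa peptides, TPM
  exactly 2 (not expressed), PSM scores exactly at 47.4/20/13 (higher
  tier), group length ties at exactly 50% (retain) — each is asserted at
  the boundary in the tests.
* Local alignment scores are clamped at 0 (the empty alignment), making
  the bit score well defined for unrelated sequences.
* Group ids are assigned by descending size then smallest member id, and
  members are listed by id, so grouping output is invariant to input
  order.
* Dedup keeps the first duplicate in input order (the choice is
  arbitrary but must be fixed for reproducibility).

# Problem sizes in the test suite

The shipped tests run the generator at its default conditions (14
families + 3 known-AMP copies across 4 genomes, ~59 precursors, ~1,700
candidate peptides), verify the aligner against a brute-force
affine-gap DP on 200 random pairs of length ≤ 60, and check grouping
against a union-find oracle over the exact pairwise bit-score matrix of
the planted precursors. These sizes exercise every code path while
keeping the whole suite under a minute.

# Known limitations

* The signal-peptide and convertase heuristics are intentionally crude;
  on real proteomes they will both miss and over-call cleavage sites,
  and results there should use real predictor output via the annotation
  TSV.
* Karlin–Altschul constants are fixed, not estimated per scoring system;
  bit scores for non-default matrices or gap costs are nominal.
* E-values, composition-based statistics and HSP chaining are out of
  scope; the 100-bit criterion is a raw similarity threshold.
* GO filtering matches accessions only — no ancestor propagation across
  the ontology graph.
* The two-cysteine class is reported but not prioritised; disulfide
  connectivity is never predicted.
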