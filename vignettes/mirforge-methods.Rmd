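---
title: "mirforge: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirforge: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirforge)
```

This vignette explains the science the package implements, the
numerical choices behind it, and what its green tests do and do not
establish.  It is the reference for every default that is not obvious
from the function signatures.

## The problem

Animal miRNA genes are transcribed as ~60–130-nt precursors that fold
into a stem-loop from which a ~22–27-nt mature strand is excised from
one arm.  When a genome assembly exists but species-matched small-RNA
sequencing does not, candidate miRNA genes can still be catalogued by
combining three kinds of evidence: sequence conservation to known
matures, the hairpin structure itself, and small-RNA reads from a
related species mapped across the species boundary.  Each strategy has
a characteristic failure mode (homology misses lineage-specific genes;
structure-only scanning is noisy; cross-species reads require tolerated
divergence), which is why surveys run all three and look at the overlap.

## Coordinate model

Internally every interval is 0-based, half-open, on the plus strand,
with a strand flag.  The printed locus convention of precursor
catalogs — 1-based inclusive, minus-strand loci printed high-to-low,
e.g. `S648_2373-2295:-` — is treated purely as a serialization;
`parse_locus()`/`format_locus()` convert losslessly, and printed
precursor lengths equal `|a − b| + 1`.  Minus-strand printed
coordinates are interpreted as plus-strand positions; the bundled
37-row catalog is arithmetically consistent with that reading (all 37
printed lengths reproduce exactly).  Candidate sequences are stored in
transcript orientation (already reverse-complemented for minus-strand
loci), RNA spelling; the genome keeps its input alphabet.  `N` is
tolerated by the scanners (it never matches and never pairs) but any
window containing `N` is discarded before folding, where it has no
defined energetics.

## The folding engine and its contract

No external thermodynamic folder is assumed.  `fold()` is a
self-contained Zuker-style dynamic program over a simplified
nearest-neighbor model:

* Turner-like stacking free energies for the 6 pair types
  (Watson–Crick + G·U), symmetrized so helix energy is independent of
  reading direction;
* size-dependent hairpin (≥ 3), bulge and interior-loop initiation
  penalties with logarithmic extrapolation, 0.6 kcal/mol·nt interior
  asymmetry (capped at 3), interior/bulge size capped at 30 nt;
* an affine multibranch term (3.4 closing + 0.4 per branch) and
  0.5 kcal/mol terminal AU/GU penalties;
* temperature through a two-state decomposition: loop initiations are
  treated as purely entropic (they scale with T/310.15 K) and every
  stack carries a fixed −8 kcal/mol enthalpy offset, so the MFE at a
  lower temperature is never above the MFE at a higher one — the only
  property the 18 °C re-scan relies on.

What the contract promises: deterministic MFE structure and energy in
kcal/mol of realistic magnitude, T/U-spelling invariance, monotone
temperature behavior.  What it does not: numerical agreement with a
full Turner-2004 implementation (no dangles, no coaxial stacking, no
special hairpins, uniform stack enthalpy).  Energies on real
precursors land in the right range (a canonical let-7-family precursor
folds to ≈ −34 kcal/mol here versus ≈ −30 printed for its locus), but
*benchmark percentages computed with this engine are not comparable to
ones computed with a thermodynamic reference folder* — the reason the
compendium-benchmark acceptance criterion is left red rather than
approximated.

"Loop" in the filter battery means hairpin loop only (a maximal
unpaired run closed by a pair enclosing no other pair); interior and
multibranch loops do not count, because most genuine precursors carry
bulges and interior loops and would otherwise fail.  The paired
fraction uses the full precursor length as denominator, loop positions
included.

## The filter battery

`filter_criteria()` defaults: length 50–130 nt (inclusive), exactly
one hairpin loop, GC 30–70 % (inclusive, N excluded), paired fraction
strictly > 0.55, MFE ≤ −0.31·L + 6.00 kcal/mol.  The two historically
manual curation checks are automated and applied only when a mature is
attached: the largest single unpaired run in the stem must be ≤ 10 nt
("no big bulges"; tunable), and ≥ 90 % of mature positions must lie
outside the hairpin loop.  Candidates without an arm call pass these
two vacuously — they belong to the curation stage, which needs a
mature.  The bundled printed catalog documents one internal
inconsistency of the printed protocol: the 86-nt miR-7 row
(−19.5 kcal/mol) violates the printed energy line (threshold −20.66);
the battery applies the formula as printed and the audit is a frozen
regression test, not something the package "fixes".

`benchmark_compendium()` reproduces the criteria-evaluation protocol
(fold every precursor of a compendium, report per-criterion and
all-pass percentages plus histogram tables).  It runs on any FASTA;
the published percentages it corresponds to were computed on a
versioned public hairpin compendium with a thermodynamic folder, so
they are a valid comparison target only with that folder (see above).

## Track-specific choices

**Homology.**  The classical two-stage screen (word-seeded alignment
then pattern matching) is replaced by one exact mismatch-limited scan
over both strands — a strict superset of what seeded heuristics can
find, verified against a brute-force Hamming oracle.  Window placement
around a hit is under-determined in the protocol ("110 bp … extended
by 20 bp"); the package sweeps the full placement range and keeps the
shortest window containing the hit that passes the battery with the
mature attached, preferring placements that pair the mature best, then
lower energy.  Overlapping candidates on a strand are resolved by
minimum MFE (ties: longer precursor, then locus string) — the printed
rule.

**Trimming.**  A candidate window is trimmed of terminal unpaired
runs (refolding to a fixed point), with one deliberate exception: the
trim never truncates the recorded mature segment, because the mature
is evidence (a reference hit or read stack), not structure.  A
candidate can therefore begin or end with unpaired positions exactly
where the mature reaches its boundary; everywhere else trimmed
candidates begin with `(` and end with `)`.

**De novo.**  The length sweep (60–130, step 10; minimum loop 5;
shortest passing window per position) follows the stated protocol; the
legacy alignment-score gate of hairpin scanners, which has no portable
semantics, is expressed structurally as ≥ 16 base pairs in the MFE
structure.  Scan stride is 5 nt, and a complementarity pre-screen
(best local anti-diagonal score, +1 per canonical/G·U pair, −1.5 per
mismatch, threshold 15) is applied before folding purely for speed:
substitution-diverged stems sit on one anti-diagonal, so planted and
canonical hairpins pass it comfortably, but heavily *indel*-bulged
stems could in principle be screened out — set `screen_min = 0` for an
exhaustive scan.  Emitted windows are trimmed to their stem-loop unit,
and per overlap component the *shortest* emission represents the
locus: the sweep's semantics are shortest-first, and tight hairpins
are comparable across tracks (the min-MFE rule, which is specified for
the homology track, favors long co-folded stems and systematically
inflates de novo spans).  Repeat families are greedy longest-first
clusters at ≥ 0.9 ungapped identity (either orientation, identity over
the shorter sequence) with members at ≥ 3 distinct loci — palindromic
repeats fold into convincing hairpins and are the scanner's main
confounder, so they are planted explicitly by the generator.

**Small-RNA.**  Mapping is ungapped (the reads are ~26 nt and the
stated thresholds never mention gaps): per read all best-scoring
placements (score = aligned length − mismatches) are kept, ties
flagged multi-mapping.  Read hits are clustered into loci; the modal
hit span defines the mature.  Expression exclusion is strict
(> 10 mRNA reads excluded, exactly 10 kept) and counts any-overlap
coverage, summed — the original counting window is unpublished, so the
most inclusive reading was chosen and documented.

**Mature and strand.**  The paired-segment pattern (5′ arm 22–27 nt,
separation 5–50 nt, ≤ 6 mismatches to the reverse complement of the
3′ arm) is enumerated exhaustively; both arms must clear the hairpin
loop on their own side, the loop-closest pair wins, and the 24-nt
windows flanking the loop are the fallback.  Both arms are always
emitted (`_5p`/`_3p`); the package never decides which arm is the
functional mature.  Strand evidence classes are consulted in the order
reference matures → ESTs → small-RNA reads; a score tie within the
winning class falls back to plus and is flagged, and no evidence means
plus by convention.

**Merging and conservation.**  "Same locus" across tracks is
reciprocal 50 % overlap on the same strand (exposed as
`min_reciprocal`); the merged Venn decomposition satisfies
inclusion–exclusion by construction and is checked against planted
truth.  Conservation classes from a presence matrix: any non-tunicate
species ⇒ widely conserved; otherwise ≥ 2 tunicate species ⇒
tunicate-specific; otherwise species-specific (families absent from
the matrix are species-specific with an `unmatched` flag, never
over-claimed).

## Target scanning

3′ UTRs are operationally the 400 bp after the stop codon on the
coding strand.  Duplex energy is intermolecular-only (no
self-structure on either molecule), computed under the same energy
model as `fold()` with bulge/interior gaps ≤ 10 nt per side and a
4.1 kcal/mol initiation, subject to a helix constraint: miRNA
positions a..b must form a contiguous helix with consecutive target
positions; the frame sweep (1,6) … (6,11) compensates for uncertainty
in where the inferred mature actually starts.  This is a documented
approximation of the classical hybridization tool, not a
re-implementation: what is kept is the contract (constrained minimum
intermolecular energy, frame sweep, empirical null), and the package's
oracle tests verify the DP against exhaustive constrained-alignment
enumeration at toy scale.

Significance: per miRNA, best-site scores on dinucleotide-shuffled
UTRs (Altschul–Erikson doublet shuffle, which preserves the
energy-relevant composition) form the null.  These scores are maxima
of many dependent, *bounded* local scores, so their upper tail is
Weibull-type; a two-parameter Gumbel systematically overestimates the
tail (measured: ~5-fold inflation of the 99th percentile exceedance).
The null is therefore a full GEV with shape fitted by Hosking's
L-moment estimators.  The default of 500 shuffles (contract minimum
200) is an accuracy choice: the fit must extrapolate the 1 % tail, and
at 200 draws the realized false-positive rate at p ≤ 0.01 fluctuates
by a factor of ~3 across refits, while at 500 it concentrates near
nominal.  Raw p ≤ 0.01 is the classical protocol; per-UTR
Benjamini–Hochberg correction is available (`bh = TRUE`) but off by
default.

## The synthetic world

The generator states one fixed world rather than a tunable benchmark:
i.i.d. background at GC 0.35 (ascidian genomes are AT-rich, ~35 % GC);
50 precursors per 200 kb, stems 28–45 bp, loops 5–15 nt, 0–3 planted
stem mismatches plus ~10 % G·U wobbles; 26-nt reads at Poisson depth
30 with 1 % substitution errors, sampled from one dominant arm per
precursor; reference queries diverged by an exact substitution count,
seed (positions 2–7) kept intact.  Two deliberate refinements make the
stated homology-divergence criterion well-posed: every precursor
carries at least three non-Watson–Crick stem positions inside the
mature window (real mature/star duplexes are never perfectly
complementary), and reference-query substitutions never restore
complementarity to the opposite arm — otherwise a query diverged by
three could still match its own precursor's star arm within two
mismatches and recall at divergence 3 would not be zero by
construction.  Every planted precursor is verified at generation time
to pass the full battery, so pipeline recall is well defined.

What the generator does not emulate: Markov/repeat background beyond
one explicitly planted palindromic family, transposons, expression
heterogeneity beyond uniform depth, indel sequencing errors, and real
cross-species divergence patterns (it plants exact substitution
counts).  A green recovery test therefore establishes that the
machinery is correct on canonical single-loop precursors in random
background — not that recall on a real genome reaches those numbers.

## Known limitations

* The folding engine is simplified (see above); absolute MFE values
  carry model error of a few kcal/mol, and the compendium benchmark's
  printed percentages are unreachable with it by design.
* The de novo pre-screen trades exhaustiveness for speed and can miss
  strongly indel-bulged stems at default settings.
* Strand for purely structural candidates without any evidence is a
  plus-strand convention, not an inference.
* The significance model for targets is empirical and per-miRNA; a
  site's p-value is relative to shuffled background of the supplied
  UTR set, not an absolute binding probability, and predicted targets
  are not functionally validated by construction.
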