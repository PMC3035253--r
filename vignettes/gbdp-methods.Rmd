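---
title: "Genome-to-genome distances and in-silico species delineation with gbdp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-to-genome distances and in-silico species delineation with gbdp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdp)
```

## The problem

Bacterial and archaeal species are pragmatically defined through DNA-DNA
hybridization (DDH): when two strains' genomic DNA re-associates at 70% or
more, they are conventionally regarded as one species. DDH is laborious,
poorly reproducible, and each experiment's result cannot be reused to
build a comparative database. With genome sequences now cheap, the natural
replacement is a genome-to-genome distance (GGD) computed from the
sequences themselves, calibrated so that a distance threshold plays the
role of the 70% DDH boundary. `gbdp` implements this workflow end to end:
match-based distances, threshold calibration, evaluation statistics, and a
simulator for studying how incomplete genome sequencing perturbs each
distance.

## The distance model

The raw material is a pair of *directed match sets*: all local matches
found by querying genome $x$ against genome $y$, and all matches from the
opposite direction. Matches are either HSPs (high-scoring segment pairs
from BLAST-family programs, carrying an alignment length, an identity
count, a score and an e-value) or MUMs/exact matches (identities equal to
length; the match length stands in for the missing score). From a reduced
match set we accumulate per direction

- $H_{xy}$: the total match length, and
- $I_{xy}$: the total number of identical base pairs,

and from the genome pair the normalizing length $\lambda(x,y)$, either the
sum of the two genome lengths or twice the length of the shorter genome.
Three similarity families are formed:

$$s_1 = \frac{H_{xy}+H_{yx}}{\lambda},\qquad
  s_2 = \frac{I_{xy}+I_{yx}}{H_{xy}+H_{yx}},\qquad
  s_3 = \frac{I_{xy}+I_{yx}}{\lambda},$$

each yielding a distance $d = 1-s$ clamped to $[0,1]$, with an optional
monotone log transform $d' = -\ln(1-d)$. The two $\lambda$ variants
(family 2 has no length term) and the log switch give ten distance
functions, canonically numbered 0–9: 0–3 are family 1, 4–5 family 2, 6–9
family 3; within families, indices 0, 2, 6, 8 use the length sum and 1, 3,
7, 9 twice the minimum length; 2, 3, 5, 8, 9 are the log variants.

Three structural properties matter in practice and are enforced by tests:

- **Rank invariance of the log transform.** $-\ln(1-d)$ is strictly
  increasing on $[0,1)$, so any rank-based analysis (Kendall correlation,
  threshold ordering) is bit-identical between a base function and its log
  variant. Any other monotone log form would behave identically under
  ranks, so the choice is observationally equivalent for ranking purposes.
- **Length independence of family 2.** $s_2$ contains no genome length, so
  appending non-homologous sequence to one genome — or deleting parts of
  it — leaves the distance unchanged as long as the match inventory is
  unaffected. This is the mechanism behind family 2's robustness for
  incomplete genomes.
- **MUM degeneracy.** For exact-match input $I = H$, so family 2 is
  identically 0 (the package warns when family 2 is requested on
  identity-only sets) and families 1 and 3 coincide. Family 2 is only
  informative for HSP-like input whose matches contain mismatches.

Degenerate inputs are mapped deterministically: a pair with no matches at
all has distance 1 under every family (family 2's 0/0 is defined as
maximally distant); similarity ratios above 1, which can only arise in the
raw coverage mode with repeats, clamp to distance 0; before a log
transform the distance is capped at $1-10^{-12}$ so the transform stays
finite.

The displayed forms above are a reconstruction from the component
definitions, the distance orientation, and the stated properties (length
independence of family 2, MUM degeneracy, the 0–9 numbering); all of these
are verified by the test suite.

## Overlap removal

Repeats inflate $H$ and $I$: one repetitive segment can appear in many
matches. The *greedy-with-trimming* algorithm removes this multiplicity:
matches are visited in descending score order (ties: longer first, then
lexicographic coordinates, making the output platform-independent); each
candidate is clipped against the union of already-accepted intervals on
the query side and on the subject side; clipped ends shrink the opposite
side, the alignment length and the identity count proportionally
(identities rounded down); a candidate split internally by an accepted
interval keeps its single longest fragment (ties: leftmost); fully covered
candidates are dropped. The result has zero pairwise overlap on both
genome sides, never exceeds the input's total length, and is idempotent.
Keeping one fragment per candidate (rather than emitting all fragments)
keeps the provenance one-to-one; it is a documented choice where the
algorithm's name underdetermines the behaviour, and it can only make the
retained totals smaller, never larger.

Clipping proceeds query side, then subject side, then a final query
re-check. Each clip replaces both intervals by sub-intervals, so a side
that is already disjoint from the accepted unions stays disjoint and the
fixed point is reached within these three passes.

The *coverage* variant skips trimming. Its default bookkeeping collapses
match footprints so every genomic position counts once per side: with
$|U_q|, |U_s|$ the footprint-union lengths and $L_q, L_s$ the raw span
sums, totals are scaled by $c = \min(1, |U_q|/L_q, |U_s|/L_s)$, preserving
the identity fraction $I/H$ and reducing to the identity on overlap-free
input (where trimming and coverage then agree exactly). A literal raw-sum
mode (`mode = "raw"`) that multi-counts overlaps is available; it can push
similarities above 1 for repeat-rich genomes, which the distance clamp
absorbs.

## Threshold calibration

Given a calibration table of genome pairs with both a GGD and a wet-lab
DDH percentage, `ggd_threshold()` finds the distance threshold $T$
minimizing the *error ratio*: (false positives + false negatives) / N,
where a false positive is a pair with distance at most $T$ but DDH below
the cutoff (default 70%), and a false negative the converse. The boundary
is inclusive — distance exactly $T$ predicts same-species. The error ratio
is piecewise constant with breakpoints at observed distances, and the scan
evaluates it on a 1001-point grid from the observed minimum to the maximum
inclusive (step width 1/1000 of the range), returning the smallest grid
threshold attaining the minimum. Smallest-$T$ tie-breaking is
reproducible and conservative toward calling pairs different species. The
DDH cutoff is a parameter because some genera accept boundaries other
than 70%. The fit is a classed object with `print`, `summary`, `coef`,
`predict` and `plot` methods; `predict` applies the threshold to new
distances.

Two caveats follow from the grid construction and are reflected in the
tests: the grid cannot express a threshold below the smallest observed
distance, so the "call everything different" classifier is only
approximable to within the record sitting at the minimum; and grid and
breakpoint scans agree exactly only when every gap between consecutive
observed distances exceeds the grid step.

## Evaluation statistics

Method comparison uses Kendall's tau-b (tie-corrected; DDH tables contain
tied values) as the primary statistic — rank-based correlation is
indifferent to the saturation of some distance formulas and to the log
transform — with Pearson's r reported for reference. Euclidean distance
between a complete-genome GGD vector and its incomplete-genome counterpart
quantifies simulation drift; it is unnormalized, which is monotone per
fixed vector length either way. Uncorrected p-distances from a supplied
16S rRNA alignment use pairwise deletion: alignment columns holding a gap
or any ambiguity character in either sequence of a pair are excluded, and
U is read as T. Correlations are computed through `stats::cor`; the
p-distance is a direct implementation of the pairwise-deletion rule
(cross-checked in the tests against `ape::dist.dna(model = "raw",
pairwise.deletion = TRUE)` on gap-only data, whose ambiguity handling
differs).

## Simulating incomplete genomes

`simulate_incomplete()` emulates partial sequencing per replicon: the
Lander-Waterman read count $N = \lceil G(-\ln(1-p))/L \rceil$ for target
retained proportion $p$ and fixed read length $L$ (default 700 bp, a
realistic single-read length) is drawn as uniform read start positions
(with replacement); each read marks $L$ downstream positions sequenced,
truncating at the linear replicon end (no wrap-around; terminal coverage
is slightly depressed, negligibly for $G \gg L$); unsequenced positions
are removed, leaving disjoint contigs that are exact substrings of the
input. Reads are error-free by construction, so the simulation isolates
the effect of *missing* sequence; it does not model sequencing error,
chimeric assembly, or quality decay at low coverage, and conclusions about
robustness are accordingly optimistic for real drafts. Replicate $r$ of a
run uses seed $\texttt{base\_seed} + r$, making every run exactly
reproducible.

## The synthetic genome-pair generator

`generate_genome_pair()` provides the test bed: genome A uniform over
{A,C,G,T}; genome B derived by iid point substitutions (each hit site
switches to a uniformly chosen different base), non-overlapping segment
deletions (placed one per equal-width block), and optional appended copies
of a repeat segment. It emulates the features the distance machinery must
handle — point divergence, missing segments, shared repeats — but not
genome-scale compositional structure (GC skew, codon bias), indel-rich
alignment, or horizontal transfer; passing tests therefore demonstrate
algorithmic correctness and the claimed structural properties, not
field performance on real genome pairs, whose match inventories come from
external aligners.

Because the built-in matcher reports exact matches, synthetic pipelines
behave like MUM-based ones: family 2 saturates at 0 whenever any match
exists. The robustness experiments in the tests and the acceptance script
exploit exactly this regime, mirroring how MUM-based distances behave,
while HSP-like behaviour is exercised through parsed BLAST tables with
identities below the alignment length.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale data chosen to
exercise every code path while keeping a full run in minutes on one core:
synthetic genomes of 1–50 kb (one 0.5–1 Mb replicon for the
Lander-Waterman calibration, where island statistics need length), 20-pair
robustness studies at 50% deletion, 100–200 random cases per
property-style test, exact-matcher oracles on sequences of a few hundred
bp. Key defaults: internal matcher minimum match length 20 bp (8 bp is
the hard floor, below which seeding is dominated by chance matches);
e-value filter 1e-2; DDH cutoff 70%; threshold grid 1000 intervals; read
length 700 bp. The default distance specification is family 3 with the
length-sum denominator and trimming — the best-performing HSP-based
combination — while family 2 is the recommendation when genomes are known
to be substantially incomplete.

## Known limitations

- The internal matcher corresponds to `mummer -maxmatch` semantics:
  maximal, not necessarily unique, matches; MUM uniqueness filtering is
  not reproduced (trimming handles the repeats uniqueness would remove).
- BLAST identity counts are reconstructed from percent identity
  (`round(pident * length / 100)`), exact to under 1 bp per HSP.
- Distance matrices are computed in a pairwise loop; very large genome
  collections are better served by chunking at the caller level.
- The threshold is optimized on the full calibration set, as is standard
  for this calibration; no cross-validation is performed.
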