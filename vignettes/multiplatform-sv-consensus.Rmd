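---
title: "Multi-platform somatic SV integration and Hi-C junction detection: methods"
author: "svconsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform somatic SV integration and Hi-C junction detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svconsensus)
```

# Scope

`svconsensus` implements the integration machinery used to build a
high-confidence somatic structural-variant (SV) call set from many
sequencing platforms and callers, together with a Hi-C contact-matrix
rearrangement detector. This vignette documents the model behind each
stage, the tunable parameters and their defaults, the numerical choices
made where the procedure left room, and the known limitations — in
particular what the synthetic data generator does and does not emulate,
and hence what passing tests do and do not show about real data.

# The integration model

## Records, call sets, size classes

An SV record carries two breakends (1-based), a type
(DEL/DUP/INS/INV/TRA/BND) and an absolute size in bp. Translocations and
unresolved breakends have size 0 and are exempt from all size logic;
insertions have coincident breakends and carry the inserted length.
Breakends are stored in canonical order so that all pairwise comparisons
are orientation-free.

A call set is the output of one (platform, tool, replicate, sample)
combination. The full design emulated here is 4 Illumina tools and 2
linked-read tools at 11 replicates each, plus single-replicate PacBio,
ONT and Hi-C tools — 71 tumor call sets and their matched normals.

Merging operates per size class, with upper-inclusive boundaries and one
merge window per class:

| class | size range (bp) | window (bp) |
|---|---|---|
| 1 | 50–100 | 50 |
| 2 | 101–500 | 100 |
| 3 | 501–1000 | 500 |
| 4 | 1001–30,000 | 1000 |
| 5 | >30,000 and all TRA/BND | 10,000 |

A 100 bp SV belongs to class 1 (upper-inclusive tie-break). Records
under 50 bp are rejected as sub-threshold.

## Windowed merging and somatic subtraction

Two records are linkable iff they share a type, both breakend
chromosomes match, and both breakend positions differ by at most the
class window; insertions compare the insertion point plus reciprocal
size similarity ≥ 0.5, because their END coordinate is degenerate.
Merged groups are **connected components** of this relation (transitive
merging): two members of one cluster may individually violate the
pairwise rule. This mirrors how chained window-based merging behaves in
practice and is what the oracle tests verify against a brute-force
transitive closure.

A tumor cluster is somatic iff no normal-sample cluster is linkable to
its representative at the same window. The subtraction window defaults
to the class merge window but is exposed as a parameter, since for small
SVs the choice is a judgment call.

The cluster representative is the member with the highest replicate
support for its (platform, tool), with ties broken by smallest
coordinate and then lexicographic id; this makes every downstream table
deterministic under permutation of the inputs.

## Similarity clustering, exclusions, consensus scores

Merged SVs of the same type additionally cluster when their reciprocal
size similarity `min(s_a, s_b) / max(s_a, s_b)` exceeds 0.5 (TRA exempt)
and their breakends fall within the class clustering window (TRA:
10 kb). When a pair spans two classes the larger window applies.

Before scoring, member contributions can be excluded by a provenance
predicate; the packaged default removes 10X Long Ranger deletions under
20 kb, which are unreliable at that scale. Counts are recomputed and
clusters left empty are dropped.

Frequencies are computed against a **replicate census**, never against
hard-coded denominators:

* per-tool frequency — distinct replicates of the tool containing the
  SV over the replicates the tool was run on (0 or 1 for
  single-replicate tools);
* per-platform frequency — distinct (tool, replicate) call sets on the
  platform containing the SV over the platform's census total (44 for
  four Illumina tools with 11 replicates);
* consensus score — the sum of per-tool frequencies.

A tool is identified by its (platform, tool) pair: the same caller run
on two platforms counts as two tools, matching how the study design
tallies call sets. The **initial** set keeps clusters present in at
least two (platform, tool, replicate) call sets, outside the blacklist
and on primary chromosomes; the **high-confidence** set additionally
requires at least two platforms *and* at least two tools, then removes
clusters in supplied loss-of-heterozygosity regions. The chain is
monotone by construction.

# The Hi-C detector

## Statistic

Read pairs with both MAPQ strictly above 20 are binned at width
`w` = 50 kb into a symmetric contact matrix `N`. For a bin pair (i, j),
`N+` sums the north-east and south-west quadrants out to range `R` and
`N-` the north-west and south-east quadrants; each sum's two terms
include the center row, column and cell, exactly as the defining
formulas state, so the center cell is double-counted inside `N+` and
inside `N-` (implemented literally; the shared cross cancels in the
difference `N+ − N−`). The z-scores are

$$Z^+ = \frac{N^+ - N^-}{\sqrt{N^-}}, \qquad
  Z^- = \frac{N^- - N^+}{\sqrt{N^+}},$$

with denominators floored at 1 so they stay finite and monotone in the
numerator. Candidates are bin pairs where `max(Z+, Z−)` exceeds `Z_min`
and is a local maximum within a Chebyshev range of 3 bins (3w).

`R` is not prescribed anywhere; the default `R = 10` bins spans 500 kb
at the initial bin width, comfortably inside the ±2 Mb refinement
window, and is configurable.

## Numerical choices that the statistic forces

Three behaviours of the literal statistic shaped the implementation:

1. **Chromosome-block truncation.** A quadrant window that crosses from
   one chromosome block into the next sweeps up the neighboring
   chromosome's near-diagonal mass; at depth 5 this produced dozens of
   spurious boundary candidates per null matrix. Quadrant windows
   therefore stop at chromosome-block boundaries. (The exported
   `quadrant_sums()` keeps the plain matrix-edge truncation, as its
   contract states.)
2. **Intra-chromosomal decay centering.** On the distance-decay
   background, the south-east quadrant of an intra-chromosomal pair
   always sits closer to the diagonal than the north-west quadrant, so
   `E[N−] > E[N+]` systematically — just outside the suppressed diagonal
   band the systematic `Z−` exceeds 10 at default depth. Raw-count
   z-scores on intra pairs therefore cannot have a clean homogeneous
   null. Intra-chromosomal pairs are scored with a decay-centred
   standardized contrast instead:
   $$\tilde Z = \frac{(N^+ - N^-) - (E^+ - E^-)}{\sqrt{V}},$$
   where `E` is the expected matrix (per-offset mean counts pooled
   across chromosomes — the standard observed/expected estimate, with a
   constant for inter-chromosomal cells) and `V` is the expected
   variance contributed by the strictly interior quadrant cells (the
   shared center cross cancels in the difference). Inter-chromosomal
   pairs keep the literal formulas. Intra pairs within `R` bins of the
   diagonal are suppressed.
3. **Satellite maxima and refinement.** On a sparse inter-chromosomal
   background the global `max(Z+, Z−)` often sits at satellite cells
   about `R` bins off the junction: there one quadrant pair catches a
   signal arm while the opposite pair is nearly empty, so the floored
   denominator is tiny, while the junction corner holds the bright
   center cross in its own `N−`. This is a property of the statistic,
   not a bug, and it is why breakpoint refinement exists: the
   exponential quadrant kernels correlate the ±2 Mb submatrix and their
   global maximum consolidates every satellite onto the junction itself.
   Localization claims in the tests are therefore made on the refined
   top candidate — the pipeline's actual breakpoint output.

## Refinement and classification

Two kernels with values `exp(−(|dx| + |dy|) · w / decay)` — one
supported on the NE/SW quadrants, one on NW/SE — are cross-correlated
with the contact submatrix extending ±2 Mb around the candidate
(truncated at chromosome ends). The larger of the two correlation maxima
gives the refined breakpoint at bin-center resolution; ties break toward
the NE/SW kernel and then the smallest coordinates, and an all-zero
submatrix falls back to the candidate bin centers with a flag. The decay
constant defaults to 5 bins (250 kb at w = 50 kb) and is configurable.
For a one-sided flat
block the kernel argmax provably sits inside the quadrant rather than at
its corner (both kernel quadrant supports collect from the single block
at interior positions); exact corner recovery holds for the two-sided
junction pattern the kernels model.

Classification computes the read-pair sum in each of the four R-bin
quadrants around the refined breakpoint and calls a quadrant *elevated*
iff its observed sum exceeds `theta` (default 3) times its expected sum
under the same decay model **and** holds at least `min_pairs` (default
5) read pairs. The expected-sum comparison absorbs the decay gradient
across intra-chromosomal quadrants; the absolute floor keeps a single
stray pair in an otherwise empty quadrant from counting. Two simpler
backgrounds were tried and rejected: the ring median collapses to 0 on
sparse counts (stray pairs then count as elevated) and the ring mean is
contaminated by the implant's own decay tails (duplication templates
then fail the theta test). The decision table — one elevated quadrant:
non-reciprocal translocation (inter) or deletion (intra); two diagonally
opposite: reciprocal translocation (inter) or inversion (intra); all
four: segmental duplication; anything else: unclassified — is this
package's own reconstruction of the canonical contact signatures of
each event class. No learned post-classifier is used: candidate
filtering is the deterministic score/read-support rule of
`filter_candidates()`, so every decision in the chain is auditable.

# The synthetic data generator

The generator produces every input the pipeline needs, at desk scale:

* **Genome**: three 20 Mb chromosomes with a 2% mappability blacklist.
  All Hi-C calibration statements below refer to this genome.
* **Truth sets**: non-overlapping somatic and germline SVs with
  log-uniform sizes per type; the default composition (70 DEL, 25 DUP,
  55 INS, 15 INV, 15 TRA somatic) follows the shape of a real
  breast-cancer consensus set at roughly one-tenth scale, with sized
  types capped at 100 kb so the toy genome can host them without
  overlap.
* **Caller emulation**: per-platform sensitivity tables (long reads
  strongest for insertions and sub-kilobase SVs, short reads good for
  mid-size deletions but weak for insertions, linked reads favouring
  large events, Hi-C limited to megabase-scale events and
  translocations), Gaussian breakpoint jitter (10–50 bp for sequencing
  platforms, 25 kb for Hi-C), multiplicative size jitter, and uniform
  false positives per Mb. These numbers are simulation defaults
  encoding qualitative platform behaviour, not measured values. Truth
  ids travel in a reserved INFO key so evaluation can compute exact
  recall; the pipeline itself never reads them.
* **Hi-C matrices**: Poisson background with mean `depth / (1 + d/w)`
  at intra-chromosomal distance `d` and `depth / 5000` for
  inter-chromosomal pairs (a realistic inter/near-diagonal contact
  ratio at 50 kb bins). Each implanted rearrangement adds a fresh
  distance-decay diagonal emanating from its junction at
  `signal_factor × depth / (1 + s)` for taxicab offset `s`, on the
  NE/SW quadrants (reciprocal translocations, inversions), one quadrant
  (non-reciprocal translocations, deletions) or all four
  (duplications). A flat 5× inter-chromosomal constant would be both
  undetectable and physically wrong — a real fusion junction behaves
  like a new diagonal.
* **Purity titration**: a somatic SV is detected at tumor purity `p`
  and depth `D` iff a Poisson draw with mean
  `D × p × het_fraction × capture_eff` reaches `min_support`. Defaults:
  het_fraction 0.5 (heterozygous SV allele fraction), capture_eff 0.4
  (fraction of junction-spanning pairs that are informative),
  min_support 3 (the minimum supporting-read count typical of the
  callers emulated, e.g. Sniffles' `-s 3`). Germline SVs are present at
  purity 1 regardless of the tumor fraction. With these constants,
  detection at 100X saturates above 50% purity and collapses below 20%,
  reproducing the qualitative titration finding the model targets.

**What the generator does not emulate** — and hence what green tests do
not establish about real data: read-level errors and alignment artifacts
(breakpoint jitter is Gaussian, real callers err systematically near
repeats), sequence-resolved insertions, coverage waviness and GC bias,
clustered/complex rearrangements (implants are placed independently),
matrix normalization effects in Hi-C, and caller-specific FILTER
semantics beyond PASS. The replicate design is also idealized:
replicates are exchangeable draws, whereas real technical replicates
share library- and center-level biases, so real-data replicate support
is more correlated than simulated support.

# Evaluation

Recall/precision use exact truth-id matching when simulator ids are
present and fall back to distance matching (the orthogonal-matching
rules with the size floor dropped from 500 bp — an optical-mapping
resolution limit — to the 50 bp SV definition) otherwise; the two agree
within 1% when jitter is well inside the merge window, which is itself a
tested property. Cross-platform relative sensitivity is the proportion
of a reference platform's calls reproduced by another platform,
asymmetric by construction with unit diagonal. Orthogonal validation
follows the optical-mapping clustering criteria: sized types above
500 bp with >50% reciprocal similarity within 10 kb; translocations
within 50 kb, orientation ignored; greedy one-to-one assignment by
ascending breakend distance.

# Problem sizes

The shipped analyses and tests run the full study design (142 emulated
call sets, ~18,000 records) for integration, 1200-bin contact matrices
(3 × 20 Mb at 50 kb) for Hi-C with 20 detection and 50 null seeds, and
10-seed titration series over six purities and six depths. These sizes
were chosen so every property is exercised at full pipeline depth while
a complete run stays interactive on a laptop.

# Known limitations

* Transitive merging can chain distinct nearby events into one cluster
  when call sets are dense; the per-class window sizes keep this rare
  at realistic SV densities but it is inherent to the design.
* Size-class splitting before merging means two calls of the same event
  whose jittered sizes fall on opposite sides of a class boundary are
  merged only if the similarity clustering step reunites them.
* The Hi-C detector reports bin-resolution breakpoints (refined to bin
  centers); base-pair resolution would need the raw pairs at a finer
  refinement bin width, which `refine_breakpoint()` accepts but the
  simulator does not generate.
* Event classification assumes a single junction per ±2R neighborhood;
  overlapping events (chromothripsis-like clusters) will typically come
  out `unclassified`.
* Manual curation — the human review step that typically finalizes a
  published consensus call set — is intentionally not modelled.
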