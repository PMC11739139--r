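---
title: "Methods: simulating and detecting horizontal transfer and recombination of LTR retrotransposons"
author: "retroHTT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting horizontal transfer and recombination of LTR retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroHTT)
```

This vignette is the package's own account of its models, parameter
choices, numerical decisions and limitations. Everything quantitative
stated here is computed by the test suite or by `scripts/acceptance.R`;
nothing is quoted from external sources.

## 1. The inference chain and its assumptions

LTR retrotransposons have an LTR–internal–LTR structure: two direct long
terminal repeats flanking an internal region encoding *gag* and *pol*.
Three biological processes drive the signals this package works with:

* **Intra-element LTR recombination** excises the internal region, leaving
  a solo LTR. Hence LTR and internal copy numbers are estimated separately:
  internal sequence decays quickly after a subfamily stops transposing,
  while solo LTRs persist. Internal presence (or full-length elements)
  indicates relatively recent activity; LTR-only presence indicates recent
  or past activity; neither indicates no evidence of the subfamily.
* **Horizontal transposon transfer (HTT)** copies one element lineage into
  another host lineage. Its fingerprints are (i) incongruence between host
  and element trees, (ii) cross-lineage element pairs far more similar than
  their hosts' divergence allows, and (iii) patchy presence across host
  lineages.
* **Inter-subfamily recombination** between co-resident diverged
  subfamilies creates chimeric elements whose ancestry switches along the
  sequence, detectable as a sign change in a sliding-window divergence
  contrast against two parent representatives, and as discordant placement
  in trees built from the two sides of the breakpoint.

The package assumes haploid (or effectively haploid) host genomes, treats
substitution as the only mutational process in sequence space (no indels),
and models within-strain homogenization only through element turnover
(transposition/loss), not gene conversion.

## 2. The forward simulator

`simulateFamilyHistory()` evolves an element inventory along a rooted host
strain tree. Along every branch, sequences accumulate substitutions under
the Kimura two-parameter (K2P) model via the closed-form K80 transition
probabilities, so a branch of length *t* produces an expected *t*
substitutions per site with transition/transversion rate ratio `kappa`
(default 2, a typical nuclear value). Per-element stochastic events are
drawn as a Gillespie walk: transposition (duplication; default rate 0.25
per full-length element per unit branch length), solo-LTR formation (0.15),
one-sided truncation removing 25–80% of the element (0.08), and loss
(0.03). Scheduled events model subfamily extinction on a branch, HTT (the
recipient receives a copy of a donor-branch element state at the stated
time, so the transferred lineage truly descends from the donor at transfer
time), and recombination (a chimera built from a parent-A and a parent-B
element with stated breakpoints, alternating A/B/A... between them).

Design choices worth stating:

* **No indels.** Truth alignments of any query region are therefore exact
  positional extractions — gap-free by construction — which keeps homology
  bookkeeping exact for every downstream stage.
* **Replay.** The simulator is a pure function of (tree, parameters, seed);
  the event log records what happened, and re-running with identical inputs
  is byte-identical. This is the form of replayability the tests assert.
* **Study conditions.** The default synthetic study uses 8 strains in 4
  lineages, lineage backbone branch lengths ~0.05 substitutions/site with
  within-lineage depths 15% of that, two subfamilies ("TyA", "TyB") derived
  from one ancestor at ~12% pairwise divergence, 300-bp LTRs and 3000-bp
  internal regions, 30x coverage with 100-bp reads and 1% base error, and
  60-kb background per strain. These are scaled-down but proportioned like
  real yeast Ty panels (real Ty4-family elements are ~371-bp LTRs around a
  ~5.2-kb internal region; strain panels are deeper but shallower per
  lineage); the scale was chosen once so that a full scenario runs in
  seconds and the whole acceptance battery in minutes on one CPU.
* **Host background** is i.i.d. random nucleotide sequence split into two
  contigs per strain — sufficient for a single-copy depth baseline and
  dispersed insertion sites, nothing more. Elements are embedded with 5-bp
  target-site duplications and random strand.
* **What passing tests do not show.** Real data add indels and alignment
  error, mappability and GC biases, diploid heterozygosity, nested
  insertions and reference-assembly artifacts. Results on the simulator
  validate the inference logic, not robustness to those nuisances.

Four bundled scenarios fix the event schedules: `vertical_only` (none),
`htt_single` (subfamily TyB extinct early on the stems of lineages 3 and 4,
then re-introduced into lineage 4 from lineage 1 at mid-branch),
`htt_plus_recombinant` (additionally one single-breakpoint chimera — 5'
side from the resident subfamily, mirroring a gag-plus-start-of-pol swap —
and one two-breakpoint chimera with a swapped middle segment), and
`recombinant_only` (chimeras without HTT; this fourth preset exists so the
HTT-flag factorial has a recombination-without-transfer arm). Chimera
breakpoints are configuration values (defaults 1550 and 1100/2400 in query
coordinates), not constants.

## 3. Copy number from coverage

`simulateReadEvidence()` samples uniform read starts and projects reads
overlapping embedded copies onto query coordinates through the truth
homology map — it stands in for a read mapper without implementing one.
Depth over both LTRs is collapsed onto the 5' LTR frame, mirroring the
separate-LTR-query convention of coverage-based TE pipelines: one
full-length element contributes 2 to the LTR estimate and 1 to the
internal estimate, a solo LTR contributes 1 and 0.

`normalizeCopyNumber()` is mean depth over the full region — edges
included, deliberately — divided by the single-copy baseline (mean depth
over non-element background in synthetic mode; a user-supplied scalar on
real data, where it comes from whatever genome-wide estimator the user
trusts). `computeBreadth()` is the fraction of region positions at depth
>= 1. Profiles above 100x are binomially thinned to the cap
(`downsampleDepth()`), with the baseline rescaled so estimates are
unchanged in expectation.

Presence calls are strict: LTR copy number > 1 and internal copy number
> 0.5 (both configurable). A consequence worth knowing: a strain whose only
copy is a single solo LTR has a true LTR copy number of exactly 1 and is
called absent — a borderline the estimator will straddle at random. The
pipeline's presence-agreement metric therefore compares calls against the
same thresholds applied to the *true* copy numbers, which is the
well-defined notion of correctness for a thresholded estimator.

## 4. Annotation and classification

`defragment()` chains same-target, same-strand, same-query hits whose
target gap is at most 250 bp and whose query intervals are collinear for
the strand. The 250-bp default sits above the fragmentation gaps the
simulator emits (40–120 bp) and far below the spacing between distinct
insertions (>= 500 bp).

`classifyElement()` uses per-region query coverage: solo LTR if >= 0.8 of
one LTR and < 5% of the internal region; FLE if >= 0.9 of the internal
region and >= 0.8 of both LTRs; otherwise truncated. These three thresholds
are this package's own operational definitions (no published numeric
definition of "full-length" exists to adopt); they cleanly separate the
three classes on simulated data with up to 15% divergence and 50%
fragmentation, and they are all exposed in configuration. Note the
interaction that sets the scale: a fragmentation gap of up to ~120 bp costs
up to 4% internal coverage on a 3-kb internal region, safely inside the
0.9 threshold — on much shorter regions the same gap would misclassify, so
the thresholds and the gap scale belong together.

`detectLTRPairs()` is a seed-and-extend direct-repeat finder with
LTR-structure constraints: 16-bp exact seeds, ungapped X-drop extension
(match +2 / mismatch −2 / drop 10), repeat length 100–1000, start
separation 1500–15000, identity >= 0.80, `tg...ca` termini and a 5-bp
target-site duplication, with best-overlap selection. Two numerical
details: extension can overshoot the true repeat end by chance matches, so
boundaries are refined to the terminal motif within a 30-bp vicinity; and
because a TSD can itself begin with "TG", several motif anchors may exist —
the anchor pair consistent with a TSD is preferred. On 1 Mb of random
sequence the detector returns zero candidates; random 16-mer collisions do
occur, but extension cannot reach the 100-bp/80%-identity floor.

`rescueDivergentFLE()` implements the structural rescue of a subfamily too
diverged for the homology query: truncated elements are promoted to FLE
when they reciprocally overlap (>= 80%) a de novo LTR-pair candidate and
belong to a group of >= 3 mutually similar (>= 90% identity) elements
dispersed over >= 2 contigs. The dispersal requirement keeps tandem
artifacts from qualifying.

## 5. Strain consensus

`majorityConsensus()` emits, per site, the unique most frequent base among
quality-filtered counts (mapping quality >= 20, base quality >= 20), and
`N` on ties or depth below the minimum — never the query base, so
missingness is explicit rather than silently reference-biased, and never
IUPAC ambiguity codes beyond N. The QC gate (`qcStrain()`) requires
internal copy number > 0.75 and breadth > 0.9, both strict; strains with no
internal sequence can never pass, which the tests assert. The
consensus-as-ancestor-proxy premise is checked two ways: the
concerted-evolution fraction (`concertedEvolutionCheck()`: how many
multi-element strains have monophyletic own-element clades) and a direct
property — across replicate simulations with within-strain paralog
variation, the consensus sits at least as close to the true within-strain
ancestor as the median single copy does.

## 6. Sliding-window divergence and breakpoints

`k2p()` implements the K2P distance with pairwise deletion and explicit
saturation signalling (`status = "saturated"` instead of a number — trees
refuse such pairs rather than imputing). `slidingWindowDivergence()` uses
50-bp windows at 10-bp steps over alignment columns (window coordinates are
columns, not ungapped positions, so profiles from different candidates stay
comparable; `alignmentColumnToSeqPos()` maps back). Windows with fewer than
half their columns comparable are missing.

`inferBreakpoints()` contrasts the two parent distances per window
(Δd = d(candidate, A) − d(candidate, B)) and calls a breakpoint at sign
changes between runs of >= 3 same-sign windows, at the midpoint between the
flanking window centres. Two numerical guards matter:

* Windows with |Δd| below half the median |Δd| are *uninformative* and are
  skipped without breaking a run. Overlapping windows (80% overlap at
  w=50/s=10) make sign noise near zero strongly autocorrelated; without the
  magnitude guard, noise runs of three windows both break up true segments
  and fabricate breakpoints on pure candidates. The sign-run rule itself
  and `min_seg = 3` are retained as the transparent calling rule; the
  fraction (0.5) is configuration.
* Missing-value windows *do* break runs, and no breakpoint is called across
  a gap of missing evidence.

Parent representatives matter: the pipeline picks, for each chimera, the
nearest pure element of each parent subfamily by whole-region K2P distance.
With distant representatives the per-window contrast shrinks toward the
inter-subfamily divergence difference and noise dominates. On planted
chimeras with parents 5–15% diverged, >= 90% of breakpoints are recovered
within ±50 columns with zero false calls on pure candidates; breakpoint
placement is only ever as precise as the window grid, which is why
agreement with any visually-read breakpoint is segment-level, not
coordinate-exact.

## 7. Trees, supports and HTT flags

`njTree()` implements Saitou–Nei neighbor joining and Gascuel's BIONJ
(variance-weighted reduction) in double precision, with deterministic
lexicographic tie-breaking and clamping of negative branch estimates (the
deficit moved to the adjacent branch). On additive matrices both variants
reproduce topology and branch lengths to better than 1e-9, which the tests
verify against an exhaustive least-squares topology search; the ape
implementations serve as an independent topological cross-check. Maximum
likelihood inference is deliberately out of scope: the claims this package
makes are clade-membership statements that distance methods reproduce on
its data.

`bootstrapSupport()` resamples alignment columns (seeded; supports are
invariant to taxon input order because only column indices are drawn) and
scores each original bipartition by its replicate frequency. In replicates,
saturated pairs are imputed at twice the largest finite distance so every
replicate yields a tree; the full-alignment matrix must be saturation-free.

`httFlag()` emits three evidence types:

* **Incongruence** — a well-supported (>= 70% by default) species-specific
  element clade whose sister species in the element tree shares no member
  with the species' topological sister on the host tree (walking rootward
  past species absent from the element tree). Two design lessons are baked
  in: the expectation must be the host *topological* sister, not the
  distance-nearest species (branch-length asymmetry decouples the two); and
  hidden paralogy is a real confounder — if one paralog lineage is lost in
  the true sister species, sisters reshuffle with 100% support and no
  transfer. The guard: when a distance matrix is available, the clade must
  also be *closer* to its observed sister than the host divergence divided
  by `host_excess` (default 1.5). Vertical clades sit at or beyond host
  divergence from any sister; transferred clades sit well below.
* **Excess similarity** — a species pair whose minimum cross-species
  element distance is below `sim_ratio` (0.5) of the median within-species
  element distance *and* below host divergence by the `host_excess` factor.
  Under vertical descent and comparable rates, element divergence is
  bounded below by host divergence, so the host-divergence margin is the
  load-bearing condition; the within-species ratio alone is inflated by
  multi-subfamily genomes.
* **Patchy distribution** — a subfamily whose present strains are
  non-monophyletic on the host tree with at least 2 absent strains nested
  inside the presence clade. Requiring two nested absences keeps single
  stochastic losses from flagging.

On the factorial design (HTT +/- x recombination +/-, five independent
replicate simulations per cell, chimeras excluded from the flag tree since
the recombination stage identifies them separately), flag sensitivity and
specificity both reach 100% under the default study conditions; the
acceptance script recomputes this from scratch at every run.

## 8. Degenerate inputs and error behaviour

Saturated distance pairs and zero-comparable-site pairs are distinct
statuses, not numbers; `njTree()` refuses saturated matrices with an
actionable message. The sister group of the full tip set, and the
concerted-evolution check with no multi-element strain, raise classed
errors (`retroHTT_undefined`). Config validation aggregates all violations
with their key paths and warns (not errors) on unknown keys. Hit-table
parsing rejects malformed rows with their line number. Zero-copy strains
produce all-zero profiles with a background-only baseline rather than NaN.

## 9. Known limitations

Beyond the simulator's scope limits (section 2): the breakpoint caller
assumes exactly two candidate parents; three-way mosaics are out of scope.
The incongruence guard requires element distances, so purely topological
inputs fall back to the unguarded rule and inherit its paralogy false
positives. The excess-similarity rule assumes comparable host and element
substitution rates (a `rate_scale` parameter exists but defaults to 1).
Consensus never emits heterozygous ambiguity codes, by design. Problem
sizes in tests and the acceptance script (8 strains, 3.6-kb elements,
20-replicate batteries) were chosen once as the package's study conditions
and are stated in section 2.
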