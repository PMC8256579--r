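---
title: "Models and methods behind gptSpectra"
author: "gptSpectra authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gptSpectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gptSpectra)
```

# The assay and its data structure

In the *gpt* delta transgenic rodent gene mutation assay, lambda EG10
phages rescued from tissue genomic DNA are packaged and plated in
*E. coli*. Colonies on chloramphenicol-only plates give the **titer** (the
number of rescued, plateable reporter copies); colonies surviving
6-thioguanine selection carry an inactivating mutation in the 456-nt
*E. coli gpt* coding sequence, and each confirmed resistant colony is
sequenced. The raw data are therefore, per animal: a titer, a mutant
colony count, and one sequence (or pre-called mutation) per colony.

Two features of this design drive the whole analysis:

* **Clonal expansion.** A single mutational event in a stem-cell lineage
  of the tissue can populate many reporter copies, so several colonies
  from one animal may carry the *identical* mutation. Colony counts
  therefore overstate the number of mutational events; the clonally
  corrected ("independent") count collapses identical within-animal
  events.
* **Small-n group design.** Studies compare a handful of treatment groups
  (here: mismatch-repair-proficient vs knockout, with and without an
  oxidant in the drinking water) with 3–5 animals each, so all group-level
  inference must run on per-animal values.

# Coordinate convention and reference annotation

All coordinates are 1-based on the coding strand; position 1 is the first
nucleotide of the *gpt* coding sequence. The packaged reference is
validated at load time by a calibration self-test: positions 110 and 115
must fall in 5′-CG-3′ dinucleotides, and positions 92 and 113 must be the
3′ G of 5′-GpG-3′. These landmarks are how spectra from this reporter are
reported in the field, and they are only reproducible under one numbering
— encoding them as a checked invariant means a wrong bundled sequence or
offset fails loudly instead of silently shifting every downstream
position.

Annotations derived eagerly from the sequence:

* **CpG positions** — both the C and the G of every CG dinucleotide. For a
  substitution at a G:C pair, "CpG context" means the mutated pair
  participates in a CG on either strand; this covers the G of CG and the G
  whose complement strand carries the CG equally.
* **GpG context** — the 3′ G of coding-strand 5′-GpG-3′ only. This is a
  reported annotation, not a spectrum category: it is how
  oxidative-stress-associated G-to-A sites are described, and it is
  deliberately strand-asymmetric because that is how such sites are
  communicated.
* **Mononucleotide runs** — maximal single-base runs of length ≥ 3
  (`runMinLength`, configurable). "A-runs" are the runs whose base is A
  *or* T on the coding strand: published run tables list T-runs (e.g.
  173–175, 179–181, 325–327) among the A-runs because the slipping unit is
  the A:T base pair.

One naming wrinkle worth documenting: published run tables sometimes label
the first *gpt* A-run "7–12" while the surrounding text calls it the
five-adenine run at 8–12. On the calibrated sequence position 7 is a G and
positions 8–12 are the five A's, so this package reports the maximal run
8–12; both labels refer to the same run.

# Mutation calling and indel normalization

Colony sequences are aligned to the reference with Needleman–Wunsch global
alignment (`Biostrings::pairwiseAlignment`) under unit-scale costs: match
+1, mismatch −1, gap opening 1.5, gap extension 1. Two properties of this
scoring are load-bearing:

* gap extension ≤ gap opening keeps multi-base indels contiguous (one
  2-base deletion beats two separated 1-base deletions);
* a mismatch is cheaper than an insertion+deletion pair, so substitutions
  are never decomposed into paired gaps.

Event extraction walks the alignment columns; adjacent gap columns of the
same kind merge into one indel. Sequences below 90% identity
(`minIdentity`) are rejected as implausible mutants rather than called.
Amplicon inputs longer than the reference (the assay sequences a 739-bp
fragment containing *gpt*) use a global-in-reference / local-in-colony
alignment, so flanking sequence is ignored; only events inside the
reference window are ever reported. A consequence worth knowing: with
flanked input, an insertion *before* position 1 is indistinguishable from
flank and is not called; with unflanked input it is called with the anchor
convention position 0.

Every indel is then **left-aligned**: shifted to its 5′-most placement
among all placements yielding the same alternate sequence. Any within-run
placement of a slippage indel is biologically equivalent, and run-level
bookkeeping needs one canonical choice; 5′-most on the coding strand
matches the dominant variant-normalization convention. The operation is
idempotent and provably preserves the alternate sequence (tested by
re-applying events and comparing strings).

# Classification

Substitutions are classified at the base-pair level: the class of
(ref, alt) equals the class of their complements, so twelve ordered pairs
collapse onto six classes. Colonies reduce to one spectrum category each:
a single event maps to its class (deletions split by size 1 vs ≥ 2;
insertions of any size are one category, with the size kept on the event);
colonies with ≥ 2 events, or a complex event, are "other". This is the
minimal rule that keeps one category per colony so that category counts
sum to the number of sequenced, mutation-bearing colonies. Colonies whose
sequence shows no *gpt* event (6-TG-resistant but reference-identical)
count toward mutant frequency — their resistance phenotype was confirmed
independently of sequencing — but are excluded from spectrum denominators.

Run context is assigned to a substitution inside a run, or to an indel
whose inserted/deleted bases match the run base and whose left-aligned
placement touches the run interval (anchor at start−1 included, since
that is where a left-aligned run insertion lands). Whether a substitution
at a run-flanking base should count as a run mutation is genuinely
ambiguous in published tables (a terminal "AAAC" row can be read either
way); the rule is configurable (`includeFlank`, default FALSE) and the
packaged example encodes the terminal-substitution reading, i.e. the
mutated base inside the run.

# Frequencies and clonal correction

Per animal: MF = mutant colonies / titer; independent mutation frequency
= independent mutations / titer. Clonal identity is an exact
(position, kind, alleles) match within one animal — after left-alignment
this equals identity of alternate sequences — and events in different
animals never collapse, because cross-animal recurrence is biologically
independent. Group summaries are means ± sample SD (n−1) over animals,
never pooled counts over pooled titers; the SD is what small-n group
comparisons run on. The pooled ratio is still reported alongside for
completeness. Whether published per-category group frequencies used
per-animal averaging or pooling is typically unstated; per-animal is the
default here because error bars require per-animal values.

A known, documented bias: when two independent mutations coincide at the
same site and alleles within one animal by chance, clonal correction
cannot distinguish them and counts one. The independent-event estimator is
therefore biased slightly downward at heavily weighted sites (hotspots);
the real assay has exactly the same limitation. The simulator's truth
table records both views, and the test suite checks the estimator against
the collapsed (distinct-alternate-sequence) truth exactly.

# Hotspots, A-run tables, statistics

A **hotspot** is a (position, specific change) carried by independent
events in ≥ 3 distinct animals of one treatment group. Support counts
animals, not colonies — clonal correction is applied first, so duplicating
any colony can never change a call (a tested invariant), and raising the
threshold can only shrink the called set. Events from multi-event
("other") colonies contribute to position tallies.

The **A-run table** tabulates colonies whose single event carries A:T-run
context, one row per (run, change), with colony and independent counts per
group and per-group grand totals.

**Fisher's exact test** conditions on both margins and sums exact
hypergeometric point probabilities. The two-sided p follows the
point-probability definition (sum of all tables no more probable than the
observed one) — the dominant convention of exact-test implementations —
rather than tail-doubling. Both one- and two-sided values are always
reported, because the sidedness of published significance statements is
often unstated, and the two can straddle 0.05: for the A-run mutant
comparison 30/149 vs 12/107 the one-sided p is 0.040 while the two-sided
p is 0.062, so a "< 0.05" claim for that comparison is only reproducible
one-sided. The package surfaces both and asserts neither.

**Tukey–Kramer** all-pairs comparison uses the classical one-way-ANOVA
pooled within-group variance and studentized-range p-values, with the
Kramer standard error for unbalanced 3–5-animal groups. It is applied to
raw (untransformed) per-animal frequencies, matching how such data are
presented as mean ± SD; callers wanting a log scale pass transformed
values. Degenerate inputs are defined, not accidental: zero pooled
variance with zero difference gives p = 1, with nonzero difference p = 0.

# The synthetic-assay generator

`simulateAssay` emulates what the analysis assumes about real data, per
animal:

* titer ~ log-normal (default meanlog log(6e5), sdlog 0.3; order 10⁵–10⁶);
* independent mutations per category ~ Poisson(titer × per-locus rate);
* substitution positions drawn from a weighted spectrum: eligible bases of
  the class's pair, weight × `cpg_multiplier` for G:C→A:T at CpG sites,
  × `hotspot_multipliers[position]` at designated hotspot positions;
* A-run slippage indels at a per-run rate (`arun_indel_rate`), deletion
  with probability 0.7, otherwise insertion of one (p = 0.8) or two run
  bases;
* clonal copies per independent mutation = 1 + Geometric(`clonal_p`),
  default mean ≈ 1.54 — crypt-lineage expansion is multiplicative and a
  geometric tail is the simplest such model;
* a `no_mutation_fraction` (default 0.05) of resistant colonies carries no
  detectable event;
* a realism guard refuses configurations whose expected mutant colonies
  exceed titer/10, since the assay regime is rare-mutant selection.

`defaultStudyConfig()` fixes the study conditions the package emulates:
four groups (repair-bearing vehicle n = 4, bearing dosed n = 5, knockout
vehicle n = 3, knockout dosed n = 4), per-group total independent-mutation
rates 0.40, 0.64, 3.14 and 2.67 × 10⁻⁵ split across categories in
proportion to the packaged example spectrum, with half (vehicle knockout)
to 70% (dosed knockout) of the single-base indel mass routed through the
A-run channel. `clonal_p = 0.65` makes the mutant/independent frequency
ratio ≈ 1.54, the regime such studies report. `cpg_multiplier = 5` follows
from the CpG sub-count algebra: with roughly a fifth of G:C sites in CpG
context, a multiplier m satisfies m/(m + 4) ≈ CpG share of G:C→A:T
(≈ 0.55), giving m ≈ 5. Hotspot multipliers (120 at the GpG sites 92/113,
30 at the CpG sites 110/115, i.e. equal effective weights once the CpG
multiplier applies) concentrate roughly 0.9 expected independent G:C→A:T
events per animal on each hotspot, the intensity at which 2–3 of 4
animals are typically hit. These presets document a realistic regime;
they are not claims about any particular cohort, and they were fixed as
conditions, not tuned against outcomes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing/base-calling error, PCR jackpots,
plating and packaging efficiency variation, sex effects, per-copy (80
copies/haploid) normalization, mutation-spectrum differences between
tissues, and any mechanistic adduct chemistry. Recovery tests demonstrate
estimator correctness under the model, not model correctness for a tissue.

# Numerical and testing choices

* Percentages in spectrum tables are integer-rounded (`round`), matching
  how such tables are printed; a rounding-sum check tolerates the
  inevitable ±(categories/2) deviation from 100.
* Exact-test p-values compare point probabilities with a relative 1e-7
  tolerance when deciding "no more probable", avoiding floating-point
  misclassification of ties.
* Alignment tie-breaks are fixed by the scoring (substitution over paired
  gaps) plus left-alignment, so calls are deterministic.
* The test suite checks calling against exhaustive single-edit enumeration
  on references up to 50 nt; Fisher against a binomial-coefficient
  enumeration oracle for margins ≤ 30 and against the reference
  implementation in `stats`; Tukey against `stats::TukeyHSD` and a
  10,000-replicate null simulation of the family-wise error rate;
  and parameter recovery over 100 simulated studies (unbiased colony-count
  route, with the clonal-correction identity checked exactly per animal).
  These problem sizes keep every oracle exhaustive or tightly
  Monte-Carlo-bounded while the whole suite stays in the minutes range.

# Known limitations

* No chromatogram (AB1) base-calling, quality trimming, or mixed-peak
  handling — inputs are final sequences or pre-called tables.
* No trinucleotide-signature (96-channel) decomposition and no
  transcription-strand asymmetry analysis; context is CpG/GpG/run only.
* Insertions before position 1 of a flanked amplicon cannot be observed.
* The independent-mutation estimator undercounts coincident same-site
  events within an animal (direction documented above).
* Statistics are the study-design classics (exact Fisher, Tukey–Kramer);
  no mixed models or sex stratification.
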