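---
title: "Resolving cyclic lipodepsipeptide stereochemistry from NRPS architecture, Marfey's counts and HSQC fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving cyclic lipodepsipeptide stereochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipstereo)
library(dplyr)
```

## The problem

Cyclic lipodepsipeptides (CLiPs) produced by *Pseudomonas* species are
assembled by non-ribosomal peptide synthetases (NRPS): one module per
residue, each with a condensation (C), adenylation (A) and thiolation
domain. Mass spectrometry and standard 2D NMR settle the *planar* structure
— which residues sit where — but not the D/L configuration of each
stereocenter. Two diastereomers of one peptide have identical mass and
identical planar structure yet can differ in bioactivity; worse, a single
assembly line can emit *both*, as the entolysin A/B pair shows, where the
two products differ only in the configuration of one serine.

The package turns the pieces of evidence that are cheap to obtain into a
constrained search over configurations:

1. **Architecture rules** (`predict_configurations()`,
   `derive_hard_constraints()`). The C-domain of module *i + 1* condenses
   residue *i + 1* onto the chain; if it is a dual
   epimerization/condensation (E/C) domain it also epimerizes residue *i*
   from L to D, while a condensation-only LCL domain leaves residue *i* in
   the L form. The terminal residue, released by the thioesterase without a
   downstream C-domain, stays L. Because E/C domains are *sometimes*
   epi-inactive, only the LCL and terminal rules are hard constraints; an
   E/C successor merely makes D the naive prediction.
2. **Marfey's composition counts** (`enumerate_assignments()`). Marfey's
   analysis reports, per residue class, how many copies are D and how many
   are L — but not at which positions. Glu/Gln derivatives co-report as
   `Glx` (and Leu/Ile may pool as `Xle` when the composition comes from
   mass data), which `pool_residues()` handles by mapping sequence residues
   onto pooled class names.
3. **Homology priors on E/C activity** (`apply_epi_labels()`). An E/C
   domain that clusters with experimentally epi-inactive domains can be
   labelled `INACTIVE` (pinning its position to L), a confident one
   `ACTIVE` (pinning D). `INTERMITTENT` and `UNKNOWN` pin nothing. The
   labels are binary prunes, not probabilistic weights, because that is how
   such priors are used in practice: to shortlist synthesis targets, not to
   build a posterior.
4. **HSQC CH&alpha; fingerprints** (`match_peaklists()`). The set of
   (&delta;H, &delta;C) alpha cross-peaks is a configuration-sensitive
   fingerprint: two samples of the same compound overlay almost perfectly,
   while a single D/L switch displaces the peaks around the switched
   residue. Matching two peak lists dereplicates a compound without any
   resonance assignment.

## The combinatorial core

For residue class $c$ with $n_D(c)$ D-copies, let $F(c)$ be its positions
left free by the hard constraints and $f_D(c)$ the number of its positions
pinned to D. Every constraint family is per-position and every composition
constraint is per-class, so the consistent assignments factorize:

$$N = \prod_c \binom{|F(c)|}{\,n_D(c) - f_D(c)\,}$$

`count_assignments()` evaluates this closed form;
`enumerate_assignments()` materializes the set (in deterministic
lexicographic order, D before L); `brute_force_enumerate()` filters all
$2^n$ configuration vectors and exists purely as an independent oracle —
the suite checks all three agree on hundreds of random instances, and that
any tightening of a position's allowed set can only shrink the count.

For the entolysin inputs this arithmetic gives the familiar cascade:

```{r entolysin}
sys <- read_nrps(clipstereo_example("entolysin_nrps.tsv"))
seq14 <- pool_residues(sys$residue)
comp_a <- read_composition(clipstereo_example("entolysin_marfeys_A.tsv"))
comp_b <- read_composition(clipstereo_example("entolysin_marfeys_B.tsv"))

c(B = count_assignments(seq14, comp_b),   # 18 diastereomers
  A = count_assignments(seq14, comp_a))   # 36: serines split 1 D : 1 L

hc <- derive_hard_constraints(sys)        # L at 11, 12 (LCL) and 14 (terminal)
count_assignments(seq14, comp_a, hc)      # 6
class_arrangements(seq14, comp_a, hc, residue_class = "Leu")  # 3

# homology prior: module-2 E/C epi-inactive => N-terminal Leu is L
sys2 <- apply_epi_labels(sys, data.frame(index = 2, epi_label = "INACTIVE"))
prioritize_candidates(
  enumerate_assignments(seq14, comp_a, derive_hard_constraints(sys2)),
  enumerate_assignments(seq14, comp_b, derive_hard_constraints(sys2)))
```

Three candidates survive — the three sequences worth synthesizing, among
them the final entolysin A (`LDDDDDDDDDLLLL`) and B (`LDDDDDDDDDLLDL`)
assignments. Infeasible inputs (constraints pinning more D's of a class
than the composition provides) return an *empty set plus a warning naming
the violated class*: a silent empty result would hide inconsistent
Marfey's data.

## Fingerprint matching: metric, pairing, verdict

Visual overlay of two HSQC spectra is made quantitative in three steps.

* **Metric.** `combined_distance()` is the weighted Euclidean distance
  $\sqrt{\Delta\delta_H^2 + (\Delta\delta_C/w)^2}$ with carbon weight
  $w = 10$, the conventional chemical-shift-perturbation scaling that puts
  both nuclei on a common 1H-equivalent ppm scale. $w$ is an argument
  everywhere it matters.
* **Pairing.** `pair_peaks()` solves the linear assignment problem exactly
  (an $O(n^3)$ Hungarian solver lives in the package; peak lists are tens
  of peaks, so plain R is ample). Greedy nearest-neighbour pairing is
  order-dependent in crowded CH&alpha; regions, which is why a global
  optimum is used; the tests verify it against exhaustive enumeration of
  all pairings for small lists. Labels are never used to force pairs —
  matching must work on unassigned spectra. Surplus peaks of the longer
  list are reported unpaired.
* **Verdict.** `classify_match()` declares `MATCH` only when peak counts
  are equal and the *worst* pair lies within the threshold, default 0.03
  combined-shift units. The default separates the two regimes the
  simulator produces: replicate noise (&sigma;H = 0.005 ppm,
  &sigma;C = 0.05 ppm per measurement, so pair differences of a few
  thousandths) and D/L-switch displacements (0.12 ppm 1H-equivalent and up,
  an order of magnitude larger). `rank_residue_differences()` orders pairs
  by distance (ties broken on ascending reference &delta;H) so the
  switched residue surfaces at the top — the quantitative counterpart of
  reading the most-displaced peaks off an overlay.

## Histidine motifs of C-domains

`classify_primary_motif()` scans for the catalytic `HHxxxDG` motif; a
final G marks an LCL domain, while H (or the rarer A/N) marks an E/C
domain. `scan_secondary_motif()` searches the N-terminal region for the
E/C-diagnostic `HH[I/L]xxxxGD` consensus with these conventions:

* `nterm_window = 120` residues operationalizes "close to the N-terminus";
  no published number exists, so it is a configurable default chosen to
  cover the region comfortably on pre-excised domain sequences.
* At most one insertion, only inside the wildcard block (matched span 10
  instead of 9); observed insertions are histidine or proline, so the
  apparent inserted residue reported is the leftmost H (else P) in the
  block. No deletions.
* Scoring counts matched constrained positions (max 5); a hit must match
  all but at most one. Ranking: score, then insertion-free, then leftmost.
* Coordinates are 1-based inclusive, following R convention.

The flank residue immediately before the matched span is reported and
classified by `flag_atypical_flank()`: leucine is the conserved, typical
case; a histidine there is the anomaly characteristic of the entolysin
module-14 E/C domain, the one with intermittent epimerization activity.
`build_pfm()` supplies the logo arithmetic (column frequencies and
information content $IC = \log_2 20 - H$ against a uniform background, the
standard logo convention without compositional correction), and
`autoplot()` on the result draws a logo-style stack.

## What the simulator emulates — and what it does not

`sim_config()` fixes the study conditions; its defaults *are* the
conditions every stochastic claim in the test suite is made under:

| parameter | default | meaning |
|---|---|---|
| `n_modules` | 14 | entolysin-sized assembly line |
| `p_ec` | 0.75 | chance a non-initial C-domain is E/C |
| `p_inactive` | 0.1 | per-E/C chance of being epi-inactive |
| `p_intermittent` | 0.15 | chance the system has one intermittent E/C |
| `major_minor_ratio` | 3:2 | product abundance of an intermittent system |
| `noise_sigma_h`, `noise_sigma_c` | 0.005, 0.05 ppm | replicate measurement noise |
| `switch_perturbation_h` | 0.12 ppm | 1H displacement at a switched residue (13C is 10×) |
| `decay_span` | 2 | residues over which the displacement decays linearly to zero |
| `mutation_rate`, `insertion_prob` | 0, 0.2 | domain-sequence drift and secondary-motif insertion chance |

Design choices worth knowing:

* **At most one intermittent E/C per system**, drawn uniformly among the
  E/C domains with probability `p_intermittent`, so a ground truth has two
  products exactly when one domain is intermittent, the major product
  carrying the unepimerized L form at the affected position. The 3:2 ratio
  is treated as a sampling ratio (`sample_products()`), without modelling
  extraction or ionization bias.
* **Base chemical shifts** are drawn per residue class from coarse
  CH&alpha;-typical ranges (1H 3.8–5.3 ppm, 13C 45–65 ppm): a class centre
  keyed to the class name plus a broad per-position spread (±0.25 ppm 1H,
  ±2.5 ppm 13C). The spread is deliberately wide relative to the switch
  displacement so that peaks are separable — the generator's job is to
  make the matching problem well-posed, not to predict chemistry. The
  displacement model (same-sign 1H/13C shift, linear decay over
  `decay_span`) is an artifact convention emulating the qualitative
  observation that differences concentrate at and next to the switched
  residue.
* **All randomness flows from one integer seed** through
  `split_seed(seed, stream)`, a documented hash that separates independent
  streams (system layout, class centres, positional jitter, measurement
  noise, domain backgrounds). Two products of one system therefore share
  identical base fingerprints, and regenerating noise never moves the base
  peaks.
* **Reserved letters in domain simulation.** Background sequences exclude
  H, and the secondary motif's wildcard block additionally excludes P, D
  and G. This guarantees that at mutation rate 0 the planted motif is the
  *unique* best-scoring hit and the planted insertion the unique H/P in
  the block, so exact-offset recovery is a property of the scanner, not of
  luck. Point mutations (at `mutation_rate`) spare the pattern-constrained
  positions but may hit wildcards, which is why full-truth recovery
  (offset + insertion flag + inserted residue) degrades as the rate rises.

What passing tests therefore show: the enumeration logic is exact (oracle
agreement), the recovery guarantees hold under the stated generative
mechanism, and the matcher separates noise from switch-scale displacements
with the default threshold. What they do not show: performance on real
spectra with overlapping peaks, solvent/temperature shifts between
laboratories, mis-picked peaks, or Marfey's miscounts (the `swap_error`
mode exists to exercise the infeasibility reporting, not to model assay
error realistically); nor that motif flanks *cause* intermittent activity
— the package detects the association only.

## Numerical and degenerate-input choices

* Candidate listings are sorted with byte-wise (`radix`) ordering, so
  identical inputs give byte-identical output on any platform.
* The empty sequence has exactly one (empty) assignment — the empty
  product.
* `brute_force_enumerate()` refuses beyond 24 positions; the closed form
  and generator have no such limit.
* Peak lists must be nonempty and duplicate-free in both coordinates;
  duplicate *file rows* are collapsed with a warning.
* Unequal peak counts are a `MISMATCH` regardless of distances: a missing
  or extra peak is structural evidence, not noise.
* Problem sizes in the test suite (500 random enumeration instances up to
  n = 16, 500 simulated systems, 200 + 200 fingerprint pairs, 500 planted
  domains) were chosen so the full suite runs in about a minute while the
  stochastic claims are tested at the sample sizes stated above.

## Limitations

* A-domain substrate prediction and domain excision are upstream of this
  package: it consumes residue predictions and pre-excised domain
  sequences.
* Epimerization-activity labels come from homology done elsewhere
  (phylogenetics is out of scope); the package only consumes and applies
  them.
* The terminal residue is hard-coded L. A hypothetical terminal module
  whose product is D-configured before thioesterase release has, to our
  knowledge, no documented precedent in this family; if one surfaces, the
  constraint is a single row to relax in `derive_hard_constraints()`.
* The fingerprint verdict is a single-threshold rule on the worst pair; it
  does not model field-strength or solvent differences between the two
  lists, which must be acquired under comparable conditions.
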