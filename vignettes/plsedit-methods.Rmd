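---
title: "Methods: PPR-RNA recognition, off-target scanning and editing-site calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPR-RNA recognition, off-target scanning and editing-site calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsedit)
```

## Scope and model

`plsedit` covers the computational side of studying C-to-U RNA editing by
PLS-type pentatricopeptide repeat (PPR) proteins expressed in a bacterial
host: predicting where a factor can bind and edit, calling editing sites from
sequencing base counts, summarising off-target sets, and quantifying editing
from Sanger traces. It deliberately stops upstream of read alignment and
downstream of biochemistry: inputs are arrays, sequences and per-site count
tables, never BAM files, and no attempt is made to model deaminase kinetics
or RNA structure.

### The repeat register and the recognition code

A PLS-type array alternates P-, L- and S-type repeats and ends in a P2-L2-S2
triplet. Repeats are numbered backwards: S-1 is the numbered repeat adjacent
to P2, and it pairs with nucleotide −4 relative to the edited cytidine
(position 0), so a numbered repeat *k* addresses position −(k + 3) and the
triplet addresses −3..−1. The code itself reads the residues at repeat
positions 5 and L (last): T/S + N selects A, T/S + D selects G, N + N selects
C or U without preference, N + S prefers C over U, and N + D prefers U over
C. Any other residue pair — including gaps — carries no expectation. The
package treats the code as a total function with exactly those five rules;
repeats outside the code are paired and displayed but never scored, because
only coded combinations carry interpretable signal.

### Match categories and the score

Each repeat-nucleotide pair is classified as a perfect match, a pyrimidine
transition (the dispreferred pyrimidine of a ranked rule), a purine
transition (the other purine where a purine is expected), a mismatch, or
no-expectation (uncoded repeat or N). The score is a weighted sum with
defaults chosen from the observed mutation phenotypes: single purine changes
at coded P/S positions abolish editing while several pyrimidine changes are
tolerated, so purine matches weigh +2 against +1 for pyrimidine matches,
purine transitions and mismatches cost −1, and pyrimidine transitions still
earn +0.5. L-type repeats demonstrably can contribute (a coded L repeat
matching its guanosine in the worked example), but their general weight is
unclear, so they earn a reduced +0.5 on a match by default and can be
promoted to full P/S weight (`promote_l = TRUE`). The triplet repeats score
zero: the strong −3..−1 context preference is empirical, not code-derived,
and is handled by explicit scanner constraints instead. A linear score
cannot represent the observation that some conceptually improved matches
*reduce* editing; no attempt is made to model that, and the score should be
read as a binding-plausibility ranking, not an efficiency prediction.

### Scanning and register shifts

`scan_transcriptome()` profiles every cytidine on both strands, evaluates the
register shifted by ±1 nucleotide (reporting a shift only when it strictly
improves the score, ties prefer the unshifted register, then −1), applies
optional nucleotide constraints on the −3..−1 context and drops candidates
below `min_score`. The default threshold is 60% of the array's maximum
attainable score — a pragmatic choice to keep candidate lists small; it is a
plain argument, and the ranked list is a deterministic function of its
inputs (ties broken by sequence id, coordinate, strand). Internally the
scanner uses a vectorised scorer compiled from the array; the test suite
verifies it against an independent per-site re-profiling oracle.

Windows are `W = 33` upstream and `D = 5` downstream of the site (the span
used for cloned targets), truncations are N-padded, and N never contributes
to the score. Minus-strand windows are displayed 5'→3' on the edited strand.

### Editing-site nomenclature

Labels are gene + `eU` + transcript position + amino-acid change
(`ccmFCeU103PS`), where the position is 1-based within the CDS from the A of
the start codon, negative upstream of it (−1 adjacent, no 0). Synonymous
edits carry an empty change plus a `synonymous` flag; antisense calls get the
suffix `as` and no amino-acid change. The default genetic code is the
bacterial table (11), identical to the standard code at the amino-acid level.

### The calling cascade

`call_sites()` works from per-site base counts of RNA replicates, one DNA
sample and any number of control RNA samples. A site is called, per
orientation (sense C→U, antisense G→A), only if every RNA replicate and the
DNA sample reach `min_coverage` (default 10); the DNA is > 98% reference and
every RNA replicate > 98% reference-plus-edit (strict inequalities, exactly
98% fails); the altered base is detected (≥ `min_alt`, default 1 read) in
*every* replicate; and no covered control shows more than `max_control_alt`
(default 0) altered reads. The editing level is the altered-read fraction in
RNA minus the same fraction in DNA, unclipped, so DNA variants cancel and
noise can produce small negative values. The cascade is monotone: relaxing
any threshold can only add calls. Missing DNA is an error rather than a
skip, because the subtraction is part of the level's definition. The
"detected in every replicate" threshold of one read is a documented choice
— the underlying criterion is qualitative — and is exposed in the
configuration.

### Consensus analysis

`frequency_matrix()` builds per-position A/C/G/U counts over aligned
windows, excluding N from denominators (ambiguous positions should not
dilute conservation). Shading follows the conservation conventions of
off-target panels: at least 90% black, 60% light green, 30% yellow, with
inclusive thresholds ("conservation in 90% of sequences" reads as at-least).
Ties in the majority nucleotide do not affect fractions and are broken
alphabetically only for display. Windows enter the matrix post
shift-annotation, so a ±1 site contributes its shifted alignment.

### Sanger quantification

Editing from a chromatogram is the T peak height over the sum of T and C
peak heights — scale invariant by construction. Replicates aggregate to the
mean and the sample (n − 1) standard deviation; the population form was not
specified by convention, and the sample form is the conservative choice for
the n ≥ 3 replicate designs this emulates (fewer than three replicates
warns).

## The synthetic-data generator

The generator exists so that every stage is testable with known ground
truth, without any external downloads. It emulates: (1) a random background
transcriptome with planted target windows whose match profiles have
controlled numbers of degraded pairs (and optionally a forced −3..−1
context), mirroring the structure of real off-target sets; (2) multinomial
base counts for RNA/DNA/control samples in which a true base is miscalled
uniformly to the three other bases at a per-base error rate, with edited
sites mixing T at the true level into RNA only, DNA variants carrying a 50%
C/T mixture, and control-shared sites carrying their level in the control;
(3) peak pairs with multiplicative Gaussian noise. Everything is a pure
function of its parameters and a single integer seed.

The recovery preset fixes the study-like conditions used throughout the
tests: ten edited sites at levels evenly spaced from 0.05 to 1.0, three
DNA-variant and two control-shared decoys, two RNA replicates at 200×
coverage, 0.5% per-base error, in a 6 kb background. These sizes keep the
full loop (simulate → count → call) under a few seconds while leaving the
binomial noise realistic. What passing recovery shows — and does not show —
deserves care: the generator has no alignment artifacts, no strand bias, no
coverage heterogeneity and no correlated errors, so recovery demonstrates
the correctness of the cascade logic and level estimator, not robustness to
mapping pathologies.

Two numerical consequences of the declared error model are handled
explicitly rather than hidden:

* **Control tolerance.** With a per-base error *e*, the control sample shows
  T reads at rate *e*/3 even at unedited sites; a zero-tolerance control
  filter would reject genuinely edited sites about half the time at 200×.
  The preset therefore derives `max_control_alt = qbinom(0.999, coverage,
  error/3)` (= 3 reads at the preset conditions) from the error model — high
  enough to ignore sequencing error, four orders of magnitude below a shared
  edit. The package-wide default remains the strict 0 appropriate for the
  near-zero-error regime.
* **Level accuracy.** The estimated level is compared to truth within three
  binomial standard deviations computed at the error-adjusted expected alt
  fraction `p_eff = level·(1 − e) + (1 − level)·e/3` (per-replicate n,
  conservative). Computing the deviation at the raw truth level would give a
  zero-width band at level 1.0, which the known −(4/3)·level·e bias of the
  estimator fails deterministically.

Even so, the strict > 98% DNA purity filter rejects a clean site at 200×
with 0.5% error about 1.9% of the time — an inherent property of those
conditions, visible as an occasional 9-of-10 recovery at some seeds.

## Worked-example fixtures

The bundled PPR65-like array and window panel (`ppr65_example()`) are a
*synthetic reconstruction*: the repeat residues and every constrained window
nucleotide implement the published textual description of this factor (the
coded-repeat identities, the native purine transition at −9, six of eight
coded P/S repeats matching, all seven off-targets showing G at −9, six of
seven sharing the native −3..−1 context), while unconstrained positions are
arbitrary fixed filler. They are faithful to the described recognition
logic, but they are not the deposited sequences, and the bundled off-target
editing percentages are illustrative ordering values only.

## Known limitations

* The score is linear and cannot encode cooperativity or the
  improved-match-reduces-editing phenomenon.
* Selectivity at −3..−1 is handled as an empirical constraint set, not a
  model of the E1/E2/DYW domains.
* The caller consumes count tables; building them from alignments (pileups,
  mapping-quality filtering) is out of scope.
* Antisense windows are always displayed 5'→3' on the edited strand; no
  operon or transcription-unit inference is attempted.
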