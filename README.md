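# plsedit

Tools for the computational side of C-to-U RNA editing by PLS-type
pentatricopeptide repeat (PPR) proteins — the plant-type editing factors that
can be expressed in *E. coli* and direct site-specific cytidine-to-uridine
conversion on co-expressed RNA targets. The package is aimed at groups
characterising such factors: it predicts where an array can bind and edit,
calls editing sites from sequencing base counts, summarises off-target sets,
and quantifies editing from Sanger traces, with a synthetic-data generator
that makes every stage testable against known ground truth.

## The model in brief

A PLS-type array pairs one repeat per nucleotide upstream of the edited
cytidine (position 0), with repeat S-1 juxtaposed to nucleotide −4: numbered
repeat *k* addresses position −(k + 3), the terminal P2-L2-S2 triplet
addresses −3..−1. The residues at repeat positions 5 and L (last) specify the
preferred nucleotide:

| res5 + resL | expectation |
|---|---|
| T/S + N | A |
| T/S + D | G |
| N + N | C/U (unranked) |
| N + S | C > U |
| N + D | U > C |

Every repeat-nucleotide pair is classified (match, pyrimidine transition,
purine transition, mismatch, no expectation) and scored; purine positions
weigh double and purine transitions are penalised, reflecting the observed
asymmetry in mutation tolerance. A scanner ranks every cytidine on both
strands of a transcriptome by this score, annotates ±1 register shifts, and
labels sites with the standard nomenclature (gene + `eU` + CDS position +
amino-acid change, e.g. `ccmFCeU103PS`). An editing-site caller applies the
strict RNA-vs-DNA cascade — coverage, > 98% purity (strict), detection in
every replicate, absence from controls — and reports the editing level
(altered fraction in RNA minus the same fraction in DNA).

## Worked example

The bundled `ppr65_example()` provides a 15-repeat PLS array and its native
target window plus seven aligned off-target windows (a synthetic
reconstruction of the described factor, see the methods vignette):

```r
library(plsedit)
ex <- ppr65_example()
match_profile(ex$array, ex$native)
#> <match_profile> PPR65 vs ccmFCeU103PS  score = 9.5
#>  repeat_label position nt expectation          category weight
#>        P-15MK      -18  G                NO_EXPECTATION    0.0
#>        L-14AE      -17  C                NO_EXPECTATION    0.0
#>        S-13NN      -16  G         C/U          MISMATCH   -1.0
#>        P-12TD      -15  G           G             MATCH    2.0
#>        L-11IR      -14  C                NO_EXPECTATION    0.0
#>        S-10TN      -13  A           A             MATCH    2.0
#>         P-9TN      -12  A           A             MATCH    2.0
#>         L-8AE      -11  G                NO_EXPECTATION    0.0
#>         S-7ND      -10  U         U>C             MATCH    1.0
#>         P-6TD       -9  A           G PURINE_TRANSITION   -1.0
#>         L-5TD       -8  G           G             MATCH    0.5
#>         S-4SN       -7  A           A             MATCH    2.0
#>         P-3TD       -6  G           G             MATCH    2.0
#>         L-2VT       -5  C                NO_EXPECTATION    0.0
#>         S-1RK       -4  U                NO_EXPECTATION    0.0
#>          P2KD       -3  C                NO_EXPECTATION    0.0
#>          L2FE       -2  U                NO_EXPECTATION    0.0
#>          S2PN       -1  U                NO_EXPECTATION    0.0
```

Six of the eight coded P/S repeats match perfectly; the factor tolerates a
native purine transition at −9 (A where the code expects G) and a mismatch at
−16. Over the off-target panel, the conserved −9 guanosine and the shared
site-adjacent context stand out:

```r
count_perfect_PS_matches(match_profile(ex$array, ex$native))
#> $n_match [1] 6      $n_coded [1] 8
fm <- frequency_matrix(ex$offtarget_windows)
fm$counts["G", "-9"]                                   #> 7   (of 7, shaded black)
identity_count(ex$offtarget_windows, c(-1, -2, -3), ex$native)
#> [1] 6
```

An end-to-end synthetic run — plant edited sites, simulate counts, call:

```r
pre <- simulate_recovery_preset(seed = 1)
calls <- call_sites(pre$counts, pre$config)
nrow(calls)                                            #> 10  (all planted, no decoys)
```

A thin command-line wrapper is installed under `exec/plsedit`
(`plsedit scan --array A.tsv --fasta genome.fa`, `plsedit call --counts
c.tsv`, `plsedit simulate --preset recovery --seed 17 --out dir/`, ...).

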