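---
title: "Mapping and transmission analysis of a mosaic hemizygous deletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and transmission analysis of a mosaic hemizygous deletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemidel)
```

## The problem

A founder bull that is somatically and germline mosaic for a multi-megabase
deletion sires daughters that are hemizygous for the deleted segment: they
carry only the maternal copy.  Three observable consequences drive the whole
analysis, and `hemidel` implements each as a separate module:

1. **SNP arrays cannot see hemizygosity.** A hemizygous marker is called as
   if homozygous for the remaining allele.  When the sire is homozygous for
   the *other* allele, the trio check sees an impossible opposite-homozygote
   pair (sire AA, daughter BB) — a Mendelian error.  Such errors cluster
   over the deleted interval in affected daughters only, while affected
   heterozygous calls inside the interval become depleted.
2. **Sequencing depth halves** over a hemizygous segment, read pairs that
   straddle the junction have deletion-inflated insert sizes, and reads
   crossing the junction are soft-clipped at the breakpoints, their clipped
   tails spelling out any non-template inserted bases.
3. **Transmission is distorted.** If male carriers die in utero with
   probability $\lambda$, carrier males are depleted at birth but not in
   sperm or blastocysts, the overall sex ratio shifts, and failed
   inseminations carry an upper bound on how long a doomed conceptus
   gestated.

No external data are needed: a seeded generator (`simulate_cohort()`)
produces a full cohort — pedigree, genotypes, depth, read evidence,
stage-wise counts, insemination records — under exactly this model, with
the ground truth retained for parameter-recovery testing.

## The genetic model

Let $m$ be the founder's germline mosaicism: the fraction of germ cells
heterozygous for the deletion.  Each such cell transmits the deletion to
half its gametes, so the carrier-sperm fraction is $m/2$, and
`mosaicism_from_sperm()` inverts this: $\hat m = 2k/n$ for $k$ carrier
spermatozoa among $n$ scored, with a Clopper–Pearson interval on $k/n$
doubled and capped at 1.  The cap is a safety device; at the observed
fractions (about a third) it never binds.

Conceptions are unselected: a conceptus is a carrier with probability
$m/2$ and male with probability $1/2$, independently.  Male carriers die
before birth with probability $\lambda$; everyone else survives.  Birth
categories are therefore multinomial with probabilities proportional to

| category | weight |
|---|---|
| male carrier | $(m/2)(1-\lambda)/2$ |
| male non-carrier | $(1-m/2)/2$ |
| female carrier | $(m/2)/2$ |
| female non-carrier | $(1-m/2)/2$ |

which yields the method-of-moments lethality estimate
$\hat\lambda = 1 - (\text{male carriers})/(\text{female carriers})$ at
birth (`estimate_male_lethality()`).

The default generator parameters are the study-scale design the package
emulates: a genotyped sire with 19 unaffected and 3 affected daughters
(plus the affected daughters' dams), a 3,708,143 bp deletion between
retained flanks 49,422,588 and 53,130,732 with a 4 bp `ACAT` junction
insertion, $m = 0.68$ (the midpoint of the 66–70% reported range),
$\lambda = 0.86$ (implied by 2 carrier males against 14 carrier females at
birth), 76 births, two sperm-FISH experiments of 1000 spermatozoa, 165
blastocysts, and 61 AI records of which 35 failed with 1 + 6 + 8 artifact
records.  These defaults are fixed study conditions, not tuning knobs.

## Mendelian-error deletion mapping

`opposite_homozygote_flags()` marks sire–progeny call pairs {0,2} in either
order; any missing call vetoes the flag.  `build_error_profile()` tallies
these per marker, split by progeny phenotype, together with affected
heterozygosity and the number of informative comparisons (sire homozygous,
progeny called).

`call_candidate_regions()` seeds on markers with at least
`min_affected_errors = 2` affected errors and **zero** unaffected errors —
the affected-only requirement is what separates a transmitted deletion from
genotyping noise.  Seeds within `max_gap_bp = 1` Mb merge; clusters of
fewer than `min_cluster_size = 5` markers are dropped; bounds extend to the
midpoints with the flanking clean markers; and the score penalises affected
heterozygous markers inside the region (`het_penalty = 1`), since a truly
hemizygous animal can only be heterozygous there by call error.  Ties in
score break to the leftmost region, so output order is deterministic.

Resolution is bounded by the marker lattice *and* by detection
probability: a given in-deletion marker yields an error in a given trio
only when the sire is homozygous and the transmitted maternal allele is
opposite (roughly $p q$ averaged over allele frequencies, with the
affected-only seed rule discarding more), so the outermost *detected*
marker sits, in expectation, several markers inside the true flank.  The
mapped region is accordingly expected to under-cover a multi-megabase
deletion by some hundreds of kilobases at 50K-like density — tests assert
truth overlap on every seeded cohort and containment within the
midpoint-extension geometry, not base-pair agreement.

`hemizygosity_consistency()` checks, over informative in-region markers,
that each affected call is homozygous for an allele its dam carries
(i.e. explainable by loss of the paternal allele); on error-free cohorts it
is exactly 1 inside the deletion and strictly below 1 on random regions.

## Sequencing evidence

`normalize_depth()` scales window depth by the genome median;
`segment_depth()` smooths with a running median ($k = 5$), bins into
nullizygous/hemizygous/diploid at 0.25 and 0.75, and absorbs state runs
shorter than `min_windows` into their longer neighbour.  At the default
12× coverage with 10 kb windows, $P(\text{Pois}(12) \le 8) \approx 0.155$
and the median filter turns chance dips into spurious hemizygous runs of
5–8 windows at a rate of about one per thousand windows; `min_windows = 25`
(250 kb) is therefore the default — far above what noise reaches, far
below the megabase scale this caller targets.  Smoothing shifts state
transitions by up to $\lfloor k/2 \rfloor$ windows, so called boundaries
are expected within about 3 windows of the true flanks, and the called
`mean_ratio` of the deletion segment sits at 0.5.

`locate_breakpoints_from_pairs()` brackets the junction from discordant
pairs (insert beyond mean + 4 SD), each fully aligned read contributing
only its own extent so clipped reads can never push the bracket past a
flank.  `assemble_junction()` then builds per-side majority consensus
(≥ 60% per column, else an ambiguity error) from the clipped reads in the
bracket; right-clip positions fix the left flank, left-clip positions the
right flank, and a missing side is recovered by anchoring the other side's
consensus against the reference (12 bp anchors, unique-match required).
The inserted sequence is the consensus prefix/suffix that does not match
the reference extension, requiring at least 5 matching flank bases so a
chance one-base agreement cannot masquerade as a shorter insert; a
consensus too short to test every candidate insert length is treated as
inconclusive rather than conflicting, because left-clip heads are
structurally short (at most `min_anchor + insert` bases).  With fewer than
`min_support = 3` clipped reads the caller refuses (`insufficient
support`) rather than guessing — across seeded cohorts every produced call
is exact to the base, including the empty insertion of a clean deletion.

`deletion_length()` fixes the coordinate convention: printed breakpoint
positions are the *retained* flanking bases, the deleted interval is open,
and length $= \text{right} - \text{left} - 1$ — the only convention under
which the printed flanks and printed length agree.  `merge_evidence()`
gives junction coordinates precedence over window-resolution segments and
flags a junction without overlapping hemizygous depth as discordant.

The reference is supplied as a fetch function; the simulator caches ±1 kb
of synthetic sequence around each true flank, which is the only part any
assembly step reads.  No external genome is used.

## Transmission statistics

All chi-square and binomial machinery delegates to `stats::`:
`chi2_independence_2x2()` is the uncorrected Pearson test (the continuity
correction is deliberately absent — the corrected statistic on the progeny
table would be ≈ 5.3, not the 6.7 the uncorrected test gives),
`chi2_goodness_of_fit()` the usual $\sum (O-E)^2/E$ with $k - 1$ df, and
the dominant-inheritance expectation is the equal-quarters vector (carrier
× sex, heterozygous non-mosaic sire, 1:1 sex ratio).
`stage_comparison()` tests the *later* stage's counts against the
*earlier* stage's proportions; the direction is a package choice (the
natural reading of "does the distribution change as development
proceeds?") and is overridable by swapping arguments.  A zero reference
cell pools with the same-carrier opposite-sex cell before testing, and
pooling that would silently discard observed counts errors instead.

At the default parameters the analytic power of the sperm-versus-birth
comparison (noncentrality ≈ 10.9 at $n = 76$, 3 df) is about 0.80 at
$\alpha = 0.05$ and 0.59 at $\alpha = 0.01$, so the tests assert the
stable qualitative pattern across seeds — sperm versus blastocyst central
(median $p > 0.05$), sperm versus birth distorted (median $p < 0.05$,
majority of seeds significant) — rather than a near-certain significance
that the design cannot deliver.

`welch_t()` computes the Welch statistic and Welch–Satterthwaite df from
group summaries (no installed routine accepts summaries directly); it is
cross-checked in the tests against `t.test()` on raw vectors constructed
to have exactly those summaries.

`filter_ai_records()` applies the three artifact rules in fixed order —
superovulation, adjacent AI within 1 day, low-fertility cow (≥ 3
consecutive failures) — attributing each discard to the first matching
rule so category counts stay disjoint (1 + 6 + 8 on the default cohort,
leaving 20 clean failures).  `lethality_window()` converts each clean
failure to an upper bound on the conceptus's gestation length: interval to
the next AI minus one cycle (21 d), or interval to the next calving minus
gestation (285 d) minus one cycle.  Non-positive bounds are flagged
inconsistent and excluded from the maximum; records with no next event are
a precondition violation, and an all-invalid set yields an explicit NA
maximum rather than a number.

## What the generator does and does not emulate

The generator reproduces the *structure* of the evidence: apparent
homozygosity with a small hemizygote no-call rate (arrays cannot see copy
number, so the founder's own array calls are his constitutional diploid
genotype — mosaicism affects transmission only), per-call flip errors at
0.002, Poisson depth, Gaussian fragment sizes, soft-clips with exact
junction-spanning sequence, and artifact-laden insemination records whose
clean failures are consistent by construction with a death-day bound of
88 days.

It does **not** emulate linkage disequilibrium (markers are independent
draws from their MAFs), array intensity or cluster-calling artifacts,
alignment ambiguity in repetitive sequence (the synthetic reference is
i.i.d. random, so 12-mers are effectively unique), GC-dependent depth
waves, or inhomogeneous insemination calendars.  Passing tests therefore
demonstrate the pipeline's correctness under the stated model, not
robustness to every failure mode of real array or sequencing data;
micro-homology at real breakpoints, in particular, could shift flank
assignment by a few bases in ways the random reference almost never
produces.

## Numerical and design choices

- Internal coordinates are 1-based inclusive everywhere; BED converts at
  the IO boundary and round-trips exactly.
- Missing genotype calls are −1 in memory and on disk; missing parents are
  `"0"` in pedigree files; an empty clipped sequence is `"."` on disk.
- Parsing is strict by default (unknown genotype tokens are errors);
  lenient mode coerces them to −1.  Synthetic data should never need
  silent coercion.
- All randomness flows from one `set.seed()` at the top of
  `simulate_cohort()`, with components drawn in a fixed order, so a bundle
  is bit-reproducible from its seed; `run_pipeline()` reports are
  byte-identical across reruns of the same configuration.
- The error-region score's tie-break (leftmost wins) and the
  largest-neighbour rule for absorbing short depth runs make every output
  deterministic.
- Problem sizes used in the test-suite simulations: full default cohorts
  (6000 markers, 12,000 depth windows) for region-recovery runs, a
  reduced 600-marker / 20 Mb / 600 kb-deletion configuration for IO and
  junction tests, 200 seeds for count-moment checks, 2000 draws for CI
  coverage.

## A worked run

```{r, eval = FALSE}
report <- run_pipeline(list(seed = 7))
report$candidate_regions[1, c("chrom", "start", "end", "n_error_markers")]
report$deletion_call$junction[c("left_flank", "right_flank", "inserted_seq")]
report$stats$mosaicism$mosaicism
report$stats$lethality$max_bound_days
report$truth_recovery
```

On seed 7 the top candidate region spans 49.47–52.82 Mb (fully inside the
true deletion, under-covering as expected at 50K-like density), the
junction call is exact — flanks 49,422,588 / 53,130,732 with insertion
`ACAT`, length 3,708,143 bp — the mosaicism estimate is `2 * k / n` of the
simulated sperm counts, and the lethality window maximum never exceeds the
generator's 88-day truth bound.

## Known limitations

- The mapped region's boundary error is set by marker density times
  detection probability (hundreds of kb here), not by the algorithm; only
  sequencing evidence is base-exact.
- `assemble_junction()` assumes a single junction inside the bracket;
  two nearby events would be flagged ambiguous, not decomposed.
- The lethality bound is an upper bound from observational records, not a
  survival model of death timing; it inherits the fixed average cycle and
  gestation lengths.
- With fewer than about 15 informative markers in the deletion the seed
  threshold (2 affected errors, 5-marker clusters) can fail to fire;
  density, not the scan, is then the limit.
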