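---
title: "Quantifying allele-specific CRISPR editing outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific CRISPR editing outcomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## Scope and model

`ampedit` analyses deep amplicon sequencing of a diploid locus whose two
alleles differ at exactly one position, after CRISPR-Cas9 editing aimed at
one of them. The statistical object it estimates is the per-sample
*editing profile*: the fraction of sequenced alleles (and of
target-allele reads) carrying a CRISPR-induced change, and the discrete
distribution of canonical indel variants among the edited reads. The
motivating application is a deep-intronic disease variant that creates a
cryptic donor splice site; editing success is then judged by whether the
induced indels destroy that cryptic site without touching the healthy
allele.

Three modelling assumptions run through the package:

* **Diploid, uni-allelic target.** Each sequenced read represents one
  allele of one cell, the locus is diploid, and only one allele is
  targeted. Under this assumption an editing efficiency of $e$ percent
  *of all sequenced alleles* implies $\min(100, 2e)$ percent of cells
  carry an edit; `implied_cell_fraction()` reports exactly this and
  echoes the assumption as an attribute, because it fails under
  aneuploidy, sample mixing or PCR bias.
* **Full-length amplicons.** Analysis is restricted to reads containing
  both *indicator sequences* — the first and last `indicator_len` bases
  of the reference window — in order. Reads are assumed to be pre-merged
  single sequences; paired-end merging is a solved upstream step and is
  deliberately out of scope.
* **Error model of the artifact rule.** Substitutions far from the cut
  are treated as sequencing artifacts, substitutions and indels within
  the editing window as editing outcomes. This is a *rule*, not an
  inference: a sequencing error that happens to fall inside the window is
  attributed to editing by definition (see *Known biases* below).

## The reference pair and the editing window

`build_allele_references()` extracts the $2f+1$ nt window centred on the
variant ($f$ = `flank`, default 40, so 81 nt): the *target* reference
carries the alternate base at index $f$, the *non-target* reference the
reference base; they differ nowhere else. All coordinates in the package
are 0-based and half-open; insertions use inter-base coordinates.

`locate_cut_site()` places a blunt cut `cut_offset` bases 5′ of the PAM
(default 3 — standard Cas9 biochemistry, applied uniformly to all
orthologs since none of the common ones is documented to differ at the
resolution of this analysis; configurable for exotic nucleases). The
guide must match the target reference exactly once on its stated strand
with its IUPAC PAM pattern immediately 3′; zero or multiple matches are
errors, not warnings, because a silently mis-placed window invalidates
every downstream call.

The *editing window* of half-width $h$ (default 5) is read as the
half-open base interval $[c-h, c+h)$ for substitutions and deletions and
the inclusive inter-base interval $[c-h, c+h]$ for insertions, where $c$
is the cut. "5 bases up- or downstream" is ambiguous between 10 and 11
bases; the half-open choice is symmetric around the cut, covers exactly
$2h$ bases, and is exposed through `half_width` so either convention can
be selected.

## Alignment and canonicalization

Reads are aligned globally against **both** references with affine gap
penalties (Gotoh's algorithm, implemented in C++). Defaults
(+2 match, −3 mismatch, −8 gap open, −1 gap extend; a gap of length $L$
costs $\mathrm{open} + (L-1)\,\mathrm{extend}$) make one long gap cheaper
than scattered mismatches — a 9-base deletion costs −16 while nine
mismatches would cost −45 — which matches the dominant single-indel
structure of Cas9 repair outcomes. End gaps are penalized because
qualifying reads span the whole window; a `free_ends` policy exists for
truncated-read experiments.

Dynamic-programming optima are not unique, so two layers force
determinism:

1. the traceback prefers diagonal over deletion over insertion at every
   tie, and
2. `normalize_ops()` left-aligns every indel to the start of its repeat
   context, merges adjacent compatible operations, and iterates to a
   fixed point.

The result is one canonical operation list per edit-equivalence class:
idempotent, independent of which optimal alignment produced it, and used
to build the spectrum key `kind|offset|ref_len|alt` (offsets relative to
the cut). Substitutions are kept per base rather than merged into runs,
which keeps the discriminating-base exclusion (below) exact.

The test suite checks the aligner against an *exhaustive recursive
oracle* — a memoised three-state recursion written independently of the
C++ code — on 10,000 random sequence pairs up to length 12, and checks on
every produced alignment that applying the operations to the reference
reconstructs the read exactly.

## Allele assignment and classification

A read is assigned to the allele with the higher alignment score. On a
tie, the base aligned opposite the discriminating position decides;
if that base is deleted or matches neither allele the read is
*ambiguous* — kept in the filtered-read denominator, excluded from both
allele tallies, and reported separately. The substitution at the
discriminating position itself is allele signal and is never counted as
an edit or an artifact on either allele.

Within-window operations set the mutation class with the priority
deletion+insertion > deletion > insertion > base-pair exchange > WT.
Out-of-window substitutions are tallied as artifacts. The protocol rules
only on out-of-window *substitutions*; for out-of-window **indels** the
package takes the conservative symmetric choice: the read stays WT,
is excluded from edited counts, and is tallied in a dedicated
`n_offwindow_indel` field so the choice is fully visible in the output.

## The synthetic generator: what it emulates and what it does not

`simulate_reads()` draws, per read: allele of origin
(Bernoulli, default share 0.5 — a balanced diploid locus), edited status
on the target allele (Bernoulli, default rate 0.3, the upper end of the
20–30% range typical of ribonucleoprotein transfection bulks), an
outcome from the configured spectrum (default del9 0.49, insA 0.27,
insT 0.12, del2 0.12 — one dominant microhomology-style deletion plus
1-bp insertions, the characteristic shape of single-cut repair), and
independent per-base substitution errors (default 0.001, typical for
merged short reads) on positions not created by the variant. Qualities
are constant Q30 because classification ignores them. Output is
byte-deterministic given the seed.

The generator deliberately does **not** model PCR amplification bias,
chimeras, platform-specific indel errors, or UMI structure. Passing
end-to-end tests therefore demonstrate the correctness of the *analysis
rules*, not robustness to those real-data pathologies; the optional
indel-error and `free_ends` settings let a user stress two of them.

The built-in `demo_locus()` is fully synthetic: an 81-nt window whose
centre C>T completes a canonical donor motif (`CAG|GTAAGT`) and whose
guide covers the variant with an NGG PAM placing the cut 6 bases
downstream. The cut was placed so that the default spectrum's deletions
never remove the discriminating base — otherwise every edited read would
be allele-ambiguous and efficiencies unmeasurable. The geometric price
is that those deletions clip only the intronic tail of the donor motif,
so the built-in PWM comparator scores them *neutral* rather than
*disrupting*; fixtures that do destroy the GT core are used to exercise
the disrupting branch.

## Known biases and numerical choices

* **Artifact-rule false positives.** With a per-base error rate
  $\epsilon$ and a $2h$-base window, a fraction $\approx 2h\epsilon$ of
  truly unedited reads acquires a window substitution and is counted as
  `base_pair_exchange`. At defaults this inflates within-target
  efficiency by ~0.7–0.9 percentage points and dilutes every spectrum
  share by ~2–3% relative. This is forced by the classification rule
  itself, and at low editing rates it exceeds three binomial standard
  errors of a 20,000-read sample no matter how good the implementation
  is. The tests therefore separate the two effects: estimator
  consistency is verified on error-free reads against the nominal rates
  0.1/0.25/0.3 over 20 seeds, the rule-forced bias is asserted to be
  positive and bounded by $2(2h{+}1)\epsilon$ at the default error
  rate, and the default-condition recovery (rate 0.3, error 0.001,
  10 seeds) is checked against the generator's realized truth table,
  where the pipeline-only error sits well within three
  binomial/multinomial standard errors.
* **Efficiency denominators.** Both "of all filtered alleles" and
  "within the target allele" are always reported, since both framings
  are in common use and they differ by the allele share.
* **Degenerate inputs.** Zero filtered reads yield a zero profile with
  missing (".") percentages rather than an error; samples below
  `min_reads_per_sample` (default 10,000) warn but still process;
  spectra with zero mass refuse comparison.
* **Concordance statistics.** Pearson $r$ over the union of variant keys
  (missing = 0) plus total variation distance
  $\tfrac{1}{2}\sum_k |a_k - b_k|/100$; $r$ is undefined (reported `NA`)
  when fewer than two keys or zero variance — TVD covers those cases.
  Neither statistic is canonical for spectra; both are reported for
  interpretability.
* **PWM scorer.** Log-odds with pseudocount 0.5 against a configurable
  background; the built-in matrix encodes the classic U2 donor-site
  composition over positions −3..+6. It is a monotone splice-score
  comparator, not a splice predictor: categories are *relative* to the
  wild-type and pathological scores (disrupting strictly below wild
  type; enhancing at or above pathological; margins configurable).
  Externally computed scores (e.g. from a deep-learning predictor) can
  be substituted via `external_splice_scores()` without changing the
  comparator logic. Acceptor-site scoring uses the same machinery with
  a second matrix and is off by default.
* **Prevalence aggregation.** The three-dataset mean counts "not
  detected" as 0 but keeps rows missing everywhere as missing ("–"),
  reproducing the source table's own distinction; values are rounded to
  8 decimals, the table's print precision. Decimal commas are accepted
  on input.

## Problem sizes

The shipped tests run the full pipeline at 20,000 reads per sample
(30 simulated samples across the recovery properties), the alignment
oracle at 10,000 random pairs, and keep each module's unit fixtures at
tens of reads; the complete suite finishes in roughly two minutes on one
core. The acceptance script (`scripts/acceptance.R`) re-runs one 20,000
read sample, three 12,000-read replicates and the prevalence table in a
few seconds.

## Limitations

Beyond the generator's simplifications listed above: the package handles
exactly two alleles (no multi-allelic loci), does not use base
qualities, does not detect chimeric reads, and does not attempt to
reproduce any external alignment service's parameters — equivalence with
web-tool outputs is not claimed. Population-genetic interpretation of
the prevalence module (carrier frequencies, Hardy–Weinberg) is out of
scope.
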