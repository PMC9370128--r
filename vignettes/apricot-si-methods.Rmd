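---
title: "Methods: S-genotyping, compatibility classification, and S-locus diversity in apricot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: S-genotyping, compatibility classification, and S-locus diversity in apricot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apricotSI)
```

## The biological model

Apricot carries Rosaceae-type gametophytic self-incompatibility (GSI). The
multiallelic S-locus holds the pistil-expressed *S-RNase* and the
pollen-expressed *SFB* gene; a haploid pollen grain is arrested in the
style when its S-allele matches either of the two alleles expressed by the
diploid pistil. The model in `pollen_rejected()` is exactly that rule plus
one apricot-specific exception: the *Sc* haplotype carries a 358 bp
insertion in *SFBc* that inactivates the pollen-side recognition, so *Sc*
pollen is accepted by every pistil, including *Sc*-carrying ones.
Consequences implemented throughout the package:

- a genotype containing *Sc* is self-compatible;
- two self-incompatible cultivars sharing both alleles are mutually
  cross-incompatible (an *incompatibility group*); sharing one allele makes
  a cross semi-compatible (half the pollen rejected); sharing none, fully
  compatible;
- *ScSc* homozygotes and, more generally, self-compatible cultivars are
  universal pollen donors.

`cross_verdict()` counts rejected donor haplotypes r ∈ {0, 1, 2} and maps
them to fractions of compatible pollen 1, 0.5, 0. Semi-compatible crosses
are reported as their own category and never folded into "incompatible":
yield effects of semi-compatibility are documented in other *Prunus* crops
but not established in apricot, so the package keeps the distinction
visible and leaves agronomic judgement to the user.

## Genotype calling from fragment sizes

Input is a set of per-assay fragment-size lists (electropherogram peak
calling is upstream of this package). The packaged panel
(`default_panel()`) encodes the diagnostic sizes:

| assay | product | candidates |
|---|---|---|
| SRC_FIRST_INTRON | 358 bp | {Sc, S8} (ambiguity class) |
| SRC_FIRST_INTRON | 408 bp | {S1, S7} (ambiguity class) |
| SRC_FIRST_INTRON | 390 bp | {S6, S9} (placeholder, `verified = FALSE`) |
| PRUC_SECOND_INTRON | 1300 / 1500 bp | S6 / S9 (placeholders) |
| SHLM12 | 650 bp | S1 |
| SHLM34 | 413 bp | S7 |
| APRFBC8 | 150 / 500 bp | S8 / Sc |

Only the sizes anchored to published electropherograms are marked
verified. First-intron sizes for the remaining alleles exist in the prior
literature but are not printed in the sources transcribed here, so they
are configurable panel entries rather than hard-coded guesses; the
`verified = FALSE` rows (including both Pru-C2/C4R products) are synthetic
placeholders whose only job is to make the S6/S9 disambiguation path and
the simulator exercisable. Users with calibrated size tables should extend
the panel CSV.

Numerical choices:

- **Size tolerance** defaults to 3 bp per entry — the scale of capillary
  electrophoresis sizing error. The panel validator requires expected
  sizes within an assay to differ by more than twice the tolerance, which
  makes size matching unambiguous by construction and calling invariant to
  within-tolerance jitter.
- **Decision tree**: each first-intron peak is matched to a size class; a
  single-candidate class is diagnostic on its own, while ambiguity classes
  need a member confirmed by a specific secondary assay. An allele
  reported by a specific assay but unsupported by any first-intron peak is
  retained (the more specific assay wins, as the bench workflow intends)
  and the disagreement is logged in the trace.
- **Degenerate outcomes**: more than two resolved alleles is an error
  carrying the trace; zero resolved alleles with no pending ambiguity is
  `UNRESOLVED`. An unresolved {Sc, S8} class — the signature of AprFBC8
  primer mismatch — flags `NEEDS_POLLINATION_TEST`, and a lone *Sc*
  amplification is recorded as (Sc, unknown) with a presumed-homozygote
  marker rather than being promoted to *ScSc*.

`predict_amplicons()` is the exact forward model; round-tripping it
through `call_genotype()` is the identity on every heterozygous pair the
panel can resolve, which the test suite asserts exhaustively.

## Pollen-tube scoring

`summarize_self_pollination()` turns pistil-level microscopy scores
(percent of style traveled, reached-base flag, callose tip) into a call.
Defaults: at least **10 pistils** for a conclusive call and a majority
threshold of **0.5** — the smallest defensible reading of "most pistils";
both are arguments. The mean percent of style traveled is computed over
all pistils, counting reached-base pistils at 100, which matches how such
summaries are reported. Failing cross-pollination controls warn but do not
veto a call: a failed control suggests pollen- or pistil-quality problems
and deserves attention, but the self-pollination evidence remains what it
is. `resolve_sc_s8()` then maps self-compatible → *Sc* and
self-incompatible → *S8*.

## Classification precedence

`classify_self_compatibility()` applies, in order: *Sc* present →
self-compatible; direct phenotype evidence (a microscopy summary or a
recorded pollination-test result) → its call; *S8* without *Sc* →
self-incompatible; any other complete non-*Sc* genotype →
self-incompatible; otherwise unclassified. Putting phenotype evidence
ahead of the genotype presumptions is a deliberate design choice: the
genotype rules are presumptions from S-locus content, and a handful of
cultivars ('Katy' being the canonical case) are self-compatible through
pollen-part mutations outside the S-locus, so a verified phenotype must be
able to override them. The packaged compilations carry such literature
phenotypes in a dedicated `phenotype` column; the package does not model
the underlying M-locus genetics.

Presumed-homozygous single-*Sc* records are treated as *ScSc* for cross
verdicts (their pollen is all *Sc*) but keep the presumption flag in
reports, since homozygosity would require sequencing to confirm.

## Incompatibility groups

`assign_groups()` assigns only self-incompatible cultivars with complete
genotypes. Lookup order: registry genotype → historical label; novel
genotype shared by ≥ 2 input cultivars → a new group numbered after the
registry's highest Roman numeral (continuing the accreted historical
series rather than restarting); novel unique genotype → group `"0"`,
the universal-pollinizer candidates. The packaged registry covers groups
I–XXVI plus the group-0 genotypes; one transcription choice deserves
note: the source table prints the label XXVI for two different genotypes
(S1S6 and S6S8), which its own row order shows to be a typographical slip,
so the registry records S1S6 as XXIV. Without that correction the defining
property of the partition — all pairs within a numbered group
incompatible, no incompatible pair across two numbered groups — would be
violated; the test suite asserts the property exhaustively over the full
compilation. Group 0 is exempt from the property (its members share no
genotype with anyone *by definition of the table*, though the transcribed
table itself contains two repeated genotypes there, kept verbatim).

## Diversity statistics

`count_alleles()` builds the population × allele copy-count table: a
complete genotype contributes two copies (homozygotes two of one allele);
an incomplete genotype contributes its known allele as one copy — throwing
away the known copy would silently deflate allele counts — and
presumed-homozygous records likewise contribute one observed copy only.
Optional mean-frequency imputation (`impute = TRUE`, off by default)
replaces each unknown copy with the pooled allele-frequency vector,
yielding fractional counts; it is off by default because downstream
conventions for fractional counts differ between software packages and the
imputation changes no conclusion on complete data.

`allelic_richness()` is hypergeometric rarefaction,
\(A_r(g) = \sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]\), computed on log
scale; with fractional counts the binomial coefficients generalize through
the gamma function, and any allele with \(N - N_i < g\) contributes 1
exactly. `g` defaults to the minimum copy total across included
populations — the smallest population sets the comparable scale, standard
rarefaction practice. At `g = N` the estimator returns the observed
\(N_a\) identically. Note that published per-country tables computed with
other software can embed a different (unstated) convention for very small
populations — single-cultivar countries are sometimes printed with
\(A_r < N_a\) at what would be full sample size, which plain
hypergeometric rarefaction cannot produce; this package documents its
convention instead of imitating an unverifiable one, and keeps
single-cultivar populations by default (`min_cultivars = 1`).

`chisq_monte_carlo()` computes Pearson's \(X^2\) and a simulated p-value
\((1 + \#\{X^2_b \ge X^2_{obs}\})/(B+1)\) from `B = 2000` null tables
drawn uniformly with both margins fixed (Patefield's algorithm via
`stats::r2dtable`). The add-one correction avoids p = 0 at small `B`. The
statistic is cross-checked against `stats::chisq.test` to 1e-9 and the
test's empirical size at α = 0.05 is verified to sit in [0.03, 0.07] over
500 null simulations. Zero rows/columns are dropped with a warning;
fractional (imputed) tables are rounded for the null sampler only.

## The synthetic generator

`simulate_cultivars()` draws diploid genotypes allele-by-allele from a
population's frequency vector, with three structural features of real
S-locus data: (i) the **GSI constraint** — non-*Sc* homozygotes are
rejection-resampled, since a self-incompatible homozygote cannot arise
under GSI, while *ScSc* can; (ii) an optional forced self-compatible
fraction (`sc_fraction`); (iii) masking of the second allele with a given
missingness rate, emulating single-allele reports from preferential
amplification. `simulate_assays()` forward-predicts every panel product
and adds Gaussian sizing jitter plus per-assay dropout (the
no-amplification outcome). `simulate_pistils()` uses a deliberately
separated two-regime model: self-compatible pistils reach the base (100%
traveled); self-incompatible ones arrest with a callose tip at a percent
drawn uniformly on [40, 80], bracketing reported mid-style arrest means.
A single global seed fans out to fixed per-stage child seeds, so
end-to-end runs are byte-reproducible.

What the generator does **not** emulate: pedigree/coalescent structure,
linkage, genotyping artifacts beyond Gaussian jitter and dropout, pistil
counts varying by flower quality, or partial-style arrest in compatible
crosses. Passing recovery tests on synthetic data therefore demonstrates
the correctness of the decision tree and estimators under the package's
own error model, not robustness to every bench artifact.

Problem sizes used by the test suite were chosen to make sampling error
negligible relative to the asserted tolerances: 500 cultivars per
population for frequency recovery (binomial SD ≈ 0.01 per allele at
uniform frequencies, against a 0.03 tolerance), 500 null tables for the
size check of the Monte-Carlo test, and exhaustive enumeration (≤ 12
copies) for the rarefaction oracle.

## Known limitations

- Country and origin-class metadata in the packaged compilations are
  filled only where the transcribed sources state them; most records carry
  `unknown`, so per-country diversity summaries on the fixtures are
  illustrative, not authoritative. The diversity machinery is validated on
  synthetic populations with known ground truth instead.
- The panel ships with placeholder (unverified) sizes for the S6/S9 paths;
  calling those alleles on real data requires user-supplied calibrated
  sizes.
- Homozygosity of single-*Sc* cultivars is presumed, not demonstrated.
- Flowering-time overlap, the other half of pollinizer choice in practice,
  is out of scope.
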