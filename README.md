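# apricotSI

Pollination requirements of apricot (*Prunus armeniaca*) cultivars under
gametophytic self-incompatibility (GSI).

Most apricot cultivars carry a functional S-locus: the pistil expresses an
S-RNase and the pollen an SFB (S-haplotype-specific F-box) protein, and a
pollen grain is rejected whenever its single S-haplotype matches either of
the two S-alleles expressed in the pistil. One haplotype, *Sc*, carries a
358 bp insertion in *SFBc* that abolishes pollen-side rejection, so
*Sc*-carrying cultivars are self-compatible. Orchard design therefore
hinges on S-genotypes: self-incompatible cultivars sharing both S-alleles
form a cross-incompatibility group and cannot pollinate each other.

The package implements the full desk workflow used to genotype and classify
cultivars:

- **Allele calling** (`call_genotype()`): resolves an S-genotype from
  multi-primer PCR fragment sizes. The S-RNase first-intron assay (SRc)
  classifies haplotypes by size — 358 bp is the *Sc*/*S8* ambiguity class,
  408 bp the *S1*/*S7* class — and allele-specific assays narrow each
  class: SHLM1/2 (650 bp → *S1*), SHLM3/4 (413 bp → *S7*), Pru-C2/C4R
  (second intron, *S6* vs *S9*), and AprFBC8 on the SFB region
  (150 bp → *S8*, 500 bp → *Sc*).
- **Pollen-tube scoring** (`summarize_self_pollination()`,
  `resolve_sc_s8()`): when AprFBC8 fails to amplify, fluorescence
  microscopy of self-pollinated pistils decides the *Sc*/*S8* ambiguity
  (tubes reaching the style base → *Sc*; arrest mid-style with callose
  tips → *S8*).
- **Classification and groups** (`classify_self_compatibility()`,
  `assign_groups()`, `pollinizer_matrix()`): self-(in)compatibility calls,
  incompatibility-group allocation against the historical registry
  (groups I–XXVI plus group 0 for so-far-unique genotypes), and
  donor × pistil compatibility matrices.
- **S-locus diversity** (`diversity_report()`): per-population allele
  counts and frequencies, rarefied allelic richness
  `A_r(g) = Σ_i [1 − C(N−N_i, g) / C(N, g)]`, private alleles, and a
  Monte-Carlo chi-square test of allele × country association with
  fixed-margins (Patefield) null tables.
- **Synthetic data** (`simulate_cultivars()`, `simulate_assays()`,
  `simulate_pistils()`): seeded generators for population allele pools,
  diploid genotypes under the GSI constraint, noisy amplicon sizes with
  assay dropout, and pistil-level outcomes.

Published cultivar compilations (103 self-incompatible/unclassified
records, 153 self-compatible records, and the 66-cultivar study cohort),
the primer panel, and the group registry ship as plain-text fixtures via
`load_fixture()`.

## Worked example

```r
library(apricotSI)

study <- load_fixture("study66")
cl <- classify_cultivars(study)
table(cl$self_compat)
#>   SELF_COMPATIBLE SELF_INCOMPATIBLE      UNCLASSIFIED
#>                49                12                 5
```

Of the 66 genotyped cultivars, 49 are self-compatible (48 carry *Sc*, one
is a pollen-part mutant verified by pollination tests), 12 are
self-incompatible, and 5 expose only a single non-*Sc* allele and stay
unclassified. The self-incompatible ones land in their
cross-incompatibility groups:

```r
asg <- assign_groups(study)
head(asg[order(asg$group), ], 5)
#>                  name genotype group
#> 12             Harcot     S1S4     0
#> 1               Muñoz     S2S6   III
#> 2             Pandora     S2S6   III
#> 3           Sweet Cot     S2S8     V
#> 4  Apribang (ASF0405)     S6S9  VIII
```

'Harcot' (S1S4) has no genotype partner, so it joins group 0 — a
universal-pollinizer candidate. A caller run on the fragment sizes of a
two-peak electropherogram:

```r
call_genotype(list(SRC_FIRST_INTRON = c(358, 408),
                   SHLM12 = 650, APRFBC8 = 500))
#> <s_call> status: COMPLETE
#> genotype: S1Sc
```

The 650 bp SHLM1/2 product resolves the 408 bp class to *S1*; the 500 bp
AprFBC8 product resolves the 358 bp class to *Sc*.

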