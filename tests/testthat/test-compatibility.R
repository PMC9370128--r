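test_that("genotype-based self-compatibility calls follow the Sc/S8 rules", {
  si <- classify_self_compatibility(s_genotype("S2", "S6"))
  expect_equal(si$call, "SELF_INCOMPATIBLE")
  expect_equal(si$basis, "two_nonSc_alleles")

  sc <- classify_self_compatibility(s_genotype("S5", "Sc"))
  expect_equal(sc$call, "SELF_COMPATIBLE")
  expect_equal(sc$basis, "Sc_present")

  un <- classify_self_compatibility(s_genotype("S3"))
  expect_equal(un$call, "UNCLASSIFIED")
  expect_equal(un$basis, "insufficient_genotype")

  # an S8 carrier without Sc is presumed self-incompatible even if incomplete
  s8 <- classify_self_compatibility(s_genotype("S8"))
  expect_equal(s8$call, "SELF_INCOMPATIBLE")
  expect_equal(s8$basis, "S8_no_Sc")
})

test_that("direct phenotype evidence overrides genotype presumption", {
  # pollen-part mutants outside the S-locus: self-compatible despite S1S2
  katy <- classify_self_compatibility(s_genotype("S1", "S2"), phenotype = "SC")
  expect_equal(katy$call, "SELF_COMPATIBLE")
  expect_equal(katy$basis, "microscopy")

  # a microscopy summary works the same way
  obs <- simulate_pistils("X", "SI", n = 12, seed = 3)
  summ <- summarize_self_pollination(obs)
  mic <- classify_self_compatibility(s_genotype("S3"), phenotype = summ)
  expect_equal(mic$call, "SELF_INCOMPATIBLE")
  expect_equal(mic$basis, "microscopy")

  # Sc in the genotype still decides first
  both <- classify_self_compatibility(s_genotype("S1", "Sc"), phenotype = "SI")
  expect_equal(both$basis, "Sc_present")
})

test_that("pollen rejection implements GSI with the Sc exception", {
  expect_true(pollen_rejected("S1", s_genotype("S1", "S2")))
  expect_false(pollen_rejected("S3", s_genotype("S1", "S2")))
  expect_false(pollen_rejected("Sc", s_genotype("Sc", "Sc")))
  expect_false(pollen_rejected("Sc", s_genotype("S1", "Sc")))
  expect_error(pollen_rejected("S1", s_genotype("S3")), "complete")
  # presumed ScSc pistils are usable
  expect_false(pollen_rejected("Sc", s_genotype("Sc", presumed_homozygous = TRUE)))
})

test_that("cross verdicts count rejected donor haplotypes", {
  v <- cross_verdict(s_genotype("S1", "S2"), s_genotype("S1", "S2"))
  expect_equal(v$category, "INCOMPATIBLE")
  expect_equal(v$compatible_pollen_fraction, 0)

  v <- cross_verdict(s_genotype("S1", "S2"), s_genotype("S1", "S3"))
  expect_equal(v$category, "SEMI_COMPATIBLE")
  expect_equal(v$compatible_pollen_fraction, 0.5)

  # self-compatible cultivars are universal pollen donors
  v <- cross_verdict(s_genotype("Sc", "Sc"), s_genotype("S6", "S9"))
  expect_equal(v$category, "FULLY_COMPATIBLE")

  v <- cross_verdict(s_genotype("S1", "S2"), s_genotype("S3", "S4"))
  expect_equal(v$category, "FULLY_COMPATIBLE")

  v <- cross_verdict(s_genotype("S1"), s_genotype("S1", "S2"))
  expect_equal(v$category, "UNDETERMINED")
  expect_true(is.na(v$compatible_pollen_fraction))
})

test_that("any Sc-carrying cultivar keeps at least half its pollen acceptable", {
  set.seed(5)
  others <- sample(setdiff(s_alleles(), "Sc"), 12)
  for (a in others) {
    v <- cross_verdict(s_genotype(a, "Sc"), s_genotype(a, "Sc"))
    expect_gte(v$compatible_pollen_fraction, 0.5)
  }
})

test_that("group allocation uses the registry, founds new groups, and falls back to 0", {
  t1 <- load_fixture("compiled_si_table1")
  asg <- assign_groups(t1)
  expect_equal(asg$group[asg$name == "Farely"], "XXV")
  expect_equal(asg$group[asg$name == "Samourai"], "XXI")
  expect_equal(asg$group[asg$name == "Martinet"], "0")
  expect_equal(asg$group[asg$name == "Harcot"], "0")
  # unclassified single-allele records are listed separately, unassigned
  expect_true("Mogador" %in% attr(asg, "unclassified"))
  expect_false("Mogador" %in% asg$name)

  # a novel genotype shared by two cultivars founds the next numbered group
  novel <- make_cultivar_table(c("N1", "N2", "N3"),
                               c("S5", "S5", "S13"), c("S13", "S13", "S22"))
  asg2 <- assign_groups(novel)
  expect_equal(asg2$group[asg2$name %in% c("N1", "N2")], c("XXVII", "XXVII"))
  expect_equal(asg2$group[asg2$name == "N3"], "0")
  expect_equal(attr(asg2, "new_groups"), "XXVII")

  empty <- make_cultivar_table(character(0), character(0))
  expect_equal(nrow(assign_groups(empty)), 0)
})

test_that("the pollinizer matrix encodes verdicts with a self-verdict diagonal", {
  t1 <- load_fixture("compiled_si_table1")
  g8 <- t1[t1$allele1 == "S6" & !is.na(t1$allele2) & t1$allele2 == "S9", ]
  m <- pollinizer_matrix(structure(g8, class = c("cultivar_table", "data.frame")))
  expect_true(all(m == "I"))

  mix <- make_cultivar_table(c("SelfFert", "A", "B"),
                             c("Sc", "S1", "S1"), c("Sc", "S2", "S3"))
  mm <- pollinizer_matrix(mix)
  expect_true(all(mm["SelfFert", ] == "F"))
  expect_equal(mm["A", "A"], "I")
  expect_equal(mm["A", "B"], "S")
})

test_that("verdicts are symmetric for complete heterozygous non-Sc genotypes", {
  sp <- population_spec("t", paste0("S", 1:8), rep(1 / 8, 8), n = 10)
  sim <- simulate_cultivars(sp, seed = 99)
  m <- pollinizer_matrix(sim$cultivars)
  expect_identical(unname(unclass(m)), unname(t(unclass(m))))
})

test_that("the study cohort partitions into the three classes", {
  cl <- classify_cultivars(load_fixture("study66"))
  expect_equal(sum(table(cl$self_compat)), 66)
})
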