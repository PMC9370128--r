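test_that("population specs validate their parameters", {
  expect_error(population_spec("p", c("S1", "S2"), c(0.7, 0.7), n = 5),
               "sum to 1")
  expect_error(population_spec("p", c("S1", "S2"), n = 5, sc_fraction = 1.5),
               "sc_fraction")
  expect_error(population_spec("p", c("S1", "S2"), n = 5, missingness = -0.1),
               "missingness")
  expect_error(population_spec("p", c("S99"), n = 5), "unknown S-allele")
})

test_that("generation is reproducible byte-for-byte under a seed", {
  sp <- population_spec("PopA", c("S1", "S2", "Sc"), c(0.4, 0.3, 0.3), n = 100)
  a <- simulate_cultivars(sp, seed = 7)
  b <- simulate_cultivars(sp, seed = 7)
  expect_identical(a, b)
  c <- simulate_cultivars(sp, seed = 8)
  expect_false(identical(a$truth, c$truth))
  expect_equal(nrow(a$cultivars), 100)
})

test_that("the GSI constraint forbids non-Sc homozygotes", {
  sp <- population_spec("P", c("S1", "S2", "Sc"), c(0.45, 0.45, 0.1), n = 400)
  sim <- simulate_cultivars(sp, seed = 3)
  hom <- sim$truth$allele1 == sim$truth$allele2
  expect_true(all(sim$truth$allele1[hom] == "Sc"))

  # switched off, non-Sc homozygotes appear at these frequencies
  free <- simulate_cultivars(sp, gsi_constraint = FALSE, seed = 3)
  homf <- free$truth$allele1 == free$truth$allele2
  expect_true(any(free$truth$allele1[homf] != "Sc"))
})

test_that("missingness masks the expected share of second alleles", {
  sp <- population_spec("P", paste0("S", 1:6), rep(1 / 6, 6), n = 1000,
                        missingness = 0.1)
  sim <- simulate_cultivars(sp, seed = 11)
  frac <- mean(is.na(sim$cultivars$allele2))
  expect_gt(frac, 0.07)
  expect_lt(frac, 0.13)
  expect_identical(is.na(sim$cultivars$allele2), sim$truth$masked)
})

test_that("sc_fraction forces the self-compatible share of genotypes", {
  sp <- population_spec("P", c("S1", "S2", "S3", "Sc"),
                        c(0.3, 0.3, 0.3, 0.1), n = 600, sc_fraction = 0.6)
  sim <- simulate_cultivars(sp, seed = 23)
  carries_sc <- sim$truth$allele1 == "Sc" | sim$truth$allele2 == "Sc"
  expect_gt(mean(carries_sc), 0.55)
  expect_lt(mean(carries_sc), 0.7)
})

test_that("noise-free assays round-trip every resolvable simulated genotype", {
  sp <- population_spec("P", c("S1", "S6", "S7", "S8", "S9", "Sc"),
                        rep(1 / 6, 6), n = 60)
  sim <- simulate_cultivars(sp, seed = 29)
  assays <- simulate_assays(sim$truth, size_noise_sd = 0, dropout = 0, seed = 29)
  calls <- call_genotypes(assays)
  het <- sim$truth[sim$truth$allele1 != sim$truth$allele2, ]
  for (i in seq_len(nrow(het))) {
    got <- calls[[het$name[i]]]
    expect_equal(got$status, "COMPLETE", info = het$name[i])
    expect_true(got$genotype == s_genotype(het$allele1[i], het$allele2[i]),
                info = het$name[i])
  }
})

test_that("SFB assay dropout flags every Sc/S8 carrier for pollination tests", {
  sp <- population_spec("P", c("S1", "S8", "S9", "Sc"), rep(0.25, 4), n = 50)
  sim <- simulate_cultivars(sp, seed = 31)
  assays <- simulate_assays(sim$truth, dropout = 0, seed = 31)
  # suppress the SFB assay entirely: attempted, no amplification
  assays$size_bp[assays$assay == "APRFBC8"] <- NA
  calls <- call_genotypes(assays)
  carriers <- sim$truth$allele1 %in% c("S8", "Sc") |
    sim$truth$allele2 %in% c("S8", "Sc")
  for (i in which(carriers)) {
    expect_true(calls[[sim$truth$name[i]]]$trace$needs_pollination_test,
                info = sim$truth$name[i])
  }
})

test_that("pistil simulation matches the SC and SI outcome models", {
  sc <- simulate_pistils("Water", "SC", n = 17, seed = 1)
  ssc <- summarize_self_pollination(sc)
  expect_equal(ssc$call, "SELF_COMPATIBLE")
  expect_equal(ssc$fraction_reached_base, 1)

  si <- simulate_pistils("Samourai", "SI", n = 10, seed = 1)
  expect_true(all(si$percent >= 40 & si$percent <= 80))
  expect_true(all(si$callose_tip))
  expect_equal(summarize_self_pollination(si)$call, "SELF_INCOMPATIBLE")

  expect_error(simulate_pistils("X", "SC", n = 0), "at least one")
})

test_that("the seeded pipeline runs end-to-end without errors", {
  specs <- list(
    population_spec("East", c("S1", "S6", "S8", "S9"), rep(0.25, 4), n = 20),
    population_spec("West", c("S1", "S7", "S9", "Sc"), rep(0.25, 4), n = 20))
  sim <- simulate_cultivars(specs, seed = 37)
  assays <- simulate_assays(sim$truth, size_noise_sd = 0.5, dropout = 0,
                            seed = 37)
  calls <- call_genotypes(assays)
  expect_true(all(vapply(calls, `[[`, character(1), "status") != "UNRESOLVED"))
  cl <- classify_cultivars(sim$cultivars)
  expect_true(all(cl$self_compat %in%
    c("SELF_COMPATIBLE", "SELF_INCOMPATIBLE", "UNCLASSIFIED")))
  asg <- assign_groups(sim$cultivars)
  expect_true(all(asg$group != ""))
  drep <- diversity_report(sim$cultivars, B = 199, seed = 37)
  expect_equal(drep$pooled$n_populations, 2)
})
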