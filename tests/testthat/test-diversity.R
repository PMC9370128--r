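test_that("allele-copy counting handles diploids, homozygotes, and missing copies", {
  cv <- make_cultivar_table(c("Shalakh", "Hom", "Half"),
                            c("S5", "S2", "S3"), c("S11", "S2", NA),
                            country = c("Armenia", "Spain", "Spain"))
  tab <- count_alleles(cv)
  expect_equal(tab["Armenia", "S5"], 1)
  expect_equal(tab["Armenia", "S11"], 1)
  expect_equal(tab["Spain", "S2"], 2)
  expect_equal(tab["Spain", "S3"], 1)
  expect_equal(sum(tab["Armenia", ]), 2)
  expect_equal(attr(tab, "missing_copies")[["Spain"]], 1)

  # mean-frequency imputation spreads the unknown copy, keeping totals
  ti <- count_alleles(cv, impute = TRUE)
  expect_equal(sum(ti), 6)
  expect_gt(ti["Spain", "S5"], 0)   # fractional counts appear
  expect_lt(ti["Spain", "S5"], 1)
})

test_that("rarefied allelic richness matches hand- and brute-force values", {
  expect_equal(allelic_richness(c(A = 1, B = 1), 2), 2)
  expect_equal(allelic_richness(c(A = 2, B = 1), 2), 5 / 3, tolerance = 1e-12)
  expect_equal(allelic_richness(c(A = 4), 2), 1)
  expect_error(allelic_richness(c(A = 2), 3), "outside")

  # exhaustive-enumeration oracle for all small populations and all g
  set.seed(21)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    counts <- as.numeric(stats::rmultinom(1, sample(4:12, 1), rep(1, k)))
    counts <- counts[counts > 0]
    N <- sum(counts)
    for (g in seq_len(N)) {
      expect_equal(allelic_richness(counts, g), ar_exhaustive(counts, g),
                   tolerance = 1e-9)
    }
  }
})

test_that("allelic richness is monotone in g and hits Na at g = N", {
  set.seed(31)
  for (rep in 1:10) {
    counts <- as.numeric(stats::rmultinom(1, 30, rep(1, 6)))
    counts <- counts[counts > 0]
    N <- sum(counts)
    vals <- vapply(seq_len(N), function(g) allelic_richness(counts, g),
                   numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
    expect_equal(vals[N], length(counts))
    expect_gte(vals[1], 1)
  }
  # fractional (imputed) counts stay within [1, Na]
  fr <- c(2.4, 1.3, 0.3)
  ar <- allelic_richness(fr, 2)
  expect_gte(ar, 1)
  expect_lte(ar, 3)
})

test_that("private alleles are those confined to a single population", {
  m <- rbind(Romania = c(S9 = 1, S19 = 1, Sc = 0),
             Spain = c(S9 = 4, S19 = 0, Sc = 6))
  pa <- private_alleles(m)
  expect_equal(pa$Romania, "S19")
  expect_equal(pa$Spain, "Sc")

  same <- rbind(a = c(x = 2, y = 1), b = c(x = 1, y = 3))
  expect_true(all(lengths(private_alleles(same)) == 0))

  solo <- m[1, , drop = FALSE]
  expect_setequal(private_alleles(solo)$Romania, c("S9", "S19"))

  # brute-force scan agrees on a random table
  set.seed(9)
  rt <- random_count_table(4, 6) - 1
  pa2 <- private_alleles(rt)
  for (p in rownames(rt)) {
    for (al in colnames(rt)) {
      is_priv <- rt[p, al] > 0 && all(rt[setdiff(rownames(rt), p), al] == 0)
      expect_equal(al %in% pa2[[p]], is_priv)
    }
  }
})

test_that("the Monte-Carlo chi-square statistic and p-value behave", {
  flat <- matrix(5, 2, 2)
  r <- chisq_monte_carlo(flat, B = 199, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  diag2 <- matrix(c(10, 0, 0, 10), 2)
  r2 <- chisq_monte_carlo(diag2, B = 199, seed = 1)
  expect_equal(r2$statistic, 20)

  # deterministic given a seed, and the ambient RNG state is untouched
  set.seed(123); before <- stats::runif(1)
  a <- chisq_monte_carlo(diag2, B = 500, seed = 42)
  b <- chisq_monte_carlo(diag2, B = 500, seed = 42)
  expect_identical(a$p_value, b$p_value)
  set.seed(123)
  expect_identical(stats::runif(1), before)

  # degenerate margins are dropped with a warning
  degen <- rbind(c(3, 0, 2), c(4, 0, 1), c(0, 0, 0))
  expect_warning(r3 <- chisq_monte_carlo(degen, B = 99, seed = 1), "zero")
  expect_true(is.finite(r3$statistic))

  expect_error(chisq_monte_carlo(matrix(1, 1, 2), B = 9), "at least 2")
})

test_that("heatmap percentages are row-stochastic", {
  set.seed(13)
  rt <- random_count_table(5, 7)
  pct <- frequency_heatmap(rt)
  expect_equal(unname(rowSums(pct)), rep(100, 5), tolerance = 1e-9)
  one <- frequency_heatmap(matrix(c(4), 1, 1, dimnames = list("p", "S1")))
  expect_equal(unname(one[1, 1]), 100)
  f <- tempfile(fileext = ".png")
  plot_frequency_heatmap(rt, f)
  expect_true(file.size(f) > 0)
})

test_that("the diversity report assembles per-population and pooled statistics", {
  cv <- make_cultivar_table(
    paste0("c", 1:9),
    c("S1", "S2", "S1", "S3", "S2", "S3", "S6", "S7", "S6"),
    c("S2", "S5", "S5", "S4", "S5", "S5", "S7", "S8", "S8"),
    country = rep(c("A", "B", "C"), each = 3))
  rep1 <- diversity_report(cv, B = 199, seed = 5)
  expect_equal(rep1$g, 6)   # auto: minimum copy total across populations
  expect_equal(nrow(rep1$per_population), 3)
  expect_equal(rep1$per_population$Na, c(3, 4, 3))
  expect_equal(rep1$pooled$n_populations, 3)
  expect_equal(rep1$pooled$Na_se,
               stats::sd(rep1$per_population$Na) / sqrt(3), tolerance = 1e-12)
  # A population's private pool is recovered exactly for disjoint pools
  expect_setequal(rep1$per_population$private[3] |>
                    strsplit(";") |> unlist(), c("S6", "S7", "S8"))
  expect_s3_class(rep1$chisq, "mc_chisq")
})

test_that("synthetic populations with disjoint pools recover their private alleles", {
  specs <- list(
    population_spec("P1", c("S1", "S2", "S3"), n = 30),
    population_spec("P2", c("S4", "S5", "S6"), n = 30),
    population_spec("P3", c("S7", "S8", "S9"), n = 30))
  sim <- simulate_cultivars(specs, seed = 17)
  tab <- count_alleles(sim$cultivars)
  pa <- private_alleles(tab)
  expect_setequal(pa$P1, intersect(colnames(tab), c("S1", "S2", "S3")))
  expect_setequal(pa$P2, intersect(colnames(tab), c("S4", "S5", "S6")))
  expect_setequal(pa$P3, intersect(colnames(tab), c("S7", "S8", "S9")))
})
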