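# Synthetic data with the statistical structure the pipeline assumes:
# population allele pools with specified frequencies, diploid genotypes
# sampled under the GSI constraint (no non-Sc homozygotes), amplicon-size
# measurement noise and assay dropout, and pistil-level pollen-tube
# outcomes for self-compatible vs self-incompatible cultivars.
#
# A single global seed fans out deterministically to per-stage child seeds
# so end-to-end runs repeat exactly.

child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 65536 * 31627 + k * 7919) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Specify a synthetic population
#'
#' @param name population name (used as the country/population key).
#' @param alleles allele pool, a subset of [s_alleles()].
#' @param freqs allele frequencies summing to 1, or `NULL` to draw a
#'   symmetric Dirichlet(1) vector at simulation time.
#' @param n number of cultivars to generate.
#' @param sc_fraction probability that a genotype carries `Sc` (the
#'   self-compatible fraction); `NA` (default) lets it emerge from the
#'   frequency of `Sc` in the pool.
#' @param missingness probability that a genotype's second allele is masked
#'   to unknown (emulating single-allele reports).
#' @param origin_class origin class recorded for the generated cultivars.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(name, alleles, freqs = NULL, n,
                            sc_fraction = NA, missingness = 0,
                            origin_class = "unknown") {
  alleles <- canonical_allele(alleles)
  stopifnot(!anyNA(alleles), length(alleles) >= 1L, n >= 1L)
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == length(alleles), all(freqs >= 0))
    if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1", call. = FALSE)
  }
  if (!is.na(sc_fraction) && (sc_fraction < 0 || sc_fraction > 1)) {
    stop("sc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (missingness < 0 || missingness > 1) {
    stop("missingness must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, alleles = alleles, freqs = freqs, n = as.integer(n),
                 sc_fraction = sc_fraction, missingness = missingness,
                 origin_class = origin_class),
            class = "population_spec")
}

sample_allele <- function(alleles, freqs) {
  alleles[sample.int(length(alleles), 1L, prob = freqs)]
}

#' Simulate cultivar records from population specs
#'
#' Diploid genotypes are drawn allele-by-allele from each population's
#' frequency vector. Under the GSI constraint (default), non-`Sc`
#' homozygotes are rejected and resampled — gametophytic
#' self-incompatibility forbids them, while `ScSc` homozygotes can arise
#' through self-compatible parents. With `sc_fraction` set, that fraction
#' of genotypes is forced to carry `Sc`, the rest drawn from the non-`Sc`
#' pool. Masked (missing) second alleles emulate single-allele reports.
#'
#' @param specs a `population_spec` or list of them.
#' @param gsi_constraint reject non-`Sc` homozygotes (default `TRUE`).
#' @param seed integer seed; generation is byte-reproducible given a seed.
#' @return List with `cultivars` (a `cultivar_table`, masked view) and
#'   `truth` (data frame with the true alleles per cultivar).
#' @export
#' @examples
#' sp <- population_spec("PopA", c("S1", "S2", "Sc"), c(0.4, 0.3, 0.3), n = 10)
#' sim <- simulate_cultivars(sp, seed = 7)
simulate_cultivars <- function(specs, gsi_constraint = TRUE, seed = NULL) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "population_spec")))

  rows <- list()
  truth <- list()
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    with_seed(child_seed(seed, si), {
      freqs <- sp$freqs %||% {
        w <- stats::rgamma(length(sp$alleles), 1)
        w / sum(w)
      }
      for (i in seq_len(sp$n)) {
        repeat {
          if (!is.na(sp$sc_fraction) && "Sc" %in% sp$alleles) {
            if (stats::runif(1) < sp$sc_fraction) {
              a1 <- "Sc"
              a2 <- sample_allele(sp$alleles, freqs)
            } else {
              nz <- sp$alleles != "Sc"
              a1 <- sample_allele(sp$alleles[nz], freqs[nz])
              a2 <- sample_allele(sp$alleles[nz], freqs[nz])
            }
          } else {
            a1 <- sample_allele(sp$alleles, freqs)
            a2 <- sample_allele(sp$alleles, freqs)
          }
          if (!gsi_constraint || a1 != a2 || a1 == "Sc") break
        }
        r <- order(allele_rank(c(a1, a2)))
        a1s <- c(a1, a2)[r][1L]; a2s <- c(a1, a2)[r][2L]
        masked <- stats::runif(1) < sp$missingness
        nm <- sprintf("SIM-%s-%03d", sp$name, i)
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, country = sp$name, origin_class = sp$origin_class,
          allele1 = a1s, allele2 = if (masked) NA_character_ else a2s,
          flags = "", presumed_homozygous = FALSE, phenotype = NA_character_,
          source = "synthetic", stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          name = nm, population = sp$name, allele1 = a1s, allele2 = a2s,
          masked = masked, stringsAsFactors = FALSE)
      }
    })
  }
  list(cultivars = as_cultivar_table(do.call(rbind, rows)),
       truth = do.call(rbind, truth))
}

#' Simulate PCR assay results for simulated cultivars
#'
#' Forward-predicts every diagnostic amplicon from the true genotypes and
#' adds Gaussian measurement jitter; with probability `dropout` an
#' attempted assay yields no amplification (recorded as an `NA` size, the
#' way primer mismatch shows up at the bench).
#'
#' @param truth truth table from [simulate_cultivars()].
#' @param panel a `primer_panel`.
#' @param size_noise_sd Gaussian jitter SD on fragment sizes in bp
#'   (default 0).
#' @param dropout per-assay no-amplification probability (default 0).
#' @param seed integer seed.
#' @return Long-format assay table (`cultivar`, `assay`, `size_bp`) as
#'   from [read_assays()].
#' @export
simulate_assays <- function(truth, panel = default_panel(), size_noise_sd = 0,
                            dropout = 0, seed = NULL) {
  stopifnot(size_noise_sd >= 0, dropout >= 0, dropout <= 1)
  assay_ids <- unique(panel$assay)
  with_seed(child_seed(seed, 104729L), {
    out <- lapply(seq_len(nrow(truth)), function(i) {
      g <- s_genotype(truth$allele1[i], truth$allele2[i])
      pred <- predict_amplicons(g, panel)
      res <- lapply(assay_ids, function(a) {
        sizes <- pred$expected_bp[pred$assay == a]
        if (length(sizes) == 0L) return(NULL)
        if (stats::runif(1) < dropout) {
          return(data.frame(cultivar = truth$name[i], assay = a,
                            size_bp = NA_real_, stringsAsFactors = FALSE))
        }
        data.frame(cultivar = truth$name[i], assay = a,
                   size_bp = sizes + stats::rnorm(length(sizes), 0, size_noise_sd),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    })
    do.call(rbind, out)
  })
}

#' Simulate pistil observations for one cultivar
#'
#' The self-compatible model sends every pollen tube to the base of the
#' style (100% traveled); the self-incompatible model arrests every tube
#' mid-style with a callose tip, the percent traveled drawn uniformly on
#' \[40, 80\].
#'
#' @param cultivar cultivar name.
#' @param truth `"SC"` or `"SI"`.
#' @param n number of pistils (at least 1).
#' @param seed integer seed.
#' @return Pistil observation data frame (as from [read_pistils()]).
#' @export
simulate_pistils <- function(cultivar, truth = c("SC", "SI"), n, seed = NULL) {
  truth <- match.arg(truth)
  if (n < 1L) stop("need at least one pistil", call. = FALSE)
  with_seed(child_seed(seed, 224737L), {
    if (truth == "SC") {
      data.frame(cultivar = cultivar, cross = "self", donor = cultivar,
                 percent = rep(100, n), reached_base = TRUE,
                 callose_tip = FALSE, stringsAsFactors = FALSE)
    } else {
      data.frame(cultivar = cultivar, cross = "self", donor = cultivar,
                 percent = stats::runif(n, 40, 80), reached_base = FALSE,
                 callose_tip = TRUE, stringsAsFactors = FALSE)
    }
  })
}
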