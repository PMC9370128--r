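# S-locus diversity statistics per population: allele-copy counts and
# frequencies, rarefied allelic richness, private alleles, and a
# Monte-Carlo chi-square test of allele x population association with
# fixed-margins (Patefield) null tables.

#' Allele-copy count table per population
#'
#' Each complete diploid genotype contributes two allele copies (a
#' homozygote contributes two of one allele); an incomplete genotype
#' contributes its known allele as one copy and skips the unknown copy.
#' Presumed-homozygous single-`Sc` records also contribute one copy only
#' (homozygosity is a presumption, not an observation). With
#' `impute = TRUE`, each skipped unknown copy is replaced by the pooled
#' mean allele frequencies, yielding fractional counts (mean-frequency
#' imputation of missing data).
#'
#' @param cultivars a `cultivar_table`.
#' @param group_by column used as the population key (default `"country"`).
#' @param impute replace unknown copies with mean allele frequencies
#'   (default `FALSE`).
#' @return Numeric matrix (populations x alleles) of class
#'   `allele_count_table`, with attributes `n_cultivars` and
#'   `missing_copies` per population.
#' @export
count_alleles <- function(cultivars, group_by = "country", impute = FALSE) {
  if (!group_by %in% names(cultivars)) {
    stop("grouping column not found: ", group_by, call. = FALSE)
  }
  pop <- trimws(as.character(cultivars[[group_by]]))
  pop[is.na(pop) | pop == ""] <- "unknown"
  pops <- sort(unique(pop))
  alleles <- s_alleles()

  m <- matrix(0, nrow = length(pops), ncol = length(alleles),
              dimnames = list(population = pops, allele = alleles))
  missing_copies <- stats::setNames(numeric(length(pops)), pops)
  for (i in seq_len(nrow(cultivars))) {
    p <- pop[i]
    m[p, cultivars$allele1[i]] <- m[p, cultivars$allele1[i]] + 1
    if (!is.na(cultivars$allele2[i])) {
      m[p, cultivars$allele2[i]] <- m[p, cultivars$allele2[i]] + 1
    } else {
      missing_copies[p] <- missing_copies[p] + 1
    }
  }

  if (impute && sum(missing_copies) > 0) {
    freq <- colSums(m) / sum(m)  # pooled frequencies over observed copies
    m <- m + outer(missing_copies, freq)
  }

  m <- m[, colSums(m) > 0, drop = FALSE]
  attr(m, "n_cultivars") <- as.vector(table(factor(pop, levels = pops)))
  attr(m, "missing_copies") <- missing_copies
  attr(m, "imputed") <- isTRUE(impute)
  class(m) <- c("allele_count_table", class(m))
  m
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` allele
#' copies drawn without replacement from a population with copy counts
#' \eqn{N_i}: \eqn{A_r(g) = \sum_i \left[1 - \binom{N - N_i}{g} /
#' \binom{N}{g}\right]} with \eqn{N = \sum_i N_i}. Standardizes richness
#' across unequal sample sizes; at `g = N` it equals the observed number of
#' distinct alleles exactly. Fractional counts (from mean-frequency
#' imputation) are supported through the gamma-function generalization of
#' the binomial coefficients.
#'
#' @param counts non-negative allele-copy counts for one population.
#' @param g subsample size, `1 <= g <= sum(counts)`.
#' @return Expected distinct-allele count, a scalar in `[1, N_a]`.
#' @export
#' @examples
#' allelic_richness(c(A = 2, B = 1), g = 2)  # 5/3
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no allele copies", call. = FALSE)
  if (any(counts < 0)) stop("negative allele counts", call. = FALSE)
  N <- sum(counts)
  if (g < 1 || g > N) {
    stop(sprintf("subsample size g = %s outside [1, N = %s]", g, format(N)),
         call. = FALSE)
  }
  terms <- vapply(counts, function(Ni) {
    if (N - Ni < g) 1 else 1 - exp(lchoose(N - Ni, g) - lchoose(N, g))
  }, numeric(1))
  sum(terms)
}

#' Private alleles per population
#'
#' An allele is private to a population when its count is positive there
#' and zero in every other population of the table.
#'
#' @param table an `allele_count_table` (or populations x alleles matrix).
#' @return Named list of character vectors of private allele labels.
#' @export
private_alleles <- function(table) {
  if (nrow(table) < 1L) stop("need at least one population", call. = FALSE)
  out <- lapply(rownames(table), function(p) {
    here <- table[p, ] > 0
    elsewhere <- if (nrow(table) > 1L) {
      colSums(table[setdiff(rownames(table), p), , drop = FALSE]) > 0
    } else {
      rep(FALSE, ncol(table))
    }
    colnames(table)[here & !elsewhere]
  })
  stats::setNames(out, rownames(table))
}

pearson_x2 <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

#' Monte-Carlo chi-square test of allele x population association
#'
#' Pearson's \eqn{X^2} on the contingency table, with the p-value obtained
#' by simulation rather than the asymptotic distribution (appropriate for
#' sparse allele tables): null tables are drawn uniformly with both margins
#' fixed (Patefield's algorithm, via [stats::r2dtable()]), and
#' \eqn{p = (1 + \#\{X^2_b \ge X^2_{obs}\}) / (B + 1)}. Zero rows or
#' columns are dropped with a warning before testing.
#'
#' @param table counts matrix (populations x alleles); fractional counts
#'   are rounded for the simulation.
#' @param B number of Monte-Carlo replicates (default 2000).
#' @param seed optional integer seed; the result is deterministic given a
#'   seed, and the caller's RNG state is left untouched.
#' @return List of class `mc_chisq`: `statistic`, `p_value`, `B`, `seed`.
#' @export
#' @examples
#' chisq_monte_carlo(matrix(c(10, 0, 0, 10), 2), seed = 1)
chisq_monte_carlo <- function(table, B = 2000, seed = NULL) {
  m <- as.matrix(table)
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " zero row(s) and ", sum(zc),
            " zero column(s) before testing", call. = FALSE)
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 populations and 2 alleles with positive margins",
         call. = FALSE)
  }

  x2 <- pearson_x2(m)

  mi <- round(m)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sims <- vapply(stats::r2dtable(B, rowSums(mi), colSums(mi)), pearson_x2,
                 numeric(1))
  p <- (1 + sum(sims >= x2 - 1e-12)) / (B + 1)

  structure(list(statistic = x2, p_value = p, B = B,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "mc_chisq")
}

#' @export
print.mc_chisq <- function(x, ...) {
  cat(sprintf("Monte-Carlo chi-square: X-squared = %.4f, p = %.4g (B = %d)\n",
              x$statistic, x$p_value, x$B))
  invisible(x)
}

#' Allele-frequency percentage matrix (heatmap values)
#'
#' Each cell is the percentage of a population's allele copies carried by
#' one allele: `100 * count / row total`; rows sum to 100.
#'
#' @param table an `allele_count_table`.
#' @return Numeric matrix of percentages with the same dimnames.
#' @export
frequency_heatmap <- function(table) {
  m <- as.matrix(table)
  keep <- rowSums(m) > 0
  sweep(m[keep, , drop = FALSE], 1, rowSums(m[keep, , drop = FALSE]), "/") * 100
}

#' Plot an allele-frequency heatmap to a file
#'
#' Base-graphics rendering of [frequency_heatmap()]: populations as rows,
#' alleles as columns, cell shading by percentage with the value printed in
#' each non-empty cell.
#'
#' @param table an `allele_count_table`.
#' @param file output PNG path.
#' @param main plot title.
#' @return The percentage matrix, invisibly.
#' @export
plot_frequency_heatmap <- function(table, file, main = "S-allele frequencies (%)") {
  pct <- frequency_heatmap(table)
  grDevices::png(file, width = 160 * ncol(pct) + 240, height = 60 * nrow(pct) + 200,
                 res = 120)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 8, 6, 1))
  on.exit(graphics::par(op), add = TRUE)
  z <- t(pct[rev(seq_len(nrow(pct))), , drop = FALSE])
  graphics::image(seq_len(ncol(pct)), seq_len(nrow(pct)), z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(3, at = seq_len(ncol(pct)), labels = colnames(pct), las = 2,
                 tick = FALSE)
  graphics::axis(2, at = seq_len(nrow(pct)), labels = rev(rownames(pct)),
                 las = 1, tick = FALSE)
  for (i in seq_len(nrow(pct))) {
    for (j in seq_len(ncol(pct))) {
      v <- pct[i, j]
      if (v > 0) {
        graphics::text(j, nrow(pct) - i + 1, sprintf("%.0f", v), cex = 0.7)
      }
    }
  }
  invisible(pct)
}

#' Per-population S-locus diversity report
#'
#' Assembles, for one origin class (or all cultivars), the per-population
#' allele counts, number of distinct alleles (\eqn{N_a}), rarefied allelic
#' richness (\eqn{A_r}, at a common subsample size), and private alleles
#' (\eqn{P_a}); pooled mean, SD and SE of \eqn{N_a} and \eqn{A_r} across
#' populations; and the Monte-Carlo chi-square test of allele x population
#' association.
#'
#' @param cultivars a `cultivar_table`.
#' @param origin_class optional filter, `"traditional"` or `"breeding"`.
#' @param group_by population key column (default `"country"`).
#' @param g rarefaction subsample size; `"auto"` (default) uses the minimum
#'   allele-copy total across included populations.
#' @param B Monte-Carlo replicates for the chi-square test.
#' @param seed integer seed for the Monte-Carlo test.
#' @param impute mean-frequency imputation of unknown copies.
#' @param min_cultivars drop populations with fewer cultivars (default 1 =
#'   keep all).
#' @return List of class `diversity_report`: `table` (counts),
#'   `per_population` (data frame with `n_cultivars`, `n_copies`, `Na`,
#'   `Ar`, `Pa`, `private`), `g`, `pooled` (means/SDs/SEs), and `chisq`.
#' @export
diversity_report <- function(cultivars, origin_class = NULL,
                             group_by = "country", g = "auto", B = 2000,
                             seed = NULL, impute = FALSE, min_cultivars = 1) {
  df <- as.data.frame(cultivars)
  if (!is.null(origin_class)) {
    origin_class <- match.arg(origin_class, c("traditional", "breeding"))
    df <- df[df$origin_class == origin_class, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no cultivars after filtering", call. = FALSE)

  tab <- count_alleles(as_cultivar_table(df), group_by = group_by,
                       impute = impute)
  keep <- attr(tab, "n_cultivars") >= min_cultivars & rowSums(tab) > 0
  counts <- tab[keep, , drop = FALSE]
  class(counts) <- class(tab)

  copies <- rowSums(counts)
  if (identical(g, "auto")) g <- floor(min(copies))
  g <- as.numeric(g)

  na <- apply(counts, 1, function(r) sum(r > 0))
  ar <- apply(counts, 1, allelic_richness, g = g)
  priv <- private_alleles(counts)

  per_pop <- data.frame(
    population = rownames(counts),
    n_cultivars = attr(tab, "n_cultivars")[keep],
    n_copies = as.numeric(copies),
    Na = as.numeric(na),
    Ar = as.numeric(ar),
    Pa = lengths(priv),
    private = vapply(priv, paste, character(1), collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE)

  npop <- nrow(per_pop)
  pooled <- list(
    n_populations = npop,
    Na_mean = mean(per_pop$Na), Na_sd = stats::sd(per_pop$Na),
    Na_se = stats::sd(per_pop$Na) / sqrt(npop),
    Ar_mean = mean(per_pop$Ar), Ar_sd = stats::sd(per_pop$Ar),
    Ar_se = stats::sd(per_pop$Ar) / sqrt(npop),
    Pa_total = sum(per_pop$Pa))

  chisq <- if (nrow(counts) >= 2L && ncol(counts) >= 2L) {
    suppressWarnings(chisq_monte_carlo(counts, B = B, seed = seed))
  }

  structure(list(table = counts, per_population = per_pop, g = g,
                 pooled = pooled, chisq = chisq,
                 origin_class = origin_class %||% "all"),
            class = "diversity_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.diversity_report <- function(x, ...) {
  cat("S-locus diversity report (", x$origin_class, " cultivars)\n", sep = "")
  cat("rarefaction subsample size g =", x$g, "allele copies\n\n")
  print(x$per_population[c("population", "n_cultivars", "Na", "Ar", "Pa",
                           "private")], row.names = FALSE, digits = 3)
  with(x$pooled, cat(sprintf(
    "\nMean +/- SD: Na = %.2f +/- %.2f (SE %.2f); Ar = %.2f +/- %.2f (SE %.2f)\n",
    Na_mean, Na_sd, Na_se, Ar_mean, Ar_sd, Ar_se)))
  if (!is.null(x$chisq)) print(x$chisq)
  invisible(x)
}
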