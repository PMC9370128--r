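# Shared helpers: in-code fixtures and brute-force oracles.

# a minimal cultivar table built in code
make_cultivar_table <- function(name, allele1, allele2 = NA, country = "",
                                phenotype = NA_character_,
                                presumed_homozygous = FALSE) {
  n <- length(name)
  df <- data.frame(
    name = name, country = rep_len(country, n),
    origin_class = rep_len("unknown", n),
    allele1 = allele1, allele2 = rep_len(allele2, n),
    flags = rep_len("", n),
    presumed_homozygous = rep_len(presumed_homozygous, n),
    phenotype = rep_len(phenotype, n), source = rep_len(NA_character_, n),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".csv")
  df$allele2[is.na(df$allele2)] <- ""
  df$phenotype[is.na(df$phenotype)] <- ""
  df$source[is.na(df$source)] <- ""
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  read_cultivar_table(path)
}

# alleles the packaged panel can detect at all
panel_alleles <- function(panel = default_panel()) {
  sort(unique(unlist(panel$candidates)))
}

# all heterozygous pairs the panel can resolve
resolvable_pairs <- function(panel = default_panel()) {
  al <- panel_alleles(panel)
  utils::combn(al, 2, simplify = FALSE)
}

# exhaustive rarefaction oracle: mean distinct alleles over all subsets
ar_exhaustive <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  sets <- utils::combn(length(copies), g)
  mean(apply(sets, 2, function(ix) length(unique(copies[ix]))))
}

random_count_table <- function(nr, nc, lambda = 4) {
  m <- matrix(stats::rpois(nr * nc, lambda) + 1, nr, nc)
  dimnames(m) <- list(paste0("pop", seq_len(nr)), paste0("S", seq_len(nc)))
  m
}
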