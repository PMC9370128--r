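# Readers and writers for the package's tabular interchange formats, and the
# packaged transcriptions of the published cultivar compilations.
#
# Cultivar table CSV schema (UTF-8, comma-separated by default):
#   name, country, origin_class, allele1, allele2, flags,
#   presumed_homozygous, phenotype, source
# where
#   origin_class        traditional | breeding | unknown (empty = unknown)
#   allele1/allele2     S-allele tokens; empty allele2 = unknown
#   flags               semicolon-joined subset of {a,b,c,d}:
#                       a = genotype first reported in the source study,
#                       b = genotype completed there (one allele known before),
#                       c = Sc/S8 resolved by fluorescence microscopy,
#                       d = Sc/S8 confirmed with the SFB-specific primers
#   presumed_homozygous TRUE/FALSE (single-allele rows presumed homozygous)
#   phenotype           SC | SI | empty; self-(in)compatibility established by
#                       pollination experiments (direct phenotype evidence)
#   source              this_study | previous; which column of the published
#                       compilation the record was transcribed from

cultivar_cols <- c("name", "country", "origin_class", "allele1", "allele2",
                   "flags", "presumed_homozygous", "phenotype", "source")

# accent- and case-insensitive key used for duplicate detection
name_key <- function(x) {
  ascii <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  ascii[is.na(ascii)] <- x[is.na(ascii)]
  # transliteration may leave accent marks as punctuation; compare on the
  # alphanumeric skeleton only
  gsub("[^a-z0-9]", "", tolower(ascii))
}

#' Read a cultivar table
#'
#' Parses and validates a cultivar table CSV (see the package vignette for
#' the schema). Allele tokens are canonicalized, genotypes are put in
#' canonical order, and duplicate cultivar names (compared case- and
#' accent-insensitively) are rejected with the offending line numbers.
#'
#' @param path path to a CSV (or TSV) file.
#' @param sep field delimiter, `","` (default) or `"\t"`.
#' @return A `data.frame` of class `cultivar_table` with the documented
#'   columns; `allele2` is `NA` for single-allele records.
#' @export
read_cultivar_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  required <- c("name", "country", "origin_class", "allele1", "allele2", "flags")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cultivar table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(cultivar_cols, names(df))) {
    df[[col]] <- character(nrow(df))
  }
  df <- df[cultivar_cols]
  if (nrow(df) == 0L) return(as_cultivar_table(df[0, ]))

  # row-level allele validation with line numbers (header = line 1)
  for (col in c("allele1", "allele2")) {
    tok <- trimws(df[[col]])
    bad <- tok != "" & !is_s_allele(tok)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("line %d: unknown S-allele token '%s' in column %s",
                   i + 1L, df[[col]][i], col), call. = FALSE)
    }
  }
  df$allele1 <- canonical_allele(df$allele1)
  df$allele2 <- canonical_allele(df$allele2)
  if (anyNA(df$allele1) && !all(is.na(df$allele2[is.na(df$allele1)]))) {
    # keep the known allele in slot 1
    swap <- is.na(df$allele1) & !is.na(df$allele2)
    df$allele1[swap] <- df$allele2[swap]
    df$allele2[swap] <- NA_character_
  }
  if (anyNA(df$allele1)) {
    i <- which(is.na(df$allele1))[1L]
    stop(sprintf("line %d: record '%s' has no known allele", i + 1L, df$name[i]),
         call. = FALSE)
  }
  # canonical order within genotype
  both <- !is.na(df$allele2)
  if (any(both)) {
    swap <- both & allele_rank(df$allele1) > allele_rank(df$allele2)
    tmp <- df$allele1[swap]
    df$allele1[swap] <- df$allele2[swap]
    df$allele2[swap] <- tmp
  }

  key <- name_key(df$name)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    lines <- which(key == d) + 1L
    stop(sprintf("duplicate cultivar '%s' on lines %s", df$name[key == d][1L],
                 paste(lines, collapse = " and ")), call. = FALSE)
  }

  oc <- trimws(df$origin_class)
  oc[oc == ""] <- "unknown"
  bad_oc <- !oc %in% c("traditional", "breeding", "unknown")
  if (any(bad_oc)) {
    stop("invalid origin_class value(s): ",
         paste(unique(oc[bad_oc]), collapse = ", "), call. = FALSE)
  }
  df$origin_class <- oc

  flag_tokens <- strsplit(ifelse(is.na(df$flags), "", df$flags), ";", fixed = TRUE)
  bad_flag <- vapply(flag_tokens, function(f) any(!f %in% c("a", "b", "c", "d")),
                     logical(1))
  if (any(bad_flag)) {
    i <- which(bad_flag)[1L]
    stop(sprintf("line %d: invalid flags '%s' (allowed: a;b;c;d)",
                 i + 1L, df$flags[i]), call. = FALSE)
  }

  ph <- toupper(trimws(df$presumed_homozygous))
  df$presumed_homozygous <- ph %in% c("TRUE", "T", "1", "YES")
  df$presumed_homozygous[!is.na(df$allele2)] <- FALSE

  phen <- toupper(trimws(df$phenotype))
  phen[phen == ""] <- NA_character_
  if (any(!is.na(phen) & !phen %in% c("SC", "SI"))) {
    stop("phenotype column values must be SC, SI, or empty", call. = FALSE)
  }
  df$phenotype <- phen

  src <- trimws(df$source)
  src[src == ""] <- NA_character_
  df$source <- src

  as_cultivar_table(df)
}

as_cultivar_table <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("cultivar_table", "data.frame")
  df
}

#' Write a cultivar table in canonical form
#'
#' The inverse of [read_cultivar_table()]: writes the canonical column set in
#' canonical order. Reading a canonical file and writing it back reproduces
#' it byte-identically.
#'
#' @param df a `cultivar_table` (or compatible data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cultivar_table <- function(df, path) {
  out <- as.data.frame(df)[cultivar_cols]
  out$allele2[is.na(out$allele2)] <- ""
  out$phenotype[is.na(out$phenotype)] <- ""
  out$source[is.na(out$source)] <- ""
  out$presumed_homozygous <- ifelse(out$presumed_homozygous, "TRUE", "FALSE")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cultivar_cols, collapse = ","), con, useBytes = TRUE)
  lines <- do.call(paste, c(unname(as.list(out)), sep = ","))
  if (length(lines)) writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Extract the genotype of one cultivar record
#'
#' @param df a `cultivar_table`.
#' @param i row index or cultivar name.
#' @return An [s_genotype].
#' @export
record_genotype <- function(df, i) {
  if (is.character(i)) i <- match(i, df$name)
  s_genotype(df$allele1[i], df$allele2[i],
             presumed_homozygous = df$presumed_homozygous[i])
}

#' Read a primer panel table
#'
#' Panel CSV schema: `assay, primer_f, primer_r, expected_bp, candidates,
#' tolerance_bp, verified`, one row per diagnostic fragment size;
#' `candidates` is a semicolon-joined allele set (an ambiguity class when it
#' has more than one member). `verified = FALSE` marks placeholder sizes not
#' anchored to a published figure (used only by the simulator and the
#' secondary-intron path). Validates that within an assay the expected sizes
#' differ pairwise by more than twice the tolerance, so size matching is
#' unambiguous.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `primer_panel` with a list-column
#'   `candidates`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("assay", "primer_f", "primer_r", "expected_bp", "candidates",
                "tolerance_bp")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("panel table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$verified)) df$verified <- TRUE
  df$verified <- as.logical(df$verified)
  df$expected_bp <- as.numeric(df$expected_bp)
  df$tolerance_bp <- as.numeric(df$tolerance_bp)
  if (any(df$tolerance_bp < 0)) stop("tolerance_bp must be non-negative")
  if (any(df$expected_bp <= 0)) stop("expected_bp must be positive")
  df$candidates <- lapply(strsplit(df$candidates, ";", fixed = TRUE),
                          canonical_allele)
  for (a in unique(df$assay)) {
    sz <- df$expected_bp[df$assay == a]
    tol <- max(df$tolerance_bp[df$assay == a])
    if (length(sz) > 1L && min(stats::dist(sz)) <= 2 * tol) {
      stop("assay ", a, ": expected sizes closer than 2 x tolerance", call. = FALSE)
    }
  }
  class(df) <- c("primer_panel", "data.frame")
  df
}

#' The packaged primer panel
#'
#' The five-assay panel used for apricot S-genotyping: the S-RNase
#' first-intron consensus assay (SRc-F/SRc-R), the second-intron
#' Pru-C2/Pru-C4R assay distinguishing S6 from S9, the S1-specific
#' SHLM1/SHLM2 and S7-specific SHLM3/SHLM4 assays, and the SFB-region
#' AprFBC8-F/AprFBC8-R assay distinguishing S8 (150 bp) from Sc (500 bp).
#' First-intron sizes are anchored at 358 bp (Sc/S8 class) and 408 bp
#' (S1/S7 class); entries flagged `verified = FALSE` are synthetic
#' placeholders for products whose published length is not printed.
#'
#' @return A `primer_panel` data frame.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "panel.csv", package = "apricotSI",
                         mustWork = TRUE))
}

#' Read an incompatibility-group registry
#'
#' Registry CSV schema: `allele1, allele2, group`, mapping complete non-Sc
#' genotypes to the historical incompatibility-group labels (Roman numerals,
#' or `"0"` for genotypes so far unique to one cultivar). A genotype mapped
#' to two different labels is an error.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `group_registry` with a `key` column.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("allele1", "allele2", "group")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("registry is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$allele1 <- canonical_allele(df$allele1)
  df$allele2 <- canonical_allele(df$allele2)
  if (anyNA(df$allele1) || anyNA(df$allele2)) {
    stop("registry genotypes must be complete", call. = FALSE)
  }
  if (any(df$allele1 == "Sc" | df$allele2 == "Sc")) {
    stop("registry genotypes must not contain Sc", call. = FALSE)
  }
  df$key <- mapply(genotype_key, df$allele1, df$allele2, USE.NAMES = FALSE)
  df <- unique(df[c("allele1", "allele2", "group", "key")])
  if (anyDuplicated(df$key)) {
    k <- df$key[duplicated(df$key)][1L]
    stop("registry conflict: genotype ", k, " maps to labels ",
         paste(df$group[df$key == k], collapse = " and "), call. = FALSE)
  }
  class(df) <- c("group_registry", "data.frame")
  df
}

#' The packaged incompatibility-group registry
#'
#' @return A `group_registry` mapping the published group genotypes
#'   (groups I--XXVI plus group 0) to their labels.
#' @export
default_registry <- function() {
  read_registry(system.file("extdata", "registry.csv", package = "apricotSI",
                            mustWork = TRUE))
}

#' Read a PCR assay-result table
#'
#' Long-format CSV: `cultivar, assay, size_bp`, one row per observed
#' fragment; a row with an empty `size_bp` records an attempted assay with
#' no amplification.
#'
#' @param path CSV path.
#' @return A data frame with columns `cultivar`, `assay`, `size_bp`
#'   (numeric, `NA` = no amplification).
#' @export
read_assays <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("cultivar", "assay", "size_bp")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("assay table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$size_bp <- suppressWarnings(as.numeric(df$size_bp))
  if (any(!is.na(df$size_bp) & df$size_bp <= 0)) {
    stop("fragment sizes must be positive", call. = FALSE)
  }
  df
}

#' Read a pistil observation table
#'
#' CSV schema: `cultivar, cross (self|cross), donor, percent, reached_base,
#' callose_tip`. Enforces the scoring invariants: percentages lie in
#' \[0, 100\] and a pollen tube that reached the base of the style traveled
#' 100% of it.
#'
#' @param path CSV path.
#' @return A data frame of pistil observations.
#' @export
read_pistils <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("cultivar", "cross", "donor", "percent", "reached_base",
                "callose_tip")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("pistil table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$percent <- as.numeric(df$percent)
  df$reached_base <- as.logical(df$reached_base)
  df$callose_tip <- as.logical(df$callose_tip)
  validate_pistils(df)
  df
}

validate_pistils <- function(df) {
  if (any(df$percent < 0 | df$percent > 100, na.rm = TRUE)) {
    stop("percent_style_traveled must lie in [0, 100]", call. = FALSE)
  }
  if (any(df$reached_base & df$percent != 100, na.rm = TRUE)) {
    stop("reached_base implies percent_style_traveled = 100", call. = FALSE)
  }
  if (!all(df$cross %in% c("self", "cross"))) {
    stop("cross must be 'self' or 'cross'", call. = FALSE)
  }
  invisible(df)
}

#' Load a packaged fixture
#'
#' The published cultivar compilations, primer panel, and group registry,
#' transcribed verbatim as plain-text CSVs:
#' \describe{
#'   \item{`compiled_si_table1`}{the 103-cultivar self-incompatible /
#'     unclassified compilation (incompatibility groups I--XXVI, group 0,
#'     and single-allele unclassified records).}
#'   \item{`compiled_sc_table2`}{the 153-cultivar self-compatible
#'     compilation.}
#'   \item{`study66`}{the 66 cultivars genotyped in the source study (the
#'     `source == "this_study"` rows of both compilations).}
#'   \item{`panel`}{the primer panel, as [default_panel()].}
#'   \item{`registry`}{the group registry, as [default_registry()].}
#' }
#'
#' @param which one of `"study66"`, `"compiled_si_table1"`,
#'   `"compiled_sc_table2"`, `"panel"`, `"registry"`.
#' @return A `cultivar_table`, `primer_panel`, or `group_registry`.
#' @export
#' @examples
#' nrow(load_fixture("study66"))
load_fixture <- function(which = c("study66", "compiled_si_table1",
                                   "compiled_sc_table2", "panel", "registry")) {
  which <- match.arg(which)
  path <- function(f) system.file("extdata", f, package = "apricotSI",
                                  mustWork = TRUE)
  switch(which,
    compiled_si_table1 = read_cultivar_table(path("cultivars_si_table1.csv")),
    compiled_sc_table2 = read_cultivar_table(path("cultivars_sc_table2.csv")),
    study66 = {
      t1 <- read_cultivar_table(path("cultivars_si_table1.csv"))
      t2 <- read_cultivar_table(path("cultivars_sc_table2.csv"))
      both <- rbind(as.data.frame(t1), as.data.frame(t2))
      as_cultivar_table(both[!is.na(both$source) & both$source == "this_study", ])
    },
    panel = default_panel(),
    registry = default_registry()
  )
}
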