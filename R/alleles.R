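#' S-allele vocabulary
#'
#' Named S-alleles described for apricot (*Prunus armeniaca*): `S1`--`S20`,
#' `S22`--`S31`, `S52`, `S53`, the unsequenced `Sv` and `Sx`, plus `Sc`, the
#' haplotype associated with self-compatibility (a pollen-part mutant carrying
#' a 358 bp insertion in *SFBc* that abolishes pollen-side rejection). The
#' vector order is the canonical sort order used throughout the package, with
#' `Sc` last so that genotypes print in the conventional form (e.g. `S8Sc`).
#'
#' @return Character vector of allele labels in canonical order.
#' @export
#' @examples
#' s_alleles()
s_alleles <- function() {
  c(paste0("S", c(1:20, 22:31, 52, 53)), "Sv", "Sx", "Sc")
}

#' Test whether tokens are valid S-allele labels
#'
#' Comparison is case-insensitive; `NA` and empty strings are not labels.
#'
#' @param x character vector of tokens.
#' @return Logical vector.
#' @export
is_s_allele <- function(x) {
  !is.na(x) & tolower(x) %in% tolower(s_alleles())
}

#' Canonicalize S-allele tokens
#'
#' Maps case-variant tokens (`"s1"`, `"SC"`) to the canonical spelling.
#' Empty strings and `NA` become `NA` (the unknown-allele sentinel). Any
#' other token is an error naming the offending token.
#'
#' @param x character vector of tokens.
#' @return Character vector of canonical labels, `NA` for unknown slots.
#' @export
canonical_allele <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  idx <- match(tolower(trimws(x)), tolower(s_alleles()))
  bad <- !is.na(x) & is.na(idx)
  if (any(bad)) {
    stop("unknown S-allele token(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  out <- s_alleles()[idx]
  out
}

allele_rank <- function(x) match(x, s_alleles())

#' S-genotype of a diploid cultivar
#'
#' An unordered pair of S-allele labels. The second allele may be unknown
#' (`NA`), which is how single-allele reports (e.g. a lone `Sc`
#' amplification) are represented; `presumed_homozygous = TRUE` marks
#' single-`Sc` cultivars presumed to be `ScSc` pending sequencing.
#' Alleles are stored in canonical order, so `s_genotype("S9", "S1")` and
#' `s_genotype("S1", "S9")` are identical.
#'
#' @param a1,a2 allele labels (case-insensitive); `a2` may be `NA` or `""`.
#' @param presumed_homozygous logical; single-allele genotype presumed
#'   homozygous (only meaningful when `a2` is unknown).
#' @return An object of class `s_genotype`: list with elements `alleles`
#'   (length-2 character, `NA` = unknown, known alleles first) and
#'   `presumed_homozygous`.
#' @export
#' @examples
#' s_genotype("S9", "S1")          # canonicalizes to S1 S9
#' s_genotype("Sc", presumed_homozygous = TRUE)
s_genotype <- function(a1, a2 = NA, presumed_homozygous = FALSE) {
  al <- canonical_allele(c(a1, a2))
  if (length(al) != 2L) stop("a genotype has exactly two allele slots")
  al <- al[order(is.na(al), allele_rank(al), na.last = TRUE)]
  if (is.na(al[1L]) && !is.na(al[2L])) al <- rev(al)  # known allele first
  if (all(is.na(al))) stop("a genotype needs at least one known allele")
  if (!is.na(al[2L])) presumed_homozygous <- FALSE
  structure(
    list(alleles = al, presumed_homozygous = isTRUE(presumed_homozygous)),
    class = "s_genotype"
  )
}

#' @export
format.s_genotype <- function(x, ...) {
  a <- x$alleles
  a[is.na(a)] <- "-"
  out <- paste0(a, collapse = "")
  if (x$presumed_homozygous) out <- paste0(out, " (presumed ", a[1L], a[1L], ")")
  out
}

#' @export
print.s_genotype <- function(x, ...) {
  cat("<s_genotype> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
Ops.s_genotype <- function(e1, e2) {
  if (!.Generic %in% c("==", "!=")) {
    stop("operation '", .Generic, "' not defined for s_genotype objects")
  }
  same <- identical(e1$alleles, e2$alleles)
  if (.Generic == "==") same else !same
}

#' Is a genotype complete?
#'
#' A genotype is complete when both alleles are known.
#'
#' @param g an [s_genotype].
#' @return Logical scalar.
#' @export
genotype_complete <- function(g) {
  stopifnot(inherits(g, "s_genotype"))
  !anyNA(g$alleles)
}

#' Effective allele pair for compatibility arithmetic
#'
#' Presumed-homozygous single-allele genotypes are treated as true
#' homozygotes (e.g. a lone `Sc` presumed `ScSc`) when computing pollen
#' rejection; other incomplete genotypes keep their unknown slot.
#'
#' @param g an [s_genotype].
#' @return Length-2 character vector, `NA` for unknown.
#' @export
effective_alleles <- function(g) {
  stopifnot(inherits(g, "s_genotype"))
  a <- g$alleles
  if (is.na(a[2L]) && g$presumed_homozygous) a[2L] <- a[1L]
  a
}

genotype_key <- function(a1, a2) {
  # canonical string key for registry lookup, order-insensitive
  r <- order(allele_rank(c(a1, a2)))
  paste(c(a1, a2)[r], collapse = "|")
}
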