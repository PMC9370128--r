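# Self-(in)compatibility classification, incompatibility-group allocation,
# and donor x pistil pollinizer verdicts under gametophytic
# self-incompatibility: a pollen grain is rejected when its single
# S-haplotype matches either pistil allele, except Sc pollen, whose SFB
# loss-of-function insertion abolishes pollen-side rejection.

#' Classify self-(in)compatibility from a genotype
#'
#' Decision order: an `Sc`-carrying genotype is self-compatible; otherwise
#' direct phenotype evidence (a microscopy summary or a recorded
#' pollination-test result), when available, decides — phenotype
#' observations override genotype-based presumption, which is how
#' self-compatible cultivars with non-`Sc` genotypes (pollen-part mutations
#' outside the S-locus, e.g. 'Katy') are classified correctly; otherwise an
#' `S8` carrier without `Sc` is presumed self-incompatible (the intact
#' *SFB8* haplotype), as is any complete genotype of two non-`Sc` alleles;
#' a single known non-`Sc` allele alone is unclassifiable.
#'
#' @param g an [s_genotype].
#' @param phenotype optional direct evidence: a `pollination_summary`, or
#'   one of `"SC"` / `"SI"` (a phenotype recorded in the source
#'   literature). Inconclusive summaries are ignored.
#' @return List of class `self_compat_call` with elements `call`
#'   (`"SELF_COMPATIBLE"`, `"SELF_INCOMPATIBLE"`, `"UNCLASSIFIED"`) and
#'   `basis` (`"Sc_present"`, `"microscopy"`, `"S8_no_Sc"`,
#'   `"two_nonSc_alleles"`, `"insufficient_genotype"`).
#' @export
#' @examples
#' classify_self_compatibility(s_genotype("S5", "Sc"))
#' classify_self_compatibility(s_genotype("S2", "S6"))
classify_self_compatibility <- function(g, phenotype = NULL) {
  stopifnot(inherits(g, "s_genotype"))
  a <- g$alleles
  known <- a[!is.na(a)]

  phen <- NULL
  if (inherits(phenotype, "pollination_summary")) {
    if (phenotype$call != "INCONCLUSIVE") {
      phen <- if (phenotype$call == "SELF_COMPATIBLE") "SC" else "SI"
    }
  } else if (is.character(phenotype) && length(phenotype) == 1L &&
             !is.na(phenotype) && phenotype %in% c("SC", "SI")) {
    phen <- phenotype
  }

  if ("Sc" %in% known) {
    out <- list(call = "SELF_COMPATIBLE", basis = "Sc_present")
  } else if (!is.null(phen)) {
    out <- list(call = if (phen == "SC") "SELF_COMPATIBLE" else
                  "SELF_INCOMPATIBLE",
                basis = "microscopy")
  } else if ("S8" %in% known) {
    out <- list(call = "SELF_INCOMPATIBLE", basis = "S8_no_Sc")
  } else if (genotype_complete(g)) {
    out <- list(call = "SELF_INCOMPATIBLE", basis = "two_nonSc_alleles")
  } else {
    out <- list(call = "UNCLASSIFIED", basis = "insufficient_genotype")
  }
  structure(out, class = "self_compat_call")
}

#' @export
print.self_compat_call <- function(x, ...) {
  cat("<self_compat_call>", x$call, "(basis:", x$basis, ")\n")
  invisible(x)
}

#' Classify every record of a cultivar table
#'
#' Applies [classify_self_compatibility()] row-wise, using the table's
#' `phenotype` column as direct evidence where present.
#'
#' @param cultivars a `cultivar_table`.
#' @return The table with `self_compat` and `basis` columns appended.
#' @export
classify_cultivars <- function(cultivars) {
  res <- lapply(seq_len(nrow(cultivars)), function(i) {
    classify_self_compatibility(record_genotype(cultivars, i),
                                phenotype = cultivars$phenotype[i])
  })
  cultivars$self_compat <- vapply(res, `[[`, character(1), "call")
  cultivars$basis <- vapply(res, `[[`, character(1), "basis")
  cultivars
}

#' Is a pollen haplotype rejected by a pistil?
#'
#' The gametophytic rule with the apricot exception: rejection occurs iff
#' the pollen S-allele matches either pistil allele and is not `Sc`.
#'
#' @param pollen_allele a single S-allele label.
#' @param pistil an [s_genotype]; must be complete (presumed-homozygous
#'   single-`Sc` genotypes count as `ScSc`).
#' @return Logical scalar.
#' @export
pollen_rejected <- function(pollen_allele, pistil) {
  pollen_allele <- canonical_allele(pollen_allele)
  if (is.na(pollen_allele)) stop("pollen allele must be known", call. = FALSE)
  pa <- effective_alleles(pistil)
  if (anyNA(pa)) stop("pistil genotype must be complete", call. = FALSE)
  pollen_allele %in% pa && pollen_allele != "Sc"
}

#' Verdict for one donor x pistil cross
#'
#' Counts how many of the donor's two pollen haplotypes the pistil rejects:
#' none is a fully compatible cross, one is semi-compatible (half the
#' pollen rejected), two is an incompatible cross. An unknown allele on
#' either side makes the verdict undetermined, except that
#' presumed-homozygous single-`Sc` genotypes are treated as `ScSc`.
#'
#' @param donor,pistil [s_genotype] objects.
#' @return List of class `cross_verdict` with `category`
#'   (`"FULLY_COMPATIBLE"`, `"SEMI_COMPATIBLE"`, `"INCOMPATIBLE"`,
#'   `"UNDETERMINED"`), `compatible_pollen_fraction` (1, 0.5, 0, or `NA`),
#'   and `code` (`"F"`, `"S"`, `"I"`, `"U"`).
#' @export
#' @examples
#' cross_verdict(s_genotype("S1", "S2"), s_genotype("S1", "S3"))
cross_verdict <- function(donor, pistil) {
  stopifnot(inherits(donor, "s_genotype"), inherits(pistil, "s_genotype"))
  da <- effective_alleles(donor)
  pa <- effective_alleles(pistil)
  if (anyNA(da) || anyNA(pa)) {
    return(structure(list(category = "UNDETERMINED",
                          compatible_pollen_fraction = NA_real_, code = "U"),
                     class = "cross_verdict"))
  }
  r <- sum(vapply(da, function(a) a %in% pa && a != "Sc", logical(1)))
  category <- c("FULLY_COMPATIBLE", "SEMI_COMPATIBLE", "INCOMPATIBLE")[r + 1L]
  structure(list(category = category,
                 compatible_pollen_fraction = 1 - r / 2,
                 code = c("F", "S", "I")[r + 1L]),
            class = "cross_verdict")
}

#' @export
print.cross_verdict <- function(x, ...) {
  cat("<cross_verdict>", x$category,
      sprintf("(compatible pollen fraction: %s)\n",
              format(x$compatible_pollen_fraction)))
  invisible(x)
}

registry_numeral_max <- function(registry) {
  num <- registry$group[registry$group != "0"]
  if (length(num) == 0L) return(0L)
  max(as.integer(utils::as.roman(num)))
}

#' Allocate self-incompatible cultivars to incompatibility groups
#'
#' Only cultivars classified self-incompatible with a complete genotype are
#' assignable. A genotype present in the registry gets its historical
#' label; a new genotype shared by at least two input cultivars founds a
#' new group, numbered sequentially after the registry's highest Roman
#' numeral; a genotype unique in the input and absent from the registry
#' goes to group `"0"` (no cross-incompatible partner known, a
#' universal-pollinizer candidate). Unclassified cultivars are reported
#' separately, unassigned.
#'
#' @param cultivars a `cultivar_table`.
#' @param registry a `group_registry`.
#' @return Data frame of class `group_assignment` with columns `name`,
#'   `genotype`, `group`, plus attributes `unclassified` (names) and
#'   `new_groups` (labels founded by this input).
#' @export
assign_groups <- function(cultivars, registry = default_registry()) {
  cl <- classify_cultivars(cultivars)
  si <- cl[cl$self_compat == "SELF_INCOMPATIBLE" & !is.na(cl$allele2), ,
           drop = FALSE]
  unclassified <- cl$name[cl$self_compat == "UNCLASSIFIED"]
  new_labels <- character(0)

  if (nrow(si) == 0L) {
    out <- data.frame(name = character(0), genotype = character(0),
                      group = character(0), stringsAsFactors = FALSE)
  } else {
    key <- mapply(genotype_key, si$allele1, si$allele2, USE.NAMES = FALSE)
    group <- registry$group[match(key, registry$key)]

    # new genotypes: shared ones found new numbered groups, singletons -> "0"
    novel <- is.na(group)
    if (any(novel)) {
      tab <- table(key[novel])
      shared <- names(tab)[tab >= 2L]
      next_num <- registry_numeral_max(registry)
      for (k in shared) {
        next_num <- next_num + 1L
        lab <- as.character(utils::as.roman(next_num))
        group[key == k] <- lab
        new_labels <- c(new_labels, lab)
      }
      group[is.na(group)] <- "0"
    }
    out <- data.frame(name = si$name,
                      genotype = paste0(si$allele1, si$allele2),
                      group = group, stringsAsFactors = FALSE)
  }
  attr(out, "unclassified") <- unclassified
  attr(out, "new_groups") <- new_labels
  class(out) <- c("group_assignment", "data.frame")
  out
}

#' Donor x pistil pollinizer matrix
#'
#' Square matrix of cross verdict codes over a set of cultivars: rows are
#' pollen donors, columns pistil parents; the diagonal is the
#' self-pollination verdict. Codes: `F` fully compatible, `S`
#' semi-compatible, `I` incompatible, `U` undetermined.
#'
#' @param cultivars a `cultivar_table`.
#' @return Character matrix with cultivar names as dimnames, class
#'   `pollinizer_matrix`.
#' @export
pollinizer_matrix <- function(cultivars) {
  gts <- lapply(seq_len(nrow(cultivars)), function(i) record_genotype(cultivars, i))
  n <- length(gts)
  m <- matrix("U", n, n, dimnames = list(donor = cultivars$name,
                                         pistil = cultivars$name))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- cross_verdict(gts[[i]], gts[[j]])$code
    }
  }
  class(m) <- c("pollinizer_matrix", class(m))
  m
}

#' @export
print.pollinizer_matrix <- function(x, ...) {
  cat("<pollinizer_matrix> codes: F fully compatible, S semi-compatible,",
      "I incompatible, U undetermined\n")
  print(unclass(x), quote = FALSE)
  invisible(x)
}

#' Write a pollinizer matrix as CSV
#'
#' @param m a `pollinizer_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pollinizer_matrix <- function(m, path) {
  utils::write.csv(unclass(m), path, fileEncoding = "UTF-8")
  invisible(path)
}
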