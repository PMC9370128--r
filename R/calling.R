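# S-genotype calling from multi-primer PCR fragment sizes.
#
# The decision tree mirrors the bench workflow: the first-intron consensus
# assay (SRc) classifies each haplotype into a size class, two of which are
# ambiguous (358 bp = Sc/S8, the S1/S7 class at 408 bp, and the unanchored
# S6/S9 class); allele-specific secondary assays (SHLM1/2 for S1, SHLM3/4
# for S7, Pru-C2/C4R second-intron sizes for S6/S9, AprFBC8 for S8 vs Sc)
# then narrow each ambiguity class to its member(s).

#' Match an observed fragment size against an assay's size table
#'
#' @param panel a `primer_panel` (see [read_panel()]).
#' @param assay assay identifier, e.g. `"SRC_FIRST_INTRON"`.
#' @param observed observed fragment length in bp (positive scalar).
#' @return The candidate allele set of the unique expected size within
#'   tolerance, or `character(0)` if no expected size matches.
#' @export
#' @examples
#' match_size(default_panel(), "SRC_FIRST_INTRON", 358)
match_size <- function(panel, assay, observed) {
  stopifnot(is.numeric(observed), length(observed) == 1L)
  if (is.na(observed) || observed <= 0) stop("observed size must be positive")
  rows <- panel[panel$assay == assay, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown assay: ", assay, call. = FALSE)
  hit <- which(abs(rows$expected_bp - observed) <= rows$tolerance_bp)
  if (length(hit) > 1L) {
    stop("assay ", assay, ": size ", observed,
         " matches more than one expected fragment (panel misconfigured)",
         call. = FALSE)
  }
  if (length(hit) == 0L) return(character(0))
  rows$candidates[[hit]]
}

matched_bp <- function(panel, assay, observed) {
  rows <- panel[panel$assay == assay, , drop = FALSE]
  hit <- which(abs(rows$expected_bp - observed) <= rows$tolerance_bp)
  if (length(hit) == 1L) rows$expected_bp[hit] else NA_real_
}

#' Predict diagnostic amplicons for a complete genotype
#'
#' The forward model inverse to [call_genotype()]: for every panel entry
#' whose candidate set contains an allele of the genotype, one product of
#' the expected size is predicted. Alleles with no diagnostic product under
#' an assay are omitted for that assay; a homozygote yields each product
#' once.
#'
#' @param genotype a complete [s_genotype].
#' @param panel a `primer_panel`; defaults to the packaged panel.
#' @return Data frame with columns `assay`, `allele`, `expected_bp`, in
#'   panel order.
#' @export
#' @examples
#' predict_amplicons(s_genotype("S1", "S9"))
predict_amplicons <- function(genotype, panel = default_panel()) {
  stopifnot(inherits(genotype, "s_genotype"))
  if (!genotype_complete(genotype)) {
    stop("predict_amplicons requires a complete genotype", call. = FALSE)
  }
  alleles <- unique(genotype$alleles)
  out <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i) {
    present <- intersect(panel$candidates[[i]], alleles)
    if (length(present) == 0L) return(NULL)
    data.frame(assay = panel$assay[i], allele = paste(present, collapse = ";"),
               expected_bp = panel$expected_bp[i], stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(assay = character(0), allele = character(0),
                      expected_bp = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Call an S-genotype from one cultivar's assay results
#'
#' Applies the disambiguation decision tree. Every first-intron peak is
#' assigned a candidate class by size; allele-specific secondary assays
#' resolve the class members actually present. When an Sc/S8 class cannot
#' be resolved because the SFB assay was attempted but gave no
#' amplification (primer mismatch), the genotype is returned incomplete
#' with `needs_pollination_test = TRUE`, to be settled by
#' [resolve_sc_s8()] after a controlled self-pollination experiment.
#'
#' An allele reported by a specific secondary assay is retained even if no
#' first-intron peak supports it (the specific assay wins); the
#' disagreement is logged in the trace's `conflicts`.
#'
#' @param assays named list of observed fragment-size vectors, one element
#'   per assay (e.g. `list(SRC_FIRST_INTRON = c(358, 408), APRFBC8 = 500)`).
#'   `numeric(0)` records an attempted assay with no amplification.
#' @param panel a `primer_panel`.
#' @return List of class `s_call` with elements `genotype` (an
#'   [s_genotype], or `NULL` when nothing resolved), `trace` (a
#'   `call_trace`), and `status` (`"COMPLETE"`, `"INCOMPLETE"`, or
#'   `"UNRESOLVED"`).
#' @export
#' @examples
#' call_genotype(list(SRC_FIRST_INTRON = c(358, 408),
#'                    SHLM12 = 650, APRFBC8 = 500))
call_genotype <- function(assays, panel = default_panel()) {
  stopifnot(is.list(assays), !is.null(names(assays)))
  if (!"SRC_FIRST_INTRON" %in% names(assays)) {
    stop("at least one SRC_FIRST_INTRON result is required", call. = FALSE)
  }
  unknown <- setdiff(names(assays), unique(panel$assay))
  if (length(unknown)) {
    stop("assay(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  trace_rows <- list()
  note <- function(assay, obs, exp, cand) {
    trace_rows[[length(trace_rows) + 1L]] <<- data.frame(
      assay = assay, observed_bp = obs, matched_bp = exp,
      candidates = paste(cand, collapse = ";"), stringsAsFactors = FALSE)
  }

  # first-intron peaks -> candidate classes
  classes <- list()
  for (obs in sort(assays$SRC_FIRST_INTRON)) {
    cand <- match_size(panel, "SRC_FIRST_INTRON", obs)
    note("SRC_FIRST_INTRON", obs, matched_bp(panel, "SRC_FIRST_INTRON", obs), cand)
    if (length(cand)) classes[[length(classes) + 1L]] <- list(obs = obs, cand = cand)
  }

  # secondary assays -> confirmed alleles
  secondary <- setdiff(names(assays), "SRC_FIRST_INTRON")
  confirmed <- character(0)
  attempted_empty <- character(0)
  for (a in secondary) {
    sizes <- assays[[a]]
    sizes <- sizes[!is.na(sizes)]
    if (length(sizes) == 0L) {
      attempted_empty <- c(attempted_empty, a)
      note(a, NA_real_, NA_real_, character(0))
      next
    }
    for (obs in sort(sizes)) {
      cand <- match_size(panel, a, obs)
      note(a, obs, matched_bp(panel, a, obs), cand)
      if (length(cand) == 1L) confirmed <- union(confirmed, cand)
    }
  }

  # resolve each first-intron class by its confirmed members
  resolved <- character(0)
  ambiguities <- list()
  attribution <- list()  # first-intron peak size -> resolved allele(s)
  needs_poll <- FALSE
  for (cl in classes) {
    # a single-candidate size is diagnostic on its own; ambiguity classes
    # need a member confirmed by a specific secondary assay
    members <- if (length(cl$cand) == 1L) cl$cand else
      intersect(cl$cand, confirmed)
    if (length(members) > 0L) {
      resolved <- union(resolved, members)
      attribution[[as.character(cl$obs)]] <- members
    } else {
      ambiguities[[length(ambiguities) + 1L]] <- cl$cand
      if (setequal(cl$cand, c("S8", "Sc"))) needs_poll <- TRUE
    }
  }

  # specific assays win over the first-intron classification
  conflicts <- character(0)
  orphan <- setdiff(confirmed, unlist(lapply(classes, `[[`, "cand")))
  if (length(orphan)) {
    conflicts <- sprintf(
      "allele %s reported by a specific assay but unsupported by a first-intron peak",
      orphan)
    resolved <- union(resolved, orphan)
  }

  resolved <- resolved[order(allele_rank(resolved))]
  if (length(resolved) > 2L) {
    stop("inconsistent assays: more than two alleles resolved (",
         paste(resolved, collapse = ", "), ")", call. = FALSE)
  }

  if (length(resolved) == 2L) {
    genotype <- s_genotype(resolved[1L], resolved[2L])
    status <- "COMPLETE"
  } else if (length(resolved) == 1L) {
    # one-peak-only calls are homozygote candidates; presumed only for Sc
    lone_peak <- length(classes) == 1L && length(ambiguities) == 0L
    genotype <- s_genotype(resolved[1L],
                           presumed_homozygous = lone_peak && resolved[1L] == "Sc")
    status <- "INCOMPLETE"
  } else if (length(ambiguities) > 0L) {
    genotype <- NULL
    status <- "INCOMPLETE"
  } else {
    genotype <- NULL
    status <- "UNRESOLVED"
  }

  trace <- structure(
    list(matches = do.call(rbind, trace_rows),
         resolved = resolved,
         ambiguities = ambiguities,
         attribution = attribution,
         conflicts = conflicts,
         assays_no_amplification = attempted_empty,
         needs_pollination_test = needs_poll),
    class = "call_trace")

  structure(list(genotype = genotype, trace = trace, status = status),
            class = "s_call")
}

#' @export
print.call_trace <- function(x, ...) {
  cat("<call_trace>\n")
  if (!is.null(x$matches)) print(x$matches, row.names = FALSE)
  cat("resolved:", if (length(x$resolved)) paste(x$resolved, collapse = " ")
      else "(none)", "\n")
  for (amb in x$ambiguities) {
    cat("unresolved ambiguity: {", paste(amb, collapse = ", "), "}\n")
  }
  for (msg in x$conflicts) cat("conflict:", msg, "\n")
  if (x$needs_pollination_test) cat("flag: NEEDS_POLLINATION_TEST\n")
  invisible(x)
}

#' @export
print.s_call <- function(x, ...) {
  cat("<s_call> status:", x$status, "\n")
  if (!is.null(x$genotype)) cat("genotype:", format(x$genotype), "\n")
  print(x$trace)
  invisible(x)
}

#' Call genotypes for every cultivar in a long-format assay table
#'
#' @param assay_table data frame as returned by [read_assays()].
#' @param panel a `primer_panel`.
#' @return Named list of `s_call` objects, one per cultivar.
#' @export
call_genotypes <- function(assay_table, panel = default_panel()) {
  split_by <- split(assay_table, assay_table$cultivar)
  lapply(split_by, function(df) {
    assays <- lapply(split(df$size_bp, df$assay), function(v) v[!is.na(v)])
    call_genotype(assays, panel)
  })
}
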