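# Interpretation of controlled-pollination microscopy: aniline-blue scored
# pistils are summarized into a self-(in)compatibility call. Used as the
# fallback when the SFB assay fails to amplify and the Sc/S8 ambiguity
# cannot be settled molecularly.

#' Summarize self-pollination pistil observations
#'
#' A cultivar is called self-compatible when pollen tubes reached the base
#' of the style in more than `majority` of self-pollinated pistils, and
#' self-incompatible when growth was arrested along the style in more than
#' `majority` of them; anything else (including fewer than `min_pistils`
#' observations) is inconclusive. The mean percent of style traveled is
#' computed over all pistils, counting reached-base pistils at 100.
#'
#' @param obs data frame of pistil observations (see [read_pistils()]); all
#'   rows must be self-pollinations of a single cultivar.
#' @param min_pistils minimum number of pistils for a non-inconclusive call
#'   (default 10).
#' @param majority fraction that constitutes "most" pistils (default 0.5).
#' @param controls optional data frame of cross-pollination observations of
#'   the same pistil parent with a known-compatible donor; if fewer than
#'   `majority` of control pistils show tubes at the base, a warning is
#'   issued (pollen or pistil quality suspect), but the call is not gated.
#' @return List of class `pollination_summary`: `cultivar`, `n`,
#'   `fraction_reached_base`, `fraction_arrested`, `mean_percent`, `call`
#'   (`"SELF_COMPATIBLE"`, `"SELF_INCOMPATIBLE"`, `"INCONCLUSIVE"`), and
#'   `reason` for inconclusive calls.
#' @export
#' @examples
#' obs <- simulate_pistils("Water", "SC", n = 17, seed = 1)
#' summarize_self_pollination(obs)
summarize_self_pollination <- function(obs, min_pistils = 10, majority = 0.5,
                                       controls = NULL) {
  if (is.null(obs) || nrow(obs) == 0L) {
    stop("no pistil observations supplied", call. = FALSE)
  }
  validate_pistils(obs)
  if (any(obs$cross != "self")) {
    stop("summarize_self_pollination expects self-pollinations only",
         call. = FALSE)
  }
  cv <- unique(obs$cultivar)
  if (length(cv) != 1L) {
    stop("observations mix cultivars: ", paste(cv, collapse = ", "),
         call. = FALSE)
  }

  n <- nrow(obs)
  frac_base <- mean(obs$reached_base)
  frac_arrested <- mean(!obs$reached_base)
  mean_pct <- mean(obs$percent)

  if (!is.null(controls) && nrow(controls) > 0L) {
    validate_pistils(controls)
    if (mean(controls$reached_base) <= majority) {
      warning("cross-pollination controls for '", cv,
              "' did not reach the style base in most pistils; ",
              "pollination quality suspect", call. = FALSE)
    }
  }

  reason <- NA_character_
  if (n < min_pistils) {
    call <- "INCONCLUSIVE"
    reason <- sprintf("only %d pistils (minimum %d)", n, min_pistils)
  } else if (frac_base > majority) {
    call <- "SELF_COMPATIBLE"
  } else if (frac_arrested > majority) {
    call <- "SELF_INCOMPATIBLE"
  } else {
    call <- "INCONCLUSIVE"
    reason <- "no majority outcome"
  }

  structure(list(cultivar = cv, n = n, fraction_reached_base = frac_base,
                 fraction_arrested = frac_arrested, mean_percent = mean_pct,
                 call = call, reason = reason),
            class = "pollination_summary")
}

#' @export
print.pollination_summary <- function(x, ...) {
  cat("<pollination_summary> '", x$cultivar, "': ", x$call, "\n", sep = "")
  cat(sprintf("  n = %d pistils; %.0f%% reached base; mean %.1f%% of style traveled\n",
              x$n, 100 * x$fraction_reached_base, x$mean_percent))
  if (!is.na(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Resolve an Sc/S8 ambiguity with a pollination result
#'
#' When the SFB assay gives no amplification, the first-intron 358 bp class
#' cannot be split molecularly; the phenotype decides: a self-compatible
#' cultivar carries `Sc` (the loss-of-function SFB haplotype), a
#' self-incompatible one carries `S8`.
#'
#' @param call an `s_call` from [call_genotype()] whose trace holds exactly
#'   one unresolved `{Sc, S8}` ambiguity.
#' @param summary a `pollination_summary` with a conclusive call.
#' @return The completed [s_genotype].
#' @export
resolve_sc_s8 <- function(call, summary) {
  stopifnot(inherits(call, "s_call"), inherits(summary, "pollination_summary"))
  amb <- Filter(function(a) setequal(a, c("S8", "Sc")), call$trace$ambiguities)
  if (length(amb) != 1L || length(call$trace$ambiguities) != 1L) {
    stop("genotype must carry exactly one unresolved {Sc, S8} ambiguity",
         call. = FALSE)
  }
  if (summary$call == "INCONCLUSIVE") {
    stop("pollination summary is inconclusive; ambiguity retained",
         call. = FALSE)
  }
  allele <- if (summary$call == "SELF_COMPATIBLE") "Sc" else "S8"
  other <- call$trace$resolved
  if (length(other) == 0L) {
    s_genotype(allele, presumed_homozygous = allele == "Sc")
  } else if (length(other) == 1L) {
    s_genotype(other, allele)
  } else {
    stop("genotype already complete; nothing to resolve", call. = FALSE)
  }
}
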