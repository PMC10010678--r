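# Identification-quality filters.

#' Detect an N-glycosylation sequon
#'
#' Tests for the N-X-S/T motif where X is any residue except proline.
#' Peptides containing a sequon are excluded from O-glycan motif statistics
#' because incomplete N-glycan removal would confound them.
#'
#' @param sequence Character vector of uppercase peptide sequences.
#' @return Logical vector; sequences shorter than 3 residues return `FALSE`.
#' @export
#' @examples
#' hasNSequon(c("PNGTK", "PNPSK"))  # TRUE, FALSE
hasNSequon <- function(sequence) {
  grepl("N[^P][ST]", sequence)
}

#' Filter identifications to the high-confidence glyco set
#'
#' Applies the standard quality criteria jointly: target records only,
#' `q_value` strictly below the threshold, localization level in the allowed
#' set, every site localization probability strictly above the threshold, no
#' N-sequon, and minimum peptide length. Unmodified records are always
#' dropped from the glyco set. Per-criterion removal counts (both
#' first-failure and any-failure tallies) are reported via `message()` and
#' attached as the `"filterCounts"` attribute, retrievable with
#' [filterCounts()]. Per-file retained counts are always included so
#' replicate-averaged summaries can be produced downstream.
#'
#' @param x A [GlycoPSMSet].
#' @param config A [FilterConfig].
#' @param verbose Emit the removal-count log.
#' @return The filtered [GlycoPSMSet] (a subset of the input, in input
#'   order). Applying the filter twice equals applying it once.
#' @export
filterIdentifications <- function(x, config = FilterConfig(),
                                  verbose = TRUE) {
  stopifnot(is(x, "GlycoPSMSet"), is(config, "FilterConfig"))
  rec <- psmRecords(x)
  n <- nrow(rec)
  fail <- list()
  fail$decoy <- if (config@targetsOnly) rec$is_decoy else rep(FALSE, n)
  fail$q_value <- !(rec$q_value < config@maxQ)
  fail$unmodified <- rec$localization_level == "unmodified"
  fail$level <- !(rec$localization_level %in% config@allowedLevels) &
    !fail$unmodified
  fail$site_probability <- vapply(rec$sites, function(s)
    nrow(s) > 0L && any(!(s$localization_probability >
                            config@minSiteProbability)), NA)
  if (n == 0L) fail$site_probability <- logical(0)
  fail$n_sequon <- if (config@excludeNSequon) hasNSequon(rec$base_sequence)
                   else rep(FALSE, n)
  fail$length <- nchar(rec$base_sequence) < config@minPeptideLength
  fail_mat <- do.call(cbind, fail)
  any_fail <- if (n) rowSums(fail_mat) > 0L else logical(0)
  keep <- !any_fail
  first_fail <- if (n) apply(fail_mat, 1L, function(z)
    if (any(z)) names(fail)[which(z)[1L]] else NA_character_)
    else character(0)
  counts <- list(
    input = n, retained = sum(keep), removed = sum(any_fail),
    any_failure = colSums(fail_mat),
    first_failure = table(factor(first_fail, levels = names(fail))),
    per_file_retained = table(rec$source_file[keep]))
  if (verbose && n) {
    message(sprintf("filterIdentifications: %d -> %d record(s) (%d removed)",
                    n, sum(keep), sum(any_fail)))
    for (nm in names(fail))
      message(sprintf("  %-16s any-failure %5d  first-failure %5d", nm,
                      counts$any_failure[[nm]],
                      counts$first_failure[[nm]]))
  }
  out <- GlycoPSMSet(rec[keep, , drop = FALSE])
  attr(out, "filterCounts") <- counts
  out
}

#' @rdname filterIdentifications
#' @export
filterCounts <- function(x) attr(x, "filterCounts")
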