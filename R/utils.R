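# Shared constants and small helpers.

# The 20-residue alphabet, alphabetical. Ambiguity codes (B, J, O, U, X, Z)
# are rejected everywhere by contract.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

LOCALIZATION_LEVELS <- c("Level1", "Level1b", "Level2", "Level3", "unmodified")

#' Schechter--Berger position labels for a cleavage window
#'
#' Labels run from P<flank> down to P1 (N-terminal to the scissile bond) and
#' P1' up to P<flank>' (C-terminal). Cleavage occurs between P1 and P1'.
#'
#' @param flank Number of residues on each side of the cleavage point.
#' @return Character vector of length `2 * flank`.
#' @export
#' @examples
#' windowPositions()
windowPositions <- function(flank = 5L) {
  stopifnot(flank >= 1)
  c(paste0("P", flank:1), paste0("P", 1:flank, "'"))
}

.assert_aa <- function(x, what = "sequence") {
  bad <- !grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), x)
  if (any(bad)) {
    chars <- unique(unlist(strsplit(x[bad][1L], "")))
    off <- setdiff(chars, AA20)
    stop(sprintf("invalid %s: non-standard residue(s) %s in \"%s\"",
                 what, paste(off, collapse = ", "),
                 substr(x[bad][1L], 1, 30)), call. = FALSE)
  }
  invisible(TRUE)
}

.chars <- function(seq) strsplit(seq, "")[[1]]

# Reverse a sequence and remap 1-based positions accordingly (decoy helper).
.reverse_seq <- function(seq) paste(rev(.chars(seq)), collapse = "")
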