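# Placing glycopeptides on protein sequences and classifying termini.

#' Locate a peptide within a protein database
#'
#' Finds all exact occurrences of a peptide across all proteins (no
#' isobaric-residue equivalence).
#'
#' @param peptide Uppercase peptide sequence.
#' @param proteins An `AAStringSet` from [readProteinFasta()] or a named
#'   character vector of sequences.
#' @return A `data.frame` with columns `accession`, `start` (1-based),
#'   sorted by `(accession, start)`; zero rows when absent.
#' @export
locatePeptide <- function(peptide, proteins) {
  stopifnot(nzchar(peptide))
  seqs <- .protein_seqs(proteins)
  # zero-width lookahead so overlapping occurrences are all reported
  pat <- paste0("(?=", peptide, ")")
  hits <- lapply(names(seqs), function(acc) {
    m <- gregexpr(pat, seqs[[acc]], perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    data.frame(accession = acc, start = as.integer(m))
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    return(data.frame(accession = character(0), start = integer(0)))
  hits[order(hits$accession, hits$start), , drop = FALSE]
}

#' Classify peptide termini as tryptic-like or protease-derived
#'
#' The N-terminus is tryptic-like iff the peptide starts at residue 1, or at
#' residue 2 after an initiator methionine under
#' `metPolicy = "variable_cleavage"`, or the preceding residue is K/R. The
#' C-terminus is tryptic-like iff the peptide ends at the protein C-terminus
#' or its last residue is K/R. Protein termini count as tryptic-like because
#' they carry no protease-cleavage evidence. The category is `fully_tryptic`
#' (both termini tryptic-like), `nterm` (non-tryptic N-terminus), `cterm`
#' (non-tryptic C-terminus) or `both`.
#'
#' @param accession,start,end Peptide locus (1-based, inclusive).
#' @param proteins Protein database as in [locatePeptide()].
#' @param metPolicy `"variable_cleavage"` (default, mirroring a variable
#'   initiator-methionine search setting) or `"none"`.
#' @param prolineSuppression Suppress K/R boundaries followed by proline
#'   (off by default; the plain trypsin rule is `K|`, `R|`).
#' @return One of `"fully_tryptic"`, `"nterm"`, `"cterm"`, `"both"`.
#' @export
classifyTermini <- function(accession, start, end, proteins,
                            metPolicy = c("variable_cleavage", "none"),
                            prolineSuppression = FALSE) {
  metPolicy <- match.arg(metPolicy)
  seq_ <- .protein_seq(proteins, accession)
  if (is.null(seq_))
    stop(sprintf("unknown accession \"%s\"", accession), call. = FALSE)
  L <- nchar(seq_)
  if (start < 1L || end > L || end < start)
    stop(sprintf("locus %d-%d out of bounds for %s (length %d)", start, end,
                 accession, L), call. = FALSE)
  at <- function(i) substr(seq_, i, i)
  kr_boundary <- function(i) {    # cut after residue i conforms to trypsin
    at(i) %in% c("K", "R") &&
      !(prolineSuppression && i < L && at(i + 1L) == "P")
  }
  n_tryptic <- start == 1L ||
    (start == 2L && metPolicy == "variable_cleavage" && at(1L) == "M") ||
    kr_boundary(start - 1L)
  c_tryptic <- end == L || kr_boundary(end)
  if (n_tryptic && c_tryptic) "fully_tryptic"
  else if (!n_tryptic && c_tryptic) "nterm"
  else if (n_tryptic && !c_tryptic) "cterm"
  else "both"
}

#' Map filtered glycopeptides onto protein sequences
#'
#' Places each record of a (filtered) [GlycoPSMSet] on the protein database
#' and classifies its termini. Records whose peptide is not found are
#' dropped with a count; peptides occurring at more than one locus are
#' flagged ambiguous and, under the default `"drop"` policy, removed from
#' motif statistics (a multi-locus peptide contributes conflicting windows);
#' the `"all"` policy enumerates every locus.
#'
#' @param x A [GlycoPSMSet].
#' @param proteins Protein database as in [locatePeptide()].
#' @param ambiguousPolicy `"drop"` or `"all"`.
#' @param metPolicy,prolineSuppression Passed to [classifyTermini()].
#' @param verbose Emit mapping counts.
#' @return A `data.frame` with one row per mapped locus: `accession`,
#'   `start`, `end`, `category`, `ambiguous`, `base_sequence`, `source_file`,
#'   `scan`, `q_value` and list column `sites`. The attribute
#'   `"mappingCounts"` holds input/unmapped/ambiguous tallies.
#' @export
mapGlycopeptides <- function(x, proteins, ambiguousPolicy = c("drop", "all"),
                             metPolicy = c("variable_cleavage", "none"),
                             prolineSuppression = FALSE, verbose = TRUE) {
  stopifnot(is(x, "GlycoPSMSet"))
  ambiguousPolicy <- match.arg(ambiguousPolicy)
  metPolicy <- match.arg(metPolicy)
  rec <- psmRecords(x)
  out <- vector("list", nrow(rec))
  n_unmapped <- 0L
  n_ambiguous <- 0L
  for (i in seq_len(nrow(rec))) {
    loci <- locatePeptide(rec$base_sequence[i], proteins)
    if (nrow(loci) == 0L) { n_unmapped <- n_unmapped + 1L; next }
    amb <- nrow(loci) > 1L
    if (amb) {
      n_ambiguous <- n_ambiguous + 1L
      if (ambiguousPolicy == "drop") next
    }
    end <- loci$start + nchar(rec$base_sequence[i]) - 1L
    cat_ <- vapply(seq_len(nrow(loci)), function(j)
      classifyTermini(loci$accession[j], loci$start[j], end[j], proteins,
                      metPolicy, prolineSuppression), "")
    df <- data.frame(accession = loci$accession, start = loci$start,
                     end = end, category = cat_, ambiguous = amb,
                     base_sequence = rec$base_sequence[i],
                     source_file = rec$source_file[i], scan = rec$scan[i],
                     q_value = rec$q_value[i])
    df$sites <- rep(rec$sites[i], nrow(loci))
    out[[i]] <- df
  }
  out <- out[!vapply(out, is.null, NA)]
  mapped <- if (length(out)) do.call(rbind, out) else
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), category = character(0),
               ambiguous = logical(0), base_sequence = character(0),
               source_file = character(0), scan = character(0),
               q_value = numeric(0), sites = I(list()))
  rownames(mapped) <- NULL
  counts <- list(input = nrow(rec), mapped = nrow(mapped),
                 unmapped = n_unmapped, ambiguous = n_ambiguous,
                 by_category = table(factor(mapped$category,
                   levels = c("fully_tryptic", "nterm", "cterm", "both"))))
  if (verbose)
    message(sprintf(
      "mapGlycopeptides: %d record(s) -> %d locus/loci (%d unmapped, %d ambiguous [%s])",
      nrow(rec), nrow(mapped), n_unmapped, n_ambiguous, ambiguousPolicy))
  attr(mapped, "mappingCounts") <- counts
  mapped
}

#' Write a mapped-peptide table
#'
#' @param mapped Output of [mapGlycopeptides()].
#' @param path Output TSV path.
#' @export
writeMappedPeptides <- function(mapped, path) {
  out <- mapped[c("accession", "start", "end", "category", "ambiguous",
                  "base_sequence", "source_file", "scan")]
  out$sites <- vapply(mapped$sites, .format_sites_cell, "")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
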