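# Reading and writing identification tables and protein FASTA.

#' Column maps for glycoPSM table dialects
#'
#' A column map translates the headers of an external identification table
#' into the canonical internal schema (`source_file`, `scan`,
#' `base_sequence`, `protein_accession`, `is_decoy`, `q_value`,
#' `localization_level`, `sites`). The map is a named character vector
#' (canonical name -> source header) with attributes `glycan_dialect`
#' (`"compact"` or `"parenthesized"`), `site_encoding` (`"canonical"` for
#' semicolon-separated `pos:glycan:prob` triplets, `"bracketed"` for
#' `[pos,glycan,prob]` groups) and `decoy_encoding` (`"logical"` or `"TD"`
#' for target/decoy letter markers).
#'
#' `canonicalColumnMap()` is the identity map for tables written by
#' [writePSMTable()]. `metaMorpheusColumnMap()` is a best-effort adapter for
#' O-Pair Search `oglyco.psmtsv` output; the native headers are configurable
#' because they are version-dependent.
#'
#' @return A named character vector with parser-hint attributes.
#' @export
canonicalColumnMap <- function() {
  map <- setNames(PSM_COLUMNS, PSM_COLUMNS)
  attr(map, "glycan_dialect") <- "compact"
  attr(map, "site_encoding") <- "canonical"
  attr(map, "decoy_encoding") <- "logical"
  map
}

#' @rdname canonicalColumnMap
#' @param overrides Named character vector replacing individual source
#'   headers.
#' @export
metaMorpheusColumnMap <- function(overrides = character(0)) {
  map <- c(source_file = "File Name", scan = "Scan Number",
           base_sequence = "Base Sequence",
           protein_accession = "Protein Accession",
           is_decoy = "Decoy", q_value = "QValue",
           localization_level = "GlycoLocalizationLevel",
           sites = "Localized Glycans")
  if (length(overrides)) map[names(overrides)] <- overrides
  attr(map, "glycan_dialect") <- "parenthesized"
  attr(map, "site_encoding") <- "bracketed"
  attr(map, "decoy_encoding") <- "TD"
  map
}

.parse_sites_cell <- function(cell, encoding, row) {
  cell <- trimws(cell)
  if (is.na(cell) || !nzchar(cell)) return(.empty_sites())
  parts <- if (encoding == "canonical") {
    strsplit(cell, ";", fixed = TRUE)[[1]]
  } else {
    m <- regmatches(cell, gregexpr("\\[[^]]*\\]", cell))[[1]]
    if (!length(m))
      stop(sprintf("row %d: malformed site-assignment cell \"%s\"", row,
                   cell), call. = FALSE)
    gsub(",", ":", substr(m, 2, nchar(m) - 1L), fixed = TRUE)
  }
  fields <- strsplit(trimws(parts), ":", fixed = TRUE)
  if (any(lengths(fields) != 3L))
    stop(sprintf("row %d: malformed site-assignment cell \"%s\" (expected pos:glycan:prob triplets)",
                 row, cell), call. = FALSE)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  prob <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(pos) || anyNA(prob))
    stop(sprintf("row %d: non-numeric position or probability in \"%s\"",
                 row, cell), call. = FALSE)
  glycan <- vapply(vapply(fields, `[[`, "", 2L), function(g)
    tryCatch(glycanText(g), error = function(e)
      stop(sprintf("row %d: %s", row, conditionMessage(e)), call. = FALSE)),
    "", USE.NAMES = FALSE)
  data.frame(peptide_position = pos, glycan = glycan,
             localization_probability = prob)
}

.format_sites_cell <- function(sites) {
  if (nrow(sites) == 0L) return("")
  paste(sprintf("%d:%s:%g", sites$peptide_position, sites$glycan,
                sites$localization_probability), collapse = ";")
}

.normalize_level <- function(x, row) {
  lv <- gsub("\\s", "", x)
  lv[tolower(lv) %in% c("", "na", "unmodified", "none")] <- "unmodified"
  bad <- !lv %in% LOCALIZATION_LEVELS
  if (any(bad))
    stop(sprintf("row %d: unknown localization level \"%s\"", row[bad][1],
                 x[bad][1]), call. = FALSE)
  lv
}

#' Read a glycopeptide identification table
#'
#' Reads a tab-separated identification table and normalizes it into a
#' [GlycoPSMSet] through a column map. Rows failing type coercion are
#' rejected with row-numbered errors by default; with `permissive = TRUE`
#' malformed rows are skipped with a warning and their count is reported in
#' a message, because silently dropping rows would corrupt downstream motif
#' statistics.
#'
#' @param path Path to a TSV file with a header row.
#' @param columnMap A column map (see [canonicalColumnMap()]).
#' @param permissive Skip malformed rows instead of failing.
#' @return A [GlycoPSMSet] with records in file order.
#' @seealso [writePSMTable()]
#' @export
readPSMTable <- function(path, columnMap = canonicalColumnMap(),
                         permissive = FALSE) {
  stopifnot(file.exists(path))
  raw <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
  need <- setdiff(PSM_COLUMNS, "sites")
  missing_src <- columnMap[!columnMap %in% names(raw)]
  if (length(missing_src))
    stop(sprintf("missing mapped column(s): %s (for canonical field(s) %s)",
                 paste(unname(missing_src), collapse = ", "),
                 paste(names(missing_src), collapse = ", ")), call. = FALSE)
  enc <- attr(columnMap, "site_encoding") %||% "canonical"
  dec <- attr(columnMap, "decoy_encoding") %||% "logical"
  n <- nrow(raw)
  parse_row <- function(i) {
    decoy_raw <- raw[[columnMap[["is_decoy"]]]][i]
    is_decoy <- if (dec == "TD") {
      if (!toupper(decoy_raw) %in% c("T", "D"))
        stop(sprintf("row %d: decoy marker must be T or D, got \"%s\"", i,
                     decoy_raw), call. = FALSE)
      toupper(decoy_raw) == "D"
    } else {
      v <- as.logical(decoy_raw)
      if (is.na(v))
        stop(sprintf("row %d: is_decoy must be TRUE/FALSE, got \"%s\"", i,
                     decoy_raw), call. = FALSE)
      v
    }
    q <- suppressWarnings(as.numeric(raw[[columnMap[["q_value"]]]][i]))
    if (is.na(q) || q < 0 || q > 1)
      stop(sprintf("row %d: q_value must be a number in [0, 1], got \"%s\"",
                   i, raw[[columnMap[["q_value"]]]][i]), call. = FALSE)
    seq_ <- toupper(trimws(raw[[columnMap[["base_sequence"]]]][i]))
    if (!grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"), seq_))
      stop(sprintf("row %d: invalid base sequence \"%s\"", i, seq_),
           call. = FALSE)
    list(source_file = raw[[columnMap[["source_file"]]]][i],
         scan = raw[[columnMap[["scan"]]]][i],
         base_sequence = seq_,
         protein_accession = raw[[columnMap[["protein_accession"]]]][i],
         is_decoy = is_decoy, q_value = q,
         localization_level = .normalize_level(
           raw[[columnMap[["localization_level"]]]][i], i),
         sites = .parse_sites_cell(raw[[columnMap[["sites"]]]][i], enc, i))
  }
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    parsed <- tryCatch(parse_row(i), error = function(e) {
      if (!permissive) stop(e)
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(parsed)) skipped <- skipped + 1L
    else rows[[i]] <- parsed           # never assign NULL: it shrinks a list
  }
  rows <- rows[!vapply(rows, is.null, NA)]
  if (skipped > 0L)
    message(sprintf("readPSMTable: skipped %d malformed row(s) of %d",
                    skipped, n))
  if (!length(rows)) return(GlycoPSMSet())
  rec <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[need], stringsAsFactors = FALSE)))
  rec$sites <- lapply(rows, `[[`, "sites")
  GlycoPSMSet(rec)
}

#' Write a glycoPSM table in the canonical dialect
#'
#' Writes a UTF-8 tab-separated table with the canonical columns
#' `source_file`, `scan`, `base_sequence`, `protein_accession`, `is_decoy`,
#' `q_value`, `localization_level`, `sites` (semicolon-separated
#' `pos:glycan:prob` triplets). A table written here re-reads to an
#' identical record set with [readPSMTable()].
#'
#' @param x A [GlycoPSMSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePSMTable <- function(x, path) {
  stopifnot(is(x, "GlycoPSMSet"))
  rec <- psmRecords(x)
  out <- rec[setdiff(PSM_COLUMNS, "sites")]
  out$q_value <- vapply(rec$q_value, function(q) format(q, digits = 15), "")
  out$sites <- vapply(rec$sites, .format_sites_cell, "")
  out <- out[PSM_COLUMNS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# FASTA

#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20-residue alphabet;
#' ambiguity codes are rejected with an error naming the residue and record.
#' The accession is the first whitespace-delimited token of the header; for
#' UniProt pipe-delimited headers (`>sp|P12345|NAME`) the second pipe field
#' is used and the full header is retained in the element metadata.
#'
#' @param path FASTA file path.
#' @return A [Biostrings::AAStringSet] named by accession, with the original
#'   header in `mcols(x)$description`.
#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @export
readProteinFasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no records in FASTA file", call. = FALSE)
  headers <- names(aa)
  first <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  acc <- vapply(first, function(tok) {
    f <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(f) >= 3L) f[2L] else tok
  }, "", USE.NAMES = FALSE)
  if (anyDuplicated(acc))
    stop(sprintf("duplicate accession \"%s\" in %s",
                 acc[duplicated(acc)][1], path), call. = FALSE)
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs)))
    stop(sprintf("empty sequence for record \"%s\"",
                 acc[!nzchar(seqs)][1]), call. = FALSE)
  for (i in seq_along(seqs)) {
    off <- setdiff(unique(.chars(seqs[i])), AA20)
    if (length(off))
      stop(sprintf("record \"%s\": non-standard residue(s) %s", acc[i],
                   paste(off, collapse = ", ")), call. = FALSE)
  }
  out <- Biostrings::AAStringSet(setNames(seqs, acc))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = headers)
  out
}

#' @rdname readProteinFasta
#' @param x An `AAStringSet` (or named character vector) to write.
#' @export
writeProteinFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Resolve a protein sequence (character) from an AAStringSet-like object.
.protein_seq <- function(proteins, accession) {
  if (is.character(proteins)) {
    if (!accession %in% names(proteins)) return(NULL)
    return(proteins[[accession]])
  }
  if (!accession %in% names(proteins)) return(NULL)
  as.character(proteins[[accession]])
}

.protein_seqs <- function(proteins) {
  if (is.character(proteins)) return(proteins)
  setNames(as.character(proteins), names(proteins))
}
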