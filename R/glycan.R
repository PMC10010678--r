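# Glycan composition parsing and the glycan database format.

#' Parse an O-glycan composition string
#'
#' Parses the five-class letter code in which N denotes HexNAc, H denotes
#' Hex, A denotes NeuAc, G denotes NeuGc and F denotes Fucose. Both the
#' compact dialect (`"N1H1A1"`) and the parenthesized dialect
#' (`"N(1)H(1)A(1)"`) are accepted; token order is free on input and
#' canonicalized (N, H, A, G, F) on output. Repeated letters are summed.
#'
#' @param text A single glycan-notation string.
#' @return A [GlycanComposition].
#' @export
#' @examples
#' parseGlycan("N1")        # Tn antigen
#' parseGlycan("H(1)N(1)")  # T antigen, canonical text "N1H1"
parseGlycan <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s", "", text)
  s <- gsub("([A-Za-z])\\((\\d+)\\)", "\\1\\2", s)   # N(1) -> N1
  if (!nzchar(s)) stop("empty glycan composition", call. = FALSE)
  m <- gregexpr("[A-Za-z]\\d+", s)[[1]]
  toks <- regmatches(s, gregexpr("[A-Za-z]\\d+", s))[[1]]
  if (m[1] == -1L || paste(toks, collapse = "") != s)
    stop(sprintf("malformed glycan composition \"%s\"", text), call. = FALSE)
  letters_ <- toupper(substr(toks, 1, 1))
  counts <- as.integer(substring(toks, 2))
  unknown <- setdiff(letters_, unname(GLYCAN_CLASSES))
  if (length(unknown))
    stop(sprintf("unknown monosaccharide code \"%s\" in \"%s\" (known: %s)",
                 toks[match(unknown[1], letters_)], text,
                 paste(GLYCAN_CLASSES, collapse = ", ")), call. = FALSE)
  if (any(counts < 1L))
    stop(sprintf("non-positive count in token \"%s\" of \"%s\"",
                 toks[which(counts < 1L)[1]], text), call. = FALSE)
  cts <- setNames(integer(length(GLYCAN_CLASSES)), names(GLYCAN_CLASSES))
  for (i in seq_along(toks)) {
    cls <- names(GLYCAN_CLASSES)[match(letters_[i], GLYCAN_CLASSES)]
    cts[cls] <- cts[cls] + counts[i]
  }
  new("GlycanComposition", counts = cts)
}

#' Canonical text rendering of a glycan composition
#'
#' @param x A [GlycanComposition] or a composition string.
#' @return Canonical composition string (letter+count in fixed N, H, A, G, F
#'   order, zero-count tokens omitted).
#' @export
#' @examples
#' glycanText(parseGlycan("H(1)N(1)"))  # "N1H1"
glycanText <- function(x) {
  if (is.character(x)) x <- parseGlycan(x)
  stopifnot(is(x, "GlycanComposition"))
  cts <- x@counts
  keep <- cts > 0L
  paste0(GLYCAN_CLASSES[keep], cts[keep], collapse = "")
}

#' @describeIn glycanText Vectorized canonicalization of composition strings.
#' @export
canonicalGlycan <- function(x) vapply(x, function(s) glycanText(s), "",
                                      USE.NAMES = FALSE)

#' Does a glycan composition contain a sialic acid?
#'
#' True when the composition includes NeuAc or NeuGc.
#'
#' @param x Character vector of composition strings (any accepted dialect).
#' @return Logical vector.
#' @export
isSialylated <- function(x) {
  vapply(x, function(s) {
    cts <- parseGlycan(s)@counts
    cts[["neuac"]] > 0L || cts[["neugc"]] > 0L
  }, NA, USE.NAMES = FALSE)
}

#' Read / write a glycan composition database
#'
#' The database format is plain text, one composition per line in canonical
#' notation; blank lines and `#` comment lines are ignored. Compositions are
#' canonicalized on read and duplicates are rejected.
#'
#' @param path File path.
#' @return `readGlycanDatabase`: character vector of canonical compositions.
#' @export
readGlycanDatabase <- function(path) {
  stopifnot(file.exists(path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- canonicalGlycan(lines)
  if (anyDuplicated(out))
    stop(sprintf("duplicate composition \"%s\" in %s",
                 out[duplicated(out)][1], path), call. = FALSE)
  out
}

#' @rdname readGlycanDatabase
#' @param compositions Character vector of composition strings.
#' @export
writeGlycanDatabase <- function(compositions, path) {
  writeLines(canonicalGlycan(compositions), path)
  invisible(path)
}
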