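# Declarative protease cleavage-rule engine: site enumeration and
# full / semi-specific / non-specific in-silico digestion.

# Compact cut-spec mini-grammar:
#   "K|"          cleave C-terminal to K                (P1 = {K})
#   "|T"          cleave N-terminal to T                (P1' = {T})
#   "[ST]x|[ST]"  P2 in {S,T}, P1 any, P1' in {S,T}
# "x" (or "X") is the wildcard; bracket classes list allowed residues.
.parse_class <- function(tok) {
  if (tok %in% c("x", "X", "")) return(NULL)
  if (grepl("^\\[[A-Z]+\\]$", tok))
    return(.chars(substr(tok, 2, nchar(tok) - 1L)))
  if (grepl("^[A-Z]$", tok)) return(tok)
  stop(sprintf("cannot parse residue class \"%s\"", tok), call. = FALSE)
}

.class_text <- function(cls) {
  if (is.null(cls)) return("x")
  if (length(cls) == 1L) cls else paste0("[", paste(cls, collapse = ""), "]")
}

#' Parse a compact cleavage-context specification
#'
#' @param text Compact notation such as `"K|"`, `"|T"` or `"[ST]x|[ST]"`.
#' @return A `list(p2 =, p1 =, p1prime =)` cut spec (NULL = wildcard).
#' @export
parseCutSpec <- function(text) {
  s <- gsub("\\s", "", text)
  if (length(gregexpr("|", s, fixed = TRUE)[[1]]) != 1L || !grepl("|", s,
      fixed = TRUE))
    stop(sprintf("cut spec \"%s\" must contain exactly one \"|\"", text),
         call. = FALSE)
  halves <- strsplit(s, "|", fixed = TRUE)[[1]]
  left <- if (length(halves) >= 1L) halves[1] else ""
  right <- if (length(halves) >= 2L) halves[2] else ""
  toks_of <- function(h) {
    if (!nzchar(h)) return(character(0))
    regmatches(h, gregexpr("\\[[A-Z]+\\]|[A-Zx]", h))[[1]]
  }
  lt <- toks_of(left); rt <- toks_of(right)
  if (length(lt) > 2L || length(rt) > 1L)
    stop(sprintf("cut spec \"%s\": at most P2 P1 | P1' supported", text),
         call. = FALSE)
  p1 <- if (length(lt) >= 1L) .parse_class(lt[length(lt)]) else NULL
  p2 <- if (length(lt) == 2L) .parse_class(lt[1]) else NULL
  p1prime <- if (length(rt) == 1L) .parse_class(rt[1]) else NULL
  list(p2 = p2, p1 = p1, p1prime = p1prime)
}

.cutspec_text <- function(cs) {
  left <- paste0(if (is.null(cs$p2)) "" else .class_text(cs$p2),
                 if (is.null(cs$p1) && is.null(cs$p2)) "" else
                   .class_text(cs$p1))
  right <- if (is.null(cs$p1prime)) "" else .class_text(cs$p1prime)
  paste0(left, "|", right)
}

#' Construct a protease rule
#'
#' @param name Rule name.
#' @param cutSpecs Character vector in compact notation (see
#'   [parseCutSpec()]) or a list of parsed cut specs.
#' @param specificity `"full"`, `"semi"` or `"nonspecific"`.
#' @param minLength,maxLength Default length bounds.
#' @param maxMissed Default missed-cleavage budget.
#' @return A [ProteaseRule].
#' @export
ProteaseRule <- function(name, cutSpecs = list(), specificity = "full",
                         minLength = 5L, maxLength = 60L, maxMissed = 3L) {
  if (is.character(cutSpecs)) cutSpecs <- lapply(cutSpecs, parseCutSpec)
  new("ProteaseRule", name = name, cutSpecs = cutSpecs,
      specificity = specificity, minLength = as.integer(minLength),
      maxLength = as.integer(maxLength), maxMissed = as.integer(maxMissed))
}

#' Built-in protease rules
#'
#' The shipped registry: Trypsin (`K|`, `R|`, full), Semi-Trypsin (same
#' contexts, semi), Non-Specific (all substrings, lengths 5-60), OgpA and
#' IMPa (`|T`, `|S`: cleavage immediately N-terminal to S/T; the
#' glycan-conditionality of the real enzymes lives in the simulator, the
#' rule engine is sequence-only), StcE (`[ST]x|[ST]`: S/T at P2 and P1'
#' around the cut), and the combined X-Trypsin rules for sequential
#' glycoprotease + trypsin digestions (missed-cleavage budget 12, because
#' every S/T consumes the budget). Rules are editable: load alternatives
#' with [readProteaseRules()].
#'
#' @return `proteaseRules()`: named list of [ProteaseRule] objects.
#' @export
#' @examples
#' names(proteaseRules())
#' getProtease("StcE")
proteaseRules <- function() {
  tryp <- c("K|", "R|")
  glyco <- c("|T", "|S")
  list(
    Trypsin = ProteaseRule("Trypsin", tryp, "full"),
    `Semi-Trypsin` = ProteaseRule("Semi-Trypsin", tryp, "semi"),
    `Non-Specific` = ProteaseRule("Non-Specific", list(), "nonspecific",
                                  minLength = 5L, maxLength = 60L,
                                  maxMissed = 0L),
    OgpA = ProteaseRule("OgpA", glyco, "full"),
    IMPa = ProteaseRule("IMPa", glyco, "full"),
    StcE = ProteaseRule("StcE", "[ST]x|[ST]", "full"),
    `OgpA-Trypsin` = ProteaseRule("OgpA-Trypsin", c(glyco, tryp), "full",
                                  maxMissed = 12L),
    `IMPa-Trypsin` = ProteaseRule("IMPa-Trypsin", c(glyco, tryp), "full",
                                  maxMissed = 12L),
    `StcE-Trypsin` = ProteaseRule("StcE-Trypsin", c("[ST]x|[ST]", tryp),
                                  "full", maxMissed = 12L))
}

#' @rdname proteaseRules
#' @param name Rule name.
#' @export
getProtease <- function(name) {
  rules <- proteaseRules()
  if (!name %in% names(rules))
    stop(sprintf("unknown protease rule \"%s\"; available: %s", name,
                 paste(names(rules), collapse = ", ")), call. = FALSE)
  rules[[name]]
}

#' Combine protease rules for sequential digestion
#'
#' The combined rule is the union of the component cleavage contexts; the
#' missed-cleavage budget counts all internal sites of the union.
#'
#' @param a,b [ProteaseRule] objects.
#' @param name Name for the combined rule (default `"a-b"`).
#' @param maxMissed Missed-cleavage budget for the combined rule.
#' @return A [ProteaseRule].
#' @export
combineRules <- function(a, b, name = paste(a@name, b@name, sep = "-"),
                         maxMissed = 12L) {
  stopifnot(is(a, "ProteaseRule"), is(b, "ProteaseRule"))
  ProteaseRule(name, cutSpecs = c(a@cutSpecs, b@cutSpecs),
               specificity = "full",
               minLength = min(a@minLength, b@minLength),
               maxLength = max(a@maxLength, b@maxLength),
               maxMissed = maxMissed)
}

#' Enumerate cleavage sites of a rule on a sequence
#'
#' Site `i` denotes the inter-residue bond between residues `i` and `i + 1`
#' (1-based). A site is included when some cleavage context matches: residue
#' `i` in the P1 class, residue `i + 1` in the P1' class, and (for a
#' non-wildcard P2 class) `i >= 2` with residue `i - 1` in the P2 class.
#'
#' @param sequence Uppercase amino-acid string.
#' @param rule A [ProteaseRule] or rule name.
#' @return Sorted integer vector of sites in `1 .. nchar(sequence) - 1`.
#' @export
#' @examples
#' enumerateCleavageSites("MKRPEPTIDEK", "Trypsin")  # 2 3
#' enumerateCleavageSites("ATVTSG", "StcE")          # 3
enumerateCleavageSites <- function(sequence, rule) {
  if (is.character(rule)) rule <- getProtease(rule)
  r <- .chars(sequence)
  L <- length(r)
  if (L < 2L || !length(rule@cutSpecs)) return(integer(0))
  i <- seq_len(L - 1L)
  hit <- rep(FALSE, L - 1L)
  for (cs in rule@cutSpecs) {
    m <- rep(TRUE, L - 1L)
    if (!is.null(cs$p1)) m <- m & r[i] %in% cs$p1
    if (!is.null(cs$p1prime)) m <- m & r[i + 1L] %in% cs$p1prime
    if (!is.null(cs$p2)) m <- m & i >= 2L & c("", r)[i] %in% cs$p2
    hit <- hit | m
  }
  which(hit)
}

#' In-silico digestion of a protein sequence
#'
#' Digests one sequence under a rule. With `full` specificity, peptides run
#' between chosen cleavage sites (protein termini are implicit boundaries)
#' and may span up to `missed` internal sites. With `semi` specificity at
#' least one terminus must conform to the rule, with the same internal-site
#' accounting. `nonspecific` enumerates all substrings within the length
#' bounds. With `metPolicy = "variable_cleavage"` and a leading methionine,
#' initiator-Met-clipped variants starting at residue 2 are also generated.
#'
#' @param sequence Uppercase amino-acid string.
#' @param rule A [ProteaseRule] or rule name; rules can be combined first
#'   with [combineRules()].
#' @param missed Missed-cleavage budget (default: the rule's).
#' @param minLength,maxLength Length bounds (default: the rule's).
#' @param metPolicy `"none"` or `"variable_cleavage"`.
#' @return A `data.frame` with columns `start`, `end`, `peptide`, `missed`,
#'   deduplicated and sorted by `(start, end)`.
#' @export
#' @examples
#' digestSequence("MKRPEPTIDEK", "Trypsin", missed = 0,
#'                minLength = 1, maxLength = 60)$peptide
digestSequence <- function(sequence, rule, missed = NULL, minLength = NULL,
                           maxLength = NULL, metPolicy = c("none",
                             "variable_cleavage")) {
  if (is.character(rule)) rule <- getProtease(rule)
  metPolicy <- match.arg(metPolicy)
  missed <- if (is.null(missed)) rule@maxMissed else as.integer(missed)
  minLength <- if (is.null(minLength)) rule@minLength else
    as.integer(minLength)
  maxLength <- if (is.null(maxLength)) rule@maxLength else
    as.integer(maxLength)
  stopifnot(missed >= 0L, minLength >= 1L, maxLength >= minLength)
  L <- nchar(sequence)
  met_variant <- metPolicy == "variable_cleavage" &&
    substr(sequence, 1, 1) == "M"

  if (rule@specificity == "nonspecific") {
    lens <- seq.int(minLength, min(maxLength, L))
    if (!length(lens) || minLength > L) {
      out <- data.frame(start = integer(0), end = integer(0),
                        peptide = character(0), missed = integer(0))
      return(out)
    }
    start <- unlist(lapply(lens, function(l) seq_len(L - l + 1L)))
    end <- unlist(lapply(lens, function(l) seq_len(L - l + 1L) + l - 1L))
    df <- data.frame(start = start, end = end, missed = NA_integer_)
  } else {
    sites <- enumerateCleavageSites(sequence, rule)
    cs <- cumsum(tabulate(sites, nbins = L))      # cs[i] = # sites <= i
    nsites_in <- function(s, e) {                 # sites in [s, e-1]
      (if (length(e)) c(0L, cs)[e] else integer(0)) - c(0L, cs)[s]
    }
    nboundary <- c(0L, sites)
    cboundary <- c(sites, L)
    if (rule@specificity == "full") {
      B <- c(0L, sites, L)
      nb <- length(B)
      js <- rep(seq_len(nb - 1L), each = nb - 1L)
      ks <- rep(2:nb, times = nb - 1L)
      ok <- ks > js & (ks - js - 1L) <= missed
      start <- B[js[ok]] + 1L
      end <- B[ks[ok]]
      df <- data.frame(start = start, end = end,
                       missed = nsites_in(start, end))
      if (met_variant) {
        ext <- df[df$start == 1L & df$end >= 2L, , drop = FALSE]
        if (nrow(ext)) {
          ext$start <- 2L
          ext$missed <- nsites_in(ext$start, ext$end)
          df <- rbind(df, ext[ext$missed <= missed, , drop = FALSE])
        }
      }
    } else {                                      # semi
      start <- rep(seq_len(L), times = L - seq_len(L) + 1L)
      end <- unlist(lapply(seq_len(L), function(s) s:L))
      len <- end - start + 1L
      keep_len <- len >= minLength & len <= maxLength
      start <- start[keep_len]; end <- end[keep_len]
      confN <- (start - 1L) %in% nboundary |
        (met_variant & start == 2L)
      confC <- end %in% cboundary
      m <- nsites_in(start, end)
      ok <- (confN | confC) & m <= missed
      df <- data.frame(start = start[ok], end = end[ok], missed = m[ok])
    }
  }
  len <- df$end - df$start + 1L
  df <- df[len >= minLength & len <= maxLength, , drop = FALSE]
  df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  df$peptide <- if (nrow(df)) substring(sequence, df$start, df$end)
                else character(0)
  rownames(df) <- NULL
  df[c("start", "end", "peptide", "missed")]
}

# ---------------------------------------------------------------------------
# Protease definitions file (TSV): name, contexts (compact notation,
# comma-separated), specificity, min_length, max_length, max_missed.

#' Read / write protease definition files
#'
#' The definitions file is a TSV with columns `name`, `contexts`
#' (comma-separated compact cut specs), `specificity`, `min_length`,
#' `max_length`, `max_missed`. [motifToRule()] emits a candidate definition
#' from a recovered motif, closing the loop from motif discovery back to a
#' defined protease setting.
#'
#' @param path File path.
#' @return `readProteaseRules`: named list of [ProteaseRule] objects.
#' @export
readProteaseRules <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("name", "contexts", "specificity", "min_length", "max_length",
            "max_missed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(paste("protease definitions file missing column(s):",
               paste(miss, collapse = ", ")), call. = FALSE)
  rules <- lapply(seq_len(nrow(df)), function(i) {
    ctx <- trimws(strsplit(df$contexts[i], ",")[[1]])
    ctx <- ctx[nzchar(ctx)]
    ProteaseRule(df$name[i], ctx, df$specificity[i], df$min_length[i],
                 df$max_length[i], df$max_missed[i])
  })
  setNames(rules, df$name)
}

#' @rdname readProteaseRules
#' @param rules A [ProteaseRule] or list of them.
#' @export
writeProteaseRules <- function(rules, path) {
  if (is(rules, "ProteaseRule")) rules <- list(rules)
  df <- do.call(rbind, lapply(rules, function(r)
    data.frame(name = r@name,
               contexts = paste(vapply(r@cutSpecs, .cutspec_text, ""),
                                collapse = ","),
               specificity = r@specificity, min_length = r@minLength,
               max_length = r@maxLength, max_missed = r@maxMissed)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
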