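# Cleavage windows and motif statistics: the sequence logo, the
# percent-glycosylated bars and the glycan composition distributions.

#' Extract P5 -> P5' cleavage windows around non-tryptic termini
#'
#' For `nterm` peptides the peptide's first residue is the P1' alignment
#' point (one `n_aligned` window); for `cterm` peptides the last residue is
#' the P1 alignment point (one `c_aligned` window); `both` peptides yield
#' two windows. Fully tryptic peptides carry no cleavage evidence and are
#' dropped here. Window characters are read from the protein sequence, so
#' context beyond the peptide comes from the protein; positions before
#' residue 1 or past the protein end are gap (`-`) padded. Localized glycans
#' whose protein position (`start + peptide_position - 1`) falls inside the
#' window are tallied at their window position.
#'
#' @param mapped Output of [mapGlycopeptides()].
#' @param proteins Protein database as in [locatePeptide()].
#' @param flank Residues on each side of the cleavage point (>= 1).
#' @return A `data.frame` with one row per window: `window` (string of
#'   length `2 * flank`), `side` (`n_aligned`/`c_aligned`), `accession`,
#'   `cleavage` (protein coordinate of the cut: the bond between `cleavage`
#'   and `cleavage + 1`), `win_start` (protein coordinate of window position
#'   1, possibly < 1), `pep_start`, `pep_end`, `source_file`, `scan`,
#'   `base_sequence` and list columns `sites` (the record's assignments) and
#'   `glycans` (`data.frame(win_pos, glycan)` tallied in this window).
#' @export
extractWindows <- function(mapped, proteins, flank = 5L) {
  flank <- as.integer(flank)
  stopifnot(flank >= 1L)
  seqs <- .protein_seqs(proteins)
  keep <- mapped$category != "fully_tryptic"
  mapped <- mapped[keep, , drop = FALSE]
  one_window <- function(i, side) {
    acc <- mapped$accession[i]
    seq_ <- seqs[[acc]]
    if (is.null(seq_) || is.na(seq_))
      stop(sprintf("inconsistent locus: unknown accession \"%s\"", acc),
           call. = FALSE)
    L <- nchar(seq_)
    s <- mapped$start[i]; e <- mapped$end[i]
    if (s < 1L || e > L)
      stop(sprintf("inconsistent locus %d-%d on %s", s, e, acc),
           call. = FALSE)
    win_start <- if (side == "n_aligned") s - flank else e - flank + 1L
    pos <- win_start + seq_len(2L * flank) - 1L
    chars <- ifelse(pos >= 1L & pos <= L,
                    substring(seq_, pmax(pos, 1L), pmax(pos, 1L)), "-")
    sites <- mapped$sites[[i]]
    gly <- .empty_glycans()
    if (nrow(sites)) {
      ppos <- s + sites$peptide_position - 1L
      inside <- ppos >= win_start & ppos <= win_start + 2L * flank - 1L
      if (any(inside))
        gly <- data.frame(win_pos = ppos[inside] - win_start + 1L,
                          glycan = sites$glycan[inside])
    }
    data.frame(window = paste(chars, collapse = ""), side = side,
               accession = acc,
               cleavage = if (side == "n_aligned") s - 1L else e,
               win_start = win_start, pep_start = s, pep_end = e,
               source_file = mapped$source_file[i], scan = mapped$scan[i],
               base_sequence = mapped$base_sequence[i],
               glycans = I(list(gly)), sites = I(mapped$sites[i]))
  }
  rows <- list()
  for (i in seq_len(nrow(mapped))) {
    cat_ <- mapped$category[i]
    if (cat_ %in% c("nterm", "both"))
      rows[[length(rows) + 1L]] <- one_window(i, "n_aligned")
    if (cat_ %in% c("cterm", "both"))
      rows[[length(rows) + 1L]] <- one_window(i, "c_aligned")
  }
  if (!length(rows))
    return(data.frame(window = character(0), side = character(0),
                      accession = character(0), cleavage = integer(0),
                      win_start = integer(0), pep_start = integer(0),
                      pep_end = integer(0), source_file = character(0),
                      scan = character(0), base_sequence = character(0),
                      glycans = I(list()), sites = I(list())))
  out <- do.call(rbind, rows)
  attr(out, "flank") <- flank
  rownames(out) <- NULL
  out
}

.empty_glycans <- function() {
  data.frame(win_pos = integer(0), glycan = character(0))
}

.window_flank <- function(windows) {
  attr(windows, "flank") %||% (nchar(windows$window[1]) %/% 2L)
}

.position_index <- function(labels, flank) {
  all_labels <- windowPositions(flank)
  idx <- match(labels, all_labels)
  if (anyNA(idx))
    stop(sprintf("unknown window position label(s): %s (expected %s)",
                 paste(labels[is.na(idx)], collapse = ", "),
                 paste(all_labels, collapse = ", ")), call. = FALSE)
  idx
}

# Per-window logical matrix: is window position j inside the mapped peptide?
.in_peptide <- function(windows, flank) {
  pos <- outer(windows$win_start, seq_len(2L * flank) - 1L, `+`)
  pos >= windows$pep_start & pos <= windows$pep_end
}

#' Percent of peptide S/T residues glycosylated, per window position
#'
#' For each window position the numerator counts windows with a localized
#' glycan at that position and the denominator counts windows whose residue
#' at that position is serine or threonine (serine and threonine are summed)
#' AND lies within the identified peptide. Positions contributed only by
#' protein context (or gaps) are excluded from the denominator: site
#' localization evidence cannot exist outside the identified sequence, so
#' counting such residues would understate glycosylation. Positions with a
#' zero denominator report `NA`, never 0 -- absence of S/T is not a claim of
#' 0% glycosylation.
#'
#' @param windows Output of [extractWindows()].
#' @return Named numeric vector of fractions (one per window position).
#' @export
percentGlycosylated <- function(windows) {
  flank <- .window_flank(windows)
  labels <- windowPositions(flank)
  n <- nrow(windows)
  if (!n) return(setNames(rep(NA_real_, 2L * flank), labels))
  chars <- do.call(rbind, strsplit(windows$window, ""))
  st <- chars == "S" | chars == "T"
  denom_mat <- st & .in_peptide(windows, flank)
  num <- integer(2L * flank)
  for (g in windows$glycans)
    if (nrow(g)) {
      p <- unique(g$win_pos)
      num[p] <- num[p] + 1L
    }
  denom <- colSums(denom_mat)
  out <- ifelse(denom > 0L, num / denom, NA_real_)
  setNames(out, labels)
}

#' Glycan composition distribution at selected window positions
#'
#' Counts each canonical composition among the glycans tallied at the
#' requested positions and normalizes to fractions. With `byFile = TRUE`
#' the counts are additionally broken down by source file.
#'
#' @param windows Output of [extractWindows()].
#' @param positions Window position labels (default the P2, P1, P1' pie
#'   positions).
#' @param byFile Add a per-source-file breakdown.
#' @return Named list (by position label) of data frames with columns
#'   `glycan`, `count`, `fraction` (and `source_file` when `byFile`);
#'   zero-row data frame where no glycan was observed.
#' @export
glycanDistribution <- function(windows, positions = c("P2", "P1", "P1'"),
                               byFile = FALSE) {
  flank <- .window_flank(windows)
  idx <- .position_index(positions, flank)
  long <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i) {
    g <- windows$glycans[[i]]
    if (!nrow(g)) return(NULL)
    data.frame(win_pos = g$win_pos, glycan = g$glycan,
               source_file = windows$source_file[i])
  }))
  out <- lapply(idx, function(j) {
    sub <- if (is.null(long)) NULL else long[long$win_pos == j, , drop = FALSE]
    if (is.null(sub) || !nrow(sub)) {
      empty <- data.frame(glycan = character(0), count = integer(0),
                          fraction = numeric(0))
      if (byFile) empty$source_file <- character(0)
      return(empty)
    }
    if (byFile) {
      tab <- as.data.frame(table(glycan = sub$glycan,
                                 source_file = sub$source_file),
                           stringsAsFactors = FALSE)
      tab <- tab[tab$Freq > 0L, , drop = FALSE]
      names(tab)[names(tab) == "Freq"] <- "count"
      tab$fraction <- tab$count / sum(tab$count)
      tab <- tab[order(-tab$count, tab$glycan), c("glycan", "count",
                                                  "fraction", "source_file")]
    } else {
      tt <- table(sub$glycan)
      tab <- data.frame(glycan = names(tt), count = as.integer(tt),
                        fraction = as.integer(tt) / sum(tt))
      tab <- tab[order(-tab$count, tab$glycan), , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab
  })
  setNames(out, positions)
}

#' Sequence-logo matrices: residue frequencies and information content
#'
#' Per window position, residue frequencies are computed over the 20
#' residues among non-gap characters (protein context included, exactly the
#' 10-residue windows a logo renderer consumes), and the information content
#' is `IC = log2(20) - H` with `H` the Shannon entropy in bits. The optional
#' small-sample correction subtracts `e(n) = 19 / (2 ln 2 n)` (clamped at
#' zero), with `n` the non-gap count; it is off by default and the report
#' records which mode was used. All-gap positions report `NA`.
#'
#' @param windows Output of [extractWindows()].
#' @param correction Apply the small-sample correction.
#' @return List with `frequencies` (20 x positions matrix), `ic` (bits),
#'   `nNonGap`, and `heights` (`frequencies` scaled by `ic`, the letter
#'   heights a renderer would draw).
#' @export
computeLogo <- function(windows, correction = FALSE) {
  stopifnot(nrow(windows) >= 1L)
  flank <- .window_flank(windows)
  labels <- windowPositions(flank)
  chars <- do.call(rbind, strsplit(windows$window, ""))
  freq <- matrix(0, nrow = length(AA20), ncol = 2L * flank,
                 dimnames = list(AA20, labels))
  n_nongap <- integer(2L * flank)
  for (j in seq_len(2L * flank)) {
    col <- chars[, j]
    col <- col[col != "-"]
    n_nongap[j] <- length(col)
    if (length(col))
      freq[, j] <- tabulate(factor(col, levels = AA20),
                            nbins = length(AA20)) / length(col)
  }
  ic <- vapply(seq_len(2L * flank), function(j) {
    if (n_nongap[j] == 0L) return(NA_real_)
    f <- freq[, j]; f <- f[f > 0]
    h <- -sum(f * log2(f))
    val <- log2(20) - h
    if (correction) val <- val - 19 / (2 * log(2) * n_nongap[j])
    max(val, 0)
  }, 0)
  list(frequencies = freq, ic = setNames(ic, labels),
       nNonGap = setNames(n_nongap, labels),
       heights = sweep(freq, 2L, ifelse(is.na(ic), 0, ic), `*`))
}

#' Assemble the full motif report
#'
#' Combines the sequence-logo matrices, the per-position percent
#' glycosylated and the glycan distributions at the configured positions
#' into a [MotifReport]. The default counting unit is the identification
#' record (PSM level); `countUnit = "glycopeptide"` first collapses windows
#' to unique glycopeptides (key: base sequence + site assignments + side +
#' locus).
#'
#' @param windows Output of [extractWindows()]; must be non-empty.
#' @param piePositions Positions for the glycan distribution panels.
#' @param correction Small-sample correction for the information content.
#' @param countUnit `"psm"` or `"glycopeptide"`.
#' @return A [MotifReport].
#' @export
buildMotifReport <- function(windows, piePositions = c("P2", "P1", "P1'"),
                             correction = FALSE,
                             countUnit = c("psm", "glycopeptide")) {
  countUnit <- match.arg(countUnit)
  if (!nrow(windows))
    stop("no cleavage windows: cannot build a motif report", call. = FALSE)
  flank <- .window_flank(windows)
  if (countUnit == "glycopeptide") {
    key <- paste(windows$base_sequence,
                 vapply(windows$sites, .format_sites_cell, ""),
                 windows$side, windows$accession, windows$cleavage)
    windows <- windows[!duplicated(key), , drop = FALSE]
    attr(windows, "flank") <- flank
  }
  logo <- computeLogo(windows, correction = correction)
  new("MotifReport", nWindows = nrow(windows), countUnit = countUnit,
      frequencyMatrix = logo$frequencies,
      informationContent = logo$ic, icCorrection = correction,
      pctGlycosylated = percentGlycosylated(windows),
      glycanDistribution = glycanDistribution(windows, piePositions),
      perFileCounts = {
        tt <- table(windows$source_file)
        setNames(as.integer(tt), names(tt))
      })
}

#' Write motif report tables
#'
#' Writes `motif_report.tsv` (one row per window position: label, non-gap
#' count, IC in bits, percent glycosylated or the literal `NA`, top residue,
#' and the 20 residue frequencies) and `glycan_distribution.tsv` (position,
#' composition, count, fraction). Undefined values serialize as `NA`.
#'
#' @param report A [MotifReport].
#' @param dir Output directory (created if absent).
#' @return Paths of the written files, invisibly.
#' @export
writeMotifReport <- function(report, dir) {
  stopifnot(is(report, "MotifReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  freq <- report@frequencyMatrix
  # recover non-gap counts proportionally is not possible; recompute top only
  top <- rownames(freq)[apply(freq, 2, which.max)]
  top[colSums(freq) == 0] <- NA_character_
  main <- data.frame(position = colnames(freq),
                     IC_bits = report@informationContent,
                     pct_glycosylated = report@pctGlycosylated,
                     top_residue = top)
  main <- cbind(main, t(freq))
  f1 <- file.path(dir, "motif_report.tsv")
  write.table(main, f1, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  gd <- report@glycanDistribution
  long <- do.call(rbind, lapply(names(gd), function(p) {
    if (!nrow(gd[[p]])) return(NULL)
    cbind(position = p, gd[[p]])
  }))
  f2 <- file.path(dir, "glycan_distribution.tsv")
  if (is.null(long))
    long <- data.frame(position = character(0), glycan = character(0),
                       count = integer(0), fraction = numeric(0))
  write.table(long, f2, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(c(f1, f2))
}

#' Write the cleavage-window table
#'
#' One row per window: window string, side, accession, cleavage coordinate,
#' and the tallied glycans as `win_pos:composition` pairs.
#'
#' @param windows Output of [extractWindows()].
#' @param path Output TSV path.
#' @export
writeWindows <- function(windows, path) {
  out <- windows[c("window", "side", "accession", "cleavage", "pep_start",
                   "pep_end", "source_file", "scan")]
  out$glycans_at <- vapply(windows$glycans, function(g)
    paste(sprintf("%d:%s", g$win_pos, g$glycan), collapse = ";"), "")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a candidate protease rule from a recovered motif
#'
#' Reads the P2, P1 and P1' frequency columns of a motif report and builds a
#' cleavage context from the smallest residue class reaching the frequency
#' threshold at each position (wildcard when no class of at most
#' `maxClassSize` residues reaches it). This closes the loop from motif
#' discovery back to a defined protease setting.
#'
#' @param report A [MotifReport].
#' @param name Name for the candidate rule.
#' @param threshold Residue-class frequency threshold.
#' @param maxClassSize Largest residue class before falling back to the
#'   wildcard.
#' @return A [ProteaseRule] (full specificity).
#' @export
motifToRule <- function(report, name = "candidate", threshold = 0.9,
                        maxClassSize = 4L) {
  stopifnot(is(report, "MotifReport"))
  freq <- report@frequencyMatrix
  class_at <- function(pos) {
    if (!pos %in% colnames(freq)) return(NULL)
    f <- sort(freq[, pos], decreasing = TRUE)
    f <- f[f > 0]
    k <- which(cumsum(f) >= threshold)[1]
    if (is.na(k) || k > maxClassSize) NULL else names(f)[seq_len(k)]
  }
  spec <- list(p2 = class_at("P2"), p1 = class_at("P1"),
               p1prime = class_at("P1'"))
  if (is.null(spec$p1) && is.null(spec$p1prime))
    stop("motif is unconstrained at P1 and P1'; no rule derivable",
         call. = FALSE)
  ProteaseRule(name, list(spec), "full")
}
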