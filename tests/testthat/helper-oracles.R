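# Independent brute-force oracles and fixture builders shared across tests.
# Oracles deliberately avoid the implementation's code paths.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(len, st_weight = 3) {
  w <- rep(1, 20)
  w[AA %in% c("S", "T")] <- st_weight
  paste(sample(AA, len, replace = TRUE, prob = w), collapse = "")
}

# Exhaustive per-position scan of the cleavage contexts.
oracle_sites <- function(seq, rule) {
  r <- strsplit(seq, "")[[1]]
  L <- length(r)
  out <- integer(0)
  if (L >= 2) for (i in 1:(L - 1)) {
    for (cs in rule@cutSpecs) {
      ok <- TRUE
      if (!is.null(cs$p1) && !(r[i] %in% cs$p1)) ok <- FALSE
      if (ok && !is.null(cs$p1prime) && !(r[i + 1] %in% cs$p1prime))
        ok <- FALSE
      if (ok && !is.null(cs$p2)) ok <- (i >= 2) && (r[i - 1] %in% cs$p2)
      if (ok) { out <- c(out, i); break }
    }
  }
  out
}

# All-substrings digestion oracle: enumerate every substring, test terminus
# conformity and internal-site counts directly.
oracle_digest <- function(seq, rule, missed = rule@maxMissed,
                          minL = rule@minLength, maxL = rule@maxLength,
                          metPolicy = "none") {
  L <- nchar(seq)
  subs <- expand.grid(start = 1:L, end = 1:L)
  subs <- subs[subs$end >= subs$start, , drop = FALSE]
  len <- subs$end - subs$start + 1
  subs <- subs[len >= minL & len <= maxL, , drop = FALSE]
  if (rule@specificity == "nonspecific") {
    keep <- rep(TRUE, nrow(subs))
  } else {
    sites <- oracle_sites(seq, rule)
    met <- metPolicy == "variable_cleavage" && substr(seq, 1, 1) == "M"
    confN <- (subs$start - 1) %in% c(0, sites) | (met & subs$start == 2)
    confC <- subs$end %in% c(sites, L)
    m <- if (length(sites))
      rowSums(outer(subs$start, sites, "<=") &
                outer(subs$end - 1, sites, ">="))
    else rep(0L, nrow(subs))
    keep <- m <= missed &
      if (rule@specificity == "full") confN & confC else confN | confC
  }
  out <- subs[keep, , drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  paste(out$start, out$end)
}

digest_keys <- function(df) paste(df$start, df$end)

# Slice-with-padding window oracle: pad the protein with flank gap
# characters on both sides and take a plain substring.
oracle_window <- function(protein, start, end, side, flank = 5) {
  padded <- paste0(strrep("-", flank), protein, strrep("-", flank))
  if (side == "n_aligned") substr(padded, start, start + 2 * flank - 1)
  else substr(padded, end + 1, end + 2 * flank)
}

# Sliding-window N-sequon oracle.
oracle_nsequon <- function(seq) {
  r <- strsplit(seq, "")[[1]]
  L <- length(r)
  if (L < 3) return(FALSE)
  for (i in 1:(L - 2))
    if (r[i] == "N" && r[i + 1] != "P" && r[i + 2] %in% c("S", "T"))
      return(TRUE)
  FALSE
}

# Row-by-row filter oracle operating on the raw record fields.
oracle_filter_keep <- function(rec, maxQ = 0.01, levels = "Level1",
                               minProb = 0.75, minLen = 5) {
  vapply(seq_len(nrow(rec)), function(i) {
    s <- rec$sites[[i]]
    !rec$is_decoy[i] &&
      rec$q_value[i] < maxQ &&
      rec$localization_level[i] %in% levels &&
      (nrow(s) == 0L || all(s$localization_probability > minProb)) &&
      rec$localization_level[i] != "unmodified" &&
      !oracle_nsequon(rec$base_sequence[i]) &&
      nchar(rec$base_sequence[i]) >= minLen
  }, NA)
}

# Build a GlycoPSMSet row conveniently.
make_psm <- function(base_sequence, sites = NULL, q_value = 0.001,
                     level = "Level1", decoy = FALSE, source_file = "f1",
                     scan = "1", accession = "PROT1") {
  rec <- data.frame(source_file = source_file, scan = scan,
                    base_sequence = base_sequence,
                    protein_accession = accession, is_decoy = decoy,
                    q_value = q_value, localization_level = level)
  rec$sites <- list(if (is.null(sites))
    data.frame(peptide_position = integer(0), glycan = character(0),
               localization_probability = numeric(0)) else sites)
  rec
}

make_sites <- function(pos, glycan = "N1H1", prob = 0.95) {
  data.frame(peptide_position = as.integer(pos),
             glycan = rep_len(glycan, length(pos)),
             localization_probability = rep_len(prob, length(pos)))
}

psm_set <- function(...) GlycoPSMSet(do.call(rbind, list(...)))

models_to_proteins <- function(models) {
  stats::setNames(vapply(models, function(m) m@sequence, ""),
                  vapply(models, function(m) m@accession, ""))
}

# Run the post-read pipeline stages on an in-memory PSM set.
recover_windows <- function(psms, proteins, filter = FilterConfig()) {
  filt <- filterIdentifications(psms, filter, verbose = FALSE)
  mapped <- mapGlycopeptides(filt, proteins, verbose = FALSE)
  extractWindows(mapped, proteins)
}
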