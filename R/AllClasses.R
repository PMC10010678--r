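# S4 class definitions, validity methods, show methods and accessors.

#' @import methods
#' @importFrom stats setNames runif rbinom
#' @importFrom utils read.delim write.table head
NULL

GLYCAN_CLASSES <- c(hexnac = "N", hex = "H", neuac = "A", neugc = "G",
                    fuc = "F")

# ---------------------------------------------------------------------------
# GlycanComposition

#' GlycanComposition: monosaccharide-class counts of one O-glycan
#'
#' An O-glycan composition in the five-class letter code used for O-glycan
#' databases: N = HexNAc, H = Hex, A = NeuAc, G = NeuGc, F = Fucose.
#' Structural isomers are not distinguished. The canonical text rendering is
#' letter+count tokens in fixed order N, H, A, G, F with zero-count tokens
#' omitted, e.g. `"N1H1A1"`.
#'
#' @slot counts Named non-negative integer vector
#'   (`hexnac`, `hex`, `neuac`, `neugc`, `fuc`); total must be >= 1.
#' @seealso [parseGlycan()], [glycanText()]
#' @export
setClass("GlycanComposition", representation(counts = "integer"))

setValidity("GlycanComposition", function(object) {
  cts <- object@counts
  if (!identical(names(cts), names(GLYCAN_CLASSES)))
    return("counts must be named hexnac, hex, neuac, neugc, fuc")
  if (anyNA(cts) || any(cts < 0L))
    return("all counts must be non-negative integers")
  if (sum(cts) < 1L)
    return("an O-glycan has at least one monosaccharide")
  TRUE
})

#' @describeIn GlycanComposition Construct from per-class counts.
#' @param hexnac,hex,neuac,neugc,fuc Non-negative integer counts.
#' @export
GlycanComposition <- function(hexnac = 0L, hex = 0L, neuac = 0L, neugc = 0L,
                              fuc = 0L) {
  new("GlycanComposition",
      counts = setNames(as.integer(c(hexnac, hex, neuac, neugc, fuc)),
                        names(GLYCAN_CLASSES)))
}

#' @describeIn GlycanComposition Per-class counts accessor.
#' @param x A `GlycanComposition`.
#' @export
glycanCounts <- function(x) {
  stopifnot(is(x, "GlycanComposition"))
  x@counts
}

setMethod("show", "GlycanComposition", function(object) {
  cat("GlycanComposition:", glycanText(object),
      sprintf("(%d monosaccharides)\n", sum(object@counts)))
})

# ---------------------------------------------------------------------------
# GlycoPSMSet

#' GlycoPSMSet: a set of glycopeptide-spectrum matches
#'
#' Container for glycopeptide identification records in the canonical
#' internal schema. Each record carries the spectrum provenance
#' (`source_file`, `scan`), the peptide `base_sequence`, the matched
#' `protein_accession`, the target/decoy flag, the identification `q_value`,
#' the site-localization level (`Level1`, `Level1b`, `Level2`, `Level3` or
#' `unmodified`), and a list of site assignments. A site assignment is a
#' `data.frame` with columns `peptide_position` (1-based within the peptide),
#' `glycan` (canonical composition text) and `localization_probability`.
#'
#' @slot records A `data.frame` with one row per identification and a list
#'   column `sites` of site-assignment data frames.
#' @seealso [readPSMTable()], [filterIdentifications()]
#' @export
setClass("GlycoPSMSet", representation(records = "data.frame"))

PSM_COLUMNS <- c("source_file", "scan", "base_sequence", "protein_accession",
                 "is_decoy", "q_value", "localization_level", "sites")

setValidity("GlycoPSMSet", function(object) {
  rec <- object@records
  miss <- setdiff(PSM_COLUMNS, names(rec))
  if (length(miss))
    return(paste("missing record columns:", paste(miss, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  if (!is.logical(rec$is_decoy)) return("is_decoy must be logical")
  if (!is.numeric(rec$q_value) || anyNA(rec$q_value) ||
      any(rec$q_value < 0 | rec$q_value > 1))
    return("q_value must lie in [0, 1]")
  if (!all(rec$localization_level %in% LOCALIZATION_LEVELS))
    return(paste("localization_level must be one of:",
                 paste(LOCALIZATION_LEVELS, collapse = ", ")))
  if (!all(grepl(paste0("^[", paste(AA20, collapse = ""), "]+$"),
                 rec$base_sequence)))
    return("base_sequence must use the 20-residue uppercase alphabet")
  for (i in seq_len(nrow(rec))) {
    s <- rec$sites[[i]]
    unmod <- identical(rec$localization_level[i], "unmodified")
    if (unmod && nrow(s) > 0L)
      return(sprintf("record %d: unmodified records must carry no sites", i))
    if (!unmod && nrow(s) == 0L)
      return(sprintf("record %d: glyco records must carry >= 1 site", i))
    if (nrow(s) == 0L) next
    if (anyDuplicated(s$peptide_position))
      return(sprintf("record %d: duplicate site positions", i))
    len <- nchar(rec$base_sequence[i])
    if (any(s$peptide_position < 1L | s$peptide_position > len))
      return(sprintf("record %d: site position outside the peptide", i))
    res <- substring(rec$base_sequence[i], s$peptide_position,
                     s$peptide_position)
    if (!all(res %in% c("S", "T")))
      return(sprintf("record %d: site residue must be S or T", i))
    if (any(s$localization_probability < 0 | s$localization_probability > 1))
      return(sprintf("record %d: localization probability outside [0, 1]", i))
  }
  TRUE
})

.empty_sites <- function() {
  data.frame(peptide_position = integer(0), glycan = character(0),
             localization_probability = numeric(0))
}

#' @describeIn GlycoPSMSet Construct from a records data frame (list column
#'   `sites`; missing `sites` entries are replaced by empty assignments).
#' @param records A `data.frame` with the canonical columns.
#' @export
GlycoPSMSet <- function(records = NULL) {
  if (is.null(records)) {
    records <- data.frame(source_file = character(0), scan = character(0),
                          base_sequence = character(0),
                          protein_accession = character(0),
                          is_decoy = logical(0), q_value = numeric(0),
                          localization_level = character(0))
    records$sites <- list()
  }
  if (is.null(records$sites))
    records$sites <- replicate(nrow(records), .empty_sites(), simplify = FALSE)
  rownames(records) <- NULL
  new("GlycoPSMSet", records = records)
}

#' @describeIn GlycoPSMSet Records accessor (data frame, one row per PSM).
#' @export
psmRecords <- function(x) {
  stopifnot(is(x, "GlycoPSMSet"))
  x@records
}

setMethod("length", "GlycoPSMSet", function(x) nrow(x@records))

setMethod("show", "GlycoPSMSet", function(object) {
  rec <- object@records
  nglyco <- sum(rec$localization_level != "unmodified")
  cat(sprintf("GlycoPSMSet with %d record(s): %d glyco, %d decoy, %d file(s)\n",
              nrow(rec), nglyco, sum(rec$is_decoy),
              length(unique(rec$source_file))))
  if (nrow(rec))
    cat(sprintf("  q-value range: [%.4g, %.4g]\n",
                min(rec$q_value), max(rec$q_value)))
})

# ---------------------------------------------------------------------------
# FilterConfig

#' FilterConfig: identification-quality filter thresholds
#'
#' Thresholds for reducing a [GlycoPSMSet] to the high-confidence glycoPSM
#' set used for motif generation. Defaults follow standard practice for
#' site-localized O-glycoproteomics: q-value strictly below 0.01, Level 1
#' localization only, every site localization probability strictly above
#' 0.75, targets only, N-sequon-containing peptides excluded, and a minimum
#' peptide length of 5 residues. Unmodified records are always dropped from
#' the glyco set.
#'
#' @slot maxQ Retain records with `q_value < maxQ` (strict).
#' @slot allowedLevels Localization levels retained.
#' @slot minSiteProbability Every site must have probability strictly above
#'   this value.
#' @slot excludeNSequon Drop peptides containing N-X-S/T with X != P.
#' @slot minPeptideLength Minimum peptide length retained.
#' @slot targetsOnly Drop decoy records.
#' @export
setClass("FilterConfig",
         representation(maxQ = "numeric", allowedLevels = "character",
                        minSiteProbability = "numeric",
                        excludeNSequon = "logical",
                        minPeptideLength = "integer",
                        targetsOnly = "logical"))

setValidity("FilterConfig", function(object) {
  if (object@maxQ <= 0 || object@maxQ > 1) return("0 < maxQ <= 1 required")
  if (object@minSiteProbability < 0 || object@minSiteProbability > 1)
    return("minSiteProbability must lie in [0, 1]")
  if (!all(object@allowedLevels %in% setdiff(LOCALIZATION_LEVELS,
                                             "unmodified")))
    return("allowedLevels must be glyco localization levels")
  TRUE
})

#' @describeIn FilterConfig Constructor with the standard defaults.
#' @param maxQ,allowedLevels,minSiteProbability,excludeNSequon,
#'   minPeptideLength,targetsOnly See slot documentation.
#' @export
FilterConfig <- function(maxQ = 0.01, allowedLevels = "Level1",
                         minSiteProbability = 0.75, excludeNSequon = TRUE,
                         minPeptideLength = 5L, targetsOnly = TRUE) {
  new("FilterConfig", maxQ = maxQ, allowedLevels = allowedLevels,
      minSiteProbability = minSiteProbability,
      excludeNSequon = excludeNSequon,
      minPeptideLength = as.integer(minPeptideLength),
      targetsOnly = targetsOnly)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig:\n",
      sprintf("  q-value < %g; levels {%s}; site probability > %g\n",
              object@maxQ, paste(object@allowedLevels, collapse = ", "),
              object@minSiteProbability),
      sprintf("  N-sequon excluded: %s; min length %d; targets only: %s\n",
              object@excludeNSequon, object@minPeptideLength,
              object@targetsOnly))
})

# ---------------------------------------------------------------------------
# ProteaseRule

#' ProteaseRule: declarative protease cleavage specification
#'
#' A cleavage rule is a set of cleavage-context specifications, each giving
#' residue classes for the P2, P1 and P1' positions around the scissile bond
#' (cleavage between P1 and P1'); `NULL` means wildcard. Specificity `full`
#' requires both peptide termini to conform, `semi` at least one, and
#' `nonspecific` enumerates all substrings within the length bounds. Length
#' bounds and missed-cleavage budgets stored on the rule are defaults that
#' [digestSequence()] can override.
#'
#' In the compact notation of the protease definitions file, `"K|"` cleaves
#' C-terminal to K, `"|T"` cleaves N-terminal to T, and `"[ST]x|[ST]"`
#' requires S/T at P2, any residue at P1 and S/T at P1'.
#'
#' @slot name Rule name.
#' @slot cutSpecs List of `list(p2 =, p1 =, p1prime =)` residue-class
#'   character vectors (or `NULL` for wildcard).
#' @slot specificity One of `"full"`, `"semi"`, `"nonspecific"`.
#' @slot minLength,maxLength Default peptide length bounds.
#' @slot maxMissed Default missed-cleavage budget.
#' @seealso [proteaseRules()], [digestSequence()],
#'   [enumerateCleavageSites()]
#' @export
setClass("ProteaseRule",
         representation(name = "character", cutSpecs = "list",
                        specificity = "character", minLength = "integer",
                        maxLength = "integer", maxMissed = "integer"))

setValidity("ProteaseRule", function(object) {
  if (!object@specificity %in% c("full", "semi", "nonspecific"))
    return("specificity must be full, semi or nonspecific")
  if (object@minLength < 1L) return("minLength >= 1 required")
  if (object@maxLength < object@minLength)
    return("maxLength >= minLength required")
  if (object@maxMissed < 0L) return("maxMissed >= 0 required")
  if (object@specificity != "nonspecific") {
    if (!length(object@cutSpecs))
      return("a specific rule needs at least one cleavage context")
    for (cs in object@cutSpecs) {
      if (!all(c("p2", "p1", "p1prime") %in% names(cs)))
        return("each cut spec needs p2, p1 and p1prime entries")
      if (is.null(cs$p1) && is.null(cs$p1prime))
        return("at least one of p1/p1prime must be non-wildcard")
      for (cls in cs[c("p2", "p1", "p1prime")])
        if (!is.null(cls) && !all(cls %in% AA20))
          return("residue classes must use the 20-residue alphabet")
    }
  }
  TRUE
})

setMethod("show", "ProteaseRule", function(object) {
  cat(sprintf("ProteaseRule \"%s\" (%s)\n", object@name, object@specificity))
  if (length(object@cutSpecs))
    cat("  contexts:", paste(vapply(object@cutSpecs, .cutspec_text, ""),
                             collapse = ", "), "\n")
  cat(sprintf("  defaults: length %d-%d, %d missed cleavage(s)\n",
              object@minLength, object@maxLength, object@maxMissed))
})

# ---------------------------------------------------------------------------
# MotifReport

#' MotifReport: the three-panel cleavage-motif summary
#'
#' Aggregated motif statistics over a set of cleavage windows: per-position
#' residue frequencies and information content (the sequence logo), the
#' percent of peptide S/T residues observed glycosylated at each position,
#' and the glycan composition distribution at selected positions.
#'
#' @slot nWindows Number of windows summarised.
#' @slot countUnit `"psm"` (identification-level tallies) or
#'   `"glycopeptide"` (unique glycopeptide collapse).
#' @slot frequencyMatrix 20 x positions residue frequency matrix (gaps
#'   excluded from the denominators).
#' @slot informationContent Per-position information content in bits
#'   (`log2(20) - H`), `NA` where a position is all-gap.
#' @slot icCorrection Whether the small-sample correction was applied.
#' @slot pctGlycosylated Per-position fraction of in-peptide S/T residues
#'   carrying a localized glycan; `NA` where no S/T was observed.
#' @slot glycanDistribution Named list (by position label) of data frames
#'   with columns `glycan`, `count`, `fraction`.
#' @slot perFileCounts Named integer vector of window counts per source file.
#' @seealso [buildMotifReport()], [writeMotifReport()]
#' @export
setClass("MotifReport",
         representation(nWindows = "integer", countUnit = "character",
                        frequencyMatrix = "matrix",
                        informationContent = "numeric",
                        icCorrection = "logical",
                        pctGlycosylated = "numeric",
                        glycanDistribution = "list",
                        perFileCounts = "integer"))

#' @describeIn MotifReport Number of windows.
#' @param x A `MotifReport`.
#' @export
nWindows <- function(x) { stopifnot(is(x, "MotifReport")); x@nWindows }

#' @describeIn MotifReport Residue frequency matrix.
#' @export
frequencyMatrix <- function(x) {
  stopifnot(is(x, "MotifReport")); x@frequencyMatrix
}

#' @describeIn MotifReport Per-position information content (bits).
#' @export
informationContent <- function(x) {
  stopifnot(is(x, "MotifReport")); x@informationContent
}

#' @describeIn MotifReport Per-position percent glycosylated (fractions).
#' @export
pctGlycosylated <- function(x) {
  stopifnot(is(x, "MotifReport")); x@pctGlycosylated
}

setMethod("show", "MotifReport", function(object) {
  cat(sprintf("MotifReport over %d window(s) [%s-level]\n", object@nWindows,
              object@countUnit))
  pos <- colnames(object@frequencyMatrix)
  top <- rownames(object@frequencyMatrix)[
    apply(object@frequencyMatrix, 2, which.max)]
  cat("  position :", format(pos, width = 5), "\n")
  cat("  top res  :", format(top, width = 5), "\n")
  cat("  IC (bits):", format(round(object@informationContent, 2),
                             width = 5), "\n")
  cat("  %glyco   :", format(ifelse(is.na(object@pctGlycosylated), "NA",
                                    round(100 * object@pctGlycosylated)),
                             width = 5), "\n")
})

# ---------------------------------------------------------------------------
# GlycoproteinModel

#' GlycoproteinModel: a protein with stochastic O-glycosylation
#'
#' Describes one glycoprotein for simulation: the backbone sequence, the
#' per-site probability that each S/T residue is occupied by an O-glycan,
#' and a weighted menu of glycan compositions sampled for occupied sites.
#'
#' @slot accession Protein identifier.
#' @slot sequence Amino-acid sequence (20-letter alphabet).
#' @slot occupancy Named numeric vector: names are S/T residue positions,
#'   values are occupancy probabilities in `[0, 1]`.
#' @slot glycanMenu Named numeric vector of positive sampling weights, names
#'   are canonical glycan composition strings; normalized internally.
#' @seealso [simulateGlycoforms()], [randomGlycoproteins()]
#' @export
setClass("GlycoproteinModel",
         representation(accession = "character", sequence = "character",
                        occupancy = "numeric", glycanMenu = "numeric"))

setValidity("GlycoproteinModel", function(object) {
  .assert_aa(object@sequence, "protein sequence")
  pos <- as.integer(names(object@occupancy))
  if (anyNA(pos)) return("occupancy must be named by residue position")
  res <- substring(object@sequence, pos, pos)
  if (!all(res %in% c("S", "T")))
    return("occupancy keys must address S/T residues")
  if (any(object@occupancy < 0 | object@occupancy > 1))
    return("occupancy probabilities must lie in [0, 1]")
  if (!length(object@glycanMenu) || any(object@glycanMenu <= 0))
    return("glycanMenu weights must be positive")
  TRUE
})

#' @describeIn GlycoproteinModel Constructor. A scalar `occupancy` is
#'   expanded to every S/T residue of the sequence.
#' @param accession,sequence,occupancy,glycanMenu See slot documentation.
#' @export
GlycoproteinModel <- function(accession, sequence, occupancy = 0.5,
                              glycanMenu = c(N1 = 0.3, N1H1 = 0.7)) {
  if (is.null(names(occupancy))) {
    stopifnot(length(occupancy) == 1L)
    st <- which(.chars(sequence) %in% c("S", "T"))
    occupancy <- setNames(rep(occupancy, length(st)), st)
  }
  names(glycanMenu) <- vapply(names(glycanMenu), canonicalGlycan, "")
  new("GlycoproteinModel", accession = accession, sequence = sequence,
      occupancy = occupancy, glycanMenu = glycanMenu / sum(glycanMenu))
}

setMethod("show", "GlycoproteinModel", function(object) {
  cat(sprintf("GlycoproteinModel %s: %d aa, %d potential glycosite(s)\n",
              object@accession, nchar(object@sequence),
              length(object@occupancy)))
  cat("  glycan menu:",
      paste(sprintf("%s (%.2f)", names(object@glycanMenu),
                    object@glycanMenu), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SimulationConfig

#' SimulationConfig: glycan-conditional proteolysis simulation settings
#'
#' Parameters for simulating an O-glycoprotease digestion followed by an
#' optional complete trypsin stage, and for emitting a noisy identification
#' table. Cleavage is sequence-gated by the named protease rule and
#' glycan-gated by the occupancy of the conditioning residue (P1' for
#' OgpA/IMPa-style enzymes, P2 for StcE-style); each candidate site is cut
#' independently with probability `efficiency`, multiplied by
#' `sialylationMultiplier` when the conditioning glycan contains a sialic
#' acid (NeuAc or NeuGc). For P1'-conditioned enzymes the default also
#' requires the P1 residue to be un-glycosylated, mirroring the known OgpA
#' motif.
#'
#' @slot protease Name of a built-in glycoprotease rule (`"OgpA"`, `"IMPa"`
#'   or `"StcE"`).
#' @slot efficiency Per-site cleavage probability in `[0, 1]`.
#' @slot sialylationMultiplier Efficiency multiplier in `[0, 1]` applied when
#'   the conditioning glycan is sialylated.
#' @slot requireUnmodifiedP1 Require an un-glycosylated P1 residue for
#'   P1'-conditioned cleavage.
#' @slot trypsinStage Apply trypsin after the glycoprotease.
#' @slot trypsinMiss Probability that an individual tryptic site is missed
#'   (0 = complete digestion).
#' @slot nPSMs Number of identification records sampled (with replacement)
#'   from the simulated fragments; 0 emits one record per fragment.
#' @slot falseLocalizationRate Fraction of glyco records whose glycan is
#'   moved to another S/T and whose localization is downgraded below the
#'   filter threshold.
#' @slot decoyFraction Fraction of records converted to reversed-sequence
#'   decoys.
#' @slot qAboveFraction Fraction of records drawn with a q-value at or above
#'   0.01 (to exercise the q-value filter).
#' @slot minLength,maxLength Fragment length bounds retained for the table.
#' @slot seed Integer seed; all randomness flows from it.
#' @seealso [simulateDataset()], [simulateDigest()]
#' @export
setClass("SimulationConfig",
         representation(protease = "character", efficiency = "numeric",
                        sialylationMultiplier = "numeric",
                        requireUnmodifiedP1 = "logical",
                        trypsinStage = "logical", trypsinMiss = "numeric",
                        nPSMs = "integer", falseLocalizationRate = "numeric",
                        decoyFraction = "numeric", qAboveFraction = "numeric",
                        minLength = "integer", maxLength = "integer",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  probs <- c(object@efficiency, object@sialylationMultiplier,
             object@trypsinMiss, object@falseLocalizationRate,
             object@decoyFraction, object@qAboveFraction)
  if (any(probs < 0 | probs > 1))
    return("all probabilities must lie in [0, 1]")
  if (object@nPSMs < 0L) return("nPSMs must be >= 0")
  if (object@minLength < 1L || object@maxLength < object@minLength)
    return("invalid length bounds")
  TRUE
})

#' @describeIn SimulationConfig Constructor with documented defaults.
#' @param protease,efficiency,sialylationMultiplier,requireUnmodifiedP1,
#'   trypsinStage,trypsinMiss,nPSMs,falseLocalizationRate,decoyFraction,
#'   qAboveFraction,minLength,maxLength,seed See slot documentation.
#' @export
SimulationConfig <- function(protease = "OgpA", efficiency = 0.9,
                             sialylationMultiplier = 1,
                             requireUnmodifiedP1 = NA,
                             trypsinStage = TRUE, trypsinMiss = 0,
                             nPSMs = 1000L, falseLocalizationRate = 0,
                             decoyFraction = 0, qAboveFraction = 0,
                             minLength = 5L, maxLength = 60L, seed = 1L) {
  if (is.na(requireUnmodifiedP1))
    requireUnmodifiedP1 <- .condition_position(protease) == "P1prime"
  new("SimulationConfig", protease = protease, efficiency = efficiency,
      sialylationMultiplier = sialylationMultiplier,
      requireUnmodifiedP1 = requireUnmodifiedP1,
      trypsinStage = trypsinStage, trypsinMiss = trypsinMiss,
      nPSMs = as.integer(nPSMs),
      falseLocalizationRate = falseLocalizationRate,
      decoyFraction = decoyFraction, qAboveFraction = qAboveFraction,
      minLength = as.integer(minLength), maxLength = as.integer(maxLength),
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %s-style cleavage, efficiency %.2f, sialylation x%.2f\n",
              object@protease, object@efficiency,
              object@sialylationMultiplier))
  cat(sprintf("  trypsin stage: %s (miss %.2f); nPSMs %d; seed %d\n",
              object@trypsinStage, object@trypsinMiss, object@nPSMs,
              object@seed))
  cat(sprintf("  noise: false localization %.2f, decoys %.2f, q >= 0.01 fraction %.2f\n",
              object@falseLocalizationRate, object@decoyFraction,
              object@qAboveFraction))
})
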