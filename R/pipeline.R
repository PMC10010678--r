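# Pipeline runners tying the stages together: read -> filter -> map ->
# window -> report, plus digestion and simulation entry points.

#' Run the motif-discovery pipeline
#'
#' Executes the full chain on one or more identification tables: read,
#' quality-filter, map onto the protein database, classify termini, extract
#' P5 -> P5' cleavage windows and assemble the motif report. When an output
#' directory is given, writes `motif_report.tsv`,
#' `glycan_distribution.tsv`, `windows.tsv`, `mapped_peptides.tsv`, a
#' candidate protease definition derived from the motif
#' (`candidate_protease.tsv`, where derivable) and a run manifest
#' (`manifest.json`) echoing the configuration, a hash of the inputs and
#' per-stage record counts, so every report is auditable against its
#' configuration.
#'
#' An empty post-filter set or a window set emptied by the fully-tryptic
#' drop raises a "no cleavage evidence" error rather than returning an
#' empty report.
#'
#' @param psmFiles Character vector of identification-table paths.
#' @param fastaFile Protein FASTA path (the database used in the search).
#' @param outDir Optional output directory.
#' @param columnMap Column map for the tables (see [canonicalColumnMap()]).
#' @param filter A [FilterConfig].
#' @param ambiguousPolicy,metPolicy,prolineSuppression Passed to
#'   [mapGlycopeptides()].
#' @param flank Window half-width.
#' @param piePositions Glycan-distribution positions.
#' @param correction Small-sample information-content correction.
#' @param countUnit `"psm"` or `"glycopeptide"`.
#' @param ruleName,ruleThreshold Candidate-rule derivation (see
#'   [motifToRule()]).
#' @param verbose Emit per-stage logs.
#' @return List with `report` ([MotifReport]), `windows`, `mapped`,
#'   `psms` (filtered [GlycoPSMSet]), `counts` (per-stage record counts)
#'   and, when written, `paths`.
#' @export
runMotifPipeline <- function(psmFiles, fastaFile, outDir = NULL,
                             columnMap = canonicalColumnMap(),
                             filter = FilterConfig(),
                             ambiguousPolicy = "drop",
                             metPolicy = "variable_cleavage",
                             prolineSuppression = FALSE, flank = 5L,
                             piePositions = c("P2", "P1", "P1'"),
                             correction = FALSE, countUnit = "psm",
                             ruleName = "candidate", ruleThreshold = 0.9,
                             verbose = TRUE) {
  stopifnot(length(psmFiles) >= 1L)
  proteins <- readProteinFasta(fastaFile)
  sets <- lapply(psmFiles, readPSMTable, columnMap = columnMap)
  rec <- do.call(rbind, lapply(sets, psmRecords))
  psms <- GlycoPSMSet(rec)
  n_read <- length(psms)
  per_file_read <- vapply(sets, length, 0L)
  filtered <- filterIdentifications(psms, filter, verbose = verbose)
  if (length(filtered) == 0L)
    stop("no cleavage evidence: no identifications survive filtering",
         call. = FALSE)
  mapped <- mapGlycopeptides(filtered, proteins,
                             ambiguousPolicy = ambiguousPolicy,
                             metPolicy = metPolicy,
                             prolineSuppression = prolineSuppression,
                             verbose = verbose)
  windows <- extractWindows(mapped, proteins, flank = flank)
  if (nrow(windows) == 0L)
    stop(paste("no cleavage evidence: all mapped peptides are fully",
               "tryptic or unmapped"), call. = FALSE)
  report <- buildMotifReport(windows, piePositions = piePositions,
                             correction = correction, countUnit = countUnit)
  cat_tab <- attr(mapped, "mappingCounts")$by_category
  counts <- list(
    files = length(psmFiles), read = n_read,
    per_file_read = setNames(as.list(per_file_read), basename(psmFiles)),
    filtered = length(filtered),
    mapped = nrow(mapped), by_category = as.list(cat_tab),
    windows = nrow(windows),
    windows_expected = unname(cat_tab[["nterm"]] + cat_tab[["cterm"]] +
                                2L * cat_tab[["both"]]),
    report_windows = nWindows(report))
  out <- list(report = report, windows = windows, mapped = mapped,
              psms = filtered, counts = counts)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    paths <- writeMotifReport(report, outDir)
    paths <- c(paths, file.path(outDir, "windows.tsv"),
               file.path(outDir, "mapped_peptides.tsv"))
    writeWindows(windows, file.path(outDir, "windows.tsv"))
    writeMappedPeptides(mapped, file.path(outDir, "mapped_peptides.tsv"))
    rule <- tryCatch(motifToRule(report, ruleName,
                                 threshold = ruleThreshold),
                     error = function(e) NULL)
    if (!is.null(rule)) {
      writeProteaseRules(rule, file.path(outDir, "candidate_protease.tsv"))
      paths <- c(paths, file.path(outDir, "candidate_protease.tsv"))
    }
    manifest <- list(
      package = "glycoMotif",
      version = as.character(utils::packageVersion("glycoMotif")),
      inputs = list(psm_files = psmFiles, fasta = fastaFile,
                    md5 = as.list(tools::md5sum(c(psmFiles, fastaFile)))),
      config = list(
        filter = list(max_q = filter@maxQ,
                      allowed_levels = filter@allowedLevels,
                      min_site_probability = filter@minSiteProbability,
                      exclude_n_sequon = filter@excludeNSequon,
                      min_peptide_length = filter@minPeptideLength,
                      targets_only = filter@targetsOnly),
        ambiguous_policy = ambiguousPolicy, met_policy = metPolicy,
        proline_suppression = prolineSuppression, flank = flank,
        pie_positions = piePositions, ic_correction = correction,
        count_unit = countUnit, rule_threshold = ruleThreshold),
      counts = counts)
    manifest_path <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$paths <- c(paths, manifest_path)
  }
  out
}

#' Digest a sequence or FASTA database from the command line
#'
#' Thin wrapper over [digestSequence()] accepting either a raw sequence or
#' a FASTA path; unknown rule names raise an error listing the available
#' rules.
#'
#' @param input An amino-acid sequence or a FASTA file path.
#' @param rule Rule name (see [proteaseRules()]) or a [ProteaseRule].
#' @param missed,minLength,maxLength,metPolicy Passed to
#'   [digestSequence()].
#' @param path Optional output TSV path.
#' @return A `data.frame` of peptides (`accession`, `start`, `end`,
#'   `peptide`, `missed`), sorted.
#' @export
runDigest <- function(input, rule = "Trypsin", missed = NULL,
                      minLength = NULL, maxLength = NULL,
                      metPolicy = "none", path = NULL) {
  if (is.character(rule)) rule <- getProtease(rule)
  seqs <- if (length(input) == 1L && file.exists(input))
    .protein_seqs(readProteinFasta(input))
  else setNames(toupper(input),
                if (is.null(names(input))) paste0("seq", seq_along(input))
                else names(input))
  for (s in seqs) .assert_aa(s)
  out <- do.call(rbind, lapply(names(seqs), function(acc) {
    df <- digestSequence(seqs[[acc]], rule, missed = missed,
                         minLength = minLength, maxLength = maxLength,
                         metPolicy = metPolicy)
    if (nrow(df)) cbind(accession = acc, df) else NULL
  }))
  if (is.null(out))
    out <- data.frame(accession = character(0), start = integer(0),
                      end = integer(0), peptide = character(0),
                      missed = integer(0))
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
  out
}

#' Run a simulation and write its outputs
#'
#' @param config A [SimulationConfig].
#' @param models Optional list of [GlycoproteinModel]s; by default five
#'   random ~400-residue glycoproteins with 20% S/T are drawn from the
#'   configuration seed.
#' @param dir Output directory for `psms.tsv`, `ground_truth.tsv` and
#'   `proteins.fasta`.
#' @param nInstances Glycoform instances per model.
#' @param verbose Log a per-category summary.
#' @return The [simulateDataset()] result list.
#' @export
runSimulate <- function(config, models = NULL, dir = NULL,
                        nInstances = 20L, verbose = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(models))
    models <- randomGlycoproteins(seed = config@seed)
  res <- simulateDataset(models, config, nInstances = nInstances, dir = dir)
  if (verbose) {
    rec <- psmRecords(res$psms)
    message(sprintf(
      "runSimulate: %d fragment(s), %d PSM(s) (%d glyco, %d decoy), %d true glyco cut(s)",
      nrow(res$fragments), nrow(rec),
      sum(rec$localization_level != "unmodified"), sum(rec$is_decoy),
      nrow(res$truth)))
  }
  res
}

#' Simulate, recover the motif, and score against ground truth
#'
#' The single-command recovery check: simulates a dataset, runs the motif
#' pipeline on the emitted table, and scores the recovered cleavage
#' windows against the simulated ground truth (the fraction of inferred
#' cleavage coordinates that are true glyco-rule cuts).
#'
#' @param config A [SimulationConfig].
#' @param models As in [runSimulate()].
#' @param outDir Optional directory for both simulation and pipeline
#'   outputs.
#' @param nInstances Glycoform instances per model.
#' @param ... Further arguments to [runMotifPipeline()].
#' @return List with `simulation`, `pipeline`, and `cutPrecision` (fraction
#'   of window cleavage coordinates present in the ground truth).
#' @export
runRecover <- function(config, models = NULL, outDir = NULL,
                       nInstances = 20L, ...) {
  sim_dir <- if (is.null(outDir)) tempfile("glycomotif-sim-") else
    file.path(outDir, "simulation")
  res <- runSimulate(config, models = models, dir = sim_dir,
                     nInstances = nInstances, verbose = FALSE)
  pipe <- runMotifPipeline(res$paths[["psms"]], res$paths[["fasta"]],
                           outDir = if (is.null(outDir)) NULL else
                             file.path(outDir, "motif"),
                           verbose = FALSE, ...)
  truth_keys <- unique(paste(res$truth$accession, res$truth$site))
  win_keys <- paste(pipe$windows$accession, pipe$windows$cleavage)
  precision <- if (length(win_keys)) mean(win_keys %in% truth_keys) else
    NA_real_
  list(simulation = res, pipeline = pipe, cutPrecision = precision)
}
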