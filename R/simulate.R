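# Glycan-conditional proteolysis simulator: synthetic glycoproteins,
# glycoform sampling, digestion, and emission of canonical glycoPSM tables
# with controlled noise.

# Which residue's occupancy licenses a cut for each built-in glycoprotease.
.condition_position <- function(protease) {
  switch(protease,
         OgpA = "P1prime", IMPa = "P1prime", StcE = "P2",
         stop(sprintf("no glycan-conditional model for protease \"%s\"",
                      protease), call. = FALSE))
}

#' Generate random glycoprotein backbones
#'
#' Draws synthetic protein sequences with a controlled serine/threonine
#' density (split evenly between S and T); the remaining mass is uniform
#' over the other 18 residues, so tryptic K/R sites occur at a realistic
#' ~9% rate.
#'
#' @param n Number of proteins.
#' @param length Sequence length of each protein.
#' @param stFraction Combined S+T frequency.
#' @param occupancy,glycanMenu Passed to [GlycoproteinModel()].
#' @param seed Optional integer seed (restored afterwards).
#' @return List of [GlycoproteinModel] objects with accessions
#'   `SYNPROT1..n`.
#' @export
randomGlycoproteins <- function(n = 5L, length = 400L, stFraction = 0.2,
                                occupancy = 0.5,
                                glycanMenu = c(N1 = 0.3, N1H1 = 0.7),
                                seed = NULL) {
  draw <- function() {
    others <- setdiff(AA20, c("S", "T"))
    probs <- c(rep(stFraction / 2, 2), rep((1 - stFraction) /
                                             length(others),
                                           length(others)))
    lapply(seq_len(n), function(i) {
      seq_ <- paste(sample(c("S", "T", others), length, replace = TRUE,
                           prob = probs), collapse = "")
      GlycoproteinModel(paste0("SYNPROT", i), seq_, occupancy, glycanMenu)
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sample glycoform instances of a glycoprotein model
#'
#' Each instance draws site occupancy independently per potential glycosite
#' and assigns occupied sites a composition sampled from the glycan menu.
#' Identical seeds give identical instance lists.
#'
#' @param model A [GlycoproteinModel].
#' @param n Number of instances.
#' @param seed Optional integer seed (restored afterwards; omit when an
#'   outer seed already governs the stream).
#' @return List of instances; each is a `list(accession, sequence, sites)`
#'   with `sites` a `data.frame(pos, glycan)`.
#' @export
simulateGlycoforms <- function(model, n, seed = NULL) {
  stopifnot(is(model, "GlycoproteinModel"), n >= 1L)
  draw <- function() {
    pos <- as.integer(names(model@occupancy))
    menu <- model@glycanMenu
    lapply(seq_len(n), function(i) {
      occ <- runif(length(pos)) < model@occupancy
      k <- sum(occ)
      glycan <- if (k) sample(names(menu), k, replace = TRUE,
                              prob = menu) else character(0)
      list(accession = model@accession, sequence = model@sequence,
           sites = data.frame(pos = pos[occ], glycan = glycan))
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Digest one glycoform instance under a glycan-conditional rule
#'
#' Candidate sites are the sequence-rule sites of the configured
#' glycoprotease whose glycan condition holds on the instance (OgpA/IMPa:
#' occupied S/T at P1', by default with an un-glycosylated P1; StcE:
#' occupied S/T at P2). Each candidate is cut independently with probability
#' `efficiency`, multiplied by the sialylation multiplier when the
#' conditioning glycan contains NeuAc/NeuGc. A uniform draw is consumed for
#' every candidate regardless of outcome, so runs from the same seed are
#' coupled across parameter values (the realized cut set shrinks
#' monotonically as the multiplier decreases). The optional trypsin stage
#' then cleaves K|/R| sites, each retained with probability
#' `1 - trypsinMiss`.
#'
#' @param instance One element of [simulateGlycoforms()] output.
#' @param config A [SimulationConfig].
#' @return A `data.frame` of fragments: `accession`, `start`, `end`,
#'   `peptide`, `nterm_type`, `cterm_type` (`protein`, `glyco` or
#'   `trypsin`), and list column `sites` (carried assignments as
#'   `data.frame(pos, glycan)` in protein coordinates).
#' @export
simulateDigest <- function(instance, config) {
  stopifnot(is(config, "SimulationConfig"))
  seq_ <- instance$sequence
  L <- nchar(seq_)
  rule <- getProtease(config@protease)
  seq_sites <- enumerateCleavageSites(seq_, rule)
  occupied <- instance$sites$pos
  glycan_at <- setNames(instance$sites$glycan, occupied)
  cond_pos <- .condition_position(config@protease)
  cond_res <- if (cond_pos == "P1prime") seq_sites + 1L else seq_sites - 1L
  ok <- cond_res %in% occupied
  if (cond_pos == "P1prime" && config@requireUnmodifiedP1)
    ok <- ok & !(seq_sites %in% occupied)
  candidates <- seq_sites[ok]
  cond_glycan <- glycan_at[as.character(cond_res[ok])]
  p <- rep(config@efficiency, length(candidates))
  if (length(candidates)) {
    sial <- isSialylated(cond_glycan)
    p[sial] <- p[sial] * config@sialylationMultiplier
  }
  u <- runif(length(candidates))         # always drawn: seed coupling
  glyco_cuts <- candidates[u < p]
  tryp_cuts <- integer(0)
  if (config@trypsinStage) {
    tsites <- enumerateCleavageSites(seq_, getProtease("Trypsin"))
    ut <- runif(length(tsites))
    tryp_cuts <- tsites[ut >= config@trypsinMiss]
  }
  bounds <- sort(unique(c(0L, glyco_cuts, tryp_cuts, L)))
  start <- bounds[-length(bounds)] + 1L
  end <- bounds[-1L]
  cut_type <- function(cut) {
    ifelse(cut %in% glyco_cuts, "glyco",
           ifelse(cut %in% tryp_cuts, "trypsin", "protein"))
  }
  frag <- data.frame(accession = instance$accession, start = start,
                     end = end, peptide = substring(seq_, start, end),
                     nterm_type = cut_type(start - 1L),
                     cterm_type = cut_type(end))
  frag$sites <- lapply(seq_len(nrow(frag)), function(i) {
    inside <- occupied >= frag$start[i] & occupied <= frag$end[i]
    data.frame(pos = occupied[inside], glycan = glycan_at[inside],
               row.names = NULL)
  })
  frag
}

.q_draw <- function(n, above_fraction) {
  hi <- runif(n) < above_fraction
  q <- runif(n, 0, 0.0099)
  q[hi] <- runif(sum(hi), 0.01, 0.3)
  q
}

#' Emit a canonical glycoPSM table from simulated fragments
#'
#' Samples identification records (with replacement when `nPSMs > 0`,
#' otherwise one record per fragment) from fragments within the configured
#' length bounds, draws q-values (a configured fraction at or above 0.01),
#' injects reversed-sequence decoys, and applies false-localization noise:
#' affected records have one glycan moved to a random other unoccupied S/T
#' in the peptide and their localization downgraded below the Level 1
#' threshold. Site positions are converted to peptide coordinates; clean
#' records are Level 1 with localization probability 0.95 (or `unmodified`
#' when the fragment carries no glycan).
#'
#' @param fragments Pooled [simulateDigest()] output (rows may come from
#'   several instances/proteins).
#' @param config A [SimulationConfig].
#' @param path Optional output TSV path ([writePSMTable()] format).
#' @param sourceFile Value for the `source_file` column.
#' @return A [GlycoPSMSet] (written to `path` when given).
#' @export
emitPSMTable <- function(fragments, config, path = NULL,
                         sourceFile = "simulated.raw") {
  stopifnot(is(config, "SimulationConfig"))
  len <- nchar(fragments$peptide)
  pool <- fragments[len >= config@minLength & len <= config@maxLength, ,
                    drop = FALSE]
  if (!nrow(pool)) stop("no fragments within length bounds", call. = FALSE)
  idx <- if (config@nPSMs > 0L)
    sample.int(nrow(pool), config@nPSMs, replace = TRUE)
  else seq_len(nrow(pool))
  n <- length(idx)
  q <- .q_draw(n, config@qAboveFraction)
  decoy <- runif(n) < config@decoyFraction
  false_loc <- runif(n) < config@falseLocalizationRate
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    fr <- pool[idx[k], ]
    pep <- fr$peptide
    sites <- fr$sites[[1]]
    pep_pos <- sites$pos - fr$start + 1L
    glycan <- sites$glycan
    prob <- rep(0.95, length(pep_pos))
    level <- if (length(pep_pos)) "Level1" else "unmodified"
    if (false_loc[k] && length(pep_pos)) {
      st_all <- which(.chars(pep) %in% c("S", "T"))
      free <- setdiff(st_all, pep_pos)
      if (length(free)) {
        j <- sample.int(length(pep_pos), 1L)
        pep_pos[j] <- free[sample.int(length(free), 1L)]
        prob[] <- 0.5
        level <- "Level2"
      }
    }
    if (decoy[k]) {
      pep <- .reverse_seq(pep)
      pep_pos <- nchar(pep) - pep_pos + 1L
    }
    ord <- order(pep_pos)
    rows[[k]] <- data.frame(
      source_file = sourceFile, scan = as.character(k),
      base_sequence = pep,
      protein_accession = if (decoy[k]) paste0("DECOY_", fr$accession)
                          else fr$accession,
      is_decoy = decoy[k], q_value = q[k], localization_level = level)
    rows[[k]]$sites <- list(data.frame(
      peptide_position = pep_pos[ord], glycan = glycan[ord],
      localization_probability = prob[ord], row.names = NULL))
  }
  rec <- do.call(rbind, rows)
  out <- GlycoPSMSet(rec)
  if (!is.null(path)) writePSMTable(out, path)
  out
}

#' Run the whole simulation: glycoforms, digestion, table emission
#'
#' Draws `nInstances` glycoform instances per model, digests each under the
#' configured glycan-conditional rule, pools the fragments and emits the
#' identification table plus a ground-truth record of realized
#' glyco-cleavage sites and true site assignments. All randomness flows
#' from `config@seed`; identical configurations produce byte-identical
#' output files.
#'
#' @param models List of [GlycoproteinModel] objects (or one model).
#' @param config A [SimulationConfig].
#' @param nInstances Glycoform instances drawn per model.
#' @param dir Optional output directory; when given, writes `psms.tsv`,
#'   `ground_truth.tsv` and `proteins.fasta`.
#' @param sourceFile `source_file` value for the emitted table.
#' @return List with `psms` ([GlycoPSMSet]), `fragments` (pooled
#'   `data.frame`), `truth` (`data.frame` of realized glyco cuts:
#'   `accession`, `instance`, `site`, `conditioning_glycan`), `models`, and
#'   `paths` (when written).
#' @export
simulateDataset <- function(models, config, nInstances = 20L, dir = NULL,
                            sourceFile = "simulated.raw") {
  if (is(models, "GlycoproteinModel")) models <- list(models)
  stopifnot(is(config, "SimulationConfig"))
  run <- function() {
    all_frag <- list()
    truth <- list()
    for (model in models) {
      instances <- simulateGlycoforms(model, nInstances)
      for (ii in seq_along(instances)) {
        frag <- simulateDigest(instances[[ii]], config)
        frag$instance <- ii
        all_frag[[length(all_frag) + 1L]] <- frag
        glyco_cuts <- sort(unique(c(
          frag$start[frag$nterm_type == "glyco"] - 1L,
          frag$end[frag$cterm_type == "glyco"])))
        if (length(glyco_cuts)) {
          cond_pos <- .condition_position(config@protease)
          cond_res <- if (cond_pos == "P1prime") glyco_cuts + 1L
                      else glyco_cuts - 1L
          gl <- setNames(instances[[ii]]$sites$glycan,
                         instances[[ii]]$sites$pos)
          truth[[length(truth) + 1L]] <- data.frame(
            accession = model@accession, instance = ii, site = glyco_cuts,
            conditioning_glycan = unname(gl[as.character(cond_res)]))
        }
      }
    }
    fragments <- do.call(rbind, all_frag)
    rownames(fragments) <- NULL
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(accession = character(0), instance = integer(0),
                 site = integer(0), conditioning_glycan = character(0))
    psms <- emitPSMTable(fragments, config, sourceFile = sourceFile)
    list(psms = psms, fragments = fragments, truth = truth)
  }
  res <- withr::with_seed(config@seed, run())
  res$models <- models
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(psms = file.path(dir, "psms.tsv"),
               truth = file.path(dir, "ground_truth.tsv"),
               fasta = file.path(dir, "proteins.fasta"))
    writePSMTable(res$psms, paths[["psms"]])
    write.table(res$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeProteinFasta(setNames(
      vapply(models, function(m) m@sequence, ""),
      vapply(models, function(m) m@accession, "")), paths[["fasta"]])
    res$paths <- paths
  }
  res
}

#' Sialylation-sensitivity sweep
#'
#' Re-runs the simulation at a series of sialylation multipliers, holding
#' the seed (hence the glycoform instances and all per-site uniform draws)
#' fixed, so the realized cut sets are monotonically coupled across the
#' sweep. For each multiplier the number of glyco-rule-derived fragments
#' (fragments with at least one glyco terminus) and the sialylated fraction
#' among glycans observed at P1' of the recovered windows are reported.
#'
#' @param models List of [GlycoproteinModel] objects; the menu should
#'   contain at least one sialylated composition for the sweep to bite.
#' @param config A [SimulationConfig]; its `sialylationMultiplier` is
#'   overridden by each sweep value.
#' @param multipliers Decreasing sweep values.
#' @param nInstances Instances per model.
#' @return A `data.frame` with columns `multiplier`, `n_glyco_fragments`,
#'   `sialylated_fraction_P1prime`.
#' @export
sialylationSweep <- function(models, config,
                             multipliers = c(1, 0.75, 0.5, 0.25, 0),
                             nInstances = 20L) {
  rows <- lapply(multipliers, function(m) {
    cfg <- config
    cfg@sialylationMultiplier <- m
    cfg@nPSMs <- 0L   # exhaustive emission keeps the coupling deterministic
    res <- simulateDataset(models, cfg, nInstances = nInstances)
    nglyco <- sum(res$fragments$nterm_type == "glyco" |
                    res$fragments$cterm_type == "glyco")
    sia <- NA_real_
    filt <- filterIdentifications(res$psms, FilterConfig(), verbose = FALSE)
    if (length(filt)) {
      prot <- setNames(vapply(res$models, function(x) x@sequence, ""),
                       vapply(res$models, function(x) x@accession, ""))
      mapped <- mapGlycopeptides(filt, prot, verbose = FALSE)
      win <- extractWindows(mapped, prot)
      gd <- glycanDistribution(win, "P1'")[["P1'"]]
      if (nrow(gd))
        sia <- sum(gd$fraction[isSialylated(gd$glycan)])
      else sia <- NA_real_
    }
    data.frame(multiplier = m, n_glyco_fragments = nglyco,
               sialylated_fraction_P1prime = sia)
  })
  do.call(rbind, rows)
}
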