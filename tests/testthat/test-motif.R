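# Cleavage windows, percent glycosylated, glycan distributions and logos.

# A reusable fixture: nterm peptide TSAPTTR at 4-10 of MKTTSAPTTR.
nterm_windows <- function(glycan_pos = 1L) {
  prot <- c(PROT1 = "MKTTSAPTTR")
  x <- GlycoPSMSet(make_psm("TSAPTTR", make_sites(glycan_pos)))
  mapped <- mapGlycopeptides(x, prot, verbose = FALSE)
  extractWindows(mapped, prot)
}

test_that("window extraction matches the hand-checked alignments", {
  w <- nterm_windows()
  expect_equal(w$window, "--MKTTSAPT")     # P5, P4 gaps; P1' = T at pos 4
  expect_equal(w$side, "n_aligned")
  expect_equal(w$cleavage, 3L)
  # c-aligned hand check: cterm end at 8 of MKTTSAPTTR -> "TSAPTTR---"
  expect_equal(oracle_window("MKTTSAPTTR", 4, 8, "c_aligned"),
               "TSAPTTR---")
})

test_that("both-category peptides emit exactly two windows", {
  prot <- c(P = "GGATSAPTTAGG")
  x <- GlycoPSMSet(make_psm("TSAPTT", make_sites(1)))
  mapped <- mapGlycopeptides(x, prot, verbose = FALSE)
  expect_equal(mapped$category, "both")
  w <- extractWindows(mapped, prot)
  expect_equal(nrow(w), 2L)
  expect_setequal(w$side, c("n_aligned", "c_aligned"))
})

test_that("fully tryptic peptides contribute no windows", {
  prot <- c(P = "AKTSAPTTKGG")
  x <- GlycoPSMSet(make_psm("TSAPTTK", make_sites(1)))
  mapped <- mapGlycopeptides(x, prot, verbose = FALSE)
  expect_equal(mapped$category, "fully_tryptic")
  expect_equal(nrow(extractWindows(mapped, prot)), 0L)
})

test_that("window extraction agrees with the slice-with-padding oracle", {
  set.seed(51)
  for (i in 1:500) {
    L <- sample(12:60, 1)
    s <- random_seq(L)
    prot <- c(ACC = s)
    start <- sample(seq_len(L - 6), 1)
    end <- min(L, start + sample(5:20, 1))
    side <- sample(c("n_aligned", "c_aligned"), 1)
    mapped <- data.frame(accession = "ACC", start = start, end = end,
                         category = if (side == "n_aligned") "nterm"
                                    else "cterm",
                         ambiguous = FALSE,
                         base_sequence = substr(s, start, end),
                         source_file = "f", scan = "1", q_value = 0)
    mapped$sites <- list(make_sites(integer(0)))
    w <- extractWindows(mapped, prot)
    expect_equal(w$window, oracle_window(s, start, end, side),
                 info = paste(s, start, end, side))
  }
})

test_that("glycans land on the correct window position", {
  w <- nterm_windows(glycan_pos = 2L)   # S at peptide pos 2 = protein pos 5
  expect_equal(w$glycans[[1]]$win_pos, 7L)      # P2'
  expect_equal(names(which(!is.na(percentGlycosylated(w)) &
                             percentGlycosylated(w) > 0)), "P2'")
})

test_that("percent glycosylated counts S/T inside the peptide only", {
  w <- nterm_windows()
  pg <- percentGlycosylated(w)
  expect_equal(pg[["P1'"]], 1)
  # P1 (protein pos 3, T) lies outside the peptide: no evidence, NA
  expect_true(is.na(pg[["P1"]]))
  # gap and non-S/T positions are undefined, not zero
  expect_true(is.na(pg[["P4"]]))
  expect_equal(pg[["P2'"]], 0)   # S at protein pos 5, in peptide, no glycan
})

test_that("ten identifications with nine glycosylated P1' serines give 90%", {
  prot <- c(STD = "MAGLVSPEPTIDE")
  rec <- do.call(rbind, c(
    lapply(1:9, function(i) make_psm("SPEPTIDE", make_sites(1),
                                     scan = as.character(i),
                                     accession = "STD")),
    list(make_psm("SPEPTIDE", make_sites(5), scan = "10",
                  accession = "STD"))))
  w <- recover_windows(GlycoPSMSet(rec), prot)
  expect_equal(nrow(w), 10L)
  expect_equal(percentGlycosylated(w)[["P1'"]], 0.9)
})

test_that("glycan distributions normalize and pool across files", {
  prot <- c(PROT1 = "MKTTSAPTTR")
  rec <- rbind(
    make_psm("TSAPTTR", make_sites(1, "N1H1"), scan = "1"),
    make_psm("TSAPTTR", make_sites(1, "N1H1"), scan = "2",
             source_file = "f2"),
    make_psm("TSAPTTR", make_sites(1, "N1"), scan = "3"))
  w <- recover_windows(GlycoPSMSet(rec), prot)
  gd <- glycanDistribution(w, "P1'")[["P1'"]]
  expect_equal(gd$fraction[gd$glycan == "N1H1"], 2 / 3)
  expect_equal(gd$fraction[gd$glycan == "N1"], 1 / 3)
  expect_equal(sum(gd$fraction), 1)
  byfile <- glycanDistribution(w, "P1'", byFile = TRUE)[["P1'"]]
  expect_setequal(byfile$source_file[byfile$glycan == "N1H1"],
                  c("f1", "f2"))
  expect_equal(nrow(glycanDistribution(w, "P2")[["P2"]]), 0L)
  expect_error(glycanDistribution(w, "P9"), "unknown window position")
})

test_that("information content follows the closed-form entropy", {
  w <- nterm_windows()
  logo <- computeLogo(w)
  # single window: every non-gap column is one-hot, IC = log2(20)
  expect_equal(unname(logo$ic[["P1'"]]), log2(20), tolerance = 1e-12)
  expect_true(all(is.na(logo$ic[c("P5", "P4")])))   # all-gap positions
  expect_equal(colSums(logo$frequencies)[!is.na(logo$ic)],
               stats::setNames(rep(1, 8), names(logo$ic)[!is.na(logo$ic)]),
               tolerance = 1e-9)
  # 50/50 split at one position: IC = log2(20) - 1; the peptides end at
  # the protein C-terminus so each contributes exactly one n-aligned window
  prot <- c(P1 = "GGGGGATTTTTT", P2 = "GGGGGTTTTTTT")
  rec <- rbind(make_psm("ATTTTTT", make_sites(2), accession = "P1"),
               make_psm("TTTTTTT", make_sites(2), accession = "P2",
                        scan = "2"))
  w2 <- recover_windows(GlycoPSMSet(rec), prot)
  logo2 <- computeLogo(w2)
  expect_equal(unname(logo2$ic[["P1'"]]), log2(20) - 1, tolerance = 1e-12)
  # uniform over all 20 residues: IC = 0
  freq <- matrix(1 / 20, 20, 1)
  h <- -sum(freq * log2(freq))
  expect_equal(log2(20) - h, 0, tolerance = 1e-12)
})

test_that("the small-sample correction lowers IC and is clamped at zero", {
  w <- nterm_windows()
  plain <- computeLogo(w, correction = FALSE)$ic[["P1'"]]
  corr <- computeLogo(w, correction = TRUE)$ic[["P1'"]]
  expect_lt(corr, plain)
  expect_gte(corr, 0)
})

test_that("glycan tallies conserve every assignment and ignore order", {
  set.seed(52)
  models <- randomGlycoproteins(2, 200, 0.2, seed = 52)
  cfg <- SimulationConfig(protease = "OgpA", nPSMs = 200L, seed = 52L)
  res <- simulateDataset(models, cfg, nInstances = 5L)
  prot <- models_to_proteins(models)
  w <- recover_windows(res$psms, prot)
  total_assignments <- sum(vapply(w$glycans, nrow, 0L))
  gd <- glycanDistribution(w, windowPositions())
  expect_equal(sum(vapply(gd, function(d) sum(d$count), 0)),
               total_assignments)
  perm <- w[sample(nrow(w)), , drop = FALSE]
  attr(perm, "flank") <- 5L
  expect_equal(percentGlycosylated(perm), percentGlycosylated(w))
  gd_perm <- glycanDistribution(perm, "P1'")
  expect_equal(gd_perm, glycanDistribution(w, "P1'"))
})

test_that("motif reports assemble, collapse to glycopeptides, and serialize", {
  prot <- c(PROT1 = "MKTTSAPTTR")
  rec <- rbind(
    make_psm("TSAPTTR", make_sites(1), scan = "1"),
    make_psm("TSAPTTR", make_sites(1), scan = "2"),   # same glycopeptide
    make_psm("TSAPTTR", make_sites(2), scan = "3"))
  w <- recover_windows(GlycoPSMSet(rec), prot)
  rep_psm <- buildMotifReport(w)
  expect_equal(nWindows(rep_psm), 3L)
  rep_gp <- buildMotifReport(w, countUnit = "glycopeptide")
  expect_equal(nWindows(rep_gp), 2L)
  expect_equal(sum(rep_psm@perFileCounts), 3L)
  dir <- withr::local_tempdir()
  writeMotifReport(rep_psm, dir)
  tab <- utils::read.delim(file.path(dir, "motif_report.tsv"))
  expect_equal(nrow(tab), 10L)
  expect_true(is.na(tab$pct_glycosylated[tab$position == "P5"]))
  expect_error(buildMotifReport(w[0, , drop = FALSE]), "no cleavage windows")
})

test_that("a recovered motif derives a usable candidate rule", {
  set.seed(53)
  models <- randomGlycoproteins(3, 300, 0.2, seed = 53)
  cfg <- SimulationConfig(protease = "StcE", nPSMs = 400L, seed = 53L)
  res <- simulateDataset(models, cfg, nInstances = 10L)
  w <- recover_windows(res$psms, models_to_proteins(models))
  rule <- motifToRule(buildMotifReport(w), "StcE-candidate",
                      threshold = 0.95)
  expect_setequal(rule@cutSpecs[[1]]$p2, c("S", "T"))
  expect_setequal(rule@cutSpecs[[1]]$p1prime, c("S", "T"))
  expect_null(rule@cutSpecs[[1]]$p1)
})
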