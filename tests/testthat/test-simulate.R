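# Glycan-conditional proteolysis simulator.

test_that("degenerate occupancy and menu give deterministic glycoforms", {
  m <- GlycoproteinModel("P", "AAATAAA", occupancy = 1,
                         glycanMenu = c(N1H1 = 1))
  inst <- simulateGlycoforms(m, 5, seed = 61)
  for (g in inst) {
    expect_equal(g$sites$pos, 4L)
    expect_equal(g$sites$glycan, "N1H1")
  }
})

test_that("occupancy draws behave binomially", {
  m <- GlycoproteinModel("P", "AAATAAA", occupancy = 0.5)
  inst <- simulateGlycoforms(m, 10000, seed = 62)
  occ <- mean(vapply(inst, function(g) nrow(g$sites) > 0, NA))
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(occ - 0.5), 3 * se)
})

test_that("identical seeds give identical glycoform lists", {
  m <- GlycoproteinModel("P", random_seq(100), occupancy = 0.4)
  expect_identical(simulateGlycoforms(m, 20, seed = 63),
                   simulateGlycoforms(m, 20, seed = 63))
})

test_that("every glyco-derived N-terminus starts at an occupied S/T", {
  set.seed(64)
  models <- randomGlycoproteins(3, 250, 0.2, seed = 64)
  cfg <- SimulationConfig(protease = "OgpA", efficiency = 1, seed = 64L)
  for (model in models) {
    inst <- simulateGlycoforms(model, 3, seed = 65)
    for (g in inst) {
      frag <- simulateDigest(g, cfg)
      glyco_n <- frag[frag$nterm_type == "glyco", , drop = FALSE]
      for (j in seq_len(nrow(glyco_n))) {
        expect_true(substr(glyco_n$peptide[j], 1, 1) %in% c("S", "T"))
        expect_true(glyco_n$start[j] %in% g$sites$pos)
      }
      # fragments tile the instance
      expect_identical(paste(frag$peptide[order(frag$start)],
                             collapse = ""), g$sequence)
      # carried glycans lie inside their fragment
      for (j in seq_len(nrow(frag))) {
        s <- frag$sites[[j]]
        expect_true(all(s$pos >= frag$start[j] & s$pos <= frag$end[j]))
      }
    }
  }
})

test_that("a zero sialylation multiplier annihilates sialylated cleavage", {
  m <- GlycoproteinModel("P", random_seq(200), occupancy = 0.8,
                         glycanMenu = c(N1H1A1 = 1))   # all sialylated
  cfg <- SimulationConfig(protease = "OgpA", efficiency = 1,
                          sialylationMultiplier = 0, seed = 66L)
  inst <- simulateGlycoforms(m, 5, seed = 66)
  for (g in inst) {
    frag <- simulateDigest(g, cfg)
    expect_false(any(frag$nterm_type == "glyco"))
    expect_false(any(frag$cterm_type == "glyco"))
  }
})

test_that("StcE-style cleavage realizes at an occupied T/S-X-T/S context", {
  # occupied T at position 2 = P2 of the V3|T4 bond
  inst <- list(accession = "P", sequence = "ATVTSGAAA",
               sites = data.frame(pos = 2L, glycan = "N1H1"))
  cfg <- SimulationConfig(protease = "StcE", efficiency = 1,
                          trypsinStage = FALSE, seed = 67L)
  frag <- withr::with_seed(67, simulateDigest(inst, cfg))
  expect_equal(sort(unique(c(frag$start - 1L, frag$end))),
               sort(unique(c(0L, 3L, 9L))))
  expect_equal(frag$cterm_type[frag$end == 3L], "glyco")
})

test_that("OgpA-style cleavage requires an un-glycosylated P1 by default", {
  # adjacent occupied T5,T6: cut before T6 would put a glycan at P1
  inst <- list(accession = "P", sequence = "AAAATTAAA",
               sites = data.frame(pos = c(5L, 6L),
                                  glycan = c("N1", "N1")))
  cfg <- SimulationConfig(protease = "OgpA", efficiency = 1,
                          trypsinStage = FALSE, seed = 68L)
  frag <- withr::with_seed(68, simulateDigest(inst, cfg))
  expect_true(4L %in% frag$end)       # cut before T5 (P1 = A4)
  expect_false(5L %in% frag$end)      # no cut before T6 (P1 = occupied T5)
  cfg2 <- SimulationConfig(protease = "OgpA", efficiency = 1,
                           requireUnmodifiedP1 = FALSE,
                           trypsinStage = FALSE, seed = 68L)
  frag2 <- withr::with_seed(68, simulateDigest(inst, cfg2))
  expect_true(all(c(4L, 5L) %in% frag2$end))
})

test_that("emitted tables round-trip and honour the noise switches", {
  models <- randomGlycoproteins(2, 200, 0.2, seed = 69)
  cfg <- SimulationConfig(protease = "OgpA", nPSMs = 300L,
                          decoyFraction = 0.1, qAboveFraction = 0.2,
                          falseLocalizationRate = 0.1, seed = 69L)
  dir <- withr::local_tempdir()
  res <- simulateDataset(models, cfg, nInstances = 5L, dir = dir)
  expect_equal(length(res$psms), 300L)
  back <- readPSMTable(res$paths[["psms"]])
  expect_equal(psmRecords(back), psmRecords(res$psms))
  rec <- psmRecords(res$psms)
  expect_gt(sum(rec$is_decoy), 0L)
  expect_gt(sum(rec$q_value >= 0.01), 0L)
  expect_gt(sum(rec$localization_level == "Level2"), 0L)
  # decoy sequences are reversals of pool peptides
  dec <- rec$base_sequence[rec$is_decoy][1]
  rev_dec <- paste(rev(strsplit(dec, "")[[1]]), collapse = "")
  expect_true(rev_dec %in% res$fragments$peptide)
})

test_that("the simulation is reproducible from its seed alone", {
  models <- randomGlycoproteins(2, 150, 0.2, seed = 70)
  cfg <- SimulationConfig(protease = "OgpA", nPSMs = 100L,
                          decoyFraction = 0.1, seed = 70L)
  a <- simulateDataset(models, cfg, nInstances = 3L)
  b <- simulateDataset(models, cfg, nInstances = 3L)
  expect_identical(psmRecords(a$psms), psmRecords(b$psms))
  expect_identical(a$truth, b$truth)
  expect_equal(sum(psmRecords(a$psms)$is_decoy),
               sum(psmRecords(b$psms)$is_decoy))
})

test_that("noise-free tables pass the filter exactly at the q cut", {
  models <- randomGlycoproteins(2, 200, 0.2, seed = 71)
  cfg <- SimulationConfig(protease = "OgpA", nPSMs = 200L,
                          qAboveFraction = 0.3, seed = 71L)
  res <- simulateDataset(models, cfg, nInstances = 5L)
  rec <- psmRecords(res$psms)
  filt <- filterIdentifications(res$psms, verbose = FALSE)
  keep <- oracle_filter_keep(rec)
  expect_identical(psmRecords(filt)$scan, rec$scan[keep])
})

test_that("ground truth lists exactly the realized glyco cuts", {
  models <- randomGlycoproteins(1, 150, 0.25, seed = 72)
  cfg <- SimulationConfig(protease = "OgpA", nPSMs = 50L, seed = 72L)
  res <- simulateDataset(models, cfg, nInstances = 2L)
  frag <- res$fragments
  for (ii in unique(frag$instance)) {
    fi <- frag[frag$instance == ii, ]
    cuts <- sort(unique(c(fi$start[fi$nterm_type == "glyco"] - 1L,
                          fi$end[fi$cterm_type == "glyco"])))
    expect_equal(res$truth$site[res$truth$instance == ii], cuts)
  }
  expect_true(all(!is.na(res$truth$conditioning_glycan)))
})
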