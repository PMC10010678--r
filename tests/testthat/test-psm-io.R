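# Glycan notation, identification-table I/O and FASTA handling.

test_that("glycan compositions parse in both dialects and canonicalize", {
  expect_equal(glycanCounts(parseGlycan("N1"))[["hexnac"]], 1L)
  expect_equal(sum(glycanCounts(parseGlycan("N1"))), 1L)   # Tn antigen
  expect_equal(glycanText(parseGlycan("H(1)N(1)")), "N1H1")
  expect_equal(glycanText(parseGlycan("A1H1N1")), "N1H1A1")
  expect_equal(glycanText(parseGlycan("N1N1H2")), "N2H2")  # repeats summed
  expect_error(parseGlycan("X2"), "unknown monosaccharide.*X2")
  expect_error(parseGlycan("N0"), "count")
  expect_error(parseGlycan("  "), "empty")
  expect_error(parseGlycan("N1junk"), "malformed")
})

test_that("glycan parsing is idempotent on its canonical rendering", {
  set.seed(11)
  for (i in 1:50) {
    cts <- stats::rbinom(5, 3, 0.4)
    if (sum(cts) == 0) cts[1] <- 1
    g <- GlycanComposition(cts[1], cts[2], cts[3], cts[4], cts[5])
    expect_identical(glycanText(parseGlycan(glycanText(g))), glycanText(g))
  }
})

test_that("sialylation detection keys on NeuAc/NeuGc content", {
  expect_equal(isSialylated(c("N1H1", "N1H1A1", "N1G1", "N1F1")),
               c(FALSE, TRUE, TRUE, FALSE))
})

test_that("glycan databases round-trip and reject duplicates", {
  path <- withr::local_tempfile(fileext = ".txt")
  db <- c("N1", "N1H1", "N1H1A1")
  writeGlycanDatabase(db, path)
  expect_identical(readGlycanDatabase(path), db)
  writeLines(c("N1", "H1N1", "N1H1"), path)  # same composition twice
  expect_error(readGlycanDatabase(path), "duplicate")
  ship <- system.file("extdata", "oglycan_db_synthetic_22.txt",
                      package = "glycoMotif")
  expect_length(readGlycanDatabase(ship), 22L)
})

test_that("canonical PSM tables round-trip field-for-field", {
  rec <- rbind(
    make_psm("TTSAPTTR", make_sites(c(1, 2), c("N1H1", "N1"), 0.95),
             scan = "10"),
    make_psm("RTTPAEK", NULL, level = "unmodified", decoy = TRUE,
             scan = "11", q_value = 0.2))
  x <- GlycoPSMSet(rec)
  expect_equal(length(x), 2L)
  expect_equal(sum(psmRecords(x)$is_decoy), 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePSMTable(x, path)
  y <- readPSMTable(path)
  expect_equal(psmRecords(y), psmRecords(x))
})

test_that("header-only tables give an empty record set", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("source_file", "scan", "base_sequence",
                     "protein_accession", "is_decoy", "q_value",
                     "localization_level", "sites"), collapse = "\t"), path)
  expect_equal(length(readPSMTable(path)), 0L)
})

test_that("missing mapped columns are reported by canonical name", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("source_file", "scan", "base_sequence",
                       "protein_accession", "is_decoy",
                       "localization_level", "sites"), collapse = "\t"),
               paste(c("f", "1", "PEPTIDE", "P1", "FALSE", "Level1",
                       "1:N1:0.9"), collapse = "\t")), path)
  expect_error(readPSMTable(path), "q_value")
})

test_that("malformed rows fail with row numbers, or skip when permissive", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("source_file", "scan", "base_sequence",
                 "protein_accession", "is_decoy", "q_value",
                 "localization_level", "sites"), collapse = "\t")
  good <- paste(c("f", "1", "TSAPK", "P1", "FALSE", "0.001", "Level1",
                  "1:N1:0.9"), collapse = "\t")
  bad <- paste(c("f", "2", "TSAPK", "P1", "FALSE", "not-a-number",
                 "Level1", "1:N1:0.9"), collapse = "\t")
  writeLines(c(hdr, good, bad), path)
  expect_error(readPSMTable(path), "row 2")
  suppressMessages(expect_warning(
    y <- readPSMTable(path, permissive = TRUE), "row 2"))
  expect_equal(length(y), 1L)
})

test_that("the O-Pair-style dialect adapter normalizes to the canonical schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("File Name", "Scan Number", "Base Sequence",
                 "Protein Accession", "Decoy", "QValue",
                 "GlycoLocalizationLevel", "Localized Glycans"),
               collapse = "\t")
  row1 <- paste(c("a.raw", "100", "TTSAPK", "P1", "T", "0.002", "Level 1",
                  "[2,H(1)N(1),0.98]"), collapse = "\t")
  row2 <- paste(c("a.raw", "101", "KPEPTIDEK", "P1", "D", "0.2",
                  "Level 2", "[5,N(1),0.5]"), collapse = "\t")
  writeLines(c(hdr, row1, row2), path)
  x <- readPSMTable(path, metaMorpheusColumnMap())
  rec <- psmRecords(x)
  expect_equal(rec$is_decoy, c(FALSE, TRUE))
  expect_equal(rec$localization_level, c("Level1", "Level2"))
  expect_equal(rec$sites[[1]]$glycan, "N1H1")   # dialect + reordering
  expect_equal(rec$sites[[1]]$peptide_position, 2L)
})

test_that("FASTA accessions follow UniProt conventions and order persists", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P12345|NAME some description", "MKTT",
               ">simple_header", "MKTTSAPTTR"), path)
  aa <- readProteinFasta(path)
  expect_identical(names(aa), c("P12345", "simple_header"))
  expect_identical(as.character(aa[["P12345"]]), "MKTT")
  expect_identical(S4Vectors::mcols(aa)$description[1],
                   "sp|P12345|NAME some description")
})

test_that("FASTA validation rejects ambiguity codes and duplicates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P12345|NAME", "MKBT"), path)
  expect_error(readProteinFasta(path), "P12345.*B")
  writeLines(c(">A", "MKTT", ">A", "MKTA"), path)
  expect_error(readProteinFasta(path), "duplicate")
})

test_that("FASTA write-then-read is the identity", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(ACC1 = "MKTTSAPTTR", ACC2 = "MSTSTSTK")
  writeProteinFasta(seqs, path)
  aa <- readProteinFasta(path)
  expect_identical(stats::setNames(as.character(aa), names(aa)), seqs)
})
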