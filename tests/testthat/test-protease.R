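# Cleavage-rule engine: site enumeration and digestion.

test_that("cleavage sites match the printed rule semantics", {
  expect_equal(enumerateCleavageSites("MKRPEPTIDEK", "Trypsin"), c(2L, 3L))
  expect_equal(enumerateCleavageSites("ATVTSG", "StcE"), 3L)
  expect_equal(enumerateCleavageSites("ATVTSG", "OgpA"), c(1L, 3L, 4L))
  expect_equal(enumerateCleavageSites("ATVTSG", "IMPa"),
               enumerateCleavageSites("ATVTSG", "OgpA"))
  expect_equal(enumerateCleavageSites("A", "Trypsin"), integer(0))
})

test_that("compact cut-spec notation round-trips", {
  for (txt in c("K|", "|T", "[ST]x|[ST]", "[KR]|P")) {
    cs <- parseCutSpec(txt)
    expect_identical(glycoMotif:::.cutspec_text(cs), txt)
  }
  expect_error(parseCutSpec("KT"), "\\|")
  expect_null(parseCutSpec("K|")$p2)
  expect_equal(parseCutSpec("[ST]x|[ST]")$p2, c("S", "T"))
})

test_that("full tryptic digestion reproduces the hand-worked fragments", {
  d0 <- digestSequence("MKRPEPTIDEK", "Trypsin", missed = 0,
                       minLength = 1, maxLength = 60)
  expect_setequal(d0$peptide, c("MK", "R", "PEPTIDEK"))
  d1 <- digestSequence("MKRPEPTIDEK", "Trypsin", missed = 1,
                       minLength = 5, maxLength = 60)
  expect_setequal(d1$peptide, c("RPEPTIDEK", "PEPTIDEK"))
  expect_true(all(d1$missed <= 1))
})

test_that("non-specific digestion counts follow the closed form", {
  for (L in c(5L, 10L, 33L, 80L)) {
    d <- digestSequence(strrep("A", L), "Non-Specific")
    lens <- 5:min(60L, L)
    expect_equal(nrow(d), sum(L - lens + 1L))
  }
  expect_equal(nrow(digestSequence("AAAA", "Non-Specific")), 0L)
})

test_that("initiator-methionine variants appear under variable cleavage", {
  d <- digestSequence("MKTTSAPK", "Trypsin", missed = 0, minLength = 1,
                      maxLength = 60, metPolicy = "variable_cleavage")
  expect_true("K" %in% d$peptide)      # Met-clipped variant of "MK"
  d2 <- digestSequence("MKTTSAPK", "Trypsin", missed = 0, minLength = 1,
                       maxLength = 60, metPolicy = "none")
  expect_false("K" %in% d2$peptide[d2$start == 2])
})

test_that("zero-missed full fragments tile the protein exactly", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_seq(sample(10:70, 1))
    for (rn in c("Trypsin", "OgpA", "StcE")) {
      d <- digestSequence(s, rn, missed = 0, minLength = 1, maxLength = 100)
      expect_identical(paste(d$peptide[order(d$start)], collapse = ""), s)
    }
  }
})

test_that("peptide sets grow monotonically in missed cleavages and length", {
  set.seed(32)
  for (i in 1:10) {
    s <- random_seq(sample(20:70, 1))
    rule <- getProtease("OgpA-Trypsin")
    prev <- character(0)
    for (m in c(0, 2, 4, 8)) {
      cur <- digest_keys(digestSequence(s, rule, missed = m,
                                        minLength = 1, maxLength = 60))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
    small <- digest_keys(digestSequence(s, rule, missed = 3, minLength = 1,
                                        maxLength = 20))
    large <- digest_keys(digestSequence(s, rule, missed = 3, minLength = 1,
                                        maxLength = 60))
    expect_true(all(small %in% large))
  }
})

test_that("full is a subset of semi is a subset of non-specific", {
  set.seed(33)
  tr_full <- getProtease("Trypsin")
  tr_semi <- getProtease("Semi-Trypsin")
  ns <- getProtease("Non-Specific")
  for (i in 1:10) {
    s <- random_seq(sample(20:70, 1))
    full <- digest_keys(digestSequence(s, tr_full, missed = 3))
    semi <- digest_keys(digestSequence(s, tr_semi, missed = 3))
    nonsp <- digest_keys(digestSequence(s, ns))
    expect_true(all(full %in% semi))
    expect_true(all(semi %in% nonsp))
  }
})

test_that("digestion equals the all-substrings oracle for every built-in rule", {
  set.seed(34)
  rules <- proteaseRules()
  for (i in 1:40) {
    s <- random_seq(sample(2:80, 1))
    for (rn in names(rules)) {
      d <- digestSequence(s, rules[[rn]])
      expect_identical(digest_keys(d), oracle_digest(s, rules[[rn]]),
                       info = paste(rn, s))
    }
  }
})

test_that("combined glycoprotease-trypsin termini are protein ends, after K/R, or before S/T", {
  set.seed(35)
  for (i in 1:10) {
    s <- random_seq(sample(30:70, 1))
    r <- strsplit(s, "")[[1]]
    d <- digestSequence(s, "OgpA-Trypsin", missed = 12, minLength = 1,
                        maxLength = 80)
    n_ok <- d$start == 1 | r[pmax(d$start - 1, 1)] %in% c("K", "R") |
      r[d$start] %in% c("S", "T")
    c_ok <- d$end == nchar(s) | r[d$end] %in% c("K", "R") |
      r[pmin(d$end + 1, nchar(s))] %in% c("S", "T")
    expect_true(all(n_ok & c_ok))
  }
})

test_that("rule combination unions the contexts", {
  comb <- combineRules(getProtease("StcE"), getProtease("Trypsin"))
  expect_equal(comb@name, "StcE-Trypsin")
  expect_setequal(
    enumerateCleavageSites("ATVTSGKA", comb),
    union(enumerateCleavageSites("ATVTSGKA", "StcE"),
          enumerateCleavageSites("ATVTSGKA", "Trypsin")))
})

test_that("protease definition files round-trip and unknown rules fail loudly", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeProteaseRules(proteaseRules(), path)
  back <- readProteaseRules(path)
  expect_setequal(names(back), names(proteaseRules()))
  stce <- back[["StcE"]]
  expect_equal(stce@cutSpecs, getProtease("StcE")@cutSpecs)
  expect_error(getProtease("Xyz"), "available.*Trypsin")
})
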