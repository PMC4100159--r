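test_that("the generator is a pure function of its spec", {
  sp <- syntheticSpec(20L, 30L, motif = data.frame(position = 3L,
                                                   residue = "K", rho = 2),
                      padFraction = 0.3, seed = 12L)
  a <- generateDataset(sp)
  b <- generateDataset(sp)
  expect_identical(residues(a), residues(b))
  expect_identical(siteLabels(a), siteLabels(b))
  c <- generateDataset(syntheticSpec(20L, 30L, seed = 13L))
  expect_false(identical(residues(a), residues(c)))
  # the generator restores the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generateDataset(sp)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null specs produce classes with matching residue frequencies", {
  d <- generateDataset(syntheticSpec(1000L, 1000L, seed = 2L))
  lab <- siteLabels(d)
  fp <- bpbPosterior(countPositions(d[which(lab == 1)]))
  fn <- bpbPosterior(countPositions(d[which(lab == -1)]))
  # per-cell binomial sd of the difference is ~0.0097; 5 sigma over 20x21
  # cells (center excluded)
  expect_lt(max(abs(fp - fn)[, -11]), 0.05)
})

test_that("planted motifs hit their target frequencies and class contrast", {
  sp <- syntheticSpec(2000L, 2000L,
                      motif = data.frame(position = 3L, residue = "K",
                                         rho = 3), seed = 8L)
  d <- generateDataset(sp)
  lab <- siteLabels(d)
  fPos <- countPositions(d[which(lab == 1)])@counts["K", 3] / 2000
  # binomial 4 sigma around the planted probability 3/20
  expect_lt(abs(fPos - 0.15), 4 * sqrt(0.15 * 0.85 / 2000))

  prof <- buildBiProfile(residues(d)[lab == 1], residues(d)[lab == -1])
  expect_gt(positiveProfile(prof)["K", 3], negativeProfile(prof)["K", 3])
})

test_that("exclusive deterministic motifs separate the classes by column", {
  sep <- fixtureDataset("separable")
  lab <- siteLabels(sep)
  at5 <- substr(residues(sep), 5, 5)
  expect_true(all(at5[lab == 1] == "W"))
  expect_true(all(at5[lab == -1] != "W"))
})

test_that("invalid specs are rejected", {
  expect_error(syntheticSpec(10L, 10L,
                             motif = data.frame(position = 11L, residue = "K",
                                                rho = 2)), "center")
  expect_error(syntheticSpec(10L, 10L,
                             motif = data.frame(position = 3L, residue = "K",
                                                rho = -1)), "positive")
  expect_error(syntheticSpec(10L, 10L,
                             motif = data.frame(position = 3L, residue = "K",
                                                rho = 25)), "below 1")
  expect_error(syntheticSpec(10L, 10L,
                             motif = data.frame(position = 3L, residue = "B",
                                                rho = 2)), "amino acid")
  expect_error(syntheticSpec(10L, 10L, padFraction = 1.2), "padFraction")
})

test_that("padding is terminal, leaves centers intact, and hits its rate", {
  pad <- fixtureDataset("padded")   # padFraction 0.5, n = 200
  res <- residues(pad)
  expect_true(all(substr(res, 11, 11) == "C"))
  frac <- mean(grepl("X", res))
  expect_gt(frac, 0.35)
  expect_lt(frac, 0.65)
  # validity of the class already guarantees contiguous terminal X runs
  expect_s4_class(pad, "PeptideWindowSet")
})

test_that("the fixture suite round-trips through its own file dialects", {
  dir <- withr::local_tempdir()
  man <- makeFixtureSuite(dir, L = 21L)
  expect_setequal(names(man), c("null", "weak-motif", "separable", "padded"))
  files <- list.files(dir)
  expect_true(all(c("null.windows.tsv", "null.fasta", "null.sites.tsv",
                    "manifest.json") %in% files))

  # regenerating is byte-identical
  dir2 <- withr::local_tempdir()
  makeFixtureSuite(dir2, L = 21L)
  for (f in list.files(dir)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }

  # FASTA + site table reproduce the window TSV exactly (padding included)
  for (name in c("padded", "weak-motif")) {
    fromTsv <- readWindows(file.path(dir, paste0(name, ".windows.tsv")))
    rebuilt <- extractDataset(readProteins(file.path(dir, paste0(name, ".fasta"))),
                              readSiteTable(file.path(dir, paste0(name, ".sites.tsv"))),
                              L = 21L)
    expect_identical(residues(rebuilt), residues(fromTsv))
    expect_identical(siteLabels(rebuilt), siteLabels(fromTsv))
  }

  # manifest statistics match the regenerated data
  man2 <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  wk <- fixtureDataset("weak-motif")
  lab <- siteLabels(wk)
  pr <- relativePropensity(countPositions(wk[which(lab == 1)]),
                           countPositions(wk[which(lab == -1)]))
  expect_equal(man2$`weak-motif`$plantedPropensity, unname(pr@r["K", 3]))
})
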