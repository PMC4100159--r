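test_that("position counting matches hand tallies and the X rule", {
  cc <- countPositions(c("ACA", "CCC"))
  expect_identical(unname(cc@counts["A", 1]), 1L)
  expect_identical(unname(cc@counts["C", 1]), 1L)
  expect_identical(unname(cc@counts["C", 2]), 2L)
  expect_identical(unname(cc@counts["A", 3]), 1L)
  expect_identical(unname(cc@counts["C", 3]), 1L)
  expect_identical(sum(cc@counts), 6L)

  xc <- countPositions("XCA")
  expect_identical(sum(xc@counts[, 1]), 0L)
  expect_identical(xc@effectiveN, c(0L, 1L, 1L))

  expect_error(countPositions(character(0)), "empty")
  expect_error(countPositions(c("ACA", "AACAA")), "mixed lengths")
})

test_that("position counting equals an independent brute-force tally", {
  for (seed in 1:5) {
    w <- randWindows(40, L = 11, seed = seed)
    # plant some terminal padding too
    w[1] <- paste0("XXX", substr(w[1], 4, 11))
    expect_identical(unname(countPositions(w)@counts), unname(bruteTally(w)))
  }
})

test_that("relative propensity is the ratio of positional frequencies", {
  pos <- countPositions(c("KCA", "KCD", "ACD", "DCA"))
  neg <- countPositions(c("KCA", "ACD", "DCA", "ECD"))
  r <- relativePropensity(pos, neg)
  expect_equal(unname(r@r["K", 1]), (2 / 4) / (1 / 4))  # ratio 2.0 by definition

  same <- relativePropensity(pos, pos)
  expect_true(all(same@r[pos@counts > 0] == 1))

  # zero negative frequency at pseudocount 0 -> undefined, excluded
  expect_true(is.na(r@r["E", 3]) || r@r["E", 3] >= 0)  # E absent in pos col 3
  r2 <- relativePropensity(neg, pos)
  expect_true(is.na(r2@r["E", 1]))  # E never at pos 1 in the denominator set
})

test_that("propensity averages are row means over defined non-center cells", {
  pos <- countPositions(randWindows(60, L = 5, seed = 9))
  neg <- countPositions(randWindows(60, L = 5, seed = 10))
  pr <- relativePropensity(pos, neg, pseudocount = 1)
  center <- 3L
  for (aa in c("A", "K", "W")) {
    cells <- pr@r[aa, -center]
    expect_equal(unname(pr@averages[aa]), mean(cells, na.rm = TRUE))
  }
})

test_that("BPB posteriors are positional frequencies", {
  p <- bpbPosterior(countPositions(c("ACA", "ACA", "CCA", "DCA")))
  expect_equal(unname(p["A", 1]), 0.5)
  expect_equal(unname(p["C", 1]), 0.25)
  expect_equal(unname(p["D", 1]), 0.25)
  expect_equal(sum(p[, 2]), 1)

  # all-X column -> zeros; single window -> 1.0
  px <- bpbPosterior(countPositions(c("XCK", "XCK")))
  expect_true(all(px[, 1] == 0))
  expect_equal(unname(px["K", 3]), 1)

  # columns without X sum to 1 within 1e-12
  p2 <- bpbPosterior(countPositions(randWindows(50, L = 7, seed = 2)))
  expect_true(all(abs(colSums(p2) - 1) < 1e-12))
})

test_that("the normal CDF wrapper is exact and symmetric", {
  expect_identical(normalCdf(0), 0.5)
  expect_equal(normalCdf(1.0), 0.8413447, tolerance = 1e-7)
  xs <- seq(-6, 6, by = 0.37)
  expect_equal(normalCdf(xs) + normalCdf(-xs), rep(1, length(xs)))
  expect_error(normalCdf(Inf), "finite")
  expect_error(normalCdf(NA_real_), "finite")
})

test_that("ANBPB matches the hand-standardized worked example", {
  # 20 windows of length 1 column under test: counts {8, 12 x 1, 7 x 0},
  # mean = n*p = 1, population sd = sqrt(56/20)
  w <- c(rep("ACA", 0),
         rep(sprintf("%sC%s", "K", "A"), 8),
         sprintf("%sC%s", c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                            "N", "P"), "A"))
  cc <- countPositions(w)  # col 1: K = 8, twelve singletons, seven zeros
  expect_identical(unname(cc@counts["K", 1]), 8L)
  post <- anbpbPosterior(cc)
  V <- sqrt(56 / 20)
  expect_equal(unname(post["K", 1]), pnorm(7 / V), tolerance = 1e-12)
  expect_equal(unname(roundHalfUp(post["K", 1], 4)), 1)
  expect_equal(unname(roundHalfUp(post["W", 1], 4)), 0.2750)  # a count-0 residue

  # within a column, entries are non-decreasing in the count
  ord <- order(cc@counts[, 1])
  expect_true(all(diff(post[ord, 1]) >= 0))

  # uniform column (the center, all "C") is NOT degenerate: V > 0 there;
  # a truly uniform column is
  uw <- vapply(AA, function(a) paste0(a, "C", a), character(1))
  up <- anbpbPosterior(countPositions(uw))
  expect_true(all(up[, 1] == 0.5))  # each residue once: V = 0

  expect_error(anbpbPosterior(countPositions("ACA")), "at least 2")
})

test_that("ANBPB is invariant to window order", {
  w <- randWindows(30, L = 9, seed = 4)
  a <- anbpbPosterior(countPositions(w))
  b <- anbpbPosterior(countPositions(rev(w)))
  expect_identical(a, b)
})

test_that("bi-profiles record class sizes and detect planted enrichment", {
  posW <- randWindows(25, L = 7, seed = 5)
  negW <- randWindows(35, L = 7, seed = 6)
  bp <- buildBiProfile(posW, negW, method = "bpb")
  expect_identical(bp@nPos, 25L)
  expect_identical(bp@nNeg, 35L)
  same <- buildBiProfile(posW, posW, method = "bpb")
  expect_identical(positiveProfile(same), negativeProfile(same))

  fx <- fixtureDataset("weak-motif")
  prof <- buildBiProfile(residues(fx)[siteLabels(fx) == 1],
                         residues(fx)[siteLabels(fx) == -1])
  expect_gt(positiveProfile(prof)["K", 3], negativeProfile(prof)["K", 3])
})

test_that("planted enrichment is recovered without bias", {
  # mean of the propensity estimate at the planted cell over 20 generator
  # seeds; the per-draw sd at 2000+2000 is ~0.37, so 3 standard errors of
  # the 20-seed mean is ~0.25
  rs <- vapply(1:20, function(s) {
    d <- generateDataset(syntheticSpec(
      2000L, 2000L, motif = data.frame(position = 3L, residue = "K", rho = 3),
      seed = s))
    lab <- siteLabels(d)
    pr <- relativePropensity(countPositions(d[which(lab == 1)]),
                             countPositions(d[which(lab == -1)]))
    pr@r["K", 3]
  }, numeric(1))
  expect_lt(abs(mean(rs) - 3), 0.25)
})

test_that("bi-profile JSON documents round-trip", {
  fx <- fixtureDataset("padded")
  prof <- buildBiProfile(residues(fx)[siteLabels(fx) == 1],
                         residues(fx)[siteLabels(fx) == -1])
  f <- withr::local_tempfile(fileext = ".json")
  writeBiProfile(prof, f)
  back <- readBiProfile(f)
  expect_identical(profileMethod(back), profileMethod(prof))
  expect_equal(positiveProfile(back), positiveProfile(prof))
  expect_equal(negativeProfile(back), negativeProfile(prof))
  expect_identical(back@nPos, prof@nPos)
})
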