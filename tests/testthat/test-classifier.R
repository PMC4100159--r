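test_that("the RBF kernel is a symmetric positive similarity", {
  set.seed(1)
  x <- matrix(rnorm(30), 6)
  K <- rbfKernel(x, x, gamma = 0.3)
  expect_equal(diag(K), rep(1, 6))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
})

test_that("training separates a separable toy set and validates input", {
  toy <- separableToy()
  m <- trainModel(toy$x, toy$y, modelConfig())
  pred <- predict(m, toy$x)
  expect_identical(as.integer(pred), toy$y)

  expect_error(trainModel(toy$x, rep(1L, nrow(toy$x)), modelConfig()),
               "each class")
  bad <- toy$x; bad[1, 1] <- NaN
  expect_error(trainModel(bad, toy$y, modelConfig()), "NA/NaN")
})

test_that("batch prediction equals per-row prediction and 0 maps to -1", {
  toy <- separableToy()
  m <- trainModel(toy$x, toy$y, modelConfig())
  batch <- predict(m, toy$x)
  single <- vapply(seq_len(nrow(toy$x)), function(i) {
    as.integer(predict(m, toy$x[i, , drop = FALSE]))
  }, integer(1))
  expect_identical(as.integer(batch), single)

  # decision value exactly 0 is called negative: rig a one-SV model whose
  # decision at its own support vector is exactly zero
  m0 <- m
  m0@sv <- matrix(0.5, 1, ncol(toy$x))
  m0@coefs <- 1
  m0@rho <- 1          # k(sv, sv) = 1 -> decision = 1 - 1 = 0
  m0@flip <- 1
  p0 <- predict(m0, m0@sv)
  expect_identical(as.integer(p0), -1L)
  expect_identical(attr(p0, "decision"), 0)
})

test_that("interior solutions are invariant to duplication and row order", {
  toy <- separableToy()
  m1 <- trainModel(toy$x, toy$y, modelConfig(cost = 10, gamma = 0.5, wPos = 1))
  m2 <- trainModel(rbind(toy$x, toy$x), c(toy$y, toy$y),
                   modelConfig(cost = 10, gamma = 0.5, wPos = 1))
  # agreement is bounded by the optimizer termination tolerance (1e-6)
  expect_equal(decisionValues(m1, toy$x), decisionValues(m2, toy$x),
               tolerance = 1e-6)

  fx <- fixtureDataset("padded")
  lab <- siteLabels(fx)
  prof <- buildBiProfile(residues(fx)[lab == 1], residues(fx)[lab == -1])
  fe <- encodeDataset(fx, prof)
  ma <- trainModel(fe, lab, profile = prof, layout = attr(fe, "layout"))
  set.seed(11)
  perm <- sample(nrow(fe))
  mb <- trainModel(fe[perm, ], lab[perm], profile = prof,
                   layout = attr(fe, "layout"))
  expect_lt(max(abs(decisionValues(ma, fe) - decisionValues(mb, fe))), 1e-5)
})

test_that("raising the positive weight drives training sensitivity up", {
  set.seed(21)
  d <- 6L
  x <- rbind(matrix(rnorm(10 * d, 0.6, 0.5), 10),   # positives, overlapping
             matrix(rnorm(40 * d, 0.0, 0.5), 40))
  y <- rep(c(1L, -1L), c(10, 40))
  snAt <- function(w) {
    m <- trainModel(x, y, modelConfig(cost = 1, gamma = 0.1, wPos = w))
    sum(predict(m, x) == 1L & y == 1L) / sum(y == 1L)
  }
  expect_lt(snAt(1), 1)
  expect_equal(snAt(60), 1)
})

test_that("weight-parameter search maximizes MCC with ties toward smaller W", {
  fx <- fixtureDataset("padded")[c(1:30, 101:160)]  # imbalanced 30+:60-
  evalFast <- function(w, cfg) {
    repeatedKFold(w, k = 5, repeats = 1, seed = 9, config = cfg)$mean
  }
  gs <- gridSearchWeight(fx, candidates = c(1, 2), evaluator = evalFast)
  # oracle: exhaustive evaluation of the same candidates
  oracleMcc <- vapply(c(1, 2), function(w) {
    evalFast(fx, modelConfig(wPos = w))@mcc
  }, numeric(1))
  expect_equal(unname(gs$mcc), oracleMcc)
  expect_identical(gs$best, c(1, 2)[which.max(oracleMcc)])

  # single candidate, and ties
  one <- gridSearchWeight(fx, candidates = 2.5, evaluator = evalFast)
  expect_identical(one$best, 2.5)
  constEval <- function(w, cfg) metricsFromCounts(5, 5, 5, 5)
  tie <- gridSearchWeight(fx, candidates = c(2.5, 1.5, 2), evaluator = constEval)
  expect_identical(tie$best, 1.5)
  expect_error(gridSearchWeight(fx, candidates = numeric(0),
                                evaluator = constEval), "empty")
})

test_that("cost/gamma search equals brute-force enumeration of the grid", {
  fx <- fixtureDataset("separable")[c(1:30, 101:130)]
  lab <- siteLabels(fx)
  prof <- buildBiProfile(residues(fx)[lab == 1], residues(fx)[lab == -1])
  fe <- encodeDataset(fx, prof)
  log2C <- c(0, 4.5)
  log2g <- c(-5, -1)
  gs <- gridSearchCostGamma(fe, lab, log2C = log2C, log2gamma = log2g,
                            folds = 5, seed = 3)

  # independent oracle: same folds, but e1071 end to end
  foldId <- makeStratifiedFolds(lab, 5, seed = 3)
  oracle <- matrix(NA_real_, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    correct <- 0L
    for (f in 1:5) {
      test <- foldId == f
      fit <- e1071::svm(fe[!test, ], factor(lab[!test], levels = c("1", "-1")),
                        kernel = "radial", cost = 2^log2C[a],
                        gamma = 2^log2g[b],
                        class.weights = c("1" = 2, "-1" = 1),
                        scale = FALSE, tolerance = 1e-6)
      pr <- predict(fit, fe[test, ])
      correct <- correct + sum(as.integer(as.character(pr)) == lab[test])
    }
    oracle[a, b] <- correct / length(lab)
  }
  expect_equal(unname(gs$accuracy), oracle)
  best <- which(oracle == max(oracle), arr.ind = TRUE)
  best <- best[order(log2C[best[, 1]], log2g[best[, 2]]), , drop = FALSE]
  expect_equal(gs$cost, 2^log2C[best[1, 1]])
  expect_equal(gs$gamma, 2^log2g[best[1, 2]])

  # a 1 x 1 grid returns that point; the default grid contains the
  # published operating point
  tiny <- gridSearchCostGamma(fe, lab, log2C = 3, log2gamma = -2, folds = 5,
                              seed = 3)
  expect_equal(tiny$cost, 8)
  expect_equal(tiny$gamma, 0.25)
  expect_true(4.5 %in% seq(-5, 15, by = 0.5))
  expect_true(-5 %in% seq(-15, 3, by = 1))
  expect_equal(2^4.5, 22.62742, tolerance = 1e-6)
  expect_equal(2^-5, 0.03125)

  expect_error(gridSearchCostGamma(fe, lab, log2C = 1, log2gamma = 1,
                                   folds = 40, seed = 1), "exceeds")
})

test_that("models survive a JSON round trip with identical predictions", {
  fx <- fixtureDataset("padded")
  lab <- siteLabels(fx)
  prof <- buildBiProfile(residues(fx)[lab == 1], residues(fx)[lab == -1])
  fe <- encodeDataset(fx, prof)
  m <- trainModel(fe, lab, profile = prof, layout = attr(fe, "layout"))
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  back <- readModel(f)
  expect_identical(as.integer(predict(back, fe)), as.integer(predict(m, fe)))
  expect_equal(decisionValues(back, fe), decisionValues(m, fe))
  expect_identical(back@layout, m@layout)
  # layout mismatch is refused
  expect_error(predict(back, fe[, 1:10]), "layout mismatch")
})
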