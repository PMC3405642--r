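test_that("nucleotide encoding is the A=1,G=2,C=3,T=4 bijection", {
  raw <- matrix(c("A", "G", "C", "T"), nrow = 1,
                dimnames = list("s1", c(10, 20, 30, 40)))
  gm <- encodeGenotypes(raw, "X")
  expect_identical(unname(genotypeCodes(gm)[, 1L]), 1:4)

  allA <- matrix("A", 3, 4, dimnames = list(paste0("s", 1:3), 1:4))
  expect_true(all(genotypeCodes(encodeGenotypes(allA, "X")) == 1L))

  # round-trip identity on a random matrix
  withr::with_seed(3, {
    rnd <- matrix(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  10, 20, dimnames = list(paste0("s", 1:10), 1:20))
  })
  expect_identical(decodeGenotypes(encodeGenotypes(rnd, "X")), rnd)

  # unknown letters become missing (0) with a message
  withN <- matrix(c("A", "N", "-", "T"), nrow = 1,
                  dimnames = list("s1", 1:4))
  expect_message(gmN <- encodeGenotypes(withN, "X"), "2 cell")
  expect_identical(unname(genotypeCodes(gmN)[, 1L]), c(1L, 0L, 0L, 4L))
})

test_that("genotype matrices round-trip through TSV", {
  withr::with_seed(4, {
    rnd <- matrix(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  6, 10, dimnames = list(paste0("s", 1:6),
                                         sort(sample(16569, 10))))
  })
  gm <- encodeGenotypes(rnd, rep(c("a", "b"), each = 3))
  path <- tempfile(fileext = ".tsv")
  writeGenotypesTsv(gm, path)
  back <- readGenotypesTsv(path)
  expect_identical(genotypeCodes(back), genotypeCodes(gm))
  expect_identical(classLabels(back), classLabels(gm))
  expect_identical(loci(back), loci(gm))
})

test_that("stratified split reproduces the printed 2/3 arithmetic", {
  cases <- list(c(96L, 64L), c(112L, 75L), c(3L, 2L))
  for (cs in cases) {
    sp <- splitTrainValidation(rep("x", cs[1L]), seed = 1)
    expect_length(sp$train, cs[2L])
    expect_length(sp$validation, cs[1L] - cs[2L])
    expect_identical(sort(c(sp$train, sp$validation)), seq_len(cs[1L]))
  }
  # per-class stratification
  labels <- rep(c("a", "b"), c(96L, 112L))
  sp <- splitTrainValidation(labels, seed = 9)
  expect_identical(sum(labels[sp$train] == "a"), 64L)
  expect_identical(sum(labels[sp$train] == "b"), 75L)
  # deterministic given seed, different across seeds
  expect_identical(splitTrainValidation(labels, seed = 9), sp)
  expect_false(identical(splitTrainValidation(labels, seed = 10), sp))
  expect_error(splitTrainValidation("x", seed = 1), "fewer than 2")
})

test_that("prediction matches the Gaussian weighted-sum formula", {
  center <- matrix(c(1, 2, 3, 4), nrow = 1)
  model <- new("RBFModel", centers = center, widths = 1, weights = 1,
               bias = 0, loci = c(10L, 20L, 30L, 40L),
               positiveClass = "X", trainIds = "t",
               validationIds = "v")
  # at the center the basis value is 1, so the score equals the weight
  expect_equal(unname(predict(model, c(1, 2, 3, 4))), 1)
  # at distance d the raw score is exp(-d^2/2); oracle = direct formula
  for (d in c(0.5, 1, 2, 3.7)) {
    x <- c(1 + d, 2, 3, 4)
    expect_equal(unname(predict(model, x, type = "raw")), exp(-d^2 / 2))
  }
  # zero weights and bias give zero everywhere
  zero <- new("RBFModel", centers = center, widths = 1, weights = 0,
              bias = 0, loci = c(10L, 20L, 30L, 40L), positiveClass = "X",
              trainIds = "t", validationIds = "v")
  expect_identical(unname(predict(zero, c(4, 3, 2, 1))), 0)
  expect_error(predict(model, c(1, 2)), "loci")
})

test_that("training separates planted point clouds perfectly", {
  gm <- make_separated_cohort()
  fit <- trainRBF(gm, "pos", m = 2L, seed = 1)
  prob <- predict(fit, gm)
  expect_true(all(prob >= 0 & prob <= 1))
  truth <- classLabels(gm) == "pos"
  # validation accuracy 1.0 at threshold 0.5; oracle = nearest centroid
  expect_identical(unname(prob > 0.5), unname(truth))
})

test_that("training is deterministic for a fixed seed", {
  tabs <- test_tabs
  spec <- simCohortSpec(
    list(list(classLabel = "AD", n = 24L, mixture = c(G2a = 0.6)),
         list(classLabel = "PD", n = 24L, mixture = c(B5b = 0.6))),
    carrierCompleteness = 0.9, noiseRate = 2)
  sim <- simulateCohort(spec, tabs, test_ref, seed = 2)
  f1 <- trainRBF(sim$genotypes, "AD", m = 4L, seed = 5)
  f2 <- trainRBF(sim$genotypes, "AD", m = 4L, seed = 5)
  expect_identical(f1@weights, f2@weights)
  expect_identical(f1@centers, f2@centers)
  expect_identical(f1@trainIds, f2@trainIds)
})

test_that("constant zero targets fit to near-zero predictions", {
  withr::with_seed(6, {
    X <- matrix(sample(1:4, 80, replace = TRUE), 20, 4)
  })
  fit <- mtHaploDx:::fitRBF(X, rep(0, 20L), m = 4L, seed = 1, ridge = 1e-6)
  raw <- fit$bias +
    mtHaploDx:::rbfDesign(X, fit$centers, fit$widths) %*% fit$weights
  expect_lt(max(abs(raw)), 1e-6)
})

test_that("degenerate and invalid training inputs error cleanly", {
  gm <- make_separated_cohort(nPer = 6L)
  expect_error(trainRBF(gm, "absent"), "no samples")
  expect_error(trainRBF(gm, "pos", m = 1000L, seed = 1), "exceeds")
  # all-identical rows fall back to a single effective center
  raw <- matrix("A", 8, 5, dimnames = list(paste0("s", 1:8), 1:5))
  gmFlat <- encodeGenotypes(raw, rep(c("pos", "neg"), each = 4))
  fit <- trainRBF(gmFlat, "pos", m = 4L, seed = 1)
  expect_identical(nrow(fit@centers), 1L)
})

test_that("model persistence round-trips bit-exactly", {
  gm <- make_separated_cohort()
  fit <- trainRBF(gm, "pos", m = 2L, seed = 3)
  path <- tempfile(fileext = ".txt")
  writeRBFModel(fit, path)
  back <- readRBFModel(path)
  for (slot in c("centers", "widths", "weights", "bias", "loci",
                 "positiveClass", "trainIds", "validationIds"))
    expect_identical(methods::slot(back, slot), methods::slot(fit, slot))
  expect_identical(predict(back, gm, type = "raw"),
                   predict(fit, gm, type = "raw"))
  notModel <- tempfile()
  dput(list(format = "other"), notModel)
  expect_error(readRBFModel(notModel), "not an mtHaploDx")
})

test_that("reported probabilities always lie in [0,1]", {
  spec <- simCohortSpec(
    list(list(classLabel = "AD", n = 30L, mixture = c(G2a = 0.5)),
         list(classLabel = "T2D", n = 30L, mixture = c(D4b2b = 0.5))),
    carrierCompleteness = 0.85, noiseRate = 3)
  sim <- simulateCohort(spec, test_tabs, test_ref, seed = 8)
  fit <- trainRBF(sim$genotypes, "AD", seed = 8)
  prob <- predict(fit, sim$genotypes)
  expect_true(all(prob >= 0 & prob <= 1))
})
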