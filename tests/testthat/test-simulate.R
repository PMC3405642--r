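test_that("complete noise-free carriers match their source exactly", {
  spec <- simCohortSpec(
    list(list(classLabel = "AD", n = 20L,
              mixture = c(G2a = 0.5, N9b1 = 0.3))),
    carrierCompleteness = 1, noiseRate = 0)
  sim <- simulateCohort(spec, test_tabs, test_ref, seed = 3)
  expect_identical(nrow(sim$truth), 20L)
  expect_identical(sum(sim$truth$haplogroup == "G2a", na.rm = TRUE), 10L)
  expect_identical(sum(sim$truth$haplogroup == "N9b1", na.rm = TRUE), 6L)
  for (i in which(!is.na(sim$truth$haplogroup))) {
    src <- sim$truth$haplogroup[i]
    v <- sim$variants[[sim$truth$sample[i]]]
    r <- computeMatchRatio(v, getProfile(test_tabs$AD, src))
    e <- profileEntries(getProfile(test_tabs$AD, src))
    # one allele per locus: a twice-listed locus contributes one match
    expect_identical(r$matched, length(unique(e$locus)))
    a <- assignHaplogroup(v, test_tabs$AD)
    expect_identical(a$haplogroup, src)
  }
  # background individuals carry nothing at completeness 1 / noise 0
  bg <- sim$truth$sample[is.na(sim$truth$haplogroup)]
  expect_true(all(lengths(sim$variants[bg]) == 0L))
})

test_that("simulation is a pure function of (spec, seed)", {
  spec <- simCohortSpec(
    list(list(classLabel = "PD", n = 12L, mixture = c(B5b = 0.6))),
    carrierCompleteness = 0.9, noiseRate = 2)
  s1 <- simulateCohort(spec, test_tabs, test_ref, seed = 7)
  s2 <- simulateCohort(spec, test_tabs, test_ref, seed = 7)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$variants, variantAlleles),
                   lapply(s2$variants, variantAlleles))
  expect_identical(genotypeCodes(s1$genotypes),
                   genotypeCodes(s2$genotypes))
  s3 <- simulateCohort(spec, test_tabs, test_ref, seed = 8)
  expect_false(identical(lapply(s1$variants, variantAlleles),
                         lapply(s3$variants, variantAlleles)))
})

test_that("noise never lands on the individual's own profile loci", {
  spec <- simCohortSpec(
    list(list(classLabel = "T2D", n = 30L, mixture = c(D4b2b = 1))),
    carrierCompleteness = 0.5, noiseRate = 5)
  sim <- simulateCohort(spec, test_tabs, test_ref, seed = 9)
  own <- profileEntries(getProfile(test_tabs$T2D, "D4b2b"))
  for (sid in sim$truth$sample) {
    v <- sim$variants[[sid]]
    onProfile <- variantLoci(v) %in% own$locus
    # every on-profile variant carries the profile's mutant allele
    if (any(onProfile)) {
      al <- variantAlleles(v)[onProfile]
      ok <- vapply(seq_along(al), function(i) {
        l <- as.integer(names(al)[i])
        al[[i]] %in% own$mutant[own$locus == l]
      }, logical(1))
      expect_true(all(ok))
    }
    # noise alleles are non-reference at their locus
    noise <- variantAlleles(v)[!onProfile]
    if (length(noise)) {
      refs <- vapply(as.integer(names(noise)), function(l)
        substring(test_ref, l, l), character(1))
      expect_true(all(unname(noise) != refs))
    }
  }
})

test_that("the genotype matrix encodes carriers consistently", {
  spec <- simCohortSpec(
    list(list(classLabel = "AD", n = 10L, mixture = c(G2a = 1))),
    carrierCompleteness = 1, noiseRate = 0)
  sim <- simulateCohort(spec, test_tabs, test_ref, seed = 4)
  gm <- sim$genotypes
  letters <- decodeGenotypes(gm)
  e <- profileEntries(getProfile(test_tabs$AD, "G2a"))
  e <- e[!duplicated(e$locus), ]
  for (i in seq_len(nrow(e)))
    expect_true(all(letters[, as.character(e$locus[i])] == e$mutant[i]))
  expect_identical(unname(classLabels(gm)), sim$truth$classLabel)
})

test_that("unknown mixtures and classes are rejected", {
  expect_error(simulateCohort(
    simCohortSpec(list(list(classLabel = "AD", n = 5L,
                            mixture = c(ZZZ = 1)))),
    test_tabs, test_ref, seed = 1), "unknown haplogroup")
  expect_error(simulateCohort(
    simCohortSpec(list(list(classLabel = "Nope", n = 5L))),
    test_tabs, test_ref, seed = 1), "no profile table")
  expect_error(simCohortSpec(list(list(classLabel = "AD", n = 5L)),
                             carrierCompleteness = 1.2), "\\[0, 1\\]")
})

test_that("YAML cohort specs load with defaults", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("classes:",
               "  - classLabel: AD",
               "    n: 8",
               "    mixture:",
               "      G2a: 0.5",
               "  - classLabel: PD",
               "    n: 4",
               "noiseRate: 1"), path)
  spec <- readSimSpec(path)
  expect_identical(length(spec@classes), 2L)
  expect_identical(spec@classes[[1L]]$mixture, c(G2a = 0.5))
  expect_identical(spec@carrierCompleteness, 0.9)
  expect_identical(spec@noiseRate, 1)
})

test_that("null cohorts yield no stable dominant haplogroup", {
  # positive and negative classes identically distributed: the selected
  # top individuals should not recover one planted haplogroup reliably
  spec <- simCohortSpec(
    list(list(classLabel = "AD", n = 48L,
              mixture = c(G2a = 0.5, N9b1 = 0.5)),
         list(classLabel = "PD", n = 48L,
              mixture = c(B5b = 0.5, G1a = 0.5))),
    carrierCompleteness = 0.95, noiseRate = 2)
  sim <- simulateCohort(spec, test_tabs, test_ref, seed = 13)
  fit <- trainRBF(sim$genotypes, "AD", m = 4L, seed = 13)
  pos <- sampleIds(sim$genotypes)[classLabels(sim$genotypes) == "AD"]
  sel <- selectModifiedCluster(predict(fit, sim$genotypes,
                                       type = "raw")[pos], topN = 15L)
  assoc <- associateSubset(sim$variants[selectedIds(sel)], test_tabs$AD)
  # both planted haplogroups appear; neither takes the whole subset
  expect_setequal(assoc$haplogroup, c("G2a", "N9b1"))
  expect_true(all(assoc$percent < 100L))
})
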