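test_that("worked match ratios and missing loci reproduce exactly", {
  g2a <- getProfile(test_tabs$AD, "G2a")
  r <- computeMatchRatio(worked_cases$case_AD, g2a)
  expect_identical(r$matched, 11L)
  expect_identical(r$total, 13L)
  expect_equal(r$ratio, 11 / 13)
  expect_identical(sort(r$missingLoci), c(14200L, 16278L))

  b5b <- getProfile(test_tabs$PD, "B5b")
  r <- computeMatchRatio(worked_cases$case_PD, b5b)
  expect_identical(c(r$matched, r$total), c(10L, 12L))

  d4b2b <- getProfile(test_tabs$T2D, "D4b2b")
  r <- computeMatchRatio(worked_cases$case_T2D, d4b2b)
  expect_identical(c(r$matched, r$total), c(11L, 13L))

  d4b2a <- getProfile(test_tabs$Centenarian, "D4b2a")
  r <- computeMatchRatio(worked_cases$case_CENT, d4b2a)
  expect_identical(c(r$matched, r$total), c(13L, 15L))
})

test_that("ratio rendering rounds half away from zero at 3 decimals", {
  expect_identical(renderRatio(11 / 13), 0.846)
  expect_identical(renderRatio(13 / 15), 0.867)
  expect_identical(renderRatio(10 / 12), 0.833)
  expect_identical(renderRatio(10 / 12, digits = 2L), 0.83)
  expect_identical(renderRatio(0.0005), 0.001)
})

test_that("ratio extremes behave: empty set 0, full carrier 1", {
  for (tab in test_tabs)
    for (p in profiles(tab)) {
      r0 <- computeMatchRatio(VariantSet("empty"), p)
      expect_identical(r0$matched, 0L)
      expect_identical(r0$ratio, 0)
      expect_identical(sort(r0$missingLoci),
                       sort(profileEntries(p)$locus))
      e <- profileEntries(p)
      # a twice-listed locus cannot be fully carried (one allele/locus);
      # drop duplicate-locus entries to build the carrier
      ec <- e[!duplicated(e$locus), ]
      full <- computeMatchRatio(VariantSet("full", ec$locus, ec$mutant), p)
      expect_identical(full$matched, nrow(ec))
      expect_identical(full$ratio == 1, nrow(ec) == nrow(e))
    }
})

test_that("profile-matching mutations raise ratios, others never do", {
  withr::with_seed(51, {
    vs <- lapply(1:40, function(i)
      randomVariantSet(sprintf("v%02d", i), sample(0:12, 1L)))
  })
  p <- getProfile(test_tabs$T2D, "D4b2b")
  e <- profileEntries(p)
  for (v in vs) {
    base <- computeMatchRatio(v, p)
    # brute-force oracle equivalence
    oracle <- bruteMatchRatio(v, p)
    expect_identical(base$matched, oracle$matched)
    expect_equal(base$ratio, oracle$ratio)
    expect_true(base$ratio >= 0 && base$ratio <= 1)
    # add a missing profile mutation -> ratio increases
    miss <- setdiff(e$locus, variantLoci(v))
    if (length(miss)) {
      l <- miss[1L]
      v2 <- VariantSet("aug", c(variantLoci(v), l),
                       c(unname(variantAlleles(v)),
                         e$mutant[e$locus == l][1L]))
      expect_gt(computeMatchRatio(v2, p)$ratio, base$ratio)
    }
    # add a non-profile mutation -> ratio unchanged
    free <- setdiff(1:16569, c(e$locus, variantLoci(v)))[1L]
    v3 <- VariantSet("noise", c(variantLoci(v), free),
                     c(unname(variantAlleles(v)), "A"))
    expect_identical(computeMatchRatio(v3, p)$ratio, base$ratio)
  }
})

test_that("allele matching distinguishes mutant from merely non-normal", {
  p <- getProfile(test_tabs$AD, "G2a")
  e <- profileEntries(p)
  # observed allele differs from both normal and mutant at every locus
  other <- vapply(seq_len(nrow(e)), function(i)
    setdiff(c("A", "C", "G", "T"), c(e$normal[i], e$mutant[i]))[1L],
    character(1))
  v <- VariantSet("odd", e$locus, other)
  expect_identical(computeMatchRatio(v, p)$matched, 0L)
  expect_identical(computeMatchRatio(v, p, requireAlleleMatch = FALSE)
                   $matched, nrow(e))
})

test_that("diagnose flags strictly above the threshold and sorts", {
  rep <- diagnose(worked_cases$case_T2D, test_tabs)
  e <- reportEntries(rep)
  expect_false(is.unsorted(rev(e$ratio)))
  expect_identical(e$flagged, e$ratio > 0.8)
  top <- e[e$classLabel == "T2D" & e$haplogroup == "D4b2b", ]
  expect_identical(c(top$matched, top$total), c(11L, 13L))
  expect_identical(top$rendered, 0.846)
  expect_true(top$flagged)

  # a ratio exactly at the threshold is not flagged
  p <- HaplogroupProfile("H", "X", data.frame(
    locus = 1:5, normal = rep("A", 5), mutant = rep("G", 5)))
  tab <- ProfileTable(list(p))
  v <- VariantSet("s", 1:4, rep("G", 4))  # 4/5 = 0.8
  expect_false(reportEntries(diagnose(v, tab, threshold = 0.8))$flagged)
  expect_true(reportEntries(diagnose(v, tab, threshold = 0.79))$flagged)

  expect_error(diagnose(worked_cases$case_AD, list()), "no profile")
  expect_error(diagnose(worked_cases$case_AD, test_tabs, threshold = 1.2),
               "in \\(0, 1\\)")
})

test_that("zero-overlap individuals get all-zero unflagged reports", {
  profLoci <- unique(unlist(lapply(test_tabs, function(tab)
    lapply(profiles(tab), function(p) profileEntries(p)$locus))))
  free <- setdiff(1:16569, profLoci)[1:5]
  v <- VariantSet("none", free, rep("A", 5L))
  e <- reportEntries(diagnose(v, test_tabs))
  expect_true(all(e$ratio == 0))
  expect_false(any(e$flagged))
})

test_that("batch diagnosis equals independent single calls", {
  withr::with_seed(61, {
    vs <- lapply(1:100, function(i)
      randomVariantSet(sprintf("b%03d", i), sample(0:15, 1L)))
  })
  names(vs) <- vapply(vs, sampleId, character(1))
  batch <- diagnoseBatch(vs, test_tabs)
  expect_identical(names(batch), names(vs))
  for (i in c(1L, 27L, 58L, 100L))
    expect_identical(reportEntries(batch[[i]]),
                     reportEntries(diagnose(vs[[i]], test_tabs)))
  expect_length(diagnoseBatch(list(), test_tabs), 0L)

  # the four worked examples in one batch, top ratios in order
  reps <- diagnoseBatch(worked_cases, test_tabs["AD"])
  top <- vapply(reps, function(r) reportEntries(r)$ratio[1L], numeric(1))
  expect_equal(unname(top["case_AD"]), 11 / 13)
})

test_that("diagnosis TSV carries matched/total and missing loci", {
  rep <- diagnose(worked_cases$case_AD, test_tabs["AD"])
  path <- tempfile(fileext = ".tsv")
  writeDiagnosisTsv(rep, path)
  df <- read.delim(path)
  g2a <- df[df$haplogroup == "G2a", ]
  expect_identical(c(g2a$matched, g2a$total), c(11L, 13L))
  expect_identical(g2a$missing_loci, "14200,16278")
})
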