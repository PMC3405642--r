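#' Render a match ratio at fixed decimals
#'
#' Rounds half away from zero, the convention used for all printed ratios
#' (11/13 renders as 0.846, 13/15 as 0.867, 10/12 as 0.833 at three
#' decimals).
#'
#' @param ratio numeric ratio in `[0, 1]`.
#' @param digits decimal places, default 3.
#' @return the rounded numeric value.
#' @export
renderRatio <- function(ratio, digits = 3L) {
  roundHalfAway(ratio, digits)
}

#' Match ratio of a person's mutations against one haplogroup profile
#'
#' The diagnostic statistic: the number of the profile's defining entries
#' (locus, mutant allele) present in the person's variant set, divided by
#' the profile size. Mutations outside the profile never affect the
#' ratio. A profile listing one locus twice with different mutant alleles
#' counts both entries in the denominator.
#'
#' @param v a [VariantSet-class].
#' @param profile a [HaplogroupProfile-class].
#' @param requireAlleleMatch if `TRUE` (default) the observed allele must
#'   equal the entry's mutant allele; if `FALSE` any non-normal call at
#'   the entry's locus matches.
#' @return list with `matched` and `total` counts, the exact `ratio`,
#'   and integer vectors `matchedLoci` and `missingLoci` (profile entries
#'   split by match status).
#' @examples
#' tab <- readProfileTable(packagedProfilePath("ad"))
#' cases <- readVariantsTsv(system.file("extdata", "examples",
#'   "worked_cases.tsv", package = "mtHaploDx"))
#' r <- computeMatchRatio(cases$case_AD, getProfile(tab, "G2a"))
#' c(r$matched, r$total)     # 11 13
#' renderRatio(r$ratio)      # 0.846
#' r$missingLoci             # 14200 16278
#' @export
computeMatchRatio <- function(v, profile, requireAlleleMatch = TRUE) {
  stopifnot(methods::is(v, "VariantSet"),
            methods::is(profile, "HaplogroupProfile"))
  e <- profile@entries
  idx <- match(e$locus, v@loci)
  hasCall <- !is.na(idx)
  hit <- hasCall & if (requireAlleleMatch)
    v@alleles[ifelse(hasCall, idx, 1L)] == e$mutant
  else
    v@alleles[ifelse(hasCall, idx, 1L)] != e$normal
  total <- nrow(e)
  matched <- sum(hit)
  list(matched = matched, total = total, ratio = matched / total,
       matchedLoci = e$locus[hit], missingLoci = e$locus[!hit])
}

#' Diagnose a person against all loaded haplogroup profile tables
#'
#' Computes the match ratio of the person's mtDNA mutations against every
#' (class, haplogroup) profile and flags the entries whose ratio is
#' strictly greater than the decision threshold: a flagged entry means the
#' person's likelihood of belonging to that study class (getting the
#' disease, or reaching extreme age) is elevated relative to ordinary
#' healthy persons. Entries are sorted by descending ratio.
#'
#' @param v a [VariantSet-class].
#' @param tables a [ProfileTable-class] or list of them.
#' @param threshold decision threshold in (0, 1), default 0.8; the flag
#'   uses strict `ratio > threshold`.
#' @param requireAlleleMatch passed to [computeMatchRatio()].
#' @return a [DiagnosisReport-class].
#' @examples
#' cases <- readVariantsTsv(system.file("extdata", "examples",
#'   "worked_cases.tsv", package = "mtHaploDx"))
#' diagnose(cases$case_CENT, packagedProfileTables())
#' @export
diagnose <- function(v, tables, threshold = 0.8,
                     requireAlleleMatch = TRUE) {
  stopifnot(methods::is(v, "VariantSet"))
  if (methods::is(tables, "ProfileTable")) tables <- list(tables)
  if (!length(tables)) stop("no profile tables loaded", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  rows <- list()
  for (tab in tables) {
    for (p in profiles(tab)) {
      r <- computeMatchRatio(v, p, requireAlleleMatch)
      rows[[length(rows) + 1L]] <- data.frame(
        classLabel = classLabel(tab), haplogroup = haplogroupName(p),
        matched = r$matched, total = r$total, ratio = r$ratio,
        rendered = renderRatio(r$ratio), flagged = r$ratio > threshold,
        matchedLoci = I(list(r$matchedLoci)),
        missingLoci = I(list(r$missingLoci)))
    }
  }
  entries <- do.call(rbind, rows)
  entries <- entries[order(-entries$ratio, entries$classLabel,
                           entries$haplogroup), ]
  rownames(entries) <- NULL
  methods::new("DiagnosisReport", sampleId = sampleId(v),
               threshold = threshold, entries = entries)
}

#' Diagnose a batch of variant sets
#'
#' Independent per-sample reports, order preserved; errors gain the
#' offending sample id as context.
#'
#' @param variantSets list of [VariantSet-class] objects.
#' @param tables,threshold,requireAlleleMatch as in [diagnose()].
#' @return list of [DiagnosisReport-class], named by sample id.
#' @export
diagnoseBatch <- function(variantSets, tables, threshold = 0.8,
                          requireAlleleMatch = TRUE) {
  out <- lapply(variantSets, function(v)
    tryCatch(diagnose(v, tables, threshold, requireAlleleMatch),
             error = function(e)
               stopf("sample %s: %s", sampleId(v), conditionMessage(e))))
  names(out) <- vapply(out, sampleId, character(1))
  out
}

#' Write diagnosis reports as TSV
#'
#' Columns: `sample`, `class`, `haplogroup`, `matched`, `total`, `ratio`
#' (rendered at 3 decimals), `flagged`, `missing_loci` (comma-separated).
#'
#' @param reports a [DiagnosisReport-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDiagnosisTsv <- function(reports, path) {
  if (methods::is(reports, "DiagnosisReport")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    e <- r@entries
    data.frame(sample = r@sampleId, class = e$classLabel,
               haplogroup = e$haplogroup, matched = e$matched,
               total = e$total, ratio = sprintf("%.3f", e$rendered),
               flagged = e$flagged,
               missing_loci = vapply(e$missingLoci, paste, character(1),
                                     collapse = ","))
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
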