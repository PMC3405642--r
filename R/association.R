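#' Per-position nucleotide summaries of a selected subset
#'
#' For every locus at which at least one subset member carries a
#' non-reference allele, counts the carriers of the most frequent mutant
#' allele (Y), the carriers of the normal (reference) allele (X, members
#' with no recorded variant at the locus carry the reference implicitly),
#' and carriers of any other allele. Each summary renders as
#' `"locus N>M (Y/X)"`, e.g. `"16362 T>C (9/6)"`.
#'
#' @param subset list of [VariantSet-class] objects (the selected
#'   individuals).
#' @param reference the rCRS reference (16,569-nt string or `DNAString`).
#' @return data.frame with columns `locus`, `normal`, `mutant`, `mutCount`
#'   (Y), `normCount` (X), `otherCount`, `rendered`, ordered by locus;
#'   zero rows when the subset carries no variation.
#' @examples
#' ref <- syntheticReference()
#' vs <- list(VariantSet("a", 16362L, "C"), VariantSet("b", 16362L, "C"),
#'            VariantSet("c"))
#' summarizePositions(vs, ref)$rendered  # "16362 T>C (2/1)"
#' @export
summarizePositions <- function(subset, reference) {
  if (!length(subset)) stop("subset must be non-empty", call. = FALSE)
  if (methods::is(subset, "VariantSet")) subset <- list(subset)
  reference <- checkReference(reference)
  n <- length(subset)
  df <- do.call(rbind, lapply(subset, as.data.frame))
  if (is.null(df) || !nrow(df)) {
    out <- data.frame(locus = integer(), normal = character(),
                      mutant = character(), mutCount = integer(),
                      normCount = integer(), otherCount = integer(),
                      rendered = character())
    return(out)
  }
  out <- lapply(sort(unique(df$locus)), function(l) {
    normal <- refBase(reference, l)
    obs <- df$allele[df$locus == l]
    nonref <- obs[obs != normal]
    if (!length(nonref)) return(NULL)  # recorded calls all equal reference
    counts <- sort(table(nonref), decreasing = TRUE)
    ## modal mutant allele; ties broken alphabetically (sort is stable on
    ## the already-alphabetical table names)
    mutant <- names(counts)[1L]
    y <- as.integer(counts[1L])
    other <- length(nonref) - y
    x <- n - length(df$locus[df$locus == l])  # implicit reference carriers
    x <- x + sum(obs == normal)
    data.frame(locus = l, normal = normal, mutant = mutant,
               mutCount = y, normCount = x, otherCount = other,
               rendered = sprintf("%d %s>%s (%d/%d)", l, normal, mutant,
                                  y, x))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(locus = integer(), normal = character(),
                      mutant = character(), mutCount = integer(),
                      normCount = integer(), otherCount = integer(),
                      rendered = character())
  rownames(out) <- NULL
  out
}

#' Assign a person to the best-matching haplogroup of a profile table
#'
#' Scores every profile by the fraction of its defining entries present in
#' the person's variant set and returns the best. Ties are broken in
#' favour of the larger profile, then by name order.
#'
#' @param v a [VariantSet-class].
#' @param table a [ProfileTable-class].
#' @param requireAlleleMatch if `TRUE` (default) a variant matches an
#'   entry only when its observed allele equals the entry's mutant allele;
#'   otherwise any non-reference call at the locus counts.
#' @return list with `haplogroup` (name, or `NA` for an empty variant
#'   set) and `fraction` (matched entries / profile size).
#' @examples
#' tab <- readProfileTable(packagedProfilePath("ad"))
#' g2a <- profileEntries(getProfile(tab, "G2a"))
#' v <- VariantSet("carrier", g2a$locus, g2a$mutant)
#' assignHaplogroup(v, tab)  # G2a, fraction 1
#' @export
assignHaplogroup <- function(v, table, requireAlleleMatch = TRUE) {
  stopifnot(methods::is(v, "VariantSet"), methods::is(table, "ProfileTable"))
  if (!length(v@loci))
    return(list(haplogroup = NA_character_, fraction = 0))
  fr <- vapply(profiles(table), function(p)
    computeMatchRatio(v, p, requireAlleleMatch = requireAlleleMatch)$ratio,
    numeric(1))
  sizes <- vapply(profiles(table), profileSize, integer(1))
  ord <- order(-fr, -sizes, names(fr))
  list(haplogroup = names(fr)[ord[1L]], fraction = unname(fr[ord[1L]]))
}

#' Associate a selected subset with haplogroups
#'
#' Assigns each subset member to its best-matching haplogroup via
#' [assignHaplogroup()]; members whose best match fraction is below
#' `minFraction` stay unassigned. Reports, per haplogroup, the percentage
#' of subset members assigned (rounded to whole percent, half away from
#' zero: 8 of 15 gives 53\%, 3 of 15 gives 20\%).
#'
#' @param subset list of [VariantSet-class] objects.
#' @param table a [ProfileTable-class].
#' @param minFraction minimum match fraction for an assignment to count,
#'   default 0.5 (cohort association tolerates partial profiles; distinct
#'   from the diagnostic 0.8 threshold).
#' @param requireAlleleMatch passed to [assignHaplogroup()].
#' @return data.frame with columns `haplogroup`, `percent`, `nAssigned`,
#'   `subsetSize`, in descending percentage; attributes `classLabel` and
#'   `assignments` (per-member haplogroup or `NA`).
#' @export
associateSubset <- function(subset, table, minFraction = 0.5,
                            requireAlleleMatch = TRUE) {
  if (!length(subset)) stop("subset must be non-empty", call. = FALSE)
  if (methods::is(subset, "VariantSet")) subset <- list(subset)
  asn <- vapply(subset, function(v) {
    a <- assignHaplogroup(v, table, requireAlleleMatch)
    if (!is.na(a$haplogroup) && a$fraction >= minFraction) a$haplogroup
    else NA_character_
  }, character(1))
  names(asn) <- vapply(subset, sampleId, character(1))
  n <- length(subset)
  counts <- table(factor(asn, levels = haplogroupNames(table)))
  keep <- counts > 0L
  out <- data.frame(haplogroup = names(counts)[keep],
                    percent = as.integer(
                      roundHalfAway(100 * as.integer(counts[keep]) / n)),
                    nAssigned = as.integer(counts[keep]),
                    subsetSize = n)
  out <- out[order(-out$percent, out$haplogroup), ]
  rownames(out) <- NULL
  attr(out, "classLabel") <- classLabel(table)
  attr(out, "assignments") <- asn
  out
}

#' Write an association report as TSV
#'
#' Columns: `haplogroup`, `percent`, `n_assigned`, `subset_size`.
#'
#' @param report data.frame from [associateSubset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssociationTsv <- function(report, path) {
  df <- data.frame(haplogroup = report$haplogroup,
                   percent = report$percent,
                   n_assigned = report$nAssigned,
                   subset_size = report$subsetSize)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
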