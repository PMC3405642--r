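#' Construct a haplogroup defining-SNP profile
#'
#' @param haplogroup haplogroup name, e.g. `"G2a"`.
#' @param classLabel study-class label, e.g. `"AD"`.
#' @param entries data.frame with columns `locus` (1-based rCRS position),
#'   `normal` and `mutant` (single nucleotides). Entry order is preserved;
#'   the same locus may recur with a different mutant allele and both
#'   entries count toward the profile size.
#' @return a [HaplogroupProfile-class].
#' @examples
#' HaplogroupProfile("toy", "demo",
#'   data.frame(locus = c(100L, 200L), normal = c("A", "C"),
#'              mutant = c("G", "T")))
#' @export
HaplogroupProfile <- function(haplogroup, classLabel, entries) {
  entries <- as.data.frame(entries)[, c("locus", "normal", "mutant")]
  entries$locus <- as.integer(entries$locus)
  entries$normal <- toupper(as.character(entries$normal))
  entries$mutant <- toupper(as.character(entries$mutant))
  rownames(entries) <- NULL
  methods::new("HaplogroupProfile", haplogroup = as.character(haplogroup),
               classLabel = as.character(classLabel), entries = entries)
}

#' Construct a profile table from a list of profiles
#'
#' @param profiles list of [HaplogroupProfile-class] objects sharing one
#'   class label.
#' @param classLabel the shared study-class label; defaults to the label of
#'   the first profile.
#' @return a [ProfileTable-class].
#' @export
ProfileTable <- function(profiles, classLabel = NULL) {
  if (!length(profiles)) stop("profiles must be non-empty", call. = FALSE)
  if (is.null(classLabel)) classLabel <- profiles[[1L]]@classLabel
  names(profiles) <- vapply(profiles, haplogroupName, character(1))
  methods::new("ProfileTable", classLabel = as.character(classLabel),
               profiles = profiles)
}

#' Read a haplogroup profile table from TSV
#'
#' The on-disk dialect is tab-separated with a header row
#' `locus  normal  mutant  haplogroup` and optional `#` comment lines; a
#' leading comment of the form `# class: <label>` carries the study-class
#' label. Loci are 1-based rCRS positions. Entry order within each
#' haplogroup is preserved.
#'
#' @param path path to a profile TSV file.
#' @param classLabel study-class label; if `NULL`, taken from the
#'   `# class:` header line (required then).
#' @return a validated [ProfileTable-class].
#' @examples
#' tab <- readProfileTable(packagedProfilePath("ad"))
#' profileSize(getProfile(tab, "G2a"))  # 13
#' @seealso [writeProfileTable()], [packagedProfileTables()]
#' @export
readProfileTable <- function(path, classLabel = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(classLabel)) {
    cl <- grep("^#\\s*class:", lines, value = TRUE)
    if (length(cl))
      classLabel <- trimws(sub("^#\\s*class:\\s*", "", cl[1L]))
    else
      stopf("%s: no '# class:' header and no classLabel given", path)
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stopf("%s: empty profile file", path)
  fields <- strsplit(body, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1L]]))
  need <- c("locus", "normal", "mutant", "haplogroup")
  idx <- match(need, header)
  if (anyNA(idx))
    stopf("%s: header must contain columns %s", path,
          paste(need, collapse = ", "))
  rows <- fields[-1L]
  ## line numbers in the original file, for error messages
  lineno <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))[-1L]
  recs <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    if (length(f) < max(idx))
      stopf("%s line %d: expected %d tab-separated fields, got %d",
            path, lineno[i], max(idx), length(f))
    locus <- suppressWarnings(as.integer(f[idx[1L]]))
    if (is.na(locus) || locus < 1L || locus > MT_LENGTH)
      stopf("%s line %d: locus '%s' is not an rCRS position in 1..%d",
            path, lineno[i], f[idx[1L]], MT_LENGTH)
    nn <- toupper(f[idx[2L]]); nm <- toupper(f[idx[3L]])
    if (!nn %in% NUC || !nm %in% NUC)
      stopf("%s line %d: alleles must be A/C/G/T, got '%s'>'%s'",
            path, lineno[i], f[idx[2L]], f[idx[3L]])
    if (nn == nm)
      stopf("%s line %d: normal and mutant allele are both '%s'",
            path, lineno[i], nn)
    recs[[i]] <- data.frame(locus = locus, normal = nn, mutant = nm,
                            haplogroup = f[idx[4L]])
  }
  df <- do.call(rbind, recs)
  if (anyDuplicated(df[, c("haplogroup", "locus", "mutant")]))
    stopf("%s: duplicate (haplogroup, locus, mutant) entries", path)
  groups <- unique(df$haplogroup)  # keep file order
  profs <- lapply(groups, function(g)
    HaplogroupProfile(g, classLabel, df[df$haplogroup == g, 1:3]))
  ProfileTable(profs, classLabel)
}

#' Write a profile table to TSV
#'
#' Writes the canonical tab-separated dialect read by
#' [readProfileTable()]; `readProfileTable(writeProfileTable(t))`
#' reproduces `t` exactly, including entry order.
#'
#' @param table a [ProfileTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(table, path) {
  stopifnot(methods::is(table, "ProfileTable"))
  methods::validObject(table)
  rows <- lapply(profiles(table), function(p) {
    e <- p@entries
    e$haplogroup <- p@haplogroup
    e
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# class: %s", classLabel(table)), con)
  writeLines("locus\tnormal\tmutant\thaplogroup", con)
  writeLines(sprintf("%d\t%s\t%s\t%s", df$locus, df$normal, df$mutant,
                     df$haplogroup), con)
  invisible(path)
}

#' Path to a packaged profile table
#'
#' Eight defining-SNP profile tables ship with the package, one per study
#' class: `"ad"`, `"pd"`, `"t2d"`, `"t2d_angiopathy"`, `"centenarian"`,
#' `"semi_supercentenarian"`, `"nonobese_young_male"`,
#' `"obese_young_male"`.
#'
#' @param name one of the class table names above.
#' @return path to the installed TSV file.
#' @export
packagedProfilePath <- function(name = c("ad", "pd", "t2d",
                                         "t2d_angiopathy", "centenarian",
                                         "semi_supercentenarian",
                                         "nonobese_young_male",
                                         "obese_young_male")) {
  name <- match.arg(name)
  system.file("extdata", "profiles", paste0(name, ".tsv"),
              package = "mtHaploDx", mustWork = TRUE)
}

#' Load all packaged profile tables
#'
#' @return named list of the eight packaged [ProfileTable-class] objects,
#'   keyed by their study-class labels.
#' @examples
#' tabs <- packagedProfileTables()
#' vapply(profiles(tabs$AD), profileSize, integer(1))
#' @export
packagedProfileTables <- function() {
  names <- eval(formals(packagedProfilePath)$name)
  tabs <- lapply(names, function(n) readProfileTable(packagedProfilePath(n)))
  stats::setNames(tabs, vapply(tabs, classLabel, character(1)))
}

#' Check a profile table's normal alleles against a reference sequence
#'
#' Compares every entry's normal allele with the reference base at its
#' locus and reports the disagreements; an empty report means the table is
#' consistent with the reference.
#'
#' @param table a [ProfileTable-class].
#' @param reference the rCRS reference as a single 16,569-nt character
#'   string or `Biostrings::DNAString`.
#' @return data.frame with columns `haplogroup`, `locus`, `normal`,
#'   `referenceBase`, one row per mismatching entry (zero rows when
#'   consistent).
#' @export
validateAgainstReference <- function(table, reference) {
  stopifnot(methods::is(table, "ProfileTable"))
  reference <- checkReference(reference)
  out <- lapply(profiles(table), function(p) {
    e <- p@entries
    rb <- vapply(e$locus, function(l) refBase(reference, l), character(1))
    bad <- rb != e$normal
    if (!any(bad)) return(NULL)
    data.frame(haplogroup = p@haplogroup, locus = e$locus[bad],
               normal = e$normal[bad], referenceBase = rb[bad])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(haplogroup = character(), locus = integer(),
                      normal = character(), referenceBase = character())
  rownames(out) <- NULL
  out
}
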