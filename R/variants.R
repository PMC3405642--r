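#' Construct a VariantSet
#'
#' @param sampleId sample label.
#' @param loci integer rCRS positions (1-based).
#' @param alleles observed nucleotides (A/C/G/T), parallel to `loci`.
#' @return a [VariantSet-class].
#' @examples
#' VariantSet("p1", c(709L, 16362L), c("A", "C"))
#' @export
VariantSet <- function(sampleId, loci = integer(), alleles = character()) {
  methods::new("VariantSet", sampleId = as.character(sampleId),
               loci = as.integer(loci),
               alleles = toupper(as.character(alleles)))
}

#' Coerce a VariantSet to a data.frame
#'
#' @param x a [VariantSet-class].
#' @param row.names,optional,... ignored; present for signature
#'   compatibility.
#' @return data.frame with columns `sample`, `locus`, `allele`.
#' @export
as.data.frame.VariantSet <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(sample = rep(x@sampleId, length(x@loci)), locus = x@loci,
             allele = x@alleles)
}

#' Read per-individual variant sets from TSV
#'
#' The variant dialect is tab-separated with a header `sample  locus
#' allele` and optional `#` comment lines: one row per observed mtDNA
#' mutation, loci in 1-based rCRS coordinates.
#'
#' @param path path to a variant TSV file.
#' @return named list of [VariantSet-class] objects, one per distinct
#'   sample, in order of first appearance.
#' @examples
#' cases <- readVariantsTsv(system.file("extdata", "examples",
#'   "worked_cases.tsv", package = "mtHaploDx"))
#' length(cases$case_AD)  # 11
#' @export
readVariantsTsv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "integer",
                                         "character"))
  need <- c("sample", "locus", "allele")
  if (!all(need %in% names(df)))
    stopf("%s: header must contain columns %s", path,
          paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(stats::setNames(list(), character()))
  df$allele <- toupper(df$allele)
  bad <- !df$allele %in% NUC
  if (any(bad))
    stopf("%s: allele '%s' for sample %s at locus %d is not A/C/G/T",
          path, df$allele[which(bad)[1L]], df$sample[which(bad)[1L]],
          df$locus[which(bad)[1L]])
  key <- paste(df$sample, df$locus)
  if (anyDuplicated(key)) {
    d <- df[key %in% key[duplicated(key)], ]
    if (any(tapply(d$allele, paste(d$sample, d$locus),
                   function(a) length(unique(a))) > 1L))
      stopf("%s: conflicting alleles at one locus for one sample", path)
    df <- df[!duplicated(key), ]
  }
  ids <- unique(df$sample)
  out <- lapply(ids, function(s) {
    rows <- df[df$sample == s, ]
    VariantSet(s, rows$locus, rows$allele)
  })
  stats::setNames(out, ids)
}

#' Write variant sets to TSV
#'
#' @param variantSets a [VariantSet-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVariantsTsv <- function(variantSets, path) {
  if (methods::is(variantSets, "VariantSet"))
    variantSets <- list(variantSets)
  df <- do.call(rbind, lapply(variantSets, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("sample\tlocus\tallele", con)
  if (!is.null(df) && nrow(df))
    writeLines(sprintf("%s\t%d\t%s", df$sample, df$locus, df$allele), con)
  invisible(path)
}

#' Read per-individual variant sets from a minimal VCF
#'
#' Reads a VCF 4.x file holding single-nucleotide variants on one
#' mitochondrial contig and returns one [VariantSet-class] per sample
#' column. Records are skipped (and counted) when their FILTER is neither
#' `PASS` nor `.`, or when an ALT allele is not a single nucleotide
#' (indels, symbolic alleles). Multiallelic records are expanded per ALT.
#' The GT field is used only to detect non-reference calls: any non-zero
#' allele index marks the sample as carrying the corresponding ALT; when a
#' call names several ALT alleles the first non-zero index is used (the
#' data model is a haploid-style consensus, one allele per locus).
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return named list of [VariantSet-class] objects, one per sample, with
#'   attribute `skipped` giving the count of skipped records.
#' @export
readVariantsVcf <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "rCRS")
  if (ncol(vcf) == 0L)
    stopf("%s: VCF has no sample columns", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  if (length(rr) &&
      length(unique(as.character(GenomeInfoDb::seqnames(rr)))) > 1L)
    stopf("%s: expected a single mitochondrial contig", path)
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- VariantAnnotation::alt(vcf)  # DNAStringSetList
  filt <- VariantAnnotation::filt(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stopf("%s: VCF has no GT field", path)
  samples <- colnames(vcf)
  acc <- lapply(samples, function(s) list(loci = integer(),
                                          alleles = character()))
  names(acc) <- samples
  skipped <- 0L
  for (r in seq_along(rr)) {
    if (!filt[r] %in% c("PASS", ".")) { skipped <- skipped + 1L; next }
    alts <- as.character(alt[[r]])
    snv <- nchar(ref[r]) == 1L & nchar(alts) == 1L & alts %in% NUC
    skipped <- skipped + sum(!snv)
    if (!any(snv)) next
    for (s in samples) {
      call <- gt[r, s]
      if (is.na(call) || call %in% c(".", "./.", ".|.")) next
      idx <- suppressWarnings(
        as.integer(strsplit(call, "[/|]")[[1L]]))
      idx <- idx[!is.na(idx) & idx > 0L]
      idx <- idx[idx <= length(alts)]
      idx <- idx[snv[idx]]
      if (!length(idx)) next
      a <- alts[idx[1L]]
      if (pos[r] %in% acc[[s]]$loci) next
      acc[[s]]$loci <- c(acc[[s]]$loci, pos[r])
      acc[[s]]$alleles <- c(acc[[s]]$alleles, a)
    }
  }
  out <- lapply(samples, function(s)
    VariantSet(s, acc[[s]]$loci, acc[[s]]$alleles))
  names(out) <- samples
  if (skipped) message(skipped, " non-SNV or filtered record(s) skipped")
  attr(out, "skipped") <- skipped
  out
}

#' Derive a VariantSet by comparing a sequence with the reference
#'
#' Position-wise comparison of a full-length mitochondrial sequence with
#' the reference: every position where the two differ becomes a variant
#' (1-based locus, observed allele).
#'
#' @param seq nucleotide sequence (character string or
#'   `Biostrings::DNAString`) of the same length as the reference.
#' @param reference the reference sequence (16,569 nt).
#' @param sampleId label for the resulting [VariantSet-class].
#' @return a [VariantSet-class]; empty when `seq` equals the reference.
#' @export
variantsFromSequence <- function(seq, reference, sampleId = "sample") {
  reference <- checkReference(reference)
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  seq <- toupper(seq)
  if (nchar(seq) != nchar(reference))
    stopf("sequence length %d does not match reference length %d",
          nchar(seq), nchar(reference))
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  r <- strsplit(reference, "", fixed = TRUE)[[1L]]
  if (!all(s %in% NUC))
    stopf("sequence letters must be A/C/G/T")
  diff <- which(s != r)
  VariantSet(sampleId, diff, s[diff])
}
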