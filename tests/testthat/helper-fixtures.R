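# shared fixtures: packaged tables, synthetic reference, random variant
# sets, and independent brute-force oracles

test_tabs <- packagedProfileTables()
test_ref <- as.character(syntheticReference(test_tabs))

worked_cases <- readVariantsTsv(system.file(
  "extdata", "examples", "worked_cases.tsv", package = "mtHaploDx"))

# random variant set with n variants at distinct loci, non-reference
# alleles drawn uniformly
randomVariantSet <- function(id, n, ref = test_ref) {
  loci <- sample(nchar(ref), n)
  alleles <- vapply(loci, function(l) {
    sample(setdiff(c("A", "C", "G", "T"), substring(ref, l, l)), 1L)
  }, character(1))
  VariantSet(id, loci, alleles)
}

# oracle: naive per-entry loop over a profile, independent of the
# vectorised implementation
bruteMatchRatio <- function(v, profile) {
  e <- profileEntries(profile)
  alleles <- variantAlleles(v)
  matched <- 0L
  for (i in seq_len(nrow(e))) {
    l <- as.character(e$locus[i])
    if (l %in% names(alleles) && alleles[[l]] == e$mutant[i])
      matched <- matched + 1L
  }
  list(matched = matched, total = nrow(e), ratio = matched / nrow(e))
}

# oracle: exhaustive best-fraction matcher over a table
bruteAssign <- function(v, table) {
  if (length(v) == 0L) return(NA_character_)
  fr <- vapply(profiles(table), function(p) bruteMatchRatio(v, p)$ratio,
               numeric(1))
  sz <- vapply(profiles(table), profileSize, integer(1))
  names(fr)[order(-fr, -sz, names(fr))][1L]
}

# oracle: per-position tally by explicit loops
brutePositionCounts <- function(subset, ref) {
  n <- length(subset)
  df <- do.call(rbind, lapply(subset, as.data.frame))
  out <- list()
  for (l in sort(unique(df$locus))) {
    normal <- substring(ref, l, l)
    obs <- df$allele[df$locus == l]
    nonref <- obs[obs != normal]
    if (!length(nonref)) next
    tab <- sort(table(nonref), decreasing = TRUE)
    mutant <- names(tab)[1L]
    out[[as.character(l)]] <- c(Y = unname(tab[1L]),
                                X = n - length(obs) + sum(obs == normal))
  }
  out
}

# linearly separable cohort: positives all "A", negatives all "T"
make_separated_cohort <- function(nPer = 30L, nLoci = 12L) {
  raw <- rbind(matrix("A", nPer, nLoci), matrix("T", nPer, nLoci))
  dimnames(raw) <- list(sprintf("s%02d", seq_len(2L * nPer)),
                        seq_len(nLoci))
  encodeGenotypes(raw, rep(c("pos", "neg"), each = nPer))
}

# minimal single-contig VCF writer for reader tests
writeTempVcf <- function(records, samples, gts) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrM,length=16569>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    paste(c("chrM", r$pos, ".", r$ref, r$alt, ".",
            if (is.null(r$filter)) "PASS" else r$filter, ".", "GT",
            gts[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}
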