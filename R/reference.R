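#' Synthetic stand-in for the rCRS mitochondrial reference
#'
#' Builds a deterministic 16,569-nt synthetic reference sequence that is
#' consistent with the packaged profile tables: at every profile locus the
#' base equals the table's normal (rCRS) allele, and all remaining
#' positions are filled with a fixed pseudo-random nucleotide stream. It
#' is NOT the real rCRS — bases away from profile loci are arbitrary — but
#' it supports reference-dependent operations (position summaries,
#' sequence-to-variant comparison, cohort simulation) with exact agreement
#' at every locus the method actually uses.
#'
#' @param tables list of [ProfileTable-class] objects whose normal alleles
#'   pin down the reference at profile loci; defaults to all packaged
#'   tables. Tables must agree wherever loci are shared.
#' @return a `Biostrings::DNAString` of length 16,569.
#' @examples
#' ref <- syntheticReference()
#' nrow(validateAgainstReference(packagedProfileTables()$AD, ref))  # 0
#' @export
syntheticReference <- function(tables = packagedProfileTables()) {
  if (methods::is(tables, "ProfileTable")) tables <- list(tables)
  pins <- do.call(rbind, lapply(tables, function(tab)
    do.call(rbind, lapply(profiles(tab), function(p)
      p@entries[, c("locus", "normal")]))))
  pins <- unique(pins)
  dup <- pins$locus[duplicated(pins$locus)]
  if (length(dup))
    stopf("conflicting normal alleles across tables at locus %s",
          paste(unique(dup), collapse = ", "))
  ## arbitrary fixed fill seed: the sequence is a synthetic constant
  bases <- withSeed(16569L, sample(NUC, MT_LENGTH, replace = TRUE))
  bases[pins$locus] <- pins$normal
  Biostrings::DNAString(paste(bases, collapse = ""))
}

#' Read a reference mitochondrial sequence from FASTA
#'
#' @param path path to a FASTA file holding a single 16,569-nt sequence.
#' @return a `Biostrings::DNAString`.
#' @export
readReferenceFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L)
    stopf("expected a single reference sequence, found %d", length(seqs))
  ref <- seqs[[1L]]
  if (length(ref) != MT_LENGTH)
    stopf("reference must be %d nt long, got %d", MT_LENGTH, length(ref))
  ref
}
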