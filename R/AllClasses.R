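#' @import methods
#' @importFrom stats kmeans dist rbinom rpois sd
#' @importFrom utils read.delim write.table head
NULL

MT_LENGTH <- 16569L
NUC <- c("A", "C", "G", "T")

## integer encoding of nucleotides used throughout the classifier:
## A=1, G=2, C=3, T=4; 0 = missing
NUC_CODE <- c(A = 1L, G = 2L, C = 3L, T = 4L)

#' HaplogroupProfile: the defining mtDNA mutations of one haplogroup
#'
#' Holds the defining-SNP profile of a single mitochondrial haplogroup for
#' one study class: a table of (locus, normal allele, mutant allele) triples
#' in 1-based rCRS coordinates. A locus may appear twice with different
#' mutant alleles; both entries count toward the profile size (the
#' denominator of the match ratio).
#'
#' @slot haplogroup single character, e.g. "G2a".
#' @slot classLabel single character study-class label, e.g. "AD".
#' @slot entries data.frame with integer column `locus` and character
#'   columns `normal`, `mutant` (alleles in A/C/G/T), in table order.
#'
#' @seealso [readProfileTable()], [computeMatchRatio()]
#' @export
setClass("HaplogroupProfile",
  representation(haplogroup = "character",
                 classLabel = "character",
                 entries = "data.frame"))

setValidity("HaplogroupProfile", function(object) {
  e <- object@entries
  msgs <- character()
  if (length(object@haplogroup) != 1L || !nzchar(object@haplogroup))
    msgs <- c(msgs, "haplogroup must be a single non-empty string")
  if (length(object@classLabel) != 1L)
    msgs <- c(msgs, "classLabel must be a single string")
  if (!all(c("locus", "normal", "mutant") %in% names(e)))
    msgs <- c(msgs, "entries must have columns locus, normal, mutant")
  else {
    if (nrow(e) == 0L)
      msgs <- c(msgs, "profile must have at least one entry")
    if (!is.integer(e$locus) || anyNA(e$locus) ||
        any(e$locus < 1L | e$locus > MT_LENGTH))
      msgs <- c(msgs, sprintf("loci must be integers in 1..%d", MT_LENGTH))
    if (!all(e$normal %in% NUC) || !all(e$mutant %in% NUC))
      msgs <- c(msgs, "alleles must be one of A, C, G, T")
    if (any(e$normal == e$mutant))
      msgs <- c(msgs, "normal and mutant allele must differ")
    if (anyDuplicated(paste(e$locus, e$mutant)))
      msgs <- c(msgs, "(locus, mutant) pairs must be unique within a profile")
  }
  if (length(msgs)) msgs else TRUE
})

#' ProfileTable: all haplogroup profiles of one study class
#'
#' @slot classLabel single character study-class label shared by all
#'   member profiles.
#' @slot profiles named list of [HaplogroupProfile-class] objects; names
#'   are the haplogroup names and must be unique.
#'
#' @seealso [readProfileTable()], [packagedProfileTables()]
#' @export
setClass("ProfileTable",
  representation(classLabel = "character", profiles = "list"))

setValidity("ProfileTable", function(object) {
  msgs <- character()
  if (length(object@classLabel) != 1L)
    msgs <- c(msgs, "classLabel must be a single string")
  if (!length(object@profiles))
    msgs <- c(msgs, "table must contain at least one profile")
  if (!all(vapply(object@profiles, is, logical(1), "HaplogroupProfile")))
    msgs <- c(msgs, "profiles must all be HaplogroupProfile objects")
  else {
    labs <- vapply(object@profiles, function(p) p@classLabel, character(1))
    if (any(labs != object@classLabel))
      msgs <- c(msgs, "all profiles must share the table's classLabel")
    nms <- vapply(object@profiles, function(p) p@haplogroup, character(1),
                  USE.NAMES = FALSE)
    if (anyDuplicated(nms))
      msgs <- c(msgs, "haplogroup names must be unique within a table")
    if (!identical(names(object@profiles), nms))
      msgs <- c(msgs, "list names must equal the haplogroup names")
  }
  if (length(msgs)) msgs else TRUE
})

#' VariantSet: one person's observed mtDNA mutations
#'
#' A set of single-nucleotide mtDNA variants for one individual, each a
#' (locus, observed allele) pair in 1-based rCRS coordinates. At most one
#' allele per locus (haploid-style consensus calls; heteroplasmy is out of
#' the data model).
#'
#' @slot sampleId single character sample label.
#' @slot loci integer vector of rCRS positions, unique, in 1..16569.
#' @slot alleles character vector of observed alleles (A/C/G/T), parallel
#'   to `loci`.
#'
#' @seealso [VariantSet()], [readVariantsTsv()], [diagnose()]
#' @export
setClass("VariantSet",
  representation(sampleId = "character", loci = "integer",
                 alleles = "character"))

setValidity("VariantSet", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L)
    msgs <- c(msgs, "sampleId must be a single string")
  if (length(object@loci) != length(object@alleles))
    msgs <- c(msgs, "loci and alleles must have equal length")
  if (anyNA(object@loci) || any(object@loci < 1L | object@loci > MT_LENGTH))
    msgs <- c(msgs, sprintf("loci must be in 1..%d", MT_LENGTH))
  if (anyDuplicated(object@loci))
    msgs <- c(msgs, "at most one observed allele per locus")
  if (!all(object@alleles %in% NUC))
    msgs <- c(msgs, "alleles must be one of A, C, G, T")
  if (length(msgs)) msgs else TRUE
})

#' GenotypeMatrix: cohort-by-locus encoded mtSNP genotypes
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the numerically
#' encoded genotypes of a cohort. The single assay `"codes"` is an integer
#' matrix with loci as rows and samples as columns; nucleotides are encoded
#' A=1, G=2, C=3, T=4 and 0 marks a missing call. `rowData()$locus` carries
#' the 1-based rCRS positions and `colData()$classLabel` the per-sample
#' study class.
#'
#' @seealso [encodeGenotypes()], [trainRBF()]
#' @export
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msgs <- character()
  if (!"codes" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'codes' is required")
  else {
    codes <- SummarizedExperiment::assay(object, "codes")
    if (!is.integer(codes) || anyNA(codes) || any(codes < 0L | codes > 4L))
      msgs <- c(msgs, "codes must be integers in 0..4 (0 = missing)")
  }
  if (!"locus" %in% names(SummarizedExperiment::rowData(object)))
    msgs <- c(msgs, "rowData must have a 'locus' column")
  if (!"classLabel" %in% names(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must have a 'classLabel' column")
  if (is.null(colnames(object)))
    msgs <- c(msgs, "samples must be named")
  if (length(msgs)) msgs else TRUE
})

#' RBFModel: a trained radial basis function network
#'
#' A Gaussian radial basis function network over encoded genotype vectors:
#' f(x) = bias + sum_i w_i * exp(-||x - M_i||^2 / (2 sigma_i^2)), where the
#' centers M_i are placed by k-means on the training rows, the widths
#' sigma_i are set from center-to-center distances, and the weights w_i are
#' fit by ridge-regularised least squares against 0/1 class targets.
#'
#' @slot centers numeric matrix, one row per basis function, columns = loci.
#' @slot widths positive numeric vector, one per center.
#' @slot weights numeric vector, one per center.
#' @slot bias single numeric offset.
#' @slot loci integer rCRS positions defining the input dimension order.
#' @slot positiveClass character label of the class trained as target 1.
#' @slot trainIds,validationIds character sample ids of the 2/3 - 1/3 split
#'   used at fit time.
#'
#' @seealso [trainRBF()], [predict,RBFModel-method]
#' @export
setClass("RBFModel",
  representation(centers = "matrix", widths = "numeric",
                 weights = "numeric", bias = "numeric",
                 loci = "integer", positiveClass = "character",
                 trainIds = "character", validationIds = "character"))

setValidity("RBFModel", function(object) {
  msgs <- character()
  m <- nrow(object@centers)
  if (m < 1L) msgs <- c(msgs, "at least one center is required")
  if (length(object@widths) != m || any(object@widths <= 0))
    msgs <- c(msgs, "widths must be positive, one per center")
  if (length(object@weights) != m)
    msgs <- c(msgs, "number of weights must equal number of centers")
  if (length(object@bias) != 1L)
    msgs <- c(msgs, "bias must be a single number")
  if (ncol(object@centers) != length(object@loci))
    msgs <- c(msgs, "center dimension must equal number of loci")
  if (length(msgs)) msgs else TRUE
})

#' ClusterReport: per-cluster membership and mean predicted probability
#'
#' Partition of a scored cohort into the basis-function clusters of an RBF
#' model (each sample assigned to its nearest center), with per-cluster
#' mean predicted probability reported as a percentage, in descending
#' order.
#'
#' @slot classLabel target class of the underlying model.
#' @slot clusters data.frame with columns `clusterId`, `n`, `probPct`.
#' @slot members named list (by clusterId) of member sample id vectors.
#'
#' @seealso [formClusters()]
#' @export
setClass("ClusterReport",
  representation(classLabel = "character", clusters = "data.frame",
                 members = "list"))

setValidity("ClusterReport", function(object) {
  msgs <- character()
  cl <- object@clusters
  if (!all(c("clusterId", "n", "probPct") %in% names(cl)))
    msgs <- c(msgs, "clusters needs columns clusterId, n, probPct")
  else {
    if (any(cl$probPct < 0 | cl$probPct > 100))
      msgs <- c(msgs, "probPct must lie in [0, 100]")
    if (is.unsorted(rev(cl$probPct)))
      msgs <- c(msgs, "clusters must be sorted by descending probPct")
    ids <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(ids))
      msgs <- c(msgs, "cluster member sets must be disjoint")
    if (!identical(as.integer(cl$n),
                   as.integer(lengths(object@members)[as.character(cl$clusterId)])))
      msgs <- c(msgs, "member counts must match the cluster table")
  }
  if (length(msgs)) msgs else TRUE
})

#' SelectionResult: the "modified cluster" of top-ranked individuals
#'
#' @slot sampleIds selected sample ids, in descending score order.
#' @slot scores predicted probabilities of the selected samples.
#' @slot rule description of the selection rule applied ("top-N" or
#'   "threshold").
#'
#' @seealso [selectModifiedCluster()]
#' @export
setClass("SelectionResult",
  representation(sampleIds = "character", scores = "numeric",
                 rule = "character"))

setValidity("SelectionResult", function(object) {
  if (length(object@sampleIds) != length(object@scores))
    "sampleIds and scores must have equal length"
  else TRUE
})

#' DiagnosisReport: match ratios of one person against all profiles
#'
#' One row per (class, haplogroup) profile: the number of that profile's
#' defining mutations the person carries, the profile size, their exact
#' ratio, and whether the ratio exceeds the decision threshold. Sorted by
#' descending ratio.
#'
#' @slot sampleId the person's sample id.
#' @slot threshold decision threshold the flags refer to.
#' @slot entries data.frame with columns `classLabel`, `haplogroup`,
#'   `matched`, `total`, `ratio`, `rendered`, `flagged` and list columns
#'   `matchedLoci`, `missingLoci`.
#'
#' @seealso [diagnose()]
#' @export
setClass("DiagnosisReport",
  representation(sampleId = "character", threshold = "numeric",
                 entries = "data.frame"))

#' SimSpec: design of a synthetic mtDNA cohort
#'
#' Describes the cohort the simulator generates: per class a size and a
#' haplogroup mixture (proportions of individuals seeded from each
#' defining-SNP profile; the remainder are background individuals carrying
#' noise mutations only), a per-entry carrier completeness, and an expected
#' number of random non-profile noise mutations per individual.
#'
#' @slot classes list of lists with elements `classLabel`, `n`, `mixture`
#'   (named numeric of proportions over haplogroup names of that class's
#'   profile table; may sum to < 1).
#' @slot carrierCompleteness probability that an assigned individual
#'   carries each entry of its source profile (default 0.9).
#' @slot noiseRate expected count of random non-profile mutations per
#'   individual (default 3).
#'
#' @seealso [simCohortSpec()], [simulateCohort()]
#' @export
setClass("SimSpec",
  representation(classes = "list", carrierCompleteness = "numeric",
                 noiseRate = "numeric"))

setValidity("SimSpec", function(object) {
  msgs <- character()
  if (length(object@carrierCompleteness) != 1L ||
      object@carrierCompleteness < 0 || object@carrierCompleteness > 1)
    msgs <- c(msgs, "carrierCompleteness must be in [0, 1]")
  if (length(object@noiseRate) != 1L || object@noiseRate < 0)
    msgs <- c(msgs, "noiseRate must be nonnegative")
  for (cl in object@classes) {
    if (!all(c("classLabel", "n") %in% names(cl)))
      msgs <- c(msgs, "each class needs classLabel and n")
    else if (cl$n < 1)
      msgs <- c(msgs, "class sizes must be positive")
    mix <- cl$mixture
    if (!is.null(mix)) {
      if (is.null(names(mix)) || any(mix < 0) || sum(mix) > 1 + 1e-9)
        msgs <- c(msgs,
          "mixture must be named, nonnegative, and sum to at most 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})
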