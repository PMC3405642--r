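#' Accessors for mtHaploDx classes
#'
#' Small accessor generics: `haplogroupName()` and `classLabel()` return the
#' labels of a profile or table; `profileEntries()` the (locus, normal,
#' mutant) data.frame of a profile; `profileSize()` its entry count (the
#' match-ratio denominator); `profiles()` and `haplogroupNames()` the
#' contents of a [ProfileTable-class]; `getProfile()` one named profile;
#' `sampleId()` a [VariantSet-class]'s sample label; `variantLoci()` and
#' `variantAlleles()` its positions and observed alleles.
#'
#' @param x an mtHaploDx object.
#' @param name a haplogroup name.
#' @return The accessed component; see each method's class documentation.
#' @name accessors
#' @aliases haplogroupName classLabel profileEntries profileSize profiles
#'   haplogroupNames getProfile sampleId variantLoci variantAlleles
#' @examples
#' tab <- readProfileTable(packagedProfilePath("ad"))
#' haplogroupNames(tab)
#' profileSize(getProfile(tab, "G2a"))
NULL

#' @rdname accessors
#' @export
setGeneric("haplogroupName", function(x) standardGeneric("haplogroupName"))
#' @rdname accessors
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))
#' @rdname accessors
#' @export
setGeneric("profileEntries", function(x) standardGeneric("profileEntries"))
#' @rdname accessors
#' @export
setGeneric("profileSize", function(x) standardGeneric("profileSize"))
#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setGeneric("haplogroupNames", function(x) standardGeneric("haplogroupNames"))
#' @rdname accessors
#' @export
setGeneric("getProfile", function(x, name) standardGeneric("getProfile"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("variantLoci", function(x) standardGeneric("variantLoci"))
#' @rdname accessors
#' @export
setGeneric("variantAlleles", function(x) standardGeneric("variantAlleles"))

setMethod("haplogroupName", "HaplogroupProfile", function(x) x@haplogroup)
setMethod("classLabel", "HaplogroupProfile", function(x) x@classLabel)
setMethod("classLabel", "ProfileTable", function(x) x@classLabel)
setMethod("profileEntries", "HaplogroupProfile", function(x) x@entries)
setMethod("profileSize", "HaplogroupProfile", function(x) nrow(x@entries))
setMethod("profiles", "ProfileTable", function(x) x@profiles)
setMethod("haplogroupNames", "ProfileTable", function(x) names(x@profiles))
setMethod("getProfile", "ProfileTable", function(x, name) {
  if (!name %in% names(x@profiles))
    stop("no haplogroup '", name, "' in the ", x@classLabel, " table",
         call. = FALSE)
  x@profiles[[name]]
})
setMethod("sampleId", "VariantSet", function(x) x@sampleId)
setMethod("variantLoci", "VariantSet", function(x) x@loci)
setMethod("variantAlleles", "VariantSet", function(x) {
  stats::setNames(x@alleles, x@loci)
})

#' @describeIn accessors number of variants in a VariantSet.
#' @export
setMethod("length", "VariantSet", function(x) length(x@loci))

#' Genotype-matrix accessors
#'
#' `sampleIds()`, `classLabels()`, `loci()` and `genotypeCodes()` expose the
#' components of a [GenotypeMatrix-class]: sample names, per-sample class
#' labels, rCRS positions and the integer code matrix (loci x samples,
#' A=1, G=2, C=3, T=4, 0 = missing).
#'
#' @param x a [GenotypeMatrix-class] (or [RBFModel-class] for `loci`).
#' @return character, character, integer vector and integer matrix
#'   respectively.
#' @name genotype-accessors
#' @aliases sampleIds classLabels loci genotypeCodes
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname genotype-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname genotype-accessors
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))
#' @rdname genotype-accessors
#' @export
setGeneric("genotypeCodes", function(x) standardGeneric("genotypeCodes"))

setMethod("sampleIds", "GenotypeMatrix", function(x) colnames(x))
setMethod("classLabels", "GenotypeMatrix", function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$classLabel),
                  colnames(x))
})
setMethod("loci", "GenotypeMatrix", function(x) {
  as.integer(SummarizedExperiment::rowData(x)$locus)
})
setMethod("loci", "RBFModel", function(x) x@loci)
setMethod("genotypeCodes", "GenotypeMatrix", function(x) {
  SummarizedExperiment::assay(x, "codes")
})

#' Selection and report accessors
#'
#' @param x a [SelectionResult-class], [ClusterReport-class] or
#'   [DiagnosisReport-class].
#' @return `selectedIds()`/`selectedScores()`: the ranked selected samples
#'   and their scores. `clusterTable()`: the per-cluster summary
#'   data.frame; `clusterMembers()`: the per-cluster member id lists.
#'   `reportEntries()`: the per-(class, haplogroup) diagnosis data.frame.
#' @name report-accessors
#' @aliases selectedIds selectedScores clusterTable clusterMembers
#'   reportEntries
NULL

#' @rdname report-accessors
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))
#' @rdname report-accessors
#' @export
setGeneric("selectedScores", function(x) standardGeneric("selectedScores"))
#' @rdname report-accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname report-accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname report-accessors
#' @export
setGeneric("reportEntries", function(x) standardGeneric("reportEntries"))

setMethod("selectedIds", "SelectionResult", function(x) x@sampleIds)
setMethod("selectedScores", "SelectionResult", function(x) {
  stats::setNames(x@scores, x@sampleIds)
})
setMethod("clusterTable", "ClusterReport", function(x) x@clusters)
setMethod("clusterMembers", "ClusterReport", function(x) x@members)
setMethod("reportEntries", "DiagnosisReport", function(x) x@entries)
setMethod("sampleId", "DiagnosisReport", function(x) x@sampleId)

setMethod("show", "HaplogroupProfile", function(object) {
  cat(sprintf("HaplogroupProfile %s [%s]: %d defining mutations\n",
              object@haplogroup, object@classLabel, nrow(object@entries)))
  e <- object@entries
  cat(" ", paste0(e$locus, " ", e$normal, ">", e$mutant, collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "ProfileTable", function(object) {
  cat(sprintf("ProfileTable [%s]: %d haplogroups\n",
              object@classLabel, length(object@profiles)))
  for (p in object@profiles)
    cat(sprintf("  %-10s %2d entries\n", p@haplogroup, nrow(p@entries)))
})

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet %s: %d variants\n",
              object@sampleId, length(object@loci)))
  if (length(object@loci)) {
    shown <- head(seq_along(object@loci), 12L)
    cat(" ", paste0(object@loci[shown], object@alleles[shown],
                    collapse = ", "),
        if (length(object@loci) > 12L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "RBFModel", function(object) {
  cat(sprintf(
    "RBFModel: %d Gaussian centers over %d loci (positive class: %s)\n",
    nrow(object@centers), length(object@loci), object@positiveClass))
  cat(sprintf("  train/validation: %d/%d samples\n",
              length(object@trainIds), length(object@validationIds)))
})

setMethod("show", "ClusterReport", function(object) {
  cat(sprintf("ClusterReport [%s]: %d clusters, %d samples\n",
              object@classLabel, nrow(object@clusters),
              sum(object@clusters$n)))
  print(object@clusters, row.names = FALSE)
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d selected\n",
              object@rule, length(object@sampleIds)))
})

setMethod("show", "DiagnosisReport", function(object) {
  cat(sprintf("DiagnosisReport %s (threshold %.3g)\n",
              object@sampleId, object@threshold))
  e <- object@entries
  print(e[, c("classLabel", "haplogroup", "matched", "total",
              "rendered", "flagged")], row.names = FALSE)
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf("SimSpec: %d classes, completeness %.2f, noise rate %.2f\n",
              length(object@classes), object@carrierCompleteness,
              object@noiseRate))
  for (cl in object@classes) {
    mix <- cl$mixture
    cat(sprintf("  %s (n=%d): %s\n", cl$classLabel, cl$n,
                if (is.null(mix) || !length(mix)) "background only"
                else paste0(names(mix), "=", mix, collapse = ", ")))
  }
})
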