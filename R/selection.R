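#' Cluster a scored cohort by the RBF model's basis functions
#'
#' Assigns every sample to its nearest basis-function center (the hidden
#' layer's grouping of similar input vectors) and reports, per cluster,
#' the member count and the mean predicted probability as a percentage.
#' Empty clusters are dropped and clusters are listed in descending mean
#' probability.
#'
#' @param model an [RBFModel-class].
#' @param gm a [GenotypeMatrix-class] over the model's loci.
#' @return a [ClusterReport-class]; the clusters partition the cohort.
#' @seealso [selectModifiedCluster()], [writeClusterReportTsv()]
#' @export
formClusters <- function(model, gm) {
  stopifnot(methods::is(model, "RBFModel"),
            methods::is(gm, "GenotypeMatrix"))
  if (!identical(loci(gm), loci(model)))
    stop("loci of the genotype matrix do not match the model",
         call. = FALSE)
  X <- t(genotypeCodes(gm))
  storage.mode(X) <- "double"
  m <- nrow(model@centers)
  d2 <- vapply(seq_len(m), function(j)
    rowSums(sweep(X, 2L, model@centers[j, ], "-")^2), numeric(nrow(X)))
  assign <- max.col(-matrix(d2, nrow = nrow(X)), ties.method = "first")
  prob <- predict(model, gm, type = "prob")
  ids <- sampleIds(gm)
  present <- sort(unique(assign))
  tab <- data.frame(
    clusterId = present,
    n = vapply(present, function(k) sum(assign == k), integer(1)),
    probPct = vapply(present, function(k)
      mean(prob[assign == k]) * 100, numeric(1)))
  ord <- order(-tab$probPct, tab$clusterId)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  members <- lapply(tab$clusterId, function(k) ids[assign == k])
  names(members) <- as.character(tab$clusterId)
  methods::new("ClusterReport", classLabel = model@positiveClass,
               clusters = tab, members = members)
}

#' Select the "modified cluster" of top-ranked individuals
#'
#' Ranks individuals by predicted probability of belonging to the target
#' class and selects either the `topN` highest-ranked (score ties broken
#' by ascending sample id) or all individuals whose score is strictly
#' greater than `threshold`.
#'
#' @param scores named numeric vector of per-sample predicted
#'   probabilities.
#' @param topN number of individuals to select; if more than available,
#'   all are selected with a warning.
#' @param threshold probability cutoff in `[0, 1]`; selection is strict
#'   (`score > threshold`). Give exactly one of `topN`, `threshold`.
#' @return a [SelectionResult-class] in descending score order.
#' @examples
#' s <- c(a = 0.9, b = 0.2, c = 0.5)
#' selectedIds(selectModifiedCluster(s, topN = 2))
#' selectedIds(selectModifiedCluster(s, threshold = 0.5))  # "a" only
#' @export
selectModifiedCluster <- function(scores, topN = NULL, threshold = NULL) {
  if (!length(scores)) stop("scores must be non-empty", call. = FALSE)
  if (is.null(names(scores)))
    names(scores) <- paste0("S", seq_along(scores))
  if (is.null(topN) == is.null(threshold))
    stop("give exactly one of topN or threshold", call. = FALSE)
  ord <- order(-scores, names(scores))
  ranked <- scores[ord]
  if (!is.null(topN)) {
    if (topN < 1) stop("topN must be at least 1", call. = FALSE)
    if (topN > length(ranked)) {
      warning("topN = ", topN, " exceeds the ", length(ranked),
              " scored samples; selecting all")
      topN <- length(ranked)
    }
    sel <- ranked[seq_len(topN)]
    rule <- sprintf("top-%d", as.integer(topN))
  } else {
    if (threshold < 0 || threshold > 1)
      stop("threshold must be in [0, 1]", call. = FALSE)
    sel <- ranked[ranked > threshold]
    rule <- sprintf("threshold > %g", threshold)
  }
  methods::new("SelectionResult", sampleIds = names(sel),
               scores = unname(sel), rule = rule)
}

#' Write a cluster report as TSV
#'
#' Columns: `classification_id`, `n_persons`,
#' `predicted_probability_pct`, `member_ids` (comma-separated).
#'
#' @param report a [ClusterReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClusterReportTsv <- function(report, path) {
  stopifnot(methods::is(report, "ClusterReport"))
  tab <- report@clusters
  df <- data.frame(
    classification_id = seq_len(nrow(tab)),
    n_persons = tab$n,
    predicted_probability_pct = roundHalfAway(tab$probPct, 1L),
    member_ids = vapply(report@members[as.character(tab$clusterId)],
                        paste, character(1), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
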