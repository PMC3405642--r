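#' Construct a GenotypeMatrix from encoded codes
#'
#' @param codes integer matrix of codes in 0..4, loci as rows, samples as
#'   columns (A=1, G=2, C=3, T=4, 0 = missing).
#' @param loci integer rCRS positions, one per row.
#' @param sampleIds character sample names, one per column.
#' @param classLabels per-sample study-class labels.
#' @return a [GenotypeMatrix-class].
#' @export
GenotypeMatrix <- function(codes, loci, sampleIds, classLabels) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  dimnames(codes) <- list(as.character(loci), as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(codes = codes),
    rowData = S4Vectors::DataFrame(locus = as.integer(loci)),
    colData = S4Vectors::DataFrame(classLabel = as.character(classLabels),
                                   row.names = as.character(sampleIds)))
  methods::new("GenotypeMatrix", se)
}

#' Encode a nucleotide genotype table numerically
#'
#' Converts a samples-by-loci table of nucleotide letters into the integer
#' encoding used by the RBF network: A, G, C and T become 1, 2, 3 and 4.
#' Anything else (empty cells, `NA`, `N`, gaps) is treated as missing and
#' encoded 0; a message reports how many cells were affected.
#'
#' @param raw character matrix or data.frame of single letters, samples as
#'   rows and loci as columns; column names must be rCRS positions.
#' @param classLabels per-sample study-class labels (recycled if length 1).
#' @param sampleIds sample names; defaults to `rownames(raw)`.
#' @return a [GenotypeMatrix-class].
#' @examples
#' raw <- matrix(c("A", "G", "C", "T"), nrow = 1,
#'               dimnames = list("s1", c(100, 200, 300, 400)))
#' genotypeCodes(encodeGenotypes(raw, "demo"))  # 1 2 3 4
#' @seealso [decodeGenotypes()]
#' @export
encodeGenotypes <- function(raw, classLabels, sampleIds = rownames(raw)) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw)))
    stop("column names must give the rCRS positions", call. = FALSE)
  lociVec <- suppressWarnings(as.integer(colnames(raw)))
  if (anyNA(lociVec))
    stop("column names must be integer rCRS positions", call. = FALSE)
  if (is.null(sampleIds))
    sampleIds <- paste0("S", seq_len(nrow(raw)))
  letters <- toupper(raw)
  codes <- matrix(unname(NUC_CODE[letters]), nrow = nrow(raw))
  nMissing <- sum(is.na(codes) | is.na(letters))
  codes[is.na(codes)] <- 0L
  if (nMissing)
    message(nMissing, " cell(s) not in {A,C,G,T} encoded as missing (0)")
  classLabels <- rep_len(as.character(classLabels), nrow(raw))
  GenotypeMatrix(t(codes), lociVec, sampleIds, classLabels)
}

#' Decode an encoded genotype matrix back to nucleotide letters
#'
#' Inverse of [encodeGenotypes()]: 1, 2, 3, 4 become A, G, C, T and 0
#' becomes `NA`.
#'
#' @param gm a [GenotypeMatrix-class].
#' @return character matrix, samples as rows, loci as columns.
#' @export
decodeGenotypes <- function(gm) {
  stopifnot(methods::is(gm, "GenotypeMatrix"))
  codes <- t(genotypeCodes(gm))
  out <- matrix(c(NA_character_, names(NUC_CODE))[codes + 1L],
                nrow = nrow(codes), dimnames = dimnames(codes))
  out
}

#' Read and write genotype matrices as TSV
#'
#' The genotype dialect is tab-separated: first column `sample`, second
#' column `class`, remaining columns one per locus with rCRS positions as
#' header, cells single nucleotide letters (empty = missing). `#` comment
#' lines are ignored.
#'
#' @param path file path.
#' @param gm a [GenotypeMatrix-class] (for writing).
#' @return `readGenotypesTsv`: a [GenotypeMatrix-class];
#'   `writeGenotypesTsv`: `path`, invisibly.
#' @export
readGenotypesTsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (!all(c("sample", "class") %in% names(df)[1:2]))
    stopf("%s: first two columns must be 'sample' and 'class'", path)
  raw <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(raw) <- df$sample
  suppressMessages(encodeGenotypes(raw, df$class, df$sample))
}

#' @rdname readGenotypesTsv
#' @export
writeGenotypesTsv <- function(gm, path) {
  letters <- decodeGenotypes(gm)
  letters[is.na(letters)] <- ""
  df <- data.frame(sample = sampleIds(gm), class = unname(classLabels(gm)),
                   letters, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stratified 2/3 - 1/3 train/validation split
#'
#' Splits a cohort into training and validation subsets per class: each
#' class contributes `round(trainFraction * n)` samples to training (96
#' gives 64/32, 112 gives 75/37) and the rest to validation. The split is
#' deterministic for a fixed seed.
#'
#' @param classLabels per-sample class labels (character or factor),
#'   named by sample id if available.
#' @param seed RNG seed for the within-class shuffle.
#' @param trainFraction fraction of each class used for training, default
#'   2/3.
#' @return list with integer index vectors `train` and `validation`
#'   (disjoint, covering all samples).
#' @examples
#' sp <- splitTrainValidation(rep("AD", 96), seed = 1)
#' lengths(sp)  # 64 32
#' @export
splitTrainValidation <- function(classLabels, seed = 1L,
                                 trainFraction = 2 / 3) {
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)", call. = FALSE)
  classLabels <- as.character(classLabels)
  train <- integer()
  withSeed(seed, {
    for (cl in unique(classLabels)) {
      idx <- which(classLabels == cl)
      if (length(idx) < 2L)
        stopf("class '%s' has fewer than 2 samples", cl)
      nTrain <- as.integer(roundHalfAway(trainFraction * length(idx)))
      nTrain <- max(1L, min(nTrain, length(idx) - 1L))
      train <- c(train, sample(idx)[seq_len(nTrain)])
    }
  })
  train <- sort(train)
  list(train = train,
       validation = setdiff(seq_along(classLabels), train))
}

## Gaussian basis design matrix: n x m matrix of exp(-d^2 / (2 sigma^2))
rbfDesign <- function(X, centers, widths) {
  n <- nrow(X)
  m <- nrow(centers)
  Phi <- matrix(0, n, m)
  for (j in seq_len(m)) {
    d2 <- rowSums(sweep(X, 2L, centers[j, ], "-")^2)
    Phi[, j] <- exp(-d2 / (2 * widths[j]^2))
  }
  Phi
}

## widths: distance from each center to its nearest other center;
## degenerate cases fall back to the data scale or 1
centerWidths <- function(centers, X) {
  m <- nrow(centers)
  if (m == 1L) {
    d <- sqrt(rowSums(sweep(X, 2L, centers[1L, ], "-")^2))
    s <- stats::sd(d)
    return(max(if (is.finite(s) && s > 0) s else mean(d), 1))
  }
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  w <- apply(D, 1L, min)
  pos <- w[is.finite(w) & w > 0]
  fallback <- if (length(pos)) min(pos) else 1
  w[!is.finite(w) | w <= 0] <- fallback
  w
}

fitRBF <- function(X, y, m, seed, ridge) {
  distinct <- nrow(unique(X))
  m <- min(m, distinct)
  km <- withSeed(seed, stats::kmeans(X, centers = m, nstart = 5L,
                                     iter.max = 50L))
  centers <- km$centers
  widths <- centerWidths(centers, X)
  Phi <- cbind(1, rbfDesign(X, centers, widths))
  pen <- diag(c(0, rep(ridge, ncol(Phi) - 1L)))
  beta <- solve(crossprod(Phi) + pen, crossprod(Phi, y))
  list(centers = centers, widths = widths,
       weights = as.numeric(beta[-1L]), bias = as.numeric(beta[1L]))
}

#' Train an RBF network classifier on a genotype cohort
#'
#' Fits the Gaussian radial basis function network over numerically
#' encoded genotype vectors. Samples of `positiveClass` are the correct
#' examples (target 1) and all other classes the incorrect examples
#' (target 0). The cohort is first split per class into 2/3 training and
#' 1/3 validation; centers are placed by seeded k-means on the training
#' rows, widths are the distance from each center to its nearest other
#' center, and the output weights are fit by ridge-regularised least
#' squares. With `m = "auto"` the center count is chosen from a small grid
#' (2, 4, 8, 16, 32) by validation accuracy at the 0.5 threshold.
#'
#' @param gm a [GenotypeMatrix-class] with at least one positive and one
#'   negative sample.
#' @param positiveClass the class label trained as target 1.
#' @param m number of basis functions, or `"auto"` (default).
#' @param seed RNG seed controlling the split and k-means; the fit is
#'   deterministic for a fixed seed.
#' @param ridge nonnegative ridge penalty on the weights, default `1e-6`.
#' @param trainFraction training fraction of the per-class split, default
#'   2/3.
#' @return an [RBFModel-class].
#' @examples
#' tabs <- packagedProfileTables()
#' spec <- simCohortSpec(
#'   list(list(classLabel = "AD", n = 30, mixture = c(G2a = 0.7)),
#'        list(classLabel = "T2D", n = 30, mixture = c(D4b2b = 0.7))),
#'   carrierCompleteness = 1, noiseRate = 0)
#' sim <- simulateCohort(spec, tabs, syntheticReference(), seed = 1)
#' fit <- trainRBF(sim$genotypes, "AD", m = 2, seed = 1)
#' @seealso [predict,RBFModel-method], [formClusters()]
#' @export
trainRBF <- function(gm, positiveClass, m = "auto", seed = 1L,
                     ridge = 1e-6, trainFraction = 2 / 3) {
  stopifnot(methods::is(gm, "GenotypeMatrix"))
  if (ridge < 0) stop("ridge must be nonnegative", call. = FALSE)
  labels <- classLabels(gm)
  if (!positiveClass %in% labels)
    stopf("no samples of class '%s'", positiveClass)
  X <- t(genotypeCodes(gm))
  storage.mode(X) <- "double"
  split <- splitTrainValidation(labels, seed = seed,
                                trainFraction = trainFraction)
  yAll <- as.numeric(labels == positiveClass)
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- yAll[split$train]
  if (!any(ytr == 1) || !any(ytr == 0))
    stop("training split needs at least one positive and one negative ",
         "sample", call. = FALSE)
  grid <- if (identical(m, "auto")) c(2L, 4L, 8L, 16L, 32L)
          else as.integer(m)
  if (!identical(m, "auto") && grid > nrow(Xtr))
    stopf("m = %d exceeds the %d training samples", grid, nrow(Xtr))
  grid <- grid[grid <= nrow(Xtr)]
  if (!length(grid)) grid <- 2L
  fits <- lapply(grid, function(mm) fitRBF(Xtr, ytr, mm, seed, ridge))
  if (length(fits) > 1L) {
    Xva <- X[split$validation, , drop = FALSE]
    yva <- yAll[split$validation]
    acc <- vapply(fits, function(f) {
      p <- f$bias + rbfDesign(Xva, f$centers, f$widths) %*% f$weights
      mean((p > 0.5) == (yva == 1))
    }, numeric(1))
    fit <- fits[[which.max(acc)]]
  } else fit <- fits[[1L]]
  methods::new("RBFModel", centers = unname(fit$centers),
               widths = fit$widths, weights = fit$weights,
               bias = fit$bias, loci = loci(gm),
               positiveClass = as.character(positiveClass),
               trainIds = sampleIds(gm)[split$train],
               validationIds = sampleIds(gm)[split$validation])
}

## raw (unclipped) weighted-sum scores for an encoded sample-by-locus
## matrix
rbfRawScores <- function(model, X) {
  if (ncol(X) != length(model@loci))
    stopf("input has %d loci but the model expects %d", ncol(X),
          length(model@loci))
  as.numeric(model@bias +
               rbfDesign(X, model@centers, model@widths) %*% model@weights)
}

predictMatrix <- function(object, newdata) {
  if (methods::is(newdata, "GenotypeMatrix")) {
    if (!identical(loci(newdata), object@loci))
      stop("loci of the genotype matrix do not match the model",
           call. = FALSE)
    X <- t(genotypeCodes(newdata))
  } else {
    X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
         else as.matrix(newdata)
  }
  storage.mode(X) <- "double"
  X
}

#' Predict class probabilities with an RBF model
#'
#' Evaluates the weighted sum f(x) = bias + sum_i w_i
#' exp(-||x - M_i||^2 / (2 sigma_i^2)) for each sample. The raw weighted
#' sum may leave [0, 1]; reported probabilities (`type = "prob"`) are
#' clipped to [0, 1], while `type = "raw"` returns the unclipped values
#' used internally for ranking.
#'
#' @param object an [RBFModel-class].
#' @param newdata a [GenotypeMatrix-class] with the model's loci, or a
#'   numeric matrix/vector of encoded genotypes (samples as rows).
#' @param type `"prob"` (clipped, default) or `"raw"`.
#' @return named numeric vector of scores, one per sample.
#' @export
setMethod("predict", "RBFModel",
  function(object, newdata, type = c("prob", "raw")) {
    type <- match.arg(type)
    X <- predictMatrix(object, newdata)
    f <- rbfRawScores(object, X)
    if (type == "prob") f <- pmin(1, pmax(0, f))
    names(f) <- if (methods::is(newdata, "GenotypeMatrix"))
      sampleIds(newdata) else rownames(X)
    f
  })

#' Save and restore an RBF model as structured text
#'
#' A versioned single-file plain-text format (R expression with hexadecimal
#' floating-point literals) storing centers, widths, weights, bias, loci
#' and labels; the round-trip is bit-exact.
#'
#' @param model an [RBFModel-class].
#' @param path file path.
#' @return `writeRBFModel`: `path` invisibly; `readRBFModel`: the restored
#'   [RBFModel-class].
#' @export
writeRBFModel <- function(model, path) {
  stopifnot(methods::is(model, "RBFModel"))
  payload <- list(format = "mtHaploDx-rbf", version = 1L,
                  centers = unname(model@centers), widths = model@widths,
                  weights = model@weights, bias = model@bias,
                  loci = model@loci, positiveClass = model@positiveClass,
                  trainIds = model@trainIds,
                  validationIds = model@validationIds)
  dput(payload, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname writeRBFModel
#' @export
readRBFModel <- function(path) {
  payload <- dget(path)
  if (!identical(payload$format, "mtHaploDx-rbf"))
    stopf("%s is not an mtHaploDx RBF model file", path)
  if (!identical(payload$version, 1L))
    stopf("unsupported model file version %s", payload$version)
  methods::new("RBFModel", centers = payload$centers,
               widths = payload$widths, weights = payload$weights,
               bias = payload$bias, loci = payload$loci,
               positiveClass = payload$positiveClass,
               trainIds = payload$trainIds,
               validationIds = payload$validationIds)
}
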