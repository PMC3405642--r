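#' Specify a synthetic cohort design
#'
#' @param classes list of class designs, each a list with `classLabel`
#'   (must name a profile table at simulation time), `n` (cohort size) and
#'   optionally `mixture`: a named numeric of proportions over that
#'   table's haplogroup names. Proportions may sum to less than 1; the
#'   remainder are background individuals carrying noise mutations only.
#' @param carrierCompleteness probability that an assigned individual
#'   carries each entry of its source profile, default 0.9.
#' @param noiseRate expected (Poisson) count of random non-profile
#'   mutations per individual, default 3.
#' @return a [SimSpec-class].
#' @examples
#' simCohortSpec(list(
#'   list(classLabel = "AD", n = 96, mixture = c(G2a = 0.53, N9b1 = 0.2)),
#'   list(classLabel = "T2D", n = 96, mixture = c(D4b2b = 0.6))))
#' @export
simCohortSpec <- function(classes, carrierCompleteness = 0.9,
                          noiseRate = 3) {
  methods::new("SimSpec", classes = classes,
               carrierCompleteness = carrierCompleteness,
               noiseRate = noiseRate)
}

#' Read a cohort design from a YAML config file
#'
#' Expects top-level keys `classes` (list of `classLabel`, `size`,
#' optional `mixture` mapping), `carrierCompleteness` and `noiseRate`.
#'
#' @param path path to a YAML file.
#' @return a [SimSpec-class].
#' @export
readSimSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  classes <- lapply(cfg$classes, function(cl) {
    mix <- if (!is.null(cl$mixture)) unlist(cl$mixture)
    ## accept "n" as a synonym of "size" (note YAML 1.1 reads a bare `n`
    ## key as the boolean FALSE, hence the extra lookup)
    size <- cl$size
    if (is.null(size)) size <- cl$n
    if (is.null(size)) size <- cl[["FALSE"]]
    if (is.null(size))
      stopf("class '%s' in %s has no size", cl$classLabel, path)
    list(classLabel = cl$classLabel, n = as.integer(size), mixture = mix)
  })
  simCohortSpec(classes,
                carrierCompleteness =
                  if (is.null(cfg$carrierCompleteness)) 0.9
                  else as.numeric(cfg$carrierCompleteness),
                noiseRate = if (is.null(cfg$noiseRate)) 3
                            else as.numeric(cfg$noiseRate))
}

#' Simulate an mtDNA cohort with planted haplogroup structure
#'
#' Each class member is either seeded from one of the class's haplogroup
#' profiles (with the spec's mixture proportions; deterministic rounded
#' counts, remainder background) or is a background individual. A seeded
#' individual carries each entry of its source profile independently with
#' probability `carrierCompleteness`; where a profile lists two mutant
#' alleles at one locus, one is chosen at random (a person carries one
#' allele per locus). Every individual additionally receives
#' Poisson(`noiseRate`) noise mutations at uniformly drawn loci outside
#' its own source profile, each with a random non-reference allele. The
#' output is fully reproducible from (spec, seed).
#'
#' @param spec a [SimSpec-class].
#' @param tables named list of [ProfileTable-class] objects keyed by class
#'   label (e.g. [packagedProfileTables()]).
#' @param reference the rCRS reference (or [syntheticReference()]).
#' @param seed RNG seed.
#' @return list with `genotypes` (a [GenotypeMatrix-class] over the union
#'   of all profile loci plus the noise loci actually used), `variants`
#'   (named list of [VariantSet-class]) and `truth` (data.frame with
#'   columns `sample`, `classLabel`, `haplogroup`; background individuals
#'   have `NA` haplogroup).
#' @examples
#' tabs <- packagedProfileTables()
#' spec <- simCohortSpec(list(list(classLabel = "AD", n = 10,
#'                                 mixture = c(G2a = 1))),
#'                       carrierCompleteness = 1, noiseRate = 0)
#' sim <- simulateCohort(spec, tabs, syntheticReference(), seed = 1)
#' table(sim$truth$haplogroup)
#' @export
simulateCohort <- function(spec, tables, reference, seed = 1L) {
  stopifnot(methods::is(spec, "SimSpec"))
  methods::validObject(spec)
  reference <- checkReference(reference)
  for (cl in spec@classes) {
    if (!cl$classLabel %in% names(tables))
      stopf("no profile table for class '%s'", cl$classLabel)
    bad <- setdiff(names(cl$mixture),
                   haplogroupNames(tables[[cl$classLabel]]))
    if (length(bad))
      stopf("unknown haplogroup(s) %s in class '%s'",
            paste(bad, collapse = ", "), cl$classLabel)
  }
  variants <- list()
  truth <- list()
  withSeed(seed, {
    for (cl in spec@classes) {
      tab <- tables[[cl$classLabel]]
      mix <- cl$mixture
      counts <- if (is.null(mix)) integer()
                else as.integer(floor(mix * cl$n + 0.5))
      ## floor+0.5 rounding can overshoot n; trim from the largest group
      while (sum(counts) > cl$n) {
        i <- which.max(counts); counts[i] <- counts[i] - 1L
      }
      sources <- c(rep(names(mix), counts),
                   rep(NA_character_, cl$n - sum(counts)))
      for (i in seq_len(cl$n)) {
        sid <- sprintf("%s_%03d", cl$classLabel, i)
        src <- sources[i]
        lociV <- integer(); allV <- character()
        ownLoci <- integer()
        if (!is.na(src)) {
          e <- profiles(tab)[[src]]@entries
          ownLoci <- unique(e$locus)
          carry <- stats::rbinom(nrow(e), 1L,
                                 spec@carrierCompleteness) == 1L
          ec <- e[carry, , drop = FALSE]
          ## one allele per locus: where both mutant alleles of a
          ## twice-listed locus were drawn, keep one at random
          if (anyDuplicated(ec$locus)) {
            keep <- unlist(lapply(split(seq_len(nrow(ec)), ec$locus),
                                  function(ix) ix[sample.int(length(ix), 1L)]))
            ec <- ec[sort(keep), , drop = FALSE]
          }
          lociV <- ec$locus; allV <- ec$mutant
        }
        nNoise <- stats::rpois(1L, spec@noiseRate)
        if (nNoise > 0L) {
          pool <- setdiff(seq_len(MT_LENGTH), ownLoci)
          nl <- sample(pool, min(nNoise, length(pool)))
          na <- vapply(nl, function(l)
            sample(setdiff(NUC, refBase(reference, l)), 1L), character(1))
          lociV <- c(lociV, nl); allV <- c(allV, na)
        }
        ord <- order(lociV)
        variants[[sid]] <- VariantSet(sid, lociV[ord], allV[ord])
        truth[[sid]] <- data.frame(sample = sid,
                                   classLabel = cl$classLabel,
                                   haplogroup = src)
      }
    }
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  ## matrix loci: union of all profile loci plus noise loci actually used
  profLoci <- unlist(lapply(tables, function(tab)
    lapply(profiles(tab), function(p) p@entries$locus)))
  usedLoci <- unlist(lapply(variants, variantLoci))
  allLoci <- sort(unique(c(profLoci, usedLoci)))
  refBases <- vapply(allLoci, function(l) refBase(reference, l),
                     character(1))
  raw <- matrix(rep(refBases, each = length(variants)),
                nrow = length(variants),
                dimnames = list(names(variants), allLoci))
  for (sid in names(variants)) {
    v <- variants[[sid]]
    raw[sid, match(v@loci, allLoci)] <- v@alleles
  }
  gm <- suppressMessages(
    encodeGenotypes(raw, truth$classLabel, truth$sample))
  list(genotypes = gm, variants = variants, truth = truth)
}

#' End-to-end planted-haplogroup recovery check
#'
#' Runs the full pipeline on a simulated two-class cohort with a planted
#' dominant haplogroup in the positive class: simulate, train the RBF
#' network on the positive class, rank the positive-class individuals by
#' predicted probability, select the top `topN`, and associate the
#' selection with the positive class's profile table. Recovery succeeds
#' when the planted haplogroup is the modal assignment of the selection.
#'
#' @param tables named list of [ProfileTable-class] (e.g.
#'   [packagedProfileTables()]).
#' @param reference the reference sequence.
#' @param positiveClass,negativeClass class labels of the two simulated
#'   cohorts (default `"AD"` vs `"T2D"`).
#' @param positiveHaplogroup,negativeHaplogroup the planted dominant
#'   haplogroups (defaults `"G2a"` and `"D4b2b"`); each receives
#'   `dominantProportion` of its class, the rest background.
#' @param dominantProportion proportion of each class seeded from its
#'   dominant haplogroup, default 0.6.
#' @param nPerClass individuals per class, default 96.
#' @param carrierCompleteness,noiseRate simulator settings, defaults 0.95
#'   and 2.
#' @param topN size of the selected modified cluster, default 15.
#' @param m RBF center count, default 4.
#' @param seed RNG seed driving the whole run.
#' @return list with logical `recovered`, the `modal` assignment, the
#'   association data.frame and the [SelectionResult-class].
#' @export
pipelineRecoveryCheck <- function(tables, reference,
                                  positiveClass = "AD",
                                  negativeClass = "T2D",
                                  positiveHaplogroup = "G2a",
                                  negativeHaplogroup = "D4b2b",
                                  dominantProportion = 0.6,
                                  nPerClass = 96L,
                                  carrierCompleteness = 0.95,
                                  noiseRate = 2, topN = 15L, m = 4L,
                                  seed = 1L) {
  spec <- simCohortSpec(
    list(list(classLabel = positiveClass, n = nPerClass,
              mixture = stats::setNames(dominantProportion,
                                        positiveHaplogroup)),
         list(classLabel = negativeClass, n = nPerClass,
              mixture = stats::setNames(dominantProportion,
                                        negativeHaplogroup))),
    carrierCompleteness = carrierCompleteness, noiseRate = noiseRate)
  sim <- simulateCohort(spec, tables, reference, seed = seed)
  fit <- trainRBF(sim$genotypes, positiveClass, m = m, seed = seed)
  scores <- predict(fit, sim$genotypes, type = "raw")
  pos <- sampleIds(sim$genotypes)[
    classLabels(sim$genotypes) == positiveClass]
  sel <- selectModifiedCluster(scores[pos], topN = topN)
  assoc <- associateSubset(sim$variants[selectedIds(sel)],
                           tables[[positiveClass]])
  modal <- if (nrow(assoc)) assoc$haplogroup[1L] else NA_character_
  list(recovered = identical(modal, positiveHaplogroup), modal = modal,
       association = assoc, selection = sel)
}
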