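#' Specification of a synthetic pharmacogenomic dataset
#'
#' Describes a simulated cell-line panel mirroring the structure of a
#' GDSC-style screen: sparse binary somatic-mutation and hypermethylation
#' matrices, a sparse ternary CNV matrix, a one-hot tissue matrix,
#' continuous expression driven by low-rank latent factors (the first
#' factor is coupled to tissue, emulating the documented overlap between
#' tissue lineage and genome-wide expression patterns), eleven pathway
#' activation scores that mix those latent factors with pathway-own
#' components, and a continuous dose-response AUC built from planted
#' driver features plus Gaussian noise.
#'
#' Drivers are given as a list of lists with fields `layer`, `effect`
#' (shift in units of the AUC noise SD), `direction` (`"sensitivity"`
#' lowers AUC, `"resistance"` raises it) and, per layer, `carrierFrac`
#' (mutation/cnv/methylation), `tissue` (tissue index), `pathway`
#' (pathway index; the effect scales with the standardized score) or
#' `latent` (expression latent-factor index).
#'
#' @param nCells number of cell lines, default 300.
#' @param nGenes named counts of genomic features per layer.
#' @param sparsity named per-layer event frequencies.
#' @param nTissues number of tissue types, default 12 (sampling
#'   probabilities decay linearly so tissue sizes are uneven, as in real
#'   panels).
#' @param nExprGenes number of expression features, default 500.
#' @param nLatent number of latent expression factors, default 6.
#' @param nPathways number of pathway scores, default 11.
#' @param tissueCoupling strength of the tissue effect on the first
#'   latent factor, default 1.
#' @param pathwayLatentWeight,pathwayOwnWeight relative weight of shared
#'   latent factors versus pathway-own components in the pathway scores.
#' @param noiseSd SD of the Gaussian AUC noise, default 0.1 (AUC units).
#' @param baseline mean AUC of a driver-free cell line, default 0.7.
#' @param drivers list of planted drivers (possibly empty: a null world
#'   in which the response is independent of every feature).
#' @param duplicateDrivers number of exact duplicate columns to append
#'   per genomic driver, exercising redundancy removal. Default 0.
#' @param seed integer seed.
#' @return Classed list (`syntheticSpec`).
#' @export
syntheticSpec <- function(nCells = 300L,
                          nGenes = c(mutation = 500L, cnv = 300L,
                                     methylation = 300L),
                          sparsity = c(mutation = 0.10, cnv = 0.08,
                                       methylation = 0.08),
                          nTissues = 12L, nExprGenes = 500L, nLatent = 6L,
                          nPathways = 11L, tissueCoupling = 1,
                          pathwayLatentWeight = 0.4,
                          pathwayOwnWeight = 0.9, noiseSd = 0.1,
                          baseline = 0.7, drivers = list(),
                          duplicateDrivers = 0L, seed = 1L) {
  spec <- list(nCells = as.integer(nCells), nGenes = nGenes,
               sparsity = sparsity, nTissues = as.integer(nTissues),
               nExprGenes = as.integer(nExprGenes),
               nLatent = as.integer(nLatent),
               nPathways = as.integer(nPathways),
               tissueCoupling = tissueCoupling,
               pathwayLatentWeight = pathwayLatentWeight,
               pathwayOwnWeight = pathwayOwnWeight, noiseSd = noiseSd,
               baseline = baseline, drivers = drivers,
               duplicateDrivers = as.integer(duplicateDrivers),
               seed = as.integer(seed))
  class(spec) <- "syntheticSpec"
  spec
}

#' Standard simulation scenarios
#'
#' Three fixed study conditions used throughout the package's tests and
#' examples:
#'
#' * `nullWorldSpec()`: no planted drivers; the response is independent
#'   of every feature. Used for type-I-error and chance-level checks.
#' * `plantedMutationSpec()`: a single somatic-mutation driver with a
#'   2-noise-SD sensitivity effect carried by 30% of cell lines. Used
#'   for parameter-recovery checks.
#' * `twoDriverSpec()`: a strong mutation driver (2 SD, 30% carriers)
#'   plus a strong pathway-activation driver (1.5 SD per score SD), on
#'   top of weak but detectable drivers in the CNV, hypermethylation and
#'   tissue layers (1.2 SD) so that all six first-step models survive in
#'   every fold and the full set of 41 ablation subsets is computed.
#'   Removing the mutation and pathway inputs simultaneously should then
#'   be the most damaging ablation.
#'
#' @param seed integer seed.
#' @param effect,carrierFrac driver effect size (noise-SD units) and
#'   carrier fraction for `plantedMutationSpec()`.
#' @return A [syntheticSpec()].
#' @export
nullWorldSpec <- function(seed = 1L) syntheticSpec(seed = seed)

#' @rdname nullWorldSpec
#' @export
plantedMutationSpec <- function(seed = 1L, effect = 2, carrierFrac = 0.3) {
  syntheticSpec(seed = seed, drivers = list(
    list(layer = "mutation", effect = effect, direction = "sensitivity",
         carrierFrac = carrierFrac)))
}

#' @rdname nullWorldSpec
#' @export
twoDriverSpec <- function(seed = 1L) {
  syntheticSpec(seed = seed, drivers = list(
    list(layer = "mutation", effect = 2, direction = "sensitivity",
         carrierFrac = 0.3),
    list(layer = "pathway", effect = 1.5, direction = "resistance",
         pathway = 3L),
    list(layer = "cnv", effect = 1.2, direction = "sensitivity",
         carrierFrac = 0.25),
    list(layer = "methylation", effect = 1.2, direction = "resistance",
         carrierFrac = 0.25),
    list(layer = "tissue", effect = 1.2, direction = "sensitivity",
         tissue = 1L)))
}

#' Generate a synthetic aligned dataset with known ground truth
#'
#' Draws one dataset from a [syntheticSpec()]. Deterministic given the
#' spec seed. A warning is emitted for drivers whose expected carrier
#' count falls below the screening threshold of the discrete first-step
#' models (such a driver is planted but undetectable by design).
#'
#' @param spec a [syntheticSpec()].
#' @return List with `dataset` (an [OmicsDataset-class]) and `truth`
#'   (data.frame of resolved planted drivers: `layer`, `feature`,
#'   `effect`, `direction`).
#' @export
generateDataset <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  .withSeed(spec$seed, .generateDataset(spec))
}

.generateDataset <- function(spec) {
  n <- spec$nCells
  ids <- sprintf("CL%04d", seq_len(n))

  # tissue: uneven categorical, one-hot encoded
  tprob <- rev(seq_len(spec$nTissues))
  tprob <- tprob / sum(tprob)
  tissueIdx <- sample.int(spec$nTissues, n, replace = TRUE, prob = tprob)
  tissueNames <- sprintf("tissue%02d", seq_len(spec$nTissues))
  tissue <- matrix(0, n, spec$nTissues, dimnames = list(ids, tissueNames))
  tissue[cbind(seq_len(n), tissueIdx)] <- 1

  # latent expression factors; factor 1 carries the tissue signal
  latent <- matrix(stats::rnorm(n * spec$nLatent), n, spec$nLatent)
  tissueShift <- stats::rnorm(spec$nTissues)
  latent[, 1L] <- spec$tissueCoupling * tissueShift[tissueIdx] +
    stats::rnorm(n)

  loadings <- matrix(stats::rnorm(spec$nExprGenes * spec$nLatent, sd = 0.5),
                     spec$nExprGenes, spec$nLatent)
  geneMeans <- stats::rnorm(spec$nExprGenes, mean = 7, sd = 1)
  expr <- latent %*% t(loadings) +
    matrix(stats::rnorm(n * spec$nExprGenes, sd = 0.7), n) +
    matrix(geneMeans, n, spec$nExprGenes, byrow = TRUE)
  dimnames(expr) <- list(ids, sprintf("EXPR_G%04d", seq_len(spec$nExprGenes)))

  # pathway scores: shared latent load plus pathway-own component
  pwLoad <- matrix(stats::rnorm(spec$nPathways * spec$nLatent),
                   spec$nPathways, spec$nLatent)
  pwOwn <- matrix(stats::rnorm(n * spec$nPathways), n, spec$nPathways)
  pathway <- spec$pathwayLatentWeight * latent %*% t(pwLoad) +
    spec$pathwayOwnWeight * pwOwn +
    matrix(stats::rnorm(n * spec$nPathways, sd = 0.2), n)
  dimnames(pathway) <- list(ids, sprintf("pathway%02d",
                                         seq_len(spec$nPathways)))

  genomic <- list()
  prefixes <- c(mutation = "MUT", cnv = "CNV", methylation = "METH")
  for (layer in names(prefixes)) {
    g <- spec$nGenes[[layer]]
    s <- spec$sparsity[[layer]]
    if (layer == "cnv") {
      m <- matrix(sample(c(-1, 0, 1), n * g, replace = TRUE,
                         prob = c(s / 2, 1 - s, s / 2)), n, g)
    } else {
      m <- matrix(stats::rbinom(n * g, 1L, s), n, g)
    }
    dimnames(m) <- list(ids, sprintf("%s_G%04d", prefixes[[layer]],
                                     seq_len(g)))
    genomic[[layer]] <- m
  }

  # plant drivers and accumulate their response contribution (noise-SD units)
  shift <- numeric(n)
  truth <- data.frame(layer = character(), feature = character(),
                      effect = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  dupCols <- list(mutation = NULL, cnv = NULL, methylation = NULL)
  for (d in spec$drivers) {
    sgn <- if (identical(d$direction, "resistance")) 1 else -1
    if (d$layer %in% names(prefixes)) {
      col <- if (!is.null(d$feature)) d$feature else 1L
      if (d$layer == "cnv") {
        carrier <- stats::rbinom(n, 1L, d$carrierFrac)
        state <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.3, 0.7))
        genomic[[d$layer]][, col] <- carrier * state
      } else {
        carrier <- stats::rbinom(n, 1L, d$carrierFrac)
        genomic[[d$layer]][, col] <- carrier
      }
      if (d$carrierFrac * n * 0.45 < 15)
        warning(sprintf(
          "driver in '%s': expected training carrier count below the screening threshold",
          d$layer))
      shift <- shift + sgn * d$effect * carrier
      feat <- colnames(genomic[[d$layer]])[col]
      if (spec$duplicateDrivers > 0L)
        dupCols[[d$layer]] <- c(dupCols[[d$layer]],
                                rep(feat, spec$duplicateDrivers))
    } else if (d$layer == "tissue") {
      k <- if (!is.null(d$tissue)) d$tissue else 1L
      shift <- shift + sgn * d$effect * (tissueIdx == k)
      feat <- tissueNames[k]
    } else if (d$layer == "pathway") {
      j <- if (!is.null(d$pathway)) d$pathway else 1L
      shift <- shift + sgn * d$effect * as.vector(scale(pathway[, j]))
      feat <- colnames(pathway)[j]
    } else if (d$layer == "expression") {
      l <- if (!is.null(d$latent)) d$latent else 2L
      shift <- shift + sgn * d$effect * as.vector(scale(latent[, l]))
      feat <- sprintf("latent%d", l)
    } else {
      .validationError(sprintf("unknown driver layer '%s'", d$layer))
    }
    truth <- rbind(truth, data.frame(layer = d$layer, feature = feat,
                                     effect = d$effect,
                                     direction = if (sgn > 0) "resistance"
                                                 else "sensitivity",
                                     stringsAsFactors = FALSE))
  }
  for (layer in names(dupCols)) {
    if (is.null(dupCols[[layer]])) next
    extra <- genomic[[layer]][, dupCols[[layer]], drop = FALSE]
    colnames(extra) <- sprintf("%s_dup%02d", dupCols[[layer]],
                               seq_along(dupCols[[layer]]))
    genomic[[layer]] <- cbind(genomic[[layer]], extra)
  }

  auc <- spec$baseline + spec$noiseSd * (shift + stats::rnorm(n))
  names(auc) <- ids

  dataset <- alignDataset(
    list(mutation = FeatureMatrix(genomic$mutation, "binary"),
         cnv = FeatureMatrix(genomic$cnv, "ternary"),
         methylation = FeatureMatrix(genomic$methylation, "binary"),
         tissue = FeatureMatrix(tissue, "onehot"),
         pathway = FeatureMatrix(pathway, "continuous"),
         expression = FeatureMatrix(expr, "continuous")),
    auc, drug = sprintf("synthetic-seed%d", spec$seed), verbose = FALSE)
  list(dataset = dataset, truth = truth)
}

#' Write a synthetic dataset as a delimited fixture bundle
#'
#' Emits the same TSV layout that [readFeatureMatrix()] /
#' [readResponseTable()] expect: one file per layer plus a response
#' table, so the full file-based entry point can be exercised end to end.
#'
#' @param sim result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @param delim `"tab"` or `"comma"`.
#' @return Named character vector of file paths, invisibly.
#' @export
writeDatasetBundle <- function(sim, dir, delim = "tab") {
  dataset <- sim$dataset
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in presentLayers(dataset)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    writeFeatureMatrix(dataset@layers[[nm]], p, delim)
    paths[nm] <- p
  }
  resp <- matrix(response(dataset), ncol = 1L,
                 dimnames = list(cellLines(dataset), drugLabel(dataset)))
  p <- file.path(dir, "response.tsv")
  out <- data.frame(cell_line = rownames(resp), check.names = FALSE)
  out[[colnames(resp)]] <- sprintf("%.17g", resp[, 1L])
  utils::write.table(out, p, sep = .delimChar(delim), quote = FALSE,
                     row.names = FALSE)
  paths["response"] <- p
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["truth"] <- file.path(dir, "truth.tsv")
  invisible(paths)
}

#' Evaluate recovery of planted drivers from a run
#'
#' Compares a [runTwoStep()] bundle against the ground truth of the
#' synthetic dataset it was computed on: per driver, in how many folds
#' the feature was declared significant, whether it is flagged stable
#' (at least 7 of 10 folds) with the correct effect direction, the mean
#' test ROC-AUC of its source first-step model, and - when ablation
#' records are present - whether the worst ablation subset (per
#' algorithm) removes all driver layers simultaneously.
#'
#' @param bundle a [TwoStepRun-class].
#' @param truth ground-truth data.frame from [generateDataset()].
#' @param driverLayers layers whose simultaneous removal is expected to
#'   be most damaging; defaults to every layer carrying a planted driver.
#' @return List with `drivers` (per-driver recovery data.frame),
#'   `firstStepAuc`, `secondStepAuc` (named mean test ROC-AUCs) and
#'   `ablationAgreement` (fraction and per-algorithm logical vector;
#'   `NULL` without ablation records). Latent expression drivers have no
#'   single named feature and report `NA` hit counts.
#' @export
plantedTruthEval <- function(bundle, truth, driverLayers = NULL) {
  stab <- stabilityTable(bundle)
  nFolds <- bundle@config$nFolds
  drivers <- truth
  drivers$foldHits <- NA_integer_
  drivers$stable <- NA
  drivers$directionRecovered <- NA
  for (i in seq_len(nrow(truth))) {
    if (!truth$layer[i] %in% c("mutation", "cnv", "methylation", "tissue"))
      next
    row <- stab[stab$dataType == truth$layer[i] &
                stab$feature == truth$feature[i], , drop = FALSE]
    drivers$foldHits[i] <- if (nrow(row)) row$foldHits[1L] else 0L
    drivers$stable[i] <- if (nrow(row)) row$stable[1L] else FALSE
    drivers$directionRecovered[i] <-
      if (nrow(row)) row$direction[1L] == truth$direction[i] else FALSE
  }
  roc <- rocAucTable(bundle)
  testRoc <- roc[roc$set == "test", , drop = FALSE]
  meanBy <- function(rows) {
    v <- tapply(rows$rocAuc, rows$model, mean, na.rm = TRUE)
    v[order(names(v))]
  }
  first <- testRoc[testRoc$step == "first", , drop = FALSE]
  second <- testRoc[testRoc$step == "second", , drop = FALSE]
  abl <- ablationTable(bundle)
  agreement <- NULL
  if (!is.null(abl) && nrow(abl)) {
    if (is.null(driverLayers)) driverLayers <- unique(truth$layer)
    driverLayers <- intersect(driverLayers, canonicalLayers())
    perAlg <- vapply(split(abl, abl$algorithm), function(rows) {
      worst <- rows$subset[which.min(rows$relPerformance)]
      all(driverLayers %in% strsplit(worst, "+", fixed = TRUE)[[1L]])
    }, logical(1L))
    agreement <- list(perAlgorithm = perAlg, fraction = mean(perAlg))
  }
  list(drivers = drivers, firstStepAuc = meanBy(first),
       secondStepAuc = meanBy(second), ablationAgreement = agreement)
}
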