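#' Random-forest classification of exposure groups from metabolite
#' profiles
#'
#' Grows an ensemble of randomized decision trees (via \pkg{ranger}) on
#' log2-transformed, per-metabolite min-imputed abundances and estimates
#' the proportion of samples classified correctly. Split points are drawn
#' at random within each candidate feature's range (extremely-randomized
#' splits): in profiling designs with few samples and hundreds of
#' metabolites, many noise features separate a tiny training set by
#' chance with razor-thin margins, and exhaustive split search cannot
#' distinguish them from wide-margin true effects — randomized thresholds
#' make the split quality margin-sensitive. `mtryFraction` of the
#' features is drawn per split (default a third, the classic forest
#' heuristic).
#'
#' Accuracy schemes:
#' \describe{
#'   \item{`loocv`}{stratified leave-one-out cross-validation — each fold
#'     holds out one sample *per group*, so training folds stay balanced
#'     (a plain leave-one-sample-out fold makes the held-out sample's
#'     class the training minority, which biases votes against it at very
#'     small n). Trees are grown on the full training fold; the ensemble
#'     randomness is the split randomization. Default, and the
#'     appropriate choice for designs of ~5 samples/group.}
#'   \item{`oob`}{classic bootstrap bagging with out-of-bag votes;
#'     requires at least 3 samples per group.}
#' }
#'
#' Importance is permutation importance (decrease in out-of-bag accuracy
#' when a feature is permuted), computed on a bootstrap ensemble grown on
#' all samples with the same seed — comparable across abundance scales.
#'
#' @param se metabolite SummarizedExperiment (assay `abundance`, natural
#'   scale, NAs allowed unless a feature is entirely missing) with
#'   `colData$group`.
#' @param nTrees trees in the ensemble.
#' @param scheme accuracy estimation scheme, see Details.
#' @param mtryFraction fraction of features drawn per split.
#' @param seed integer seed; reports are identical under the same seed.
#' @return a [ClassificationReport-class].
#' @export
rfClassify <- function(se, nTrees = 500, scheme = c("loocv", "oob"),
                       mtryFraction = 1 / 3, seed = 1) {
  scheme <- match.arg(scheme)
  groups <- sampleGroups(se)
  if (length(unique(groups)) < 2)
    .paramError("se", "need at least 2 groups")
  if (scheme == "oob" && min(table(groups)) < 3)
    .paramError("scheme", "oob needs >= 3 samples per group; use loocv")
  vals <- SummarizedExperiment::assay(se, 1)
  allMissing <- rownames(vals)[rowSums(!is.na(vals)) == 0]
  if (length(allMissing))
    stop("feature(s) entirely missing: ",
         paste(utils::head(allMissing, 5), collapse = ", "))
  vals <- .imputeMin(vals)
  vals[vals <= 0] <- min(vals[vals > 0]) / 2
  x <- t(log2(vals))
  y <- factor(unname(groups))
  mtry <- max(1L, floor(ncol(x) * mtryFraction))
  common <- list(num.trees = nTrees, mtry = mtry,
                 splitrule = "extratrees", num.random.splits = 1,
                 num.threads = 1)

  if (scheme == "oob") {
    fit <- do.call(ranger::ranger,
                   c(list(x = x, y = y, seed = as.integer(seed)), common))
    pred <- fit$predictions
  } else {
    byGroup <- split(seq_along(y), y)
    nFolds <- max(lengths(byGroup))
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(nFolds)) {
      hold <- unlist(lapply(byGroup, function(i)
        if (f <= length(i)) i[f] else integer()))
      fit <- do.call(ranger::ranger,
                     c(list(x = x[-hold, , drop = FALSE], y = y[-hold],
                            replace = FALSE, sample.fraction = 1,
                            seed = childSeed(seed, "classify") + f),
                       common))
      pred[hold] <- stats::predict(fit, x[hold, , drop = FALSE],
                                   num.threads = 1)$predictions
    }
  }
  acc <- mean(pred == y, na.rm = TRUE)
  conf <- table(truth = y, predicted = pred)

  impFit <- do.call(ranger::ranger,
                    c(list(x = x, y = y, importance = "permutation",
                           seed = as.integer(seed)), common))
  imp <- impFit$variable.importance
  o <- order(-imp, names(imp))
  impDf <- data.frame(metabolite = names(imp)[o],
                      importance = unname(imp)[o],
                      row.names = NULL, stringsAsFactors = FALSE)
  rd <- SummarizedExperiment::rowData(se)
  ann <- data.frame(metabolite = rownames(se),
                    super_pathway = if ("super_pathway" %in% names(rd))
                      as.character(rd$super_pathway) else "unknown",
                    stringsAsFactors = FALSE)

  new("ClassificationReport", accuracy = acc, scheme = scheme,
      confusion = unclass(conf), importance = impDf,
      nTrees = as.integer(nTrees), seed = as.integer(seed),
      annotations = ann)
}

#' Ranked biochemical importance table
#'
#' The tabular analogue of a biochemical importance plot: every input
#' metabolite ranked by permutation importance (descending), ties broken
#' by metabolite id, annotated with its super-pathway.
#'
#' @param report a [ClassificationReport-class].
#' @return data.frame with columns rank, metabolite, importance,
#'   super_pathway.
#' @export
importanceTable <- function(report) {
  imp <- report@importance
  ann <- report@annotations
  data.frame(rank = seq_len(nrow(imp)), metabolite = imp$metabolite,
             importance = imp$importance,
             super_pathway = ann$super_pathway[match(imp$metabolite,
                                                     ann$metabolite)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @describeIn rfClassify accuracy estimate accessor
#' @param report a `ClassificationReport`.
#' @export
accuracyEstimate <- function(report) report@accuracy
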