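#' @importFrom methods new validObject is slot
#' @importFrom stats phyper pt rnorm runif rbinom smooth.spline predict
#'   p.adjust median quantile setNames complete.cases
#' @importFrom utils read.delim write.table head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Timestamped log line on standard error
#'
#' All pipeline-stage logging goes through this helper so that results on
#' standard output are never mixed with diagnostics.
#'
#' @param ... character fragments pasted into the message.
#' @param level severity label (INFO, WARN).
#' @keywords internal
logMsg <- function(..., level = "INFO") {
  message(sprintf("[%s] %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  level, paste0(...)))
}

# Named offsets of the per-stage seed stream. The scheme is fixed and
# documented: child = (seed * 131 + offset) mod (2^31 - 1), so each stage of
# a run is independently reproducible from the single global seed.
.stageOffsets <- c(
  expression = 11L, metabolome = 23L, network = 37L, pathways = 41L,
  deg = 53L, metab = 59L, gsea = 67L, ora = 71L, kda = 79L,
  classify = 83L, integrate = 89L, pipeline = 97L
)

#' Derive a per-stage child seed from a global seed
#'
#' Expands one global seed into independent per-stage seeds by a fixed
#' affine scheme, `(seed * 131 + offset) mod (2^31 - 1)`, with a documented
#' offset per stage name. Re-running any single stage with its child seed
#' reproduces that stage exactly.
#'
#' @param seed single integer global seed.
#' @param stage stage name, one of `names(OmicKDA:::.stageOffsets)`.
#' @return a single integer seed below 2^31.
#' @examples
#' childSeed(7, "network")
#' @export
childSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  stage <- match.arg(stage, names(.stageOffsets))
  as.integer((abs(as.numeric(seed)) * 131 + .stageOffsets[[stage]]) %% 2147483647)
}

# consistent parameter error: names the offending argument
.paramError <- function(arg, msg) {
  stop(sprintf("invalid argument '%s': %s", arg, msg), call. = FALSE)
}

.usageError <- function(msg) {
  cond <- structure(class = c("omickda_usage_error", "error", "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

# group labels of a SummarizedExperiment produced/consumed by this package
#' Sample group labels of an omics matrix
#' @param se a [SummarizedExperiment::SummarizedExperiment] with a `group`
#'   column in its `colData`.
#' @return character vector of group labels, named by sample id.
#' @export
sampleGroups <- function(se) {
  g <- SummarizedExperiment::colData(se)$group
  stats::setNames(as.character(g), colnames(se))
}
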