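#' @import methods
NULL

.abundanceUnits <- c("copies_per_ul", "reads", "proportion")

#' AbundanceTable: a sample-by-taxon abundance matrix with a unit tag
#'
#' The central container of the package: a numeric matrix with samples as
#' rows and taxa as columns, tagged with the unit of measurement. qPCR
#' tables (\code{unit = "copies_per_ul"}) use \code{NA} for negative calls
#' (no detection above the cutoff); read-count and proportion tables have
#' no missing values. Proportion tables must have rows summing to 1 over
#' the taxon set the table declares.
#'
#' @slot values numeric matrix, samples x taxa, with dimnames.
#' @slot unit one of \code{"copies_per_ul"}, \code{"reads"},
#'   \code{"proportion"}.
#'
#' @seealso [abundanceTable()], [relativeAbundance()], [isPositive()]
#' @export
setClass("AbundanceTable",
         slots = c(values = "matrix", unit = "character"))

setValidity("AbundanceTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have sample rownames and taxon colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated sample names")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated taxon names")
  }
  if (length(object@unit) != 1L || !object@unit %in% .abundanceUnits)
    msg <- c(msg, sprintf("'unit' must be one of %s",
                          paste(.abundanceUnits, collapse = ", ")))
  if (is.numeric(v) && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "abundances must be nonnegative")
  if (length(object@unit) == 1L && object@unit != "copies_per_ul" &&
      anyNA(v))
    msg <- c(msg, "NA values are only allowed for unit 'copies_per_ul'")
  if (length(object@unit) == 1L && object@unit == "proportion" &&
      nrow(v) > 0L && ncol(v) > 0L &&
      any(abs(rowSums(v) - 1) > 1e-9))
    msg <- c(msg, "proportion rows must sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' StandardCurve: per-assay log-linear qPCR calibration
#'
#' Log-linear calibration of quantification cycle (Cq) against log10 known
#' template copies, fitted from serial dilutions of a quantification
#' standard. The slope is expected negative; an ideal 100\%-efficient assay
#' has slope -1/log10(2) = -3.3219.
#'
#' @slot assay assay (target species) identifier.
#' @slot slope Cq change per log10 copies (negative).
#' @slot intercept Cq at 1 copy/ul.
#' @slot rSquared coefficient of determination of the calibration fit.
#' @slot validRange copies/ul range covered by the standards
#'   (default 1e3 to 1e7).
#'
#' @seealso [fitStandardCurve()], [quantifyReaction()]
#' @export
setClass("StandardCurve",
         slots = c(assay = "character", slope = "numeric",
                   intercept = "numeric", rSquared = "numeric",
                   validRange = "numeric"))

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (length(object@slope) != 1L || is.na(object@slope) ||
      object@slope >= 0)
    msg <- c(msg, "'slope' must be a single negative number")
  if (length(object@intercept) != 1L || is.na(object@intercept))
    msg <- c(msg, "'intercept' must be a single number")
  if (length(object@validRange) != 2L ||
      object@validRange[1L] <= 0 ||
      object@validRange[1L] >= object@validRange[2L])
    msg <- c(msg, "'validRange' must be increasing positive c(low, high)")
  if (length(msg)) msg else TRUE
})

#' CommunityTruth: ground truth of a simulated community
#'
#' The known state of a simulated microbial community: absolute genome
#' abundances (copies/ul), per-taxon sequencing measurement efficiencies
#' (geometric mean 1 across taxa), per-taxon mean 16S gene copy numbers,
#' and per-sample sequencing depths. Paired qPCR and amplicon observations
#' are drawn from this truth with [observeQPCR()] and [observeNGS()].
#'
#' @slot samples,taxa identifiers.
#' @slot trueAbundance samples x taxa matrix of genome copies/ul.
#' @slot efficiency per-taxon sequencing efficiency, geometric mean 1.
#' @slot copyNumber per-taxon mean 16S copies per genome, in [1, 15].
#' @slot depth per-sample total read count.
#' @slot detectionLimit qPCR censoring threshold in copies/ul.
#' @slot seed root seed the truth was generated from.
#'
#' @seealso [simulateTruth()], [trueBias()]
#' @export
setClass("CommunityTruth",
         slots = c(samples = "character", taxa = "character",
                   trueAbundance = "matrix", efficiency = "numeric",
                   copyNumber = "numeric", depth = "numeric",
                   detectionLimit = "numeric", seed = "integer"))

setValidity("CommunityTruth", function(object) {
  msg <- character()
  a <- object@trueAbundance
  nT <- length(object@taxa)
  if (nT < 2L) msg <- c(msg, "need at least 2 taxa")
  if (!identical(dim(a), c(length(object@samples), nT)))
    msg <- c(msg, "'trueAbundance' dimensions must match samples x taxa")
  if (any(a < 0)) msg <- c(msg, "'trueAbundance' must be nonnegative")
  if (length(object@efficiency) != nT ||
      any(object@efficiency <= 0))
    msg <- c(msg, "'efficiency' must be positive, one per taxon")
  else if (abs(mean(log(object@efficiency))) > 1e-12)
    msg <- c(msg, "'efficiency' must have geometric mean 1 within 1e-12")
  if (length(object@copyNumber) != nT ||
      any(object@copyNumber < 1 | object@copyNumber > 15))
    msg <- c(msg, "'copyNumber' must lie in [1, 15], one per taxon")
  if (length(object@depth) != length(object@samples) ||
      any(object@depth < 1))
    msg <- c(msg, "'depth' must be a positive count per sample")
  if (length(object@detectionLimit) != 1L || object@detectionLimit <= 0)
    msg <- c(msg, "'detectionLimit' must be a single positive number")
  if (identical(dim(a), c(length(object@samples), nT)) &&
      nrow(a) > 0L &&
      any(rowSums(a > object@detectionLimit) < 2L))
    msg <- c(msg,
             "every sample needs >= 2 taxa above the detection limit")
  if (length(msg)) msg else TRUE
})

.detectionCategories <- c("shared_positive", "qpcr_only", "ngs_only",
                          "ngs_exclusive", "undetected")

#' DetectionMatrix: per-(sample, taxon) detection categories
#'
#' Classifies every (sample, taxon) cell into one of five categories
#' comparing a targeted qPCR panel against non-targeted amplicon
#' sequencing: \code{shared_positive} (both methods), \code{qpcr_only},
#' \code{ngs_only} (panel taxa seen by one method), \code{ngs_exclusive}
#' (taxa outside the qPCR assay panel, seen by sequencing only), and
#' \code{undetected}.
#'
#' @slot categories character matrix, samples x taxa.
#' @slot panel taxa covered by the qPCR assay panel.
#'
#' @seealso [classifyDetections()], [detectionCounts()]
#' @export
setClass("DetectionMatrix",
         slots = c(categories = "matrix", panel = "character"))

setValidity("DetectionMatrix", function(object) {
  cm <- object@categories
  msg <- character()
  if (!is.character(cm) || is.null(rownames(cm)) || is.null(colnames(cm)))
    msg <- c(msg, "'categories' must be a character matrix with dimnames")
  else {
    if (!all(cm %in% .detectionCategories))
      msg <- c(msg, "unknown detection category")
    off <- setdiff(colnames(cm), object@panel)
    onp <- intersect(colnames(cm), object@panel)
    if (length(onp) && any(cm[, onp, drop = FALSE] == "ngs_exclusive"))
      msg <- c(msg, "'ngs_exclusive' is reserved for taxa outside the panel")
    if (length(off) &&
        any(cm[, off, drop = FALSE] %in%
            c("shared_positive", "qpcr_only", "ngs_only")))
      msg <- c(msg, "panel categories assigned to a non-panel taxon")
  }
  if (length(msg)) msg else TRUE
})

#' PairedCompositions: per-sample observed/reference proportion pairs
#'
#' The input of the compositional bias estimator. For each sample, the
#' observed (sequencing) and reference (qPCR) measurements are restricted
#' to the taxa the reference detected in that sample, pseudocounts are
#' applied to observed zeros, and both vectors are renormalized to sum
#' to 1 over that shared subset.
#'
#' @slot observed,reference named lists (one element per sample) of named
#'   proportion vectors over identical taxon subsets.
#' @slot taxa the taxon universe (union over samples).
#' @slot pseudocount pseudocount applied to observed zeros before
#'   renormalization.
#'
#' @seealso [buildPairedCompositions()], [estimateBias()]
#' @export
setClass("PairedCompositions",
         slots = c(observed = "list", reference = "list",
                   taxa = "character", pseudocount = "numeric"))

setValidity("PairedCompositions", function(object) {
  msg <- character()
  if (!identical(names(object@observed), names(object@reference)))
    msg <- c(msg, "observed and reference must cover identical samples")
  for (s in names(object@observed)) {
    o <- object@observed[[s]]
    r <- object@reference[[s]]
    if (!identical(names(o), names(r))) {
      msg <- c(msg, sprintf("sample '%s': taxon subsets differ", s))
      next
    }
    if (abs(sum(o) - 1) > 1e-9 || abs(sum(r) - 1) > 1e-9)
      msg <- c(msg, sprintf("sample '%s': compositions must sum to 1", s))
    if (any(r <= 0))
      msg <- c(msg, sprintf("sample '%s': reference entries must be > 0", s))
    if (any(o <= 0))
      msg <- c(msg, sprintf("sample '%s': observed entries must be > 0", s))
    if (!all(names(o) %in% object@taxa))
      msg <- c(msg, sprintf("sample '%s': taxa outside the universe", s))
  }
  if (length(msg)) msg else TRUE
})

#' BiasEstimate: per-taxon compositional bias with bootstrap uncertainty
#'
#' Point estimates of the per-taxon measurement efficiency of the observed
#' method relative to the reference, normalized to geometric mean 1 over
#' the estimated taxa, together with bootstrap geometric standard errors
#' (GSE; \code{NA} when a taxon was estimated from a single sample or the
#' bootstrap was not run).
#'
#' @slot estimate named per-taxon bias point estimates (geometric mean 1).
#' @slot gse named per-taxon geometric standard errors (>= 1 or NA).
#' @slot nBootstrap number of bootstrap replicates used (0 if none).
#' @slot nSamplesUsed named per-taxon count of samples informing the
#'   estimate.
#'
#' @seealso [estimateBias()], [bootstrapGSE()], [gseInterval()]
#' @export
setClass("BiasEstimate",
         slots = c(estimate = "numeric", gse = "numeric",
                   nBootstrap = "integer", nSamplesUsed = "integer"))

setValidity("BiasEstimate", function(object) {
  msg <- character()
  est <- object@estimate
  if (is.null(names(est)) || any(est <= 0))
    msg <- c(msg, "'estimate' must be named and positive")
  else if (abs(mean(log(est))) > 1e-9)
    msg <- c(msg, "'estimate' must have geometric mean 1 within 1e-9")
  if (!identical(names(object@gse), names(est)))
    msg <- c(msg, "'gse' must be named like 'estimate'")
  if (any(object@gse < 1, na.rm = TRUE))
    msg <- c(msg, "'gse' must be >= 1 where defined")
  if (length(msg)) msg else TRUE
})
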