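#' @include AllClasses.R
NULL

#' Construct an AbundanceTable
#'
#' @param values numeric matrix, samples as rows, taxa as columns, with
#'   dimnames. A data.frame is coerced.
#' @param unit one of \code{"copies_per_ul"}, \code{"reads"},
#'   \code{"proportion"}.
#'
#' @return An [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(50, 50, 90, 10), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("S01", "S02"), c("taxonA", "taxonB")))
#' abundanceTable(m, unit = "reads")
#' @export
abundanceTable <- function(values, unit = c("reads", "copies_per_ul",
                                            "proportion")) {
  unit <- match.arg(unit)
  if (is.data.frame(values)) values <- as.matrix(values)
  new("AbundanceTable", values = values, unit = unit)
}

#' @describeIn abundanceTable the underlying sample-by-taxon matrix.
#' @param x,object an \code{AbundanceTable}.
#' @export
abundValues <- function(x) x@values

#' @describeIn abundanceTable the unit tag.
#' @export
abundUnit <- function(x) x@unit

#' Sample and taxon identifiers
#'
#' @param x an \code{AbundanceTable}, \code{CommunityTruth} or
#'   \code{DetectionMatrix}.
#' @return Character vector of identifiers.
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname sampleNames
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "AbundanceTable", function(x) rownames(x@values))

#' @rdname sampleNames
#' @export
setMethod("taxonNames", "AbundanceTable", function(x) colnames(x@values))

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "CommunityTruth", function(x) x@samples)

#' @rdname sampleNames
#' @export
setMethod("taxonNames", "CommunityTruth", function(x) x@taxa)

#' @rdname sampleNames
#' @export
setMethod("sampleNames", "DetectionMatrix",
          function(x) rownames(x@categories))

#' @rdname sampleNames
#' @export
setMethod("taxonNames", "DetectionMatrix",
          function(x) colnames(x@categories))

#' Positivity of abundance measurements
#'
#' A cell is positive when a measurement was obtained: for qPCR tables a
#' non-missing value (negative calls are stored as \code{NA}), for read
#' counts at least one read, for proportions a value above zero.
#'
#' @param x an [AbundanceTable-class].
#' @return Logical samples-by-taxa matrix.
#' @export
isPositive <- function(x) {
  stopifnot(is(x, "AbundanceTable"))
  !is.na(x@values) & x@values > 0
}

#' Subset an AbundanceTable
#'
#' @param x an \code{AbundanceTable}.
#' @param i,j sample / taxon indices or names.
#' @param ... ignored.
#' @param drop ignored; the result is always an \code{AbundanceTable}.
#' @export
setMethod("[", "AbundanceTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@values))
  if (missing(j)) j <- seq_len(ncol(x@values))
  initialize(x, values = x@values[i, j, drop = FALSE])
})

setMethod("show", "AbundanceTable", function(object) {
  v <- object@values
  cat(sprintf("AbundanceTable: %d samples x %d taxa [%s]\n",
              nrow(v), ncol(v), object@unit))
  if (object@unit == "copies_per_ul")
    cat(sprintf("  negative calls (NA): %d of %d cells\n",
                sum(is.na(v)), length(v)))
  n <- min(4L, nrow(v)); m <- min(4L, ncol(v))
  if (n && m) print(signif(v[seq_len(n), seq_len(m), drop = FALSE], 4))
  if (nrow(v) > n || ncol(v) > m) cat("  ...\n")
  invisible(NULL)
})

setMethod("show", "StandardCurve", function(object) {
  cat(sprintf(
    "StandardCurve '%s': Cq = %.4f * log10(copies) + %.4f\n",
    object@assay, object@slope, object@intercept))
  cat(sprintf("  efficiency %.3f, R^2 %.4f, valid %g-%g copies/ul\n",
              amplificationEfficiency(object), object@rSquared,
              object@validRange[1L], object@validRange[2L]))
  invisible(NULL)
})

setMethod("show", "CommunityTruth", function(object) {
  cat(sprintf(
    "CommunityTruth: %d samples x %d taxa (seed %d)\n",
    length(object@samples), length(object@taxa), object@seed))
  cat(sprintf("  detection limit %g copies/ul; depth %s reads\n",
              object@detectionLimit,
              paste(unique(object@depth), collapse = "/")))
  cat(sprintf("  16S copy numbers %s; efficiency range %.3g-%.3g\n",
              paste(range(object@copyNumber), collapse = "-"),
              min(object@efficiency), max(object@efficiency)))
  invisible(NULL)
})

setMethod("show", "DetectionMatrix", function(object) {
  cat(sprintf("DetectionMatrix: %d samples x %d taxa (%d panel assays)\n",
              nrow(object@categories), ncol(object@categories),
              length(object@panel)))
  print(detectionCounts(object))
  invisible(NULL)
})

setMethod("show", "PairedCompositions", function(object) {
  ns <- lengths(object@observed)
  cat(sprintf(
    "PairedCompositions: %d samples, %d taxa (pseudocount %g)\n",
    length(object@observed), length(object@taxa), object@pseudocount))
  cat(sprintf("  taxa per sample: %d-%d\n", min(ns), max(ns)))
  invisible(NULL)
})

setMethod("show", "BiasEstimate", function(object) {
  cat(sprintf("BiasEstimate: %d taxa (geometric mean 1)\n",
              length(object@estimate)))
  if (object@nBootstrap > 0L)
    cat(sprintf("  bootstrap GSE from %d replicates\n", object@nBootstrap))
  print(head(gseInterval(object), 8L))
  if (length(object@estimate) > 8L) cat("  ...\n")
  invisible(NULL)
})

#' @describeIn estimateBias per-taxon point estimates of a
#'   \code{BiasEstimate}.
#' @param x a \code{BiasEstimate}.
#' @export
biasEstimates <- function(x) {
  stopifnot(is(x, "BiasEstimate"))
  x@estimate
}

#' @describeIn estimateBias per-taxon geometric standard errors.
#' @export
biasGSE <- function(x) {
  stopifnot(is(x, "BiasEstimate"))
  x@gse
}
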