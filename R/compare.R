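#' Classify per-(sample, taxon) detections across the two methods
#'
#' Compares a targeted qPCR panel with non-targeted amplicon sequencing
#' cell by cell. For taxa covered by the assay panel: positive by both
#' methods = \code{shared_positive}, by one = \code{qpcr_only} /
#' \code{ngs_only}. Taxa outside the panel with at least one read are
#' \code{ngs_exclusive}; everything else is \code{undetected}. qPCR
#' positivity is a non-missing value (the 2-of-3 / cutoff rules are
#' applied upstream by [quantifyReactions()]); sequencing positivity is at
#' least one read.
#'
#' @param qpcr qPCR [AbundanceTable-class] (copies/ul, \code{NA} =
#'   negative call).
#' @param ngs sequencing [AbundanceTable-class] (reads).
#' @param panel taxa covered by qPCR assays; defaults to the qPCR table's
#'   taxa.
#'
#' @return A [DetectionMatrix-class] over the union of both taxon sets.
#' @export
classifyDetections <- function(qpcr, ngs, panel = taxonNames(qpcr)) {
  stopifnot(is(qpcr, "AbundanceTable"), is(ngs, "AbundanceTable"))
  if (!setequal(sampleNames(qpcr), sampleNames(ngs)))
    stop("qPCR and sequencing tables must cover the same samples")
  samples <- sampleNames(qpcr)
  taxa <- union(panel, union(taxonNames(qpcr), taxonNames(ngs)))
  qpos <- npos <- matrix(FALSE, length(samples), length(taxa),
                         dimnames = list(samples, taxa))
  qp <- isPositive(qpcr)
  qpos[samples, taxonNames(qpcr)] <- qp[samples, ]
  np <- isPositive(ngs)
  npos[samples, taxonNames(ngs)] <- np[samples, ]
  cat_ <- matrix("undetected", length(samples), length(taxa),
                 dimnames = list(samples, taxa))
  onPanel <- matrix(rep(taxa %in% panel, each = length(samples)),
                    length(samples))
  cat_[onPanel & qpos & npos] <- "shared_positive"
  cat_[onPanel & qpos & !npos] <- "qpcr_only"
  cat_[onPanel & !qpos & npos] <- "ngs_only"
  cat_[!onPanel & npos] <- "ngs_exclusive"
  new("DetectionMatrix", categories = cat_, panel = panel)
}

#' @describeIn classifyDetections tally of cells per detection category.
#' @param x a \code{DetectionMatrix}.
#' @export
detectionCounts <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  counts <- table(factor(x@categories, levels = .detectionCategories))
  stats::setNames(as.integer(counts), names(counts))
}

#' @describeIn classifyDetections per-sample sets of shared-positive taxa.
#' @export
sharedTaxa <- function(x) {
  stopifnot(is(x, "DetectionMatrix"))
  apply(x@categories, 1L, function(row)
    colnames(x@categories)[row == "shared_positive"], simplify = FALSE)
}

#' Per-sample read coverage of a taxon set
#'
#' Percentage of each sample's reads assigned to a given per-sample taxon
#' set (typically the taxa detected by both methods), summarizing how much
#' of the community the targeted panel captures.
#'
#' @param ngs sequencing [AbundanceTable-class] (reads).
#' @param panelDetected a [DetectionMatrix-class] (shared-positive taxa
#'   are used) or a named list of per-sample taxon character vectors.
#'
#' @return A list with \code{perSample} (named percentages), \code{mean},
#'   \code{min} and \code{max}.
#' @export
coverageStats <- function(ngs, panelDetected) {
  stopifnot(is(ngs, "AbundanceTable"))
  if (is(panelDetected, "DetectionMatrix"))
    panelDetected <- sharedTaxa(panelDetected)
  v <- ngs@values
  samples <- rownames(v)
  if (!all(samples %in% names(panelDetected)))
    stop("per-sample taxon sets missing for some samples")
  pct <- vapply(samples, function(s) {
    tot <- sum(v[s, ])
    if (tot <= 0)
      stop(sprintf("sample '%s' has zero total reads", s))
    set <- intersect(panelDetected[[s]], colnames(v))
    100 * sum(v[s, set]) / tot
  }, numeric(1L))
  list(perSample = pct, mean = mean(pct), min = min(pct), max = max(pct))
}

#' Coefficient of determination between paired measurements
#'
#' \code{logLogR2()} fits ordinary least squares on log10-transformed
#' pairs (absolute copies vs read counts); \code{linearR2()} fits on the
#' raw scale (used for relative abundance pairs). Both return the R
#' squared of the fit.
#'
#' @param x,y paired measurements (e.g. reads and copies/ul); at least 3
#'   pairs, and strictly positive for the log version.
#'
#' @return R squared of the simple OLS fit.
#' @export
logLogR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired values")
  if (any(x <= 0) || any(y <= 0))
    stop("log-log R^2 requires strictly positive values")
  linearR2(log10(x), log10(y))
}

#' @rdname logLogR2
#' @export
linearR2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired values")
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \code{sum(|x - y|) / sum(x + y)}: 0 for identical vectors, 1 for
#' disjoint support.
#'
#' @param x,y nonnegative vectors over the same taxon ordering.
#' @return Dissimilarity in [0, 1].
#' @examples
#' brayCurtis(c(0.7, 0.3), c(0.5, 0.5))  # 0.2
#' @export
brayCurtis <- function(x, y) {
  if (length(x) != length(y))
    stop("vectors must have the same length (same taxon ordering)")
  if (any(x < 0) || any(y < 0))
    stop("entries must be nonnegative")
  tot <- sum(x) + sum(y)
  if (tot == 0)
    stop("both vectors are all-zero; dissimilarity undefined")
  sum(abs(x - y)) / tot
}

#' @describeIn brayCurtis full pairwise dissimilarity matrix over the
#'   rows of a profile matrix.
#' @param m matrix with profiles as rows.
#' @export
brayCurtisMatrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      d[i, j] <- d[j, i] <- brayCurtis(m[i, ], m[j, ])
  d
}

#' UPGMA (average linkage) clustering of a dissimilarity matrix
#'
#' Agglomerative average-linkage clustering producing a rooted ultrametric
#' dendrogram. Labels are sorted lexicographically before clustering so
#' equal-distance merges resolve deterministically across platforms. Leaf
#' heights in the returned tree are half the cophenetic distance, so
#' tip-to-tip path lengths reproduce the merge distances.
#'
#' @param d symmetric nonnegative dissimilarity matrix with zero diagonal
#'   (labels as dimnames), or a \code{dist} object.
#'
#' @return An \code{ape} \code{phylo} tree (ultrametric, rooted).
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("'d' must be a square dissimilarity matrix or a dist object")
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("L", seq_len(nrow(d))),
                        paste0("L", seq_len(nrow(d))))
  if (!isSymmetric(unname(d), tol = 1e-12))
    stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) != 0))
    stop("dissimilarity matrix must have a zero diagonal")
  if (any(d < 0))
    stop("dissimilarities must be nonnegative")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}

#' Cluster paired method profiles of the same samples
#'
#' Builds one relative-abundance profile per (sample, method) over a
#' shared taxon set, computes all pairwise Bray-Curtis dissimilarities,
#' clusters the 2N profiles by UPGMA, and reports for each sample whether
#' its two method profiles end up as sibling leaves -- the tree-based
#' notion of "the two methods agree on this sample".
#'
#' @param qpcr qPCR [AbundanceTable-class] (copies/ul).
#' @param ngs sequencing [AbundanceTable-class] (reads or corrected
#'   counts).
#' @param taxa shared taxon set both profiles are renormalized over.
#' @param methodLabels labels appended to sample names for the two
#'   profiles.
#'
#' @return A list: \code{tree} (\code{phylo}), \code{dist} (2N x 2N
#'   Bray-Curtis matrix), \code{siblings} (named logical per sample) and
#'   \code{siblingRate}.
#' @export
clusterMethodProfiles <- function(qpcr, ngs, taxa,
                                  methodLabels = c("qPCR", "NGS")) {
  stopifnot(is(qpcr, "AbundanceTable"), is(ngs, "AbundanceTable"))
  if (!setequal(sampleNames(qpcr), sampleNames(ngs)))
    stop("qPCR and sequencing tables must cover the same samples")
  samples <- sort(sampleNames(qpcr))
  pq <- abundValues(relativeAbundance(qpcr, taxa = taxa))[samples, ,
                                                          drop = FALSE]
  pn <- abundValues(relativeAbundance(ngs, taxa = taxa))[samples, ,
                                                         drop = FALSE]
  prof <- rbind(pq, pn)
  rownames(prof) <- c(paste(samples, methodLabels[1L], sep = "_"),
                      paste(samples, methodLabels[2L], sep = "_"))
  d <- brayCurtisMatrix(prof)
  tree <- upgmaTree(d)
  parentOf <- function(label) {
    tip <- match(label, tree$tip.label)
    tree$edge[tree$edge[, 2L] == tip, 1L]
  }
  siblings <- vapply(samples, function(s)
    parentOf(paste(s, methodLabels[1L], sep = "_")) ==
      parentOf(paste(s, methodLabels[2L], sep = "_")), logical(1L))
  list(tree = tree, dist = d, siblings = siblings,
       siblingRate = mean(siblings))
}
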