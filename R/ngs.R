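#' Convert abundances to relative abundances (proportions)
#'
#' Divides each sample row by its total over the declared taxon set.
#' Negative qPCR calls (\code{NA}) contribute zero. The last taxon column
#' absorbs floating-point rounding so rows sum to 1 exactly.
#'
#' @param table an [AbundanceTable-class].
#' @param taxa optional taxon subset to restrict and renormalize over.
#'
#' @return An [AbundanceTable-class] with \code{unit = "proportion"}.
#' @examples
#' m <- matrix(c(80, 10, 10), 1, dimnames = list("S01", c("A", "B", "C")))
#' abundValues(relativeAbundance(abundanceTable(m, "reads"),
#'                               taxa = c("A", "B")))  # 8/9, 1/9
#' @export
relativeAbundance <- function(table, taxa = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  v <- table@values
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, colnames(v))
    if (length(miss))
      stop("taxa absent from the table: ", paste(miss, collapse = ", "))
    v <- v[, taxa, drop = FALSE]
  }
  v[is.na(v)] <- 0
  tot <- rowSums(v)
  bad <- tot <= 0
  if (any(bad))
    stop("zero total abundance in sample(s): ",
         paste(rownames(v)[bad], collapse = ", "))
  p <- v / tot
  if (ncol(p) > 1L) {
    last <- ncol(p)
    p[, last] <- pmax(0, 1 - rowSums(p[, -last, drop = FALSE]))
  }
  abundanceTable(p, unit = "proportion")
}

#' Merge taxon columns into a named group
#'
#' Sums the listed member columns into a single group column; members
#' absent from the table contribute zero, and a table lacking every member
#' gains an all-zero group column. For qPCR tables a group whose present
#' members are all negative calls stays a negative call.
#'
#' @param table an [AbundanceTable-class].
#' @param members taxon labels to merge (absent ones ignored).
#' @param group label of the merged column.
#'
#' @return An [AbundanceTable-class] (same unit).
#' @export
mergeTaxa <- function(table, members, group) {
  stopifnot(is(table, "AbundanceTable"))
  v <- table@values
  if (group %in% setdiff(colnames(v), members))
    stop(sprintf("group label '%s' collides with an existing taxon", group))
  present <- intersect(members, colnames(v))
  keep <- v[, setdiff(colnames(v), members), drop = FALSE]
  if (length(present)) {
    sub <- v[, present, drop = FALSE]
    merged <- rowSums(sub, na.rm = TRUE)
    if (table@unit == "copies_per_ul")
      merged[rowSums(!is.na(sub)) == 0L] <- NA_real_
  } else {
    merged <- rep(0, nrow(v))
  }
  out <- cbind(keep, merged)
  colnames(out)[ncol(out)] <- group
  rownames(out) <- rownames(v)
  abundanceTable(out, unit = table@unit)
}

#' Merge the Lactiplantibacillus plantarum group across both methods
#'
#' V1-V2 16S amplicons cannot separate \emph{Lactiplantibacillus
#' plantarum}, \emph{L. pentosus} and \emph{L. paraplantarum}; the
#' sequencing pipeline assigns reads to \emph{plantarum}/\emph{pentosus}
#' while the targeted panel assays \emph{plantarum} and
#' \emph{paraplantarum}. This correction merges each method's members into
#' one common "L. plantarum group" column so the two tables describe the
#' same taxon.
#'
#' @param ngs sequencing [AbundanceTable-class] (reads or proportions).
#' @param qpcr qPCR [AbundanceTable-class] (copies/ul).
#' @param ngsMembers,qpcrMembers member taxa merged on each side.
#' @param group common label of the merged column.
#'
#' @return A list with elements \code{ngs} and \code{qpcr}, each with the
#'   group column in place of its members.
#' @export
mergePlantarumGroup <- function(ngs, qpcr,
    ngsMembers = c("Lactiplantibacillus pentosus",
                   "Lactiplantibacillus plantarum"),
    qpcrMembers = c("Lactiplantibacillus plantarum",
                    "Lactiplantibacillus paraplantarum"),
    group = "L. plantarum group") {
  list(ngs = mergeTaxa(ngs, ngsMembers, group),
       qpcr = mergeTaxa(qpcr, qpcrMembers, group))
}

#' 16S gene copy-number normalization (GCN)
#'
#' Divides each taxon's read counts by its mean 16S rRNA gene copies per
#' genome, approximating genome-level abundance. Proportions computed
#' downstream from the corrected counts are then comparable to single-copy
#' gene qPCR measurements.
#'
#' @param table an [AbundanceTable-class] of read counts.
#' @param copyNumbers named numeric vector, taxon -> mean 16S copies per
#'   genome (> 0).
#' @param default copy number used for taxa missing from
#'   \code{copyNumbers}; if \code{NULL} (default) missing taxa are an
#'   error.
#'
#' @return An [AbundanceTable-class] of corrected counts (same unit).
#' @examples
#' m <- matrix(c(89, 10), 1, dimnames = list("S01", c("A", "B")))
#' gcn <- c(A = 8.9, B = 1)
#' abundValues(gcnNormalize(abundanceTable(m, "reads"), gcn))  # 10, 10
#' @export
gcnNormalize <- function(table, copyNumbers, default = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  if (any(copyNumbers <= 0, na.rm = TRUE))
    stop("copy numbers must be positive")
  taxa <- colnames(table@values)
  miss <- setdiff(taxa, names(copyNumbers))
  if (length(miss) && is.null(default))
    stop("no 16S copy number for taxa: ", paste(miss, collapse = ", "))
  cn <- rep(if (is.null(default)) NA_real_ else default, length(taxa))
  names(cn) <- taxa
  hit <- intersect(taxa, names(copyNumbers))
  cn[hit] <- copyNumbers[hit]
  abundanceTable(sweep(table@values, 2L, cn, "/"), unit = table@unit)
}

#' Filter taxa by detection prevalence
#'
#' Keeps taxa detected in strictly more than a given fraction of samples
#' (default 0.30, i.e. "more than 30\% of samples"), the prevalence rule
#' used to define the most prevalent community members.
#'
#' @param table an [AbundanceTable-class].
#' @param threshold prevalence fraction; strict inequality.
#'
#' @return The filtered [AbundanceTable-class].
#' @export
prevalenceFilter <- function(table, threshold = 0.30) {
  stopifnot(is(table, "AbundanceTable"), threshold >= 0, threshold < 1)
  prev <- colMeans(isPositive(table))
  table[, prev > threshold]
}

#' Normalize taxon labels
#'
#' Trims and squeezes whitespace in taxon column names and applies an
#' optional synonym map (e.g. pre-reclassification genus names like
#' "Lactobacillus plantarum" -> "Lactiplantibacillus plantarum").
#' Matching is case-sensitive after whitespace normalization; columns that
#' become identical are summed.
#'
#' @param table an [AbundanceTable-class].
#' @param synonyms named character vector, old label -> canonical label.
#'
#' @return An [AbundanceTable-class] with canonical taxon labels.
#' @export
normalizeTaxa <- function(table, synonyms = NULL) {
  stopifnot(is(table, "AbundanceTable"))
  v <- table@values
  lab <- gsub("\\s+", " ", trimws(colnames(v)))
  if (!is.null(synonyms)) {
    hit <- lab %in% names(synonyms)
    lab[hit] <- synonyms[lab[hit]]
  }
  if (anyDuplicated(lab)) {
    agg <- sapply(unique(lab), function(l)
      rowSums(v[, lab == l, drop = FALSE], na.rm = TRUE))
    if (nrow(v) == 1L) agg <- matrix(agg, nrow = 1L,
                                     dimnames = list(rownames(v),
                                                     unique(lab)))
    v <- agg
  } else colnames(v) <- lab
  abundanceTable(v, unit = table@unit)
}
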