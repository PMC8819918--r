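#' Run the full qPCR-vs-sequencing comparison pipeline
#'
#' Orchestrates the end-to-end analysis on a pair of quantified tables:
#' detection classification, read-coverage statistics, pooled
#' correlations, and -- for each analysis variant -- compositional bias
#' estimation with bootstrap GSEs and per-sample Bray-Curtis
#' dissimilarity of the sequencing profile to the qPCR reference. The
#' three variants mirror the standard correction ladder: \code{raw},
#' \code{merged} (common taxon group for the amplicon-indistinguishable
#' \emph{L. plantarum} group species) and \code{merged_gcn} (additionally
#' 16S gene copy-number normalized). The final variant's paired method
#' profiles are clustered by UPGMA.
#'
#' @param qpcr qPCR [AbundanceTable-class] (copies/ul, \code{NA} =
#'   negative call), e.g. from [quantifyReactions()].
#' @param ngs sequencing [AbundanceTable-class] (reads).
#' @param panel taxa covered by qPCR assays (default: the qPCR table's
#'   taxa).
#' @param copyNumbers optional named taxon -> mean 16S copies vector;
#'   enables the \code{merged_gcn} (or \code{gcn}) variant.
#' @param ngsGroupMembers,qpcrGroupMembers,groupLabel taxon-group merge
#'   applied to each method's table (see [mergePlantarumGroup()]);
#'   \code{NULL} members disable the merge variant.
#' @param pseudocount pseudocount for observed zeros in the bias input.
#' @param nBootstrap bootstrap replicates for GSEs (0 disables).
#' @param seed RNG seed for the bootstrap.
#'
#' @return A list with elements \code{detection} (matrix + counts),
#'   \code{coverage}, \code{r2} (log-log on copies vs reads; linear on
#'   relative abundances), \code{variants} (per variant: \code{bias},
#'   \code{brayCurtis} per sample, \code{panel}) and \code{clustering}
#'   (UPGMA tree + sibling report for the last variant).
#' @export
runPipeline <- function(qpcr, ngs, panel = taxonNames(qpcr),
                        copyNumbers = NULL,
                        ngsGroupMembers = NULL, qpcrGroupMembers = NULL,
                        groupLabel = "L. plantarum group",
                        pseudocount = 1, nBootstrap = 1000, seed = 1) {
  stopifnot(is(qpcr, "AbundanceTable"), is(ngs, "AbundanceTable"))

  det <- classifyDetections(qpcr, ngs, panel = panel)
  coverage <- coverageStats(ngs, det)

  shared <- det@categories == "shared_positive"
  qv <- qpcr@values[rownames(shared), , drop = FALSE]
  nv <- ngs@values[rownames(shared), , drop = FALSE]
  sharedIdx <- which(shared, arr.ind = TRUE)
  sharedCells <- data.frame(
    sample = rownames(shared)[sharedIdx[, 1L]],
    taxon = colnames(shared)[sharedIdx[, 2L]])
  copies <- qv[cbind(sharedCells$sample, sharedCells$taxon)]
  reads <- nv[cbind(sharedCells$sample, sharedCells$taxon)]
  qRel <- abundValues(relativeAbundance(qpcr))
  nRel <- abundValues(relativeAbundance(ngs))
  r2 <- list(
    logCopiesVsLogReads = logLogR2(reads, copies),
    relativeAbundance = linearR2(
      nRel[cbind(sharedCells$sample, sharedCells$taxon)],
      qRel[cbind(sharedCells$sample, sharedCells$taxon)]))

  variantInput <- list(raw = list(qpcr = qpcr, ngs = ngs, panel = panel))
  doMerge <- !is.null(ngsGroupMembers) && !is.null(qpcrGroupMembers)
  if (doMerge) {
    merged <- mergePlantarumGroup(ngs, qpcr,
                                  ngsMembers = ngsGroupMembers,
                                  qpcrMembers = qpcrGroupMembers,
                                  group = groupLabel)
    mPanel <- c(setdiff(panel, qpcrGroupMembers), groupLabel)
    variantInput$merged <- list(qpcr = merged$qpcr, ngs = merged$ngs,
                                panel = mPanel)
  }
  if (!is.null(copyNumbers)) {
    base <- if (doMerge) variantInput$merged else variantInput$raw
    gcnName <- if (doMerge) "merged_gcn" else "gcn"
    cn <- copyNumbers
    if (doMerge) {
      # a merged group inherits the mean copy number of its members
      mem <- intersect(ngsGroupMembers, names(cn))
      if (length(mem)) cn[groupLabel] <- mean(cn[mem])
    }
    variantInput[[gcnName]] <- list(
      qpcr = base$qpcr,
      ngs = gcnNormalize(base$ngs, cn, default = mean(cn)),
      panel = base$panel)
  }

  variants <- lapply(variantInput, function(vi) {
    pc <- suppressWarnings(
      buildPairedCompositions(vi$qpcr, vi$ngs, panel = vi$panel,
                              pseudocount = pseudocount))
    bias <- if (nBootstrap >= 2 && length(pc@observed) >= 2L)
      bootstrapGSE(pc, nReps = nBootstrap, seed = seed)
    else estimateBias(pc)
    bc <- vapply(names(pc@observed), function(s)
      brayCurtis(pc@observed[[s]], pc@reference[[s]]), numeric(1L))
    list(bias = bias, brayCurtis = bc, panel = vi$panel)
  })

  final <- variantInput[[length(variantInput)]]
  finalShared <- intersect(final$panel,
                           taxonNames(final$ngs)[colSums(
                             isPositive(final$ngs)) > 0])
  clustering <- clusterMethodProfiles(final$qpcr, final$ngs,
                                      taxa = finalShared)

  list(detection = det, detectionCounts = detectionCounts(det),
       coverage = coverage, r2 = r2, variants = variants,
       clustering = clustering)
}

#' Summary statistics of the packaged per-sample coverage table
#'
#' The package ships, as plain-text package data, the per-sample
#' percentages of sequencing reads assigned to (a) the 15 species/groups
#' shared with the qPCR panel, (b) other non-panel species, and the two
#' abundant non-panel species \emph{Lactiplantibacillus pentosus} and
#' \emph{Lentilactobacillus sunkii}, for a published 21-sample Raclette
#' du Valais PDO cheese survey. This function recomputes the summary
#' statistics (mean/min/max) from the per-sample values.
#'
#' @param file path to the coverage table; default: the packaged copy.
#'
#' @return A list with \code{perSample} (the table), \code{shared},
#'   \code{sharedPlusPentosus} and \code{other}, each c(mean, min, max).
#' @export
table2Check <- function(file = system.file("extdata",
                                           "table2_coverage.tsv",
                                           package = "ampliBias")) {
  if (!nzchar(file) || !file.exists(file))
    stop("coverage fixture not found")
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sm <- function(x) c(mean = mean(x), min = min(x), max = max(x))
  pent <- ifelse(is.na(df$pentosus_pct), 0, df$pentosus_pct)
  list(perSample = df,
       shared = sm(df$shared_pct),
       sharedPlusPentosus = sm(df$shared_pct + pent),
       other = sm(df$other_pct))
}
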