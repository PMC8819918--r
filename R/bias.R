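#' Build paired observed/reference compositions for bias estimation
#'
#' For each sample, restricts both methods to the panel taxa the reference
#' (qPCR) detected in that sample, substitutes a pseudocount for observed
#' (sequencing) zeros so log-ratios are defined, and renormalizes both
#' vectors over that subset. Samples in which the reference detected fewer
#' than two panel taxa are dropped with a warning: a one-taxon composition
#' carries no ratio information.
#'
#' @param qpcr qPCR [AbundanceTable-class] (copies/ul, \code{NA} =
#'   negative call).
#' @param ngs sequencing [AbundanceTable-class] (read counts; taxa absent
#'   from the table count as zero reads).
#' @param panel taxa assayed by qPCR; defaults to the qPCR table's taxa.
#' @param pseudocount value replacing observed zeros (default 1 read).
#'
#' @return A [PairedCompositions-class].
#' @export
buildPairedCompositions <- function(qpcr, ngs, panel = taxonNames(qpcr),
                                    pseudocount = 1) {
  stopifnot(is(qpcr, "AbundanceTable"), is(ngs, "AbundanceTable"),
            pseudocount > 0)
  if (!setequal(sampleNames(qpcr), sampleNames(ngs)))
    stop("qPCR and sequencing tables must cover the same samples")
  if (!all(panel %in% taxonNames(qpcr)))
    stop("panel taxa missing from the qPCR table: ",
         paste(setdiff(panel, taxonNames(qpcr)), collapse = ", "))
  qv <- qpcr@values
  nv <- ngs@values
  observed <- reference <- list()
  dropped <- character()
  for (s in sampleNames(qpcr)) {
    qrow <- qv[s, panel]
    subset <- panel[!is.na(qrow) & qrow > 0]
    if (length(subset) < 2L) {
      dropped <- c(dropped, s)
      next
    }
    ref <- qrow[subset]
    obs <- vapply(subset, function(t)
      if (t %in% colnames(nv)) nv[s, t] else 0, numeric(1L))
    obs[obs == 0] <- pseudocount
    observed[[s]] <- obs / sum(obs)
    reference[[s]] <- ref / sum(ref)
  }
  if (length(dropped))
    warning("dropped sample(s) with < 2 reference-positive panel taxa: ",
            paste(dropped, collapse = ", "))
  if (!length(observed))
    stop("no sample has >= 2 reference-positive panel taxa")
  new("PairedCompositions", observed = observed, reference = reference,
      taxa = sort(unique(unlist(lapply(observed, names)))),
      pseudocount = pseudocount)
}

# long-format (sample, taxon, log observed/reference ratio) rows
.pcLong <- function(pc) {
  do.call(rbind, lapply(names(pc@observed), function(s)
    data.frame(sample = s, taxon = names(pc@observed[[s]]),
               logr = log(pc@observed[[s]] / pc@reference[[s]]),
               row.names = NULL)))
}

.checkConnected <- function(pc) {
  comps <- taxonComponents(lapply(pc@observed, names))
  if (length(comps) > 1L)
    stop("taxon co-occurrence graph is disconnected; components: ",
         paste(vapply(comps, paste, "", collapse = "+"), collapse = " | "))
  invisible(TRUE)
}

#' Estimate per-taxon compositional measurement bias
#'
#' Fits the multiplicative efficiency model of compositional measurement
#' error: the observed proportion ratio of taxon t in sample i satisfies
#' \code{log r_it = log B_t + log c_i + noise}, where \code{B_t} is the
#' taxon's relative measurement efficiency (the bias) and \code{c_i} a
#' free per-sample constant absorbing the compositional closure. The
#' least-squares fit over all present (sample, taxon) cells under the
#' identifiability constraint \code{sum_t log B_t = 0} handles ragged
#' per-sample taxon subsets; with complete data it reduces to the
#' closed-form geometric-mean estimator ([estimateBiasClosedForm()]).
#' Estimates above 1 mean the observed method over-measures a taxon
#' relative to the reference; below 1, under-measures.
#'
#' @param pc a [PairedCompositions-class].
#'
#' @return A [BiasEstimate-class] (no GSEs; see [bootstrapGSE()]).
#' @examples
#' m <- matrix(c(0.5, 0.5), 1, dimnames = list("S01", c("A", "B")))
#' ref <- abundanceTable(m * 1000, "copies_per_ul")
#' obs <- abundanceTable(matrix(c(80, 20), 1,
#'        dimnames = list("S01", c("A", "B"))), "reads")
#' biasEstimates(estimateBias(buildPairedCompositions(ref, obs)))
#' # A = 2, B = 0.5
#' @export
estimateBias <- function(pc) {
  stopifnot(is(pc, "PairedCompositions"))
  .checkConnected(pc)
  long <- .pcLong(pc)
  long$sample <- factor(long$sample)
  long$taxon <- factor(long$taxon, levels = pc@taxa)
  if (nlevels(long$sample) == 1L) {
    fit <- stats::lm(logr ~ 0 + taxon, data = long)
    beta <- stats::coef(fit)
    names(beta) <- levels(long$taxon)
  } else {
    fit <- stats::lm(logr ~ sample + taxon, data = long)
    cf <- stats::coef(fit)
    beta <- c(0, cf[grep("^taxon", names(cf))])
    names(beta) <- levels(long$taxon)
  }
  logB <- beta - mean(beta)
  nUsed <- vapply(split(long$sample, long$taxon),
                  function(s) length(unique(s)), integer(1L))
  new("BiasEstimate", estimate = exp(logB),
      gse = stats::setNames(rep(NA_real_, length(logB)), names(logB)),
      nBootstrap = 0L, nSamplesUsed = nUsed[names(logB)])
}

#' Closed-form bias estimator for complete compositions
#'
#' When every sample covers the identical taxon set, the least-squares
#' solution has the closed form \code{B_t = geometric mean over samples of
#' (r_it / geometric-mean_t' r_it')}, i.e. center each sample's
#' observed/reference ratio vector by its geometric mean, then average the
#' centered log-ratios per taxon. Kept as an independent cross-check of
#' [estimateBias()].
#'
#' @param pc a [PairedCompositions-class] whose samples all cover the
#'   same taxa.
#'
#' @return Named per-taxon bias estimates (geometric mean 1).
#' @export
estimateBiasClosedForm <- function(pc) {
  stopifnot(is(pc, "PairedCompositions"))
  sets <- lapply(pc@observed, names)
  if (!all(vapply(sets, identical, logical(1L), y = sets[[1L]])))
    stop("closed form requires every sample to cover the same taxa")
  logr <- do.call(rbind, lapply(names(pc@observed), function(s)
    log(pc@observed[[s]] / pc@reference[[s]])))
  centered <- logr - rowMeans(logr)
  exp(colMeans(centered))
}

#' Bootstrap geometric standard errors for bias estimates
#'
#' Resamples whole samples with replacement \code{nReps} times,
#' re-estimates the bias on each replicate, and reports per-taxon
#' geometric standard errors \code{GSE_t = exp(sd(log B_t))} over the
#' replicates in which the taxon was estimable. Replicates whose resampled
#' taxon co-occurrence graph is disconnected are skipped (the joint
#' estimate is unidentified there); taxa informed by a single sample in
#' the full data get \code{GSE = NA}, as a spread estimated from one
#' observation is undefined.
#'
#' @param pc a [PairedCompositions-class] with at least 2 samples.
#' @param nReps number of bootstrap replicates (default 1000).
#' @param seed RNG seed; the caller's RNG state is left untouched.
#'
#' @return A [BiasEstimate-class] combining the full-data point estimates
#'   with bootstrap GSEs.
#' @export
bootstrapGSE <- function(pc, nReps = 1000, seed = 1) {
  stopifnot(is(pc, "PairedCompositions"))
  if (nReps < 2) stop("need at least 2 bootstrap replicates")
  samples <- names(pc@observed)
  if (length(samples) < 2L)
    stop("bootstrap requires at least 2 samples")
  est <- estimateBias(pc)
  logB <- matrix(NA_real_, nReps, length(pc@taxa),
                 dimnames = list(NULL, pc@taxa))
  skipped <- 0L
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      idx <- sample.int(length(samples), replace = TRUE)
      obs <- pc@observed[idx]
      ref <- pc@reference[idx]
      names(obs) <- names(ref) <- sprintf("bs%03d", seq_along(idx))
      taxa <- sort(unique(unlist(lapply(obs, names))))
      sub <- new("PairedCompositions", observed = obs, reference = ref,
                 taxa = taxa, pseudocount = pc@pseudocount)
      if (length(taxonComponents(lapply(obs, names))) > 1L) {
        skipped <- skipped + 1L
        next
      }
      b <- estimateBias(sub)@estimate
      logB[r, names(b)] <- log(b)
    }
  })
  gse <- apply(logB, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) NA_real_ else exp(stats::sd(col))
  })
  gse[est@nSamplesUsed[names(gse)] < 2L] <- NA_real_
  gse <- pmax(gse, 1)  # guard against sd underflow on identical samples
  if (skipped)
    attr(gse, "skippedReplicates") <- skipped
  initialize(est, gse = gse[names(est@estimate)],
             nBootstrap = as.integer(nReps))
}

#' Multiplicative two-GSE intervals for bias estimates
#'
#' @param est a [BiasEstimate-class].
#'
#' @return A data.frame with columns \code{taxon}, \code{estimate},
#'   \code{gse}, \code{low} (= estimate / GSE^2), \code{high}
#'   (= estimate * GSE^2) and \code{nSamplesUsed}.
#' @export
gseInterval <- function(est) {
  stopifnot(is(est, "BiasEstimate"))
  data.frame(taxon = names(est@estimate),
             estimate = unname(est@estimate),
             gse = unname(est@gse),
             low = unname(est@estimate / est@gse^2),
             high = unname(est@estimate * est@gse^2),
             nSamplesUsed = unname(est@nSamplesUsed[names(est@estimate)]),
             row.names = NULL)
}
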