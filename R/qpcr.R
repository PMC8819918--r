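#' Fit a qPCR standard calibration curve
#'
#' Least-squares fit of quantification cycle (Cq) on log10 known template
#' copies, from a serial dilution of a quantification standard. Requires at
#' least 3 calibration points spanning at least 2 orders of magnitude
#' inside the valid range (default 1e3 to 1e7 copies/ul).
#'
#' @param copies known template concentrations, copies/ul.
#' @param cq measured quantification cycles, same length as \code{copies}.
#' @param assay assay identifier stored on the curve.
#' @param validRange copies/ul range the standards are allowed to span.
#'
#' @return A [StandardCurve-class].
#' @examples
#' fitStandardCurve(c(1e3, 1e5, 1e7), c(28.035, 21.3912, 14.7474))
#' @export
fitStandardCurve <- function(copies, cq, assay = "",
                             validRange = c(1e3, 1e7)) {
  if (length(copies) != length(cq))
    stop("'copies' and 'cq' must have the same length")
  if (length(copies) < 3L)
    stop("need at least 3 calibration points")
  if (any(!is.finite(copies)) || any(copies <= 0) || any(!is.finite(cq)))
    stop("calibration points must be finite with positive copies")
  if (any(copies < validRange[1L]) || any(copies > validRange[2L]))
    stop(sprintf("calibration copies must lie within [%g, %g]",
                 validRange[1L], validRange[2L]))
  lc <- log10(copies)
  if (diff(range(lc)) < 2 - 1e-12)
    stop("calibration points must span at least 2 orders of magnitude")
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop("calibration slope must be negative; check the input points")
  # direct R^2: summary.lm() warns on exactly collinear standards
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  new("StandardCurve", assay = assay, slope = slope,
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = r2, validRange = validRange)
}

#' @describeIn fitStandardCurve amplification efficiency implied by the
#'   slope, \code{10^(-1/slope) - 1} (1.0 = perfect doubling per cycle).
#' @param curve a \code{StandardCurve}.
#' @export
amplificationEfficiency <- function(curve) {
  stopifnot(is(curve, "StandardCurve"))
  10^(-1 / curve@slope) - 1
}

#' @describeIn fitStandardCurve expected Cq for a given template
#'   concentration under the curve (the inverse of
#'   [quantifyReaction()]).
#' @export
cqFromCopies <- function(copies, curve) {
  stopifnot(is(curve, "StandardCurve"))
  curve@intercept + curve@slope * log10(copies)
}

#' Quantify single qPCR reactions against a standard curve
#'
#' Converts per-reaction Cq values to absolute template concentrations,
#' \code{copies = 10^((cq - intercept)/slope)}. Reactions that are flagged
#' (instrument/melt-curve rejection), show no amplification (\code{NA}
#' Cq), or quantify below the detection cutoff (default 800 copies/ul, the
#' microfluidic-chip recommendation) are negative calls, returned as
#' \code{NA}.
#'
#' @param cq quantification cycle(s); \code{NA} = no amplification.
#' @param curve the assay's [StandardCurve-class].
#' @param flagged logical, recycled along \code{cq}: reactions rejected by
#'   the instrument software.
#' @param cutoff detection limit in copies/ul; quantifications below it
#'   are censored to negative calls.
#'
#' @return Numeric vector of copies/ul with \code{NA} for negative calls.
#'   Values above the calibrated range are extrapolated with a warning.
#' @examples
#' curve <- fitStandardCurve(c(1e3, 1e5, 1e7), c(28.035, 21.3912, 14.7474))
#' quantifyReaction(24.7123, curve)    # 10^4 copies/ul
#' quantifyReaction(24.7123, curve, flagged = TRUE)  # negative call
#' @export
quantifyReaction <- function(cq, curve, flagged = FALSE, cutoff = 800) {
  stopifnot(is(curve, "StandardCurve"), cutoff > 0)
  flagged <- rep_len(as.logical(flagged), length(cq))
  copies <- 10^((cq - curve@intercept) / curve@slope)
  copies[flagged | is.na(cq)] <- NA_real_
  high <- !is.na(copies) & copies > curve@validRange[2L]
  if (any(high))
    warning(sprintf(
      "%d reaction(s) quantified above the calibrated range (> %g copies/ul); extrapolating",
      sum(high), curve@validRange[2L]))
  copies[!is.na(copies) & copies < cutoff] <- NA_real_
  copies
}

#' Aggregate technical qPCR triplicates
#'
#' Applies the at-least-2-of-3 rule: a (sample, assay) combination is
#' called positive only if at least two of its three reactions quantify at
#' or above the cutoff; the reported concentration is then the arithmetic
#' mean of the positive reactions. Otherwise the result is a negative
#' call.
#'
#' @param copies per-reaction copies/ul for one (sample, assay); negative
#'   calls as \code{NA}. Values below \code{cutoff} are also treated as
#'   negative.
#' @param cutoff detection limit in copies/ul.
#' @param allowIncomplete if \code{TRUE}, apply the >= 2 positive rule to
#'   however many replicates exist; by default exactly 3 are required.
#'
#' @return A list with \code{copies} (mean over positive reactions, or
#'   \code{NA} for a negative call) and \code{nPositive}.
#' @examples
#' aggregateTriplicates(c(1000, 900, NA))   # positive, 950 copies/ul
#' aggregateTriplicates(c(700, 750, 900))   # negative call: one positive
#' @export
aggregateTriplicates <- function(copies, cutoff = 800,
                                 allowIncomplete = FALSE) {
  if (!allowIncomplete && length(copies) != 3L)
    stop(sprintf("expected exactly 3 replicates, got %d (set allowIncomplete = TRUE to relax)",
                 length(copies)))
  pos <- !is.na(copies) & copies >= cutoff
  n <- sum(pos)
  list(copies = if (n >= 2L) mean(copies[pos]) else NA_real_,
       nPositive = n)
}

#' Quantify a full reaction table into a sample-by-assay abundance table
#'
#' Runs [quantifyReaction()] on every well of a long-format reaction table
#' and [aggregateTriplicates()] on every (sample, assay) group.
#'
#' @param reactions data.frame with columns \code{sample}, \code{assay},
#'   \code{replicate}, \code{cq} (\code{NA} = no amplification) and
#'   optionally \code{flagged}.
#' @param curves a single [StandardCurve-class] applied to every assay, or
#'   a named list of curves keyed by assay.
#' @param cutoff detection limit in copies/ul.
#' @param allowIncomplete passed to [aggregateTriplicates()].
#'
#' @return An [AbundanceTable-class] with \code{unit = "copies_per_ul"};
#'   negative calls are \code{NA}.
#' @export
quantifyReactions <- function(reactions, curves, cutoff = 800,
                              allowIncomplete = FALSE) {
  need <- c("sample", "assay", "replicate", "cq")
  if (!all(need %in% names(reactions)))
    stop("reactions table needs columns: ",
         paste(need, collapse = ", "))
  if (is.null(reactions$flagged)) reactions$flagged <- FALSE
  if (is(curves, "StandardCurve")) {
    one <- curves
    curves <- NULL
  } else one <- NULL
  samples <- unique(as.character(reactions$sample))
  assays <- unique(as.character(reactions$assay))
  out <- matrix(NA_real_, length(samples), length(assays),
                dimnames = list(samples, assays))
  for (a in assays) {
    curve <- if (is.null(one)) curves[[a]] else one
    if (is.null(curve))
      stop(sprintf("no standard curve supplied for assay '%s'", a))
    sel <- reactions$assay == a
    cp <- quantifyReaction(reactions$cq[sel], curve,
                           flagged = reactions$flagged[sel],
                           cutoff = cutoff)
    bySample <- split(cp, as.character(reactions$sample[sel]))
    for (s in names(bySample))
      out[s, a] <- aggregateTriplicates(bySample[[s]], cutoff = cutoff,
                                        allowIncomplete = allowIncomplete)$copies
  }
  abundanceTable(out, unit = "copies_per_ul")
}

#' Pool assay columns into taxon groups
#'
#' Sums abundance columns into named groups, e.g. pooling the two
#' \emph{Lactococcus lactis} subspecies assays (subsp. \emph{lactis},
#' subsp. \emph{cremoris}) into a single \emph{Lc. lactis} column so the
#' targeted panel matches the taxonomic resolution of 16S sequencing. A
#' group is positive if any member is positive (absent members contribute
#' zero); a group whose members are all negative calls stays a negative
#' call.
#'
#' @param table an [AbundanceTable-class].
#' @param poolingMap named character vector mapping member taxon ->
#'   group label. Taxa not named pass through unchanged.
#'
#' @return An [AbundanceTable-class] with pooled columns (same unit).
#' @examples
#' m <- matrix(c(30000, 2000), 1, dimnames = list("S01",
#'      c("Lc. lactis subsp. lactis", "Lc. lactis subsp. cremoris")))
#' tab <- abundanceTable(m, "copies_per_ul")
#' pool <- c("Lc. lactis subsp. lactis" = "Lc. lactis",
#'           "Lc. lactis subsp. cremoris" = "Lc. lactis")
#' abundValues(poolSubspecies(tab, pool))
#' @export
poolSubspecies <- function(table, poolingMap) {
  stopifnot(is(table, "AbundanceTable"))
  v <- table@values
  members <- names(poolingMap)
  if (!all(members %in% colnames(v)))
    stop("pooling map names taxa absent from the table: ",
         paste(setdiff(members, colnames(v)), collapse = ", "))
  keep <- setdiff(colnames(v), members)
  clash <- intersect(unique(poolingMap), keep)
  if (length(clash))
    stop("group label collides with an existing ungrouped taxon: ",
         paste(clash, collapse = ", "))
  out <- v[, keep, drop = FALSE]
  for (g in unique(poolingMap)) {
    sub <- v[, members[poolingMap == g], drop = FALSE]
    pooled <- rowSums(sub, na.rm = TRUE)
    pooled[rowSums(!is.na(sub)) == 0L] <- NA_real_
    out <- cbind(out, pooled)
    colnames(out)[ncol(out)] <- g
  }
  abundanceTable(out, unit = table@unit)
}
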