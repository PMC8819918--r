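#' Read and write abundance tables as delimited text
#'
#' Tables are stored samples-as-rows x taxa-as-columns with a header row
#' of taxon labels and sample identifiers in the first column. Empty
#' cells in a copies/ul table are negative calls (\code{NA}).
#'
#' @param file path to a TSV (or CSV, see \code{sep}) file.
#' @param unit unit tag of the table being read.
#' @param sep field separator.
#'
#' @return \code{readAbundanceTable()}: an [AbundanceTable-class];
#'   \code{writeAbundanceTable()}: the path, invisibly.
#' @export
readAbundanceTable <- function(file, unit = c("reads", "copies_per_ul",
                                              "proportion"),
                               sep = "\t") {
  unit <- match.arg(unit)
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, row.names = 1L,
                          na.strings = c("NA", ""))
  abundanceTable(as.matrix(df), unit = unit)
}

#' @rdname readAbundanceTable
#' @param table an [AbundanceTable-class] to write.
#' @export
writeAbundanceTable <- function(table, file, sep = "\t") {
  stopifnot(is(table, "AbundanceTable"))
  df <- data.frame(sample = rownames(table@values),
                   table@values, check.names = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Read a long-format qPCR reaction table
#'
#' Expects columns \code{sample}, \code{assay}, \code{replicate},
#' \code{cq} (empty = no amplification) and optionally \code{flagged}
#' (logical or 0/1).
#'
#' @param file path to a delimited file.
#' @param sep field separator.
#' @return A data.frame suitable for [quantifyReactions()].
#' @export
readReactions <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE,
                          na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  need <- c("sample", "assay", "replicate", "cq")
  if (!all(need %in% names(df)))
    stop("reaction table needs columns: ", paste(need, collapse = ", "))
  if (!is.null(df$flagged)) df$flagged <- as.logical(df$flagged)
  df
}

#' Read a taxon-to-16S-copy-number table
#'
#' Expects columns \code{taxon} and \code{mean_copies}.
#'
#' @param file path to a delimited file.
#' @param sep field separator.
#' @return Named numeric vector, taxon -> mean 16S copies per genome.
#' @export
readCopyNumbers <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("taxon", "mean_copies") %in% names(df)))
    stop("copy-number table needs columns 'taxon' and 'mean_copies'")
  stats::setNames(as.numeric(df$mean_copies), df$taxon)
}

#' Read a qPCR standard (calibration) points table
#'
#' Expects columns \code{assay}, \code{copies} and \code{cq}; one curve
#' is fitted per assay with [fitStandardCurve()].
#'
#' @param file path to a delimited file.
#' @param sep field separator.
#' @param validRange passed to [fitStandardCurve()].
#' @return Named list of [StandardCurve-class] objects keyed by assay.
#' @export
readStandardCurves <- function(file, sep = "\t",
                               validRange = c(1e3, 1e7)) {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("assay", "copies", "cq") %in% names(df)))
    stop("standards table needs columns 'assay', 'copies' and 'cq'")
  lapply(split(df, df$assay), function(d)
    fitStandardCurve(d$copies, d$cq, assay = d$assay[1L],
                     validRange = validRange))
}
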