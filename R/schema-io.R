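#' Load a variable table as a StudySchema
#'
#' Reads a delimited variable table with header columns \code{name},
#' \code{dtype} and \code{epoque} (extra columns ignored, any column
#' order). Row order is preserved as the canonical variable order. The
#' dtype vocabulary is closed (\code{continuous}, \code{ordinal},
#' \code{categorical}); the spelling \code{cardinal} is accepted as a
#' synonym of \code{continuous}.
#'
#' @param path path to a CSV or TSV file (delimiter sniffed from the
#'   header line, or forced via \code{sep}).
#' @param target optional name of the designated outcome variable.
#' @param nTiers declared tier count (default: the maximum epoque seen).
#' @param sep field delimiter; \code{NULL} (default) sniffs "," vs tab.
#' @return a validated \linkS4class{StudySchema}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("name,dtype,epoque", "A,continuous,1", "B,ordinal,2",
#'              "T,continuous,7"), f)
#' loadSchema(f, target = "T")
#' @export
loadSchema <- function(path, target = NA_character_, nTiers = NULL,
                       sep = NULL) {
  if (is.null(sep)) sep <- .sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", check.names = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("name", "dtype", "epoque")
  if (!all(need %in% names(tab)))
    stop("variable table must have columns name, dtype, epoque; found: ",
         paste(names(tab), collapse = ", "))
  dtype <- tolower(trimws(tab$dtype))
  dtype[dtype == "cardinal"] <- "continuous"
  bad <- !dtype %in% .DTYPES
  if (any(bad))
    stop(sprintf("unknown dtype '%s' in row %d (variable '%s')",
                 tab$dtype[which(bad)[1]], which(bad)[1],
                 tab$name[which(bad)[1]]))
  if (anyDuplicated(tab$name))
    stop("duplicate variable name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  ep <- suppressWarnings(as.integer(tab$epoque))
  if (anyNA(ep))
    stop(sprintf("non-integer epoque in row %d (variable '%s')",
                 which(is.na(ep))[1], tab$name[which(is.na(ep))[1]]))
  if (is.null(nTiers)) nTiers <- max(ep)
  if (any(ep < 1L | ep > nTiers))
    stop(sprintf("epoque outside 1..%d in row %d (variable '%s')", nTiers,
                 which(ep < 1L | ep > nTiers)[1],
                 tab$name[which(ep < 1L | ep > nTiers)[1]]))
  StudySchema(tab$name, dtype, ep, target = target, nTiers = nTiers)
}

.sniffSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

.MISSING_TOKENS <- c("", "NA", "NaN", "nan", "na", "N/A", "null", "NULL")

#' Load a data table against a schema
#'
#' Reads a delimited subject-by-variable table whose header names must
#' match the schema's variable names (any column order; a mismatch in
#' either direction is an error listing the offending names). Columns are
#' reordered to the canonical order. Empty cells and the tokens NA / NaN /
#' N/A / null are recorded as missing. Zero-observed-variance columns are
#' flagged degenerate with a warning.
#'
#' @param path path to a CSV/TSV data file.
#' @param schema a \linkS4class{StudySchema}.
#' @param sep field delimiter; \code{NULL} sniffs from the header.
#' @return a \linkS4class{DataMatrix}.
#' @export
loadData <- function(path, schema, sep = NULL) {
  if (is.null(sep)) sep <- .sniffSep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = .MISSING_TOKENS, quote = "\"",
                           check.names = FALSE)
  for (j in seq_along(tab))
    if (!is.numeric(tab[[j]]))
      tab[[j]] <- suppressWarnings(as.numeric(tab[[j]]))
  DataMatrix(tab, schema)
}

#' Write a DataMatrix and its schema to delimited files
#'
#' Companion writer for [loadData()]/[loadSchema()]; round-trips are
#' lossless for representable values.
#'
#' @param data a \linkS4class{DataMatrix}.
#' @param dataPath,schemaPath output file paths (written as CSV).
#' @return invisibly, the two paths.
#' @export
writeData <- function(data, dataPath, schemaPath = NULL) {
  utils::write.csv(as.data.frame(data@values), dataPath, row.names = FALSE,
                   quote = FALSE, na = "")
  if (!is.null(schemaPath))
    utils::write.csv(data@schema@variables, schemaPath, row.names = FALSE,
                     quote = FALSE)
  invisible(c(dataPath, schemaPath))
}
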