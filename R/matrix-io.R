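# Plain-text matrix dialect: first row = host names (optional corner
# token), first column = virus names, cells separated by runs of spaces
# or tabs, rows by line breaks.

.readLinesArg <- function(file, text) {
  if (!is.null(text)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    if (is.null(file)) stop("supply either 'file' or 'text'")
    lines <- readLines(file, warn = FALSE)
  }
  lines <- sub("[\r]+$", "", lines)
  lines[nzchar(trimws(lines))]
}

.tokenize <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

# Parse the numeric body of a matrix file, logging repairs.
# Returns list(values, virusNames, hostNames, log).
.parseMatrixText <- function(lines, what = "QPBIN") {
  if (length(lines) < 2L)
    stop(what, " file must contain a header row and at least one virus row")
  toks <- lapply(lines, .tokenize)
  body <- toks[-1L]
  ncells <- length(body[[1L]]) - 1L
  if (ncells < 1L)
    stop(what, " row 2 has no data cells")
  ragged <- which(vapply(body, length, 1L) != ncells + 1L)
  if (length(ragged))
    stop(sprintf("%s file is ragged at row %d: expected %d columns",
                 what, ragged[1L] + 1L, ncells + 1L))
  header <- toks[[1L]]
  # corner cell auto-detection: header has ncells or ncells + 1 tokens
  if (length(header) == ncells + 1L) header <- header[-1L]
  if (length(header) != ncells)
    stop(sprintf("%s header has %d names but rows have %d data cells",
                 what, length(header), ncells))
  virus <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(virus))
    stop(what, " contains duplicate virus names: ",
         paste(unique(virus[duplicated(virus)]), collapse = ", "))
  if (anyDuplicated(header))
    stop(what, " contains duplicate column names: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  raw <- t(vapply(body, function(tk) tk[-1L], character(ncells)))
  if (ncells == 1L) raw <- matrix(raw, ncol = 1L)  # vapply drops shape
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  log <- .emptyCorrections()
  bad <- which(is.na(vals))
  for (i in bad) {
    loc <- arrayInd(i, dim(vals))
    log <- rbind(log, data.frame(
      location = sprintf("%s[%s,%s]", what, virus[loc[1L]], header[loc[2L]]),
      original = raw[i], corrected = "0",
      rule = "non-numeric cell set to 0", stringsAsFactors = FALSE))
  }
  vals[bad] <- 0
  dimnames(vals) <- list(virus, header)
  list(values = vals, virusNames = virus, hostNames = header, log = log)
}

.logClamp <- function(log, what, vals, idx, newval, rule) {
  for (i in idx) {
    loc <- arrayInd(i, dim(vals))
    log <- rbind(log, data.frame(
      location = sprintf("%s[%s,%s]", what,
                         rownames(vals)[loc[1L]], colnames(vals)[loc[2L]]),
      original = format(vals[i], digits = 8), corrected = format(newval, digits = 8),
      rule = rule, stringsAsFactors = FALSE))
  }
  log
}

#' Read a quantitative phage-bacteria infection network (QPBIN)
#'
#' Parses the plain-text matrix dialect: the first row lists host names
#' (a corner token above the virus-name column is optional and
#' auto-detected), the first column lists virus names, and cells hold
#' infection strengths from 0 (no lysis) to 1 (complete lysis), separated
#' by spaces or tabs. Out-of-range values are clamped into \[0, 1\] and
#' non-numeric cells set to 0; every such repair is recorded in the
#' correction log. Duplicate names and ragged rows are hard errors.
#'
#' @param file path to a matrix file.
#' @param text matrix content as a single string (alternative to
#'   \code{file}).
#' @param rescale optional positive number: divide all cells by it on
#'   read (logged). Use \code{rescale = 3} for raw 0-3 cross-streak
#'   virulence scores.
#' @return a [QPBIN-class]; inspect repairs with [corrections()].
#' @examples
#' q <- readQPBIN(text = "H1 H2\nV1 0.9 0\nV2 0 0.5")
#' as.matrix(q)
#' @seealso [readQPPIN()], [writeMatrix()]
#' @export
readQPBIN <- function(file = NULL, text = NULL, rescale = NULL) {
  p <- .parseMatrixText(.readLinesArg(file, text), "QPBIN")
  vals <- p$values
  log <- p$log
  if (!is.null(rescale)) {
    stopifnot(is.numeric(rescale), rescale > 0)
    vals <- vals / rescale
    log <- rbind(log, data.frame(
      location = "QPBIN[*,*]", original = sprintf("scale 0-%g", rescale),
      corrected = "scale 0-1",
      rule = sprintf("all cells divided by %g on import", rescale),
      stringsAsFactors = FALSE))
  }
  hi <- which(vals > 1)
  log <- .logClamp(log, "QPBIN", vals, hi, 1, "value > 1 clamped to 1")
  vals[hi] <- 1
  lo <- which(vals < 0)
  log <- .logClamp(log, "QPBIN", vals, lo, 0, "value < 0 clamped to 0")
  vals[lo] <- 0
  QPBIN(vals, corrections = log)
}

#' Read a quantitative phage-phage interaction network (QPPIN)
#'
#' Parses a square matrix in the same dialect as [readQPBIN()] and aligns
#' it, by name, to the virus order of an already-loaded QPBIN. A factor of
#' 1 is neutral or unknown; values below 1 are antagonistic (0 = complete
#' lethality); values above 1 are synergistic. Viruses absent from the
#' file receive neutral rows and columns (logged); a non-unit diagonal is
#' forced to 1 (logged). Viruses in the file that the QPBIN does not know
#' ("orphan interactions") and negative factors are hard errors. With
#' \code{file} and \code{text} both NULL an all-neutral matrix is
#' synthesised.
#'
#' @param file,text as in [readQPBIN()]; both NULL yields [neutralQPPIN()].
#' @param expectedViruses character vector, the QPBIN virus order to align
#'   to (or a [QPBIN-class] from which it is taken).
#' @return a [QPPIN-class] aligned to \code{expectedViruses}.
#' @examples
#' q <- readQPBIN(text = "H1\nV1 0.9\nV2 0.5")
#' readQPPIN(text = "V1 V2\nV1 1 0.2\nV2 0.2 1", expectedViruses = q)
#' @export
readQPPIN <- function(file = NULL, text = NULL, expectedViruses) {
  if (is(expectedViruses, "QPBIN")) expectedViruses <- virusNames(expectedViruses)
  if (is.null(file) && is.null(text)) return(neutralQPPIN(expectedViruses))
  p <- .parseMatrixText(.readLinesArg(file, text), "QPPIN")
  vals <- p$values
  if (nrow(vals) != ncol(vals) || !setequal(rownames(vals), colnames(vals)))
    stop("QPPIN must be square with matching row and column virus names")
  vals <- vals[, rownames(vals), drop = FALSE]
  orphan <- setdiff(rownames(vals), expectedViruses)
  if (length(orphan))
    stop("QPPIN contains viruses absent from the QPBIN: ",
         paste(orphan, collapse = ", "))
  if (any(vals < 0))
    stop("QPPIN contains negative interaction factors; these have no defined meaning")
  log <- p$log
  missing <- setdiff(expectedViruses, rownames(vals))
  n <- length(expectedViruses)
  full <- matrix(1, n, n, dimnames = list(expectedViruses, expectedViruses))
  present <- rownames(vals)
  full[present, present] <- vals
  for (m in missing) {
    log <- rbind(log, data.frame(
      location = sprintf("QPPIN[%s,*]", m), original = "absent",
      corrected = "1", rule = "virus missing from QPPIN; neutral row/column added",
      stringsAsFactors = FALSE))
  }
  offdiag <- which(diag(full) != 1)
  for (i in offdiag) {
    log <- rbind(log, data.frame(
      location = sprintf("QPPIN[%s,%s]", expectedViruses[i], expectedViruses[i]),
      original = format(diag(full)[i], digits = 8), corrected = "1",
      rule = "diagonal forced to 1", stringsAsFactors = FALSE))
  }
  diag(full) <- 1
  QPPIN(full, corrections = log)
}

#' Write a network matrix in the plain-text dialect
#'
#' Emits text that [readQPBIN()] / [readQPPIN()] parse back to the same
#' values (round-trip faithful to at least 6 significant digits). The
#' header carries a corner token \code{"name"}.
#'
#' @param m a [QPBIN-class] or [QPPIN-class].
#' @param file optional path; when NULL the text is returned invisibly.
#' @return the matrix text, invisibly.
#' @export
writeMatrix <- function(m, file = NULL) {
  vals <- as.matrix(m)
  cells <- apply(vals, 1L, function(r) paste(formatC(r, digits = 8, format = "g"),
                                             collapse = " "))
  lines <- c(paste(c("name", colnames(vals)), collapse = " "),
             paste(rownames(vals), cells))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(text, file, sep = "")
  invisible(text)
}

#' Binarize a QPBIN
#'
#' Reduces the quantitative network to the classical binary host-range
#' matrix: cells above the threshold become 1, the rest 0. Useful to
#' reproduce designs driven purely by host range.
#'
#' @param qpbin a [QPBIN-class].
#' @param tau infection threshold (default 0).
#' @return a [QPBIN-class] with 0/1 values.
#' @export
binarizeQPBIN <- function(qpbin, tau = 0) {
  v <- as.matrix(qpbin)
  QPBIN((v > tau) * 1, corrections = corrections(qpbin))
}
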