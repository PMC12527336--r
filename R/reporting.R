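# Structured design report: a pure, deterministic function of the input
# matrices and the configuration. All numbers are rendered with 4
# decimal places so repeated runs diff cleanly.

.fmt <- function(x) sprintf("%.4f", x)

.sizeTable <- function(result) {
  rows <- lapply(result@bestPerSize, function(entry) {
    ev <- entry$evaluation
    data.frame(size = length(entry$cocktail),
               cocktail = paste(entry$cocktail, collapse = "+"),
               coverage = ev@coverage,
               totalInhibition = ev@totalInhibition,
               antagonismBurden = ev@antagonismBurden,
               meanRedundancy = ev@meanRedundancy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

.breakdownTable <- function(entry, qpbin, qppin) {
  ev <- entry$evaluation
  rows <- list()
  for (p in entry$cocktail) {
    for (h in hostNames(qpbin)) {
      veff <- effectiveVirulence(p, h, entry$cocktail, qpbin, qppin)
      if (veff > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          virus = p, host = h, expectedLysisEfficiency = veff,
          stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build a cocktail design report
#'
#' Runs the configured search under both objective orderings (broadest
#' host range with minimal antagonism, and highest virulence), designs
#' the rotation series when more than one cocktail is requested, and
#' assembles configuration echo, input corrections, network summary and
#' per-size result tables into a [DesignReport-class]. The report is a
#' pure function of its inputs: identical inputs give identical reports.
#'
#' @param qpbin a [QPBIN-class].
#' @param qppin a [QPPIN-class] or NULL (all-neutral).
#' @param config a [DesignConfig-class].
#' @return a [DesignReport-class].
#' @examples
#' fx <- workedExampleFixture()
#' rep <- buildReport(fx$qpbin, fx$qppin, designConfig(maxSize = 3))
#' cat(renderReport(rep))
#' @export
buildReport <- function(qpbin, qppin = NULL, config = designConfig()) {
  qppin <- .alignQPPIN(qpbin, qppin)
  corr <- rbind(corrections(qpbin), corrections(qppin))
  cfgCov <- config; cfgCov@objective <- "coverage_first"
  cfgVir <- config; cfgVir@objective <- "virulence_first"
  resCov <- designCocktail(qpbin, qppin, cfgCov)
  resVir <- designCocktail(qpbin, qppin, cfgVir)
  seriesWarnings <- character()
  series <- if (config@nCocktails > 1L) {
    withCallingHandlers(
      designCocktailSeries(qpbin, qppin, config),
      warning = function(w) {
        seriesWarnings <<- c(seriesWarnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  } else list()
  primary <- if (config@objective == "coverage_first") resCov else resVir
  breakdowns <- list()
  if (length(primary@overallBest))
    breakdowns$selected <- .breakdownTable(primary@overallBest, qpbin, qppin)
  if (!isNeutral(qppin) && config@objective != "coverage_first" &&
      length(resCov@overallBest))
    breakdowns$alternative <- .breakdownTable(resCov@overallBest, qpbin, qppin)
  new("DesignReport", config = config, corrections = corr,
      networkSummary = summarizeNetwork(qpbin, config@tau),
      resultCoverage = resCov, resultVirulence = resVir,
      series = series, breakdowns = breakdowns,
      seriesWarnings = seriesWarnings,
      qppinNeutral = isNeutral(qppin))
}

.renderConfig <- function(cfg) {
  c("[configuration]",
    paste0("maxSize: ", cfg@maxSize),
    paste0("algorithm: ", cfg@algorithm),
    paste0("objective: ", cfg@objective),
    paste0("infectionThreshold: ", .fmt(cfg@tau)),
    paste0("redundancyMode: ", cfg@redundancyMode),
    paste0("redundancyTarget: ", cfg@redundancyTarget),
    paste0("nCocktails: ", cfg@nCocktails),
    paste0("enumerationBudget: ", format(cfg@enumerationBudget, scientific = FALSE)),
    paste0("seed: ", ifelse(is.na(cfg@seed), "none", cfg@seed)))
}

.renderTable <- function(df, digits = 4) {
  if (is.null(df) || !nrow(df)) return("(none)")
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], .fmt)
  cells <- rbind(names(df), apply(as.matrix(df), 2L, as.character))
  widths <- apply(nchar(cells), 2L, max)
  apply(cells, 1L, function(r)
    paste(sprintf("%-*s", widths, r), collapse = "  "))
}

.renderWinner <- function(entry, breakdown, label) {
  if (is.null(entry) || !length(entry)) return(c(label, "(no feasible cocktail)"))
  ev <- entry$evaluation
  contrib <- data.frame(virus = names(ev@perVirusContribution),
                        contribution = unname(ev@perVirusContribution),
                        stringsAsFactors = FALSE)
  c(label,
    paste0("cocktail: ", paste(entry$cocktail, collapse = ", ")),
    sprintf("coverage: %d of %d coverable hosts", ev@coverage,
            length(ev@perHostInhibition)),
    paste0("total predicted inhibition: ", .fmt(ev@totalInhibition)),
    paste0("antagonism burden: ", .fmt(ev@antagonismBurden)),
    paste0("mean co-infection redundancy: ", .fmt(ev@meanRedundancy)),
    "",
    "virus-host breakdown (expected lysis efficiency):",
    .renderTable(breakdown),
    "",
    "per-virus contribution to total inhibition:",
    .renderTable(contrib))
}

#' Render a design report
#'
#' \code{format = "text"} produces the human-readable report as a single
#' string; \code{format = "tsv"} produces machine-readable tables (one
#' data.frame per section, written as \code{<file>.<section>.tsv} when a
#' path prefix is given). Rendering is deterministic: the same report
#' renders byte-identically.
#'
#' @param report a [DesignReport-class].
#' @param format "text" or "tsv".
#' @param file optional path (text) or path prefix (tsv).
#' @return the report text (invisibly), or for "tsv" a named list of
#'   data.frames (invisibly).
#' @export
renderReport <- function(report, format = c("text", "tsv"), file = NULL) {
  format <- match.arg(format)
  ns <- report@networkSummary
  sizeCov <- .sizeTable(report@resultCoverage)
  sizeVir <- .sizeTable(report@resultVirulence)
  if (format == "tsv") {
    tabs <- list(
      config = data.frame(parameter = c("maxSize", "algorithm", "objective",
                                        "infectionThreshold", "redundancyMode",
                                        "redundancyTarget", "nCocktails"),
                          value = c(report@config@maxSize,
                                    report@config@algorithm,
                                    report@config@objective,
                                    report@config@tau,
                                    report@config@redundancyMode,
                                    report@config@redundancyTarget,
                                    report@config@nCocktails),
                          stringsAsFactors = FALSE),
      corrections = report@corrections,
      network = data.frame(fill = ns@fill, entropyBits = ns@entropyBits,
                           density = ns@density, tau = ns@tau),
      phages = ns@perPhage,
      hosts = ns@perHost,
      cocktails = rbind(
        if (!is.null(sizeCov)) cbind(objective = "coverage_first", sizeCov),
        if (!is.null(sizeVir)) cbind(objective = "virulence_first", sizeVir)))
    if (!is.null(file)) {
      for (nm in names(tabs)) {
        tb <- tabs[[nm]]
        if (is.null(tb)) next
        utils::write.table(tb, paste0(file, ".", nm, ".tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }
    return(invisible(tabs))
  }
  lines <- c("== PhageMix cocktail design report ==", "",
             .renderConfig(report@config), "",
             "[input corrections]",
             .renderTable(report@corrections), "",
             "[network summary]",
             sprintf("viruses: %d  hosts: %d", nrow(ns@perPhage), nrow(ns@perHost)),
             paste0("fill: ", .fmt(ns@fill)),
             paste0("binary entropy (bits): ", .fmt(ns@entropyBits)),
             paste0("density (edges per node): ", .fmt(ns@density)),
             paste0("uncoverable hosts: ",
                    if (length(report@resultCoverage@uncoverableHosts))
                      paste(report@resultCoverage@uncoverableHosts, collapse = ", ")
                    else "(none)"),
             paste0("viruses removed (empty host range): ",
                    if (length(report@resultCoverage@removedViruses))
                      paste(report@resultCoverage@removedViruses, collapse = ", ")
                    else "(none)"), "",
             "[best cocktail per size -- broadest host range, minimal antagonism]",
             .renderTable(sizeCov), "",
             "[best cocktail per size -- highest virulence]",
             .renderTable(sizeVir), "")
  primary <- if (report@config@objective == "coverage_first")
    report@resultCoverage else report@resultVirulence
  lines <- c(lines,
             .renderWinner(primary@overallBest, report@breakdowns$selected,
                           sprintf("[selected cocktail (objective: %s)]",
                                   report@config@objective)), "")
  if (!is.null(report@breakdowns$alternative)) {
    lines <- c(lines,
               .renderWinner(report@resultCoverage@overallBest,
                             report@breakdowns$alternative,
                             "[alternative antagonism-minimized cocktail]"), "")
  }
  if (length(report@series)) {
    lines <- c(lines, "[rotation series (phage-disjoint cocktails)]")
    for (i in seq_along(report@series)) {
      best <- report@series[[i]]@overallBest
      lines <- c(lines, sprintf(
        "cocktail %d: %s (coverage %d, total inhibition %s)", i,
        paste(best$cocktail, collapse = ", "),
        best$evaluation@coverage, .fmt(best$evaluation@totalInhibition)))
    }
    for (w in report@seriesWarnings)
      lines <- c(lines, paste0("note: ", w))
    lines <- c(lines, "")
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(text, file, sep = "")
  invisible(text)
}
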