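#' Export a network for Cytoscape
#'
#' Builds the edge list of the (optionally cocktail-restricted) network:
#' virus-host edges for every infection strength above 0 (interaction
#' type \code{"infects"}) and virus-virus edges for every non-neutral
#' interaction factor (\code{"antagonizes"} for w < 1,
#' \code{"synergizes"} for w > 1). Writes a SIF file
#' (\code{source<TAB>interaction<TAB>target}) plus a TSV edge-attribute
#' table with the weights, and optionally GraphML.
#'
#' @param qpbin a [QPBIN-class].
#' @param qppin a [QPPIN-class] or NULL (treated as all-neutral).
#' @param cocktail optional character vector of viruses; when given, only
#'   edges involving these viruses are exported. Unknown viruses are an
#'   error.
#' @param file optional path prefix; when given, \code{<file>.sif} and
#'   \code{<file>.edges.tsv} (and \code{<file>.graphml} if requested) are
#'   written.
#' @param graphml also write GraphML (via \pkg{igraph})?
#' @return invisibly, a data.frame with columns source, interaction,
#'   target, weight — one row per exported edge.
#' @examples
#' fx <- workedExampleFixture()
#' edges <- exportNetwork(fx$qpbin, fx$qppin)
#' nrow(edges[edges$interaction == "infects", ])
#' @export
exportNetwork <- function(qpbin, qppin = NULL, cocktail = NULL,
                          file = NULL, graphml = FALSE) {
  v <- as.matrix(qpbin)
  if (is.null(qppin)) qppin <- neutralQPPIN(virusNames(qpbin))
  w <- as.matrix(qppin)
  if (!identical(rownames(w), rownames(v)))
    stop("QPPIN viruses do not match the QPBIN")
  if (!is.null(cocktail)) {
    bad <- setdiff(cocktail, rownames(v))
    if (length(bad))
      stop("cocktail contains unknown viruses: ", paste(bad, collapse = ", "))
    v <- v[cocktail, , drop = FALSE]
    w <- w[cocktail, cocktail, drop = FALSE]
  }
  vh <- which(v > 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(v)[vh[, 1L]],
                      interaction = rep("infects", nrow(vh)),
                      target = colnames(v)[vh[, 2L]],
                      weight = v[vh], stringsAsFactors = FALSE)
  vv <- which(w != 1 & row(w) != col(w), arr.ind = TRUE)
  if (nrow(vv)) {
    edges <- rbind(edges, data.frame(
      source = rownames(w)[vv[, 1L]],
      interaction = ifelse(w[vv] < 1, "antagonizes", "synergizes"),
      target = colnames(w)[vv[, 2L]],
      weight = w[vv], stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$interaction, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file)) {
    sif <- sprintf("%s\t%s\t%s", edges$source, edges$interaction, edges$target)
    writeLines(sif, paste0(file, ".sif"))
    utils::write.table(edges, paste0(file, ".edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (graphml) {
      g <- igraph::graph_from_data_frame(
        edges[, c("source", "target", "interaction", "weight")],
        directed = TRUE)
      igraph::V(g)$type <- ifelse(names(igraph::V(g)) %in% rownames(v),
                                  "virus", "host")
      igraph::write_graph(g, paste0(file, ".graphml"), format = "graphml")
    }
  }
  invisible(edges)
}
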