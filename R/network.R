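# PTM regulatory network assembly: a query protein set is mapped onto
# pathway membership, pathway-internal edges among included members are
# retained, and PPI edges incident to at least one query pull in
# potential new pathway members.

#' Assemble a PTM regulatory network
#'
#' Nodes are the union of the query proteins, the members of every
#' pathway touched by a query, and the PPI partners of queries. Node
#' attributes record whether a node is a query, whether it maps to a
#' pathway, and which PTM types annotate it. Pathway edges are kept when
#' both endpoints are included; PPI edges are kept when at least one
#' endpoint is a query (so interaction partners can reveal potential new
#' pathway members).
#'
#' @param queries Character vector of query protein IDs.
#' @param ptm_sites Optional site table; used to set \code{has_ptm} and
#'   \code{ptm_types} node attributes.
#' @param pathway_members Data frame (\code{pathway_id, member_id}) or a
#'   named list of member-ID vectors.
#' @param pathway_edges Data frame or 2-column matrix of
#'   (member, member) edges.
#' @param ppi_edges Data frame or 2-column matrix of (protein, protein)
#'   edges; an optional third column is kept as edge attribute
#'   \code{source_db}.
#' @return An igraph object (class also \code{"PTMNetwork"}) with node
#'   attributes \code{is_query}, \code{pathway_mapped}, \code{has_ptm},
#'   \code{ptm_types} (semicolon-joined) and edge attribute \code{kind}
#'   (\code{"pathway"} or \code{"ppi"}).
#' @export
build_network <- function(queries, ptm_sites = NULL,
                          pathway_members = NULL, pathway_edges = NULL,
                          ppi_edges = NULL) {
  queries <- unique(as.character(queries))
  if (is.data.frame(pathway_members)) {
    pathway_members <- split(as.character(pathway_members$member_id),
                             pathway_members$pathway_id)
  }
  pathway_members <- lapply(pathway_members, function(m)
    unique(as.character(m)))

  touched <- Filter(function(m) any(queries %in% m), pathway_members)
  member_nodes <- unique(unlist(touched, use.names = FALSE))
  mapped_ids <- unique(unlist(pathway_members, use.names = FALSE))

  pe <- normalize_edges(pathway_edges)
  pp <- normalize_edges(ppi_edges)
  pp <- pp[pp[[1L]] %in% queries | pp[[2L]] %in% queries, , drop = FALSE]
  partner_nodes <- unique(c(pp[[1L]], pp[[2L]]))

  nodes <- unique(c(queries, member_nodes, partner_nodes))
  pe <- pe[pe[[1L]] %in% nodes & pe[[2L]] %in% nodes, , drop = FALSE]

  edges <- rbind(
    if (nrow(pe)) data.frame(from = pe[[1L]], to = pe[[2L]],
                             kind = "pathway",
                             source_db = NA_character_,
                             stringsAsFactors = FALSE),
    if (nrow(pp)) data.frame(from = pp[[1L]], to = pp[[2L]], kind = "ppi",
                             source_db = if (ncol(pp) >= 3L)
                               as.character(pp[[3L]]) else NA_character_,
                             stringsAsFactors = FALSE))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        kind = character(), source_db = character(),
                        stringsAsFactors = FALSE)
  # order-independence: canonicalize undirected edges and node order
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to),
               edges$kind, sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  edges <- edges[order(edges$kind, pmin(edges$from, edges$to),
                       pmax(edges$from, edges$to)), , drop = FALSE]
  nodes <- sort(nodes)

  ptm_by_node <- list()
  if (!is.null(ptm_sites) && nrow(ptm_sites)) {
    ptm_by_node <- lapply(split(ptm_sites$ptm_type, ptm_sites$accession),
                          function(x) sort(unique(x)))
  }
  vdf <- data.frame(
    name = nodes,
    is_query = nodes %in% queries,
    pathway_mapped = nodes %in% mapped_ids,
    has_ptm = nodes %in% names(ptm_by_node),
    ptm_types = vapply(nodes, function(id) {
      paste(ptm_by_node[[id]], collapse = ";")
    }, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vdf)
  class(g) <- c("PTMNetwork", class(g))
  g
}

normalize_edges <- function(e) {
  if (is.null(e)) {
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  e <- as.data.frame(e, stringsAsFactors = FALSE)
  e[[1L]] <- as.character(e[[1L]])
  e[[2L]] <- as.character(e[[2L]])
  e
}

#' Export a PTM network
#'
#' \code{graphml} is a lossless attribute export (re-importable with
#' igraph); \code{sif} and \code{edge-tsv} are plain edge lists for the
#' Cytoscape ecosystem.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @param format One of \code{"graphml"}, \code{"sif"},
#'   \code{"edge-tsv"}.
#' @export
export_graph <- function(net, path, format = c("graphml", "sif",
                                               "edge-tsv")) {
  format <- match.arg(format)
  g <- net
  class(g) <- "igraph"
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(g, what = "edges")
    if (format == "sif") {
      writeLines(sprintf("%s\t%s\t%s", ed$from, ed$kind, ed$to), path)
    } else {
      write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
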