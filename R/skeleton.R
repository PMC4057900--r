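# Molecular skeleton graph of a PBDE congener.
#
# The graph is topological: every non-hydrogen heavy atom of interest is a
# vertex, every bond an edge of unit length.  The two phenyl rings are
# 6-cycles C1..C6 and C1'..C6'; the bridging ether oxygen is contracted so
# the two ipso carbons (C1, C1') are joined by a single edge.  Each
# bromine is a pendant vertex bonded to its ring carbon.  This contraction
# is what makes the Br(2)-Br(2') shortest path 5 bonds, the convention
# under which the descriptor tables of the calibration dataset reproduce.

#' Build the skeleton graph of a congener
#'
#' @param spec A [congener_spec()].
#' @return An object of class \code{skeleton_graph}: list with
#'   \describe{
#'     \item{graph}{the underlying \pkg{igraph} object;}
#'     \item{vertices}{data frame with columns \code{name}, \code{element}
#'       (\code{"C"} or \code{"Br"}) and \code{ring} (\code{"A"},
#'       \code{"B"}, or \code{"none"} for bromines);}
#'     \item{edges}{two-column character matrix of bonds.}
#'   }
#' @examples
#' sk <- build_skeleton(parse_congener("2,2',4,4'"))
#' nrow(sk$vertices)  # 12 carbons + 4 bromines
#' @export
build_skeleton <- function(spec) {
  if (!inherits(spec, "congener_spec")) {
    qspr_error("build_skeleton() expects a congener_spec", "parse_error")
  }
  ca <- paste0("C", 1:6)
  cb <- paste0("C", 1:6, "'")
  ring_edges <- function(v) cbind(v, v[c(2:6, 1)])
  edges <- rbind(
    ring_edges(ca),
    ring_edges(cb),
    c("C1", "C1'") # contracted ether bridge
  )
  br <- character(0)
  for (p in spec$ring_a) {
    v <- paste0("Br", p)
    edges <- rbind(edges, c(v, paste0("C", p)))
    br <- c(br, v)
  }
  for (p in spec$ring_b) {
    v <- paste0("Br", p, "'")
    edges <- rbind(edges, c(v, paste0("C", p, "'")))
    br <- c(br, v)
  }
  vertices <- data.frame(
    name = c(ca, cb, br),
    element = c(rep("C", 12L), rep("Br", length(br))),
    ring = c(rep("A", 6L), rep("B", 6L), rep("none", length(br))),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = vertices
  )
  structure(
    list(graph = g, vertices = vertices, edges = unname(edges), spec = spec),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %s: %d vertices (%d C, %d Br), %d edges\n",
    x$spec$name, nrow(x$vertices), sum(x$vertices$element == "C"),
    sum(x$vertices$element == "Br"), nrow(x$edges)
  ))
  invisible(x)
}

#' All-pairs shortest-path distances on a skeleton graph
#'
#' Topological distances in bond counts, computed by breadth-first search
#' from every vertex (all edges have unit length).
#'
#' @param skeleton A [build_skeleton()] result.
#' @return A symmetric integer matrix with zero diagonal, with vertex
#'   names as dimnames.
#' @export
all_pairs_distances <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  g <- skeleton$graph
  if (!igraph::is_connected(g)) {
    qspr_error("skeleton graph is disconnected", "connectivity_error")
  }
  d <- igraph::distances(g, algorithm = "unweighted")
  storage.mode(d) <- "integer"
  d
}

#' Export a skeleton graph as an edge list
#'
#' Debugging aid; writes (or returns) the bonds as two-column text.  Not a
#' stable interchange format.
#'
#' @param skeleton A \code{skeleton_graph}.
#' @param path Optional file to write a two-column whitespace-separated
#'   edge list to.
#' @return The edge matrix, invisibly when written to file.
#' @export
skeleton_edgelist <- function(skeleton, path = NULL) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  el <- skeleton$edges
  if (!is.null(path)) {
    utils::write.table(el, path,
      quote = FALSE, row.names = FALSE,
      col.names = FALSE
    )
    return(invisible(el))
  }
  el
}
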