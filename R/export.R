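#' Export one ego network as a graph document
#'
#' Builds the per-participant graph for downstream rendering: one node
#' per rostered alter carrying the alter attributes, undirected
#' alter-alter edges (with the tie strength as `weight`) among the first
#' ten roster members, and optionally an ego node tied to each of those
#' first-ten alters.
#'
#' @param record A usable [ego_record()]; an empty roster is an error.
#' @param include_ego Add the ego node and its spokes.
#' @param path Optional output path; when given the graph is written
#'   there.
#' @param format `"graphml"` or `"edgelist"` (tab-separated
#'   `from  to  weight`).
#' @return The [igraph::graph] object, invisibly.
#' @export
export_graph <- function(record, include_ego = TRUE, path = NULL,
                         format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  m <- n_alters(record)
  if (m == 0) stop("cannot export an empty network", call. = FALSE)
  k <- min(m, .tie_cap)
  vnames <- paste0("alter", seq_len(m))
  verts <- data.frame(name = vnames, stringsAsFactors = FALSE)
  for (f in names(.alter_fields)) {
    v <- record$alters[[f]]
    if (is.logical(v)) v <- as.integer(v)
    verts[[f]] <- v
  }
  edges <- data.frame(from = character(), to = character(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(record$ties) && k >= 2) {
    idx <- which(upper.tri(record$ties) & record$ties >= 1, arr.ind = TRUE)
    if (nrow(idx)) {
      edges <- data.frame(from = vnames[idx[, 1]], to = vnames[idx[, 2]],
                          weight = record$ties[idx], stringsAsFactors = FALSE)
    }
  }
  if (include_ego) {
    verts <- rbind(data.frame(name = "ego", stringsAsFactors = FALSE,
                              c(.empty_alters(1))), verts)
    edges <- rbind(data.frame(from = "ego", to = vnames[seq_len(k)],
                              weight = 1, stringsAsFactors = FALSE), edges)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  if (!is.null(path)) {
    if (format == "graphml") {
      # graphml attribute handlers reject NA strings; blank them instead
      for (at in igraph::vertex_attr_names(g)) {
        v <- igraph::vertex_attr(g, at)
        if (is.character(v)) igraph::vertex_attr(g, at) <- ifelse(is.na(v), "", v)
        if (is.logical(v)) igraph::vertex_attr(g, at) <- as.integer(v)
      }
      igraph::write_graph(g, path, format = "graphml")
    } else {
      write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(g)
}
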