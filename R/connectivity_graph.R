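# Arc-diagram data model for the SP graph: region-grouped, degree-sorted
# node ordering with degree-scaled radii, plus lossless graph export.

#' Degree-sorted arc-diagram layout
#'
#' Nodes are grouped by region and sorted within each group by descending
#' degree -- the number of distinct SP partners -- with ties broken
#' lexicographically by `cell_id`. Radii scale linearly with degree between
#' `r_min` and `r_max` (all `r_min` when the maximum degree is 0). With
#' `degree_mode = "sp_count"` the radius scales by the summed co-firing
#' counts of a node's SP edges instead of its partner count.
#'
#' @param graph an [build_sp_graph()] result.
#' @param r_min,r_max radius range (arbitrary plotting units).
#' @param degree_mode `"partners"` (default) or `"sp_count"`.
#' @return An `arc_layout` tibble: `cell_id`, `region`, `degree`, `order`
#'   (global position), `radius`. Pure function of the graph.
#' @export
degree_layout <- function(graph, r_min = 1, r_max = 4,
                          degree_mode = c("partners", "sp_count")) {
  stopifnot(inherits(graph, "sp_graph"), r_max >= r_min)
  degree_mode <- match.arg(degree_mode)
  sp <- graph$edges[graph$edges$sp_flag, ]
  deg <- vapply(graph$nodes$cell_id, function(id) {
    on_edge <- sp$cell_a == id | sp$cell_b == id
    if (degree_mode == "partners") {
      length(unique(c(sp$cell_a[on_edge], sp$cell_b[on_edge]))) -
        as.integer(any(on_edge))
    } else {
      as.integer(sum(sp$co_count[on_edge]))
    }
  }, integer(1))
  out <- tibble(
    cell_id = graph$nodes$cell_id,
    region = graph$nodes$region,
    degree = unname(deg)
  )
  out <- dplyr::arrange(out, .data$region, dplyr::desc(.data$degree),
                        .data$cell_id)
  max_deg <- max(out$degree, 0L)
  out$order <- seq_len(nrow(out))
  out$radius <- if (max_deg == 0L) {
    rep(r_min, nrow(out))
  } else {
    r_min + (r_max - r_min) * out$degree / max_deg
  }
  class(out) <- c("arc_layout", class(out))
  out
}

as_igraph <- function(graph) {
  ed <- tidy(graph)
  igraph::graph_from_data_frame(
    d = ed[c("cell_a", "cell_b", "co_count", "sp_flag", "scope")],
    directed = FALSE,
    vertices = graph$nodes
  )
}

#' Export / import the SP graph
#'
#' Writes the graph losslessly (nodes with regions, edges with co-firing
#' counts, SP flags and scope labels) as an edge-list CSV pair
#' (`<stem>_nodes.csv`, `<stem>_edges.csv`) or a GraphML file.
#'
#' @param graph an [build_sp_graph()] result.
#' @param path output path; for `format = "edgelist"` the stem of the two
#'   CSV files.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "sp_graph"))
  if (format == "edgelist") {
    stem <- sub("\\.csv$", "", path)
    readr::write_csv(graph$nodes, paste0(stem, "_nodes.csv"), progress = FALSE)
    readr::write_csv(tidy(graph), paste0(stem, "_edges.csv"), progress = FALSE)
  } else {
    ig <- as_igraph(graph)
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_graph
#' @param min_co SP threshold recorded on the re-imported graph.
#' @export
import_graph <- function(path, format = c("edgelist", "graphml"),
                         min_co = 5L) {
  format <- match.arg(format)
  if (format == "edgelist") {
    stem <- sub("\\.csv$", "", path)
    nodes <- readr::read_csv(paste0(stem, "_nodes.csv"),
                             show_col_types = FALSE, progress = FALSE)
    edges <- readr::read_csv(paste0(stem, "_edges.csv"),
                             show_col_types = FALSE, progress = FALSE)
  } else {
    ig <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(
      cell_id = igraph::vertex_attr(ig, "name"),
      region = igraph::vertex_attr(ig, "region")
    )
    el <- igraph::as_data_frame(ig, what = "edges")
    edges <- tibble(cell_a = el$from, cell_b = el$to,
                    co_count = as.integer(el$co_count),
                    sp_flag = as.logical(el$sp_flag))
  }
  edges <- dplyr::arrange(
    tibble(cell_a = pmin(edges$cell_a, edges$cell_b),
           cell_b = pmax(edges$cell_a, edges$cell_b),
           co_count = as.integer(edges$co_count),
           sp_flag = as.logical(edges$sp_flag)),
    .data$cell_a, .data$cell_b
  )
  structure(
    list(nodes = as_tibble(nodes)[c("cell_id", "region")],
         edges = edges, min_co = as.integer(min_co),
         n_sync_events = NA_integer_),
    class = "sp_graph"
  )
}
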