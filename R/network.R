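#' Directional river network of sampling stations
#'
#' A `river_graph` is a directed acyclic graph whose nodes are sampling
#' stations plus virtual origin nodes (one upstream of the main-stem head and
#' one upstream of each tributary mouth). Edges point downstream only and
#' carry positive weights (default 1 = presence/absence connectivity).
#'
#' @param edges Tibble/data frame with columns `parent`, `child`, `weight`
#'   (weight optional, default 1).
#' @param nodes Optional node table with columns `node`, `type`
#'   (`"origin"` or `"station"`); inferred if missing (origins = nodes with
#'   no parent).
#' @return An object of class `river_graph` with elements `edges`, `nodes`.
#' @export
#' @examples
#' g <- river_graph(data.frame(parent = c("o", "s1"), child = c("s1", "s2")))
#' station_ids(g)
river_graph <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("parent", "child") %in% names(edges)))
    rl_abort("edge table needs parent and child columns", "config_error")
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(edges$weight <= 0))
    rl_abort("edge weights must be > 0", "config_error")
  if (is.null(nodes)) {
    ids <- unique(c(edges$parent, edges$child))
    nodes <- tibble(node = ids,
                    type = ifelse(ids %in% edges$child, "station", "origin"))
  } else {
    nodes <- as_tibble(nodes)
  }
  g <- structure(list(edges = edges, nodes = nodes), class = "river_graph")
  ig <- as_igraph(g)
  if (!igraph::is_dag(ig))
    rl_abort("cycle detected: a river graph must be acyclic", "structural_error")
  origins <- nodes$node[nodes$type == "origin"]
  if (length(origins) == 0)
    rl_abort("graph has no origin node", "structural_error")
  reach <- unique(unlist(lapply(origins, function(o)
    names(igraph::subcomponent(ig, o, mode = "out")))))
  unreachable <- setdiff(station_ids(g), reach)
  if (length(unreachable))
    rl_abort(paste("stations unreachable from any origin:",
                   paste(unreachable, collapse = ", ")), "structural_error")
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[, c("parent", "child", "weight")],
    directed = TRUE,
    vertices = graph$nodes$node
  )
}

#' @rdname river_graph
#' @param graph A `river_graph`.
#' @export
station_ids <- function(graph) {
  graph$nodes$node[graph$nodes$type == "station"]
}

#' @rdname river_graph
#' @export
origin_ids <- function(graph) {
  graph$nodes$node[graph$nodes$type == "origin"]
}

#' @export
print.river_graph <- function(x, ...) {
  cat("<river_graph> ", length(station_ids(x)), " stations, ",
      length(origin_ids(x)), " origins, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

station_id <- function(transect, lane, lanes) {
  sprintf("S%03d", (transect - 1L) * lanes + lane)
}

#' Generate the station connectivity network of a synthetic river
#'
#' Builds the directional graph implied by a [river_config()]: each lateral
#' water mass (lane) runs as a parallel downstream chain across the
#' transects; one virtual origin feeds the main-stem head (all lanes of
#' transect 1) and one virtual origin sits upstream of each tributary mouth.
#' The topology is fully determined by the configuration.
#'
#' @param config A [river_config()].
#' @return A [river_graph()] whose node table carries `transect`, `lane`, and
#'   `distance_km` for stations.
#' @export
#' @examples
#' g <- generate_network(river_config(n_transects = 3, stations_per_transect = 2))
#' g
generate_network <- function(config) {
  config <- validate_river_config(config)
  nt <- config$n_transects
  L <- config$stations_per_transect
  st <- tidyr::expand_grid(transect = seq_len(nt), lane = seq_len(L)) %>%
    mutate(node = station_id(.data$transect, .data$lane, L),
           type = "station",
           distance_km = (.data$transect - 1) * config$transect_spacing_km)
  # main-stem origin feeds every lane of the first transect
  head_edges <- tibble(parent = "O_main",
                       child = station_id(1L, seq_len(L), L),
                       weight = 1)
  chain <- tidyr::expand_grid(transect = seq_len(nt - 1L), lane = seq_len(L)) %>%
    mutate(parent = station_id(.data$transect, .data$lane, L),
           child = station_id(.data$transect + 1L, .data$lane, L),
           weight = 1) %>%
    select("parent", "child", "weight")
  tr <- config$tributaries
  if (!is.null(tr) && nrow(tr) > 0) {
    trib_edges <- tibble(parent = paste0("O_", tr$name),
                         child = station_id(tr$transect, tr$lane, L),
                         weight = 1)
    origin_nodes <- tibble(node = c("O_main", paste0("O_", tr$name)),
                           type = "origin", transect = NA_integer_,
                           lane = NA_integer_, distance_km = NA_real_)
  } else {
    trib_edges <- NULL
    origin_nodes <- tibble(node = "O_main", type = "origin",
                           transect = NA_integer_, lane = NA_integer_,
                           distance_km = NA_real_)
  }
  edges <- bind_rows(head_edges, chain, trib_edges)
  nodes <- bind_rows(
    origin_nodes,
    st %>% select("node", "type", "transect", "lane", "distance_km")
  )
  river_graph(edges, nodes)
}

#' Read and write river graphs
#'
#' Edge lists are written as three-column TSV (`parent<TAB>child<TAB>weight`);
#' GraphML goes through igraph.
#'
#' @param graph A `river_graph`.
#' @param path File path.
#' @return `read_edge_list()` returns a `river_graph`; the writers return
#'   `path` invisibly.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_tsv(graph$edges, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  river_graph(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(ig, what = "edges")
  names(ed)[1:2] <- c("parent", "child")
  if (is.null(ed$weight)) ed$weight <- 1
  river_graph(ed[, c("parent", "child", "weight")])
}
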