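# Component-target interaction networks: assembly, degree statistics,
# SIF / GraphML export. Graphs are igraph objects with a 'role' vertex
# attribute ("component" or "target").

#' Build a bipartite component-target network
#'
#' Nodes are components and targets; an undirected edge links a component to
#' each target it acts on. Duplicate edge rows collapse to one edge;
#' self-referencing edges (a component naming itself as target) are
#' rejected. Declared components with no surviving edge are dropped by
#' default, mirroring the convention of hiding free (unconnected) proteins
#' in interaction maps; set `keep_isolates = TRUE` to retain them.
#'
#' @param edges Data frame with columns `component_name`, `target_symbol`.
#' @param components Optional character vector (or `component_table`) of
#'   declared component names; edges naming an undeclared component are a
#'   referential-integrity error, and isolated declared components are kept
#'   only under `keep_isolates`.
#' @param keep_isolates Retain declared components with no edges.
#' @return An [igraph::igraph] with vertex attributes `name` and `role`.
#' @examples
#' g <- build_component_target_network(
#'   data.frame(component_name = "chamazulene",
#'              target_symbol = c("IL6", "JAK3", "RORC")))
#' igraph::degree(g)
#' @export
build_component_target_network <- function(edges, components = NULL,
                                           keep_isolates = FALSE) {
  edges <- normalize_edges(edges)
  self_ref <- edges$component_name == edges$target_symbol |
    toupper(edges$component_name) == edges$target_symbol
  if (any(self_ref)) {
    stop("self-referencing edge(s): ",
         paste(edges$component_name[self_ref], collapse = ", "))
  }
  declared <- NULL
  if (!is.null(components)) {
    declared <- if (is.data.frame(components)) components$name else components
    declared <- trimws(as.character(declared))
    unknown <- setdiff(edges$component_name, declared)
    if (length(unknown)) {
      stop("edge list references undeclared component(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  comp_nodes <- unique(edges$component_name)
  if (keep_isolates && !is.null(declared)) {
    comp_nodes <- unique(c(comp_nodes, declared))
  }
  tgt_nodes <- unique(edges$target_symbol)
  clash <- intersect(comp_nodes, tgt_nodes)
  if (length(clash)) {
    stop("name(s) used as both component and target: ",
         paste(clash, collapse = ", "))
  }
  vertices <- data.frame(
    name = c(comp_nodes, tgt_nodes),
    role = c(rep("component", length(comp_nodes)),
             rep("target", length(tgt_nodes))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Degree statistics of an interaction network
#'
#' @param network An igraph object (as from
#'   [build_component_target_network()] or [import_network()]).
#' @return A list of class `degree_stats`: `n_nodes`, `n_edges`,
#'   `mean_degree` (2|E|/|V| for undirected graphs; 0 for an empty graph)
#'   and `table`, the per-node degrees sorted descending then by name.
#' @export
degree_statistics <- function(network) {
  stopifnot(igraph::is_igraph(network))
  n_nodes <- igraph::vcount(network)
  n_edges <- igraph::ecount(network)
  deg <- igraph::degree(network)
  tab <- data.frame(
    name = names(deg),
    role = if ("role" %in% igraph::vertex_attr_names(network)) {
      igraph::V(network)$role
    } else {
      rep(NA_character_, n_nodes)
    },
    degree = as.integer(deg),
    stringsAsFactors = FALSE
  )
  if (nrow(tab)) {
    tab <- tab[order(-tab$degree, tab$name), , drop = FALSE]
    rownames(tab) <- NULL
  }
  out <- list(
    n_nodes = n_nodes,
    n_edges = n_edges,
    mean_degree = if (n_nodes == 0L) 0 else 2 * n_edges / n_nodes,
    table = tab
  )
  class(out) <- "degree_stats"
  out
}

#' @export
print.degree_stats <- function(x, n = 10L, ...) {
  cat(sprintf("network: %d nodes, %d edges, mean degree %.3f\n",
              x$n_nodes, x$n_edges, x$mean_degree))
  if (nrow(x$table)) {
    print.data.frame(utils::head(x$table, n), row.names = FALSE)
  }
  invisible(x)
}

#' Export a network to SIF or GraphML
#'
#' SIF is the three-column tab-separated `source  relation  target` format
#' understood by Cytoscape; isolated nodes are written as single-column
#' lines, so node and edge sets round-trip through [import_network()]
#' exactly. GraphML export (via igraph) carries the `role` vertex attribute.
#'
#' @param network An igraph object.
#' @param path Output file.
#' @param format `"sif"` or `"graphml"`.
#' @param relation Relation token written in SIF edge lines.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml"),
                           relation = "interacts") {
  stopifnot(igraph::is_igraph(network))
  format <- tolower(format[1L])
  if (!format %in% c("sif", "graphml")) {
    stop("unknown export format '", format, "' (use 'sif' or 'graphml')")
  }
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(network, names = TRUE)
  lines <- if (nrow(el)) {
    paste(el[, 1L], relation, el[, 2L], sep = "\t")
  } else {
    character(0)
  }
  isolated <- igraph::V(network)$name[igraph::degree(network) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File to read.
#' @param format `"sif"` or `"graphml"`.
#' @return An igraph object.
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- tolower(format[1L])
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  if (format != "sif") {
    stop("unknown import format '", format, "' (use 'sif' or 'graphml')")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edge_rows <- parts[lengths(parts) >= 3L]
  node_rows <- parts[lengths(parts) == 1L]
  edges <- if (length(edge_rows)) {
    do.call(rbind, lapply(edge_rows, function(p) {
      # SIF allows several targets per line: source relation t1 t2 ...
      cbind(p[1L], p[-(1:2)])
    }))
  } else {
    matrix(character(0), ncol = 2L)
  }
  nodes <- unique(c(as.vector(edges), unlist(node_rows)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, nodes), ncol = 2L)))
  }
  igraph::simplify(g)
}
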