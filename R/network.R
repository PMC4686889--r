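#' Undirected simple gene network
#'
#' Canonical container for the analysis graph: a node set and a set of
#' unordered edges with self-loops and duplicates removed. Edges are stored
#' with endpoints sorted so `a-b` and `b-a` are one edge.
#'
#' @param edges Data frame or tibble whose first two columns are node
#'   tokens; extra columns are ignored.
#' @param nodes Optional character vector of nodes to retain even when
#'   isolated (a node roster); defaults to the edge endpoints only.
#' @return An object of class `gene_network` with elements `nodes`
#'   (sorted character) and `edges` (tibble `from`, `to`, `from < to`).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    abort("`edges` must be a data frame with at least two columns.")
  }
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  bad <- which(is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b))
  if (length(bad)) {
    abort(sprintf("malformed edge row(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  loops <- a == b
  if (any(loops)) {
    inform(sprintf("dropped %d self-loop(s).", sum(loops)))
    a <- a[!loops]
    b <- b[!loops]
  }
  e <- tibble(from = pmin(a, b), to = pmax(a, b)) |>
    distinct() |>
    arrange(.data$from, .data$to)
  node_set <- sort(unique(c(e$from, e$to, as.character(nodes %||% character(0)))))
  structure(list(nodes = node_set, edges = e), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Tidy a network into its edge list
#'
#' @param x A `gene_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`).
#' @method tidy gene_network
#' @export
tidy.gene_network <- function(x, ...) x$edges

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Merge edge lists into one simple undirected network
#'
#' Union of edge sets as unordered pairs; self-loops dropped; duplicates,
#' including reversed duplicates across inputs, collapse to one edge. Any
#' direction annotation on the inputs is discarded.
#'
#' @param ... Data frames (first two columns = endpoints) and/or
#'   `gene_network` objects.
#' @param nodes Optional node roster of isolated nodes to retain.
#' @return A `gene_network`.
#' @examples
#' merge_networks(data.frame(a = "A", b = "B"), data.frame(a = "B", b = "A"))
#' @export
merge_networks <- function(..., nodes = NULL) {
  inputs <- list(...)
  if (!length(inputs)) abort("supply at least one edge list.")
  edge_tbls <- lapply(inputs, function(x) {
    if (inherits(x, "gene_network")) return(x$edges)
    if (!is.data.frame(x) || ncol(x) < 2L) {
      abort("each input must be a two-column data frame or gene_network.")
    }
    tibble(from = as.character(x[[1]]), to = as.character(x[[2]]))
  })
  gene_network(bind_rows(edge_tbls), nodes = nodes)
}

#' Induce the subgraph on a gene set
#'
#' Keeps the nodes of the network that belong to `genes` and the edges with
#' both endpoints kept.
#'
#' @param network A `gene_network`.
#' @param genes Character vector of gene ids.
#' @return A `gene_network`.
#' @export
induce_subgraph <- function(network, genes) {
  stopifnot(inherits(network, "gene_network"))
  genes <- as.character(genes)
  keep_nodes <- intersect(network$nodes, genes)
  e <- filter(network$edges, .data$from %in% keep_nodes,
              .data$to %in% keep_nodes)
  structure(list(nodes = keep_nodes, edges = e), class = "gene_network")
}

#' Extract the biggest connected component
#'
#' Returns the connected component with the most nodes. Ties are broken
#' deterministically in favour of the component containing the
#' lexicographically smallest node.
#'
#' @param network A `gene_network`.
#' @return A `gene_network` restricted to the winning component; an empty
#'   network (with a warning) when the input has no nodes.
#' @export
biggest_connected_component <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (!length(network$nodes)) {
    warn("empty network; returning it unchanged.")
    return(network)
  }
  comp <- igraph::components(as_igraph(network))
  sizes <- comp$csize
  best_size <- max(sizes)
  cands <- which(sizes == best_size)
  if (length(cands) > 1L) {
    # tie: the component holding the alphabetically first tied node wins
    first_node <- min(names(comp$membership)[comp$membership %in% cands])
    winner <- comp$membership[[first_node]]
  } else {
    winner <- cands
  }
  induce_subgraph(network, names(comp$membership)[comp$membership == winner])
}

#' Read a two-column edge list (TSV or SIF)
#'
#' TSV rows are `from<TAB>to[<TAB>ignored...]`; SIF rows are
#' `from<TAB>relation<TAB>to...` (detected from the `.sif` extension).
#'
#' @param path File path.
#' @return A tibble `from`, `to` suitable for [merge_networks()].
#' @export
read_edge_list <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2L) abort("edge list needs at least two columns.")
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    if (ncol(df) < 3L) abort("SIF rows need source, relation, target.")
    tibble(from = df[[1]], to = df[[3]])
  } else {
    tibble(from = df[[1]], to = df[[2]])
  }
}
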