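#' County adjacency graphs
#'
#' A `county_graph` stores the areal contiguity structure used by the
#' intrinsic CAR priors: an ordered node table (one row per county, in the
#' canonical node order used by every model array) and an undirected edge
#' table. Edges are stored once, with `from` preceding `to` in node order.
#'
#' @param nodes A data frame with at least a `county_id` column; optional
#'   columns `region` (one of `"eastern"`, `"central"`, `"western"`) and
#'   `urban` (logical) are carried along and used to form under-reporting
#'   strata.
#' @param edges A data frame with columns `from` and `to` holding county ids.
#'   Self-edges are rejected; duplicate edges (in either orientation) are
#'   collapsed with a warning.
#' @return A `county_graph` object.
#' @export
county_graph <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  stopifnot("county_id" %in% names(nodes))
  nodes$county_id <- as.character(nodes$county_id)
  if (anyDuplicated(nodes$county_id)) {
    stop("duplicate county ids in node table", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  ef <- match(as.character(edges$from), nodes$county_id)
  et <- match(as.character(edges$to), nodes$county_id)
  if (anyNA(ef) || anyNA(et)) {
    bad <- unique(c(edges$from[is.na(ef)], edges$to[is.na(et)]))
    stop("edge endpoints not in node table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(ef == et)) stop("self-edges are not allowed", call. = FALSE)
  lo <- pmin(ef, et)
  hi <- pmax(ef, et)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed", call. = FALSE)
    keep <- !duplicated(key)
    lo <- lo[keep]
    hi <- hi[keep]
  }
  o <- order(lo, hi)
  structure(
    list(
      nodes = nodes,
      edges = tibble::tibble(
        from = nodes$county_id[lo[o]],
        to = nodes$county_id[hi[o]]
      )
    ),
    class = "county_graph"
  )
}

#' @export
print.county_graph <- function(x, ...) {
  comp <- graph_components(x)
  cat(sprintf(
    "<county_graph: %d counties, %d edges, %d connected component%s>\n",
    n_counties(x), nrow(x$edges), comp$n, if (comp$n == 1) "" else "s"
  ))
  invisible(x)
}

#' @rdname county_graph
#' @param graph A `county_graph`.
#' @export
n_counties <- function(graph) nrow(graph$nodes)

#' Rook-adjacency lattice of counties
#'
#' Builds a rectangular grid of synthetic counties with rook contiguity
#' (horizontal and vertical neighbours), the stand-in for a real county map.
#' Node order is row-major. Region labels mimic an east/central/west split by
#' column tertile (left to right: western, central, eastern) and an
#' urban/rural flag alternates by row, so that under-reporting strata
#' (region x urban) are spatially coherent.
#'
#' @param n_rows,n_cols Positive grid dimensions.
#' @return A `county_graph` whose node table carries `row`, `col`, `region`
#'   and `urban` columns.
#' @examples
#' g <- make_lattice(2, 2)
#' n_counties(g) # 4
#' @export
make_lattice <- function(n_rows, n_cols) {
  if (length(n_rows) != 1 || length(n_cols) != 1 ||
      is.na(n_rows) || is.na(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("n_rows and n_cols must be positive integers", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  idx <- seq_len(n_rows * n_cols)
  row <- (idx - 1L) %/% n_cols + 1L
  col <- (idx - 1L) %% n_cols + 1L
  ids <- sprintf("c%04d", idx)
  tertile <- ceiling(col / n_cols * 3)
  region <- c("western", "central", "eastern")[tertile]
  nodes <- tibble::tibble(
    county_id = ids, row = row, col = col,
    region = region, urban = row %% 2L == 1L
  )
  right <- idx[col < n_cols]
  down <- idx[row < n_rows]
  edges <- tibble::tibble(
    from = ids[c(right, down)],
    to = ids[c(right + 1L, down + n_cols)]
  )
  county_graph(nodes, edges)
}

# Edge endpoints as integer node indices (m x 2, from < to).
edge_index <- function(graph) {
  cbind(
    match(graph$edges$from, graph$nodes$county_id),
    match(graph$edges$to, graph$nodes$county_id)
  )
}

#' Adjacency and Laplacian matrices of a county graph
#'
#' @param graph A `county_graph`.
#' @return `adjacency_matrix()` returns the sparse symmetric 0/1 contiguity
#'   matrix W (zero diagonal); `laplacian_matrix()` returns D - W with D the
#'   diagonal of neighbour counts.
#' @export
adjacency_matrix <- function(graph) {
  n <- n_counties(graph)
  e <- edge_index(graph)
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = 1,
    dims = c(n, n), dimnames = list(graph$nodes$county_id, graph$nodes$county_id)
  )
}

#' @rdname adjacency_matrix
#' @export
laplacian_matrix <- function(graph) {
  W <- adjacency_matrix(graph)
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Connected components of a county graph
#'
#' Counties with no neighbours (islands) form their own components; the CAR
#' prior is rank-deficient by one per component, which the log-density and
#' the precision updates account for.
#'
#' @param graph A `county_graph`.
#' @return A list with `n` (component count) and `membership` (integer vector
#'   in node order).
#' @export
graph_components <- function(graph) {
  n <- n_counties(graph)
  e <- edge_index(graph)
  # union-find; n is at most a few thousand here
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(e)) {
    for (k in seq_len(nrow(e))) {
      a <- find(e[k, 1])
      b <- find(e[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  membership <- match(roots, unique(roots))
  list(n = length(unique(roots)), membership = membership)
}

# Greedy proper colouring: classes of nodes with no internal edges, so that
# single-site Metropolis updates within a class are conditionally independent
# under the CAR prior and can be vectorised.
graph_coloring <- function(graph) {
  n <- n_counties(graph)
  e <- edge_index(graph)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    nbr[[e[k, 1]]] <- c(nbr[[e[k, 1]]], e[k, 2])
    nbr[[e[k, 2]]] <- c(nbr[[e[k, 2]]], e[k, 1])
  }
  color <- integer(n)
  for (i in seq_len(n)) {
    used <- color[nbr[[i]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    color[i] <- c0
  }
  split(seq_len(n), color)
}

#' Read and write edge-list graph files
#'
#' The on-disk format is a whitespace-separated text file with one undirected
#' edge per line (two county ids); isolated counties can be listed on a line
#' by themselves. Duplicate edges are collapsed with a warning on read.
#'
#' @param path File path.
#' @param graph A `county_graph`.
#' @param nodes Optional node table for `read_edge_list()`; when omitted the
#'   node set is the sorted set of ids appearing in the file.
#' @return `read_edge_list()` returns a `county_graph`;
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(toks) > 2
  if (any(bad)) {
    stop("malformed edge list at line(s) ", paste(which(bad), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  singles <- unlist(toks[lengths(toks) == 1])
  pairs <- toks[lengths(toks) == 2]
  from <- vapply(pairs, `[[`, character(1), 1)
  to <- vapply(pairs, `[[`, character(1), 2)
  if (is.null(nodes)) {
    nodes <- tibble::tibble(county_id = sort(unique(c(from, to, singles))))
  }
  county_graph(nodes, tibble::tibble(from = from, to = to))
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  deg <- table(factor(c(graph$edges$from, graph$edges$to),
                      levels = graph$nodes$county_id))
  isolated <- graph$nodes$county_id[deg == 0]
  writeLines(c(paste(graph$edges$from, graph$edges$to), isolated), con)
  invisible(path)
}

#' Restrict a county graph to a subset of counties
#'
#' Keeps the induced subgraph: listed counties, and the edges joining two of
#' them. Node order is preserved.
#'
#' @param graph A `county_graph`.
#' @param ids Character vector of county ids to keep.
#' @return A `county_graph`.
#' @export
subgraph <- function(graph, ids) {
  keep <- graph$nodes$county_id %in% ids
  nodes <- graph$nodes[keep, ]
  e <- graph$edges[graph$edges$from %in% nodes$county_id &
                     graph$edges$to %in% nodes$county_id, ]
  county_graph(nodes, e)
}
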