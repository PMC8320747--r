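#' Directed acyclic graphs over named nodes
#'
#' A `bn_dag` stores an ordered node label vector and, per node, the integer
#' indices of its parents. Construction validates acyclicity (a topological
#' order must exist), absence of self-loops and duplicate parents.
#'
#' @param nodes character vector of node labels (unique).
#' @param parents list, one integer vector of parent indices per node
#'   (may be empty). Alternatively see [dag_from_edges()].
#' @return an object of class `bn_dag`.
#' @export
new_dag <- function(nodes, parents = rep(list(integer(0)), length(nodes))) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes),
            length(parents) == length(nodes))
  parents <- lapply(parents, function(p) sort(unique(as.integer(p))))
  p <- length(nodes)
  for (i in seq_len(p)) {
    if (any(parents[[i]] == i)) stop("self-loop at node ", nodes[i])
    if (length(parents[[i]]) && (min(parents[[i]]) < 1 || max(parents[[i]]) > p))
      stop("parent index out of range for node ", nodes[i])
  }
  dag <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  if (is.null(topo_sort(dag))) stop("graph contains a directed cycle")
  dag
}

#' Build a DAG from an edge list
#'
#' @param nodes character node labels.
#' @param edges two-column character matrix (parent, child); may have 0 rows.
#' @export
dag_from_edges <- function(nodes, edges) {
  parents <- rep(list(integer(0)), length(nodes))
  if (NROW(edges) > 0) {
    pi <- match(edges[, 1], nodes)
    ci <- match(edges[, 2], nodes)
    if (anyNA(pi) || anyNA(ci)) stop("edge references unknown node")
    for (k in seq_along(pi)) parents[[ci[k]]] <- c(parents[[ci[k]]], pi[k])
  }
  new_dag(nodes, parents)
}

#' Edge list of a DAG
#' @param dag a `bn_dag`.
#' @return two-column character matrix (parent, child).
#' @export
dag_edges <- function(dag) {
  ci <- rep(seq_along(dag$nodes), lengths(dag$parents))
  pi <- unlist(dag$parents, use.names = FALSE)
  cbind(parent = dag$nodes[pi], child = dag$nodes[ci], deparse.level = 0)
}

#' Topological order of a DAG
#'
#' Kahn's algorithm. Returns `NULL` when the graph is cyclic, which
#' [new_dag()] uses as its acyclicity oracle.
#'
#' @param dag a `bn_dag` (or a bare list with a `parents` field).
#' @return integer vector of node indices in topological order, or `NULL`.
#' @export
topo_sort <- function(dag) {
  p <- length(dag$parents)
  indeg <- lengths(dag$parents)
  children <- rep(list(integer(0)), p)
  for (i in seq_len(p)) for (j in dag$parents[[i]])
    children[[j]] <- c(children[[j]], i)
  frontier <- which(indeg == 0)
  order <- integer(0)
  while (length(frontier)) {
    v <- frontier[1]; frontier <- frontier[-1]
    order <- c(order, v)
    for (w in children[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) frontier <- c(frontier, w)
    }
  }
  if (length(order) < p) NULL else order
}

# Children lists (inverse of parents).
dag_children <- function(dag) {
  p <- length(dag$parents)
  children <- rep(list(integer(0)), p)
  for (i in seq_len(p)) for (j in dag$parents[[i]])
    children[[j]] <- c(children[[j]], i)
  children
}

#' Ancestor sets of every node
#' @param dag a `bn_dag`.
#' @return list of integer ancestor index vectors, one per node.
#' @export
dag_ancestors <- function(dag) {
  ord <- topo_sort(dag)
  anc <- rep(list(integer(0)), length(dag$nodes))
  for (i in ord) {
    ps <- dag$parents[[i]]
    anc[[i]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
  }
  anc
}

# Indices of nodes with a directed path from any of `from` (descendant
# closure including `from` itself).
dag_descendant_closure <- function(dag, from) {
  children <- dag_children(dag)
  seen <- logical(length(dag$nodes))
  stack <- as.integer(from)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (!seen[v]) {
      seen[v] <- TRUE
      stack <- c(stack, children[[v]])
    }
  }
  which(seen)
}

# combn() that never hits the scalar-x trap (combn(5, 2) == combn(1:5, 2))
combn_list <- function(x, m) {
  if (length(x) < m) return(list())
  if (length(x) == m) return(list(x))
  utils::combn(x, m, simplify = FALSE)
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("bn_dag:", length(x$nodes), "nodes,", sum(lengths(x$parents)), "edges\n")
  invisible(x)
}

# Dense adjacency-matrix view used by the learning code: amat[i, j] == TRUE
# means an edge mark i -> j; an undirected edge has both marks set.
dag_to_amat <- function(dag) {
  p <- length(dag$nodes)
  a <- matrix(FALSE, p, p, dimnames = list(dag$nodes, dag$nodes))
  e <- dag_edges(dag)
  if (nrow(e)) a[cbind(match(e[, 1], dag$nodes), match(e[, 2], dag$nodes))] <- TRUE
  a
}

amat_to_dag <- function(amat, nodes = colnames(amat)) {
  if (any(amat & t(amat))) stop("adjacency matrix has undirected edges")
  parents <- lapply(seq_len(ncol(amat)), function(j) which(amat[, j]))
  new_dag(nodes, parents)
}
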