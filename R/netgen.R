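#' Specification of a synthetic DAG topology
#'
#' Describes one of the five supported graph families together with its
#' generation knobs. Undirected families are converted to DAGs by drawing a
#' uniform random node permutation and orienting every edge from earlier to
#' later rank.
#'
#' @param structure_type one of `"forest_fire"`, `"ic_dag"`,
#'   `"barabasi_albert"`, `"waxman"`, `"small_world"`.
#' @param n_vars number of nodes (>= 1).
#' @param max_in_degree parent cap per node, or `Inf` for uncapped (the
#'   default, matching the experiment grids used throughout).
#' @param ... per-family knobs overriding the defaults:
#'   `fw_prob` (forest-fire forward burn probability, 0.2),
#'   `edge_mean` (ic_dag expected parents per node, 1.5),
#'   `attachment` (Barabási–Albert edges per new node, 1),
#'   `wax_alpha`/`wax_beta` (Waxman intensity 0.4 / scale 0.1 on the unit
#'   square), `ring_degree`/`rewire_prob` (small-world ring degree 2,
#'   rewiring probability 0.2). Defaults keep mean in-degree in the sparse
#'   1–2 range at 20–60 nodes.
#' @return a `structure_spec` object.
#' @export
structure_spec <- function(structure_type, n_vars,
                           max_in_degree = Inf, ...) {
  types <- c("forest_fire", "ic_dag", "barabasi_albert", "waxman", "small_world")
  if (!is.character(structure_type) || length(structure_type) != 1 ||
      !structure_type %in% types)
    stop("unknown structure_type; must be one of: ", paste(types, collapse = ", "))
  n_vars <- as.integer(n_vars)
  stopifnot(n_vars >= 1)
  if (!identical(max_in_degree, Inf)) {
    max_in_degree <- as.integer(max_in_degree)
    stopifnot(max_in_degree >= 1)
  }
  knobs <- list(fw_prob = 0.2, edge_mean = 1.5, attachment = 1,
                wax_alpha = 0.4, wax_beta = 0.1,
                ring_degree = 2, rewire_prob = 0.2)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(knobs))
  if (length(unknown)) stop("unknown generator knob(s): ",
                            paste(unknown, collapse = ", "))
  knobs[names(dots)] <- dots
  structure(list(structure_type = structure_type, n_vars = n_vars,
                 max_in_degree = max_in_degree, knobs = knobs),
            class = "structure_spec")
}

# Undirected edge index pairs (i, j) from an igraph object, simplified.
igraph_edge_pairs <- function(g) {
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  e <- igraph::as_edgelist(g, names = FALSE)
  matrix(as.integer(e), ncol = 2)
}

#' Generate a random DAG of a given structure type
#'
#' Draws the raw topology from the requested graph family, orients all edges
#' along a uniform random permutation of the nodes (earlier rank -> later
#' rank, which guarantees acyclicity), and enforces the in-degree cap by
#' removing surplus parents uniformly at random.
#'
#' @param spec a [structure_spec()].
#' @param seed integer seed; identical `(spec, seed)` yield identical DAGs.
#' @return a [new_dag()] object with nodes `V0 ... V{p-1}`.
#' @export
generate_dag <- function(spec, seed) {
  stopifnot(inherits(spec, "structure_spec"))
  p <- spec$n_vars
  nodes <- paste0("V", seq_len(p) - 1L)
  k <- spec$knobs
  with_seed(seed, {
    pairs <- if (p == 1) {
      matrix(integer(0), ncol = 2)
    } else switch(spec$structure_type,
      forest_fire = igraph_edge_pairs(
        igraph::sample_forestfire(p, fw.prob = k$fw_prob, bw.factor = 0)),
      barabasi_albert = igraph_edge_pairs(
        igraph::sample_pa(p, m = k$attachment, directed = FALSE)),
      small_world = igraph_edge_pairs(
        igraph::sample_smallworld(1, p, nei = max(1L, as.integer(k$ring_degree / 2)),
                                  p = k$rewire_prob)),
      waxman = {
        x <- runif(p); y <- runif(p)
        idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
        d <- sqrt((x[idx[, 1]] - x[idx[, 2]])^2 + (y[idx[, 1]] - y[idx[, 2]])^2)
        prob <- k$wax_alpha * exp(-d / (k$wax_beta * sqrt(2)))
        keep <- runif(nrow(idx)) < prob
        matrix(as.integer(idx[keep, , drop = FALSE]), ncol = 2)
      },
      ic_dag = {
        idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
        q <- min(1, 2 * k$edge_mean / (p - 1))
        keep <- runif(nrow(idx)) < q
        matrix(as.integer(idx[keep, , drop = FALSE]), ncol = 2)
      },
      stop("unknown structure_type"))

    # acyclic orientation along a uniform random node permutation
    rank <- sample.int(p)
    parents <- rep(list(integer(0)), p)
    if (nrow(pairs)) {
      flip <- rank[pairs[, 1]] > rank[pairs[, 2]]
      from <- ifelse(flip, pairs[, 2], pairs[, 1])
      to <- ifelse(flip, pairs[, 1], pairs[, 2])
      for (e in seq_along(from)) parents[[to[e]]] <- c(parents[[to[e]]], from[e])
      parents <- lapply(parents, function(ps) sort(unique(ps)))
    }
    if (is.finite(spec$max_in_degree)) {
      cap <- spec$max_in_degree
      parents <- lapply(parents, function(ps) {
        if (length(ps) > cap) sort(sample(ps, cap)) else ps
      })
    }
    new_dag(nodes, parents)
  })
}

#' Sample per-variable category counts
#'
#' Each variable's number of levels is drawn integer-uniform on `{2, ..., M}`
#' with `M = 2 * avg_levels - 2`, so the expected level count equals
#' `avg_levels`.
#'
#' @param p number of variables.
#' @param avg_levels target mean level count `l >= 2`.
#' @param seed integer seed.
#' @return integer vector of length `p`, entries in `{2, ..., 2l - 2}`.
#' @export
sample_levels <- function(p, avg_levels, seed) {
  if (avg_levels < 2) stop("avg_levels must be >= 2")
  M <- as.integer(round(2 * avg_levels - 2))
  with_seed(seed, sample.int(M - 1L, p, replace = TRUE) + 1L)
}

#' Per-row Dirichlet concentration under the imbalance normalization
#'
#' The global imbalance `alpha` is divided by the CPT size:
#' `alpha_i = alpha / (r * q)` where `r` is the node's cardinality and `q`
#' the product of its parents' cardinalities. This is the symmetric
#' concentration of every CPT row drawn by [populate_cpts()].
#'
#' @param alpha global imbalance (> 0).
#' @param levels the node's cardinality `r`.
#' @param parent_levels integer cardinalities of the node's parents (empty
#'   for a root, giving `q = 1`).
#' @export
cpt_concentration <- function(alpha, levels, parent_levels = integer(0)) {
  if (alpha <= 0) stop("alpha must be > 0")
  alpha / (levels * prod(parent_levels))
}

#' Populate a DAG with Dirichlet-drawn conditional probability tables
#'
#' Every CPT row of node `i` (one row per parent-level configuration) is an
#' independent draw from a symmetric Dirichlet whose concentration is the
#' global imbalance `alpha` normalized by the table size:
#' `alpha_i = alpha / (r_i * q_i)` where `r_i` is the node's cardinality and
#' `q_i` the product of its parents' cardinalities. Small `alpha` yields
#' low-entropy (imbalanced) conditionals and hence strong, easily detectable
#' parent-child relationships.
#'
#' @param dag a `bn_dag`.
#' @param levels integer cardinalities (all >= 2), one per node.
#' @param alpha global imbalance, > 0.
#' @param seed integer seed.
#' @return a `discrete_bn` (DAG + levels + CPT list).
#' @export
populate_cpts <- function(dag, levels, alpha, seed) {
  if (alpha <= 0) stop("alpha must be > 0")
  levels <- as.integer(levels)
  stopifnot(length(levels) == length(dag$nodes), all(levels >= 2))
  with_seed(seed, {
    cpts <- vector("list", length(dag$nodes))
    for (i in seq_along(dag$nodes)) {
      r <- levels[i]
      q <- prod(levels[dag$parents[[i]]])
      a_i <- cpt_concentration(alpha, r, levels[dag$parents[[i]]])
      g <- matrix(rgamma(q * r, shape = a_i), nrow = q)
      rs <- rowSums(g)
      bad <- which(!is.finite(rs) | rs <= 0)
      for (b in bad) {  # alpha_i underflow: Dirichlet limit is a one-hot row
        g[b, ] <- 0
        g[b, sample.int(r, 1)] <- 1
        rs[b] <- 1
      }
      cpts[[i]] <- g / rs
    }
    new_discrete_bn(dag, levels, cpts)
  })
}

#' Construct a discrete Bayesian network
#'
#' @param dag a `bn_dag`.
#' @param levels integer per-node cardinalities.
#' @param cpts list of CPT matrices, one per node, with `q_i` rows (parent
#'   configurations, first parent index varying fastest) and `r_i` columns;
#'   each row must sum to 1 within 1e-9.
#' @return a `discrete_bn`.
#' @export
new_discrete_bn <- function(dag, levels, cpts) {
  levels <- as.integer(levels)
  stopifnot(inherits(dag, "bn_dag"),
            length(levels) == length(dag$nodes),
            length(cpts) == length(dag$nodes))
  for (i in seq_along(cpts)) {
    q <- prod(levels[dag$parents[[i]]])
    if (!is.matrix(cpts[[i]]) || nrow(cpts[[i]]) != q ||
        ncol(cpts[[i]]) != levels[i])
      stop("CPT of node ", dag$nodes[i], " has wrong shape")
    if (any(cpts[[i]] < 0) || any(abs(rowSums(cpts[[i]]) - 1) > 1e-9))
      stop("CPT rows of node ", dag$nodes[i], " must be probabilities summing to 1")
  }
  structure(list(dag = dag, levels = levels, cpts = cpts),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("discrete_bn:", length(x$dag$nodes), "nodes,",
      sum(lengths(x$dag$parents)), "edges, levels",
      paste(range(x$levels), collapse = "-"),
      sprintf("(%d free parameters)\n",
              sum(vapply(seq_along(x$levels), function(i)
                parameter_count(x, x$dag$nodes[i]), numeric(1)))))
  invisible(x)
}

#' Free-parameter count of a node's local distribution
#'
#' `(r_i - 1) * q_i`: each of the `q_i` parent configurations carries an
#' `r_i`-category multinomial with `r_i - 1` free probabilities.
#'
#' @param bn a `discrete_bn`.
#' @param node node label.
#' @export
parameter_count <- function(bn, node) {
  i <- match(node, bn$dag$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  (bn$levels[i] - 1) * prod(bn$levels[bn$dag$parents[[i]]])
}

# Mixed-radix parent-configuration row index (1-based, first parent fastest).
parent_config_index <- function(codes, parent_levels) {
  if (length(parent_levels) == 0) return(rep(1L, NROW(codes)))
  stride <- cumprod(c(1L, parent_levels[-length(parent_levels)]))
  as.integer(codes %*% stride) + 1L
}

#' Draw samples from a discrete Bayesian network
#'
#' Ancestral (forward) sampling in topological order; each node's code is
#' drawn from its CPT row selected by the already-sampled parent codes.
#'
#' @param bn a `discrete_bn`.
#' @param n number of rows (>= 0).
#' @param seed integer seed; identical `(bn, n, seed)` give identical data.
#' @return a `bn_dataset`: integer matrix (0-based codes) with one column per
#'   node and a `levels` attribute of declared cardinalities.
#' @export
forward_sample <- function(bn, n, seed) {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  p <- length(bn$dag$nodes)
  x <- matrix(0L, nrow = n, ncol = p, dimnames = list(NULL, bn$dag$nodes))
  if (n > 0) with_seed(seed, {
    for (i in topo_sort(bn$dag)) {
      ps <- bn$dag$parents[[i]]
      cfg <- parent_config_index(x[, ps, drop = FALSE], bn$levels[ps])
      cp <- bn$cpts[[i]] %*% upper.tri(diag(bn$levels[i]), diag = TRUE)
      u <- runif(n)
      x[, i] <- as.integer(rowSums(u > cp[cfg, , drop = FALSE]))
    }
    x
  })
  as_dataset(x, bn$levels)
}

#' Categorical dataset container
#'
#' @param x integer matrix of 0-based category codes, columns named.
#' @param levels declared per-column cardinalities; when omitted, inferred
#'   as (max observed code + 1), at least 1.
#' @return `bn_dataset`: the matrix with a `levels` attribute.
#' @export
as_dataset <- function(x, levels = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (is.null(levels)) {
    levels <- apply(x, 2, function(col) {
      if (length(col) == 0) 1L else max(col) + 1L
    })
    levels <- pmax(as.integer(levels), 1L)
  }
  levels <- as.integer(levels)
  stopifnot(length(levels) == ncol(x))
  if (nrow(x) && any(x < 0 | x >= rep(levels, each = nrow(x))))
    stop("category code outside declared level range")
  structure(x, levels = levels, class = c("bn_dataset", "matrix", "array"))
}

#' @export
#' @rdname as_dataset
dataset_levels <- function(x) {
  lv <- attr(x, "levels")
  if (is.null(lv)) lv <- apply(as.matrix(x), 2, function(col) max(col) + 1L)
  as.integer(lv)
}

# Coerce learner input to an integer matrix + levels, accepting bn_dataset,
# plain matrices, or data frames of integer codes.
as_data_matrix <- function(data) {
  if (inherits(data, "bn_dataset"))
    return(list(x = unclass_dataset(data), levels = dataset_levels(data)))
  x <- as.matrix(data)
  storage.mode(x) <- "integer"
  lv <- pmax(apply(x, 2, function(col) if (nrow(x)) max(col) + 1L else 1L), 1L)
  list(x = x, levels = as.integer(lv))
}

unclass_dataset <- function(x) {
  attr(x, "levels") <- NULL
  class(x) <- NULL
  x
}
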