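#' Read and write discrete Bayesian networks as JSON
#'
#' Schema: `{"nodes": [{"name", "levels", "parents", "cpt"}]}` where `cpt`
#' is the row-major flattening of the `q x r` table (rows are parent
#' configurations, first listed parent varying fastest).
#'
#' @param bn a `discrete_bn`.
#' @param path file path.
#' @return `read_bn_json` returns a `discrete_bn`; `write_bn_json` its path,
#'   invisibly.
#' @export
write_bn_json <- function(bn, path) {
  nodes <- lapply(seq_along(bn$dag$nodes), function(i) {
    list(name = bn$dag$nodes[i],
         levels = bn$levels[i],
         parents = as.list(bn$dag$nodes[bn$dag$parents[[i]]]),
         cpt = as.vector(t(bn$cpts[[i]])))
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  names <- vapply(spec$nodes, function(nd) nd$name, character(1))
  levels <- vapply(spec$nodes, function(nd) as.integer(nd$levels), integer(1))
  parents <- lapply(spec$nodes, function(nd)
    match(unlist(nd$parents, use.names = FALSE), names))
  parents <- lapply(parents, function(p) if (is.null(p)) integer(0) else p)
  dag <- new_dag(names, parents)
  cpts <- lapply(seq_along(names), function(i) {
    q <- prod(levels[dag$parents[[i]]])
    matrix(unlist(spec$nodes[[i]]$cpt, use.names = FALSE),
           nrow = q, ncol = levels[i], byrow = TRUE)
  })
  new_discrete_bn(dag, levels, cpts)
}

#' Write / read a categorical dataset as CSV
#'
#' RFC-4180 CSV with a header row and 0-based integer category codes.
#'
#' @param data a `bn_dataset` (or integer matrix).
#' @param path file path.
#' @param levels optional declared cardinalities when reading; inferred from
#'   the observed codes otherwise.
#' @export
write_dataset_csv <- function(data, path) {
  write.csv(as.data.frame(unclass_dataset(as_dataset(data))), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, levels = NULL) {
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) stop("empty dataset file")
  as_dataset(as.matrix(df), levels)
}

#' Export a DAG as a two-column edge-list CSV
#' @param dag a `bn_dag`.
#' @param path file path.
#' @export
write_dag_edges_csv <- function(dag, path) {
  e <- dag_edges(dag)
  df <- data.frame(parent = e[, 1], child = e[, 2])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a discrete Bayesian network in BIF format
#'
#' Minimal Bayesian Interchange Format writer: level labels are the code
#' strings `"0" ... "r-1"`.
#'
#' @param bn a `discrete_bn`.
#' @param path file path.
#' @param name network name written to the header.
#' @export
write_bn_bif <- function(bn, path, name = "network") {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("network ", name, " {", "\n}")
  for (i in seq_along(bn$dag$nodes)) {
    wl("variable ", bn$dag$nodes[i], " {")
    wl("  type discrete [ ", bn$levels[i], " ] { ",
       paste(seq_len(bn$levels[i]) - 1, collapse = ", "), " };")
    wl("}")
  }
  for (i in seq_along(bn$dag$nodes)) {
    ps <- bn$dag$parents[[i]]
    if (length(ps) == 0) {
      wl("probability ( ", bn$dag$nodes[i], " ) {")
      wl("  table ", paste(format(bn$cpts[[i]][1, ], digits = 10),
                           collapse = ", "), ";")
    } else {
      wl("probability ( ", bn$dag$nodes[i], " | ",
         paste(bn$dag$nodes[ps], collapse = ", "), " ) {")
      plev <- bn$levels[ps]
      for (row in seq_len(nrow(bn$cpts[[i]]))) {
        cfg <- integer(length(ps))
        rem <- row - 1L
        for (k in seq_along(ps)) {  # first parent fastest
          cfg[k] <- rem %% plev[k]
          rem <- rem %/% plev[k]
        }
        wl("  ( ", paste(cfg, collapse = ", "), " ) ",
           paste(format(bn$cpts[[i]][row, ], digits = 10), collapse = ", "),
           ";")
      }
    }
    wl("}")
  }
  invisible(path)
}
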