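#' Maximum-likelihood parameter fitting
#'
#' CPT rows are conditional relative frequencies of the data given the DAG;
#' parent configurations never observed receive a uniform row (flagged in
#' the attribute `unseen_rows`), which keeps downstream interventional
#' inference defined.
#'
#' @param dag a `bn_dag` whose nodes name columns of `data`.
#' @param data a `bn_dataset` or integer code matrix.
#' @param levels declared cardinalities per node; defaults to the dataset's.
#' @return a `discrete_bn`.
#' @export
mle_fit <- function(dag, data, levels = NULL) {
  dm <- as_data_matrix(data)
  idx <- match(dag$nodes, colnames(dm$x))
  if (anyNA(idx)) stop("data columns must match DAG nodes")
  if (is.null(levels)) levels <- dm$levels[idx]
  levels <- as.integer(levels)
  if (nrow(dm$x) &&
      any(apply(dm$x[, idx, drop = FALSE], 2, max) >= levels))
    stop("category code outside declared level range")
  unseen <- 0L
  lvfull <- expand_levels(dm, idx, levels)
  cpts <- lapply(seq_along(dag$nodes), function(i) {
    ps <- dag$parents[[i]]
    r <- levels[i]
    q <- prod(levels[ps])
    # counts in mixed-radix order: first parent fastest, node slowest
    cnt <- matrix(joint_counts(dm$x, idx[c(ps, i)] - 1L, lvfull),
                  nrow = q, ncol = r)
    rs <- rowSums(cnt)
    zero <- rs == 0
    unseen <<- unseen + sum(zero)
    out <- cnt / ifelse(rs == 0, 1, rs)
    out[zero, ] <- 1 / r
    out
  })
  bn <- new_discrete_bn(dag, levels, cpts)
  attr(bn, "unseen_rows") <- unseen
  bn
}

# declared levels aligned to the full data column order
expand_levels <- function(dm, idx, levels) {
  lv <- dm$levels
  lv[idx] <- levels
  lv
}
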