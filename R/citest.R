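#' Chi-square conditional independence test with mutual information
#'
#' G-test: the statistic is `2 * n * MI(x; y | Z)` computed from observed
#' frequencies (zero-count cells contribute 0), referred to a chi-square
#' distribution with `(r_x - 1) * (r_y - 1) * prod(r_z)` degrees of freedom,
#' cardinalities taken from the declared levels. The pair is declared
#' independent when `p > level`.
#'
#' @param data a `bn_dataset` or integer code matrix.
#' @param x,y column names or indices of the tested pair.
#' @param Z conditioning column names or indices (possibly empty).
#' @param level significance level in (0, 1).
#' @return list with `statistic`, `dof`, `p_value`, `independent`.
#' @export
chi_square_mi_test <- function(data, x, y, Z = integer(0), level = 0.05) {
  stopifnot(level > 0, level < 1)
  dm <- as_data_matrix(data)
  if (nrow(dm$x) == 0) stop("empty dataset")
  ix <- resolve_col_dm(dm, x); iy <- resolve_col_dm(dm, y)
  iZ <- if (length(Z)) sort(vapply(Z, resolve_col_dm, integer(1), dm = dm)) else integer(0)
  if (ix == iy || ix %in% iZ || iy %in% iZ)
    stop("x, y and Z must be distinct")
  lv <- dm$levels
  dof <- (lv[ix] - 1) * (lv[iy] - 1) * prod(lv[iZ])
  if (dof <= 0)
    return(list(statistic = 0, dof = dof, p_value = 1, independent = TRUE))
  g <- 2 * (cat_loglik(dm$x, c(ix, iy, iZ) - 1L, lv) -
              cat_loglik(dm$x, c(ix, iZ) - 1L, lv) -
              cat_loglik(dm$x, c(iy, iZ) - 1L, lv) +
              (if (length(iZ)) cat_loglik(dm$x, iZ - 1L, lv) else 0))
  g <- max(g, 0)
  p <- pchisq(g, dof, lower.tail = FALSE)
  list(statistic = g, dof = dof, p_value = p, independent = p > level)
}

resolve_col_dm <- function(dm, v) {
  if (is.character(v)) {
    i <- match(v, colnames(dm$x))
    if (anyNA(i)) stop("unknown column: ", v)
    i
  } else as.integer(v)
}

# Pairwise empirical mutual information matrix (nats, per-sample).
pairwise_mi <- function(dm) {
  p <- ncol(dm$x)
  lv <- dm$levels
  ll1 <- vapply(seq_len(p), function(i) cat_loglik(dm$x, i - 1L, lv), numeric(1))
  mi <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p)) {
    v <- cat_loglik(dm$x, c(i, j) - 1L, lv) - ll1[i] - ll1[j]
    mi[i, j] <- mi[j, i] <- max(v, 0)
  }
  mi
}

#' Candidate parent sets from pairwise mutual information
#'
#' For each variable, the `K` other variables with the highest pairwise
#' empirical mutual information; ties broken by column order.
#'
#' @param data a `bn_dataset` or integer code matrix.
#' @param K candidates per node (>= 0).
#' @return named list (one per column) of candidate column-name vectors.
#' @export
mi_candidate_parents <- function(data, K) {
  stopifnot(K >= 0)
  dm <- as_data_matrix(data)
  p <- ncol(dm$x)
  nms <- colnames(dm$x)
  mi <- if (p >= 2) pairwise_mi(dm) else matrix(0, p, p)
  out <- lapply(seq_len(p), function(i) {
    others <- setdiff(seq_len(p), i)
    ranked <- others[order(-mi[i, others], others)]
    nms[head(ranked, min(K, length(ranked)))]
  })
  names(out) <- nms
  out
}
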