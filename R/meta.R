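#' Shannon entropy of a categorical column (bits)
#'
#' `-sum p log2 p` over observed frequencies, with `0 * log 0 = 0`.
#'
#' @param column vector of category codes (nonempty).
#' @export
shannon_entropy <- function(column) {
  if (length(column) == 0) stop("empty column")
  p <- tabulate(match(column, unique(column))) / length(column)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Concentration coefficient (Goodman-Kruskal tau)
#'
#' Proportional reduction in prediction error of `y` given `x`, computed
#' from the joint frequency table:
#' `tau = (sum_ij p_ij^2 / p_i. - sum_j p_.j^2) / (1 - sum_j p_.j^2)`.
#' Defined as 0 when `y` is constant.
#'
#' @param x_column,y_column equal-length code vectors.
#' @return tau in \[0, 1\].
#' @export
concentration_coefficient <- function(x_column, y_column) {
  stopifnot(length(x_column) == length(y_column))
  n <- length(x_column)
  tab <- table(x_column, y_column) / n
  pj <- colSums(tab)
  denom <- 1 - sum(pj^2)
  if (denom <= 0) return(0)
  pi_ <- rowSums(tab)
  num <- sum(tab[pi_ > 0, , drop = FALSE]^2 / pi_[pi_ > 0]) - sum(pj^2)
  max(0, min(1, num / denom))
}

#' Information-theoretic meta-feature vector of a categorical dataset
#'
#' Eight non-negative components in fixed order: mean, sd, min, max of the
#' per-column Shannon entropies normalized by `log2(cardinality)` (declared
#' cardinality; a constant declared-1 column scores 0), followed by mean,
#' sd, min, max of the Goodman-Kruskal tau over all ordered column pairs.
#' Permutation-invariant in both rows and columns.
#'
#' @param dataset a `bn_dataset` or integer code matrix with >= 2 columns.
#' @return named numeric vector of length 8.
#' @export
meta_feature_vector <- function(dataset) {
  dm <- as_data_matrix(dataset)
  p <- ncol(dm$x)
  if (p < 2) stop("meta-features need at least 2 columns")
  ent <- vapply(seq_len(p), function(i) {
    r <- dm$levels[i]
    if (r <= 1) return(0)
    shannon_entropy(dm$x[, i]) / log2(r)
  }, numeric(1))
  pairs <- expand.grid(x = seq_len(p), y = seq_len(p))
  pairs <- pairs[pairs$x != pairs$y, ]
  taus <- mapply(function(i, j)
    concentration_coefficient(dm$x[, i], dm$x[, j]), pairs$x, pairs$y)
  c(entropy_mean = mean(ent), entropy_sd = sd(ent),
    entropy_min = min(ent), entropy_max = max(ent),
    tau_mean = mean(taus), tau_sd = sd(taus),
    tau_min = min(taus), tau_max = max(taus))
}

#' Mean cosine similarity between a reference and synthetic datasets
#'
#' Cosine similarity between the [meta_feature_vector()]s of the reference
#' dataset and each synthetic dataset, averaged; components are
#' non-negative so the result lies in \[0, 1\]. A zero-norm vector yields
#' similarity 0 for that pair (flagged via attribute `zero_norm_pairs`).
#'
#' @param real the reference dataset.
#' @param synthetic nonempty list of synthetic datasets.
#' @return mean cosine similarity in \[0, 1\].
#' @export
dataset_similarity <- function(real, synthetic) {
  if (!is.list(synthetic) || length(synthetic) == 0)
    stop("synthetic must be a nonempty list of datasets")
  v0 <- meta_feature_vector(real)
  zero_pairs <- 0L
  sims <- vapply(synthetic, function(d) {
    v <- meta_feature_vector(d)
    n0 <- sqrt(sum(v0^2)); n1 <- sqrt(sum(v^2))
    if (n0 == 0 || n1 == 0) {
      zero_pairs <<- zero_pairs + 1L
      return(0)
    }
    sum(v0 * v) / (n0 * n1)
  }, numeric(1))
  structure(mean(sims), zero_norm_pairs = zero_pairs)
}
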