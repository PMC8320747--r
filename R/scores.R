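# Decomposable scores for discrete Bayesian networks.
#
# Both scores share a single counting primitive: the maximized categorical
# log-likelihood of a joint column set (cat_loglik, in C++). The conditional
# ML log-likelihood of node | parents is ll(family) - ll(parents), and both
# scores are functions of those two terms, so one cache serves everything.

.regret_cache <- new.env(parent = emptyenv())

# log-sum-exp of two values
lse2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(m)
  m + log(exp(a - m) + exp(b - m))
}

#' Logarithm of the multinomial NML normalizing sum
#'
#' Computes `log C(n, r)`, the log of the Shtarkov normalizing sum of the
#' `r`-category multinomial model class at sample size `n` (the minimax
#' regret of the NML code). Uses the exact linear-time recurrence
#' `C(n, r) = C(n, r-1) + n/(r-2) * C(n, r-2)` seeded by the exact
#' binomial sum for `r = 2`, in log space; above `n * r > cell_limit` a
#' Szpankowski-style large-`n` asymptotic is used instead.
#'
#' @param n sample size (>= 0).
#' @param r number of categories (>= 1).
#' @param cell_limit exact-computation budget in table cells (default 1e7).
#' @return `log C(n, r)` (0 when `n == 0` or `r == 1`).
#' @export
multinomial_nml_regret <- function(n, r, cell_limit = 1e7) {
  n <- as.integer(n); r <- as.integer(r)
  stopifnot(n >= 0, r >= 1)
  if (n == 0 || r == 1) return(0)
  if (as.double(n) * as.double(r) > cell_limit) {
    # fixed-r, large-n asymptotic: C_r(n) ~ (n/2)^((r-1)/2) * sqrt(pi)/Gamma(r/2)
    return(((r - 1) / 2) * log(n / 2) + 0.5 * log(pi) - lgamma(r / 2))
  }
  key <- as.character(n)
  logc <- .regret_cache[[key]]  # logc[k] = log C(n, k)
  if (is.null(logc)) {
    k <- 0:n
    terms <- lchoose(n, k) +
      ifelse(k == 0, 0, k * (log(k) - log(n))) +
      ifelse(k == n, 0, (n - k) * (log(n - k) - log(n)))
    m <- max(terms)
    logc <- c(0, m + log(sum(exp(terms - m))))
  }
  if (length(logc) < r) {
    logc <- c(logc, rep(NA_real_, r - length(logc)))
    for (k in seq.int(max(which(!is.na(logc))) + 1L, r))
      logc[k] <- lse2(logc[k - 1], log(n / (k - 2)) + logc[k - 2])
  }
  .regret_cache[[key]] <- logc
  logc[r]
}

#' Local BIC score of a node given a parent set
#'
#' Maximized multinomial log-likelihood of `node | parents` minus the BIC
#' penalty `(log n) / 2 * (r - 1) * q`, with cardinalities taken from the
#' declared levels of the dataset (so constant columns are scored
#' consistently).
#'
#' @param data a `bn_dataset` (or integer code matrix).
#' @param node column name or index of the child.
#' @param parents column names or indices of the parents (may be empty).
#' @return the local score (log scale, higher is better).
#' @export
bic_local <- function(data, node, parents = character(0)) {
  m <- score_model(data, "bic")
  local_score(m, resolve_col(m, node), resolve_cols(m, parents))
}

#' Local qNML score of a node given a parent set
#'
#' Quotient NML: `logNML1(node + parents) - logNML1(parents)` where
#' `logNML1(S)` treats the columns in `S` as a single categorical variable
#' with the product of their declared cardinalities and equals its maximized
#' log-likelihood minus [multinomial_nml_regret()].
#'
#' @inheritParams bic_local
#' @export
qnml_local <- function(data, node, parents = character(0)) {
  m <- score_model(data, "qnml")
  local_score(m, resolve_col(m, node), resolve_cols(m, parents))
}

#' Build a cached decomposable score over a dataset
#'
#' @param data a `bn_dataset` or integer matrix of category codes.
#' @param kind `"bic"` or `"qnml"`.
#' @param regret_cell_limit passed to [multinomial_nml_regret()].
#' @return a `score_model` holding the data, declared levels and a local
#'   score cache keyed by (node, parent set); use [local_score()] and
#'   [score_dag()] to evaluate.
#' @export
score_model <- function(data, kind = c("bic", "qnml"), regret_cell_limit = 1e7) {
  kind <- match.arg(kind)
  dm <- as_data_matrix(data)
  if (nrow(dm$x) == 0) stop("cannot score an empty dataset")
  structure(list(x = dm$x, levels = dm$levels, n = nrow(dm$x), kind = kind,
                 nodes = colnames(dm$x), regret_cell_limit = regret_cell_limit,
                 cache = new.env(parent = emptyenv())),
            class = "score_model")
}

resolve_col <- function(model, v) {
  if (is.character(v)) {
    i <- match(v, model$nodes)
    if (anyNA(i)) stop("unknown column: ", v)
    i
  } else as.integer(v)
}
resolve_cols <- function(model, v) {
  if (length(v) == 0) integer(0) else sort(vapply(v, resolve_col,
                                                  integer(1), model = model))
}

#' Evaluate (and cache) a local score
#' @param model a [score_model()].
#' @param node child column index.
#' @param parents integer parent column indices (node excluded).
#' @export
local_score <- function(model, node, parents = integer(0)) {
  parents <- sort(as.integer(parents))
  if (node %in% parents) stop("node may not be its own parent")
  key <- paste0(node, "|", paste(parents, collapse = ","))
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  lv <- model$levels
  ll_fam <- cat_loglik(model$x, c(parents, node) - 1L, lv)
  ll_par <- if (length(parents)) cat_loglik(model$x, parents - 1L, lv) else 0
  val <- if (model$kind == "bic") {
    q <- prod(lv[parents])
    ll_fam - ll_par - log(model$n) / 2 * (lv[node] - 1) * q
  } else {
    r_fam <- prod(lv[c(parents, node)])
    r_par <- prod(lv[parents])
    (ll_fam - multinomial_nml_regret(model$n, r_fam, model$regret_cell_limit)) -
      (ll_par - multinomial_nml_regret(model$n, r_par, model$regret_cell_limit))
  }
  model$cache[[key]] <- val
  val
}

#' Total decomposable score of a DAG
#' @param model a [score_model()].
#' @param dag a `bn_dag` whose nodes match the data columns.
#' @export
score_dag <- function(model, dag) {
  idx <- match(dag$nodes, model$nodes)
  if (anyNA(idx)) stop("DAG nodes must match data columns")
  sum(vapply(seq_along(dag$nodes), function(i)
    local_score(model, idx[i], idx[dag$parents[[i]]]), numeric(1)))
}
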