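# Exact inference in discrete BNs by variable elimination, plus the
# do-operator (graph surgery). Factors are lists (vars, card, vals) with
# vals in mixed-radix order, first listed variable fastest.

factor_new <- function(vars, card, vals) {
  list(vars = as.integer(vars), card = as.integer(card), vals = as.numeric(vals))
}

# index vector (1-based) into factor f for every joint assignment of
# out_vars (first var fastest)
factor_map <- function(out_vars, out_card, f) {
  n_out <- prod(out_card)
  idx <- rep(1L, n_out)
  stride_out <- cumprod(c(1, out_card[-length(out_card)]))
  stride_f <- cumprod(c(1, f$card[-length(f$card)]))
  for (k in seq_along(f$vars)) {
    j <- match(f$vars[k], out_vars)
    digit <- (seq_len(n_out) - 1L) %/% stride_out[j] %% out_card[j]
    idx <- idx + digit * stride_f[k]
  }
  idx
}

factor_product <- function(f1, f2) {
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  if (prod(card) > 1e7) stop("factor too large", call. = FALSE)
  factor_new(vars, card,
             f1$vals[factor_map(vars, card, f1)] *
               f2$vals[factor_map(vars, card, f2)])
}

factor_marginalize <- function(f, v) {
  k <- match(v, f$vars)
  if (is.na(k)) return(f)
  if (length(f$vars) == 1) return(factor_new(integer(0), integer(0), sum(f$vals)))
  perm <- c(setdiff(seq_along(f$vars), k), k)
  arr <- aperm(array(f$vals, dim = f$card), perm)
  factor_new(f$vars[perm[-length(perm)]], f$card[perm[-length(perm)]],
             rowSums(matrix(arr, ncol = f$card[k])))
}

# factor of node i's CPT over (parents..., i)
node_factor <- function(bn, i) {
  ps <- bn$dag$parents[[i]]
  factor_new(c(ps, i), c(bn$levels[ps], bn$levels[i]), as.vector(bn$cpts[[i]]))
}

# Exact marginal of node `target` in the sub-network spanned by its
# ancestor closure, with optional clamped evidence nodes (each clamped node
# contributes a point-mass factor and loses its CPT). Returns a probability
# vector, or NULL when the elimination would exceed the size guard.
ve_marginal <- function(bn, target, clamp = integer(0), clamp_val = integer(0),
                        cell_guard = 1e6) {
  # ancestors computed on the mutilated graph: clamped nodes keep no parents
  dag2 <- bn$dag
  for (k in seq_along(clamp)) dag2$parents[[clamp[k]]] <- integer(0)
  anc2 <- local({
    seen <- logical(length(dag2$nodes))
    stack <- target
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, dag2$parents[[v]]) }
    }
    which(seen)
  })
  factors <- list()
  for (i in anc2) {
    k <- match(i, clamp)
    if (!is.na(k)) {
      vals <- rep(0, bn$levels[i]); vals[clamp_val[k] + 1L] <- 1
      factors[[length(factors) + 1]] <- factor_new(i, bn$levels[i], vals)
    } else {
      factors[[length(factors) + 1]] <- node_factor(bn, i)
    }
  }
  elim <- setdiff(anc2, target)
  # min-degree elimination ordering on the factor interaction graph
  while (length(elim)) {
    nb_size <- vapply(elim, function(v) {
      vs <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      prod(bn$levels[vs])
    }, numeric(1))
    v <- elim[which.min(nb_size)]
    if (min(nb_size) > cell_guard) return(NULL)
    elim <- setdiff(elim, v)
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    merged <- Reduce(factor_product, factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(merged, v)))
  }
  out <- Reduce(factor_product, factors)
  out <- array(out$vals, dim = out$card)
  if (length(out) != bn$levels[target]) stop("inference bookkeeping error")
  as.numeric(out) / sum(out)
}

#' Interventional distribution by graph surgery
#'
#' `P(A | do(B = b))`: removes `B`'s incoming edges, clamps `B = b`, and
#' runs exact variable elimination restricted to the target's ancestor
#' closure in the mutilated graph. If the elimination would exceed the size
#' guard, falls back to forward sampling of the mutilated network.
#'
#' @param bn a `discrete_bn`.
#' @param B intervention node label (distinct from `A`).
#' @param b clamped level code of `B` (0-based).
#' @param A target node label.
#' @param fallback_n forward-sampling size used when exact elimination is
#'   infeasible (default 1e5).
#' @param fallback_seed seed for the sampling fallback.
#' @return probability vector over `A`'s levels (sums to 1).
#' @export
do_distribution <- function(bn, B, b, A, fallback_n = 1e5, fallback_seed = 1) {
  iB <- match(B, bn$dag$nodes); iA <- match(A, bn$dag$nodes)
  if (is.na(iB) || is.na(iA)) stop("unknown node")
  if (iB == iA) stop("intervention and target must differ")
  b <- as.integer(b)
  if (b < 0 || b >= bn$levels[iB]) stop("invalid level for ", B)
  out <- ve_marginal(bn, iA, clamp = iB, clamp_val = b)
  if (is.null(out)) {
    x <- sample_mutilated(bn, iB, b, fallback_n, fallback_seed)
    out <- tabulate(x[, iA] + 1L, nbins = bn$levels[iA]) / fallback_n
  }
  out
}

sample_mutilated <- function(bn, iB, b, n, seed) {
  bn2 <- bn
  bn2$dag$parents[[iB]] <- integer(0)
  vals <- rep(0, bn$levels[iB]); vals[b + 1L] <- 1
  bn2$cpts[[iB]] <- matrix(vals, nrow = 1)
  forward_sample(bn2, n, seed)
}

# All interventional distributions P(A | do(B = b)) for every level b of B
# in one elimination: drop B's CPT (surgery, B free), restrict to the
# target's ancestor closure in the mutilated graph, eliminate everything
# but {A, B}. Returns a levels(B) x levels(A) matrix with unit row sums,
# or NULL past the size guard.
ve_do_profile <- function(bn, iB, iA, cell_guard = 1e6) {
  anc <- local({
    par2 <- bn$dag$parents
    par2[[iB]] <- integer(0)
    seen <- logical(length(bn$dag$nodes))
    stack <- iA
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!seen[v]) { seen[v] <- TRUE; stack <- c(stack, par2[[v]]) }
    }
    which(seen)
  })
  if (!(iB %in% anc)) {
    m <- ve_marginal(bn, iA, cell_guard = cell_guard)
    if (is.null(m)) return(NULL)
    return(matrix(m, nrow = bn$levels[iB], ncol = bn$levels[iA],
                  byrow = TRUE))
  }
  factors <- lapply(setdiff(anc, iB), function(i) node_factor(bn, i))
  keep <- c(iA, iB)
  elim <- setdiff(anc, keep)
  while (length(elim)) {
    nb_size <- vapply(elim, function(v) {
      vs <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      prod(bn$levels[vs])
    }, numeric(1))
    v <- elim[which.min(nb_size)]
    if (min(nb_size) > cell_guard) return(NULL)
    elim <- setdiff(elim, v)
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    merged <- Reduce(factor_product, factors[touch])
    factors <- c(factors[!touch], list(factor_marginalize(merged, v)))
  }
  out <- Reduce(factor_product, factors)
  # arrange as (B, A)
  perm <- match(c(iB, iA), out$vars)
  if (anyNA(perm)) return(NULL)
  arr <- aperm(array(out$vals, dim = out$card), perm)
  m <- matrix(arr, nrow = bn$levels[iB], ncol = bn$levels[iA])
  m / rowSums(m)
}
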