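#' Order-space MCMC configuration
#'
#' @param iterations Metropolis-Hastings steps per restart (> burn_in).
#' @param burn_in steps discarded before the best-order tracking weighs in
#'   (the chain still moves during burn-in).
#' @param candidate_size K: initial per-node candidate parents, ranked by
#'   pairwise mutual information.
#' @param expansion_cap maximum parent-set size considered per node.
#' @param max_candidates hard cap on the per-node candidate set after greedy
#'   expansion (keeps subset enumeration bounded).
#' @param restarts independent chains; the best-scoring visited order across
#'   all chains is used.
#' @param score `"bic"` or `"qnml"`.
#' @param seed integer seed; the run is reproducible given `(data, cfg)`.
#' @return an `order_mcmc_config`.
#' @export
order_mcmc_config <- function(iterations = 10000, burn_in = 1000,
                              candidate_size = 8, expansion_cap = 5,
                              max_candidates = 12, restarts = 3,
                              score = c("bic", "qnml"), seed = 1) {
  score <- match.arg(score)
  stopifnot(iterations > burn_in, burn_in >= 0, candidate_size >= 0,
            expansion_cap >= 0, restarts >= 1, max_candidates <= 16,
            max_candidates >= candidate_size)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 candidate_size = as.integer(candidate_size),
                 expansion_cap = as.integer(expansion_cap),
                 max_candidates = as.integer(max_candidates),
                 restarts = as.integer(restarts), score = score,
                 seed = as.integer(seed)),
            class = "order_mcmc_config")
}

popcount16 <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) {
      t0 <- integer(65536)
      for (b in 0:15) t0 <- t0 + bitwAnd(bitwShiftR(0:65535, b), 1L)
      tab <<- t0
    }
    tab[x + 1L]
  }
})

# Per-node table of all candidate-subset parent sets (as bitmasks over the
# node's candidate vector) with their local scores.
subset_tables <- function(model, cand_idx, cap) {
  p <- length(cand_idx)
  lapply(seq_len(p), function(i) {
    m <- length(cand_idx[[i]])
    masks <- 0:(2^m - 1)
    masks <- masks[popcount16(masks) <= cap]
    scores <- vapply(masks, function(msk) {
      pa <- cand_idx[[i]][bitwAnd(bitwShiftR(msk, 0:(max(m, 1) - 1)), 1L) == 1L]
      local_score(model, i, pa)
    }, numeric(1))
    list(masks = masks, scores = scores)
  })
}

# best score of node i when exactly the candidate bits in `pm` are permitted
best_under <- function(tab, pm) {
  ok <- bitwAnd(tab$masks, bitwNot(pm)) == 0L
  max(tab$scores[ok])
}
best_mask_under <- function(tab, pm) {
  ok <- bitwAnd(tab$masks, bitwNot(pm)) == 0L
  sc <- tab$scores
  sc[!ok] <- -Inf
  tab$masks[which.max(sc)]
}

#' Score a topological node ordering
#'
#' The order score is the sum over nodes of the best local score achievable
#' with a parent set drawn from the intersection of the node's candidate set
#' and its predecessors in the order, with set size capped.
#'
#' @param order permutation of all column names (or indices) of the data
#'   behind `model`.
#' @param model a [score_model()].
#' @param candidates named list of candidate parent name vectors (e.g. from
#'   [mi_candidate_parents()]).
#' @param expansion_cap maximum parent-set size.
#' @export
order_score <- function(order, model, candidates, expansion_cap = 5) {
  p <- length(model$nodes)
  ord <- if (is.character(order)) match(order, model$nodes) else as.integer(order)
  if (length(ord) != p || anyNA(ord) || anyDuplicated(ord))
    stop("order must be a permutation of all nodes")
  pos <- order(ord)
  total <- 0
  for (i in seq_len(p)) {
    cand <- match(candidates[[model$nodes[i]]], model$nodes)
    pool <- cand[pos[cand] < pos[i]]
    best <- local_score(model, i, integer(0))
    for (k in seq_len(min(length(pool), expansion_cap)))
      for (S in combn_list(pool, k))
        best <- max(best, local_score(model, i, S))
    total <- total + best
  }
  total
}

#' Hybrid structure learning by MCMC over topological orders
#'
#' Candidate parent sets are seeded with the top-K pairwise-mutual-
#' information variables and greedily expanded while doing so improves the
#' node's best achievable local score. A Metropolis-Hastings chain over
#' node orderings (proposals: adjacent transposition or random pair swap,
#' symmetric) maximizes the order score; the best-visited order's per-node
#' argmax parent sets form the output DAG, reduced to its CPDAG.
#'
#' @param data a `bn_dataset` or integer code matrix.
#' @param cfg an [order_mcmc_config()].
#' @return a `learned_structure`.
#' @export
order_mcmc_learn <- function(data, cfg = order_mcmc_config()) {
  model <- score_model(data, cfg$score)
  p <- ncol(model$x)
  nms <- model$nodes
  amat0 <- matrix(FALSE, p, p, dimnames = list(nms, nms))
  if (p <= 1)
    return(new_learned_structure(amat0, paste0("ordermcmc-", cfg$score),
                                 unclass(cfg)))
  cap <- cfg$expansion_cap

  with_seed(cfg$seed, {
    # -- candidate sets: top-K MI, then greedy expansion ------------------
    dm <- list(x = model$x, levels = model$levels)
    mi <- pairwise_mi(dm)
    cand_idx <- lapply(seq_len(p), function(i) {
      others <- setdiff(seq_len(p), i)
      head(others[order(-mi[i, others], others)], cfg$candidate_size)
    })
    best_over <- function(i, cand) {  # best local score over subsets <= cap
      best <- local_score(model, i, integer(0)); arg <- integer(0)
      for (k in seq_len(min(length(cand), cap)))
        for (S in combn_list(cand, k)) {
          v <- local_score(model, i, S)
          if (v > best) { best <- v; arg <- S }
        }
      list(score = best, arg = arg)
    }
    for (i in seq_len(p)) {
      repeat {
        if (length(cand_idx[[i]]) >= cfg$max_candidates) break
        cur <- best_over(i, cand_idx[[i]])
        if (length(cur$arg) >= cap) break
        pool <- setdiff(seq_len(p), c(i, cand_idx[[i]]))
        if (!length(pool)) break
        gains <- vapply(pool, function(v)
          local_score(model, i, sort(c(cur$arg, v))) - cur$score, numeric(1))
        if (max(gains) <= 1e-9) break
        cand_idx[[i]] <- sort(c(cand_idx[[i]], pool[which.max(gains)]))
      }
    }

    tabs <- subset_tables(model, cand_idx, cap)

    pred_mask <- function(i, pos) {
      ci <- cand_idx[[i]]
      if (!length(ci)) return(0L)
      as.integer(sum(bitwShiftL(1L, which(pos[ci] < pos[i]) - 1L)))
    }

    best_total <- -Inf; best_pos <- NULL
    for (chain in seq_len(cfg$restarts)) {
      ord <- sample.int(p)          # ord[k] = node at position k
      pos <- order(ord)
      ns <- vapply(seq_len(p), function(i)
        best_under(tabs[[i]], pred_mask(i, pos)), numeric(1))
      total <- sum(ns)
      if (total > best_total) { best_total <- total; best_pos <- pos }
      for (it in seq_len(cfg$iterations)) {
        if (runif(1) < 0.5) {
          j <- sample.int(p - 1, 1)
          lo <- j; hi <- j + 1L
        } else {
          jj <- sort(sample.int(p, 2))
          lo <- jj[1]; hi <- jj[2]
        }
        a <- ord[lo]; b <- ord[hi]
        new_ord <- ord; new_ord[lo] <- b; new_ord[hi] <- a
        new_pos <- pos; new_pos[a] <- hi; new_pos[b] <- lo
        touch <- c(a, b)
        if (hi - lo > 1) {
          between <- ord[(lo + 1):(hi - 1)]
          touch <- c(touch, between[vapply(between, function(v)
            any(cand_idx[[v]] %in% c(a, b)), logical(1))])
        }
        new_ns <- ns
        for (v in touch) new_ns[v] <- best_under(tabs[[v]], pred_mask(v, new_pos))
        new_total <- total + sum(new_ns[touch]) - sum(ns[touch])
        if (log(runif(1)) < new_total - total) {
          ord <- new_ord; pos <- new_pos; ns <- new_ns; total <- new_total
          if (total > best_total) { best_total <- total; best_pos <- pos }
        }
      }
    }

    parents <- lapply(seq_len(p), function(i) {
      msk <- best_mask_under(tabs[[i]], pred_mask(i, best_pos))
      ci <- cand_idx[[i]]
      if (!length(ci) || msk == 0L) integer(0)
      else ci[bitwAnd(bitwShiftR(msk, seq_along(ci) - 1L), 1L) == 1L]
    })
    dag <- new_dag(nms, parents)
    new_learned_structure(dag_to_cpdag_amat(dag),
                          paste0("ordermcmc-", cfg$score),
                          unclass(cfg), score = best_total)
  })
}
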