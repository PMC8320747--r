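#' Greedy equivalence search
#'
#' Score-based structure learning over equivalence classes: a forward phase
#' greedily applies the best score-increasing insert operator, then a
#' backward phase the best delete operator, alternating until neither phase
#' improves the (decomposable, score-equivalent) objective. Operator
#' validity follows the standard insert/delete conditions (clique and
#' semi-directed-path tests); after every operator the state is re-closed to
#' a CPDAG. Deterministic given data and score.
#'
#' @param data a `bn_dataset` or integer code matrix (>= 1 row; >= 2 rows
#'   for a meaningful fit).
#' @param score `"bic"` (default), `"qnml"`, or a ready [score_model()].
#' @param max_subset_size cap on the enumerated insert/delete neighbor
#'   subsets (default 4); only binds in locally dense regions.
#' @return a `learned_structure`.
#' @export
ges_learn <- function(data, score = "bic", max_subset_size = 4) {
  model <- if (inherits(score, "score_model")) score else score_model(data, score)
  p <- ncol(model$x)
  nms <- model$nodes
  if (is.null(nms)) nms <- paste0("V", seq_len(p) - 1L)
  amat <- matrix(FALSE, p, p, dimnames = list(nms, nms))
  if (p <= 1)
    return(new_learned_structure(amat, "ges", list(score = model$kind)))

  ls_ <- function(y, pa) local_score(model, y, pa)
  # insert/delete score diffs are re-derived every step but depend only on
  # (y, Pa(y), x, subset); cache them across steps
  diff_cache <- new.env(parent = emptyenv())
  cached_diff <- function(key, with, without) {
    hit <- diff_cache[[key]]
    if (!is.null(hit)) return(hit)
    d <- ls_(with$y, with$pa) - ls_(without$y, without$pa)
    diff_cache[[key]] <- d
    d
  }

  is_clique <- function(adjm, S) {
    if (length(S) <= 1) return(TRUE)
    all(adjm[S, S] | diag(length(S)) > 0)
  }
  # TRUE when every semi-directed path y ~> x avoids-fails: i.e. all such
  # paths intersect S (so the insert creates no cycle).
  blocked <- function(amat, y, x, S) {
    seen <- rep(FALSE, p)
    stack <- y
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v] || v %in% S) next
      seen[v] <- TRUE
      if (v == x) return(FALSE)
      stack <- c(stack, which(amat[v, ]))
    }
    TRUE
  }
  subsets_upto <- function(set, kmax) {
    out <- list(integer(0))
    for (k in seq_len(min(length(set), kmax)))
      out <- c(out, combn_list(set, k))
    out
  }
  # re-close a PDAG to its CPDAG via a consistent extension
  reclose <- function(amat) {
    damat <- pdag_to_dag_amat(amat)
    dag_to_cpdag_amat(amat_to_dag(damat, nodes = nms))
  }

  forward_step <- function(amat) {
    und <- amat & t(amat); adjm <- amat | t(amat)
    pa_of <- lapply(seq_len(p), function(y) which(amat[, y] & !amat[y, ]))
    cands <- list(); diffs <- numeric(0)
    for (y in seq_len(p)) {
      nonadj <- which(!adjm[, y] & seq_len(p) != y)
      ny <- which(und[, y])
      pa <- pa_of[[y]]
      pa_key <- paste(pa, collapse = ",")
      for (x in nonadj) {
        na_yx <- ny[adjm[ny, x]]
        t_pool <- setdiff(ny, c(na_yx, x))
        for (T in subsets_upto(t_pool, max_subset_size)) {
          if (!is_clique(adjm, c(na_yx, T))) next
          base <- sort(unique(c(pa, na_yx, T)))
          key <- paste0("+", y, "|", pa_key, "|", x, "|",
                        paste(c(na_yx, T), collapse = ","))
          d <- cached_diff(key, list(y = y, pa = sort(c(base, x))),
                           list(y = y, pa = base))
          if (d > 1e-10) {
            cands[[length(cands) + 1]] <- list(x = x, y = y, T = T,
                                               S = c(na_yx, T))
            diffs <- c(diffs, d)
          }
        }
      }
    }
    if (!length(cands)) return(NULL)
    for (i in order(-diffs)) {
      op <- cands[[i]]
      if (blocked(amat, op$y, op$x, op$S)) {
        amat[op$x, op$y] <- TRUE
        for (t in op$T) amat[op$y, t] <- FALSE
        return(list(amat = reclose(amat), diff = diffs[i]))
      }
    }
    NULL
  }

  backward_step <- function(amat) {
    und <- amat & t(amat); adjm <- amat | t(amat)
    cands <- list(); diffs <- numeric(0)
    for (y in seq_len(p)) {
      pa <- which(amat[, y] & !amat[y, ])
      pa_key <- paste(pa, collapse = ",")
      ny <- which(und[, y])
      for (x in which(adjm[, y])) {
        if (!(x %in% pa || und[x, y])) next    # x must be parent or neighbor
        na_yx <- ny[adjm[ny, x]]
        for (H in subsets_upto(na_yx, max_subset_size)) {
          keep <- setdiff(na_yx, H)
          if (!is_clique(adjm, keep)) next
          base <- sort(unique(setdiff(c(pa, keep), x)))
          key <- paste0("-", y, "|", pa_key, "|", x, "|",
                        paste(keep, collapse = ","))
          d <- cached_diff(key, list(y = y, pa = base),
                           list(y = y, pa = sort(unique(c(base, x)))))
          if (d > 1e-10) {
            cands[[length(cands) + 1]] <- list(x = x, y = y, H = H)
            diffs <- c(diffs, d)
          }
        }
      }
    }
    if (!length(cands)) return(NULL)
    op <- cands[[which.max(diffs)]]
    amat[op$x, op$y] <- FALSE; amat[op$y, op$x] <- FALSE
    for (h in op$H) {
      amat[h, op$y] <- FALSE                    # orient y -> h
      if (amat[op$x, h] && amat[h, op$x]) amat[h, op$x] <- FALSE  # x -> h
    }
    list(amat = reclose(amat), diff = max(diffs))
  }

  repeat {
    improved <- FALSE
    repeat {
      step <- forward_step(amat)
      if (is.null(step)) break
      amat <- step$amat; improved <- TRUE
    }
    repeat {
      step <- backward_step(amat)
      if (is.null(step)) break
      amat <- step$amat; improved <- TRUE
    }
    if (!improved) break
  }
  new_learned_structure(amat, "ges", list(score = model$kind),
                        score = score_dag(model, cpdag_to_dag(amat, seed = 1)))
}
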