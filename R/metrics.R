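#' Skeleton precision and recall against a ground truth
#'
#' True positives are undirected adjacencies present in both summaries.
#' Empty denominators follow the convention: `TP + FP = 0` gives missing
#' precision, `TP + FN = 0` missing recall; missing values are excluded
#' from downstream aggregation rather than coerced to 0.
#'
#' @param truth,learned `cpdag_summary` objects (or structures coercible by
#'   [extract_cpdag()]) over the same node set.
#' @return list with `precision` and `recall` (each in \[0, 1\] or `NA`).
#' @export
skeleton_pr <- function(truth, learned) {
  truth <- extract_cpdag(truth); learned <- extract_cpdag(learned)
  check_same_nodes(truth, learned)
  pr_from_sets(skeleton_keys(truth), skeleton_keys(learned))
}

#' V-structure precision and recall against a ground truth
#'
#' As [skeleton_pr()] over canonicalized unshielded-collider triples
#' (parent pair sorted).
#'
#' @inheritParams skeleton_pr
#' @export
vstructure_pr <- function(truth, learned) {
  truth <- extract_cpdag(truth); learned <- extract_cpdag(learned)
  check_same_nodes(truth, learned)
  pr_from_sets(vstructure_keys(truth), vstructure_keys(learned))
}

check_same_nodes <- function(a, b) {
  if (!setequal(a$nodes, b$nodes))
    stop("structures are over different node sets")
}

pr_from_sets <- function(true_keys, learned_keys) {
  tp <- length(intersect(true_keys, learned_keys))
  fp <- length(setdiff(learned_keys, true_keys))
  fn <- length(setdiff(true_keys, learned_keys))
  list(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

#' Interventional odds ratio with standard error and CI
#'
#' With `a = P(A = a1 | do(B = b1))`, `c = P(A = a1 | do(B = b2))` and
#' `b, d` their complements, computes `OR = (a/c) / (b/d)`, the Woolf
#' log-scale standard error `SE = sqrt(1/(aN) + 1/(bN) + 1/(cN) + 1/(dN))`,
#' the 95% CI `exp(log(OR) +/- z * SE)`, and the effect category from
#' [classify_or()]. Exact zeros among `a, b, c, d` trigger a Haldane-style
#' continuity adjustment (`+ 0.5/N` on each probability), flagged in the
#' record.
#'
#' @param bn a `discrete_bn` (true or MLE-fitted).
#' @param B intervention node label; `b1`, `b2` its two contrasted levels.
#' @param A target node label; `a1` the target level (vs. rest).
#' @param N training-sample size behind the estimates (>= 1).
#' @param z CI multiplier (default 1.96 for 95%).
#' @return an `odds_ratio_record`.
#' @export
odds_ratio <- function(bn, B, b1, b2, A, a1, N, z = 1.96) {
  stopifnot(b1 != b2, N >= 1)
  iA <- match(A, bn$dag$nodes)
  d1 <- do_distribution(bn, B, b1, A)
  d2 <- do_distribution(bn, B, b2, A)
  a <- d1[a1 + 1L]; b <- 1 - a
  c_ <- d2[a1 + 1L]; d <- 1 - c_
  adjusted <- FALSE
  if (any(c(a, b, c_, d) == 0)) {
    adj <- 0.5 / N
    a <- a + adj; b <- b + adj; c_ <- c_ + adj; d <- d + adj
    adjusted <- TRUE
  }
  or <- (a / c_) / (b / d)
  se <- sqrt(1 / (a * N) + 1 / (b * N) + 1 / (c_ * N) + 1 / (d * N))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  rec <- structure(list(B = B, b1 = b1, b2 = b2, A = A, a1 = a1,
                        a = a, b = b, c = c_, d = d, or_value = or,
                        se = se, ci = ci, N = N, adjusted = adjusted),
                   class = "odds_ratio_record")
  rec$category <- classify_or(rec)
  rec
}

#' Effect category of an odds-ratio record
#'
#' `-1` (protective) when the CI lies entirely below 1, `+1` (detrimental)
#' entirely above 1, `0` (neutral) when the CI contains 1.
#'
#' @param record an `odds_ratio_record` (anything with a `ci` field).
#' @export
classify_or <- function(record) {
  ci <- record$ci
  if (ci[2] < 1) -1L else if (ci[1] > 1) 1L else 0L
}

#' Heuristic intervention target: the node with the most ancestors
#'
#' Ties are broken by node order (first label wins).
#'
#' @param dag a `bn_dag`.
#' @export
select_target <- function(dag) {
  if (length(dag$nodes) == 0) stop("empty DAG")
  counts <- lengths(dag_ancestors(dag))
  dag$nodes[which.max(counts)]
}

#' Enumerate all interventional odds ratios for a target
#'
#' One record per non-target variable `B`, unordered level pair of `B`
#' (stored as `(higher, lower)` code), and target-level-vs-rest dichotomy
#' `a1`; for a binary target only `a1 = 1` is kept (the two dichotomies are
#' reciprocal). Interventions on variables with no directed path to the
#' target reuse the target's plain marginal, so their OR is exactly 1.
#'
#' @param bn a `discrete_bn`.
#' @param target target node label.
#' @param N sample size used for SEs (see [odds_ratio()]).
#' @param fallback_seed seed for the sampling fallback used when exact
#'   elimination exceeds its size guard.
#' @return an `intervention_set`: named list of `odds_ratio_record`s keyed
#'   by `"B:b1:b2:a1"`, with attributes `target` and `N`.
#' @export
enumerate_interventions <- function(bn, target, N, fallback_seed = 1) {
  iA <- match(target, bn$dag$nodes)
  if (is.na(iA)) stop("unknown target")
  rA <- bn$levels[iA]
  a1s <- if (rA == 2) 1L else seq_len(rA) - 1L
  records <- list()
  # one interventional profile per variable, shared across its level pairs
  marginal <- NULL
  for (iB in seq_along(bn$dag$nodes)) {
    if (iB == iA) next
    B <- bn$dag$nodes[iB]
    has_path <- iA %in% dag_descendant_closure(bn$dag, iB)
    rB <- bn$levels[iB]
    dists <- vector("list", rB)
    if (!has_path) {
      # surgery cannot affect a non-descendant: plain marginal, OR exactly 1
      if (is.null(marginal)) {
        marginal <- ve_marginal(bn, iA)
        if (is.null(marginal)) {
          x <- forward_sample(bn, 1e5, fallback_seed)
          marginal <- tabulate(x[, iA] + 1L, nbins = rA) / 1e5
        }
      }
      for (bv in seq_len(rB)) dists[[bv]] <- marginal
    } else {
      prof <- ve_do_profile(bn, iB, iA)
      if (is.null(prof)) {
        for (bv in seq_len(rB) - 1L) {
          x <- sample_mutilated(bn, iB, bv, 1e5,
                                derive_seed(fallback_seed, B, bv))
          dists[[bv + 1L]] <- tabulate(x[, iA] + 1L, nbins = rA) / 1e5
        }
      } else {
        for (bv in seq_len(rB)) dists[[bv]] <- prof[bv, ]
      }
    }
    for (pair in combn_list(seq_len(rB) - 1L, 2)) {
      b1 <- max(pair); b2 <- min(pair)
      for (a1 in a1s) {
        rec <- odds_ratio_from_dists(dists[[b1 + 1L]], dists[[b2 + 1L]],
                                     B, b1, b2, target, a1, N)
        records[[paste(B, b1, b2, a1, sep = ":")]] <- rec
      }
    }
  }
  structure(records, target = target, N = N, class = "intervention_set")
}

# odds_ratio() with the two do-distributions already in hand
odds_ratio_from_dists <- function(d1, d2, B, b1, b2, A, a1, N, z = 1.96) {
  a <- d1[a1 + 1L]; b <- 1 - a
  c_ <- d2[a1 + 1L]; d <- 1 - c_
  adjusted <- FALSE
  if (any(c(a, b, c_, d) == 0)) {
    adj <- 0.5 / N
    a <- a + adj; b <- b + adj; c_ <- c_ + adj; d <- d + adj
    adjusted <- TRUE
  }
  or <- (a / c_) / (b / d)
  se <- sqrt(1 / (a * N) + 1 / (b * N) + 1 / (c_ * N) + 1 / (d * N))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  rec <- structure(list(B = B, b1 = b1, b2 = b2, A = A, a1 = a1,
                        a = a, b = b, c = c_, d = d, or_value = or,
                        se = se, ci = ci, N = N, adjusted = adjusted),
                   class = "odds_ratio_record")
  rec$category <- classify_or(rec)
  rec
}

#' Proportion of correct interventional odds ratios
#'
#' `PCOR(O, O-hat) = sum_i max(f(O_i) * f(O-hat_i), 0) / sum_i f(O_i)^2`
#' over records aligned by key, where `f` is the effect category (-1
#' protective, 0 neutral, 1 detrimental). When the truth has no non-neutral
#' effect the denominator is 0; the score is then 0 with attribute
#' `no_true_effects = TRUE`.
#'
#' @param o_true,o_learned `intervention_set`s with identical keys.
#' @return the PCOR in \[0, 1\].
#' @export
pcor <- function(o_true, o_learned) {
  if (!setequal(names(o_true), names(o_learned)))
    stop("intervention sets have mismatched keys")
  keys <- names(o_true)
  ft <- vapply(o_true[keys], function(r) as.numeric(r$category), numeric(1))
  fl <- vapply(o_learned[keys], function(r) as.numeric(r$category), numeric(1))
  den <- sum(ft^2)
  if (den == 0)
    return(structure(0, no_true_effects = TRUE))
  sum(pmax(ft * fl, 0)) / den
}
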