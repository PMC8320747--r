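#' PC algorithm configuration
#'
#' @param significance_level test level for the conditional-independence
#'   G-test (default 0.05).
#' @param max_condition_size largest conditioning set tried (default 3).
#' @param stable use the order-stable skeleton phase (adjacency sets are
#'   snapshotted per level so results do not depend on processing order;
#'   default TRUE).
#' @param collider_rule `"maxp"` (default): for each unshielded triple the
#'   separating set with the largest test p-value over both adjacency sides
#'   decides the orientation — robust to the arbitrary first-found separator
#'   of the skeleton phase; `"sepset"`: classic orientation from the
#'   recorded separating sets.
#' @return a `pc_config`.
#' @export
pc_config <- function(significance_level = 0.05, max_condition_size = 3,
                      stable = TRUE, collider_rule = c("maxp", "sepset")) {
  collider_rule <- match.arg(collider_rule)
  stopifnot(significance_level > 0, significance_level < 1,
            max_condition_size >= 0)
  structure(list(significance_level = significance_level,
                 max_condition_size = as.integer(max_condition_size),
                 stable = stable, collider_rule = collider_rule),
            class = "pc_config")
}

#' Constraint-based structure learning (PC)
#'
#' Starts from the complete undirected graph and prunes edges by
#' conditional-independence G-tests with growing conditioning sets
#' (order-stable variant), orients unshielded colliders from the recorded
#' separating sets, and closes under the Meek propagation rules.
#' Deterministic given data and configuration, and invariant to column
#' permutation (all iteration is in canonical label order).
#'
#' @param data a `bn_dataset` or integer code matrix (>= 2 rows for a
#'   non-trivial result).
#' @param cfg a [pc_config()].
#' @return a `learned_structure` whose `cpdag` field summarizes the
#'   estimated equivalence class.
#' @export
pc_learn <- function(data, cfg = pc_config()) {
  dm <- as_data_matrix(data)
  p <- ncol(dm$x)
  nms <- colnames(dm$x)
  if (is.null(nms)) nms <- colnames(dm$x) <- paste0("V", seq_len(p) - 1L)
  lab_order <- order(nms)
  empty <- matrix(FALSE, p, p, dimnames = list(nms, nms))
  if (p <= 1 || nrow(dm$x) < 2)
    return(new_learned_structure(empty, "pc", unclass(cfg)))

  lv <- dm$levels
  alpha <- cfg$significance_level
  adj <- matrix(TRUE, p, p, dimnames = list(nms, nms)); diag(adj) <- FALSE
  sepset <- vector("list", p * p)   # sepset[[(x-1)*p + y]]

  g_pvalue <- function(ix, iy, iZ) {
    dof <- (lv[ix] - 1) * (lv[iy] - 1) * prod(lv[iZ])
    if (dof <= 0) return(1)
    g <- 2 * (cat_loglik(dm$x, c(ix, iy, iZ) - 1L, lv) -
                cat_loglik(dm$x, c(ix, iZ) - 1L, lv) -
                cat_loglik(dm$x, c(iy, iZ) - 1L, lv) +
                (if (length(iZ)) cat_loglik(dm$x, iZ - 1L, lv) else 0))
    pchisq(max(g, 0), dof, lower.tail = FALSE)
  }
  g_independent <- function(ix, iy, iZ) g_pvalue(ix, iy, iZ) > alpha

  for (l in 0:cfg$max_condition_size) {
    snapshot <- if (cfg$stable) adj else NULL
    any_candidate <- FALSE
    for (x in lab_order) for (y in lab_order) {
      if (x == y || !adj[x, y] || nms[x] >= nms[y]) next
      for (side in c(x, y)) {
        base <- if (cfg$stable) snapshot else adj
        nbrs <- setdiff(which(base[side, ]), c(x, y))
        nbrs <- nbrs[order(nms[nbrs])]
        if (length(nbrs) < l) next
        any_candidate <- TRUE
        subsets <- if (l == 0) list(integer(0))
                   else combn_list(nbrs, l)
        removed <- FALSE
        for (S in subsets) {
          if (g_independent(x, y, S)) {
            adj[x, y] <- adj[y, x] <- FALSE
            sepset[[(x - 1) * p + y]] <- sepset[[(y - 1) * p + x]] <- S
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
      if (!adj[x, y]) next
    }
    if (!any_candidate && l > 0) break
  }

  # orient unshielded colliders x -> z <- y when z is outside the deciding
  # separating set of (x, y)
  maxp_cache <- new.env(parent = emptyenv())
  maxp_sepset <- function(x, y) {
    key <- paste0(x, ":", y)
    hit <- maxp_cache[[key]]
    if (!is.null(hit)) return(hit$S)
    # the independence-certifying subset with the largest p-value, searched
    # over both adjacency sides at all sizes up to the cap
    best_p <- -1; best_S <- NULL
    for (side in c(x, y)) {
      nbrs <- setdiff(which(adj[side, ]), c(x, y))
      nbrs <- nbrs[order(nms[nbrs])]
      for (l in 0:min(length(nbrs), cfg$max_condition_size)) {
        for (S in if (l == 0) list(integer(0)) else combn_list(nbrs, l)) {
          pv <- g_pvalue(x, y, S)
          if (pv > best_p) { best_p <- pv; best_S <- S }
        }
      }
    }
    out <- if (best_p > alpha) best_S else sepset[[(x - 1) * p + y]]
    maxp_cache[[key]] <- list(S = out)
    out
  }
  amat <- adj
  for (z in lab_order) {
    nb <- which(adj[z, ])
    nb <- nb[order(nms[nb])]
    if (length(nb) < 2) next
    for (k in combn_list(nb, 2)) {
      x <- k[1]; y <- k[2]
      if (adj[x, y]) next
      S <- if (cfg$collider_rule == "maxp") maxp_sepset(x, y)
           else sepset[[(x - 1) * p + y]]
      if (!(z %in% S)) {
        # keep the opposing mark so conflicting triples never delete an edge
        if (amat[x, z]) amat[z, x] <- FALSE
        if (amat[y, z]) amat[z, y] <- FALSE
      }
    }
  }
  amat <- meek_rules(amat)
  new_learned_structure(amat, "pc", unclass(cfg))
}
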