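# CPDAG machinery: equivalence-class summaries (skeleton + V-structures),
# Meek orientation rules, and consistent extension of partially directed
# graphs (Dor-Tarsi).
#
# Partially directed graphs are held as logical "mark" matrices:
# amat[i, j] == TRUE is a mark i -> j; both marks set means an undirected
# edge; exactly one mark set means a directed edge.

#' Skeleton and V-structure summary of a structure
#'
#' The canonical representation of a Markov equivalence class: the set of
#' undirected adjacencies plus the set of unshielded colliders
#' `a -> c <- b` (with `a`, `b` non-adjacent), the parent pair stored in
#' sorted order.
#'
#' @param x a `bn_dag`, a `learned_structure`, or a mark matrix.
#' @return a `cpdag_summary` with fields `nodes`, `skeleton` (two-column
#'   character matrix, pair sorted), `v_structures` (three-column character
#'   matrix: parent, collider, parent; parents sorted).
#' @export
extract_cpdag <- function(x) {
  if (inherits(x, "cpdag_summary")) return(x)
  amat <- if (inherits(x, "bn_dag")) dag_to_amat(x)
          else if (inherits(x, "learned_structure")) x$amat
          else x
  nodes <- colnames(amat)
  p <- ncol(amat)
  adj <- amat | t(amat)
  sk <- which(adj & upper.tri(adj), arr.ind = TRUE)
  skeleton <- cbind(nodes[sk[, 1]], nodes[sk[, 2]], deparse.level = 0)
  vs <- matrix(character(0), ncol = 3)
  dir <- amat & !t(amat)   # strictly directed marks
  for (cld in seq_len(p)) {
    pa <- which(dir[, cld])
    if (length(pa) >= 2) {
      for (k in combn_list(pa, 2))
        if (!adj[k[1], k[2]])
          vs <- rbind(vs, c(nodes[k[1]], nodes[cld], nodes[k[2]]))
    }
  }
  structure(list(nodes = nodes, skeleton = skeleton, v_structures = vs),
            class = "cpdag_summary")
}

#' @export
print.cpdag_summary <- function(x, ...) {
  cat("cpdag_summary:", length(x$nodes), "nodes,", nrow(x$skeleton),
      "skeleton edges,", nrow(x$v_structures), "v-structures\n")
  invisible(x)
}

skeleton_keys <- function(s) {
  if (nrow(s$skeleton) == 0) return(character(0))
  apply(s$skeleton, 1, function(r) paste(sort(r), collapse = "~"))
}

vstructure_keys <- function(s) {
  if (nrow(s$v_structures) == 0) return(character(0))
  apply(s$v_structures, 1, function(r)
    paste(paste(sort(r[c(1, 3)]), collapse = ","), r[2], sep = ">"))
}

# Meek orientation rules R1-R3, applied to a mark matrix until fixed point.
meek_rules <- function(amat) {
  p <- ncol(amat)
  repeat {
    changed <- FALSE
    und <- amat & t(amat)
    dir <- amat & !t(amat)
    adj <- amat | t(amat)
    for (b in seq_len(p)) {
      nb <- which(und[b, ])
      for (c in nb) {
        if (!(amat[b, c] && amat[c, b])) next   # oriented earlier this sweep
        # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
        if (any(dir[, b] & !adj[, c] & seq_len(p) != c)) {
          amat[c, b] <- FALSE; changed <- TRUE; und <- amat & t(amat)
          dir <- amat & !t(amat); next
        }
        # R2: b -> k -> c with b - c  =>  b -> c
        if (any(dir[b, ] & dir[, c])) {
          amat[c, b] <- FALSE; changed <- TRUE; und <- amat & t(amat)
          dir <- amat & !t(amat); next
        }
        # R3: b - a1, b - a2, a1 -> c, a2 -> c, a1 and a2 non-adjacent
        a12 <- which(und[b, ] & dir[, c])
        if (length(a12) >= 2) {
          hit <- FALSE
          for (k in combn_list(a12, 2))
            if (!adj[k[1], k[2]]) { hit <- TRUE; break }
          if (hit) {
            amat[c, b] <- FALSE; changed <- TRUE; und <- amat & t(amat)
            dir <- amat & !t(amat); next
          }
        }
      }
    }
    if (!changed) break
  }
  amat
}

# CPDAG (as a mark matrix) of a DAG: undirected skeleton, V-structure edges
# oriented, Meek closure.
dag_to_cpdag_amat <- function(dag) {
  a <- dag_to_amat(dag)
  adj <- a | t(a)
  cp <- adj  # all edges undirected
  p <- ncol(a)
  for (cld in seq_len(p)) {
    pa <- dag$parents[[cld]]
    if (length(pa) >= 2) {
      for (k in combn_list(pa, 2)) {
        if (!adj[k[1], k[2]]) {
          cp[cld, k[1]] <- FALSE
          cp[cld, k[2]] <- FALSE
        }
      }
    }
  }
  meek_rules(cp)
}

# Consistent extension of a partially directed mark matrix (Dor & Tarsi):
# returns a fully directed mark matrix with the same skeleton and
# V-structures, or signals an error when none exists.
pdag_to_dag_amat <- function(amat) {
  out <- amat & !t(amat)   # keep already-directed marks
  work <- amat
  alive <- rep(TRUE, ncol(amat))
  p <- ncol(amat)
  while (any(alive)) {
    found <- FALSE
    for (x in which(alive)) {
      dir_out <- work[x, ] & !work[, x] & alive
      if (any(dir_out)) next                      # not a sink
      nb_und <- which(work[x, ] & work[, x] & alive)
      adj_x <- which((work[x, ] | work[, x]) & alive)
      ok <- TRUE
      for (y in nb_und) {
        others <- setdiff(adj_x, y)
        if (length(others) &&
            !all(work[y, others] | work[others, y])) { ok <- FALSE; break }
      }
      if (!ok) next
      for (y in nb_und) out[y, x] <- TRUE         # orient y -> x
      alive[x] <- FALSE
      work[x, ] <- FALSE; work[, x] <- FALSE
      found <- TRUE
      break
    }
    if (!found) stop("partially directed graph admits no consistent extension")
  }
  out
}

#' Orient a CPDAG into a member DAG of its equivalence class
#'
#' Undirected edges are oriented without creating cycles or new
#' V-structures (consistent extension). The choice among admissible
#' extensions is randomized by `seed` but deterministic for a fixed seed.
#'
#' @param x a `learned_structure` or mark matrix (CPDAG/PDAG).
#' @param seed integer seed.
#' @return a `bn_dag`.
#' @export
cpdag_to_dag <- function(x, seed = 1) {
  amat <- if (inherits(x, "learned_structure")) x$amat else x
  p <- ncol(amat)
  with_seed(seed, {
    perm <- sample.int(p)          # randomize which extension is picked
    a2 <- amat[perm, perm]
    d2 <- pdag_to_dag_amat(a2)
    inv <- order(perm)
    amat_to_dag(d2[inv, inv], nodes = colnames(amat))
  })
}

# Wrap a mark matrix as a learned structure with provenance.
new_learned_structure <- function(amat, algorithm, config = list(),
                                  score = NA_real_, flags = character(0)) {
  structure(list(amat = amat, nodes = colnames(amat),
                 cpdag = extract_cpdag(amat),
                 provenance = list(algorithm = algorithm, config = config,
                                   score = score, flags = flags)),
            class = "learned_structure")
}

#' @export
print.learned_structure <- function(x, ...) {
  cat("learned_structure (", x$provenance$algorithm, "): ",
      nrow(x$cpdag$skeleton), " skeleton edges, ",
      nrow(x$cpdag$v_structures), " v-structures\n", sep = "")
  invisible(x)
}
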