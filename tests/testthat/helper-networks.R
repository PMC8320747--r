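# Small fixture networks and brute-force oracles, built in code.

# binary chain A -> B -> C with strong (0.9/0.1) conditionals
chain_bn <- function(strength = 0.9) {
  dag <- new_dag(c("A", "B", "C"), list(integer(0), 1L, 2L))
  edge_cpt <- matrix(c(strength, 1 - strength, 1 - strength, strength),
                     2, byrow = TRUE)
  new_discrete_bn(dag, c(2L, 2L, 2L),
                  list(matrix(c(.5, .5), 1), edge_cpt, edge_cpt))
}

# random sparse discrete BN through the package generator
random_bn <- function(p, seed, alpha = 6, avg_levels = 3,
                      type = "ic_dag") {
  dag <- generate_dag(structure_spec(type, p), seed)
  lv <- sample_levels(p, avg_levels, seed + 1)
  populate_cpts(dag, lv, alpha, seed + 2)
}

# all DAGs on the given nodes, as bn_dag objects (3 states per node pair,
# cycle-filtered); 25 DAGs for 3 nodes, 543 for 4
all_dags <- function(nodes) {
  p <- length(nodes)
  pairs <- combn_idx(p)
  out <- list()
  states <- rep(list(0:2), nrow(pairs))
  grid <- do.call(expand.grid, states)
  for (g in seq_len(nrow(grid))) {
    parents <- rep(list(integer(0)), p)
    for (k in seq_len(nrow(pairs))) {
      s <- grid[g, k]
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (s == 1) parents[[j]] <- c(parents[[j]], i)
      if (s == 2) parents[[i]] <- c(parents[[i]], j)
    }
    dag <- tryCatch(new_dag(nodes, parents), error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1]] <- dag
  }
  out
}

combn_idx <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# exhaustive maximum-score DAG over all DAGs on the data's columns
exhaustive_best_dag <- function(data, kind = "bic") {
  model <- score_model(data, kind)
  dags <- all_dags(model$nodes)
  scores <- vapply(dags, function(d) score_dag(model, d), numeric(1))
  dags[[which.max(scores)]]
}

# canonical string of a cpdag_summary, for equality testing
cpdag_signature <- function(x) {
  s <- extract_cpdag(x)
  sk <- apply(s$skeleton, 1, function(r) paste(sort(r), collapse = "~"))
  vs <- if (nrow(s$v_structures)) {
    apply(s$v_structures, 1, function(r)
      paste(paste(sort(r[c(1, 3)]), collapse = ","), r[2], sep = ">"))
  } else character(0)
  paste(c(sort(sk), "|", sort(vs)), collapse = ";")
}

# brute-force log NML normalizing sum by enumerating all r^n sequences
enumerate_regret <- function(n, r) {
  if (n == 0 || r == 1) return(0)
  seqs <- do.call(expand.grid, rep(list(seq_len(r)), n))
  tot <- 0
  for (i in seq_len(nrow(seqs))) {
    cnt <- tabulate(as.integer(seqs[i, ]), nbins = r)
    tot <- tot + prod((cnt[cnt > 0] / n)^cnt[cnt > 0])
  }
  log(tot)
}

# reorder the columns of a bn_dataset (plain matrix out)
unclass_dataset_cols <- function(x, perm) {
  m <- causalsheet:::unclass_dataset(x)
  m[, perm, drop = FALSE]
}

# learner stub that returns the generating truth (fully directed, so the
# MLE refit happens on the true DAG) for self-evaluation runs
oracle_learner <- function(data, seed, truth) {
  causalsheet:::new_learned_structure(
    causalsheet:::dag_to_amat(truth), "oracle")
}
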