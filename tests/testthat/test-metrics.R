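test_that("CPDAG extraction identifies skeletons and unshielded colliders", {
  chain <- new_dag(c("A", "B", "C"), list(integer(0), 1L, 2L))
  s <- extract_cpdag(chain)
  expect_setequal(apply(s$skeleton, 1, paste, collapse = "-"),
                  c("A-B", "B-C"))
  expect_equal(nrow(s$v_structures), 0)

  collider <- new_dag(c("A", "B", "C"), list(integer(0), integer(0),
                                             c(1L, 2L)))
  sc <- extract_cpdag(collider)
  expect_equal(sc$v_structures, matrix(c("A", "C", "B"), 1))

  shielded <- new_dag(c("A", "B", "C"), list(integer(0), 1L, c(1L, 2L)))
  expect_equal(nrow(extract_cpdag(shielded)$v_structures), 0)
})

test_that("Markov-equivalent DAGs share one CPDAG summary (brute force)", {
  for (nodes in list(c("A", "B", "C"), c("A", "B", "C", "D"))) {
    dags <- all_dags(nodes)
    sig <- vapply(dags, cpdag_signature, character(1))
    # oracle equivalence: same skeleton + same colliders <=> same signature
    oracle <- vapply(dags, function(d) {
      sk <- sort(apply(extract_cpdag(d)$skeleton, 1,
                       function(r) paste(sort(r), collapse = "~")))
      vs <- extract_cpdag(d)$v_structures
      vsk <- if (nrow(vs)) sort(apply(vs, 1, paste, collapse = "|"))
             else character(0)
      paste(c(sk, "#", vsk), collapse = ";")
    }, character(1))
    expect_equal(length(unique(sig)), length(unique(oracle)))
    expect_true(all(tapply(oracle, sig, function(v) length(unique(v))) == 1))
  }
})

test_that("precision/recall set arithmetic and missing conventions", {
  t3 <- extract_cpdag(new_dag(c("A", "B", "C"), list(integer(0), 1L, 2L)))
  expect_equal(skeleton_pr(t3, t3), list(precision = 1, recall = 1))
  learned <- extract_cpdag(new_dag(c("A", "B", "C"),
                                   list(integer(0), 1L, 1L)))  # A-B, A-C
  pr <- skeleton_pr(t3, learned)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.5)
  none <- extract_cpdag(new_dag(c("A", "B", "C")))
  pr2 <- skeleton_pr(t3, none)
  expect_true(is.na(pr2$precision))
  expect_equal(pr2$recall, 0)

  vt <- extract_cpdag(new_dag(c("A", "B", "C", "D", "E"),
                              list(integer(0), integer(0), c(1L, 2L),
                                   integer(0), c(3L, 4L))))
  expect_equal(nrow(vt$v_structures), 2)
  half <- extract_cpdag(new_dag(c("A", "B", "C", "D", "E"),
                                list(integer(0), integer(0), c(1L, 2L),
                                     integer(0), integer(0))))
  vpr <- vstructure_pr(vt, half)
  expect_equal(vpr$precision, 1)
  expect_equal(vpr$recall, 0.5)
  empty_both <- vstructure_pr(t3, t3)
  expect_true(is.na(empty_both$precision) && is.na(empty_both$recall))
  expect_error(skeleton_pr(t3, extract_cpdag(new_dag(c("X", "Y")))),
               "different node sets")
})

test_that("do-distributions implement graph surgery correctly", {
  bn <- chain_bn()
  d <- do_distribution(bn, "B", 1L, "C")
  expect_equal(d, c(0.1, 0.9), tolerance = 1e-12)
  # no directed path: intervention equals the marginal
  dm <- do_distribution(bn, "C", 1L, "A")
  expect_equal(dm, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(do_distribution(bn, "A", 0L, "C")), 1, tolerance = 1e-9)
  expect_error(do_distribution(bn, "B", 5L, "C"), "invalid level")
  # when B is a root, do(B=b) equals conditioning on B = b
  for (s in 1:20) {
    bn4 <- random_bn(4, 700 + s, alpha = 6)
    roots <- which(lengths(bn4$dag$parents) == 0)
    others <- setdiff(seq_len(4), roots)
    if (!length(roots) || !length(others)) next
    B <- bn4$dag$nodes[roots[1]]; A <- bn4$dag$nodes[others[1]]
    x <- forward_sample(bn4, 2e5, 800 + s)
    sel <- x[, B] == 0L
    cond <- tabulate(x[sel, A] + 1L, nbins = bn4$levels[others[1]]) /
      sum(sel)
    expect_lt(max(abs(do_distribution(bn4, B, 0L, A) - cond)), 0.02)
  }
})

test_that("odds ratios match hand arithmetic and symmetry", {
  # direct construction: a = 0.8, c = 0.4 -> OR = 6
  bn <- new_discrete_bn(
    new_dag(c("B", "A"), list(integer(0), 1L)), c(2L, 2L),
    list(matrix(c(.5, .5), 1),
         matrix(c(.6, .4, .2, .8), 2, byrow = TRUE)))
  rec <- odds_ratio(bn, "B", 1L, 0L, "A", 1L, 1000)
  expect_equal(rec$or_value, 6, tolerance = 1e-12)
  expect_equal(rec$se, sqrt(1 / 800 + 1 / 200 + 1 / 400 + 1 / 600),
               tolerance = 1e-12)
  expect_equal(rec$ci, exp(log(6) + c(-1, 1) * 1.96 * rec$se),
               tolerance = 1e-12)
  expect_equal(rec$ci, c(4.92, 7.31), tolerance = 0.01)
  expect_equal(rec$category, 1L)
  swapped <- odds_ratio(bn, "B", 0L, 1L, "A", 1L, 1000)
  expect_equal(swapped$or_value, 1 / rec$or_value, tolerance = 1e-12)
  expect_equal(abs(log(swapped$or_value)), abs(log(rec$or_value)),
               tolerance = 1e-12)
  expect_equal(swapped$category, -rec$category)
})

test_that("effect classification follows the CI position", {
  expect_equal(classify_or(list(ci = c(4.92, 7.31))), 1L)
  expect_equal(classify_or(list(ci = c(0.7, 1.3))), 0L)
  expect_equal(classify_or(list(ci = c(0.2, 0.6))), -1L)
})

test_that("target selection maximizes ancestors with stable ties", {
  chain <- new_dag(c("A", "B", "C"), list(integer(0), 1L, 2L))
  expect_equal(select_target(chain), "C")
  edgeless <- new_dag(c("Z", "Q", "M"))
  expect_equal(select_target(edgeless), "Z")
  diamond <- new_dag(c("A", "B", "C", "D"),
                     list(integer(0), 1L, 1L, c(2L, 3L)))
  expect_equal(select_target(diamond), "D")
})

test_that("intervention enumeration counts and no-path neutrality", {
  bn2 <- new_discrete_bn(new_dag(c("A", "B")), c(2L, 2L),
                         list(matrix(c(.5, .5), 1), matrix(c(.3, .7), 1)))
  expect_length(enumerate_interventions(bn2, "A", 100), 1)
  bn3 <- new_discrete_bn(new_dag(c("A", "B")), c(3L, 2L),
                         list(matrix(rep(1 / 3, 3), 1),
                              matrix(c(.3, .7), 1)))
  expect_length(enumerate_interventions(bn3, "A", 100), 3)
  single <- new_discrete_bn(new_dag("A"), 2L, list(matrix(c(.5, .5), 1)))
  expect_length(enumerate_interventions(single, "A", 100), 0)
  # no directed path: OR exactly 1, neutral, for any N
  bn <- chain_bn()
  for (N in c(10, 1e6)) {
    o <- enumerate_interventions(bn, "A", N)
    expect_true(all(vapply(o, function(r) r$or_value == 1, logical(1))))
    expect_true(all(vapply(o, function(r) r$category == 0L, logical(1))))
  }
})

test_that("PCOR identities and hand-enumerated case", {
  bn <- chain_bn()
  o <- enumerate_interventions(bn, "C", 5000)
  expect_true(any(vapply(o, function(r) r$category != 0, logical(1))))
  expect_equal(as.numeric(pcor(o, o)), 1)

  mk <- function(cats) {
    recs <- lapply(cats, function(f)
      structure(list(category = f), class = "odds_ratio_record"))
    names(recs) <- paste0("B", seq_along(cats), ":1:0:1")
    structure(recs, class = "intervention_set")
  }
  # f_true = (1, -1, 0, 1), f_learned = (1, 1, 0, -1): numerator 1, denom 3
  expect_equal(as.numeric(pcor(mk(c(1, -1, 0, 1)), mk(c(1, 1, 0, -1)))),
               1 / 3)
  allneutral <- pcor(mk(c(0, 0)), mk(c(1, -1)))
  expect_equal(as.numeric(allneutral), 0)
  expect_true(attr(allneutral, "no_true_effects"))
  expect_error(pcor(mk(c(1, 0)), mk(c(1, 0, 1))), "mismatched keys")
  # range property over random category vectors
  set.seed(99)
  for (k in 1:25) {
    ft <- sample(c(-1, 0, 1), 6, TRUE); fl <- sample(c(-1, 0, 1), 6, TRUE)
    v <- as.numeric(pcor(mk(ft), mk(fl)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("self-evaluation with an oracle learner is perfect", {
  for (s in 1:50) {
    bn <- random_bn(5, 1200 + 3 * s, alpha = 6)
    truth <- extract_cpdag(bn$dag)
    learned <- oracle_learner(NULL, 0, bn$dag)
    sk <- skeleton_pr(truth, learned$cpdag)
    vs <- vstructure_pr(truth, learned$cpdag)
    expect_true(is.na(sk$precision) || sk$precision == 1)
    expect_true(is.na(sk$recall) || sk$recall == 1)
    expect_true(is.na(vs$precision) || vs$precision == 1)
    o <- enumerate_interventions(bn, select_target(bn$dag), 1000)
    p <- pcor(o, o)
    expect_true(as.numeric(p) == 1 ||
                  (as.numeric(p) == 0 && isTRUE(attr(p, "no_true_effects"))))
  }
})
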