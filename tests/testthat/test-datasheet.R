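small_grid <- function(...) {
  experiment_grid("collection", variables = 6, samples = 400,
                  avg_levels = 3, alpha = 6, structure_types = "ic_dag",
                  trials = 2, master_seed = 7, ...)
}

test_that("run_trial executes the full pipeline per algorithm", {
  grid <- small_grid(algorithms = list(oracle = oracle_learner,
                                       pc = function(data, seed, truth)
                                         pc_learn(data),
                                       ges = function(data, seed, truth)
                                         ges_learn(data)))
  rows <- run_trial(grid, 6L, 400L, "ic_dag", 1L)
  expect_equal(nrow(rows), 3)                       # one row per algorithm
  oracle <- rows[rows$algorithm == "oracle", ]
  expect_equal(oracle$skeleton_precision, 1)
  expect_equal(oracle$skeleton_recall, 1)
  # parameters are refit from the finite sample, so OR categories near
  # their CI boundary may flip; structure-true self-evaluation must still
  # score (near-)perfectly or be flagged as having no true effects
  expect_true(oracle$pcor >= 0.8 ||
                (oracle$pcor == 0 && oracle$pcor_no_true_effects))
  again <- run_trial(grid, 6L, 400L, "ic_dag", 1L)
  expect_identical(rows, again)                     # determinism contract
})

test_that("failing learners are flagged without aborting the run", {
  grid <- small_grid(algorithms = list(
    boom = function(data, seed, truth) stop("deliberate failure"),
    oracle = oracle_learner))
  rows <- run_trial(grid, 6L, 400L, "ic_dag", 1L)
  expect_equal(nrow(rows), 2)
  expect_true(is.na(rows$skeleton_precision[rows$algorithm == "boom"]))
  expect_match(rows$error[rows$algorithm == "boom"], "deliberate")
  expect_false(is.na(rows$skeleton_precision[rows$algorithm == "oracle"]))
})

test_that("run_grid enumerates the full factorial and counts pairs", {
  grid <- experiment_grid("collection", variables = c(4, 5),
                          samples = c(100, 200), avg_levels = 2, alpha = 6,
                          structure_types = c("ic_dag", "small_world"),
                          trials = 2, algorithms = list(oracle = oracle_learner),
                          master_seed = 3)
  sz <- grid_size(grid)
  expect_equal(sz$configurations, 8)
  expect_equal(sz$generated_pairs, 16)
  res <- run_grid(grid)
  expect_equal(nrow(res), 16)
  expect_equal(attr(res, "generated_pairs"), 16)
  # generation-only run
  gen <- experiment_grid("collection", variables = 4, samples = 100,
                         avg_levels = 2, alpha = 6,
                         structure_types = "ic_dag", trials = 3,
                         algorithms = character(0), master_seed = 3)
  res0 <- run_grid(gen)
  expect_equal(nrow(res0), 0)
  expect_equal(attr(res0, "generated_pairs"), 3)
})

test_that("grid runs resume from a results file", {
  grid <- small_grid(algorithms = list(oracle = oracle_learner))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  full <- run_grid(grid)
  res1 <- run_grid(grid, results_file = f)
  expect_equal(nrow(read.csv(f)), nrow(full))
  res2 <- run_grid(grid, results_file = f)       # everything already done
  expect_equal(nrow(res2), nrow(full))
  expect_equal(attr(res2, "generated_pairs"), attr(full, "generated_pairs"))
})

test_that("aggregation reproduces quantile arithmetic and formatting", {
  mk <- function(vals) {
    data.frame(variables = 10L, samples = 100L, structure_type = "ic_dag",
               trial = seq_along(vals), algorithm = "pc",
               skeleton_precision = vals, skeleton_recall = vals,
               v_precision = vals, v_recall = vals, pcor = vals,
               pcor_no_true_effects = FALSE, error = NA_character_,
               seed = 1L)
  }
  cells <- aggregate_results(mk(c(0, 1)))
  pcor_cell <- cells[cells$metric == "pcor", ]
  expect_equal(pcor_cell$median, 0.5)
  expect_equal(pcor_cell$iqr, 0.5)
  expect_equal(pcor_cell$cell, "0.50 (0.50)")
  one <- aggregate_results(mk(0.7))
  expect_equal(one$cell[one$metric == "pcor"], "0.70 (0.00)")
  expect_equal(aggregate_results(mk(c(0.86, NA)))$n[1], 1)
  # independent quantile oracle on random value sets
  set.seed(12)
  for (k in 1:100) {
    vals <- runif(sample(3:12, 1))
    got <- aggregate_results(mk(vals))
    got <- got[got$metric == "pcor", ]
    expect_equal(got$median, as.numeric(quantile(vals, 0.5, type = 7)))
    expect_equal(got$iqr,
                 as.numeric(diff(quantile(vals, c(0.25, 0.75), type = 7))))
  }
  # row order invariance
  r <- mk(runif(8)); rs <- r[sample(8), ]
  expect_equal(aggregate_results(r), aggregate_results(rs))
})

test_that("example aggregate cell renders in the m.mm (i.ii) format", {
  cells <- aggregate_results(data.frame(
    variables = 30L, samples = 5000L, structure_type = "ic_dag",
    trial = 1:5, algorithm = "pc",
    skeleton_precision = 1, skeleton_recall = 1,
    v_precision = c(0.60, 0.70, 0.86, 0.94, 1.00), v_recall = 1,
    pcor = 1, pcor_no_true_effects = FALSE, error = NA_character_,
    seed = 1L))
  expect_equal(cells$cell[cells$metric == "v_precision"], "0.86 (0.24)")
})

test_that("recommendations honor the PCOR threshold and IQR cap", {
  mk_cells <- function(med, iqr, samples, vars = 30L) {
    data.frame(variables = vars, samples = samples, algorithm = "pc",
               metric = "pcor", median = med, iqr = iqr,
               n = 10L, cell = "")
  }
  good <- rbind(mk_cells(0.9, 0.1, 1000L), mk_cells(0.95, 0.1, 2000L))
  rec <- recommend(good, 0.8)
  expect_equal(rec$sample_size$recommended_samples, 1000L)
  expect_equal(rec$sample_size$verdict, "recommended")
  bad <- rbind(mk_cells(0.5, 0.1, 1000L), mk_cells(0.6, 0.1, 2000L))
  rec2 <- recommend(bad, 0.8)
  expect_equal(rec2$sample_size$verdict, "insufficient")
  # high IQR disqualifies even above-threshold medians
  wobbly <- mk_cells(0.9, 0.6, 1000L)
  expect_equal(recommend(wobbly, 0.8)$sample_size$verdict, "insufficient")
  # variable-reduction alternative at the smallest sample size
  multi <- rbind(mk_cells(0.9, 0.1, 1000L, vars = 20L),
                 mk_cells(0.5, 0.1, 1000L, vars = 40L))
  expect_equal(recommend(multi, 0.8)$variable_reduction$max_qualifying_variables,
               20L)
})

test_that("dataset characterization reads observable properties", {
  x <- as_dataset(cbind(A = rep(0:1, length.out = 5),
                        B = rep(0:2, length.out = 5),
                        C = c(0L, 1L, 2L, 3L, 0L)))
  ch <- characterize_dataset(x)
  expect_equal(ch$p, 3)
  expect_equal(ch$n, 5)
  expect_equal(ch$avg_levels, 3)
  const <- characterize_dataset(cbind(A = rep(0L, 4), B = rep(0:1, 2)))
  expect_equal(const$constant_columns, "A")
  expect_error(characterize_dataset(cbind(A = integer(0))), "empty")
})

test_that("datasheets render deterministically with mode-specific sections", {
  grid <- small_grid(algorithms = list(oracle = oracle_learner))
  res <- run_grid(grid)
  report <- build_datasheet(grid, res)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  render_datasheet(report, d1)
  md <- readLines(file.path(d1, "report.md"))
  expect_true(any(grepl("^## Recommendations", md)))
  expect_true(any(grepl("^## Proportion of Correct Odds Ratios", md)))
  expect_true(any(grepl("^## Skeleton Precision and Recall", md)))
  expect_true(any(grepl("^## V-structure Precision and Recall", md)))
  render_datasheet(report, d2)
  expect_identical(md, readLines(file.path(d2, "report.md")))
  expect_true(file.exists(file.path(d1, "tables.json")))
  expect_true(file.exists(file.path(d1, "pivot_pcor.csv")))
  expect_true(file.exists(file.path(d1, "results_long.csv")))

  grid_ex <- experiment_grid("existing", variables = 6, samples = 400,
                             avg_levels = 3, alpha = 6,
                             structure_types = "ic_dag", trials = 2,
                             algorithms = list(oracle = oracle_learner),
                             master_seed = 7)
  rep_ex <- build_datasheet(grid_ex, run_grid(grid_ex), similarity = 0.93)
  d3 <- file.path(tempdir(), "ds3")
  on.exit(unlink(d3, recursive = TRUE), add = TRUE)
  render_datasheet(rep_ex, d3)
  md3 <- readLines(file.path(d3, "report.md"))
  expect_true(any(grepl("^## Improving with More Samples", md3)))
  expect_true(any(grepl("^## Improving with Less Variables", md3)))
  expect_true(any(grepl("similarity", md3)))
})

test_that("existing-data grids expand the observed characteristics", {
  chars <- list(p = 40, n = 5000, avg_levels = 3)
  grid <- existing_data_grid(chars, alpha = 20, trials = 1,
                             algorithms = "pc")
  expect_equal(grid$variables, c(40L, 30L, 20L, 10L))
  expect_equal(grid$samples, c(5000L, 7500L, 10000L, 12500L))
  expect_equal(grid$mode, "existing")
})
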