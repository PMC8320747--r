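#' Define an experiment grid for datasheet generation
#'
#' Describes the full factorial experiment behind a causal datasheet: every
#' combination of variable count, sample size and structure type is
#' generated `trials` times, each learned by every requested algorithm and
#' scored against its generating truth.
#'
#' @param mode `"collection"` (planned survey: variables and samples are
#'   ranges to explore) or `"existing"` (characteristics observed from a
#'   dataset, expanded with the improve-with-more-samples /
#'   fewer-variables pattern).
#' @param variables integer vector of variable counts.
#' @param samples integer vector of sample sizes.
#' @param avg_levels mean category count per variable (>= 2; levels are
#'   drawn uniformly on `{2, ..., 2*avg_levels - 2}`).
#' @param alpha global CPT imbalance (Dirichlet normalization `alpha/(r q)`).
#' @param structure_types character subset of the five generator families.
#' @param max_in_degree parent cap (default uncapped).
#' @param trials repetitions per configuration.
#' @param algorithms character vector among `"pc"`, `"ges"`,
#'   `"ordermcmc-bic"`, `"ordermcmc-qnml"`, or a named list of learner
#'   functions `f(data, seed, truth)` returning a `learned_structure`.
#' @param master_seed master seed; all child seeds derive from it.
#' @param pcor_threshold user PCOR requirement driving [recommend()].
#' @param iqr_cap maximum acceptable PCOR IQR for a recommendation
#'   (default 0.40).
#' @param learner_options optional list of per-algorithm configs:
#'   `pc` (a [pc_config()]), `ges` (score name), `ordermcmc` (argument list
#'   for [order_mcmc_config()], seed and score filled per trial).
#' @param interventional evaluate interventional performance (PCOR) in
#'   addition to the structural metrics; disable for structural-only
#'   experiments (default TRUE).
#' @return an `experiment_grid`.
#' @export
experiment_grid <- function(mode = c("collection", "existing"),
                            variables, samples, avg_levels = 3, alpha = 20,
                            structure_types = c("forest_fire",
                                                "barabasi_albert", "ic_dag",
                                                "waxman", "small_world"),
                            max_in_degree = Inf, trials = 10,
                            algorithms = c("pc", "ges"),
                            master_seed = 1, pcor_threshold = 0.8,
                            iqr_cap = 0.40, learner_options = list(),
                            interventional = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(variables) >= 1, length(samples) >= 1,
            length(structure_types) >= 1, trials >= 1)
  structure(list(mode = mode, variables = as.integer(variables),
                 samples = as.integer(samples), avg_levels = avg_levels,
                 alpha = alpha, structure_types = structure_types,
                 max_in_degree = max_in_degree, trials = as.integer(trials),
                 algorithms = algorithms, master_seed = as.integer(master_seed),
                 pcor_threshold = pcor_threshold, iqr_cap = iqr_cap,
                 learner_options = learner_options,
                 interventional = interventional),
            class = "experiment_grid")
}

#' Planned run counts of a grid
#'
#' @param grid an [experiment_grid()].
#' @return list with `configurations` (property combinations),
#'   `generated_pairs` (BN/dataset pairs = configurations x trials) and
#'   `metric_rows` (pairs x algorithms).
#' @export
grid_size <- function(grid) {
  cfg <- length(grid$variables) * length(grid$samples) *
    length(grid$structure_types)
  n_alg <- if (is.list(grid$algorithms)) length(grid$algorithms)
           else length(grid$algorithms)
  list(configurations = cfg,
       generated_pairs = cfg * grid$trials,
       metric_rows = cfg * grid$trials * n_alg)
}

# resolve the algorithm spec to a named list of f(data, seed, truth)
resolve_learners <- function(grid) {
  spec <- grid$algorithms
  opts <- grid$learner_options
  if (is.list(spec) && !is.null(names(spec))) return(spec)
  built <- list(
    "pc" = function(data, seed, truth)
      pc_learn(data, if (is.null(opts$pc)) pc_config() else opts$pc),
    "ges" = function(data, seed, truth)
      ges_learn(data, if (is.null(opts$ges)) "bic" else opts$ges),
    "ordermcmc-bic" = function(data, seed, truth)
      order_mcmc_learn(data, do.call(order_mcmc_config, utils::modifyList(
        c(list(score = "bic", seed = seed)),
        if (is.null(opts$ordermcmc)) list() else opts$ordermcmc))),
    "ordermcmc-qnml" = function(data, seed, truth)
      order_mcmc_learn(data, do.call(order_mcmc_config, utils::modifyList(
        c(list(score = "qnml", seed = seed)),
        if (is.null(opts$ordermcmc)) list() else opts$ordermcmc))))
  unknown <- setdiff(spec, names(built))
  if (length(unknown)) stop("unknown algorithm(s): ",
                            paste(unknown, collapse = ", "))
  built[spec]
}

trial_metric_names <- c("skeleton_precision", "skeleton_recall",
                        "v_precision", "v_recall", "pcor")

empty_trial_frame <- function() {
  data.frame(variables = integer(0), samples = integer(0),
             structure_type = character(0), trial = integer(0),
             algorithm = character(0),
             skeleton_precision = numeric(0), skeleton_recall = numeric(0),
             v_precision = numeric(0), v_recall = numeric(0),
             pcor = numeric(0), pcor_no_true_effects = logical(0),
             error = character(0), seed = integer(0))
}

#' Run one generation/learn/evaluate trial
#'
#' Executes the full pipeline for one configuration cell and trial index:
#' generate a DAG of the requested structure type, sample per-variable
#' levels, populate CPTs (`alpha` normalization), draw the synthetic
#' dataset, then for every algorithm learn a structure, fit parameters by
#' MLE on a consistent DAG extension, and score skeleton/V-structure
#' precision-recall plus PCOR against the generating truth (target =
#' maximum-ancestors node of the true DAG). A failing learner yields a row
#' of missing metrics with an error flag; the run continues.
#'
#' @param grid an [experiment_grid()].
#' @param n_vars,n_samples,structure_type,trial cell coordinates.
#' @return data.frame with one row per algorithm (zero rows when the grid
#'   lists no algorithms - a generation-only run).
#' @export
run_trial <- function(grid, n_vars, n_samples, structure_type, trial) {
  ms <- grid$master_seed
  sd_dag <- derive_seed(ms, n_vars, n_samples, structure_type, trial, "dag")
  sd_lev <- derive_seed(ms, n_vars, n_samples, structure_type, trial, "levels")
  sd_cpt <- derive_seed(ms, n_vars, n_samples, structure_type, trial, "cpt")
  sd_smp <- derive_seed(ms, n_vars, n_samples, structure_type, trial, "sample")

  spec <- structure_spec(structure_type, n_vars,
                         max_in_degree = grid$max_in_degree)
  dag <- generate_dag(spec, sd_dag)
  levels <- sample_levels(n_vars, grid$avg_levels, sd_lev)
  bn <- populate_cpts(dag, levels, grid$alpha, sd_cpt)
  data <- forward_sample(bn, n_samples, sd_smp)

  learners <- resolve_learners(grid)
  if (length(learners) == 0) return(empty_trial_frame())

  truth <- extract_cpdag(dag)
  target <- select_target(dag)
  interventional <- !isFALSE(grid$interventional)
  o_true <- if (interventional)
    enumerate_interventions(bn, target, N = n_samples) else NULL

  rows <- lapply(names(learners), function(alg) {
    sd_alg <- derive_seed(ms, n_vars, n_samples, structure_type, trial, alg)
    res <- tryCatch({
      learned <- learners[[alg]](data, sd_alg, dag)
      sk <- skeleton_pr(truth, learned$cpdag)
      vs <- vstructure_pr(truth, learned$cpdag)
      if (interventional) {
        dag_l <- cpdag_to_dag(learned, seed = sd_alg)
        bn_l <- mle_fit(dag_l, data, levels)
        o_l <- enumerate_interventions(bn_l, target, N = n_samples)
        pc <- pcor(o_true, o_l)
      } else {
        pc <- NA_real_
      }
      list(sk = sk, vs = vs, pcor = as.numeric(pc),
           noeff = isTRUE(attr(pc, "no_true_effects")), err = NA_character_)
    }, error = function(e) {
      list(sk = list(precision = NA_real_, recall = NA_real_),
           vs = list(precision = NA_real_, recall = NA_real_),
           pcor = NA_real_, noeff = NA, err = conditionMessage(e))
    })
    data.frame(variables = n_vars, samples = n_samples,
               structure_type = structure_type, trial = trial,
               algorithm = alg,
               skeleton_precision = res$sk$precision,
               skeleton_recall = res$sk$recall,
               v_precision = res$vs$precision,
               v_recall = res$vs$recall,
               pcor = res$pcor, pcor_no_true_effects = res$noeff,
               error = res$err, seed = sd_alg)
  })
  do.call(rbind, rows)
}

#' Run a whole experiment grid
#'
#' Iterates all `(variables, samples, structure_type, trial)` cells with
#' derived child seeds. When `results_file` is given, completed rows are
#' appended to it after every trial and already-present cells are skipped
#' on restart (resumable runs).
#'
#' @param grid an [experiment_grid()].
#' @param results_file optional CSV path for append-only persistence.
#' @param verbose print one line per trial to stderr.
#' @return data.frame of trial results; attribute `generated_pairs` counts
#'   the BN/dataset pairs generated in this call plus any resumed ones.
#' @export
run_grid <- function(grid, results_file = NULL, verbose = FALSE) {
  done <- NULL
  if (!is.null(results_file) && file.exists(results_file)) {
    done <- read.csv(results_file, stringsAsFactors = FALSE)
  }
  all_rows <- if (is.null(done)) list() else list(done)
  generated <- 0L
  for (v in grid$variables) for (s in grid$samples)
    for (st in grid$structure_types) for (tr in seq_len(grid$trials)) {
      if (!is.null(done) &&
          any(done$variables == v & done$samples == s &
                done$structure_type == st & done$trial == tr)) next
      t0 <- proc.time()[3]
      rows <- run_trial(grid, v, s, st, tr)
      generated <- generated + 1L
      if (verbose)
        message(sprintf("p=%d n=%d %s trial %d: %.1fs", v, s, st, tr,
                        proc.time()[3] - t0))
      if (nrow(rows) && !is.null(results_file)) {
        new_file <- !file.exists(results_file)
        write.table(rows, results_file, sep = ",", row.names = FALSE,
                    col.names = new_file, append = !new_file)
      }
      all_rows[[length(all_rows) + 1]] <- rows
    }
  out <- do.call(rbind, all_rows)
  if (is.null(out) || nrow(out) == 0) out <- empty_trial_frame()
  n_resumed <- if (is.null(done)) 0L else
    length(unique(paste(done$variables, done$samples, done$structure_type,
                        done$trial)))
  attr(out, "generated_pairs") <- generated + n_resumed
  out
}

#' Aggregate trial metrics into median/IQR cells
#'
#' Per `(variables, samples, algorithm)` cell and metric: median, IQR
#' (`Q3 - Q1`, linear-interpolation quantiles) and the count of non-missing
#' values, pooled across structure types and trials (stratify with
#' `by_structure = TRUE`). Missing metrics are excluded, not zero-filled.
#'
#' @param results trial results from [run_grid()].
#' @param by_structure additionally stratify by structure type.
#' @return data.frame with columns `variables`, `samples`, `algorithm`,
#'   (`structure_type`,) `metric`, `median`, `iqr`, `n`, `cell` (the
#'   rendered `"m.mm (i.ii)"` string).
#' @export
aggregate_results <- function(results, by_structure = FALSE) {
  stopifnot(nrow(results) > 0)
  keys <- c("variables", "samples", "algorithm",
            if (by_structure) "structure_type")
  out <- list()
  grp <- interaction(results[keys], drop = TRUE)
  for (g in levels(grp)) {
    sub <- results[grp == g, ]
    for (m in trial_metric_names) {
      vals <- sub[[m]][!is.na(sub[[m]])]
      row <- sub[1, keys, drop = FALSE]
      row$metric <- m
      if (length(vals)) {
        qs <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        row$median <- qs[2]; row$iqr <- qs[3] - qs[1]; row$n <- length(vals)
        row$cell <- sprintf("%.2f (%.2f)", qs[2], qs[3] - qs[1])
      } else {
        row$median <- NA_real_; row$iqr <- NA_real_; row$n <- 0L
        row$cell <- ""
      }
      out[[length(out) + 1]] <- row
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$variables, out$samples, out$algorithm, out$metric), ]
}

#' Sample-size and variable-count recommendations
#'
#' For every variable count and algorithm, the smallest tested sample size
#' whose median PCOR meets the threshold with IQR at most `iqr_cap`; when
#' none qualifies the verdict is `"insufficient"`. Also reports, per
#' algorithm at the smallest tested sample size, the largest variable count
#' that qualifies (the reduce-variables alternative).
#'
#' @param cells aggregated cells from [aggregate_results()].
#' @param pcor_threshold required median PCOR.
#' @param iqr_cap maximum acceptable PCOR IQR (default 0.40).
#' @return list with data.frames `sample_size` and `variable_reduction`.
#' @export
recommend <- function(cells, pcor_threshold, iqr_cap = 0.40) {
  pc <- cells[cells$metric == "pcor" & !is.na(cells$median), ]
  pc$ok <- pc$median >= pcor_threshold & pc$iqr <= iqr_cap
  samp <- list()
  for (v in sort(unique(pc$variables))) for (a in sort(unique(pc$algorithm))) {
    sub <- pc[pc$variables == v & pc$algorithm == a, ]
    if (!nrow(sub)) next
    ok <- sub[sub$ok, ]
    samp[[length(samp) + 1]] <- data.frame(
      variables = v, algorithm = a,
      recommended_samples = if (nrow(ok)) min(ok$samples) else NA_integer_,
      verdict = if (nrow(ok)) "recommended" else "insufficient")
  }
  redu <- list()
  n_min <- min(pc$samples)
  for (a in sort(unique(pc$algorithm))) {
    sub <- pc[pc$samples == n_min & pc$algorithm == a & pc$ok, ]
    redu[[length(redu) + 1]] <- data.frame(
      algorithm = a, samples = n_min,
      max_qualifying_variables = if (nrow(sub)) max(sub$variables)
                                 else NA_integer_)
  }
  list(sample_size = do.call(rbind, samp),
       variable_reduction = do.call(rbind, redu))
}

#' Observable characteristics of a categorical dataset
#'
#' @param table a `bn_dataset`, integer code matrix, or data.frame of codes.
#' @return list with `p` (columns), `n` (rows), `avg_levels` (mean observed
#'   cardinality) and `cardinalities`; constant columns (cardinality 1) are
#'   flagged in `constant_columns` for user override.
#' @export
characterize_dataset <- function(table) {
  dm <- as_data_matrix(table)
  if (nrow(dm$x) == 0) stop("empty dataset")
  card <- apply(dm$x, 2, function(col) length(unique(col)))
  list(p = ncol(dm$x), n = nrow(dm$x), avg_levels = mean(card),
       cardinalities = as.integer(card),
       constant_columns = colnames(dm$x)[card == 1])
}

#' Default grid for an existing dataset
#'
#' Expands the observed characteristics with the improve-with-more-samples
#' pattern (`n x {1, 1.5, 2, 2.5}`) and improve-with-fewer-variables
#' pattern (`p x {1, 3/4, 1/2, 1/4}`, rounded).
#'
#' @param chars output of [characterize_dataset()].
#' @param ... further arguments to [experiment_grid()].
#' @export
existing_data_grid <- function(chars, ...) {
  experiment_grid(mode = "existing",
                  variables = unique(pmax(1L, as.integer(round(
                    chars$p * c(1, 3 / 4, 1 / 2, 1 / 4))))),
                  samples = unique(as.integer(round(
                    chars$n * c(1, 1.5, 2, 2.5)))),
                  avg_levels = max(2, chars$avg_levels), ...)
}

#' Assemble a datasheet report
#'
#' @param grid the [experiment_grid()] that produced `results`.
#' @param results trial results from [run_grid()].
#' @param similarity optional [dataset_similarity()] score (existing mode).
#' @return a `datasheet_report` holding the configuration echo, aggregated
#'   cells, recommendations, raw (violin-ready) results and provenance.
#' @export
build_datasheet <- function(grid, results, similarity = NULL) {
  cells <- aggregate_results(results)
  recs <- recommend(cells, grid$pcor_threshold, grid$iqr_cap)
  structure(list(mode = grid$mode, grid = grid, cells = cells,
                 recommendations = recs, results = results,
                 similarity = similarity,
                 provenance = list(master_seed = grid$master_seed,
                                   generated_pairs =
                                     attr(results, "generated_pairs"))),
            class = "datasheet_report")
}

pivot_lines <- function(cells, metric) {
  sub <- cells[cells$metric == metric, ]
  samp <- sort(unique(sub$samples))
  hdr <- paste(c("Variables", "Algorithm", format(samp)), collapse = " | ")
  sep <- paste(rep("---", length(samp) + 2), collapse = " | ")
  body <- character(0)
  for (v in sort(unique(sub$variables)))
    for (a in sort(unique(sub$algorithm))) {
      row <- sub[sub$variables == v & sub$algorithm == a, ]
      vals <- vapply(samp, function(s) {
        hit <- row$cell[row$samples == s]
        if (length(hit)) hit else ""
      }, character(1))
      body <- c(body, paste(c(v, a, vals), collapse = " | "))
    }
  c(paste("|", hdr, "|"), paste("|", sep, "|"), paste("|", body, "|"))
}

#' Render a datasheet to files
#'
#' Writes, deterministically: `report.md` (the datasheet, with the
#' mode-appropriate section order), `tables.json` (all aggregated cells and
#' recommendations), one pivot CSV per metric, and `results_long.csv`
#' (violin-plot-ready raw metric values).
#'
#' @param report a [build_datasheet()] report.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
render_datasheet <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- report$cells
  md <- c(paste0("# Causal Datasheet (",
                 if (report$mode == "collection") "Data Collection"
                 else "Existing Dataset", ")"), "")
  md <- c(md, "## Configuration", "",
          paste0("- Variables: ", paste(report$grid$variables, collapse = ", ")),
          paste0("- Samples: ", paste(report$grid$samples, collapse = ", ")),
          paste0("- Average levels: ", report$grid$avg_levels),
          paste0("- Alpha (imbalance): ", report$grid$alpha),
          paste0("- Structure types: ",
                 paste(report$grid$structure_types, collapse = ", ")),
          paste0("- Maximum in-degree: ",
                 if (is.finite(report$grid$max_in_degree))
                   report$grid$max_in_degree else "uncapped"),
          paste0("- Trials: ", report$grid$trials),
          paste0("- Master seed: ", report$grid$master_seed), "")
  if (!is.null(report$similarity))
    md <- c(md, paste0("- Meta-feature similarity to reference dataset: ",
                       sprintf("%.2f", as.numeric(report$similarity))), "")
  md <- c(md, "## Recommendations", "",
          paste0("PCOR threshold ", report$grid$pcor_threshold,
                 ", IQR cap ", report$grid$iqr_cap, "."), "")
  rs <- report$recommendations$sample_size
  if (!is.null(rs)) for (i in seq_len(nrow(rs)))
    md <- c(md, paste0("- ", rs$variables[i], " variables, ", rs$algorithm[i],
                       ": ", if (rs$verdict[i] == "recommended")
                         paste0(rs$recommended_samples[i], " samples")
                       else "not recommended at any tested size"))
  md <- c(md, "")
  section <- function(title, metric_set) {
    out <- c(paste0("## ", title), "")
    for (m in metric_set)
      out <- c(out, paste0("### ", gsub("_", " ", m)), "",
               pivot_lines(cells, m), "")
    out
  }
  if (report$mode == "collection") {
    md <- c(md,
            section("Proportion of Correct Odds Ratios", "pcor"),
            section("Skeleton Precision and Recall",
                    c("skeleton_precision", "skeleton_recall")),
            section("V-structure Precision and Recall",
                    c("v_precision", "v_recall")))
  } else {
    md <- c(md,
            section("Correctness of Causal Effects", "pcor"),
            section("Learning the Skeleton",
                    c("skeleton_precision", "skeleton_recall")),
            section("Learning the Direction",
                    c("v_precision", "v_recall")),
            "## Improving with More Samples", "",
            "See the larger sample-size columns of the pivot tables above.",
            "",
            "## Improving with Less Variables", "",
            "See the smaller variable-count rows of the pivot tables above.",
            "")
  }
  writeLines(md, file.path(dir, "report.md"))
  jsonlite::write_json(
    list(mode = report$mode, cells = cells,
         recommendations = report$recommendations,
         similarity = if (is.null(report$similarity)) NULL
                      else as.numeric(report$similarity),
         provenance = report$provenance),
    file.path(dir, "tables.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  for (m in trial_metric_names) {
    sub <- cells[cells$metric == m, ]
    write.csv(sub[order(sub$variables, sub$algorithm, sub$samples), ],
              file.path(dir, paste0("pivot_", m, ".csv")), row.names = FALSE)
  }
  write.csv(report$results, file.path(dir, "results_long.csv"),
            row.names = FALSE)
  invisible(dir)
}
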