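#' Configure the end-to-end optimization pipeline
#'
#' Bundles every stage's settings: the central composite design, the
#' synthetic release model (or a path to measured data), the data split,
#' training limits, the hidden-node sweep and the brute-force search
#' grid. One global seed drives all randomness; each stage derives its
#' own seed from it by a fixed counter scheme, so a configuration fully
#' determines the run.
#'
#' @param ccd A [ccd_spec()].
#' @param release_model A [release_model_params()] used to simulate the
#'   study and the reference profile, or `NULL` if `dataset_path` points
#'   to measured data.
#' @param dataset_path Optional path to a measured-dissolution dataset
#'   (CSV, see [read_dataset()]); overrides the synthetic study.
#' @param reference Either a [dissolution_profile()] to match, or a
#'   [formulation()] at which the synthetic reference is generated
#'   (default: 45 mg HPMC, 30 mg xanthan, 5 mg Carbopol, 10% Surelease).
#' @param split A [split_spec()] (its seed is derived from `seed`).
#' @param limits A [train_limits()].
#' @param sweep_candidates Hidden-node counts for the architecture
#'   sweep (default 3:10).
#' @param sweep_repeats Training repeats per candidate (default 1).
#' @param grid A [search_grid()].
#' @param top_k Runner-up count in the optimization report.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ccd = ccd_spec(),
                            release_model = release_model_params(),
                            dataset_path = NULL,
                            reference = formulation(45, 30, 5, 10),
                            split = split_spec(),
                            limits = train_limits(),
                            sweep_candidates = 3:10,
                            sweep_repeats = 1L,
                            grid = search_grid(),
                            top_k = 10L,
                            seed = 1L) {
  stopifnot(inherits(ccd, "ccd_spec"), inherits(split, "split_spec"),
            inherits(limits, "train_limits"), inherits(grid, "search_grid"))
  if (is.null(dataset_path) && !inherits(release_model, "release_model_params")) {
    stopf("either a release model or a dataset path must be supplied")
  }
  if (length(sweep_candidates) < 1L) stopf("sweep candidate range is empty")
  if (!(inherits(reference, "dissolution_profile") ||
        inherits(reference, "formulation"))) {
    stopf("reference must be a dissolution_profile or a formulation")
  }
  structure(list(ccd = ccd, release_model = release_model,
                 dataset_path = dataset_path, reference = reference,
                 split = split, limits = limits,
                 sweep_candidates = as.integer(sweep_candidates),
                 sweep_repeats = as.integer(sweep_repeats),
                 grid = grid, top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full formulation-optimization pipeline
#'
#' Executes the study workflow end to end: generate the central
#' composite design; obtain dissolution profiles (simulated from the
#' synthetic release model, or read from `dataset_path`); sweep the
#' hidden-layer size on held-out R-squared; retrain the selected
#' architecture on the full corpus; brute-force search the composition
#' domain for the highest f2 against the reference profile. All
#' intermediate artifacts (design, dataset, sweep table, model file,
#' optimization report, run log) are written to `out_dir` so any stage
#' can be rerun in isolation.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing), or `NULL` to
#'   skip writing artifacts.
#' @return A list of class `pipeline_result`: `dataset`, `sweep`, `net`,
#'   `reference`, `optimization`, and `seeds` (the derived stage seeds).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(design = derive_seed(config$seed, 1L),
                study = derive_seed(config$seed, 2L),
                sweep = derive_seed(config$seed, 3L),
                retrain = derive_seed(config$seed, 4L))
  log_lines <- c(sprintf("dissopt pipeline, package version %s",
                         as.character(utils::packageVersion("dissopt"))),
                 sprintf("global seed %d", config$seed))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  design <- stage("design", generate_ccd(config$ccd))
  dataset <- stage("data", {
    if (!is.null(config$dataset_path)) {
      read_dataset(config$dataset_path)
    } else {
      generate_study(config$release_model, design, seed = seeds$study)
    }
  })
  log_lines <- c(log_lines, sprintf("dataset: %d records", length(dataset)))

  sweep <- stage("sweep", node_sweep(dataset,
                                     candidates = config$sweep_candidates,
                                     repeats = config$sweep_repeats,
                                     split = config$split,
                                     limits = config$limits,
                                     seed = seeds$sweep))
  log_lines <- c(log_lines,
                 sprintf("sweep selected %d hidden nodes", sweep$selected))

  net <- stage("retrain", retrain_full(dataset, sweep$selected,
                                       limits = config$limits,
                                       seed = seeds$retrain))

  reference <- stage("reference", {
    if (inherits(config$reference, "dissolution_profile")) {
      config$reference
    } else {
      if (is.null(config$release_model)) {
        stopf("a formulation reference requires a release model")
      }
      make_reference(config$release_model, config$reference)
    }
  })

  opt <- stage("optimize", optimize_formulation(net, reference,
                                                grid = config$grid,
                                                top_k = config$top_k))
  log_lines <- c(log_lines,
                 sprintf("best candidate f2 = %.4f over %d evaluations",
                         opt$f2, opt$n_evaluated))

  result <- structure(list(dataset = dataset, sweep = sweep, net = net,
                           reference = reference, optimization = opt,
                           seeds = seeds),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(design, file.path(out_dir, "design.csv"))
    write_dataset(dataset, file.path(out_dir, "dataset.csv"))
    utils::write.csv(sweep$table, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    write_surrogate(net, file.path(out_dir, "model.json"))
    report <- c(
      list(best = as.list(unclass(opt$best)),
           predicted_profile = list(
             times_h = opt$predicted_profile$times_h,
             release_pct = clip_profile(opt$predicted_profile)$release_pct),
           f2 = opt$f2, n_evaluated = opt$n_evaluated),
      list(top_k = opt$top_k))
    jsonlite::write_json(report, file.path(out_dir, "optimization.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d records, %d hidden nodes selected\n",
              length(x$dataset), x$sweep$selected))
  print(x$optimization)
  invisible(x)
}
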