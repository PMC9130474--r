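#' Configure an end-to-end CTG classification run
#'
#' Exactly one of `input` (a CSV path in the CTG schema) or `synthetic` (a
#' [synthetic_ctg_spec()]) must be given.
#'
#' @param input Path to a CTG CSV, or `NULL`.
#' @param synthetic A `synthetic_ctg_spec`, or `NULL`.
#' @param out_dir Output directory for the run's report files.
#' @param bins Bins per attribute for itemset encoding (default 4).
#' @param mi_threshold Mutual-information filter threshold (default 0.01).
#' @param minsupport Frequent-itemset support threshold (default 0.1).
#' @param sweep_grid Minsupport grid for the reported sweep.
#' @param profile Classifier profile: `"test"` or `"paper"` (Ada-RF scale).
#' @param seed Master seed; stage seeds are derived from it.
#' @param boost_seed Seed of the boosted classifiers (default 25).
#' @return An object of class `ctg_pipeline_config`.
#' @export
ctg_pipeline_config <- function(input = NULL, synthetic = NULL,
                                out_dir = tempfile("ctg_run_"),
                                bins = 4, mi_threshold = 0.01,
                                minsupport = 0.1,
                                sweep_grid = c(0.05, 0.08, 0.1, 0.15, 0.2, 0.3),
                                profile = c("test", "paper"),
                                seed = 1L, boost_seed = 25L) {
  profile <- match.arg(profile)
  if (is.null(input) == is.null(synthetic)) {
    stop("give exactly one input source: `input` or `synthetic`",
         call. = FALSE)
  }
  stopifnot(mi_threshold >= 0, minsupport > 0, minsupport <= 1, bins >= 2)
  structure(list(input = input, synthetic = synthetic, out_dir = out_dir,
                 bins = bins, mi_threshold = mi_threshold,
                 minsupport = minsupport, sweep_grid = sweep_grid,
                 profile = profile, seed = as.integer(seed),
                 boost_seed = as.integer(boost_seed)),
            class = "ctg_pipeline_config")
}

#' Run the full classification pipeline
#'
#' Sequences the method end to end: read or simulate the table, screen
#' attributes (rank screen + mutual-information filter), mine per-class
#' frequent itemsets and fuse the attribute columns ("feature extraction"),
#' benchmark the five classifiers on the three pairwise class combinations
#' with both the raw and the extracted feature sets ("Model 1"), reassign
#' the suspect records by the four-model voting ensemble ("Model 2"), and
#' evaluate the fused two-class dataset against the blanket baselines.
#' All reports are written to `config$out_dir` together with a manifest
#' sufficient to re-run the configuration exactly; identical configurations
#' produce identical outputs.
#'
#' @param config A [ctg_pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory stage results: `table`,
#'   `screen`, `sweep`, `class_sets`, `fused`, `benchmark`, `votes`,
#'   `relabeled`, `evaluation`, `manifest`.
#' @export
run_ctg_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ctg_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ctgfusion] ", ...)

  # stage: input
  synthetic <- NULL
  if (!is.null(config$input)) {
    say("reading ", config$input)
    table <- read_ctg_table(config$input)
  } else {
    say("simulating synthetic CTG table")
    synthetic <- generate_ctg(config$synthetic)
    table <- synthetic$table
  }
  write_ctg_table(table, file.path(config$out_dir, "input_table.csv"))

  # stage: prefilter
  say("screening attributes")
  screen <- screen_features(table, threshold = config$mi_threshold)
  readr::write_csv(screen$report,
                   file.path(config$out_dir, "screen_report.csv"),
                   progress = FALSE)

  # stage: apriori feature selection
  say("mining per-class frequent itemsets (minsupport = ",
      config$minsupport, ")")
  sweep <- support_sweep(table, grid = config$sweep_grid, bins = config$bins,
                         subset = screen$subset)
  readr::write_csv(sweep$counts,
                   file.path(config$out_dir, "support_sweep.csv"),
                   progress = FALSE)
  class_sets <- lapply(c(health = 1L, suspect = 2L, pathologic = 3L),
                       function(cl) {
    class_frequent_attributes(table, cl, minsupport = config$minsupport,
                              bins = config$bins, subset = screen$subset)
  })
  fused <- fuse_attribute_sets(class_sets)
  write_feature_subset(fused, file.path(config$out_dir, "feature_subset.txt"))
  itemsets <- dplyr::bind_rows(lapply(names(class_sets), function(nm) {
    cl <- c(health = 1L, suspect = 2L, pathologic = 3L)[[nm]]
    slice <- table[table$nsp == cl, , drop = FALSE]
    fi <- apriori(encode_transactions(slice, screen$subset, config$bins),
                  config$minsupport)
    dplyr::mutate(tidy.frequent_itemsets(fi), class = nm, .before = 1)
  }))
  readr::write_csv(itemsets,
                   file.path(config$out_dir, "frequent_itemsets.csv"),
                   progress = FALSE)

  # stage: Model 1 benchmark
  say("benchmarking five classifiers on pairwise combinations")
  specs <- default_classifier_specs(profile = config$profile)
  for (nm in c("adaboost", "ada_rf")) specs[[nm]]$seed <- config$boost_seed
  bench <- benchmark_models(
    table, specs = specs,
    subsets = list(raw = feature_subset(1:22, "manual"), extracted = fused),
    train_fraction = 0.75, seed = config$seed
  )
  readr::write_csv(tidy.ctg_benchmark(bench),
                   file.path(config$out_dir, "benchmark.csv"),
                   progress = FALSE)

  # stage: Model 2 reassignment
  say("reassigning suspect records by four-model vote")
  four <- specs[c("knn", "gaussian_nb", "sgd_logistic", "adaboost")]
  votes <- predict_suspects(table, fused, specs = four) |>
    integrate_votes()
  readr::write_csv(votes, file.path(config$out_dir, "votes.csv"),
                   progress = FALSE)
  relabeled <- relabel_suspects(table, votes)
  rl_out <- relabeled$table
  rl_out$original_nsp <- table$nsp
  readr::write_csv(dplyr::rename(rl_out, NSP = "nsp"),
                   file.path(config$out_dir, "relabeled.csv"),
                   progress = FALSE)

  # stage: fused two-class evaluation
  say("evaluating the fused two-class dataset")
  evaluation <- evaluate_fusion(table, votes, fused, spec = specs$ada_rf,
                                seed = config$seed)
  readr::write_csv(evaluation, file.path(config$out_dir, "evaluation.csv"),
                   progress = FALSE)

  manifest <- list(
    package = "ctgfusion",
    version = as.character(utils::packageVersion("ctgfusion")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config_as_list(config),
    n_records = nrow(table),
    label_counts = as.list(table(table$nsp)),
    fused_attributes = fused$attributes,
    sweep_selected = sweep$selected,
    files = c("input_table.csv", "screen_report.csv", "support_sweep.csv",
              "frequent_itemsets.csv", "feature_subset.txt", "benchmark.csv",
              "votes.csv", "relabeled.csv", "evaluation.csv")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done; reports in ", config$out_dir)
  invisible(list(table = table, synthetic = synthetic, screen = screen,
                 sweep = sweep, class_sets = class_sets, fused = fused,
                 benchmark = bench, votes = votes, relabeled = relabeled,
                 evaluation = evaluation, manifest = manifest))
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) {
    sp <- out$synthetic
    out$synthetic <- list(n_per_class = sp$n_per_class,
                          separation = sp$separation,
                          informative_features = sp$informative_features,
                          constant_features = sp$constant_features,
                          suspect_mixture_weight = sp$suspect_mixture_weight,
                          heavy_tails = sp$heavy_tails, seed = sp$seed)
  }
  out
}
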