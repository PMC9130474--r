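#' Split a CTG table into training and test sets
#'
#' Random, optionally label-stratified partition. Under stratification each
#' class contributes `round(train_fraction * n_class)` training records, so
#' every stratum is within one record of the requested fraction. The split
#' is a pure function of the seed.
#'
#' @param table A CTG table.
#' @param train_fraction Fraction of records to train on, in (0, 1).
#' @param seed Integer seed.
#' @param stratified Stratify by the NSP label (default `TRUE`).
#' @return A list with `train` and `test` CTG tables (disjoint; union is the
#'   input).
#' @export
split_train_test <- function(table, train_fraction = 0.75, seed = 1L,
                             stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(table)
  if (stratified) {
    counts <- table(table$nsp)
    if (any(counts < 2)) {
      stop("stratified split needs at least 2 records per class", call. = FALSE)
    }
    train_idx <- unlist(lapply(sort(unique(table$nsp)), function(cl) {
      idx <- which(table$nsp == cl)
      sample(idx, round(train_fraction * length(idx)))
    }))
  } else {
    train_idx <- sample.int(n, round(train_fraction * n))
  }
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE])
}

#' Restrict a CTG table to a pair of classes
#'
#' @param table A CTG table.
#' @param pair Two distinct NSP codes from {1, 2, 3}, e.g. `c(1, 3)` for the
#'   normal-vs-pathologic combination.
#' @return The records of the two classes, in original order.
#' @export
make_pairwise_dataset <- function(table, pair) {
  pair <- sort(unique(as.integer(pair)))
  if (length(pair) != 2 || !all(pair %in% 1:3)) {
    stop("pair must be two distinct classes from {1,2,3}", call. = FALSE)
  }
  absent <- pair[!pair %in% table$nsp]
  if (length(absent) > 0) {
    stop("class ", paste(absent, collapse = ", "), " absent from table",
         call. = FALSE)
  }
  table[table$nsp %in% pair, , drop = FALSE]
}

#' Benchmark classifiers over pairwise class combinations
#'
#' "Model 1": for every (classifier, class pair, feature set) combination,
#' restricts the table to the pair, makes one stratified train/test split,
#' fits on the training split, and records held-out accuracy, AUC (positive
#' class = the larger NSP code), and wall-clock fitting+prediction time.
#'
#' @param table A CTG table.
#' @param specs Named list of `classifier_spec`s (default: all five).
#' @param pairs List of class pairs (default: `(1,3)`, `(1,2)`, `(2,3)`).
#' @param subsets Named list of `feature_subset`s to compare (default: all
#'   22 attributes under the name `"raw"`).
#' @param train_fraction,seed,stratified Passed to [split_train_test()].
#' @return An object of class `ctg_benchmark`: a tibble with columns
#'   `classifier`, `pair`, `feature_set`, `accuracy`, `auc`, `seconds`, and
#'   a `roc` list-column of ROC-point tibbles.
#' @export
benchmark_models <- function(table,
                             specs = default_classifier_specs(),
                             pairs = list(c(1, 3), c(1, 2), c(2, 3)),
                             subsets = list(raw = feature_subset(1:22, "manual")),
                             train_fraction = 0.75, seed = 1L,
                             stratified = TRUE) {
  if (is.null(names(subsets))) {
    names(subsets) <- vapply(subsets, `[[`, "", "provenance")
  }
  rows <- list()
  for (pair in pairs) {
    pdat <- make_pairwise_dataset(table, pair)
    spl <- split_train_test(pdat, train_fraction, seed, stratified)
    positive <- max(pair)
    for (sname in names(subsets)) {
      for (cname in names(specs)) {
        t0 <- proc.time()[["elapsed"]]
        model <- fit_classifier(specs[[cname]], spl$train, subsets[[sname]])
        pred <- predict(model, spl$test, type = "class")
        score <- predict(model, spl$test, type = "score")
        secs <- proc.time()[["elapsed"]] - t0
        ra <- roc_and_auc(score, spl$test$nsp == positive)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          classifier = cname,
          pair = paste(sort(pair), collapse = ""),
          feature_set = sname,
          accuracy = mean(pred == spl$test$nsp),
          auc = ra$auc,
          seconds = secs,
          roc = list(ra$roc)
        )
      }
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("ctg_benchmark", class(tibble::tibble())))
}

#' @exportS3Method generics::tidy
tidy.ctg_benchmark <- function(x, ...) {
  tibble::as_tibble(x[c("classifier", "pair", "feature_set", "accuracy",
                        "auc", "seconds")])
}

#' @exportS3Method generics::glance
glance.ctg_benchmark <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    best_classifier = x$classifier[which.max(x$accuracy)],
    best_accuracy = max(x$accuracy),
    best_auc = max(x$auc),
    total_seconds = sum(x$seconds)
  )
}

#' Plot benchmark accuracies
#'
#' Accuracy per classifier, faceted by class pair, coloured by feature set.
#'
#' @param object A `ctg_benchmark`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ctg_benchmark <- function(object, ...) {
  ggplot2::ggplot(tidy.ctg_benchmark(object),
                  ggplot2::aes(x = .data$classifier, y = .data$accuracy,
                               fill = .data$feature_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~pair, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "held-out accuracy", fill = "features") +
    ggplot2::theme_minimal()
}

#' Plot ROC curves of a benchmark
#'
#' @param x A `ctg_benchmark`.
#' @param pair Class-pair label to plot (e.g. `"13"`); default: first.
#' @param feature_set Feature-set label; default: first.
#' @return A ggplot object.
#' @export
plot_benchmark_roc <- function(x, pair = NULL, feature_set = NULL) {
  if (is.null(pair)) pair <- x$pair[1]
  if (is.null(feature_set)) feature_set <- x$feature_set[1]
  sel <- x[x$pair == pair & x$feature_set == feature_set, ]
  pts <- dplyr::bind_rows(lapply(seq_len(nrow(sel)), function(i) {
    dplyr::mutate(sel$roc[[i]], classifier = sel$classifier[i])
  }))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                    colour = .data$classifier)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(title = paste("class pair", pair, "-", feature_set),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Plot a support sweep
#'
#' Per-class frequent-attribute counts against the minsupport grid.
#'
#' @param object A `support_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.support_sweep <- function(object, ...) {
  p <- ggplot2::ggplot(object$counts,
                       ggplot2::aes(x = .data$minsupport,
                                    y = .data$n_attributes,
                                    colour = .data$class)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "minsupport", y = "frequent attributes") +
    ggplot2::theme_minimal()
  if (object$selection_ok) {
    p <- p + ggplot2::geom_vline(xintercept = object$selected, linetype = 2)
  }
  p
}
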