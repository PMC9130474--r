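#' Predict suspect records with the four-model ensemble
#'
#' "Model 2", step 1: trains k-nearest neighbours, Gaussian naive Bayes,
#' SGD logistic regression, and AdaBoost on *all* normal (1) and pathologic
#' (3) records — suspects never contribute labels, so nothing is held out
#' here — and predicts a normal-or-pathologic label for every suspect (2)
#' record.
#'
#' @param table A CTG table containing classes 1, 2 and 3.
#' @param subset A `feature_subset` of attributes to use.
#' @param specs Named list of the four `classifier_spec`s (default:
#'   `knn`, `gaussian_nb`, `sgd_logistic`, `adaboost` with their defaults).
#' @return An object of class `suspect_votes`: a tibble with `record_id`
#'   (row index of the suspect record in `table`) and one vote column in
#'   {1, 3} per model.
#' @export
predict_suspects <- function(table, subset,
                             specs = default_classifier_specs()[
                               c("knn", "gaussian_nb", "sgd_logistic",
                                 "adaboost")]) {
  for (cl in c(1L, 3L)) {
    if (!cl %in% table$nsp) {
      stop("reassignment needs class ", cl, " present", call. = FALSE)
    }
  }
  sus_idx <- which(table$nsp == 2L)
  if (length(sus_idx) == 0) {
    stop("no suspect (class 2) records to reassign", call. = FALSE)
  }
  train <- table[table$nsp %in% c(1L, 3L), , drop = FALSE]
  suspects <- table[sus_idx, , drop = FALSE]
  votes <- lapply(specs, function(sp) {
    model <- fit_classifier(sp, train, subset)
    as.integer(predict(model, suspects, type = "class"))
  })
  out <- tibble::tibble(record_id = sus_idx)
  for (nm in names(votes)) out[[nm]] <- votes[[nm]]
  structure(out, class = c("suspect_votes", class(tibble::tibble())))
}

#' Integrate per-model votes into a fused label
#'
#' Majority vote over the four model predictions; on a 2-2 tie the arbiter
#' model's vote decides. AdaBoost is the default arbiter as the strongest of
#' the four single models. Alternative policies: `"weighted"` weights each
#' model's vote by a supplied accuracy and breaks remaining ties with the
#' arbiter; `"unanimous"` fuses only unanimous records and leaves the rest
#' `NA` (abstain).
#'
#' @param votes A `suspect_votes` tibble.
#' @param arbiter Column name of the tie-breaking model (default
#'   `"adaboost"`).
#' @param policy `"majority"`, `"weighted"`, or `"unanimous"`.
#' @param weights Named numeric vector of per-model weights (for
#'   `policy = "weighted"`).
#' @return The `votes` tibble with `fused` (in {1, 3}, or `NA` under
#'   `"unanimous"` abstention) and `unanimous` (logical) columns added.
#' @export
integrate_votes <- function(votes, arbiter = "adaboost",
                            policy = c("majority", "weighted", "unanimous"),
                            weights = NULL) {
  policy <- match.arg(policy)
  model_cols <- setdiff(names(votes), c("record_id", "fused", "unanimous"))
  if (!arbiter %in% model_cols) {
    stop("arbiter ", arbiter, " is not a vote column", call. = FALSE)
  }
  V <- as.matrix(votes[model_cols])
  if (ncol(V) != 4) stop("expected exactly 4 votes per record", call. = FALSE)
  if (anyNA(V)) stop("missing vote", call. = FALSE)

  n1 <- rowSums(V == 1L)
  n3 <- rowSums(V == 3L)
  fused <- switch(policy,
    majority = ifelse(n1 > n3, 1L, ifelse(n3 > n1, 3L, votes[[arbiter]])),
    weighted = {
      if (is.null(weights)) stop("weighted policy needs weights", call. = FALSE)
      w <- weights[model_cols]
      s1 <- as.numeric((V == 1L) %*% w)
      s3 <- as.numeric((V == 3L) %*% w)
      ifelse(s1 > s3, 1L, ifelse(s3 > s1, 3L, votes[[arbiter]]))
    },
    unanimous = ifelse(n1 == 4L, 1L, ifelse(n3 == 4L, 3L, NA_integer_))
  )
  votes$fused <- as.integer(fused)
  votes$unanimous <- n1 == 4L | n3 == 4L
  votes
}

#' Replace suspect labels with their fused predictions
#'
#' Rewrites the label of every suspect record with its fused vote, leaving
#' classes 1 and 3 (and every feature value) untouched; the result has
#' labels in {1, 3} only. The original and fused labels are retained as a
#' provenance table.
#'
#' @param table The CTG table the votes were computed on.
#' @param votes A `suspect_votes` tibble with a `fused` column (see
#'   [integrate_votes()]); every suspect record must have a non-`NA` fused
#'   label.
#' @return An object of class `ctg_relabeled`: a list with `table` (the
#'   relabeled CTG table) and `provenance` (tibble: `record_id`,
#'   `original`, `fused`).
#' @export
relabel_suspects <- function(table, votes) {
  sus_idx <- which(table$nsp == 2L)
  if (!"fused" %in% names(votes)) {
    stop("votes have no fused column; call integrate_votes() first",
         call. = FALSE)
  }
  if (!all(votes$record_id %in% sus_idx)) {
    stop("votes refer to records that are not suspects in this table",
         call. = FALSE)
  }
  missing <- setdiff(sus_idx, votes$record_id[!is.na(votes$fused)])
  if (length(missing) > 0) {
    stop(length(missing), " suspect record(s) without a fused label",
         call. = FALSE)
  }
  out <- table
  out$nsp[votes$record_id] <- votes$fused
  structure(
    list(table = out,
         provenance = tibble::tibble(record_id = votes$record_id,
                                     original = 2L, fused = votes$fused)),
    class = "ctg_relabeled"
  )
}

#' @export
print.ctg_relabeled <- function(x, ...) {
  cat("<ctg_relabeled>", nrow(x$table), "records;",
      nrow(x$provenance), "suspects fused to",
      sum(x$provenance$fused == 1L), "normal /",
      sum(x$provenance$fused == 3L), "pathologic\n")
  invisible(x)
}

#' Evaluate the fused two-class dataset against blanket baselines
#'
#' Fits the evaluation classifier (Ada-RF by default) on a held-out split of
#' three two-class versions of the dataset: (a) suspects relabeled by the
#' Model-2 ensemble, (b) all suspects blanket-assigned to normal, (c) all
#' suspects blanket-assigned to pathologic. Reports held-out standard
#' accuracy, the positive-predictive metrics, and AUC side by side.
#'
#' @param table The original three-class CTG table.
#' @param votes A `suspect_votes` tibble with fused labels.
#' @param subset A `feature_subset` of attributes to use.
#' @param spec Evaluation classifier (default `classifier_spec("ada_rf")`).
#' @param train_fraction,seed Passed to [split_train_test()].
#' @return A tibble with one row per variant (`model2`,
#'   `suspect_as_normal`, `suspect_as_pathologic`) and columns `accuracy`
#'   (standard), `paper_accuracy`, `sensitivity`, `f1`, `auc`.
#' @export
evaluate_fusion <- function(table, votes, subset,
                            spec = classifier_spec("ada_rf"),
                            train_fraction = 0.75, seed = 1L) {
  variants <- list(
    model2 = relabel_suspects(table, votes)$table$nsp,
    suspect_as_normal = ifelse(table$nsp == 2L, 1L, table$nsp),
    suspect_as_pathologic = ifelse(table$nsp == 2L, 3L, table$nsp)
  )
  rows <- lapply(names(variants), function(vn) {
    tab <- table
    tab$nsp <- as.integer(variants[[vn]])
    spl <- split_train_test(tab, train_fraction, seed, stratified = TRUE)
    model <- fit_classifier(spec, spl$train, subset)
    pred <- predict(model, spl$test, type = "class")
    score <- predict(model, spl$test, type = "score")
    cm <- confusion_matrix(pred, spl$test$nsp, positive = 1L)
    mr <- paper_metrics(cm)
    tibble::tibble(
      variant = vn,
      accuracy = mean(pred == spl$test$nsp),
      paper_accuracy = mr$paper_accuracy,
      sensitivity = mr$sensitivity,
      f1 = mr$f1,
      auc = roc_and_auc(score, spl$test$nsp == 3L)$auc
    )
  })
  dplyr::bind_rows(rows)
}
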