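#' Specify one of the five benchmark classifiers
#'
#' The classifier families and hyperparameter defaults used throughout the
#' package:
#'
#' * `knn` — k-nearest neighbours, majority vote, Euclidean distance on
#'   min-max scaled features (scaling fitted on the training split only);
#'   `k = 5`.
#' * `gaussian_nb` — Gaussian naive Bayes: per-class, per-feature Gaussian
#'   likelihoods with variance smoothing `var_smoothing * max(feature
#'   variance)` added to every variance.
#' * `sgd_logistic` — logistic regression fitted by stochastic gradient
#'   descent, one sample per update, inverse-scaling learning rate
#'   `eta0 / t^power_t`, capped at `max_iter = 10000` updates or an epoch
#'   log-loss improvement below `tol = 1e-3`; features min-max scaled.
#' * `adaboost` — real-valued (SAMME.R-style) boosting of depth-1 decision
#'   stumps: `n_rounds = 100`, `learning_rate = 0.5`, `seed = 25`.
#' * `ada_rf` — discrete (SAMME) boosting of random-forest base learners.
#'   The `"paper"` profile uses 500 boosting rounds of 1,000-tree forests;
#'   the default `"test"` profile keeps the same architecture at desk scale
#'   (25 rounds of 50-tree forests).
#'
#' @param name One of `"knn"`, `"gaussian_nb"`, `"sgd_logistic"`,
#'   `"adaboost"`, `"ada_rf"`.
#' @param ... Hyperparameter overrides (see above for names).
#' @param profile `"test"` or `"paper"`; only affects `ada_rf` scale.
#' @param seed Integer seed for any randomized component (tie-breaking,
#'   shuffling, forest growing). Defaults to 25 for the boosted families.
#' @return An object of class `classifier_spec`.
#' @examples
#' classifier_spec("knn", k = 3)
#' classifier_spec("ada_rf", profile = "paper")
#' @export
classifier_spec <- function(name = c("knn", "gaussian_nb", "sgd_logistic",
                                     "adaboost", "ada_rf"),
                            ..., profile = c("test", "paper"), seed = NULL) {
  name <- match.arg(name)
  profile <- match.arg(profile)
  defaults <- switch(name,
    knn = list(k = 5),
    gaussian_nb = list(var_smoothing = 1e-9),
    sgd_logistic = list(eta0 = 0.5, power_t = 0.25, max_iter = 10000,
                        tol = 1e-3),
    adaboost = list(n_rounds = 100, learning_rate = 0.5, max_depth = 1),
    ada_rf = if (profile == "paper") {
      list(n_rounds = 500, rf_trees = 1000, learning_rate = 0.5)
    } else {
      list(n_rounds = 25, rf_trees = 50, learning_rate = 0.5)
    }
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad) > 0) {
    stop("unknown hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hyper <- utils::modifyList(defaults, over)
  if (is.null(seed)) seed <- if (name %in% c("adaboost", "ada_rf")) 25L else 1L
  structure(list(name = name, hyperparameters = hyper, profile = profile,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat("<classifier_spec>", x$name, "(", hp, ") seed:", x$seed, "\n")
  invisible(x)
}

#' Default specifications of the five benchmark classifiers
#'
#' @param profile Passed to [classifier_spec()] for `ada_rf`.
#' @return Named list of `classifier_spec`s.
#' @export
default_classifier_specs <- function(profile = c("test", "paper")) {
  profile <- match.arg(profile)
  nm <- c("knn", "gaussian_nb", "sgd_logistic", "adaboost", "ada_rf")
  stats::setNames(lapply(nm, classifier_spec, profile = profile), nm)
}

#' Fit a classifier on a binary CTG task
#'
#' Trains the classifier described by `spec` on the records of `train`,
#' using the attributes of `subset` as features. The training labels must
#' contain exactly two distinct NSP codes; the fitted model predicts those
#' codes and scores the class with the larger code as the positive class.
#' Fitting is deterministic given the spec (including its seed) and data.
#'
#' @param spec A `classifier_spec`.
#' @param train A CTG table with exactly two classes.
#' @param subset A `feature_subset` of attributes to use as features.
#' @return An object of class `ctg_model`.
#' @export
fit_classifier <- function(spec, train, subset) {
  stopifnot(inherits(spec, "classifier_spec"), inherits(subset, "feature_subset"))
  lv <- sort(unique(train$nsp))
  if (length(lv) < 2) stop("training data contain a single class", call. = FALSE)
  if (length(lv) > 2) stop("training data contain more than two classes",
                           call. = FALSE)
  feats <- subset_names(subset)
  X <- as.matrix(train[feats])
  y <- train$nsp

  scale_range <- NULL
  if (spec$name %in% c("knn", "sgd_logistic")) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    scale_range <- list(lo = lo, hi = hi)
    X <- minmax_apply(X, scale_range)
  }

  fit <- switch(spec$name,
    knn = list(X = X, y = y),
    gaussian_nb = fit_gnb(X, y, lv, spec$hyperparameters$var_smoothing),
    sgd_logistic = fit_sgd_logistic(X, y, lv, spec),
    adaboost = fit_adaboost(X, y, lv, spec),
    ada_rf = fit_ada_rf(X, y, lv, spec)
  )
  structure(list(spec = spec, levels = lv, features = feats,
                 scale_range = scale_range, fit = fit),
            class = "ctg_model")
}

minmax_apply <- function(X, r) {
  span <- pmax(r$hi - r$lo, .Machine$double.eps)
  sweep(sweep(X, 2, r$lo, "-"), 2, span, "/")
}

#' @export
print.ctg_model <- function(x, ...) {
  cat("<ctg_model>", x$spec$name, "on classes",
      paste(x$levels, collapse = " vs "), "with", length(x$features),
      "features\n")
  invisible(x)
}

#' Predict classes or positive-class scores from a fitted model
#'
#' @param object A `ctg_model`.
#' @param newdata A CTG table (the label column, if present, is ignored).
#' @param type `"class"` for NSP codes, `"score"` for the probability-scale
#'   confidence of the class with the larger code.
#' @param ... Unused.
#' @return Integer labels or numeric scores.
#' @export
predict.ctg_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[object$features])
  if (!is.null(object$scale_range)) X <- minmax_apply(X, object$scale_range)
  score <- switch(object$spec$name,
    knn = predict_knn(object, X),
    gaussian_nb = predict_gnb(object, X),
    sgd_logistic = stats::plogis(drop(cbind(1, X) %*% object$fit$theta)),
    adaboost = stats::plogis(adaboost_margin(object$fit, X)),
    ada_rf = stats::plogis(ada_rf_margin(object$fit, X))
  )
  if (type == "score") return(score)
  ifelse(score > 0.5, object$levels[2], object$levels[1])
}

# ---- KNN ----------------------------------------------------------------

predict_knn <- function(object, X) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(object$spec$seed)  # reproducible tie-breaking
  k <- object$spec$hyperparameters$k
  pred <- class::knn(object$fit$X, X, factor(object$fit$y), k = k,
                     prob = TRUE)
  win <- attr(pred, "prob")
  lab <- as.integer(as.character(pred))
  ifelse(lab == object$levels[2], win, 1 - win)
}

# ---- Gaussian naive Bayes -----------------------------------------------

# Per-class Gaussian likelihoods: P(x_j | C_k) = N(x_j; u_k, s2_k), with
# s2_k floored by var_smoothing * max feature variance (numerical guard for
# near-constant features).
fit_gnb <- function(X, y, lv, var_smoothing) {
  eps <- var_smoothing * max(apply(X, 2, stats::var), .Machine$double.eps)
  per_class <- lapply(lv, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    list(prior = nrow(Xc) / nrow(X),
         mean = colMeans(Xc),
         var = apply(Xc, 2, stats::var) * (nrow(Xc) - 1) / nrow(Xc) + eps)
  })
  names(per_class) <- lv
  list(per_class = per_class)
}

predict_gnb <- function(object, X) {
  ll <- vapply(object$fit$per_class, function(p) {
    log(p$prior) + rowSums(
      -0.5 * log(2 * pi * rep(1, nrow(X)) %o% p$var) -
        sweep(X, 2, p$mean, "-")^2 / (2 * rep(1, nrow(X)) %o% p$var))
  }, numeric(nrow(X)))
  if (!is.matrix(ll)) ll <- matrix(ll, nrow = 1)
  1 / (1 + exp(ll[, 1] - ll[, 2]))
}

# ---- SGD logistic regression --------------------------------------------

# Stochastic gradient descent on the logistic model, one sample j per
# update: theta <- theta - alpha_t * (h_theta(x^(j)) - y_j) * x^(j), with
# inverse-scaling learning rate alpha_t = eta0 / t^power_t. Updates are
# capped at max_iter; training also stops when the full-data log-loss
# improves by less than tol over an epoch.
fit_sgd_logistic <- function(X, y, lv, spec) {
  hp <- spec$hyperparameters
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  Z <- cbind(1, X)
  yb <- as.numeric(y == lv[2])
  theta <- rep(0, ncol(Z))
  n <- nrow(Z)
  t_step <- 0
  prev_loss <- Inf
  logloss <- function(theta) {
    p <- pmin(pmax(stats::plogis(drop(Z %*% theta)), 1e-12), 1 - 1e-12)
    -mean(yb * log(p) + (1 - yb) * log(1 - p))
  }
  while (t_step < hp$max_iter) {
    for (j in sample.int(n)) {
      t_step <- t_step + 1
      alpha <- hp$eta0 / t_step^hp$power_t
      h <- stats::plogis(sum(Z[j, ] * theta))
      theta <- theta - alpha * (h - yb[j]) * Z[j, ]
      if (t_step >= hp$max_iter) break
    }
    loss <- logloss(theta)
    if (prev_loss - loss < hp$tol) break
    prev_loss <- loss
  }
  list(theta = theta, n_updates = t_step)
}

# ---- AdaBoost (real-valued, SAMME.R-style, stump base) ------------------

fit_adaboost <- function(X, y, lv, spec) {
  hp <- spec$hyperparameters
  n <- nrow(X)
  ypm <- ifelse(y == lv[2], 1, -1)
  df <- data.frame(y = factor(ypm, levels = c(-1, 1)), X)
  w <- rep(1 / n, n)
  stumps <- list()
  ctrl <- rpart::rpart.control(maxdepth = hp$max_depth, cp = 0, minsplit = 2,
                               minbucket = 1, xval = 0)
  for (m in seq_len(hp$n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w * n, method = "class",
                        control = ctrl)
    p <- pmin(pmax(stats::predict(fit, df, type = "prob")[, "1"], 1e-10),
              1 - 1e-10)
    h <- 0.5 * log(p / (1 - p))
    w <- w * exp(-hp$learning_rate * ypm * h)
    if (sum(w) <= 0 || !all(is.finite(w))) break
    w <- w / sum(w)
    stumps[[m]] <- fit
  }
  list(stumps = stumps, learning_rate = hp$learning_rate,
       feature_names = colnames(X))
}

adaboost_margin <- function(fit, X) {
  df <- data.frame(X)
  names(df) <- fit$feature_names
  contrib <- vapply(fit$stumps, function(s) {
    p <- pmin(pmax(stats::predict(s, df, type = "prob")[, "1"], 1e-10),
              1 - 1e-10)
    0.5 * log(p / (1 - p))
  }, numeric(nrow(df)))
  if (!is.matrix(contrib)) contrib <- matrix(contrib, nrow = nrow(df))
  fit$learning_rate * rowSums(contrib)
}

# ---- Ada-RF (discrete SAMME, random-forest base) ------------------------

fit_ada_rf <- function(X, y, lv, spec) {
  hp <- spec$hyperparameters
  n <- nrow(X)
  yf <- factor(y, levels = lv)
  w <- rep(1 / n, n)
  rounds <- list()
  # ranger's weighted bootstrap draws from R's RNG as well as its own seed,
  # so pin both to make boosting a pure function of spec and data
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (m in seq_len(hp$n_rounds)) {
    set.seed(spec$seed + m)
    rf <- ranger::ranger(x = as.data.frame(X), y = yf,
                         num.trees = hp$rf_trees, case.weights = w,
                         seed = spec$seed + m, num.threads = 1)
    pred <- stats::predict(rf, data = as.data.frame(X),
                           num.threads = 1)$predictions
    miss <- pred != yf
    err <- sum(w[miss])
    if (err <= 0) {
      # perfect weighted fit: this learner decides alone
      rounds[[m]] <- list(rf = rf, alpha = hp$learning_rate * log(1e10))
      break
    }
    if (err >= 0.5) break  # no better than chance under current weights
    alpha <- hp$learning_rate * log((1 - err) / err)
    rounds[[m]] <- list(rf = rf, alpha = alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (length(rounds) == 0) {
    stop("ada_rf: first base learner no better than chance", call. = FALSE)
  }
  list(rounds = rounds, levels = lv, feature_names = colnames(X),
       seed = spec$seed)
}

ada_rf_margin <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- fit$feature_names
  # even tree counts can tie; ranger breaks prediction ties from R's RNG,
  # so pin it for reproducible scores
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  margins <- vapply(seq_along(fit$rounds), function(i) {
    r <- fit$rounds[[i]]
    set.seed(fit$seed + i)
    pred <- stats::predict(r$rf, data = df, num.threads = 1,
                           seed = fit$seed + i)$predictions
    r$alpha * ifelse(pred == fit$levels[2], 1, -1)
  }, numeric(nrow(df)))
  if (!is.matrix(margins)) margins <- matrix(margins, nrow = nrow(df))
  rowSums(margins)
}
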