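# Two well-separated Gaussian clusters (classes 1 and 3) for separable-case
# checks, embedded in the full 22-column schema.
separable_ctg <- function(n_per_class = 40, gap = 30, seed = 17) {
  spec <- synthetic_ctg_spec(n_per_class = c(n_per_class, 2, n_per_class),
                             separation = gap / 10, seed = seed)
  generate_ctg(spec)$table |> make_pairwise_dataset(c(1, 3))
}

informative <- function() feature_subset(c(1:6, 8, 9, 14, 18, 19), "manual")

test_that("every classifier family separates linearly separable clusters", {
  tab <- separable_ctg()
  spl <- split_train_test(tab, 0.75, seed = 2)
  for (nm in names(default_classifier_specs())) {
    model <- fit_classifier(classifier_spec(nm), spl$train, informative())
    expect_equal(mean(predict(model, spl$test) == spl$test$nsp), 1,
                 info = nm)
  }
})

test_that("training is deterministic given spec, data and seed", {
  tab <- separable_ctg(30, gap = 5)
  for (nm in names(default_classifier_specs())) {
    m1 <- fit_classifier(classifier_spec(nm), tab, informative())
    m2 <- fit_classifier(classifier_spec(nm), tab, informative())
    expect_identical(predict(m1, tab, type = "score"),
                     predict(m2, tab, type = "score"), info = nm)
  }
})

test_that("Gaussian NB recovers the generating moments", {
  spec <- synthetic_ctg_spec(n_per_class = c(2000, 2, 2000), seed = 3)
  tab <- generate_ctg(spec)$table |> make_pairwise_dataset(c(1, 3))
  model <- fit_classifier(classifier_spec("gaussian_nb"), tab, informative())
  lb_fit <- model$fit$per_class[["1"]]$mean[["LB"]]
  mu <- spec$params$mean1[spec$params$name == "LB"]
  se <- spec$params$sd[spec$params$name == "LB"] / sqrt(2000)
  expect_lt(abs(lb_fit - mu), 3 * se)
})

test_that("Gaussian NB posteriors match an independent implementation", {
  skip_if_not_installed("e1071")
  syn <- syn_small(9, n = c(60, 2, 40))
  tab <- make_pairwise_dataset(syn$table, c(1, 3))
  sub <- informative()
  model <- fit_classifier(classifier_spec("gaussian_nb"), tab, sub)
  ours <- predict(model, tab, type = "score")
  nb <- e1071::naiveBayes(x = as.data.frame(tab[subset_names(sub)]),
                          y = factor(tab$nsp))
  ref <- predict(nb, as.data.frame(tab[subset_names(sub)]),
                 type = "raw")[, "3"]
  expect_equal(ours, unname(ref), tolerance = 1e-4)
})

test_that("1-NN memorizes duplicate-free training data", {
  tab <- separable_ctg(25, gap = 2)
  model <- fit_classifier(classifier_spec("knn", k = 1), tab, informative())
  expect_equal(mean(predict(model, tab) == tab$nsp), 1)
})

test_that("SGD logistic converges to a separating rule on separated data", {
  tab <- separable_ctg(40, gap = 20)
  model <- fit_classifier(classifier_spec("sgd_logistic"), tab, informative())
  expect_lte(model$fit$n_updates, 10000)
  expect_equal(mean(predict(model, tab) == tab$nsp), 1)
})

test_that("AdaBoost training error does not increase with rounds", {
  syn <- syn_small(23, n = c(60, 2, 50))
  tab <- make_pairwise_dataset(syn$table, c(1, 3))
  errs <- vapply(c(1, 5, 25), function(m) {
    fit <- fit_classifier(classifier_spec("adaboost", n_rounds = m),
                          tab, informative())
    mean(predict(fit, tab) != tab$nsp)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("hyperparameter contracts are enforced", {
  expect_error(classifier_spec("knn", bogus = 1), "bogus")
  spec <- classifier_spec("ada_rf", profile = "paper")
  expect_equal(spec$hyperparameters$n_rounds, 500)
  expect_equal(spec$hyperparameters$rf_trees, 1000)
  expect_equal(classifier_spec("adaboost")$seed, 25L)
  tab <- toy_ctg(10, nsp = rep(1L, 10))
  expect_error(fit_classifier(classifier_spec("knn"), tab, informative()),
               "single class")
})

test_that("pairwise restriction and splitting behave arithmetically", {
  tab <- toy_ctg(10, nsp = rep(c(1L, 2L, 3L), c(5, 3, 2)))
  expect_equal(nrow(make_pairwise_dataset(tab, c(1, 3))), 7)
  expect_equal(nrow(make_pairwise_dataset(tab, c(2, 3))), 5)
  expect_error(make_pairwise_dataset(tab, c(1, 1)), "distinct")

  big <- toy_ctg(100, nsp = rep(c(1L, 3L), c(60, 40)))
  spl <- split_train_test(big, 0.75, seed = 4)
  expect_equal(nrow(spl$train), 75)
  expect_equal(nrow(spl$test), 25)
  # same seed, same partition; union is the input
  spl2 <- split_train_test(big, 0.75, seed = 4)
  expect_identical(spl, spl2)
  expect_equal(dplyr::bind_rows(spl$train, spl$test) |>
                 dplyr::arrange(LB), dplyr::arrange(big, LB))
  # per-stratum rounding: {1:40, 3:20} at 0.75 -> train {1:30, 3:15}
  strat <- toy_ctg(60, nsp = rep(c(1L, 3L), c(40, 20)))
  sp <- split_train_test(strat, 0.75, seed = 1)
  expect_equal(as.integer(table(sp$train$nsp)), c(30L, 15L))
  expect_error(split_train_test(toy_ctg(3, nsp = c(1L, 1L, 3L)), 0.5, 1),
               "at least 2")
})

test_that("the benchmark grid fills one cell per combination", {
  syn <- syn_small(5, n = c(80, 30, 25))
  b <- benchmark_models(
    syn$table,
    specs = default_classifier_specs()[c("knn", "gaussian_nb")],
    subsets = list(raw = feature_subset(1:22, "manual"),
                   extracted = informative()),
    seed = 8
  )
  expect_equal(nrow(b), 2 * 3 * 2)
  expect_true(all(b$accuracy >= 0 & b$accuracy <= 1))
  expect_true(all(b$auc >= 0 & b$auc <= 1))
  expect_setequal(unique(b$pair), c("13", "12", "23"))
  # reproducible bit-for-bit under the master seed
  b2 <- benchmark_models(
    syn$table,
    specs = default_classifier_specs()[c("knn", "gaussian_nb")],
    subsets = list(raw = feature_subset(1:22, "manual"),
                   extracted = informative()),
    seed = 8
  )
  expect_identical(tidy(b)[c("classifier", "pair", "feature_set",
                             "accuracy", "auc")],
                   tidy(b2)[c("classifier", "pair", "feature_set",
                              "accuracy", "auc")])
  gl <- glance(b)
  expect_equal(gl$n_cells, 12L)
})

test_that("feature extraction costs little accuracy when informative features stay", {
  syn <- syn_small(29, n = c(200, 50, 40))
  b <- benchmark_models(
    syn$table,
    specs = default_classifier_specs()[c("gaussian_nb", "knn")],
    pairs = list(c(1, 3)),
    subsets = list(raw = feature_subset(1:22, "manual"),
                   extracted = informative()),
    seed = 11
  )
  wide <- tidyr::pivot_wider(tidy(b)[c("classifier", "feature_set", "accuracy")],
                             names_from = "feature_set",
                             values_from = "accuracy")
  expect_true(all(wide$raw - wide$extracted <= 0.05))
})

test_that("pure-noise features perform near the majority rate", {
  syn <- syn_small(41, n = c(150, 30, 50))
  noise_only <- feature_subset(c(13, 15, 16, 20, 21, 22), "manual")
  b <- benchmark_models(syn$table,
                        specs = default_classifier_specs()["gaussian_nb"],
                        pairs = list(c(1, 3)),
                        subsets = list(noise = noise_only), seed = 13)
  # majority class (normal) is 150/200 = 0.75 of the pair; binomial noise
  # on a 50-record test set has sd ~ 0.06
  expect_lt(abs(b$accuracy - 0.75), 3 * sqrt(0.75 * 0.25 / 50))
})

test_that("benchmark plots build without error", {
  syn <- syn_small(5, n = c(40, 12, 12))
  b <- benchmark_models(syn$table,
                        specs = default_classifier_specs()["gaussian_nb"],
                        seed = 1)
  expect_s3_class(ggplot2::autoplot(b), "ggplot")
  expect_s3_class(plot_benchmark_roc(b), "ggplot")
})
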