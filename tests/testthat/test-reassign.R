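fused_set <- function() feature_subset(c(1:6, 8, 9, 14, 18, 19), "manual")

test_that("strongly separated suspects drawn from one class get unanimous votes", {
  syn <- generate_ctg(synthetic_ctg_spec(n_per_class = c(100, 30, 80),
                                         suspect_mixture_weight = 1,
                                         seed = 19))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  expect_true(all(votes$fused == 1L))
  expect_true(all(votes$unanimous))
})

test_that("reassignment preconditions are enforced", {
  no3 <- toy_ctg(20, nsp = rep(c(1L, 2L), each = 10))
  expect_error(predict_suspects(no3, fused_set()), "class 3")
  nosus <- toy_ctg(20, nsp = rep(c(1L, 3L), each = 10))
  expect_error(predict_suspects(nosus, fused_set()), "no suspect")
})

test_that("the fused-normal fraction tracks the mixture weight", {
  syn <- generate_ctg(synthetic_ctg_spec(n_per_class = c(250, 80, 80),
                                         suspect_mixture_weight = 0.7,
                                         seed = 23))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  expect_lt(abs(mean(votes$fused == 1L) - 0.7), 3 * sqrt(0.7 * 0.3 / 80))
  # at high separation the fused labels recover the latent truth
  expect_gt(mean(votes$fused == syn$latent_truth), 0.95)
})

test_that("vote integration follows majority with an arbiter tie-break", {
  v <- tibble::tibble(record_id = 1:4,
                      knn = c(1L, 3L, 1L, 1L),
                      gaussian_nb = c(1L, 3L, 1L, 1L),
                      sgd_logistic = c(1L, 3L, 3L, 3L),
                      adaboost = c(1L, 1L, 3L, 1L))
  got <- integrate_votes(v)
  expect_equal(got$fused, c(1L, 3L, 3L, 1L))  # ties at rows 3-4 -> adaboost
  expect_equal(got$unanimous, c(TRUE, FALSE, FALSE, FALSE))
  alt <- integrate_votes(v, arbiter = "knn")
  expect_equal(alt$fused[3], 1L)
  expect_error(integrate_votes(v, arbiter = "nope"), "arbiter")
  expect_error(integrate_votes(v[-2]), "4 votes")
  v_na <- v; v_na$knn[1] <- NA_integer_
  expect_error(integrate_votes(v_na), "missing vote")
})

test_that("vote integration is symmetric in the non-arbiter models", {
  withr::local_seed(37)
  for (i in 1:20) {
    v <- tibble::tibble(record_id = 1:6,
                        knn = sample(c(1L, 3L), 6, TRUE),
                        gaussian_nb = sample(c(1L, 3L), 6, TRUE),
                        sgd_logistic = sample(c(1L, 3L), 6, TRUE),
                        adaboost = sample(c(1L, 3L), 6, TRUE))
    base <- integrate_votes(v)$fused
    perm <- v[c("record_id", "sgd_logistic", "knn", "gaussian_nb", "adaboost")]
    expect_equal(integrate_votes(perm)$fused, base)
  }
})

test_that("alternative integration policies behave as documented", {
  v <- tibble::tibble(record_id = 1:2,
                      knn = c(1L, 1L), gaussian_nb = c(1L, 3L),
                      sgd_logistic = c(1L, 1L), adaboost = c(1L, 3L))
  u <- integrate_votes(v, policy = "unanimous")
  expect_equal(u$fused, c(1L, NA_integer_))
  w <- integrate_votes(v, policy = "weighted",
                       weights = c(knn = 0.1, gaussian_nb = 5,
                                   sgd_logistic = 0.1, adaboost = 5))
  expect_equal(w$fused, c(1L, 3L))
})

test_that("relabeling rewrites suspects only and keeps features intact", {
  syn <- syn_small(31, n = c(60, 10, 30))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  rl <- relabel_suspects(syn$table, votes)
  expect_equal(nrow(rl$table), nrow(syn$table))
  expect_false(any(rl$table$nsp == 2L))
  expect_equal(rl$table[ctg_attributes()$name],
               syn$table[ctg_attributes()$name])
  untouched <- syn$table$nsp != 2L
  expect_equal(rl$table$nsp[untouched], syn$table$nsp[untouched])
  # bookkeeping: all-to-normal fusion grows class 1 by the suspect count
  votes10 <- votes; votes10$fused <- rep(1L, nrow(votes10))
  rl10 <- relabel_suspects(syn$table, votes10)
  expect_equal(sum(rl10$table$nsp == 1L), sum(syn$table$nsp == 1L) + 10)
})

test_that("relabeling a table without suspects is the identity", {
  tab <- toy_ctg(20, nsp = rep(c(1L, 3L), each = 10))
  empty_votes <- tibble::tibble(record_id = integer(0), fused = integer(0))
  rl <- relabel_suspects(tab, empty_votes)
  expect_equal(rl$table, tab)
  # an unfused suspect is an error
  tab2 <- toy_ctg(20, nsp = rep(c(1L, 2L), each = 10))
  expect_error(relabel_suspects(tab2, empty_votes), "without a fused label")
})

test_that("relabeled class proportions track the latent truth", {
  syn <- generate_ctg(synthetic_ctg_spec(n_per_class = c(150, 60, 60),
                                         seed = 43))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  rl <- relabel_suspects(syn$table, votes)
  true_n1 <- sum(syn$table$nsp == 1L) + sum(syn$latent_truth == 1L)
  expect_lt(abs(sum(rl$table$nsp == 1L) - true_n1),
            0.1 * length(syn$latent_truth) + 1)
})

test_that("fused votes do no worse than the average single model", {
  syn <- generate_ctg(synthetic_ctg_spec(n_per_class = c(200, 60, 60),
                                         separation = 0.35, seed = 47))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  singles <- vapply(c("knn", "gaussian_nb", "sgd_logistic", "adaboost"),
                    function(nm) mean(votes[[nm]] == syn$latent_truth),
                    numeric(1))
  fused_acc <- mean(votes$fused == syn$latent_truth)
  expect_gte(fused_acc, mean(singles) - 0.01)
})

test_that("fusion evaluation compares the three variants coherently", {
  syn <- generate_ctg(synthetic_ctg_spec(n_per_class = c(120, 30, 60),
                                         suspect_mixture_weight = 1,
                                         seed = 53))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  ev <- evaluate_fusion(syn$table, votes, fused_set(),
                        spec = classifier_spec("gaussian_nb"), seed = 3)
  expect_setequal(ev$variant,
                  c("model2", "suspect_as_normal", "suspect_as_pathologic"))
  # with mixture weight 1 and clean separation the ensemble fuses all
  # suspects to normal, so model2 coincides with the blanket-normal variant
  expect_true(all(votes$fused == 1L))
  expect_equal(ev$accuracy[ev$variant == "model2"],
               ev$accuracy[ev$variant == "suspect_as_normal"])
})

test_that("symmetric mixtures make the two blanket baselines comparable", {
  syn <- generate_ctg(synthetic_ctg_spec(n_per_class = c(100, 60, 100),
                                         suspect_mixture_weight = 0.5,
                                         seed = 59))
  votes <- integrate_votes(predict_suspects(syn$table, fused_set()))
  ev <- evaluate_fusion(syn$table, votes, fused_set(),
                        spec = classifier_spec("gaussian_nb"), seed = 5)
  acc_b <- ev$accuracy[ev$variant == "suspect_as_normal"]
  acc_c <- ev$accuracy[ev$variant == "suspect_as_pathologic"]
  expect_lt(abs(acc_b - acc_c), 0.12)
  expect_gte(ev$accuracy[ev$variant == "model2"], min(acc_b, acc_c))
})
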