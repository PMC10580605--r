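test_that("train/test split partitions deterministically", {
  tab <- linear_trait_table(100)
  sp <- split_train_test(tab, 0.75, seed = 4)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$test))),
               sort(rownames(tab)))
  sp2 <- split_train_test(tab, 0.75, seed = 4)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(tab, 0.75, seed = 5)))
  tiny <- split_train_test(linear_trait_table(8), 0.75, seed = 1)
  expect_equal(nrow(tiny$train), 6)
  expect_equal(nrow(tiny$test), 2)
  expect_error(split_train_test(linear_trait_table(7)), "at least 8")
})

test_that("a lone perfect predictor enters with partial R2 = 1 and VIF 1", {
  withr::with_seed(2, {
    d <- data.frame(PH = runif(50))
    d$LS <- 2 * d$PH
  })
  m <- stepwise_mlr(d, mlr_config(candidates = "PH"))
  expect_equal(m$trace$entered, "PH")
  expect_equal(m$trace$partial_r2, 1, tolerance = 1e-10)
  expect_equal(m$trace$vif, 1)
  expect_equal(unname(coef(m$fit)), c(0, 2), tolerance = 1e-8)
})

test_that("stepwise recovers a noiseless linear model exactly", {
  d <- linear_trait_table(200, seed = 3)
  m <- stepwise_mlr(d)
  expect_setequal(m$trace$entered, c("PH", "PeD", "IL1", "IL2"))
  expect_equal(m$trace$model_r2[4], 1, tolerance = 1e-8)
  expect_equal(unname(coef(m$fit)[c("PH", "PeD", "IL1", "IL2")]),
               c(0.002, -0.03, 0.01, 0.005), tolerance = 1e-8)
})

test_that("stepwise trace increments sum to the final model R2", {
  tab <- gen_trait_table(trait_gen_config(n = 400, seed = 6))
  m <- stepwise_mlr(tab)
  expect_true(all(diff(m$trace$model_r2) >= 0))
  expect_equal(sum(m$trace$partial_r2),
               m$trace$model_r2[nrow(m$trace)], tolerance = 1e-10)
  expect_true(all(m$trace$vif >= 1))
})

test_that("the planted dominant trait enters first at scale", {
  tab <- gen_trait_table(trait_gen_config(n = 20000, seed = 8))
  m <- stepwise_mlr(tab)
  expect_equal(m$trace$entered[1], "PH")
  # exhaustive single-variable check: PH has the largest marginal R2
  marginals <- vapply(c("PH", "PeD", "IL1", "IL2"), function(v) {
    summary(lm(reformulate(v, "LS"), tab))$r.squared
  }, numeric(1))
  expect_equal(names(which.max(marginals)), "PH")
  expect_equal(m$trace$partial_r2[1], unname(marginals["PH"]),
               tolerance = 1e-10)
  expect_equal(m$trace$partial_r2[1], 0.78^2, tolerance = 0.02)
})

test_that("stepwise keeps pure noise out at the entry level", {
  hits <- vapply(1:60, function(s) {
    withr::with_seed(1000 + s, {
      d <- data.frame(PH = rnorm(60), PeD = rnorm(60), IL1 = rnorm(60),
                      IL2 = rnorm(60), LS = rnorm(60))
    })
    nrow(stepwise_mlr(d)$trace) == 0
  }, logical(1))
  # entry is a level-0.05 test per candidate; empty traces dominate
  expect_gte(mean(hits), 0.7)
})

test_that("stepwise raises a degenerate-design error naming the culprit", {
  d <- linear_trait_table(50, seed = 9)
  d$PeD <- 2 * d$PH
  expect_error(stepwise_mlr(d), "degenerate design.*PeD|degenerate design.*PH")
})

test_that("network fit has constant, linear, and reproducibility behavior", {
  d <- linear_trait_table(120, seed = 5)
  dc <- d; dc$LS <- 0.4
  mc <- fit_ann(dc, ann_config(iterations = 300, seed = 1))
  expect_lt(max(abs(predict(mc, dc) - 0.4)), 0.01)
  m1 <- fit_ann(d, ann_config(seed = 7))
  expect_gte(r2(d$LS, predict(m1, d)), 0.95)
  m2 <- fit_ann(d, ann_config(seed = 7))
  expect_identical(predict(m1, d), predict(m2, d))
  expect_false(identical(predict(m1, d),
                         predict(fit_ann(d, ann_config(seed = 8)), d)))
})

test_that("SVR respects the epsilon tube and solver determinism", {
  d <- linear_trait_table(60, seed = 4)
  dc <- d; dc$LS <- 0.3
  mc <- fit_svr(dc)
  expect_lt(max(abs(predict(mc, dc) - 0.3)), svr_config()$epsilon + 1e-6)
  m1 <- fit_svr(d); m2 <- fit_svr(d)
  expect_equal(predict(m1, d), predict(m2, d), tolerance = 1e-12)
  expect_equal(m1$fit$index, m2$fit$index)
  expect_error(fit_svr(d[1, ]), "two training rows")
})

test_that("SVR under the study config cannot reach exact-zero scores", {
  tab <- gen_trait_table(trait_gen_config(n = 456, seed = 12,
                                          zero_inflation = "censor"))
  m <- fit_svr(tab)
  zero_rows <- tab[tab$LS == 0, ]
  expect_gt(nrow(zero_rows), 20)
  preds <- predict(m, zero_rows)
  expect_true(all(preds > -svr_config()$epsilon))
  # the tube keeps predictions away from the point mass at zero
  expect_gt(mean(preds > 0), 0.9)
})

test_that("forest predictions are means of training responses", {
  d <- linear_trait_table(80, seed = 6)
  dc <- d; dc$LS <- 0.25
  # constant response triggers randomForest's unique-values notice
  mc <- suppressWarnings(fit_rf(dc, rf_config(seed = 2)))
  expect_equal(predict(mc, dc), rep(0.25, 80), tolerance = 1e-12)
  m1 <- fit_rf(d, rf_config(seed = 3))
  preds <- predict(m1, d)
  expect_true(all(preds >= min(d$LS) & preds <= max(d$LS)))
  m2 <- fit_rf(d, rf_config(seed = 3))
  expect_identical(preds, predict(m2, d))
  # training RMSE beats the best constant predictor
  expect_lt(rmse(d$LS, preds), rmse(d$LS, rep(mean(d$LS), 80)))
})

test_that("evaluation pairs predictions with observations per split", {
  d <- linear_trait_table(100, seed = 7)
  m <- stepwise_mlr(d)
  ev <- evaluate_model(m, d, "training")
  expect_equal(ev$report$r2, 1, tolerance = 1e-10)
  expect_equal(ev$report$rmse, 0, tolerance = 1e-10)
  expect_equal(ev$report$coverage25, 1)
  expect_equal(unique(ev$predictions$split), "training")
  expect_error(evaluate_model(m, d[, c("PeD", "IL1", "IL2", "LS")]),
               "missing")
})

test_that("model comparison shares one split and ranks by testing R2", {
  tab <- gen_trait_table(trait_gen_config(n = 200, seed = 10,
                                          zero_inflation = "censor"))
  cmp <- compare_models(tab,
                        list(mlr = mlr_config(), rf = rf_config(seed = 1)),
                        split_seed = 2)
  expect_equal(nrow(cmp$grid), 4)  # 2 models x 2 splits
  expect_equal(unname(cmp$split_sizes), c(150, 50))
  test_rows <- cmp$grid[cmp$grid$split == "testing", ]
  expect_equal(test_rows$rank, order(order(-test_rows$r2, test_rows$rmse)))
  # identical config listed twice gives identical metric rows
  cmp2 <- compare_models(tab,
                         list(a = rf_config(seed = 5),
                              b = rf_config(seed = 5)), split_seed = 2)
  ga <- cmp2$grid[cmp2$grid$model == "a", -1]
  gb <- cmp2$grid[cmp2$grid$model == "b", -1]
  rownames(ga) <- rownames(gb) <- NULL
  expect_equal(ga[setdiff(names(ga), "rank")], gb[setdiff(names(gb), "rank")])
  # single config still yields a well-formed one-model grid
  cmp1 <- compare_models(tab, list(rf = rf_config(seed = 1)))
  expect_equal(unique(cmp1$grid$rank), 1L)
})
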