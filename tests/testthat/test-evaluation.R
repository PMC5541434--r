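test_that("per-drug RMSE follows its closed forms", {
  expect_equal(drug_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(drug_rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  withr::with_seed(1, v <- rnorm(10))
  expect_equal(drug_rmse(v, v + 0.7), 0.7)
  expect_equal(drug_rmse(v, v - 1.2), 1.2)
  expect_error(drug_rmse(numeric(0), numeric(0)), "empty")
  expect_error(drug_rmse(1:3, 1:2), "lengths")
})

test_that("RMSE obeys the triangle-like bound on random vectors", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- rnorm(12); b <- rnorm(12); cc <- rnorm(12)
    })
    expect_lte(drug_rmse(a, cc),
               drug_rmse(a, b) + drug_rmse(b, cc) + 1e-12)
  }
})

test_that("per-drug PCC follows its closed forms and NA contract", {
  v <- c(1.2, -0.5, 2.2, 0.4)
  expect_equal(drug_pcc(v, 2 * v + 1), 1)
  expect_equal(drug_pcc(v, -v), -1)
  expect_equal(drug_pcc(c(1, 2, 3), c(1, 2, 4)), 9 / (2 * sqrt(21)),
               tolerance = 1e-12)
  expect_true(is.na(drug_pcc(c(1, 2), c(3, 4))))        # too few pairs
  expect_true(is.na(drug_pcc(c(1, 1, 1), c(1, 2, 3))))  # zero variance
})

test_that("quartile split tracks the sensitivity direction", {
  vals <- matrix(as.numeric(1:8), 1, 8,
                 dimnames = list("d1", paste0("c", 1:8)))
  R <- response_matrix(vals, "lower_is_sensitive")
  sp <- sensitive_resistant_split(R, "d1")
  expect_setequal(sp$sensitive, c("c1", "c2"))   # two lowest log-IC50
  expect_setequal(sp$resistant, c("c7", "c8"))
  R2 <- response_matrix(vals, "higher_is_sensitive")
  sp2 <- sensitive_resistant_split(R2, "d1")
  expect_setequal(sp2$sensitive, sp$resistant)   # labels swap
  expect_setequal(sp2$resistant, sp$sensitive)
  expect_setequal(c(sp2$sensitive, sp2$resistant),
                  c(sp$sensitive, sp$resistant)) # union unchanged
})

test_that("degenerate drugs are excluded from the quartile split", {
  flat <- matrix(5, 1, 9, dimnames = list("d1", paste0("c", 1:9)))
  R <- response_matrix(flat, "lower_is_sensitive")
  sp <- sensitive_resistant_split(R, "d1")
  expect_s3_class(sp, "sr_split_excluded")
  expect_length(sp, 0)
  expect_match(attr(sp, "reason"), "degenerate")
  few <- matrix(as.numeric(1:6), 1, 6,
                dimnames = list("d1", paste0("c", 1:6)))
  sp2 <- sensitive_resistant_split(response_matrix(few, "lower_is_sensitive"),
                                   "d1")
  expect_s3_class(sp2, "sr_split_excluded")
  expect_match(attr(sp2, "reason"), "fewer than 8")
  expect_error(sensitive_resistant_split(R, "nope"), "unknown drug")
})

test_that("perfect predictions score perfectly", {
  R <- random_response(6, 12, missing = 0.2, seed = 2)
  rep <- evaluate_predictions(R, ifelse(is.na(R$values), 0, R$values))
  defined <- !is.na(rep$per_drug$pcc)
  expect_equal(rep$per_drug$pcc[defined], rep(1, sum(defined)),
               tolerance = 1e-12)
  expect_true(all(rep$per_drug$rmse == 0))
})

test_that("evaluation matches a naive per-drug loop oracle", {
  for (seed in 1:4) {
    R <- random_response(5, 20, missing = 0.25, seed = seed)
    withr::with_seed(seed + 100,
                     pred <- R$values + matrix(rnorm(100, sd = 0.5), 5, 20))
    pred[is.na(pred)] <- 0
    held <- which(R$mask, arr.ind = TRUE)
    rep <- evaluate_predictions(R, pred, heldout = held)
    oracle <- naive_metrics(R, pred, held)
    for (col in c("pcc", "rmse", "pcc_sr", "rmse_sr"))
      expect_equal(rep$per_drug[[col]], oracle[[col]], tolerance = 1e-12,
                   info = paste(col, "seed", seed))
    expect_equal(unname(rep$drug_averaged["pcc"]),
                 mean(oracle$pcc, na.rm = TRUE), tolerance = 1e-12)
  }
})

test_that("drug-averaged metrics are exact means of per-drug columns", {
  R <- random_response(8, 25, missing = 0.3, seed = 3)
  withr::with_seed(7, pred <- matrix(rnorm(200), 8, 25))
  rep <- evaluate_predictions(R, pred)
  for (col in c("pcc", "rmse", "pcc_sr", "rmse_sr")) {
    expect_equal(unname(rep$drug_averaged[col]),
                 mean(rep$per_drug[[col]], na.rm = TRUE))
    expect_equal(unname(rep$excluded[col]), sum(is.na(rep$per_drug[[col]])))
  }
})

test_that("evaluation is invariant to permuting cell lines jointly", {
  R <- random_response(5, 15, missing = 0.2, seed = 4)
  withr::with_seed(5, pred <- matrix(rnorm(75), 5, 15))
  rep1 <- evaluate_predictions(R, pred)
  perm <- withr::with_seed(6, sample(15))
  Rp <- response_matrix(R$values[, perm], R$direction)
  rep2 <- evaluate_predictions(Rp, pred[, perm])
  expect_equal(rep1$drug_averaged, rep2$drug_averaged, tolerance = 1e-12)
  expect_equal(rep1$per_drug$pcc, rep2$per_drug$pcc, tolerance = 1e-12)
})

test_that("fold assignment balances, reproduces, and validates", {
  R <- random_response(10, 10, missing = 0, seed = 5)
  f <- kfold_entries(R, 10, seed = 1)
  expect_equal(as.integer(table(f$fold)), rep(10L, 10))
  expect_equal(f$entries, which(R$mask, arr.ind = TRUE),
               ignore_attr = TRUE)

  R2 <- random_response(10, 11, missing = 9 / 110, seed = 5)  # 101 observed
  expect_equal(sum(R2$mask), 101L)
  f2 <- kfold_entries(R2, 10, seed = 1)
  expect_setequal(as.integer(table(f2$fold)), c(10L, 11L))
  expect_equal(sum(table(f2$fold) == 11L), 1L)

  f3 <- kfold_entries(R, 10, seed = 1)
  expect_identical(f3$fold, f$fold)
  expect_false(identical(kfold_entries(R, 10, seed = 2)$fold, f$fold))
  expect_error(kfold_entries(R, 101), "exceeds")
  expect_error(kfold_entries(R, 1), "at least 2")
})

test_that("cross-validation recovers a noiseless factorizable matrix", {
  inst <- simulate_instance(simulation_config(m = 30, n = 40, k_true = 3,
                                              noise_level = 0,
                                              missing_fraction = 0,
                                              seed = 11))
  cfg <- srmf_config(K = 3, lambda_l = 0.01, lambda_d = 0.01,
                     lambda_c = 0.01, seed = 1)
  rep <- cross_validate(inst$response, inst$Sd, inst$Sc, cfg,
                        k = 5, seed = 3)
  expect_gt(rep$drug_averaged[["pcc"]], 0.99)
  rep2 <- cross_validate(inst$response, inst$Sd, inst$Sc, cfg,
                         k = 5, seed = 3)
  expect_equal(rep$drug_averaged, rep2$drug_averaged)  # same seed, same folds
})

test_that("held-out values can never influence training", {
  R <- random_response(8, 10, missing = 0.1, seed = 12)
  folds <- kfold_entries(R, 4, seed = 2)
  hold <- folds$entries[folds$fold == 1, , drop = FALSE]
  R_tampered <- R
  R_tampered$values[hold] <- R$values[hold] + 100  # rewrite held-out cells
  cfg <- srmf_config(K = 2, lambda_d = 0, lambda_c = 0, max_iter = 30,
                     seed = 1)
  fit1 <- srmf_fit(mask_fold_for_test(R, folds, 1), config = cfg)
  fit2 <- srmf_fit(mask_fold_for_test(R_tampered, folds, 1), config = cfg)
  expect_identical(predict(fit1), predict(fit2))
})

test_that("leave-one-entry-out runs on a tiny complete fixture", {
  inst <- simulate_instance(simulation_config(m = 4, n = 5, k_true = 1,
                                              noise_level = 0,
                                              missing_fraction = 0,
                                              seed = 13))
  cfg <- srmf_config(K = 1, lambda_l = 0.01, lambda_d = 0, lambda_c = 0,
                     max_iter = 30)
  rep <- cross_validate(inst$response, config = cfg, k = 20, seed = 1)
  expect_equal(rep$n_entries, 20L)
})

test_that("grid search returns the argmax with deterministic tie-break", {
  inst <- simulate_instance(simulation_config(m = 12, n = 15, k_true = 2,
                                              noise_level = 0.2, seed = 14))
  cfg <- srmf_config(K = 2, max_iter = 30)
  one <- data.frame(lambda_l = 0.25, lambda_d = 0, lambda_c = 0.5)
  gs1 <- grid_search(inst$response, Sc = inst$Sc, grid = one, config = cfg,
                     k = 2, seed = 1)
  expect_equal(gs1$best_config$lambda_c, 0.5)
  expect_equal(gs1$best_score, gs1$scores$score[1])

  grid <- data.frame(lambda_l = c(0.1, 0.1, 2), lambda_d = 0,
                     lambda_c = c(0.01, 0.5, 0.5))
  gs <- grid_search(inst$response, Sc = inst$Sc, grid = grid, config = cfg,
                    k = 2, seed = 1)
  expect_equal(gs$best_score, max(gs$scores$score))
  expect_equal(which(gs$scores$score == gs$best_score)[1],
               which(gs$scores$lambda_l == gs$best_config$lambda_l &
                     gs$scores$lambda_c == gs$best_config$lambda_c)[1])
  expect_error(grid_search(inst$response, grid = grid[0, ], config = cfg),
               "non-empty")
})

test_that("the default regularization grid enumerates 384 configurations", {
  g <- default_lambda_grid()
  expect_equal(nrow(g), 6 * 8 * 8)
  expect_setequal(unique(g$lambda_l), 2^(-3:2))
  expect_setequal(unique(g$lambda_d), c(2^(-5:1), 0))
  expect_setequal(unique(g$lambda_c), c(2^(-5:1), 0))
  # lexicographic (lambda_l, lambda_d, lambda_c) enumeration order
  expect_equal(g$lambda_l[1:64], rep(2^-3, 64))
  expect_equal(g$lambda_c[1:8], c(2^(-5:1), 0))
})
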