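test_that("background sampling exhausts, reproduces, and is uniform", {
  env <- toy_env(toy_grid(5, 10))
  # Exhaustion: fewer valid cells than requested returns all of them.
  expect_equal(nrow(sample_background(env, 10000, seed = 1)), 50)
  env_masked <- toy_env(toy_grid(5, 10), na_cells_a = 1:10)
  expect_equal(nrow(sample_background(env_masked, 10000, seed = 1)), 40)
  # Determinism.
  big <- toy_env(toy_grid(30, 30))
  expect_identical(sample_background(big, 100, seed = 9),
                   sample_background(big, 100, seed = 9))
  # Per-cell inclusion frequency over many seeds approximates n / N.
  n <- 100
  N <- 900
  hits <- numeric(N)
  for (s in 1:300) {
    bg <- sample_background(big, n, seed = s)
    hits[cell_index(big$grid, bg$row, bg$col)] <-
      hits[cell_index(big$grid, bg$row, bg$col)] + 1
  }
  freq <- hits / 300
  expect_equal(mean(freq), n / N, tolerance = 1e-9) # exact by construction
  expect_lt(max(abs(freq - n / N)), 4 * sqrt((n / N) * (1 - n / N) / 300))
  # No valid cells at all.
  none <- toy_env(toy_grid(2, 2), na_cells_a = 1:4)
  expect_error(sample_background(none, 10), class = "traitstack_no_valid_cells")
})

test_that("fitting recovers an informative layer and respects the ridge limit", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  m <- fit_sdm(fx$presences, fx$background, fx$env, spec, lambda = 0.1)
  expect_gt(m$beta[["lin_a"]], 0)
  # Ridge limit: a huge penalty flattens the suitability surface.
  m_big <- fit_sdm(fx$presences, fx$background, fx$env, spec, lambda = 1e8)
  s <- predict_suitability(m_big, fx$env)
  expect_lt(max(s$values) - min(s$values), 1e-4)
  expect_equal(mean(s$values), 0.5, tolerance = 1e-3)
})

test_that("duplicated presence rows do not change the fit", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  m1 <- fit_sdm(fx$presences, fx$background, fx$env, spec)
  m2 <- fit_sdm(dplyr::bind_rows(fx$presences, fx$presences), fx$background,
                fx$env, spec)
  expect_equal(m1$beta, m2$beta, tolerance = 1e-6)
  expect_equal(m1$tau10, m2$tau10, tolerance = 1e-6)
})

test_that("prediction is the logistic output with prevalence 0.5", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  m <- fit_sdm(fx$presences, fx$background, fx$env, spec)
  # All-zero coefficients predict exactly 0.5 everywhere valid.
  m0 <- m
  m0$beta[] <- 0
  m0$offset <- 0
  s0 <- predict_suitability(m0, fx$env)
  expect_true(all(s0$values == 0.5))
  # A monotone model ranks suitability exactly as the layer.
  m_mono <- m0
  m_mono$beta[["lin_a"]] <- 1
  s <- predict_suitability(m_mono, fx$env)
  expect_equal(cor(as.vector(s$values), as.vector(fx$env$layers$a),
                   method = "spearman"), 1)
  expect_true(all(s$values > 0 & s$values < 1))
  # Projection onto an identical stack reproduces the map; masked cells NA.
  expect_identical(predict_suitability(m, fx$env)$values,
                   predict_suitability(m, fx$env)$values)
  env_masked <- toy_env(toy_grid(20, 20), na_cells_a = 1:5)
  expect_equal(sum(is.na(predict_suitability(m, env_masked)$values)), 5)
  # Missing layer is an error.
  env_short <- env_stack(fx$grid, list(a = fx$env$layers$a))
  expect_error(predict_suitability(m, env_short),
               class = "traitstack_missing_layer")
})

test_that("rank AUC matches its definition and brute force", {
  expect_equal(compute_auc(rep(0.9, 5), rep(0.1, 7)), 1.0)
  expect_equal(compute_auc(c(0.3, 0.5), c(0.3, 0.5)), 0.5)
  expect_equal(compute_auc(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  expect_error(compute_auc(numeric(0), 1), class = "traitstack_too_few")
})

test_that("cross-validation is seeded and boundary cases run", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  ev1 <- crossvalidate(fx$presences, fx$background, fx$env, spec, k = 5,
                       seed = 42, decile = 1)
  ev2 <- crossvalidate(fx$presences, fx$background, fx$env, spec, k = 5,
                       seed = 42, decile = 1)
  expect_identical(attr(ev1, "fold_aucs"), attr(ev2, "fold_aucs"))
  expect_true(ev1$test_auc_mean > 0.7 && ev1$test_auc_mean <= 1)
  expect_true(ev1$train_auc > 0.7)
  # Leave-one-out on 5 presences.
  small <- fx$presences[1:5, ]
  ev_loo <- crossvalidate(small, fx$background, fx$env, spec, k = 5, seed = 1)
  expect_equal(ev_loo$n_occ, 5)
  expect_error(crossvalidate(small, fx$background, fx$env, spec, k = 6),
               class = "traitstack_too_few")
})

test_that("the training-presence threshold honours the nearest-rank rule", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  m <- fit_sdm(fx$presences, fx$background, fx$env, spec)
  # Ten distinct suitabilities: tau is the 2nd smallest, omission 0.10.
  m10 <- m
  m10$presence_suitability <- c(0.15, 0.2, 0.3, 0.35, 0.4, 0.5, 0.6, 0.7,
                                0.8, 0.9)
  s <- predict_suitability(m, fx$env)
  thr <- threshold_10pct(m10, s)
  expect_equal(thr$tau, 0.2)
  expect_equal(thr$omission_rate, 0.10)
  # All-equal suitabilities: tau is that value, omission 0.
  m_eq <- m
  m_eq$presence_suitability <- rep(0.4, 7)
  thr_eq <- threshold_10pct(m_eq, s)
  expect_equal(thr_eq$tau, 0.4)
  expect_equal(thr_eq$omission_rate, 0)
  # Binary map is 0/1 with 1 exactly where suitability >= tau.
  expect_true(all(thr$binary$values %in% c(0L, 1L)))
  expect_identical(thr$binary$values == 1L, s$values >= thr$tau)
  # Thresholding is monotone: a higher cutoff never adds suitable cells.
  m_hi <- m
  m_hi$presence_suitability <- m$presence_suitability + 0.2
  hi <- threshold_10pct(m_hi, s)
  if (hi$tau > thr$tau) {
    expect_true(all(hi$binary$values <= thr$binary$values))
  }
})

test_that("permutation importance isolates the informative layer", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  m <- fit_sdm(fx$presences, fx$background, fx$env, spec, lambda = 0.1)
  # Zero out everything except layer a: importance concentrates at 100%.
  m1 <- m
  m1$beta[!grepl("_a$", names(m1$beta))] <- 0
  vc1 <- variable_contribution(m1, fx$env, seed = 3, n_rep = 5)
  expect_equal(vc1$contribution_pct[vc1$layer == "a"], 100)
  expect_equal(vc1$contribution_pct[vc1$layer == "b"], 0)
  # Percentages always total 100 (when any signal exists).
  vc <- variable_contribution(m, fx$env, seed = 3, n_rep = 5)
  expect_equal(sum(vc$contribution_pct), 100, tolerance = 1e-9)
  # A pure-noise extra layer earns a near-zero share.
  withr::with_seed(8, {
    env3 <- env_stack(fx$grid, c(fx$env$layers,
                                 list(noise = matrix(rnorm(400), 20, 20))))
  })
  m3 <- fit_sdm(fx$presences, fx$background, env3,
                feature_spec(layers = c("a", "b", "noise")), lambda = 0.1)
  vc3 <- variable_contribution(m3, env3, seed = 3, n_rep = 10)
  expect_lt(vc3$contribution_pct[vc3$layer == "noise"], 10)
  expect_gt(vc3$contribution_pct[vc3$layer == "a"], 50)
})

test_that("non-convergence raises a diagnostic error", {
  fx <- separable_fixture()
  spec <- feature_spec(layers = c("a", "b"))
  expect_error(
    fit_sdm(fx$presences, fx$background, fx$env, spec, lambda = 0,
            max_iter = 1),
    class = "traitstack_nonconvergence"
  )
})
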