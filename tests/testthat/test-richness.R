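ones10 <- function(grid = toy_grid(4, 5)) {
  lapply(1:10, function(d) {
    toy_binary(matrix(1L, grid$n_rows, grid$n_cols), grid, decile = d)
  })
}

random_binaries <- function(grid, seed, p = 0.5) {
  withr::with_seed(seed, {
    lapply(1:10, function(d) {
      toy_binary(matrix(rbinom(grid$n_rows * grid$n_cols, 1, p),
                        grid$n_rows, grid$n_cols), grid, decile = d)
    })
  })
}

test_that("stacking equals the cell-wise sum with nodata propagation", {
  grid <- toy_grid(4, 5)
  expect_true(all(stack_richness(ones10(grid))$values == 10L))
  zeros <- lapply(ones10(grid), function(b) {
    b$values[] <- 0L
    b
  })
  expect_true(all(stack_richness(zeros)$values == 0L))
  # Random maps against an independent elementwise-sum oracle.
  bins <- random_binaries(grid, seed = 2)
  r <- stack_richness(bins)
  oracle <- matrix(0L, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      oracle[i, j] <- sum(vapply(bins, function(b) b$values[i, j], integer(1)))
    }
  }
  expect_identical(r$values, oracle)
  expect_true(all(r$values >= 0 & r$values <= 10))
  # Nodata in any input propagates.
  bins[[3]]$values[2, 2] <- NA
  expect_true(is.na(stack_richness(bins)$values[2, 2]))
  # Grid mismatch errors.
  bad <- c(bins[1:9], list(toy_binary(matrix(0L, 3, 3), toy_grid(3, 3))))
  expect_error(stack_richness(bad), class = "traitstack_grid_mismatch")
})

test_that("richness change differences scenarios and flags unsuitable baselines", {
  grid <- toy_grid(2, 2)
  cur <- toy_richness(matrix(c(7L, 0L, 3L, 5L), 2, 2), grid)
  fut <- toy_richness(matrix(c(5L, 0L, 6L, 5L), 2, 2), grid,
                      scenario = scenario_spec("gfdl-cm3", "8.5", "2080s"))
  chg <- richness_change(cur, fut)
  expect_equal(chg$delta, matrix(c(-2L, 0L, 3L, 0L), 2, 2))
  # The 0 -> 0 cell is flagged; the 5 -> 5 cell is a true no-change.
  expect_identical(chg$unsuitable_baseline_mask,
                   matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
  expect_error(richness_change(fut, cur),
               class = "traitstack_scenario_mismatch")
})

test_that("absolute change matches brute force and net loss is antisymmetric", {
  grid <- toy_grid(6, 6)
  withr::with_seed(31, {
    for (i in 1:10) {
      a <- matrix(sample(0:10, 36, replace = TRUE), 6, 6)
      b <- matrix(sample(0:10, 36, replace = TRUE), 6, 6)
      cur <- toy_richness(a, grid)
      fut <- toy_richness(b, grid, scenario_spec("inm-cm4", "4.5", "2050s"))
      chg <- richness_change(cur, fut)
      expect_equal(sum(abs(chg$delta)), sum(abs(b - a)))
      s_fwd <- summarize_change(chg)
      # Swapping current and future negates the net loss.
      rev_chg <- chg
      rev_chg$delta <- -chg$delta
      rev_chg$unsuitable_baseline_mask <- !is.na(b) & b == 0
      s_rev <- summarize_change(rev_chg)
      expect_equal(s_fwd$net_loss, -s_rev$net_loss)
    }
  })
})

test_that("change summaries count losses, gains and magnitudes", {
  grid <- toy_grid(10, 10)
  delta <- matrix(0L, 10, 10)
  delta[1:30] <- -2L
  delta[31:40] <- 3L
  cur_vals <- matrix(5L, 10, 10)
  chg <- richness_change(
    toy_richness(cur_vals, grid),
    toy_richness(cur_vals + delta, grid, scenario_spec("inm-cm4", "4.5", "2050s"))
  )
  s <- summarize_change(chg)
  expect_equal(s$denominator, 100)
  expect_equal(s$percent_loss, 30)
  expect_equal(s$percent_gain, 10)
  expect_equal(s$net_loss, 20)
  expect_equal(s$delta_2, 0)
  expect_equal(s[["delta_-2"]], 30)
  expect_equal(s$delta_3, 10)
  # Histogram consistency: negative columns reconstruct percent_loss.
  neg <- sum(unlist(s[paste0("delta_", -10:-1)]))
  expect_equal(100 * neg / s$denominator, s$percent_loss)
  # Nonzero histogram total equals the changed-cell count.
  changed <- sum(unlist(s[paste0("delta_", c(-10:-1, 1:10))]))
  expect_equal(changed, 40)

  # All-unchanged map: zero net loss, empty magnitude histogram.
  chg0 <- richness_change(
    toy_richness(cur_vals, grid),
    toy_richness(cur_vals, grid, scenario_spec("inm-cm4", "4.5", "2050s"))
  )
  s0 <- summarize_change(chg0)
  expect_equal(s0$net_loss, 0)
  expect_equal(sum(unlist(s0[paste0("delta_", c(-10:-1, 1:10))])), 0)

  # Suitable-only denominator drops baseline-unsuitable cells.
  cur2 <- cur_vals
  cur2[1:20] <- 0L
  chg2 <- richness_change(
    toy_richness(cur2, grid),
    toy_richness(cur2, grid, scenario_spec("inm-cm4", "4.5", "2050s"))
  )
  expect_equal(summarize_change(chg2, denominator_rule = "suitable_only")$denominator,
               80)
  # Empty extent errors.
  expect_error(summarize_change(chg, matrix(FALSE, 10, 10)),
               class = "traitstack_empty_extent")
})

test_that("per-population summaries add up over a partition of the extent", {
  grid <- toy_grid(12, 10)
  withr::with_seed(13, {
    a <- matrix(sample(0:10, 120, replace = TRUE), 12, 10)
    b <- matrix(sample(0:10, 120, replace = TRUE), 12, 10)
  })
  chg <- richness_change(
    toy_richness(a, grid),
    toy_richness(b, grid, scenario_spec("inm-cm4", "4.5", "2050s"))
  )
  parts <- population_extents(grid)
  whole <- summarize_change(chg)
  weighted <- sum(vapply(parts, function(mask) {
    s <- summarize_change(chg, mask)
    s$net_loss * s$denominator
  }, numeric(1))) / whole$denominator
  expect_equal(weighted, whole$net_loss)
})

test_that("percent_area uses half-up rounding to one decimal", {
  expect_equal(percent_area(0, 156659), 0.0)
  expect_equal(percent_area(1, 3), 33.3)
  expect_equal(percent_area(1, 8), 12.5)
  expect_equal(percent_area(125, 1000), 12.5)
  expect_equal(percent_area(15, 200), 7.5)  # 7.5 exactly, stays 7.5
  expect_error(percent_area(1, 0), class = "traitstack_bad_count")
  expect_error(percent_area(5, 3), class = "traitstack_bad_count")
})

test_that("tail frequencies are ratios over the richness >= 1 landscape", {
  grid <- toy_grid(6, 6)
  bins <- random_binaries(grid, seed = 77, p = 0.3)
  r <- stack_richness(bins)
  tf <- tail_frequency(bins, r)
  suitable <- sum(r$values >= 1)
  for (d in c(1, 10)) {
    oracle <- sum(bins[[d]]$values[r$values >= 1] == 1) / suitable
    # The numerator counts decile-d cells anywhere in the extent; with these
    # maps every decile-d presence has richness >= 1 by construction.
    expect_equal(tf$frequency[tf$decile == d], oracle)
  }
  # Decile 1 present wherever suitable -> frequency 1.
  bins1 <- bins
  bins1[[1]]$values <- matrix(as.integer(r$values >= 1), 6, 6)
  r1 <- stack_richness(bins1)
  tf1 <- tail_frequency(bins1, r1)
  expect_equal(tf1$frequency[tf1$decile == 1], 1.0)
  # Decile 10 absent everywhere -> 0.
  bins0 <- bins1
  bins0[[10]]$values[] <- 0L
  tf0 <- tail_frequency(bins0, stack_richness(bins0))
  expect_equal(tf0$frequency[tf0$decile == 10], 0.0)
  # No suitable cells: frequency is missing, not zero.
  empty <- lapply(bins, function(b) {
    b$values[] <- 0L
    b
  })
  tfe <- tail_frequency(empty, stack_richness(empty))
  expect_true(all(is.na(tfe$frequency)))
})

test_that("GCM averaging reports a t-based interval around the mean", {
  rows <- dplyr::bind_rows(lapply(c("inm-cm4", "mpi-esm-lr", "gfdl-cm3"),
    function(g) {
      tibble::tibble(extent = "range", denominator_rule = "all_valid",
                     rcp = "4.5", period = "2050s", gcm = g,
                     net_loss = c("inm-cm4" = 18, "mpi-esm-lr" = 21,
                                  "gfdl-cm3" = 24)[[g]])
    }))
  m <- summarize_across_gcms(rows)
  expect_equal(m$net_loss_mean, 21)
  expect_equal(m$net_loss_lo, 21 - qt(0.975, 2) * 3 / sqrt(3))
})
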