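test_that("combination encoding is a bijection on non-empty decile subsets", {
  expect_equal(encode_combination(1:10), 1023)
  expect_equal(encode_combination(1), 1)
  expect_equal(encode_combination(10), 512)
  expect_error(encode_combination(integer(0)), class = "traitstack_empty_set")
  expect_error(encode_combination(11), class = "traitstack_bad_decile")
  # Exhaustive round trip over all 1023 masks.
  for (m in 1:1023) {
    expect_identical(encode_combination(decode_combination(m)), m)
  }
  # All subsets map to distinct masks; 45 combinations have richness 2.
  richness <- vapply(1:1023, function(m) length(decode_combination(m)),
                     integer(1))
  expect_equal(sum(richness == 2), 45)
  expect_equal(sum(richness == 2), choose(10, 2))
})

test_that("cell similarity rescales mean pairwise decile distance", {
  expect_equal(cell_similarity(4), 1.0)
  expect_equal(cell_similarity(c(1, 10)), 0.0)
  expect_equal(cell_similarity(c(2, 3, 4)), 1 - ((1 + 2 + 1) / 3) / 9)
  # Independent pair-enumeration oracle over random sets.
  oracle <- function(set) {
    if (length(set) == 1) return(1)
    tot <- 0
    npair <- 0
    for (i in seq_along(set)) {
      for (j in seq_along(set)) {
        if (i < j) {
          tot <- tot + abs(set[i] - set[j])
          npair <- npair + 1
        }
      }
    }
    1 - (tot / npair) / 9
  }
  withr::with_seed(21, {
    for (rep in 1:50) {
      set <- sample(1:10, sample(1:10, 1))
      expect_equal(cell_similarity(set), oracle(set))
    }
  })
  # Bounds: 1 only for singletons, 0 only for {1, 10}.
  sims <- vapply(1:1023, function(m) cell_similarity(decode_combination(m)),
                 numeric(1))
  expect_true(all(sims >= 0 & sims <= 1))
  expect_identical(which(sims == 1), as.integer(2^(0:9)))
  expect_identical(which(sims == 0), encode_combination(c(1, 10)))
})

test_that("dropping the most extreme decile never lowers similarity", {
  # Exhaustive over all masks with >= 2 deciles: remove the endpoint
  # farthest from the set mean (ties to the late end).
  for (m in 1:1023) {
    set <- decode_combination(m)
    if (length(set) < 2) next
    extreme <- if (max(set) - mean(set) >= mean(set) - min(set)) {
      max(set)
    } else {
      min(set)
    }
    expect_gte(cell_similarity(setdiff(set, extreme)) + 1e-12,
               cell_similarity(set))
  }
})

test_that("the community matrix tallies cells by combination", {
  grid <- toy_grid(6, 6)
  # Every suitable cell supports exactly deciles {2, 3}.
  bins <- lapply(1:10, function(d) {
    v <- matrix(0L, 6, 6)
    if (d %in% c(2, 3)) v[1:12] <- 1L
    toy_binary(v, grid, decile = d)
  })
  extents <- list(central = matrix(TRUE, 6, 6))
  cm <- build_community_matrix(list(bins), list(scenario_spec()), extents)
  expect_equal(sum(cm$counts > 0), 1)
  expect_equal(unname(cm$counts[1, encode_combination(c(2, 3))]), 12)

  # Row sums equal the suitable-cell counts from the stacked map.
  bins_r <- lapply(1:10, function(d) {
    withr::with_seed(100 + d,
      toy_binary(matrix(rbinom(36, 1, 0.3), 6, 6), grid, decile = d))
  })
  cm_r <- build_community_matrix(list(bins_r), list(scenario_spec()), extents)
  richness <- stack_richness(bins_r)
  expect_equal(unname(rowSums(cm_r$counts)), sum(richness$values >= 1))
  # Each counted mask's popcount matches the richness of its cells.
  tl <- tidy(cm_r)
  expect_true(all(tl$richness == popcount10(tl$mask)))

  # Disjoint population extents tally independently.
  top <- matrix(FALSE, 6, 6)
  top[1:3, ] <- TRUE
  cm2 <- build_community_matrix(list(bins_r), list(scenario_spec()),
                                list(northern = top, southern = !top))
  expect_equal(unname(colSums(cm2$counts)), unname(cm_r$counts[1, ]))
})

test_that("scenario similarity is the count-weighted cell similarity", {
  grid <- toy_grid(4, 4)
  mk <- function(sets, scenario) {
    # sets: list mapping each of the 16 cells to a decile set (or NULL).
    lapply(1:10, function(d) {
      v <- matrix(0L, 4, 4)
      for (i in seq_along(sets)) {
        if (d %in% sets[[i]]) v[i] <- 1L
      }
      toy_binary(v, grid, decile = d)
    })
  }
  extents <- list(central = matrix(TRUE, 4, 4))
  sc_fut <- scenario_spec("inm-cm4", "4.5", "2050s")
  # Current: all singletons -> similarity 1. Future: half {1,10}, half {5}.
  sets_cur <- rep(list(5), 16)
  sets_fut <- c(rep(list(c(1, 10)), 8), rep(list(5), 8))
  cm <- build_community_matrix(
    list(mk(sets_cur, scenario_spec()), mk(sets_fut, sc_fut)),
    list(scenario_spec(), sc_fut), extents
  )
  sim <- scenario_similarity(cm)
  expect_equal(sim$similarity[sim$period == "current"], 1.0)
  expect_equal(sim$similarity[sim$period != "current"], 0.5)
  # Baseline delta of current against itself is zero by construction.
  expect_equal(sim$baseline_delta[sim$period == "current"], 0)
  expect_equal(sim$baseline_delta[sim$period != "current"], -0.5)
})

test_that("the constrained fraction matches an explicit hat-matrix oracle", {
  withr::with_seed(99, {
    Y <- matrix(rnorm(24), 4, 6)
    groups <- factor(c("a", "a", "b", "b"))
  })
  res <- rda_communities(Y, data.frame(g = groups), permutations = 49,
                         seed = 5)
  # Oracle: explicit projection matrix H = X (X'X)^-1 X'.
  X <- cbind(1, as.numeric(groups == "b"))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  oracle <- sum((H %*% Yc)^2) / sum(Yc^2)
  expect_equal(res$constrained_fraction, oracle)

  # Saturated constraints (one level per row) explain everything.
  sat <- rda_communities(Y, data.frame(g = factor(1:4)), permutations = 49,
                         seed = 5)
  expect_equal(sat$constrained_fraction, 1.0)
  # A constant constraint explains nothing.
  none <- rda_communities(Y, data.frame(g = factor(rep("x", 4))),
                          permutations = 49, seed = 5)
  expect_equal(none$constrained_fraction, 0)
  # Genuinely aliased constraints raise an error naming the aliased columns.
  expect_error(
    rda_communities(Y, data.frame(g = groups, h = groups), permutations = 9,
                    seed = 1),
    class = "traitstack_aliased_constraints"
  )
})

test_that("our constrained fraction agrees with vegan's RDA", {
  withr::with_seed(123, {
    Y <- matrix(rpois(60, 4), 6, 10)
    groups <- factor(c("a", "a", "b", "b", "c", "c"))
  })
  ours <- rda_communities(Y, data.frame(g = groups), permutations = 49,
                          seed = 2)
  fit <- vegan::rda(Y ~ g, data = data.frame(g = groups))
  expect_equal(ours$constrained_fraction,
               fit$CCA$tot.chi / fit$tot.chi, tolerance = 1e-10)
})

test_that("stepwise selection finds planted structure and stops when saturated", {
  withr::with_seed(42, {
    n <- 24
    g <- factor(rep(c("a", "b", "c"), each = 8))
    noise1 <- factor(sample(rep(c("x", "y"), n / 2)))
    noise2 <- factor(sample(rep(c("u", "v", "w"), n / 3)))
    signal <- matrix(0, n, 8)
    signal[g == "b", 1:4] <- 6
    signal[g == "c", 5:8] <- 6
    Y <- signal + matrix(rnorm(n * 8), n, 8)
  })
  sel <- select_constraints(Y, data.frame(g = g, n1 = noise1, n2 = noise2),
                            permutations = 199, seed = 7)
  expect_identical(sel$selected, "g")
  # With the saturated factor already in, nothing further is addable.
  # A saturated candidate (one level per row) leaves no residual df: it is
  # never testable, hence never selected.
  sat <- select_constraints(Y, data.frame(id = factor(1:24), g = g),
                            permutations = 99, seed = 7)
  expect_false("id" %in% sat$selected)
})
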