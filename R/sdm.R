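#' Feature specification for the presence-background model
#'
#' Describes how raw environmental layers are expanded into model features.
#' Layers are standardized with per-layer normalization constants (mean, sd)
#' estimated once at fit time from the training cells and reused verbatim for
#' every projection, so predictions depend only on layer values and the
#' stored normalizers. Available feature classes: `linear` (always present),
#' `quadratic`, `product` (pairwise interactions) and `hinge` (one-sided
#' ramps at training quantile knots). A layer flagged categorical is
#' dummy-coded from its training levels and excluded from the nonlinear
#' classes.
#'
#' @param layers Character vector of layer names the model uses.
#' @param classes Feature classes, subset of
#'   `c("linear", "quadratic", "product", "hinge")`; must include `linear`.
#' @param categorical Names of layers to dummy-code.
#' @param hinge_knots Number of hinge knots per continuous layer (used when
#'   `"hinge"` is in `classes`).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(layers = c("cmi", "ppt_wt", "rh", "td", "stream_order"),
                         classes = c("linear", "quadratic"),
                         categorical = character(),
                         hinge_knots = 4) {
  classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  if (!"linear" %in% classes) {
    ts_abort("feature classes must include 'linear'", "spec_invalid")
  }
  structure(
    list(layers = layers, classes = classes, categorical = categorical,
         hinge_knots = hinge_knots, norm = NULL, knots = NULL, levels = NULL),
    class = "feature_spec"
  )
}

# Estimate normalization constants (and hinge knots / categorical levels)
# from the training design rows. X is a cells-by-layers matrix of raw values.
calibrate_spec <- function(spec, X) {
  cont <- setdiff(spec$layers, spec$categorical)
  norm <- lapply(cont, function(nm) {
    v <- X[, nm]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      ts_abort(sprintf("degenerate normalization for layer '%s' (sd = 0)", nm),
               "degenerate_norm")
    }
    c(mean = mean(v), sd = s)
  })
  names(norm) <- cont
  spec$norm <- norm
  if ("hinge" %in% spec$classes) {
    spec$knots <- lapply(cont, function(nm) {
      z <- (X[, nm] - norm[[nm]]["mean"]) / norm[[nm]]["sd"]
      unname(quantile(z, probs = seq_len(spec$hinge_knots) /
                        (spec$hinge_knots + 1)))
    })
    names(spec$knots) <- cont
  }
  if (length(spec$categorical) > 0) {
    spec$levels <- lapply(spec$categorical, function(nm) sort(unique(X[, nm])))
    names(spec$levels) <- spec$categorical
  }
  spec
}

# Expand raw layer values into the feature matrix using the spec's stored
# normalization constants (spec must be calibrated).
expand_features <- function(spec, X) {
  if (is.null(spec$norm)) {
    ts_abort("feature_spec has no normalization constants (not calibrated)",
             "spec_invalid")
  }
  missing_layers <- setdiff(spec$layers, colnames(X))
  if (length(missing_layers) > 0) {
    ts_abort(paste("missing layer(s):", paste(missing_layers, collapse = ", ")),
             "missing_layer")
  }
  cont <- setdiff(spec$layers, spec$categorical)
  Z <- vapply(cont, function(nm) {
    (X[, nm] - spec$norm[[nm]]["mean"]) / spec$norm[[nm]]["sd"]
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) Z <- matrix(Z, nrow = 1, dimnames = list(NULL, cont))
  cols <- list()
  for (nm in cont) cols[[paste0("lin_", nm)]] <- Z[, nm]
  if ("quadratic" %in% spec$classes) {
    for (nm in cont) cols[[paste0("quad_", nm)]] <- Z[, nm]^2
  }
  if ("product" %in% spec$classes && length(cont) > 1) {
    pairs <- utils::combn(cont, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      cols[[paste0("prod_", a, "_", b)]] <- Z[, a] * Z[, b]
    }
  }
  if ("hinge" %in% spec$classes) {
    for (nm in cont) {
      for (k in seq_along(spec$knots[[nm]])) {
        cols[[sprintf("hinge_%s_%d", nm, k)]] <-
          pmax(0, Z[, nm] - spec$knots[[nm]][k])
      }
    }
  }
  for (nm in spec$categorical) {
    for (lv in spec$levels[[nm]]) {
      cols[[sprintf("cat_%s_%s", nm, format(lv))]] <- as.numeric(X[, nm] == lv)
    }
  }
  do.call(cbind, cols)
}

#' Sample background cells
#'
#' Uniform sample without replacement from the valid cells of the stack (all
#' of them when fewer than `n` exist). Presence cells are deliberately not
#' excluded, following presence-background convention.
#'
#' @param env An [env_stack()].
#' @param n Target sample size (default 10000).
#' @param seed Integer seed.
#' @return Tibble of 0-based `row`, `col` cells.
#' @export
sample_background <- function(env, n = 10000, seed = 1L) {
  stopifnot(inherits(env, "env_stack"))
  valid <- which(env$valid_mask)
  if (length(valid) == 0) ts_abort("no valid cells to sample", "no_valid_cells")
  pick <- if (length(valid) <= n) {
    valid
  } else {
    withr::with_seed(as.integer(seed), sample(valid, n))
  }
  nr <- env$grid$n_rows
  tibble::tibble(row = (pick - 1L) %% nr, col = (pick - 1L) %/% nr)
}

#' Fit a presence-background distribution model
#'
#' Maximizes the ridge-penalized log-likelihood of the weighted-logistic
#' formulation of maximum-entropy presence-background modelling: presence
#' rows carry total weight 1 and background rows total weight 100, so the
#' solution approaches the maximum-entropy fit while remaining an ordinary
#' penalized GLM (and is invariant to duplicating presence rows). Fitting is
#' Newton/IRLS with penalty `lambda` on all non-intercept coefficients of the
#' standardized features.
#'
#' @param presences Tibble of 0-based `row`, `col` presence cells (>= 2), as
#'   produced by [thin_presences()] (one decile's rows).
#' @param background Tibble of background cells from [sample_background()].
#' @param env Training [env_stack()].
#' @param spec A [feature_spec()].
#' @param lambda Ridge penalty on standardized features (default 1).
#' @param max_iter Iteration cap; exceeding it raises a non-convergence error
#'   carrying diagnostics.
#' @param tol Convergence tolerance on the coefficient update.
#' @param decile Optional decile index carried in the model object.
#' @return An object of class `sdm_model` with coefficients, the calibrated
#'   feature spec, the logistic-output normalizer, training threshold
#'   \eqn{\tau_{10}} and training cells.
#' @export
fit_sdm <- function(presences, background, env, spec = feature_spec(),
                    lambda = 1.0, max_iter = 500, tol = 1e-8, decile = NA) {
  presences <- tibble::as_tibble(presences)
  background <- tibble::as_tibble(background)
  if (nrow(presences) < 2) ts_abort("need at least 2 presences", "too_few")
  if (nrow(background) < 1) ts_abort("background is empty", "too_few")
  missing_layers <- setdiff(spec$layers, names(env$layers))
  if (length(missing_layers) > 0) {
    ts_abort(paste("missing layer(s):", paste(missing_layers, collapse = ", ")),
             "missing_layer")
  }
  Xp <- extract_cells(env, presences, spec$layers)
  Xb <- extract_cells(env, background, spec$layers)
  # Normalization constants come from the background sample alone (the
  # presence-background convention); the fit is then exactly invariant to
  # duplicating presence rows, since presence mass is normalized to 1.
  spec <- calibrate_spec(spec, Xb)
  Fp <- expand_features(spec, Xp)
  Fb <- expand_features(spec, Xb)
  X <- rbind(Fp, Fb)
  y <- c(rep(1, nrow(Fp)), rep(0, nrow(Fb)))
  # Normalized weights: presence mass 1, background mass 100.
  w <- c(rep(1 / nrow(Fp), nrow(Fp)), rep(100 / nrow(Fb), nrow(Fb)))
  fit <- ridge_logistic_irls(X, y, w, lambda, max_iter, tol)
  # Maximum-entropy logistic output with default prevalence 0.5:
  # s(x) = plogis(eta(x) - E_q[eta]) where q is the fitted exponential
  # distribution over the background sample. The intercept cancels.
  eta_b <- drop(Fb %*% fit$beta)
  q <- exp(eta_b - max(eta_b))
  q <- q / sum(q)
  offset <- sum(q * eta_b)
  model <- structure(
    list(
      decile = decile, spec = spec,
      beta = stats::setNames(fit$beta, colnames(X)),
      intercept = fit$intercept, offset = offset,
      lambda = lambda, n_iter = fit$n_iter,
      presence_cells = presences[, c("row", "col")],
      background_cells = background[, c("row", "col")]
    ),
    class = "sdm_model"
  )
  model$presence_suitability <- drop(plogis(Fp %*% fit$beta - offset))
  thr <- presence_threshold(model$presence_suitability, percentile = 10)
  model$tau10 <- thr$tau
  model$omission_rate <- thr$omission
  model
}

# Newton/IRLS for the weighted logistic likelihood with ridge penalty on the
# slope coefficients (intercept unpenalized).
ridge_logistic_irls <- function(X, y, w, lambda, max_iter, tol) {
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- rep(0, p)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    v <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(Xd, w * (y - mu))) - drop(pen %*% beta)
    H <- crossprod(Xd * (w * v), Xd) + pen
    step <- solve(H, grad)
    beta <- beta + step
    delta <- max(abs(step))
    if (delta < tol) {
      return(list(beta = beta[-1], intercept = beta[1], n_iter = it))
    }
  }
  ts_abort(
    sprintf("IRLS did not converge in %d iterations (last update %.3g)",
            max_iter, delta),
    "nonconvergence", iterations = max_iter, last_update = delta
  )
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf(
    "<sdm_model> decile %s: %d features, lambda = %g, %d presences, %d background, tau10 = %.3f\n",
    format(x$decile), length(x$beta), x$lambda, nrow(x$presence_cells),
    nrow(x$background_cells), x$tau10
  ))
  invisible(x)
}

#' Predict habitat suitability
#'
#' Logistic-output suitability in (0, 1) for every valid cell of a stack,
#' using the model's stored normalization constants (projection onto a future
#' stack never re-normalizes). A model with all-zero coefficients predicts
#' 0.5 everywhere, the default-prevalence baseline.
#'
#' @param model An [fit_sdm()] model.
#' @param env An [env_stack()] providing all layers in the model's spec.
#' @return A `suitability_map`: list with `grid`, `values` (matrix in (0,1),
#'   `NA` at masked cells), `decile`.
#' @export
predict_suitability <- function(model, env) {
  stopifnot(inherits(model, "sdm_model"), inherits(env, "env_stack"))
  missing_layers <- setdiff(model$spec$layers, names(env$layers))
  if (length(missing_layers) > 0) {
    ts_abort(paste("missing layer(s):", paste(missing_layers, collapse = ", ")),
             "missing_layer")
  }
  ncell <- env$grid$n_rows * env$grid$n_cols
  X <- vapply(model$spec$layers, function(nm) as.vector(env$layers[[nm]]),
              numeric(ncell))
  s <- suitability_at(model, X)
  vals <- matrix(s, env$grid$n_rows, env$grid$n_cols)
  vals[!env$valid_mask] <- NA
  structure(list(grid = env$grid, values = vals, decile = model$decile),
            class = "suitability_map")
}

# Suitability for a raw-layer value matrix (columns = model layers).
suitability_at <- function(model, X) {
  Fm <- expand_features(model$spec, X)
  drop(plogis(Fm %*% model$beta - model$offset))
}

#' Rank-based AUC for presence versus background scores
#'
#' Mann-Whitney AUC: the probability that a random presence outscores a
#' random background point, with half credit for ties.
#'
#' @param presence_scores,background_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores)
  nb <- length(background_scores)
  if (np == 0 || nb == 0) {
    ts_abort("both score vectors must be non-empty", "too_few")
  }
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Cross-validate a decile model
#'
#' Seeded random partition of the presences into `k` folds; each fold is held
#' out, the model refitted on the rest, and held-out presences scored against
#' the full background sample (presence-background test AUC). A final model
#' on all presences supplies the training AUC, threshold and omission rate.
#'
#' @inheritParams fit_sdm
#' @param k Number of folds (default 5); `k = n` gives leave-one-out.
#' @param seed Integer seed for the fold assignment.
#' @return An `sdm_eval` one-row tibble: `decile`, `n_occ`, `n_background`,
#'   `test_auc_mean`, `test_auc_sd`, `train_auc`, `tau10`, `omission_rate`,
#'   plus the final model in the `model` attribute.
#' @export
crossvalidate <- function(presences, background, env, spec = feature_spec(),
                          lambda = 1.0, k = 5, seed = 1L, decile = NA) {
  presences <- tibble::as_tibble(presences)
  n <- nrow(presences)
  if (k > n) {
    ts_abort(sprintf("k = %d exceeds the number of presences (%d)", k, n),
             "too_few")
  }
  folds <- withr::with_seed(as.integer(seed),
                            sample(rep(seq_len(k), length.out = n)))
  aucs <- vapply(seq_len(k), function(fold) {
    train <- presences[folds != fold, , drop = FALSE]
    test <- presences[folds == fold, , drop = FALSE]
    m <- fit_sdm(train, background, env, spec, lambda)
    Xt <- extract_cells(env, test, m$spec$layers)
    Xb <- extract_cells(env, background, m$spec$layers)
    compute_auc(suitability_at(m, Xt), suitability_at(m, Xb))
  }, numeric(1))
  final <- fit_sdm(presences, background, env, spec, lambda, decile = decile)
  Xp <- extract_cells(env, presences, final$spec$layers)
  Xb <- extract_cells(env, background, final$spec$layers)
  train_auc <- compute_auc(suitability_at(final, Xp), suitability_at(final, Xb))
  out <- tibble::tibble(
    decile = decile, n_occ = n, n_background = nrow(background),
    test_auc_mean = mean(aucs), test_auc_sd = sd(aucs),
    train_auc = train_auc, tau10 = final$tau10,
    omission_rate = final$omission_rate
  )
  structure(out, model = final, fold_aucs = aucs,
            class = c("sdm_eval", class(out)))
}

# Training-presence threshold: the largest presence suitability v whose
# strictly-below fraction does not exceed percentile/100 (nearest-rank rule;
# omission is guaranteed <= percentile/100).
presence_threshold <- function(scores, percentile = 10) {
  n <- length(scores)
  frac_below <- vapply(scores, function(v) mean(scores < v), numeric(1))
  tau <- max(scores[frac_below <= percentile / 100])
  list(tau = tau, omission = mean(scores < tau))
}

#' Binarize a suitability map at the 10% training presence threshold
#'
#' \eqn{\tau_{10}} is the largest training-presence suitability such that the
#' fraction of training presences scoring strictly below it is at most 10%
#' (nearest-rank); cells with suitability `>= tau` become 1, others 0. The
#' resulting omission rate never exceeds 10%.
#'
#' @param model An [fit_sdm()] model (supplies the training threshold).
#' @param suitability A [predict_suitability()] map.
#' @param percentile Threshold percentile (default 10).
#' @return A list with `binary` (a `binary_map`), `tau` and `omission_rate`.
#' @export
threshold_10pct <- function(model, suitability, percentile = 10) {
  stopifnot(inherits(model, "sdm_model"), inherits(suitability, "suitability_map"))
  thr <- presence_threshold(model$presence_suitability, percentile)
  vals <- matrix(NA_integer_, suitability$grid$n_rows, suitability$grid$n_cols)
  ok <- !is.na(suitability$values)
  vals[ok] <- as.integer(suitability$values[ok] >= thr$tau)
  binary <- structure(
    list(grid = suitability$grid, values = vals, decile = model$decile,
         tau = thr$tau),
    class = "binary_map"
  )
  list(binary = binary, tau = thr$tau, omission_rate = thr$omission)
}

#' Permutation importance of environmental layers
#'
#' Importance of a layer is the drop in training AUC when that layer's raw
#' values are permuted across the evaluation points (training presences plus
#' background), averaged over `n_rep` permutations, floored at zero and
#' normalized to sum to 100. This replaces path-dependent "percent
#' contribution" measures with a fit-agnostic one.
#'
#' @param model An [fit_sdm()] model.
#' @param env The training [env_stack()].
#' @param seed Integer seed for the permutations.
#' @param n_rep Permutations per layer.
#' @return Tibble with columns `layer`, `auc_drop`, `contribution_pct`.
#' @export
variable_contribution <- function(model, env, seed = 1L, n_rep = 10) {
  stopifnot(inherits(model, "sdm_model"))
  Xp <- extract_cells(env, model$presence_cells, model$spec$layers)
  Xb <- extract_cells(env, model$background_cells, model$spec$layers)
  X <- rbind(Xp, Xb)
  np <- nrow(Xp)
  base_auc <- compute_auc(suitability_at(model, X)[seq_len(np)],
                          suitability_at(model, X)[-seq_len(np)])
  drops <- withr::with_seed(as.integer(seed), {
    vapply(model$spec$layers, function(nm) {
      mean(vapply(seq_len(n_rep), function(rep) {
        Xperm <- X
        Xperm[, nm] <- sample(Xperm[, nm])
        s <- suitability_at(model, Xperm)
        base_auc - compute_auc(s[seq_len(np)], s[-seq_len(np)])
      }, numeric(1)))
    }, numeric(1))
  })
  drops <- pmax(drops, 0)
  pct <- if (sum(drops) > 0) 100 * drops / sum(drops) else drops * 0
  tibble::tibble(layer = model$spec$layers, auc_drop = unname(drops),
                 contribution_pct = unname(pct))
}
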