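test_that("feature matrices append an intercept and round-trip scaling", {
  acts <- fake_acts(40, units = rep(64, 8), seed = 41)
  X <- build_feature_matrix(acts, stage = "L3")
  expect_equal(dim(X), c(40, 65))
  expect_true(all(X[, 65] == 1))
  expect_equal(unname(colMeans(X[, 1:64])), rep(0, 64), tolerance = 1e-12)

  # de-standardization round-trips the original activations
  back <- sweep(sweep(X[, 1:64], 2, attr(X, "scale"), `*`), 2,
                attr(X, "center"), `+`)
  expect_equal(max(abs(back - acts$L3)), 0, tolerance = 1e-10)

  # stored scaling is reused verbatim at test time
  X2 <- build_feature_matrix(acts$L3 + 1, scaling = list(
    center = attr(X, "center"), scale = attr(X, "scale")))
  expect_equal(unname(X2[, 1:64] - X[, 1:64]),
               matrix(1 / attr(X, "scale"), 40, 64, byrow = TRUE),
               tolerance = 1e-10)

  # zero-variance columns survive standardization
  A <- cbind(rnorm(10), rep(2, 10))
  Xz <- build_feature_matrix(A)
  expect_true(all(is.finite(Xz)))
})

test_that("ROMP solves trivial and orthonormal instances exactly", {
  # zero response: empty support, zero intercept, zero residual
  X <- build_feature_matrix(matrix(rnorm(80), 16, 5))
  s0 <- romp_solve(X, rep(0, 16))
  expect_length(s0$support, 0)
  expect_equal(s0$w, rep(0, 6))
  expect_equal(s0$residual_norm, 0)

  # orthonormal columns orthogonal to the intercept: y = 3 * column 2
  set.seed(42)
  m <- 16
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(m * 4), m, 4))))
  Q[, 1] <- Q[, 1] * sign(Q[1, 1])          # fix QR sign indeterminacy
  Xo <- cbind(Q[, 2:5], Q[, 1] * sqrt(m))   # last column is all-ones
  expect_equal(unname(Xo[, 5]), rep(1, m), tolerance = 1e-12)
  y <- 3 * Xo[, 2]
  so <- romp_solve(Xo, y, sparsity_s = 2)
  expect_equal(so$support, 2L)
  expect_equal(so$w[2], 3, tolerance = 1e-10)
  expect_equal(so$w[c(1, 3, 4)], rep(0, 3))
  expect_lt(so$residual_norm, 1e-10)
})

test_that("ROMP matches exhaustive-subset least squares on sparse problems", {
  # noiseless 3-sparse targets, m = 20 rows, n = 40 features
  exhaustive <- function(X, y, k) {
    feat <- seq_len(ncol(X) - 1L)
    best <- NULL
    best_rss <- Inf
    for (cmb in utils::combn(feat, k, simplify = FALSE)) {
      cols <- c(cmb, ncol(X))
      f <- stats::lm.fit(X[, cols, drop = FALSE], y)
      rss <- sum(f$residuals^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- list(support = cmb, coef = f$coefficients)
      }
    }
    best
  }
  set.seed(43)
  for (trial in 1:3) {
    A <- matrix(rnorm(20 * 40), 20, 40)
    X <- build_feature_matrix(A)
    support_true <- sample(40, 3)
    w_true <- runif(3, 1, 2) * sample(c(-1, 1), 3, replace = TRUE)
    y <- as.vector(X[, support_true, drop = FALSE] %*% w_true) + 0.7
    sol <- romp_solve(X, y, sparsity_s = 3)
    expect_true(all(support_true %in% sol$support))
    expect_lt(sol$residual_norm, 1e-6 * sqrt(sum(y^2)) + 1e-9)
    oracle <- exhaustive(X, y, 3)
    expect_setequal(oracle$support, support_true)
    w_oracle <- numeric(41)
    w_oracle[c(oracle$support, 41)] <- oracle$coef
    expect_lt(max(abs(sol$w[support_true] - w_oracle[support_true])), 1e-6)
  }
})

test_that("ROMP respects its support cap and decreases the residual", {
  set.seed(44)
  X <- build_feature_matrix(matrix(rnorm(30 * 80), 30, 80))
  y <- rnorm(30)
  for (s in c(1, 3, 5)) {
    sol <- romp_solve(X, y, sparsity_s = s)
    expect_lte(length(sol$support), 2 * s)
    expect_true(all(sol$w[setdiff(seq_len(80), sol$support)] == 0))
    r_intercept <- sqrt(sum((y - mean(y))^2))
    expect_lte(sol$residual_norm, r_intercept + 1e-12)
  }
  expect_error(romp_solve(X, y, sparsity_s = 0), "sparsity_s")
  expect_error(romp_solve(X, rnorm(10)), "nrow")
})

test_that("the model bank covers every (ROI, stage) combination", {
  sheet <- make_sheet(6, seed = 45)
  acts <- fake_acts(20, units = rep(30, 8), seed = 45)
  rd <- simulate_vertex_responses(acts, sheet, rep_noise_sd = 0.2, seed = 45)
  cm <- splithalf_consistency(rd, sheet)
  sel <- select_vertices(cm, sheet, n_per_hemisphere = 3)
  bank <- train_models(rd, acts, sel, sparsity_s = 3)
  expect_s3_class(bank, "encoding_bank")
  expect_length(bank$models, 5)
  expect_true(all(vapply(bank$models, length, integer(1)) == 8))
  expect_equal(length(bank$rois) * length(bank$stages), 40)
  expect_true(all(vapply(bank$models[["V1"]], length, integer(1)) == 6))
})

test_that("noiseless sparse vertices are fit to machine precision", {
  set.seed(46)
  acts <- fake_acts(24, units = rep(40, 8), seed = 46)
  sheet <- make_sheet(4, seed = 46)
  rd <- simulate_vertex_responses(acts, sheet, sparsity_k = 3,
                                  rep_noise_sd = 0, seed = 46)
  cm <- data.frame(vertex_id = sheet$vertex_id,
                   consistency = runif(nrow(sheet)))
  sel <- select_vertices(cm, sheet, n_per_hemisphere = 2)
  bank <- train_models(rd, acts, sel, sparsity_s = 3)
  layer_of <- rd$ground_truth$layer
  for (roi in bank$rois) {
    for (i in seq_along(bank$vertices[[roi]])) {
      v <- bank$vertices[[roi]][i]
      st <- paste0("L", layer_of[v])
      sol <- bank$models[[roi]][[st]][[i]]
      expect_lt(sol$residual_norm,
                1e-6 * sqrt(sum(response_patterns(rd, "RE")[v, ]^2)) + 1e-8)
    }
  }

  # zero-response vertex gives a zero-weight model
  rd0 <- rd
  rd0$betas[sel$vertex_id[1], seq_len(24), ] <- 0
  bank0 <- train_models(rd0, acts, sel[1, , drop = FALSE], sparsity_s = 3)
  sol0 <- bank0$models[[sel$roi[1]]][["L1"]][[1]]
  expect_true(all(sol0$w == 0))
})

test_that("generalization testing recovers exact and null regimes", {
  set.seed(47)
  sheet <- make_sheet(40, seed = 47)   # 400 vertices
  acts <- fake_acts(40, units = rep(50, 8), seed = 47)
  rd <- simulate_vertex_responses(acts, sheet, rho_AI = 1, rho_AN = 0,
                                  rep_noise_sd = 0, seed = 47)
  cm <- data.frame(vertex_id = sheet$vertex_id,
                   consistency = runif(nrow(sheet)))
  sel <- select_vertices(cm, sheet, n_per_hemisphere = 30)
  bank <- train_models(rd, acts, sel, stages = "L3", sparsity_s = 3)

  # measured responses equal to the model predictions: r = 1 everywhere
  exact <- rd
  for (roi in bank$rois) {
    pred <- predict(bank, acts, roi = roi, stage = "L3")
    ai_cols <- which(rd$image_info$type == "AI")
    for (r in 1:2) {
      exact$betas[bank$vertices[[roi]], ai_cols, r] <- t(pred)
    }
  }
  gen <- test_generalization(bank, acts, exact, type = "AI", n_boot = 50,
                             n_perm = 50, seed = 1)
  expect_equal(nrow(gen), 5)
  expect_equal(gen$mean_r, rep(1, 5), tolerance = 1e-8)

  # fully decoupled measured responses: per-cell mean r (60 vertices x 40
  # images) within +-0.1 of zero
  gen_an <- test_generalization(bank, acts, rd, type = "AN", n_boot = 50,
                                n_perm = 50, seed = 1)
  expect_lt(max(abs(gen_an$mean_r)), 0.1)
})

test_that("generalization accuracy tracks the coupling and swaps with it", {
  acts <- fake_acts(40, units = rep(40, 8), seed = 48)
  adv_acts <- lapply(acts, function(a) a + matrix(rnorm(length(a), sd = 0.1),
                                                  nrow(a)))
  sheet <- make_sheet(6, seed = 48)
  cm <- data.frame(vertex_id = sheet$vertex_id, consistency = 0.9)
  sel <- select_vertices(cm, sheet, n_per_hemisphere = 3)

  run_one <- function(rho_ai, rho_an, seed) {
    rd <- simulate_vertex_responses(acts, sheet, rho_AI = rho_ai,
                                    rho_AN = rho_an, rep_noise_sd = 0.2,
                                    seed = seed)
    bank <- train_models(rd, acts, sel, sparsity_s = 3)
    ai <- test_generalization(bank, adv_acts, rd, type = "AI", n_boot = 10,
                              n_perm = 10, seed = seed)
    an <- test_generalization(bank, adv_acts, rd, type = "AN", n_boot = 10,
                              n_perm = 10, seed = seed)
    c(ai = mean(ai$mean_r), an = mean(an$mean_r))
  }

  # monotone recovery over the coupling grid, 10 seeds
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  curves <- sapply(seq_along(rhos), function(j) {
    mean(vapply(1:10, function(s) {
      run_one(rhos[j], 0, seed = 100 * s + j)[["ai"]]
    }, numeric(1)))
  })
  expect_gte(cor(curves, rhos, method = "spearman"), 0.9)

  # swapping the generators swaps the accuracy ordering
  fwd <- run_one(0.8, 0, seed = 7)
  swp <- run_one(0, 0.8, seed = 7)
  expect_gt(fwd[["ai"]], fwd[["an"]])
  expect_gt(swp[["an"]], swp[["ai"]])
})
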