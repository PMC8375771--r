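test_that("image generation is deterministic and respects pixel bounds", {
  a <- generate_image_classes(4, 3, image_size = 16, seed = 7)
  b <- generate_image_classes(4, 3, image_size = 16, seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$nuisance, b$nuisance)
  d <- generate_image_classes(4, 3, image_size = 16, seed = 8)
  expect_false(identical(a$pixels, d$pixels))

  expect_true(all(a$pixels >= 0 & a$pixels <= 255))
  expect_equal(dim(a$pixels), c(16 * 16 * 3, 12))
  expect_equal(a$class_id, rep(1:4, each = 3))
})

test_that("one exemplar per class yields one image per category", {
  stim <- generate_image_classes(40, 1, image_size = 16, seed = 7)
  expect_equal(ncol(stim$pixels), 40)
  expect_equal(stim$class_id, 1:40)
})

test_that("invalid stimulus parameters are rejected", {
  expect_error(generate_image_classes(1, 5, seed = 1), "n_classes")
  expect_error(generate_image_classes(4, 0, seed = 1), "n_per_class")
  expect_error(generate_image_classes(4, 5, image_size = 8, seed = 1),
               "image_size")
})

test_that("a surrogate classifier separates the two-class set", {
  stim <- generate_image_classes(2, 200, seed = 1)
  net <- train_surrogate(stim, epochs = 4, seed = 1)
  expect_gte(net$holdout_accuracy, 0.95)
})

test_that("stimulus sets round-trip through PNG + JSON manifest", {
  stim <- generate_image_classes(3, 2, image_size = 16, seed = 12)
  d <- tempfile("stimset-")
  write_stimulus_set(stim, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_stimulus_set(d)
  expect_equal(back$class_id, stim$class_id)
  expect_equal(back$type, stim$type)
  expect_equal(back$image_shape, stim$image_shape)
  # 8-bit quantization: within half an intensity step
  expect_lt(max(abs(back$pixels - stim$pixels)), 0.51)
  unlink(d, recursive = TRUE)
})

test_that("design has the reference run length and per-run image counts", {
  d <- build_design(seed = 3)
  expect_s3_class(d, "experiment_design")
  expect_equal(d$trials_per_run, 129)
  expect_length(d$sessions, 2)
  for (sess in d$sessions) {
    expect_length(sess, 5)
    for (run in sess) {
      expect_equal(nrow(run), 129)
      expect_equal(sum(is.na(run$image_id)), 9)
      counts <- table(run$image_id)
      expect_true(all(counts == 2))
      expect_length(counts, 60)
    }
  }
  # session 2 uses the second half of the images
  ids2 <- unique(stats::na.omit(d$sessions[[2]][[1]]$image_id))
  expect_setequal(ids2, 61:120)
})

test_that("design is seeded and handles the single-trial edge case", {
  expect_identical(build_design(seed = 5), build_design(seed = 5))
  expect_false(identical(build_design(seed = 5)$sessions,
                         build_design(seed = 6)$sessions))
  one <- build_design(1, 1, 0, 1, 1, seed = 1)
  run <- one$sessions[[1]][[1]]
  expect_equal(nrow(run), 1)
  expect_equal(run$image_id, 1L)
  expect_error(build_design(runs_per_session = 0), "positive")
})

test_that("condition enumeration counts predictors per (image, repetition)", {
  expect_equal(nrow(enumerate_conditions(build_design(seed = 1))), 241)
  expect_equal(nrow(enumerate_conditions(
    build_design(1, 1, 2, 1, 1, seed = 1))), 2)
  expect_equal(nrow(enumerate_conditions(
    build_design(3, 2, 1, 1, 1, seed = 1))), 7)
  tab <- enumerate_conditions(build_design(seed = 1))
  expect_equal(sum(is.na(tab$image_id)), 1)  # single blank predictor
  expect_false(any(duplicated(tab[, c("image_id", "repetition")])))
})

test_that("sheet layout has disjoint seeded blocks of the requested size", {
  sheet <- make_sheet(150, seed = 4)
  expect_equal(nrow(sheet), 1500)
  expect_equal(as.vector(table(sheet$roi)), rep(300L, 5))
  expect_identical(make_sheet(150, seed = 4), sheet)

  small <- make_sheet(20, seed = 9)
  # ROI blocks are spatially disjoint within each hemisphere
  for (h in c("LH", "RH")) {
    sub <- small[small$hemisphere == h, ]
    rngs <- lapply(split(sub$x, sub$roi), range)
    rngs <- rngs[order(vapply(rngs, `[`, numeric(1), 1))]
    for (i in seq_len(length(rngs) - 1)) {
      expect_lt(rngs[[i]][2], rngs[[i + 1]][1])
    }
  }
  # coordinates unique within hemisphere
  expect_false(any(duplicated(small[, c("hemisphere", "x", "y")])))
})

test_that("response simulation honors its degenerate limits", {
  acts <- fake_acts(12, seed = 2)
  sheet <- make_sheet(5, seed = 2)
  rd <- simulate_vertex_responses(acts, sheet, rho_AI = 1, rho_AN = 0,
                                  rep_noise_sd = 0, seed = 3)
  re <- response_patterns(rd, "RE")
  ai <- response_patterns(rd, "AI")
  expect_equal(ai, re, tolerance = 1e-12)

  expect_error(simulate_vertex_responses(acts, sheet, rho_AI = 1.2),
               "rho")
  bad <- acts
  bad$L3 <- NULL
  expect_error(simulate_vertex_responses(bad[c(1, 2)], sheet), NA)
  bad2 <- acts
  bad2$L2 <- matrix(0, 5, 4)   # wrong number of images
  expect_error(simulate_vertex_responses(bad2, sheet), "L2")
})

test_that("ground truth regenerates the dataset bit-exactly", {
  acts <- fake_acts(10, seed = 5)
  sheet <- make_sheet(4, seed = 5)
  rd <- simulate_vertex_responses(acts, sheet, seed = 21)
  rd2 <- regenerate_responses(rd, acts)
  expect_identical(rd$betas, rd2$betas)
  expect_identical(rd$ground_truth, rd2$ground_truth)
})

test_that("decoupled adversarial-noise responses have near-zero similarity", {
  # Monte-Carlo check at 500 vertices: with rho_AN = 0 the population-level
  # RE-AN RDM similarity should sit within +-0.1 of zero
  acts <- fake_acts(40, seed = 6)
  sheet <- make_sheet(50, seed = 6)  # 500 vertices
  rd <- simulate_vertex_responses(acts, sheet, rho_AI = 0.8, rho_AN = 0,
                                  rep_noise_sd = 0.4, seed = 8)
  s <- similarity_pair(t(response_patterns(rd, "RE")),
                       t(response_patterns(rd, "AN")),
                       t(response_patterns(rd, "AI")))
  expect_lt(abs(s[["r_re_an"]]), 0.1)
  expect_gt(s[["r_re_ai"]], s[["r_re_an"]])
})

test_that("RE-AI similarity is monotone in the coupling parameter", {
  acts <- fake_acts(20, seed = 3)
  sheet <- make_sheet(20, seed = 3)  # 200 vertices
  rhos <- c(0, 0.25, 0.5, 0.75, 1)
  sims <- matrix(NA_real_, 3, length(rhos))
  for (s in 1:3) {
    for (j in seq_along(rhos)) {
      rd <- simulate_vertex_responses(acts, sheet, rho_AI = rhos[j],
                                      rho_AN = 0, rep_noise_sd = 0.3,
                                      seed = 100 * s + j)
      sims[s, j] <- similarity_pair(
        t(response_patterns(rd, "RE")), t(response_patterns(rd, "AN")),
        t(response_patterns(rd, "AI")))[["r_re_ai"]]
    }
  }
  means <- colMeans(sims)
  expect_true(all(diff(means) > 0))
})
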