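test_that("correlation-distance RDMs match hand-computed values", {
  a <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 4, 6))
  m <- compute_rdm(a)
  expect_equal(m[1, 2], 2)          # perfectly anticorrelated
  expect_equal(m[1, 3], 0)          # perfectly correlated
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
  expect_true(all(diag(m) == 0))

  big <- compute_rdm(matrix(rnorm(40 * 10), 40, 10))
  expect_equal(dim(big), c(40, 40))

  # CSV export round-trips the matrix with its item-id header
  f <- tempfile(fileext = ".csv")
  write_rdm(big, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), unclass(big), ignore_attr = TRUE)
  unlink(f)

  expect_error(compute_rdm(rbind(c(1, 1, 1), c(1, 2, 3))), "item.*1")
  expect_error(compute_rdm(matrix(1, 1, 3)), "2 items")
})

test_that("euclidean RDMs are available and identical rows give zero", {
  a <- rbind(c(0, 0), c(3, 4), c(0, 0))
  m <- compute_rdm(a, metric = "euclidean")
  expect_equal(m[1, 2], 5)
  expect_equal(m[1, 3], 0)
})

test_that("RDM symmetry and zero diagonal hold over a random battery", {
  set.seed(42)
  for (i in 1:10) {
    m <- compute_rdm(matrix(rnorm(8 * 15), 8, 15))
    expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 2))
  }
})

test_that("RDM similarity is Spearman over the strict upper triangle", {
  m <- compute_rdm(matrix(rnorm(6 * 12), 6, 12))
  expect_equal(rdm_similarity(m, m), 1.0)

  # reversed rank order of the upper triangle gives -1
  n <- 4
  u1 <- c(1, 2, 3, 4, 5, 6)
  u2 <- c(6, 5, 4, 3, 2, 1)
  mk <- function(u) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- u
    m <- m + t(m)
    structure(m, item_ids = seq_len(n), metric = "correlation",
              class = c("rdm", "matrix", "array"))
  }
  expect_equal(rdm_similarity(mk(u1), mk(u2)), -1.0)

  # frozen oracle: independent rank-then-Pearson on (1,2,3,4,5,6) vs
  # (2,1,3,4,6,5) gives 1 - 6*sum(d^2)/(n(n^2-1)) = 1 - 24/210 = 31/35
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 1, 3, 4, 6, 5)
  oracle <- stats::cor(rank(a), rank(b))
  expect_equal(rdm_similarity(mk(a), mk(b)), oracle)
  expect_equal(oracle, 31 / 35)

  m2 <- compute_rdm(matrix(rnorm(5 * 12), 5, 12))
  expect_error(rdm_similarity(m, m2), "identical item sets")
})

test_that("similarity pairs recover coupling structure", {
  set.seed(7)
  re <- matrix(rnorm(40 * 500), 40, 500)
  s <- similarity_pair(re, matrix(rnorm(40 * 500), 40, 500), re)
  expect_equal(s[["r_re_ai"]], 1.0)
  expect_lt(abs(s[["r_re_an"]]), 0.1)   # independent => near zero

  ai <- mix_with_noise(re, 0.8)
  an <- mix_with_noise(re, 0)
  s2 <- similarity_pair(re, an, ai)
  expect_gt(s2[["r_re_ai"]], s2[["r_re_an"]])
})

test_that("bootstrap difference collapses at frac = 1 and detects coupling", {
  set.seed(3)
  re <- matrix(rnorm(20 * 60), 20, 60)
  ai <- mix_with_noise(re, 0.8)
  an <- mix_with_noise(re, 0)

  full <- bootstrap_difference(re, an, ai, frac = 1, n_boot = 50, seed = 1)
  expect_length(full$diffs, 50)
  expect_equal(diff(range(full$diffs)), 0)
  expect_equal(full$diffs[1], full$observed[["diff"]])

  expect_error(bootstrap_difference(re, an, ai, frac = 1.5), "frac")
  expect_error(bootstrap_difference(re[, 1:5], an[, 1:5], ai[, 1:5]),
               "10 units")
})

test_that("the coupled scenario is detected at 500 vertices", {
  set.seed(11)
  re <- matrix(rnorm(40 * 500), 40, 500)
  ai <- mix_with_noise(re, 0.8)
  an <- mix_with_noise(re, 0)
  bt <- bootstrap_difference(re, an, ai, frac = 0.8, n_boot = 200, seed = 4)
  expect_lt(bt$p, 0.05)
  expect_equal(length(bt$diffs), 200)
})

test_that("permutation p-values behave at the extremes and match exhaustion", {
  set.seed(5)
  re <- matrix(rnorm(5 * 40), 5, 40)
  # identical activations: observed similarity is the distribution maximum
  pn <- permutation_null(re, re, n_perm = 200, seed = 2)
  expect_equal(pn$observed, 1.0)
  expect_lte(pn$p, (1 + sum(pn$null >= 1 - 1e-12)) / 201)

  # Monte-Carlo null agrees with the exhaustive 5! = 120 permutation null
  adv <- matrix(rnorm(5 * 40), 5, 40)
  u_adv <- advrep:::rdm_upper(adv)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) all(sort(p) == 1:5)), ]
  exact <- apply(perms, 1, function(p) {
    advrep:::spearman_vec(advrep:::rdm_upper(re[p, ]), u_adv)
  })
  obs <- advrep:::spearman_vec(advrep:::rdm_upper(re), u_adv)
  p_exact <- mean(exact >= obs)
  pn2 <- permutation_null(re, adv, n_perm = 400, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 400)
  expect_lt(abs(pn2$p - p_exact), 4 * se + 0.01)
  expect_error(permutation_null(re[1:3, ], adv[1:3, ]), "5 items")
})

test_that("permutation test size is close to nominal under the null", {
  # independent adversarial activations; empirical size at alpha = 0.05
  # should not exceed 1.5x nominal over 200 seeds
  hits <- logical(200)
  for (s in 1:200) {
    set.seed(5000 + s)
    re <- matrix(rnorm(10 * 30), 10, 30)
    adv <- matrix(rnorm(10 * 30), 10, 30)
    hits[s] <- permutation_null(re, adv, n_perm = 99, seed = s)$p < 0.05
  }
  expect_lte(mean(hits), 0.075)
})

test_that("Mann-Kendall agrees with direct pair enumeration", {
  expect_equal(mann_kendall(c(1, 2, 3, 4, 5))$S, 10)
  expect_equal(mann_kendall(c(2, 2, 2, 2))$S, 0)
  expect_equal(mann_kendall(c(1, 3, 2))$S, 1)
  expect_error(mann_kendall(c(1, 2)), "length")

  brute_s <- function(x) {
    s <- 0
    for (i in seq_along(x)) {
      for (j in seq_along(x)) {
        if (i < j) s <- s + sign(x[j] - x[i])
      }
    }
    s
  }
  set.seed(13)
  for (i in 1:40) {
    n <- sample(3:7, 1)
    x <- sample(1:4, n, replace = TRUE)   # ties likely
    mk <- mann_kendall(x)
    expect_equal(mk$S, brute_s(x))
    expect_gte(mk$var_s, 0)
    expect_true(mk$p >= 0 && mk$p <= 1)
    # tie-corrected variance matches the closed form computed directly
    ties <- table(x); ties <- ties[ties > 1]
    v <- (n * (n - 1) * (2 * n + 5) -
            sum(ties * (ties - 1) * (2 * ties + 5))) / 18
    expect_equal(mk$var_s, v)
  }
})

test_that("searchlight disks are symmetric and tiny disks yield NA", {
  sheet <- make_sheet(25, seed = 8)
  disks <- advrep:::searchlight_disks(sheet, 3.0)
  for (v in seq(1, nrow(sheet), by = 17)) {
    for (u in disks[[v]]) {
      expect_true(v %in% disks[[u]])
    }
  }
  # all disk members share hemisphere
  for (v in seq(1, nrow(sheet), by = 31)) {
    expect_true(all(sheet$hemisphere[disks[[v]]] == sheet$hemisphere[v]))
  }

  acts <- fake_acts(12, seed = 4)
  rd <- simulate_vertex_responses(acts, sheet, seed = 4)
  tiny <- searchlight_map(rd, sheet, radius = 0.01)
  expect_true(all(is.na(tiny$r_re_ai)))
  expect_true(all(tiny$disk_size == 1))
})

test_that("searchlight maps show the coupled ordering on synthetic data", {
  sheet <- make_sheet(30, seed = 14)
  acts <- fake_acts(20, seed = 14)
  rd <- simulate_vertex_responses(acts, sheet, rho_AI = 0.8, rho_AN = 0,
                                  rep_noise_sd = 0.3, seed = 14)
  sl <- searchlight_map(rd, sheet, radius = 3)
  expect_gt(mean(sl$r_re_ai, na.rm = TRUE), mean(sl$r_re_an, na.rm = TRUE))
  expect_true(all(abs(sl$r_re_ai) <= 1, na.rm = TRUE))
})

test_that("layer profiles cover all stages and flag degenerate copies", {
  net <- tiny_model()
  # 12-item RE set plus AI = RE copies and freshly jittered AN stand-ins
  re <- generate_image_classes(12, 1, image_size = 16, seed = 21)
  re$type <- rep("RE", 12)
  ai <- re; ai$type <- rep("AI", 12)
  an <- generate_image_classes(12, 1, image_size = 16, seed = 99)
  an$type <- rep("AN", 12)
  prof <- layer_profile(net, combine_stimuli(re, an, ai),
                        n_boot = 30, n_perm = 30, seed = 2)
  expect_length(prof$summaries, 8)
  expect_equal(prof$profile$r_re_ai, rep(1, 8), tolerance = 1e-12)
  expect_equal(prof$trend_re_ai$S, 0)   # constant profile has no trend
})
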