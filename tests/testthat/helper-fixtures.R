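# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small 12-class classifier on 16x16 images: fast, used by most model and
# adversarial unit tests (12 classes keep every stage, including the
# softmax head, above the minimum unit count of the resampling tests).
tiny_stim <- function() {
  fixture("tiny_stim", function() {
    generate_image_classes(12, 30, image_size = 16, seed = 11)
  })
}

tiny_model <- function() {
  fixture("tiny_model", function() {
    train_surrogate(tiny_stim(), epochs = 12, seed = 11)
  })
}

# 5-class classifier at the full 32x32 image size, for the adversarial
# generation checks at the reference thresholds.
accept_stim <- function() {
  fixture("accept_stim", function() {
    generate_image_classes(5, 40, image_size = 32, seed = 2)
  })
}

accept_model <- function() {
  fixture("accept_model", function() {
    train_surrogate(accept_stim(), epochs = 10, seed = 2)
  })
}

# Full-scale pipeline run (40 classes, 500 vertices per ROI, default
# coupling rho_AI = 0.8 / rho_AN = 0) shared by the acceptance checks.
pipeline_report <- function() {
  fixture("pipeline_report", function() {
    # a handful of encoding fits are rank-deficient by design and warn
    suppressWarnings(
      run_pipeline(list(seed = 1, n_vertices_per_roi_per_hemi = 250),
                   verbose = FALSE))
  })
}

# Synthetic activation stacks (images x units per stage) for analyses that
# do not need a real classifier.
fake_acts <- function(n_img, units = c(64, 48, 48, 48, 32, 24, 16, 12),
                      seed = 1) {
  set.seed(seed)
  out <- lapply(units, function(u) matrix(rnorm(n_img * u), n_img, u))
  names(out) <- paste0("L", seq_along(units))
  out
}

# Equal-variance mixture of a pattern matrix with fresh noise, column-wise.
mix_with_noise <- function(z, rho) {
  e <- matrix(rnorm(length(z)), nrow(z), ncol(z))
  rho * z + sqrt(1 - rho^2) * e
}
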