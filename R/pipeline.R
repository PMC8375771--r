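#' Validate and normalize a pipeline configuration
#'
#' Fills every unspecified field with the experiment-scale default, checks
#' ranges, derives the per-stage seeds from the global seed, and reports
#' every violation with the offending field's name. The defaults mirror
#' the reference experiment: 40 classes with one regular image each (120
#' stimuli with the two adversarial counterparts), two sessions of five
#' 129-trial runs, a five-ROI two-hemisphere sheet, 80% resampling with
#' 1000 bootstrap and permutation replicates, a 3-unit searchlight radius
#' and 100 selected vertices per hemisphere per ROI.
#'
#' @param config named list of overrides (possibly empty).
#' @return a normalized \code{advrep_config} list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    # stimuli / surrogate
    n_classes = 40L, image_size = 32L, n_train_per_class = 25L,
    epochs = 15L, conv_widths = c(8L, 16L, 16L, 16L, 32L),
    fc_widths = c(128L, 64L), min_accuracy = 0.95,
    # adversarial generation
    lambda_reg = 1e-4, step_size = 1.0, target_prob = 0.99,
    stop_prob = 0.5, noise_bound = 5, an_max_iter = 2000L,
    ai_max_iter = 8000L,
    # design
    images_per_session = NULL, reps_per_image = 2L, blanks_per_run = 9L,
    runs_per_session = 5L, sessions = 2L,
    # sheet / simulation
    n_vertices_per_roi_per_hemi = 150L,
    rois = c("V1", "V2", "V3", "V4", "LO"),
    sparsity_k = 3L, rho_AI = 0.8, rho_AN = 0.0, rep_noise_sd = 0.4,
    # analysis
    frac = 0.8, n_boot = 1000L, n_perm = 1000L, radius = 3.0,
    n_per_hemisphere = 100L, sparsity_s = 10L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  errs <- character(0L)
  need_pos <- c("n_classes", "image_size", "n_train_per_class", "epochs",
                "reps_per_image", "runs_per_session", "sessions",
                "n_vertices_per_roi_per_hemi", "sparsity_k", "n_boot",
                "n_perm", "n_per_hemisphere", "sparsity_s", "an_max_iter",
                "ai_max_iter")
  for (f in need_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 1) {
      errs <- c(errs, sprintf("%s: must be a positive count", f))
    }
  }
  if (cfg$frac <= 0 || cfg$frac > 1) {
    errs <- c(errs, "frac: must be in (0, 1]")
  }
  if (cfg$rho_AI < 0 || cfg$rho_AI > 1) errs <- c(errs, "rho_AI: must be in [0, 1]")
  if (cfg$rho_AN < 0 || cfg$rho_AN > 1) errs <- c(errs, "rho_AN: must be in [0, 1]")
  if (cfg$rep_noise_sd < 0) errs <- c(errs, "rep_noise_sd: must be >= 0")
  if (cfg$radius <= 0) errs <- c(errs, "radius: must be > 0")
  if (cfg$blanks_per_run < 0) errs <- c(errs, "blanks_per_run: must be >= 0")
  if (cfg$image_size < 16) errs <- c(errs, "image_size: must be >= 16")
  if (length(errs)) {
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }
  if (is.null(cfg$images_per_session)) {
    total <- 3L * cfg$n_classes
    if (total %% cfg$sessions != 0L) {
      stop("images_per_session: 3 * n_classes (", total,
           ") is not divisible by sessions (", cfg$sessions, ")",
           call. = FALSE)
    }
    cfg$images_per_session <- total %/% cfg$sessions
  }
  # per-stage seeds derived from the global seed (kept within 32-bit range)
  base <- as.integer(cfg$seed) %% 100000L
  cfg$seeds <- list(stimuli = base + 11L, train = base + 23L,
                    wrong_class = base + 37L, ai = base + 41L,
                    design = base + 53L, sheet = base + 67L,
                    responses = base + 79L, analysis = base + 97L)
  structure(cfg, class = "advrep_config")
}

#' Run the full representational-comparison pipeline
#'
#' Executes the end-to-end experiment on synthetic data: generate regular
#' images, train the surrogate classifier, generate the adversarial-noise
#' and adversarial-interference counterparts, lay out the experiment
#' design and cortical sheet, simulate vertex responses with the
#' configured representational coupling, and run the analyses — ROI-level
#' RSA with bootstrap/permutation inference, the layer-wise profile with
#' trend tests, the searchlight map, consistency-based vertex selection,
#' and the forward-encoding generalization tests. Every stage is seeded
#' from the global seed, so a configuration reproduces its report exactly.
#'
#' @param config list of configuration overrides, or an
#'   \code{advrep_config} from [validate_config()].
#' @param out_dir optional directory for machine-readable outputs (JSON
#'   report, CSV tables, PNG images).
#' @param verbose log stage progress to stderr.
#' @return an \code{advrep_report}; see the elements documented in
#'   [validate_config()] and the analysis functions.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, verbose = TRUE) {
  cfg <- if (inherits(config, "advrep_config")) config else validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  train_stim <- stage("synthesize-training-images",
    generate_image_classes(cfg$n_classes, cfg$n_train_per_class,
                           cfg$image_size, seed = cfg$seeds$train))
  re_stim <- stage("synthesize-stimuli",
    generate_image_classes(cfg$n_classes, 1L, cfg$image_size,
                           seed = cfg$seeds$stimuli))
  model <- stage("train-surrogate",
    train_surrogate(train_stim, epochs = cfg$epochs, seed = cfg$seeds$train,
                    conv_widths = cfg$conv_widths, fc_widths = cfg$fc_widths,
                    min_accuracy = cfg$min_accuracy))
  mean_image <- rowMeans(train_stim$pixels)
  adv_cfg_an <- adversarial_config(lambda_reg = cfg$lambda_reg,
                                   step_size = cfg$step_size,
                                   max_iter = cfg$an_max_iter,
                                   target_prob = cfg$target_prob,
                                   stop_prob = cfg$stop_prob,
                                   noise_bound = cfg$noise_bound)
  adv_cfg_ai <- adversarial_config(lambda_reg = cfg$lambda_reg,
                                   step_size = cfg$step_size,
                                   max_iter = cfg$ai_max_iter,
                                   target_prob = cfg$target_prob,
                                   stop_prob = cfg$stop_prob,
                                   noise_bound = cfg$noise_bound)
  an_res <- stage("generate-an",
    generate_an_batch(model, seq_len(cfg$n_classes), mean_image, adv_cfg_an))
  wrong <- wrong_class_assignment(cfg$n_classes, seed = cfg$seeds$wrong_class)
  ai_res <- stage("generate-ai",
    generate_ai_batch(model, re_stim, wrong, adv_cfg_ai,
                      seed = cfg$seeds$ai))
  as_set <- function(results, type) {
    structure(list(
      pixels = vapply(results, function(r) as.vector(r$image),
                      numeric(prod(re_stim$image_shape))),
      image_shape = re_stim$image_shape,
      class_id = seq_len(cfg$n_classes),
      type = rep(type, cfg$n_classes),
      nuisance = NULL, n_classes = cfg$n_classes, seed = cfg$seed
    ), class = "stimulus_set")
  }
  stimuli <- combine_stimuli(re_stim, as_set(an_res, "AN"),
                             as_set(ai_res, "AI"))
  adversarial_diag <- data.frame(
    mode = rep(c("AN", "AI"), each = cfg$n_classes),
    class_id = rep(seq_len(cfg$n_classes), 2L),
    final_prob = c(vapply(an_res, `[[`, numeric(1L), "final_prob"),
                   vapply(ai_res, `[[`, numeric(1L), "final_prob")),
    iterations = c(vapply(an_res, `[[`, numeric(1L), "iterations"),
                   vapply(ai_res, `[[`, numeric(1L), "iterations")),
    converged = c(vapply(an_res, `[[`, logical(1L), "converged"),
                  vapply(ai_res, `[[`, logical(1L), "converged")))

  design <- stage("design",
    build_design(cfg$images_per_session, cfg$reps_per_image,
                 cfg$blanks_per_run, cfg$runs_per_session, cfg$sessions,
                 seed = cfg$seeds$design))
  conditions <- enumerate_conditions(design)

  sheet <- stage("sheet",
    make_sheet(cfg$n_vertices_per_roi_per_hemi, cfg$rois,
               seed = cfg$seeds$sheet))
  acts_re <- stage("activations-re", stage_activations(model, re_stim))
  responses <- stage("simulate-responses",
    simulate_vertex_responses(acts_re, sheet, sparsity_k = cfg$sparsity_k,
                              rho_AI = cfg$rho_AI, rho_AN = cfg$rho_AN,
                              rep_noise_sd = cfg$rep_noise_sd,
                              seed = cfg$seeds$responses))

  roi_rsa <- stage("roi-rsa", {
    re <- response_patterns(responses, "RE")
    an <- response_patterns(responses, "AN")
    ai <- response_patterns(responses, "AI")
    out <- list()
    for (i in seq_along(cfg$rois)) {
      roi <- cfg$rois[i]
      ix <- which(sheet$roi == roi)
      out[[roi]] <- similarity_summary(
        t(re[ix, , drop = FALSE]), t(an[ix, , drop = FALSE]),
        t(ai[ix, , drop = FALSE]), frac = cfg$frac, n_boot = cfg$n_boot,
        n_perm = cfg$n_perm, seed = cfg$seeds$analysis + i)
    }
    out
  })
  cnn_profile <- stage("layer-profile",
    layer_profile(model, stimuli, frac = cfg$frac, n_boot = cfg$n_boot,
                  n_perm = cfg$n_perm, seed = cfg$seeds$analysis))
  slmap <- stage("searchlight", searchlight_map(responses, sheet,
                                                radius = cfg$radius))
  consistency <- stage("splithalf-consistency",
    splithalf_consistency(responses, sheet, radius = cfg$radius))
  selected <- stage("select-vertices",
    select_vertices(consistency, sheet,
                    n_per_hemisphere = cfg$n_per_hemisphere))
  bank <- stage("train-encoding-models",
    train_models(responses, acts_re, selected, sparsity_s = cfg$sparsity_s))
  acts_ai <- stage("activations-ai",
    stage_activations(model, stimuli$pixels[, stimuli$type == "AI"]))
  acts_an <- stage("activations-an",
    stage_activations(model, stimuli$pixels[, stimuli$type == "AN"]))
  gen_ai <- stage("test-generalization-ai",
    test_generalization(bank, acts_ai, responses, type = "AI",
                        frac = cfg$frac, n_boot = cfg$n_boot,
                        n_perm = cfg$n_perm, seed = cfg$seeds$analysis))
  gen_an <- stage("test-generalization-an",
    test_generalization(bank, acts_an, responses, type = "AN",
                        frac = cfg$frac, n_boot = cfg$n_boot,
                        n_perm = cfg$n_perm, seed = cfg$seeds$analysis))

  report <- structure(list(
    config = cfg,
    stimulus_manifest = data.frame(
      type = c("RE", "AN", "AI", "total"),
      n = c(sum(stimuli$type == "RE"), sum(stimuli$type == "AN"),
            sum(stimuli$type == "AI"), length(stimuli$type))),
    surrogate_accuracy = model$holdout_accuracy,
    adversarial = adversarial_diag,
    trials_per_run = design$trials_per_run,
    n_conditions = nrow(conditions),
    roi_rsa = roi_rsa,
    layer_profile = cnn_profile$profile,
    trend_re_an = cnn_profile$trend_re_an,
    trend_re_ai = cnn_profile$trend_re_ai,
    searchlight = data.frame(
      mean_r_re_an = mean(slmap$r_re_an, na.rm = TRUE),
      mean_r_re_ai = mean(slmap$r_re_ai, na.rm = TRUE),
      n_defined = sum(!is.na(slmap$r_re_ai))),
    searchlight_map = slmap,
    selected_vertices = selected,
    encoding = rbind(gen_ai, gen_an)
  ), class = "advrep_report")
  report$objects <- list(model = model, stimuli = stimuli,
                         responses = responses, bank = bank,
                         design = design, conditions = conditions)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.advrep_report <- function(x, ...) {
  cat("Pipeline report\n===============\n")
  cat(sprintf("stimuli: %d (per type: %s)\n",
              x$stimulus_manifest$n[4L],
              paste(x$stimulus_manifest$n[1:3], collapse = "/")))
  cat(sprintf("surrogate held-out accuracy: %.3f\n", x$surrogate_accuracy))
  cat(sprintf("trials/run: %d, conditions: %d\n", x$trials_per_run,
              x$n_conditions))
  cat("\nROI RSA (RE-AN vs RE-AI):\n")
  for (roi in names(x$roi_rsa)) {
    s <- x$roi_rsa[[roi]]
    cat(sprintf("  %-3s r_re_an = %6.3f, r_re_ai = %6.3f, boot p = %.4g\n",
                roi, s$r_re_an, s$r_re_ai, s$boot_p))
  }
  cat("\nLayer profile:\n")
  print(x$layer_profile, digits = 3)
  cat(sprintf("\nsearchlight means: r_re_an = %.3f, r_re_ai = %.3f\n",
              x$searchlight$mean_r_re_an, x$searchlight$mean_r_re_ai))
  cat(sprintf("\nencoding generalization (mean over cells): AI r = %.3f, AN r = %.3f\n",
              mean(x$encoding$mean_r[x$encoding$type == "AI"]),
              mean(x$encoding$mean_r[x$encoding$type == "AN"])))
  invisible(x)
}

# Strip heavyweight objects and serialize the report deterministically.
report_json <- function(report) {
  keep <- report[c("stimulus_manifest", "surrogate_accuracy",
                   "adversarial", "trials_per_run", "n_conditions",
                   "layer_profile", "searchlight", "encoding")]
  keep$config <- unclass(report$config)
  keep$roi_rsa <- lapply(report$roi_rsa, function(s) {
    list(r_re_an = s$r_re_an, r_re_ai = s$r_re_ai, diff = s$diff,
         boot_ci = s$boot_ci, boot_p = s$boot_p,
         perm_p_an = s$perm_p_an, perm_p_ai = s$perm_p_ai)
  })
  keep$trend_re_an <- report$trend_re_an
  keep$trend_re_ai <- report$trend_re_ai
  jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Write the machine-readable outputs of a pipeline report
#'
#' Writes \code{report.json}, CSV tables (layer profile, encoding
#' accuracies, searchlight map, selected vertices, sheet) and, when the
#' \pkg{png} package is available, the stimulus images as PNG files.
#'
#' @param report an \code{advrep_report}.
#' @param out_dir output directory (created if missing).
#' @param images also write stimulus PNGs.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir, images = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(report_json(report), file.path(out_dir, "report.json"))
  utils::write.csv(report$layer_profile,
                   file.path(out_dir, "layer_profile.csv"),
                   row.names = FALSE)
  utils::write.csv(report$encoding, file.path(out_dir, "encoding.csv"),
                   row.names = FALSE)
  utils::write.csv(report$searchlight_map,
                   file.path(out_dir, "searchlight_map.csv"),
                   row.names = FALSE)
  utils::write.csv(report$selected_vertices,
                   file.path(out_dir, "selected_vertices.csv"),
                   row.names = FALSE)
  if (!is.null(report$objects$responses)) {
    export_response_dataset(report$objects$responses,
                            file.path(out_dir, "responses"))
  }
  if (images && requireNamespace("png", quietly = TRUE)) {
    stim <- report$objects$stimuli
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_along(stim$type)) {
      png::writePNG(aperm(get_image(stim, i), c(1L, 2L, 3L)) / 255,
                    file.path(img_dir, sprintf("%s_%03d.png",
                                               stim$type[i],
                                               stim$class_id[i])))
    }
  }
  invisible(out_dir)
}

#' Export a response dataset as plain-text files
#'
#' Writes the betas (long CSV: vertex, image, repetition, beta), the sheet
#' CSV and a JSON ground-truth sidecar sufficient to regenerate the
#' dataset bit-exactly with [regenerate_responses()].
#'
#' @param responses a \code{response_dataset}.
#' @param prefix path prefix for \code{<prefix>_betas.csv},
#'   \code{<prefix>_sheet.csv}, \code{<prefix>_ground_truth.json}.
#' @return \code{prefix}, invisibly.
#' @export
export_response_dataset <- function(responses, prefix) {
  d <- dim(responses$betas)
  long <- data.frame(
    vertex_id = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    image_id = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    repetition = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
    beta = as.vector(responses$betas))
  utils::write.csv(long, paste0(prefix, "_betas.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(responses$sheet),
                   paste0(prefix, "_sheet.csv"), row.names = FALSE)
  writeLines(jsonlite::toJSON(responses$ground_truth, auto_unbox = TRUE,
                              digits = NA),
             paste0(prefix, "_ground_truth.json"))
  invisible(prefix)
}
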