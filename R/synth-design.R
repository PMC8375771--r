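#' Build the trial-level experiment design
#'
#' Lays out the scanning sessions of the main experiment. Each session
#' presents its share of the images; within a run every image of the
#' session appears exactly \code{reps_per_image} times, interleaved with
#' \code{blanks_per_run} blank trials in seeded-random order. At the
#' defaults (60 images per session, 2 repetitions, 9 blanks, 5 runs, 2
#' sessions) every run has 60 x 2 + 9 = 129 trials.
#'
#' Blank trials carry no stimulus; the position of blanks within a run is
#' uniformly random, as is the stimulus order.
#'
#' @param n_images_per_session images shown in each session.
#' @param reps_per_image presentations of each image within a run.
#' @param blanks_per_run blank trials per run.
#' @param runs_per_session runs in each session.
#' @param sessions number of sessions.
#' @param seed integer seed for the trial orders.
#' @return an \code{experiment_design}: list with \code{sessions} (list of
#'   sessions, each a list of run data frames with columns \code{trial},
#'   \code{image_id} (\code{NA} for blanks), \code{repetition}),
#'   \code{n_images}, \code{reps_per_image}, \code{blanks_per_run} and
#'   \code{trials_per_run}.
#' @examples
#' d <- build_design()
#' nrow(d$sessions[[1]][[1]])  # 129
#' @export
build_design <- function(n_images_per_session = 60L, reps_per_image = 2L,
                         blanks_per_run = 9L, runs_per_session = 5L,
                         sessions = 2L, seed = 1L) {
  args <- c(n_images_per_session = n_images_per_session,
            reps_per_image = reps_per_image,
            runs_per_session = runs_per_session, sessions = sessions)
  if (any(args < 1L)) {
    stop("counts must be positive: ",
         paste(names(args)[args < 1L], collapse = ", "), call. = FALSE)
  }
  if (blanks_per_run < 0L) stop("blanks_per_run must be >= 0", call. = FALSE)
  set.seed(seed)
  n_trials <- n_images_per_session * reps_per_image + blanks_per_run
  sess <- vector("list", sessions)
  for (s in seq_len(sessions)) {
    image_ids <- (s - 1L) * n_images_per_session + seq_len(n_images_per_session)
    runs <- vector("list", runs_per_session)
    for (r in seq_len(runs_per_session)) {
      ids <- c(rep(image_ids, each = reps_per_image),
               rep(NA_integer_, blanks_per_run))
      ids <- ids[sample(length(ids))]
      rep_idx <- stats::ave(seq_along(ids), ids, FUN = seq_along)
      rep_idx[is.na(ids)] <- NA_integer_
      runs[[r]] <- data.frame(trial = seq_len(n_trials), image_id = ids,
                              repetition = rep_idx)
    }
    sess[[s]] <- runs
  }
  structure(list(sessions = sess,
                 n_images = n_images_per_session * sessions,
                 n_images_per_session = n_images_per_session,
                 reps_per_image = reps_per_image,
                 blanks_per_run = blanks_per_run,
                 runs_per_session = runs_per_session,
                 n_sessions = sessions,
                 trials_per_run = n_trials,
                 seed = seed),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "Experiment design: %d sessions x %d runs, %d trials/run (%d images x %d reps + %d blanks)\n",
    x$n_sessions, x$runs_per_session, x$trials_per_run,
    x$n_images_per_session, x$reps_per_image, x$blanks_per_run))
  invisible(x)
}

#' Enumerate the condition (predictor) table of a design
#'
#' Every (image, repetition) pair across the whole experiment is a
#' distinct predictor — the two presentations of an image are deliberately
#' kept separate so that split-half consistency can be computed — and all
#' blank trials share a single predictor. At the paper-scale defaults this
#' gives 120 x 2 + 1 = 241 conditions.
#'
#' @param design an \code{experiment_design}.
#' @return a \code{condition_table} data frame with columns
#'   \code{predictor}, \code{image_id} (\code{NA} for the blank predictor)
#'   and \code{repetition}.
#' @export
enumerate_conditions <- function(design) {
  if (!inherits(design, "experiment_design")) {
    stop("design must be an experiment_design", call. = FALSE)
  }
  tab <- expand.grid(repetition = seq_len(design$reps_per_image),
                     image_id = seq_len(design$n_images))
  tab <- tab[order(tab$image_id, tab$repetition), c("image_id", "repetition")]
  tab <- rbind(tab, data.frame(image_id = NA_integer_,
                               repetition = NA_integer_))
  tab$predictor <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab[, c("predictor", "image_id", "repetition")],
            class = c("condition_table", "data.frame"))
}

#' Lay out a synthetic two-hemisphere cortical sheet
#'
#' Places vertices on a jittered 2D grid, one spatially disjoint block per
#' (ROI, hemisphere) combination, in "sheet units" with unit grid spacing.
#' The flat-map coordinates stand in for a flattened cortical surface, so
#' Euclidean distance on the sheet plays the role of geodesic distance.
#'
#' @param n_vertices_per_roi_per_hemi vertices in each (ROI, hemisphere)
#'   block.
#' @param rois character vector of ROI labels.
#' @param seed integer seed for the coordinate jitter.
#' @return a \code{cortical_sheet} data frame with columns
#'   \code{vertex_id}, \code{hemisphere} (\code{"LH"}/\code{"RH"}),
#'   \code{roi}, \code{x}, \code{y}.
#' @examples
#' sheet <- make_sheet(150, seed = 1)
#' nrow(sheet)  # 1500
#' @export
make_sheet <- function(n_vertices_per_roi_per_hemi = 150L,
                       rois = c("V1", "V2", "V3", "V4", "LO"), seed = 1L) {
  n <- as.integer(n_vertices_per_roi_per_hemi)
  if (n < 1L) stop("need at least one vertex per block", call. = FALSE)
  set.seed(seed)
  side <- ceiling(sqrt(n))
  gap <- side + 4L   # keeps blocks disjoint even with jitter
  blocks <- expand.grid(hemisphere = c("LH", "RH"), roi = rois,
                        stringsAsFactors = FALSE)
  out <- vector("list", nrow(blocks))
  for (b in seq_len(nrow(blocks))) {
    gx <- (seq_len(n) - 1L) %% side
    gy <- (seq_len(n) - 1L) %/% side
    out[[b]] <- data.frame(
      hemisphere = blocks$hemisphere[b],
      roi = blocks$roi[b],
      x = gx + stats::runif(n, -0.2, 0.2) +
        gap * (match(blocks$roi[b], rois) - 1L),
      y = gy + stats::runif(n, -0.2, 0.2) +
        gap * (match(blocks$hemisphere[b], c("LH", "RH")) - 1L)
    )
  }
  sheet <- do.call(rbind, out)
  sheet <- cbind(vertex_id = seq_len(nrow(sheet)), sheet)
  rownames(sheet) <- NULL
  structure(sheet, class = c("cortical_sheet", "data.frame"),
            rois = rois, seed = seed)
}
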