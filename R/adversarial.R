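#' Configuration for adversarial image generation
#'
#' @param lambda_reg L2 regularization weight pulling the image toward the
#'   anchor (the mean image for noise images, the regular image for the
#'   gradient-based interference variant), on the 0-255 pixel scale.
#' @param step_size gradient-ascent step size in pixel-intensity units; the
#'   class-probability gradient is normalized to unit maximum absolute
#'   value before stepping, so each iteration moves pixels by at most
#'   \code{step_size}.
#' @param max_iter iteration cap.
#' @param target_prob stopping probability for gradient ascent (0.99 for
#'   noise images and the gradient interference variant).
#' @param stop_prob stopping probability for the hill-climb interference
#'   generator (0.5: wrong class becomes the top-1 label).
#' @param noise_bound half-width of the uniform per-pixel noise used by the
#'   hill-climb (noise drawn from \code{[-noise_bound, noise_bound]}).
#' @param pixel_range admissible pixel intensities; every update is clipped
#'   to this range so images stay renderable.
#' @param change_tol convergence tolerance: gradient ascent also stops when
#'   the maximum absolute pixel change over the last 10 iterations falls
#'   below this value.
#' @param gradient_on differentiate the class probability (default) or its
#'   logarithm.
#' @return a list of class \code{adversarial_config}.
#' @export
adversarial_config <- function(lambda_reg = 1e-4, step_size = 1.0,
                               max_iter = 2000L, target_prob = 0.99,
                               stop_prob = 0.5, noise_bound = 5,
                               pixel_range = c(0, 255), change_tol = 1e-3,
                               gradient_on = c("prob", "logprob")) {
  gradient_on <- match.arg(gradient_on)
  if (lambda_reg < 0) stop("lambda_reg must be >= 0", call. = FALSE)
  if (target_prob <= 0 || target_prob >= 1) {
    stop("target_prob must be in (0, 1)", call. = FALSE)
  }
  if (stop_prob <= 0 || stop_prob >= 1) {
    stop("stop_prob must be in (0, 1)", call. = FALSE)
  }
  if (noise_bound <= 0) stop("noise_bound must be > 0", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  structure(list(lambda_reg = lambda_reg, step_size = step_size,
                 max_iter = as.integer(max_iter), target_prob = target_prob,
                 stop_prob = stop_prob, noise_bound = noise_bound,
                 pixel_range = pixel_range, change_tol = change_tol,
                 gradient_on = gradient_on),
            class = "adversarial_config")
}

# Batched regularized gradient ascent on the target-class probability.
# Each column of X0 ascends toward its own target class; anchors is either
# one anchor image (recycled) or one column per image.
#
# The update is steepest ascent under the max norm: the probability
# gradient is normalized to unit maximum absolute value, so step_size is in
# pixel-intensity units. The L2 anchor penalty is applied as a proximal
# (implicit) shrink toward the anchor, which is unconditionally stable and
# pins the image exactly to the anchor in the lambda -> Inf limit.
ascend_batch <- function(model, X0, target_classes, anchors, config) {
  n <- ncol(X0)
  X <- X0
  if (is.null(dim(anchors))) anchors <- matrix(anchors, nrow(X0), n)
  if (ncol(anchors) == 1L && n > 1L) {
    anchors <- matrix(anchors, nrow(X0), n)
  }
  lo <- config$pixel_range[1L]
  hi <- config$pixel_range[2L]
  active <- rep(TRUE, n)
  iters <- integer(n)
  traj <- vector("list", n)
  change_hist <- matrix(Inf, 10L, n)
  P0 <- net_forward(model, X)$probs
  p_cur <- P0[cbind(target_classes, seq_len(n))]
  for (i in seq_len(n)) traj[[i]] <- p_cur[i]
  active <- p_cur < config$target_prob
  it <- 0L
  while (any(active) && it < config$max_iter) {
    it <- it + 1L
    ia <- which(active)
    gr <- net_input_gradient(model, X[, ia, drop = FALSE],
                             target_classes[ia], on = config$gradient_on)
    gmax <- apply(abs(gr$grad), 2L, max)
    ghat <- sweep(gr$grad, 2L, pmax(gmax, .Machine$double.xmin), `/`)
    Xa <- X[, ia, drop = FALSE]
    anc <- anchors[, ia, drop = FALSE]
    shrink <- 1 / (1 + 2 * config$step_size * config$lambda_reg)
    Xnew <- anc + (Xa + config$step_size * ghat - anc) * shrink
    Xnew <- pmin(pmax(Xnew, lo), hi)
    delta <- apply(abs(Xnew - X[, ia, drop = FALSE]), 2L, max)
    X[, ia] <- Xnew
    Pn <- net_forward(model, X[, ia, drop = FALSE])$probs
    pn <- Pn[cbind(target_classes[ia], seq_along(ia))]
    for (k in seq_along(ia)) {
      i <- ia[k]
      iters[i] <- it
      traj[[i]] <- c(traj[[i]], pn[k])
      change_hist[1L + (it - 1L) %% 10L, i] <- delta[k]
      if (pn[k] >= config$target_prob || max(change_hist[, i]) < config$change_tol) {
        active[i] <- FALSE
      }
    }
    p_cur[ia] <- pn
  }
  list(X = X, prob = p_cur, iterations = iters, trajectory = traj,
       converged = p_cur >= config$target_prob)
}

make_generation_result <- function(x, shape, class_id, prob, traj, iters,
                                   converged, mode, extra = list()) {
  structure(c(list(
    image = array(x, dim = shape),
    class_id = class_id,
    final_prob = prob,
    trajectory = traj,
    iterations = iters,
    converged = converged,
    mode = mode
  ), extra), class = "generation_result")
}

#' @export
print.generation_result <- function(x, ...) {
  cat(sprintf(
    "Adversarial generation result (%s): class %d, final prob %.4f, %d iterations, %s\n",
    x$mode, x$class_id, x$final_prob, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Generate an adversarial-noise (AN) image by activation maximization
#'
#' Performs regularized gradient ascent on the target-class probability,
#' starting from the mean image: maximizes
#' \eqn{P_c(I) - \lambda \, ||I - I_{mean}||_2^2}
#' with pixel clipping after every step. The search stops when the
#' target-class probability reaches \code{config$target_prob} (0.99 by
#' default), when pixel values converge (maximum absolute change below
#' \code{config$change_tol} for 10 consecutive iterations), or at
#' \code{config$max_iter}, in which case the result is flagged
#' \code{converged = FALSE}.
#'
#' @param model a \code{surrogate_cnn}.
#' @param target_class class whose probability is maximized.
#' @param mean_image anchor image (array or vector, model input shape);
#'   also the initialization.
#' @param config an [adversarial_config()].
#' @param seed unused by the deterministic ascent; kept for interface
#'   symmetry with the stochastic generators.
#' @return a \code{generation_result} with the image, the per-iteration
#'   target-class probability trajectory, the iteration count and a
#'   convergence flag.
#' @export
generate_an <- function(model, target_class, mean_image,
                        config = adversarial_config(), seed = 1L) {
  X0 <- as_image_matrix(mean_image, shape = model$input_shape)$X
  res <- ascend_batch(model, X0, as.integer(target_class), X0, config)
  make_generation_result(res$X[, 1L], model$input_shape,
                         as.integer(target_class), res$prob[1L],
                         res$trajectory[[1L]], res$iterations[1L],
                         res$converged[1L], mode = "an")
}

#' Generate a batch of AN images, one per target class
#'
#' Batched variant of [generate_an()] used by the pipeline: all images
#' ascend simultaneously, each toward its own target class.
#'
#' @inheritParams generate_an
#' @param target_classes integer vector of target classes.
#' @return list of \code{generation_result}, one per target class.
#' @export
generate_an_batch <- function(model, target_classes, mean_image,
                              config = adversarial_config()) {
  target_classes <- as.integer(target_classes)
  n <- length(target_classes)
  x0 <- as_image_matrix(mean_image, shape = model$input_shape)$X
  X0 <- matrix(x0, nrow(x0), n)
  res <- ascend_batch(model, X0, target_classes, x0, config)
  lapply(seq_len(n), function(i) {
    make_generation_result(res$X[, i], model$input_shape, target_classes[i],
                           res$prob[i], res$trajectory[[i]],
                           res$iterations[i], res$converged[i], mode = "an")
  })
}

#' Generate an adversarial-interference (AI) image by noise hill-climbing
#'
#' Starting from a regular image, repeatedly adds fresh uniform noise
#' (drawn per pixel from \code{[-noise_bound, noise_bound]}, 5 by default),
#' keeps the perturbed image only if the probability of the designated
#' wrong class strictly increases, and clips pixels to the admissible
#' range. The climb stops once the wrong-class probability exceeds
#' \code{config$stop_prob} (0.5 by default, making the wrong class the
#' top-1 label) or at \code{max_iter} (flagged \code{converged = FALSE}).
#'
#' @param model a \code{surrogate_cnn}.
#' @param re_image the regular image to perturb.
#' @param wrong_class target wrong class (must differ from the image's true
#'   class).
#' @param config an [adversarial_config()].
#' @param seed seed for the noise draws.
#' @param true_class optional true class of \code{re_image}, checked
#'   against \code{wrong_class} when supplied.
#' @return a \code{generation_result}; the trajectory records the
#'   wrong-class probability after every iteration (accepted or not), and
#'   \code{accepted} gives the indices of accepted iterations.
#' @export
generate_ai_hillclimb <- function(model, re_image, wrong_class,
                                  config = adversarial_config(), seed = 1L,
                                  true_class = NULL) {
  wrong_class <- as.integer(wrong_class)
  if (!is.null(true_class) && wrong_class == as.integer(true_class)) {
    stop("wrong_class must differ from the true class", call. = FALSE)
  }
  x0 <- as_image_matrix(re_image, shape = model$input_shape)$X
  res <- hillclimb_batch(model, x0, wrong_class, config, seed)
  make_generation_result(res$X[, 1L], model$input_shape, wrong_class,
                         res$prob[1L], res$trajectory[[1L]],
                         res$iterations[1L], res$converged[1L],
                         mode = "ai-hillclimb",
                         extra = list(accepted = res$accepted[[1L]]))
}

# Batched accept/reject hill-climb; one wrong class per image column.
hillclimb_batch <- function(model, X0, wrong_classes, config, seed) {
  set.seed(seed)
  n <- ncol(X0)
  wrong_classes <- rep_len(as.integer(wrong_classes), n)
  lo <- config$pixel_range[1L]
  hi <- config$pixel_range[2L]
  X <- X0
  D <- nrow(X0)
  p_cur <- net_forward(model, X)$probs[cbind(wrong_classes, seq_len(n))]
  traj <- lapply(seq_len(n), function(i) p_cur[i])
  accepted <- vector("list", n)
  iters <- integer(n)
  active <- p_cur <= config$stop_prob
  it <- 0L
  while (any(active) && it < config$max_iter) {
    it <- it + 1L
    ia <- which(active)
    noise <- matrix(stats::runif(D * length(ia), -config$noise_bound,
                                 config$noise_bound), D, length(ia))
    cand <- pmin(pmax(X[, ia, drop = FALSE] + noise, lo), hi)
    pc <- net_forward(model, cand)$probs[cbind(wrong_classes[ia],
                                               seq_along(ia))]
    for (k in seq_along(ia)) {
      i <- ia[k]
      iters[i] <- it
      if (pc[k] > p_cur[i]) {
        X[, i] <- cand[, k]
        p_cur[i] <- pc[k]
        accepted[[i]] <- c(accepted[[i]], it)
      }
      traj[[i]] <- c(traj[[i]], p_cur[i])
      if (p_cur[i] > config$stop_prob) active[i] <- FALSE
    }
  }
  list(X = X, prob = p_cur, iterations = iters, trajectory = traj,
       accepted = accepted, converged = p_cur > config$stop_prob)
}

#' Generate a batch of AI images by noise hill-climbing
#'
#' Batched variant of [generate_ai_hillclimb()]: every regular image climbs
#' toward its own wrong class, all images sharing each iteration's forward
#' pass.
#'
#' @param model a \code{surrogate_cnn}.
#' @param re_images stimulus set / image array / pixel matrix of regular
#'   images.
#' @param wrong_classes integer vector, one wrong class per image.
#' @param config an [adversarial_config()].
#' @param seed seed for the noise draws.
#' @return list of \code{generation_result}.
#' @export
generate_ai_batch <- function(model, re_images, wrong_classes,
                              config = adversarial_config(), seed = 1L) {
  X0 <- as_image_matrix(re_images, shape = model$input_shape)$X
  res <- hillclimb_batch(model, X0, wrong_classes, config, seed)
  lapply(seq_len(ncol(X0)), function(i) {
    make_generation_result(res$X[, i], model$input_shape,
                           as.integer(wrong_classes[i]), res$prob[i],
                           res$trajectory[[i]], res$iterations[i],
                           res$converged[i], mode = "ai-hillclimb",
                           extra = list(accepted = res$accepted[[i]]))
  })
}

#' Generate an AI image by regularized gradient ascent (gradient variant)
#'
#' Same ascent as [generate_an()] but anchored at (and initialized from)
#' the regular image, targeting the wrong class with stopping probability
#' \code{config$target_prob} (0.99 by default). With \code{lambda_reg = 0}
#' this reduces exactly to [generate_an()] targeted at the wrong class and
#' initialized at the regular image.
#'
#' @inheritParams generate_ai_hillclimb
#' @return a \code{generation_result}.
#' @export
generate_ai_gradient <- function(model, re_image, wrong_class,
                                 config = adversarial_config(),
                                 true_class = NULL) {
  wrong_class <- as.integer(wrong_class)
  if (!is.null(true_class) && wrong_class == as.integer(true_class)) {
    stop("wrong_class must differ from the true class", call. = FALSE)
  }
  X0 <- as_image_matrix(re_image, shape = model$input_shape)$X
  res <- ascend_batch(model, X0, wrong_class, X0, config)
  make_generation_result(res$X[, 1L], model$input_shape, wrong_class,
                         res$prob[1L], res$trajectory[[1L]],
                         res$iterations[1L], res$converged[1L],
                         mode = "ai-gradient")
}

#' Seeded derangement of class labels for wrong-class assignment
#'
#' Draws a uniformly random permutation with no fixed point, used to assign
#' each regular image a wrong class for interference generation.
#'
#' @param n_classes number of classes (>= 2).
#' @param seed integer seed.
#' @return integer vector \code{w} with \code{w[i] != i} for all i.
#' @export
wrong_class_assignment <- function(n_classes, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("need at least 2 classes", call. = FALSE)
  set.seed(seed)
  repeat {
    p <- sample(n_classes)
    if (all(p != seq_len(n_classes))) return(p)
  }
}
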