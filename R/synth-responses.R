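#' Simulate vertex responses with controllable representational coupling
#'
#' Generates the beta-weight responses of every vertex on a cortical sheet
#' to the regular (RE), adversarial-noise (AN) and adversarial-interference
#' (AI) images, with recorded ground truth. Each vertex is assigned a
#' source stage of the classifier and responds to the RE images through a
#' sparse linear combination (\code{sparsity_k} nonzero weights) of that
#' stage's unit activations; the resulting tuning curve over images is
#' standardized and corrupted by additive Gaussian repetition noise.
#'
#' The responses to the adversarial images are generated at the
#' response-pattern level rather than by passing adversarial images through
#' a simulated brain: the AI tuning curve of a vertex is a
#' \code{rho_AI}-weighted mixture of its RE tuning curve with independent
#' standard normal noise, rescaled to equal variance
#' (\eqn{\rho z_{RE} + \sqrt{1-\rho^2}\, \epsilon}), and likewise for AN
#' with \code{rho_AN}. \code{rho = 1} duplicates the RE pattern exactly;
#' \code{rho = 0} decouples it completely. This makes the population-level
#' RE-AI and RE-AN representational similarities directly controllable.
#'
#' @param activations_by_layer named list (\code{L1..L8}) of images x units
#'   activation matrices for the RE images (see [stage_activations()]).
#' @param sheet a \code{cortical_sheet} from [make_sheet()].
#' @param sparsity_k number of nonzero generating weights per vertex.
#' @param rho_AI,rho_AN representational coupling of the AI / AN tuning
#'   curves to the RE tuning curve, in \code{[0, 1]}.
#' @param rep_noise_sd additive Gaussian noise per presentation, in units
#'   of the (unit-variance) standardized tuning curve.
#' @param reps number of repetitions (2 at the experiment defaults).
#' @param seed integer seed; the same arguments and seed reproduce the
#'   dataset bit-exactly.
#' @return a \code{response_dataset}: list with \code{betas} (vertex x
#'   image x repetition array over the 3 x n_images stimuli, ordered RE,
#'   AN, AI), \code{image_info} (data frame with \code{image_id},
#'   \code{type}, \code{class_id}), \code{sheet}, and \code{ground_truth}
#'   (per-vertex source layer, support indices, weights, plus all
#'   generator arguments and the seed).
#' @export
simulate_vertex_responses <- function(activations_by_layer, sheet,
                                      sparsity_k = 3L, rho_AI = 0.8,
                                      rho_AN = 0.0, rep_noise_sd = 0.4,
                                      reps = 2L, seed = 1L) {
  if (is.null(names(activations_by_layer))) {
    names(activations_by_layer) <- paste0("L", seq_along(activations_by_layer))
  }
  n_layers <- length(activations_by_layer)
  n_img <- nrow(activations_by_layer[[1L]])
  ok <- vapply(activations_by_layer, function(a) {
    is.matrix(a) && nrow(a) == n_img
  }, logical(1L))
  if (!all(ok)) {
    stop("activations missing or misshapen for layer(s): ",
         paste(names(activations_by_layer)[!ok], collapse = ", "),
         call. = FALSE)
  }
  if (rho_AI < 0 || rho_AI > 1 || rho_AN < 0 || rho_AN > 1) {
    stop("rho_AI and rho_AN must be in [0, 1]", call. = FALSE)
  }
  if (sparsity_k < 1L) stop("sparsity_k must be >= 1", call. = FALSE)
  n_v <- nrow(sheet)
  set.seed(seed)
  layer_of <- sample(n_layers, n_v, replace = TRUE)
  betas <- array(0, dim = c(n_v, 3L * n_img, reps))
  gt_support <- vector("list", n_v)
  gt_weights <- vector("list", n_v)
  mix <- function(z, rho) {
    eps <- stats::rnorm(length(z))
    eps <- (eps - mean(eps)) / stats::sd(eps)
    rho * z + sqrt(1 - rho^2) * eps
  }
  for (v in seq_len(n_v)) {
    A <- activations_by_layer[[layer_of[v]]]
    support <- sample(ncol(A), min(sparsity_k, ncol(A)))
    w <- stats::rnorm(length(support))
    raw <- as.vector(A[, support, drop = FALSE] %*% w)
    s <- stats::sd(raw)
    z_re <- if (s > 0) (raw - mean(raw)) / s else raw * 0
    z_an <- mix(z_re, rho_AN)
    z_ai <- mix(z_re, rho_AI)
    for (r in seq_len(reps)) {
      betas[v, , r] <- c(z_re, z_an, z_ai) +
        stats::rnorm(3L * n_img, sd = rep_noise_sd)
    }
    gt_support[[v]] <- support
    gt_weights[[v]] <- w
  }
  image_info <- data.frame(
    image_id = seq_len(3L * n_img),
    type = rep(c("RE", "AN", "AI"), each = n_img),
    class_id = rep(seq_len(n_img), times = 3L)
  )
  structure(list(
    betas = betas,
    image_info = image_info,
    sheet = sheet,
    ground_truth = list(layer = layer_of, support = gt_support,
                        weights = gt_weights, sparsity_k = sparsity_k,
                        rho_AI = rho_AI, rho_AN = rho_AN,
                        rep_noise_sd = rep_noise_sd, reps = reps,
                        seed = seed)
  ), class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  d <- dim(x$betas)
  cat(sprintf(
    "Response dataset: %d vertices x %d images x %d repetitions (rho_AI=%.2f, rho_AN=%.2f, noise sd=%.2f)\n",
    d[1L], d[2L], d[3L], x$ground_truth$rho_AI, x$ground_truth$rho_AN,
    x$ground_truth$rep_noise_sd))
  invisible(x)
}

#' Regenerate a response dataset from its recorded ground truth
#'
#' Replays the simulation with the arguments and seed stored in
#' \code{ground_truth}; the result is bit-identical to the original.
#'
#' @param responses a \code{response_dataset}.
#' @param activations_by_layer the activation list originally supplied.
#' @return a \code{response_dataset}.
#' @export
regenerate_responses <- function(responses, activations_by_layer) {
  gt <- responses$ground_truth
  simulate_vertex_responses(activations_by_layer, responses$sheet,
                            sparsity_k = gt$sparsity_k, rho_AI = gt$rho_AI,
                            rho_AN = gt$rho_AN,
                            rep_noise_sd = gt$rep_noise_sd,
                            reps = gt$reps, seed = gt$seed)
}

# Vertex x image matrix for one image type, repetitions averaged (or a
# single repetition when rep is given).
response_patterns <- function(responses, type = c("RE", "AN", "AI"),
                              rep = NULL, vertices = NULL) {
  type <- match.arg(type)
  cols <- which(responses$image_info$type == type)
  if (is.null(vertices)) vertices <- seq_len(dim(responses$betas)[1L])
  if (is.null(rep)) {
    B <- responses$betas[vertices, cols, , drop = FALSE]
    out <- apply(B, c(1L, 2L), mean)
  } else {
    out <- responses$betas[vertices, cols, rep]
    if (is.null(dim(out))) out <- matrix(out, nrow = length(vertices))
  }
  out
}
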