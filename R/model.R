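#' Train the eight-stage surrogate classifier
#'
#' Fits a small convolutional network with the canonical eight-stage layout
#' used throughout the package: five convolutional stages with ReLU gating
#' (spatial 2x2 max-pooling after stages 1, 2 and 5), two fully connected
#' ReLU stages, and a softmax output stage. The network stands in for a
#' large pretrained classifier: it exposes per-stage activations and input
#' gradients, which is all the downstream representational analyses need.
#'
#' Training uses mini-batch Adam on the softmax cross-entropy, is fully
#' deterministic given \code{seed}, and evaluates a stratified held-out
#' split. If held-out accuracy falls below \code{min_accuracy} the function
#' signals an error of class \code{"advrep_training_error"} carrying the
#' per-class accuracy table, rather than returning a silently poor model.
#'
#' @param stimuli a \code{stimulus_set} (see [generate_image_classes()]) or
#'   a numeric array \code{H x W x C x n} of pixel intensities in
#'   \code{[0, 255]}.
#' @param labels integer class labels in \code{1..n_classes}; taken from
#'   the stimulus set when omitted.
#' @param epochs number of passes over the training split.
#' @param seed integer seed controlling initialization, batching and the
#'   held-out split.
#' @param conv_widths,fc_widths channel/unit counts of the five
#'   convolutional and two fully connected stages.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param holdout fraction of images held out for evaluation.
#' @param min_accuracy minimum acceptable held-out accuracy.
#' @param verbose print per-epoch loss.
#' @return an object of class \code{surrogate_cnn} with elements
#'   \code{stages} (stage specifications), \code{params} (weights),
#'   \code{input_shape}, \code{n_classes} and \code{holdout_accuracy}.
#' @examples
#' set.seed(1)
#' stim <- generate_image_classes(2, 30, image_size = 16, seed = 5)
#' net <- train_surrogate(stim, epochs = 6, seed = 5)
#' net$holdout_accuracy
#' @export
train_surrogate <- function(stimuli, labels = NULL, epochs = 30L, seed = 1L,
                            conv_widths = c(8L, 16L, 16L, 16L, 32L),
                            fc_widths = c(128L, 64L),
                            lr = 1e-3, batch_size = 32L, holdout = 0.2,
                            min_accuracy = 0.95, verbose = FALSE) {
  d <- as_image_matrix(stimuli)
  if (is.null(labels)) {
    if (is.null(d$labels)) {
      stop("labels must be supplied when stimuli is a bare array", call. = FALSE)
    }
    labels <- d$labels
  }
  labels <- as.integer(labels)
  n <- ncol(d$X)
  if (length(labels) != n) stop("one label per image required", call. = FALSE)
  n_classes <- max(labels)
  if (length(unique(labels)) < 2L) {
    stop("at least 2 classes are required to train the surrogate", call. = FALSE)
  }
  tab <- table(labels)
  if (min(tab) < 20L) {
    stop("at least 20 images per class are required; smallest class has ",
         min(tab), call. = FALSE)
  }

  set.seed(seed)
  # stratified held-out split
  hold <- unlist(lapply(split(seq_len(n), labels), function(ix) {
    sample(ix, max(1L, round(holdout * length(ix))))
  }), use.names = FALSE)
  tr <- setdiff(seq_len(n), hold)

  net <- new_surrogate(d$shape, n_classes, conv_widths, fc_widths, seed)
  state <- adam_init(net$params)
  t_step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    losses <- c()
    for (start in seq(1L, length(ord), by = batch_size)) {
      ix <- ord[start:min(start + batch_size - 1L, length(ord))]
      Xb <- d$X[, ix, drop = FALSE]
      yb <- labels[ix]
      fwd <- net_forward(net, Xb, want_cache = TRUE)
      P <- fwd$probs
      sel <- cbind(yb, seq_along(ix))
      losses <- c(losses, -mean(log(pmax(P[sel], 1e-12))))
      dLogits <- P
      dLogits[sel] <- dLogits[sel] - 1
      dLogits <- dLogits / length(ix)
      bk <- net_backward(net, fwd, dLogits)
      t_step <- t_step + 1L
      upd <- adam_step(net$params, bk$grads, state, lr, t_step)
      net$params <- upd$params
      state <- upd$state
    }
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, mean(losses)))
  }

  pred <- predict_classes(net, d$X[, hold, drop = FALSE])
  acc <- mean(pred == labels[hold])
  per_class <- tapply(pred == labels[hold], labels[hold], mean)
  net$holdout_accuracy <- acc
  net$holdout_per_class <- per_class
  net$seed <- seed
  class(net) <- "surrogate_cnn"
  if (acc < min_accuracy) {
    cond <- structure(
      class = c("advrep_training_error", "error", "condition"),
      list(message = sprintf(
        "surrogate held-out accuracy %.3f below required %.3f (per-class: %s)",
        acc, min_accuracy,
        paste(sprintf("%s=%.2f", names(per_class), per_class), collapse = ", ")),
        call = sys.call(-1), model = net)
    )
    stop(cond)
  }
  net
}

# Untrained surrogate with seeded He-normal weights (internal; also used
# for toy-model gradient checks).
new_surrogate <- function(input_shape, n_classes,
                          conv_widths = c(8L, 16L, 16L, 16L, 32L),
                          fc_widths = c(128L, 64L), seed = 1L) {
  stages <- surrogate_architecture(input_shape, n_classes, conv_widths,
                                   fc_widths)
  structure(list(stages = stages, params = init_params(stages, seed),
                 input_shape = input_shape, n_classes = n_classes,
                 chw = chw_perm(input_shape[1L], input_shape[2L],
                                input_shape[3L])),
            class = "surrogate_cnn")
}

predict_classes <- function(net, X, chunk = 256L) {
  out <- integer(ncol(X))
  for (start in seq(1L, ncol(X), by = chunk)) {
    ix <- start:min(start + chunk - 1L, ncol(X))
    P <- net_forward(net, X[, ix, drop = FALSE])$probs
    out[ix] <- max.col(t(P), ties.method = "first")
  }
  out
}

#' @export
print.surrogate_cnn <- function(x, ...) {
  cat("Surrogate hierarchical classifier (8 stages)\n")
  cat(sprintf("  input: %s, classes: %d\n",
              paste(x$input_shape, collapse = "x"), x$n_classes))
  for (st in x$stages) {
    cat(sprintf("  %s  %-22s width %d, %d units\n",
                st$name, st$kind, st$width, st$n_units))
  }
  if (!is.null(x$holdout_accuracy)) {
    cat(sprintf("  held-out accuracy: %.3f\n", x$holdout_accuracy))
  }
  invisible(x)
}

#' Stage specifications of a surrogate classifier
#'
#' @param model a \code{surrogate_cnn}.
#' @return data frame with \code{name}, \code{kind}, \code{width} and
#'   \code{n_units} for each of the 8 stages.
#' @export
stage_specs <- function(model) {
  data.frame(
    name = vapply(model$stages, `[[`, character(1L), "name"),
    kind = vapply(model$stages, `[[`, character(1L), "kind"),
    width = vapply(model$stages, function(s) as.integer(s$width),
                   integer(1L)),
    n_units = vapply(model$stages, function(s) as.integer(s$n_units),
                     integer(1L))
  )
}

#' Predict class labels or probabilities from a surrogate classifier
#'
#' @param object a \code{surrogate_cnn}.
#' @param newdata image array (\code{H x W x C} or \code{H x W x C x n}),
#'   image matrix (pixels x n) or \code{stimulus_set}.
#' @param type \code{"class"} for top-1 labels, \code{"prob"} for the full
#'   softmax matrix (classes x images).
#' @param ... unused.
#' @export
predict.surrogate_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as_image_matrix(newdata, shape = object$input_shape)$X
  if (type == "class") {
    predict_classes(object, X)
  } else {
    net_forward(object, X)$probs
  }
}

#' Forward pass returning per-stage activations
#'
#' Runs one image through the classifier and returns the flattened
#' activation vector of every stage together with the softmax output.
#' Stage 8 activations are the class probabilities themselves.
#'
#' @param model a \code{surrogate_cnn}.
#' @param image an \code{H x W x C} array (or pixel vector) on the
#'   \code{[0, 255]} scale.
#' @return an \code{activation_stack}: list with \code{per_stage} (named
#'   list \code{L1..L8} of numeric vectors), \code{probabilities} and
#'   \code{top1}.
#' @export
forward_with_activations <- function(model, image) {
  X <- as_image_matrix(image, shape = model$input_shape)$X
  if (ncol(X) != 1L) stop("forward_with_activations takes a single image", call. = FALSE)
  fwd <- net_forward(model, X, want_stages = TRUE)
  per_stage <- lapply(fwd$acts, as.vector)
  names(per_stage) <- paste0("L", 1:8)
  structure(list(per_stage = per_stage,
                 probabilities = as.vector(fwd$probs),
                 top1 = which.max(fwd$probs)),
            class = "activation_stack")
}

#' Per-stage activation matrices for a batch of images
#'
#' Convenience wrapper used by the representational analyses: runs all
#' images through the classifier and returns, for each of the 8 stages, an
#' images x units activation matrix.
#'
#' @param model a \code{surrogate_cnn}.
#' @param images image array \code{H x W x C x n}, pixel matrix or
#'   \code{stimulus_set}.
#' @param chunk number of images per forward batch.
#' @return named list \code{L1..L8} of \code{n x units} matrices.
#' @export
stage_activations <- function(model, images, chunk = 64L) {
  X <- as_image_matrix(images, shape = model$input_shape)$X
  n <- ncol(X)
  out <- lapply(model$stages, function(st) matrix(0, n, st$n_units))
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    fwd <- net_forward(model, X[, ix, drop = FALSE], want_stages = TRUE)
    for (s in 1:8) out[[s]][ix, ] <- t(fwd$acts[[s]])
  }
  names(out) <- paste0("L", 1:8)
  out
}

#' Gradient of a class probability with respect to image pixels
#'
#' Backpropagates from the softmax output to pixel space, returning the
#' gradient of the probability (or log-probability) of \code{class_id}
#' with respect to the raw pixel intensities.
#'
#' @param model a \code{surrogate_cnn}.
#' @param image \code{H x W x C} array or pixel vector on \code{[0, 255]}.
#' @param class_id target class in \code{1..n_classes}.
#' @param on differentiate the probability (default) or log-probability.
#' @return numeric array with the same shape as \code{image}.
#' @export
input_gradient <- function(model, image, class_id, on = c("prob", "logprob")) {
  on <- match.arg(on)
  class_id <- as.integer(class_id)
  if (class_id < 1L || class_id > model$n_classes) {
    stop("class_id must be in 1..", model$n_classes, call. = FALSE)
  }
  X <- as_image_matrix(image, shape = model$input_shape)$X
  if (ncol(X) != 1L) stop("input_gradient takes a single image", call. = FALSE)
  g <- net_input_gradient(model, X, class_id, on = on)$grad
  array(g, dim = model$input_shape)
}

# Coerce stimulus sets / arrays / vectors to a pixel matrix (D x n).
as_image_matrix <- function(x, shape = NULL) {
  if (inherits(x, "stimulus_set")) {
    return(list(X = x$pixels, labels = x$class_id, shape = x$image_shape))
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    d <- dim(x)
    if (!is.null(shape) && !identical(as.integer(d[1:3]), as.integer(shape))) {
      stop("image array is ", paste(d[1:3], collapse = "x"),
           " pixels; model expects ", paste(shape, collapse = "x"),
           call. = FALSE)
    }
    return(list(X = matrix(x, prod(d[1:3]), d[4L]), labels = NULL, shape = d[1:3]))
  }
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    if (!is.null(shape) && !identical(as.integer(d), as.integer(shape))) {
      stop("image array is ", paste(d, collapse = "x"),
           " pixels; model expects ", paste(shape, collapse = "x"),
           call. = FALSE)
    }
    return(list(X = matrix(as.vector(x), ncol = 1L), labels = NULL, shape = d))
  }
  if (is.matrix(x)) {
    if (!is.null(shape) && nrow(x) != prod(shape)) {
      stop("image matrix has ", nrow(x), " pixels; model expects ",
           prod(shape), call. = FALSE)
    }
    return(list(X = x, labels = NULL, shape = shape))
  }
  if (is.numeric(x)) {
    if (!is.null(shape) && length(x) != prod(shape)) {
      stop("image vector has ", length(x), " pixels; model expects ",
           prod(shape), call. = FALSE)
    }
    return(list(X = matrix(x, ncol = 1L), labels = NULL, shape = shape))
  }
  stop("cannot interpret 'stimuli' as images", call. = FALSE)
}
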