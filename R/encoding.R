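#' Build a standardized feature matrix from stage activations
#'
#' Assembles the design matrix of a forward encoding model: one row per
#' image, one column per unit of the chosen stage, plus a trailing
#' intercept column of ones. Feature columns are standardized to zero mean
#' and unit variance (computed on these images, typically the training
#' set); the centers and scales are stored so the identical transformation
#' can be reused at test time. Zero-variance columns are centered but left
#' unscaled.
#'
#' @param activations images x units activation matrix for one stage, or a
#'   named list of stage matrices together with \code{stage}.
#' @param stage stage name (\code{"L1"}..\code{"L8"}) when
#'   \code{activations} is a list.
#' @param image_order optional row permutation applied before assembly.
#' @param scaling optional list \code{(center, scale)} from a previous
#'   call, reused verbatim (test-time transform).
#' @return a numeric matrix \code{m x (n_units + 1)} with attributes
#'   \code{center} and \code{scale}; the last column is the intercept.
#' @export
build_feature_matrix <- function(activations, stage = NULL,
                                 image_order = NULL, scaling = NULL) {
  A <- if (is.list(activations) && !is.null(stage)) {
    activations[[stage]]
  } else {
    activations
  }
  if (!is.matrix(A)) stop("activations must form a matrix", call. = FALSE)
  if (!is.null(image_order)) A <- A[image_order, , drop = FALSE]
  if (is.null(scaling)) {
    center <- colMeans(A)
    scale <- apply(A, 2L, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  } else {
    center <- scaling$center
    scale <- scaling$scale
  }
  Z <- sweep(sweep(A, 2L, center, `-`), 2L, scale, `/`)
  X <- cbind(Z, intercept = 1)
  attr(X, "center") <- center
  attr(X, "scale") <- scale
  X
}

#' Regularized orthogonal matching pursuit (ROMP)
#'
#' Greedy sparse recovery for the underdetermined regression
#' \eqn{y = Xw} with \eqn{\min ||w||_0}: per iteration the residual is
#' correlated with all feature columns (\eqn{u = X^T r}), the
#' \code{sparsity_s} largest entries of \eqn{|u|} are shortlisted, the
#' shortlist is regularized to its most energetic subset with comparable
#' magnitudes (all within a factor of 2), that subset joins the support,
#' and the weights are refit by least squares on the support. Iteration
#' stops when the support reaches \code{2 * sparsity_s} non-intercept
#' features or the residual norm drops to \code{residual_tol}. The
#' intercept (last column) is always in the support and never competes in
#' the selection.
#'
#' @param X feature matrix from [build_feature_matrix()] (intercept last).
#' @param y numeric response vector, one value per row of \code{X}.
#' @param sparsity_s per-iteration shortlist size; the support is capped at
#'   \code{2 * sparsity_s} features.
#' @param residual_tol stopping residual norm; by default
#'   \code{1e-6 * ||y||}.
#' @return a \code{sparse_solution}: list with \code{w} (full-length weight
#'   vector, zeros off the support), \code{support} (non-intercept support
#'   indices), \code{residual_norm}, \code{iterations}, \code{fitted}.
#' @export
romp_solve <- function(X, y, sparsity_s = 10L, residual_tol = NULL) {
  sparsity_s <- as.integer(sparsity_s)
  if (sparsity_s < 1L) stop("sparsity_s must be >= 1", call. = FALSE)
  if (ncol(X) < 1L) stop("X must have at least one column", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  p <- ncol(X)
  icol <- p                               # intercept column
  feat <- seq_len(p - 1L)
  if (is.null(residual_tol)) residual_tol <- 1e-6 * sqrt(sum(y^2))

  w <- numeric(p)
  if (sqrt(sum(y^2)) <= residual_tol) {
    return(structure(list(w = w, support = integer(0L), residual_norm = 0,
                          iterations = 0L, fitted = rep(0, length(y))),
                     class = "sparse_solution"))
  }

  support <- integer(0L)
  fit_ls <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    ft <- tryCatch(stats::lsfit(Xs, y, intercept = FALSE)$coefficients,
                   error = function(e) NULL)
    if (is.null(ft) || anyNA(ft)) {
      # rank-deficient support: minimum-norm least squares via pseudoinverse
      warning("rank-deficient least squares on support; using minimum-norm solution",
              call. = FALSE)
      sv <- svd(Xs)
      pos <- sv$d > max(dim(Xs)) * .Machine$double.eps * sv$d[1L]
      ft <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
      ft <- as.vector(ft)
    }
    ft
  }

  # intercept-only start
  coefs <- fit_ls(icol)
  r <- y - X[, icol] * coefs
  it <- 0L
  repeat {
    if (sqrt(sum(r^2)) <= residual_tol || length(support) >= 2L * sparsity_s) {
      break
    }
    cand <- setdiff(feat, support)
    if (length(cand) == 0L) break
    u <- abs(as.vector(crossprod(X[, cand, drop = FALSE], r)))
    if (max(u) == 0) break
    ord <- order(u, decreasing = TRUE)
    J <- ord[seq_len(min(sparsity_s, length(cand)))]
    uJ <- u[J]                            # sorted decreasing
    # regularization: maximal contiguous windows with max <= 2 * min,
    # keep the one with the largest l2 energy
    best <- NULL
    best_energy <- -Inf
    i <- 1L
    while (i <= length(J)) {
      j <- i
      while (j < length(J) && uJ[i] <= 2 * uJ[j + 1L]) j <- j + 1L
      energy <- sum(uJ[i:j]^2)
      if (energy > best_energy) {
        best_energy <- energy
        best <- i:j
      }
      i <- j + 1L
    }
    J0 <- cand[J[best]]
    # respect the support cap, preferring larger correlations
    room <- 2L * sparsity_s - length(support)
    if (length(J0) > room) J0 <- J0[seq_len(room)]
    support <- c(support, J0)
    it <- it + 1L
    cols <- c(support, icol)
    coefs <- fit_ls(cols)
    r <- y - X[, cols, drop = FALSE] %*% coefs
  }
  cols <- c(support, icol)
  w[cols] <- coefs
  structure(list(w = w, support = sort(support),
                 residual_norm = sqrt(sum(r^2)), iterations = it,
                 fitted = as.vector(X[, cols, drop = FALSE] %*% coefs)),
            class = "sparse_solution")
}

#' @export
print.sparse_solution <- function(x, ...) {
  cat(sprintf(
    "Sparse solution: %d features + intercept, residual norm %.3g, %d iterations\n",
    length(x$support), x$residual_norm, x$iterations))
  invisible(x)
}

#' @export
coef.sparse_solution <- function(object, ...) object$w

#' Train the bank of forward encoding models
#'
#' Fits, for every selected vertex and every classifier stage, a sparse
#' linear encoding model predicting the vertex's regular-image responses
#' (repetitions averaged) from the stage's unit activations via
#' [romp_solve()]. With 5 ROIs and 8 stages this yields 40 (ROI, stage)
#' model groups.
#'
#' @param responses a \code{response_dataset}.
#' @param activations_by_layer named list of stage activation matrices for
#'   the RE images (images x units).
#' @param selected_vertices data frame from [select_vertices()].
#' @param stages stage names to model (default all 8).
#' @param sparsity_s per-iteration ROMP shortlist size.
#' @return an \code{encoding_bank}: list with \code{models} (nested list
#'   \code{roi -> stage -> list of sparse_solution}), \code{vertices}
#'   (per-ROI vertex ids), \code{scalings} (per-stage feature scaling) and
#'   \code{stages}, \code{rois}.
#' @export
train_models <- function(responses, activations_by_layer, selected_vertices,
                         stages = paste0("L", 1:8), sparsity_s = 10L) {
  rois <- sort(unique(selected_vertices$roi))
  re <- response_patterns(responses, "RE")
  feats <- list()
  scalings <- list()
  for (st in stages) {
    X <- build_feature_matrix(activations_by_layer, stage = st)
    feats[[st]] <- X
    scalings[[st]] <- list(center = attr(X, "center"),
                           scale = attr(X, "scale"))
  }
  models <- list()
  vertices <- list()
  for (roi in rois) {
    vid <- selected_vertices$vertex_id[selected_vertices$roi == roi]
    vertices[[roi]] <- vid
    models[[roi]] <- list()
    for (st in stages) {
      X <- feats[[st]]
      models[[roi]][[st]] <- lapply(vid, function(v) {
        romp_solve(X, re[v, ], sparsity_s = sparsity_s)
      })
    }
  }
  structure(list(models = models, vertices = vertices, scalings = scalings,
                 stages = stages, rois = rois, sparsity_s = sparsity_s),
            class = "encoding_bank")
}

#' @export
print.encoding_bank <- function(x, ...) {
  cat(sprintf(
    "Encoding bank: %d ROIs x %d stages = %d model groups (%d vertices/ROI, ROMP s = %d)\n",
    length(x$rois), length(x$stages), length(x$rois) * length(x$stages),
    length(x$vertices[[1L]]), x$sparsity_s))
  invisible(x)
}

#' Predict vertex responses from an encoding bank
#'
#' @param object an \code{encoding_bank}.
#' @param newdata named list of stage activation matrices (images x units)
#'   for the stimuli to predict.
#' @param roi,stage model group to use.
#' @param ... unused.
#' @return images x vertices matrix of predicted responses.
#' @export
predict.encoding_bank <- function(object, newdata, roi, stage, ...) {
  X <- build_feature_matrix(newdata, stage = stage,
                            scaling = object$scalings[[stage]])
  sols <- object$models[[roi]][[stage]]
  W <- vapply(sols, `[[`, numeric(ncol(X)), "w")
  unname(X %*% W)
}

#' Test generalization of encoding models to adversarial images
#'
#' For every (ROI, stage) model group, predicts the responses to a set of
#' adversarial images from their activations, correlates prediction with
#' measurement per vertex across images (Pearson), and averages over
#' vertices. Inference per cell: a bootstrap CI from resampling a fraction
#' of the vertices without replacement, and a permutation p-value from
#' shuffling the image labels of the measured responses.
#'
#' @param bank an \code{encoding_bank} from [train_models()].
#' @param activations_adv named list of stage activation matrices for the
#'   adversarial images (same class order as training).
#' @param responses the \code{response_dataset} holding the measured
#'   responses.
#' @param type which measured responses to test against (\code{"AN"} or
#'   \code{"AI"}).
#' @param frac,n_boot,n_perm,seed inference parameters.
#' @return data frame with one row per (ROI, stage): \code{mean_r},
#'   \code{ci_lo}, \code{ci_hi}, \code{perm_p}, and a \code{vertex_r}
#'   attribute (list of per-vertex correlations).
#' @export
test_generalization <- function(bank, activations_adv, responses,
                                type = c("AI", "AN"), frac = 0.8,
                                n_boot = 1000L, n_perm = 1000L, seed = 1L) {
  type <- match.arg(type)
  measured_all <- response_patterns(responses, type)   # vertex x image
  out <- list()
  vertex_r <- list()
  k <- 0L
  for (roi in bank$rois) {
    vid <- bank$vertices[[roi]]
    M <- t(measured_all[vid, , drop = FALSE])          # images x vertices
    for (st in bank$stages) {
      k <- k + 1L
      P <- predict(bank, activations_adv, roi = roi, stage = st)
      # standardize once; row permutations of a standardized matrix stay
      # standardized, so the permutation null reduces to cross-products
      Ps <- scale(P); Ps[!is.finite(Ps)] <- 0
      Ms <- scale(M); Ms[!is.finite(Ms)] <- 0
      n_img <- nrow(M)
      r_v <- colSums(Ps * Ms) / (n_img - 1L)
      mean_r <- mean(r_v)
      set.seed(seed + k)
      n_v <- length(r_v)
      m <- floor(frac * n_v)
      boot <- replicate(n_boot, mean(r_v[sample(n_v, m)]))
      # permutation: shuffle image labels of the measured responses
      null <- vapply(seq_len(n_perm), function(b) {
        mean(colSums(Ps * Ms[sample(n_img), , drop = FALSE]) / (n_img - 1L))
      }, numeric(1L))
      out[[k]] <- data.frame(
        roi = roi, stage = st, type = type, mean_r = mean_r,
        ci_lo = stats::quantile(boot, 0.025, names = FALSE),
        ci_hi = stats::quantile(boot, 0.975, names = FALSE),
        perm_p = (1 + sum(null >= mean_r)) / (n_perm + 1))
      vertex_r[[paste(roi, st, sep = ".")]] <- r_v
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "vertex_r") <- vertex_r
  res
}

# Columnwise Pearson correlation between two equally-shaped matrices;
# zero-variance columns yield 0 (no linear association detectable).
pearson_cols <- function(A, B) {
  As <- scale(A)
  Bs <- scale(B)
  r <- colSums(As * Bs) / (nrow(A) - 1L)
  r[!is.finite(r)] <- 0
  r
}
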