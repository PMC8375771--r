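#' Representational dissimilarity matrix
#'
#' Computes the pairwise dissimilarity between the response patterns of a
#' set of items. The default metric is correlation distance (1 minus the
#' Pearson correlation between item feature vectors); squared-free
#' Euclidean distance is available as an alternative.
#'
#' @param activations items x features numeric matrix (one row per image).
#' @param item_ids optional item identifiers (defaults to row order).
#' @param metric \code{"correlation"} (default) or \code{"euclidean"}.
#' @return an \code{rdm}: symmetric zero-diagonal matrix with
#'   \code{item_ids} attribute.
#' @examples
#' a <- matrix(c(1, 2, 3, 3, 2, 1, 2, 4, 6), 3, byrow = TRUE)
#' compute_rdm(a)
#' @export
compute_rdm <- function(activations, item_ids = NULL,
                        metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.matrix(activations)) activations <- as.matrix(activations)
  n <- nrow(activations)
  if (n < 2L) stop("need at least 2 items", call. = FALSE)
  if (is.null(item_ids)) item_ids <- seq_len(n)
  if (metric == "correlation") {
    v <- apply(activations, 1L, stats::var)
    if (any(v == 0)) {
      stop("zero-variance feature vector for item(s): ",
           paste(item_ids[v == 0], collapse = ", "),
           "; correlation distance undefined", call. = FALSE)
    }
    m <- 1 - stats::cor(t(activations))
  } else {
    m <- as.matrix(stats::dist(activations))
  }
  diag(m) <- 0
  dimnames(m) <- list(item_ids, item_ids)
  structure(m, item_ids = item_ids, metric = metric,
            class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d items, metric = %s\n", nrow(x), attr(x, "metric")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

upper_entries <- function(m) m[upper.tri(m)]

#' Write an RDM to CSV with an item-id header
#'
#' @param rdm an \code{rdm}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  df <- as.data.frame(unclass(rdm))
  names(df) <- attr(rdm, "item_ids")
  utils::write.csv(cbind(item_id = attr(rdm, "item_ids"), df), path,
                   row.names = FALSE)
  invisible(path)
}

#' Spearman similarity between two RDMs
#'
#' Rank correlation between the strictly-upper-triangle entries of two
#' RDMs over the same items, with average ranks for ties. Rank correlation
#' is the recommended statistic for comparing representational geometries
#' because it is invariant to monotone transformations of the
#' dissimilarity scale.
#'
#' @param rdm_a,rdm_b RDMs over identical item sets in identical order.
#' @return Spearman correlation in \code{[-1, 1]}.
#' @export
rdm_similarity <- function(rdm_a, rdm_b) {
  if (!identical(dim(rdm_a), dim(rdm_b)) ||
      !identical(attr(rdm_a, "item_ids"), attr(rdm_b, "item_ids"))) {
    stop("RDMs must cover identical item sets in identical order",
         call. = FALSE)
  }
  stats::cor(upper_entries(rdm_a), upper_entries(rdm_b),
             method = "spearman")
}

# Fast internal path: correlation-distance RDM upper triangles and their
# Spearman correlation, skipping validation.
rdm_upper <- function(activations) {
  cm <- stats::cor(t(activations))
  1 - cm[upper.tri(cm)]
}

spearman_vec <- function(a, b) stats::cor(rank(a), rank(b))

#' RE-AN and RE-AI similarities for one unit population
#'
#' Computes the three RDMs (regular, adversarial-noise and
#' adversarial-interference images) over the same units and returns the
#' rank correlation of the regular-image RDM with each adversarial RDM.
#'
#' @param acts_re,acts_an,acts_ai items x units activation (or response)
#'   matrices sharing item order by class.
#' @return named numeric vector \code{c(r_re_an, r_re_ai)}.
#' @export
similarity_pair <- function(acts_re, acts_an, acts_ai) {
  u_re <- rdm_upper(check_rdm_input(acts_re, "RE"))
  u_an <- rdm_upper(check_rdm_input(acts_an, "AN"))
  u_ai <- rdm_upper(check_rdm_input(acts_ai, "AI"))
  c(r_re_an = spearman_vec(u_re, u_an), r_re_ai = spearman_vec(u_re, u_ai))
}

check_rdm_input <- function(a, label) {
  if (!is.matrix(a)) a <- as.matrix(a)
  v <- apply(a, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance ", label, " pattern for item(s): ",
         paste(which(v == 0), collapse = ", "), call. = FALSE)
  }
  a
}

#' Bootstrap test of the RE-AI minus RE-AN similarity difference
#'
#' Resamples a fraction of the units (voxels, vertices or artificial
#' neurons) without replacement, recomputes both similarities in each
#' replicate and records their difference. The replicate distribution
#' yields a percentile confidence interval and a one-sided p-value for the
#' directional hypothesis that the RE-AI similarity exceeds the RE-AN
#' similarity.
#'
#' @param acts_re,acts_an,acts_ai items x units matrices.
#' @param frac fraction of units per replicate (0.8 by default; replicates
#'   of \code{frac = 1} all equal the point estimate).
#' @param n_boot number of replicates.
#' @param seed integer seed.
#' @return list with \code{observed} (named vector with both similarities
#'   and their difference), \code{diffs} (the \code{n_boot} replicate
#'   differences), \code{ci} (2.5/97.5 percentiles), and \code{p}
#'   (add-one one-sided bootstrap p, \eqn{(1 + \#\{d \le 0\})/(n_{boot}+1)}).
#' @export
bootstrap_difference <- function(acts_re, acts_an, acts_ai, frac = 0.8,
                                 n_boot = 1000L, seed = 1L) {
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  n_units <- ncol(acts_re)
  if (n_units < 10L) stop("need at least 10 units", call. = FALSE)
  obs <- similarity_pair(acts_re, acts_an, acts_ai)
  m <- floor(frac * n_units)
  set.seed(seed)
  diffs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ix <- sample(n_units, m)
    s <- similarity_pair(acts_re[, ix, drop = FALSE],
                         acts_an[, ix, drop = FALSE],
                         acts_ai[, ix, drop = FALSE])
    diffs[b] <- s["r_re_ai"] - s["r_re_an"]
  }
  list(observed = c(obs, diff = unname(obs["r_re_ai"] - obs["r_re_an"])),
       diffs = diffs,
       ci = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
       p = (1 + sum(diffs <= 0)) / (n_boot + 1),
       n_boot = n_boot, frac = frac)
}

#' Permutation null for the absolute RDM similarity
#'
#' Builds the null distribution of the similarity between the
#' regular-image RDM and an adversarial RDM by permuting the image labels
#' of the regular-image activations — pairing labels with wrong activity
#' patterns — and recomputing the similarity.
#'
#' @param acts_re,acts_adv items x units matrices.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list with \code{observed}, \code{null} (length \code{n_perm})
#'   and \code{p} (add-one one-sided p, observed >= null).
#' @export
permutation_null <- function(acts_re, acts_adv, n_perm = 1000L, seed = 1L) {
  n <- nrow(acts_re)
  if (n < 5L) stop("need at least 5 items", call. = FALSE)
  u_adv <- rdm_upper(check_rdm_input(acts_adv, "adversarial"))
  acts_re <- check_rdm_input(acts_re, "RE")
  obs <- spearman_vec(rdm_upper(acts_re), u_adv)
  set.seed(seed)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    u_perm <- rdm_upper(acts_re[sample(n), , drop = FALSE])
    null[b] <- spearman_vec(u_perm, u_adv)
  }
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (n_perm + 1), n_perm = n_perm)
}

#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in a sequence:
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)}, with the tie-corrected
#' variance, a continuity-corrected normal z statistic and a two-sided
#' p-value.
#'
#' @param sequence numeric vector, length >= 3.
#' @return list with \code{S}, \code{var_s}, \code{z} and \code{p}.
#' @examples
#' mann_kendall(c(1, 2, 3, 4, 5))$S  # 10
#' @export
mann_kendall <- function(sequence) {
  x <- as.numeric(sequence)
  n <- length(x)
  if (n < 3L) stop("sequence must have length >= 3", call. = FALSE)
  d <- sign(outer(x, x, `-`))
  S <- sum(d[lower.tri(d)])          # sum over i < j of sign(x_j - x_i)
  ties <- table(x)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s == 0) 0 else if (S > 0) (S - 1) / sqrt(var_s)
       else if (S < 0) (S + 1) / sqrt(var_s) else 0
  list(S = S, var_s = var_s, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Similarity summary for one unit population
#'
#' Combines the point similarities with bootstrap and permutation
#' inference: the RE-AI minus RE-AN difference is tested by unit
#' resampling, and each absolute similarity against its label-permutation
#' null. The label permutation is applied within each unit subsample
#' (permutation nested inside the resampling), so both tests see the same
#' resampling scheme.
#'
#' @param acts_re,acts_an,acts_ai items x units matrices.
#' @param frac resampled fraction of units.
#' @param n_boot bootstrap replicates for the difference test.
#' @param n_perm permutation replicates for the absolute-similarity nulls.
#' @param seed integer seed.
#' @return a \code{similarity_summary}: list with \code{r_re_an},
#'   \code{r_re_ai}, \code{diff}, \code{boot_ci}, \code{boot_p},
#'   \code{perm_p_an}, \code{perm_p_ai}, \code{n_boot}, \code{n_perm}.
#' @export
similarity_summary <- function(acts_re, acts_an, acts_ai, frac = 0.8,
                               n_boot = 1000L, n_perm = 1000L, seed = 1L) {
  bt <- bootstrap_difference(acts_re, acts_an, acts_ai, frac = frac,
                             n_boot = n_boot, seed = seed)
  n_units <- ncol(acts_re)
  n_items <- nrow(acts_re)
  m <- floor(frac * n_units)
  set.seed(seed + 1L)
  null_an <- numeric(n_perm)
  null_ai <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    ix <- sample(n_units, m)
    perm <- sample(n_items)
    u_perm <- rdm_upper(acts_re[perm, ix, drop = FALSE])
    null_an[b] <- spearman_vec(u_perm, rdm_upper(acts_an[, ix, drop = FALSE]))
    null_ai[b] <- spearman_vec(u_perm, rdm_upper(acts_ai[, ix, drop = FALSE]))
  }
  structure(list(
    r_re_an = unname(bt$observed["r_re_an"]),
    r_re_ai = unname(bt$observed["r_re_ai"]),
    diff = unname(bt$observed["diff"]),
    boot_ci = bt$ci,
    boot_p = bt$p,
    perm_p_an = (1 + sum(null_an >= bt$observed["r_re_an"])) / (n_perm + 1),
    perm_p_ai = (1 + sum(null_ai >= bt$observed["r_re_ai"])) / (n_perm + 1),
    n_boot = n_boot, n_perm = n_perm
  ), class = "similarity_summary")
}

#' @export
print.similarity_summary <- function(x, ...) {
  cat(sprintf(
    "RE-AN r = %.3f (perm p = %.4g); RE-AI r = %.3f (perm p = %.4g)\n",
    x$r_re_an, x$perm_p_an, x$r_re_ai, x$perm_p_ai))
  cat(sprintf("diff = %.3f, 95%% boot CI [%.3f, %.3f], boot p = %.4g\n",
              x$diff, x$boot_ci[1L], x$boot_ci[2L], x$boot_p))
  invisible(x)
}

#' Layer-wise similarity profile of a classifier
#'
#' Computes, for each of the 8 stages, the RE-AN and RE-AI similarities
#' over artificial neurons with bootstrap and permutation inference, and
#' Mann-Kendall trend tests over the two 8-point similarity profiles.
#'
#' @param model a \code{surrogate_cnn}.
#' @param stimulus_set a combined \code{stimulus_set} containing equal
#'   numbers of RE, AN and AI images with matching class order (see
#'   [combine_stimuli()]).
#' @param frac,n_boot,n_perm,seed inference parameters, as in
#'   [similarity_summary()].
#' @return list with \code{summaries} (list of 8
#'   \code{similarity_summary}), \code{profile} (data frame with one row
#'   per stage), \code{trend_re_an} and \code{trend_re_ai} (Mann-Kendall
#'   results).
#' @export
layer_profile <- function(model, stimulus_set, frac = 0.8, n_boot = 1000L,
                          n_perm = 1000L, seed = 1L) {
  types <- stimulus_set$type
  if (!all(c("RE", "AN", "AI") %in% types)) {
    stop("stimulus_set must contain RE, AN and AI images", call. = FALSE)
  }
  acts <- stage_activations(model, stimulus_set)
  summaries <- vector("list", 8L)
  for (s in 1:8) {
    A <- acts[[s]]
    keep <- apply(A, 2L, stats::var) > 0   # drop dead units
    A <- A[, keep, drop = FALSE]
    summaries[[s]] <- similarity_summary(
      A[types == "RE", , drop = FALSE], A[types == "AN", , drop = FALSE],
      A[types == "AI", , drop = FALSE],
      frac = frac, n_boot = n_boot, n_perm = n_perm, seed = seed + s)
  }
  names(summaries) <- paste0("L", 1:8)
  profile <- data.frame(
    stage = paste0("L", 1:8),
    r_re_an = vapply(summaries, `[[`, numeric(1L), "r_re_an"),
    r_re_ai = vapply(summaries, `[[`, numeric(1L), "r_re_ai"),
    boot_p = vapply(summaries, `[[`, numeric(1L), "boot_p"),
    perm_p_an = vapply(summaries, `[[`, numeric(1L), "perm_p_an"),
    perm_p_ai = vapply(summaries, `[[`, numeric(1L), "perm_p_ai"),
    row.names = NULL
  )
  list(summaries = summaries, profile = profile,
       trend_re_an = mann_kendall(profile$r_re_an),
       trend_re_ai = mann_kendall(profile$r_re_ai))
}

# Disk membership (indices into sheet rows) for every vertex: vertices of
# the same hemisphere within `radius` on the flat map.
searchlight_disks <- function(sheet, radius) {
  n <- nrow(sheet)
  disks <- vector("list", n)
  for (h in unique(sheet$hemisphere)) {
    ix <- which(sheet$hemisphere == h)
    d <- as.matrix(stats::dist(sheet[ix, c("x", "y")]))
    for (k in seq_along(ix)) {
      disks[[ix[k]]] <- ix[d[k, ] <= radius]
    }
  }
  disks
}

#' Searchlight map of RE-AN and RE-AI similarities
#'
#' For every vertex, gathers the vertices within \code{radius} sheet units
#' on the same hemisphere's flat map (Euclidean distance standing in for
#' geodesic distance on the already-flat synthetic sheet), and computes the
#' RE-AN and RE-AI similarities from the disk's response patterns with
#' repetitions averaged. Disks with fewer than \code{min_vertices} vertices
#' yield missing values.
#'
#' @param responses a \code{response_dataset}.
#' @param sheet the matching \code{cortical_sheet} (defaults to the one in
#'   \code{responses}).
#' @param radius disk radius in sheet units.
#' @param min_vertices minimum disk size for a defined similarity.
#' @return data frame with \code{vertex_id}, \code{r_re_an},
#'   \code{r_re_ai}, \code{disk_size}.
#' @export
searchlight_map <- function(responses, sheet = responses$sheet,
                            radius = 3.0, min_vertices = 3L) {
  if (nrow(sheet) != dim(responses$betas)[1L]) {
    stop("responses are not aligned to the sheet", call. = FALSE)
  }
  re <- response_patterns(responses, "RE")
  an <- response_patterns(responses, "AN")
  ai <- response_patterns(responses, "AI")
  disks <- searchlight_disks(sheet, radius)
  n <- nrow(sheet)
  out <- data.frame(vertex_id = sheet$vertex_id,
                    r_re_an = NA_real_, r_re_ai = NA_real_,
                    disk_size = vapply(disks, length, integer(1L)))
  for (v in seq_len(n)) {
    ix <- disks[[v]]
    if (length(ix) < min_vertices) next
    # degenerate (zero-variance) disk patterns yield NA, not an error
    s <- tryCatch(similarity_pair(t(re[ix, , drop = FALSE]),
                                  t(an[ix, , drop = FALSE]),
                                  t(ai[ix, , drop = FALSE])),
                  error = function(e) c(r_re_an = NA_real_,
                                        r_re_ai = NA_real_))
    out$r_re_an[v] <- s["r_re_an"]
    out$r_re_ai[v] <- s["r_re_ai"]
  }
  out
}
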