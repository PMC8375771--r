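#' Split-half RDM consistency map
#'
#' Reliability map used for task-related vertex selection: for each vertex,
#' the regular-image response patterns of the vertices in its searchlight
#' disk are split by presentation trial, one RDM is computed from each of
#' the two trials, and the two RDMs are compared by Spearman rank
#' correlation. Only regular-image responses enter this computation, so
#' selection is independent of the adversarial responses analyzed later.
#'
#' @param responses a \code{response_dataset} with exactly 2 repetitions.
#' @param sheet the matching \code{cortical_sheet}.
#' @param radius searchlight disk radius in sheet units.
#' @param min_vertices minimum disk size for a defined value.
#' @return data frame with \code{vertex_id}, \code{consistency} (Spearman
#'   value in \code{[-1, 1]}, \code{NA} for tiny disks), \code{disk_size}.
#' @export
splithalf_consistency <- function(responses, sheet = responses$sheet,
                                  radius = 3.0, min_vertices = 3L) {
  if (dim(responses$betas)[3L] != 2L) {
    stop("split-half consistency requires exactly 2 repetitions; got ",
         dim(responses$betas)[3L], call. = FALSE)
  }
  if (nrow(sheet) != dim(responses$betas)[1L]) {
    stop("responses are not aligned to the sheet", call. = FALSE)
  }
  re1 <- response_patterns(responses, "RE", rep = 1L)
  re2 <- response_patterns(responses, "RE", rep = 2L)
  disks <- searchlight_disks(sheet, radius)
  out <- data.frame(vertex_id = sheet$vertex_id,
                    consistency = NA_real_,
                    disk_size = vapply(disks, length, integer(1L)))
  for (v in seq_len(nrow(sheet))) {
    ix <- disks[[v]]
    if (length(ix) < min_vertices) next
    out$consistency[v] <- tryCatch(
      spearman_vec(rdm_upper(t(re1[ix, , drop = FALSE])),
                   rdm_upper(t(re2[ix, , drop = FALSE]))),
      error = function(e) NA_real_)
  }
  out
}

#' Select the most consistent vertices per hemisphere per ROI
#'
#' Retains, in every ROI, the \code{n_per_hemisphere} vertices with the
#' highest split-half consistency from each hemisphere (200 per ROI at the
#' defaults; the 400-per-ROI robustness variant is
#' \code{n_per_hemisphere = 200}). Vertices with missing consistency are
#' excluded before ranking; ties are broken by ascending vertex id so the
#' selection is a deterministic function of the consistency map.
#'
#' @param consistency_map data frame from [splithalf_consistency()].
#' @param sheet the matching \code{cortical_sheet}.
#' @param n_per_hemisphere vertices to keep per (ROI, hemisphere) block.
#' @return data frame with \code{roi}, \code{hemisphere}, \code{vertex_id},
#'   \code{consistency}, sorted by ROI, hemisphere and rank.
#' @export
select_vertices <- function(consistency_map, sheet, n_per_hemisphere = 100L) {
  n_per_hemisphere <- as.integer(n_per_hemisphere)
  tab <- merge(sheet, consistency_map[, c("vertex_id", "consistency")],
               by = "vertex_id")
  tab <- tab[!is.na(tab$consistency), ]
  blocks <- split(tab, list(tab$roi, tab$hemisphere), drop = FALSE)
  out <- Map(function(b, nm) {
    if (nrow(b) < n_per_hemisphere) {
      stop(sprintf(
        "block %s has only %d vertices with defined consistency (need %d)",
        nm, nrow(b), n_per_hemisphere), call. = FALSE)
    }
    b <- b[order(-b$consistency, b$vertex_id), ]
    b[seq_len(n_per_hemisphere), c("roi", "hemisphere", "vertex_id",
                                   "consistency")]
  }, blocks, names(blocks))
  res <- do.call(rbind, out)
  res <- res[order(res$roi, res$hemisphere, -res$consistency,
                   res$vertex_id), ]
  rownames(res) <- NULL
  res
}
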