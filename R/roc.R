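# ROI-level comparison metrics: the 20-step p-value threshold ladder,
# criterion-free ROC curves and trapezoidal AUC, both overlap percentages,
# and the normalized proportion profile along the visual hierarchy.

#' The 20-step p-value threshold ladder
#'
#' Ten log-spaced thresholds from 1e-10 to 1e-1 plus ten log-spaced
#' thresholds from 10^-0.9 to 1: a stringent-to-liberal criterion sweep for
#' criterion-free ROC construction.
#'
#' @return Strictly increasing numeric vector of length 20; first element
#'   1e-10, last 1.
#' @export
threshold_ladder <- function() {
  c(10^seq(-10, -1, length.out = 10), 10^seq(-0.9, 0, length.out = 10))
}

#' Criterion-free ROC curve over p-value thresholds
#'
#' For every threshold, the hit rate is the proportion of signal-ROI voxels
#' with p strictly below it and the false-alarm rate the same proportion in
#' the reference ROI; the points are augmented with (0,0) and (1,1) and the
#' AUC is the trapezoidal area over the false-alarm axis. AUC reaches 1 when
#' every signal voxel passes at a threshold no reference voxel passes, 0.5
#' when the two ROIs pass in equal proportions throughout, and 0 in the
#' reversed case.
#'
#' @param hit_pvals P-values of the signal-ROI voxels (non-empty).
#' @param fa_pvals P-values of the reference-ROI voxels (non-empty). Pool
#'   voxel lists (not averaged proportions) when several reference ROIs are
#'   used.
#' @param ladder Increasing threshold vector (default [threshold_ladder()]).
#' @return Object of class `roc_result`: list with `points` (data frame
#'   `threshold`, `fa`, `hit`, including the augmented endpoints) and `auc`.
#' @export
roc_curve <- function(hit_pvals, fa_pvals, ladder = threshold_ladder()) {
  hit_pvals <- hit_pvals[!is.na(hit_pvals)]
  fa_pvals <- fa_pvals[!is.na(fa_pvals)]
  if (!length(hit_pvals) || !length(fa_pvals))
    stop("both ROIs must contain voxels")
  if (is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be strictly increasing")
  hit <- vapply(ladder, function(th) mean(hit_pvals < th), numeric(1))
  fa <- vapply(ladder, function(th) mean(fa_pvals < th), numeric(1))
  pts <- data.frame(threshold = c(0, ladder, Inf),
                    fa = c(0, fa, 1), hit = c(0, hit, 1))
  auc <- sum(diff(pts$fa) * (utils::head(pts$hit, -1) +
                               utils::tail(pts$hit, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result:", nrow(x$points), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

.as_voxel_set <- function(x) {
  if (is.logical(x)) which(x) else unique(as.integer(x))
}

#' Whole-brain overlap percentage
#'
#' Percentage of the voxels activated in the tagging analysis that were also
#' activated by the localizer: `100 * |SW intersect FL| / |SW|`.
#'
#' @param sw_voxels Activated voxel set from the frequency-tagged analysis
#'   (logical mask or integer indices; must be non-empty).
#' @param fl_voxels Activated voxel set from the localizer.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_whole_brain <- function(sw_voxels, fl_voxels) {
  sw <- .as_voxel_set(sw_voxels)
  fl <- .as_voxel_set(fl_voxels)
  if (!length(sw)) stop("empty activated set: overlap undefined")
  100 * length(intersect(sw, fl)) / length(sw)
}

#' Within-ROI overlap percentage
#'
#' Percentage of a functionally-defined ROI's voxels that the tagging
#' analysis activated: `100 * |FD intersect SW| / |FD|`.
#'
#' @param fd_voxels Functionally-defined ROI voxel set (non-empty).
#' @param sw_voxels Activated voxel set.
#' @return Percentage in `[0, 100]`.
#' @export
overlap_roi <- function(fd_voxels, sw_voxels) {
  fd <- .as_voxel_set(fd_voxels)
  sw <- .as_voxel_set(sw_voxels)
  if (!length(fd)) stop("empty ROI: overlap undefined")
  100 * length(intersect(fd, sw)) / length(fd)
}

#' Normalized proportion profile along the visual hierarchy
#'
#' Per area, the proportion of voxels with p below `threshold`, divided by
#' the mean proportion in the first two (early visual) areas. A value near 1
#' means activation at the early-visual level; values increasing along the
#' list quantify preferential engagement of higher areas.
#'
#' @param pval_maps Named list of per-voxel p-value vectors, in hierarchical
#'   order; must contain `V1` and `V2` (or whatever the first two baseline
#'   areas are named via `baseline`).
#' @param threshold Activation threshold on p (default 0.001, strict `<`).
#' @param baseline Names of the two baseline areas (default `c("V1",
#'   "V2")`).
#' @return Named numeric vector of fold changes, one per area.
#' @export
normalized_proportion_profile <- function(pval_maps, threshold = 0.001,
                                          baseline = c("V1", "V2")) {
  stopifnot(is.list(pval_maps), !is.null(names(pval_maps)))
  if (!all(baseline %in% names(pval_maps)))
    stop("baseline areas missing from pval_maps: ",
         paste(setdiff(baseline, names(pval_maps)), collapse = ", "))
  prop <- vapply(pval_maps, function(p) mean(p < threshold, na.rm = TRUE),
                 numeric(1))
  base <- mean(prop[baseline])
  if (base <= 0)
    stop("baseline areas have zero activated proportion; ",
         "profile normalization undefined")
  prop / base
}
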