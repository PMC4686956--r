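# Run configuration and the end-to-end simulate -> analyze -> compare
# pipeline, producing a machine-readable report.

#' Assemble a run configuration
#'
#' All tunable parameters of stimulus generation, simulation and analysis in
#' one serializable, versioned object. Defaults are the standard study
#' configuration: 9 decomposition levels, 8 harmonics, 200 frames per cycle,
#' TR 2.46 s, 216 volumes, tagging at 0.06/0.08/0.10 Hz, FDR q = 0.05,
#' 14-bin SNR band, the 20-step threshold ladder.
#'
#' @param seed Root seed; every random stage consumes a seed derived from
#'   it.
#' @param levels,n_harmonics,frames_per_cycle,n_cycles Stimulus parameters.
#' @param TR,n_volumes,n_runs,noise_sd,amplitude Simulation parameters.
#' @param frequencies Named tagging frequencies (Hz).
#' @param q FDR level.
#' @param band_bins SNR band width in bins.
#' @param activation_p Activation threshold for overlap/profile maps.
#' @param spec ROI table, see [roi_spec()].
#' @return Object of class `swift_config` (a validated named list).
#' @export
swift_config <- function(seed = 1, levels = 9, n_harmonics = 8,
                         frames_per_cycle = 200, n_cycles = 3,
                         TR = 2.46, n_volumes = 216, n_runs = 3,
                         noise_sd = 1, amplitude = 1,
                         frequencies = swift_tag_freqs, q = 0.05,
                         band_bins = 14, activation_p = 0.001,
                         spec = roi_spec()) {
  cfg <- list(version = as.character(utils::packageVersion("swiftag")),
              seed = as.integer(seed), levels = levels,
              n_harmonics = n_harmonics,
              frames_per_cycle = frames_per_cycle, n_cycles = n_cycles,
              TR = TR, n_volumes = n_volumes, n_runs = n_runs,
              noise_sd = noise_sd, amplitude = amplitude,
              frequencies = frequencies, q = q, band_bins = band_bins,
              activation_p = activation_p, spec = spec)
  stopifnot(cfg$TR > 0, cfg$n_volumes >= 8, cfg$n_runs >= 1,
            all(cfg$frequencies > 0), cfg$q > 0, cfg$q < 1)
  if (any(spec$n_voxels < 1))
    stop("zero-size ROI in spec: ",
         paste(spec$roi[spec$n_voxels < 1], collapse = ", "))
  structure(cfg, class = "swift_config")
}

# deterministic per-stage seeds below 2^31
.stage_seed <- function(seed, stage) {
  (as.integer(seed) * 7919L + match(stage, c("study", "localizer",
                                             "analysis")) * 104729L) %%
    2147483647L
}

#' Run the full synthetic pipeline
#'
#' Simulates a frequency-tagged study and a block-design localizer on the
#' same voxel grid, runs the tagging analysis and the localizer GLM,
#' and summarizes them with ROC/AUC (each category ROI against the pooled
#' other category ROIs), overlap percentages, and the normalized proportion
#' profile along V1, V2, V3, V4 and the pooled high-level areas.
#'
#' @param config A [swift_config()].
#' @return Object of class `swift_report`: nested list with `config`,
#'   `seeds`, and sections `auc`, `overlap`, `profile`, `fdr`; identical
#'   config + seed gives identical numbers.
#' @export
run_pipeline <- function(config = swift_config()) {
  stopifnot(inherits(config, "swift_config"))
  seeds <- list(study = .stage_seed(config$seed, "study"),
                localizer = .stage_seed(config$seed, "localizer"))

  study <- generate_study(spec = config$spec,
                          frequencies = config$frequencies,
                          TR = config$TR, n_volumes = config$n_volumes,
                          n_runs = config$n_runs,
                          noise_sd = config$noise_sd, seed = seeds$study)
  maps <- tagging_analysis(study)
  truth <- study$truth

  cat_roi <- c(faces = "FFA", scenes = "PPA", objects = "LOC")
  cat_roi <- cat_roi[cat_roi %in% truth$roi]

  # ROC: per category, its ROI's p-values at its own frequency vs the
  # pooled p-values of the other category ROIs at that same frequency
  auc <- lapply(names(cat_roi), function(cat) {
    pm <- maps[[cat]]$p
    hit <- pm[truth$roi == cat_roi[[cat]]]
    fa <- pm[truth$roi %in% setdiff(unname(cat_roi), cat_roi[[cat]])]
    roc_curve(hit, fa)$auc
  })
  names(auc) <- names(cat_roi)

  # minimum p over tagging frequencies = "responds to any category"
  pmin_map <- Reduce(pmin, lapply(maps, `[[`, "p"))
  sw_set <- which(pmin_map < config$activation_p)

  # localizer: block design on the same voxels; category-selective voxels
  # (the tagged voxels of the category ROIs) respond to their blocks
  loc <- .simulate_localizer(study, config, seeds$localizer)
  fl_set <- which(loc$p_category < config$activation_p)

  overlap <- list(
    whole_brain = if (length(sw_set))
      overlap_whole_brain(sw_set, fl_set) else NA_real_,
    per_roi = vapply(unname(cat_roi), function(r)
      overlap_roi(which(truth$roi == r), sw_set), numeric(1))
  )

  areas <- intersect(c("V1", "V2", "V3", "V4"), unique(truth$roi))
  pmaps <- lapply(areas, function(a) pmin_map[truth$roi == a])
  names(pmaps) <- areas
  hl <- truth$roi %in% unname(cat_roi)
  if (any(hl)) pmaps$HL <- pmin_map[hl]
  profile <- normalized_proportion_profile(pmaps,
                                           threshold = config$activation_p)

  fdr_mask <- fdr_bh(pmin_map, q = config$q)
  structure(
    list(config = config, seeds = seeds,
         auc = auc, overlap = overlap, profile = as.list(profile),
         fdr = list(q = config$q, n_rejected = sum(fdr_mask),
                    n_voxels = length(pmin_map)),
         truth_summary = list(n_tagged = sum(truth$tagged),
                              n_voxels = nrow(truth))),
    class = "swift_report"
  )
}

# Block-design localizer on the study's voxel grid: tagged voxels of each
# category ROI respond to that category's blocks; all other voxels are
# noise. Returns the category-contrast p per voxel (truth row order).
.simulate_localizer <- function(study, config, seed) {
  truth <- study$truth
  TR <- study$TR
  n_vol <- 120L
  cats <- names(config$frequencies)
  onsets <- lapply(seq_along(cats), function(i)
    seq((i - 1) * 35, n_vol * TR - 35, by = 35 * length(cats)))
  names(onsets) <- cats
  conditions <- lapply(onsets, function(o) list(onsets = o, duration = 20))
  des <- block_design(conditions, TR, n_vol)
  cat_roi <- c(faces = "FFA", scenes = "PPA", objects = "LOC")
  hrf <- canonical_hrf(TR)
  .with_seed(seed, {
    Y <- matrix(stats::rnorm(n_vol * nrow(truth), 0, config$noise_sd),
                n_vol, nrow(truth))
    for (cat in cats) {
      sel <- which(truth$roi == cat_roi[[cat]] & truth$tagged)
      if (!length(sel)) next
      reg <- des$X[, cat]
      Y[, sel] <- Y[, sel] + reg * config$amplitude
    }
  })
  # each category tested against the pooled others; take the per-voxel best
  pmat <- vapply(cats, function(cat) {
    w <- numeric(ncol(des$X))
    names(w) <- colnames(des$X)
    w[cat] <- 1
    w[setdiff(cats, cat)] <- -1 / (length(cats) - 1)
    pr <- glm_contrast(Y, des, unname(w))
    ifelse(pr$t > 0, pr$p / 2, 1 - pr$p / 2)   # one-sided: category > others
  }, numeric(nrow(truth)))
  list(p_category = apply(pmat, 1, min))
}

#' @export
print.swift_report <- function(x, ...) {
  cat("swift_report (seed", x$config$seed, ")\n")
  cat("  AUC:", paste(sprintf("%s %.3f", names(x$auc), unlist(x$auc)),
                      collapse = ", "), "\n")
  cat("  overlap: whole-brain",
      sprintf("%.1f%%", x$overlap$whole_brain), "| per ROI:",
      paste(sprintf("%s %.1f%%", names(x$overlap$per_roi),
                    x$overlap$per_roi), collapse = ", "), "\n")
  cat("  profile:", paste(sprintf("%s %.2f", names(x$profile),
                                  unlist(x$profile)), collapse = ", "), "\n")
  cat("  FDR q =", x$fdr$q, ":", x$fdr$n_rejected, "of", x$fdr$n_voxels,
      "voxels rejected\n")
  invisible(x)
}

#' Export a pipeline report as JSON
#'
#' @param report A `swift_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  stopifnot(inherits(report, "swift_report"))
  out <- unclass(report)
  out$config <- unclass(out$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
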