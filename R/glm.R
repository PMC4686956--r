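# Block-design GLM benchmark: boxcar regressors convolved with the canonical
# response, OLS contrast t-maps. This is the comparison pipeline against
# which the frequency-tagged analysis is benchmarked.

#' Block-design GLM design matrix
#'
#' One regressor per condition: a boxcar (1 during blocks of `duration`
#' seconds starting at each onset) sampled at TR and convolved with the
#' canonical response; plus an intercept and, optionally, a discrete cosine
#' drift set with a 128 s cutoff emulating a high-pass filter.
#'
#' @param conditions Named list; each element a list with `onsets` (seconds)
#'   and optional `duration` (seconds, default 20).
#' @param TR Repetition time in seconds.
#' @param n_volumes Number of volumes.
#' @param hrf An [canonical_hrf()] kernel (default: canonical at this TR).
#' @param drift `"none"` (default) or `"dct"`.
#' @param drift_cutoff High-pass cutoff in seconds for the DCT set
#'   (default 128).
#' @return Object of class `design_matrix`: list with `X` (matrix,
#'   `n_volumes` rows), `condition_names`, `df_residual`.
#' @export
block_design <- function(conditions, TR, n_volumes, hrf = NULL,
                         drift = c("none", "dct"), drift_cutoff = 128) {
  drift <- match.arg(drift)
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)),
            all(nzchar(names(conditions))))
  if (is.null(hrf)) hrf <- canonical_hrf(TR)
  run_len <- n_volumes * TR
  times <- (seq_len(n_volumes) - 1) * TR
  make_reg <- function(cond) {
    dur <- if (is.null(cond$duration)) 20 else cond$duration
    if (any(cond$onsets < 0 | cond$onsets >= run_len))
      stop("block onsets outside the run")
    box <- rowSums(vapply(cond$onsets, function(o)
      as.numeric(times >= o & times < o + dur), numeric(n_volumes)))
    conv <- stats::convolve(box, rev(hrf$samples), type = "open")
    conv[seq_len(n_volumes)]
  }
  regs <- vapply(conditions, make_reg, numeric(n_volumes))
  X <- cbind(intercept = 1, regs)
  if (drift == "dct") {
    K <- max(0L, floor(2 * run_len / drift_cutoff))
    if (K > 0) {
      tt <- seq_len(n_volumes) - 0.5
      D <- vapply(seq_len(K), function(k)
        cos(pi * k * tt / n_volumes), numeric(n_volumes))
      colnames(D) <- paste0("dct", seq_len(K))
      X <- cbind(X, D)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dep, collapse = ", "))
  }
  structure(list(X = X, condition_names = names(conditions),
                 df_residual = n_volumes - ncol(X), TR = TR),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("design_matrix:", nrow(x$X), "volumes x", ncol(x$X), "columns (",
      paste(colnames(x$X), collapse = ", "), "), residual df",
      x$df_residual, "\n")
  invisible(x)
}

#' Named contrast presets for the localizer conditions
#'
#' Standard category contrasts (`"faces-gt-objects"`, `"scenes-gt-objects"`,
#' `"objects-gt-scenes"`) expanded to a weight vector over a design's
#' columns.
#'
#' @param name Preset name, `<a>-gt-<b>` with `a`, `b` condition names.
#' @param design A `design_matrix` containing both conditions.
#' @return Numeric contrast vector (length = design columns).
#' @export
localizer_contrast <- function(name, design) {
  parts <- strsplit(name, "-gt-", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("contrast preset must be of the form '<a>-gt-<b>'")
  w <- numeric(ncol(design$X))
  names(w) <- colnames(design$X)
  for (i in 1:2) {
    if (!parts[i] %in% colnames(design$X))
      stop("condition not in design: ", parts[i])
    w[parts[i]] <- c(1, -1)[i]
  }
  unname(w)
}

#' OLS contrast t- and p-maps
#'
#' Fits `Y = X beta + e` by ordinary least squares voxel-wise and tests the
#' contrast `c' beta = 0`: `t = c' beta_hat / sqrt(sigma2_hat * c'(X'X)^-1
#' c)` with two-tailed p on the residual degrees of freedom.
#'
#' @param series Matrix (time x voxels) or 4D array (x, y, z, t).
#' @param design A `design_matrix`.
#' @param contrast Numeric weights, length = design columns, not all zero.
#' @return List with `t`, `p` (vectors, or 3D arrays for 4D input), `beta`
#'   (columns x voxels matrix), `df`.
#' @export
glm_contrast <- function(series, design, contrast) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (length(contrast) != ncol(X))
    stop("contrast length (", length(contrast),
         ") must equal design columns (", ncol(X), ")")
  if (all(contrast == 0)) stop("contrast of all zeros is invalid")
  is4d <- length(dim(series)) == 4
  if (is4d) {
    d <- dim(series)
    series <- t(matrix(series, prod(d[1:3]), d[4]))
  }
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  if (nrow(series) != nrow(X))
    stop("series has ", nrow(series), " volumes; design expects ", nrow(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular normal equations")
  beta <- qr.coef(qrX, series)
  res <- series - X %*% beta
  df <- design$df_residual
  sigma2 <- colSums(res^2) / df
  XtXinv_c <- backsolve(qr.R(qrX), backsolve(qr.R(qrX), contrast,
                                             transpose = TRUE))
  cvar <- sum(contrast * XtXinv_c)
  est <- as.numeric(crossprod(contrast, beta))
  tstat <- est / sqrt(sigma2 * cvar)
  p <- 2 * stats::pt(-abs(tstat), df)
  if (is4d) {
    tstat <- array(tstat, d[1:3])
    p <- array(p, d[1:3])
  }
  list(t = tstat, p = p, beta = beta, df = df)
}
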