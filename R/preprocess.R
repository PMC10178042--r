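#' Reflectance calibration against white and dark references
#'
#' Converts raw detector counts to relative reflectance using the usual
#' white/dark reference correction `Rc = (Rr - Rd) / (Rw - Rd)`, applied
#' element-wise. All three arrays must have identical shape.
#'
#' @param rr raw signal array (vector or matrix, arbitrary units).
#' @param rw all-white reference array, same shape as `rr`.
#' @param rd all-black (dark current) reference array, same shape as `rr`.
#' @return Calibrated reflectance array of the same shape.
#' @export
calibrate_reflectance <- function(rr, rw, rd) {
  if (!identical(dim(rr), dim(rw)) || !identical(dim(rr), dim(rd)) ||
      length(rr) != length(rw) || length(rr) != length(rd))
    stop("rr, rw and rd must have identical shapes")
  denom <- rw - rd
  if (any(denom == 0)) {
    bad <- which(denom == 0)
    if (is.matrix(denom)) bad <- unique(((bad - 1) %/% nrow(denom)) + 1)
    stop(sprintf("white and dark references coincide at channel(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  (rr - rd) / denom
}

#' Fit a multiplicative scatter correction reference
#'
#' The MSC reference is the channel-wise mean spectrum of the fitting set.
#' Fit it on the training partition only, then transform any partition with
#' [apply_msc()], so no test spectrum influences the correction.
#'
#' @param x numeric matrix of spectra (rows = samples), at least 2 rows.
#' @return An object of class `msc_reference`.
#' @export
fit_msc <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("MSC reference needs at least 2 spectra")
  ref <- colMeans(x)
  if (diff(range(ref)) == 0)
    stop("mean spectrum is constant; MSC reference would be degenerate")
  structure(list(reference = ref), class = "msc_reference")
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on the reference by ordinary least squares,
#' `x ~ a + b * ref`, and corrected as `(x - a) / b`, removing the per-sample
#' additive and multiplicative scatter components.
#'
#' @param x numeric matrix of spectra to correct.
#' @param ref an `msc_reference` from [fit_msc()] (or a numeric vector).
#' @param b_tol slopes with `|b|` below this are rejected as uncorrelated with
#'   the reference (default 1e-12).
#' @return Corrected matrix of the same shape.
#' @export
apply_msc <- function(x, ref, b_tol = 1e-12) {
  x <- as.matrix(x)
  r <- if (inherits(ref, "msc_reference")) ref$reference else as.numeric(ref)
  if (ncol(x) != length(r))
    stop("column count does not match the reference length")
  rc <- r - mean(r)
  ss <- sum(rc^2)
  xm <- rowMeans(x)
  b <- as.numeric((x - xm) %*% rc) / ss
  if (any(abs(b) < b_tol))
    stop(sprintf("spectrum %d is uncorrelated with the MSC reference (|b| < %g)",
                 which(abs(b) < b_tol)[1], b_tol))
  a <- xm - b * mean(r)
  (x - a) / b
}

#' Standard normal variate transformation
#'
#' Standardises each spectrum to zero mean and unit standard deviation
#' (denominator `n - 1`), removing per-sample offset and scale effects.
#'
#' @param x numeric matrix of spectra (rows = samples); no row may be constant.
#' @return Transformed matrix of the same shape.
#' @export
snv <- function(x) {
  x <- as.matrix(x)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
  if (any(s == 0))
    stop(sprintf("row %d is constant; SNV undefined", which(s == 0)[1]))
  (x - m) / s
}

#' Per-spectrum min-max normalisation
#'
#' Rescales each spectrum (row) linearly into [0, 1]. A per-channel
#' (column-wise) variant is available via `axis = "channel"` but the row-wise
#' form is the default: it is invariant to per-sample scale and offset.
#'
#' @param x numeric matrix of spectra.
#' @param axis `"row"` (default) or `"channel"`.
#' @return Normalised matrix of the same shape.
#' @export
normalize_minmax <- function(x, axis = c("row", "channel")) {
  axis <- match.arg(axis)
  x <- as.matrix(x)
  if (axis == "channel") x <- t(x)
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  if (any(hi == lo))
    stop(sprintf("%s %d is constant; min-max normalisation undefined",
                 if (axis == "row") "row" else "channel", which(hi == lo)[1]))
  out <- (x - lo) / (hi - lo)
  if (axis == "channel") out <- t(out)
  out
}

#' Preprocess a train/test pair without leakage
#'
#' Applies one of the preprocessing treatments to both partitions, fitting
#' any required statistics (the MSC reference) on the training partition
#' only. `"nm"` and `"snv"` are per-spectrum and need no fitted statistics;
#' `"none"` passes data through unchanged.
#'
#' @param train,test [labeled_spectra()] partitions (`test` may be `NULL`).
#' @param method one of `"none"`, `"nm"`, `"msc"`, `"snv"`.
#' @return List with `train`, `test` (transformed copies) and `msc_ref`
#'   (`NULL` unless `method = "msc"`).
#' @export
preprocess_spectra <- function(train, test = NULL,
                               method = c("none", "nm", "msc", "snv")) {
  method <- match.arg(method)
  stopifnot(inherits(train, "labeled_spectra"))
  msc_ref <- if (method == "msc") fit_msc(train$reflectance) else NULL
  tf <- function(sp) {
    if (is.null(sp)) return(NULL)
    sp$reflectance <- switch(method,
      none = sp$reflectance,
      nm   = normalize_minmax(sp$reflectance),
      msc  = apply_msc(sp$reflectance, msc_ref),
      snv  = snv(sp$reflectance))
    sp
  }
  list(train = tf(train), test = tf(test), msc_ref = msc_ref)
}
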