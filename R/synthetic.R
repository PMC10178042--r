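#' Class labels used throughout the package
#'
#' The five surface-treatment groups: an untreated control plus four
#' pesticides. Integer labels 0--4 map onto this vector in order.
#'
#' @format Character vector of length 5.
#' @export
pesticide_classes <- c("None", "Acetamiprid", "Malathion",
                       "Difenoconazole", "Beta-cypermethrin")

#' Configuration for the synthetic SWIR spectra generator
#'
#' Describes a five-class population of short-wave infrared reflectance
#' spectra: a shared smooth base curve with Gaussian peaks and valleys at
#' fixed wavelengths, a class-dependent reflectance offset confined to the
#' 1493--2038 nm window (the control class lowest, Malathion highest),
#' per-sample multiplicative/additive scatter distortion, and additive
#' Gaussian noise.
#'
#' @param n_per_class samples generated per class (default 160, i.e. 800 in
#'   total across the 5 classes).
#' @param n_channels number of wavelength channels (default 233).
#' @param wl_min,wl_max wavelength range in nm (defaults 1000 and 2500).
#' @param peak_centers,valley_centers nm positions of the reflectance peaks
#'   and valleys shared by all classes.
#' @param peak_width Gaussian sigma (nm) of each peak/valley bump.
#' @param bump_height reflectance amplitude of each peak/valley bump.
#' @param class_offsets length-5 numeric; reflectance delta added to each
#'   class over `offset_window`. Entry 1 (class 0, no residue) must be the
#'   strict minimum and entry 3 (class 2, Malathion) the strict maximum.
#' @param offset_window nm interval supporting the class offset bump.
#' @param noise_sd standard deviation of the additive channel noise
#'   (reflectance units).
#' @param scatter_slope_range,scatter_offset_range ranges for the per-sample
#'   affine distortion `a * x + b`; degenerate ranges `c(1, 1)` / `c(0, 0)`
#'   disable it.
#' @param seed integer seed making generation fully reproducible.
#' @return An object of class `spectra_config`.
#' @export
spectra_config <- function(n_per_class = 160L,
                           n_channels = 233L,
                           wl_min = 1000, wl_max = 2500,
                           peak_centers = c(1125, 1340, 1801, 2000, 2313, 2370),
                           valley_centers = c(1020, 1269, 1552, 1929, 2432, 2466),
                           peak_width = 35,
                           bump_height = 0.08,
                           class_offsets = c(0, 0.05, 0.12, 0.07, 0.09),
                           offset_window = c(1493, 2038),
                           noise_sd = 0.02,
                           scatter_slope_range = c(0.9, 1.1),
                           scatter_offset_range = c(-0.05, 0.05),
                           seed = 1L) {
  if (n_per_class < 0) stop("n_per_class must be >= 0")
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (!(wl_min < wl_max)) stop("wl_min must be < wl_max")
  centers <- c(peak_centers, valley_centers)
  if (any(centers < wl_min | centers > wl_max))
    stop("all peak/valley centers must lie within [wl_min, wl_max]")
  if (length(class_offsets) != 5)
    stop("class_offsets must have exactly 5 entries (one per class)")
  if (which.min(class_offsets) != 1L || sum(class_offsets == min(class_offsets)) > 1L)
    stop("class_offsets: entry for class 0 (no residue) must be the strict minimum")
  if (which.max(class_offsets) != 3L || sum(class_offsets == max(class_offsets)) > 1L)
    stop("class_offsets: entry for class 2 (Malathion) must be the strict maximum")
  if (peak_width <= 0) stop("peak_width must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(length(offset_window) == 2, offset_window[1] < offset_window[2],
            length(scatter_slope_range) == 2, length(scatter_offset_range) == 2,
            diff(scatter_slope_range) >= 0, diff(scatter_offset_range) >= 0)
  structure(list(
    n_per_class = as.integer(n_per_class), n_channels = as.integer(n_channels),
    wl_min = wl_min, wl_max = wl_max,
    peak_centers = peak_centers, valley_centers = valley_centers,
    peak_width = peak_width, bump_height = bump_height,
    class_offsets = class_offsets, offset_window = offset_window,
    noise_sd = noise_sd,
    scatter_slope_range = scatter_slope_range,
    scatter_offset_range = scatter_offset_range,
    seed = as.integer(seed)
  ), class = "spectra_config")
}

#' Labeled spectra container
#'
#' The universal exchange object: a strictly increasing wavelength grid, an
#' `n_samples x n_channels` reflectance matrix, and integer class labels in
#' 0--4.
#'
#' @param wavelengths numeric vector, strictly increasing, in nm.
#' @param reflectance numeric matrix, one row per sample.
#' @param labels integer vector of class labels (values 0--4), one per row.
#' @param class_names character vector naming the label levels.
#' @return An object of class `labeled_spectra`.
#' @export
labeled_spectra <- function(wavelengths, reflectance, labels,
                            class_names = pesticide_classes) {
  reflectance <- as.matrix(reflectance)
  labels <- as.integer(labels)
  if (length(wavelengths) != ncol(reflectance))
    stop("wavelengths length must equal the number of reflectance columns")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (nrow(reflectance) != length(labels))
    stop("reflectance row count must equal labels length")
  if (length(labels) && !all(is.finite(reflectance)))
    stop("reflectance contains non-finite values")
  if (length(labels) && !all(labels %in% 0:4))
    stop("labels must take values in 0..4")
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = reflectance,
                 labels = labels,
                 class_names = class_names),
            class = "labeled_spectra")
}

#' @export
print.labeled_spectra <- function(x, ...) {
  cat(sprintf("labeled_spectra: %d samples x %d channels (%.1f-%.1f nm)\n",
              nrow(x$reflectance), ncol(x$reflectance),
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$labels)) {
    tab <- table(factor(x$labels, levels = 0:4, labels = x$class_names))
    print(tab)
  }
  invisible(x)
}

# shared noiseless base curve: low-order polynomial baseline plus signed
# Gaussian bumps at the configured peak/valley wavelengths
base_spectrum <- function(wavelengths, config) {
  u <- 2 * (wavelengths - config$wl_min) / (config$wl_max - config$wl_min) - 1
  base <- 0.55 - 0.10 * u - 0.08 * u^2
  for (p in config$peak_centers)
    base <- base + config$bump_height * exp(-(wavelengths - p)^2 / (2 * config$peak_width^2))
  for (v in config$valley_centers)
    base <- base - config$bump_height * exp(-(wavelengths - v)^2 / (2 * config$peak_width^2))
  base
}

# raised-cosine bump supported exactly on the class-offset window:
# 0 at the edges, 1 at the centre, 0 outside
offset_profile <- function(wavelengths, window) {
  centre <- mean(window)
  half <- diff(window) / 2
  inside <- abs(wavelengths - centre) < half
  prof <- numeric(length(wavelengths))
  prof[inside] <- 0.5 * (1 + cos(pi * (wavelengths[inside] - centre) / half))
  prof
}

#' Generate synthetic labeled SWIR spectra
#'
#' Draws `n_per_class` spectra for each of the 5 classes. Each spectrum is the
#' shared base curve plus its class offset bump, distorted per sample by an
#' affine map `a * x + b` (scatter emulation) and additive Gaussian noise.
#' Fully reproducible from `config$seed`.
#'
#' @param config a [spectra_config()].
#' @return A [labeled_spectra()] with `5 * n_per_class` rows.
#' @export
generate_spectra <- function(config) {
  if (!inherits(config, "spectra_config"))
    stop("config must be created by spectra_config()")
  set.seed(config$seed)
  wl <- seq(config$wl_min, config$wl_max, length.out = config$n_channels)
  base <- base_spectrum(wl, config)
  prof <- offset_profile(wl, config$offset_window)
  n <- 5L * config$n_per_class
  labels <- rep(0:4, each = config$n_per_class)
  if (n == 0L) {
    return(labeled_spectra(wl, matrix(numeric(0), 0, config$n_channels),
                           integer(0)))
  }
  clean <- matrix(base, n, config$n_channels, byrow = TRUE) +
    outer(config$class_offsets[labels + 1L], prof)
  a <- stats::runif(n, config$scatter_slope_range[1], config$scatter_slope_range[2])
  b <- stats::runif(n, config$scatter_offset_range[1], config$scatter_offset_range[2])
  x <- clean * a + b
  if (config$noise_sd > 0)
    x <- x + matrix(stats::rnorm(n * config$n_channels, sd = config$noise_sd),
                    n, config$n_channels)
  labeled_spectra(wl, x, labels)
}

#' Apply a fixed affine scatter distortion to every spectrum
#'
#' Replaces every row `x` by `slope * x + offset`. Used as a fixture for the
#' scatter-correction treatments (MSC/SNV), which should undo it.
#'
#' @param spectra a [labeled_spectra()].
#' @param slope multiplicative distortion, must be non-zero.
#' @param offset additive distortion.
#' @return A [labeled_spectra()] with distorted reflectance.
#' @export
apply_scatter <- function(spectra, slope, offset) {
  stopifnot(inherits(spectra, "labeled_spectra"))
  if (slope == 0) stop("slope must be non-zero (distortion would not be invertible)")
  out <- spectra
  out$reflectance <- slope * spectra$reflectance + offset
  out
}

#' Stratified train/test split
#'
#' Splits per class: the test set gets `floor(n_class * (1 - train_fraction))`
#' samples drawn at random, the remainder goes to training, so the default
#' 160-per-class population with `train_fraction = 0.75` yields exactly
#' 120 training and 40 test spectra per class (600/200 overall).
#'
#' @param spectra a [labeled_spectra()].
#' @param train_fraction fraction of each class assigned to training,
#'   strictly between 0 and 1 (default 0.75, i.e. a 3:1 split).
#' @param seed integer seed; the same seed always yields the same partition.
#' @return A list with elements `train` and `test` (both [labeled_spectra()]),
#'   carrying the selected row indices as attributes `train_idx`/`test_idx`.
#' @export
stratified_split <- function(spectra, train_fraction = 0.75, seed = 1L) {
  stopifnot(inherits(spectra, "labeled_spectra"))
  if (!nrow(spectra$reflectance)) stop("cannot split an empty spectra set")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie strictly between 0 and 1")
  counts <- table(spectra$labels)
  if (any(counts < 2))
    stop("every class present must have at least 2 samples")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in sort(unique(spectra$labels))) {
    idx <- which(spectra$labels == cl)
    n_test <- floor(length(idx) * (1 - train_fraction))
    if (n_test > 0)
      test_idx <- c(test_idx, sort(sample(idx, n_test)))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(spectra$labels), test_idx)
  subset_spectra <- function(i) {
    labeled_spectra(spectra$wavelengths,
                    spectra$reflectance[i, , drop = FALSE],
                    spectra$labels[i], spectra$class_names)
  }
  out <- list(train = subset_spectra(train_idx), test = subset_spectra(test_idx))
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  out
}

#' Write labeled spectra to CSV
#'
#' One row per sample; header `label,wl_<nm>,...` with '.' as the decimal
#' separator, UTF-8 encoded.
#'
#' @param spectra a [labeled_spectra()].
#' @param path output file path.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "labeled_spectra"))
  df <- data.frame(label = spectra$labels, spectra$reflectance)
  names(df) <- c("label", paste0("wl_", as.character(spectra$wavelengths)))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read labeled spectra from CSV
#'
#' Inverse of [write_spectra()]: wavelengths are recovered from the
#' `wl_<nm>` column names.
#'
#' @param path CSV file path.
#' @param class_names label-level names (default [pesticide_classes]).
#' @return A [labeled_spectra()].
#' @export
read_spectra <- function(path, class_names = pesticide_classes) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(df)[1] != "label" || !all(startsWith(names(df)[-1], "wl_")))
    stop("not a spectra CSV: expected header 'label,wl_<nm>,...'")
  wl <- as.numeric(sub("^wl_", "", names(df)[-1]))
  labeled_spectra(wl, as.matrix(df[, -1, drop = FALSE]), df$label, class_names)
}
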