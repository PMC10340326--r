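#' Define a spectral peak
#'
#' A single resonance used by the synthetic spectrum generator, drawn as a
#' Lorentzian line (the natural NMR lineshape).
#'
#' @param center Chemical shift of the peak maximum (ppm).
#' @param width Half-width at half-maximum (ppm); must be positive.
#' @param amplitude Base peak height (arbitrary units); must be non-negative.
#' @return An object of class `nmr_peak`.
#' @export
peak <- function(center, width, amplitude) {
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("peak 'center' must be a finite number", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || !(width > 0))
    stop("peak 'width' must be > 0", call. = FALSE)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("peak 'amplitude' must be >= 0", call. = FALSE)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "nmr_peak")
}

#' Parameters of the two-class synthetic NMR dataset
#'
#' The generator emulates a binary origin-authentication study: the two classes
#' share identical peak positions, but the non-authentic class carries larger
#' peak intensities inside the sugar region (glucose/fructose/sucrose
#' resonances), which is the class-discriminating structure observed in real
#' origin studies. Solvent residual peaks (methanol-d3 CHD2OD and HDO) are
#' modelled separately: their amplitude varies strongly from sample to sample
#' but carries no class information, which is why preprocessing excises them.
#'
#' @param n_geo,n_non Samples per class (authentic / non-authentic); >= 1.
#' @param axis_range Length-2 numeric, `(ppm_min, ppm_max)` of the simulated axis.
#' @param n_points Number of axis points (>= 2). The axis is stored in
#'   decreasing ppm order (NMR display convention).
#' @param peaks List of [peak()] objects (metabolite resonances).
#' @param sugar_region Length-2 numeric `(lo, hi)`: region in which the class
#'   effect applies.
#' @param class_ratio Multiplicative factor (> 0) applied to non-authentic
#'   peak amplitudes whose center lies inside `sugar_region`. Values > 1 make
#'   the authentic class relatively lower in the sugar region.
#' @param intensity_cv Coefficient of variation of the per-sample, per-peak
#'   lognormal amplitude factor (biological concentration spread); >= 0.
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.); >= 0.
#' @param solvent_peaks List of [peak()] objects for solvent residuals; they
#'   receive no class effect and their own (larger) variability.
#' @param solvent_cv Coefficient of variation of the solvent amplitude factor.
#' @param seed Integer random seed; fixes the dataset bit-for-bit.
#' @return An object of class `synth_params`.
#' @seealso [default_synth_params()], [generate_dataset()]
#' @export
synth_params <- function(n_geo, n_non, axis_range, n_points, peaks,
                         sugar_region, class_ratio = 1.5, intensity_cv = 0.1,
                         noise_sd = 0, solvent_peaks = list(),
                         solvent_cv = 0.5, seed = 1L) {
  p <- structure(
    list(n_geo = n_geo, n_non = n_non, axis_range = as.numeric(axis_range),
         n_points = n_points, peaks = peaks, sugar_region = as.numeric(sugar_region),
         class_ratio = class_ratio, intensity_cv = intensity_cv,
         noise_sd = noise_sd, solvent_peaks = solvent_peaks,
         solvent_cv = solvent_cv, seed = as.integer(seed)),
    class = "synth_params")
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  bad <- function(field, why) {
    stop(sprintf("invalid synth_params: '%s' %s", field, why), call. = FALSE)
  }
  if (!is.numeric(p$n_geo) || p$n_geo < 1) bad("n_geo", "must be >= 1")
  if (!is.numeric(p$n_non) || p$n_non < 1) bad("n_non", "must be >= 1")
  if (length(p$axis_range) != 2L || !(p$axis_range[1] < p$axis_range[2]))
    bad("axis_range", "must satisfy ppm_min < ppm_max")
  if (!is.numeric(p$n_points) || p$n_points < 2) bad("n_points", "must be >= 2")
  if (length(p$sugar_region) != 2L || !(p$sugar_region[1] < p$sugar_region[2]))
    bad("sugar_region", "must satisfy lo < hi")
  if (!(p$class_ratio > 0)) bad("class_ratio", "must be > 0")
  if (p$intensity_cv < 0) bad("intensity_cv", "must be >= 0")
  if (p$noise_sd < 0) bad("noise_sd", "must be >= 0")
  if (p$solvent_cv < 0) bad("solvent_cv", "must be >= 0")
  for (pk in c(p$peaks, p$solvent_peaks)) {
    if (!inherits(pk, "nmr_peak")) bad("peaks", "must all be peak() objects")
    if (pk$center < p$axis_range[1] || pk$center > p$axis_range[2])
      bad("peaks", sprintf("peak center %.3f ppm lies outside axis_range", pk$center))
  }
  invisible(p)
}

#' Default synthetic-study parameters
#'
#' Emulates a balanced 140-sample origin study (70 authentic + 70
#' non-authentic) over a 0.50--9.50 ppm axis, with a fixed 14-peak metabolite
#' table spanning the aliphatic (0.8--3.0 ppm), sugar (3.5--5.5 ppm) and
#' aromatic (6.5--9.0 ppm) regions, a 1.5-fold sugar-region class effect, 10%
#' per-peak biological variability, additive noise at 1% of the tallest peak,
#' and high-variability solvent residuals at 3.31 ppm (CHD2OD) and 4.79 ppm
#' (HDO). Peak positions and amplitudes are fabricated, documented constants;
#' they are chosen to be sugar-dominated as in real yam extracts.
#'
#' @return A `synth_params` object with a fixed seed (20230613 truncated to a
#'   documented default of 2023).
#' @export
default_synth_params <- function() {
  metab <- list(
    # aliphatic region: amino / organic acid methyls and methylenes
    peak(0.92, 0.012, 18), peak(1.18, 0.012, 14), peak(1.33, 0.012, 20),
    peak(1.48, 0.012, 16), peak(2.05, 0.015, 12), peak(2.35, 0.015, 14),
    peak(2.68, 0.015, 10), peak(2.90, 0.015, 8),
    # sugar region: carbohydrate envelope, dominates the spectrum
    peak(3.55, 0.020, 55), peak(3.72, 0.022, 70), peak(3.85, 0.020, 60),
    peak(4.12, 0.020, 45), peak(5.23, 0.015, 40), peak(5.41, 0.015, 35),
    # aromatic region
    peak(6.85, 0.012, 4), peak(7.35, 0.012, 5), peak(8.10, 0.012, 3.5),
    peak(8.46, 0.010, 2.5))
  solvent <- list(
    peak(3.31, 0.012, 80),   # CHD2OD residual
    peak(4.79, 0.050, 150))  # HDO residual, broad and highly variable
  max_amp <- max(vapply(metab, function(x) x$amplitude, numeric(1)))
  synth_params(
    n_geo = 70, n_non = 70,
    axis_range = c(0.50, 9.50), n_points = 4096,
    peaks = metab, sugar_region = c(3.50, 6.00),
    class_ratio = 1.5, intensity_cv = 0.1,
    noise_sd = 0.01 * max_amp,
    solvent_peaks = solvent, solvent_cv = 0.5,
    seed = 2023L)
}

lorentzian <- function(ppm, center, width) {
  width^2 / ((ppm - center)^2 + width^2)
}

#' Generate a two-class synthetic NMR dataset
#'
#' Each spectrum is a sum of Lorentzian lines. Every (sample, peak) pair draws
#' an independent lognormal amplitude factor with mean 1 and coefficient of
#' variation `intensity_cv` (`solvent_cv` for solvent peaks); non-authentic
#' samples additionally multiply the amplitude of every metabolite peak whose
#' center falls in `sugar_region` by `class_ratio`. Gaussian noise of standard
#' deviation `noise_sd` is added pointwise. The same seed reproduces the
#' dataset bit-for-bit.
#'
#' @param params A [synth_params()] object.
#' @return An `nmr_dataset`: shared decreasing ppm axis, an intensity matrix
#'   (points x samples), sample ids `geo_001`... / `non_001`..., and labels in
#'   `{geo_authentic, non_authentic}`.
#' @export
generate_dataset <- function(params) {
  validate_synth_params(params)
  set.seed(params$seed)
  ppm <- seq(params$axis_range[2], params$axis_range[1],
             length.out = params$n_points)
  n <- params$n_geo + params$n_non
  labels <- c(rep("geo_authentic", params$n_geo),
              rep("non_authentic", params$n_non))
  ids <- c(sprintf("geo_%03d", seq_len(params$n_geo)),
           sprintf("non_%03d", seq_len(params$n_non)))

  lognormal_factors <- function(n_peaks, n_samples, cv) {
    if (cv <= 0 || n_peaks == 0L)
      return(matrix(1, nrow = n_peaks, ncol = n_samples))
    sdlog <- sqrt(log(1 + cv^2))
    matrix(stats::rlnorm(n_peaks * n_samples, meanlog = -sdlog^2 / 2,
                         sdlog = sdlog),
           nrow = n_peaks, ncol = n_samples)
  }
  basis <- function(pks) {
    if (length(pks) == 0L) return(matrix(0, nrow = length(ppm), ncol = 0L))
    vapply(pks, function(pk) pk$amplitude * lorentzian(ppm, pk$center, pk$width),
           numeric(length(ppm)))
  }

  # draw order is fixed (metabolite factors, solvent factors, noise) so that
  # a given seed pins the whole dataset
  fmet <- lognormal_factors(length(params$peaks), n, params$intensity_cv)
  fsol <- lognormal_factors(length(params$solvent_peaks), n, params$solvent_cv)
  noise <- if (params$noise_sd > 0) {
    matrix(stats::rnorm(length(ppm) * n, sd = params$noise_sd),
           nrow = length(ppm), ncol = n)
  } else matrix(0, nrow = length(ppm), ncol = n)

  in_sugar <- vapply(params$peaks, function(pk) {
    pk$center >= params$sugar_region[1] && pk$center <= params$sugar_region[2]
  }, logical(1))
  class_mult <- matrix(1, nrow = length(params$peaks), ncol = n)
  class_mult[in_sugar, labels == "non_authentic"] <- params$class_ratio

  intens <- basis(params$peaks) %*% (fmet * class_mult)
  if (length(params$solvent_peaks) > 0L)
    intens <- intens + basis(params$solvent_peaks) %*% fsol
  intens <- intens + noise

  new_nmr_dataset(ppm, intens, ids, labels)
}

#' @rdname generate_dataset
#' @param ppm Shared chemical-shift axis (strictly monotone).
#' @param intensities Numeric matrix, `length(ppm)` rows x one column per sample.
#' @param sample_ids Unique sample identifiers.
#' @param labels Class labels, one per sample (may be `NA` for unlabeled data).
#' @export
new_nmr_dataset <- function(ppm, intensities, sample_ids, labels) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(ppm))
    stop("intensity matrix must have one row per ppm point", call. = FALSE)
  if (ncol(intensities) != length(sample_ids))
    stop("need one sample_id per intensity column", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("sample_ids must be unique", call. = FALSE)
  if (length(labels) != length(sample_ids))
    stop("need one label per sample", call. = FALSE)
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  if (!all(is.finite(intensities)))
    stop("all intensities must be finite", call. = FALSE)
  colnames(intensities) <- sample_ids
  structure(list(ppm = as.numeric(ppm), intensities = intensities,
                 sample_ids = as.character(sample_ids),
                 labels = as.character(labels)),
            class = "nmr_dataset")
}

#' @export
print.nmr_dataset <- function(x, ...) {
  cat(sprintf("<nmr_dataset> %d samples x %d points, ppm %.2f..%.2f\n",
              length(x$sample_ids), length(x$ppm), x$ppm[1],
              x$ppm[length(x$ppm)]))
  print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' Number of samples in a dataset
#' @param dataset An `nmr_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' Extract one spectrum from a dataset
#' @param dataset An `nmr_dataset`.
#' @param i Sample index or sample id.
#' @return An `nmr_spectrum` (sample_id, ppm, intensity, label).
#' @export
get_spectrum <- function(dataset, i) {
  if (is.character(i)) i <- match(i, dataset$sample_ids)
  if (is.na(i) || i < 1 || i > n_samples(dataset))
    stop("no such sample", call. = FALSE)
  structure(list(sample_id = dataset$sample_ids[i], ppm = dataset$ppm,
                 intensity = dataset$intensities[, i],
                 label = dataset$labels[i]),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %s (%s), %d points, ppm %.2f..%.2f\n",
              x$sample_id, x$label, length(x$ppm), x$ppm[1],
              x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Write / read a spectra matrix as CSV
#'
#' The matrix CSV stores the ppm axis in the first column (`ppm`) and one
#' column per sample, with sample ids as the header. Labels live in a
#' companion two-column CSV (`sample_id,label`); by default its path is the
#' matrix path with a `_labels.csv` suffix. Readers accept either axis
#' orientation and keep it as stored.
#'
#' @param dataset An `nmr_dataset`.
#' @param path Matrix CSV path.
#' @param labels_path Companion labels CSV path (default derived from `path`).
#' @return `write_dataset_csv()` the paths invisibly; `read_dataset_csv()` an
#'   `nmr_dataset` (labels are `NA` if no labels file is found).
#' @export
write_dataset_csv <- function(dataset, path, labels_path = default_labels_path(path)) {
  df <- data.frame(ppm = dataset$ppm, dataset$intensities,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  utils::write.csv(data.frame(sample_id = dataset$sample_ids,
                              label = dataset$labels),
                   labels_path, row.names = FALSE)
  invisible(c(matrix = path, labels = labels_path))
}

default_labels_path <- function(path) {
  sub("\\.csv$", "_labels.csv", path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, labels_path = default_labels_path(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("spectra CSV needs a ppm column plus at least one sample column",
         call. = FALSE)
  num <- suppressWarnings(
    vapply(raw, as.numeric, numeric(nrow(raw)), USE.NAMES = TRUE))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(raw),
                                       dimnames = list(NULL, names(raw)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at data row %d, column '%s'",
                 bad[1], colnames(num)[bad[2]]), call. = FALSE)
  }
  ids <- colnames(num)[-1]
  labels <- rep(NA_character_, length(ids))
  if (file.exists(labels_path)) {
    lab <- utils::read.csv(labels_path, colClasses = "character")
    labels <- lab$label[match(ids, lab$sample_id)]
  }
  new_nmr_dataset(num[, 1], num[, -1, drop = FALSE], ids, labels)
}
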