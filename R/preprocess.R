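#' A closed ppm interval
#' @param lo,hi Interval bounds in ppm, `lo < hi`. Both endpoints are included
#'   when selecting or excluding axis points.
#' @return A `ppm_range` object.
#' @export
ppm_range <- function(lo, hi) {
  if (!is.numeric(lo) || !is.numeric(hi) || !(lo < hi))
    stop("ppm_range requires lo < hi", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "ppm_range")
}

#' Preprocessing specification: crop plus solvent exclusions
#'
#' @param crop A [ppm_range()] to crop the axis to (default 0.50--9.50 ppm).
#' @param exclusions List of [ppm_range()]s to excise (e.g. solvent residual
#'   regions); may be empty. Must each overlap the crop window and be pairwise
#'   non-overlapping.
#' @return A `preprocess_spec` object.
#' @export
preprocess_spec <- function(crop = ppm_range(0.50, 9.50), exclusions = list()) {
  stopifnot(inherits(crop, "ppm_range"))
  for (e in exclusions) {
    if (!inherits(e, "ppm_range"))
      stop("exclusions must be ppm_range objects", call. = FALSE)
    if (e$hi < crop$lo || e$lo > crop$hi)
      stop("every exclusion must overlap the crop window", call. = FALSE)
  }
  if (length(exclusions) > 1L) {
    ord <- order(vapply(exclusions, `[[`, numeric(1), "lo"))
    exclusions <- exclusions[ord]
    for (i in seq_len(length(exclusions) - 1L)) {
      if (exclusions[[i]]$hi >= exclusions[[i + 1L]]$lo)
        stop("exclusions must be pairwise non-overlapping", call. = FALSE)
    }
  }
  structure(list(crop = crop, exclusions = exclusions),
            class = "preprocess_spec")
}

#' Standard preprocessing regimes
#'
#' Regime 1 crops the spectrum to 0.50--9.50 ppm. Regimes 2 and 3 additionally
#' excise the solvent residual regions 3.28--3.34 ppm (CHD2OD) and
#' 4.6--5.2 ppm (HDO). Excised points are deleted outright, so downstream
#' vectors shorten and rendered images draw the retained segments
#' contiguously.
#'
#' @param experiment 1 (crop only) or 2/3 (crop + solvent exclusions).
#' @return A [preprocess_spec()].
#' @export
default_preprocess_spec <- function(experiment = 2L) {
  excl <- if (experiment >= 2L) {
    list(ppm_range(3.28, 3.34), ppm_range(4.6, 5.2))
  } else list()
  preprocess_spec(crop = ppm_range(0.50, 9.50), exclusions = excl)
}

keep_mask_crop <- function(ppm, crop) ppm >= crop$lo & ppm <= crop$hi

keep_mask_exclusions <- function(ppm, exclusions) {
  keep <- rep(TRUE, length(ppm))
  for (e in exclusions) keep[ppm >= e$lo & ppm <= e$hi] <- FALSE
  keep
}

subset_axis <- function(x, keep) UseMethod("subset_axis")

#' @export
subset_axis.nmr_spectrum <- function(x, keep) {
  structure(list(sample_id = x$sample_id, ppm = x$ppm[keep],
                 intensity = x$intensity[keep], label = x$label),
            class = "nmr_spectrum")
}

#' @export
subset_axis.nmr_dataset <- function(x, keep) {
  new_nmr_dataset(x$ppm[keep], x$intensities[keep, , drop = FALSE],
                  x$sample_ids, x$labels)
}

#' Crop a spectrum or dataset to a ppm window
#'
#' Keeps exactly the axis points with `lo <= ppm <= hi` (closed interval),
#' preserving the original point order.
#'
#' @param x An `nmr_spectrum` or `nmr_dataset`.
#' @param crop A [ppm_range()].
#' @return The same class of object with the reduced axis.
#' @export
crop_to_range <- function(x, crop) {
  stopifnot(inherits(crop, "ppm_range"))
  ppm <- if (inherits(x, "nmr_dataset")) x$ppm else x$ppm
  keep <- keep_mask_crop(ppm, crop)
  if (!any(keep))
    stop("degenerate input: crop window retains no axis points", call. = FALSE)
  subset_axis(x, keep)
}

#' Excise ppm regions from a spectrum or dataset
#'
#' Points falling inside any exclusion interval (closed) are deleted; the
#' remaining points are concatenated in their original order with no gap
#' placeholder, matching the reduced-vector regime used after solvent removal.
#'
#' @param x An `nmr_spectrum` or `nmr_dataset`.
#' @param exclusions List of [ppm_range()]s (possibly empty).
#' @return The same class of object with the reduced axis.
#' @export
exclude_regions <- function(x, exclusions) {
  if (length(exclusions) == 0L) return(x)
  ppm <- x$ppm
  if (length(ppm) == 0L) stop("empty spectrum", call. = FALSE)
  keep <- keep_mask_exclusions(ppm, exclusions)
  if (!any(keep))
    stop("degenerate input: exclusions delete every axis point", call. = FALSE)
  subset_axis(x, keep)
}

#' Apply a preprocessing spec to a dataset
#'
#' Crops first, then excises the exclusion regions, identically for every
#' sample (all samples share one axis). Applying the same spec twice is
#' idempotent.
#'
#' @param spec A [preprocess_spec()].
#' @param dataset An `nmr_dataset` (also accepts a single `nmr_spectrum`).
#' @return The preprocessed object.
#' @export
preprocess_apply <- function(spec, dataset) {
  stopifnot(inherits(spec, "preprocess_spec"))
  out <- crop_to_range(dataset, spec$crop)
  exclude_regions(out, spec$exclusions)
}
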