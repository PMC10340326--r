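#' Rendering specification for spectrum rasterization
#'
#' Defaults mirror the image geometry used for texture capture: 1156 x 600
#' pixel 8-bit grayscale, black 1-px connected trace on a white background, no
#' axes, ticks, text or anti-aliasing — texture features must not encode
#' plotting chrome.
#'
#' @param width,height Image size in pixels (>= 3 each).
#' @param foreground,background Gray levels 0--255 for trace and background;
#'   must differ.
#' @param line_thickness Trace thickness in pixels (vertical dilation).
#' @param intensity_ceiling `"dataset_max"` (default: one ceiling shared by
#'   all samples, so the between-sample absolute intensity differences that
#'   carry the origin signal in internally referenced spectra survive
#'   rendering) or `"spectrum_max"` (each image scaled to its own maximum,
#'   making the render invariant to global intensity scaling).
#' @return A `render_spec` object.
#' @export
render_spec <- function(width = 1156L, height = 600L, foreground = 0L,
                        background = 255L, line_thickness = 1L,
                        intensity_ceiling = c("dataset_max", "spectrum_max")) {
  intensity_ceiling <- match.arg(intensity_ceiling)
  if (width < 3L || height < 3L)
    stop("render_spec: width and height must be >= 3", call. = FALSE)
  if (foreground == background)
    stop("render_spec: foreground must differ from background", call. = FALSE)
  if (any(c(foreground, background) < 0) || any(c(foreground, background) > 255))
    stop("render_spec: gray levels must lie in [0, 255]", call. = FALSE)
  if (line_thickness < 1L)
    stop("render_spec: line_thickness must be >= 1", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 foreground = as.integer(foreground),
                 background = as.integer(background),
                 line_thickness = as.integer(line_thickness),
                 intensity_ceiling = intensity_ceiling),
            class = "render_spec")
}

new_spectrum_image <- function(pixels, sample_id = NA_character_) {
  structure(list(pixels = pixels, sample_id = sample_id),
            class = "spectrum_image")
}

#' @export
print.spectrum_image <- function(x, ...) {
  cat(sprintf("<spectrum_image> %d x %d px (h x w), sample %s\n",
              nrow(x$pixels), ncol(x$pixels), x$sample_id))
  invisible(x)
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "spectrum_image")) return(image$pixels)
  if (is.matrix(image)) return(image)
  stop("expected a spectrum_image or a numeric matrix", call. = FALSE)
}

#' Rasterize a spectrum into a fixed-size grayscale image
#'
#' The axis maps left-to-right onto columns in order of decreasing ppm (NMR
#' display convention); after region excision the retained points are drawn
#' contiguously by index. Intensities map linearly so that 0 sits on the
#' bottom row and the ceiling on the top row; values above the ceiling (or
#' below 0) are clipped. When several points land in one column the column
#' takes their maximum intensity (peak-preserving). The trace is drawn with
#' vertical-fill connectivity: every column is filled from its own trace row
#' to the previous column's row, so the polyline is 4-connected. The renderer
#' is fully deterministic.
#'
#' @param spectrum An `nmr_spectrum` with at least 2 points.
#' @param spec A [render_spec()].
#' @param ceiling_value Intensity mapped to the top row. Defaults to the
#'   spectrum's own maximum; pass a dataset-wide maximum for the
#'   `"dataset_max"` regime.
#' @return A `spectrum_image` (integer pixel matrix, `height` rows x `width`
#'   columns, values in 0..255).
#' @seealso [rasterize_dataset()]
#' @export
rasterize <- function(spectrum, spec = render_spec(), ceiling_value = NULL) {
  stopifnot(inherits(spec, "render_spec"))
  y <- spectrum$intensity
  if (length(y) < 2L)
    stop("degenerate input: need at least 2 spectrum points", call. = FALSE)
  if (!all(is.finite(y)))
    stop("non-finite intensity values", call. = FALSE)
  # order points left-to-right by decreasing ppm
  ord <- order(spectrum$ppm, decreasing = TRUE)
  y <- y[ord]
  n <- length(y)
  w <- spec$width; h <- spec$height
  ceil_val <- if (is.null(ceiling_value)) max(y) else ceiling_value
  if (!is.finite(ceil_val) || ceil_val <= 0) ceil_val <- 1  # flat/degenerate: all to bottom row

  # assign sample points to columns; bin by max (peak-preserving)
  col_of <- floor((seq_len(n) - 1L) * w / n) + 1L
  col_max <- rep(-Inf, w)
  agg <- tapply(y, col_of, max)
  col_max[as.integer(names(agg))] <- agg

  # fill unoccupied columns by linear interpolation between occupied ones
  occ <- which(is.finite(col_max))
  if (length(occ) < w) {
    col_max <- stats::approx(occ, col_max[occ], xout = seq_len(w),
                             rule = 2)$y
  }

  t_clip <- pmin(pmax(col_max, 0), ceil_val)
  rows <- h - as.integer(round(t_clip / ceil_val * (h - 1L)))  # 0 -> bottom row h

  px <- matrix(spec$background, nrow = h, ncol = w)
  half <- (spec$line_thickness - 1L) %/% 2L
  lo <- pmin(c(rows[1], rows[-w]), rows)
  hi <- pmax(c(rows[1], rows[-w]), rows)
  lo <- pmax(lo - half, 1L)
  hi <- pmin(hi + half + (spec$line_thickness - 1L) %% 2L, h)
  for (cidx in seq_len(w)) px[lo[cidx]:hi[cidx], cidx] <- spec$foreground
  new_spectrum_image(px, spectrum$sample_id)
}

#' Rasterize every spectrum of a dataset
#'
#' @param dataset An `nmr_dataset`.
#' @param spec A [render_spec()]. Under `"dataset_max"` the ceiling is the
#'   global intensity maximum across samples.
#' @return A list of `spectrum_image`s, one per sample.
#' @export
rasterize_dataset <- function(dataset, spec = render_spec()) {
  ceiling_value <- if (spec$intensity_ceiling == "dataset_max") {
    max(dataset$intensities)
  } else NULL
  lapply(seq_len(n_samples(dataset)), function(i) {
    rasterize(get_spectrum(dataset, i), spec, ceiling_value = ceiling_value)
  })
}

#' Write / read an 8-bit grayscale PNG
#'
#' The round trip is lossless for 8-bit grayscale images. On read, RGB/RGBA
#' PNGs are converted to gray with the ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); the alpha channel is ignored.
#'
#' @param image A `spectrum_image` or integer matrix with values in 0..255.
#' @param path PNG file path.
#' @return `read_png()` returns a `spectrum_image` whose sample id is the file
#'   base name.
#' @export
write_png <- function(image, path) {
  px <- as_pixel_matrix(image)
  if (any(px < 0) || any(px > 255))
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' @rdname write_png
#' @export
read_png <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  arr <- tryCatch(png::readPNG(path),
                  error = function(e) stop("not a readable PNG file: ", path,
                                           call. = FALSE))
  gray <- if (length(dim(arr)) == 2L) {
    arr
  } else {
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  }
  px <- matrix(as.integer(round(gray * 255)), nrow = nrow(gray))
  new_spectrum_image(px, sub("\\.png$", "", basename(path)))
}
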