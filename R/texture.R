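#' Local binary pattern configuration
#'
#' Circular LBP with `p` samples on a radius-`r` circle around each pixel.
#' Defaults (`r = 1`, `p = 8`) give the riu2 operator with a 10-dimensional
#' feature vector.
#'
#' @param r Neighborhood radius in pixels (> 0).
#' @param p Number of circular samples (even, >= 4).
#' @param mode `"riu2"` (rotation-invariant uniform mapping, default) or
#'   `"basic"` (raw `2^p` codes).
#' @param interpolation `"bilinear"` (default) or `"nearest"` for non-integer
#'   sample positions; exact pixel values are used at integer positions.
#' @return An `lbp_config` object.
#' @export
lbp_config <- function(r = 1, p = 8L, mode = c("riu2", "basic"),
                       interpolation = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  if (!(r > 0)) stop("lbp_config: r must be > 0", call. = FALSE)
  if (p < 4L || p %% 2L != 0L)
    stop("lbp_config: p must be even and >= 4", call. = FALSE)
  structure(list(r = r, p = as.integer(p), mode = mode,
                 interpolation = interpolation),
            class = "lbp_config")
}

# circle geometry: neighbor i sits at angle 2*pi*i/p from the +column axis,
# counter-clockwise, i.e. offset (-r sin(theta), +r cos(theta)) in (row, col).
# offsets within 1e-9 of an integer are snapped so exact pixel values are used.
neighbor_offsets <- function(r, p) {
  theta <- 2 * pi * (0:(p - 1L)) / p
  dr <- -r * sin(theta)
  dc <- r * cos(theta)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  list(dr = snap(dr), dc = snap(dc))
}

#' Sample the circular neighborhood of one pixel
#'
#' @param image A `spectrum_image` or numeric matrix.
#' @param row,col Center pixel position (1-based); must be at least `ceil(r)`
#'   pixels from every border.
#' @param config An [lbp_config()].
#' @return Numeric vector of `p` neighbor gray values, counter-clockwise from
#'   the +column axis.
#' @export
sample_neighbors <- function(image, row, col, config = lbp_config()) {
  m <- as_pixel_matrix(image)
  b <- ceiling(config$r)
  if (row <= b || row > nrow(m) - b || col <= b || col > ncol(m) - b)
    stop("center pixel too close to the image border", call. = FALSE)
  off <- neighbor_offsets(config$r, config$p)
  vapply(seq_len(config$p), function(i) {
    y <- row + off$dr[i]; x <- col + off$dc[i]
    if (y == round(y) && x == round(x)) return(m[round(y), round(x)])
    if (config$interpolation == "nearest") return(m[round(y), round(x)])
    y0 <- floor(y); x0 <- floor(x); fy <- y - y0; fx <- x - x0
    (1 - fy) * (1 - fx) * m[y0, x0] + (1 - fy) * fx * m[y0, x0 + 1] +
      fy * (1 - fx) * m[y0 + 1, x0] + fy * fx * m[y0 + 1, x0 + 1]
  }, numeric(1))
}

#' Threshold neighbors against the center pixel
#'
#' Bit i is `s(g_i - g_c)` with the sign function `s(x) = 1` iff `x >= 0`:
#' ties (neighbor equal to center) give 1, so a constant image produces the
#' all-ones pattern.
#'
#' @param center Center gray value.
#' @param neighbors Numeric vector of neighbor gray values.
#' @return Integer 0/1 vector of the same length.
#' @export
threshold_pattern <- function(center, neighbors) {
  as.integer(neighbors >= center)
}

#' Uniformity of a circular binary pattern
#'
#' The number of 0/1 transitions around the circle:
#' `U = |s_{p-1} - s_0| + sum_{i=1}^{p-1} |s_i - s_{i-1}|`. `U` is even and
#' lies in `[0, p]`; patterns with `U <= 2` are called uniform.
#'
#' @param pattern Integer 0/1 vector.
#' @return Integer transition count.
#' @export
uniformity <- function(pattern) {
  p <- length(pattern)
  sum(abs(pattern - pattern[c(p, seq_len(p - 1L))]))
}

#' Rotation-invariant uniform (riu2) code of a pattern
#'
#' Uniform patterns (`U <= 2`) are coded by their number of 1-bits (0..p);
#' every non-uniform pattern collapses to the single code `p + 1`, giving
#' `p + 2` codes in total.
#'
#' @param pattern Integer 0/1 vector of length `p`.
#' @return Integer code in `[0, p + 1]`.
#' @export
riu2_code <- function(pattern) {
  if (uniformity(pattern) <= 2L) sum(pattern) else length(pattern) + 1L
}

#' Full riu2 lookup table over all 2^p basic patterns
#'
#' Entry `k + 1` holds the riu2 code of the basic pattern whose bits are the
#' little-endian binary digits of `k` (bit i = neighbor i).
#'
#' @param p Number of neighbors (>= 4).
#' @return Integer vector of length `2^p` with exactly `p + 2` distinct values.
#' @export
riu2_mapping_table <- function(p) {
  if (p < 4L) stop("p must be >= 4", call. = FALSE)
  codes <- integer(2^p)
  for (k in 0:(2^p - 1L)) {
    bits <- bitwAnd(bitwShiftR(k, 0:(p - 1L)), 1L)
    codes[k + 1L] <- riu2_code(bits)
  }
  codes
}

# riu2 (or basic) code at every interior pixel, vectorized over the image.
# Offsets are scalar per neighbor, so bilinear interpolation reduces to a
# weighted sum of four shifted submatrices.
lbp_code_matrix <- function(image, config = lbp_config()) {
  m <- as_pixel_matrix(image)
  b <- ceiling(config$r)
  h <- nrow(m); w <- ncol(m)
  if (h < 2 * b + 1 || w < 2 * b + 1)
    stop("degenerate input: image smaller than the LBP neighborhood",
         call. = FALSE)
  rows <- (b + 1L):(h - b)
  cols <- (b + 1L):(w - b)
  center <- m[rows, cols, drop = FALSE]
  off <- neighbor_offsets(config$r, config$p)

  neighbor_plane <- function(dr, dc) {
    if (dr == round(dr) && dc == round(dc))
      return(m[rows + dr, cols + dc, drop = FALSE])
    if (config$interpolation == "nearest")
      return(m[rows + round(dr), cols + round(dc), drop = FALSE])
    y0 <- floor(dr); x0 <- floor(dc); fy <- dr - y0; fx <- dc - x0
    (1 - fy) * (1 - fx) * m[rows + y0, cols + x0, drop = FALSE] +
      (1 - fy) * fx       * m[rows + y0, cols + x0 + 1L, drop = FALSE] +
      fy       * (1 - fx) * m[rows + y0 + 1L, cols + x0, drop = FALSE] +
      fy       * fx       * m[rows + y0 + 1L, cols + x0 + 1L, drop = FALSE]
  }

  p <- config$p
  nbits <- 0L; trans <- 0L; basic <- 0
  first_bit <- NULL; prev_bit <- NULL
  for (i in seq_len(p)) {
    bit <- (neighbor_plane(off$dr[i], off$dc[i]) >= center) * 1L
    nbits <- nbits + bit
    if (config$mode == "basic") basic <- basic + bit * 2^(i - 1L)
    if (is.null(first_bit)) first_bit <- bit else trans <- trans + abs(bit - prev_bit)
    prev_bit <- bit
  }
  trans <- trans + abs(prev_bit - first_bit)
  if (config$mode == "basic") return(basic)
  codes <- nbits
  codes[trans > 2L] <- p + 1L
  codes
}

#' riu2 LBP histogram feature vector of an image
#'
#' The riu2 code is computed at every pixel whose full circular neighborhood
#' lies inside the image (a border of width `ceil(r)` is skipped rather than
#' padded, so no artificial edge texture enters the histogram). The histogram
#' over codes `0..p+1` is the image's feature vector, of length `p + 2` (10
#' for `p = 8`); in `"basic"` mode it is the histogram over the `2^p` raw
#' codes.
#'
#' @param image A `spectrum_image` or numeric matrix.
#' @param config An [lbp_config()].
#' @param normalize `"frequency"` (entries sum to 1, default — comparable
#'   across image sizes) or `"counts"` (entries sum to the number of interior
#'   pixels).
#' @return Named numeric vector (`code_0`, `code_1`, ...).
#' @export
lbp_histogram <- function(image, config = lbp_config(),
                          normalize = c("frequency", "counts")) {
  normalize <- match.arg(normalize)
  codes <- lbp_code_matrix(image, config)
  nbins <- if (config$mode == "riu2") config$p + 2L else 2L^config$p
  counts <- tabulate(as.integer(codes) + 1L, nbins = nbins)
  names(counts) <- paste0("code_", seq_len(nbins) - 1L)
  if (normalize == "frequency") counts / sum(counts) else counts
}

#' riu2 feature matrix for a list of images
#'
#' @param images A list of `spectrum_image`s (e.g. from [rasterize_dataset()]).
#' @param config An [lbp_config()].
#' @param normalize Passed to [lbp_histogram()].
#' @return Numeric matrix, one row per image, `p + 2` feature columns; row
#'   names are the images' sample ids.
#' @export
lbp_features <- function(images, config = lbp_config(),
                         normalize = "frequency") {
  feats <- t(vapply(images, lbp_histogram, config = config,
                    normalize = normalize,
                    FUN.VALUE = numeric(if (config$mode == "riu2")
                      config$p + 2L else 2L^config$p)))
  rownames(feats) <- vapply(images, function(im) {
    if (inherits(im, "spectrum_image")) im$sample_id else NA_character_
  }, character(1))
  feats
}

#' Write a feature matrix with ids and labels as CSV
#'
#' One row per sample: `sample_id`, `label`, then one column per feature.
#'
#' @param features Numeric matrix with sample ids as row names.
#' @param labels Class labels, one per row.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(features, labels, path) {
  df <- data.frame(sample_id = rownames(features), label = labels,
                   features, check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
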