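#' A single time-resolved photograph
#'
#' @param pixels Numeric matrix of grayscale intensities (any affine scale;
#'   segmentation is invariant to affine rescaling).
#' @param um_per_px Pixel scale (um per pixel), > 0.
#' @param delay Delay since the laser pulse (s).
#' @param replicate_id Replicate index.
#' @param sample_id Sample identifier.
#' @return List of class `lcr_frame`.
#' @export
lcr_frame <- function(pixels, um_per_px, delay = NA_real_,
                      replicate_id = NA_integer_, sample_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite")
  if (!is.numeric(um_per_px) || um_per_px <= 0)
    stop("um_per_px must be > 0")
  structure(list(pixels = pixels, um_per_px = um_per_px, delay = delay,
                 replicate_id = replicate_id, sample_id = sample_id),
            class = "lcr_frame")
}

#' Read a grayscale frame from TIFF or PNG
#'
#' Multi-channel images are averaged to grayscale. The pixel scale is always
#' user-supplied (it depends on the objective and camera).
#'
#' @param path Image path (`.tif`, `.tiff` or `.png`).
#' @param um_per_px Pixel scale (um/px).
#' @param delay,replicate_id,sample_id Acquisition metadata.
#' @return [lcr_frame()].
#' @export
read_frame <- function(path, um_per_px, delay = NA_real_,
                       replicate_id = NA_integer_,
                       sample_id = NA_character_) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path),
               png = png::readPNG(path),
               stop("unsupported image format: .", ext))
  if (length(dim(px)) == 3) px <- apply(px, c(1, 2), mean)
  lcr_frame(px, um_per_px, delay, replicate_id, sample_id)
}

#' Segment the bubble in a frame
#'
#' Two-class k-means on the pixel intensities (deterministic: initial centers
#' at the intensity minimum and maximum), with the bubble taken as the darker
#' class by default. The largest connected component is kept, its holes are
#' filled, and the equivalent radius of a circle with the same pixel area is
#' reported, assuming spherical symmetry of the bubble cross-section.
#'
#' If the two class centers are separated by less than `min_separation`
#' pooled within-class standard deviations — an effectively uniform frame —
#' a flagged no-bubble result (radius 0) is returned rather than an error.
#'
#' @param frame [lcr_frame()], at least 2 distinct intensity levels for a
#'   bubble to be found.
#' @param polarity `"dark"` (default; bubble darker than background) or
#'   `"bright"`.
#' @param min_separation Contrast threshold, in units of pooled within-class
#'   standard deviation.
#' @return List of class `lcr_segmentation`: `mask` (logical matrix), `area`
#'   (px), `equivalent_radius` (m), `flags` (`no_bubble`,
#'   `multiple_components`, `touching_border`), `centers`.
#' @export
segment_frame <- function(frame, polarity = c("dark", "bright"),
                          min_separation = 3) {
  polarity <- match.arg(polarity)
  px <- frame$pixels
  v <- as.vector(px)
  no_bubble <- function() {
    structure(list(mask = matrix(FALSE, nrow(px), ncol(px)), area = 0L,
                   equivalent_radius = 0,
                   flags = list(no_bubble = TRUE, multiple_components = FALSE,
                                touching_border = FALSE),
                   centers = range(v)), class = "lcr_segmentation")
  }
  if (length(unique(v)) < 2) return(no_bubble())
  km <- stats::kmeans(v, centers = matrix(c(min(v), max(v))))
  lo <- which.min(km$centers)
  within_sd <- sqrt(sum(km$withinss) / max(length(v) - 2, 1))
  if (abs(diff(range(km$centers))) < min_separation * within_sd)
    return(no_bubble())
  bubble_class <- if (polarity == "dark") lo else which.max(km$centers)
  mask <- matrix(km$cluster == bubble_class, nrow(px), ncol(px))

  labels <- EBImage::bwlabel(EBImage::Image(mask * 1))
  n_comp <- max(labels)
  if (n_comp == 0) return(no_bubble())
  sizes <- tabulate(as.integer(labels)[as.integer(labels) > 0], n_comp)
  keep <- which.max(sizes)
  main <- EBImage::fillHull(EBImage::Image((labels == keep) * 1))
  mask <- matrix(as.integer(main) > 0, nrow(px), ncol(px))
  area <- sum(mask)
  touching <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
  structure(list(
    mask = mask, area = area,
    equivalent_radius = frame$um_per_px * sqrt(area / pi) * 1e-6,
    flags = list(no_bubble = FALSE, multiple_components = n_comp > 1,
                 touching_border = touching),
    centers = as.numeric(km$centers)), class = "lcr_segmentation")
}

#' Assemble segmented frames into a radius-time dataset
#'
#' Segments each frame and emits one (delay, radius, replicate) row per
#' frame — no averaging — sorted by delay then replicate. Frames whose bubble
#' touches the image border underestimate the radius and are excluded by
#' default with a warning; frames with no detectable bubble are always
#' dropped.
#'
#' @param frames List of [lcr_frame()] sharing one sample and pixel scale.
#' @param exclude_border Drop border-touching bubbles (default `TRUE`).
#' @param ... Passed to [segment_frame()].
#' @return [lcr_dataset()].
#' @export
build_series <- function(frames, exclude_border = TRUE, ...) {
  if (!length(frames)) stop("no frames supplied")
  scales <- vapply(frames, function(f) f$um_per_px, numeric(1))
  if (length(unique(scales)) > 1)
    stop("frames have mixed pixel scales; segment them separately")
  ids <- unique(stats::na.omit(vapply(frames, function(f)
    f$sample_id, character(1))))
  if (length(ids) > 1) stop("frames mix sample ids: ",
                            paste(ids, collapse = ", "))
  segs <- lapply(frames, segment_frame, ...)
  rows <- data.frame(
    time = vapply(frames, function(f) f$delay, numeric(1)),
    radius = vapply(segs, function(s) s$equivalent_radius, numeric(1)),
    replicate_id = vapply(frames, function(f)
      as.integer(f$replicate_id), integer(1)),
    border = vapply(segs, function(s) s$flags$touching_border, logical(1)),
    empty = vapply(segs, function(s) s$flags$no_bubble, logical(1)))
  if (exclude_border && any(rows$border))
    warning(sum(rows$border),
            " frame(s) with border-touching bubbles excluded", call. = FALSE)
  keep <- !rows$empty & (!exclude_border | !rows$border)
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows)) stop("no usable bubble detections in the frame stack")
  rows <- rows[order(rows$time, rows$replicate_id), ]
  lcr_dataset(rows$time, rows$radius, rows$replicate_id,
              if (length(ids)) ids else "sample")
}

#' Render a synthetic bubble photograph
#'
#' Centered dark disk (optional center jitter) on a bright background with a
#' Gaussian-blurred edge and additive intensity noise; deterministic for a
#' fixed seed. Serves as the stand-in for the instrument so the segmentation
#' stage is testable end to end.
#'
#' @param radius Bubble radius (m); 0 renders a blank frame.
#' @param um_per_px Pixel scale (um/px).
#' @param frame_dim Frame size `c(rows, cols)` in pixels.
#' @param blur_px Gaussian edge width (px).
#' @param noise_sigma Additive intensity noise, as a fraction of the
#'   disk/background contrast.
#' @param center_jitter_px Uniform jitter of the disk center (px).
#' @param background,contrast Background intensity and disk depth (0-1).
#' @param seed Seed for noise and jitter; `NULL` uses the current stream.
#' @param delay,replicate_id,sample_id Metadata stored on the frame.
#' @return [lcr_frame()].
#' @export
render_synthetic_frame <- function(radius, um_per_px, frame_dim = c(160L, 160L),
                                   blur_px = 1.5, noise_sigma = 0.05,
                                   center_jitter_px = 0, background = 0.85,
                                   contrast = 0.7, seed = NULL,
                                   delay = NA_real_,
                                   replicate_id = NA_integer_,
                                   sample_id = NA_character_) {
  r_px <- radius * 1e6 / um_per_px
  if (r_px >= min(frame_dim) / 2 - center_jitter_px - 2 * blur_px)
    stop("disk exceeds the frame: radius ", signif(r_px, 4), " px in a ",
         paste(frame_dim, collapse = "x"), " frame")
  with_seed(seed, {
    cy <- (frame_dim[1] + 1) / 2
    cx <- (frame_dim[2] + 1) / 2
    if (center_jitter_px > 0) {
      cy <- cy + stats::runif(1, -center_jitter_px, center_jitter_px)
      cx <- cx + stats::runif(1, -center_jitter_px, center_jitter_px)
    }
    d <- sqrt(outer((seq_len(frame_dim[1]) - cy) ^ 2,
                    (seq_len(frame_dim[2]) - cx) ^ 2, `+`))
    px <- matrix(background, frame_dim[1], frame_dim[2])
    if (r_px > 0)
      px <- px - contrast * stats::pnorm((r_px - d) / max(blur_px, 1e-9))
    if (noise_sigma > 0)
      px <- px + noise_sigma * contrast *
        stats::rnorm(length(px))
    px <- pmin(pmax(px, 0), 1)
    lcr_frame(px, um_per_px, delay, replicate_id, sample_id)
  })
}
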