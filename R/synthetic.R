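# run expr under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses (and advances) the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Acquisition protocol for synthetic radius-time data
#'
#' Emulates the statistical structure of time-resolved single-exposure
#' photography: delays in fixed increments (1 us by default), several
#' replicate bubble events per delay (5 by default), and multiplicative
#' Gaussian radius noise (sigma = 3% by default) with an optional additive
#' floor. The defaults define the acquisition conditions used throughout the
#' package's recovery studies.
#'
#' @param delay_step Delay increment (s).
#' @param delay_min,delay_max Delay range (s).
#' @param replicates Replicate measurements per delay (>= 1).
#' @param noise_sigma Multiplicative radius noise standard deviation.
#' @param noise_floor Additive radius noise standard deviation (m).
#' @param seed Integer seed making the generated data deterministic; `NULL`
#'   draws from the current RNG stream.
#' @return List of class `lcr_protocol`.
#' @export
acquisition_protocol <- function(delay_step = 1e-6, delay_min = 0,
                                 delay_max = 30e-6, replicates = 5L,
                                 noise_sigma = 0.03, noise_floor = 0,
                                 seed = NULL) {
  stopifnot(delay_step > 0, delay_max >= delay_min, replicates >= 1,
            noise_sigma >= 0, noise_floor >= 0)
  structure(list(delay_step = delay_step, delay_min = delay_min,
                 delay_max = delay_max, replicates = as.integer(replicates),
                 noise_sigma = noise_sigma, noise_floor = noise_floor,
                 seed = seed),
            class = "lcr_protocol")
}

#' Generate a synthetic radius-time dataset
#'
#' Simulates one full cycle at the true parameters, samples the model radius
#' at the protocol delays (shifted by the true time offset), and adds
#' independent noise per replicate. Delays at which the bubble does not exist
#' (before inception or after collapse) are omitted, matching what
#' time-resolved photography can observe.
#'
#' @param true_params [fit_parameters()] generating the data.
#' @param mat [material()] for the fixed constants.
#' @param ambient [ambient_conditions()].
#' @param protocol [acquisition_protocol()].
#' @param sample_id Sample identifier stored in the dataset.
#' @param solver [solver_options()].
#' @return [lcr_dataset()]; the generating trajectory is attached as
#'   attribute `trajectory`.
#' @export
generate_dataset <- function(true_params, mat = material(),
                             ambient = ambient_conditions(),
                             protocol = acquisition_protocol(),
                             sample_id = "synthetic",
                             solver = solver_options()) {
  tr <- simulate_cycle(true_params$R_max, params_material(true_params, mat),
                       ambient, mode = "failure", solver = solver)
  if (tr$T_hg < protocol$delay_step)
    stop("degenerate protocol: cycle time shorter than one delay step")
  delays <- seq(protocol$delay_min, protocol$delay_max,
                by = protocol$delay_step)
  inside <- delays - true_params$t0 >= 0 &
    delays - true_params$t0 <= tr$T_hg
  delays <- delays[inside]
  if (!length(delays))
    stop("no protocol delay falls inside the simulated cycle window")
  model_r <- trajectory_radius(tr, delays - true_params$t0)
  rows <- with_seed(protocol$seed, {
    do.call(rbind, lapply(seq_len(protocol$replicates), function(rep_i) {
      noisy <- model_r * (1 + protocol$noise_sigma *
                            stats::rnorm(length(model_r))) +
        protocol$noise_floor * stats::rnorm(length(model_r))
      data.frame(time = delays, radius = noisy, replicate_id = rep_i)
    }))
  })
  rows <- rows[order(rows$time, rows$replicate_id), ]
  ds <- lcr_dataset(rows$time, rows$radius, rows$replicate_id, sample_id)
  attr(ds, "trajectory") <- tr
  ds
}

#' Generate a synthetic frame stack with manifest
#'
#' Renders one synthetic photograph per (delay, replicate) of
#' [generate_dataset()] output — noise enters through the pixel renderer, so
#' the rendered radii are the noise-free model radii — and writes a manifest
#' consistent with the imaging-module input schema.
#'
#' @param true_params,mat,ambient,protocol,solver As in [generate_dataset()].
#' @param dir Output directory for the PNG frames and `manifest.tsv`.
#' @param sample_id Sample identifier.
#' @param um_per_px Pixel scale of the rendered frames (um/px).
#' @param frame_dim Frame size in pixels, `c(rows, cols)`.
#' @param blur_px Gaussian edge blur of the rendered disk (px).
#' @param pixel_noise_sigma Additive pixel intensity noise (fraction of
#'   contrast).
#' @return The manifest as a data.frame (`path`, `delay_us`, `replicate_id`,
#'   `sample_id`, `um_per_px`), invisibly; files are written under `dir`.
#' @export
generate_frame_stack <- function(true_params, mat = material(),
                                 ambient = ambient_conditions(),
                                 protocol = acquisition_protocol(),
                                 dir = tempfile("frames"),
                                 sample_id = "synthetic",
                                 um_per_px = 2, frame_dim = c(160L, 160L),
                                 blur_px = 1.5, pixel_noise_sigma = 0.05,
                                 solver = solver_options()) {
  noise_free <- acquisition_protocol(
    delay_step = protocol$delay_step, delay_min = protocol$delay_min,
    delay_max = protocol$delay_max, replicates = protocol$replicates,
    noise_sigma = 0, noise_floor = 0, seed = protocol$seed)
  ds <- generate_dataset(true_params, mat, ambient, noise_free, sample_id,
                         solver)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base_seed <- if (is.null(protocol$seed)) NULL else protocol$seed
  rows <- lapply(seq_len(nrow(ds)), function(i) {
    fr <- render_synthetic_frame(
      radius = ds$radius[i], um_per_px = um_per_px, frame_dim = frame_dim,
      blur_px = blur_px, noise_sigma = pixel_noise_sigma,
      seed = if (is.null(base_seed)) NULL else base_seed + i,
      delay = ds$time[i], replicate_id = ds$replicate_id[i],
      sample_id = sample_id)
    path <- file.path(dir, sprintf("frame_%03d.png", i))
    png::writePNG(fr$pixels, path)
    data.frame(path = path, delay_us = ds$time[i] * 1e6,
               replicate_id = ds$replicate_id[i], sample_id = sample_id,
               um_per_px = um_per_px)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
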