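# LiDAR scan simulator: beams traverse the canopy top-down, intercepted
# layer by layer under a Beer-Lambert model; survivors return soil points.

#' Scanner configuration
#'
#' @param beam_spacing spacing of the beam grid along and across track, m.
#' @param layer thickness of the interception layers, m.
#' @param extinction baseline extinction coefficient, 1/m per unit of
#'   green-area density; the per-layer interception probability is
#'   `1 - exp(-extinction * density * layer)`.
#' @param ground_fraction fraction of beams passing through between-row
#'   gaps straight to the soil.
#' @param z_noise_sd per-return vertical noise standard deviation, m
#'   (noise is truncated at three standard deviations so no return falls
#'   below terrain minus `3 * z_noise_sd`).
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(beam_spacing = 0.02, layer = 0.01, extinction = 0.55,
                        ground_fraction = 0.10, z_noise_sd = 0.003) {
  assert_scalar_num(beam_spacing, "beam_spacing", positive = TRUE)
  assert_scalar_num(layer, "layer", positive = TRUE)
  assert_scalar_num(extinction, "extinction", positive = TRUE)
  assert_scalar_num(ground_fraction, "ground_fraction", nonneg = TRUE)
  assert_scalar_num(z_noise_sd, "z_noise_sd", nonneg = TRUE)
  structure(list(beam_spacing = beam_spacing, layer = layer,
                 extinction = extinction, ground_fraction = ground_fraction,
                 z_noise_sd = z_noise_sd),
            class = "scan_config")
}

#' First-interception layer of a set of beams
#'
#' Sends `n_beams` beams through a stack of layers ordered top-down; beam
#' by layer, interception occurs with that layer's probability, and a beam
#' stops at its first interception. Uses the current RNG state.
#'
#' @param n_beams number of beams.
#' @param layer_probs per-layer interception probabilities, top first.
#' @return integer vector of length `n_beams`: the 1-based layer of first
#'   interception, or 0 for beams that pass through to the ground.
#' @export
simulate_interception <- function(n_beams, layer_probs) {
  stopifnot(n_beams >= 0, all(layer_probs >= 0), all(layer_probs <= 1))
  hit_layer <- integer(n_beams)
  alive <- rep(TRUE, n_beams)
  for (l in seq_along(layer_probs)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    hit <- stats::runif(length(idx)) < layer_probs[l]
    hit_layer[idx[hit]] <- l
    alive[idx[hit]] <- FALSE
  }
  hit_layer
}

#' Simulate a LiDAR scan of every plot in a trial
#'
#' For each plot, beams are laid out on a regular grid over the sampled
#' rectangle and traverse the canopy top-down in layers. Each layer
#' intercepts a beam with probability `1 - exp(-k * d * dz)`, where `k` is
#' the scanner's baseline extinction coefficient and `d` the plot's
#' green-area density per metre at the scan date (genotype canopy density
#' and the spatial field multiplier both enter through `d`). The first
#' interception produces a canopy return at that layer's height; beams that
#' pass through (plus a configurable between-row gap fraction) return soil
#' points at the plot's terrain elevation. Every beam yields exactly one
#' return.
#'
#' @param design a `trial_design`.
#' @param truth a `sim_truth` for that design.
#' @param date scan date (`Date` or coercible).
#' @param config a [scan_config()].
#' @param rng_seed integer seed.
#' @return a named list of [point_cloud] objects, one per plot, in design
#'   order; the scan date is attached as attribute `date`.
#' @export
simulate_scan <- function(design, truth, date, config = scan_config(),
                          rng_seed = NULL) {
  if (!inherits(design, "trial_design") || nrow(design) == 0) {
    stop_pheno("`design` must be a non-empty trial_design",
               "phenolidar_validation_error")
  }
  stopifnot(inherits(config, "scan_config"))
  date <- as.Date(date)
  state <- canopy_state(truth, design$genotype, date)
  log_mult <- truth$plots$log_mult[match(design$plot_id, truth$plots$plot_id)]
  terrain <- truth$plots$terrain_z[match(design$plot_id, truth$plots$plot_id)]

  with_seed_(rng_seed, {
    clouds <- vector("list", nrow(design))
    names(clouds) <- design$plot_id
    for (i in seq_len(nrow(design))) {
      rect <- design_rect(design, i)
      nbx <- max(1L, floor((rect$x_max - rect$x_min) / config$beam_spacing))
      nby <- max(1L, floor((rect$y_max - rect$y_min) / config$beam_spacing))
      bx <- rect$x_min + (seq_len(nbx) - 0.5) *
        (rect$x_max - rect$x_min) / nbx
      by <- rect$y_min + (seq_len(nby) - 0.5) *
        (rect$y_max - rect$y_min) / nby
      beams <- expand.grid(x = bx, y = by)
      n_beams <- nrow(beams)

      h <- state$height[i] * exp(0.5 * log_mult[i])
      gai <- state$gai[i] * exp(log_mult[i])
      n_layers <- if (h > config$layer && gai > 1e-8) {
        as.integer(ceiling(h / config$layer))
      } else 0L

      if (n_layers > 0) {
        # horizontal canopy cover grows with green area (young row crops
        # leave inter-row soil exposed); leaf area concentrates within the
        # covered fraction
        cover <- 1 - exp(-0.8 * gai)
        gap_p <- config$ground_fraction +
          (1 - config$ground_fraction) * (1 - cover)
        # two-zone vertical profile: 60% of the green area (leaves, ears)
        # in the top 35% of the canopy, the rest in the sparse stem zone
        n_top <- max(1L, ceiling(0.35 * n_layers))
        dens <- rep((0.4 * gai / cover) / (h * 0.65), n_layers)
        dens[seq_len(n_top)] <- (0.6 * gai / cover) / (h * 0.35)
        p_layer <- 1 - exp(-config$extinction * dens * config$layer)
        gap <- stats::runif(n_beams) < gap_p
        hit <- integer(n_beams)
        hit[!gap] <- simulate_interception(sum(!gap), p_layer)
      } else {
        hit <- integer(n_beams)
      }

      z <- numeric(n_beams)
      canopy <- hit > 0
      if (any(canopy)) {
        # return height uniform within the intercepting layer, from the top
        z[canopy] <- h - (hit[canopy] - stats::runif(sum(canopy))) *
          config$layer
        z[canopy] <- pmax(z[canopy], 0)
      }
      noise <- stats::rnorm(n_beams, 0, config$z_noise_sd)
      noise <- pmin(pmax(noise, -3 * config$z_noise_sd),
                    3 * config$z_noise_sd)
      z <- terrain[i] + z + noise
      clouds[[i]] <- point_cloud(beams$x, beams$y, z,
                                 beam_id = seq_len(n_beams))
    }
    attr(clouds, "date") <- date
    clouds
  })
}
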