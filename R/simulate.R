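# Synthetic DNA-PAINT myofibrils with known ground truth.
#
# The generator emulates what the reconstruction software hands to this
# pipeline: a localization table (positions in camera pixels, photon
# counts, PSF fit widths), a rectangular pick, and the geometry that
# produced them. Blinking kinetics are not simulated at frame level;
# localizations are drawn directly with the stated precision, since the
# analysis starts after reconstruction and frame indices are bookkeeping.

#' Describe one epitope of a simulated myofibril
#'
#' @param label Epitope label (e.g. `"Sls-Ig13/14"`).
#' @param offset_nm True half-distance of the epitope bands from each
#'   Z-disc (nm).
#' @param band_sigma_nm Axial spread of the epitope band (nm), default 12.
#' @param n_locs_per_band Localizations drawn per band (one side of one
#'   Z-disc), default 300.
#' @param channel_label Imaging channel of the epitope.
#' @param offset_jitter_nm Sarcomere-to-sarcomere SD of the realized
#'   half-distance (nm), default 4 — matches the few-nanometre
#'   per-sarcomere variability seen in flight-muscle data.
#' @return A `sim_epitope` list.
#' @export
sim_epitope <- function(label, offset_nm, band_sigma_nm = 12,
                        n_locs_per_band = 300, channel_label = "ch1",
                        offset_jitter_nm = 4) {
  if (!is_scalar_number(offset_nm) || offset_nm <= 0) {
    stopf("invalid simulation config: offset_nm must be > 0")
  }
  if (!is_scalar_number(band_sigma_nm) || band_sigma_nm < 0) {
    stopf("invalid simulation config: band_sigma_nm must be >= 0")
  }
  if (!is_scalar_number(n_locs_per_band) || n_locs_per_band < 1) {
    stopf("invalid simulation config: n_locs_per_band must be >= 1")
  }
  if (!is_scalar_number(offset_jitter_nm) || offset_jitter_nm < 0) {
    stopf("invalid simulation config: offset_jitter_nm must be >= 0")
  }
  structure(
    list(
      label = label, offset_nm = offset_nm, band_sigma_nm = band_sigma_nm,
      n_locs_per_band = as.integer(n_locs_per_band),
      channel_label = channel_label, offset_jitter_nm = offset_jitter_nm
    ),
    class = "sim_epitope"
  )
}

#' Configuration of a simulated myofibril
#'
#' Defaults reflect flight-muscle DNA-PAINT imaging: a 3.5 um sarcomere
#' lattice with mounting-induced period jitter, 5 nm localization
#' precision (within the 4-8 nm NeNA range of such acquisitions), a 130 nm
#' effective camera pixel, about 15,000 frames, and a single-emitter PSF
#' width near 1.0 px with a contaminating wide-fit population.
#'
#' @param n_sarcomeres Number of sarcomeres (Z-disc count is one more).
#' @param sarcomere_mean_nm Mean period (nm), default 3500.
#' @param sarcomere_sd_nm Period jitter SD (nm), default 100; must stay
#'   below a third of the period.
#' @param epitopes List of [sim_epitope()]; all must share one channel.
#' @param loc_precision_nm Isotropic localization SD added to every band
#'   draw (nm), default 5.
#' @param background_per_um Uniform background localizations per um of
#'   axis, default 17 (about 10% of one 300-localization band pair per
#'   3.5 um sarcomere).
#' @param outlier_frac Fraction of rows given inflated (sx, sy), default
#'   0.05.
#' @param pixel_size_nm Camera pixel pitch, default 130.
#' @param myofibril_angle_rad Myofibril orientation, default 0.3.
#' @param myofibril_width_nm Transverse spread scale (Gaussian SD is half
#'   of this), default 900.
#' @param n_frames Acquisition length in frames, default 15000.
#' @param seed Integer seed; the whole simulation is deterministic in it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sarcomeres = 30, sarcomere_mean_nm = 3500,
                       sarcomere_sd_nm = 100,
                       epitopes = list(sim_epitope("Sls-Ig51/Fn2", 98)),
                       loc_precision_nm = 5, background_per_um = 17,
                       outlier_frac = 0.05, pixel_size_nm = 130,
                       myofibril_angle_rad = 0.3, myofibril_width_nm = 900,
                       n_frames = 15000, seed = 0) {
  if (!is_scalar_number(n_sarcomeres) || n_sarcomeres < 1) {
    stopf("invalid simulation config: n_sarcomeres must be >= 1")
  }
  if (!is_scalar_number(sarcomere_sd_nm) || sarcomere_sd_nm < 0 ||
      sarcomere_sd_nm >= sarcomere_mean_nm / 3) {
    stopf("invalid simulation config: sarcomere_sd_nm must be in [0, period/3)")
  }
  if (!is.list(epitopes) || length(epitopes) == 0 ||
      !all(vapply(epitopes, inherits, logical(1), "sim_epitope"))) {
    stopf("invalid simulation config: epitopes must be a list of sim_epitope")
  }
  chs <- unique(vapply(epitopes, `[[`, character(1), "channel_label"))
  if (length(chs) != 1) {
    stopf(paste0(
      "invalid simulation config: all epitopes of one table must share a ",
      "channel_label (use simulate_two_colour for dual-channel data)"
    ))
  }
  if (!is_scalar_number(outlier_frac) || outlier_frac < 0 || outlier_frac > 1) {
    stopf("invalid simulation config: outlier_frac must be in [0, 1]")
  }
  if (!is_scalar_number(loc_precision_nm) || loc_precision_nm < 0) {
    stopf("invalid simulation config: loc_precision_nm must be >= 0")
  }
  if (!is_scalar_number(background_per_um) || background_per_um < 0) {
    stopf("invalid simulation config: background_per_um must be >= 0")
  }
  if (!is_scalar_number(n_frames) || n_frames < 1) {
    stopf("invalid simulation config: n_frames must be >= 1")
  }
  if (!is_scalar_number(pixel_size_nm) || pixel_size_nm <= 0) {
    stopf("invalid simulation config: pixel_size_nm must be > 0")
  }
  structure(
    list(
      n_sarcomeres = as.integer(n_sarcomeres),
      sarcomere_mean_nm = sarcomere_mean_nm,
      sarcomere_sd_nm = sarcomere_sd_nm,
      epitopes = epitopes,
      loc_precision_nm = loc_precision_nm,
      background_per_um = background_per_um,
      outlier_frac = outlier_frac,
      pixel_size_nm = pixel_size_nm,
      myofibril_angle_rad = myofibril_angle_rad,
      myofibril_width_nm = myofibril_width_nm,
      n_frames = as.integer(n_frames),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

SIM_MARGIN_NM <- 1000
SIM_PSF_WIDTH_PX <- 1.0
SIM_PSF_SD_PX <- 0.04

# Z-disc lattice, axis length, and scene placement; all randomness comes
# from `seed`.
sim_geometry <- function(config, seed) {
  with_seed(seed, {
    periods <- stats::rnorm(config$n_sarcomeres, config$sarcomere_mean_nm,
                            config$sarcomere_sd_nm)
    periods <- pmax(periods, config$sarcomere_mean_nm / 2)
    z_nm <- SIM_MARGIN_NM + c(0, cumsum(periods))
    list(
      z_nm = z_nm,
      axis_len_nm = 2 * SIM_MARGIN_NM + sum(periods),
      translate_nm = stats::runif(2, -2000, 2000)
    )
  })
}

# Draw the localizations of one channel on a fixed geometry.
sim_channel <- function(geom, config, seed) {
  with_seed(seed, {
    z <- geom$z_nm
    nz <- length(z)
    ax <- numeric(0)
    tag <- character(0)
    ep_label <- character(0)
    zdisc_id <- integer(0)
    side_v <- integer(0)
    realized <- list()
    for (e in config$epitopes) {
      r <- pmax(stats::rnorm(nz, e$offset_nm, e$offset_jitter_nm), 1)
      realized[[e$label]] <- r
      sd_ax <- sqrt(e$band_sigma_nm^2 + config$loc_precision_nm^2)
      for (side in c(-1L, 1L)) {
        centers <- z + side * r
        draws <- stats::rnorm(nz * e$n_locs_per_band,
                              mean = rep(centers, each = e$n_locs_per_band),
                              sd = sd_ax)
        ax <- c(ax, draws)
        tag <- c(tag, rep("band", length(draws)))
        ep_label <- c(ep_label, rep(e$label, length(draws)))
        zdisc_id <- c(zdisc_id, rep(seq_len(nz), each = e$n_locs_per_band))
        side_v <- c(side_v, rep(side, length(draws)))
      }
    }
    n_band <- length(ax)
    n_bg <- round(config$background_per_um * geom$axis_len_nm / 1000)
    if (n_bg > 0) {
      ax <- c(ax, stats::runif(n_bg, 0, geom$axis_len_nm))
      tag <- c(tag, rep("background", n_bg))
      ep_label <- c(ep_label, rep(NA_character_, n_bg))
      zdisc_id <- c(zdisc_id, rep(NA_integer_, n_bg))
      side_v <- c(side_v, rep(NA_integer_, n_bg))
    }
    n_out <- round(config$outlier_frac * (n_band + n_bg))
    if (n_out > 0) {
      ax <- c(ax, stats::runif(n_out, 0, geom$axis_len_nm))
      tag <- c(tag, rep("outlier", n_out))
      ep_label <- c(ep_label, rep(NA_character_, n_out))
      zdisc_id <- c(zdisc_id, rep(NA_integer_, n_out))
      side_v <- c(side_v, rep(NA_integer_, n_out))
    }
    n <- length(ax)
    tv <- stats::rnorm(n, 0, config$myofibril_width_nm / 2)
    sx <- pmax(stats::rnorm(n, SIM_PSF_WIDTH_PX, SIM_PSF_SD_PX), 0.2)
    sy <- pmax(stats::rnorm(n, SIM_PSF_WIDTH_PX, SIM_PSF_SD_PX), 0.2)
    if (n_out > 0) {
      oi <- which(tag == "outlier")
      sx[oi] <- sx[oi] + stats::runif(n_out, 0.3, 0.8)
      sy[oi] <- sy[oi] + stats::runif(n_out, 0.3, 0.8)
    }
    a <- config$myofibril_angle_rad
    u <- ax - geom$axis_len_nm / 2
    X <- (u * cos(a) - tv * sin(a) + geom$translate_nm[1]) /
      config$pixel_size_nm
    Y <- (u * sin(a) + tv * cos(a) + geom$translate_nm[2]) /
      config$pixel_size_nm
    locs <- loc_table(
      data.frame(
        frame = floor(stats::runif(n, 0, config$n_frames)),
        x = X, y = Y,
        photons = stats::rlnorm(n, log(5000), 0.3),
        sx = sx, sy = sy
      ),
      pixel_size_nm = config$pixel_size_nm,
      channel_label = config$epitopes[[1]]$channel_label
    )
    list(
      locs = locs,
      realized = realized,
      provenance = data.frame(
        tag = tag, epitope_label = ep_label,
        zdisc_id = zdisc_id, side = side_v
      )
    )
  })
}

sim_truth <- function(geom, config, channel_draw) {
  a <- config$myofibril_angle_rad
  na <- normalize_angle(a)
  flipped <- abs(cos(a - na) + 1) < 1e-9
  s <- if (flipped) -1 else 1
  list(
    zdisc_axis_nm = s * (geom$z_nm - geom$axis_len_nm / 2),
    axis_len_nm = geom$axis_len_nm,
    flipped = flipped,
    epitopes = data.frame(
      label = vapply(config$epitopes, `[[`, character(1), "label"),
      channel_label = vapply(config$epitopes, `[[`, character(1),
                             "channel_label"),
      offset_nm = vapply(config$epitopes, `[[`, numeric(1), "offset_nm")
    ),
    realized_offsets = channel_draw$realized,
    provenance = channel_draw$provenance
  )
}

sim_pick <- function(geom, config) {
  pick_region(
    center_x = geom$translate_nm[1] / config$pixel_size_nm,
    center_y = geom$translate_nm[2] / config$pixel_size_nm,
    length = geom$axis_len_nm / config$pixel_size_nm,
    width = 2 * config$myofibril_width_nm / config$pixel_size_nm,
    angle = config$myofibril_angle_rad
  )
}

#' Simulate one DNA-PAINT myofibril
#'
#' Places Z-discs sequentially with jittered spacing, draws two bands per
#' epitope and Z-disc at the (per-sarcomere realized) half-distance,
#' adds uniform axial background and a wide-fit outlier population, then
#' rotates and translates the whole scene and returns the matching pick.
#' `truth$zdisc_axis_nm` gives Z-disc positions in the pick-axis frame
#' (nm relative to the pick center, as produced by
#' [rotate_to_pick_axis()] + [project_profile()]), and
#' `truth$realized_offsets` the per-Z-disc true half-distances per epitope.
#'
#' @param config A [sim_config()].
#' @return List with `locs` ([loc_table()]), `pick` ([pick_region()]) and
#'   `truth`.
#' @export
simulate_myofibril <- function(config) {
  if (!inherits(config, "sim_config")) stopf("config must be a sim_config")
  geom <- sim_geometry(config, config$seed)
  draw <- sim_channel(geom, config, config$seed + 1L)
  list(
    locs = draw$locs,
    pick = sim_pick(geom, config),
    truth = sim_truth(geom, config, draw)
  )
}

#' Simulate a dual-colour acquisition of one myofibril
#'
#' With `shared_geometry = TRUE` (the default) both channels share the
#' Z-disc lattice, orientation and pick derived from `config_a`'s seed,
#' while band, background and outlier draws stay independent per channel —
#' the situation of a two-colour experiment on one myofibril. With the
#' flag unset, the two configs are simulated fully independently.
#'
#' @param config_a,config_b [sim_config()] for the two channels; pixel
#'   sizes must match, and (for shared geometry) the lattice parameters.
#' @param shared_geometry Share the Z-disc lattice between channels?
#' @return List with elements `a` and `b`, each like the return of
#'   [simulate_myofibril()]; under shared geometry both carry the same
#'   `pick` and Z-disc truth.
#' @export
simulate_two_colour <- function(config_a, config_b, shared_geometry = TRUE) {
  if (config_a$pixel_size_nm != config_b$pixel_size_nm) {
    stopf("pixel_size_nm mismatch between channels")
  }
  if (!shared_geometry) {
    return(list(a = simulate_myofibril(config_a),
                b = simulate_myofibril(config_b)))
  }
  for (field in c("n_sarcomeres", "sarcomere_mean_nm", "sarcomere_sd_nm",
                  "myofibril_angle_rad", "myofibril_width_nm")) {
    if (!identical(config_a[[field]], config_b[[field]])) {
      stopf("shared geometry requires equal %s in both configs", field)
    }
  }
  geom <- sim_geometry(config_a, config_a$seed)
  draw_a <- sim_channel(geom, config_a, config_a$seed + 1L)
  draw_b <- sim_channel(geom, config_b, config_b$seed + 2L)
  pick <- sim_pick(geom, config_a)
  list(
    a = list(locs = draw_a$locs, pick = pick,
             truth = sim_truth(geom, config_a, draw_a)),
    b = list(locs = draw_b$locs, pick = pick,
             truth = sim_truth(geom, config_b, draw_b))
  )
}
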