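#' Synthetic-data configuration
#'
#' Parameters of the seeded generators that emulate the study system: facial
#' patch reflectance spectra (a black stripe whose reflectance rises on
#' paling, white, blue and yellow patches), a trichromatic-plus-luminance
#' fish visual system, depth-attenuated ambient light, staged same-sex
#' contests in which losers pale, and mirror-image-stimulation trials in
#' which manipulated signals draw more and faster aggression. All defaults
#' are synthetic stand-ins chosen to be realistic for a littoral cichlid,
#' never measured values.
#'
#' @param seed integer seed used by every generator unless overridden.
#' @param ... named overrides of any default listed below.
#' @return object of class `synthetic_config` (a named list).
#' @details Defaults: black stripe reflectance 0.04 (dark) / 0.20 (pale)
#'   with a melanin-brown spectral tilt (reflectance rising with wavelength,
#'   slope 1.2 across the grid; paling scales the curve multiplicatively so
#'   the chromatic position is unchanged); white 0.80; blue a Gaussian band
#'   (peak 470 nm, width 40 nm, amplitude 0.60 over a 0.05 baseline); yellow
#'   a long-pass sigmoid (cutoff 540 nm, softness 30 nm, rising from 0.15 to
#'   0.45); smooth multiplicative noise sd 0.05, standing for measurement
#'   error plus between-individual variation together.
#'   Visual system: cone lambda-max 455/530/565 nm, relative densities
#'   1:2:2, noise parameter such that the long-wavelength cone has Weber
#'   fraction 0.05; luminance Weber fraction 0.05. Light: broadband surface
#'   irradiance, U-shaped attenuation with minimum near 490 nm, depth 10 m.
#'   Contests: 20 pairs, logistic size effect 2 per cm on winning, loser
#'   paling probability 0.9 vs winner 0.1, aggressive event rates 40
#'   (winner) / 15 (loser), submissive 5 / 25 per 20-min combat. Mirror
#'   trials: 48 fish, baseline 10 bouts, bout multipliers control 1.0,
#'   paled 1.5, darkened 2.6; latency baseline 120 s with multipliers
#'   1/1.2 (paled) and 1/1.7 (darkened); individual sd 0.3 and second-trial
#'   order effect -0.1 on the log scale; trial duration 600 s.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    grid = default_grid(),
    # spectra
    r_dark = 0.04, r_pale = 0.20, black_slope = 1.2, white_level = 0.80,
    blue_peak_nm = 470, blue_width_nm = 40, blue_amp = 0.60,
    yellow_cutoff_nm = 540, yellow_softness_nm = 30, yellow_level = 0.45,
    yellow_baseline = 0.15,
    baseline_reflectance = 0.05, noise_sd = 0.05,
    # visual system
    lambda_max = c(455, 530, 565), densities = c(1, 2, 2),
    nu = 0.05 * sqrt(2), luminance_weber = 0.05,
    # light environment
    depth_m = 10, surface_peak_nm = 560, surface_width_nm = 250,
    attenuation_min = 0.02, attenuation_curvature = 0.3,
    attenuation_center_nm = 490, attenuation_halfwidth_nm = 160,
    # contests
    n_pairs = 20, length_mean_cm = 6, length_sd_cm = 0.8,
    within_pair_sd_cm = 0.3, size_effect = 2,
    p_pale_loser = 0.9, p_pale_winner = 0.1,
    rate_aggressive_winner = 40, rate_aggressive_loser = 15,
    rate_submissive_winner = 5, rate_submissive_loser = 25,
    # mirror-image-stimulation trials
    n_fish = 48, baseline_bouts = 10,
    bout_multipliers = c(control = 1.0, paled = 1.5, darkened = 2.6),
    individual_sd = 0.3, order_effect = -0.1,
    latency_baseline_s = 120,
    latency_multipliers = c(control = 1.0, paled = 1 / 1.2,
                            darkened = 1 / 1.7),
    latency_sd_log = 0.4, trial_duration_s = 600)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  stopifnot(cfg$r_pale > cfg$r_dark, all(cfg$bout_multipliers > 0),
            cfg$p_pale_loser >= 0, cfg$p_pale_loser <= 1,
            cfg$p_pale_winner >= 0, cfg$p_pale_winner <= 1)
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

# smooth multiplicative noise curve: spline through a few random knots
smooth_noise <- function(grid, sd) {
  if (sd == 0) return(rep(0, length(grid)))
  knots <- seq(min(grid), max(grid), length.out = 6)
  z <- stats::rnorm(length(knots), 0, sd)
  stats::spline(knots, z, xout = grid)$y
}

#' Generate facial patch spectra for one fish
#'
#' Five reflectance spectra emulating the facial mask: flat-low black
#' stripes (the horizontal stripe pales — its reflectance rises — in
#' subordinate and manipulated-pale states, while the vertical stripe is
#' always dark), a flat-high white patch, a short-wavelength Gaussian blue
#' band, and a long-pass sigmoidal yellow. Optional smooth multiplicative
#' noise emulates measurement error.
#'
#' @param config a [synthetic_config].
#' @param fish_id fish label.
#' @param state signalling state (see [color_patch()]).
#' @param seed optional seed; when given the call is fully reproducible on
#'   its own, otherwise the ambient RNG stream is used.
#' @return list of 5 [color_patch] objects.
#' @export
gen_face_spectra <- function(config, fish_id, state, seed = NULL) {
  if (!state %in% PATCH_STATES)
    stop("unknown state '", state, "'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- config$grid
  pale <- state %in% c("subordinate", "manipulated_pale")
  r_h <- if (pale) config$r_pale else config$r_dark
  base <- config$baseline_reflectance
  ybase <- config$yellow_baseline
  # melanin reflectance rises with wavelength (brownish tint); paling scales
  # the whole curve multiplicatively, leaving chromatic position unchanged
  tilt <- 1 + config$black_slope * (g - 525) / 450
  shapes <- list(
    black_horizontal_stripe = r_h * tilt,
    black_vertical_stripe = config$r_dark * tilt,
    white = rep(config$white_level, length(g)),
    blue = base + config$blue_amp *
      exp(-((g - config$blue_peak_nm) / config$blue_width_nm)^2),
    yellow = ybase + (config$yellow_level - ybase) *
      stats::plogis((g - config$yellow_cutoff_nm) / config$yellow_softness_nm))
  lapply(names(shapes), function(lab) {
    v <- shapes[[lab]] * exp(smooth_noise(g, config$noise_sd))
    color_patch(fish_id, state, lab,
                spectrum(g, pmin(pmax(v, 0), 1), "reflectance"))
  })
}

#' Generate a synthetic visual system
#'
#' Trichromatic receptor set built from the A1 pigment nomogram at the
#' configured lambda-max values, with the default double-cone luminance
#' channel and Weber fractions derived from the noise parameter.
#'
#' @param config a [synthetic_config].
#' @return a [visual_system].
#' @export
gen_visual_system <- function(config) {
  lm <- config$lambda_max
  if (length(lm) < 2 || length(lm) > 4 || is.unsorted(lm, strictly = TRUE))
    stop("lambda_max must be 2-4 ascending values", call. = FALSE)
  recs <- lapply(seq_along(lm), function(i)
    receptor_class(paste0("cone", lm[i]),
                   pigment_template(lm[i], config$grid),
                   relative_density = config$densities[i]))
  visual_system(recs, noise_parameter = config$nu,
                luminance_weber = config$luminance_weber)
}

#' Generate a synthetic underwater light environment
#'
#' Broadband smooth surface irradiance and a U-shaped diffuse attenuation
#' coefficient with its minimum in the 450-550 nm window, so that the
#' ambient spectrum at depth peaks in the blue-green as in clear lake water.
#'
#' @param config a [synthetic_config].
#' @return a [light_environment] at `config$depth_m`.
#' @export
gen_light_environment <- function(config) {
  g <- config$grid
  i0 <- exp(-((g - config$surface_peak_nm) / config$surface_width_nm)^2)
  k <- config$attenuation_min + config$attenuation_curvature *
    ((g - config$attenuation_center_nm) / config$attenuation_halfwidth_nm)^2
  light_environment(spectrum(g, i0, "irradiance"),
                    spectrum(g, pmin(k, 1), "transmission"),
                    config$depth_m)
}

#' Generate a full conspicuousness dataset
#'
#' Patch spectra for `n_fish` fish, each measured in a single signalling
#' state (states are cycled across fish, so the default yields half dominant
#' winners and half subordinate losers, mirroring post-contest measurement),
#' with independent smooth measurement noise per patch.
#'
#' @param config a [synthetic_config].
#' @param n_fish number of fish.
#' @param states character vector of states cycled over fish; pass a single
#'   state for a one-state (e.g. dominant-only) dataset.
#' @param seed optional seed (defaults to `config$seed`).
#' @return list of [color_patch] objects.
#' @export
gen_conspicuousness_dataset <- function(config, n_fish = 20,
                                        states = c("dominant", "subordinate"),
                                        seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  state_of <- rep(states, length.out = n_fish)
  out <- list()
  for (i in seq_len(n_fish))
    out <- c(out, gen_face_spectra(config, sprintf("fish%02d", i),
                                   state_of[i]))
  out
}

#' Generate staged contests
#'
#' Same-sex dyads matched on standard length and mass (small within-pair
#' differences), with the contest outcome drawn from a logistic function of
#' the latent size/ability difference, behavior counts drawn at
#' winner-biased Poisson rates, and end-of-contest stripe state pale with
#' high probability for losers and low probability for winners. Both fish
#' start the contest dark-striped.
#'
#' @param config a [synthetic_config].
#' @param seed optional seed (defaults to `config$seed`).
#' @return dyad data frame, one row per fish (two per `pair_id`), with the
#'   columns required by [matching_test()], [outcome_lmm()] and
#'   [stripe_outcome_glmm()].
#' @export
gen_contests <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_pairs
  stopifnot(n >= 1)
  rows <- lapply(seq_len(n), function(p) {
    sex <- if (p %% 2 == 0) "F" else "M"
    base_len <- stats::rnorm(1, config$length_mean_cm, config$length_sd_cm)
    diff <- stats::rnorm(1, 0, config$within_pair_sd_cm)
    len <- base_len + c(diff / 2, -diff / 2)
    mass <- 0.015 * len^3 * exp(stats::rnorm(2, 0, 0.05))
    latent <- config$size_effect * (len - config$length_mean_cm) +
      stats::rnorm(2, 0, 1)
    p1_wins <- stats::rbinom(1, 1, stats::plogis(latent[1] - latent[2])) == 1
    winner <- c(p1_wins, !p1_wins)
    agg <- stats::rpois(2, ifelse(winner, config$rate_aggressive_winner,
                                  config$rate_aggressive_loser))
    sub <- stats::rpois(2, ifelse(winner, config$rate_submissive_winner,
                                  config$rate_submissive_loser))
    p_pale <- ifelse(winner, config$p_pale_winner, config$p_pale_loser)
    stripe_end <- ifelse(stats::runif(2) < p_pale, "pale", "dark")
    data.frame(pair_id = sprintf("pair%02d", p),
               fish_id = sprintf("pair%02d_f%d", p, 1:2),
               sex = sex, standard_length_cm = len, mass_g = mass,
               stripe_begin = "dark", stripe_end = stripe_end,
               aggressive_count = agg, submissive_count = sub,
               winner = winner, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a behavior event stream
#'
#' Time-sorted ethogram events for a set of fish over a contest of given
#' duration, with per-fish aggressive and submissive Poisson rates; used to
#' exercise [score_ethogram()].
#'
#' @param fish_ids fish labels.
#' @param aggressive_rate,submissive_rate expected event counts per fish
#'   over the contest (recycled).
#' @param duration_s contest duration (default 1200 s, a 20-min combat).
#' @param seed optional seed.
#' @return event data frame (`time_s`, `actor_id`, `behavior_code`), sorted
#'   by time.
#' @export
gen_behavior_events <- function(fish_ids, aggressive_rate = 20,
                                submissive_rate = 10, duration_s = 1200,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eth <- default_ethogram()
  agg_codes <- eth$behavior_code[eth$valence == "aggressive"]
  sub_codes <- eth$behavior_code[eth$valence == "submissive"]
  neu_codes <- eth$behavior_code[eth$valence == "neutral"]
  aggressive_rate <- rep_len(aggressive_rate, length(fish_ids))
  submissive_rate <- rep_len(submissive_rate, length(fish_ids))
  rows <- lapply(seq_along(fish_ids), function(i) {
    n_a <- stats::rpois(1, aggressive_rate[i])
    n_s <- stats::rpois(1, submissive_rate[i])
    n_n <- stats::rpois(1, 5)
    data.frame(
      time_s = stats::runif(n_a + n_s + n_n, 0, duration_s),
      actor_id = fish_ids[i],
      behavior_code = c(sample(agg_codes, n_a, TRUE),
                        sample(sub_codes, n_s, TRUE),
                        sample(neu_codes, n_n, TRUE)),
      stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$time_s), ]
}

#' Generate mirror-image-stimulation trials
#'
#' Each fish is assigned two of the three treatments uniformly at random
#' (without replacement) in randomized order. Aggressive bouts follow a
#' Poisson-lognormal model — log mean = log(baseline) + log(treatment
#' multiplier) + individual effect + order effect — which produces the
#' overdispersion that motivates the square-root transform downstream.
#' Latency to attack is lognormal with treatment multipliers; latencies
#' exceeding the trial duration are censored at it.
#'
#' @param config a [synthetic_config].
#' @param seed optional seed (defaults to `config$seed`).
#' @return MIS trial data frame (see [validate_mis_trials()]).
#' @export
gen_mis_trials <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_fish
  stopifnot(n >= 3)
  trts <- c("control", "paled", "darkened")
  rows <- lapply(seq_len(n), function(i) {
    fish <- sprintf("fish%03d", i)
    sex <- if (i %% 2 == 0) "F" else "M"
    my_trts <- sample(trts, 2)
    indiv <- stats::rnorm(1, 0, config$individual_sd)
    lapply(1:2, function(ord) {
      trt <- my_trts[ord]
      lmu <- log(config$baseline_bouts) + log(config$bout_multipliers[trt]) +
        indiv + if (ord == 2) config$order_effect else 0
      bouts <- stats::rpois(1, exp(lmu))
      lat <- exp(log(config$latency_baseline_s *
                       config$latency_multipliers[trt]) +
                   stats::rnorm(1, 0, config$latency_sd_log))
      censored <- lat > config$trial_duration_s
      data.frame(fish_id = fish, sex = sex, treatment = trt,
                 order_index = ord, aggressive_bouts = bouts,
                 latency_s = if (censored) config$trial_duration_s else lat,
                 censored = censored, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}
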