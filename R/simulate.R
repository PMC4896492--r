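#' Configuration for the synthetic icEEG generator
#'
#' Defaults emulate the grouped subdural-electrode study design: 1000 Hz
#' sampling, five stimulus categories with post-artifact-rejection trial
#' counts (face 46, animate 31, place 49, tool 29, word 38), epochs spanning
#' -1 to +2 s around stimulus onset, a -700 to -200 ms baseline, and
#' category-dependent gamma-band (60-120 Hz) amplitude gains that vary
#' smoothly with electrode coordinate plus a multiplicative subject-level
#' random modulation.
#'
#' @param n_subjects Number of subjects.
#' @param electrodes_per_subject Electrode count per subject (scalar, or
#'   length-2 range sampled uniformly per subject).
#' @param sampling_rate_hz Sampling rate, 1000 or 2000 Hz.
#' @param categories Ordered character vector of stimulus categories.
#' @param trials_per_category Trials per category (scalar or named per
#'   category), all >= 2.
#' @param epoch_window_s Epoch `c(start, end)` in seconds relative to stimulus
#'   onset.
#' @param baseline_window_s Baseline window (s), strictly pre-stimulus.
#' @param gamma_band_hz Gamma band edges (Hz) of the injected carrier.
#' @param selectivity_effect Named list per category: `list(base =, slope =)`.
#'   The injected amplitude gain of electrode e for category c is
#'   `max(0, (base_c + slope_c * grad_e) * subject_modulation)`, where
#'   `grad_e` is the electrode's mean-centered gradient coordinate (lateral
#'   position in VTC, ventral position in LOC, mm). Set all entries to 0 for a
#'   global-null dataset.
#' @param noise_model List: `pink_exponent` (power-law exponent alpha of the
#'   1/f^alpha background), `pink_sd`, `white_sd` (microvolts), `line_hz` and
#'   `line_amplitude` (optional mains component), `gamma_sd` (SD of the
#'   band-limited carrier that receives the category gain), and optional
#'   `tone_hz`/`tone_amplitude` (pure in-band tone receiving the same gain,
#'   used for closed-form checks).
#' @param coordinate_model List with `vtc_fraction` (share of electrodes in
#'   VTC) and per-region ranges; z is generated collinear with the lateral
#'   coordinate in VTC and x collinear with y in LOC, mimicking grid geometry.
#' @param onset_s Time (s, >= 0) at which the category gain switches on.
#' @param ramp_s Linear ramp duration (s) of the gain onset.
#' @param subject_sd SD of the multiplicative subject modulation
#'   `1 + N(0, subject_sd)` (floored at 0.1).
#' @param seed Integer seed; electrode k is generated under substream
#'   `seed + k` so electrode subsets are reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 6,
                       electrodes_per_subject = 8,
                       sampling_rate_hz = 1000,
                       categories = c("face", "animate", "place", "tool", "word"),
                       trials_per_category = c(face = 46, animate = 31,
                                               place = 49, tool = 29, word = 38),
                       epoch_window_s = c(-1, 2),
                       baseline_window_s = c(-0.7, -0.2),
                       gamma_band_hz = c(60, 120),
                       selectivity_effect = list(
                         face = list(base = 0.9, slope = 0.020),
                         animate = list(base = 0.5, slope = 0.010),
                         place = list(base = 0.9, slope = -0.020),
                         tool = list(base = 0.5, slope = -0.010),
                         word = list(base = 0.6, slope = 0.015)
                       ),
                       noise_model = list(pink_exponent = 2, pink_sd = 20,
                                          white_sd = 5, line_hz = 60,
                                          line_amplitude = 0, gamma_sd = 5,
                                          tone_hz = NULL, tone_amplitude = 0),
                       coordinate_model = list(
                         vtc_fraction = 0.65,
                         VTC = list(lat_range = c(25, 60), y_range = c(-75, -30),
                                    z_coef = c(-30, 0.45), z_noise = 1.5),
                         LOC = list(z_range = c(-12, 25), y_range = c(-95, -60),
                                    lat_coef = c(90, 0.55), lat_noise = 2)
                       ),
                       onset_s = 0.2,
                       ramp_s = 0.05,
                       subject_sd = 0.3,
                       seed = 1) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!cfg$sampling_rate_hz %in% c(1000, 2000)) {
    abort("`sampling_rate_hz` must be 1000 or 2000.")
  }
  if (cfg$epoch_window_s[1] >= cfg$epoch_window_s[2]) {
    abort("Invalid `epoch_window_s`: start must precede end.")
  }
  if (cfg$baseline_window_s[1] >= cfg$baseline_window_s[2] ||
      cfg$baseline_window_s[2] > 0) {
    abort("`baseline_window_s` must be increasing and strictly pre-stimulus.")
  }
  if (cfg$baseline_window_s[1] < cfg$epoch_window_s[1]) {
    abort("`baseline_window_s` must lie inside `epoch_window_s`.")
  }
  tpc <- expand_trials(cfg$trials_per_category, cfg$categories)
  if (any(tpc < 2)) abort("`trials_per_category` must be >= 2 for every category.")
  if (cfg$onset_s < 0) abort("`onset_s` must be >= 0 (no pre-stimulus modulation).")
  if (cfg$n_subjects < 1) abort("`n_subjects` must be positive.")
  missing_eff <- setdiff(cfg$categories, names(cfg$selectivity_effect))
  if (length(missing_eff)) {
    abort(paste("`selectivity_effect` missing categories:",
                paste(missing_eff, collapse = ", ")))
  }
  invisible(cfg)
}

expand_trials <- function(tpc, categories) {
  if (length(tpc) == 1) tpc <- setNames(rep(tpc, length(categories)), categories)
  if (is.null(names(tpc))) names(tpc) <- categories
  tpc[categories]
}

#' Simulate a multi-subject icEEG dataset with known ground truth
#'
#' Generates per-electrode trial epochs (1/f^alpha background + white noise +
#' optional mains tone + a band-limited gamma carrier whose post-stimulus
#' amplitude is multiplied by `1 + gain`, ramping over `ramp_s` at `onset_s`),
#' electrode geometry in Talairach-like coordinates, and a ground-truth table
#' of injected effects.
#'
#' @param config A [sim_config()].
#' @return A list of class `gamma_dataset`: `epochs` (tibble with `subject`,
#'   `electrode`, `region`, `hemisphere` and a `data` list-column of
#'   [epoch_set()] objects), `geometry`, `ground_truth`, `config`.
#' @examples
#' ds <- simulate_dataset(sim_config(n_subjects = 1, electrodes_per_subject = 2,
#'                                   trials_per_category = 4))
#' ds$geometry
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  layout <- withr::with_seed(config$seed, sim_layout(config))
  geometry <- layout$geometry
  truth <- layout$truth
  time <- epoch_time_axis(config)
  rows <- vector("list", nrow(geometry))
  for (k in seq_len(nrow(geometry))) {
    g <- geometry[k, ]
    gains <- truth$effect[truth$electrode == g$electrode]
    names(gains) <- truth$category[truth$electrode == g$electrode]
    ep <- withr::with_seed(
      (config$seed + k) %% .Machine$integer.max,
      sim_electrode_epochs(config, time, gains, g$electrode, g$subject)
    )
    rows[[k]] <- tibble(
      subject = g$subject, electrode = g$electrode,
      region = g$region, hemisphere = g$hemisphere, data = list(ep)
    )
  }
  structure(
    list(epochs = list_rbind(rows), geometry = geometry,
         ground_truth = truth, config = config),
    class = "gamma_dataset"
  )
}

#' @export
print.gamma_dataset <- function(x, ...) {
  cat(sprintf(
    "<gamma_dataset> %d subjects, %d electrodes, %d categories @ %g Hz (seed %d)\n",
    length(unique(x$geometry$subject)), nrow(x$geometry),
    length(x$config$categories), x$config$sampling_rate_hz, x$config$seed
  ))
  invisible(x)
}

epoch_time_axis <- function(config) {
  fs <- config$sampling_rate_hz
  w <- config$epoch_window_s
  seq(round(w[1] * fs), round(w[2] * fs)) / fs
}

# geometry, subject modulation and ground-truth effects (run under the global
# seed substream)
sim_layout <- function(config) {
  n_sub <- config$n_subjects
  n_left <- ceiling(0.6 * n_sub) # mirrors the 16:10 left:right cohort split
  subjects <- tibble(
    subject = sprintf("S%02d", seq_len(n_sub)),
    hemisphere = rep(c("L", "R"), c(n_left, n_sub - n_left)),
    modulation = pmax(0.1, 1 + rnorm(n_sub, 0, config$subject_sd))
  )
  eps <- config$electrodes_per_subject
  n_el <- if (length(eps) == 2) {
    sample(seq(eps[1], eps[2]), n_sub, replace = TRUE)
  } else {
    rep(eps, n_sub)
  }
  cm <- config$coordinate_model
  rows <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    n <- n_el[s]
    n_vtc <- round(cm$vtc_fraction * n)
    region <- rep(c("VTC", "LOC"), c(n_vtc, n - n_vtc))
    hemi <- subjects$hemisphere[s]
    sgn <- if (hemi == "L") -1 else 1
    lat <- y <- z <- numeric(n)
    is_vtc <- region == "VTC"
    if (any(is_vtc)) {
      m <- cm$VTC
      lat[is_vtc] <- runif(sum(is_vtc), m$lat_range[1], m$lat_range[2])
      y[is_vtc] <- runif(sum(is_vtc), m$y_range[1], m$y_range[2])
      z[is_vtc] <- m$z_coef[1] + m$z_coef[2] * lat[is_vtc] +
        rnorm(sum(is_vtc), 0, m$z_noise)
    }
    if (any(!is_vtc)) {
      m <- cm$LOC
      z[!is_vtc] <- runif(sum(!is_vtc), m$z_range[1], m$z_range[2])
      y[!is_vtc] <- runif(sum(!is_vtc), m$y_range[1], m$y_range[2])
      lat[!is_vtc] <- m$lat_coef[1] + m$lat_coef[2] * y[!is_vtc] +
        rnorm(sum(!is_vtc), 0, m$lat_noise)
    }
    rows[[s]] <- tibble(
      subject = subjects$subject[s],
      electrode = sprintf("%s_e%02d", subjects$subject[s], seq_len(n)),
      hemisphere = hemi, region = region,
      x = sgn * lat, y = y, z = z,
      gradient = ifelse(region == "VTC", lat, -z) # lateral / ventral position
    )
  }
  geometry <- list_rbind(rows) |>
    group_by(.data$region, .data$hemisphere) |>
    mutate(gradient_centered = .data$gradient - mean(.data$gradient)) |>
    ungroup()
  truth <- tidyr::crossing(
    geometry |>
      select("electrode", "subject", "region", "hemisphere", "gradient_centered"),
    category = config$categories
  ) |>
    left_join(subjects |> select("subject", "modulation"), by = "subject") |>
    mutate(
      base = map_dbl(.data$category, ~ config$selectivity_effect[[.x]]$base),
      slope = map_dbl(.data$category, ~ config$selectivity_effect[[.x]]$slope),
      effect = pmax(0, (.data$base + .data$slope * .data$gradient_centered) *
                      .data$modulation),
      selective = .data$effect > 0,
      onset_s = config$onset_s
    ) |>
    select("electrode", "subject", "region", "hemisphere", "category",
           "effect", "selective", "onset_s", "slope",
           subject_modulation = "modulation")
  list(geometry = geometry |> select(-"gradient", -"gradient_centered"),
       truth = truth)
}

# epochs for one electrode, under the electrode's own RNG substream
sim_electrode_epochs <- function(config, time, gains, electrode, subject) {
  fs <- config$sampling_rate_hz
  n_samples <- length(time)
  nm <- config$noise_model
  tpc <- expand_trials(config$trials_per_category, config$categories)
  labels <- rep(config$categories, times = tpc)
  n_trials <- length(labels)
  env <- gain_envelope(time, config$onset_s, config$ramp_s)
  v <- matrix(0, n_trials, n_samples)
  for (i in seq_len(n_trials)) {
    g <- gains[[labels[i]]]
    trial_env <- 1 + g * env
    x <- pink_noise(n_samples, fs, nm$pink_exponent) * nm$pink_sd +
      rnorm(n_samples, 0, nm$white_sd) +
      band_noise(n_samples, fs, config$gamma_band_hz) * nm$gamma_sd * trial_env
    if (!is.null(nm$line_amplitude) && nm$line_amplitude > 0) {
      x <- x + nm$line_amplitude * sin(2 * pi * nm$line_hz * time + runif(1, 0, 2 * pi))
    }
    if (!is.null(nm$tone_hz) && !is.null(nm$tone_amplitude) && nm$tone_amplitude > 0) {
      x <- x + nm$tone_amplitude * sin(2 * pi * nm$tone_hz * time) * trial_env
    }
    v[i, ] <- x
  }
  epoch_set(v, fs, category = labels, time = time,
            electrode = electrode, subject = subject)
}

# linear 0 -> 1 ramp starting at onset, flat afterwards; 0 pre-stimulus
gain_envelope <- function(time, onset_s, ramp_s) {
  if (ramp_s <= 0) return(as.numeric(time >= onset_s))
  pmin(1, pmax(0, (time - onset_s) / ramp_s))
}

# Fourier-synthesized 1/f^alpha noise, unit SD
pink_noise <- function(n, fs, alpha = 2) {
  spectrum_noise(n, fs, function(f) f^(-alpha / 2))
}

# band-limited white noise (ideal FFT brick-wall), unit SD
band_noise <- function(n, fs, band) {
  spectrum_noise(n, fs, function(f) as.numeric(f >= band[1] & f <= band[2]))
}

spectrum_noise <- function(n_out, fs, shape) {
  # synthesize at a 5-smooth length >= n_out (fast FFT), keep the first n_out
  # samples of the stationary circular series
  n <- stats::nextn(n_out, c(2, 3, 5))
  half <- floor(n / 2)
  f <- seq_len(half) * fs / n
  amp <- shape(f)
  phase <- runif(half, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- spec
  if (n %% 2 == 0) {
    full[half + 1] <- complex(real = amp[half] * cos(phase[half]))
    full[seq(n, half + 2)] <- Conj(full[2:half])
  } else {
    full[seq(n, half + 2)] <- Conj(full[2:(half + 1)])
  }
  x <- (Re(fft(full, inverse = TRUE)) / n)[seq_len(n_out)]
  s <- sd(x)
  if (s == 0) x else (x - mean(x)) / s
}
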