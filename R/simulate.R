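# All randomness is routed through derived integer seeds so a cohort is
# a pure function of one user-facing seed; the session RNG state is
# saved and restored around every draw.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed mixing for sub-streams.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (sum(utf8ToInt(as.character(p))) + 13)) %% 2147483647
  }
  as.integer(h)
}

#' Synthetic subject profile
#'
#' Per-subject kinematic parameters for the signal generator. Each
#' subject gets their own bounce frequency, overall amplitude, arm-swing
#' strength, left/right asymmetry, sensor noise level and a wrist-tilt
#' angle (a rotation in the x-z plane emulating watch orientation
#' differences). The spread of these draws is what makes
#' leave-one-subject-out evaluation genuinely harder than a random
#' split.
#'
#' @param subject_id character scalar.
#' @param rng_seed integer; all draws are reproducible from it.
#' @param ... optional overrides for any drawn field
#'   (`bounce_freq_hz`, `amplitude_scale`, `arm_swing_gain`,
#'   `asymmetry_gain`, `noise_sd_g`, `tilt_rad`, `h2`, `h3`).
#' @return list of class `"har_subject_profile"`.
#' @export
subject_profile <- function(subject_id, rng_seed, ...) {
  drawn <- with_seed(derive_seed(rng_seed, "profile", subject_id), {
    list(
      bounce_freq_hz = stats::runif(1, 1.2, 2.6),
      amplitude_scale = stats::runif(1, 0.7, 1.3),
      arm_swing_gain = stats::runif(1, 0.2, 0.9),
      asymmetry_gain = stats::runif(1, 0.4, 0.9),
      noise_sd_g = stats::runif(1, 0.03, 0.08),
      tilt_rad = stats::runif(1, -0.26, 0.26),
      h2 = stats::runif(1, 0.25, 0.5),
      h3 = stats::runif(1, 0.08, 0.22))
  })
  over <- list(...)
  bad <- setdiff(names(over), names(drawn))
  if (length(bad) > 0) stop("unknown profile field(s): ",
                            paste(bad, collapse = ", "))
  drawn[names(over)] <- over
  structure(c(list(subject_id = as.character(subject_id),
                   rng_seed = as.integer(rng_seed)), drawn),
            class = "har_subject_profile")
}

#' Class signal specifications
#'
#' The per-motion signal model used by the generator. Amplitudes encode
#' the intended intensity ordering (standing < walking < jumps, two-leg
#' jump largest); marching alternates sides every bounce cycle
#' (sub-harmonic lateral energy), one-leg jumps are fixed-sided with
#' opposite lateral sign, so left and right jumps are exact mirror
#' images and deliberately the most confusable pair.
#'
#' @return named list (one entry per motion code) of class-signal specs
#'   with fields `label`, `vertical_amp_g`, `freq_factor`, `periodic`,
#'   `alternation`, `baseline_offset_g`.
#' @export
class_signal_specs <- function() {
  spec <- function(label, amp, ff, periodic, alternation)
    list(label = label, vertical_amp_g = amp, freq_factor = ff,
         periodic = periodic, alternation = alternation,
         baseline_offset_g = c(0, 0, -1))
  list(
    ST = spec("ST", 0.02, 1.0, FALSE, "none"),
    WL = spec("WL", 0.15, 0.6, TRUE, "none"),
    MR = spec("MR", 0.55, 1.0, TRUE, "left-right"),
    TJ = spec("TJ", 1.20, 1.0, TRUE, "none"),
    LJ = spec("LJ", 0.80, 1.0, TRUE, "left-only"),
    RJ = spec("RJ", 0.80, 1.0, TRUE, "right-only"))
}

#' Generate one synthetic recording
#'
#' Builds a 3-axis wrist acceleration bout for one (subject, set,
#' motion): gravity offset, a bounce carrier at the subject's bounce
#' frequency with two harmonics, an arm-swing sinusoid at half the
#' carrier, class-specific lateral structure (alternating sub-harmonic
#' for marching, fixed-sided offset for one-leg jumps, slow quasi-
#' periodic pattern for walking, pure noise about gravity for
#' standing), a per-subject wrist tilt, and white Gaussian sensor
#' noise. Identical arguments always reproduce identical samples.
#'
#' @param profile a [subject_profile()].
#' @param spec one entry of [class_signal_specs()].
#' @param duration_s duration in seconds (study protocol: 10).
#' @param rate_hz sampling rate (study protocol: 100).
#' @param set_index set number; part of the derived random stream, so
#'   different sets of the same subject differ in phase and jitter.
#' @return A [recording()].
#' @export
generate_recording <- function(profile, spec, duration_s = 10,
                               rate_hz = 100, set_index = 1L) {
  stopifnot(inherits(profile, "har_subject_profile"),
            duration_s > 0, rate_hz > 0)
  n <- as.integer(round(duration_s * rate_hz))
  tt <- (seq_len(n) - 1L) / rate_hz
  # the two one-leg classes share one stream: with identical seeds the
  # right jump is the exact lateral mirror of the left jump
  stream <- if (spec$alternation %in% c("left-only", "right-only"))
    "oneleg" else spec$label
  seed <- derive_seed(profile$rng_seed, "rec", set_index, stream)
  sig <- with_seed(seed, {
    amp <- spec$vertical_amp_g * profile$amplitude_scale
    f <- profile$bounce_freq_hz * spec$freq_factor *
      (1 + stats::rnorm(1, 0, 0.01))
    phi <- stats::runif(1, 0, 2 * pi)
    x <- numeric(n); y <- numeric(n); z <- numeric(n)
    if (spec$periodic) {
      ph <- 2 * pi * f * tt + phi
      if (spec$label == "WL") {
        # quasi-periodic: slow phase drift, single weak harmonic
        ph <- ph + cumsum(stats::rnorm(n, 0, 0.05))
        z <- amp * (sin(ph) + 0.3 * sin(2 * ph + 0.7))
      } else {
        z <- amp * (sin(ph) + profile$h2 * sin(2 * ph + 0.9) +
                      profile$h3 * sin(3 * ph + 1.7))
      }
      # arm swing at half the carrier
      x <- profile$arm_swing_gain * amp * 0.5 *
        sin(pi * f * tt + phi / 2)
      y <- 0.08 * amp * sin(ph + 1.1)
      if (spec$alternation == "left-right") {
        # side switches every bounce cycle: sub-harmonic at f/2
        y <- y + profile$asymmetry_gain * amp * 0.5 *
          sin(pi * f * tt + phi)
        z <- z * (1 + 0.3 * profile$asymmetry_gain *
                    sin(pi * f * tt + phi))
      } else if (spec$alternation %in% c("left-only", "right-only")) {
        # fixed side: lateral offset pulsing at the carrier, one sign
        y <- y + profile$asymmetry_gain * amp *
          (0.25 + 0.25 * sin(ph + 0.4))
        x <- x + 0.1 * profile$asymmetry_gain * amp * sin(ph + 2.3)
      }
    }
    base <- spec$baseline_offset_g
    x <- x + base[1]; y <- y + base[2]; z <- z + base[3]
    # wrist tilt: rotation in the x-z plane (commutes with the
    # lateral mirror, keeping LJ/RJ exact mirror images)
    ct <- cos(profile$tilt_rad); st <- sin(profile$tilt_rad)
    xr <- ct * x + st * z
    zr <- -st * x + ct * z
    x <- xr; z <- zr
    if (profile$noise_sd_g > 0) {
      x <- x + stats::rnorm(n, 0, profile$noise_sd_g)
      y <- y + stats::rnorm(n, 0, profile$noise_sd_g)
      z <- z + stats::rnorm(n, 0, profile$noise_sd_g)
    }
    if (spec$alternation == "right-only") y <- -y
    list(x = x, y = y, z = z)
  })
  recording(data.frame(t = tt, x = sig$x, y = sig$y, z = sig$z),
            subject_id = profile$subject_id, set_index = set_index,
            label = spec$label, sample_rate_hz = rate_hz)
}

#' Generate a labeled multi-subject cohort
#'
#' Emulates the study protocol: each subject performs the six motions
#' in order ST, WL, MR, TJ, LJ, RJ for `duration_s` seconds, repeated
#' over `n_sets` sets. Defaults are the protocol values: 8 subjects,
#' 5 sets, 10 s at 100 Hz (240 recordings). The whole cohort is a pure
#' function of `seed`.
#'
#' @param n_subjects number of subjects (>= 2); ids are A, B, C, ...
#' @param n_sets sets per subject.
#' @param seed integer master seed.
#' @param out_dir if non-NULL, sensor-log CSVs plus `manifest.csv` are
#'   written there (refused if the directory already contains files and
#'   `overwrite` is FALSE).
#' @param duration_s,rate_hz recording duration and sampling rate.
#' @param overwrite allow writing into a non-empty directory.
#' @return list of class `"har_cohort"`: `recordings` (list of
#'   [recording()]), `manifest` (data.frame), `profiles`.
#' @export
generate_cohort <- function(n_subjects = 8, n_sets = 5, seed = 1,
                            out_dir = NULL, duration_s = 10,
                            rate_hz = 100, overwrite = FALSE) {
  stopifnot(n_subjects >= 2, n_sets >= 1)
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 &&
        !overwrite) {
      stop("output directory ", out_dir,
           " is not empty; use overwrite = TRUE")
    }
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  ids <- make.unique(rep(LETTERS, length.out = n_subjects), sep = "")
  specs <- class_signal_specs()
  profiles <- lapply(seq_len(n_subjects), function(i) {
    subject_profile(ids[i], derive_seed(seed, "subject", i))
  })
  names(profiles) <- ids
  recordings <- list()
  rows <- list()
  k <- 0L
  for (p in profiles) {
    for (s in seq_len(n_sets)) {
      for (lab in motion_labels()) {
        k <- k + 1L
        rec <- generate_recording(p, specs[[lab]], duration_s, rate_hz,
                                  set_index = s)
        recordings[[k]] <- rec
        fp <- sprintf("subj%s_set%d_%s.csv", p$subject_id, s, lab)
        rows[[k]] <- data.frame(file_path = fp,
                                subject_id = p$subject_id,
                                set_index = s, label = lab,
                                sample_rate_hz = rate_hz,
                                stringsAsFactors = FALSE)
        if (!is.null(out_dir)) {
          write_recording(rec, file.path(out_dir, fp))
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    attr(manifest, "manifest_dir") <- normalizePath(out_dir)
  }
  structure(list(recordings = recordings, manifest = manifest,
                 profiles = profiles, seed = seed),
            class = "har_cohort")
}

#' @export
print.har_cohort <- function(x, ...) {
  cat(sprintf("<har_cohort> %d subjects x %d sets x 6 motions = %d recordings (seed %s)\n",
              length(x$profiles),
              max(x$manifest$set_index), length(x$recordings),
              format(x$seed)))
  invisible(x)
}

#' Segment every recording of a cohort into one window set
#'
#' @param cohort a `"har_cohort"` (or a list of recordings).
#' @param config a [windowing_config()].
#' @return A `"har_window_set"` over all recordings.
#' @export
cohort_windows <- function(cohort, config = windowing_config()) {
  recs <- if (inherits(cohort, "har_cohort")) cohort$recordings else cohort
  bind_window_sets(lapply(recs, segment_recording, config = config))
}
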