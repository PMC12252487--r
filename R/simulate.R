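#' Paced-breathing protocol
#'
#' Describes one guided breathing cycle as four segments: inhalation, a pause
#' at the end of inhalation, exhalation, and a pause at the end of exhalation.
#' The default 6/2/6/1 s cycle lasts 15 s, i.e. 4 breaths per minute, the slow
#' pacing used to elicit respiratory sinus arrhythmia in the low-frequency
#' band.
#'
#' @param inhale_s,post_inhale_pause_s,exhale_s,post_exhale_pause_s segment
#'   durations in seconds, all non-negative, summing to a positive cycle.
#' @return An object of class `breathing_protocol` with the four segments plus
#'   derived `cycle_s` and `breaths_per_min`.
#' @examples
#' p <- breathing_protocol()
#' p$cycle_s           # 15
#' p$breaths_per_min   # 4
#' @export
breathing_protocol <- function(inhale_s = 6, post_inhale_pause_s = 2,
                               exhale_s = 6, post_exhale_pause_s = 1) {
  segs <- c(inhale_s, post_inhale_pause_s, exhale_s, post_exhale_pause_s)
  if (anyNA(segs) || any(segs < 0)) stop_frphrv("protocol durations must be >= 0")
  cycle <- sum(segs)
  if (cycle <= 0) stop_frphrv("breathing cycle must have positive duration")
  structure(list(inhale_s = inhale_s,
                 post_inhale_pause_s = post_inhale_pause_s,
                 exhale_s = exhale_s,
                 post_exhale_pause_s = post_exhale_pause_s,
                 cycle_s = cycle,
                 breaths_per_min = 60 / cycle),
            class = "breathing_protocol")
}

#' @export
print.breathing_protocol <- function(x, ...) {
  cat(sprintf("Breathing protocol %g/%g/%g/%g s: cycle %g s, %.2g breaths/min\n",
              x$inhale_s, x$post_inhale_pause_s, x$exhale_s,
              x$post_exhale_pause_s, x$cycle_s, x$breaths_per_min))
  invisible(x)
}

#' RR simulator parameters
#'
#' Parameters of the additive-sinusoid RR model used by [simulate_rr()]:
#' a baseline interval modulated by respiratory sinus arrhythmia (RSA) at the
#' breathing frequency, a 0.1 Hz Mayer-wave component, and white beat-level
#' noise. The no-nonphysical-interval guard requires
#' `rsa_amp_ms + mayer_amp_ms + 4 * noise_sd_ms < baseline_rr_ms`.
#'
#' @param baseline_rr_ms mean RR interval, ms; must lie in (333, 2000).
#' @param rsa_amp_ms amplitude of the RSA sinusoid, ms.
#' @param resp_freq_hz breathing frequency, Hz.
#' @param mayer_amp_ms amplitude of the 0.1 Hz component, ms.
#' @param noise_sd_ms SD of Gaussian beat noise, ms.
#' @param duration_s recording length, s.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(baseline_rr_ms = 800, rsa_amp_ms = 25,
                       resp_freq_hz = 0.25, mayer_amp_ms = 15,
                       noise_sd_ms = 15, duration_s = 300, seed = NULL) {
  if (!(baseline_rr_ms > 333 && baseline_rr_ms < 2000)) {
    stop_frphrv("baseline_rr_ms must lie in (333, 2000) ms")
  }
  if (rsa_amp_ms < 0 || mayer_amp_ms < 0 || noise_sd_ms < 0) {
    stop_frphrv("amplitudes and noise SD must be non-negative")
  }
  if (resp_freq_hz <= 0) stop_frphrv("resp_freq_hz must be positive")
  if (duration_s <= 0) stop_frphrv("duration_s must be positive")
  if (rsa_amp_ms + mayer_amp_ms + 4 * noise_sd_ms >= baseline_rr_ms) {
    stop_frphrv("nonphysical parameters: rsa_amp + mayer_amp + 4*noise_sd ",
                "must stay below baseline_rr_ms")
  }
  structure(list(baseline_rr_ms = baseline_rr_ms, rsa_amp_ms = rsa_amp_ms,
                 resp_freq_hz = resp_freq_hz, mayer_amp_ms = mayer_amp_ms,
                 noise_sd_ms = noise_sd_ms, duration_s = duration_s,
                 seed = seed),
            class = "sim_params")
}

#' Default spontaneous-breathing parameters
#'
#' Spontaneous breathing at ~0.25 Hz (15 breaths/min) with modest RSA.
#' @param ... overrides passed to [sim_params()].
#' @export
spontaneous_params <- function(...) {
  args <- utils::modifyList(list(rsa_amp_ms = 25, resp_freq_hz = 0.25),
                            list(...))
  do.call(sim_params, args)
}

#' Default slow-paced-breathing parameters
#'
#' Guided breathing on the default 15 s cycle (1/15 Hz) with RSA several-fold
#' larger than the spontaneous default, the hallmark of slow pacing.
#' @param ... overrides passed to [sim_params()].
#' @export
paced_params <- function(...) {
  args <- utils::modifyList(list(rsa_amp_ms = 100, resp_freq_hz = 1 / 15),
                            list(...))
  do.call(sim_params, args)
}

#' Simulate an RR-interval recording
#'
#' Generates beats iteratively: beat `k + 1` occurs at
#' `t_{k+1} = t_k + RR(t_k) / 1000`, where
#' `RR(t) = baseline + rsa_amp * sin(2 pi f_resp t) + mayer_amp * sin(2 pi 0.1 t)
#' + N(0, noise_sd)`. With a [breathing_protocol()] supplied, the breathing
#' frequency is taken from its cycle (`1 / cycle_s`). Under the parameter
#' guard every interval stays inside the 333-2000 ms artefact screen.
#'
#' @param params a [sim_params()] object.
#' @param protocol optional [breathing_protocol()]; overrides `resp_freq_hz`.
#' @param subject_id,condition labels stored on the result.
#' @return An [rr_series()].
#' @export
simulate_rr <- function(params, protocol = NULL,
                        subject_id = NA_character_,
                        condition = NA_character_) {
  stopifnot(inherits(params, "sim_params"))
  f <- params$resp_freq_hz
  if (!is.null(protocol)) {
    stopifnot(inherits(protocol, "breathing_protocol"))
    f <- 1 / protocol$cycle_s
  }
  with_seed(params$seed, {
    # upper bound on beat count: shortest possible interval under the guard
    n_max <- ceiling(params$duration_s * 1000 /
                       (params$baseline_rr_ms - params$rsa_amp_ms -
                          params$mayer_amp_ms - 4 * params$noise_sd_ms)) + 2L
    intervals <- numeric(n_max)
    t <- 0
    k <- 0L
    while (t < params$duration_s) {
      rr <- params$baseline_rr_ms +
        params$rsa_amp_ms * sin(2 * pi * f * t) +
        params$mayer_amp_ms * sin(2 * pi * 0.1 * t) +
        (if (params$noise_sd_ms > 0) stats::rnorm(1, 0, params$noise_sd_ms) else 0)
      # noise beyond 4 SD could leave the physiological screen; clamp it
      lo <- params$baseline_rr_ms - params$rsa_amp_ms - params$mayer_amp_ms -
        4 * params$noise_sd_ms
      hi <- params$baseline_rr_ms + params$rsa_amp_ms + params$mayer_amp_ms +
        4 * params$noise_sd_ms
      rr <- min(max(rr, lo), hi)
      k <- k + 1L
      intervals[k] <- rr
      t <- t + rr / 1000
    }
    rr_series(intervals[seq_len(k)], subject_id = subject_id,
              condition = condition)
  })
}

#' Simulate a paired breathing cohort
#'
#' Generates `n_subjects` paired recordings (one spontaneous, one slow-paced
#' per subject). Between-subject variability is introduced by jittering the
#' baseline RR (truncated normal, SD 40 ms, +/- 120 ms) and by a shared
#' multiplicative RSA-amplitude factor (truncated normal, SD 0.2, in
#' [0.5, 1.5]) so the paced/spontaneous amplitude ratio is preserved within
#' subject. Each recording gets a reproducible sub-seed derived from `seed`.
#'
#' @param n_subjects number of subjects, >= 2.
#' @param spont,paced [sim_params()] templates for the two arms.
#' @param seed cohort seed (drives jitter and every per-recording sub-seed).
#' @return An object of class `hrv_cohort`: list with `recordings` (list of
#'   [rr_series()]) and `manifest` (data.frame: subject_id, condition, seed).
#' @export
simulate_cohort <- function(n_subjects = 60,
                            spont = spontaneous_params(),
                            paced = paced_params(),
                            seed = 1) {
  if (n_subjects < 2) {
    stop_frphrv("n_subjects must be >= 2 (pairwise statistics undefined)")
  }
  stopifnot(inherits(spont, "sim_params"), inherits(paced, "sim_params"))
  rtrunc_norm <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    pmin(pmax(x, lo), hi)
  }
  jit <- with_seed(seed, list(
    baseline = rtrunc_norm(n_subjects, 0, 40, -120, 120),
    rsa_mult = rtrunc_norm(n_subjects, 1, 0.2, 0.5, 1.5)
  ))
  recordings <- vector("list", 2L * n_subjects)
  manifest <- data.frame(subject_id = character(2L * n_subjects),
                         condition = character(2L * n_subjects),
                         seed = numeric(2L * n_subjects),
                         stringsAsFactors = FALSE)
  conds <- c("spontaneous", "slow_paced")
  templates <- list(spontaneous = spont, slow_paced = paced)
  r <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    for (ci in 1:2) {
      cond <- conds[ci]
      tmpl <- templates[[cond]]
      sub_seed <- derive_seed(seed, 2L * i + ci)
      p <- sim_params(
        baseline_rr_ms = tmpl$baseline_rr_ms + jit$baseline[i],
        rsa_amp_ms = tmpl$rsa_amp_ms * jit$rsa_mult[i],
        resp_freq_hz = tmpl$resp_freq_hz,
        mayer_amp_ms = tmpl$mayer_amp_ms,
        noise_sd_ms = tmpl$noise_sd_ms,
        duration_s = tmpl$duration_s,
        seed = sub_seed
      )
      r <- r + 1L
      recordings[[r]] <- simulate_rr(p, subject_id = sid, condition = cond)
      manifest$subject_id[r] <- sid
      manifest$condition[r] <- cond
      manifest$seed[r] <- sub_seed
    }
  }
  structure(list(recordings = recordings, manifest = manifest, seed = seed),
            class = "hrv_cohort")
}

#' @export
print.hrv_cohort <- function(x, ...) {
  n <- nrow(x$manifest)
  cat(sprintf("HRV cohort: %d recordings (%d paired subjects), seed %s\n",
              n, n %/% 2L, format(x$seed)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Writes one RR text file per recording plus a `manifest.csv`
#' (subject_id, condition, path, seed) into `dir`.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory, created if missing.
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$path <- sprintf("%s_%s.txt", man$subject_id, man$condition)
  for (i in seq_along(cohort$recordings)) {
    write_rr(cohort$recordings[[i]], file.path(dir, man$path[i]))
  }
  out <- file.path(dir, "manifest.csv")
  utils::write.csv(man, out, row.names = FALSE)
  invisible(out)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path path to a `manifest.csv` written by [write_cohort()];
#'   RR files are resolved relative to its directory.
#' @return An `hrv_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(man)), function(i) {
    read_rr(file.path(base, man$path[i]), subject_id = man$subject_id[i],
            condition = man$condition[i])
  })
  structure(list(recordings = recs, manifest = man, seed = NA_real_),
            class = "hrv_cohort")
}
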