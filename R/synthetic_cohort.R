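#' Phenotype configuration for the synthetic cohort generator
#'
#' Describes one diagnostic group's distribution of tremor, kinetics, pen
#' force, non-motor symptom probabilities and demographics. The defaults of
#' the three presets ([phenotype_presets()]) are the study conditions the
#' generator emulates; see the methods vignette for the rationale of each
#' number.
#'
#' @param group `"CG"`, `"PD"` or `"DD"`.
#' @param tremor_freq_range Tremor frequency range in Hz (uniform per
#'   participant).
#' @param tremor_amplitude `c(mean, sd)` of the radial tremor amplitude in
#'   cm (sampled per participant, floored at `amplitude_floor`).
#' @param amplitude_floor Minimum amplitude in cm.
#' @param laterality Proportion of tremor amplitude on the affected side:
#'   the affected arm tremors at the sampled amplitude `A`, the other at
#'   `A * (1 - laterality) / laterality` (0.5 = bilateral).
#' @param draw_duration `c(mean, sd)` drawing duration in seconds.
#' @param force_level `c(mean, sd)`: group-level mean force and nominal
#'   within-recording sample SD; both vary per participant (the SD
#'   log-normally), so force statistics overlap between groups.
#' @param motion_noise SD (cm) of unstructured radial jitter.
#' @param nms_yes_prob 30-vector of per-item questionnaire yes
#'   probabilities (scalar recycled).
#' @param age_dist `c(mean, sd)` of age in years.
#' @param female_prob Probability of gender `"female"`.
#' @param hy_probs For PD: probabilities of Hoehn–Yahr stages
#'   `c(1, 2, 2.5, 3, 4, 5)`.
#' @return Object of class `phenotype_config`.
#' @export
phenotype_config <- function(group, tremor_freq_range, tremor_amplitude,
                             amplitude_floor = 0.01, laterality,
                             draw_duration, force_level, motion_noise,
                             nms_yes_prob, age_dist, female_prob,
                             hy_probs = NULL) {
  group <- match.arg(group, c("CG", "PD", "DD"))
  if (length(nms_yes_prob) == 1L) nms_yes_prob <- rep(nms_yes_prob, 30L)
  stopifnot(length(nms_yes_prob) == 30L,
            all(nms_yes_prob >= 0 & nms_yes_prob <= 1),
            laterality >= 0.5, laterality <= 1,
            all(tremor_amplitude >= 0), all(draw_duration > 0),
            motion_noise >= 0, female_prob >= 0, female_prob <= 1)
  structure(
    list(group = group, tremor_freq_range = tremor_freq_range,
         tremor_amplitude = tremor_amplitude,
         amplitude_floor = amplitude_floor, laterality = laterality,
         draw_duration = draw_duration, force_level = force_level,
         motion_noise = motion_noise, nms_yes_prob = nms_yes_prob,
         age_dist = age_dist, female_prob = female_prob,
         hy_probs = hy_probs),
    class = "phenotype_config"
  )
}

#' Default phenotype presets for the three diagnostic groups
#'
#' CG: no pathological tremor, only a faint 8–12 Hz physiological
#' oscillation and motion jitter, fast drawing, low questionnaire yes
#' rates. PD: 4–6 Hz rest tremor, markedly unilateral, slower drawing
#' (bradykinesia), elevated yes rates. DD: heterogeneous 5–10 Hz,
#' essentially bilateral tremor with PD-like yes rates, so the
#' questionnaire separates disease from control but not PD from DD.
#'
#' @return Named list of [phenotype_config()] objects (CG, PD, DD).
#' @export
phenotype_presets <- function() {
  list(
    CG = phenotype_config(
      "CG", tremor_freq_range = c(7, 12), tremor_amplitude = c(0.10, 0.05),
      amplitude_floor = 0.01, laterality = 0.5,
      draw_duration = c(24, 7), force_level = c(1.0, 0.20),
      motion_noise = 0.04, nms_yes_prob = 0.06,
      age_dist = c(58, 12), female_prob = 0.37),
    PD = phenotype_config(
      "PD", tremor_freq_range = c(4, 6), tremor_amplitude = c(0.20, 0.12),
      amplitude_floor = 0.01, laterality = 0.85,
      draw_duration = c(30, 8), force_level = c(1.05, 0.22),
      motion_noise = 0.04, nms_yes_prob = 0.33,
      age_dist = c(68, 9), female_prob = 0.667,
      hy_probs = c(3, 4, 5, 7, 3, 2) / 24),
    DD = phenotype_config(
      "DD", tremor_freq_range = c(5, 9), tremor_amplitude = c(0.22, 0.13),
      amplitude_floor = 0.01, laterality = 0.60,
      draw_duration = c(29, 8), force_level = c(1.0, 0.22),
      motion_noise = 0.04, nms_yes_prob = 0.31,
      age_dist = c(58, 12), female_prob = 0.54)
  )
}

#' Cohort-level generator configuration
#'
#' @param n_per_group Named counts `c(CG = , PD = , DD = )`; the default
#'   27/24/26 mirrors the study cohort sizes.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param sampling_rate Stylus sampling rate in Hz, default 240.
#' @param template Reference spiral, default [make_reference_spiral()].
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(CG = 27, PD = 24, DD = 26),
                          seed = 1, sampling_rate = 240,
                          template = make_reference_spiral()) {
  stopifnot(all(n_per_group >= 1), all(c("CG", "PD", "DD") %in%
                                         names(n_per_group)))
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 sampling_rate = sampling_rate, template = template),
            class = "cohort_config")
}

# sample the per-participant realisation of a phenotype
sample_participant_traits <- function(ph) {
  amp <- max(ph$amplitude_floor,
             rnorm(1, ph$tremor_amplitude[1], ph$tremor_amplitude[2]))
  list(
    tremor_freq = runif(1, ph$tremor_freq_range[1], ph$tremor_freq_range[2]),
    tremor_amplitude = amp,
    affected = sample(c("left", "right"), 1),
    duration = max(8, rnorm(1, ph$draw_duration[1], ph$draw_duration[2])),
    force_mean = max(0.2, rnorm(1, ph$force_level[1],
                                ph$force_level[2] / 2)),
    force_sd = ph$force_level[2] * exp(rnorm(1, 0, 0.3)),
    age = round(min(90, max(30, rnorm(1, ph$age_dist[1], ph$age_dist[2])))),
    gender = if (runif(1) < ph$female_prob) "female" else "male",
    hoehn_yahr = if (is.null(ph$hy_probs)) NULL else
      sample(c(1, 2, 2.5, 3, 4, 5), 1, prob = ph$hy_probs)
  )
}

#' Simulate one spiral drawing recording
#'
#' The pen sweeps the template at roughly constant arc-length speed
#' (`theta(t) = theta_max * sqrt(t / D)`), with a radial tremor
#' `A_side * sin(2 * pi * f * t + phase)`, unstructured Gaussian radial
#' jitter, and doubled jitter in the first and last 4% of samples emulating
#' pen drop/lift. Force is Gaussian around the participant's mean, clipped
#' at 0. Timestamps advance at the sampling rate with small positive
#' jitter, so they are strictly increasing. Consumes the current RNG
#' stream, so a fixed seed reproduces the recording bit for bit.
#'
#' @param ph A [phenotype_config()].
#' @param cc A [cohort_config()].
#' @param hand `"left"` or `"right"`.
#' @param repetition 1 or 2.
#' @param traits Per-participant draws from the phenotype (internal; a
#'   fresh realisation is sampled when omitted).
#' @param participant_id Identifier stamped on the recording.
#' @return A [drawing_recording()].
#' @export
simulate_drawing <- function(ph, cc = cohort_config(), hand = "right",
                             repetition = 1, traits = NULL,
                             participant_id = "sim") {
  if (is.null(traits)) traits <- sample_participant_traits(ph)
  tpl <- cc$template
  rate <- cc$sampling_rate
  duration <- traits$duration * exp(rnorm(1, 0, 0.05))  # per-repetition
  n <- max(64L, round(duration * rate))
  dt <- (1 / rate) * (1 + pmin(0.5, pmax(-0.5, rnorm(n - 1, 0, 0.01))))
  t <- c(0, cumsum(dt))
  theta_max <- 2 * pi * tpl$n_loops
  theta <- theta_max * sqrt(t / t[n])
  amp_side <- if (hand == traits$affected) {
    traits$tremor_amplitude
  } else {
    traits$tremor_amplitude * (1 - ph$laterality) / ph$laterality
  }
  freq <- traits$tremor_freq + rnorm(1, 0, 0.1)
  phase <- runif(1, 0, 2 * pi)
  # band-limited hand jitter: a stylus position cannot jump sample to
  # sample at 240 Hz, so iid noise is smoothed (~27 Hz cutoff) and
  # rescaled to the target SD; the pen drop/lift edge burst doubles it
  w <- 9L
  smooth_noise <- as.numeric(stats::filter(rnorm(n + w - 1L), rep(1, w) / w,
                                           sides = 2L))
  smooth_noise <- smooth_noise[!is.na(smooth_noise)][seq_len(n)] * sqrt(w)
  scale_sd <- rep(ph$motion_noise, n)
  edge <- ceiling(0.04 * n)
  scale_sd[c(seq_len(edge), seq.int(n - edge + 1L, n))] <-
    ph$motion_noise * 2
  r <- spiral_radius(tpl, theta) +
    amp_side * sin(2 * pi * freq * t + phase) +
    smooth_noise * scale_sd
  r <- pmax(r, 0)
  force_sd <- traits$force_sd %||% ph$force_level[2]
  force <- pmax(0, rnorm(n, traits$force_mean, force_sd))
  drawing_recording(
    participant_id = participant_id, hand = hand, repetition = repetition,
    samples = data.frame(
      t = t,
      x = tpl$center[1] + r * cos(theta),
      y = tpl$center[2] + r * sin(theta),
      force = force),
    nominal_rate = rate
  )
}

#' Simulate a questionnaire response
#'
#' 30 independent Bernoulli draws with the phenotype's per-item yes
#' probabilities.
#'
#' @param ph A [phenotype_config()].
#' @return A [questionnaire_response()].
#' @export
simulate_questionnaire <- function(ph) {
  questionnaire_response(rbinom(30L, 1L, ph$nms_yes_prob))
}

#' Generate a full synthetic cohort
#'
#' Deterministic in `cc$seed`: participants of each group are sampled from
#' their phenotype preset, each with 2 hands x 2 repetitions of spiral
#' recordings, a questionnaire and demographics (Hoehn–Yahr stages for PD).
#'
#' @param cc A [cohort_config()].
#' @param presets Named list of phenotypes, default [phenotype_presets()].
#' @return A [cohort_dataset()].
#' @export
generate_cohort <- function(cc = cohort_config(),
                            presets = phenotype_presets()) {
  set.seed(cc$seed)
  participants <- list()
  for (grp in c("CG", "PD", "DD")) {
    ph <- presets[[grp]]
    for (i in seq_len(cc$n_per_group[[grp]])) {
      id <- sprintf("%s%02d", grp, i)
      traits <- sample_participant_traits(ph)
      recs <- list()
      for (hand in c("left", "right")) {
        for (rep_i in 1:2) {
          recs[[length(recs) + 1L]] <-
            simulate_drawing(ph, cc, hand, rep_i, traits, id)
        }
      }
      participants[[id]] <- participant_record(
        participant_id = id, group = grp, age = traits$age,
        gender = traits$gender, recordings = recs,
        questionnaire = simulate_questionnaire(ph),
        hoehn_yahr = traits$hoehn_yahr)
    }
  }
  cohort_dataset(participants)
}
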