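# fixtures built in code: ideal and perturbed spiral recordings

tpl <- spiraldx::make_reference_spiral()

# exact template samples: theta swept linearly over [theta_from, 8*pi],
# or at constant arc-length speed when constant_speed = TRUE
ideal_recording <- function(n = 2000, duration = 25, theta_from = 0,
                            template = tpl, force = 1,
                            id = "ideal", hand = "right", repetition = 1,
                            constant_speed = FALSE) {
  theta <- seq(theta_from, 2 * pi * template$n_loops, length.out = n)
  if (constant_speed) {
    dense <- seq(max(theta_from, 0.05), 2 * pi * template$n_loops,
                 length.out = 20 * n)
    pd <- spiraldx::spiral_points(template, dense)
    arc <- c(0, cumsum(sqrt(diff(pd$x)^2 + diff(pd$y)^2)))
    theta <- approx(arc, dense, xout = seq(0, max(arc), length.out = n))$y
  }
  pts <- spiraldx::spiral_points(template, theta)
  spiraldx::drawing_recording(
    id, hand, repetition,
    data.frame(t = seq(0, duration, length.out = n),
               x = pts$x, y = pts$y, force = force))
}

# template sweep with a radial perturbation A*sin(2*pi*f*t) and optional
# iid radial noise; constructed directly, independent of the package's
# cohort simulator
tremor_recording <- function(A, f, noise_sd = 0, n = 6000, duration = 25,
                             theta_from = 0, template = tpl,
                             hand = "right", repetition = 1,
                             id = "tremor") {
  t <- seq(0, duration, length.out = n)
  theta <- seq(theta_from, 2 * pi * template$n_loops, length.out = n)
  ramp <- pmin(1, theta / (2 * pi))  # keeps the radius positive near centre
  r <- spiraldx::spiral_radius(template, theta) +
    ramp * A * sin(2 * pi * f * t) +
    (if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0)
  spiraldx::drawing_recording(
    id, hand, repetition,
    data.frame(t = t, x = r * cos(theta), y = r * sin(theta), force = 1))
}

# random smooth trajectory for round-trip / property tests
random_recording <- function(n = 200, id = "rnd", hand = "left",
                             repetition = 1) {
  t <- cumsum(runif(n, 0.002, 0.01))
  theta <- seq(0.3, runif(1, 4, 9) * pi, length.out = n)
  r <- 0.15 * theta + cumsum(rnorm(n, 0, 0.01))
  r <- pmax(r, 0.01)
  spiraldx::drawing_recording(
    id, hand, repetition,
    data.frame(t = t - t[1], x = r * cos(theta), y = r * sin(theta),
               force = pmax(0, rnorm(n, 1, 0.2))))
}

# participant drawing the exact template with all four recordings
ideal_participant <- function(id = "P1", group = "CG", qyes_items = rep(0, 30)) {
  recs <- list(
    ideal_recording(id = id, hand = "left", repetition = 1,
                    constant_speed = TRUE),
    ideal_recording(id = id, hand = "left", repetition = 2,
                    constant_speed = TRUE),
    ideal_recording(id = id, hand = "right", repetition = 1,
                    constant_speed = TRUE),
    ideal_recording(id = id, hand = "right", repetition = 2,
                    constant_speed = TRUE))
  spiraldx::participant_record(
    id, group, age = 60, gender = "female", recordings = recs,
    questionnaire = spiraldx::questionnaire_response(qyes_items))
}

# feature table with prescribed group sizes and a single informative
# feature; remaining columns are noise — fast stand-in for cohort
# extraction in classifier tests
synthetic_feature_table <- function(n_cg = 27, n_pd = 24, n_dd = 26,
                                    signal_strength = 3) {
  n <- n_cg + n_pd + n_dd
  group <- rep(c("CG", "PD", "DD"), c(n_cg, n_pd, n_dd))
  diseased <- as.integer(group != "CG")
  tbl <- tibble::tibble(
    participant_id = sprintf("S%02d", seq_len(n)), group = group,
    age = round(rnorm(n, 60, 10)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    hoehn_yahr = ifelse(group == "PD", 2, NA_real_),
    QYes = pmin(30, pmax(0, round(rnorm(n, 3 + signal_strength * diseased, 2))))
  )
  for (f in setdiff(spiraldx::feature_names(), "QYes")) {
    tbl[[f]] <- pmax(0.01, rnorm(n, 1 + signal_strength * 0.3 * diseased *
                                   (group == "PD"), 1))
  }
  tbl
}
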