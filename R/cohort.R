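# Synthetic cohort generator: subjects with ages, demographics and
# sleep-feature values that follow configured age-trajectory curves, plus
# a shared latent developmental noise and per-feature measurement noise.
# A "delayed" group is produced by evaluating every curve at
# age + trajectory_offset. Feature-level generation (the default) is used
# by the statistical layer; record-level parameters for signal-level
# cohorts come from [default_record_params()].

#' Default feature trajectory curves
#'
#' A catalogue of `k` linear age curves plus a few grounded in reported
#' pediatric sleep trajectories: fast-spindle density rising 0.9 to 1.9
#' events/min between ages 4 and 16, slow-spindle density with an
#' inverted-U peaking near age 10, SO density rising 10 to 15/min, and SO
#' peak-to-peak amplitude declining with age. Generic curves get slopes
#' spread over both signs so the feature set is informative about age
#' without being collinear.
#'
#' @param k total number of curves (>= 4).
#' @param seed seed for the generic slopes/intercepts.
#' @return named list of functions of age (years).
#' @export
default_feature_curves <- function(k = 40, seed = 42) {
  stopifnot(k >= 4)
  curves <- list(
    fs_density_c3 = function(age) 0.9 + (1.9 - 0.9) / 12 * (age - 4),
    ss_density_f3 = function(age) 2.4 - 0.02 * (age - 10)^2,
    so_density_f4 = function(age) 10 + 5 / 12 * (age - 4),
    so_p2p_o1 = function(age) 140 - 5 * (age - 4)
  )
  n_gen <- k - length(curves)
  gen <- with_seed(substream_seed(seed, 211L), {
    list(slope = stats::runif(n_gen, 0.2, 2) *
           sample(c(-1, 1), n_gen, replace = TRUE),
         intercept = stats::runif(n_gen, -5, 5))
  })
  for (j in seq_len(n_gen)) {
    local({
      a <- gen$intercept[j]; b <- gen$slope[j]
      curves[[paste0("feature_", sprintf("%02d", j))]] <<-
        function(age) a + b * age
    })
  }
  curves
}

#' Simulate a feature-level cohort
#'
#' Each subject i has an effective age `age_i + trajectory_offset_i` and a
#' latent developmental age `eff_age + N(0, subject_noise_sd)` shared by
#' all features; feature j is `curve_j(latent)` plus measurement noise
#' with SD `feature_noise_frac` times the SD of curve j over the age
#' range. With zero noise the features reproduce the curves exactly.
#'
#' @param n number of non-delayed ("non-NDD") subjects.
#' @param age_range years, curves must be defined over it.
#' @param curves from [default_feature_curves()].
#' @param subject_noise_sd latent developmental noise SD (years); this is
#'   the floor on brain-age residual error.
#' @param feature_noise_frac per-feature measurement noise as a fraction
#'   of each curve's span SD.
#' @param groups optional data.frame(group, n, trajectory_offset) of extra
#'   groups (e.g. a delayed group at offset -2).
#' @param seed integer seed.
#' @return list(table = data.frame with subject_id, age, sex, race, ahi,
#'   medication, group, trajectory_offset and one column per feature;
#'   true_features = noise-free curve values at effective age;
#'   features = feature column names).
#' @export
simulate_cohort <- function(n = 600, age_range = c(2.5, 17.5),
                            curves = default_feature_curves(),
                            subject_noise_sd = 1.0,
                            feature_noise_frac = 0.4,
                            groups = NULL, seed = 1) {
  stopifnot(n >= 10, length(curves) >= 1)
  grid <- seq(age_range[1], age_range[2], length.out = 101)
  for (nm in names(curves)) {
    v <- curves[[nm]](grid)
    if (any(!is.finite(v)))
      stop("trajectory curve '", nm, "' undefined over the age range")
  }
  span_sd <- vapply(curves, function(f) stats::sd(f(grid)), numeric(1))

  plan <- data.frame(group = "non-NDD", n = n, trajectory_offset = 0,
                     stringsAsFactors = FALSE)
  if (!is.null(groups)) plan <- rbind(plan, groups)

  rows <- list(); truth <- list()
  sid <- 0L
  for (g in seq_len(nrow(plan))) {
    for (i in seq_len(plan$n[g])) {
      sid <- sid + 1L
      with_seed(substream_seed(seed, 301L, sid), {
        off <- plan$trajectory_offset[g]
        # sample ages so the shifted effective age stays where the curves
        # are defined (no clamping, which would attenuate the delay)
        age <- stats::runif(1, age_range[1] - min(0, off),
                            age_range[2] - max(0, off))
        eff <- age + off
        latent <- eff + stats::rnorm(1, 0, subject_noise_sd)
        latent <- min(max(latent, age_range[1] - 2), age_range[2] + 2)
        tf <- vapply(curves, function(f) f(eff), numeric(1))
        fv <- vapply(seq_along(curves), function(j) {
          curves[[j]](latent) +
            stats::rnorm(1, 0, feature_noise_frac * span_sd[j])
        }, numeric(1))
        names(fv) <- names(curves)
        rows[[sid]] <- c(list(
          subject_id = sprintf("S%04d", sid), age = age,
          sex = sample(c("F", "M"), 1),
          race = sample(c("white", "black", "other"), 1,
                        prob = c(0.55, 0.3, 0.15)),
          ahi = stats::rexp(1, 1),
          medication = stats::runif(1) < 0.1,
          group = plan$group[g],
          trajectory_offset = plan$trajectory_offset[g]), as.list(fv))
        truth[[sid]] <- tf
      })
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tru <- do.call(rbind, truth)
  rownames(tru) <- tab$subject_id
  list(table = tab, true_features = tru, features = names(curves))
}

#' Record-level generation parameters as a function of age
#'
#' Maps age to the event specs and noise parameters of a signal-level
#' synthetic record, following reported pediatric N2 trajectories:
#' fast-spindle density rises 0.9 to 1.9 events/min between ages 4 and
#' 16; the true SO event rate rises (4 to 8 events/min) while SO
#' amplitude declines (negative peak 85 uV at age 4 to 40 uV at age 16,
#' peak-to-peak about 1.6x), crossing the fixed -40 uV / 75 uV absolute
#' thresholds mid-adolescence -- the regime in which a relative SO
#' threshold tracks the rising event rate while the absolute threshold
#' loses the shrinking events and reports the opposite age trend.
#'
#' @param age years.
#' @return list(specs = list of [event_spec()], noise = noise params).
#' @export
default_record_params <- function(age) {
  neg <- 85 - 45 / 12 * (age - 4)
  list(specs = list(
    event_spec("fast_spindle", density = 0.9 + (1.9 - 0.9) / 12 * (age - 4),
               amplitude = 30, channels = "C3"),
    event_spec("so", density = 4 + 4 / 12 * (age - 4), amplitude = neg,
               duration = 0.6, pos_duration = 0.5, pos_fraction = 0.6,
               amplitude_cv = 0.35)),
    noise = default_noise_params())
}
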