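#' Configuration for the synthetic cohort generator
#'
#' Describes a quota-sampled cohort: equal numbers of participants in each of
#' the eight sex-by-nutrition strata, sex-specific height distributions,
#' per-stratum truncated-normal BMI, and circumference/length/skinfold
#' measurements derived from weight and height through linear relations plus
#' Gaussian noise. Defaults are calibrated so that, with
#' `n_per_stratum = 30` (240 participants), the cohort's marginal medians sit
#' near a young-adult outpatient population: weight about 64.5 kg, height
#' about 162.5 cm, MAC about 28.6 cm.
#'
#' @param n_per_stratum Participants per sex-by-nutrition stratum (default 30,
#'   i.e. 240 in total over 2 sexes x 4 nutrition levels).
#' @param seed Integer seed; cohorts are byte-identical given the same config.
#' @param height_mean,height_sd Named numeric (`male`, `female`): height
#'   distribution in cm.
#' @param bmi_params Named list per nutrition level, each
#'   `c(mean, sd, lo, hi)`: truncated-normal BMI parameters; `[lo, hi)` must
#'   lie inside the level's WHO interval.
#' @param derived Named list of linear derivation rules for the measured
#'   fields, each `list(on =, slope =, intercept =, sd =, min =)` with
#'   optional `sex_offset = c(male=, female=)`; `on` is `"weight"`,
#'   `"height"` or `"bmi"`.
#' @param age_meanlog,age_sdlog Log-normal parameters for age above 18 years.
#' @param planted_equation Optional equation id: [plant_equation_truth()]
#'   rewrites measured weight as that equation's prediction plus noise.
#' @param planted_noise_sd SD (kg) of the noise added to the planted truth.
#' @param max_reject Iteration cap for rejection sampling; breaching it is a
#'   configuration error, never a silent relaxation of the bounds.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_stratum = 30L,
                             seed = NULL,
                             height_mean = c(male = 167, female = 159.5),
                             height_sd = c(male = 8.4, female = 6.4),
                             bmi_params = list(
                               underweight = c(mean = 17.3, sd = 1.0, lo = 14.0, hi = 18.5),
                               normal      = c(mean = 22.0, sd = 2.0, lo = 18.5, hi = 25.0),
                               overweight  = c(mean = 27.2, sd = 1.4, lo = 25.0, hi = 30.0),
                               obese       = c(mean = 33.0, sd = 2.8, lo = 30.0, hi = 50.0)
                             ),
                             derived = list(
                               mac_cm = list(on = "weight", slope = 0.35, intercept = 6.0, sd = 1.0, min = 12),
                               ac_cm  = list(on = "weight", slope = 0.90, intercept = 23.7, sd = 3.0, min = 40),
                               cc_cm  = list(on = "weight", slope = 0.25, intercept = 18.4, sd = 1.0, min = 18),
                               hc_cm  = list(on = "weight", slope = 0.75, intercept = 48.0, sd = 2.5, min = 55),
                               kh_cm  = list(on = "height", slope = 0.3169, intercept = 0.0, sd = 1.2, min = 35,
                                             sex_offset = c(male = 0.5, female = -1.0)),
                               sst_mm = list(on = "bmi", slope = 1.1, intercept = -14.5, sd = 3.0, min = 3,
                                             sex_offset = c(male = -1.5, female = 1.5))
                             ),
                             age_meanlog = log(11), age_sdlog = 0.65,
                             planted_equation = NULL,
                             planted_noise_sd = 0,
                             max_reject = 10000L) {
  stopifnot(n_per_stratum >= 1L, planted_noise_sd >= 0, max_reject >= 1L)
  if (any(height_sd <= 0) || any(vapply(bmi_params, function(p) p[["sd"]] <= 0, logical(1)))) {
    stop("all scale parameters must be strictly positive", call. = FALSE)
  }
  for (lvl in names(bmi_params)) {
    p <- bmi_params[[lvl]]
    if (p[["lo"]] >= p[["hi"]]) {
      stop("impossible truncation bounds for BMI stratum '", lvl, "'", call. = FALSE)
    }
  }
  if (!setequal(names(bmi_params), NUTRITION_LEVELS)) {
    stop("bmi_params must name exactly the four nutrition levels", call. = FALSE)
  }
  if (!is.null(planted_equation)) resolve_equation_ids(planted_equation)
  structure(
    list(
      n_per_stratum = as.integer(n_per_stratum), seed = seed,
      height_mean = height_mean, height_sd = height_sd,
      bmi_params = bmi_params, derived = derived,
      age_meanlog = age_meanlog, age_sdlog = age_sdlog,
      planted_equation = planted_equation,
      planted_noise_sd = planted_noise_sd,
      max_reject = as.integer(max_reject)
    ),
    class = "synthetic_config"
  )
}

# Truncated-normal draws by rejection, redrawing only the out-of-bounds
# entries so the consumed stream stays deterministic. Interval is [lo, hi).
rtruncnorm_reject <- function(n, mean, sd, lo, hi, max_reject) {
  x <- stats::rnorm(n, mean, sd)
  for (iter in seq_len(max_reject)) {
    bad <- which(x < lo | x >= hi)
    if (!length(bad)) return(x)
    x[bad] <- stats::rnorm(length(bad), mean, sd)
  }
  stop("rejection sampling failed to satisfy bounds [", lo, ", ", hi,
       ") within ", max_reject, " iterations; check the configuration",
       call. = FALSE)
}

#' Generate a synthetic quota-sampled anthropometric cohort
#'
#' Emits one record per participant with all measurement fields populated.
#' Strata are generated in a fixed order (male then female; underweight,
#' normal, overweight, obese within sex) from a single seeded random stream,
#' so earlier strata's draws do not move when later strata are added. Within
#' each stratum: height is drawn from the sex's normal distribution
#' (truncated to 100-250 cm), BMI from the stratum's truncated normal, weight
#' is set to `BMI * (height/100)^2`, and the remaining measurements are
#' linear functions of weight, height or BMI plus Gaussian noise, truncated
#' above their physiological floors by rejection. Every emitted record's BMI
#' therefore falls inside its stratum's interval by construction.
#'
#' @param config A [synthetic_config()].
#' @return Record tibble (same schema the ingest reader consumes) with
#'   columns `participant_id`, `sex`, `nutrition_stratum`, `age_years`,
#'   `weight_kg`, `height_cm`, `mac_cm`, `ac_cm`, `cc_cm`, `hc_cm`, `kh_cm`,
#'   `sst_mm`; the config is attached as attribute `synthetic_config` for
#'   provenance.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_per_stratum = 2, seed = 1))
#' nrow(cohort)
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) withr::local_seed(as.integer(config$seed))

  n <- config$n_per_stratum
  strata <- expand.grid(
    nutrition = NUTRITION_LEVELS, sex = c("male", "female"),
    stringsAsFactors = FALSE
  )[, c("sex", "nutrition")]

  blocks <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s <- strata$sex[i]
    lvl <- strata$nutrition[i]
    p <- config$bmi_params[[lvl]]
    height <- rtruncnorm_reject(n, config$height_mean[[s]], config$height_sd[[s]],
                                100, 250, config$max_reject)
    bmi_val <- rtruncnorm_reject(n, p[["mean"]], p[["sd"]], p[["lo"]], p[["hi"]],
                                 config$max_reject)
    weight <- bmi_val * (height / 100)^2
    age <- 18 + stats::rlnorm(n, config$age_meanlog, config$age_sdlog)

    block <- tibble::tibble(
      sex = s, nutrition_stratum = lvl,
      age_years = age, weight_kg = weight, height_cm = height
    )
    for (field in names(config$derived)) {
      rule <- config$derived[[field]]
      base <- switch(rule$on,
        weight = weight, height = height, bmi = bmi_val,
        stop("unknown derivation base '", rule$on, "'", call. = FALSE)
      )
      mu <- rule$intercept + rule$slope * base
      if (!is.null(rule$sex_offset)) mu <- mu + rule$sex_offset[[s]]
      lo <- max(rule$min, .Machine$double.eps)
      block[[field]] <- rtruncnorm_reject(n, 0, rule$sd, lo - mu, Inf,
                                          config$max_reject) + mu
    }
    blocks[[i]] <- block
  }

  cohort <- dplyr::bind_rows(blocks)
  cohort <- dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("S%04d", seq_len(nrow(cohort)))),
    cohort
  )
  attr(cohort, "synthetic_config") <- config
  cohort
}

#' Generate a cohort whose true weight follows a known equation
#'
#' Builds a cohort exactly as [generate_cohort()], then overwrites measured
#' weight with the planted equation's prediction plus `Normal(0, sd)` noise
#' (noise redrawn for any draw that would make weight non-positive). Used for
#' ranking-recovery testing: a validation pipeline run on such a cohort
#' should rank the planted equation best.
#'
#' Note the rewritten weight breaks the BMI-in-stratum guarantee of
#' [generate_cohort()]; nutrition strata in downstream reports are
#' recomputed from the rewritten weight.
#'
#' @param config A [synthetic_config()] with `planted_equation` set.
#' @return Record tibble as in [generate_cohort()], with attribute
#'   `planted_truth` recording the equation and noise SD.
#' @export
plant_equation_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$planted_equation)) {
    stop("config$planted_equation must be set", call. = FALSE)
  }
  cohort <- generate_cohort(config)
  req <- setdiff(required_variables(config$planted_equation), "sex")
  absent <- setdiff(req, names(cohort))
  if (length(absent)) {
    stop("planted equation requires field(s) the generator does not emit: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  res <- eval_equation(cohort, config$planted_equation)
  if (!all(res$evaluable)) {
    stop("planted equation not evaluable on ", sum(!res$evaluable),
         " generated record(s)", call. = FALSE)
  }
  truth <- res$predicted_kg
  noise <- if (config$planted_noise_sd > 0) {
    rtruncnorm_reject(length(truth), 0, config$planted_noise_sd,
                      -truth + .Machine$double.eps, Inf, config$max_reject)
  } else {
    rep(0, length(truth))
  }
  cohort$weight_kg <- truth + noise
  attr(cohort, "planted_truth") <- list(
    equation = config$planted_equation, noise_sd = config$planted_noise_sd
  )
  cohort
}

#' Write a synthetic-config to a human-readable YAML file
#' @param config A [synthetic_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  # 17 significant digits so numeric parameters round-trip exactly
  yaml::write_yaml(rapply(unclass(config), as.list, how = "replace"), path,
                   precision = 17L)
  invisible(path)
}

#' Read a synthetic-config from YAML
#' @param path YAML file written by [write_synthetic_config()] or hand-edited.
#' @return A validated [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) if (is.null(x)) NULL else unlist(x)
  synthetic_config(
    n_per_stratum = raw$n_per_stratum,
    seed = raw$seed,
    height_mean = num(raw$height_mean), height_sd = num(raw$height_sd),
    bmi_params = lapply(raw$bmi_params, num),
    derived = lapply(raw$derived, function(r) {
      r$sex_offset <- num(r$sex_offset)
      r[!vapply(r, is.null, logical(1))]
    }),
    age_meanlog = raw$age_meanlog, age_sdlog = raw$age_sdlog,
    planted_equation = raw$planted_equation,
    planted_noise_sd = raw$planted_noise_sd %||% 0,
    max_reject = raw$max_reject %||% 10000L
  )
}
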