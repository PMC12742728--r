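#' Signed percentage error of a prediction
#'
#' Convention: `100 * (predicted - actual) / actual`, i.e. positive when the
#' equation overestimates. Vectorized over pairs.
#'
#' @param predicted Predicted weights, kg.
#' @param actual Measured weights, kg; must be strictly positive.
#' @return Percentage errors.
#' @examples
#' percent_error(110, 100)
#' @export
percent_error <- function(predicted, actual) {
  check_paired(predicted, actual)
  if (any(actual <= 0)) stop("actual weights must be strictly positive", call. = FALSE)
  100 * (predicted - actual) / actual
}

#' Percentage of predictions within a relative tolerance of the actual value
#'
#' The within-tolerance accuracy standard in the weight-estimation
#' literature: P10 is `p_within(..., tolerance = 0.10)`, P20 uses 0.20.
#' The boundary is inclusive: an absolute relative error exactly equal to
#' the tolerance counts as within.
#'
#' @param predicted,actual Equal-length paired vectors, kg; `actual > 0`.
#' @param tolerance Relative tolerance as a fraction (0.10 for P10).
#' @return Percentage in `[0, 100]`.
#' @examples
#' p_within(c(95, 120, 100), c(100, 100, 100), 0.10)
#' @export
p_within <- function(predicted, actual, tolerance) {
  check_paired(predicted, actual, min_n = 1L)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("tolerance must be a single positive fraction", call. = FALSE)
  }
  if (any(actual <= 0)) stop("actual weights must be strictly positive", call. = FALSE)
  100 * mean(abs(predicted - actual) / actual <= tolerance)
}

#' Mean percentage error (MPE)
#'
#' Arithmetic mean of [percent_error()] over pairs; signed, so over- and
#' underestimates can cancel.
#'
#' @inheritParams p_within
#' @return MPE in percent.
#' @export
mean_percentage_error <- function(predicted, actual) {
  check_paired(predicted, actual, min_n = 1L)
  mean(percent_error(predicted, actual))
}

#' Bland-Altman agreement analysis
#'
#' Method-comparison analysis of predicted against measured weight.
#' Differences are `predicted - actual` (estimate minus reference); bias is
#' their mean, the 95% limits of agreement (LOA) are `bias +/- 1.96 * s` with
#' `s` the sample standard deviation of the differences (n-1 denominator).
#' Confidence intervals follow the classical large-sample formulas: the bias
#' uses standard error `s/sqrt(n)`, each LOA uses `s*sqrt(3/n)`, both with a
#' Student-t critical value at `n - 1` degrees of freedom.
#'
#' @inheritParams p_within
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return Object of class `bland_altman`: a list with `n`, `bias`, `sd`,
#'   `loa_lower`, `loa_upper`, the three confidence intervals (`bias_ci`,
#'   `loa_lower_ci`, `loa_upper_ci`, each a length-2 numeric), a `degenerate`
#'   flag (TRUE when the differences have zero variance, collapsing the LOA
#'   onto the bias), and `points`, a tibble of per-pair plot coordinates
#'   (`pair_mean`, `difference`).
#' @examples
#' bland_altman(c(51, 49, 51, 49), c(50, 50, 50, 50))
#' @export
bland_altman <- function(predicted, actual, conf_level = 0.95) {
  check_paired(predicted, actual, min_n = 3L,
               msg = "Bland-Altman confidence intervals need n >= 3")
  d <- predicted - actual
  n <- length(d)
  bias <- mean(d)
  s <- stats::sd(d)
  degenerate <- s == 0
  loa <- bias + c(-1, 1) * 1.96 * s
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(
    list(
      n = n, bias = bias, sd = s,
      loa_lower = loa[1L], loa_upper = loa[2L],
      bias_ci = bias + c(-1, 1) * tcrit * se_bias,
      loa_lower_ci = loa[1L] + c(-1, 1) * tcrit * se_loa,
      loa_upper_ci = loa[2L] + c(-1, 1) * tcrit * se_loa,
      conf_level = conf_level,
      degenerate = degenerate,
      points = tibble::tibble(
        pair_mean = (predicted + actual) / 2,
        difference = d
      )
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias: %8.3f kg  [%.3f, %.3f]\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LOA:  %8.3f kg  [%.3f, %.3f]\n", x$loa_lower,
              x$loa_lower_ci[1], x$loa_lower_ci[2]))
  cat(sprintf("        %8.3f kg  [%.3f, %.3f]\n", x$loa_upper,
              x$loa_upper_ci[1], x$loa_upper_ci[2]))
  if (x$degenerate) cat("  note: zero-variance differences; LOA collapse onto the bias\n")
  invisible(x)
}

#' Body mass index
#'
#' @param weight_kg Weight in kg, positive.
#' @param height_cm Height in cm, positive.
#' @return BMI in kg/m^2.
#' @examples
#' bmi(64.5, 162.5)
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0, na.rm = TRUE) || any(height_cm <= 0, na.rm = TRUE)) {
    stop("weight and height must be strictly positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

NUTRITION_LEVELS <- c("underweight", "normal", "overweight", "obese")

#' Classify nutrition status from BMI
#'
#' WHO adult categories: underweight below 18.5, normal 18.5 to <25,
#' overweight 25 to <30, obese 30 and above (lower boundaries inclusive).
#'
#' @param bmi_value BMI in kg/m^2, positive.
#' @return Factor with levels underweight, normal, overweight, obese.
#' @examples
#' classify_nutrition(c(17, 18.5, 27, 30))
#' @export
classify_nutrition <- function(bmi_value) {
  if (any(bmi_value <= 0, na.rm = TRUE)) stop("BMI must be strictly positive", call. = FALSE)
  cut(bmi_value, breaks = c(0, 18.5, 25, 30, Inf),
      labels = NUTRITION_LEVELS, right = FALSE)
}

# One-row accuracy summary for a set of prediction/actual pairs. Tolerates
# tiny strata: CIs need n >= 3, LOA need n >= 2, P10/P20/MPE need n >= 1;
# anything below threshold is NA rather than an error so subgroup tables can
# always be emitted.
accuracy_row <- function(predicted, actual) {
  n <- length(predicted)
  if (n == 0L) {
    return(tibble::tibble(
      n_evaluated = 0L, p10 = NA_real_, p20 = NA_real_, mpe = NA_real_,
      ba_bias = NA_real_, ba_sd = NA_real_,
      ba_loa_lower = NA_real_, ba_loa_upper = NA_real_,
      ba_bias_ci_lo = NA_real_, ba_bias_ci_hi = NA_real_,
      ba_loa_lower_ci_lo = NA_real_, ba_loa_lower_ci_hi = NA_real_,
      ba_loa_upper_ci_lo = NA_real_, ba_loa_upper_ci_hi = NA_real_,
      n_implausible = 0L
    ))
  }
  d <- predicted - actual
  bias <- mean(d)
  s <- if (n >= 2L) stats::sd(d) else NA_real_
  loa <- bias + c(-1, 1) * 1.96 * s
  if (n >= 3L) {
    ba <- bland_altman(predicted, actual)
    bias_ci <- ba$bias_ci; lo_ci <- ba$loa_lower_ci; hi_ci <- ba$loa_upper_ci
  } else {
    bias_ci <- lo_ci <- hi_ci <- c(NA_real_, NA_real_)
  }
  tibble::tibble(
    n_evaluated = n,
    p10 = p_within(predicted, actual, 0.10),
    p20 = p_within(predicted, actual, 0.20),
    mpe = mean_percentage_error(predicted, actual),
    ba_bias = bias, ba_sd = s,
    ba_loa_lower = loa[1L], ba_loa_upper = loa[2L],
    ba_bias_ci_lo = bias_ci[1L], ba_bias_ci_hi = bias_ci[2L],
    ba_loa_lower_ci_lo = lo_ci[1L], ba_loa_lower_ci_hi = lo_ci[2L],
    ba_loa_upper_ci_lo = hi_ci[1L], ba_loa_upper_ci_hi = hi_ci[2L],
    n_implausible = sum(predicted <= 0)
  )
}

#' Accuracy of weight-prediction equations, overall and by stratum
#'
#' Runs every requested equation over the record set and summarizes accuracy
#' (P10, P20, MPE, Bland-Altman bias and limits of agreement with 95% CIs)
#' for each requested stratification axis: `overall`, `sex` (male/female) and
#' `nutrition` (WHO BMI category computed from each record's measured weight
#' and height). Non-evaluable predictions are excluded pairwise per equation;
#' `n_evaluated` reports how many pairs entered each cell. Strata with no
#' records are emitted with `n_evaluated = 0` and NA metrics. Predicted
#' weights at or below zero are counted in `n_implausible`.
#'
#' @param records Record tibble carrying measured `weight_kg` (and
#'   `height_cm` when the nutrition axis is requested).
#' @param equation_ids Equation ids or `"all"`.
#' @param axes Subset of `c("overall", "sex", "nutrition")`.
#' @return Tibble with one row per axis level and equation: `axis`, `level`,
#'   `equation`, `n_evaluated`, `p10`, `p20`, `mpe`, Bland-Altman columns and
#'   `n_implausible`.
#' @export
stratified_accuracy <- function(records, equation_ids = "all",
                                axes = c("overall", "sex", "nutrition")) {
  axes <- match.arg(axes, several.ok = TRUE)
  ids <- resolve_equation_ids(equation_ids)
  records <- tibble::as_tibble(records)
  if (!"weight_kg" %in% names(records) || anyNA(records$weight_kg)) {
    stop("records must carry a complete measured weight_kg column", call. = FALSE)
  }

  preds <- predict_all(records, ids)
  base <- tibble::tibble(
    participant_id = as.character(records$participant_id),
    actual = records$weight_kg,
    sex = normalize_sex(records$sex)
  )
  if ("nutrition" %in% axes) {
    base$nutrition <- as.character(classify_nutrition(bmi(records$weight_kg, records$height_cm)))
  }
  joined <- dplyr::inner_join(preds, base, by = "participant_id")

  strata <- list()
  if ("overall" %in% axes) {
    strata <- c(strata, list(list(axis = "overall", level = "overall",
                                  keep = rep(TRUE, nrow(joined)))))
  }
  if ("sex" %in% axes) {
    for (s in c("male", "female")) {
      strata <- c(strata, list(list(axis = "sex", level = s, keep = joined$sex == s)))
    }
  }
  if ("nutrition" %in% axes) {
    for (lvl in NUTRITION_LEVELS) {
      strata <- c(strata, list(list(axis = "nutrition", level = lvl,
                                    keep = joined$nutrition == lvl)))
    }
  }

  rows <- lapply(strata, function(st) {
    dplyr::bind_rows(lapply(ids, function(id) {
      cell <- joined[st$keep & joined$equation == id & joined$evaluable, ]
      dplyr::bind_cols(
        tibble::tibble(axis = st$axis, level = st$level, equation = id),
        accuracy_row(cell$predicted_kg, cell$actual)
      )
    }))
  })
  dplyr::bind_rows(rows)
}

check_paired <- function(predicted, actual, min_n = 1L, msg = NULL) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must be paired vectors of equal length", call. = FALSE)
  }
  if (length(predicted) < min_n) {
    stop(msg %||% sprintf("need at least %d pair(s)", min_n), call. = FALSE)
  }
  invisible(TRUE)
}
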