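#' Numeric sex code used inside weight-prediction equations
#'
#' Several published equations carry sex as a numeric regressor rather than
#' as separate male/female coefficient sets. The convention in this
#' literature is male = 1, female = 2.
#'
#' @param sex Character vector of `"male"` / `"female"` labels (see
#'   [normalize_sex()] for accepted aliases).
#' @return Integer vector: 1 for male, 2 for female.
#' @examples
#' sex_code(c("male", "female"))
#' @export
sex_code <- function(sex) {
  sex <- normalize_sex(sex)
  unname(c(male = 1L, female = 2L)[sex])
}

#' Normalize sex labels
#'
#' Accepts the usual encodings found in field data: `male`/`female`,
#' `m`/`f` (any case), and the numeric codes `1`/`2`.
#'
#' @param sex Character or numeric vector.
#' @return Character vector of `"male"` / `"female"`.
#' @export
normalize_sex <- function(sex) {
  key <- tolower(trimws(as.character(sex)))
  out <- c(
    male = "male", m = "male", `1` = "male",
    female = "female", f = "female", `2` = "female"
  )[key]
  if (anyNA(out[!is.na(key)]) || anyNA(key)) {
    bad <- unique(sex[is.na(out) | is.na(key)])
    stop("unrecognized sex label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(out)
}

# Measurement columns an AnthropometricRecord may carry, with units encoded
# in the canonical names (cm for lengths/circumferences, mm for skinfold).
RECORD_COLUMNS <- c(
  "participant_id", "sex", "age_years", "weight_kg", "height_cm",
  "mac_cm", "ac_cm", "cc_cm", "hc_cm", "kh_cm", "sst_mm"
)

MEASUREMENT_COLUMNS <- setdiff(RECORD_COLUMNS, c("participant_id", "sex"))

# Declarative equation registry. Coefficients are transcribed verbatim from
# the source publications at full printed precision; `sex_code` is a
# pseudo-variable (male = 1, female = 2) resolved from the record's sex.
# provenance_r2 is metadata only and never enters a computation.
.equation_registry <- list(
  Ch = list(
    id = "Ch", name = "Chumlea",
    sex_specific = TRUE,
    variables = c("mac_cm", "cc_cm", "sst_mm", "kh_cm"),
    coefficients = list(
      male   = c(mac_cm = 1.73, cc_cm = 0.98, sst_mm = 0.37, kh_cm = 1.16),
      female = c(mac_cm = 0.98, cc_cm = 1.27, sst_mm = 0.40, kh_cm = 0.87)
    ),
    intercept = c(male = -81.69, female = -62.35),
    provenance_r2 = c(male = 0.90, female = 0.85)
  ),
  R1 = list(
    id = "R1", name = "Rabito 1",
    sex_specific = FALSE,
    variables = c("mac_cm", "ac_cm", "cc_cm", "sst_mm"),
    coefficients = c(mac_cm = 0.5030, ac_cm = 0.5632, cc_cm = 1.3180, sst_mm = 0.0339),
    intercept = -43.1560,
    provenance_r2 = 0.93
  ),
  R2 = list(
    id = "R2", name = "Rabito 2",
    sex_specific = FALSE,
    variables = c("mac_cm", "ac_cm", "cc_cm"),
    coefficients = c(mac_cm = 0.4808, ac_cm = 0.5646, cc_cm = 1.316),
    intercept = -42.2450,
    provenance_r2 = 0.93
  ),
  R3 = list(
    id = "R3", name = "Rabito 3",
    sex_specific = FALSE,
    variables = c("mac_cm", "ac_cm", "cc_cm"),
    coefficients = c(mac_cm = 0.5759, ac_cm = 0.5263, cc_cm = 1.2452, sex_code = -4.8689),
    intercept = -32.9241,
    provenance_r2 = 0.94
  ),
  Cr = list(
    id = "Cr", name = "Crandall",
    sex_specific = TRUE,
    variables = c("mac_cm", "height_cm"),
    coefficients = list(
      male   = c(mac_cm = 3.29, height_cm = 0.43),
      female = c(mac_cm = 2.15, height_cm = 0.54)
    ),
    intercept = c(male = -93.2, female = -64.6),
    provenance_r2 = c(male = 0.59, female = 0.55)
  ),
  L = list(
    id = "L", name = "Lorenz",
    sex_specific = TRUE,
    variables = c("height_cm", "ac_cm", "hc_cm"),
    coefficients = list(
      male   = c(height_cm = 0.60035, ac_cm = 0.785, hc_cm = 0.392),
      female = c(height_cm = 0.4053, ac_cm = 0.325, hc_cm = 0.836)
    ),
    intercept = c(male = -137.432, female = -110.924),
    provenance_r2 = c(male = 0.85, female = 0.82)
  ),
  KK = list(
    id = "KK", name = "Kokong",
    sex_specific = FALSE,
    variables = "height_cm",
    coefficients = c(height_cm = 1),
    intercept = -100,
    provenance_r2 = 1.0
  ),
  J = list(
    id = "J", name = "Jung",
    sex_specific = TRUE,
    variables = c("kh_cm", "mac_cm", "age_years"),
    coefficients = list(
      male   = c(kh_cm = 0.928, mac_cm = 2.508, age_years = -0.144),
      female = c(kh_cm = 0.826, mac_cm = 2.116, age_years = -0.133)
    ),
    intercept = c(male = -42.543, female = -31.486),
    # the source prints female R^2 = 0.133; kept verbatim as provenance
    provenance_r2 = c(male = 0.81, female = 0.133)
  ),
  C = list(
    id = "C", name = "Cattermole",
    sex_specific = FALSE,
    variables = "mac_cm",
    coefficients = c(mac_cm = 4),
    intercept = -50,
    provenance_r2 = NA_real_
  )
)

#' Weight-prediction equation registry
#'
#' Returns the registry of the nine evaluable published equations, as a named
#' list of equation specifications (id, display name, required variables,
#' coefficients, intercept, sex handling, provenance R-squared). The registry
#' is data, not code, so the transcription can be audited in one place.
#'
#' @return Named list of equation specs, one per equation id.
#' @examples
#' names(equation_registry())
#' equation_registry()$R3$coefficients
#' @export
equation_registry <- function() .equation_registry

#' Equation identifiers known to the registry
#' @return Character vector of equation ids.
#' @export
equation_ids <- function() names(.equation_registry)

get_equation <- function(equation_id) {
  spec <- .equation_registry[[equation_id]]
  if (is.null(spec)) {
    stop("unknown equation id '", equation_id, "'; registry holds: ",
         paste(equation_ids(), collapse = ", "), call. = FALSE)
  }
  spec
}

#' Variables an equation requires on a record
#'
#' Includes `"sex"` when the equation has per-sex coefficient sets or carries
#' a coded-sex term.
#'
#' @param equation_id Equation id (see [equation_ids()]).
#' @return Character vector of record column names.
#' @export
required_variables <- function(equation_id) {
  spec <- get_equation(equation_id)
  vars <- spec$variables
  uses_sex <- spec$sex_specific ||
    (!spec$sex_specific && "sex_code" %in% names(spec$coefficients))
  if (uses_sex) vars <- c(vars, "sex")
  vars
}

# Vectorized evaluator over a record tibble. Returns predictions with NA
# where a required variable is missing, plus the per-record evaluability
# mask and which variables were missing.
eval_equation <- function(records, equation_id) {
  spec <- get_equation(equation_id)
  n <- nrow(records)
  req <- required_variables(equation_id)
  absent_cols <- setdiff(req, names(records))

  present <- matrix(TRUE, nrow = n, ncol = length(req), dimnames = list(NULL, req))
  for (v in req) {
    present[, v] <- if (v %in% absent_cols) FALSE else !is.na(records[[v]])
  }
  evaluable <- apply(present, 1L, all)

  pred <- rep(NA_real_, n)
  if (any(evaluable)) {
    if (spec$sex_specific) {
      sexes <- normalize_sex(records$sex[evaluable])
      idx <- which(evaluable)
      for (s in c("male", "female")) {
        rows <- idx[sexes == s]
        if (!length(rows)) next
        coef <- spec$coefficients[[s]]
        acc <- rep(spec$intercept[[s]], length(rows))
        for (v in names(coef)) acc <- acc + coef[[v]] * records[[v]][rows]
        pred[rows] <- acc
      }
    } else {
      coef <- spec$coefficients
      idx <- which(evaluable)
      acc <- rep(spec$intercept, length(idx))
      for (v in names(coef)) {
        x <- if (v == "sex_code") sex_code(records$sex[idx]) else records[[v]][idx]
        acc <- acc + coef[[v]] * x
      }
      pred[idx] <- acc
    }
  }

  missing_vars <- lapply(seq_len(n), function(i) req[!present[i, ]])
  list(predicted_kg = pred, evaluable = evaluable, missing = missing_vars)
}

#' Predict weight for a single record
#'
#' Evaluates one equation on one anthropometric record, exactly as published
#' (no intermediate rounding) and dispatching to the correct sex branch for
#' the sex-specific equations.
#'
#' @param record A one-row data frame or named list with the canonical
#'   record fields (`sex`, `age_years`, `height_cm`, `mac_cm`, `ac_cm`,
#'   `cc_cm`, `hc_cm`, `kh_cm`, `sst_mm`); only the equation's required
#'   variables need be present.
#' @param equation_id Equation id (see [equation_ids()]).
#' @return Predicted weight in kg (a single numeric, full floating
#'   precision). Negative values are possible for extreme inputs and are
#'   returned as-is; report writers flag them as implausible.
#' @examples
#' predict_weight(list(mac_cm = 28.6, ac_cm = 81.8, cc_cm = 34.5, sex = "male"), "R3")
#' predict_weight(list(height_cm = 162.5), "KK")
#' @export
predict_weight <- function(record, equation_id) {
  rec <- tibble::as_tibble(record[!vapply(record, is.null, logical(1))])
  if (nrow(rec) != 1L) stop("predict_weight() expects exactly one record", call. = FALSE)
  res <- eval_equation(rec, equation_id)
  if (!res$evaluable) {
    stop("equation '", equation_id, "' is not evaluable: missing required variable(s) ",
         paste(res$missing[[1L]], collapse = ", "), call. = FALSE)
  }
  res$predicted_kg
}

#' Predict weight for a record set under one or more equations
#'
#' Evaluates every requested equation on every record. Records on which an
#' equation is missing a required variable are flagged non-evaluable, never
#' imputed. Row order is deterministic: input record order within equation,
#' equations in the requested order.
#'
#' @param records Record tibble (see [read_records()] or [generate_cohort()]).
#' @param equation_ids Character vector of equation ids, or `"all"` (default)
#'   for the full registry.
#' @return Tibble with columns `participant_id`, `equation`, `predicted_kg`,
#'   `evaluable`, `missing_variables` (comma-separated, `""` when evaluable).
#' @export
predict_all <- function(records, equation_ids = "all") {
  ids <- resolve_equation_ids(equation_ids)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    warning("empty record set: returning an empty prediction table", call. = FALSE)
    return(tibble::tibble(
      participant_id = character(), equation = character(),
      predicted_kg = numeric(), evaluable = logical(),
      missing_variables = character()
    ))
  }
  pid <- if ("participant_id" %in% names(records)) {
    as.character(records$participant_id)
  } else {
    as.character(seq_len(nrow(records)))
  }
  out <- lapply(ids, function(id) {
    res <- eval_equation(records, id)
    tibble::tibble(
      participant_id = pid,
      equation = id,
      predicted_kg = res$predicted_kg,
      evaluable = res$evaluable,
      missing_variables = vapply(res$missing, paste, character(1), collapse = ",")
    )
  })
  dplyr::bind_rows(out)
}

resolve_equation_ids <- function(equation_ids) {
  if (identical(equation_ids, "all")) return(equation_ids())
  ids <- as.character(equation_ids)
  unknown <- setdiff(ids, equation_ids())
  if (length(unknown)) {
    stop("unknown equation id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids
}

#' Write the equation registry to a human-readable YAML file
#'
#' One block per equation: id, display name, required variables, coefficient
#' sets (per sex where applicable), intercept and provenance R-squared, so
#' the transcription can be audited or swapped out.
#'
#' @param path Output file path.
#' @param registry Registry list (defaults to the built-in registry).
#' @return `path`, invisibly.
#' @export
write_equation_registry <- function(path, registry = equation_registry()) {
  yaml::write_yaml(lapply(registry, function(spec) {
    spec$coefficients <- if (spec$sex_specific) {
      lapply(spec$coefficients, as.list)
    } else {
      as.list(spec$coefficients)
    }
    spec$intercept <- as.list(spec$intercept)
    spec$provenance_r2 <- as.list(spec$provenance_r2)
    spec
  }), path, precision = 15L)
  invisible(path)
}

#' Read an equation registry from a YAML file
#'
#' Inverse of [write_equation_registry()]; validates the structural
#' invariants (coefficient variables declared, both sex branches present for
#' sex-specific equations) before returning.
#'
#' @param path YAML file written by [write_equation_registry()] or edited by
#'   hand in the same shape.
#' @return Registry list usable wherever the built-in registry is.
#' @export
read_equation_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- lapply(raw, function(spec) {
    spec$sex_specific <- isTRUE(spec$sex_specific)
    if (spec$sex_specific) {
      spec$coefficients <- lapply(spec$coefficients, function(x) unlist(x))
      spec$intercept <- unlist(spec$intercept)
    } else {
      spec$coefficients <- unlist(spec$coefficients)
      spec$intercept <- unlist(spec$intercept)[[1L]]
    }
    spec$variables <- as.character(unlist(spec$variables))
    spec$provenance_r2 <- unlist(spec$provenance_r2)
    spec
  })
  names(reg) <- vapply(reg, `[[`, character(1), "id")
  for (spec in reg) validate_equation_spec(spec)
  reg
}

validate_equation_spec <- function(spec) {
  coef_vars <- if (spec$sex_specific) {
    if (!all(c("male", "female") %in% names(spec$coefficients))) {
      stop("equation '", spec$id, "': sex-specific spec must carry both male and female coefficient sets",
           call. = FALSE)
    }
    unique(unlist(lapply(spec$coefficients, names)))
  } else {
    names(spec$coefficients)
  }
  declared <- c(spec$variables, "sex_code")
  if (!all(coef_vars %in% declared)) {
    stop("equation '", spec$id, "': coefficient variable(s) not declared: ",
         paste(setdiff(coef_vars, declared), collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}
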