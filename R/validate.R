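#' Run the full validation pipeline over a record set
#'
#' Composes prediction, stratified accuracy, Bland-Altman plot data and
#' cohort descriptives into one report bundle, together with a run manifest
#' recording the inputs and the statistical conventions in force (percentage
#' error sign, LOA multiplier, BMI cutoffs, quantile definition), so a
#' report can be reproduced and audited. Identical inputs yield
#' byte-identical reports.
#'
#' @param records Record tibble with measured `weight_kg` and `height_cm`.
#' @param equation_ids Equation ids or `"all"`.
#' @param axes Stratification axes for the subgroup report; the overall
#'   report is always produced.
#' @return Object of class `validation_bundle`: list with `overall`
#'   (per-equation accuracy), `subgroup` (per stratum), `ba_points`
#'   (per-pair Bland-Altman coordinates and the three reference lines per
#'   equation), `descriptives`, `predictions` and `manifest`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_per_stratum = 5, seed = 1))
#' bundle <- run_validation(cohort)
#' bundle$overall[, c("equation", "p10", "p20")]
#' @export
run_validation <- function(records, equation_ids = "all",
                           axes = c("sex", "nutrition")) {
  ids <- resolve_equation_ids(equation_ids)
  axes <- match.arg(axes, c("sex", "nutrition"), several.ok = TRUE)
  records <- tibble::as_tibble(records)

  overall <- stratified_accuracy(records, ids, axes = "overall")
  subgroup <- stratified_accuracy(records, ids, axes = axes)

  preds <- predict_all(records, ids)
  actual <- tibble::tibble(
    participant_id = as.character(records$participant_id),
    actual_kg = records$weight_kg
  )
  pred_full <- dplyr::inner_join(preds, actual, by = "participant_id")
  ba_points <- dplyr::transmute(
    dplyr::filter(pred_full, .data$evaluable),
    equation = .data$equation,
    participant_id = .data$participant_id,
    pair_mean = (.data$predicted_kg + .data$actual_kg) / 2,
    difference = .data$predicted_kg - .data$actual_kg
  )
  ba_lines <- dplyr::select(
    overall, "equation",
    bias = "ba_bias", loa_lower = "ba_loa_lower", loa_upper = "ba_loa_upper"
  )

  n_implausible <- sum(pred_full$evaluable & pred_full$predicted_kg <= 0)
  if (n_implausible > 0) {
    warning(n_implausible,
            " predicted weight(s) were non-positive; flagged implausible in the reports",
            call. = FALSE)
  }

  syn <- attr(records, "synthetic_config")
  planted <- attr(records, "planted_truth")
  manifest <- list(
    package = "anthroweight",
    package_version = as.character(utils::packageVersion("anthroweight")),
    n_records = nrow(records),
    equations = ids,
    axes = axes,
    conventions = list(
      percentage_error = "100 * (predicted - actual) / actual",
      bland_altman_difference = "predicted - actual",
      loa_multiplier = 1.96,
      loa_ci = "Student-t at n-1 df; SE(bias) = s/sqrt(n), SE(LOA) = s*sqrt(3/n)",
      bmi_cutoffs = "WHO adult: <18.5 / [18.5,25) / [25,30) / >=30",
      p_within_boundary = "inclusive (<= tolerance)",
      quantile_type = 7,
      display_rounding = "2 decimal places, half-up"
    ),
    synthetic_seed = if (!is.null(syn)) syn$seed,
    planted_truth = planted
  )

  structure(
    list(overall = overall, subgroup = subgroup,
         ba_points = ba_points, ba_lines = ba_lines,
         descriptives = describe_cohort(records),
         predictions = pred_full, manifest = manifest),
    class = "validation_bundle"
  )
}

#' @export
print.validation_bundle <- function(x, ...) {
  cat(sprintf("validation of %d equation(s) on %d record(s)\n",
              length(x$manifest$equations), x$manifest$n_records))
  disp <- dplyr::mutate(
    dplyr::select(x$overall, "equation", "n_evaluated", "p10", "p20", "mpe",
                  "ba_loa_lower", "ba_loa_upper"),
    dplyr::across(dplyr::where(is.double), \(v) round_half_up(v, 2))
  )
  print(as.data.frame(disp), row.names = FALSE)
  invisible(x)
}

# Round half away from zero at `digits` decimals (base round() is half-even;
# published tables in this literature round half-up).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a validation bundle to disk
#'
#' Emits the overall accuracy table and the subgroup table as CSV (both the
#' full-precision machine columns and 2-decimal display columns), the
#' Bland-Altman per-pair points with the bias/LOA reference lines as CSV for
#' external plotting, the descriptive table as CSV, the complete bundle as
#' JSON, and a YAML run manifest. Output is deterministic: identical bundles
#' produce byte-identical files.
#'
#' @param bundle A [run_validation()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_validation_reports <- function(bundle, dir) {
  stopifnot(inherits(bundle, "validation_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    overall = file.path(dir, "accuracy_overall.csv"),
    subgroup = file.path(dir, "accuracy_subgroup.csv"),
    ba_points = file.path(dir, "bland_altman_points.csv"),
    descriptives = file.path(dir, "descriptives.csv"),
    json = file.path(dir, "report.json"),
    manifest = file.path(dir, "manifest.yaml")
  )

  overall <- add_display_columns(bundle$overall,
                                 c("p10", "p20", "mpe", "ba_bias",
                                   "ba_loa_lower", "ba_loa_upper"))
  overall$implausible_flag <- bundle$overall$n_implausible > 0
  readr::write_csv(overall, paths[["overall"]], na = "", progress = FALSE)

  subgroup <- add_display_columns(bundle$subgroup, c("p10", "p20"))
  readr::write_csv(subgroup, paths[["subgroup"]], na = "", progress = FALSE)

  ba <- dplyr::left_join(bundle$ba_points, bundle$ba_lines, by = "equation")
  readr::write_csv(ba, paths[["ba_points"]], na = "", progress = FALSE)

  readr::write_csv(bundle$descriptives, paths[["descriptives"]], na = "", progress = FALSE)

  jsonlite::write_json(
    list(overall = bundle$overall, subgroup = bundle$subgroup,
         descriptives = bundle$descriptives, manifest = bundle$manifest),
    paths[["json"]], auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  yaml::write_yaml(bundle$manifest, paths[["manifest"]])
  invisible(paths)
}

add_display_columns <- function(tbl, cols) {
  for (col in cols) {
    tbl[[paste0(col, "_display")]] <- ifelse(
      is.na(tbl[[col]]), NA_character_,
      sprintf(paste0("%.2f"), round_half_up(tbl[[col]], 2))
    )
  }
  tbl
}

#' Bland-Altman plot for one equation
#'
#' Per-pair differences against pair means, with the bias (dashed) and 95%
#' limits of agreement (dotted) as horizontal reference lines.
#'
#' @param bundle A [run_validation()] result.
#' @param equation_id Equation to plot.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(bundle, equation_id) {
  stopifnot(inherits(bundle, "validation_bundle"))
  resolve_equation_ids(equation_id)
  pts <- dplyr::filter(bundle$ba_points, .data$equation == equation_id)
  lines <- dplyr::filter(bundle$ba_lines, .data$equation == equation_id)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$pair_mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = lines$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(lines$loa_lower, lines$loa_upper),
                        linetype = "dotted") +
    ggplot2::labs(
      x = "Mean of predicted and measured weight (kg)",
      y = "Predicted - measured weight (kg)",
      title = paste0("Bland-Altman agreement: ",
                     equation_registry()[[equation_id]]$name)
    ) +
    ggplot2::theme_minimal()
}
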