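# Independent oracles, deliberately written as literal straight-line
# arithmetic (one function per equation and sex branch), never touching the
# package's registry or evaluator.

oracle_predict <- function(id, sex = NULL, age = NA, h = NA, mac = NA, ac = NA,
                           cc = NA, hc = NA, kh = NA, sst = NA) {
  s <- if (!is.null(sex) && sex == "male") 1 else 2
  switch(id,
    Ch = if (sex == "male") {
      (mac * 1.73) + (cc * 0.98) + (sst * 0.37) + (kh * 1.16) - 81.69
    } else {
      (mac * 0.98) + (cc * 1.27) + (sst * 0.40) + (kh * 0.87) - 62.35
    },
    R1 = (0.5030 * mac) + (0.5632 * ac) + (1.3180 * cc) + (0.0339 * sst) - 43.1560,
    R2 = (0.4808 * mac) + (0.5646 * ac) + (1.316 * cc) - 42.2450,
    R3 = (0.5759 * mac) + (0.5263 * ac) + (1.2452 * cc) - (4.8689 * s) - 32.9241,
    Cr = if (sex == "male") {
      -93.2 + (3.29 * mac) + (0.43 * h)
    } else {
      -64.6 + (2.15 * mac) + (0.54 * h)
    },
    L = if (sex == "male") {
      -137.432 + (0.60035 * h) + (0.785 * ac) + (0.392 * hc)
    } else {
      -110.924 + (0.4053 * h) + (0.325 * ac) + (0.836 * hc)
    },
    KK = h - 100,
    J = if (sex == "male") {
      kh * 0.928 + mac * 2.508 - age * 0.144 - 42.543
    } else {
      kh * 0.826 + mac * 2.116 - age * 0.133 - 31.486
    },
    C = (4 * mac) - 50,
    stop("oracle has no equation ", id)
  )
}

# Random complete records spanning (generously) the adult measurement ranges.
random_records <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = runif(n, 18, 90),
    weight_kg = runif(n, 35, 140),
    height_cm = runif(n, 140, 200),
    mac_cm = runif(n, 18, 42),
    ac_cm = runif(n, 55, 130),
    cc_cm = runif(n, 25, 48),
    hc_cm = runif(n, 75, 135),
    kh_cm = runif(n, 40, 62),
    sst_mm = runif(n, 4, 40)
  )
}

oracle_predict_record <- function(id, rec) {
  oracle_predict(
    id, sex = rec$sex, age = rec$age_years, h = rec$height_cm,
    mac = rec$mac_cm, ac = rec$ac_cm, cc = rec$cc_cm, hc = rec$hc_cm,
    kh = rec$kh_cm, sst = rec$sst_mm
  )
}

# Brute-force Bland-Altman oracle: explicit loops, no stats shortcuts.
oracle_bland_altman <- function(predicted, actual) {
  n <- length(predicted)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- predicted[i] - actual[i]
  bias <- 0
  for (i in seq_len(n)) bias <- bias + d[i]
  bias <- bias / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - bias)^2
  s <- sqrt(ss / (n - 1))
  tcrit <- stats::qt(0.975, n - 1)
  list(
    bias = bias, sd = s,
    loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
    bias_ci = c(bias - tcrit * s / sqrt(n), bias + tcrit * s / sqrt(n)),
    loa_lower_ci = bias - 1.96 * s + c(-1, 1) * tcrit * s * sqrt(3 / n),
    loa_upper_ci = bias + 1.96 * s + c(-1, 1) * tcrit * s * sqrt(3 / n)
  )
}

# Brute-force MPE oracle.
oracle_mpe <- function(predicted, actual) {
  total <- 0
  for (i in seq_along(predicted)) {
    total <- total + 100 * (predicted[i] - actual[i]) / actual[i]
  }
  total / length(predicted)
}
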