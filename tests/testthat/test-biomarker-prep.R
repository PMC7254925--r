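# Biomarker construction: urine/energy conversions, completeness rules,
# calibration, densities and agreement summaries.

test_that("protein and potassium conversions apply the excretion fractions", {
  expect_equal(protein_from_nitrogen(0), 0)
  expect_equal(protein_from_nitrogen(11.34), 11.34 / 0.81 * 6.25)
  expect_equal(protein_from_nitrogen(11.34), 87.5)
  expect_equal(potassium_from_excretion(0), 0)
  expect_equal(potassium_from_excretion(1.68), 2.10)
  expect_error(protein_from_nitrogen(-1), ">= 0")
  expect_error(potassium_from_excretion(-0.1), ">= 0")
})

test_that("conversions are linear and strictly monotone (property)", {
  set.seed(21)
  x <- stats::runif(50, 0.01, 30)
  expect_equal(protein_from_nitrogen(2 * x), 2 * protein_from_nitrogen(x))
  expect_equal(potassium_from_excretion(2 * x),
               2 * potassium_from_excretion(x))
  expect_true(all(diff(protein_from_nitrogen(sort(x))) > 0))
  # rescaling is monotone decreasing in recovery
  rec <- sort(stats::runif(20, 40, 110))
  expect_true(all(diff(rescale_for_recovery(10, rec)) < 0))
})

test_that("sugar calibration applies the published coefficients", {
  expect_equal(calibrate_sugar_biomarker(5, 1, log(50)),
               5 - 1.67 - 0.02 + 0.71 * log(50))
  expect_equal(round(calibrate_sugar_biomarker(5, 1, log(50)), 3), 6.088)
  # sex coefficient reads off directly
  expect_equal(calibrate_sugar_biomarker(5, 0, 3.9) -
                 calibrate_sugar_biomarker(5, 1, 3.9), 0.02)
  # zero coefficients give the identity
  id <- calibration_coefficients(0, 0, 0)
  expect_equal(calibrate_sugar_biomarker(4.2, 1, 3.5, id), 4.2)
  expect_error(calibrate_sugar_biomarker(5, 2, 3.9), "sex")
})

test_that("PABA classification follows the completeness rules", {
  expect_equal(classify_paba(93, 0, "sensitivity"), "complete")
  expect_equal(classify_paba(60, 0, "sensitivity"), "rescalable")
  expect_equal(classify_paba(40, 0, "sensitivity"), "excluded")
  expect_equal(classify_paba(120, 0, "sensitivity"), "excluded")
  expect_equal(classify_paba(100, 2, "main"), "excluded")
  expect_equal(classify_paba(40, 0, "main"), "complete")
  # closed boundaries: 85 and 110 complete, 50 rescalable
  expect_equal(classify_paba(c(85, 110, 50), 0, "sensitivity"),
               c("complete", "complete", "rescalable"))
})

test_that("PABA classification partitions its domain (property)", {
  set.seed(22)
  rec <- c(stats::runif(200, 0, 130), 0, 50, 85, 110)
  mv <- sample(0:3, length(rec), replace = TRUE)
  for (mode in c("main", "sensitivity")) {
    st <- classify_paba(rec, mv, mode)
    expect_true(all(st %in% c("complete", "rescalable", "excluded")))
    expect_length(st, length(rec))
    expect_true(all(st[mv >= 2] == "excluded"))
  }
})

test_that("recovery rescaling matches the proportional rule", {
  expect_equal(rescale_for_recovery(10, 62), 10 * 93 / 62)
  expect_equal(rescale_for_recovery(10, 62), 15, tolerance = 1e-12)
  expect_equal(rescale_for_recovery(7.3, 93), 7.3)
  expect_error(rescale_for_recovery(1, 0), "> 0")
})

test_that("TEE satisfies its defining identity and the weight-change rule", {
  r <- total_energy_expenditure(6.3, 3.6, 0)
  expect_equal(r$tee, 11.0)
  expect_false(r$excluded)
  # TEE - 0.1 TEE = REE + AEE exactly
  set.seed(23)
  ree <- stats::runif(30, 4, 9); aee <- stats::runif(30, 1, 5)
  r <- total_energy_expenditure(ree, aee, 0)
  expect_equal(r$tee - 0.1 * r$tee, ree + aee)
  r <- total_energy_expenditure(7, 3, 6.2)
  expect_true(r$excluded)
  expect_true(is.na(r$tee))
  expect_false(total_energy_expenditure(7, 3, -4.9)$excluded)
  expect_error(total_energy_expenditure(-1, 3, 0), ">= 0")
})

test_that("nutrient density is a scale-invariant ratio", {
  expect_equal(round(nutrient_density(85.0, 8.7), 2), 9.77)
  expect_equal(nutrient_density(0, 5), 0)
  expect_equal(nutrient_density(2 * 85, 2 * 8.7), nutrient_density(85, 8.7))
  expect_error(nutrient_density(10, 0), "> 0")
})

test_that("geometric mean matches brute-force recomputation", {
  expect_equal(geometric_mean_ci(c(1, 10, 100))$geometric_mean, 10)
  g <- geometric_mean_ci(rep(7, 5))
  expect_equal(g$geometric_mean, 7)
  expect_equal(g$ci, c(7, 7))
  set.seed(24)
  x <- stats::rlnorm(100, 3, 0.4)
  g <- geometric_mean_ci(x)
  expect_equal(g$geometric_mean, exp(mean(log(x))), tolerance = 1e-12)
  tt <- stats::t.test(log(x))
  expect_equal(g$ci, exp(as.numeric(tt$conf.int)), tolerance = 1e-12)
  expect_error(geometric_mean_ci(c(1, 0, 2)), "positive")
})

test_that("mean percent difference implements the log-scale Bland-Altman rule", {
  x <- c(3.2, 4.1, 2.8)
  expect_equal(mean_percent_difference(x, x)$percent, 0)
  expect_equal(mean_percent_difference(x + log(1.12), x)$percent, 12,
               tolerance = 1e-10)
  set.seed(25)
  tool <- stats::rnorm(80, 4, 0.3); ref <- stats::rnorm(80, 4, 0.3)
  tool[c(3, 9)] <- NA
  got <- mean_percent_difference(tool, ref)
  d <- (tool - ref)[!is.na(tool - ref)]
  expect_equal(got$percent, 100 * (exp(mean(d)) - 1), tolerance = 1e-12)
  expect_equal(got$n, 78)
  expect_error(mean_percent_difference(NA_real_, 1), "no complete pairs")
})

test_that("raw-record preparation round-trips the simulated biomarkers", {
  sc <- quick_scenario(seed = 501)
  co <- generate_cohort(sc)
  raw <- generate_raw_records(sc, co)
  up <- prepare_urine_records(raw$urine, raw$covariates, mode = "sensitivity")
  ep <- prepare_energy_records(raw$energy)
  key <- function(d) paste(d$participant_id, d$occasion)
  bio <- function(nut) co[co$instrument == "biomarker" & co$nutrient == nut, ]
  for (case in list(list("protein", "protein_biomarker", TRUE),
                    list("potassium", "potassium_biomarker", TRUE),
                    list("total_sugars", "sugar_biomarker_calibrated",
                         FALSE))) {
    b <- bio(case[[1]])
    v <- up[[case[[2]]]][match(key(b), key(up))]
    if (case[[3]]) v <- log(v)
    ok <- up$paba_status[match(key(b), key(up))] != "excluded" & !is.na(v) &
      !is.na(b$value)
    expect_gt(sum(ok), 100)
    expect_lt(max(abs(v[ok] - b$value[ok])), 1e-10)
  }
  b <- bio("energy")
  v <- log(ep$tee[match(key(b), key(ep))])
  ok <- !is.na(v) & !is.na(b$value)
  expect_lt(max(abs(v[ok] - b$value[ok])), 1e-10)
})

test_that("re-rescaling is forbidden by the rescaled flag", {
  sc <- quick_scenario(seed = 502, n = 40)
  co <- generate_cohort(sc)
  raw <- generate_raw_records(sc, co)
  up <- prepare_urine_records(raw$urine, raw$covariates, mode = "sensitivity")
  expect_true(any(up$rescaled))
  expect_error(prepare_urine_records(up, raw$covariates,
                                     mode = "sensitivity"),
               "already")
})

test_that("excluded collections yield missing biomarkers", {
  urine <- data.frame(participant_id = c("a", "b", "c"), occasion = 1L,
                      urine_volume = 1.5, nitrogen = 10, potassium = 2,
                      sucrose = 40, fructose = 30,
                      paba_recovery = c(95, 40, 95),
                      missed_voids = c(0, 0, 2))
  covs <- data.frame(participant_id = c("a", "b", "c"), sex = c(0, 1, 0),
                     age = c(30, 45, 50))
  up <- prepare_urine_records(urine, covs, mode = "sensitivity")
  expect_equal(up$paba_status, c("complete", "excluded", "excluded"))
  expect_equal(is.na(up$protein_biomarker), c(FALSE, TRUE, TRUE))
  expect_equal(is.na(up$sugar_biomarker_calibrated), c(FALSE, TRUE, TRUE))
})
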