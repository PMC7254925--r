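# End-to-end orchestration: simulate (or load) -> biomarker prep -> ML fit ->
# validity metrics -> rendered tables shaped like a validation paper's
# geometric-means, single-administration and repeat-administration tables.

#' Round half away from zero
#'
#' Table rendering uses half-up rounding (0.425 -> 0.43) to match the
#' convention of the published tables; R's `round()` rounds half to even.
#' Applied only at render time — all internal computation keeps full
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Validity metrics table for repeat administrations
#'
#' Renders the closed-form extrapolation from printed single- and
#' two-administration metrics as a table over `k = 1..K`, with both
#' full-precision and 2-decimal (half-up) columns.
#'
#' @param lambda1,lambda2,rho1 Printed metrics (see
#'   [extrapolation_input()]).
#' @param K Maximum repeat count.
#' @return Data frame with columns `k`, `lambda`, `rho`, `lambda_2dp`,
#'   `rho_2dp`.
#' @export
#' @examples
#' extrapolation_table(0.27, 0.37, 0.40, K = 5)
extrapolation_table <- function(lambda1, lambda2, rho1, K = 5L) {
  tab <- extrapolate_from_pair(extrapolation_input(lambda1, lambda2, rho1),
                               k = seq_len(K))
  tab$lambda_2dp <- round_half_up(tab$lambda, 2L)
  tab$rho_2dp <- round_half_up(tab$rho, 2L)
  tab
}

# One bootstrap pass over participants computing lambda_k and rho_k for all
# requested k; returns point estimates and percentile CIs per k.
boot_metrics_k <- function(fit, instrument, ks, n_boot, seed, level = 0.95) {
  alpha <- (1 - level) / 2
  lam_hat <- attenuation_factor(fit$params, instrument, ks)
  rho_hat <- correlation_with_truth(fit$params, instrument, ks)
  lam_b <- matrix(NA_real_, n_boot, length(ks))
  rho_b <- matrix(NA_real_, n_boot, length(ks))
  set.seed(as.integer(seed))
  n <- nrow(fit$y)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    yb <- fit$y[sample.int(n, n, replace = TRUE), , drop = FALSE]
    pats <- suppressWarnings(pattern_stats(yb, warn_empty = FALSE))
    fb <- tryCatch(
      fit_patterns(pats, fit$design, fit$theta, fit$drift, maxit = 200L),
      error = function(e) NULL)
    if (is.null(fb) || fb$convergence != 0L) { failed <- failed + 1L; next }
    lam_b[b, ] <- attenuation_factor(fb$params, instrument, ks)
    rho_b[b, ] <- correlation_with_truth(fb$params, instrument, ks)
  }
  if (failed > 0.2 * n_boot)
    warning(failed, "/", n_boot, " bootstrap replicates failed", call. = FALSE)
  qs <- function(m, j, p) stats::quantile(m[, j], p, na.rm = TRUE, names = FALSE)
  data.frame(
    instrument = instrument, k = ks,
    lambda = lam_hat,
    lambda_lo = vapply(seq_along(ks), function(j) qs(lam_b, j, alpha), 0),
    lambda_hi = vapply(seq_along(ks), function(j) qs(lam_b, j, 1 - alpha), 0),
    rho = rho_hat,
    rho_lo = vapply(seq_along(ks), function(j) qs(rho_b, j, alpha), 0),
    rho_hi = vapply(seq_along(ks), function(j) qs(rho_b, j, 1 - alpha), 0),
    n_boot_used = n_boot - failed)
}

# Per-participant occasion means of log values for one nutrient/instrument.
participant_log_means <- function(cohort, nutrient, instrument) {
  d <- cohort[cohort$nutrient == nutrient & cohort$instrument == instrument, ]
  tapply(d$value, d$participant_id, mean, na.rm = TRUE)
}

# Replace the cohort's biomarker columns by the prepared-biomarker values,
# so the fit consumes what the prep stage produced.
merge_prepared <- function(cohort, urine_prepped, energy_prepped) {
  key <- function(id, occ) paste(id, occ, sep = "\r")
  replace_bio <- function(cohort, nutrient, tbl, col, already_log) {
    i <- which(cohort$nutrient == nutrient & cohort$instrument == "biomarker")
    j <- match(key(cohort$participant_id[i], cohort$occasion[i]),
               key(tbl$participant_id, tbl$occasion))
    v <- tbl[[col]][j]
    if (!already_log) v <- ifelse(!is.na(v) & v > 0, log(v), NA_real_)
    # cells missing in the original cohort stay missing
    v[is.na(cohort$value[i])] <- NA_real_
    cohort$value[i] <- v
    cohort
  }
  cohort <- replace_bio(cohort, "protein", urine_prepped,
                        "protein_biomarker", FALSE)
  cohort <- replace_bio(cohort, "potassium", urine_prepped,
                        "potassium_biomarker", FALSE)
  cohort <- replace_bio(cohort, "total_sugars", urine_prepped,
                        "sugar_biomarker_calibrated", TRUE)
  cohort <- replace_bio(cohort, "energy", energy_prepped, "tee", FALSE)
  cohort
}

#' Run the full validation analysis pipeline
#'
#' Simulates (or loads) a cohort, constructs biomarkers from raw records,
#' fits the measurement error model per nutrient, and renders three
#' tables: geometric means at the first visit (`table2`),
#' single-administration validity metrics with mean percentage differences
#' (`table3`), and repeat-administration metrics for `k = 1..K`
#' (`table4`), plus optional subgroup fits.  Deterministic given the
#' configuration: identical configs produce byte-identical outputs.
#'
#' @param config A named list (or path to a JSON file) with entries:
#'   * `scenario`: arguments for [simulation_scenario()] (at least `seed`),
#'     or `NULL` to load `cohort_file` instead;
#'   * `cohort_file`: path to a long-format delimited cohort (natural
#'     units, log-transformed on load) when not simulating;
#'   * `prep_mode`: `"main"` (default) or `"sensitivity"` urine handling;
#'   * `nutrients`: subset to analyse (default: all present);
#'   * `K`: maximum repeat administrations (default 5);
#'   * `n_boot`: bootstrap replicates for CIs (default 200);
#'   * `boot_seed`: seed for the bootstrap (default 1);
#'   * `strata`: character vector among `"sex"`, `"age"`, `"bmi"`
#'     (default none);
#'   * `out_dir`: directory for outputs, or `NULL` to skip writing.
#' @return (Invisibly) a list with `cohort`, `fits`, `table2`, `table3`,
#'   `table4`, `subgroups`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  K <- config$K %||% 5L
  n_boot <- config$n_boot %||% 200L
  boot_seed <- config$boot_seed %||% 1L
  prep_mode <- config$prep_mode %||% "main"
  design <- design_spec(config$scenario$n_occasions %||% 3L)

  if (!is.null(config$scenario)) {
    scenario <- do.call(simulation_scenario, config$scenario)
    cohort <- generate_cohort(scenario)
    raw <- generate_raw_records(scenario, cohort)
    urine_prepped <- prepare_urine_records(raw$urine, raw$covariates,
                                           mode = prep_mode)
    energy_prepped <- prepare_energy_records(raw$energy)
    cohort <- merge_prepared(cohort, urine_prepped, energy_prepped)
    seed_used <- scenario$seed
  } else if (!is.null(config$cohort_file)) {
    cohort <- read_cohort(config$cohort_file)
    scenario <- NULL
    seed_used <- NA_integer_
  } else stop("config needs either 'scenario' or 'cohort_file'",
              call. = FALSE)

  nutrients <- config$nutrients %||% unique(cohort$nutrient)

  # Table-2-like: first-visit geometric means per instrument, plus
  # nutrient densities (self-report density over own energy; biomarker
  # density over TEE).
  t2 <- list()
  for (nut in nutrients) {
    for (ins in c("webq", "recall", "biomarker")) {
      v <- cohort$value[cohort$nutrient == nut & cohort$instrument == ins &
                          cohort$occasion == 1L]
      g <- geometric_mean_ci(exp(v[!is.na(v)]))
      t2[[length(t2) + 1L]] <- data.frame(
        measure = "intake", nutrient = nut, instrument = ins, n = g$n,
        geometric_mean = g$geometric_mean,
        ci_lo = g$ci[1], ci_hi = g$ci[2])
    }
  }
  if ("energy" %in% nutrients) {
    for (nut in setdiff(nutrients, "energy")) {
      for (ins in c("webq", "recall", "biomarker")) {
        sel <- cohort$instrument == ins & cohort$occasion == 1L
        vn <- cohort$value[sel & cohort$nutrient == nut]
        ve <- cohort$value[sel & cohort$nutrient == "energy"]
        dens <- nutrient_density(exp(vn), exp(ve))
        dens <- dens[!is.na(dens)]
        if (!length(dens)) next
        g <- geometric_mean_ci(dens)
        t2[[length(t2) + 1L]] <- data.frame(
          measure = "density", nutrient = nut, instrument = ins, n = g$n,
          geometric_mean = g$geometric_mean,
          ci_lo = g$ci[1], ci_hi = g$ci[2])
      }
    }
  }
  table2 <- do.call(rbind, t2)

  fits <- list()
  t3 <- list(); t4 <- list()
  for (nut in nutrients) {
    fit <- fit_model(cohort, design = design, nutrient = nut)
    fits[[nut]] <- fit
    for (ins in c("webq", "recall")) {
      m1 <- boot_metrics_k(fit, ins, 1L, n_boot, boot_seed)
      pd <- mean_percent_difference(
        participant_log_means(cohort, nut, ins),
        participant_log_means(cohort, nut, "biomarker"))
      t3[[length(t3) + 1L]] <- data.frame(
        nutrient = nut, instrument = ins, n = fit$n,
        lambda = m1$lambda, lambda_lo = m1$lambda_lo,
        lambda_hi = m1$lambda_hi,
        rho = m1$rho, rho_lo = m1$rho_lo, rho_hi = m1$rho_hi,
        pct_diff = pd$percent, pct_lo = pd$ci[1], pct_hi = pd$ci[2])
    }
    mk <- boot_metrics_k(fit, "webq", seq_len(K), n_boot, boot_seed)
    mk <- cbind(nutrient = nut, mk)
    t4[[length(t4) + 1L]] <- mk
  }
  table3 <- do.call(rbind, t3)
  table4 <- do.call(rbind, t4)

  subgroups <- list()
  for (st in config$strata %||% character()) {
    sg <- fit_subgroups(cohort[cohort$nutrient %in% nutrients, ] |>
                          (\(d) cohort_measurements(d, TRUE))(),
                        stratifier = st, nutrient = nutrients[1L],
                        design = design)
    subgroups[[st]] <- data.frame(
      stratum = names(sg),
      n = vapply(sg, function(f) f$n, 0L),
      lambda1 = vapply(sg, function(f)
        attenuation_factor(f$params, "webq", 1L), 0),
      rho1 = vapply(sg, function(f)
        correlation_with_truth(f$params, "webq", 1L), 0))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("dietvalid")),
    seed = seed_used, boot_seed = boot_seed, n_boot = n_boot, K = K,
    prep_mode = prep_mode, nutrients = nutrients,
    scenario_hash = if (!is.null(scenario)) scenario_hash(scenario) else NA,
    n_participants = fits[[1L]]$n)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- c(paste("seed:", seed_used),
             paste("scenario_hash:", manifest$scenario_hash))
    render2 <- function(df, cols) {
      df[cols] <- lapply(df[cols], round_half_up, digits = 2L)
      df
    }
    write_cohort(render2(table2, c("geometric_mean", "ci_lo", "ci_hi")),
                 file.path(config$out_dir, "table2_geometric_means.tsv"),
                 header = hdr)
    write_cohort(render2(table3, c("lambda", "lambda_lo", "lambda_hi",
                                   "rho", "rho_lo", "rho_hi",
                                   "pct_diff", "pct_lo", "pct_hi")),
                 file.path(config$out_dir, "table3_single_administration.tsv"),
                 header = hdr)
    write_cohort(render2(table4, c("lambda", "lambda_lo", "lambda_hi",
                                   "rho", "rho_lo", "rho_hi")),
                 file.path(config$out_dir,
                           "table4_repeat_administrations.tsv"),
                 header = hdr)
    for (nut in nutrients)
      write_parameters(fits[[nut]]$params,
                       file.path(config$out_dir,
                                 paste0("parameters_", nut, ".json")))
    for (st in names(subgroups))
      write_cohort(render2(subgroups[[st]], c("lambda1", "rho1")),
                   file.path(config$out_dir, paste0("subgroup_", st, ".tsv")),
                   header = hdr)
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(config$out_dir, "run_manifest.json"))
  }
  invisible(list(cohort = cohort, fits = fits, table2 = table2,
                 table3 = table3, table4 = table4, subgroups = subgroups,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
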