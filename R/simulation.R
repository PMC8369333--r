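#' Simulation setting: two normal groups with a known true effect size
#'
#' @param label Short name of the setting (e.g. `"null"`, `"small"`).
#' @param mean1,sd1 Mean and standard deviation of group 1.
#' @param mean2,sd2 Mean and standard deviation of group 2. The second
#'   parameter of each group is a *standard deviation*, not a variance.
#' @return An object of class `simulation_setting` carrying `true_delta`,
#'   the standardized effect size implied by the group parameters.
#' @export
simulation_setting <- function(label, mean1, sd1, mean2, sd2) {
  if (!(sd1 > 0 && sd2 > 0)) stop("sds must be > 0", call. = FALSE)
  structure(
    list(label = label, mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
         true_delta = cohen_delta(mean1, sd1, mean2, sd2)),
    class = "simulation_setting"
  )
}

#' The four built-in effect-size settings
#'
#' `null`: both groups standard normal (true delta 0). `small`: Normal(2.89,
#' SD 1.84) vs Normal(3.5, SD 1.56), true delta about -0.357. `medium`:
#' Normal(254.08, SD 2.36) vs Normal(255.84, SD 3.04), about -0.646.
#' `large`: Normal(15.01, SD 3.4) vs Normal(19.91, SD 5.8), about -1.03.
#'
#' @return Named list of four [simulation_setting()] objects.
#' @export
builtin_settings <- function() {
  list(
    null = simulation_setting("null", 0, 1, 0, 1),
    small = simulation_setting("small", 2.89, 1.84, 3.5, 1.56),
    medium = simulation_setting("medium", 254.08, 2.36, 255.84, 3.04),
    large = simulation_setting("large", 15.01, 3.4, 19.91, 5.8)
  )
}

.all_methods <- c("jzs_bf", "oh_bf", "noh_bf", "hybrid_bf",
                  "rope_hpd95", "rope_full", "rope_support")

#' Simulation design for the Monte-Carlo error-rate study
#'
#' The defaults reproduce the study grid: four effect settings, per-group
#' sample sizes 10 to 200 in steps of 10, Cauchy prior scales `1/sqrt(2)`,
#' `1`, `sqrt(2)`, equivalence regions `[-0.05, 0.05]`, `[-0.1, 0.1]`,
#' `[-0.15, 0.15]`, 1000 replicates per cell, and six methods (the hybrid
#' model is implemented but excluded from the default grid).
#'
#' @param settings List of [simulation_setting()]s.
#' @param n_grid Per-group sample sizes.
#' @param prior_scales Cauchy prior scales on delta.
#' @param regions List of [equivalence_region()]s (standardized scale).
#' @param methods Subset of `"jzs_bf"`, `"oh_bf"`, `"noh_bf"`, `"hybrid_bf"`,
#'   `"rope_hpd95"`, `"rope_full"`, `"rope_support"`.
#' @param reps Replicates per cell.
#' @param master_seed Master seed; all per-replicate seeds derive from it.
#' @param grid_points Posterior grid resolution for the ROPE methods.
#' @param hpd_mass HPD mass for `rope_hpd95`.
#' @param support_k Corroboration factor for `rope_support`.
#' @param full_epsilon Excluded tail mass for `rope_full`.
#' @param bf_threshold Evidence threshold for [bf_decision()].
#' @param oh_null_scale_ratio Null/alternative scale ratio of the OH model.
#' @param hybrid_pi0 Point-null weight for the hybrid model.
#' @param failure_budget Maximum tolerated fraction of numerically failed
#'   replicates per cell (default 0: any failure aborts the cell).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(settings = builtin_settings(),
                              n_grid = seq(10, 200, by = 10),
                              prior_scales = c(1 / sqrt(2), 1, sqrt(2)),
                              regions = list(
                                equivalence_region(-0.05, 0.05),
                                equivalence_region(-0.1, 0.1),
                                equivalence_region(-0.15, 0.15)),
                              methods = c("jzs_bf", "oh_bf", "noh_bf",
                                          "rope_hpd95", "rope_full",
                                          "rope_support"),
                              reps = 1000, master_seed = 1,
                              grid_points = 1001, hpd_mass = 0.95,
                              support_k = 1, full_epsilon = 1e-6,
                              bf_threshold = 3, oh_null_scale_ratio = 0.1,
                              hybrid_pi0 = 0.5, failure_budget = 0) {
  stopifnot(reps >= 1, all(n_grid >= 2), all(prior_scales > 0))
  methods <- match.arg(methods, .all_methods, several.ok = TRUE)
  if (inherits(regions, "equivalence_region")) regions <- list(regions)
  for (r in regions) .check_region(r)
  for (s in settings) {
    if (!inherits(s, "simulation_setting")) {
      stop("settings must be simulation_setting objects", call. = FALSE)
    }
  }
  structure(
    list(settings = settings, n_grid = as.integer(n_grid),
         prior_scales = prior_scales, regions = regions, methods = methods,
         reps = as.integer(reps), master_seed = as.integer(master_seed),
         grid_points = grid_points, hpd_mass = hpd_mass,
         support_k = support_k, full_epsilon = full_epsilon,
         bf_threshold = bf_threshold,
         oh_null_scale_ratio = oh_null_scale_ratio,
         hybrid_pi0 = hybrid_pi0, failure_budget = failure_budget),
    class = "simulation_design"
  )
}

# deterministic 31-bit seed from (master_seed, setting, n, replicate); the
# method, prior and region do not enter, so every method sees the same data
.cell_seed <- function(master_seed, label, n, rep) {
  h <- 0
  for (x in c(master_seed, utf8ToInt(as.character(label)), n, rep)) {
    h <- (h * 31 + x) %% 2147483647
  }
  as.integer(h)
}

#' Simulate one two-group dataset from a setting
#'
#' @param setting A [simulation_setting()].
#' @param n Per-group sample size (>= 2).
#' @param seed Integer seed; the same seed reproduces the same dataset.
#' @return List with numeric vectors `group1` and `group2`, each length `n`.
#' @export
simulate_dataset <- function(setting, n, seed = NULL) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  list(group1 = stats::rnorm(n, setting$mean1, setting$sd1),
       group2 = stats::rnorm(n, setting$mean2, setting$sd2))
}

.region_key <- function(region) {
  sprintf("[%g,%g]", region$lower, region$upper)
}

# evaluate every requested method x region for one replicate; returns a
# character matrix of outcomes [method, region]
.evaluate_replicate <- function(tt, prior, regions, methods, opt) {
  out <- matrix(NA_character_, nrow = length(methods),
                ncol = length(regions),
                dimnames = list(methods, vapply(regions, .region_key, "")))
  need_grid <- any(methods %in% c("rope_hpd95", "rope_full", "rope_support"))
  g <- NULL
  intervals <- list()
  if (need_grid) {
    g <- posterior_grid(tt$t, tt$df, tt$effective_n, prior,
                        grid_points = opt$grid_points)
    if ("rope_hpd95" %in% methods) {
      intervals$rope_hpd95 <- hpd_interval(g, opt$hpd_mass)
    }
    if ("rope_full" %in% methods) {
      intervals$rope_full <- full_interval(g, opt$full_epsilon)
    }
    if ("rope_support" %in% methods) {
      intervals$rope_support <- support_interval(g, opt$support_k)
    }
  }
  # region-independent Bayes factors are computed once
  fixed <- list()
  if ("jzs_bf" %in% methods) {
    fixed$jzs_bf <- bf_decision(
      jzs_bf01(tt$t, tt$df, tt$effective_n, prior), opt$bf_threshold)$outcome
  }
  if ("oh_bf" %in% methods) {
    fixed$oh_bf <- bf_decision(
      oh_bf01(tt$t, tt$df, tt$effective_n, r1 = prior$scale,
              r0 = prior$scale * opt$oh_null_scale_ratio),
      opt$bf_threshold)$outcome
  }
  for (j in seq_along(regions)) {
    region <- regions[[j]]
    for (m in methods) {
      out[m, j] <- if (m %in% names(fixed)) {
        fixed[[m]]
      } else if (m == "noh_bf") {
        bf_decision(noh_bf01(tt$t, tt$df, tt$effective_n, prior, region),
                    opt$bf_threshold)$outcome
      } else if (m == "hybrid_bf") {
        bf_decision(hybrid_bf01(tt$t, tt$df, tt$effective_n, prior, region,
                                opt$hybrid_pi0), opt$bf_threshold)$outcome
      } else {
        rope_decision(intervals[[m]], region)$outcome
      }
    }
  }
  out
}

#' Monte-Carlo error rates for one (setting, n, prior) cell
#'
#' Simulates `reps` datasets, computes the pooled t-statistic for each,
#' evaluates every requested method for every candidate region on the same
#' datasets (and on a shared posterior grid for the interval methods), and
#' classifies the three-way decisions against the setting's truth. Rates
#' are outcome counts over `reps` with binomial Monte-Carlo standard
#' errors.
#'
#' @param setting A [simulation_setting()].
#' @param n Per-group sample size.
#' @param prior_scale Cauchy prior scale on delta (location 0).
#' @param regions List of [equivalence_region()]s evaluated jointly.
#' @param methods Character vector of method names (see
#'   [simulation_design()]).
#' @param reps Number of replicates.
#' @param master_seed Master seed.
#' @param options List of method options; missing entries fall back to the
#'   [simulation_design()] defaults.
#' @return A data frame with one row per method x region:
#'   `setting, method, prior_scale, region_lower, region_upper, n, reps,
#'   type1, type1_se, type2, type2_se, power, power_se, inconclusive,
#'   acceptance, total_error, master_seed`.
#' @export
run_cell <- function(setting, n, prior_scale = 1 / sqrt(2),
                     regions = list(equivalence_region(-0.1, 0.1)),
                     methods = "noh_bf", reps = 1000, master_seed = 1,
                     options = list()) {
  if (inherits(regions, "equivalence_region")) regions <- list(regions)
  defaults <- simulation_design(settings = list(setting), n_grid = n,
                                reps = reps, master_seed = master_seed)
  opt <- utils::modifyList(defaults[c("grid_points", "hpd_mass", "support_k",
                                      "full_epsilon", "bf_threshold",
                                      "oh_null_scale_ratio", "hybrid_pi0",
                                      "failure_budget")],
                           options)
  methods <- match.arg(methods, .all_methods, several.ok = TRUE)
  prior <- cauchy_prior(0, prior_scale)
  truth <- if (setting$true_delta == 0) "null_true" else "effect_present"

  classes <- c("type_I", "type_II", "correct_detection",
               "correct_acceptance", "inconclusive")
  counts <- array(0L, dim = c(length(methods), length(regions),
                              length(classes)),
                  dimnames = list(methods, NULL, classes))
  accepts <- matrix(0L, length(methods), length(regions),
                    dimnames = list(methods, NULL))
  failures <- 0L

  for (rep in seq_len(reps)) {
    seed <- .cell_seed(master_seed, setting$label, n, rep)
    dat <- simulate_dataset(setting, n, seed)
    tt <- pooled_t(summarize(dat$group1, dat$group2))
    res <- tryCatch(
      .evaluate_replicate(tt, prior, regions, methods, opt),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > opt$failure_budget * reps) {
        stop("numerical failure in replicate ", rep, " of cell (",
             setting$label, ", n = ", n, "): ", conditionMessage(res),
             call. = FALSE)
      }
      next
    }
    for (m in methods) {
      for (j in seq_along(regions)) {
        cls <- classify_outcome(res[m, j], truth)
        counts[m, j, cls] <- counts[m, j, cls] + 1L
        if (res[m, j] == "accept_H0") accepts[m, j] <- accepts[m, j] + 1L
      }
    }
  }

  denom <- reps - failures
  rows <- list()
  for (m in methods) {
    for (j in seq_along(regions)) {
      p <- counts[m, j, ] / denom
      se <- sqrt(p * (1 - p) / denom)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = setting$label, method = m, prior_scale = prior_scale,
        region_lower = regions[[j]]$lower,
        region_upper = regions[[j]]$upper,
        n = n, reps = denom,
        type1 = p[["type_I"]], type1_se = se[["type_I"]],
        type2 = p[["type_II"]], type2_se = se[["type_II"]],
        power = p[["correct_detection"]], power_se = se[["correct_detection"]],
        inconclusive = p[["inconclusive"]],
        acceptance = accepts[m, j] / denom,
        total_error = p[["type_I"]] + p[["type_II"]],
        master_seed = master_seed,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full factorial Monte-Carlo grid
#'
#' One [run_cell()] per (setting, n, prior scale); all methods and regions
#' within a cell reuse the same simulated datasets and posterior grids.
#' Per-replicate seeds are derived from `(master_seed, setting, n,
#' replicate)` only, so the result is independent of the order in which
#' cells are executed.
#'
#' @param design A [simulation_design()].
#' @param verbose Print per-cell progress to stderr.
#' @return Data frame of error-rate records (see [run_cell()]).
#' @export
run_grid <- function(design, verbose = FALSE) {
  if (!inherits(design, "simulation_design")) {
    stop("expected a 'simulation_design' object", call. = FALSE)
  }
  opt <- design[c("grid_points", "hpd_mass", "support_k", "full_epsilon",
                  "bf_threshold", "oh_null_scale_ratio", "hybrid_pi0",
                  "failure_budget")]
  rows <- list()
  for (setting in design$settings) {
    for (n in design$n_grid) {
      for (scale in design$prior_scales) {
        if (verbose) {
          message(sprintf("cell: setting=%s n=%d prior_scale=%.4g",
                          setting$label, n, scale))
        }
        rows[[length(rows) + 1L]] <- run_cell(
          setting, n, prior_scale = scale, regions = design$regions,
          methods = design$methods, reps = design$reps,
          master_seed = design$master_seed, options = opt)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.results_columns <- c("setting", "method", "prior_scale", "region_lower",
                      "region_upper", "n", "reps", "type1", "type1_se",
                      "type2", "type2_se", "power", "power_se",
                      "inconclusive", "acceptance", "total_error",
                      "master_seed")

#' Write / read a simulation results table
#'
#' Plain CSV with a fixed column order, `.` decimal separator and UTF-8
#' encoding; the master seed is embedded in every row so the table is
#' self-describing.
#'
#' @param table Data frame from [run_grid()] or [run_cell()].
#' @param path Output/input CSV path.
#' @return `write_results_csv` returns `path` invisibly; `read_results_csv`
#'   returns the table.
#' @export
write_results_csv <- function(table, path) {
  missing_cols <- setdiff(.results_columns, names(table))
  if (length(missing_cols)) {
    stop("results table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(table[, .results_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.results_columns, names(tab))
  if (length(missing_cols)) {
    stop("not a results table (missing: ",
         paste(missing_cols, collapse = ", "), ")", call. = FALSE)
  }
  tab
}
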