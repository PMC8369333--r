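#' Objective criteria for equivalence-region selection
#'
#' The inputs of the region-selection procedure: the largest acceptable type
#' I error rate, the smallest acceptable power against the effect size of
#' interest, the attainable per-group sample size, and the elicited prior.
#' The prior is an input, never a tuning knob: a single call ranks methods
#' and regions under one prior scale only.
#'
#' @param alpha_max Maximum acceptable type I error rate, in (0, 1).
#' @param power_min Minimum required power, in (0, 1).
#' @param n Attainable per-group sample size; matched to the largest
#'   simulated sample size not exceeding it.
#' @param prior_scale Elicited Cauchy prior scale.
#' @param effect_label Label of the effect setting power is read from
#'   (`"small"`, `"medium"` or `"large"` for the built-in settings).
#' @param methods Optional subset of candidate methods (default: all in the
#'   table).
#' @param regions Optional list of candidate [equivalence_region()]s
#'   (default: all in the table).
#' @param conservative If `TRUE`, admissibility uses Monte-Carlo-error
#'   buffers: `alpha + 2 se <= alpha_max` and `power - 2 se >= power_min`.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(alpha_max, power_min, n,
                               prior_scale = 1,
                               effect_label = "small",
                               methods = NULL, regions = NULL,
                               conservative = FALSE) {
  if (!(alpha_max > 0 && alpha_max < 1)) {
    stop("alpha_max must be in (0, 1)", call. = FALSE)
  }
  if (!(power_min > 0 && power_min < 1)) {
    stop("power_min must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(regions)) {
    if (inherits(regions, "equivalence_region")) regions <- list(regions)
    for (r in regions) .check_region(r)
  }
  structure(
    list(alpha_max = alpha_max, power_min = power_min, n = as.integer(n),
         prior_scale = prior_scale, effect_label = effect_label,
         methods = methods, regions = regions,
         conservative = isTRUE(conservative)),
    class = "selection_criteria"
  )
}

# assemble per-(method, region) alpha and power from the table, erroring
# with the explicit list of missing cells
.selection_table <- function(table, criteria, total = FALSE) {
  sims <- sort(unique(table$n))
  sims <- sims[sims <= criteria$n]
  if (length(sims) == 0) {
    stop("no simulated sample size at or below n = ", criteria$n,
         call. = FALSE)
  }
  n_use <- max(sims)
  sub <- table[table$n == n_use &
                 abs(table$prior_scale - criteria$prior_scale) < 1e-8, ]
  if (nrow(sub) == 0) {
    stop("no cells with prior_scale = ", criteria$prior_scale,
         " at n = ", n_use, "; simulate them first", call. = FALSE)
  }
  cand <- unique(sub[, c("method", "region_lower", "region_upper")])
  if (!is.null(criteria$methods)) {
    cand <- cand[cand$method %in% criteria$methods, ]
  }
  if (!is.null(criteria$regions)) {
    keep <- rep(FALSE, nrow(cand))
    for (r in criteria$regions) {
      keep <- keep | (abs(cand$region_lower - r$lower) < 1e-8 &
                        abs(cand$region_upper - r$upper) < 1e-8)
    }
    cand <- cand[keep, ]
  }
  if (nrow(cand) == 0) stop("no candidate (method, region) pairs in table",
                            call. = FALSE)

  pick <- function(setting, m, lo, hi) {
    sub[sub$setting == setting & sub$method == m &
          abs(sub$region_lower - lo) < 1e-8 &
          abs(sub$region_upper - hi) < 1e-8, ]
  }
  missing_cells <- character(0)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    m <- cand$method[i]
    lo <- cand$region_lower[i]
    hi <- cand$region_upper[i]
    null_row <- pick("null", m, lo, hi)
    eff_row <- pick(criteria$effect_label, m, lo, hi)
    if (nrow(null_row) != 1 || nrow(eff_row) != 1) {
      missing_cells <- c(missing_cells, sprintf(
        "(%s, [%g, %g], n = %d, prior %g: need one 'null' and one '%s' cell)",
        m, lo, hi, n_use, criteria$prior_scale, criteria$effect_label))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      method = m, region_lower = lo, region_upper = hi,
      width = hi - lo,
      estimated_alpha = null_row$type1, alpha_se = null_row$type1_se,
      estimated_power = eff_row$power, power_se = eff_row$power_se,
      estimated_type2 = eff_row$type2,
      total_error = null_row$type1 + eff_row$type2,
      stringsAsFactors = FALSE
    )
  }
  if (length(missing_cells)) {
    stop("missing simulation cells:\n  ",
         paste(missing_cells, collapse = "\n  "), call. = FALSE)
  }
  ranked <- do.call(rbind, rows)
  ranked <- ranked[order(ranked$width, ranked$estimated_alpha,
                         -ranked$estimated_power), ]
  rownames(ranked) <- NULL
  list(ranked = ranked, n_used = n_use)
}

.finish_recommendation <- function(st, criteria, admissible, rule) {
  ranked <- st$ranked
  ranked$admissible <- admissible
  chosen <- if (any(admissible)) ranked[which(admissible)[1], ] else NULL
  nearest_miss <- NULL
  if (is.null(chosen)) {
    # diagnostics: the entry closest to feasibility
    short <- pmax(criteria$alpha_max * 0 + ranked$estimated_alpha -
                    criteria$alpha_max, 0) +
      pmax(criteria$power_min - ranked$estimated_power, 0)
    nearest_miss <- ranked[which.min(short), ]
  }
  structure(
    list(ranked = ranked, chosen = chosen, criteria = criteria,
         n_used = st$n_used, rule = rule, nearest_miss = nearest_miss),
    class = "equiv_recommendation"
  )
}

#' Select the narrowest admissible equivalence region
#'
#' Reads Monte-Carlo type I error (from the null-setting cells) and power
#' (from the chosen effect-setting cells) for every candidate (method,
#' region) pair at the matched sample size and prior, keeps the pairs
#' meeting `alpha <= alpha_max` and `power >= power_min`, and ranks them:
#' narrowest region first (a narrower region makes the equivalence statement
#' more precise), then lowest type I error, then highest power. A pure
#' function of the table and the criteria; no simulation is run here.
#'
#' @param table Results table from [run_grid()] or [read_results_csv()].
#' @param criteria A [selection_criteria()].
#' @return An object of class `equiv_recommendation`: `ranked` (all
#'   candidates with estimates and an `admissible` flag), `chosen` (the top
#'   admissible entry, or `NULL` with nearest-miss diagnostics), `n_used`.
#' @export
select_design <- function(table, criteria) {
  if (!inherits(criteria, "selection_criteria")) {
    stop("expected a 'selection_criteria' object", call. = FALSE)
  }
  st <- .selection_table(table, criteria)
  r <- st$ranked
  admissible <- if (criteria$conservative) {
    (r$estimated_alpha + 2 * r$alpha_se <= criteria$alpha_max) &
      (r$estimated_power - 2 * r$power_se >= criteria$power_min)
  } else {
    r$estimated_alpha <= criteria$alpha_max &
      r$estimated_power >= criteria$power_min
  }
  .finish_recommendation(st, criteria, admissible, rule = "alpha_power")
}

#' Select by total (type I + type II) error rate
#'
#' Variant of [select_design()] whose admissibility criterion is the sum of
#' the type I rate (null cell) and type II rate (effect cell) not exceeding
#' `total_max`. This treats a false positive and a false negative as equally
#' costly, which is often unrealistic in biomedical applications; use with
#' that caveat in mind.
#'
#' @inheritParams select_design
#' @param total_max Maximum acceptable total misclassification rate.
#' @return An `equiv_recommendation` (see [select_design()]).
#' @export
select_by_total_error <- function(table, criteria, total_max) {
  if (!inherits(criteria, "selection_criteria")) {
    stop("expected a 'selection_criteria' object", call. = FALSE)
  }
  if (!(total_max >= 0)) stop("total_max must be >= 0", call. = FALSE)
  st <- .selection_table(table, criteria)
  admissible <- st$ranked$total_error <= total_max
  out <- .finish_recommendation(st, criteria, admissible,
                                rule = "total_error")
  out$total_max <- total_max
  out
}

#' @export
print.equiv_recommendation <- function(x, ...) {
  cat(format_recommendation(x), sep = "\n")
  invisible(x)
}

#' Human-readable recommendation report
#'
#' @param x An `equiv_recommendation`.
#' @return Character vector of report lines.
#' @export
format_recommendation <- function(x) {
  cr <- x$criteria
  head <- if (x$rule == "total_error") {
    sprintf("criteria: total error <= %g, n = %d (matched to simulated n = %d), prior scale %g, effect '%s'",
            x$total_max, cr$n, x$n_used, cr$prior_scale, cr$effect_label)
  } else {
    sprintf("criteria: alpha <= %g, power >= %g, n = %d (matched to simulated n = %d), prior scale %g, effect '%s'",
            cr$alpha_max, cr$power_min, cr$n, x$n_used, cr$prior_scale,
            cr$effect_label)
  }
  lines <- c("Equivalence-region recommendation", head, "")
  r <- x$ranked
  lines <- c(lines, sprintf(
    "%-14s %-16s %-10s %-10s %s", "method", "region", "alpha", "power",
    "admissible"))
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "%-14s [%6.3f, %6.3f] %-10.4f %-10.4f %s",
      r$method[i], r$region_lower[i], r$region_upper[i],
      r$estimated_alpha[i], r$estimated_power[i],
      if (r$admissible[i]) "yes" else "no"))
  }
  lines <- c(lines, "")
  if (is.null(x$chosen)) {
    lines <- c(lines, "chosen: none (no admissible pair)",
               sprintf("nearest miss: %s with [%g, %g] (alpha %.4f, power %.4f)",
                       x$nearest_miss$method, x$nearest_miss$region_lower,
                       x$nearest_miss$region_upper,
                       x$nearest_miss$estimated_alpha,
                       x$nearest_miss$estimated_power))
  } else {
    lines <- c(lines, sprintf(
      "chosen: %s with region [%g, %g] (alpha %.4f, power %.4f)",
      x$chosen$method, x$chosen$region_lower, x$chosen$region_upper,
      x$chosen$estimated_alpha, x$chosen$estimated_power))
  }
  lines
}

#' Write a recommendation report to disk
#'
#' Writes `<prefix>.csv` (the ranked candidate table) and `<prefix>.txt`
#' (the human-readable report).
#'
#' @param x An `equiv_recommendation`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_recommendation <- function(x, prefix) {
  csv <- paste0(prefix, ".csv")
  txt <- paste0(prefix, ".txt")
  utils::write.csv(x$ranked, csv, row.names = FALSE, fileEncoding = "UTF-8")
  writeLines(format_recommendation(x), txt)
  invisible(c(csv, txt))
}
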