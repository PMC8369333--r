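decision <- function(outcome, method, evidence) {
  stopifnot(outcome %in% c("accept_H0", "reject_H0", "inconclusive"))
  structure(list(outcome = outcome, method = method, evidence = evidence),
            class = "equiv_decision")
}

#' @export
print.equiv_decision <- function(x, ...) {
  cat(sprintf("decision: %s (method %s)\n", x$outcome, x$method))
  invisible(x)
}

#' Three-way decision from a Bayes factor
#'
#' Accept the (interval or point) null when `BF01 >= threshold`, reject it
#' when `BF01 <= 1/threshold`, and remain inconclusive in between. The
#' default threshold 3 corresponds to at least moderate evidence on
#' conventional Bayes factor scales. Boundary values count toward the
#' decisive side (exactly `1/threshold` rejects, exactly `threshold`
#' accepts) so the rule is deterministic.
#'
#' @param bf A `bf_result` (from [jzs_bf01()], [oh_bf01()], [noh_bf01()] or
#'   [hybrid_bf01()]) or a plain positive number interpreted as BF01.
#' @param threshold Evidence threshold, > 1 (default 3).
#' @return An `equiv_decision` with outcome `accept_H0`, `reject_H0` or
#'   `inconclusive` and the BF01 as `evidence`.
#' @export
bf_decision <- function(bf, threshold = 3) {
  if (!(threshold > 1)) stop("threshold must be > 1", call. = FALSE)
  if (inherits(bf, "bf_result")) {
    method <- paste0(bf$model$model, "_bf")
    bf01 <- bf$bf01
  } else {
    method <- "bf"
    bf01 <- bf
  }
  if (!is.finite(bf01) || bf01 <= 0) stop("bf01 must be > 0", call. = FALSE)
  outcome <- if (bf01 <= 1 / threshold) {
    "reject_H0"
  } else if (bf01 >= threshold) {
    "accept_H0"
  } else {
    "inconclusive"
  }
  decision(outcome, method, bf01)
}

#' Three-way ROPE decision from an interval estimate
#'
#' Accept the interval null when the posterior interval lies entirely inside
#' the equivalence region (closed comparison: an endpoint exactly on the
#' region boundary counts as inside); reject it when the interval is
#' strictly separated from the region; otherwise the situation is
#' inconclusive. An empty support interval is inconclusive: an empty set
#' carries no locational evidence, and treating it as vacuously inside the
#' region would accept the null on no evidence.
#'
#' @param interval An `interval_estimate` (from [hpd_interval()],
#'   [full_interval()] or [support_interval()]).
#' @param region An [equivalence_region()] on the standardized-effect scale.
#' @return An `equiv_decision`; `evidence` holds the interval bounds.
#' @export
rope_decision <- function(interval, region) {
  if (!inherits(interval, "interval_estimate")) {
    stop("expected an 'interval_estimate' object", call. = FALSE)
  }
  region <- .check_region(region)
  if (region$scale != "standardized_effect") {
    stop("interval estimates are on the standardized effect scale; ",
         "the region uses scale '", region$scale, "'", call. = FALSE)
  }
  method <- switch(interval$kind,
                   hpd95 = "rope_hpd95", hpd = "rope_hpd95",
                   hpd100 = "rope_full", support = "rope_support",
                   "rope")
  if (interval$empty) {
    return(decision("inconclusive", method, c(NA_real_, NA_real_)))
  }
  outcome <- if (region$lower <= interval$lower &&
                 interval$upper <= region$upper) {
    "accept_H0"
  } else if (interval$upper < region$lower ||
             interval$lower > region$upper) {
    "reject_H0"
  } else {
    "inconclusive"
  }
  decision(outcome, method, c(interval$lower, interval$upper))
}

#' Classify a decision against the known truth of a simulation setting
#'
#' Maps a three-way decision and the data-generating truth to the Monte
#' Carlo bookkeeping categories: rejecting the interval null when the true
#' effect is zero is a type I error; accepting it when an effect is present
#' is a type II error; rejecting under a present effect is a correct
#' detection (counts toward power); accepting under a true null is a correct
#' acceptance; inconclusive decisions contribute to no error rate.
#'
#' @param d An `equiv_decision`.
#' @param truth `"null_true"` or `"effect_present"`.
#' @return One of `"type_I"`, `"type_II"`, `"correct_detection"`,
#'   `"correct_acceptance"`, `"inconclusive"`.
#' @export
classify_outcome <- function(d, truth = c("null_true", "effect_present")) {
  truth <- match.arg(truth)
  outcome <- if (inherits(d, "equiv_decision")) d$outcome else d
  if (outcome == "inconclusive") return("inconclusive")
  if (truth == "null_true") {
    if (outcome == "reject_H0") "type_I" else "correct_acceptance"
  } else {
    if (outcome == "accept_H0") "type_II" else "correct_detection"
  }
}
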