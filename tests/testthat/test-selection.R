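# hand-built results tables: selection must be a pure function of the table
make_row <- function(setting, method, lo, hi, n, type1 = 0, type2 = 0,
                     power = 0, prior_scale = 1, reps = 1000) {
  data.frame(setting = setting, method = method, prior_scale = prior_scale,
             region_lower = lo, region_upper = hi, n = n, reps = reps,
             type1 = type1, type1_se = sqrt(type1 * (1 - type1) / reps),
             type2 = type2, type2_se = sqrt(type2 * (1 - type2) / reps),
             power = power, power_se = sqrt(power * (1 - power) / reps),
             inconclusive = 1 - type1 - type2 - power -
               if (setting == "null") 1 - type1 else 0,
             acceptance = if (setting == "null") 1 - type1 else type2,
             total_error = type1 + type2, master_seed = 1,
             stringsAsFactors = FALSE)
}

toy_table <- function() {
  rows <- list()
  for (reg in list(c(-0.05, 0.05), c(-0.1, 0.1))) {
    # narrow region: hpd95 meets both criteria, noh misses power,
    # support has higher alpha; wide region: everything weaker
    narrow <- reg[2] == 0.05
    rows <- c(rows, list(
      make_row("null", "noh_bf", reg[1], reg[2], 170,
               type1 = if (narrow) 0.01 else 0.005),
      make_row("small", "noh_bf", reg[1], reg[2], 170, type2 = 0.05,
               power = if (narrow) 0.70 else 0.55),
      make_row("null", "rope_hpd95", reg[1], reg[2], 170,
               type1 = if (narrow) 0.02 else 0.01),
      make_row("small", "rope_hpd95", reg[1], reg[2], 170, type2 = 0.02,
               power = if (narrow) 0.83 else 0.65),
      make_row("null", "rope_support", reg[1], reg[2], 170,
               type1 = if (narrow) 0.04 else 0.02),
      make_row("small", "rope_support", reg[1], reg[2], 170, type2 = 0.01,
               power = if (narrow) 0.85 else 0.7)
    ))
  }
  do.call(rbind, rows)
}

test_that("select_design picks the narrowest admissible pair with least alpha", {
  tab <- toy_table()
  rec <- select_design(tab, selection_criteria(0.05, 0.8, n = 170))
  expect_equal(rec$n_used, 170L)
  # hpd95 and support both admissible at [-0.05, 0.05]; hpd95 has lower alpha
  expect_equal(rec$chosen$method, "rope_hpd95")
  expect_equal(rec$chosen$region_lower, -0.05)
  expect_equal(rec$chosen$region_upper, 0.05)
  adm <- rec$ranked[rec$ranked$admissible, ]
  expect_true(all(adm$estimated_alpha <= 0.05))
  expect_true(all(adm$estimated_power >= 0.8))
  # the chosen region is never wider than any admissible region
  expect_true(all(rec$chosen$width <= adm$width))

  # relaxing the power requirement admits the NOH pair at the narrow region
  rec2 <- select_design(tab, selection_criteria(0.05, 0.6, n = 170))
  adm2 <- rec2$ranked[rec2$ranked$admissible, ]
  expect_true(any(adm2$method == "noh_bf" & adm2$region_upper == 0.05))
  # monotonicity: the admissible set only grows when criteria are relaxed
  key <- function(r) paste(r$method, r$region_lower, r$region_upper)
  expect_true(all(key(adm) %in% key(adm2)))
})

test_that("infeasible criteria yield no choice but nearest-miss diagnostics", {
  tab <- toy_table()
  rec <- select_design(tab, selection_criteria(1e-6, 0.99, n = 170))
  expect_null(rec$chosen)
  expect_false(any(rec$ranked$admissible))
  expect_s3_class(rec, "equiv_recommendation")
  expect_false(is.null(rec$nearest_miss))
  txt <- format_recommendation(rec)
  expect_true(any(grepl("chosen: none", txt)))
})

test_that("n is floored to the nearest simulated value and cells must exist", {
  tab <- toy_table()
  rec <- select_design(tab, selection_criteria(0.05, 0.8, n = 175))
  expect_equal(rec$n_used, 170L)
  expect_error(select_design(tab, selection_criteria(0.05, 0.8, n = 100)),
               "at or below")
  # effect cells absent: explicit missing-cell error naming the cells
  expect_error(
    select_design(tab, selection_criteria(0.05, 0.8, n = 170,
                                          effect_label = "large")),
    "missing simulation cells")
  # wrong prior scale: nothing to rank
  expect_error(
    select_design(tab, selection_criteria(0.05, 0.8, n = 170,
                                          prior_scale = 2)),
    "prior_scale")
})

test_that("conservative mode tightens admissibility with MC buffers", {
  tab <- toy_table()
  # power 0.83 with se ~ 0.012: power - 2 se > 0.8 fails at power_min 0.82
  rec <- select_design(tab, selection_criteria(0.05, 0.82, n = 170,
                                               conservative = TRUE))
  plain <- select_design(tab, selection_criteria(0.05, 0.82, n = 170))
  expect_lte(sum(rec$ranked$admissible), sum(plain$ranked$admissible))
})

test_that("select_by_total_error uses type1 + type2 and vacuous bounds", {
  tab <- toy_table()
  rec <- select_by_total_error(tab, selection_criteria(0.05, 0.8, n = 170),
                               total_max = 0.05)
  adm <- rec$ranked[rec$ranked$admissible, ]
  expect_true(all(adm$total_error <= 0.05))
  # total_max = 1 admits everything; chosen is narrowest with least alpha
  rec1 <- select_by_total_error(tab, selection_criteria(0.05, 0.8, n = 170),
                                total_max = 1)
  expect_true(all(rec1$ranked$admissible))
  expect_equal(rec1$chosen$region_upper, 0.05)
  expect_equal(rec1$chosen$method, "noh_bf")  # lowest alpha at that width
  # total_max = 0: nothing qualifies
  rec0 <- select_by_total_error(tab, selection_criteria(0.05, 0.8, n = 170),
                                total_max = 0)
  expect_null(rec0$chosen)
})

test_that("recommendation reports are written as CSV and text", {
  tab <- toy_table()
  rec <- select_design(tab, selection_criteria(0.05, 0.8, n = 170))
  prefix <- tempfile()
  paths <- write_recommendation(rec, prefix)
  expect_true(all(file.exists(paths)))
  ranked <- read.csv(paste0(prefix, ".csv"))
  expect_equal(nrow(ranked), nrow(rec$ranked))
  report <- readLines(paste0(prefix, ".txt"))
  expect_true(any(grepl("chosen: rope_hpd95", report)))
})
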