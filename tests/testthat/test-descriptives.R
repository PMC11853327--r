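test_that("half-up rounding rounds .5 away from zero at 2 dp", {
  expect_equal(round_half_up(1.005, 2), 1.01)
  expect_equal(round_half_up(2.0968, 2), 2.10)
  expect_equal(round_half_up(-1.005, 2), -1.01)
  expect_equal(round_half_up(12.8005, 2), 12.80)
})

test_that("ADRs per ICSR reproduce the published reporting ratios", {
  aggs <- fixture_aggs()
  expect_equal(adrs_per_icsr(aggs, "bevacizumab")$value, 1.79)
  expect_equal(adrs_per_icsr(aggs, "panitumumab")$value, 2.10)

  one <- aggregate_icsr(icsr_dataset(tibble::tibble(
    icsr_id = rep("X", 10), drug = "d", pt_code = NA_integer_,
    pt_name = "Nausea", outcome = "Unknown"
  )))
  # relax the case structure: 10 rows on 10 cases
  ten <- aggregate_icsr(icsr_dataset(tibble::tibble(
    icsr_id = paste0("X", 1:10), drug = "d", pt_code = NA_integer_,
    pt_name = "Nausea", outcome = "Unknown"
  )))
  expect_equal(adrs_per_icsr(ten, "d")$value, 1.00)
  expect_equal(adrs_per_icsr(one, "d")$value, 10.00)
})

test_that("condition proportions reproduce the published shares", {
  aggs <- fixture_aggs()
  bev <- condition_proportion(aggs, "bevacizumab")
  expect_equal(bev$value, 1.41)
  expect_equal(bev$n, 1505L)
  pan <- condition_proportion(aggs, "panitumumab")
  expect_equal(pan$value, 2.30)
  expect_equal(pan$n, 346L)
  expect_equal(condition_proportion(aggs, "bevacizumab", character(0))$value,
               0.00)
})

test_that("condition proportions over all labels sum to 100 within rounding", {
  withr::with_seed(5150, {
    for (i in 1:5) {
      aggs <- aggregate_icsr(generate_icsr(random_spec()))
      for (drug in unique(aggs$drug)) {
        total <- sum(vapply(condition_levels(), function(cc) {
          condition_proportion(aggs, drug, cc)$value
        }, numeric(1)))
        expect_lt(abs(total - 100), 0.02)
      }
    }
  })
})

test_that("outcome breakdowns reproduce the published percentages", {
  aggs <- fixture_aggs()

  bev_ineff <- outcome_breakdown(aggs, "bevacizumab", "ineffectiveness")
  expect_equal(bev_ineff$n_unfavorable, 181L)
  expect_equal(bev_ineff$n_fatal, 92L)
  expect_equal(bev_ineff$pct_unfavorable, 12.80)
  expect_equal(bev_ineff$pct_fatal_of_unfavorable, 50.83)

  pan_ineff <- outcome_breakdown(aggs, "panitumumab", "ineffectiveness")
  expect_equal(pan_ineff$pct_unfavorable, 4.88)
  expect_equal(pan_ineff$pct_fatal_of_unfavorable, 25.00)

  bev_res <- outcome_breakdown(aggs, "bevacizumab", "resistance")
  expect_equal(bev_res$pct_unfavorable, 10.99)
  expect_equal(bev_res$pct_fatal_of_unfavorable, 80.00)

  pan_res <- outcome_breakdown(aggs, "panitumumab", "resistance")
  expect_equal(pan_res$n_unfavorable, 1L)
  expect_equal(pan_res$pct_fatal_of_unfavorable, 100.00)
  # recomputed from raw counts: 1 of 18 (see the methods vignette on the
  # non-derivable published figure for this share)
  expect_equal(pan_res$pct_unfavorable, 5.56)
})

test_that("outcome invariants hold: fatal <= unfavorable <= cases", {
  withr::with_seed(99, {
    for (i in 1:5) {
      ds <- generate_icsr(random_spec())
      aggs <- aggregate_icsr(ds)
      for (drug in unique(aggs$drug)) {
        for (cond in condition_levels()) {
          rows <- aggs[aggs$drug == drug & aggs$condition == cond, ]
          if (sum(rows$count) == 0) next
          bd <- outcome_breakdown(aggs, drug, cond)
          expect_lte(bd$n_fatal, bd$n_unfavorable)
          expect_lte(bd$n_unfavorable, bd$n_cases)
          expect_gte(bd$pct_unfavorable, 0)
          expect_lte(bd$pct_unfavorable, 100)
        }
      }
    }
  })
})

test_that("PT distributions cover dictionary PTs and sum to condition counts", {
  ds <- fixture_dataset()
  aggs <- fixture_aggs()
  bev_res <- pt_distribution(ds, "bevacizumab", "resistance")
  expect_equal(nrow(bev_res), 2L)  # both resistance PTs reported, incl. zeroes
  expect_equal(bev_res$count[bev_res$pt_name == "Drug resistance"], 82L)
  expect_equal(bev_res$count[bev_res$pt_name == "Multiple drug resistance"],
               9L)  # 91 total minus 82
  expect_equal(sum(bev_res$count),
               sum(aggs$count[aggs$drug == "bevacizumab" &
                                aggs$condition == "resistance"]))

  ineff <- pt_distribution(ds, "panitumumab", "ineffectiveness")
  expect_equal(sum(ineff$count), 328L)
  expect_equal(nrow(ineff), 11L)
})

test_that("degenerate descriptive inputs raise undefined-ratio errors", {
  aggs <- fixture_aggs()
  expect_error(adrs_per_icsr(aggs, "cetuximab"), "not present")
  expect_error(outcome_breakdown(aggs, "bevacizumab", "nonsense"), "condition")

  ds <- tiny_dataset()
  small <- aggregate_icsr(ds)
  expect_error(outcome_breakdown(small, "panitumumab", "resistance"),
               "undefined")
  expect_error(pt_distribution(ds, "cetuximab", "resistance"), "not present")
})

test_that("describe_dataset assembles all four report tables", {
  desc <- describe_dataset(fixture_dataset())
  expect_named(desc, c("reporting", "condition_proportions",
                       "outcome_breakdowns", "pt_distributions"))
  rep_bev <- desc$reporting[desc$reporting$drug == "bevacizumab", ]
  expect_equal(rep_bev$adrs_per_icsr, 1.79)
  expect_equal(rep_bev$n_icsrs, 59693L)
  expect_equal(nrow(desc$outcome_breakdowns), 4L)  # 2 drugs x 2 conditions
})
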