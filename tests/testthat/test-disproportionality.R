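test_that("2x2 tables assemble from aggregates with complements by subtraction", {
  aggs <- fixture_aggs()
  tab <- build_table(aggs, "panitumumab", "bevacizumab", "ineffectiveness")
  expect_equal(tab$a, 328L)
  expect_equal(tab$b, 14723L)
  expect_equal(tab$c, 1414L)
  expect_equal(tab$d, 105671L)

  tab <- build_table(aggs, "panitumumab", "bevacizumab", "resistance")
  expect_equal(unlist(tab[c("a", "b", "c", "d")], use.names = FALSE),
               c(18L, 15033L, 91L, 106994L))

  expect_error(build_table(aggs, "panitumumab", "panitumumab"), "differ")
  expect_error(build_table(aggs, "panitumumab", "cetuximab"), "cetuximab")
})

test_that("a drug with no ADRs of the condition gives a = 0, b = n_adrs", {
  aggs <- aggregate_icsr(tiny_dataset())
  tab <- build_table(aggs, "panitumumab", "bevacizumab", "resistance")
  expect_equal(tab$a, 0L)
  expect_equal(tab$b, 1L)
})

test_that("the ROR engine reproduces the published ineffectiveness estimate", {
  res <- compute_ror(tibble::tibble(a = 328, b = 14723, c = 1414, d = 105671))
  expect_equal(round(res$ror, 4), 1.6649)
  expect_equal(round(res$ci_low, 4), 1.4746)
  expect_equal(round(res$ci_high, 4), 1.8797)
  expect_true(res$defined)
  expect_true(res$signal)
})

test_that("the resistance comparison matches direct formula evaluation", {
  res <- compute_ror(tibble::tibble(a = 18, b = 15033, c = 91, d = 106994))
  oracle <- oracle_ror(18, 15033, 91, 106994)
  expect_equal(res$ror, oracle$ror, tolerance = 1e-12)
  expect_equal(res$ci_low, oracle$ci_low, tolerance = 1e-12)
  expect_equal(res$ci_high, oracle$ci_high, tolerance = 1e-12)
  # frozen oracle values (a=18, b=15033, c=91, d=106994)
  expect_equal(round(res$ror, 4), 1.4078)
  expect_equal(round(res$ci_low, 3), 0.849)
  expect_equal(round(res$ci_high, 3), 2.335)
  expect_false(res$signal)  # CI spans 1
})

test_that("a balanced table gives ROR 1 with p-value 1", {
  res <- compute_ror(tibble::tibble(a = 50, b = 9950, c = 50, d = 9950))
  expect_equal(res$ror, 1)
  expect_equal(res$p_value, 1)
  expect_false(res$signal)
})

test_that("zero cells yield defined = FALSE, never an exception", {
  res <- compute_ror(tibble::tibble(a = c(0, 5, 5), b = c(10, 0, 10),
                                    c = c(5, 5, 5), d = c(10, 10, 10)))
  expect_equal(res$defined, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(res$ror[1:2])))
  expect_false(any(res$signal[1:2]))
  expect_error(compute_ror(tibble::tibble(a = -1, b = 1, c = 1, d = 1)),
               "negative")
})

test_that("the signal rule needs >= 5 reports and lower CI strictly above 1", {
  mk <- function(n, lo) tibble::tibble(defined = TRUE, n_reports = n, ci_low = lo)
  expect_true(classify_signal(mk(5L, 1.0001)))
  expect_false(classify_signal(mk(4L, 2.0)))
  expect_false(classify_signal(mk(100L, 1.0)))  # strict inequality
  expect_false(classify_signal(tibble::tibble(defined = FALSE, n_reports = 10L,
                                              ci_low = NA_real_)))
  expect_true(classify_signal(mk(3L, 2.0), min_reports = 3L))
})

test_that("CI bounds are log-symmetric around the estimate", {
  withr::with_seed(314, {
    for (i in 1:50) {
      cells <- sample(1:500, 4, replace = TRUE)
      res <- compute_ror(tibble::tibble(a = cells[1], b = cells[2],
                                        c = cells[3], d = cells[4]))
      expect_lt(abs((log(res$ci_high) - log(res$ror)) -
                      (log(res$ror) - log(res$ci_low))), 1e-9)
      expect_lte(res$ci_low, res$ror)
      expect_lte(res$ror, res$ci_high)
    }
  })
})

test_that("swapping target and comparator inverts the estimate and the CI", {
  aggs <- fixture_aggs()
  for (cond in list("resistance", "ineffectiveness",
                    c("resistance", "ineffectiveness"))) {
    ab <- compute_ror(build_table(aggs, "panitumumab", "bevacizumab", cond))
    ba <- compute_ror(build_table(aggs, "bevacizumab", "panitumumab", cond))
    expect_lt(abs(ab$ror * ba$ror - 1), 1e-9)
    expect_lt(abs(ab$ci_low * ba$ci_high - 1), 1e-9)
    expect_lt(abs(ab$ci_high * ba$ci_low - 1), 1e-9)
  }
})

test_that("ROR increases in a and the CI narrows as cells grow", {
  base <- tibble::tibble(a = 20, b = 80, c = 30, d = 70)
  r0 <- compute_ror(base)
  r1 <- compute_ror(dplyr::mutate(base, a = a + 1))
  expect_gt(r1$ror, r0$ror)

  for (cell in c("a", "b", "c", "d")) {
    grown <- base
    grown[[cell]] <- grown[[cell]] + 10
    expect_lt(compute_ror(grown)$log_se, r0$log_se)
  }

  scaled <- compute_ror(dplyr::mutate(base, a = a * 7, b = b * 7,
                                      c = c * 7, d = d * 7))
  expect_equal(scaled$ror, r0$ror, tolerance = 1e-12)
  expect_lt(scaled$log_se, r0$log_se)
  expect_gt(scaled$ci_low, r0$ci_low)
  expect_lt(scaled$ci_high, r0$ci_high)
})

test_that("build_table agrees with brute-force row tallies on random listings", {
  withr::with_seed(271828, {
    for (i in 1:25) {
      spec <- random_spec()
      ds <- generate_icsr(spec)
      aggs <- aggregate_icsr(ds)
      drugs <- unique(ds$records$drug)
      if (length(drugs) < 2) next
      pair <- sample(drugs, 2)
      conds <- sample(condition_levels(), sample(1:2, 1))
      tab <- build_table(aggs, pair[1], pair[2], conds)
      oracle <- brute_force_table(ds$records, pair[1], pair[2], conds)
      expect_equal(unlist(tab[c("a", "b", "c", "d")], use.names = FALSE),
                   unname(oracle))
      if (all(oracle > 0)) {
        expect_equal(compute_ror(tab)$ror,
                     (oracle["a"] * oracle["d"]) / (oracle["b"] * oracle["c"]),
                     ignore_attr = TRUE, tolerance = 1e-12)
      }
    }
  })
})

test_that("panels preserve comparator order and isolate undefined rows", {
  withr::with_seed(4, {
    spec <- synthetic_spec(list(
      tgt = list(n_icsrs = 50L, conditions = list(
        ineffectiveness = list(outcomes = c(unknown = 100L)),
        other = list(outcomes = c(unknown = 9900L)))),
      cmp1 = list(n_icsrs = 50L, conditions = list(
        ineffectiveness = list(outcomes = c(unknown = 50L)),
        other = list(outcomes = c(unknown = 9950L)))),
      cmp0 = list(n_icsrs = 10L, conditions = list(
        other = list(outcomes = c(unknown = 500L)))),
      cmp2 = list(n_icsrs = 20L, conditions = list(
        ineffectiveness = list(outcomes = c(unknown = 10L)),
        other = list(outcomes = c(unknown = 990L))))
    ))
    aggs <- aggregate_icsr(generate_icsr(spec))
    panel <- run_panel(aggs, "tgt", c("cmp1", "cmp0", "cmp2"),
                       "ineffectiveness")
    expect_equal(panel$comparator, c("cmp1", "cmp0", "cmp2"))
    expect_equal(panel$defined, c(TRUE, FALSE, TRUE))
    # known-count cross product: (100 * 9950) / (9900 * 50)
    expect_equal(panel$ror[1], (100 * 9950) / (9900 * 50), tolerance = 1e-12)
    expect_error(run_panel(aggs, "tgt", character(0)), "empty")
    expect_error(run_panel(aggs, "tgt", c("cmp1", "ghost1", "ghost2")),
                 "ghost1.*ghost2")
  })
})

test_that("signal tables write the forest-plot-ready column layout", {
  aggs <- fixture_aggs()
  panel <- run_panel(aggs, "panitumumab", "bevacizumab",
                     c("resistance", "ineffectiveness"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_table(panel, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("target", "comparator", "condition", "a", "b", "c", "d",
                 "ror", "ci_low", "ci_high", "p_value", "n_reports",
                 "signal", "defined"))
  expect_equal(back$a, 346)  # both conditions pooled
})
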