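# Synthetic cohort simulator: determinism, sizes, planted structure.

test_that("the same seed reproduces cohorts and event tables exactly", {
  a <- simulate_cohort(5, 5, "BM", seed = 61)
  b <- simulate_cohort(5, 5, "BM", seed = 61)
  expect_identical(a, b)
  p <- a[[1]]
  t1 <- simulate_events(p, 500, seed = 62)
  t2 <- simulate_events(p, 500, seed = 62)
  expect_identical(t1$values, t2$values)
})

test_that("cohort sizes and labels are exact", {
  co <- simulate_cohort(97, 10, "BM", seed = 63)
  expect_length(co, 107)
  truth <- vapply(co, `[[`, character(1), "truth")
  expect_equal(sum(truth == "WM"), 97)
  expect_equal(sum(truth == "MZL"), 10)
  co2 <- simulate_cohort(0, 5, "PB", seed = 64)
  expect_length(co2, 5)
  expect_true(all(vapply(co2, `[[`, character(1), "truth") == "MZL"))
})

test_that("event simulation enforces its input contract", {
  p <- simulate_profile("WM", "BM", seed = 65)
  expect_s3_class(simulate_events(p, 100, seed = 65), "wm_events")
  expect_error(simulate_events(p, 50), "at least 100")
  bad <- p
  bad$grades$CD19$percent_positive <- 140
  expect_error(simulate_events(bad, 1000), "infeasible")
})

test_that("control profiles carry no clone and cannot be scored", {
  ctl <- simulate_profile("control", "BM", seed = 66)
  expect_identical(ctl$light_chain, "none")
  expect_equal(ctl$clonal_fraction, 0)
  expect_length(ctl$grades, 0)
})

test_that("prevalence parameters are recovered in moderate cohorts", {
  set.seed(67)
  cfg <- sim_config()
  profs <- replicate(600, simulate_profile("WM", "BM", cfg),
                     simplify = FALSE)
  kap <- mean(vapply(profs, `[[`, character(1), "light_chain") == "kappa")
  ci <- stats::binom.test(round(600 * kap), 600)$conf.int
  expect_true(ci[1] <= 0.79 && 0.79 <= ci[2])
  cd13 <- mean(vapply(profs, function(p)
    p$grades$CD13$percent_positive >= 2, logical(1)))
  ci13 <- stats::binom.test(round(600 * cd13), 600)$conf.int
  expect_true(ci13[1] <= 2 / 3 && 2 / 3 <= ci13[2])
})

test_that("clonal fraction distributions match the group and compartment", {
  set.seed(68)
  bm <- vapply(replicate(400, simulate_profile("WM", "BM"), simplify = FALSE),
               `[[`, numeric(1), "clonal_fraction")
  expect_true(all(bm >= 2 & bm <= 92))
  expect_lt(abs(mean(bm) - 45), 4)
  pb_wm <- vapply(replicate(300, simulate_profile("WM", "PB"), simplify = FALSE),
                  `[[`, numeric(1), "clonal_fraction")
  pb_mzl <- vapply(replicate(300, simulate_profile("MZL", "PB"), simplify = FALSE),
                   `[[`, numeric(1), "clonal_fraction")
  expect_lt(abs(median(pb_wm) - 7), 2.5)
  expect_lt(abs(median(pb_mzl) - 52), 12)
  expect_lt(median(pb_wm), median(pb_mzl))
})

test_that("WM scores stochastically dominate MZL scores", {
  co <- simulate_cohort(100, 100, "BM", seed = 69)
  scores <- vapply(lapply(co, score_profile), `[[`, integer(1), "total")
  truth <- vapply(co, `[[`, character(1), "truth")
  mw <- mann_whitney(scores[truth == "WM"], scores[truth == "MZL"],
                     alternative = "greater")
  expect_lt(mw$p_value, 0.001)
})

test_that("the CXCR4-mutated subgroup shows the planted CD38 shift", {
  set.seed(70)
  cfg <- sim_config()
  mut <- replicate(60, simulate_profile("WM_CXCR4mut", "BM", cfg),
                   simplify = FALSE)
  wt <- replicate(60, simulate_profile("WM", "BM", cfg), simplify = FALSE)
  cd38_pos <- function(ps) mean(vapply(ps, function(p)
    p$grades$CD38$percent_positive >= 30, logical(1)))
  expect_lt(cd38_pos(mut), cd38_pos(wt))
})

test_that("simulated event tables carry ground-truth population labels", {
  p <- simulate_profile("WM", "BM", seed = 71)
  tab <- simulate_events(p, 2000, seed = 71)
  labs <- tab$metadata$population
  expect_length(labs, 2000)
  expect_setequal(unique(labs), c("clonal_b", "residual_b", "t_cells", "other"))
  # planted clonal share of lymphocytes approximates the profile value
  lymph <- labs != "other"
  expect_lt(abs(100 * sum(labs == "clonal_b") / sum(lymph) -
                  p$clonal_fraction), 6)
})

test_that("cohort summaries round-trip through the summary-table reader", {
  co <- simulate_cohort(3, 2, "PB", seed = 72)
  f <- tempfile(fileext = ".csv")
  write_cohort_summary(co, f)
  recs <- read_summary_table(f)
  expect_length(recs, 5)
  profs <- lapply(recs, profile_from_summary)
  totals <- vapply(lapply(profs, score_profile), `[[`, integer(1), "total")
  direct <- vapply(lapply(co, score_profile), `[[`, integer(1), "total")
  expect_equal(totals, direct)
})
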