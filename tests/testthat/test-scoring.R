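# The 6-point BM and 7-point PB scores and the WM/MZL call.

test_that("archetypal profiles score at the extremes", {
  wm <- patient_profile(c(CD19 = "weak", FMC7 = "negative", CD22 = "weak",
                          CD79b = "strong", CD27 = "negative", CD13 = "normal"),
                        percents = c(CD13 = 3), compartment = "BM")
  s <- bm_score(wm)
  expect_equal(s$total, 6L)
  expect_identical(s$call, "WM")

  mzl <- patient_profile(c(CD19 = "normal", FMC7 = "normal", CD22 = "normal",
                           CD79b = "normal", CD27 = "normal", CD13 = "negative"),
                         percents = c(CD13 = 0), compartment = "BM")
  s0 <- bm_score(mzl)
  expect_equal(s0$total, 0L)
  expect_identical(s0$call, "MZL")
})

test_that("the CD79b point requires CD22 negative or weak", {
  p <- patient_profile(c(CD19 = "weak", FMC7 = "weak", CD22 = "normal",
                         CD79b = "strong", CD27 = "weak", CD13 = "normal"),
                       percents = c(CD13 = 5), compartment = "BM")
  s <- bm_score(p)
  expect_equal(s$total, 4L)  # CD79b point withheld: CD22 is normal
  expect_equal(unname(s$criterion_points[s$criteria == "CD79b"]), 0L)
  expect_identical(s$call, "WM")
  # fully negative CD22 also satisfies the condition (monotone reading)
  p2 <- patient_profile(c(CD19 = "normal", FMC7 = "normal", CD22 = "negative",
                          CD79b = "strong", CD27 = "normal", CD13 = "negative"),
                        percents = c(CD13 = 0), compartment = "BM")
  s2 <- bm_score(p2)
  expect_equal(unname(s2$criterion_points[s2$criteria == "CD79b"]), 1L)
  expect_equal(unname(s2$criterion_points[s2$criteria == "CD22"]), 1L)
})

test_that("the PB clonal-fraction criterion is strictly below 10%", {
  base <- c(CD19 = "weak", FMC7 = "negative", CD22 = "weak",
            CD79b = "strong", CD27 = "negative", CD13 = "normal")
  for (cf in c(7, 9.99)) {
    s <- pb_score(patient_profile(base, percents = c(CD13 = 3),
                                  compartment = "PB", clonal_fraction = cf))
    expect_equal(s$total, 7L)
    expect_identical(s$call, "WM")
  }
  s10 <- pb_score(patient_profile(base, percents = c(CD13 = 3),
                                  compartment = "PB", clonal_fraction = 10))
  expect_equal(s10$total, 6L)  # exactly 10% does not score
  mzl <- patient_profile(c(CD19 = "normal", FMC7 = "strong", CD22 = "strong",
                           CD79b = "normal", CD27 = "normal", CD13 = "negative"),
                         percents = c(CD13 = 0), compartment = "PB",
                         clonal_fraction = 52)
  sm <- pb_score(mzl)
  expect_equal(sm$total, 0L)
  expect_identical(sm$call, "MZL")
})

test_that("classification flips exactly at 3/6 in BM and 4/7 in PB", {
  expect_identical(classify(3, "BM"), "WM")
  expect_identical(classify(2, "BM"), "MZL")
  expect_identical(classify(4, "PB"), "WM")
  expect_identical(classify(3, "PB"), "MZL")
  expect_identical(classify(0, "BM"), "MZL")
  expect_error(classify(7, "BM"), "range")
})

test_that("all criterion combinations match the brute-force oracle", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(combos) <- c("CD19", "FMC7", "CD22", "CD79b", "CD27", "CD13")
  for (i in seq_len(nrow(combos))) {
    sat <- unlist(combos[i, ])
    prof <- profile_for_criteria(sat, "BM")
    s <- bm_score(prof)
    grades <- vapply(prof$grades, `[[`, character(1), "grade")
    expect_equal(s$total,
                 oracle_points(grades, prof$grades$CD13$percent_positive))
    expect_identical(s$call, if (s$total >= 3) "WM" else "MZL")
  }
  # PB: same six plus the clonal-fraction bit
  for (i in seq_len(nrow(combos))) {
    sat <- unlist(combos[i, ])
    for (cf in c(7, 52)) {
      prof <- profile_for_criteria(sat, "PB", clonal_fraction = cf)
      s <- pb_score(prof)
      grades <- vapply(prof$grades, `[[`, character(1), "grade")
      expect_equal(s$total,
                   oracle_points(grades, prof$grades$CD13$percent_positive, cf))
      expect_identical(s$call, if (s$total >= 4) "WM" else "MZL")
    }
  }
})

test_that("scores are monotone: satisfying one more criterion never lowers the call", {
  set.seed(41)
  for (rep in 1:25) {
    sat <- setNames(runif(6) < 0.5,
                    c("CD19", "FMC7", "CD22", "CD79b", "CD27", "CD13"))
    s0 <- bm_score(profile_for_criteria(sat, "BM"))
    for (k in names(sat)[!sat]) {
      sat2 <- sat; sat2[k] <- TRUE
      s1 <- bm_score(profile_for_criteria(sat2, "BM"))
      expect_gte(s1$total, s0$total)
      expect_false(s0$call == "WM" && s1$call == "MZL")
    }
  }
})

test_that("scoring is deterministic and order-free", {
  p <- patient_profile(c(CD13 = "normal", CD27 = "weak", CD79b = "strong",
                         CD22 = "weak", FMC7 = "normal", CD19 = "weak"),
                       percents = c(CD13 = 4), compartment = "BM")
  expect_identical(bm_score(p)$total, bm_score(p)$total)
  expect_equal(bm_score(p)$total, 5L)
})

test_that("a missing criterion that could change the call suppresses it", {
  p <- patient_profile(c(CD19 = "weak", FMC7 = "negative", CD22 = "normal",
                         CD79b = "normal", CD27 = "normal"),
                       compartment = "BM")  # CD13 unknown, total 2 of 5
  s <- bm_score(p)
  expect_equal(s$total, 2L)
  expect_equal(s$max_total, 5L)
  expect_true(is.na(s$call))            # 2 or 3 depending on CD13
  expect_identical(s$missing_criteria, "CD13")
  # but a decided call is still made when the missing point cannot matter
  p2 <- patient_profile(c(CD19 = "normal", FMC7 = "normal", CD22 = "normal",
                          CD79b = "normal", CD27 = "normal"),
                        compartment = "BM")
  expect_identical(bm_score(p2)$call, "MZL")
})

test_that("a WM call with strong FMC7 carries an advisory note", {
  p <- patient_profile(c(CD19 = "weak", FMC7 = "strong", CD22 = "weak",
                         CD79b = "strong", CD27 = "weak", CD13 = "normal"),
                       percents = c(CD13 = 5), compartment = "BM")
  s <- bm_score(p)
  expect_identical(s$call, "WM")
  expect_match(s$advisory, "FMC7")
})
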