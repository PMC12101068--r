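# Gating: lymphocyte gate, B-cell clonality partition, percent-positive
# and MFI.

test_that("percent_positive counts events above the cutoff", {
  vals <- matrix(c(1:100), ncol = 1, dimnames = list(NULL, "CD13"))
  tab <- event_table(vals)
  expect_equal(percent_positive(tab, "CD13", 63), 37.0)
  expect_equal(percent_positive(tab, "CD13", 1000), 0.0)
  expect_equal(percent_positive(tab, "CD13", -Inf), 100.0)
  expect_error(percent_positive(tab, "CD22", 0), "CD22")
})

test_that("percent_positive is invariant under permutation and duplication,
           and non-increasing in the cutoff", {
  set.seed(21)
  x <- rlnorm(500, 4, 1)
  tab <- event_table(matrix(x, ncol = 1, dimnames = list(NULL, "CD19")))
  perm <- event_table(matrix(sample(x), ncol = 1, dimnames = list(NULL, "CD19")))
  dup <- event_table(matrix(rep(x, 2), ncol = 1, dimnames = list(NULL, "CD19")))
  for (cut in c(-Inf, 10, 50, 200, Inf)) {
    p <- percent_positive(tab, "CD19", cut)
    expect_equal(percent_positive(perm, "CD19", cut), p)
    expect_equal(percent_positive(dup, "CD19", cut), p)
  }
  cuts <- sort(runif(20, 0, 500))
  pcts <- vapply(cuts, function(cu) percent_positive(tab, "CD19", cu), numeric(1))
  expect_true(all(diff(pcts) <= 0))
})

test_that("MFI is the arithmetic mean on the instrument scale", {
  tab <- event_table(matrix(c(10, 20, 30), ncol = 1,
                            dimnames = list(NULL, "CD22")))
  expect_equal(mfi(tab, "CD22"), 20.0)
  one <- event_table(matrix(42.5, ncol = 1, dimnames = list(NULL, "CD22")))
  expect_equal(mfi(one, "CD22"), 42.5)
  set.seed(22)
  big <- event_table(matrix(rlnorm(10000, 5, 0.5), ncol = 1,
                            dimnames = list(NULL, "CD22")))
  expect_lt(abs(mfi(big, "CD22") / exp(5 + 0.125) - 1), 0.02)
})

test_that("the lymphocyte gate recovers planted lymphocytes and keeps pure input", {
  set.seed(23)
  n <- 10000
  lym <- cbind(CD45 = rlnorm(0.7 * n, log(3000), 0.15),
               SSC = rlnorm(0.7 * n, log(250), 0.3))
  gran <- cbind(CD45 = rlnorm(0.3 * n, log(1000), 0.25),
                SSC = rlnorm(0.3 * n, log(2800), 0.3))
  tab <- event_table(rbind(lym, gran),
                     metadata = list(population = rep(c("lymph", "gran"),
                                                      c(nrow(lym), nrow(gran)))))
  gated <- gate_lymphocytes(tab)
  truth <- gated$metadata$population
  expect_gt(sum(truth == "lymph") / nrow(lym), 0.95)       # recovery
  expect_gt(mean(truth == "lymph"), 0.98)                   # purity
  pure <- event_table(lym)
  expect_gte(n_events(gate_lymphocytes(pure)) / nrow(lym), 0.99)
  bad <- event_table(cbind(CD45 = rep(0, 100), SSC = rlnorm(100, 5, 1)))
  expect_error(gate_lymphocytes(bad), "gating error")
  nossc <- event_table(cbind(CD45 = rlnorm(100, 8, 1)))
  expect_error(gate_lymphocytes(nossc), "gating error")
})

test_that("light-chain restriction detection recovers planted clones", {
  set.seed(24)
  # 80% kappa clone among polytypic residual B cells
  tab <- make_b_cells(4000, 80, "kappa")
  part <- partition_b_cells(tab)
  expect_identical(part$light_chain, "kappa")
  expect_lt(abs(100 * n_events(part$clonal) / 4000 - 80), 3)
  # fully polytypic: no restriction
  poly <- make_b_cells(4000, 0)
  expect_identical(partition_b_cells(poly)$light_chain, "none")
  # pure lambda clone (symmetry)
  lam <- make_b_cells(4000, 100, "lambda")
  partl <- partition_b_cells(lam)
  expect_identical(partl$light_chain, "lambda")
  expect_gt(n_events(partl$clonal) / 4000, 0.95)
})

test_that("planted clone fractions 10-80% are recovered within 3 points", {
  set.seed(25)
  for (f in c(10, 30, 50, 80)) {
    part <- partition_b_cells(make_b_cells(2000, f, "kappa"))
    expect_identical(part$light_chain, "kappa")
    got <- 100 * n_events(part$clonal) / n_events(part$b_cells)
    expect_lt(abs(got - f), 3)
  }
})

test_that("too few B cells yields no clonality call with a low-count flag", {
  set.seed(26)
  tab <- make_b_cells(30, 100, "kappa")
  part <- partition_b_cells(tab)
  expect_identical(part$light_chain, "none")
  expect_true("low_b_count" %in% part$flags)
})

test_that("population summaries honour their structural invariants", {
  set.seed(27)
  p <- simulate_profile("WM", "BM")
  tab <- simulate_events(p, 15000)
  s <- summarize_events(tab)
  pops <- s$populations
  expect_lte(pops$clonal_b$n_events + pops$residual_b$n_events,
             pops$b_cells$n_events)
  expect_equal(s$clonal_fraction_of_lymphocytes,
               100 * pops$clonal_b$n_events / pops$lymphocytes$n_events)
  for (pn in names(pops)) {
    pct <- pops[[pn]]$pct
    expect_true(all(is.na(pct) | (pct >= 0 & pct <= 100)))
    if (pops[[pn]]$n_events > 0)
      expect_true(all(is.na(pops[[pn]]$mfi) | pops[[pn]]$mfi > 0))
  }
  # WM clone expresses CD79b more strongly than residual normal B cells
  expect_gt(pops$clonal_b$mfi[["CD79b"]] / pops$residual_b$mfi[["CD79b"]], 1)
})

test_that("three-tube summaries cover all panel markers exactly once", {
  set.seed(28)
  p <- simulate_profile("WM", "BM")
  tubes <- simulate_events(p, 6000, tubes = TRUE)
  expect_length(tubes, 3)
  s <- summarize_events(tubes)
  got <- names(s$populations$clonal_b$pct)
  expect_setequal(got, c("CD19", "CD20", "CD22", "CD79b", "CD27", "CD13",
                         "FMC7", "CD38", "CD5", "CD23", "CD43",
                         "kappa", "lambda"))
  expect_false(anyDuplicated(got) > 0)
  expect_identical(s$light_chain, p$light_chain)
})

test_that("healthy-control samples yield no clonal population", {
  set.seed(29)
  ctl <- simulate_profile("control", "BM")
  s <- summarize_events(simulate_events(ctl, 15000))
  expect_identical(s$light_chain, "none")
  expect_equal(s$clonal_fraction_of_lymphocytes, 0)
  expect_error(grade_panel(s), "no clonal")
})
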