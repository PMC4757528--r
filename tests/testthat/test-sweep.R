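# small synthetic predictor/survival set built directly at the array level,
# so sweep behavior can be tested independently of the imaging stages
make_sweep_fixture <- function(n = 40, grid = threshold_grid(c(50, 100, 150),
                                                             c(0, 1))) {
  np <- length(grid$pe_thresholds); ns <- length(grid$ser_thresholds)
  records <- lapply(seq_len(n), function(i) {
    base <- rexp(1, 1 / 20)
    m <- matrix(base * exp(-0.01 * outer(grid$pe_thresholds,
                                         grid$ser_thresholds * 50, "+")),
                np, ns, dimnames = list(pe_t = grid$pe_thresholds,
                                        ser_t = grid$ser_thresholds))
    structure(list(patient_id = sprintf("P%02d", i),
                   subtype = sample(c("HRpos_HER2neg", "HER2pos", "TN",
                                      "unknown"), 1),
                   delta_ftv2 = m - 100, delta_ftvf = m - 120, ftv_f = m),
              class = "predictor_record")
  })
  arr <- predictor_array(records)
  surv <- survival_records(data.frame(
    patient_id = arr$patient_id, subtype = arr$subtype,
    rfs_months = rexp(n, 0.02) + 0.5, event = rbinom(n, 1, 0.6)))
  list(arr = arr, surv = surv, grid = grid)
}

test_that("a sweep fits every grid cell and carries its bookkeeping", {
  set.seed(81)
  fx <- make_sweep_fixture()
  sw <- sweep_cox(fx$arr, fx$surv, fx$grid, "ftv_f", "full")
  expect_equal(sw$n_fits, 6)
  expect_equal(dim(sw$p), c(3, 2))
  expect_equal(sw$n_significant,
               sum(sw$p < 0.05 & sw$converged & !sw$degenerate, na.rm = TRUE))
  expect_true(all(sw$hr[sw$converged] > 0))
  # default grid attempts all 198 cells
  set.seed(82)
  fx2 <- make_sweep_fixture(n = 30, grid = default_grid())
  sw2 <- sweep_cox(fx2$arr, fx2$surv, fx2$grid, "delta_ftvf", "full")
  expect_equal(sw2$n_fits, 198)
})

test_that("subset filtering drops other subtypes and rejects empty subsets", {
  set.seed(83)
  fx <- make_sweep_fixture(n = 50)
  tn <- sweep_cox(fx$arr, fx$surv, fx$grid, "ftv_f", "TN")
  expect_equal(max(tn$n, na.rm = TRUE), sum(fx$surv$subtype == "TN"))
  no_tn <- fx$surv
  no_tn$subtype[no_tn$subtype == "TN"] <- "unknown"
  expect_error(sweep_cox(fx$arr, no_tn, fx$grid, "ftv_f", "TN"), "empty subset")
  expect_error(sweep_cox(fx$arr, fx$surv, fx$grid, "ftv_f", "basal"),
               "unknown subset")
})

test_that("patients missing a predictor at a cell are dropped cell-wise only", {
  set.seed(84)
  fx <- make_sweep_fixture(n = 30)
  fx$arr$ftv_f[1:5, 1, 1] <- NA  # five patients missing at cell (1,1)
  sw <- sweep_cox(fx$arr, fx$surv, fx$grid, "ftv_f", "full")
  expect_equal(sw$n[1, 1], 25)
  expect_equal(sw$n[2, 2], 30)
})

test_that("the optimum is the lowest eligible p with deterministic tie-breaks", {
  set.seed(85)
  fx <- make_sweep_fixture()
  sw <- sweep_cox(fx$arr, fx$surv, fx$grid, "ftv_f", "full")
  opt <- select_optimized(sw)
  eligible <- sw$converged & !sw$degenerate & is.finite(sw$p)
  expect_equal(sw$p[attr(opt, "index")[1], attr(opt, "index")[2]],
               min(sw$p[eligible]))

  # hand-built result with an exact tie differing only in pe_t
  sw2 <- sw
  sw2$p[, ] <- 0.5; sw2$hr[, ] <- 1
  sw2$p[2, 1] <- sw2$p[3, 1] <- 0.01
  sw2$converged[, ] <- TRUE; sw2$degenerate[, ] <- FALSE
  opt2 <- select_optimized(sw2)
  expect_equal(unname(opt2["pe_t"]), sw2$grid$pe_thresholds[2])  # lower pe_t
  expect_true(attr(opt2, "tie_broken"))

  # all-degenerate sweep: selection error with diagnostics
  sw3 <- sw
  sw3$degenerate[, ] <- TRUE
  expect_error(select_optimized(sw3), "no eligible cells")
})

test_that("sweep and comparison tables expose the documented columns", {
  set.seed(86)
  fx <- make_sweep_fixture()
  sw <- sweep_cox(fx$arr, fx$surv, fx$grid, "delta_ftv2", "full")
  tab <- sweep_table(sw)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("subset", "predictor", "pe_t", "ser_t", "n", "events",
                      "beta", "hr", "ci_lo", "ci_hi", "lr_p", "converged",
                      "degenerate"))
  cr <- comparison_row(sw)
  expect_equal(nrow(cr), 1)
  expect_true(all(c("opt_hr", "opt_ci_lo", "opt_ci_hi", "opt_p",
                    "def_hr", "def_ci_lo", "def_ci_hi", "def_p")
                  %in% names(cr)))
})

test_that("per-predictor default scales match the reporting units", {
  expect_equal(default_scale("delta_ftv2"), 10)
  expect_equal(default_scale("delta_ftvf"), 10)
  expect_equal(default_scale("ftv_f"), 1)
})
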