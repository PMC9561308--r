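test_that("discount factors follow annual compounding", {
  econ <- econ_params()
  expect_equal(discount_factor(0, econ), 1)
  expect_equal(discount_factor(1, econ), 1 / 1.05)
  expect_equal(discount_factor(2, econ), 1 / 1.05^2)
  econ0 <- econ_params(discount_rate = 0)
  expect_equal(discount_factor(c(0, 3, 9.7), econ0), rep(1, 3))
  expect_error(discount_factor(-1, econ))
})

test_that("drug cost per cycle follows the dosing rules", {
  econ <- econ_params()
  arms <- build_strategies(base_config())
  # 20 mg/day x 21 d x 4.255 $/mg + 200 mg x 25.98 $/mg
  expect_equal(drug_cost_per_cycle(arms$lp, econ),
               20 * 21 * 4.255 + 200 * 25.98)
  expect_equal(drug_cost_per_cycle(arms$lp, econ), 6983.10)

  dox_only <- strategy("dox",
    list(drug_component("doxorubicin", 0.3220, "per_admin_bsa_mg_per_m2", 60)),
    duration_cycles = 5, ae = arms$chemo$ae,
    os = arms$chemo$os, pfs = arms$chemo$pfs)
  expect_equal(drug_cost_per_cycle(dox_only, econ), 60 * 1.64 * 0.3220)

  free <- strategy("free",
    list(drug_component("placebo", 0, "per_cycle_fixed_mg", 100)),
    duration_cycles = 5, ae = arms$chemo$ae,
    os = arms$chemo$os, pfs = arms$chemo$pfs)
  expect_equal(drug_cost_per_cycle(free, econ), 0)
  expect_error(drug_component("bad", -1, "per_cycle_fixed_mg", 100))
})

test_that("the cohort trace starts at (1,0,0), conserves mass and is monotone", {
  econ <- econ_params()
  m <- table1_models()
  tr <- compute_trace(m$lp_os, m$lp_pfs, econ)
  expect_equal(nrow(tr), 174)
  expect_equal(unlist(tr[1, c("pfd", "pd", "dead")]),
               c(pfd = 1, pd = 0, dead = 0))
  expect_true(all(abs(tr$pfd + tr$pd + tr$dead - 1) < 1e-9))
  expect_true(all(diff(tr$dead) >= 0))
  expect_true(all(diff(tr$pfd) <= 0))
  expect_true(all(tr$pfd >= 0 & tr$pd >= 0 & tr$dead <= 1))
})

test_that("half of the cohort is dead at the overall-survival median", {
  econ <- econ_params()
  m <- table1_models()
  tr <- compute_trace(m$lp_os, m$lp_pfs, econ)
  med <- median_by_root(m$lp_os)
  k <- which.min(abs(tr$t_months - med))
  # nearest cycle start can sit up to a third of a month from the median
  expect_equal(tr$dead[k], 0.5, tolerance = 0.02)
})

test_that("degenerate economic settings collapse the arm totals as expected", {
  cfg <- base_config()
  arms <- build_strategies(cfg)

  zero_h <- econ_params(horizon_years = 0)
  r0 <- run_arm(arms$lp, cfg$costs, cfg$utilities, zero_h)
  expect_equal(r0$total_cost, 0)
  expect_equal(r0$total_qalys, 0)

  undisc <- econ_params(discount_rate = 0)
  r1 <- run_arm(arms$lp, cfg$costs, cfg$utilities, undisc)
  expect_equal(r1$total_cost, r1$undiscounted$total_cost)
  expect_equal(r1$total_qalys, r1$undiscounted$total_qalys)
  expect_equal(r1$total_life_years, r1$undiscounted$total_life_years)
})

test_that("QALYs equal life years when utilities are 1 and disutilities 0", {
  cfg <- base_config()
  cfg$utilities$pfd <- 1
  cfg$utilities$pd <- 1
  for (ae in names(cfg$utilities$ae_disutility))
    cfg$utilities$ae_disutility[[ae]] <- 0
  econ <- econ_from_config(cfg)
  for (arm in build_strategies(cfg)) {
    r <- run_arm(arm, cfg$costs, cfg$utilities, econ)
    expect_equal(r$total_qalys, r$total_life_years, tolerance = 1e-9)
    expect_lte(r$total_qalys, r$total_life_years + 1e-12)
  }
})

test_that("total cost is linear in prices (doubling all unit costs doubles it)", {
  cfg <- base_config()
  cfg2 <- cfg
  for (p in names(cfg2$prices_per_mg))
    cfg2$prices_per_mg[[p]] <- 2 * cfg2$prices_per_mg[[p]]
  for (p in names(cfg2$costs$ae))
    cfg2$costs$ae[[p]] <- 2 * cfg2$costs$ae[[p]]
  cfg2$costs$followup_per_cycle <- 2 * cfg2$costs$followup_per_cycle
  cfg2$costs$bsc_per_cycle <- 2 * cfg2$costs$bsc_per_cycle
  a <- run_base_case(cfg); b <- run_base_case(cfg2)
  expect_equal(b$arms$intervention$total_cost,
               2 * a$arms$intervention$total_cost, tolerance = 1e-12)
  expect_equal(b$arms$comparator$total_cost,
               2 * a$arms$comparator$total_cost, tolerance = 1e-12)
  expect_equal(b$delta_qaly, a$delta_qaly, tolerance = 1e-12)
})

test_that("discounted totals never exceed undiscounted totals", {
  cfg <- base_config()
  econ <- econ_from_config(cfg)
  for (arm in build_strategies(cfg)) {
    r <- run_arm(arm, cfg$costs, cfg$utilities, econ)
    expect_lte(r$total_cost, r$undiscounted$total_cost)
    expect_lte(r$total_life_years, r$undiscounted$total_life_years)
    expect_lte(r$total_qalys, r$undiscounted$total_qalys)
  }
})

test_that("totals are non-negative and weakly increasing in the horizon", {
  cfg <- base_config()
  arms <- build_strategies(cfg)
  prev <- c(0, 0, 0)
  for (h in c(1, 2, 5, 10)) {
    econ <- econ_params(horizon_years = h)
    r <- run_arm(arms$chemo, cfg$costs, cfg$utilities, econ)
    now <- c(r$total_cost, r$total_life_years, r$total_qalys)
    expect_true(all(now >= prev - 1e-12))
    prev <- now
  }
})

test_that("the combination arm dominates chemotherapy in overall survival", {
  m <- table1_models()
  # the independently fitted OS curves cross once at ~2.5 months
  # (the steeper chemotherapy shape starts above); beyond that the
  # combination curve dominates for the whole horizon
  grid <- seq(3, 120, by = 0.5)
  expect_true(all(survival_prob(m$lp_os, grid) >=
                  survival_prob(m$chemo_os, grid)))
  res <- run_base_case(base_config())
  expect_gt(res$arms$intervention$total_life_years,
            res$arms$comparator$total_life_years)
})

test_that("the half-cycle correction switch shifts totals only slightly", {
  cfg <- base_config()
  cfg$model$half_cycle_correction <- TRUE
  a <- run_base_case(base_config())
  b <- run_base_case(cfg)
  expect_false(isTRUE(all.equal(a$delta_cost, b$delta_cost)))
  expect_lt(abs(b$delta_cost - a$delta_cost) / a$delta_cost, 0.05)
  expect_lt(abs(b$delta_qaly - a$delta_qaly) / a$delta_qaly, 0.05)
})
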