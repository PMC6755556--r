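mk_pair <- function(kd_f, n_f, kd_l, n_l, logp_f = NA, logp_l = NA,
                    id = "p") {
  suppressWarnings(f2l_pair(
    compound_record(paste0(id, "_F"), n_f, affinity = kd_f,
                    affinity_unit = "M", affinity_kind = "KD",
                    logp = logp_f),
    compound_record(paste0(id, "_L"), n_l, affinity = kd_l,
                    affinity_unit = "M", affinity_kind = "KD",
                    logp = logp_l),
    project_id = id))
}

test_that("pair size efficiency is the affinity gain per added atom, unit-free", {
  p <- mk_pair(1e-3, 10, 1e-9, 30)
  expect_equal(pair_mse(p), 0.30)
  expect_equal(pair_mse(mk_pair(1e-6, 10, 1e-6, 25)), 0)
  # nanomolar re-expression changes nothing (ratio inside the log)
  p_nm <- suppressWarnings(f2l_pair(
    compound_record("f", 10, affinity = 1e6, affinity_unit = "nM",
                    affinity_kind = "KD"),
    compound_record("l", 30, affinity = 1, affinity_unit = "nM",
                    affinity_kind = "KD")))
  expect_identical(pair_mse(p_nm), pair_mse(p))
  expect_error(pair_mse(mk_pair(1e-3, 15, 1e-6, 15)), "equal N_nH")
})

test_that("lipophilicity-corrected gain separates affinity from hydrophobic bulk", {
  # affinity gain exactly matched by a logP gain: zero
  p0 <- mk_pair(1e-4, 10, 1e-7, 20, logp_f = 1, logp_l = 4)
  expect_equal(pair_lip_eff(p0), 0, tolerance = 1e-12)
  p3 <- mk_pair(1e-4, 10, 1e-7, 20, logp_f = 1, logp_l = 1)
  expect_equal(pair_lip_eff(p3), 3, tolerance = 1e-12)
  expect_error(pair_lip_eff(mk_pair(1e-4, 10, 1e-7, 20)), "logP")
})

test_that("pair summaries are bit-identical under common unit re-expression", {
  units <- c("M", "mM", "uM", "nM")
  base_kd <- c(f = 2.3e-4, l = 3.1e-8)
  vals <- lapply(units, function(u) {
    s <- parse_conc_unit(u)
    p <- suppressWarnings(f2l_pair(
      compound_record("f", 12, affinity = base_kd["f"] / s,
                      affinity_unit = u, affinity_kind = "KD", logp = 1.2),
      compound_record("l", 27, affinity = base_kd["l"] / s,
                      affinity_unit = u, affinity_kind = "KD",
                      logp = 3.4)))
    c(pair_mse(p), pair_lip_eff(p))
  })
  for (v in vals[-1]) expect_identical(v, vals[[1]])
})

test_that("the grid paired test matches its closed form and flips sign where predicted", {
  # leads grow 10 -> 30 atoms with equal eta at 1 M: mean delta eta is
  # positive below 1 M and negative above
  pairs <- lapply(1:6, function(i) {
    pkf <- 2.5 + 0.1 * i
    mk_pair(10^(-pkf), 10, 10^(-3 * pkf), 30, id = paste0("p", i))
  })
  # equal eta at 1 M by construction: pk_l / 30 = pk_f / 10
  gt <- grid_paired_test(pairs, cstd_grid(c(0.001, 0.01, 0.1, 1, 10)))
  expect_equal(gt$mean_delta_eta[4], 0, tolerance = 1e-12)
  expect_true(all(gt$mean_delta_eta[1:3] > 0))
  expect_lt(gt$mean_delta_eta[5], 0)
  # closed form: mean difference between grid points
  slope <- attr(gt, "slope")
  expect_equal(slope, mean(vapply(pairs, function(p)
    1 / p$lead$n_nh - 1 / p$fragment$n_nh, numeric(1))))
  for (k in 2:5)
    expect_equal(gt$mean_delta_eta[k] - gt$mean_delta_eta[k - 1],
                 log10(gt$cstd_molar[k] / gt$cstd_molar[k - 1]) * slope,
                 tolerance = 1e-12)
  expect_error(grid_paired_test(pairs[1:2]), "at least 3")
})

test_that("the matched-pair t statistics agree with stats::t.test", {
  pairs <- make_f2l_cohort(12, seed = 99)
  gt <- grid_paired_test(pairs, cstd_grid(c(0.01, 1)))
  for (k in 1:2) {
    cm <- gt$cstd_molar[k]
    d <- vapply(pairs, function(p)
      eta_bind(p$lead, thermo_context(c_standard = cm))$value -
        eta_bind(p$fragment, thermo_context(c_standard = cm))$value,
      numeric(1))
    tt <- stats::t.test(d)
    expect_equal(gt$t[k], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(gt$p[k], tt$p.value, tolerance = 1e-10)
  }
})

test_that("quartile maps match brute-force sorted quartiles and degenerate correctly", {
  # identical slopes: all five numbers equal
  pairs <- lapply(1:6, function(i)
    mk_pair(1e-4, 10, 10^(-4 - 0.3 * 15), 25, id = paste0("q", i)))
  qm <- quartile_map(pairs)
  expect_equal(unname(qm$mse), rep(0.3, 5), tolerance = 1e-12)
  # known slopes 1..5: median 3
  pairs2 <- lapply(1:5, function(s)
    mk_pair(1e-4, 10, 10^(-4 - s * 10), 20, id = paste0("s", s)))
  qm2 <- quartile_map(pairs2)
  expect_equal(unname(qm2$mse["median"]), 3)
  # random slopes vs an independent sort-based oracle (type 7)
  set.seed(3)
  slopes <- round(stats::runif(11, 0.1, 1.4), 3)
  pairs3 <- lapply(seq_along(slopes), function(i)
    mk_pair(1e-4, 10, 10^(-4 - slopes[i] * 12), 22, id = paste0("r", i)))
  qm3 <- quartile_map(pairs3)
  s <- sort(slopes); n <- length(s)
  oracle_q <- function(p) {  # linear interpolation of order statistics
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  expect_equal(unname(qm3$mse),
               c(s[1], oracle_q(0.25), oracle_q(0.5), oracle_q(0.75),
                 s[n]), tolerance = 1e-12)
  expect_error(quartile_map(pairs3[1:4]), "at least 5")
})

test_that("rule audits apply the numeric Ro3/Ro5 limits and report missing data", {
  recs <- list(
    compound_record("frag_ok", 15, p_affinity = 4, affinity_kind = "pKD",
                    mw = 250, logp = 2, hbd = 1, hba = 2),
    compound_record("mw_over", 20, p_affinity = 5, affinity_kind = "pKD",
                    mw = 320, logp = 2, hbd = 2, hba = 3),
    compound_record("drug", 35, p_affinity = 8, affinity_kind = "pKD",
                    mw = 480, logp = 4.5, hbd = 2, hba = 8),
    compound_record("no_props", 12, p_affinity = 4,
                    affinity_kind = "pKD"))
  audit <- rule_audit(recs)
  expect_true(audit$ro3_pass[1])
  expect_false(audit$ro3_pass[2])
  expect_identical(audit$ro3_fail_on[2], "mw")
  expect_true(audit$ro5_pass[3])
  expect_false(audit$ro3_pass[3])
  expect_false(audit$ro3_assessable[4])
  expect_true(is.na(audit$ro3_pass[4]))
  expect_match(attr(audit, "hb_convention"), "Lipinski")
})
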