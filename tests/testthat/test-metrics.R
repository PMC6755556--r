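test_that("compound records derive the missing affinity form and flag IC50 approximations", {
  r1 <- compound_record("a", 10, affinity = 1, affinity_unit = "mM",
                        affinity_kind = "KD")
  expect_equal(r1$kd_molar, 1e-3)
  expect_equal(r1$pkd, 3)
  expect_false(r1$approx)
  r2 <- compound_record("b", 20, p_affinity = 6, affinity_kind = "pIC50")
  expect_equal(r2$kd_molar, 1e-6)
  expect_true(r2$approx)
  # p-scale relative to a non-molar reference unit
  r3 <- compound_record("c", 15, p_affinity = 2, p_ref_unit = "nM",
                        affinity_kind = "pKD")
  expect_equal(r3$kd_molar, 1e-11)
  expect_error(compound_record("d", 10), "exactly one")
  expect_error(compound_record("e", 10, affinity = 1, p_affinity = 3),
               "exactly one")
  expect_error(compound_record("f", 0, p_affinity = 3), "positive integer")
  expect_error(compound_record("g", 10, affinity = -2,
                               affinity_unit = "M"), "positive")
})

test_that("eta_bind matches the worked grid values and is zero at K_D = C-standard", {
  r10 <- rec_kd("a", 10, 1e-3)
  expect_equal(eta_bind(r10, thermo_context(c_standard = 0.1))$value, 0.20)
  r30 <- rec_kd("b", 30, 1e-9)
  expect_equal(round(eta_bind(r30, thermo_context(c_standard = 10))$value,
                     2), 0.33)
  expect_equal(eta_bind(rec_kd("c", 25, 0.05),
                        thermo_context(c_standard = 0.05))$value, 0)
})

test_that("dg_per_atom is RT ln10 times eta_bind and reproduces the 0.4 kcal/mol calibration", {
  r <- rec_kd("a", 10, 1e-3)
  expect_equal(round(dg_per_atom(r, ctx298)$value, 1), 0.4)
  for (cs in c(0.01, 1, 10)) {
    ctx <- thermo_context(298, cs)
    expect_equal(dg_per_atom(r, ctx)$value,
                 eta_bind(r, ctx)$value * RT298LN10, tolerance = 1e-12)
  }
})

test_that("a per-atom efficiency floor translates to the stated affinity thresholds", {
  ctx300 <- thermo_context(300)
  expect_equal(round(pkd_from_dg_per_atom(0.12, 50, ctx300), 1), 4.4)
  expect_equal(round(pkd_from_dg_per_atom(0.12, 214, ctx300), 1), 18.7)
  # inverse map is consistent with the forward metric
  pk <- pkd_from_dg_per_atom(0.12, 50, ctx300)
  rec <- compound_record("z", 50, p_affinity = pk, affinity_kind = "pKD")
  expect_equal(dg_per_atom(rec, ctx300)$value, 0.12, tolerance = 1e-12)
})

test_that("BEI scales inversely with molecular weight and vanishes at 1 M potency", {
  r <- compound_record("a", 22, affinity = 1, affinity_unit = "uM",
                       affinity_kind = "IC50", mw = 300)
  expect_equal(bei(r)$value, 20)
  expect_true(bei(r)$approx)
  r2 <- compound_record("b", 22, affinity = 1, affinity_unit = "uM",
                        affinity_kind = "IC50", mw = 600)
  expect_equal(bei(r2)$value, 10)
  r3 <- compound_record("c", 22, affinity = 1, affinity_unit = "M",
                        affinity_kind = "IC50", mw = 450)
  expect_equal(bei(r3)$value, 0)
  expect_error(bei(rec_kd("d", 5, 1e-6)), "MW")
})

test_that("LEAN is pIC50 per atom and coincides with eta_bind at the 1 M reference", {
  r <- compound_record("a", 20, p_affinity = 6, affinity_kind = "pIC50")
  expect_equal(lean(r)$value, 0.30)
  expect_equal(lean(r)$value,
               eta_bind(r, thermo_context(c_standard = 1))$value)
  r0 <- compound_record("b", 20, p_affinity = 0, affinity_kind = "pIC50")
  expect_equal(lean(r0)$value, 0)
})

test_that("LLE offsets affinity by lipophilicity and its differences are unit-invariant", {
  r <- compound_record("a", 25, p_affinity = 9, affinity_kind = "pKD",
                       logp = 3)
  expect_equal(lle(r)$value, 6)
  expect_null(lle(r)$c_standard)
  r0 <- compound_record("b", 25, p_affinity = 7.2, affinity_kind = "pKD",
                        logp = 0)
  expect_equal(lle(r0)$value, 7.2)
  # a common reference-unit change shifts both LLE values equally
  shift <- 3  # e.g. quoting p-values against 1 mM instead of 1 M
  d0 <- lle(r)$value - lle(r0)$value
  ra <- compound_record("a2", 25, p_affinity = 9 - shift,
                        affinity_kind = "pKD", logp = 3)
  rb <- compound_record("b2", 25, p_affinity = 7.2 - shift,
                        affinity_kind = "pKD", logp = 0)
  expect_equal(lle(ra)$value - lle(rb)$value, d0, tolerance = 1e-12)
  expect_error(lle(rec_kd("c", 5, 1e-6)), "logP")
})

test_that("fit quality divides by the size reference and stays C-standard dependent", {
  r <- rec_kd("a", 10, 1e-3)   # dg_per_atom = 0.409 at 1 M, 298 K
  self_ref <- function(n) dg_per_atom(r, ctx298)$value
  expect_equal(fq(r, self_ref, ctx298)$value, 1)
  half <- compound_record("h", 10, p_affinity = 1.5, affinity_kind = "pKD")
  double_ref <- function(n) 2 * dg_per_atom(half, ctx298)$value
  expect_equal(fq(half, double_ref, ctx298)$value, 0.5, tolerance = 1e-12)
  # changing C-standard changes FQ when the reference is held fixed
  fq1 <- fq(r, function(n) 0.4, thermo_context(298, 1))$value
  fq10 <- fq(r, function(n) 0.4, thermo_context(298, 10))$value
  expect_gt(abs(fq10 - fq1), 0.1)
  expect_error(fq(r, function(n) -1, ctx298), "positive")
})

test_that("enthalpic efficiency needs no standard concentration", {
  ee <- enthalpic_efficiency(-10, 20)
  expect_equal(ee$value, 0.5)
  expect_null(ee$c_standard)
  expect_equal(enthalpic_efficiency(0, 7)$value, 0)
})

test_that("eta_bind obeys the affine C-standard shift law for arbitrary records", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    kd <- 10^stats::runif(1, -12, 0)
    r <- rec_kd(paste0("r", i), n, kd)
    c1 <- 10^stats::runif(1, -3, 1); c2 <- 10^stats::runif(1, -3, 1)
    e1 <- eta_bind(r, thermo_context(c_standard = c1))$value
    e2 <- eta_bind(r, thermo_context(c_standard = c2))$value
    expect_equal(e2 - e1, log10(c2 / c1) / n, tolerance = 1e-12)
  }
})

test_that("pK_D differences are unit-invariant but eta_bind differences are not (unless sizes match)", {
  a <- rec_kd("a", 12, 1e-5)
  b <- rec_kd("b", 31, 1e-8)
  dpk <- b$pkd - a$pkd
  # re-expressing both affinities in nM leaves the pK difference unchanged
  a2 <- compound_record("a", 12, affinity = 1e-5 / 1e-9,
                        affinity_unit = "nM", affinity_kind = "KD")
  b2 <- compound_record("b", 31, affinity = 1e-8 / 1e-9,
                        affinity_unit = "nM", affinity_kind = "KD")
  expect_equal(b2$pkd - a2$pkd, dpk, tolerance = 1e-12)
  # eta differences move when C-standard moves and sizes differ
  d1 <- eta_bind(b, thermo_context(c_standard = 1))$value -
    eta_bind(a, thermo_context(c_standard = 1))$value
  d2 <- eta_bind(b, thermo_context(c_standard = 10))$value -
    eta_bind(a, thermo_context(c_standard = 10))$value
  expect_false(isTRUE(all.equal(d1, d2)))
  # ... but not when sizes are equal
  c1 <- rec_kd("c", 12, 1e-7)
  e1 <- eta_bind(c1, thermo_context(c_standard = 1))$value -
    eta_bind(a, thermo_context(c_standard = 1))$value
  e2 <- eta_bind(c1, thermo_context(c_standard = 10))$value -
    eta_bind(a, thermo_context(c_standard = 10))$value
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("metric computation does not mutate the input record", {
  r <- compound_record("a", 10, affinity = 1, affinity_unit = "mM",
                       affinity_kind = "KD", mw = 200, logp = 1)
  snapshot <- unclass(r)
  invisible(eta_bind(r, ctx298)); invisible(dg_per_atom(r, ctx298))
  invisible(bei(r)); invisible(lean(r)); invisible(lle(r))
  expect_identical(unclass(r), snapshot)
})

test_that("metric_table emits long-format rows and skips metrics lacking inputs", {
  recs <- list(
    compound_record("full", 10, affinity = 1, affinity_unit = "uM",
                    affinity_kind = "KD", mw = 250, logp = 2),
    rec_kd("bare", 20, 1e-8))
  tab <- metric_table(recs, ctx = ctx298)
  expect_true(all(c("eta_bind", "lean") %in% tolower(unique(tab$metric)) |
                    c("ETA_BIND", "LEAN") %in% unique(tab$metric)))
  expect_equal(sum(tab$id == "full"), 5)   # all five metrics
  expect_equal(sum(tab$id == "bare"), 3)   # no MW, no logP
})
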