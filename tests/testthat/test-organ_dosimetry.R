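test_that("conversion-factor dose is tia x mass x C", {
  expect_equal(dose_fricke(organ_uptake("x", 0, 1), 0.064), 0)
  tumor <- organ_uptake("tumor", 19.8, 0.126)
  expect_equal(dose_fricke(tumor, 0.064), 19.8 * 0.126 * 0.064)
  expect_equal(dose_fricke(tumor, 0.064), 0.160, tolerance = 0.01)
  expect_error(organ_uptake("x", 1, NA), "mass")
  expect_error(organ_uptake("x", 1), "mass")
  expect_error(organ_uptake("x", -1, 1), "non-negative")
})

test_that("MIRD dose sums source contributions through the S kernel", {
  s1 <- s_value_table("a", "a", 0.5)
  expect_equal(dose_mird(c(a = 1), s1, "a"), 0.5)
  s2 <- s_value_table(c("a", "b", "a", "b"), c("a", "b", "b", "a"),
                      c(0.1, 0.2, 0.0, 0.0))
  expect_equal(dose_mird(c(a = 1, b = 2), s2, "a"), 0.1)
  expect_equal(dose_mird(c(a = 1, b = 2), s2, "b"), 0.4)
  # two sources (1, 2) MBq.h against S (0.1, 0.2) -> 0.5 Gy
  expect_error(s_value_table(c("a", "b"), c("t", "t"), c(0.1, 0.2)),
               "self-dose")
  s4 <- s_value_table(c("a", "b", "t"), c("t", "t", "t"), c(0.1, 0.2, 0))
  expect_equal(dose_mird(c(a = 1, b = 2), s4, "t"), 0.5)
  expect_error(dose_mird(numeric(0), s1, "a"), "at least one")
  expect_error(dose_mird(c(1, 2), s1, "a"), "named")
})

test_that("missing S pairs contribute zero with a warning", {
  s <- s_value_table("a", "a", 0.5)
  expect_warning(d <- dose_mird(c(a = 1, ghost = 3), s, "a"), "using 0")
  expect_equal(d, 0.5)
})

test_that("both formalisms are linear in administered activity", {
  s <- s_value_table(c("a", "b", "b"), c("a", "b", "a"), c(0.3, 0.1, 0.02))
  tias <- c(a = 1.2, b = 0.7)
  for (scale in c(2, 10)) {
    expect_equal(dose_mird(tias * scale, s, "a"),
                 scale * dose_mird(tias, s, "a"))
  }
  up <- organ_uptake("a", 1.2, 0.5)
  up2 <- organ_uptake("a", 1.2 * 3, 0.5)
  expect_equal(dose_fricke(up2, 0.064), 3 * dose_fricke(up, 0.064))
})

test_that("adding a source organ never decreases any target dose", {
  s <- s_value_table(c("a", "b", "a", "b"), c("a", "b", "b", "a"),
                     c(0.3, 0.1, 0.02, 0.05))
  base <- dose_mird(c(a = 1), s, "a")
  more <- dose_mird(c(a = 1, b = 2), s, "a")
  expect_gte(more, base)
})

test_that("a self-dose table with S = C makes the two formalisms coincide", {
  c_val <- 0.064
  uptakes <- mouse_uptake_fixture()
  organs <- vapply(uptakes, `[[`, character(1), "organ")
  s <- s_value_table(organs, organs, rep(c_val, length(organs)))
  rpt <- suppressWarnings(dose_report(uptakes, s, c_val, injected_MBq = 15))
  expect_equal(rpt$dose_fricke_Gy, rpt$dose_mird_Gy, tolerance = 1e-12)
  expect_equal(rpt$ratio_fricke_mird, rep(1, nrow(rpt)))
})

test_that("the dose report reproduces hand-computed values", {
  uptakes <- list(organ_uptake("tumor", 19.8, 0.126),
                  organ_uptake("liver", 0.48, 1.20))
  s <- s_value_table(c("tumor", "liver", "tumor", "liver"),
                     c("tumor", "liver", "liver", "tumor"),
                     c(0.5, 0.01, 0.001, 0.002))
  rpt <- suppressWarnings(dose_report(uptakes, s, 0.064, injected_MBq = 15))
  tia_tumor <- 19.8 * 0.126   # whole-organ MBq.h
  tia_liver <- 0.48 * 1.20
  expect_equal(rpt$dose_fricke_Gy,
               c(19.8 * 0.126 * 0.064, 0.48 * 1.20 * 0.064))
  expect_equal(rpt$dose_mird_Gy[rpt$organ == "tumor"],
               tia_tumor * 0.5 + tia_liver * 0.002)
  expect_equal(rpt$dose_mird_Gy[rpt$organ == "liver"],
               tia_liver * 0.01 + tia_tumor * 0.001)
  expect_equal(rpt$pct_ia_h_per_g, c(19.8, 0.48) / 15 * 100)
  # an empty S table yields a zero MIRD column (with warnings)
  s_empty <- s_value_table(character(0), character(0), numeric(0))
  rpt0 <- suppressWarnings(dose_report(uptakes, s_empty, 0.064, 15))
  expect_equal(rpt0$dose_mird_Gy, c(0, 0))
})

test_that("uptake and S-value CSV dialects round-trip", {
  upath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("organ,tia_MBq_h_per_g,mass_g", "tumor,19.8,0.126"), upath)
  ups <- read_uptake_csv(upath)
  expect_equal(ups[[1]]$mass_g, 0.126)
  spath <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target,S_Gy_per_MBq_h", "tumor,tumor,0.5"), spath)
  s <- read_svalue_csv(spath)
  expect_equal(s_value(s, "tumor", "tumor"), 0.5)
  # the shipped illustrative fixtures load cleanly
  fixture <- read_svalue_csv(system.file("extdata",
                                         "mouse_svalues_synthetic.csv",
                                         package = "frickedose"))
  expect_s3_class(fixture, "s_value_table")
  expect_length(mouse_uptake_fixture(), 6)
})
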