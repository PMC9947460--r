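# Sweep drivers: consistency, serialization, resumability.

test_that("sweep tables round-trip losslessly through CSV", {
  df <- data.frame(eps_H_fat = c(0, 0.03), proptosis_mm = c(0, 1.23456789),
                   dAL_um = c(0, -12.3456789), case = c("a", "b"),
                   failed = c(FALSE, FALSE))
  f <- tempfile(fileext = ".csv")
  write_sweep_csv(df, f)
  back <- read_sweep_csv(f)
  expect_equal(back$proptosis_mm, df$proptosis_mm, tolerance = 1e-12)
  expect_equal(back$case, df$case)
  unlink(f)
})

test_that("sweeps resume from cached cells", {
  out_dir <- tempfile("sweepcache")
  case <- preset_case("baseline")
  loads <- case$loads
  loads$eps_H_fat <- c(0, 0.02)
  ns <- asNamespace("orbitfem")
  t1 <- system.time(r1 <- ns$.cached_protocol(case, loads, "coarse", 2, out_dir))
  expect_false(r1$cached)
  t2 <- system.time(r2 <- ns$.cached_protocol(case, loads, "coarse", 2, out_dir))
  expect_true(r2$cached)
  expect_lt(t2[["elapsed"]], 0.2 * t1[["elapsed"]])
  expect_equal(r2$biometrics$proptosis_mm, r1$biometrics$proptosis_mm,
               tolerance = 1e-9)
  unlink(out_dir, recursive = TRUE)
})

test_that("a single-point grid reproduces the protocol output", {
  pr <- baseline_run()
  g <- run_icp_grid(icp_values = 13.6, eps_values = c(0, 0.035, 0.07),
                    density = "coarse")
  expect_false(any(g$failed))
  r <- g[abs(g$eps_H_fat - 0.07) < 1e-9, ]
  expect_equal(r$proptosis_mm,
               pr$biometrics$proptosis_mm[abs(pr$biometrics$eps_H_fat - 0.07) < 1e-9],
               tolerance = 0.01)
})
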