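test_that("no sign change means no crossings", {
  g <- wl_grid(200, 350, 0.5)
  s <- spectrum(g, exp(-(wavelengths(g) - 260)^2 / 500) + 0.5)
  d <- derivative(s, 2, 4)
  d$amplitude <- abs(d$amplitude) + 0.01
  expect_equal(nrow(find_zero_crossings(d)), 0L)
})

test_that("crossings of a sampled sine land on its known roots", {
  g <- wl_grid(200, 350, 0.1)
  s <- spectrum(g, sin(2 * pi * (wavelengths(g) - 200) / 50) + 1)
  d1 <- derivative(s, 1, 0.2)
  # cos roots: 212.5 + 25 k
  cr <- find_zero_crossings(d1)$wavelength_nm
  expected <- seq(212.5, 337.5, 25)
  expected <- expected[expected >= d1$grid$start_nm &
                         expected <= d1$grid$stop_nm]
  expect_length(cr, length(expected))
  expect_lt(max(abs(cr - expected)), 0.05)
})

test_that("exact on-grid zeros are reported once, at the grid point", {
  ds <- structure(list(grid = wl_grid(200, 212, 1),
                       amplitude = c(2, 1, 0, -1, -2, -1, 0, 1, 2, 1, 0, 0, -1),
                       order = 1L, delta_lambda_nm = 2, backend = "diff",
                       source_label = "toy"), class = "deriv_spectrum")
  cr <- find_zero_crossings(ds)
  expect_equal(cr$wavelength_nm, c(202, 206, 210))
  expect_equal(cr$direction, c("+-", "-+", "+-"))
})

test_that("zero crossings do not move under positive scaling of the source", {
  for (m in preset) {
    base <- noise_free(m, mean(m$valid_range))
    cr0 <- find_zero_crossings(derivative(base, 3, 28))$wavelength_nm
    for (alpha in c(0.3, 2, 11)) {
      scaled <- spectrum(base$grid, alpha * base$absorbance)
      cr <- find_zero_crossings(derivative(scaled, 3, 28))$wavelength_nm
      expect_equal(cr, cr0, tolerance = 1e-9)
    }
  }
})

screen_presets <- function(order = 3, dl = 28) {
  bs <- lapply(c(20, 40, 60, 80), function(c) noise_free(preset$bup_like, c))
  ns <- lapply(c(5, 10, 15, 20), function(c) noise_free(preset$nal_like, c))
  list(a = screen_candidates(bs, ns, order, dl),
       b = screen_candidates(ns, bs, order, dl))
}

test_that("screening on noise-free presets gives stable, selective candidates", {
  sc <- screen_presets()
  # crossings of c*f(lambda) do not move with c
  expect_true(all(sc$a$crossing_stability_nm < 1e-9))
  expect_true(all(sc$b$crossing_stability_nm < 1e-9))
  # the top candidate eliminates the interferent almost completely
  expect_lt(sc$a$residual_interference[1], 0.01)
  expect_lt(sc$b$residual_interference[1], 0.01)
  # sorted by descending sensitivity
  expect_true(!is.unsorted(rev(sc$a$sensitivity)))
})

test_that("screening demands three distinct concentrations per component", {
  bs <- lapply(c(20, 40), function(c) noise_free(preset$bup_like, c))
  ns <- lapply(c(5, 10, 15), function(c) noise_free(preset$nal_like, c))
  expect_error(screen_candidates(bs, ns, 3, 28), "3 distinct")
})

test_that("identical target and interferent yields unusable candidates", {
  bs <- lapply(c(20, 40, 60), function(c) noise_free(preset$bup_like, c))
  sc <- screen_candidates(bs, bs, 3, 28)
  # sensitivity at the analyte's own crossings is ~0, so nothing is usable
  expect_true(all(!sc$usable))
  expect_error(select_working_pair(sc, sc), "no feasible")
})

test_that("working-pair selection applies thresholds and tie-breaks", {
  cand <- function(wl, sens, resid, stab = 0) {
    structure(data.frame(wavelength_nm = wl, direction = "+-",
                         sensitivity = sens, crossing_stability_nm = stab,
                         residual_interference = resid, usable = TRUE),
              class = c("candidate_table", "data.frame"))
  }
  one <- cand(250, 1e-5, 0.001)
  sel <- select_working_pair(one, one)
  expect_equal(sel$a$wavelength_nm, 250)

  tie <- rbind(cand(255, 1e-5, 0.005), cand(251, 1e-5, 0.001))
  class(tie) <- c("candidate_table", "data.frame")
  sel <- select_working_pair(tie, one)
  expect_equal(sel$a$residual_interference, 0.001)

  bad <- cand(250, 1e-5, 0.5)
  expect_error(select_working_pair(bad, one), "no feasible candidate")
  expect_error(select_working_pair(one, cand(250, 1e-5, 0.1, stab = 5)),
               "analyte b")
})

test_that("measuring one analyte at the pair wavelength is immune to doubling
          the other (noise-free)", {
  sc <- screen_presets()
  sel <- select_working_pair(sc$a, sc$b)
  # calibrate each analyte noise-free at its working wavelength
  quant_at <- function(model, fixed, fixed_conc, wl, probe_conc,
                       partner_mult = 1) {
    concs <- c(20, 40, 60, 80) * (if (model$name == "nal_like") 0.25 else 1)
    amps <- vapply(concs, function(c) {
      s <- simulate_spectrum(list(model, fixed), c(c, fixed_conc),
                             noise = NULL)
      amplitude_at(derivative(s, 3, 28), wl)
    }, 0)
    cc <- fit_calibration(concs, amps, analyte = model$name)
    s <- simulate_spectrum(list(model, fixed),
                           c(probe_conc, fixed_conc * partner_mult),
                           noise = NULL)
    suppressWarnings(quantify(amplitude_at(derivative(s, 3, 28), wl),
                              cc))$concentration_ugml
  }
  base_a <- quant_at(preset$bup_like, preset$nal_like, 12.5,
                     sel$a$wavelength_nm, 50)
  dbl_a <- quant_at(preset$bup_like, preset$nal_like, 12.5,
                    sel$a$wavelength_nm, 50, partner_mult = 2)
  expect_lt(abs(dbl_a - base_a) / base_a * 100, 1)
  base_b <- quant_at(preset$nal_like, preset$bup_like, 50,
                     sel$b$wavelength_nm, 12.5)
  dbl_b <- quant_at(preset$nal_like, preset$bup_like, 50,
                    sel$b$wavelength_nm, 12.5, partner_mult = 2)
  expect_lt(abs(dbl_b - base_b) / base_b * 100, 1)
})
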