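test_that("trace extraction is the ROI mean, linear in its masks", {
  spec <- bleach_spec(60, 800, offset = 40, n_frames = 120, noise_sd = 5,
                      seed = 6)
  stack <- simulate_bleach_stack(spec, ny = 12, nx = 12)

  one <- matrix(FALSE, 12, 12); one[4, 7] <- TRUE
  tr1 <- extract_trace(stack, one)
  expect_equal(tr1$intensity, stack[, 4, 7])

  whole <- matrix(TRUE, 12, 12)
  trw <- extract_trace(stack, whole)
  ideal <- attr(stack, "ideal")
  expect_lt(max(abs(trw$intensity - ideal)), 5 / sqrt(144) * 5)

  septum <- matrix(FALSE, 12, 12); septum[5:8, ] <- TRUE
  periph <- !septum
  trs <- extract_trace(stack, septum, roi_label = "septum")
  trp <- extract_trace(stack, periph, roi_label = "periphery")
  recomposed <- (sum(septum) * trs$intensity + sum(periph) * trp$intensity) /
    length(septum)
  expect_equal(recomposed, trw$intensity, tolerance = 1e-12)

  expect_error(extract_trace(stack, matrix(FALSE, 12, 12)), "empty")
  expect_error(extract_trace(stack, matrix(TRUE, 5, 5)), "shape")
})

test_that("decay fits are exact on noise-free traces across the parameter range", {
  grid <- expand.grid(A = c(200, 1000), tau = c(5, 100, 600), B = c(0, 50))
  for (i in seq_len(nrow(grid))) {
    tr <- simulate_bleach_trace(bleach_spec(grid$tau[i], grid$A[i],
                                            offset = grid$B[i]))
    fit <- fit_decay(tr)
    expect_true(fit$converged)
    expect_lt(abs(fit$tau_frames - grid$tau[i]) / grid$tau[i], 1e-6)
    expect_lt(abs(fit$amplitude - grid$A[i]) / grid$A[i], 1e-6)
  }
})

test_that("degenerate traces come back flagged non-converged, never silently", {
  flat <- fit_decay(rep(100, 50))
  expect_false(flat$converged)
  expect_match(flat$diagnostic, "constant")
  rising <- fit_decay(seq(10, 500, length.out = 50))
  expect_false(rising$converged)
  expect_match(rising$diagnostic, "not decreasing")
})

test_that("FRET efficiency follows E = 1 - tau/tau' including negative values", {
  mkfit <- function(tau) fit_decay(simulate_bleach_trace(
    bleach_spec(tau, 1000, offset = 50)))
  f100 <- mkfit(100)
  expect_equal(fret_efficiency(f100, mkfit(100), n_boot = 0)$efficiency, 0,
               tolerance = 1e-9)
  expect_equal(fret_efficiency(f100, mkfit(125), n_boot = 0)$efficiency, 0.2,
               tolerance = 1e-9)
  neg <- fret_efficiency(f100, mkfit(90), n_boot = 0)
  expect_equal(neg$efficiency, 1 - 100 / 90, tolerance = 1e-9)
  expect_lt(neg$efficiency, 0)

  bad <- fit_decay(rep(5, 50))
  expect_error(fret_efficiency(list(bad), f100, n_boot = 0), "no converged")
})

test_that("E is invariant to rescaling the intensities of either arm", {
  tr_d <- simulate_bleach_trace(bleach_spec(100, 1000, offset = 50,
                                            noise_sd = 10, seed = 41))
  tr_a <- simulate_bleach_trace(bleach_spec(130, 1000, offset = 50,
                                            noise_sd = 10, seed = 42))
  scale_trace <- function(tr, c) bleach_trace(tr$intensity * c)
  e1 <- fret_efficiency(fit_decay(tr_d), fit_decay(tr_a),
                        n_boot = 0)$efficiency
  e2 <- fret_efficiency(fit_decay(scale_trace(tr_d, 7.3)),
                        fit_decay(scale_trace(tr_a, 0.2)),
                        n_boot = 0)$efficiency
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("subcellular analysis reports per-compartment E, absences and arm errors", {
  mk <- function(tau, ds, roi, cond, seed) simulate_bleach_trace(
    bleach_spec(tau, 1000, offset = 50, noise_sd = 20, seed = seed),
    roi_label = roi, division_state = ds, condition = cond)
  traces <- list()
  s <- 0
  for (j in 1:8) {
    s <- s + 4
    # dividing/periphery carries a true E = 0.15; dividing/septum is null
    traces <- c(traces, list(
      mk(100, "dividing", "periphery", "donor_only", s),
      mk(100 / (1 - 0.15), "dividing", "periphery", "donor_plus_acceptor", s + 1),
      mk(100, "dividing", "septum", "donor_only", s + 2),
      mk(100, "dividing", "septum", "donor_plus_acceptor", s + 3)))
  }
  # non-dividing whole-cell arm lacking its donor-only counterpart
  traces <- c(traces, list(mk(110, "non_dividing", "whole_cell",
                              "donor_plus_acceptor", 999)))
  tab <- subcellular_fret(traces, n_boot = 100, seed = 5)
  per <- tab[tab$division_state == "dividing" & tab$roi_label == "periphery", ]
  sep <- tab[tab$division_state == "dividing" & tab$roi_label == "septum", ]
  ndc <- tab[tab$division_state == "non_dividing", ]
  expect_identical(per$status, "ok")
  expect_lt(abs(per$efficiency_pct - 15), 3)
  expect_lt(abs(sep$efficiency_pct), 3)
  expect_match(ndc$status, "donor-only")
  expect_true(is.na(ndc$efficiency_pct))
})
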