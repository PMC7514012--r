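# A hand-built trajectory object for metric tests: values on a uniform
# grid, no integration involved.
fake_traj <- function(times, values, compartment = "I_alpha", mode = "none") {
  states <- matrix(values, ncol = length(compartment),
                   dimnames = list(NULL, compartment))
  structure(list(times = times, states = states,
                 meta = list(mode = mode, horizon = max(times),
                             dt = diff(times)[1])),
            class = "ibd_trajectory")
}

test_that("healthy interval is centered on health with half-gap half-width", {
  iv <- healthy_interval(4, 2)
  expect_equal(c(iv$lower, iv$upper), c(1, 3))
  iv <- healthy_interval(1, 3)
  expect_equal(c(iv$lower, iv$upper), c(2, 4))
  iv <- healthy_interval(2, 2)
  expect_equal(c(iv$lower, iv$upper), c(2, 2))
  expect_error(healthy_interval(-1, 2), ">= 0")
})

test_that("interval width is invariant under which side the patient is on", {
  for (gap in c(0.5, 1, 2)) {
    lo <- healthy_interval(3 - gap, 3)
    hi <- healthy_interval(3 + gap, 3)
    expect_equal(hi$upper - hi$lower, lo$upper - lo$lower)
    expect_equal(lo$lower + lo$upper, hi$lower + hi$upper)  # same center
  }
})

test_that("occupancy is 100% inside, 0% outside, and handles zero width", {
  tm <- seq(0, 50, by = 0.01)
  iv <- healthy_interval(4, 2, compartment = "I_alpha")
  inside <- fake_traj(tm, rep(2.5, length(tm)))
  outside <- fake_traj(tm, rep(3.5, length(tm)))
  expect_equal(occupancy(inside, iv)$occupancy, 100)
  expect_equal(occupancy(outside, iv)$occupancy, 0)
  # zero-width interval: a compartment already at the healthy level is in
  # band (the statistic measures departure from health)
  iv0 <- healthy_interval(2, 2, compartment = "I_alpha")
  at_health <- fake_traj(tm, rep(2, length(tm)))
  expect_equal(occupancy(at_health, iv0)$occupancy, 100)
  expect_equal(occupancy(outside, iv0)$occupancy, 0)
})

test_that("square-wave occupancy matches the exhaustive grid-count oracle", {
  tm <- seq(0, 50, by = 0.01)
  iv <- healthy_interval(4, 2, compartment = "I_alpha")  # band [1, 3]
  # in band on even weeks, out on odd weeks
  vals <- ifelse(floor(tm) %% 2 == 0, 2, 5)
  traj <- fake_traj(tm, vals)
  got <- occupancy(traj, iv, window = c(14, 50))$occupancy
  sel <- tm >= 14 & tm <= 50
  oracle <- 100 * sum(vals[sel] >= 1 & vals[sel] <= 3) / sum(sel)
  expect_equal(got, oracle)
  # one grid step of slack around the construction's nominal 50%
  expect_lt(abs(got - 50), 100 * 0.01 / (50 - 14) + 1e-9)
})

test_that("occupancy rejects windows outside the trajectory span", {
  tm <- seq(0, 10, by = 0.1)
  traj <- fake_traj(tm, rep(1, length(tm)))
  iv <- healthy_interval(2, 1, compartment = "I_alpha")
  expect_error(occupancy(traj, iv, window = c(5, 20)), "outside")
  expect_error(occupancy(traj, iv, window = c(7, 7)), "t0 < t1")
})

test_that("ratio change of health against itself is identically zero", {
  h <- cached_healthy()
  tr <- simulate_therapy(h$model, mode = "none", init = h$ss, horizon = 50,
                         dt = 0.1)
  rep <- ratio_report(tr, h$ss)
  expect_equal(rep$pct_change_min, rep(0, nrow(rep)), tolerance = 1e-5)
  expect_equal(rep$pct_change_max, rep(0, nrow(rep)), tolerance = 1e-5)
  expect_true(all(rep$flagged_gaps == 0))
  expect_true(all(rep$ratio_min <= rep$ratio_max))
})

test_that("doubling the pro compartment doubles the ratio (+100%)", {
  tm <- seq(0, 50, by = 0.05)
  healthy_ss <- c(I_alpha = 2, I_10 = 1)
  traj <- fake_traj(tm, cbind(rep(4, length(tm)), rep(1, length(tm))),
                    compartment = c("I_alpha", "I_10"))
  rep <- ratio_report(traj, healthy_ss, pairs = list(c("I_alpha", "I_10")))
  expect_equal(rep$pct_change_min, 100)
  expect_equal(rep$pct_change_max, 100)
})

test_that("ratio min/max match a brute-force scan of the grid", {
  tm <- seq(0, 50, by = 0.01)
  pro <- 2 + sin(tm / 3) + 0.5 * (tm > 25)
  anti <- 1 + 0.3 * cos(tm / 5)
  traj <- fake_traj(tm, cbind(pro, anti), compartment = c("I_alpha", "I_10"))
  rep <- ratio_report(traj, c(I_alpha = 2, I_10 = 1),
                      pairs = list(c("I_alpha", "I_10")), window = c(14, 50))
  sel <- tm >= 14 & tm <= 50
  r <- pro[sel] / anti[sel]
  expect_equal(rep$ratio_min, min(r))
  expect_equal(rep$ratio_max, max(r))
})

test_that("a vanishing denominator is flagged, not turned into infinity", {
  tm <- seq(0, 50, by = 0.1)
  anti <- ifelse(tm < 25, 1, 0)
  traj <- fake_traj(tm, cbind(rep(2, length(tm)), anti),
                    compartment = c("I_alpha", "I_10"))
  rep <- ratio_report(traj, c(I_alpha = 2, I_10 = 1),
                      pairs = list(c("I_alpha", "I_10")), window = c(0, 50))
  expect_gt(rep$flagged_gaps, 0)
  expect_true(is.finite(rep$ratio_max))
})

test_that("fold changes are unity at health and track single perturbations", {
  h <- cached_healthy()
  fc <- fold_change(h$ss, h$ss)
  expect_equal(fc$fold_change, rep(1, nrow(fc)))
  tripled <- h$ss
  tripled[["Th1"]] <- 3 * tripled[["Th1"]]
  fc2 <- fold_change(tripled, h$ss)
  expect_equal(fc2$fold_change[fc2$compartment == "Th1"], 3)
  expect_equal(fc2$fold_change[fc2$compartment != "Th1"],
               rep(1, nrow(fc2) - 1))
  zero <- h$ss; zero[["Th1"]] <- 0
  expect_error(fold_change(h$ss, zero), "> 0")
})
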