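test_that("TNF-alpha rate law reproduces hand-evaluated cases", {
  # pure decay
  s <- c(M1 = 0, Th1 = 0, I_alpha = 2, D_alpha = 0)
  p <- zero_params(delta_alpha = 0.5)
  expect_equal(unname(rhs_tnf_alpha(s, p, vM = 0)[1]), -1.0)

  # symmetric neutralization loss: the sigma*I*D term drains both sides
  s <- c(M1 = 0, Th1 = 0, I_alpha = 1, D_alpha = 1)
  p <- zero_params(sigma_D_alpha = 0.3)
  d <- rhs_tnf_alpha(s, p, vM = 0)
  expect_equal(unname(d), c(-0.3, -0.3))

  # full production/decay balance
  s <- c(M1 = 1, Th1 = 2, I_alpha = 4, D_alpha = 0)
  p <- zero_params(v_alpha_M = 2, v_alpha_1 = 3, delta_alpha = 1)
  expect_equal(unname(rhs_tnf_alpha(s, p, vM = 0)[1]), 2 + 6 - 4)
})

test_that("IL-12 rate law has the half-saturation suppression structure", {
  p <- zero_params(v_12M = 4, zeta_10 = 2)
  base <- c(M1 = 1, I_12 = 0, I_10 = 0, D_12 = 0)

  # I_10 = zeta_10 halves production; I_10 = 0 leaves it untouched
  s_half <- base; s_half[["I_10"]] <- 2
  expect_equal(unname(rhs_il12(s_half, p, vM = 0)[1]), 4 / 2)
  expect_equal(unname(rhs_il12(base, p, vM = 0)[1]), 4)

  # hand evaluation with decay
  p2 <- zero_params(v_12M = 4, zeta_10 = 1, delta_12 = 1)
  s2 <- c(M1 = 1, I_12 = 1, I_10 = 3, D_12 = 0)
  expect_equal(unname(rhs_il12(s2, p2, vM = 0)[1]), 4 / 4 - 1)

  # suppression is monotone: dI_12/dt non-increasing in I_10
  d_prev <- Inf
  for (i10 in seq(0, 5, by = 0.25)) {
    s <- base; s[["I_10"]] <- i10
    d <- unname(rhs_il12(s, p, vM = 0)[1])
    expect_lte(d, d_prev + 1e-12)
    d_prev <- d
  }

  expect_error(rhs_il12(base, zero_params(zeta_10 = 0)), "zeta_10")
})

test_that("IL-10 rate law follows the adopted Treg-modulation reading", {
  # decay only
  s <- c(M2 = 0, Treg = 0, I_10 = 5, I_gamma = 0, I_2 = 0, D_10 = 0)
  p <- zero_params(delta_10 = 0.2)
  expect_equal(unname(rhs_il10(s, p, vM = 0)[1]), -1.0)

  # IFN-gamma = 0 removes the modulation: Treg term reduces to v_10r * Treg
  p <- zero_params(v_10r = 2, n_2r = 7, zeta_2 = 1)
  s <- c(M2 = 0, Treg = 3, I_10 = 0, I_gamma = 0, I_2 = 0.4, D_10 = 0)
  expect_equal(unname(rhs_il10(s, p, vM = 0)[1]), 2 * 3)

  # drug source/clearance, hand evaluation
  p <- zero_params(delta_D_10 = 0.5, v_D10 = 0.4)
  s <- c(M2 = 0, Treg = 0, I_10 = 0, I_gamma = 0, I_2 = 0, D_10 = 2)
  d <- rhs_il10(s, p, vM = 0)
  expect_equal(unname(d[2]), -1.0)
  expect_equal(unname(d[1]), 0.8)

  # IFN-gamma aids, IL-2 interferes
  p <- zero_params(v_10r = 1, n_2r = 1, zeta_2 = 1)
  mk <- function(ig, i2) c(M2 = 0, Treg = 1, I_10 = 0, I_gamma = ig,
                           I_2 = i2, D_10 = 0)
  d0 <- unname(rhs_il10(mk(0, 0), p)[1])
  expect_gt(unname(rhs_il10(mk(2, 0), p)[1]), d0)
  expect_lt(unname(rhs_il10(mk(2, 5), p)[1]), unname(rhs_il10(mk(2, 0), p)[1]))

  expect_error(rhs_il10(mk(0, 0), zero_params(zeta_2 = 0)), "zeta_2")
})

test_that("rate laws reject negative states, rates and infusion", {
  s <- c(M1 = 0, Th1 = 0, I_alpha = -1, D_alpha = 0)
  expect_error(rhs_tnf_alpha(s, zero_params()), "non-negative")
  s2 <- c(M1 = 0, Th1 = 0, I_alpha = 1, D_alpha = 0)
  p <- zero_params(); p[["delta_alpha"]] <- -1
  expect_error(rhs_tnf_alpha(s2, p), "non-negative")
  expect_error(rhs_tnf_alpha(s2, zero_params(), vM = -2), "non-negative")
})

test_that("full derivative assembles registry terms: a - b*x per toy species", {
  m <- toy_model(species = c("X", "Y"),
                 params = c(aX = 3, bX = 0.5, aY = 1, bY = 2),
                 terms = list(
                   list(target = "X", rate = "aX"),
                   list(target = "X", type = "decay", rate = "bX"),
                   list(target = "Y", rate = "aY"),
                   list(target = "Y", type = "decay", rate = "bY")))
  s <- immune_state(m, c(X = 4, Y = 1))
  d <- rhs_full(s, m, mode = "none")
  expect_equal(d[["X"]], 3 - 0.5 * 4)
  expect_equal(d[["Y"]], 1 - 2 * 1)
  # all remaining (built-in) compartments have zero rates here
  expect_equal(unname(d[setdiff(names(d), c("X", "Y"))]),
               rep(0, length(d) - 2))
})

test_that("zero state with no constant production is a fixed point", {
  m <- toy_model(species = "X", params = c(bX = 1),
                 terms = list(list(target = "X", type = "decay",
                                   rate = "bX")))
  d <- rhs_full(immune_state(m), m, mode = "none")
  expect_equal(unname(d), rep(0, length(d)))
})

test_that("drug terms vanish in the drug-free limit", {
  h <- cached_healthy()
  s <- h$ss  # drug compartments 0
  d_none <- rhs_full(s, h$model, mode = "none")
  for (md in c("anti_tnf", "anti_il12", "il10")) {
    d <- rhs_full(s, h$model, mode = md, vM = 0)
    expect_equal(d, d_none, tolerance = 1e-14)
  }
})

test_that("infusion routes to exactly the compartment of the active mode", {
  h <- cached_healthy()
  s <- h$ss
  drug_of <- c(anti_tnf = "D_alpha", anti_il12 = "D_12", il10 = "D_10")
  for (md in names(drug_of)) {
    d0 <- rhs_full(s, h$model, mode = md, vM = 0)
    d1 <- rhs_full(s, h$model, mode = md, vM = 3)
    diff <- d1 - d0
    expect_equal(unname(diff[drug_of[[md]]]), 3)
    expect_equal(unname(diff[setdiff(names(diff), drug_of[[md]])]),
                 rep(0, length(diff) - 1))
  }
})
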