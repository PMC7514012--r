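#' Simulate the immune network under a therapy
#'
#' Integrates the full network over the treatment horizon with the chosen
#' therapy's infusion forcing. The piecewise-constant forcing is handled
#' exactly: integration is restarted at every dose-window boundary, and
#' within a segment the infusion rate is constant. Output is reported on a
#' uniform grid (default step 0.01 week), the grid later used by the
#' occupancy and ratio statistics.
#'
#' The run is deterministic given the model, schedule, initial state and
#' solver tolerances. If any compartment falls below `-10 * atol` the run
#' stops with a diagnostic rather than silently clipping: with non-negative
#' parameters and initial conditions the rate laws cannot produce negative
#' states, so a violation indicates an integration failure.
#'
#' @param model an [ibd_model()].
#' @param mode therapy mode: `"none"`, `"anti_tnf"`, `"anti_il12"` or
#'   `"il10"`; selects the drug compartment receiving the infusion.
#' @param schedule a [dose_schedule()]; defaults to
#'   [infliximab_schedule()] over the horizon with the model's nominal dose
#'   (ignored for mode `"none"`).
#' @param init named initial state (see [immune_state()]); non-negative.
#' @param horizon treatment horizon (weeks, > 0).
#' @param dt uniform output step (weeks).
#' @param rtol,atol relative/absolute solver tolerances (lsoda).
#' @param label free-text label stored in the trajectory metadata.
#' @return An object of class `ibd_trajectory`: list with `times` (vector),
#'   `states` (time x compartment matrix) and `meta`.
#' @seealso [steady_state()], [occupancy()], [ratio_report()]
#' @export
#' @examples
#' m <- healthy_model()
#' ss <- steady_state(m)
#' tr <- simulate_therapy(m, mode = "none", init = ss$state, horizon = 2)
#' tr
simulate_therapy <- function(model, mode = c("none", "anti_tnf", "anti_il12",
                                             "il10"),
                             schedule = NULL, init, horizon = 50, dt = 0.01,
                             rtol = 1e-8, atol = 1e-10, label = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ibd_model"))
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be > 0", call. = FALSE)
  x0 <- init[model$species]
  if (any(is.na(x0)))
    stop("init is missing compartments of the model registry", call. = FALSE)
  if (any(x0 < 0)) stop("init must be non-negative", call. = FALSE)
  names(x0) <- model$species

  if (mode != "none" && is.null(schedule)) {
    dose <- model$dosing$dose_total
    if (is.list(dose) || length(dose) > 1) dose <- dose[[mode]]
    schedule <- infliximab_schedule(horizon, dose_total = dose,
                                    duration = model$dosing$infusion_duration)
  }

  grid <- seq(0, horizon, by = dt)
  if (abs(grid[length(grid)] - horizon) > 1e-12) grid <- c(grid, horizon)

  breaks <- if (mode == "none" || is.null(schedule)) numeric(0) else
    schedule_breakpoints(schedule, horizon)
  seg_bounds <- sort(unique(c(0, breaks, horizon)))

  deriv <- function(t, y, parms) {
    vM <- parms$vM
    list(unname(rhs_full(stats::setNames(y, model$species), model,
                         mode = mode, vM = vM)))
  }

  states <- matrix(NA_real_, nrow = length(grid), ncol = length(model$species),
                   dimnames = list(NULL, model$species))
  states[1, ] <- x0
  y <- x0
  for (k in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[k]; b <- seg_bounds[k + 1]
    vM <- if (mode == "none" || is.null(schedule)) 0 else
      infusion_rate((a + b) / 2, schedule)
    inner <- grid[grid > a + 1e-12 & grid < b - 1e-12]
    times <- unique(c(a, inner, b))
    sol <- deSolve::ode(y = unname(y), times = times, func = deriv,
                        parms = list(vM = vM), method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integrator failed in segment [%g, %g]; last time %g",
                   a, b, max(sol[, 1])), call. = FALSE)
    vals <- sol[, -1, drop = FALSE]
    keep <- match(round(inner, 10), round(times, 10))
    idx <- match(round(inner, 10), round(grid, 10))
    if (length(idx)) states[idx, ] <- vals[keep, , drop = FALSE]
    y <- stats::setNames(vals[nrow(vals), ], model$species)
    bi <- match(round(b, 10), round(grid, 10))
    if (!is.na(bi)) states[bi, ] <- y
  }

  if (min(states) < -10 * atol)
    stop(sprintf(
      "negative concentration detected (min %.3e < -10*atol); integration unreliable",
      min(states)), call. = FALSE)
  states[states < 0] <- 0   # damp roundoff-scale undershoot (within -10*atol)

  structure(list(
    times = grid,
    states = states,
    meta = list(mode = mode, label = label, horizon = horizon, dt = dt,
                rtol = rtol, atol = atol,
                schedule = if (mode == "none") NULL else schedule,
                model = model$name,
                param_hash = config_hash(model$params))),
    class = "ibd_trajectory")
}

#' Drug-free steady state
#'
#' Finds the steady state of the drug-free network: a non-negative state at
#' which every derivative vanishes (max-norm of the right-hand side below
#' `tol`). The search integrates the system for `burn_in` weeks from `init`
#' to reach the attractor's neighborhood, then polishes with a damped Newton
#' iteration on the non-drug species (drug compartments are held at 0, an
#' invariant set of the drug-free dynamics). Only the steady state reachable
#' from `init` is reported; no search for alternative equilibria is made.
#'
#' @param model an [ibd_model()].
#' @param init optional named initial state; defaults to 0.5 for all
#'   non-drug compartments.
#' @param burn_in burn-in integration length (weeks).
#' @param tol convergence tolerance on the max-norm of the derivative.
#' @param max_iter maximum Newton iterations.
#' @return list with `state` (named steady state, drugs at 0), `residual`
#'   (max-norm of the rhs) and `iterations`.
#' @export
steady_state <- function(model, init = NULL, burn_in = 500, tol = 1e-10,
                         max_iter = 50) {
  stopifnot(inherits(model, "ibd_model"))
  if (is.null(init)) init <- immune_state(model, default = 0.5)
  base <- setdiff(model$species, c("D_alpha", "D_12", "D_10"))

  if (burn_in > 0) {
    tr <- simulate_therapy(model, mode = "none", init = init,
                           horizon = burn_in, dt = burn_in / 4,
                           rtol = 1e-8, atol = 1e-10)
    x <- tr$states[nrow(tr$states), base]
  } else {
    x <- init[base]
  }

  f <- function(xb) {
    s <- immune_state(model)
    s[base] <- pmax(xb, 0)
    rhs_full(s, model, mode = "none")[base]
  }
  fx <- f(x)
  it <- 0
  while (max(abs(fx)) > tol && it < max_iter) {
    it <- it + 1
    J <- matrix(0, length(base), length(base))
    for (j in seq_along(base)) {
      h <- 1e-7 * max(abs(x[j]), 1e-4)
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- max(x[j] - h, 0)
      J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step))
      stop("singular Jacobian in steady-state search; try another init",
           call. = FALSE)
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn <- f(xn)
      if (max(abs(fn)) < max(abs(fx)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn; fx <- fn
  }
  if (max(abs(fx)) > tol)
    stop(sprintf(
      "steady-state search did not converge (residual %.3e after %d iterations); try a different init or longer burn_in",
      max(abs(fx)), it), call. = FALSE)
  s <- immune_state(model)
  s[base] <- x
  list(state = s, residual = max(abs(fx)), iterations = it)
}

#' @export
print.ibd_trajectory <- function(x, ...) {
  cat("IBD therapy trajectory (mode:", x$meta$mode, ")\n")
  cat(sprintf("  %d time points over %g weeks (dt = %g)\n",
              length(x$times), x$meta$horizon, x$meta$dt))
  cat("  compartments:", paste(colnames(x$states), collapse = ", "), "\n")
  fin <- x$states[nrow(x$states), ]
  cat("  final state:\n")
  print(round(fin, 4))
  invisible(x)
}

#' @export
as.data.frame.ibd_trajectory <- function(x, ..., long = FALSE) {
  wide <- data.frame(time = x$times, x$states, check.names = FALSE)
  if (!long) return(wide)
  data.frame(
    time = rep(x$times, times = ncol(x$states)),
    compartment = rep(colnames(x$states), each = length(x$times)),
    value = as.vector(x$states))
}

#' Plot a therapy trajectory
#'
#' Draws selected compartments against time; when healthy and patient
#' reference levels are supplied, the healthy band (patient/healthy levels
#' and the interval around the healthy level) is overlaid the way
#' treatment-quality figures in this literature are drawn.
#'
#' @param x an `ibd_trajectory`.
#' @param compartments compartments to draw (default: the three drug-coupled
#'   cytokines and Th1).
#' @param healthy,patient optional named reference states for the interval
#'   overlay.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ibd_trajectory <- function(x, compartments = c("I_alpha", "I_12",
                                                    "I_2", "Th1"),
                                healthy = NULL, patient = NULL, ...) {
  compartments <- intersect(compartments, colnames(x$states))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(compartments)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (cp in compartments) {
    graphics::plot(x$times, x$states[, cp], type = "l", xlab = "weeks",
                   ylab = expression(concentration ~ (g/cm^3)), main = cp, ...)
    if (!is.null(healthy) && !is.null(patient) && cp %in% names(healthy)) {
      iv <- healthy_interval(patient[[cp]], healthy[[cp]], compartment = cp)
      graphics::abline(h = healthy[[cp]], col = "darkgreen", lty = 3)
      graphics::abline(h = patient[[cp]], col = "red", lty = 3)
      graphics::abline(h = c(iv$lower, iv$upper), col = "orange", lty = 2)
    }
  }
  invisible(x)
}
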