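#' Healthy-individual interval
#'
#' The treatment-quality band for a compartment: centered on the healthy
#' steady-state level, with half-width equal to half the absolute
#' patient-healthy gap,
#' \deqn{[h - |p - h|/2, \; h + |p - h|/2].}
#' A patient already at the healthy level yields a zero-width interval;
#' membership testing then uses a small absolute tolerance
#' (`1e-9 * healthy`) so such a compartment scores 100% occupancy rather
#' than 0% — the statistic measures departure from health.
#'
#' @param patient_level patient (pre-treatment steady-state) concentration.
#' @param healthy_level healthy steady-state concentration.
#' @param compartment optional compartment name carried in the result.
#' @return An object of class `healthy_interval`: list with `compartment`,
#'   `healthy`, `patient`, `lower`, `upper`.
#' @export
#' @examples
#' healthy_interval(4, 2)  # [1, 3]
#' healthy_interval(1, 3)  # [2, 4]
healthy_interval <- function(patient_level, healthy_level,
                             compartment = NA_character_) {
  if (patient_level < 0 || healthy_level < 0)
    stop("levels must be >= 0", call. = FALSE)
  half <- abs(patient_level - healthy_level) / 2
  structure(list(compartment = compartment,
                 healthy = healthy_level, patient = patient_level,
                 lower = healthy_level - half, upper = healthy_level + half),
            class = "healthy_interval")
}

#' @export
print.healthy_interval <- function(x, ...) {
  cat(sprintf("Healthy interval%s: [%.6g, %.6g] (healthy %.6g, patient %.6g)\n",
              if (is.na(x$compartment)) "" else paste0(" for ", x$compartment),
              x$lower, x$upper, x$healthy, x$patient))
  invisible(x)
}

#' Interval occupancy over the analysis window
#'
#' The percentage of the analysis window a compartment spends inside its
#' healthy interval: 100% if the trajectory stays in band at all times, 0%
#' if it never enters. Membership is tested on the trajectory's uniform
#' output grid (closed interval, with absolute tolerance
#' `1e-9 * healthy_level` so zero-width intervals behave sensibly), and the
#' occupancy is the in-band fraction of grid points in the window. The
#' default window of 14-50 weeks discards the initial transient driven by
#' the starting condition.
#'
#' @param traj an `ibd_trajectory`.
#' @param intervals a list of [healthy_interval()]s, or a single one;
#'   compartments not covered are skipped.
#' @param window analysis window `c(t0, t1)` in weeks; must lie within the
#'   trajectory's time span.
#' @return An object of class `occupancy_report`: data frame with columns
#'   `compartment`, `occupancy` (percent), `lower`, `upper`, plus attributes
#'   `window` and `mode`.
#' @export
occupancy <- function(traj, intervals, window = c(14, 50)) {
  stopifnot(inherits(traj, "ibd_trajectory"))
  if (inherits(intervals, "healthy_interval")) intervals <- list(intervals)
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(t0, t1) with t0 < t1", call. = FALSE)
  if (window[1] < min(traj$times) - 1e-9 ||
      window[2] > max(traj$times) + 1e-9)
    stop("analysis window lies outside the trajectory time span",
         call. = FALSE)
  sel <- traj$times >= window[1] - 1e-12 & traj$times <= window[2] + 1e-12
  rows <- lapply(intervals, function(iv) {
    cp <- iv$compartment
    if (is.na(cp) || !cp %in% colnames(traj$states))
      stop("interval has no matching trajectory compartment: ", cp,
           call. = FALSE)
    v <- traj$states[sel, cp]
    tol <- 1e-9 * iv$healthy
    inside <- v >= iv$lower - tol & v <= iv$upper + tol
    data.frame(compartment = cp, occupancy = 100 * mean(inside),
               lower = iv$lower, upper = iv$upper)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, window = window, mode = traj$meta$mode,
            class = c("occupancy_report", "data.frame"))
}

#' @export
print.occupancy_report <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Occupancy of the healthy interval, weeks %g-%g (mode: %s)\n",
              w[1], w[2], attr(x, "mode")))
  print.data.frame(cbind(x[, "compartment", drop = FALSE],
                         occupancy = sprintf("%.2f%%", x$occupancy),
                         round(x[, c("lower", "upper")], 4)),
                   row.names = FALSE)
  invisible(x)
}

#' Default pro/anti-inflammatory ratio pairs
#'
#' The ratios discussed in this literature: each antibody target cytokine
#' (TNF-alpha, IL-12) against each anti-inflammatory cytokine (IL-10,
#' IL-4), plus the Th1/Th2 and Th1/Treg cell-balance ratios.
#'
#' @return list of length-2 character vectors `c(pro, anti)`.
#' @export
default_ratio_pairs <- function() {
  list(c("I_alpha", "I_10"), c("I_alpha", "I_4"),
       c("I_12", "I_10"), c("I_12", "I_4"),
       c("Th1", "Th2"), c("Th1", "Treg"))
}

#' Pro- to anti-inflammatory ratio report
#'
#' For each configured (pro, anti) compartment pair, forms the ratio time
#' series `pro(t)/anti(t)` over the analysis window and summarizes its
#' minimum and maximum (min and max are reported because the immune system
#' oscillates naturally over the dosing cycle), together with the percent
#' change relative to the healthy steady-state ratio,
#' `100 * (ratio - healthy_ratio) / healthy_ratio`. Grid points where the
#' denominator is not strictly positive are excluded and counted as a
#' flagged gap rather than producing infinities.
#'
#' @param traj an `ibd_trajectory`.
#' @param healthy_ss named healthy steady-state vector (strictly positive
#'   for all referenced compartments).
#' @param pairs list of `c(pro, anti)` pairs; default
#'   [default_ratio_pairs()].
#' @param window analysis window in weeks.
#' @return An object of class `ratio_report`: data frame with columns
#'   `pro`, `anti`, `ratio_min`, `ratio_max`, `healthy_ratio`,
#'   `pct_change_min`, `pct_change_max`, `flagged_gaps` (count of excluded
#'   grid points).
#' @export
ratio_report <- function(traj, healthy_ss, pairs = default_ratio_pairs(),
                         window = c(14, 50)) {
  stopifnot(inherits(traj, "ibd_trajectory"))
  sel <- traj$times >= window[1] - 1e-12 & traj$times <= window[2] + 1e-12
  if (!any(sel)) stop("window outside trajectory span", call. = FALSE)
  rows <- lapply(pairs, function(pr) {
    pro <- pr[1]; anti <- pr[2]
    for (cp in c(pro, anti))
      if (!cp %in% colnames(traj$states))
        stop("unknown compartment in ratio pair: ", cp, call. = FALSE)
    h_ratio <- healthy_ss[[pro]] / healthy_ss[[anti]]
    if (!is.finite(h_ratio) || healthy_ss[[anti]] <= 0)
      stop("healthy level of '", anti, "' must be > 0", call. = FALSE)
    num <- traj$states[sel, pro]
    den <- traj$states[sel, anti]
    ok <- den > 0
    r <- num[ok] / den[ok]
    if (!length(r))
      return(data.frame(pro = pro, anti = anti, ratio_min = NA_real_,
                        ratio_max = NA_real_, healthy_ratio = h_ratio,
                        pct_change_min = NA_real_, pct_change_max = NA_real_,
                        flagged_gaps = sum(!ok)))
    data.frame(pro = pro, anti = anti,
               ratio_min = min(r), ratio_max = max(r),
               healthy_ratio = h_ratio,
               pct_change_min = 100 * (min(r) - h_ratio) / h_ratio,
               pct_change_max = 100 * (max(r) - h_ratio) / h_ratio,
               flagged_gaps = sum(!ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, window = window, mode = traj$meta$mode,
            class = c("ratio_report", "data.frame"))
}

#' @export
print.ratio_report <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Pro/anti-inflammatory ratios, weeks %g-%g (mode: %s)\n",
              w[1], w[2], attr(x, "mode")))
  df <- x
  df[] <- lapply(df, function(col) if (is.numeric(col)) round(col, 3) else col)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Compartment groups used in fold-change summaries
#'
#' @return named list of compartment groups: `pro_cytokines`,
#'   `anti_cytokines`, `immune_cells`.
#' @export
compartment_groups <- function() {
  list(pro_cytokines = c("I_alpha", "I_12", "I_gamma", "I_2"),
       anti_cytokines = c("I_10", "I_4"),
       immune_cells = c("M1", "M2", "Th1", "Th2", "Th17", "Treg"))
}

#' Steady-state fold changes of a patient case
#'
#' Component-wise ratio of the patient-case drug-free steady state to the
#' healthy steady state, grouped as pro-inflammatory cytokines,
#' anti-inflammatory cytokines and immune cells.
#'
#' @param case_ss named patient-case steady-state vector.
#' @param healthy_ss named healthy steady-state vector (strictly positive
#'   for all grouped compartments).
#' @param groups compartment grouping; default [compartment_groups()].
#' @return An object of class `fold_change_report`: data frame with
#'   `compartment`, `group`, `fold_change`.
#' @export
fold_change <- function(case_ss, healthy_ss, groups = compartment_groups()) {
  rows <- lapply(names(groups), function(g) {
    cps <- groups[[g]]
    h <- healthy_ss[cps]
    if (any(h <= 0))
      stop("healthy steady state must be > 0 for fold changes (",
           paste(cps[h <= 0], collapse = ", "), ")", call. = FALSE)
    data.frame(compartment = cps, group = g,
               fold_change = unname(case_ss[cps] / h))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("fold_change_report", "data.frame"))
}

#' @export
print.fold_change_report <- function(x, ...) {
  cat("Steady-state fold changes (case / healthy)\n")
  df <- x; df$fold_change <- round(df$fold_change, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Stacked-bar occupancy figure
#'
#' Draws per-compartment occupancies as a bar chart, the way
#' treatment-comparison figures in this literature summarize time-in-band
#' across compartments.
#'
#' @param x an `occupancy_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.occupancy_report <- function(x, ...) {
  graphics::barplot(x$occupancy, names.arg = x$compartment, las = 2,
                    ylab = "occupancy (%)", ylim = c(0, 100), ...)
  invisible(x)
}
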