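#' Patient-case scenarios
#'
#' The package ships a healthy baseline and four nominal patient cases
#' classified by the steady-state balance of the two helper-T axes relative
#' to healthy: case 1 (Th1 above, Th2 below), case 2 (Th1 below, Th2
#' above), case 3 (both above, together with the anti-inflammatory
#' cytokines IL-4 and IL-10), case 4 (both below). In every case TNF-alpha
#' is elevated. Each case overrides exactly ten baseline parameters by
#' multiplicative factors; the scenario files under
#' `system.file("extdata", "scenarios", package = "ibdtherapy")` document
#' the choice and carry provenance "nominal".
#'
#' @param label one of `"healthy"`, `"case1"`, `"case2"`, `"case3"`,
#'   `"case4"`.
#' @param baseline baseline model the overrides act on; default
#'   [healthy_model()].
#' @return An object of class `patient_case`: list with `label`,
#'   `overrides` (named factors), `provenance`, `description` and `model`
#'   (the [ibd_model()] with overrides applied).
#' @seealso [generate_synthetic_case()], [case_taxonomy()]
#' @export
#' @examples
#' pc <- load_case("case1")
#' pc
load_case <- function(label, baseline = healthy_model()) {
  label <- as.character(label)
  if (!label %in% case_labels())
    stop("unknown case label '", label, "'; known labels: ",
         paste(case_labels(), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", "scenarios", paste0(label, ".yaml"),
                      package = "ibdtherapy")
  cfg <- yaml::read_yaml(path)
  overrides <- unlist(cfg$overrides)
  if (is.null(overrides)) overrides <- stats::setNames(numeric(0), character(0))
  model <- apply_overrides(baseline, overrides, name = label)
  structure(list(label = label, overrides = overrides,
                 provenance = cfg$provenance,
                 description = cfg$description, model = model),
            class = "patient_case")
}

#' @rdname load_case
#' @export
case_labels <- function() c("healthy", "case1", "case2", "case3", "case4")

#' Th1/Th2 taxonomy of the four patient cases
#'
#' The defining steady-state sign pattern of each case relative to healthy:
#' `+1` means above the healthy level, `-1` below.
#'
#' @return named list of `c(Th1 = , Th2 = )` sign patterns.
#' @export
case_taxonomy <- function() {
  list(case1 = c(Th1 = 1, Th2 = -1),
       case2 = c(Th1 = -1, Th2 = 1),
       case3 = c(Th1 = 1, Th2 = 1),
       case4 = c(Th1 = -1, Th2 = -1))
}

# Does this case steady state satisfy the taxonomy's Th1/Th2 sign pattern?
taxonomy_ok <- function(case_ss, healthy_ss, pattern) {
  all(sign(case_ss[names(pattern)] - healthy_ss[names(pattern)]) == pattern)
}

#' Generate a synthetic patient case
#'
#' Draws a random patient with the statistical structure the analysis
#' assumes: each of the chosen case's ten override factors is perturbed by
#' an independent log-normal multiplier (median 1, log-scale standard
#' deviation `spread`), and the draw is accepted only if the resulting
#' drug-free steady state satisfies the case's Th1/Th2 sign pattern
#' ([case_taxonomy()]). Rejection sampling keeps the generator simple and
#' auditable, and its acceptance rate is itself a useful diagnostic of how
#' sharply the taxonomy constrains patient heterogeneity. The draw sequence
#' is deterministic given `seed` and leaves the global RNG state untouched.
#'
#' @param taxonomy one of `"case1"` ... `"case4"`.
#' @param seed integer seed; determines the case completely.
#' @param spread log-scale standard deviation of the multiplicative
#'   perturbations (> 0; `spread -> 0` recovers the nominal case).
#' @param baseline baseline model; default [healthy_model()].
#' @param max_draws rejection budget.
#' @return A `patient_case` with label `"synthetic:<seed>"`, plus fields
#'   `taxonomy`, `n_draws` (draws used) and `steady_state` (the accepted
#'   steady state).
#' @export
generate_synthetic_case <- function(taxonomy, seed, spread = 0.2,
                                    baseline = healthy_model(),
                                    max_draws = 1000) {
  taxonomy <- match.arg(taxonomy, names(case_taxonomy()))
  if (!is.numeric(spread) || spread < 0)
    stop("spread must be >= 0", call. = FALSE)
  nominal <- load_case(taxonomy, baseline = baseline)
  pattern <- case_taxonomy()[[taxonomy]]
  healthy_ss <- steady_state(baseline)$state
  nominal_ss <- steady_state(nominal$model)$state

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  for (draw in seq_len(max_draws)) {
    mult <- exp(stats::rnorm(length(nominal$overrides), 0, spread))
    factors <- nominal$overrides * mult
    model <- apply_overrides(baseline, factors,
                             name = paste0("synthetic:", seed))
    ss <- steady_state(model, init = nominal_ss, burn_in = 50)$state
    if (taxonomy_ok(ss, healthy_ss, pattern)) {
      return(structure(list(
        label = paste0("synthetic:", seed), overrides = factors,
        provenance = "synthetic", taxonomy = taxonomy,
        description = sprintf("synthetic %s patient (seed %d, spread %g)",
                              taxonomy, seed, spread),
        model = model, n_draws = draw, steady_state = ss),
        class = "patient_case"))
    }
  }
  stop(sprintf(
    "rejection budget exhausted for %s: 0 of %d draws satisfied the taxonomy (spread %g too large?)",
    taxonomy, max_draws, spread), call. = FALSE)
}

#' Nominal drug parameters and dose magnitude
#'
#' Returns the shipped nominal drug parameterization: antibody
#' binding/neutralization and clearance rates for the anti-TNF-alpha and
#' anti-IL-12 therapies, the IL-10 action and elimination rates for
#' recombinant IL-10, and the default dose magnitude of the infusion
#' schedule. Every value carries provenance "nominal": the set is
#' calibrated so that under the standard schedule the target cytokine dips
#' below its pre-treatment patient level, not transcribed from any
#' published table.
#'
#' @param model model whose drug parameters to report; default
#'   [healthy_model()].
#' @return list with `drug_params` (named vector), `dose_total`,
#'   `infusion_duration`, `provenance`.
#' @export
drug_nominals <- function(model = healthy_model()) {
  dp <- model$params[c("sigma_D_alpha", "delta_D_alpha",
                       "sigma_D_12", "delta_D_12",
                       "v_D10", "delta_D_10")]
  list(drug_params = dp,
       dose_total = model$dosing$dose_total,
       infusion_duration = model$dosing$infusion_duration,
       provenance = model$provenance)
}

#' @export
print.patient_case <- function(x, ...) {
  cat("Patient case '", x$label, "' (provenance: ", x$provenance, ")\n",
      sep = "")
  if (!is.null(x$description)) cat(" ", trimws(x$description), "\n")
  if (length(x$overrides)) {
    cat("  overrides (multiplicative factors on the healthy baseline):\n")
    print(round(x$overrides, 4))
  } else cat("  no overrides (healthy baseline)\n")
  if (!is.null(x$n_draws))
    cat("  accepted on draw", x$n_draws, "\n")
  invisible(x)
}
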