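#' Drug-coupled cytokine rate laws
#'
#' The three biologic therapies couple a target cytokine to a drug
#' compartment. Antibody therapies (anti-TNF-alpha, anti-IL-12) neutralize
#' their target by mass action: the bimolecular term `sigma * I * D` removes
#' cytokine and antibody at the same rate, so in a reduced system containing
#' only this term `I - D` is conserved. Recombinant IL-10 instead acts as a
#' source for the endogenous cytokine at rate `v_D10 * D_10`; its own
#' clearance `delta_D_10` is interpreted as total elimination (including
#' conversion), so the pair is deliberately not mass-conserving.
#'
#' `rhs_tnf_alpha()` returns
#' \deqn{dI_\alpha/dt = v_{\alpha M} M_1 + v_{\alpha 1} Th_1 -
#'   \delta_\alpha I_\alpha - \sigma_{D\alpha} I_\alpha D_\alpha}
#' \deqn{dD_\alpha/dt = v_M - \sigma_{D\alpha} I_\alpha D_\alpha -
#'   \delta_{D\alpha} D_\alpha}
#'
#' `rhs_il12()` returns
#' \deqn{dI_{12}/dt = v_{12M} M_1 / (1 + I_{10}/\zeta_{10}) -
#'   \delta_{12} I_{12} - \sigma_{D12} I_{12} D_{12}}
#' \deqn{dD_{12}/dt = v_M - \sigma_{D12} I_{12} D_{12} -
#'   \delta_{D12} D_{12}}
#'
#' `rhs_il10()` returns
#' \deqn{dI_{10}/dt = v_{10M} M_2 + v_{10r} [1 + n_{2r}
#'   I_\gamma/(\zeta_2 + I_2)] T_r - \delta_{10} I_{10} + v_{D10} D_{10}}
#' \deqn{dD_{10}/dt = v_M - \delta_{D10} D_{10}}
#'
#' @param state named numeric vector with (at least) the compartments the
#'   rate law reads; all entries must be finite and non-negative.
#' @param params named numeric vector of rate constants (finite, >= 0;
#'   `zeta_10 > 0`, `zeta_2 > 0`).
#' @param vM infusion rate of the corresponding drug at the current time
#'   (concentration per week; 0 outside infusion windows).
#' @return numeric vector of length 2: the cytokine and drug derivatives.
#' @seealso [rhs_full()], [infusion_rate()]
#' @export
#' @examples
#' p <- c(v_alpha_M = 2, v_alpha_1 = 3, delta_alpha = 1,
#'        sigma_D_alpha = 0, delta_D_alpha = 0.35)
#' s <- c(M1 = 1, Th1 = 2, I_alpha = 4, D_alpha = 0)
#' rhs_tnf_alpha(s, p, vM = 0)  # c(dI_alpha, dD_alpha) = c(4, 0)
rhs_tnf_alpha <- function(state, params, vM = 0) {
  .check_rhs_inputs(state, params, vM)
  p <- params
  neut <- p[["sigma_D_alpha"]] * state[["I_alpha"]] * state[["D_alpha"]]
  dI <- p[["v_alpha_M"]] * state[["M1"]] + p[["v_alpha_1"]] * state[["Th1"]] -
    p[["delta_alpha"]] * state[["I_alpha"]] - neut
  dD <- vM - neut - p[["delta_D_alpha"]] * state[["D_alpha"]]
  c(dI_alpha = dI, dD_alpha = dD)
}

#' @rdname rhs_tnf_alpha
#' @export
rhs_il12 <- function(state, params, vM = 0) {
  .check_rhs_inputs(state, params, vM)
  p <- params
  if (p[["zeta_10"]] <= 0)
    stop("zeta_10 must be > 0", call. = FALSE)
  neut <- p[["sigma_D_12"]] * state[["I_12"]] * state[["D_12"]]
  dI <- p[["v_12M"]] * state[["M1"]] / (1 + state[["I_10"]] / p[["zeta_10"]]) -
    p[["delta_12"]] * state[["I_12"]] - neut
  dD <- vM - neut - p[["delta_D_12"]] * state[["D_12"]]
  c(dI_12 = dI, dD_12 = dD)
}

#' @rdname rhs_tnf_alpha
#' @export
rhs_il10 <- function(state, params, vM = 0) {
  .check_rhs_inputs(state, params, vM)
  p <- params
  if (p[["zeta_2"]] <= 0)
    stop("zeta_2 must be > 0", call. = FALSE)
  treg_mod <- 1 + p[["n_2r"]] * state[["I_gamma"]] /
    (p[["zeta_2"]] + state[["I_2"]])
  dI <- p[["v_10M"]] * state[["M2"]] +
    p[["v_10r"]] * treg_mod * state[["Treg"]] -
    p[["delta_10"]] * state[["I_10"]] +
    p[["v_D10"]] * state[["D_10"]]
  dD <- vM - p[["delta_D_10"]] * state[["D_10"]]
  c(dI_10 = dI, dD_10 = dD)
}

.check_rhs_inputs <- function(state, params, vM) {
  if (any(!is.finite(state)) || any(state < 0))
    stop("state must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(params)) || any(params < 0))
    stop("rate constants must be finite and non-negative", call. = FALSE)
  if (!is.finite(vM) || vM < 0)
    stop("infusion rate must be finite and non-negative", call. = FALSE)
  invisible(NULL)
}

#' Full network derivative
#'
#' Assembles the derivative of the complete state vector: the built-in
#' drug-coupled rate laws for `I_alpha`, `I_12`, `I_10` and their drug
#' compartments, plus the term-registry rate laws for every other species.
#' The therapy mode decides which single drug compartment receives the
#' infusion forcing `vM(t)`; the others evolve with `vM = 0`.
#'
#' @param state named numeric state vector in the model's species order.
#' @param model an [ibd_model()].
#' @param mode therapy mode: one of `"none"`, `"anti_tnf"`, `"anti_il12"`,
#'   `"il10"`.
#' @param vM infusion rate at the current time (ignored for mode "none").
#' @return named numeric derivative vector in state order.
#' @export
#' @examples
#' m <- healthy_model()
#' s <- immune_state(m, default = 0.3)
#' rhs_full(s, m, mode = "none")
rhs_full <- function(state, model, mode = "none", vM = 0) {
  mode <- match.arg(mode, c("none", "anti_tnf", "anti_il12", "il10"))
  x <- state[model$species]
  if (any(is.na(x)))
    stop("state is missing compartments of the model registry",
         call. = FALSE)
  p <- model$params
  dx <- numeric(length(x))
  names(dx) <- model$species

  # term-registry species
  for (tm in model$compiled) {
    v <- p[[tm$rate]]
    for (f in tm$factors) {
      v <- v * switch(f$type,
        linear = x[[f$species]],
        saturating = x[[f$species]] / (p[[f$K]] + x[[f$species]]),
        inhibition = 1 / (1 + x[[f$species]] / p[[f$K]]),
        aided = 1 + p[[f$n]] * x[[f$aid]] / (p[[f$K]] + x[[f$interfere]]))
    }
    dx[[tm$target]] <- dx[[tm$target]] + tm$sign * v
  }

  va <- if (mode == "anti_tnf") vM else 0
  v12 <- if (mode == "anti_il12") vM else 0
  v10 <- if (mode == "il10") vM else 0

  neut_a <- p[["sigma_D_alpha"]] * x[["I_alpha"]] * x[["D_alpha"]]
  dx[["I_alpha"]] <- dx[["I_alpha"]] +
    p[["v_alpha_M"]] * x[["M1"]] + p[["v_alpha_1"]] * x[["Th1"]] -
    p[["delta_alpha"]] * x[["I_alpha"]] - neut_a
  dx[["D_alpha"]] <- va - neut_a - p[["delta_D_alpha"]] * x[["D_alpha"]]

  neut_12 <- p[["sigma_D_12"]] * x[["I_12"]] * x[["D_12"]]
  dx[["I_12"]] <- dx[["I_12"]] +
    p[["v_12M"]] * x[["M1"]] / (1 + x[["I_10"]] / p[["zeta_10"]]) -
    p[["delta_12"]] * x[["I_12"]] - neut_12
  dx[["D_12"]] <- v12 - neut_12 - p[["delta_D_12"]] * x[["D_12"]]

  treg_mod <- 1 + p[["n_2r"]] * x[["I_gamma"]] / (p[["zeta_2"]] + x[["I_2"]])
  dx[["I_10"]] <- dx[["I_10"]] +
    p[["v_10M"]] * x[["M2"]] + p[["v_10r"]] * treg_mod * x[["Treg"]] -
    p[["delta_10"]] * x[["I_10"]] + p[["v_D10"]] * x[["D_10"]]
  dx[["D_10"]] <- v10 - p[["delta_D_10"]] * x[["D_10"]]

  dx
}
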