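# Shared fixtures, built in code.

# Minimal parameter set: every built-in rate 0 except the half-saturation
# constants, which must be positive. Tests switch on the pieces they need.
zero_params <- function(...) {
  p <- stats::setNames(numeric(length(ibdtherapy:::.builtin_params)),
                       ibdtherapy:::.builtin_params)
  p[c("zeta_10", "zeta_2")] <- 1
  over <- c(...)
  p[names(over)] <- over
  p
}

# A model containing only the built-in compartments (plus optional extras
# with registry terms); used for closed-form and conservation checks.
toy_model <- function(..., species = character(0), terms = list(),
                      params = c()) {
  ibd_model(species = c(ibdtherapy:::.builtin_species, species),
            params = c(zero_params(...), params),
            terms = terms, name = "toy")
}

# Cached nominal healthy model and steady state (computed once per run).
cached_healthy <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      env$m <- healthy_model()
      env$ss <- steady_state(env$m)$state
    }
    list(model = env$m, ss = env$ss)
  }
})

cached_case_ss <- local({
  env <- new.env()
  function(label) {
    if (is.null(env[[label]])) {
      h <- cached_healthy()
      env[[label]] <- steady_state(load_case(label,
                                             baseline = h$model)$model)$state
    }
    env[[label]]
  }
})
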