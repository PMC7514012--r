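#' Immune-network model objects
#'
#' An `ibd_model` bundles everything needed to evaluate the right-hand side
#' of the IBD immune network: the compartment registry (state-vector order),
#' a named vector of rate constants, and a term registry describing the
#' base-network rate laws. The three drug-coupled cytokines (TNF-alpha,
#' IL-12, IL-10) and their drug compartments have built-in rate laws (see
#' [rhs_tnf_alpha()], [rhs_il12()], [rhs_il10()]); all remaining species are
#' governed by the configurable term registry, so the base network can be
#' re-parameterized or extended without code changes.
#'
#' @section Built-in compartments:
#' `I_alpha`, `I_12`, `I_10` (cytokines) and `D_alpha`, `D_12`, `D_10`
#' (drugs) must be present in `species`. The minimum registry shipped in the
#' package configuration additionally contains `M1`, `M2`, `Th1`, `Th2`,
#' `Th17`, `Treg`, `I_gamma`, `I_2`, `I_4`.
#'
#' @param species character vector of compartment names, in state order.
#' @param params named numeric vector of non-negative rate constants.
#' @param terms list of term specifications for the base-network species;
#'   see [load_model_config()] for the schema.
#' @param dosing list with `dose_total` and `infusion_duration` defaults.
#' @param name model label used in printing and metadata.
#' @param provenance provenance tag (`"nominal"`, `"user"`, ...).
#'
#' @return An object of class `ibd_model`.
#' @seealso [load_model_config()], [rhs_full()], [steady_state()]
#' @export
ibd_model <- function(species, params, terms, dosing = NULL,
                      name = "model", provenance = "user") {
  species <- as.character(species)
  if (anyDuplicated(species))
    stop("compartment names must be unique", call. = FALSE)
  missing_builtin <- setdiff(.builtin_species, species)
  if (length(missing_builtin))
    stop("species registry must contain the built-in compartments: ",
         paste(missing_builtin, collapse = ", "), call. = FALSE)
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop("all parameters must be named", call. = FALSE)
  params <- unlist(params)
  if (any(!is.finite(params)) || any(params < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  for (nm in c("zeta_10", "zeta_2"))
    if (!is.na(params[nm]) && params[nm] <= 0)
      stop(nm, " must be > 0", call. = FALSE)
  missing_p <- setdiff(.builtin_params, names(params))
  if (length(missing_p))
    stop("missing built-in parameters: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  compiled <- compile_terms(terms, species, params)
  if (is.null(dosing))
    dosing <- list(dose_total = list(anti_tnf = 2, anti_il12 = 2, il10 = 2),
                   infusion_duration = 1 / 7)
  structure(
    list(species = species, params = params, terms = terms,
         compiled = compiled, dosing = dosing,
         name = name, provenance = provenance),
    class = "ibd_model")
}

# Compartments the built-in drug-coupled rate laws read or write; every
# model must declare them (with zero rates they are inert).
.builtin_species <- c("M1", "M2", "Th1", "Treg", "I_gamma", "I_2",
                      "I_alpha", "I_12", "I_10", "D_alpha", "D_12", "D_10")

.builtin_params <- c(
  "v_alpha_M", "v_alpha_1", "delta_alpha",
  "v_12M", "zeta_10", "delta_12",
  "v_10M", "v_10r", "n_2r", "zeta_2", "delta_10",
  "sigma_D_alpha", "delta_D_alpha", "sigma_D_12", "delta_D_12",
  "v_D10", "delta_D_10")

.factor_types <- c("linear", "saturating", "inhibition", "aided")

# Compile the declarative term list into an index-based form the RHS can
# evaluate cheaply: parameter and species references become integer indices.
compile_terms <- function(terms, species, params) {
  pnames <- names(params)
  sp_idx <- function(s, what) {
    i <- match(s, species)
    if (is.na(i))
      stop("term references unknown species '", s, "' (", what, ")",
           call. = FALSE)
    i
  }
  par_idx <- function(p, what) {
    i <- match(p, pnames)
    if (is.na(i))
      stop("term references unknown parameter '", p, "' (", what, ")",
           call. = FALSE)
    i
  }
  lapply(terms, function(tm) {
    if (is.null(tm$target) || is.null(tm$rate))
      stop("each term needs 'target' and 'rate' fields", call. = FALSE)
    target <- sp_idx(tm$target, "target")
    rate <- par_idx(tm$rate, paste0("rate of term for ", tm$target))
    if (identical(tm$type, "decay")) {
      return(list(target = target, rate = rate, sign = -1,
                  factors = list(list(type = "linear", species = target))))
    }
    sign <- if (is.null(tm$sign)) 1 else as.numeric(tm$sign)
    if (!sign %in% c(-1, 1))
      stop("term sign must be +1 or -1", call. = FALSE)
    factors <- lapply(tm$factors, function(f) {
      if (is.null(f$type) || !f$type %in% .factor_types)
        stop("unknown factor type '", f$type, "'", call. = FALSE)
      switch(f$type,
        linear = list(type = "linear",
                      species = sp_idx(f$species, "linear factor")),
        saturating = list(type = "saturating",
                          species = sp_idx(f$species, "saturating factor"),
                          K = par_idx(f$K, "saturation constant")),
        inhibition = list(type = "inhibition",
                          species = sp_idx(f$species, "inhibition factor"),
                          K = par_idx(f$K, "inhibition constant")),
        aided = list(type = "aided",
                     aid = sp_idx(f$aid, "aided factor"),
                     interfere = sp_idx(f$interfere, "aided factor"),
                     n = par_idx(f$n, "aided coefficient"),
                     K = par_idx(f$K, "aided constant")))
    })
    list(target = target, rate = rate, sign = sign, factors = factors)
  })
}

#' Load a model configuration file
#'
#' Reads a structured YAML configuration with sections `species`, `params`,
#' `terms` and `dosing`, validates it, and returns an [ibd_model()]. The
#' package ships a nominal healthy baseline as
#' `system.file("extdata", "model_healthy.yaml", package = "ibdtherapy")`.
#'
#' @section Term schema:
#' Each entry of `terms` contributes `sign * rate * prod(factors)` to its
#' target's derivative. `rate` names a parameter. Factor types: `linear`
#' (`X`), `saturating` (`X/(K+X)`), `inhibition` (`1/(1+X/K)`) and `aided`
#' (`1 + n*A/(K+B)`, fields `aid`, `interfere`, `n`, `K`); `K` and `n` name
#' parameters so scenario overrides can rescale them. `type: decay` is
#' shorthand for a first-order loss `-rate * target`.
#'
#' @param path path to a YAML configuration file.
#' @return An `ibd_model`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (field in c("species", "params", "terms"))
    if (is.null(cfg[[field]]))
      stop("config is missing the '", field, "' section", call. = FALSE)
  ibd_model(species = cfg$species,
            params = unlist(cfg$params),
            terms = cfg$terms,
            dosing = cfg$dosing,
            name = if (is.null(cfg$name)) "model" else cfg$name,
            provenance = if (is.null(cfg$provenance)) "user" else cfg$provenance)
}

#' The shipped nominal healthy baseline model
#'
#' Convenience loader for the package's nominal healthy configuration. All
#' values carry provenance "nominal": they are authored for this package to
#' reproduce the qualitative patient-case patterns, not transcribed from a
#' published parameter table.
#'
#' @return An `ibd_model`.
#' @export
#' @examples
#' m <- healthy_model()
#' m
healthy_model <- function() {
  path <- system.file("extdata", "model_healthy.yaml", package = "ibdtherapy")
  load_model_config(path)
}

#' Construct an immune state vector
#'
#' Builds a named, non-negative state vector in the model's compartment
#' order. Unspecified compartments default to `default` (drug compartments
#' always default to 0).
#'
#' @param model an `ibd_model`.
#' @param ... named compartment concentrations.
#' @param default value for unspecified non-drug compartments.
#' @return named numeric vector in state order.
#' @export
immune_state <- function(model, ..., default = 0) {
  vals <- c(...)
  x <- rep(default, length(model$species))
  names(x) <- model$species
  x[startsWith(names(x), "D_")] <- 0
  if (length(vals)) {
    unknown <- setdiff(names(vals), model$species)
    if (length(unknown))
      stop("unknown compartments: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    x[names(vals)] <- vals
  }
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  x
}

#' Apply multiplicative parameter overrides
#'
#' @param model an `ibd_model`.
#' @param factors named numeric vector of multiplicative factors (> 0)
#'   applied to the corresponding parameters.
#' @param name label for the resulting model.
#' @return a new `ibd_model` with scaled parameters.
#' @export
apply_overrides <- function(model, factors, name = model$name) {
  if (!length(factors)) {
    model$name <- name
    return(model)
  }
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    stop("override factors must be named", call. = FALSE)
  factors <- unlist(factors)
  unknown <- setdiff(names(factors), names(model$params))
  if (length(unknown))
    stop("overrides reference unknown parameters: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("override factors must be finite and > 0", call. = FALSE)
  p <- model$params
  p[names(factors)] <- p[names(factors)] * factors
  ibd_model(model$species, p, model$terms, dosing = model$dosing,
            name = name, provenance = model$provenance)
}

#' @export
print.ibd_model <- function(x, ...) {
  cat("IBD immune-network model '", x$name, "' (provenance: ",
      x$provenance, ")\n", sep = "")
  cat("  compartments:", length(x$species), "--",
      paste(x$species, collapse = ", "), "\n")
  cat("  parameters:  ", length(x$params), "rate constants (per week)\n")
  cat("  registry:    ", length(x$terms),
      "terms for the base-network species\n")
  invisible(x)
}
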