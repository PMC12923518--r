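#' Candidate learning models
#'
#' The package implements six candidate models of trial-by-trial learning on
#' the loss-avoidance card task. Each model couples a *perceptual* model of
#' how the loss probability of the reference card is tracked with the common
#' softmax *observation* model (inverse temperature `beta`, optionally a
#' loss-sensitivity exponent `rho`):
#'
#' * `"rw"` -- Rescorla-Wagner delta rule (learning rate `alpha`).
#' * `"k1"` -- Sutton's K1 adaptive-gain delta rule (meta-learning rate
#'   `mu_meta`, initial log learning rate `b0`).
#' * `"hgf2"` -- two-level binary Hierarchical Gaussian Filter
#'   (log-volatility `omega`).
#' * `"hgf2_loss"` -- two-level HGF plus loss sensitivity `rho`.
#' * `"hgf3"` -- three-level binary HGF (`omega`, coupling `kappa`,
#'   meta-volatility `theta`; `kappa` is fixed at 1 by default).
#' * `"hgf3_loss"` -- three-level HGF plus `rho`.
#'
#' @return `costlearn_models()` returns the character vector of model labels.
#' @export
costlearn_models <- function() {
  c("rw", "k1", "hgf2", "hgf2_loss", "hgf3", "hgf3_loss")
}

# Parameter table per model: names, transform linking the unconstrained
# (fitting) scale to the native scale, and default prior on the unconstrained
# scale. `fixed` parameters are pinned at `fixed_native` and not fitted.
model_param_table <- function(model_spec) {
  model_spec <- match.arg(model_spec, costlearn_models())
  row <- function(name, transform, mean, sd, fixed = FALSE, fixed_native = NA_real_) {
    data.frame(name = name, transform = transform, mean = mean, sd = sd,
               fixed = fixed, fixed_native = fixed_native,
               stringsAsFactors = FALSE)
  }
  beta <- row("beta", "log", 0, 2)
  rho  <- row("rho", "log", 0, 1)
  tab <- switch(model_spec,
    rw        = rbind(row("alpha", "logit", 0, 2), beta),
    k1        = rbind(row("mu_meta", "log", -2, 2), row("b0", "identity", -2.3, 2), beta),
    hgf2      = rbind(row("omega", "identity", -3, 4), beta),
    hgf2_loss = rbind(row("omega", "identity", -3, 4), beta, rho),
    hgf3      = rbind(row("omega", "identity", -3, 4),
                      row("kappa", "log", 0, 1, fixed = TRUE, fixed_native = 1),
                      row("theta", "log", -6, 4), beta),
    hgf3_loss = rbind(row("omega", "identity", -3, 4),
                      row("kappa", "log", 0, 1, fixed = TRUE, fixed_native = 1),
                      row("theta", "log", -6, 4), beta, rho))
  rownames(tab) <- tab$name
  tab
}

#' Default priors for a model
#'
#' Priors are independent Gaussians on each parameter's unconstrained scale
#' (logit for rates in (0,1), log for strictly positive parameters, identity
#' for the HGF log-volatility `omega`, which is already unbounded). The
#' defaults are weakly informative: `omega ~ N(-3, 16)`,
#' `log beta ~ N(0, 4)`, `log rho ~ N(0, 1)`, `logit alpha ~ N(0, 4)`,
#' K1 `log mu_meta ~ N(-2, 4)` and `b0 ~ N(-2.3, 4)`, HGF3
#' `log theta ~ N(-6, 16)` with the level-2/3 coupling `kappa` fixed at 1.
#'
#' @param model_spec model label, one of [costlearn_models()].
#' @return a data frame with one row per parameter and columns `name`,
#'   `transform` (`"logit"`, `"log"` or `"identity"`), `mean`, `sd`
#'   (unconstrained-scale Gaussian prior), `fixed` and `fixed_native`.
#' @examples
#' default_priors("hgf2_loss")
#' @export
default_priors <- function(model_spec) {
  model_param_table(model_spec)
}

check_priors <- function(priors, model_spec) {
  tab <- model_param_table(model_spec)
  need <- c("name", "transform", "mean", "sd", "fixed", "fixed_native")
  if (!all(need %in% names(priors)))
    stop("priors must have columns: ", paste(need, collapse = ", "))
  if (!setequal(priors$name, tab$name))
    stop("priors must cover exactly the parameters of '", model_spec, "': ",
         paste(tab$name, collapse = ", "))
  if (any(priors$sd[!priors$fixed] <= 0))
    stop("prior standard deviations must be positive")
  priors[match(tab$name, priors$name), , drop = FALSE]
}

# transforms between unconstrained and native scales
to_native <- function(x, transform) {
  switch(transform,
         logit = stats::plogis(x),
         log = exp(x),
         identity = x,
         stop("unknown transform: ", transform))
}

from_native <- function(x, transform) {
  switch(transform,
         logit = stats::qlogis(x),
         log = log(x),
         identity = x,
         stop("unknown transform: ", transform))
}

# vector version over a parameter table
theta_to_params <- function(theta, tab) {
  stopifnot(length(theta) == nrow(tab))
  out <- mapply(to_native, theta, tab$transform)
  names(out) <- tab$name
  as.list(out)
}

params_to_theta <- function(params, tab) {
  vapply(seq_len(nrow(tab)), function(i) {
    from_native(params[[tab$name[i]]], tab$transform[i])
  }, numeric(1))
}

# Validate a native-scale parameter list for a model, naming the offender.
check_params <- function(params, model_spec) {
  tab <- model_param_table(model_spec)
  missing <- setdiff(tab$name, names(params))
  if (length(missing))
    stop("missing parameter(s) for '", model_spec, "': ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    val <- params[[tab$name[i]]]
    if (!is.finite(val))
      stop("parameter '", tab$name[i], "' must be finite")
    # beta = 0 (fully random choice) is a valid boundary value natively,
    # even though the fitted log scale never reaches it
    ok <- switch(tab$transform[i],
                 logit = val > 0 && val < 1,
                 log = val > 0 || (tab$name[i] == "beta" && val == 0),
                 identity = TRUE)
    if (!ok)
      stop("parameter '", tab$name[i], "' violates its constraint (",
           switch(tab$transform[i], logit = "must be in (0,1)",
                  log = "must be > 0", identity = ""), ")")
  }
  if ("beta" %in% names(params) && params$beta < 0)
    stop("parameter 'beta' must be >= 0")
  invisible(params)
}
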