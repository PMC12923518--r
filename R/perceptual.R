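#' Perceptual model updates
#'
#' Single-trial belief updates for the candidate perceptual models. All
#' models track the probability that the reference card (card 1) is the
#' losing card; the binary outcome `u` is 1 when card 1 loses on the trial.
#'
#' `rw_update()` is the Rescorla-Wagner delta rule `v' = v + alpha (u - v)`.
#'
#' `k1_update()` is Sutton's K1 scheme: a delta rule whose learning rate
#' `exp(b)` (capped at 1) adapts through the recent correlation of
#' prediction errors, via the gain trace `h`:
#' `b' = b + mu_meta * delta * h`, `lr = min(1, exp(b'))`,
#' `v' = v + lr * delta`, `h' = h * max(0, 1 - lr) + lr * delta`.
#'
#' `hgf2_update()` is the canonical binary two-level Hierarchical Gaussian
#' Filter step: prediction `s_hat = logistic(mu2)`; predicted variance
#' `sigma2_hat = sigma2 + exp(omega)`; posterior precision
#' `pi2 = 1/sigma2_hat + s_hat (1 - s_hat)`; update
#' `mu2' = mu2 + (1/pi2) (u - s_hat)`, `sigma2' = 1/pi2`. The trajectory
#' records the outcome prediction error `delta1 = u - s_hat` and the
#' precision-weighted prediction error `eps2 = (1/pi2) delta1`.
#'
#' `hgf3_update()` adds a third level that tracks log-volatility: the
#' level-2 step uses effective log-volatility `kappa * mu3 + omega`, and
#' `(mu3, sigma3)` are updated from the level-2 volatility prediction error
#' with step variance `theta`.
#'
#' @param state named list of state variables (see [init_state()]).
#' @param u binary outcome for the reference card (1 = card 1 lost).
#' @param alpha Rescorla-Wagner learning rate in (0,1).
#' @param mu_meta K1 meta-learning rate (> 0).
#' @param omega HGF tonic log-volatility (unbounded).
#' @param kappa HGF3 level-2/3 coupling (> 0).
#' @param theta HGF3 meta-volatility / level-3 step variance (> 0).
#' @return the updated state list; HGF updates also carry the trajectory
#'   entries `s_hat`, `delta1` and `eps2` for the trial.
#' @name perceptual-updates
NULL

#' @rdname perceptual-updates
#' @export
rw_update <- function(state, u, alpha) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("parameter 'alpha' violates its constraint (must be in (0,1))")
  stopifnot(u %in% c(0, 1), state$v >= 0, state$v <= 1)
  state$s_hat <- state$v
  state$delta1 <- u - state$v
  state$v <- state$v + alpha * (u - state$v)
  state
}

#' @rdname perceptual-updates
#' @export
k1_update <- function(state, u, mu_meta) {
  if (!is.finite(mu_meta) || mu_meta < 0)
    stop("parameter 'mu_meta' violates its constraint (must be >= 0)")
  if (!all(is.finite(c(state$v, state$h, state$b))))
    stop("K1 state diverged (non-finite state)")
  delta <- u - state$v
  state$s_hat <- state$v
  state$delta1 <- delta
  b <- state$b + mu_meta * delta * state$h
  b <- max(min(b, 20), -20)                     # overflow guard only
  lr <- min(1, exp(b))
  state$b <- b
  state$lr <- lr
  state$v <- state$v + lr * delta
  state$h <- state$h * max(0, 1 - lr) + lr * delta
  state
}

#' @rdname perceptual-updates
#' @export
hgf2_update <- function(state, u, omega) {
  if (!is.finite(state$sigma2) || state$sigma2 <= 0)
    stop("invalid HGF state: sigma2 must be > 0")
  s_hat <- stats::plogis(state$mu2)
  sigma2_hat <- state$sigma2 + exp(omega)
  pi2 <- 1 / sigma2_hat + s_hat * (1 - s_hat)
  delta1 <- u - s_hat
  state$mu2 <- state$mu2 + delta1 / pi2
  state$sigma2 <- 1 / pi2
  state$s_hat <- s_hat
  state$delta1 <- delta1
  state$eps2 <- delta1 / pi2
  state
}

#' @rdname perceptual-updates
#' @export
hgf3_update <- function(state, u, omega, kappa, theta) {
  if (!is.finite(state$sigma2) || state$sigma2 <= 0 ||
      !is.finite(state$sigma3) || state$sigma3 <= 0)
    stop("invalid HGF state: sigma2 and sigma3 must be > 0")
  if (kappa <= 0) stop("parameter 'kappa' violates its constraint (must be > 0)")
  if (theta < 0) stop("parameter 'theta' violates its constraint (must be >= 0)")
  s_hat <- stats::plogis(state$mu2)
  v2 <- exp(kappa * state$mu3 + omega)
  sigma2_hat <- state$sigma2 + v2
  pi2 <- 1 / sigma2_hat + s_hat * (1 - s_hat)
  delta1 <- u - s_hat
  mu2_new <- state$mu2 + delta1 / pi2
  sigma2_new <- 1 / pi2
  # level-3 update from the volatility prediction error at level 2
  w2 <- v2 / sigma2_hat
  delta2 <- (sigma2_new + (mu2_new - state$mu2)^2) / sigma2_hat - 1
  pi3_hat <- 1 / (state$sigma3 + theta)
  pi3 <- pi3_hat + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
  if (!is.finite(pi3) || pi3 <= 0)
    stop("invalid trajectory: non-positive level-3 precision")
  state$mu3 <- state$mu3 + (kappa / (2 * pi3)) * w2 * delta2
  state$sigma3 <- 1 / pi3
  state$mu2 <- mu2_new
  state$sigma2 <- sigma2_new
  state$s_hat <- s_hat
  state$delta1 <- delta1
  state$eps2 <- delta1 / pi2
  state
}

#' Initial perceptual state
#'
#' Neutral starting beliefs shared by all models: the predicted loss
#' probability for the reference card starts at 0.5 (`v = 0.5` for the
#' delta-rule models, `mu2 = 0` for the HGF), with unit starting variances
#' (`sigma2 = 1`) and, for the three-level HGF, `mu3 = 1`, `sigma3 = 1`.
#' Initial states are fixed, not fitted.
#'
#' @param model_spec model label, one of [costlearn_models()].
#' @param params native-scale parameter list (K1 needs `b0`).
#' @return a named list of state variables.
#' @export
init_state <- function(model_spec, params = list()) {
  model_spec <- match.arg(model_spec, costlearn_models())
  switch(model_spec,
         rw = list(v = 0.5),
         k1 = list(v = 0.5, h = 0, b = if (!is.null(params$b0)) params$b0 else -2.3),
         hgf2 = ,
         hgf2_loss = list(mu2 = 0, sigma2 = 1),
         hgf3 = ,
         hgf3_loss = list(mu2 = 0, sigma2 = 1, mu3 = 1, sigma3 = 1))
}

#' Run a belief trajectory over a sequence of outcomes
#'
#' Folds the model's single-trial update over a binary outcome sequence
#' (1 = the reference card lost on that trial) from the fixed initial state
#' and returns the full trajectory. The prediction `s_hat` on each row is
#' the model's predicted loss probability for the reference card *before*
#' seeing that trial's outcome; state columns hold the post-update state.
#'
#' @param model_spec model label, one of [costlearn_models()].
#' @param params native-scale parameter list for the model's perceptual
#'   parameters (observation parameters are ignored here).
#' @param outcomes integer vector of 0/1 outcomes for the reference card.
#' @return a data frame with one row per trial: `trial`, `u`, `s_hat`,
#'   `delta1`, plus model state columns (`v` / `lr` / `mu2`, `sigma2`,
#'   `eps2`, `mu3`, `sigma3` as applicable).
#' @examples
#' tr <- run_trajectory("hgf2", list(omega = -2, beta = 1),
#'                      outcomes = rbinom(20, 1, 0.75))
#' head(tr)
#' @export
run_trajectory <- function(model_spec, params, outcomes) {
  model_spec <- match.arg(model_spec, costlearn_models())
  n <- length(outcomes)
  if (n == 0) {
    return(data.frame(trial = integer(0), u = integer(0),
                      s_hat = numeric(0), delta1 = numeric(0)))
  }
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be binary 0/1")
  state <- init_state(model_spec, params)
  is_hgf3 <- model_spec %in% c("hgf3", "hgf3_loss")
  is_hgf2 <- model_spec %in% c("hgf2", "hgf2_loss")
  s_hat <- delta1 <- numeric(n)
  if (is_hgf2 || is_hgf3) { mu2 <- sigma2 <- eps2 <- numeric(n) }
  if (is_hgf3) { mu3 <- sigma3 <- numeric(n) }
  if (model_spec == "rw") v <- numeric(n)
  if (model_spec == "k1") { v <- lr <- numeric(n) }
  for (t in seq_len(n)) {
    state <- tryCatch(
      switch(model_spec,
             rw = rw_update(state, outcomes[t], params$alpha),
             k1 = k1_update(state, outcomes[t], params$mu_meta),
             hgf2 = ,
             hgf2_loss = hgf2_update(state, outcomes[t], params$omega),
             hgf3 = ,
             hgf3_loss = hgf3_update(state, outcomes[t], params$omega,
                                     params$kappa, params$theta)),
      error = function(e) stop("trial ", t, ": ", conditionMessage(e),
                               call. = FALSE))
    s_hat[t] <- state$s_hat
    delta1[t] <- state$delta1
    if (is_hgf2 || is_hgf3) {
      mu2[t] <- state$mu2; sigma2[t] <- state$sigma2; eps2[t] <- state$eps2
    }
    if (is_hgf3) { mu3[t] <- state$mu3; sigma3[t] <- state$sigma3 }
    if (model_spec == "rw") v[t] <- state$v
    if (model_spec == "k1") { v[t] <- state$v; lr[t] <- state$lr }
  }
  out <- data.frame(trial = seq_len(n), u = outcomes, s_hat = s_hat,
                    delta1 = delta1)
  if (model_spec == "rw") out$v <- v
  if (model_spec == "k1") { out$v <- v; out$lr <- lr }
  if (is_hgf2 || is_hgf3) { out$mu2 <- mu2; out$sigma2 <- sigma2; out$eps2 <- eps2 }
  if (is_hgf3) { out$mu3 <- mu3; out$sigma3 <- sigma3 }
  out
}

#' Write a belief trajectory to TSV
#'
#' @param trajectory data frame from [run_trajectory()].
#' @param path output file path.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
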