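#' Expected loss value of a card
#'
#' Utility of choosing a card whose predicted loss probability is `p_loss`
#' and displayed loss magnitude is `magnitude` dollars. Loss sensitivity
#' `rho` enters as a power on magnitude, `v = -p_loss * magnitude^rho`, so
#' that `rho` bends the impact of the dollar amounts while the inverse
#' temperature `beta` scales overall choice consistency; the two are
#' separately identifiable in a two-option loss-only softmax (a purely
#' multiplicative loss weight would be collinear with `beta`).
#'
#' @param p_loss predicted loss probability in (0,1) (vectorised).
#' @param magnitude loss magnitude in dollars, > 0 (vectorised).
#' @param rho loss-sensitivity exponent, > 0. Default 1 (risk-neutral
#'   expected loss).
#' @return the (non-positive) expected loss utility.
#' @examples
#' expected_loss_value(0.8, 4, rho = 0.5)  # -1.6
#' @export
expected_loss_value <- function(p_loss, magnitude, rho = 1) {
  if (any(magnitude <= 0)) stop("magnitude must be > 0")
  if (any(rho <= 0)) stop("parameter 'rho' violates its constraint (must be > 0)")
  -p_loss * magnitude^rho
}

#' Softmax choice probability
#'
#' Probability of choosing card 1 given the two utilities:
#' `logistic(beta * (v1 - v2))`, strictly inside (0,1) for finite inputs.
#'
#' @param v1,v2 utilities of card 1 and card 2 (vectorised).
#' @param beta inverse temperature, >= 0.
#' @return probability of choosing card 1.
#' @examples
#' choice_probability(-1, -2, beta = 1)  # plogis(1)
#' @export
choice_probability <- function(v1, v2, beta) {
  if (any(!is.finite(c(v1, v2)))) stop("utilities must be finite")
  if (any(beta < 0)) stop("parameter 'beta' violates its constraint (must be >= 0)")
  stats::plogis(beta * (v1 - v2))
}

# ---- internal fast belief-trajectory predictions (s_hat per trial) --------
# These inline the per-trial recursions of run_trajectory() without per-trial
# validation, for use inside optimisation loops. They return the vector of
# pre-update predictions s_hat, or NULL when the trajectory is invalid
# (non-finite state or non-positive precision), which the likelihood maps to
# an "invalid candidate" sentinel for the optimiser.
shat_series <- function(model_spec, params, u) {
  n <- length(u)
  s_hat <- numeric(n)
  if (model_spec == "rw") {
    a <- params$alpha
    if (!is.finite(a) || a <= 0 || a >= 1) return(NULL)
    v <- 0.5
    for (t in seq_len(n)) {
      s_hat[t] <- v
      v <- v + a * (u[t] - v)
    }
  } else if (model_spec == "k1") {
    m <- params$mu_meta
    if (!is.finite(m) || m < 0) return(NULL)
    v <- 0.5; h <- 0; b <- params$b0
    for (t in seq_len(n)) {
      s_hat[t] <- v
      d <- u[t] - v
      b <- b + m * d * h
      if (b > 20) b <- 20 else if (b < -20) b <- -20
      lr <- exp(b)
      if (lr > 1) lr <- 1
      v <- v + lr * d
      h <- h * max(0, 1 - lr) + lr * d
    }
  } else if (model_spec %in% c("hgf2", "hgf2_loss")) {
    ew <- exp(params$omega)
    mu2 <- 0; sigma2 <- 1
    for (t in seq_len(n)) {
      sh <- 1 / (1 + exp(-mu2))
      s_hat[t] <- sh
      pi2 <- 1 / (sigma2 + ew) + sh * (1 - sh)
      mu2 <- mu2 + (u[t] - sh) / pi2
      sigma2 <- 1 / pi2
    }
    if (!is.finite(mu2)) return(NULL)
  } else {
    k <- params$kappa; th <- params$theta; om <- params$omega
    if (!is.finite(k) || k <= 0 || th < 0) return(NULL)
    mu2 <- 0; sigma2 <- 1; mu3 <- 1; sigma3 <- 1
    for (t in seq_len(n)) {
      sh <- 1 / (1 + exp(-mu2))
      s_hat[t] <- sh
      v2 <- exp(k * mu3 + om)
      sigma2_hat <- sigma2 + v2
      pi2 <- 1 / sigma2_hat + sh * (1 - sh)
      mu2_new <- mu2 + (u[t] - sh) / pi2
      sigma2_new <- 1 / pi2
      w2 <- v2 / sigma2_hat
      delta2 <- (sigma2_new + (mu2_new - mu2)^2) / sigma2_hat - 1
      pi3 <- 1 / (sigma3 + th) + (k^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
      if (!is.finite(pi3) || pi3 <= 0) return(NULL)
      mu3 <- mu3 + (k / (2 * pi3)) * w2 * delta2
      sigma3 <- 1 / pi3
      mu2 <- mu2_new
      sigma2 <- sigma2_new
    }
    if (!is.finite(mu2) || !is.finite(mu3)) return(NULL)
  }
  s_hat
}

# Per-trial probability of choosing card 1 from predictions and magnitudes.
p_choose1 <- function(s_hat, mag1, mag2, beta, rho) {
  v1 <- -s_hat * mag1^rho
  v2 <- -(1 - s_hat) * mag2^rho
  stats::plogis(beta * (v1 - v2))
}

# Outcome for the reference card: u = 1 iff card 1 was the losing card.
reference_outcome <- function(dataset) {
  if (!is.null(dataset$correct_card)) {
    as.integer(dataset$correct_card == 2)
  } else {
    # recover from choice + loss indicator: chosen card lost iff outcome == 1
    as.integer(ifelse(dataset$choice == 1, dataset$outcome, 1 - dataset$outcome))
  }
}

#' Choice log-likelihood of a subject dataset
#'
#' Runs the perceptual model over the subject's full outcome sequence (both
#' contexts, in presentation order, one parameter set for the whole
#' session), converts the per-trial predicted loss probabilities and the two
#' cards' magnitudes into softmax choice probabilities, and sums the log
#' probabilities of the observed choices. Probabilities are clamped away
#' from 0 and 1 so the value is always finite for a valid trajectory;
#' parameter regimes that make the trajectory diverge return `-Inf` as an
#' "invalid candidate" sentinel for the optimiser.
#'
#' @param model_spec model label, one of [costlearn_models()].
#' @param params native-scale parameter list (perceptual parameters plus
#'   `beta`, and `rho` for the `_loss` models; `rho` defaults to 1 when the
#'   model does not carry it).
#' @param dataset subject trial data frame with columns `choice`,
#'   `mag_card1`, `mag_card2` and `correct_card` (or `outcome`).
#' @return total log-likelihood (scalar).
#' @export
log_likelihood <- function(model_spec, params, dataset) {
  model_spec <- match.arg(model_spec, costlearn_models())
  check_params(params, model_spec)
  ll_fast(model_spec, params, reference_outcome(dataset),
          dataset$mag_card1, dataset$mag_card2, dataset$choice)
}

ll_fast <- function(model_spec, params, u, mag1, mag2, choice) {
  s_hat <- shat_series(model_spec, params, u)
  if (is.null(s_hat)) return(-Inf)
  has_rho <- model_spec %in% c("hgf2_loss", "hgf3_loss")
  rho <- if (has_rho && !is.null(params$rho)) params$rho else 1
  p1 <- p_choose1(s_hat, mag1, mag2, params$beta, rho)
  p <- ifelse(choice == 1, p1, 1 - p1)
  eps <- .Machine$double.eps
  sum(log(pmin(pmax(p, eps), 1 - eps)))
}
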