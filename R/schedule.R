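#' Generate a task schedule
#'
#' Builds the 200-trial loss-avoidance schedule: 100 contiguous trials in a
#' *stable* context where one card predicts loss with probability 0.75 and
#' the other 0.25 throughout, and 100 contiguous trials in a *volatile*
#' context where the assignment (0.80 vs 0.20) reverses after every 25
#' trials (at volatile-block offsets 25, 50 and 75). Which card starts as
#' the high-loss card in each context is randomised per schedule. The two
#' cards' loss magnitudes are drawn independently and uniformly on [1, 5]
#' dollars per trial (see [draw_magnitudes()]), and the correct
#' (loss-avoiding) card is drawn per trial from the contingency:
#' `P(correct_card = 2) = p_loss_card1`.
#'
#' @param block_order `"stable_first"` or `"volatile_first"`.
#' @param seed optional integer seed for reproducibility.
#' @param n_per_context trials per context (default 100; the volatile block
#'   reverses at every quarter of its length).
#' @return a data frame with one row per trial and columns `trial`,
#'   `context`, `block_order`, `p_loss_card1`, `mag_card1`, `mag_card2`,
#'   `correct_card`.
#' @examples
#' sched <- generate_schedule("stable_first", seed = 1)
#' table(sched$context, sched$p_loss_card1)
#' @export
generate_schedule <- function(block_order = c("stable_first", "volatile_first"),
                              seed = NULL, n_per_context = 100) {
  block_order <- match.arg(block_order)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_per_context >= 4, n_per_context %% 4 == 0)

  # stable context: one p_loss for all trials, side randomised
  p_stable <- sample(c(0.75, 0.25), 1)
  p_stable_vec <- rep(p_stable, n_per_context)

  # volatile context: 0.80/0.20 reversing every quarter block (complement
  # taken from the exact pair, not by subtraction, to keep values exact)
  pair <- if (sample(c(TRUE, FALSE), 1)) c(0.80, 0.20) else c(0.20, 0.80)
  seg <- n_per_context / 4
  segs <- rep(c(pair, pair), each = seg)

  if (block_order == "stable_first") {
    p_loss <- c(p_stable_vec, segs)
    context <- rep(c("stable", "volatile"), each = n_per_context)
  } else {
    p_loss <- c(segs, p_stable_vec)
    context <- rep(c("volatile", "stable"), each = n_per_context)
  }
  n <- 2 * n_per_context
  mags <- draw_magnitudes(n)
  correct_card <- ifelse(stats::runif(n) < p_loss, 2L, 1L)
  data.frame(trial = seq_len(n),
             context = context,
             block_order = block_order,
             p_loss_card1 = p_loss,
             mag_card1 = mags$mag_card1,
             mag_card2 = mags$mag_card2,
             correct_card = correct_card,
             stringsAsFactors = FALSE)
}

#' Draw per-trial loss magnitudes
#'
#' Magnitudes for the two cards are independent continuous uniform draws on
#' [1, 5] dollars (rounded to the nearest dollar for on-screen presentation
#' only; the raw values are retained and used throughout). Under this
#' scheme the absolute magnitude difference follows a triangular law on
#' [0, 4] with `P(|d| <= 1) = 7/16` and `P(|d| >= 3) = 1/16`.
#'
#' @param n_trials number of trials (>= 1).
#' @param seed optional integer seed.
#' @return data frame with columns `mag_card1`, `mag_card2`.
#' @export
draw_magnitudes <- function(n_trials, seed = NULL) {
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(mag_card1 = stats::runif(n_trials, 1, 5),
             mag_card2 = stats::runif(n_trials, 1, 5))
}
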