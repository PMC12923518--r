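#' Winsorize extreme outliers
#'
#' Flags values beyond the conventional *extreme*-outlier boxplot fence
#' (above `Q3 + 3 * IQR`, with linear-interpolation / type-7 quartiles) and
#' replaces each by the maximum non-extreme value plus one standard
#' deviation of the non-extreme values, i.e. winsorizes to within one SD of
#' the largest non-extreme observation. Only the upper tail is treated
#' (designed for the right-skewed inverse-temperature estimates). The
#' operation is a no-op when nothing lies beyond the fence, and is
#' idempotent.
#'
#' @param values numeric vector of per-subject parameter estimates
#'   (length >= 4).
#' @return a list: `values` (adjusted vector), `flagged` (data frame with
#'   `index`, `original`, `replacement`; zero rows when nothing was
#'   flagged), `fence`.
#' @examples
#' winsorize_extreme(c(1:10, 100))
#' @export
winsorize_extreme <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 4)
  if (length(unique(values)) == 1L)
    return(list(values = values,
                flagged = data.frame(index = integer(0), original = numeric(0),
                                     replacement = numeric(0)),
                fence = Inf))
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  fence <- q[2] + 3 * (q[2] - q[1])
  extreme <- which(values > fence)
  if (!length(extreme))
    return(list(values = values,
                flagged = data.frame(index = integer(0), original = numeric(0),
                                     replacement = numeric(0)),
                fence = fence))
  keep <- values[-extreme]
  replacement <- max(keep) + stats::sd(keep)
  out <- values
  out[extreme] <- replacement
  list(values = out,
       flagged = data.frame(index = extreme, original = values[extreme],
                            replacement = replacement),
       fence = fence)
}
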