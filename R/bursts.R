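#' Burst sizes from an exit-event stream
#'
#' Consecutive exits separated by less than `gap_threshold` belong to one
#' burst (an uninterrupted run of escapes between clogging intervals); the
#' burst size is the number of events in the maximal run. Sizes are
#' returned in temporal order and always sum to the number of events.
#'
#' @param times exit times (s), sorted non-decreasing.
#' @param gap_threshold time gap (s) that separates bursts, `> 0`.
#' @return Integer vector of burst sizes; empty for empty input.
#' @examples
#' bursts_from_exits(c(0.10, 0.15, 0.18, 1.00, 1.05), 0.5)  # 3 2
#' @export
bursts_from_exits <- function(times, gap_threshold) {
  if (gap_threshold <= 0) stop("gap_threshold must be positive")
  if (length(times) == 0) return(integer(0))
  if (is.unsorted(times)) stop("exit times must be sorted non-decreasing")
  if (length(times) == 1) return(1L)
  breaks <- diff(times) >= gap_threshold
  as.integer(rle(cumsum(c(0, breaks)))$lengths)
}

#' Burst-size frequency distribution
#'
#' Tabulates `F(S)`, the number of bursts of each size, normalized by the
#' iteration count `q` (the number of pooled runs). Sizes with zero count
#' are omitted.
#'
#' @param sizes integer burst sizes.
#' @param q normalization count, `> 0`.
#' @return Data frame with columns `S`, `F` and `F_norm = F / q`.
#' @export
burst_frequency <- function(sizes, q = 1) {
  if (q <= 0) stop("q must be positive")
  if (length(sizes) == 0)
    return(data.frame(S = integer(0), F = integer(0), F_norm = numeric(0)))
  tab <- table(sizes)
  data.frame(S = as.integer(names(tab)), F = as.integer(tab),
             F_norm = as.numeric(tab) / q)
}

#' Log-log linearity of the burst-size distribution
#'
#' Least-squares line through `(log10 S, log10 F(S)/q)`. A negative slope
#' with high coefficient of determination indicates the inverse
#' (power-law-like) relation between evacuation burst scale and its
#' frequency.
#'
#' @param freq data frame from [burst_frequency()] (columns `S`,
#'   `F_norm`); at least three distinct sizes with positive frequency.
#' @return List with `slope`, `intercept` and `r_squared`.
#' @examples
#' loglog_fit(data.frame(S = 1:10, F_norm = (1:10)^-2))$slope  # -2
#' @export
loglog_fit <- function(freq) {
  keep <- freq$F_norm > 0
  if (sum(keep) < 3)
    stop("log-log fit needs at least three sizes with positive frequency")
  lx <- log10(freq$S[keep])
  ly <- log10(freq$F_norm[keep])
  fit <- lm(ly ~ lx)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}
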