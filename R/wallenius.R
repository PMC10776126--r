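#' Wallenius noncentral hypergeometric probability mass function
#'
#' Distribution of the number of "red" items drawn when sampling `n` items
#' one at a time, without replacement, from `m1` red and `m2` white items,
#' each red item having sampling weight `omega` relative to white. Computed
#' exactly by dynamic programming over the draw sequence: after drawing `x`
#' reds in `j` draws, the next draw is red with probability
#' `omega * (m1 - x) / (omega * (m1 - x) + (m2 - (j - x)))`. With
#' `omega = 1` this reduces to the central hypergeometric.
#'
#' This is the biased-urn model behind probe-count-bias-adjusted gene-set
#' testing: genes carrying more array probes are more likely to contain a
#' significant probe by chance alone, so "drawing" hit genes is a weighted
#' sampling process.
#'
#' @param m1 Number of red (in-set) items.
#' @param m2 Number of white (out-of-set) items.
#' @param n Number of draws (`0 <= n <= m1 + m2`).
#' @param omega Odds weight of red items (> 0).
#' @return Numeric vector of `P(X = x)` for `x = 0..min(n, m1)`, named by x.
#' @export
#' @examples
#' all.equal(unname(wallenius_pmf(5, 15, 6, 1)), dhyper(0:5, 5, 15, 6))
wallenius_pmf <- function(m1, m2, n, omega) {
  stopifnot(m1 >= 0, m2 >= 0, n >= 0, n <= m1 + m2, omega > 0)
  x_max <- min(n, m1)
  # prob[x + 1] = P(x reds after j draws)
  prob <- c(1, rep(0, x_max))
  if (n == 0) return(setNames(prob, 0:x_max))
  for (j in seq_len(n)) {
    new <- numeric(x_max + 1)
    up <- min(j - 1, x_max)
    for (x in 0:up) {
      p_state <- prob[x + 1]
      if (p_state == 0) next
      red_left <- m1 - x
      white_left <- m2 - (j - 1 - x)
      tot <- omega * red_left + white_left
      if (tot <= 0) next
      p_red <- omega * red_left / tot
      if (x < x_max && red_left > 0) new[x + 2] <- new[x + 2] + p_state * p_red
      if (white_left > 0) new[x + 1] <- new[x + 1] + p_state * (1 - p_red)
    }
    prob <- new
  }
  setNames(prob, 0:x_max)
}

#' Upper-tail probability of the Wallenius distribution
#'
#' `P(X >= x)` under [wallenius_pmf()]'s model — the one-sided
#' over-representation p-value for a biased urn.
#'
#' @inheritParams wallenius_pmf
#' @param x Observed count.
#' @return `P(X >= x)`.
#' @export
wallenius_upper_tail <- function(x, m1, m2, n, omega) {
  pmf <- wallenius_pmf(m1, m2, n, omega)
  min(1, sum(pmf[as.integer(names(pmf)) >= x]))
}
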