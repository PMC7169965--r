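#' Binomial upper-tail probability
#'
#' `P(X >= x)` for `X ~ Binomial(n, p)`, computed in log space for
#' numerical stability. This is the probability model behind the
#' compositional-bias P-values: the chance of seeing at least `x` target
#' residues in a window of `n` given an expected per-residue frequency `p`.
#'
#' @param x Number of matching residues (vectorised).
#' @param n Window length in residues (vectorised).
#' @param p Expected per-residue frequency, strictly inside (0, 1).
#' @param log10_p If `TRUE`, return `log10` of the tail probability.
#' @return Numeric vector of tail probabilities (or their `log10`).
#' @examples
#' binomial_tail_p(0, 10, 0.05)  # certain event: 1
#' binomial_tail_p(1, 1, 0.05)   # single trial: 0.05
#' @export
binomial_tail_p <- function(x, n, p, log10_p = FALSE) {
  if (any(x < 0) || any(x > n)) {
    stop("x must satisfy 0 <= x <= n", call. = FALSE)
  }
  if (any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  }
  lp <- stats::pbinom(x - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  lp[x == 0] <- 0  # exact: P(X >= 0) = 1
  if (log10_p) lp / log(10) else exp(lp)
}

#' Lowest-binomial-P biased subsequence for a residue set
#'
#' Scans every window whose length lies within `window_bounds` (clipped to
#' the sequence length) and returns the window minimising the binomial
#' upper-tail probability of its count of target residues, given the
#' expected per-residue frequency. For a pooled residue set the expected
#' frequency is the sum of the per-residue expectations (so {Q,N} at 0.05
#' each is scanned at 0.10). Ties are broken towards the leftmost, then
#' shortest window.
#'
#' @param sequence A residue string.
#' @param residues Character vector of target residues, e.g. `"Q"`, `"N"`
#'   or `c("Q", "N")`.
#' @param p_expect Expected fractional frequency per target residue
#'   (default 0.05).
#' @param window_bounds Length-2 numeric `(min, max)` window size in
#'   residues; default `c(15, 500)`. Sequences shorter than the minimum are
#'   scanned with the window clipped to the sequence length.
#' @return A one-row tibble: `residue_set`, `start`, `end`, `x`, `n`,
#'   `log10_p`.
#' @export
scan_lowest_p <- function(sequence, residues = c("Q", "N"),
                          p_expect = 0.05, window_bounds = c(15, 500)) {
  stopifnot(length(window_bounds) == 2, window_bounds[1] >= 1,
            window_bounds[2] >= window_bounds[1])
  s <- clean_sequence(sequence)
  len <- nchar(s)
  if (len == 0) stop("sequence is empty", call. = FALSE)
  p <- p_expect * length(residues)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  ind <- as.integer(chars %in% toupper(residues))
  cs <- c(0L, cumsum(ind))
  l_min <- min(window_bounds[1], len)
  l_max <- min(window_bounds[2], len)
  best <- list(lp = Inf, start = NA_integer_, len = NA_integer_, x = NA_integer_)
  for (L in l_min:l_max) {
    starts <- 1:(len - L + 1)
    x <- cs[starts + L] - cs[starts]
    lp <- binomial_tail_p(x, L, p, log10_p = TRUE)
    i <- which.min(lp)  # leftmost minimum for this length
    if (lp[i] < best$lp) {
      best <- list(lp = lp[i], start = starts[i], len = L, x = x[i])
    } else if (lp[i] == best$lp && starts[i] < best$start) {
      best <- list(lp = lp[i], start = starts[i], len = L, x = x[i])
    }
  }
  tibble::tibble(
    residue_set = paste(unique(toupper(residues)), collapse = ""),
    start = as.integer(best$start),
    end = as.integer(best$start + best$len - 1),
    x = as.integer(best$x),
    n = as.integer(best$len),
    log10_p = best$lp
  )
}

#' Most biased subsequence across Q, N and pooled Q+N
#'
#' Runs [scan_lowest_p()] for the residue sets {Q}, {N} and {Q,N} (the
#' pooled set at twice the per-residue expectation) and returns the result
#' with the lowest `log10_p`. Ties prefer the pooled {Q,N} set, then {Q},
#' then the leftmost interval.
#'
#' @inheritParams scan_lowest_p
#' @return A one-row tibble as from [scan_lowest_p()].
#' @export
best_of_qn <- function(sequence, p_expect = 0.05,
                       window_bounds = c(15, 500)) {
  cand <- dplyr::bind_rows(
    scan_lowest_p(sequence, c("Q", "N"), p_expect, window_bounds),
    scan_lowest_p(sequence, "Q", p_expect, window_bounds),
    scan_lowest_p(sequence, "N", p_expect, window_bounds)
  )
  ## bind order encodes the tie preference QN > Q > N
  best <- which(cand$log10_p == min(cand$log10_p))
  cand[best[1], ]
}

#' Compositional-bias scan over a table of sequences
#'
#' Applies [best_of_qn()] to each sequence and returns one row per
#' sequence; `log10_flps_p` is the log10 binomial P-value of the most
#' biased Q / N / Q+N subsequence.
#'
#' @param records A data frame with `seq_id` and `sequence` columns, or a
#'   named character vector.
#' @inheritParams scan_lowest_p
#' @return A tibble: `seq_id`, `residue_set`, `start`, `end`, `x`, `n`,
#'   `log10_flps_p`.
#' @export
scan_bias <- function(records, p_expect = 0.05, window_bounds = c(15, 500)) {
  records <- as_protein_records(records)
  purrr::map2_dfr(records$sequence, records$seq_id, function(s, id) {
    r <- best_of_qn(s, p_expect, window_bounds)
    tibble::tibble(seq_id = id, r)
  }) |>
    dplyr::rename(log10_flps_p = "log10_p")
}
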