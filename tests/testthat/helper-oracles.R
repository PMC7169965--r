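# Independent brute-force oracles and shared fixtures. Each oracle
# re-derives its quantity from first principles, not through the package's
# computation path.

## Toy parameter set with hand-checkable tables: Q enriched 4x, L depleted
## 4x, everything else identical between states.
toy_params <- function(core_length = 5) {
  fp <- fb <- stats::setNames(rep(1 / 20, 20), prionfam:::AA20)
  fp["Q"] <- 0.20; fb["Q"] <- 0.05
  fp["L"] <- 0.02; fb["L"] <- 0.08
  rest <- setdiff(prionfam:::AA20, c("Q", "L"))
  fp[rest] <- (1 - 0.22) / length(rest)
  fb[rest] <- (1 - 0.13) / length(rest)
  score_params(f_prion = fp, f_background = fb,
               core_length = core_length)
}

## Identity tables: every per-residue LLR is exactly 0.
identity_params <- function(core_length = 5) {
  f <- stats::setNames(rep(1 / 20, 20), prionfam:::AA20)
  score_params(f_prion = f, f_background = f, core_length = core_length)
}

## Per-residue LLR straight from the definition.
oracle_llr_profile <- function(sequence, params) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  vapply(chars, function(a) {
    if (a %in% names(params$f_prion)) {
      log(params$f_prion[[a]] / params$f_background[[a]]) /
        log(params$log_base)
    } else {
      0
    }
  }, numeric(1), USE.NAMES = FALSE)
}

## Exhaustive fixed-window maximum (leftmost window on ties).
oracle_core_window <- function(sequence, params) {
  x <- oracle_llr_profile(sequence, params)
  n <- length(x)
  cl <- params$core_length
  if (n < cl) return(list(score = NA_real_, start = NA, end = NA))
  best <- -Inf; s <- NA
  for (i in 1:(n - cl + 1)) {
    v <- sum(x[i:(i + cl - 1)])
    if (v > best) { best <- v; s <- i }
  }
  list(score = best, start = s, end = s + cl - 1)
}

## Exhaustive enumeration of all runs of length >= core_length with the
## two-state transition terms derived from first principles; ties resolved
## leftmost start, then shortest.
oracle_best_run <- function(sequence, params) {
  x <- oracle_llr_profile(sequence, params)
  n <- length(x)
  cl <- params$core_length
  if (n < cl) return(list(score = NA_real_, start = NA, end = NA))
  lb <- log(params$log_base)
  a_pp <- 1 - 1 / params$prion_run_length
  a_pb <- 1 / params$prion_run_length
  a_bb <- 1 - 1 / params$background_run_length
  a_bp <- 1 / params$background_run_length
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 1:(n - cl + 1)) {
    for (j in (i + cl - 1):n) {
      v <- sum(x[i:j]) + (j - i) * log(a_pp / a_bb) / lb
      if (i > 1) v <- v + log(a_bp / a_bb) / lb
      if (j < n) v <- v + log(a_pb / a_bb) / lb
      if (v > best + 1e-12) { best <- v; bi <- i; bj <- j }
    }
  }
  list(score = best, start = bi, end = bj)
}

## Exact binomial upper tail by direct term summation.
oracle_binom_tail <- function(x, n, p) {
  if (x == 0) return(1)
  k <- x:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

## Exhaustive lowest-tail-probability window over all start/length pairs.
oracle_scan <- function(sequence, residues, p, bounds) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  len <- length(chars)
  ind <- chars %in% residues
  best <- list(lp = Inf, start = NA, end = NA)
  for (L in min(bounds[1], len):min(bounds[2], len)) {
    for (s in 1:(len - L + 1)) {
      x <- sum(ind[s:(s + L - 1)])
      lp <- if (x == 0) 0 else {
        stats::pbinom(x - 1, L, p, lower.tail = FALSE, log.p = TRUE) /
          log(10)
      }
      if (lp < best$lp) best <- list(lp = lp, start = s, end = s + L - 1)
    }
  }
  best
}

## Random test sequence with an optional planted Q/N-rich tract.
random_test_seq <- function(n, tract_at = NULL, tract_len = 0,
                            qn = 0.8) {
  res <- sample(prionfam:::AA20, n, replace = TRUE,
                prob = prionfam:::UNIPROT_BACKGROUND_FREQS)
  if (!is.null(tract_at) && tract_len > 0) {
    idx <- tract_at:(tract_at + tract_len - 1)
    is_qn <- stats::runif(tract_len) < qn
    res[idx][is_qn] <- sample(c("Q", "N"), sum(is_qn), replace = TRUE)
  }
  paste(res, collapse = "")
}

## Truth-derived curated RRM annotations for a generated family.
truth_domains <- function(truth) {
  d <- truth[truth$feature_type == "domain", , drop = FALSE]
  domain_intervals(d$seq_id, d$start, d$end, kind = "RRM",
                   source = "curated")
}
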