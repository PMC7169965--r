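#' @keywords internal
"_PACKAGE"

## Standard amino-acid alphabet (one-letter), fixed ordering used throughout.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ambiguity / non-standard codes scored neutrally (LLR 0).
AA_AMBIG <- c("X", "B", "Z", "U")

## Prion-state amino-acid frequencies: strongly N/Q-enriched composition
## modelled on experimentally characterised yeast prion-forming domains.
PRION_STATE_FREQS <- c(
  A = 0.0488, C = 0.0018, D = 0.0205, E = 0.0234, F = 0.0318,
  G = 0.0895, H = 0.0138, I = 0.0231, K = 0.0255, L = 0.0427,
  M = 0.0139, N = 0.2273, P = 0.0494, Q = 0.2125, R = 0.0215,
  S = 0.0958, T = 0.0434, V = 0.0239, W = 0.0034, Y = 0.0370
)

## Background composition modelled on the S. cerevisiae proteome.
YEAST_BACKGROUND_FREQS <- c(
  A = 0.0552, C = 0.0126, D = 0.0586, E = 0.0655, F = 0.0441,
  G = 0.0498, H = 0.0217, I = 0.0655, K = 0.0735, L = 0.0950,
  M = 0.0207, N = 0.0615, P = 0.0438, Q = 0.0396, R = 0.0445,
  S = 0.0896, T = 0.0592, V = 0.0559, W = 0.0104, Y = 0.0337
)

## Average composition across a broad protein knowledgebase; used as the
## default background for the synthetic-family generator.
UNIPROT_BACKGROUND_FREQS <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0657, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)

#' Validate and normalise an amino-acid frequency table
#'
#' Checks that `freqs` is a numeric vector named by the 20 standard amino
#' acids, applies a pseudocount floor of `1e-6` to every entry, and
#' renormalises so the table sums to exactly 1.
#'
#' @param freqs Named numeric vector over the 20 standard amino acids.
#' @param what Label used in error messages.
#' @return Named numeric vector in the canonical alphabet order, summing to 1.
#' @export
normalize_freqs <- function(freqs, what = "frequency table") {
  if (!is.numeric(freqs) || is.null(names(freqs))) {
    stop(what, " must be a named numeric vector over the 20 amino acids",
         call. = FALSE)
  }
  missing <- setdiff(AA20, names(freqs))
  if (length(missing) > 0) {
    stop(what, " is missing amino acids: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f <- freqs[AA20]
  if (any(!is.finite(f)) || any(f < 0)) {
    stop(what, " must contain finite non-negative values", call. = FALSE)
  }
  if (abs(sum(f) - 1) > 0.05) {
    stop(what, " sums to ", signif(sum(f), 4), "; expected ~1", call. = FALSE)
  }
  f <- pmax(f, 1e-6)
  f / sum(f)
}

#' Scoring parameters for the prion-like composition model
#'
#' Bundles the two amino-acid frequency tables of the two-state model (a
#' prion-like state `f_prion` and a background state `f_background`), the
#' logarithm base of the reported log-likelihood ratios, the minimum core
#' length of a prion-like call, and the expected run lengths of the two
#' states, which set the transition log-odds of the run parse.
#'
#' @param f_prion Named amino-acid frequency vector for the prion-like state.
#' @param f_background Named amino-acid frequency vector for the background
#'   state.
#' @param log_base Base of the reported log-likelihood ratios (default `e`).
#' @param core_length Minimum contiguous run length, in residues, required
#'   for a prion-like call (default 60).
#' @param prion_run_length,background_run_length Expected residence lengths
#'   (residues) of the prion-like and background states; these parameterise
#'   the state-transition probabilities of the run parse.
#' @return An object of class `score_params`.
#' @examples
#' p <- score_params()
#' p$core_length
#' @export
score_params <- function(f_prion = PRION_STATE_FREQS,
                         f_background = YEAST_BACKGROUND_FREQS,
                         log_base = exp(1),
                         core_length = 60,
                         prion_run_length = 100,
                         background_run_length = 100) {
  stopifnot(is.numeric(log_base), length(log_base) == 1, log_base > 1)
  stopifnot(is.numeric(core_length), length(core_length) == 1,
            core_length >= 1)
  stopifnot(prion_run_length > 1, background_run_length > 1)
  fp <- normalize_freqs(f_prion, "f_prion")
  fb <- normalize_freqs(f_background, "f_background")
  structure(
    list(f_prion = fp,
         f_background = fb,
         log_base = log_base,
         core_length = as.integer(core_length),
         prion_run_length = prion_run_length,
         background_run_length = background_run_length),
    class = "score_params"
  )
}

#' @export
print.score_params <- function(x, ...) {
  cat("<score_params>\n")
  cat("  log base:      ", format(x$log_base), "\n")
  cat("  core length:   ", x$core_length, "residues\n")
  cat("  run lengths:   ", x$prion_run_length, "(prion) /",
      x$background_run_length, "(background)\n")
  qn <- sum(x$f_prion[c("Q", "N")])
  cat("  prion-state Q+N:", sprintf("%.3f", qn),
      " background Q+N:",
      sprintf("%.3f", sum(x$f_background[c("Q", "N")])), "\n")
  invisible(x)
}

#' Read scoring parameters from a flat TSV file
#'
#' The file format is three tab-separated columns `param`, `aa`, `value`
#' with 20 `f_prion` rows, 20 `f_background` rows and scalar rows
#' (`aa` empty) for `log_base`, `core_length`, `prion_run_length` and
#' `background_run_length`. The package ships a documented default at
#' `system.file("extdata", "prion_score_params.tsv", package = "prionfam")`.
#'
#' @param path Path to the parameter file.
#' @return A [score_params()] object.
#' @export
read_score_params <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    param = readr::col_character(),
    aa = readr::col_character(),
    value = readr::col_double()
  ))
  pull_table <- function(key) {
    rows <- tab[tab$param == key & !is.na(tab$aa), ]
    stats::setNames(rows$value, rows$aa)
  }
  pull_scalar <- function(key, default) {
    v <- tab$value[tab$param == key & is.na(tab$aa)]
    if (length(v) == 0) default else v[[1]]
  }
  score_params(
    f_prion = pull_table("f_prion"),
    f_background = pull_table("f_background"),
    log_base = pull_scalar("log_base", exp(1)),
    core_length = pull_scalar("core_length", 60),
    prion_run_length = pull_scalar("prion_run_length", 100),
    background_run_length = pull_scalar("background_run_length", 100)
  )
}

#' Write scoring parameters to a flat TSV file
#'
#' @param params A [score_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_params <- function(params, path) {
  stopifnot(inherits(params, "score_params"))
  tab <- dplyr::bind_rows(
    tibble::tibble(param = "f_prion", aa = AA20,
                   value = unname(params$f_prion)),
    tibble::tibble(param = "f_background", aa = AA20,
                   value = unname(params$f_background)),
    tibble::tibble(
      param = c("log_base", "core_length",
                "prion_run_length", "background_run_length"),
      aa = NA_character_,
      value = c(params$log_base, params$core_length,
                params$prion_run_length, params$background_run_length)
    )
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Default scoring parameters shipped with the package
#'
#' Loads the packaged parameter file (N/Q-rich prion-state table versus a
#' budding-yeast-like background, natural log, 60-residue core).
#'
#' @return A [score_params()] object.
#' @export
default_score_params <- function() {
  path <- system.file("extdata", "prion_score_params.tsv",
                      package = "prionfam")
  if (nzchar(path)) read_score_params(path) else score_params()
}
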