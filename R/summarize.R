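#' Fractions of proteins passing the two LLR thresholds
#'
#' For the (optionally filtered) annotation rows, computes the fraction
#' with `best_llr > 0.0` and with `best_llr >= 15.0`, reporting the
#' numerators and denominator alongside display percentages rounded to
#' whole numbers.
#'
#' @param rows A family-annotation tibble with at least `best_llr` (and
#'   optionally `family` and `clade` columns used by the filters).
#' @param family,clade Optional filter values matched against the `family`
#'   / `clade` columns.
#' @return A one-row tibble: `n`, `n_gt0`, `n_ge15`, `fraction_gt0`,
#'   `fraction_ge15`, `pct_gt0`, `pct_ge15`.
#' @export
threshold_fractions <- function(rows, family = NULL, clade = NULL) {
  rows <- filter_rows(rows, family, clade)
  llr <- rows$best_llr
  n <- length(llr)
  n_gt0 <- sum(!is.na(llr) & llr > 0)
  n_ge15 <- sum(!is.na(llr) & llr >= 15)
  tibble::tibble(
    n = n, n_gt0 = n_gt0, n_ge15 = n_ge15,
    fraction_gt0 = n_gt0 / n, fraction_ge15 = n_ge15 / n,
    pct_gt0 = round(100 * n_gt0 / n), pct_ge15 = round(100 * n_ge15 / n)
  )
}

filter_rows <- function(rows, family = NULL, clade = NULL) {
  rows <- tibble::as_tibble(rows)
  if (!is.null(family)) rows <- rows[rows$family %in% family, , drop = FALSE]
  if (!is.null(clade)) rows <- rows[rows$clade %in% clade, , drop = FALSE]
  if (nrow(rows) == 0) stop("no rows after filtering", call. = FALSE)
  rows
}

#' Fraction of proteins with multiple prion-like domains
#'
#' @param rows Annotation tibble with per-protein prion-like domain counts
#'   (`n_prion_at_0`, `n_prion_at_15`).
#' @param threshold Which count column to use: `"0"` (LLR > 0.0) or
#'   `"15"` (LLR >= 15.0).
#' @param family,clade Optional filters as in [threshold_fractions()].
#' @return A one-row tibble: `n`, `n_multi`, `fraction_multi`, `pct_multi`.
#' @export
multi_prion_fraction <- function(rows, threshold = c("0", "15"),
                                 family = NULL, clade = NULL) {
  threshold <- match.arg(threshold)
  rows <- filter_rows(rows, family, clade)
  col <- if (threshold == "0") "n_prion_at_0" else "n_prion_at_15"
  counts <- rows[[col]]
  if (is.null(counts)) stop("rows lack column ", col, call. = FALSE)
  n <- length(counts)
  n_multi <- sum(counts >= 2, na.rm = TRUE)
  tibble::tibble(n = n, n_multi = n_multi,
                 fraction_multi = n_multi / n,
                 pct_multi = round(100 * n_multi / n))
}

#' Distribution of RRM-domain counts
#'
#' Exact integer histogram of the per-protein RRM count, with the number
#' of proteins carrying more than three RRMs attached as attribute
#' `n_above_3`.
#'
#' @param rows Annotation tibble with an `n_rrm` column.
#' @param family,clade Optional filters.
#' @return A tibble `n_rrm`, `count` ordered by `n_rrm`, with attribute
#'   `n_above_3`.
#' @export
rrm_distribution <- function(rows, family = NULL, clade = NULL) {
  rows <- filter_rows(rows, family, clade)
  hist <- rows |>
    dplyr::count(.data$n_rrm, name = "count") |>
    dplyr::arrange(.data$n_rrm)
  attr(hist, "n_above_3") <- sum(rows$n_rrm > 3, na.rm = TRUE)
  hist
}

#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation between two numeric columns, with the
#' two-tailed p-value from the t transform. Rows where either value is
#' missing are dropped pairwise and counted.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble: `r`, `p_value`, `n`, `n_dropped`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in a column", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x), n_dropped = n_dropped)
}

#' Prune a clade or leaf set from a phylogeny
#'
#' Removes either an explicit set of leaves or the whole clade below the
#' most recent common ancestor of a set of leaves, collapsing the unary
#' nodes left behind (their branch lengths are summed), so pairwise path
#' lengths among surviving leaves are preserved.
#'
#' @param tree A rooted `phylo` tree (e.g. from [ape::read.tree()]).
#' @param leaves Character vector of leaf labels to remove (may be empty,
#'   returning the tree unchanged).
#' @param mrca_of Alternative selector: remove the entire clade spanned by
#'   the most recent common ancestor of these leaf labels.
#' @return The pruned `phylo` tree.
#' @export
prune_clade <- function(tree, leaves = NULL, mrca_of = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(leaves) && !is.null(mrca_of)) {
    stop("give either 'leaves' or 'mrca_of', not both", call. = FALSE)
  }
  if (is.null(leaves) && is.null(mrca_of)) {
    stop("give a 'leaves' set or an 'mrca_of' selector", call. = FALSE)
  }
  if (!is.null(mrca_of)) {
    missing <- setdiff(mrca_of, tree$tip.label)
    if (length(missing) > 0) {
      stop("labels not in tree: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (length(mrca_of) == 1) {
      leaves <- mrca_of
    } else {
      node <- ape::getMRCA(tree, mrca_of)
      desc <- ape::extract.clade(tree, node)$tip.label
      leaves <- desc
    }
  }
  leaves <- as.character(leaves)
  if (length(leaves) == 0) return(tree)
  missing <- setdiff(leaves, tree$tip.label)
  if (length(missing) > 0) {
    stop("labels not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(setdiff(tree$tip.label, leaves)) < 2) {
    stop("pruning would leave fewer than 2 leaves", call. = FALSE)
  }
  ape::drop.tip(tree, leaves, collapse.singles = TRUE)
}

#' Family-level summary of annotation rows
#'
#' Computes, overall and per family, the threshold fractions, multi-domain
#' fractions at both thresholds, the internal-extra-domain fraction, the
#' RRM-count histogram and the correlation between the run-parse LLR and
#' the compositional-bias `log10` P-value.
#'
#' @param rows A family-annotation tibble (see [annotate_family()]).
#' @return An object of class `family_summary`; see [tidy.family_summary()]
#'   and [glance.family_summary()].
#' @export
summarize_family <- function(rows) {
  rows <- tibble::as_tibble(rows)
  groups <- c(list(overall = rows),
              split(rows, rows$family))
  per_group <- purrr::imap_dfr(groups, function(g, name) {
    tf <- threshold_fractions(g)
    m0 <- multi_prion_fraction(g, "0")
    m15 <- multi_prion_fraction(g, "15")
    extra0 <- sum(pmax(g$n_prion_at_0 - 1, 0), na.rm = TRUE)
    ## a protein contributes at most its extra-domain count as internal
    internal0 <- sum(pmin(g$n_internal_at_0,
                          pmax(g$n_prion_at_0 - 1, 0)), na.rm = TRUE)
    tibble::tibble(
      group = name, n = tf$n,
      fraction_gt0 = tf$fraction_gt0, fraction_ge15 = tf$fraction_ge15,
      fraction_multi_at_0 = m0$fraction_multi,
      fraction_multi_at_15 = m15$fraction_multi,
      fraction_internal_extra = if (extra0 > 0) internal0 / extra0
                                else NA_real_,
      fraction_rrm3 = mean(g$n_rrm == 3, na.rm = TRUE),
      n_rrm_gt3 = sum(g$n_rrm > 3, na.rm = TRUE)
    )
  })
  cor_llr_bias <- if (!is.null(rows$log10_flps_p) &&
                      sum(stats::complete.cases(
                        rows[, c("best_llr", "log10_flps_p")])) >= 3) {
    ## lower log10 P = stronger bias, so flip sign for a positive r
    pearson_r(rows$best_llr, -rows$log10_flps_p)
  } else {
    NULL
  }
  structure(list(per_group = per_group,
                 rrm_histogram = rrm_distribution(rows),
                 cor_llr_bias = cor_llr_bias,
                 n = nrow(rows)),
            class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat("<family_summary> over", x$n, "proteins\n\n")
  print(x$per_group)
  if (!is.null(x$cor_llr_bias)) {
    cat("\nLLR vs compositional bias (-log10 P): r =",
        sprintf("%.3f", x$cor_llr_bias$r),
        " p =", format(x$cor_llr_bias$p_value, digits = 3),
        " n =", x$cor_llr_bias$n, "\n")
  }
  invisible(x)
}

#' Tidy a family summary into a long tibble
#'
#' @param x A `family_summary` object.
#' @param ... Unused.
#' @return A tibble with one row per group and statistic.
#' @export
tidy.family_summary <- function(x, ...) {
  x$per_group |>
    tidyr::pivot_longer(-c("group", "n"), names_to = "statistic",
                        values_to = "value")
}

#' One-row overview of a family summary
#'
#' @param x A `family_summary` object.
#' @param ... Unused.
#' @return A one-row tibble with the overall fractions and the LLR-bias
#'   correlation.
#' @export
glance.family_summary <- function(x, ...) {
  overall <- x$per_group[x$per_group$group == "overall", ]
  tibble::tibble(
    n = x$n,
    fraction_gt0 = overall$fraction_gt0,
    fraction_ge15 = overall$fraction_ge15,
    fraction_multi_at_0 = overall$fraction_multi_at_0,
    fraction_multi_at_15 = overall$fraction_multi_at_15,
    fraction_rrm3 = overall$fraction_rrm3,
    r_llr_bias = if (is.null(x$cor_llr_bias)) NA_real_
                 else x$cor_llr_bias$r
  )
}

#' Generic tidiers
#'
#' Broom-style generics provided for package result objects.
#' @param x An object.
#' @param ... Method arguments.
#' @name tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Export per-protein annotation rings
#'
#' Writes one TSV per annotation ring (run-parse LLR, disorder
#' percentages, RRM count, prion-like domain counts at both thresholds,
#' compositional-bias log10 P), each keyed by `seq_id`, suitable for
#' generic tree-annotation viewers.
#'
#' @param rows Family-annotation tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_annotation_rings <- function(rows, dir) {
  rows <- tibble::as_tibble(rows)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rings <- c(best_llr = "llr", pct_disorder_a = "disorder_a",
             pct_disorder_b = "disorder_b", n_rrm = "rrm_count",
             n_prion_at_0 = "prion_count_at_0",
             n_prion_at_15 = "prion_count_at_15",
             log10_flps_p = "flps_log10_p")
  rings <- rings[names(rings) %in% names(rows)]
  paths <- purrr::imap_chr(rings, function(fname, col) {
    path <- file.path(dir, paste0("ring_", fname, ".tsv"))
    readr::write_tsv(rows[, c("seq_id", col)], path)
    path
  })
  invisible(unname(paths))
}
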