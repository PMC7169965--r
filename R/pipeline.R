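#' Build the per-protein family-annotation table
#'
#' The end-to-end analysis for one ortholog family: consolidates the
#' domain annotations (greedy overlap reduction), decomposes each protein
#' into buffered inter-domain fragments, scores the whole protein and
#' every fragment with the prion-like run parse, scans each protein for
#' its most biased Q / N / Q+N subsequence, and assembles one annotation
#' row per protein.
#'
#' @param records Protein records (tibble with `seq_id`, `sequence`;
#'   optional `species`, `family`, `clade` columns are carried through).
#' @param domains Domain-interval tibble of curated (and, if already
#'   merged via [extend_annotations()], homology) annotations. Proteins
#'   without annotations are treated as domain-free.
#' @param params A [score_params()] object.
#' @param buffer Fragment buffer in residues (default 10).
#' @param p_expect Expected per-residue Q and N frequency for the bias
#'   scan (default 0.05).
#' @return A tibble with one row per protein: identity columns, `length`,
#'   `best_llr`, `passes_0`, `passes_15`, `n_rrm`, `n_prion_at_0`,
#'   `n_prion_at_15`, `n_internal_at_0`, `log10_flps_p`.
#' @export
annotate_family <- function(records, domains = NULL,
                            params = default_score_params(),
                            buffer = 10, p_expect = 0.05) {
  records <- as_protein_records(records)
  if (is.null(domains)) {
    domains <- tibble::tibble(seq_id = character(), start = integer(),
                              end = integer(), kind = character(),
                              source = character())
  }
  kept <- kept_domains(reduce_overlaps(domains))

  whole <- score_prion(records, params)
  fragments <- decompose_fragments(records, kept, buffer)
  counts <- score_fragments(records, fragments, params) |>
    count_prion_fragments()
  bias <- scan_bias(records, p_expect)
  rrm <- kept |>
    dplyr::filter(.data$kind == "RRM") |>
    dplyr::count(.data$seq_id, name = "n_rrm")

  whole |>
    dplyr::select(-"start", -"end", -"core_score") |>
    dplyr::left_join(rrm, by = "seq_id") |>
    dplyr::left_join(counts, by = "seq_id") |>
    dplyr::left_join(dplyr::select(bias, "seq_id", "log10_flps_p"),
                     by = "seq_id") |>
    dplyr::mutate(
      n_rrm = tidyr::replace_na(.data$n_rrm, 0L),
      n_prion_at_0 = tidyr::replace_na(.data$n_prion_at_0, 0L),
      n_prion_at_15 = tidyr::replace_na(.data$n_prion_at_15, 0L),
      n_internal_at_0 = tidyr::replace_na(.data$n_internal_at_0, 0L)
    )
}
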