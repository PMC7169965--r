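#' Construct a domain-interval table
#'
#' Canonical tibble of domain annotations: 1-based inclusive residue
#' coordinates, a `kind` (`"RRM"` or `"other"`) and a `source`
#' (`"curated"` or `"homology"`).
#'
#' @param seq_id,start,end,kind,source Vectors of equal length (scalars
#'   recycled).
#' @return A tibble with columns `seq_id`, `start`, `end`, `kind`,
#'   `source`.
#' @export
domain_intervals <- function(seq_id, start, end, kind = "RRM",
                             source = "curated") {
  d <- tibble::tibble(seq_id = as.character(seq_id),
                      start = as.integer(start), end = as.integer(end),
                      kind = kind, source = source)
  validate_intervals(d)
  d
}

validate_intervals <- function(d, seq_lengths = NULL) {
  bad <- which(is.na(d$start) | is.na(d$end) | d$start < 1 | d$end < d$start)
  if (length(bad) > 0) {
    stop("invalid domain coordinates for ", d$seq_id[bad[1]],
         " [", d$start[bad[1]], ", ", d$end[bad[1]], "]", call. = FALSE)
  }
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[d$seq_id]
    over <- which(!is.na(len) & d$end > len)
    if (length(over) > 0) {
      stop("domain end exceeds sequence length for ", d$seq_id[over[1]],
           call. = FALSE)
    }
  }
  invisible(d)
}

#' Greedy overlap reduction of domain annotations
#'
#' Sorts annotations in decreasing order of domain length and walks the
#' sorted list, keeping an interval only if it shares no residue with an
#' already-kept interval on the same sequence; all others are flagged.
#' Length ties are broken by earlier start, then curated source over
#' homology, then input order. The input is never mutated.
#'
#' @param annotations A domain-interval tibble (see [domain_intervals()]).
#' @return The input tibble with an added logical column `kept`; flagged
#'   (overlapping) rows have `kept = FALSE`.
#' @examples
#' d <- domain_intervals("s1", c(1, 50, 200), c(100, 120, 250))
#' reduce_overlaps(d)
#' @export
reduce_overlaps <- function(annotations) {
  d <- tibble::as_tibble(annotations)
  validate_intervals(d)
  if (nrow(d) == 0) return(dplyr::mutate(d, kept = logical(0)))
  len <- d$end - d$start + 1
  src_rank <- ifelse(!is.null(d$source) & d$source == "curated", 0L, 1L)
  ord <- order(-len, d$start, src_rank, seq_len(nrow(d)))
  kept <- logical(nrow(d))
  for (split in split(ord, d$seq_id[ord])) {
    kept_rows <- integer(0)
    for (i in split) {
      overlaps <- any(d$start[i] <= d$end[kept_rows] &
                        d$end[i] >= d$start[kept_rows])
      if (!overlaps) {
        kept[i] <- TRUE
        kept_rows <- c(kept_rows, i)
      }
    }
  }
  dplyr::mutate(d, kept = kept)
}

#' Extract the kept (non-overlapping) annotations
#'
#' @param reduced Output of [reduce_overlaps()].
#' @return The kept rows, without the `kept` column, sorted by sequence and
#'   start.
#' @export
kept_domains <- function(reduced) {
  reduced |>
    dplyr::filter(.data$kept) |>
    dplyr::select(-"kept") |>
    dplyr::arrange(.data$seq_id, .data$start)
}

#' Augment domain annotations with homology-derived intervals
#'
#' Each similarity hit against the RRM-domain library with an e-value at or
#' below `evalue_max` contributes a homology-source RRM interval spanning
#' the hit's query coordinates. The result is the curated table plus the
#' new homology intervals, ready for [reduce_overlaps()].
#'
#' @param curated A domain-interval tibble of existing annotations (may be
#'   empty).
#' @param hits A hit table with columns `qseqid` (or `query_id`), `qstart`,
#'   `qend`, `evalue`.
#' @param records Protein records (tibble with `seq_id`, `sequence`) used
#'   to validate hit identifiers and coordinates.
#' @param evalue_max Inclusion threshold on the hit e-value (default
#'   `1e-4`).
#' @return A combined domain-interval tibble.
#' @export
extend_annotations <- function(curated, hits, records, evalue_max = 1e-4) {
  records <- as_protein_records(records)
  hits <- tibble::as_tibble(hits)
  if ("query_id" %in% names(hits) && !("qseqid" %in% names(hits))) {
    hits <- dplyr::rename(hits, qseqid = "query_id")
  }
  need <- c("qseqid", "qstart", "qend", "evalue")
  if (!all(need %in% names(hits))) {
    stop("hit table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(hits$qseqid), records$seq_id)
  if (length(unknown) > 0) {
    stop("hits reference unknown seq_id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keep <- hits$evalue <= evalue_max
  new_iv <- tibble::tibble(
    seq_id = hits$qseqid[keep],
    start = as.integer(hits$qstart[keep]),
    end = as.integer(hits$qend[keep]),
    kind = "RRM",
    source = "homology"
  )
  lens <- stats::setNames(nchar(records$sequence), records$seq_id)
  validate_intervals(new_iv, lens)
  dplyr::bind_rows(tibble::as_tibble(curated), new_iv)
}

#' Decompose one sequence into buffered inter-domain fragments
#'
#' Splits a sequence into the regions delimited by its kept domain
#' annotations: one fragment before the first domain (`n_terminal`), one
#' between each adjacent pair (`internal`) and one after the last
#' (`c_terminal`). Each fragment is the raw inter-domain gap extended by
#' `buffer` residues into the flanking domain(s) and clipped to the
#' sequence bounds; a zero-length gap between adjacent domains still
#' yields a `2 * buffer` fragment straddling the junction. With no domains
#' the whole sequence is one `n_terminal` fragment.
#'
#' @param seq_length Sequence length in residues.
#' @param kept A tibble of non-overlapping kept domains for this sequence
#'   (columns `start`, `end`), in any order.
#' @param buffer Residues added onto both ends of each fragment
#'   (default 10).
#' @return A tibble: `start`, `end`, `position_class`.
#' @examples
#' fragment_decompose(300, tibble::tibble(start = c(101, 201),
#'                                        end = c(160, 260)))
#' @export
fragment_decompose <- function(seq_length, kept, buffer = 10) {
  stopifnot(seq_length >= 1, buffer >= 0)
  kept <- tibble::as_tibble(kept)
  if (nrow(kept) == 0) {
    return(tibble::tibble(start = 1L, end = as.integer(seq_length),
                          position_class = "n_terminal"))
  }
  kept <- dplyr::arrange(kept, .data$start)
  if (any(kept$start[-1] <= kept$end[-nrow(kept)])) {
    stop("kept domains overlap; run reduce_overlaps() first", call. = FALSE)
  }
  k <- nrow(kept)
  ## raw gaps: before first, between pairs, after last (may be empty)
  raw_start <- c(1L, kept$end + 1L)
  raw_end <- c(kept$start - 1L, as.integer(seq_length))
  cls <- c("n_terminal", rep("internal", max(k - 1, 0)), "c_terminal")
  ## buffer extends into flanking domains only (not past sequence termini)
  buf_start <- raw_start - ifelse(seq_along(raw_start) > 1, buffer, 0L)
  buf_end <- raw_end + ifelse(seq_along(raw_end) < k + 1, buffer, 0L)
  out <- tibble::tibble(
    start = pmax(1L, as.integer(buf_start)),
    end = pmin(as.integer(seq_length), as.integer(buf_end)),
    position_class = cls
  )
  dplyr::filter(out, .data$end >= .data$start)
}

#' Fragment decomposition over a table of sequences
#'
#' @param records Protein records (`seq_id`, `sequence`).
#' @param kept Kept domain-interval tibble across sequences.
#' @param buffer Buffer residues (default 10).
#' @return A tibble: `seq_id`, `fragment_id`, `start`, `end`,
#'   `position_class`.
#' @export
decompose_fragments <- function(records, kept, buffer = 10) {
  records <- as_protein_records(records)
  kept <- tibble::as_tibble(kept)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    id <- records$seq_id[i]
    fr <- fragment_decompose(nchar(records$sequence[i]),
                             kept[kept$seq_id == id, , drop = FALSE],
                             buffer)
    tibble::tibble(seq_id = id,
                   fragment_id = paste0(id, "_f", seq_len(nrow(fr))),
                   fr)
  })
}

#' Score fragments for prion-like composition
#'
#' Extracts each fragment's subsequence and applies the run parse
#' ([map_parse_llr()]); fragments shorter than the core length carry the
#' "no domain" sentinel.
#'
#' @param records Protein records (`seq_id`, `sequence`).
#' @param fragments Fragment tibble from [decompose_fragments()].
#' @param params A [score_params()] object.
#' @return The fragment tibble with `best_llr`, `passes_0`, `passes_15`
#'   columns added.
#' @export
score_fragments <- function(records, fragments,
                            params = default_score_params()) {
  records <- as_protein_records(records)
  seqs <- stats::setNames(records$sequence, records$seq_id)
  scores <- purrr::map_dfr(seq_len(nrow(fragments)), function(i) {
    sub <- substr(seqs[[fragments$seq_id[i]]],
                  fragments$start[i], fragments$end[i])
    map_parse_llr(sub, params)[, c("best_llr", "passes_0", "passes_15")]
  })
  dplyr::bind_cols(tibble::as_tibble(fragments), scores)
}

#' Count prion-like fragments per protein
#'
#' Counts, for each sequence, the fragments whose run-parse score passes
#' each threshold (`> 0.0` and `>= 15.0`), and the internal fragments
#' passing the lower threshold.
#'
#' @param scored_fragments Output of [score_fragments()] (needs `seq_id`,
#'   `position_class`, `passes_0`, `passes_15`).
#' @return A tibble: `seq_id`, `n_prion_at_0`, `n_prion_at_15`,
#'   `n_internal_at_0`.
#' @export
count_prion_fragments <- function(scored_fragments) {
  scored_fragments |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::summarise(
      n_prion_at_0 = sum(.data$passes_0),
      n_prion_at_15 = sum(.data$passes_15),
      n_internal_at_0 = sum(.data$passes_0 &
                              .data$position_class == "internal"),
      .groups = "drop"
    )
}
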