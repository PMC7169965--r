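#' Normalise a similarity hit table
#'
#' Accepts either outfmt-6-style column names (`qseqid`, `sseqid`,
#' `evalue`, `bitscore`, ...) or the canonical `query_id` / `subject_id`
#' names, and returns a tibble with at least `query_id`, `subject_id`,
#' `evalue`, `bitscore` (plus `query_coverage` when present or derivable
#' from `qstart`/`qend` and a query-length table).
#'
#' @param hits A data frame of similarity hits.
#' @param query_lengths Optional named vector (or tibble with `seq_id`,
#'   `length`) of query sequence lengths, used to derive `query_coverage`
#'   as aligned query span / query length.
#' @return A tibble of hits with canonical column names.
#' @export
as_hit_table <- function(hits, query_lengths = NULL) {
  h <- tibble::as_tibble(hits)
  ren <- c(query_id = "qseqid", subject_id = "sseqid")
  for (i in seq_along(ren)) {
    if (ren[[i]] %in% names(h) && !(names(ren)[i] %in% names(h))) {
      names(h)[names(h) == ren[[i]]] <- names(ren)[i]
    }
  }
  need <- c("query_id", "subject_id", "evalue", "bitscore")
  if (!all(need %in% names(h))) {
    stop("hit table must provide columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!("query_coverage" %in% names(h)) && !is.null(query_lengths) &&
      all(c("qstart", "qend") %in% names(h))) {
    if (is.data.frame(query_lengths)) {
      query_lengths <- stats::setNames(query_lengths$length,
                                       query_lengths$seq_id)
    }
    h$query_coverage <- (abs(h$qend - h$qstart) + 1) /
      unname(query_lengths[h$query_id])
  }
  if ("query_coverage" %in% names(h)) {
    if (any(is.na(h$query_coverage)) ||
        any(h$query_coverage < 0 | h$query_coverage > 1)) {
      stop("query_coverage must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(h$evalue < 0)) stop("evalue must be >= 0", call. = FALSE)
  h
}

## Unique best subject per query by bitscore; queries whose top bitscore is
## tied between subjects are dropped (disqualified).
unique_best_hits <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(query_id = character(),
                          subject_id = character()))
  }
  hits |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$bitscore == max(.data$bitscore)) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("query_id", "subject_id")
}

#' Reciprocal-best-hit ortholog pairs
#'
#' Given similarity tables for proteome A searched against proteome B and
#' vice versa, returns the pairs `(a, b)` such that `b` is `a`'s unique
#' best subject by bitscore in the A-vs-B table and `a` is `b`'s unique
#' best subject in the B-vs-A table. Queries whose best bitscore is tied
#' between several subjects are disqualified.
#'
#' @param hits_ab,hits_ba Hit tables (see [as_hit_table()]).
#' @return A tibble with columns `id_a`, `id_b`, sorted by `id_a`.
#' @export
rbh_pairs <- function(hits_ab, hits_ba) {
  ab <- unique_best_hits(as_hit_table(hits_ab))
  ba <- unique_best_hits(as_hit_table(hits_ba))
  out <- dplyr::inner_join(
    ab, ba,
    by = c(query_id = "subject_id", subject_id = "query_id")
  )
  tibble::tibble(id_a = out$query_id, id_b = out$subject_id) |>
    dplyr::arrange(.data$id_a)
}

#' Reference identifier sets for the paralog sieve
#'
#' The three curated ortholog sets the comparative filter discriminates
#' between: the Pub1/Tia1 family, the Nam8/Ngr1 family, and the Pab1
#' outgroup. The sets must be pairwise disjoint.
#'
#' @param pub1_ids,nam8_ids,pab1_ids Character vectors of identifiers.
#' @return An object of class `reference_sets`.
#' @export
reference_sets <- function(pub1_ids, nam8_ids, pab1_ids) {
  sets <- list(pub1_ids = unique(as.character(pub1_ids)),
               nam8_ids = unique(as.character(nam8_ids)),
               pab1_ids = unique(as.character(pab1_ids)))
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  for (p in pairs) {
    shared <- intersect(sets[[p[1]]], sets[[p[2]]])
    if (length(shared) > 0) {
      stop(p[1], " and ", p[2], " share identifiers: ",
           paste(utils::head(shared, 3), collapse = ", "), call. = FALSE)
    }
  }
  structure(sets, class = "reference_sets")
}

#' Cross-reference identifiers against RBH orthology and reference proteomes
#'
#' Flags each input identifier by whether it is an RBH ortholog and keeps
#' only identifiers drawn from the reference proteomes; identifiers outside
#' the reference proteomes are excluded from downstream family tables.
#'
#' @param ids Character vector of ortholog-set identifiers.
#' @param rbh_set A tibble from [rbh_pairs()] or a character vector of RBH
#'   identifiers.
#' @param reference_proteome_ids Character vector of identifiers present in
#'   the reference proteomes.
#' @return A tibble with one row per retained identifier: `seq_id`,
#'   `in_reference_proteome`, `is_rbh_ortholog`.
#' @export
cross_reference <- function(ids, rbh_set, reference_proteome_ids) {
  if (is.data.frame(rbh_set)) rbh_set <- c(rbh_set$id_a, rbh_set$id_b)
  tibble::tibble(seq_id = as.character(ids)) |>
    dplyr::mutate(
      in_reference_proteome = .data$seq_id %in% reference_proteome_ids,
      is_rbh_ortholog = .data$seq_id %in% rbh_set
    ) |>
    dplyr::filter(.data$in_reference_proteome)
}

#' Comparative paralog sieve
#'
#' Labels a proteome sequence a candidate paralog of the Pub1/Tia1 or
#' Nam8/Ngr1 families when it has at least one significant match (e-value
#' at or below `evalue_max`, covering more than `min_coverage` of the
#' query) against the combined reference sets, and its best such hit (by
#' bitscore, with lower e-value breaking ties; an unresolved tie excludes
#' the query) is to a Pub1/Tia1 or Nam8/Ngr1 sequence rather than a Pab1
#' sequence. Sequences already in any reference set are never returned.
#'
#' @param self_hits Hit table of proteome sequences searched against the
#'   reference sets; must carry `query_coverage` (see [as_hit_table()]).
#' @param refs A [reference_sets()] object.
#' @param evalue_max Significance threshold (default `1e-4`).
#' @param min_coverage Strict lower bound on query coverage (default 0.5).
#' @return A tibble of candidate paralogs: `seq_id`, `best_subject`,
#'   `best_set`, `evalue`, `bitscore`, `query_coverage`.
#' @export
paralog_sieve <- function(self_hits, refs, evalue_max = 1e-4,
                          min_coverage = 0.5) {
  stopifnot(inherits(refs, "reference_sets"))
  h <- as_hit_table(self_hits)
  if (!("query_coverage" %in% names(h))) {
    stop("self_hits must carry query_coverage", call. = FALSE)
  }
  all_ref <- unlist(refs, use.names = FALSE)
  target_ids <- c(refs$pub1_ids, refs$nam8_ids)
  qual <- h |>
    dplyr::filter(.data$evalue <= evalue_max,
                  .data$query_coverage > min_coverage,
                  !(.data$query_id %in% all_ref),
                  .data$subject_id %in% all_ref)
  if (nrow(qual) == 0) {
    return(tibble::tibble(seq_id = character(), best_subject = character(),
                          best_set = character(), evalue = numeric(),
                          bitscore = numeric(), query_coverage = numeric()))
  }
  best <- qual |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$bitscore == max(.data$bitscore)) |>
    dplyr::filter(.data$evalue == min(.data$evalue)) |>
    dplyr::filter(dplyr::n() == 1) |>  # unresolved best-hit tie: excluded
    dplyr::ungroup()
  best |>
    dplyr::filter(.data$subject_id %in% target_ids) |>
    dplyr::transmute(
      seq_id = .data$query_id,
      best_subject = .data$subject_id,
      best_set = ifelse(.data$subject_id %in% refs$pub1_ids,
                        "pub1", "nam8"),
      evalue = .data$evalue,
      bitscore = .data$bitscore,
      query_coverage = .data$query_coverage
    ) |>
    dplyr::arrange(.data$seq_id)
}
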