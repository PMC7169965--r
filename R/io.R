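#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with `seq_id` (first whitespace-delimited token of the
#'   header) and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    seq_id = sub("\\s.*$", "", names(aa)),
    sequence = unname(as.character(aa))
  )
}

#' Write protein records to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param records Protein records (tibble with `seq_id`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  records <- as_protein_records(records)
  aa <- Biostrings::AAStringSet(stats::setNames(records$sequence,
                                                records$seq_id))
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read a BLAST outfmt-6-style tabular hit file
#'
#' Reads the 12 standard columns (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`); a header line is
#' detected and honoured, and any extra columns (e.g. `query_coverage`)
#' are kept.
#'
#' @param path Path to the TSV file.
#' @return A tibble of hits.
#' @export
read_hit_table <- function(path) {
  std <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
           "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  first <- readLines(path, n = 1)
  has_header <- grepl("qseqid|query_id", first)
  if (has_header) {
    readr::read_tsv(path, col_types = readr::cols())
  } else {
    readr::read_tsv(path, col_names = std, col_types = readr::cols())
  }
}

#' Write a hit table as outfmt-6-style TSV
#'
#' @param hits Hit tibble (e.g. from [generate_hit_table()]).
#' @param path Output path.
#' @param header Write a header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, header = TRUE) {
  readr::write_tsv(tibble::as_tibble(hits), path, col_names = header)
  invisible(path)
}

#' Read a domain-annotation table
#'
#' Expects tab-separated columns `seq_id`, `start`, `end` and optionally
#' `kind` and `source` (defaulted to `"RRM"` / `"curated"`). Coordinates
#' are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A domain-interval tibble.
#' @export
read_domain_table <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols())
  if (!("kind" %in% names(d))) d$kind <- "RRM"
  if (!("source" %in% names(d))) d$source <- "curated"
  domain_intervals(d$seq_id, d$start, d$end, d$kind, d$source)
}

#' Read a per-protein family-annotation table
#'
#' Maps column headers through a documented alias table so tables written
#' with the historical supplementary-style headers load onto the
#' package's canonical names (`seq_id`, `family`, `best_llr`,
#' `n_prion_at_0`, `n_prion_at_15`, `n_internal_at_0`, `n_rrm`,
#' `pct_disorder_a`, `pct_disorder_b`, `log10_flps_p`).
#'
#' @param path Path to the TSV file.
#' @return A tibble of annotation rows.
#' @export
read_family_annotations <- function(path) {
  aliases <- c(
    seq_id = "seq_id", id = "seq_id", protein = "seq_id",
    family = "family", clade = "clade", species = "species",
    best_llr = "best_llr", llr = "best_llr", plaac_llr = "best_llr",
    n_prion_at_0 = "n_prion_at_0", prion_domains_gt0 = "n_prion_at_0",
    n_prion_at_15 = "n_prion_at_15", prion_domains_ge15 = "n_prion_at_15",
    n_internal_at_0 = "n_internal_at_0",
    n_rrm = "n_rrm", rrm_count = "n_rrm",
    pct_disorder_a = "pct_disorder_a", iupred_pct = "pct_disorder_a",
    pct_disorder_b = "pct_disorder_b", disopred_pct = "pct_disorder_b",
    log10_flps_p = "log10_flps_p", flps_log10_p = "log10_flps_p"
  )
  d <- readr::read_tsv(path, col_types = readr::cols())
  hit <- tolower(names(d)) %in% names(aliases)
  names(d)[hit] <- unname(aliases[tolower(names(d))[hit]])
  tibble::as_tibble(d)
}

#' Write a per-protein family-annotation table
#'
#' @param rows Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_annotations <- function(rows, path) {
  readr::write_tsv(tibble::as_tibble(rows), path)
  invisible(path)
}
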