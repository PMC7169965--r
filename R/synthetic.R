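## Fixed 80-residue RRM-like consensus used as the conserved core of every
## planted domain; mutated per copy at the spec'd mutation rate.
RRM_CONSENSUS <- paste0(
  "KLFVGGLSWETTEKELRDHFSQFGEVVDCVVMRDPNTKRSRGFGFVTYS",
  "SVEEVDAAMNARPHKVDGRVVEPKRAVSRE"
)

## Run an expression with a locally seeded RNG, restoring the caller's RNG
## state afterwards; all generator randomness flows through this.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic ortholog family
#'
#' Describes the ground-truth architecture the generator plants in every
#' sequence: a number of conserved ~80-residue RRM-like domains separated
#' by i.i.d. background linkers, plus zero or more N/Q-enriched tracts of
#' tunable length and enrichment, placed in terminal and/or internal
#' linkers.
#'
#' @param n_sequences Number of sequences (default 100, the scale of the
#'   study's ortholog families).
#' @param n_domains_range Integer interval for the number of planted
#'   domains per sequence (default `c(3, 3)`: the conserved three-RRM
#'   scaffold).
#' @param domain_length Planted domain length in residues (default 80).
#' @param linker_length_range Integer interval for linker lengths
#'   (default `c(60, 120)`).
#' @param prion_tracts_per_seq Integer interval for the number of planted
#'   N/Q tracts per sequence (default `c(1, 1)`).
#' @param tract_length Planted tract length in residues (default 60).
#' @param tract_qn_fraction Target Q+N fraction inside planted tracts
#'   (default 0.7, in the range of characterised yeast prion domains).
#' @param tract_placement `"terminal"`, `"internal"` or `"mixed"`:
#'   which linkers may receive tracts. Internal linkers are flanked by
#'   planted domains on both sides.
#' @param background_freqs Amino-acid frequency table for linkers and
#'   non-Q/N tract residues (default: knowledgebase-average composition).
#' @param mutation_rate Per-site substitution probability applied to the
#'   domain consensus (default 0.1).
#' @param family_label Family tag stamped on the records (default
#'   `"Pub1/Tia1"`).
#' @param seed Integer seed; identical specs produce byte-identical
#'   output.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(n_sequences = 100,
                        n_domains_range = c(3, 3),
                        domain_length = 80,
                        linker_length_range = c(60, 120),
                        prion_tracts_per_seq = c(1, 1),
                        tract_length = 60,
                        tract_qn_fraction = 0.7,
                        tract_placement = c("terminal", "internal", "mixed"),
                        background_freqs = UNIPROT_BACKGROUND_FREQS,
                        mutation_rate = 0.1,
                        family_label = "Pub1/Tia1",
                        seed = 1) {
  tract_placement <- match.arg(tract_placement)
  stopifnot(n_sequences >= 0,
            length(n_domains_range) == 2,
            n_domains_range[1] >= 0,
            n_domains_range[2] >= n_domains_range[1],
            domain_length >= 1,
            length(linker_length_range) == 2,
            linker_length_range[1] >= 0,
            linker_length_range[2] >= linker_length_range[1],
            length(prion_tracts_per_seq) == 2,
            prion_tracts_per_seq[1] >= 0,
            prion_tracts_per_seq[2] >= prion_tracts_per_seq[1],
            tract_length >= 1,
            tract_qn_fraction >= 0, tract_qn_fraction <= 1,
            mutation_rate >= 0, mutation_rate < 1)
  bg <- normalize_freqs(background_freqs, "background_freqs")
  if (prion_tracts_per_seq[2] > 0 &&
      tract_qn_fraction < sum(bg[c("Q", "N")])) {
    stop("tract_qn_fraction must be at least the background Q+N frequency (",
         signif(sum(bg[c("Q", "N")]), 3), ") when tracts are planted",
         call. = FALSE)
  }
  spec <- structure(
    list(n_sequences = as.integer(n_sequences),
         n_domains_range = as.integer(n_domains_range),
         domain_length = as.integer(domain_length),
         linker_length_range = as.integer(linker_length_range),
         prion_tracts_per_seq = as.integer(prion_tracts_per_seq),
         tract_length = as.integer(tract_length),
         tract_qn_fraction = tract_qn_fraction,
         tract_placement = tract_placement,
         background_freqs = bg,
         mutation_rate = mutation_rate,
         family_label = family_label,
         seed = as.integer(seed)),
    class = "family_spec"
  )
  check_spec_feasible(spec)
  spec
}

## A spec is infeasible when even the most permissive architecture cannot
## host the requested number of tracts (one tract per eligible linker).
check_spec_feasible <- function(spec) {
  k_max <- spec$n_domains_range[2]
  eligible <- switch(spec$tract_placement,
    terminal = if (k_max >= 1) 2L else 1L,
    internal = max(k_max - 1L, 0L),
    mixed = k_max + 1L
  )
  if (spec$prion_tracts_per_seq[1] > eligible) {
    stop("infeasible spec: ", spec$prion_tracts_per_seq[1],
         " tract(s) requested but at most ", eligible, " ",
         spec$tract_placement, " linker position(s) exist", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.family_spec <- function(x, ...) {
  cat("<family_spec>", x$n_sequences, "sequences,",
      paste(x$n_domains_range, collapse = "-"), "domains x",
      x$domain_length, "aa,",
      paste(x$prion_tracts_per_seq, collapse = "-"),
      sprintf("tract(s) x %d aa (Q+N %.2f, %s), seed %d\n",
              x$tract_length, x$tract_qn_fraction, x$tract_placement,
              x$seed))
  invisible(x)
}

draw_background <- function(n, freqs) {
  if (n == 0) return("")
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs),
        collapse = "")
}

draw_tract <- function(n, qn_fraction, freqs) {
  is_qn <- stats::runif(n) < qn_fraction
  res <- character(n)
  res[is_qn] <- sample(c("Q", "N"), sum(is_qn), replace = TRUE)
  non_qn <- freqs[setdiff(names(freqs), c("Q", "N"))]
  res[!is_qn] <- sample(names(non_qn), sum(!is_qn), replace = TRUE,
                        prob = non_qn)
  paste(res, collapse = "")
}

mutate_consensus <- function(consensus, length_out, rate, freqs) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  if (length_out <= length(chars)) {
    chars <- chars[seq_len(length_out)]
  } else {
    extra <- strsplit(draw_background(length_out - length(chars), freqs),
                      "", fixed = TRUE)[[1]]
    chars <- c(chars, extra)
  }
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(names(freqs), sum(hit), replace = TRUE,
                         prob = freqs)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic ortholog family with known ground truth
#'
#' Builds `n_sequences` proteins, each a chain of background linkers and
#' mutated copies of a fixed RRM-like consensus, with N/Q-enriched tracts
#' inserted into eligible linkers. Every planted feature is recorded in
#' the truth table; residues outside planted features are i.i.d. draws
#' from the background table. Output is deterministic under the spec's
#' seed.
#'
#' @param spec A [family_spec()].
#' @return A list with `records` (tibble: `seq_id`, `species`, `family`,
#'   `sequence`) and `truth` (tibble: `seq_id`, `feature_type`
#'   (`"domain"`/`"tract"`), `start`, `end`, `class`).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  if (spec$n_sequences == 0) {
    return(list(
      records = tibble::tibble(seq_id = character(), species = character(),
                               family = character(), sequence = character()),
      truth = tibble::tibble(seq_id = character(), feature_type = character(),
                             start = integer(), end = integer(),
                             class = character())
    ))
  }
  with_local_seed(spec$seed, {
    out <- purrr::map(seq_len(spec$n_sequences), function(k) {
      generate_one_sequence(spec, k)
    })
    list(records = purrr::map_dfr(out, "record"),
         truth = purrr::map_dfr(out, "truth"))
  })
}

generate_one_sequence <- function(spec, k) {
  id <- sprintf("syn%04d", k)
  rng_int <- function(range) {
    if (range[1] == range[2]) range[1]
    else sample(range[1]:range[2], 1)
  }
  n_dom <- rng_int(spec$n_domains_range)
  n_tract <- rng_int(spec$prion_tracts_per_seq)
  linker_len <- vapply(seq_len(n_dom + 1), function(i) {
    rng_int(spec$linker_length_range)
  }, integer(1))

  ## linker i sits before domain i; linker n_dom+1 is C-terminal
  eligible <- switch(spec$tract_placement,
    terminal = unique(c(1L, n_dom + 1L)),
    internal = if (n_dom >= 2) 2:n_dom else integer(0),
    mixed = seq_len(n_dom + 1L)
  )
  if (n_tract > length(eligible)) {
    stop("infeasible architecture for ", id, ": ", n_tract,
         " tract(s) but only ", length(eligible),
         " eligible linker(s)", call. = FALSE)
  }
  tract_linkers <- if (n_tract > 0) {
    sort(sample(eligible, n_tract))
  } else {
    integer(0)
  }

  pieces <- character(0)
  truth <- list()
  pos <- 0L
  linker_class <- function(i) {
    if (i == 1) "n_terminal"
    else if (i == n_dom + 1) "c_terminal"
    else "internal"
  }
  emit_linker <- function(i) {
    len <- linker_len[i]
    if (i %in% tract_linkers) {
      at <- sample.int(len + 1L, 1) - 1L  # tract insertion offset 0..len
      left <- draw_background(at, spec$background_freqs)
      tract <- draw_tract(spec$tract_length, spec$tract_qn_fraction,
                          spec$background_freqs)
      right <- draw_background(len - at, spec$background_freqs)
      truth[[length(truth) + 1]] <<- tibble::tibble(
        seq_id = id, feature_type = "tract",
        start = pos + at + 1L,
        end = pos + at + spec$tract_length,
        class = linker_class(i)
      )
      pieces <<- c(pieces, left, tract, right)
      pos <<- pos + len + spec$tract_length
    } else {
      pieces <<- c(pieces, draw_background(len, spec$background_freqs))
      pos <<- pos + len
    }
  }
  for (i in seq_len(n_dom)) {
    emit_linker(i)
    dom <- mutate_consensus(RRM_CONSENSUS, spec$domain_length,
                            spec$mutation_rate, spec$background_freqs)
    truth[[length(truth) + 1]] <- tibble::tibble(
      seq_id = id, feature_type = "domain",
      start = pos + 1L, end = pos + spec$domain_length,
      class = NA_character_
    )
    pieces <- c(pieces, dom)
    pos <- pos + spec$domain_length
  }
  emit_linker(n_dom + 1L)

  list(
    record = tibble::tibble(seq_id = id,
                            species = sprintf("sp%03d", k),
                            family = spec$family_label,
                            sequence = paste(pieces, collapse = "")),
    truth = if (length(truth) > 0) dplyr::bind_rows(truth)
            else tibble::tibble(seq_id = character(),
                                feature_type = character(),
                                start = integer(), end = integer(),
                                class = character())
  )
}

#' Fabricate similarity hit tables with known downstream truth
#'
#' Builds outfmt-6-style hit tables realising one of three scenarios so
#' the downstream filters can be tested against a known expected answer,
#' which is attached as attribute `expected` (and, for the paralog
#' scenario, the fabricated [reference_sets()] as attribute `refs`).
#'
#' * `"rbh"`: splits the records into two pseudo-proteomes A and B and
#'   plants mutual unique best hits between matched members, plus decoy
#'   hits, one asymmetric pair and one tied-best query (when enough
#'   records are supplied); `expected` is the tibble of reciprocal pairs.
#' * `"paralog"`: treats the records as sieve candidates and fabricates
#'   self-proteome hits against invented Pub1/Nam8/Pab1 reference ids; 2
#'   of every 5 candidates are constructed to prefer the Pub1/Nam8 sets
#'   with qualifying e-value and coverage, the rest prefer Pab1, fail the
#'   coverage bound, or fail the e-value bound; `expected` is the
#'   character vector of planted preferrers.
#' * `"domain_extension"`: emits one hit per planted domain with the true
#'   query coordinates; every third hit gets an e-value above the 1e-4
#'   inclusion threshold; `expected` is the tibble of intervals a
#'   threshold-respecting consumer should add.
#'
#' @param records Records tibble from [generate_family()].
#' @param truth Truth tibble from [generate_family()].
#' @param scenario One of `"rbh"`, `"paralog"`, `"domain_extension"`.
#' @param seed Integer seed.
#' @return A hit tibble with outfmt-6-style columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`) plus `query_coverage` and,
#'   for `"rbh"`, a `table` column (`"ab"`/`"ba"`).
#' @export
generate_hit_table <- function(records, truth, scenario, seed = 1) {
  if (!scenario %in% c("rbh", "paralog", "domain_extension")) {
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  }
  records <- as_protein_records(records)
  if (nrow(records) == 0) stop("records must be non-empty", call. = FALSE)
  with_local_seed(seed, switch(scenario,
    rbh = hit_table_rbh(records),
    paralog = hit_table_paralog(records),
    domain_extension = hit_table_domain_extension(records, truth)
  ))
}

hit_row <- function(q, s, qlen, evalue, bitscore, qstart = 1L,
                    qend = qlen, coverage = (qend - qstart + 1) / qlen) {
  tibble::tibble(
    qseqid = q, sseqid = s,
    pident = round(stats::runif(1, 35, 99), 1),
    length = as.integer(qend - qstart + 1),
    mismatch = as.integer(round((qend - qstart + 1) * 0.2)),
    gapopen = sample.int(5L, 1) - 1L,
    qstart = as.integer(qstart), qend = as.integer(qend),
    sstart = 1L, send = as.integer(qend - qstart + 1),
    evalue = evalue, bitscore = bitscore,
    query_coverage = coverage
  )
}

hit_table_rbh <- function(records) {
  n <- nrow(records)
  half <- n %/% 2
  if (half < 1) stop("rbh scenario needs at least 2 records", call. = FALSE)
  a_ids <- records$seq_id[seq_len(half)]
  b_ids <- records$seq_id[(half + 1):(2 * half)]
  lens <- stats::setNames(nchar(records$sequence), records$seq_id)
  rows <- list()
  expected <- character(0)
  for (i in seq_len(half)) {
    a <- a_ids[i]; b <- b_ids[i]
    asym <- half >= 3 && i == half        # b's best points elsewhere
    tie <- half >= 4 && i == half - 1     # a's best bitscore is tied
    top <- 400 + i
    rows[[length(rows) + 1]] <- dplyr::mutate(
      hit_row(a, b, lens[a], 1e-50, top), table = "ab")
    if (tie) {
      other <- b_ids[if (i == 1) 2 else 1]
      rows[[length(rows) + 1]] <- dplyr::mutate(
        hit_row(a, other, lens[a], 1e-50, top), table = "ab")
    }
    if (asym) {
      other_a <- a_ids[1]
      rows[[length(rows) + 1]] <- dplyr::mutate(
        hit_row(b, other_a, lens[b], 1e-60, top + 50), table = "ba")
      rows[[length(rows) + 1]] <- dplyr::mutate(
        hit_row(b, a, lens[b], 1e-50, top), table = "ba")
    } else {
      rows[[length(rows) + 1]] <- dplyr::mutate(
        hit_row(b, a, lens[b], 1e-50, top), table = "ba")
    }
    ## decoy sub-optimal hits
    if (half >= 2) {
      decoy_b <- b_ids[if (i == 1) half else i - 1]
      rows[[length(rows) + 1]] <- dplyr::mutate(
        hit_row(a, decoy_b, lens[a], 1e-10, top - 100), table = "ab")
    }
    if (!asym && !tie) expected <- c(expected, a)
  }
  out <- dplyr::bind_rows(rows)
  exp_tbl <- tibble::tibble(
    id_a = expected,
    id_b = b_ids[match(expected, a_ids)]
  ) |> dplyr::arrange(.data$id_a)
  attr(out, "expected") <- exp_tbl
  out
}

hit_table_paralog <- function(records) {
  refs <- reference_sets(
    pub1_ids = paste0("PUB1_ref", 1:3),
    nam8_ids = paste0("NAM8_ref", 1:3),
    pab1_ids = paste0("PAB1_ref", 1:3)
  )
  lens <- stats::setNames(nchar(records$sequence), records$seq_id)
  rows <- list()
  expected <- character(0)
  for (i in seq_len(nrow(records))) {
    q <- records$seq_id[i]
    qlen <- lens[q]
    kind <- (i - 1) %% 5
    target <- if (i %% 2 == 0) refs$pub1_ids[1] else refs$nam8_ids[1]
    if (kind <= 1) {
      ## planted preferrer: qualifying hit to Pub1/Nam8, weaker Pab1 hit
      rows[[length(rows) + 1]] <- hit_row(
        q, target, qlen, 1e-20, 300,
        qstart = 1L, qend = as.integer(ceiling(0.8 * qlen)))
      rows[[length(rows) + 1]] <- hit_row(
        q, refs$pab1_ids[1], qlen, 1e-8, 150,
        qstart = 1L, qend = as.integer(ceiling(0.7 * qlen)))
      expected <- c(expected, q)
    } else if (kind == 2) {
      ## prefers Pab1: its qualifying best hit is to the outgroup
      rows[[length(rows) + 1]] <- hit_row(
        q, refs$pab1_ids[1], qlen, 1e-30, 400,
        qstart = 1L, qend = as.integer(ceiling(0.9 * qlen)))
      rows[[length(rows) + 1]] <- hit_row(
        q, target, qlen, 1e-10, 200,
        qstart = 1L, qend = as.integer(ceiling(0.8 * qlen)))
    } else if (kind == 3) {
      ## fails the >50% coverage bound
      rows[[length(rows) + 1]] <- hit_row(
        q, target, qlen, 1e-20, 300,
        qstart = 1L, qend = as.integer(floor(0.4 * qlen)))
    } else {
      ## fails the e-value bound
      rows[[length(rows) + 1]] <- hit_row(
        q, target, qlen, 1e-3, 60,
        qstart = 1L, qend = as.integer(ceiling(0.8 * qlen)))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "expected") <- sort(expected)
  attr(out, "refs") <- refs
  out
}

hit_table_domain_extension <- function(records, truth) {
  doms <- truth[truth$feature_type == "domain", , drop = FALSE]
  if (nrow(doms) == 0) {
    stop("domain_extension scenario needs planted domains in truth",
         call. = FALSE)
  }
  lens <- stats::setNames(nchar(records$sequence), records$seq_id)
  rows <- purrr::map(seq_len(nrow(doms)), function(i) {
    evalue <- if (i %% 3 == 0) 1e-3 else 1e-30  # every 3rd fails threshold
    hit_row(doms$seq_id[i], sprintf("RRMlib_%03d", i),
            lens[doms$seq_id[i]], evalue,
            bitscore = if (evalue <= 1e-4) 180 else 40,
            qstart = doms$start[i], qend = doms$end[i])
  })
  out <- dplyr::bind_rows(rows)
  keep <- out$evalue <= 1e-4
  attr(out, "expected") <- tibble::tibble(
    seq_id = out$qseqid[keep],
    start = out$qstart[keep],
    end = out$qend[keep]
  )
  out
}
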