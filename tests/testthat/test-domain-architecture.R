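test_that("greedy overlap reduction follows the longest-first rule", {
  d <- domain_intervals("s1", c(1, 50, 200), c(100, 120, 250))
  out <- reduce_overlaps(d)
  expect_equal(out$kept, c(TRUE, FALSE, TRUE))

  # single interval: kept as-is
  one <- reduce_overlaps(domain_intervals("s1", 5, 50))
  expect_true(one$kept)

  # two identical intervals: exactly one kept
  two <- reduce_overlaps(domain_intervals("s1", c(10, 10), c(60, 60)))
  expect_equal(sum(two$kept), 1L)

  # same coordinates on different sequences never conflict
  cross <- reduce_overlaps(domain_intervals(c("s1", "s2"), c(1, 1),
                                            c(80, 80)))
  expect_true(all(cross$kept))

  expect_error(reduce_overlaps(tibble::tibble(seq_id = "s1", start = 10,
                                              end = 5)),
               "invalid domain coordinates")
})

test_that("overlap reduction is idempotent and kept sets never overlap", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    start <- sample(1:400, n, replace = TRUE)
    d <- domain_intervals(sample(c("sA", "sB"), n, replace = TRUE),
                          start, start + sample(10:120, n, replace = TRUE))
    out <- reduce_overlaps(d)
    kept <- kept_domains(out)
    # pairwise non-overlap within each sequence
    by_seq <- split(kept, kept$seq_id)
    for (k in by_seq) {
      if (nrow(k) > 1) {
        expect_true(all(k$start[-1] > k$end[-nrow(k)]))
      }
    }
    # every flagged interval overlaps at least one kept interval
    flagged <- out[!out$kept, ]
    for (i in seq_len(nrow(flagged))) {
      same <- kept[kept$seq_id == flagged$seq_id[i], ]
      expect_true(any(flagged$start[i] <= same$end &
                        flagged$end[i] >= same$start))
    }
    # idempotence: re-running on the kept set keeps everything
    expect_true(all(reduce_overlaps(kept)$kept))
  }
})

test_that("homology hits extend annotations at the e-value threshold", {
  recs <- tibble::tibble(seq_id = c("p1", "p2"),
                         sequence = strrep("A", c(300, 300)))
  cur <- domain_intervals("p1", 10, 90)

  # empty hit table adds nothing
  empty <- tibble::tibble(qseqid = character(), qstart = integer(),
                          qend = integer(), evalue = numeric())
  expect_equal(nrow(extend_annotations(cur, empty, recs)), 1L)

  # a hit at e = 1e-3 is excluded (threshold is inclusive at 1e-4)
  h <- tibble::tibble(qseqid = c("p1", "p2", "p2"),
                      qstart = c(100, 5, 150), qend = c(180, 85, 230),
                      evalue = c(1e-3, 1e-4, 1e-20))
  out <- extend_annotations(cur, h, recs)
  expect_equal(nrow(out), 3L)  # 1 curated + 2 passing hits
  added <- out[out$source == "homology", ]
  expect_equal(added$seq_id, c("p2", "p2"))
  expect_equal(added$start, c(5L, 150L))

  # fabricated table: exactly the sub-threshold hits become intervals
  set.seed(3)
  h10 <- tibble::tibble(
    qseqid = rep(c("p1", "p2"), 5),
    qstart = seq(1, 271, by = 30), qend = seq(20, 290, by = 30),
    evalue = c(1e-10, 1e-3, 1e-5, 0.01, 1e-4, 1e-20, 0.5, 1e-6, 2e-4, 1e-8)
  )
  out10 <- extend_annotations(domain_intervals(character(), integer(),
                                               integer()),
                              h10, recs)
  expect_equal(nrow(out10), sum(h10$evalue <= 1e-4))

  expect_error(extend_annotations(cur, tibble::tibble(
    qseqid = "ghost", qstart = 1, qend = 10, evalue = 1e-9), recs),
    "unknown seq_id")
})

test_that("fragment decomposition buffers into flanking domains", {
  kept <- tibble::tibble(start = c(101, 201), end = c(160, 260))
  fr <- fragment_decompose(300, kept, buffer = 10)
  expect_equal(fr$start, c(1L, 151L, 251L))
  expect_equal(fr$end, c(110L, 210L, 300L))
  expect_equal(fr$position_class, c("n_terminal", "internal", "c_terminal"))

  # no domains: the whole sequence is one n-terminal fragment
  none <- fragment_decompose(150, tibble::tibble(start = integer(),
                                                 end = integer()))
  expect_equal(nrow(none), 1L)
  expect_equal(c(none$start, none$end), c(1L, 150L))
  expect_equal(none$position_class, "n_terminal")

  # adjacent domains: the zero-length junction still yields 2*buffer
  adj <- fragment_decompose(200, tibble::tibble(start = c(1, 61),
                                                end = c(60, 120)))
  internal <- adj[adj$position_class == "internal", ]
  expect_equal(c(internal$start, internal$end), c(51L, 70L))
  expect_equal(internal$end - internal$start + 1L, 20L)
})

test_that("unbuffered gaps plus kept domains tile the sequence exactly", {
  set.seed(17)
  for (rep in 1:50) {
    len <- sample(150:600, 1)
    k <- sample(0:4, 1)
    kept <- if (k == 0) {
      tibble::tibble(start = integer(), end = integer())
    } else {
      bounds <- sort(sample(seq_len(len), 2 * k))
      tibble::tibble(start = bounds[seq(1, 2 * k, 2)],
                     end = bounds[seq(2, 2 * k, 2)])
    }
    fr <- fragment_decompose(len, kept, buffer = 0)  # raw gaps
    covered <- sort(c(unlist(purrr::map2(fr$start, fr$end, seq)),
                      unlist(purrr::map2(kept$start, kept$end, seq))))
    expect_equal(covered, seq_len(len))
    # fragment count = kept + 1 when no gap is annihilated
    if (all(c(1, len) %in% covered) && nrow(fr) == nrow(kept) + 1) {
      expect_equal(nrow(fr), nrow(kept) + 1)
    }
  }
})

test_that("prion-like fragments are counted per protein and threshold", {
  scored <- tibble::tibble(
    seq_id = c("a", "a", "a", "b", "b"),
    position_class = c("n_terminal", "internal", "c_terminal",
                       "n_terminal", "c_terminal"),
    best_llr = c(20, 5, -3, NA, -1)
  )
  scored <- dplyr::bind_cols(scored,
                             classify_thresholds(scored$best_llr))
  out <- count_prion_fragments(scored)
  a <- out[out$seq_id == "a", ]
  expect_equal(c(a$n_prion_at_0, a$n_prion_at_15, a$n_internal_at_0),
               c(2L, 1L, 1L))
  b <- out[out$seq_id == "b", ]
  expect_equal(c(b$n_prion_at_0, b$n_prion_at_15), c(0L, 0L))
  # nesting invariant
  expect_true(all(out$n_prion_at_15 <= out$n_prion_at_0))
})

test_that("terminal and internal planted tracts are recovered end-to-end", {
  spec <- family_spec(n_sequences = 6, n_domains_range = c(3, 3),
                      prion_tracts_per_seq = c(2, 2),
                      tract_qn_fraction = 0.9, tract_length = 70,
                      tract_placement = "mixed", seed = 41)
  fam <- generate_family(spec)
  kept <- kept_domains(reduce_overlaps(truth_domains(fam$truth)))
  scored <- score_fragments(fam$records,
                            decompose_fragments(fam$records, kept))
  counts <- count_prion_fragments(scored)
  truth_counts <- fam$truth |>
    dplyr::filter(feature_type == "tract") |>
    dplyr::count(seq_id, name = "n_tracts")
  truth_internal <- fam$truth |>
    dplyr::filter(feature_type == "tract", class == "internal") |>
    dplyr::count(seq_id, name = "n_internal")
  joined <- counts |>
    dplyr::left_join(truth_counts, by = "seq_id") |>
    dplyr::left_join(truth_internal, by = "seq_id") |>
    dplyr::mutate(n_internal = tidyr::replace_na(n_internal, 0L))
  expect_equal(joined$n_prion_at_0, joined$n_tracts)
  expect_equal(joined$n_internal_at_0, joined$n_internal)
})
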