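test_that("per-residue LLR follows the log-ratio definition", {
  p <- toy_params()
  expect_equal(per_residue_llr("Q", p), log(4), tolerance = 1e-12)
  expect_equal(per_residue_llr("L", p), log(0.25), tolerance = 1e-12)
  expect_equal(per_residue_llr("A", identity_params()), 0)
  # ambiguity codes score 0
  expect_equal(per_residue_llr(c("X", "B", "Z", "U"), p), rep(0, 4))
  expect_error(per_residue_llr("J", p), "invalid residue 'J'")
})

test_that("sequence cleaning is case-insensitive and strips stops", {
  expect_identical(clean_sequence("acdQ"), "ACDQ")
  expect_warning(s <- clean_sequence("QQ*NN"), "stop character")
  expect_identical(s, "QQNN")
  expect_error(clean_sequence("QQ1NN"), "position 3")
})

test_that("core window score matches hand-computable cases", {
  p <- toy_params(core_length = 60)
  allq <- strrep("Q", 60)
  r <- core_window_score(allq, p)
  expect_equal(r$core_score, 60 * log(4), tolerance = 1e-9)
  expect_equal(c(r$core_start, r$core_end), c(1L, 60L))

  # identity tables give exactly zero everywhere
  set.seed(11)
  s <- random_test_seq(120)
  expect_equal(core_window_score(s, identity_params(60))$core_score, 0)

  # shorter than the core: a "no score" row, not an error
  short <- core_window_score(strrep("Q", 59), p)
  expect_true(is.na(short$core_score))
})

test_that("core window score equals exhaustive window enumeration", {
  p <- toy_params(core_length = 60)
  set.seed(42)
  for (rep in 1:5) {
    s <- random_test_seq(200, tract_at = 80, tract_len = 50)
    got <- core_window_score(s, p)
    want <- oracle_core_window(s, p)
    expect_equal(got$core_score, want$score, tolerance = 1e-9)
    expect_equal(got$core_start, as.integer(want$start))
  }
})

test_that("run parse equals brute-force run enumeration on short sequences", {
  set.seed(7)
  params_list <- list(toy_params(core_length = 10),
                      default_score_params())
  for (p in params_list) {
    for (rep in 1:4) {
      n <- sample(80:200, 1)
      s <- random_test_seq(n, tract_at = 20, tract_len = 40, qn = 0.7)
      got <- map_parse_llr(s, p)
      want <- oracle_best_run(s, p)
      expect_equal(got$best_llr, want$score, tolerance = 1e-9)
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
    }
  }
})

test_that("run parse finds planted tracts and sets flags per thresholds", {
  p <- default_score_params()
  # all-negative composition: best run exists but passes nothing
  neg <- map_parse_llr(strrep("L", 100), p)
  expect_lt(neg$best_llr, 0)
  expect_false(neg$passes_0)

  # planted high-Q/N tract inside neutral flanks
  spec <- family_spec(n_sequences = 10, tract_qn_fraction = 0.9,
                      tract_length = 80, n_domains_range = c(1, 1),
                      tract_placement = "terminal", seed = 7)
  fam <- generate_family(spec)
  tracts <- fam$truth[fam$truth$feature_type == "tract", ]
  for (i in seq_len(nrow(tracts))) {
    seq <- fam$records$sequence[fam$records$seq_id == tracts$seq_id[i]]
    got <- map_parse_llr(seq, p)
    overlap <- min(got$end, tracts$end[i]) - max(got$start, tracts$start[i]) + 1
    expect_gte(overlap, 50)
    expect_true(got$passes_15)
  }

  # sequences shorter than the core carry the sentinel
  s <- map_parse_llr(strrep("Q", 59), p)
  expect_true(is.na(s$best_llr))
  expect_false(s$passes_0)
  expect_false(s$passes_15)
})

test_that("threshold classification is strict at 0 and inclusive at 15", {
  got <- classify_thresholds(c(15.0, 0.0, 7.3, -2, NA))
  expect_equal(got$passes_0, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(got$passes_15, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # nesting: passing 15 implies passing 0
  expect_true(all(!got$passes_15 | got$passes_0))
})

test_that("raising a residue's LLR never decreases the core window score", {
  p <- toy_params(core_length = 20)
  set.seed(5)
  for (rep in 1:20) {
    s <- random_test_seq(60)
    base <- core_window_score(s, p)$core_score
    # replace a random L (lowest LLR) with Q (highest LLR)
    chars <- strsplit(s, "")[[1]]
    pos <- sample(60, 1)
    chars[pos] <- "Q"
    expect_gte(core_window_score(paste(chars, collapse = ""), p)$core_score,
               base - 1e-12)
  }
})

test_that("prepending neutral residues shifts the interval, not the score", {
  # A has f_P = f_B in this table, so its LLR is exactly 0
  fp <- fb <- stats::setNames(rep(1 / 20, 20), prionfam:::AA20)
  fp["Q"] <- 0.2; fp["N"] <- 0.1
  fp[setdiff(prionfam:::AA20, c("Q", "N", "A"))] <- (1 - 0.35) / 17
  fp["A"] <- fb[["A"]]
  p <- score_params(f_prion = fp, f_background = fb, core_length = 10)
  set.seed(9)
  s <- random_test_seq(80, tract_at = 30, tract_len = 20, qn = 0.9)
  base <- map_parse_llr(s, p)
  shifted <- map_parse_llr(paste0(strrep("A", 25), s), p)
  expect_equal(shifted$best_llr, base$best_llr, tolerance = 1e-9)
  expect_equal(shifted$start - 25L, base$start)
})

test_that("score_prion keeps metadata and scores every record", {
  recs <- tibble::tibble(
    seq_id = c("a", "b"),
    species = c("s1", "s2"),
    sequence = c(strrep("Q", 70), strrep("L", 70))
  )
  out <- score_prion(recs, toy_params(core_length = 60))
  expect_equal(out$seq_id, c("a", "b"))
  expect_equal(out$species, c("s1", "s2"))
  expect_equal(out$length, c(70L, 70L))
  expect_true(out$passes_15[1])
  expect_false(out$passes_0[2])
  expect_error(score_prion(c("QQ")), "named")
})
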