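mk_rows <- function(llr, n0 = 0, n15 = 0, nint = 0, rrm = 3,
                    family = "Pub1/Tia1") {
  tibble::tibble(seq_id = paste0("r", seq_along(llr)), family = family,
                 best_llr = llr, n_prion_at_0 = n0, n_prion_at_15 = n15,
                 n_internal_at_0 = nint, n_rrm = rrm)
}

test_that("threshold fractions count strictly above 0 and inclusively at 15", {
  # 53 of 65 at >= 15 displays as 82%
  rows <- mk_rows(c(rep(20, 53), rep(5, 8), rep(-1, 4)))
  tf <- threshold_fractions(rows)
  expect_equal(tf$n, 65L)
  expect_equal(tf$n_ge15, 53L)
  expect_equal(tf$pct_ge15, 82)
  expect_equal(tf$n_gt0, 61L)
  expect_equal(tf$pct_gt0, 94)

  # scores exactly at 0 pass neither threshold
  zero <- threshold_fractions(mk_rows(rep(0, 10)))
  expect_equal(c(zero$fraction_gt0, zero$fraction_ge15), c(0, 0))

  # simple direct count
  expect_equal(threshold_fractions(mk_rows(c(rep(1, 7), rep(-1, 3))))$fraction_gt0,
               0.7)

  # nesting holds for any rows
  set.seed(8)
  rnd <- mk_rows(stats::rnorm(50, 10, 10))
  tf2 <- threshold_fractions(rnd)
  expect_lte(tf2$fraction_ge15, tf2$fraction_gt0)

  expect_error(threshold_fractions(rows, family = "absent"), "no rows")
})

test_that("multi-domain fractions use the selected threshold column", {
  expect_equal(multi_prion_fraction(mk_rows(rep(20, 10),
                                            n0 = c(rep(1, 9), 0)))$fraction_multi,
               0)
  rows <- mk_rows(rep(20, 50), n0 = c(rep(2, 5), 3, rep(1, 44)))
  expect_equal(multi_prion_fraction(rows, "0")$fraction_multi, 0.12)
  rows15 <- mk_rows(rep(20, 50), n0 = 2, n15 = c(rep(2, 3), rep(0, 47)))
  expect_equal(multi_prion_fraction(rows15, "15")$fraction_multi, 0.06)
})

test_that("RRM histograms are exact and conserve the row count", {
  rows <- mk_rows(rep(1, 5), rrm = c(1, 2, 3, 3, 4))
  h <- rrm_distribution(rows)
  expect_equal(h$n_rrm, c(1, 2, 3, 4))
  expect_equal(h$count, c(1L, 1L, 2L, 1L))
  expect_equal(sum(h$count), nrow(rows))
  expect_equal(attr(h, "n_above_3"), 1L)

  all3 <- rrm_distribution(mk_rows(rep(1, 7)))
  expect_equal(all3$count, 7L)
  expect_equal(attr(all3, "n_above_3"), 0L)
})

test_that("Pearson correlation matches closed-form and sampling checks", {
  perfect <- pearson_r(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perfect$r, 1)
  anti <- pearson_r(c(1, 2, 3), c(6, 4, 2))
  expect_equal(anti$r, -1)

  set.seed(5)
  ind <- pearson_r(stats::rnorm(10000), stats::rnorm(10000))
  expect_lt(abs(ind$r), 0.05)

  # symmetry and self-correlation
  set.seed(6)
  x <- stats::rnorm(30); y <- stats::rnorm(30)
  expect_equal(pearson_r(x, y)$r, pearson_r(y, x)$r)
  expect_equal(pearson_r(x, x)$r, 1)

  # pairwise deletion is counted
  xm <- c(x, NA); ym <- c(y, 1)
  expect_equal(pearson_r(xm, ym)$n_dropped, 1L)

  expect_error(pearson_r(rep(1, 10), stats::rnorm(10)), "zero variance")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

test_that("clade pruning preserves path lengths among survivors", {
  tree <- ape::read.tree(text = "((a:1,b:2):3,(c:4,d:5):6);")

  # prune a cherry: remaining pairwise distance unchanged
  pruned <- prune_clade(tree, leaves = c("c", "d"))
  expect_setequal(pruned$tip.label, c("a", "b"))
  d0 <- ape::cophenetic.phylo(tree)["a", "b"]
  expect_equal(ape::cophenetic.phylo(pruned)["a", "b"], d0,
               tolerance = 1e-9)

  # empty selector: identical tree
  expect_identical(prune_clade(tree, leaves = character(0)), tree)

  # mrca selector removes a whole planted clade
  big <- ape::read.tree(
    text = "(((pab1:1,pab2:1):1,pab3:2):2,((p1:1,p2:1):1,(p3:1,p4:1):1):1);")
  out <- prune_clade(big, mrca_of = c("pab1", "pab3"))
  expect_equal(sum(grepl("^pab", out$tip.label)), 0L)
  expect_setequal(out$tip.label, c("p1", "p2", "p3", "p4"))
  d_before <- ape::cophenetic.phylo(big)[c("p1", "p4"), c("p1", "p4")]
  d_after <- ape::cophenetic.phylo(out)[c("p1", "p4"), c("p1", "p4")]
  expect_equal(d_after, d_before, tolerance = 1e-9)

  expect_error(prune_clade(big, leaves = "ghost"), "not in tree")
  expect_error(prune_clade(big), "selector")
})

test_that("annotation rings round-trip their numeric columns exactly", {
  rows <- tibble::tibble(
    seq_id = c("a", "b", "c"), family = "Pub1/Tia1",
    best_llr = c(12.5, -3.25, 40.125), n_rrm = c(3L, 2L, 3L),
    n_prion_at_0 = c(1L, 0L, 2L), n_prion_at_15 = c(1L, 0L, 1L),
    n_internal_at_0 = 0L,
    pct_disorder_a = c(55.5, 20.25, 70.0)
  )
  dir <- withr::local_tempdir()
  paths <- export_annotation_rings(rows, dir)
  expect_true(all(file.exists(paths)))
  llr_file <- paths[grepl("ring_llr", paths)]
  back <- readr::read_tsv(llr_file, col_types = readr::cols())
  expect_equal(back$best_llr, rows$best_llr)
  expect_equal(back$seq_id, rows$seq_id)

  # empty rows produce headers-only files
  paths0 <- export_annotation_rings(rows[0, ], withr::local_tempdir())
  expect_true(all(vapply(paths0, function(p) length(readLines(p)) == 1,
                         logical(1))))
})

test_that("family summaries aggregate, tidy and glance coherently", {
  rows <- dplyr::bind_rows(
    mk_rows(c(rep(30, 8), rep(5, 1), rep(-2, 1)), family = "Pub1/Tia1",
            n0 = c(rep(2, 1), rep(1, 9))),
    mk_rows(c(rep(20, 5), rep(1, 5)), family = "Nam8/Ngr1",
            n0 = c(rep(2, 2), rep(1, 8)))
  )
  rows$n_prion_at_15 <- pmin(rows$n_prion_at_0,
                             ifelse(rows$best_llr >= 15, 1L, 0L))
  rows$log10_flps_p <- -rows$best_llr / 2 + stats::rnorm(nrow(rows), 0, 0.1)
  s <- summarize_family(rows)
  expect_s3_class(s, "family_summary")
  expect_setequal(s$per_group$group,
                  c("overall", "Pub1/Tia1", "Nam8/Ngr1"))
  overall <- s$per_group[s$per_group$group == "overall", ]
  expect_equal(overall$n, 20L)
  expect_equal(overall$fraction_multi_at_0, 3 / 20)
  expect_gte(overall$fraction_gt0, overall$fraction_ge15)

  td <- tidy(s)
  expect_true(all(c("group", "statistic", "value") %in% names(td)))
  gl <- glance(s)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$fraction_rrm3, 1)
  expect_gt(gl$r_llr_bias, 0.9)  # bias column built anti-linear to the LLR
})
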