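# Index computation, means over replicates, index differences, paired t
# and BH correction.

fake_records <- function(ref_id, unaltered = 0, trimmed = 0, tailed = 0,
                         trimmed_tailed = 0, line_id = "L", replicate_id = "r1") {
  tibble::tibble(
    line_id = line_id, replicate_id = replicate_id,
    sequence = sprintf("S%d", seq_len(4)),
    count = c(unaltered, trimmed, tailed, trimmed_tailed),
    ref_id = ref_id,
    trim_len = c(0L, 3L, 0L, 1L),
    tail_seq = c("", "", "TT", "T"),
    category = c("unaltered", "trimmed", "tailed", "trimmed_tailed")
  ) |> dplyr::filter(count > 0)
}

test_that("indexes count each modified read once, regardless of degree", {
  idx <- compute_indexes(fake_records("M1", unaltered = 8, trimmed = 1, tailed = 1))
  expect_equal(idx$total, 10L)
  expect_equal(idx$trimming_index, 0.1)
  expect_equal(idx$tailing_index, 0.1)

  # a trimmed_tailed read contributes to BOTH numerators
  idx2 <- compute_indexes(fake_records("M1", unaltered = 6, trimmed_tailed = 4))
  expect_equal(idx2$trimming_index, 0.4)
  expect_equal(idx2$tailing_index, 0.4)

  # degree blindness: trim by 5 weighs the same as trim by 1
  rec <- tibble::tibble(
    line_id = "L", replicate_id = "r1",
    sequence = c("a", "b"), count = c(1L, 1L), ref_id = "M1",
    trim_len = c(5L, 1L), tail_seq = "", category = "trimmed"
  )
  idx3 <- compute_indexes(rec)
  expect_equal(idx3$trimming_index, 1)

  # ambiguous/unclassified never enter totals; zero-read miRNAs have no row
  rec_amb <- dplyr::mutate(rec, category = c("ambiguous", "unclassified"),
                           ref_id = NA_character_)
  expect_equal(nrow(compute_indexes(rec_amb)), 0)
})

test_that("category counts partition totals and index numerators are integers", {
  set.seed(31)
  refs <- random_refs(5)
  reads <- purrr::map_dfr(seq_len(nrow(refs)), function(j) {
    m <- refs$sequence[j]
    n <- 50
    t <- sample(0:3, n, replace = TRUE)
    tibble::tibble(sequence = substring(m, 1, nchar(m) - t))
  })
  tab <- dplyr::count(reads, sequence, name = "count") |>
    dplyr::mutate(line_id = "L", replicate_id = "r1")
  cl <- quiet(classify_table(tab, refs))
  idx <- compute_indexes(cl)
  expect_true(all(idx$trimming_index >= 0 & idx$trimming_index <= 1))
  expect_equal(idx$trimming_index * idx$total, round(idx$trimming_index * idx$total))
  cat_tot <- cl |>
    dplyr::filter(category %in% c("unaltered", "trimmed", "tailed", "trimmed_tailed")) |>
    dplyr::count(ref_id, wt = count, name = "n")
  expect_equal(sum(cat_tot$n), sum(idx$total))
})

test_that("means are taken over the replicates where the index is defined", {
  idx <- dplyr::bind_rows(
    fake_records("M1", unaltered = 9, trimmed = 1, replicate_id = "r1") |> compute_indexes(),
    fake_records("M1", unaltered = 7, trimmed = 3, replicate_id = "r2") |> compute_indexes(),
    fake_records("M2", unaltered = 6, trimmed = 4, replicate_id = "r2") |> compute_indexes()
  )
  m <- mean_indexes(idx)
  expect_equal(m$mean_index[m$ref_id == "M1" & m$modification == "trimming"], 0.2)
  # M2 defined in one replicate only: mean over that replicate, n_used = 1
  expect_equal(m$mean_index[m$ref_id == "M2" & m$modification == "trimming"], 0.4)
  expect_equal(m$n_used[m$ref_id == "M2" & m$modification == "trimming"], 1L)
})

test_that("index differences subtract the reference mean, antisymmetrically", {
  a <- tibble::tibble(ref_id = c("M1", "M2"), modification = "trimming",
                      mean_index = c(0.3, 0.5))
  b <- tibble::tibble(ref_id = c("M1", "M2"), modification = "trimming",
                      mean_index = c(0.1, 0.2))
  ids <- index_differences(a, b)
  expect_equal(ids$id_value, c(0.2, 0.3))
  # self-comparison: exactly zero
  expect_equal(index_differences(a, a)$id_value, c(0, 0))
  # swapping line and reference negates every ID
  expect_equal(index_differences(b, a)$id_value, -ids$id_value)
  # only miRNAs defined in both lines are emitted
  ids2 <- index_differences(a, b[1, ])
  expect_equal(ids2$ref_id, "M1")
})

test_that("paired t on the three-pair example reproduces the closed form", {
  lm <- tibble::tibble(ref_id = c("a", "b", "c"), modification = "trimming",
                       mean_index = c(0.10, 0.30, 0.50))
  rm_ <- tibble::tibble(ref_id = c("a", "b", "c"), modification = "trimming",
                        mean_index = c(0.05, 0.20, 0.35))
  res <- paired_index_test(lm, rm_, "trimming")
  expect_equal(res$n_pairs, 3L)
  expect_equal(res$t_stat, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)
  # closed form for df = 2: P(T <= t) = 1/2 + t / (2 sqrt(t^2 + 2))
  t <- res$t_stat
  p_closed <- 2 * (1 - (0.5 + t / (2 * sqrt(t^2 + 2))))
  expect_equal(res$p_value, p_closed, tolerance = 1e-12)
})

test_that("degenerate paired inputs are flagged, not mis-reported", {
  lm <- tibble::tibble(ref_id = letters[1:3], modification = "trimming",
                       mean_index = c(0.1, 0.2, 0.3))
  # identical vectors: zero mean difference, no p
  res0 <- paired_index_test(lm, lm, "trimming")
  expect_true(is.na(res0$p_value))
  expect_equal(res0$note, "degenerate_zero")
  # constant nonzero differences: machine-floor p, flagged
  shifted <- dplyr::mutate(lm, mean_index = mean_index + 0.1)
  res1 <- paired_index_test(shifted, lm, "trimming")
  expect_equal(res1$note, "zero_variance_nonzero_mean")
  expect_lt(res1$p_value, 1e-300)
  # fewer pairs than min_pairs: warned, p absent
  expect_warning(res2 <- paired_index_test(lm[1:2, ], lm[1:2, ], "trimming"),
                 "fewer than min_pairs")
  expect_true(is.na(res2$p_value))
})

test_that("BH correction matches hand-computed examples and groups by modification", {
  res <- tibble::tibble(
    modification = rep("trimming", 4),
    p_value = c(0.01, 0.02, 0.03, 0.04)
  )
  q <- fdr_correct(res)$q_value
  expect_equal(q, rep(0.04, 4))

  expect_equal(fdr_correct(tibble::tibble(modification = "t", p_value = 0.2))$q_value, 0.2)
  expect_equal(
    fdr_correct(tibble::tibble(modification = "t", p_value = c(0.5, 1.0)))$q_value,
    c(1.0, 1.0)
  )

  # trimming and tailing are corrected separately; q >= p always
  mixed <- tibble::tibble(
    modification = c("trimming", "trimming", "tailing"),
    p_value = c(0.01, 0.04, 0.03)
  )
  qm <- fdr_correct(mixed)
  expect_equal(qm$q_value[qm$modification == "tailing"], 0.03)
  expect_true(all(qm$q_value >= qm$p_value))

  # NA p-values stay NA and do not shrink the correction denominator
  withna <- tibble::tibble(modification = "t", p_value = c(0.02, NA, 0.04))
  qn <- fdr_correct(withna)$q_value
  expect_true(is.na(qn[2]))
  expect_equal(qn[c(1, 3)], c(0.04, 0.04))
})

test_that("compare_lines pools FDR across lines and exposes tidy/glance", {
  set.seed(41)
  # two mutant lines vs one reference, built from per-replicate indexes
  mk_idx <- function(line, shift) {
    tidyr::expand_grid(ref_id = sprintf("M%02d", 1:6), replicate_id = c("r1", "r2", "r3")) |>
      dplyr::mutate(
        line_id = line, total = 100L,
        trimming_index = pmin(1, pmax(0, 0.2 + shift + runif(dplyr::n(), -0.03, 0.03))),
        tailing_index = pmin(1, pmax(0, 0.1 + runif(dplyr::n(), -0.03, 0.03)))
      )
  }
  idx <- dplyr::bind_rows(mk_idx("wt", 0), mk_idx("mutA", 0.15), mk_idx("mutB", 0))
  cmp <- compare_lines(idx, c(mutA = "wt", mutB = "wt"))
  expect_s3_class(cmp, "tt_comparison")
  expect_equal(nrow(cmp$tests), 4) # 2 lines x 2 modifications
  expect_equal(sort(unique(cmp$tests$modification)), c("tailing", "trimming"))
  td <- tidy(cmp)
  expect_true(all(c("q_value", "stars") %in% names(td)))
  gl <- glance(cmp)
  expect_equal(gl$n_lines, 2L)
  # elevated line has positive mean ID for trimming
  expect_gt(cmp$tests$mean_id[cmp$tests$line_id == "mutA" &
                                cmp$tests$modification == "trimming"], 0.1)
  expect_error(compare_lines(idx, c(mutA = "absent")), "absent")
})
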