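make_summaries <- function(lengths, rates) {
  maps <- purrr::map2_dfr(names(lengths), rates, function(cc, r) {
    tibble::tibble(chrom = cc, start = 0, end = lengths[[cc]], rate = r)
  })
  chromosome_summary(rate_map(maps), lengths)
}

test_that("size-rate correlation recovers monotone structure", {
  lengths <- c(a = 40e6, b = 30e6, c = 10e6, d = 5e6)
  cs <- make_summaries(lengths, c(1e-8, 2e-8, 3e-8, 4e-8))
  k <- size_rate_correlation(cs)
  expect_equal(k$estimate, -1)

  cs2 <- make_summaries(lengths, rep(2e-8, 4))
  k2 <- size_rate_correlation(cs2)
  expect_true(is.na(k2$estimate))
  expect_equal(k2$note, "zero_variance")

  expect_error(size_rate_correlation(cs[1:2, ]), ">= 3")
})

test_that("micro/macro contrast needs both populated classes", {
  lengths <- c(a = 40e6, b = 30e6, c = 10e6, d = 5e6)
  cs <- make_summaries(lengths, c(1e-8, 1.2e-8, 3e-8, 3.3e-8))
  mm <- micro_macro_contrast(cs)
  expect_gt(mm$ratio, 2)
  expect_equal(mm$n_micro, 2)

  onlymacro <- make_summaries(c(a = 40e6, b = 30e6), c(1e-8, 2e-8))
  expect_error(micro_macro_contrast(onlymacro), "microchromosomes")
  single <- make_summaries(c(a = 40e6, c = 10e6), c(1e-8, 3e-8))
  expect_error(micro_macro_contrast(single), "n >= 2")
})

test_that("distance profiles are flat on constant maps and peak where planted", {
  m <- rate_map(tibble::tibble(chrom = "c", start = 0, end = 2e6,
                               rate = 1e-8))
  anchors <- feature_table(tibble::tibble(
    chrom = "c", start = seq(5e5, 15e5, by = 1e5), category = "TSS",
    end = seq(5e5, 15e5, by = 1e5) + 1, strand = "+",
    id = paste0("t", 1:11)))
  pr <- distance_profile(m, anchors, bin = 5000, span = 50000)
  expect_true(all(abs(pr$mean_rate - 1) < 1e-12))
  expect_equal(nrow(pr), 20)
  expect_equal(attr(pr, "inside_anchor"), 1)

  # rate 10x in [anchor, anchor + 5 kb): maximum at first downstream bin
  pieces <- purrr::map_dfr(seq(5e5, 15e5, by = 1e5), function(a) {
    tibble::tibble(start = a, end = a + 5000, rate = 1e-7)
  })
  rest <- tibble::tibble(start = c(0, seq(5e5, 15e5, by = 1e5) + 5000),
                         end = c(5e5, seq(6e5, 15e5, by = 1e5),
                                 2e6), rate = 1e-8)
  m2 <- rate_map(dplyr::bind_rows(dplyr::mutate(pieces, chrom = "c"),
                                  dplyr::mutate(rest, chrom = "c")))
  pr2 <- distance_profile(m2, anchors, bin = 5000, span = 50000)
  expect_equal(pr2$offset[which.max(pr2$mean_rate)], 2500)
})

test_that("distance profiles respect strand and translation symmetry", {
  set.seed(211)
  m <- random_toy_map(span = 200000, n_pieces = 40, gap_prob = 0.1,
                      chrom = "c")
  pos <- seq(60000, 140000, by = 10000)
  plus <- feature_table(tibble::tibble(chrom = "c", start = pos,
                                       end = pos + 1, strand = "+",
                                       category = "TSS",
                                       id = paste0("p", seq_along(pos))))
  # mirror the whole system about the midpoint 100000
  L <- 200000
  mm <- rate_map(tibble::tibble(chrom = "c", start = L - m$end,
                                end = L - m$start, rate = m$rate))
  minus <- feature_table(tibble::tibble(chrom = "c",
                                        start = L - pos - 1,
                                        end = L - pos, strand = "-",
                                        category = "TSS",
                                        id = paste0("m", seq_along(pos))))
  p1 <- distance_profile(m, plus, bin = 5000, span = 30000)
  p2 <- distance_profile(mm, minus, bin = 5000, span = 30000)
  expect_equal(p2$mean_rate, p1$mean_rate, tolerance = 1e-12)

  shift <- 12345
  ms <- rate_map(tibble::tibble(chrom = "c", start = m$start + shift,
                                end = m$end + shift, rate = m$rate))
  ps <- feature_table(tibble::tibble(chrom = "c", start = pos + shift,
                                     end = pos + shift + 1, strand = "+",
                                     category = "TSS",
                                     id = paste0("s", seq_along(pos))))
  p3 <- distance_profile(ms, ps, bin = 5000, span = 30000)
  expect_equal(p3$mean_rate, p1$mean_rate, tolerance = 1e-12)
})

test_that("flank trends pick up approach slopes around a planted peak", {
  # symmetric tent peaking at the anchor
  offs <- seq(-50000, 45000, by = 5000)
  prof <- tibble::tibble(offset = offs + 2500,
                         mean_rate = 10 - abs(offs + 2500) / 5000,
                         n_anchor = 100, ci_half = 0.1)
  class(prof) <- c("distance_profile", class(prof))
  tr <- profile_flank_trend(prof, flank = 50000)
  expect_equal(tr$tau[tr$side == "upstream"], 1)
  expect_equal(tr$tau[tr$side == "downstream"], -1)

  flat <- dplyr::mutate(prof, mean_rate = 5)
  tr2 <- profile_flank_trend(flat)
  expect_equal(tr2$note, c("zero_variance", "zero_variance"))

  expect_error(profile_flank_trend(prof[0, ]), "empty")
})

test_that("category contrasts flag planted deviations and low n", {
  set.seed(223)
  wins <- tibble::tibble(chrom = "c", start = 0, end = 1,
                         rate = stats::rlnorm(300, 0, 0.3))
  feats <- tibble::tibble(category = rep(c("hot", "null"), each = 40),
                          mean_rate = c(stats::rlnorm(40, log(10), 0.1),
                                        sample(wins$rate, 40)))
  ct <- category_rate_contrast(feats, wins)
  expect_lt(ct$p_adjusted[ct$category == "hot"], 0.001)
  expect_gt(ct$p_adjusted[ct$category == "null"], 0.01)

  single <- tibble::tibble(category = "solo", mean_rate = 3)
  ct2 <- category_rate_contrast(single, wins)
  expect_true(ct2$low_n)
  expect_false(is.na(ct2$p_value))

  allna <- tibble::tibble(category = c("x", "gone"),
                          mean_rate = c(1, NA))
  expect_warning(category_rate_contrast(allna, wins), "gone")
})

test_that("RT-overlap contrasts report empty cells as missing", {
  m <- rate_map(tibble::tibble(chrom = "c", start = 0, end = 1e5,
                               rate = 1e-8))
  feats <- feature_table(tibble::tibble(
    chrom = "c", start = seq(0, 9e4, by = 1e4),
    end = seq(0, 9e4, by = 1e4) + 5000,
    category = "gene", id = paste0("g", 1:10)))
  rts <- feature_table(tibble::tibble(
    chrom = "c", start = c(1000, 21000), end = c(2000, 22000),
    category = c("LINE", "LINE"), id = c("L1", "L2")))
  out <- rt_overlap_contrast(m, feats, rts)
  expect_equal(out$n_with, 2)
  expect_equal(out$n_without, 8)

  rts0 <- feature_table(tibble::tibble(
    chrom = "c", start = 1, end = 2, category = "SINE", id = "S"))
  out2 <- rt_overlap_contrast(m, feats, rts0[0, ])
  expect_equal(nrow(out2), 0)
  # family with zero placements on this chromosome -> all without
  rts3 <- feature_table(tibble::tibble(
    chrom = "other", start = 1, end = 2, category = "SINE", id = "S"))
  out3 <- rt_overlap_contrast(m, feats, rts3)
  expect_equal(out3$n_with, 0)
  expect_true(is.na(out3$p_value))
  expect_true(is.na(out3$mean_with))
})

test_that("contrasts are invariant to feature input order", {
  set.seed(227)
  m <- random_toy_map(span = 100000, n_pieces = 30, gap_prob = 0,
                      chrom = "c")
  feats <- feature_table(tibble::tibble(
    chrom = "c", start = s <- sample(1:90000, 30),
    end = s + 2000, category = sample(c("gene", "CpGi"), 30, TRUE),
    id = paste0("f", 1:30)))
  rts <- feature_table(tibble::tibble(
    chrom = "c", start = s2 <- sample(1:90000, 10), end = s2 + 1500,
    category = "LINE", id = paste0("L", 1:10)))
  a <- rt_overlap_contrast(m, feats, rts)
  b <- rt_overlap_contrast(m, feats[sample(30), ], rts[sample(10), ])
  expect_equal(dplyr::arrange(a, .data$category),
               dplyr::arrange(b, .data$category))
})
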