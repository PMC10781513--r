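test_that("map files parse in both dialects and reject bad rows", {
  p3 <- withr::local_tempfile(fileext = ".map")
  writeLines(c("0 100 1e-8", "100 300 3e-8"), p3)
  m <- read_rate_map(p3, chrom = "chr1")
  expect_equal(nrow(m), 2)
  expect_equal(max(m$end), 300)
  expect_equal(m$rate, c(1e-8, 3e-8))

  p4 <- withr::local_tempfile(fileext = ".map")
  writeLines(c("chrom start end rate",
               "chr1\t0\t100\t1e-8", "chr2\t0\t50\t2e-8"), p4)
  m4 <- read_rate_map(p4)
  expect_setequal(unique(m4$chrom), c("chr1", "chr2"))

  # 1-based inclusive input converts to 0-based half-open on ingest
  p1b <- withr::local_tempfile(fileext = ".map")
  writeLines(c("1 100 1e-8", "101 300 3e-8"), p1b)
  m1 <- read_rate_map(p1b, chrom = "chr1", one_based = TRUE)
  expect_equal(m1$start, c(0, 100))
  expect_equal(m1$end, c(100, 300))

  bad <- withr::local_tempfile()
  writeLines(c("chr1 100 300 1e-8", "chr1 0 100 1e-8"), bad)
  expect_error(read_rate_map(bad), "out of order")

  ovl <- withr::local_tempfile()
  writeLines(c("chr1 0 100 1e-8", "chr1 50 150 1e-8"), ovl)
  expect_error(read_rate_map(ovl), "overlap")

  mal <- withr::local_tempfile()
  writeLines(c("chr1 0 100 1e-8", "chr1 oops"), mal)
  expect_error(read_rate_map(mal), "line 2")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_warning(me <- read_rate_map(empty), "empty")
  expect_equal(nrow(me), 0)
})

test_that("rate map invariants are enforced", {
  expect_error(rate_map(tibble::tibble(chrom = "c", start = 10, end = 10,
                                       rate = 1e-8)), "end <= start")
  expect_error(rate_map(tibble::tibble(chrom = "c", start = 0, end = 10,
                                       rate = -1e-8)), ">= 0")
  expect_error(rate_map(tibble::tibble(chrom = "c", start = c(0, 5),
                                       end = c(10, 15),
                                       rate = c(1e-8, 1e-8))),
               "overlapping")
  expect_error(rate_map(tibble::tibble(chrom = "c", start = 0, end = 10,
                                       rate = Inf)), "finite")
})

test_that("unit conversion is exact and self-inverse", {
  expect_identical(rate_to_cm_per_mb(1e-8), 1)
  expect_identical(rate_to_cm_per_mb(0), 0)
  expect_equal(rate_to_cm_per_mb(4.6e-9), 0.46)
  expect_error(rate_to_cm_per_mb(-1), ">= 0")
  r <- stats::runif(100, 0, 1e-6)
  expect_equal(cm_per_mb_to_rate(rate_to_cm_per_mb(r)), r,
               tolerance = 1e-15)
})

test_that("cumulative genetic map integrates rates and skips gaps", {
  m <- rate_map(tibble::tibble(chrom = "c", start = c(0, 100),
                               end = c(100, 300), rate = c(1e-8, 3e-8)))
  gm <- cumulative_genetic_map(m)
  expect_equal(gm$cm[gm$pos == 300], 7e-4)
  expect_equal(gm$cm[1], 0)

  single <- rate_map(tibble::tibble(chrom = "c", start = 0, end = 1e8,
                                    rate = 1e-8))
  expect_equal(max(cumulative_genetic_map(single)$cm), 100)

  gap <- rate_map(tibble::tibble(chrom = "c", start = c(0, 200),
                                 end = c(100, 300), rate = 1e-8))
  expect_equal(max(cumulative_genetic_map(gap)$cm), 2e-4)
  expect_true(!is.unsorted(cumulative_genetic_map(gap)$cm))

  expect_equal(nrow(cumulative_genetic_map(m[0, ])), 0)
})

test_that("weighted mean rate matches hand arithmetic and gap semantics", {
  m <- rate_map(tibble::tibble(chrom = "c", start = c(0, 100),
                               end = c(100, 300), rate = c(1e-8, 3e-8)))
  expect_equal(weighted_mean_rate(m, 0, 300)$mean_rate,
               (100 * 1e-8 + 200 * 3e-8) / 300)
  expect_equal(weighted_mean_rate(m, 50, 150)$mean_rate, 2e-8)
  expect_true(is.na(weighted_mean_rate(m, 400, 500)$mean_rate))
  expect_equal(weighted_mean_rate(m, 400, 500)$covered_bp, 0)
  expect_error(weighted_mean_rate(m, 300, 100), "end > start")
})

test_that("weighted means and window rates equal the per-base oracle", {
  set.seed(11)
  for (rep in 1:25) {
    m <- random_toy_map()
    span <- max(m$end)
    v <- per_base_rates(m, span)
    for (reg in list(c(0, span), c(137, 2244), c(5000, 9000))) {
      got <- weighted_mean_rate(m, reg[1], reg[2])$mean_rate
      expect_equal(got, per_base_mean(v, reg[1], reg[2]),
                   tolerance = 1e-12)
    }
    w <- window_rates(m, 1000, min_covered_fraction = 0,
                      chrom_lengths = c(toy = span))
    oracle <- vapply(seq_len(nrow(w)), function(i) {
      per_base_mean(v, w$start[i], w$end[i])
    }, numeric(1))
    expect_equal(w$rate, oracle, tolerance = 1e-12)
  }
})

test_that("windowing conserves total map distance", {
  set.seed(21)
  for (ws in c(700, 1000, 4096)) {
    m <- random_toy_map()
    w <- window_rates(m, ws, min_covered_fraction = 0)
    total <- sum(m$rate * (m$end - m$start))
    got <- sum(w$rate * w$covered_bp, na.rm = TRUE)
    expect_equal(got, total, tolerance = 1e-12)
  }
})

test_that("windows flag low coverage and gaps", {
  m <- rate_map(tibble::tibble(chrom = "c", start = 0, end = 1e6,
                               rate = 1e-8))
  w <- window_rates(m, 2e5)
  expect_equal(nrow(w), 5)
  expect_equal(w$rate, rep(1e-8, 5))

  gappy <- rate_map(tibble::tibble(chrom = "c", start = c(0, 3000),
                                   end = c(1000, 4000), rate = 1e-8))
  w2 <- window_rates(gappy, 1000, chrom_lengths = c(c = 4000))
  expect_true(is.na(w2$rate[2]))   # window fully inside the gap
  expect_true(w2$low_coverage[2])
  # terminal partial window keeps its true span
  w3 <- window_rates(m, 3e5)
  expect_equal(w3$end[4] - w3$start[4], 1e5)
})

test_that("genetic map endpoint matches the chromosome mean rate", {
  set.seed(31)
  m <- random_toy_map(gap_prob = 0)
  gm <- cumulative_genetic_map(m)
  span_mb <- max(m$end) / 1e6
  mean_cm_mb <- rate_to_cm_per_mb(
    weighted_mean_rate(m, 0, max(m$end))$mean_rate)
  expect_equal(max(gm$cm) / span_mb, mean_cm_mb, tolerance = 1e-12)
})

test_that("chromosome summaries combine map, length and demography", {
  m <- rate_map(tibble::tibble(chrom = "c", start = 0, end = 1e8,
                               rate = 1e-8))
  cs <- chromosome_summary(m, c(c = 1e8), theta = 0.0092)
  expect_equal(cs$expected_co, 1.0)
  expect_equal(cs$map_length_cm, 100)
  expect_equal(cs$ne, 5e5)
  expect_equal(cs$rho, 4 * 5e5 * 1e-8)   # 0.02

  small <- rate_map(tibble::tibble(chrom = c("a", "b"),
                                   start = 0,
                                   end = c(19999999, 20000001),
                                   rate = 1e-8))
  cs2 <- chromosome_summary(small, c(a = 19999999, b = 20000001))
  expect_equal(cs2$class, c("micro", "macro"))

  expect_error(chromosome_summary(m, c(c = 1e8), theta = -1), "> 0")
  expect_error(chromosome_summary(m, c(c = 10)), "smaller than map span")
})

test_that("effective population size honors the scaling factor", {
  expect_equal(effective_population_size(0.0092, 4.6e-9, 4), 5e5)
  expect_equal(effective_population_size(0.0092, 4.6e-9, 1), 2e6)
  expect_error(effective_population_size(0.0092, 0), "> 0")
  expect_error(effective_population_size(-1), "> 0")
})

test_that("demography models validate and time-average", {
  dem <- demography_model(tibble::tibble(time = c(0, 100, 1000),
                                         ne = c(1e4, 5e4, 2e4)))
  # durations 100 and 900 up to t = 1000
  expect_equal(time_averaged_ne(dem, 1000), (1e4 * 100 + 5e4 * 900) / 1000)
  expect_error(demography_model(tibble::tibble(time = c(5, 10), ne = 1e4)),
               "from 0")
  p <- withr::local_tempfile()
  writeLines(c("0 10000", "100 50000"), p)
  expect_s3_class(read_demography(p), "demography_model")
})
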