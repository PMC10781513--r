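test_that("GFF3 and BED readers normalise coordinate conventions", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
               "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=m1;Parent=g1",
               "chr1\tsrc\tCDS\t101\t160\t.\t+\t.\tID=c1;Parent=m1"),
             gff)
  suppressMessages(f <- read_features(gff))
  expect_equal(f$start[f$category == "mRNA"], 100)
  expect_equal(f$end[f$category == "mRNA"], 200)
  expect_false("CDS" %in% f$category)   # outside the vocabulary

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed)
  b <- read_features(bed, category = "CpGi")
  expect_equal(b$start, 100)
  expect_equal(b$end, 200)
  expect_equal(b$category, "CpGi")

  badbed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t200\t200", badbed)
  expect_error(read_features(badbed), "end <= start")
})

test_that("TSS derivation is strand-aware and de-duplicated", {
  g <- feature_table(tibble::tibble(
    chrom = "c", start = c(100, 100, 100), end = c(200, 200, 300),
    strand = c("+", "+", "-"), category = "mRNA",
    id = c("m1", "m2", "m3")))
  tss <- derive_tss(g)
  expect_equal(nrow(tss), 2)   # m1/m2 share a TSS
  expect_equal(tss$start[tss$strand == "+"], 100)
  expect_equal(tss$start[tss$strand == "-"], 299)
  expect_equal(tss$end - tss$start, c(1, 1))

  unk <- feature_table(tibble::tibble(chrom = "c", start = 10, end = 50,
                                      strand = "*", category = "mRNA",
                                      id = "m"))
  expect_warning(t2 <- derive_tss(unk), "unknown strand")
  expect_equal(t2$start, 10)
})

test_that("promoters sit upstream, clip at bounds, and split on CpGi", {
  tss <- feature_table(tibble::tibble(
    chrom = "c", start = c(5000, 1000, 8000), end = c(5001, 1001, 8001),
    strand = c("+", "+", "-"), category = "TSS", id = c("a", "b", "d")))
  pr <- derive_promoters(tss)
  expect_equal(pr$start[pr$id == "a"], 3000)
  expect_equal(pr$end[pr$id == "a"], 5000)
  expect_equal(pr$start[pr$id == "b"], 0)     # clipped
  expect_equal(pr$end[pr$id == "b"], 1000)
  expect_equal(pr$start[pr$id == "d"], 8001)  # downstream in genome coords
  expect_equal(pr$end[pr$id == "d"], 10001)

  cpgi <- feature_table(tibble::tibble(chrom = "c", start = 4999,
                                       end = 5050, category = "CpGi"))
  pr2 <- derive_promoters(tss, cpgi = cpgi)
  expect_equal(pr2$category[pr2$id == "a"], "promoter_with_CpGi")
  expect_equal(pr2$category[pr2$id == "b"], "promoter_without_CpGi")
})

test_that("promoters mirror exactly under strand reflection", {
  L <- 100000
  set.seed(5)
  pos <- sample(3000:(L - 3000), 20)
  tss_plus <- feature_table(tibble::tibble(
    chrom = "c", start = pos, end = pos + 1, strand = "+",
    category = "TSS", id = paste0("t", seq_along(pos))))
  # reflect about the midpoint: position p -> L - 1 - p, strand flipped
  tss_minus <- feature_table(tibble::tibble(
    chrom = "c", start = L - 1 - pos, end = L - pos, strand = "-",
    category = "TSS", id = paste0("t", seq_along(pos))))
  p1 <- derive_promoters(tss_plus, chrom_lengths = c(c = L))
  p2 <- derive_promoters(tss_minus, chrom_lengths = c(c = L))
  p2r <- tibble::tibble(start = L - p2$end, end = L - p2$start,
                        id = p2$id)
  p1o <- p1[match(p2r$id, p1$id), ]
  expect_equal(p2r$start, p1o$start)
  expect_equal(p2r$end, p1o$end)
})

test_that("intergenic regions complement the merged gene union", {
  g <- feature_table(tibble::tibble(
    chrom = "c", start = c(100, 150), end = c(200, 300),
    category = "gene", id = c("g1", "g2")))
  ig <- derive_intergenic(g, c(c = 400))
  expect_equal(ig$start, c(0, 300))
  expect_equal(ig$end, c(100, 400))

  none <- derive_intergenic(g[0, ], c(c = 400))
  expect_equal(none$start, 0)
  expect_equal(none$end, 400)

  full <- feature_table(tibble::tibble(chrom = "c", start = 0, end = 400,
                                       category = "gene", id = "g"))
  expect_equal(nrow(derive_intergenic(full, c(c = 400))), 0)

  # complement of the complement reproduces the merged union
  back <- derive_intergenic(ig, c(c = 400))
  expect_equal(back$start, 100)
  expect_equal(back$end, 300)
})

test_that("window density counts overlaps; coverage uses the union", {
  w <- tibble::tibble(chrom = "c", start = c(0, 1000), end = c(1000, 2000))
  f1 <- feature_table(tibble::tibble(chrom = "c", start = 100, end = 200,
                                     category = "x", id = "f1"))
  r1 <- window_density_coverage(f1, w)
  expect_equal(r1$density, c(1L, 0L))
  expect_equal(r1$coverage, c(0.1, 0))

  f2 <- feature_table(tibble::tibble(chrom = "c", start = c(100, 150),
                                     end = c(200, 250), category = "x",
                                     id = c("a", "b")))
  r2 <- window_density_coverage(f2, w)
  expect_equal(r2$density[1], 2L)
  expect_equal(r2$coverage[1], 0.15)

  # feature abutting a window end falls in the next window only
  f3 <- feature_table(tibble::tibble(chrom = "c", start = 1000, end = 1100,
                                     category = "x", id = "f3"))
  r3 <- window_density_coverage(f3, w)
  expect_equal(r3$density, c(0L, 1L))

  # a feature spanning several windows counts once in each
  f4 <- feature_table(tibble::tibble(chrom = "c", start = 500, end = 1500,
                                     category = "x", id = "f4"))
  r4 <- window_density_coverage(f4, w)
  expect_equal(r4$density, c(1L, 1L))
  expect_true(all(r4$coverage >= 0 & r4$coverage <= 1))
})

test_that("per-feature rates match a per-base intersection oracle", {
  m <- rate_map(tibble::tibble(chrom = "toy", start = 0, end = 10000,
                               rate = 1e-8))
  fr <- mean_rate_by_feature(m, toy_features())
  expect_equal(fr$mean_rate, rep(1, 3))   # constant map -> 1 cM/Mb

  gapmap <- rate_map(tibble::tibble(chrom = "toy", start = 0, end = 500,
                                    rate = 1e-8))
  fr2 <- mean_rate_by_feature(gapmap, toy_features())
  expect_true(all(is.na(fr2$mean_rate)))
  expect_equal(nrow(category_rate_summary(fr2)), 0)

  set.seed(42)
  for (rep in 1:10) {
    m <- random_toy_map()
    v <- per_base_rates(m, max(m$end))
    f <- toy_features()
    got <- mean_rate_by_feature(m, f, units = "r")
    oracle <- vapply(seq_len(nrow(f)), function(i) {
      per_base_mean(v, f$start[i], f$end[i])
    }, numeric(1))
    expect_equal(got$mean_rate, oracle, tolerance = 1e-12)
  }
})

test_that("overlap split is an exhaustive half-open partition", {
  genes <- toy_features()
  line <- feature_table(tibble::tibble(chrom = "toy", start = 1500,
                                       end = 1600, category = "LINE",
                                       id = "L1"))
  sp <- overlap_split(genes, line, family = "LINE")
  expect_equal(sum(sp$overlaps) + sum(!sp$overlaps), nrow(genes))
  expect_true(sp$overlaps[sp$id == "g1"])

  abut <- feature_table(tibble::tibble(chrom = "toy", start = 2000,
                                       end = 2100, category = "LINE",
                                       id = "L2"))
  sp2 <- overlap_split(genes, abut, family = "LINE")
  expect_false(sp2$overlaps[sp2$id == "g1"])   # half-open: no overlap

  sp3 <- overlap_split(genes, line[0, ])
  expect_true(all(!sp3$overlaps))

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    f <- feature_table(tibble::tibble(
      chrom = "toy", start = s <- sample(1:10000, n),
      end = s + sample(10:500, n, replace = TRUE),
      category = "gene", id = paste0("g", 1:n)))
    r <- feature_table(tibble::tibble(
      chrom = "toy", start = s2 <- sample(1:10000, 5),
      end = s2 + 100, category = "LINE", id = paste0("L", 1:5)))
    sp <- overlap_split(f, r)
    expect_equal(sum(sp$overlaps) + sum(!sp$overlaps), n)
  }
})
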