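#' Chromosome size versus recombination rate
#'
#' Kendall tau-b between log10 chromosome length (Mb) and the mean
#' recombination rate in cM/Mb. The log transform does not change tau (a
#' rank statistic) but is kept for parity with conventional reporting.
#'
#' @param summaries Output of [chromosome_summary()], `>= 3` rows.
#' @return A `cor_result`.
#' @export
size_rate_correlation <- function(summaries) {
  if (nrow(summaries) < 3) stop("need >= 3 chromosomes")
  kendall_tau_b(log10(summaries$length / 1e6), summaries$rate_cm_mb)
}

#' Micro- versus macrochromosome rate contrast
#'
#' Class means of cM/Mb rates and a Welch two-sample t-test between
#' microchromosomes and macrochromosomes.
#'
#' @param summaries Output of [chromosome_summary()] with a `class`
#'   column; both classes need `>= 2` chromosomes.
#' @return One-row tibble: `micro_mean`, `macro_mean`, `ratio`,
#'   `statistic`, `p_value`, `n_micro`, `n_macro`.
#' @export
micro_macro_contrast <- function(summaries) {
  mi <- summaries$rate_cm_mb[summaries$class == "micro"]
  ma <- summaries$rate_cm_mb[summaries$class == "macro"]
  if (length(mi) == 0) stop("no microchromosomes in summaries")
  if (length(ma) == 0) stop("no macrochromosomes in summaries")
  wt <- welch_t(mi, ma)
  tibble::tibble(micro_mean = mean(mi), macro_mean = mean(ma),
                 ratio = mean(mi) / mean(ma),
                 statistic = wt$statistic, p_value = wt$p_value,
                 n_micro = length(mi), n_macro = length(ma))
}

#' Recombination profile around anchor features
#'
#' Averages the recombination rate in fixed-width bins of distance from a
#' set of anchors (TSS, CpG islands, ...). Each anchor's zero point is its
#' strand-aware first base when `orient_by_strand` is set (offsets are
#' mirrored for `-`-strand anchors so that negative offsets always mean
#' "upstream"); otherwise the interval start. Per bin, the mean is taken
#' across anchors with a defined windowed rate, with a 95% normal
#' confidence half-width.
#'
#' @param map A `rate_map`.
#' @param anchors Feature tibble of anchor points/intervals.
#' @param bin Bin width in bp (default 5000).
#' @param span Profile half-width in bp (default 200000).
#' @param orient_by_strand Mirror offsets for `-`-strand anchors.
#' @param units `"cm_mb"` (default) or `"r"`.
#' @return A `distance_profile` tibble: `offset` (bin center, bp;
#'   negative = upstream), `mean_rate`, `n_anchor`, `ci_half`. The
#'   attribute `"inside_anchor"` carries the mean rate over the anchors'
#'   own spans (relevant for interval anchors such as CpG islands).
#' @export
distance_profile <- function(map, anchors, bin = 5000, span = 200000,
                             orient_by_strand = TRUE,
                             units = c("cm_mb", "r")) {
  units <- match.arg(units)
  map <- rate_map(map)
  if (nrow(anchors) == 0) stop("no anchors")
  offs <- seq(-span, span - bin, by = bin)   # oriented bin starts
  zero <- ifelse(orient_by_strand & anchors$strand == "-",
                 anchors$end - 1, anchors$start)
  minus <- orient_by_strand & anchors$strand == "-"
  per_bin <- purrr::map_dfr(seq_along(offs), function(i) {
    o <- offs[i]
    # oriented bin [o, o + bin) maps to genomic coordinates per anchor
    gstart <- ifelse(minus, zero - (o + bin) + 1, zero + o)
    gend <- gstart + bin
    keep <- gstart >= 0
    vals <- rep(NA_real_, length(zero))
    if (any(keep)) {
      wm <- dplyr::group_map(
        dplyr::group_by(tibble::tibble(chrom = anchors$chrom[keep],
                                       s = gstart[keep], e = gend[keep],
                                       idx = which(keep)),
                        .data$chrom),
        function(d, key) {
          mc <- map[map$chrom == key$chrom, ]
          r <- weighted_mean_rate_vec(mc, d$s, d$e)
          tibble::tibble(idx = d$idx, v = r$mean_rate)
        }) |> dplyr::bind_rows()
      vals[wm$idx] <- wm$v
    }
    v <- vals[!is.na(vals)]
    tibble::tibble(offset = o + bin / 2,
                   mean_rate = if (length(v)) mean(v) else NA_real_,
                   n_anchor = length(v),
                   ci_half = if (length(v) > 1) {
                     1.96 * stats::sd(v) / sqrt(length(v))
                   } else NA_real_)
  })
  if (units == "cm_mb") {
    per_bin$mean_rate <- per_bin$mean_rate * 1e8
    per_bin$ci_half <- per_bin$ci_half * 1e8
  }
  # mean rate inside the anchors' own spans (useful for interval anchors
  # such as CpG islands, whose interior is not part of the flank bins)
  inside <- weighted_mean_rate(map, anchors$start,
                               pmax(anchors$end, anchors$start + 1),
                               chrom = anchors$chrom)
  iv <- inside$mean_rate[!is.na(inside$mean_rate)]
  attr(per_bin, "inside_anchor") <-
    if (length(iv)) mean(iv) * (if (units == "cm_mb") 1e8 else 1)
    else NA_real_
  class(per_bin) <- c("distance_profile", class(per_bin))
  per_bin
}

#' Flank trends of a distance profile
#'
#' Kendall tau between bin offset and mean rate, separately over the
#' upstream (`[-flank, 0)`) and downstream (`(0, flank]`) bins. A rate
#' rising toward the anchor gives a positive upstream tau and a negative
#' downstream tau.
#'
#' @param profile Output of [distance_profile()].
#' @param flank Flank width in bp (default 50000).
#' @return Tibble with rows `upstream`/`downstream`: `tau`, `p_value`,
#'   `n_bins`, `note`.
#' @export
profile_flank_trend <- function(profile, flank = 50000) {
  up <- profile[profile$offset > -flank & profile$offset < 0 &
                  !is.na(profile$mean_rate), ]
  dn <- profile[profile$offset > 0 & profile$offset < flank &
                  !is.na(profile$mean_rate), ]
  if (nrow(up) == 0 && nrow(dn) == 0) stop("profile empty over the flank")
  one <- function(d, side) {
    if (nrow(d) < 3) {
      return(tibble::tibble(side = side, tau = NA_real_,
                            p_value = NA_real_, n_bins = nrow(d),
                            note = "too_few_bins"))
    }
    k <- kendall_tau_b(d$offset, d$mean_rate)
    tibble::tibble(side = side, tau = k$estimate, p_value = k$p_value,
                   n_bins = k$n,
                   note = if (length(k$note)) k$note else NA_character_)
  }
  dplyr::bind_rows(one(up, "upstream"), one(dn, "downstream"))
}

#' Annotation-category rate contrasts against the genome-wide distribution
#'
#' For each category, a Wilcoxon rank-sum test of the per-feature mean
#' rates against the genome-wide per-window rate distribution, with
#' multiplicity correction across categories.
#'
#' @param feature_rates Output of [mean_rate_by_feature()] (must carry
#'   `category` and `mean_rate`, in the same units as the windows).
#' @param genome_windows Window table whose non-missing `rate` column is
#'   the reference distribution (conventionally 200 kb windows).
#' @param correction `"holm"` (default) or `"bh"`.
#' @return Tibble per category: `n`, `median_rate`, `mean_rate`,
#'   `statistic`, `p_value`, `p_adjusted`, `low_n`.
#' @export
category_rate_contrast <- function(feature_rates, genome_windows,
                                   correction = "holm") {
  ref <- genome_windows$rate[!is.na(genome_windows$rate)]
  if (length(ref) == 0) stop("no reference window rates")
  d <- feature_rates[!is.na(feature_rates$mean_rate), ]
  cats <- unique(d$category)
  empty <- setdiff(unique(feature_rates$category), cats)
  if (length(empty)) {
    warning("skipping categories with no rated features: ",
            paste(empty, collapse = ", "))
  }
  out <- purrr::map_dfr(cats, function(cc) {
    v <- d$mean_rate[d$category == cc]
    w <- wilcoxon_rank_sum(v, ref)
    tibble::tibble(category = cc, n = length(v),
                   median_rate = stats::median(v), mean_rate = mean(v),
                   statistic = w$statistic, p_value = w$p_value,
                   low_n = length(v) < 5)
  })
  out$p_adjusted <- holm_adjust(out$p_value, method = correction)
  out
}

#' Recombination contrasts by retrotransposon overlap
#'
#' For each annotation category and each RT family, compares the mean
#' recombination rate of category features that overlap the family
#' (>= 1 bp) against those that do not, with a Wilcoxon rank-sum test.
#' Cells where either side is empty are reported as missing.
#'
#' @param map A `rate_map`.
#' @param features Feature tibble with the categories to contrast
#'   (e.g. CpGi, gene, promoter, intergenic).
#' @param rts Feature tibble of RT placements with `category` in
#'   `{LTR, LINE, SINE}` (or any family labels).
#' @param units `"cm_mb"` (default) or `"r"`.
#' @param correction Multiplicity correction across cells.
#' @return Tibble per (category, family): group sizes, means, medians,
#'   `p_value`, `p_adjusted`.
#' @export
rt_overlap_contrast <- function(map, features, rts,
                                units = "cm_mb", correction = "holm") {
  rated <- mean_rate_by_feature(map, features, units = units)
  rated <- rated[!is.na(rated$mean_rate), ]
  fams <- unique(rts$category)
  cats <- unique(rated$category)
  out <- purrr::map_dfr(cats, function(cc) {
    purrr::map_dfr(fams, function(ff) {
      fc <- overlap_split(rated[rated$category == cc, ], rts, family = ff)
      wi <- fc$mean_rate[fc$overlaps]
      wo <- fc$mean_rate[!fc$overlaps]
      base <- tibble::tibble(category = cc, family = ff,
                             n_with = length(wi), n_without = length(wo),
                             mean_with = if (length(wi)) mean(wi) else NA,
                             mean_without = if (length(wo)) mean(wo) else NA,
                             median_with = if (length(wi))
                               stats::median(wi) else NA,
                             median_without = if (length(wo))
                               stats::median(wo) else NA)
      base$p_value <- if (length(wi) > 0 && length(wo) > 0) {
        wilcoxon_rank_sum(wi, wo)$p_value
      } else NA_real_
      base
    })
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(category = character(), family = character(),
                          n_with = integer(), n_without = integer(),
                          mean_with = numeric(), mean_without = numeric(),
                          median_with = numeric(),
                          median_without = numeric(),
                          p_value = numeric(), p_adjusted = numeric()))
  }
  out$p_adjusted <- holm_adjust(out$p_value, method = correction)
  out
}

#' Window-level feature correlation table
#'
#' Pairwise Kendall tau-b of the recombination rate against each other
#' window statistic, the building block of genome-wide association
#' summaries.
#'
#' @param windows Window table with a `rate` column and the statistic
#'   columns named in `vars`.
#' @param vars Columns to correlate with `rate` (default: every numeric
#'   column except coordinates and `rate`).
#' @param correction Multiplicity correction.
#' @return Tibble: `variable`, `tau`, `p_value`, `p_adjusted`, `n`.
#' @export
rate_feature_correlations <- function(windows, vars = NULL,
                                      correction = "holm") {
  stopifnot("rate" %in% names(windows))
  if (is.null(vars)) {
    vars <- setdiff(names(windows)[vapply(windows, is.numeric, logical(1))],
                    c("chrom", "start", "end", "rate", "covered_bp",
                      "covered_frac", "gc_support", "callable_bp",
                      "n_sites", "complexity_support"))
  }
  out <- purrr::map_dfr(vars, function(v) {
    k <- kendall_tau_b(windows$rate, windows[[v]])
    tibble::tibble(variable = v, tau = k$estimate, p_value = k$p_value,
                   n = k$n)
  })
  out$p_adjusted <- holm_adjust(out$p_value, method = correction)
  out
}
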