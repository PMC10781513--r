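#' Pair two species' maps on a shared window grid
#'
#' Applies the identical non-overlapping tiling to both maps (which must
#' live on the same reference coordinates) and keeps the windows where
#' both species have a defined rate.
#'
#' @param map_a,map_b `rate_map`s sharing chromosome names.
#' @param window_size Window size in bp.
#' @param min_covered_fraction Coverage floor per window and species.
#' @param units `"r"` (default) or `"cm_mb"`.
#' @return Tibble: `chrom`, `start`, `end`, `rate_a`, `rate_b`. The
#'   attribute `"dropped"` counts windows lost to missingness; chromosomes
#'   present in only one map are recorded in attribute `"unshared"`.
#' @export
align_windows <- function(map_a, map_b, window_size,
                          min_covered_fraction = 0.5,
                          units = c("r", "cm_mb")) {
  units <- match.arg(units)
  map_a <- rate_map(map_a); map_b <- rate_map(map_b)
  ca <- unique(map_a$chrom); cb <- unique(map_b$chrom)
  shared <- intersect(ca, cb)
  if (length(shared) == 0) {
    stop("no shared chromosomes; A has {", paste(ca, collapse = ","),
         "}, B has {", paste(cb, collapse = ","), "}")
  }
  unshared <- setdiff(union(ca, cb), shared)
  if (length(unshared)) {
    message("chromosome(s) absent from one species: ",
            paste(unshared, collapse = ", "))
  }
  # a common tiling: per shared chromosome, span = max of the two spans
  len <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(map_a, map_b), .data$chrom),
    length = max(.data$end), .groups = "drop")
  len <- len[len$chrom %in% shared, ]
  wa <- window_rates(map_a[map_a$chrom %in% shared, ], window_size,
                     min_covered_fraction, chrom_lengths = len,
                     units = units)
  wb <- window_rates(map_b[map_b$chrom %in% shared, ], window_size,
                     min_covered_fraction, chrom_lengths = len,
                     units = units)
  out <- tibble::tibble(chrom = wa$chrom, start = wa$start, end = wa$end,
                        rate_a = wa$rate, rate_b = wb$rate)
  keep <- !is.na(out$rate_a) & !is.na(out$rate_b)
  res <- out[keep, ]
  attr(res, "dropped") <- sum(!keep)
  attr(res, "unshared") <- unshared
  res
}

#' Cross-species conservation statistics
#'
#' Kendall tau-b between the paired window rates, genome-wide and
#' optionally per chromosome. Units with fewer than 3 pairs are skipped
#' with a recorded reason.
#'
#' @param pairs Output of [align_windows()].
#' @param per_chromosome Also report per-chromosome correlations.
#' @return Tibble: `unit`, `n`, `tau`, `p_value`, `note`.
#' @export
conservation_stats <- function(pairs, per_chromosome = FALSE) {
  one <- function(d, unit) {
    if (nrow(d) < 3) {
      return(tibble::tibble(unit = unit, n = nrow(d), tau = NA_real_,
                            p_value = NA_real_, note = "fewer than 3 pairs"))
    }
    k <- kendall_tau_b(d$rate_a, d$rate_b)
    tibble::tibble(unit = unit, n = k$n, tau = k$estimate,
                   p_value = k$p_value,
                   note = if (length(k$note)) k$note else NA_character_)
  }
  out <- one(pairs, "genome")
  if (per_chromosome) {
    out <- dplyr::bind_rows(out, purrr::map_dfr(
      unique(pairs$chrom),
      function(cc) one(pairs[pairs$chrom == cc, ], cc)))
  }
  out
}

#' Normalised log-rate difference track
#'
#' Per-window `log(rate_a) - log(rate_b)`; windows where either rate is
#' zero or missing are dropped and counted in the `"dropped_nonpositive"`
#' attribute. Antisymmetric in the two species by construction.
#'
#' @param pairs Output of [align_windows()].
#' @param base Logarithm base (default 10).
#' @return `pairs` with a `log_diff` column, nonpositive-rate windows
#'   removed.
#' @export
normalized_log_difference <- function(pairs, base = 10) {
  keep <- !is.na(pairs$rate_a) & !is.na(pairs$rate_b) &
    pairs$rate_a > 0 & pairs$rate_b > 0
  out <- pairs[keep, ]
  out$log_diff <- log(out$rate_a, base) - log(out$rate_b, base)
  attr(out, "dropped_nonpositive") <- sum(!keep)
  out
}

#' Exclude chromosomes with insufficient SNP density
#'
#' @param densities Tibble with `chrom` and one variants-per-kb column per
#'   species (any names beyond `chrom`).
#' @param min_density Minimum density; a chromosome below it in any
#'   species is excluded.
#' @return Tibble: `chrom`, `reason` for each excluded chromosome
#'   (zero rows when nothing is excluded).
#' @export
snp_density_mask <- function(densities, min_density) {
  dcols <- setdiff(names(densities), "chrom")
  stopifnot(length(dcols) >= 1, min_density >= 0)
  purrr::map_dfr(seq_len(nrow(densities)), function(i) {
    low <- dcols[which(unlist(densities[i, dcols]) < min_density)]
    if (length(low) == 0) return(NULL)
    tibble::tibble(chrom = densities$chrom[i],
                   reason = paste0("SNP density below ", min_density,
                                   " in ", paste(low, collapse = ", ")))
  })
}

#' Subsample-consistency check for conservation estimates
#'
#' Recomputes the genome-wide conservation tau from a random fraction of
#' the paired windows, mirroring subset-robustness checks at the map
#' level. Seed-controlled.
#'
#' @param pairs Output of [align_windows()].
#' @param fraction Fraction of windows to keep (default 0.5).
#' @param n_rep Number of subsamples.
#' @param seed RNG seed.
#' @return Tibble: `rep`, `n`, `tau`.
#' @export
conservation_subsample <- function(pairs, fraction = 0.5, n_rep = 10,
                                   seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(seed)
  purrr::map_dfr(seq_len(n_rep), function(i) {
    idx <- sample(nrow(pairs), ceiling(fraction * nrow(pairs)))
    k <- kendall_tau_b(pairs$rate_a[idx], pairs$rate_b[idx])
    tibble::tibble(rep = i, n = k$n, tau = k$estimate)
  })
}
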