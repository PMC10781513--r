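#' Positions of CpG dinucleotides
#'
#' 0-based positions of the C of each `CG` dinucleotide, case-insensitive.
#'
#' @param sequence A single sequence (character or `DNAString`).
#' @return Integer vector of positions (possibly empty).
#' @export
cpg_positions <- function(sequence) {
  s <- toupper(as.character(sequence))
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Distance threshold for CpG clustering
#'
#' The clustering threshold is the integer-floored median of the
#' consecutive-CpG distances of the chromosome, the default percentile of
#' distance-based island callers.
#'
#' @param positions Output of [cpg_positions()]; needs `>= 2` CpGs.
#' @return Integer threshold, or `NA` when undefined.
#' @export
distance_threshold <- function(positions) {
  if (length(positions) < 2) return(NA_integer_)
  as.integer(floor(stats::median(diff(positions))))
}

#' Detect CpG islands by distance clustering
#'
#' Candidate islands are maximal runs of two or more CpGs whose
#' consecutive distances all stay at or below the chromosome's median
#' CpG distance. Island significance uses a geometric null for spacings
#' whose success probability is the chromosome-wide CpG density
#' (`n_cpg / sequence length`, the expected CpG rate per position): the
#' total intra-island distance `D` (a sum of `n_cpg - 1` spacings) is
#' then negative-binomial, and the island p-value is `P(X <= D)` — small
#' when the CpGs sit unusually close together. Islands are retained when
#' their span is at least `min_length` bp and their p-value at most
#' `max_p`.
#'
#' @param genome A single sequence, a named character vector, a
#'   `DNAStringSet`, or a FASTA path.
#' @param min_length Minimum island span in bp (default 50).
#' @param max_p Maximum island p-value (default 1e-5).
#' @param keep_all If `TRUE`, return all candidate clusters with a
#'   `retained` flag instead of filtering.
#' @return Feature tibble of category `CpGi` with `n_cpg` and `p_value`
#'   columns; spans run from the first C to past the last G (half-open).
#' @export
detect_islands <- function(genome, min_length = 50, max_p = 1e-5,
                           keep_all = FALSE) {
  if (is.character(genome) && is.null(names(genome)) &&
      length(genome) == 1 && !file.exists(genome)) {
    genome <- c(seq = genome)
  }
  genome <- as_genome(genome)
  out <- purrr::map_dfr(names(genome), function(cc) {
    detect_islands_chr(as.character(genome[[cc]]), cc)
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_cpg = integer(),
                          p_value = numeric())
  }
  out$length <- out$end - out$start
  out$retained <- out$length >= min_length & out$p_value <= max_p
  out$strand <- "*"
  out$category <- "CpGi"
  out$id <- paste0("CpGi_", seq_len(nrow(out)))
  cols <- c("chrom", "start", "end", "strand", "category", "id",
            "n_cpg", "p_value", "length", "retained")
  out <- out[cols]
  if (!keep_all) {
    out <- out[out$retained, ]
    out$retained <- NULL
  }
  out
}

detect_islands_chr <- function(s, chrom) {
  pos <- cpg_positions(s)
  if (length(pos) < 2) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_cpg = integer(),
                          p_value = numeric()))
  }
  d <- diff(pos)
  thr <- distance_threshold(pos)
  # geometric spacing parameter (support >= 1): chromosome-wide CpG
  # density, robust when most CpGs sit inside clusters
  p_hat <- min(1, length(pos) / nchar(s))
  close <- d <= thr
  # runs of consecutive "close" spacings = candidate clusters
  r <- rle(close)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- r$values
  purrr::map_dfr(which(keep), function(j) {
    i1 <- starts_idx[j]          # first spacing index in the run
    i2 <- ends_idx[j]            # last spacing index
    n_cpg <- i2 - i1 + 2L
    D <- sum(d[i1:i2])
    k <- n_cpg - 1L
    # sum of k geometrics (support >= 1) is NB shifted by k
    p <- stats::pnbinom(D - k, size = k, prob = p_hat)
    tibble::tibble(chrom = chrom,
                   start = pos[i1],
                   end = pos[i2 + 1] + 2,   # past the G of the last CpG
                   n_cpg = n_cpg, p_value = p)
  })
}

#' Write CpG islands as BED with score columns
#' @param islands Output of [detect_islands()].
#' @param path Output path.
#' @export
write_islands_bed <- function(islands, path) {
  d <- tibble::tibble(chrom = islands$chrom,
                      start = format(islands$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(islands$end, scientific = FALSE,
                                   trim = TRUE),
                      n_cpg = islands$n_cpg,
                      p_value = signif(islands$p_value, 6))
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}
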