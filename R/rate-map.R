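#' Construct and validate a recombination rate map
#'
#' A rate map is a tibble of sorted, non-overlapping, half-open genomic
#' intervals, each carrying a per-base-pair, per-generation recombination
#' rate `r`. Gaps between intervals mean "no estimate" (missing data) and
#' are never treated as rate zero: LD-based estimators only emit rates
#' between informative SNP pairs.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, `rate`.
#'   Coordinates are 0-based half-open; `rate` is per-bp per-generation.
#' @return A validated tibble of class `rate_map`.
#' @examples
#' rate_map(tibble::tibble(chrom = "chr1",
#'                         start = c(0, 100), end = c(100, 300),
#'                         rate = c(1e-8, 3e-8)))
#' @export
rate_map <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", "rate")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("rate map is missing column(s): ", paste(miss, collapse = ", "))
  }
  x <- tibble::as_tibble(x)[need]
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$rate <- as.numeric(x$rate)
  validate_rate_map(x)
  x <- dplyr::arrange(x, .data$chrom, .data$start)
  class(x) <- c("rate_map", class(tibble::tibble()))
  x
}

validate_rate_map <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end)) stop("rate map has missing coordinates")
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    stop("rate map interval with end <= start at row ", bad[1])
  }
  if (anyNA(x$rate) || any(!is.finite(x$rate))) {
    stop("rate map rates must be finite")
  }
  if (any(x$rate < 0)) {
    stop("rate map rates must be >= 0 (row ",
         which(x$rate < 0)[1], ")")
  }
  ord <- order(x$chrom, x$start)
  xo <- x[ord, ]
  same <- xo$chrom[-1] == xo$chrom[-nrow(xo)]
  overl <- which(same & xo$start[-1] < xo$end[-nrow(xo)])
  if (length(overl) > 0) {
    stop("overlapping rate map intervals on ", xo$chrom[overl[1] + 1],
         " near position ", xo$start[overl[1] + 1])
  }
  invisible(x)
}

#' Read a piecewise-constant recombination map from text
#'
#' Reads whitespace/tab-separated rate map rows in either a 3-column
#' per-chromosome dialect (`start end rate`) or a 4-column dialect with a
#' leading chromosome name (`chrom start end rate`), the formats emitted by
#' LD-based estimators such as Pyrho.
#'
#' @param path Path to the map text file. A header line is auto-detected.
#' @param chrom Chromosome name to assign when the file is 3-column.
#' @param one_based If `TRUE`, input coordinates are 1-based inclusive and
#'   are converted to the internal 0-based half-open convention on ingest.
#' @return A `rate_map` tibble (empty, with a warning, for an empty file).
#' @export
read_rate_map <- function(path, chrom = NULL, one_based = FALSE) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) > 0) {
    # tolerate a single non-numeric header row
    first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (suppressWarnings(anyNA(as.numeric(utils::tail(first, 2))))) {
      lines <- lines[-1]
    }
  }
  if (length(lines) == 0) {
    warning("empty rate map file: ", path)
    return(rate_map(tibble::tibble(chrom = character(), start = numeric(),
                                   end = numeric(), rate = numeric())))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- lengths(fields)
  if (!all(ncol %in% c(3L, 4L)) || length(unique(ncol)) != 1L) {
    stop("malformed rate map row at line ",
         which(!ncol %in% c(3L, 4L) | ncol != ncol[1])[1], " of ", path)
  }
  mat <- do.call(rbind, fields)
  if (ncol[1] == 3L) {
    if (is.null(chrom)) {
      stop("3-column map files need an explicit `chrom`")
    }
    df <- tibble::tibble(chrom = chrom,
                         start = as.numeric(mat[, 1]),
                         end = as.numeric(mat[, 2]),
                         rate = as.numeric(mat[, 3]))
  } else {
    df <- tibble::tibble(chrom = mat[, 1],
                         start = as.numeric(mat[, 2]),
                         end = as.numeric(mat[, 3]),
                         rate = as.numeric(mat[, 4]))
  }
  bad <- which(!stats::complete.cases(df[c("start", "end", "rate")]))
  if (length(bad) > 0) {
    stop("malformed rate map row at line ", bad[1], " of ", path)
  }
  if (one_based) {
    df$start <- df$start - 1
  }
  # preserve file order for error reporting: an out-of-order file is invalid
  for (cc in unique(df$chrom)) {
    s <- df$start[df$chrom == cc]
    if (is.unsorted(s)) {
      stop("rate map rows out of order on ", cc, " at line ",
           which(df$chrom == cc)[which(diff(s) < 0)[1] + 1], " of ", path)
    }
  }
  rate_map(df)
}

#' Write a rate map in 4-column text form
#' @param map A `rate_map`.
#' @param path Output file path.
#' @export
write_rate_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map)[c("chrom", "start", "end", "rate")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Convert recombination rates between r and cM/Mb
#'
#' `rate_to_cm_per_mb()` converts a per-bp per-generation rate `r` into
#' cM/Mb (1 Morgan = 100 cM, 1 Mb = 1e6 bp, hence a factor 1e8);
#' `cm_per_mb_to_rate()` is its inverse.
#'
#' @param r Per-bp per-generation recombination rate(s), `>= 0`.
#' @return Numeric vector in cM/Mb.
#' @examples
#' rate_to_cm_per_mb(1e-8) # 1 cM/Mb
#' @export
rate_to_cm_per_mb <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop("recombination rate must be >= 0")
  r * 1e8
}

#' @rdname rate_to_cm_per_mb
#' @param x Rate(s) in cM/Mb, `>= 0`.
#' @export
cm_per_mb_to_rate <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("recombination rate must be >= 0")
  x / 1e8
}

#' Cumulative genetic map from a rate map
#'
#' Integrates the piecewise-constant rate into cumulative genetic distance:
#' at each interval boundary `b`, cM(b) = 100 * sum of `r_i * len_i` over
#' intervals before `b`. Gaps contribute zero genetic distance. The map
#' starts at 0 cM at the first mapped position.
#'
#' @param map A `rate_map`.
#' @return A tibble with columns `chrom`, `pos` (bp) and `cm`, one row per
#'   interval boundary.
#' @export
cumulative_genetic_map <- function(map) {
  map <- rate_map(map)
  if (nrow(map) == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          cm = numeric()))
  }
  dplyr::group_modify(dplyr::group_by(map, .data$chrom), function(d, key) {
    len <- d$end - d$start
    cum <- cumsum(d$rate * len) * 100
    pos <- c(d$start[1], d$end)
    # at a gap the next interval starts at the same cumulative distance
    tibble::tibble(pos = pos, cm = c(0, cum))
  }) |> dplyr::ungroup()
}

#' Write a genetic map as tab-separated text (chrom, pos, cM)
#' @param gm Output of [cumulative_genetic_map()].
#' @param path Output file path.
#' @export
write_genetic_map <- function(gm, path) {
  readr::write_tsv(gm, path, col_names = FALSE)
  invisible(path)
}

# Per-chromosome cumulative arrays enabling O(log n) region queries:
# cov(x) = mapped bp in [map start, x); mass(x) = integral of r over that.
map_cum_index <- function(map_chr) {
  len <- map_chr$end - map_chr$start
  list(start = map_chr$start, end = map_chr$end,
       cum_len = c(0, cumsum(len)),
       cum_mass = c(0, cumsum(map_chr$rate * len)),
       rate = map_chr$rate)
}

# Vectorised evaluation of cov()/mass() at arbitrary positions x.
cum_eval <- function(idx, x) {
  i <- findInterval(x, idx$start)        # last interval starting <= x
  inside <- i >= 1 & x > idx$start[pmax(i, 1)]
  part_len <- ifelse(inside, pmin(x, idx$end[pmax(i, 1)]) -
                       idx$start[pmax(i, 1)], 0)
  base <- ifelse(i >= 1, idx$cum_len[pmax(i, 1)], 0)
  basem <- ifelse(i >= 1, idx$cum_mass[pmax(i, 1)], 0)
  list(cov = base + part_len,
       mass = basem + part_len * ifelse(i >= 1, idx$rate[pmax(i, 1)], 0))
}

# Weighted mean rate over many regions of one chromosome at once.
# Returns tibble(mean_rate, covered_bp); mean_rate NA when covered_bp == 0.
weighted_mean_rate_vec <- function(map_chr, starts, ends) {
  if (nrow(map_chr) == 0) {
    return(tibble::tibble(mean_rate = rep(NA_real_, length(starts)),
                          covered_bp = rep(0, length(starts))))
  }
  idx <- map_cum_index(map_chr)
  a <- cum_eval(idx, starts)
  b <- cum_eval(idx, ends)
  cov <- b$cov - a$cov
  mass <- b$mass - a$mass
  tibble::tibble(mean_rate = ifelse(cov > 0, mass / cov, NA_real_),
                 covered_bp = cov)
}

#' Length-weighted mean recombination rate over a region
#'
#' Averages the map's rate over a genomic region, weighting each
#' intersecting interval by its physical overlap. Unmapped gaps are
#' excluded from the denominator, so the mean reflects only positions with
#' an estimate; a region with no mapped bases yields `NA`.
#'
#' @param map A `rate_map`.
#' @param start,end Region bounds (0-based half-open); vectors are allowed
#'   and are recycled against each other.
#' @param chrom Chromosome of the region(s); may be omitted for a
#'   single-chromosome map.
#' @return A tibble with columns `chrom`, `start`, `end`, `mean_rate`,
#'   `covered_bp`.
#' @export
weighted_mean_rate <- function(map, start, end, chrom = NULL) {
  map <- rate_map(map)
  if (any(end <= start)) stop("region must have end > start")
  if (is.null(chrom)) {
    uc <- unique(map$chrom)
    if (length(uc) > 1) stop("`chrom` is required for a multi-chromosome map")
    chrom <- if (length(uc) == 1) uc else NA_character_
  }
  reg <- tibble::tibble(chrom = chrom, start = start, end = end,
                        .row = seq_along(start))
  out <- dplyr::group_modify(dplyr::group_by(reg, .data$chrom),
    function(d, key) {
      mc <- map[map$chrom == key$chrom, ]
      dplyr::bind_cols(d, weighted_mean_rate_vec(mc, d$start, d$end))
    }) |> dplyr::ungroup()
  dplyr::select(dplyr::arrange(out, .data$.row), -".row")
}

#' Tile a chromosome set into fixed windows
#'
#' @param chrom_lengths Named numeric vector or tibble (`chrom`, `length`).
#' @param window_size Window size in bp.
#' @return Tibble of half-open windows (`chrom`, `start`, `end`); the last
#'   window of each chromosome is truncated at the chromosome end.
#' @export
tile_windows <- function(chrom_lengths, window_size) {
  cl <- as_chrom_lengths(chrom_lengths)
  stopifnot(window_size > 0)
  purrr::map2_dfr(cl$chrom, cl$length, function(cc, L) {
    n <- ceiling(L / window_size)
    s <- (seq_len(n) - 1) * window_size
    tibble::tibble(chrom = cc, start = s, end = pmin(s + window_size, L))
  })
}

as_chrom_lengths <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "length") %in% names(x)))
    tibble::tibble(chrom = as.character(x$chrom), length = as.numeric(x$length))
  } else {
    stopifnot(!is.null(names(x)))
    tibble::tibble(chrom = names(x), length = as.numeric(x))
  }
}

#' Windowed mean recombination rates
#'
#' Tiles each chromosome into non-overlapping windows from position 0 and
#' computes the length-weighted mean rate per window. Windows whose mapped
#' fraction falls below `min_covered_fraction` are flagged and their rate
#' is reported as missing; the terminal partial window is retained with its
#' true span.
#'
#' @param map A `rate_map`.
#' @param window_size Window size in bp (the analyses here use 50 kb,
#'   100 kb, 200 kb and 1 Mb).
#' @param min_covered_fraction Minimum mapped fraction for a window to
#'   receive a rate (default 0.5; use 0 to keep every covered window).
#' @param chrom_lengths Optional chromosome lengths; defaults to each
#'   chromosome's map span end.
#' @param units `"r"` (per-bp per-generation, default) or `"cm_mb"`.
#' @return A window table: `chrom`, `start`, `end`, `rate`, `covered_bp`,
#'   `covered_frac`, `low_coverage`.
#' @export
window_rates <- function(map, window_size, min_covered_fraction = 0.5,
                         chrom_lengths = NULL, units = c("r", "cm_mb")) {
  units <- match.arg(units)
  map <- rate_map(map)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- dplyr::summarise(dplyr::group_by(map, .data$chrom),
                                      length = max(.data$end),
                                      .groups = "drop")
  }
  win <- tile_windows(chrom_lengths, window_size)
  out <- dplyr::group_modify(dplyr::group_by(win, .data$chrom),
    function(d, key) {
      mc <- map[map$chrom == key$chrom, ]
      dplyr::bind_cols(d, weighted_mean_rate_vec(mc, d$start, d$end))
    }) |> dplyr::ungroup()
  out <- dplyr::mutate(out,
    covered_frac = .data$covered_bp / (.data$end - .data$start),
    low_coverage = .data$covered_frac < min_covered_fraction,
    rate = ifelse(.data$low_coverage, NA_real_, .data$mean_rate))
  if (units == "cm_mb") out$rate <- rate_to_cm_per_mb(out$rate)
  dplyr::select(out, "chrom", "start", "end", "rate", "covered_bp",
                "covered_frac", "low_coverage")
}

#' Write a window statistic as BedGraph text
#'
#' @param windows A window table with `chrom`, `start`, `end` and the
#'   column named in `value`.
#' @param path Output path.
#' @param value Name of the value column (default `"rate"`). Missing
#'   values are dropped.
#' @export
write_bedgraph <- function(windows, path, value = "rate") {
  d <- windows[!is.na(windows[[value]]),
               c("chrom", "start", "end", value)]
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}

#' Effective population size from theta
#'
#' Under the standard coalescent `theta = 4 Ne mu`, so `Ne = theta /
#' (4 mu)` (the default, `factor = 4`). `factor = 1` implements the
#' literal `theta / mu` convention used when theta has already been scaled.
#'
#' @param theta Per-site population mutation parameter, `> 0`.
#' @param mu Per-bp per-generation mutation rate (default `4.6e-9`, the
#'   collared flycatcher estimate commonly borrowed for songbirds).
#' @param factor 4 (default) or 1.
#' @return Effective population size.
#' @examples
#' effective_population_size(0.0092) # 5e5
#' @export
effective_population_size <- function(theta, mu = 4.6e-9, factor = 4) {
  if (any(theta <= 0) || any(mu <= 0)) {
    stop("theta and mu must be > 0")
  }
  if (!factor %in% c(1, 4)) stop("factor must be 1 or 4")
  theta / (factor * mu)
}

#' Piecewise-constant demography model
#'
#' @param epochs Tibble/data.frame with `time` (start of epoch, in
#'   generations, strictly increasing from 0) and `ne` (`> 0`).
#' @param mu Per-bp per-generation mutation rate.
#' @return A `demography_model` list.
#' @export
demography_model <- function(epochs, mu = 4.6e-9) {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("time", "ne") %in% names(epochs)))
  if (nrow(epochs) == 0 || epochs$time[1] != 0 ||
      is.unsorted(epochs$time, strictly = TRUE)) {
    stop("epoch times must strictly increase from 0")
  }
  if (any(epochs$ne <= 0)) stop("Ne must be > 0")
  if (mu <= 0) stop("mu must be > 0")
  structure(list(epochs = epochs, mu = mu), class = "demography_model")
}

#' @rdname demography_model
#' @param path Two-column whitespace-separated text (generation, Ne).
#' @export
read_demography <- function(path, mu = 4.6e-9) {
  d <- utils::read.table(path, col.names = c("time", "ne"))
  demography_model(tibble::as_tibble(d), mu = mu)
}

#' Time-averaged effective population size
#'
#' Averages a piecewise-constant Ne trajectory over `[0, t_max]`
#' generations, weighting each epoch by its duration.
#'
#' @param dem A `demography_model`.
#' @param t_max Upper time bound in generations (default: last breakpoint).
#' @export
time_averaged_ne <- function(dem, t_max = NULL) {
  stopifnot(inherits(dem, "demography_model"))
  e <- dem$epochs
  if (is.null(t_max)) t_max <- max(e$time)
  if (t_max <= 0) return(e$ne[1])
  bounds <- c(e$time, Inf)
  dur <- pmin(bounds[-1], t_max) - pmin(e$time, t_max)
  sum(e$ne * dur) / sum(dur)
}

#' Per-chromosome recombination summaries
#'
#' For each chromosome: the length-weighted mean rate `r`, its cM/Mb
#' equivalent, total genetic map length (100 * integral of r), expected
#' crossovers per meiosis (`mean r * length`), the population-scaled rate
#' `rho = 4 Ne r`, and a micro/macro class (`micro` iff length below
#' `micro_threshold`; avian microchromosomes are conventionally < 20 Mb).
#'
#' @param map A `rate_map` (one or many chromosomes).
#' @param chrom_lengths Named vector or tibble (`chrom`, `length`); must be
#'   at least each chromosome's map span.
#' @param theta Per-site theta used for Ne (optional; `rho`/`ne` are `NA`
#'   without it).
#' @param mu Mutation rate for [effective_population_size()].
#' @param ne_factor Passed to [effective_population_size()].
#' @param micro_threshold Length below which a chromosome is `micro` (bp).
#' @return One tibble row per chromosome.
#' @export
chromosome_summary <- function(map, chrom_lengths, theta = NULL,
                               mu = 4.6e-9, ne_factor = 4,
                               micro_threshold = 20e6) {
  map <- rate_map(map)
  cl <- as_chrom_lengths(chrom_lengths)
  span <- dplyr::summarise(dplyr::group_by(map, .data$chrom),
                           span = max(.data$end), .groups = "drop")
  chk <- dplyr::inner_join(span, cl, by = "chrom")
  if (any(chk$length < chk$span)) {
    stop("chromosome length smaller than map span for ",
         chk$chrom[chk$length < chk$span][1])
  }
  if (!is.null(theta) && any(theta <= 0)) stop("theta must be > 0")
  ne <- if (is.null(theta)) NA_real_ else {
    effective_population_size(theta, mu, ne_factor)
  }
  per <- dplyr::summarise(dplyr::group_by(map, .data$chrom),
    mapped_bp = sum(.data$end - .data$start),
    map_length_cm = 100 * sum(.data$rate * (.data$end - .data$start)),
    .groups = "drop")
  out <- dplyr::inner_join(cl, per, by = "chrom")
  dplyr::mutate(out,
    mean_rate = .data$map_length_cm / 100 / .data$mapped_bp,
    rate_cm_mb = rate_to_cm_per_mb(.data$mean_rate),
    expected_co = .data$mean_rate * .data$length,
    ne = ne,
    rho = 4 * ne * .data$mean_rate,
    class = ifelse(.data$length < micro_threshold, "micro", "macro"))
}
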