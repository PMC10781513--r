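# Brute-force oracles and small fixture builders shared across tests.

# Random piecewise-constant map on one chromosome of span <= max_span,
# with gaps.
random_toy_map <- function(span = 10000, n_pieces = 8, gap_prob = 0.3,
                           chrom = "toy") {
  br <- sort(sample(seq_len(span - 1), n_pieces - 1))
  starts <- c(0, br)
  ends <- c(br, span)
  keep <- stats::runif(n_pieces) > gap_prob
  if (!any(keep)) keep[1] <- TRUE
  rate_map(tibble::tibble(chrom = chrom, start = starts[keep],
                          end = ends[keep],
                          rate = stats::runif(sum(keep), 0, 1e-7)))
}

# Per-base expansion of a map: vector of rates indexed by position 1..span,
# NA in gaps. The explicit loop-style oracle for interval arithmetic.
per_base_rates <- function(map_chr, span) {
  v <- rep(NA_real_, span)
  for (i in seq_len(nrow(map_chr))) {
    v[(map_chr$start[i] + 1):map_chr$end[i]] <- map_chr$rate[i]
  }
  v
}

# Oracle mean over [start, end) from the per-base vector.
per_base_mean <- function(v, start, end) {
  if (start >= length(v)) return(NA_real_)
  seg <- v[(start + 1):min(end, length(v))]
  if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
}

# O(n^2) enumeration oracle for Kendall tau-b.
tau_b_enum <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx * dy > 0) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Exact two-sided Wilcoxon p by full enumeration of group labelings.
wilcox_p_enum <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[1:na]) - na * (na + 1) / 2
  us <- apply(utils::combn(n, na), 2, function(idx) {
    sum(r[idx]) - na * (na + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# A small deterministic feature tibble.
toy_features <- function(chrom = "toy") {
  feature_table(tibble::tibble(
    chrom = chrom,
    start = c(1000, 4000, 7000),
    end = c(2000, 5500, 7400),
    strand = c("+", "-", "+"),
    category = "gene",
    id = paste0("g", 1:3)))
}

# Scaled-down simulation config for fast unit tests.
test_sim_config <- function(...) {
  sim_config(chrom_lengths = c(chrA = 3e6, chrB = 2.4e6, chrC = 9e5,
                               chrD = 6e5),
             micro_threshold = 1e6,
             telomere_width = 2e5, terminal_drop_width = 3e4,
             segment = 5e3, ...)
}
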