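#' Configuration for the synthetic recombination landscape
#'
#' Defaults emulate an avian-like genome at desk scale: eight chromosomes
#' spanning macro (>= 20 Mb) and micro (< 20 Mb) sizes, a size-dependent
#' baseline rate (`base_rate * (L / ref_length)^-beta`), telomeric rate
#' elevation with a sharp terminal drop, central recombination deserts on
#' macrochromosomes, CpG-island/promoter-linked local rate boosts, a
#' LINE-in-promoter rate coupling, multiplicative log-normal noise, GC and
#' nucleotide-diversity tracks coupled to the rate landscape, and a
#' correlated sister-species map.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param micro_threshold Micro/macro boundary in bp.
#' @param base_rate Baseline per-bp per-generation rate at `ref_length`.
#' @param ref_length Reference length for the size scaling.
#' @param beta Size exponent (baseline proportional to `length^-beta`).
#' @param micro_boost Extra multiplicative boost on microchromosomes.
#' @param telomere_boost,telomere_width Rate multiplier and width (bp) of
#'   the elevated subtelomeric zone.
#' @param terminal_drop_factor,terminal_drop_width Multiplier and width of
#'   the depressed terminal tip inside the telomeric zone.
#' @param desert_factor,desert_width_frac Multiplier and fractional width
#'   of the central desert (macrochromosomes only).
#' @param feature_rate_coupling Exponent coupling CpG-island and gene
#'   placement intensity to the rate shape field (0 = uniform placement).
#' @param cpgi_boost,promoter_boost Local rate multipliers on CpG islands
#'   and promoters.
#' @param rt_per_mb Named per-family retrotransposon placements per Mb.
#' @param rt_length Named list of (min, max) RT lengths in bp.
#' @param rt_promoter_boost Named rate multipliers applied over promoters
#'   that overlap the family (the planted RT-rate coupling).
#' @param noise_sd SD of the multiplicative log-normal rate noise.
#' @param segment Rate-map segment size in bp (noise resolution).
#' @param genes_per_mb,gene_length Gene density and length range.
#' @param cpgi_per_mb,cpgi_length CpG-island density and length range.
#' @param promoter_cpgi_fraction Fraction of genes given a promoter CpGi.
#' @param gc_base,gc_amp,gc_window Mean GC, its amplitude along the
#'   (standardised log) rate shape, and the GC window size.
#' @param sister_rho Per-chromosome log-scale correlation of the sister
#'   map (scalar or named vector, in [0, 1]).
#' @param pi_a,pi_b,pi_noise_sd Diversity coupling `pi = a + b * r` plus
#'   Gaussian noise, truncated at `1e-5`.
#' @param n_samples Diploid sample count for the synthetic VCF.
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 40e6, chr2 = 32e6,
                                         chr3 = 25e6, chr4 = 21e6,
                                         chr5 = 12e6, chr6 = 8e6,
                                         chr7 = 5e6, chr8 = 2e6),
                       micro_threshold = 20e6,
                       base_rate = 3e-8, ref_length = 20e6, beta = 0.5,
                       micro_boost = 1,
                       telomere_boost = 4, telomere_width = 1e6,
                       terminal_drop_factor = 0.2,
                       terminal_drop_width = 1e5,
                       desert_factor = 0.15, desert_width_frac = 0.25,
                       feature_rate_coupling = 1,
                       cpgi_boost = 2, promoter_boost = 1.5,
                       rt_per_mb = c(LINE = 60, LTR = 15, SINE = 20),
                       rt_length = list(LINE = c(500, 5000),
                                        LTR = c(1000, 8000),
                                        SINE = c(100, 300)),
                       rt_promoter_boost = c(LINE = 2, LTR = 1, SINE = 1),
                       noise_sd = 0.4, segment = 10e3,
                       genes_per_mb = 6, gene_length = c(5e3, 5e4),
                       cpgi_per_mb = 10, cpgi_length = c(300, 1500),
                       promoter_cpgi_fraction = 0.5,
                       gc_base = 0.42, gc_amp = 0.03, gc_window = 200e3,
                       sister_rho = 0.8,
                       pi_a = 0.001, pi_b = 4e4, pi_noise_sd = 3e-4,
                       n_samples = 10) {
  cfg <- as.list(environment())
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1e3),
            beta >= 0, micro_boost > 0, telomere_boost > 0,
            desert_factor > 0, noise_sd >= 0, pi_b >= 0,
            all(sister_rho >= 0 & sister_rho <= 1))
  structure(cfg, class = "sim_config")
}

# Deterministic multiplicative shape field of one chromosome, as
# piecewise-constant breakpoints + factors (telomeres, terminal drops,
# central desert). Returns tibble(start, end, shape).
shape_field <- function(L, cfg) {
  is_micro <- L < cfg$micro_threshold
  tw <- min(cfg$telomere_width, L / 4)
  dw <- min(cfg$terminal_drop_width, tw / 2)
  br <- c(0, dw, tw, L - tw, L - dw, L)
  fac <- c(cfg$terminal_drop_factor, cfg$telomere_boost, 1,
           cfg$telomere_boost, cfg$terminal_drop_factor)
  d <- tibble::tibble(start = br[-length(br)], end = br[-1], shape = fac)
  if (!is_micro && cfg$desert_factor != 1 && cfg$desert_width_frac > 0) {
    half <- cfg$desert_width_frac * L / 2
    d <- split_field(d, c(L / 2 - half, L / 2 + half))
    mid <- (d$start + d$end) / 2
    inside <- mid > L / 2 - half & mid < L / 2 + half
    d$shape[inside] <- d$shape[inside] * cfg$desert_factor
  }
  d[d$end > d$start, ]
}

# Split a piecewise field at additional breakpoints.
split_field <- function(d, at) {
  at <- sort(unique(at))
  for (x in at) {
    hit <- which(d$start < x & d$end > x)
    if (length(hit) == 1) {
      row <- d[hit, ]
      left <- row; left$end <- x
      right <- row; right$start <- x
      d <- dplyr::bind_rows(d[seq_len(hit - 1), ], left, right,
                            d[-seq_len(hit), ])
    }
  }
  d
}

# Weighted placement of n interval starts along a shape field.
place_weighted <- function(n, field, len_range, L, gamma) {
  if (n <= 0) return(numeric(0))
  w <- (field$shape^gamma) * (field$end - field$start)
  seg <- sample.int(nrow(field), n, replace = TRUE, prob = w)
  starts <- field$start[seg] +
    stats::runif(n) * (field$end[seg] - field$start[seg])
  pmin(pmax(floor(starts), 0), L - len_range[2] - 1)
}

# Drop intervals that overlap a previously kept one (+ min_gap).
thin_intervals <- function(start, end, min_gap = 0) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  keep <- logical(length(start))
  last_end <- -Inf
  for (i in seq_along(start)) {
    if (start[i] >= last_end + min_gap) {
      keep[i] <- TRUE
      last_end <- end[i]
    }
  }
  ord <- integer(length(o)); ord[o] <- seq_along(o)
  keep[ord]
}

#' Simulate genome annotations (genes, CpG islands, retrotransposons)
#'
#' Places genes (with mRNA, exon and UTR sub-features, strands and
#' promoter CpG islands), additional CpG islands, and per-family
#' retrotransposon intervals. Gene and CpG-island placement intensity
#' follows the deterministic rate shape field raised to
#' `feature_rate_coupling`, which is what couples window-level CpGi/gene
#' density to the recombination landscape; RT placement is uniform.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `genes` (feature tibble incl. mRNA/exon/UTR rows),
#'   `cpgi`, `rts`, `chrom_lengths`.
#' @export
simulate_annotations <- function(config, seed) {
  cfg <- config
  set.seed(seed)
  res <- purrr::imap(cfg$chrom_lengths, function(L, cc) {
    field <- shape_field(L, cfg)
    n_gene <- round(cfg$genes_per_mb * L / 1e6)
    gs <- place_weighted(n_gene, field, cfg$gene_length, L,
                         cfg$feature_rate_coupling)
    glen <- floor(stats::runif(n_gene, cfg$gene_length[1],
                               cfg$gene_length[2]))
    keep <- thin_intervals(gs, gs + glen, min_gap = 1000)
    gs <- gs[keep]; glen <- glen[keep]
    strand <- sample(c("+", "-"), length(gs), replace = TRUE)
    genes <- gene_models(cc, gs, gs + glen, strand)
    # CpG islands: promoter-linked + free-standing, shape-coupled
    tssrow <- genes[genes$category == "mRNA", ]
    tpos <- ifelse(tssrow$strand == "+", tssrow$start, tssrow$end - 1)
    prom_sel <- stats::runif(length(tpos)) < cfg$promoter_cpgi_fraction
    plen <- floor(stats::runif(sum(prom_sel), cfg$cpgi_length[1],
                               cfg$cpgi_length[2]))
    pstart <- pmax(0, ifelse(tssrow$strand[prom_sel] == "+",
                             tpos[prom_sel] - 500 - plen,
                             tpos[prom_sel] + 500))
    n_free <- round(cfg$cpgi_per_mb * L / 1e6)
    fs <- place_weighted(n_free, field, cfg$cpgi_length, L,
                         cfg$feature_rate_coupling)
    flen <- floor(stats::runif(n_free, cfg$cpgi_length[1],
                               cfg$cpgi_length[2]))
    cs <- c(pstart, fs); clen <- c(plen, flen)
    keep <- thin_intervals(cs, cs + clen, min_gap = 3000)
    cpgi <- tibble::tibble(chrom = cc, start = cs[keep],
                           end = cs[keep] + clen[keep], strand = "*",
                           category = "CpGi")
    # retrotransposons, uniform placement per family
    rts <- purrr::imap_dfr(as.list(cfg$rt_per_mb), function(rate, fam) {
      n <- round(rate * L / 1e6)
      if (n == 0) return(NULL)
      lr <- cfg$rt_length[[fam]]
      s <- floor(stats::runif(n, 0, L - lr[2] - 1))
      tibble::tibble(chrom = cc, start = s,
                     end = s + floor(stats::runif(n, lr[1], lr[2])),
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     category = fam)
    })
    list(genes = genes, cpgi = cpgi, rts = rts)
  })
  out <- list(
    genes = feature_table(dplyr::bind_rows(purrr::map(res, "genes"))),
    cpgi = feature_table(dplyr::bind_rows(purrr::map(res, "cpgi"))),
    rts = feature_table(dplyr::bind_rows(purrr::map(res, "rts"))),
    chrom_lengths = cfg$chrom_lengths)
  out
}

# Gene + mRNA + exon + UTR rows for one chromosome.
gene_models <- function(cc, start, end, strand) {
  n <- length(start)
  if (n == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          category = character(), id = character(),
                          parent = character()))
  }
  gid <- sprintf("%s_g%04d", cc, seq_len(n))
  mid <- paste0(gid, ".t1")
  len <- end - start
  e1 <- pmax(200, floor(len * 0.1))
  rows <- list(
    tibble::tibble(chrom = cc, start = start, end = end, strand = strand,
                   category = "gene", id = gid, parent = NA_character_),
    tibble::tibble(chrom = cc, start = start, end = end, strand = strand,
                   category = "mRNA", id = mid, parent = gid),
    tibble::tibble(chrom = cc, start = start, end = start + e1,
                   strand = strand, category = "exon",
                   id = paste0(mid, ".e1"), parent = mid),
    tibble::tibble(chrom = cc, start = end - e1, end = end,
                   strand = strand, category = "exon",
                   id = paste0(mid, ".e2"), parent = mid),
    tibble::tibble(chrom = cc,
                   start = ifelse(strand == "+", start, end - 200),
                   end = ifelse(strand == "+", start + 200, end),
                   strand = strand, category = "five_prime_UTR",
                   id = paste0(mid, ".u5"), parent = mid),
    tibble::tibble(chrom = cc,
                   start = ifelse(strand == "+", end - 200, start),
                   end = ifelse(strand == "+", end, start + 200),
                   strand = strand, category = "three_prime_UTR",
                   id = paste0(mid, ".u3"), parent = mid))
  dplyr::bind_rows(rows)
}

#' Simulate a recombination rate map with known truth
#'
#' The per-bp rate is `base(L) * shape(x) * boost(x) * exp(N(0, sd^2))`:
#' a size-dependent baseline, the telomere/terminal-drop/desert shape
#' field, local multiplicative boosts over CpG islands, promoters and
#' promoters overlapping boosted RT families, and segment-level
#' log-normal noise. Emitted as sorted non-overlapping intervals.
#'
#' @param config A [sim_config()].
#' @param annotations Output of [simulate_annotations()].
#' @param seed Integer seed.
#' @return List: `map` (a `rate_map`), `truth` (per-chromosome baselines,
#'   boost bookkeeping and the config).
#' @export
simulate_rate_map <- function(config, annotations, seed) {
  cfg <- config
  set.seed(seed + 1L)
  ann <- annotations
  tss <- derive_tss(ann$genes)
  prom <- derive_promoters(tss, length = 2000,
                           chrom_lengths = ann$chrom_lengths)
  boosted_fams <- names(cfg$rt_promoter_boost)[cfg$rt_promoter_boost != 1]
  maps <- purrr::imap(cfg$chrom_lengths, function(L, cc) {
    base <- cfg$base_rate * (L / cfg$ref_length)^(-cfg$beta) *
      ifelse(L < cfg$micro_threshold, cfg$micro_boost, 1)
    field <- shape_field(L, cfg)
    cp <- ann$cpgi[ann$cpgi$chrom == cc, ]
    pr <- prom[prom$chrom == cc, ]
    # promoters overlapping a boosted RT family
    pr_boost <- rep(1, nrow(pr))
    for (fam in boosted_fams) {
      hit <- overlap_split(pr, ann$rts[ann$rts$chrom == cc, ],
                           family = fam)$overlaps
      pr_boost <- pr_boost * ifelse(hit, cfg$rt_promoter_boost[[fam]], 1)
    }
    br <- sort(unique(c(seq(0, L, by = cfg$segment), L,
                        field$start, field$end,
                        cp$start, cp$end, pr$start, pr$end)))
    br <- br[br >= 0 & br <= L]
    d <- tibble::tibble(start = br[-length(br)], end = br[-1])
    mid <- (d$start + d$end) / 2
    sh <- field$shape[findInterval(mid, field$start)]
    r <- base * sh
    if (nrow(cp) > 0) {
      inc <- IRanges::overlapsAny(
        IRanges::IRanges(mid + 1, mid + 1), as_iranges(cp))
      r <- r * ifelse(inc, cfg$cpgi_boost, 1)
    }
    if (nrow(pr) > 0) {
      ov <- IRanges::findOverlaps(IRanges::IRanges(mid + 1, mid + 1),
                                  as_iranges(pr))
      fac <- rep(1, length(mid))
      qh <- S4Vectors::queryHits(ov)
      fac[qh] <- cfg$promoter_boost * pr_boost[S4Vectors::subjectHits(ov)]
      r <- r * fac
    }
    noise <- stats::rnorm(ceiling(L / cfg$segment) + 1, 0, cfg$noise_sd)
    r <- r * exp(noise[floor(d$start / cfg$segment) + 1])
    tibble::tibble(chrom = cc, start = d$start, end = d$end, rate = r)
  })
  map <- rate_map(dplyr::bind_rows(maps))
  truth <- list(
    config = cfg,
    base_rate = purrr::imap_dbl(cfg$chrom_lengths, function(L, cc) {
      cfg$base_rate * (L / cfg$ref_length)^(-cfg$beta) *
        ifelse(L < cfg$micro_threshold, cfg$micro_boost, 1)
    }),
    class = ifelse(cfg$chrom_lengths < cfg$micro_threshold,
                   "micro", "macro"),
    boosted_families = boosted_fams)
  list(map = map, truth = truth)
}

#' Simulate a correlated sister-species map
#'
#' Per chromosome, the sister's log rate is `rho * z + sqrt(1 - rho^2) *
#' eps` on the standardised log scale (`z` the focal map's standardised
#' log rate, `eps` independent standard normal), rescaled back to the
#' focal chromosome's log mean and sd (or a supplied target mean). The
#' interval structure is preserved.
#'
#' @param map A `rate_map`.
#' @param rho Scalar or per-chromosome named vector in [0, 1].
#' @param seed Integer seed.
#' @param target_mean Optional per-chromosome named vector of sister mean
#'   rates.
#' @return A `rate_map` for the sister species.
#' @export
simulate_sister_map <- function(map, rho, seed, target_mean = NULL) {
  map <- rate_map(map)
  set.seed(seed + 2L)
  out <- dplyr::group_modify(dplyr::group_by(map, .data$chrom),
    function(d, key) {
      rc <- if (length(rho) == 1) rho else rho[[key$chrom]]
      stopifnot(rc >= 0, rc <= 1)
      lg <- log(pmax(d$rate, 1e-300))
      mu <- mean(lg); sdv <- stats::sd(lg)
      z <- if (sdv > 0) (lg - mu) / sdv else rep(0, length(lg))
      zb <- rc * z + sqrt(1 - rc^2) * stats::rnorm(length(z))
      mu_b <- if (!is.null(target_mean)) {
        log(target_mean[[key$chrom]])
      } else mu
      d$rate <- exp(mu_b + sdv * zb)
      d
    }) |> dplyr::ungroup()
  rate_map(out)
}

#' Simulate sequence for a chromosome set
#'
#' Draws bases with per-window GC targets tied to the rate shape field
#' (`gc = gc_base + gc_amp * standardised log mean shape`), then plants
#' each annotated CpG island as a dense CG run over its interval so that
#' the island detector can recover it.
#'
#' @param config A [sim_config()].
#' @param annotations Output of [simulate_annotations()].
#' @param seed Integer seed.
#' @param chromosomes Subset of chromosome names (default: all).
#' @return A named `Biostrings::DNAStringSet`.
#' @export
simulate_sequence <- function(config, annotations, seed,
                              chromosomes = NULL) {
  cfg <- config
  cls <- cfg$chrom_lengths
  if (!is.null(chromosomes)) cls <- cls[chromosomes]
  seqs <- purrr::imap(cls, function(L, cc) {
    i <- match(cc, names(cfg$chrom_lengths))
    set.seed(seed + 131L * i + 7L)
    field <- shape_field(L, cfg)
    ws <- (seq_len(ceiling(L / cfg$gc_window)) - 1) * cfg$gc_window
    we <- pmin(ws + cfg$gc_window, L)
    msh <- log(vapply(seq_along(ws), function(j) {
      ov <- pmax(0, pmin(field$end, we[j]) - pmax(field$start, ws[j]))
      sum(field$shape * ov) / sum(ov)
    }, numeric(1)))
    zz <- if (stats::sd(msh) > 0) (msh - mean(msh)) / stats::sd(msh)
          else rep(0, length(msh))
    gcw <- pmin(0.7, pmax(0.25, cfg$gc_base + cfg$gc_amp * zz))
    gc_at <- rep(gcw, times = round(we - ws))
    isgc <- stats::runif(L) < gc_at
    pick <- stats::runif(L) < 0.5
    bytes <- raw(L)
    bytes[isgc & pick] <- as.raw(71L)   # G
    bytes[isgc & !pick] <- as.raw(67L)  # C
    bytes[!isgc & pick] <- as.raw(65L)  # A
    bytes[!isgc & !pick] <- as.raw(84L) # T
    # plant CpG islands as CG runs
    cp <- annotations$cpgi[annotations$cpgi$chrom == cc, ]
    if (nrow(cp) > 0) {
      for (j in seq_len(nrow(cp))) {
        idx <- (cp$start[j] + 1):min(cp$end[j], L)
        bytes[idx] <- rep(as.raw(c(67L, 71L)),
                          length.out = length(idx))
        # break background CpGs in the immediate flanks so the planted
        # island keeps crisp boundaries
        for (fl in list(c(max(1, cp$start[j] - 150), cp$start[j]),
                        c(min(cp$end[j] + 1, L),
                          min(cp$end[j] + 151, L)))) {
          if (fl[2] > fl[1]) {
            seg <- fl[1]:(fl[2] - 1)
            cg <- seg[bytes[seg] == as.raw(67L) &
                        bytes[seg + 1] == as.raw(71L)]
            bytes[cg + 1] <- as.raw(65L)
          }
        }
      }
    }
    rawToChar(bytes)
  })
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Simulate a genome bundle (annotations + sequence + files)
#'
#' Convenience wrapper producing cross-consistent FASTA, GFF3 and BED
#' outputs from one seed. With the same config and seed the files are
#' byte-identical across runs.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param sequence Generate FASTA sequence (can be restricted via
#'   `chromosomes` to bound run time on large configs).
#' @param chromosomes Chromosome subset for sequence generation.
#' @return List: `annotations`, `genome` (`DNAStringSet` or `NULL`),
#'   `paths` (written files).
#' @export
simulate_genome <- function(config, seed, dir = NULL, sequence = TRUE,
                            chromosomes = NULL) {
  ann <- simulate_annotations(config, seed)
  genome <- if (sequence) {
    simulate_sequence(config, ann, seed, chromosomes = chromosomes)
  } else NULL
  paths <- character(0)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p_gff <- file.path(dir, "annotation.gff3")
    write_gff3(ann$genes, p_gff)
    p_cpgi <- file.path(dir, "cpgi.bed")
    write_bed(ann$cpgi, p_cpgi)
    p_rt <- file.path(dir, "retrotransposons.bed")
    write_bed(ann$rts, p_rt)
    paths <- c(gff3 = p_gff, cpgi = p_cpgi, rts = p_rt)
    if (!is.null(genome)) {
      p_fa <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(genome, p_fa, width = 80)
      paths <- c(paths, fasta = p_fa)
    }
  }
  list(annotations = ann, genome = genome, paths = paths)
}

#' Write features as GFF3 (1-based inclusive)
#' @param features Feature tibble (with optional `parent` column).
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  f <- features
  attrs <- paste0("ID=", f$id)
  if ("parent" %in% names(f)) {
    has_par <- !is.na(f$parent)
    attrs[has_par] <- paste0(attrs[has_par], ";Parent=", f$parent[has_par])
  }
  lines <- paste(f$chrom, "recland", f$category,
                 format(f$start + 1, scientific = FALSE, trim = TRUE),
                 format(f$end, scientific = FALSE, trim = TRUE),
                 ".", ifelse(f$strand %in% c("+", "-"), f$strand, "."),
                 ".", attrs, sep = "\t")
  readr::write_lines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Simulate nucleotide-diversity data as a VCF plus callable mask
#'
#' Per 200 kb window the target diversity is `pi_a + pi_b * rate +
#' N(0, pi_noise_sd)`, truncated below at 1e-5. Biallelic SNPs are placed
#' so that the unbiased per-site heterozygosity summed over the window
#' matches the target in expectation: allele counts follow a neutral-like
#' `1/i` frequency spectrum across `2 n_samples` haplotypes, and the
#' per-window site count is `target * window_bp / E[site contribution]`.
#'
#' @param map A `rate_map` (rates in r units).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param chromosomes Chromosome subset (VCF emission cost scales with
#'   genome size; default: all map chromosomes).
#' @param path Output VCF path (default: tempfile).
#' @param window Window size for the diversity coupling (default 200 kb).
#' @return List: `vcf` (path), `callable` (interval tibble), `targets`
#'   (window table with `target_pi`).
#' @export
simulate_diversity <- function(map, config, seed, chromosomes = NULL,
                               path = NULL, window = 200e3) {
  cfg <- config
  map <- rate_map(map)
  if (!is.null(chromosomes)) map <- map[map$chrom %in% chromosomes, ]
  set.seed(seed + 3L)
  if (is.null(path)) path <- tempfile(fileext = ".vcf")
  n_hap <- 2L * cfg$n_samples
  i_all <- seq_len(n_hap - 1)
  q <- (1 / i_all) / sum(1 / i_all)
  p_i <- i_all / n_hap
  e_contrib <- sum(q * 2 * p_i * (1 - p_i) * n_hap / (n_hap - 1))
  wr <- window_rates(map, window, min_covered_fraction = 0)
  wr$target_pi <- pmax(1e-5, cfg$pi_a + cfg$pi_b *
                         ifelse(is.na(wr$rate), 0, wr$rate) +
                         stats::rnorm(nrow(wr), 0, cfg$pi_noise_sd))
  sites <- purrr::map_dfr(seq_len(nrow(wr)), function(i) {
    L <- wr$end[i] - wr$start[i]
    ns <- round(wr$target_pi[i] * L / e_contrib)
    if (ns <= 0) return(NULL)
    pos <- sort(sample.int(L, min(ns, L), replace = FALSE)) + wr$start[i]
    tibble::tibble(chrom = wr$chrom[i], pos = pos,
                   alt_count = sample(i_all, length(pos), replace = TRUE,
                                      prob = q))
  })
  # genotypes: distribute alt alleles over random haplotypes per site
  gt_rows <- vapply(seq_len(nrow(sites)), function(j) {
    hap <- integer(n_hap)
    hap[sample.int(n_hap, sites$alt_count[j])] <- 1L
    paste(paste0(hap[seq(1, n_hap, by = 2)], "/",
                 hap[seq(2, n_hap, by = 2)]), collapse = "\t")
  }, character(1))
  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  header <- c("##fileformat=VCFv4.2",
              "##source=recland-simulate",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  body <- paste(sites$chrom, format(sites$pos + 1, scientific = FALSE,
                                    trim = TRUE),
                ".", "A", "G", ".", "PASS", ".", "GT", gt_rows, sep = "\t")
  readr::write_lines(c(header, body), path)
  callable <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(wr),
                                               .data$chrom),
                               start = min(.data$start),
                               end = max(.data$end), .groups = "drop")
  list(vcf = path, callable = callable,
       targets = wr[c("chrom", "start", "end", "rate", "target_pi")])
}

#' Serialise generator truth alongside outputs
#' @param truth The `truth` element of [simulate_rate_map()].
#' @param path Output JSON path.
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
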