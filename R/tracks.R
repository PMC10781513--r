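#' Windowed GC content
#'
#' Fraction (G + C) / (A + C + G + T) per window, case-insensitive;
#' ambiguity codes and N are excluded from the denominator. A window with
#' no unambiguous base is missing.
#'
#' @param genome A `Biostrings::DNAStringSet`, a named character vector of
#'   sequences, or a FASTA path.
#' @param windows Window table (`chrom`, `start`, `end`).
#' @return `windows` with `gc` and `gc_support` (unambiguous bp) columns.
#' @export
gc_content_windows <- function(genome, windows) {
  genome <- as_genome(genome)
  dplyr::group_modify(dplyr::group_by(tibble::as_tibble(windows),
                                      .data$chrom),
    function(d, key) {
      if (!key$chrom %in% names(genome)) {
        d$gc <- NA_real_
        d$gc_support <- 0
        return(d)
      }
      seq <- genome[[key$chrom]]
      v <- Biostrings::Views(seq, start = d$start + 1,
                             end = pmin(d$end, length(seq)))
      f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
      tot <- rowSums(f)
      d$gc <- ifelse(tot > 0, (f[, "C"] + f[, "G"]) / tot, NA_real_)
      d$gc_support <- tot
      d
    }) |> dplyr::ungroup()
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    stopifnot(!is.null(names(genome)))
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("cannot interpret `genome`")
}

#' Windowed nucleotide diversity from a VCF
#'
#' Per window, pi is the sum over biallelic SNP sites of the unbiased
#' per-site heterozygosity `2 p (1 - p) n / (n - 1)` (with `p` the
#' alternate-allele frequency among non-missing alleles and `n` the
#' non-missing allele count), divided by the callable base count of the
#' window. Sites absent from the VCF but inside the callable mask are
#' monomorphic and contribute zero to the numerator while remaining in the
#' denominator.
#'
#' A window is missing when its callable span is below `min_called_bp`, or
#' when fewer than `min_data_fraction` of the individuals have adequate
#' data there. Per-individual support is approximated as the callable span
#' times the individual's genotype call rate at the window's variant sites
#' (1 when the window has no variants).
#'
#' @param vcf Path to a VCF, or a `vcfR` object.
#' @param windows Window table (`chrom`, `start`, `end`).
#' @param callable Optional interval tibble (`chrom`, `start`, `end`) of
#'   callable positions. Defaults to the full window spans, with a warning,
#'   which is only appropriate for synthetic data with no missing sites.
#' @param min_called_bp Minimum callable bp per window (default 20000,
#'   the convention for 200 kb windows).
#' @param min_data_fraction Minimum fraction of individuals with
#'   `min_called_bp` of support in the window (default 0.7).
#' @return `windows` with `pi`, `callable_bp` and `n_sites` columns.
#' @export
pi_windows <- function(vcf, windows, callable = NULL,
                       min_called_bp = 20000, min_data_fraction = 0.7) {
  v <- as_vcf_tbl(vcf)
  if (is.null(callable)) {
    warning("no callable mask supplied; assuming all window positions ",
            "are callable")
    callable <- tibble::as_tibble(windows)[c("chrom", "start", "end")]
  }
  win <- tibble::as_tibble(windows)
  dplyr::group_modify(dplyr::group_by(win, .data$chrom), function(d, key) {
    cb <- callable[callable$chrom == key$chrom, ]
    site <- v[v$chrom == key$chrom, ]
    # callable bp per window via interval clipping
    d$callable_bp <- vapply(seq_len(nrow(d)), function(i) {
      sum(pmax(0, pmin(cb$end, d$end[i]) - pmax(cb$start, d$start[i])))
    }, numeric(1))
    wi <- findInterval(site$pos, d$start)
    ok <- wi >= 1 & site$pos < d$end[pmax(wi, 1)]
    num <- rep(0, nrow(d))
    nsit <- rep(0L, nrow(d))
    callrate <- rep(1, nrow(d))
    if (any(ok)) {
      s <- site[ok, ]
      w <- wi[ok]
      agg <- tapply(s$het, w, sum)
      num[as.integer(names(agg))] <- agg
      cnt <- table(w)
      nsit[as.integer(names(cnt))] <- as.integer(cnt)
      # per-individual call-rate floor, averaged into a fraction of
      # individuals meeting min_called_bp of support
      gt_ok <- s$gt_called   # sites x individuals logical matrix
      for (iw in unique(w)) {
        rows <- which(w == iw)
        ind_rate <- colMeans(gt_ok[rows, , drop = FALSE])
        ind_bp <- ind_rate * d$callable_bp[iw]
        callrate[iw] <- mean(ind_bp >= min_called_bp)
      }
    }
    d$n_sites <- nsit
    d$pi <- ifelse(d$callable_bp >= min_called_bp &
                     callrate >= min_data_fraction,
                   num / d$callable_bp, NA_real_)
    d
  }) |> dplyr::ungroup()
}

# Normalise VCF input to a per-site tibble with the quantities pi needs:
# chrom, pos (0-based), het = 2p(1-p)n/(n-1), gt_called matrix attribute.
as_vcf_tbl <- function(vcf) {
  if (is.character(vcf)) {
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  }
  stopifnot(inherits(vcf, "vcfR"))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no genotypes")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  alt <- fix[, "ALT"]
  biall <- !is.na(alt) & !grepl(",", alt) &
    nchar(fix[, "REF"]) == 1 & nchar(alt) == 1
  gt <- gt[biall, , drop = FALSE]
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  called1 <- a1 %in% c("0", "1")
  called2 <- a2 %in% c("0", "1")
  dim(called1) <- dim(called2) <- dim(gt)
  altc <- (a1 == "1") + (a2 == "1")
  dim(altc) <- dim(gt)
  altc[!(called1 & called2)] <- NA
  n_all <- rowSums(called1 & called2) * 2
  n_alt <- rowSums(altc, na.rm = TRUE)
  p <- ifelse(n_all > 0, n_alt / n_all, NA_real_)
  het <- ifelse(n_all > 1, 2 * p * (1 - p) * n_all / (n_all - 1), 0)
  out <- tibble::tibble(chrom = as.character(fix[biall, "CHROM"]),
                        pos = as.numeric(fix[biall, "POS"]) - 1,
                        het = het)
  out$gt_called <- called1 & called2
  out
}

#' Per-position k-mer uniqueness flags
#'
#' A position is unique when the forward k-mer starting there occurs
#' exactly once among all forward k-mers of the whole genome. K-mers
#' containing ambiguous bases, and the trailing `k - 1` positions of each
#' sequence, are undefined (`NA`).
#'
#' @param genome As in [gc_content_windows()].
#' @param k K-mer length (default 16, minimum 8).
#' @return Named list of logical vectors (one per sequence): `TRUE`
#'   unique, `FALSE` repeated, `NA` undefined.
#' @export
unique_kmer_index <- function(genome, k = 16) {
  stopifnot(k >= 8)
  genome <- as_genome(genome)
  seqs <- lapply(seq_along(genome), function(i) {
    as.character(genome[[i]])
  })
  names(seqs) <- names(genome)
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1), k:L)
  })
  all_k <- unlist(kmers, use.names = FALSE)
  dup <- duplicated(all_k) | duplicated(all_k, fromLast = TRUE)
  off <- 0
  out <- lapply(seq_along(seqs), function(i) {
    L <- nchar(seqs[[i]])
    nk <- max(0, L - k + 1)
    flags <- rep(NA, L)
    if (nk > 0) {
      f <- !dup[(off + 1):(off + nk)]
      amb <- grepl("[^ACGT]", kmers[[i]])
      f[amb] <- NA
      flags[1:nk] <- f
    }
    off <<- off + nk
    flags
  })
  names(out) <- names(seqs)
  out
}

#' Windowed sequence-uniqueness complexity
#'
#' A [0, 1] uniqueness proxy for sequence complexity: the fraction of
#' defined k-mer start positions in each window whose k-mer is
#' genome-unique. 1 means fully unique sequence, 0 fully repeated.
#'
#' @param flags Output of [unique_kmer_index()].
#' @param windows Window table.
#' @return `windows` with `complexity` and `complexity_support` columns.
#' @export
complexity_windows <- function(flags, windows) {
  dplyr::group_modify(dplyr::group_by(tibble::as_tibble(windows),
                                      .data$chrom),
    function(d, key) {
      f <- flags[[key$chrom]]
      if (is.null(f)) {
        d$complexity <- NA_real_
        d$complexity_support <- 0
        return(d)
      }
      d$complexity <- vapply(seq_len(nrow(d)), function(i) {
        seg <- f[(d$start[i] + 1):min(d$end[i], length(f))]
        if (all(is.na(seg))) NA_real_ else mean(seg, na.rm = TRUE)
      }, numeric(1))
      d$complexity_support <- vapply(seq_len(nrow(d)), function(i) {
        seg <- f[(d$start[i] + 1):min(d$end[i], length(f))]
        sum(!is.na(seg))
      }, numeric(1))
      d
    }) |> dplyr::ungroup()
}
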