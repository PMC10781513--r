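#' Feature tables
#'
#' Genomic features are plain tibbles with columns `chrom`, `start`, `end`
#' (0-based half-open), `strand` (`"+"`, `"-"` or `"*"`), `category` and
#' `id`. Categories come from a controlled vocabulary covering gene
#' structure, regulatory anchors, CpG islands and retrotransposon families.
#'
#' @param x A data frame carrying at least `chrom`, `start`, `end`.
#' @param category Category label to assign when `x` has none.
#' @return A validated feature tibble.
#' @export
feature_table <- function(x, category = NULL) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (!"strand" %in% names(x)) x$strand <- "*"
  if (!"category" %in% names(x)) {
    x$category <- if (is.null(category)) "feature" else category
  }
  if (!"id" %in% names(x)) x$id <- paste0(x$category, "_", seq_len(nrow(x)))
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$strand[is.na(x$strand) | !x$strand %in% c("+", "-")] <- "*"
  if (any(x$end <= x$start)) {
    stop("feature with end <= start at row ", which(x$end <= x$start)[1])
  }
  dplyr::arrange(x[c("chrom", "start", "end", "strand", "category", "id")],
                 .data$chrom, .data$start)
}

feature_vocabulary <- c(
  "gene", "mRNA", "exon", "five_prime_UTR", "three_prime_UTR", "TSS",
  "promoter", "promoter_with_CpGi", "promoter_without_CpGi", "CpGi",
  "intergenic", "LTR", "LINE", "SINE")

#' Read genomic features from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) coordinates are
#' both normalised to the internal 0-based half-open convention. GFF3
#' `type` values are mapped onto the package vocabulary; unrecognised
#' types are dropped with a message.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param category Category to assign to BED records (default: file stem).
#' @return A feature tibble.
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed"),
                          category = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3"
              else "bed"
  }
  if (format == "gff3") {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      g <- tibble::as_tibble(rtracklayer::readGFF(
        path, columns = c("seqid", "type", "start", "end", "strand"),
        tags = c("ID", "Parent")))
      g$ID <- as.character(g$ID)
      par <- vapply(g$Parent, function(p) {
        if (length(p) == 0) NA_character_ else as.character(p[[1]])
      }, character(1))
    } else {
      raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                               quote = "", stringsAsFactors = FALSE)
      g <- tibble::tibble(seqid = raw[[1]], type = raw[[3]],
                          start = raw[[4]], end = raw[[5]],
                          strand = raw[[7]])
      g$ID <- stringr::str_match(raw[[9]], "ID=([^;]+)")[, 2]
      par <- stringr::str_match(raw[[9]], "Parent=([^;]+)")[, 2]
    }
    if (any(g$end < g$start)) {
      stop("GFF3 record with end < start at row ",
           which(g$end < g$start)[1])
    }
    keep <- as.character(g$type) %in% feature_vocabulary
    if (any(!keep)) {
      message("dropping ", sum(!keep), " GFF3 record(s) of unhandled type")
    }
    g <- g[keep, ]
    par <- par[keep]
    out <- tibble::tibble(
      chrom = as.character(g$seqid),
      start = g$start - 1,        # 1-based inclusive -> 0-based half-open
      end = as.numeric(g$end),
      strand = as.character(g$strand),
      category = as.character(g$type),
      id = ifelse(is.na(g$ID) | g$ID == "",
                  paste0(as.character(g$type), "_", seq_len(nrow(g))), g$ID),
      parent = par)
    feature_table(out)
  } else {
    d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (is.null(category)) {
      category <- sub("\\.bed$", "", basename(path), ignore.case = TRUE)
    }
    out <- tibble::tibble(chrom = as.character(d[[1]]),
                          start = as.numeric(d[[2]]),
                          end = as.numeric(d[[3]]),
                          strand = if (ncol(d) >= 6) d[[6]] else "*",
                          category = category,
                          id = if (ncol(d) >= 4 && !is.numeric(d[[4]]))
                                 as.character(d[[4]])
                               else paste0(category, "_", seq_len(nrow(d))))
    if (any(out$end <= out$start)) {
      stop("BED record with end <= start at row ",
           which(out$end <= out$start)[1])
    }
    feature_table(out)
  }
}

#' Write features as BED (0-based half-open)
#' @param features Feature tibble.
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  d <- tibble::tibble(chrom = features$chrom,
                      start = format(features$start, scientific = FALSE,
                                     trim = TRUE),
                      end = format(features$end, scientific = FALSE,
                                   trim = TRUE),
                      name = features$id,
                      score = 0L,
                      strand = ifelse(features$strand %in% c("+", "-"),
                                      features$strand, "."))
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(path)
}

# IRanges view of one chromosome's features.
as_iranges <- function(d) {
  IRanges::IRanges(start = d$start + 1, end = d$end)
}

#' Transcription start sites from mRNA features
#'
#' One 1-bp TSS per mRNA: the first transcribed base, i.e. `start` on the
#' `+` strand and `end - 1` on the `-` strand. Identical (chrom, position,
#' strand) TSS across isoforms are collapsed. Features with unknown strand
#' are treated as `+` with a warning.
#'
#' @param genes Feature tibble containing `mRNA` rows (falls back to
#'   `gene` rows when no mRNA is annotated).
#' @return Feature tibble of category `TSS`.
#' @export
derive_tss <- function(genes) {
  m <- genes[genes$category == "mRNA", ]
  if (nrow(m) == 0) m <- genes[genes$category == "gene", ]
  if (nrow(m) == 0) stop("no mRNA or gene features to derive TSS from")
  unk <- !m$strand %in% c("+", "-")
  if (any(unk)) {
    warning(sum(unk), " feature(s) with unknown strand treated as '+'")
    m$strand[unk] <- "+"
  }
  pos <- ifelse(m$strand == "+", m$start, m$end - 1)
  out <- tibble::tibble(chrom = m$chrom, start = pos, end = pos + 1,
                        strand = m$strand, category = "TSS", id = m$id)
  out <- dplyr::distinct(out, .data$chrom, .data$start, .data$strand,
                         .keep_all = TRUE)
  feature_table(out)
}

#' Promoters upstream of TSS
#'
#' The promoter is the `length` bp immediately upstream of each TSS
#' (`[tss - length, tss)` on `+`, mirrored on `-`), clipped to chromosome
#' bounds. When a CpG-island set is supplied, promoters are labelled
#' `promoter_with_CpGi` or `promoter_without_CpGi` by >= 1 bp overlap.
#'
#' @param tss Output of [derive_tss()].
#' @param length Promoter length in bp (default 2000).
#' @param cpgi Optional CpG-island feature tibble.
#' @param chrom_lengths Optional lengths used to clip on the right.
#' @return Feature tibble of promoters.
#' @export
derive_promoters <- function(tss, length = 2000, cpgi = NULL,
                             chrom_lengths = NULL) {
  stopifnot(nrow(tss) > 0)
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$start - length, tss$start + 1)
  end <- ifelse(plus, tss$start, tss$start + 1 + length)
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths)) {
    cl <- as_chrom_lengths(chrom_lengths)
    end <- pmin(end, cl$length[match(tss$chrom, cl$chrom)])
  }
  keep <- end > start
  out <- tibble::tibble(chrom = tss$chrom[keep], start = start[keep],
                        end = end[keep], strand = tss$strand[keep],
                        category = "promoter", id = tss$id[keep])
  if (!is.null(cpgi) && nrow(out) > 0) {
    out <- overlap_split(out, cpgi)
    out$category <- ifelse(out$overlaps, "promoter_with_CpGi",
                           "promoter_without_CpGi")
    out$overlaps <- NULL
  }
  feature_table(out)
}

#' Intergenic regions
#'
#' Complement of the union of gene spans within each chromosome (introns
#' count as genic).
#'
#' @param genes Feature tibble; rows of category `gene` are used (all rows
#'   if none are labelled `gene`).
#' @param chrom_lengths Named vector or tibble (`chrom`, `length`).
#' @return Feature tibble of category `intergenic`.
#' @export
derive_intergenic <- function(genes, chrom_lengths) {
  cl <- as_chrom_lengths(chrom_lengths)
  g <- genes[genes$category == "gene", ]
  if (nrow(g) == 0) g <- genes
  out <- purrr::map2_dfr(cl$chrom, cl$length, function(cc, L) {
    gc <- g[g$chrom == cc, ]
    if (nrow(gc) == 0) {
      return(tibble::tibble(chrom = cc, start = 0, end = L))
    }
    gaps <- IRanges::gaps(IRanges::reduce(as_iranges(gc)),
                          start = 1, end = L)
    tibble::tibble(chrom = cc, start = IRanges::start(gaps) - 1,
                   end = IRanges::end(gaps))
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          category = character(), id = character()))
  }
  feature_table(out, category = "intergenic")
}

#' Per-window feature density and coverage
#'
#' Density counts the features overlapping each window (a feature spanning
#' several windows counts once in each, matching `bedtools annotate`);
#' coverage is the fraction of window bases covered by the union of the
#' features.
#'
#' @param features Feature tibble.
#' @param windows Window table (`chrom`, `start`, `end`), non-overlapping.
#' @param mode `"both"` (default), `"density"` or `"coverage"`.
#' @return `windows` with `density` and/or `coverage` columns appended.
#' @export
window_density_coverage <- function(features, windows,
                                    mode = c("both", "density", "coverage")) {
  mode <- match.arg(mode)
  out <- dplyr::group_modify(dplyr::group_by(tibble::as_tibble(windows),
                                             .data$chrom),
    function(d, key) {
      f <- features[features$chrom == key$chrom, ]
      w <- as_iranges(d)
      if (mode %in% c("both", "density")) {
        d$density <- if (nrow(f) == 0) 0L else
          IRanges::countOverlaps(w, as_iranges(f))
      }
      if (mode %in% c("both", "coverage")) {
        if (nrow(f) == 0) {
          d$coverage <- 0
        } else {
          red <- IRanges::reduce(as_iranges(f))
          ov <- IRanges::findOverlaps(w, red)
          inter <- IRanges::pintersect(w[S4Vectors::queryHits(ov)],
                                       red[S4Vectors::subjectHits(ov)])
          bp <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
          cov <- numeric(length(w))
          cov[as.integer(names(bp))] <- bp
          d$coverage <- cov / IRanges::width(w)
        }
      }
      d
    }) |> dplyr::ungroup()
  out
}

#' Mean recombination rate per feature
#'
#' Length-weighted mean of the map over each feature interval; features
#' lying wholly in map gaps get `NA` and are excluded from category-level
#' summaries.
#'
#' @param map A `rate_map`.
#' @param features Feature tibble.
#' @param units `"cm_mb"` (default) or `"r"`.
#' @return `features` with `mean_rate` and `covered_bp` columns.
#' @export
mean_rate_by_feature <- function(map, features, units = c("cm_mb", "r")) {
  units <- match.arg(units)
  map <- rate_map(map)
  out <- dplyr::group_modify(dplyr::group_by(tibble::as_tibble(features),
                                             .data$chrom),
    function(d, key) {
      mc <- map[map$chrom == key$chrom, ]
      dplyr::bind_cols(d, weighted_mean_rate_vec(mc, d$start, d$end))
    }) |> dplyr::ungroup()
  if (units == "cm_mb") out$mean_rate <- rate_to_cm_per_mb(out$mean_rate)
  out
}

#' Category-level rate summaries
#'
#' @param feature_rates Output of [mean_rate_by_feature()].
#' @return Tibble with per-category `n`, `median_rate`, `mean_rate`.
#' @export
category_rate_summary <- function(feature_rates) {
  d <- feature_rates[!is.na(feature_rates$mean_rate), ]
  dplyr::summarise(dplyr::group_by(d, .data$category),
                   n = dplyr::n(),
                   median_rate = stats::median(.data$mean_rate),
                   mean_rate = mean(.data$mean_rate),
                   .groups = "drop")
}

#' Split features by retrotransposon overlap
#'
#' Flags each feature by whether it overlaps (>= 1 bp, half-open
#' arithmetic) any interval of the given set, e.g. one retrotransposon
#' family. The flag partitions the input exhaustively and disjointly.
#'
#' @param features Feature tibble.
#' @param rts Interval tibble (e.g. one RT family's placements).
#' @param family Optional: restrict `rts` to rows of this `category`.
#' @return `features` with a logical `overlaps` column.
#' @export
overlap_split <- function(features, rts, family = NULL) {
  if (!is.null(family)) rts <- rts[rts$category == family, ]
  features <- tibble::as_tibble(features)
  features$overlaps <- FALSE
  if (nrow(rts) == 0 || nrow(features) == 0) return(features)
  for (cc in unique(features$chrom)) {
    fi <- which(features$chrom == cc)
    rc <- rts[rts$chrom == cc, ]
    if (nrow(rc) == 0) next
    n <- IRanges::countOverlaps(as_iranges(features[fi, ]), as_iranges(rc))
    features$overlaps[fi] <- n > 0
  }
  features
}
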