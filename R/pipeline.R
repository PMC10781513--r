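#' Run configuration for the analysis pipeline
#'
#' Bundles the paths and parameters shared by the pipeline subcommands.
#' Flags override these defaults when the bundled command-line script is
#' used; a config file overrides flags.
#'
#' @param map Path to a rate-map text file (4-column) or a `rate_map`.
#' @param gff3,cpgi_bed,rt_bed,fasta,vcf Optional input paths.
#' @param chrom_lengths Named vector/tibble of chromosome lengths.
#' @param window_sizes Window sizes in bp (default 50 kb, 100 kb, 200 kb,
#'   1 Mb).
#' @param mu Mutation rate per bp per generation.
#' @param ne_factor 4 or 1, see [effective_population_size()].
#' @param theta Per-site theta (optional, enables rho).
#' @param micro_threshold Micro/macro boundary in bp.
#' @param profile_bin,profile_span Distance-profile geometry in bp.
#' @param correction Multiplicity correction method.
#' @param min_snp_density Minimum variants/kb for species comparison.
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(map = NULL, gff3 = NULL, cpgi_bed = NULL,
                       rt_bed = NULL, fasta = NULL, vcf = NULL,
                       chrom_lengths = NULL,
                       window_sizes = c(50e3, 100e3, 200e3, 1e6),
                       mu = 4.6e-9, ne_factor = 4, theta = NULL,
                       micro_threshold = 20e6,
                       profile_bin = 5000, profile_span = 200e3,
                       correction = "holm", min_snp_density = 0,
                       seed = 1) {
  stopifnot(all(window_sizes > 0))
  structure(as.list(environment()), class = "run_config")
}

load_map_input <- function(config) {
  m <- config$map
  if (is.null(m)) stop("run_config has no rate map input")
  if (is.character(m)) {
    if (!file.exists(m)) stop("missing input: ", m)
    m <- read_rate_map(m)
  }
  rate_map(m)
}

config_chrom_lengths <- function(config, map) {
  if (!is.null(config$chrom_lengths)) {
    return(as_chrom_lengths(config$chrom_lengths))
  }
  dplyr::summarise(dplyr::group_by(map, .data$chrom),
                   length = max(.data$end), .groups = "drop")
}

#' Run one pipeline subcommand
#'
#' Subcommands mirror the analysis stages: `simulate` (write a synthetic
#' genome, map, truth and VCF), `windows` (windowed rates per configured
#' size), `correlate` (window-level feature correlation table),
#' `profile` (distance profiles around TSS and CpG islands), `islands`
#' (CpG-island detection on a FASTA), `complexity` (windowed k-mer
#' uniqueness), `compare` (cross-species conservation given two maps) and
#' `summary` (per-chromosome summaries plus genome-wide aggregates). Each
#' run writes its tables plus a machine-readable `provenance.json`
#' (inputs, parameters, package version, seed).
#'
#' @param name Subcommand name.
#' @param config A [run_config()] (for `simulate`, its `seed` drives a
#'   default [sim_config()]).
#' @param out_dir Output directory.
#' @param ... Subcommand extras: `map_b` (path or `rate_map`) for
#'   `compare`; `sim` (a [sim_config()]) for `simulate`.
#' @return Invisible named vector of output paths.
#' @export
run_subcommand <- function(name, config, out_dir, ...) {
  extras <- list(...)
  stopifnot(inherits(config, "run_config"))
  names_ok <- c("simulate", "windows", "correlate", "profile", "islands",
                "complexity", "compare", "summary")
  if (!name %in% names_ok) {
    stop("unknown subcommand '", name, "'; available: ",
         paste(names_ok, collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(name,
    simulate = cmd_simulate(config, out_dir, extras$sim),
    windows = cmd_windows(config, out_dir),
    correlate = cmd_correlate(config, out_dir),
    profile = cmd_profile(config, out_dir),
    islands = cmd_islands(config, out_dir),
    complexity = cmd_complexity(config, out_dir),
    compare = cmd_compare(config, out_dir, extras$map_b),
    summary = cmd_summary(config, out_dir))
  prov <- list(subcommand = name,
               parameters = config_provenance(config),
               package_version = as.character(
                 utils::packageVersion("recland")),
               r_version = paste(R.version$major, R.version$minor,
                                 sep = "."),
               outputs = as.list(paths))
  pj <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, pj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(paths, provenance = pj))
}

config_provenance <- function(config) {
  p <- unclass(config)
  p$map <- if (is.character(p$map)) p$map else
    if (is.null(p$map)) NULL else "<in-memory rate_map>"
  if (!is.null(p$chrom_lengths)) p$chrom_lengths <- as.list(
    stats::setNames(as_chrom_lengths(p$chrom_lengths)$length,
                    as_chrom_lengths(p$chrom_lengths)$chrom))
  p
}

cmd_simulate <- function(config, out_dir, sim = NULL) {
  if (is.null(sim)) sim <- sim_config()
  seed <- config$seed
  g <- simulate_genome(sim, seed, dir = out_dir, sequence = FALSE)
  rm_ <- simulate_rate_map(sim, g$annotations, seed)
  p_map <- file.path(out_dir, "rates.map")
  write_rate_map(rm_$map, p_map)
  p_truth <- file.path(out_dir, "truth.json")
  write_truth(rm_$truth, p_truth)
  c(g$paths, map = p_map, truth = p_truth)
}

cmd_windows <- function(config, out_dir) {
  map <- load_map_input(config)
  cl <- config_chrom_lengths(config, map)
  out <- character(0)
  for (ws in config$window_sizes) {
    w <- window_rates(map, ws, chrom_lengths = cl, units = "cm_mb")
    p <- file.path(out_dir, sprintf("rates_%dbp.bedgraph", as.integer(ws)))
    write_bedgraph(w, p)
    out <- c(out, p)
  }
  names(out) <- sprintf("windows_%d", as.integer(config$window_sizes))
  out
}

# windowed rate + available feature tracks, correlation table
cmd_correlate <- function(config, out_dir) {
  map <- load_map_input(config)
  cl <- config_chrom_lengths(config, map)
  ws <- max(min(config$window_sizes), 200e3)
  w <- window_rates(map, ws, chrom_lengths = cl, units = "cm_mb")
  if (!is.null(config$gff3)) {
    genes <- read_features(config$gff3)
    gg <- genes[genes$category == "gene", ]
    w <- window_density_coverage(gg, w, mode = "both")
    w <- dplyr::rename(w, gene_density = "density",
                       gene_coverage = "coverage")
  }
  if (!is.null(config$cpgi_bed)) {
    cpgi <- read_features(config$cpgi_bed, category = "CpGi")
    w <- window_density_coverage(cpgi, w, mode = "both")
    w <- dplyr::rename(w, cpgi_density = "density",
                       cpgi_coverage = "coverage")
  }
  if (!is.null(config$fasta)) {
    w <- gc_content_windows(config$fasta, w)
  }
  if (!is.null(config$vcf)) {
    w <- pi_windows(config$vcf, w)
  }
  ct <- rate_feature_correlations(w, correction = config$correction)
  p1 <- file.path(out_dir, "window_table.tsv")
  readr::write_tsv(w, p1)
  p2 <- file.path(out_dir, "rate_correlations.tsv")
  readr::write_tsv(ct, p2)
  c(window_table = p1, correlations = p2)
}

cmd_profile <- function(config, out_dir) {
  map <- load_map_input(config)
  out <- character(0)
  if (!is.null(config$gff3)) {
    tss <- derive_tss(read_features(config$gff3))
    pr <- distance_profile(map, tss, bin = config$profile_bin,
                           span = config$profile_span)
    p <- file.path(out_dir, "profile_tss.tsv")
    readr::write_tsv(pr, p)
    out <- c(out, profile_tss = p)
  }
  if (!is.null(config$cpgi_bed)) {
    cpgi <- read_features(config$cpgi_bed, category = "CpGi")
    pr <- distance_profile(map, cpgi, bin = config$profile_bin,
                           span = config$profile_span,
                           orient_by_strand = FALSE)
    p <- file.path(out_dir, "profile_cpgi.tsv")
    readr::write_tsv(pr, p)
    out <- c(out, profile_cpgi = p)
  }
  if (length(out) == 0) stop("profile needs gff3 and/or cpgi_bed inputs")
  out
}

cmd_islands <- function(config, out_dir) {
  if (is.null(config$fasta)) stop("islands needs a fasta input")
  isl <- detect_islands(config$fasta)
  p <- file.path(out_dir, "cpg_islands.bed")
  write_islands_bed(isl, p)
  c(islands = p)
}

cmd_complexity <- function(config, out_dir) {
  if (is.null(config$fasta)) stop("complexity needs a fasta input")
  genome <- as_genome(config$fasta)
  flags <- unique_kmer_index(genome)
  cl <- tibble::tibble(chrom = names(genome),
                       length = Biostrings::width(genome))
  w <- tile_windows(cl, min(config$window_sizes))
  cx <- complexity_windows(flags, w)
  p <- file.path(out_dir, "complexity.bedgraph")
  write_bedgraph(cx, p, value = "complexity")
  c(complexity = p)
}

cmd_compare <- function(config, out_dir, map_b) {
  if (is.null(map_b)) stop("compare needs a second map (`map_b`)")
  map_a <- load_map_input(config)
  if (is.character(map_b)) map_b <- read_rate_map(map_b)
  out <- character(0)
  for (ws in config$window_sizes) {
    pairs <- align_windows(map_a, map_b, ws)
    cs <- conservation_stats(pairs, per_chromosome = TRUE)
    p <- file.path(out_dir, sprintf("conservation_%dbp.tsv",
                                    as.integer(ws)))
    readr::write_tsv(cs, p)
    out <- c(out, p)
  }
  pairs50 <- align_windows(map_a, map_b, min(config$window_sizes))
  ld <- normalized_log_difference(pairs50)
  p <- file.path(out_dir, "log_difference.bedgraph")
  write_bedgraph(ld, p, value = "log_diff")
  out <- c(out, log_difference = p)
  out
}

cmd_summary <- function(config, out_dir) {
  map <- load_map_input(config)
  cl <- config_chrom_lengths(config, map)
  cs <- chromosome_summary(map, cl, theta = config$theta,
                           mu = config$mu, ne_factor = config$ne_factor,
                           micro_threshold = config$micro_threshold)
  p1 <- file.path(out_dir, "chromosome_summary.tsv")
  readr::write_tsv(cs, p1)
  genome_rate <- sum(cs$mean_rate * cs$mapped_bp) / sum(cs$mapped_bp)
  agg <- tibble::tibble(
    statistic = c("genome_mean_rate_cm_mb", "map_length_cm",
                  "n_chromosomes", "n_micro", "n_macro"),
    value = c(rate_to_cm_per_mb(genome_rate), sum(cs$map_length_cm),
              nrow(cs), sum(cs$class == "micro"),
              sum(cs$class == "macro")))
  p2 <- file.path(out_dir, "genome_summary.tsv")
  readr::write_tsv(agg, p2)
  c(chromosome_summary = p1, genome_summary = p2)
}
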