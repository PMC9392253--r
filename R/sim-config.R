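#' Simulation configuration
#'
#' One validated object holds every parameter of the synthetic-data
#' generators; the seed fully determines all outputs.
#'
#' @param seed integer RNG seed
#' @param genome_length circular genome length in bp
#' @param repeat_spec data.frame with columns length (bp), identity
#'   (percent), count, and optionally orientation ("direct"/"inverted");
#'   one planted repeat pair group per row
#' @param read_error_rate i.i.d. substitution error rate of simulated reads
#' @param read_length_mean,read_length_sd read length distribution
#'   (lognormal, truncated to `[500, 4 * mean]`)
#' @param coverage fold coverage of simulated read sets
#' @param recomb_fraction fraction of reads drawn from recombinant
#'   conformations
#' @param n_inversions inversions applied by the rearrangement generator
#' @param pop_sizes haplotype counts, c(wild, cultivated)
#' @param sweep_windows data.frame start, end (bp, 1-based closed),
#'   reduction (fold diversity reduction in the cultivated group), boost
#'   (extra pull toward fixation; 1 = none); NULL for neutral
#' @param snp_density variant sites per bp of the circle
#' @param missing_rate i.i.d. missing-call rate
#' @param depth_bands numeric c(low_min, low_max, high_min, high_max) ratio
#'   bands; defaults to the empirical low (0.24-0.72) and high (6.94-142.98)
#'   bands
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       repeat_spec = data.frame(length = c(60L, 300L, 800L, 2000L),
                                                identity = 100,
                                                count = 1L),
                       read_error_rate = 0.05,
                       read_length_mean = 2000L,
                       read_length_sd = 500L,
                       coverage = 30,
                       recomb_fraction = 0.3,
                       n_inversions = 3L,
                       pop_sizes = c(wild = 20L, cul = 20L),
                       sweep_windows = NULL,
                       snp_density = 0.04,
                       missing_rate = 0.02,
                       depth_bands = c(low_min = 0.24, low_max = 0.72,
                                       high_min = 6.94, high_max = 142.98)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(genome_length > 0)
  if (!is.null(repeat_spec)) {
    stopifnot(is.data.frame(repeat_spec))
    if (nrow(repeat_spec) && is.null(repeat_spec$orientation)) {
      repeat_spec$orientation <- "direct"
    }
    if (nrow(repeat_spec)) {
      stopifnot(all(repeat_spec$identity >= 0 & repeat_spec$identity <= 100),
                all(repeat_spec$length > 0), all(repeat_spec$count >= 0),
                all(repeat_spec$orientation %in% c("direct", "inverted")))
    }
  }
  for (fr in c(read_error_rate, recomb_fraction, missing_rate)) {
    stopifnot(fr >= 0, fr <= 1)
  }
  stopifnot(length(pop_sizes) == 2L, all(pop_sizes >= 2L))
  stopifnot(length(depth_bands) == 4L)
  if (!(depth_bands[1L] <= depth_bands[2L] &&
        depth_bands[2L] < depth_bands[3L] &&
        depth_bands[3L] <= depth_bands[4L])) {
    stop("depth bands must satisfy low_min <= low_max < high_min <= high_max")
  }
  if (!is.null(sweep_windows) && nrow(sweep_windows)) {
    stopifnot(all(c("start", "end", "reduction") %in% names(sweep_windows)))
    if (is.null(sweep_windows$boost)) sweep_windows$boost <- 1
  }
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    repeat_spec = repeat_spec, read_error_rate = read_error_rate,
    read_length_mean = read_length_mean, read_length_sd = read_length_sd,
    coverage = coverage, recomb_fraction = recomb_fraction,
    n_inversions = as.integer(n_inversions), pop_sizes = pop_sizes,
    sweep_windows = sweep_windows, snp_density = snp_density,
    missing_rate = missing_rate, depth_bands = depth_bands
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(yaml::as.yaml(x[setdiff(names(x), c("repeat_spec", "sweep_windows"))]))
  if (!is.null(x$repeat_spec) && nrow(x$repeat_spec)) {
    cat("repeat_spec:\n"); print(x$repeat_spec, row.names = FALSE)
  }
  if (!is.null(x$sweep_windows) && nrow(x$sweep_windows)) {
    cat("sweep_windows:\n"); print(x$sweep_windows, row.names = FALSE)
  }
  invisible(x)
}
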