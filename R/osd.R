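#' Compute per-window Observed Strain Differences (OSD)
#'
#' OSD for a window is the number of homozygous SNV differences between the
#' two compared strains falling in the window, divided by the number of
#' bases in the window callable in both strains. Windows whose callable
#' count falls below the usable-window floor are flagged unusable and get an
#' undefined (NA) OSD: with almost no callable sequence the ratio is
#' dominated by noise, and such windows would otherwise distort the density
#' estimate.
#'
#' @param variants A `variant_set` from [read_variants()] (its SNV stream is
#'   used), or a data.frame with `chrom` and `pos` (1-based) columns.
#' @param windows A [build_windows()] grid.
#' @param callable Per-window callable-base counts from [callable_mask()].
#' @param min_callable_frac Usable-window floor as a fraction of the nominal
#'   window size (default 0.10).
#' @return data.frame of class `osd_windows`: the window grid plus
#'   `snv_count`, `callable_bases`, `osd`, `usable`.
#' @export
compute_osd <- function(variants, windows, callable,
                        min_callable_frac = 0.1) {
  stopifnot(inherits(windows, "genome_windows"))
  sites <- if (inherits(variants, "variant_set")) variants$snvs else variants
  if (length(callable) != nrow(windows))
    stop("callable must have one entry per window")
  window_size <- attr(windows, "window_size")
  snv_count <- integer(nrow(windows))
  for (chrom in unique(sites$chrom)) {
    pos <- sites$pos[sites$chrom == chrom]
    idx <- which(windows$chrom == chrom)
    if (length(idx) == 0)
      stop("variant on chromosome absent from the window grid: ", chrom)
    chrom_end <- max(windows$end[idx])
    if (any(pos > chrom_end)) {
      bad <- pos[pos > chrom_end][1]
      stop("variant beyond chromosome end: ", chrom, ":", bad,
           " (chromosome length ", chrom_end, ")")
    }
    # a site at 1-based position p belongs to the window with start <= p-1 < end
    w <- findInterval(pos - 1, windows$start[idx])
    tab <- tabulate(w, nbins = length(idx))
    snv_count[idx] <- snv_count[idx] + tab
  }
  usable <- callable >= min_callable_frac * window_size
  osd <- ifelse(usable & callable > 0, snv_count / callable, NA_real_)
  out <- cbind(as.data.frame(windows),
               data.frame(snv_count = snv_count, callable_bases = callable,
                          osd = osd, usable = usable))
  structure(out, class = c("osd_windows", "data.frame"),
            window_size = window_size,
            min_callable_frac = min_callable_frac)
}

# Oversmoothed bandwidth for the Gaussian kernel (Wand & Jones' upper-bound
# selector): h_OS = 3 * (1 / (70 sqrt(pi)))^(1/5) * sd(x) * n^(-1/5)
# (constant ~= 1.144).
oversmoothed_bandwidth <- function(x) {
  3 * (1 / (70 * sqrt(pi)))^(1 / 5) * stats::sd(x) * length(x)^(-1 / 5)
}

#' Binned Gaussian kernel density estimate of the OSD distribution
#'
#' Smooths the genome-wide set of defined window OSD values on a fixed grid
#' of equally spaced points spanning `[0, max(osd)]`: the values are
#' linearly binned onto the grid, then convolved with a Gaussian kernel. The
#' default bandwidth is the Wand–Jones oversmoothed selector for the
#' Gaussian kernel, `1.144 * sd * n^(-1/5)` — deliberately conservative
#' smoothing, so the bimodal IBD/divergent structure shows two clean peaks
#' and a single valley rather than spurious wiggles. The grid starts at 0 so
#' the spike of zero-OSD (fully IBD) windows sits inside the first peak.
#'
#' @param osd Numeric OSD values (an `osd_windows` object is also accepted;
#'   its usable windows' OSD values are taken). NAs are dropped.
#' @param grid_points Number of grid points (default 401).
#' @param bandwidth Optional explicit bandwidth override, in OSD units.
#' @return Object of class `density_profile`: list with `grid`, `density`,
#'   `bandwidth`, `n`.
#' @export
estimate_density <- function(osd, grid_points = 401, bandwidth = NULL) {
  if (inherits(osd, "osd_windows")) osd <- osd$osd[osd$usable]
  x <- osd[!is.na(osd)]
  if (length(x) < 2) stop("need at least 2 defined OSD values")
  if (grid_points < 3) stop("grid_points must be >= 3")
  if (is.null(bandwidth)) bandwidth <- oversmoothed_bandwidth(x)
  if (!is.finite(bandwidth) || bandwidth <= 0)
    stop("degenerate bandwidth (all OSD values identical?); ",
         "supply an explicit `bandwidth` override")
  hi <- max(x)
  if (hi <= 0)
    stop("all OSD values are zero; density grid would be degenerate; ",
         "nothing to smooth")
  grid <- seq(0, hi, length.out = grid_points)
  delta <- grid[2] - grid[1]
  # linear binning: each value splits its mass between the two bracketing
  # grid points in proportion to proximity
  j <- pmin(floor(x / delta) + 1, grid_points - 1)
  frac <- x / delta - (j - 1)
  counts <- numeric(grid_points)
  lower <- tapply((1 - frac), j, sum)
  upper <- tapply(frac, j + 1, sum)
  counts[as.integer(names(lower))] <- counts[as.integer(names(lower))] + lower
  counts[as.integer(names(upper))] <- counts[as.integer(names(upper))] + upper
  # convolve bin counts with the Gaussian kernel evaluated at grid offsets
  kern <- stats::dnorm(delta * (0:(grid_points - 1)), sd = bandwidth)
  dens <- vapply(seq_len(grid_points), function(g) {
    sum(counts * kern[abs(g - seq_len(grid_points)) + 1])
  }, numeric(1)) / length(x)
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 n = length(x)),
            class = "density_profile")
}

# Collapse the density vector into runs of equal value and classify each run
# as local max / local min / neither. Plateaus count once, at their first
# grid index. The grid boundary may host a maximum (the zero-OSD peak sits
# at grid point 1) but never a minimum: a valley is by definition interior.
density_extrema <- function(density) {
  r <- rle(density)
  v <- r$values
  m <- length(v)
  left <- c(-Inf, v[-m])
  right <- c(v[-1], -Inf)
  is_max <- v > left & v > right
  left_min <- c(Inf, v[-m])
  right_min <- c(v[-1], Inf)
  is_min <- v < left_min & v < right_min
  is_min[c(1, m)] <- FALSE
  first_idx <- cumsum(c(1, r$lengths[-m]))
  data.frame(index = first_idx, value = v, is_max = is_max, is_min = is_min)
}

#' Locate the Polymorphism Enrichment Threshold (PET)
#'
#' The PET is the OSD value at the first local minimum of the smoothed OSD
#' density occurring strictly after the first local maximum, scanning from
#' the low-OSD end of the grid. It is the valley separating the
#' identity-by-descent peak (low OSD) from the divergent-ancestry peak
#' (high OSD). If the density has no such valley — a unimodal distribution —
#' a condition of class `osd_no_valley` is signalled: callers should treat
#' this as "no divergent class detectable", not as a crash.
#'
#' @param profile A [estimate_density()] result.
#' @return The PET as a single numeric OSD value (a grid point), with the
#'   grid index in attribute `"index"`.
#' @export
find_pet <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  ext <- density_extrema(profile$density)
  max_rows <- which(ext$is_max)
  if (length(max_rows) == 0)
    stop_no_valley("no local maximum in the OSD density")
  first_max <- max_rows[1]
  min_rows <- which(ext$is_min & seq_len(nrow(ext)) > first_max)
  if (length(min_rows) == 0)
    stop_no_valley(
      "no local minimum after the first maximum (unimodal OSD density)")
  idx <- ext$index[min_rows[1]]
  structure(profile$grid[idx], index = idx)
}

stop_no_valley <- function(msg) {
  stop(structure(class = c("osd_no_valley", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Density mode locations of the two OSD peaks
#'
#' Returns the grid locations of the first local density maximum and of the
#' highest maximum after the PET valley — an alternative "peak position"
#' statistic to the mean window OSD on each side of the PET reported by
#' [summarize_comparison()].
#'
#' @param profile A [estimate_density()] result.
#' @return Named numeric vector `c(first_peak =, second_peak =)`.
#' @export
density_modes <- function(profile) {
  pet <- find_pet(profile)
  ext <- density_extrema(profile$density)
  maxima <- ext[ext$is_max, , drop = FALSE]
  first <- profile$grid[maxima$index[1]]
  after <- maxima[maxima$index > attr(pet, "index"), , drop = FALSE]
  second <- profile$grid[after$index[which.max(after$value)]]
  c(first_peak = first, second_peak = second)
}

#' Merge contiguous supra-PET windows into divergent haplotype blocks
#'
#' Maximal runs of genomically adjacent windows (same chromosome, each
#' window ending where the next starts) whose OSD is greater than or equal
#' to the PET are merged into single blocks — the divergent haplotype
#' blocks. Windows with undefined OSD break runs.
#'
#' @param osd_windows A [compute_osd()] result, sorted by chromosome and
#'   start.
#' @param pet PET value (from [find_pet()] or an explicit override).
#' @return data.frame of class `haplotype_blocks`: `chrom`, `start`, `end`,
#'   `n_windows`, `snv_count`, `mean_osd`, `has_partial` (whether the block
#'   contains a trailing partial window).
#' @export
merge_blocks <- function(osd_windows, pet) {
  stopifnot(inherits(osd_windows, "osd_windows"), is.numeric(pet))
  w <- osd_windows
  n <- nrow(w)
  prev_same <- if (n > 1) w$chrom[-1] == w$chrom[-n] else logical(0)
  if (any(w$start[-1][prev_same] <= w$start[-n][prev_same]) ||
      is.unsorted(match(w$chrom, unique(w$chrom))))
    stop("windows must be sorted by chromosome and start")
  above <- !is.na(w$osd) & w$osd >= pet
  adjacent <- c(FALSE, w$chrom[-1] == w$chrom[-nrow(w)] &
                       w$start[-1] == w$end[-nrow(w)])
  block_id <- cumsum(!(above & adjacent))
  block_id[!above] <- NA
  keep <- !is.na(block_id)
  if (!any(keep))
    return(structure(
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 n_windows = integer(0), snv_count = integer(0),
                 mean_osd = numeric(0), has_partial = logical(0)),
      class = c("haplotype_blocks", "data.frame")))
  g <- factor(block_id[keep], levels = unique(block_id[keep]))
  out <- data.frame(
    chrom = as.character(tapply(w$chrom[keep], g, `[`, 1)),
    start = as.numeric(tapply(w$start[keep], g, min)),
    end = as.numeric(tapply(w$end[keep], g, max)),
    n_windows = as.integer(table(g)),
    snv_count = as.integer(tapply(w$snv_count[keep], g, sum)),
    mean_osd = as.numeric(tapply(w$osd[keep], g, mean)),
    has_partial = as.logical(tapply(w$partial[keep], g, any)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("haplotype_blocks", "data.frame"))
}

#' Summary statistics for one pairwise OSD comparison
#'
#' Produces the per-comparison summary row: PET; number and percentage of
#' windows at or above the PET; block count and block-length mean/SD; mean
#' window OSD below and at/above the PET (the "first peak" / "second peak"
#' averages); and total vs in-block SNV counts. Percentages use the full
#' window grid as denominator. Blocks containing a trailing partial window
#' are excluded from the block-length mean/SD by default, since their length
#' is not a multiple of the window size.
#'
#' @param osd_windows A [compute_osd()] result.
#' @param blocks A [merge_blocks()] result.
#' @param variants A `variant_set` or data.frame with `chrom`, `pos`.
#' @param pet The PET used.
#' @param comparison Optional comparison label (e.g. `"LH/LN"`).
#' @param include_partial_lengths Include blocks with partial windows in the
#'   block-length statistics (default FALSE).
#' @return One-row data.frame of class `comparison_summary`.
#' @export
summarize_comparison <- function(osd_windows, blocks, variants, pet,
                                 comparison = NA_character_,
                                 include_partial_lengths = FALSE) {
  stopifnot(inherits(osd_windows, "osd_windows"))
  sites <- if (inherits(variants, "variant_set")) variants$snvs else variants
  w <- osd_windows
  defined <- !is.na(w$osd)
  above <- defined & w$osd >= pet
  n_windows <- nrow(w)
  n_above <- sum(above)
  len_blocks <- if (include_partial_lengths) blocks else
    blocks[!blocks$has_partial, , drop = FALSE]
  n_total <- nrow(sites)
  n_in <- count_sites_in_intervals(sites, blocks)
  data.frame(
    comparison = comparison,
    pet = pet,
    n_windows = n_windows,
    n_windows_above = n_above,
    pct_windows_above = 100 * n_above / n_windows,
    n_blocks = nrow(blocks),
    mean_block_length = if (nrow(len_blocks) > 0)
      mean(len_blocks$end - len_blocks$start) else NA_real_,
    sd_block_length = if (nrow(len_blocks) > 1)
      stats::sd(len_blocks$end - len_blocks$start) else NA_real_,
    mean_osd_below = if (any(defined & !above))
      mean(w$osd[defined & !above]) else NA_real_,
    mean_osd_above = if (n_above > 0) mean(w$osd[above]) else NA_real_,
    n_snps_total = n_total,
    n_snps_in_blocks = n_in,
    pct_snps_in_blocks = if (n_total > 0) 100 * n_in / n_total else 0,
    stringsAsFactors = FALSE
  ) -> out
  structure(out, class = c("comparison_summary", "data.frame"))
}

# Count variant sites (1-based pos) falling inside a set of 0-based
# half-open intervals.
count_sites_in_intervals <- function(sites, intervals) {
  if (nrow(sites) == 0 || nrow(intervals) == 0) return(0L)
  total <- 0L
  for (chrom in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    pos <- sites$pos[sites$chrom == chrom]
    if (length(pos) == 0) next
    ir <- IRanges::reduce(IRanges::IRanges(iv$start + 1, iv$end))
    hits <- IRanges::countOverlaps(IRanges::IRanges(pos, pos), ir)
    total <- total + sum(hits > 0)
  }
  total
}
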