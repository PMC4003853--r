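# Build an osd_windows object directly from a vector of per-window SNV
# counts on one chromosome with full callable windows.
osd_from_counts <- function(counts, window_size = 1e5, callable = NULL) {
  w <- build_windows(c(chr1 = length(counts) * window_size), window_size)
  pos <- unlist(lapply(seq_along(counts), function(i)
    if (counts[i] > 0) (i - 1) * window_size + seq_len(counts[i]) else
      numeric(0)))
  sites <- data.frame(chrom = rep("chr1", length(pos)), pos = pos)
  if (is.null(callable)) callable <- rep(window_size, length(counts))
  compute_osd(sites, w, callable)
}

test_that("osd is the SNV count over callable bases, NA below the floor", {
  osd <- osd_from_counts(c(0, 45, 10), callable = c(100000, 100000, 5000))
  expect_equal(osd$osd[1], 0)
  expect_equal(osd$osd[2], 4.5e-4)
  expect_true(is.na(osd$osd[3]))   # below the 10% usable-window floor
  expect_false(osd$usable[3])
  expect_equal(osd$snv_count[3], 10)  # count still recorded
})

test_that("per-window counts equal a brute-force scan and conserve the total", {
  set.seed(55)
  sizes <- c(c1 = 1.05e6, c2 = 5e5)
  w <- build_windows(sizes)
  sites <- data.frame(
    chrom = sample(names(sizes), 800, replace = TRUE))
  sites$pos <- vapply(sites$chrom, function(ch)
    sample.int(sizes[[ch]], 1), numeric(1))
  osd <- compute_osd(sites, w, rep(1e5, nrow(w)))
  oracle <- vapply(seq_len(nrow(w)), function(i)
    sum(sites$chrom == w$chrom[i] &
        sites$pos - 1 >= w$start[i] & sites$pos - 1 < w$end[i]), numeric(1))
  expect_equal(osd$snv_count, oracle)
  expect_equal(sum(osd$snv_count), nrow(sites))
})

test_that("variants beyond the chromosome end are rejected by name", {
  w <- build_windows(c(chr1 = 2e5))
  bad <- data.frame(chrom = "chr1", pos = 2e5 + 1)
  expect_error(compute_osd(bad, w, rep(1e5, 2)), "chr1:200001")
})

test_that("the density grid has 401 points and is peaked at the sample mode", {
  set.seed(9)
  x <- rnorm(1000, mean = 5, sd = 0.5)
  prof <- estimate_density(x)
  expect_length(prof$grid, 401)
  expect_length(prof$density, 401)
  expect_true(all(prof$density >= 0))
  expect_equal(prof$bandwidth,
               1.1439882 * sd(x) * 1000^(-1 / 5), tolerance = 1e-4)
  # argmax within one grid step of the direct-sum estimate's argmax
  direct <- direct_kde(x, prof$grid, prof$bandwidth)
  expect_lte(abs(which.max(prof$density) - which.max(direct)), 1)
})

test_that("binned density matches the exact direct sum within 1% everywhere", {
  set.seed(11)
  x <- c(rep(0, 180), rexp(245, 1 / 5e-6), rnorm(75, 1.5e-3, 4e-4))
  x <- pmax(x, 0)[1:500]
  prof <- estimate_density(x)
  direct <- direct_kde(x, prof$grid, prof$bandwidth)
  expect_lt(max(abs(prof$density - direct) / direct), 0.01)
})

test_that("binned density agrees with the reference binned implementation", {
  # same bandwidth, same grid range: KernSmooth's FFT-based binned KDE
  set.seed(12)
  x <- pmax(c(rep(0, 100), rexp(300, 1 / 1e-5), rnorm(100, 1.5e-3, 3e-4)), 0)
  prof <- estimate_density(x)
  bk <- KernSmooth::bkde(x, bandwidth = prof$bandwidth, gridsize = 401L,
                         range.x = c(0, max(x)), truncate = FALSE)
  expect_equal(prof$grid, bk$x)
  expect_lt(max(abs(prof$density - bk$y)) / max(prof$density), 1e-3)
})

test_that("degenerate OSD sets produce informative density errors", {
  expect_error(estimate_density(c(0.5)), "at least 2")
  expect_error(estimate_density(rep(0.5, 10)), "bandwidth")
  expect_error(estimate_density(rep(0, 10), bandwidth = 0.1), "zero")
})

test_that("the PET of a symmetric mixture sits at the midpoint of the modes", {
  set.seed(31)
  m1 <- 2; m2 <- 8
  half <- rnorm(400, m1, 0.7)
  x <- c(half, m1 + m2 - half, 0, m1 + m2)  # exactly symmetric on [0, 10]
  prof <- estimate_density(x, bandwidth = 0.7)
  pet <- find_pet(prof)
  step <- prof$grid[2] - prof$grid[1]
  expect_lte(abs(as.numeric(pet) - (m1 + m2) / 2), step)
})

test_that("the PET equals the exhaustive grid-search valley for OSD-like mixtures", {
  set.seed(63)
  n <- 1000
  x <- c(abs(rnorm(round(0.85 * n), 5e-6, 5e-6)),
         rnorm(n - round(0.85 * n), 1.5e-3, 3e-4))
  x <- pmax(x, 0)
  prof <- estimate_density(x)
  pet <- find_pet(prof)
  # oracle: scan every grid point, find all strict local maxima, then take
  # the argmin of density between the first two
  d <- prof$density
  loc_max <- which(vapply(seq_along(d), function(i) {
    left <- if (i == 1) -Inf else d[i - 1]
    right <- if (i == length(d)) -Inf else d[i + 1]
    d[i] > left && d[i] > right
  }, logical(1)))
  expect_gte(length(loc_max), 2)
  between <- seq(loc_max[1], loc_max[2])
  oracle_pet <- prof$grid[between[which.min(d[between])]]
  expect_equal(as.numeric(pet), oracle_pet)
})

test_that("a unimodal sample raises the no-valley condition", {
  set.seed(5)
  prof <- estimate_density(rnorm(500, 10, 1))
  expect_error(find_pet(prof), class = "osd_no_valley")
  expect_error(find_pet(prof), "unimodal")
})

test_that("contiguous supra-PET windows merge into blocks; gaps split them", {
  # a 100-Mb chromosome with supra-PET runs mirroring known block patterns:
  # 14 windows at 41.7-43.1 Mb; 29.7-30.0 and 30.1-30.3 split by one
  # sub-PET window
  counts <- rep(0L, 1000)
  counts[418:431] <- 150          # windows starting 41.7 .. 43.0 Mb
  counts[298:300] <- 150          # 29.7 .. 29.9
  counts[302:303] <- 150          # 30.1 .. 30.2
  osd <- osd_from_counts(counts)
  pet <- 1e-3
  blocks <- merge_blocks(osd, pet)
  expect_equal(nrow(blocks), 3)
  expect_equal(blocks$start, c(29.7e6, 30.1e6, 41.7e6))
  expect_equal(blocks$end, c(30.0e6, 30.3e6, 43.1e6))
  expect_equal(blocks$end - blocks$start, c(0.3e6, 0.2e6, 1.4e6))
  expect_equal(blocks$n_windows, c(3, 2, 14))
  # no window at or above the PET -> no blocks
  expect_equal(nrow(merge_blocks(osd, 1)), 0)
})

test_that("undefined-OSD windows break block runs", {
  osd <- osd_from_counts(c(100, 100, 100),
                         callable = c(1e5, 4e3, 1e5))  # middle unusable
  blocks <- merge_blocks(osd, 5e-4)
  expect_equal(nrow(blocks), 2)
  expect_equal(blocks$start, c(0, 2e5))
})

test_that("unsorted windows are rejected", {
  osd <- osd_from_counts(c(1, 2, 3))
  expect_error(merge_blocks(osd[c(2, 1, 3), ], 1e-5), "sorted")
})

test_that("block membership partitions the supra-PET windows", {
  set.seed(88)
  for (i in 1:5) {
    counts <- rpois(200, lambda = sample(c(0.5, 150), 200, TRUE, c(.8, .2)))
    osd <- osd_from_counts(counts)
    pet <- 5e-4
    blocks <- merge_blocks(osd, pet)
    above <- !is.na(osd$osd) & osd$osd >= pet
    expect_equal(sum(blocks$n_windows), sum(above))
    expect_equal(sum(blocks$snv_count), sum(osd$snv_count[above]))
    # every constituent window of every block is supra-PET
    for (j in seq_len(nrow(blocks))) {
      inside <- osd$start >= blocks$start[j] & osd$end <= blocks$end[j]
      expect_true(all(osd$osd[inside] >= pet))
    }
  }
})

test_that("raising the PET never increases total block length", {
  set.seed(23)
  counts <- rpois(300, lambda = sample(c(0.5, 60, 150), 300, TRUE))
  osd <- osd_from_counts(counts)
  pets <- seq(1e-5, 2e-3, length.out = 20)
  total <- vapply(pets, function(p) {
    b <- merge_blocks(osd, p)
    sum(b$end - b$start)
  }, numeric(1))
  expect_true(all(diff(total) <= 0))
})

test_that("summary percentages and counts are internally consistent", {
  counts <- c(rep(0L, 80), rep(150L, 20))
  osd <- osd_from_counts(counts)
  pet <- 5e-4
  blocks <- merge_blocks(osd, pet)
  sites <- data.frame(chrom = "chr1",
                      pos = unlist(lapply(which(counts > 0), function(i)
                        (i - 1) * 1e5 + seq_len(counts[i]))))
  s <- summarize_comparison(osd, blocks, sites, pet, comparison = "A/B")
  expect_equal(s$n_windows_above, 20)
  expect_equal(s$pct_windows_above, 20)
  expect_equal(s$n_snps_total, 3000)
  expect_equal(s$n_snps_in_blocks, 3000)
  expect_equal(s$pct_snps_in_blocks, 100)
  expect_equal(s$mean_osd_below, 0)
  expect_equal(s$mean_osd_above, 1.5e-3)
  expect_equal(100 * s$n_windows_above / s$n_windows, s$pct_windows_above)
})

test_that("a zero-variant comparison summarizes to zero counts", {
  osd <- osd_from_counts(rep(0L, 10))
  blocks <- merge_blocks(osd, 1e-4)
  s <- summarize_comparison(osd, blocks,
                            data.frame(chrom = character(0), pos = numeric(0)),
                            1e-4)
  expect_equal(s$n_blocks, 0)
  expect_equal(s$n_snps_total, 0)
  expect_equal(s$pct_snps_in_blocks, 0)
  expect_true(is.na(s$mean_osd_above))
})

test_that("density modes report the two peak locations", {
  set.seed(2)
  x <- pmax(c(abs(rnorm(850, 1e-5, 1e-5)), rnorm(150, 1.5e-3, 2e-4)), 0)
  prof <- estimate_density(x)
  modes <- density_modes(prof)
  expect_lt(modes[["first_peak"]], 2e-4)
  expect_gt(modes[["second_peak"]], 1e-3)
  expect_lt(abs(modes[["second_peak"]] - 1.5e-3), 3e-4)
})

test_that("parameter recovery: blocks match truth on >=300kb-segment mosaics", {
  # aggregate over 10 seeded 20-Mb mosaics at the two-regime rates
  tot_div <- 0; tot_cov <- 0; tot_block <- 0; tot_shared_hit <- 0
  tot_shared <- 0
  for (s in 1:10) {
    p <- mosaic_params(c(chr1 = 5e7), divergent_fraction = 0.15,
                       seg_length_mean = 9e5, seg_length_min = 3e5,
                       rate_ibd = 5e-6, rate_divergent = 1.5e-3, seed = s)
    sim <- simulate_mosaic(p)
    w <- build_windows(p$chrom_lengths)
    cal <- callable_mask(w, sim$gaps$S1, sim$gaps$S2)
    osd <- compute_osd(sim$variants[sim$variants$class == "SNV", ], w, cal)
    pet <- tryCatch(as.numeric(find_pet(estimate_density(osd))),
                    osd_no_valley = function(e) NA_real_)
    if (is.na(pet)) next
    blocks <- merge_blocks(osd, pet)
    ts <- truth_segments(sim, c("S1", "S2"))
    cov <- osdhaplomap:::overlap_bp(blocks, ts)
    div <- sum(ts$end - ts$start)
    blk <- sum(blocks$end - blocks$start)
    tot_div <- tot_div + div
    tot_cov <- tot_cov + cov
    tot_block <- tot_block + blk
    tot_shared_hit <- tot_shared_hit + (blk - cov)
    tot_shared <- tot_shared + (5e7 - div)
  }
  expect_gte(tot_cov / tot_div, 0.95)          # divergent bases recovered
  expect_lte(tot_shared_hit / tot_shared, 0.05)  # shared bases mislabelled
  jaccard <- tot_cov / (tot_div + tot_block - tot_cov)
  expect_gte(jaccard, 0.90)
})
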