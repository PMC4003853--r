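#' Parameters for the mosaic-genome simulator
#'
#' Builds and validates the parameter set for [simulate_mosaic()]. The
#' simulator emulates the genome structure the OSD method assumes: inbred
#' strains derived from a common founder colony whose chromosomes are mosaics
#' of identity-by-descent (IBD) segments — carrying only the few mutations
#' fixed after the strains separated — and divergent-ancestry segments fixed
#' from different founder haplotypes, which carry orders of magnitude more
#' homozygous differences.
#'
#' Default rates correspond to the two modes of the pairwise OSD distribution
#' observed between closely related inbred rat strains: about 5e-6 SNVs/bp
#' within shared segments and 1.5e-3 SNVs/bp within divergent segments, with
#' divergent blocks averaging about 0.9 Mb and covering about 15% of the
#' genome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param n_strains Number of inbred strains to simulate (>= 2).
#' @param divergent_fraction Proportion of each chromosome covered by
#'   divergent-ancestry segments, in `[0, 1]`.
#' @param seg_length_mean Mean divergent-segment length in bp. Segment
#'   lengths are drawn from an exponential distribution with this mean
#'   (truncated at the chromosome's divergent-bp budget).
#' @param seg_length_min Minimum divergent-segment length in bp (default 0:
#'   pure exponential). When positive, lengths follow a shifted exponential
#'   with the same mean, so short segments below the window resolution can
#'   be excluded from recovery studies.
#' @param rate_divergent Expected homozygous SNV differences per bp between
#'   two strains inside divergent segments. Must exceed `rate_ibd`.
#' @param rate_ibd Expected homozygous SNV differences per bp inside shared
#'   (IBD) segments.
#' @param gap_fraction Proportion of each strain's genome masked as
#'   zero-coverage gaps, in `[0, 1)`.
#' @param gap_length_mean Mean zero-coverage gap length in bp.
#' @param indel_fraction Proportion of simulated variant sites emitted as
#'   1-bp indels rather than SNVs (SNPs and indels are tallied separately
#'   downstream).
#' @param strains Optional character vector of strain names
#'   (default `S1..Sn`).
#' @param seed Integer seed. One global seed drives deterministic
#'   per-chromosome / per-pair / per-strain substreams, so results do not
#'   depend on chromosome order.
#'
#' @return An object of class `mosaic_params` (a validated list).
#' @seealso [simulate_mosaic()], [write_fixture()]
#' @export
#' @examples
#' p <- mosaic_params(c(chr1 = 5e6), divergent_fraction = 0.15, seed = 1)
mosaic_params <- function(chrom_lengths,
                          n_strains = 2,
                          divergent_fraction = 0.15,
                          seg_length_mean = 9e5,
                          seg_length_min = 0,
                          rate_divergent = 1.5e-3,
                          rate_ibd = 5e-6,
                          gap_fraction = 0.05,
                          gap_length_mean = 2e4,
                          indel_fraction = 0,
                          strains = NULL,
                          seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector (chromosome -> length)")
  if (any(chrom_lengths < 1))
    stop("all chromosome lengths must be positive")
  if (anyDuplicated(names(chrom_lengths)))
    stop("duplicated chromosome names in chrom_lengths")
  if (n_strains < 2) stop("n_strains must be >= 2")
  if (divergent_fraction < 0 || divergent_fraction > 1)
    stop("divergent_fraction must lie in [0, 1]")
  if (!(rate_divergent > rate_ibd) || rate_ibd < 0)
    stop("rates must satisfy rate_divergent > rate_ibd >= 0")
  if (seg_length_mean <= 0 || gap_length_mean <= 0)
    stop("all lengths must be positive")
  if (seg_length_min < 0 || seg_length_min >= seg_length_mean)
    stop("seg_length_min must lie in [0, seg_length_mean)")
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must lie in [0, 1)")
  if (indel_fraction < 0 || indel_fraction > 1)
    stop("indel_fraction must lie in [0, 1]")
  if (is.null(strains)) strains <- paste0("S", seq_len(n_strains))
  if (length(strains) != n_strains || anyDuplicated(strains))
    stop("strains must be ", n_strains, " unique names")
  structure(list(
    chrom_lengths = round(chrom_lengths),
    n_strains = as.integer(n_strains),
    divergent_fraction = divergent_fraction,
    seg_length_mean = seg_length_mean,
    seg_length_min = seg_length_min,
    rate_divergent = rate_divergent,
    rate_ibd = rate_ibd,
    gap_fraction = gap_fraction,
    gap_length_mean = gap_length_mean,
    indel_fraction = indel_fraction,
    strains = strains,
    seed = as.integer(seed)
  ), class = "mosaic_params")
}

# Deterministic substream seed from the global seed and a sequence of string
# tokens (chromosome name, pair label, ...). Keeps results independent of the
# order in which chromosomes/pairs are processed.
substream_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tok in unlist(list(...))) {
    for (c in utf8ToInt(as.character(tok))) {
      h <- (h * 31 + c) %% 2147483647
    }
  }
  as.integer(max(1, h))
}

# Evaluate expr under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Place non-overlapping intervals totalling target_bp on [0, chrom_len),
# lengths ~ min_len + Exp(mean_len - min_len) truncated so the total hits
# target_bp exactly. Returns a two-column matrix (start, end), 0-based
# half-open, sorted.
place_segments <- function(chrom_len, target_bp, mean_len, min_len = 0) {
  target_bp <- round(target_bp)
  if (target_bp <= 0) return(matrix(numeric(0), ncol = 2))
  if (target_bp > chrom_len)
    stop("infeasible parameters: divergent_fraction demands more sequence (",
         target_bp, " bp) than the chromosome holds (", chrom_len, " bp)")
  lens <- numeric(0)
  tot <- 0
  while (tot < target_bp) {
    l <- max(1, round(min_len + stats::rexp(1, rate = 1 / (mean_len - min_len))))
    l <- min(l, target_bp - tot)
    if (l < min_len && length(lens) > 0) {
      # remainder shorter than the minimum: extend the previous segment
      lens[length(lens)] <- lens[length(lens)] + l
    } else {
      lens <- c(lens, l)
    }
    tot <- tot + l
  }
  k <- length(lens)
  free <- chrom_len - tot
  # stick-breaking: k+1 inter-segment spacings summing to the free sequence
  spacings <- diff(c(0, sort(stats::runif(k)), 1)) * free
  starts <- round(cumsum(spacings)[seq_len(k)] + cumsum(c(0, lens))[seq_len(k)])
  segs <- cbind(start = starts, end = starts + lens)
  # rounding can make neighbours touch; merge to keep segments maximal
  if (k > 1) {
    keep_open <- segs[-k, 2] < segs[-1, 1]
    grp <- cumsum(c(TRUE, keep_open))
    segs <- cbind(start = tapply(segs[, 1], grp, min),
                  end = tapply(segs[, 2], grp, max))
  }
  segs
}

# Poisson-process variant positions (1-based) on a set of 0-based half-open
# intervals at `rate` per bp.
poisson_positions <- function(intervals, rate) {
  if (nrow(intervals) == 0 || rate <= 0) return(integer(0))
  out <- lapply(seq_len(nrow(intervals)), function(i) {
    len <- intervals[i, 2] - intervals[i, 1]
    n <- stats::rpois(1, len * rate)
    if (n == 0) return(integer(0))
    sort(intervals[i, 1] + sample.int(len, n, replace = TRUE))
  })
  sort(unlist(out))
}

# Complement of sorted non-overlapping intervals within [0, chrom_len).
complement_intervals <- function(intervals, chrom_len) {
  if (nrow(intervals) == 0)
    return(matrix(c(0, chrom_len), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  starts <- c(0, intervals[, 2])
  ends <- c(intervals[, 1], chrom_len)
  keep <- ends > starts
  cbind(start = starts[keep], end = ends[keep])
}

#' Simulate a mosaic multi-strain genome
#'
#' Tiles each chromosome with alternating shared-ancestry and
#' divergent-ancestry segments, then generates homozygous variant differences
#' between every strain pair as a Poisson process: `rate_divergent` per bp
#' inside that pair's divergent segments and `rate_ibd` per bp elsewhere.
#' Exactly one strain of the pair is homozygous for the alternate allele at
#' each site; all other strains are homozygous reference. Zero-coverage gap
#' intervals are placed independently per strain, from an RNG substream that
#' does not influence variant positions.
#'
#' @param params A [mosaic_params()] object.
#' @return An object of class `mosaic_sim`: a list with
#'   \describe{
#'     \item{variants}{data.frame with `chrom`, `pos` (1-based), `ref`,
#'       `alt`, `class` (`"SNV"`/`"indel"`), and one genotype column per
#'       strain (`"0/0"` or `"1/1"`).}
#'     \item{gaps}{named list (per strain) of 0-based half-open gap interval
#'       data.frames (`chrom`, `start`, `end`).}
#'     \item{truth}{list with `divergent_segments` (data.frame `chrom`,
#'       `start`, `end`, `pair`) and `params`.}
#'   }
#'   The same seed yields bit-identical output.
#' @export
#' @examples
#' sim <- simulate_mosaic(mosaic_params(c(chr1 = 2e6), seed = 7))
#' head(sim$variants)
simulate_mosaic <- function(params) {
  stopifnot(inherits(params, "mosaic_params"))
  p <- params
  chroms <- names(p$chrom_lengths)
  pairs <- utils::combn(p$strains, 2, simplify = FALSE)
  bases <- c("A", "C", "G", "T")

  truth_list <- list()
  var_list <- list()
  for (chrom in chroms) {
    len <- p$chrom_lengths[[chrom]]
    # one divergent-segment mosaic per strain pair
    chrom_sites <- list()
    for (pr in pairs) {
      pair_id <- paste(pr, collapse = "|")
      segs <- with_local_seed(
        substream_seed(p$seed, "segments", chrom, pair_id),
        place_segments(len, p$divergent_fraction * len, p$seg_length_mean,
                       p$seg_length_min)
      )
      if (nrow(segs) > 0)
        truth_list[[length(truth_list) + 1]] <- data.frame(
          chrom = chrom, start = segs[, 1], end = segs[, 2],
          pair = pair_id, row.names = NULL)
      sites <- with_local_seed(
        substream_seed(p$seed, "variants", chrom, pair_id), {
          pos_div <- poisson_positions(segs, p$rate_divergent)
          pos_ibd <- poisson_positions(complement_intervals(segs, len),
                                       p$rate_ibd)
          pos <- sort(c(pos_div, pos_ibd))
          pos <- pos[!duplicated(pos)]
          n <- length(pos)
          if (n == 0) NULL else data.frame(
            chrom = chrom, pos = pos,
            ref = sample(bases, n, replace = TRUE),
            alt_shift = sample.int(3, n, replace = TRUE),
            carrier = sample(pr, n, replace = TRUE),
            is_indel = stats::runif(n) < p$indel_fraction,
            row.names = NULL)
        })
      if (!is.null(sites)) chrom_sites[[pair_id]] <- sites
    }
    if (length(chrom_sites) > 0) {
      sites <- do.call(rbind, chrom_sites)
      sites <- sites[order(sites$pos), , drop = FALSE]
      sites <- sites[!duplicated(sites$pos), , drop = FALSE]
      var_list[[chrom]] <- sites
    }
  }

  variants <- if (length(var_list) > 0) do.call(rbind, var_list) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt_shift = integer(0), carrier = character(0),
               is_indel = logical(0))
  rownames(variants) <- NULL
  # alt allele: ref rotated by 1-3 within A/C/G/T (never equal to ref);
  # indels: 1-bp insertion relative to ref
  ref_idx <- match(variants$ref, bases)
  alt <- bases[(ref_idx - 1 + variants$alt_shift) %% 4 + 1]
  is_indel <- variants$is_indel
  alt[is_indel] <- paste0(variants$ref[is_indel], alt[is_indel])
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = alt,
                    class = ifelse(is_indel, "indel", "SNV"),
                    row.names = NULL, stringsAsFactors = FALSE)
  for (s in p$strains)
    out[[s]] <- ifelse(variants$carrier == s, "1/1", "0/0")
  out$chrom <- factor(out$chrom, levels = chroms)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$chrom <- as.character(out$chrom)
  rownames(out) <- NULL

  gaps <- lapply(p$strains, function(s) {
    gap_list <- lapply(chroms, function(chrom) {
      len <- p$chrom_lengths[[chrom]]
      segs <- with_local_seed(
        substream_seed(p$seed, "gaps", chrom, s),
        place_segments(len, p$gap_fraction * len, p$gap_length_mean))
      if (nrow(segs) == 0) return(NULL)
      data.frame(chrom = chrom, start = segs[, 1], end = segs[, 2],
                 row.names = NULL)
    })
    gap_df <- do.call(rbind, gap_list)
    if (is.null(gap_df))
      gap_df <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0))
    gap_df
  })
  names(gaps) <- p$strains

  truth_segments <- if (length(truth_list) > 0) do.call(rbind, truth_list) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               pair = character(0))

  structure(list(
    variants = out,
    gaps = gaps,
    truth = list(divergent_segments = truth_segments, params = p)
  ), class = "mosaic_sim")
}

#' Extract one strain pair's ground-truth divergent segments
#'
#' @param sim A `mosaic_sim` object.
#' @param pair Character vector of two strain names.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open), sorted.
#' @export
truth_segments <- function(sim, pair) {
  stopifnot(inherits(sim, "mosaic_sim"), length(pair) == 2)
  ids <- c(paste(pair, collapse = "|"), paste(rev(pair), collapse = "|"))
  seg <- sim$truth$divergent_segments
  seg <- seg[seg$pair %in% ids, c("chrom", "start", "end"), drop = FALSE]
  seg[order(seg$chrom, seg$start), , drop = FALSE]
}

#' Write a simulated mosaic to standard file formats
#'
#' Emits a VCF 4.2 file with one sample column per strain, one zero-coverage
#' gap BED per strain, a two-column chromosome-sizes TSV, and a BED of
#' ground-truth divergent segments (name column = strain pair). Files
#' round-trip losslessly through [read_variants()], [read_bed()] and
#' [read_chrom_sizes()].
#'
#' @param sim A `mosaic_sim` object from [simulate_mosaic()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"mosaic"`).
#' @return Named list of file paths: `vcf`, `gaps` (named per strain),
#'   `chrom_sizes`, `truth`.
#' @export
write_fixture <- function(sim, dir, prefix = "mosaic") {
  stopifnot(inherits(sim, "mosaic_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  p <- sim$truth$params
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  write_vcf(sim$variants, p$strains, p$chrom_lengths, vcf_path)
  gap_paths <- vapply(p$strains, function(s) {
    path <- file.path(dir, paste0(prefix, ".gaps.", s, ".bed"))
    write_bed(sim$gaps[[s]], path)
    path
  }, character(1))
  sizes_path <- file.path(dir, paste0(prefix, ".chrom.sizes"))
  utils::write.table(
    data.frame(names(p$chrom_lengths), unname(p$chrom_lengths)),
    sizes_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  truth_path <- file.path(dir, paste0(prefix, ".truth.bed"))
  write_bed(sim$truth$divergent_segments, truth_path)
  list(vcf = vcf_path, gaps = gap_paths, chrom_sizes = sizes_path,
       truth = truth_path)
}
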