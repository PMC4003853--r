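#' Read a chromosome-sizes file
#'
#' @param path Two-column TSV: chromosome name, length in bp.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (nrow(df) == 0) stop("empty chromosome-sizes file: ", path)
  if (any(df$length <= 0))
    stop("non-positive chromosome length in ", path)
  stats::setNames(df$length, df$chrom)
}

#' Read a BED file (0-based half-open intervals)
#'
#' @param path BED path; columns chrom, start, end and optionally a name
#'   (fourth) column.
#' @return data.frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  n_fields <- max(utils::count.fields(path, sep = "\t"), 0)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0))
  if (!is.finite(n_fields) || length(readLines(path, n = 1)) == 0)
    return(empty)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs >= 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  if (any(df$start >= df$end))
    stop("BED intervals must satisfy start < end: ", path)
  df[, seq_len(min(4, ncol(df))), drop = FALSE]
}

#' Write intervals to a BED file
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional further
#'   columns (written in order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "pair"), names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Minimal VCF 4.2 emitter for the simulator: fixed columns + GT-only sample
# columns. `variants` must carry chrom/pos/ref/alt plus one genotype column
# per strain.
write_vcf <- function(variants, strains, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=osdhaplomap_simulate_mosaic",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
            as.integer(chrom_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t")
  ), con)
  if (nrow(variants) > 0) {
    chrom <- factor(variants$chrom, levels = names(chrom_lengths))
    ord <- order(chrom, variants$pos)
    v <- variants[ord, , drop = FALSE]
    body <- cbind(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                  ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                  as.matrix(v[, strains, drop = FALSE]))
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

# Classify a vector of GT strings: "hom_ref", "hom_alt" (with allele index
# attribute), "het", or "missing".
parse_gt <- function(gt) {
  gt <- gsub("\\|", "/", gt)
  parts <- strsplit(gt, "/", fixed = TRUE)
  a1 <- vapply(parts, function(x) x[1], character(1))
  a2 <- vapply(parts, function(x) if (length(x) > 1) x[2] else x[1],
               character(1))
  miss <- is.na(gt) | a1 == "." | a2 == "."
  hom <- !miss & a1 == a2
  allele <- rep(NA_integer_, length(gt))
  allele[hom] <- as.integer(a1[hom])
  list(hom = hom, miss = miss, allele = allele)
}

#' Read homozygous strain-pair differences from a VCF
#'
#' Loads a multi-sample VCF and keeps, for one strain pair, only the sites
#' where both strains carry homozygous, non-missing genotype calls that
#' differ from each other — the sites that enter the OSD numerator.
#' Heterozygous or missing calls and sites where the pair is identical are
#' dropped and tallied in a filter log. Multi-allelic records are decomposed
#' into biallelic sites first (a call to a different alternate allele is
#' treated as missing at that biallelic site). Indels are routed to a
#' separate stream from SNVs, since the two are tallied separately.
#'
#' @param path VCF 4.x file with one sample column per strain.
#' @param pair Character vector of the two strain (sample) names to compare.
#' @return Object of class `variant_set`: list with
#'   \describe{
#'     \item{snvs}{data.frame `chrom`, `pos`, `ref`, `alt`, `gt_a`, `gt_b`
#'       of retained SNV difference sites.}
#'     \item{indels}{same layout, indel difference sites.}
#'     \item{filter_log}{named counts: `n_records`, `n_sites`,
#'       `dropped_het`, `dropped_missing`, `dropped_identical`,
#'       `retained_snv`, `retained_indel`.}
#'     \item{pair, samples}{the strain pair and all sample names found.}
#'   }
#' @export
read_variants <- function(path, pair) {
  if (length(pair) != 2) stop("pair must name exactly two strains")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing_strains <- setdiff(pair, samples)
  if (length(missing_strains) > 0)
    stop("unknown strain(s) ", paste(missing_strains, collapse = ", "),
         "; available samples: ", paste(samples, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  n_rec <- nrow(vcf@gt)
  if (is.null(n_rec) || n_rec == 0) {
    return(empty_variant_set(pair, samples))
  }
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  if (anyNA(pos))
    stop("malformed VCF record (non-numeric POS) at record ",
         which(is.na(pos))[1])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  ga <- parse_gt(gt[, pair[1]])
  gb <- parse_gt(gt[, pair[2]])

  # decompose multi-allelic records: one biallelic site per ALT allele
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep(seq_len(n_rec), n_alt)
  k <- sequence(n_alt)
  alt <- unlist(alts)

  # per biallelic site: allele index k maps to hom_alt; 0 to hom_ref; a
  # homozygous call for another alternate allele is missing at this site
  site_call <- function(g, rec, k) {
    al <- g$allele[rec]
    call <- rep("missing", length(rec))
    call[!g$miss[rec] & !g$hom[rec]] <- "het"
    call[g$hom[rec] & al == 0] <- "hom_ref"
    call[g$hom[rec] & !is.na(al) & al == k] <- "hom_alt"
    call
  }
  ca <- site_call(ga, rec, k)
  cb <- site_call(gb, rec, k)

  het <- ca == "het" | cb == "het"
  miss <- !het & (ca == "missing" | cb == "missing")
  ident <- !het & !miss & ca == cb
  keep <- !het & !miss & !ident

  ref <- fix[rec, "REF"]
  is_indel <- nchar(ref) != nchar(alt)
  sites <- data.frame(chrom = fix[rec, "CHROM"][keep],
                      pos = pos[rec][keep],
                      ref = ref[keep], alt = alt[keep],
                      gt_a = ca[keep], gt_b = cb[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  kept_indel <- is_indel[keep]
  structure(list(
    snvs = sites[!kept_indel, , drop = FALSE],
    indels = sites[kept_indel, , drop = FALSE],
    filter_log = c(n_records = n_rec, n_sites = length(rec),
                   dropped_het = sum(het), dropped_missing = sum(miss),
                   dropped_identical = sum(ident),
                   retained_snv = sum(keep & !is_indel),
                   retained_indel = sum(keep & is_indel)),
    pair = pair, samples = samples
  ), class = "variant_set")
}

empty_variant_set <- function(pair, samples) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      gt_a = character(0), gt_b = character(0))
  structure(list(
    snvs = empty, indels = empty,
    filter_log = c(n_records = 0, n_sites = 0, dropped_het = 0,
                   dropped_missing = 0, dropped_identical = 0,
                   retained_snv = 0, retained_indel = 0),
    pair = pair, samples = samples
  ), class = "variant_set")
}

#' Tile chromosomes with fixed non-overlapping windows
#'
#' Builds the genome-wide grid of non-overlapping windows (default 100 kb)
#' on which OSD is computed. Per chromosome the windows are
#' `[0, w), [w, 2w), ...` in 0-based half-open coordinates; a trailing
#' partial window is retained and flagged.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param window_size Window width in bp (default 100,000).
#' @return data.frame of class `genome_windows` with `chrom`, `start`,
#'   `end`, `partial`; attributes `window_size` and `chrom_sizes`.
#' @export
#' @examples
#' build_windows(c(chr1 = 250000))  # 3 windows, last one partial
build_windows <- function(chrom_sizes, window_size = 100000) {
  if (window_size < 1) stop("window_size must be positive")
  if (any(chrom_sizes <= 0)) stop("zero-length chromosome in chrom_sizes")
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  per_chrom <- lapply(names(chrom_sizes), function(chrom) {
    len <- chrom_sizes[[chrom]]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = chrom, start = starts, end = ends,
               partial = (ends - starts) < window_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  structure(out, class = c("genome_windows", "data.frame"),
            window_size = window_size, chrom_sizes = chrom_sizes)
}

#' Per-window callable-base counts from zero-coverage gap masks
#'
#' A base is callable for a comparison only if it lies outside every
#' compared strain's zero-coverage gaps. For each window this returns
#' `window length - |window intersect union(gaps)|`; the result is the OSD
#' denominator.
#'
#' @param windows A [build_windows()] object.
#' @param ... One gap-interval data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open) per strain in the comparison, or a single list of them.
#' @return Numeric vector of callable-base counts, aligned with
#'   `windows` rows.
#' @export
callable_mask <- function(windows, ...) {
  stopifnot(inherits(windows, "genome_windows"))
  gap_sets <- list(...)
  if (length(gap_sets) == 1 && is.list(gap_sets[[1]]) &&
      !is.data.frame(gap_sets[[1]]))
    gap_sets <- gap_sets[[1]]
  gaps <- do.call(rbind, lapply(gap_sets, function(g)
    g[, c("chrom", "start", "end"), drop = FALSE]))
  if (is.null(gaps))
    gaps <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0))
  unknown <- setdiff(unique(gaps$chrom), unique(windows$chrom))
  if (length(unknown) > 0) {
    warning("skipping gap intervals on unknown chromosome(s): ",
            paste(unknown, collapse = ", "))
    gaps <- gaps[!(gaps$chrom %in% unknown), , drop = FALSE]
  }
  callable <- windows$end - windows$start
  for (chrom in unique(gaps$chrom)) {
    g <- gaps[gaps$chrom == chrom, , drop = FALSE]
    gr <- IRanges::reduce(IRanges::IRanges(g$start + 1, g$end))
    idx <- which(windows$chrom == chrom)
    wr <- IRanges::IRanges(windows$start[idx] + 1, windows$end[idx])
    ov <- IRanges::findOverlaps(wr, gr)
    if (length(ov) > 0) {
      inter <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                   gr[S4Vectors::subjectHits(ov)])
      masked <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      callable[idx[as.integer(names(masked))]] <-
        callable[idx[as.integer(names(masked))]] - as.numeric(masked)
    }
  }
  callable
}
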