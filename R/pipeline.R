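#' Configuration for an end-to-end pairwise OSD run
#'
#' @param vcf Multi-sample VCF path.
#' @param pair Character vector of the two strain names.
#' @param gaps_a,gaps_b Zero-coverage gap BED paths for the two strains.
#' @param chrom_sizes Chromosome-sizes TSV path.
#' @param qtl Optional QTL BED-like TSV path (enables fine-mapping output).
#' @param out_dir Output directory for run artifacts.
#' @param window_size Window width in bp (>= 1000; default 100,000).
#' @param grid_points Density grid size (default 401).
#' @param bandwidth Optional explicit KDE bandwidth override.
#' @param pet Optional explicit PET override (skips valley detection).
#' @param min_callable_frac Usable-window floor (default 0.10).
#' @param seed Integer seed recorded in the run log (the scan itself is
#'   deterministic; the seed funnels any simulation upstream).
#' @return Validated list of class `run_config`.
#' @export
run_config <- function(vcf, pair, gaps_a, gaps_b, chrom_sizes,
                       qtl = NULL, out_dir = ".",
                       window_size = 100000, grid_points = 401,
                       bandwidth = NULL, pet = NULL,
                       min_callable_frac = 0.1, seed = 1L) {
  paths <- c(vcf = vcf, gaps_a = gaps_a, gaps_b = gaps_b,
             chrom_sizes = chrom_sizes)
  if (!is.null(qtl)) paths <- c(paths, qtl = qtl)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("input file(s) not found: ",
         paste(names(missing), "=", missing, collapse = ", "))
  if (window_size < 1000) stop("window_size must be >= 1000")
  if (length(pair) != 2) stop("pair must name exactly two strains")
  structure(list(vcf = vcf, pair = pair, gaps_a = gaps_a, gaps_b = gaps_b,
                 chrom_sizes = chrom_sizes, qtl = qtl, out_dir = out_dir,
                 window_size = window_size, grid_points = grid_points,
                 bandwidth = bandwidth, pet = pet,
                 min_callable_frac = min_callable_frac,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pairwise OSD scan
#'
#' Executes read -> callable mask -> per-window OSD -> density -> PET ->
#' block merging -> summary for one strain pair, and writes the run
#' artifacts: a window table TSV, blocks BED and TSV, a density-profile
#' TSV, a one-row summary TSV, and a plain-text log of filter and window
#' counts. If the OSD density is unimodal (no valley), the run completes
#' with an empty block list and the summary flagged `unimodal`; the
#' condition is reported in the log, not swallowed.
#'
#' @param config A [run_config()].
#' @return List of class `pairwise_run`: `osd_windows`, `profile`, `pet`
#'   (NA when unimodal), `unimodal`, `blocks`, `summary`, `variants`
#'   (filter log only), `qtl_overlap` (when a QTL file was configured),
#'   `paths` (named artifact paths).
#' @export
run_pairwise <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  prefix <- file.path(cfg$out_dir, paste(cfg$pair, collapse = "_vs_"))
  comparison <- paste(cfg$pair, collapse = "/")

  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  variants <- read_variants(cfg$vcf, cfg$pair)
  gaps_a <- read_bed(cfg$gaps_a)
  gaps_b <- read_bed(cfg$gaps_b)
  windows <- build_windows(sizes, cfg$window_size)
  callable <- callable_mask(windows, gaps_a, gaps_b)
  osd <- compute_osd(variants, windows, callable, cfg$min_callable_frac)
  profile <- estimate_density(osd, cfg$grid_points, cfg$bandwidth)

  unimodal <- FALSE
  if (!is.null(cfg$pet)) {
    pet <- cfg$pet
  } else {
    pet <- tryCatch(as.numeric(find_pet(profile)),
                    osd_no_valley = function(e) {
                      unimodal <<- TRUE
                      NA_real_
                    })
  }
  blocks <- if (unimodal) merge_blocks(osd, Inf) else merge_blocks(osd, pet)
  summary <- summarize_comparison(osd, blocks, variants,
                                  if (unimodal) NA_real_ else pet,
                                  comparison = comparison)
  summary$unimodal <- unimodal

  qtl_overlap <- NULL
  if (!is.null(cfg$qtl))
    qtl_overlap <- intersect_qtl(blocks, read_qtl(cfg$qtl))

  paths <- c(windows = paste0(prefix, ".windows.tsv"),
             blocks_tsv = paste0(prefix, ".blocks.tsv"),
             blocks_bed = paste0(prefix, ".blocks.bed"),
             density = paste0(prefix, ".density.tsv"),
             summary = paste0(prefix, ".summary.tsv"),
             log = paste0(prefix, ".log"))
  write_tsv_plain(as.data.frame(osd), paths[["windows"]])
  write_tsv_plain(as.data.frame(blocks), paths[["blocks_tsv"]])
  write_bed(blocks, paths[["blocks_bed"]])
  write_tsv_plain(data.frame(grid = profile$grid,
                             density = profile$density),
                  paths[["density"]])
  write_tsv_plain(as.data.frame(summary), paths[["summary"]])
  if (!is.null(qtl_overlap)) {
    paths <- c(paths, qtl = paste0(prefix, ".qtl_overlap.tsv"))
    write_tsv_plain(qtl_overlap$per_qtl, paths[["qtl"]])
  }
  fl <- variants$filter_log
  log_lines <- c(
    paste0("run: ", comparison),
    paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", cfg$seed),
    paste0("window_size: ", cfg$window_size),
    paste0("grid_points: ", cfg$grid_points),
    paste0("bandwidth: ", format(profile$bandwidth, digits = 6)),
    paste0("pet: ", if (unimodal) "NA (unimodal, no valley)" else
      format(pet, digits = 6)),
    paste0(names(fl), ": ", fl),
    paste0("windows_excluded_low_callable: ", sum(!osd$usable)),
    paste0("windows_partial: ", sum(osd$partial)))
  writeLines(log_lines, paths[["log"]])

  structure(list(osd_windows = osd, profile = profile,
                 pet = if (unimodal) NA_real_ else pet,
                 unimodal = unimodal, blocks = blocks, summary = summary,
                 variants = variants, qtl_overlap = qtl_overlap,
                 paths = paths),
            class = "pairwise_run")
}

write_tsv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num))
    df[[j]] <- format(df[[j]], digits = 15, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render multi-comparison summary and per-chromosome block tables
#'
#' Builds the two standard report layouts: a multi-comparison summary table
#' with a group-averages row (computed from the unrounded per-comparison
#' values, then rounded for display), and a per-chromosome block listing
#' with coordinates rounded to 0.1 Mb.
#'
#' @param summaries List of [summarize_comparison()] rows (or a single
#'   data.frame of such rows) for one comparison group.
#' @param blocks Optional [merge_blocks()] result to render as the block
#'   listing.
#' @return List with `summary_table` (per-comparison rows plus an
#'   `"Average"` row) and `block_table` (or NULL): `block`, `chrom`,
#'   `start_mb`, `end_mb`, `length_mb`.
#' @export
report_tables <- function(summaries, blocks = NULL) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  if (length(summaries) == 0) stop("missing artifact: summaries")
  need <- c("comparison", "pet", "n_windows_above", "pct_windows_above",
            "n_blocks", "mean_block_length", "sd_block_length",
            "mean_osd_below", "mean_osd_above", "n_snps_total",
            "n_snps_in_blocks", "pct_snps_in_blocks")
  rows <- do.call(rbind, lapply(summaries, function(s) {
    miss <- setdiff(need, names(s))
    if (length(miss) > 0)
      stop("missing artifact column(s) in summary: ",
           paste(miss, collapse = ", "))
    as.data.frame(s)[, need, drop = FALSE]
  }))
  num_cols <- setdiff(need, "comparison")
  avg <- rows[1, , drop = FALSE]
  avg$comparison <- "Average"
  for (cl in num_cols) avg[[cl]] <- mean(rows[[cl]], na.rm = TRUE)
  tab <- rbind(rows, avg)
  disp <- tab
  disp$pet <- signif(disp$pet, 3)
  disp$mean_osd_below <- signif(disp$mean_osd_below, 3)
  disp$mean_osd_above <- signif(disp$mean_osd_above, 3)
  for (cl in c("n_windows_above", "n_blocks", "mean_block_length",
               "sd_block_length", "n_snps_total", "n_snps_in_blocks"))
    disp[[cl]] <- round(disp[[cl]])
  for (cl in c("pct_windows_above", "pct_snps_in_blocks"))
    disp[[cl]] <- round(disp[[cl]], 2)
  rownames(disp) <- NULL

  block_table <- NULL
  if (!is.null(blocks)) {
    block_table <- data.frame(
      block = seq_len(nrow(blocks)),
      chrom = blocks$chrom,
      start_mb = round(blocks$start / 1e6, 1),
      end_mb = round(blocks$end / 1e6, 1),
      length_mb = round((blocks$end - blocks$start) / 1e6, 1),
      stringsAsFactors = FALSE)
  }
  list(summary_table = disp, block_table = block_table)
}
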