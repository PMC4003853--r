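#' Read a QTL interval table
#'
#' @param path BED-like TSV: chrom, start, end (0-based half-open) and a
#'   trait-label column.
#' @return data.frame `chrom`, `start`, `end`, `trait`.
#' @export
read_qtl <- function(path) {
  df <- read_bed(path)
  if ("name" %in% names(df)) names(df)[names(df) == "name"] <- "trait"
  else df$trait <- NA_character_
  df
}

as_iranges_by_chrom <- function(df) {
  split(IRanges::IRanges(df$start + 1, df$end), df$chrom)
}

overlap_bp <- function(a, b) {
  # total bp of intersection between two interval data.frames
  # (0-based half-open), after per-chromosome union
  total <- 0
  for (chrom in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- IRanges::reduce(IRanges::IRanges(
      a$start[a$chrom == chrom] + 1, a$end[a$chrom == chrom]))
    rb <- IRanges::reduce(IRanges::IRanges(
      b$start[b$chrom == chrom] + 1, b$end[b$chrom == chrom]))
    total <- total + sum(IRanges::width(IRanges::intersect(ra, rb)))
  }
  total
}

union_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(vapply(split(df, df$chrom), function(d)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(d$start + 1, d$end)))), numeric(1)))
}

#' Fine-map QTL intervals by intersection with divergent haplotype blocks
#'
#' Within a QTL interval, only the sub-regions that fall inside divergent
#' haplotype blocks can harbour the ancestrally selected variants that cause
#' the phenotype difference; everything identical by descent between the
#' mapped strains is excluded. This reports, per QTL and genome-wide, the
#' QTL bp covered by blocks and the resulting percentage narrowing
#' (100 - % covered). Overlapping QTL intervals are merged (union
#' semantics) for the genome-wide totals; per-trait rows keep them separate.
#'
#' @param blocks A [merge_blocks()] result (or any data.frame of 0-based
#'   half-open intervals with `chrom`, `start`, `end`).
#' @param qtl data.frame `chrom`, `start`, `end`, `trait`
#'   (see [read_qtl()]).
#' @return Object of class `qtl_overlap`: list with
#'   \describe{
#'     \item{per_qtl}{data.frame: one row per QTL interval with `qtl_bp`,
#'       `covered_bp`, `pct_covered`, `pct_narrowing`, `n_blocks`.}
#'     \item{genome}{named numeric: `total_qtl_bp` (union), `covered_bp`,
#'       `pct_covered`, `pct_narrowing`.}
#'     \item{blocks_by_qtl}{list (per QTL row) of the overlapping blocks.}
#'   }
#' @export
intersect_qtl <- function(blocks, qtl) {
  stopifnot(all(c("chrom", "start", "end") %in% names(qtl)))
  per <- lapply(seq_len(nrow(qtl)), function(i) {
    q <- qtl[i, , drop = FALSE]
    b <- blocks[blocks$chrom == q$chrom & blocks$end > q$start &
                blocks$start < q$end, , drop = FALSE]
    cov <- overlap_bp(q, b)
    list(row = data.frame(
      chrom = q$chrom, start = q$start, end = q$end,
      trait = if ("trait" %in% names(q)) q$trait else NA_character_,
      qtl_bp = q$end - q$start, covered_bp = cov,
      pct_covered = 100 * cov / (q$end - q$start),
      pct_narrowing = 100 - 100 * cov / (q$end - q$start),
      n_blocks = nrow(b), stringsAsFactors = FALSE),
      blocks = b)
  })
  per_qtl <- do.call(rbind, lapply(per, `[[`, "row"))
  rownames(per_qtl) <- NULL
  total <- union_bp(qtl)
  covered <- overlap_bp(qtl, blocks)
  structure(list(
    per_qtl = per_qtl,
    genome = c(total_qtl_bp = total, covered_bp = covered,
               pct_covered = if (total > 0) 100 * covered / total else 0,
               pct_narrowing = if (total > 0)
                 100 - 100 * covered / total else 0),
    blocks_by_qtl = lapply(per, `[[`, "blocks")
  ), class = "qtl_overlap")
}

#' Haplotype blocks from a SNP genotyping panel
#'
#' For a strain pair, each panel SNP is polymorphic (the two strains carry
#' different alleles) or monomorphic. Each maximal run of polymorphic SNPs
#' defines one haplotype block bounded by the nearest flanking monomorphic
#' SNPs; at a chromosome edge with no flanking monomorphic SNP the
#' chromosome bound is used instead (when `chrom_sizes` is supplied;
#' otherwise the run's outermost SNP). SNPs with a missing call in either
#' strain are dropped first.
#'
#' @param panel data.frame: `chrom`, `pos` (1-based, strictly increasing
#'   within chromosome) and one allele column per strain.
#' @param pair Character vector of two strain column names.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open; bounds sit
#'   at the flanking monomorphic SNP positions), plus `n_polymorphic`.
#' @export
panel_blocks <- function(panel, pair, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(panel)),
            all(pair %in% names(panel)), length(pair) == 2)
  a <- as.character(panel[[pair[1]]])
  b <- as.character(panel[[pair[2]]])
  ok <- !is.na(a) & !is.na(b) & a != "" & b != ""
  panel <- panel[ok, , drop = FALSE]
  poly <- a[ok] != b[ok]
  out <- list()
  for (chrom in unique(panel$chrom)) {
    idx <- which(panel$chrom == chrom)
    pos <- panel$pos[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("panel positions must be strictly increasing within ", chrom)
    p <- poly[idx]
    if (!any(p)) next
    r <- rle(p)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1
    for (j in which(r$values)) {
      left_snp <- run_start[j] - 1   # nearest monomorphic SNP to the left
      right_snp <- run_end[j] + 1
      left <- if (left_snp >= 1) pos[left_snp] - 1 else 0
      right <- if (right_snp <= length(pos)) pos[right_snp] else
        if (!is.null(chrom_sizes) && chrom %in% names(chrom_sizes))
          chrom_sizes[[chrom]] else pos[run_end[j]]
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = left, end = right,
        n_polymorphic = r$lengths[j], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_polymorphic = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify OSD blocks against genotyping-panel blocks
#'
#' Labels each sequence-derived (OSD) haplotype block by its relation to the
#' genotyping-panel block set: `novel` (no overlap with any panel block),
#' `refined` (strictly inside a longer panel block — resequencing sharpened
#' the boundaries), `extended` (reaches beyond every overlapping panel
#' block on at least one side), or `concordant` (same extent).
#'
#' @param osd_blocks Interval data.frame (`chrom`, `start`, `end`), 0-based
#'   half-open, e.g. from [merge_blocks()].
#' @param geno_blocks Interval data.frame from [panel_blocks()].
#' @return `osd_blocks` with an added `label` column.
#' @export
compare_blocksets <- function(osd_blocks, geno_blocks) {
  label <- character(nrow(osd_blocks))
  for (i in seq_len(nrow(osd_blocks))) {
    o <- osd_blocks[i, ]
    g <- geno_blocks[geno_blocks$chrom == o$chrom &
                     geno_blocks$end > o$start &
                     geno_blocks$start < o$end, , drop = FALSE]
    if (nrow(g) == 0) { label[i] <- "novel"; next }
    contained <- any(g$start <= o$start & g$end >= o$end)
    if (!contained) { label[i] <- "extended"; next }
    strictly_inside <- any(g$start <= o$start & g$end >= o$end &
                           (g$end - g$start) > (o$end - o$start))
    label[i] <- if (strictly_inside) "refined" else "concordant"
  }
  out <- osd_blocks
  out$label <- label
  out
}

#' Consequence-term vocabulary for functional variant classes
#'
#' The fixed mapping from functional classes to the predictor's consequence
#' terms: non-synonymous coding (`NON_SYNONYMOUS_CODING`), splice site
#' (`SPLICE_SITE`, `ESSENTIAL_SPLICE_SITE`), frameshift
#' (`FRAMESHIFT_CODING`) and stop gained (`STOP_GAINED`).
#'
#' @return Named list: class label -> character vector of terms.
#' @export
consequence_classes <- function() {
  list(non_synonymous = "NON_SYNONYMOUS_CODING",
       splice_site = c("SPLICE_SITE", "ESSENTIAL_SPLICE_SITE"),
       frameshift = "FRAMESHIFT_CODING",
       stop_gained = "STOP_GAINED")
}

#' Filter annotated variants by functional consequence class
#'
#' Retains the variants whose annotation contains at least one consequence
#' term of a wanted class, and attaches the matched class labels. Classes
#' may be given as class labels (`"non_synonymous"`, `"splice_site"`,
#' `"frameshift"`, `"stop_gained"`) or as raw consequence terms.
#'
#' @param variants data.frame with a `consequences` column: consequence
#'   terms separated by `&`, `,` or `;`.
#' @param classes Wanted classes (labels or terms). Default: all four.
#' @return The retained rows with an added `classes` column (comma-joined
#'   matched labels).
#' @export
filter_consequences <- function(variants,
                                classes = names(consequence_classes())) {
  stopifnot("consequences" %in% names(variants))
  vocab <- consequence_classes()
  all_terms <- unlist(vocab, use.names = FALSE)
  wanted <- character(0)
  for (cl in classes) {
    if (cl %in% names(vocab)) wanted <- c(wanted, cl)
    else if (cl %in% all_terms)
      wanted <- c(wanted, names(vocab)[vapply(vocab, function(v)
        cl %in% v, logical(1))])
    else stop("unknown consequence class or term: ", cl,
              "; vocabulary: ", paste(names(vocab), collapse = ", "),
              " (terms: ", paste(all_terms, collapse = ", "), ")")
  }
  wanted <- unique(wanted)
  term_lists <- strsplit(as.character(variants$consequences), "[&,;]\\s*")
  labels <- vapply(term_lists, function(terms) {
    hit <- wanted[vapply(vocab[wanted], function(v)
      any(terms %in% v), logical(1))]
    paste(hit, collapse = ",")
  }, character(1))
  out <- variants[nzchar(labels), , drop = FALSE]
  out$classes <- labels[nzchar(labels)]
  rownames(out) <- NULL
  out
}

#' Define a phenotype-grouped strain panel
#'
#' @param strains All strains in the panel.
#' @param phenotype_groups Named list: group name -> strain subset.
#' @param exclusions Strains removed from the panel before any testing
#'   (e.g. reference-identical substrains, or strains with a confounding
#'   phenotype).
#' @return Object of class `strain_panel` with `strains` (after
#'   exclusions), `phenotype_groups` (after exclusions), `exclusions`.
#' @export
strain_panel <- function(strains, phenotype_groups,
                         exclusions = character(0)) {
  stopifnot(is.list(phenotype_groups), !is.null(names(phenotype_groups)))
  bad <- setdiff(unlist(phenotype_groups), strains)
  if (length(bad) > 0)
    stop("group members not in panel: ", paste(bad, collapse = ", "))
  kept <- setdiff(strains, exclusions)
  groups <- lapply(phenotype_groups, setdiff, y = exclusions)
  structure(list(strains = kept, phenotype_groups = groups,
                 exclusions = intersect(exclusions, strains)),
            class = "strain_panel")
}

#' Metabolic-syndrome phenotype groupings for rat strain panels
#'
#' The standard groupings used for enrichment testing across sequenced rat
#' strains: obese (LH, SBH, SS, SHR, LL, LEW), dyslipidemic (LH, SS, SHR)
#' and hypertensive (LH, FHH, MHS, SBH, SHR, SHRSP, SS).
#'
#' @return Named list of strain name vectors.
#' @export
mets_strain_groups <- function() {
  list(obese = c("LH", "SBH", "SS", "SHR", "LL", "LEW"),
       dyslipidemic = c("LH", "SS", "SHR"),
       hypertensive = c("LH", "FHH", "MHS", "SBH", "SHR", "SHRSP", "SS"))
}

#' Carrier status of strains at one variant
#'
#' Determines which strains are homozygous for the minor allele at a
#' biallelic site. The minor allele is the rarer of the two alleles among
#' homozygous calls; heterozygous or missing strains are indeterminate and
#' are excluded from that variant's enrichment table (their count is
#' returned).
#'
#' @param genotypes Named character vector of per-strain genotypes,
#'   e.g. `"G/G"`, `"G/T"`, `NA`. A single letter is read as homozygous.
#' @return List: `carriers`, `non_carriers`, `indeterminate`,
#'   `minor_allele`.
#' @export
carrier_status <- function(genotypes) {
  gt <- gsub("\\|", "/", as.character(genotypes))
  one <- !is.na(gt) & !grepl("/", gt)
  gt[one] <- paste0(gt[one], "/", gt[one])
  parts <- strsplit(gt, "/", fixed = TRUE)
  a1 <- vapply(parts, `[`, character(1), 1)
  a2 <- vapply(parts, function(x) if (length(x) > 1) x[2] else NA_character_,
               character(1))
  hom <- !is.na(a1) & !is.na(a2) & a1 == a2 & a1 != "."
  alleles <- a1[hom]
  if (length(unique(alleles)) < 2)
    stop("site is monomorphic among homozygous calls")
  tab <- sort(table(alleles))
  minor <- names(tab)[1]
  strains <- names(genotypes)
  list(carriers = strains[hom][alleles == minor],
       non_carriers = strains[hom][alleles != minor],
       indeterminate = strains[!hom],
       minor_allele = minor)
}

#' Fisher exact test of carrier enrichment in a phenotype group
#'
#' Builds the 2x2 table (carrier / non-carrier) x (in-group / out-group)
#' over the panel strains after exclusions and returns the two-tailed exact
#' p-value: the sum of the probabilities of all tables with the same
#' margins whose hypergeometric probability does not exceed that of the
#' observed table.
#'
#' @param carriers Strains homozygous for the minor allele
#'   (subset of the panel after exclusions).
#' @param panel A [strain_panel()].
#' @param group Phenotype-group name in the panel.
#' @param variant_id Optional variant label carried into the result.
#' @param indeterminate Strains with heterozygous/missing calls to drop
#'   from this variant's table (default none).
#' @return Object of class `enrichment_result`: list with `variant_id`,
#'   `group`, `table` (2x2 matrix), `p_two_tailed`, `n_indeterminate`.
#' @export
fisher_enrichment <- function(carriers, panel, group,
                              variant_id = NA_character_,
                              indeterminate = character(0)) {
  stopifnot(inherits(panel, "strain_panel"))
  if (!group %in% names(panel$phenotype_groups))
    stop("unknown group: ", group, "; available: ",
         paste(names(panel$phenotype_groups), collapse = ", "))
  strains <- setdiff(panel$strains, indeterminate)
  grp <- setdiff(panel$phenotype_groups[[group]], indeterminate)
  if (length(grp) == 0)
    stop("phenotype group '", group, "' is empty after exclusions")
  bad <- setdiff(carriers, strains)
  if (length(bad) > 0)
    stop("carriers not in panel (after exclusions): ",
         paste(bad, collapse = ", "))
  in_grp <- strains %in% grp
  carrier <- strains %in% carriers
  tab <- matrix(c(sum(carrier & in_grp), sum(carrier & !in_grp),
                  sum(!carrier & in_grp), sum(!carrier & !in_grp)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("carrier", "non_carrier"),
                                c("in_group", "out_group")))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(variant_id = variant_id, group = group, table = tab,
                 p_two_tailed = min(p, 1),
                 n_indeterminate = length(intersect(indeterminate,
                                                    panel$strains))),
            class = "enrichment_result")
}
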