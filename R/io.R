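# Reading, writing and quality-filtering genotype panels.
#
# Filters mirror the conventional resequencing pipeline: genotype-level
# depth masking (GD < 5 or above the individual's mean depth + 3 SD), then
# site-level removal on minor allele count < 3 and missingness > 0.10.
# All boundary conventions are strict inequalities, exactly as stated.

#' Read a genotype panel from a VCF
#'
#' Retains biallelic SNP records only (multi-allelic sites and indels are
#' dropped and counted), maps missing genotypes to `NA` and captures the
#' per-genotype `DP` field when present.
#'
#' @param vcf_path path to a VCF 4.x file (plain or gzipped).
#' @param population_map either a data.frame with columns `id`,
#'   `population` and optionally `group`, or the path of a tab-separated
#'   file with those columns. When `NULL`, all samples are placed in a
#'   single population `"pop1"`.
#' @param category_table optional data.frame or TSV path with columns
#'   `scaffold` (or `CHROM`), `pos` (or `POS`) and `category`.
#' @return A [genotype_panel()]. The number of non-biallelic-SNP records
#'   dropped is available as `attr(panel, "dropped_records")`.
#' @export
read_genotypes <- function(vcf_path, population_map = NULL,
                           category_table = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snp <- vcfR::is.biallelic(v) &
    nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  dropped <- sum(!snp)
  if (!any(snp)) stop("no biallelic SNP records in ", vcf_path)
  v <- v[snp, ]
  fix <- fix[snp, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(g) {
    a <- substr(g, 1, 1); b <- substr(g, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  }
  dosage <- t(apply(gt, 2, conv))
  dosage <- matrix(as.integer(dosage), nrow = ncol(gt),
                   dimnames = list(colnames(gt), NULL))
  depth <- NULL
  if (any(grepl("##FORMAT=<ID=DP", v@meta, fixed = TRUE))) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- t(dp)
  }
  ids <- colnames(gt)
  if (is.null(population_map)) {
    ind <- data.frame(id = ids, population = "pop1", group = "pop1")
  } else {
    pm <- if (is.character(population_map))
      utils::read.table(population_map, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else population_map
    if (!all(ids %in% pm$id))
      stop("samples missing from population map: ",
           paste(setdiff(ids, pm$id), collapse = ", "))
    ind <- pm[match(ids, pm$id), , drop = FALSE]
    if (is.null(ind$group)) ind$group <- ind$population
  }
  sites <- data.frame(scaffold = fix$CHROM, pos = as.numeric(fix$POS),
                      ref = fix$REF, alt = fix$ALT)
  if (!is.null(category_table)) {
    ct <- if (is.character(category_table))
      utils::read.table(category_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else category_table
    names(ct) <- sub("^CHROM$", "scaffold", sub("^POS$", "pos", names(ct)))
    key <- paste(sites$scaffold, sites$pos)
    idx <- match(key, paste(ct$scaffold, ct$pos))
    sites$category <- ifelse(is.na(idx), "unclassified", ct$category[idx])
  }
  panel <- genotype_panel(dosage, sites, ind, depth = depth)
  attr(panel, "dropped_records") <- dropped
  panel
}

#' Write a genotype panel as VCF 4.2
#'
#' @param panel genotype panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=hbdload", con)
  for (sc in names(panel$scaffold_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", sc,
                       as.integer(panel$scaffold_lengths[[sc]])), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  has_dp <- !is.null(panel$depth)
  if (has_dp)
    writeLines('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
               con)
  ids <- panel$individuals$id
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  s <- panel$sites
  ref <- if (is.null(s$ref)) rep("A", nrow(s)) else s$ref
  alt <- if (is.null(s$alt)) rep("T", nrow(s)) else s$alt
  for (j in seq_len(nrow(s))) {
    g <- panel$dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1])
    if (has_dp) {
      dp <- panel$depth[, j]
      gt <- paste(gt, ifelse(is.na(dp), ".", dp), sep = ":")
    }
    writeLines(paste(c(s$scaffold[j], s$pos[j], ".", ref[j], alt[j], ".",
                       "PASS", ".", if (has_dp) "GT:DP" else "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Mask genotypes by sequencing depth
#'
#' Sets to missing any genotype whose depth is below `min_depth` or
#' strictly above the individual's mean depth plus `sd_multiplier` times
#' the individual's depth standard deviation. Both thresholds are computed
#' per individual before any masking.
#'
#' @param panel genotype panel with a depth matrix.
#' @param min_depth minimum genotype depth (strict `<` masks; default 5).
#' @param sd_multiplier upper bound is mean + `sd_multiplier` * SD
#'   (strict `>` masks; default 3).
#' @param drop_individuals if `TRUE`, individuals (not genotypes) failing
#'   either rule at any site are removed wholesale instead; off by
#'   default, masking being the conservative reading.
#' @return The masked panel; counts of masked genotypes are in
#'   `attr(, "masked_genotypes")`.
#' @export
mask_by_depth <- function(panel, min_depth = 5, sd_multiplier = 3,
                          drop_individuals = FALSE) {
  if (is.null(panel$depth))
    stop("panel has no per-genotype depth; cannot apply the depth rule")
  dp <- panel$depth
  mu <- rowMeans(dp, na.rm = TRUE)
  sdv <- apply(dp, 1, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv)] <- 0
  hi <- mu + sd_multiplier * sdv
  bad <- (dp < min_depth) | (dp > hi)   # strict inequalities as printed
  bad[is.na(bad)] <- TRUE
  if (drop_individuals) {
    keep <- rowSums(bad) == 0
    out <- panel[keep, ]
    attr(out, "masked_genotypes") <- 0L
    return(out)
  }
  panel$dosage[bad] <- NA_integer_
  attr(panel, "masked_genotypes") <- sum(bad)
  panel
}

#' Filter sites on minor allele count and missingness
#'
#' Removes sites with within-panel minor allele count below `min_mac`
#' (strict `<`) or missing-genotype fraction above `max_missing`
#' (strict `>`). Site order is preserved; the operation is idempotent.
#'
#' @param panel genotype panel.
#' @param min_mac minimum minor allele count (default 3).
#' @param max_missing maximum missing fraction (default 0.10).
#' @return Filtered panel; per-rule removal counts in
#'   `attr(, "filter_report")`.
#' @export
filter_sites <- function(panel, min_mac = 3, max_missing = 0.10) {
  d <- panel$dosage
  alt <- colSums(d, na.rm = TRUE)
  n_ok <- colSums(!is.na(d))
  mac <- pmin(alt, 2 * n_ok - alt)
  miss <- colMeans(is.na(d))
  low_mac <- mac < min_mac
  high_miss <- miss > max_missing
  keep <- !(low_mac | high_miss)
  out <- panel[, keep]
  attr(out, "filter_report") <- c(removed_mac = sum(low_mac),
                                  removed_missing = sum(high_miss),
                                  kept = sum(keep))
  out
}

#' Genetic map
#'
#' @param anchors data.frame with columns `scaffold`, `pos` (bp) and
#'   `cM` (or `gpos` in Morgans), or the path of such a TSV. Genetic
#'   positions must be non-decreasing in physical position per scaffold.
#' @param default_rate Morgans per bp used for scaffolds absent from the
#'   map and beyond the outermost anchors (default 2e-8).
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(anchors, default_rate = 2e-8) {
  if (is.character(anchors))
    anchors <- utils::read.table(anchors, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  names(anchors) <- sub("^CHROM$", "scaffold", sub("^POS$", "pos",
                                                   names(anchors)))
  if (!is.null(anchors$cM) && is.null(anchors$gpos))
    anchors$gpos <- anchors$cM / 100
  if (!all(c("scaffold", "pos", "gpos") %in% names(anchors)))
    stop("map needs scaffold, pos and cM (or gpos) columns")
  anchors <- anchors[order(anchors$scaffold, anchors$pos), , drop = FALSE]
  for (sc in unique(anchors$scaffold)) {
    g <- anchors$gpos[anchors$scaffold == sc]
    if (any(diff(g) < 0))
      stop("genetic positions decrease within scaffold ", sc,
           "; map must be sorted and monotone")
  }
  structure(list(anchors = anchors, default_rate = default_rate),
            class = "genetic_map")
}

#' Interpolate genetic positions onto a panel
#'
#' Linear interpolation between map anchors; beyond the outermost anchors
#' the map is extended from the nearest anchor at `default_rate`; scaffolds
#' absent from the map get `pos * default_rate` Morgans throughout.
#'
#' @param panel genotype panel.
#' @param map a [genetic_map()], or `NULL` to apply the constant
#'   `default_rate` everywhere.
#' @param default_rate Morgans per bp fallback (used when `map` is `NULL`;
#'   otherwise the map's own default applies).
#' @return Panel with a populated `gpos` site column (Morgans).
#' @export
interpolate_genetic_positions <- function(panel, map = NULL,
                                          default_rate = 2e-8) {
  s <- panel$sites
  g <- numeric(nrow(s))
  rate <- if (is.null(map)) default_rate else map$default_rate
  for (sc in unique(s$scaffold)) {
    idx <- which(s$scaffold == sc)
    p <- s$pos[idx]
    a <- if (is.null(map)) NULL
         else map$anchors[map$anchors$scaffold == sc, , drop = FALSE]
    if (is.null(a) || nrow(a) == 0) {
      g[idx] <- p * rate
    } else if (nrow(a) == 1) {
      g[idx] <- a$gpos + (p - a$pos) * rate
    } else {
      gi <- stats::approx(a$pos, a$gpos, xout = p, rule = 1)$y
      below <- p < a$pos[1]
      above <- p > a$pos[nrow(a)]
      gi[below] <- a$gpos[1] + (p[below] - a$pos[1]) * rate
      gi[above] <- a$gpos[nrow(a)] + (p[above] - a$pos[nrow(a)]) * rate
      g[idx] <- gi
    }
  }
  g <- pmax(g, 0)
  panel$sites$gpos <- g
  for (sc in unique(s$scaffold)) {
    idx <- which(s$scaffold == sc)
    if (any(diff(panel$sites$gpos[idx]) < 0))
      stop("interpolated genetic positions decrease within scaffold ", sc)
  }
  panel
}

#' Write sidecar tables of a panel
#'
#' Writers for the plain-text companions of a VCF: the sample-to-population
#' table, per-site functional categories, the genetic map implied by the
#' panel's `gpos` column, and truth tracts from the simulator.
#'
#' @param panel genotype panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @name sidecar-writers
NULL

#' @rdname sidecar-writers
#' @export
write_population_table <- function(panel, path) {
  utils::write.table(panel$individuals[, c("id", "population", "group")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sidecar-writers
#' @export
write_category_table <- function(panel, path) {
  df <- data.frame(CHROM = panel$sites$scaffold, POS = panel$sites$pos,
                   CATEGORY = panel$sites$category)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sidecar-writers
#' @export
write_genetic_map <- function(panel, path) {
  if (is.null(panel$sites$gpos)) stop("panel has no genetic positions")
  df <- data.frame(CHROM = panel$sites$scaffold, POS = panel$sites$pos,
                   cM = panel$sites$gpos * 100)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulator truth tracts as BED
#'
#' BED intervals are 0-based half-open; the name column carries the HBD
#' class rate and the fifth column the individual id.
#'
#' @param truth truth component of [generate_panel()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  tr <- truth$tracts
  df <- data.frame(tr$scaffold, as.integer(tr$start_bp),
                   as.integer(tr$end_bp), tr$class_rate, tr$id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
write_truth_summary <- function(truth, path) {
  utils::write.table(truth$autozygous_fraction, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
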