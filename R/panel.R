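#' @useDynLib hbdload, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.CATEGORIES <- c("intergenic", "neutral", "low", "moderate", "high", "unclassified")

#' Genotype panel
#'
#' The substrate of every analysis stage: an individuals-by-sites dosage
#' matrix (0/1/2 copies of the alternate allele, `NA` for missing) plus
#' site, individual and optional per-genotype depth metadata.
#'
#' @param dosage integer/numeric matrix, individuals in rows, sites in
#'   columns. Values must be 0, 1, 2 or `NA`.
#' @param sites data.frame with columns `scaffold`, `pos` (1-based bp) and
#'   optionally `ref`, `alt`, `gpos` (genetic position, Morgans) and
#'   `category` (one of intergenic/neutral/low/moderate/high/unclassified).
#' @param individuals data.frame with columns `id`, `population` and
#'   optionally `group`.
#' @param depth optional matrix of per-genotype sequencing depths, same
#'   dimensions as `dosage`.
#' @param scaffold_lengths optional named numeric vector of scaffold
#'   lengths in bp; defaults to the largest observed position per scaffold.
#'
#' @details Physical positions must be strictly increasing within each
#' scaffold. Positions are 1-based inclusive on the VCF side and converted
#' to 0-based half-open intervals only in BED output.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, sites, individuals, depth = NULL,
                           scaffold_lengths = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(is.na(dosage) | dosage %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (nrow(sites) != ncol(dosage))
    stop("sites table and dosage matrix disagree on the number of sites")
  if (nrow(individuals) != nrow(dosage))
    stop("individuals table and dosage matrix disagree on the number of individuals")
  if (!all(c("scaffold", "pos") %in% names(sites)))
    stop("sites needs 'scaffold' and 'pos' columns")
  if (!all(c("id", "population") %in% names(individuals)))
    stop("individuals needs 'id' and 'population' columns")
  sites$scaffold <- as.character(sites$scaffold)
  individuals$id <- as.character(individuals$id)
  if (anyDuplicated(individuals$id))
    stop("individual ids must be unique")
  if (is.null(individuals$group)) individuals$group <- individuals$population
  if (is.null(sites$category)) sites$category <- "unclassified"
  if (!all(sites$category %in% .CATEGORIES))
    stop("unknown site category; allowed: ", paste(.CATEGORIES, collapse = ", "))
  for (sc in unique(sites$scaffold)) {
    p <- sites$pos[sites$scaffold == sc]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within scaffold ", sc)
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    if (!all(dim(depth) == dim(dosage)))
      stop("depth matrix must match dosage dimensions")
  }
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(sites$pos, sites$scaffold, max)
    scaffold_lengths <- stats::setNames(as.numeric(scaffold_lengths),
                                        names(scaffold_lengths))
  }
  rownames(dosage) <- individuals$id
  structure(list(dosage = dosage, sites = sites, individuals = individuals,
                 depth = depth, scaffold_lengths = scaffold_lengths),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "sites on", length(unique(x$sites$scaffold)), "scaffold(s)\n")
  cat("Populations:",
      paste(sprintf("%s (n=%d)", names(table(x$individuals$population)),
                    table(x$individuals$population)), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("Missing genotypes: %.2f%%; depth %s; genetic positions %s\n",
              100 * miss,
              if (is.null(x$depth)) "absent" else "present",
              if (is.null(x$sites$gpos) || all(is.na(x$sites$gpos)))
                "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel
#'
#' @param x genotype panel.
#' @param i individual index (logical, integer or id character vector).
#' @param j site index (logical or integer).
#' @param ... unused.
#' @return A `genotype_panel` restricted to the selected rows/columns.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$individuals$id)
  genotype_panel(x$dosage[i, j, drop = FALSE],
                 x$sites[j, , drop = FALSE],
                 x$individuals[i, , drop = FALSE],
                 depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE],
                 scaffold_lengths = x$scaffold_lengths)
}

#' Per-population (or global) alternate-allele frequencies
#'
#' @param panel genotype panel.
#' @param scope `"population"` for one frequency vector per population,
#'   `"global"` for a single panel-wide vector.
#' @param clamp frequencies are clamped into `[clamp, 1 - clamp]` so that
#'   HMM emission likelihoods stay positive at sites monomorphic in a
#'   population.
#' @return A list of numeric frequency vectors keyed by population name
#'   (scope `"population"`) or a single-element list named `"global"`.
#' @export
allele_frequencies <- function(panel, scope = c("population", "global"),
                               clamp = 1e-6) {
  scope <- match.arg(scope)
  freq1 <- function(rows) {
    d <- panel$dosage[rows, , drop = FALSE]
    f <- colMeans(d, na.rm = TRUE) / 2
    f[is.nan(f)] <- 0.5            # all-missing site: uninformative
    pmin(pmax(f, clamp), 1 - clamp)
  }
  if (scope == "global")
    return(list(global = freq1(seq_len(nrow(panel$dosage)))))
  pops <- unique(panel$individuals$population)
  out <- lapply(pops, function(p) freq1(panel$individuals$population == p))
  names(out) <- pops
  out
}

# genetic distances (Morgans) between adjacent markers, with an effectively
# infinite distance at scaffold boundaries so the chain restarts from the
# stationary mixing distribution on each scaffold.
.marker_distances <- function(sites) {
  g <- sites$gpos
  if (is.null(g) || anyNA(g))
    stop("genetic positions missing; run interpolate_genetic_positions() first")
  d <- diff(g)
  newsc <- sites$scaffold[-1] != sites$scaffold[-nrow(sites)]
  d[newsc] <- 1e9
  if (any(d < 0)) stop("genetic positions must be non-decreasing within scaffold")
  d
}
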