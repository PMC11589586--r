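# Nucleotide diversity, effective population size and block-bootstrap
# uncertainty.

# per-site unbiased heterozygosity terms: 2 d (m - d) / (m (m - 1)),
# d = alt copies among m non-missing copies; sites with m < 2 are NA
.pi_terms <- function(dosage) {
  d <- colSums(dosage, na.rm = TRUE)
  m <- 2 * colSums(!is.na(dosage))
  term <- ifelse(m >= 2, 2 * d * (m - d) / (m * (m - 1)), NA_real_)
  list(term = term, skipped = sum(m < 2))
}

#' Nucleotide diversity
#'
#' Per-site diversity `2 d (m - d) / (m (m - 1))` (expected pairwise
#' difference among the `m` non-missing allele copies, `d` of which carry
#' the alternate allele), averaged over a chosen denominator.
#'
#' @param panel genotype panel.
#' @param population population to estimate in; default all individuals.
#' @param individuals optional explicit id subset (e.g. an unrelated set).
#' @param denominator `"sites"` (number of sites in the analyzed panel,
#'   matching SNP-panel-based estimates, whose absolute values are inflated
#'   relative to per-bp diversity) or a positive number interpreted as a
#'   callable genome length in bp, yielding per-bp diversity.
#' @return Object of class `diversity_estimate`: `pi`, the denominator
#'   mode, the number of usable sites and the count of sites skipped for
#'   having fewer than two non-missing allele copies.
#' @export
nucleotide_diversity <- function(panel, population = NULL,
                                 individuals = NULL,
                                 denominator = "sites") {
  rows <- seq_len(nrow(panel$dosage))
  if (!is.null(population))
    rows <- which(panel$individuals$population %in% population)
  if (!is.null(individuals))
    rows <- intersect(rows, match(individuals, panel$individuals$id))
  if (length(rows) < 2) stop("need at least 2 individuals")
  pt <- .pi_terms(panel$dosage[rows, , drop = FALSE])
  denom <- if (identical(denominator, "sites")) length(pt$term)
           else as.numeric(denominator)
  if (!is.finite(denom) || denom <= 0) stop("invalid denominator")
  pi <- sum(pt$term, na.rm = TRUE) / denom
  structure(list(pi = pi, denominator = denominator,
                 n_sites = sum(!is.na(pt$term)), skipped = pt$skipped),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("pi = %.6g over %d sites (denominator: %s; %d sites skipped)\n",
              x$pi, x$n_sites,
              if (identical(x$denominator, "sites")) "sites in panel"
              else paste0(format(x$denominator, big.mark = ","), " bp"),
              x$skipped))
  invisible(x)
}

#' Effective population size from diversity
#'
#' Under neutral equilibrium, `Ne = pi / (4 mu)`.
#'
#' @param pi nucleotide diversity (a number or a `diversity_estimate`).
#' @param mu per-site per-generation mutation rate; the default 4.6e-9 is
#'   the collared flycatcher pedigree estimate commonly borrowed for birds.
#' @return `Ne`.
#' @export
effective_size <- function(pi, mu = 4.6e-9) {
  if (inherits(pi, "diversity_estimate")) pi <- pi$pi
  if (!is.finite(mu) || mu <= 0) stop("mutation rate must be positive")
  pi / (4 * mu)
}

#' Block bootstrap of diversity and Ne
#'
#' Tiles the genome into physical blocks, resamples blocks with
#' replacement and recomputes the diversity (and `Ne`) on each replicate.
#' The replicate standard deviation is reported as the standard error.
#'
#' @inheritParams nucleotide_diversity
#' @param block_bp block length in bp (default 1 Mb).
#' @param reps bootstrap replicates (default 1000).
#' @param mu mutation rate for the `Ne` transform.
#' @param seed integer seed; the resampling is fully reproducible.
#' @return list with `pi_mean`, `pi_se`, `ne_mean`, `ne_se`, `n_blocks`,
#'   `reps` and the point estimates `pi_hat`, `ne_hat`.
#' @export
block_bootstrap <- function(panel, population = NULL, individuals = NULL,
                            block_bp = 1e6, reps = 1000, mu = 4.6e-9,
                            denominator = "sites", seed = 1L) {
  rows <- seq_len(nrow(panel$dosage))
  if (!is.null(population))
    rows <- which(panel$individuals$population %in% population)
  if (!is.null(individuals))
    rows <- intersect(rows, match(individuals, panel$individuals$id))
  if (length(rows) < 2) stop("need at least 2 individuals")
  pt <- .pi_terms(panel$dosage[rows, , drop = FALSE])
  block <- paste(panel$sites$scaffold,
                 floor((panel$sites$pos - 1) / block_bp))
  ublock <- unique(block)
  B <- length(ublock)
  if (B < 2) stop("fewer than 2 blocks; decrease block_bp")
  bsum <- tapply(ifelse(is.na(pt$term), 0, pt$term), block, sum)[ublock]
  bcnt <- tapply(rep(1, length(block)), block, sum)[ublock]
  per_site <- identical(denominator, "sites")
  .with_seed(seed, {
    pis <- vapply(seq_len(reps), function(r) {
      take <- sample.int(B, B, replace = TRUE)
      if (per_site) sum(bsum[take]) / sum(bcnt[take])
      else sum(bsum[take]) / as.numeric(denominator)
    }, 0.0)
    nes <- pis / (4 * mu)
    pi_hat <- if (per_site) sum(bsum) / sum(bcnt)
              else sum(bsum) / as.numeric(denominator)
    list(pi_hat = pi_hat, ne_hat = pi_hat / (4 * mu),
         pi_mean = mean(pis), pi_se = stats::sd(pis),
         ne_mean = mean(nes), ne_se = stats::sd(nes),
         n_blocks = B, reps = reps)
  })
}

#' Per-population diversity table
#'
#' @param panel genotype panel.
#' @param unrelated_only restrict each population to its
#'   [unrelated_set()] before estimating (the related-sample correction).
#' @param ... passed to [block_bootstrap()].
#' @return data.frame with population, pi, Ne, bootstrap mean/SE and
#'   metadata.
#' @export
diversity_table <- function(panel, unrelated_only = TRUE, ...) {
  out <- NULL
  for (p in unique(panel$individuals$population)) {
    ids <- panel$individuals$id[panel$individuals$population == p]
    if (unrelated_only && length(ids) > 2) {
      sub <- panel[panel$individuals$population == p, ]
      ids <- unrelated_set(allele_sharing_matrix(sub))
      if (length(ids) < 2)
        ids <- panel$individuals$id[panel$individuals$population == p]
    }
    bb <- block_bootstrap(panel, population = p, individuals = ids, ...)
    out <- rbind(out, data.frame(population = p, n = length(ids),
                                 pi = bb$pi_hat, ne = bb$ne_hat,
                                 pi_boot_mean = bb$pi_mean,
                                 pi_se = bb$pi_se,
                                 ne_boot_mean = bb$ne_mean,
                                 ne_se = bb$ne_se,
                                 n_blocks = bb$n_blocks))
  }
  out
}
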