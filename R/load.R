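# Minor-allele load statistics: global minor-allele calling by bootstrap,
# per-individual load counts by functional category, and the R_XY family
# of two-group load ratios with block-jackknife uncertainty.

#' Call minor alleles globally by bootstrap
#'
#' Each replicate draws, with replacement, an equal number of unrelated
#' individuals from every population (the size of the smallest unrelated
#' set by default), counts both alleles globally and votes for the rarer
#' one; a replicate with the two alleles at exactly equal counts votes for
#' the alternate allele. The final call is the across-replicate majority,
#' again breaking an exact tie towards the alternate allele. The call is
#' invariant to relabelling ref/alt at input.
#'
#' @param panel genotype panel.
#' @param unrelated_sets named list `population -> ids`; e.g. built with
#'   [unrelated_set()]. Every population must contribute at least one id.
#' @param reps bootstrap replicates (default 1000).
#' @param n_per_pop individuals drawn per population per replicate;
#'   default the smallest unrelated-set size.
#' @param seed integer seed.
#' @return data.frame of class `minor_allele_call`: per site the minor
#'   allele (`"ref"`/`"alt"`), the fraction of replicates voting for it,
#'   the replicate count, and an `informative` flag (`FALSE` when every
#'   replicate saw the site monomorphic).
#' @export
call_minor_alleles <- function(panel, unrelated_sets, reps = 1000,
                               n_per_pop = NULL, seed = 1L) {
  if (!length(unrelated_sets) || any(!lengths(unrelated_sets)))
    stop("every population needs a non-empty unrelated set")
  rows_by_pop <- lapply(unrelated_sets, function(ids) {
    r <- match(ids, panel$individuals$id)
    if (anyNA(r)) stop("unrelated-set ids missing from panel")
    r
  })
  if (is.null(n_per_pop)) n_per_pop <- min(lengths(rows_by_pop))
  m <- ncol(panel$dosage)
  .with_seed(seed, {
    votes_alt <- integer(m)       # replicates in which alt is the rarer allele
    mono <- integer(m)            # replicates in which the site is monomorphic
    for (r in seq_len(reps)) {
      take <- unlist(lapply(rows_by_pop, function(rr)
        rr[sample.int(length(rr), n_per_pop, replace = TRUE)]))
      d <- panel$dosage[take, , drop = FALSE]
      alt <- colSums(d, na.rm = TRUE)
      tot <- 2 * colSums(!is.na(d))
      ref <- tot - alt
      votes_alt <- votes_alt + (alt <= ref)   # tie votes alt
      mono <- mono + (alt == 0 | ref == 0)
    }
    frac_alt <- votes_alt / reps
    minor <- ifelse(frac_alt >= 0.5, "alt", "ref")  # across-replicate tie: alt
    data.frame(scaffold = panel$sites$scaffold, pos = panel$sites$pos,
               minor = minor,
               vote = pmax(frac_alt, 1 - frac_alt),
               reps = reps,
               informative = mono < reps)
  }) -> out
  class(out) <- c("minor_allele_call", "data.frame")
  out
}

# dosage of the minor allele (0/1/2, NA preserved)
.minor_dosage <- function(panel, calls) {
  X <- panel$dosage
  flip <- calls$minor == "ref"
  X[, flip] <- 2 - X[, flip, drop = FALSE]
  X
}

#' Per-individual minor-allele load counts
#'
#' For every individual and functional category: the minor-allele copy
#' count (heterozygote 1, homozygote 2), the number of homozygous-minor
#' sites, the number of sites at which the individual carries at least one
#' minor allele (its polymorphic-site count), and both counts normalized
#' by that polymorphic-site count. Missing genotypes are skipped; sites
#' lacking a category are reported under `"unclassified"`.
#'
#' @param panel genotype panel (with site categories).
#' @param calls a [call_minor_alleles()] table covering the panel's sites.
#' @return data.frame with one row per individual x category plus a
#'   `"total"` category row aggregating all sites.
#' @export
individual_load_counts <- function(panel, calls) {
  if (nrow(calls) != ncol(panel$dosage))
    stop("minor-allele calls do not cover the panel's sites")
  D <- .minor_dosage(panel, calls)
  cat <- panel$sites$category
  n <- nrow(D)
  poly_total <- rowSums(D > 0, na.rm = TRUE)
  out <- NULL
  for (cc in c(unique(cat), "total")) {
    cols <- if (cc == "total") seq_len(ncol(D)) else which(cat == cc)
    sub <- D[, cols, drop = FALSE]
    copies <- rowSums(sub, na.rm = TRUE)
    hom <- rowSums(sub == 2, na.rm = TRUE)
    out <- rbind(out, data.frame(
      id = panel$individuals$id,
      population = panel$individuals$population,
      group = panel$individuals$group,
      category = cc, copies = copies, hom_sites = hom,
      n_sites = length(cols), poly_sites = poly_total,
      copies_norm = ifelse(poly_total > 0, copies / poly_total, NA),
      hom_norm = ifelse(poly_total > 0, hom / poly_total, NA)))
  }
  rownames(out) <- NULL
  out
}

# per-site L-term contributions for one category's site columns
.l_terms <- function(panel, calls, rows_x, rows_y, cols,
                     l2_form = c("literal", "dodds")) {
  l2_form <- match.arg(l2_form)
  D <- .minor_dosage(panel, calls)
  dx <- colSums(D[rows_x, cols, drop = FALSE], na.rm = TRUE)
  nx <- 2 * colSums(!is.na(D[rows_x, cols, drop = FALSE]))
  dy <- colSums(D[rows_y, cols, drop = FALSE], na.rm = TRUE)
  ny <- 2 * colSums(!is.na(D[rows_y, cols, drop = FALSE]))
  ok <- nx > 0 & ny > 0
  dx <- dx[ok]; nx <- nx[ok]; dy <- dy[ok]; ny <- ny[ok]
  fx <- dx / nx; fy <- dy / ny
  l1_xy <- fx * (1 - fy)
  l1_yx <- fy * (1 - fx)
  if (l2_form == "literal") {
    # the printed form reduces algebraically to 2d/n (its (n-d) factors
    # cancel; at d = n the reduced value 2 is the continuous limit)
    hx <- 2 * fx; hy <- 2 * fy
  } else {
    hx <- ifelse(nx > 1, dx * (dx - 1) / (nx * (nx - 1)), 0)
    hy <- ifelse(ny > 1, dy * (dy - 1) / (ny * (ny - 1)), 0)
  }
  l2_xy <- hx * (1 - hy)
  l2_yx <- hy * (1 - hx)
  list(l1_xy = l1_xy, l1_yx = l1_yx, l2_xy = l2_xy, l2_yx = l2_yx,
       cols = cols[ok])
}

#' R_XY minor-allele load ratios between two groups
#'
#' For a functional category, `L_XnotY = sum_i (d_X/n_X)(1 - d_Y/n_Y)`
#' over the category's sites (`d` = minor-allele copies, `n` = non-missing
#' allele copies in the group at site `i`); `R_XY = L_XnotY / L_YnotX`.
#' The homozygous analogue `R2_XY` uses the expected-homozygote terms; the
#' normalized `R'` ratios divide by the same ratio computed on intergenic
#' sites, cancelling demography shared across categories. Block-jackknife
#' standard errors are attached via [jackknife_se()].
#'
#' @param panel genotype panel with site categories.
#' @param calls a [call_minor_alleles()] table.
#' @param group_x,group_y disjoint group labels (matched against the
#'   individuals' `group` column, falling back to `population`).
#' @param categories categories to report (default neutral/low/moderate/
#'   high).
#' @param intergenic_category category used for the normalization
#'   (default `"intergenic"`).
#' @param l2_form `"literal"` evaluates the expected-homozygosity term as
#'   printed in the defining equations (which reduces to `2d/n`);
#'   `"dodds"` substitutes the unbiased homozygosity `d(d-1)/(n(n-1))`.
#' @param block_bp jackknife block length in bp (default 5 Mb).
#' @param min_blocks minimum jackknife blocks (default 10).
#' @param jackknife set `FALSE` to skip the jackknife (SEs and
#'   significance flags are then `NA`), e.g. on small worked examples.
#' @return data.frame of class `rxy_result`, one row per category, with
#'   the L terms, `r_xy`, `r2_xy`, normalized `r_prime` and `r2_prime`,
#'   jackknife SEs and significance flags (`TRUE` when the SE interval
#'   around the ratio excludes 1).
#' @export
rxy <- function(panel, calls, group_x, group_y,
                categories = c("neutral", "low", "moderate", "high"),
                intergenic_category = "intergenic",
                l2_form = c("literal", "dodds"),
                block_bp = 5e6, min_blocks = 10, jackknife = TRUE) {
  l2_form <- match.arg(l2_form)
  grp <- panel$individuals$group
  if (!any(grp %in% c(group_x, group_y))) grp <- panel$individuals$population
  rows_x <- which(grp == group_x)
  rows_y <- which(grp == group_y)
  if (!length(rows_x) || !length(rows_y))
    stop("empty group; check group_x/group_y labels")
  if (length(intersect(rows_x, rows_y))) stop("groups must be disjoint")
  cat <- panel$sites$category
  block <- paste(panel$sites$scaffold,
                 floor((panel$sites$pos - 1) / block_bp))
  term_tab <- function(cc) {
    cols <- which(cat == cc)
    if (!length(cols)) stop("no sites in category ", cc)
    lt <- .l_terms(panel, calls, rows_x, rows_y, cols, l2_form)
    data.frame(block = block[lt$cols], l1_xy = lt$l1_xy, l1_yx = lt$l1_yx,
               l2_xy = lt$l2_xy, l2_yx = lt$l2_yx)
  }
  inter <- term_tab(intergenic_category)
  agg <- function(tt) {
    s <- rowsum(tt[, -1], tt$block)
    s[order(rownames(s)), , drop = FALSE]
  }
  inter_b <- agg(inter)
  out <- NULL
  for (cc in categories) {
    tt <- term_tab(cc)
    L1xy <- sum(tt$l1_xy); L1yx <- sum(tt$l1_yx)
    L2xy <- sum(tt$l2_xy); L2yx <- sum(tt$l2_yx)
    if (L1yx == 0 || sum(inter$l1_yx) == 0)
      stop("L_YnotX is zero for category ", cc,
           " (or intergenic); R_XY undefined")
    jk <- if (jackknife)
      jackknife_se(agg(tt), inter_b, min_blocks = min_blocks)
    else c(r = NA_real_, r2 = NA_real_, r_prime = NA_real_,
           r2_prime = NA_real_, n_blocks = NA_real_)
    r1 <- L1xy / L1yx
    r2 <- L2xy / L2yx
    r1p <- r1 / (sum(inter$l1_xy) / sum(inter$l1_yx))
    r2p <- r2 / (sum(inter$l2_xy) / sum(inter$l2_yx))
    out <- rbind(out, data.frame(
      category = cc, l_xnoty = L1xy, l_ynotx = L1yx,
      l2_xnoty = L2xy, l2_ynotx = L2yx,
      r_xy = r1, r2_xy = r2, r_prime = r1p, r2_prime = r2p,
      se_r = jk["r"], se_r2 = jk["r2"],
      se_r_prime = jk["r_prime"], se_r2_prime = jk["r2_prime"],
      sig_r_prime = abs(r1p - 1) > jk["r_prime"],
      sig_r2_prime = abs(r2p - 1) > jk["r2_prime"],
      n_blocks = jk["n_blocks"]))
  }
  rownames(out) <- NULL
  attr(out, "l2_form") <- l2_form
  attr(out, "groups") <- c(X = group_x, Y = group_y)
  class(out) <- c("rxy_result", "data.frame")
  out
}

#' Delete-one block jackknife for the R_XY ratios
#'
#' Given per-block sums of the four L terms for a focal category and for
#' the intergenic reference, recomputes each ratio with one contiguous
#' physical block deleted and returns the jackknife standard errors.
#'
#' @param category_blocks,intergenic_blocks data.frames (blocks x
#'   `l1_xy`, `l1_yx`, `l2_xy`, `l2_yx`) of per-block term sums; row
#'   names identify blocks. The union of both block sets is jackknifed.
#' @param min_blocks fewer blocks than this raises an error suggesting a
#'   smaller block size (default 10).
#' @return Named vector: SEs for `r`, `r2`, `r_prime`, `r2_prime`, plus
#'   `n_blocks`.
#' @export
jackknife_se <- function(category_blocks, intergenic_blocks,
                         min_blocks = 10) {
  blocks <- sort(union(rownames(category_blocks),
                       rownames(intergenic_blocks)))
  g <- length(blocks)
  if (g < min_blocks)
    stop("only ", g, " jackknife blocks; use a smaller block_bp")
  get <- function(tab, col) {
    v <- stats::setNames(rep(0, g), blocks)
    v[rownames(tab)] <- tab[[col]]
    v
  }
  c1xy <- get(category_blocks, "l1_xy"); c1yx <- get(category_blocks, "l1_yx")
  c2xy <- get(category_blocks, "l2_xy"); c2yx <- get(category_blocks, "l2_yx")
  i1xy <- get(intergenic_blocks, "l1_xy"); i1yx <- get(intergenic_blocks, "l1_yx")
  i2xy <- get(intergenic_blocks, "l2_xy"); i2yx <- get(intergenic_blocks, "l2_yx")
  loo <- function(v) sum(v) - v     # leave-one-out totals
  r_j <- loo(c1xy) / loo(c1yx)
  r2_j <- loo(c2xy) / loo(c2yx)
  rp_j <- r_j / (loo(i1xy) / loo(i1yx))
  r2p_j <- r2_j / (loo(i2xy) / loo(i2yx))
  jse <- function(th) {
    th <- th[is.finite(th)]
    k <- length(th)
    if (k < 2) return(NA_real_)
    sqrt((k - 1) / k * sum((th - mean(th))^2))
  }
  c(r = jse(r_j), r2 = jse(r2_j), r_prime = jse(rp_j),
    r2_prime = jse(r2p_j), n_blocks = g)
}

#' Two-group Wilcoxon comparison with effect size
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction, no continuity correction) plus the effect size
#' `r = |Z| / sqrt(n_A + n_B)`, labelled negligible/small/moderate/large
#' at the conventional 0.1/0.3/0.5 cut-offs.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @return list with `W`, `p_value`, `effect_size`, `label`, `n_a`, `n_b`.
#' @export
group_compare <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b))
    stop("both groups must be non-empty")
  wt <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                           correct = FALSE)
  na <- length(values_a); nb <- length(values_b); N <- na + nb
  r_all <- rank(c(values_a, values_b))
  W <- sum(r_all[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  ties <- table(r_all)
  sig2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  r <- abs(z) / sqrt(N)
  label <- if (r < 0.1) "negligible" else if (r < 0.3) "small"
           else if (r < 0.5) "moderate" else "large"
  list(W = unname(wt$statistic), p_value = wt$p.value,
       effect_size = r, label = label, n_a = na, n_b = nb)
}
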