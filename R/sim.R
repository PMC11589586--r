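# Synthetic genotype panels with planted homozygosity-by-descent tracts.
#
# The generator emulates the statistical structure a model-based HBD caller
# sees in a resequencing panel: per-individual autozygous tracts with
# class-specific exponential lengths, Hardy-Weinberg emission outside tracts,
# population divergence via the Balding-Nichols construction, full-sib pairs,
# and group-asymmetric minor-allele burdens per functional category. It does
# not simulate haplotypes, linkage disequilibrium or selection dynamics.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.DEFAULT_RATES <- 2^(1:13)

#' Simulation configuration
#'
#' Assembles and validates the knobs of the synthetic-panel generator.
#' Defaults describe a scaled-down two-population survey: a large, weakly
#' drifted continental population and a small, strongly drifted island
#' population, with autozygosity concentrated in intermediate-age HBD
#' classes on the island.
#'
#' @param n_populations number of populations.
#' @param population_labels population names.
#' @param group_labels group label per population (e.g. continent/island or
#'   refugium/recolonized).
#' @param n_individuals unrelated individuals per population.
#' @param n_scaffolds,scaffold_length genome layout (bp per scaffold).
#' @param n_sites segregating sites per scaffold.
#' @param recomb_rate Morgans per bp (constant within the simulation;
#'   default 2e-8, a typical avian-scale average).
#' @param ancestral_freq_shape shape of the symmetric Beta distribution the
#'   ancestral alternate-allele frequencies are drawn from. The default 1
#'   (uniform) mimics a quality-filtered panel in which rare variants have
#'   been removed by a minor-allele-count filter.
#' @param divergence per-population Balding-Nichols drift parameter
#'   (F_ST-like) in `[0, 1)`.
#' @param hbd_class_rates per-generation HBD class rates (expected segment
#'   length is `1/rate` Morgans); default `2, 4, ..., 8192`.
#' @param hbd_class_weights list (one numeric vector per population) of
#'   expected genome fractions per HBD class; the non-HBD fraction is the
#'   complement. Each vector must have `length(hbd_class_rates)` entries,
#'   be non-negative and sum to at most 1.
#' @param genotype_error probability that a genotype inside a planted tract
#'   is emitted heterozygous.
#' @param category_fractions site proportions over intergenic, neutral,
#'   low, moderate, high (in that order), summing to 1.
#' @param load_shift named list `group -> c(category = factor)` of
#'   multiplicative shifts applied to minor-allele frequencies of that
#'   category in that group; intergenic sites are never shifted.
#' @param sib_pair_count full-sib pairs appended per population.
#' @param mean_depth mean simulated per-genotype sequencing depth.
#' @param seed integer; fully determines the generated panel.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2,
                       population_labels = c("MAINLAND", "ISLE"),
                       group_labels = c("continent", "island"),
                       n_individuals = c(20, 20),
                       n_scaffolds = 10,
                       scaffold_length = 5e7,
                       n_sites = 2000,
                       recomb_rate = 2e-8,
                       ancestral_freq_shape = 1,
                       divergence = c(0.02, 0.10),
                       hbd_class_rates = .DEFAULT_RATES,
                       hbd_class_weights = NULL,
                       genotype_error = 0.001,
                       category_fractions = c(intergenic = 0.50,
                                              neutral = 0.30, low = 0.10,
                                              moderate = 0.07, high = 0.03),
                       load_shift = list(),
                       sib_pair_count = rep(0L, n_populations),
                       mean_depth = 16,
                       seed = 1L) {
  K <- length(hbd_class_rates)
  if (is.null(hbd_class_weights)) {
    w_cont <- numeric(K); w_isl <- numeric(K)
    w_cont[hbd_class_rates %in% c(64, 128)] <- 0.02
    w_isl[hbd_class_rates %in% c(16, 32, 64, 128, 256)] <- 0.02
    hbd_class_weights <- list(w_cont, w_isl)[seq_len(n_populations)]
    if (n_populations > 2)
      hbd_class_weights <- c(hbd_class_weights,
                             replicate(n_populations - 2, w_cont,
                                       simplify = FALSE))
  }
  cfg <- list(n_populations = n_populations,
              population_labels = as.character(population_labels),
              group_labels = as.character(group_labels),
              n_individuals = as.integer(n_individuals),
              n_scaffolds = as.integer(n_scaffolds),
              scaffold_length = scaffold_length,
              n_sites = as.integer(n_sites),
              recomb_rate = recomb_rate,
              ancestral_freq_shape = ancestral_freq_shape,
              divergence = divergence,
              hbd_class_rates = hbd_class_rates,
              hbd_class_weights = hbd_class_weights,
              genotype_error = genotype_error,
              category_fractions = category_fractions,
              load_shift = load_shift,
              sib_pair_count = as.integer(sib_pair_count),
              mean_depth = mean_depth,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_populations >= 1,
            length(cfg$population_labels) == cfg$n_populations,
            length(cfg$group_labels) == cfg$n_populations,
            length(cfg$n_individuals) == cfg$n_populations,
            length(cfg$divergence) == cfg$n_populations,
            length(cfg$sib_pair_count) == cfg$n_populations,
            length(cfg$hbd_class_weights) == cfg$n_populations)
  if (any(cfg$divergence < 0 | cfg$divergence >= 1))
    stop("divergence must lie in [0, 1)")
  r <- cfg$hbd_class_rates
  if (any(r <= 0) || any(diff(r) <= 0))
    stop("hbd_class_rates must be positive and strictly increasing")
  for (w in cfg$hbd_class_weights) {
    if (length(w) != length(r) || any(w < 0) || sum(w) > 1 + 1e-12)
      stop("each hbd_class_weights vector needs one non-negative entry per class, summing to <= 1")
  }
  cf <- cfg$category_fractions
  if (length(cf) != 5 ||
      !identical(names(cf), c("intergenic", "neutral", "low", "moderate", "high")))
    stop("category_fractions must be named intergenic, neutral, low, moderate, high")
  if (any(cf < 0) || abs(sum(cf) - 1) > 1e-12)
    stop("category_fractions must be non-negative and sum to 1 (within 1e-12)")
  if (cfg$genotype_error < 0 || cfg$genotype_error >= 1)
    stop("genotype_error must lie in [0, 1)")
  for (g in names(cfg$load_shift)) {
    s <- cfg$load_shift[[g]]
    if (any(s <= 0)) stop("load_shift factors must be positive")
    if (!all(names(s) %in% c("neutral", "low", "moderate", "high")))
      stop("load_shift applies to neutral/low/moderate/high only, never intergenic")
  }
  invisible(cfg)
}

#' Plant HBD tracts along one scaffold
#'
#' Draws the autozygous mosaic of a single individual as an alternating
#' renewal process: non-HBD gaps are exponential with mean
#' `w0 / sum(w_k * R_k)` Morgans, each tract picks class `k` with
#' probability proportional to `w_k * R_k` and has exponential length with
#' mean `1/R_k` Morgans. The expected genome fraction in class `k` is then
#' exactly `w_k`, and the expected total HBD fraction is `sum(w_k)`.
#'
#' @param genetic_length scaffold length in Morgans (> 0).
#' @param class_weights expected genome fraction per HBD class (the non-HBD
#'   weight is the complement `1 - sum(class_weights)`).
#' @param class_rates per-generation class rates, one per weight.
#' @return data.frame with columns `start`, `end` (Morgans, half-open) and
#'   `class` (index into `class_rates`); zero rows when all weights are 0.
#' @export
plant_hbd_tracts <- function(genetic_length, class_weights,
                             class_rates = .DEFAULT_RATES) {
  if (!is.finite(genetic_length) || genetic_length <= 0)
    stop("genetic_length must be positive")
  if (length(class_weights) != length(class_rates))
    stop("one weight per class rate required")
  if (any(class_weights < 0) || sum(class_weights) > 1 + 1e-12)
    stop("class weights must be non-negative and sum to <= 1")
  w <- class_weights
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      class = integer(0))
  if (sum(w) < .Machine$double.eps) return(empty)
  wbar <- sum(w * class_rates)
  gap_mean <- (1 - sum(w)) / wbar
  pick <- w * class_rates / wbar
  pos <- 0; starts <- numeric(0); ends <- numeric(0); cls <- integer(0)
  repeat {
    pos <- pos + stats::rexp(1, rate = 1 / max(gap_mean, .Machine$double.xmin))
    if (pos >= genetic_length) break
    k <- sample.int(length(w), 1, prob = pick)
    len <- stats::rexp(1, rate = class_rates[k])
    starts <- c(starts, pos)
    ends <- c(ends, min(pos + len, genetic_length))
    cls <- c(cls, k)
    pos <- pos + len
    if (pos >= genetic_length) break
  }
  data.frame(start = starts, end = ends, class = cls)
}

#' Shift minor-allele frequencies of selected categories
#'
#' Multiplies the minor-allele frequency by a category-specific factor,
#' clamping into `[0, 1]`; intergenic sites are never shifted. Which allele
#' is "minor" is decided from the supplied frequencies (the allele with
#' frequency below 0.5; ties treat the alternate allele as minor).
#'
#' @param freqs alternate-allele frequencies in `[0, 1]`.
#' @param categories per-site functional category.
#' @param shifts named numeric vector `c(category = factor)`, factors > 0.
#' @return Shifted alternate-allele frequency vector.
#' @export
apply_load_asymmetry <- function(freqs, categories, shifts) {
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  if (length(shifts) && any(shifts <= 0))
    stop("load shifts must be positive")
  if ("intergenic" %in% names(shifts))
    stop("intergenic sites are never shifted")
  out <- freqs
  for (cat in names(shifts)) {
    idx <- which(categories == cat)
    if (!length(idx)) next
    f <- out[idx]
    alt_minor <- f <= 0.5
    f[alt_minor] <- pmin(1, f[alt_minor] * shifts[[cat]])
    f[!alt_minor] <- 1 - pmin(1, (1 - f[!alt_minor]) * shifts[[cat]])
    out[idx] <- f
  }
  out
}

.offspring_dosage <- function(mom, dad) {
  transmit <- function(g) ifelse(g == 0, 0L,
                          ifelse(g == 2, 1L,
                                 as.integer(stats::runif(length(g)) < 0.5)))
  transmit(mom) + transmit(dad)
}

#' Generate a genotype panel with known truth
#'
#' Draws ancestral allele frequencies, per-population frequencies via the
#' Balding-Nichols construction, per-individual HBD tract mosaics, and
#' genotypes: Hardy-Weinberg outside tracts; inside a tract the individual
#' is homozygous for a single founder allele sampled with probability equal
#' to its population frequency, heterozygous only with probability
#' `genotype_error`. Full-sib pairs (two offspring of the same simulated
#' parents, no planted tracts) are appended after the unrelated
#' individuals and flagged in the `family` metadata column.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a [genotype_panel()]) and `truth`
#'   (tracts in bp, per-individual autozygous fractions, pedigree links).
#' @export
generate_panel <- function(config) {
  validate_sim_config(unclass(config))
  cfg <- config
  .with_seed(cfg$seed, {
    n_scaf <- cfg$n_scaffolds
    scaf_names <- sprintf("scaffold_%02d", seq_len(n_scaf))
    genome_bp <- n_scaf * cfg$scaffold_length
    # --- sites ---------------------------------------------------------
    site_list <- lapply(seq_len(n_scaf), function(s) {
      pos <- sort(sample.int(cfg$scaffold_length, cfg$n_sites))
      data.frame(scaffold = scaf_names[s], pos = pos)
    })
    sites <- do.call(rbind, site_list)
    m <- nrow(sites)
    sites$ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
    sites$alt <- vapply(sites$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    sites$gpos <- sites$pos * cfg$recomb_rate
    sites$category <- sample(names(cfg$category_fractions), m, replace = TRUE,
                             prob = cfg$category_fractions)
    p_anc <- stats::rbeta(m, cfg$ancestral_freq_shape, cfg$ancestral_freq_shape)
    # --- per-population frequencies ------------------------------------
    pop_freq <- vector("list", cfg$n_populations)
    for (p in seq_len(cfg$n_populations)) {
      Fst <- cfg$divergence[p]
      f <- if (Fst > 0) {
        a <- p_anc * (1 - Fst) / Fst
        b <- (1 - p_anc) * (1 - Fst) / Fst
        stats::rbeta(m, pmax(a, 1e-8), pmax(b, 1e-8))
      } else p_anc
      grp <- cfg$group_labels[p]
      if (!is.null(cfg$load_shift[[grp]]))
        f <- apply_load_asymmetry(f, sites$category, cfg$load_shift[[grp]])
      pop_freq[[p]] <- f
    }
    # --- individuals ----------------------------------------------------
    glen <- cfg$scaffold_length * cfg$recomb_rate
    dosage <- NULL; ind <- NULL; tracts <- NULL
    draw_unrelated <- function(f, weights, id) {
      g <- integer(m); tr <- NULL
      for (s in seq_len(n_scaf)) {
        idx <- which(sites$scaffold == scaf_names[s])
        tt <- plant_hbd_tracts(glen, weights, cfg$hbd_class_rates)
        gp <- sites$gpos[idx]
        in_tract <- rep(FALSE, length(idx))
        if (nrow(tt)) {
          for (j in seq_len(nrow(tt)))
            in_tract <- in_tract | (gp >= tt$start[j] & gp < tt$end[j])
          tr <- rbind(tr, data.frame(
            id = id, scaffold = scaf_names[s],
            start_bp = floor(tt$start / cfg$recomb_rate),
            end_bp = pmin(ceiling(tt$end / cfg$recomb_rate),
                          cfg$scaffold_length),
            class_rate = cfg$hbd_class_rates[tt$class]))
        }
        fi <- f[idx]
        gs <- stats::rbinom(length(idx), 2, fi)
        if (any(in_tract)) {
          nh <- sum(in_tract)
          hom <- ifelse(stats::runif(nh) < fi[in_tract], 2L, 0L)
          err <- stats::runif(nh) < cfg$genotype_error
          hom[err] <- 1L
          gs[in_tract] <- hom
        }
        g[idx] <- gs
      }
      list(g = g, tr = tr)
    }
    rows <- list(); fam <- character(0)
    for (p in seq_len(cfg$n_populations)) {
      for (i in seq_len(cfg$n_individuals[p])) {
        id <- sprintf("%s_%03d", cfg$population_labels[p], i)
        d <- draw_unrelated(pop_freq[[p]], cfg$hbd_class_weights[[p]], id)
        rows[[id]] <- d$g; tracts <- rbind(tracts, d$tr)
        ind <- rbind(ind, data.frame(id = id,
                                     population = cfg$population_labels[p],
                                     group = cfg$group_labels[p],
                                     family = NA_character_))
      }
    }
    for (p in seq_len(cfg$n_populations)) {
      for (sp in seq_len(cfg$sib_pair_count[p])) {
        mom <- stats::rbinom(m, 2, pop_freq[[p]])
        dad <- stats::rbinom(m, 2, pop_freq[[p]])
        famid <- sprintf("%s_fam%02d", cfg$population_labels[p], sp)
        for (child in 1:2) {
          id <- sprintf("%s_sib%02d_%d", cfg$population_labels[p], sp, child)
          rows[[id]] <- .offspring_dosage(mom, dad)
          ind <- rbind(ind, data.frame(id = id,
                                       population = cfg$population_labels[p],
                                       group = cfg$group_labels[p],
                                       family = famid))
        }
      }
    }
    dosage <- do.call(rbind, rows)
    depth <- matrix(stats::rpois(length(dosage), cfg$mean_depth),
                    nrow = nrow(dosage))
    panel <- genotype_panel(dosage, sites, ind, depth = depth,
                            scaffold_lengths = stats::setNames(
                              rep(cfg$scaffold_length, n_scaf), scaf_names))
    if (is.null(tracts))
      tracts <- data.frame(id = character(0), scaffold = character(0),
                           start_bp = numeric(0), end_bp = numeric(0),
                           class_rate = numeric(0))
    frac <- vapply(ind$id, function(i) {
      tt <- tracts[tracts$id == i, , drop = FALSE]
      sum(tt$end_bp - tt$start_bp) / genome_bp
    }, 0.0)
    truth <- list(tracts = tracts,
                  autozygous_fraction = data.frame(id = ind$id,
                                                   fraction = unname(frac)),
                  pedigree = ind[!is.na(ind$family),
                                 c("id", "family", "population")],
                  genome_bp = genome_bp)
    list(panel = panel, truth = truth)
  })
}
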