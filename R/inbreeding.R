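# Allele-sharing matrix, F_AS, relatedness filtering and the
# F_HBD-vs-F_AS contrast diagnosing the temporal origin of inbreeding.

#' Allele-sharing matrix
#'
#' Mean per-locus allele matching between every pair of individuals:
#' at one locus with dosages `x_i`, `x_j` the matching is
#' `(x_i * x_j + (2 - x_i) * (2 - x_j)) / 4`, i.e. the probability that a
#' random allele from `i` matches a random allele from `j`. The diagonal is
#' within-individual matching: 1 at homozygous loci, 0.5 at heterozygous
#' loci. Averages run over loci non-missing in both individuals. The
#' statistic is invariant to which allele is labelled reference.
#'
#' @param panel genotype panel (a single individual yields the 1x1 matrix
#'   of within-individual matching; pairwise use needs two or more).
#' @return list of class `allele_sharing`: `matching` (symmetric matrix)
#'   and `n_loci` (per-pair locus counts). Pairs sharing no loci get `NA`.
#' @export
allele_sharing_matrix <- function(panel) {
  X <- panel$dosage
  if (nrow(X) < 1) stop("allele sharing needs at least one individual")
  ok <- !is.na(X)
  A <- X; A[!ok] <- 0
  B <- 2 - X; B[!ok] <- 0
  num <- (A %*% t(A) + B %*% t(B)) / 4
  cnt <- ok %*% t(ok)
  M <- num / cnt
  M[cnt == 0] <- NA
  dimnames(M) <- list(panel$individuals$id, panel$individuals$id)
  structure(list(matching = M, n_loci = cnt), class = "allele_sharing")
}

# pairwise relatedness standardized by the population's mean between-
# individual matching: beta_ij = (M_ij - Mbar_B) / (1 - Mbar_B)
.beta_matrix <- function(M) {
  off <- M[upper.tri(M)]
  if (anyNA(off)) stop("pairs with no shared loci; cannot standardize")
  mb <- mean(off)
  if (mb >= 1) stop("mean between-individual sharing is 1 (monomorphic panel); relatedness undefined")
  (M - mb) / (1 - mb)
}

#' Select an unrelated individual set
#'
#' Standardizes pairwise matching into relatedness
#' `beta_ij = (M_ij - Mbar_B) / (1 - Mbar_B)` (with `Mbar_B` the mean
#' off-diagonal matching over the population) and greedily removes, until
#' no pair exceeds the threshold, the individual involved in the most
#' violating pairs (ties broken by removing the lexicographically lowest
#' id).
#'
#' @param sharing an [allele_sharing_matrix()] (or its `matching` matrix)
#'   restricted to one population.
#' @param threshold relatedness cut-off (default 0.05, strict `<` keeps).
#' @return Character vector of retained individual ids.
#' @export
unrelated_set <- function(sharing, threshold = 0.05) {
  M <- if (inherits(sharing, "allele_sharing")) sharing$matching else sharing
  if (is.null(dim(M)) || nrow(M) == 0) stop("empty population")
  if (nrow(M) == 1) return(rownames(M))
  beta <- .beta_matrix(M)
  keep <- rownames(M)
  repeat {
    b <- beta[keep, keep, drop = FALSE]
    diag(b) <- -Inf
    viol <- b >= threshold
    nv <- rowSums(viol)
    if (all(nv == 0)) break
    worst <- which(nv == max(nv))
    drop_id <- sort(names(worst))[1]
    keep <- setdiff(keep, drop_id)
    if (length(keep) <= 1) break
  }
  keep
}

#' Allele-sharing inbreeding coefficient F_AS
#'
#' The within-individual matching scaled by the population's mean
#' between-individual matching. The self-kinship
#' `beta_ii = (M_ii - Mbar_B) / (1 - Mbar_B)` (with `Mbar_B` the mean
#' between-individual matching over pairs of a reference set, typically an
#' unrelated subset of the individual's population) estimates
#' `(1 + F_i) / 2`, so the reported coefficient is
#' `F_AS,i = 2 beta_ii - 1`: zero under random mating, 1 for a fully
#' homozygous genome, negative when the individual matches alleles less
#' than random pairs of its population do.
#'
#' @param panel genotype panel.
#' @param population population whose individuals are scored; default all
#'   populations, each scored against its own reference.
#' @param reference_sets optional named list `population -> ids` used for
#'   the between-individual average (e.g. from [unrelated_set()]); default
#'   all members of the population.
#' @return data.frame with columns `id`, `population`, `f_as`.
#' @export
f_as <- function(panel, population = NULL, reference_sets = NULL) {
  pops <- if (is.null(population)) unique(panel$individuals$population)
          else population
  out <- NULL
  for (p in pops) {
    rows <- which(panel$individuals$population == p)
    if (length(rows) < 2) stop("population ", p, " has fewer than 2 individuals")
    sub <- panel[rows, ]
    M <- allele_sharing_matrix(sub)$matching
    ref <- if (!is.null(reference_sets) && !is.null(reference_sets[[p]]))
      reference_sets[[p]] else rownames(M)
    if (length(ref) < 2) stop("reference set for ", p, " needs >= 2 members")
    if (!all(ref %in% rownames(M))) stop("reference ids outside population ", p)
    Mr <- M[ref, ref, drop = FALSE]
    mb <- mean(Mr[upper.tri(Mr)])
    if (mb >= 1)
      stop("mean between-individual sharing is 1 in ", p,
           " (monomorphic panel); F_AS undefined")
    fi <- 2 * (diag(M) - mb) / (1 - mb) - 1
    out <- rbind(out, data.frame(id = rownames(M), population = p,
                                 f_as = unname(fi)))
  }
  rownames(out) <- NULL
  out
}

#' Contrast F_HBD against F_AS to label inbreeding origin
#'
#' Individuals with `F_HBD` clearly above `F_AS` owe their inbreeding to
#' ancient coalescence events (small historical effective size); the
#' reverse pattern indicates population structure or recent consanguinity
#' inflating allele sharing; values on the identity line are labelled
#' `"on-line"`.
#'
#' @param records data.frame with columns `f_hbd` and `f_as` (e.g. the
#'   merge of [hbd_fit()] records and [f_as()]).
#' @param delta half-width of the on-line band (default 0.01); a reporting
#'   convenience, the raw coefficients remain the quantitative output.
#' @return `records` with an added `origin` column in
#'   `{"ancient", "recent/structured", "on-line"}`.
#' @export
inbreeding_contrast <- function(records, delta = 0.01) {
  stopifnot(all(c("f_hbd", "f_as") %in% names(records)))
  d <- records$f_hbd - records$f_as
  records$origin <- ifelse(d > delta, "ancient",
                    ifelse(-d > delta, "recent/structured", "on-line"))
  records
}

#' Per-individual inbreeding table
#'
#' Convenience join of the HBD fit records with `F_AS`, with origin labels.
#'
#' @param fit an [hbd_fit()].
#' @param panel the panel the fit came from.
#' @param relatedness_threshold pairwise relatedness above which
#'   individuals are excluded from each population's F_AS reference set.
#' @param delta passed to [inbreeding_contrast()].
#' @return data.frame with id, population, group, F_HBD, F_AS, N_HBD,
#'   S_HBD and origin label.
#' @export
inbreeding_records <- function(fit, panel, relatedness_threshold = 0.05,
                               delta = 0.01) {
  refs <- list()
  for (p in unique(panel$individuals$population)) {
    sub <- panel[panel$individuals$population == p, ]
    if (nrow(sub$dosage) < 2) next
    refs[[p]] <- unrelated_set(allele_sharing_matrix(sub),
                               threshold = relatedness_threshold)
  }
  fa <- f_as(panel, reference_sets = refs)
  rec <- merge(fit$records, fa[, c("id", "f_as")], by = "id", sort = FALSE)
  rec <- inbreeding_contrast(rec, delta = delta)
  rec[match(fit$records$id, rec$id), ]
}
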