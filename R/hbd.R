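# Multi-class homozygosity-by-descent HMM.
#
# The chain runs over ordered markers with genetic distances in Morgans.
# Each HBD class k has a per-Morgan exit rate R_k; R_k equals twice the
# expected number of generations since the coalescence event that created
# the segment, so class-k tracts have mean length 1/R_k Morgans. One
# non-HBD state (same rate as the oldest class by default) completes the
# model; mixing coefficients M give the probability of entering each state
# when a segment ends, and also serve as the initial distribution.

#' HBD model specification
#'
#' @param rates HBD class rates; default the 13-class ladder
#'   `2, 4, ..., 8192`.
#' @param nonhbd_rate exit rate of the non-HBD state (default the largest
#'   class rate).
#' @param mixing mixing coefficients over the `length(rates) + 1` states
#'   (HBD classes first, non-HBD last), summing to 1; default uniform.
#' @param error genotyping-error rate `e` in `[0, 1)`: inside an HBD state
#'   a genotype is emitted from the Hardy-Weinberg law with probability `e`
#'   instead of the homozygous-founder law.
#' @return Object of class `hbd_model_spec`.
#' @export
hbd_model_spec <- function(rates = .DEFAULT_RATES,
                           nonhbd_rate = max(rates),
                           mixing = NULL, error = 0.001) {
  if (any(rates <= 0) || any(diff(rates) <= 0))
    stop("class rates must be positive and strictly increasing")
  if (nonhbd_rate <= 0) stop("non-HBD rate must be positive")
  S <- length(rates) + 1L
  if (is.null(mixing)) mixing <- rep(1 / S, S)
  if (length(mixing) != S || any(mixing < 0) ||
      abs(sum(mixing) - 1) > 1e-12)
    stop("mixing must have one non-negative entry per state (incl. non-HBD) summing to 1")
  if (error < 0 || error >= 1) stop("error rate must lie in [0, 1)")
  structure(list(rates = rates, nonhbd_rate = nonhbd_rate,
                 mixing = mixing, error = error,
                 state_rates = c(rates, nonhbd_rate), n_states = S),
            class = "hbd_model_spec")
}

#' @export
print.hbd_model_spec <- function(x, ...) {
  cat("HBD model:", length(x$rates), "HBD classes + 1 non-HBD state\n")
  cat("Rates:", paste(x$rates, collapse = ", "),
      "| non-HBD:", x$nonhbd_rate, "\n")
  cat("Error rate:", x$error, "\n")
  cat("Mixing:", paste(signif(x$mixing, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Expected coalescence age of an HBD class
#'
#' A class of rate `R` collects segments whose coalescence event lies about
#' `R/2` generations back.
#'
#' @param rate class rate(s).
#' @return Generations since coalescence.
#' @export
rate_to_generations <- function(rate) rate / 2

#' Autozygosity horizon implied by a rate threshold
#'
#' Classes with rate at most `T` count as autozygous; the horizon is the
#' coalescence age of the oldest included class.
#'
#' @param model an [hbd_model_spec()].
#' @param T rate threshold (default 1024).
#' @param strict if `TRUE`, use `rate < T` instead of the default
#'   `rate <= T`.
#' @return Horizon in generations.
#' @export
autozygosity_horizon <- function(model = hbd_model_spec(), T = 1024,
                                 strict = FALSE) {
  inc <- if (strict) model$rates < T else model$rates <= T
  if (!any(inc)) return(0)
  rate_to_generations(max(model$rates[inc]))
}

# Emission likelihood matrix (markers x states). Genotypes are alt-allele
# dosages (0/1/2, NA = missing, likelihood 1 in every state); freqs are
# alt-allele frequencies in (0,1).
.hbd_emissions <- function(genotypes, freqs, model) {
  if (length(genotypes) == 0) stop("zero-length observation sequence")
  if (length(freqs) != length(genotypes))
    stop("one allele frequency per genotype required")
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  T_ <- length(genotypes); S <- model$n_states; e <- model$error
  f <- freqs
  hwe <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  hbd <- cbind(1 - f, 0, f)
  g1 <- genotypes + 1L
  idx <- cbind(seq_len(T_), g1)
  hwe_g <- rep(1, T_); hbd_g <- rep(1, T_)
  ok <- !is.na(genotypes)
  hwe_g[ok] <- hwe[idx[ok, , drop = FALSE]]
  hbd_g[ok] <- (1 - e) * hbd[idx[ok, , drop = FALSE]] + e * hwe[idx[ok, , drop = FALSE]]
  emis <- matrix(hbd_g, nrow = T_, ncol = S)
  emis[, S] <- hwe_g
  emis
}

# stay probabilities exp(-R_s * d_t), shared across EM iterations
.stay_probs <- function(model, distances) {
  if (any(distances < 0)) stop("genetic distances must be non-negative")
  exp(-outer(as.numeric(distances), model$state_rates))
}

# EM on precomputed emissions/stay-probabilities; returns model + trace
.em_mixing <- function(emis, P, model, tol, max_iter) {
  ll <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    res <- hmm_forward_backward(emis, P, model$mixing)
    ll <- c(ll, res$loglik)
    if (it > 1 && abs(ll[it] - ll[it - 1]) < tol) { converged <- TRUE; break }
    m_new <- pmax(res$entries / sum(res$entries), 0)
    model$mixing <- m_new / sum(m_new)
  }
  attr(model, "loglik") <- ll
  attr(model, "converged") <- converged
  attr(model, "iterations") <- length(ll)
  model
}

#' Forward-backward decoding under the HBD model
#'
#' Exact scaled forward-backward pass; numerically stable for panels of
#' millions of markers.
#'
#' @param genotypes alt-allele dosages (0/1/2, `NA` missing) in marker
#'   order.
#' @param freqs alt-allele frequencies in `(0, 1)`, one per marker.
#' @param model an [hbd_model_spec()].
#' @param distances genetic distances between adjacent markers (Morgans,
#'   `length(genotypes) - 1`, all `>= 0`).
#' @return Object of class `hbd_decoding`: per-marker posterior matrix
#'   `gamma` (rows sum to 1), total `loglik`, expected state-entry counts
#'   `entries`, and the model used.
#' @export
forward_backward <- function(genotypes, freqs, model, distances) {
  emis <- .hbd_emissions(genotypes, freqs, model)
  if (length(distances) != length(genotypes) - 1)
    stop("need one genetic distance per adjacent marker pair")
  res <- hmm_forward_backward(emis, .stay_probs(model, distances),
                              model$mixing)
  structure(list(gamma = res$gamma, loglik = res$loglik,
                 entries = res$entries, model = model),
            class = "hbd_decoding")
}

#' Fit mixing coefficients by EM
#'
#' Class rates stay fixed (a fixed-rate multi-class model); only the mixing
#' coefficients are estimated. Each EM iteration re-estimates M from the
#' expected state-entry counts of the forward-backward pass, so the
#' log-likelihood is non-decreasing.
#'
#' @inheritParams forward_backward
#' @param tol stop when the log-likelihood improves by less than `tol`.
#' @param max_iter iteration cap; hitting it flags (not raises)
#'   non-convergence.
#' @return The input model with fitted `mixing`, plus attributes
#'   `loglik` (trace), `converged` and `iterations`.
#' @export
fit_mixing_coefficients <- function(genotypes, freqs, model, distances,
                                    tol = 1e-4, max_iter = 100) {
  if (model$n_states == 1) {
    model$mixing <- 1
    attr(model, "loglik") <- numeric(0)
    attr(model, "converged") <- TRUE
    attr(model, "iterations") <- 0L
    return(model)
  }
  emis <- .hbd_emissions(genotypes, freqs, model)
  .em_mixing(emis, .stay_probs(model, distances), model, tol, max_iter)
}

#' Viterbi HBD segments
#'
#' Decodes the single most probable state path and merges consecutive
#' markers assigned to the same HBD class into segments; the non-HBD state
#' yields no segments. Segment bounds are the physical positions of the
#' first and last marker of the run.
#'
#' @inheritParams forward_backward
#' @param sites data.frame with `scaffold` and `pos` columns, one row per
#'   marker.
#' @return data.frame with columns `scaffold`, `start`, `end` (bp,
#'   inclusive), `rate` (class rate), `length` (bp) and `n_markers`.
#' @export
viterbi_segments <- function(genotypes, freqs, model, distances, sites) {
  emis <- .hbd_emissions(genotypes, freqs, model)
  path <- hmm_viterbi(emis, .stay_probs(model, distances), model$mixing)
  .segments_from_path(path, model, sites)
}

.segments_from_path <- function(path, model, sites) {
  K <- model$n_states - 1L
  runs <- rle(paste(sites$scaffold, path))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  state <- path[starts]
  keep <- state <= K
  if (!any(keep))
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), rate = numeric(0),
                      length = numeric(0), n_markers = integer(0)))
  starts <- starts[keep]; ends <- ends[keep]; state <- state[keep]
  out <- data.frame(scaffold = sites$scaffold[starts],
                    start = sites$pos[starts], end = sites$pos[ends],
                    rate = model$rates[state],
                    length = sites$pos[ends] - sites$pos[starts] + 1,
                    n_markers = ends - starts + 1L)
  rownames(out) <- NULL
  out
}

#' Inbreeding coefficient from a decoding
#'
#' `F_HBD` is the mean, over markers, of the summed posterior probability
#' of the HBD classes whose rate is at most `T`. With `T = 1024` and the
#' default rate ladder, segments coalescing up to 512 generations back
#' count as autozygous.
#'
#' @param decoding an `hbd_decoding` from [forward_backward()].
#' @param T rate threshold (default 1024).
#' @param strict use `rate < T` instead of `rate <= T`.
#' @return `F_HBD` in `[0, 1]`.
#' @export
f_hbd <- function(decoding, T = 1024, strict = FALSE) {
  rates <- decoding$model$rates
  inc <- if (strict) rates < T else rates <= T
  if (!any(inc)) {
    warning("threshold T below the smallest class rate; F_HBD is 0")
    return(0)
  }
  mean(rowSums(decoding$gamma[, which(inc), drop = FALSE]))
}

#' Per-individual HBD segment summaries
#'
#' @param segments segment table from [viterbi_segments()] for one
#'   individual.
#' @param T rate threshold: only classes with rate `<= T` (the autozygous
#'   classes) are counted.
#' @return list with `n_hbd` (segment count), `s_hbd` (mean segment length
#'   in bp, 0 when there are no segments) and `class_sums` (summed length
#'   per class rate).
#' @export
segment_summaries <- function(segments, T = 1024) {
  seg <- segments[segments$rate <= T, , drop = FALSE]
  if (nrow(seg) == 0)
    return(list(n_hbd = 0L, s_hbd = 0, class_sums = numeric(0)))
  sums <- tapply(seg$length, seg$rate, sum)
  list(n_hbd = nrow(seg), s_hbd = mean(seg$length),
       class_sums = stats::setNames(as.numeric(sums), names(sums)))
}

#' Fit the HBD model to every individual of a panel
#'
#' The central model fit: for each individual, mixing coefficients are
#' estimated by EM (rates fixed), the genome is decoded, Viterbi segments
#' are extracted and `F_HBD` is computed.
#'
#' @param panel a [genotype_panel()] with genetic positions (`gpos`).
#' @param rates HBD class rates.
#' @param error genotyping-error rate of the emission model.
#' @param T autozygosity rate threshold for `F_HBD` and segment summaries.
#' @param freq_scope `"population"` (emission allele frequencies computed
#'   within each individual's population) or `"global"` (panel-wide).
#' @param fit if `FALSE`, skip EM and decode under uniform mixing.
#' @param tol,max_iter EM controls.
#' @param keep_posteriors retain the full per-marker posterior matrices
#'   (memory-heavy; the per-marker HBD probabilities needed downstream are
#'   always retained).
#' @param individuals optional id subset to fit; emission allele
#'   frequencies are still computed from the whole panel.
#' @return Object of class `hbd_fit` with components `records`
#'   (per-individual F_HBD, N_HBD, S_HBD, log-likelihood, convergence),
#'   `mixing` (individuals x states), `segments`, `hbd_prob` and
#'   `hbd_prob_T` (individuals x markers posterior HBD probabilities, all
#'   classes and rate-limited), `panel` metadata and the model template.
#' @export
hbd_fit <- function(panel, rates = .DEFAULT_RATES, error = 0.001,
                    T = 1024, freq_scope = c("population", "global"),
                    fit = TRUE, tol = 1e-4, max_iter = 100,
                    keep_posteriors = FALSE, individuals = NULL) {
  freq_scope <- match.arg(freq_scope)
  freqs <- allele_frequencies(panel, scope = freq_scope)
  dist <- .marker_distances(panel$sites)
  template <- hbd_model_spec(rates = rates, error = error)
  rows <- if (is.null(individuals)) seq_len(nrow(panel$dosage))
          else match(individuals, panel$individuals$id)
  if (anyNA(rows)) stop("unknown individual ids")
  n <- length(rows); m <- ncol(panel$dosage)
  K <- length(rates)
  inc_T <- which(rates <= T)
  ids <- panel$individuals$id[rows]
  recs <- vector("list", n); segs <- vector("list", n)
  mixing <- matrix(NA_real_, n, K + 1,
                   dimnames = list(ids, c(paste0("R", rates), "nonHBD")))
  hbd_prob <- matrix(NA_real_, n, m)
  hbd_prob_T <- matrix(NA_real_, n, m)
  posteriors <- if (keep_posteriors) vector("list", n) else NULL
  P <- .stay_probs(template, dist)
  for (j in seq_len(n)) {
    i <- rows[j]
    id <- panel$individuals$id[i]
    f <- if (freq_scope == "global") freqs[["global"]]
         else freqs[[panel$individuals$population[i]]]
    g <- panel$dosage[i, ]
    mod <- template
    emis <- .hbd_emissions(g, f, mod)
    if (fit) mod <- .em_mixing(emis, P, mod, tol, max_iter)
    raw <- hmm_forward_backward(emis, P, mod$mixing)
    dec <- structure(list(gamma = raw$gamma, loglik = raw$loglik,
                          entries = raw$entries, model = mod),
                     class = "hbd_decoding")
    path <- hmm_viterbi(emis, P, mod$mixing)
    sg <- .segments_from_path(path, mod, panel$sites)
    ss <- segment_summaries(sg, T = T)
    mixing[j, ] <- mod$mixing
    hbd_prob[j, ] <- 1 - dec$gamma[, K + 1]
    hbd_prob_T[j, ] <- rowSums(dec$gamma[, inc_T, drop = FALSE])
    if (keep_posteriors) posteriors[[j]] <- dec$gamma
    recs[[j]] <- data.frame(
      id = id, population = panel$individuals$population[i],
      group = panel$individuals$group[i],
      f_hbd = f_hbd(dec, T = T), loglik = dec$loglik,
      n_hbd = ss$n_hbd, s_hbd = ss$s_hbd,
      converged = if (fit) attr(mod, "converged") else NA,
      iterations = if (fit) attr(mod, "iterations") else 0L)
    if (nrow(sg)) segs[[j]] <- cbind(id = id, sg)
  }
  segments <- if (any(!vapply(segs, is.null, TRUE)))
    do.call(rbind, segs[!vapply(segs, is.null, TRUE)])
  else data.frame(id = character(0), scaffold = character(0),
                  start = numeric(0), end = numeric(0), rate = numeric(0),
                  length = numeric(0), n_markers = integer(0))
  structure(list(records = do.call(rbind, recs), mixing = mixing,
                 segments = segments, hbd_prob = hbd_prob,
                 hbd_prob_T = hbd_prob_T, posteriors = posteriors,
                 sites = panel$sites,
                 individuals = panel$individuals[rows, , drop = FALSE],
                 model = template, T = T, freq_scope = freq_scope),
            class = "hbd_fit")
}

#' @export
print.hbd_fit <- function(x, ...) {
  cat("HBD model fit:", nrow(x$records), "individuals,",
      nrow(x$sites), "markers,", length(x$model$rates),
      "HBD classes (T =", x$T, "=>",
      autozygosity_horizon(x$model, x$T), "generations)\n")
  cat(sprintf("F_HBD: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$records$f_hbd), min(x$records$f_hbd),
              max(x$records$f_hbd)))
  cat("Segments:", nrow(x$segments), "| frequency scope:", x$freq_scope, "\n")
  invisible(x)
}

#' @export
summary.hbd_fit <- function(object, ...) {
  r <- object$records
  pops <- split(r, r$population)
  tab <- do.call(rbind, lapply(names(pops), function(p) {
    data.frame(population = p, n = nrow(pops[[p]]),
               mean_f_hbd = mean(pops[[p]]$f_hbd),
               mean_n_hbd = mean(pops[[p]]$n_hbd),
               mean_s_hbd = mean(pops[[p]]$s_hbd))
  }))
  structure(list(by_population = tab, records = r, T = object$T),
            class = "summary.hbd_fit")
}

#' @export
print.summary.hbd_fit <- function(x, ...) {
  cat("Per-population HBD summary (T =", x$T, "):\n")
  print(x$by_population, row.names = FALSE)
  invisible(x)
}

#' @export
coef.hbd_fit <- function(object, ...) object$mixing

#' @export
fitted.hbd_fit <- function(object, ...)
  stats::setNames(object$records$f_hbd, object$records$id)

#' Plot an HBD fit
#'
#' Scatter of per-individual segment count against mean segment length,
#' point size scaled by `F_HBD` and colours by group.
#'
#' @param x an `hbd_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hbd_fit <- function(x, ...) {
  r <- x$records
  grp <- factor(r$group)
  graphics::plot(r$s_hbd, r$n_hbd, col = as.integer(grp),
                 pch = 19, cex = 0.5 + 3 * r$f_hbd,
                 xlab = "mean HBD segment length S_HBD (bp)",
                 ylab = "HBD segment count N_HBD", ...)
  graphics::legend("topleft", legend = levels(grp),
                   col = seq_along(levels(grp)), pch = 19, bty = "n")
  invisible(x)
}
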