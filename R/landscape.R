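# Genome-wide autozygosity landscape: per-SNP HBD probability averaged
# across individuals, sliding-window summaries, island/desert calling and
# gene-density association.

#' Per-SNP HBD probability across individuals
#'
#' At each SNP, the posterior probability of belonging to any HBD class
#' (equivalently `1 - P(non-HBD)`) averaged across individuals.
#'
#' @param fit an [hbd_fit()], or a matrix (individuals x SNPs) of
#'   per-individual HBD probabilities.
#' @param limit_T if `TRUE`, restrict to classes with rate `<= T` of the
#'   fit (the autozygous classes); default uses all HBD classes.
#' @return data.frame with `scaffold`, `pos` and `prob` per SNP.
#' @export
per_snp_hbd_probability <- function(fit, limit_T = FALSE) {
  if (inherits(fit, "hbd_fit")) {
    mat <- if (limit_T) fit$hbd_prob_T else fit$hbd_prob
    sites <- fit$sites
  } else {
    mat <- fit
    sites <- attr(fit, "sites")
    if (is.null(sites)) stop("matrix input needs a 'sites' attribute")
  }
  if (ncol(mat) != nrow(sites)) stop("decodings do not share the site set")
  data.frame(scaffold = sites$scaffold, pos = sites$pos,
             prob = colMeans(mat))
}

#' Sliding-window average of a per-SNP track
#'
#' Physical windows of fixed width and step, left-aligned at the scaffold
#' start, last partial window kept. Scaffolds with fewer SNPs than
#' `min_scaffold_snps` are dropped entirely; windows containing no SNP are
#' emitted with a missing value.
#'
#' @param track data.frame with `scaffold`, `pos`, `prob` (from
#'   [per_snp_hbd_probability()]).
#' @param width window width in bp (default 100 kb).
#' @param step window step in bp (default 20 kb; must not exceed `width`).
#' @param min_scaffold_snps minimum SNPs for a scaffold to be analyzed
#'   (default 10000).
#' @param scaffold_lengths optional named lengths; default the largest SNP
#'   position per scaffold.
#' @return data.frame of class `window_track`: `scaffold`, `start`, `end`
#'   (1-based inclusive bp), `prob` (mean over contained SNPs, `NA` if
#'   empty), `n_snps`, and a `flag` column initialised to `"none"`.
#' @export
window_average <- function(track, width = 1e5, step = 2e4,
                           min_scaffold_snps = 10000,
                           scaffold_lengths = NULL) {
  if (step > width) stop("step must not exceed width")
  out <- NULL
  for (sc in unique(track$scaffold)) {
    rows <- track[track$scaffold == sc, , drop = FALSE]
    if (nrow(rows) < min_scaffold_snps) next
    L <- if (!is.null(scaffold_lengths) && sc %in% names(scaffold_lengths))
      scaffold_lengths[[sc]] else max(rows$pos)
    starts <- seq(1, L, by = step)
    ends <- pmin(starts + width - 1, L)
    idx0 <- findInterval(starts - 1, rows$pos)      # snps strictly before start
    idx1 <- findInterval(ends, rows$pos)            # snps up to end
    csum <- c(0, cumsum(rows$prob))
    n <- idx1 - idx0
    prob <- ifelse(n > 0, (csum[idx1 + 1] - csum[idx0 + 1]) / n, NA_real_)
    out <- rbind(out, data.frame(scaffold = sc, start = starts, end = ends,
                                 prob = prob, n_snps = n, flag = "none"))
  }
  if (is.null(out))
    out <- data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0), prob = numeric(0),
                      n_snps = integer(0), flag = character(0))
  class(out) <- c("window_track", "data.frame")
  attr(out, "width") <- width
  attr(out, "step") <- step
  out
}

#' Flag HBD islands and deserts
#'
#' Windows at or above the upper `tail` quantile of the window
#' probabilities are islands; windows at or below the lower `tail`
#' quantile are deserts. When ties would over-fill a tail beyond
#' `ceiling(tail * n)` windows, only windows strictly inside the tail are
#' flagged (so a constant track flags nothing); any residual over-fill is
#' resolved deterministically by genomic order.
#'
#' @param windows a `window_track` from [window_average()].
#' @param tail tail mass per side (default 0.025, i.e. the extreme 2.5%).
#' @return The track with its `flag` column set to `"island"`, `"desert"`
#'   or `"none"`.
#' @export
hbd_islands_deserts <- function(windows, tail = 0.025) {
  v <- windows$prob
  ok <- which(!is.na(v))
  if (!length(ok)) stop("all windows are missing; nothing to flag")
  windows$flag <- "none"
  if (tail <= 0) return(windows)
  if (length(ok) < 1 / tail)
    warning("fewer than 1/tail windows with values; tails may be empty")
  cap <- ceiling(tail * length(ok))
  hi <- stats::quantile(v[ok], 1 - tail, names = FALSE)
  lo <- stats::quantile(v[ok], tail, names = FALSE)
  pick <- function(cand_loose, cand_strict) {
    cand <- if (length(cand_loose) > cap) cand_strict else cand_loose
    if (length(cand) > cap) cand <- cand[seq_len(cap)]  # genomic order
    cand
  }
  isl <- pick(ok[v[ok] >= hi], ok[v[ok] > hi])
  des <- pick(ok[v[ok] <= lo], ok[v[ok] < lo])
  des <- setdiff(des, isl)
  windows$flag[isl] <- "island"
  windows$flag[des] <- "desert"
  windows
}

#' Read gene intervals
#'
#' BED input (0-based half-open) or GFF3 (1-based inclusive; only rows
#' whose type is `gene` are used). Returned intervals are 0-based
#' half-open.
#'
#' @param path BED or GFF3 file.
#' @param format `"bed"` or `"gff3"`; guessed from the extension by
#'   default.
#' @return data.frame with `scaffold`, `start`, `end`.
#' @export
read_gene_intervals <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  if (format == "bed") {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    data.frame(scaffold = as.character(df[[1]]),
               start = as.numeric(df[[2]]), end = as.numeric(df[[3]]))
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    df <- df[df[[3]] == "gene", , drop = FALSE]
    data.frame(scaffold = as.character(df[[1]]),
               start = as.numeric(df[[4]]) - 1, end = as.numeric(df[[5]]))
  }
}

#' Gene-density association of window HBD probability
#'
#' Counts the genes overlapping each window (half-open overlap; a gene is
#' counted in every window it touches) and correlates the count with the
#' window HBD probability by Spearman rank correlation, with a permutation
#' p-value obtained by shuffling the probabilities across windows.
#'
#' @param windows a `window_track`.
#' @param genes data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open, e.g. from [read_gene_intervals()]).
#' @param n_perm permutation replicates (default 10000).
#' @param seed integer seed for the permutations.
#' @return list with the windows (gene counts added), `rho`, `p_value`
#'   and `n_perm`.
#' @export
gene_density_association <- function(windows, genes, n_perm = 10000,
                                     seed = 1L) {
  if (nrow(genes) == 0)
    stop("no gene intervals supplied; correlation undefined")
  cnt <- integer(nrow(windows))
  for (sc in unique(windows$scaffold)) {
    wi <- which(windows$scaffold == sc)
    gi <- genes[genes$scaffold == sc, , drop = FALSE]
    if (!nrow(gi)) next
    # window [start-1, end) vs gene [start, end), both half-open
    for (k in wi) {
      cnt[k] <- sum(gi$start < windows$end[k] &
                    gi$end > (windows$start[k] - 1))
    }
  }
  windows$n_genes <- cnt
  ok <- !is.na(windows$prob)
  if (sum(cnt[ok]) == 0)
    stop("no genes overlap any analyzed window; correlation undefined")
  x <- windows$prob[ok]; y <- cnt[ok]
  rho <- stats::cor(x, y, method = "spearman")
  .with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i)
      stats::cor(sample(x), y, method = "spearman"), 0.0)
    p <- (1 + sum(abs(perm) >= abs(rho))) / (1 + n_perm)
    list(windows = windows, rho = rho, p_value = p, n_perm = n_perm)
  })
}
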