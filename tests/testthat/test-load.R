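# Minor-allele calling, per-individual load counts, R_XY ratios,
# jackknife SEs and the Wilcoxon group comparison.

load_panel <- function(dosage, cats, pops = NULL, pos = NULL,
                       scaffold = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(pops)) pops <- rep("P", n)
  genotype_panel(dosage,
                 data.frame(scaffold = if (is.null(scaffold)) "s" else scaffold,
                            pos = if (is.null(pos)) seq_len(m) else pos,
                            category = cats),
                 data.frame(id = sprintf("i%02d", seq_len(n)),
                            population = pops, group = pops))
}

test_that("minor alleles are called by bootstrap majority with the alt tie rule", {
  # site 1: everyone heterozygous -> exact tie in every replicate -> alt
  # site 2: alt absent -> alt minor with full vote
  # site 3: alt fixed -> ref minor with full vote
  dos <- cbind(rep(1L, 8), rep(0L, 8), rep(2L, 8))
  p <- load_panel(dos, rep("neutral", 3))
  calls <- call_minor_alleles(p, list(P = p$individuals$id), reps = 50,
                              seed = 2)
  expect_equal(calls$minor, c("alt", "alt", "ref"))
  expect_equal(calls$vote, c(1, 1, 1))
  expect_true(all(!calls$informative[2:3]))
  expect_true(calls$informative[1])
  expect_error(call_minor_alleles(p, list(P = character(0))), "non-empty")
})

test_that("minor-allele calling is invariant to ref/alt relabelling away from ties", {
  # at an exact within-replicate tie the vote goes to the alternate allele
  # by convention, which is inherently label-asymmetric; away from ties the
  # call must be label-invariant, so frequencies are kept well below 0.5
  set.seed(3)
  dos <- matrix(rbinom(10 * 40, 2, 0.12), 10, 40)
  p <- load_panel(dos, rep("neutral", 40))
  q <- load_panel(2L - dos, rep("neutral", 40))
  ca <- call_minor_alleles(p, list(P = p$individuals$id), reps = 100, seed = 5)
  cb <- call_minor_alleles(q, list(P = q$individuals$id), reps = 100, seed = 5)
  expect_equal(ca$minor == "alt", cb$minor == "ref")
  # vote fractions may differ only by the occasional tie replicate
  expect_true(all(abs(ca$vote - cb$vote) <= 0.05))
})

test_that("load counts per category match hand enumeration and conserve totals", {
  # sites: high(het), high(hom-minor), neutral(hom-major), intergenic(het)
  dos <- rbind(c(1L, 2L, 0L, 1L),
               c(0L, 0L, 0L, 0L))
  p <- load_panel(dos, c("high", "high", "neutral", "intergenic"))
  calls <- data.frame(scaffold = "s", pos = 1:4,
                      minor = rep("alt", 4), vote = 1, reps = 1,
                      informative = TRUE)
  lc <- individual_load_counts(p, calls)
  i1_high <- lc[lc$id == "i01" & lc$category == "high", ]
  expect_equal(i1_high$copies, 3)
  expect_equal(i1_high$hom_sites, 1)
  i1_tot <- lc[lc$id == "i01" & lc$category == "total", ]
  expect_equal(i1_tot$copies, 4)
  expect_equal(i1_tot$poly_sites, 3)
  expect_equal(i1_high$copies_norm, 3 / 3)
  # per-category copies sum to the all-sites count
  for (id in c("i01", "i02")) {
    sub <- lc[lc$id == id, ]
    expect_equal(sum(sub$copies[sub$category != "total"]),
                 sub$copies[sub$category == "total"])
  }
})

test_that("R_XY matches direct evaluation on a two-site toy and is reciprocal", {
  # group X: site1 d=2/10, site2 d=0/10; group Y: site1 0/10, site2 4/10
  X <- rbind(c(2L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L), c(0L, 0L))
  Y <- rbind(c(0L, 2L), c(0L, 2L), c(0L, 0L), c(0L, 0L), c(0L, 0L))
  dos <- rbind(X, Y)
  # two symmetric intergenic sites so the normalization ratio is exactly 1
  inter <- cbind(c(rep(1L, 2), rep(0L, 3), rep(1L, 2), rep(0L, 3)),
                 c(rep(1L, 2), rep(0L, 3), rep(1L, 2), rep(0L, 3)))
  dos <- cbind(dos, inter)
  p <- load_panel(dos, c("neutral", "neutral", "intergenic", "intergenic"),
                  pops = rep(c("X", "Y"), each = 5))
  calls <- data.frame(scaffold = "s", pos = 1:4,
                      minor = rep("alt", 4), vote = 1, reps = 1,
                      informative = TRUE)
  res <- rxy(p, calls, "X", "Y", categories = "neutral", jackknife = FALSE)
  expect_equal(res$l_xnoty, 0.2 * (1 - 0) + 0 * (1 - 0.4))
  expect_equal(res$l_ynotx, 0 * (1 - 0.2) + 0.4 * (1 - 0))
  expect_equal(res$r_xy, 0.5)
  expect_equal(res$r_prime, 0.5)     # intergenic ratio is exactly 1
  rev <- rxy(p, calls, "Y", "X", categories = "neutral", jackknife = FALSE)
  expect_equal(res$r_xy * rev$r_xy, 1)
  expect_equal(res$r2_xy * rev$r2_xy, 1)
  # identical per-site d/n in both groups: all ratios are exactly 1
  q <- load_panel(rbind(X, X), c("neutral", "neutral"),
                  pops = rep(c("X", "Y"), each = 5))
  calls2 <- calls[1:2, ]
  calls2$pos <- 1:2
  same <- rxy(q, calls2, "X", "Y", categories = "neutral",
              intergenic_category = "neutral", jackknife = FALSE)
  expect_equal(same$r_xy, 1)
  expect_equal(same$r_prime, 1)
  expect_error(rxy(p, calls, "X", "Z"), "empty group")
})

test_that("the literal and homozygosity L2 forms differ as documented", {
  dos <- rbind(c(2L, 0L), c(2L, 0L), c(0L, 0L),
               c(1L, 1L), c(0L, 1L), c(0L, 0L))
  p <- load_panel(dos, c("neutral", "intergenic"),
                  pops = rep(c("X", "Y"), each = 3))
  calls <- data.frame(scaffold = "s", pos = 1:2, minor = rep("alt", 2),
                      vote = 1, reps = 1, informative = TRUE)
  lit <- rxy(p, calls, "X", "Y", categories = "neutral", jackknife = FALSE)
  dod <- rxy(p, calls, "X", "Y", categories = "neutral",
             l2_form = "dodds", jackknife = FALSE)
  # literal: 2d/n terms; dodds: d(d-1)/(n(n-1))
  expect_equal(lit$l2_xnoty, (2 * 4 / 6) * (1 - 2 * 1 / 6))
  expect_equal(dod$l2_xnoty, (4 * 3 / (6 * 5)) * (1 - 0))
  expect_false(isTRUE(all.equal(lit$r2_xy, dod$r2_xy)))
})

test_that("jackknife SE matches the closed-form delete-one formula on a 3-block toy", {
  cat_b <- data.frame(l1_xy = c(1.0, 2.0, 1.5), l1_yx = c(0.8, 1.1, 1.0),
                      l2_xy = c(0.5, 0.7, 0.6), l2_yx = c(0.4, 0.6, 0.5),
                      row.names = c("b1", "b2", "b3"))
  int_b <- data.frame(l1_xy = c(2.0, 2.2, 2.1), l1_yx = c(2.0, 2.1, 2.2),
                      l2_xy = c(1.0, 1.1, 1.2), l2_yx = c(1.0, 1.2, 1.1),
                      row.names = c("b1", "b2", "b3"))
  se <- jackknife_se(cat_b, int_b, min_blocks = 3)
  # independent closed form: theta_(j) with block j removed
  th <- vapply(1:3, function(j)
    sum(cat_b$l1_xy[-j]) / sum(cat_b$l1_yx[-j]), 0.0)
  expect_equal(unname(se["r"]),
               sqrt(2 / 3 * sum((th - mean(th))^2)))
  thp <- vapply(1:3, function(j)
    (sum(cat_b$l1_xy[-j]) / sum(cat_b$l1_yx[-j])) /
    (sum(int_b$l1_xy[-j]) / sum(int_b$l1_yx[-j])), 0.0)
  expect_equal(unname(se["r_prime"]),
               sqrt(2 / 3 * sum((thp - mean(thp))^2)))
  # identical block contributions give zero SE
  flat <- data.frame(l1_xy = rep(1, 3), l1_yx = rep(1, 3),
                     l2_xy = rep(1, 3), l2_yx = rep(1, 3),
                     row.names = c("b1", "b2", "b3"))
  expect_equal(unname(jackknife_se(flat, flat, min_blocks = 3)["r"]), 0)
  expect_error(jackknife_se(cat_b, int_b), "smaller block_bp")
})

test_that("Wilcoxon comparison matches enumeration, with effect-size labels", {
  res <- group_compare(1:3, 4:6)
  # exhaustive: all A values below all B values -> W = 0
  expect_equal(res$W, 0)
  wt <- wilcox.test(1:3, 4:6, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, wt$p.value)
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_lt(same$effect_size, 1e-12)
  expect_equal(same$label, "negligible")
  big <- group_compare(1:10, 11:20)
  expect_equal(big$label, "large")
  expect_gt(big$effect_size, 0.5)
  expect_error(group_compare(numeric(0), 1), "non-empty")
})
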