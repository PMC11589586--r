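# HBD HMM: oracle equivalence, EM behaviour, decoding properties,
# F_HBD and segment summaries.

test_that("forward-backward and Viterbi match exhaustive path enumeration", {
  for (case in 1:4) {
    set.seed(case)
    T_ <- sample(3:6, 1)
    rates <- sort(sample(c(2, 16, 64, 256), sample(1:2, 1)))
    model <- hbd_model_spec(rates = rates, nonhbd_rate = 512,
                            mixing = NULL, error = 0.01)
    g <- sample(c(0L, 1L, 2L, NA), T_, replace = TRUE)
    f <- runif(T_, 0.1, 0.9)
    d <- runif(T_ - 1, 0, 0.05)
    dec <- forward_backward(g, f, model, d)
    emis <- hbdload:::.hbd_emissions(g, f, model)
    or <- oracle_enumerate(emis, model$state_rates, model$mixing, d)
    expect_lt(max(abs(dec$gamma - or$gamma)), 1e-10)
    expect_lt(abs(dec$loglik - or$loglik), 1e-10)
    path <- hbdload:::hmm_viterbi(emis, hbdload:::.stay_probs(model, d),
                                  model$mixing)
    # tie-robust: the decoded path must attain the enumerated maximum
    pp <- oracle_path_prob(as.integer(path), emis, model$state_rates,
                           model$mixing, d)
    expect_lt(abs(pp - or$max_path_prob) / or$max_path_prob, 1e-10)
  }
})

test_that("posteriors sum to one at every marker", {
  set.seed(7)
  model <- hbd_model_spec()
  g <- sample(c(0L, 1L, 2L, NA), 500, replace = TRUE)
  f <- runif(500, 0.05, 0.95)
  d <- rexp(499, 500)
  dec <- forward_backward(g, f, model, d)
  expect_lt(max(abs(rowSums(dec$gamma) - 1)), 1e-9)
  expect_true(is.finite(dec$loglik))
})

test_that("an uninformative single marker returns the mixing coefficients", {
  model <- hbd_model_spec(rates = c(4, 64), nonhbd_rate = 512,
                          mixing = c(0.2, 0.3, 0.5))
  dec <- forward_backward(NA_integer_, 0.5, model, numeric(0))
  expect_equal(as.numeric(dec$gamma), model$mixing)
})

test_that("zero-length observations are rejected", {
  model <- hbd_model_spec()
  expect_error(forward_backward(integer(0), numeric(0), model, numeric(0)),
               "zero-length")
  expect_error(forward_backward(c(0L, 1L), c(0, 0.5), model, 0.01),
               "strictly in")
})

test_that("EM log-likelihood is non-decreasing and recovers planted mixing", {
  model <- hbd_model_spec(rates = 64, nonhbd_rate = 8192, error = 0.002)
  T_ <- 20000
  f <- runif(T_, 0.1, 0.9)
  d <- rep(1 / 1000, T_ - 1)
  sim <- simulate_hmm(T_, model$state_rates, c(0.2, 0.8), f,
                      error = 0.002, dist = d, seed = 99)
  fit <- fit_mixing_coefficients(sim$genotypes, f, model, d, max_iter = 80)
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) > -1e-8))
  expect_lt(abs(fit$mixing[1] - 0.2), 0.05)
})

test_that("with all distances zero the chain never transitions", {
  set.seed(3)
  model <- hbd_model_spec(rates = c(8, 128), nonhbd_rate = 512)
  g <- sample(0:2, 50, replace = TRUE)
  f <- runif(50, 0.2, 0.8)
  dec <- forward_backward(g, f, model, rep(0, 49))
  # one state assignment shared by all markers: posterior identical rows
  expect_lt(max(abs(sweep(dec$gamma, 2, dec$gamma[1, ]))), 1e-9)
})

test_that("Viterbi merges forced homozygous runs into one spanning segment", {
  model <- hbd_model_spec(rates = c(4, 64), nonhbd_rate = 512, error = 0)
  g <- rep(2L, 8)
  f <- rep(0.5, 8)
  d <- rep(1e-4, 7)
  sites <- data.frame(scaffold = "s1", pos = (1:8) * 1e4)
  seg <- viterbi_segments(g, f, model, d, sites)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 1e4)
  expect_equal(seg$end, 8e4)
  expect_true(seg$rate %in% c(4, 64))
  # sorted and non-overlapping on a mixed decode
  set.seed(11)
  g2 <- sample(c(0L, 1L, 2L), 300, replace = TRUE)
  seg2 <- viterbi_segments(g2, runif(300, 0.2, 0.8), model,
                           rep(5e-4, 299),
                           data.frame(scaffold = "s1", pos = (1:300) * 1e3))
  if (nrow(seg2) > 1) {
    expect_true(all(diff(seg2$start) > 0))
    expect_true(all(seg2$end[-nrow(seg2)] < seg2$start[-1]))
  }
})

test_that("F_HBD reduces to posterior mass below the rate threshold", {
  model <- hbd_model_spec(rates = c(2, 2048), nonhbd_rate = 8192)
  dec <- structure(list(gamma = matrix(c(1, 0, 0), 5, 3, byrow = TRUE),
                        model = model), class = "hbd_decoding")
  expect_equal(f_hbd(dec, T = 1024), 1)         # all mass in rate-2 class
  dec$gamma <- matrix(c(0, 0, 1), 5, 3, byrow = TRUE)
  expect_equal(f_hbd(dec, T = 1024), 0)         # all mass non-HBD
  dec$gamma <- matrix(c(0.3, 0.4, 0.3), 5, 3, byrow = TRUE)
  expect_equal(f_hbd(dec, T = 1024), 0.3)       # rate 2048 excluded at T=1024
  expect_equal(f_hbd(dec, T = 2048), 0.7)
  expect_warning(v <- f_hbd(dec, T = 1), "below the smallest")
  expect_equal(v, 0)
})

test_that("F_HBD is monotone non-decreasing in T", {
  set.seed(5)
  model <- hbd_model_spec()
  g <- sample(c(0L, 1L, 2L), 400, replace = TRUE)
  dec <- forward_backward(g, runif(400, 0.1, 0.9), model, rep(1e-3, 399))
  vals <- vapply(c(2, 16, 128, 1024, 8192), function(T) f_hbd(dec, T), 0.0)
  expect_true(all(diff(vals) >= 0))
})

test_that("the default rate ladder with T = 1024 spans 512 generations", {
  model <- hbd_model_spec()
  expect_equal(model$rates, 2^(1:13))
  expect_equal(autozygosity_horizon(model, T = 1024), 512)
  expect_equal(autozygosity_horizon(model, T = 1024, strict = TRUE), 256)
  expect_equal(rate_to_generations(64), 32)
})

test_that("segment summaries count and measure autozygous classes only", {
  segs <- data.frame(scaffold = "s", start = c(1, 1, 1, 1),
                     end = c(1e6, 3e6, 2e6, 5e6),
                     rate = c(64, 64, 2048, 2048),
                     length = c(1e6, 3e6, 2e6, 5e6), n_markers = 1:4)
  ss <- segment_summaries(segs, T = 1024)
  expect_equal(ss$n_hbd, 2L)
  expect_equal(ss$s_hbd, 2e6)
  expect_equal(ss$class_sums, c("64" = 4e6))
  empty <- segment_summaries(segs[0, ], T = 1024)
  expect_equal(empty$n_hbd, 0L)
  expect_equal(empty$s_hbd, 0)
  expect_length(empty$class_sums, 0)
})

test_that("hbd_fit returns coherent records and methods on a small panel", {
  w <- numeric(13); w[6] <- 0.2
  cfg <- sim_config(n_populations = 1, population_labels = "P",
                    group_labels = "g", n_individuals = 4, n_scaffolds = 3,
                    scaffold_length = 5e7, n_sites = 500, divergence = 0,
                    hbd_class_weights = list(w), seed = 77)
  gen <- generate_panel(cfg)
  fit <- hbd_fit(gen$panel, max_iter = 30, keep_posteriors = TRUE)
  expect_s3_class(fit, "hbd_fit")
  expect_equal(nrow(fit$records), 4)
  expect_true(all(fit$records$f_hbd >= 0 & fit$records$f_hbd <= 1))
  expect_equal(dim(coef(fit)), c(4L, 14L))
  expect_equal(unname(fitted(fit)), fit$records$f_hbd)
  expect_output(print(fit), "HBD model fit")
  expect_output(print(summary(fit)), "Per-population")
  # per-marker HBD probability equals 1 - P(non-HBD)
  for (i in 1:4)
    expect_equal(fit$hbd_prob[i, ], 1 - fit$posteriors[[i]][, 14])
  # posterior mass of autozygous classes never exceeds the all-class mass
  expect_true(all(fit$hbd_prob_T <= fit$hbd_prob + 1e-12))
})
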