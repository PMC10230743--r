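test_that("split-Rhat separates well-mixed from disjoint chains", {
  set.seed(1)
  same <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(split_rhat(same), 1.02)
  offset <- cbind(rnorm(1000), rnorm(1000) + 5)
  expect_gt(split_rhat(offset), 1.1)
  # within-chain drift is caught by the split
  drift <- cbind(c(rnorm(500), rnorm(500) + 5),
                 c(rnorm(500), rnorm(500) + 5))
  expect_gt(split_rhat(drift), 1.1)
  expect_error(split_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("effective sample size is sane for iid and autocorrelated chains", {
  set.seed(2)
  iid <- cbind(rnorm(800), rnorm(800))
  expect_gt(ess_basic(iid), 800)
  ar <- matrix(0, 800, 2)
  for (c in 1:2) for (t in 2:800) ar[t, c] <- 0.95 * ar[t - 1, c] + rnorm(1)
  expect_lt(ess_basic(ar), 400)
})

test_that("posterior summaries match sort-based quantiles and flag significance", {
  rows <- make_mm_rows(n_ind = 10, seed = 4)
  fit <- fit_beta_mm(rows,
                     model_spec(response = "jaccard", terms = "sri",
                                interactions = character(0)),
                     tiny_settings(seed = 9))
  sm <- summarize_fit(fit)
  d <- fit$draws[, "sri"]
  expect_equal(sm$estimate[sm$term == "sri"], mean(d))
  expect_equal(sm$est_error[sm$term == "sri"], sd(d))
  s <- sort(d)
  expect_equal(sm$q2.5[sm$term == "sri"],
               unname(quantile(s, 0.025, type = 7)))
  expect_equal(sm$q97.5[sm$term == "sri"],
               unname(quantile(s, 0.975, type = 7)))
  # symmetric draws around zero are not significant
  expect_false(sm$q2.5[sm$term == "sri"] > 0 && sm$q97.5[sm$term == "sri"] < 0)
  # mean of simple draws
  expect_equal(mean(c(1, 2, 3, 4)), 2.5)
})

test_that("seeded fits are bit-reproducible", {
  rows <- make_mm_rows(n_ind = 8, seed = 3)
  spec <- model_spec(response = "jaccard", terms = "sri",
                     interactions = character(0))
  f1 <- fit_beta_mm(rows, spec, tiny_settings(seed = 42))
  f2 <- fit_beta_mm(rows, spec, tiny_settings(seed = 42))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_beta_mm(rows, spec, tiny_settings(seed = 43))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("the fit recovers a planted slope from its own likelihood", {
  rows <- make_mm_rows(n_ind = 40, samples_each = 2, beta = c(-1, 0.4),
                       sigma_ind = 0.1, sigma_samp = 0.1, phi = 50, seed = 8)
  fit <- fit_beta_mm(rows,
                     model_spec(response = "jaccard", terms = "sri",
                                interactions = character(0)),
                     mm_settings_reduced(seed = 21))
  sm <- summarize_fit(fit)
  sri <- sm[sm$term == "sri", ]
  expect_gt(sri$q97.5, 0.4 - 1e-9)
  expect_lt(sri$q2.5, 0.4 + 1e-9)
  expect_equal(sri$estimate, 0.4, tolerance = 0.15)
  phi <- sm[sm$term == "phi", ]
  expect_equal(phi$estimate, 50, tolerance = 0.25)
})

test_that("a near-constant null response gives a null intercept model", {
  set.seed(10)
  rows <- make_mm_rows(n_ind = 12, seed = 10)
  rows$sri <- rnorm(nrow(rows))
  rows$jaccard <- pmin(pmax(0.5 + rnorm(nrow(rows), 0, 0.01), 0.01), 0.99)
  fit <- fit_beta_mm(rows,
                     model_spec(response = "jaccard", terms = "sri",
                                interactions = character(0)),
                     tiny_settings(seed = 2))
  sm <- summarize_fit(fit)
  expect_lt(abs(sm$estimate[sm$term == "Intercept"]), 0.05)
  expect_false(sm$significant[sm$term == "sri"])
})

test_that("posterior matches an independent Gibbs-sampler fit of the same model", {
  rows <- make_mm_rows(n_ind = 12, samples_each = 2, beta = c(-1, 0.4),
                       sigma_ind = 0.3, sigma_samp = 0.2, phi = 50, seed = 1)
  spec <- model_spec(response = "jaccard", terms = "sri",
                     interactions = character(0))
  fit <- fit_beta_mm(rows, spec,
                     mm_settings(chains = 2, warmup = 600, iter = 600,
                                 max_leapfrog = 16, seed = 3))
  sm <- summarize_fit(fit)

  library(rjags)
  b <- dyadtrans:::.bmm_build(rows, spec)
  jd <- list(y = b$y, x = b$X[, 2], ia = b$ia + 1, ib = b$ib + 1,
             sa = b$sa + 1, sb = b$sb + 1, N = length(b$y),
             NI = b$n_u, NS = b$n_w)
  mstr <- "model{
    for(d in 1:N){
      logit(mu[d]) <- b0 + b1*x[d] + uu[ia[d]] + uu[ib[d]] + ww[sa[d]] + ww[sb[d]]
      y[d] ~ dbeta(mu[d]*phi, (1-mu[d])*phi)
    }
    for(i in 1:NI){ uu[i] ~ dnorm(0, tau_u) }
    for(s in 1:NS){ ww[s] ~ dnorm(0, tau_w) }
    b0 ~ dnorm(0, 0.16); b1 ~ dnorm(0, 0.16)
    sig_u ~ dt(0, 0.16, 3) T(0,); sig_w ~ dt(0, 0.16, 3) T(0,)
    tau_u <- pow(sig_u, -2); tau_w <- pow(sig_w, -2)
    phi ~ dgamma(0.01, 0.01)
  }"
  jm <- jags.model(textConnection(mstr), data = jd, n.chains = 2,
                   quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 7))
  update(jm, 1500, progress.bar = "none")
  ps <- coda.samples(jm, c("b1", "phi", "sig_w"), 3000,
                     progress.bar = "none")
  js <- summary(ps)$statistics
  expect_equal(sm$estimate[sm$term == "sri"], js["b1", "Mean"],
               tolerance = 0.02)
  expect_equal(sm$est_error[sm$term == "sri"], js["b1", "SD"],
               tolerance = 0.3)
  expect_equal(sm$estimate[sm$term == "phi"], js["phi", "Mean"],
               tolerance = 0.05)
  expect_equal(sm$estimate[sm$term == "sigma_samp"], js["sig_w", "Mean"],
               tolerance = 0.2)
})

test_that("dropping the multi-membership terms distorts dispersion and interval width", {
  # paired comparison on data simulated from the full likelihood with
  # strong grouping: the misspecified (no random effect) fit must absorb
  # the group variation into the Beta dispersion, collapsing phi far below
  # its generative value and materially changing the slope interval, while
  # the full model recovers phi and covers the true slope
  rows <- make_mm_rows(n_ind = 25, samples_each = 3, beta = c(-1, 0.3),
                       sigma_ind = 0.5, sigma_samp = 0.3, phi = 60,
                       seed = 12, pair_covariate = TRUE)
  spec_full <- model_spec(response = "jaccard", terms = "sri",
                          interactions = character(0))
  spec_norf <- model_spec(response = "jaccard", terms = "sri",
                          interactions = character(0),
                          re_individual = FALSE, re_sample = FALSE)
  full <- summarize_fit(fit_beta_mm(rows, spec_full, tiny_settings(1)))
  norf <- summarize_fit(fit_beta_mm(rows, spec_norf, tiny_settings(1)))
  get <- function(sm, term, col) sm[sm$term == term, col]
  # full model: phi near 60, sigma_ind detected, slope CI covers 0.3
  expect_equal(get(full, "phi", "estimate"), 60, tolerance = 0.15)
  expect_gt(get(full, "sigma_ind", "q2.5"), 0.2)
  expect_lt(get(full, "sri", "q2.5"), 0.3)
  expect_gt(get(full, "sri", "q97.5"), 0.3)
  # misspecified model: dispersion collapses by more than half
  expect_lt(get(norf, "phi", "estimate"), 30)
  # and the two fits disagree materially about slope uncertainty
  ci <- function(sm) get(sm, "sri", "q97.5") - get(sm, "sri", "q2.5")
  expect_gt(abs(log(ci(norf) / ci(full))), log(1.25))
})

test_that("input validation guides the caller", {
  rows <- make_mm_rows(n_ind = 6, seed = 5)
  spec <- model_spec(response = "jaccard", terms = "sri",
                     interactions = character(0))
  bad <- rows
  bad$jaccard[1] <- 1
  expect_error(fit_beta_mm(bad, spec, tiny_settings()), "squeeze")
  expect_error(model_spec(terms = "sri", interactions = "sri:age_sim"),
               "main effects")
  expect_error(mm_settings(chains = 0))
})

test_that("convergence checking needs two chains and writes trace plots", {
  rows <- make_mm_rows(n_ind = 8, seed = 6)
  spec <- model_spec(response = "jaccard", terms = "sri",
                     interactions = character(0))
  one <- fit_beta_mm(rows, spec,
                     mm_settings(chains = 1, warmup = 100, iter = 100,
                                 max_leapfrog = 6, seed = 1))
  expect_error(check_convergence(one), "2 chains")
  fit <- fit_beta_mm(rows, spec, tiny_settings(seed = 7))
  dir <- withr::local_tempdir()
  conv <- check_convergence(fit, rhat_threshold = 1.2, plot_dir = dir)
  expect_named(conv$rhat)
  expect_true(length(list.files(dir, pattern = "^trace_.*png$")) >= 3)
  # threshold is respected exactly
  strict <- check_convergence(fit, rhat_threshold = 1 + 1e-9)
  expect_false(strict$pass)
})

test_that("stratum effects compose main and interaction terms", {
  # draw-wise composition on a fitted object
  rows <- make_mm_rows(n_ind = 10, seed = 13)
  rows$age_sim <- rbinom(nrow(rows), 1, 0.5)
  spec <- model_spec(response = "jaccard", terms = c("sri", "age_sim"),
                     interactions = "sri:age_sim")
  fit <- fit_beta_mm(rows, spec, tiny_settings(seed = 3))
  e0 <- stratum_effect(fit, "sri", "age_sim", 0)
  e1 <- stratum_effect(fit, "sri", "age_sim", 1)
  expect_equal(e0$estimate, mean(fit$draws[, "sri"]))
  expect_equal(e1$estimate,
               mean(fit$draws[, "sri"] + fit$draws[, "sri:age_sim"]))
  expect_lt(e1$lower, e1$estimate)
  expect_gt(e1$upper, e1$estimate)
  # no interaction in the fit: main effect with a note
  fit2 <- fit_beta_mm(rows, model_spec(response = "jaccard",
                                       terms = c("sri", "age_sim"),
                                       interactions = character(0)),
                      tiny_settings(seed = 3))
  e <- stratum_effect(fit2, "sri", "age_sim", 1)
  expect_match(e$note, "main effect")
  # point composition on plain coefficients; zero interaction is level-free
  expect_equal(stratum_effect(c(main = 0.2, interaction = 0), 0)$estimate,
               stratum_effect(c(main = 0.2, interaction = 0), 1)$estimate)
})
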