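#' Specify the dyadic Beta regression model
#'
#' Describes which response and fixed effects enter the model and which
#' multi-membership random intercepts are used. Interactions are written
#' `"a:b"` and must be over included main effects.
#'
#' @param response `"jaccard"` or `"braycurtis"` (a column of the dyad
#'   table).
#' @param terms fixed-effect columns of the dyad table.
#' @param interactions character vector of `"a:b"` interaction terms
#'   (possibly empty).
#' @param re_individual,re_sample include the multi-membership random
#'   intercept for the two individuals / the two samples of each dyad.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response = c("jaccard", "braycurtis"),
                       terms = c("mo_status", "sri", "relatedness",
                                 "age_sim", "sex_sim", "spatial_dist",
                                 "interval_days"),
                       interactions = c("mo_status:age_sim", "sri:age_sim"),
                       re_individual = TRUE, re_sample = TRUE) {
  response <- match.arg(response)
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% terms)) {
      stop("interaction terms must be 'a:b' over included main effects: ", ia)
    }
  }
  structure(list(response = response, terms = terms,
                 interactions = interactions,
                 re_individual = re_individual, re_sample = re_sample),
            class = "model_spec")
}

#' Sampler settings for [fit_beta_mm()]
#'
#' Defaults are 4 chains of 1,000 warmup + 1,000 kept draws; the `reduced`
#' preset (2 chains of 500 + 500) is used for the family-exclusion scan
#' where many models are fitted.
#'
#' @param chains,warmup,iter chain count, warmup iterations, kept draws per
#'   chain.
#' @param max_leapfrog trajectory length; each transition uses a jittered
#'   number of leapfrog steps in `[0.8, 1] * max_leapfrog`.
#' @param adapt_delta target acceptance probability for step-size
#'   adaptation.
#' @param prior_beta_sd Normal prior SD on (standardized-scale)
#'   coefficients.
#' @param prior_sigma_df,prior_sigma_scale half-Student-t prior on the
#'   random-effect SDs.
#' @param prior_phi_shape,prior_phi_rate Gamma prior on the Beta precision.
#' @param init_jitter SD of the Normal jitter on initial values, per chain.
#' @param seed integer seed; the whole fit is reproducible given it.
#' @return An `mm_settings` list.
#' @export
mm_settings <- function(chains = 4L, warmup = 1000L, iter = 1000L,
                        max_leapfrog = 16L, adapt_delta = 0.8,
                        prior_beta_sd = 2.5, prior_sigma_df = 3,
                        prior_sigma_scale = 2.5, prior_phi_shape = 0.01,
                        prior_phi_rate = 0.01, init_jitter = 0.05,
                        seed = 1L) {
  stopifnot(chains >= 1, warmup >= 50, iter >= 50, max_leapfrog >= 1,
            adapt_delta > 0, adapt_delta < 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter),
                 max_leapfrog = as.integer(max_leapfrog),
                 adapt_delta = adapt_delta, prior_beta_sd = prior_beta_sd,
                 prior_sigma_df = prior_sigma_df,
                 prior_sigma_scale = prior_sigma_scale,
                 prior_phi_shape = prior_phi_shape,
                 prior_phi_rate = prior_phi_rate,
                 init_jitter = init_jitter, seed = as.integer(seed)),
            class = "mm_settings")
}

#' @rdname mm_settings
#' @export
mm_settings_reduced <- function(seed = 1L) {
  mm_settings(chains = 2L, warmup = 500L, iter = 500L, max_leapfrog = 8L,
              seed = seed)
}

# design matrix + group indices from a dyad table and a model_spec
.bmm_build <- function(rows, spec) {
  y <- rows[[spec$response]]
  if (is.null(y)) stop("dyad table has no response column: ", spec$response)
  if (any(y <= 0 | y >= 1)) {
    stop("response values must lie strictly in (0, 1); apply ",
         "squeeze_response() to the similarities first")
  }
  X <- cbind(Intercept = rep(1, nrow(rows)))
  for (tm in spec$terms) {
    v <- rows[[tm]]
    if (is.null(v)) stop("dyad table has no term column: ", tm)
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- tm
  }
  for (ia in spec$interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    X <- cbind(X, rows[[parts[1]]] * rows[[parts[2]]])
    colnames(X)[ncol(X)] <- ia
  }
  ind_levels <- sort(unique(c(rows$individual_a, rows$individual_b)))
  samp_levels <- sort(unique(c(rows$sample_a, rows$sample_b)))
  use_u <- isTRUE(spec$re_individual)
  use_w <- isTRUE(spec$re_sample)
  list(
    y = as.numeric(y), X = X,
    ia = if (use_u) match(rows$individual_a, ind_levels) - 1L else integer(nrow(rows)),
    ib = if (use_u) match(rows$individual_b, ind_levels) - 1L else integer(nrow(rows)),
    sa = if (use_w) match(rows$sample_a, samp_levels) - 1L else integer(nrow(rows)),
    sb = if (use_w) match(rows$sample_b, samp_levels) - 1L else integer(nrow(rows)),
    n_u = if (use_u) length(ind_levels) else 0L,
    n_w = if (use_w) length(samp_levels) else 0L,
    ind_levels = ind_levels, samp_levels = samp_levels
  )
}

.bmm_prior <- function(settings) {
  list(beta_sd = settings$prior_beta_sd, sigma_df = settings$prior_sigma_df,
       sigma_scale = settings$prior_sigma_scale,
       phi_shape = settings$prior_phi_shape,
       phi_rate = settings$prior_phi_rate)
}

#' Fit the Bayesian dyadic Beta multi-membership model
#'
#' Fits `y_d ~ Beta(mu_d * phi, (1 - mu_d) * phi)` with
#' `logit(mu_d) = x_d' beta + u_A(d) + u_B(d) + w_sA(d) + w_sB(d)`, where
#' `u ~ Normal(0, sigma_ind)` is shared across all dyads an individual
#' appears in (entering once for each of the two members) and `w` likewise
#' for samples. Sampling is by adaptive Hamiltonian Monte Carlo on the
#' unconstrained scale with a thin-QR reparameterised fixed-effects block;
#' step size is tuned by dual averaging and a diagonal mass matrix is
#' estimated during warmup.
#' Fits are bit-reproducible given `settings$seed`.
#'
#' @param rows a `dyad_table`; the response column must already be strictly
#'   inside (0, 1) (see [squeeze_response()]).
#' @param spec a [model_spec()].
#' @param settings an [mm_settings()].
#' @return An `mm_fit` object: `draws` (matrix, kept iterations x
#'   parameters, with `sigma_ind`/`sigma_samp`/`phi` on their natural
#'   scale), `chain` (chain index per draw), `par_names`, plus the spec,
#'   settings, acceptance rates and group levels.
#' @export
fit_beta_mm <- function(rows, spec = model_spec(),
                        settings = mm_settings()) {
  b <- .bmm_build(rows, spec)
  if (length(b$ind_levels) < 2L) stop("need at least 2 individuals")
  prior <- .bmm_prior(settings)
  p <- ncol(b$X)
  npar <- p + b$n_u + b$n_w + (b$n_u > 0) + (b$n_w > 0) + 1L

  # thin-QR reparameterisation of the fixed-effects block: the sampler works
  # on theta with X beta = Q theta (near-isotropic geometry), the prior is
  # applied to beta = R^-1 theta exactly, and draws are mapped back below
  qrx <- qr(b$X)
  sq <- sqrt(nrow(b$X) - 1)
  Q <- qr.Q(qrx)[, seq_len(p), drop = FALSE] * sq
  Rmat <- qr.R(qrx)[seq_len(p), seq_len(p), drop = FALSE] / sq
  if (abs(det(Rmat)) < 1e-12) stop("design matrix is rank deficient")
  Rinv <- solve(Rmat)

  # moment-based initial values: intercept at logit(mean y), phi from the
  # Beta variance relation, small random-effect scales
  my <- mean(b$y)
  vy <- stats::var(b$y)
  phi0 <- max(2, min(500, my * (1 - my) / max(vy, 1e-6) - 1))
  init <- numeric(npar)
  beta0 <- numeric(p)
  beta0[1] <- stats::qlogis(my)
  init[seq_len(p)] <- Rmat %*% beta0  # theta scale
  k <- p + b$n_u + b$n_w
  if (b$n_u > 0) { init[k + 1] <- log(0.1); k <- k + 1 }
  if (b$n_w > 0) { init[k + 1] <- log(0.1); k <- k + 1 }
  init[k + 1] <- log(phi0)

  dat <- b[c("y", "ia", "ib", "sa", "sb", "n_u", "n_w")]
  dat$X <- Q
  dat$Rinv <- Rinv
  set.seed(settings$seed)
  res <- .bmm_sample(dat, prior, init, settings$chains, settings$warmup,
                     settings$iter, settings$max_leapfrog,
                     settings$adapt_delta, settings$init_jitter)
  # back to the beta scale
  res$draws[, seq_len(p)] <- res$draws[, seq_len(p), drop = FALSE] %*% t(Rinv)

  par_names <- c(colnames(b$X),
                 if (b$n_u > 0) paste0("u_ind[", b$ind_levels, "]"),
                 if (b$n_w > 0) paste0("w_samp[", b$samp_levels, "]"),
                 if (b$n_u > 0) "sigma_ind",
                 if (b$n_w > 0) "sigma_samp",
                 "phi")
  draws <- res$draws
  colnames(draws) <- par_names
  # natural scale for the variance-type parameters
  for (nm in intersect(c("sigma_ind", "sigma_samp", "phi"), par_names)) {
    draws[, nm] <- exp(draws[, nm])
  }
  structure(list(draws = draws, chain = as.integer(res$chain),
                 par_names = par_names,
                 fixed_names = colnames(b$X),
                 spec = spec, settings = settings,
                 n_obs = length(b$y), n_ind = b$n_u, n_samp = b$n_w,
                 ind_levels = b$ind_levels, samp_levels = b$samp_levels,
                 accept = as.numeric(res$accept),
                 step_size = as.numeric(res$step_size)),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "Beta multi-membership dyadic model: %d rows, %d individuals, %d samples\n",
    x$n_obs, x$n_ind, x$n_samp))
  cat(sprintf("  %d chains x %d draws (mean acceptance %.2f)\n",
              x$settings$chains, x$settings$iter, mean(x$accept)))
  print(summarize_fit(x))
  invisible(x)
}

#' Split-Rhat and effective sample size
#'
#' `split_rhat()` implements the split potential-scale-reduction statistic:
#' each chain is halved, and Rhat is `sqrt(var_plus / W)` where `W` is the
#' mean within-half variance and `var_plus` the weighted total-variance
#' estimate. `ess_basic()` estimates effective sample size from
#' chain-averaged autocorrelations with Geyer initial-positive truncation.
#'
#' @param x numeric matrix of draws, iterations x chains (>= 2 chains for
#'   Rhat).
#' @return A single number.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("split_rhat needs at least 2 chains")
  n <- nrow(x)
  half <- n %/% 2L
  pieces <- c(lapply(seq_len(ncol(x)), function(j) x[seq_len(half), j]),
              lapply(seq_len(ncol(x)), function(j) x[(n - half + 1L):n, j]))
  m <- length(pieces)
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @rdname split_rhat
#' @export
ess_basic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- ncol(x)
  W <- mean(apply(x, 2, stats::var))
  if (W <= 0) return(n * m)
  ch_mean <- colMeans(x)
  var_plus <- (n - 1) / n * W + if (m > 1) stats::var(ch_mean) else 0
  # chain-averaged autocovariances
  max_lag <- min(n - 1L, 400L)
  rho <- numeric(max_lag)
  for (t in seq_len(max_lag)) {
    acov <- mean(vapply(seq_len(m), function(j) {
      v <- x[, j] - ch_mean[j]
      sum(v[1:(n - t)] * v[(t + 1):n]) / n
    }, 0))
    rho[t] <- 1 - (W - acov) / var_plus
  }
  # Geyer: sum consecutive pairs while positive
  s <- 0
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, (n * m) / (1 + 2 * s))
}

.draws_by_chain <- function(fit, par) {
  matrix(fit$draws[, par], nrow = fit$settings$iter,
         ncol = fit$settings$chains)
}

#' Posterior summary table
#'
#' Posterior mean, SD (`est_error`, the posterior standard deviation),
#' central 95% credible interval, split-Rhat, effective sample size, and a
#' significance flag (the 95% interval excludes zero) per parameter.
#' Random-effect values (`u_ind[...]`, `w_samp[...]`) are omitted by
#' default.
#'
#' @param fit an `mm_fit`.
#' @param include_ranef include per-individual / per-sample effect rows.
#' @return data.frame with columns `term`, `estimate`, `est_error`, `q2.5`,
#'   `q97.5`, `rhat`, `ess`, `significant`.
#' @export
summarize_fit <- function(fit, include_ranef = FALSE) {
  pars <- if (include_ranef) fit$par_names else
    c(fit$fixed_names,
      intersect(c("sigma_ind", "sigma_samp", "phi"), fit$par_names))
  multi <- fit$settings$chains >= 2L
  out <- do.call(rbind, lapply(pars, function(p) {
    d <- fit$draws[, p]
    q <- unname(stats::quantile(d, c(0.025, 0.975), type = 7))
    bych <- .draws_by_chain(fit, p)
    data.frame(term = p, estimate = mean(d), est_error = stats::sd(d),
               q2.5 = q[1], q97.5 = q[2],
               rhat = if (multi) split_rhat(bych) else NA_real_,
               ess = ess_basic(bych),
               significant = q[1] > 0 | q[2] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.mm_fit <- function(object, ...) summarize_fit(object, ...)

#' Convergence check for an mm_fit
#'
#' Computes split-Rhat for every sampled parameter and passes iff all are
#' below `rhat_threshold`. With `plot_dir` set, writes one PNG trace plot
#' per fixed-effect/variance parameter for visual inspection.
#'
#' @param fit an `mm_fit` with >= 2 chains.
#' @param rhat_threshold pass/fail threshold (default 1.05).
#' @param plot_dir optional directory for trace-plot PNGs.
#' @return list: `pass` (logical), `rhat` (named vector), `threshold`,
#'   `worst` (parameter with largest Rhat).
#' @export
check_convergence <- function(fit, rhat_threshold = 1.05, plot_dir = NULL) {
  if (fit$settings$chains < 2L) {
    stop("Rhat requires at least 2 chains; refit with chains >= 2")
  }
  pars <- c(fit$fixed_names,
            intersect(c("sigma_ind", "sigma_samp", "phi"), fit$par_names))
  rh <- vapply(pars, function(p) split_rhat(.draws_by_chain(fit, p)), 0)
  if (!is.null(plot_dir)) {
    dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in pars) {
      f <- file.path(plot_dir, paste0("trace_", gsub("[^A-Za-z0-9_.-]", "_", p), ".png"))
      grDevices::png(f, width = 700, height = 350)
      m <- .draws_by_chain(fit, p)
      graphics::matplot(m, type = "l", lty = 1, xlab = "iteration",
                        ylab = p, main = sprintf("%s (Rhat %.3f)", p, rh[p]))
      grDevices::dev.off()
    }
  }
  list(pass = all(rh < rhat_threshold), rhat = rh,
       threshold = rhat_threshold, worst = names(rh)[which.max(rh)])
}

#' Stratum-specific (marginal) effect of a term under an interaction
#'
#' The effect of `main` when the binary `modifier` is at `level` is
#' `beta_main + level * beta_interaction`. Applied to a fitted model the
#' composition is done draw-wise, so the reported interval is a true
#' posterior credible interval; applied to a plain named coefficient vector
#' (`c(main = ..., interaction = ...)`) it composes the point estimates.
#'
#' @param object an `mm_fit`, or a named numeric vector with elements
#'   `main` and `interaction`.
#' @param main,modifier term names in the fit (ignored for numeric input).
#' @param level 0 or 1.
#' @param ... unused.
#' @return list with `estimate`, `lower`, `upper` (NA for point input),
#'   `level` and possibly `note`.
#' @export
stratum_effect <- function(object, ...) UseMethod("stratum_effect")

#' @rdname stratum_effect
#' @export
stratum_effect.mm_fit <- function(object, main, modifier, level, ...) {
  stopifnot(level %in% c(0, 1))
  if (!main %in% object$fixed_names) stop("term not in fit: ", main)
  ia <- c(paste0(main, ":", modifier), paste0(modifier, ":", main))
  ia <- ia[ia %in% object$fixed_names]
  if (length(ia) == 0L) {
    d <- object$draws[, main]
    note <- sprintf("no %s x %s interaction in the fit; returning the main effect",
                    main, modifier)
  } else {
    d <- object$draws[, main] + level * object$draws[, ia[1]]
    note <- NULL
  }
  q <- unname(stats::quantile(d, c(0.025, 0.975)))
  out <- list(estimate = mean(d), lower = q[1], upper = q[2], level = level)
  if (!is.null(note)) out$note <- note
  out
}

#' @rdname stratum_effect
#' @export
stratum_effect.numeric <- function(object, level, ...) {
  stopifnot(level %in% c(0, 1))
  if (!all(c("main", "interaction") %in% names(object))) {
    stop("numeric input must be named c(main = ..., interaction = ...)")
  }
  list(estimate = unname(object["main"] + level * object["interaction"]),
       lower = NA_real_, upper = NA_real_, level = level)
}

#' Write a posterior summary as TSV
#'
#' Columns mirror the usual reporting layout: term, estimate, est. error,
#' CI bounds, Rhat, ESS, significance.
#'
#' @param summary data.frame from [summarize_fit()].
#' @param path output file.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
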