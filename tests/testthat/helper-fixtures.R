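# toy fixtures and independent brute-force oracles used across the suite

toy_asv <- function() {
  m <- matrix(c(5, 0, 3,
                0, 2, 4,
                1, 1, 0,
                8, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("asv", 1:3)))
  asv_table(m, "counts")
}

toy_tax <- function() {
  data.frame(asv_id = paste0("asv", 1:3),
             kingdom = "Bacteria",
             phylum = c("Bacteroidota", "Cyanobacteria", "Bacillota"),
             class = NA, order = NA,
             family = c("Muribaculaceae", NA, "Lachnospiraceae"),
             genus = NA, stringsAsFactors = FALSE)
}

# five individuals: mother M1 with offspring o1 (sire F1) and o2 (sire
# unknown), plus the sire F1 and an unrelated u1
toy_pedigree <- function() {
  pedigree_table(data.frame(
    individual_id = c("M1", "F1", "o1", "o2", "u1"),
    mother_id = c(NA, NA, "M1", "M1", NA),
    father_id = c(NA, NA, "F1", NA, NA),
    sex = c("F", "M", "F", "M", "F"),
    stringsAsFactors = FALSE))
}

# --- independent oracles (naive set / arithmetic implementations) ---

bf_jaccard <- function(a, b) {
  pa <- which(a > 0)
  pb <- which(b > 0)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

bf_braycurtis <- function(a, b) {
  1 - sum(abs(a - b)) / sum(a + b)
}

# night-by-night tally of the adjusted SRI
bf_sri <- function(records, a, b) {
  ra <- records[records$individual_id == a, ]
  rb <- records[records$individual_id == b, ]
  lo <- max(min(ra$night), min(rb$night))
  hi <- min(max(ra$night), max(rb$night))
  if (lo > hi) return(0)
  x <- 0; d <- 0
  for (night in lo:hi) {
    la <- ra$location_id[ra$night == night]
    lb <- rb$location_id[rb$night == night]
    if (length(la) || length(lb)) d <- d + 1
    if (length(intersect(la, lb))) x <- x + 1
  }
  if (d == 0) 0 else x / d
}

# exhaustive-permutation Mantel p by direct enumeration (independent of the
# package's recursion: builds permutations via expand.grid filtering)
bf_mantel_exact <- function(m1, m2) {
  n <- nrow(m1)
  idx_all <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  idx_all <- idx_all[apply(idx_all, 1, function(r) !anyDuplicated(r)), ,
                     drop = FALSE]
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt])
  r_all <- apply(idx_all, 1, function(idx) cor(m1[lt], m2[idx, idx][lt]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

random_records <- function(n_ind = 10, n_nights = 30, n_loc = 4, p = 0.5) {
  ids <- sprintf("i%02d", seq_len(n_ind))
  out <- expand.grid(individual_id = ids, night = seq_len(n_nights),
                     stringsAsFactors = FALSE)
  out <- out[runif(nrow(out)) < p, ]
  out$location_id <- sample(sprintf("L%d", seq_len(n_loc)), nrow(out),
                            replace = TRUE)
  out$x <- as.numeric(factor(out$location_id))
  out$y <- 0
  out[c("individual_id", "location_id", "x", "y", "night")]
}

# dyad rows generated directly from the model likelihood (ground truth for
# parameter-recovery tests)
make_mm_rows <- function(n_ind = 30, samples_each = 2, beta = c(-1, 0.4),
                        sigma_ind = 0.1, sigma_samp = 0.1, phi = 50,
                        seed = 1, pair_covariate = FALSE) {
  set.seed(seed)
  ind <- sprintf("i%02d", seq_len(n_ind))
  n_samp <- n_ind * samples_each
  samp <- sprintf("s%03d", seq_len(n_samp))
  samp_ind <- rep(ind, each = samples_each)
  pr <- t(combn(n_samp, 2))
  pr <- pr[samp_ind[pr[, 1]] != samp_ind[pr[, 2]], , drop = FALSE]
  if (pair_covariate) {
    key <- paste(pmin(samp_ind[pr[, 1]], samp_ind[pr[, 2]]),
                 pmax(samp_ind[pr[, 1]], samp_ind[pr[, 2]]))
    x_pair <- rnorm(length(unique(key)))
    names(x_pair) <- unique(key)
    x <- unname(x_pair[key])
  } else {
    x <- rnorm(nrow(pr))
  }
  u <- rnorm(n_ind, 0, sigma_ind)
  names(u) <- ind
  w <- rnorm(n_samp, 0, sigma_samp)
  names(w) <- samp
  rows <- data.frame(
    sample_a = samp[pr[, 1]], sample_b = samp[pr[, 2]],
    individual_a = samp_ind[pr[, 1]], individual_b = samp_ind[pr[, 2]],
    sri = x, stringsAsFactors = FALSE)
  eta <- beta[1] + beta[2] * x + u[rows$individual_a] + u[rows$individual_b] +
    w[rows$sample_a] + w[rows$sample_b]
  mu <- plogis(eta)
  rows$jaccard <- pmin(pmax(rbeta(nrow(rows), mu * phi, (1 - mu) * phi),
                            1e-9), 1 - 1e-9)
  rows
}

# fast sampler preset for unit tests (not the analysis presets)
tiny_settings <- function(seed = 1) {
  mm_settings(chains = 2, warmup = 250, iter = 250, max_leapfrog = 8,
              seed = seed)
}
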