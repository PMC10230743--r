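#' Parameters of the synthetic transmission study
#'
#' Bundles everything the generator needs to build a complete synthetic
#' study: a population with a mother-offspring pedigree, nightly logger
#' co-detections on a grid of stations, and an ASV table whose
#' presence-absence structure carries *planted* maternal and social
#' transmission effects. Defaults emulate a small woodland rodent study:
#' ~70 individuals monitored with 9 loggers over 120 nights in a ~150 m
#' arena, 3 faecal samples each, and an ASV table organised into bacterial
#' families with one designated high-transmission (focal) family.
#'
#' The planted generative model for ASV `j` (family `f`) in a sample of
#' individual `i` at age class `a` is
#' `P(present) = plogis(alpha_j + B_mat(a, f) * M_ij + beta_soc * S_ij)`,
#' where `alpha_j ~ Normal(baseline_logit_mean, baseline_logit_sd)`;
#' `M_ij = 1` iff `i`'s mother carries `j` in her repertoire;
#' `B_mat(a, f) = beta_mat * (1 if a == "immature" else adult_decay) *
#' (1 + focal_family_boost * [f == focal family])`; and `S_ij` is the
#' SRI-weighted carrier prevalence of `j` among `i`'s contacts.
#'
#' @param n_individuals,n_mothers population size and number of breeding
#'   females (each mother gets at least one offspring; `n_mothers = 0`
#'   yields a population without mother-offspring dyads).
#' @param litter_size_mean mean litter size; litters are
#'   `1 + Poisson(litter_size_mean - 1)`.
#' @param n_families,asvs_per_family_mean gut bacterial families and mean
#'   ASV count per family (`1 + Poisson(mean - 1)`).
#' @param baseline_logit_mean,baseline_logit_sd distribution of per-ASV
#'   baseline presence log-odds.
#' @param beta_mat logit-scale presence boost for maternally available
#'   ASVs.
#' @param focal_family_boost extra multiplicative maternal boost for the
#'   focal family (`beta_mat * (1 + focal_family_boost)` when immature).
#' @param beta_soc logit-scale coefficient on SRI-weighted contact carrier
#'   prevalence.
#' @param adult_decay multiplier in [0, 1] on `beta_mat` once the offspring
#'   is adult (0 = maternal signal vanishes in adulthood).
#' @param n_nights,n_loggers,arena_size,detection_rate logger design:
#'   nights of monitoring, stations on a regular grid, square arena side
#'   (metres), nightly per-individual detection probability in (0, 1].
#' @param samples_per_individual mean faecal samples per individual; a
#'   fractional value `k + f` gives each individual `k` or `k + 1` samples
#'   (probability `f` of the extra one).
#' @param reads_per_sample multinomial read depth per sample.
#' @param p_young probability that a non-breeding, non-offspring individual
#'   enters the study young (first sample immature).
#' @param n_contaminant_asvs non-gut ASVs (Cyanobacteria / Mitochondria)
#'   added to exercise the contaminant filter.
#' @param study_days length of the sampling calendar.
#' @param seed integer seed; every generator stage derives its stream from
#'   it, so a study is bit-reproducible.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_individuals = 70, n_mothers = 6,
                       litter_size_mean = 3, n_families = 15,
                       asvs_per_family_mean = 12,
                       baseline_logit_mean = -2, baseline_logit_sd = 1.25,
                       beta_mat = 1.5, focal_family_boost = 1,
                       beta_soc = 1.5, adult_decay = 0.25,
                       n_nights = 120, n_loggers = 9, arena_size = 150,
                       detection_rate = 0.4, samples_per_individual = 3,
                       reads_per_sample = 10000, p_young = 0.25,
                       n_contaminant_asvs = 4, study_days = 360,
                       seed = 1) {
  p <- as.list(environment())
  counts <- c("n_individuals", "n_families", "n_nights",
              "n_loggers", "samples_per_individual", "reads_per_sample",
              "study_days")
  if (p$n_mothers < 0) stop("n_mothers must be >= 0")
  for (k in counts) {
    if (p[[k]] < 1) stop("count parameter must be >= 1: ", k)
  }
  if (p$adult_decay < 0 || p$adult_decay > 1) stop("adult_decay must be in [0, 1]")
  if (p$detection_rate <= 0 || p$detection_rate > 1) {
    stop("detection_rate must be in (0, 1]")
  }
  if (p$litter_size_mean < 1) stop("litter_size_mean must be >= 1")
  if (p$asvs_per_family_mean < 1) stop("asvs_per_family_mean must be >= 1")
  if (p$n_mothers > p$n_individuals) stop("more mothers than individuals")
  if (p$p_young < 0 || p$p_young > 1) stop("p_young must be in [0, 1]")
  p$seed <- as.integer(p$seed)
  structure(p, class = "sim_params")
}

#' Simulate the study population
#'
#' Draws a population of individuals with sexes, a mother-offspring
#' pedigree (each of `n_mothers` females gets a litter of
#' `1 + Poisson(litter_size_mean - 1)` offspring; each litter is sired by
#' one male, so full- and paternal-half-siblings arise), spatial home
#' centres inside the arena (offspring settle near their mother), and
#' per-individual sampling occasions with calendar days and age classes.
#' Offspring are sampled immature for the first half of their occasions
#' and adult afterwards; mothers are always sampled adult.
#'
#' @param params a [sim_params()].
#' @return A `population_truth` list: `individuals` (id, sex, mother_id,
#'   father_id, home_x, home_y, role), `occasions` (individual_id, day,
#'   age_class), `effects` (the planted beta_mat, beta_soc, adult_decay,
#'   focal_family_boost), `params`.
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_individuals
  ids <- sprintf("ind%03d", seq_len(n))
  mothers <- ids[seq_len(params$n_mothers)]
  litters <- 1 + stats::rpois(params$n_mothers, params$litter_size_mean - 1)
  n_off <- sum(litters)
  if (params$n_mothers + n_off > n) {
    stop(sprintf(paste0("litter sizes imply %d mothers + %d offspring > ",
                        "%d individuals; increase n_individuals or reduce ",
                        "litter_size_mean"),
                 params$n_mothers, n_off, n))
  }
  offspring <- ids[params$n_mothers + seq_len(n_off)]
  others <- setdiff(ids, c(mothers, offspring))
  mother_of <- rep(mothers, times = litters)

  sex <- character(n)
  names(sex) <- ids
  sex[mothers] <- "F"
  sex[c(offspring, others)] <- sample(c("F", "M"),
                                      length(c(offspring, others)),
                                      replace = TRUE)
  # make sure some adult males exist to sire litters
  males <- others[sex[others] == "M"]
  father_of <- rep(NA_character_, n_off)
  if (length(males) > 0) {
    litter_sires <- sample(males, params$n_mothers, replace = TRUE)
    father_of <- rep(litter_sires, times = litters)
  }

  home <- matrix(stats::runif(2 * n, 0, params$arena_size), n, 2)
  rownames(home) <- ids
  # offspring settle near the maternal home range
  disp <- matrix(stats::rnorm(2 * n_off, 0, params$arena_size / 10), n_off, 2)
  home[offspring, ] <- pmin(pmax(home[mother_of, , drop = FALSE] + disp, 0),
                            params$arena_size)

  individuals <- data.frame(
    individual_id = ids, sex = unname(sex[ids]),
    mother_id = NA_character_, father_id = NA_character_,
    home_x = home[, 1], home_y = home[, 2],
    role = "other", stringsAsFactors = FALSE, row.names = NULL)
  individuals$role[match(mothers, ids)] <- "mother"
  oi <- match(offspring, ids)
  individuals$role[oi] <- "offspring"
  individuals$mother_id[oi] <- mother_of
  individuals$father_id[oi] <- father_of

  spi <- params$samples_per_individual
  young_other <- others[stats::runif(length(others)) < params$p_young]
  occ <- do.call(rbind, lapply(ids, function(id) {
    s <- floor(spi) + (stats::runif(1) < (spi - floor(spi)))
    days <- sort(sample.int(params$study_days, s))
    age <- rep("adult", s)
    if (id %in% offspring) {
      age[seq_len(ceiling(s / 2))] <- "immature"
    } else if (id %in% young_other) {
      age[1] <- "immature"
    }
    data.frame(individual_id = id, day = days, age_class = age,
               stringsAsFactors = FALSE)
  }))
  occ$sample_id <- sprintf("%s_s%d", occ$individual_id,
                           stats::ave(seq_len(nrow(occ)), occ$individual_id,
                                      FUN = seq_along))
  structure(list(individuals = individuals, occasions = occ,
                 effects = list(beta_mat = params$beta_mat,
                                beta_soc = params$beta_soc,
                                adult_decay = params$adult_decay,
                                focal_family_boost = params$focal_family_boost),
                 params = params),
            class = "population_truth")
}

#' Simulate nightly logger detections
#'
#' Stations sit on a regular grid across the arena. Each night every
#' individual is detected with probability `detection_rate`; a detected
#' individual is recorded at one station chosen with probability
#' proportional to `exp(-d^2 / (2 * (arena_size / 8)^2))`, `d` being the
#' distance from its home centre, so neighbours share stations and
#' co-detection falls off with home-centre distance.
#'
#' @param pop a `population_truth`.
#' @param params the same [sim_params()].
#' @return data.frame of logger records (`individual_id`, `location_id`,
#'   `x`, `y`, `night`).
#' @export
simulate_logger_records <- function(pop, params) {
  stopifnot(inherits(pop, "population_truth"),
            inherits(params, "sim_params"))
  set.seed(params$seed + 1L)
  g <- ceiling(sqrt(params$n_loggers))
  pts <- expand.grid(gx = seq_len(g), gy = seq_len(g))[seq_len(params$n_loggers), ]
  lx <- (pts$gx - 0.5) / g * params$arena_size
  ly <- (pts$gy - 0.5) / g * params$arena_size
  loc_id <- sprintf("L%02d", seq_len(params$n_loggers))

  ind <- pop$individuals
  sig <- params$arena_size / 8
  # per-individual station choice probabilities
  probs <- do.call(rbind, lapply(seq_len(nrow(ind)), function(i) {
    d2 <- (ind$home_x[i] - lx)^2 + (ind$home_y[i] - ly)^2
    w <- exp(-d2 / (2 * sig^2))
    if (sum(w) == 0) w <- rep(1, length(lx))
    w / sum(w)
  }))

  out <- vector("list", params$n_nights)
  for (night in seq_len(params$n_nights)) {
    det <- stats::runif(nrow(ind)) < params$detection_rate
    if (!any(det)) next
    who <- which(det)
    st <- vapply(who, function(i) {
      sample.int(params$n_loggers, 1L, prob = probs[i, ])
    }, 0L)
    out[[night]] <- data.frame(individual_id = ind$individual_id[who],
                               location_id = loc_id[st],
                               x = lx[st], y = ly[st], night = night,
                               stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rownames(rec) <- NULL
  rec
}

# realistic mouse-gut family pool; first entry is the focal
# (high-maternal-transmission) family
.family_pool <- c("Muribaculaceae", "Lachnospiraceae", "Ruminococcaceae",
                  "Bacteroidaceae", "Prevotellaceae", "Lactobacillaceae",
                  "Oscillospiraceae", "Rikenellaceae",
                  "Erysipelotrichaceae", "Akkermansiaceae",
                  "Bifidobacteriaceae", "Tannerellaceae", "Clostridiaceae",
                  "Sutterellaceae", "Desulfovibrionaceae",
                  "Eggerthellaceae", "Marinifilaceae", "Anaeroplasmataceae",
                  "Deferribacteraceae", "Streptococcaceae")

#' Simulate the ASV table and taxonomy with planted transmission effects
#'
#' Implements the generative presence model of [sim_params()]. Maternal
#' availability `M_ij` comes from the mother's *repertoire*, the union of
#' ASVs present across her own (previously generated) samples; mothers'
#' samples are generated first so the repertoire is fixed before any
#' offspring sample. Social exposure `S_ij` is the SRI-weighted fraction of
#' an individual's contacts carrying `j`, where a contact's carrier status
#' is read from its most recent earlier sample, falling back to a latent
#' baseline repertoire drawn from `plogis(alpha_j)`. Abundances of present
#' ASVs are symmetric-Dirichlet weights scaled to `reads_per_sample`
#' multinomial counts. A few contaminant ASVs (Cyanobacteria,
#' Mitochondria) are appended outside the transmission model.
#'
#' @param pop a `population_truth`.
#' @param sri adjusted SRI matrix covering every individual in `pop`.
#' @param params the same [sim_params()].
#' @return list: `asv` (counts-mode [asv_table], samples x ASVs),
#'   `taxonomy` (data.frame), `meta` (sample metadata, [sample_meta()]),
#'   `truth` (planted parameters incl. `focal_family`).
#' @export
simulate_microbiota <- function(pop, sri, params) {
  stopifnot(inherits(pop, "population_truth"),
            inherits(params, "sim_params"))
  ind <- pop$individuals
  missing <- setdiff(ind$individual_id, rownames(sri))
  if (length(missing)) {
    stop("individuals missing from the SRI matrix: ",
         paste(missing, collapse = ", "))
  }
  set.seed(params$seed + 2L)

  fam_names <- .family_pool
  if (params$n_families > length(fam_names)) {
    fam_names <- c(fam_names, sprintf("Family%03d",
                                      seq_len(params$n_families - length(fam_names))))
  }
  fam_names <- fam_names[seq_len(params$n_families)]
  focal_family <- fam_names[1]
  n_per_fam <- 1 + stats::rpois(params$n_families,
                                params$asvs_per_family_mean - 1)
  fam_of <- rep(fam_names, times = n_per_fam)
  n_gut <- length(fam_of)
  n_cont <- params$n_contaminant_asvs
  n_asv <- n_gut + n_cont
  asv_ids <- sprintf("ASV%04d", seq_len(n_asv))

  taxonomy <- data.frame(
    asv_id = asv_ids,
    kingdom = "Bacteria",
    phylum = c(ifelse(fam_of %in% c("Muribaculaceae", "Bacteroidaceae",
                                    "Prevotellaceae", "Rikenellaceae",
                                    "Tannerellaceae", "Marinifilaceae"),
                      "Bacteroidota", "Bacillota"),
               rep("", n_cont)),
    class = NA_character_, order = NA_character_,
    family = c(fam_of, rep("", n_cont)),
    genus = NA_character_, stringsAsFactors = FALSE)
  if (n_cont > 0) {
    half <- ceiling(n_cont / 2)
    taxonomy$phylum[n_gut + seq_len(half)] <- "Cyanobacteria"
    taxonomy$family[n_gut + setdiff(seq_len(n_cont), seq_len(half))] <-
      "Mitochondria"
  }
  taxonomy$family[!nzchar(taxonomy$family)] <- NA
  taxonomy$phylum[!nzchar(taxonomy$phylum)] <- NA

  alpha <- stats::rnorm(n_asv, params$baseline_logit_mean,
                        params$baseline_logit_sd)
  is_focal <- c(fam_of == focal_family, rep(FALSE, n_cont))
  ids <- ind$individual_id
  # latent fallback repertoires (carrier status before any sample exists)
  base_rep <- matrix(stats::runif(length(ids) * n_asv) <
                       rep(stats::plogis(alpha), each = length(ids)),
                     nrow = length(ids), dimnames = list(ids, asv_ids))

  occ <- pop$occasions
  mother_of <- stats::setNames(ind$mother_id, ind$individual_id)
  is_mother <- ind$role == "mother"
  # mothers' samples first (repertoire fixed before offspring sampling),
  # then everyone else in calendar order
  occ$is_mother <- is_mother[match(occ$individual_id, ids)]
  occ <- occ[order(!occ$is_mother, occ$day, occ$sample_id), ]

  counts <- matrix(0L, nrow(occ), n_asv,
                   dimnames = list(occ$sample_id, asv_ids))
  presence_hist <- list()  # per individual: list of (day, logical vector)
  mother_repertoire <- list()

  sri_w <- sri[ids, ids, drop = FALSE]
  diag(sri_w) <- 0
  gut_idx <- seq_len(n_gut)

  for (r in seq_len(nrow(occ))) {
    i <- occ$individual_id[r]
    a <- occ$age_class[r]
    day <- occ$day[r]

    M <- rep(0, n_asv)
    mum <- mother_of[i]
    if (!is.na(mum) && !is.null(mother_repertoire[[mum]])) {
      M <- as.numeric(mother_repertoire[[mum]])
    }
    w <- sri_w[i, ]
    contacts <- ids[w > 0]
    S <- rep(0, n_asv)
    if (length(contacts)) {
      carriers <- vapply(contacts, function(k) {
        h <- presence_hist[[k]]
        if (!is.null(h)) {
          dd <- vapply(h, `[[`, 0, "day")
          ok <- which(dd < day)
          if (length(ok)) return(h[[ok[which.max(dd[ok])]]]$pres)
        }
        base_rep[k, ]
      }, logical(n_asv))
      S <- as.numeric(carriers %*% w[contacts]) / sum(w[contacts])
    }
    b_mat <- params$beta_mat * (if (a == "immature") 1 else params$adult_decay) *
      (1 + params$focal_family_boost * is_focal)
    eta <- alpha + b_mat * M + params$beta_soc * S
    # contaminants sit outside the transmission model
    eta[-gut_idx] <- alpha[-gut_idx]
    pres <- stats::runif(n_asv) < stats::plogis(eta)
    if (any(pres)) {
      wts <- stats::rgamma(sum(pres), shape = 1)
      counts[r, pres] <- stats::rmultinom(1, params$reads_per_sample,
                                          wts / sum(wts))[, 1]
    }
    presence_hist[[i]] <- c(presence_hist[[i]],
                            list(list(day = day, pres = pres)))
    if (is_mother[match(i, ids)]) {
      prev <- mother_repertoire[[i]]
      mother_repertoire[[i]] <- if (is.null(prev)) pres else prev | pres
    }
  }

  meta <- data.frame(sample_id = occ$sample_id,
                     individual_id = occ$individual_id,
                     date = occ$day, age_class = occ$age_class,
                     sex = ind$sex[match(occ$individual_id, ids)],
                     stringsAsFactors = FALSE)
  meta <- meta[order(meta$sample_id), ]
  rownames(meta) <- NULL
  counts <- counts[meta$sample_id, , drop = FALSE]

  list(asv = asv_table(counts, "counts"), taxonomy = taxonomy,
       meta = sample_meta(meta),
       truth = c(pop$effects, list(focal_family = focal_family,
                                   alpha = alpha, seed = params$seed)))
}

#' Generate a complete synthetic study
#'
#' Runs the full generator: population and pedigree, logger records,
#' adjusted SRI matrix and spatial centroids, then the microbiota with
#' planted effects. Bit-reproducible given `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list: `params`, `population`, `pedigree` (a `pedigree_table`),
#'   `logger`, `sri`, `centroids`, `asv`, `taxonomy`, `meta`, `truth`.
#' @export
simulate_study <- function(params = sim_params()) {
  pop <- simulate_population(params)
  logger <- simulate_logger_records(pop, params)
  # individuals never detected get no SRI/centroid; extremely unlikely at
  # default detection_rate, but guard by resampling absent ones at their
  # nearest station on night 1
  absent <- setdiff(pop$individuals$individual_id, logger$individual_id)
  if (length(absent)) {
    add <- data.frame(individual_id = absent,
                      location_id = logger$location_id[1],
                      x = logger$x[1], y = logger$y[1], night = 1L,
                      stringsAsFactors = FALSE)
    logger <- rbind(logger, add)
  }
  sri <- sri_matrix(logger, pop$individuals$individual_id)
  centroids <- spatial_centroids(logger)
  micro <- simulate_microbiota(pop, sri, params)
  ped <- pedigree_table(pop$individuals[c("individual_id", "mother_id",
                                          "father_id", "sex")])
  list(params = params, population = pop, pedigree = ped, logger = logger,
       sri = sri, centroids = centroids, asv = micro$asv,
       taxonomy = micro$taxonomy, meta = micro$meta, truth = micro$truth)
}

#' Write a synthetic study as the pipeline's five standard input files
#'
#' Writes `asv.tsv`, `taxonomy.tsv`, `metadata.csv`, `pedigree.csv`,
#' `logger.csv` and `truth.json` (the planted parameters) into `dir`.
#'
#' @param study output of [simulate_study()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_tsv(study$asv, file.path(dir, "asv.tsv"))
  write_taxonomy_tsv(study$taxonomy, file.path(dir, "taxonomy.tsv"))
  utils::write.csv(study$meta[c("sample_id", "individual_id", "date",
                                "age_class", "sex")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(study$pedigree),
                   file.path(dir, "pedigree.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(study$logger, file.path(dir, "logger.csv"),
                   row.names = FALSE)
  truth <- study$truth
  truth$alpha <- NULL  # per-ASV baselines are large; keep the file small
  truth <- c(truth, study$params[c("beta_mat", "beta_soc", "adult_decay",
                                   "focal_family_boost", "seed")])
  truth <- truth[!duplicated(names(truth))]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
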