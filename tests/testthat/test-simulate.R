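small_params <- function(...) {
  base <- list(n_individuals = 24, n_mothers = 3, litter_size_mean = 2,
               n_families = 6, asvs_per_family_mean = 8, n_nights = 40,
               samples_per_individual = 2, reads_per_sample = 2000)
  do.call(sim_params, utils::modifyList(base, list(...)))
}

test_that("parameter validation enforces the documented ranges", {
  expect_error(sim_params(detection_rate = 0), "detection_rate")
  expect_error(sim_params(adult_decay = 1.5), "adult_decay")
  expect_error(sim_params(n_individuals = 0), "n_individuals")
  expect_error(sim_params(n_mothers = -1), "n_mothers")
  expect_error(sim_params(litter_size_mean = 0.5), "litter_size_mean")
  expect_silent(sim_params(n_mothers = 0))
})

test_that("seeded population simulation is deterministic", {
  p <- small_params(seed = 7)
  expect_identical(simulate_population(p), simulate_population(p))
  p2 <- small_params(seed = 8)
  expect_false(identical(simulate_population(p)$individuals,
                         simulate_population(p2)$individuals))
})

test_that("a full seeded study is bit-reproducible end to end", {
  p <- small_params(seed = 19)
  s1 <- simulate_study(p)
  s2 <- simulate_study(p)
  expect_identical(unclass(s1$asv), unclass(s2$asv))
  expect_identical(s1$sri, s2$sri)
  expect_identical(s1$logger, s2$logger)
  expect_identical(s1$meta, s2$meta)
})

test_that("populations honour pedigree and age-class invariants", {
  pop <- simulate_population(small_params(seed = 3))
  ind <- pop$individuals
  mothers <- ind$individual_id[ind$role == "mother"]
  # every mother has >= 1 offspring and is female
  kids <- table(ind$mother_id[!is.na(ind$mother_id)])
  expect_setequal(names(kids), mothers)
  expect_true(all(kids >= 1))
  expect_true(all(ind$sex[match(mothers, ind$individual_id)] == "F"))
  # home centres inside the arena
  expect_true(all(ind$home_x >= 0 & ind$home_x <= 150))
  expect_true(all(ind$home_y >= 0 & ind$home_y <= 150))
  # immature occasions precede adult occasions for every individual
  occ <- pop$occasions
  for (id in unique(occ$individual_id)) {
    o <- occ[occ$individual_id == id, ]
    o <- o[order(o$day), ]
    expect_true(!is.unsorted(rev(o$age_class)))  # immature < adult reversed
  }
})

test_that("no mothers means no mother-offspring dyads downstream", {
  pop <- simulate_population(small_params(n_mothers = 0, seed = 5))
  expect_true(all(is.na(pop$individuals$mother_id)))
})

test_that("excessive litters for the population size are a parameter error", {
  p <- sim_params(n_individuals = 8, n_mothers = 5, litter_size_mean = 4,
                  seed = 1)
  expect_error(simulate_population(p), "litter sizes imply")
})

test_that("realised offspring counts match the litter distribution in expectation", {
  # 6 mothers x mean litter 3 -> 18 expected offspring
  offs <- vapply(1:200, function(s) {
    pop <- simulate_population(sim_params(n_individuals = 60, n_mothers = 6,
                                          litter_size_mean = 3, seed = s))
    sum(!is.na(pop$individuals$mother_id))
  }, 0)
  # SE of the mean ~ sqrt(6 * 2 / 200) = 0.24
  expect_equal(mean(offs), 18, tolerance = 0.05)
})

test_that("logger detections follow the detection design", {
  p <- small_params(detection_rate = 1, n_loggers = 1, seed = 2)
  pop <- simulate_population(p)
  rec <- simulate_logger_records(pop, p)
  # one logger, certain detection: everyone every night at that station
  expect_equal(nrow(rec), 24 * 40)
  expect_equal(unique(rec$location_id), "L01")
  sri <- sri_matrix(rec)
  expect_true(all(sri == 1))
})

test_that("co-detection falls off with home-centre distance", {
  cors <- vapply(1:50, function(s) {
    p <- sim_params(n_individuals = 16, n_mothers = 0, n_nights = 30,
                    n_loggers = 9, detection_rate = 0.8, seed = s)
    pop <- simulate_population(p)
    rec <- simulate_logger_records(pop, p)
    sri <- sri_matrix(rec, pop$individuals$individual_id)
    d <- as.matrix(dist(pop$individuals[c("home_x", "home_y")]))
    lt <- lower.tri(d)
    suppressWarnings(cor(d[lt], sri[lt], method = "spearman"))
  }, 0)
  expect_lt(mean(cors, na.rm = TRUE), -0.3)
})

test_that("null transmission effects leave mother-offspring dyads unremarkable", {
  p <- small_params(beta_mat = 0, beta_soc = 0, focal_family_boost = 0,
                    n_individuals = 40, n_mothers = 6, seed = 31)
  study <- simulate_study(p)
  jac <- similarity_matrix(preprocess_asv(study$asv, study$taxonomy),
                           "jaccard")
  rows <- build_dyads(study$meta, jac, study$sri, study$centroids,
                      study$pedigree)
  mo <- rows$jaccard[rows$mo_status == 1]
  non <- rows$jaccard[rows$mo_status == 0]
  obs <- mean(mo) - mean(non)
  # two-sided permutation test on the dyad labels
  set.seed(1)
  pool <- c(mo, non)
  null <- vapply(1:499, function(i) {
    idx <- sample(length(pool), length(mo))
    mean(pool[idx]) - mean(pool[-idx])
  }, 0)
  p_perm <- (1 + sum(abs(null) >= abs(obs))) / 500
  expect_gt(p_perm, 0.01)
})

test_that("maternal effects concentrate in immature offspring samples when decay is total", {
  excess <- t(vapply(1:20, function(s) {
    p <- small_params(beta_mat = 2, beta_soc = 0, adult_decay = 0,
                      n_individuals = 30, n_mothers = 5,
                      samples_per_individual = 2, p_young = 0, seed = 100 + s)
    study <- simulate_study(p)
    jac <- similarity_matrix(preprocess_asv(study$asv, study$taxonomy),
                             "jaccard")
    rows <- build_dyads(study$meta, jac, study$sri, study$centroids,
                        study$pedigree)
    age <- setNames(study$meta$age_class, study$meta$sample_id)
    imm <- age[rows$sample_a] == "immature" | age[rows$sample_b] == "immature"
    mo <- rows$mo_status == 1
    c(imm = mean(rows$jaccard[mo & imm]) - mean(rows$jaccard[!mo & imm]),
      adult = mean(rows$jaccard[mo & !imm]) - mean(rows$jaccard[!mo & !imm]))
  }, c(imm = 0, adult = 0)))
  expect_gt(mean(excess[, "imm"]), 0.02)
  expect_lt(abs(mean(excess[, "adult"])), 0.02)
  expect_gt(mean(excess[, "imm"]), mean(excess[, "adult"]) + 0.02)
})

test_that("the focal family dominates joint mother-offspring sharing when boosted", {
  # per family, the richness-relative excess of jointly-present ASVs in
  # mother-offspring sample pairs over background pairs, aggregated over
  # replicate studies (single studies have ~50 MO pairs and are noisy)
  excess_one <- function(seed) {
    p <- small_params(beta_mat = 1.5, focal_family_boost = 4, beta_soc = 0,
                      n_individuals = 30, n_mothers = 6, seed = seed)
    study <- simulate_study(p)
    tax <- study$taxonomy
    pres <- unclass(study$asv) > 0
    ped <- study$pedigree
    meta <- study$meta
    fams <- setdiff(unique(tax$family), NA)
    mo_sum <- setNames(numeric(length(fams)), fams)
    bg_sum <- mo_sum
    mo_n <- 0; bg_n <- 0
    for (i in seq_len(nrow(meta) - 1)) {
      for (j in (i + 1):nrow(meta)) {
        a <- meta$individual_id[i]; b <- meta$individual_id[j]
        if (a == b) next
        joint <- pres[i, ] & pres[j, ]
        is_mo <- mother_offspring(ped, a, b) == 1
        per_fam <- vapply(fams, function(f)
          sum(joint[tax$asv_id[tax$family %in% f]]), 0)
        if (is_mo) { mo_sum <- mo_sum + per_fam; mo_n <- mo_n + 1 }
        else { bg_sum <- bg_sum + per_fam; bg_n <- bg_n + 1 }
      }
    }
    (mo_sum / mo_n - bg_sum / bg_n) / as.numeric(table(tax$family)[fams])
  }
  total <- Reduce(`+`, lapply(c(11, 21, 31, 41, 51), excess_one))
  expect_identical(names(which.max(total)), "Muribaculaceae")
})

test_that("stronger social transmission raises similarity of well-associated dyads", {
  gap <- vapply(c(0, 3), function(bs) {
    mean(vapply(1:6, function(s) {
      p <- small_params(beta_mat = 0, beta_soc = bs, n_individuals = 30,
                        n_mothers = 0, detection_rate = 0.6, seed = 400 + s)
      study <- simulate_study(p)
      jac <- similarity_matrix(preprocess_asv(study$asv, study$taxonomy),
                               "jaccard")
      rows <- build_dyads(study$meta, jac, study$sri, study$centroids,
                          study$pedigree)
      hi <- rows$sri >= quantile(rows$sri, 0.75)
      lo <- rows$sri == 0
      mean(rows$jaccard[hi]) - mean(rows$jaccard[lo])
    }, 0))
  }, 0)
  expect_gt(gap[2], gap[1])
  expect_gt(gap[2], 0)
})

test_that("individuals missing from the SRI matrix are reported by name", {
  p <- small_params(seed = 2)
  pop <- simulate_population(p)
  rec <- simulate_logger_records(pop, p)
  sri <- sri_matrix(rec, pop$individuals$individual_id)
  bad <- sri[-1, -1]
  expect_error(simulate_microbiota(pop, bad, p),
               pop$individuals$individual_id[1])
})

test_that("write_study produces the five standard inputs plus the truth file", {
  study <- simulate_study(small_params(seed = 23))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_setequal(list.files(dir),
                  c("asv.tsv", "taxonomy.tsv", "metadata.csv",
                    "pedigree.csv", "logger.csv", "truth.json"))
  back <- read_asv_tsv(file.path(dir, "asv.tsv"))
  expect_equal(unclass(back), unclass(study$asv))
  ped <- read_pedigree_csv(file.path(dir, "pedigree.csv"))
  expect_identical(ped$mother_id, study$pedigree$mother_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$beta_mat, study$params$beta_mat)
  expect_identical(truth$focal_family, "Muribaculaceae")
})
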