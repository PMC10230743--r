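#' Run the dyadic transmission pipeline end to end
#'
#' Orchestrates the full analysis from a YAML (or list) configuration:
#' input loading (or synthetic-study generation), ASV pre-processing,
#' similarity matrices, adjusted SRI network, dyad assembly and filtering,
#' the Beta multi-membership model fit with convergence check, and
#' optionally the Mantel confound check and the family-exclusion scan. All
#' artefacts are written to `output_dir` together with a machine-readable
#' `provenance.json` (config hash, seeds, package version, filter log).
#'
#' Config keys:
#' \describe{
#'   \item{simulate}{list of [sim_params()] arguments; mutually exclusive
#'     with `inputs`.}
#'   \item{inputs}{list of paths: `asv`, `taxonomy`, `metadata`,
#'     `pedigree`, `logger`. `asv` may be TSV or BIOM (`.biom`).}
#'   \item{metric}{`"jaccard"` (default) or `"braycurtis"` — response
#'     metric for the model.}
#'   \item{model}{[model_spec()] arguments (optional).}
#'   \item{sampler}{[mm_settings()] arguments (optional).}
#'   \item{scan}{logical; run the family-exclusion scan (default FALSE).}
#'   \item{mantel}{logical; Mantel test of mother-offspring status vs SRI
#'     (default TRUE).}
#'   \item{output_dir}{artefact directory.}
#' }
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param output_dir overrides `config$output_dir` when given.
#' @return Invisibly, a list with the main in-memory results (`fit`,
#'   `summary`, `report`, `convergence`, and `mantel`/`scan` when run);
#'   artefacts on disk in the output directory.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  metric <- config$metric %||% "jaccard"
  if (!metric %in% c("jaccard", "braycurtis")) {
    stop("unknown metric label: ", metric)
  }
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("config must name an output_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$simulate) && !is.null(config$inputs)) {
    stop("config must give either `simulate` or `inputs`, not both")
  }
  if (!is.null(config$simulate)) {
    params <- do.call(sim_params, config$simulate)
    study <- simulate_study(params)
    asv <- study$asv; tax <- study$taxonomy; meta <- study$meta
    ped <- study$pedigree; logger <- study$logger
  } else if (!is.null(config$inputs)) {
    ins <- config$inputs
    need <- c("asv", "taxonomy", "metadata", "pedigree", "logger")
    miss <- setdiff(need, names(ins))
    if (length(miss)) stop("config$inputs missing: ",
                           paste(miss, collapse = ", "))
    for (f in unlist(ins[need])) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
    asv <- if (grepl("\\.biom$", ins$asv)) read_asv_biom(ins$asv)
           else read_asv_tsv(ins$asv)
    tax <- read_taxonomy_tsv(ins$taxonomy)
    meta <- read_sample_meta_csv(ins$metadata)
    ped <- read_pedigree_csv(ins$pedigree)
    logger <- read_logger_csv(ins$logger)
  } else {
    stop("config must contain a `simulate` block or an `inputs` block")
  }

  # taxa filters (fixed order: non-gut -> singletons -> proportions)
  filtered <- preprocess_asv(asv, tax)
  write_asv_tsv(filtered, file.path(out, "asv_filtered.tsv"))

  jac <- similarity_matrix(filtered, "jaccard")
  bc <- similarity_matrix(filtered, "braycurtis")
  write_matrix_tsv(jac, file.path(out, "similarity_jaccard.tsv"))
  write_matrix_tsv(bc, file.path(out, "similarity_braycurtis.tsv"))

  sri <- sri_matrix(logger, sort(unique(meta$individual_id)))
  centroids <- spatial_centroids(logger)
  write_matrix_tsv(sri, file.path(out, "sri.tsv"))

  rows <- build_dyads(meta, jac, sri, centroids, ped, braycurtis = bc)
  filt <- apply_filters(rows, meta, ped)
  rows <- filt$rows
  rows$jaccard <- squeeze_response(rows$jaccard, nrow(rows))
  rows$braycurtis <- squeeze_response(rows$braycurtis, nrow(rows))
  rows <- standardize_covariates(rows)
  write_dyads_tsv(rows, file.path(out, "dyads.tsv"), filt$report)

  spec <- do.call(model_spec, c(list(response = metric),
                                config$model %||% list()))
  settings <- do.call(mm_settings, config$sampler %||% list())
  fit <- fit_beta_mm(rows, spec, settings)
  sm <- summarize_fit(fit)
  write_summary_tsv(sm, file.path(out, "posterior_summary.tsv"))
  conv <- check_convergence(fit, plot_dir = file.path(out, "traces"))
  jsonlite::write_json(list(pass = conv$pass, threshold = conv$threshold,
                            rhat = as.list(conv$rhat)),
                       file.path(out, "convergence.json"),
                       auto_unbox = TRUE, digits = NA)

  results <- list(fit = fit, summary = sm, report = filt$report,
                  convergence = conv)

  if (isTRUE(config$mantel %||% TRUE)) {
    ids <- rownames(sri)
    mo <- outer(ids, ids,
                Vectorize(function(a, b)
                  if (a == b) 0 else mother_offspring(ped, a, b)))
    dimnames(mo) <- list(ids, ids)
    results$mantel <- tryCatch(
      mantel_test(mo, sri, n_perm = config$mantel_permutations %||% 9999,
                  seed = settings$seed),
      error = function(e) list(r = NA_real_, p = NA_real_,
                               note = conditionMessage(e)))
    jsonlite::write_json(results$mantel, file.path(out, "mantel.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if (isTRUE(config$scan)) {
    counts_filtered <- remove_singletons(filter_nongut(asv, tax))
    scan <- family_exclusion_scan(counts_filtered, tax, meta, sri,
                                  centroids, ped, spec,
                                  mm_settings_reduced(seed = settings$seed))
    write_scan_tsv(scan, file.path(out, "family_scan.tsv"))
    results$scan <- scan
    results$richness <- richness_vs_effect(scan)
  }

  prov <- list(
    package = "dyadtrans",
    version = as.character(utils::packageVersion("dyadtrans")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_file = cfg_path,
    config_md5 = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                 else NA_character_,
    metric = metric,
    seed = settings$seed,
    sampler = unclass(settings),
    filter_log = attr(filtered, "filter_log"),
    filter_report = unclass(filt$report),
    convergence_pass = conv$pass
  )
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  if (!conv$pass) {
    warning("model did not pass the Rhat convergence check; see ",
            file.path(out, "convergence.json"))
  }
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
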