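#' Sample metadata
#'
#' One row per faecal sample: `sample_id`, `individual_id`, `date`
#' (ISO `yyyy-mm-dd` or integer study day), `age_class`
#' (`"immature"`/`"adult"`), `sex` (`"F"`/`"M"`).
#'
#' @param path CSV file.
#' @return data.frame with a `day` column added (numeric day number).
#' @export
read_sample_meta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sample_meta(df)
}

#' @rdname read_sample_meta_csv
#' @param df data.frame with the columns above.
#' @export
sample_meta <- function(df) {
  need <- c("sample_id", "individual_id", "date", "age_class", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (!all(df$age_class %in% c("immature", "adult"))) {
    stop("age_class must be 'immature' or 'adult'")
  }
  day <- suppressWarnings(as.numeric(df$date))
  if (anyNA(day)) {
    d <- as.Date(as.character(df$date))
    if (anyNA(d)) stop("unparseable dates: ",
                       paste(utils::head(df$date[is.na(d)], 5L), collapse = ", "))
    day <- as.numeric(d)
  }
  df$day <- day
  df
}

#' Assemble the dyadic sample-pair dataset
#'
#' Builds one row per unordered pair of samples from two *different*
#' individuals (within-individual pairs are dropped), with the response
#' similarities and all dyadic covariates:
#' \describe{
#'   \item{jaccard, braycurtis}{pairwise microbiota similarity (from the
#'     supplied similarity matrices; `braycurtis` optional).}
#'   \item{mo_status}{1 iff the pair is a mother and her offspring.}
#'   \item{relatedness}{pedigree relatedness (0 / 0.25 / 0.5).}
#'   \item{sri}{adjusted Simple Ratio Index of the two individuals.}
#'   \item{age_sim, sex_sim}{1 if the two samples share age class / the two
#'     individuals share sex, else 0.}
#'   \item{spatial_dist}{Euclidean distance between the individuals' spatial
#'     centroids (metres).}
#'   \item{interval_days}{absolute difference between sampling days.}
#' }
#'
#' @param meta sample metadata ([sample_meta()]).
#' @param jaccard sample-by-sample Jaccard similarity matrix covering all
#'   samples in `meta`.
#' @param sri individual-by-individual adjusted SRI matrix.
#' @param centroids data.frame `individual_id`, `x`, `y`
#'   ([spatial_centroids()]).
#' @param ped a `pedigree_table`.
#' @param braycurtis optional Bray-Curtis similarity matrix.
#' @return data.frame of dyad rows (class `dyad_table`).
#' @export
build_dyads <- function(meta, jaccard, sri, centroids, ped,
                        braycurtis = NULL) {
  meta <- sample_meta(meta)
  ids <- unique(meta$individual_id)
  gaps <- c(
    if (length(g <- setdiff(meta$sample_id, rownames(jaccard))))
      paste("samples missing from jaccard matrix:", paste(g, collapse = ", ")),
    if (length(g <- setdiff(ids, rownames(sri))))
      paste("individuals missing from SRI matrix:", paste(g, collapse = ", ")),
    if (length(g <- setdiff(ids, centroids$individual_id)))
      paste("individuals missing centroids:", paste(g, collapse = ", ")),
    if (length(g <- setdiff(ids, ped$individual_id)))
      paste("individuals missing from pedigree:", paste(g, collapse = ", ")),
    if (!is.null(braycurtis) &&
        length(g <- setdiff(meta$sample_id, rownames(braycurtis))))
      paste("samples missing from braycurtis matrix:", paste(g, collapse = ", "))
  )
  if (length(gaps)) stop("incomplete auxiliary inputs:\n  ",
                         paste(gaps, collapse = "\n  "))

  n <- nrow(meta)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ia <- pr[, 1]
  ib <- pr[, 2]
  keep <- meta$individual_id[ia] != meta$individual_id[ib]
  ia <- ia[keep]
  ib <- ib[keep]

  # individual-level lookups
  cx <- stats::setNames(centroids$x, centroids$individual_id)
  cy <- stats::setNames(centroids$y, centroids$individual_id)
  A <- meta$individual_id[ia]
  B <- meta$individual_id[ib]
  upair <- unique(data.frame(A = pmin(A, B), B = pmax(A, B),
                             stringsAsFactors = FALSE))
  upair$mo <- mapply(mother_offspring, a = upair$A, b = upair$B,
                     MoreArgs = list(ped = ped))
  upair$rel <- mapply(relatedness, a = upair$A, b = upair$B,
                      MoreArgs = list(ped = ped))
  key <- paste(pmin(A, B), pmax(A, B))
  m <- match(key, paste(upair$A, upair$B))

  rows <- data.frame(
    sample_a = meta$sample_id[ia],
    sample_b = meta$sample_id[ib],
    individual_a = A,
    individual_b = B,
    jaccard = jaccard[cbind(meta$sample_id[ia], meta$sample_id[ib])],
    mo_status = as.integer(upair$mo[m]),
    relatedness = upair$rel[m],
    sri = sri[cbind(A, B)],
    age_sim = as.integer(meta$age_class[ia] == meta$age_class[ib]),
    sex_sim = as.integer(meta$sex[ia] == meta$sex[ib]),
    spatial_dist = sqrt((cx[A] - cx[B])^2 + (cy[A] - cy[B])^2),
    interval_days = abs(meta$day[ia] - meta$day[ib]),
    age_a = meta$age_class[ia],
    age_b = meta$age_class[ib],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(braycurtis)) {
    rows$braycurtis <- braycurtis[cbind(rows$sample_a, rows$sample_b)]
  }
  class(rows) <- c("dyad_table", "data.frame")
  rows
}

#' Apply the dyadic exclusion filters
#'
#' Two exclusions, applied jointly: (i) sample-pairs where both samples are
#' immature; (ii) mother-offspring sample-pairs where the *mother's* sample
#' is immature. Rule (ii) makes age-class similarity among mother-offspring
#' pairs a function of offspring age only: a mixed-age MO pair can then only
#' arise from an immature offspring. The two removal sets can overlap, so
#' the report lists both sets and their intersection alongside the stage
#' counts.
#'
#' @param rows a `dyad_table` from [build_dyads()].
#' @param meta the sample metadata the rows were built from.
#' @param ped the `pedigree_table` (identifies which dyad member is the
#'   mother).
#' @return list with `rows` (filtered `dyad_table`) and `report`, a
#'   `filter_report` list: `n_total`, `n_immature_immature`,
#'   `n_mother_immature`, `n_overlap`, `n_removed`, `n_final`, `n_final_mo`.
#' @export
apply_filters <- function(rows, meta, ped) {
  meta <- sample_meta(meta)
  age <- stats::setNames(meta$age_class, meta$sample_id)
  imm_a <- age[rows$sample_a] == "immature"
  imm_b <- age[rows$sample_b] == "immature"
  imm_imm <- imm_a & imm_b

  # rule (ii): identify which member of an MO pair is the mother
  mum <- stats::setNames(ped$mother_id, ped$individual_id)
  is_mum_a <- rows$mo_status == 1 &
    !is.na(mum[rows$individual_b]) &
    mum[rows$individual_b] == rows$individual_a
  is_mum_b <- rows$mo_status == 1 &
    !is.na(mum[rows$individual_a]) &
    mum[rows$individual_a] == rows$individual_b
  mother_imm <- (is_mum_a & imm_a) | (is_mum_b & imm_b)

  drop <- imm_imm | mother_imm
  out <- rows[!drop, , drop = FALSE]
  class(out) <- c("dyad_table", "data.frame")
  report <- structure(list(
    n_total = nrow(rows),
    n_total_mo = sum(rows$mo_status == 1),
    n_immature_immature = sum(imm_imm),
    n_mother_immature = sum(mother_imm),
    n_overlap = sum(imm_imm & mother_imm),
    n_removed = sum(drop),
    n_final = nrow(out),
    n_final_mo = sum(out$mo_status == 1)
  ), class = "filter_report")
  list(rows = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("dyadic filter report\n")
  cat(sprintf("  between-individual sample-pairs: %d (%d mother-offspring)\n",
              x$n_total, x$n_total_mo))
  cat(sprintf("  immature-immature pairs:         %d\n", x$n_immature_immature))
  cat(sprintf("  mother-sampled-immature MO pairs:%d\n", x$n_mother_immature))
  cat(sprintf("  overlap of the two removal sets: %d\n", x$n_overlap))
  cat(sprintf("  removed (union):                 %d\n", x$n_removed))
  cat(sprintf("  final: %d (%d mother-offspring)\n", x$n_final, x$n_final_mo))
  invisible(x)
}

#' Centre and scale the continuous dyadic covariates
#'
#' Continuous covariates (`sri`, `relatedness`, `spatial_dist`,
#' `interval_days`) are centred and scaled to unit standard deviation so
#' posterior effect sizes are comparable across predictors; binary
#' covariates stay 0/1. A zero-variance covariate is left unscaled with a
#' warning. The centre/scale pairs are stored in attribute `"scaling"` for
#' back-transformation.
#'
#' @param rows a `dyad_table`.
#' @param covariates which columns to standardize.
#' @return The `dyad_table` with standardized columns and a `"scaling"`
#'   attribute (data.frame `covariate`, `center`, `scale`).
#' @export
standardize_covariates <- function(rows,
                                   covariates = c("sri", "relatedness",
                                                  "spatial_dist",
                                                  "interval_days")) {
  sc <- data.frame(covariate = covariates, center = NA_real_,
                   scale = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(covariates)) {
    v <- rows[[covariates[k]]]
    if (is.null(v)) stop("no such covariate column: ", covariates[k])
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance covariate left unscaled: ", covariates[k])
      sc$center[k] <- 0
      sc$scale[k] <- 1
      next
    }
    sc$center[k] <- mean(v)
    sc$scale[k] <- s
    rows[[covariates[k]]] <- (v - sc$center[k]) / sc$scale[k]
  }
  attr(rows, "scaling") <- sc
  rows
}

#' @rdname standardize_covariates
#' @param x standardized values of one covariate.
#' @param covariate covariate name to invert.
#' @export
unstandardize <- function(x, rows, covariate) {
  sc <- attr(rows, "scaling")
  if (is.null(sc)) stop("no scaling attribute on this dyad table")
  i <- match(covariate, sc$covariate)
  if (is.na(i)) stop("covariate was not standardized: ", covariate)
  x * sc$scale[i] + sc$center[i]
}

#' Compress similarities from [0, 1] into the open unit interval
#'
#' The Beta likelihood is undefined at exactly 0 or 1, so observed
#' similarities are compressed with the standard Smithson-Verkuilen
#' transform `(y * (n - 1) + 0.5) / n`, where `n` is the number of rows in
#' the modelled dataset. Apply once, after filtering, with the final row
#' count.
#'
#' @param y similarity values in [0, 1].
#' @param n number of observations (>= 2).
#' @return Values in (0, 1); 0.5 is a fixed point.
#' @export
squeeze_response <- function(y, n) {
  stopifnot(n >= 2, all(y >= 0 & y <= 1))
  (y * (n - 1) + 0.5) / n
}

#' Write a dyad table (TSV) with its filter report (JSON sidecar)
#'
#' @param rows `dyad_table`.
#' @param path TSV path; the report, if given, goes to
#'   `sub("\\\\.tsv$", "_filter_report.json", path)`.
#' @param report optional `filter_report`.
#' @export
write_dyads_tsv <- function(rows, path, report = NULL) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report)) {
    jpath <- sub("\\.tsv$", "_filter_report.json", path)
    jsonlite::write_json(unclass(report), jpath, auto_unbox = TRUE)
  }
  invisible(path)
}
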