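#' Leave-one-bacterial-family-out attribution scan
#'
#' Quantifies how much each bacterial family contributes to the maternal
#' transmission signals. For every family with assigned ASVs in the table,
#' the Jaccard similarity is recomputed with that family excluded, the dyad
#' table's response is rebuilt (covariates and exclusion filters do not
#' depend on taxa, so the rows themselves are unchanged), and the
#' interaction model is refitted with the reduced sampler. Each row records
#' the posterior mean and 95% CI of the mother-offspring main effect and of
#' the mother-offspring x age-class-similarity interaction, plus their
#' deltas against the full-table reference fit (delta = excluded-model
#' effect minus full-model effect). ASVs with no family assignment are
#' never excluded; they are reported as an `Unassigned` pseudo-row with
#' `scanned = FALSE`.
#'
#' Per-family fits use derived seeds (`base_seed + family index`) so the
#' scan is reproducible and parallelisable by family.
#'
#' @param asv pre-processed [asv_table] (contaminants and singletons
#'   already removed; counts or proportions — Jaccard uses presence only).
#' @param tax taxonomy covering the table.
#' @param meta,sri,centroids,ped the usual auxiliary inputs of
#'   [build_dyads()].
#' @param spec [model_spec()]; must include the `mo_status:age_sim`
#'   interaction.
#' @param settings sampler settings; defaults to the reduced preset.
#' @param base_seed base seed for the per-family derived seeds.
#' @return data.frame (class `family_scan`) with one reference row
#'   (`family == "(none excluded)"`), one row per assigned family, and an
#'   `Unassigned` pseudo-row if applicable.
#' @export
family_exclusion_scan <- function(asv, tax, meta, sri, centroids, ped,
                                  spec = model_spec(),
                                  settings = mm_settings_reduced(),
                                  base_seed = settings$seed) {
  if (!"mo_status:age_sim" %in% spec$interactions) {
    stop("the scan needs the mo_status:age_sim interaction in the model spec")
  }
  tx <- .tax_for(asv, tax)
  fams <- table(tx$family[!is.na(tx$family)])
  if (length(fams) < 2L) stop("need at least 2 assigned bacterial families")
  n_unassigned <- sum(is.na(tx$family))

  # dyad rows are taxon-independent; build once and swap the response
  base_rows <- build_dyads(meta, similarity_matrix(asv, "jaccard"),
                           sri, centroids, ped)
  filt <- apply_filters(base_rows, meta, ped)
  n_rows <- nrow(filt$rows)

  fit_one <- function(sim, seed) {
    rows <- filt$rows
    rows$jaccard <- squeeze_response(
      sim[cbind(rows$sample_a, rows$sample_b)], n_rows)
    rows <- standardize_covariates(rows)
    s <- settings
    s$seed <- as.integer(seed)
    fit <- fit_beta_mm(rows, spec, s)
    sm <- summarize_fit(fit)
    mo <- sm[sm$term == "mo_status", ]
    ia <- sm[sm$term == "mo_status:age_sim", ]
    c(mo_mean = mo$estimate, mo_lo = mo$q2.5, mo_hi = mo$q97.5,
      int_mean = ia$estimate, int_lo = ia$q2.5, int_hi = ia$q97.5)
  }

  ref <- fit_one(similarity_matrix(asv, "jaccard"), base_seed)
  rows_out <- list(data.frame(
    family = "(none excluded)", n_asvs = ncol(asv),
    log_n_asvs = log(ncol(asv)),
    mo_mean = ref["mo_mean"], mo_lo = ref["mo_lo"], mo_hi = ref["mo_hi"],
    int_mean = ref["int_mean"], int_lo = ref["int_lo"],
    int_hi = ref["int_hi"],
    delta_mo = 0, delta_int = 0,
    mo_significant = ref["mo_lo"] > 0 | ref["mo_hi"] < 0,
    int_significant = ref["int_lo"] > 0 | ref["int_hi"] < 0,
    scanned = TRUE, reason = "reference", stringsAsFactors = FALSE))

  for (k in seq_along(fams)) {
    fam <- names(fams)[k]
    red <- exclude_family(asv, tax, fam)
    if (ncol(red) == 0L || any(rowSums(red) == 0)) {
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        family = fam, n_asvs = as.integer(fams[k]),
        log_n_asvs = log(as.integer(fams[k])),
        mo_mean = NA_real_, mo_lo = NA_real_, mo_hi = NA_real_,
        int_mean = NA_real_, int_lo = NA_real_, int_hi = NA_real_,
        delta_mo = NA_real_, delta_int = NA_real_,
        mo_significant = NA, int_significant = NA,
        scanned = FALSE,
        reason = "exclusion empties at least one sample",
        stringsAsFactors = FALSE)
      next
    }
    est <- fit_one(similarity_matrix(red, "jaccard"), base_seed + k)
    rows_out[[length(rows_out) + 1L]] <- data.frame(
      family = fam, n_asvs = as.integer(fams[k]),
      log_n_asvs = log(as.integer(fams[k])),
      mo_mean = est["mo_mean"], mo_lo = est["mo_lo"], mo_hi = est["mo_hi"],
      int_mean = est["int_mean"], int_lo = est["int_lo"],
      int_hi = est["int_hi"],
      delta_mo = est["mo_mean"] - ref["mo_mean"],
      delta_int = est["int_mean"] - ref["int_mean"],
      mo_significant = est["mo_lo"] > 0 | est["mo_hi"] < 0,
      int_significant = est["int_lo"] > 0 | est["int_hi"] < 0,
      scanned = TRUE, reason = "", stringsAsFactors = FALSE)
  }
  if (n_unassigned > 0) {
    rows_out[[length(rows_out) + 1L]] <- data.frame(
      family = "Unassigned", n_asvs = n_unassigned,
      log_n_asvs = log(n_unassigned),
      mo_mean = NA_real_, mo_lo = NA_real_, mo_hi = NA_real_,
      int_mean = NA_real_, int_lo = NA_real_, int_hi = NA_real_,
      delta_mo = NA_real_, delta_int = NA_real_,
      mo_significant = NA, int_significant = NA,
      scanned = FALSE, reason = "family unassigned; not scanned",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  class(out) <- c("family_scan", "data.frame")
  out
}

#' Richness diagnostic for a family-exclusion scan
#'
#' A family's influence could trivially track how many ASVs it removes from
#' the similarity metric. This diagnostic reports the Spearman rank
#' correlation between each family's logged ASV richness and its effect
#' deltas, and flags whether the strongest attenuator of the maternal main
#' effect is also the richest family.
#'
#' @param scan a `family_scan`.
#' @return list: `cor_richness_delta_mo`, `cor_richness_delta_int`
#'   (Spearman), `top_attenuator` (family with the most negative
#'   `delta_mo`), `top_attenuator_is_richest` (logical), and `plot_data`
#'   (the scanned rows, for plotting deltas against `log_n_asvs`).
#' @export
richness_vs_effect <- function(scan) {
  sc <- scan[scan$scanned & scan$family != "(none excluded)", , drop = FALSE]
  if (nrow(sc) < 3L) stop("need at least 3 scanned family rows")
  c_mo <- if (stats::sd(sc$delta_mo) == 0) 0 else
    stats::cor(sc$log_n_asvs, sc$delta_mo, method = "spearman")
  c_int <- if (stats::sd(sc$delta_int) == 0) 0 else
    stats::cor(sc$log_n_asvs, sc$delta_int, method = "spearman")
  top <- sc$family[which.min(sc$delta_mo)]
  list(cor_richness_delta_mo = c_mo,
       cor_richness_delta_int = c_int,
       top_attenuator = top,
       top_attenuator_is_richest =
         sc$n_asvs[sc$family == top] == max(sc$n_asvs),
       plot_data = sc)
}

#' Plot a family-exclusion scan
#'
#' Draws the scanned effect (posterior mean and 95% CI with one family
#' excluded) against the logged ASV richness of the dropped family, with
#' the full-model reference shown as a horizontal band — the usual layout
#' for leave-one-taxon-out influence displays.
#'
#' @param scan a `family_scan`.
#' @param effect `"main"` (mother-offspring main effect) or
#'   `"interaction"`.
#' @param path optional PNG path; when `NULL`, draws on the active device.
#' @return Invisibly, the plotted data.
#' @export
plot_family_scan <- function(scan, effect = c("main", "interaction"),
                             path = NULL) {
  effect <- match.arg(effect)
  cols <- if (effect == "main") c("mo_mean", "mo_lo", "mo_hi")
          else c("int_mean", "int_lo", "int_hi")
  ref <- scan[scan$family == "(none excluded)", ]
  sc <- scan[scan$scanned & scan$family != "(none excluded)", , drop = FALSE]
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  ylim <- range(sc[[cols[2]]], sc[[cols[3]]], ref[[cols[2]]], ref[[cols[3]]])
  graphics::plot(sc$log_n_asvs, sc[[cols[1]]], ylim = ylim, pch = 19,
                 xlab = "log(number of ASVs in dropped family)",
                 ylab = if (effect == "main") "mother-offspring effect"
                        else "mother-offspring x age-similarity effect",
                 main = "Family-exclusion scan")
  graphics::arrows(sc$log_n_asvs, sc[[cols[2]]], sc$log_n_asvs,
                   sc[[cols[3]]], angle = 90, code = 3, length = 0.03)
  graphics::abline(h = ref[[cols[1]]], col = "red")
  graphics::abline(h = c(ref[[cols[2]]], ref[[cols[3]]]), col = "red",
                   lty = 3)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  graphics::text(sc$log_n_asvs, sc[[cols[1]]], sc$family, pos = 4,
                 cex = 0.7)
  invisible(sc)
}

#' @rdname family_exclusion_scan
#' @param scan a `family_scan` to write.
#' @param path TSV path.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
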