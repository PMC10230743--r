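#' Remove non-gut taxa from an ASV table
#'
#' Drops every ASV whose taxonomic lineage contains any excluded label at any
#' rank, matched case-insensitively. The default exclusion list removes the
#' usual 16S contaminants of gut profiles: Cyanobacteria (chloroplast reads)
#' and Mitochondria.
#'
#' @param asv an [asv_table].
#' @param tax taxonomy data.frame as from [read_taxonomy_tsv()]; must cover
#'   every ASV in `asv`.
#' @param excluded character vector of taxon labels; an empty vector is a
#'   no-op.
#' @return The filtered [asv_table].
#' @export
filter_nongut <- function(asv, tax,
                          excluded = c("Cyanobacteria", "Mitochondria")) {
  if (length(excluded) == 0L) return(asv)
  tx <- .tax_for(asv, tax)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  lin <- tolower(do.call(paste, c(lapply(tx[ranks], function(x)
    ifelse(is.na(x), "", x)), sep = ";")))
  hit <- Reduce(`|`, lapply(tolower(excluded), function(lbl)
    grepl(lbl, lin, fixed = TRUE)))
  asv[, !hit, drop = FALSE]
}

#' Remove singleton ASVs
#'
#' The default singleton definition follows the DADA2-community convention:
#' an ASV whose total read count across the whole dataset is <= 1. The
#' alternative definition (present in exactly one sample, any abundance) is
#' available via `definition = "one_sample"`.
#'
#' @param asv an [asv_table] in counts mode.
#' @param definition `"total_count"` (default) or `"one_sample"`.
#' @return The filtered [asv_table].
#' @export
remove_singletons <- function(asv, definition = c("total_count", "one_sample")) {
  definition <- match.arg(definition)
  if (asv_mode(asv) != "counts") {
    stop("singleton removal is defined on read counts; got a proportions-mode table")
  }
  keep <- if (definition == "total_count") {
    colSums(asv) > 1
  } else {
    colSums(asv > 0) > 1
  }
  asv[, keep, drop = FALSE]
}

#' Normalise counts to within-sample proportional abundance
#'
#' @param asv an [asv_table] in counts mode.
#' @return An [asv_table] in proportions mode (each row sums to 1).
#' @export
normalize_proportions <- function(asv) {
  if (asv_mode(asv) != "counts") stop("input must be in counts mode")
  rs <- rowSums(asv)
  if (any(rs == 0)) {
    stop("cannot normalise all-zero sample(s): ",
         paste(utils::head(rownames(asv)[rs == 0], 5L), collapse = ", "))
  }
  asv_table(unclass(asv) / rs, "proportions")
}

#' Drop one bacterial family from an ASV table
#'
#' Removes all ASVs assigned to `family` (exact match on the family rank,
#' rank prefixes already stripped by the reader). ASVs with unassigned family
#' are never removed. Excluding a family absent from the taxonomy returns the
#' table unchanged.
#'
#' @inheritParams filter_nongut
#' @param family family label to exclude.
#' @return The reduced [asv_table].
#' @export
exclude_family <- function(asv, tax, family) {
  stopifnot(is.character(family), length(family) == 1L)
  tx <- .tax_for(asv, tax)
  hit <- !is.na(tx$family) & tx$family == family
  asv[, !hit, drop = FALSE]
}

#' Standard pre-processing chain for ASV tables
#'
#' Applies, in this fixed order: non-gut taxon removal, singleton removal,
#' proportional normalisation. The order is fixed so that the singleton
#' filter acts on counts already stripped of contaminant reads; it is
#' recorded in the returned attribute `"filter_log"`.
#'
#' @inheritParams filter_nongut
#' @param singleton_definition passed to [remove_singletons()].
#' @return A proportions-mode [asv_table] with a `"filter_log"` attribute
#'   (character vector of steps with ASV counts).
#' @export
preprocess_asv <- function(asv, tax,
                           excluded = c("Cyanobacteria", "Mitochondria"),
                           singleton_definition = "total_count") {
  log <- sprintf("input: %d ASVs", ncol(asv))
  asv <- filter_nongut(asv, tax, excluded)
  log <- c(log, sprintf("non-gut removal (%s): %d ASVs",
                        paste(excluded, collapse = ","), ncol(asv)))
  asv <- remove_singletons(asv, singleton_definition)
  log <- c(log, sprintf("singleton removal (%s): %d ASVs",
                        singleton_definition, ncol(asv)))
  asv <- normalize_proportions(asv)
  log <- c(log, "normalised to proportions")
  attr(asv, "filter_log") <- log
  asv
}
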