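#' ASV abundance tables
#'
#' An `asv_table` is a numeric matrix of non-negative abundances with samples
#' as rows and amplicon sequence variants (ASVs) as columns, plus a `mode`
#' attribute that records whether entries are raw read counts (`"counts"`) or
#' within-sample proportions (`"proportions"`). All filtering and similarity
#' functions in the package operate on this container.
#'
#' @param x numeric matrix (samples x ASVs) with dimnames; no negative or
#'   non-finite entries.
#' @param mode `"counts"` or `"proportions"`. In proportions mode every
#'   non-empty row must sum to 1 (tolerance 1e-9).
#' @return An object of class `asv_table` (a matrix with a `mode` attribute).
#' @examples
#' m <- matrix(c(5, 0, 2, 3), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' tab <- asv_table(m, "counts")
#' asv_mode(tab)
#' @export
asv_table <- function(x, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix (samples x ASVs)")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("`x` must carry sample ids as rownames and ASV ids as colnames")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("abundances must be finite")
  if (any(x < 0)) stop("abundances must be non-negative")
  if (mode == "proportions") {
    rs <- rowSums(x)
    bad <- rs > 0 & abs(rs - 1) > 1e-9
    if (any(bad)) {
      stop("proportions-mode rows must sum to 1; offending samples: ",
           paste(utils::head(rownames(x)[bad], 5L), collapse = ", "))
    }
  }
  structure(x, mode = mode, class = c("asv_table", "matrix", "array"))
}

#' @rdname asv_table
#' @export
asv_mode <- function(x) {
  m <- attr(x, "mode")
  if (is.null(m)) stop("not an asv_table: no mode attribute")
  m
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("asv_table: %d samples x %d ASVs (%s mode)\n",
              nrow(x), ncol(x), asv_mode(x)))
  invisible(x)
}

# keep class/mode when subsetting with drop = FALSE
#' @export
`[.asv_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, mode = attr(x, "mode"),
                     class = c("asv_table", "matrix", "array"))
  }
  out
}

#' Read and write ASV tables
#'
#' TSV layout: samples as rows, first column `sample_id`, remaining columns
#' one per ASV. `read_asv_biom()` reads a BIOM-format file via the
#' \pkg{biomformat} package (BIOM stores ASVs as rows; the table is
#' transposed on read).
#'
#' @param path file path.
#' @param mode abundance mode of the stored table, `"counts"` by default.
#' @return An [asv_table].
#' @export
read_asv_tsv <- function(path, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    stop("first column of an ASV TSV must be `sample_id`")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  asv_table(m, mode)
}

#' @rdname read_asv_tsv
#' @param x an [asv_table] to write.
#' @export
write_asv_tsv <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_asv_tsv
#' @export
read_asv_biom <- function(path, mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("reading BIOM files requires the `biomformat` package")
  }
  b <- biomformat::read_biom(path)
  m <- t(as.matrix(biomformat::biom_data(b)))
  storage.mode(m) <- "double"
  asv_table(m, mode)
}

#' Read a taxonomy table
#'
#' Accepts either split rank columns (`asv_id`, `kingdom`, `phylum`, `class`,
#' `order`, `family`, `genus`) or a two-column file (`asv_id`, `taxonomy`)
#' holding GreenGenes-style lineage strings
#' (`k__Bacteria; p__...; c__...; o__...; f__...; g__...`). Rank prefixes
#' (`k__` etc.) are stripped; empty ranks become `NA`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `asv_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if ("taxonomy" %in% names(df)) {
    parts <- strsplit(df$taxonomy, ";\\s*")
    m <- t(vapply(parts, function(p) {
      p <- sub("^[a-z]__", "", p)
      length(p) <- 6L
      p
    }, character(6L)))
    out <- data.frame(asv_id = df$asv_id, m, stringsAsFactors = FALSE)
    names(out) <- c("asv_id", ranks)
  } else {
    miss <- setdiff(c("asv_id", ranks), names(df))
    if (length(miss)) stop("taxonomy TSV missing columns: ",
                           paste(miss, collapse = ", "))
    out <- df[, c("asv_id", ranks)]
    for (r in ranks) out[[r]] <- sub("^[a-z]__", "", as.character(out[[r]]))
  }
  for (r in ranks) out[[r]][!nzchar(out[[r]]) | is.na(out[[r]])] <- NA_character_
  out
}

#' @rdname read_taxonomy_tsv
#' @param tax taxonomy data.frame to write.
#' @export
write_taxonomy_tsv <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# taxonomy rows for the ASVs of a table, in table column order
.tax_for <- function(asv, tax) {
  missing <- setdiff(colnames(asv), tax$asv_id)
  if (length(missing)) {
    stop("taxonomy does not cover ASVs: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (+%d more)", length(missing) - 5L))
  }
  tax[match(colnames(asv), tax$asv_id), , drop = FALSE]
}
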