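#' Pairwise microbiota similarity between two samples
#'
#' `jaccard_similarity()` is the proportion of ASVs shared between two
#' samples, |present in both| / |present in either|, with presence defined as
#' abundance strictly greater than zero (1 minus the binary Jaccard
#' distance). `braycurtis_similarity()` is 1 minus the Bray-Curtis
#' dissimilarity, `1 - sum(|a - b|) / sum(a + b)`, computed on proportional
#' abundances. Both are symmetric and lie in [0, 1].
#'
#' @param a,b numeric abundance vectors over the same ASV universe.
#' @return A single similarity value in [0, 1].
#' @examples
#' jaccard_similarity(c(1, 1, 1, 0), c(0, 1, 1, 1))   # 2 shared / 4 in union
#' braycurtis_similarity(c(0.5, 0.5), c(0.25, 0.75))
#' @export
jaccard_similarity <- function(a, b) {
  .check_pair(a, b)
  pa <- a > 0
  pb <- b > 0
  if (!any(pa) && !any(pb)) {
    stop("Jaccard similarity undefined: both samples are empty")
  }
  sum(pa & pb) / sum(pa | pb)
}

#' @rdname jaccard_similarity
#' @export
braycurtis_similarity <- function(a, b) {
  .check_pair(a, b)
  tot <- sum(a) + sum(b)
  if (tot == 0) stop("Bray-Curtis similarity undefined: both samples are empty")
  1 - sum(abs(a - b)) / tot
}

.check_pair <- function(a, b) {
  if (length(a) != length(b)) stop("samples must share the same ASV universe")
  if (anyNA(a) || anyNA(b) || any(a < 0) || any(b < 0)) {
    stop("abundances must be non-negative and non-missing")
  }
  invisible(NULL)
}

#' Sample-by-sample similarity matrix
#'
#' Computes all pairwise similarities of an ASV table through
#' \code{vegan::vegdist} (`jaccard` with `binary = TRUE`, or `bray`),
#' returned as a symmetric similarity (not distance) matrix with unit
#' diagonal. Bray-Curtis requires a proportions-mode table; Jaccard accepts
#' either mode since it only uses presence.
#'
#' @param asv an [asv_table].
#' @param metric `"jaccard"` or `"braycurtis"`.
#' @return Symmetric numeric matrix (samples x samples), values in [0, 1],
#'   with attribute `"metric"`.
#' @export
similarity_matrix <- function(asv, metric = c("jaccard", "braycurtis")) {
  metric <- match.arg(metric)
  if (ncol(asv) == 0L) stop("similarity undefined on an empty ASV table")
  empty <- rowSums(asv) == 0
  if (any(empty)) {
    stop("similarity undefined for empty sample(s): ",
         paste(utils::head(rownames(asv)[empty], 5L), collapse = ", "))
  }
  d <- if (metric == "jaccard") {
    vegan::vegdist(unclass(asv), method = "jaccard", binary = TRUE)
  } else {
    if (asv_mode(asv) != "proportions") {
      stop("Bray-Curtis similarity requires a proportions-mode table")
    }
    vegan::vegdist(unclass(asv), method = "bray")
  }
  s <- 1 - as.matrix(d)
  diag(s) <- 1
  dimnames(s) <- list(rownames(asv), rownames(asv))
  attr(s, "metric") <- metric
  s
}

#' Read or write a square labelled matrix as TSV
#'
#' Used for similarity and social-association matrices: first column `id`,
#' remaining columns labelled by the same ids.
#'
#' @param m square numeric matrix with matching dimnames.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(nrow(m) == ncol(m), !is.null(rownames(m)))
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix TSV is not square-labelled (row ids != column ids)")
  }
  m
}
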