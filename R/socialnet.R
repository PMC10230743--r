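#' Logger detection records
#'
#' Nightly PIT-tag logger detections: one row per (individual, night,
#' location) detection event. A night is one 12-h window; co-detection means
#' being recorded at the same location id on the same night (multiple reads
#' of the same pair at one location in one night count once).
#'
#' @param path CSV with columns `individual_id`, `location_id`, `x`, `y`,
#'   `night`.
#' @return data.frame of records.
#' @export
read_logger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "location_id", "x", "y", "night")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("logger CSV missing columns: ",
                         paste(miss, collapse = ", "))
  .check_logger(df)
  df
}

.check_logger <- function(records) {
  if (any(records$night < 1) || any(records$night != round(records$night))) {
    stop("night indices must be integers >= 1")
  }
  if (any(!is.finite(records$x)) || any(!is.finite(records$y))) {
    stop("logger coordinates must be finite")
  }
  invisible(records)
}

# per-individual (first, last) detection night
.lifespans <- function(records) {
  f <- tapply(records$night, records$individual_id, min)
  l <- tapply(records$night, records$individual_id, max)
  data.frame(individual_id = names(f), first = as.numeric(f),
             last = as.numeric(l), stringsAsFactors = FALSE)
}

#' Adjusted Simple Ratio Index for one pair
#'
#' The Simple Ratio Index is the fraction of sampling nights on which two
#' individuals were detected together, out of nights on which either was
#' detected. The adjusted version restricts both tallies to the overlap of
#' the two individuals' logger lifespans (the window between each one's first
#' and last detection), so that pairs whose monitoring periods barely overlap
#' are not penalised for nights when one of them was not present at all.
#' Returns 0 when the lifespans do not overlap or no night in the overlap has
#' a detection of either individual.
#'
#' @param records logger record data.frame ([read_logger_csv()]).
#' @param a,b individual ids.
#' @return Adjusted SRI in [0, 1].
#' @export
adjusted_sri <- function(records, a, b) {
  .check_logger(records)
  ra <- records[records$individual_id == a, , drop = FALSE]
  rb <- records[records$individual_id == b, , drop = FALSE]
  if (nrow(ra) == 0L) stop("no logger records for individual: ", a)
  if (nrow(rb) == 0L) stop("no logger records for individual: ", b)
  lo <- max(min(ra$night), min(rb$night))
  hi <- min(max(ra$night), max(rb$night))
  if (lo > hi) return(0)
  ra <- ra[ra$night >= lo & ra$night <= hi, , drop = FALSE]
  rb <- rb[rb$night >= lo & rb$night <= hi, , drop = FALSE]
  either <- union(ra$night, rb$night)
  if (length(either) == 0L) return(0)
  together <- intersect(paste(ra$night, ra$location_id),
                        paste(rb$night, rb$location_id))
  x <- length(unique(sub(" .*$", "", together)))
  x / length(either)
}

#' Adjusted SRI matrix over all individuals
#'
#' @param records logger record data.frame.
#' @param individuals optional character vector fixing the matrix order;
#'   defaults to the sorted individuals present in `records`.
#' @return Symmetric individual-by-individual matrix of adjusted SRI values
#'   in [0, 1] with unit diagonal left at 1.
#' @export
sri_matrix <- function(records, individuals = NULL) {
  .check_logger(records)
  if (is.null(individuals)) {
    individuals <- sort(unique(records$individual_id))
  } else {
    miss <- setdiff(individuals, records$individual_id)
    if (length(miss)) stop("no logger records for individual(s): ",
                           paste(miss, collapse = ", "))
  }
  n <- length(individuals)
  # one pass: per-individual night sets and per-night location sets
  recs <- split(records[c("night", "location_id")], records$individual_id)
  m <- diag(1, n)
  dimnames(m) <- list(individuals, individuals)
  if (n < 2L) return(m)
  nights <- lapply(recs, function(r) sort(unique(r$night)))
  keys <- lapply(recs, function(r) unique(paste(r$night, r$location_id)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ri <- recs[[individuals[i]]]
      rj <- recs[[individuals[j]]]
      lo <- max(min(ri$night), min(rj$night))
      hi <- min(max(ri$night), max(rj$night))
      if (lo > hi) next
      ni <- nights[[individuals[i]]]
      nj <- nights[[individuals[j]]]
      either <- union(ni[ni >= lo & ni <= hi], nj[nj >= lo & nj <= hi])
      if (length(either) == 0L) next
      ki <- keys[[individuals[i]]]
      kj <- keys[[individuals[j]]]
      kn <- as.numeric(sub(" .*$", "", intersect(ki, kj)))
      x <- length(unique(kn[kn >= lo & kn <= hi]))
      m[i, j] <- m[j, i] <- x / length(either)
    }
  }
  m
}

#' Spatial centroids and distances from logger records
#'
#' An individual's centroid is the arithmetic mean of the coordinates of all
#' its detections (each record counts once, so heavily-used loggers weigh
#' more). `spatial_distance()` is the Euclidean distance between two
#' centroids, in the coordinate units of the records (metres).
#'
#' @param records logger record data.frame.
#' @param individual individual id.
#' @return `spatial_centroid()`: named numeric `c(x, y)`;
#'   `spatial_centroids()`: data.frame `individual_id`, `x`, `y`.
#' @export
spatial_centroid <- function(records, individual) {
  r <- records[records$individual_id == individual, , drop = FALSE]
  if (nrow(r) == 0L) stop("no logger records for individual: ", individual)
  c(x = mean(r$x), y = mean(r$y))
}

#' @rdname spatial_centroid
#' @export
spatial_centroids <- function(records) {
  ids <- sort(unique(records$individual_id))
  xy <- t(vapply(ids, function(i) spatial_centroid(records, i), numeric(2)))
  data.frame(individual_id = ids, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname spatial_centroid
#' @param a_centroid,b_centroid numeric `(x, y)` pairs.
#' @export
spatial_distance <- function(a_centroid, b_centroid) {
  sqrt(sum((as.numeric(a_centroid)[1:2] - as.numeric(b_centroid)[1:2])^2))
}
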