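#' Pedigree tables and dyadic kinship coding
#'
#' A pedigree is a data.frame with one row per individual: `individual_id`,
#' `mother_id`, `father_id`, `sex` (`"F"`/`"M"`, may be `NA`). Blank or `NA`
#' parents are unknown; two individuals with unknown mothers are treated as
#' having distinct (unshared) mothers.
#'
#' @param path CSV file with the four columns above.
#' @return Pedigree data.frame (class `pedigree_table`).
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  pedigree_table(df)
}

#' @rdname read_pedigree_csv
#' @param df data.frame with columns `individual_id`, `mother_id`,
#'   `father_id`, `sex`.
#' @export
pedigree_table <- function(df) {
  need <- c("individual_id", "mother_id", "father_id", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids in pedigree")
  if (any(!is.na(df$mother_id) & df$mother_id == df$individual_id) ||
      any(!is.na(df$father_id) & df$father_id == df$individual_id)) {
    stop("an individual cannot be its own parent")
  }
  sex_of <- stats::setNames(df$sex, df$individual_id)
  bad_mum <- df$mother_id[!is.na(df$mother_id) &
                          !is.na(sex_of[df$mother_id]) &
                          sex_of[df$mother_id] == "M"]
  if (length(bad_mum)) stop("recorded mothers with male sex: ",
                            paste(unique(bad_mum), collapse = ", "))
  class(df) <- c("pedigree_table", "data.frame")
  df
}

.ped_row <- function(ped, id) {
  i <- match(id, ped$individual_id)
  if (is.na(i)) stop("individual not in pedigree: ", id)
  ped[i, , drop = FALSE]
}

#' Dyadic genetic relatedness from a pedigree
#'
#' First-degree coding used for the dyadic models: parent-offspring and
#' full-sibling pairs are 0.5, half-siblings (exactly one shared recorded
#' parent) 0.25, everything else 0. Deeper relationships (grandparents,
#' cousins) are deliberately coded 0; missing parents never match.
#'
#' @param ped a `pedigree_table`.
#' @param a,b individual ids (order irrelevant).
#' @return 0, 0.25 or 0.5.
#' @examples
#' ped <- pedigree_table(data.frame(
#'   individual_id = c("M1", "F1", "o1", "o2", "u1"),
#'   mother_id = c(NA, NA, "M1", "M1", NA),
#'   father_id = c(NA, NA, "F1", NA, NA),
#'   sex = c("F", "M", "F", "M", "F")))
#' relatedness(ped, "M1", "o1")  # mother-offspring: 0.5
#' relatedness(ped, "o1", "o2")  # share only the mother: 0.25
#' relatedness(ped, "o1", "u1")  # unrelated: 0
#' @export
relatedness <- function(ped, a, b) {
  ra <- .ped_row(ped, a)
  rb <- .ped_row(ped, b)
  if (a == b) stop("relatedness is defined between two distinct individuals")
  # parent-offspring
  if ((!is.na(ra$mother_id) && ra$mother_id == b) ||
      (!is.na(ra$father_id) && ra$father_id == b) ||
      (!is.na(rb$mother_id) && rb$mother_id == a) ||
      (!is.na(rb$father_id) && rb$father_id == a)) {
    return(0.5)
  }
  share_m <- !is.na(ra$mother_id) && !is.na(rb$mother_id) &&
    ra$mother_id == rb$mother_id
  share_f <- !is.na(ra$father_id) && !is.na(rb$father_id) &&
    ra$father_id == rb$father_id
  if (share_m && share_f) return(0.5)   # full siblings
  if (share_m || share_f) return(0.25)  # half siblings
  0
}

#' Mother-offspring status of a dyad
#'
#' 1 iff one member is the recorded mother of the other; father-offspring
#' pairs are 0. Symmetric in its arguments.
#'
#' @inheritParams relatedness
#' @return 0 or 1 (integer).
#' @export
mother_offspring <- function(ped, a, b) {
  ra <- .ped_row(ped, a)
  rb <- .ped_row(ped, b)
  mo <- (!is.na(ra$mother_id) && ra$mother_id == b) ||
    (!is.na(rb$mother_id) && rb$mother_id == a)
  as.integer(mo)
}
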