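#' Accession-by-trait table
#'
#' Container for a quantitative trait table: an n x m numeric matrix with
#' unique accession ids as row names and unique trait names as column names,
#' plus a per-trait direction flag used by membership-function scoring
#' (\code{"higher"} = larger values are favourable, \code{"lower"} = smaller
#' values are favourable). Missing values are allowed; all-missing columns
#' are not.
#'
#' @param values numeric matrix (accessions x traits) with dimnames, or a
#'   data.frame with an id column given by \code{id_col}.
#' @param direction character vector of \code{"higher"}/\code{"lower"}, one
#'   per trait (recycled if length 1).
#' @param id_col when \code{values} is a data.frame, name of the accession id
#'   column (default first column).
#' @return object of class \code{trait_matrix} with elements \code{values},
#'   \code{direction}.
#' @export
trait_matrix <- function(values, direction = "higher", id_col = NULL) {
  if (is.data.frame(values)) {
    if (is.null(id_col)) id_col <- names(values)[1L]
    ids <- as.character(values[[id_col]])
    values <- as.matrix(values[setdiff(names(values), id_col)])
    rownames(values) <- ids
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("acc%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("trait%02d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("accession ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("trait names must be unique")
  if (ncol(values) < 1L) stop("need at least one trait")
  all_na <- colSums(!is.na(values)) == 0L
  if (any(all_na))
    stop("all-missing trait column(s): ",
         paste(colnames(values)[all_na], collapse = ", "))
  direction <- match.arg(rep(direction, length.out = ncol(values)),
                         c("higher", "lower"), several.ok = TRUE)
  names(direction) <- colnames(values)
  structure(list(values = values, direction = direction),
            class = "trait_matrix")
}

#' @export
as.matrix.trait_matrix <- function(x, ...) x$values

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d accessions x %d traits\n",
              nrow(x$values), ncol(x$values)))
  cat("traits:", paste(utils::head(colnames(x$values), 8L), collapse = ", "),
      if (ncol(x$values) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Subset a trait matrix by accession ids
#'
#' @param tm trait_matrix.
#' @param ids character vector of accession ids to keep.
#' @return trait_matrix restricted to \code{ids} (in the given order).
#' @export
subset_accessions <- function(tm, ids) {
  stopifnot(inherits(tm, "trait_matrix"))
  missing_ids <- setdiff(ids, rownames(tm$values))
  if (length(missing_ids))
    stop("unknown accession id(s): ", paste(missing_ids, collapse = ", "))
  trait_matrix(tm$values[ids, , drop = FALSE], tm$direction)
}

#' Read a trait table from CSV/TSV
#'
#' First column is taken as the accession id unless \code{id_col} says
#' otherwise.
#'
#' @param path file path; delimiter inferred from extension (.tsv/.txt = tab).
#' @inheritParams trait_matrix
#' @return trait_matrix
#' @export
read_traits <- function(path, direction = "higher", id_col = NULL) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  trait_matrix(df, direction = direction, id_col = id_col)
}

#' Write a trait table as CSV
#'
#' @param tm trait_matrix
#' @param path output path
#' @export
write_traits <- function(tm, path) {
  df <- data.frame(accession = rownames(tm$values), tm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
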