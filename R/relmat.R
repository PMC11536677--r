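#' Relationship matrices with a tagged genetic base
#'
#' A `relmat` is a plain symmetric numeric matrix carrying three attributes:
#' the animal ids (as dimnames), the average expected heterozygosity of the
#' base population the matrix refers to (`base_het`, a value in (0, 0.5] or
#' `NA` when unknown, as for a plain pedigree matrix), and a `kind` tag
#' (`"pedigree"`, `"genomic"` or `"metafounder"`). The tag matters because
#' the metafounder algebra repeatedly rescales matrices between bases and it
#' is easy to combine matrices referring to different heterozygosities by
#' mistake.
#'
#' @param values symmetric numeric matrix.
#' @param ids character vector of animal identifiers, one per row.
#' @param base_het average expected base heterozygosity in (0, 0.5], or `NA`.
#' @param kind one of `"pedigree"`, `"genomic"`, `"metafounder"`.
#' @return an object of class `relmat`.
#' @export
relmat <- function(values, ids = rownames(values), base_het = NA_real_,
                   kind = c("pedigree", "genomic", "metafounder")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("relationship matrix must be square")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values)))
  ids <- as.character(ids)
  if (length(ids) != nrow(values))
    stopf("'ids' length (%d) does not match matrix order (%d)",
          length(ids), nrow(values))
  if (anyDuplicated(ids)) stopf("duplicated animal ids in relationship matrix")
  if (nrow(values) > 0 && max(abs(values - t(values))) > 1e-10)
    stopf("relationship matrix is not symmetric within 1e-10")
  if (!is.na(base_het)) check_scalar(base_het, "base_het", 0, 0.5, open_lower = TRUE)
  dimnames(values) <- list(ids, ids)
  structure(values, base_het = as.numeric(base_het), kind = kind,
            class = c("relmat", "matrix", "array"))
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("<relmat> %d x %d, kind = %s, base heterozygosity = %s\n",
              nrow(x), ncol(x), attr(x, "kind"),
              if (is.na(attr(x, "base_het"))) "unknown"
              else format(attr(x, "base_het"))))
  print(unclass_relmat(x), ...)
  invisible(x)
}

unclass_relmat <- function(x) {
  attr(x, "base_het") <- NULL
  attr(x, "kind") <- NULL
  class(x) <- NULL
  x
}

is_relmat <- function(x) inherits(x, "relmat")

rel_ids <- function(x) rownames(x)

#' Extract a submatrix of a relationship matrix
#'
#' Returns the rows and columns of `A` for the requested animals, in the
#' requested order, preserving the base-heterozygosity and kind tags. This is
#' how the submatrix of genotyped animals A_g is cut out of the full
#' pedigree matrix.
#'
#' @param A a [relmat].
#' @param ids character vector of animal ids, a subset of `rownames(A)`.
#' @return a [relmat] of order `length(ids)`.
#' @export
extract_submatrix <- function(A, ids) {
  if (!is_relmat(A)) stopf("'A' must be a relmat")
  ids <- as.character(ids)
  missing <- setdiff(ids, rel_ids(A))
  if (length(missing))
    stopf("animal id(s) not in matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  relmat(unclass_relmat(A)[ids, ids, drop = FALSE], ids = ids,
         base_het = attr(A, "base_het"), kind = attr(A, "kind"))
}

#' Rescale a relationship matrix to a different base heterozygosity
#'
#' Applies the panmictic-index transform elementwise:
#' `A_to = (H_from / H_to) * (A - 2) + 2`. Rescaling to the
#' maximum-heterozygosity base (`H_to = 0.5`) gives `2 * H_from * (A - 2) + 2`.
#' The value 2 is a fixed point: a pair of animals with relationship 2 (full
#' identity) stays at 2 under any change of base.
#'
#' @param A a [relmat].
#' @param H_from heterozygosity of the base `A` currently refers to, in (0, 0.5].
#' @param H_to heterozygosity of the target base, in (0, 0.5].
#' @return a [relmat] tagged with `base_het = H_to`.
#' @export
rescale_relationship <- function(A, H_from, H_to) {
  if (!is_relmat(A)) stopf("'A' must be a relmat")
  check_scalar(H_from, "H_from", 0, 0.5, open_lower = TRUE)
  check_scalar(H_to, "H_to", 0, 0.5, open_lower = TRUE)
  out <- (H_from / H_to) * (unclass_relmat(A) - 2) + 2
  relmat(out, ids = rel_ids(A), base_het = H_to, kind = attr(A, "kind"))
}

#' Read and write tab-delimited relationship matrices
#'
#' Matrices are stored as tab-delimited text with animal ids in the header
#' row and in the first column.
#'
#' @param A a [relmat].
#' @param path file path.
#' @param base_het,kind tags to attach on reading (the text format does not
#'   carry them).
#' @return `write_relmat` returns `path` invisibly; `read_relmat` a [relmat].
#' @export
write_relmat <- function(A, path) {
  df <- data.frame(id = rel_ids(A), unclass_relmat(A), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relmat
#' @export
read_relmat <- function(path, base_het = NA_real_, kind = "pedigree") {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  relmat(vals, ids = ids, base_het = base_het, kind = kind)
}
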