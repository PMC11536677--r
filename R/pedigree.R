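#' Pedigrees
#'
#' A pedigree is a data frame with character columns `animal`, `sire`, `dam`;
#' unknown parents are coded `NA` (the text format uses `0`). Constructors
#' validate uniqueness of animal ids and that every named parent appears as
#' an animal record.
#'
#' @param animal,sire,dam vectors of identifiers; `0`, `""` and `NA` denote
#'   an unknown parent.
#' @return a `data.frame` of class `pedigree`.
#' @export
pedigree <- function(animal, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA_character_
    x
  }
  ped <- data.frame(animal = as.character(animal), sire = norm(sire),
                    dam = norm(dam), stringsAsFactors = FALSE)
  if (anyDuplicated(ped$animal))
    stopf("duplicated animal id(s): %s",
          paste(utils::head(unique(ped$animal[duplicated(ped$animal)]), 5),
                collapse = ", "))
  parents <- stats::na.omit(c(ped$sire, ped$dam))
  absent <- setdiff(parents, ped$animal)
  if (length(absent))
    stopf("parent id(s) absent from pedigree records: %s",
          paste(utils::head(absent, 5), collapse = ", "))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d animals, %d founders (both parents unknown)\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam))))
  print(as.data.frame(utils::head(x, 10)), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Topologically sort a pedigree
#'
#' Returns a copy of the pedigree in which every parent precedes its
#' offspring (Kahn's algorithm, stable with respect to the input order).
#' A parentage cycle is an error naming an animal on the cycle.
#'
#' @param ped a [pedigree].
#' @return a sorted [pedigree].
#' @export
validate_and_sort <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  if (n == 0) return(ped)
  if (is_sorted_pedigree(ped)) return(ped)  # stable: valid input is untouched
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- idx[ped$sire]; di <- idx[ped$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    on_cycle <- ped$animal[setdiff(seq_len(n), order)]
    stopf("pedigree contains a parentage cycle involving animal '%s'",
          on_cycle[1])
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

as_pedigree <- function(x) {
  if (inherits(x, "pedigree")) return(x)
  if (is.data.frame(x) && all(c("animal", "sire", "dam") %in% names(x)))
    return(pedigree(x$animal, x$sire, x$dam))
  stopf("cannot interpret input as a pedigree")
}

is_sorted_pedigree <- function(ped) {
  pos <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  ok <- function(p, i) is.na(p) | pos[p] < i
  all(ok(ped$sire, seq_len(nrow(ped)))) && all(ok(ped$dam, seq_len(nrow(ped))))
}

#' Numerator relationship matrix with inbreeding
#'
#' Builds the additive (numerator) relationship matrix A by the tabular
#' method: for animal `i` with parents `s`, `d`,
#' `a_ii = 1 + 0.5 * a_sd` and `a_ij = 0.5 * (a_js + a_jd)` for `j < i`,
#' with an unknown parent contributing 0. Diagonal elements are `1 + F`
#' where `F` is the inbreeding coefficient relative to the pedigree base.
#'
#' @param ped a topologically sorted [pedigree] (see [validate_and_sort()]).
#' @return a [relmat] of kind `"pedigree"` with unknown (`NA`) base
#'   heterozygosity.
#' @export
build_A <- function(ped) {
  ped <- as_pedigree(ped)
  if (!is_sorted_pedigree(ped))
    stopf("pedigree is not sorted; call validate_and_sort() first")
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[j, s]
      if (!is.na(d)) row <- row + 0.5 * A[j, d]
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  relmat(A, ids = ped$animal, base_het = NA_real_, kind = "pedigree")
}

#' Thin genotyped animals to one member per half-sib family
#'
#' Reduces a set of genotyped animals so that close family structure does not
#' dominate a population-structure analysis. Rules, applied in order:
#' one member is selected per paternal half-sib group (genotyped animals
#' sharing a known sire), then one per maternal half-sib group; an animal
#' belonging to both kinds of group is retained only if selected in both.
#' Next, any genotyped animal whose sire and dam are both genotyped is
#' removed as redundant. Finally animals with both parents unknown are always
#' kept. Within a group, `mode = "best"` selects the member with the highest
#' call rate (ties broken by pedigree order) and `mode = "random"` a seeded
#' uniform draw.
#'
#' @param ped a [pedigree].
#' @param genotyped character vector of genotyped animal ids.
#' @param call_rates named numeric vector of per-animal genotype call rates;
#'   required for `mode = "best"`.
#' @param mode `"best"` or `"random"`.
#' @param seed integer seed used by `mode = "random"`.
#' @return character vector of retained animal ids (in pedigree order).
#' @export
halfsib_sample <- function(ped, genotyped, call_rates = NULL,
                           mode = c("best", "random"), seed = 1L) {
  ped <- as_pedigree(ped)
  mode <- match.arg(mode)
  genotyped <- as.character(genotyped)
  unknown <- setdiff(genotyped, ped$animal)
  if (length(unknown))
    stopf("genotyped id(s) not in pedigree: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  sub <- ped[ped$animal %in% genotyped, , drop = FALSE]  # pedigree order
  if (mode == "best") {
    if (is.null(call_rates)) stopf("mode = 'best' requires call_rates")
    miss <- setdiff(sub$animal, names(call_rates))
    if (length(miss))
      stopf("missing call rate for animal(s): %s",
            paste(utils::head(miss, 5), collapse = ", "))
  }

  pick <- function(members) {
    if (length(members) == 1L) return(members)
    if (mode == "best") {
      cr <- call_rates[members]
      members[which.max(cr)]  # which.max keeps the first (pedigree-order) tie
    } else {
      members[sample.int(length(members), 1L)]
    }
  }

  with_local_seed(if (mode == "random") seed else NULL, {
    pat_groups <- split(sub$animal, sub$sire)  # drops NA sires
    mat_groups <- split(sub$animal, sub$dam)
    sel_pat <- unlist(lapply(pat_groups, pick), use.names = FALSE)
    sel_mat <- unlist(lapply(mat_groups, pick), use.names = FALSE)
    keep <- rep(TRUE, nrow(sub))
    has_pat <- !is.na(sub$sire)
    has_mat <- !is.na(sub$dam)
    keep[has_pat & !(sub$animal %in% sel_pat)] <- FALSE
    keep[has_mat & !(sub$animal %in% sel_mat)] <- FALSE
    # redundant offspring of two genotyped parents
    both_geno <- !is.na(sub$sire) & !is.na(sub$dam) &
      sub$sire %in% genotyped & sub$dam %in% genotyped
    keep[both_geno] <- FALSE
    # forced keep: founders with no pedigree information at all
    keep[is.na(sub$sire) & is.na(sub$dam)] <- TRUE
    sub$animal[keep]
  })
}

#' Read and write pedigree CSV files
#'
#' The text format is a CSV with header `animal,sire,dam`, unknown parents
#' coded `0`.
#'
#' @param ped a [pedigree].
#' @param path file path.
#' @return `read_pedigree` returns a [pedigree]; `write_pedigree` the path,
#'   invisibly.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("animal", "sire", "dam") %in% names(df)))
    stopf("pedigree file '%s' lacks animal,sire,dam header", path)
  pedigree(df$animal, df$sire, df$dam)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  out <- data.frame(animal = ped$animal,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
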