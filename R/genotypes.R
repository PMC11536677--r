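#' Genotype matrices
#'
#' A `geno` object holds an `n x m` integer matrix of reference-allele counts
#' (0/1/2, `NA` for missing) with animal ids as rownames, marker ids as
#' colnames, and an optional marker map (`marker`, `chromosome`, `position`).
#'
#' @param counts numeric/integer matrix of 0/1/2 counts, `NA` for missing.
#' @param animal_ids,marker_ids identifiers; default taken from dimnames.
#' @param map optional data frame with columns `marker`, `chromosome`,
#'   `position` covering (at least) all markers.
#' @return an object of class `geno`.
#' @export
geno <- function(counts, animal_ids = rownames(counts),
                 marker_ids = colnames(counts), map = NULL) {
  counts <- as.matrix(counts)
  if (is.null(animal_ids)) animal_ids <- sprintf("A%d", seq_len(nrow(counts)))
  if (is.null(marker_ids)) marker_ids <- sprintf("M%d", seq_len(ncol(counts)))
  animal_ids <- as.character(animal_ids); marker_ids <- as.character(marker_ids)
  if (length(animal_ids) != nrow(counts) || length(marker_ids) != ncol(counts))
    stopf("id lengths do not match genotype matrix dimensions")
  if (anyDuplicated(animal_ids)) stopf("duplicated animal ids")
  if (anyDuplicated(marker_ids)) stopf("duplicated marker ids")
  bad <- !(counts %in% c(0, 1, 2) | is.na(counts))
  if (any(bad)) stopf("genotype counts must be 0, 1, 2 or NA")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(animal_ids, marker_ids)
  if (!is.null(map)) {
    if (!all(c("marker", "chromosome", "position") %in% names(map)))
      stopf("map must have columns marker, chromosome, position")
    missing <- setdiff(marker_ids, as.character(map$marker))
    if (length(missing))
      stopf("map does not cover marker(s): %s",
            paste(utils::head(missing, 5), collapse = ", "))
    map <- map[match(marker_ids, as.character(map$marker)), , drop = FALSE]
    rownames(map) <- NULL
  }
  structure(list(counts = counts, map = map), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf("<geno> %d animals x %d markers, %.2f%% missing%s\n",
              nrow(x$counts), ncol(x$counts),
              100 * mean(is.na(x$counts)),
              if (is.null(x$map)) "" else ", with marker map"))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$counts)

geno_subset <- function(g, animals = NULL, markers = NULL) {
  counts <- g$counts
  if (!is.null(animals)) counts <- counts[animals, , drop = FALSE]
  if (!is.null(markers)) counts <- counts[, markers, drop = FALSE]
  geno(counts, map = if (is.null(g$map)) NULL else
    g$map[g$map$marker %in% colnames(counts), , drop = FALSE])
}

#' Per-animal and per-marker call rates
#' @param g a [geno].
#' @return a list with numeric vectors `animal` and `marker`.
#' @export
call_rates <- function(g) {
  list(animal = rowMeans(!is.na(g$counts)),
       marker = colMeans(!is.na(g$counts)))
}

#' Minor allele frequencies from observed counts
#' @param g a [geno].
#' @return named numeric vector of per-marker MAF (missing entries ignored).
#' @export
maf <- function(g) {
  p <- colMeans(g$counts, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Marker quality control
#'
#' Removes markers with call rate below `callrate_min`, minor allele
#' frequency below `maf_min`, and (optionally) markers whose genotype vector
#' is identical to an earlier retained marker. Rules are applied in that
#' order; the exclusion log records the first rule that removed each marker.
#'
#' @param g a [geno].
#' @param callrate_min minimum marker call rate (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param drop_redundant drop exact duplicates of an earlier marker.
#' @return a [geno] with attribute `"qc_log"`: a data frame
#'   `marker, excluded, reason`.
#' @export
qc_filter <- function(g, callrate_min = 0.95, maf_min = 0.01,
                      drop_redundant = TRUE) {
  check_scalar(callrate_min, "callrate_min", 0, 1)
  check_scalar(maf_min, "maf_min", 0, 1)
  cr <- call_rates(g)$marker
  fq <- maf(g)
  m <- ncol(g$counts)
  reason <- rep(NA_character_, m)
  reason[cr < callrate_min] <- "call_rate"
  reason[is.na(reason) & (is.na(fq) | fq < maf_min)] <- "maf"
  if (drop_redundant) {
    cand <- which(is.na(reason))
    if (length(cand) > 1) {
      key <- apply(g$counts[, cand, drop = FALSE], 2,
                   function(z) paste(ifelse(is.na(z), "N", z), collapse = ""))
      reason[cand[duplicated(key)]] <- "redundant"
    }
  }
  keep <- which(is.na(reason))
  if (!length(keep)) stopf("quality control removed every marker")
  out <- geno_subset(g, markers = keep)
  attr(out, "qc_log") <- data.frame(marker = colnames(g$counts),
                                    excluded = !is.na(reason),
                                    reason = reason)
  out
}

#' Positional SNP thinning: keep every other marker
#'
#' Within each chromosome, markers are ranked by position and the odd ranks
#' (1st, 3rd, ...) kept. This reduces linkage disequilibrium between
#' neighbouring SNPs while retaining half of the panel.
#'
#' @param g a [geno] with a marker map.
#' @return a thinned [geno].
#' @export
thin_every_other <- function(g) {
  if (is.null(g$map)) stopf("thinning requires a marker map")
  if (anyNA(g$map$position)) stopf("marker map has missing positions")
  keep <- unlist(lapply(split(seq_len(nrow(g$map)), g$map$chromosome),
                        function(i) {
                          i <- i[order(g$map$position[i])]
                          i[seq(1, length(i), by = 2)]
                        }), use.names = FALSE)
  geno_subset(g, markers = sort(keep))
}

#' Observed per-animal heterozygosity
#'
#' Fraction of heterozygous loci per animal: `H_T = (# genotype 1) / m`.
#'
#' @param g a [geno] without missing entries.
#' @return named numeric vector of per-animal `H_T`.
#' @export
observed_heterozygosity <- function(g) {
  if (ncol(g$counts) == 0) stopf("no markers")
  if (anyNA(g$counts)) stopf("missing genotypes; run QC/imputation first")
  rowMeans(g$counts == 1L)
}

#' Genomic relationship matrix at a fixed genetic base
#'
#' VanRaden's first method with the base allele frequency fixed (by default)
#' at 0.5 for every locus: genotype counts are centred as
#' `z - 1 - 2 * (p_B - 0.5)` and the cross-product divided by
#' `c = sum_j 2 p_Bj q_Bj = m * H_B`. With `p_B = 0.5` every diagonal element
#' satisfies `G_TT = 2 - H_T / H_B`, i.e. `1 + F` of the animal relative to a
#' base population of maximum heterozygosity, which is what makes this G
#' combinable with the metafounder algebra. Missing genotypes are imputed at
#' the centred base expectation (0).
#'
#' @param g a [geno].
#' @param base_freq scalar or per-marker base allele frequency in (0, 1);
#'   default 0.5.
#' @return a [relmat] of kind `"genomic"` tagged with
#'   `base_het = mean(2 p_B q_B)`.
#' @export
build_G <- function(g, base_freq = 0.5) {
  m <- ncol(g$counts)
  if (m == 0) stopf("no markers")
  if (length(base_freq) == 1L) base_freq <- rep(base_freq, m)
  if (length(base_freq) != m)
    stopf("base_freq must be scalar or one value per marker")
  if (any(base_freq <= 0 | base_freq >= 1))
    stopf("base allele frequencies must lie strictly in (0, 1)")
  M <- sweep(g$counts, 2, 1 + 2 * (base_freq - 0.5))
  M[is.na(M)] <- 0
  c_scale <- sum(2 * base_freq * (1 - base_freq))
  G <- tcrossprod(M) / c_scale
  relmat(G, ids = rownames(g$counts),
         base_het = mean(2 * base_freq * (1 - base_freq)), kind = "genomic")
}

#' Read and write genotype matrices
#'
#' Tab-delimited text: animal ids in the first column (`animal`), marker ids
#' in the header row; missing genotypes written as `NA`. `read_genotypes`
#' optionally attaches a marker map read with [read_marker_map()]. A
#' PLINK-style `.raw` additive export (header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by marker columns) is also
#' accepted by `read_genotypes`.
#'
#' @param g a [geno].
#' @param path file path.
#' @param map optional marker map data frame.
#' @return `read_genotypes` a [geno]; writers return the path invisibly.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(animal = rownames(g$counts), g$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map = NULL) {
  head1 <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  plink <- identical(utils::head(head1, 6),
                     c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (plink) {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE)
    counts <- as.matrix(df[, -(1:6), drop = FALSE])
    rownames(counts) <- as.character(df$IID)
    # PLINK suffixes marker names with the counted allele, e.g. "snp1_A"
    colnames(counts) <- sub("_[ACGT0-9]+$", "", colnames(counts))
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- as.character(df[[1]])
  }
  geno(counts, map = map)
}

#' @rdname write_genotypes
#' @export
read_marker_map <- function(path) {
  map <- utils::read.csv(path)
  if (!all(c("marker", "chromosome", "position") %in% names(map)))
    stopf("marker map '%s' lacks marker,chromosome,position header", path)
  map$marker <- as.character(map$marker)
  map
}

#' @rdname write_genotypes
#' @export
write_marker_map <- function(map, path) {
  utils::write.csv(map[, c("marker", "chromosome", "position")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
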