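#' Metafounder self-relationship matrices
#'
#' A `gamma_mat` is a symmetric `k x k` matrix of metafounder self- and
#' cross-relationships together with the genetic base it refers to:
#' `"max-het"` (the hypothetical base of maximum heterozygosity, written
#' Gamma_X), `"pedigree-base"` (rescaled to the heterozygosity of the actual
#' pedigree base, Gamma_B), or `"standardized"` (Gamma_B brought to the form
#' of a conventional relationship matrix, Gamma_B*).
#'
#' @param values symmetric `k x k` matrix.
#' @param reference one of `"max-het"`, `"pedigree-base"`, `"standardized"`.
#' @param base_het the pedigree-base heterozygosity used for the latter two
#'   forms (`NA` for `"max-het"`).
#' @return an object of class `gamma_mat`.
#' @export
gamma_mat <- function(values, reference = c("max-het", "pedigree-base",
                                            "standardized"),
                      base_het = NA_real_) {
  reference <- match.arg(reference)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("Gamma must be square")
  if (nrow(values) > 0 && max(abs(values - t(values))) > 1e-10)
    stopf("Gamma is not symmetric within 1e-10")
  if (reference == "max-het" && nrow(values) > 0 &&
      (min(values) < -2 - 1e-9 || max(values) > 2 + 1e-9))
    stopf("Gamma_X entries must lie in [-2, 2]")
  if (is.null(rownames(values)))
    dimnames(values) <- list(paste0("S", seq_len(nrow(values))),
                             paste0("S", seq_len(nrow(values))))
  structure(values, reference = reference, base_het = as.numeric(base_het),
            class = c("gamma_mat", "matrix", "array"))
}

#' @export
print.gamma_mat <- function(x, ...) {
  cat(sprintf("<gamma_mat> k = %d, reference = %s%s\n", nrow(x),
              attr(x, "reference"),
              if (is.na(attr(x, "base_het"))) ""
              else sprintf(" (H_B = %.4f)", attr(x, "base_het"))))
  y <- x
  attributes(y) <- attributes(y)[c("dim", "dimnames")]
  print(y, ...)
  invisible(x)
}

gamma_values <- function(x) {
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

#' Metafounder relationships from strata allele frequencies
#'
#' Computes `Gamma = 8 * (P' - 0.5)(P - 0.5) / m` from an `m x k` matrix of
#' strata allele frequencies. The implicit reference is the base of maximum
#' heterozygosity (all frequencies 0.5): a stratum whose frequencies all sit
#' at 0.5 has self-relationship 0, one whose loci are all fixed has
#' self-relationship 2 (fully drifted).
#'
#' @param P `m x k` matrix of strata allele frequencies in `[0, 1]`.
#' @return a [gamma_mat] with reference `"max-het"`.
#' @export
gamma_matrix <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) == 0) stopf("no markers in P")
  if (min(P) < 0 || max(P) > 1) stopf("allele frequencies must lie in [0, 1]")
  D <- P - 0.5
  G <- 8 * crossprod(D) / nrow(P)
  if (!is.null(colnames(P))) dimnames(G) <- list(colnames(P), colnames(P))
  gamma_mat(G, reference = "max-het")
}

#' GLS estimation of strata allele frequencies
#'
#' Estimates, marker by marker, the strata allele frequencies
#' `p_j = 0.5 * (Q' A_g^-1 Q)^-1 Q' A_g^-1 z_j` (Gengler-style generalized
#' least squares), which corrects the estimates for the pedigree relatedness
#' among the genotyped animals so that family structure already represented
#' in `A_g` is not double counted. `A_g` is factored once and reused across
#' markers. Estimates falling outside `[0, 1]` are clipped and counted.
#'
#' @param Q `n x k` ancestry matrix for the animals of `A_g` (or of
#'   `subset`).
#' @param A_g a [relmat] for the same animals.
#' @param g a [geno] with the same animals (missing entries mean-imputed).
#' @param subset optional character vector of animal ids to restrict the
#'   estimation to (e.g. animals with most of their ancestry traceable to a
#'   fixed base period).
#' @return an `m x k` matrix of frequencies with attribute `"n_clipped"`,
#'   the count of out-of-range estimates before clipping.
#' @export
gls_strata_frequencies <- function(Q, A_g, g, subset = NULL) {
  Q <- as.matrix(Q)
  ids <- rel_ids(A_g)
  if (!is.null(subset)) {
    subset <- as.character(subset)
    A_g <- extract_submatrix(A_g, subset)
    if (!is.null(rownames(Q))) Q <- Q[subset, , drop = FALSE]
    ids <- subset
  }
  if (nrow(Q) != nrow(A_g))
    stopf("Q has %d rows but A_g is of order %d", nrow(Q), nrow(A_g))
  Z <- g$counts[ids, , drop = FALSE]
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    na_idx <- which(is.na(Z), arr.ind = TRUE)
    Z[na_idx] <- mu[na_idx[, 2]]
  }
  R <- tryCatch(chol(unclass_relmat(A_g)),
                error = function(e) stopf("A_g is singular or not positive definite"))
  # whiten: A^-1 x = R^-1 (R^-T x)
  Ainv_mult <- function(X)
    backsolve(R, backsolve(R, X, transpose = TRUE))
  B <- Ainv_mult(Q)                       # A^-1 Q, n x k
  QtAQ <- crossprod(Q, B)
  if (rcond(QtAQ) < 1e-12)
    stopf("Q is rank deficient given A_g; reduce the number of strata")
  Pt <- 0.5 * solve(QtAQ, crossprod(B, Z))   # k x m
  P <- t(Pt)
  n_clipped <- sum(P < 0 | P > 1)
  P <- pmin(pmax(P, 0), 1)
  dimnames(P) <- list(colnames(Z), colnames(Q))
  attr(P, "n_clipped") <- n_clipped
  P
}

#' Pivotal gamma from the means of G and A_g
#'
#' The scalar self-relationship of the whole pedigree base relative to a
#' base of maximum heterozygosity, estimated from the overall means of the
#' genomic and pedigree relationship matrices:
#' `gamma = (mean(G) - mean(A_g)) / (1 - mean(A_g) / 2)`, valid when G is
#' built at base allele frequency 0.5. It doubles as an estimate of the
#' pedigree-base heterozygosity through `H_B = 0.5 - 0.25 * gamma`.
#'
#' @param G,A_g [relmat]s over the same animals in the same order.
#' @return scalar gamma.
#' @export
pivotal_gamma <- function(G, A_g) {
  if (!identical(rel_ids(G), rel_ids(A_g)))
    stopf("G and A_g must cover the same animals in the same order")
  mA <- mean(unclass_relmat(A_g))
  if (abs(1 - mA / 2) < 1e-12)
    stopf("mean(A_g) = 2: pivotal gamma is undefined")
  (mean(unclass_relmat(G)) - mA) / (1 - mA / 2)
}

#' Convert between a base's gamma and its heterozygosity
#'
#' A base population with average expected heterozygosity `H` in (0, 0.5]
#' corresponds, relative to the maximum-heterozygosity base, to the
#' self-relationship `gamma = 2 (1 - 2H) = 4 (0.5 - H)`; conversely
#' `H = 0.5 - 0.25 * gamma` for `gamma` in [0, 2).
#'
#' @param gamma,H exactly one must be given.
#' @return a list with both `gamma` and `H`.
#' @export
gamma_het_convert <- function(gamma = NULL, H = NULL) {
  if (is.null(gamma) == is.null(H))
    stopf("supply exactly one of 'gamma' or 'H'")
  if (!is.null(gamma)) {
    check_scalar(gamma, "gamma", 0, 2, open_upper = TRUE)
    H <- 0.5 - 0.25 * gamma
  } else {
    check_scalar(H, "H", 0, 0.5, open_lower = TRUE)
    gamma <- 4 * (0.5 - H)
  }
  list(gamma = gamma, H = H)
}

#' Rescale Gamma from the maximum-heterozygosity base to the pedigree base
#'
#' `Gamma_B = (1 / (2 H_B)) * (Gamma_X - 2) + 2`, applied elementwise. The
#' value 2 is a fixed point of the map.
#'
#' @param gamma_X a [gamma_mat] with reference `"max-het"`.
#' @param H_B pedigree-base heterozygosity in (0, 0.5].
#' @return a [gamma_mat] with reference `"pedigree-base"`.
#' @export
rescale_gamma_to_base <- function(gamma_X, H_B) {
  stopifnot(inherits(gamma_X, "gamma_mat"))
  if (attr(gamma_X, "reference") != "max-het")
    stopf("input Gamma must refer to the maximum-heterozygosity base")
  check_scalar(H_B, "H_B", 0, 0.5, open_lower = TRUE)
  gamma_mat((gamma_values(gamma_X) - 2) / (2 * H_B) + 2,
            reference = "pedigree-base", base_het = H_B)
}

#' Standardize Gamma_B to relationship-matrix form
#'
#' `Gamma_B* = (I - D_B) + Gamma_B` with `D_B = diag(0.5 * diag(Gamma_B))`:
#' diagonal elements become `1 + 0.5 * diag(Gamma_B)` (the `1 + F` form of a
#' conventional relationship matrix) while off-diagonals are unchanged.
#'
#' @param gamma_B a [gamma_mat] with reference `"pedigree-base"`.
#' @return a [gamma_mat] with reference `"standardized"`.
#' @export
standardize_gamma <- function(gamma_B) {
  stopifnot(inherits(gamma_B, "gamma_mat"))
  if (attr(gamma_B, "reference") != "pedigree-base")
    stopf("input Gamma must refer to the pedigree base")
  V <- gamma_values(gamma_B)
  diag(V) <- 1 + 0.5 * diag(V)
  gamma_mat(V, reference = "standardized",
            base_het = attr(gamma_B, "base_het"))
}

#' Inject stratification into the pedigree relationship matrix
#'
#' `A_B^Gamma = A_g + Q (Gamma_B* - I) Q'`: adds the metafounder
#' relationships, weighted by the animals' ancestry proportions, to the
#' pedigree submatrix while staying at the pedigree base.
#'
#' @param A_g a [relmat] of the genotyped animals.
#' @param Q `n x k` ancestry matrix, rows matching `A_g`.
#' @param gamma_Bstar a [gamma_mat] with reference `"standardized"`.
#' @return a [relmat] of kind `"metafounder"` at the pedigree base.
#' @export
approx_A_gamma <- function(A_g, Q, gamma_Bstar) {
  stopifnot(inherits(gamma_Bstar, "gamma_mat"))
  if (attr(gamma_Bstar, "reference") != "standardized")
    stopf("Gamma must be standardized (Gamma_B*) before combination with A_g")
  Q <- as.matrix(Q)
  if (nrow(Q) != nrow(A_g))
    stopf("Q has %d rows but A_g is of order %d", nrow(Q), nrow(A_g))
  if (ncol(Q) != nrow(gamma_Bstar))
    stopf("Q has %d columns but Gamma is of order %d", ncol(Q),
          nrow(gamma_Bstar))
  V <- gamma_values(gamma_Bstar)
  out <- unclass_relmat(A_g) + Q %*% (V - diag(nrow(V))) %*% t(Q)
  out <- (out + t(out)) / 2
  relmat(out, ids = rel_ids(A_g), base_het = attr(gamma_Bstar, "base_het"),
         kind = "metafounder")
}

#' Full chain: strata frequencies to the metafounder-augmented matrix
#'
#' Runs the complete algebra: `Gamma_X` from the strata allele frequencies,
#' rescale to the pedigree base `H_B`, standardize, combine with `A_g`, and
#' finally rescale the result to the maximum-heterozygosity base so it is
#' directly comparable with a G built at base frequency 0.5. When `H_B` is
#' not supplied it is derived from the pivotal gamma of `G` and `A_g`
#' (which is why `G` is an argument). With a single stratum the chain
#' collapses exactly to Christensen's scalar rescaling
#' `2 H_B (A_g - 2) + 2`.
#'
#' @param A_g pedigree submatrix of the genotyped animals ([relmat]).
#' @param Q `n x k` ancestry matrix.
#' @param P `m x k` strata allele frequency matrix.
#' @param H_B pedigree-base heterozygosity; derived from `G` if missing.
#' @param G genomic [relmat] at base 0.5, needed only when `H_B` is missing.
#' @return a [relmat] `A^Gamma` at the maximum-heterozygosity base, with
#'   attribute `"provenance"`: a list holding `gamma_X`, `gamma_B`,
#'   `gamma_Bstar`, `H_B`, `pivotal_gamma` and clipping information.
#' @export
build_A_gamma <- function(A_g, Q, P, H_B = NULL, G = NULL) {
  piv <- NA_real_
  if (is.null(H_B)) {
    if (is.null(G)) stopf("supply either H_B or G to derive it from")
    piv <- pivotal_gamma(G, A_g)
    if (piv < 0 || piv >= 2)
      stopf("pivotal gamma %.4f is outside [0, 2); supply H_B explicitly", piv)
    H_B <- gamma_het_convert(gamma = piv)$H
  }
  gX <- gamma_matrix(P)
  gB <- rescale_gamma_to_base(gX, H_B)
  gBs <- standardize_gamma(gB)
  A_B_gamma <- approx_A_gamma(A_g, Q, gBs)
  out <- rescale_relationship(A_B_gamma, H_from = H_B, H_to = 0.5)
  attr(out, "provenance") <- list(gamma_X = gX, gamma_B = gB,
                                  gamma_Bstar = gBs, H_B = H_B,
                                  pivotal_gamma = piv,
                                  n_clipped = attr(P, "n_clipped"))
  out
}

#' Write a provenance record as a key-value text file
#'
#' @param A_gamma a [relmat] from [build_A_gamma()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_provenance <- function(A_gamma, path) {
  pr <- attr(A_gamma, "provenance")
  if (is.null(pr)) stopf("matrix carries no provenance record")
  lines <- c(sprintf("k\t%d", nrow(pr$gamma_X)),
             sprintf("pivotal_gamma\t%.10g", pr$pivotal_gamma),
             sprintf("H_B\t%.10g", pr$H_B),
             sprintf("n_clipped\t%s", pr$n_clipped %||% "NA"),
             sprintf("n_animals\t%d", nrow(A_gamma)))
  writeLines(lines, path)
  invisible(path)
}
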