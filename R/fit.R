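#' Fit the metafounder model at a chosen number of strata
#'
#' The one-call interface to the whole method. Given genotypes and a
#' pedigree it: (1) builds the pedigree submatrix `A_g` of the genotyped
#' animals and the genomic matrix `G` at base allele frequency 0.5; (2)
#' obtains a strata model at `k` — by the built-in EM estimator, optionally
#' on a half-sib-thinned sample of the animals, or from ADMIXTURE `.Q`/`.P`
#' files; (3) extends the ancestry matrix to all genotyped animals — fitted
#' animals keep their fitted rows, the rest are filled by regression on the
#' strata allele frequencies; (4) estimates GLS strata
#' allele frequencies correcting for pedigree relatedness; (5) builds the
#' metafounder matrix `Gamma` and the augmented relationship matrix
#' `A^Gamma`, rescaled to the base of `G`; and (6) evaluates the
#' compatibility of `A^Gamma` (and, for reference, `A_g`) with `G`.
#'
#' @param g a [geno] of the genotyped animals (post QC).
#' @param ped a [pedigree] covering the genotyped animals.
#' @param k number of strata.
#' @param sample_mode `"full"`, `"halfsib-best"` or `"halfsib-random"`:
#'   which animals enter the strata estimation (see [halfsib_sample()]).
#' @param strata_files optional `list(q = , p = )` of ADMIXTURE output paths
#'   to use instead of the built-in estimator.
#' @param with_intercept include an intercept column in the Q projection and
#'   flag animals with intercept above 0.1.
#' @param H_B pedigree-base heterozygosity; derived from the pivotal gamma
#'   of `G` and `A_g` when missing.
#' @param seed integer seed.
#' @param ... passed to [fit_admixture_lite()].
#' @return an object of class `metafounder_fit` with components `A_g`, `G`,
#'   `A_gamma`, `gamma` (the provenance chain of Gamma matrices), `strata`
#'   (the `strata_fit`), `Q` (projected, all animals), `P_gls`,
#'   `pivotal_gamma`, `H_B`, `evaluation` (regression and mean-difference
#'   diagnostics for both `A_g` and `A^Gamma`), and `projection` (intercept
#'   flags when requested).
#' @export
fit_metafounders <- function(g, ped, k, sample_mode = c("full", "halfsib-best",
                                                        "halfsib-random"),
                             strata_files = NULL, with_intercept = FALSE,
                             H_B = NULL, seed = 1L, ...) {
  sample_mode <- match.arg(sample_mode)
  ped <- validate_and_sort(ped)
  ids <- rownames(g$counts)
  A_g <- extract_submatrix(build_A(ped), ids)
  G <- build_G(g)
  fit_ids <- switch(sample_mode,
    "full" = ids,
    "halfsib-best" = halfsib_sample(ped, ids,
                                    call_rates = call_rates(g)$animal,
                                    mode = "best"),
    "halfsib-random" = halfsib_sample(ped, ids, mode = "random", seed = seed))
  strata <- if (!is.null(strata_files))
    read_admixture(strata_files$q, strata_files$p, ids = fit_ids,
                   marker_ids = colnames(g$counts),
                   genotypes = g)
  else
    fit_admixture_lite(geno_subset(g, animals = fit_ids), k = k, seed = seed,
                       ...)
  proj <- project_Q(strata$P_A, g, with_intercept = with_intercept)
  # fitted animals keep their fitted ancestry rows; the regression projection
  # covers only the animals absent from the strata fit
  Q_all <- proj$Q
  Q_all[rownames(strata$Q), ] <- strata$Q
  proj$Q <- Q_all
  P_gls <- gls_strata_frequencies(proj$Q, A_g, g)
  piv <- pivotal_gamma(G, A_g)
  if (is.null(H_B)) H_B <- gamma_het_convert(gamma = piv)$H
  A_gamma <- build_A_gamma(A_g, proj$Q, P_gls, H_B = H_B)
  attr(A_gamma, "provenance")$pivotal_gamma <- piv
  eval_tab <- rbind(
    A_g = c(regress_matrices(A_g, G), mean_differences(G, A_g)),
    A_gamma = c(regress_matrices(A_gamma, G), mean_differences(G, A_gamma)))
  structure(list(A_g = A_g, G = G, A_gamma = A_gamma,
                 gamma = attr(A_gamma, "provenance"),
                 strata = strata, Q = proj$Q, P_gls = P_gls,
                 pivotal_gamma = piv, H_B = H_B,
                 evaluation = as.data.frame(eval_tab),
                 projection = proj, k = strata$k,
                 sample_mode = sample_mode, fit_ids = fit_ids,
                 call = match.call()),
            class = "metafounder_fit")
}

#' @export
print.metafounder_fit <- function(x, ...) {
  cat(sprintf("Metafounder fit: k = %d strata, %d genotyped animals\n",
              x$k, nrow(x$A_g)))
  cat(sprintf("  pivotal gamma = %.3f  (pedigree-base heterozygosity H_B = %.3f)\n",
              x$pivotal_gamma, x$H_B))
  ev <- x$evaluation
  cat(sprintf("  A_g     on G: a = %6.3f  b = %5.3f  R2 = %5.3f\n",
              ev["A_g", "a"], ev["A_g", "b"], ev["A_g", "r2"]))
  cat(sprintf("  A^Gamma on G: a = %6.3f  b = %5.3f  R2 = %5.3f\n",
              ev["A_gamma", "a"], ev["A_gamma", "b"], ev["A_gamma", "r2"]))
  invisible(x)
}

#' @export
summary.metafounder_fit <- function(object, ...) {
  print(object)
  cat("\nGamma (metafounder self-relationships, max-heterozygosity base):\n")
  print(round(gamma_values(object$gamma$gamma_X), 3))
  cat("\nMean ancestry proportions:\n")
  print(round(colMeans(object$Q), 4))
  cat(sprintf("\nMean differences to G (all / diagonal): %.4f / %.4f\n",
              object$evaluation["A_gamma", "mean_diff"],
              object$evaluation["A_gamma", "diag_diff"]))
  if (!is.null(object$projection$intercepts))
    cat(sprintf("Animals flagged by projection intercept > 0.1: %d\n",
                length(object$projection$flagged)))
  invisible(object)
}

#' @export
coef.metafounder_fit <- function(object, which = c("gamma", "Q", "P"), ...) {
  which <- match.arg(which)
  switch(which,
         gamma = gamma_values(object$gamma$gamma_X),
         Q = object$Q,
         P = object$P_gls)
}

#' @export
residuals.metafounder_fit <- function(object, ...) {
  unclass_relmat(object$G) - unclass_relmat(object$A_gamma)
}

#' @export
predict.metafounder_fit <- function(object, newdata, ...) {
  project_Q(object$strata$P_A, newdata, ...)$Q
}

#' Principal-component comparison plot of A^Gamma and G
#'
#' Plots the first two eigenvalue-scaled principal components of `G`,
#' `A_g` and `A^Gamma` side by side (see [pca_scaled()]).
#'
#' @param x a `metafounder_fit`.
#' @param ... passed to `plot`.
#' @export
plot.metafounder_fit <- function(x, ...) {
  mats <- list(G = x$G, A_g = x$A_g, `A^Gamma` = x$A_gamma)
  graphics::par(mfrow = c(1, 3))
  for (nm in names(mats)) {
    pc <- pca_scaled(mats[[nm]], 2)
    graphics::plot(pc$PC1, pc$PC2, xlab = "PC1", ylab = "PC2", main = nm, ...)
  }
  invisible(x)
}
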