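#' Element regression of one relationship matrix on another
#'
#' Ordinary least squares of all `n^2` elements of `A_like` on the
#' corresponding elements of `G` (optionally the upper triangle including
#' the diagonal, which changes the weighting of diagonal elements). When
#' `A_like` and `G` are on the same genetic base the intercept should be
#' near 0 and the slope near 1; a slope above 1 indicates overdispersion of
#' `A_like`. The R-squared is invariant under affine transforms of
#' `A_like`, so rescaling a matrix between bases never changes its fit.
#'
#' @param A_like,G [relmat]s over the same animals in the same order.
#' @param elements `"all"` (default) or `"upper"` (upper triangle with
#'   diagonal).
#' @return named numeric vector `c(a, b, r2)`.
#' @export
regress_matrices <- function(A_like, G, elements = c("all", "upper")) {
  elements <- match.arg(elements)
  if (!identical(rel_ids(A_like), rel_ids(G)))
    stopf("matrices must cover the same animals in the same order")
  x <- unclass_relmat(G); y <- unclass_relmat(A_like)
  if (elements == "upper") {
    keep <- upper.tri(x, diag = TRUE)
    x <- x[keep]; y <- y[keep]
  }
  x <- as.vector(x); y <- as.vector(y)
  vx <- stats::var(x)
  if (vx == 0) stopf("elements of G are constant; slope undefined")
  b <- stats::cov(x, y) / vx
  a <- mean(y) - b * mean(x)
  vy <- stats::var(y)
  r2 <- if (vy == 0) 1 else (b^2 * vx) / vy
  c(a = a, b = b, r2 = r2)
}

#' Mean differences between G and an A-variant
#'
#' Returns `mean(G) - mean(A_like)` over all elements and over the diagonal.
#' Both are 0 when the matrices refer to the same overall heterozygosity; in
#' particular, rescaling `A_g` by its own pivotal gamma drives the overall
#' mean difference to exactly 0.
#'
#' @param G,A_like [relmat]s over the same animals in the same order.
#' @return named numeric vector `c(mean_diff, diag_diff)`.
#' @export
mean_differences <- function(G, A_like) {
  if (!identical(rel_ids(G), rel_ids(A_like)))
    stopf("matrices must cover the same animals in the same order")
  g <- unclass_relmat(G); a <- unclass_relmat(A_like)
  c(mean_diff = mean(g) - mean(a),
    diag_diff = mean(diag(g)) - mean(diag(a)))
}

#' Eigenvalue-scaled principal components of a relationship matrix
#'
#' Eigendecomposition with components ordered by decreasing eigenvalue and
#' coordinates computed as eigenvector times eigenvalue (not its square
#' root), so the spread of a component reflects the share of variance it
#' carries. Signs are fixed so that each component's largest-magnitude
#' loading is positive.
#'
#' @param M a [relmat] (or symmetric matrix).
#' @param n_components number of components to return.
#' @return a data frame of coordinates (`PC1`, `PC2`, ...) with animal ids
#'   as rownames and the eigenvalues as attribute `"eigenvalues"`.
#' @export
pca_scaled <- function(M, n_components = 2L) {
  V <- if (is_relmat(M)) unclass_relmat(M) else as.matrix(M)
  if (n_components > nrow(V))
    stopf("n_components (%d) exceeds matrix order (%d)", n_components,
          nrow(V))
  eig <- eigen(V, symmetric = TRUE)
  coords <- sapply(seq_len(n_components), function(j) {
    v <- eig$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    v * eig$values[j]
  })
  coords <- matrix(coords, nrow = nrow(V))
  dimnames(coords) <- list(rownames(V), paste0("PC", seq_len(n_components)))
  out <- as.data.frame(coords)
  attr(out, "eigenvalues") <- eig$values
  out
}

#' Sweep the number of strata and evaluate A^Gamma against G
#'
#' For each `k` in `k_range`: obtain the strata model on the selected sample
#' of animals (built-in EM fit, or ADMIXTURE files via `strata_files`),
#' project ancestry proportions onto all genotyped animals, estimate GLS
#' strata allele frequencies against `A_g`, build `A^Gamma`, and evaluate it
#' against `G` by element regression and mean differences. A failure at one
#' `k` is recorded in that row and the sweep continues.
#'
#' @param g a [geno] of all genotyped animals (post QC).
#' @param ped a [pedigree] covering the genotyped animals.
#' @param k_range integer vector of strata counts to evaluate.
#' @param sample_mode `"full"` (fit on all animals), `"halfsib-best"` or
#'   `"halfsib-random"` (one member per half-sib family, see
#'   [halfsib_sample()]).
#' @param strata_files optional named list mapping `k` to
#'   `list(q = path, p = path)` of ADMIXTURE output to use instead of the
#'   built-in estimator.
#' @param with_intercept use an intercept column when projecting Q.
#' @param seed integer seed (EM initialisation and random sampling).
#' @param ... passed to [fit_admixture_lite()].
#' @return an object of class `metafounder_sweep`: a data frame with columns
#'   `k, a, b, r2, mean_diff, diag_diff, error` plus attributes (`fits`,
#'   settings).
#' @export
k_sweep <- function(g, ped, k_range, sample_mode = c("full", "halfsib-best",
                                                     "halfsib-random"),
                    strata_files = NULL, with_intercept = FALSE, seed = 1L,
                    ...) {
  sample_mode <- match.arg(sample_mode)
  if (!length(k_range)) stopf("k_range is empty")
  k_range <- sort(unique(as.integer(k_range)))
  ped <- validate_and_sort(ped)
  A <- build_A(ped)
  ids <- rownames(g$counts)
  A_g <- extract_submatrix(A, ids)
  G <- build_G(g)
  fit_ids <- switch(sample_mode,
    "full" = ids,
    "halfsib-best" = halfsib_sample(ped, ids,
                                    call_rates = call_rates(g)$animal,
                                    mode = "best"),
    "halfsib-random" = halfsib_sample(ped, ids, mode = "random", seed = seed))
  rows <- vector("list", length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    res <- tryCatch({
      fit <- if (!is.null(strata_files)) {
        spec_k <- strata_files[[as.character(k)]]
        if (is.null(spec_k)) stopf("no ADMIXTURE files supplied for k = %d", k)
        read_admixture(spec_k$q, spec_k$p, ids = fit_ids,
                       marker_ids = colnames(g$counts))
      } else {
        fit_admixture_lite(geno_subset(g, animals = fit_ids), k = k,
                           seed = seed, ...)
      }
      Q_all <- project_Q(fit$P_A, g, with_intercept = with_intercept)$Q
      Q_all[rownames(fit$Q), ] <- fit$Q   # projection only fills the rest
      P_gls <- gls_strata_frequencies(Q_all, A_g, g)
      A_gamma <- build_A_gamma(A_g, Q_all, P_gls, G = G)
      stats_reg <- regress_matrices(A_gamma, G)
      stats_mean <- mean_differences(G, A_gamma)
      fits[[i]] <- fit
      data.frame(k = k, a = stats_reg["a"], b = stats_reg["b"],
                 r2 = stats_reg["r2"], mean_diff = stats_mean["mean_diff"],
                 diag_diff = stats_mean["diag_diff"], error = NA_character_)
    }, error = function(e) {
      data.frame(k = k, a = NA_real_, b = NA_real_, r2 = NA_real_,
                 mean_diff = NA_real_, diag_diff = NA_real_,
                 error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, fits = fits, fit_ids = fit_ids,
            sample_mode = sample_mode, seed = seed,
            class = c("metafounder_sweep", "data.frame"))
}

#' @export
print.metafounder_sweep <- function(x, ...) {
  cat(sprintf("<metafounder_sweep> %d values of k, sample = %s (%d animals fitted)\n",
              nrow(x), attr(x, "sample_mode"), length(attr(x, "fit_ids"))))
  df <- as.data.frame(x)
  df[, c("a", "b", "r2", "mean_diff", "diag_diff")] <-
    round(df[, c("a", "b", "r2", "mean_diff", "diag_diff")], 3)
  print(df, ...)
  invisible(x)
}

#' @export
plot.metafounder_sweep <- function(x, ...) {
  df <- as.data.frame(x)
  ok <- !is.na(df$r2)
  graphics::par(mfrow = c(1, 2))
  graphics::plot(df$k[ok], df$r2[ok], type = "b", xlab = "k",
                 ylab = expression(R^2), main = "Fit of A^Gamma on G", ...)
  graphics::plot(df$k[ok], df$b[ok], type = "b", xlab = "k", ylab = "slope b",
                 main = "Dispersion", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Write a sweep report as CSV
#' @param report a `metafounder_sweep`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sweep <- function(report, path) {
  utils::write.csv(as.data.frame(report)[, c("k", "a", "b", "r2",
                                             "mean_diff", "diag_diff")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Select the number of strata from a sweep report
#'
#' Codifies the informal optimum: among rows whose slope does not exceed
#' `slope_cap + slope_tol`, pick the `k` with maximal R-squared; ties are
#' broken by smaller `|b - 1|`, then smaller `|mean_diff|`, then smaller
#' `k`. If no row satisfies the cap, the row minimising `|b - 1|` is
#' returned with a warning (the slope criterion guards against
#' overdispersion of A^Gamma).
#'
#' @param report a `metafounder_sweep` (or data frame with columns
#'   `k, a, b, r2, mean_diff`).
#' @param slope_cap upper limit for the slope (default 1).
#' @param slope_tol tolerance above the cap (default 0.05).
#' @return the selected `k` (integer).
#' @export
select_k <- function(report, slope_cap = 1.0, slope_tol = 0.05) {
  df <- as.data.frame(report)
  df <- df[!is.na(df$b) & !is.na(df$r2), , drop = FALSE]
  if (!nrow(df)) stopf("report contains no evaluable rows")
  ok <- df$b <= slope_cap + slope_tol
  if (!any(ok)) {
    warning("no k satisfies the slope cap; returning the k with slope closest to 1")
    return(df$k[which.min(abs(df$b - 1))])
  }
  cand <- df[ok, , drop = FALSE]
  ord <- order(-cand$r2, abs(cand$b - 1), abs(cand$mean_diff), cand$k)
  cand$k[ord[1]]
}
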