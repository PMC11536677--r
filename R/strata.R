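#' Strata (admixture) models
#'
#' A `strata_fit` holds the `n x k` ancestry matrix `Q` (rows sum to 1), the
#' `m x k` strata allele frequency matrix `P_A`, the binomial admixture
#' log-likelihood of the fitted data, and bookkeeping (iterations,
#' convergence flag, fitted animal ids).
#'
#' @name strata_fit
NULL

new_strata_fit <- function(Q, P_A, log_likelihood = NA_real_,
                           iterations = NA_integer_, converged = NA) {
  stopifnot(ncol(Q) == ncol(P_A))
  structure(list(Q = Q, P_A = P_A, k = ncol(Q),
                 log_likelihood = log_likelihood,
                 iterations = iterations, converged = converged,
                 ids = rownames(Q)),
            class = "strata_fit")
}

#' @export
print.strata_fit <- function(x, ...) {
  cat(sprintf("<strata_fit> k = %d, %d animals, %d markers\n",
              x$k, nrow(x$Q), nrow(x$P_A)))
  if (!is.na(x$log_likelihood))
    cat(sprintf("  log-likelihood %.3f after %s iterations (%s)\n",
                x$log_likelihood,
                ifelse(is.na(x$iterations), "?", x$iterations),
                if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.strata_fit <- function(object, ...) object$Q

#' @export
logLik.strata_fit <- function(object, ...) {
  structure(object$log_likelihood, df = NA, class = "logLik")
}

#' @export
summary.strata_fit <- function(object, ...) {
  cat(sprintf("Admixture model, k = %d strata, %d animals, %d markers\n",
              object$k, nrow(object$Q), nrow(object$P_A)))
  cat("Mean ancestry proportions per stratum:\n")
  print(round(colMeans(object$Q), 4))
  cat("Strata allele frequency summary:\n")
  print(apply(object$P_A, 2, function(p)
    c(min = min(p), mean = mean(p), max = max(p))))
  invisible(object)
}

# binomial admixture log-likelihood for counts Z given Q, P (both clipped)
admixture_loglik <- function(Z, Q, P, eps = 1e-10) {
  f <- Q %*% t(P)
  f <- pmin(pmax(f, eps), 1 - eps)
  sum(Z * log(f) + (2 - Z) * log(1 - f), na.rm = TRUE)
}

#' Unsupervised admixture estimation by EM
#'
#' Maximises the binomial admixture log-likelihood
#' `sum_ij [ z_ij log(sum_l q_il p_jl) + (2 - z_ij) log(sum_l q_il (1 - p_jl)) ]`
#' over ancestry proportions `Q` and strata allele frequencies `P_A` by
#' block EM updates (as in frappe/STRUCTURE-style estimators). `Q` is
#' initialised from per-animal Dirichlet(1) draws and `P_A` from observed
#' allele frequencies perturbed by noise; both initial draws are keyed to the
#' animal/marker identifier (not its row position) so a permutation of the
#' animals yields the identical fit. Frequencies are clipped to
#' `(1e-6, 1 - 1e-6)`. Missing genotype entries are ignored by the updates,
#' which is what the cross-validation masking relies on.
#'
#' @param g a [geno].
#' @param k number of strata (>= 1).
#' @param tol stop when the relative log-likelihood improvement falls below
#'   `tol` (default 1e-6).
#' @param max_iter maximum EM iterations (default 2000).
#' @param seed integer seed for the initialisation.
#' @return a `strata_fit`; element `loglik_trace` records the log-likelihood
#'   after every iteration (non-decreasing, an EM guarantee), and `converged`
#'   is `FALSE` when `max_iter` was exhausted (no error is thrown).
#' @export
fit_admixture_lite <- function(g, k, tol = 1e-6, max_iter = 2000L, seed = 1L) {
  check_scalar(k, "k", 1)
  k <- as.integer(k)
  Z <- g$counts
  n <- nrow(Z); m <- ncol(Z)
  storage.mode(Z) <- "double"
  obs <- !is.na(Z)
  Zf <- Z; Zf[!obs] <- 0           # masked entries contribute nothing
  W2 <- (2 - Z); W2[!obs] <- 0
  eps <- 1e-6

  # initialisation keyed to ids, not row order
  Q <- t(vapply(rownames(Z), function(id) {
    gdraw <- with_local_seed(id_seed(id, seed), stats::rgamma(k, 1))
    gdraw / sum(gdraw)
  }, numeric(k)))
  if (k == 1L) Q <- matrix(1, n, 1)
  pbar <- colSums(Zf) / (2 * colSums(obs))
  pbar[!is.finite(pbar)] <- 0.5
  P <- vapply(seq_len(k), function(l)
    vapply(colnames(Z), function(mid) {
      u <- with_local_seed(id_seed(paste0(mid, "#", l), seed),
                           stats::runif(1, -0.1, 0.1))
      u
    }, numeric(1)), numeric(m))
  P <- pmin(pmax(pbar + P, eps), 1 - eps)
  dim(P) <- c(m, k)

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    F1 <- Q %*% t(P)
    F1 <- pmin(pmax(F1, 1e-10), 1 - 1e-10)
    F0 <- 1 - F1
    Anum <- matrix(0, m, k)   # expected reference-allele counts per stratum
    Bnum <- matrix(0, m, k)   # expected alternative-allele counts
    Qnew <- matrix(0, n, k)
    for (l in seq_len(k)) {
      R1 <- (Zf / F1) * outer(Q[, l], P[, l])      # n x m
      R0 <- (W2 / F0) * outer(Q[, l], 1 - P[, l])
      Anum[, l] <- colSums(R1)
      Bnum[, l] <- colSums(R0)
      Qnew[, l] <- rowSums(R1) + rowSums(R0)
    }
    P <- Anum / (Anum + Bnum)
    P[!is.finite(P)] <- 0.5
    P <- pmin(pmax(P, eps), 1 - eps)
    denom <- rowSums(Qnew)
    Q <- Qnew / ifelse(denom > 0, denom, 1)
    if (k == 1L) Q[] <- 1
    ll <- admixture_loglik(Z, Q, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    if (k == 1L) { converged <- TRUE; break }  # closed-form optimum in one step
    ll_old <- ll
  }
  rownames(Q) <- rownames(Z); colnames(Q) <- paste0("S", seq_len(k))
  rownames(P) <- colnames(Z); colnames(P) <- colnames(Q)
  out <- new_strata_fit(Q, P, log_likelihood = trace[length(trace)],
                        iterations = iter, converged = converged)
  out$loglik_trace <- trace
  out
}

#' Read ADMIXTURE .Q and .P output files
#'
#' ADMIXTURE writes whitespace-delimited, headerless matrices: `.Q` with one
#' row per fitted animal and one column per stratum, `.P` with one row per
#' marker. Rows of `.Q` that do not sum to 1 (some dialects truncate digits)
#' are renormalised with a warning.
#'
#' @param q_path path to the `.Q` file.
#' @param p_path path to the `.P` file.
#' @param ids animal identifiers, one per `.Q` row.
#' @param marker_ids marker identifiers, one per `.P` row.
#' @param genotypes optional [geno] for the same animals/markers, used to
#'   recompute the log-likelihood.
#' @return a `strata_fit`.
#' @export
read_admixture <- function(q_path, p_path, ids, marker_ids, genotypes = NULL) {
  Q <- as.matrix(utils::read.table(q_path, header = FALSE))
  P <- as.matrix(utils::read.table(p_path, header = FALSE))
  if (nrow(Q) != length(ids))
    stopf(".Q has %d rows but %d animal ids were given", nrow(Q), length(ids))
  if (nrow(P) != length(marker_ids))
    stopf(".P has %d rows but %d marker ids were given", nrow(P),
          length(marker_ids))
  if (ncol(Q) != ncol(P))
    stopf(".Q has k = %d but .P has k = %d columns", ncol(Q), ncol(P))
  rs <- rowSums(Q)
  off <- abs(rs - 1) > 1e-6
  if (any(off)) {
    warning(sprintf("%d .Q row(s) did not sum to 1; renormalised", sum(off)))
    Q <- Q / rs
  }
  dimnames(Q) <- list(as.character(ids), paste0("S", seq_len(ncol(Q))))
  dimnames(P) <- list(as.character(marker_ids), colnames(Q))
  ll <- if (!is.null(genotypes))
    admixture_loglik(genotypes$counts[as.character(ids),
                                      as.character(marker_ids), drop = FALSE],
                     Q, P)
  else NA_real_
  new_strata_fit(Q, P, log_likelihood = ll)
}

#' Write a strata model in ADMIXTURE's .Q/.P dialect
#'
#' @param fit a `strata_fit`.
#' @param q_path,p_path output paths.
#' @return invisibly, the two paths.
#' @export
write_admixture <- function(fit, q_path, p_path) {
  utils::write.table(fit$Q, q_path, row.names = FALSE, col.names = FALSE)
  utils::write.table(fit$P_A, p_path, row.names = FALSE, col.names = FALSE)
  invisible(c(q_path, p_path))
}

#' Project ancestry proportions onto animals via regression
#'
#' Regresses one half of each animal's genotype vector on the strata allele
#' frequencies: `q_i' = (P'P)^-1 P' (0.5 z_i)`. With `with_intercept = TRUE`
#' the design is augmented by a column of ones and the intercept reported; a
#' large intercept for many animals indicates that `k` is too small to
#' capture all strata, and animals with intercept above
#' `intercept_threshold` are flagged. Negative ancestry estimates are clamped
#' to 0, and any row whose entries sum to more than 1 is proportionally
#' rescaled to sum 1.
#'
#' @param P_A `m x k` strata allele frequency matrix (e.g. from a
#'   `strata_fit`).
#' @param g a [geno] whose markers match the rows of `P_A` (missing entries
#'   are mean-imputed per marker before the regression).
#' @param with_intercept add an intercept column to the design.
#' @param intercept_threshold flag animals whose intercept exceeds this
#'   (default 0.1).
#' @return a list of class `q_projection` with `Q` (projected proportions),
#'   `intercepts` (or `NULL`), and `flagged` (ids with large intercepts).
#' @export
project_Q <- function(P_A, g, with_intercept = FALSE,
                      intercept_threshold = 0.1) {
  P_A <- as.matrix(P_A)
  Z <- g$counts[, rownames(P_A) %||% colnames(g$counts), drop = FALSE]
  if (ncol(Z) != nrow(P_A))
    stopf("marker sets of P_A (%d) and genotypes (%d) do not align",
          nrow(P_A), ncol(Z))
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    na_idx <- which(is.na(Z), arr.ind = TRUE)
    Z[na_idx] <- mu[na_idx[, 2]]
  }
  X <- if (with_intercept) cbind(`(Intercept)` = 1, P_A) else P_A
  XtX <- crossprod(X)
  ok <- tryCatch({ R <- chol(XtX); TRUE }, error = function(e) FALSE)
  if (!ok || kappa(XtX) > 1e12)
    stopf(paste("P'P is (near) singular; use fewer strata or more markers"))
  B <- backsolve(R, backsolve(R, crossprod(X, 0.5 * t(Z)), transpose = TRUE))
  B <- t(B)                                  # n x (k [+1])
  intercepts <- NULL
  if (with_intercept) {
    intercepts <- stats::setNames(B[, 1], rownames(Z))
    B <- B[, -1, drop = FALSE]
  }
  B[B < 0] <- 0
  s <- rowSums(B)
  over <- s > 1
  B[over, ] <- B[over, , drop = FALSE] / s[over]
  dimnames(B) <- list(rownames(Z), colnames(P_A))
  flagged <- if (with_intercept)
    rownames(Z)[abs(intercepts) > intercept_threshold] else character(0)
  structure(list(Q = B, intercepts = intercepts, flagged = flagged),
            class = "q_projection")
}

#' @export
print.q_projection <- function(x, ...) {
  cat(sprintf("<q_projection> %d animals x %d strata%s\n",
              nrow(x$Q), ncol(x$Q),
              if (is.null(x$intercepts)) ""
              else sprintf(", %d flagged by intercept", length(x$flagged))))
  invisible(x)
}

#' Predict ancestry proportions for new animals
#'
#' Projects genotypes onto a fitted strata model via [project_Q()].
#'
#' @param object a `strata_fit`.
#' @param newdata a [geno] on the same markers.
#' @param ... passed to [project_Q()].
#' @return the projected `Q` matrix.
#' @export
predict.strata_fit <- function(object, newdata, ...) {
  project_Q(object$P_A, newdata, ...)$Q
}

#' Masked-entry cross-validation error for a choice of k
#'
#' For each fold, a random `mask_fraction` of the genotype entries is hidden,
#' the admixture model refitted on the remaining entries, and the hidden
#' counts predicted as `2 * sum_l q_il p_jl`. Returns the mean squared error
#' over all masked entries, the criterion used to compare values of `k`.
#'
#' @param g a [geno] with complete entries.
#' @param k number of strata.
#' @param mask_fraction fraction of entries masked per fold, in (0, 1).
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param ... passed to [fit_admixture_lite()].
#' @return mean squared prediction error (scalar) with attribute
#'   `"per_fold"`.
#' @export
cv_error <- function(g, k, mask_fraction = 0.1, folds = 10L, seed = 1L, ...) {
  check_scalar(mask_fraction, "mask_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  Z <- g$counts
  n_entries <- length(Z)
  errs <- with_local_seed(seed, {
    vapply(seq_len(folds), function(f) {
      masked <- which(stats::runif(n_entries) < mask_fraction & !is.na(Z))
      if (!length(masked)) stopf("fold %d masked zero entries", f)
      Zm <- Z
      Zm[masked] <- NA
      fit <- fit_admixture_lite(geno(Zm, map = g$map), k = k,
                                seed = sample.int(2^30, 1), ...)
      pred <- 2 * (fit$Q %*% t(fit$P_A))[masked]
      mean((pred - as.double(Z[masked]))^2)
    }, numeric(1))
  })
  structure(mean(errs), per_fold = errs)
}
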