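# genotypes drawn from a known admixture model
admixed_geno <- function(Q, P, seed = 1) {
  set.seed(seed)
  f <- Q %*% t(P)
  counts <- matrix(rbinom(length(f), 2L, f), nrow(f), ncol(f))
  dimnames(counts) <- list(rownames(Q) %||%
                             paste0("a", seq_len(nrow(Q))),
                           rownames(P) %||%
                             paste0("m", seq_len(nrow(P))))
  geno(counts)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("k = 1 collapses to observed frequencies in one iteration", {
  g <- random_geno(20, 50, seed = 3)
  fit <- fit_admixture_lite(g, k = 1, seed = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 20))
  expect_equal(unname(fit$P_A[, 1]), unname(colMeans(g$counts) / 2),
               tolerance = 1e-5)
  expect_equal(fit$iterations, 1L)
  expect_true(fit$converged)
})

test_that("EM log-likelihood is non-decreasing and label-permutation safe", {
  Q <- rbind(diag(2), diag(2), matrix(0.5, 4, 2))
  P <- cbind(rep(c(0.1, 0.9), 25), rep(c(0.9, 0.1), 25))
  g <- admixed_geno(Q, P, seed = 2)
  fit <- fit_admixture_lite(g, k = 2, seed = 5, max_iter = 50)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  # permuting stratum labels leaves the likelihood unchanged
  ll_perm <- metafoundr:::admixture_loglik(g$counts, fit$Q[, 2:1],
                                           fit$P_A[, 2:1])
  expect_equal(ll_perm, fit$log_likelihood)
  # non-convergence is reported via the flag, not an error
  short <- fit_admixture_lite(g, k = 2, seed = 5, max_iter = 2)
  expect_false(short$converged)
})

test_that("well-separated strata are recovered by the EM estimator", {
  set.seed(4)
  n_per <- 25; m <- 300
  Q <- rbind(cbind(rep(1, n_per), 0), cbind(rep(0, n_per), 1))
  rownames(Q) <- paste0("a", seq_len(2 * n_per))
  P <- cbind(c(rep(0.05, m / 2), rep(0.95, m / 2)),
             c(rep(0.95, m / 2), rep(0.05, m / 2)))
  g <- admixed_geno(Q, P, seed = 6)
  fit <- fit_admixture_lite(g, k = 2, seed = 3)
  perm <- align_strata(fit$P_A, P)
  expect_lt(max(abs(fit$Q[, perm] - Q)), 0.05)

  # projecting the fitted animals from the fitted P_A reproduces Q
  Q_proj <- project_Q(fit$P_A, g)$Q
  expect_lt(max(abs(Q_proj - fit$Q)), 0.05)
})

test_that("the fit is invariant to the order of the animals", {
  g <- admixed_geno(rbind(diag(2), matrix(0.5, 6, 2)),
                    cbind(runif(80, 0, 0.3), runif(80, 0.7, 1)), seed = 9)
  fit <- fit_admixture_lite(g, k = 2, seed = 11, max_iter = 40)
  perm <- rev(rownames(g$counts))
  fit_perm <- fit_admixture_lite(geno(g$counts[perm, ]), k = 2, seed = 11,
                                 max_iter = 40)
  expect_equal(fit_perm$Q[rownames(fit$Q), ], fit$Q, tolerance = 1e-8)
  expect_equal(fit_perm$P_A, fit$P_A, tolerance = 1e-8)
})

test_that("ADMIXTURE .Q/.P files are parsed with dialect tolerance", {
  qf <- withr::local_tempfile(fileext = ".Q")
  pf <- withr::local_tempfile(fileext = ".P")
  writeLines(c("0.7 0.3", "0.2 0.8", "0.5 0.5"), qf)
  writeLines(c("0.1 0.9", "0.4 0.6", "0.25 0.75", "0.9 0.1"), pf)
  fit <- read_admixture(qf, pf, ids = c("x", "y", "z"),
                        marker_ids = paste0("m", 1:4))
  expect_equal(dim(fit$Q), c(3, 2))
  expect_equal(dim(fit$P_A), c(4, 2))
  expect_equal(fit$k, 2)

  writeLines(c("0.6 0.3", "0.2 0.8", "0.5 0.5"), qf)  # row sums 0.9
  expect_warning(fit2 <- read_admixture(qf, pf, c("x", "y", "z"),
                                        paste0("m", 1:4)), "renormalised")
  expect_equal(rowSums(fit2$Q), rep(1, 3), ignore_attr = TRUE)

  writeLines(c("0.1 0.2 0.7", "0.3 0.3 0.4", "1 0 0"), qf)  # k mismatch
  expect_error(read_admixture(qf, pf, c("x", "y", "z"), paste0("m", 1:4)),
               "k = ")
  expect_error(read_admixture(pf, pf, c("x", "y", "z"), paste0("m", 1:4)),
               "rows")
})

test_that("Q projection solves the regression and applies the row rules", {
  # single stratum, P all 1, all-reference animal: exact fit, q = 1
  g1 <- geno(matrix(2L, 1, 3, dimnames = list("a", paste0("m", 1:3))))
  pr <- project_Q(matrix(1, 3, 1, dimnames = list(paste0("m", 1:3), "S1")),
                  g1)
  expect_equal(unname(pr$Q[1, 1]), 1)

  # exact fit with an intercept column: intercept 0, nothing flagged
  gi <- geno(matrix(c(2L, 2L, 0L), 1, 3,
                    dimnames = list("a", paste0("m", 1:3))))
  pri <- project_Q(matrix(c(1, 1, 0), 3, 1,
                          dimnames = list(paste0("m", 1:3), "S1")),
                   gi, with_intercept = TRUE)
  expect_equal(unname(pri$Q[1, 1]), 1)
  expect_equal(unname(pri$intercepts[1]), 0, tolerance = 1e-12)
  expect_length(pri$flagged, 0)

  # orthogonal two-marker design
  g2 <- geno(matrix(c(2L, 0L), 1, 2, dimnames = list("a", c("m1", "m2"))))
  P2 <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("m1", "m2"), NULL))
  expect_equal(unname(project_Q(P2, g2)$Q[1, ]), c(1, 0))

  # raw estimate (0.8, 0.6) is proportionally rescaled to sum 1
  P3 <- rbind(matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE),
              matrix(rep(c(0, 1), 5), 5, 2, byrow = TRUE))
  rownames(P3) <- paste0("m", 1:10)
  z <- c(2L, 2L, 2L, 1L, 1L,   # 0.5 * sum = 4 -> q1_raw = 0.8
         2L, 2L, 1L, 1L, 0L)   # 0.5 * sum = 3 -> q2_raw = 0.6
  g3 <- geno(matrix(z, 1, 10, dimnames = list("a", rownames(P3))))
  expect_equal(unname(project_Q(P3, g3)$Q[1, ]), c(0.8, 0.6) / 1.4,
               tolerance = 1e-12)

  # collinear strata frequencies are refused
  Pc <- cbind(rep(0.4, 10), rep(0.4, 10))
  rownames(Pc) <- paste0("m", 1:10)
  gx <- random_geno(2, 10, seed = 1)
  colnames(gx$counts) <- paste0("m", 1:10)
  expect_error(project_Q(Pc, gx), "singular")
})

test_that("cross-validation predicts masked genotypes by the model mean", {
  # prediction arithmetic: q = (0.5, 0.5), p_j = (0.2, 0.6) -> 0.8
  expect_equal(2 * sum(c(0.5, 0.5) * c(0.2, 0.6)), 0.8)

  Q <- rbind(diag(2), diag(2), diag(2), matrix(0.5, 2, 2))
  P <- cbind(runif(60, 0, 0.25), runif(60, 0.75, 1))
  g <- admixed_geno(Q, P, seed = 12)
  expect_error(cv_error(g, k = 2, mask_fraction = 1e-9, folds = 1, seed = 1),
               "zero entries")
  e1 <- cv_error(g, k = 1, mask_fraction = 0.1, folds = 2, seed = 2,
                 max_iter = 40)
  e2 <- cv_error(g, k = 2, mask_fraction = 0.1, folds = 2, seed = 2,
                 max_iter = 40)
  expect_lte(e2, e1)
})
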