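const_relmat <- function(off, diag_val, n = 4, kind = "pedigree") {
  M <- matrix(off, n, n); diag(M) <- diag_val
  relmat(M, ids = paste0("a", 1:n), kind = kind)
}

test_that("GLS strata frequencies collapse to means under identity A", {
  # single stratum: GLS is the sample mean / 2
  g <- random_geno(10, 30, seed = 2)
  A_I <- relmat(diag(10), ids = rownames(g$counts))
  Q1 <- matrix(1, 10, 1, dimnames = list(rownames(g$counts), "S1"))
  P <- gls_strata_frequencies(Q1, A_I, g)
  expect_equal(unname(P[, 1]), unname(colMeans(g$counts) / 2),
               tolerance = 1e-12)

  # two-group indicator: blockwise means
  counts <- rbind(matrix(2L, 3, 4), matrix(0L, 3, 4))
  rownames(counts) <- paste0("a", 1:6)
  g2 <- geno(counts)
  Q2 <- cbind(rep(1:0, each = 3), rep(0:1, each = 3))
  rownames(Q2) <- rownames(counts)
  A2 <- relmat(diag(6), ids = rownames(counts))
  P2 <- gls_strata_frequencies(Q2, A2, g2)
  expect_equal(unname(P2), matrix(c(1, 0), 4, 2, byrow = TRUE),
               ignore_attr = TRUE)

  expect_error(gls_strata_frequencies(Q2[, c(1, 1)], A2, g2),
               "rank deficient")
  expect_error(gls_strata_frequencies(Q2[1:3, ], A2, g2), "rows")
})

test_that("GLS recovers true strata frequencies on founder data", {
  sim <- simulate_population(sim_config(k_true = 2, m = 800, fst = 0.2,
                                        n_founders = 300, alpha = 0.2,
                                        n_generations = 0, seed = 17))
  A_I <- relmat(diag(300), ids = sim$pedigree$animal)
  P <- gls_strata_frequencies(sim$Q_true, A_I, sim$genotypes)
  expect_lt(mean(abs(P - sim$P_true)), 0.05)
  expect_true(attr(P, "n_clipped") >= 0)
})

test_that("Gamma from frequencies matches the closed form", {
  expect_equal(unclass(gamma_matrix(matrix(0.5, 10, 2))),
               matrix(0, 2, 2), ignore_attr = TRUE)
  # fully drifted single stratum
  expect_equal(unclass(gamma_matrix(matrix(c(0, 1, 1, 0), 4, 1))),
               matrix(2), ignore_attr = TRUE)
  # hand evaluation at m = 2, k = 2
  P <- matrix(c(0.1, 0.9, 0.5, 0.5), 2, 2)
  expect_equal(unclass(gamma_matrix(P)),
               matrix(c(1.28, 0, 0, 0), 2, 2), ignore_attr = TRUE)
  expect_error(gamma_matrix(matrix(numeric(0), 0, 2)), "no markers")
  expect_error(gamma_matrix(matrix(1.5, 3, 1)), "frequencies")
})

test_that("pivotal gamma matches the mean formula and its edge cases", {
  G <- const_relmat(0.5, 0.5, kind = "genomic")   # mean 0.5
  A0 <- const_relmat(0, 0)                        # mean 0
  expect_equal(pivotal_gamma(G, A0), 0.5)
  A02 <- const_relmat(0.2, 0.2)
  G07 <- const_relmat(0.7, 0.7, kind = "genomic")
  expect_equal(pivotal_gamma(G07, A02), 0.5 / 0.9)
  expect_equal(pivotal_gamma(A02, A02), 0)
  expect_error(pivotal_gamma(G, const_relmat(2, 2)), "undefined")
})

test_that("gamma/heterozygosity conversion reproduces the worked example", {
  conv <- gamma_het_convert(gamma = 0.694)
  expect_equal(conv$H, 0.3265)
  expect_lt(abs(conv$H - 0.327), 5.1e-4)  # agrees at 3 printed decimals
  expect_equal(gamma_het_convert(gamma = 0)$H, 0.5)
  expect_equal(gamma_het_convert(H = 0.3265)$gamma, 0.694)
  expect_error(gamma_het_convert(H = 0), "range")
  expect_error(gamma_het_convert(gamma = 2), "range")
  expect_error(gamma_het_convert(gamma = 0.5, H = 0.4), "exactly one")
})

test_that("Gamma base rescaling and standardization follow the affine maps", {
  gX <- gamma_mat(matrix(c(0, 2, 2, 2), 2, 2))
  # H_B = 0.5 leaves Gamma unchanged; 2 is a fixed point
  gB_id <- rescale_gamma_to_base(gX, 0.5)
  expect_equal(unclass(gB_id), unclass(gX), ignore_attr = TRUE)
  gB <- rescale_gamma_to_base(gX, 0.3265)
  expect_equal(gB[1, 1], (0 - 2) / (2 * 0.3265) + 2, tolerance = 1e-12)
  expect_equal(gB[2, 2], 2)
  expect_error(rescale_gamma_to_base(gB, 0.4), "maximum-heterozygosity")

  gB2 <- gamma_mat(matrix(c(0.4, -0.2, -0.2, 0.6), 2, 2),
                   reference = "pedigree-base", base_het = 0.33)
  gS <- standardize_gamma(gB2)
  expect_equal(unclass(gS), matrix(c(1.2, -0.2, -0.2, 1.3), 2, 2),
               ignore_attr = TRUE)
  expect_equal(unclass(standardize_gamma(
    gamma_mat(matrix(0, 2, 2), "pedigree-base", 0.33))), diag(2),
    ignore_attr = TRUE)
})

test_that("A_B^Gamma combines A_g and Q-weighted metafounder relationships", {
  A_I <- relmat(diag(2), ids = c("x", "y"))
  gS <- gamma_mat(matrix(c(1.2, -0.2, -0.2, 1.3), 2, 2),
                  reference = "standardized", base_het = 0.33)
  # identity Gamma* adds nothing
  gI <- gamma_mat(diag(2), reference = "standardized", base_het = 0.33)
  expect_equal(unclass(approx_A_gamma(A_I, diag(2), gI)), diag(2),
               ignore_attr = TRUE)
  # unit Q rows: the example matrix carries through
  out <- approx_A_gamma(A_I, diag(2), gS)
  expect_equal(unclass(out), matrix(c(1.2, -0.2, -0.2, 1.3), 2, 2),
               ignore_attr = TRUE)
  # k = 1, Q all ones: uniform shift by g / 2
  gs1 <- gamma_mat(matrix(1 + 0.3, 1, 1), reference = "standardized",
                   base_het = 0.33)
  out1 <- approx_A_gamma(A_I, matrix(1, 2, 1), gs1)
  expect_equal(unclass(out1), diag(2) + 0.3, ignore_attr = TRUE)
  expect_error(approx_A_gamma(A_I, matrix(1, 3, 1), gs1), "rows")
  expect_error(approx_A_gamma(A_I, diag(2), gamma_mat(diag(2))),
               "standardized")
})

test_that("relationship rescaling is an involution with fixed point 2", {
  A <- const_relmat(1, 1.2)
  expect_equal(unclass(rescale_relationship(A, 0.4, 0.4)), unclass(A),
               ignore_attr = TRUE)
  B <- rescale_relationship(A, 0.3265, 0.5)
  expect_equal(B[1, 2], 2 * 0.3265 * (1 - 2) + 2, tolerance = 1e-12)
  # round trip
  back <- rescale_relationship(B, 0.5, 0.3265)
  expect_equal(unclass(back), unclass(A), tolerance = 1e-12,
               ignore_attr = TRUE)
  # any element equal to 2 is invariant
  C <- const_relmat(2, 2)
  expect_equal(unclass(rescale_relationship(C, 0.25, 0.5)), unclass(C),
               ignore_attr = TRUE)
  expect_error(rescale_relationship(A, 0, 0.5), "range")
})

test_that("rescaling A_g by its own pivotal gamma zeroes the mean difference", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 12
    X <- matrix(rnorm(n * 20), n)
    A <- relmat(tcrossprod(X) / 20 + diag(n) * 0.1, ids = paste0("i", 1:n))
    Y <- matrix(rnorm(n * 20), n)
    # G with a larger overall mean, as for a drifted base (gamma in [0, 2))
    G <- relmat(tcrossprod(Y) / 20 + 0.4, ids = paste0("i", 1:n),
                kind = "genomic")
    gam <- pivotal_gamma(G, A)
    H_B <- 0.5 - 0.25 * gam
    A_resc <- rescale_relationship(A, H_from = H_B, H_to = 0.5)
    expect_equal(unname(mean_differences(G, A_resc)["mean_diff"]), 0,
                 tolerance = 1e-12)
  }
})

test_that("a single stratum reduces the chain to Christensen's rescaling", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 8; m <- 40
    A <- relmat(tcrossprod(matrix(rnorm(n * 12), n)) / 12 + diag(n),
                ids = paste0("i", 1:n))
    P1 <- matrix(runif(m, 0.05, 0.95), m, 1)
    gam <- gamma_matrix(P1)[1, 1]
    H_B <- 0.5 - gam / 4
    Q1 <- matrix(1, n, 1)
    A_gamma <- build_A_gamma(A, Q1, P1, H_B = H_B)
    christensen <- 2 * H_B * (unclass(A) - 2) + 2
    expect_equal(unclass(A_gamma), christensen, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # no stratification, max-het base: the chain is the identity
  A <- relmat(diag(3), ids = c("a", "b", "c"))
  out <- build_A_gamma(A, matrix(1, 3, 1), matrix(0.5, 10, 1), H_B = 0.5)
  expect_equal(unclass(out), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Gamma of GLS frequencies approaches the truth on founder data", {
  devs <- vapply(1:3, function(r) {
    sim <- simulate_population(sim_config(k_true = 3, m = 1500, fst = 0.2,
                                          n_founders = 300, alpha = 0.2,
                                          n_generations = 0, seed = 100 + r))
    A_I <- relmat(diag(300), ids = sim$pedigree$animal)
    P <- gls_strata_frequencies(sim$Q_true, A_I, sim$genotypes)
    mean(abs(unclass(gamma_matrix(P)) - unclass(sim$gamma_true)))
  }, numeric(1))
  expect_lt(mean(devs), 0.1)
})
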