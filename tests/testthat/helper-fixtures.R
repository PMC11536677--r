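# fixtures and independent oracles used across test files

# small admixed simulation shared by several files
toy_sim <- function(seed = 7, ...) {
  args <- utils::modifyList(list(k_true = 3, m = 400, fst = 0.3,
                                 n_founders = 50, n_generations = 1,
                                 sires_per_generation = 3,
                                 offspring_per_sire = 8, seed = seed),
                            list(...))
  simulate_population(do.call(sim_config, args))
}

# random genotype matrix with no missing entries
random_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  counts <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  geno(counts)
}

# Monte-Carlo identity-by-descent oracle for the numerator relationship
# matrix: drops uniquely labelled founder alleles through the pedigree and
# estimates a_ij = 2 * P(two randomly drawn alleles are IBD). Returns the
# estimate and its standard-error matrix.
gene_drop_oracle <- function(ped, reps = 1e4, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  L1 <- matrix(0L, reps, n); L2 <- matrix(0L, reps, n)
  label <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      label <- label + 1L; L1[, i] <- label
    } else {
      pick <- stats::runif(reps) < 0.5
      L1[, i] <- ifelse(pick, L1[, si[i]], L2[, si[i]])
    }
    if (is.na(di[i])) {
      label <- label + 1L; L2[, i] <- label
    } else {
      pick <- stats::runif(reps) < 0.5
      L2[, i] <- ifelse(pick, L1[, di[i]], L2[, di[i]])
    }
  }
  est <- matrix(0, n, n); se <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- ((L1[, i] == L1[, j]) + (L1[, i] == L2[, j]) +
                  (L2[, i] == L1[, j]) + (L2[, i] == L2[, j])) / 2
      est[i, j] <- est[j, i] <- mean(share)
      se[i, j] <- se[j, i] <- stats::sd(share) / sqrt(reps)
    }
  }
  dimnames(est) <- dimnames(se) <- list(ped$animal, ped$animal)
  list(est = est, se = se)
}

# 12-animal pedigree with founders, half sibs, full sibs and an inbred mating
deep_pedigree <- function() {
  pedigree(animal = c("f1", "f2", "f3", "f4",
                      "o1", "o2", "o3", "o4",
                      "g1", "g2", "g3", "g4"),
           sire   = c(0, 0, 0, 0,
                      "f1", "f1", "f3", "f3",
                      "o1", "o1", "o3", "o1"),
           dam    = c(0, 0, 0, 0,
                      "f2", "f2", "f2", "f4",
                      "o3", "o4", "f2", "g1"))
}

# align stratum labels of an estimated P/Q pair to the truth by greedy
# correlation matching on the allele-frequency columns
align_strata <- function(P_est, P_true) {
  k <- ncol(P_true)
  cors <- stats::cor(P_est, P_true)
  perm <- integer(k)
  taken <- rep(FALSE, k)
  for (j in order(-apply(cors, 2, max))) {
    cand <- order(-cors[, j])
    cand <- cand[!taken[cand]]
    perm[j] <- cand[1]
    taken[cand[1]] <- TRUE
  }
  perm
}
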