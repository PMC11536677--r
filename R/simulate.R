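#' Simulation configuration for admixed populations
#'
#' Bundles and validates the parameters of the synthetic-population
#' generator: `k_true` ancestral strata with Balding-Nichols divergence
#' `fst` around ancestral frequencies drawn uniformly from
#' `ancestral_freq_bounds`; `n_founders` admixed founders with ancestry rows
#' drawn from a symmetric Dirichlet with concentration `alpha`; and
#' `n_generations` of gene dropping in which `sires_per_generation` sires
#' each produce `offspring_per_sire` offspring from distinct dams, creating
#' the large paternal half-sib families typical of dairy cattle.
#'
#' @param k_true number of ancestral strata (>= 1).
#' @param m number of biallelic markers.
#' @param fst Balding-Nichols divergence per stratum, in (0, 1).
#' @param ancestral_freq_bounds interval inside (0, 1) for ancestral
#'   frequencies.
#' @param n_founders number of founder animals.
#' @param alpha Dirichlet concentration of founder ancestry (< 1 gives
#'   near-unadmixed founders, > 1 well-mixed ones).
#' @param n_generations generations of gene dropping (0 = founders only).
#' @param sires_per_generation,offspring_per_sire half-sib family design.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(k_true = 3, m = 2000, fst = 0.25,
                       ancestral_freq_bounds = c(0.1, 0.9),
                       n_founders = 200, alpha = 0.2, n_generations = 2,
                       sires_per_generation = 5, offspring_per_sire = 20,
                       seed = 1L) {
  check_scalar(k_true, "k_true", 1)
  check_scalar(m, "m", 1)
  check_scalar(fst, "fst", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (length(ancestral_freq_bounds) != 2 ||
      ancestral_freq_bounds[1] <= 0 || ancestral_freq_bounds[2] >= 1 ||
      ancestral_freq_bounds[1] > ancestral_freq_bounds[2])
    stopf("ancestral_freq_bounds must be an interval inside (0, 1)")
  check_scalar(n_founders, "n_founders", 1)
  check_scalar(alpha, "alpha", 0, Inf, open_lower = TRUE)
  check_scalar(n_generations, "n_generations", 0)
  check_scalar(sires_per_generation, "sires_per_generation", 1)
  check_scalar(offspring_per_sire, "offspring_per_sire", 1)
  structure(list(k_true = as.integer(k_true), m = as.integer(m), fst = fst,
                 ancestral_freq_bounds = ancestral_freq_bounds,
                 n_founders = as.integer(n_founders), alpha = alpha,
                 n_generations = as.integer(n_generations),
                 sires_per_generation = as.integer(sires_per_generation),
                 offspring_per_sire = as.integer(offspring_per_sire),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Balding-Nichols strata allele frequencies
#'
#' For each marker an ancestral frequency `p0` is drawn uniformly from
#' `bounds`; each stratum's frequency is then drawn from
#' `Beta(p0 (1 - fst) / fst, (1 - p0)(1 - fst) / fst)`, which has mean `p0`
#' and variance `fst * p0 * (1 - p0)`. Frequencies are clipped to
#' `(1e-6, 1 - 1e-6)` so no locus is exactly fixed.
#'
#' @param m number of markers.
#' @param k number of strata.
#' @param fst divergence parameter in (0, 1).
#' @param bounds interval inside (0, 1) for the ancestral frequency.
#' @param seed integer seed.
#' @return an `m x k` matrix of strata allele frequencies, with attribute
#'   `"ancestral"` holding the `p0` draws.
#' @export
draw_strata_frequencies <- function(m, k, fst, bounds = c(0.1, 0.9),
                                    seed = 1L) {
  check_scalar(fst, "fst", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (bounds[1] <= 0 || bounds[2] >= 1 || bounds[1] > bounds[2])
    stopf("bounds must lie inside (0, 1)")
  with_local_seed(seed, {
    p0 <- stats::runif(m, bounds[1], bounds[2])
    lambda <- (1 - fst) / fst
    P <- matrix(stats::rbeta(m * k, rep(p0 * lambda, k),
                             rep((1 - p0) * lambda, k)), nrow = m, ncol = k)
    P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
    dimnames(P) <- list(paste0("M", seq_len(m)), paste0("S", seq_len(k)))
    attr(P, "ancestral") <- p0
    P
  })
}

#' Simulate an admixed, pedigreed population with known truth
#'
#' Draws strata frequencies (Balding-Nichols), founder ancestry rows
#' (Dirichlet), founder genotypes at marker `j` as two independent Bernoulli
#' alleles with success probability `q_i . p_j` (so the genotype is
#' Binomial(2, q_i . p_j)), and then gene-drops alleles through
#' `n_generations` of matings: each parent transmits one of its two alleles
#' per locus, chosen uniformly. Each generation, `sires_per_generation`
#' sires are drawn from the previous generation and each is mated to
#' `offspring_per_sire` distinct dams from that generation, producing
#' paternal half-sib families. The "true" ancestry of a non-founder is the
#' average of its parents' rows (the expectation of transmitted ancestry).
#'
#' @param config a [sim_config].
#' @return a list of class `sim_truth` with elements `pedigree` ([pedigree]),
#'   `genotypes` ([geno], with marker map), `Q_true` (n x k), `P_true`
#'   (m x k), `gamma_true` (the [gamma_matrix()] of `P_true`), `generation`
#'   (named integer vector), and `config`.
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    P <- draw_strata_frequencies(cfg$m, cfg$k_true, cfg$fst,
                                 cfg$ancestral_freq_bounds,
                                 seed = stats::runif(1, 1, 2^30))
    k <- cfg$k_true; m <- cfg$m; nf <- cfg$n_founders
    # founder ancestry: symmetric Dirichlet(alpha) via normalised gammas
    Gm <- matrix(stats::rgamma(nf * k, shape = cfg$alpha), nf, k)
    Q <- Gm / rowSums(Gm)
    # founder alleles
    pi_f <- Q %*% t(P)                 # nf x m expected allele frequency
    a1 <- matrix(stats::rbinom(nf * m, 1L, pi_f), nf, m)
    a2 <- matrix(stats::rbinom(nf * m, 1L, pi_f), nf, m)
    ids <- paste0("G0_", seq_len(nf))
    sire <- rep(NA_character_, nf); dam <- rep(NA_character_, nf)
    generation <- rep(0L, nf)
    prev <- seq_len(nf)
    for (g in seq_len(cfg$n_generations)) {
      n_prev <- length(prev)
      if (cfg$sires_per_generation > n_prev)
        stopf("generation %d needs %d sires but only %d candidates exist",
              g, cfg$sires_per_generation, n_prev)
      if (cfg$offspring_per_sire > n_prev - 1L)
        stopf("generation %d needs %d distinct dams per sire but only %d candidates exist",
              g, cfg$offspring_per_sire, n_prev - 1L)
      sires <- prev[sample.int(n_prev, cfg$sires_per_generation)]
      new_rows <- integer(0)
      for (s in sires) {
        cand <- setdiff(prev, s)
        dams <- cand[sample.int(length(cand), cfg$offspring_per_sire)]
        for (d in dams) {
          pick_s <- stats::rbinom(m, 1L, 0.5) == 1L
          pick_d <- stats::rbinom(m, 1L, 0.5) == 1L
          child_a1 <- ifelse(pick_s, a1[s, ], a2[s, ])
          child_a2 <- ifelse(pick_d, a1[d, ], a2[d, ])
          a1 <- rbind(a1, child_a1); a2 <- rbind(a2, child_a2)
          Q <- rbind(Q, (Q[s, ] + Q[d, ]) / 2)
          ids <- c(ids, paste0("G", g, "_", length(ids) + 1L))
          sire <- c(sire, ids[s]); dam <- c(dam, ids[d])
          generation <- c(generation, g)
          new_rows <- c(new_rows, length(ids))
        }
      }
      prev <- new_rows
    }
    counts <- a1 + a2
    dimnames(counts) <- list(ids, rownames(P))
    rownames(Q) <- ids; colnames(Q) <- colnames(P)
    map <- data.frame(marker = rownames(P),
                      chromosome = rep(seq_len(min(10L, m)), length.out = m),
                      position = seq_len(m) * 1000L)
    map <- map[order(map$chromosome, map$position), ]
    structure(list(pedigree = pedigree(ids, sire, dam),
                   genotypes = geno(counts, map = map),
                   Q_true = Q, P_true = P[, , drop = FALSE],
                   gamma_true = gamma_matrix(P),
                   generation = stats::setNames(generation, ids),
                   config = cfg),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d animals (%d founders), %d markers, ",
                     "%d strata, fst = %g\n"),
              nrow(x$Q_true), x$config$n_founders, x$config$m,
              x$config$k_true, x$config$fst))
  invisible(x)
}

#' Export a simulated dataset to plain-text files
#'
#' Writes `pedigree.csv`, `genotypes.tsv`, `map.csv` and the truth files
#' `Q_true.tsv`, `P_true.tsv`, `gamma_true.tsv` into `directory`.
#' [read_dataset()] reads them back into an equivalent object.
#'
#' @param truth a `sim_truth` from [simulate_population()].
#' @param directory output directory (created if absent).
#' @return the directory, invisibly.
#' @export
export_dataset <- function(truth, directory) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create directory '%s'", directory)
  wt <- function(x, file) {
    path <- file.path(directory, file)
    ok <- tryCatch({
      utils::write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                         path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stopf("failed to write '%s'", path)
  }
  write_pedigree(truth$pedigree, file.path(directory, "pedigree.csv"))
  write_genotypes(truth$genotypes, file.path(directory, "genotypes.tsv"))
  write_marker_map(truth$genotypes$map, file.path(directory, "map.csv"))
  wt(truth$Q_true, "Q_true.tsv")
  wt(truth$P_true, "P_true.tsv")
  wt(truth$gamma_true, "gamma_true.tsv")
  invisible(directory)
}

#' @rdname export_dataset
#' @export
read_dataset <- function(directory) {
  rt <- function(file) {
    df <- utils::read.delim(file.path(directory, file), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
  }
  map <- read_marker_map(file.path(directory, "map.csv"))
  list(pedigree = read_pedigree(file.path(directory, "pedigree.csv")),
       genotypes = read_genotypes(file.path(directory, "genotypes.tsv"),
                                  map = map),
       Q_true = rt("Q_true.tsv"), P_true = rt("P_true.tsv"),
       gamma_true = rt("gamma_true.tsv"))
}
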