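#' Watterson's theta from segregating sites
#'
#' theta = S / (a_n L) with a_n = sum_{i=1}^{n-1} 1/i, S the number of
#' segregating sites among `n_alleles` sampled alleles over `L` silent
#' sites. Can also be given a `population_sample`, from which S, n and L are
#' taken directly (a column counts once as segregating regardless of how
#' many allelic states it shows, the infinite-sites convention).
#'
#' @param S Number of segregating sites, or a `population_sample`.
#' @param n_alleles Number of sampled alleles (>= 2; ignored if `S` is a
#'   sample).
#' @param L Number of silent sites surveyed (> 0; ignored if `S` is a
#'   sample).
#' @return One-row tibble: statistic ("theta_s"), value (per site),
#'   n_alleles, L, S.
#' @examples
#' watterson_theta(S = 100, n_alleles = 10, L = 1e4)
#' @export
watterson_theta <- function(S, n_alleles = NULL, L = NULL) {
  if (inherits(S, "population_sample")) {
    smp <- S
    S <- ncol(smp$genotypes)
    n_alleles <- smp$n_alleles
    L <- smp$L
  }
  if (n_alleles < 2) abort("`n_alleles` must be >= 2.")
  if (L <= 0) abort("`L` must be > 0.")
  a_n <- sum(1 / seq_len(n_alleles - 1))
  tibble(statistic = "theta_s", value = S / (a_n * L),
         n_alleles = as.integer(n_alleles), L = as.integer(L),
         S = as.integer(S))
}

#' Nucleotide diversity (pi) of a population sample
#'
#' Average pairwise difference per site: pi = (n/(n-1)) * mean over sites of
#' 2 p (1 - p), where p is the derived-allele frequency; non-segregating
#' sites contribute zero and the denominator is all L sites.
#'
#' @param sample A `population_sample` (0/1 genotype matrix).
#' @return One-row tibble: statistic ("pi_s"), value (per site), n_alleles,
#'   L, S.
#' @export
nucleotide_diversity <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  n <- sample$n_alleles
  g <- sample$genotypes
  het <- if (ncol(g) == 0) 0 else {
    p <- colMeans(g)
    sum(2 * p * (1 - p)) * n / (n - 1)
  }
  tibble(statistic = "pi_s", value = het / sample$L,
         n_alleles = as.integer(n), L = as.integer(sample$L),
         S = ncol(sample$genotypes))
}

#' Effective population size from silent-site diversity
#'
#' Under neutral equilibrium the expected silent-site diversity equals
#' 4 Ne u in diploids and 2 Ne u in haploids; Ne is obtained by dividing
#' the diversity estimate by (2 or 4) x u_bs.
#'
#' @param diversity Per-site diversity value (theta_s or pi_s), or a one-row
#'   tibble from [watterson_theta()] / [nucleotide_diversity()].
#' @param u_bs Base-substitution mutation rate per site per generation (> 0).
#' @param ploidy "haploid" or "diploid".
#' @return One-row tibble: Ne, ploidy, statistic, diversity, u_bs.
#' @examples
#' effective_population_size(0.200, u_bs = 2.92e-10, ploidy = "haploid")
#' @export
effective_population_size <- function(diversity, u_bs,
                                      ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  statistic <- NA_character_
  if (is.data.frame(diversity)) {
    statistic <- diversity$statistic[1]
    diversity <- diversity$value[1]
  }
  if (any(u_bs <= 0)) abort("`u_bs` must be > 0.")
  fac <- if (ploidy == "haploid") 2 else 4
  tibble(Ne = diversity / (fac * u_bs), ploidy = ploidy,
         statistic = statistic, diversity = diversity, u_bs = u_bs)
}

#' Stability of Watterson's theta under allele subsampling
#'
#' Recomputes theta on random allele subsets of increasing size; a
#' diagnostic for whether the sampled allele count is large enough for a
#' stable estimate.
#'
#' @param sample A `population_sample`.
#' @param sizes Subsample sizes (each between 2 and `n_alleles`).
#' @param seed Optional integer seed.
#' @return Tibble with columns n_alleles, theta (one row per size).
#' @export
theta_stability <- function(sample, sizes, seed = NULL) {
  stopifnot(inherits(sample, "population_sample"))
  if (any(sizes < 2) || any(sizes > sample$n_alleles)) {
    abort("subsample sizes must lie in [2, n_alleles].")
  }
  with_seed_or_not(seed, {
    purrr::map_dfr(sizes, function(k) {
      rows <- if (k == sample$n_alleles) {
        seq_len(k)
      } else {
        sample.int(sample$n_alleles, k)
      }
      g <- sample$genotypes[rows, , drop = FALSE]
      seg <- sum(colSums(g) > 0 & colSums(g) < k)
      tibble(n_alleles = k,
             theta = watterson_theta(seg, k, sample$L)$value)
    })
  })
}
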