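#' Simulate a reference genome
#'
#' Draws an i.i.d. nucleotide sequence with a target GC content. The result is
#' a light-weight `reference_genome` object holding one base per site; it is
#' the coordinate system for all downstream mutation-accumulation (MA)
#' simulation and calling (positions are 0-based internally, 1-based in
#' emitted files).
#'
#' @param length Number of sites (>= 1).
#' @param gc Expected GC fraction in `[0, 1]`.
#' @param seed Optional integer seed; identical seeds give identical genomes.
#' @param label Sequence name used in FASTA/VCF output.
#' @return A `reference_genome`: list with `bases` (character vector of
#'   A/C/G/T, one per site) and `label`.
#' @examples
#' ref <- simulate_reference(100, gc = 0.4, seed = 1)
#' mean(ref$bases %in% c("G", "C"))
#' @export
simulate_reference <- function(length, gc = 0.5, seed = NULL, label = "chr1") {
  if (length(length) != 1 || is.na(length) || length < 1) {
    abort("`length` must be a single integer >= 1.")
  }
  if (gc < 0 || gc > 1) abort("`gc` must lie in [0, 1].")
  bases <- with_seed_or_not(seed, {
    sample(BASES, size = length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  })
  structure(list(bases = bases, label = label), class = "reference_genome")
}

#' @export
length.reference_genome <- function(x) length(x$bases)

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %d bp, GC %.3f\n", x$label,
              length(x$bases), mean(x$bases %in% c("G", "C"))))
  invisible(x)
}

#' Default indel size distribution
#'
#' Signed indel lengths (negative = deletion, positive = insertion) with a
#' short/large mixture: 85% of events are short (1-9 bp, geometrically
#' decaying within the class) and 15% are large (10-200 bp, uniform within
#' the class), mirroring the short/large event split observed in bacterial MA
#' data. Signs are symmetric.
#'
#' @param p_large Probability that an event is large (> 9 bp).
#' @param geom_rate Geometric decay for short lengths: P(len = k) proportional
#'   to `geom_rate^(k - 1)` for k in 1..9.
#' @param max_large Largest event size in bp.
#' @return A tibble with columns `size` (signed integer length, no zeros) and
#'   `prob` (summing to 1).
#' @export
indel_size_default <- function(p_large = 0.15, geom_rate = 0.5,
                               max_large = 200) {
  short <- geom_rate^(0:8)
  short <- short / sum(short) * (1 - p_large)
  large <- rep(p_large / (max_large - 9), max_large - 9)
  sizes <- c(1:9, 10:max_large)
  probs <- c(short, large)
  tibble(
    size = c(-rev(sizes), sizes),
    prob = c(rev(probs), probs) / 2
  )
}

new_mutation_events <- function(line_id = character(), position = integer(),
                                kind = character(), ref_base = NA_character_,
                                alt_base = NA_character_,
                                length = NA_integer_) {
  tibble(
    line_id = line_id, position = as.integer(position), kind = kind,
    ref_base = ref_base, alt_base = alt_base,
    length = as.integer(length),
    size_class = as.character(indel_size_class(kind, length))
  )
}

#' Classify indel events as short or large
#'
#' Events longer than 9 bp are "large"; substitutions get `NA`.
#'
#' @param kind Character vector: "substitution", "insertion" or "deletion".
#' @param length Event length in bp (`NA` for substitutions).
#' @return Character vector: "short", "large" or `NA`.
#' @export
indel_size_class <- function(kind, length) {
  ifelse(kind == "substitution", NA_character_,
         ifelse(length > 9, "large", "short"))
}

# Decompose merged indel events into per-base gap calls (position, sign),
# the raw representation an aligner-derived gap track would provide.
events_to_gap_calls <- function(events) {
  ev <- dplyr::filter(events, .data$kind != "substitution")
  if (nrow(ev) == 0) {
    return(tibble(position = integer(), sign = integer()))
  }
  purrr::pmap_dfr(list(ev$position, ev$length, ev$kind),
    function(pos, len, kind) {
      tibble(position = pos + 0:(len - 1),
             sign = if (kind == "deletion") -1L else 1L)
    }) %>%
    arrange(.data$position)
}

#' Simulate a mutation-accumulation experiment
#'
#' Generates ground-truth mutations for `n_lines` independently bottlenecked
#' MA lines. Per line, the number of base substitutions is Poisson with mean
#' `u_bs * n * t_gen` and the number of indel events Poisson with mean
#' `u_id * n * t_gen` (n = reference length); sites are uniform, substitution
#' alternate bases uniform over the three non-reference bases, and signed
#' indel lengths are drawn from `indel_size_dist`. Mutation totals are drawn
#' in a single Poisson per line rather than per transfer: under MA
#' bottlenecking selection is negligible and the estimators only see totals.
#'
#' Each line also carries two raw indel gap-call tracks emulating two
#' independent alignment algorithms: both contain the true events (the second
#' with a small per-event position jitter), plus line-specific false calls at
#' rate `indel_fp_rate` per site per track that only concordance filtering
#' removes. `n_ancestral_variants` substitution variants shared by every line
#' (founder variants relative to the reference) are planted to exercise
#' shared-variant screening; they are not part of any line's `true_events`.
#'
#' @param ref A `reference_genome`.
#' @param n_lines Number of MA lines (>= 1).
#' @param t_gen Generations elapsed per line (> 0).
#' @param u_bs,u_id True base-substitution / indel-event rates per site per
#'   generation (>= 0).
#' @param indel_size_dist Tibble with columns `size` (signed length) and
#'   `prob`; see [indel_size_default()].
#' @param indel_fp_rate Per-site rate of spurious single-base gap calls in
#'   each aligner track.
#' @param aligner_jitter Maximum absolute position offset (bp) of the second
#'   track's events.
#' @param n_ancestral_variants Founder substitution variants shared by all
#'   lines.
#' @param seed Optional integer seed.
#' @return An `ma_experiment`: list with `reference`, `lines` (list of
#'   `ma_line` objects with `line_id`, `true_events`, `gap_calls_a`,
#'   `gap_calls_b`), `t_gen`, `true_u_bs`, `true_u_id`,
#'   `ancestral_variants`, `seed`.
#' @examples
#' ref <- simulate_reference(1000, seed = 1)
#' ma <- simulate_ma_experiment(ref, n_lines = 3, t_gen = 1000,
#'                              u_bs = 1e-5, u_id = 2e-6, seed = 2)
#' true_events(ma)
#' @export
simulate_ma_experiment <- function(ref, n_lines, t_gen, u_bs, u_id,
                                   indel_size_dist = indel_size_default(),
                                   indel_fp_rate = 5e-7,
                                   aligner_jitter = 1,
                                   n_ancestral_variants = 0,
                                   seed = NULL) {
  stopifnot(inherits(ref, "reference_genome"))
  if (n_lines < 1) abort("`n_lines` must be >= 1.")
  if (t_gen <= 0) abort("`t_gen` must be > 0.")
  if (u_bs < 0 || u_id < 0) abort("mutation rates must be >= 0.")
  if (nrow(indel_size_dist) == 0 || any(indel_size_dist$size == 0) ||
      any(indel_size_dist$prob < 0) || sum(indel_size_dist$prob) <= 0) {
    abort("`indel_size_dist` must be non-empty with non-zero sizes and non-negative weights.")
  }
  n <- length(ref)
  with_seed_or_not(seed, {
    ancestral <- if (n_ancestral_variants > 0) {
      pos <- sample.int(n, n_ancestral_variants) - 1L
      tibble(position = pos,
             ref_base = ref$bases[pos + 1L],
             alt_base = purrr::map_chr(ref$bases[pos + 1L],
                                       ~ sample(setdiff(BASES, .x), 1)))
    } else {
      tibble(position = integer(), ref_base = character(),
             alt_base = character())
    }
    lines <- purrr::map(seq_len(n_lines), function(i) {
      simulate_ma_line(sprintf("line_%03d", i), ref, t_gen, u_bs, u_id,
                       indel_size_dist, indel_fp_rate, aligner_jitter)
    })
    structure(
      list(reference = ref, lines = lines, t_gen = t_gen,
           true_u_bs = u_bs, true_u_id = u_id,
           ancestral_variants = ancestral, seed = seed),
      class = "ma_experiment")
  })
}

simulate_ma_line <- function(line_id, ref, t_gen, u_bs, u_id,
                             indel_size_dist, indel_fp_rate, aligner_jitter) {
  n <- length(ref)
  m_bs <- rpois(1, u_bs * n * t_gen)
  m_id <- rpois(1, u_id * n * t_gen)
  sub_pos <- sort(sample.int(n, min(m_bs, n)) - 1L)
  subs <- new_mutation_events(
    line_id = rep(line_id, length(sub_pos)), position = sub_pos,
    kind = rep("substitution", length(sub_pos)),
    ref_base = ref$bases[sub_pos + 1L],
    alt_base = purrr::map_chr(ref$bases[sub_pos + 1L],
                              ~ sample(setdiff(BASES, .x), 1)))
  indels <- draw_indel_events(line_id, n, m_id, indel_size_dist)
  events <- bind_rows(subs, indels) %>% arrange(.data$position)

  true_calls <- events_to_gap_calls(events)
  jitter_b <- if (nrow(true_calls) > 0 && aligner_jitter > 0) {
    # one offset per event, applied to all of its per-base calls
    ev <- dplyr::filter(events, .data$kind != "substitution")
    offs <- sample(seq(-aligner_jitter, aligner_jitter), nrow(ev),
                   replace = TRUE)
    rep(offs, ev$length)
  } else {
    0L
  }
  calls_b <- true_calls
  if (nrow(calls_b) > 0) {
    calls_b$position <- pmax(0L, pmin(n - 1L,
                                      calls_b$position + jitter_b))
  }
  fp_a <- draw_false_gap_calls(n, indel_fp_rate)
  fp_b <- draw_false_gap_calls(n, indel_fp_rate)
  structure(
    list(line_id = line_id, true_events = events,
         gap_calls_a = bind_rows(true_calls, fp_a) %>%
           arrange(.data$position),
         gap_calls_b = bind_rows(calls_b, fp_b) %>%
           arrange(.data$position)),
    class = "ma_line")
}

# Place m indel events uniformly, rejecting placements that would merge with
# or contradict an already placed event (overlap or same-sign adjacency).
draw_indel_events <- function(line_id, n, m, indel_size_dist) {
  if (m == 0) {
    return(new_mutation_events())
  }
  sizes <- sample(indel_size_dist$size, m, replace = TRUE,
                  prob = indel_size_dist$prob)
  if (any(abs(sizes) >= n)) {
    abort("indel sizes must be smaller than the reference length.")
  }
  taken_lo <- integer(0)
  taken_hi <- integer(0)
  pos <- integer(m)
  for (i in seq_len(m)) {
    len <- abs(sizes[i])
    tries <- 0L
    repeat {
      p <- sample.int(n - len + 1L, 1) - 1L
      # keep one spacer base so adjacent events never merge
      if (!any(p <= taken_hi + 1L & (p + len - 1L) >= taken_lo - 1L)) break
      tries <- tries + 1L
      if (tries > 1000L) abort("could not place non-overlapping indel events; reference too short for the requested rate.")
    }
    pos[i] <- p
    taken_lo <- c(taken_lo, p)
    taken_hi <- c(taken_hi, p + len - 1L)
  }
  new_mutation_events(
    line_id = rep(line_id, m), position = pos,
    kind = ifelse(sizes < 0, "deletion", "insertion"),
    length = abs(sizes))
}

draw_false_gap_calls <- function(n, rate) {
  k <- rpois(1, rate * n)
  if (k == 0) {
    return(tibble(position = integer(), sign = integer()))
  }
  tibble(position = sample.int(n, k) - 1L,
         sign = sample(c(-1L, 1L), k, replace = TRUE))
}

#' @export
print.ma_experiment <- function(x, ...) {
  ev <- true_events(x)
  cat(sprintf(
    "<ma_experiment> %d lines x %d sites, T = %g generations\n",
    length(x$lines), length(x$reference), x$t_gen))
  cat(sprintf("  true u_bs = %g, true u_id = %g; %d substitutions, %d indel events planted\n",
              x$true_u_bs, x$true_u_id,
              sum(ev$kind == "substitution"), sum(ev$kind != "substitution")))
  invisible(x)
}

#' Ground-truth mutations of an MA experiment
#'
#' @param experiment An `ma_experiment`.
#' @return Tibble of all planted [mutation events][indel_size_class] across
#'   lines (line_id, position, kind, ref_base, alt_base, length, size_class).
#' @export
true_events <- function(experiment) {
  stopifnot(inherits(experiment, "ma_experiment"))
  purrr::map_dfr(experiment$lines, "true_events")
}

#' Simulate per-site read-count configurations for one MA line
#'
#' Emulates ~100x whole-genome resequencing of a clonal MA line reduced to
#' per-site base counts: per-site depth is Poisson(`mean_coverage`) split
#' binomially between strands, and each read reports the line's true base
#' with probability `1 - error_rate`, otherwise one of the three other bases
#' uniformly. The line's true base is the reference modified by the
#' experiment's shared founder variants and the line's own substitutions;
#' deleted sites get zero coverage.
#'
#' @param experiment An `ma_experiment`.
#' @param line_id Which line to sequence.
#' @param mean_coverage Mean depth per site (> 0).
#' @param error_rate Per read-base error probability in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return Tibble with one row per reference site: `position` (0-based) and
#'   the eight strand-specific counts `A,a,C,c,G,g,T,t` (upper = forward).
#' @export
simulate_site_counts <- function(experiment, line_id, mean_coverage = 100,
                                 error_rate = 1e-3, seed = NULL) {
  stopifnot(inherits(experiment, "ma_experiment"))
  if (mean_coverage <= 0) abort("`mean_coverage` must be > 0.")
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1).")
  line <- experiment_line(experiment, line_id)
  truth <- line_true_bases(experiment, line)
  with_seed_or_not(seed, {
    simulate_counts_from_truth(truth$base_code, truth$deleted,
                               mean_coverage, error_rate)
  })
}

experiment_line <- function(experiment, line_id) {
  ids <- purrr::map_chr(experiment$lines, "line_id")
  i <- match(line_id, ids)
  if (is.na(i)) abort(sprintf("unknown line_id '%s'", line_id))
  experiment$lines[[i]]
}

# Integer-coded true base per site for a line (founder variants + own
# substitutions applied), plus a deleted-site mask.
line_true_bases <- function(experiment, line) {
  code <- match(experiment$reference$bases, BASES)
  anc <- experiment$ancestral_variants
  if (nrow(anc) > 0) {
    code[anc$position + 1L] <- match(anc$alt_base, BASES)
  }
  ev <- line$true_events
  subs <- dplyr::filter(ev, .data$kind == "substitution")
  if (nrow(subs) > 0) {
    code[subs$position + 1L] <- match(subs$alt_base, BASES)
  }
  deleted <- rep(FALSE, length(code))
  dels <- dplyr::filter(ev, .data$kind == "deletion")
  if (nrow(dels) > 0) {
    for (i in seq_len(nrow(dels))) {
      deleted[dels$position[i] + seq_len(dels$length[i])] <- TRUE
    }
  }
  list(base_code = code, deleted = deleted)
}

simulate_counts_from_truth <- function(base_code, deleted, mean_coverage,
                                       error_rate) {
  n <- length(base_code)
  cov <- rpois(n, mean_coverage)
  cov[deleted] <- 0L
  fwd <- rbinom(n, cov, 0.5)
  rev <- cov - fwd
  strand_counts <- function(depth) {
    err <- rbinom(n, depth, error_rate)
    e1 <- rbinom(n, err, 1 / 3)
    e2 <- rbinom(n, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    # off-base columns in increasing code order, skipping the true base
    off <- matrix(0L, n, 3)
    off[, 1] <- e1; off[, 2] <- e2; off[, 3] <- e3
    cnt <- matrix(0L, n, 4)
    idx <- cbind(seq_len(n), base_code)
    cnt[idx] <- depth - err
    offcodes <- off_base_codes(base_code)
    for (j in 1:3) cnt[cbind(seq_len(n), offcodes[, j])] <-
      cnt[cbind(seq_len(n), offcodes[, j])] + off[, j]
    cnt
  }
  cf <- strand_counts(fwd)
  cr <- strand_counts(rev)
  tibble(position = 0:(n - 1L),
         A = cf[, 1], a = cr[, 1], C = cf[, 2], c = cr[, 2],
         G = cf[, 3], g = cr[, 3], T = cf[, 4], t = cr[, 4])
}

# For each site, codes of the three non-true bases (columns in code order).
off_base_codes <- function(base_code) {
  lut <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  lut[base_code, , drop = FALSE]
}

#' Simulate a neutral coalescent population sample
#'
#' Standard Kingman coalescent under the infinite-sites model: with k
#' lineages, coalescence waits an Exponential(k(k-1)/2) time; mutations fall
#' on branches as a Poisson process with rate `theta * L / 2` per unit
#' coalescent time, and each mutation yields one segregating 0/1 column
#' (derived state on the leaves under the mutated branch).
#'
#' @param n_alleles Number of sampled alleles (>= 2).
#' @param L Number of silent sites the sample represents (> 0).
#' @param theta Per-site population mutation rate (>= 0).
#' @param seed Optional integer seed.
#' @return A `population_sample`: list with `genotypes` (n_alleles x S 0/1
#'   matrix; S = number of segregating sites), `n_alleles`, `L`,
#'   `true_theta`.
#' @examples
#' s <- simulate_population_sample(10, L = 1000, theta = 0.01, seed = 1)
#' ncol(s$genotypes)  # segregating sites
#' @export
simulate_population_sample <- function(n_alleles, L, theta, seed = NULL) {
  if (n_alleles < 2) abort("`n_alleles` must be >= 2.")
  if (L <= 0) abort("`L` must be > 0.")
  if (theta < 0) abort("`theta` must be >= 0.")
  with_seed_or_not(seed, {
    # lineage membership per epoch: list of leaf index sets
    lineages <- as.list(seq_len(n_alleles))
    epochs <- list()
    k <- n_alleles
    while (k > 1) {
      t_k <- rexp(1, rate = k * (k - 1) / 2)
      epochs[[length(epochs) + 1]] <- list(sets = lineages, dt = t_k)
      pair <- sample.int(k, 2)
      merged <- c(lineages[[pair[1]]], lineages[[pair[2]]])
      lineages <- c(lineages[-pair], list(merged))
      k <- k - 1
    }
    epoch_len <- purrr::map_dbl(epochs, "dt")
    epoch_k <- purrr::map_int(epochs, ~ length(.x$sets))
    total_len <- sum(epoch_len * epoch_k)
    s_sites <- rpois(1, theta * L / 2 * total_len)
    geno <- matrix(0L, nrow = n_alleles, ncol = s_sites)
    if (s_sites > 0) {
      ep <- sample.int(length(epochs), s_sites, replace = TRUE,
                       prob = epoch_len * epoch_k)
      for (j in seq_len(s_sites)) {
        sets <- epochs[[ep[j]]]$sets
        carriers <- sets[[sample.int(length(sets), 1)]]
        geno[carriers, j] <- 1L
      }
    }
    structure(list(genotypes = geno, n_alleles = n_alleles, L = L,
                   true_theta = theta),
              class = "population_sample")
  })
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("<population_sample> %d alleles, %d silent sites, %d segregating (true theta = %g)\n",
              x$n_alleles, x$L, ncol(x$genotypes), x$true_theta))
  invisible(x)
}

#' Simulate a colony-count transfer log
#'
#' Colony sizes at the end of each growth period between single-colony
#' transfers, lognormally scattered around `mean_colony_cells`
#' (parameterized so the geometric mean equals `mean_colony_cells`;
#' `sdlog = 0` removes all noise). log2 of these counts estimates cell
#' divisions per transfer.
#'
#' @param n_transfers Number of transfers (>= 1).
#' @param mean_colony_cells Typical viable cell count per colony.
#' @param sdlog Lognormal scatter (SD on the natural-log scale).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_transfers` colony cell counts.
#' @export
simulate_transfer_log <- function(n_transfers, mean_colony_cells,
                                  sdlog = 0.2, seed = NULL) {
  if (n_transfers < 1) abort("`n_transfers` must be >= 1.")
  with_seed_or_not(seed, {
    exp(rnorm(n_transfers, mean = log(mean_colony_cells), sd = sdlog))
  })
}
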