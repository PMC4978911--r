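cfg <- calling_config()

test_that("consensus base applies coverage, fraction and strand thresholds", {
  row <- function(...) {
    out <- as.list(rep(0, 8))
    names(out) <- c("A", "a", "C", "c", "G", "g", "T", "t")
    out[names(list(...))] <- list(...)
    as.data.frame(out)
  }
  expect_identical(consensus_base(row(A = 50, a = 50), cfg), "A")
  expect_identical(consensus_base(row(A = 2, a = 1), cfg), NA_character_)
  # pooled fraction exactly at the threshold passes (80/100 >= 0.8)
  expect_identical(consensus_base(row(G = 40, g = 40, A = 20), cfg), "G")
  # just below the threshold fails
  expect_identical(consensus_base(row(G = 39, g = 40, A = 21), cfg),
                   NA_character_)
  # strand support: winning base needs both strands
  expect_identical(consensus_base(row(A = 99, a = 1), cfg), NA_character_)
  expect_error(calling_config(min_consensus_fraction = 0.5), "0.5")
})

test_that("callable sites agree with a brute-force per-site recount", {
  counts <- random_counts(500, mean_cov = 25, seed = 2)
  brute <- sum(vapply(seq_len(500), function(i) {
    !is.na(consensus_base(counts[i, , drop = FALSE], cfg))
  }, logical(1)))
  expect_identical(callable_sites(counts, cfg), brute)

  ref <- simulate_reference(300, seed = 3)
  ma <- simulate_ma_experiment(ref, 1, 100, 0, 0, seed = 4)
  clean <- simulate_site_counts(ma, "line_001", 100, 0, seed = 5)
  expect_identical(callable_sites(clean, cfg), 300L)
  # force 10 sites below min_coverage
  low <- clean
  low[1:10, c("A", "a", "C", "c", "G", "g", "T", "t")] <- 0L
  expect_identical(callable_sites(low, cfg), 290L)
})

test_that("planted substitutions are recovered exactly with no false positives", {
  ref <- simulate_reference(2e4, seed = 11)
  ma <- simulate_ma_experiment(ref, 10, 1000, u_bs = 2.5e-7, u_id = 0,
                               seed = 12)
  truth <- true_events(ma)
  expect_gt(nrow(truth), 30)
  called <- call_experiment(ma, cfg, mean_coverage = 100, error_rate = 1e-3,
                            seed = 13)
  key <- function(d) event_key(d, c("line_id", "position", "alt_base"))
  expect_equal(key(called$calls), key(truth))
})

test_that("lines identical to the reference yield zero calls", {
  ref <- simulate_reference(1000, seed = 21)
  ma <- simulate_ma_experiment(ref, 4, 100, 0, 0, seed = 22)
  called <- call_experiment(ma, cfg, 100, 0, seed = 23)
  expect_identical(nrow(called$calls), 0L)
  expect_identical(unname(called$callable$n), rep(1000, 4))
})

test_that("shared variants are screened out and flagged", {
  # consensus matrix interface: 6 lines, 20 sites, codes 1:4
  cons <- matrix(1L, nrow = 20, ncol = 6,
                 dimnames = list(NULL, paste0("L", 1:6)))
  cons[5, 2] <- 3L              # private variant -> called
  cons[9, c(3, 4)] <- 2L        # shared by 2 > max_lines_sharing -> flagged
  cons[15, ] <- 4L              # shared by all -> invisible without ref
  calls <- call_line_substitutions(cons, cfg)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$line_id, "L2")
  expect_identical(calls$position, 4L)
  expect_identical(calls$ref_base, "A")
  expect_identical(calls$alt_base, "G")
  shared <- attr(calls, "shared_variants")
  expect_identical(shared$position, 8L)
  expect_identical(shared$n_lines_sharing, 2L)

  # with a reference, the unanimous founder variant is flagged too
  ref <- structure(list(bases = rep("A", 20), label = "chr1"),
                   class = "reference_genome")
  calls2 <- call_line_substitutions(cons, cfg, ref = ref)
  shared2 <- attr(calls2, "shared_variants")
  expect_true(14L %in% shared2$position)
  expect_identical(nrow(calls2), 1L)
})

test_that("substitution calls are invariant to line ordering", {
  ref <- simulate_reference(5000, seed = 31)
  ma <- simulate_ma_experiment(ref, 6, 1000, u_bs = 1e-6, u_id = 0,
                               seed = 32)
  counts <- lapply(purrr::map_chr(ma$lines, "line_id"), function(id) {
    simulate_site_counts(ma, id, 80, 1e-3, seed = 100 + match(id, purrr::map_chr(ma$lines, "line_id")))
  })
  names(counts) <- purrr::map_chr(ma$lines, "line_id")
  fwd <- call_line_substitutions(counts, cfg)
  revd <- call_line_substitutions(rev(counts), cfg)
  key <- function(d) dplyr::arrange(tibble::as_tibble(d), line_id, position)
  expect_equal(key(fwd), key(revd))
})

test_that("gap runs merge into events and merging is idempotent", {
  one_del <- merge_indel_events(
    data.frame(position = c(100, 101, 102), sign = -1L))
  expect_identical(one_del$kind, "deletion")
  expect_identical(one_del$length, 3L)
  expect_identical(one_del$position, 100L)
  expect_identical(one_del$size_class, "short")

  two <- merge_indel_events(
    data.frame(position = c(100, 200), sign = c(-1L, 1L)))
  expect_identical(nrow(two), 2L)

  large <- merge_indel_events(
    data.frame(position = 500 + 0:11, sign = 1L))
  expect_identical(large$size_class, "large")
  expect_identical(large$length, 12L)

  # idempotence: decompose back to gap calls and re-merge
  again <- merge_indel_events(driftbarrier:::events_to_gap_calls(large))
  expect_equal(again$position, large$position)
  expect_equal(again$length, large$length)
  expect_equal(again$kind, large$kind)

  # contradictory calls at one position are dropped and reported
  confl <- merge_indel_events(
    data.frame(position = c(50, 50), sign = c(1L, -1L)))
  expect_identical(nrow(confl), 0L)
  expect_identical(attr(confl, "conflicts"), 50)
})

test_that("dual-callset intersection keeps concordant events only", {
  ev <- function(pos, kind, len) {
    driftbarrier:::new_mutation_events(
      line_id = rep("l1", length(pos)), position = pos, kind = kind,
      length = len)
  }
  a <- ev(c(1000, 3000), c("deletion", "insertion"), c(2L, 5L))
  expect_equal(intersect_indel_callsets(a, a, cfg)$position, a$position)
  only_a <- intersect_indel_callsets(a, a[1, ], cfg)
  expect_identical(only_a$position, 1000L)
  # positions within slop match once
  b <- ev(1002, "deletion", 2L)
  expect_identical(nrow(intersect_indel_callsets(a, b, cfg)), 1L)
  expect_identical(nrow(intersect_indel_callsets(
    a, ev(1004, "deletion", 2L), cfg)), 0L)
  # short events must agree in length, large ones need not
  expect_identical(nrow(intersect_indel_callsets(
    a, ev(1000, "deletion", 3L), cfg)), 0L)
  big_a <- ev(7000, "deletion", 20L)
  expect_identical(nrow(intersect_indel_callsets(
    big_a, ev(7001, "deletion", 18L), cfg)), 1L)

  # brute-force matching oracle on random callsets
  withr::with_seed(99, {
    for (rep in 1:20) {
      na <- sample(1:8, 1); nb <- sample(1:8, 1)
      ra <- ev(sample(1:500, na),
               sample(c("deletion", "insertion"), na, TRUE),
               sample(c(1:12), na, TRUE))
      rb <- ev(sample(1:500, nb),
               sample(c("deletion", "insertion"), nb, TRUE),
               sample(c(1:12), nb, TRUE))
      got <- intersect_indel_callsets(ra, rb, cfg)
      expect_equal(got$position, ra$position[match_events_brute(ra, rb, 3)])
    }
  })
})

test_that("called indels recover the planted events through both aligners", {
  ref <- simulate_reference(5e4, seed = 41)
  ma <- simulate_ma_experiment(ref, 8, 1000, u_bs = 0, u_id = 1e-7,
                               seed = 42)
  truth <- true_events(ma)
  expect_gt(nrow(truth), 10)
  calls <- purrr::map_dfr(ma$lines, call_line_indels, cfg = cfg)
  key <- function(d) event_key(d)
  expect_equal(key(calls), key(truth))
  # every called event lies within the reference
  expect_true(all(calls$position >= 0 & calls$position < 5e4))
})

test_that("false-positive substitution rate is negligible at 100x, error 1e-3", {
  ref <- simulate_reference(1e6, seed = 51)
  ma <- simulate_ma_experiment(ref, 3, 1000, 0, 0, seed = 52)
  called <- call_experiment(ma, cfg, mean_coverage = 100, error_rate = 1e-3,
                            seed = 53)
  n_callable <- sum(called$callable$n)
  expect_gt(n_callable, 2.9e6)
  # design bound: <= 1e-8 per callable site; at this size that means 0 calls
  expect_lte(nrow(called$calls) / n_callable, 1e-8)
})
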