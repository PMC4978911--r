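#' Consensus-calling configuration
#'
#' Thresholds for consensus base calling from per-site read-count
#' configurations and for cross-line screening of shared variants. Defaults
#' follow common practice for consensus callers on ~100x MA-line data; the
#' exact values are explicit, tunable stand-ins.
#'
#' @param min_coverage Minimum pooled depth for a site to be callable.
#' @param min_consensus_fraction Minimum fraction of pooled reads supporting
#'   the winning base (must exceed 0.5).
#' @param min_forward,min_reverse Minimum strand-specific support for the
#'   winning base.
#' @param max_lines_sharing A variant seen in more than this many lines is
#'   flagged as a putative ancestral/false call and excluded from mutation
#'   counts.
#' @param position_slop Maximum positional disagreement (bp) when matching
#'   indel events between the two aligner callsets.
#' @return A `calling_config` list.
#' @export
calling_config <- function(min_coverage = 10, min_consensus_fraction = 0.8,
                           min_forward = 2, min_reverse = 2,
                           max_lines_sharing = 1, position_slop = 3) {
  if (min_consensus_fraction <= 0.5 || min_consensus_fraction > 1) {
    abort("`min_consensus_fraction` must lie in (0.5, 1].")
  }
  structure(list(min_coverage = min_coverage,
                 min_consensus_fraction = min_consensus_fraction,
                 min_forward = min_forward, min_reverse = min_reverse,
                 max_lines_sharing = max_lines_sharing,
                 position_slop = position_slop),
            class = "calling_config")
}

#' Consensus base per site from a count configuration
#'
#' For each row of eight strand-specific counts (A,a,C,c,G,g,T,t), returns
#' the base whose pooled forward+reverse fraction reaches
#' `min_consensus_fraction`, provided total depth reaches `min_coverage` and
#' the winning base has at least `min_forward`/`min_reverse` reads on each
#' strand; otherwise `NA` (no-call).
#'
#' @param counts Data frame with columns `A,a,C,c,G,g,T,t` (one row per
#'   site), e.g. from [simulate_site_counts()].
#' @param cfg A [calling_config()].
#' @return Character vector (one element per row): "A","C","G","T" or `NA`.
#' @examples
#' counts <- data.frame(A = 50, a = 50, C = 0, c = 0,
#'                      G = 0, g = 0, T = 0, t = 0)
#' consensus_base(counts, calling_config())
#' @export
consensus_base <- function(counts, cfg = calling_config()) {
  BASES[consensus_codes(counts, cfg)]
}

# Integer-coded consensus (1:4 = A,C,G,T; NA = no-call); the workhorse used
# by the streamed pipeline so large experiments never hold character
# matrices.
consensus_codes <- function(counts, cfg) {
  fwd <- cbind(counts$A, counts$C, counts$G, counts$T)
  rev <- cbind(counts$a, counts$c, counts$g, counts$t)
  pooled <- fwd + rev
  depth <- rowSums(pooled)
  win <- max.col(pooled, ties.method = "first")
  idx <- cbind(seq_len(nrow(pooled)), win)
  ok <- depth >= cfg$min_coverage &
    pooled[idx] >= cfg$min_consensus_fraction * depth &
    fwd[idx] >= cfg$min_forward &
    rev[idx] >= cfg$min_reverse
  ifelse(ok, win, NA_integer_)
}

#' Callable sites for one MA line
#'
#' The number of sites at which the line yields a consensus call under `cfg`;
#' this is the denominator n in the per-line rate u = m / (n T).
#'
#' @inheritParams consensus_base
#' @return Integer count of callable sites.
#' @export
callable_sites <- function(counts, cfg = calling_config()) {
  sum(!is.na(consensus_codes(counts, cfg)))
}

#' Call substitution mutations across MA lines
#'
#' Implements reference-free consensus calling across lines: a substitution
#' is called for line i at a site when line i's consensus base differs from
#' the consensus shared by the other lines (their modal called base; ties
#' leave the site uncalled). A variant whose identical consensus is carried
#' by more than `max_lines_sharing` lines is excluded from the calls and
#' flagged as a putative ancestral/false call; when a reference is supplied,
#' sites where *every* line's consensus differs from the reference are also
#' flagged (such founder variants are otherwise invisible to a cross-line
#' caller).
#'
#' @param counts Named list (line_id -> per-site count data frame, all with
#'   the same sites in the same order) or a pre-computed consensus matrix
#'   (sites x lines, integer codes 1:4/`NA`, column names = line ids).
#' @param cfg A [calling_config()].
#' @param ref Optional `reference_genome` used only to flag all-line founder
#'   variants.
#' @return Tibble of substitution calls (line_id, position, kind, ref_base =
#'   cross-line consensus, alt_base, length, size_class) with an attribute
#'   `"shared_variants"`: tibble (position, alt_base, n_lines_sharing) of
#'   screened-out variants.
#' @export
call_line_substitutions <- function(counts, cfg = calling_config(),
                                    ref = NULL) {
  cons <- if (is.matrix(counts)) {
    counts
  } else {
    if (length(counts) < 2) abort("need counts for at least 2 lines.")
    vapply(counts, function(x) consensus_codes(x, cfg),
           integer(nrow(counts[[1]])))
  }
  if (ncol(cons) < 2) abort("need at least 2 lines.")
  call_substitutions_from_consensus(cons, cfg, ref)
}

call_substitutions_from_consensus <- function(cons, cfg, ref = NULL) {
  line_ids <- colnames(cons) %||% sprintf("line_%03d", seq_len(ncol(cons)))
  n_sites <- nrow(cons)
  base_count <- matrix(0L, n_sites, 4)
  for (b in 1:4) base_count[, b] <- rowSums(cons == b, na.rm = TRUE)
  n_called <- rowSums(base_count)
  max_count <- do.call(pmax, as.data.frame(base_count))
  modal <- max.col(base_count, ties.method = "first")

  ref_code <- if (!is.null(ref)) match(ref$bases, BASES) else NULL
  # candidate sites: any cross-line disagreement, or (with a reference) a
  # unanimous non-reference consensus
  cand <- which(n_called > 0 &
                  (max_count < n_called |
                     (!is.null(ref_code) & n_called > 0 &
                        modal != (ref_code %||% modal))))

  calls <- list()
  shared <- list()
  for (s in cand) {
    cnt <- base_count[s, ]
    for (i in which(!is.na(cons[s, ]))) {
      b <- cons[s, i]
      others <- cnt
      others[b] <- others[b] - 1L
      if (sum(others) == 0) next  # no other called line
      om <- which(others == max(others))
      if (length(om) > 1) next    # ambiguous cross-line consensus
      if (b == om) next
      n_sharing <- as.integer(cnt[b])
      if (n_sharing > cfg$max_lines_sharing) {
        shared[[length(shared) + 1]] <-
          tibble(position = s - 1L, alt_base = BASES[b],
                 n_lines_sharing = n_sharing)
      } else {
        calls[[length(calls) + 1]] <-
          tibble(line_id = line_ids[i], position = s - 1L,
                 ref_base = BASES[om], alt_base = BASES[b])
      }
    }
    # unanimous founder variant relative to the reference
    if (!is.null(ref_code) && max_count[s] == n_called[s] &&
        modal[s] != ref_code[s]) {
      shared[[length(shared) + 1]] <-
        tibble(position = s - 1L, alt_base = BASES[modal[s]],
               n_lines_sharing = as.integer(n_called[s]))
    }
  }
  out <- if (length(calls)) {
    cl <- bind_rows(calls) %>% distinct() %>%
      arrange(.data$line_id, .data$position)
    new_mutation_events(line_id = cl$line_id, position = cl$position,
                        kind = rep("substitution", nrow(cl)),
                        ref_base = cl$ref_base, alt_base = cl$alt_base)
  } else {
    new_mutation_events()
  }
  attr(out, "shared_variants") <- if (length(shared)) {
    bind_rows(shared) %>% distinct() %>% arrange(.data$position)
  } else {
    tibble(position = integer(), alt_base = character(),
           n_lines_sharing = integer())
  }
  out
}

#' Merge per-base gap calls into indel events
#'
#' Maximal runs of adjacent gap calls with the same sign are merged into a
#' single insertion or deletion event with summed length; the indel *event*,
#' not its size in bp, is the unit in which indel rates are expressed.
#' Positions carrying both an insertion and a deletion call are dropped and
#' reported in the `"conflicts"` attribute.
#'
#' @param gap_calls Data frame with columns `position` (0-based) and `sign`
#'   (+1 insertion, -1 deletion); one row per gapped base.
#' @param line_id Line identifier attached to the returned events.
#' @return Tibble of indel [mutation events][indel_size_class]; idempotent
#'   under re-application via [events_to_gaps()] semantics.
#' @examples
#' merge_indel_events(data.frame(position = c(100, 101, 102), sign = -1))
#' @export
merge_indel_events <- function(gap_calls, line_id = NA_character_) {
  gc <- as_tibble(gap_calls) %>% distinct() %>% arrange(.data$position)
  conflicts <- gc$position[duplicated(gc$position)]
  gc <- dplyr::filter(gc, !.data$position %in% conflicts)
  if (nrow(gc) == 0) {
    out <- new_mutation_events()
    attr(out, "conflicts") <- unique(conflicts)
    return(out)
  }
  run_id <- cumsum(c(TRUE, diff(gc$position) != 1 | diff(gc$sign) != 0))
  ev <- gc %>%
    mutate(run = run_id) %>%
    group_by(.data$run) %>%
    summarise(position = min(.data$position), length = n(),
              sign = .data$sign[1], .groups = "drop")
  out <- new_mutation_events(
    line_id = rep(line_id, nrow(ev)), position = ev$position,
    kind = ifelse(ev$sign < 0, "deletion", "insertion"),
    length = ev$length)
  attr(out, "conflicts") <- unique(conflicts)
  out
}

#' Intersect indel callsets from two aligners
#'
#' Emulates dual-aligner concordance filtering: an indel event is retained
#' only if both callsets contain an event of the same kind within
#' `position_slop` bp, with identical lengths additionally required for
#' short (<= 9 bp) events. Matching is greedy one-to-one in position order;
#' the retained event takes callset A's coordinates.
#'
#' @param events_a,events_b Merged indel-event tibbles for the same line
#'   (see [merge_indel_events()]).
#' @param cfg A [calling_config()] (supplies `position_slop`).
#' @return Tibble of concordant indel events.
#' @export
intersect_indel_callsets <- function(events_a, events_b,
                                     cfg = calling_config()) {
  a <- dplyr::filter(as_tibble(events_a), .data$kind != "substitution")
  b <- dplyr::filter(as_tibble(events_b), .data$kind != "substitution")
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, ])
  used <- rep(FALSE, nrow(b))
  keep <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(a))) {
    ok <- !used & b$kind == a$kind[i] &
      abs(b$position - a$position[i]) <= cfg$position_slop &
      (a$length[i] > 9 | b$length == a$length[i])
    j <- which(ok)[1]
    if (!is.na(j)) {
      used[j] <- TRUE
      keep[i] <- TRUE
    }
  }
  a[keep, ]
}

#' Call indel events for one MA line
#'
#' Merges each aligner's raw gap calls into events and keeps the
#' dual-aligner concordant set.
#'
#' @param line An `ma_line` (element of an `ma_experiment`).
#' @param cfg A [calling_config()].
#' @return Tibble of called indel events for the line.
#' @export
call_line_indels <- function(line, cfg = calling_config()) {
  ev_a <- merge_indel_events(line$gap_calls_a, line_id = line$line_id)
  ev_b <- merge_indel_events(line$gap_calls_b, line_id = line$line_id)
  intersect_indel_callsets(ev_a, ev_b, cfg)
}
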