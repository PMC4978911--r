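#' Per-line mutation rate and its standard error
#'
#' The per-line rate is u = m / (n T) with m observed mutations, n callable
#' sites and T generations; its Poisson-sampling standard error is
#' sqrt(u / (n T)). Vectorized over lines.
#'
#' @param m Observed mutation count(s) (>= 0).
#' @param n Callable sites per line (> 0).
#' @param t_gen Generations per line (> 0).
#' @param line_id Optional line identifiers.
#' @return Tibble with columns line_id, m, n, t_gen, u, se.
#' @examples
#' line_rate(m = 20, n = 4e6, t_gen = 5000)
#' @export
line_rate <- function(m, n, t_gen, line_id = NULL) {
  if (any(n <= 0)) abort("`n` must be > 0.")
  if (any(t_gen <= 0)) abort("`t_gen` must be > 0.")
  if (any(m < 0)) abort("`m` must be >= 0.")
  u <- m / (n * t_gen)
  tibble(
    line_id = line_id %||% sprintf("line_%03d", seq_along(u)),
    m = m, n = n, t_gen = t_gen,
    u = u, se = sqrt(u / (n * t_gen))
  )
}

#' Pool per-line rates across an MA experiment
#'
#' The pooled rate is the unweighted mean of the per-line rates, with
#' standard error equal to the SD of the per-line rates divided by the
#' square root of the number of lines.
#'
#' @param rates Tibble of per-line rates from [line_rate()] (requires column
#'   `u`).
#' @return One-row tibble: mean_u, s (across-line SD), n_lines, se_pooled.
#' @export
pooled_rate <- function(rates) {
  if (nrow(rates) < 2) abort("need at least 2 lines to pool.")
  s <- sd(rates$u)
  tibble(mean_u = mean(rates$u), s = s, n_lines = nrow(rates),
         se_pooled = s / sqrt(nrow(rates)))
}

#' Generations elapsed from colony cell counts
#'
#' Divisions per transfer are estimated as the mean of log2(viable cells per
#' colony): a colony founded by one cell reaches N cells after log2(N)
#' doublings. Total generations T = divisions per transfer x number of
#' transfers.
#'
#' @param cell_counts Viable cell counts of sampled colonies (>= 1 each).
#' @param n_transfers Total single-colony transfers in the MA design.
#' @return One-row tibble: divisions_per_transfer, n_transfers, t_gen.
#' @examples
#' generations_from_colonies(2^20, n_transfers = 100)  # T = 2000
#' @export
generations_from_colonies <- function(cell_counts, n_transfers) {
  if (length(cell_counts) == 0) abort("`cell_counts` is empty.")
  if (any(cell_counts < 1)) abort("`cell_counts` must be >= 1.")
  if (n_transfers < 1) abort("`n_transfers` must be >= 1.")
  div <- mean(log2(cell_counts))
  tibble(divisions_per_transfer = div, n_transfers = n_transfers,
         t_gen = div * n_transfers)
}

#' Split called events into substitution and indel rates
#'
#' Counts substitutions and indel *events* (post-merge; a 50-bp deletion is
#' one event) and converts each to a rate via [line_rate()].
#'
#' @param events Tibble of mutation events with a `kind` column
#'   ("substitution", "insertion", "deletion").
#' @param n Callable sites.
#' @param t_gen Generations.
#' @param line_id Line identifier for the output rows.
#' @return Tibble with two rows (type = "bs", "id") and columns of
#'   [line_rate()].
#' @export
split_rates <- function(events, n, t_gen, line_id = NA_character_) {
  bad <- setdiff(unique(events$kind),
                 c("substitution", "insertion", "deletion"))
  if (length(bad)) {
    abort(paste0("unclassified event kind(s): ", paste(bad, collapse = ", ")))
  }
  m_bs <- sum(events$kind == "substitution")
  m_id <- sum(events$kind != "substitution")
  bind_rows(
    mutate(line_rate(m_bs, n, t_gen, line_id = line_id), type = "bs"),
    mutate(line_rate(m_id, n, t_gen, line_id = line_id), type = "id")
  ) %>%
    select("type", dplyr::everything())
}

#' Per-line substitution and indel rates for a whole experiment
#'
#' Joins per-line called events with per-line callable-site counts and a
#' shared (or per-line) generation count. Lines with zero callable sites are
#' dropped with a warning.
#'
#' @param events Tibble of called events across lines (column `line_id`).
#' @param callable Tibble with columns `line_id`, `n`.
#' @param t_gen Generations: a scalar shared by all lines, or a vector named
#'   by line id.
#' @return Tibble of per-line rates, one row per line and type ("bs"/"id").
#' @export
ma_line_rates <- function(events, callable, t_gen) {
  drop <- callable$n <= 0
  if (any(drop)) {
    warn(sprintf("dropping %d line(s) with no callable sites: %s",
                 sum(drop), paste(callable$line_id[drop], collapse = ", ")))
    callable <- callable[!drop, ]
  }
  t_of <- function(id) {
    if (length(t_gen) == 1 && is.null(names(t_gen))) t_gen else t_gen[[id]]
  }
  purrr::map_dfr(seq_len(nrow(callable)), function(i) {
    id <- callable$line_id[i]
    ev <- dplyr::filter(events, .data$line_id == id)
    split_rates(ev, callable$n[i], t_of(id), line_id = id)
  })
}
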