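#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the simulate -> call -> estimate -> popgen ->
#' comparative pipeline. The default scale is a demonstration-sized MA
#' experiment that runs in seconds; the defaults for coverage, error rate
#' and rates mirror the regime the estimators are designed for (~100x
#' clonal resequencing, thousands of generations).
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param n_sites Reference length (bp).
#' @param gc Reference GC content.
#' @param n_lines Number of MA lines.
#' @param t_gen Generations per line.
#' @param u_bs,u_id True mutation rates per site per generation.
#' @param mean_coverage,error_rate Sequencing model.
#' @param n_alleles,pop_L,theta Population-sample stage.
#' @param calling A [calling_config()].
#' @param ploidy Ploidy used when converting diversity to Ne.
#' @param s_coeff,t_link Antimutator-threshold parameters.
#' @param species_table,tree Paths to comparative inputs (`NULL` = packaged
#'   fixtures).
#' @param out_dir Optional directory; when set, stage outputs are written as
#'   FASTA/VCF/TSV files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_sites = 1e5, gc = 0.5, n_lines = 8,
                            t_gen = 2000, u_bs = 2e-8, u_id = 5e-9,
                            mean_coverage = 100, error_rate = 1e-3,
                            n_alleles = 20, pop_L = 1e4, theta = 0.01,
                            calling = calling_config(),
                            ploidy = "haploid",
                            s_coeff = 0.01, t_link = 2,
                            species_table = NULL, tree = NULL,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes, in order: reference + MA-experiment simulation, per-line
#' sequencing simulation and consensus substitution calling (streamed line
#' by line so only one line's counts are in memory at a time), dual-aligner
#' indel calling, per-line and pooled rate estimation, coalescent
#' population-sample simulation with theta/pi/Ne estimation, and the
#' comparative analysis on the packaged species table and tree. Per-stage
#' summaries are logged to stderr. Identical configurations produce
#' identical results and an identical manifest hash.
#'
#' @param config A [pipeline_config()].
#' @return A list with `manifest` (see [run_manifest()]) and per-stage
#'   results: `experiment`, `calls`, `callable`, `rates` (per line),
#'   `pooled` (per type), `diversity`, `ne`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, code) {
    inform(sprintf("[driftbarrier] stage: %s", name))
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  cfg <- config
  ref <- stage("simulate reference", {
    simulate_reference(cfg$n_sites, cfg$gc, seed = cfg$seed)
  })
  ma <- stage("simulate MA experiment", {
    simulate_ma_experiment(ref, cfg$n_lines, cfg$t_gen, cfg$u_bs, cfg$u_id,
                           seed = cfg$seed + 1L)
  })
  called <- stage("sequence and call lines", {
    call_experiment(ma, cfg$calling, cfg$mean_coverage, cfg$error_rate,
                    seed = cfg$seed + 2L)
  })
  rates <- stage("estimate rates", {
    ma_line_rates(called$calls, called$callable, cfg$t_gen)
  })
  pooled <- stage("pool rates", {
    rates %>%
      group_by(.data$type) %>%
      dplyr::group_modify(~ pooled_rate(.x)) %>%
      ungroup()
  })
  pop <- stage("simulate population sample", {
    simulate_population_sample(cfg$n_alleles, cfg$pop_L, cfg$theta,
                               seed = cfg$seed + 3L)
  })
  diversity <- stage("estimate diversity", {
    bind_rows(watterson_theta(pop), nucleotide_diversity(pop))
  })
  ne <- stage("effective population size", {
    u_hat <- pooled$mean_u[pooled$type == "bs"]
    effective_population_size(diversity[1, ], u_hat, cfg$ploidy)
  })
  report <- stage("comparative analysis", {
    reproduce_analysis(read_species_table(cfg$species_table),
                    read_newick(cfg$tree), cfg$s_coeff, cfg$t_link)
  })
  if (!is.null(cfg$out_dir)) {
    stage("write outputs", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_reference_fasta(ref, file.path(cfg$out_dir, "reference.fasta"))
      write_mutations_vcf(true_events(ma), ref,
                          file.path(cfg$out_dir, "truth.vcf"))
      write_mutations_tsv(called$calls,
                          file.path(cfg$out_dir, "calls.tsv"))
      readr::write_tsv(rates, file.path(cfg$out_dir, "rates_per_line.tsv"))
      readr::write_tsv(pooled, file.path(cfg$out_dir, "rates_pooled.tsv"))
      readr::write_tsv(diversity, file.path(cfg$out_dir, "diversity.tsv"))
      write_population_tsv(pop, file.path(cfg$out_dir, "population.tsv"))
    })
  }
  list(manifest = run_manifest(config), experiment = ma,
       calls = called$calls, callable = called$callable,
       rates = rates, pooled = pooled, diversity = diversity, ne = ne,
       report = report)
}

#' Sequence and call an entire MA experiment
#'
#' For each line, simulates per-site count configurations, reduces them to
#' consensus calls and callable-site counts, then applies cross-line
#' substitution calling and dual-aligner indel calling. Counts are
#' generated and discarded line by line.
#'
#' @param experiment An `ma_experiment`.
#' @param cfg A [calling_config()].
#' @param mean_coverage,error_rate Sequencing model (see
#'   [simulate_site_counts()]).
#' @param seed Optional integer seed.
#' @return List: `calls` (tibble of substitution + indel events across
#'   lines), `callable` (tibble line_id, n), `shared_variants` (screened
#'   substitution variants).
#' @export
call_experiment <- function(experiment, cfg = calling_config(),
                            mean_coverage = 100, error_rate = 1e-3,
                            seed = NULL) {
  n <- length(experiment$reference)
  ids <- purrr::map_chr(experiment$lines, "line_id")
  cons <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  with_seed_or_not(seed, {
    for (i in seq_along(ids)) {
      counts <- simulate_site_counts(experiment, ids[i], mean_coverage,
                                     error_rate, seed = NULL)
      cons[, i] <- consensus_codes(counts, cfg)
    }
  })
  subs <- call_line_substitutions(cons, cfg, ref = experiment$reference)
  indels <- purrr::map_dfr(experiment$lines, call_line_indels, cfg = cfg)
  callable <- tibble(line_id = ids,
                     n = colSums(!is.na(cons)))
  list(calls = bind_rows(as_tibble(subs), indels) %>%
         arrange(.data$line_id, .data$position),
       callable = callable,
       shared_variants = attr(subs, "shared_variants"))
}

#' Manifest describing a pipeline run
#'
#' Hashes the configuration and the comparative input files so that
#' identical configurations + inputs yield an identical manifest hash;
#' the timestamp is informational and excluded from the hash.
#'
#' @param config A [pipeline_config()].
#' @return List: version, config_hash, input_hashes, hash, timestamp.
#' @export
run_manifest <- function(config) {
  paths <- c(
    species_table = config$species_table %||%
      system.file("extdata", "species_table.csv", package = "driftbarrier"),
    tree = config$tree %||%
      system.file("extdata", "species_tree.nwk", package = "driftbarrier"))
  input_hashes <- vapply(paths, function(p) rlang::hash(readLines(p)),
                         character(1))
  cfg_hash <- rlang::hash(unclass(config))
  list(version = as.character(utils::packageVersion("driftbarrier")),
       config_hash = cfg_hash,
       input_hashes = input_hashes,
       hash = rlang::hash(list(cfg_hash, input_hashes)),
       timestamp = format(Sys.time(), tz = "UTC"))
}
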