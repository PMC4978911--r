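#' Read the comparative species table
#'
#' Loads a species table in the packaged format (printed, scaled units:
#' genome sizes x 1e7 sites, rates x 1e-10 per site per generation, Ne x
#' 1e6) and resolves all columns to absolute units. The packaged default
#' transcribes the published 15-species comparative table; its `Ne` column
#' stores the tabulated Ne, which [recompute_ne()] can compare against the
#' value implied by each row's diversity and u_bs (the M. musculus row is
#' flagged as a known discrepancy).
#'
#' @param path CSV path; default is the packaged fixture.
#' @return Tibble with one row per species: name, label, group
#'   ("bacteria"/"unicellular_eukaryote"/"multicellular_eukaryote"), ploidy,
#'   Ge, Gc_plus_Gnc (sites), u_id, u_bs (per site per generation),
#'   diversity_value, diversity_digits (decimal places as printed),
#'   diversity_type ("theta"/"pi"), Ne (individuals), ne_flag.
#' @examples
#' tab <- read_species_table()
#' table(tab$group)
#' @export
read_species_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "species_table.csv",
                                package = "driftbarrier")
  # read everything as character: the printed number of decimals in
  # diversity_value is meaningful (it sets the rounding tolerance later)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  needed <- c("name", "label", "group", "ploidy", "Ge_1e7_sites",
              "Gc_plus_Gnc_1e7_sites", "u_id_1e-10", "u_bs_1e-10",
              "diversity_value", "diversity_type", "Ne_printed_1e6",
              "ne_flag")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    abort(paste0("species table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort("species table has a header but no rows.")
  out <- tibble(
    name = raw$name, label = raw$label, group = raw$group,
    ploidy = raw$ploidy,
    Ge = as.numeric(raw$Ge_1e7_sites) * 1e7,
    Gc_plus_Gnc = as.numeric(raw$Gc_plus_Gnc_1e7_sites) * 1e7,
    u_id = as.numeric(raw$`u_id_1e-10`) * 1e-10,
    u_bs = as.numeric(raw$`u_bs_1e-10`) * 1e-10,
    diversity_value = as.numeric(raw$diversity_value),
    diversity_digits = decimal_places(raw$diversity_value),
    diversity_type = raw$diversity_type,
    Ne = as.numeric(raw$Ne_printed_1e6) * 1e6,
    ne_flag = as.logical(raw$ne_flag)
  )
  for (col in c("Ge", "Gc_plus_Gnc", "u_id", "u_bs", "diversity_value",
                "Ne")) {
    bad <- which(!is.finite(out[[col]]) | out[[col]] <= 0)
    if (length(bad)) {
      abort(sprintf("non-positive or missing %s for row(s): %s", col,
                    paste(out$name[bad], collapse = ", ")))
    }
  }
  if (any(out$Gc_plus_Gnc < out$Ge)) {
    abort("Gc_plus_Gnc must be >= Ge for every species.")
  }
  out
}

decimal_places <- function(x) {
  vapply(strsplit(x, ".", fixed = TRUE), function(p) {
    if (length(p) < 2) 0L else nchar(p[2])
  }, integer(1))
}

#' Write a species table back to CSV (printed units)
#'
#' Inverse of [read_species_table()]: rescales absolute columns to the
#' packaged printed units so that a write/read round trip is the identity.
#'
#' @param records Tibble from [read_species_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(records, path) {
  out <- tibble(
    name = records$name, label = records$label, group = records$group,
    ploidy = records$ploidy,
    `Ge_1e7_sites` = records$Ge / 1e7,
    `Gc_plus_Gnc_1e7_sites` = records$Gc_plus_Gnc / 1e7,
    `u_id_1e-10` = records$u_id / 1e-10,
    `u_bs_1e-10` = records$u_bs / 1e-10,
    diversity_value = formatC(records$diversity_value, format = "f",
                              digits = max(records$diversity_digits)),
    diversity_type = records$diversity_type,
    `Ne_printed_1e6` = records$Ne / 1e6,
    ne_flag = records$ne_flag
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a phylogeny in newick format
#'
#' @param path Newick file; default is the packaged 15-species tree (all
#'   branch lengths 1).
#' @param labels Optional character vector of expected tip labels; any
#'   mismatch aborts listing the offending names.
#' @return An ape `phylo` tree.
#' @export
read_newick <- function(path = NULL, labels = NULL) {
  path <- path %||% system.file("extdata", "species_tree.nwk",
                                package = "driftbarrier")
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(sprintf("could not parse newick file '%s'", path))
  if (!is.null(labels)) {
    extra <- setdiff(tree$tip.label, labels)
    missing <- setdiff(labels, tree$tip.label)
    if (length(extra) || length(missing)) {
      abort(paste0(
        "tree/table label mismatch.",
        if (length(missing)) paste0(" Missing from tree: ",
                                    paste(missing, collapse = ", "), "."),
        if (length(extra)) paste0(" Unknown in tree: ",
                                  paste(extra, collapse = ", "), ".")))
    }
  }
  tree
}

#' Write a reference genome as FASTA
#'
#' @param ref A `reference_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  seq <- Biostrings::DNAStringSet(paste(ref$bases, collapse = ""))
  names(seq) <- ref$label
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path (first record is used).
#' @return A `reference_genome`.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) abort(sprintf("no sequences in '%s'", path))
  structure(list(bases = strsplit(as.character(seqs[[1]]), "")[[1]],
                 label = names(seqs)[1]),
            class = "reference_genome")
}

#' Write mutation events as a minimal VCF
#'
#' Standard VCF encoding against the reference: substitutions are written at
#' POS = position + 1 with single-base REF/ALT; a deletion of length L at
#' 0-based position p is anchored at the preceding base (POS = p, REF =
#' anchor + deleted sequence, ALT = anchor); an insertion at p is anchored
#' the same way with the inserted bases appended to ALT (inserted sequence
#' is drawn here as repeated `N` placeholders are not allowed in VCF, so an
#' arbitrary fixed base is used; event coordinates and lengths, the
#' quantities the estimators consume, round-trip exactly). One genotype
#' column per line id; carriers get `1`, others `0`.
#'
#' @param events Tibble of mutation events (line_id, position, kind,
#'   ref_base, alt_base, length).
#' @param ref The `reference_genome` the positions refer to.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_mutations_vcf <- function(events, ref, path) {
  line_ids <- sort(unique(events$line_id))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref$label, length(ref)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", line_ids), collapse = "\t")
  )
  ev <- arrange(as_tibble(events), .data$position, .data$line_id)
  key <- paste(ev$position, ev$kind, ev$length, ev$alt_base)
  rows <- purrr::map_chr(which(!duplicated(key)), function(i) {
    pos0 <- ev$position[i]
    if (ev$kind[i] == "substitution") {
      pos1 <- pos0 + 1L
      ref_f <- ref$bases[pos0 + 1L]
      alt_f <- ev$alt_base[i]
    } else if (ev$kind[i] == "deletion") {
      pos1 <- pos0  # anchor base before the deleted run
      anchor <- if (pos0 >= 1) ref$bases[pos0] else "N"
      ref_f <- paste0(anchor, paste(
        ref$bases[pos0 + seq_len(ev$length[i])], collapse = ""))
      alt_f <- anchor
    } else {
      pos1 <- pos0
      anchor <- if (pos0 >= 1) ref$bases[pos0] else "N"
      ref_f <- anchor
      alt_f <- paste0(anchor, strrep("A", ev$length[i]))
    }
    carriers <- ev$line_id[key == key[i]]
    gt <- ifelse(line_ids %in% carriers, "1", "0")
    paste(c(ref$label, pos1, ".", ref_f, alt_f, ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read mutation events from a minimal VCF
#'
#' Inverse of [write_mutations_vcf()]: recovers per-line mutation events
#' (0-based positions, kinds, lengths) from REF/ALT shapes and the genotype
#' columns.
#'
#' @param path VCF path.
#' @return Tibble of mutation events.
#' @export
read_mutations_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (nrow(fix) == 0) return(new_mutation_events())
  line_ids <- colnames(gt)[-1]
  purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    pos1 <- as.integer(fix$POS[i])
    ref_f <- fix$REF[i]
    alt_f <- fix$ALT[i]
    carriers <- line_ids[gt[i, -1] == "1"]
    if (nchar(ref_f) == 1 && nchar(alt_f) == 1) {
      new_mutation_events(line_id = carriers,
                          position = rep(pos1 - 1L, length(carriers)),
                          kind = rep("substitution", length(carriers)),
                          ref_base = ref_f, alt_base = alt_f)
    } else if (nchar(ref_f) > nchar(alt_f)) {
      len <- nchar(ref_f) - nchar(alt_f)
      new_mutation_events(line_id = carriers,
                          position = rep(pos1, length(carriers)),
                          kind = rep("deletion", length(carriers)),
                          length = len)
    } else {
      len <- nchar(alt_f) - nchar(ref_f)
      new_mutation_events(line_id = carriers,
                          position = rep(pos1, length(carriers)),
                          kind = rep("insertion", length(carriers)),
                          length = len)
    }
  }) %>%
    arrange(.data$line_id, .data$position)
}

#' Write mutation events as TSV
#'
#' Positions are emitted 1-based (`position_1based`); all other columns are
#' as in the event tibble.
#'
#' @param events Tibble of mutation events.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutations_tsv <- function(events, path) {
  out <- as_tibble(events) %>%
    mutate(position_1based = .data$position + 1L) %>%
    select("line_id", "position_1based", "kind", "ref_base", "alt_base",
           "length", "size_class")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write per-site count configurations as TSV
#'
#' @param counts Count tibble from [simulate_site_counts()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_counts_tsv <- function(counts, path) {
  out <- mutate(counts, position_1based = .data$position + 1L) %>%
    select("position_1based", "A", "a", "C", "c", "G", "g", "T", "t")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a population sample's genotype matrix as TSV
#'
#' 0/1 matrix, one row per allele, one column per segregating site.
#'
#' @param sample A `population_sample`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_population_tsv <- function(sample, path) {
  g <- sample$genotypes
  colnames(g) <- if (ncol(g) > 0) paste0("site_", seq_len(ncol(g))) else NULL
  readr::write_tsv(as_tibble(as.data.frame(g)), path)
  invisible(path)
}
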