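# Deterministic synthetic fixtures: a two-chain dimer whose inter-chain
# region distances are planted by construction, plus matching annotations and
# toy catalogs, so the full bottom-up -> top-down pipeline is testable
# offline with known ground truth.

#' Specify a synthetic dimer fixture
#'
#' Defines a two-chain toy structure with `n_planted` truly-interacting
#' region pairs (minimum CA-CA distance drawn from `planted_distance_range`,
#' default 4.5-5.5 Angstrom — comfortably inside a 6-Angstrom contact
#' filter) and `n_decoys` catalogued-but-distant pairs (distance drawn from
#' `decoy_distance_range`, never below `decoy_floor`, default 20 Angstrom —
#' far outside any swept cutoff). All randomness is consumed here, under
#' `seed`, so the generators downstream are purely deterministic functions
#' of the spec.
#'
#' @param seed integer RNG seed.
#' @param n_planted,n_decoys pair counts.
#' @param region_length residues per region.
#' @param planted_distance_range,decoy_distance_range target minimum
#'   distances (Angstrom) for planted and decoy pairs.
#' @param decoy_floor smallest admissible decoy distance.
#' @param ca_spacing CA-CA spacing along each region (3.8 Angstrom, the
#'   canonical backbone virtual-bond length).
#' @param block_gap spatial separation between successive region pairs,
#'   large enough that cross-pair distances never interfere.
#' @return object of class `fixture_spec`.
#' @export
toy_fixture_spec <- function(seed = 1, n_planted = 3, n_decoys = 2,
                             region_length = 8,
                             planted_distance_range = c(4.5, 5.5),
                             decoy_distance_range = c(20, 30),
                             decoy_floor = 20,
                             ca_spacing = 3.8, block_gap = 100) {
  if (n_planted < 1) generation_error("need at least one planted pair")
  if (decoy_distance_range[1] < decoy_floor) {
    generation_error(sprintf("decoy distance range starts below the stated floor (%g Angstrom)",
                             decoy_floor))
  }
  if (planted_distance_range[1] <= 0) generation_error("planted distances must be positive")
  set.seed(as.integer(seed))
  n <- n_planted + n_decoys
  target <- round(c(
    stats::runif(n_planted, planted_distance_range[1], planted_distance_range[2]),
    if (n_decoys > 0) stats::runif(n_decoys, decoy_distance_range[1], decoy_distance_range[2])
  ), 3)
  kind <- c(rep("planted", n_planted), rep("decoy", n_decoys))
  # alternate interaction kinds so both catalog routes are exercised
  itype <- ifelse(seq_len(n) %% 2 == 1, "DDI", "DMI")
  L <- as.integer(region_length)
  pairs <- data.frame(
    pair_id = sprintf("pair%02d", seq_len(n)),
    kind = kind,
    interaction_kind = itype,
    start_a = (seq_len(n) - 1L) * L + 1L,
    end_a = seq_len(n) * L,
    start_b = (seq_len(n) - 1L) * L + 1L,
    end_b = seq_len(n) * L,
    target_distance = target,
    stringsAsFactors = FALSE
  )
  structure(list(seed = as.integer(seed), n_planted = n_planted,
                 n_decoys = n_decoys, region_length = L,
                 ca_spacing = ca_spacing, block_gap = block_gap,
                 decoy_floor = decoy_floor, pairs = pairs),
            class = "fixture_spec")
}

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z) {
  sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, resname, chain, resno, x, y, z)
}

FIXTURE_AA3 <- c("ALA", "GLY", "SER", "LEU", "VAL", "THR", "PRO", "LYS")

#' Generate a toy dimer structure with planted contact distances
#'
#' Chains A and B each carry one region per pair, laid out as straight CA
#' traces. The two regions of pair k share an x-grid and a z-block and are
#' separated along y by exactly the pair's target distance, so their minimum
#' CA-CA distance equals the target by construction (aligned residues are at
#' the target distance; staggered ones are strictly farther). Successive
#' pairs are separated by `block_gap` along z, so cross-pair distances are
#' two orders of magnitude larger. Coordinates are exact at PDB precision
#' (3 decimals); the planted minima are realized within 1e-3 Angstrom. The
#' same spec yields byte-identical PDB text.
#'
#' @param spec a [toy_fixture_spec()].
#' @param path optional file path; when given, the PDB text is written there.
#' @return list with `pdb_lines` (character vector), `ground_truth` (the
#'   spec's pair table) and `path` (NULL unless written).
#' @export
make_toy_structure <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  pairs <- spec$pairs
  L <- spec$region_length
  lines <- character(0)
  serial <- 0L
  for (ch in c("A", "B")) {
    for (k in seq_len(nrow(pairs))) {
      z <- (k - 1) * spec$block_gap
      y <- if (ch == "A") 0 else pairs$target_distance[k]
      start <- if (ch == "A") pairs$start_a[k] else pairs$start_b[k]
      for (i in seq_len(L)) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(
          serial, FIXTURE_AA3[(i - 1L) %% length(FIXTURE_AA3) + 1L], ch,
          start + i - 1L, (i - 1) * spec$ca_spacing, y, z))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  list(pdb_lines = lines, ground_truth = pairs, path = path)
}

fixture_ids <- function(spec) {
  pairs <- spec$pairs
  n <- nrow(pairs)
  data.frame(
    pair_id = pairs$pair_id,
    id_a = sprintf("PF8%04d", seq_len(n)),
    id_b = ifelse(pairs$interaction_kind == "DDI",
                  sprintf("PF7%04d", seq_len(n)),
                  sprintf("LIG_TOY_%d", seq_len(n))),
    stringsAsFactors = FALSE
  )
}

#' Generate annotations and catalogs matching a toy structure
#'
#' Produces domain hits for both proteins, motif hits for protein B, and DDI
#' and DMI catalogs containing exactly the planted and decoy pairs of the
#' spec (decoys are catalogued too: they must be emitted by the bottom-up
#' stage and rejected only by the contact filter). Odd-numbered pairs are
#' domain-domain, even-numbered domain-motif. The DDI catalog rows are split
#' across two source tables with one pair duplicated in reversed order, so
#' merging and unordered deduplication are exercised on every fixture.
#'
#' @param spec a [toy_fixture_spec()].
#' @param dir optional directory; when given, InterProScan-dialect TSVs, an
#'   ELM-dialect TSV and catalog TSVs are written there.
#' @return list with `annot_a`/`annot_b` ([protein_annotations()] bundles for
#'   proteins `protA`/`protB`), `ddi_catalog`, `dmi_catalog`,
#'   `truth_candidates` (the expected bottom-up candidate table),
#'   `chain_map`, and `files` (named paths when `dir` was given).
#' @export
make_toy_annotations <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  pairs <- spec$pairs
  ids <- fixture_ids(spec)
  is_ddi <- pairs$interaction_kind == "DDI"

  dom_a <- domain_hits("protA", ids$id_a, pairs$start_a, pairs$end_a,
                       description = paste0("toy domain ", ids$id_a))
  dom_b <- domain_hits("protB", ids$id_b[is_ddi], pairs$start_b[is_ddi],
                       pairs$end_b[is_ddi],
                       description = paste0("toy domain ", ids$id_b[is_ddi]))
  mot_b <- if (any(!is_ddi)) {
    data.frame(protein = "protB", elm_id = ids$id_b[!is_ddi],
               start = pairs$start_b[!is_ddi], end = pairs$end_b[!is_ddi],
               matched = NA_character_, stringsAsFactors = FALSE)
  } else {
    empty_motif_hits()
  }

  ddi_rows <- data.frame(pfam_a = ids$id_a[is_ddi], pfam_b = ids$id_b[is_ddi],
                         stringsAsFactors = FALSE)
  # split across two sources; first pair repeated reversed in the second
  half <- ceiling(nrow(ddi_rows) / 2)
  src1 <- ddi_rows[seq_len(half), , drop = FALSE]
  src2 <- rbind(ddi_rows[-seq_len(half), , drop = FALSE],
                data.frame(pfam_a = ddi_rows$pfam_b[1], pfam_b = ddi_rows$pfam_a[1],
                           stringsAsFactors = FALSE))
  ddi_cat <- compile_ddi_catalog(list(toy_src_1 = src1, toy_src_2 = src2))

  dmi_tab <- data.frame(`ELM identifier` = ids$id_b[!is_ddi],
                        `Interaction Domain Id` = ids$id_a[!is_ddi],
                        check.names = FALSE, stringsAsFactors = FALSE)
  dmi_cat <- load_dmi_catalog(dmi_tab)

  truth <- data.frame(
    protein_a = "protA", kind_a = "domain", id_a = ids$id_a,
    start_a = pairs$start_a, end_a = pairs$end_a,
    protein_b = "protB",
    kind_b = ifelse(is_ddi, "domain", "motif"), id_b = ids$id_b,
    start_b = pairs$start_b, end_b = pairs$end_b,
    interaction_kind = pairs$interaction_kind,
    catalog_key = ifelse(is_ddi,
                         gsub("\t", ":", ddi_pair_key(ids$id_a, ids$id_b), fixed = TRUE),
                         paste(ids$id_b, ids$id_a, sep = ":")),
    stringsAsFactors = FALSE
  )
  truth <- sort_candidates(truth)

  files <- NULL
  if (!is.null(dir)) {
    files <- list(
      domains_a = file.path(dir, "protA_interproscan.tsv"),
      domains_b = file.path(dir, "protB_interproscan.tsv"),
      motifs_b = file.path(dir, "protB_elm.tsv"),
      ddi = file.path(dir, "toy_ddi_catalog.tsv"),
      dmi = file.path(dir, "toy_dmi_catalog.tsv")
    )
    write_interproscan_tsv(dom_a, files$domains_a)
    write_interproscan_tsv(dom_b, files$domains_b)
    write_elm_predict_tsv(mot_b, files$motifs_b)
    write_ddi_catalog(ddi_cat, files$ddi)
    utils::write.table(dmi_tab, files$dmi, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }

  list(
    annot_a = protein_annotations("protA", domains = dom_a),
    annot_b = protein_annotations("protB", domains = dom_b, motifs = mot_b),
    ddi_catalog = ddi_cat, dmi_catalog = dmi_cat,
    truth_candidates = truth,
    chain_map = chain_map("A", "B"),
    files = files
  )
}

#' Generate a complete toy fixture (structure + annotations)
#'
#' @param spec a [toy_fixture_spec()].
#' @param dir optional directory for file output (the PDB is written as
#'   `dimer.pdb` there).
#' @return the [make_toy_annotations()] list extended with `structure`
#'   (the [make_toy_structure()] result) and `model` (the parsed
#'   `structure_model`).
#' @export
make_toy_fixture <- function(spec, dir = NULL) {
  ann <- make_toy_annotations(spec, dir = dir)
  pdb_path <- if (!is.null(dir)) file.path(dir, "dimer.pdb") else tempfile(fileext = ".pdb")
  st <- make_toy_structure(spec, path = pdb_path)
  ann$structure <- st
  ann$model <- parse_structure(pdb_path)
  if (is.null(dir)) unlink(pdb_path) else ann$files$pdb <- pdb_path
  ann
}
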