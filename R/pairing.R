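CANDIDATE_COLUMNS <- c("protein_a", "kind_a", "id_a", "start_a", "end_a",
                       "protein_b", "kind_b", "id_b", "start_b", "end_b",
                       "interaction_kind", "catalog_key")

empty_candidates <- function() {
  data.frame(protein_a = character(0), kind_a = character(0),
             id_a = character(0), start_a = integer(0), end_a = integer(0),
             protein_b = character(0), kind_b = character(0),
             id_b = character(0), start_b = integer(0), end_b = integer(0),
             interaction_kind = character(0), catalog_key = character(0),
             stringsAsFactors = FALSE)
}

sort_candidates <- function(df) {
  df <- df[order(df$interaction_kind, df$start_a, df$start_b,
                 df$id_a, df$id_b, df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Predict domain-domain interaction candidates between two proteins
#'
#' Emits one candidate per (occurrence on A, occurrence on B) pair whose Pfam
#' pair is in the DDI catalog. Output is occurrence-level: a repeated domain
#' yields one candidate per copy, because downstream contact filtering needs
#' concrete residue coordinates for each copy.
#'
#' @param hits_a,hits_b domain-hit data frames for the two proteins (the same
#'   accession may appear on both sides for a homodimer).
#' @param catalog a [compile_ddi_catalog()] result.
#' @return a candidate table (see [predict_interactions()] for the schema),
#'   ordered by (start_a, start_b).
#' @export
predict_ddis <- function(hits_a, hits_b, catalog) {
  stopifnot(inherits(catalog, "ddi_catalog"))
  if (nrow(hits_a) == 0 || nrow(hits_b) == 0) return(empty_candidates())
  grid <- expand.grid(i = seq_len(nrow(hits_a)), j = seq_len(nrow(hits_b)))
  keep <- has_ddi(catalog, hits_a$pfam[grid$i], hits_b$pfam[grid$j])
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) return(empty_candidates())
  a <- hits_a[grid$i, ]; b <- hits_b[grid$j, ]
  df <- data.frame(
    protein_a = a$protein, kind_a = "domain", id_a = a$pfam,
    start_a = a$start, end_a = a$end,
    protein_b = b$protein, kind_b = "domain", id_b = b$pfam,
    start_b = b$start, end_b = b$end,
    interaction_kind = "DDI",
    catalog_key = ddi_pair_key(a$pfam, b$pfam),
    stringsAsFactors = FALSE
  )
  df$catalog_key <- gsub("\t", ":", df$catalog_key, fixed = TRUE)
  sort_candidates(df)
}

#' Predict domain-motif interaction candidates
#'
#' One candidate per (domain occurrence, motif occurrence) whose
#' (ELM class, Pfam domain) pair is catalogued. Direction is per call — the
#' domain hits and the motif hits must annotate different proteins of the
#' input pair; [predict_interactions()] calls both directions.
#'
#' @param domain_hits domain-hit data frame (one protein).
#' @param motif_hits motif-hit data frame (the other protein).
#' @param catalog a [load_dmi_catalog()] result.
#' @return candidate table; the domain side is reported as `a`, the motif
#'   side as `b`.
#' @export
predict_dmis <- function(domain_hits, motif_hits, catalog) {
  stopifnot(inherits(catalog, "dmi_catalog"))
  if (nrow(domain_hits) == 0 || nrow(motif_hits) == 0) return(empty_candidates())
  grid <- expand.grid(i = seq_len(nrow(domain_hits)), j = seq_len(nrow(motif_hits)))
  keep <- has_dmi(catalog, motif_hits$elm_id[grid$j], domain_hits$pfam[grid$i])
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0) return(empty_candidates())
  d <- domain_hits[grid$i, ]; m <- motif_hits[grid$j, ]
  df <- data.frame(
    protein_a = d$protein, kind_a = "domain", id_a = d$pfam,
    start_a = d$start, end_a = d$end,
    protein_b = m$protein, kind_b = "motif", id_b = m$elm_id,
    start_b = m$start, end_b = m$end,
    interaction_kind = "DMI",
    catalog_key = paste(m$elm_id, d$pfam, sep = ":"),
    stringsAsFactors = FALSE
  )
  sort_candidates(df)
}

#' Bundle a protein's annotations
#'
#' @param protein identifier.
#' @param domains domain-hit data frame or NULL.
#' @param motifs motif-hit data frame or NULL.
#' @return object of class `protein_annotations`.
#' @export
protein_annotations <- function(protein, domains = NULL, motifs = NULL) {
  domains <- domains %||% empty_domain_hits()
  motifs <- motifs %||% empty_motif_hits()
  if (nrow(domains) == 0 && nrow(motifs) == 0) {
    validation_error(sprintf(
      "annotation bundle for %s is empty: provide domain hits, motif hits, or both",
      protein))
  }
  structure(list(protein = protein, domains = domains, motifs = motifs),
            class = "protein_annotations")
}

#' Predict all catalogued interactions between two annotated proteins
#'
#' Bottom-up prediction: the union of domain-domain candidates
#' (`predict_ddis(A, B)`) and domain-motif candidates in both directions
#' (`predict_dmis(domains_A, motifs_B)` and `predict_dmis(domains_B,
#' motifs_A)`, the latter reported with protein A still on the `a` side).
#' A candidate is emitted only when each protein carries one-half of a
#' catalogued pair. Motif-motif interactions are not predictable — no catalog
#' documents them — so when neither protein has domain annotations the call
#' raises a capability error rather than returning an empty table.
#'
#' @param annot_a,annot_b [protein_annotations()] bundles.
#' @param ddi_catalog a [compile_ddi_catalog()] result.
#' @param dmi_catalog a [load_dmi_catalog()] result.
#' @return candidate table: data frame with columns `protein_a`, `kind_a`,
#'   `id_a`, `start_a`, `end_a`, `protein_b`, `kind_b`, `id_b`, `start_b`,
#'   `end_b`, `interaction_kind` (DDI/DMI), `catalog_key`; stable sort by
#'   (interaction_kind, start_a, start_b, ids).
#' @export
predict_interactions <- function(annot_a, annot_b, ddi_catalog, dmi_catalog) {
  stopifnot(inherits(annot_a, "protein_annotations"),
            inherits(annot_b, "protein_annotations"))
  if (nrow(annot_a$domains) == 0 && nrow(annot_b$domains) == 0) {
    capability_error("motif-motif interactions not supported; provide domain information for at least one protein")
  }
  ddi <- predict_ddis(annot_a$domains, annot_b$domains, ddi_catalog)
  dmi_ab <- predict_dmis(annot_a$domains, annot_b$motifs, dmi_catalog)
  dmi_ba <- predict_dmis(annot_b$domains, annot_a$motifs, dmi_catalog)
  if (nrow(dmi_ba) > 0) {
    # keep protein A on the `a` side: swap roles of the reversed direction
    dmi_ba <- data.frame(
      protein_a = dmi_ba$protein_b, kind_a = dmi_ba$kind_b, id_a = dmi_ba$id_b,
      start_a = dmi_ba$start_b, end_a = dmi_ba$end_b,
      protein_b = dmi_ba$protein_a, kind_b = dmi_ba$kind_a, id_b = dmi_ba$id_a,
      start_b = dmi_ba$start_a, end_b = dmi_ba$end_a,
      interaction_kind = dmi_ba$interaction_kind,
      catalog_key = dmi_ba$catalog_key, stringsAsFactors = FALSE
    )
  }
  sort_candidates(rbind(ddi, dmi_ab, dmi_ba))
}

#' Number of domain:motif compatibility checks before catalog filtering
#'
#' The size of the cross product a manual inspection would face: every
#' domain occurrence against every motif occurrence. Two Pfam domains against
#' 546 candidate SLiMs is already 1092 pairs to eyeball — the motivation for
#' automating the catalog lookup.
#'
#' @param n_domains,n_motifs non-negative counts.
#' @return `n_domains * n_motifs`.
#' @examples
#' count_candidate_pairings(2, 546)
#' @export
count_candidate_pairings <- function(n_domains, n_motifs) {
  if (n_domains < 0 || n_motifs < 0) {
    validation_error("counts must be non-negative")
  }
  as.numeric(n_domains) * as.numeric(n_motifs)
}

#' Read/write candidate tables
#'
#' TSV persistence for the candidate schema produced by
#' [predict_interactions()].
#'
#' @param candidates candidate table.
#' @param path TSV path.
#' @export
write_candidates <- function(candidates, path) {
  utils::write.table(candidates[, CANDIDATE_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) io_error(sprintf("candidate table not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(CANDIDATE_COLUMNS, names(df))
  if (length(missing)) {
    schema_error(sprintf("candidate table %s is missing columns: %s",
                         path, paste(missing, collapse = ", ")))
  }
  df[, CANDIDATE_COLUMNS]
}

#' Emit candidate regions as cropped FASTA records
#'
#' Writes each protein's candidate regions (plus a configurable flank) as
#' FASTA records, ready for structure prediction of just the putative
#' interface — restricting the fold to the interacting regions reduces
#' computational load and avoids confounding intramolecular contacts.
#'
#' @param candidates candidate table.
#' @param records named list of [protein_record()]s covering every protein in
#'   the table.
#' @param path output FASTA path.
#' @param flank residues added on both sides of each region (clamped to the
#'   sequence; default 0).
#' @return `path`, invisibly.
#' @export
write_cropped_fasta <- function(candidates, records, path, flank = 0) {
  regions <- unique(rbind(
    data.frame(protein = candidates$protein_a, id = candidates$id_a,
               start = candidates$start_a, end = candidates$end_a,
               stringsAsFactors = FALSE),
    data.frame(protein = candidates$protein_b, id = candidates$id_b,
               start = candidates$start_b, end = candidates$end_b,
               stringsAsFactors = FALSE)
  ))
  regions <- regions[order(regions$protein, regions$start, regions$id), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    rec <- records[[r$protein]]
    if (is.null(rec)) lookup_error(sprintf("no sequence record for protein %s", r$protein))
    s <- max(1L, r$start - flank)
    e <- min(nchar(rec$sequence), r$end + flank)
    lines <- c(lines,
               sprintf(">%s|%s|%d-%d", r$protein, r$id, s, e),
               substring(rec$sequence, s, e))
  }
  writeLines(lines, path)
  invisible(path)
}
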