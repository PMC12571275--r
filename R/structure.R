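STANDARD_AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS",
                  "ILE","LEU","LYS","MET","PHE","PRO","SER","THR","TRP",
                  "TYR","VAL")

#' Parse a PDB file into a structure model
#'
#' Reads a PDB-format structure (e.g. AlphaFold-Multimer output) and extracts
#' one alpha-carbon (CA) per residue. Only the first model of a multi-model
#' file is used. HETATM residues are ignored except standard amino acids
#' flagged as HETATM, which are kept. Alternate locations are resolved to the
#' highest-occupancy conformer, ties broken by altloc letter; if duplicate CA
#' records for one residue survive resolution, the first is kept with a
#' warning.
#'
#' @param path PDB file.
#' @return object of class `structure_model`: list with `atoms`, a data
#'   frame of resolved CA atoms (columns `chain`, `resno`, `icode`, `resid`,
#'   `x`, `y`, `z`, coordinates in Angstrom), and `chains`, the chain
#'   identifiers in file order.
#' @export
parse_structure <- function(path) {
  if (!file.exists(path)) io_error(sprintf("PDB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # first model only
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) lines <- lines[seq_len(endm[1])]
  if (!any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM"))) {
    format_error(sprintf("%s contains no ATOM/HETATM records", path))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) format_error(sprintf("failed to parse PDB %s: %s",
                                             path, conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[at$elety == "CA", , drop = FALSE]
  at <- at[at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% STANDARD_AA3), ,
           drop = FALSE]
  if (nrow(at) == 0) format_error(sprintf("%s has no alpha-carbon records", path))
  at$icode <- ifelse(is.na(at$insert), "", as.character(at$insert))
  at$alt <- ifelse(is.na(at$alt), "", as.character(at$alt))
  at$o[is.na(at$o)] <- 1

  # altloc resolution: highest occupancy first, ties by altloc letter;
  # file order preserved within a key so "first kept" is well-defined
  key <- paste(at$chain, at$resno, at$icode, sep = "\r")
  ord <- order(match(key, unique(key)), -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  key <- key[ord]
  dup_alt <- duplicated(paste(key, at$alt))
  if (any(dup_alt)) {
    warning(sprintf("%d duplicate CA record(s) after altloc resolution; keeping the first of each",
                    sum(dup_alt)))
  }
  at <- at[!duplicated(key), , drop = FALSE]

  atoms <- data.frame(chain = as.character(at$chain), resno = as.integer(at$resno),
                      icode = at$icode, resid = as.character(at$resid),
                      x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = unique(atoms$chain)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d chains (%s), %d CA residues\n",
              length(x$chains), paste(x$chains, collapse = ", "),
              nrow(x$atoms)))
  invisible(x)
}

#' Map annotated proteins onto structure chains
#'
#' Annotation coordinates (UniProt/sequence numbering) map to structure
#' residue numbers via an additive per-chain offset:
#' `structure resno = annotation coordinate + offset`. AlphaFold output is
#' numbered from 1 in sequence coordinates, so the default offset 0 is
#' correct there; renumbered experimental PDB chains need an explicit offset.
#'
#' @param chain_a,chain_b chain identifiers for protein A and protein B.
#'   They must differ: a homodimer still occupies two distinct chains.
#' @param offset_a,offset_b integer numbering offsets.
#' @return object of class `chain_map`.
#' @export
chain_map <- function(chain_a, chain_b, offset_a = 0L, offset_b = 0L) {
  if (identical(chain_a, chain_b)) {
    validation_error("chain_a and chain_b must be distinct chains (a homodimer occupies two chains)")
  }
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 offset_a = as.integer(offset_a), offset_b = as.integer(offset_b)),
            class = "chain_map")
}

#' Default chain assignment: the first two chains in file order
#'
#' @param model a [parse_structure()] result.
#' @return a [chain_map()] mapping protein A to the first chain and protein B
#'   to the second.
#' @export
default_chain_map <- function(model) {
  if (length(model$chains) < 2) {
    validation_error("model has fewer than two chains; specify chains explicitly")
  }
  chain_map(model$chains[1], model$chains[2])
}

#' Select the resolved residues of a region on one chain
#'
#' Returns all residues of `chain` with `start <= resno <= end` that carry a
#' CA. Ranges select by residue number, ignoring insertion codes (a
#' documented limitation). The fraction of the window resolved in the model
#' is attached as attribute `coverage`.
#'
#' @param model a `structure_model`.
#' @param chain chain identifier (must exist in the model).
#' @param start,end residue-number range, inclusive, `start <= end`.
#' @return data frame of selected CA rows with attribute `coverage`.
#' @export
select_region <- function(model, chain, start, end) {
  stopifnot(inherits(model, "structure_model"), start <= end)
  if (!(chain %in% model$chains)) {
    lookup_error(sprintf("chain '%s' not present in model (chains: %s)",
                         chain, paste(model$chains, collapse = ", ")))
  }
  sel <- model$atoms[model$atoms$chain == chain &
                     model$atoms$resno >= start &
                     model$atoms$resno <= end, , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "coverage") <- nrow(sel) / (end - start + 1)
  sel
}

# All pairwise CA-CA Euclidean distances between two selections (matrix
# n_a x n_b), full double precision.
pair_distance_matrix <- function(sel_a, sel_b) {
  dx <- outer(sel_a$x, sel_b$x, "-")
  dy <- outer(sel_a$y, sel_b$y, "-")
  dz <- outer(sel_a$z, sel_b$z, "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Minimum alpha-carbon distance between two regions
#'
#' The contact metric of the top-down filter: the minimum Euclidean CA-CA
#' distance over the cross product of the two residue selections, in
#' Angstrom. Symmetric in its arguments. Selections carry their own
#' coordinates, so no model argument is needed.
#'
#' @param sel_a,sel_b non-empty [select_region()] results (any data frame
#'   with `x`, `y`, `z` columns works).
#' @return minimum distance in Angstrom.
#' @export
min_region_distance <- function(sel_a, sel_b) {
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0) {
    empty_selection_error("cannot compute a distance for an empty residue selection")
  }
  min(pair_distance_matrix(sel_a, sel_b))
}

#' Label residue pairs within a contact cutoff
#'
#' Enumerates every CA pair of the two selections at distance <= `cutoff`,
#' annotated with chain, residue number, amino acid and distance, sorted by
#' distance ascending (ties by residue numbers).
#'
#' @param sel_a,sel_b [select_region()] results.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return data frame with columns `chain_a`, `resno_a`, `aa_a`, `chain_b`,
#'   `resno_b`, `aa_b`, `distance`.
#' @export
contact_residue_pairs <- function(sel_a, sel_b, cutoff) {
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      aa_a = character(0), chain_b = character(0),
                      resno_b = integer(0), aa_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0) return(empty)
  d <- pair_distance_matrix(sel_a, sel_b)
  idx <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  out <- data.frame(
    chain_a = sel_a$chain[idx[, 1]], resno_a = sel_a$resno[idx[, 1]],
    aa_a = sel_a$resid[idx[, 1]],
    chain_b = sel_b$chain[idx[, 2]], resno_b = sel_b$resno[idx[, 2]],
    aa_b = sel_b$resid[idx[, 2]],
    distance = d[idx], stringsAsFactors = FALSE
  )
  out <- out[order(out$distance, out$resno_a, out$resno_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

candidate_selections <- function(candidate, model, map) {
  stopifnot(inherits(map, "chain_map"))
  sel_a <- select_region(model, map$chain_a,
                         candidate$start_a + map$offset_a,
                         candidate$end_a + map$offset_a)
  sel_b <- select_region(model, map$chain_b,
                         candidate$start_b + map$offset_b,
                         candidate$end_b + map$offset_b)
  list(a = sel_a, b = sel_b)
}

#' Filter interaction candidates by contact distance
#'
#' The top-down validation step: each candidate's two regions are mapped
#' onto the model via the chain map, and the candidate passes if its minimum
#' CA-CA distance is at or below `cutoff` (<=, no epsilon). Candidates whose
#' regions have no resolved residues cannot be judged either way and are
#' reported with status `"unevaluable"` — never silently dropped into pass
#' or fail.
#'
#' @param candidates candidate table ([predict_interactions()]).
#' @param model a `structure_model`.
#' @param map a [chain_map()].
#' @param cutoff contact distance cutoff in Angstrom (> 0).
#' @return the candidate table extended with `min_distance`, `n_contacts`
#'   (CA pairs within cutoff), `coverage_a`, `coverage_b` and `status`
#'   (`"pass"`, `"fail"` or `"unevaluable"`).
#' @export
filter_by_distance <- function(candidates, model, map, cutoff) {
  if (!inherits(map, "chain_map")) {
    validation_error("map must be a chain_map resolving both proteins to chains")
  }
  if (!is.numeric(cutoff) || cutoff <= 0) {
    validation_error("cutoff must be a positive distance in Angstrom")
  }
  n <- nrow(candidates)
  min_distance <- rep(NA_real_, n)
  n_contacts <- rep(NA_integer_, n)
  coverage_a <- numeric(n); coverage_b <- numeric(n)
  status <- character(n)
  for (i in seq_len(n)) {
    sels <- candidate_selections(candidates[i, ], model, map)
    coverage_a[i] <- attr(sels$a, "coverage")
    coverage_b[i] <- attr(sels$b, "coverage")
    if (nrow(sels$a) == 0 || nrow(sels$b) == 0) {
      status[i] <- "unevaluable"
      next
    }
    d <- pair_distance_matrix(sels$a, sels$b)
    min_distance[i] <- min(d)
    n_contacts[i] <- sum(d <= cutoff)
    status[i] <- if (min_distance[i] <= cutoff) "pass" else "fail"
  }
  out <- candidates
  out$min_distance <- min_distance
  out$n_contacts <- n_contacts
  out$coverage_a <- coverage_a
  out$coverage_b <- coverage_b
  out$status <- status
  rownames(out) <- NULL
  out
}

#' Sweep the contact-distance cutoff over a candidate set
#'
#' Recommended top-down procedure: start loose and tighten, evaluating the
#' filter at each cutoff from 11 Angstrom down to 4 in 1-Angstrom steps. The
#' 11-Angstrom ceiling follows coarse-grained elastic-network practice for
#' CA-CA interactions; contacts below 4 Angstrom are not observed in
#' practice. Reports the per-cutoff pass sets plus, per candidate, the
#' smallest swept cutoff at which it passes (its detection distance; NA if it
#' passes at none, i.e. beyond the largest cutoff).
#'
#' @param candidates candidate table.
#' @param model a `structure_model`.
#' @param map a [chain_map()].
#' @param cutoffs distances in Angstrom (default `11:4`).
#' @return list with `report` (the candidate table plus `min_distance`,
#'   `status` at the loosest cutoff, and one logical `pass_<d>` column per
#'   cutoff) and `detection` (candidate table plus `min_distance` and
#'   `detection_distance`).
#' @export
distance_sweep <- function(candidates, model, map, cutoffs = 11:4) {
  if (any(cutoffs <= 0)) validation_error("cutoffs must be positive")
  cutoffs <- sort(unique(as.numeric(cutoffs)), decreasing = TRUE)
  base <- filter_by_distance(candidates, model, map, cutoff = max(cutoffs))
  report <- base
  for (d in cutoffs) {
    report[[sprintf("pass_%g", d)]] <-
      !is.na(base$min_distance) & base$min_distance <= d
  }
  detection <- candidates
  detection$min_distance <- base$min_distance
  detection$detection_distance <- vapply(base$min_distance, function(md) {
    if (is.na(md)) return(NA_real_)
    ok <- cutoffs[md <= cutoffs]
    if (length(ok) == 0) NA_real_ else min(ok)
  }, numeric(1))
  list(report = report, detection = detection)
}

#' Write a contact report
#'
#' TSV for the tabular part; optionally a JSON document carrying the full
#' labeled contact-pair lists per passing candidate.
#'
#' @param report a [filter_by_distance()] result.
#' @param path output TSV path.
#' @param json_path optional JSON output path.
#' @param model,map,cutoff required when `json_path` is given, to recompute
#'   the labeled pairs.
#' @return `path`, invisibly.
#' @export
write_contact_report <- function(report, path, json_path = NULL,
                                 model = NULL, map = NULL, cutoff = NULL) {
  fmt <- report
  for (col in c("min_distance", "coverage_a", "coverage_b")) {
    if (col %in% names(fmt)) fmt[[col]] <- ifelse(is.na(fmt[[col]]), "NA",
                                                  sprintf("%.3f", fmt[[col]]))
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(json_path)) {
    if (is.null(model) || is.null(map) || is.null(cutoff)) {
      validation_error("model, map and cutoff are required to write labeled contacts")
    }
    recs <- lapply(seq_len(nrow(report)), function(i) {
      row <- report[i, ]
      pairs <- if (identical(row$status, "pass")) {
        sels <- candidate_selections(row, model, map)
        contact_residue_pairs(sels$a, sels$b, cutoff)
      } else {
        data.frame()
      }
      list(candidate = as.list(row[, CANDIDATE_COLUMNS]),
           status = row$status,
           min_distance = if (is.na(row$min_distance)) NULL else round(row$min_distance, 3),
           contacts = pairs)
    })
    jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = 3,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
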