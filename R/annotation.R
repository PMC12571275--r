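AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y","X","U","B","Z")

#' Create a protein record
#'
#' A minimal container for one protein: an identifier (accession or user
#' label) and an amino-acid sequence in one-letter codes. Sequences are
#' uppercased on ingest; characters outside the 20 standard codes plus
#' X, U, B, Z are rejected.
#'
#' @param identifier accession or label (non-empty string).
#' @param sequence amino-acid string.
#' @return object of class `protein_record` (list with `identifier`,
#'   `sequence`).
#' @export
protein_record <- function(identifier, sequence) {
  if (!is.character(identifier) || length(identifier) != 1 || !nzchar(identifier)) {
    validation_error("protein identifier must be a non-empty string")
  }
  sequence <- toupper(gsub("[ \t\r\n]", "", as.character(sequence)))
  if (!nzchar(sequence)) validation_error("protein sequence must be non-empty")
  chars <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad)) {
    validation_error(sprintf("sequence of %s contains invalid characters: %s",
                             identifier, paste(bad, collapse = "")))
  }
  structure(list(identifier = identifier, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("protein_record %s (%d aa)\n", x$identifier, nchar(x$sequence)))
  invisible(x)
}

#' Read a multi-record FASTA file
#'
#' The identifier is the description line up to the first whitespace.
#'
#' @param path FASTA file.
#' @return named list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) io_error(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) format_error(sprintf("failed to parse FASTA %s: %s",
                                                           path, conditionMessage(e))))
  ids <- sub("\\s.*$", "", names(set))
  recs <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]))
  })
  names(recs) <- ids
  recs
}

empty_domain_hits <- function() {
  data.frame(protein = character(0), pfam = character(0),
             start = integer(0), end = integer(0),
             description = character(0), stringsAsFactors = FALSE)
}

empty_motif_hits <- function() {
  data.frame(protein = character(0), elm_id = character(0),
             start = integer(0), end = integer(0),
             matched = character(0), stringsAsFactors = FALSE)
}

#' Construct a domain-hit table
#'
#' @param protein,pfam,start,end,description parallel vectors; coordinates
#'   are 1-based inclusive residue indices.
#' @return data frame with columns `protein`, `pfam`, `start`, `end`,
#'   `description`.
#' @export
domain_hits <- function(protein, pfam, start, end, description = "") {
  if (length(protein) == 0) return(empty_domain_hits())
  pfam <- assert_pfam(pfam)
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end)) || any(start < 1) || any(start > end)) {
    validation_error("domain hit coordinates must satisfy 1 <= start <= end")
  }
  df <- data.frame(protein = as.character(protein), pfam = pfam,
                   start = start, end = end,
                   description = as.character(description),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("protein", "pfam", "start", "end")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse an InterProScan TSV into domain hits
#'
#' Follows the InterProScan TSV convention: at least 11 tab-separated columns
#' (protein accession, sequence MD5, length, analysis, signature accession,
#' signature description, start, stop, score, status, date, ...). Only rows
#' whose analysis is in `keep_analyses` are returned; with the default
#' (`"Pfam"`) the signature accession must also normalize to a Pfam ID, so
#' stray non-Pfam accessions are excluded. Identical
#' (protein, pfam, start, end) hits are deduplicated.
#'
#' @param path TSV file path.
#' @param keep_analyses character set of analysis names to keep.
#' @return a domain-hit data frame (see [domain_hits()]).
#' @export
parse_interproscan_tsv <- function(path, keep_analyses = "Pfam") {
  if (!file.exists(path)) io_error(sprintf("InterProScan TSV not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_domain_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 11)) {
    bad <- which(n < 11)[1]
    format_error(sprintf("line %d of %s has %d tab-separated columns; the InterProScan dialect requires at least 11",
                         bad, path, n[bad]))
  }
  keep_default <- identical(sort(keep_analyses), "Pfam")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (!(f[4] %in% keep_analyses)) return(NULL)
    start <- suppressWarnings(as.integer(f[7]))
    end <- suppressWarnings(as.integer(f[8]))
    if (is.na(start) || is.na(end) ||
        f[7] != as.character(start) || f[8] != as.character(end)) {
      format_error(sprintf("line %d of %s: non-integer coordinates '%s'..'%s'",
                           i, path, f[7], f[8]))
    }
    acc <- pfam_normalize(f[5])
    if (keep_default && !grepl("^PF[0-9]{5}$", acc)) return(NULL)
    data.frame(protein = f[1], pfam = acc, start = start, end = end,
               description = f[6], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_domain_hits())
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("protein", "pfam", "start", "end")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write domain hits as an InterProScan-dialect TSV
#'
#' Emits the 11-column headerless layout [parse_interproscan_tsv()] reads, so
#' hit tables round-trip through write/parse unchanged. Intended for fixture
#' generation and for exchanging annotations between runs.
#'
#' @param hits a domain-hit data frame.
#' @param path output path.
#' @export
write_interproscan_tsv <- function(hits, path) {
  lines <- sprintf("%s\tmd5\t0\tPfam\t%s\t%s\t%d\t%d\t0.0\tT\t01-01-2026",
                   hits$protein, hits$pfam, hits$description,
                   hits$start, hits$end)
  writeLines(lines, path)
  invisible(path)
}

#' Scan a protein sequence for short linear motifs (SLiMs)
#'
#' Applies each motif class's regular expression to the sequence and reports
#' every matching position. By default matches may OVERLAP: the search
#' restarts one position after each match start (implemented with a
#' zero-width lookahead, so `^` and `$` anchors stay relative to the full
#' sequence). SLiM occurrences can overlap, and a non-overlapping scan would
#' silently lose candidates; `overlapping = FALSE` gives the strict
#' left-to-right non-overlapping scan for parity with `stringr`-style
#' locators.
#'
#' @param protein a [protein_record()].
#' @param classes a motif-class data frame ([load_motif_classes()]).
#' @param overlapping report overlapping occurrences (default TRUE).
#' @return a motif-hit data frame with columns `protein`, `elm_id`, `start`,
#'   `end`, `matched`, sorted by (elm_id, start). `matched` equals the
#'   1-based inclusive slice `sequence[start..end]`.
#' @examples
#' p <- protein_record("toy", "AAAA")
#' cls <- data.frame(elm_id = "LIG_TOY_1", pattern = "AA", description = "")
#' scan_slims(p, cls)  # 3 overlapping matches
#' @export
scan_slims <- function(protein, classes, overlapping = TRUE) {
  stopifnot(inherits(protein, "protein_record"))
  seqstr <- protein$sequence
  out <- lapply(seq_len(nrow(classes)), function(i) {
    pat <- classes$pattern[i]
    elm <- classes$elm_id[i]
    hits <- tryCatch(suppressWarnings({
      if (overlapping) {
        m <- gregexpr(paste0("(?=(", pat, "))"), seqstr, perl = TRUE)[[1]]
        if (m[1] == -1L) return(NULL)
        cs <- attr(m, "capture.start")[, 1L]
        cl <- attr(m, "capture.length")[, 1L]
        keep <- cl > 0
        data.frame(start = cs[keep], len = cl[keep])
      } else {
        m <- gregexpr(pat, seqstr, perl = TRUE)[[1]]
        if (m[1] == -1L) return(NULL)
        len <- attr(m, "match.length")
        keep <- len > 0
        data.frame(start = as.integer(m)[keep], len = len[keep])
      }
    }), error = function(e) {
      pattern_error(sprintf("motif class %s: invalid pattern '%s' (%s)",
                            elm, pat, conditionMessage(e)))
    })
    if (is.null(hits) || nrow(hits) == 0) return(NULL)
    data.frame(protein = protein$identifier, elm_id = elm,
               start = as.integer(hits$start),
               end = as.integer(hits$start + hits$len - 1L),
               matched = substring(seqstr, hits$start, hits$start + hits$len - 1L),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty_motif_hits())
  df <- do.call(rbind, out)
  df <- df[order(df$elm_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse an ELM-Predict style TSV into motif hits
#'
#' Expects columns for the ELM class identifier, start and stop (1-based
#' inclusive, as ELM reports them); accepts the common header spellings.
#'
#' @param path TSV file path or data frame.
#' @param protein identifier used when the table lacks a protein column.
#' @return a motif-hit data frame (columns `protein`, `elm_id`, `start`,
#'   `end`, `matched`; `matched` is NA when the table does not carry the
#'   matched subsequence).
#' @export
parse_elm_predict_tsv <- function(path, protein = NA_character_) {
  tab <- read_table_source(path, header = TRUE)
  df <- tab$df
  if (nrow(df) == 0) return(empty_motif_hits())
  pick <- function(cands, required = TRUE) {
    for (cand in cands) {
      idx <- match(tolower(cand), tolower(trimws(names(df))))
      if (!is.na(idx)) return(idx)
    }
    if (required) schema_error(sprintf("required column (%s) missing from %s",
                                       paste(cands, collapse = "/"), tab$label))
    NA_integer_
  }
  ie <- pick(c("elm_identifier", "ELMIdentifier", "elm_id"))
  is_ <- pick(c("start"))
  ist <- pick(c("stop", "end"))
  ip <- pick(c("protein", "accession"), required = FALSE)
  im <- pick(c("matched", "match"), required = FALSE)
  out <- data.frame(
    protein = if (!is.na(ip)) as.character(df[[ip]]) else protein,
    elm_id = trimws(as.character(df[[ie]])),
    start = as.integer(df[[is_]]),
    end = as.integer(df[[ist]]),
    matched = if (!is.na(im)) as.character(df[[im]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start) | is.na(out$end))) {
    format_error(sprintf("non-integer start/stop coordinates in %s", tab$label))
  }
  rownames(out) <- NULL
  out
}

#' Write motif hits as an ELM-Predict style TSV
#'
#' @param hits a motif-hit data frame.
#' @param path output path.
#' @export
write_elm_predict_tsv <- function(hits, path) {
  df <- data.frame(protein = hits$protein, elm_identifier = hits$elm_id,
                   start = hits$start, stop = hits$end,
                   matched = hits$matched, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Parse a UniProt FASTA payload
#'
#' For headers of the UniProt form `>db|ACCESSION|NAME ...` the accession is
#' used as the identifier; otherwise the first whitespace-delimited token.
#' Line-wrapped sequence bodies are concatenated.
#'
#' @param lines character vector of payload lines (or one string with
#'   embedded newlines).
#' @return a [protein_record()].
#' @export
parse_uniprot_fasta <- function(lines) {
  if (length(lines) == 1) lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2 || !startsWith(lines[1], ">")) {
    format_error("malformed FASTA payload: expected a '>' header followed by sequence lines")
  }
  header <- sub("^>", "", lines[1])
  token <- sub("\\s.*$", "", header)
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  id <- if (length(parts) >= 2) parts[2] else token
  protein_record(id, paste(lines[-1], collapse = ""))
}

#' Extract Pfam domain hits from an InterPro API payload
#'
#' Walks the InterPro `entry/pfam/protein/uniprot/<accession>` JSON: one
#' domain hit per location fragment, so an entry split into fragments yields
#' one hit per fragment.
#'
#' @param payload JSON text, or an already-parsed list.
#' @param accession protein identifier to stamp on the hits.
#' @return a domain-hit data frame.
#' @export
parse_interpro_domains <- function(payload, accession) {
  if (is.character(payload)) {
    payload <- tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
                        error = function(e) format_error(sprintf(
                          "malformed InterPro JSON payload: %s", conditionMessage(e))))
  }
  results <- payload$results %||% list()
  rows <- list()
  for (res in results) {
    acc <- pfam_normalize(res$metadata$accession %||% "")
    if (!grepl("^PF[0-9]{5}$", acc)) next
    descr <- res$metadata$name %||% ""
    for (prot in res$proteins %||% list()) {
      for (loc in prot$entry_protein_locations %||% list()) {
        for (frag in loc$fragments %||% list()) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein = accession, pfam = acc,
            start = as.integer(frag$start), end = as.integer(frag$`end`),
            description = descr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_domain_hits())
  df <- do.call(rbind, rows)
  df <- df[!duplicated(df[c("protein", "pfam", "start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$pfam), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Fetch a protein sequence from UniProt (network)
#'
#' Network access is off by default; every online operation in the package
#' sits behind an explicit `network` flag so pipelines are offline-safe and
#' reproducible. With `network = FALSE` a capability error is raised.
#'
#' @param accession UniProt accession.
#' @param network set TRUE to allow the HTTP request.
#' @param base_url REST endpoint prefix.
#' @return a [protein_record()].
#' @export
fetch_sequence <- function(accession, network = FALSE,
                           base_url = "https://rest.uniprot.org/uniprotkb/") {
  if (!network) {
    capability_error("network access disabled: pass network = TRUE to fetch sequences from UniProt")
  }
  u <- paste0(base_url, accession, ".fasta")
  lines <- tryCatch(readLines(u, warn = FALSE),
                    error = function(e) lookup_error(sprintf(
                      "failed to fetch %s from UniProt: %s", accession,
                      conditionMessage(e))))
  parse_uniprot_fasta(lines)
}

#' Fetch Pfam domain annotations from InterPro (network)
#'
#' @inheritParams fetch_sequence
#' @return a domain-hit data frame.
#' @export
fetch_domains <- function(accession, network = FALSE,
                          base_url = "https://www.ebi.ac.uk/interpro/api/entry/pfam/protein/uniprot/") {
  if (!network) {
    capability_error("network access disabled: pass network = TRUE to fetch domains from InterPro")
  }
  u <- paste0(base_url, accession)
  txt <- tryCatch(paste(readLines(u, warn = FALSE), collapse = "\n"),
                  error = function(e) lookup_error(sprintf(
                    "failed to fetch %s from InterPro: %s", accession,
                    conditionMessage(e))))
  parse_interpro_domains(txt, accession)
}
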