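#' Normalize Pfam accessions
#'
#' Strips surrounding whitespace and any `.N` version suffix (source releases
#' differ in whether accessions carry versions, e.g. `PF00001.21`) and
#' uppercases the result. A normalized accession has the form `PF` followed by
#' exactly five digits.
#'
#' @param x character vector of raw Pfam accessions.
#' @return character vector of normalized accessions (not validated; see
#'   [pfam_is_valid()]).
#' @examples
#' pfam_normalize(c(" PF00001.21", "pf00400"))
#' @export
pfam_normalize <- function(x) {
  toupper(sub("\\..*$", "", trimws(as.character(x))))
}

#' @rdname pfam_normalize
#' @return for `pfam_is_valid`, a logical vector: does each normalized
#'   accession match `PF` + 5 digits?
#' @export
pfam_is_valid <- function(x) {
  grepl("^PF[0-9]{5}$", pfam_normalize(x))
}

assert_pfam <- function(x, what = "Pfam ID") {
  x <- pfam_normalize(x)
  bad <- !grepl("^PF[0-9]{5}$", x)
  if (any(bad)) {
    validation_error(sprintf("malformed %s: %s", what,
                             paste(x[bad], collapse = ", ")))
  }
  x
}

# Canonical unordered pair key: lexicographically sorted, tab-joined.
ddi_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Resolve a column spec (name or 1-based index) against a data frame.
resolve_column <- function(df, spec, file = "<data frame>") {
  if (is.numeric(spec)) {
    if (spec < 1 || spec > ncol(df)) {
      schema_error(sprintf("column index %d out of range in %s", spec, file))
    }
    return(as.integer(spec))
  }
  idx <- match(spec, names(df))
  if (is.na(idx)) {
    # tolerate whitespace/case differences in headers
    idx <- match(tolower(trimws(spec)), tolower(trimws(names(df))))
  }
  if (is.na(idx)) {
    schema_error(sprintf("no column '%s' in %s (columns: %s)", spec, file,
                         paste(names(df), collapse = ", ")))
  }
  idx
}

read_table_source <- function(src, header = TRUE, file_label = NULL) {
  if (is.data.frame(src)) {
    return(list(df = src, label = file_label %||% "<data frame>"))
  }
  if (!is.character(src) || length(src) != 1) {
    validation_error("a source must be a file path or a data frame")
  }
  if (!file.exists(src)) {
    io_error(sprintf("cannot read source table: file not found: %s", src))
  }
  df <- tryCatch(
    utils::read.delim(src, header = header, sep = "\t", quote = "\"",
                      comment.char = "", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) io_error(sprintf("failed to read %s: %s", src,
                                         conditionMessage(e)))
  )
  list(df = df, label = file_label %||% basename(src))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compile a domain-domain interaction (DDI) catalog
#'
#' Merges one or more tabular sources of interacting Pfam pairs (3did-style
#' flat exports, DOMINE-style TSVs, or previously serialized catalogs) into a
#' single deduplicated catalog of unordered Pfam-ID pairs. Physical domain
#' interaction is symmetric, so `(A,B)` and `(B,A)` collapse to one entry,
#' stored in canonical lexicographic order. Self-pairs `(A,A)` are kept:
#' homotypic domain interactions exist. Rows whose ID columns do not
#' normalize to valid Pfam accessions are skipped and counted, not fatal —
#' DOMINE-style exports carry extra annotation columns and odd rows.
#'
#' @param sources a list of sources. Each element is a file path, a data
#'   frame, or a list with elements `path` (or `df`), and optionally `col_a`,
#'   `col_b`, `header` overriding the defaults for that source. Names of the
#'   list are used as provenance labels.
#' @param col_a,col_b default columns holding the two Pfam IDs, as names or
#'   1-based indices (default: first two columns, the DOMINE dialect).
#' @param header default: do sources carry a header row?
#' @return an object of class `ddi_catalog`: a list with `pairs` (data frame
#'   with columns `pfam_a`, `pfam_b`, sorted), `provenance` (named list,
#'   canonical pair key to character vector of source labels) and `n_skipped`
#'   (rows dropped for unparseable IDs).
#' @seealso [has_ddi()], [write_ddi_catalog()]
#' @export
compile_ddi_catalog <- function(sources, col_a = 1, col_b = 2, header = TRUE) {
  if (is.data.frame(sources) || is.character(sources)) sources <- list(sources)
  labels <- names(sources)
  keys <- character(0)
  prov <- list()
  n_skipped <- 0L

  for (i in seq_along(sources)) {
    src <- sources[[i]]
    lab <- if (!is.null(labels) && nzchar(labels[i] %||% "")) labels[i] else NULL
    ca <- col_a; cb <- col_b; hd <- header
    if (is.list(src) && !is.data.frame(src)) {
      ca <- src$col_a %||% ca
      cb <- src$col_b %||% cb
      hd <- src$header %||% hd
      lab <- src$label %||% lab
      src <- src$df %||% src$path
      if (is.null(src)) validation_error("source list needs a 'path' or 'df' element")
    }
    tab <- read_table_source(src, header = hd, file_label = lab)
    df <- tab$df
    lab <- lab %||% tab$label
    if (nrow(df) == 0) next
    if (ncol(df) < 2) {
      schema_error(sprintf("source %s has fewer than two columns; cannot identify Pfam ID columns", lab))
    }
    ia <- resolve_column(df, ca, lab)
    ib <- resolve_column(df, cb, lab)
    a <- pfam_normalize(df[[ia]])
    b <- pfam_normalize(df[[ib]])
    ok <- grepl("^PF[0-9]{5}$", a) & grepl("^PF[0-9]{5}$", b)
    n_skipped <- n_skipped + sum(!ok)
    if (!any(ok)) next
    k <- unique(ddi_pair_key(a[ok], b[ok]))
    keys <- c(keys, k)
    for (key in k) prov[[key]] <- unique(c(prov[[key]], lab))
  }

  keys <- sort(unique(keys))
  parts <- if (length(keys)) strsplit(keys, "\t", fixed = TRUE) else list()
  pairs <- data.frame(
    pfam_a = vapply(parts, `[`, character(1), 1L),
    pfam_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  structure(
    list(pairs = pairs, provenance = prov[keys], n_skipped = n_skipped),
    class = "ddi_catalog"
  )
}

#' @export
print.ddi_catalog <- function(x, ...) {
  cat(sprintf("DDI catalog: %d unique unordered Pfam pairs (%d unparseable rows skipped)\n",
              nrow(x$pairs), x$n_skipped))
  invisible(x)
}

#' @export
length.ddi_catalog <- function(x) nrow(x$pairs)

#' Query a DDI catalog for an interacting pair
#'
#' Membership is symmetric: `has_ddi(cat, a, b)` and `has_ddi(cat, b, a)` are
#' identical. IDs are normalized before lookup; malformed IDs raise a
#' validation error.
#'
#' @param catalog a [compile_ddi_catalog()] result.
#' @param a,b Pfam accessions (vectorized; recycled to common length).
#' @return logical vector.
#' @export
has_ddi <- function(catalog, a, b) {
  stopifnot(inherits(catalog, "ddi_catalog"))
  a <- assert_pfam(a)
  b <- assert_pfam(b)
  ddi_pair_key(a, b) %in% ddi_pair_key(catalog$pairs$pfam_a, catalog$pairs$pfam_b)
}

#' Serialize / reload a DDI catalog
#'
#' The catalog is written as a two-column TSV of canonically sorted pairs in
#' lexicographic order (bit-stable output for reproducible diffs) plus a JSON
#' sidecar (`<path>.provenance.json`) recording per-pair source labels and the
#' skipped-row count. `compile_ddi_catalog()` run on the TSV reproduces the
#' same catalog (idempotence).
#'
#' @param catalog a `ddi_catalog`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ddi_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ddi_catalog"))
  utils::write.table(catalog$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  sidecar <- paste0(path, ".provenance.json")
  jsonlite::write_json(
    list(n_pairs = nrow(catalog$pairs), n_skipped = catalog$n_skipped,
         provenance = catalog$provenance),
    sidecar, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Load a domain-motif interaction (DMI) catalog
#'
#' Reads an ELM "interaction domains" style table linking an ELM motif class
#' to the Pfam domain it binds. Duplicate `(elm_id, domain)` rows collapse to
#' one record; rows missing either identifier, or whose domain does not
#' normalize to a Pfam accession, are skipped with a warning. Motif regular
#' expressions can be attached by passing the ELM classes table, so the
#' catalog can drive sequence scanning directly.
#'
#' @param table file path or data frame with ELM identifier and interaction
#'   domain columns.
#' @param elm_col,domain_col column names or indices; defaults match the ELM
#'   export headers (`"ELM identifier"`, `"Interaction Domain Id"`).
#' @param classes optional [load_motif_classes()] result used to attach each
#'   class's regular expression.
#' @return an object of class `dmi_catalog`: list with `records`, a data
#'   frame with columns `elm_id`, `domain`, `pattern` (NA when unknown).
#' @export
load_dmi_catalog <- function(table, elm_col = "ELM identifier",
                             domain_col = "Interaction Domain Id",
                             classes = NULL) {
  tab <- read_table_source(table, header = TRUE)
  df <- tab$df
  if (nrow(df) == 0) {
    records <- data.frame(elm_id = character(0), domain = character(0),
                          pattern = character(0), stringsAsFactors = FALSE)
    return(structure(list(records = records), class = "dmi_catalog"))
  }
  ie <- resolve_column(df, elm_col, tab$label)
  id <- resolve_column(df, domain_col, tab$label)
  elm <- trimws(as.character(df[[ie]]))
  dom <- pfam_normalize(df[[id]])
  ok <- nzchar(elm) & !is.na(elm) & grepl("^PF[0-9]{5}$", dom)
  if (any(!ok)) {
    warning(sprintf("%d row(s) in %s skipped: missing ELM identifier or invalid Pfam ID",
                    sum(!ok), tab$label))
  }
  records <- unique(data.frame(elm_id = elm[ok], domain = dom[ok],
                               stringsAsFactors = FALSE))
  records <- records[order(records$elm_id, records$domain), , drop = FALSE]
  rownames(records) <- NULL
  records$pattern <- if (!is.null(classes)) {
    classes$pattern[match(records$elm_id, classes$elm_id)]
  } else {
    NA_character_
  }
  structure(list(records = records), class = "dmi_catalog")
}

#' @export
print.dmi_catalog <- function(x, ...) {
  cat(sprintf("DMI catalog: %d (ELM class, Pfam domain) records, %d distinct classes\n",
              nrow(x$records), length(unique(x$records$elm_id))))
  invisible(x)
}

#' @export
length.dmi_catalog <- function(x) nrow(x$records)

#' Query a DMI catalog
#'
#' `dmi_domains_for_motif` returns the Pfam domains recorded as binding an ELM
#' class; `dmi_motifs_for_domain` is the inverse. Unknown identifiers give an
#' empty result, not an error.
#'
#' @param catalog a [load_dmi_catalog()] result.
#' @param elm_id ELM class identifier.
#' @return sorted character vector of Pfam IDs (or ELM IDs for the inverse).
#' @export
dmi_domains_for_motif <- function(catalog, elm_id) {
  stopifnot(inherits(catalog, "dmi_catalog"))
  sort(unique(catalog$records$domain[catalog$records$elm_id == elm_id]))
}

#' @rdname dmi_domains_for_motif
#' @param pfam Pfam accession.
#' @export
dmi_motifs_for_domain <- function(catalog, pfam) {
  stopifnot(inherits(catalog, "dmi_catalog"))
  pfam <- assert_pfam(pfam)
  sort(unique(catalog$records$elm_id[catalog$records$domain == pfam]))
}

has_dmi <- function(catalog, elm_id, pfam) {
  stopifnot(inherits(catalog, "dmi_catalog"))
  paste(elm_id, pfam_normalize(pfam), sep = "\t") %in%
    paste(catalog$records$elm_id, catalog$records$domain, sep = "\t")
}

#' Load motif class definitions
#'
#' Reads an ELM-classes style table of motif classes: identifier, regular
#' expression, free-text description. Every pattern must compile; an invalid
#' pattern raises an error naming the class.
#'
#' @param table file path or data frame with columns `ELMIdentifier`, `Regex`,
#'   `Description` (case-insensitive; `elm_id`/`pattern`/`description` also
#'   accepted).
#' @return data frame with columns `elm_id`, `pattern`, `description`.
#' @export
load_motif_classes <- function(table) {
  tab <- read_table_source(table, header = TRUE)
  df <- tab$df
  pick <- function(cands) {
    for (cand in cands) {
      idx <- match(tolower(cand), tolower(trimws(names(df))))
      if (!is.na(idx)) return(idx)
    }
    schema_error(sprintf("none of the columns %s found in %s",
                         paste(cands, collapse = "/"), tab$label))
  }
  ie <- pick(c("ELMIdentifier", "elm_id", "ELM identifier"))
  ir <- pick(c("Regex", "pattern"))
  idsc <- tryCatch(pick(c("Description", "description")), error = function(e) NA_integer_)
  out <- data.frame(
    elm_id = trimws(as.character(df[[ie]])),
    pattern = as.character(df[[ir]]),
    description = if (!is.na(idsc)) as.character(df[[idsc]]) else "",
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    ok <- tryCatch({
      suppressWarnings(regexpr(out$pattern[i], "", perl = TRUE))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) pattern_error(sprintf("motif class %s has an invalid regular expression: %s",
                                   out$elm_id[i], out$pattern[i]))
  }
  out
}
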