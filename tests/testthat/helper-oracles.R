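# Independent brute-force oracles used across the suite. These deliberately
# take the dumbest correct path (explicit loops, position-by-position regex
# anchoring, sorted-string sets) so they share no code with the package
# implementations they check.

toy_extdata <- function(file) {
  system.file("extdata", file, package = "ppiface", mustWork = TRUE)
}

fixture_path <- function(file) {
  testthat::test_path("fixtures", file)
}

# distinct unordered pair set via sorted "A|B" strings
oracle_pair_set <- function(a, b) {
  keys <- vapply(seq_along(a), function(i) {
    p <- sort(c(a[i], b[i]))
    paste(p, collapse = "|")
  }, character(1))
  sort(unique(keys))
}

catalog_pair_set <- function(catalog) {
  oracle_pair_set(catalog$pairs$pfam_a, catalog$pairs$pfam_b)
}

# position-by-position anchored-match scan; patterns beginning with "^" are
# only tested at position 1 (the anchor refers to the full sequence)
oracle_scan <- function(seqstr, pattern) {
  n <- nchar(seqstr)
  starts <- integer(0); ends <- integer(0)
  positions <- if (startsWith(pattern, "^")) 1L else seq_len(n)
  anchored <- paste0("^(?:", sub("^\\^", "", pattern), ")")
  for (i in positions) {
    m <- regexpr(anchored, substring(seqstr, i), perl = TRUE)
    len <- attr(m, "match.length")
    if (m == 1L && len > 0) {
      starts <- c(starts, i)
      ends <- c(ends, i + len - 1L)
    }
  }
  data.frame(start = starts, end = ends)
}

# exhaustive double-loop minimum CA-CA distance
oracle_min_dist <- function(sel_a, sel_b) {
  best <- Inf
  for (i in seq_len(nrow(sel_a))) {
    for (j in seq_len(nrow(sel_b))) {
      d <- sqrt((sel_a$x[i] - sel_b$x[j])^2 +
                (sel_a$y[i] - sel_b$y[j])^2 +
                (sel_a$z[i] - sel_b$z[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# exhaustive enumeration of pairs within a cutoff
oracle_contact_pairs <- function(sel_a, sel_b, cutoff) {
  rows <- list()
  for (i in seq_len(nrow(sel_a))) {
    for (j in seq_len(nrow(sel_b))) {
      d <- sqrt((sel_a$x[i] - sel_b$x[j])^2 +
                (sel_a$y[i] - sel_b$y[j])^2 +
                (sel_a$z[i] - sel_b$z[j])^2)
      if (d <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          resno_a = sel_a$resno[i], resno_b = sel_b$resno[j], distance = d)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(resno_a = integer(0), resno_b = integer(0),
                      distance = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$distance, out$resno_a, out$resno_b), , drop = FALSE]
}

# a residue-selection data frame with random coordinates, compatible with
# the selection objects select_region() returns
random_selection <- function(n, chain = "A", spread = 30) {
  data.frame(chain = chain, resno = seq_len(n), icode = "",
             resid = "ALA",
             x = stats::runif(n, -spread, spread),
             y = stats::runif(n, -spread, spread),
             z = stats::runif(n, -spread, spread),
             stringsAsFactors = FALSE)
}

random_aa_sequence <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE), collapse = "")
}

toy_classes <- function() {
  load_motif_classes(toy_extdata("toy_elm_classes.tsv"))
}
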