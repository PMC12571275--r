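pdb_line <- function(serial, chain, resno, x, y, z, alt = " ", occ = 1,
                     resname = "ALA", record = "ATOM  ", name = " CA ") {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          record, serial, name, alt, resname, chain, resno, x, y, z, occ, 0)
}

write_pdb <- function(lines) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  writeLines(c(lines, "END"), f)
  f
}

test_that("PDB parsing extracts one CA per residue across chains", {
  lines <- c(
    pdb_line(1, "A", 1, 0, 0, 0), pdb_line(2, "A", 2, 3.8, 0, 0),
    pdb_line(3, "A", 3, 7.6, 0, 0),
    pdb_line(4, "B", 1, 0, 10, 0), pdb_line(5, "B", 2, 3.8, 10, 0),
    pdb_line(6, "B", 3, 7.6, 10, 0))
  m <- parse_structure(write_pdb(lines))
  expect_equal(nrow(m$atoms), 6)
  expect_equal(m$chains, c("A", "B"))
  expect_equal(m$atoms$x[2], 3.8)

  # no ATOM records is a format error
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(parse_structure(f), class = "ppiface_format_error")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    pdb_line(1, "A", 1, 0, 0, 0, alt = "A", occ = 0.6),
    pdb_line(2, "A", 1, 5, 0, 0, alt = "B", occ = 0.4),
    # tie on occupancy: altloc letter breaks it (A wins)
    pdb_line(3, "A", 2, 1, 1, 1, alt = "B", occ = 0.5),
    pdb_line(4, "A", 2, 2, 2, 2, alt = "A", occ = 0.5))
  m <- parse_structure(write_pdb(lines))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x[m$atoms$resno == 1], 0)
  expect_equal(m$atoms$x[m$atoms$resno == 2], 2)
})

test_that("only the first model is read; HETATM standard residues are kept", {
  lines <- c(
    "MODEL        1",
    pdb_line(1, "A", 1, 0, 0, 0),
    pdb_line(2, "A", 2, 0, 5, 0, record = "HETATM"),          # MSE-like but standard code
    sub("ALA", "HOH", pdb_line(3, "A", 90, 9, 9, 9, record = "HETATM")),  # water: dropped
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "A", 1, 99, 99, 99),
    "ENDMDL")
  m <- parse_structure(write_pdb(lines))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$resno, c(1L, 2L))
  expect_equal(m$atoms$x[1], 0)  # model 2 coordinates never seen
})

test_that("generated structures round-trip through write -> parse at PDB precision", {
  spec <- toy_fixture_spec(seed = 77)
  f <- withr::local_tempfile(fileext = ".pdb")
  st <- make_toy_structure(spec, path = f)
  m <- parse_structure(f)
  # every CA coordinate survives to 3 decimals (PDB fixed-column precision)
  raw <- st$pdb_lines[startsWith(st$pdb_lines, "ATOM")]
  expect_equal(nrow(m$atoms), length(raw))
  xyz <- do.call(rbind, lapply(raw, function(l) {
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))
  }))
  expect_equal(as.matrix(m$atoms[, c("x", "y", "z")]), xyz,
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("region selection filters by chain and residue window with coverage", {
  lines <- c(pdb_line(1, "A", 1, 0, 0, 0), pdb_line(2, "A", 2, 1, 0, 0),
             pdb_line(3, "A", 3, 2, 0, 0))
  m <- parse_structure(write_pdb(lines))
  sel <- select_region(m, "A", 1, 2)
  expect_equal(nrow(sel), 2)
  expect_equal(attr(sel, "coverage"), 1)

  off <- select_region(m, "A", 10, 20)
  expect_equal(nrow(off), 0)
  expect_equal(attr(off, "coverage"), 0)

  expect_error(select_region(m, "Z", 1, 2), class = "ppiface_lookup_error")

  # gapped chain: brute-force list-filter oracle
  set.seed(19)
  resnos <- sort(sample(1:60, 25))
  gap_lines <- vapply(seq_along(resnos), function(i) {
    pdb_line(i, "A", resnos[i], i * 1.5, 0, 0)
  }, character(1))
  mg <- parse_structure(write_pdb(gap_lines))
  for (k in 1:5) {
    w <- sort(sample(1:60, 2))
    sel <- select_region(mg, "A", w[1], w[2])
    expect_equal(sel$resno, resnos[resnos >= w[1] & resnos <= w[2]])
    expect_equal(attr(sel, "coverage"),
                 sum(resnos >= w[1] & resnos <= w[2]) / (w[2] - w[1] + 1))
  }
})

test_that("minimum region distance is exact, symmetric, and oracle-equivalent", {
  a <- data.frame(chain = "A", resno = 1L, icode = "", resid = "ALA",
                  x = 0, y = 0, z = 0)
  b <- data.frame(chain = "B", resno = 1L, icode = "", resid = "GLY",
                  x = 6, y = 0, z = 0)
  expect_identical(min_region_distance(a, b), 6)
  expect_identical(min_region_distance(a, a), 0)  # degenerate self-pair
  expect_error(min_region_distance(a[0, ], b), class = "ppiface_empty_selection")

  set.seed(29)
  for (k in 1:20) {
    sa <- random_selection(sample(1:15, 1))
    sb <- random_selection(sample(1:15, 1), chain = "B")
    expect_identical(min_region_distance(sa, sb), min_region_distance(sb, sa))
    expect_equal(min_region_distance(sa, sb), oracle_min_dist(sa, sb))
  }
})

test_that("distances are invariant under rigid rotation and translation", {
  set.seed(41)
  sa <- random_selection(12)
  sb <- random_selection(9, chain = "B")
  theta <- 0.7; phi <- 1.3
  rz <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0, 0, cos(phi), -sin(phi), 0, sin(phi), cos(phi)), 3, byrow = TRUE)
  R <- rz %*% rx
  shift <- c(12.3, -4.5, 99)
  transform_sel <- function(s) {
    xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
    s$x <- xyz[, 1] + shift[1]; s$y <- xyz[, 2] + shift[2]; s$z <- xyz[, 3] + shift[3]
    s
  }
  d0 <- min_region_distance(sa, sb)
  d1 <- min_region_distance(transform_sel(sa), transform_sel(sb))
  expect_lt(abs(d0 - d1), 1e-6)
})

test_that("contact labeling enumerates exactly the pairs within the cutoff", {
  # construction: exactly 3 CA pairs under 5 A
  a <- data.frame(chain = "A", resno = 1:2, icode = "", resid = "ALA",
                  x = c(0, 100), y = 0, z = 0)
  b <- data.frame(chain = "B", resno = 1:3, icode = "", resid = "GLY",
                  x = c(3, 4, 102), y = 0, z = 0)
  got <- contact_residue_pairs(a, b, 5)
  expect_equal(nrow(got), 3)
  expect_equal(got$distance, c(2, 3, 4))  # sorted ascending
  expect_true(all(diff(got$distance) >= 0))

  # cutoff below the minimum -> empty
  expect_equal(nrow(contact_residue_pairs(a, b, 1.5)), 0)

  # seeded random regions: identical to the exhaustive enumeration oracle
  set.seed(53)
  for (k in 1:10) {
    sa <- random_selection(sample(3:20, 1))
    sb <- random_selection(sample(3:20, 1), chain = "B")
    cut <- runif(1, 5, 25)
    got <- contact_residue_pairs(sa, sb, cut)
    exp <- oracle_contact_pairs(sa, sb, cut)
    expect_equal(got[, c("resno_a", "resno_b", "distance")], exp,
                 ignore_attr = TRUE)
  }
})

test_that("distance filter partitions candidates into pass/fail/unevaluable", {
  fx <- make_toy_fixture(toy_fixture_spec(seed = 61))
  cand <- fx$truth_candidates
  rep6 <- filter_by_distance(cand, fx$model, fx$chain_map, cutoff = 6)
  truth <- fx$structure$ground_truth
  expect_equal(rep6$status[order(rep6$start_a)],
               ifelse(truth$kind == "planted", "pass", "fail")[order(truth$start_a)])

  # cutoff 4 is below every planted distance (drawn from 4.5-5.5): none pass
  rep4 <- filter_by_distance(cand, fx$model, fx$chain_map, cutoff = 4)
  expect_equal(sum(rep4$status == "pass"), 0)

  # a candidate outside the resolved model is unevaluable, never pass/fail
  ghost <- cand[1, ]
  ghost$start_a <- 5000L; ghost$end_a <- 5010L
  repg <- filter_by_distance(rbind(cand[1, ], ghost), fx$model, fx$chain_map, 6)
  expect_equal(repg$status, c("pass", "unevaluable"))
  expect_true(is.na(repg$min_distance[2]))

  # exact boundary: min distance == cutoff passes (<=, no epsilon)
  d <- rep6$min_distance[1]
  repb <- filter_by_distance(rep6[1, 1:12], fx$model, fx$chain_map, cutoff = d)
  expect_equal(repb$status, "pass")

  # chain map errors
  expect_error(filter_by_distance(cand, fx$model, list(), 6),
               class = "ppiface_validation_error")
  expect_error(chain_map("A", "A"), class = "ppiface_validation_error")

  # pass set equals brute-force recomputation of every min distance
  for (i in seq_len(nrow(rep6))) {
    sa <- select_region(fx$model, "A", rep6$start_a[i], rep6$end_a[i])
    sb <- select_region(fx$model, "B", rep6$start_b[i], rep6$end_b[i])
    expect_equal(rep6$min_distance[i], oracle_min_dist(sa, sb))
  }
})

test_that("the sweep reports nested pass sets and detection distances", {
  fx <- make_toy_fixture(toy_fixture_spec(seed = 67, n_planted = 4, n_decoys = 3))
  cand <- fx$truth_candidates
  sw <- distance_sweep(cand, fx$model, fx$chain_map, cutoffs = 11:4)

  # nesting: pass(d) subset of pass(d+1)
  for (d in 4:10) {
    p_lo <- sw$report[[sprintf("pass_%d", d)]]
    p_hi <- sw$report[[sprintf("pass_%d", d + 1)]]
    expect_true(all(!p_lo | p_hi))
  }

  # detection distance is the ceiling of the min distance within the sweep
  md <- sw$detection$min_distance
  expected_det <- ifelse(md > 11, NA_real_, pmax(ceiling(md), 4))
  expect_equal(sw$detection$detection_distance, expected_det)

  # consistency: passing at cutoff c iff contact pairs at c is non-empty
  for (i in seq_len(nrow(cand))) {
    sa <- select_region(fx$model, "A", cand$start_a[i], cand$end_a[i])
    sb <- select_region(fx$model, "B", cand$start_b[i], cand$end_b[i])
    for (cutval in c(5, 8, 11)) {
      expect_equal(sw$report[[sprintf("pass_%d", cutval)]][i],
                   nrow(contact_residue_pairs(sa, sb, cutval)) > 0)
    }
  }
})

test_that("contact reports serialize to TSV and labeled JSON", {
  fx <- make_toy_fixture(toy_fixture_spec(seed = 71))
  rep6 <- filter_by_distance(fx$truth_candidates, fx$model, fx$chain_map, 6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_contact_report(rep6, tsv, json_path = js, model = fx$model,
                       map = fx$chain_map, cutoff = 6)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(rep6))
  expect_equal(back$status, rep6$status)
  doc <- jsonlite::read_json(js)
  expect_equal(length(doc), nrow(rep6))
  n_pass_contacts <- vapply(doc, function(d) length(d$contacts), integer(1))
  expect_true(all(n_pass_contacts[vapply(doc, function(d) d$status, character(1)) == "pass"] > 0))
})
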