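test_that("read_structure parses fixed-column records verbatim", {
  txt <- c(pdb_line(1, "N", "GLY", "A", 5, 1.234, -2.5, 3.75),
           pdb_line(2, "CA", "GLY", "A", 5, 2.345, -1.25, 4.5))
  s <- read_structure(txt)
  expect_equal(length(residue_keys(s)), 1L)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x, c(1.234, 2.345))
  expect_equal(s$atoms$y, c(-2.5, -1.25))
  expect_equal(s$atoms$resno, c(5L, 5L))
  expect_equal(s$atoms$element, c("N", "C"))
})

test_that("read_structure rejects empty and malformed input", {
  expect_error(read_structure(""), "empty structure")
  expect_error(read_structure("REMARK nothing here"), "empty structure")
  bad <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "ATOM      2  CA")
  expect_error(read_structure(bad), "line 2")
  badc <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0))
  substr(badc, 31, 38) <- "   xx.xx"
  expect_error(read_structure(badc), "line 1")
})

test_that("altloc resolution keeps the highest occupancy, ties to first", {
  txt <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
           pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, altloc = "B"))
  s <- read_structure(txt)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$x, 9)
  # tie: first encountered wins
  txt2 <- c(pdb_line(1, "CA", "ALA", "A", 1, 1, 1, 1, occ = 0.5, altloc = "A"),
            pdb_line(2, "CA", "ALA", "A", 1, 2, 2, 2, occ = 0.5, altloc = "B"))
  expect_equal(read_structure(txt2)$atoms$x, 1)
})

test_that("HETATM water is skipped by default, kept on request", {
  wat <- sub("^ATOM  ", "HETATM", pdb_line(2, "O", "HOH", "A", 99, 5, 5, 5))
  txt <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0), wat)
  expect_equal(nrow(read_structure(txt)$atoms), 1L)
  expect_equal(nrow(read_structure(txt, skip_water = FALSE)$atoms), 2L)
})

test_that("select_residues uses inclusive author-numbered ranges", {
  cplx <- fixture_complex()
  keys <- select_residues(cplx, "R", "271-294")
  expect_length(keys, 24L)
  expect_equal(parse_res_key(keys[1])$resno, 271L)
  expect_equal(parse_res_key(keys[24])$resno, 294L)
  expect_length(select_residues(cplx, "R", "274-274"), 1L)
  expect_length(select_residues(cplx, "Q", "1-100"), 0L)
  expect_error(select_residues(cplx, "R", "10-5"), "exceeds")
})

test_that("multi-model PDB and score table round-trip into an ensemble", {
  e <- fixture_ensemble(n = 3L)
  pdb <- tempfile(fileext = ".pdb")
  sc <- tempfile(fileext = ".tsv")
  write_pdb(e, pdb)
  write_scores_tsv(e, sc)
  e2 <- read_ensemble(pdb, sc)
  expect_length(e2$members, 3L)
  expect_equal(vapply(e2$members, `[[`, 0L, "conformation_id"), 1:3)
  expect_equal(vapply(e2$members, `[[`, 0, "score"),
               vapply(e$members, `[[`, 0, "score"), tolerance = 1e-4)
  expect_equal(sort(residue_keys(e2$members[[1]]$structure)),
               sort(residue_keys(e$members[[1]]$structure)))
  # coordinates survive the fixed-format write to 1e-3
  a1 <- e$members[[2]]$structure$atoms
  a2 <- e2$members[[2]]$structure$atoms
  a1 <- a1[order(res_key(a1$chain, a1$resno, a1$ins), a1$atom), ]
  a2 <- a2[order(res_key(a2$chain, a2$resno, a2$ins), a2$atom), ]
  expect_equal(a2$x, a1$x, tolerance = 1e-3)
})

test_that("ensemble topology invariant rejects perturbed members", {
  base <- make_structure(data.frame(chain = "R", resno = 1:4,
                                    x = 0:3 * 4, y = 0, z = 0))
  ok <- list(list(conformation_id = 1L, structure = base, score = -1),
             list(conformation_id = 2L, structure = base, score = 0))
  expect_silent(new_ensemble(ok))
  for (seed in 1:5) {
    drop <- withr::with_seed(seed, sample(1:4, 1))
    mut <- make_structure(data.frame(chain = "R", resno = setdiff(1:4, drop),
                                     x = 1:3, y = 0, z = 0))
    bad <- list(ok[[1]], list(conformation_id = 2L, structure = mut, score = 0))
    expect_error(new_ensemble(bad), "topology")
  }
  expect_error(
    read_ensemble(c(pdb_line(1, "CA", "ALA", "R", 1, 0, 0, 0), "END"),
                  scores = data.frame(conformation_id = 2L, score = 1)),
    "missing score")
})

test_that("analysis tables round-trip through their TSV format", {
  cm <- make_contact_map(data.frame(
    conformation_id = c(2L, 1L), receptor = c("R:283:", "R:275:"),
    peptide = c("P:3:", "P:2:"), min_distance = c(4.21, 5.5),
    rec_atom = c("CEN", "CA"), pep_atom = c("O", "CA"),
    stringsAsFactors = FALSE), ensemble_size = 2L)
  f <- tempfile(fileext = ".tsv")
  write_tables(cm, f)
  cm2 <- read_tables(f)
  expect_s3_class(cm2, "ecl2_contact_map")
  expect_equal(attr(cm2, "cutoff"), 5.5)
  expect_equal(attr(cm2, "ensemble_size"), 2L)
  # deterministic sort: receptor resno then peptide resno
  expect_equal(cm2$receptor, c("R:275:", "R:283:"))
  expect_equal(cm2$min_distance[2], 4.21)
  # a second write of the read object is byte-identical (idempotence)
  f2 <- tempfile(fileext = ".tsv")
  write_tables(cm2, f2)
  expect_identical(readLines(f), readLines(f2))

  ft <- frequency_table(cm, min_count = 0)
  f3 <- tempfile(fileext = ".tsv")
  write_tables(ft, f3)
  ft2 <- read_tables(f3)
  expect_equal(as.data.frame(ft2), as.data.frame(ft))
  expect_equal(attr(ft2, "min_count"), 0L)

  # empty frequency table -> header-only file
  empty <- frequency_table(make_contact_map(
    data.frame(conformation_id = integer(), receptor = character(),
               peptide = character(), stringsAsFactors = FALSE), 0L))
  f4 <- tempfile(fileext = ".tsv")
  write_tables(empty, f4)
  body <- grep("^#!", readLines(f4), value = TRUE, invert = TRUE)
  expect_length(body, 1L)
  expect_true(startsWith(body, "#"))
  expect_equal(nrow(read_tables(f4)), 0L)
})
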