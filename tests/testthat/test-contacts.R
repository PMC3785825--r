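test_that("the contact boundary is inclusive at the cutoff", {
  s <- make_structure(data.frame(chain = c("R", "P"), resno = c(1, 1),
                                 x = c(0, 5.5), y = 0, z = 0))
  hit <- compute_contacts(s, "R:1:", "P:1:", cutoff = 5.5)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$min_distance, 5.5)
  s6 <- make_structure(data.frame(chain = c("R", "P"), resno = c(1, 1),
                                  x = c(0, 6.0), y = 0, z = 0))
  expect_equal(nrow(compute_contacts(s6, "R:1:", "P:1:", 5.5)), 0L)
  expect_error(compute_contacts(s, "R:9:", "P:1:"), "absent")
  expect_error(compute_contacts(s, character(0), "P:1:"), "empty")
})

test_that("contacts equal the exhaustive all-atom-pairs oracle", {
  for (seed in 1:6) {
    s <- random_structure(seed)
    rsel <- res_key("R", 1:6)
    psel <- res_key("P", 1:4)
    got <- compute_contacts(s, rsel, psel, 5.5)
    want <- oracle_contacts(s, rsel, psel, 5.5)
    got <- got[order(got$receptor, got$peptide), ]
    want <- want[order(want$receptor, want$peptide), ]
    expect_equal(got$receptor, want$receptor)
    expect_equal(got$peptide, want$peptide)
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
    # the recorded atom pair realizes the recorded minimum distance
    for (i in seq_len(nrow(got))) {
      a <- s$atoms
      k <- res_key(a$chain, a$resno, a$ins)
      ra <- a[k == got$receptor[i] & a$atom == got$rec_atom[i], ]
      pa <- a[k == got$peptide[i] & a$atom == got$pep_atom[i], ]
      d <- sqrt((ra$x - pa$x)^2 + (ra$y - pa$y)^2 + (ra$z - pa$z)^2)
      expect_equal(d, got$min_distance[i], tolerance = 1e-9)
    }
  }
})

test_that("contact relation is symmetric and monotone in the cutoff", {
  s <- random_structure(42)
  rsel <- res_key("R", 1:6)
  psel <- res_key("P", 1:4)
  fwd <- compute_contacts(s, rsel, psel, 5.5)
  rev <- compute_contacts(s, psel, rsel, 5.5)
  key_f <- sort(paste(fwd$receptor, fwd$peptide))
  key_r <- sort(paste(rev$peptide, rev$receptor))
  expect_equal(key_f, key_r)
  expect_equal(sort(fwd$min_distance), sort(rev$min_distance), tolerance = 1e-12)
  for (cut in c(3, 4.5, 5.5, 7)) {
    lo <- compute_contacts(s, rsel, psel, cut)
    hi <- compute_contacts(s, rsel, psel, cut + 1.5)
    expect_true(all(paste(lo$receptor, lo$peptide) %in%
                      paste(hi$receptor, hi$peptide)))
  }
})

test_that("key-interaction counting counts pairs whose receptor is key", {
  pairs <- data.frame(
    receptor = res_key("R", c(283, 283, 288, 275)),
    peptide = res_key("P", c(3, 4, 6, 2)),
    stringsAsFactors = FALSE)
  expect_equal(count_key_interactions(pairs, res_key("R", c(283, 288))), 3L)
  expect_equal(count_key_interactions(pairs, character(0)), 0L)
  # monotone in the key set
  subsets <- list(c(283), c(283, 288), c(283, 288, 275))
  counts <- vapply(subsets, function(k) count_key_interactions(pairs, res_key("R", k)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("frequency aggregation counts conformations and prunes correctly", {
  rows <- do.call(rbind, lapply(1:10, function(id) {
    out <- data.frame(conformation_id = id, receptor = "R:288:",
                      peptide = "P:6:", stringsAsFactors = FALSE)
    if (id <= 7) out else out[0, ]
  }))
  rows <- rbind(rows, data.frame(conformation_id = 1:10, receptor = "R:275:",
                                 peptide = "P:2:", stringsAsFactors = FALSE))
  cm <- make_contact_map(rows, ensemble_size = 10L)
  ft <- frequency_table(cm, min_count = 0)
  expect_equal(ft$count[ft$receptor == "R:288:"], 7L)
  expect_equal(ft$count[ft$receptor == "R:275:"], 10L)
  ft10 <- frequency_table(cm, min_count = 10)
  expect_false("R:288:" %in% ft10$receptor)
  expect_true("R:275:" %in% ft10$receptor)
  # pruned table is a subset of the unpruned table
  expect_true(all(paste(ft10$receptor, ft10$peptide) %in%
                    paste(ft$receptor, ft$peptide)))
  # ensemble of 1: every observed pair has count 1
  one <- frequency_table(make_contact_map(rows[rows$conformation_id == 1, ], 1L))
  expect_true(all(one$count == 1L))
  # counts reproducible by independent recount
  df <- as.data.frame(cm)
  recount <- table(paste(df$receptor, df$peptide))
  for (i in seq_len(nrow(ft))) {
    expect_equal(ft$count[i], unname(recount[paste(ft$receptor[i], ft$peptide[i])]))
  }
})

test_that("bridge detection requires a broken direct contact", {
  # endpoints 7 A apart (no direct contact), candidate 4 A from each
  s <- make_structure(data.frame(chain = "R", resno = c(1, 2, 3),
                                 x = c(0, 7, 3.5), y = c(0, 0, sqrt(16 - 3.5^2)),
                                 z = 0))
  hit <- detect_bridges(s, "R:1:", "R:2:", "R:3:", cutoff = 5.5)
  expect_equal(hit$candidate, "R:3:")
  expect_equal(hit$dist_a, 4, tolerance = 1e-9)
  expect_equal(hit$dist_b, 4, tolerance = 1e-9)
  # direct contact -> no bridge regardless of candidates
  s2 <- make_structure(data.frame(chain = "R", resno = c(1, 2, 3),
                                  x = c(0, 4, 2), y = c(0, 0, 1), z = 0))
  expect_equal(nrow(detect_bridges(s2, "R:1:", "R:2:", "R:3:")), 0L)
  # candidate out of reach -> empty
  s3 <- make_structure(data.frame(chain = "R", resno = c(1, 2, 3),
                                  x = c(0, 7, 50), y = 0, z = 0))
  expect_equal(nrow(detect_bridges(s3, "R:1:", "R:2:", "R:3:")), 0L)
  # sorted by the larger of the two distances
  s4 <- make_structure(data.frame(chain = "R", resno = c(1, 2, 3, 4),
                                  x = c(0, 7, 3.5, 3.5),
                                  y = c(0, 0, sqrt(16 - 3.5^2), sqrt(25 - 3.5^2)),
                                  z = 0))
  hits <- detect_bridges(s4, "R:1:", "R:2:", res_key("R", c(4, 3)))
  expect_equal(hits$candidate, res_key("R", c(3, 4)))
})

test_that("side-chain orientation splits at the threshold angle", {
  mk <- function(dx, dy, dz) {
    make_structure(data.frame(chain = "R", resno = c(1, 1),
                              atom = c("CA", "CEN"),
                              x = c(0, dx), y = c(0, dy), z = c(0, dz)))
  }
  up <- classify_side_chain_orientation(mk(0, 0, 2), "R:1:")
  expect_equal(up$angle_deg, 0, tolerance = 1e-9)
  expect_equal(up$label, "vertical")
  # antiparallel counts as vertical too (unsigned angle)
  down <- classify_side_chain_orientation(mk(0, 0, -2), "R:1:")
  expect_equal(down$angle_deg, 0, tolerance = 1e-9)
  flat <- classify_side_chain_orientation(mk(2, 0, 0), "R:1:")
  expect_equal(flat$angle_deg, 90, tolerance = 1e-9)
  expect_equal(flat$label, "horizontal")
  tilt <- classify_side_chain_orientation(mk(2 * sin(60 * pi / 180), 0,
                                             2 * cos(60 * pi / 180)), "R:1:")
  expect_equal(tilt$angle_deg, 60, tolerance = 0.1)
  expect_equal(tilt$label, "horizontal")
  # custom threshold flips the label
  expect_equal(classify_side_chain_orientation(
    mk(2 * sin(60 * pi / 180), 0, 2 * cos(60 * pi / 180)), "R:1:",
    threshold = 75)$label, "vertical")
  gly <- make_structure(data.frame(chain = "R", resno = 1, atom = "CA",
                                   x = 0, y = 0, z = 0, resid = "GLY"))
  expect_error(classify_side_chain_orientation(gly, "R:1:"), "orientation undefined")
})
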