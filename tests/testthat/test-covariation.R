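test_that("alignment construction validates shape and alphabet", {
  a <- new_alignment(c(s1 = "ACDEFGHIKL", s2 = "ACDEFGHIKL"))
  expect_equal(a$n_col, 10L)
  expect_error(new_alignment(c(s1 = "ACDE", s2 = "ACD")), "ragged")
  err <- tryCatch(new_alignment(c(s1 = "ACDE", s2 = "ACZE")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "illegal character 'Z'")
  expect_match(err, "column 3")
  expect_error(new_alignment(c(only = "ACDE")), "at least 2")
})

test_that("aligned FASTA round-trips through the Biostrings reader", {
  al <- make_toy_paired_alignments(seed = 5)$receptor_sys1
  f <- tempfile(fileext = ".fasta")
  write_alignment(al, f)
  back <- read_alignment(f)
  expect_identical(back$sequences, al$sequences)
  expect_identical(back$mat, al$mat)
})

test_that("column conservation equals the brute-force modal fraction", {
  a <- new_alignment(c(s1 = "DDDD", s2 = "DDDE", s3 = "DD-D", s4 = "DDDD"))
  expect_equal(column_conservation(a, 1), 1)
  expect_equal(column_conservation(a, 3), 1)     # gap excluded from denominator
  expect_equal(column_conservation(a, 4), 0.75)
  allgap <- new_alignment(c(s1 = "A-", s2 = "C-"))
  expect_equal(column_conservation(allgap, 2), 0)
  expect_true(is.na(modal_residue(allgap, 2)))
  # randomized columns against an independent recount
  aas <- c("A", "C", "D", "E", "F", "-")
  for (seed in 1:5) {
    mat <- withr::with_seed(seed, matrix(sample(aas, 8 * 12, TRUE), 8, 12))
    al <- new_alignment(stats::setNames(apply(mat, 1, paste, collapse = ""),
                                        paste0("sp", 1:8)))
    for (col in 1:12) {
      ch <- mat[, col]
      ch <- ch[ch != "-"]
      want <- if (!length(ch)) 0 else max(table(ch)) / length(ch)
      expect_equal(column_conservation(al, col), want)
    }
  }
})

test_that("hydrogen-bond capability matches the curated side-chain table", {
  expect_false(hbond_capable("L"))
  expect_true(hbond_capable("D"))
  expect_true(hbond_capable("T"))
  capable <- c("S", "T", "Y", "N", "Q", "D", "E", "H", "K", "R", "W", "C")
  for (aa in c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
               "P", "Q", "R", "S", "T", "V", "W", "Y")) {
    expect_identical(hbond_capable(aa), aa %in% capable)
  }
  expect_error(hbond_capable("Z"), "invalid")
})

test_that("candidate filtering keeps conserved shared H-bond-capable columns", {
  rec1 <- new_alignment(c(a = "TTLLDA", b = "TTLLDA", c = "TTLLDA"))
  rec2 <- new_alignment(c(a = "TALLDC", b = "TALLDC", c = "TALLDC"))
  map <- data.frame(col1 = 1:6, col2 = 1:6)
  got <- conserved_hbond_candidates(rec1, rec2, map, segment = 1:6)
  # col 1 (shared invariant T) and col 5 (shared invariant D) pass;
  # col 3/4 (L, not capable) and col 2/6 (modal residues differ) do not
  expect_equal(got$col1, c(1L, 5L))
  expect_equal(got$residue, c("T", "D"))
  # conserved in one system only -> excluded
  rec2b <- new_alignment(c(a = "TTLLDA", b = "TALLDA", c = "TCLLDA"))
  expect_false(2L %in% conserved_hbond_candidates(rec1, rec2b, map, 1:6)$col1)
  expect_error(conserved_hbond_candidates(
    rec1, rec2, data.frame(col1 = c(1, 1), col2 = c(1, 2)), 1:2), "injective")
})

test_that("candidate filtering agrees with brute-force enumeration", {
  for (seed in 1:4) {
    p <- make_toy_paired_alignments(n_col = 30, seed = 700 + seed,
                                    noise_rate = 0.15)
    map <- p$receptor_map
    got <- conserved_hbond_candidates(p$receptor_sys1, p$receptor_sys2, map,
                                      1:30, min_conservation = 0.8)$col1
    want <- integer(0)
    for (col in 1:30) {
      m1 <- modal_residue(p$receptor_sys1, col)
      m2 <- modal_residue(p$receptor_sys2, col)
      k1 <- column_conservation(p$receptor_sys1, col)
      k2 <- column_conservation(p$receptor_sys2, col)
      if (!is.na(m1) && !is.na(m2) && m1 == m2 && k1 >= 0.8 && k2 >= 0.8 &&
          hbond_capable(m1)) {
        want <- c(want, col)
      }
    }
    expect_equal(got, want)
  }
})

test_that("the planted complementary pair ranks first with score 1", {
  p <- make_toy_paired_alignments(n_species = 6, n_col = 30,
                                  receptor_col = 12, peptide_col = 6,
                                  noise_rate = 0, seed = 2)
  hits <- correlated_pairs(p)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$receptor_col1, 12L)
  expect_equal(hits$peptide_col1, 6L)
  expect_equal(hits$score, 1)
  expect_equal(hits$receptor_res1, "D")
  expect_equal(hits$receptor_res2, "K")
})

test_that("the screen requires differences on both sides", {
  p <- make_toy_paired_alignments(noise_rate = 0, seed = 3)
  # identical systems: no inter-system differences anywhere
  p_same <- p
  p_same$receptor_sys2 <- p$receptor_sys1
  p_same$peptide_sys2 <- p$peptide_sys1
  expect_equal(nrow(correlated_pairs(p_same)), 0L)
  # only the receptor column differs -> excluded
  p_rec_only <- p
  p_rec_only$peptide_sys2 <- p$peptide_sys1
  expect_equal(nrow(correlated_pairs(p_rec_only)), 0L)
  expect_error(correlated_pairs(list(receptor_map = data.frame(),
                                     peptide_map = data.frame())), "empty")
})

test_that("the screen is invariant to species relabeling and row order", {
  p <- make_toy_paired_alignments(noise_rate = 0.05, seed = 8)
  base <- correlated_pairs(p)
  shuffle <- function(al, seed) {
    ord <- withr::with_seed(seed, sample(length(al$sequences)))
    seqs <- al$sequences[ord]
    names(seqs) <- paste0("renamed", seq_along(seqs))
    new_alignment(seqs)
  }
  p2 <- p
  p2$receptor_sys1 <- shuffle(p$receptor_sys1, 1)
  p2$peptide_sys2 <- shuffle(p$peptide_sys2, 2)
  expect_equal(correlated_pairs(p2), base)
})

test_that("raising the conservation threshold never adds hits", {
  p <- make_toy_paired_alignments(noise_rate = 0.2, seed = 13)
  lo <- correlated_pairs(p, min_conservation = 0.5)
  hi <- correlated_pairs(p, min_conservation = 0.8)
  strict <- correlated_pairs(p, min_conservation = 0.95)
  id <- function(h) paste(h$receptor_col1, h$peptide_col1)
  expect_true(all(id(hi) %in% id(lo)))
  expect_true(all(id(strict) %in% id(hi)))
})
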