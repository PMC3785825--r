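test_that("score percentiles rank best-first with deterministic ties", {
  e1 <- make_score_ensemble(3.2)
  r1 <- rank_by_score(e1)
  expect_equal(r1$percentile, 1)
  e3 <- make_score_ensemble(c(0, -10, -5), ids = c(7L, 8L, 9L))
  r3 <- rank_by_score(e3)
  expect_equal(r3$percentile[match(c(8L, 9L, 7L), r3$conformation_id)],
               c(1 / 3, 2 / 3, 1))
  # ties broken by conformation id ascending
  et <- make_score_ensemble(c(5, 5, 1), ids = c(2L, 1L, 3L))
  rt <- rank_by_score(et)
  expect_equal(rt$rank[match(c(3L, 1L, 2L), rt$conformation_id)], 1:3)
  # exactly floor(N * p) members pass a percentile bound
  e100 <- make_score_ensemble(withr::with_seed(1, stats::rnorm(100)))
  r100 <- rank_by_score(e100)
  expect_equal(sum(r100$percentile <= 0.15), 15L)
})

test_that("criteria selection matches a hand-checked fixture", {
  # 5 conformations; only 1 and 4 realize the probe contact 6 <-> 288
  rows <- rbind(
    data.frame(conformation_id = 1L, receptor = "R:288:", peptide = "P:6:"),
    data.frame(conformation_id = 1L, receptor = "R:283:", peptide = "P:3:"),
    data.frame(conformation_id = 2L, receptor = "R:283:", peptide = "P:3:"),
    data.frame(conformation_id = 3L, receptor = "R:275:", peptide = "P:2:"),
    data.frame(conformation_id = 4L, receptor = "R:287:", peptide = "P:6:"),
    data.frame(conformation_id = 5L, receptor = "R:288:", peptide = "P:5:"))
  cm <- make_contact_map(rows, ensemble_size = 5L)
  e <- make_score_ensemble(c(-9, -8, -7, -6, -5), ids = 1:5)
  key <- res_key("R", c(283, 287, 288))
  crit <- selection_criteria()       # mandatory 6 <-> {280, 287, 288}, min 1 key
  sel <- apply_criteria(cm, e, key, crit)
  expect_equal(nrow(sel), 5L)        # every member receives a verdict
  expect_equal(sel$conformation_id[sel$selected], c(1L, 4L))
  expect_equal(attr(sel, "ranking"), c(1L, 4L))
  # verdicts reconstruct `selected` by conjunction, exhaustively
  expect_equal(sel$selected,
               sel$mandatory_ok & sel$key_ok & sel$score_ok & sel$orientation_ok)
  # applying the same criteria twice is idempotent
  sel2 <- apply_criteria(cm, e, key, crit)
  expect_identical(as.data.frame(sel2), as.data.frame(sel))

  # empty criteria select everything
  all_in <- apply_criteria(cm, e, key,
                           selection_criteria(mandatory_contacts = list(),
                                              min_key_interactions = 0L))
  expect_true(all(all_in$selected))
})

test_that("selection shrinks monotonically as criteria tighten", {
  rows <- withr::with_seed(99, do.call(rbind, lapply(1:12, function(id) {
    data.frame(conformation_id = id,
               receptor = res_key("R", sample(c(275, 280, 283, 287, 288),
                                              size = (id %% 4) + 1)),
               peptide = res_key("P", 6), stringsAsFactors = FALSE)
  })))
  cm <- make_contact_map(rows, ensemble_size = 12L)
  e <- make_score_ensemble(withr::with_seed(5, stats::rnorm(12)), ids = 1:12)
  key <- res_key("R", c(280, 283, 287, 288))
  base <- selection_criteria(min_key_interactions = 1L)
  sel_base <- apply_criteria(cm, e, key, base)$selected

  tighter_percentile <- selection_criteria(min_key_interactions = 1L,
                                           score_percentile_max = 0.5)
  tighter_key <- selection_criteria(min_key_interactions = 3L)
  fewer_partners <- selection_criteria(
    mandatory_contacts = list(list(peptide = "P:6:", partners = "R:288:")))
  for (crit in list(tighter_percentile, tighter_key, fewer_partners)) {
    sel <- apply_criteria(cm, e, key, crit)$selected
    expect_true(all(which(sel) %in% which(sel_base)))
  }
  expect_error(selection_criteria(score_percentile_max = 0))
  expect_error(selection_criteria(
    mandatory_contacts = list(list(peptide = "P:6:", partners = character(0)))))
})

test_that("a planted ideal conformation is singled out at strict criteria", {
  # member 3: best score, probe contact, many key interactions
  rows <- rbind(
    data.frame(conformation_id = 3L, receptor = res_key("R", c(288, 283, 280)),
               peptide = res_key("P", c(6, 3, 11))),
    data.frame(conformation_id = 1L, receptor = "R:283:", peptide = "P:3:"),
    data.frame(conformation_id = 2L, receptor = "R:288:", peptide = "P:6:"))
  cm <- make_contact_map(rows, ensemble_size = 4L)
  e <- make_score_ensemble(c(-2, -1, -50, 0), ids = 1:4)
  crit <- selection_criteria(min_key_interactions = 3L,
                             score_percentile_max = 0.25)
  sel <- apply_criteria(cm, e, res_key("R", c(280, 283, 288)), crit)
  expect_equal(attr(sel, "ranking"), 3L)
})

test_that("orientation requirements are enforced through the label channel", {
  rows <- data.frame(conformation_id = 1:2, receptor = "R:288:", peptide = "P:6:")
  cm <- make_contact_map(rows, ensemble_size = 2L)
  e <- make_score_ensemble(c(-1, -2), ids = 1:2)
  crit <- selection_criteria(orientation_requirements =
                               list(list(residue = "R:283:", label = "vertical")))
  expect_error(apply_criteria(cm, e, "R:288:", crit), "orientation")
  ori <- data.frame(conformation_id = 1:2, residue = "R:283:",
                    label = c("vertical", "horizontal"))
  sel <- apply_criteria(cm, e, "R:288:", crit, orientations = ori)
  expect_equal(sel$conformation_id[sel$selected], 1L)
})

test_that("satisfied fractions count contacted key residues", {
  key13 <- res_key("R", c(273, 274, 277, 278, 280, 282, 283, 284, 285, 287,
                          288, 290, 291))
  none <- data.frame(receptor = character(), peptide = character())
  sf0 <- satisfied_fraction(none, key13)
  expect_equal(sf0$numerator, 0L)
  expect_equal(sf0$denominator, 13L)
  pairs <- data.frame(
    receptor = res_key("R", c(280, 280, 283, 284, 285, 287, 288, 299)),
    peptide = res_key("P", c(10, 11, 3, 5, 5, 5, 6, 1)))
  sf <- satisfied_fraction(pairs, key13)
  expect_equal(sf$numerator, 6L)
  expect_equal(sf$fraction, 6 / 13)
  expect_error(satisfied_fraction(pairs, character(0)), "non-empty")
})

test_that("probe-partner labels classify conformations for scatter output", {
  rows <- rbind(
    data.frame(conformation_id = 1L, receptor = "R:288:", peptide = "P:6:"),
    data.frame(conformation_id = 2L, receptor = c("R:287:", "R:288:"),
               peptide = "P:6:"),
    data.frame(conformation_id = 3L, receptor = "R:275:", peptide = "P:6:"))
  cm <- make_contact_map(rows, ensemble_size = 4L)
  lab <- partner_labels(cm, "P:6:", res_key("R", c(280, 287, 288)))
  expect_equal(lab$partner_label[match(1:4, lab$conformation_id)],
               c("288", "both", "none", "none"))
})
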