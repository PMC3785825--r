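test_that("toy complex construction is deterministic and correctly sized", {
  s1 <- build_toy_complex(toy_complex_spec(seed = 7))
  s2 <- build_toy_complex(toy_complex_spec(seed = 7))
  expect_identical(s1$atoms, s2$atoms)
  # 3 helices x 10 + 20 loop + 7 peptide residues
  expect_length(residue_keys(s1), 3L * 10L + 20L + 7L)
  expect_equal(sum(grepl("^P:", residue_keys(s1))), 7L)
  expect_error(toy_complex_spec(loop_sequence = "RS"), "at least 3")
})

test_that("the built complex has no non-bonded heavy-atom pair under 2.5 A", {
  expect_equal(nrow(find_clashes(fixture_complex(), 2.5)), 0L)
})

test_that("parser agrees with an independent PDB reader on the toy complex", {
  f <- tempfile(fileext = ".pdb")
  write_pdb(fixture_complex(), f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ours$atoms), nrow(ref$atom))
  expect_equal(ours$atoms$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(ours$atoms$resno, ref$atom$resno)
  expect_equal(ours$atoms$atom, ref$atom$elety)
})

test_that("sampled ensembles are closed, clash-free and reproducible", {
  e <- fixture_ensemble(n = 6L, seed = 3L)
  expect_length(e$members, 6L)
  stats <- attr(e, "attempt_stats")
  expect_equal(stats$closure_failures, 0L)
  for (m in e$members) {
    s <- m$structure
    # seam continuity: the loop's last carbonyl carbon must bond the
    # C-side anchor nitrogen (1.33 A ideal, closure tolerance 0.5)
    a <- s$atoms
    cl <- as.numeric(a[a$chain == "R" & a$resno == 293 & a$atom == "C",
                       c("x", "y", "z")])
    an <- as.numeric(a[a$chain == "R" & a$resno == 294 & a$atom == "N",
                       c("x", "y", "z")])
    expect_lt(abs(sqrt(sum((cl - an)^2)) - 1.329), 1.0)
    # exhaustive O(N^2) clash oracle
    expect_equal(nrow(find_clashes(s, 2.5)), 0L)
  }
  # fixed region copied verbatim
  a1 <- e$members[[1]]$structure$atoms
  a2 <- e$members[[2]]$structure$atoms
  fixed1 <- a1[!(a1$chain == "R" & a1$resno >= 274 & a1$resno <= 293), ]
  fixed2 <- a2[!(a2$chain == "R" & a2$resno >= 274 & a2$resno <= 293), ]
  expect_identical(fixed1[order(res_key(fixed1$chain, fixed1$resno), fixed1$atom), ],
                   fixed2[order(res_key(fixed2$chain, fixed2$resno), fixed2$atom), ])
  # same seed twice -> identical coordinates
  e2 <- sample_loop_ensemble(fixture_complex(),
                             p = loop_sampler_params(n_conformations = 6L, seed = 3L))
  expect_identical(e$members[[4]]$structure$atoms, e2$members[[4]]$structure$atoms)
  # n = 0 -> empty ensemble
  e0 <- sample_loop_ensemble(fixture_complex(),
                             p = loop_sampler_params(n_conformations = 0L, seed = 1L))
  expect_length(e0$members, 0L)
})

test_that("loop ensembles are conformationally diverse", {
  e <- fixture_ensemble(n = 10L, seed = 3L)
  cas <- lapply(e$members, function(m) {
    a <- m$structure$atoms
    as.matrix(a[a$chain == "R" & a$resno >= 274 & a$resno <= 293 &
                  a$atom == "CA", c("x", "y", "z")])
  })
  rmsds <- c()
  for (i in 1:(length(cas) - 1)) {
    for (j in (i + 1):length(cas)) {
      rmsds <- c(rmsds, sqrt(mean(rowSums((cas[[i]] - cas[[j]])^2))))
    }
  }
  expect_gt(mean(rmsds), 1)
})

test_that("pseudo-energy depends only on internal distances", {
  s <- fixture_complex()
  base <- pseudo_energy(s)
  # arbitrary rigid-body motion
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% Rz
  xyz <- sweep(xyz, 2, c(11.2, -5.4, 3.3), "+")
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
  expect_lt(abs(pseudo_energy(moved) - base), 1e-9)
  # identical conformations score identically
  expect_identical(pseudo_energy(s), pseudo_energy(s))
})

test_that("pseudo-energy strictly increases when overlap is introduced", {
  s <- fixture_complex()
  base <- pseudo_energy(s)
  # push the peptide into the loop: move it toward the loop centroid
  a <- s$atoms
  loop_cen <- colMeans(a[a$chain == "R" & a$resno >= 274 & a$resno <= 293,
                         c("x", "y", "z")])
  pep <- a$chain == "P"
  pep_cen <- colMeans(a[pep, c("x", "y", "z")])
  shift <- (loop_cen - pep_cen)
  shift <- shift / sqrt(sum(shift^2))
  overlapped <- s
  steps <- 0
  repeat {
    overlapped$atoms[pep, c("x", "y", "z")] <-
      overlapped$atoms[pep, c("x", "y", "z")] + rep(shift, each = sum(pep))
    steps <- steps + 1
    if (nrow(find_clashes(overlapped, 3.2)) > 0 || steps > 20) break
  }
  expect_gt(pseudo_energy(overlapped), base)
})

test_that("dose-response simulation matches the logistic identities", {
  conc <- 10^seq(-12, -6, by = 0.5)
  cur <- simulate_dose_response(c(5, 100, 9, 1), conc, noise_sd = 0, seed = 1)
  # at c = EC50 the noiseless response is the midpoint
  at_ec50 <- simulate_dose_response(c(5, 100, 9, 1), 1e-9, 0, 1)
  expect_equal(at_ec50$responses, (5 + 100) / 2, tolerance = 1e-10)
  # c -> 0 tends to basal
  at_low <- simulate_dose_response(c(5, 100, 9, 1), 1e-18, 0, 1)
  expect_equal(at_low$responses, 5, tolerance = 1e-6)
  # monotone increasing for hill > 0
  expect_true(all(diff(cur$responses) > 0))
  # seeded noise reproducible
  n1 <- simulate_dose_response(c(0, 100, 8, 1), conc, noise_sd = 5, seed = 3)
  n2 <- simulate_dose_response(c(0, 100, 8, 1), conc, noise_sd = 5, seed = 3)
  expect_identical(n1$responses, n2$responses)
  expect_error(simulate_dose_response(c(0, 100, 8, 1), c(1e-9, -1e-8), 0, 1),
               "positive")
})

test_that("mutagenesis simulation plants effects where asked", {
  scanned <- res_key("R", 271:294)
  planted <- res_key("R", c(280, 287, 288))
  eff0 <- effect_spec(planted, delta_pec50 = 0, replicate_sd = 0, seed = 2)
  rec0 <- simulate_mutagenesis(10.6, eff0, scanned)
  expect_equal(nrow(rec0), 24L)
  expect_equal(rec0$pec50_mean, rec0$wt_pec50_mean, tolerance = 1e-12)
  eff <- effect_spec(planted, delta_pec50 = 1, replicate_sd = 0, seed = 2)
  rec <- simulate_mutagenesis(10.6, eff, scanned)
  shift <- rec$pec50_mean - rec$wt_pec50_mean
  expect_equal(unname(shift[rec$residue %in% planted]), rep(-1, 3))
  expect_equal(unname(shift[!rec$residue %in% planted]), rep(0, 21))
  # deterministic
  effn <- effect_spec(planted, replicate_sd = 0.15, seed = 11)
  expect_identical(simulate_mutagenesis(10.6, effn, scanned),
                   simulate_mutagenesis(10.6, effn, scanned))
  expect_error(simulate_mutagenesis(10.6, eff, res_key("R", 271:279)),
               "not in the scan")
  # table round-trips through TSV
  f <- tempfile(fileext = ".tsv")
  write_mutagenesis_tsv(simulate_mutagenesis(10.6, effn, scanned), f)
  back <- read_mutagenesis_tsv(f)
  orig <- simulate_mutagenesis(10.6, effn, scanned)
  expect_equal(back$pec50_mean, orig$pec50_mean, tolerance = 1e-9)
  expect_equal(back$replicate_mut[[3]], orig$replicate_mut[[3]], tolerance = 1e-9)
})
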