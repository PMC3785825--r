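# Shared fixtures, all built in code. The toy complex and a small ensemble
# are memoized per test run because they are comparatively expensive.

.fixture_env <- new.env()

fixture_complex <- function() {
  if (is.null(.fixture_env$cplx)) {
    .fixture_env$cplx <- build_toy_complex(toy_complex_spec(seed = 7))
  }
  .fixture_env$cplx
}

fixture_ensemble <- function(n = 10L, seed = 3L) {
  key <- paste0("e", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- sample_loop_ensemble(
      fixture_complex(), p = loop_sampler_params(n_conformations = n, seed = seed))
  }
  .fixture_env[[key]]
}

# Structure from a bare coordinate table: one atom "CA" (plus optional
# extras) per row; handy for geometric fixtures.
make_structure <- function(df) {
  defaults <- data.frame(ins = "", resid = "ALA", atom = "CA", element = "C",
                         occ = 1, altloc = "", stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  new_structure(df[, c("chain", "resno", "ins", "resid", "atom", "element",
                       "x", "y", "z", "occ", "altloc")])
}

# Minimal PDB ATOM line with standard columns.
pdb_line <- function(serial, atom, resid, chain, resno, x, y, z,
                     occ = 1, altloc = "", element = substr(atom, 1, 1)) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", atom), altloc, resid, chain, resno, x, y, z, occ, 0,
          element)
}

# Brute-force residue-pair contact oracle: double loop over every heavy
# atom pair, entirely independent of compute_contacts' implementation.
oracle_contacts <- function(s, receptor_sel, peptide_sel, cutoff) {
  a <- s$atoms[!(toupper(s$atoms$element) %in% c("H", "D")), ]
  key <- res_key(a$chain, a$resno, a$ins)
  out <- list()
  for (rk in receptor_sel) {
    for (pk in peptide_sel) {
      ra <- a[key == rk, ]
      pa <- a[key == pk, ]
      best <- Inf
      for (i in seq_len(nrow(ra))) {
        for (j in seq_len(nrow(pa))) {
          d <- sqrt((ra$x[i] - pa$x[j])^2 + (ra$y[i] - pa$y[j])^2 +
                      (ra$z[i] - pa$z[j])^2)
          if (d < best) best <- d
        }
      }
      if (best <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(receptor = rk, peptide = pk,
                                              min_distance = best,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(receptor = character(), peptide = character(),
               min_distance = numeric(), stringsAsFactors = FALSE)
}

# Random multi-residue structure for property tests (<= 500 atoms).
random_structure <- function(seed, n_rec = 6L, n_pep = 4L, atoms_per_res = 5L) {
  withr::with_seed(seed, {
    rows <- list()
    serial <- 0L
    for (ch in c("R", "P")) {
      n_res <- if (ch == "R") n_rec else n_pep
      for (r in seq_len(n_res)) {
        centre <- stats::runif(3, 0, 15)
        for (k in seq_len(atoms_per_res)) {
          serial <- serial + 1L
          p <- centre + stats::rnorm(3, 0, 1.5)
          rows[[serial]] <- data.frame(chain = ch, resno = r, x = p[1],
                                       y = p[2], z = p[3],
                                       atom = paste0("A", k),
                                       stringsAsFactors = FALSE)
        }
      }
    }
    make_structure(do.call(rbind, rows))
  })
}

# A classed contact map built directly from a pair table, for filter tests.
make_contact_map <- function(df, ensemble_size, cutoff = 5.5) {
  need <- c("conformation_id", "receptor", "peptide")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$min_distance)) df$min_distance <- rep(4, nrow(df))
  if (is.null(df$rec_atom)) df$rec_atom <- rep("CA", nrow(df))
  if (is.null(df$pep_atom)) df$pep_atom <- rep("CA", nrow(df))
  structure(df, class = c("ecl2_contact_map", "data.frame"),
            cutoff = cutoff, ensemble_size = as.integer(ensemble_size))
}

# A minimal ensemble carrying only ids and scores (single shared residue).
make_score_ensemble <- function(scores, ids = seq_along(scores)) {
  base <- make_structure(data.frame(chain = "R", resno = 1,
                                    x = 0, y = 0, z = 0))
  members <- Map(function(id, sc) {
    list(conformation_id = id, structure = base, score = sc)
  }, ids, scores)
  new_ensemble(members)
}
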