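# Toy receptor-peptide complex builder: a small helical bundle with one
# remodelled loop segment and a short peptide docked above the loop anchors.
# It stands in, at desk scale, for a homology-modelled receptor with a
# peptide agonist docked over the extracellular loops.

#' Specification of the toy receptor-peptide complex
#'
#' Defaults emulate the studied system: a 20-residue remodelled loop
#' (author numbering 274-293, the second extracellular loop segment) between
#' two bundle helices, with the published residue identities placed at their
#' published positions (R274, Y277, Y278, D280, N281, C282, W283, I284,
#' S285, D287, T288, L290, L291, Y292) and generic residues elsewhere, and a
#' 7-residue peptide (ACDTATC, the peptide agonist N-terminus, chain "P",
#' residues 1-7). Helix sequences are poly-alanine. The sequences are
#' synthetic stand-ins, not the real receptor sequence.
#'
#' @param n_helices number of bundle helices (default 3).
#' @param helix_length residues per helix (default 10).
#' @param loop_sequence 1-letter loop sequence, length >= 3.
#' @param peptide_sequence 1-letter peptide sequence.
#' @param loop_start author number of the first loop residue (default 274).
#' @param receptor_chain,peptide_chain chain ids (defaults "R", "P").
#' @param helix_spacing centre-to-centre distance between adjacent helix
#'   axes, Angstrom (default 10.5).
#' @param peptide_height height of the peptide centroid above the loop
#'   anchors' midpoint, Angstrom (default 6).
#' @param peptide_offset lateral displacement of the peptide centroid,
#'   perpendicular to the anchor-anchor axis, Angstrom (default 6; the
#'   combined displacement must keep the peptide within 12 Angstrom of the
#'   midpoint). The offset moves the peptide off the plane swept by the
#'   loop's hairpin excursion so that loop-peptide contacts are frequent
#'   but hard overlaps are not forced.
#' @param seed integer seed controlling the initial loop conformation.
#' @return list of class `ecl2_toy_spec`.
#' @export
toy_complex_spec <- function(n_helices = 3L, helix_length = 10L,
                             loop_sequence = "RSSYYGDNCWISGDTGLLYG",
                             peptide_sequence = "ACDTATC",
                             loop_start = 274L,
                             receptor_chain = "R", peptide_chain = "P",
                             helix_spacing = 10.5, peptide_height = 6,
                             peptide_offset = 6, seed = 1L) {
  if (nchar(loop_sequence) < 3L) stop("loop_sequence must have at least 3 residues")
  if (n_helices < 2L) stop("need at least 2 helices to anchor the loop")
  if (sqrt(peptide_height^2 + peptide_offset^2) > 12) {
    stop("peptide placement must stay within 12 Angstrom of the loop anchors' midpoint")
  }
  structure(list(
    n_helices = as.integer(n_helices), helix_length = as.integer(helix_length),
    loop_sequence = loop_sequence, peptide_sequence = peptide_sequence,
    loop_start = as.integer(loop_start),
    receptor_chain = receptor_chain, peptide_chain = peptide_chain,
    helix_spacing = helix_spacing, peptide_height = peptide_height,
    peptide_offset = peptide_offset, seed = as.integer(seed)
  ), class = "ecl2_toy_spec")
}

seq_to_3letter <- function(seq1) {
  letters1 <- strsplit(toupper(seq1), "")[[1L]]
  bad <- !(letters1 %in% names(AA_1TO3))
  if (any(bad)) stop("unknown residue code(s): ", paste(letters1[bad], collapse = ", "))
  unname(AA_1TO3[letters1])
}

# Atom rows (N, CA, C, O, CEN) for one residue given its backbone triad.
residue_atom_rows <- function(chain, resno, resid, bb, psi) {
  O <- place_carbonyl_o(bb$N, bb$CA, bb$C, psi)
  rows <- data.frame(
    chain = chain, resno = resno, ins = "", resid = resid,
    atom = c("N", "CA", "C", "O"),
    element = c("N", "C", "C", "O"),
    x = c(bb$N[1L], bb$CA[1L], bb$C[1L], O[1L]),
    y = c(bb$N[2L], bb$CA[2L], bb$C[2L], O[2L]),
    z = c(bb$N[3L], bb$CA[3L], bb$C[3L], O[3L]),
    occ = 1, altloc = "", stringsAsFactors = FALSE
  )
  d <- CEN_DISTANCE[[resid]]
  if (!is.na(d)) {
    cen <- bb$CA + d * cbeta_direction(bb$N, bb$CA, bb$C)
    rows <- rbind(rows, data.frame(
      chain = chain, resno = resno, ins = "", resid = resid,
      atom = "CEN", element = "C",
      x = cen[1L], y = cen[2L], z = cen[3L], occ = 1, altloc = "",
      stringsAsFactors = FALSE
    ))
  }
  rows
}

# Build a straight segment (helix or extended strand) and return its atom
# table plus backbone triads, in a local frame.
build_segment_atoms <- function(chain, resnos, resids, phi, psi) {
  n <- length(resnos)
  bbs <- build_backbone(rep(phi, n), rep(psi, n))
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    residue_atom_rows(chain, resnos[i], resids[i], bbs[[i]], psi)
  }))
  list(atoms = atoms, bbs = bbs)
}

transform_atoms <- function(atoms, R, shift) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, "+")
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  atoms
}

segment_ca <- function(atoms, resno) {
  row <- atoms[atoms$resno == resno & atoms$atom == "CA", ]
  c(row$x, row$y, row$z)
}

#' Build the toy receptor-peptide complex
#'
#' Constructs ideal alpha-helical backbone stubs (phi = -57, psi = -47)
#' arranged on a circle with alternating up/down directions, an extended
#' peptide chain floating above the loop anchors, and an initial closed,
#' clash-free loop conformation connecting the first helix's C-terminus to
#' the second helix's N-terminus (sampled and closed by cyclic coordinate
#' descent, retried until clash-free). Side chains are single pseudo-atoms
#' ("CEN") along the virtual C-alpha -> C-beta direction at a residue-type
#' specific distance. Deterministic for a fixed `spec$seed`.
#'
#' @param spec an [toy_complex_spec()].
#' @return an `ecl2_structure` whose metadata records the remodelled loop
#'   segment and the spec.
#' @export
build_toy_complex <- function(spec = toy_complex_spec()) {
  fx <- build_toy_fixed(spec)
  loop_resids <- seq_to_3letter(spec$loop_sequence)
  loop <- withr::with_seed(spec$seed, {
    sample_closed_clashfree_loop(
      fx$fixed, chain = spec$receptor_chain,
      loop_start = spec$loop_start, loop_end = fx$loop_end,
      loop_resids = loop_resids,
      closure_tolerance = 0.5, clash_distance = 2.5, max_attempts = 200L
    )
  })
  if (is.null(loop)) stop("failed to build an initial clash-free loop conformation")

  atoms <- rbind(fx$receptor_fixed, loop, fx$pep_atoms)
  new_structure(atoms, metadata = list(
    remodelled_segments = data.frame(chain = spec$receptor_chain,
                                     start = spec$loop_start, end = fx$loop_end,
                                     stringsAsFactors = FALSE),
    spec = spec
  ))
}

# Fixed (non-loop) part of the toy complex: helices + peptide, plus anchor
# bookkeeping. Split out so the loop sampler can be exercised on the bare
# scaffold.
build_toy_fixed <- function(spec) {
  stopifnot(inherits(spec, "ecl2_toy_spec"))
  L_loop <- nchar(spec$loop_sequence)
  loop_end <- spec$loop_start + L_loop - 1L
  h_len <- spec$helix_length
  n_hel <- spec$n_helices
  rb <- spec$helix_spacing / (2 * sin(pi / n_hel))

  helix_resnos <- vector("list", n_hel)
  helix_resnos[[1L]] <- (spec$loop_start - h_len):(spec$loop_start - 1L)
  helix_resnos[[2L]] <- (loop_end + 1L):(loop_end + h_len)
  if (n_hel > 2L) {
    nxt <- loop_end + h_len + 7L
    for (k in 3L:n_hel) {
      helix_resnos[[k]] <- nxt:(nxt + h_len - 1L)
      nxt <- nxt + h_len + 6L
    }
  }

  placed <- vector("list", n_hel)
  z_top <- NULL
  for (k in seq_len(n_hel)) {
    seg <- build_segment_atoms(spec$receptor_chain, helix_resnos[[k]],
                               rep("ALA", h_len), -57, -47)
    ca1 <- seg$bbs[[1L]]$CA
    caN <- seg$bbs[[h_len]]$CA
    up <- k %% 2L == 1L
    R <- rotation_from_to(caN - ca1, if (up) c(0, 0, 1) else c(0, 0, -1))
    th <- 2 * pi * (k - 1L) / n_hel
    base <- c(rb * cos(th), rb * sin(th), 0)
    atoms <- transform_atoms(seg$atoms, R, c(0, 0, 0))
    ref <- as.numeric(atoms[atoms$resno == helix_resnos[[k]][1L] & atoms$atom == "CA",
                            c("x", "y", "z")])
    if (up) {
      atoms <- transform_atoms(atoms, diag(3), base - ref)
    } else {
      if (is.null(z_top)) stop("internal: down helix placed before up helix")
      atoms <- transform_atoms(atoms, diag(3), c(base[1L], base[2L], z_top) - ref)
    }
    placed[[k]] <- atoms
    if (k == 1L) z_top <- max(atoms$z[atoms$atom == "CA"])
  }
  receptor_fixed <- do.call(rbind, placed)

  # extended peptide above the loop anchors, long axis parallel to the
  # anchor-anchor line, displaced laterally off the hairpin plane
  pep_res <- seq_to_3letter(spec$peptide_sequence)
  pep <- build_segment_atoms(spec$peptide_chain, seq_along(pep_res), pep_res, -140, 135)
  pep_ca1 <- pep$bbs[[1L]]$CA
  pep_caN <- pep$bbs[[length(pep_res)]]$CA
  anchor_n_ca <- segment_ca(placed[[1L]], spec$loop_start - 1L)
  anchor_c_ca <- segment_ca(placed[[2L]], loop_end + 1L)
  mid <- (anchor_n_ca + anchor_c_ca) / 2
  ab <- anchor_c_ca - anchor_n_ca
  ab_h <- vunit(c(ab[1L], ab[2L], 0))
  perp <- vunit(vcross(ab_h, c(0, 0, 1)))
  Rp <- rotation_from_to(pep_caN - pep_ca1, ab_h)
  pep_atoms <- transform_atoms(pep$atoms, Rp, c(0, 0, 0))
  pep_centroid <- colMeans(pep_atoms[, c("x", "y", "z")])
  pep_atoms <- transform_atoms(
    pep_atoms, diag(3),
    mid + spec$peptide_offset * perp + c(0, 0, spec$peptide_height) -
      as.numeric(pep_centroid))

  fixed <- new_structure(rbind(receptor_fixed, pep_atoms))
  list(fixed = fixed, receptor_fixed = receptor_fixed, pep_atoms = pep_atoms,
       loop_end = loop_end)
}
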