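# Loop-ensemble sampler: backbone dihedrals drawn from a three-basin
# Ramachandran mixture, grown clash-aware as a hairpin from both anchors,
# closed at the apex by cyclic coordinate descent (CCD), and clash-rejected
# against the whole complex. A surrogate pseudo-energy scores each accepted
# conformation (lower = more probable), standing in for the
# statistical-potential score a modelling package would assign.

#' Loop sampler parameters
#'
#' @param n_conformations ensemble size (default 100, the study-scale
#'   ensemble size).
#' @param closure_tolerance maximum allowed displacement per anchor atom
#'   (N, CA, C) after closure, Angstrom (default 0.5).
#' @param clash_distance minimum allowed non-bonded heavy-atom distance,
#'   Angstrom (default 2.5).
#' @param max_attempts_per_conformation sampling attempts before giving up
#'   (default 100).
#' @param max_ccd_iterations CCD sweeps per attempt (default 200).
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `ecl2_sampler_params`.
#' @export
loop_sampler_params <- function(n_conformations = 100L, closure_tolerance = 0.5,
                                clash_distance = 2.5,
                                max_attempts_per_conformation = 100L,
                                max_ccd_iterations = 200L, seed = 1L) {
  stopifnot(n_conformations >= 0L, closure_tolerance > 0, clash_distance > 0)
  structure(list(
    n_conformations = as.integer(n_conformations),
    closure_tolerance = closure_tolerance,
    clash_distance = clash_distance,
    max_attempts_per_conformation = as.integer(max_attempts_per_conformation),
    max_ccd_iterations = as.integer(max_ccd_iterations),
    seed = as.integer(seed)
  ), class = "ecl2_sampler_params")
}

# Three-basin Ramachandran mixture for coil sampling: alpha (-63,-43),
# beta (-120,130), left-handed (55,45); weights 0.35/0.55/0.10, sigma 20 deg.
RAMA_BASINS <- list(
  phi = c(-63, -120, 55), psi = c(-43, 130, 45),
  w = c(0.35, 0.55, 0.10), sigma = 20
)

sample_rama <- function(n) {
  basin <- sample.int(3L, n, replace = TRUE, prob = RAMA_BASINS$w)
  phi <- RAMA_BASINS$phi[basin] + stats::rnorm(n, 0, RAMA_BASINS$sigma)
  psi <- RAMA_BASINS$psi[basin] + stats::rnorm(n, 0, RAMA_BASINS$sigma)
  list(phi = phi, psi = psi)
}

backbone_triad <- function(s, chain, resno) {
  a <- s$atoms
  sel <- a[a$chain == chain & a$resno == resno & a$ins == "", , drop = FALSE]
  get <- function(nm) {
    row <- sel[sel$atom == nm, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("loop anchor residue ", res_key(chain, resno),
           " lacks backbone atom ", nm)
    }
    c(row$x, row$y, row$z)
  }
  list(N = get("N"), CA = get("CA"), C = get("C"))
}

# Cyclic coordinate descent closure. M is the mobile backbone matrix
# (rows N1,CA1,C1,...,N',CA',C'); aN the fixed N-side anchor triad; target
# the triad the primed atoms must land on. Per-move rotations are capped so
# the closure correction is spread over all dihedrals instead of crumpling
# the chain about the first few. Returns list(M, closed, err, iterations).
ccd_close <- function(M, aN, target, tol, max_iter, max_step_disp = 0.4) {
  n_row <- nrow(M)
  L <- n_row / 3L - 1L
  tgt <- rbind(target$N, target$CA, target$C)
  mt_rows <- (3L * L + 1L):(3L * L + 3L)

  axis_list <- list(list(p1 = aN$CA, p2 = aN$C, from = 1L))
  for (i in seq_len(L)) {
    b <- 3L * (i - 1L)
    axis_list[[length(axis_list) + 1L]] <- list(row1 = b + 1L, row2 = b + 2L, from = b + 3L)
    axis_list[[length(axis_list) + 1L]] <- list(row1 = b + 2L, row2 = b + 3L, from = b + 4L)
  }
  axis_list[[length(axis_list) + 1L]] <-
    list(row1 = 3L * L + 1L, row2 = 3L * L + 2L, from = 3L * L + 3L)
  # sweep axes closest to the moving end first, so small-lever dihedrals
  # absorb most of the error and the chain is disturbed minimally
  axis_list <- rev(axis_list)

  atom_err <- function() sqrt(rowSums((M[mt_rows, , drop = FALSE] - tgt)^2))
  for (iter in seq_len(max_iter)) {
    if (all(atom_err() <= tol)) {
      return(list(M = M, closed = TRUE, err = atom_err(), iterations = iter - 1L))
    }
    for (ax in axis_list) {
      p1 <- if (is.null(ax$p1)) M[ax$row1, ] else ax$p1
      p2 <- if (is.null(ax$p2)) M[ax$row2, ] else ax$p2
      u <- p2 - p1
      un <- sqrt(sum(u * u))
      if (un < 1e-9) next
      u <- u / un
      mob <- mt_rows[mt_rows >= ax$from]
      if (!length(mob)) next
      mv <- M[mob, , drop = FALSE]
      fv <- tgt[mt_rows %in% mob, , drop = FALSE]
      rel <- sweep(mv, 2L, p1)
      proj <- as.numeric(rel %*% u)
      o <- sweep(proj %*% t(u), 2L, p1, "+")
      r <- mv - o
      s <- fv - o
      uxr <- cbind(u[2L] * r[, 3L] - u[3L] * r[, 2L],
                   u[3L] * r[, 1L] - u[1L] * r[, 3L],
                   u[1L] * r[, 2L] - u[2L] * r[, 1L])
      theta <- atan2(sum(s * uxr), sum(s * r))
      # cap the rotation by the displacement it causes at the moving end,
      # so long-lever (base) dihedrals cannot sweep the chain sideways
      r_max <- max(sqrt(rowSums(r^2)), 1e-6)
      cap <- max_step_disp / r_max
      theta <- max(-cap, min(cap, theta))
      if (abs(theta) < 1e-10) next
      rows <- ax$from:n_row
      M[rows, ] <- rotate_points(M[rows, , drop = FALSE], p1, u, theta)
    }
  }
  list(M = M, closed = all(atom_err() <= tol), err = atom_err(), iterations = max_iter)
}

# --- sampling machinery ------------------------------------------------
# One attempt = (i) draw a randomized hairpin-shaped guide path between the
# anchors, (ii) grow the C-side leg backward and the N-side leg forward
# along the guide, clash-aware residue by residue, (iii) close the small
# remaining gap at the hairpin apex by CCD over the N-side leg's dihedrals
# (the apex sits in open space, so the closure correction cannot drive the
# chain through the bundle or the peptide), (iv) exhaustive clash check.

# Precompute everything reusable across attempts.
loop_sampler_context <- function(fixed, chain, loop_start, loop_end, loop_resids) {
  h <- heavy_atoms(fixed)
  list(
    aN = backbone_triad(fixed, chain, loop_start - 1L),
    target = backbone_triad(fixed, chain, loop_end + 1L),
    chain = chain, loop_start = loop_start,
    loop_resids = loop_resids, L = length(loop_resids),
    cen_d = unname(CEN_DISTANCE[loop_resids]),
    fixed_xyz = as.matrix(h[, c("x", "y", "z")]),
    fixed_d2 = rowSums(as.matrix(h[, c("x", "y", "z")])^2),
    fixed_resno = h$resno, fixed_chain = h$chain
  )
}

# Growth-time copy of the context with the fixed atoms restricted to a
# bounding box around the guide (margin generous relative to the guide
# tube); the final acceptance check always runs against the full context.
subset_ctx <- function(ctx, guide, margin = 12) {
  lo <- apply(guide, 2L, min) - margin
  hi <- apply(guide, 2L, max) + margin
  keep <- ctx$fixed_xyz[, 1L] >= lo[1L] & ctx$fixed_xyz[, 1L] <= hi[1L] &
    ctx$fixed_xyz[, 2L] >= lo[2L] & ctx$fixed_xyz[, 2L] <= hi[2L] &
    ctx$fixed_xyz[, 3L] >= lo[3L] & ctx$fixed_xyz[, 3L] <= hi[3L]
  ctx$fixed_xyz <- ctx$fixed_xyz[keep, , drop = FALSE]
  ctx$fixed_d2 <- ctx$fixed_d2[keep]
  ctx$fixed_resno <- ctx$fixed_resno[keep]
  ctx$fixed_chain <- ctx$fixed_chain[keep]
  ctx
}

# Randomized hairpin guide: a tent-shaped excursion whose per-step rise
# matches the chain's natural rise; random tilt, apex height and lateral
# bow give conformational diversity. Guide points are nudged out of the
# fixed structure so the clash and guide terms never fight. guide(i) is the
# intended CA position of loop residue i (i = L+1 is the C-anchor image).
make_guide <- function(ctx) {
  L1 <- ctx$L + 1L
  A <- ctx$aN$CA; B <- ctx$target$CA
  ab <- B - A
  perp <- vcross(ab, c(0, 0, 1))
  perp <- if (vnorm(perp) < 1e-6) c(1, 0, 0) else vunit(perp)
  alpha <- stats::rnorm(1L, 0, 12) * DEG
  apex <- stats::runif(1L, 1.1, 1.45) * L1
  bow <- stats::rnorm(1L, 0, 2.5)
  splay <- stats::runif(1L, 1.5, 3.5) * sample(c(-1, 1), 1L)
  bump_dir <- cos(alpha) * c(0, 0, 1) + sin(alpha) * perp
  tent <- function(t) 1 - abs(1 - 2 * t)
  pts <- t(vapply(seq_len(L1), function(i) {
    t_ <- i / L1
    # splay pushes the rising and descending legs onto opposite sides of
    # the hairpin plane so they do not collide at mid-height
    A + t_ * ab + apex * tent(t_) * bump_dir +
      (bow * sin(pi * t_) + splay * sin(2 * pi * t_)) * perp
  }, numeric(3L)))
  for (rep in 1:3) {
    d2g <- outer(rowSums(pts^2), rowSums(ctx$fixed_xyz^2), "+") -
      2 * pts %*% t(ctx$fixed_xyz)
    for (i in seq_len(L1)) {
      j <- which.min(d2g[i, ])
      d <- sqrt(max(d2g[i, j], 1e-9))
      if (d < 4.5) {
        away <- pts[i, ] - ctx$fixed_xyz[j, ]
        away <- if (vnorm(away) < 1e-6) c(0, 0, 1) else vunit(away)
        pts[i, ] <- pts[i, ] + (4.5 - d) * away
      }
    }
  }
  pts
}

# Residue heavy atoms (N, CA, C, O, CEN) given the triad and the psi that
# orients the carbonyl.
residue_heavy_pts <- function(ctx, i, N, CA, C, psi) {
  O <- place_carbonyl_o(N, CA, C, psi)
  pts <- rbind(N, CA, C, O)
  if (i >= 1L && i <= ctx$L && !is.na(ctx$cen_d[i])) {
    pts <- rbind(pts, CA + ctx$cen_d[i] * cbeta_direction(N, CA, C))
  }
  pts
}

# Count, per candidate, the clashing points in a stacked candidate matrix
# (rows grouped by point type, `try_id` mapping rows to candidates).
batch_clashes <- function(ctx, P, pt_resno, try_id, n_try, ref_xyz, ref_resno, thr2) {
  d2f <- outer(rowSums(P^2), ctx$fixed_d2, "+") - 2 * P %*% t(ctx$fixed_xyz)
  exf <- matrix(ctx$fixed_chain == ctx$chain, nrow(P), length(ctx$fixed_chain),
                byrow = TRUE) &
    (abs(outer(pt_resno, ctx$fixed_resno, "-")) <= 1L)
  hits <- rowSums(d2f < thr2 & !exf)
  if (length(ref_resno)) {
    d2l <- outer(rowSums(P^2), rowSums(ref_xyz^2), "+") - 2 * P %*% t(ref_xyz)
    ok <- abs(outer(pt_resno, ref_resno, "-")) >= 2L
    hits <- hits + rowSums(d2l < thr2 & ok)
  }
  as.numeric(rowsum(hits, try_id, reorder = TRUE))
}

# Grow loop residues L, L-1, ..., m+1 backward from the C-side anchor along
# the guide; all n_try candidate placements per residue are generated and
# scored in one vectorized batch. Growth never hard-fails; the final clash
# check arbitrates.
grow_leg_backward <- function(ctx, guide, m, clash_distance, n_try = 40L,
                              tube_radius = 2.5, guide_weight = 2) {
  g <- BB_GEOM
  thr2 <- clash_distance^2
  nxt <- ctx$target                       # residue "j+1" triad, start = anchor
  phi_next <- sample_rama(1L)$phi         # phi of the anchor residue image
  triads <- vector("list", ctx$L)
  cloud <- matrix(0, 0L, 3L)
  cloud_resno <- integer(0)
  js <- if (ctx$L >= m + 1L) seq(ctx$L, m + 1L) else integer(0)
  img <- NULL
  ones <- rep(180, n_try)
  for (j in c(js, m)) {
    if (j == m) {
      # image block of residue m, positioned later by the closure: one draw
      draw <- sample_rama(1L)
      Cj <- place_atom(nxt$C, nxt$CA, nxt$N, g$c_n, g$ang_c_n_ca, phi_next)
      CAj <- place_atom(nxt$CA, nxt$N, Cj, g$ca_c, g$ang_ca_c_n, 180)
      Nj <- place_atom(nxt$N, Cj, CAj, g$n_ca, g$ang_n_ca_c, draw$psi[1L])
      img <- list(N = Nj, CA = CAj, C = Cj)
      break
    }
    d1 <- sample_rama(n_try); d2 <- sample_rama(n_try)
    psi_t <- d1$psi
    phi_t <- d1$phi
    phi_next_t <- c(phi_next, d2$phi[-1L])
    C_t <- place_atom_rows(nxt$C, nxt$CA, nxt$N, g$c_n, g$ang_c_n_ca, phi_next_t)
    CA_t <- place_atom_rows(nxt$CA, nxt$N, C_t, g$ca_c, g$ang_ca_c_n, ones)
    N_t <- place_atom_rows(nxt$N, C_t, CA_t, g$n_ca, g$ang_n_ca_c, psi_t)
    resno_j <- ctx$loop_start + j - 1L
    Nx <- matrix(nxt$N, n_try, 3L, byrow = TRUE)
    psi_act <- dihedral_rows(N_t, CA_t, C_t, Nx)
    O_t <- place_atom_rows(N_t, CA_t, C_t, g$c_o, g$ang_ca_c_o, psi_act + 180)
    has_cen <- !is.na(ctx$cen_d[j])
    P <- rbind(N_t, CA_t, C_t, O_t)
    if (has_cen) {
      P <- rbind(P, CA_t + ctx$cen_d[j] * cbeta_direction_rows(N_t, CA_t, C_t))
    }
    try_id <- rep(seq_len(n_try), 4L + has_cen)
    ncl <- batch_clashes(ctx, P, rep(resno_j, nrow(P)), try_id, n_try,
                         cloud, cloud_resno, thr2)
    # tighter guide adherence toward the seam keeps the closure gap small
    w_seam <- 1 + 3 * ((ctx$L - j + 1L) / (ctx$L - m))^2
    off <- pmax(0, sqrt(rowSums(sweep(CA_t, 2L, guide[j, ])^2)) - tube_radius / w_seam)
    look <- 0
    if (j > m + 1L) {
      Cv <- place_atom_rows(C_t, CA_t, N_t, g$c_n, g$ang_c_n_ca, phi_t)
      CAv <- place_atom_rows(CA_t, N_t, Cv, g$ca_c, g$ang_ca_c_n, ones)
      look <- pmax(0, sqrt(rowSums(sweep(CAv, 2L, guide[j - 1L, ])^2)) - tube_radius / w_seam)
    }
    score <- 1000 * ncl + guide_weight * w_seam * (off^2 + look^2)
    bi <- which.min(score)
    triads[[j]] <- list(N = N_t[bi, ], CA = CA_t[bi, ], C = C_t[bi, ])
    pts <- P[try_id == bi, , drop = FALSE]
    cloud <- rbind(cloud, pts)
    cloud_resno <- c(cloud_resno, rep(resno_j, nrow(pts)))
    nxt <- triads[[j]]
    phi_next <- phi_t[bi]
  }
  # reversed-chain matrix (blocks [C_j, CA_j, N_j] for j = L .. m+1, plus
  # the image block of residue m): lets the same CCD routine flex the
  # backward leg from the C-side anchor
  Mrev <- NULL
  if (length(js)) {
    Mrev <- do.call(rbind, lapply(js, function(j) {
      tr <- triads[[j]]
      rbind(tr$C, tr$CA, tr$N)
    }))
    Mrev <- rbind(Mrev, img$C, img$CA, img$N)
  }
  list(triads = triads, cloud = cloud, cloud_resno = cloud_resno, Mrev = Mrev)
}

# Symmetric closure: alternate CCD on the forward leg (its image residue
# m+1 chasing the backward leg's residue m+1) and on the reversed backward
# leg (its image residue m chasing the forward leg's residue m) until the
# seam agrees to within `tol` per atom. Flexing both legs halves the
# correction each must absorb.
ping_pong_close <- function(ctx, F, Mrev, m, tol, max_rounds = 40L, iters = 5L) {
  aN_b <- list(N = ctx$target$C, CA = ctx$target$CA, C = ctx$target$N)
  b_m1 <- function() {
    b <- 3L * (ctx$L - m - 1L)
    list(N = Mrev[b + 3L, ], CA = Mrev[b + 2L, ], C = Mrev[b + 1L, ])
  }
  f_m <- function() {
    b <- 3L * (m - 1L)
    list(N = F[b + 1L, ], CA = F[b + 2L, ], C = F[b + 3L, ])
  }
  seam_err <- function() {
    tb <- b_m1()
    img <- F[(3L * m + 1L):(3L * m + 3L), , drop = FALSE]
    max(sqrt(rowSums((img - rbind(tb$N, tb$CA, tb$C))^2)))
  }
  for (round in seq_len(max_rounds)) {
    resF <- ccd_close(F, ctx$aN, b_m1(), tol, iters)
    F <- resF$M
    if (seam_err() <= tol) break
    fm <- f_m()
    resB <- ccd_close(Mrev, aN_b, list(N = fm$C, CA = fm$CA, C = fm$N), tol, iters)
    Mrev <- resB$M
    if (seam_err() <= tol) break
  }
  list(F = F, Mrev = Mrev, closed = seam_err() <= tol, err = seam_err())
}

# Grow residues 1..m forward from the N-side anchor along the guide,
# avoiding the fixed structure and the already-grown backward leg; the
# chain continues one extra "image" residue whose triad the closure must
# bring onto the backward leg's first residue. Candidates are batched like
# the backward leg.
grow_leg_forward <- function(ctx, guide, m, back, clash_distance, n_try = 40L,
                             tube_radius = 2.5, guide_weight = 2) {
  g <- BB_GEOM
  thr2 <- clash_distance^2
  n_build <- m + 1L
  prevN <- ctx$aN$N; prevCA <- ctx$aN$CA; prevC <- ctx$aN$C
  prev_psi_cur <- sample_rama(1L)$psi
  M <- matrix(0, 3L * n_build, 3L)
  cloud <- back$cloud
  cloud_resno <- back$cloud_resno
  ones <- rep(180, n_try)
  prev_psi_next <- NA_real_
  for (i in seq_len(n_build)) {
    d1 <- sample_rama(n_try); d2 <- sample_rama(n_try)
    prev_psi_t <- c(prev_psi_cur, d1$psi[-1L])
    phi_t <- d1$phi
    psi_t <- d2$psi
    N_t <- place_atom_rows(prevN, prevCA, prevC, g$c_n, g$ang_ca_c_n, prev_psi_t)
    CA_t <- place_atom_rows(prevCA, prevC, N_t, g$n_ca, g$ang_c_n_ca, ones)
    C_t <- place_atom_rows(prevC, N_t, CA_t, g$ca_c, g$ang_n_ca_c, phi_t)
    resno_i <- ctx$loop_start + i - 1L
    # previous residue's carbonyl O moves with prev_psi: include it
    Np <- matrix(prevN, n_try, 3L, byrow = TRUE)
    CAp <- matrix(prevCA, n_try, 3L, byrow = TRUE)
    Cp <- matrix(prevC, n_try, 3L, byrow = TRUE)
    psi_prev_act <- dihedral_rows(Np, CAp, Cp, N_t)
    O_prev_t <- place_atom_rows(prevN, prevCA, prevC, g$c_o, g$ang_ca_c_o,
                                psi_prev_act + 180)
    has_cen <- i <= ctx$L && !is.na(ctx$cen_d[i])
    P <- rbind(N_t, CA_t, C_t, O_prev_t)
    pt_resno <- c(rep(resno_i, 3L * n_try), rep(resno_i - 1L, n_try))
    if (has_cen) {
      P <- rbind(P, CA_t + ctx$cen_d[i] * cbeta_direction_rows(N_t, CA_t, C_t))
      pt_resno <- c(pt_resno, rep(resno_i, n_try))
    }
    try_id <- rep(seq_len(n_try), 4L + has_cen)
    ncl <- batch_clashes(ctx, P, pt_resno, try_id, n_try, cloud, cloud_resno, thr2)
    w_seam <- 1 + 3 * (i / n_build)^2
    off <- pmax(0, sqrt(rowSums(sweep(CA_t, 2L, guide[min(i, ctx$L + 1L), ])^2)) -
                  tube_radius / w_seam)
    look <- 0
    if (i < n_build) {
      Nv <- place_atom_rows(N_t, CA_t, C_t, g$c_n, g$ang_ca_c_n, psi_t)
      CAv <- place_atom_rows(CA_t, C_t, Nv, g$n_ca, g$ang_c_n_ca, ones)
      look <- pmax(0, sqrt(rowSums(sweep(CAv, 2L, guide[i + 1L, ])^2)) -
                     tube_radius / w_seam)
    }
    score <- 1000 * ncl + guide_weight * w_seam * (off^2 + look^2)
    bi <- which.min(score)
    b <- 3L * (i - 1L)
    M[b + 1L, ] <- N_t[bi, ]; M[b + 2L, ] <- CA_t[bi, ]; M[b + 3L, ] <- C_t[bi, ]
    pts <- P[try_id == bi, , drop = FALSE]
    cloud <- rbind(cloud, pts)
    cloud_resno <- c(cloud_resno, pt_resno[try_id == bi])
    prevN <- N_t[bi, ]; prevCA <- CA_t[bi, ]; prevC <- C_t[bi, ]
    prev_psi_cur <- psi_t[bi]
  }
  list(M = M)
}

# Heavy atoms (N, CA, C, O, CEN) of the whole loop given the merged chain
# matrix M_full (rows for residues 1..L plus the C-anchor triad); O of
# residue i uses the actual next amide nitrogen.
loop_heavy_coords <- function(ctx, M) {
  L <- ctx$L
  xyz <- matrix(0, 0L, 3L)
  resno <- integer(0)
  atom <- character(0)
  for (i in seq_len(L)) {
    b <- 3L * (i - 1L)
    N <- M[b + 1L, ]; CA <- M[b + 2L, ]; C <- M[b + 3L, ]
    psi_i <- dihedral_angle(N, CA, C, M[b + 4L, ])
    pts <- residue_heavy_pts(ctx, i, N, CA, C, psi_i)
    xyz <- rbind(xyz, pts)
    resno <- c(resno, rep(ctx$loop_start + i - 1L, nrow(pts)))
    atom <- c(atom, c("N", "CA", "C", "O", "CEN")[seq_len(nrow(pts))])
  }
  list(xyz = xyz, resno = resno, atom = atom)
}

# Per-loop-residue clash counts against the fixed structure and within the
# loop (non-bonded rule: different chain, or >= 2 apart in numbering).
loop_clash_profile <- function(ctx, lh, clash_distance) {
  thr2 <- clash_distance^2
  counts <- integer(ctx$L)
  lx <- lh$xyz
  cross2 <- outer(rowSums(lx^2), rowSums(ctx$fixed_xyz^2), "+") -
    2 * lx %*% t(ctx$fixed_xyz)
  excl <- outer(lh$resno, ctx$fixed_resno, function(a, b) abs(a - b) <= 1L) &
    matrix(ctx$fixed_chain == ctx$chain, nrow(lx), length(ctx$fixed_chain), byrow = TRUE)
  hits <- which(cross2 < thr2 & !excl, arr.ind = TRUE)
  intra2 <- outer(rowSums(lx^2), rowSums(lx^2), "+") - 2 * lx %*% t(lx)
  iexcl <- abs(outer(lh$resno, lh$resno, "-")) <= 1L
  ihits <- which(upper.tri(intra2) & intra2 < thr2 & !iexcl, arr.ind = TRUE)
  for (r in lh$resno[hits[, 1L]]) {
    j <- r - ctx$loop_start + 1L
    counts[j] <- counts[j] + 1L
  }
  for (r in c(lh$resno[ihits[, 1L]], lh$resno[ihits[, 2L]])) {
    j <- r - ctx$loop_start + 1L
    counts[j] <- counts[j] + 1L
  }
  counts
}

# Closed merged chain matrix -> loop atom table.
loop_atoms_from_chain <- function(ctx, M) {
  rows <- lapply(seq_len(ctx$L), function(i) {
    b <- 3L * (i - 1L)
    bb <- list(N = M[b + 1L, ], CA = M[b + 2L, ], C = M[b + 3L, ])
    psi_i <- dihedral_angle(bb$N, bb$CA, bb$C, M[b + 4L, ])
    residue_atom_rows(ctx$chain, ctx$loop_start + i - 1L, ctx$loop_resids[i],
                      bb, psi_i)
  })
  do.call(rbind, rows)
}

# One attempt; returns list(loop_atoms or NULL, closed flag).
sample_loop_attempt <- function(ctx, closure_tolerance, clash_distance,
                                max_ccd_iterations) {
  guide <- make_guide(ctx)
  m <- ceiling(ctx$L / 2)
  gctx <- subset_ctx(ctx, guide)
  back <- grow_leg_backward(gctx, guide, m, clash_distance)
  fwd <- grow_leg_forward(gctx, guide, m, back, clash_distance)
  if (is.null(back$Mrev)) {
    # loop too short to split: close the forward leg onto the anchor
    res <- ccd_close(fwd$M, ctx$aN, ctx$target, closure_tolerance,
                     max_ccd_iterations)
    if (!res$closed) return(list(loop_atoms = NULL, closed = FALSE))
    M_full <- rbind(res$M[seq_len(3L * m), , drop = FALSE],
                    ctx$target$N, ctx$target$CA, ctx$target$C)
  } else {
    pp <- ping_pong_close(ctx, fwd$M, back$Mrev, m, closure_tolerance,
                          max_rounds = max(2L, max_ccd_iterations %/% 30L),
                          iters = 30L)
    if (!pp$closed) return(list(loop_atoms = NULL, closed = FALSE))
    M_full <- pp$F[seq_len(3L * m), , drop = FALSE]
    for (j in seq(m + 1L, ctx$L)) {
      b <- 3L * (ctx$L - j)
      M_full <- rbind(M_full, pp$Mrev[b + 3L, ], pp$Mrev[b + 2L, ],
                      pp$Mrev[b + 1L, ])
    }
    M_full <- rbind(M_full, ctx$target$N, ctx$target$CA, ctx$target$C)
  }
  lh <- loop_heavy_coords(ctx, M_full)
  if (sum(loop_clash_profile(ctx, lh, clash_distance)) == 0L) {
    return(list(loop_atoms = loop_atoms_from_chain(ctx, M_full), closed = TRUE))
  }
  list(loop_atoms = NULL, closed = TRUE)
}

# Sample until a closed AND clash-free loop is found; NULL after
# max_attempts. Uses the caller's RNG stream.
sample_closed_clashfree_loop <- function(fixed, chain, loop_start, loop_end,
                                         loop_resids, closure_tolerance,
                                         clash_distance, max_attempts,
                                         max_ccd_iterations = 200L,
                                         stats_env = NULL) {
  ctx <- loop_sampler_context(fixed, chain, loop_start, loop_end, loop_resids)
  for (att in seq_len(max_attempts)) {
    out <- sample_loop_attempt(ctx, closure_tolerance, clash_distance,
                               max_ccd_iterations)
    if (!is.null(stats_env)) {
      stats_env$attempts <- stats_env$attempts + 1L
      if (!out$closed) stats_env$closure_failures <- stats_env$closure_failures + 1L
      else if (is.null(out$loop_atoms)) {
        stats_env$clash_rejections <- stats_env$clash_rejections + 1L
      }
    }
    if (!is.null(out$loop_atoms)) {
      attr(out$loop_atoms, "attempts") <- att
      return(out$loop_atoms)
    }
  }
  NULL
}

#' Sample a closed, clash-free loop ensemble
#'
#' Each member's loop backbone is drawn from a Ramachandran mixture along a
#' randomized hairpin-shaped guide path, grown clash-aware from both
#' anchors, and closed by cyclic coordinate descent at the hairpin apex so
#' that the reconstructed chain meets the C-terminal anchor (the N, CA, C
#' atoms of the residue after the loop) to within `closure_tolerance` per
#' anchor atom; candidates with any non-bonded heavy-atom pair closer than
#' `clash_distance` (residues at least 2 apart in sequence, or different
#' chains) are rejected and resampled. Residues outside the loop are copied
#' verbatim. Each accepted conformation is scored with [pseudo_energy()].
#' Deterministic for a fixed `p$seed`.
#'
#' @param complex an `ecl2_structure`, typically from [build_toy_complex()].
#' @param loop data.frame(chain, start, end); defaults to the complex's
#'   remodelled segment metadata.
#' @param p an [loop_sampler_params()].
#' @return an `ecl2_ensemble` with an `attempt_stats` attribute (attempts,
#'   closure failures, clash rejections).
#' @export
sample_loop_ensemble <- function(complex, loop = NULL, p = loop_sampler_params()) {
  stopifnot(inherits(complex, "ecl2_structure"), inherits(p, "ecl2_sampler_params"))
  if (is.null(loop)) loop <- complex$metadata$remodelled_segments
  if (is.null(loop)) stop("no loop segment given and none recorded in metadata")
  loop <- loop[1L, , drop = FALSE]
  a <- complex$atoms
  in_loop <- a$chain == loop$chain & a$resno >= loop$start & a$resno <= loop$end
  fixed <- new_structure(a[!in_loop, , drop = FALSE], metadata = complex$metadata)
  loop_rows <- a[in_loop, , drop = FALSE]
  loop_resnos <- sort(unique(loop_rows$resno))
  loop_resids <- vapply(loop_resnos, function(r) loop_rows$resid[loop_rows$resno == r][1L], "")
  stats_env <- new.env()
  stats_env$attempts <- 0L
  stats_env$closure_failures <- 0L
  stats_env$clash_rejections <- 0L

  members <- withr::with_seed(p$seed, {
    lapply(seq_len(p$n_conformations), function(id) {
      loop_atoms <- sample_closed_clashfree_loop(
        fixed, loop$chain, loop$start, loop$end, loop_resids,
        p$closure_tolerance, p$clash_distance,
        p$max_attempts_per_conformation, p$max_ccd_iterations,
        stats_env = stats_env
      )
      if (is.null(loop_atoms)) {
        stop(sprintf(
          paste0("loop closure failed for conformation %d after %d attempts ",
                 "(total attempts %d, closure failures %d, clash rejections %d)"),
          id, p$max_attempts_per_conformation, stats_env$attempts,
          stats_env$closure_failures, stats_env$clash_rejections
        ))
      }
      s <- new_structure(rbind(fixed$atoms, loop_atoms),
                         metadata = complex$metadata)
      list(conformation_id = id, structure = s,
           score = pseudo_energy(s, loop = loop))
    })
  })
  e <- new_ensemble(members,
                    remodelled_segments = loop,
                    fixed_region_tolerance = 0.01)
  attr(e, "attempt_stats") <- list(
    attempts = stats_env$attempts,
    closure_failures = stats_env$closure_failures,
    clash_rejections = stats_env$clash_rejections
  )
  e
}

#' Surrogate conformation score
#'
#' A cheap stand-in for a statistical-potential score: a soft-sphere overlap
#' penalty `sum k*(r0 - d)^2` over non-bonded heavy-atom pairs closer than
#' `r0`, plus `0.1 *` the radius of gyration (Angstrom) of the loop's heavy
#' atoms. Lower is more probable. Depends only on internal distances, so it
#' is invariant to rigid-body motion of the whole complex.
#'
#' @param s an `ecl2_structure` with at least 2 residues.
#' @param loop data.frame(chain, start, end) naming the loop whose radius of
#'   gyration enters the score; defaults to the remodelled segment metadata,
#'   falling back to all heavy atoms.
#' @param r0 overlap onset distance, Angstrom (default 3.2).
#' @param k overlap force constant (default 10).
#' @return numeric score (dimensionless).
#' @export
pseudo_energy <- function(s, loop = NULL, r0 = 3.2, k = 10) {
  if (length(residue_keys(s)) < 2L) stop("pseudo_energy needs at least 2 residues")
  if (is.null(loop)) loop <- s$metadata$remodelled_segments
  h <- heavy_atoms(s)
  xyz <- as.matrix(h[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  nonbonded <- !(outer(h$chain, h$chain, "==") & abs(outer(h$resno, h$resno, "-")) <= 1L)
  sel <- upper.tri(d2) & nonbonded & d2 < r0^2
  overlap <- sum(k * (r0 - sqrt(d2[sel]))^2)
  if (!is.null(loop)) {
    lsel <- h$chain == loop$chain[1L] & h$resno >= loop$start[1L] & h$resno <= loop$end[1L]
    lxyz <- xyz[lsel, , drop = FALSE]
  } else lxyz <- xyz
  if (!nrow(lxyz)) lxyz <- xyz
  cen <- colMeans(lxyz)
  rg <- sqrt(mean(rowSums(sweep(lxyz, 2L, cen)^2)))
  overlap + 0.1 * rg
}
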