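# Contact analysis: residue-residue contacts at a fixed heavy-atom distance
# cutoff (5.5 Angstrom by default, the published cutoff), ensemble frequency
# aggregation, key-interaction counting, bridge detection and side-chain
# orientation classification.

residue_xyz_list <- function(s, keys) {
  h <- heavy_atoms(s)
  missing <- setdiff(keys, unique(h$key))
  if (length(missing)) {
    stop("selection references residue(s) absent from the structure: ",
         paste(missing, collapse = ", "))
  }
  lapply(keys, function(k) {
    sub <- h[h$key == k, , drop = FALSE]
    list(xyz = as.matrix(sub[, c("x", "y", "z")]), atom = sub$atom)
  })
}

#' Compute receptor-peptide residue contacts in one conformation
#'
#' A residue pair is in contact iff the minimum distance over all
#' heavy-atom pairs (backbone included, hydrogens ignored) is less than or
#' equal to `cutoff` - boundary inclusive. The minimum distance and the atom
#' pair realizing it are recorded.
#'
#' @param s an `ecl2_structure` (one conformation).
#' @param receptor_sel,peptide_sel character vectors of residue keys.
#' @param cutoff contact cutoff in Angstrom (default 5.5).
#' @return data.frame of class `ecl2_contacts` with columns `receptor`,
#'   `peptide`, `min_distance`, `rec_atom`, `pep_atom`; attribute `cutoff`.
#' @export
compute_contacts <- function(s, receptor_sel, peptide_sel, cutoff = 5.5) {
  if (!length(receptor_sel) || !length(peptide_sel)) stop("empty residue selection")
  if (cutoff <= 0) stop("cutoff must be positive")
  rl <- residue_xyz_list(s, receptor_sel)
  pl <- residue_xyz_list(s, peptide_sel)
  rows <- list()
  for (i in seq_along(rl)) {
    a <- rl[[i]]
    for (j in seq_along(pl)) {
      b <- pl[[j]]
      d2 <- outer(rowSums(a$xyz^2), rowSums(b$xyz^2), "+") - 2 * a$xyz %*% t(b$xyz)
      d2[d2 < 0] <- 0
      mi <- arrayInd(which.min(d2), dim(d2))
      dmin <- sqrt(d2[mi])
      if (dmin <= cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          receptor = receptor_sel[i], peptide = peptide_sel[j],
          min_distance = dmin,
          rec_atom = a$atom[mi[1L]], pep_atom = b$atom[mi[2L]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(receptor = character(), peptide = character(),
               min_distance = numeric(), rec_atom = character(),
               pep_atom = character(), stringsAsFactors = FALSE)
  structure(out, class = c("ecl2_contacts", "data.frame"), cutoff = cutoff)
}

#' Contact map over a whole ensemble
#'
#' Runs [compute_contacts()] for every conformation and stacks the results
#' with a `conformation_id` column.
#'
#' @param e an `ecl2_ensemble`.
#' @inheritParams compute_contacts
#' @return data.frame of class `ecl2_contact_map`; attributes `cutoff` and
#'   `ensemble_size`.
#' @export
compute_contact_map <- function(e, receptor_sel, peptide_sel, cutoff = 5.5) {
  stopifnot(inherits(e, "ecl2_ensemble"))
  maps <- lapply(e$members, function(m) {
    cc <- compute_contacts(m$structure, receptor_sel, peptide_sel, cutoff)
    if (nrow(cc)) cbind(conformation_id = m$conformation_id, as.data.frame(cc))
    else cbind(conformation_id = integer(0), as.data.frame(cc))
  })
  out <- do.call(rbind, maps)
  if (is.null(out)) {
    out <- data.frame(conformation_id = integer(), receptor = character(),
                      peptide = character(), min_distance = numeric(),
                      rec_atom = character(), pep_atom = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("ecl2_contact_map", "data.frame"),
            cutoff = cutoff, ensemble_size = length(e$members))
}

#' Count contacts made by key residues
#'
#' Number of contact pairs whose receptor residue belongs to the key set
#' (each receptor-peptide pair counts once, so one key residue touching
#' three peptide residues contributes three).
#'
#' @param pairs an `ecl2_contacts` data.frame (one conformation).
#' @param key character vector of key residue keys.
#' @return integer count.
#' @export
count_key_interactions <- function(pairs, key) {
  sum(pairs$receptor %in% key)
}

#' Aggregate ensemble interaction frequencies
#'
#' Counts, for every receptor-peptide residue pair, the number of
#' conformations in which the pair is in contact. Pairs seen in fewer than
#' `min_count` conformations are omitted (the published display prune uses
#' 10 of 100 structures).
#'
#' @param cm an `ecl2_contact_map`.
#' @param min_count prune threshold (default 0 = keep everything).
#' @return data.frame of class `ecl2_freq_table` with columns `receptor`,
#'   `peptide`, `count`; attributes `ensemble_size`, `min_count`.
#' @export
frequency_table <- function(cm, min_count = 0L) {
  stopifnot(inherits(cm, "ecl2_contact_map"))
  df <- as.data.frame(cm)
  if (nrow(df)) {
    key <- paste(df$receptor, df$peptide, sep = "|")
    # one count per conformation per pair even if duplicated
    uk <- !duplicated(paste(key, df$conformation_id))
    tab <- table(key[uk])
    parts <- strsplit(names(tab), "|", fixed = TRUE)
    out <- data.frame(
      receptor = vapply(parts, `[`, "", 1L),
      peptide = vapply(parts, `[`, "", 2L),
      count = as.integer(tab), stringsAsFactors = FALSE
    )
    out <- out[out$count >= min_count, , drop = FALSE]
    out <- sort_contact_rows(out)
  } else {
    out <- data.frame(receptor = character(), peptide = character(),
                      count = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("ecl2_freq_table", "data.frame"),
            ensemble_size = attr(cm, "ensemble_size"),
            min_count = as.integer(min_count))
}

#' Detect bridging residues between two non-contacting residues
#'
#' A candidate bridges `a` and `b` when it lies within `cutoff` of both
#' while `a` and `b` themselves are NOT within `cutoff` of each other (if
#' they are in direct contact there is nothing to bridge and the result is
#' empty). Results are sorted by the larger of the two distances, closest
#' bridges first.
#'
#' @param s an `ecl2_structure`.
#' @param a,b residue keys of the two endpoint residues.
#' @param candidates character vector of candidate residue keys.
#' @param cutoff Angstrom (default 5.5).
#' @return data.frame with columns `candidate`, `dist_a`, `dist_b` (possibly
#'   empty).
#' @export
detect_bridges <- function(s, a, b, candidates, cutoff = 5.5) {
  empty <- data.frame(candidate = character(), dist_a = numeric(),
                      dist_b = numeric(), stringsAsFactors = FALSE)
  if (min_residue_distance(s, a, b) <= cutoff) return(empty)
  if (!length(candidates)) return(empty)
  da <- vapply(candidates, function(k) min_residue_distance(s, k, a), 0)
  db <- vapply(candidates, function(k) min_residue_distance(s, k, b), 0)
  keep <- da <= cutoff & db <= cutoff
  out <- data.frame(candidate = candidates[keep], dist_a = da[keep],
                    dist_b = db[keep], stringsAsFactors = FALSE)
  out <- out[order(pmax(out$dist_a, out$dist_b)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify side-chain orientation relative to the bundle axis
#'
#' The orientation angle is `acos(|v . axis|)` in degrees, where `v` is the
#' unit vector from CA to the side-chain heavy-atom centroid (pseudo-atom
#' CEN included; N, CA, C, O, OXT excluded). Angles below `threshold`
#' degrees are labelled "vertical", otherwise "horizontal". The bundle axis
#' defaults to +z: structures are expected to be oriented with the
#' extracellular face at +z.
#'
#' @param s an `ecl2_structure`.
#' @param r residue key.
#' @param bundle_axis 3-vector (default c(0,0,1)); normalized internally.
#' @param threshold vertical/horizontal boundary in degrees (default 45).
#' @return list with `label` ("vertical"/"horizontal") and `angle_deg` in
#'   `[0, 90]`.
#' @export
classify_side_chain_orientation <- function(s, r, bundle_axis = c(0, 0, 1),
                                            threshold = 45) {
  h <- heavy_atoms(s)
  sub <- h[h$key == r, , drop = FALSE]
  if (!nrow(sub)) stop("residue not found in structure: ", r)
  ca <- sub[sub$atom == "CA", c("x", "y", "z"), drop = FALSE]
  if (nrow(ca) != 1L) stop("residue ", r, " lacks a CA atom")
  side <- sub[!(sub$atom %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
  if (!nrow(side)) {
    stop("residue ", r, " has no side-chain atoms: orientation undefined (glycine?)")
  }
  cen <- colMeans(side[, c("x", "y", "z")])
  v <- vunit(as.numeric(cen) - as.numeric(ca))
  ax <- vunit(bundle_axis)
  angle <- acos(pmin(1, abs(sum(v * ax)))) / DEG
  list(label = if (angle < threshold) "vertical" else "horizontal",
       angle_deg = angle)
}

#' Mandatory-partner labels per conformation
#'
#' For scatter-style reporting (interaction count vs score, coloured by
#' which allowed partner contacts the probe peptide residue): returns, per
#' conformation, which of the allowed receptor partners contact
#' `peptide_key` - a single residue number, `"both"`/`"multi"` when more
#' than one does, or `"none"`.
#'
#' @param cm an `ecl2_contact_map`.
#' @param peptide_key probe peptide residue key (e.g. `"P:6:"`).
#' @param partners character vector of allowed receptor partner keys.
#' @return data.frame(conformation_id, partner_label).
#' @export
partner_labels <- function(cm, peptide_key, partners) {
  ids <- sort(unique(as.data.frame(cm)$conformation_id))
  if (!is.null(attr(cm, "ensemble_size"))) {
    # conformations with no contacts at all still get a row
    ids <- sort(unique(c(ids, seq_len(attr(cm, "ensemble_size")))))
  }
  df <- as.data.frame(cm)
  lab <- vapply(ids, function(id) {
    hit <- df$receptor[df$conformation_id == id & df$peptide == peptide_key &
                         df$receptor %in% partners]
    hit <- unique(hit)
    if (!length(hit)) "none"
    else if (length(hit) == 1L) as.character(parse_res_key(hit)$resno)
    else if (length(hit) == 2L) "both"
    else "multi"
  }, "")
  data.frame(conformation_id = ids, partner_label = lab, stringsAsFactors = FALSE)
}
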