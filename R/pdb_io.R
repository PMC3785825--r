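# PDB reading/writing (fixed-column ATOM/HETATM/MODEL/ENDMDL subset) and
# ensemble assembly. Only the record types needed for conformational
# ensembles are handled; mmCIF is out of scope.

pdb_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
  }
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  if (!nzchar(nm)) stop("cannot infer element from atom name '", atom_name, "'")
  first <- toupper(substr(nm, 1L, 1L))
  # names like 1HB / HG21 are hydrogens; two-letter elements are rare in
  # protein models and not produced by this package
  if (grepl("^[0-9]", atom_name) || first == "H") "H" else first
}

parse_pdb_atoms <- function(lines, skip_water = TRUE) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1L, 4L) == "ATOM" |
    substr(lines, 1L, 6L) == "HETATM"
  idx <- which(is_atom)
  if (!length(idx)) {
    return(data.frame(chain = character(), resno = integer(), ins = character(),
                      resid = character(), atom = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      occ = numeric(), altloc = character(),
                      het = logical(), line = integer(), stringsAsFactors = FALSE))
  }
  ln <- lines[idx]
  bad <- nchar(ln) < 54L
  if (any(bad)) {
    stop("malformed ATOM/HETATM record (too short) at line ", idx[which(bad)[1L]])
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(ln, 31L, 38L)); y <- num(substr(ln, 39L, 46L)); z <- num(substr(ln, 47L, 54L))
  badc <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  if (any(badc)) {
    stop("malformed ATOM/HETATM coordinates at line ", idx[which(badc)[1L]])
  }
  resno <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
  badr <- is.na(resno)
  if (any(badr)) stop("malformed residue number at line ", idx[which(badr)[1L]])
  occ <- num(substr(ln, 55L, 60L))
  occ[!is.finite(occ)] <- 1.0
  el <- trimws(substr(ln, 77L, 78L))
  atom <- trimws(substr(ln, 13L, 16L))
  noel <- !nzchar(el)
  if (any(noel)) el[noel] <- vapply(atom[noel], infer_element, "")
  out <- data.frame(
    chain = trimws(substr(ln, 22L, 22L)),
    resno = resno,
    ins = trimws(substr(ln, 27L, 27L)),
    resid = trimws(substr(ln, 18L, 20L)),
    atom = atom,
    element = el,
    x = x, y = y, z = z,
    occ = occ,
    altloc = trimws(substr(ln, 17L, 17L)),
    het = startsWith(ln, "HETATM"),
    line = idx,
    stringsAsFactors = FALSE
  )
  if (skip_water) out <- out[!(out$het & out$resid %in% WATER_RESNAMES), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Keep one altloc per (residue, atom name): highest occupancy, ties resolved
# in favour of the first encountered.
resolve_altlocs <- function(atoms) {
  if (!nrow(atoms) || all(atoms$altloc == "")) return(atoms)
  id <- paste(atom_keys(atoms), atoms$atom, sep = "|")
  ord <- order(id, -atoms$occ, seq_len(nrow(atoms)))
  keep <- ord[!duplicated(id[ord])]
  out <- atoms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

split_models <- function(lines) {
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) return(list(lines))
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) < length(model_starts)) model_ends <- c(model_ends, length(lines))
  ids <- suppressWarnings(as.integer(substr(lines[model_starts], 11L, 14L)))
  ids[is.na(ids)] <- seq_along(model_starts)
  out <- vector("list", length(model_starts))
  for (i in seq_along(model_starts)) {
    out[[i]] <- lines[(model_starts[i] + 1L):(model_ends[i] - 1L)]
  }
  names(out) <- ids
  out
}

#' Read a structure from PDB-format text
#'
#' Parses ATOM/HETATM records by fixed columns. HETATM waters are skipped by
#' default; for duplicated alternate locations only the highest-occupancy
#' altloc is kept (ties go to the first encountered). If the text contains
#' multiple MODEL blocks, only the first model is read (use
#' [read_ensemble()] for multi-model files). Elements missing from columns
#' 77-78 are inferred from the atom name; hydrogens are retained in the atom
#' table but ignored by all distance computations.
#'
#' @param source a file path, a single string of PDB text, or a character
#'   vector of lines.
#' @param skip_water drop HETATM water records (default TRUE).
#' @return an `ecl2_structure`.
#' @export
read_structure <- function(source, skip_water = TRUE) {
  lines <- pdb_lines(source)
  models <- split_models(lines)
  atoms <- resolve_altlocs(parse_pdb_atoms(models[[1L]], skip_water = skip_water))
  if (!nrow(atoms)) stop("no ATOM records found: empty structure")
  atoms$het <- NULL
  atoms$line <- NULL
  new_structure(atoms)
}

#' Read a conformational ensemble
#'
#' Accepts either one multi-model PDB file (MODEL/ENDMDL blocks; the MODEL
#' serial numbers are the conformation ids) or an ordered vector of
#' single-model PDB paths with explicit `conformation_ids` (a manifest).
#' Every conformation must carry a score in `scores` and all members must
#' share an identical residue-key set; coordinates outside
#' `remodelled_segments` are additionally required to agree across members
#' within `fixed_region_tolerance` (per-residue heavy-atom RMSD).
#'
#' @param source path to a multi-model PDB, multi-model PDB text, or a
#'   character vector of file paths.
#' @param scores data.frame with columns `conformation_id`, `score` (lower =
#'   more probable), or path to a 2-column TSV.
#' @param conformation_ids integer ids for file-list input; defaults to
#'   1..n_files.
#' @param remodelled_segments optional data.frame(chain, start, end) of
#'   remodelled residue ranges.
#' @param fixed_region_tolerance Angstrom tolerance for the fixed-region
#'   agreement check (default 0.01).
#' @return an `ecl2_ensemble`.
#' @export
read_ensemble <- function(source, scores, conformation_ids = NULL,
                          remodelled_segments = NULL,
                          fixed_region_tolerance = 0.01) {
  if (is.character(scores) && length(scores) == 1L && file.exists(scores)) {
    scores <- read_scores_tsv(scores)
  }
  stopifnot(is.data.frame(scores), all(c("conformation_id", "score") %in% names(scores)))
  is_paths <- is.character(source) && length(source) >= 1L &&
    all(!grepl("\n", source, fixed = TRUE)) && all(file.exists(source)) &&
    length(source) > 1L
  if (is_paths || (length(source) == 1L && file.exists(source) &&
                   !any(startsWith(readLines(source, n = 50L, warn = FALSE), "MODEL")) &&
                   !is.null(conformation_ids))) {
    files <- source
    ids <- if (is.null(conformation_ids)) seq_along(files) else as.integer(conformation_ids)
    if (length(ids) != length(files)) stop("conformation_ids must match the number of files")
    structs <- lapply(files, read_structure)
  } else {
    lines <- pdb_lines(source)
    models <- split_models(lines)
    ids <- if (!is.null(conformation_ids)) as.integer(conformation_ids) else
      as.integer(names(models) %||% seq_along(models))
    if (is.null(names(models)) && is.null(conformation_ids)) ids <- seq_along(models)
    structs <- lapply(models, function(m) {
      atoms <- resolve_altlocs(parse_pdb_atoms(m))
      if (!nrow(atoms)) stop("no ATOM records found in a model: empty structure")
      atoms$het <- NULL
      atoms$line <- NULL
      new_structure(atoms)
    })
  }
  missing_scores <- setdiff(ids, scores$conformation_id)
  if (length(missing_scores)) {
    stop("missing score for conformation id(s): ", paste(missing_scores, collapse = ", "))
  }
  members <- Map(function(id, s) {
    list(conformation_id = id, structure = s,
         score = scores$score[match(id, scores$conformation_id)])
  }, ids, structs)
  members <- members[order(vapply(members, `[[`, 0L, "conformation_id"))]
  new_ensemble(members, remodelled_segments = remodelled_segments,
               fixed_region_tolerance = fixed_region_tolerance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an ensemble from conformation records
#'
#' Verifies the topology invariant (identical residue-key sets across
#' members) and, when remodelled segments are given, that residues outside
#' them agree across members within the tolerance.
#'
#' @param members list of `list(conformation_id, structure, score)`.
#' @param remodelled_segments data.frame(chain, start, end) or NULL.
#' @param fixed_region_tolerance per-residue heavy-atom RMSD tolerance, Angstrom.
#' @return an `ecl2_ensemble`.
#' @export
new_ensemble <- function(members, remodelled_segments = NULL,
                         fixed_region_tolerance = 0.01) {
  if (length(members)) {
    scores <- vapply(members, `[[`, 0, "score")
    if (!all(is.finite(scores))) stop("non-finite conformation score")
    keys <- lapply(members, function(m) residue_keys(m$structure))
    ref <- keys[[1L]]
    for (i in seq_along(keys)) {
      if (!identical(sort(keys[[i]]), sort(ref))) {
        off <- c(setdiff(ref, keys[[i]]), setdiff(keys[[i]], ref))
        stop("ensemble topology mismatch at conformation ",
             members[[i]]$conformation_id, "; offending residues: ",
             paste(off, collapse = ", "))
      }
    }
  }
  e <- structure(list(members = members,
                      remodelled_segments = remodelled_segments,
                      fixed_region_tolerance = fixed_region_tolerance),
                 class = "ecl2_ensemble")
  if (!is.null(remodelled_segments) && length(members) > 1L) {
    check_fixed_region(e)
  }
  e
}

in_segments <- function(atoms, segments) {
  hit <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(segments))) {
    hit <- hit | (atoms$chain == segments$chain[i] &
                    atoms$resno >= segments$start[i] &
                    atoms$resno <= segments$end[i])
  }
  hit
}

check_fixed_region <- function(e) {
  segs <- e$remodelled_segments
  tol <- e$fixed_region_tolerance
  ref <- e$members[[1L]]$structure$atoms
  fixed_ref <- ref[!in_segments(ref, segs) & is_heavy(ref$element), , drop = FALSE]
  ord <- order(atom_keys(fixed_ref), fixed_ref$atom)
  fixed_ref <- fixed_ref[ord, , drop = FALSE]
  for (m in e$members[-1L]) {
    a <- m$structure$atoms
    fa <- a[!in_segments(a, segs) & is_heavy(a$element), , drop = FALSE]
    fa <- fa[order(atom_keys(fa), fa$atom), , drop = FALSE]
    if (nrow(fa) != nrow(fixed_ref)) {
      stop("fixed-region atom mismatch at conformation ", m$conformation_id)
    }
    d2 <- (fa$x - fixed_ref$x)^2 + (fa$y - fixed_ref$y)^2 + (fa$z - fixed_ref$z)^2
    rms <- tapply(d2, atom_keys(fa), function(v) sqrt(mean(v)))
    if (any(rms > tol)) {
      stop("fixed-region drift above tolerance at conformation ",
           m$conformation_id, ": ",
           paste(names(rms)[rms > tol], collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.ecl2_ensemble <- function(x, ...) {
  cat(sprintf("<ecl2_ensemble> %d conformations\n", length(x$members)))
  invisible(x)
}

#' @rdname read_ensemble
#' @param e an `ecl2_ensemble`.
#' @return `ensemble_scores()`: data.frame(conformation_id, score).
#' @export
ensemble_scores <- function(e) {
  data.frame(
    conformation_id = vapply(e$members, `[[`, 0L, "conformation_id"),
    score = vapply(e$members, `[[`, 0, "score")
  )
}

format_pdb_atom <- function(a, serial) {
  el <- toupper(a$element)
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial,
          if (nchar(a$atom) >= 4L) a$atom else paste0(" ", a$atom),
          substr(a$altloc, 1L, 1L),
          a$resid, a$chain, a$resno, substr(a$ins, 1L, 1L),
          a$x, a$y, a$z, a$occ, 0, el)
}

structure_pdb_lines <- function(s) {
  a <- s$atoms
  vapply(seq_len(nrow(a)), function(i) format_pdb_atom(a[i, ], i), "")
}

#' Write structures and ensembles as PDB
#'
#' Ensembles are written as multi-model files (MODEL n = conformation id);
#' scores are written separately with [write_scores_tsv()].
#'
#' @param x an `ecl2_structure` or `ecl2_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "ecl2_structure")) {
    lines <- c(structure_pdb_lines(x), "END")
  } else if (inherits(x, "ecl2_ensemble")) {
    lines <- unlist(lapply(x$members, function(m) {
      c(sprintf("MODEL     %4d", m$conformation_id),
        structure_pdb_lines(m$structure),
        "ENDMDL")
    }))
    lines <- c(lines, "END")
  } else stop("write_pdb handles ecl2_structure / ecl2_ensemble objects")
  writeLines(lines, path)
  invisible(path)
}

#' Score-table TSV I/O
#'
#' Two-column tab-separated table `conformation_id<TAB>score` with a
#' `#`-prefixed header.
#'
#' @param scores data.frame(conformation_id, score) or an `ecl2_ensemble`.
#' @param path file path.
#' @return `read_scores_tsv()`: data.frame(conformation_id, score).
#' @export
write_scores_tsv <- function(scores, path) {
  if (inherits(scores, "ecl2_ensemble")) scores <- ensemble_scores(scores)
  write_tsv_impl(scores[, c("conformation_id", "score")], path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  df <- read_tsv_impl(path)
  df$conformation_id <- as.integer(df$conformation_id)
  df$score <- as.numeric(df$score)
  df
}
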