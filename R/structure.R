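#' Structure objects
#'
#' A structure is a flat atom table plus free-form metadata. Atoms are grouped
#' into residues by the key (chain, author residue number, insertion code);
#' author (PDB) numbering is used throughout, matching published residue
#' labels (e.g. the scanned receptor loop 271-294, peptide 1-37).
#'
#' @param atoms data.frame with columns `chain`, `resno`, `ins`, `resid`
#'   (3-letter code), `atom` (atom name), `element`, `x`, `y`, `z`, `occ`,
#'   `altloc`.
#' @param metadata named list of free-form annotations.
#' @return An object of class `ecl2_structure`.
#' @export
new_structure <- function(atoms, metadata = list()) {
  req <- c("chain", "resno", "ins", "resid", "atom", "element",
           "x", "y", "z", "occ", "altloc")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "ecl2_structure")
}

#' Residue key strings
#'
#' Residues are addressed as `"chain:resno:ins"` strings (insertion code
#' usually empty, giving keys like `"R:274:"`).
#'
#' @param chain chain identifier(s).
#' @param resno author residue number(s).
#' @param ins insertion code(s), default empty.
#' @return character vector of keys.
#' @export
res_key <- function(chain, resno, ins = "") {
  if (!length(resno)) return(character(0))
  paste(chain, resno, ins, sep = ":")
}

#' @rdname res_key
#' @param key character vector of keys to split.
#' @return `parse_res_key()`: data.frame with columns chain, resno, ins.
#' @export
parse_res_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, `[`, "", 1L),
    resno = as.integer(vapply(parts, `[`, "", 2L)),
    ins = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

atom_keys <- function(atoms) res_key(atoms$chain, atoms$resno, atoms$ins)

#' @export
print.ecl2_structure <- function(x, ...) {
  k <- unique(atom_keys(x$atoms))
  cat(sprintf("<ecl2_structure> %d residues, %d atoms, chains: %s\n",
              length(k), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Residue keys of a structure, in atom-table order
#' @param s an `ecl2_structure`.
#' @return character vector of unique residue keys.
#' @export
residue_keys <- function(s) unique(atom_keys(s$atoms))

is_heavy <- function(element) !(toupper(element) %in% c("H", "D"))

# Heavy-atom subtable, with residue keys attached.
heavy_atoms <- function(s) {
  a <- s$atoms[is_heavy(s$atoms$element), , drop = FALSE]
  a$key <- atom_keys(a)
  a
}

#' Select residues of one chain by an author-numbered range
#'
#' The range is inclusive at both ends, so `"271-294"` selects 24 residues
#' when all of 271..294 are present. Residues absent from the structure are
#' simply not returned; a chain with no residue in range gives an empty
#' vector.
#'
#' @param s an `ecl2_structure`.
#' @param chain_id chain identifier.
#' @param range_spec string `"start-end"` in author numbering.
#' @return character vector of residue keys in sequence order.
#' @export
select_residues <- function(s, chain_id, range_spec) {
  m <- regmatches(range_spec, regexec("^\\s*(-?\\d+)\\s*-\\s*(-?\\d+)\\s*$", range_spec))[[1L]]
  if (length(m) != 3L) stop("range_spec must look like 'start-end', got: ", range_spec)
  start <- as.integer(m[2L]); end <- as.integer(m[3L])
  if (start > end) stop("range start (", start, ") exceeds end (", end, ")")
  a <- s$atoms
  sel <- a$chain == chain_id & a$resno >= start & a$resno <= end
  hits <- a[sel, , drop = FALSE]
  hits <- hits[order(hits$resno, hits$ins), , drop = FALSE]
  unique(atom_keys(hits))
}

# Minimum heavy-atom distance between two residues (by key).
min_residue_distance <- function(s, key1, key2) {
  h <- heavy_atoms(s)
  a <- h[h$key == key1, c("x", "y", "z"), drop = FALSE]
  b <- h[h$key == key2, c("x", "y", "z"), drop = FALSE]
  if (!nrow(a)) stop("residue not found in structure: ", key1)
  if (!nrow(b)) stop("residue not found in structure: ", key2)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * as.matrix(a) %*% t(as.matrix(b))
  sqrt(max(0, min(d2)))
}

#' Find non-bonded heavy-atom clashes
#'
#' Exhaustive O(N^2) scan over heavy-atom pairs from residues that are
#' non-bonded: different chains, or at least 2 apart in author numbering on
#' the same chain. Pairs closer than `clash_distance` are reported.
#'
#' @param s an `ecl2_structure`.
#' @param clash_distance distance threshold in Angstrom (default 2.5).
#' @return data.frame of clashing pairs (possibly empty) with the two atom
#'   indices, residue keys and the distance.
#' @export
find_clashes <- function(s, clash_distance = 2.5) {
  h <- heavy_atoms(s)
  n <- nrow(h)
  empty <- data.frame(key1 = character(), key2 = character(),
                      atom1 = character(), atom2 = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  xyz <- as.matrix(h[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  d2[d2 < 0] <- 0
  same_chain <- outer(h$chain, h$chain, "==")
  near_seq <- abs(outer(h$resno, h$resno, "-")) <= 1L
  bonded <- same_chain & near_seq
  hit <- which(upper.tri(d2) & !bonded & d2 < clash_distance^2, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  data.frame(
    key1 = h$key[hit[, 1L]], key2 = h$key[hit[, 2L]],
    atom1 = h$atom[hit[, 1L]], atom2 = h$atom[hit[, 2L]],
    distance = sqrt(d2[hit]), stringsAsFactors = FALSE
  )
}
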