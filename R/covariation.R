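# Paired-system sequence analysis: per-column conservation, the
# conserved + H-bond-capable candidate filter for the probe peptide
# residue's receptor partners, and a correlated-substitution screen between
# two receptor-peptide systems (e.g. the CGRP-receptor system against the
# calcitonin-receptor/amylin system).

aln_alphabet <- function() c(names(AA_1TO3), "-")

#' Alignment objects
#'
#' A multi-species alignment is a named character vector of equal-length
#' gapped sequences (20 amino-acid letters plus "-").
#'
#' @param sequences named character vector of aligned sequences.
#' @return object of class `ecl2_alignment` with elements `sequences`,
#'   `n_col`, and `mat` (a rows x columns character matrix).
#' @export
new_alignment <- function(sequences) {
  if (length(sequences) < 2L) stop("an alignment needs at least 2 sequences")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(widths), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  bad <- which(!(mat %in% aln_alphabet()))
  if (length(bad)) {
    pos <- arrayInd(bad[1L], dim(mat))
    stop("illegal character '", mat[bad[1L]], "' in sequence '",
         names(sequences)[pos[1L]] %||% pos[1L], "' at column ", pos[2L])
  }
  rownames(mat) <- names(sequences)
  structure(list(sequences = sequences, n_col = unique(widths), mat = mat),
            class = "ecl2_alignment")
}

#' Read an aligned FASTA file
#'
#' Sequences are read with \code{Biostrings::readAAStringSet}; the
#' equal-length and alphabet checks of [new_alignment()] are then enforced.
#'
#' @param path aligned FASTA file.
#' @return an `ecl2_alignment`.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  new_alignment(stats::setNames(as.character(set), names(set)))
}

#' @rdname read_alignment
#' @param a an `ecl2_alignment` to write.
#' @export
write_alignment <- function(a, path) {
  set <- Biostrings::AAStringSet(a$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.ecl2_alignment <- function(x, ...) {
  cat(sprintf("<ecl2_alignment> %d sequences x %d columns\n",
              length(x$sequences), x$n_col))
  invisible(x)
}

column_chars <- function(a, col) {
  if (col < 1L || col > a$n_col) stop("column ", col, " out of range 1..", a$n_col)
  a$mat[, col]
}

#' Per-column conservation
#'
#' Fraction of non-gap rows carrying the modal (most frequent) residue;
#' gaps are excluded from the denominator and an all-gap column scores 0.
#' Modal ties are broken alphabetically for determinism.
#'
#' @param a an `ecl2_alignment`.
#' @param col 1-based column index.
#' @return fraction in `[0, 1]`.
#' @export
column_conservation <- function(a, col) {
  ch <- column_chars(a, col)
  ch <- ch[ch != "-"]
  if (!length(ch)) return(0)
  max(table(ch)) / length(ch)
}

#' @rdname column_conservation
#' @return `modal_residue()`: the modal non-gap residue (alphabetical on
#'   ties), or NA for an all-gap column.
#' @export
modal_residue <- function(a, col) {
  ch <- column_chars(a, col)
  ch <- ch[ch != "-"]
  if (!length(ch)) return(NA_character_)
  tab <- table(ch)
  names(tab)[which.max(tab)]  # table() is alphabetical; which.max takes the first
}

gap_fraction <- function(a, col) mean(column_chars(a, col) == "-")

HBOND_CAPABLE <- c("S", "T", "Y", "N", "Q", "D", "E", "H", "K", "R", "W", "C")

#' Side-chain hydrogen-bond capability
#'
#' TRUE iff the residue's side chain can donate or accept a hydrogen bond.
#' The set used is S, T, Y, N, Q, D, E, H, K, R plus the weak donors W and
#' C (inclusive reading; the constant `HBOND_CAPABLE` is exported for
#' reconfiguration).
#'
#' @param residue 1-letter amino-acid code(s).
#' @return logical vector.
#' @export
hbond_capable <- function(residue) {
  residue <- toupper(residue)
  bad <- !(residue %in% names(AA_1TO3))
  if (any(bad)) stop("invalid residue code(s): ", paste(residue[bad], collapse = ", "))
  residue %in% HBOND_CAPABLE
}

#' Conserved, H-bond-capable partner candidates
#'
#' Receptor columns (within `segment`, in system-1 coordinates) where both
#' systems are conserved at `min_conservation` or better, the modal
#' residues agree across systems, and that residue can form a side-chain
#' hydrogen bond. This is the filter that, applied to the loop segment,
#' singles out the published D/D/T candidate partners for the probe peptide
#' threonine.
#'
#' @param rec1,rec2 `ecl2_alignment`s of the two receptor systems.
#' @param column_map data.frame(col1, col2) mapping system-1 columns to
#'   system-2 columns (injective).
#' @param segment integer vector of system-1 columns to screen.
#' @param min_conservation conservation threshold (default 0.9).
#' @param max_gap_fraction skip columns gappier than this in either system
#'   (default 0.5).
#' @return data.frame(col1, col2, residue, cons1, cons2).
#' @export
conserved_hbond_candidates <- function(rec1, rec2, column_map, segment,
                                       min_conservation = 0.9,
                                       max_gap_fraction = 0.5) {
  if (anyDuplicated(column_map$col1) || anyDuplicated(column_map$col2)) {
    stop("column_map must be injective")
  }
  rows <- list()
  for (c1 in intersect(segment, column_map$col1)) {
    c2 <- column_map$col2[match(c1, column_map$col1)]
    if (gap_fraction(rec1, c1) > max_gap_fraction) next
    if (gap_fraction(rec2, c2) > max_gap_fraction) next
    m1 <- modal_residue(rec1, c1); m2 <- modal_residue(rec2, c2)
    if (is.na(m1) || is.na(m2) || m1 != m2) next
    k1 <- column_conservation(rec1, c1); k2 <- column_conservation(rec2, c2)
    if (k1 < min_conservation || k2 < min_conservation) next
    if (!hbond_capable(m1)) next
    rows[[length(rows) + 1L]] <- data.frame(col1 = c1, col2 = c2, residue = m1,
                                            cons1 = k1, cons2 = k2,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(col1 = integer(), col2 = integer(), residue = character(),
                      cons1 = numeric(), cons2 = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlated-substitution screen between two receptor-peptide systems
#'
#' For every mapped receptor-column pair crossed with every mapped
#' peptide-column pair: a hit requires the inter-system modal residues to
#' differ at BOTH the receptor and the peptide column, with all four
#' intra-system conservations at `min_conservation` or better. The
#' composite score is the product of the four conservation fractions (so a
#' perfectly conserved complementary swap scores 1.0); hits are ranked by
#' score descending, ties broken by (receptor column, peptide column)
#' ascending. Columns gappier than `max_gap_fraction` in any alignment are
#' skipped; gaps never count as modal residues.
#'
#' @param p list with alignments `receptor_sys1`, `receptor_sys2`,
#'   `peptide_sys1`, `peptide_sys2` and maps `receptor_map`, `peptide_map`
#'   (data.frames col1, col2), e.g. from [make_toy_paired_alignments()].
#' @param min_conservation threshold on all four conservations (default 0.8).
#' @param max_gap_fraction gap-column skip threshold (default 0.5).
#' @return data.frame of hits: receptor_col1, receptor_col2, peptide_col1,
#'   peptide_col2, the four conservations, the modal residues and `score`.
#' @export
correlated_pairs <- function(p, min_conservation = 0.8, max_gap_fraction = 0.5) {
  if (!nrow(p$receptor_map) || !nrow(p$peptide_map)) stop("empty column map")
  col_info <- function(a1, a2, map) {
    keep <- logical(nrow(map))
    info <- vector("list", nrow(map))
    for (i in seq_len(nrow(map))) {
      c1 <- map$col1[i]; c2 <- map$col2[i]
      if (gap_fraction(a1, c1) > max_gap_fraction ||
          gap_fraction(a2, c2) > max_gap_fraction) next
      m1 <- modal_residue(a1, c1); m2 <- modal_residue(a2, c2)
      if (is.na(m1) || is.na(m2)) next
      keep[i] <- TRUE
      info[[i]] <- list(c1 = c1, c2 = c2, m1 = m1, m2 = m2,
                        k1 = column_conservation(a1, c1),
                        k2 = column_conservation(a2, c2))
    }
    info[keep]
  }
  rec <- col_info(p$receptor_sys1, p$receptor_sys2, p$receptor_map)
  pep <- col_info(p$peptide_sys1, p$peptide_sys2, p$peptide_map)
  rows <- list()
  for (r in rec) {
    if (r$m1 == r$m2) next                      # receptor difference flag
    if (r$k1 < min_conservation || r$k2 < min_conservation) next
    for (q in pep) {
      if (q$m1 == q$m2) next                    # peptide difference flag
      if (q$k1 < min_conservation || q$k2 < min_conservation) next
      rows[[length(rows) + 1L]] <- data.frame(
        receptor_col1 = r$c1, receptor_col2 = r$c2,
        peptide_col1 = q$c1, peptide_col2 = q$c2,
        receptor_res1 = r$m1, receptor_res2 = r$m2,
        peptide_res1 = q$m1, peptide_res2 = q$m2,
        cons_receptor1 = r$k1, cons_receptor2 = r$k2,
        cons_peptide1 = q$k1, cons_peptide2 = q$k2,
        score = r$k1 * r$k2 * q$k1 * q$k2,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(receptor_col1 = integer(), receptor_col2 = integer(),
                      peptide_col1 = integer(), peptide_col2 = integer(),
                      receptor_res1 = character(), receptor_res2 = character(),
                      peptide_res1 = character(), peptide_res2 = character(),
                      cons_receptor1 = numeric(), cons_receptor2 = numeric(),
                      cons_peptide1 = numeric(), cons_peptide2 = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$receptor_col1, out$peptide_col1), , drop = FALSE]
  rownames(out) <- NULL
  out
}
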