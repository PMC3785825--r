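# Conformation selection: encodes the heuristic used to pick loop
# conformations consistent with the mutagenesis - a mandatory
# peptide-partner contact, a minimum number of key-residue interactions, a
# score percentile bound, and an optional side-chain orientation
# requirement. Verdicts are reported for every member, never just the
# survivors.

#' Selection criteria
#'
#' Defaults mirror the published heuristic: the probe peptide residue
#' (T6-like, key `"P:6:"`) must contact one of the allowed receptor
#' partners (D280/D287/T288-like, keys 280/287/288), at least one key
#' interaction must be present, and no score bound is applied unless asked
#' for (`score_percentile_max = 0.15` reproduces the top-15% energy
#' argument). The orientation requirement (vertical tryptophan, residue
#' 283) is optional and off by default.
#'
#' @param mandatory_contacts list of `list(peptide = key, partners = keys)`;
#'   every element must be realized for a conformation to pass.
#' @param min_key_interactions minimum key-interaction count (default 1).
#' @param score_percentile_max keep conformations with score percentile at
#'   or below this fraction (default 1.0 = no pruning).
#' @param orientation_requirements optional list of
#'   `list(residue = key, label = "vertical"/"horizontal")`.
#' @return list of class `ecl2_criteria`.
#' @export
selection_criteria <- function(
    mandatory_contacts = list(list(peptide = "P:6:",
                                   partners = c("R:280:", "R:287:", "R:288:"))),
    min_key_interactions = 1L,
    score_percentile_max = 1.0,
    orientation_requirements = NULL) {
  if (!(score_percentile_max > 0 && score_percentile_max <= 1)) {
    stop("score_percentile_max must be in (0, 1]")
  }
  for (mc in mandatory_contacts) {
    if (!length(mc$partners)) stop("mandatory contact with empty partner set")
  }
  structure(list(mandatory_contacts = mandatory_contacts,
                 min_key_interactions = as.integer(min_key_interactions),
                 score_percentile_max = score_percentile_max,
                 orientation_requirements = orientation_requirements),
            class = "ecl2_criteria")
}

#' Percentile ranks of ensemble scores
#'
#' Percentile = rank/N with rank 1 the lowest (best) score; ties are broken
#' by conformation id ascending, so ranks are a permutation and exactly
#' `floor(N * p)` conformations satisfy `percentile <= p` for p a multiple
#' of 1/N.
#'
#' @param e an `ecl2_ensemble`.
#' @return data.frame(conformation_id, score, rank, percentile).
#' @export
rank_by_score <- function(e) {
  stopifnot(inherits(e, "ecl2_ensemble"), length(e$members) >= 1L)
  sc <- ensemble_scores(e)
  ord <- order(sc$score, sc$conformation_id)
  rank <- integer(nrow(sc))
  rank[ord] <- seq_len(nrow(sc))
  data.frame(conformation_id = sc$conformation_id, score = sc$score,
             rank = rank, percentile = rank / nrow(sc))
}

#' Apply selection criteria over an ensemble
#'
#' A conformation is selected iff (i) every mandatory contact is realized -
#' the probe peptide residue contacts at least one allowed partner; (ii) its
#' key-interaction count is at least `min_key_interactions`; (iii) its score
#' percentile is at most `score_percentile_max`; and (iv) any orientation
#' requirements hold. All members receive a verdict row; `selected` is the
#' conjunction of the per-criterion booleans.
#'
#' @param cm an `ecl2_contact_map` covering all ensemble members.
#' @param e the `ecl2_ensemble`.
#' @param key key-residue keys for the ligand under study (an
#'   `ecl2_key_residues` per-ligand vector, or any character vector).
#' @param crit an [selection_criteria()].
#' @param orientations optional data.frame(conformation_id, residue, label)
#'   from [classify_side_chain_orientation()] applied per member; required
#'   when `crit$orientation_requirements` is non-empty.
#' @return data.frame of class `ecl2_selection`; attribute `ranking` holds
#'   the selected ids ordered by score ascending.
#' @export
apply_criteria <- function(cm, e, key, crit, orientations = NULL) {
  stopifnot(inherits(cm, "ecl2_contact_map"), inherits(e, "ecl2_ensemble"),
            inherits(crit, "ecl2_criteria"))
  if (length(crit$orientation_requirements) && is.null(orientations)) {
    stop("orientation requirements present but no orientation labels supplied")
  }
  ranks <- rank_by_score(e)
  df <- as.data.frame(cm)
  rows <- lapply(seq_len(nrow(ranks)), function(i) {
    id <- ranks$conformation_id[i]
    pairs <- df[df$conformation_id == id, , drop = FALSE]
    mandatory_ok <- all(vapply(crit$mandatory_contacts, function(mc) {
      any(pairs$peptide == mc$peptide & pairs$receptor %in% mc$partners)
    }, TRUE))
    kcount <- count_key_interactions(pairs, key)
    key_ok <- kcount >= crit$min_key_interactions
    score_ok <- ranks$percentile[i] <= crit$score_percentile_max
    orientation_ok <- TRUE
    for (req in crit$orientation_requirements) {
      lab <- orientations$label[orientations$conformation_id == id &
                                  orientations$residue == req$residue]
      if (!length(lab)) stop("missing orientation label for conformation ", id,
                             " residue ", req$residue)
      orientation_ok <- orientation_ok && identical(lab[1L], req$label)
    }
    data.frame(conformation_id = id, score = ranks$score[i],
               score_percentile = ranks$percentile[i],
               key_interaction_count = kcount,
               mandatory_ok = mandatory_ok, key_ok = key_ok,
               score_ok = score_ok, orientation_ok = orientation_ok,
               selected = mandatory_ok && key_ok && score_ok && orientation_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sel <- out[out$selected, , drop = FALSE]
  ranking <- sel$conformation_id[order(sel$score, sel$conformation_id)]
  structure(out, class = c("ecl2_selection", "data.frame"), ranking = ranking)
}

#' Fraction of key residues a conformation satisfies
#'
#' Counts the key residues that contact the peptide at all in the given
#' conformation's contact set (the published preferred structures satisfy
#' 6/13 and 4/7 of their respective scan results).
#'
#' @param pairs an `ecl2_contacts` data.frame for one conformation.
#' @param key non-empty character vector of key residue keys for one ligand.
#' @return list with `numerator`, `denominator` and `fraction`.
#' @export
satisfied_fraction <- function(pairs, key) {
  if (!length(key)) stop("key set must be non-empty")
  num <- length(intersect(unique(pairs$receptor), key))
  list(numerator = num, denominator = length(key), fraction = num / length(key))
}
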