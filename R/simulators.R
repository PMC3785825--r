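# Simulators for the experimental inputs: sigmoidal cAMP concentration-
# response curves, and paired WT/mutant alanine-scan tables with planted
# contact-residue effects.

#' Simulate a sigmoidal concentration-response curve
#'
#' Four-parameter logistic in -log10 concentration:
#' `response(c) = basal + (emax - basal) / (1 + 10^((pec50 + log10(c)) * (-hill)))`
#' plus Gaussian noise. At `c = EC50` the noiseless response is the midpoint
#' `(basal + emax) / 2`; as `c -> 0` it tends to `basal`.
#'
#' @param params numeric vector or list `(basal, emax, pec50, hill)`;
#'   basal/emax in % of the fitted WT maximum, pec50 in -log10 molar.
#' @param concentrations molar concentrations, strictly positive (typically
#'   log-spaced, e.g. 1e-12 to 1e-6).
#' @param noise_sd Gaussian noise standard deviation, percentage points
#'   (default 0).
#' @param seed integer seed.
#' @return list of class `ecl2_dose_response` with elements
#'   `concentrations`, `responses`, `params`.
#' @export
simulate_dose_response <- function(params, concentrations, noise_sd = 0, seed = 1L) {
  params <- as.numeric(unlist(params))
  stopifnot(length(params) == 4L)
  if (any(concentrations <= 0)) stop("concentrations must be positive (molar)")
  concentrations <- sort(concentrations)
  basal <- params[1L]; emax <- params[2L]; pec50 <- params[3L]; hill <- params[4L]
  mu <- basal + (emax - basal) / (1 + 10^((pec50 + log10(concentrations)) * (-hill)))
  resp <- withr::with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  structure(list(concentrations = concentrations, responses = resp,
                 params = c(basal = basal, emax = emax, pec50 = pec50, hill = hill)),
            class = "ecl2_dose_response")
}

#' Planted-effect specification for the simulated alanine scan
#'
#' @param planted_contact_residues character vector of residue keys (see
#'   [res_key()]) whose mutation is given a real potency effect.
#' @param delta_pec50 planted potency loss in log units (default 1.0, i.e. a
#'   10-fold EC50 shift, the size of the large published effects).
#' @param replicate_sd between-replicate pEC50 standard deviation, log units
#'   (default 0.15).
#' @param n_replicates paired replicates per mutant (default 5).
#' @param seed integer seed.
#' @return list of class `ecl2_effect_spec`.
#' @export
effect_spec <- function(planted_contact_residues, delta_pec50 = 1.0,
                        replicate_sd = 0.15, n_replicates = 5L, seed = 1L) {
  stopifnot(delta_pec50 >= 0, n_replicates >= 2L)
  structure(list(planted_contact_residues = planted_contact_residues,
                 delta_pec50 = delta_pec50, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
            class = "ecl2_effect_spec")
}

mutant_label_for <- function(key, wt_letter) {
  resno <- parse_res_key(key)$resno
  if (wt_letter == "A") sprintf("A%dL", resno) else sprintf("%s%dA", wt_letter, resno)
}

#' Simulate a paired alanine-scan pharmacology table
#'
#' For every scanned residue, draws `n_replicates` paired WT and mutant
#' pEC50 replicates. Planted contact residues get a true mutant mean of
#' `wt_pec50 - delta_pec50`; all others a true mean equal to WT. Replicates
#' are independent Gaussians around the true means (paired design: each
#' mutant carries its own WT control replicates).
#'
#' @param wt_pec50 true WT pEC50, -log10 molar.
#' @param effects an [effect_spec()]; `planted_contact_residues` must be a
#'   subset of `scanned_residues`.
#' @param scanned_residues character vector of residue keys to scan.
#' @param ligand ligand label for the records (default "CGRP").
#' @param wt_letters optional named character vector key -> 1-letter WT
#'   residue used to build mutant labels (alanines are mutated to leucine);
#'   unknown residues are labelled "X".
#' @return data.frame of class `ecl2_mutagenesis` with one row per mutant:
#'   label, ligand, residue key, per-arm means/sems/n and list-columns
#'   `replicate_wt`, `replicate_mut`.
#' @export
simulate_mutagenesis <- function(wt_pec50, effects, scanned_residues,
                                 ligand = "CGRP", wt_letters = NULL) {
  stopifnot(inherits(effects, "ecl2_effect_spec"))
  missing_planted <- setdiff(effects$planted_contact_residues, scanned_residues)
  if (length(missing_planted)) {
    stop("planted residues not in the scan: ", paste(missing_planted, collapse = ", "))
  }
  n <- effects$n_replicates
  sd <- effects$replicate_sd
  withr::with_seed(effects$seed, {
    rows <- lapply(scanned_residues, function(key) {
      planted <- key %in% effects$planted_contact_residues
      mu_mut <- wt_pec50 - if (planted) effects$delta_pec50 else 0
      wt_rep <- stats::rnorm(n, wt_pec50, sd)
      mut_rep <- stats::rnorm(n, mu_mut, sd)
      wl <- if (!is.null(wt_letters) && key %in% names(wt_letters)) wt_letters[[key]] else "X"
      data.frame(
        mutant = mutant_label_for(key, wl), ligand = ligand, residue = key,
        pec50_mean = mean(mut_rep), pec50_sem = stats::sd(mut_rep) / sqrt(n), n = n,
        wt_pec50_mean = mean(wt_rep), wt_sem = stats::sd(wt_rep) / sqrt(n),
        emax_pct = 100, expression_pct = 100,
        replicate_wt = I(list(wt_rep)), replicate_mut = I(list(mut_rep)),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    class(out) <- c("ecl2_mutagenesis", "data.frame")
    out
  })
}

#' Mutagenesis table TSV I/O
#'
#' Columns: mutant, ligand, pec50_mean, pec50_sem, n, wt_pec50_mean, wt_sem,
#' emax_pct, expression_pct, plus comma-joined replicate columns when
#' replicate-level data are present.
#'
#' @param records an `ecl2_mutagenesis` data.frame.
#' @param path file path.
#' @return `read_mutagenesis_tsv()`: an `ecl2_mutagenesis` data.frame.
#' @export
write_mutagenesis_tsv <- function(records, path) {
  df <- as.data.frame(records)
  join <- function(col) vapply(col, function(v) paste(formatC(v, format = "g", digits = 15), collapse = ","), "")
  if ("replicate_wt" %in% names(df)) df$replicate_wt <- join(df$replicate_wt)
  if ("replicate_mut" %in% names(df)) df$replicate_mut <- join(df$replicate_mut)
  write_tsv_impl(df, path)
}

#' @rdname write_mutagenesis_tsv
#' @export
read_mutagenesis_tsv <- function(path) {
  df <- read_tsv_impl(path)
  attr(df, "file_attrs") <- NULL
  split_reps <- function(col) I(lapply(strsplit(as.character(col), ",", fixed = TRUE), as.numeric))
  if ("replicate_wt" %in% names(df)) df$replicate_wt <- split_reps(df$replicate_wt)
  if ("replicate_mut" %in% names(df)) df$replicate_mut <- split_reps(df$replicate_mut)
  if ("n" %in% names(df)) df$n <- as.integer(df$n)
  class(df) <- c("ecl2_mutagenesis", "data.frame")
  df
}

#' Toy paired multi-species alignments with one planted covarying pair
#'
#' Generates four synthetic alignments (two receptor orthologue sets, two
#' peptide orthologue sets) that are internally invariant apart from light
#' substitution noise, with one planted complementary pair: the receptor
#' systems differ at `receptor_col` (D in system 1, K in system 2) and the
#' peptide systems differ, in mirror, at `peptide_col` (R in system 1, D in
#' system 2). Used by the demo pipeline and the covariation tests.
#'
#' @param n_species sequences per alignment (default 6).
#' @param n_col alignment length (default 30).
#' @param receptor_col,peptide_col planted column indices.
#' @param noise_rate per-cell probability of a random substitution away from
#'   the planted columns (default 0.02).
#' @param seed integer seed.
#' @return list with alignments `receptor_sys1`, `receptor_sys2`,
#'   `peptide_sys1`, `peptide_sys2` and identity column maps
#'   `receptor_map`, `peptide_map`.
#' @export
make_toy_paired_alignments <- function(n_species = 6L, n_col = 30L,
                                       receptor_col = 12L, peptide_col = 6L,
                                       noise_rate = 0.02, seed = 1L) {
  aa <- setdiff(names(AA_1TO3), c("D", "K", "R"))
  withr::with_seed(seed, {
    base_rec <- sample(aa, n_col, replace = TRUE)
    base_pep <- sample(aa, n_col, replace = TRUE)
    mk <- function(base, col, letter, prefix) {
      cons <- base
      cons[col] <- letter
      rows <- vapply(seq_len(n_species), function(i) {
        r <- cons
        flip <- stats::runif(n_col) < noise_rate & seq_len(n_col) != col
        r[flip] <- sample(aa, sum(flip), replace = TRUE)
        paste(r, collapse = "")
      }, "")
      names(rows) <- paste0(prefix, "_sp", seq_len(n_species))
      new_alignment(rows)
    }
    out <- list(
      receptor_sys1 = mk(base_rec, receptor_col, "D", "rec1"),
      receptor_sys2 = mk(base_rec, receptor_col, "K", "rec2"),
      peptide_sys1 = mk(base_pep, peptide_col, "R", "pep1"),
      peptide_sys2 = mk(base_pep, peptide_col, "D", "pep2"),
      receptor_map = data.frame(col1 = seq_len(n_col), col2 = seq_len(n_col)),
      peptide_map = data.frame(col1 = seq_len(n_col), col2 = seq_len(n_col))
    )
    out
  })
}
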