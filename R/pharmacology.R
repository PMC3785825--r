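# Pharmacology computations: Hill-curve fitting, potency fold changes,
# paired significance flags, key-residue derivation from a scan table, and
# the expression-potency correlation.

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of the same logistic used by
#' [simulate_dose_response()]. The Hill slope is fixed at 1 unless
#' `fit_hill = TRUE` (published potency analyses report pEC50/Emax only).
#' Fitting is by Levenberg-Marquardt least squares
#' (\code{minpack.lm::nlsLM}).
#'
#' @param curve an `ecl2_dose_response`, or a list with `concentrations` and
#'   `responses`.
#' @param fit_hill also estimate the Hill slope (default FALSE).
#' @return list with `estimates` (basal, emax, pec50, and hill when fitted),
#'   `se` (standard errors), `fitted` values and the `fit` object.
#' @export
fit_hill <- function(curve, fit_hill = FALSE) {
  conc <- curve$concentrations
  resp <- curve$responses
  if (length(conc) < 4L) stop("need at least 4 concentration points")
  ord <- order(conc)
  conc <- conc[ord]; resp <- resp[ord]
  lc <- log10(conc)
  df <- data.frame(lc = lc, resp = resp)
  start <- list(basal = min(resp), emax = max(resp),
                pec50 = -lc[which.min(abs(resp - (min(resp) + max(resp)) / 2))])
  fml <- if (fit_hill) {
    start$hill <- 1
    resp ~ basal + (emax - basal) / (1 + 10^((pec50 + lc) * (-hill)))
  } else {
    resp ~ basal + (emax - basal) / (1 + 10^(-(pec50 + lc)))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("curve fit did not converge: ", conditionMessage(e))
  )
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  fitted <- stats::fitted(fit)
  # monotonicity check: a systematic decrease along increasing concentration
  # beyond the noise level suggests the logistic is the wrong model
  noise <- stats::sd(resp - fitted)
  viol <- max(cummax(resp) - resp)
  if (is.finite(noise) && viol > 3 * max(noise, 1e-9)) {
    warning("responses decrease with concentration beyond the noise level")
  }
  list(estimates = est, se = se, fitted = as.numeric(fitted), fit = fit)
}

#' Potency fold change from two pEC50 values
#'
#' `fold = 10^(pec50_wt - pec50_mut)`; a fold of 10 corresponds to a one
#' log-unit potency loss.
#'
#' @param pec50_wt,pec50_mut pEC50 values, -log10 molar.
#' @return dimensionless fold change.
#' @export
fold_change <- function(pec50_wt, pec50_mut) {
  stopifnot(is.finite(pec50_wt), is.finite(pec50_mut))
  10^(pec50_wt - pec50_mut)
}

#' Flag significant mutants by paired t-test
#'
#' Two-tailed paired Student's t-test of mutant vs matched WT pEC50
#' replicates, per record. No multiple-testing correction is applied across
#' mutants, matching per-mutant reporting conventions. Degenerate cases:
#' all within-pair differences zero gives `significant = FALSE`; zero
#' within-pair variance with a nonzero mean difference is flagged
#' significant with the p-value reported at the machine floor.
#'
#' @param records an `ecl2_mutagenesis` data.frame with list-columns
#'   `replicate_wt`, `replicate_mut` (equal lengths, n >= 3).
#' @param alpha significance level (default 0.05).
#' @return `records` with columns `p_value` and `significant` added.
#' @export
flag_significance <- function(records, alpha = 0.05) {
  stopifnot(all(c("replicate_wt", "replicate_mut") %in% names(records)))
  pv <- vapply(seq_len(nrow(records)), function(i) {
    wt <- records$replicate_wt[[i]]
    mu <- records$replicate_mut[[i]]
    if (length(wt) != length(mu)) stop("unequal WT/mutant replicate lengths in row ", i)
    if (length(wt) < 3L) stop("need at least 3 paired replicates in row ", i)
    d <- mu - wt
    if (all(d == 0)) return(1)
    if (stats::sd(d) == 0) return(.Machine$double.xmin)
    stats::t.test(mu, wt, paired = TRUE)$p.value
  }, 0)
  records$p_value <- pv
  records$significant <- pv < alpha
  records
}

parse_mutant_label <- function(label) {
  m <- gregexpr("[A-Z]\\d+[A-Z]", label)[[1L]]
  toks <- regmatches(label, gregexpr("[A-Z]\\d+[A-Z]", label))[[1L]]
  if (!length(toks) || sum(nchar(toks)) != nchar(label)) {
    stop("unparseable mutant label: '", label, "'")
  }
  data.frame(
    wt = substr(toks, 1L, 1L),
    resno = as.integer(gsub("[A-Z]", "", toks)),
    mut = substring(toks, nchar(toks)),
    stringsAsFactors = FALSE
  )
}

#' Derive the key-residue set from a scan table
#'
#' A residue enters the per-ligand key set iff its record for that ligand is
#' significant AND the pEC50 shift is a reduction (potency losses define
#' "impairment"; potency increases are excluded). Double mutants (labels
#' with two substitutions, e.g. "L290AL291A") never enter the set; they are
#' retained in fold-change analyses only.
#'
#' @param records data.frame with columns `mutant`, `ligand`, a significance
#'   column (`significant` logical, or "yes"/"no"/"unknown"), and either a
#'   `pec50_shift` column (mutant minus WT, log units) or both `pec50_mean`
#'   and `wt_pec50_mean`.
#' @param chain chain id used to build residue keys (default "R").
#' @return list of class `ecl2_key_residues` with `by_ligand` (named list of
#'   key vectors) and `union`.
#' @export
derive_key_residues <- function(records, chain = "R") {
  df <- as.data.frame(records)
  sig <- df$significant
  if (is.character(sig)) sig <- tolower(sig) == "yes"
  if (is.null(sig)) stop("records need a 'significant' column")
  shift <- if ("pec50_shift" %in% names(df)) df$pec50_shift else
    df$pec50_mean - df$wt_pec50_mean
  parsed <- lapply(df$mutant, parse_mutant_label)
  n_subs <- vapply(parsed, nrow, 0L)
  by_ligand <- list()
  for (lig in sort(unique(df$ligand))) {
    rows <- which(df$ligand == lig & n_subs == 1L & sig %in% TRUE & shift < 0)
    resnos <- sort(unique(vapply(parsed[rows], function(p) p$resno, 0L)))
    by_ligand[[lig]] <- res_key(chain, resnos)
  }
  structure(list(by_ligand = by_ligand,
                 union = sort(unique(unlist(by_ligand, use.names = FALSE)))),
            class = "ecl2_key_residues")
}

#' @export
print.ecl2_key_residues <- function(x, ...) {
  for (lig in names(x$by_ligand)) {
    cat(sprintf("%s: %d residues: %s\n", lig, length(x$by_ligand[[lig]]),
                paste(x$by_ligand[[lig]], collapse = " ")))
  }
  cat(sprintf("union: %d residues\n", length(x$union)))
  invisible(x)
}

#' Squared correlation between surface expression and potency shift
#'
#' Squared Pearson correlation over the mutants shared between the two
#' inputs; used to check that potency losses are not explained by loss of
#' cell-surface expression.
#'
#' @param expression named numeric vector, mutant -> expression in % of WT.
#' @param pec50_shift named numeric vector, mutant -> pEC50 shift, log units.
#' @return r squared.
#' @export
expression_pec50_correlation <- function(expression, pec50_shift) {
  shared <- intersect(names(expression), names(pec50_shift))
  if (length(shared) < 3L) stop("need at least 3 shared mutants")
  x <- expression[shared]; y <- pec50_shift[shared]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  unname(stats::cor(x, y)^2)
}
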