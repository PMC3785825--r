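# Pipeline driver: wires the stages (simulate -> contacts -> pharm ->
# filter -> covary) behind one validated config, writing TSV outputs, a
# machine-readable JSON summary and a log. Identical config + seeds give
# byte-identical outputs.

#' Pipeline configuration
#'
#' Accepts a YAML file path or a named list. Defaults equal the published
#' analysis settings: contact cutoff 5.5 Angstrom, ensemble of 100
#' conformations, display prune at 10 structures, score percentile bound
#' 0.15 when the energy criterion is enabled.
#'
#' @param config path to a YAML file or a named list; see the bundled
#'   `demo_pipeline_config()` for the full key set.
#' @return validated list of class `ecl2_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(
    out_dir = "ecl2scan_out",
    seed = 42L,
    stages = list(simulate = TRUE, contacts = TRUE, pharm = TRUE,
                  filter = TRUE, covary = TRUE),
    paths = list(ensemble = NULL, scores = NULL, mutagenesis = NULL,
                 alignments = NULL),
    parameters = list(
      cutoff = 5.5, min_count = 10L, n_conformations = 100L,
      alpha = 0.05, wt_pec50 = 10.6, delta_pec50 = 1.0,
      replicate_sd = 0.15, n_replicates = 5L,
      receptor_chain = "R", peptide_chain = "P",
      loop_range = "274-293",
      use_score_percentile = FALSE, score_percentile_max = 0.15,
      min_key_interactions = 1L,
      mandatory_peptide = "P:6:",
      mandatory_partners = c("R:280:", "R:287:", "R:288:"),
      min_conservation = 0.8
    )
  )
  cfg <- utils::modifyList(defaults, config)
  if (cfg$parameters$cutoff <= 0) stop("cutoff must be positive")
  st <- cfg$stages
  if (!isTRUE(st$simulate)) {
    if (isTRUE(st$contacts) && (is.null(cfg$paths$ensemble) || is.null(cfg$paths$scores))) {
      stop("contacts stage enabled but no ensemble/scores path given and simulate disabled")
    }
    if (isTRUE(st$pharm) && is.null(cfg$paths$mutagenesis)) {
      stop("pharm stage enabled but no mutagenesis path given and simulate disabled")
    }
    if (isTRUE(st$covary) && is.null(cfg$paths$alignments)) {
      stop("covary stage enabled but no alignments path given and simulate disabled")
    }
  }
  if (isTRUE(st$filter) && !isTRUE(st$contacts)) {
    stop("filter stage requires the contacts stage")
  }
  structure(cfg, class = c("ecl2_config", "list"))
}

#' Demo configuration for the bundled synthetic pipeline
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_conformations ensemble size (default 20 for a fast demo).
#' @return an `ecl2_config`.
#' @export
demo_pipeline_config <- function(out_dir = tempfile("ecl2scan_demo_"), seed = 42L,
                                 n_conformations = 20L) {
  pipeline_config(list(
    out_dir = out_dir, seed = as.integer(seed),
    parameters = list(n_conformations = as.integer(n_conformations),
                      min_count = 2L)
  ))
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Stages run in dependency order; each writes its TSV outputs under
#' `config$out_dir` and the run finishes with `report.json` (ensemble size,
#' key-residue sets, selected conformation ids, satisfied fractions,
#' covariation hits, and all parameters) plus `run.log`. Reruns with the
#' same config and seed are byte-identical.
#'
#' @param config an `ecl2_config`, a list, or a YAML path.
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config = demo_pipeline_config()) {
  cfg <- if (inherits(config, "ecl2_config")) config else pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "run.log")
  con <- file(logf, "w")
  on.exit(close(con))
  par <- cfg$parameters
  log_line(con, "parameters: ", jsonlite::toJSON(par, auto_unbox = TRUE))
  report <- list(parameters = par, seed = cfg$seed)

  ensemble <- NULL
  mut <- NULL
  alignments <- NULL

  if (isTRUE(cfg$stages$simulate)) {
    log_line(con, "stage simulate: building toy complex and sampling ",
             par$n_conformations, " loop conformations")
    cplx <- build_toy_complex(toy_complex_spec(seed = cfg$seed))
    sp <- loop_sampler_params(n_conformations = par$n_conformations,
                              seed = cfg$seed + 1L)
    ensemble <- sample_loop_ensemble(cplx, p = sp)
    write_pdb(ensemble, file.path(cfg$out_dir, "ensemble.pdb"))
    write_scores_tsv(ensemble, file.path(cfg$out_dir, "scores.tsv"))
    loop_keys <- select_residues(cplx, par$receptor_chain, par$loop_range)
    wt_letters <- stats::setNames(
      AA_3TO1[vapply(loop_keys, function(k) {
        a <- cplx$atoms
        pk <- parse_res_key(k)
        a$resid[a$chain == pk$chain & a$resno == pk$resno][1L]
      }, "")], loop_keys)
    planted <- intersect(par$mandatory_partners, loop_keys)
    mut <- simulate_mutagenesis(
      par$wt_pec50,
      effect_spec(planted, delta_pec50 = par$delta_pec50,
                  replicate_sd = par$replicate_sd,
                  n_replicates = par$n_replicates, seed = cfg$seed + 2L),
      scanned_residues = loop_keys, wt_letters = wt_letters
    )
    write_mutagenesis_tsv(mut, file.path(cfg$out_dir, "mutagenesis.tsv"))
    alignments <- make_toy_paired_alignments(seed = cfg$seed + 3L)
    for (nm in c("receptor_sys1", "receptor_sys2", "peptide_sys1", "peptide_sys2")) {
      write_alignment(alignments[[nm]], file.path(cfg$out_dir, paste0(nm, ".fasta")))
    }
  } else {
    if (isTRUE(cfg$stages$contacts)) {
      ensemble <- read_ensemble(cfg$paths$ensemble, cfg$paths$scores)
    }
    if (isTRUE(cfg$stages$pharm)) mut <- read_mutagenesis_tsv(cfg$paths$mutagenesis)
    if (isTRUE(cfg$stages$covary)) {
      al <- cfg$paths$alignments
      alignments <- list(
        receptor_sys1 = read_alignment(al$receptor_sys1),
        receptor_sys2 = read_alignment(al$receptor_sys2),
        peptide_sys1 = read_alignment(al$peptide_sys1),
        peptide_sys2 = read_alignment(al$peptide_sys2),
        receptor_map = utils::read.delim(al$receptor_map, comment.char = ""),
        peptide_map = utils::read.delim(al$peptide_map, comment.char = "")
      )
    }
  }
  if (!is.null(ensemble)) report$ensemble_size <- length(ensemble$members)

  key <- NULL
  if (isTRUE(cfg$stages$pharm)) {
    log_line(con, "stage pharm: paired significance + key-residue derivation")
    flags <- flag_significance(mut, alpha = par$alpha)
    key <- derive_key_residues(flags, chain = par$receptor_chain)
    out <- as.data.frame(flags)
    out$replicate_wt <- NULL; out$replicate_mut <- NULL
    write_tsv_impl(out, file.path(cfg$out_dir, "pharm_flags.tsv"))
    kr <- data.frame(
      ligand = rep(names(key$by_ligand), lengths(key$by_ligand)),
      residue = unlist(key$by_ligand, use.names = FALSE)
    )
    write_tsv_impl(kr, file.path(cfg$out_dir, "key_residues.tsv"))
    report$key_residues <- key$by_ligand
  }

  cm <- NULL
  if (isTRUE(cfg$stages$contacts)) {
    log_line(con, "stage contacts: cutoff ", par$cutoff, " A")
    s1 <- ensemble$members[[1L]]$structure
    receptor_sel <- select_residues(s1, par$receptor_chain, par$loop_range)
    pep_atoms <- s1$atoms[s1$atoms$chain == par$peptide_chain, , drop = FALSE]
    peptide_sel <- unique(atom_keys(pep_atoms))
    cm <- compute_contact_map(ensemble, receptor_sel, peptide_sel, par$cutoff)
    write_tables(cm, file.path(cfg$out_dir, "contacts.tsv"))
    ft <- frequency_table(cm, min_count = par$min_count)
    write_tables(ft, file.path(cfg$out_dir, "frequency.tsv"))
    report$n_contact_pairs <- nrow(cm)
    report$n_frequent_pairs <- nrow(ft)
  }

  if (isTRUE(cfg$stages$filter)) {
    log_line(con, "stage filter: criteria-based conformation selection")
    crit <- selection_criteria(
      mandatory_contacts = list(list(peptide = par$mandatory_peptide,
                                     partners = par$mandatory_partners)),
      min_key_interactions = par$min_key_interactions,
      score_percentile_max = if (isTRUE(par$use_score_percentile))
        par$score_percentile_max else 1.0
    )
    key_vec <- if (!is.null(key)) key$by_ligand[[1L]] else par$mandatory_partners
    selres <- apply_criteria(cm, ensemble, key_vec, crit)
    write_tables(selres, file.path(cfg$out_dir, "selection.tsv"))
    pl <- partner_labels(cm, par$mandatory_peptide, par$mandatory_partners)
    # scatter-style data: count vs score coloured by probe partner
    fig <- merge(as.data.frame(selres)[, c("conformation_id", "score",
                                           "key_interaction_count")],
                 pl, by = "conformation_id")
    write_tsv_impl(fig[order(fig$conformation_id), ],
                   file.path(cfg$out_dir, "count_vs_score.tsv"))
    report$selected_conformations <- attr(selres, "ranking")
    if (length(attr(selres, "ranking"))) {
      best <- attr(selres, "ranking")[1L]
      bp <- as.data.frame(cm)
      bp <- bp[bp$conformation_id == best, , drop = FALSE]
      sf <- satisfied_fraction(bp, key_vec)
      report$satisfied_fraction <- sf
      log_line(con, "preferred conformation ", best, " satisfies ",
               sf$numerator, "/", sf$denominator, " scan results")
    }
  }

  if (isTRUE(cfg$stages$covary)) {
    log_line(con, "stage covary: correlated-substitution screen")
    hits <- correlated_pairs(alignments, min_conservation = par$min_conservation)
    write_tsv_impl(hits, file.path(cfg$out_dir, "covariation_hits.tsv"))
    report$covariation_hits <- hits
  }

  report_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  validate_report(report)
  log_line(con, "report written: ", report_path)
  invisible(report)
}

#' Validate a pipeline report against the bundled schema
#'
#' Minimal structural validation: required keys present and of the expected
#' JSON type, per `inst/extdata/report_schema.json`.
#'
#' @param report the report list, or a path to `report.json`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report_schema.json",
                                            package = "ecl2scan"))
  for (k in unlist(schema$required)) {
    if (is.null(report[[k]])) stop("report lacks required key: ", k)
  }
  types <- schema$types
  for (k in names(types)) {
    if (is.null(report[[k]])) next
    ok <- switch(types[[k]],
                 number = is.numeric(report[[k]]) || is.integer(report[[k]]),
                 object = is.list(report[[k]]),
                 array = is.list(report[[k]]) || is.vector(report[[k]]),
                 TRUE)
    if (!ok) stop("report key '", k, "' is not of type ", types[[k]])
  }
  invisible(TRUE)
}
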