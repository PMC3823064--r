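# End-to-end orchestration: shells -> D&V positions -> scores -> groups;
# q-score permutation test; Venn sets; kinetics -> classification;
# parsimony. Each stage is optional and driven by which inputs the
# config provides; any stage failure aborts with a stage-named error.

#' Default pipeline parameters
#'
#' The documented defaults of every stage: shell radii (first shell
#' 3.40 A), the D&V selection window (<15 A, modal fraction in
#' \[0.25, 0.75)), the mutual grouping cutoff (<9), the shortlist bound
#' (>10), the conservation level (0.75), permutation draws (100000) and
#' the no-saturation bound (40 mM).
#'
#' @return named list of parameters.
#' @export
pipeline_defaults <- function() {
  list(
    cofactor = "PLP", ligand = NULL,
    radii = DEFAULT_SHELL_RADII, first_shell = 3.4,
    d_max = 15, f_low = 0.25, f_high = 0.75,
    dv_cutoff = 9, shortlist_min = 10,
    level = 0.75, n_perm = 100000L, seed = 1L,
    scorer = "clustalx", matrix = "BLOSUM62",
    ns_bound = 40, kinetic_model = "auto",
    asp_substrate = "Asp", aromatic_substrate = "Phe",
    representative_policy = "lex"
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort_config("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("config must be a list or YAML path")
  params <- utils::modifyList(pipeline_defaults(), config$params %||% list())
  list(inputs = config$inputs %||% list(),
       ids = config$ids %||% list(),
       params = params)
}

#' Run the full specificity-evolution analysis
#'
#' Executes, in dependency order, whichever stages the config's inputs
#' allow: structure shells and residue distances; conservation q-scores
#' with the active-site permutation test; the Venn partition of conserved
#' columns; D&V position selection, scoring, pairwise comparison and
#' grouping; ping-pong kinetic fits with specificity classification; and
#' root-constrained parsimony on the annotated phylogeny. Stages whose
#' inputs are absent are marked `skipped`.
#'
#' @param config a list (or path to a YAML file) with elements `inputs`
#'   (paths: `alignment`, `structure`, `tree`, `annotations`,
#'   `kinetics`), `ids` (`ref_id`, `reference_panel`, `candidates`,
#'   `group_a`, `group_b`) and `params` overriding
#'   [pipeline_defaults()].
#' @return list of class `specswap_report` with one element per stage
#'   plus `provenance`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  inputs <- cfg$inputs
  ids <- cfg$ids
  p <- cfg$params
  report <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("specswap_stage_error", "specswap_error")))
    })
  }
  skipped <- list(status = "skipped")

  msa <- if (!is.null(inputs$alignment)) {
    stage("alignment", read_alignment(inputs$alignment))
  }
  structure_model <- if (!is.null(inputs$structure)) {
    stage("structure", read_structure(inputs$structure))
  }

  report$shells <- if (!is.null(structure_model)) stage("shells", {
    targets <- c(p$cofactor, p$ligand)
    dist <- residue_min_distances(structure_model, targets)
    sh <- assign_shells(dist, p$radii)
    first_shell <- residues_within(dist, p$first_shell, closed = TRUE)
    list(status = "ok", distances = dist, shells = sh,
         first_shell_residues = first_shell)
  }) else skipped

  report$conservation <- if (!is.null(msa) && !is.null(structure_model) &&
                             !is.null(ids$ref_id)) stage("conservation", {
    # the permutation null draws from columns ungapped in the reference
    q <- qscores(msa, scorer = p$scorer, matrix = p$matrix)
    cof_dist <- residue_min_distances(structure_model, p$cofactor)
    map <- map_columns_to_reference(msa, ids$ref_id, cof_dist)
    shell_dist <- report$shells$distances
    first_res <- residues_within(shell_dist, p$first_shell, closed = TRUE)
    obs_cols <- map$column[map$residue_number %in% first_res]
    perm <- permutation_test(q, obs_cols, map$column,
                             n_perm = p$n_perm, seed = p$seed)
    perm$null_sums <- NULL  # keep the report light
    list(status = "ok", qscores = q, observed_columns = obs_cols,
         permutation = perm)
  }) else skipped

  report$venn <- if (!is.null(msa) && !is.null(ids$group_a) &&
                     !is.null(ids$group_b)) stage("venn", {
    v <- venn_partition(msa, ids$group_a, ids$group_b, p$level)
    list(status = "ok", sets = v,
         counts = c(intersection = length(v$set_intersection),
                    A_only = length(v$set_A_only),
                    B_only = length(v$set_B_only)))
  }) else skipped

  report$dv <- if (!is.null(msa) && !is.null(structure_model) &&
                   !is.null(ids$ref_id) &&
                   !is.null(ids$reference_panel)) stage("dv", {
    cof_dist <- residue_min_distances(structure_model, p$cofactor)
    map <- map_columns_to_reference(msa, ids$ref_id, cof_dist)
    prof <- column_profiles(msa)
    pos <- select_dv_positions(prof, map, cof_dist,
                               d_max = p$d_max, f_low = p$f_low,
                               f_high = p$f_high)
    cands <- ids$candidates %||% setdiff(msa$ids, ids$reference_panel)
    cards <- dv_scorecards(cands, msa, ids$reference_panel, pos)
    short <- dv_shortlist(cards, p$shortlist_min)
    out <- list(status = "ok", positions = pos, scorecards = cards,
                shortlist = short)
    if (length(short) >= 2L) {
      mat <- pairwise_dv_matrix(short, cards, msa)
      part <- group_candidates(mat, p$dv_cutoff)
      out$pairwise <- mat
      out$groups <- part
      out$representatives <- pick_representatives(
        part, p$representative_policy, scorecards = cards)
    }
    out
  }) else skipped

  report$kinetics <- if (!is.null(inputs$kinetics)) stage("kinetics", {
    data <- read_kinetic_table(inputs$kinetics)
    enzymes <- unique(data$enzyme)
    fits <- list()
    for (enz in enzymes) {
      subs <- unique(data$substrate[data$enzyme == enz])
      if (!all(c(p$asp_substrate, p$aromatic_substrate) %in% subs)) next
      fits[[enz]] <- list(
        asp = fit_pingpong(data, enz, p$asp_substrate,
                           model = p$kinetic_model, ns_bound = p$ns_bound),
        aromatic = fit_pingpong(data, enz, p$aromatic_substrate,
                                model = p$kinetic_model,
                                ns_bound = p$ns_bound))
    }
    list(status = "ok", fits = fits,
         summary = if (length(fits)) kinetics_summary(fits))
  }) else skipped

  report$parsimony <- if (!is.null(inputs$tree) &&
                          !is.null(inputs$annotations)) stage("parsimony", {
    tree <- read_tree(inputs$tree)
    states <- read_leaf_states(inputs$annotations, tree)
    ann <- annotated_phylogeny(tree, states)
    res <- list(
      free = min_changes(ann),
      AAT = min_changes(ann, "AAT"),
      TAT = min_changes(ann, "TAT"))
    for (r in names(res)) res[[r]]$dp <- NULL
    list(status = "ok", results = res,
         min_changes = c(free = res$free$min_changes,
                         AAT_root = res$AAT$min_changes,
                         TAT_root = res$TAT$min_changes))
  }) else skipped

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("specswap")),
    seed = p$seed, params = p, inputs = inputs, ids = ids,
    timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "specswap_report"
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (machine-readable summary) and `report.txt`
#' (human-readable) under `dir`.
#'
#' @param report a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "specswap_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summarise <- function(x) {
    if (identical(x$status, "skipped")) return(list(status = "skipped"))
    out <- list(status = "ok")
    if (!is.null(x$permutation)) {
      out$observed_sum <- x$permutation$observed_sum
      out$null_max <- x$permutation$null_max
      out$p_value <- x$permutation$p_value
    }
    if (!is.null(x$first_shell_residues)) {
      out$first_shell_residues <- x$first_shell_residues
    }
    if (!is.null(x$counts)) out$venn_counts <- as.list(x$counts)
    if (!is.null(x$positions)) out$n_dv_positions <- nrow(x$positions)
    if (!is.null(x$shortlist)) out$shortlist <- x$shortlist
    if (!is.null(x$groups)) out$n_groups <- length(x$groups$groups)
    if (!is.null(x$representatives)) out$representatives <- x$representatives
    if (!is.null(x$summary)) out$kinetics_table <- x$summary
    if (!is.null(x$min_changes)) out$min_changes <- as.list(x$min_changes)
    out
  }
  json <- lapply(report[setdiff(names(report), "provenance")], summarise)
  json$provenance <- report$provenance
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.specswap_report <- function(x, ...) {
  cat("specswap pipeline report\n")
  for (nm in setdiff(names(x), "provenance")) {
    sec <- x[[nm]]
    if (identical(sec$status, "skipped")) {
      cat(sprintf("  %-12s skipped\n", nm))
      next
    }
    cat(sprintf("  %-12s ok\n", nm))
    if (!is.null(sec$permutation)) {
      cat(sprintf("    q-score sum %.1f, null max %.1f, p = %.3g\n",
                  sec$permutation$observed_sum, sec$permutation$null_max,
                  sec$permutation$p_value))
    }
    if (!is.null(sec$counts)) {
      cat(sprintf("    Venn counts: %s\n",
                  paste(sprintf("%s=%d", names(sec$counts), sec$counts),
                        collapse = ", ")))
    }
    if (!is.null(sec$positions)) {
      cat(sprintf("    %d D&V positions, %d shortlisted, %s\n",
                  nrow(sec$positions), length(sec$shortlist),
                  if (!is.null(sec$groups))
                    sprintf("%d groups", length(sec$groups$groups))
                  else "no grouping"))
    }
    if (!is.null(sec$summary)) {
      cat(sprintf("    %d enzyme(s) fitted\n", nrow(sec$summary)))
    }
    if (!is.null(sec$min_changes)) {
      cat(sprintf("    parsimony switches: %s\n",
                  paste(sprintf("%s=%d", names(sec$min_changes),
                                sec$min_changes), collapse = ", ")))
    }
  }
  invisible(x)
}
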