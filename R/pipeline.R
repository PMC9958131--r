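# Pipeline orchestration: run every analysis stage from a single config
# with fixed seeds, writing stage TSVs and a machine-readable JSON summary.
# Stages whose optional inputs are absent (no structure, no affinity
# table) are skipped and noted in the summary.

#' Assemble a pipeline configuration
#'
#' Collects input paths, condition labels and every analysis threshold in
#' one place.  Threshold defaults are the values used throughout the
#' package: site filter 10% / 1e6, region threshold 1 (twofold),
#' derivative threshold log2(1.3), coverage 1e6, alpha 0.05, fold gate 2,
#' affinity retention 500 nM, core margin 50%, 1000 cut-site and 2000
#' distance bootstrap iterations.
#'
#' @param fasta Path to the protein FASTA.
#' @param peptide_table Path to the canonical peptide table (must contain
#'   abundance columns for both condition labels).
#' @param out_dir Output directory for stage TSVs and the summary.
#' @param pdb Optional named character vector of PDB paths, names matching
#'   protein ids.
#' @param pdb_chain,pdb_offset Chain and residue-number offset for PDB
#'   reading.
#' @param affinity_table Optional path to the canonical affinity TSV.
#' @param structural_comparison Optional data frame with `protein_id`,
#'   `rmsd`, `tm_score` for the change-score regressions.
#' @param native_label,cit_label Condition labels (defaults `"native"`,
#'   `"cit"`).
#' @param min_site_fraction,min_site_abundance Site-filter thresholds.
#' @param region_threshold Enrichment threshold for region calling.
#' @param derivative_threshold Cut-site detection threshold.
#' @param coverage_threshold Adequate-coverage abundance.
#' @param alpha FDR level.
#' @param fold Fold-change gate.
#' @param affinity_threshold Binding-core retention threshold (nM).
#' @param core_margin Core enrichment margin.
#' @param cutsite_iterations,distance_iterations Bootstrap iteration
#'   counts.
#' @param pooled_cutsite_bootstrap Pool cut sites across proteins for the
#'   citrulline-association bootstrap (default `TRUE`); per-protein
#'   results are always reported too.
#' @param seed Master seed.
#' @return List of class `citmap_config`.
#' @export
pipeline_config <- function(fasta, peptide_table, out_dir,
                            pdb = NULL, pdb_chain = "A", pdb_offset = 0L,
                            affinity_table = NULL,
                            structural_comparison = NULL,
                            native_label = "native", cit_label = "cit",
                            min_site_fraction = 0.10,
                            min_site_abundance = 1e6,
                            region_threshold = 1.0,
                            derivative_threshold = log2(1.3),
                            coverage_threshold = 1e6,
                            alpha = 0.05, fold = 2,
                            affinity_threshold = 500,
                            core_margin = 0.5,
                            cutsite_iterations = 1000L,
                            distance_iterations = 2000L,
                            pooled_cutsite_bootstrap = TRUE,
                            seed = 1L) {
  structure(as.list(environment()), class = "citmap_config")
}

#' Validate a pipeline configuration
#'
#' Structural and semantic checks; findings are returned rather than
#' raised, so the caller decides whether warnings are acceptable.
#'
#' @param config A `citmap_config`.
#' @return `data.frame` with `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows when the config is clean.
#' @export
validate_config <- function(config) {
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (is.null(config$fasta) || !file.exists(config$fasta)) {
    note("error", "fasta path missing or not found")
  }
  if (is.null(config$peptide_table) || !file.exists(config$peptide_table)) {
    note("error", "peptide_table path missing or not found")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    note("error", "alpha must lie in (0, 1)")
  }
  if (config$fold < 1) note("error", "fold gate must be >= 1")
  if (config$min_site_fraction < 0 || config$min_site_fraction > 1) {
    note("error", "min_site_fraction must lie in [0, 1]")
  }
  if (config$affinity_threshold <= 0) {
    note("error", "affinity_threshold must be positive")
  }
  if (config$cutsite_iterations < 1000) {
    note("warning", "cutsite_iterations below 1000")
  }
  if (config$distance_iterations < 2000) {
    note("warning", "distance_iterations below 2000")
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(0), message = character(0)))
  }
  do.call(rbind, findings)
}

#' Run the full analysis pipeline
#'
#' Executes, per protein: citrullination-site evidence and filtering,
#' enrichment profile, changed-region calling, differential peptide
#' testing, change score, cut-site detection/classification with the
#' citrulline-association bootstraps, linear (and, when a structure is
#' available, 3D) distance-to-citrulline analysis, and (when an affinity
#' table is supplied) the binding-core repertoire.  Change-score
#' regressions against arginine frequency (and RMSD / 1/TM-score when
#' structural scalars are supplied) close the run.  All stage outputs are
#' written to `config$out_dir` as TSVs plus a `summary.json` embedding the
#' resolved config; given the same config and seed the bundle is
#' byte-identical across runs.
#'
#' @param config A `citmap_config` (see [pipeline_config()]).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  errs <- findings$message[findings$level == "error"]
  if (length(errs) > 0) {
    stop("invalid configuration: ", paste(errs, collapse = "; "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- read_fasta(config$fasta)
  peptides_all <- read_peptide_table(config$peptide_table)
  affinity <- if (!is.null(config$affinity_table)) {
    read_affinity_table(config$affinity_table)
  } else NULL

  per_protein <- list()
  pooled_sites <- list()
  all_scores <- list()
  all_distances <- list()
  for (pi in seq_along(proteins)) {
    protein <- proteins[[pi]]
    peptides <- peptides_all[peptides_all$protein_id == protein$id, ,
                             drop = FALSE]
    if (nrow(peptides) == 0) next
    stage <- .run_protein_stages(protein, peptides, affinity, config, pi)
    per_protein[[protein$id]] <- stage$summary
    pooled_sites[[protein$id]] <- stage$pooled
    all_scores[[protein$id]] <- stage$score_row
    if (nrow(stage$distances) > 0) {
      all_distances[[protein$id]] <- stage$distances
    }
  }
  if (length(per_protein) == 0) {
    stop("no protein in the FASTA matches any peptide-table row")
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("citmap")),
    config = .serializable_config(config),
    proteins = per_protein
  )

  scores <- do.call(rbind, all_scores)
  utils::write.table(scores, file.path(config$out_dir, "change_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(scores) >= 2 && length(unique(scores$arg_frequency)) > 1) {
    reg <- fit_change_score_regression(scores$arg_frequency,
                                       scores$change_score)
    summary$regressions <- list(arginine_frequency = reg)
  }
  if (!is.null(config$structural_comparison)) {
    sc <- merge(scores, config$structural_comparison, by = "protein_id")
    if (nrow(sc) >= 2) {
      if (length(unique(sc$rmsd)) > 1) {
        summary$regressions$rmsd <-
          fit_change_score_regression(sc$rmsd, sc$change_score)
      }
      if (length(unique(sc$tm_score)) > 1) {
        summary$regressions$inv_tm_score <-
          fit_change_score_regression(1 / sc$tm_score, sc$change_score)
      }
    }
  }

  if (config$pooled_cutsite_bootstrap && length(pooled_sites) > 0) {
    summary$pooled_cutsite <- .pooled_cutsite_bootstrap(pooled_sites, config)
  }
  if (length(all_distances) > 0) {
    dist_all <- do.call(rbind, all_distances)
    rownames(dist_all) <- NULL
    utils::write.table(dist_all,
                       file.path(config$out_dir, "region_distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$distance_summary <- summarize_actual_minus_expected(dist_all)
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}

.serializable_config <- function(config) {
  cfg <- unclass(config)
  cfg$structural_comparison <- NULL
  cfg
}

.run_protein_stages <- function(protein, peptides, affinity, config, pi) {
  out <- config$out_dir
  tag <- function(name) file.path(out, paste0(protein$id, ".", name, ".tsv"))

  # citrullination sites from the citrullinated condition's evidence
  evidence <- compute_site_evidence(peptides, protein, config$cit_label)
  sites <- filter_sites(evidence, config$min_site_fraction,
                        config$min_site_abundance)
  write_site_table(sites, tag("sites"))

  # enrichment profile and changed regions
  nat_sums <- residue_sums(peptides, protein, config$native_label)
  cit_sums <- residue_sums(peptides, protein, config$cit_label)
  profile <- log2_profile(nat_sums, cit_sums,
                          coverage_threshold = config$coverage_threshold,
                          protein_id = protein$id,
                          conditions = c(native = config$native_label,
                                         cit = config$cit_label))
  write_profile_table(profile, tag("profile"))
  regions <- call_changed_regions(profile, config$region_threshold, sites)
  write_region_table(regions, tag("regions"))

  # differential peptides and change score
  diff <- differential_peptides(peptides, config$native_label,
                                config$cit_label, config$alpha, config$fold)
  utils::write.table(diff, tag("differential"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  score <- change_score(diff)
  pct_seq <- fraction_sequence_changed(diff, profile)

  # cut sites and citrulline association
  cut_sites <- call_cut_sites(profile, protein,
                              config$derivative_threshold)
  utils::write.table(cut_sites, tag("cutsites"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  eligible <- which(profile$high_coverage)
  cut_boot <- NULL
  posw <- NULL
  novel <- cut_sites$bond[cut_sites$kind == "novel"]
  if (length(novel) > 0 && length(sites$positions) > 0 &&
      length(sites$positions) <= length(eligible)) {
    cut_boot <- bootstrap_cutsite_null(
      novel, sites$positions, eligible, protein$length,
      config$cutsite_iterations, seed = mix_seed(config$seed, 11L, pi))
    posw <- positionwise_citrulline_test(
      novel, sites$positions, eligible, protein$length,
      config$cutsite_iterations, seed = mix_seed(config$seed, 12L, pi))
    utils::write.table(posw, tag("positionwise"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  # distances (linear always; 3D when a structure is configured)
  structure_model <- NULL
  if (!is.null(config$pdb) && protein$id %in% names(config$pdb)) {
    structure_model <- read_ca_coordinates(
      config$pdb[[protein$id]], chain = config$pdb_chain,
      offset = config$pdb_offset, protein_id = protein$id)
  }
  distances <- if (nrow(regions) > 0 && length(sites$positions) > 0) {
    region_distances(regions, sites, protein$length, structure_model,
                     config$distance_iterations,
                     seed = mix_seed(config$seed, 13L, pi))
  } else {
    data.frame(protein_id = character(0), start = integer(0),
               end = integer(0), direction = character(0),
               metric = character(0), actual = numeric(0),
               expected = numeric(0), actual_minus_expected = numeric(0))
  }

  # binding cores (only when predictions cover this protein's peptides)
  core_summary <- NULL
  if (!is.null(affinity)) {
    qspace <- .peptide_space_sequences(peptides, "citrullinated")
    relevant <- affinity[affinity$peptide %in% c(peptides$peptide, qspace), ,
                         drop = FALSE]
    if (nrow(relevant) > 0) {
      cores <- select_putative_cores(relevant,
                                     threshold = config$affinity_threshold)
      built <- suppressWarnings(build_binding_cores(
        cores, peptides, protein, sites, config$native_label,
        config$cit_label, config$core_margin))
      utils::write.table(built, tag("cores"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      core_summary <- summarize_core_repertoire(built)
    }
  }

  n_created <- sum(regions$direction == "created")
  n_destroyed <- sum(regions$direction == "destroyed")
  list(
    summary = list(
      n_peptides = nrow(peptides),
      n_citrulline_sites = length(sites$positions),
      change_score = score$score,
      pct_sequence_changed = pct_seq,
      n_created_regions = n_created,
      n_destroyed_regions = n_destroyed,
      pct_created_regions_with_citrulline = if (n_created > 0)
        100 * sum(regions$contains_citrulline &
                    regions$direction == "created") / n_created else NA,
      n_cut_sites = nrow(cut_sites),
      cutsite_bootstrap = if (!is.null(cut_boot))
        unclass(cut_boot) else NULL,
      positionwise = posw,
      core_summary = core_summary,
      skipped = c(if (is.null(structure_model)) "euclidean_distance",
                  if (is.null(affinity)) "binding_cores")
    ),
    pooled = list(novel_bonds = novel, cit_positions = sites$positions,
                  eligible = eligible, protein_length = protein$length),
    score_row = data.frame(
      protein_id = protein$id,
      change_score = score$score,
      pct_sequence_changed = pct_seq,
      arg_frequency = arginine_frequency(protein),
      stringsAsFactors = FALSE),
    distances = distances
  )
}

# Pooled cut-site bootstrap across proteins: each protein's citrullines
# are shuffled within its own eligible set; the pooled statistic is the
# summed windowed count.
.pooled_cutsite_bootstrap <- function(pooled_sites, config) {
  pooled_sites <- Filter(function(p) {
    length(p$novel_bonds) > 0 && length(p$cit_positions) > 0 &&
      length(p$cit_positions) <= length(p$eligible)
  }, pooled_sites)
  if (length(pooled_sites) == 0) return(NULL)
  iters <- config$cutsite_iterations
  observed <- 0
  null_total <- numeric(iters)
  for (k in seq_along(pooled_sites)) {
    p <- pooled_sites[[k]]
    mult <- .window_multiplicity(p$novel_bonds, p$protein_length,
                                 c(-1L, 2L))
    observed <- observed + sum(mult[p$cit_positions])
    null_total <- null_total + with_seed(
      mix_seed(config$seed, 14L, k), {
        vapply(seq_len(iters), function(it) {
          sum(mult[sample(p$eligible, length(p$cit_positions))])
        }, numeric(1))
      })
  }
  unclass(bootstrap_result(observed, null_total, iters,
                           config$seed, tail = "ge"))
}
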