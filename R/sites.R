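# Citrullination-site filtering.  Raw per-residue evidence (how much of the
# signal covering an arginine carries citrulline) is turned into a filtered
# site set with a dual threshold on citrullination frequency and abundance,
# separating genuinely citrullinated residues from trace deamidation noise.

#' Per-arginine citrullination evidence from located peptides
#'
#' For every arginine of the protein, sums the abundance (over replicates of
#' the given condition) of all peptides spanning it; the citrullinated share
#' is the same sum restricted to peptides carrying citrulline at that
#' residue.  Arginines with no covering peptides yield zero evidence.
#'
#' @param peptides Peptide data frame (see [read_peptide_table()]) with
#'   `start`/`end` coordinates on `protein`.
#' @param protein A [protein_record()].
#' @param condition Condition label whose replicates are summed.
#' @return `data.frame` with one row per arginine: `protein_id`, `residue`,
#'   `condition`, `cit_abundance`, `total_abundance`, `fraction`.
#' @export
compute_site_evidence <- function(peptides, protein, condition) {
  arg_pos <- which(protein_chars(protein) == "R")
  ab <- if (nrow(peptides) > 0)
    rowSums(peptide_abundances(peptides, condition)) else numeric(0)
  total <- numeric(length(arg_pos))
  cit <- numeric(length(arg_pos))
  for (k in seq_along(arg_pos)) {
    r <- arg_pos[[k]]
    span <- which(peptides$start <= r & peptides$end >= r)
    if (length(span) == 0) next
    total[[k]] <- sum(ab[span])
    carries <- span[vapply(peptides$cit_positions[span],
                           function(p) r %in% p, logical(1))]
    cit[[k]] <- sum(ab[carries])
  }
  data.frame(
    protein_id = protein$id,
    residue = arg_pos,
    condition = condition,
    cit_abundance = cit,
    total_abundance = total,
    fraction = ifelse(total > 0, cit / total, 0),
    stringsAsFactors = FALSE
  )
}

#' Filter site evidence with the dual threshold
#'
#' A residue is kept when its citrullination fraction is at least
#' `min_fraction` *and* its citrullinated abundance is at least
#' `min_abundance`.  The defaults (10% and 1e6 LFQ units) are the values
#' used for the downstream analyses throughout the package.
#'
#' @param evidence Evidence data frame from [compute_site_evidence()].
#' @param min_fraction Minimum citrullination fraction (default 0.10).
#' @param min_abundance Minimum abundance in LFQ units (default 1e6).
#' @param abundance_measure Which abundance the threshold applies to:
#'   `"citrullinated"` (default; the citrullinated share of the residue's
#'   signal) or `"total"` (all signal covering the residue).
#' @return A [cit_site_set()]; its `evidence` element carries all rows with
#'   a logical `kept` column.
#' @export
filter_sites <- function(evidence, min_fraction = 0.10, min_abundance = 1e6,
                         abundance_measure = c("citrullinated", "total")) {
  abundance_measure <- match.arg(abundance_measure)
  stopifnot(min_fraction >= 0, min_abundance >= 0)
  ab <- if (abundance_measure == "citrullinated") evidence$cit_abundance
        else evidence$total_abundance
  kept <- evidence$fraction >= min_fraction & ab >= min_abundance
  ev <- evidence
  ev$kept <- kept
  cit_site_set(
    protein_id = unique(evidence$protein_id)[[1]] %||% NA_character_,
    condition = unique(evidence$condition)[[1]] %||% NA_character_,
    positions = evidence$residue[kept],
    evidence = ev
  )
}

#' Threshold sweep over a grid of filter settings
#'
#' Reports, for every (fraction, abundance) grid point, the number of
#' residues kept per condition present in `evidence`.  Used to choose a
#' threshold pair that excludes most residues evidenced in the native
#' condition (trace deamidation) while preserving sites in the
#' citrullinated conditions.
#'
#' @param evidence Evidence rows, possibly spanning several conditions.
#' @param fraction_grid Numeric vector of fraction thresholds.
#' @param abundance_grid Numeric vector of abundance thresholds.
#' @param abundance_measure Passed to [filter_sites()].
#' @return `data.frame` with `min_fraction`, `min_abundance` and one
#'   `n_kept_<condition>` column per condition.
#' @export
sweep_thresholds <- function(evidence, fraction_grid, abundance_grid,
                             abundance_measure = c("citrullinated", "total")) {
  abundance_measure <- match.arg(abundance_measure)
  stopifnot(length(fraction_grid) > 0, length(abundance_grid) > 0)
  conditions <- unique(evidence$condition)
  grid <- expand.grid(min_fraction = fraction_grid,
                      min_abundance = abundance_grid,
                      KEEP.OUT.ATTRS = FALSE)
  counts <- matrix(0L, nrow(grid), length(conditions),
                   dimnames = list(NULL, paste0("n_kept_", conditions)))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_along(conditions)) {
      ev <- evidence[evidence$condition == conditions[[j]], , drop = FALSE]
      ss <- filter_sites(ev, grid$min_fraction[[i]], grid$min_abundance[[i]],
                         abundance_measure)
      counts[i, j] <- length(ss$positions)
    }
  }
  cbind(grid, as.data.frame(counts))
}

#' Merge site evidence from two mapping experiments
#'
#' Citrullination evidence can come from more than one experiment (e.g. a
#' tryptic site-mapping digest and the antigen-processing digest itself).
#' A residue passing the dual threshold in *either* source is incorporated.
#'
#' @param primary,secondary Evidence data frames for the same protein and
#'   condition.
#' @param ... Threshold arguments passed to [filter_sites()].
#' @return A [cit_site_set()] with the union of passing residues.
#' @export
merge_site_evidence <- function(primary, secondary, ...) {
  pid1 <- unique(primary$protein_id)
  pid2 <- unique(secondary$protein_id)
  if (!identical(sort(pid1), sort(pid2))) {
    stop("protein-id mismatch between evidence sources: ",
         paste(pid1, collapse = ","), " vs ", paste(pid2, collapse = ","))
  }
  s1 <- filter_sites(primary, ...)
  s2 <- filter_sites(secondary, ...)
  cit_site_set(
    protein_id = s1$protein_id,
    condition = s1$condition,
    positions = union(s1$positions, s2$positions),
    evidence = rbind(s1$evidence, s2$evidence)
  )
}

#' Write a site set as a TSV report
#'
#' @param sites A [cit_site_set()] whose evidence carries a `kept` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  ev <- sites$evidence
  if (is.null(ev)) {
    ev <- data.frame(protein_id = sites$protein_id, residue = sites$positions,
                     condition = sites$condition, fraction = NA_real_,
                     cit_abundance = NA_real_, kept = TRUE)
  }
  utils::write.table(
    ev[c("protein_id", "residue", "condition", "fraction", "cit_abundance",
         "kept")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
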