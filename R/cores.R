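# MHC class II binding-core repertoire analysis.  Binding predictions made
# on the digest peptides (in citrulline-as-glutamine sequence space) are
# aggregated into putative 9-mer binding cores for the RA-associated
# shared-epitope (SE) HLA-DRB1 alleles, each core's abundance is quantified
# in the native and citrullinated repertoires, and cores are classified by
# their response to citrullination and by citrulline anchor position.

#' The five RA-associated shared-epitope HLA-DRB1 alleles
#'
#' @return Character vector of allele names.
#' @export
se_alleles <- function() {
  c("DRB1*01:01", "DRB1*04:01", "DRB1*04:04", "DRB1*04:05", "DRB1*10:01")
}

# Allele labels drift across tools ("DRB1_0401", "HLA-DRB1*04:01", ...);
# compare on an alphanumeric canonical form.
.normalize_allele <- function(x) {
  gsub("[^A-Z0-9]", "", toupper(sub("^HLA-", "", x)))
}

#' Substitute citrullines with glutamine in a protein sequence
#'
#' Citrulline has no standard one-letter code; glutamine carries the same
#' terminal side-chain amide and neutral charge and is the conventional
#' stand-in for sequence-based predictors.  Offsets are unchanged, so
#' Q-space coordinates map one-to-one onto protein coordinates.
#'
#' @param protein A [protein_record()].
#' @param cit_sites A [cit_site_set()] (all positions must be arginines).
#' @return Character scalar: the Q-substituted sequence.
#' @export
substitute_citrullines <- function(protein, cit_sites) {
  chars <- protein_chars(protein)
  pos <- cit_sites$positions
  if (length(pos) == 0) return(protein$sequence)
  bad <- pos[chars[pos] != "R"]
  if (length(bad) > 0) {
    stop("position ", bad[[1]], " is not an arginine in '", protein$id, "'")
  }
  chars[pos] <- "Q"
  paste(chars, collapse = "")
}

#' Select putative binding cores from affinity predictions
#'
#' Predictions are grouped by 9-mer core sequence; a core is retained when
#' its minimum predicted affinity over the SE alleles is strictly below
#' `threshold` (default 500 nM).  Unknown allele labels raise an error
#' naming the five SE alleles.
#'
#' @param predictions Data frame from [read_affinity_table()].
#' @param alleles Allele set (default [se_alleles()]).
#' @param threshold Retention threshold in nM, strict `<` (default 500).
#' @return `data.frame` with `core`, `best_affinity_nm`, `best_allele`, and
#'   a list column `allele_affinities` of per-allele minima.
#' @export
select_putative_cores <- function(predictions, alleles = se_alleles(),
                                  threshold = 500) {
  norm_pred <- .normalize_allele(predictions$allele)
  norm_se <- .normalize_allele(alleles)
  unknown <- unique(predictions$allele[!(norm_pred %in% norm_se)])
  if (length(unknown) > 0) {
    stop("unknown allele label(s) ", paste(unknown, collapse = ", "),
         "; expected the SE alleles: ", paste(se_alleles(), collapse = ", "))
  }
  split_idx <- split(seq_len(nrow(predictions)), predictions$core)
  rows <- lapply(names(split_idx), function(core) {
    idx <- split_idx[[core]]
    per_allele <- tapply(predictions$affinity_nm[idx], norm_pred[idx], min)
    best <- min(per_allele)
    data.frame(core = core, best_affinity_nm = best,
               best_allele = alleles[match(names(per_allele)[which.min(per_allele)],
                                           norm_se)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  aff <- lapply(names(split_idx), function(core) {
    idx <- split_idx[[core]]
    tapply(predictions$affinity_nm[idx], norm_pred[idx], min)
  })
  out$allele_affinities <- aff
  out <- out[out$best_affinity_nm < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Observed sequence of each peptide in the requested sequence space: the
# citrullinated sample's peptides carry Q at their modified positions, the
# native sample's carry the stored (native, R) letters.
.peptide_space_sequences <- function(peptides, space) {
  if (space == "native") return(peptides$peptide)
  vapply(seq_len(nrow(peptides)), function(i) {
    pos <- peptides$cit_positions[[i]]
    if (length(pos) == 0) return(peptides$peptide[[i]])
    chars <- strsplit(peptides$peptide[[i]], "", fixed = TRUE)[[1]]
    rel <- pos - peptides$start[[i]] + 1L
    rel <- rel[rel >= 1L & rel <= length(chars)]
    chars[rel] <- "Q"
    paste(chars, collapse = "")
  }, character(1))
}

#' Abundance of a binding core in one condition
#'
#' Sums the replicate-summed abundance of every peptide whose observed
#' sequence contains the core as a substring.  Matching is performed in
#' the condition-appropriate sequence space: the citrullinated sample's
#' peptides are rendered with Q at their citrulline positions, so a
#' citrulline-containing core matches citrulline-carrying peptides but not
#' their native-arginine counterparts, and vice versa.
#'
#' @param core 9-mer core sequence (Q-substituted space for citrullinated
#'   repertoires).
#' @param peptides Peptide data frame.
#' @param condition Condition label whose replicates are summed.
#' @param space `"native"` or `"citrullinated"`.
#' @return LFQ abundance sum.
#' @export
core_abundance <- function(core, peptides, condition,
                           space = c("native", "citrullinated")) {
  space <- match.arg(space)
  if (nrow(peptides) == 0) return(0)
  seqs <- .peptide_space_sequences(peptides, space)
  hit <- grepl(core, seqs, fixed = TRUE)
  if (!any(hit)) return(0)
  sum(rowSums(peptide_abundances(peptides[hit, , drop = FALSE], condition)))
}

#' Classify a binding core by its response to citrullination
#'
#' `created` when only present in the citrullinated sample, `destroyed`
#' when only in the native sample, `enriched`/`reduced` at a 50% margin
#' (citrullinated abundance at least 1.5x, or at most 0.5x, the native),
#' otherwise `unchanged`.
#'
#' @param native_abundance,cit_abundance Non-negative abundances, not both
#'   zero.
#' @param margin Enrichment margin (default 0.5, i.e. +/-50%).
#' @return One of `"created"`, `"destroyed"`, `"enriched"`, `"reduced"`,
#'   `"unchanged"`.
#' @export
classify_core <- function(native_abundance, cit_abundance, margin = 0.5) {
  stopifnot(native_abundance >= 0, cit_abundance >= 0)
  if (native_abundance == 0 && cit_abundance == 0) {
    stop("core with zero abundance in both conditions")
  }
  if (native_abundance == 0) return("created")
  if (cit_abundance == 0) return("destroyed")
  if (cit_abundance >= (1 + margin) * native_abundance) return("enriched")
  if (cit_abundance <= (1 - margin) * native_abundance) return("reduced")
  "unchanged"
}

#' Citrulline anchor status of a binding core
#'
#' Pockets P1, P4, P6 and P9 of the HLA-DR groove hold the anchor residues
#' of the 9-mer core; a citrulline at any other core position faces the
#' T-cell receptor.
#'
#' @param core_start,core_end Core coordinates on the protein (1-based
#'   inclusive; `core_end = core_start + 8`).
#' @param cit_positions Citrulline positions (protein coordinates).
#' @param anchor_offsets Core offsets regarded as anchors (default
#'   `c(1, 4, 6, 9)`).
#' @return `"anchor"`, `"tcr_contact"`, or `"none"` when the core contains
#'   no citrulline.
#' @export
annotate_citrulline_anchors <- function(core_start, core_end, cit_positions,
                                        anchor_offsets = c(1L, 4L, 6L, 9L)) {
  inside <- cit_positions[cit_positions >= core_start &
                            cit_positions <= core_end]
  if (length(inside) == 0) return("none")
  offsets <- inside - core_start + 1L
  if (any(offsets %in% anchor_offsets)) "anchor" else "tcr_contact"
}

#' Assemble the classified binding-core repertoire for one protein
#'
#' Maps each retained core onto the Q-substituted protein sequence,
#' quantifies it in both repertoires, classifies its response to
#' citrullination and annotates citrulline anchor status.  Cores that match
#' no peptide in either repertoire cannot be classified and are dropped
#' with a warning.
#'
#' @param cores Data frame from [select_putative_cores()].
#' @param peptides Peptide data frame.
#' @param protein A [protein_record()].
#' @param cit_sites A [cit_site_set()].
#' @param native,cit Condition labels.
#' @param margin Enrichment margin (default 0.5).
#' @return `data.frame` with core coordinates, abundances, `class`,
#'   `contains_citrulline`, `anchor_status`, `best_affinity_nm`.
#' @export
build_binding_cores <- function(cores, peptides, protein, cit_sites,
                                native = "native", cit = "cit",
                                margin = 0.5) {
  qseq <- substitute_citrullines(protein, cit_sites)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(cores))) {
    core <- cores$core[[i]]
    at <- regexpr(core, qseq, fixed = TRUE)
    core_start <- if (at > 0) as.integer(at) else NA_integer_
    nat_ab <- core_abundance(core, peptides, native, space = "native")
    cit_ab <- core_abundance(core, peptides, cit, space = "citrullinated")
    if (nat_ab == 0 && cit_ab == 0) {
      dropped <- dropped + 1L
      next
    }
    status <- if (is.na(core_start)) "none" else
      annotate_citrulline_anchors(core_start, core_start + 8L,
                                  cit_sites$positions)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = protein$id, core = core,
      core_start = core_start,
      core_end = if (is.na(core_start)) NA_integer_ else core_start + 8L,
      native_abundance = nat_ab, cit_abundance = cit_ab,
      class = classify_core(nat_ab, cit_ab, margin),
      contains_citrulline = status != "none",
      anchor_status = status,
      best_affinity_nm = cores$best_affinity_nm[[i]],
      stringsAsFactors = FALSE)
  }
  if (dropped > 0) {
    warning(dropped, " core(s) matched no peptide in either repertoire; ",
            "dropped")
  }
  if (length(rows) == 0) {
    return(data.frame(protein_id = character(0), core = character(0),
                      core_start = integer(0), core_end = integer(0),
                      native_abundance = numeric(0),
                      cit_abundance = numeric(0), class = character(0),
                      contains_citrulline = logical(0),
                      anchor_status = character(0),
                      best_affinity_nm = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Compare affinity distributions of created and destroyed repertoires
#'
#' Nonparametric two-sided Mann-Whitney U test of the predicted affinities
#' of the created versus destroyed cores (or peptides).
#'
#' @param created_affinities,destroyed_affinities Non-empty numeric
#'   vectors of affinities in nM.
#' @return List with `U`, `p_value`, `median_created`, `median_destroyed`.
#' @export
compare_affinity_distributions <- function(created_affinities,
                                           destroyed_affinities) {
  if (length(created_affinities) == 0 || length(destroyed_affinities) == 0) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(created_affinities, destroyed_affinities,
                       alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       median_created = stats::median(created_affinities),
       median_destroyed = stats::median(destroyed_affinities))
}

#' Composition summary of a classified core repertoire
#'
#' @param cores Data frame from [build_binding_cores()].
#' @return List with per-class counts and percentages, the percentage of
#'   enriched-or-created cores, the citrulline-containing fraction within
#'   the enriched/created cores, and the anchor fraction within those.
#' @export
summarize_core_repertoire <- function(cores) {
  classes <- c("created", "enriched", "unchanged", "reduced", "destroyed")
  counts <- vapply(classes, function(cl) sum(cores$class == cl), integer(1))
  n <- nrow(cores)
  up <- cores[cores$class %in% c("created", "enriched"), , drop = FALSE]
  up_cit <- up[up$contains_citrulline, , drop = FALSE]
  list(
    n_cores = n,
    counts = counts,
    percentages = if (n > 0) 100 * counts / n else counts * NA_real_,
    pct_enriched_or_created = if (n > 0) 100 * nrow(up) / n else NA_real_,
    pct_reduced_or_destroyed = if (n > 0)
      100 * sum(counts[c("reduced", "destroyed")]) / n else NA_real_,
    pct_citrulline_in_up = if (nrow(up) > 0)
      100 * nrow(up_cit) / nrow(up) else NA_real_,
    pct_anchor_in_citrulline = if (nrow(up_cit) > 0)
      100 * sum(up_cit$anchor_status == "anchor") / nrow(up_cit)
      else NA_real_
  )
}
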