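# Enrichment mapping: per-residue log2 enrichment profiles along the
# protein, calling of created/destroyed regions, differential peptide
# testing (paired t-tests with two-stage FDR), and the antigen processing
# change score with its regressions.

#' Per-residue abundance sums for one condition
#'
#' Each residue receives the summed abundance (over replicates of the
#' condition) of every peptide whose span contains it.
#'
#' @param peptides Peptide data frame with `start`/`end` coordinates.
#' @param protein A [protein_record()].
#' @param condition Condition label.
#' @return Numeric vector of length `protein$length`.
#' @export
residue_sums <- function(peptides, protein, condition) {
  sums <- numeric(protein$length)
  if (nrow(peptides) == 0) return(sums)
  ab <- rowSums(peptide_abundances(peptides, condition))
  for (i in seq_len(nrow(peptides))) {
    if (ab[[i]] == 0) next
    span <- peptides$start[[i]]:peptides$end[[i]]
    sums[span] <- sums[span] + ab[[i]]
  }
  sums
}

#' Build a per-residue log2 enrichment profile
#'
#' `log2(cit/native)` wherever both sums are positive; residues covered in
#' only one condition receive a capped sentinel (`+cap` for
#' citrullinated-only coverage, `-cap` for native-only); residues covered in
#' neither are masked (`NA`).
#'
#' @param native_sums,cit_sums Equal-length non-negative vectors from
#'   [residue_sums()].
#' @param cap Sentinel magnitude for one-sided coverage (default 10).
#' @param coverage_threshold Abundance regarded as adequate coverage for a
#'   residue (default 1e6); drives the `high_coverage` mask used as the
#'   eligible set of the cut-site bootstrap.
#' @param protein_id,conditions Labels stored on the profile.
#' @return Object of class `residue_profile` with elements `native_sum`,
#'   `cit_sum`, `log2_enrichment`, `covered`, `high_coverage`, `cap`.
#' @export
log2_profile <- function(native_sums, cit_sums, cap = 10,
                         coverage_threshold = 1e6,
                         protein_id = NA_character_,
                         conditions = c(native = "native", cit = "cit")) {
  if (length(native_sums) != length(cit_sums)) {
    stop("native and citrullinated sum vectors differ in length")
  }
  if (any(native_sums < 0) || any(cit_sums < 0)) {
    stop("abundance sums must be non-negative")
  }
  log2e <- rep(NA_real_, length(native_sums))
  both <- native_sums > 0 & cit_sums > 0
  log2e[both] <- log2(cit_sums[both] / native_sums[both])
  log2e[both] <- pmin(pmax(log2e[both], -cap), cap)
  log2e[native_sums == 0 & cit_sums > 0] <- cap
  log2e[cit_sums == 0 & native_sums > 0] <- -cap
  structure(
    list(protein_id = protein_id, conditions = conditions,
         native_sum = native_sums, cit_sum = cit_sums,
         log2_enrichment = log2e,
         covered = native_sums > 0 | cit_sums > 0,
         high_coverage = pmax(native_sums, cit_sums) >= coverage_threshold,
         cap = cap),
    class = "residue_profile"
  )
}

#' @export
print.residue_profile <- function(x, ...) {
  cat("<residue_profile>", x$protein_id, "-", length(x$log2_enrichment),
      "residues,", sum(x$covered), "covered\n")
  invisible(x)
}

#' Call created and destroyed regions from an enrichment profile
#'
#' Created regions are maximal runs of contiguous residues with
#' `log2(enrichment) >= threshold`; destroyed regions are runs with
#' `log2(enrichment) <= -threshold`.  Masked (uncovered) residues break
#' runs.
#'
#' @param profile A `residue_profile`.
#' @param threshold Enrichment threshold (default 1, i.e. twofold).
#' @param cit_sites Optional [cit_site_set()] to set `contains_citrulline`.
#' @return `data.frame` with `protein_id`, `start`, `end`, `direction`
#'   (`"created"`/`"destroyed"`), `contains_citrulline`, `mean_log2e`,
#'   sorted by `start`.
#' @export
call_changed_regions <- function(profile, threshold = 1.0, cit_sites = NULL) {
  log2e <- profile$log2_enrichment
  lab <- rep(NA_character_, length(log2e))
  lab[!is.na(log2e) & log2e >= threshold] <- "created"
  lab[!is.na(log2e) & log2e <= -threshold] <- "destroyed"
  r <- rle(ifelse(is.na(lab), "<none>", lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "<none>"
  out <- data.frame(
    protein_id = rep(profile$protein_id, sum(keep)),
    start = starts[keep], end = ends[keep],
    direction = r$values[keep],
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0) {
    out$contains_citrulline <- logical(0)
    out$mean_log2e <- numeric(0)
    return(out)
  }
  cit <- if (is.null(cit_sites)) integer(0) else cit_sites$positions
  out$contains_citrulline <- mapply(function(s, e) any(cit >= s & cit <= e),
                                    out$start, out$end)
  out$mean_log2e <- mapply(function(s, e) mean(log2e[s:e]),
                           out$start, out$end)
  out[order(out$start), , drop = FALSE]
}

#' Two-stage step-up false discovery rate adjustment
#'
#' The two-stage linear step-up procedure: a first Benjamini-Hochberg pass
#' at level `alpha / (1 + alpha)` estimates the number of true nulls `m0`;
#' the adjusted values are then the BH-adjusted p-values rescaled by
#' `(m0 / m) * (1 + alpha)` (no rescaling when the first stage rejects
#' nothing or everything).  Results are clipped at 1.
#'
#' @param p Numeric vector of raw p-values.
#' @param alpha Nominal FDR level the procedure is run at (default 0.05).
#' @return Vector of adjusted q-values, same length and order as `p`.
#' @export
bky_adjust <- function(p, alpha = 0.05) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  bh <- stats::p.adjust(p, method = "BH")
  r1 <- sum(bh <= alpha / (1 + alpha))
  fac <- if (r1 == 0 || r1 == m) (1 + alpha) else (m - r1) / m * (1 + alpha)
  pmin(1, bh * fac)
}

#' Differential abundance testing of peptides
#'
#' Each peptide's per-replicate abundances are compared between the native
#' and citrullinated conditions by a paired two-sided Student's t-test
#' (replicates paired by index); p-values are FDR-adjusted across all
#' peptides of the run by the two-stage step-up procedure
#' ([bky_adjust()]).  Significance requires `q <= alpha` *and* at least
#' `fold`-fold enrichment or depletion.  Significant peptides absent
#' (all-zero) in exactly one condition are classed `created` or
#' `destroyed`; other significant peptides are `enriched`/`reduced`;
#' everything else is `unchanged`.
#'
#' @param peptides Peptide data frame.
#' @param native,cit Condition labels for the two members of each pair.
#' @param alpha FDR level (default 0.05).
#' @param fold Fold-change gate (default 2).
#' @param log_transform Run the t-test on `log2(x + 1)`-transformed
#'   abundances instead of raw intensities (default `FALSE`).
#' @return `data.frame` with one row per peptide: `peptide`, `start`, `end`,
#'   `native_mean`, `cit_mean`, `fold_change` (`Inf` when the native mean is
#'   zero), `t`, `p`, `q`, `class`.
#' @export
differential_peptides <- function(peptides, native = "native", cit = "cit",
                                  alpha = 0.05, fold = 2,
                                  log_transform = FALSE) {
  nat_m <- peptide_abundances(peptides, native)
  cit_m <- peptide_abundances(peptides, cit)
  if (ncol(nat_m) != ncol(cit_m)) {
    stop("conditions '", native, "' and '", cit,
         "' have different replicate counts; replicates must be paired")
  }
  if (ncol(nat_m) < 2) stop("at least 2 paired replicates are required")
  n <- nrow(peptides)
  tstat <- p <- rep(NA_real_, n)
  degenerate_equal <- logical(n)
  for (i in seq_len(n)) {
    x <- cit_m[i, ]
    y <- nat_m[i, ]
    if (log_transform) {
      x <- log2(x + 1)
      y <- log2(y + 1)
    }
    d <- x - y
    if (stats::sd(d) == 0) {
      # Zero within-pair variance: no sampling variability to test against.
      if (d[[1]] == 0) {
        tstat[[i]] <- 0
        p[[i]] <- 1
        degenerate_equal[[i]] <- TRUE
      } else {
        tstat[[i]] <- sign(d[[1]]) * Inf
        p[[i]] <- 0
      }
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      tstat[[i]] <- unname(tt$statistic)
      p[[i]] <- tt$p.value
    }
  }
  q <- bky_adjust(p, alpha)
  q[degenerate_equal] <- 1  # no sampling variability at all: never called
  nat_mean <- rowMeans(nat_m)
  cit_mean <- rowMeans(cit_m)
  fc <- ifelse(nat_mean > 0, cit_mean / nat_mean,
               ifelse(cit_mean > 0, Inf, NA_real_))
  significant <- !is.na(fc) & q <= alpha & (fc >= fold | fc <= 1 / fold)
  class <- rep("unchanged", n)
  class[significant & fc >= fold] <- "enriched"
  class[significant & fc <= 1 / fold] <- "reduced"
  class[significant & nat_mean == 0] <- "created"
  class[significant & cit_mean == 0] <- "destroyed"
  data.frame(
    peptide = peptides$peptide, start = peptides$start, end = peptides$end,
    native_mean = nat_mean, cit_mean = cit_mean, fold_change = fc,
    t = tstat, p = p, q = q, class = class,
    stringsAsFactors = FALSE
  )
}

#' Fraction of the protein sequence significantly changed
#'
#' 100 times the number of residues spanned by at least one significantly
#' changed peptide, divided by the number of residues with coverage (or the
#' full protein length).
#'
#' @param results Output of [differential_peptides()].
#' @param profile The `residue_profile` of the same run.
#' @param denominator `"covered"` (default) or `"full_length"`.
#' @return Percentage in `[0, 100]`.
#' @export
fraction_sequence_changed <- function(results, profile,
                                      denominator = c("covered",
                                                      "full_length")) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "covered") sum(profile$covered)
           else length(profile$covered)
  if (denom == 0) stop("protein has no covered residues")
  sig <- results[results$class != "unchanged", , drop = FALSE]
  hit <- logical(length(profile$covered))
  for (i in seq_len(nrow(sig))) hit[sig$start[[i]]:sig$end[[i]]] <- TRUE
  100 * sum(hit) / denom
}

#' Antigen processing change score
#'
#' The percentage of all identified peptides that were significantly
#' changed in abundance between the native and citrullinated samples
#' (enriched/created and reduced/destroyed alike).
#'
#' @param results Output of [differential_peptides()].
#' @return List with `n_peptides_total`, `n_peptides_significant`, `score`.
#' @export
change_score <- function(results) {
  if (nrow(results) == 0) stop("no peptides to score")
  n_sig <- sum(results$class != "unchanged")
  list(n_peptides_total = nrow(results),
       n_peptides_significant = n_sig,
       score = 100 * n_sig / nrow(results))
}

#' Arginine frequency of a protein
#'
#' @param protein A [protein_record()].
#' @return Percentage of residues that are arginine.
#' @export
arginine_frequency <- function(protein) {
  100 * sum(protein_chars(protein) == "R") / protein$length
}

#' Simple linear regression of change scores on an explanatory variable
#'
#' Ordinary least squares of change score against arginine frequency, RMSD,
#' or 1/TM-score.
#'
#' @param x Explanatory values (>= 2 points, not all identical).
#' @param y Change scores.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fit_change_score_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 2) stop("at least 2 points are required")
  if (length(unique(x)) == 1) stop("all x values are identical")
  if (stats::var(y) == 0) {
    # flat response: no variance to explain
    return(list(slope = 0, intercept = mean(y), r_squared = 0))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an exact fit; r^2 = 1 is the correct answer there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(stats::coef(fit)[["x"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       r_squared = r2)
}

#' Write a residue profile as TSV
#'
#' @param profile A `residue_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  utils::write.table(
    data.frame(residue = seq_along(profile$log2_enrichment),
               native_sum = profile$native_sum,
               cit_sum = profile$cit_sum,
               log2_enrichment = profile$log2_enrichment,
               covered = profile$covered,
               high_coverage = profile$high_coverage),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write changed regions in a BED-like TSV (0-based half-open spans)
#'
#' Internally all coordinates are 1-based inclusive; only this export uses
#' the BED convention.
#'
#' @param regions Region data frame from [call_changed_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(
    data.frame(protein_id = regions$protein_id,
               start = regions$start - 1L,
               end = regions$end,
               direction = regions$direction,
               contains_citrulline = regions$contains_citrulline,
               mean_log2e = regions$mean_log2e),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
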