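# Distance from changed regions to the nearest citrulline, in the linear
# sequence and in 3D (Calpha coordinates), each compared to a bootstrap
# expected distance.  Region length and location alter the chance of lying
# near a citrulline, so the actual distance is interpreted relative to the
# null mean obtained by shuffling citrulline positions.
#
# The two metrics deliberately differ: the linear metric measures from the
# region *endpoints*; the Euclidean metric from *all* region residues.
# Likewise the eligible sets differ: the linear null shuffles over all
# residues, the 3D null over structure-covered residues, and the cut-site
# null (cleavage module) over high-coverage residues.

#' Linear sequence distance from a region to the nearest citrulline
#'
#' Zero when the region contains a citrulline; otherwise the minimum over
#' citrullines of the distance to the nearer region terminus.
#'
#' @param start,end Region coordinates (1-based inclusive).
#' @param cit_positions Non-empty integer vector of citrulline positions.
#' @return Distance in residues.
#' @export
linear_distance <- function(start, end, cit_positions) {
  if (length(cit_positions) == 0) stop("citrulline set is empty")
  if (any(cit_positions >= start & cit_positions <= end)) return(0)
  min(pmin(abs(cit_positions - start), abs(cit_positions - end)))
}

# Distance of every residue position to a fixed region (vectorised form of
# linear_distance for a single citrulline at each position).
.linear_distance_by_position <- function(start, end, protein_length) {
  pos <- seq_len(protein_length)
  d <- pmin(abs(pos - start), abs(pos - end))
  d[pos >= start & pos <= end] <- 0
  d
}

#' Bootstrap expected linear distance to citrulline
#'
#' Citrulline positions are shuffled uniformly without replacement over
#' *all* residues of the protein (no coverage mask for this null), the
#' region-to-nearest-citrulline distance recomputed each iteration, and the
#' expectation taken as the null mean.
#'
#' @param start,end Region coordinates.
#' @param n_citrullines Number of citrullines to place.
#' @param protein_length Protein length.
#' @param iterations Iterations (default 2000).
#' @param seed RNG seed.
#' @return A `bootstrap_result` (its `expected` is the null mean; the
#'   `observed` slot is `NA` since this null is used for expectation only).
#' @export
bootstrap_linear_expected <- function(start, end, n_citrullines,
                                      protein_length, iterations = 2000L,
                                      seed = 1L) {
  stopifnot(n_citrullines >= 1, n_citrullines <= protein_length)
  dvec <- .linear_distance_by_position(start, end, protein_length)
  null_d <- with_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      min(dvec[sample.int(protein_length, n_citrullines)])
    }, numeric(1))
  })
  bootstrap_result(NA_real_, null_d, iterations, seed)
}

#' 3D Euclidean distance from a region to the nearest citrulline
#'
#' Minimum over (region residue, citrulline) pairs of the Calpha-Calpha
#' Euclidean distance.  Residues or citrullines lacking coordinates are
#' skipped with a warning; if nothing usable remains, an error is raised.
#'
#' @param region_residues Integer vector of residues in the region.
#' @param cit_positions Citrulline positions.
#' @param structure A [structure_model()].
#' @return Distance in Angstrom.
#' @export
euclidean_distance <- function(region_residues, cit_positions, structure) {
  rr <- intersect(region_residues, structure$coverage)
  cc <- intersect(cit_positions, structure$coverage)
  if (length(rr) < length(region_residues) ||
      length(cc) < length(cit_positions)) {
    warning("residues without Calpha coordinates skipped in 3D distance")
  }
  if (length(rr) == 0 || length(cc) == 0) {
    stop("no usable residue/citrulline pairs with coordinates")
  }
  A <- structure$coords[match(rr, structure$coverage), , drop = FALSE]
  B <- structure$coords[match(cc, structure$coverage), , drop = FALSE]
  cross <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(cross)))
}

#' Bootstrap expected 3D distance to citrulline
#'
#' As many residues as there are citrullines are relabelled uniformly
#' among the structure-covered residues; the minimum Euclidean distance
#' from the (fixed) region to the relabelled set is recorded each
#' iteration, and the expectation taken as the null mean.
#'
#' @param region_residues Residues in the region.
#' @param n_citrullines Number of residues to relabel.
#' @param structure A [structure_model()].
#' @param iterations Iterations (default 2000).
#' @param seed RNG seed.
#' @return A `bootstrap_result`.
#' @export
bootstrap_euclidean_expected <- function(region_residues, n_citrullines,
                                         structure, iterations = 2000L,
                                         seed = 1L) {
  cov <- structure$coverage
  stopifnot(n_citrullines >= 1, n_citrullines <= length(cov))
  rr <- intersect(region_residues, cov)
  if (length(rr) == 0) stop("region has no residues with coordinates")
  A <- structure$coords[match(rr, cov), , drop = FALSE]
  B <- structure$coords
  cross <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  # column j = squared distance from residue cov[j] to nearest region residue
  dmin <- sqrt(pmax(0, apply(cross, 2, min)))
  null_d <- with_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      min(dmin[sample.int(length(cov), n_citrullines)])
    }, numeric(1))
  })
  bootstrap_result(NA_real_, null_d, iterations, seed)
}

#' Actual and expected distances for a set of changed regions
#'
#' Computes, per region, the actual distance to the nearest citrulline and
#' the bootstrap expected distance, in the linear metric and (when a
#' structure is supplied) the 3D metric.
#'
#' @param regions Region data frame from [call_changed_regions()].
#' @param cit_sites A [cit_site_set()].
#' @param protein_length Protein length.
#' @param structure Optional [structure_model()] for the 3D metric.
#' @param iterations Bootstrap iterations per region (default 2000).
#' @param seed Master seed; each region/metric draws a derived sub-seed.
#' @return `data.frame` with `protein_id`, `start`, `end`, `direction`,
#'   `metric` (`linear`/`euclidean`), `actual`, `expected`,
#'   `actual_minus_expected`.
#' @export
region_distances <- function(regions, cit_sites, protein_length,
                             structure = NULL, iterations = 2000L,
                             seed = 1L) {
  cit <- cit_sites$positions
  n_cit <- length(cit)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    s <- regions$start[[i]]
    e <- regions$end[[i]]
    act <- linear_distance(s, e, cit)
    exp_lin <- bootstrap_linear_expected(
      s, e, n_cit, protein_length, iterations,
      seed = mix_seed(seed, 1L, i))$expected
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = regions$protein_id[[i]], start = s, end = e,
      direction = regions$direction[[i]], metric = "linear",
      actual = act, expected = exp_lin,
      actual_minus_expected = act - exp_lin,
      stringsAsFactors = FALSE)
    if (!is.null(structure)) {
      rr <- s:e
      if (length(intersect(rr, structure$coverage)) == 0 ||
          length(intersect(cit, structure$coverage)) == 0) {
        warning("region ", s, "-", e,
                " excluded from 3D analysis (no coordinates)")
        next
      }
      act3 <- suppressWarnings(euclidean_distance(rr, cit, structure))
      exp3 <- bootstrap_euclidean_expected(
        rr, n_cit, structure, iterations,
        seed = mix_seed(seed, 2L, i))$expected
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = regions$protein_id[[i]], start = s, end = e,
        direction = regions$direction[[i]], metric = "euclidean",
        actual = act3, expected = exp3,
        actual_minus_expected = act3 - exp3,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), direction = character(0),
                      metric = character(0), actual = numeric(0),
                      expected = numeric(0),
                      actual_minus_expected = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Summarise actual-minus-expected distances by region direction
#'
#' Regions with `actual - expected < 0` are citrulline-proximal; those
#' with `> 0` are citrulline-distal.  Per stratum the summary reports the
#' count, median and quartiles, the proximal/distal split, and the
#' Shapiro-Wilk normality p-value of the delta values (computed with
#' `stats::shapiro.test` when the stratum size permits).
#'
#' @param distances Data frame from [region_distances()].
#' @param by Stratification columns (default `c("metric", "direction")`).
#' @return Summary `data.frame`; empty strata are omitted.
#' @export
summarize_actual_minus_expected <- function(distances,
                                            by = c("metric", "direction")) {
  if (nrow(distances) == 0) stop("no distances to summarise")
  key <- interaction(distances[by], drop = TRUE)
  out <- lapply(levels(key), function(lv) {
    d <- distances$actual_minus_expected[key == lv]
    sw <- if (length(d) >= 3 && length(d) <= 5000 && stats::sd(d) > 0) {
      stats::shapiro.test(d)$p.value
    } else NA_real_
    cbind(
      distances[key == lv, by, drop = FALSE][1, , drop = FALSE],
      data.frame(n = length(d), median = stats::median(d),
                 q1 = unname(stats::quantile(d, 0.25)),
                 q3 = unname(stats::quantile(d, 0.75)),
                 n_proximal = sum(d < 0), n_distal = sum(d > 0),
                 shapiro_p = sw))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
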