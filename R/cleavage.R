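# Cleavage-site analysis.  Exopeptidase trimming blurs peptide termini, so
# conserved cut sites are not read off peptide ends; instead, steps in the
# per-residue log2 enrichment profile (local extrema of its discrete
# derivative) mark bonds where differential cleavage changed.  Citrulline
# association at those bonds is tested against a bootstrap null that
# shuffles citrulline positions over residues with adequate MS coverage.
#
# Window nomenclature (Schechter-Berger): for the bond between residues i
# and i+1, P1 = residue i, P1' = residue i+1, P2 = i-1, P2' = i+2, etc.

#' Discrete derivative of a log2 enrichment profile
#'
#' `d[i] = log2E[i+1] - log2E[i]` for bonds `i = 1 .. L-1`.  Bonds adjacent
#' to masked residues are masked (`NA`), so coverage boundaries cannot
#' produce spurious extrema.
#'
#' @param profile A `residue_profile` (length >= 2).
#' @return Numeric vector of length `L - 1`, indexed by bond.
#' @export
profile_derivative <- function(profile) {
  log2e <- profile$log2_enrichment
  L <- length(log2e)
  if (L < 2) stop("profile must cover at least 2 residues")
  diff(log2e)  # NA wherever either flanking residue is masked
}

#' Detect candidate cut sites from the derivative
#'
#' Bond `i` is reported when `|d[i]| >= threshold` and `|d[i]|` is a strict
#' local maximum of `|d|` among its unmasked neighbours.  A plateau of
#' equal `|d|` values is reported once, at its leftmost bond.  The default
#' threshold log2(1.3) suppresses minor cut sites that barely change
#' abundance.
#'
#' @param derivative Vector from [profile_derivative()].
#' @param threshold Detection threshold on `|d|` (default `log2(1.3)`).
#' @param min_separation Minimum bond distance between reported sites
#'   (default 1, i.e. no suppression); when two sites fall closer, the one
#'   with the larger `|d|` is kept.
#' @return `data.frame` with `bond`, `derivative`, `sign` (+1/-1).
#' @export
detect_cut_sites <- function(derivative, threshold = log2(1.3),
                             min_separation = 1L) {
  a <- abs(derivative)
  n <- length(a)
  bonds <- integer(0)
  # walk maximal unmasked segments; compare run-length-encoded plateaus
  seg_start <- NULL
  flush <- function(s, e) {
    if (is.null(s)) return(invisible(NULL))
    vals <- a[s:e]
    r <- rle(vals)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      v <- r$values[[k]]
      if (v < threshold) next
      left_ok <- k == 1L || r$values[[k - 1L]] < v
      right_ok <- k == length(r$values) || r$values[[k + 1L]] < v
      if (left_ok && right_ok) bonds <<- c(bonds, s + starts[[k]] - 1L)
    }
    invisible(NULL)
  }
  i <- 1L
  while (i <= n) {
    if (is.na(a[[i]])) {
      i <- i + 1L
      next
    }
    s <- i
    while (i <= n && !is.na(a[[i]])) i <- i + 1L
    flush(s, i - 1L)
  }
  bonds <- sort(bonds)
  if (min_separation > 1L && length(bonds) > 1L) {
    keep <- rep(TRUE, length(bonds))
    for (k in 2:length(bonds)) {
      prev <- max(which(keep[1:(k - 1L)]))
      if (bonds[[k]] - bonds[[prev]] < min_separation) {
        if (a[[bonds[[k]]]] > a[[bonds[[prev]]]]) keep[[prev]] <- FALSE
        else keep[[k]] <- FALSE
      }
    }
    bonds <- bonds[keep]
  }
  data.frame(bond = bonds,
             derivative = derivative[bonds],
             sign = sign(derivative[bonds]))
}

#' Classify a detected cut site as novel or masked
#'
#' The flanking residue (P1 or P1') with the larger `|log2(enrichment)|`
#' decides: a site is `novel` (created) when that dominant flank is
#' enriched in the citrullinated sample, `masked` (destroyed) when it is
#' depleted.  When both flanks sit at zero the site is uninformative and
#' `NA` is returned with a warning.
#'
#' @param profile A `residue_profile`.
#' @param bond Bond index (between residues `bond` and `bond + 1`).
#' @return `"novel"`, `"masked"`, or `NA`.
#' @export
classify_cut_site <- function(profile, bond) {
  log2e <- profile$log2_enrichment
  flanks <- log2e[c(bond, bond + 1L)]
  flanks[is.na(flanks)] <- 0
  dominant <- flanks[[which.max(abs(flanks))]]
  if (dominant > 0) return("novel")
  if (dominant < 0) return("masked")
  warning("cut site at bond ", bond, " has zero enrichment on both flanks; ",
          "excluded from classification")
  NA_character_
}

# Residue window of a cut site.  span gives offsets relative to the
# P1 residue (bond index i): c(-1, 2) is the P2..P2' 4-mer, c(-3, 4) the
# P4..P4' 8-mer.  Truncated at the protein termini.
cut_site_window <- function(bond, protein_length, span = c(-1L, 2L)) {
  w <- (bond + span[[1]]):(bond + span[[2]])
  w[w >= 1L & w <= protein_length]
}

#' Count citrullines within cut-site windows
#'
#' Sums, over all supplied sites, the number of citrulline residues falling
#' in each site's window (default the P2..P2' 4-mer).  A citrulline shared
#' by two overlapping windows is counted once per window.
#'
#' @param bonds Integer vector of bond indices.
#' @param cit_positions Integer vector of citrulline residue positions.
#' @param protein_length Protein length (windows truncate at termini).
#' @param span Window offsets relative to P1 (default `c(-1, 2)`).
#' @return Integer count.
#' @export
count_citrullines_in_windows <- function(bonds, cit_positions, protein_length,
                                         span = c(-1L, 2L)) {
  if (length(bonds) == 0) return(0L)
  sum(vapply(bonds, function(b) {
    sum(cut_site_window(b, protein_length, span) %in% cit_positions)
  }, integer(1)))
}

# Per-residue window multiplicity: how many site windows contain each
# residue.  The observed/null counting statistic is then a dot product.
.window_multiplicity <- function(bonds, protein_length, span) {
  v <- integer(protein_length)
  for (b in bonds) {
    w <- cut_site_window(b, protein_length, span)
    v[w] <- v[w] + 1L
  }
  v
}

#' Bootstrap null for citrulline counts at cut sites
#'
#' Citrulline positions are shuffled uniformly (without replacement) onto
#' the eligible residues - those with adequate MS coverage - and the
#' windowed count is recomputed each iteration.  The expected count is the
#' null mean; the empirical p-value is the fraction of iterations reaching
#' at least the observed count (reported as 0 when none does, i.e.
#' p < 1/iterations).
#'
#' @param bonds Bond indices of the cut sites under test.
#' @param cit_positions Observed citrulline positions.
#' @param eligible Integer vector of eligible residues (e.g.
#'   `which(profile$high_coverage)`).
#' @param protein_length Protein length.
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param span Window offsets relative to P1 (default the P2..P2' 4-mer).
#' @return A `bootstrap_result`.
#' @export
bootstrap_cutsite_null <- function(bonds, cit_positions, eligible,
                                   protein_length, iterations = 1000L,
                                   seed = 1L, span = c(-1L, 2L)) {
  if (length(eligible) == 0) stop("eligible residue set is empty")
  n_cit <- length(cit_positions)
  if (n_cit > length(eligible)) {
    stop("more citrullines (", n_cit, ") than eligible residues (",
         length(eligible), ")")
  }
  mult <- .window_multiplicity(bonds, protein_length, span)
  observed <- sum(mult[cit_positions])
  null_counts <- with_seed(seed, {
    vapply(seq_len(iterations), function(it) {
      sum(mult[sample(eligible, n_cit)])
    }, numeric(1))
  })
  bootstrap_result(observed, null_counts, iterations, seed, tail = "ge")
}

.POSITION_LABELS <- c("P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
                      "P1'" = 1L, "P2'" = 2L, "P3'" = 3L, "P4'" = 4L)

#' Position-wise citrulline enrichment test (P4..P4')
#'
#' For each position label P4..P4' (offsets -3..+4 from the P1 residue of
#' each bond), compares the observed number of citrullines at that position
#' across the supplied cut sites to a bootstrap null in which citrulline
#' positions are shuffled onto the eligible residues.
#'
#' @inheritParams bootstrap_cutsite_null
#' @return `data.frame` with one row per position: `position`, `offset`,
#'   `observed`, `expected`, `p_value`, `n_iterations`, `seed`.
#' @export
positionwise_citrulline_test <- function(bonds, cit_positions, eligible,
                                         protein_length, iterations = 1000L,
                                         seed = 1L) {
  if (length(eligible) == 0) stop("eligible residue set is empty")
  n_cit <- length(cit_positions)
  offs <- .POSITION_LABELS
  mults <- lapply(offs, function(o) {
    v <- integer(protein_length)
    pos <- bonds + o
    pos <- pos[pos >= 1L & pos <= protein_length]
    for (x in pos) v[[x]] <- v[[x]] + 1L
    v
  })
  observed <- vapply(mults, function(v) sum(v[cit_positions]), numeric(1))
  placements <- with_seed(seed, {
    t(vapply(seq_len(iterations), function(it) sample(eligible, n_cit),
             integer(n_cit)))
  })
  res <- lapply(seq_along(offs), function(k) {
    v <- mults[[k]]
    null_counts <- rowSums(matrix(v[placements], nrow = iterations))
    bootstrap_result(observed[[k]], null_counts, iterations, seed,
                     tail = "ge")
  })
  data.frame(
    position = names(offs),
    offset = unname(offs),
    observed = vapply(res, `[[`, numeric(1), "observed"),
    expected = vapply(res, `[[`, numeric(1), "expected"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    n_iterations = iterations,
    seed = seed,
    stringsAsFactors = FALSE
  )
}

#' Detect, classify and window cut sites for one profile
#'
#' Convenience wrapper combining [detect_cut_sites()] and
#' [classify_cut_site()], attaching the P4..P4' window sequence.
#'
#' @param profile A `residue_profile`.
#' @param protein A [protein_record()].
#' @param threshold Derivative threshold (default `log2(1.3)`).
#' @param min_separation Passed to [detect_cut_sites()].
#' @return `data.frame` with `protein_id`, `bond`, `derivative`, `sign`,
#'   `kind` (`novel`/`masked`; unclassifiable sites dropped), and
#'   `window_seq` (P4..P4', truncated at termini).
#' @export
call_cut_sites <- function(profile, protein, threshold = log2(1.3),
                           min_separation = 1L) {
  det <- detect_cut_sites(profile_derivative(profile), threshold,
                          min_separation)
  if (nrow(det) == 0) {
    det$kind <- character(0)
    det$window_seq <- character(0)
    det <- cbind(protein_id = character(0), det)
    return(det)
  }
  det$kind <- vapply(det$bond, function(b) {
    k <- suppressWarnings(classify_cut_site(profile, b))
    if (is.na(k)) NA_character_ else k
  }, character(1))
  chars <- protein_chars(protein)
  det$window_seq <- vapply(det$bond, function(b) {
    paste(chars[cut_site_window(b, protein$length, c(-3L, 4L))],
          collapse = "")
  }, character(1))
  det <- det[!is.na(det$kind), , drop = FALSE]
  cbind(protein_id = protein$id, det, stringsAsFactors = FALSE)
}
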