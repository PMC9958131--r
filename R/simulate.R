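# Synthetic digest generator.  A forward model of the paired
# native/citrullinated proteolytic-mapping experiment with known ground
# truth: citrulline-dependent proximal effects (positional cleavage-rate
# multipliers at P4..P4'), distal effects (regional accessibility
# multipliers emulating structural opening or occlusion), log-normal
# replicate noise, plus toy Calpha structures and toy affinity tables so
# every downstream stage can be exercised without real data.

#' Specify a synthetic digest scenario
#'
#' Defaults encode the study conditions emulated throughout the package:
#' four replicates per condition, arginine content above the vertebrate
#' average, half of the arginines citrullinated, a five-fold cleavage-rate
#' multiplier for citrulline at P1 and three-fold at P2', and LFQ-scale
#' abundances clearing the 1e6 coverage threshold.
#'
#' @param protein_length Protein length (default 500, typical of the
#'   autoantigens this assay is applied to, which span roughly 350-870
#'   residues).
#' @param arg_frequency Arginine frequency target (default 0.09; elevated
#'   relative to the vertebrate average, matching the arginine-rich
#'   autoantigens with high citrullination potential).
#' @param citrullination_rate Probability that an arginine is citrullinated
#'   (default 0.5).
#' @param baseline_cleavage Per-bond cleavage probability (default 0.10,
#'   giving a mean fragment length of ~10 residues, typical of
#'   MS-observed lysosomal digest peptides; sparser cleavage leaves long
#'   unobservable stretches that real repertoires do not show).
#' @param max_missed_cleavages Maximum internal cleavable bonds left uncut
#'   in a reported product (default 2): partial digestion yields a ladder
#'   of overlapping products, not a clean tiling.
#' @param missed_cleavage_penalty Abundance multiplier per missed cleavage
#'   (default 0.3).
#' @param positional_multipliers Named cleavage-rate multipliers applied in
#'   the citrullinated condition when a citrulline occupies the named
#'   position of a bond; names from `P4..P4'` (default `P1 = 5, P2' = 3`,
#'   others 1).
#' @param accessibility_regions List of regions
#'   `list(start =, end =, multiplier =, condition =)`; every peptide
#'   overlapping the region has its abundance scaled by `multiplier` in
#'   the named condition (default none), emulating structural opening or
#'   occlusion acting at a distance from any citrulline.
#' @param n_replicates Replicates per condition (default 4).
#' @param abundance_scale Baseline peptide abundance in LFQ units
#'   (default 1e7).
#' @param noise_sigma Log-normal replicate noise sigma on the natural-log
#'   scale (default 0.3).
#' @param fragment_length Observable fragment length bounds
#'   (default `c(5, 35)`).
#' @param trim_prob Probability that a fragment end is trimmed by 1-2
#'   residues, emulating exopeptidase activity (default 0, off).
#' @param seed Master seed; all stage randomness derives from it.
#' @return List of class `digest_scenario`.
#' @export
digest_scenario <- function(protein_length = 500L,
                            arg_frequency = 0.09,
                            citrullination_rate = 0.5,
                            baseline_cleavage = 0.10,
                            max_missed_cleavages = 2L,
                            missed_cleavage_penalty = 0.3,
                            positional_multipliers = c("P1" = 5, "P2'" = 3),
                            accessibility_regions = list(),
                            n_replicates = 4L,
                            abundance_scale = 1e7,
                            noise_sigma = 0.3,
                            fragment_length = c(5L, 35L),
                            trim_prob = 0,
                            seed = 1L) {
  mult <- c("P4" = 1, "P3" = 1, "P2" = 1, "P1" = 1,
            "P1'" = 1, "P2'" = 1, "P3'" = 1, "P4'" = 1)
  mult[names(positional_multipliers)] <- positional_multipliers
  stopifnot(baseline_cleavage > 0, baseline_cleavage < 1, all(mult > 0),
            arg_frequency >= 0, arg_frequency <= 1,
            citrullination_rate >= 0, citrullination_rate <= 1,
            n_replicates >= 2)
  for (reg in accessibility_regions) {
    stopifnot(reg$start >= 1, reg$end <= protein_length,
              reg$multiplier > 0)
  }
  stopifnot(max_missed_cleavages >= 0, missed_cleavage_penalty > 0,
            missed_cleavage_penalty <= 1)
  structure(
    list(protein_length = as.integer(protein_length),
         arg_frequency = arg_frequency,
         citrullination_rate = citrullination_rate,
         baseline_cleavage = baseline_cleavage,
         max_missed_cleavages = as.integer(max_missed_cleavages),
         missed_cleavage_penalty = missed_cleavage_penalty,
         positional_multipliers = mult,
         accessibility_regions = accessibility_regions,
         n_replicates = as.integer(n_replicates),
         abundance_scale = abundance_scale,
         noise_sigma = noise_sigma,
         fragment_length = as.integer(fragment_length),
         trim_prob = trim_prob,
         seed = as.integer(seed)),
    class = "digest_scenario"
  )
}

#' Generate a random protein sequence
#'
#' Residues are i.i.d.: arginine with probability `arg_frequency`, the
#' remaining mass uniform over the other 19 standard residues.
#'
#' @param length Protein length (>= 10).
#' @param arg_frequency Arginine probability per residue.
#' @param seed RNG seed.
#' @param id Record id (default derived from the seed).
#' @return A [protein_record()].
#' @export
generate_protein <- function(length, arg_frequency, seed,
                             id = sprintf("synthetic_prot_%d", seed)) {
  if (length < 10) stop("protein length must be >= 10")
  stopifnot(arg_frequency >= 0, arg_frequency <= 1)
  others <- setdiff(AA_ALPHABET_STRICT, c("R", "X"))
  probs <- c(arg_frequency, rep((1 - arg_frequency) / length(others),
                                length(others)))
  chars <- with_seed(seed, {
    sample(c("R", others), size = length, replace = TRUE, prob = probs)
  })
  protein_record(id, paste(chars, collapse = ""))
}

#' Assign citrullination sites to a protein
#'
#' Each arginine is citrullinated independently with probability `rate`.
#' Synthetic evidence fields are filled with abundances clearing the
#' default dual-threshold filter (fraction 0.5, citrullinated abundance
#' 1e7).
#'
#' @param protein A [protein_record()].
#' @param rate Citrullination probability per arginine.
#' @param seed RNG seed.
#' @param condition Condition label (default `"cit"`).
#' @return A [cit_site_set()].
#' @export
assign_citrullination <- function(protein, rate, seed, condition = "cit") {
  stopifnot(rate >= 0, rate <= 1)
  args <- which(protein_chars(protein) == "R")
  hit <- if (length(args) == 0) logical(0) else with_seed(seed, {
    stats::runif(length(args)) < rate
  })
  pos <- args[hit]
  evidence <- data.frame(
    protein_id = rep(protein$id, length(pos)),
    residue = pos,
    condition = rep(condition, length(pos)),
    cit_abundance = rep(1e7, length(pos)),
    total_abundance = rep(2e7, length(pos)),
    fraction = rep(0.5, length(pos)),
    stringsAsFactors = FALSE
  )
  cit_site_set(protein$id, condition, pos, evidence, protein = protein)
}

# Per-bond cleavage probabilities for one condition.  In the citrullinated
# condition, a citrulline at offset o from the bond's P1 residue multiplies
# the bond's rate by the corresponding positional multiplier.
.bond_probabilities <- function(protein_length, cit_positions, scenario,
                                condition) {
  p <- rep(scenario$baseline_cleavage, protein_length - 1L)
  if (condition != "cit" || length(cit_positions) == 0) return(p)
  offs <- c("P4" = -3L, "P3" = -2L, "P2" = -1L, "P1" = 0L,
            "P1'" = 1L, "P2'" = 2L, "P3'" = 3L, "P4'" = 4L)
  for (lab in names(offs)) {
    m <- scenario$positional_multipliers[[lab]]
    if (m == 1) next
    bonds <- cit_positions - offs[[lab]]
    bonds <- bonds[bonds >= 1L & bonds <= protein_length - 1L]
    p[bonds] <- p[bonds] * m
  }
  pmin(p, 1)
}

.accessibility_multiplier <- function(starts, ends, scenario, condition) {
  m <- rep(1, length(starts))
  for (reg in scenario$accessibility_regions) {
    if (!is.null(reg$condition) && reg$condition != condition) next
    overlaps <- starts <= reg$end & ends >= reg$start
    m[overlaps] <- m[overlaps] * reg$multiplier
  }
  m
}

#' Simulate one condition of a proteolytic-mapping digest
#'
#' Each peptide bond is cleavage-susceptible with probability
#' `baseline_cleavage` times the product of positional multipliers for
#' citrullines at P4..P4' offsets (citrullinated condition only).
#' Susceptibility is a property of the sequence: one uniform draw per bond
#' (shared between conditions) is compared against the per-condition rate,
#' so the citrullinated cut set nests the native one wherever multipliers
#' are >= 1, and conditions with equal rates share cut patterns exactly.
#' Susceptible bonds are cleaved in every replicate, as protease
#' specificity dictates; replicate-to-replicate variation enters through
#' the abundance noise, as in label-free quantification.  Fragments
#' between adjacent cuts whose length falls within the observable bounds
#' become peptides; abundance is
#' `abundance_scale x boundary-rate ratio x accessibility multiplier x
#' LogNormal(0, sigma)`.  The boundary-rate ratio is the cleavage rate of
#' the fragment's N-terminal boundary bond relative to baseline (1 at the
#' protein N-terminus): under first-order digestion kinetics, product
#' downstream of a faster cut accumulates proportionally, which is what
#' places a step change in per-residue abundance at every novel cut site.
#' The accessibility multiplier of the region containing the fragment
#' midpoint applies; the noise stream is drawn per
#' (seed, replicate, condition).
#'
#' @param protein A [protein_record()].
#' @param cit_sites A [cit_site_set()] (used in the citrullinated
#'   condition).
#' @param scenario A [digest_scenario()].
#' @param condition `"native"` or `"cit"`.
#' @return Peptide data frame in canonical form with abundance columns
#'   `<condition>.<replicate>`.
#' @export
simulate_digest <- function(protein, cit_sites, scenario,
                            condition = c("native", "cit")) {
  condition <- match.arg(condition)
  L <- protein$length
  stopifnot(L == scenario$protein_length)
  cit_pos <- cit_sites$positions
  p_bond <- .bond_probabilities(L, cit_pos, scenario, condition)
  chars <- protein_chars(protein)
  cond_idx <- match(condition, c("native", "cit"))
  u <- with_seed(mix_seed(scenario$seed, 101L), stats::runif(L - 1L))
  cuts <- which(u < p_bond)
  # digestion products: spans between cut bonds with up to max_missed
  # internal cleavable bonds left uncut (partial digestion ladder)
  b <- c(0L, cuts, L)
  nb <- length(b)
  prod_s <- integer(0)
  prod_e <- integer(0)
  prod_m <- integer(0)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + scenario$max_missed_cleavages)) {
      prod_s <- c(prod_s, b[[i]] + 1L)
      prod_e <- c(prod_e, b[[j]])
      prod_m <- c(prod_m, j - i - 1L)
    }
  }
  base_factor <- scenario$abundance_scale *
    scenario$missed_cleavage_penalty^prod_m *
    ifelse(prod_s == 1L, 1,
           p_bond[pmax(prod_s - 1L, 1L)] / scenario$baseline_cleavage) *
    .accessibility_multiplier(prod_s, prod_e, scenario, condition)
  n_prod <- length(prod_s)
  frag_tabs <- vector("list", scenario$n_replicates)
  for (r in seq_len(scenario$n_replicates)) {
    starts <- prod_s
    ends <- prod_e
    if (scenario$trim_prob > 0) {
      trims <- with_seed(mix_seed(scenario$seed, 103L, r, cond_idx), {
        matrix(ifelse(stats::runif(2L * n_prod) < scenario$trim_prob,
                      sample(1:2, 2L * n_prod, replace = TRUE), 0L),
               ncol = 2L)
      })
      starts <- pmin(starts + trims[, 1L], ends)
      ends <- pmax(ends - trims[, 2L], starts)
    }
    noise <- with_seed(mix_seed(scenario$seed, 102L, r, cond_idx), {
      stats::rlnorm(n_prod, meanlog = 0, sdlog = scenario$noise_sigma)
    })
    len <- ends - starts + 1L
    keep <- len >= scenario$fragment_length[[1]] &
      len <= scenario$fragment_length[[2]]
    tab <- data.frame(start = starts[keep], end = ends[keep],
                      abundance = (base_factor * noise)[keep])
    if (nrow(tab) > 1) {
      agg <- rowsum(tab$abundance, paste(tab$start, tab$end),
                    reorder = FALSE)
      first <- !duplicated(paste(tab$start, tab$end))
      tab <- tab[first, , drop = FALSE]
      tab$abundance <- agg[match(paste(tab$start, tab$end),
                                 rownames(agg)), 1L]
    }
    frag_tabs[[r]] <- tab
  }
  keys <- unique(do.call(rbind, lapply(frag_tabs, function(t)
    t[c("start", "end")])))
  keys <- keys[order(keys$start, keys$end), , drop = FALSE]
  ab <- matrix(0, nrow(keys), scenario$n_replicates,
               dimnames = list(NULL, paste0(condition, ".",
                                            seq_len(scenario$n_replicates))))
  kk <- paste(keys$start, keys$end)
  for (r in seq_len(scenario$n_replicates)) {
    t <- frag_tabs[[r]]
    if (nrow(t) == 0) next
    j <- match(paste(t$start, t$end), kk)
    ab[j, r] <- t$abundance
  }
  out <- data.frame(
    protein_id = protein$id,
    peptide = vapply(seq_len(nrow(keys)), function(i)
      paste(chars[keys$start[[i]]:keys$end[[i]]], collapse = ""),
      character(1)),
    start = keys$start, end = keys$end,
    stringsAsFactors = FALSE
  )
  out$cit_positions <- if (condition == "cit") {
    lapply(seq_len(nrow(keys)), function(i)
      cit_pos[cit_pos >= keys$start[[i]] & cit_pos <= keys$end[[i]]])
  } else {
    rep(list(integer(0)), nrow(keys))
  }
  cbind(out, as.data.frame(ab))
}

#' Simulate a paired native/citrullinated mapping experiment
#'
#' Runs [simulate_digest()] for both conditions and merges the tables on
#' the peptide span, filling zeros for peptides observed in only one
#' condition.  A citrulline-carrying species and its unmodified
#' counterpart at the same span are the same measurement (sequences match
#' up to the R-to-citrulline equivalence at the annotated positions), so
#' the paired comparison tests the processing change, not the mass shift
#' of the modification itself.
#'
#' @param protein A [protein_record()].
#' @param cit_sites A [cit_site_set()].
#' @param scenario A [digest_scenario()].
#' @return Combined peptide data frame with `native.<r>` and `cit.<r>`
#'   abundance columns.
#' @export
simulate_protmap <- function(protein, cit_sites, scenario) {
  nat <- simulate_digest(protein, cit_sites, scenario, "native")
  cit <- simulate_digest(protein, cit_sites, scenario, "cit")
  key <- function(df) paste(df$start, df$end)
  nat_cols <- grep("^native\\.", names(nat), value = TRUE)
  cit_cols <- grep("^cit\\.", names(cit), value = TRUE)
  kn <- key(nat)
  kc <- key(cit)
  all_keys <- union(kn, kc)
  id_src <- rbind(nat[.PEPTIDE_ID_COLS], cit[.PEPTIDE_ID_COLS])
  out <- id_src[match(all_keys, c(kn, kc)), , drop = FALSE]
  # citrulline annotations live on the citrullinated condition's species
  in_cit <- match(all_keys, kc)
  out$cit_positions[!is.na(in_cit)] <-
    cit$cit_positions[in_cit[!is.na(in_cit)]]
  for (col in nat_cols) {
    out[[col]] <- 0
    out[[col]][match(kn, all_keys)] <- nat[[col]]
  }
  for (col in cit_cols) {
    out[[col]] <- 0
    out[[col]][match(kc, all_keys)] <- cit[[col]]
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Toy Calpha structure: an ideal alpha-helix
#'
#' Parametrised with radius 2.3 Angstrom, 1.5 Angstrom rise and 100
#' degrees turn per residue; every residue is covered.  Consecutive Calpha
#' atoms sit ~3.8 Angstrom apart, matching real protein geometry.
#'
#' @param protein A [protein_record()].
#' @return A [structure_model()].
#' @export
generate_helix_structure <- function(protein) {
  i <- seq_len(protein$length)
  theta <- (i - 1L) * 100 * pi / 180
  coords <- cbind(x = 2.3 * cos(theta), y = 2.3 * sin(theta), z = 1.5 * i)
  rownames(coords) <- i
  structure_model(protein$id, coords)
}

# Deterministic pseudo-hash of a string combined with a seed; NOT a
# biological model, used only to fabricate reproducible toy affinities.
.toy_hash <- function(s, seed) {
  m <- 2147483647
  acc <- as.numeric(seed) %% m
  for (v in utf8ToInt(s)) acc <- (acc * 31 + v) %% m
  acc
}

#' Toy MHC-II affinity table
#'
#' Deterministic pseudo-affinities in [10, 5000] nM from a seeded hash of
#' (core, allele); cores listed in `planted_cores` receive an affinity
#' below 500 nM for the first allele, guaranteeing retained binders in
#' tests.  This generator is a test stand-in with no biological content.
#'
#' @param windows Character vector of peptide sequences (length >= 9).
#' @param seed Hash seed.
#' @param planted_cores Cores forced below the 500 nM retention threshold.
#' @param alleles Allele set (default [se_alleles()]).
#' @return Affinity prediction data frame (canonical columns).
#' @export
generate_affinity_table <- function(windows, seed,
                                    planted_cores = character(0),
                                    alleles = se_alleles()) {
  stopifnot(all(nchar(windows) >= 9))
  rows <- list()
  for (w in windows) {
    for (a in alleles) {
      off <- .toy_hash(paste0(w, "|", a, "|off"), seed) %%
        (nchar(w) - 8L)
      core <- substr(w, off + 1L, off + 9L)
      h <- .toy_hash(paste0(core, "|", a), seed)
      aff <- 10 + (h %% 4991)
      if (core %in% planted_cores && a == alleles[[1]]) {
        aff <- 10 + (h %% 489)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = w, allele = a, core = core, core_offset = as.integer(off),
        affinity_nm = aff, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
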