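# Synthetic digest generator: distributions, determinism, ground truth.

test_that("generated proteins hit the arginine frequency target", {
  p <- generate_protein(1000, 0.10, seed = 5)
  n_r <- sum(strsplit(p$sequence, "")[[1]] == "R")
  bounds <- qbinom(c(0.0005, 0.9995), 1000, 0.10)
  expect_gte(n_r, bounds[1])
  expect_lte(n_r, bounds[2])

  expect_equal(sum(strsplit(generate_protein(200, 0, 1)$sequence,
                            "")[[1]] == "R"), 0)
  expect_identical(generate_protein(300, 0.1, 9)$sequence,
                   generate_protein(300, 0.1, 9)$sequence)
  expect_error(generate_protein(5, 0.1, 1), ">= 10")
})

test_that("citrullination assignment is binomial over arginines", {
  p <- generate_protein(2000, 0.10, seed = 2)
  n_args <- sum(strsplit(p$sequence, "")[[1]] == "R")
  all_sites <- assign_citrullination(p, 1, seed = 3)
  expect_equal(length(all_sites$positions), n_args)
  expect_equal(length(assign_citrullination(p, 0, seed = 3)$positions), 0)
  half <- assign_citrullination(p, 0.5, seed = 3)
  bounds <- qbinom(c(0.0005, 0.9995), n_args, 0.5)
  expect_gte(length(half$positions), bounds[1])
  expect_lte(length(half$positions), bounds[2])
  # synthetic evidence clears the default filter
  expect_setequal(filter_sites(half$evidence)$positions, half$positions)
})

test_that("null multipliers give identical cut patterns across conditions", {
  sc <- digest_scenario(positional_multipliers = c("P1" = 1), seed = 17)
  prot <- generate_protein(sc$protein_length, sc$arg_frequency, 18)
  cit <- assign_citrullination(prot, 0.5, 19)
  nat_tab <- simulate_digest(prot, cit, sc, "native")
  cit_tab <- simulate_digest(prot, cit, sc, "cit")
  expect_identical(nat_tab[c("start", "end")], cit_tab[c("start", "end")])
})

test_that("per-bond cleavage frequency matches the boosted rate", {
  # P(cleave bond with citrulline at P1) = min(1, 5 x baseline); measured
  # across independent scenarios since susceptibility is drawn per protein
  hits <- 0
  n <- 0
  for (s in 1:60) {
    sc <- digest_scenario(seed = s)
    prot <- generate_protein(sc$protein_length, sc$arg_frequency,
                             seed = 1000 + s)
    cit <- assign_citrullination(prot, sc$citrullination_rate,
                                 seed = 2000 + s)
    tab <- simulate_digest(prot, cit, sc, "cit")
    p1_bonds <- cit$positions[cit$positions < sc$protein_length]
    cut_bonds <- setdiff(unique(tab$end), sc$protein_length)
    hits <- hits + sum(p1_bonds %in% cut_bonds)
    n <- n + length(p1_bonds)
  }
  target <- min(1, 5 * digest_scenario()$baseline_cleavage)
  se <- sqrt(target * (1 - target) / n)
  # fragment-length filtering can only hide cuts, so allow the 3 SE band
  # around the target after measuring via fragment ends including missed
  # cleavage products (which recover hidden cuts)
  expect_lt(abs(hits / n - target), 3 * se + 0.02)
})

test_that("accessibility windows scale the citrullinated abundance", {
  ratios <- c()
  for (s in 1:5) {
    sc <- digest_scenario(positional_multipliers = c("P1" = 1),
                          accessibility_regions = list(
                            list(start = 200, end = 219, multiplier = 8,
                                 condition = "cit")),
                          seed = s)
    prot <- generate_protein(sc$protein_length, sc$arg_frequency, 100 + s)
    none <- assign_citrullination(prot, 0, 200 + s)
    ns <- residue_sums(simulate_digest(prot, none, sc, "native"),
                       prot, "native")
    cs <- residue_sums(simulate_digest(prot, none, sc, "cit"), prot, "cit")
    idx <- 200:219
    ok <- ns[idx] > 0 & cs[idx] > 0
    ratios <- c(ratios, cs[idx][ok] / ns[idx][ok])
  }
  # log-normal replicate noise: the mean ratio sits near 8 within noise
  expect_gt(mean(ratios), 8 * 0.8)
  expect_lt(mean(ratios), 8 * 1.25)
})

test_that("digest tables are deterministic given the scenario seed", {
  sc <- digest_scenario(seed = 23)
  prot <- generate_protein(sc$protein_length, sc$arg_frequency, 24)
  cit <- assign_citrullination(prot, 0.5, 25)
  t1 <- simulate_protmap(prot, cit, sc)
  t2 <- simulate_protmap(prot, cit, sc)
  expect_identical(t1, t2)
})

test_that("helix structures have ideal backbone geometry", {
  prot <- generate_protein(50, 0.1, 1)
  st <- generate_helix_structure(prot)
  expect_equal(st$coverage, 1:50)
  d <- unname(sqrt(rowSums(diff(st$coords)^2)))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)  # constant spacing
  expect_equal(d[1], sqrt((2 * 2.3 * sin(50 * pi / 180))^2 + 1.5^2))
  expect_equal(d[1], 3.8, tolerance = 0.1)
})

test_that("toy affinity tables are deterministic, bounded and plantable", {
  windows <- c("ACDEFGHIKLMNP", "QRSTVWYACDEFG")
  t1 <- generate_affinity_table(windows, seed = 6)
  t2 <- generate_affinity_table(windows, seed = 6)
  expect_identical(t1, t2)
  expect_true(all(t1$affinity_nm >= 10 & t1$affinity_nm <= 5000))
  expect_equal(substr(t1$peptide[1], t1$core_offset[1] + 1,
                      t1$core_offset[1] + 9), t1$core[1])

  planted <- t1$core[1]
  t3 <- generate_affinity_table(windows, seed = 6, planted_cores = planted)
  expect_lt(min(t3$affinity_nm[t3$core == planted]), 500)
})

test_that("end-to-end ground truth is recovered across seeds", {
  n_seeds <- 20
  ok_region <- 0
  ok_p1 <- 0
  win <- c(200L, 219L)
  for (s in seq_len(n_seeds)) {
    sc <- digest_scenario(accessibility_regions = list(
      list(start = win[1], end = win[2], multiplier = 8,
           condition = "cit")), seed = s)
    prot <- generate_protein(sc$protein_length, sc$arg_frequency,
                             mix_seed(s, 1))
    cit <- assign_citrullination(prot, sc$citrullination_rate,
                                 mix_seed(s, 2))
    pep <- simulate_protmap(prot, cit, sc)
    prof <- log2_profile(residue_sums(pep, prot, "native"),
                         residue_sums(pep, prot, "cit"),
                         protein_id = prot$id)
    regions <- call_changed_regions(prof, 1, cit)
    created <- regions[regions$direction == "created", ]
    overlap <- 0
    for (i in seq_len(nrow(created))) {
      overlap <- max(overlap, length(intersect(
        created$start[i]:created$end[i], win[1]:win[2])))
    }
    if (overlap >= 0.8 * (win[2] - win[1] + 1)) ok_region <- ok_region + 1
    cuts <- call_cut_sites(prof, prot)
    novel <- cuts$bond[cuts$kind == "novel"]
    if (length(novel) > 0) {
      pw <- positionwise_citrulline_test(
        novel, cit$positions, which(prof$high_coverage), prot$length,
        1000L, mix_seed(s, 3))
      if (pw$p_value[pw$position == "P1"] <= 0.05) ok_p1 <- ok_p1 + 1
    }
  }
  expect_gte(ok_region / n_seeds, 0.8)
  expect_gte(ok_p1 / n_seeds, 0.8)
})

test_that("null scenarios produce no systematic calls", {
  n_seeds <- 50
  fp <- 0
  total <- 0
  n_regions <- 0
  for (s in seq_len(n_seeds)) {
    sc <- digest_scenario(positional_multipliers = c("P1" = 1), seed = s)
    prot <- generate_protein(sc$protein_length, sc$arg_frequency,
                             mix_seed(s, 4))
    cit <- assign_citrullination(prot, sc$citrullination_rate,
                                 mix_seed(s, 5))
    pep <- simulate_protmap(prot, cit, sc)
    d <- differential_peptides(pep)
    fp <- fp + sum(d$class != "unchanged")
    total <- total + nrow(d)
    prof <- log2_profile(residue_sums(pep, prot, "native"),
                         residue_sums(pep, prot, "cit"))
    n_regions <- n_regions + nrow(call_changed_regions(prof, 1))
  }
  expect_lte(fp / total, 0.05 * 1.5)
  expect_lte(n_regions / n_seeds, 0.2)  # noise floor
})
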