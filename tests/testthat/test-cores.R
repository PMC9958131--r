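# MHC-II binding-core selection, quantification and classification.

test_that("glutamine substitution maps citrullines faithfully", {
  p <- protein_record("p", "AKRC")
  expect_equal(substitute_citrullines(p, cit_site_set("p", "cit", 3L)),
               "AKQC")
  expect_equal(substitute_citrullines(p, cit_site_set("p", "cit",
                                                      integer(0))),
               "AKRC")
  bad <- structure(list(protein_id = "p", condition = "cit",
                        positions = 2L, evidence = NULL),
                   class = "cit_site_set")
  expect_error(substitute_citrullines(p, bad), "not an arginine")
})

test_that("putative cores are retained by strict sub-500 nM affinity", {
  preds <- data.frame(
    peptide = rep("ACDEFGHIKLM", 6),
    allele = c("DRB1*04:01", "DRB1*01:01", "DRB1*04:04",
               "DRB1*04:01", "DRB1*01:01", "DRB1*04:04"),
    core = c(rep("ACDEFGHIK", 3), rep("CDEFGHIKL", 3)),
    core_offset = c(0L, 0L, 0L, 1L, 1L, 1L),
    affinity_nm = c(400, 800, 900, 600, 700, 650),
    stringsAsFactors = FALSE)
  cores <- select_putative_cores(preds)
  expect_equal(cores$core, "ACDEFGHIK")   # one sub-threshold allele suffices
  expect_equal(cores$best_affinity_nm, 400)

  # exactly 500 nM everywhere is dropped (strict <)
  preds$affinity_nm <- rep(500, 6)
  expect_equal(nrow(select_putative_cores(preds)), 0)

  # raising the threshold never removes cores
  preds$affinity_nm <- c(400, 800, 900, 600, 700, 650)
  n1 <- nrow(select_putative_cores(preds, threshold = 500))
  n2 <- nrow(select_putative_cores(preds, threshold = 700))
  expect_gte(n2, n1)

  preds$allele[1] <- "DRB1*15:01"
  expect_error(select_putative_cores(preds), "DRB1\\*10:01")
})

test_that("core abundance sums containing peptides in the right space", {
  pep <- make_peptides(list(
    list(start = 1, end = 11, peptide = "ABCDEFGHIJK", native = c(40, 30),
         cit_ab = c(0, 0)),
    list(start = 2, end = 12, peptide = "BCDEFGHIJKL", native = c(20, 10),
         cit_ab = c(5, 5))
  ))
  expect_equal(core_abundance("BCDEFGHIJ", pep, "native"), 100)
  expect_equal(core_abundance("ABCDEFGHI", pep, "native"), 70)
  expect_equal(core_abundance("ZZZZZZZZZ", pep, "native"), 0)

  # citrulline-containing cores match only citrulline-carrying peptides
  prot_pep <- make_peptides(list(
    list(start = 1, end = 10, peptide = "AARCDEFGHI", cit = 3L,
         native = c(100, 100), cit_ab = c(60, 60)),
    list(start = 1, end = 10, peptide = "AARCDEFGHI", cit = integer(0),
         native = c(50, 50), cit_ab = c(10, 10))
  ))
  # Q-space core hits only the modified species in the citrullinated sample
  expect_equal(core_abundance("AQCDEFGHI", prot_pep, "cit",
                              space = "citrullinated"), 120)
  # native-R core hits only the unmodified species
  expect_equal(core_abundance("ARCDEFGHI", prot_pep, "cit",
                              space = "citrullinated"), 20)
  expect_equal(core_abundance("ARCDEFGHI", prot_pep, "native",
                              space = "native"), 300)
})

test_that("core classification follows the 50% margin rules", {
  expect_equal(classify_core(100, 160), "enriched")
  expect_equal(classify_core(0, 50), "created")
  expect_equal(classify_core(100, 120), "unchanged")
  expect_equal(classify_core(50, 0), "destroyed")
  expect_equal(classify_core(100, 50), "reduced")
  expect_error(classify_core(0, 0), "zero abundance")
  # scale invariance
  set.seed(9)
  for (i in 1:20) {
    a <- runif(1, 1, 100)
    b <- runif(1, 1, 100)
    k <- runif(1, 0.01, 1000)
    expect_equal(classify_core(a, b), classify_core(k * a, k * b))
  }
})

test_that("planted threefold enrichment is recovered despite noise", {
  # margin log(1.5) sits two noise SDs from the true log(3) ratio:
  # sd(log ratio) = sigma * sqrt(2/n_rep) = log(2)/2 with n_rep = 2
  sigma <- log(2) / (2 * sqrt(2 / 2))
  n_ok <- 0
  n_tot <- 200
  set.seed(31)
  for (i in seq_len(n_tot)) {
    nat <- 100 * rlnorm(2, 0, sigma)
    cit <- 300 * rlnorm(2, 0, sigma)
    if (classify_core(mean(nat), mean(cit)) %in% c("enriched", "created")) {
      n_ok <- n_ok + 1
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("citrulline anchor status follows the pocket offsets", {
  expect_equal(annotate_citrulline_anchors(10, 18, 13L), "anchor")    # P4
  expect_equal(annotate_citrulline_anchors(10, 18, 14L), "tcr_contact")
  expect_equal(annotate_citrulline_anchors(10, 18, 25L), "none")
})

test_that("Mann-Whitney comparison agrees with exact enumeration", {
  res <- compare_affinity_distributions(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$U, 0)
  expect_equal(res$median_created, 2)
  expect_equal(res$median_destroyed, 20)
  expect_equal(res$p_value, exact_mw(c(1, 2, 3), c(10, 20, 30)))

  # single-element groups: only two arrangements, p = 1
  res1 <- compare_affinity_distributions(5, 7)
  expect_equal(res1$U, 0)
  expect_equal(res1$p_value, 1)

  # identical groups cannot be told apart
  res_same <- compare_affinity_distributions(c(2, 4, 6), c(2, 4, 6))
  expect_gt(res_same$p_value, 0.9)

  # random small groups against the enumeration oracle
  set.seed(14)
  for (i in 1:10) {
    x <- sample(1:50, sample(2:6, 1))
    y <- sample(seq(0.25, 59.75, by = 0.5), sample(2:6, 1))  # tie-free
    res <- compare_affinity_distributions(x, y)
    expect_equal(res$p_value, exact_mw(x, y), tolerance = 1e-12)
  }
  expect_error(compare_affinity_distributions(numeric(0), 1), "non-empty")
})

test_that("repertoire composition percentages are computed per class", {
  cores <- data.frame(
    class = c("enriched", "enriched", "created", "reduced"),
    contains_citrulline = c(TRUE, FALSE, FALSE, FALSE),
    anchor_status = c("anchor", "none", "none", "none"))
  s <- summarize_core_repertoire(cores)
  expect_equal(s$pct_enriched_or_created, 75)
  expect_equal(unname(s$counts["reduced"]), 1L)

  all_unchanged <- data.frame(class = rep("unchanged", 3),
                              contains_citrulline = FALSE,
                              anchor_status = "none")
  s2 <- summarize_core_repertoire(all_unchanged)
  expect_equal(s2$pct_enriched_or_created, 0)
  expect_equal(s2$pct_reduced_or_destroyed, 0)

  # 10 enriched/created, 3 with citrulline, 1 anchored
  cores3 <- data.frame(
    class = rep(c("enriched", "created"), 5),
    contains_citrulline = c(rep(TRUE, 3), rep(FALSE, 7)),
    anchor_status = c("anchor", "tcr_contact", "tcr_contact",
                      rep("none", 7)))
  s3 <- summarize_core_repertoire(cores3)
  expect_equal(s3$pct_citrulline_in_up, 30)
  expect_equal(s3$pct_anchor_in_citrulline, 100 / 3)
})

test_that("assembled binding cores honour abundance and anchor logic", {
  prot <- protein_record("prot1", "AARCDEFGHIKLMNP")
  sites <- cit_site_set("prot1", "cit", 3L, protein = prot)
  pep <- make_peptides(list(
    list(start = 1, end = 12, peptide = "AARCDEFGHIKL", cit = 3L,
         native = c(0, 0), cit_ab = c(50, 50)),
    list(start = 4, end = 15, peptide = "CDEFGHIKLMNP", cit = integer(0),
         native = c(40, 40), cit_ab = c(70, 50))
  ))
  cores <- data.frame(core = c("AQCDEFGHI", "CDEFGHIKL"),
                      best_affinity_nm = c(120, 300),
                      stringsAsFactors = FALSE)
  built <- build_binding_cores(cores, pep, prot, sites)
  q_core <- built[built$core == "AQCDEFGHI", ]
  expect_equal(q_core$class, "created")
  expect_equal(q_core$anchor_status, "tcr_contact")  # citrulline at offset 3
  nat_core <- built[built$core == "CDEFGHIKL", ]
  expect_equal(nat_core$native_abundance, 80)
  expect_equal(nat_core$cit_abundance, 220)
  expect_equal(nat_core$class, "enriched")  # 220 >= 1.5 x 80
  expect_equal(nat_core$anchor_status, "none")
})
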