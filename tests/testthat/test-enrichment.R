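# Enrichment profiles, region calling, differential testing, change score.

test_that("residue_sums accumulates spanning peptides and replicates", {
  prot <- protein_record("prot1", strrep("A", 10))
  pep <- make_peptides(list(
    list(start = 1, end = 5, peptide = "AAAAA", native = c(10, 0),
         cit_ab = c(0, 0)),
    list(start = 3, end = 5, peptide = "AAA", native = c(5, 0),
         cit_ab = c(0, 0))
  ))
  s <- residue_sums(pep, prot, "native")
  expect_equal(s[1], 10)
  expect_equal(s[3], 15)
  expect_equal(s[6], 0)
  # conservation: total over residues = sum over peptides of ab x length
  expect_equal(sum(s), 10 * 5 + 5 * 3)
  # four replicates of abundance 10 give 40 on covered residues
  pep4 <- make_peptides(list(
    list(start = 2, end = 4, peptide = "AAA", native = c(10, 10, 10, 10),
         cit_ab = c(0, 0, 0, 0))))
  expect_equal(residue_sums(pep4, prot, "native")[2:4], rep(40, 3))
  # no peptides -> all zeros
  expect_equal(residue_sums(pep[0, ], prot, "native"), numeric(10))
})

test_that("log2_profile handles ratios, sentinels and masking", {
  p <- log2_profile(c(10, 0, 5, 0), c(40, 7, 5, 0))
  expect_equal(p$log2_enrichment[1], 2)
  expect_equal(p$log2_enrichment[2], 10)   # created sentinel +cap
  expect_equal(p$log2_enrichment[3], 0)
  expect_true(is.na(p$log2_enrichment[4])) # covered in neither -> masked
  expect_equal(p$covered, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(log2_profile(c(7, 1), c(0, 1))$log2_enrichment[1], -10)
  expect_error(log2_profile(c(-1, 0), c(0, 0)), "non-negative")
})

test_that("region calling finds maximal threshold runs", {
  prof <- log2_profile(2^c(0, 0, 0, 0, 0, 1.2) * 100,
                       2^c(0, 0, 1.5, 2.0, 0.5, 0) * 100)
  regions <- call_changed_regions(prof, 1)
  expect_equal(regions$start, c(3, 6))
  expect_equal(regions$end, c(4, 6))
  expect_equal(regions$direction, c("created", "destroyed"))

  # boundary inclusive: log2E exactly at the threshold is in the region
  prof2 <- log2_profile(c(100, 100), c(200, 200))
  r2 <- call_changed_regions(prof2, 1)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(1, 2))

  # all zeros -> no regions
  expect_equal(nrow(call_changed_regions(log2_profile(rep(1, 5), rep(1, 5)))),
               0)
})

test_that("regions are maximal, disjoint, sorted, and mirror on reversal", {
  set.seed(11)
  for (i in 1:20) {
    L <- 60
    nat <- runif(L, 50, 150)
    cit <- nat * 2^round(runif(L, -2, 2))
    cit[sample(L, 5)] <- 0
    prof <- log2_profile(nat, cit)
    reg <- call_changed_regions(prof, 1)
    if (nrow(reg) > 1) {
      expect_true(all(diff(reg$start) > 0))
      expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))
    }
    # maximality: adjacent residues outside each region fail its threshold
    log2e <- prof$log2_enrichment
    for (k in seq_len(nrow(reg))) {
      thr_ok <- function(v) !is.na(v) &&
        ((reg$direction[k] == "created" && v >= 1) ||
         (reg$direction[k] == "destroyed" && v <= -1))
      if (reg$start[k] > 1) expect_false(thr_ok(log2e[reg$start[k] - 1]))
      if (reg$end[k] < L) expect_false(thr_ok(log2e[reg$end[k] + 1]))
    }
    # mirror: calling on the reversed profile mirrors positions
    prof_rev <- log2_profile(rev(nat), rev(cit))
    reg_rev <- call_changed_regions(prof_rev, 1)
    expect_equal(sort(L + 1 - reg$end), sort(reg_rev$start))
    expect_equal(sort(L + 1 - reg$start), sort(reg_rev$end))
  }
})

test_that("two-stage FDR matches the independent reference to 1e-10", {
  # reference values computed with an independent implementation of the
  # two-stage step-up procedure (statsmodels fdr_tsbky) and frozen
  p <- c(0.0001, 0.0004, 0.0019, 0.0095, 0.0201, 0.0278, 0.0298, 0.0344,
         0.0459, 0.3240, 0.4262, 0.5719, 0.6528, 0.7590, 1.0000)
  ref <- c(0.001155, 0.00231, 0.007315, 0.02743125, 0.046431, 0.04917,
           0.04917, 0.04966499999999999, 0.05890500000000001, 0.37422,
           0.44751, 0.55045375, 0.5799876923076923, 0.6261749999999999,
           0.77)
  expect_equal(bky_adjust(p, 0.05), ref, tolerance = 1e-12)
  expect_lt(max(abs(bky_adjust(p, 0.05) - ref)), 1e-10)

  # first stage rejecting nothing: plain BH scaled by (1 + alpha)
  p2 <- c(0.01, 0.02, 0.03, 0.2, 0.5)
  ref2 <- c(0.0525, 0.0525, 0.0525, 0.2625, 0.525)
  expect_lt(max(abs(bky_adjust(p2, 0.05) - ref2)), 1e-10)
})

test_that("differential peptide classes follow the significance rules", {
  pep <- make_peptides(list(
    list(start = 1, end = 4, peptide = "AAAA", native = c(10, 10, 10, 10),
         cit_ab = c(40, 42, 38, 40)),
    list(start = 5, end = 8, peptide = "CCCC", native = c(10, 11, 9, 10),
         cit_ab = c(10, 11, 9, 10)),
    list(start = 9, end = 12, peptide = "DDDD", native = c(0, 0, 0, 0),
         cit_ab = c(50, 55, 45, 50)),
    list(start = 13, end = 16, peptide = "EEEE", native = c(50, 52, 48, 51),
         cit_ab = c(0, 0, 0, 0))
  ))
  res <- differential_peptides(pep)
  expect_equal(res$class, c("enriched", "unchanged", "created", "destroyed"))
  expect_equal(res$fold_change[1], 4)
  # the t statistic matches the closed form
  cf <- closed_form_paired_t(c(40, 42, 38, 40), c(10, 10, 10, 10))
  expect_equal(res$t[1], cf$t)
  expect_equal(res$p[1], cf$p)
  # identical samples: fold 1, zero within-pair variance -> q = 1
  expect_equal(res$fold_change[2], 1)
  expect_equal(res$q[2], 1)

  expect_error(differential_peptides(pep[, !grepl("\\.2|\\.3|\\.4",
                                                  names(pep))]),
               "2 paired replicates")
})

test_that("fraction of sequence changed uses the span union", {
  prot_len <- 100
  prof <- log2_profile(rep(100, prot_len), rep(100, prot_len))
  mk_res <- function(spans) data.frame(
    peptide = "x", start = vapply(spans, `[[`, 0, 1),
    end = vapply(spans, `[[`, 0, 2),
    class = rep("enriched", length(spans)))
  expect_equal(fraction_sequence_changed(mk_res(list(c(1, 10))), prof), 10)
  expect_equal(
    fraction_sequence_changed(mk_res(list(c(1, 10), c(5, 14))), prof), 14)
  none <- mk_res(list(c(1, 10)))
  none$class <- "unchanged"
  expect_equal(fraction_sequence_changed(none, prof), 0)
})

test_that("change score is the percentage of significant peptides", {
  res <- data.frame(class = c(rep("enriched", 2), "created",
                              rep("unchanged", 7)))
  expect_equal(change_score(res)$score, 30)
  expect_equal(change_score(data.frame(class = rep("unchanged", 4)))$score, 0)
  expect_equal(change_score(data.frame(class = c("created", "destroyed")))$score,
               100)
})

test_that("arginine frequency and regression behave at the edges", {
  expect_equal(arginine_frequency(protein_record("a", "RRAA")), 50)
  expect_equal(arginine_frequency(protein_record("b", "AAAA")), 0)
  expect_equal(arginine_frequency(protein_record("c", "R")), 100)

  fit <- fit_change_score_regression(1:3, c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)

  flat <- fit_change_score_regression(1:3, c(5, 5, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  expect_error(fit_change_score_regression(c(2, 2, 2), 1:3), "identical")

  set.seed(3)
  x <- rnorm(5)
  y <- 2 * x + rnorm(5)
  fit2 <- fit_change_score_regression(x, y)
  ref <- closed_form_ols(x, y)
  expect_equal(fit2$slope, ref$slope)
  expect_equal(fit2$intercept, ref$intercept)
  expect_equal(fit2$r_squared, ref$r_squared)
})
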