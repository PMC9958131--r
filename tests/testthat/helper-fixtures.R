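# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; nothing is read from disk except files
# the tests themselves write to tempdir().

# A minimal peptide table in the canonical in-memory form.
make_peptides <- function(rows) {
  # rows: list of list(start, end, peptide, cit = integer(0),
  #                    native = c(...), cit_ab = c(...))
  n <- length(rows)
  nrep <- length(rows[[1]]$native)
  df <- data.frame(
    protein_id = rep("prot1", n),
    peptide = vapply(rows, function(r) r$peptide, character(1)),
    start = vapply(rows, function(r) r$start, numeric(1)),
    end = vapply(rows, function(r) r$end, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$cit_positions <- lapply(rows, function(r) as.integer(r$cit %||% integer(0)))
  for (j in seq_len(nrep)) {
    df[[paste0("native.", j)]] <- vapply(rows, function(r) r$native[[j]],
                                         numeric(1))
    df[[paste0("cit.", j)]] <- vapply(rows, function(r) r$cit_ab[[j]],
                                      numeric(1))
  }
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a tiny PDB file with CA atoms at given residue numbers/coords.
write_toy_pdb <- function(path, resno, coords, chain = "A",
                          altloc = rep(" ", length(resno))) {
  lines <- vapply(seq_along(resno), function(i) {
    sprintf("ATOM  %5d  CA %sALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, altloc[[i]], chain, resno[[i]],
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# Exact enumeration oracles for the bootstrap expectations ---------------

# Linear metric: expected min distance from region to n_cit citrullines
# placed uniformly without replacement on 1..L.
exact_linear_expected <- function(start, end, n_cit, L) {
  dvec <- vapply(seq_len(L), function(p) {
    if (p >= start && p <= end) 0 else min(abs(p - start), abs(p - end))
  }, numeric(1))
  combs <- utils::combn(L, n_cit)
  mean(apply(combs, 2, function(idx) min(dvec[idx])))
}

# Cut-site metric: expected windowed citrulline count when n_cit
# citrullines are placed on the eligible residues.
exact_cutsite_expected <- function(bonds, eligible, n_cit, L,
                                   span = c(-1L, 2L)) {
  mult <- integer(L)
  for (b in bonds) {
    w <- (b + span[[1]]):(b + span[[2]])
    w <- w[w >= 1 & w <= L]
    mult[w] <- mult[w] + 1L
  }
  combs <- utils::combn(length(eligible), n_cit)
  mean(apply(combs, 2, function(idx) sum(mult[eligible[idx]])))
}

# Euclidean metric: expected min distance from region residues to n_cit
# relabelled residues among the covered set.
exact_euclid_expected <- function(region_residues, n_cit, structure) {
  cov <- structure$coverage
  rr <- intersect(region_residues, cov)
  A <- structure$coords[match(rr, cov), , drop = FALSE]
  dmin <- vapply(seq_along(cov), function(j) {
    sqrt(min(rowSums((A - matrix(structure$coords[j, ], nrow(A), 3,
                                 byrow = TRUE))^2)))
  }, numeric(1))
  combs <- utils::combn(length(cov), n_cit)
  mean(apply(combs, 2, function(idx) min(dmin[idx])))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all labelings.
exact_mw <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mu <- n1 * (length(y)) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Closed-form paired t-test p-value.
closed_form_paired_t <- function(x, y) {
  d <- x - y
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * stats::pt(-abs(t), df = length(d) - 1))
}

# Closed-form OLS via the normal equations.
closed_form_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  list(intercept = beta[1], slope = beta[2],
       r_squared = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
}
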