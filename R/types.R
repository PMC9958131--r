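# Domain containers.  Deliberately lightweight: plain lists and data frames
# with S3 classes, in the style of base-R analysis packages.  All residue
# coordinates are 1-based inclusive; a cleavage bond i lies between residues
# i and i + 1.

#' Amino-acid alphabet accepted throughout the package
#'
#' The 20 standard residues plus 'X' for unknown.
#' @export
AA_ALPHABET_STRICT <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Construct a protein record
#'
#' @param id Identifier (header token for FASTA-derived records).
#' @param sequence Amino-acid string; upper-cased; restricted to the 20
#'   standard residues plus `X`.
#' @param chain_label Optional chain label (e.g. for multi-chain antigens
#'   such as fibrinogen).
#' @return An object of class `protein_record` with elements `id`,
#'   `sequence`, `length` and `chain_label`.
#' @export
protein_record <- function(id, sequence, chain_label = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("protein '", id, "': sequence is empty")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET_STRICT)
  if (length(bad) > 0) {
    stop("protein '", id, "': illegal residue character '", bad[[1]], "'")
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         chain_label = chain_label),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, "-", x$length, "aa\n")
  invisible(x)
}

# Residue characters of a protein as a vector.
protein_chars <- function(protein) {
  strsplit(protein$sequence, "", fixed = TRUE)[[1]]
}

#' Construct a filtered citrullination site set
#'
#' Holds the residues called citrullinated for one protein under one
#' condition (e.g. PAD2, PAD4 or combined), together with the per-site
#' evidence that survived filtering.
#'
#' @param protein_id Protein identifier.
#' @param condition Condition label.
#' @param positions Integer vector of 1-based residue indices.
#' @param evidence Optional data frame of per-site evidence
#'   (`residue`, `cit_abundance`, `total_abundance`, `fraction`).
#' @param protein Optional [protein_record()]; when given, every position is
#'   checked to be an arginine in the native sequence.
#' @return Object of class `cit_site_set`.
#' @export
cit_site_set <- function(protein_id, condition, positions,
                         evidence = NULL, protein = NULL) {
  positions <- sort(unique(as.integer(positions)))
  if (!is.null(protein)) {
    chars <- protein_chars(protein)
    if (any(positions < 1L | positions > protein$length)) {
      stop("citrulline positions outside [1, ", protein$length, "]")
    }
    non_arg <- positions[chars[positions] != "R"]
    if (length(non_arg) > 0) {
      stop("position ", non_arg[[1]], " of protein '", protein_id,
           "' is not an arginine")
    }
  }
  structure(
    list(protein_id = protein_id, condition = condition,
         positions = positions, evidence = evidence),
    class = "cit_site_set"
  )
}

#' @export
print.cit_site_set <- function(x, ...) {
  cat("<cit_site_set>", x$protein_id, "/", x$condition, "-",
      length(x$positions), "site(s)\n")
  invisible(x)
}

#' Construct a Calpha structure model
#'
#' @param protein_id Protein identifier.
#' @param coords Numeric matrix with three columns (x, y, z in Angstrom);
#'   row names are 1-based residue indices.
#' @return Object of class `structure_model` with `coords` and integer
#'   `coverage` (residues that have a coordinate).
#' @export
structure_model <- function(protein_id, coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have three columns (x, y, z)")
  idx <- as.integer(rownames(coords))
  if (anyNA(idx)) stop("coords row names must be residue indices")
  if (anyDuplicated(idx)) {
    stop("duplicate residue index in structure: ", idx[duplicated(idx)][[1]])
  }
  if (any(idx < 1L)) stop("residue indices must be >= 1")
  o <- order(idx)
  coords <- coords[o, , drop = FALSE]
  structure(
    list(protein_id = protein_id, coords = coords, coverage = idx[o]),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$protein_id, "-", length(x$coverage),
      "residue(s) with Calpha coordinates\n")
  invisible(x)
}

#' Structural-deviation scalars for one antigen
#'
#' Root-mean-square deviation and TM-score between the native and
#' citrullinated predicted structures, consumed as precomputed inputs.
#'
#' @param protein_id Protein identifier.
#' @param rmsd RMSD in Angstrom (>= 0).
#' @param tm_score TM-score in (0, 1].
#' @return Object of class `structural_comparison`.
#' @export
structural_comparison <- function(protein_id, rmsd, tm_score) {
  .assert_scalar_number(rmsd, "rmsd")
  .assert_scalar_number(tm_score, "tm_score")
  if (rmsd < 0) stop("rmsd must be >= 0")
  if (tm_score <= 0 || tm_score > 1) stop("tm_score must lie in (0, 1]")
  structure(list(protein_id = protein_id, rmsd = rmsd, tm_score = tm_score),
            class = "structural_comparison")
}

# Bootstrap result container shared by the cut-site and distance nulls.
bootstrap_result <- function(observed, null_values, n_iterations, seed,
                             tail = c("ge", "le")) {
  tail <- match.arg(tail)
  p <- if (tail == "ge") mean(null_values >= observed) else
    mean(null_values <= observed)
  structure(
    list(observed = observed,
         expected = mean(null_values),
         p_value = p,
         n_iterations = n_iterations,
         seed = seed,
         null_mean = mean(null_values),
         null_sd = stats::sd(null_values)),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> observed %.4g, expected %.4g, p = %s (%d iterations)\n",
    x$observed, x$expected,
    if (x$p_value == 0) sprintf("< %.3g", 1 / x$n_iterations)
    else format(x$p_value), x$n_iterations))
  invisible(x)
}
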