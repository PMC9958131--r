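# Readers and writers for the external formats: FASTA sequences, PDB Calpha
# coordinates, the canonical peptide quantification table, and MHC-II
# binding-prediction tables.

#' Read protein sequences from a FASTA file
#'
#' The header token before the first whitespace becomes the record id;
#' sequences are upper-cased and validated against the 20 standard residues
#' plus `X`.
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_record()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  .fasta_validate(path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aa))
  lapply(seq_along(aa), function(i) {
    protein_record(ids[[i]], as.character(aa[[i]]))
  })
}

# Validate sequence lines against the package alphabet before parsing:
# the parser silently drops codes it does not recognise, whereas an
# illegal residue should fail loudly, naming character and record.
.fasta_validate <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  current_id <- "<no header>"
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      current_id <- sub("\\s.*$", "", sub("^>", "", ln))
      next
    }
    chars <- unique(strsplit(toupper(ln), "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, c(AA_ALPHABET_STRICT, " ", "\t"))
    if (length(bad) > 0) {
      stop("FASTA '", path, "', record '", current_id,
           "': illegal residue character '", bad[[1]], "'", call. = FALSE)
    }
  }
  invisible(path)
}

#' Write protein records to a FASTA file
#'
#' @param proteins List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  lines <- unlist(lapply(proteins, function(p) c(paste0(">", p$id), p$sequence)))
  writeLines(lines, path)
  invisible(path)
}

#' Read Calpha coordinates from a PDB file
#'
#' Retains `ATOM` records whose atom name is `CA` on the requested chain,
#' keeping only blank or `'A'` alternate-location indicators.  The residue
#' sequence number plus `offset` becomes the 1-based residue index, so
#' structures numbered from an arbitrary first residue can be aligned to the
#' sequence coordinate system.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier (default `"A"`).
#' @param offset Integer added to the PDB residue numbers (default 0).
#' @param protein_id Identifier for the returned model; defaults to the file
#'   base name.
#' @return A [structure_model()].
#' @export
read_ca_coordinates <- function(path, chain = "A", offset = 0L,
                                protein_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & at$elety == "CA" & at$chain == chain &
    (is.na(at$alt) | at$alt %in% c("", "A"))
  keep[is.na(keep)] <- FALSE
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) {
    stop("no CA atoms for chain '", chain, "' in ", path)
  }
  idx <- at$resno + as.integer(offset)
  if (anyDuplicated(idx)) {
    stop("duplicate residue index after filtering: ", idx[duplicated(idx)][[1]])
  }
  coords <- cbind(x = at$x, y = at$y, z = at$z)
  rownames(coords) <- idx
  structure_model(protein_id %||% sub("\\.pdb$", "", basename(path)), coords)
}

# Column names reserved for peptide identity in the canonical table; all
# other columns of the form <condition>.<replicate> carry abundances.
.PEPTIDE_ID_COLS <- c("protein_id", "peptide", "start", "end", "cit_positions")

#' Read a peptide quantification table
#'
#' The canonical format is tab-separated with a header:
#' `protein_id  peptide  start  end  cit_positions  <condition>.<rep> ...`.
#' `cit_positions` is a comma-separated list of protein coordinates carrying
#' citrulline (empty for unmodified peptides).  Abundance columns are named
#' `<condition>.<replicate>` with replicates paired by index across
#' conditions.  Blank or missing abundances are read as 0 (label-free
#' absence).  Rows duplicating one (protein, peptide, modification-state)
#' species have their abundances summed per replicate, with a warning.
#'
#' @param path Path to the table.
#' @param schema Optional named character vector renaming non-canonical
#'   identity columns, e.g. `c(protein_id = "Protein.Accession")`.
#' @return A `data.frame` of peptide measurements: the identity columns plus
#'   one numeric column per condition/replicate, and a list column
#'   `cit_positions` of integer protein coordinates.
#' @export
read_peptide_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!is.null(schema)) {
    for (logical_name in names(schema)) {
      j <- match(schema[[logical_name]], names(df))
      if (!is.na(j)) names(df)[j] <- logical_name
    }
  }
  required <- c("protein_id", "peptide")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("peptide table missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  ab_cols <- setdiff(grep("^.+\\.[0-9]+$", names(df), value = TRUE),
                     .PEPTIDE_ID_COLS)
  if (length(ab_cols) == 0) {
    stop("peptide table has no <condition>.<replicate> abundance columns")
  }
  for (col in ab_cols) {
    v <- df[[col]]
    v[is.na(v) | v == ""] <- "0"
    v <- as.numeric(v)
    if (anyNA(v)) stop("non-numeric abundance in column '", col, "'")
    if (any(v < 0)) stop("negative abundance in column '", col, "'")
    df[[col]] <- v
  }
  df$start <- if ("start" %in% names(df)) as.integer(df$start) else NA_integer_
  df$end <- if ("end" %in% names(df)) as.integer(df$end) else NA_integer_
  cit_raw <- if ("cit_positions" %in% names(df)) df$cit_positions else
    rep("", nrow(df))
  df$cit_positions <- lapply(cit_raw, .parse_positions)
  df <- df[c(.PEPTIDE_ID_COLS, ab_cols)]

  key <- paste(df$protein_id, df$peptide,
               vapply(df$cit_positions, paste, "", collapse = ","), sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicated (protein, peptide, modification-state) rows: ",
            "abundances summed per replicate")
    first <- !duplicated(key)
    sums <- rowsum(as.matrix(df[ab_cols]), group = key, reorder = FALSE)
    out <- df[first, , drop = FALSE]
    out[ab_cols] <- sums[match(key[first], rownames(sums)), , drop = FALSE]
    df <- out
  }
  rownames(df) <- NULL
  df
}

.parse_positions <- function(s) {
  if (is.na(s) || s == "") return(integer(0))
  sort(unique(as.integer(strsplit(s, ",", fixed = TRUE)[[1]])))
}

#' Write a peptide table in the canonical format
#'
#' Round-trips with [read_peptide_table()].
#'
#' @param peptides Peptide data frame as returned by [read_peptide_table()]
#'   or [simulate_protmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  out <- peptides
  out$cit_positions <- vapply(peptides$cit_positions, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Names of abundance columns for one condition, ordered by replicate index.
condition_columns <- function(peptides, condition) {
  cols <- grep(paste0("^", .escape_regex(condition), "\\.[0-9]+$"),
               names(peptides), value = TRUE)
  if (length(cols) == 0) {
    stop("no abundance columns for condition '", condition, "'")
  }
  cols[order(as.integer(sub("^.*\\.", "", cols)))]
}

#' Condition labels present in a peptide table
#'
#' @param peptides Peptide data frame.
#' @return Character vector of condition labels.
#' @export
peptide_conditions <- function(peptides) {
  ab_cols <- setdiff(grep("^.+\\.[0-9]+$", names(peptides), value = TRUE),
                     .PEPTIDE_ID_COLS)
  unique(sub("\\.[0-9]+$", "", ab_cols))
}

#' Per-replicate abundance matrix for one condition
#'
#' @param peptides Peptide data frame.
#' @param condition Condition label.
#' @return Numeric matrix, one row per peptide, one column per replicate
#'   (ordered by replicate index).
#' @export
peptide_abundances <- function(peptides, condition) {
  as.matrix(peptides[condition_columns(peptides, condition)])
}

.escape_regex <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)

#' Locate a peptide on its parent protein
#'
#' Exact substring search in protein coordinates.  A `Q` in the peptide is
#' allowed to match an `R` in the protein at a citrulline-annotated position
#' (citrulline is conventionally modelled by glutamine in sequence space).
#' The first match is returned; the ambiguity flag reports whether further
#' matches exist.
#'
#' @param protein A [protein_record()].
#' @param peptide_sequence Peptide string.
#' @param cit_sites Optional [cit_site_set()]; when supplied, Q-to-R
#'   equivalence is restricted to its positions.  When `NULL`, any `R` may
#'   match a peptide `Q`.
#' @return List with `start`, `end` (1-based inclusive) and `ambiguous`.
#' @export
locate_peptide <- function(protein, peptide_sequence, cit_sites = NULL) {
  np <- nchar(peptide_sequence)
  if (np < 1) stop("peptide must have length >= 1")
  L <- protein$length
  if (np > L) stop("peptide '", peptide_sequence, "' not found in protein '",
                   protein$id, "'")
  prot <- protein_chars(protein)
  pep <- strsplit(toupper(peptide_sequence), "", fixed = TRUE)[[1]]
  allowed_r <- if (is.null(cit_sites)) seq_len(L) else cit_sites$positions
  matches <- integer(0)
  for (s in seq_len(L - np + 1L)) {
    window <- prot[s:(s + np - 1L)]
    ok <- window == pep |
      (pep == "Q" & window == "R" & (s:(s + np - 1L)) %in% allowed_r)
    if (all(ok)) {
      matches <- c(matches, s)
      if (length(matches) > 1L) break
    }
  }
  if (length(matches) == 0) {
    stop("peptide '", peptide_sequence, "' not found in protein '",
         protein$id, "'")
  }
  list(start = matches[[1]], end = matches[[1]] + np - 1L,
       ambiguous = length(matches) > 1L)
}

#' Read an MHC-II binding-prediction table
#'
#' The canonical format is tab-separated with a header
#' `peptide  allele  core  core_offset  affinity_nm`, i.e. parsed predictor
#' output with a 0-based core offset and predicted IC50 in nM.  A tolerant
#' dialect accepts raw NetMHCII-style text by skipping rule/comment lines
#' and mapping columns by header token.
#'
#' @param path Path to the table.
#' @param dialect `"canonical"` (default) or `"netmhcii"`.
#' @return `data.frame` with columns `peptide`, `allele`, `core`,
#'   `core_offset`, `affinity_nm`.
#' @export
read_affinity_table <- function(path, dialect = c("canonical", "netmhcii")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("affinity table not found: ", path)
  if (dialect == "canonical") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    required <- c("peptide", "allele", "core", "core_offset", "affinity_nm")
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("affinity table missing column(s): ",
           paste(missing, collapse = ", "))
    }
    df <- df[required]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|-|$)", lines)]
    if (length(lines) < 2) stop("no data rows in NetMHCII output: ", path)
    toks <- strsplit(trimws(lines), "\\s+")
    header <- tolower(toks[[1]])
    pick <- function(...) {
      for (cand in c(...)) {
        j <- match(cand, header)
        if (!is.na(j)) return(j)
      }
      stop("cannot find column ", paste(c(...), collapse = "/"),
           " in NetMHCII output header")
    }
    j_pep <- pick("peptide")
    j_all <- pick("allele", "mhc")
    j_core <- pick("core")
    j_off <- pick("of", "offset", "pos")
    j_aff <- pick("affinity(nm)", "affinity", "aff(nm)", "ic50")
    rows <- toks[-1]
    rows <- rows[vapply(rows, length, 0L) >= max(j_pep, j_all, j_core,
                                                 j_off, j_aff)]
    df <- data.frame(
      peptide = vapply(rows, `[[`, "", j_pep),
      allele = vapply(rows, `[[`, "", j_all),
      core = vapply(rows, `[[`, "", j_core),
      core_offset = as.integer(vapply(rows, `[[`, "", j_off)),
      affinity_nm = as.numeric(vapply(rows, `[[`, "", j_aff)),
      stringsAsFactors = FALSE
    )
  }
  df$core_offset <- as.integer(df$core_offset)
  df$affinity_nm <- as.numeric(df$affinity_nm)
  if (any(df$affinity_nm <= 0)) {
    stop("non-positive predicted affinity in ", path)
  }
  stated <- substr(df$peptide, df$core_offset + 1L,
                   df$core_offset + nchar(df$core))
  bad <- which(stated != df$core)
  if (length(bad) > 0) {
    stop("core '", df$core[bad[[1]]], "' not found at offset ",
         df$core_offset[bad[[1]]], " of peptide '", df$peptide[bad[[1]]], "'")
  }
  df
}

#' Write an affinity table in the canonical format
#'
#' @param predictions Data frame as returned by [read_affinity_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity_table <- function(predictions, path) {
  utils::write.table(
    predictions[c("peptide", "allele", "core", "core_offset", "affinity_nm")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
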