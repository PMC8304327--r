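#' Read a Skyline-style transition report
#'
#' Parses a tab-separated transition-level export with one row per extracted
#' fragment-ion chromatogram area.  The expected columns are
#' `modified_sequence`, `precursor_charge`, `fragment_ion`, `label_channel`
#' (\code{"light"}/\code{"heavy"}), `sample_id`, `replicate` and `area`.
#' Unparseable areas become missing values (with a warning) rather than
#' dropping the row, so that downstream code can flag incomplete peptides.
#'
#' Phosphosites may be written either inline (\code{"pS"}, \code{"pT"}) or in
#' bracketed delta-mass notation (\code{"S[+80]"}); the latter is converted to
#' the inline form on input.
#'
#' @param path path to a TSV file.
#' @return a tibble of transition records.
#' @export
read_transition_report <- function(path) {
  if (!file.exists(path)) stop("transition report not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("modified_sequence", "precursor_charge", "fragment_ion",
                "label_channel", "sample_id", "replicate", "area")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("transition report is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("transition report is empty: ", path)
    return(tibble::tibble(
      modified_sequence = character(), precursor_charge = integer(),
      fragment_ion = character(), label_channel = character(),
      sample_id = character(), replicate = integer(), area = double()
    ))
  }
  area <- suppressWarnings(as.numeric(df$area))
  n_bad <- sum(is.na(area) & !is.na(df$area) & df$area != "")
  if (n_bad > 0) {
    warning(n_bad, " transition row(s) with unparseable area set to missing")
  }
  out <- tibble::tibble(
    modified_sequence = canonical_phospho(df$modified_sequence),
    precursor_charge = as.integer(df$precursor_charge),
    fragment_ion = df$fragment_ion,
    label_channel = df$label_channel,
    sample_id = df$sample_id,
    replicate = as.integer(df$replicate),
    area = area
  )
  bad_channel <- !out$label_channel %in% c("light", "heavy")
  if (any(bad_channel)) {
    stop("invalid label_channel value(s): ",
         paste(unique(out$label_channel[bad_channel]), collapse = ", "))
  }
  out
}

#' Convert bracketed phospho notation to the inline canonical form
#'
#' \code{"S[+80]"} (any bracketed mass close to 79.97/80 Da on S/T/Y) becomes
#' \code{"pS"}.  Sequences already in inline form pass through unchanged.
#'
#' @param seqs character vector of modified peptide sequences.
#' @return character vector in inline \code{"pS"}/\code{"pT"} notation.
#' @export
canonical_phospho <- function(seqs) {
  gsub("([STY])\\[\\+(80|79\\.9[0-9]*)\\]", "p\\1", seqs)
}

#' Strip phospho marks from a modified sequence
#' @param seqs character vector in inline notation.
#' @return the unmodified backbone sequence.
#' @export
strip_phospho <- function(seqs) gsub("p([STY])", "\\1", seqs)

#' Read a MaxQuant-style proteinGroups table
#'
#' Parses the tab-separated `proteinGroups.txt` dialect: "+"/"" QC flags are
#' converted to logicals, per-sample quantification columns (`iBAQ <sample>`
#' or `Ratio H/L normalized <sample>`) are parsed to numerics with 0 treated
#' as missing (MaxQuant writes 0 for "not quantified"), and per-sample
#' `Identification type <sample>` columns become logical "identified by
#' MS/MS" flags.  Per-sample columns are renamed to the canonical
#' `ibaq_<sample>`, `hl_<sample>` and `idtype_<sample>` used throughout the
#' interactome module.
#'
#' @param path path to a TSV file.
#' @return a tibble with one row per protein group.
#' @export
read_protein_groups <- function(path) {
  if (!file.exists(path)) stop("proteinGroups file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  ibaq_cols <- grep("^iBAQ .+", names(df), value = TRUE)
  ratio_cols <- grep("^Ratio H/L normalized .+", names(df), value = TRUE)
  if (length(ibaq_cols) + length(ratio_cols) == 0) {
    stop("no quantification columns (iBAQ/Ratio H/L normalized) found in ", path)
  }
  id_cols <- grep("^Identification type .+", names(df), value = TRUE)
  flag <- function(col) {
    if (col %in% names(df)) trimws(df[[col]]) == "+" else rep(FALSE, nrow(df))
  }
  num <- function(col) {
    if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else
      rep(NA_real_, nrow(df))
  }
  out <- tibble::tibble(
    group_id = if ("id" %in% names(df)) df[["id"]] else as.character(seq_len(nrow(df))),
    protein_ids = df[["Protein IDs"]] %||% NA_character_,
    gene_names = df[["Gene names"]] %||% NA_character_,
    reverse = flag("Reverse"),
    contaminant = flag("Potential contaminant"),
    only_by_site = flag("Only identified by site"),
    unique_peptides = as.integer(num("Unique peptides")),
    peptides = as.integer(num("Peptides")),
    msms_count = as.integer(num("MS/MS count"))
  )
  for (col in ibaq_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    v[!is.na(v) & v == 0] <- NA_real_   # intensity 0 == not quantified
    out[[paste0("ibaq_", sub("^iBAQ ", "", col))]] <- v
  }
  for (col in ratio_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    v[!is.na(v) & v == 0] <- NA_real_
    out[[paste0("hl_", sub("^Ratio H/L normalized ", "", col))]] <- v
  }
  for (col in id_cols) {
    out[[paste0("idtype_", sub("^Identification type ", "", col))]] <-
      trimws(df[[col]]) == "By MS/MS"
  }
  out
}

#' Read the bait protein FASTA
#'
#' Returns the amino-acid sequence used to anchor 1-based residue coordinates
#' (phosphosites, cleavage sites, peptide spans).
#'
#' @param path path to a FASTA file with a single protein sequence.
#' @return list with `name`, `sequence` (single string), `length`.
#' @export
read_bait_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) != 1) stop("expected exactly one sequence in ", path)
  list(name = names(aa)[1],
       sequence = as.character(aa[[1]]),
       length = Biostrings::width(aa)[1])
}

#' Check a residue at a 1-based coordinate on the bait sequence
#'
#' @param bait list as returned by [read_bait_fasta()].
#' @param residue expected one-letter amino-acid code (e.g. "S").
#' @param position 1-based residue index.
#' @return invisibly TRUE; errors if the residue does not match.
#' @export
check_site_residue <- function(bait, residue, position) {
  if (position < 1 || position > bait$length) {
    stop("position ", position, " outside protein length ", bait$length)
  }
  found <- substr(bait$sequence, position, position)
  if (found != residue) {
    stop("residue at position ", position, " is ", found, ", expected ", residue)
  }
  invisible(TRUE)
}

#' Read a capillary-western measurement table
#'
#' CSV with columns `target` (HA/actin/desthiobiotin), `compartment`
#' (CM/lysate), `construct`, `nucleotide` (ATP/ADP/none), `replicate`,
#' `signal`, `fraction_analyzed`.
#'
#' @param path path to a CSV file.
#' @return a tibble of measurements.
#' @export
read_cwb_measurements <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  required <- c("target", "compartment", "construct", "replicate",
                "signal", "fraction_analyzed")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("CWB table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"nucleotide" %in% names(df)) df$nucleotide <- "none"
  if (any(df$signal < 0, na.rm = TRUE)) stop("negative CWB signal")
  if (any(df$fraction_analyzed <= 0 | df$fraction_analyzed > 1, na.rm = TRUE)) {
    stop("fraction_analyzed must be in (0, 1]")
  }
  df
}

#' Read a gel-band peptide intensity table
#'
#' CSV with columns `peptide`, `start`, `end` (1-based inclusive residue
#' span), `genotype`, `dose`, `band`, `intensity`.
#'
#' @param path path to a CSV file.
#' @param protein_length optional bait length used to validate spans.
#' @return a tibble (a band-peptide matrix in long form).
#' @export
read_band_matrix <- function(path, protein_length = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  required <- c("peptide", "start", "end", "genotype", "dose", "band", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("band table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.null(protein_length) &&
      any(df$start < 1 | df$end > protein_length | df$start > df$end)) {
    stop("peptide span outside protein length ", protein_length)
  }
  df
}

#' Write a result table as TSV
#'
#' UTF-8, "." decimal separator, matching the MaxQuant/Skyline export
#' conventions the readers expect, so that write-then-read round-trips.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a transition report
#'
#' Emits the TSV dialect [read_transition_report()] reads, so tables
#' round-trip exactly (string-normalized).
#'
#' @param transitions transition-record tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(transitions, path) {
  write_result_tsv(transitions, path)
}

#' Write a protein-group table in the MaxQuant dialect
#'
#' Converts a canonical protein-group tibble back to the `proteinGroups.txt`
#' column dialect: logical flags become "+"/"", `ibaq_<s>`/`hl_<s>` become
#' `iBAQ <s>`/`Ratio H/L normalized <s>` (missing written as 0, as MaxQuant
#' does), and `idtype_<s>` becomes `Identification type <s>`.
#'
#' @param groups canonical protein-group tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(groups, path) {
  out <- data.frame(check.names = FALSE,
    id = groups$group_id,
    `Protein IDs` = groups$protein_ids,
    `Gene names` = groups$gene_names,
    Reverse = ifelse(groups$reverse, "+", ""),
    `Potential contaminant` = ifelse(groups$contaminant, "+", ""),
    `Only identified by site` = ifelse(groups$only_by_site, "+", ""),
    `Unique peptides` = groups$unique_peptides,
    Peptides = groups$peptides,
    `MS/MS count` = groups$msms_count
  )
  for (col in grep("^ibaq_", names(groups), value = TRUE)) {
    v <- groups[[col]]; v[is.na(v)] <- 0
    out[[paste0("iBAQ ", sub("^ibaq_", "", col))]] <- v
  }
  for (col in grep("^hl_", names(groups), value = TRUE)) {
    v <- groups[[col]]; v[is.na(v)] <- 0
    out[[paste0("Ratio H/L normalized ", sub("^hl_", "", col))]] <- v
  }
  for (col in grep("^idtype_", names(groups), value = TRUE)) {
    out[[paste0("Identification type ", sub("^idtype_", "", col))]] <-
      ifelse(groups[[col]], "By MS/MS", "")
  }
  write_result_tsv(out, path)
}

#' Write a provenance log for a pipeline run
#'
#' Records the seed, a hash of the configuration object and package/R
#' versions, so that two runs with identical inputs and seed are provably
#' identical.
#'
#' @param path output file.
#' @param seed integer seed used for the run.
#' @param config configuration object (any R value).
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, seed, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- c(
    paste0("seed: ", seed),
    paste0("config_hash: ", rlang::hash(config)),
    paste0("package: hsp90cl ", as.character(utils::packageVersion("hsp90cl"))),
    paste0("r_version: ", R.version.string)
  )
  writeLines(lines, path)
  invisible(path)
}
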