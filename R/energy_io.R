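# I/O for species-energy tables, Gaussian-style QC logs, and profile documents.

.species_cols <- c("label", "step", "model", "functional", "basis",
                   "solvent", "energy_au")

#' Construct a species-energy table
#'
#' A `species_table` is a data.frame with one row per stationary point:
#' `label` (species, e.g. RC/TS1/IM1), `step` (elementary step), `model`
#' (cluster model, e.g. QM1/QM2/QM3), `functional`, `basis`, `solvent`
#' (together the method), `energy_au` (absolute electronic energy, hartree)
#' and optionally `charge` (total model charge). The key
#' (label, step, model, functional, basis, solvent) must be unique.
#'
#' @param df data.frame with at least the required columns.
#' @param model_charge if given, every non-missing `charge` entry must equal
#'   this declared total model charge.
#' @return the validated data.frame with class `species_table`.
#' @export
species_table <- function(df, model_charge = NULL) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.species_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$energy_au) || any(!is.finite(df$energy_au))) {
    stop("`energy_au` must be finite numeric (hartree)", call. = FALSE)
  }
  key <- do.call(paste, c(df[.species_cols[-7]], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE]
    stop("duplicate species entries for (label, step, model, method): ",
         paste(unique(paste(dup$label, dup$step, dup$model, dup$functional,
                            sep = "/")), collapse = "; "), call. = FALSE)
  }
  if (!is.null(model_charge) && "charge" %in% names(df)) {
    bad <- !is.na(df$charge) & df$charge != model_charge
    if (any(bad)) {
      stop("charge of ", paste(df$label[bad], collapse = ", "),
           " differs from the declared model charge ", model_charge,
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("species_table", "data.frame")
  df
}

#' Read a species-energy table from delimited text
#'
#' Expects a header declaring at least the columns
#' `label, step, model, functional, basis, solvent, energy_au` (`charge`
#' optional); the delimiter is detected from the header line (tab if present,
#' otherwise comma). Energies are decimal hartree. Row order is preserved.
#'
#' @param path path to a TSV/CSV file.
#' @param sep field delimiter; `NULL` (default) detects tab vs comma.
#' @param model_charge optional declared total charge checked against the
#'   `charge` column (see [species_table()]).
#' @return a [species_table()].
#' @export
load_species_table <- function(path, sep = NULL, model_charge = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: no header line", call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          check.names = TRUE, quote = "\"",
                          blank.lines.skip = TRUE)
  missing_cols <- setdiff(.species_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  energy <- suppressWarnings(as.numeric(df$energy_au))
  if (nrow(df) > 0 && any(is.na(energy))) {
    bad <- which(is.na(energy))[1]
    stop(sprintf("unparseable energy_au %s at data row %d (file line %d)",
                 dQuote(df$energy_au[bad]), bad, bad + 1L), call. = FALSE)
  }
  df$energy_au <- energy
  if ("charge" %in% names(df)) df$charge <- as.integer(df$charge)
  species_table(df, model_charge = model_charge)
}

#' Write a species-energy table to delimited text
#'
#' Energies are written with nine decimals so relative energies survive a
#' round trip at better than 1e-6 kcal/mol.
#'
#' @param df a [species_table()] or compatible data.frame.
#' @param path destination file.
#' @param sep field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_species_table <- function(df, path, sep = "\t") {
  out <- as.data.frame(df)
  out$energy_au <- formatC(out$energy_au, format = "f", digits = 9)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a quantum-chemistry log record
#'
#' Holds the fields retained from a Gaussian-style text log: the final SCF
#' electronic energy (hartree), harmonic wavenumbers (cm^-1, negative values
#' encode imaginary modes), the program's printed thermal corrections
#' (hartree), the continuum dielectric constant, and molecule metadata
#' (mass in amu, rotational constants in GHz, symmetry number, charge,
#' multiplicity).
#'
#' @param final_energy_au final electronic energy, hartree.
#' @param frequencies_cm1 numeric vector of harmonic wavenumbers (cm^-1).
#' @param thermal_corrections optional named list with any of `zpe`, `energy`,
#'   `enthalpy`, `gibbs` (hartree, as printed by the generating program).
#' @param dielectric optional relative permittivity of the continuum model
#'   (must exceed 1 when given).
#' @param mass_amu,rotational_constants_ghz,symmetry_number,charge,multiplicity
#'   optional molecule metadata.
#' @param n_atoms optional declared atom count; when given, the frequency
#'   count may not exceed 3N-5.
#' @return an object of class `qc_record`.
#' @export
qc_record <- function(final_energy_au,
                      frequencies_cm1 = numeric(0),
                      thermal_corrections = NULL,
                      dielectric = NULL,
                      mass_amu = NULL,
                      rotational_constants_ghz = NULL,
                      symmetry_number = NULL,
                      charge = NULL,
                      multiplicity = NULL,
                      n_atoms = NULL) {
  stopifnot(is.numeric(final_energy_au), length(final_energy_au) == 1,
            is.finite(final_energy_au))
  frequencies_cm1 <- as.numeric(frequencies_cm1)
  if (!is.null(dielectric) && dielectric <= 1) {
    stop("a declared continuum model requires dielectric > 1", call. = FALSE)
  }
  if (!is.null(n_atoms) && length(frequencies_cm1) > max(0, 3 * n_atoms - 5)) {
    stop("more frequencies than 3N-5 for the declared atom count",
         call. = FALSE)
  }
  structure(list(
    final_energy_au = final_energy_au,
    frequencies_cm1 = frequencies_cm1,
    thermal_corrections = thermal_corrections,
    dielectric = dielectric,
    mass_amu = mass_amu,
    rotational_constants_ghz = rotational_constants_ghz,
    symmetry_number = symmetry_number,
    charge = charge,
    multiplicity = multiplicity,
    n_atoms = n_atoms
  ), class = "qc_record")
}

#' @export
print.qc_record <- function(x, ...) {
  cat("<qc_record>\n")
  cat(sprintf("  final energy: %.9f hartree\n", x$final_energy_au))
  cat(sprintf("  frequencies: %d mode(s)", length(x$frequencies_cm1)))
  n_imag <- sum(x$frequencies_cm1 < 0)
  if (n_imag > 0) cat(sprintf(" (%d imaginary)", n_imag))
  cat("\n")
  if (!is.null(x$dielectric)) cat(sprintf("  dielectric: %g\n", x$dielectric))
  invisible(x)
}

.num_re <- "[-+]?[0-9]*\\.?[0-9]+(?:[EeDd][-+]?[0-9]+)?"

.parse_fortran_num <- function(s) as.numeric(gsub("[Dd]", "e", s))

#' Parse a Gaussian-style quantum-chemistry text log
#'
#' Supported conventions: `SCF Done:` energy lines (the last one wins),
#' `Frequencies --` blocks (up to three wavenumbers per line, concatenated in
#' file order; negative values are imaginary modes), `Zero-point correction=`,
#' `Thermal correction to Energy/Enthalpy/Gibbs Free Energy=`, `Eps=`
#' (continuum dielectric), `Molecular mass:`, `Rotational constants (GHZ):`,
#' `Rotational symmetry number`, and `Charge = ... Multiplicity = ...`.
#' Absent sections yield empty/absent fields; a log with no energy line at
#' all is an error.
#'
#' @param path path to a log file, or a character vector of log lines via
#'   `text`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a [qc_record()].
#' @export
parse_qc_log <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)

  grab_last <- function(pattern) {
    hits <- grep(pattern, lines)
    if (length(hits) == 0) return(NULL)
    m <- regmatches(lines[max(hits)],
                    regexec(pattern, lines[max(hits)]))[[1]]
    .parse_fortran_num(m[2])
  }

  energy <- grab_last(paste0("SCF Done:\\s+E\\([^)]*\\)\\s*=\\s*(", .num_re, ")"))
  if (is.null(energy)) {
    stop("no 'SCF Done:' energy line found in log", call. = FALSE)
  }

  freqs <- numeric(0)
  freq_lines <- grep("Frequencies\\s*--", lines)
  for (i in freq_lines) {
    payload <- sub(".*Frequencies\\s*--", "", lines[i])
    toks <- strsplit(trimws(payload), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(.parse_fortran_num(toks))
    if (length(toks) == 0 || any(is.na(vals))) {
      stop(sprintf("malformed frequency line %d: %s", i, dQuote(lines[i])),
           call. = FALSE)
    }
    freqs <- c(freqs, vals)
  }

  thermo <- list(
    zpe      = grab_last(paste0("Zero-point correction=\\s*(", .num_re, ")")),
    energy   = grab_last(paste0("Thermal correction to Energy=\\s*(", .num_re, ")")),
    enthalpy = grab_last(paste0("Thermal correction to Enthalpy=\\s*(", .num_re, ")")),
    gibbs    = grab_last(paste0(
      "Thermal correction to Gibbs Free Energy=\\s*(", .num_re, ")"))
  )
  thermo <- thermo[!vapply(thermo, is.null, logical(1))]
  if (length(thermo) == 0) thermo <- NULL

  rot <- NULL
  rot_hits <- grep("Rotational constants \\(GHZ\\):", lines)
  if (length(rot_hits) > 0) {
    payload <- sub(".*Rotational constants \\(GHZ\\):", "", lines[max(rot_hits)])
    rot <- .parse_fortran_num(strsplit(trimws(payload), "\\s+")[[1]])
  }

  sym <- grab_last("Rotational symmetry number\\s+([0-9]+)")
  chg <- grab_last(paste0("Charge\\s*=\\s*(", .num_re, ")\\s+Multiplicity"))
  mult <- grab_last(paste0("Multiplicity\\s*=\\s*(", .num_re, ")"))

  qc_record(
    final_energy_au = energy,
    frequencies_cm1 = freqs,
    thermal_corrections = thermo,
    dielectric = grab_last(paste0("Eps=\\s*(", .num_re, ")")),
    mass_amu = grab_last(paste0("Molecular mass:\\s*(", .num_re, ")\\s*amu")),
    rotational_constants_ghz = rot,
    symmetry_number = if (is.null(sym)) NULL else as.integer(sym),
    charge = if (is.null(chg)) NULL else as.integer(chg),
    multiplicity = if (is.null(mult)) NULL else as.integer(mult)
  )
}

#' Serialize a whole profile to a schema-versioned YAML document
#'
#' The document records the schema version, the provenance (method, model,
#' stitching procedure), the per-label step map, and the ordered profile
#' points. [read_profile_document()] reproduces the profile field-for-field.
#'
#' @param profile a [whole_profile()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_profile_document <- function(profile, path) {
  stopifnot(inherits(profile, "whole_profile"))
  doc <- list(
    schema_version = 1L,
    provenance = attr(profile, "provenance"),
    steps = as.list(attr(profile, "steps")),
    points = lapply(seq_len(nrow(profile)), function(i) {
      list(label = profile$label[i],
           branch = profile$branch[i],
           energy_kcal = profile$energy_kcal[i])
    })
  )
  writeLines(yaml::as.yaml(doc, precision = 15), path, useBytes = TRUE)
  invisible(path)
}

#' Read a whole profile from a YAML document written by
#' [write_profile_document()]
#'
#' @param path path to the document.
#' @return a [whole_profile()].
#' @export
read_profile_document <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported profile document schema version: ",
         doc$schema_version %||% "<missing>", call. = FALSE)
  }
  pts <- doc$points
  df <- data.frame(
    label = vapply(pts, `[[`, character(1), "label"),
    branch = vapply(pts, `[[`, character(1), "branch"),
    energy_kcal = vapply(pts, `[[`, numeric(1), "energy_kcal"),
    stringsAsFactors = FALSE
  )
  whole_profile(df,
                provenance = doc$provenance,
                steps = unlist(doc$steps))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
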