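# Relative-energy arithmetic within elementary steps and the QM-size
# comparison report.

#' Construct an elementary step from relative energies
#'
#' Low-level constructor: an ordered reactant -> TS -> product triple with
#' energies in kcal/mol relative to the step's reactant. Use
#' [relative_energies()] to build one from absolute electronic energies.
#'
#' @param name step identifier (e.g. "hydrolysis").
#' @param relative_kcal named numeric vector of relative energies; the
#'   reactant's entry must be exactly 0. `NA` is allowed for species whose
#'   relative energy is unknown (e.g. a product not reported).
#' @param reactant,ts,product species labels in mechanistic order; exactly
#'   one TS per step.
#' @param model,method optional provenance (cluster model; functional/basis/
#'   solvent descriptor).
#' @param energy_au optional named vector of the absolute energies (hartree).
#' @return object of class `elementary_step`.
#' @export
elementary_step <- function(name, relative_kcal, reactant, ts, product,
                            model = NA_character_, method = NA_character_,
                            energy_au = NULL) {
  stopifnot(is.numeric(relative_kcal), !is.null(names(relative_kcal)))
  for (lab in c(reactant, ts, product)) {
    if (!lab %in% names(relative_kcal)) {
      stop("species ", dQuote(lab), " absent from relative_kcal", call. = FALSE)
    }
  }
  if (!identical(unname(relative_kcal[reactant]), 0)) {
    if (is.na(relative_kcal[reactant]) || relative_kcal[reactant] != 0) {
      stop("the reactant's relative energy must be exactly 0", call. = FALSE)
    }
  }
  structure(list(
    name = name,
    reactant = reactant, ts = ts, product = product,
    relative_kcal = relative_kcal,
    energy_au = energy_au,
    model = model, method = method
  ), class = "elementary_step")
}

#' @export
print.elementary_step <- function(x, ...) {
  cat(sprintf("<elementary_step> %s  [%s / %s]\n", x$name,
              x$model %||% NA, x$method %||% NA))
  cat(sprintf("  %s -> %s -> %s\n", x$reactant, x$ts, x$product))
  rel <- display_round(x$relative_kcal)
  cat("  relative energies (kcal/mol): ",
      paste(sprintf("%s=%.1f", names(rel), rel), collapse = "  "), "\n")
  invisible(x)
}

.method_string <- function(df) {
  paste(df$functional, df$basis, df$solvent, sep = "/")
}

#' Relative energies of one elementary step from absolute energies
#'
#' Converts absolute electronic energies (hartree) of the step's stationary
#' points to energies in kcal/mol relative to a reference species; the
#' reference maps to exactly 0. All species must share the same cluster
#' model and method (functional/basis/solvent). "ES" and "RC" are synonyms.
#'
#' @param species a [species_table()] (or subset data.frame) holding the
#'   step's stationary points.
#' @param reference label of the reference species (the step's initial
#'   state), e.g. "RC" for fructosylation, "IM2" for hydrolysis.
#' @param step optional step name used to subset `species`; defaults to the
#'   single step present.
#' @return an `elementary_step` with per-species `relative_kcal`.
#' @export
#' @examples
#' tab <- species_table(data.frame(
#'   label = c("IM2", "TS2", "PC2"), step = "hydrolysis", model = "QM3",
#'   functional = "B3LYP", basis = "6-31+G(d)", solvent = "cpcm80",
#'   energy_au = c(-5943.226656, -5943.201925, -5943.250060)))
#' relative_energies(tab, reference = "IM2")
relative_energies <- function(species, reference, step = NULL) {
  df <- as.data.frame(species)
  if (!is.null(step)) df <- df[df$step == step, , drop = FALSE]
  if (nrow(df) == 0) stop("no species rows to work with", call. = FALSE)
  steps <- unique(df$step)
  if (length(steps) > 1) {
    stop("species span several steps (", paste(steps, collapse = ", "),
         "); pass `step` to select one", call. = FALSE)
  }
  meth <- unique(.method_string(df))
  if (length(unique(df$model)) > 1 || length(meth) > 1) {
    stop("all species of a step must share (model, method); found models ",
         paste(unique(df$model), collapse = ", "), " and methods ",
         paste(meth, collapse = ", "), call. = FALSE)
  }
  labs <- canonical_label(df$label)
  ref <- canonical_label(reference)
  if (!ref %in% labs) {
    stop("reference species ", dQuote(reference), " not present (have: ",
         paste(df$label, collapse = ", "), ")", call. = FALSE)
  }
  e_ref <- df$energy_au[labs == ref]
  rel <- hartree_to_kcalmol(df$energy_au - e_ref)
  rel[labs == ref] <- 0  # exact zero by construction
  names(rel) <- labs
  e_abs <- stats::setNames(df$energy_au, labs)

  # mechanistic order where the canonical vocabulary applies
  known <- labs[order(match(labs, CYCLE_SPECIES))]
  is_ts <- grepl("^TS", known)
  if (sum(is_ts) != 1) {
    stop("a step needs exactly one TS; found ", sum(is_ts), call. = FALSE)
  }
  non_ts <- known[!is_ts]
  reactant <- ref
  product <- setdiff(non_ts, reactant)
  if (length(product) == 0) product <- reactant  # degenerate single species
  elementary_step(
    name = steps, relative_kcal = rel[known],
    reactant = reactant, ts = known[is_ts], product = product[length(product)],
    model = unique(df$model), method = meth, energy_au = e_abs[known]
  )
}

#' Electronic-energy barrier of an elementary step
#'
#' The TS energy relative to the step's initial state (kcal/mol): these are
#' the per-step barriers dE1 (RC -> IM1), dE2 (IM2 -> PC2) and dE3
#' (IM3 -> PC3) of the fructosylation, hydrolysis and transfructosylation
#' steps.
#'
#' @param step an `elementary_step`.
#' @return barrier in kcal/mol.
#' @export
step_barrier <- function(step) {
  stopifnot(inherits(step, "elementary_step"))
  unname(step$relative_kcal[step$ts])
}

#' Reaction energy of an elementary step
#'
#' The product energy relative to the step's initial state (kcal/mol).
#'
#' @param step an `elementary_step`.
#' @return reaction energy in kcal/mol.
#' @export
step_reaction_energy <- function(step) {
  stopifnot(inherits(step, "elementary_step"))
  unname(step$relative_kcal[step$product])
}

#' QM-size dependence report across cluster models
#'
#' Builds a species x model grid of relative energies (kcal/mol, per-step
#' reference species at 0 in every model column) to examine how the reaction
#' energetics depend on the cluster-model size. Input rows may carry either
#' absolute energies (`energy_au`, converted per step via
#' [relative_energies()]) or precomputed relative values (`delta_e_kcal`,
#' used as given). Missing cells stay `NA`, never imputed.
#'
#' @param data data.frame with columns `label`, `step`, `model` and one of
#'   `energy_au` or `delta_e_kcal`; multiple models required.
#' @param references named character vector mapping step -> reference label;
#'   defaults to the canonical cycle (RC, IM2, IM3).
#' @return a `size_comparison`: data.frame with `label`, `step` and one
#'   numeric column per model.
#' @export
size_dependence_report <- function(data,
                                   references = c(
                                     fructosylation = "RC",
                                     hydrolysis = "IM2",
                                     transfructosylation = "IM3")) {
  df <- as.data.frame(data)
  models <- unique(df$model)
  if (length(models) < 2) {
    stop("size comparison needs >= 2 cluster models; got ",
         length(models), call. = FALSE)
  }
  df$label <- canonical_label(df$label)
  per_model <- lapply(models, function(m) {
    sub <- df[df$model == m, , drop = FALSE]
    if ("energy_au" %in% names(sub) && any(!is.na(sub$energy_au))) {
      rels <- lapply(unique(sub$step), function(s) {
        st <- relative_energies(sub[sub$step == s, , drop = FALSE],
                                reference = references[[s]])
        st$relative_kcal
      })
      unlist(rels)
    } else if ("delta_e_kcal" %in% names(sub)) {
      stats::setNames(as.numeric(sub$delta_e_kcal), sub$label)
    } else {
      stop("model ", m, " has neither energy_au nor delta_e_kcal",
           call. = FALSE)
    }
  })
  names(per_model) <- models
  all_labels <- intersect(CYCLE_SPECIES, unique(df$label))
  extra <- setdiff(unique(df$label), CYCLE_SPECIES)
  all_labels <- c(all_labels, sort(extra))
  if (length(Reduce(intersect, lapply(per_model, names))) == 0) {
    stop("no species shared across models; empty comparison", call. = FALSE)
  }
  step_of <- df$step[match(all_labels, df$label)]
  out <- data.frame(label = all_labels, step = step_of,
                    stringsAsFactors = FALSE)
  for (m in models) {
    out[[m]] <- unname(per_model[[m]][all_labels])
  }
  class(out) <- c("size_comparison", "data.frame")
  out
}
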