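# Joining half-reaction profiles of differing chemical composition into one
# whole profile relative to RC = 0.

#' Construct a whole (stitched) profile
#'
#' Ordered stationary points of the catalytic cycle on one energy axis
#' relative to the reactant complex RC (exactly 0). Each point carries a
#' branch tag: `common` for the shared glycosylation segment, `hydrolysis`
#' or `transfructosylation` for the second half-reactions.
#'
#' @param points data.frame with columns `label`, `branch`, `energy_kcal`.
#' @param provenance list with (at least) `method`, `model`, `procedure`.
#' @param steps optional named character vector mapping label -> elementary
#'   step name.
#' @return object of class `whole_profile` (a data.frame).
#' @export
whole_profile <- function(points, provenance = list(), steps = NULL) {
  stopifnot(is.data.frame(points),
            all(c("label", "branch", "energy_kcal") %in% names(points)))
  bad_branch <- setdiff(unique(points$branch),
                        c("common", "hydrolysis", "transfructosylation"))
  if (length(bad_branch) > 0) {
    stop("unknown branch tag(s): ", paste(bad_branch, collapse = ", "),
         call. = FALSE)
  }
  rc <- points$energy_kcal[canonical_label(points$label) == "RC"]
  if (length(rc) > 0 && any(rc != 0)) {
    stop("the RC point of a whole profile must sit exactly at 0", call. = FALSE)
  }
  rownames(points) <- NULL
  structure(points,
            provenance = provenance,
            steps = steps,
            class = c("whole_profile", "data.frame"))
}

#' @export
print.whole_profile <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("<whole_profile> %s / %s (procedure: %s)\n",
              p$method %||% "?", p$model %||% "?", p$procedure %||% "?"))
  for (br in unique(x$branch)) {
    rows <- x[x$branch == br, ]
    cat(sprintf("  %-20s %s\n", br,
                paste(sprintf("%s %.1f", rows$label,
                              display_round(rows$energy_kcal)),
                      collapse = " | ")))
  }
  invisible(x)
}

#' Specify the junction joining two half-reactions
#'
#' When the second half-reaction starts from a species (IM2 or IM3) whose
#' chemical composition differs from the glycosyl-enzyme intermediate IM1
#' (glucose has left; water or an acceptor has entered), its reference
#' cannot be placed on the RC = 0 axis by plain subtraction. The junction
#' assigns the second half's reference an offset relative to RC, either
#' directly (`offset_kcal`) or as the sum of components
#' `dE(donor rel RC) + dG_diss` (the dissociation free energy of the
#' leaving glucose). When both are given they must agree exactly.
#'
#' @param acceptor_reference reference label of the second half (IM2 or IM3).
#' @param donor_species label whose state the second half continues from
#'   (default IM1).
#' @param offset_kcal energy assigned to `acceptor_reference` relative to RC.
#' @param delta_e_donor optional component: donor energy relative to RC,
#'   kcal/mol. If omitted while `delta_g_diss` is given, it is taken from
#'   the first half-reaction at stitch time.
#' @param delta_g_diss optional component: dissociation free energy,
#'   kcal/mol (see [dissociation_free_energy()]).
#' @return object of class `junction_spec`.
#' @export
junction_spec <- function(acceptor_reference,
                          donor_species = "IM1",
                          offset_kcal = NULL,
                          delta_e_donor = NULL,
                          delta_g_diss = NULL) {
  if (inherits(delta_g_diss, "dissociation_correction")) {
    delta_g_diss <- delta_g_diss$delta_g_diss
  }
  if (!is.null(offset_kcal) && !is.null(delta_e_donor) &&
      !is.null(delta_g_diss)) {
    if (offset_kcal != delta_e_donor + delta_g_diss) {
      stop("offset_kcal must equal delta_e_donor + delta_g_diss exactly",
           call. = FALSE)
    }
  }
  if (is.null(offset_kcal) && is.null(delta_g_diss)) {
    stop("give offset_kcal, or delta_g_diss (plus optionally delta_e_donor)",
         call. = FALSE)
  }
  structure(list(
    donor_species = donor_species,
    acceptor_reference = acceptor_reference,
    offset_kcal = offset_kcal,
    delta_e_donor = delta_e_donor,
    delta_g_diss = delta_g_diss
  ), class = "junction_spec")
}

.resolve_offset <- function(junction, first_half) {
  if (!is.null(junction$offset_kcal)) return(junction$offset_kcal)
  de <- junction$delta_e_donor
  if (is.null(de)) {
    donor <- canonical_label(junction$donor_species)
    if (!donor %in% names(first_half$relative_kcal)) {
      stop("junction donor ", dQuote(junction$donor_species),
           " absent from the first half-reaction", call. = FALSE)
    }
    de <- unname(first_half$relative_kcal[donor])
  }
  de + junction$delta_g_diss
}

.branch_of_step <- function(step_name) {
  if (step_name %in% c("hydrolysis", "transfructosylation")) step_name
  else stop("cannot infer branch from step name ", dQuote(step_name),
            "; second halves must be hydrolysis or transfructosylation",
            call. = FALSE)
}

#' Stitch half-reactions via a dissociation-corrected junction
#'
#' Builds the whole relative energy profile from the glycosylation first
#' half-reaction and one or both deglycosylation second half-reactions. The
#' common segment carries the first half's relative energies (RC at exactly
#' 0); every species of a second half is placed at
#' `offset + rel(species vs acceptor reference)`, where the offset is the
#' junction's `dE(IM1 rel RC) + dG_diss` (or a raw calibrated offset). Both
#' branches share one junction, so their TS difference equals the step-level
#' selectivity exactly.
#'
#' @param first_half `elementary_step` of the glycosylation (fructosylation)
#'   step; its reactant becomes RC = 0.
#' @param second_halves a single `elementary_step` or a list of them
#'   (hydrolysis and/or transfructosylation).
#' @param junction a [junction_spec()].
#' @return a [whole_profile()].
#' @export
stitch_bras <- function(first_half, second_halves, junction) {
  stopifnot(inherits(first_half, "elementary_step"),
            inherits(junction, "junction_spec"))
  if (inherits(second_halves, "elementary_step")) {
    second_halves <- list(second_halves)
  }
  donor <- canonical_label(junction$donor_species)
  if (!donor %in% names(first_half$relative_kcal)) {
    stop("junction donor ", dQuote(junction$donor_species),
         " absent from the first half-reaction", call. = FALSE)
  }
  offset <- .resolve_offset(junction, first_half)

  pts <- data.frame(
    label = names(first_half$relative_kcal),
    branch = "common",
    energy_kcal = unname(first_half$relative_kcal),
    stringsAsFactors = FALSE
  )
  # the first half's reactant is the cycle's RC
  pts$label[pts$label == canonical_label(first_half$reactant)] <- "RC"
  steps <- stats::setNames(rep(first_half$name, nrow(pts)), pts$label)

  for (sh in second_halves) {
    stopifnot(inherits(sh, "elementary_step"))
    ref <- canonical_label(junction$acceptor_reference)
    branch <- .branch_of_step(sh$name)
    rel <- sh$relative_kcal
    if (!ref %in% names(rel)) {
      # the declared acceptor reference applies to the branch it names;
      # other branches are referenced to their own reactant at the same
      # junction offset (the paper's procedure: both IM2 and IM3 continue
      # from IM1 + dG_diss)
      ref <- canonical_label(sh$reactant)
    }
    if (rel[ref] != 0) {
      stop("second half ", sh$name, " is not referenced to ", ref, call. = FALSE)
    }
    pts <- rbind(pts, data.frame(
      label = names(rel), branch = branch,
      energy_kcal = offset + unname(rel),
      stringsAsFactors = FALSE
    ))
    steps <- c(steps, stats::setNames(rep(sh$name, length(rel)), names(rel)))
  }

  whole_profile(
    pts,
    provenance = list(method = first_half$method, model = first_half$model,
                      procedure = "bras",
                      junction = list(
                        donor = junction$donor_species,
                        offset_kcal = offset,
                        delta_g_diss = junction$delta_g_diss)),
    steps = steps[!duplicated(names(steps))]
  )
}

#' Back out a junction offset from an overall barrier
#'
#' Inverts the stitching identity: if a branch TS sits at
#' `offset + step_barrier` relative to RC, the offset is
#' `overall_barrier - step_barrier`. Used to calibrate the junction when the
#' intermediate's absolute placement is not reported but overall barriers
#' are.
#'
#' @param target_overall_barrier branch TS energy relative to RC, kcal/mol.
#' @param step_barrier the step's own barrier (TS relative to the step's
#'   initial state), kcal/mol.
#' @return offset in kcal/mol.
#' @export
calibrate_junction_offset <- function(target_overall_barrier, step_barrier) {
  target_overall_barrier - step_barrier
}

# ---- composition-balanced ledger stitching ---------------------------------

#' Parse a simple molecular formula into element counts
#'
#' Supports element symbols with optional counts, e.g. "C6H12O6" or "H2O".
#' Used for the composition-balance check of [stitch_balanced()].
#'
#' @param formula character formula string.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(gsub("\\s", "", formula))) {
    stop("cannot parse formula ", dQuote(formula), call. = FALSE)
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  tapply(n, el, sum)
}

.add_comp <- function(a, b, mult = 1L) {
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + mult * b
  out
}

#' Stitch states of differing composition via a balanced ledger
#'
#' Generic composition-balancing alternative to the dissociation-cycle
#' junction: for every state a stoichiometric list of auxiliary species
#' (with their absolute energies) is added so that each compared state has
#' identical atomic composition, and relative energies are then plain
#' differences of the balanced sums:
#' `energy(s) = k * ([E(s) + sum aux(s)] - [E(ref) + sum aux(ref)])` with
#' `k = 627.5095` kcal/mol per hartree and the reference at 0.
#'
#' @param states a [species_table()] of the compared stationary points.
#' @param ledger data.frame with columns `state` (species label), `aux`
#'   (auxiliary molecule name), `energy_au`, `count`; one row per auxiliary
#'   per state. States absent from the ledger get no auxiliaries.
#' @param reference_state label of the state placed at 0 (RC by default).
#' @param compositions optional named character vector of molecular formulas
#'   for states and auxiliaries; when given, the net composition after
#'   balancing must be identical across all states (a deficit is an error).
#' @return a [whole_profile()] (branch tags derived from each state's step).
#' @export
stitch_balanced <- function(states, ledger = NULL, reference_state = "RC",
                            compositions = NULL) {
  df <- as.data.frame(states)
  df$label <- canonical_label(df$label)
  ref <- canonical_label(reference_state)
  if (!ref %in% df$label) {
    stop("reference state ", dQuote(reference_state), " absent", call. = FALSE)
  }
  if (is.null(ledger)) {
    ledger <- data.frame(state = character(0), aux = character(0),
                         energy_au = numeric(0), count = numeric(0))
  }
  ledger$state <- canonical_label(ledger$state)

  aux_sum <- function(lab) {
    rows <- ledger[ledger$state == lab, , drop = FALSE]
    if (nrow(rows) == 0) 0 else sum(rows$energy_au * rows$count)
  }
  balanced <- vapply(df$label, function(l) df$energy_au[df$label == l][1] +
                       aux_sum(l), numeric(1))

  if (!is.null(compositions)) {
    comp_of <- function(lab) {
      base <- parse_formula(compositions[[lab]] %||% NA_character_)
      rows <- ledger[ledger$state == lab, , drop = FALSE]
      if (nrow(rows) > 0) {
        for (i in seq_len(nrow(rows))) {
          base <- .add_comp(base,
                            parse_formula(compositions[[rows$aux[i]]] %||%
                                            NA_character_),
                            mult = as.integer(rows$count[i]))
        }
      }
      base
    }
    ref_comp <- comp_of(ref)
    for (lab in setdiff(df$label, ref)) {
      cc <- comp_of(lab)
      els <- union(names(cc), names(ref_comp))
      a <- stats::setNames(integer(length(els)), els); a[names(cc)] <- cc
      b <- stats::setNames(integer(length(els)), els); b[names(ref_comp)] <- ref_comp
      if (any(a != b)) {
        d <- a - b
        stop("composition imbalance at state ", lab, " after balancing: ",
             paste(sprintf("%s%+d", names(d)[d != 0], d[d != 0]),
                   collapse = " "), call. = FALSE)
      }
    }
  }

  e_ref <- balanced[df$label == ref][1]
  energy <- hartree_to_kcalmol(balanced - e_ref)
  energy[df$label == ref] <- 0

  branch <- vapply(df$step, function(s) {
    if (s %in% c("hydrolysis", "transfructosylation")) s else "common"
  }, character(1))
  ord <- order(match(df$label, CYCLE_SPECIES))
  whole_profile(
    data.frame(label = df$label, branch = branch, energy_kcal = unname(energy),
               stringsAsFactors = FALSE)[ord, ],
    provenance = list(method = unique(.method_string(df))[1],
                      model = unique(df$model)[1],
                      procedure = "balanced-ledger"),
    steps = stats::setNames(df$step, df$label)[ord]
  )
}

# ---- derived quantities ----------------------------------------------------

.branch_rows <- function(profile, branch) {
  if (!branch %in% profile$branch) {
    stop("profile has no branch ", dQuote(branch), call. = FALSE)
  }
  profile[profile$branch == branch, , drop = FALSE]
}

.canonical_branch_ts <- c(hydrolysis = "TS2", transfructosylation = "TS3")

#' Overall activation energy of a branch
#'
#' The branch transition state's energy relative to RC (= 0). This is the
#' reported overall barrier convention: the TS of the deglycosylation step
#' (TS2 for hydrolysis, TS3 for transfructosylation) with respect to RC —
#' not an energetic-span maximum. `mode = "span"` instead returns the
#' energetic span along the branch path (highest TS minus the lowest
#' preceding point).
#'
#' @param profile a [whole_profile()].
#' @param branch `"hydrolysis"` or `"transfructosylation"`.
#' @param mode `"ts"` (default, the reported convention) or `"span"`.
#' @return activation energy, kcal/mol.
#' @export
overall_barrier <- function(profile, branch, mode = c("ts", "span")) {
  mode <- match.arg(mode)
  rows <- .branch_rows(profile, branch)
  if (mode == "ts") {
    ts_lab <- .canonical_branch_ts[[branch]] %||% NA_character_
    hit <- rows[canonical_label(rows$label) == ts_lab, , drop = FALSE]
    if (nrow(hit) == 0) hit <- rows[grepl("^TS", canonical_label(rows$label)), ,
                                    drop = FALSE]
    if (nrow(hit) == 0) {
      stop("branch ", branch, " has no transition state", call. = FALSE)
    }
    return(hit$energy_kcal[nrow(hit)])
  }
  path <- .branch_path(profile, branch)
  ts_idx <- grep("^TS", canonical_label(path$label))
  if (length(ts_idx) == 0) {
    stop("branch ", branch, " has no transition state", call. = FALSE)
  }
  max(vapply(ts_idx, function(i) {
    path$energy_kcal[i] - min(path$energy_kcal[seq_len(i)])
  }, numeric(1)))
}

#' Overall reaction energy of a branch
#'
#' The branch product complex's energy (PC2 or PC3) relative to RC.
#'
#' @param profile a [whole_profile()].
#' @param branch `"hydrolysis"` or `"transfructosylation"`.
#' @return reaction energy, kcal/mol.
#' @export
overall_reaction_energy <- function(profile, branch) {
  rows <- .branch_rows(profile, branch)
  hit <- rows[grepl("^PC", canonical_label(rows$label)), , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("branch ", branch, " has no product complex", call. = FALSE)
  }
  hit$energy_kcal[nrow(hit)]
}

#' Step-level selectivity between transfructosylation and hydrolysis
#'
#' `ddE = dE3 - dE2`: positive values mean transfructosylation is harder
#' than hydrolysis at the step level.
#'
#' @param barrier_hydrolysis hydrolysis step barrier dE2, kcal/mol.
#' @param barrier_transfructosylation transfructosylation step barrier dE3,
#'   kcal/mol.
#' @return ddE, kcal/mol.
#' @export
selectivity_dd <- function(barrier_hydrolysis, barrier_transfructosylation) {
  barrier_transfructosylation - barrier_hydrolysis
}

.branch_path <- function(profile, branch) {
  common <- profile[profile$branch == "common", , drop = FALSE]
  rows <- .branch_rows(profile, branch)
  rbind(common, rows)
}

#' Rate-limiting step along a branch
#'
#' Finds the elementary step whose transition state lies highest relative to
#' RC along the path common segment -> branch. Ties (within `tol`) are
#' reported as ties.
#'
#' @param profile a [whole_profile()].
#' @param branch `"hydrolysis"` or `"transfructosylation"`.
#' @param tol tie tolerance in kcal/mol (default 1e-9).
#' @return list with `step` (step name(s) of the limiting TS), `ts_label`,
#'   `energy_kcal`, and logical `tie`.
#' @export
rate_limiting_step <- function(profile, branch, tol = 1e-9) {
  path <- .branch_path(profile, branch)
  ts <- path[grepl("^TS", canonical_label(path$label)), , drop = FALSE]
  if (nrow(ts) < 2) {
    stop("need >= 2 transition states on the path to determine the ",
         "rate-limiting step", call. = FALSE)
  }
  top <- max(ts$energy_kcal)
  winners <- ts[ts$energy_kcal >= top - tol, , drop = FALSE]
  steps_map <- attr(profile, "steps")
  step_names <- if (!is.null(steps_map)) {
    unname(steps_map[winners$label])
  } else {
    winners$branch
  }
  list(step = step_names, ts_label = winners$label,
       energy_kcal = top, tie = nrow(winners) > 1)
}
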