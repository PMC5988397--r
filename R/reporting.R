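# Functional-comparison tables and stepped energy-profile diagrams.

#' Construct a comparison table
#'
#' A data.frame of kcal/mol quantities whose unrounded values are kept as
#' provenance; rounding (half away from zero, 1 decimal) happens only when
#' the table is rendered by [export_table()].
#'
#' @param df data.frame; first column row labels, remaining columns numeric.
#' @param flagged optional character vector of row labels with incomplete
#'   input (kept in the table with `NA` cells, never dropped silently).
#' @return object of class `comparison_table`.
#' @export
comparison_table <- function(df, flagged = character(0)) {
  stopifnot(is.data.frame(df))
  structure(df,
            provenance = df,    # unrounded cells
            flagged = flagged,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(export_table(x, format = "markdown"), sep = "\n")
  fl <- attr(x, "flagged")
  if (length(fl) > 0) cat("flagged (incomplete): ",
                          paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Functional-comparison report: step barriers and stitched overall values
#'
#' Builds the two standard comparison grids across density functionals:
#' a step-barrier table (dE1, dE2, dE3 and the selectivity ddE = dE3 - dE2)
#' and, when stitched profiles are supplied, an overall table per functional
#' (dG_diss, activation and reaction energies of both branches relative to
#' RC). Functionals with incomplete input are flagged, never dropped.
#'
#' @param barriers data.frame with columns `functional`, `dE1`, `dE2`, `dE3`
#'   (kcal/mol).
#' @param profiles optional named list of [whole_profile()]s, one per
#'   functional (names matching `barriers$functional`).
#' @return list of class `functional_comparison` with elements `steps` and
#'   (when profiles are given) `overall`, both [comparison_table()]s.
#' @export
functional_comparison <- function(barriers, profiles = NULL) {
  stopifnot(is.data.frame(barriers), "functional" %in% names(barriers))
  need <- c("dE1", "dE2", "dE3")
  for (col in setdiff(need, names(barriers))) barriers[[col]] <- NA_real_
  flagged <- barriers$functional[
    !stats::complete.cases(barriers[, need, drop = FALSE])]
  steps <- data.frame(
    functional = barriers$functional,
    dE1 = barriers$dE1, dE2 = barriers$dE2, dE3 = barriers$dE3,
    ddE = selectivity_dd(barriers$dE2, barriers$dE3),
    stringsAsFactors = FALSE
  )
  out <- list(steps = comparison_table(steps, flagged = flagged))

  if (!is.null(profiles)) {
    rows <- lapply(barriers$functional, function(fn) {
      pr <- profiles[[fn]]
      if (is.null(pr)) {
        return(data.frame(functional = fn, dG_diss = NA_real_,
                          act_hydrolysis = NA_real_, rxn_hydrolysis = NA_real_,
                          act_transfructosylation = NA_real_,
                          rxn_transfructosylation = NA_real_))
      }
      jn <- attr(pr, "provenance")$junction
      data.frame(
        functional = fn,
        dG_diss = jn$delta_g_diss %||% NA_real_,
        act_hydrolysis = tryCatch(overall_barrier(pr, "hydrolysis"),
                                  error = function(e) NA_real_),
        rxn_hydrolysis = tryCatch(overall_reaction_energy(pr, "hydrolysis"),
                                  error = function(e) NA_real_),
        act_transfructosylation =
          tryCatch(overall_barrier(pr, "transfructosylation"),
                   error = function(e) NA_real_),
        rxn_transfructosylation =
          tryCatch(overall_reaction_energy(pr, "transfructosylation"),
                   error = function(e) NA_real_)
      )
    })
    overall <- do.call(rbind, rows)
    fl <- overall$functional[!stats::complete.cases(overall)]
    out$overall <- comparison_table(overall, flagged = fl)
  }
  class(out) <- "functional_comparison"
  out
}

#' @export
print.functional_comparison <- function(x, ...) {
  cat("Step barriers and selectivity (kcal/mol):\n")
  print(x$steps)
  if (!is.null(x$overall)) {
    cat("\nOverall activation/reaction energies relative to RC (kcal/mol):\n")
    print(x$overall)
  }
  invisible(x)
}

#' Render a comparison table as CSV/TSV or Markdown
#'
#' Numeric cells are display-rounded (half away from zero, 1 decimal)
#' exactly once at render time; re-parsing a CSV/TSV export reproduces the
#' provenance cells to within that rounding.
#'
#' @param table a [comparison_table()] (or plain data.frame).
#' @param format one of "csv", "tsv", "markdown".
#' @param path optional destination; when `NULL` the text is returned.
#' @param digits display decimals (default 1).
#' @return character vector of lines, invisibly when written to `path`.
#' @export
export_table <- function(table, format = c("csv", "tsv", "markdown"),
                         path = NULL, digits = 1) {
  format <- match.arg(format)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- ifelse(is.na(df[[j]]), NA,
                      formatC(display_round(df[[j]], digits),
                              format = "f", digits = digits))
  }
  lines <- switch(
    format,
    csv = ,
    tsv = {
      sep <- if (format == "csv") "," else "\t"
      c(paste(names(df), collapse = sep),
        if (nrow(df) > 0)
          apply(df, 1, function(r) paste(ifelse(is.na(r), "", r),
                                         collapse = sep)))
    },
    markdown = {
      cells <- rbind(names(df),
                     if (nrow(df) > 0) as.matrix(format(df)) else NULL)
      widths <- apply(nchar(cells), 2, max)
      pad <- function(r) paste0(
        "| ",
        paste(mapply(function(cell, w) formatC(cell, width = w, flag = "-"),
                     r, widths),
              collapse = " | "),
        " |")
      c(pad(names(df)),
        pad(vapply(widths, function(w) strrep("-", w), character(1))),
        if (nrow(df) > 0) apply(df, 1, function(r) pad(ifelse(is.na(r), "", r))))
    })
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

# ---- stepped profile diagram (deterministic SVG) ---------------------------

.palette <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
              "#66a61e", "#e6ab02", "#a6761d", "#666666")

.series_colour <- function(name) {
  b <- utf8ToInt(name)
  .palette[(sum(b * seq_along(b)) %% length(.palette)) + 1L]
}

.fmt <- function(x) formatC(x, format = "f", digits = 4)

#' Render stepped energy-profile diagram(s) to SVG
#'
#' Draws the conventional reaction-profile idiom: a horizontal level bar per
#' stationary point at its energy relative to RC, joined by dashed diagonal
#' connectors; hydrolysis and transfructosylation branches fork from the
#' shared glycosylation segment. Output is deterministic for fixed input
#' (fixed ordering, no timestamps); each level carries `data-label`,
#' `data-branch` and `data-energy` attributes so the drawn heights can be
#' read back programmatically. Series colours are assigned by a hash of the
#' series name.
#'
#' @param profiles a [whole_profile()] or a named list of them (e.g. one per
#'   functional) sharing the species vocabulary.
#' @param path optional destination file; when `NULL` the SVG text is
#'   returned as a character vector of lines.
#' @param width,height canvas size in SVG user units.
#' @return SVG lines (invisibly when written to `path`).
#' @export
render_profile_diagram <- function(profiles, path = NULL,
                                   width = 800, height = 500) {
  if (inherits(profiles, "whole_profile")) {
    nm <- attr(profiles, "provenance")$method %||% "profile"
    profiles <- stats::setNames(list(profiles), nm)
  }
  if (length(profiles) == 0) stop("no profiles to render", call. = FALSE)
  for (p in profiles) {
    if (!inherits(p, "whole_profile") || nrow(p) == 0) {
      stop("cannot render an empty profile", call. = FALSE)
    }
  }

  # shared x layout: common segment first, then each branch in fixed order
  ordered_points <- function(p) {
    branches <- c("common", "hydrolysis", "transfructosylation")
    do.call(rbind, lapply(intersect(branches, unique(p$branch)),
                          function(b) p[p$branch == b, , drop = FALSE]))
  }
  all_pts <- lapply(profiles, ordered_points)
  slots <- unique(do.call(rbind, all_pts)[, c("label", "branch")])
  slot_key <- paste(slots$label, slots$branch)
  n_slot <- nrow(slots)

  energies <- unlist(lapply(all_pts, `[[`, "energy_kcal"))
  rng <- range(c(0, energies))
  pad_y <- 0.08 * diff(rng) + 1
  y_of <- function(e) {
    height - 40 - (e - (rng[1] - pad_y)) /
      ((rng[2] + pad_y) - (rng[1] - pad_y)) * (height - 80)
  }
  lvl_w <- (width - 80) / n_slot * 0.55
  x_of <- function(slot) 40 + (slot - 0.5) * (width - 80) / n_slot

  out <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    sprintf('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#bbbbbb" stroke-width="0.5"/>',
            .fmt(40), .fmt(y_of(0)), .fmt(width - 40), .fmt(y_of(0)))
  )

  for (nm in names(profiles)) {
    col <- .series_colour(nm)
    pts <- all_pts[[nm]]
    idx <- match(paste(pts$label, pts$branch), slot_key)
    cx <- x_of(idx)
    cy <- y_of(pts$energy_kcal)
    # level bars
    out <- c(out, sprintf(
      '<line class="level" data-series="%s" data-label="%s" data-branch="%s" data-energy="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="3"/>',
      nm, pts$label, pts$branch, .fmt(pts$energy_kcal),
      .fmt(cx - lvl_w / 2), .fmt(cy), .fmt(cx + lvl_w / 2), .fmt(cy), col))
    # dashed connectors within common + each branch (branch paths restart
    # from the last common point)
    common_n <- sum(pts$branch == "common")
    seqs <- list()
    if (common_n > 1) seqs <- c(seqs, list(seq_len(common_n)))
    for (b in setdiff(unique(pts$branch), "common")) {
      rows <- which(pts$branch == b)
      pre <- if (common_n > 0) common_n else integer(0)
      seqs <- c(seqs, list(c(pre, rows)))
    }
    for (s in seqs) {
      if (length(s) < 2) next
      for (k in seq_len(length(s) - 1)) {
        i <- s[k]; j <- s[k + 1]
        out <- c(out, sprintf(
          '<line class="connector" data-series="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1" stroke-dasharray="4,3"/>',
          nm, .fmt(cx[i] + lvl_w / 2), .fmt(cy[i]),
          .fmt(cx[j] - lvl_w / 2), .fmt(cy[j]), col))
      }
    }
  }

  # species labels along the x axis (shared layout)
  out <- c(out, sprintf(
    '<text class="species" x="%s" y="%s" font-size="11" text-anchor="middle">%s</text>',
    .fmt(x_of(seq_len(n_slot))), .fmt(height - 12), slots$label))
  # legend, fixed order
  leg_y <- 20 + 16 * (seq_along(profiles) - 1)
  out <- c(out, sprintf(
    '<text class="legend" x="%s" y="%s" font-size="12" fill="%s">%s</text>',
    .fmt(48), .fmt(leg_y),
    vapply(names(profiles), .series_colour, character(1)), names(profiles)))
  out <- c(out, "</svg>")

  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}
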