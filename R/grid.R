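#' Enumerate the definitional parameter grid
#'
#' The full grid crosses event merging (2) x undefined-event mode (4) x
#' undefined constraint (3) x baseline mode (2) x confirmation mode with
#' the relapse-in-confirmation flag (8 modes, the flag only available for
#' the two last-confirmed modes, giving 10 combinations) x RAW window (3):
#' 1440 definitions. Two sub-grids restrict it:
#'
#' * `"harmonized"` fixes event merging (off) and the baseline mode
#'   (roving, next-confirmed), leaving 4 x 3 x 10 x 3 = 360 definitions.
#' * `"standardized"` fixes the confirmation dimension (default 12-week
#'   last-confirmed, relapses in the confirmation interval not allowed),
#'   leaving 2 x 4 x 3 x 2 x 3 = 144 definitions.
#'
#' The fixed values of the sub-grids are reconstructed from the free
#' dimensions named for each proposal and can be overridden via `fix`.
#' Enumeration order is stable: lexicographic over the axes in the order
#' event merging, undefined mode, undefined constraint, baseline mode,
#' (confirmation mode, allow flag), RAW window, with each axis in its
#' documented level order.
#'
#' @param preset `"full"`, `"harmonized"`, or `"standardized"`.
#' @param fix Named list overriding the fixed values of a sub-grid, e.g.
#'   `list(confirmation_mode = "w24_last")` for the standardized preset.
#' @return A list of `accrual_definition` objects, classed
#'   `accrual_definition_grid`.
#' @export
#' @examples
#' length(definition_grid("full"))         # 1440
#' length(definition_grid("harmonized"))   # 360
#' length(definition_grid("standardized")) # 144
definition_grid <- function(preset = c("full", "harmonized", "standardized"),
                            fix = list()) {
  preset <- match.arg(preset)
  windows <- list(c(30L, 30L), c(30L, 90L), c(90L, 90L))
  conf_pairs <- list()
  for (m in .def_axes$confirmation_mode) {
    conf_pairs[[length(conf_pairs) + 1L]] <- list(mode = m, allow = FALSE)
    if (m %in% .last_confirmed_modes) {
      conf_pairs[[length(conf_pairs) + 1L]] <- list(mode = m, allow = TRUE)
    }
  }

  axes <- list(
    event_merging = .def_axes$event_merging,
    undefined_mode = .def_axes$undefined_mode,
    undefined_constraint = .def_axes$undefined_constraint,
    baseline_mode = .def_axes$baseline_mode,
    conf = seq_along(conf_pairs),
    window = seq_along(windows)
  )

  fixed <- switch(preset,
    full = list(),
    harmonized = utils::modifyList(
      list(event_merging = FALSE, baseline_mode = "roving_next_confirmed"),
      fix),
    standardized = utils::modifyList(
      list(confirmation_mode = "w12_last",
           allow_relapse_in_confirmation = FALSE),
      fix)
  )

  if (!is.null(fixed$event_merging)) axes$event_merging <- fixed$event_merging
  if (!is.null(fixed$undefined_mode)) axes$undefined_mode <- fixed$undefined_mode
  if (!is.null(fixed$undefined_constraint)) {
    axes$undefined_constraint <- fixed$undefined_constraint
  }
  if (!is.null(fixed$baseline_mode)) axes$baseline_mode <- fixed$baseline_mode
  if (!is.null(fixed$confirmation_mode)) {
    allow <- isTRUE(fixed$allow_relapse_in_confirmation)
    axes$conf <- which(vapply(conf_pairs, function(p) {
      p$mode == fixed$confirmation_mode && p$allow == allow
    }, logical(1)))
    stopifnot(length(axes$conf) == 1)
  }
  if (!is.null(fixed$raw_window)) {
    axes$window <- which(vapply(windows, function(w) {
      all(w == fixed$raw_window)
    }, logical(1)))
    stopifnot(length(axes$window) == 1)
  }

  # lexicographic enumeration: last listed axis varies fastest
  cells <- expand.grid(
    window = axes$window, conf = axes$conf,
    baseline_mode = axes$baseline_mode,
    undefined_constraint = axes$undefined_constraint,
    undefined_mode = axes$undefined_mode,
    event_merging = axes$event_merging,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  # reorder columns so that rows come out with event_merging slowest
  cells <- cells[, rev(names(cells))]

  grid <- lapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    cp <- conf_pairs[[row$conf]]
    accrual_definition(
      event_merging = row$event_merging,
      undefined_mode = row$undefined_mode,
      undefined_constraint = row$undefined_constraint,
      baseline_mode = row$baseline_mode,
      confirmation_mode = cp$mode,
      raw_window = windows[[row$window]],
      allow_relapse_in_confirmation = cp$allow
    )
  })
  structure(grid, class = "accrual_definition_grid", preset = preset)
}

#' @export
print.accrual_definition_grid <- function(x, ...) {
  cat(sprintf("Definition grid: %d definitions (preset \"%s\")\n",
              length(x), attr(x, "preset")))
  invisible(x)
}

#' Tabulate a definition grid
#'
#' One row per definition, one column per configurable axis; the RAW
#' window is encoded as `"pre/post"`. Useful as the config key of grid
#' result tables.
#'
#' @param grid A list of `accrual_definition` objects.
#' @return A data.frame with `config_id` and one column per axis.
#' @export
grid_to_df <- function(grid) {
  rows <- lapply(grid, function(d) {
    data.frame(
      event_merging = d$event_merging,
      undefined_mode = d$undefined_mode,
      undefined_constraint = d$undefined_constraint,
      baseline_mode = d$baseline_mode,
      confirmation_mode = d$confirmation_mode,
      allow_relapse_in_confirmation = d$allow_relapse_in_confirmation,
      raw_window = paste(d$raw_window, collapse = "/"),
      confirmation_score_handling = d$confirmation_score_handling,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(config_id = seq_len(nrow(out))), out)
}
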