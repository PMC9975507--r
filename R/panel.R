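#' The canonical eight-marker aging panel
#'
#' The panel covers three primary aging hallmarks (upstream causes of
#' cellular damage) and five antagonistic hallmarks (cellular responses to
#' that damage).  Two markers are composites of two measurement channels:
#' SASP (IL-6, IL-8 secretion) and cell-cycle arrest (p21, p16 expression);
#' a composite marker is called positive when any of its components is.
#' Each component has an expected aging direction; a significant change in
#' the opposite direction does not count towards the score.
#'
#' @param component_level logical; if `TRUE`, the two composite markers are
#'   expanded so every measurement channel is its own panel item (10 items,
#'   maximum full score 10).  Default `FALSE`: the canonical 8-marker panel
#'   with maximum full score 8.
#' @return A data frame with one row per measurement channel and columns
#'   `marker`, `category` (`"primary"` or `"antagonistic"`), `component`
#'   (measurement channel name) and `direction` (`"increase"` or
#'   `"decrease"`, the change expected with aging).
#' @examples
#' marker_panel()
#' @export
marker_panel <- function(component_level = FALSE) {
  panel <- data.frame(
    marker = c(
      "DNA_damage", "Telomere_attrition", "Histone_modification",
      "SA_bGal", "SASP", "SASP", "Cell_cycle_arrest", "Cell_cycle_arrest",
      "Morphology", "LMNB1"
    ),
    category = c(rep("primary", 3), rep("antagonistic", 7)),
    component = c(
      "gH2AX_foci", "telomere_TS", "H3K9Me3_CTCF",
      "SA_bGal_fraction", "IL6", "IL8", "p21", "p16",
      "nucleus_area", "LMNB1_CTCF"
    ),
    direction = c(
      "increase", "decrease", "decrease",
      "increase", "increase", "increase", "increase", "increase",
      "increase", "decrease"
    ),
    stringsAsFactors = FALSE
  )
  if (component_level) {
    panel$marker <- ifelse(panel$marker %in% c("SASP", "Cell_cycle_arrest"),
                           paste(panel$marker, panel$component, sep = "_"),
                           panel$marker)
  }
  panel
}

#' Panel marker names in canonical order
#'
#' Order used for pattern rows and score tables: the three primary markers
#' first, then the five antagonistic markers.
#'
#' @param panel a panel definition from [marker_panel()].
#' @return character vector of marker names.
#' @export
panel_markers <- function(panel = marker_panel()) {
  unique(panel$marker)
}

#' @rdname panel_markers
#' @export
primary_markers <- function(panel = marker_panel()) {
  unique(panel$marker[panel$category == "primary"])
}

#' @rdname panel_markers
#' @export
antagonistic_markers <- function(panel = marker_panel()) {
  unique(panel$marker[panel$category == "antagonistic"])
}

# The six condition columns of the frequency table, in reporting order.
# HGPS and WS metadata labels both map onto the "progeria" column.
panel_conditions <- function() {
  c("young", "midage", "old", "replicative", "artificial", "progeria")
}

normalize_condition <- function(condition) {
  cond <- ifelse(condition %in% c("HGPS", "WS"), "progeria", condition)
  bad <- setdiff(unique(cond), panel_conditions())
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cond
}
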