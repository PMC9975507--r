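#' Score one marker pattern
#'
#' Sums the binary marker indicators into the primary AgeScore (0-3),
#' the antagonistic AgeScore (0-5) and their sum, the full AgeScore (0-8).
#'
#' @param indicators named 0/1 vector over the panel markers, or an
#'   unnamed 8-vector in canonical panel order.
#' @param panel panel definition from [marker_panel()].
#' @return list with `primary`, `antagonistic`, `full` (integers).
#' @examples
#' score_line(c(1, 1, 0, 1, 1, 0, 0, 0))
#' @export
score_line <- function(indicators, panel = marker_panel()) {
  markers <- panel_markers(panel)
  if (is.null(names(indicators))) {
    if (length(indicators) != length(markers)) {
      stop("expected ", length(markers), " indicators", call. = FALSE)
    }
    names(indicators) <- markers
  }
  if (!all(markers %in% names(indicators))) {
    stop("missing indicator(s): ",
         paste(setdiff(markers, names(indicators)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(indicators[markers] %in% c(0L, 1L))) {
    stop("indicators must be 0/1", call. = FALSE)
  }
  pri <- sum(indicators[primary_markers(panel)])
  ant <- sum(indicators[antagonistic_markers(panel)])
  list(primary = as.integer(pri), antagonistic = as.integer(ant),
       full = as.integer(pri + ant))
}

#' Score every line of a call matrix
#'
#' @param calls a [build_call_matrix()] result, or any data frame with
#'   `line_id`, `condition`, `donor_age` and one 0/1 column per marker.
#' @param panel panel definition.
#' @return data frame `line_id`, `condition`, `donor_age`, `primary`,
#'   `antagonistic`, `full`, `n_markers_assessed`.
#' @export
score_lines <- function(calls, panel = marker_panel()) {
  markers <- panel_markers(panel)
  stopifnot(all(markers %in% names(calls)))
  sc <- t(apply(as.matrix(calls[, markers]), 1L, function(r) {
    s <- score_line(stats::setNames(as.integer(r), markers), panel)
    c(s$primary, s$antagonistic, s$full)
  }))
  out <- data.frame(
    line_id = calls$line_id,
    condition = calls$condition,
    donor_age = calls$donor_age,
    primary = as.integer(sc[, 1]),
    antagonistic = as.integer(sc[, 2]),
    full = as.integer(sc[, 3]),
    stringsAsFactors = FALSE
  )
  out$n_markers_assessed <- if ("n_markers_assessed" %in% names(calls)) {
    calls$n_markers_assessed
  } else length(markers)
  out
}

#' Marker frequency table by condition
#'
#' For each of the eight markers and each condition column (young, midage,
#' old, replicative, artificial, progeria) counts positively called lines
#' and lines tested, plus row totals.  HGPS and WS metadata labels fall
#' into the progeria column.
#'
#' @param calls a call matrix (see [score_lines()] for the accepted shape).
#' @param panel panel definition.
#' @return object of class `"frequency_table"`: data frame with columns
#'   `marker`, `category`, then `<condition>_pos` / `<condition>_n` pairs,
#'   and `total_pos` / `total_n`.
#' @export
frequency_table <- function(calls, panel = marker_panel()) {
  markers <- panel_markers(panel)
  stopifnot(all(markers %in% names(calls)))
  if (any(is.na(calls$condition))) {
    stop("unlabelled row(s): every line needs a condition", call. = FALSE)
  }
  cond <- normalize_condition(calls$condition)
  conds <- intersect(panel_conditions(), unique(cond))
  out <- data.frame(
    marker = markers,
    category = vapply(markers, function(m) {
      panel$category[panel$marker == m][1]
    }, character(1)),
    stringsAsFactors = FALSE
  )
  for (cc in conds) {
    sel <- cond == cc
    out[[paste0(cc, "_pos")]] <-
      vapply(markers, function(m) sum(calls[[m]][sel] == 1L), integer(1))
    out[[paste0(cc, "_n")]] <- sum(sel)
  }
  out$total_pos <- rowSums(out[, paste0(conds, "_pos"), drop = FALSE])
  out$total_n <- nrow(calls)
  rownames(out) <- NULL
  structure(out, conditions = conds,
            class = c("frequency_table", "data.frame"))
}

#' @export
print.frequency_table <- function(x, ...) {
  conds <- attr(x, "conditions")
  disp <- data.frame(marker = x$marker, category = x$category,
                     stringsAsFactors = FALSE)
  for (cc in conds) {
    disp[[cc]] <- sprintf("%d (%d)", x[[paste0(cc, "_pos")]],
                          x[[paste0(cc, "_n")]])
  }
  disp$total <- sprintf("%d (%d)", x$total_pos, x$total_n)
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

#' Correlation between full AgeScore and donor age
#'
#' Sample Pearson correlation with its two-sided test p-value.
#'
#' @param full full AgeScores.
#' @param donor_age donor ages in years.
#' @return list with `pearson_r`, `n`, `p_value`.
#' @export
correlate_score_age <- function(full, donor_age) {
  keep <- is.finite(full) & is.finite(donor_age)
  full <- full[keep]; donor_age <- donor_age[keep]
  if (length(full) < 3L) stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(full) == 0 || stats::var(donor_age) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(full, donor_age, method = "pearson")
  list(pearson_r = unname(ct$estimate), n = length(full),
       p_value = ct$p.value)
}

#' Hamming distance between two marker patterns
#'
#' Quantifies how different two lines' marker patterns are (0 = identical,
#' 8 = complementary on the full panel).
#'
#' @param a,b 0/1 indicator vectors of equal length (panel order).
#' @return integer count of differing indicators.
#' @export
pattern_distance <- function(a, b) {
  if (length(a) != length(b)) stop("pattern lengths differ", call. = FALSE)
  if (!all(c(a, b) %in% c(0L, 1L))) stop("patterns must be 0/1", call. = FALSE)
  sum(a != b)
}

#' Write the full score report
#'
#' Emits `scores.tsv`, `frequency.tsv`, `patterns.tsv` and
#' `correlation.json` (score-age Pearson correlation over the donor-age
#' lines) into a directory, with rows ordered by condition then line id so
#' repeated runs are byte-identical.
#'
#' @param calls call matrix.
#' @param meta metadata with `line_id`, `condition`, `donor_age`; ids must
#'   cover the call matrix.
#' @param out_dir output directory (created if needed).
#' @param panel panel definition.
#' @return (invisibly) list with `scores`, `frequency`, `correlation` and
#'   the file paths.
#' @export
score_report <- function(calls, meta, out_dir, panel = marker_panel()) {
  if (nrow(calls) == 0L) stop("empty call matrix", call. = FALSE)
  if (!all(calls$line_id %in% meta$line_id)) {
    stop("call matrix lines missing from metadata: ",
         paste(setdiff(calls$line_id, meta$line_id), collapse = ", "),
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  markers <- panel_markers(panel)
  ord <- order(match(normalize_condition(calls$condition), panel_conditions()),
               calls$line_id)
  calls <- calls[ord, ]
  scores <- score_lines(calls, panel)
  freq <- frequency_table(calls, panel)
  donor <- scores$condition %in% c("young", "midage", "old")
  corr <- correlate_score_age(scores$full[donor], scores$donor_age[donor])
  paths <- list(
    scores = file.path(out_dir, "scores.tsv"),
    frequency = file.path(out_dir, "frequency.tsv"),
    patterns = file.path(out_dir, "patterns.tsv"),
    correlation = file.path(out_dir, "correlation.json")
  )
  write_tsv(scores, paths$scores)
  write_tsv(as.data.frame(freq), paths$frequency)
  write_tsv(calls[, c("line_id", "condition", markers)], paths$patterns)
  jsonlite::write_json(
    list(pearson_r = round(corr$pearson_r, 4), n = corr$n,
         p_value = signif(corr$p_value, 4)),
    paths$correlation, auto_unbox = TRUE, digits = NA
  )
  invisible(list(scores = scores, frequency = freq, correlation = corr,
                 paths = paths))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
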