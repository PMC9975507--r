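#' Population doubling level
#'
#' PDL after one passage interval:
#' `3.2 * (log10(harvested) - log10(seeded)) + passage`.  With base-10
#' logarithms a 2-fold expansion adds `3.2 * log10(2)`, about 0.96
#' doublings, i.e. the 3.2 factor makes log10 behave (approximately) like
#' log2 doubling counting.
#'
#' @param harvested number of cells harvested at the end of the interval.
#' @param seeded number of cells seeded at the start.
#' @param passage actual passage number at harvest.
#' @return numeric population doubling level (vectorized).
#' @examples
#' compute_pdl(4e5, 2e5, passage = 5)
#' @export
compute_pdl <- function(harvested, seeded, passage) {
  if (any(!is.finite(harvested)) || any(!is.finite(seeded)) ||
      any(harvested <= 0) || any(seeded <= 0)) {
    stop("harvested and seeded cell counts must be positive", call. = FALSE)
  }
  if (any(passage < 0)) stop("passage must be >= 0", call. = FALSE)
  3.2 * (log10(harvested) - log10(seeded)) + passage
}

#' Corrected total cell fluorescence (CTCF)
#'
#' `integrated_density - area * background_mean`, the standard background
#' correction for per-region immunofluorescence quantification.  Negative
#' values (region dimmer than the sampled background) are returned as-is
#' with a warning; clipping them at zero would bias group means upward.
#'
#' @param integrated_density sum of pixel intensities over the region.
#' @param area region area in pixels.
#' @param background_mean mean background grey value per pixel.
#' @return numeric CTCF (vectorized).
#' @examples
#' compute_ctcf(1000, 50, 10)
#' @export
compute_ctcf <- function(integrated_density, area, background_mean) {
  if (any(area <= 0)) stop("area must be positive", call. = FALSE)
  if (any(integrated_density < 0) || any(background_mean < 0)) {
    stop("integrated_density and background_mean must be >= 0", call. = FALSE)
  }
  ctcf <- integrated_density - area * background_mean
  if (any(ctcf < 0)) {
    warning("negative CTCF value(s): region dimmer than background",
            call. = FALSE)
  }
  ctcf
}

#' Count fluorescence foci in a nucleus patch
#'
#' Counts 8-connected components of pixels whose intensity lies inside a
#' band (inclusive on both ends) and that fall inside the nucleus mask,
#' keeping only components of at least `min_size` pixels.  Defaults match
#' the usual Fiji particle-analysis settings for gamma-H2A.X foci
#' (threshold 20-200, size 5).
#'
#' @param intensities numeric matrix of non-negative pixel intensities.
#' @param mask binary matrix of the same shape (1 = inside nucleus); `NULL`
#'   means the whole patch.
#' @param band numeric length-2, inclusive intensity band `c(low, high)`.
#' @param min_size minimum component area in pixels.
#' @return integer number of foci.
#' @examples
#' img <- matrix(0, 8, 8); img[2:4, 2:4] <- 100
#' count_foci(img)
#' @export
count_foci <- function(intensities, mask = NULL, band = c(20, 200),
                       min_size = 5) {
  if (!is.matrix(intensities)) stop("intensities must be a matrix", call. = FALSE)
  if (is.null(mask)) mask <- matrix(1L, nrow(intensities), ncol(intensities))
  if (!identical(dim(intensities), dim(mask))) {
    stop("intensities and mask shapes differ", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary", call. = FALSE)
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("band must be c(low, high) with low < high", call. = FALSE)
  }
  if (min_size < 1) stop("min_size must be >= 1", call. = FALSE)
  fg <- mask == 1 & intensities >= band[1] & intensities <= band[2]
  sizes <- label_sizes_8(fg)
  sum(sizes >= min_size)
}

# Two-pass union-find connected-component labelling, 8-neighbour
# connectivity; returns component sizes.
label_sizes_8 <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!fg[i, j]) next
      # already-labelled neighbours: above, and the three in column j-1
      nb <- integer(0)
      if (i > 1L && labels[i - 1L, j] > 0L) nb <- c(nb, labels[i - 1L, j])
      if (j > 1L) {
        for (di in -1L:1L) {
          ii <- i + di
          if (ii >= 1L && ii <= nr && labels[ii, j - 1L] > 0L) {
            nb <- c(nb, labels[ii, j - 1L])
          }
        }
      }
      if (length(nb) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        keep <- min(roots)
        labels[i, j] <- keep
        for (r in roots) parent[r] <- keep
      }
    }
  }
  if (nxt == 0L) return(integer(0))
  roots <- vapply(seq_len(nxt), find, integer(1))
  lab <- labels[labels > 0L]
  tabulate(match(roots[lab], unique(roots[lab])))
}

#' Nucleus area from a binary mask
#'
#' @param mask binary matrix (1 = nucleus).
#' @return integer area in pixels.
#' @export
measure_nucleus_area <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    stop("mask must be a binary matrix", call. = FALSE)
  }
  area <- sum(mask == 1)
  if (area == 0L) stop("empty mask", call. = FALSE)
  area
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Technical qPCR duplicates are averaged on the Cq scale, then
#' `dCt = mean(target) - mean(reference)` and the fold change is
#' `2^-(dCt - calibrator_dct)`.  With the calibrator taken as the pooled
#' control group's mean dCt, a control-like sample has fold change 1.
#'
#' @param target_cqs Cq values of the gene of interest (>= 1, typically 2).
#' @param reference_cqs Cq values of the reference gene (e.g. GAPDH).
#' @param calibrator_dct dCt of the calibrator sample/group, in cycles.
#' @return fold change (positive number).
#' @examples
#' relative_expression(c(25.0, 25.2), c(20.0, 20.0), calibrator_dct = 4.1)
#' @export
relative_expression <- function(target_cqs, reference_cqs,
                                calibrator_dct = 0) {
  if (length(target_cqs) == 0L || length(reference_cqs) == 0L) {
    stop("Cq vectors must be non-empty", call. = FALSE)
  }
  if (any(target_cqs <= 0) || any(reference_cqs <= 0)) {
    stop("Cq values must be positive", call. = FALSE)
  }
  dct <- mean(target_cqs) - mean(reference_cqs)
  2^-(dct - calibrator_dct)
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `cq = slope * log10(concentration) + intercept`.
#' Amplification efficiency is `10^(-1/slope) - 1`; a perfect assay has
#' slope `-1/log10(2)`, about -3.3219, i.e. efficiency 1.
#'
#' @param concentration standard concentrations (ng/uL), at least two
#'   distinct values.
#' @param cq measured Cq per standard.
#' @return object of class `"standard_curve"`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`.
#' @seealso [invert_standard_curve()]
#' @export
fit_standard_curve <- function(concentration, cq) {
  if (length(concentration) != length(cq)) {
    stop("concentration and cq lengths differ", call. = FALSE)
  }
  if (any(concentration <= 0)) stop("concentrations must be positive", call. = FALSE)
  lc <- log10(concentration)
  if (length(unique(lc)) < 2L) {
    stop("need >= 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(cq ~ lc)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    warning("non-negative standard-curve slope: not a valid amplification curve",
            call. = FALSE)
  }
  structure(
    list(
      slope = slope,
      intercept = unname(stats::coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      efficiency = 10^(-1 / slope) - 1
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: Cq = %.4f * log10(conc) + %.4f  (R2 %.4f, efficiency %.1f%%)\n",
    x$slope, x$intercept, x$r_squared, 100 * x$efficiency
  ))
  invisible(x)
}

#' Invert a standard curve: Cq to quantity
#'
#' @param curve a [fit_standard_curve()] object.
#' @param cq Cq value(s).
#' @return estimated quantity on the standard's concentration scale.
#' @export
invert_standard_curve <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Telomere-to-single-copy-gene ratio (T/S, MM-qPCR)
#'
#' For each of (typically three) plates, telomere and single-copy-gene
#' quantities are obtained by inverting that plate's standard curves and
#' their ratio taken; the reported T/S ratio is the mean over plates, in
#' arbitrary units.  The coefficient of variation over plates is the
#' intra-assay QC statistic: `qc_pass` is `TRUE` when CV < 0.3.
#'
#' @param cq data frame with columns `plate_id`, `target` (`"telomere"` or
#'   `"single_copy"`) and `cq`, one row per target per plate for one sample.
#' @param curves named list, one entry per plate id, each a list with
#'   elements `telomere` and `single_copy` holding [fit_standard_curve()]
#'   objects for that plate.
#' @param cv_limit QC threshold on the CV (default 0.3).
#' @return object of class `"telomere_result"`: list with `tlr` (mean T/S
#'   ratio), `per_plate_ratios`, `cv` and `qc_pass`.
#' @export
telomere_ts_ratio <- function(cq, curves, cv_limit = 0.3) {
  need <- c("plate_id", "target", "cq")
  if (!all(need %in% names(cq))) {
    stop("cq table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  plates <- unique(as.character(cq$plate_id))
  ratios <- vapply(plates, function(p) {
    rows <- cq[cq$plate_id == p, ]
    tcq <- rows$cq[rows$target == "telomere"]
    scq <- rows$cq[rows$target == "single_copy"]
    if (length(tcq) != 1L || length(scq) != 1L) {
      stop("plate ", p, ": need exactly one telomere and one single_copy Cq",
           call. = FALSE)
    }
    pc <- curves[[p]]
    if (is.null(pc) || is.null(pc$telomere) || is.null(pc$single_copy)) {
      stop("missing standard curve(s) for plate ", p, call. = FALSE)
    }
    qt <- invert_standard_curve(pc$telomere, tcq)
    qs <- invert_standard_curve(pc$single_copy, scq)
    if (qs <= 0) stop("single-copy quantity is zero on plate ", p, call. = FALSE)
    qt / qs
  }, numeric(1))
  tlr <- mean(ratios)
  cv <- if (length(ratios) > 1L) stats::sd(ratios) / tlr else 0
  structure(
    list(tlr = tlr, per_plate_ratios = unname(ratios), cv = cv,
         qc_pass = cv < cv_limit),
    class = "telomere_result"
  )
}

#' @export
print.telomere_result <- function(x, ...) {
  cat(sprintf("T/S ratio %.4f over %d plate(s), CV %.3f (%s)\n",
              x$tlr, length(x$per_plate_ratios), x$cv,
              if (x$qc_pass) "QC pass" else "QC FAIL"))
  invisible(x)
}

#' Fraction of SA-beta-galactosidase positive cells
#'
#' @param positive number of cells with cytoplasmic staining.
#' @param total total number of cells scored.
#' @return fraction in \[0, 1\] (vectorized).
#' @export
sabgal_fraction <- function(positive, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(positive < 0) || any(positive > total)) {
    stop("positive must lie in [0, total]", call. = FALSE)
  }
  positive / total
}
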