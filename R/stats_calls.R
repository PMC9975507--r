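#' One-way fixed-effects ANOVA over replicate groups
#'
#' Classical equal-variance one-way ANOVA.  Degenerate input (all values
#' identical, so no variance to test against) returns `NA` statistics with
#' a warning rather than an error: downstream calling treats it as
#' "no call".
#'
#' @param groups list of numeric vectors, one per group, each of length
#'   >= 2.
#' @return list with `f`, `p`, `df1`, `df2`.
#' @examples
#' one_way_anova(list(rnorm(4), rnorm(4, 2), rnorm(4, 4)))
#' @export
one_way_anova <- function(groups) {
  check_groups(groups, min_groups = 2L)
  values <- unlist(groups, use.names = FALSE)
  if (stats::var(values) == 0) {
    warning("degenerate variance: all values identical; no ANOVA call",
            call. = FALSE)
    return(list(f = NA_real_, p = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_))
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(f = unname(ht$statistic), p = unname(ht$p.value),
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}

check_groups <- function(groups, min_groups = 1L) {
  if (!is.list(groups) || length(groups) < min_groups) {
    stop("need a list of >= ", min_groups, " groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2L)) {
    stop("every group needs >= 2 replicate values", call. = FALSE)
  }
  if (!all(vapply(groups, is.numeric, logical(1)))) {
    stop("groups must be numeric vectors", call. = FALSE)
  }
  invisible(TRUE)
}

#' Dunnett's many-to-one comparison against a single reference
#'
#' Compares each test group to one reference group with family-wise error
#' control.  The pooled variance uses all groups (reference + tests); the
#' two-sided adjusted p-value for contrast i is
#' `1 - P(max_j |T_j| <= |t_i|)` under the multivariate t distribution with
#' the Dunnett product correlation `rho_ij = lambda_i * lambda_j`,
#' `lambda_i = sqrt(n_i / (n_i + n0))` (exact also for unbalanced group
#' sizes).  The probability is evaluated by deterministic two-dimensional
#' quadrature (conditioning on the shared control-mean variate and the
#' pooled-SD variate, see [dunnett_prob()]), with absolute accuracy well
#' below 1e-6, so call matrices are bit-reproducible.
#'
#' @param test_groups list of numeric vectors, one per test group.
#' @param reference numeric vector, the (pooled) control group.
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame with one row per test group: `estimate` (test mean
#'   minus reference mean), `t`, `df`, `p_adj`, `significant`.
#' @examples
#' set.seed(1)
#' dunnett_many_to_one(list(rnorm(6, 2), rnorm(6)), rnorm(12))
#' @export
dunnett_many_to_one <- function(test_groups, reference, alpha = 0.05) {
  check_groups(test_groups, min_groups = 1L)
  check_groups(list(reference), min_groups = 1L)
  k <- length(test_groups)
  n0 <- length(reference)
  ni <- lengths(test_groups)
  df <- n0 + sum(ni) - (k + 1L)
  means <- vapply(test_groups, mean, numeric(1))
  m0 <- mean(reference)
  ss <- sum(vapply(test_groups, function(g) sum((g - mean(g))^2), numeric(1))) +
    sum((reference - m0)^2)
  s2 <- ss / df
  est <- means - m0
  if (s2 == 0) {
    warning("degenerate variance in Dunnett comparison; no call", call. = FALSE)
    return(data.frame(estimate = est, t = NA_real_, df = df,
                      p_adj = NA_real_, significant = FALSE))
  }
  tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))
  lambda <- sqrt(ni / (ni + n0))
  p_adj <- vapply(abs(tstat), function(tt) {
    1 - dunnett_prob(tt, lambda, df)
  }, numeric(1))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  data.frame(estimate = est, t = tstat, df = df, p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Two-sided Dunnett acceptance probability
#'
#' `P(max_i |T_i| <= crit)` for the many-to-one comparison statistics
#' `T_i`, whose joint distribution is multivariate t with the product
#' correlation `rho_ij = lambda_i * lambda_j` induced by the shared
#' control group.  Uses the classical factorisation
#' `T_i = (lambda_i * Z0 + sqrt(1 - lambda_i^2) * U_i) / W` with `Z0, U_i`
#' standard normal and `nu * W^2 ~ chi^2(nu)`: conditioning on `Z0` and
#' `W` makes the `T_i` independent, leaving a deterministic
#' two-dimensional quadrature (absolute accuracy well below 1e-6, no
#' Monte-Carlo).  With a single contrast this reduces to the central t
#' distribution, which is used directly.
#'
#' @param crit non-negative critical value.
#' @param lambda vector `sqrt(n_i / (n_i + n0))`, one entry per contrast.
#' @param df residual degrees of freedom of the pooled variance;
#'   `Inf` gives the multivariate normal limit.
#' @return the acceptance probability, a number in \[0, 1\].
#' @export
dunnett_prob <- function(crit, lambda, df) {
  stopifnot(crit >= 0, all(lambda > 0), all(lambda < 1), df > 0)
  if (crit == 0) return(0)
  k <- length(lambda)
  if (k == 1L) {
    if (is.infinite(df)) return(2 * stats::pnorm(crit) - 1)
    return(2 * stats::pt(crit, df) - 1)
  }
  s <- sqrt(1 - lambda^2)
  nz <- 64L
  nw <- 48L
  zg <- gl_nodes(nz, -8.5, 8.5)
  logphi <- stats::dnorm(zg$x, log = TRUE)
  if (is.infinite(df)) {
    wx <- 1; wwt <- 1; fw <- 1; nw <- 1L
  } else {
    wlo <- sqrt(stats::qchisq(1e-13, df) / df)
    whi <- sqrt(stats::qchisq(1 - 1e-13, df) / df)
    wg <- gl_nodes(nw, wlo, whi)
    wx <- wg$x; wwt <- wg$w
    fw <- 2 * wx * df * stats::dchisq(wx^2 * df, df)   # density of W
  }
  # arrays k x nz x nw: conditional on (Z0 = z, W = w) the T_i are
  # independent, P(|T_i| <= crit | z, w) = Phi(up) - Phi(lo)
  lz <- array(outer(lambda / s, zg$x), dim = c(k, nz, nw))
  cw <- aperm(array(outer(crit / s, wx), dim = c(k, nw, nz)), c(1L, 3L, 2L))
  pr <- stats::pnorm(cw - lz) - stats::pnorm(-cw - lz)
  lp <- colSums(log(pmax(pr, 1e-300)))               # nz x nw
  innerw <- colSums(exp(lp + logphi) * zg$w)         # length nw
  p <- sum(wwt * fw * innerw)
  min(max(p, 0), 1)
}

# cached Gauss-Legendre nodes on [a, b]
gl_env <- new.env(parent = emptyenv())
gl_nodes <- function(n, a, b) {
  key <- paste(n, a, b, sep = "|")
  got <- gl_env[[key]]
  if (is.null(got)) {
    got <- pracma::gaussLegendre(n, a, b)
    gl_env[[key]] <- got
  }
  got
}

#' Call one marker component for every test line in a comparison
#'
#' Runs the full Dunnett many-to-one family for one measurement channel
#' (all test lines vs the pooled reference), then applies the
#' aging-direction gate: a line is called positive only when its adjusted
#' p-value is below `alpha` *and* its mean shift from the reference has the
#' expected sign.
#'
#' @param test_groups named list of numeric vectors (names = line ids).
#' @param reference numeric vector, pooled control replicate values.
#' @param direction `"increase"` or `"decrease"`, the expected aging
#'   direction.
#' @param alpha significance level.
#' @return data frame: `line_id`, `estimate`, `p_adj`, `direction_ok`,
#'   `indicator`.
#' @export
call_component <- function(test_groups, reference, direction,
                           alpha = 0.05) {
  direction <- match.arg(direction, c("increase", "decrease"))
  dn <- dunnett_many_to_one(test_groups, reference, alpha = alpha)
  dir_ok <- if (direction == "increase") dn$estimate > 0 else dn$estimate < 0
  data.frame(
    line_id = if (is.null(names(test_groups))) {
      as.character(seq_along(test_groups))
    } else names(test_groups),
    estimate = dn$estimate,
    p_adj = dn$p_adj,
    direction_ok = dir_ok,
    indicator = as.integer(dn$significant & dir_ok),
    stringsAsFactors = FALSE
  )
}

#' Aggregate component calls into a marker call
#'
#' A composite marker (SASP, cell-cycle arrest) is positive when any of
#' its components is positive.
#'
#' @param component_calls integer 0/1 vector of component indicators.
#' @return 0 or 1.
#' @export
aggregate_components <- function(component_calls) {
  if (length(component_calls) == 0L) stop("no components", call. = FALSE)
  as.integer(any(component_calls == 1L))
}

#' Build the lines x markers binary call matrix
#'
#' For every comparison design and every panel component, runs the Dunnett
#' many-to-one family of all test lines against the pooled reference
#' replicate values, gates on the aging direction, and aggregates
#' components into the eight marker indicators.  Lines with no
#' measurements for a marker get indicator 0 and a missing-data flag.
#'
#' @param measurements data frame with columns `line_id`, `condition`,
#'   `component`, `replicate_id`, `value` (a `marker` column is ignored;
#'   the panel defines the component-to-marker map).
#' @param meta cell-line metadata: `line_id`, `condition`, `donor_age`.
#' @param designs list of comparison designs, each a list with
#'   `condition_label`, `reference_lines`, `test_lines`; see
#'   [default_designs()].
#' @param panel panel definition from [marker_panel()].
#' @param alpha significance level per Dunnett family (default 0.05).
#' @return object of class `"call_matrix"`: data frame with `line_id`,
#'   `condition`, `donor_age`, one 0/1 column per marker, and
#'   `n_markers_assessed`.  Attribute `provenance` holds the per-component
#'   adjusted p-values, estimates and flags.
#' @export
build_call_matrix <- function(measurements, meta, designs = NULL,
                              panel = marker_panel(), alpha = 0.05) {
  stopifnot(is.data.frame(measurements), is.data.frame(meta))
  orphans <- setdiff(unique(measurements$line_id), meta$line_id)
  if (length(orphans) > 0L) {
    stop("line(s) with measurements but no metadata: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (is.null(designs)) designs <- default_designs(meta)
  if (length(designs) == 0L) {
    stop("no comparison design: metadata defines no reference group",
         call. = FALSE)
  }
  markers <- panel_markers(panel)
  rows <- list()
  prov <- list()
  for (design in designs) {
    ref_lines <- design$reference_lines
    test_lines <- design$test_lines
    if (length(ref_lines) == 0L) {
      stop("design '", design$condition_label, "' has an empty reference group",
           call. = FALSE)
    }
    # reference lines may also appear among the test lines: control lines
    # are scored against their own pooled mean, as in the study design
    comp_calls <- list()
    for (ci in seq_len(nrow(panel))) {
      comp <- panel$component[ci]
      mm <- measurements[measurements$component == comp, ]
      ref_vals <- mm$value[mm$line_id %in% ref_lines]
      grp <- lapply(test_lines, function(l) mm$value[mm$line_id == l])
      names(grp) <- test_lines
      have <- lengths(grp) >= 2L
      if (length(ref_vals) < 2L || !any(have)) {
        comp_calls[[comp]] <- data.frame(
          line_id = test_lines, estimate = NA_real_, p_adj = NA_real_,
          direction_ok = NA, indicator = 0L, missing = TRUE,
          stringsAsFactors = FALSE
        )
        next
      }
      cc <- suppressWarnings(
        call_component(grp[have], ref_vals, panel$direction[ci], alpha)
      )
      cc$indicator[is.na(cc$p_adj)] <- 0L
      out <- data.frame(line_id = test_lines, estimate = NA_real_,
                        p_adj = NA_real_, direction_ok = NA, indicator = 0L,
                        missing = !have, stringsAsFactors = FALSE)
      idx <- match(cc$line_id, out$line_id)
      out$estimate[idx] <- cc$estimate
      out$p_adj[idx] <- cc$p_adj
      out$direction_ok[idx] <- cc$direction_ok
      out$indicator[idx] <- cc$indicator
      comp_calls[[comp]] <- out
      prov[[length(prov) + 1L]] <- cbind(
        condition_label = design$condition_label, component = comp,
        marker = panel$marker[ci], out
      )
    }
    for (l in test_lines) {
      ind <- vapply(markers, function(m) {
        comps <- panel$component[panel$marker == m]
        calls <- vapply(comps, function(cp) {
          d <- comp_calls[[cp]]
          d$indicator[d$line_id == l]
        }, integer(1))
        aggregate_components(calls)
      }, integer(1))
      assessed <- vapply(markers, function(m) {
        comps <- panel$component[panel$marker == m]
        any(vapply(comps, function(cp) {
          d <- comp_calls[[cp]]
          !isTRUE(d$missing[d$line_id == l])
        }, logical(1)))
      }, logical(1))
      mrow <- meta[meta$line_id == l, ]
      if (nrow(mrow) != 1L) {
        stop("line '", l, "' missing from metadata", call. = FALSE)
      }
      row <- data.frame(line_id = l, condition = mrow$condition,
                        donor_age = mrow$donor_age, stringsAsFactors = FALSE)
      for (m in markers) row[[m]] <- ind[[m]]
      row$n_markers_assessed <- sum(assessed)
      rows[[length(rows) + 1L]] <- row
    }
  }
  cm <- do.call(rbind, rows)
  rownames(cm) <- NULL
  structure(cm, provenance = do.call(rbind, prov), alpha = alpha,
            panel = panel, class = c("call_matrix", "data.frame"))
}

#' Default comparison designs from cell-line metadata
#'
#' Mirrors the study layout: donor-age lines (young/midage/old, including
#' the young controls themselves) are compared to the pooled young lines;
#' replicatively aged and progerin-induced lines to the pooled young
#' controls; progeria lines to the pooled age-matched (young + midage)
#' controls.
#'
#' @param meta metadata with `line_id` and `condition`.
#' @return list of design lists (`condition_label`, `reference_lines`,
#'   `test_lines`).
#' @export
default_designs <- function(meta) {
  lines_of <- function(conds) meta$line_id[meta$condition %in% conds]
  young <- lines_of("young")
  designs <- list()
  donor <- lines_of(c("young", "midage", "old"))
  if (length(donor) > 0L && length(young) > 0L) {
    designs$donor_age <- list(condition_label = "donor_age",
                              reference_lines = young, test_lines = donor)
  }
  repl <- lines_of("replicative")
  if (length(repl) > 0L) {
    designs$replicative <- list(condition_label = "replicative",
                                reference_lines = young, test_lines = repl)
  }
  art <- lines_of("artificial")
  if (length(art) > 0L) {
    designs$artificial <- list(condition_label = "artificial",
                               reference_lines = young, test_lines = art)
  }
  prog <- lines_of(c("HGPS", "WS", "progeria"))
  if (length(prog) > 0L) {
    designs$progeria <- list(condition_label = "progeria",
                             reference_lines = lines_of(c("young", "midage")),
                             test_lines = prog)
  }
  designs
}

#' @export
print.call_matrix <- function(x, ...) {
  cat("call matrix:", nrow(x), "lines x", length(panel_markers(attr(x, "panel"))),
      "markers (alpha =", attr(x, "alpha"), ")\n")
  print.data.frame(x, ...)
  invisible(x)
}
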