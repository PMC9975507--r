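#' Synthetic study design
#'
#' Describes the replicate structure of a fibroblast aging-panel
#' experiment: which cell lines exist (with condition labels and donor
#' ages), how many replicates each line contributes per marker, how many
#' cells each imaging replicate aggregates, duplicate qPCR/ELISA wells and
#' the number of telomere qPCR plates.  The default mirrors the reference
#' study layout: 5 young / 3 mid-age / 6 old donor lines, 6 replicatively
#' aged, 3 progerin-induced and 4 progeria lines, 4 replicates per marker,
#' more than 15 cells per imaging replicate, duplicate wells and 3
#' telomere plates.
#'
#' @param meta cell-line metadata (`line_id`, `condition`, `donor_age`);
#'   default [reference_meta()].
#' @param replicates replicates per line per marker (3-8 in the study;
#'   default 4).
#' @param cells_per_replicate cells aggregated by one imaging replicate
#'   (must exceed 15; default 20).
#' @param sabgal_cells cells scored per SA-beta-Gal replicate.
#' @param qpcr_duplicates technical well duplicates for expression qPCR
#'   and ELISA.
#' @param telomere_plates number of telomere MM-qPCR plates.
#' @return list of class `"design_spec"`.
#' @export
design_spec <- function(meta = reference_meta(), replicates = 4L,
                        cells_per_replicate = 20L, sabgal_cells = 100L,
                        qpcr_duplicates = 2L, telomere_plates = 3L) {
  stopifnot(is.data.frame(meta),
            all(c("line_id", "condition", "donor_age") %in% names(meta)))
  if (anyDuplicated(meta$line_id)) stop("duplicate line ids", call. = FALSE)
  if (replicates < 3L) stop("replicates must be >= 3", call. = FALSE)
  if (cells_per_replicate <= 15L) {
    stop("cells_per_replicate must exceed 15", call. = FALSE)
  }
  structure(
    list(meta = meta, replicates = as.integer(replicates),
         cells_per_replicate = as.integer(cells_per_replicate),
         sabgal_cells = as.integer(sabgal_cells),
         qpcr_duplicates = as.integer(qpcr_duplicates),
         telomere_plates = as.integer(telomere_plates)),
    class = "design_spec"
  )
}

#' Per-component noise model
#'
#' Distribution families and baseline parameters for every measurement
#' channel.  The study reports no distributional information for any
#' assay, so all families and magnitudes here are modelling choices:
#' log-normal for fluorescence intensities and ELISA concentrations,
#' Poisson counts for foci per nucleus, beta-binomial for SA-beta-Gal
#' positives, normal noise on the Cq scale for qPCR, and normal cell-level
#' variation for nucleus area.  `rep_sd` entries are the implied
#' replicate-level standard deviations on each component's latent
#' modelling scale; planted standardized effects are multiples of these.
#'
#' @param design a [design_spec()]; cell counts enter the replicate-level
#'   standard deviations.
#' @return named list of per-component parameter lists.
#' @export
noise_model <- function(design = design_spec()) {
  cells <- design$cells_per_replicate
  dup <- design$qpcr_duplicates
  list(
    gH2AX_foci = list(family = "poisson_mean", lambda = 2,
                      rep_sd = sqrt(2 / cells)),
    H3K9Me3_CTCF = list(family = "lognormal", meanlog = log(1e5),
                        rep_sd = 0.15),
    # per-plate log-ratio sd implied by Cq noise through a -3.32 slope:
    # sd(log10 q) = cq_sd/3.32 per target, times sqrt(2) for the ratio,
    # times ln(10) for the natural-log scale
    telomere_TS = list(family = "telomere", base_ratio = 1, cq_sd = 0.05,
                       input_ng = 20,
                       rep_sd = sqrt(2) * (0.05 / 3.32) * log(10)),
    SA_bGal_fraction = list(family = "betabinom", p0 = 0.10, icc = 0.02,
                            cells = design$sabgal_cells,
                            rep_sd = sqrt(0.1 * 0.9 *
                                            (1 + (design$sabgal_cells - 1) * 0.02) /
                                            design$sabgal_cells)),
    IL6 = list(family = "lognormal_dup", meanlog = log(50), well_sd = 0.2,
               rep_sd = 0.2 / sqrt(dup)),
    IL8 = list(family = "lognormal_dup", meanlog = log(100), well_sd = 0.2,
               rep_sd = 0.2 / sqrt(dup)),
    p21 = list(family = "qpcr_expression", ref_cq = 20, base_dct = 5,
               cq_sd = 0.15, rep_sd = 0.15 * sqrt(2 / dup)),
    p16 = list(family = "qpcr_expression", ref_cq = 22, base_dct = 7,
               cq_sd = 0.15, rep_sd = 0.15 * sqrt(2 / dup)),
    nucleus_area = list(family = "normal_mean", mean = 5000, cell_sd = 400,
                        rep_sd = 400 / sqrt(cells)),
    LMNB1_CTCF = list(family = "lognormal", meanlog = log(2e5),
                      rep_sd = 0.15)
  )
}

#' Plant standardized effects
#'
#' Builds an effect table assigning the same standardized aging-direction
#' shift to a set of lines and components.  Effects are magnitudes in
#' units of the replicate-level standard deviation of each component's
#' latent scale; the sign of the shift applied to the data follows the
#' panel's expected aging direction, so `effect = 5` always means "5
#' replicate-SDs towards old".
#'
#' @param line_id lines to affect.
#' @param component components to affect; default all panel components.
#' @param effect standardized effect size (>= 0).
#' @return data frame `line_id`, `component`, `effect`.
#' @export
plant_effects <- function(line_id, component = marker_panel()$component,
                          effect = 5) {
  expand.grid(line_id = line_id, component = component,
              effect = effect, stringsAsFactors = FALSE)
}

#' Study-like default effect profile
#'
#' A qualitative emulation of the reference study's outcome, chosen once
#' as plausible for this assay panel (not fitted to any data): old-donor
#' lines carry partial, heterogeneous moderate effects (3 SD on a subset
#' of markers per line), replicatively aged and progerin-induced lines
#' near-complete strong effects (5 SD), progeria lines an
#' HGPS/WS-like pattern; young and mid-age lines are null except for a
#' mild senescence signal in one mid-age line.
#'
#' @param meta metadata of the lines to cover.
#' @return effect table as in [plant_effects()].
#' @export
default_effects <- function(meta = reference_meta()) {
  pnl <- marker_panel()
  comp_of <- function(markers) pnl$component[pnl$marker %in% markers]
  eff <- list()
  add <- function(lines, markers, effect) {
    lines <- intersect(lines, meta$line_id)
    if (length(lines) > 0L) {
      eff[[length(eff) + 1L]] <<- plant_effects(lines, comp_of(markers), effect)
    }
  }
  old <- meta$line_id[meta$condition == "old"]
  mid <- meta$line_id[meta$condition == "midage"]
  # heterogeneous old-donor profile: senescence markers in all old lines,
  # primary-hallmark and morphology effects only in the oldest half
  add(old, c("SA_bGal", "SASP", "LMNB1"), 3)
  oldest <- old[seq_len(ceiling(length(old) / 2))]
  add(oldest, c("DNA_damage", "Histone_modification", "Cell_cycle_arrest",
                "Morphology"), 3)
  add(mid[seq_len(min(1L, length(mid)))], c("SA_bGal", "LMNB1"), 3)
  repl <- meta$line_id[meta$condition == "replicative"]
  add(repl, setdiff(unique(pnl$marker), "Telomere_attrition"), 5)
  add(repl[seq_len(ceiling(length(repl) * 2 / 3))], "Telomere_attrition", 5)
  art <- meta$line_id[meta$condition == "artificial"]
  add(art, setdiff(unique(pnl$marker), "Histone_modification"), 5)
  hgps <- meta$line_id[meta$condition == "HGPS"]
  add(hgps, c("DNA_damage", "Histone_modification", "SA_bGal", "SASP",
              "Morphology", "LMNB1"), 5)
  ws <- meta$line_id[meta$condition == "WS"]
  add(ws, c("DNA_damage", "SA_bGal", "Cell_cycle_arrest", "Morphology"), 5)
  do.call(rbind, eff)
}

#' Ground-truth call matrix implied by planted effects
#'
#' Marker-level truth: 1 when any component of the marker carries a
#' nonzero planted effect for that line.
#'
#' @param effects effect table (`line_id`, `component`, `effect`).
#' @param meta metadata covering at least the affected lines.
#' @param panel panel definition.
#' @return a `call_matrix`-shaped data frame (no provenance).
#' @export
truth_matrix <- function(effects, meta, panel = marker_panel()) {
  markers <- panel_markers(panel)
  tm <- data.frame(line_id = meta$line_id, condition = meta$condition,
                   donor_age = meta$donor_age, stringsAsFactors = FALSE)
  for (m in markers) {
    comps <- panel$component[panel$marker == m]
    tm[[m]] <- vapply(meta$line_id, function(l) {
      as.integer(!is.null(effects) && any(
        effects$line_id == l & effects$component %in% comps &
          effects$effect != 0
      ))
    }, integer(1))
  }
  tm$n_markers_assessed <- length(markers)
  rownames(tm) <- NULL
  structure(tm, panel = panel, class = c("call_matrix", "data.frame"))
}

# independent substreams: a small LCG hash over (master, line, component)
# so adding lines or components never perturbs other draws
substream_seed <- function(master, line_idx, comp_idx) {
  lcg <- function(x) (69069 * x + 1) %% 2147483647
  h <- lcg(master %% 2147483647)
  h <- lcg(h + 104729 * line_idx)
  h <- lcg(h + 7919 * comp_idx)
  as.integer(h)
}

#' Generate a synthetic assay-level dataset
#'
#' Draws replicate-level measurements for every line and panel component
#' under the design's replicate structure, with planted standardized
#' effects in each component's aging direction.  Telomere data are
#' generated at the Cq level — per-plate standard dilution series are
#' simulated, standard curves fitted with [fit_standard_curve()] and
#' per-plate T/S ratios computed with [telomere_ts_ratio()] — so the
#' quantification path is exercised end-to-end.  Expression (p21/p16)
#' replicates are likewise generated as duplicate Cq wells and converted
#' with [relative_expression()].
#'
#' Deterministic: identical `(design, effects, seed)` give bit-identical
#' output; each (line, component) pair has its own RNG substream derived
#' from the master seed.
#'
#' @param design a [design_spec()].
#' @param effects effect table from [plant_effects()] / [default_effects()],
#'   or `NULL` for a global null.
#' @param noise a [noise_model()].
#' @param seed master integer seed.
#' @return list with `measurements` (replicate-level data frame:
#'   `line_id`, `condition`, `marker`, `component`, `replicate_id`,
#'   `value`, `unit`), `truth` (the planted [truth_matrix()]), and
#'   `telomere_cq` (the simulated Cq-level telomere table).
#' @export
generate_dataset <- function(design = design_spec(), effects = NULL,
                             noise = noise_model(design), seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  meta <- design$meta
  panel <- marker_panel()
  if (!is.null(effects)) {
    bad <- setdiff(effects$component, panel$component)
    if (length(bad) > 0L) {
      stop("unknown component(s) in effects: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  eff_of <- function(line, comp) {
    if (is.null(effects)) return(0)
    e <- effects$effect[effects$line_id == line & effects$component == comp]
    if (length(e) == 0L) 0 else e[1]
  }
  # per-plate telomere standard curves, shared by all lines
  tel <- noise$telomere_TS
  plates <- paste0("P", seq_len(design$telomere_plates))
  standards <- 100 / 3^(0:6)                    # 100 .. 0.137 ng/uL
  curves <- list()
  std_rows <- list()
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(s)
    expr
  }
  for (pi in seq_along(plates)) {
    curves[[plates[pi]]] <- withr_seed(substream_seed(seed, 0L, pi), {
      icpt <- c(telomere = 22, single_copy = 28)
      slope <- c(telomere = -3.32, single_copy = -3.35)
      pc <- list()
      for (tg in c("telomere", "single_copy")) {
        cq <- icpt[tg] + slope[tg] * log10(standards) +
          stats::rnorm(length(standards), 0, tel$cq_sd)
        pc[[tg]] <- fit_standard_curve(standards, cq)
        # the promise evaluates in this function's frame, so plain
        # assignment updates the accumulator
        std_rows[[length(std_rows) + 1L]] <- data.frame(
          sample_id = "standard", plate_id = plates[pi], target = tg,
          role = "standard", cq = cq, standard_concentration = standards,
          stringsAsFactors = FALSE
        )
      }
      pc
    })
  }
  comp_idx <- stats::setNames(seq_len(nrow(panel)) + length(plates),
                              panel$component)
  rows <- list()
  cq_rows <- std_rows
  unit_of <- c(gH2AX_foci = "foci/nucleus", H3K9Me3_CTCF = "au",
               telomere_TS = "T/S", SA_bGal_fraction = "fraction",
               IL6 = "pg/mL", IL8 = "pg/mL", p21 = "fold", p16 = "fold",
               nucleus_area = "pixels", LMNB1_CTCF = "au")
  for (li in seq_len(nrow(meta))) {
    line <- meta$line_id[li]
    for (ci in seq_len(nrow(panel))) {
      comp <- panel$component[ci]
      sgn <- if (panel$direction[ci] == "increase") 1 else -1
      e <- eff_of(line, comp)
      np <- noise[[comp]]
      vals <- withr_seed(substream_seed(seed, li, comp_idx[[comp]]), {
        switch(
          np$family,
          poisson_mean = {
            # effect acts on the replicate-mean scale
            lam <- max(np$lambda + sgn * e * np$rep_sd, 0.01)
            vapply(seq_len(design$replicates), function(r) {
              mean(stats::rpois(design$cells_per_replicate, lam))
            }, numeric(1))
          },
          lognormal = {
            exp(stats::rnorm(design$replicates,
                             np$meanlog + sgn * e * np$rep_sd, np$rep_sd))
          },
          lognormal_dup = {
            vapply(seq_len(design$replicates), function(r) {
              mean(exp(stats::rnorm(design$qpcr_duplicates,
                                    np$meanlog + sgn * e * np$rep_sd,
                                    np$well_sd)))
            }, numeric(1))
          },
          normal_mean = {
            mu <- np$mean + sgn * e * np$rep_sd
            vapply(seq_len(design$replicates), function(r) {
              mean(stats::rnorm(design$cells_per_replicate, mu, np$cell_sd))
            }, numeric(1))
          },
          betabinom = {
            p <- min(max(np$p0 + sgn * e * np$rep_sd, 0.002), 0.995)
            rho <- np$icc
            a <- p * (1 - rho) / rho
            b <- (1 - p) * (1 - rho) / rho
            vapply(seq_len(design$replicates), function(r) {
              pr <- stats::rbeta(1, a, b)
              sabgal_fraction(stats::rbinom(1, np$cells, pr), np$cells)
            }, numeric(1))
          },
          qpcr_expression = {
            # effect in fold units: dCt shift of -e * rep_sd cycles
            dct <- np$base_dct - sgn * e * np$rep_sd
            vapply(seq_len(design$replicates), function(r) {
              ref <- stats::rnorm(design$qpcr_duplicates, np$ref_cq, np$cq_sd)
              tgt <- stats::rnorm(design$qpcr_duplicates, np$ref_cq + dct,
                                  np$cq_sd)
              relative_expression(tgt, ref, calibrator_dct = np$base_dct)
            }, numeric(1))
          },
          telomere = {
            log10_ratio <- (sgn * e * np$rep_sd) / log(10)
            q_s <- np$input_ng
            q_t <- np$input_ng * 10^log10_ratio
            cq <- do.call(rbind, lapply(plates, function(p) {
              data.frame(
                sample_id = line, plate_id = p,
                target = c("telomere", "single_copy"), role = "sample",
                cq = c(
                  curves[[p]]$telomere$intercept +
                    curves[[p]]$telomere$slope * log10(q_t) +
                    stats::rnorm(1, 0, np$cq_sd),
                  curves[[p]]$single_copy$intercept +
                    curves[[p]]$single_copy$slope * log10(q_s) +
                    stats::rnorm(1, 0, np$cq_sd)
                ),
                standard_concentration = NA_real_,
                stringsAsFactors = FALSE
              )
            }))
            cq_rows[[length(cq_rows) + 1L]] <- cq
            telomere_ts_ratio(cq, curves)$per_plate_ratios
          },
          stop("unknown noise family: ", np$family, call. = FALSE)
        )
      })
      rows[[length(rows) + 1L]] <- data.frame(
        line_id = line, condition = meta$condition[li],
        marker = panel$marker[ci], component = comp,
        replicate_id = seq_along(vals), value = vals,
        unit = unit_of[[comp]], stringsAsFactors = FALSE
      )
    }
  }
  measurements <- do.call(rbind, rows)
  rownames(measurements) <- NULL
  list(
    measurements = measurements,
    truth = truth_matrix(effects, meta),
    telomere_cq = do.call(rbind, cq_rows)
  )
}

#' Monte-Carlo detection-frequency (power) simulation
#'
#' Repeatedly generates datasets under the given design and effect table,
#' runs the full calling pipeline, and reports how often each planted
#' marker is called, with the binomial Monte-Carlo standard error.  Lines
#' without a planted effect contribute to the false-call summary instead.
#'
#' @param effects effect table (may be `NULL` for a pure null run).
#' @param design a [design_spec()].
#' @param n_sims number of simulated datasets (>= 100 for stable
#'   frequencies; smaller values are allowed but noisy).
#' @param seed master seed; dataset `i` uses `seed + i`.
#' @param alpha significance level passed to the caller.
#' @return list with `detection` (per-marker data frame: `marker`,
#'   `n_planted`, `detected`, `frequency`, `mc_se`) and `false_calls`
#'   (same layout over null line-marker cells).
#' @export
power_simulation <- function(effects, design = design_spec(), n_sims = 100L,
                             seed = 1L, alpha = 0.05) {
  panel <- marker_panel()
  markers <- panel_markers(panel)
  meta <- design$meta
  truth <- truth_matrix(effects, meta)
  tmat <- as.matrix(truth[, markers])
  hits <- matrix(0, nrow(meta), length(markers),
                 dimnames = list(meta$line_id, markers))
  for (i in seq_len(n_sims)) {
    ds <- generate_dataset(design, effects, noise_model(design),
                           seed = seed + i)
    cm <- build_call_matrix(ds$measurements, meta, alpha = alpha)
    cmat <- as.matrix(cm[match(meta$line_id, cm$line_id), markers])
    hits <- hits + cmat
  }
  summarize <- function(mask) {
    data.frame(
      marker = markers,
      n_planted = colSums(mask),
      detected = colSums(hits * mask) / n_sims,
      frequency = ifelse(colSums(mask) > 0,
                         colSums(hits * mask) / (n_sims * colSums(mask)),
                         NA_real_),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  det <- summarize(tmat == 1)
  det$mc_se <- sqrt(pmax(det$frequency * (1 - det$frequency), 0) /
                      (n_sims * pmax(det$n_planted, 1)))
  fc <- summarize(tmat == 0)
  names(fc)[names(fc) == "n_planted"] <- "n_null"
  fc$mc_se <- sqrt(pmax(fc$frequency * (1 - fc$frequency), 0) /
                     (n_sims * pmax(fc$n_null, 1)))
  list(detection = det, false_calls = fc)
}
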