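test_that("one-way ANOVA matches the squared-t identity and base R", {
  set.seed(101)
  a <- rnorm(6); b <- rnorm(7, 1)
  res <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  # three clearly separated groups
  sep <- one_way_anova(list(c(0, 0, 0) + rnorm(3, 0, 1e-9),
                            c(1, 1, 1) + rnorm(3, 0, 1e-9),
                            c(2, 2, 2) + rnorm(3, 0, 1e-9)))
  expect_lt(sep$p, 1e-6)
  expect_warning(deg <- one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_true(is.na(deg$p))
  expect_error(one_way_anova(list(rnorm(3))), "groups")
  expect_error(one_way_anova(list(rnorm(3), 1)), "replicate")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(2024)
  hits <- 0L
  for (i in seq_len(1000)) {
    p <- one_way_anova(list(rnorm(4), rnorm(4), rnorm(4)))$p
    hits <- hits + (p < 0.05)
  }
  expect_lt(abs(hits / 1000 - 0.05), 0.015)
})

test_that("Dunnett with one contrast reduces to the pooled t-test", {
  set.seed(55)
  for (i in 1:5) {
    x <- rnorm(5, 1); ref <- rnorm(8)
    dn <- dunnett_many_to_one(list(x), ref)
    tt <- t.test(x, ref, var.equal = TRUE)
    expect_equal(dn$p_adj, tt$p.value, tolerance = 1e-6)
    expect_equal(dn$estimate, mean(x) - mean(ref), tolerance = 1e-12)
  }
})

test_that("Dunnett adjusted p-values match the multcomp/mvtnorm oracle", {
  skip_if_not_installed("multcomp")
  set.seed(77)
  g <- factor(rep(c("ctrl", "t1", "t2", "t3"), times = c(8, 4, 5, 4)))
  y <- rnorm(length(g)) + (g == "t2") * 1.5
  dn <- dunnett_many_to_one(split(y, g)[c("t1", "t2", "t3")],
                            y[g == "ctrl"])
  fit <- stats::aov(y ~ g)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  ps <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  # multcomp evaluates the same multivariate-t integral by quasi-Monte-Carlo
  expect_equal(dn$p_adj, as.numeric(ps), tolerance = 5e-4)
})

test_that("the many-to-one adjustment never falls below the raw t p-value", {
  set.seed(88)
  for (i in 1:10) {
    groups <- replicate(3, rnorm(4, sample(0:2, 1)), simplify = FALSE)
    ref <- rnorm(10)
    dn <- dunnett_many_to_one(groups, ref)
    raw <- vapply(seq_along(groups), function(j) {
      2 * pt(-abs(dn$t[j]), dn$df[j])
    }, numeric(1))
    expect_true(all(dn$p_adj >= raw - 1e-9))
  }
})

test_that("direction gate blocks significant anti-aging shifts", {
  set.seed(3)
  ref <- rnorm(12)
  up <- list(T1 = rnorm(6, 5))
  down <- list(T1 = rnorm(6, -5))
  same <- list(T1 = ref[1:6])
  expect_equal(call_component(up, ref, "increase")$indicator, 1L)
  expect_equal(call_component(down, ref, "increase")$indicator, 0L)
  expect_equal(call_component(down, ref, "decrease")$indicator, 1L)
  # opposite-direction shift is significant but not called
  cc <- call_component(down, ref, "increase")
  expect_lt(cc$p_adj, 0.05)
  expect_false(cc$direction_ok)
  # identical to reference: no call
  expect_equal(call_component(same, ref, "increase")$indicator, 0L)
})

test_that("degenerate variance yields a warned no-call", {
  expect_warning(
    dn <- dunnett_many_to_one(list(c(2, 2, 2)), c(2, 2, 2, 2)),
    "degenerate"
  )
  expect_false(dn$significant)
})

test_that("composite markers use the any-component rule", {
  expect_equal(aggregate_components(c(p21 = 1L, p16 = 0L)), 1L)
  expect_equal(aggregate_components(c(IL6 = 0L, IL8 = 0L)), 0L)
  expect_equal(aggregate_components(c(IL6 = 1L, IL8 = 1L)), 1L)
  expect_error(aggregate_components(integer(0)), "no components")
})

test_that("call matrix assembles indicators, provenance and missing flags", {
  meta <- small_meta(n_test = 2, n_ctrl = 3)
  set.seed(9)
  vals <- list(C1 = rnorm(4, 2), C2 = rnorm(4, 2), C3 = rnorm(4, 2),
               T1 = rnorm(4, 8), T2 = rnorm(4, 2))
  mm <- measurements_from(vals, meta)
  cm <- build_call_matrix(mm, meta)
  expect_s3_class(cm, "call_matrix")
  expect_equal(cm$DNA_damage[cm$line_id == "T1"], 1L)
  expect_equal(cm$DNA_damage[cm$line_id == "T2"], 0L)
  # only one component measured -> one marker assessed, others 0 + flagged
  expect_equal(unique(cm$n_markers_assessed), 1L)
  expect_equal(cm$SA_bGal, rep(0L, nrow(cm)))
  prov <- attr(cm, "provenance")
  expect_true(all(c("p_adj", "direction_ok", "missing") %in% names(prov)))
  # direction-filter invariant on every call made
  called <- prov[!is.na(prov$p_adj) & prov$indicator == 1L, ]
  expect_true(all(called$direction_ok))
  expect_error(build_call_matrix(mm, meta[meta$line_id != "T1", ]),
               "no metadata")
  expect_error(build_call_matrix(mm, meta[meta$condition != "young", ],
                                 designs = list()),
               "no comparison design|no metadata")
})

test_that("call matrix is deterministic and row-order invariant", {
  meta <- small_meta()
  design <- design_spec(meta = meta)
  ds <- generate_dataset(design, plant_effects("T1"), seed = 5)
  cm1 <- suppressWarnings(build_call_matrix(ds$measurements, meta))
  cm2 <- suppressWarnings(build_call_matrix(ds$measurements, meta))
  expect_identical(cm1, cm2)
  set.seed(1)
  shuffled <- ds$measurements[sample(nrow(ds$measurements)), ]
  cm3 <- suppressWarnings(build_call_matrix(shuffled, meta))
  expect_identical(as.data.frame(cm1), as.data.frame(cm3))
})
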