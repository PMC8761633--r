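test_that("raw cleavage ratios follow product/(product+substrate)", {
  expect_identical(raw_cleavage_ratio(0, 5000), 0)
  expect_identical(raw_cleavage_ratio(5000, 0), 1)
  expect_identical(raw_cleavage_ratio(3000, 1000), 0.75)
  expect_error(raw_cleavage_ratio(0, 0), "empty lane")
  expect_error(raw_cleavage_ratio(-1, 5), "non-negative")
})

test_that("relative efficiency maps the control to exactly 100", {
  expect_identical(relative_efficiency(0.6, 0.6), 100)
  expect_identical(relative_efficiency(0.3, 0.6), 50)
  expect_identical(relative_efficiency(0, 0.6), 0)
  expect_error(relative_efficiency(0.3, 0), "unusable control")
})

test_that("relative efficiencies are invariant to lane intensity scaling", {
  lanes <- tibble::tibble(
    substrate_id = c("ctl", "a", "b"), enzyme = "drosha",
    product_intensity = c(600, 300, 900),
    substrate_intensity = c(400, 700, 100),
    is_control = c(TRUE, FALSE, FALSE))
  base <- cleavage_efficiencies(lanes)
  scaled <- lanes
  scaled$product_intensity <- scaled$product_intensity * 7.3
  scaled$substrate_intensity <- scaled$substrate_intensity * 7.3
  expect_equal(base, cleavage_efficiencies(scaled))
  expect_identical(
    base$relative_efficiency[base$substrate_id == "ctl"], 100)
})

test_that("spearman equals Pearson on midranks, also under ties", {
  st <- spearman_test(c(1, 2, 3), c(10, 20, 30))
  expect_identical(st$rho, 1)
  expect_identical(spearman_test(c(1, 2, 3), c(30, 20, 10))$rho, -1)
  # tie case against an explicit midrank computation
  x <- c(1, 2, 2, 3)
  y <- c(2, 1, 3, 4)
  st2 <- spearman_test(x, y)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(st2$rho, oracle)
  # and against the standard library on a larger tied sample
  set.seed(5)
  x3 <- sample(1:6, 30, replace = TRUE)
  y3 <- x3 + sample(1:4, 30, replace = TRUE)
  st3 <- spearman_test(x3, y3)
  ct <- suppressWarnings(stats::cor.test(x3, y3, method = "spearman",
                                         exact = FALSE))
  expect_equal(st3$rho, unname(ct$estimate))
  expect_equal(st3$p_value, ct$p.value, tolerance = 1e-10)
})

test_that("spearman handles missing pairs and degenerate input", {
  st <- spearman_test(c(1, 2, NA, 4, 5), c(5, 4, 3, NA, 1))
  expect_identical(st$n, 3L)
  expect_error(spearman_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(spearman_test(c(1, 2), c(1, 2)), "at least 3")
})

test_that("small-sample spearman p comes from the permutation distribution", {
  set.seed(11)
  x <- c(3, 1, 4, 1, 5, 9, 2)
  y <- c(2, 7, 1, 8, 2, 8, 1)
  st <- spearman_test(x, y)
  # independent brute force over all 7! permutations of y
  perms <- mirhairpin:::all_permutations(7)
  rx <- rank(x); ry <- rank(y)
  rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  obs <- stats::cor(rx, ry)
  expect_equal(st$p_value, mean(abs(rhos) >= abs(obs) - 1e-12))
})

test_that("mann-whitney is exact at small n and symmetric under swap", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$p_value, 2 / 20)  # the two extreme labelings out of C(6,3)
  expect_identical(mann_whitney_u(b, a)$p_value, mw$p_value)
  # agreement with the standard library where both are exact (no ties)
  set.seed(2)
  x <- rnorm(6); y <- rnorm(7) + 0.5
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  # identical groups
  expect_identical(mann_whitney_u(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
})

test_that("large-sample mann-whitney uses the tie-corrected normal", {
  set.seed(8)
  a <- sample(1:5, 20, replace = TRUE)
  b <- sample(2:6, 25, replace = TRUE)
  mw <- mann_whitney_u(a, b)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(mw$p_value, wt$p.value, tolerance = 1e-10)
  expect_identical(mann_whitney_u(b, a)$p_value, mw$p_value)
})

test_that("the correlation report flags constant features and counts pairs", {
  features <- tibble::tibble(
    id = sprintf("m%d", 1:10),
    dg_loop = c(1:9, NA), dg_proximal = rep(2, 10))
  eff <- tibble::tibble(
    substrate_id = sprintf("m%d", 1:10), enzyme = "drosha",
    relative_efficiency = c(11:19, 20), is_control = FALSE)
  rep <- correlation_report(features, eff)
  loop_row <- rep[rep$feature == "dg_loop", ]
  expect_identical(loop_row$n, 9L)
  expect_equal(loop_row$rho, 1)
  prox_row <- rep[rep$feature == "dg_proximal", ]
  expect_true(is.na(prox_row$rho))
  expect_match(prox_row$note, "constant")
})

test_that("permuted responses yield null-distributed correlations", {
  coh <- generate_cohort(cohort_config(n_mirnas = 60, seed = 19))
  feats <- hairpin_features(coh$records)
  eff <- cleavage_efficiencies(coh$lanes)
  eff_d <- eff[eff$enzyme == "drosha" & !eff$is_control, ]
  set.seed(4)
  ps <- replicate(40, {
    shuffled <- eff_d
    shuffled$relative_efficiency <- sample(shuffled$relative_efficiency)
    correlation_report(feats, shuffled)
  }, simplify = FALSE)
  ps <- dplyr::bind_rows(ps)
  ps <- ps[ps$feature == "dg_proximal", ]
  expect_lt(mean(abs(ps$rho)), 0.2)
  expect_gt(mean(ps$p_value > 0.05), 0.8)
})

test_that("conserved-vs-unique splits families at two members", {
  records <- tibble::tibble(
    id = c("a", "b", "c", "d"),
    family = c("f1", "f1", "f1", "f2"))
  values <- tibble::tibble(id = records$id, value = c(5, 6, 7, 1))
  cmp <- conserved_vs_unique(records, values)
  expect_identical(cmp$n[cmp$group == "conserved"], 3L)
  expect_identical(cmp$n[cmp$group == "unique"], 1L)
  expect_equal(cmp$p_value[1],
               mann_whitney_u(c(5, 6, 7), 1)$p_value)
  # all singletons: comparison skipped with a warning
  rec2 <- tibble::tibble(id = c("a", "b"), family = c("f1", "f2"))
  val2 <- tibble::tibble(id = rec2$id, value = c(1, 2))
  expect_warning(cmp2 <- conserved_vs_unique(rec2, val2), "empty")
  expect_true(all(is.na(cmp2$p_value)))
})

test_that("a planted conserved-family advantage is detected", {
  coh <- generate_cohort(cohort_config(n_mirnas = 80, seed = 29))
  eff <- cleavage_efficiencies(coh$lanes)
  eff_d <- eff[eff$enzyme == "drosha" & !eff$is_control, ]
  fam_sizes <- table(coh$records$family)
  conserved <- coh$records$family %in% names(fam_sizes)[fam_sizes >= 2]
  vals <- tibble::tibble(id = eff_d$substrate_id,
                         value = eff_d$relative_efficiency)
  boost <- conserved[match(vals$id, coh$records$id)]
  vals$value <- vals$value * ifelse(boost, 2.5, 1)
  cmp <- conserved_vs_unique(coh$records, vals)
  expect_lt(cmp$p_value[1], 0.05)
  expect_gt(cmp$mean[cmp$group == "conserved"],
            cmp$mean[cmp$group == "unique"])
})

test_that("time-course summaries flag monotone substrates", {
  meas <- tibble::tibble(
    substrate_id = rep(c("s1", "s2"), each = 3),
    timepoint = rep(c(10, 30, 60), 2),
    raw_ratio = c(0.1, 0.3, 0.5, 0.4, 0.2, 0.6))
  ts <- timecourse_summary(meas)
  expect_true(all(ts$monotone[ts$substrate_id == "s1"]))
  expect_false(any(ts$monotone[ts$substrate_id == "s2"]))
  expect_true(all(ts$sd_ratio == 0))  # single replicate
  # replicates produce a nonzero SD
  meas2 <- dplyr::bind_rows(meas, meas[1, ] |>
                              dplyr::mutate(raw_ratio = 0.2))
  ts2 <- timecourse_summary(meas2)
  r1 <- ts2[ts2$substrate_id == "s1" & ts2$timepoint == 10, ]
  expect_identical(r1$n, 2L)
  expect_equal(r1$mean_ratio, 0.15)
  expect_gt(r1$sd_ratio, 0)
})
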