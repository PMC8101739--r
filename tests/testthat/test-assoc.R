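# Association statistics: exact Fisher, carrier tables, penetrance,
# onset-age t-tests and one-way ANOVA.

test_that("two-tailed Fisher reproduces published carrier-table p-values", {
  expect_equal(signif(fisher_exact_two_tailed(contingency_2x2(13, 29, 1, 49)), 3),
               1.80e-4)
  expect_equal(signif(fisher_exact_two_tailed(contingency_2x2(13, 29, 11, 2739)), 3),
               5.85e-19)
  expect_equal(signif(fisher_exact_two_tailed(contingency_2x2(13, 29, 476, 3054)), 3),
               4.90e-3)
})

test_that("Fisher degenerate and symmetric tables give p = 1", {
  # every table of the 5/5 margins has probability <= the observed one
  expect_equal(fisher_exact_two_tailed(contingency_2x2(2, 3, 3, 2)), 1)
  expect_equal(fisher_exact_two_tailed(contingency_2x2(0, 5, 0, 5)), 1)
  expect_equal(fisher_exact_two_tailed(contingency_2x2(4, 0, 4, 0)), 1)
})

test_that("Fisher equals the enumeration oracle and fisher.test on
           random tables", {
  set.seed(42)
  for (rep in 1:200) {
    v <- as.integer(rmultinom(1, sample(4:60, 1), runif(4, 0.05, 1)))
    if (sum(v[1:2]) == 0 || sum(v[3:4]) == 0) next
    p_impl <- fisher_exact_two_tailed(contingency_2x2(v[1], v[2], v[3], v[4]))
    p_oracle <- fisher_oracle(v[1], v[2], v[3], v[4])
    p_ref <- stats::fisher.test(matrix(v, 2, byrow = TRUE))$p.value
    expect_equal(p_impl, p_oracle, tolerance = 1e-10,
                 info = paste(v, collapse = ","))
    expect_equal(p_impl, min(p_ref, 1), tolerance = 1e-7,
                 info = paste(v, collapse = ","))
  }
})

test_that("Fisher p is invariant under simultaneous row+column swap and
           lies in [0, 1]", {
  set.seed(7)
  for (rep in 1:50) {
    v <- as.integer(sample(0:20, 4, replace = TRUE))
    if (sum(v) == 0) next
    p1 <- fisher_exact_two_tailed(contingency_2x2(v[1], v[2], v[3], v[4]))
    p2 <- fisher_exact_two_tailed(contingency_2x2(v[4], v[3], v[2], v[1]))
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_gte(p1, 0); expect_lte(p1, 1)
  }
})

test_that("exact test is conservative under the null", {
  # both margins binomial at one carrier frequency; type-I error at
  # alpha = 0.05 must not exceed 0.05 + 2 * MC standard error
  set.seed(123)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    a <- rbinom(1, 40, 0.2); c <- rbinom(1, 60, 0.2)
    p <- fisher_exact_two_tailed(contingency_2x2(a, 40 - a, c, 60 - c))
    if (p <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(rate, 0.05 + 2 * mc_se)
})

test_that("odds ratio applies Haldane correction only on zero cells", {
  plain <- odds_ratio(contingency_2x2(13, 29, 1, 49))
  expect_false(plain$corrected)
  expect_equal(plain$or, 13 * 49 / (29 * 1))
  corr <- odds_ratio(contingency_2x2(5, 5, 0, 10))
  expect_true(corr$corrected)
  expect_equal(corr$or, (5.5 * 10.5) / (5.5 * 0.5))
})

make_proband_cohort <- function(n_case, n_carrier, n_ctrl_fam = 0,
                                n_ctrl_carrier = 0) {
  rows <- list(); ids <- character(0)
  for (i in seq_len(n_case)) {
    id <- sprintf("P%03d", i)
    rows[[id]] <- sample_row(id, sprintf("F%03d", i), is_proband = TRUE)
    ids <- c(ids, id)
  }
  for (i in seq_len(n_ctrl_fam)) {
    id <- sprintf("Q%03d", i)
    rows[[id]] <- sample_row(id, sprintf("CF%03d", i),
                             affection = "unaffected")
    ids <- c(ids, id)
  }
  ped <- pedigree_set(do.call(rbind, rows))
  dos <- matrix(0L, 1, length(ids), dimnames = list(NULL, ids))
  dos[1, seq_len(n_carrier)] <- 1L
  if (n_ctrl_carrier > 0) {
    dos[1, n_case + seq_len(n_ctrl_carrier)] <- 1L
  }
  list(ped = ped, gm = make_gm(dos), key = make_gm(dos)$variants$key[1])
}

test_that("proband carrier table assembles case and control margins", {
  co <- make_proband_cohort(42, 13, n_ctrl_fam = 50, n_ctrl_carrier = 1)
  res <- build_family_table(co$ped, co$gm, co$key)
  expect_equal(c(res$table$a, res$table$b, res$table$c, res$table$d),
               c(13L, 29L, 1L, 49L))
  expect_equal(signif(res$p_two_tailed, 3), 1.80e-4)

  # external counts pass through verbatim
  ext <- build_family_table(co$ped, co$gm, co$key, control = c(476, 3054),
                            source = "NHLBI")
  expect_equal(c(ext$table$c, ext$table$d), c(476L, 3054L))
  expect_equal(signif(ext$p_two_tailed, 3), 4.90e-3)
})

test_that("missing proband genotype drops the family with a warning", {
  co <- make_proband_cohort(5, 2)
  co$gm$dosage[1, "P005"] <- NA_integer_
  expect_warning(res <- build_family_table(co$ped, co$gm, co$key,
                                           control = c(1, 9)),
                 "P005")
  expect_equal(res$table$a + res$table$b, 4L)
})

test_that("carrier fraction rounds to the nearest integer percent", {
  co <- make_proband_cohort(42, 13)
  cf <- carrier_fraction(co$ped, co$gm, co$key)
  expect_equal(cf$percent, 31)
  expect_equal(carrier_fraction(co$ped, co$gm, co$key)$total, 42L)
  co0 <- make_proband_cohort(42, 0)
  expect_equal(carrier_fraction(co0$ped, co0$gm, co0$key)$percent, 0)
  co21 <- make_proband_cohort(42, 21)
  expect_equal(carrier_fraction(co21$ped, co21$gm, co21$key)$percent, 50)
})

test_that("penetrance is affected carriers over known-status carriers", {
  rows <- list()
  for (i in 1:19) rows[[i]] <- sample_row(sprintf("A%02d", i),
                                          sprintf("F%02d", i))
  rows[[20]] <- sample_row("U01", "F01b", affection = "unaffected")
  rows[[21]] <- sample_row("X01", "F01c", affection = "unknown")
  ped <- pedigree_set(do.call(rbind, rows))
  ids <- ped$samples$sample_id
  dos <- matrix(1L, 1, length(ids), dimnames = list(NULL, ids))
  gm <- make_gm(dos)
  key <- gm_keys(gm)[1]
  pen <- penetrance_estimate(ped, gm, key)
  # 19 affected + 1 unaffected carrier; unknown-status carrier excluded
  expect_equal(pen$carriers, 20L)
  expect_equal(pen$penetrance, 0.95)

  dos0 <- matrix(0L, 1, length(ids), dimnames = list(NULL, ids))
  gm0 <- make_gm(dos0)
  expect_error(penetrance_estimate(ped, gm0, gm_keys(gm0)[1]),
               "no genotyped carriers")
})

test_that("pooled t-test matches the closed-form oracle on summaries
           and raw values", {
  # identical groups
  expect_equal(t_test_two_sample(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # published group summaries, pooled; oracle from the t CDF directly
  g1 <- list(mean = 44.0, sd = 14.0, n = 16)
  g2 <- list(mean = 54.4, sd = 16.1, n = 36)
  res <- t_test_two_sample(g1, g2)
  sp2 <- (15 * 14^2 + 35 * 16.1^2) / 50
  t_oracle <- (44 - 54.4) / sqrt(sp2 * (1 / 16 + 1 / 36))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 50), tolerance = 1e-12)
  expect_equal(res$df, 50)
  # raw values agree with stats::t.test
  set.seed(5)
  x <- rnorm(12, 44, 14); y <- rnorm(20, 54, 16)
  ours <- t_test_two_sample(x, y)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # hand-computed two-point case: c(0,1) vs c(2,3) gives t = -2*sqrt(2)
  hand <- t_test_two_sample(c(0, 1), c(2, 3))
  expect_equal(hand$t, -2 * sqrt(2), tolerance = 1e-12)
  # degenerate variance
  expect_equal(t_test_two_sample(c(2, 2), c(2, 2))$p, 1)
  expect_error(t_test_two_sample(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch variant matches stats::t.test", {
  set.seed(9)
  x <- rnorm(10); y <- rnorm(15, 1, 3)
  ours <- t_test_two_sample(x, y, variant = "welch")
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("one-way ANOVA matches a sums-of-squares oracle and the
           two-group t identity", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  res <- anova_one_way_bonferroni(groups)
  # direct SS computation
  all_v <- unlist(groups)
  gm_ <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - gm_)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  F_oracle <- (ss_between / 2) / (ss_within / 6)
  expect_equal(res$F, F_oracle, tolerance = 1e-12)
  expect_equal(res$df1, 2L); expect_equal(res$df2, 6L)
  expect_equal(res$p, pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # Bonferroni multiplies by the number of pairs, capped at 1
  expect_equal(res$pairwise$p_bonferroni,
               pmin(1, res$pairwise$p_raw * 3))

  # identical groups: F = 0, p = 1
  same <- anova_one_way_bonferroni(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_equal(same$F, 0); expect_equal(same$p, 1)

  # two groups: F equals the square of the pooled t statistic
  g1 <- c(3, 5, 9, 2); g2 <- c(7, 8, 12)
  two <- anova_one_way_bonferroni(list(g1, g2))
  tt <- t_test_two_sample(g1, g2)
  expect_equal(two$F, tt$t^2, tolerance = 1e-12)

  # shift invariance of F
  shifted <- anova_one_way_bonferroni(lapply(groups, `+`, 100))
  expect_equal(shifted$F, res$F, tolerance = 1e-9)

  expect_error(anova_one_way_bonferroni(list(c(1, 2))), ">= 2 groups")
  expect_error(anova_one_way_bonferroni(list(c(1, 2), 3)), "n >= 2")
})

test_that("onset-age comparison splits affecteds by carrier status", {
  rows <- list()
  onsets_c <- c(40, 42, 44, 50); onsets_n <- c(55, 60, 52, 58)
  for (i in 1:4) rows[[i]] <- sample_row(sprintf("C%d", i),
                                         sprintf("F%d", i),
                                         onset_age = onsets_c[i])
  for (i in 1:4) rows[[4 + i]] <- sample_row(sprintf("N%d", i),
                                             sprintf("F%d", 4 + i),
                                             onset_age = onsets_n[i])
  ped <- pedigree_set(do.call(rbind, rows))
  ids <- ped$samples$sample_id
  dos <- matrix(c(rep(1L, 4), rep(0L, 4)), 1,
                dimnames = list(NULL, ids))
  gm <- make_gm(dos)
  res <- onset_age_comparison(ped, gm, gm_keys(gm)[1])
  ref <- t_test_two_sample(onsets_c, onsets_n)
  expect_equal(res$t, ref$t)
  expect_equal(res$n_carrier, 4L)
  expect_equal(res$n_noncarrier, 4L)
})
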