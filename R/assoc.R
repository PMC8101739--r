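# Association layer: exact two-tailed Fisher tests on proband carrier
# counts, carrier-fraction and penetrance summaries, onset-age t-tests
# and one-way ANOVA with Bonferroni-corrected pairwise comparisons.

#' Exact two-tailed Fisher test on a 2x2 table
#'
#' Computes the exact two-sided p-value by hypergeometric enumeration
#' with the minimum-likelihood convention (the convention of mainstream
#' statistical software): conditioning on both margins, the p-value sums
#' the point probabilities of all tables whose probability does not
#' exceed that of the observed table (within relative tolerance 1e-7).
#' Point probabilities are evaluated in log space, so extreme tables
#' (e.g. carrier counts against large population databases) do not
#' underflow.
#'
#' @param tab A [contingency_2x2()], or a numeric vector `c(a, b, c, d)`.
#' @return The two-tailed p-value.
#' @examples
#' fisher_exact_two_tailed(contingency_2x2(13, 29, 1, 49))
#' @export
fisher_exact_two_tailed <- function(tab) {
  if (is.numeric(tab) && length(tab) == 4L) {
    tab <- contingency_2x2(tab[1], tab[2], tab[3], tab[4])
  }
  stopifnot(inherits(tab, "contingency_2x2"))
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  m <- a + b          # row 1 margin
  n <- cc + d         # row 2 margin
  k <- a + cc         # column 1 margin
  if (m + n == 0L) stop("zero grand total", call. = FALSE)
  if (k == 0L || k == m + n || m == 0L || n == 0L) return(1)
  support <- max(0L, k - n):min(m, k)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  logp_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  keep <- logp <= logp_obs + log1p(1e-7)
  # sum in log space relative to the maximum kept term
  lmax <- max(logp[keep])
  p <- exp(lmax) * sum(exp(logp[keep] - lmax))
  min(p, 1)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product odds ratio `(a d) / (b c)`; when any cell is zero the
#' Haldane–Anscombe correction (0.5 added to every cell) is applied and
#' flagged in the result.
#'
#' @param tab A [contingency_2x2()].
#' @return List with `or` and `corrected` (logical).
#' @export
odds_ratio <- function(tab) {
  v <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- any(v == 0L)
  if (corrected) v <- v + 0.5
  list(or = (v[1] * v[4]) / (v[2] * v[3]), corrected = corrected)
}

#' Build the proband carrier contingency table for one variant
#'
#' One proband per case family contributes to the case margin: `a` =
#' probands with alternate dosage >= 1, `b` = probands with dosage 0.
#' The control margin is either supplied verbatim (e.g. a public
#' database's carrier counts) or, when `control = NULL`, tallied from
#' the probands of the cohort's own control (non-case) families.
#' A family whose proband genotype is missing is dropped from its margin
#' with a warning.
#'
#' @param ped A [pedigree_set()].
#' @param gm A [genotype_matrix()].
#' @param key A canonical variant key present in `gm`.
#' @param control `NULL`, or numeric `c(pos, neg)` carrier counts.
#' @param source Name recorded for the control source.
#' @return A list of class `association_result`: `table`
#'   (a [contingency_2x2()]), `p_two_tailed`, `odds_ratio`,
#'   `or_corrected`, `source`.
#' @export
build_family_table <- function(ped, gm, key, control = NULL,
                               source = if (is.null(control))
                                 "sample_controls" else "external") {
  if (!key %in% gm_keys(gm)) stop("variant ", key, " not in matrix",
                                  call. = FALSE)
  tally_probands <- function(fams) {
    pro <- vapply(fams, function(f) ped_proband(ped, f), character(1))
    pro <- pro[!is.na(pro)]
    genotyped <- pro %in% gm_samples(gm)
    d <- rep(NA_integer_, length(pro))
    d[genotyped] <- gm$dosage[key, pro[genotyped]]
    dropped <- pro[is.na(d)]
    if (length(dropped)) {
      warning("proband(s) with missing genotype dropped from table: ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    d <- d[!is.na(d)]
    c(pos = sum(d >= 1L), neg = sum(d == 0L))
  }
  case_counts <- tally_probands(ped_families(ped, "case"))
  if (is.null(control)) {
    ctl_fams <- setdiff(ped_families(ped, "control"), CONTROL_FAMILY_ID)
    ctl_counts <- tally_probands(ctl_fams)
  } else {
    ctl_counts <- c(pos = as.integer(control[1]), neg = as.integer(control[2]))
  }
  tab <- contingency_2x2(case_counts["pos"], case_counts["neg"],
                         ctl_counts["pos"], ctl_counts["neg"])
  orr <- odds_ratio(tab)
  structure(list(table = tab,
                 p_two_tailed = fisher_exact_two_tailed(tab),
                 odds_ratio = orr$or, or_corrected = orr$corrected,
                 source = source),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association vs %s: a=%d b=%d c=%d d=%d  OR=%.3g%s  p=%.3g\n",
              x$source, x$table$a, x$table$b, x$table$c, x$table$d,
              x$odds_ratio, if (x$or_corrected) " (Haldane-corrected)" else "",
              x$p_two_tailed))
  invisible(x)
}

#' Fraction of case families whose proband carries a variant
#'
#' @param ped A [pedigree_set()].
#' @param gm A [genotype_matrix()].
#' @param key A canonical variant key.
#' @return List with `carriers`, `total` (number of case families) and
#'   `percent` (nearest integer).
#' @export
carrier_fraction <- function(ped, gm, key) {
  fams <- ped_families(ped, "case")
  if (length(fams) == 0L) stop("no case families", call. = FALSE)
  pro <- vapply(fams, function(f) ped_proband(ped, f), character(1))
  genotyped <- pro %in% gm_samples(gm)
  d <- rep(NA_integer_, length(pro))
  d[genotyped] <- gm$dosage[key, pro[genotyped]]
  carriers <- sum(d >= 1L, na.rm = TRUE)
  list(carriers = carriers, total = length(fams),
       percent = round(100 * carriers / length(fams)))
}

#' Penetrance estimate at one variant
#'
#' Affected carriers divided by all genotyped carriers of known
#' phenotype, cohort-wide; carriers of unknown affection status are
#' excluded from numerator and denominator.
#'
#' @param ped A [pedigree_set()].
#' @param gm A [genotype_matrix()].
#' @param key A canonical variant key.
#' @return List with `affected_carriers`, `carriers`, `penetrance`.
#' @export
penetrance_estimate <- function(ped, gm, key) {
  s <- ped$samples
  ids <- intersect(s$sample_id, gm_samples(gm))
  d <- gm$dosage[key, ids]
  carrier_ids <- ids[!is.na(d) & d >= 1L]
  status <- s$affection[match(carrier_ids, s$sample_id)]
  carrier_ids <- carrier_ids[status != "unknown"]
  status <- status[status != "unknown"]
  if (length(carrier_ids) == 0L) {
    stop("no genotyped carriers of known phenotype at ", key, call. = FALSE)
  }
  k <- sum(status == "affected")
  list(affected_carriers = k, carriers = length(carrier_ids),
       penetrance = k / length(carrier_ids))
}

#' Two-sample t-test from raw values or summary statistics
#'
#' Pooled-variance (Student) by default, per the classical convention for
#' onset-age comparisons; Welch optionally. Accepts either raw numeric
#' vectors or summary triples `list(mean=, sd=, n=)`, so printed group
#' summaries can be re-tested directly.
#'
#' @param g1,g2 Numeric vectors of raw values, or lists with `mean`,
#'   `sd`, `n` (n >= 2).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-tailed), `mean1`, `mean2`.
#' @export
t_test_two_sample <- function(g1, g2, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  summarize <- function(g) {
    if (is.list(g)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(g)))
      if (g$n < 2) stop("group n must be >= 2", call. = FALSE)
      list(m = g$mean, s = g$sd, n = g$n)
    } else {
      if (length(g) < 2) stop("group n must be >= 2", call. = FALSE)
      list(m = mean(g), s = stats::sd(g), n = length(g))
    }
  }
  a <- summarize(g1); b <- summarize(g2)
  if (a$s == 0 && b$s == 0) {
    if (a$m == b$m) {
      return(list(t = 0, df = a$n + b$n - 2, p = 1, mean1 = a$m, mean2 = b$m))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / df
    tt <- (a$m - b$m) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se2a <- a$s^2 / a$n; se2b <- b$s^2 / b$n
    tt <- (a$m - b$m) / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 /
      (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  }
  list(t = tt, df = df, p = 2 * stats::pt(-abs(tt), df),
       mean1 = a$m, mean2 = b$m)
}

#' Compare onset ages of carriers vs non-carriers
#'
#' Splits the affected, genotyped samples with recorded onset ages by
#' carrier status at `key` and runs [t_test_two_sample()].
#'
#' @param ped A [pedigree_set()].
#' @param gm A [genotype_matrix()].
#' @param key A canonical variant key.
#' @param variant Passed to [t_test_two_sample()].
#' @return The [t_test_two_sample()] result plus `n_carrier`,
#'   `n_noncarrier`.
#' @export
onset_age_comparison <- function(ped, gm, key,
                                 variant = c("pooled", "welch")) {
  s <- ped$samples
  keep <- s$affection == "affected" & !is.na(s$onset_age) &
    s$sample_id %in% gm_samples(gm)
  s <- s[keep, , drop = FALSE]
  d <- gm$dosage[key, s$sample_id]
  carrier <- !is.na(d) & d >= 1L
  noncar <- !is.na(d) & d == 0L
  res <- t_test_two_sample(s$onset_age[carrier], s$onset_age[noncar],
                           variant = variant)
  res$n_carrier <- sum(carrier)
  res$n_noncarrier <- sum(noncar)
  res
}

#' One-way ANOVA with Bonferroni-corrected pairwise comparisons
#'
#' Standard one-way fixed-effects F-test across k groups, followed by all
#' pairwise pooled two-sample t-tests with p-values multiplied by the
#' number of pairs (capped at 1).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `F`, `df1`, `df2`, `p`, and `pairwise` (data.frame:
#'   `group1`, `group2`, `p_raw`, `p_bonferroni`).
#' @export
anova_one_way_bonferroni <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2",
                                      call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(values) == 0) {        # all observations identical
    Fv <- 0; pv <- 1
  } else {
    fit <- stats::aov(values ~ grp)
    tab <- summary(fit)[[1L]]
    Fv <- tab[["F value"]][1L]
    pv <- tab[["Pr(>F)"]][1L]
  }
  pairs <- utils::combn(names(groups), 2L)
  n_pairs <- ncol(pairs)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   p_raw = NA_real_, p_bonferroni = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    p_raw <- t_test_two_sample(groups[[pw$group1[i]]],
                               groups[[pw$group2[i]]])$p
    pw$p_raw[i] <- p_raw
    pw$p_bonferroni[i] <- min(1, p_raw * n_pairs)
  }
  list(F = Fv, df1 = k - 1L, df2 = length(values) - k, p = pv,
       pairwise = pw)
}

#' Reproduce a carrier-count association table
#'
#' Runs the exact two-tailed Fisher test of the case carrier counts
#' against each control source and formats one row per source.
#'
#' @param case_pos,case_neg Case carrier-positive / negative counts.
#' @param controls data.frame with `source`, `pos`, `neg` (see
#'   [read_count_table()]).
#' @return data.frame with columns `source`, `a`, `b`, `c`, `d`, `or`,
#'   `p` (numeric) and `p_formatted` (3 significant digits).
#' @export
association_table <- function(case_pos, case_neg, controls) {
  if (nrow(controls) == 0L) stop("no control sources", call. = FALSE)
  rows <- lapply(seq_len(nrow(controls)), function(i) {
    tab <- contingency_2x2(case_pos, case_neg, controls$pos[i],
                           controls$neg[i])
    orr <- odds_ratio(tab)
    data.frame(source = controls$source[i], a = tab$a, b = tab$b,
               c = tab$c, d = tab$d, or = orr$or,
               p = fisher_exact_two_tailed(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_formatted <- formatC(signif(out$p, 3), format = "g", digits = 3)
  out
}
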