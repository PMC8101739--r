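# Between-family relatedness screen based on the KING-robust
# moment estimator: for a sample pair (i, j), over markers called in
# both,
#   phi_hat = (N_het,het - 2 N_opp) / (2 min(N_het_i, N_het_j))
#             + 1/2 - (N_het_i + N_het_j) / (4 min(N_het_i, N_het_j))
# where N_het,het counts markers at which both samples are heterozygous,
# N_opp counts opposite homozygotes, and N_het_i / N_het_j are the
# per-sample heterozygote counts. The estimator is robust to population
# structure because it uses only observed genotype counts, never assumed
# allele frequencies. Expected values: 0.5 duplicates, 0.25 first-degree
# (parent-offspring, full sibs), 0.125 second-degree, ~0 unrelated.

# Degree boundaries used by convention to bin phi into relationship
# classes (midpoints on a log scale between 0.5, 0.25, 0.125, 0.0625).
KINSHIP_DEGREE_BOUNDS <- c(duplicate = 0.3536, first = 0.1768,
                           second = 0.0884, third = 0.0442)

# cohort minor allele frequency per marker, from observed dosages
.cohort_maf <- function(gm) {
  af <- rowMeans(gm$dosage, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' KING-robust kinship estimate for one sample pair
#'
#' @param gm A [genotype_matrix()] of biallelic markers.
#' @param i,j Sample ids.
#' @param min_markers Minimum usable markers required (default 100).
#' @param min_maf Markers with cohort minor allele frequency below this
#'   are excluded per pair (default 0.01; rare markers make the
#'   heterozygote-count denominator unstable); set 0 to disable.
#' @param maf Optional precomputed per-marker cohort MAF vector (used by
#'   [kinship_screen()] to avoid recomputation).
#' @return A list of class `kinship_result`: `sample_i`, `sample_j`,
#'   `phi`, `n_snps`, `n_het_i`, `n_het_j`, `n_hethet`, `n_opp`, and
#'   `reason` (`NA` or why `phi` is `NA`).
#' @export
king_robust_pair <- function(gm, i, j, min_markers = 100L, min_maf = 0.01,
                             maf = NULL) {
  stopifnot(i %in% gm_samples(gm), j %in% gm_samples(gm))
  gi <- gm$dosage[, i]
  gj <- gm$dosage[, j]
  ok <- !is.na(gi) & !is.na(gj)
  if (min_maf > 0) {
    if (is.null(maf)) maf <- .cohort_maf(gm)
    ok <- ok & !is.na(maf) & maf >= min_maf
  }
  gi <- gi[ok]
  gj <- gj[ok]
  n <- length(gi)
  res <- list(sample_i = i, sample_j = j, phi = NA_real_, n_snps = n,
              n_het_i = sum(gi == 1L), n_het_j = sum(gj == 1L),
              n_hethet = sum(gi == 1L & gj == 1L),
              n_opp = sum(abs(gi - gj) == 2L), reason = NA_character_)
  class(res) <- "kinship_result"
  if (n < min_markers) {
    res$reason <- sprintf("only %d usable markers (< %d)", n, min_markers)
    return(res)
  }
  mh <- min(res$n_het_i, res$n_het_j)
  if (mh == 0L) {
    res$reason <- "no heterozygous markers in one sample"
    return(res)
  }
  res$phi <- (res$n_hethet - 2 * res$n_opp) / (2 * mh) + 0.5 -
    (res$n_het_i + res$n_het_j) / (4 * mh)
  res
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf("kinship %s - %s: phi=%s over %d markers\n", x$sample_i,
              x$sample_j,
              if (is.na(x$phi)) paste0("NA (", x$reason, ")")
              else sprintf("%.4f", x$phi), x$n_snps))
  invisible(x)
}

#' Screen a cohort for cryptic between-family relatedness
#'
#' Estimates the KING-robust kinship coefficient for every cross-family
#' sample pair and flags pairs exceeding `threshold` (default 0.125, the
#' conventional cut between second- and third-degree relationships, so a
#' flag means "closer than third degree"). Within-family pairs are
#' evaluated too and returned separately as a positive control.
#'
#' @param gm A [genotype_matrix()].
#' @param ped A [pedigree_set()].
#' @param threshold Kinship coefficient above which a cross-family pair
#'   is flagged (default 0.125).
#' @param min_markers,min_maf Passed to [king_robust_pair()].
#' @return List with `cross_family` and `within_family` (data.frames:
#'   `id1`, `id2`, `fid1`, `fid2`, `n_snps`, `phi`, `flag`), `max_phi`
#'   (maximum cross-family estimate, `NA` if none defined) and
#'   `threshold`.
#' @export
kinship_screen <- function(gm, ped, threshold = 0.125, min_markers = 100L,
                           min_maf = 0.01) {
  ids <- intersect(ped$samples$sample_id, gm_samples(gm))
  fid <- ped$samples$family_id[match(ids, ped$samples$sample_id)]
  n <- length(ids)
  maf <- if (min_maf > 0) .cohort_maf(gm) else NULL
  rows <- vector("list", n * (n - 1L) / 2L)
  r <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      kr <- king_robust_pair(gm, ids[i], ids[j], min_markers = min_markers,
                             min_maf = min_maf, maf = maf)
      r <- r + 1L
      rows[[r]] <- data.frame(
        id1 = ids[i], id2 = ids[j], fid1 = fid[i], fid2 = fid[j],
        n_snps = kr$n_snps, phi = kr$phi,
        flag = !is.na(kr$phi) & kr$phi > threshold,
        stringsAsFactors = FALSE)
    }
  }
  all_pairs <- do.call(rbind, rows)
  if (is.null(all_pairs)) {
    all_pairs <- data.frame(id1 = character(0), id2 = character(0),
                            fid1 = character(0), fid2 = character(0),
                            n_snps = integer(0), phi = numeric(0),
                            flag = logical(0))
  }
  cross <- all_pairs[all_pairs$fid1 != all_pairs$fid2, , drop = FALSE]
  within <- all_pairs[all_pairs$fid1 == all_pairs$fid2, , drop = FALSE]
  max_phi <- if (nrow(cross) && any(!is.na(cross$phi))) {
    max(cross$phi, na.rm = TRUE)
  } else NA_real_
  list(cross_family = cross, within_family = within, max_phi = max_phi,
       threshold = threshold)
}
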