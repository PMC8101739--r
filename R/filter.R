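# The tiered variant-selection pipeline for multiplex families under an
# autosomal-dominant model:
#   tier 0  impact prefilter (drop LOW/MODIFIER consequence classes)
#   tier 1  within-family segregation with zygosity-state matching
#   tier 2  MAF < threshold OR CADD > threshold
#   tier 3  cross-family consistency exclusion (no unaffected carrier
#           anywhere in the cohort)
#   tier 4  prioritization by multi-family sharing and gene-set membership

#' Configuration for the tiered filter
#'
#' @param maf_threshold Keep variants with population MAF strictly below
#'   this (default 0.05); a variant with unrecorded MAF is treated as
#'   novel and passes the MAF clause.
#' @param cadd_threshold Keep variants with CADD strictly above this
#'   (default 9); unrecorded CADD fails the CADD clause.
#' @param dropped_impacts Consequence classes removed before any
#'   family-level analysis (default `LOW` and `MODIFIER`); variants with
#'   no recorded impact are retained.
#' @param min_sharing_families Families that must share a variant for the
#'   `multi_family` prioritization flag (default 2).
#' @param zygosity_strict If `TRUE` (default) all affected members of a
#'   family must carry the variant in the *same* zygosity state (all het
#'   or all hom); if `FALSE` any alternate dosage >= 1 counts as shared
#'   (recorded as het).
#' @param missing_policy `"exclude_variant"` (default): a missing call in
#'   any family member considered by the segregation rule removes the
#'   variant from that family's candidates; `"treat_as_noncarrier"`:
#'   missing calls are scored as dosage 0.
#' @param cross_family_mode `"unaffected_only"` (default): a candidate is
#'   contradicted only by carriage in an unaffected subject or
#'   independent control anywhere in the cohort;
#'   `"any_contradiction"` additionally treats a genotyped affected
#'   subject in another candidate family who does not carry the variant
#'   as a contradiction (a stricter reading that ignores genetic
#'   heterogeneity).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_threshold = 0.05,
                          cadd_threshold = 9,
                          dropped_impacts = c("LOW", "MODIFIER"),
                          min_sharing_families = 2L,
                          zygosity_strict = TRUE,
                          missing_policy = c("exclude_variant",
                                             "treat_as_noncarrier"),
                          cross_family_mode = c("unaffected_only",
                                                "any_contradiction")) {
  missing_policy <- match.arg(missing_policy)
  cross_family_mode <- match.arg(cross_family_mode)
  stopifnot(maf_threshold > 0, maf_threshold < 1, cadd_threshold >= 0,
            min_sharing_families >= 1)
  structure(list(maf_threshold = maf_threshold,
                 cadd_threshold = cadd_threshold,
                 dropped_impacts = toupper(dropped_impacts),
                 min_sharing_families = as.integer(min_sharing_families),
                 zygosity_strict = isTRUE(zygosity_strict),
                 missing_policy = missing_policy,
                 cross_family_mode = cross_family_mode),
            class = "filter_config")
}

#' Impact prefilter
#'
#' Drops variants whose annotated consequence class is in
#' `config$dropped_impacts`; variants with no recorded impact are kept.
#'
#' @param annotations A [variant_annotation()] table.
#' @param config A [filter_config()].
#' @return Character vector of retained variant keys.
#' @export
impact_prefilter <- function(annotations, config = filter_config()) {
  keep <- is.na(annotations$impact) |
    !(annotations$impact %in% config$dropped_impacts)
  unique(annotations$key[keep])
}

#' Within-family segregation filter
#'
#' Returns the variants shared by *all* affected members of one family in
#' a common zygosity state and carried by *no* unaffected member. With
#' `zygosity_strict = TRUE` the shared state must be identical across
#' affecteds (all dosage 1, state `"het"`, or all dosage 2, state
#' `"hom"`); a family mixing het and hom affected carriers does not
#' nominate the variant. Unaffected members (including any independent
#' controls assigned to the family) must have dosage 0. Members with
#' unknown affection status are ignored. Missing calls are handled per
#' `config$missing_policy`.
#'
#' @param family A samples data.frame for one family (rows of
#'   `pedigree_set$samples`, possibly with borrowed controls appended).
#' @param gm A [genotype_matrix()].
#' @param config A [filter_config()].
#' @param keys Optional subset of variant keys to consider (default all).
#' @return data.frame with columns `key`, `state` (`"het"`/`"hom"`).
#' @export
family_segregation <- function(family, gm, config = filter_config(),
                               keys = gm_keys(gm)) {
  aff_ids <- family$sample_id[family$affection == "affected"]
  una_ids <- family$sample_id[family$affection == "unaffected"]
  aff_ids <- intersect(aff_ids, gm_samples(gm))
  una_ids <- intersect(una_ids, gm_samples(gm))
  if (length(aff_ids) == 0L) {
    stop("family has no affected genotyped members", call. = FALSE)
  }
  d_aff <- gm$dosage[keys, aff_ids, drop = FALSE]
  d_una <- gm$dosage[keys, una_ids, drop = FALSE]
  if (config$missing_policy == "exclude_variant") {
    usable <- !(rowSums(is.na(d_aff)) > 0L | rowSums(is.na(d_una)) > 0L)
  } else {
    d_aff[is.na(d_aff)] <- 0L
    d_una[is.na(d_una)] <- 0L
    usable <- rep(TRUE, length(keys))
  }
  una_clear <- rowSums(d_una >= 1L, na.rm = TRUE) == 0L
  if (config$zygosity_strict) {
    all_het <- rowSums(d_aff == 1L, na.rm = TRUE) == length(aff_ids)
    all_hom <- rowSums(d_aff == 2L, na.rm = TRUE) == length(aff_ids)
    sel <- usable & una_clear & (all_het | all_hom)
    state <- ifelse(all_hom, "hom", "het")[sel]
  } else {
    all_carry <- rowSums(d_aff >= 1L, na.rm = TRUE) == length(aff_ids)
    sel <- usable & una_clear & all_carry
    state <- rep("het", sum(sel))
  }
  data.frame(key = keys[sel], state = state, stringsAsFactors = FALSE)
}

#' Frequency / deleteriousness filter
#'
#' Keeps candidates that are rare (`maf < maf_threshold`; unrecorded MAF
#' counts as rare/novel) or predicted deleterious
#' (`cadd > cadd_threshold`; unrecorded CADD fails this clause).
#'
#' @param candidates data.frame with a `key` column (e.g. output of
#'   [family_segregation()]).
#' @param annotations A [variant_annotation()] table.
#' @param config A [filter_config()].
#' @return The rows of `candidates` that pass.
#' @export
freq_impact_filter <- function(candidates, annotations,
                               config = filter_config()) {
  idx <- match(candidates$key, annotations$key)
  maf <- annotations$maf[idx]
  cadd <- annotations$cadd[idx]
  pass_maf <- is.na(maf) | maf < config$maf_threshold
  pass_cadd <- !is.na(cadd) & cadd > config$cadd_threshold
  candidates[pass_maf | pass_cadd, , drop = FALSE]
}

#' Cross-family consistency exclusion
#'
#' Pools the per-family candidate sets and removes any variant whose
#' status is contradicted elsewhere in the cohort. Under the default
#' `"unaffected_only"` mode a candidate is contradicted iff any
#' unaffected subject or independent control, in any family, carries it
#' with dosage >= 1 (missing calls do not contradict). Under
#' `"any_contradiction"` a genotyped affected subject of another
#' nominating family with dosage 0 also contradicts.
#'
#' @param per_family Named list (family id -> candidate data.frame with
#'   `key` column) as produced per family by [family_segregation()] /
#'   [freq_impact_filter()].
#' @param ped A [pedigree_set()].
#' @param gm A [genotype_matrix()].
#' @param config A [filter_config()].
#' @return Character vector of surviving variant keys (sorted).
#' @export
cross_family_exclusion <- function(per_family, ped, gm,
                                   config = filter_config()) {
  all_keys <- sort(unique(unlist(lapply(per_family, `[[`, "key"),
                                 use.names = FALSE)))
  if (length(all_keys) == 0L) return(character(0))
  s <- ped$samples
  una_ids <- s$sample_id[s$affection == "unaffected" |
                           s$is_independent_control]
  una_ids <- intersect(una_ids, gm_samples(gm))
  carried <- if (length(una_ids)) {
    rowSums(gm$dosage[all_keys, una_ids, drop = FALSE] >= 1L,
            na.rm = TRUE) > 0L
  } else rep(FALSE, length(all_keys))
  excluded <- carried
  if (config$cross_family_mode == "any_contradiction") {
    for (k in seq_along(all_keys)) {
      key <- all_keys[k]
      nominating <- names(per_family)[vapply(per_family, function(df) {
        key %in% df$key
      }, logical(1))]
      aff_other <- s$sample_id[s$affection == "affected" &
                                 s$family_id %in% nominating]
      aff_other <- intersect(aff_other, gm_samples(gm))
      # a genotyped affected member of a nominating family must carry it
      if (length(aff_other)) {
        d <- gm$dosage[key, aff_other]
        if (any(!is.na(d) & d == 0L)) excluded[k] <- TRUE
      }
    }
  }
  all_keys[!excluded]
}

#' Prioritize surviving variants
#'
#' Flags each survivor for multi-family sharing (candidate in at least
#' `min_sharing_families` families), membership of its gene in the
#' inner-ear expression set, and membership in the balance/hearing set.
#' Variants with at least one flag are "prioritized". Output is totally
#' ordered: flag count desc, number of sharing families desc, CADD desc
#' (unrecorded CADD last), then (chrom, pos, ref, alt) ascending.
#'
#' @param survivors Character vector of variant keys (from
#'   [cross_family_exclusion()]).
#' @param per_family Named list of per-family candidate data.frames.
#' @param inner_ear,balance [gene_set()] objects.
#' @param annotations A [variant_annotation()] table.
#' @param config A [filter_config()].
#' @return data.frame with columns `key`, `gene`, `n_families`,
#'   `multi_family`, `inner_ear`, `balance`, `n_flags`, `cadd`, `rank`,
#'   restricted to prioritized variants and sorted by `rank`.
#' @export
prioritize <- function(survivors, per_family, inner_ear, balance,
                       annotations, config = filter_config()) {
  empty <- data.frame(key = character(0), gene = character(0),
                      n_families = integer(0), multi_family = logical(0),
                      inner_ear = logical(0), balance = logical(0),
                      n_flags = integer(0), cadd = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (length(survivors) == 0L) return(empty)
  n_fam <- vapply(survivors, function(key) {
    sum(vapply(per_family, function(df) key %in% df$key, logical(1)))
  }, integer(1))
  idx <- match(survivors, annotations$key)
  gene <- toupper(annotations$gene[idx])
  cadd <- annotations$cadd[idx]
  multi <- n_fam >= config$min_sharing_families
  in_ear <- !is.na(gene) & gene %in% inner_ear$genes
  in_bal <- !is.na(gene) & gene %in% balance$genes
  n_flags <- multi + in_ear + in_bal
  vk <- parse_variant_key(survivors)
  out <- data.frame(key = survivors, gene = annotations$gene[idx],
                    n_families = n_fam, multi_family = multi,
                    inner_ear = in_ear, balance = in_bal,
                    n_flags = as.integer(n_flags), cadd = cadd,
                    stringsAsFactors = FALSE)
  out <- out[out$n_flags >= 1L, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  vk <- vk[match(out$key, vk$key), ]
  cadd_ord <- ifelse(is.na(out$cadd), -Inf, out$cadd)
  ord <- order(-out$n_flags, -out$n_families, -cadd_ord,
               vk$chrom, vk$pos, vk$ref, vk$alt)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full tiered variant-selection pipeline
#'
#' Applies, in order: impact prefilter, per-family segregation over every
#' case family, the MAF/CADD filter, cross-family exclusion over the
#' whole cohort, and gene-set prioritization; per-tier candidate sets and
#' counts are recorded. Case families with no unaffected genotyped
#' members borrow all independent controls as unaffected members for the
#' segregation step.
#'
#' @param gm A [genotype_matrix()].
#' @param annotations A [variant_annotation()] table covering the matrix.
#' @param ped A [pedigree_set()]; every pedigree sample that should be
#'   used must be genotyped in `gm`.
#' @param inner_ear,balance [gene_set()] objects.
#' @param config A [filter_config()].
#' @return An object of class `tier_report`: list with
#'   `per_family_candidates`, `after_freq_impact` (both named lists of
#'   data.frames), `after_cross_family` (character keys), `prioritized`
#'   (the [prioritize()] data.frame) and `counts` (named integer vector:
#'   `input`, `after_impact`, `per_family_union`, `after_freq_impact`,
#'   `after_cross_family`, `prioritized`).
#' @export
run_tiered_pipeline <- function(gm, annotations, ped, inner_ear, balance,
                                config = filter_config()) {
  s <- ped$samples
  used <- s$sample_id[s$affection != "unknown" | s$is_independent_control]
  missing_ids <- setdiff(used, gm_samples(gm))
  if (length(missing_ids)) {
    stop("pedigree sample(s) missing from genotype matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  keys0 <- impact_prefilter(annotations, config)
  keys0 <- intersect(gm_keys(gm), keys0)
  controls <- s[s$is_independent_control, , drop = FALSE]
  case_fams <- ped_families(ped, "case")
  per_family <- list()
  for (f in case_fams) {
    fam <- ped_family_members(ped, f)
    has_una <- any(fam$affection == "unaffected" &
                     fam$sample_id %in% gm_samples(gm))
    if (!has_una && nrow(controls)) {
      borrowed <- controls
      borrowed$affection <- "unaffected"
      fam <- rbind(fam, borrowed[, names(fam), drop = FALSE])
    }
    per_family[[f]] <- family_segregation(fam, gm, config, keys = keys0)
  }
  after_freq <- lapply(per_family, freq_impact_filter,
                       annotations = annotations, config = config)
  survivors <- cross_family_exclusion(after_freq, ped, gm, config)
  pri <- prioritize(survivors, after_freq, inner_ear, balance, annotations,
                    config)
  union_keys <- function(lst) {
    unique(unlist(lapply(lst, `[[`, "key"), use.names = FALSE))
  }
  counts <- c(input = nrow(annotations),
              after_impact = length(keys0),
              per_family_union = length(union_keys(per_family)),
              after_freq_impact = length(union_keys(after_freq)),
              after_cross_family = length(survivors),
              prioritized = nrow(pri))
  structure(list(per_family_candidates = per_family,
                 after_freq_impact = after_freq,
                 after_cross_family = survivors,
                 prioritized = pri,
                 counts = counts),
            class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat("tier_report\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
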