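# End-to-end orchestration: simulate (or load) a cohort, run the tiered
# filter on the discovery subset, run association / kinship / summary
# statistics, and write a report directory with a run manifest.

#' Restrict a pedigree set to selected families
#'
#' @param ped A [pedigree_set()].
#' @param families Family ids to keep.
#' @return A [pedigree_set()] with only those families.
#' @export
ped_subset <- function(ped, families) {
  keep <- ped$samples$family_id %in% families
  pedigree_set(ped$samples[keep, , drop = FALSE])
}

#' Discovery subset of a cohort's pedigree
#'
#' The tiered filter is run on the sequenced discovery cohort: the case
#' families plus the independent controls. Population-frequency control
#' families enter the association stage only (they are genotyped for the
#' candidate, not exome-filtered), mirroring how family studies split
#' discovery from replication.
#'
#' @param ped A [pedigree_set()].
#' @return A [pedigree_set()] with case families and the reserved
#'   control family.
#' @export
ped_discovery_subset <- function(ped) {
  keep <- c(ped_families(ped, "case"),
            intersect(CONTROL_FAMILY_ID, names(ped$case_status)))
  ped_subset(ped, keep)
}

#' Run the full analysis on a cohort
#'
#' Executes the tiered filter on the discovery subset (case families +
#' independent controls), then, for the top-ranked candidate (or a given
#' variant), builds the proband carrier table against the cohort's
#' control families and any external count sources, estimates carrier
#' fraction and penetrance, compares onset ages, and screens for
#' cryptic between-family relatedness. Writes `tier_report.tsv`,
#' `candidates.tsv`, `association.tsv`, `kinship.tsv`, `manifest.json`
#' and `summary.txt` under `out_dir`.
#'
#' @param gm A [genotype_matrix()].
#' @param annotations A [variant_annotation()] table.
#' @param ped A [pedigree_set()].
#' @param inner_ear,balance [gene_set()] objects.
#' @param out_dir Report directory (created if needed).
#' @param config A [filter_config()].
#' @param focus_key Variant to carry into the association stage; default
#'   the top-ranked prioritized variant (if any).
#' @param external_controls Optional data.frame `source/pos/neg` of
#'   external carrier counts (see [read_count_table()]).
#' @param kinship_threshold Passed to [kinship_screen()].
#' @param seed Recorded in the manifest.
#' @return A list of class `pipeline_result`: `report` (tier_report),
#'   `association` (data.frame), `carrier`, `penetrance`, `onset`,
#'   `kinship`, `focus_key`, `manifest`, `out_dir`; files written as a
#'   side effect.
#' @export
run_pipeline <- function(gm, annotations, ped, inner_ear, balance,
                         out_dir, config = filter_config(),
                         focus_key = NULL, external_controls = NULL,
                         kinship_threshold = 0.125, seed = NA_integer_) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  disc <- ped_discovery_subset(ped)
  report <- run_tiered_pipeline(gm, annotations, disc, inner_ear, balance,
                                config)
  if (is.null(focus_key)) {
    focus_key <- if (nrow(report$prioritized)) report$prioritized$key[1L]
                 else NA_character_
  }
  association <- NULL; carrier <- NULL; penet <- NULL; onset <- NULL
  if (!is.na(focus_key)) {
    assoc_rows <- list(build_family_table(ped, gm, focus_key,
                                          control = NULL,
                                          source = "sample_controls"))
    if (!is.null(external_controls)) {
      for (i in seq_len(nrow(external_controls))) {
        assoc_rows[[length(assoc_rows) + 1L]] <-
          build_family_table(ped, gm, focus_key,
                             control = c(external_controls$pos[i],
                                         external_controls$neg[i]),
                             source = external_controls$source[i])
      }
    }
    association <- do.call(rbind, lapply(assoc_rows, function(r) {
      data.frame(source = r$source, a = r$table$a, b = r$table$b,
                 c = r$table$c, d = r$table$d, or = r$odds_ratio,
                 p = r$p_two_tailed, stringsAsFactors = FALSE)
    }))
    carrier <- carrier_fraction(ped, gm, focus_key)
    penet <- tryCatch(penetrance_estimate(ped, gm, focus_key),
                      error = function(e) NULL)
    onset <- tryCatch(onset_age_comparison(ped, gm, focus_key),
                      error = function(e) NULL)
  }
  kin <- kinship_screen(gm, disc, threshold = kinship_threshold)

  # ---- write the report ----
  write_tier_report(report, file.path(out_dir, "tier_report.tsv"))
  if (nrow(report$prioritized)) {
    pri_ann <- annotations[match(report$prioritized$key, annotations$key), ]
    pri_ann$n_families <- report$prioritized$n_families
    pri_ann$multi_family <- report$prioritized$multi_family
    pri_ann$inner_ear <- report$prioritized$inner_ear
    pri_ann$balance <- report$prioritized$balance
    pri_ann$rank <- report$prioritized$rank
    write_candidates(pri_ann, file.path(out_dir, "candidates.tsv"))
  }
  if (!is.null(association)) {
    out_assoc <- association
    out_assoc$or <- signif(out_assoc$or, 6)
    out_assoc$p <- formatC(out_assoc$p, format = "e", digits = 5)
    names(out_assoc) <- toupper(names(out_assoc))
    utils::write.table(out_assoc, file.path(out_dir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  kin_out <- rbind(cbind(kin$cross_family, scope = "cross_family"),
                   cbind(kin$within_family, scope = "within_family"))
  if (!is.null(kin_out) && nrow(kin_out)) {
    kin_out$phi <- signif(kin_out$phi, 6)
    names(kin_out) <- toupper(names(kin_out))
    utils::write.table(kin_out, file.path(out_dir, "kinship.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    tool = "pedsift",
    version = as.character(utils::packageVersion("pedsift")),
    seed = seed,
    n_samples = ncol(gm$dosage), n_variants = nrow(gm$dosage),
    n_case_families = length(ped_families(ped, "case")),
    n_control_families = length(setdiff(ped_families(ped, "control"),
                                        CONTROL_FAMILY_ID)),
    filter_config = unclass(config),
    tier_counts = as.list(report$counts),
    focus_key = focus_key,
    kinship_threshold = kinship_threshold,
    max_cross_family_phi = kin$max_phi)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- c(
    "pedsift run summary",
    "-------------------",
    sprintf("%-20s %d", names(report$counts), report$counts),
    "",
    if (!is.na(focus_key)) sprintf("focus variant: %s", focus_key),
    if (!is.null(carrier)) sprintf(
      "carrier probands: %d of %d case families (%d%%)",
      carrier$carriers, carrier$total, carrier$percent),
    if (!is.null(penet)) sprintf(
      "penetrance: %d/%d = %.3f", penet$affected_carriers, penet$carriers,
      penet$penetrance),
    if (!is.null(association)) sprintf(
      "association vs %s: p = %.3g", association$source, association$p),
    sprintf("max cross-family kinship: %s",
            ifelse(is.na(kin$max_phi), "NA", sprintf("%.4f", kin$max_phi))))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  structure(list(report = report, association = association,
                 carrier = carrier, penetrance = penet, onset = onset,
                 kinship = kin, focus_key = focus_key, manifest = manifest,
                 out_dir = out_dir),
            class = "pipeline_result")
}

#' Simulate a cohort and run the full analysis
#'
#' Convenience wrapper: [simulate_cohort()] then [run_pipeline()], with
#' the ground-truth causal variant as the association focus.
#'
#' @param sim_config A [simulation_config()].
#' @param out_dir Report directory.
#' @param filter_cfg A [filter_config()].
#' @param external_controls Optional external count sources.
#' @return The [run_pipeline()] result, plus the cohort in `$cohort`.
#' @export
run_all_simulated <- function(sim_config, out_dir,
                              filter_cfg = filter_config(),
                              external_controls = NULL) {
  cohort <- simulate_cohort(sim_config)
  res <- run_pipeline(cohort$matrix, cohort$annotations, cohort$ped,
                      cohort$gene_sets$inner_ear, cohort$gene_sets$balance,
                      out_dir, config = filter_cfg,
                      focus_key = cohort$truth$causal_key,
                      external_controls = external_controls,
                      seed = sim_config$seed)
  res$cohort <- cohort
  res
}

#' Reproduce a published carrier-count association table
#'
#' Reads case counts and control sources from a count table whose first
#' row (source `CASE` or `BPPV`, any case) gives the case carrier
#' counts, runs the exact two-tailed Fisher test against every other
#' source, and writes/returns one formatted row per source.
#'
#' @param counts_file Path to a `SOURCE POS NEG` TSV (see
#'   [read_count_table()]).
#' @param out Optional output TSV path.
#' @return The [association_table()] data.frame.
#' @export
reproduce_association_table <- function(counts_file, out = NULL) {
  counts <- read_count_table(counts_file)
  is_case <- toupper(counts$source) %in% c("CASE", "CASES", "BPPV")
  if (sum(is_case) != 1L) {
    stop("count table must contain exactly one CASE row", call. = FALSE)
  }
  if (sum(!is_case) < 1L) stop("need at least one control source",
                               call. = FALSE)
  res <- association_table(counts$pos[is_case], counts$neg[is_case],
                           counts[!is_case, , drop = FALSE])
  if (!is.null(out)) {
    fmt <- res
    fmt$or <- signif(fmt$or, 6)
    fmt$p <- NULL
    names(fmt) <- toupper(names(fmt))
    utils::write.table(fmt, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
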