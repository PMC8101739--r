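# Pedigree gene-drop simulator. Generates cohorts with the structure the
# tiered filter assumes: multiplex case families segregating an
# autosomal-dominant variant with reduced penetrance, population-matched
# control families, and a panel of independent unrelated controls, over a
# background of unlinked exonic variants with realistic MAF / impact /
# CADD annotations. Families are ascertained the way a family study
# enrolls them: case families are redrawn until at least two members are
# affected, control families and independent controls until nobody is.

#' Simulation configuration
#'
#' Defaults emulate a familial vertigo exome study: 12 multiplex case
#' families (2-3 affected and 0-2 unaffected members sequenced each), 50
#' non-case control families, 7 independent unrelated controls, a causal
#' dominant variant with penetrance 0.95 planted as a founder
#' heterozygote in a subset of case families, onset ages near 44 +/- 14
#' years for carriers vs 54 +/- 16 for affected non-carriers, and a 2.1:1
#' female/male ratio.
#'
#' @param seed Integer RNG seed; mandatory — every run is fully
#'   deterministic given the seed.
#' @param n_case_families Multiplex case families (default 12).
#' @param n_carrier_families Case families in which the shared causal
#'   variant is planted as a founder het (default 4, about a third of
#'   case families; the other case families receive a family-private
#'   rare dominant variant, modelling genetic heterogeneity).
#' @param n_control_families Non-case families (default 50); members are
#'   ascertained unaffected and enter the association stage only.
#' @param n_independent_controls Unrelated, unaffected singleton controls
#'   in the reserved `"CTRL"` family (default 7).
#' @param n_children Range of children per nuclear family (default 2:4).
#' @param n_background_variants Background exonic variants (default 5000).
#' @param rare_fraction Fraction of background MAFs drawn from the rare
#'   component Beta(0.2, 8); the rest are common, Uniform(0.05, 0.5)
#'   (default 0.7).
#' @param impact_probs Sampling probabilities of the consequence classes
#'   `HIGH, MODERATE, LOW, MODIFIER` (default .03/.25/.30/.42).
#' @param cadd_range CADD scores drawn Uniform over this range (default
#'   `c(0, 40)`).
#' @param n_genes Size of the synthetic gene pool (default 400).
#' @param causal_maf Population frequency of the causal allele outside
#'   the designated carrier families (default 0.005).
#' @param penetrance P(affected | carrier) (default 0.95).
#' @param phenocopy_rate P(affected | non-carrier) (default 0.02).
#' @param onset_carrier,onset_noncarrier `c(mean, sd)` in years of onset
#'   age for affected carriers / affected non-carriers of the causal
#'   variant (defaults `c(44, 14)` and `c(54.4, 16.1)`).
#' @param unaffected_age `c(mean, sd)` of current age for unaffected
#'   members (default `c(66.4, 10)`; family studies require unaffected
#'   relatives to be old enough to have passed the risk window).
#' @param female_fraction P(female) per individual (default 0.68,
#'   i.e. about 2.1:1 female/male).
#' @param genotype_missing_rate,genotype_error_rate Per-call rates
#'   (defaults 0).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_case_families = 12L,
                              n_carrier_families = 4L,
                              n_control_families = 50L,
                              n_independent_controls = 7L,
                              n_children = 2:4,
                              n_background_variants = 5000L,
                              rare_fraction = 0.7,
                              impact_probs = c(HIGH = 0.03, MODERATE = 0.25,
                                               LOW = 0.30, MODIFIER = 0.42),
                              cadd_range = c(0, 40),
                              n_genes = 400L,
                              causal_maf = 0.005,
                              penetrance = 0.95,
                              phenocopy_rate = 0.02,
                              onset_carrier = c(44.0, 14.0),
                              onset_noncarrier = c(54.4, 16.1),
                              unaffected_age = c(66.4, 10.0),
                              female_fraction = 0.68,
                              genotype_missing_rate = 0,
                              genotype_error_rate = 0) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  probs <- c(causal_maf, penetrance, phenocopy_rate, female_fraction,
             genotype_missing_rate, genotype_error_rate, rare_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (penetrance < phenocopy_rate) {
    stop("penetrance must be >= phenocopy_rate", call. = FALSE)
  }
  if (n_carrier_families > n_case_families) {
    stop("n_carrier_families cannot exceed n_case_families", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_case_families = as.integer(n_case_families),
                 n_carrier_families = as.integer(n_carrier_families),
                 n_control_families = as.integer(n_control_families),
                 n_independent_controls = as.integer(n_independent_controls),
                 n_children = as.integer(n_children),
                 n_background_variants = as.integer(n_background_variants),
                 rare_fraction = rare_fraction,
                 impact_probs = impact_probs,
                 cadd_range = cadd_range,
                 n_genes = as.integer(n_genes),
                 causal_maf = causal_maf,
                 penetrance = penetrance,
                 phenocopy_rate = phenocopy_rate,
                 onset_carrier = onset_carrier,
                 onset_noncarrier = onset_noncarrier,
                 unaffected_age = unaffected_age,
                 female_fraction = female_fraction,
                 genotype_missing_rate = genotype_missing_rate,
                 genotype_error_rate = genotype_error_rate),
            class = "simulation_config")
}

# draw one founder genotype vector under Hardy-Weinberg proportions
.founder_dosage <- function(maf) stats::rbinom(length(maf), 2L, maf)

# Mendelian transmission: one allele from each parent; the probability a
# parent transmits the alternate allele is dosage / 2
.child_dosage <- function(father, mother) {
  stats::rbinom(length(father), 1L, father / 2) +
    stats::rbinom(length(mother), 1L, mother / 2)
}

#' Simulate a cohort
#'
#' Draws founder genotypes in Hardy-Weinberg proportions at every
#' variant, transmits to offspring by Mendelian gene drop, plants the
#' causal variant het in one founder of each designated carrier family,
#' assigns affection as penetrant carriage or phenocopy, ascertains
#' families (case families redrawn until >= 2 affected; control families
#' and independent controls until 0 affected), and emits the sequenced
#' subset of each family (2-3 affected plus 0-2 unaffected per case
#' family; 2-3 members per control family).
#'
#' @param config A [simulation_config()].
#' @param ascertain If `TRUE` (default), apply study-style ascertainment:
#'   case families are redrawn until multiplex, control families and
#'   independent controls until unaffected, and only a sequenced subset
#'   of each family is emitted. If `FALSE`, every family is accepted on
#'   first draw with all members emitted — the raw generative process,
#'   under which the carrier affection rate converges to the configured
#'   penetrance (ascertainment deliberately biases it upward).
#' @return A list of class `sim_cohort`: `matrix` (a
#'   [genotype_matrix()]), `ped` (a [pedigree_set()]), `annotations`,
#'   `gene_sets` (list with `inner_ear` and `balance` [gene_set()]s) and
#'   `truth` (list: `causal_key`, `causal_gene`, `carrier_samples`,
#'   `carrier_families`, `provenance` named character per sample,
#'   `founders` — sample ids that are pedigree founders, `seed`).
#' @export
simulate_cohort <- function(config, ascertain = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_bg <- config$n_background_variants
  n_var <- n_bg + 1L

  # --- variant panel -------------------------------------------------
  pos <- sort(sample.int(250000000L, n_var))
  ref <- sample(c("A", "C", "G", "T"), n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                character(1))
  causal_idx <- sample.int(n_var, 1L)
  # causal variant is an anchor-base insertion (frameshift-like)
  alt[causal_idx] <- paste0(ref[causal_idx], ref[causal_idx])

  is_rare <- stats::runif(n_var) < config$rare_fraction
  maf <- ifelse(is_rare, stats::rbeta(n_var, 0.2, 8),
                stats::runif(n_var, 0.05, 0.5))
  maf <- pmin(maf, 0.5)
  maf[causal_idx] <- config$causal_maf

  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  gene_of <- sample(genes, n_var, replace = TRUE)
  impact <- sample(names(config$impact_probs), n_var, replace = TRUE,
                   prob = config$impact_probs)
  cadd <- stats::runif(n_var, config$cadd_range[1], config$cadd_range[2])
  impact[causal_idx] <- "HIGH"
  cadd[causal_idx] <- stats::runif(1, 20, 35)
  ann <- variant_annotation("chr5", pos, ref, alt, gene = gene_of,
                            impact = impact, maf = round(maf, 6),
                            cadd = round(cadd, 2))
  causal_key <- ann$key[causal_idx]
  causal_gene <- gene_of[causal_idx]

  inner_ear <- gene_set("inner_ear",
                        unique(c(causal_gene,
                                 sample(genes, max(1L, config$n_genes %/% 10)))))
  balance <- gene_set("balance", sample(genes, max(1L, config$n_genes %/% 20)))

  # family-private causal variants for non-carrier case families:
  # rare HIGH/MODERATE background variants, one per family
  private_pool <- setdiff(
    which(maf < 0.01 & impact %in% c("HIGH", "MODERATE")), causal_idx)
  n_private <- config$n_case_families - config$n_carrier_families
  if (length(private_pool) < n_private) {
    stop("too few rare deleterious background variants to assign ",
         "family-private causal variants; increase n_background_variants",
         call. = FALSE)
  }
  private_idx <- if (n_private > 0L) sample(private_pool, n_private)
                 else integer(0)

  # --- helpers over one nuclear family -------------------------------
  draw_sex <- function(n) {
    ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  }
  affection_of <- function(carrier) {
    p <- ifelse(carrier, config$penetrance, config$phenocopy_rate)
    ifelse(stats::runif(length(p)) < p, "affected", "unaffected")
  }
  draw_family <- function(fid, plant_idx = NA_integer_) {
    nc <- if (length(config$n_children) == 1L) config$n_children
          else sample(config$n_children, 1L)
    father <- .founder_dosage(maf)
    mother <- .founder_dosage(maf)
    if (!is.na(plant_idx)) {
      if (stats::runif(1) < 0.5) father[plant_idx] <- 1L
      else mother[plant_idx] <- 1L
    }
    kids <- lapply(seq_len(nc), function(i) .child_dosage(father, mother))
    dos <- cbind(father, mother, do.call(cbind, kids))
    ids <- c(paste0(fid, "_F"), paste0(fid, "_M"),
             paste0(fid, "_C", seq_len(nc)))
    colnames(dos) <- ids
    # penetrance attaches to carriage of any causal mechanism: the shared
    # causal variant (whoever carries it) or the family-private variant
    mech_idx <- if (is.na(plant_idx)) causal_idx else plant_idx
    carrier <- dos[mech_idx, ] >= 1L | dos[causal_idx, ] >= 1L
    aff <- affection_of(carrier)
    list(fid = fid, ids = ids, dosage = dos, carrier = carrier,
         affection = aff,
         father_id = c(NA, NA, rep(ids[1L], nc)),
         mother_id = c(NA, NA, rep(ids[2L], nc)),
         sex = c("male", "female", draw_sex(nc)),
         founder = c(TRUE, TRUE, rep(FALSE, nc)))
  }

  sample_rows <- list()
  dosage_cols <- list()
  founder_flags <- character(0)
  provenance <- character(0)

  append_members <- function(fam, keep, acc) {
    idx <- match(keep, fam$ids)
    carrier_causal <- fam$dosage[causal_idx, keep] >= 1L
    aff <- fam$affection[idx]
    onset <- rep(NA_real_, length(keep))
    for (k in seq_along(keep)) {
      if (aff[k] == "affected") {
        pr <- if (carrier_causal[k]) config$onset_carrier
              else config$onset_noncarrier
        onset[k] <- round(max(18, stats::rnorm(1, pr[1], pr[2])), 1)
      }
    }
    cur <- round(pmax(onset + 5, stats::rnorm(length(keep),
                                              config$unaffected_age[1],
                                              config$unaffected_age[2]),
                      na.rm = FALSE), 1)
    cur[is.na(onset)] <- round(stats::rnorm(sum(is.na(onset)),
                                            config$unaffected_age[1],
                                            config$unaffected_age[2]), 1)
    # provenance is defined relative to the shared causal variant: an
    # affected member of a private-mechanism family who lacks it is a
    # phenocopy from the causal variant's point of view
    prov <- ifelse(carrier_causal,
                   ifelse(aff == "affected", "penetrant_carrier",
                          "nonpenetrant_carrier"),
                   ifelse(aff == "affected", "phenocopy",
                          "noncarrier_unaffected"))
    rows <- data.frame(
      sample_id = keep, family_id = fam$fid,
      father_id = ifelse(fam$father_id[idx] %in% keep, fam$father_id[idx],
                         NA_character_),
      mother_id = ifelse(fam$mother_id[idx] %in% keep, fam$mother_id[idx],
                         NA_character_),
      sex = fam$sex[idx], affection = aff,
      is_proband = FALSE, is_independent_control = FALSE,
      onset_age = onset, current_age = cur, stringsAsFactors = FALSE)
    acc$sample_rows[[length(acc$sample_rows) + 1L]] <- rows
    acc$dosage_cols[[length(acc$dosage_cols) + 1L]] <-
      fam$dosage[, keep, drop = FALSE]
    acc$founder_flags <- c(acc$founder_flags,
                           keep[fam$founder[idx]])
    pv <- prov; names(pv) <- keep
    acc$provenance <- c(acc$provenance, pv)
    acc
  }
  acc <- list(sample_rows = sample_rows, dosage_cols = dosage_cols,
              founder_flags = founder_flags, provenance = provenance)

  # --- case families -------------------------------------------------
  for (f in seq_len(config$n_case_families)) {
    fid <- sprintf("FB%03d", f)
    plant <- if (f <= config$n_carrier_families) causal_idx
             else private_idx[f - config$n_carrier_families]
    tries <- 0L
    repeat {
      fam <- draw_family(fid, plant_idx = plant)
      if (!ascertain || sum(fam$affection == "affected") >= 2L) break
      tries <- tries + 1L
      if (tries > 10000L) {
        stop("cannot ascertain a multiplex case family; penetrance/",
             "phenocopy settings make >= 2 affected members implausible",
             call. = FALSE)
      }
    }
    if (ascertain) {
      aff_ids <- fam$ids[fam$affection == "affected"]
      una_ids <- fam$ids[fam$affection == "unaffected"]
      n_aff_seq <- min(length(aff_ids), sample(2:3, 1L))
      n_una_seq <- min(length(una_ids), sample(0:2, 1L))
      keep <- c(sample(aff_ids, n_aff_seq),
                if (n_una_seq > 0L) sample(una_ids, n_una_seq))
      keep <- fam$ids[fam$ids %in% keep]      # pedigree order
    } else {
      keep <- fam$ids
    }
    acc <- append_members(fam, keep, acc)
    # proband: earliest-onset sequenced affected
    rows <- acc$sample_rows[[length(acc$sample_rows)]]
    aff_rows <- which(rows$affection == "affected")
    if (length(aff_rows)) {
      pro <- aff_rows[order(rows$onset_age[aff_rows],
                            rows$sample_id[aff_rows])][1L]
      rows$is_proband[pro] <- TRUE
      acc$sample_rows[[length(acc$sample_rows)]] <- rows
    }
  }

  # --- control families (ascertained unaffected) ---------------------
  for (f in seq_len(config$n_control_families)) {
    fid <- sprintf("CF%03d", f)
    repeat {
      fam <- draw_family(fid)
      if (!ascertain || !any(fam$affection == "affected")) break
    }
    keep <- if (ascertain) fam$ids[seq_len(min(sample(2:3, 1L),
                                               length(fam$ids)))]
            else fam$ids
    acc <- append_members(fam, keep, acc)
  }

  # --- independent controls ------------------------------------------
  if (config$n_independent_controls > 0L) {
    ids <- sprintf("%s_%02d", CONTROL_FAMILY_ID,
                   seq_len(config$n_independent_controls))
    dos <- matrix(0L, n_var, length(ids), dimnames = list(NULL, ids))
    prov <- character(length(ids))
    for (k in seq_along(ids)) {
      repeat {
        g <- .founder_dosage(maf)
        carrier <- g[causal_idx] >= 1L
        if (!ascertain || affection_of(carrier)[1L] == "unaffected") break
      }
      dos[, k] <- g
      prov[k] <- if (g[causal_idx] >= 1L) "nonpenetrant_carrier"
                 else "noncarrier_unaffected"
    }
    rows <- data.frame(
      sample_id = ids, family_id = CONTROL_FAMILY_ID,
      father_id = NA_character_, mother_id = NA_character_,
      sex = draw_sex(length(ids)), affection = "unaffected",
      is_proband = FALSE, is_independent_control = TRUE,
      onset_age = NA_real_,
      current_age = round(stats::rnorm(length(ids),
                                       config$unaffected_age[1],
                                       config$unaffected_age[2]), 1),
      stringsAsFactors = FALSE)
    acc$sample_rows[[length(acc$sample_rows) + 1L]] <- rows
    acc$dosage_cols[[length(acc$dosage_cols) + 1L]] <- dos
    acc$founder_flags <- c(acc$founder_flags, ids)
    names(prov) <- ids
    acc$provenance <- c(acc$provenance, prov)
  }

  samples <- do.call(rbind, acc$sample_rows)
  dosage <- do.call(cbind, acc$dosage_cols)

  # --- genotype noise -------------------------------------------------
  if (config$genotype_error_rate > 0) {
    err <- which(stats::runif(length(dosage)) < config$genotype_error_rate)
    if (length(err)) {
      dosage[err] <- vapply(dosage[err], function(d) {
        sample(setdiff(0:2, d), 1L)
      }, integer(1))
    }
  }
  if (config$genotype_missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < config$genotype_missing_rate] <-
      NA_integer_
  }

  gm <- genotype_matrix(dosage, ann[, c("chrom", "pos", "ref", "alt")])
  ped <- pedigree_set(samples)
  carr <- gm$dosage[causal_key, ]
  carrier_samples <- names(carr)[!is.na(carr) & carr >= 1L]
  carrier_families <- unique(samples$family_id[
    match(carrier_samples, samples$sample_id)])
  truth <- list(causal_key = causal_key, causal_gene = causal_gene,
                carrier_samples = carrier_samples,
                carrier_families = carrier_families,
                provenance = acc$provenance[samples$sample_id],
                founders = acc$founder_flags,
                seed = config$seed)
  structure(list(matrix = gm, ped = ped, annotations = ann,
                 gene_sets = list(inner_ear = inner_ear, balance = balance),
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort: causal", x$truth$causal_key, "in gene",
      x$truth$causal_gene, "\n ")
  print(x$matrix)
  print(x$ped)
  invisible(x)
}

#' Plant a contradiction: make an unaffected sample a causal carrier
#'
#' Sets the target's dosage at the causal variant to heterozygous and
#' updates the truth record, modelling an unaffected (non-penetrant)
#' carrier observed outside the case families.
#'
#' @param cohort A `sim_cohort`.
#' @param target Sample id; must exist and be unaffected.
#' @return The modified cohort.
#' @export
plant_contradiction <- function(cohort, target) {
  s <- cohort$ped$samples
  if (length(target) != 1L || !target %in% s$sample_id) {
    stop("target sample not in cohort: ", target, call. = FALSE)
  }
  if (s$affection[s$sample_id == target] != "unaffected") {
    stop("contradiction target must be unaffected: ", target, call. = FALSE)
  }
  key <- cohort$truth$causal_key
  cohort$matrix$dosage[key, target] <- 1L
  cohort$truth$carrier_samples <- union(cohort$truth$carrier_samples, target)
  fid <- s$family_id[s$sample_id == target]
  cohort$truth$carrier_families <- union(cohort$truth$carrier_families, fid)
  cohort$truth$provenance[target] <- "nonpenetrant_carrier"
  cohort
}

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf`, `cohort.ped`, `annotations.tsv`, `inner_ear.txt`,
#' `balance.txt` and `truth.json`; all parse cleanly with the package's
#' readers.
#'
#' @param cohort A `sim_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             ped = file.path(out_dir, "cohort.ped"),
             annotations = file.path(out_dir, "annotations.tsv"),
             inner_ear = file.path(out_dir, "inner_ear.txt"),
             balance = file.path(out_dir, "balance.txt"),
             truth = file.path(out_dir, "truth.json"))
  write_vcf(cohort$matrix, paths["vcf"], annotations = cohort$annotations)
  write_ped(cohort$ped, paths["ped"])
  write_candidates(cohort$annotations, paths["annotations"])
  writeLines(sort(cohort$gene_sets$inner_ear$genes), paths["inner_ear"])
  writeLines(sort(cohort$gene_sets$balance$genes), paths["balance"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Simulate a genotyped pair with a known relationship
#'
#' Gene-drop at unlinked markers with common allele frequencies, for
#' calibrating kinship estimators: `"duplicate"` (expected kinship 0.5),
#' `"parent_offspring"` (0.25), `"second_degree"`
#' (grandparent-grandchild, 0.125) or `"unrelated"` (0).
#'
#' @param relationship One of the four relationship strings.
#' @param n_markers Number of unlinked markers (default 10000).
#' @param maf_range Markers' allele frequencies drawn Uniform over this
#'   range (default `c(0.05, 0.5)`).
#' @return A [genotype_matrix()] with samples `"S1"`, `"S2"`.
#' @export
simulate_relationship_pair <- function(relationship = c("duplicate",
                                                        "parent_offspring",
                                                        "second_degree",
                                                        "unrelated"),
                                       n_markers = 10000L,
                                       maf_range = c(0.05, 0.5)) {
  relationship <- match.arg(relationship)
  maf <- stats::runif(n_markers, maf_range[1], maf_range[2])
  g1 <- .founder_dosage(maf)
  g2 <- switch(relationship,
    duplicate = g1,
    parent_offspring = .child_dosage(g1, .founder_dosage(maf)),
    second_degree = {
      parent <- .child_dosage(g1, .founder_dosage(maf))
      .child_dosage(parent, .founder_dosage(maf))
    },
    unrelated = .founder_dosage(maf))
  dos <- cbind(S1 = g1, S2 = g2)
  variants <- data.frame(chrom = "chr5", pos = seq_len(n_markers) * 10L,
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

#' Count Mendelian violations in a cohort
#'
#' For every sample whose father and/or mother is genotyped, checks that
#' the observed dosage is achievable from the parental dosages under
#' biallelic Mendelian transmission (each parent transmits 0 alleles if
#' dosage 0, 1 if dosage 2, either if heterozygous; an ungenotyped or
#' missing parent contributes 0 or 1 freely). Missing calls are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @param ped A [pedigree_set()].
#' @return Number of (variant, child) violations.
#' @export
mendelian_violations <- function(gm, ped) {
  s <- ped$samples
  total <- 0L
  contrib <- function(p) {
    # per-variant allowed alternate-allele contribution range of a parent
    if (is.null(p)) {
      list(lo = rep(0L, nrow(gm$dosage)), hi = rep(1L, nrow(gm$dosage)))
    } else {
      lo <- ifelse(is.na(p), 0L, ifelse(p == 2L, 1L, 0L))
      hi <- ifelse(is.na(p), 1L, ifelse(p == 0L, 0L, 1L))
      list(lo = lo, hi = hi)
    }
  }
  for (i in seq_len(nrow(s))) {
    fa <- s$father_id[i]; mo <- s$mother_id[i]
    fa_g <- if (!is.na(fa) && fa %in% gm_samples(gm)) gm$dosage[, fa]
    mo_g <- if (!is.na(mo) && mo %in% gm_samples(gm)) gm$dosage[, mo]
    if (is.null(fa_g) && is.null(mo_g)) next
    child <- gm$dosage[, s$sample_id[i]]
    cf <- contrib(fa_g); cm <- contrib(mo_g)
    ok <- is.na(child) |
      (child >= cf$lo + cm$lo & child <= cf$hi + cm$hi)
    total <- total + sum(!ok)
  }
  total
}
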