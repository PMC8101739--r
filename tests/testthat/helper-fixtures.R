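# In-code fixture builders and independent oracles shared across tests.

# genotype matrix from a dosage matrix literal; variants auto-named
# chr5:1000, 2000, ... with A>G alleles unless a variants df is given
make_gm <- function(dosage, variants = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(variants)) {
    variants <- data.frame(chrom = "chr5",
                           pos = 1000L * seq_len(nrow(dosage)),
                           ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
  }
  genotype_matrix(dosage, variants)
}

# one pedigree sample row with defaults
sample_row <- function(sample_id, family_id, affection = "affected",
                       father_id = NA_character_, mother_id = NA_character_,
                       sex = "female", is_proband = FALSE,
                       is_independent_control = FALSE,
                       onset_age = NA_real_, current_age = NA_real_) {
  data.frame(sample_id = sample_id, family_id = family_id,
             father_id = father_id, mother_id = mother_id, sex = sex,
             affection = affection, is_proband = is_proband,
             is_independent_control = is_independent_control,
             onset_age = onset_age, current_age = current_age,
             stringsAsFactors = FALSE)
}

make_ped <- function(...) pedigree_set(do.call(rbind, list(...)))

# default annotations for a matrix: every variant MODERATE, rare, CADD 20
make_ann <- function(gm, gene = "GENE1", impact = "MODERATE", maf = 0.001,
                     cadd = 20) {
  v <- gm$variants
  n <- nrow(v)
  variant_annotation(v$chrom, v$pos, v$ref, v$alt,
                     gene = rep_len(gene, n), impact = rep_len(impact, n),
                     maf = rep_len(maf, n), cadd = rep_len(cadd, n))
}

# ---------------------------------------------------------------------
# Independent oracle: exact two-tailed Fisher p by full enumeration with
# factorial-based point probabilities (no dhyper, no log-space trick).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(m, k)
  prob_of <- function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }
  probs <- vapply(support, prob_of, numeric(1))
  p_obs <- prob_of(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# ---------------------------------------------------------------------
# Independent oracle: brute-force re-derivation of the tier report by
# direct evaluation of the selection predicates per variant, all loops,
# no shared code with the implementation.
brute_tier_oracle <- function(gm, ann, ped, inner_ear, balance, config) {
  keys <- gm_keys(gm)
  s <- ped$samples
  dosage_of <- function(key, id) gm$dosage[key, id]
  imp <- function(key) ann$impact[match(key, ann$key)]
  keep0 <- vapply(keys, function(k) {
    i <- imp(k)
    is.na(i) || !(i %in% config$dropped_impacts)
  }, logical(1))
  keys0 <- keys[keep0]

  case_fams <- ped_families(ped, "case")
  controls <- s[s$is_independent_control, , drop = FALSE]
  per_family <- list()
  for (f in case_fams) {
    mem <- s[s$family_id == f, , drop = FALSE]
    una <- mem[mem$affection == "unaffected" &
                 mem$sample_id %in% gm_samples(gm), , drop = FALSE]
    if (nrow(una) == 0L && nrow(controls) > 0L) {
      ctl <- controls
      ctl$affection <- "unaffected"
      mem <- rbind(mem, ctl)
    }
    aff_ids <- mem$sample_id[mem$affection == "affected"]
    aff_ids <- aff_ids[aff_ids %in% gm_samples(gm)]
    una_ids <- mem$sample_id[mem$affection == "unaffected"]
    una_ids <- una_ids[una_ids %in% gm_samples(gm)]
    out_key <- character(0); out_state <- character(0)
    for (k in keys0) {
      da <- vapply(aff_ids, function(id) dosage_of(k, id), integer(1))
      du <- if (length(una_ids)) {
        vapply(una_ids, function(id) dosage_of(k, id), integer(1))
      } else integer(0)
      if (config$missing_policy == "exclude_variant") {
        if (any(is.na(da)) || any(is.na(du))) next
      } else {
        da[is.na(da)] <- 0L
        du[is.na(du)] <- 0L
      }
      if (any(du >= 1L)) next
      if (config$zygosity_strict) {
        if (all(da == 1L)) {
          out_key <- c(out_key, k); out_state <- c(out_state, "het")
        } else if (all(da == 2L)) {
          out_key <- c(out_key, k); out_state <- c(out_state, "hom")
        }
      } else if (all(da >= 1L)) {
        out_key <- c(out_key, k); out_state <- c(out_state, "het")
      }
    }
    per_family[[f]] <- data.frame(key = out_key, state = out_state,
                                  stringsAsFactors = FALSE)
  }

  after_freq <- lapply(per_family, function(df) {
    ok <- vapply(df$key, function(k) {
      i <- match(k, ann$key)
      maf <- ann$maf[i]; cadd <- ann$cadd[i]
      (is.na(maf) || maf < config$maf_threshold) ||
        (!is.na(cadd) && cadd > config$cadd_threshold)
    }, logical(1))
    df[ok, , drop = FALSE]
  })

  cand <- sort(unique(unlist(lapply(after_freq, function(df) df$key))))
  una_all <- s$sample_id[(s$affection == "unaffected" |
                            s$is_independent_control) &
                           s$sample_id %in% gm_samples(gm)]
  survivors <- character(0)
  for (k in cand) {
    bad <- FALSE
    for (id in una_all) {
      d <- dosage_of(k, id)
      if (!is.na(d) && d >= 1L) { bad <- TRUE; break }
    }
    if (!bad) survivors <- c(survivors, k)
  }

  rows <- list()
  for (k in survivors) {
    nf <- 0L
    for (f in names(after_freq)) {
      if (k %in% after_freq[[f]]$key) nf <- nf + 1L
    }
    i <- match(k, ann$key)
    g <- toupper(ann$gene[i])
    flags <- c(multi = nf >= config$min_sharing_families,
               ear = !is.na(g) && g %in% inner_ear$genes,
               bal = !is.na(g) && g %in% balance$genes)
    if (sum(flags) >= 1L) {
      rows[[length(rows) + 1L]] <- data.frame(
        key = k, n_families = nf, n_flags = sum(flags),
        cadd = ifelse(is.na(ann$cadd[i]), -Inf, ann$cadd[i]),
        chrom = ann$chrom[i], pos = ann$pos[i], ref = ann$ref[i],
        alt = ann$alt[i], stringsAsFactors = FALSE)
    }
  }
  pri <- if (length(rows)) {
    df <- do.call(rbind, rows)
    df[order(-df$n_flags, -df$n_families, -df$cadd, df$chrom, df$pos,
             df$ref, df$alt), "key"]
  } else character(0)
  list(per_family = per_family, after_freq = after_freq,
       survivors = survivors, prioritized = pri)
}

# small random cohort for oracle-equivalence tests: explicit families
# with known structure, random genotypes/annotations
random_small_cohort <- function(seed, n_fam = 4, n_var = 40) {
  set.seed(seed)
  fams <- paste0("F", seq_len(n_fam))
  rows <- list()
  for (f in fams) {
    n_aff <- sample(2:3, 1)
    n_una <- sample(0:2, 1)
    ids <- paste0(f, "_", seq_len(n_aff + n_una))
    rows[[f]] <- do.call(rbind, lapply(seq_along(ids), function(i) {
      sample_row(ids[i], f,
                 affection = if (i <= n_aff) "affected" else "unaffected")
    }))
  }
  rows$ctrl <- do.call(rbind, lapply(1:2, function(i) {
    sample_row(paste0("CTRL_", i), "CTRL", affection = "unaffected",
               is_independent_control = TRUE)
  }))
  samples <- do.call(rbind, rows)
  ped <- pedigree_set(samples)
  n_s <- nrow(samples)
  dosage <- matrix(sample(c(0L, 0L, 0L, 0L, 1L, 1L, 2L, NA_integer_),
                          n_var * n_s, replace = TRUE),
                   nrow = n_var, dimnames = list(NULL, samples$sample_id))
  gm <- make_gm(dosage)
  genes <- paste0("G", 1:12)
  ann <- variant_annotation(
    gm$variants$chrom, gm$variants$pos, gm$variants$ref, gm$variants$alt,
    gene = sample(genes, n_var, replace = TRUE),
    impact = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER", NA),
                    n_var, replace = TRUE),
    maf = ifelse(runif(n_var) < 0.2, NA, round(runif(n_var, 0, 0.4), 4)),
    cadd = ifelse(runif(n_var) < 0.2, NA, round(runif(n_var, 0, 40), 2)))
  list(gm = gm, ann = ann, ped = ped,
       inner_ear = gene_set("inner_ear", sample(genes, 4)),
       balance = gene_set("balance", sample(genes, 3)))
}
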