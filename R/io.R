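# Readers and writers for the plain-text formats the pipeline touches:
# VCF 4.2 (genotypes + optional INFO annotations), PLINK-style PED with
# named extension columns, annotation TSV, gene-set lists, carrier count
# tables, and the tier-report / candidate TSV outputs.

#' Read a VCF into a genotype matrix and annotation table
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}), splits multi-allelic records
#' into one row per alternate allele, and converts diploid GT fields to
#' alternate-allele dosages: `./.` -> `NA`, `0/0` -> 0, `0/1` -> 1,
#' `1/1` -> 2. Phased separators (`|`) are accepted and treated as
#' unphased. For split multi-allelic sites, the dosage of each alternate
#' counts only that allele, so total alternate dosage is conserved.
#' Annotations are taken from the INFO keys `GENE`, `IMPACT`, `MAF`,
#' `CADD`, `RSID` when present; absent keys yield `NA` fields.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A list with `matrix` (a [genotype_matrix()]) and `annotations`
#'   (a [variant_annotation()] table, one row per split alternate).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) stop("VCF contains no records: ", path, call. = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT genotype field: ", path,
                            call. = FALSE)
  samples <- colnames(gt_raw)
  info_get <- function(key, as_num = FALSE) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key,
                                             as.numeric = as_num))
    if (is.null(x)) rep(NA, n_rec) else x
  }
  gene <- info_get("GENE"); imp <- info_get("IMPACT")
  maf <- info_get("MAF", TRUE); cadd <- info_get("CADD", TRUE)
  rsid <- fix[, "ID"]
  rsid[rsid == "."] <- NA_character_

  # split GT strings once: alleles per sample per record
  sep_ok <- is.na(gt_raw) | grepl("^[0-9.]+[/|][0-9.]+$", gt_raw)
  if (!all(sep_ok)) {
    bad <- which(!sep_ok, arr.ind = TRUE)[1L, ]
    stop("malformed or non-diploid GT '", gt_raw[!sep_ok][1L],
         "' at record ", bad[1L], ", sample ", samples[bad[2L]],
         call. = FALSE)
  }
  a1 <- sub("[/|].*$", "", gt_raw)
  a2 <- sub("^.*[/|]", "", gt_raw)

  rows <- list(); ann_rows <- list(); r <- 0L
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    for (k in seq_along(alts)) {
      r <- r + 1L
      ak <- as.character(k)
      dos <- (a1[i, ] == ak) + (a2[i, ] == ak)
      dos[is.na(gt_raw[i, ]) | a1[i, ] == "." | a2[i, ] == "."] <- NA_integer_
      rows[[r]] <- as.integer(dos)
      ann_rows[[r]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = as.character(gene[i]), impact = as.character(imp[i]),
        maf = as.numeric(maf[i]), cadd = as.numeric(cadd[i]),
        rsid = rsid[i], stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, ann_rows)
  dosage <- do.call(rbind, rows)
  colnames(dosage) <- samples
  gm <- genotype_matrix(dosage,
                        ann[, c("chrom", "pos", "ref", "alt")])
  annotations <- variant_annotation(ann$chrom, ann$pos, ann$ref, ann$alt,
                                    gene = ann$gene, impact = ann$impact,
                                    maf = ann$maf, cadd = ann$cadd,
                                    rsid = ann$rsid)
  list(matrix = gm, annotations = annotations)
}

#' Read an extended PLINK-style PED file
#'
#' Core 6 columns `FID IID PAT MAT SEX PHENO` (tab- or space-delimited;
#' a header line starting with `FID` is accepted), with optional named
#' extension columns `PROBAND` (0/1), `ONSET_AGE`, `AGE`, `CONTROL`
#' (0/1, marks independent unrelated controls). `PHENO` 2 = affected,
#' 1 = unaffected, 0 or -9 = unknown; a parent coded `"0"` is absent.
#'
#' @param path Path to the PED file.
#' @return A [pedigree_set()].
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("no such PED file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^\\s*FID\\b", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!has_header) {
    if (ncol(df) < 6L) stop("PED needs >= 6 columns", call. = FALSE)
    base_names <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENO")
    names(df)[1:6] <- base_names
    if (ncol(df) > 6L) {
      stop("PED extension columns require a header line naming them",
           call. = FALSE)
    }
  }
  names(df) <- toupper(names(df))
  req <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENO")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("PED lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  dup <- duplicated(paste(df$FID, df$IID))
  if (any(dup)) {
    stop("duplicate IID within FID: ",
         paste(unique(paste(df$FID[dup], df$IID[dup])), collapse = "; "),
         call. = FALSE)
  }
  opt_num <- function(col) {
    if (col %in% names(df)) {
      x <- suppressWarnings(as.numeric(df[[col]]))
      x[df[[col]] %in% c("", ".", "NA", "-9")] <- NA_real_
      x
    } else rep(NA_real_, nrow(df))
  }
  opt_flag <- function(col) {
    if (col %in% names(df)) df[[col]] %in% c("1", "TRUE", "T")
    else rep(FALSE, nrow(df))
  }
  affection <- c("0" = "unknown", "1" = "unaffected", "2" = "affected",
                 "-9" = "unknown")[df$PHENO]
  if (any(is.na(affection))) {
    stop("invalid PHENO value(s): ",
         paste(unique(df$PHENO[is.na(affection)]), collapse = ", "),
         call. = FALSE)
  }
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[df$SEX]
  sex[is.na(sex)] <- "unknown"
  samples <- data.frame(
    sample_id = df$IID, family_id = df$FID,
    father_id = ifelse(df$PAT == "0", NA_character_, df$PAT),
    mother_id = ifelse(df$MAT == "0", NA_character_, df$MAT),
    sex = unname(sex), affection = unname(affection),
    is_proband = opt_flag("PROBAND"),
    is_independent_control = opt_flag("CONTROL") |
      df$FID == CONTROL_FAMILY_ID,
    onset_age = opt_num("ONSET_AGE"), current_age = opt_num("AGE"),
    stringsAsFactors = FALSE)
  if (any(samples$is_proband & samples$affection != "affected")) {
    bad <- samples$sample_id[samples$is_proband &
                               samples$affection != "affected"]
    stop("proband flagged on non-affected sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  pedigree_set(samples)
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines and `#` comments are skipped; symbols are uppercased.
#'
#' @param path Path to the list file.
#' @param name Set name; default the file stem.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such gene-set file: ", path, call. = FALSE)
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  x <- x[nzchar(x)]
  if (!length(x)) stop("gene-set file is empty: ", path, call. = FALSE)
  gene_set(name, x)
}

#' Read a carrier count table
#'
#' Tab-delimited with header `SOURCE POS NEG`: one row per control
#' source, giving carrier-positive and carrier-negative counts (e.g.
#' population-database carrier tallies).
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `source`, `pos`, `neg`.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such count table: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  miss <- setdiff(c("SOURCE", "POS", "NEG"), names(df))
  if (length(miss)) stop("count table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pos <- as.integer(df$POS); neg <- as.integer(df$NEG)
  if (any(is.na(pos)) || any(is.na(neg)) || any(pos < 0) || any(neg < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  data.frame(source = as.character(df$SOURCE), pos = pos, neg = neg,
             stringsAsFactors = FALSE)
}

#' Read a variant annotation TSV
#'
#' Header `CHROM POS REF ALT GENE IMPACT MAF CADD RSID`; empty fields,
#' `.` or `NA` denote absent values.
#'
#' @param path Path to the TSV.
#' @return A [variant_annotation()] table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = c("", ".", "NA"))
  names(df) <- toupper(names(df))
  miss <- setdiff(c("CHROM", "POS", "REF", "ALT"), names(df))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  get <- function(col) if (col %in% names(df)) df[[col]] else NA
  variant_annotation(df$CHROM, as.integer(df$POS), df$REF, df$ALT,
                     gene = get("GENE"), impact = get("IMPACT"),
                     maf = as.numeric(get("MAF")),
                     cadd = as.numeric(get("CADD")), rsid = get("RSID"))
}

#' Write a variant annotation / candidate TSV
#'
#' Serializes `CHROM POS REF ALT GENE IMPACT MAF CADD RSID` plus any
#' extra columns present (e.g. prioritization flags); loss-free for all
#' annotation fields, so [read_annotations()] on the output restores the
#' table.
#'
#' @param ann A [variant_annotation()] table (extra columns allowed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(ann, path) {
  core <- c("chrom", "pos", "ref", "alt", "gene", "impact", "maf", "cadd",
            "rsid")
  extra <- setdiff(names(ann), c(core, "key"))
  out <- ann[, c(core, extra), drop = FALSE]
  names(out) <- toupper(names(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Write a tier report as TSV
#'
#' Two sections: per-tier counts (`TIER COUNT`) and the surviving global
#' variant list per tier (`TIER KEY`). [read_tier_counts()] restores the
#' counts.
#'
#' @param report A `tier_report` from [run_tiered_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tier_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("TIER\tCOUNT", con)
  for (nm in names(report$counts)) {
    writeLines(paste(nm, report$counts[[nm]], sep = "\t"), con)
  }
  writeLines("", con)
  writeLines("TIER\tKEY", con)
  for (k in report$after_cross_family) {
    writeLines(paste("after_cross_family", k, sep = "\t"), con)
  }
  if (nrow(report$prioritized)) {
    for (i in seq_len(nrow(report$prioritized))) {
      writeLines(paste("prioritized", report$prioritized$key[i], sep = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Read tier counts back from a tier-report TSV
#'
#' @param path Path written by [write_tier_report()].
#' @return Named integer vector of per-tier counts.
#' @export
read_tier_counts <- function(path) {
  lines <- readLines(path)
  stop_at <- which(lines == "")[1L]
  if (is.na(stop_at)) stop_at <- length(lines) + 1L
  df <- utils::read.table(text = lines[seq_len(stop_at - 1L)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$COUNT), df$TIER)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' One biallelic record per variant; INFO carries `GENE/IMPACT/MAF/CADD`
#' when annotations are supplied; genotypes are unphased GT dosages.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param annotations Optional [variant_annotation()] table matched by key.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, annotations = NULL) {
  v <- gm$variants
  n <- nrow(v)
  info <- rep(".", n)
  rsid <- rep(".", n)
  if (!is.null(annotations)) {
    idx <- match(v$key, annotations$key)
    fmt_num <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE,
                                                       scientific = FALSE,
                                                       digits = 15))
    parts <- cbind(
      ifelse(is.na(annotations$gene[idx]), NA,
             paste0("GENE=", annotations$gene[idx])),
      ifelse(is.na(annotations$impact[idx]), NA,
             paste0("IMPACT=", annotations$impact[idx])),
      ifelse(is.na(annotations$maf[idx]), NA,
             paste0("MAF=", fmt_num(annotations$maf[idx]))),
      ifelse(is.na(annotations$cadd[idx]), NA,
             paste0("CADD=", fmt_num(annotations$cadd[idx]))))
    info <- apply(parts, 1L, function(p) {
      p <- p[!is.na(p)]
      if (length(p)) paste(p, collapse = ";") else "."
    })
    rs <- annotations$rsid[idx]
    rsid <- ifelse(is.na(rs), ".", rs)
  }
  gt <- matrix(c("0/0", "0/1", "1/1")[gm$dosage + 1L], nrow = n)
  gt[is.na(gm$dosage)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm_samples(gm)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, rsid, v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a pedigree set as an extended PED file
#'
#' Emits the PLINK 6-column core plus named extension columns `PROBAND`,
#' `ONSET_AGE`, `AGE`, `CONTROL`, with a header line.
#'
#' @param ped A [pedigree_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  s <- ped$samples
  df <- data.frame(
    FID = s$family_id, IID = s$sample_id,
    PAT = ifelse(is.na(s$father_id), "0", s$father_id),
    MAT = ifelse(is.na(s$mother_id), "0", s$mother_id),
    SEX = c(female = "2", male = "1", unknown = "0")[s$sex],
    PHENO = c(affected = "2", unaffected = "1", unknown = "0")[s$affection],
    PROBAND = as.integer(s$is_proband),
    ONSET_AGE = ifelse(is.na(s$onset_age), ".", format(s$onset_age,
                                                       trim = TRUE)),
    AGE = ifelse(is.na(s$current_age), ".", format(s$current_age,
                                                   trim = TRUE)),
    CONTROL = as.integer(s$is_independent_control),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
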