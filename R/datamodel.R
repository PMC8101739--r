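# Reserved family id that holds independent (unrelated) controls.
CONTROL_FAMILY_ID <- "CTRL"

#' Canonical variant identifiers
#'
#' A variant is identified by its chromosome, 1-based position, reference
#' allele and a single alternate allele (multi-allelic records are split
#' before any analysis). The canonical string form `chrom:pos:ref:alt` is
#' used as a key throughout the package.
#'
#' @param chrom Chromosome label(s).
#' @param pos 1-based position(s), integer.
#' @param ref,alt Reference / single alternate allele strings over
#'   `{A,C,G,T}` (indels in VCF style, with anchor base).
#' @return Character vector of canonical keys.
#' @examples
#' variant_key("chr5", 1000, "A", "AA")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    stop("ref/alt alleles must be non-empty strings over {A,C,G,T}; bad: ",
         paste(paste0(ref[bad], ">", alt[bad]), collapse = ", "),
         call. = FALSE)
  }
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Split a canonical variant key back into its fields
#'
#' @param key Character vector of `chrom:pos:ref:alt` keys.
#' @return A data.frame with columns `chrom`, `pos`, `ref`, `alt`, `key`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("malformed variant key(s): ",
         paste(key[lengths(parts) != 4L], collapse = ", "), call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]), ref = m[, 3L],
             alt = m[, 4L], key = key, stringsAsFactors = FALSE)
}

#' Construct a genotype matrix
#'
#' Allele dosages (0, 1, 2 alternate-allele copies; `NA` = missing call)
#' for every (variant, sample) pair, stored as an integer matrix with
#' variants in rows and samples in columns.
#'
#' @param dosage Integer matrix, variants x samples, entries in
#'   `{0, 1, 2, NA}`.
#' @param variants A data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (a `key` column is added if absent); one row per matrix row.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (row names = keys, col names = sample ids) and `variants`.
#' @export
genotype_matrix <- function(dosage, variants) {
  if (!("key" %in% names(variants))) {
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(variants)) {
    stop("dosage rows (", nrow(dosage), ") != variants (", nrow(variants), ")",
         call. = FALSE)
  }
  if (anyDuplicated(variants$key)) {
    stop("duplicate variant keys: ",
         paste(unique(variants$key[duplicated(variants$key)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(dosage))) stop("dosage must have sample column names")
  if (anyDuplicated(colnames(dosage))) stop("duplicate sample ids")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  rownames(dosage) <- variants$key
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "variants x",
      ncol(x$dosage), "samples;",
      sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Sample ids of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of sample ids (column order).
#' @export
gm_samples <- function(x) colnames(x$dosage)

#' Variant keys of a genotype matrix
#' @param x A `genotype_matrix`.
#' @return Character vector of canonical variant keys (row order).
#' @export
gm_keys <- function(x) rownames(x$dosage)

#' Construct a pedigree set
#'
#' Holds per-sample pedigree and phenotype information for a cohort of
#' families, plus each family's case status. Families whose members are
#' independent unrelated controls live in the reserved family
#' `"CTRL"`.
#'
#' @param samples A data.frame with columns `sample_id`, `family_id`,
#'   `father_id`, `mother_id` (`NA` = unknown), `sex`
#'   (`"female"|"male"|"unknown"`), `affection`
#'   (`"affected"|"unaffected"|"unknown"`), `is_proband`,
#'   `is_independent_control` (logicals), `onset_age`, `current_age`
#'   (years, `NA` allowed).
#' @return An object of class `pedigree_set`: list with `samples` and
#'   `case_status` (named character, family id -> `"case"`/`"control"`;
#'   a family is a case family iff it has at least one affected member
#'   and is not the reserved control family).
#' @export
pedigree_set <- function(samples) {
  req <- c("sample_id", "family_id", "father_id", "mother_id", "sex",
           "affection", "is_proband", "is_independent_control",
           "onset_age", "current_age")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad_pro <- samples$is_proband & samples$affection != "affected"
  if (any(bad_pro)) {
    stop("proband flag on non-affected sample(s): ",
         paste(samples$sample_id[bad_pro], collapse = ", "), call. = FALSE)
  }
  npro <- tapply(samples$is_proband, samples$family_id, sum)
  if (any(npro > 1L)) {
    stop("more than one proband in family: ",
         paste(names(npro)[npro > 1L], collapse = ", "), call. = FALSE)
  }
  bad_onset <- !is.na(samples$onset_age) & samples$affection != "affected"
  if (any(bad_onset)) {
    stop("onset_age recorded for non-affected sample(s): ",
         paste(samples$sample_id[bad_onset], collapse = ", "), call. = FALSE)
  }
  # parent references must resolve within the family or be absent
  # (a named parent absent from the table entirely is allowed: ungenotyped)
  within_fam <- paste(samples$family_id, samples$sample_id)
  for (p in c("father_id", "mother_id")) {
    ref <- samples[[p]]
    in_other <- !is.na(ref) & ref %in% samples$sample_id &
      !(paste(samples$family_id, ref) %in% within_fam)
    if (any(in_other)) {
      stop(p, " of ", paste(samples$sample_id[in_other], collapse = ", "),
           " resolves outside the family", call. = FALSE)
    }
  }
  fams <- unique(samples$family_id)
  has_aff <- vapply(fams, function(f) {
    any(samples$affection[samples$family_id == f] == "affected")
  }, logical(1))
  status <- ifelse(has_aff & fams != CONTROL_FAMILY_ID, "case", "control")
  names(status) <- fams
  structure(list(samples = samples, case_status = status),
            class = "pedigree_set")
}

#' @export
print.pedigree_set <- function(x, ...) {
  cat("pedigree_set:", length(x$case_status), "families (",
      sum(x$case_status == "case"), "case /",
      sum(x$case_status == "control"), "control ),",
      nrow(x$samples), "samples\n")
  invisible(x)
}

#' Family ids of a pedigree set, optionally by case status
#' @param ped A `pedigree_set`.
#' @param status `"case"`, `"control"`, or `NULL` for all families.
#' @return Character vector of family ids.
#' @export
ped_families <- function(ped, status = NULL) {
  f <- names(ped$case_status)
  if (is.null(status)) f else f[ped$case_status == status]
}

#' Members of one family
#' @param ped A `pedigree_set`.
#' @param family_id One family id.
#' @return The samples data.frame restricted to that family.
#' @export
ped_family_members <- function(ped, family_id) {
  ped$samples[ped$samples$family_id == family_id, , drop = FALSE]
}

#' Designate the proband of a family
#'
#' Selection order: the explicit proband flag; else the affected member
#' with the earliest onset age; else the lexicographically first affected
#' member; else (families with no affected members, e.g. control
#' families) the lexicographically first member.
#'
#' @param ped A `pedigree_set`.
#' @param family_id One family id.
#' @return A single sample id, or `NA_character_` for an empty family.
#' @export
ped_proband <- function(ped, family_id) {
  mem <- ped_family_members(ped, family_id)
  if (nrow(mem) == 0L) return(NA_character_)
  if (any(mem$is_proband)) return(mem$sample_id[mem$is_proband][1L])
  aff <- mem[mem$affection == "affected", , drop = FALSE]
  if (nrow(aff)) {
    if (any(!is.na(aff$onset_age))) {
      return(aff$sample_id[order(aff$onset_age, aff$sample_id)][1L])
    }
    return(sort(aff$sample_id)[1L])
  }
  sort(mem$sample_id)[1L]
}

#' Construct a variant annotation table
#'
#' One row per (variant, gene): functional impact class, population minor
#' allele frequency, CADD deleteriousness score and dbSNP id. Absent
#' values are `NA`.
#'
#' @param chrom,pos,ref,alt Variant identity (see [variant_key()]).
#' @param gene Gene symbol (`NA` allowed).
#' @param impact One of `HIGH`, `MODERATE`, `LOW`, `MODIFIER`, or `NA`.
#' @param maf Minor allele frequency in `[0, 1]` or `NA` (unobserved /
#'   novel allele).
#' @param cadd CADD score `>= 0` or `NA`.
#' @param rsid dbSNP identifier or `NA`.
#' @return A data.frame of class `variant_annotation` keyed by `key`.
#' @export
variant_annotation <- function(chrom, pos, ref, alt, gene = NA_character_,
                               impact = NA_character_, maf = NA_real_,
                               cadd = NA_real_, rsid = NA_character_) {
  key <- variant_key(chrom, pos, ref, alt)
  impact <- toupper(as.character(impact))
  ok_imp <- is.na(impact) | impact %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")
  if (!all(ok_imp)) {
    stop("invalid impact class(es): ",
         paste(unique(impact[!ok_imp]), collapse = ", "), call. = FALSE)
  }
  maf <- as.numeric(maf)
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    stop("maf must lie in [0, 1]", call. = FALSE)
  }
  cadd <- as.numeric(cadd)
  if (any(!is.na(cadd) & cadd < 0)) stop("cadd must be >= 0", call. = FALSE)
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                    key = key, gene = as.character(gene), impact = impact,
                    maf = maf, cadd = cadd, rsid = as.character(rsid),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_annotation", "data.frame")
  out
}

#' Construct a named gene set
#'
#' @param name Set name (e.g. `"inner_ear"`).
#' @param genes Character vector of gene symbols; uppercased and
#'   deduplicated on construction.
#' @return A list of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(trimws(as.character(genes))))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' Construct a 2x2 carrier contingency table
#'
#' Layout: `a` = case carriers, `b` = case non-carriers, `c` = control
#' carriers, `d` = control non-carriers.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (sum(v) == 0) stop("contingency table has zero grand total", call. = FALSE)
  structure(stats::setNames(as.list(as.integer(v)), c("a", "b", "c", "d")),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("carrier", "non-carrier")))
  print(m)
  invisible(x)
}
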