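# Reading/writing the three external formats (scoring file, genotype dosages,
# phenotype table) and allele harmonization.

#' Read a PGS-Catalog-style variant scoring file
#'
#' Parses a tab-separated scoring file with one row per scored variant.
#' Lines starting with `#` are treated as comments and skipped. Mandatory
#' columns are `rsID`, `chr_name`, `chr_position`, `effect_allele`,
#' `other_allele` and `effect_weight`; an optional `imputation_r2` column
#' (squared correlation between imputed and true genotypes) is carried as
#' metadata. Alleles are upper-cased; row order is preserved.
#'
#' @param path Path to the scoring file.
#' @param r2_filter If `TRUE`, drop variants with `imputation_r2 <= 0.30`.
#'   Off by default: quality filtering normally happens upstream, at
#'   imputation time.
#' @return A data frame of class `grs_weights` with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `effect_weight` and (if present in the file) `imputation_r2`.
#' @export
read_score_file <- function(path, r2_filter = FALSE) {
  if (!file.exists(path)) stop("scoring file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("scoring file has no content: ", path)
  line_no <- which(keep)
  hdr <- strsplit(lines[line_no[1]], "\t", fixed = TRUE)[[1]]
  synonyms <- list(
    variant_id    = c("rsID", "rsid", "variant_id", "ID", "id"),
    chromosome    = c("chr_name", "chromosome", "chr", "CHROM"),
    position      = c("chr_position", "position", "pos", "POS"),
    effect_allele = c("effect_allele", "A1", "ALT"),
    other_allele  = c("other_allele", "reference_allele", "A2", "REF"),
    effect_weight = c("effect_weight", "weight", "beta")
  )
  col_idx <- vapply(synonyms, function(s) {
    i <- which(hdr %in% s)
    if (length(i) == 0L) NA_integer_ else i[1]
  }, integer(1))
  if (anyNA(col_idx)) {
    stop("scoring file format error: missing mandatory column(s): ",
         paste(names(col_idx)[is.na(col_idx)], collapse = ", "))
  }
  r2_idx <- which(hdr %in% c("imputation_r2", "r2", "info"))
  data_lines <- line_no[-1]
  n <- length(data_lines)
  out <- data.frame(
    variant_id = character(n), chromosome = character(n),
    position = integer(n), effect_allele = character(n),
    other_allele = character(n), effect_weight = numeric(n),
    stringsAsFactors = FALSE
  )
  if (length(r2_idx)) out$imputation_r2 <- NA_real_
  for (i in seq_len(n)) {
    f <- strsplit(lines[data_lines[i]], "\t", fixed = TRUE)[[1]]
    w <- suppressWarnings(as.numeric(f[col_idx["effect_weight"]]))
    if (is.na(w)) {
      stop("scoring file parse error: non-numeric effect_weight on line ",
           data_lines[i])
    }
    pos <- suppressWarnings(as.integer(f[col_idx["position"]]))
    if (is.na(pos) || pos < 1) {
      stop("scoring file parse error: invalid position on line ", data_lines[i])
    }
    out$variant_id[i]    <- f[col_idx["variant_id"]]
    out$chromosome[i]    <- f[col_idx["chromosome"]]
    out$position[i]      <- pos
    out$effect_allele[i] <- toupper(f[col_idx["effect_allele"]])
    out$other_allele[i]  <- toupper(f[col_idx["other_allele"]])
    out$effect_weight[i] <- w
    if (length(r2_idx) && length(f) >= r2_idx[1]) {
      out$imputation_r2[i] <- suppressWarnings(as.numeric(f[r2_idx[1]]))
    }
  }
  bad <- out$effect_allele == out$other_allele
  if (any(bad)) {
    stop("scoring file format error: effect allele equals other allele for ",
         paste(out$variant_id[bad], collapse = ", "))
  }
  if (r2_filter && !is.null(out$imputation_r2)) {
    out <- out[is.na(out$imputation_r2) | out$imputation_r2 > 0.30, ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("grs_weights", "data.frame")
  out
}

#' Write a scoring file readable by [read_score_file()]
#'
#' @param weights A `grs_weights` data frame.
#' @param path Output path.
#' @export
write_score_file <- function(weights, path) {
  cols <- c(rsID = "variant_id", chr_name = "chromosome",
            chr_position = "position", effect_allele = "effect_allele",
            other_allele = "other_allele", effect_weight = "effect_weight")
  df <- as.data.frame(weights)[, cols]
  names(df) <- names(cols)
  if (!is.null(weights$imputation_r2)) df$imputation_r2 <- weights$imputation_r2
  df$effect_weight <- format(df$effect_weight, digits = 17, trim = TRUE,
                             scientific = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_dosage_matrix <- function(dosages, sample_ids, variant_ids,
                              ref = NULL, alt = NULL,
                              missing_variants = character(0),
                              exclusions = NULL) {
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == length(variant_ids))
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosage values outside [0, 2]")
  }
  dimnames(dosages) <- list(sample_ids, variant_ids)
  structure(
    list(dosages = dosages, sample_ids = sample_ids,
         variant_ids = variant_ids,
         ref = ref %||% rep(NA_character_, length(variant_ids)),
         alt = alt %||% rep(NA_character_, length(variant_ids)),
         missing_variants = missing_variants,
         exclusions = exclusions %||%
           data.frame(variant_id = character(0), reason = character(0))),
    class = "dosage_matrix"
  )
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("<dosage_matrix> ", length(x$sample_ids), " samples x ",
      length(x$variant_ids), " variants\n", sep = "")
  if (length(x$missing_variants)) {
    cat("  absent wanted variants:",
        paste(x$missing_variants, collapse = ", "), "\n")
  }
  if (nrow(x$exclusions)) {
    cat("  excluded:", nrow(x$exclusions), "variant(s)\n")
  }
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$dosages)

#' Read effect-allele dosages for a set of wanted variants
#'
#' Reads genotype dosages from a VCF (the `DS` FORMAT field when present,
#' otherwise hard-call `GT` converted to 0/1/2 ALT-allele counts) or from a
#' plain tab-separated matrix with one sample per row (first column
#' `sample_id`, remaining columns named by variant ID). Dosages count the
#' ALT allele as written in the file; alignment to effect alleles is a
#' separate step ([harmonize_alleles()]).
#'
#' Wanted variants are matched first by ID, then by chromosome:position with
#' an identical allele set. Wanted variants absent from the file are recorded
#' in `missing_variants`; if none are found the call fails.
#'
#' @param path Path to a VCF (`.vcf`) or dosage TSV.
#' @param wanted A `grs_weights` data frame naming the variants to extract.
#' @return A `dosage_matrix` object.
#' @export
read_dosages <- function(path, wanted) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  first <- readLines(path, n = 1L)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", path) || grepl("^##fileformat=VCF", first)
  dm <- if (is_vcf) read_dosages_vcf(path, wanted) else
    read_dosages_tsv(path, wanted)
  if (length(dm$variant_ids) == 0L) {
    stop("none of the ", nrow(wanted), " wanted variants found in ", path)
  }
  dm
}

read_dosages_vcf <- function(path, wanted) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  chrpos <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  hit <- integer(0)
  found_wanted <- integer(0)
  for (i in seq_len(nrow(wanted))) {
    j <- which(ids == wanted$variant_id[i])
    if (length(j) == 0L) {
      j <- which(chrpos == paste0(wanted$chromosome[i], ":",
                                  wanted$position[i]))
      if (length(j)) {
        ok <- vapply(j, function(jj) {
          setequal(c(fix[jj, "REF"], fix[jj, "ALT"]),
                   c(wanted$effect_allele[i], wanted$other_allele[i]))
        }, logical(1))
        j <- j[ok]
      }
    }
    if (length(j)) {
      hit <- c(hit, j[1])
      found_wanted <- c(found_wanted, i)
    }
  }
  missing <- wanted$variant_id[setdiff(seq_len(nrow(wanted)), found_wanted)]
  if (length(hit) == 0L) {
    return(new_dosage_matrix(matrix(numeric(0), 0, 0), character(0),
                             character(0), missing_variants = missing))
  }
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt[hit]))
  if (has_ds) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles != "0")
    })
  }
  d <- d[hit, , drop = FALSE]
  dosages <- t(d)
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("malformed dosage at ", chrpos[hit[bad[1, 2]]],
         ": value outside [0, 2]")
  }
  new_dosage_matrix(
    dosages, sample_ids = colnames(d),
    variant_ids = wanted$variant_id[found_wanted],
    ref = unname(fix[hit, "REF"]), alt = unname(fix[hit, "ALT"]),
    missing_variants = missing
  )
}

read_dosages_tsv <- function(path, wanted) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") {
    stop("dosage TSV must have 'sample_id' as its first column")
  }
  found <- which(wanted$variant_id %in% names(tab))
  missing <- wanted$variant_id[setdiff(seq_len(nrow(wanted)), found)]
  if (length(found) == 0L) {
    return(new_dosage_matrix(matrix(numeric(0), 0, 0), character(0),
                             character(0), missing_variants = missing))
  }
  d <- as.matrix(tab[, wanted$variant_id[found], drop = FALSE])
  storage.mode(d) <- "double"
  # TSV carries no REF/ALT metadata: alleles are taken from the weights so
  # a TSV matrix is, by convention, already effect-allele coded.
  new_dosage_matrix(
    d, sample_ids = as.character(tab$sample_id),
    variant_ids = wanted$variant_id[found],
    ref = wanted$other_allele[found], alt = wanted$effect_allele[found],
    missing_variants = missing
  )
}

#' Write a dosage matrix as the TSV dialect read by [read_dosages()]
#' @param dm A `dosage_matrix`.
#' @param path Output path.
#' @export
write_dosages <- function(dm, path) {
  df <- data.frame(sample_id = dm$sample_ids, dm$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align dosages to the effect alleles of a scoring file
#'
#' For each variant: if the file ALT equals the effect allele the dosage is
#' kept; if the file REF equals the effect allele (and ALT the other allele)
#' the dosage is flipped to `2 - d`; strand-ambiguous palindromic pairs
#' (A/T, C/G) are dropped by default because strand cannot be resolved
#' without frequency-based inference; any other allele configuration is
#' dropped as unresolvable. All exclusions are recorded with a reason.
#' The output columns follow the order of the surviving weights.
#'
#' @param dm A `dosage_matrix` whose `ref`/`alt` fields describe the source
#'   file coding.
#' @param weights The `grs_weights` the matrix should be aligned to.
#' @param drop_palindromic Drop A/T and C/G variants (default `TRUE`).
#' @return A list with `dosages` (an aligned `dosage_matrix`), `weights`
#'   (the surviving rows of `weights`, in matrix column order) and
#'   `exclusions` (a data frame of dropped variants and reasons).
#' @export
harmonize_alleles <- function(dm, weights, drop_palindromic = TRUE) {
  idx <- match(dm$variant_ids, weights$variant_id)
  if (anyNA(idx)) {
    stop("variants in dosage matrix absent from weights: ",
         paste(dm$variant_ids[is.na(idx)], collapse = ", "))
  }
  w <- weights[idx, , drop = FALSE]
  n_var <- length(dm$variant_ids)
  keep <- logical(n_var)
  flip <- logical(n_var)
  reason <- character(n_var)
  for (i in seq_len(n_var)) {
    ea <- w$effect_allele[i]; oa <- w$other_allele[i]
    ref <- dm$ref[i]; alt <- dm$alt[i]
    if (drop_palindromic && is_palindromic(ea, oa)) {
      reason[i] <- "palindromic"
    } else if (!is.na(alt) && alt == ea && (is.na(ref) || ref == oa)) {
      keep[i] <- TRUE
    } else if (!is.na(ref) && ref == ea && (is.na(alt) || alt == oa)) {
      keep[i] <- TRUE; flip[i] <- TRUE
    } else {
      reason[i] <- "allele_mismatch"
    }
  }
  d <- dm$dosages[, keep, drop = FALSE]
  if (any(flip[keep])) {
    fl <- flip[keep]
    d[, fl] <- 2 - d[, fl]
  }
  exclusions <- data.frame(
    variant_id = dm$variant_ids[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE
  )
  out <- new_dosage_matrix(
    d, sample_ids = dm$sample_ids, variant_ids = dm$variant_ids[keep],
    ref = w$other_allele[keep], alt = w$effect_allele[keep],
    missing_variants = dm$missing_variants,
    exclusions = rbind(dm$exclusions, exclusions)
  )
  list(dosages = out, weights = w[keep, , drop = FALSE],
       exclusions = exclusions)
}

pheno_columns <- c(
  "sample_id", "cad_case", "stenosis_lad_pct", "stenosis_rca_pct",
  "calc_lad_pct", "calc_rca_pct", "age", "sex", "bmi", "sbp",
  "total_chol", "hdl_chol", "smoking", "htn_med", "statin"
)
pct_columns <- c("stenosis_lad_pct", "stenosis_rca_pct",
                 "calc_lad_pct", "calc_rca_pct")

#' Read a phenotype/covariate table
#'
#' Reads a CSV or TSV with one row per sample. Column names can be remapped
#' via `mapping` (a named list or the path to a YAML file) whose entries are
#' `canonical_name: file_column_name`; a `sex_labels` entry with `male`/
#' `female` sub-entries declares how sex is coded in the file. Empty strings
#' and `"NA"` are read as missing. Percentages are validated against
#' \[0, 100\] and duplicate sample IDs are an error.
#'
#' @param path Path to the phenotype file (delimiter inferred: `.csv` comma,
#'   otherwise tab).
#' @param mapping Optional column mapping (named list or YAML file path).
#' @return A data frame of class `cohort_table` with the canonical columns
#'   (`sample_id`, `cad_case`, stenosis/calcification percentages, `age`,
#'   `sex`, `bmi`, `sbp`, `total_chol`, `hdl_chol`, `smoking`, `htn_med`,
#'   `statin`); columns absent from the file are filled with `NA`.
#' @export
read_phenotypes <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- yaml::read_yaml(mapping)
  }
  sex_labels <- mapping$sex_labels %||% list(male = "male", female = "female")
  mapping$sex_labels <- NULL
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (canon in names(mapping)) {
    if (!mapping[[canon]] %in% names(raw)) {
      stop("mapped column '", mapping[[canon]], "' not found in ", path)
    }
    names(raw)[names(raw) == mapping[[canon]]] <- canon
  }
  if (!"sample_id" %in% names(raw)) {
    stop("phenotype file lacks a sample_id column (after mapping)")
  }
  out <- data.frame(sample_id = as.character(raw$sample_id),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample_id in phenotype file: ",
         out$sample_id[duplicated(out$sample_id)][1])
  }
  for (col in setdiff(pheno_columns, "sample_id")) {
    if (col %in% names(raw)) {
      if (col == "sex") {
        s <- as.character(raw$sex)
        sex <- rep(NA_character_, length(s))
        sex[s %in% as.character(sex_labels$male)] <- "male"
        sex[s %in% as.character(sex_labels$female)] <- "female"
        bad <- !is.na(s) & is.na(sex)
        if (any(bad)) {
          stop("unrecognized sex label '", s[bad][1], "' for sample ",
               out$sample_id[bad][1])
        }
        out$sex <- sex
      } else {
        out[[col]] <- as.numeric(raw[[col]])
      }
    } else {
      out[[col]] <- if (col == "sex") NA_character_ else NA_real_
    }
  }
  for (col in pct_columns) {
    bad <- !is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 100)
    if (any(bad)) {
      stop("percentage out of [0, 100] in column ", col, " for sample ",
           out$sample_id[bad][1])
    }
  }
  for (col in c("cad_case", "smoking", "htn_med", "statin")) {
    bad <- !is.na(out[[col]]) & !out[[col]] %in% c(0, 1)
    if (any(bad)) {
      stop("non-binary value in column ", col, " for sample ",
           out$sample_id[bad][1])
    }
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write a phenotype table read back identically by [read_phenotypes()]
#' @param cohort A `cohort_table`.
#' @param path Output path (`.csv` or `.tsv`).
#' @export
write_phenotypes <- function(cohort, path) {
  df <- as.data.frame(cohort)[, pheno_columns]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 17, trim = TRUE,
                                scientific = FALSE)))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Label CAD cases from stenosis percentages
#'
#' A sample is a case when the maximum available stenosis percentage across
#' the LAD and RCA columns is greater than or equal to `threshold_pct`
#' (inclusive: "50 % or more"). Samples with all stenosis values missing
#' keep a missing case label.
#'
#' @param cohort A `cohort_table`.
#' @param threshold_pct Stenosis threshold in percent (default 50).
#' @return The cohort with `cad_case` filled from stenosis.
#' @export
define_cad_cases <- function(cohort, threshold_pct = 50) {
  sten <- cbind(cohort$stenosis_lad_pct, cohort$stenosis_rca_pct)
  any_obs <- rowSums(!is.na(sten)) > 0
  mx <- suppressWarnings(apply(sten, 1, max, na.rm = TRUE))
  cohort$cad_case <- ifelse(any_obs, as.numeric(mx >= threshold_pct),
                            NA_real_)
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
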