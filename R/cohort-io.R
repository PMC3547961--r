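#' Visit and genotype tables
#'
#' The package works on two plain tables: a long-format visit table (one row
#' per BMI measurement, columns `subject_id`, `sex`, `age_years`, `bmi`) and a
#' genotype dosage table (`subject_id` plus one 0/1/2 risk-allele dosage column
#' per SNP). Both are ordinary data frames; the visit table carries class
#' `cohort` after validation.
#'
#' @name cohort-io
NULL

.sex_map <- c(M = "male", F = "female", male = "male", female = "female",
              `1` = "male", `2` = "female")

#' Canonical column-name dialect for visit tables
#'
#' @param subject_id,sex,age,bmi Column names in the file to be mapped onto
#'   the canonical `subject_id`, `sex`, `age_years`, `bmi`.
#' @return Named character vector used by [read_cohort()].
#' @export
cohort_dialect <- function(subject_id = "subject_id", sex = "sex",
                           age = "age_years", bmi = "bmi") {
  c(subject_id = subject_id, sex = sex, age = age, bmi = bmi)
}

#' Validate a visit table
#'
#' Checks the invariants every downstream model assumes: ages finite in
#' (0, 25], BMI in (5, 80), one sex per subject, no duplicate (subject, age)
#' pairs. Rows are sorted by subject then age.
#'
#' @param df Data frame with canonical columns.
#' @return The validated, sorted data frame with class `cohort`.
#' @export
validate_cohort <- function(df) {
  req <- c("subject_id", "sex", "age_years", "bmi")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$age_years) || !is.numeric(df$bmi)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$age_years))) |
                 is.na(suppressWarnings(as.numeric(df$bmi))))
    stop("non-numeric age/bmi in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  sex <- .sex_map[as.character(df$sex)]
  if (anyNA(sex)) {
    bad <- unique(as.character(df$sex)[is.na(sex)])
    stop("unknown sex code(s): ", paste(bad, collapse = ", "),
         " (accepted: M, F, male, female, 1, 2)")
  }
  df$sex <- unname(sex)
  bad_age <- which(!is.finite(df$age_years) | df$age_years <= 0 |
                   df$age_years > 25)
  if (length(bad_age)) {
    stop("age outside (0, 25] in rows: ",
         paste(utils::head(bad_age, 10), collapse = ", "))
  }
  bad_bmi <- which(!is.finite(df$bmi) | df$bmi <= 5 | df$bmi >= 80)
  if (length(bad_bmi)) {
    stop("bmi outside (5, 80) in rows: ",
         paste(utils::head(bad_bmi, 10), collapse = ", "))
  }
  df$subject_id <- as.character(df$subject_id)
  nsex <- tapply(df$sex, df$subject_id, function(s) length(unique(s)))
  if (any(nsex > 1)) {
    stop("sex not constant within subject(s): ",
         paste(utils::head(names(nsex)[nsex > 1], 5), collapse = ", "))
  }
  key <- paste(df$subject_id, df$age_years, sep = "@")
  if (anyDuplicated(key)) {
    stop("duplicate (subject, age) pair(s): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = ", "))
  }
  df <- df[order(df$subject_id, df$age_years), req, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cohort", "data.frame")
  df
}

#' Read a long-format visit table
#'
#' @param path CSV file path.
#' @param dialect Column-name map from [cohort_dialect()].
#' @return A validated `cohort` data frame.
#' @export
read_cohort <- function(path, dialect = cohort_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  # read as character so sex codes like "F" are never parsed as logicals
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(unname(dialect), names(raw))
  if (length(miss)) {
    stop("configured column(s) absent from file: ",
         paste(miss, collapse = ", "))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[dialect[[col]]]]))
    bad <- which(is.na(v) & !is.na(raw[[dialect[[col]]]]))
    if (length(bad)) {
      stop("non-numeric ", col, " in rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    v
  }
  df <- data.frame(subject_id = raw[[dialect[["subject_id"]]]],
                   sex = raw[[dialect[["sex"]]]],
                   age_years = num("age"),
                   bmi = num("bmi"),
                   stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Write a visit table in the canonical dialect
#'
#' `write_cohort()` then [read_cohort()] reproduces all records.
#'
#' @param cohort A `cohort` data frame.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' SNP metadata table
#'
#' Dosages throughout the package count copies of the obesity *risk* allele,
#' which for several established loci is the major allele; `risk_is_minor`
#' records the orientation, so the risk-allele frequency is `maf` when the
#' risk allele is minor and `1 - maf` otherwise.
#'
#' @param snp_id Character vector of SNP labels.
#' @param risk_allele One of A/C/G/T per SNP.
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param risk_is_minor Logical; is the risk allele the minor allele?
#' @return Data frame of class `snp_info` with a derived `risk_freq` column.
#' @export
snp_info <- function(snp_id, risk_allele, maf, risk_is_minor = TRUE) {
  stopifnot(length(snp_id) == length(risk_allele),
            length(snp_id) == length(maf))
  if (!all(risk_allele %in% c("A", "C", "G", "T"))) {
    stop("risk_allele must be one of A, C, G, T")
  }
  if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]")
  risk_is_minor <- rep_len(risk_is_minor, length(snp_id))
  structure(data.frame(snp_id = snp_id, risk_allele = risk_allele, maf = maf,
                       risk_is_minor = risk_is_minor,
                       risk_freq = ifelse(risk_is_minor, maf, 1 - maf),
                       stringsAsFactors = FALSE),
            class = c("snp_info", "data.frame"))
}

#' Read SNP metadata (`snp_id,risk_allele,maf[,risk_is_minor]`)
#' @param path CSV path.
#' @return `snp_info` data frame.
#' @export
read_snp_info <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  snp_info(raw$snp_id, raw$risk_allele, raw$maf,
           if ("risk_is_minor" %in% names(raw)) raw$risk_is_minor else TRUE)
}

#' Read a genotype dosage table
#'
#' One row per subject; `subject_id` plus a 0/1/2 dosage column per SNP.
#' Missing cells (empty or `NA`) are preserved as `NA`, never coerced to 0.
#'
#' @param path CSV path.
#' @param snps Optional `snp_info`; columns are checked and ordered to match.
#' @return Data frame with `subject_id` and one integer column per SNP.
#' @export
read_genotypes <- function(path, snps = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(raw)) stop("missing column: subject_id")
  raw$subject_id <- as.character(raw$subject_id)
  snp_cols <- setdiff(names(raw), "subject_id")
  if (!is.null(snps)) {
    miss <- setdiff(snps$snp_id, snp_cols)
    if (length(miss)) {
      stop("SNP column(s) absent from file: ", paste(miss, collapse = ", "))
    }
    snp_cols <- snps$snp_id
  }
  for (s in snp_cols) {
    v <- raw[[s]]
    ok <- is.na(v) | v %in% c(0, 1, 2)
    if (!all(ok)) {
      stop("dosage outside {0,1,2} for ", s, " in rows: ",
           paste(utils::head(which(!ok), 10), collapse = ", "))
    }
    raw[[s]] <- as.integer(v)
  }
  raw[, c("subject_id", snp_cols), drop = FALSE]
}

#' Split a cohort (and optionally its genotypes) by sex
#'
#' The two strata are disjoint and their union is the input; genotype rows are
#' partitioned identically by subject membership.
#'
#' @param cohort A `cohort` data frame.
#' @param genotypes Optional genotype table.
#' @return Named list with elements `male` and `female`; each holds `cohort`
#'   and (if supplied) `genotypes`.
#' @export
stratify_by_sex <- function(cohort, genotypes = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  out <- lapply(c(male = "male", female = "female"), function(s) {
    cs <- cohort[cohort$sex == s, , drop = FALSE]
    rownames(cs) <- NULL
    class(cs) <- c("cohort", "data.frame")
    res <- list(cohort = cs)
    if (!is.null(genotypes)) {
      res$genotypes <- genotypes[genotypes$subject_id %in% cs$subject_id, ,
                                 drop = FALSE]
      rownames(res$genotypes) <- NULL
    }
    res
  })
  out
}

#' Centre an age vector
#'
#' Centring is applied to polynomial model terms only; spline knots stay on
#' the raw age scale.
#'
#' @param ages Ages in years (or a `cohort`, in which case its `age_years`
#'   column is used).
#' @param center Centring constant in years; default 8 (the sample mean age of
#'   the emulated cohort) so estimates are comparable across strata.
#' @return Numeric vector `ages - center`.
#' @export
center_age <- function(ages, center = 8) {
  if (inherits(ages, "cohort")) ages <- ages$age_years
  stopifnot(is.finite(center))
  ages - center
}

#' Per-subject visit counts
#' @param cohort A `cohort`.
#' @return Integer vector named by subject.
#' @export
visits_per_subject <- function(cohort) {
  tab <- table(cohort$subject_id)
  stats::setNames(as.integer(tab), names(tab))
}
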