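#' Path to the packaged study-level dataset
#'
#' The package ships a study-level table of diagnostic-accuracy analyses of
#' four noninvasive cardiac stress tests (exercise ECG testing, stress
#' echocardiography, stress SPECT, stress CMR) against angiographically
#' confirmed obstructive coronary artery disease. One row is one analysis:
#' a study cohort evaluated with one modality/stressor combination, with its
#' printed sensitivity, specificity and accuracy percentages.
#'
#' @return Path to the packaged CSV file.
#' @export
dta_fixture_path <- function() {
  system.file("extdata", "table1_studies.csv", package = "dtameta",
              mustWork = TRUE)
}

.modalities  <- c("EST", "SE", "SPECT", "CMR")
.techniques  <- c("exercise", "dobutamine", "dipyridamole", "adenosine",
                  "dual", "none")
.designs     <- c("prospective", "retrospective")
.centers     <- c("monocentric", "multicentric")
.cad_status  <- c("suspected", "known", "mixed")
.cutoffs     <- c(50, 60, 70, 75)

#' Read and validate a study-level DTA table
#'
#' Reads a CSV with one row per analysis (see [dta_fixture_path()] for the
#' schema) and validates every field: enumerations, percentage ranges,
#' minimum sample size. The printed accuracy is soft-checked against the
#' sensitivity/specificity range (`min(sen, spe) - 5 <= acc <= max(sen, spe)
#' + 5`); violations are collected in the `"flags"` attribute, not fatal,
#' because published accuracy columns carry transcription noise.
#'
#' A `sex_subgroup` column is derived: `"female_only"` iff the cohort is 100%
#' female, `"mixed"` otherwise (including missing percent-female).
#'
#' @param path CSV path, or `"fixture"` (default) for the packaged dataset.
#' @return A `data.frame` of class `"dta_studies"` with a `"census"`
#'   attribute (row count, per-modality counts, missing-value counts) and a
#'   `"flags"` attribute listing soft-check violations.
#' @examples
#' studies <- read_study_table()
#' nrow(studies)                      # 159 analyses
#' attr(studies, "census")$modality   # per-modality analysis counts
#' @export
read_study_table <- function(path = "fixture") {
  if (identical(path, "fixture") || identical(path, "packaged"))
    path <- dta_fixture_path()
  d <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "year", "country", "design", "centers",
                "modality", "technique", "n", "pct_female", "mean_age",
                "cad_status", "stenosis_cutoff", "sen_pct", "spe_pct",
                "acc_pct")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))

  check_enum <- function(col, allowed) {
    bad <- which(!is.na(d[[col]]) & !(d[[col]] %in% allowed))
    if (length(bad))
      stop(sprintf("unknown %s value(s) at row(s) %s: %s", col,
                   paste(bad, collapse = ","),
                   paste(unique(d[[col]][bad]), collapse = ", ")))
  }
  check_enum("modality", .modalities)
  check_enum("technique", .techniques)
  check_enum("design", .designs)
  check_enum("centers", .centers)
  check_enum("cad_status", .cad_status)
  check_enum("stenosis_cutoff", .cutoffs)

  num_bad <- function(x, lo, hi) which(!is.na(x) & (x < lo | x > hi))
  if (length(i <- which(is.na(d$n) | d$n < 2)))
    stop("n must be >= 2; bad row(s): ", paste(i, collapse = ","))
  for (col in c("sen_pct", "spe_pct", "acc_pct", "pct_female")) {
    if (length(i <- num_bad(d[[col]], 0, 100)))
      stop(col, " outside [0,100] at row(s): ", paste(i, collapse = ","))
  }
  if (any(is.na(d$sen_pct)) || any(is.na(d$spe_pct)))
    stop("sen_pct / spe_pct must be present for every row")

  d$sex_subgroup <- ifelse(!is.na(d$pct_female) & d$pct_female == 100,
                           "female_only", "mixed")

  # soft consistency check on the printed accuracy column
  lo <- pmin(d$sen_pct, d$spe_pct) - 5
  hi <- pmax(d$sen_pct, d$spe_pct) + 5
  soft <- which(!is.na(d$acc_pct) & (d$acc_pct < lo | d$acc_pct > hi))
  flags <- if (length(soft)) {
    data.frame(row = soft, study_id = d$study_id[soft],
               issue = "accuracy outside [min(sen,spe)-5, max(sen,spe)+5]")
  } else {
    data.frame(row = integer(), study_id = character(), issue = character())
  }

  census <- list(
    n_rows = nrow(d),
    modality = table(d$modality),
    technique = table(d$modality, d$technique),
    n_missing = vapply(d, function(x) sum(is.na(x)), integer(1)),
    n_unique_cohorts = length(unique(d$study_id)),
    total_patients_unique = sum(d$n[!duplicated(d$study_id)])
  )
  structure(d, class = c("dta_studies", "data.frame"),
            census = census, flags = flags)
}

#' @export
print.dta_studies <- function(x, ...) {
  census <- attr(x, "census")
  cat(sprintf("Study-level DTA table: %d analyses, %d unique cohorts, %d patients\n",
              census$n_rows, census$n_unique_cohorts,
              census$total_patients_unique))
  print(census$modality)
  if (nrow(attr(x, "flags")))
    cat(sprintf("%d row(s) flagged by the accuracy soft check\n",
                nrow(attr(x, "flags"))))
  invisible(x)
}

#' Construct and validate a 2x2 contingency table
#'
#' @param tp,fp,tn,fn Non-negative integer counts (vectorized).
#' @return A `data.frame` with columns `tp`, `fp`, `tn`, `fn`.
#' @export
contingency_table <- function(tp, fp, tn, fn) {
  k <- max(length(tp), length(fp), length(tn), length(fn))
  tab <- data.frame(tp = rep_len(tp, k), fp = rep_len(fp, k),
                    tn = rep_len(tn, k), fn = rep_len(fn, k))
  if (any(unlist(tab) < 0) || any(unlist(tab) != round(unlist(tab))))
    stop("counts must be non-negative integers")
  if (any(tab$tp + tab$fn < 1))
    stop("empty diseased stratum: tp + fn must be >= 1")
  if (any(tab$tn + tab$fp < 1))
    stop("empty non-diseased stratum: tn + fp must be >= 1")
  tab
}

#' Sensitivity, specificity and accuracy from counts
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`,
#' `accuracy = (tp + tn) / (tp + fp + tn + fn)`, all as proportions in
#' \[0, 1\].
#'
#' @param tab A `data.frame` (or coercible list) with columns `tp`, `fp`,
#'   `tn`, `fn`; vectorized over rows.
#' @return A `data.frame` with columns `sensitivity`, `specificity`,
#'   `accuracy`.
#' @examples
#' derive_metrics(data.frame(tp = 12, fp = 9, tn = 17, fn = 14))
#' @export
derive_metrics <- function(tab) {
  tab <- as.data.frame(tab)
  tab <- contingency_table(tab$tp, tab$fp, tab$tn, tab$fn)
  with(tab, data.frame(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn)))
}

#' Cohen's kappa from agreement proportions
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the observed agreement
#' proportion and `p_e` the agreement expected by chance.
#'
#' @param p_o Observed agreement in \[0, 1\].
#' @param p_e Chance agreement in \[0, 1).
#' @return The kappa coefficient.
#' @export
cohen_kappa <- function(p_o, p_e) {
  stopifnot(p_o >= 0, p_o <= 1, p_e >= 0)
  if (any(p_e >= 1)) stop("kappa undefined for p_e = 1")
  (p_o - p_e) / (1 - p_e)
}
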