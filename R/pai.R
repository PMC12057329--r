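#' Compute per-patient personalized advantage indices
#'
#' The PAI is the difference between a patient's model-predicted
#' post-treatment GAD-7 score under each arm: `pai = yhat_cbt - yhat_cat`.
#' A positive PAI indicates greater predicted benefit from CAT-GSH (lower
#' predicted score under CAT); a negative PAI indicates greater benefit from
#' CBT-GSH; exactly zero indicates no preference (`indicated_arm = "none"`).
#'
#' @param yhat_cbt,yhat_cat Counterfactual predictions per patient.
#' @param patient_id Optional identifiers.
#' @param received_arm Optional received arm ("CAT"/"CBT"); enables the
#'   `optimal` flag via [assign_groups()].
#' @return A `pai_records` data frame: `patient_id`, `yhat_cat`, `yhat_cbt`,
#'   `pai`, `indicated_arm`, plus `received_arm` and `optimal` when the
#'   received arm is supplied.
#' @export
compute_pai <- function(yhat_cbt, yhat_cat, patient_id = NULL,
                        received_arm = NULL) {
  stopifnot(length(yhat_cbt) == length(yhat_cat))
  if (anyNA(yhat_cbt) || anyNA(yhat_cat))
    stop("both counterfactual predictions must be present per patient",
         call. = FALSE)
  n <- length(yhat_cbt)
  if (is.null(patient_id)) patient_id <- sprintf("P%04d", seq_len(n))
  pai <- yhat_cbt - yhat_cat
  indicated <- ifelse(pai > 0, "CAT", ifelse(pai < 0, "CBT", "none"))
  out <- data.frame(patient_id = patient_id,
                    yhat_cat = yhat_cat, yhat_cbt = yhat_cbt,
                    pai = pai, indicated_arm = indicated,
                    stringsAsFactors = FALSE)
  class(out) <- c("pai_records", "data.frame")
  if (!is.null(received_arm)) out <- assign_groups(out, received_arm)
  out
}

#' Classify patients into optimal / non-optimal treatment groups
#'
#' A patient is "optimal" when the arm they actually received matches the
#' PAI-indicated arm. Patients with no indication (PAI exactly 0) are
#' excluded from both groups and counted separately.
#'
#' @param pai_records A `pai_records` data frame.
#' @param received_arm Character vector, "CAT" or "CBT", per patient.
#' @return The `pai_records` with `received_arm` and `optimal` (logical, NA
#'   for no indication) columns; attribute `group_counts` holds the counts
#'   and proportions.
#' @export
assign_groups <- function(pai_records, received_arm) {
  stopifnot(nrow(pai_records) == length(received_arm))
  if (!all(received_arm %in% c("CAT", "CBT")))
    stop("schema error: received arm must be CAT or CBT", call. = FALSE)
  out <- pai_records
  out$received_arm <- received_arm
  out$optimal <- ifelse(out$indicated_arm == "none", NA,
                        out$indicated_arm == received_arm)
  counts <- c(optimal = sum(out$optimal %in% TRUE),
              non_optimal = sum(out$optimal %in% FALSE),
              no_indication = sum(is.na(out$optimal)))
  attr(out, "group_counts") <- list(
    counts = counts,
    proportions = counts / nrow(out))
  class(out) <- c("pai_records", "data.frame")
  out
}

#' Flag the large-predicted-benefit subgroup
#'
#' The subgroup threshold is `mean(|PAI|) + 1 * SD(|PAI|)` over the analysis
#' sample; members are the patients with `|PAI| >=` threshold. For
#' non-members no optimal treatment is considered indicated in subgroup
#' reporting. If the basis has zero variance the threshold equals the common
#' value and all patients at or above it are members (logged via a message).
#'
#' @param pai_records A `pai_records` data frame (>= 2 patients).
#' @return The records with a logical `large_benefit` column; attribute
#'   `subgroup_rule` holds the basis, mean, SD and threshold.
#' @export
large_benefit_subgroup <- function(pai_records) {
  stopifnot(nrow(pai_records) >= 2)
  basis <- abs(pai_records$pai)
  m <- mean(basis); s <- sd(basis)
  if (s == 0)
    message("zero variance of |PAI|; threshold equals the common value")
  threshold <- m + s
  out <- pai_records
  out$large_benefit <- basis >= threshold
  attr(out, "subgroup_rule") <- list(statistic_basis = "absolute-PAI",
                                     mean = m, sd = s, threshold = threshold)
  attr(out, "group_counts") <- attr(pai_records, "group_counts")
  class(out) <- c("pai_records", "data.frame")
  out
}

#' @export
print.pai_records <- function(x, ...) {
  cat(sprintf("PAI records: %d patients; indicated CAT %d / CBT %d / none %d\n",
              nrow(x), sum(x$indicated_arm == "CAT"),
              sum(x$indicated_arm == "CBT"),
              sum(x$indicated_arm == "none")))
  gc <- attr(x, "group_counts")
  if (!is.null(gc))
    cat(sprintf("  optimal %d (%.1f%%) / non-optimal %d (%.1f%%)\n",
                gc$counts["optimal"], 100 * gc$proportions["optimal"],
                gc$counts["non_optimal"], 100 * gc$proportions["non_optimal"]))
  sr <- attr(x, "subgroup_rule")
  if (!is.null(sr))
    cat(sprintf("  large-benefit threshold |PAI| >= %.2f: %d patients\n",
                sr$threshold, sum(x$large_benefit)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat(sprintf("  ... %d more rows\n", nrow(x) - 4))
  invisible(x)
}
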