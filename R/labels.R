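## Expression dichotomization and patient-level cohort splitting.

#' Percentile associated with a binarization threshold kind
#'
#' `median`, `tertile` and `quartile` cut the expression distribution at
#' the 50th, 66.67th and 75th percentile respectively; slides above the
#' cutoff are labeled expression-high.
#'
#' @param kind one of `"median"`, `"tertile"`, `"quartile"`.
#' @return The percentile in `(0, 100)`.
#' @export
threshold_percentile <- function(kind) {
  switch(match.arg(kind, c("median", "tertile", "quartile")),
         median = 50, tertile = 200 / 3, quartile = 75)
}

#' Per-slide labeled-instance proportion for a threshold kind
#'
#' The fraction of each slide's tiles that receive a pseudo-label during
#' teacher-student training: 0.25, 0.35 and 0.45 for the quartile,
#' tertile and median cutoffs.
#'
#' @inheritParams threshold_percentile
#' @return The proportion in `(0, 1)`.
#' @export
labeled_proportion <- function(kind) {
  switch(match.arg(kind, c("median", "tertile", "quartile")),
         quartile = 0.25, tertile = 0.35, median = 0.45)
}

#' Dichotomize continuous expression values at a percentile cutoff
#'
#' Computes the cutoff (type-7 linear interpolation between order
#' statistics) of `fpkm_uq` within each `cancer_type` and labels a slide
#' 1 when its value is strictly above the cutoff; ties at the cutoff go
#' negative.
#'
#' @param records data.frame with columns `slide_id`, `patient_id`,
#'   `cancer_type`, `fpkm_uq`.
#' @param kind threshold kind, see [threshold_percentile()].
#' @return A list with `cutoffs` (named per cancer type) and `labels`
#'   (named integer vector over `slide_id`).
#' @export
dichotomize_expression <- function(records, kind = "tertile") {
  needed <- c("slide_id", "cancer_type", "fpkm_uq")
  if (!all(needed %in% names(records)))
    stopf("records must have columns %s", paste(needed, collapse = ", "))
  bad <- is.na(records$fpkm_uq) | records$fpkm_uq < 0
  if (any(bad))
    stopf("missing or negative expression for slides: %s",
          paste(records$slide_id[bad], collapse = ", "))
  p <- threshold_percentile(kind) / 100
  cutoffs <- c()
  labels <- integer(nrow(records))
  for (ct in unique(records$cancer_type)) {
    sel <- records$cancer_type == ct
    v <- records$fpkm_uq[sel]
    if (length(unique(v)) < 2L)
      stopf("cancer type '%s': degenerate expression distribution", ct)
    cut <- unname(quantile(v, p, type = 7))
    cutoffs[ct] <- cut
    labels[sel] <- as.integer(v > cut)
  }
  list(cutoffs = cutoffs,
       labels = setNames(labels, records$slide_id))
}

#' Split a cohort into train/validation/test at patient granularity
#'
#' Patients (never individual slides) are assigned to partitions so that
#' every slide of a patient lands in the same partition.  Partition sizes
#' follow `fractions` under largest-remainder rounding.  When `labels`
#' are supplied the split is stratified: rounding is applied within each
#' label group, with any size drift corrected on the pooled counts.
#' Patients are sorted before seeding, so the assignment is invariant to
#' input order.
#'
#' @param patient_ids character vector (duplicates allowed; unique
#'   patients are split).
#' @param fractions length-3 numeric summing to 1, default
#'   `c(0.60, 0.15, 0.25)`.
#' @param seed integer RNG seed.
#' @param labels optional per-patient labels (named by patient or aligned
#'   with `patient_ids`) used for stratification.
#' @return An object of class `cohort_split`: list with `assignment`
#'   (named factor `train`/`val`/`test` over patients), `fractions`,
#'   `seed`.
#' @export
split_cohort <- function(patient_ids, fractions = c(0.60, 0.15, 0.25),
                         seed = 1L, labels = NULL) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L)
    stopf("fractions must be three numbers summing to 1")
  if (!is.null(labels) && is.null(names(labels)))
    labels <- setNames(labels, patient_ids)
  patients <- sort(unique(as.character(patient_ids)))
  n <- length(patients)
  if (n < 4L) stopf("need at least 4 patients to split, got %d", n)
  parts <- c("train", "val", "test")
  assign_counts <- function(ids, counts) {
    grp <- rep(parts, counts)
    setNames(grp[order(runif(length(ids)))], ids)
  }
  out <- with_seed(seed, {
    overall <- largest_remainder(n * fractions)
    if (is.null(labels)) {
      assign_counts(patients, overall)
    } else {
      lab <- labels[patients]
      strata <- split(patients, lab)
      cnt <- t(vapply(strata,
                      function(ids) largest_remainder(length(ids) * fractions),
                      integer(3)))
      ## repair per-stratum rounding so pooled counts hit the
      ## largest-remainder targets, moving one patient at a time
      while (any(colSums(cnt) != overall)) {
        over <- which(colSums(cnt) > overall)[1]
        under <- which(colSums(cnt) < overall)[1]
        s <- which(cnt[, over] > 0)
        s <- s[which.max(cnt[s, over])]
        cnt[s, over] <- cnt[s, over] - 1L
        cnt[s, under] <- cnt[s, under] + 1L
      }
      res <- character(0)
      for (k in seq_along(strata))
        res <- c(res, assign_counts(strata[[k]], cnt[k, ]))
      res[patients]
    }
  })
  assignment <- factor(out[patients], levels = parts)
  names(assignment) <- patients
  structure(list(assignment = assignment, fractions = fractions,
                 seed = as.integer(seed)),
            class = "cohort_split")
}

## Integer apportionment of (possibly fractional) target counts.
largest_remainder <- function(target) {
  base <- floor(target)
  rem <- target - base
  short <- round(sum(target)) - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Attach labels and split assignments to a cohort manifest
#'
#' Convenience wrapper producing the labeled manifest used downstream:
#' dichotomizes expression at `kind` and splits patients 60/15/25.
#'
#' @param manifest data.frame with `slide_id`, `patient_id`,
#'   `cancer_type`, `fpkm_uq`.
#' @param kind threshold kind.
#' @param seed split seed.
#' @param stratify stratify the split by label (default `TRUE`).
#' @param fractions train/val/test fractions.
#' @return The manifest with added columns `label`, `split`,
#'   `cutoff_kind`, `cutoff`.
#' @export
label_cohort <- function(manifest, kind = "tertile", seed = 1L,
                         stratify = TRUE,
                         fractions = c(0.60, 0.15, 0.25)) {
  dich <- dichotomize_expression(manifest, kind)
  manifest$label <- unname(dich$labels[manifest$slide_id])
  plab <- NULL
  if (stratify) {
    agg <- tapply(manifest$label, manifest$patient_id, max)
    plab <- setNames(as.integer(agg), names(agg))
  }
  sp <- split_cohort(manifest$patient_id, fractions, seed, labels = plab)
  manifest$split <- as.character(sp$assignment[manifest$patient_id])
  manifest$cutoff_kind <- kind
  manifest$cutoff <- unname(dich$cutoffs[manifest$cancer_type])
  ## hard guarantee: a patient never straddles partitions
  stopifnot(all(tapply(manifest$split, manifest$patient_id,
                       function(s) length(unique(s))) == 1L))
  manifest
}
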