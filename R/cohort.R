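#' Read a patient cohort table
#'
#' One row per patient with columns `patient_id`, `diagnosis`, `age`, `sex`,
#' `survival_days`, `event`, plus one column per coarse genetic domain
#' holding the fine-grained test result.  Missing values are empty cells.
#'
#' @param path CSV file path.
#' @param taxonomy Taxonomy list; its domain names select the panel columns.
#' @return data.frame of patient records.
#' @export
read_cohort <- function(path, taxonomy = default_taxonomy()) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_cohort(df, taxonomy)
  df
}

#' @rdname read_cohort
#' @param records Cohort data.frame to write.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_cohort <- function(records, taxonomy = default_taxonomy()) {
  need <- c("patient_id", "diagnosis", "age", "sex", "survival_days", "event")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("cohort table lacks columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(names(taxonomy), names(records))
  if (length(miss)) stop("cohort table lacks panel domains: ",
                         paste(miss, collapse = ", "))
  bad <- !is.na(records$survival_days) & is.na(records$event)
  if (any(bad)) stop("survival_days present without event indicator for ",
                     "patient(s) ", paste(records$patient_id[bad], collapse = ", "))
  if (any(records$age < 0, na.rm = TRUE)) stop("negative age")
  if (any(records$survival_days < 0, na.rm = TRUE)) stop("negative survival")
  invisible(TRUE)
}

#' Fractionate panel results into a patient feature barcode
#'
#' Each coarse domain result is expanded into one indicator column per fine
#' state of the taxonomy (wildtype states included), yielding a patients x
#' features matrix over \{0, 1, NA\}.  Within a domain exactly one indicator
#' is 1 for an assayed patient; if the domain was not assayed, all its
#' indicators are NA (missingness propagates from the panel).
#'
#' @param records Cohort data.frame (see [read_cohort()]).
#' @param taxonomy Taxonomy list covering every fine state in `records`.
#' @return An object of class `feature_barcode`: list with `patients`,
#'   `features`, `domains` (coarse domain of each feature) and `X`
#'   (patients x features 0/1/NA matrix).
#' @export
fractionate_features <- function(records, taxonomy = default_taxonomy()) {
  validate_cohort(records, taxonomy)
  feats <- taxonomy_features(taxonomy)
  doms <- taxonomy_domains(taxonomy)
  n <- nrow(records)
  X <- matrix(NA_integer_, n, length(feats),
              dimnames = list(records$patient_id, feats))
  for (dom in names(taxonomy)) {
    states <- taxonomy[[dom]]
    res <- as.character(records[[dom]])
    known <- !is.na(res)
    bad <- known & !(res %in% states)
    if (any(bad)) {
      i <- which(bad)[1]
      stop("unknown fine state '", res[i], "' in domain '", dom,
           "' for patient ", records$patient_id[i])
    }
    cols <- which(doms == dom)
    for (k in seq_along(states)) {
      X[known, cols[k]] <- as.integer(res[known] == states[k])
    }
  }
  structure(list(patients = as.character(records$patient_id),
                 features = feats, domains = doms, X = X),
            class = "feature_barcode")
}

#' Reconstruct the panel table from a barcode
#'
#' Inverse of [fractionate_features()]: given the taxonomy, the barcode is a
#' lossless encoding of the panel, so `reconstruct_panel()` recovers the
#' original domain columns (including missingness).
#'
#' @param barcode A `feature_barcode`.
#' @param taxonomy Taxonomy used to build it.
#' @return data.frame with `patient_id` and one column per domain.
#' @export
reconstruct_panel <- function(barcode, taxonomy = default_taxonomy()) {
  stopifnot(inherits(barcode, "feature_barcode"))
  out <- data.frame(patient_id = barcode$patients, stringsAsFactors = FALSE)
  for (dom in names(taxonomy)) {
    cols <- which(barcode$domains == dom)
    sub <- barcode$X[, cols, drop = FALSE]
    res <- rep(NA_character_, nrow(sub))
    hit <- which(sub == 1L, arr.ind = TRUE)
    res[hit[, 1]] <- taxonomy[[dom]][hit[, 2]]
    out[[dom]] <- res
  }
  out
}

#' Iterated minimum-count filter on categorical cohort variables
#'
#' Removes every patient belonging to a category level (of any of the given
#' variables) with fewer than `min_count` members, iterating until no level
#' is below threshold: removing one sparse level can push another below the
#' cut, so the filter runs to a fixed point.  NA values do not form a level.
#'
#' @param table Patient data.frame.
#' @param vars Character vector of categorical column names to police.
#' @param min_count Minimum members per retained level (default 5).
#' @return List with `table` (filtered rows) and `removed`, a data.frame of
#'   `variable`, `level`, `count` and the pass in which each level fell.
#' @export
apply_min_count_filter <- function(table, vars, min_count = 5) {
  stopifnot(is.data.frame(table), all(vars %in% names(table)))
  removed <- data.frame(variable = character(), level = character(),
                        count = integer(), pass = integer(),
                        stringsAsFactors = FALSE)
  pass <- 0L
  repeat {
    pass <- pass + 1L
    drop <- rep(FALSE, nrow(table))
    for (v in vars) {
      x <- as.character(table[[v]])
      tab <- table(x[!is.na(x)])
      low <- names(tab)[tab < min_count]
      if (length(low)) {
        removed <- rbind(removed, data.frame(
          variable = v, level = low, count = as.integer(tab[low]),
          pass = pass, stringsAsFactors = FALSE))
        drop <- drop | (!is.na(x) & x %in% low)
      }
    }
    if (!any(drop)) break
    table <- table[!drop, , drop = FALSE]
    if (nrow(table) == 0) stop("all patients filtered")
  }
  list(table = table, removed = removed)
}

#' Clamp survival times at outer percentiles
#'
#' Values below the `lo_pct` percentile are raised to it and values above
#' the `hi_pct` percentile lowered to it, attenuating extreme outliers.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param days Nonnegative numeric vector of survival times.
#' @param lo_pct,hi_pct Percentile bounds (defaults 1 and 99).
#' @return Clamped vector (NAs passed through).
#' @export
clamp_survival <- function(days, lo_pct = 1, hi_pct = 99) {
  if (length(days) == 0) stop("empty survival vector")
  if (any(days < 0, na.rm = TRUE)) stop("negative survival times")
  q <- stats::quantile(days, c(lo_pct, hi_pct) / 100,
                       na.rm = TRUE, names = FALSE, type = 7)
  pmin(pmax(days, q[1]), q[2])
}
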