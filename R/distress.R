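#' Instrument score ranges and high-distress thresholds
#'
#' PSS (perceived stress, 0-40, threshold 15), EPDS (depression risk, 0-30,
#' threshold 10), SSAI/STAI (state/trait anxiety, 20-80, threshold 40).
#' A score strictly greater than its threshold flags the instrument.
#'
#' @return data.frame with columns instrument, lo, hi, threshold.
#' @export
distress_instruments <- function() {
  data.frame(instrument = c("ssai", "stai", "pss", "epds"),
             lo = c(20, 20, 0, 0),
             hi = c(80, 80, 40, 30),
             threshold = c(40, 40, 15, 10))
}

check_score_range <- function(x, instrument) {
  ins <- distress_instruments()
  r <- ins[ins$instrument == instrument, ]
  bad <- which(!is.na(x) & (x < r$lo | x > r$hi))
  if (length(bad))
    stop("distress: ", instrument, " score out of range [", r$lo, ", ",
         r$hi, "] in row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Binary high-distress indicator
#'
#' 1 when any available score strictly exceeds its instrument threshold,
#' 0 when every available score is at or below threshold, NA when all four
#' scores are missing. Scores equal to a threshold do not flag (the
#' comparison is strict). With `mode = "complete_case"` the indicator is NA
#' unless all four scores are present.
#'
#' @param ssai,stai,pss,epds numeric score vectors (recycled to a common
#'   length); NA marks a missing questionnaire.
#' @param mode `"any_available"` (default) or `"complete_case"`.
#' @return integer vector of 0/1/NA.
#' @export
high_distress <- function(ssai = NA, stai = NA, pss = NA, epds = NA,
                          mode = c("any_available", "complete_case")) {
  mode <- match.arg(mode)
  n <- max(length(ssai), length(stai), length(pss), length(epds))
  sc <- list(ssai = rep_len(ssai, n), stai = rep_len(stai, n),
             pss = rep_len(pss, n), epds = rep_len(epds, n))
  for (ins in names(sc)) check_score_range(sc[[ins]], ins)
  thr <- stats::setNames(distress_instruments()$threshold,
                         distress_instruments()$instrument)
  ex <- sapply(names(sc), function(ins) sc[[ins]] > thr[ins])
  if (n == 1L) ex <- matrix(ex, nrow = 1L)
  n_avail <- rowSums(!is.na(ex))
  out <- as.integer(rowSums(ex, na.rm = TRUE) > 0)
  out[n_avail == 0L] <- NA_integer_
  if (mode == "complete_case") out[n_avail < 4L] <- NA_integer_
  out
}

#' Add the high-distress column to a cohort table
#'
#' @param table cohort data.frame with columns ssai, stai, pss, epds.
#' @param mode see [high_distress()].
#' @return the table with an integer `high_distress` column.
#' @export
derive_high_distress <- function(table, mode = "any_available") {
  table$high_distress <- high_distress(table$ssai, table$stai,
                                       table$pss, table$epds, mode = mode)
  table
}

#' Validate distress scores in a cohort table
#'
#' Produces a per-instrument missingness report and lists rows whose score
#' falls outside the instrument range. This is report-producing: offending
#' rows are identified, not silently altered.
#'
#' @param table cohort data.frame with columns ssai, stai, pss, epds (a
#'   `scan_id` column, when present, identifies rejected rows).
#' @return list: `n_available` (named count of non-missing scores per
#'   instrument), `rejects` (data.frame row/scan_id/instrument/value),
#'   `n_rows`.
#' @export
validate_scores <- function(table) {
  ins <- distress_instruments()
  rej <- NULL
  n_avail <- integer(0)
  for (k in seq_len(nrow(ins))) {
    nm <- ins$instrument[k]
    x <- table[[nm]]
    if (is.null(x)) x <- rep(NA_real_, nrow(table))
    n_avail[nm] <- sum(!is.na(x))
    bad <- which(!is.na(x) & (x < ins$lo[k] | x > ins$hi[k]))
    if (length(bad))
      rej <- rbind(rej, data.frame(
        row = bad,
        scan_id = if (!is.null(table$scan_id)) table$scan_id[bad] else
          NA_character_,
        instrument = nm, value = x[bad]))
  }
  list(n_available = n_avail,
       rejects = if (is.null(rej))
         data.frame(row = integer(0), scan_id = character(0),
                    instrument = character(0), value = numeric(0)) else rej,
       n_rows = nrow(table))
}
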