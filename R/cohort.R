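#' Stratified closed-cohort count data
#'
#' A `paf_cohort` holds survived/died counts for every exposure level within
#' every confounder stratum of a closed cohort (everyone either survives the
#' follow-up interval or dies in it).  It is the universal input to the PAF
#' estimators: within each stratum it determines the exposure prevalence among
#' the whole group (pe), among the deceased (pd), the death probabilities
#' (q_x), and the mortality risk ratios (RR) of each exposure level against
#' the reference level.
#'
#' Counts may be non-integer: the synthetic-cohort generator's expected-count
#' mode produces real-valued expected deaths (for example 230.77 expected
#' never-smoker deaths), and those flow through the same estimators.
#'
#' @param counts data frame with columns `stratum`, `level`, `survived`,
#'   `died`; one row per stratum x exposure level.
#' @param reference name of the reference (unexposed) level, e.g.
#'   `"never"`.  Defaults to the first level encountered.
#' @param label optional cohort label used in printing and reports.
#' @return An object of class `paf_cohort`: a list with elements `counts`
#'   (the validated data frame), `levels` (ordered level names), `reference`,
#'   and `label`.
#' @examples
#' counts <- data.frame(
#'   stratum  = rep(c("black", "white"), each = 2),
#'   level    = rep(c("nonsmoker", "smoker"), 2),
#'   survived = c(500, 200, 2700, 500),
#'   died     = c(150, 150, 500, 300)
#' )
#' coh <- cohort(counts, reference = "nonsmoker")
#' summarize_stratum(coh, "black")
#' @seealso [summarize_stratum()], [death_share_weights()],
#'   [counterfactual_paf()]
#' @export
cohort <- function(counts, reference = NULL, label = NULL) {
  required <- c("stratum", "level", "survived", "died")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0) {
    stop_data("counts is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts <- as.data.frame(counts)[required]
  counts$stratum <- as.character(counts$stratum)
  counts$level <- as.character(counts$level)
  if (nrow(counts) == 0) stop_data("cohort has no rows")

  for (col in c("survived", "died")) {
    v <- counts[[col]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop_data("column '", col, "' must be finite numeric")
    }
    if (any(v < 0)) {
      bad <- which(v < 0)[1]
      stop_data("negative ", col, " count in row ", bad, " (stratum '",
                counts$stratum[bad], "', level '", counts$level[bad], "')")
    }
  }

  levels <- unique(counts$level)
  strata <- unique(counts$stratum)
  key <- paste(counts$stratum, counts$level, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    parts <- strsplit(dup, "\r", fixed = TRUE)[[1]]
    stop_data("duplicate row for stratum '", parts[1], "', level '", parts[2], "'")
  }
  expected <- as.vector(outer(strata, levels, paste, sep = "\r"))
  absent <- setdiff(expected, key)
  if (length(absent) > 0) {
    parts <- strsplit(absent[1], "\r", fixed = TRUE)[[1]]
    stop_data("stratum '", parts[1], "' is missing counts for level '",
              parts[2], "'")
  }

  reference <- reference %||% levels[1]
  if (!reference %in% levels) {
    stop_data("reference level '", reference, "' not found among levels: ",
              paste(levels, collapse = ", "))
  }
  # reference first, remaining levels in order of appearance
  levels <- c(reference, setdiff(levels, reference))
  counts <- counts[order(match(counts$stratum, strata),
                         match(counts$level, levels)), , drop = FALSE]
  rownames(counts) <- NULL

  structure(
    list(counts = counts, levels = levels, reference = reference,
         label = label),
    class = "paf_cohort"
  )
}

#' @export
print.paf_cohort <- function(x, ...) {
  cat("Stratified closed cohort")
  if (!is.null(x$label)) cat(": ", x$label, sep = "")
  cat("\n", length(unique(x$counts$stratum)), " strata x ",
      length(x$levels), " exposure levels (reference: ", x$reference, ")\n\n",
      sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Stratum names of a cohort
#' @param x a `paf_cohort`.
#' @return character vector of stratum identifiers in table order.
#' @export
strata_ids <- function(x) {
  stopifnot(inherits(x, "paf_cohort"))
  unique(x$counts$stratum)
}

#' Summarize one stratum: pe, pd, q_x and RR per exposure level
#'
#' Computes, for each exposure level k of the given stratum, the share of the
#' stratum at that level (pe_k = N_k / N), the share of the stratum's deaths
#' at that level (pd_k = D_k / D), the death probability (q_x = D_k / N_k),
#' and the mortality risk ratio against the reference level
#' (RR_k = q_x(k) / q_x(reference)).  pe and pd each sum to one over all
#' levels including the reference; the reference RR is exactly 1.
#'
#' @param x a `paf_cohort`.
#' @param stratum stratum identifier; `NULL` is allowed when the cohort has a
#'   single stratum.
#' @param continuity if `TRUE`, apply a 0.5 continuity correction to every
#'   cell of the stratum when any death cell is zero, instead of raising an
#'   error.  Off by default: silent corrections would change reported values.
#' @return A `stratum_summary`: a list with `stratum`, a per-level data frame
#'   `levels` (columns `level`, `n`, `died`, `pe`, `pd`, `qx`, `rr`), and
#'   scalars `total`, `deaths`, `qx_total`.
#' @export
summarize_stratum <- function(x, stratum = NULL, continuity = FALSE) {
  stopifnot(inherits(x, "paf_cohort"))
  ids <- strata_ids(x)
  if (is.null(stratum)) {
    if (length(ids) != 1) stop_data("stratum must be named for a multi-stratum cohort")
    stratum <- ids
  }
  if (!stratum %in% ids) stop_data("unknown stratum '", stratum, "'")
  rows <- x$counts[x$counts$stratum == stratum, , drop = FALSE]
  rows <- rows[match(x$levels, rows$level), , drop = FALSE]

  died <- rows$died
  n <- rows$survived + rows$died
  if (continuity && any(died == 0)) {
    died <- died + 0.5
    n <- n + 1
  }
  names(died) <- names(n) <- x$levels

  N <- sum(n)
  D <- sum(died)
  ref <- x$reference
  if (n[ref] <= 0) {
    stop_data("stratum '", stratum, "' has no persons at the reference level")
  }
  if (D <= 0) {
    stop_data("stratum '", stratum,
              "' has zero total deaths: pd is undefined")
  }
  if (died[ref] <= 0) {
    stop_data("stratum '", stratum, "' has zero reference-level deaths: ",
              "RR is undefined (consider continuity = TRUE)")
  }
  qx <- died / n
  out <- list(
    stratum = stratum,
    levels = data.frame(
      level = x$levels,
      n = as.numeric(n),
      died = as.numeric(died),
      pe = as.numeric(n / N),
      pd = as.numeric(died / D),
      qx = as.numeric(qx),
      rr = as.numeric(qx / qx[ref]),
      row.names = NULL
    ),
    reference = ref,
    total = N,
    deaths = D,
    qx_total = D / N
  )
  class(out) <- "stratum_summary"
  out
}

#' @export
print.stratum_summary <- function(x, digits = 3, ...) {
  cat("Stratum '", x$stratum, "': N = ", format(x$total),
      ", deaths = ", format(x$deaths),
      ", q_x = ", round_half_up(x$qx_total, digits), "\n", sep = "")
  tab <- x$levels
  tab[c("pe", "pd", "qx", "rr")] <- lapply(tab[c("pe", "pd", "qx", "rr")],
                                           round_half_up, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summaries for every stratum of a cohort
#' @param x a `paf_cohort`.
#' @param continuity passed to [summarize_stratum()].
#' @return named list of `stratum_summary` objects, one per stratum.
#' @export
summarize_cohort <- function(x, continuity = FALSE) {
  ids <- strata_ids(x)
  stats::setNames(lapply(ids, function(s) summarize_stratum(x, s, continuity)), ids)
}

#' Pool a stratified cohort into a single combined stratum
#'
#' Sums survived and died counts elementwise across strata.  Summarizing the
#' result gives the crude (unadjusted) pe, pd and RR — the quantities that a
#' confounded analysis would use.
#'
#' @param x a `paf_cohort`.
#' @param label stratum id for the pooled counts (default `"combined"`).
#' @param ... unused, for generic consistency.
#' @return a single-stratum `paf_cohort`.
#' @export
aggregate.paf_cohort <- function(x, label = "combined", ...) {
  cts <- x$counts
  surv <- tapply(cts$survived, cts$level, sum)
  died <- tapply(cts$died, cts$level, sum)
  lev <- x$levels
  cohort(
    data.frame(stratum = label, level = lev,
               survived = as.numeric(surv[lev]),
               died = as.numeric(died[lev])),
    reference = x$reference,
    label = x$label
  )
}

#' Death-share standardization weights
#'
#' W_i, the proportion of all deaths that occurred in stratum i — the weights
#' of the weighted-sum approach, which standardizes stratum-specific PAFs by
#' the distribution of deaths over the adjustment (confounder) levels.
#'
#' @param x a `paf_cohort`.
#' @return named numeric vector summing to 1, one weight per stratum.
#' @export
death_share_weights <- function(x) {
  stopifnot(inherits(x, "paf_cohort"))
  d <- tapply(x$counts$died, x$counts$stratum, sum)
  total <- sum(d)
  if (total <= 0) stop_data("cohort has zero total deaths")
  w <- as.numeric(d[strata_ids(x)]) / total
  stats::setNames(w, strata_ids(x))
}

#' Read / write stratified cohort counts as CSV
#'
#' The file schema is one row per stratum x exposure level with header
#' `stratum,exposure_level,survived,died` and an optional `is_reference`
#' column (0/1) flagging the reference level.  Writing always emits the
#' `is_reference` column so that write-then-read reproduces the cohort
#' exactly, including the reference designation.
#'
#' @param path file path.
#' @param reference reference level name; overrides any `is_reference`
#'   column.  If neither is given the first-listed level is used.
#' @param label optional cohort label.
#' @return `read_cohort_csv` returns a `paf_cohort`; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
read_cohort_csv <- function(path, reference = NULL, label = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("stratum", "exposure_level", "survived", "died")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_data(path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop_data(path, ": no data rows")
  if (is.null(reference) && "is_reference" %in% names(df)) {
    flagged <- unique(df$exposure_level[df$is_reference %in% c(1, TRUE, "1", "true", "TRUE")])
    if (length(flagged) != 1) {
      stop_data(path, ": is_reference must flag exactly one level, found ",
                length(flagged))
    }
    reference <- flagged
  }
  names(df)[names(df) == "exposure_level"] <- "level"
  tryCatch(
    cohort(df[c("stratum", "level", "survived", "died")],
           reference = reference, label = label),
    error = function(e) stop_data(path, ": ", conditionMessage(e))
  )
}

#' @rdname read_cohort_csv
#' @param x a `paf_cohort` to write.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "paf_cohort"))
  out <- x$counts
  names(out)[names(out) == "level"] <- "exposure_level"
  out$is_reference <- as.integer(out$exposure_level == x$reference)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
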