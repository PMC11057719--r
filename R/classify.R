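#' Classify an indel spectrum into DR-white repair outcomes
#'
#' Maps spectrum weights to the three molecular outcome classes: the weight
#' at the HR-diagnostic shift (the deletion that removes the break-site
#' insertion and restores the SacI site, -23 for the canonical construct) is
#' HR; the weight at shift 0 is "no DSB" (which also absorbs precise NHEJ
#' and intersister HR, molecularly indistinguishable); all remaining weight
#' in `-K..+K` is NHEJ with indels.  Relative proportions are percentages of
#' detectable repair events (HR + NHEJ, excluding shift 0); absolute
#' proportions are percentages of all events.
#'
#' @param spec an [indel_spectrum()] with `qc_pass = TRUE`; spectra failing
#'   QC are refused.
#' @param hr_shift signed HR-diagnostic shift, a deletion in `[-K, -1]`
#'   (default -23).
#' @param sample_id,sex,tissue,condition metadata carried into the call.
#' @return A one-row `data.frame` (a *repair call*) with columns
#'   `sample_id`, `sex`, `tissue`, `condition`, `p_noDSB`, `p_HR`, `p_NHEJ`
#'   (fractions summing to 1), `rel_HR`, `rel_NHEJ` (percentages of
#'   detectable events; `NA` when no repair is detectable, never 0),
#'   `abs_HR`, `abs_total_repair` (percentages of all events) and `qc_pass`.
#' @examples
#' sp <- indel_spectrum(c(`0` = 0.5, `-23` = 0.3, `-1` = 0.2),
#'                      r_squared = 1, background = 0, qc_pass = TRUE)
#' classify_spectrum(sp)[, c("rel_HR", "rel_NHEJ", "abs_HR")]
#' @export
classify_spectrum <- function(spec, hr_shift = -23L, sample_id = NA_character_,
                              sex = NA_character_, tissue = NA_character_,
                              condition = NA_character_) {
  stopifnot(inherits(spec, "indel_spectrum"))
  if (!spec$qc_pass)
    stop("spectrum failed background QC; sample excluded from ",
         "classification", call. = FALSE)
  hr_shift <- as.integer(hr_shift)
  shifts <- as.integer(names(spec$weights))
  if (hr_shift >= 0L)
    stop("hr_shift must be a deletion (negative shift)", call. = FALSE)
  wt <- function(k) {
    i <- match(k, shifts)
    if (is.na(i)) 0 else unname(spec$weights[i])
  }
  p_hr <- wt(hr_shift)
  p_nodsb <- wt(0L)
  p_nhej <- max(0, 1 - p_hr - p_nodsb)
  detect <- p_hr + p_nhej
  data.frame(sample_id = sample_id, sex = sex, tissue = tissue,
             condition = condition,
             p_noDSB = p_nodsb, p_HR = p_hr, p_NHEJ = p_nhej,
             rel_HR = if (detect > 0) 100 * p_hr / detect else NA_real_,
             rel_NHEJ = if (detect > 0) 100 * p_nhej / detect else NA_real_,
             abs_HR = 100 * p_hr,
             abs_total_repair = 100 * detect,
             qc_pass = TRUE, stringsAsFactors = FALSE)
}

#' Group means and SEMs of repair-call statistics
#'
#' Aggregates per-sample repair calls into group summaries: for each group
#' (the distinct combinations of `keys`), the arithmetic mean and standard
#' error of the mean (sd / sqrt(n)) of `rel_HR`, `rel_NHEJ`, `abs_HR` and
#' `abs_total_repair` across samples.  Samples with undefined relative
#' proportions (no detectable repair) are excluded from the group with a
#' message, never imputed as zero: the relative statistics are conditional
#' on detectable events by definition.
#'
#' @param calls `data.frame` of repair calls, rows as returned by
#'   [classify_spectrum()] (or any per-sample table with the four statistic
#'   columns plus the grouping columns).
#' @param keys character vector of grouping column names, e.g.
#'   `c("tissue", "sex")`.
#' @return `data.frame` with one row per group, sorted by the keys, holding
#'   `n`, `n_excluded` and `<stat>_mean` / `<stat>_sem` for each statistic
#'   (SEM is `NA` for n = 1).
#' @export
aggregate_group <- function(calls, keys = c("tissue", "sex")) {
  stats_cols <- c("rel_HR", "rel_NHEJ", "abs_HR", "abs_total_repair")
  stats_cols <- intersect(stats_cols, names(calls))
  if (!all(keys %in% names(calls)))
    stop("grouping columns missing from calls: ",
         paste(setdiff(keys, names(calls)), collapse = ", "), call. = FALSE)
  if (!length(stats_cols))
    stop("no statistic columns found in calls", call. = FALSE)
  defined <- !is.na(calls[[stats_cols[1]]])
  n_undef <- sum(!defined)
  if (n_undef > 0)
    message(n_undef, " sample(s) with no detectable repair excluded ",
            "from group means")
  grp_all <- interaction(calls[keys], drop = FALSE, sep = "\r")
  groups <- split(calls[defined, , drop = FALSE], droplevels(grp_all[defined]))
  excluded <- table(droplevels(grp_all[!defined]))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) == 0) return(NULL)
    key_vals <- as.data.frame(d[1, keys, drop = FALSE], row.names = NULL)
    out <- cbind(key_vals, n = nrow(d),
                 n_excluded = if (g %in% names(excluded))
                   as.integer(excluded[[g]]) else 0L)
    for (s in stats_cols) {
      out[[paste0(s, "_mean")]] <- mean(d[[s]])
      out[[paste0(s, "_sem")]] <-
        if (nrow(d) >= 2) stats::sd(d[[s]]) / sqrt(nrow(d)) else NA_real_
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  gone <- setdiff(unique(as.character(grp_all)), names(groups))
  if (length(gone))
    warning(length(gone), " group(s) empty after exclusions, omitted",
            call. = FALSE)
  if (!length(rows)) {
    warning("no groups with defined relative proportions", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
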