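#' Score an F2 progeny phenotype into a germline repair outcome
#'
#' In the phenotypic readout of the reporter, each F2 fly reveals the repair
#' event of one premeiotic germline cell: red eyes mean the *white* gene was
#' restored by HR (body colour is ignored for these); white eyes with a
#' brown body are the unrepaired/precise class ("no DSB" or NHEJ, the
#' reporter's starting phenotype); white eyes with a yellow body mean the
#' *yellow* marker between the repeats was lost, the SSA signature.
#' Red-eyed, yellow-bodied flies (a possible double event the enumeration
#' does not cover) are scored HR with an `anomaly` flag.
#'
#' @param eye_color `"red"` or `"white"` (vectorised).
#' @param body_color `"brown"` or `"yellow"` (vectorised).
#' @return character vector in `{"HR", "NoDSB_NHEJ", "SSA"}`; attribute
#'   `anomaly` flags red+yellow records.
#' @examples
#' score_phenotype(c("red", "white", "white"),
#'                 c("brown", "brown", "yellow"))
#' @export
score_phenotype <- function(eye_color, body_color) {
  eye_color <- tolower(as.character(eye_color))
  body_color <- tolower(as.character(body_color))
  if (length(eye_color) != length(body_color))
    stop("eye_color and body_color must have equal length", call. = FALSE)
  if (!all(eye_color %in% c("red", "white")))
    stop("eye_color must be 'red' or 'white'", call. = FALSE)
  if (!all(body_color %in% c("brown", "yellow")))
    stop("body_color must be 'brown' or 'yellow'", call. = FALSE)
  out <- ifelse(eye_color == "red", "HR",
                ifelse(body_color == "yellow", "SSA", "NoDSB_NHEJ"))
  anomaly <- eye_color == "red" & body_color == "yellow"
  if (any(anomaly))
    warning(sum(anomaly), " red-eyed yellow-bodied fly/flies scored HR ",
            "(possible double event)", call. = FALSE)
  attr(out, "anomaly") <- anomaly
  out
}

#' Tally one vial of progeny into outcome counts and proportions
#'
#' @param records `data.frame` with columns `vial_id`, `parent_sex`,
#'   `eye_color`, `body_color`; one row per fly, a single vial.
#' @return one-row `data.frame` with `vial_id`, `parent_sex`, counts
#'   `n_HR`, `n_NoDSB_NHEJ`, `n_SSA`, `total`, and percentages `HR`,
#'   `NoDSB_NHEJ`, `SSA` summing to 100.
#' @export
tally_vial <- function(records) {
  if (nrow(records) == 0)
    stop("empty vial: no progeny records (unproductive cross)",
         call. = FALSE)
  if (length(unique(records$vial_id)) != 1L ||
      length(unique(records$parent_sex)) != 1L)
    stop("tally_vial expects records from a single vial and parent sex",
         call. = FALSE)
  outcome <- score_phenotype(records$eye_color, records$body_color)
  lev <- c("HR", "NoDSB_NHEJ", "SSA")
  counts <- table(factor(outcome, levels = lev))
  total <- sum(counts)
  out <- data.frame(vial_id = records$vial_id[1],
                    parent_sex = records$parent_sex[1],
                    n_HR = as.integer(counts[["HR"]]),
                    n_NoDSB_NHEJ = as.integer(counts[["NoDSB_NHEJ"]]),
                    n_SSA = as.integer(counts[["SSA"]]),
                    total = as.integer(total), stringsAsFactors = FALSE)
  for (l in lev) out[[l]] <- 100 * counts[[l]] / total
  out
}

#' Tally every vial in a progeny table
#'
#' Splits a progeny table (columns `vial_id`, `parent_sex`, `eye_color`,
#' `body_color`, one row per fly, as read from the assay's scoring CSV) into
#' vials and applies [tally_vial()].
#'
#' @param progeny progeny `data.frame`.
#' @return `data.frame` with one row per vial.
#' @export
tally_progeny <- function(progeny) {
  need <- c("vial_id", "parent_sex", "eye_color", "body_color")
  if (!all(need %in% names(progeny)))
    stop("progeny table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  vials <- split(progeny, progeny$vial_id)
  out <- do.call(rbind, lapply(vials, tally_vial))
  out <- out[order(out$vial_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sex germline outcome summaries
#'
#' The unit of analysis is the vial: per parental sex, the unweighted mean
#' of per-vial outcome percentages (each vial counts equally regardless of
#' its progeny number) with SEM = sd / sqrt(n), `n` the vial count.  The
#' pooled-progeny proportion (all flies of a sex pooled) is also reported
#' for reference; the mean of vials is primary because samples are vials
#' and error bars are SEMs across them.
#'
#' @param vials `data.frame` of vial tallies from [tally_progeny()].
#' @return `data.frame` with one row per `parent_sex`: `n_vials`,
#'   `total_progeny`, then `<outcome>_mean`, `<outcome>_sem`,
#'   `<outcome>_pooled` for each of HR, NoDSB_NHEJ, SSA.
#' @export
aggregate_germline <- function(vials) {
  if (nrow(vials) == 0) stop("no vials to aggregate", call. = FALSE)
  lev <- c("HR", "NoDSB_NHEJ", "SSA")
  by_sex <- split(vials, vials$parent_sex)
  rows <- lapply(names(by_sex), function(sx) {
    d <- by_sex[[sx]]
    out <- data.frame(parent_sex = sx, n_vials = nrow(d),
                      total_progeny = sum(d$total),
                      stringsAsFactors = FALSE)
    for (l in lev) {
      out[[paste0(l, "_mean")]] <- mean(d[[l]])
      out[[paste0(l, "_sem")]] <-
        if (nrow(d) >= 2) stats::sd(d[[l]]) / sqrt(nrow(d)) else NA_real_
      out[[paste0(l, "_pooled")]] <-
        100 * sum(d[[paste0("n_", l)]]) / sum(d$total)
    }
    out
  })
  out <- do.call(rbind, rows)
  out[order(out$parent_sex), , drop = FALSE]
}

#' Read a progeny scoring CSV
#'
#' Expects columns `vial_id`, `parent_sex`, `eye_color`, `body_color`, one
#' row per fly; values outside the phenotype enumerations are rejected
#' rather than guessed.
#'
#' @param path CSV file path.
#' @return progeny `data.frame`.
#' @export
read_progeny_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vial_id", "parent_sex", "eye_color", "body_color")
  if (!all(need %in% names(df)))
    stop("progeny CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$eye_color %in% c("red", "white")))
    stop("eye_color values must be 'red' or 'white'", call. = FALSE)
  if (!all(df$body_color %in% c("brown", "yellow")))
    stop("body_color values must be 'brown' or 'yellow'", call. = FALSE)
  if (!all(df$parent_sex %in% c("male", "female")))
    stop("parent_sex values must be 'male' or 'female'", call. = FALSE)
  if (any(!nzchar(as.character(df$vial_id))))
    stop("vial_id must be non-empty", call. = FALSE)
  df
}
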