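#' Configuration for trace decomposition
#'
#' Collects the tunable geometry and thresholds of the indel-spectrum fit.
#' Windows are in control-trace coordinates and resolved against the break
#' position at decomposition time when left `NULL`:
#'
#' * `align_window` (registration and background QC) defaults to
#'   `[break - 100, break - 20]`, upstream of the break where control and
#'   sample must agree.
#' * `decomp_window` defaults to `[break + K + 5, trace_end - K - 10]`.
#'   Starting downstream of `break + K` guarantees no modelled position
#'   overlaps unknown inserted bases, so pure shifting of the control trace
#'   is exact for every shift in `-K..+K`; ending `K` short of the trace
#'   keeps every shifted model inside the control.
#'
#' @param max_indel largest modelled indel size K in bp (default 35; spectra
#'   cover shifts `-K..+K`).
#' @param align_window,decomp_window integer length-2 vectors
#'   `c(start, end)`, or `NULL` for the defaults above.
#' @param background_threshold maximum tolerated pre-break background
#'   fraction for QC pass (default 0.15).
#' @param nonneg_tol weights below this are truncated to zero before
#'   renormalisation (default 1e-9).
#' @param offset_range registration offsets searched, `-offset_range ..
#'   +offset_range` (default 20).
#' @param min_registration_cor minimum cross-channel correlation for a
#'   usable registration (default 0.8).
#' @return a `decomposition_config` list.
#' @export
decomposition_config <- function(max_indel = 35L, align_window = NULL,
                                 decomp_window = NULL,
                                 background_threshold = 0.15,
                                 nonneg_tol = 1e-9, offset_range = 20L,
                                 min_registration_cor = 0.8) {
  max_indel <- as.integer(max_indel)
  if (max_indel < 1L) stop("max_indel must be >= 1", call. = FALSE)
  if (background_threshold < 0 || background_threshold > 1)
    stop("background_threshold must be in [0, 1]", call. = FALSE)
  structure(list(max_indel = max_indel, align_window = align_window,
                 decomp_window = decomp_window,
                 background_threshold = background_threshold,
                 nonneg_tol = nonneg_tol,
                 offset_range = as.integer(offset_range),
                 min_registration_cor = min_registration_cor),
            class = "decomposition_config")
}

# resolve window defaults against break position and trace length; enforce
# geometry needed for the shifted models to stay in bounds
resolve_windows <- function(cfg, break_position, trace_len) {
  K <- cfg$max_indel
  aw <- cfg$align_window %||% c(break_position - 100L, break_position - 20L)
  dw <- cfg$decomp_window %||%
    c(break_position + K + 5L, trace_len - K - 10L)
  aw <- as.integer(aw); dw <- as.integer(dw)
  if (aw[1] < 1L || aw[2] <= aw[1] || aw[2] >= break_position)
    stop("align_window must lie upstream of the break and inside the trace",
         call. = FALSE)
  if (dw[1] <= break_position + K)
    stop("decomp_window must start after break + max_indel", call. = FALSE)
  if (dw[2] <= dw[1])
    stop("decomp_window is empty; trace too short for max_indel = ", K,
         call. = FALSE)
  if (dw[1] - K < 1L || dw[2] + K > trace_len)
    stop("decomp_window out of control bounds for extreme shifts ",
         "(need positions ", dw[1] - K, "..", dw[2] + K, ")", call. = FALSE)
  list(align = aw, decomp = dw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Register a sample trace against its control
#'
#' Finds the integer offset `d` (sample position `p` corresponds to control
#' position `p - d`) maximising the cross-channel Pearson correlation between
#' sample and control over the upstream alignment window.  Ties prefer the
#' smallest `|d|`.
#'
#' @param control,sample [trace_data] objects on a shared coordinate frame.
#' @param cfg a [decomposition_config()].
#' @param break_position break point in control coordinates (e.g. from
#'   [locate_recognition_site()]).
#' @return integer offset; errors when the best correlation falls below
#'   `cfg$min_registration_cor` (sample unusable).
#' @export
estimate_offset <- function(control, sample, cfg = decomposition_config(),
                            break_position) {
  win <- resolve_windows(cfg, break_position, nrow(control))$align
  w <- seq(win[1], win[2])
  cm <- trace_matrix(control)
  sm <- trace_matrix(sample)
  ref_vec <- as.vector(cm[, w])
  offs <- seq(-cfg$offset_range, cfg$offset_range)
  score <- vapply(offs, function(d) {
    idx <- w + d
    if (idx[1] < 1L || idx[length(idx)] > ncol(sm)) return(-Inf)
    s <- as.vector(sm[, idx])
    if (stats::sd(s) == 0 || stats::sd(ref_vec) == 0) return(-Inf)
    stats::cor(s, ref_vec)
  }, numeric(1))
  best <- max(score)
  if (!is.finite(best) || best < cfg$min_registration_cor)
    stop("registration failed: best alignment correlation ",
         signif(best, 3), " < ", cfg$min_registration_cor, call. = FALSE)
  cand <- offs[score >= best - 1e-12]
  cand[order(abs(cand), cand)][1]
}

#' Shifted-control model matrix
#'
#' For each shift `k` in `-K..+K`, the model predicts the sample's
#' four-channel signal over the decomposition window as the control signal
#' displaced by `k`: for a net indel of `k` bases, sample position `p`
#' corresponds to control position `p - k`.  Channels are stacked
#' position-major (A, C, G, T per position).
#'
#' @inheritParams estimate_offset
#' @param control a [trace_data] control trace.
#' @return numeric matrix with `4 * window_length` rows and `2K + 1` columns
#'   named by shift; attribute `window` carries the resolved window.
#' @export
build_shifted_models <- function(control, cfg = decomposition_config(),
                                 break_position) {
  K <- cfg$max_indel
  dw <- resolve_windows(cfg, break_position, nrow(control))$decomp
  w <- seq(dw[1], dw[2])
  cm <- trace_matrix(control)
  shifts <- seq(-K, K)
  M <- vapply(shifts, function(k) as.vector(cm[, w - k]),
              numeric(4L * length(w)))
  colnames(M) <- as.character(shifts)
  attr(M, "window") <- dw
  attr(M, "shifts") <- shifts
  M
}

#' Pre-break background fraction of a trace
#'
#' Mean, over the window positions, of the fraction of total intensity not
#' carried by the dominant channel.  Used as the quality screen: samples
#' with high background are excluded from classification.
#'
#' @param trace a [trace_data] object.
#' @param window integer `c(start, end)` upstream of the break, length
#'   >= 20 positions.
#' @return fraction in `[0, 1]`.
#' @export
background_qc <- function(trace, window) {
  stopifnot(is_trace_data(trace))
  window <- as.integer(window)
  w <- seq(window[1], window[2])
  if (length(w) < 20L)
    stop("background window must cover at least 20 positions", call. = FALSE)
  if (w[1] < 1L || w[length(w)] > nrow(trace))
    stop("background window out of trace bounds", call. = FALSE)
  m <- trace_matrix(trace)[, w, drop = FALSE]
  tot <- colSums(m)
  keep <- tot > 0
  if (!any(keep))
    stop("all-zero signal in background window", call. = FALSE)
  frac <- (tot[keep] - apply(m[, keep, drop = FALSE], 2, max)) / tot[keep]
  mean(frac)
}

#' Normalized indel spectrum
#'
#' Container for the result of [decompose()]: non-negative weights over
#' shifts `-K..+K` summing to 1, the fit's `r_squared`, the pre-break
#' `background` fraction, and the QC verdict.
#'
#' @param weights named numeric vector (names are signed shifts), all
#'   >= 0, summing to 1 within 1e-9.
#' @param r_squared goodness of fit in `[0, 1]`.
#' @param background pre-break background fraction in `[0, 1]`.
#' @param qc_pass logical QC verdict.
#' @param window_used integer `c(start, end)` decomposition window.
#' @param t_stat optional named per-component t statistics (reporting only).
#' @param offset registration offset applied to the sample.
#' @return an `indel_spectrum` object.
#' @export
indel_spectrum <- function(weights, r_squared, background, qc_pass,
                           window_used = NA_integer_, t_stat = NULL,
                           offset = 0L) {
  if (is.null(names(weights)))
    stop("weights must be named by signed shift", call. = FALSE)
  if (any(weights < 0))
    stop("spectrum weights must be non-negative", call. = FALSE)
  if (isTRUE(qc_pass) && abs(sum(weights) - 1) > 1e-9)
    stop("spectrum weights must sum to 1", call. = FALSE)
  if (r_squared < 0 || r_squared > 1)
    stop("r_squared must be in [0, 1]", call. = FALSE)
  structure(list(weights = weights, r_squared = r_squared,
                 background = background, qc_pass = isTRUE(qc_pass),
                 window_used = window_used, t_stat = t_stat,
                 offset = as.integer(offset)),
            class = "indel_spectrum")
}

#' @export
print.indel_spectrum <- function(x, ...) {
  top <- sort(x$weights[x$weights > 0.005], decreasing = TRUE)
  cat("Indel spectrum over shifts ", names(x$weights)[1], "..",
      names(x$weights)[length(x$weights)], "\n", sep = "")
  cat("  R^2 = ", signif(x$r_squared, 4), ", background = ",
      signif(x$background, 3), ", QC ",
      if (x$qc_pass) "pass" else "FAIL", "\n", sep = "")
  if (length(top))
    cat(paste0("  shift ", names(top), ": ", signif(top, 4),
               collapse = "\n"), "\n")
  invisible(x)
}

#' Decompose a sample trace into an indel spectrum
#'
#' Fits the sample's stacked four-channel signal over the decomposition
#' window as a non-negative mixture of indel-shifted copies of the control
#' trace, by non-negative least squares (Lawson-Hanson).  Weights below
#' `cfg$nonneg_tol` are truncated and the remainder renormalised to sum 1;
#' `r_squared = 1 - SS_res / SS_tot` over the window; QC passes when the
#' sample's pre-break background fraction is at most
#' `cfg$background_threshold`.  The module is deterministic given its
#' inputs.
#'
#' @param control,sample [trace_data] objects.
#' @param ref a [reference_construct], or an integer break position in
#'   control coordinates.
#' @param cfg a [decomposition_config()].
#' @return an [indel_spectrum()].  A spectrum failing QC is still returned
#'   (flagged); downstream [classify_spectrum()] refuses it.
#' @examples
#' ref <- make_reference(seed = 1)
#' pr <- simulate_trace_pair(ref, truth = c(`0` = 0.6, `-23` = 0.4),
#'                           params = trace_sim_params(seed = 2))
#' sp <- decompose(pr$control, pr$sample, ref)
#' round(sp$weights[c("0", "-23")], 3)
#' @export
decompose <- function(control, sample, ref, cfg = decomposition_config()) {
  stopifnot(is_trace_data(control), is_trace_data(sample))
  break_position <- if (inherits(ref, "reference_construct"))
    locate_recognition_site(ref) else as.integer(ref)
  win <- resolve_windows(cfg, break_position, nrow(control))
  offset <- estimate_offset(control, sample, cfg, break_position)
  background <- background_qc(sample, win$align + offset)
  M <- build_shifted_models(control, cfg, break_position)
  w_idx <- seq(win$decomp[1], win$decomp[2]) + offset
  sm <- trace_matrix(sample)
  if (w_idx[length(w_idx)] > ncol(sm) || w_idx[1] < 1L)
    stop("sample trace does not cover the decomposition window",
         call. = FALSE)
  b <- as.vector(sm[, w_idx])
  if (all(b == 0))
    stop("degenerate sample: all-zero signal in decomposition window",
         call. = FALSE)
  x <- pracma::lsqnonneg(M, b)$x
  active <- which(x > cfg$nonneg_tol)
  if (length(active) == 0L)
    stop("degenerate fit: no non-zero spectrum components", call. = FALSE)
  if (qr(M[, active, drop = FALSE])$rank < length(active))
    warning("repetitive control trace: decomposition may be non-unique",
            call. = FALSE)
  fitted <- as.vector(M %*% x)
  ss_res <- sum((b - fitted)^2)
  ss_tot <- sum((b - mean(b))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  t_stat <- component_t_stats(M, b, x, active, ss_res, cfg$nonneg_tol)
  w <- x
  w[w <= cfg$nonneg_tol] <- 0
  weights <- stats::setNames(w / sum(w), colnames(M))
  indel_spectrum(weights, r_squared = r2, background = background,
                 qc_pass = background <= cfg$background_threshold,
                 window_used = win$decomp, t_stat = t_stat, offset = offset)
}

# per-component t statistics from the active-set least-squares covariance;
# reporting only, never used to gate the spectrum
component_t_stats <- function(M, b, x, active, ss_res, tol) {
  t_stat <- stats::setNames(rep(NA_real_, ncol(M)), colnames(M))
  n <- length(b)
  p <- length(active)
  if (n <= p) return(t_stat)
  sigma2 <- ss_res / (n - p)
  XtX <- crossprod(M[, active, drop = FALSE])
  inv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(inv)) return(t_stat)
  se <- sqrt(pmax(diag(inv), 0) * sigma2)
  t_stat[active] <- ifelse(se > 0, x[active] / se, Inf)
  t_stat
}
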