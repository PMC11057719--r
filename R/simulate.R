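#' Chromatogram simulation parameters
#'
#' Noise model for rendered traces: the called channel at each position
#' draws from `Normal(signal_mean * (1 - decay_rate)^(pos - 1), signal_sd)`
#' truncated at zero, the three other channels from folded
#' `Normal(0, background_sd)`.  Real chromatogram noise is more structured;
#' this is the simplest model exercising the mixture-of-shifts structure the
#' decomposition assumes, including QC failures (raise `background_sd` to
#' force them).
#'
#' @param signal_mean called-channel peak height (default 1).
#' @param signal_sd called-channel noise sd (default 0.05).
#' @param background_sd non-called-channel noise sd (default 0.02).
#' @param decay_rate per-position multiplicative amplitude decay in
#'   `[0, 0.01]` (default 0).
#' @param seed integer RNG seed; every generator in this module is a pure
#'   function of its parameters and seed.
#' @return a `trace_sim_params` list.
#' @export
trace_sim_params <- function(signal_mean = 1, signal_sd = 0.05,
                             background_sd = 0.02, decay_rate = 0,
                             seed = 1L) {
  if (signal_sd < 0 || background_sd < 0)
    stop("noise sds must be >= 0", call. = FALSE)
  if (decay_rate < 0 || decay_rate > 0.01)
    stop("decay_rate must be in [0, 0.01]", call. = FALSE)
  structure(list(signal_mean = signal_mean, signal_sd = signal_sd,
                 background_sd = background_sd, decay_rate = decay_rate,
                 seed = as.integer(seed)), class = "trace_sim_params")
}

#' Generate a synthetic DR-white reference construct
#'
#' Draws a random non-repetitive wild-type amplicon containing the SacI
#' motif `GAGCTC` exactly once, then builds the Sce amplicon by inserting,
#' inside the SacI site, a 23-bp cassette consisting of the 18-bp I-SceI
#' recognition sequence plus 5 bases duplicating the interrupted SacI
#' nucleotides, so that removing the full insertion restores the wild type
#' and `expected_hr_shift()` is -23 by construction.
#'
#' @param seed integer seed.
#' @param amplicon_len wild-type amplicon length in bp (>= 400 so the
#'   default decomposition windows fit with K = 35).
#' @return a [reference_construct()].
#' @export
make_reference <- function(seed = 1L, amplicon_len = 600L) {
  amplicon_len <- as.integer(amplicon_len)
  if (amplicon_len < 400L)
    stop("amplicon_len must be >= 400", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    m <- as.integer(floor(amplicon_len * 0.4))  # SacI motif start
    repeat {
      left <- paste(sample(c("A", "C", "G", "T"), m - 1L, replace = TRUE),
                    collapse = "")
      right <- paste(sample(c("A", "C", "G", "T"),
                            amplicon_len - m - 5L, replace = TRUE),
                     collapse = "")
      wt <- paste0(left, SACI_MOTIF, right)
      ins <- paste0(ISCEI_RECOGNITION, "GAGCT")  # 18 + 5 = 23 bp
      sce <- paste0(substr(wt, 1L, m + 2L), ins,
                    substr(wt, m + 3L, amplicon_len))
      ok <- count_matches(SACI_MOTIF, wt) == 1L &&
        count_matches(ISCEI_RECOGNITION, sce) == 1L
      if (ok) break
    }
    reference_construct(wt, sce, recognition_start = m + 3L,
                        insertion_len = 23L, cut_offset = 9L)
  })
}

count_matches <- function(pat, x) {
  hits <- gregexpr(pat, x, fixed = TRUE)[[1]]
  sum(hits > 0)
}

# render a clean sequence into a noisy four-channel trace (uses the current
# RNG stream; callers own seeding)
render_trace <- function(seq, params, length_out = nchar(seq)) {
  stopifnot(length_out <= nchar(seq))
  bases <- strsplit(substr(seq, 1L, length_out), "", fixed = TRUE)[[1]]
  n <- length(bases)
  amp <- params$signal_mean * (1 - params$decay_rate)^(seq_len(n) - 1)
  m <- matrix(abs(stats::rnorm(4L * n, 0, params$background_sd)),
              nrow = 4L, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- cbind(match(bases, c("A", "C", "G", "T")), seq_len(n))
  m[idx] <- pmax(0, stats::rnorm(n, amp, params$signal_sd))
  m
}

channels_to_trace <- function(m) {
  trace_data(data.frame(A = m["A", ], C = m["C", ], G = m["G", ],
                        T = m["T", ]))
}

#' Simulate a control/sample chromatogram pair with known mixture truth
#'
#' The control is rendered from the Sce amplicon.  The sample is the
#' truth-weighted sum of renderings of indel-bearing variants of the Sce
#' amplicon (deletion of `|k|` bases at the break for `k < 0`, insertion of
#' `k` random bases for `k > 0`), each with independent noise.  All traces
#' are truncated to a common length `nchar(sce) - max_indel` so deletion
#' variants cover every rendered position.
#'
#' @param ref a [reference_construct()].
#' @param truth named numeric vector of mixture weights; names are signed
#'   shifts with support inside `[-max_indel, max_indel]`, weights >= 0
#'   summing to 1.
#' @param params a [trace_sim_params()]; its `seed` makes the pair
#'   reproducible bit for bit.
#' @param max_indel largest modelled indel (default 35).
#' @return list with `control` and `sample` [trace_data] objects and a
#'   `manifest` list recording truth, seed and break position.
#' @export
simulate_trace_pair <- function(ref, truth, params = trace_sim_params(),
                                max_indel = 35L) {
  stopifnot(inherits(ref, "reference_construct"))
  shifts <- as.integer(names(truth))
  if (length(shifts) == 0 || anyNA(shifts))
    stop("truth must be named by signed integer shifts", call. = FALSE)
  if (any(abs(shifts) > max_indel))
    stop("truth support outside +/-", max_indel, call. = FALSE)
  if (any(truth < 0) || abs(sum(truth) - 1) > 1e-8)
    stop("truth weights must be >= 0 and sum to 1", call. = FALSE)
  brk <- locate_recognition_site(ref)
  len <- nchar(ref$sce_seq)
  n_out <- len - as.integer(max_indel)
  withr::with_seed(params$seed, {
    control <- channels_to_trace(render_trace(ref$sce_seq, params,
                                              length_out = len))
    acc <- matrix(0, nrow = 4L, ncol = n_out,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (i in seq_along(shifts)) {
      if (truth[i] == 0) next
      variant <- indel_variant(ref$sce_seq, brk, shifts[i])
      acc <- acc + truth[i] * render_trace(variant, params,
                                           length_out = n_out)
    }
    sample <- channels_to_trace(acc)
  })
  list(control = control, sample = sample,
       manifest = list(truth = truth, seed = params$seed,
                       break_position = brk, max_indel = max_indel))
}

# apply a net indel of k bases immediately downstream of the break
indel_variant <- function(seq, break_position, k) {
  if (k == 0L) return(seq)
  if (k < 0L)
    return(paste0(substr(seq, 1L, break_position),
                  substr(seq, break_position + 1L - k, nchar(seq))))
  filler <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                  collapse = "")
  paste0(substr(seq, 1L, break_position), filler,
         substr(seq, break_position + 1L, nchar(seq)))
}

#' Default NHEJ indel-size distribution
#'
#' Geometric decay in `|k|` with a configurable deletion bias, over shifts
#' `-max_indel..+max_indel` excluding 0 and the HR shift.  The assayed
#' system's true NHEJ size spectrum is unknown; this shape is a documented
#' modelling choice, config-exposed and recorded in manifests.
#'
#' @param max_indel largest shift (default 35).
#' @param hr_shift excluded HR-diagnostic shift (default -23).
#' @param decay geometric ratio per extra base (default 0.6).
#' @param deletion_bias weight multiplier for deletions vs insertions
#'   (default 2).
#' @return named numeric vector of probabilities summing to 1.
#' @export
nhej_shift_spectrum <- function(max_indel = 35L, hr_shift = -23L,
                                decay = 0.6, deletion_bias = 2) {
  shifts <- setdiff(seq(-max_indel, max_indel), c(0L, hr_shift))
  w <- ifelse(shifts < 0, deletion_bias, 1) * decay^(abs(shifts) - 1)
  stats::setNames(w / sum(w), shifts)
}

#' Outcome profile for a simulated tissue cohort
#'
#' @param label group label (tissue/sex/condition).
#' @param f_noDSB,f_HR,f_NHEJ outcome fractions summing to 1: no-DSB
#'   (shift 0), HR (the -23 deletion) and NHEJ with indels.
#' @param nhej_spectrum distribution of the NHEJ mass over shifts; default
#'   [nhej_shift_spectrum()].
#' @param tissue,sex optional metadata labels.
#' @return an `outcome_profile` list; `rel_HR_truth` is the implied
#'   HR percentage of detectable events.
#' @export
outcome_profile <- function(label, f_noDSB, f_HR, f_NHEJ,
                            nhej_spectrum = nhej_shift_spectrum(),
                            tissue = NA_character_, sex = NA_character_) {
  f <- c(f_noDSB, f_HR, f_NHEJ)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("outcome fractions must be >= 0 and sum to 1", call. = FALSE)
  if (abs(sum(nhej_spectrum) - 1) > 1e-8 || any(nhej_spectrum < 0))
    stop("nhej_spectrum must be a probability distribution", call. = FALSE)
  if (any(as.integer(names(nhej_spectrum)) %in% c(0L, -23L) &
          nhej_spectrum > 0))
    stop("nhej_spectrum must place no mass at 0 or the HR shift",
         call. = FALSE)
  structure(list(label = label, f_noDSB = f_noDSB, f_HR = f_HR,
                 f_NHEJ = f_NHEJ, nhej_spectrum = nhej_spectrum,
                 tissue = tissue, sex = sex,
                 rel_HR_truth = if (f_HR + f_NHEJ > 0)
                   100 * f_HR / (f_HR + f_NHEJ) else NA_real_),
            class = "outcome_profile")
}

#' Preset outcome profiles for the assayed tissue groups
#'
#' One preset per molecularly assayed group, encoding its HR share of
#' detectable repair events and (where reported) its detectable fraction.
#' For groups whose detectable fraction was not reported the presets use
#' 0.5 (0.725 for 3-6 h embryos, between the flanking embryo ages); the
#' relative HR/NHEJ split, the quantity the cohorts are scored on, does not
#' depend on it.
#'
#' @return `data.frame` with columns `label`, `tissue`, `sex`,
#'   `rel_HR_pct` (HR percentage of detectable events), `f_detect`
#'   (detectable fraction), `n_samples` (the assayed cohort size), and the
#'   implied `f_noDSB`, `f_HR`, `f_NHEJ`.
#' @seealso [preset_profile()] to turn a row into an [outcome_profile()];
#'   [germline_profiles()] for the phenotypic germline groups.
#' @export
tissue_profiles <- function() {
  df <- data.frame(
    label = c("embryo_0_3h", "embryo_3_6h", "embryo_6_20h",
              "whole_fly_male", "whole_fly_female",
              "salivary_gland_male", "salivary_gland_female",
              "larval_brain_male", "larval_brain_female",
              "wing_disc_male", "adult_head_male", "adult_head_female"),
    tissue = c("embryo", "embryo", "embryo", "whole_fly", "whole_fly",
               "salivary_gland", "salivary_gland", "larval_brain",
               "larval_brain", "wing_disc", "adult_head", "adult_head"),
    sex = c("mixed", "mixed", "mixed", "male", "female", "male", "female",
            "male", "female", "male", "male", "female"),
    rel_HR_pct = c(56.2, 60.5, 63.9, 47.3, 48.1, 14.1, 14.9,
                   80.4, 79.7, 63.6, 28.1, 25.7),
    f_detect = c(0.652, 0.725, 0.798, 0.20, 0.20, 0.5, 0.5,
                 0.5, 0.5, 0.5, 0.5, 0.5),
    n_samples = c(22L, 22L, 22L, 35L, 33L, 11L, 11L, 23L, 25L, 8L,
                  38L, 38L),
    stringsAsFactors = FALSE)
  df$f_noDSB <- 1 - df$f_detect
  df$f_HR <- df$f_detect * df$rel_HR_pct / 100
  df$f_NHEJ <- df$f_detect * (1 - df$rel_HR_pct / 100)
  df
}

#' @param label a `label` from [tissue_profiles()].
#' @rdname tissue_profiles
#' @export
preset_profile <- function(label) {
  df <- tissue_profiles()
  i <- match(label, df$label)
  if (is.na(i))
    stop("unknown profile '", label, "'; see tissue_profiles()",
         call. = FALSE)
  outcome_profile(df$label[i], df$f_noDSB[i], df$f_HR[i], df$f_NHEJ[i],
                  tissue = df$tissue[i], sex = df$sex[i])
}

#' Preset outcome probabilities for the premeiotic germline groups
#'
#' Per-sex mean outcome percentages of the phenotypic readout (HR,
#' no-DSB/NHEJ, SSA), with the vial counts and mean progeny per vial of the
#' assayed cohorts.
#'
#' @return `data.frame` with one row per parent sex.
#' @export
germline_profiles <- function() {
  data.frame(parent_sex = c("male", "female"),
             p_HR = c(0.330, 0.118),
             p_NoDSB_NHEJ = c(0.621, 0.866),
             p_SSA = c(0.049, 0.016),
             n_vials = c(66L, 59L),
             mean_progeny = c(89, 47),
             stringsAsFactors = FALSE)
}

#' Simulate a tissue cohort of trace pairs with per-sample truth
#'
#' Per sample, the outcome fractions are jittered by a Dirichlet
#' perturbation (concentration `jitter_concentration * f`; 0 disables
#' jitter) so cohort SEMs are non-degenerate, the truth spectrum places
#' `f_HR` at -23, `f_noDSB` at 0 and spreads `f_NHEJ` over the profile's
#' NHEJ spectrum, and a trace pair is rendered with an independent
#' per-sample seed derived from `seed`.
#'
#' @param profile an [outcome_profile()] (e.g. from [preset_profile()]).
#' @param n_samples cohort size.
#' @param params a [trace_sim_params()] (its `seed` field is ignored here).
#' @param seed master seed for the cohort.
#' @param ref optional [reference_construct()]; defaults to
#'   `make_reference(seed)`.
#' @param jitter_concentration Dirichlet concentration (default 200).
#' @param max_indel largest modelled indel (default 35).
#' @return list with `ref`, `pairs` (list of [simulate_trace_pair()]
#'   results) and `manifest` (`data.frame` of per-sample true fractions and
#'   seeds, plus the profile as an attribute).
#' @export
simulate_cohort <- function(profile, n_samples, params = trace_sim_params(),
                            seed = 1L, ref = NULL,
                            jitter_concentration = 200, max_indel = 35L) {
  stopifnot(inherits(profile, "outcome_profile"), n_samples >= 1)
  if (is.null(ref)) ref <- make_reference(seed)
  f0 <- c(profile$f_noDSB, profile$f_HR, profile$f_NHEJ)
  withr::with_seed(as.integer(seed), {
    sample_seeds <- sample.int(.Machine$integer.max - 1L, n_samples)
    fs <- t(vapply(seq_len(n_samples), function(i) {
      if (jitter_concentration <= 0) return(f0)
      g <- vapply(f0 * jitter_concentration, function(a)
        if (a > 0) stats::rgamma(1, shape = a) else 0, numeric(1))
      g / sum(g)
    }, numeric(3)))
  })
  pairs <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    truth <- c(stats::setNames(fs[i, 1], "0"),
               stats::setNames(fs[i, 2], "-23"),
               fs[i, 3] * profile$nhej_spectrum)
    truth <- truth[truth > 0]
    p_i <- params
    p_i$seed <- sample_seeds[i]
    pairs[[i]] <- simulate_trace_pair(ref, truth, p_i,
                                      max_indel = max_indel)
  }
  manifest <- data.frame(sample_id = sprintf("%s_s%02d", profile$label,
                                             seq_len(n_samples)),
                         f_noDSB = fs[, 1], f_HR = fs[, 2],
                         f_NHEJ = fs[, 3], seed = sample_seeds,
                         stringsAsFactors = FALSE)
  attr(manifest, "profile") <- profile
  list(ref = ref, pairs = pairs, manifest = manifest)
}

#' Simulate a germline progeny table
#'
#' Per vial, the progeny count draws from a Poisson truncated at >= 1 and
#' outcomes from a multinomial with probabilities `p`; phenotypes are
#' rendered by inverting the scoring rule (HR -> red/brown, no-DSB/NHEJ ->
#' white/brown, SSA -> white/yellow).
#'
#' @param p length-3 numeric, probabilities of (HR, NoDSB_NHEJ, SSA),
#'   summing to 1.
#' @param n_vials number of vials.
#' @param mean_progeny Poisson mean progeny per vial (> 0).
#' @param seed integer seed.
#' @param parent_sex `"male"` or `"female"`.
#' @return progeny `data.frame` (`vial_id`, `parent_sex`, `eye_color`,
#'   `body_color`) with a `manifest` attribute recording `p` and the seed.
#' @export
simulate_germline_cohort <- function(p, n_vials, mean_progeny, seed = 1L,
                                     parent_sex = "male") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be 3 probabilities (HR, NoDSB_NHEJ, SSA) summing to 1",
         call. = FALSE)
  if (mean_progeny <= 0) stop("mean_progeny must be > 0", call. = FALSE)
  pheno <- data.frame(outcome = c("HR", "NoDSB_NHEJ", "SSA"),
                      eye_color = c("red", "white", "white"),
                      body_color = c("brown", "brown", "yellow"),
                      stringsAsFactors = FALSE)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(n_vials), function(v) {
      n <- 0L
      while (n < 1L) n <- stats::rpois(1, mean_progeny)
      counts <- as.integer(stats::rmultinom(1, n, p))
      idx <- rep(1:3, counts)
      data.frame(vial_id = sprintf("%s_v%03d", parent_sex, v),
                 parent_sex = parent_sex,
                 eye_color = pheno$eye_color[idx],
                 body_color = pheno$body_color[idx],
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest") <- list(p = stats::setNames(p, pheno$outcome),
                                n_vials = n_vials,
                                mean_progeny = mean_progeny, seed = seed,
                                parent_sex = parent_sex)
  out
}
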