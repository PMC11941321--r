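#' Configuration of the synthetic multimodal rating experiment
#'
#' Settings for the seeded generator that emulates the structure of the
#' multimodal SAM-valence study: subjects rate, on a bounded valence scale,
#' pairs of stimulus blocks built from extreme positive/negative pictures
#' and sounds. Bivalent (picture + sound) blocks are integrated by a
#' centred weighted mean with a multiplicative negativity bias — an explicit
#' emulation of the reported nonlinearity and negative-image dominance, not
#' a published generative equation.
#'
#' @param n_subjects Number of subjects (default 227).
#' @param scale_min,scale_max Rating scale bounds (default 1 and 9, the
#'   standard 9-point SAM convention).
#' @param w_p,w_s Picture and sound weights, non-negative, summing to 1.
#' @param lambda_neg Negativity-dominance multiplier applied to negative
#'   centred components, >= 1 (default 1.5).
#' @param noise_sd Rating noise standard deviation in scale units
#'   (default 1).
#' @param nominal_positive,nominal_negative Nominal valences of the extreme
#'   positive/negative blocks (defaults 8 and 2, symmetric about the
#'   midpoint).
#' @param seed Integer seed (default 1).
#' @return An object of class `cogwell_experiment_config`.
#' @export
experiment_config <- function(n_subjects = 227, scale_min = 1, scale_max = 9,
                              w_p = 0.5, w_s = 0.5, lambda_neg = 1.5,
                              noise_sd = 1, nominal_positive = 8,
                              nominal_negative = 2, seed = 1) {
  if (scale_min >= scale_max) stop("scale_min must be < scale_max", call. = FALSE)
  if (w_p < 0 || w_s < 0 || abs(w_p + w_s - 1) > 1e-12) {
    stop("weights must be >= 0 and sum to 1", call. = FALSE)
  }
  if (lambda_neg < 1) stop("lambda_neg must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  mid <- (scale_min + scale_max) / 2
  if (nominal_positive <= mid || nominal_positive > scale_max ||
      nominal_negative >= mid || nominal_negative < scale_min) {
    stop("nominal valences must lie in-scale on the matching side of the ",
         "midpoint", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 scale_min = scale_min, scale_max = scale_max, midpoint = mid,
                 w_p = w_p, w_s = w_s, lambda_neg = lambda_neg,
                 noise_sd = noise_sd, nominal_positive = nominal_positive,
                 nominal_negative = nominal_negative, seed = as.integer(seed)),
            class = "cogwell_experiment_config")
}

#' The eight stimulus combinations of the study design
#'
#' Each session pairs two stimulus blocks, drawn from the unimodal extreme
#' blocks (P+, P-, S+, S-) and the dissonant bivalent videos (P+S-, P-S+).
#' Rows 5-8 reverse the presentation order of the pairings of rows 1-4.
#'
#' @return A data.frame with columns `index` (1..8), `stimulus1`,
#'   `stimulus2`.
#' @export
#' @examples
#' table1_combinations()
table1_combinations <- function() {
  data.frame(
    index = 1:8,
    stimulus1 = c("P+", "P-", "S+", "S-", "P+S-", "P+S-", "P-S+", "P-S+"),
    stimulus2 = c("P+S-", "P-S+", "P-S+", "P+S-", "P+", "S-", "P-", "S+"),
    stringsAsFactors = FALSE
  )
}

#' Integrate picture and sound valences into a bivalent rating
#'
#' Centred weighted mean with negativity dominance: components are centred
#' on the scale midpoint, negative centred components are amplified by
#' `lambda_neg`, the weighted mean is re-anchored at the midpoint, and the
#' result is clipped to the scale. With `lambda_neg > 1` a symmetric
#' positive/negative pair integrates below the midpoint — the dominance of
#' the negative component — and the rule is nonlinear through the
#' sign-dependent amplification and the clipping.
#'
#' @param v_p,v_s Picture and sound valences, within the scale bounds.
#'   Vectorized.
#' @param config An [experiment_config()].
#' @return Combined valence(s), within the scale bounds.
#' @export
#' @examples
#' cfg <- experiment_config()
#' integrate_valence(8, 2, cfg)  # below the midpoint: negativity dominance
integrate_valence <- function(v_p, v_s, config = experiment_config()) {
  stopifnot(inherits(config, "cogwell_experiment_config"))
  if (any(v_p < config$scale_min | v_p > config$scale_max |
          v_s < config$scale_min | v_s > config$scale_max)) {
    stop("valence outside the rating scale [", config$scale_min, ", ",
         config$scale_max, "]", call. = FALSE)
  }
  cp <- v_p - config$midpoint
  cs <- v_s - config$midpoint
  cp <- ifelse(cp < 0, config$lambda_neg * cp, cp)
  cs <- ifelse(cs < 0, config$lambda_neg * cs, cs)
  out <- config$midpoint + config$w_p * cp + config$w_s * cs
  pmin(pmax(out, config$scale_min), config$scale_max)
}

# internal: true (noiseless) valence of a stimulus block label.
# Unimodal blocks pass through their nominal valence unchanged; bivalent
# blocks integrate the two modalities.
block_true_valence <- function(label, config) {
  pos <- config$nominal_positive
  neg <- config$nominal_negative
  vapply(label, function(lb) {
    switch(lb,
           "P+" = pos, "P-" = neg, "S+" = pos, "S-" = neg,
           "P+S-" = integrate_valence(pos, neg, config),
           "P-S+" = integrate_valence(neg, pos, config),
           "P+S+" = integrate_valence(pos, pos, config),
           "P-S-" = integrate_valence(neg, neg, config),
           stop("unknown stimulus label: ", lb, call. = FALSE))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a synthetic rating dataset
#'
#' For each subject, combination and presentation slot, the rating is the
#' block's true valence (pass-through for unimodal blocks, the integration
#' rule for bivalent ones, or a supplied override) plus seeded Gaussian
#' noise, clipped to the scale. Bit-reproducible given the seed.
#'
#' @param config An [experiment_config()].
#' @param true_values Optional length-16 numeric override of the true group
#'   means, ordered by combination then slot (used when the ground truth
#'   comes from a model curve rather than the integration rule).
#' @return A data.frame of class `cogwell_ratings` with columns `subject`,
#'   `combination`, `slot`, `stimulus_label`, `valence`;
#'   `n_subjects * 8 * 2` rows.
#' @export
#' @examples
#' d <- generate_ratings(experiment_config(n_subjects = 5, seed = 42))
#' nrow(d)  # 5 * 8 * 2
generate_ratings <- function(config = experiment_config(),
                             true_values = NULL) {
  stopifnot(inherits(config, "cogwell_experiment_config"))
  comb <- table1_combinations()
  labels <- as.vector(rbind(comb$stimulus1, comb$stimulus2))  # comb-major
  truth <- if (is.null(true_values)) {
    block_true_valence(labels, config)
  } else {
    stopifnot(length(true_values) == 16L)
    as.numeric(true_values)
  }
  n <- config$n_subjects
  df <- data.frame(
    subject = rep(seq_len(n), each = 16L),
    combination = rep(rep(comb$index, each = 2L), times = n),
    slot = rep(rep(1:2, times = 8L), times = n),
    stimulus_label = rep(labels, times = n),
    stringsAsFactors = FALSE
  )
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  noise <- if (config$noise_sd > 0) {
    stats::rnorm(nrow(df), 0, config$noise_sd)
  } else {
    numeric(nrow(df))
  }
  df$valence <- pmin(pmax(rep(truth, times = n) + noise,
                          config$scale_min), config$scale_max)
  class(df) <- c("cogwell_ratings", "data.frame")
  df
}

#' Summarize a rating dataset into an observed response curve
#'
#' Per-group (combination x presentation slot) arithmetic means, ordered by
#' combination index then slot, with a sequential curve index 1..16. The
#' two-column (index, mean_valence) view is the observed curve handed to
#' the fitting procedures.
#'
#' @param dataset A `cogwell_ratings` data.frame from [generate_ratings()].
#' @return A data.frame with columns `index`, `combination`, `slot`,
#'   `stimulus_label`, `mean_valence`.
#' @export
summarize_ratings <- function(dataset) {
  stopifnot(is.data.frame(dataset), nrow(dataset) > 0L)
  agg <- stats::aggregate(valence ~ combination + slot + stimulus_label,
                          data = dataset, FUN = mean)
  agg <- agg[order(agg$combination, agg$slot), ]
  if (nrow(agg) != 16L) {
    stop("missing group: expected all 8 combinations x 2 slots, found ",
         nrow(agg), call. = FALSE)
  }
  data.frame(index = seq_len(nrow(agg)), combination = agg$combination,
             slot = agg$slot, stimulus_label = agg$stimulus_label,
             mean_valence = agg$valence, row.names = NULL)
}
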