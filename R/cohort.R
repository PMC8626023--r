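#' Simulate a per-animal cohort from a study design
#'
#' Draws one animal record per row: continuous endpoints from the design's
#' per-group normal distributions, ordinal and histology endpoints from its
#' categorical distributions, and a daily body-weight trajectory. The
#' trajectory starts at a normally distributed baseline weight and follows a
#' smooth multiplicative day-by-day trend that lands exactly on the animal's
#' drawn final percent change at day 7 — the endpoint is what is
#' parameterized; the within-week shape is a convenience, not a disease
#' model. Ordinal endpoints are drawn independently of the continuous ones.
#' MPO activity draws are truncated at 0 (activity cannot be negative).
#'
#' @param design A [study_design()].
#' @param seed Integer seed; the same design and seed reproduce the cohort
#'   exactly.
#' @return A tibble with one row per animal: `animal_id`, `group`,
#'   `bw_d0` .. `bw_d7` (g), `body_weight_change_pct`, `colon_length` (cm),
#'   `colon_weight` (g), `stool_score`, `ulcer_score`, `fecal_blood`, the
#'   five histology subscore columns, and `mpo_activity` (mU/g).
#' @examples
#' cohort <- generate_cohort(default_design(n_per_group = 5), seed = 1)
#' table(cohort$group)
#' @export
generate_cohort <- function(design, seed = NULL) {
  stopifnot(inherits(design, "study_design"))
  with_seed(seed, {
    rows <- lapply(design$groups, function(g) {
      n <- design$n_per_group
      ep <- design$endpoint_params[design$endpoint_params$group == g, ]
      draw <- function(endpoint) {
        p <- ep[ep$endpoint == endpoint, ]
        stats::rnorm(n, p$mean, p$sd)
      }
      bw_pct <- draw("body_weight_change_pct")
      baseline <- pmax(stats::rnorm(n, design$baseline_weight[["mean"]],
                                    design$baseline_weight[["sd"]]), 1)
      days <- 0:7
      # multiplicative trend: weight on day d = baseline * (1 + pct/100)^(d/7)
      bw <- outer(baseline, days, function(w0, d) w0) *
        (1 + bw_pct / 100)^(matrix(days, nrow = n, ncol = 8, byrow = TRUE) / 7)
      colnames(bw) <- paste0("bw_d", days)

      probs <- design$ordinal_probs[[g]]
      draw_ord <- function(p, scores) sample(scores, n, TRUE, prob = p)
      out <- tibble::tibble(
        group = g,
        body_weight_change_pct = bw_pct,
        colon_length = pmax(draw("colon_length"), 0.1),
        colon_weight = pmax(draw("colon_weight"), 0.01),
        stool_score = draw_ord(probs$stool, 0:3),
        ulcer_score = draw_ord(probs$ulcer, 0:3),
        fecal_blood = draw_ord(probs$blood, 0:1),
        goblet_depletion = draw_ord(probs$goblet, 0:1),
        crypt_abscesses = draw_ord(probs$crypt, 0:1),
        mucosal_architecture = draw_ord(probs$architecture, 1:3),
        muscle_thickening = draw_ord(probs$muscle, 1:3),
        immune_infiltration = draw_ord(probs$infiltration, 1:3),
        mpo_activity = pmax(draw("mpo_activity"), 0)
      )
      dplyr::bind_cols(tibble::as_tibble(bw), out)
    })
    cohort <- dplyr::bind_rows(rows)
    cohort$animal_id <- sprintf(
      "%s_%02d", cohort$group,
      stats::ave(seq_len(nrow(cohort)), cohort$group, FUN = seq_along))
    dplyr::relocate(cohort, "animal_id", "group")
  })
}

#' Synthesize a kinetic MPO trace with a known underlying activity
#'
#' Inverse of [mpo_activity()]: given a target activity in mU per gram of
#' wet tissue, builds the triplicate absorbance readings a plate reader
#' would produce. The enzyme activity in the well is
#' `target_activity * homogenate_concentration * supernatant_volume` mU; the
#' standard curve maps it to an absorbance rate, and each reading is the
#' corresponding straight line through the timepoints plus optional i.i.d.
#' Gaussian read noise. With `noise_sd = 0` the forward computation recovers
#' `target_activity` exactly (to numerical tolerance).
#'
#' @param target_activity MPO activity to encode, mU/g wet tissue; >= 0.
#' @param curve A [standard_curve()]; its slope must be positive.
#' @param noise_sd SD of absorbance read noise (absorbance units; default 0).
#' @param seed Integer seed for the noise draws.
#' @param tissue_mass,homogenate_concentration,supernatant_volume Dilution
#'   bookkeeping passed through to [mpo_kinetics()].
#' @param baseline_absorbance Absorbance at time 0 before any reaction
#'   (default 0.05), so traces stay positive under realistic noise.
#' @param time_s Timepoints in seconds (default `c(0, 30, 60)`).
#' @param n_replicates Number of replicate wells (default 3).
#' @return An [mpo_kinetics()] object.
#' @examples
#' k <- synthesize_mpo_kinetics(10, standard_curve(0.01))
#' mpo_activity(k, standard_curve(0.01)) # 10
#' @export
synthesize_mpo_kinetics <- function(target_activity, curve, noise_sd = 0,
                                    seed = NULL, tissue_mass = 0.03,
                                    homogenate_concentration = 0.030,
                                    supernatant_volume = 0.007,
                                    baseline_absorbance = 0.05,
                                    time_s = c(0, 30, 60), n_replicates = 3) {
  stop_if_not_scalar_number(target_activity, "target_activity", min = 0)
  stopifnot(inherits(curve, "standard_curve"))
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  activity_in_well <- target_activity * homogenate_concentration *
    supernatant_volume
  rate_per_min <- curve$slope * activity_in_well + curve$intercept
  slope_per_s <- rate_per_min / 60
  clean <- matrix(baseline_absorbance + slope_per_s * time_s,
                  nrow = n_replicates, ncol = length(time_s), byrow = TRUE)
  absorbance <- with_seed(seed, {
    clean + matrix(stats::rnorm(length(clean), 0, noise_sd), nrow = n_replicates)
  })
  mpo_kinetics(pmax(absorbance, 0), time_s = time_s,
               tissue_mass = tissue_mass,
               homogenate_concentration = homogenate_concentration,
               supernatant_volume = supernatant_volume)
}

#' Read or write a cohort as CSV
#'
#' One row per animal, columns named exactly as in [generate_cohort()]
#' (body-weight series as `bw_d0` .. `bw_d7`).
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv()` returns a tibble; `write_cohort_csv()`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
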