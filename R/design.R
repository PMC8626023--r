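#' Study design for a synthetic DSS-colitis cohort
#'
#' Describes a multi-arm colitis experiment well enough to simulate it:
#' ordered group labels, animals per group, per-group normal parameters for
#' the continuous endpoints (final body-weight change in percent, colon
#' length in cm, colon weight in g, MPO activity in mU/g), and per-group
#' categorical probabilities for the ordinal endpoints (stool consistency
#' 0-3, ulcer score 0-3, fecal blood 0/1, and the five histology subscores).
#'
#' @param groups Character vector of unique group labels, in display order.
#' @param n_per_group Animals per group; at least 2.
#' @param endpoint_params Data frame with columns `group`, `endpoint`,
#'   `mean`, `sd` (`sd >= 0`), one row per group x continuous endpoint.
#' @param ordinal_probs Named list (one element per group), each a named list
#'   of probability vectors: `stool` and `ulcer` (length 4, scores 0-3),
#'   `blood`, `goblet` and `crypt` (length 2, scores 0-1), `architecture`,
#'   `muscle` and `infiltration` (length 3, scores 1-3). Each vector must sum
#'   to 1.
#' @param baseline_weight Mean and SD (g) of day-0 body weight; default
#'   `c(mean = 24, sd = 1)`, matching 22-26 g adult mice.
#' @return A `study_design` object.
#' @seealso [default_design()] for the standard 5-arm layout,
#'   [generate_cohort()] to simulate from a design.
#' @export
study_design <- function(groups, n_per_group, endpoint_params, ordinal_probs,
                         baseline_weight = c(mean = 24, sd = 1)) {
  if (!is.character(groups) || anyDuplicated(groups)) {
    stop("`groups` must be a character vector of unique labels", call. = FALSE)
  }
  stop_if_not_scalar_number(n_per_group, "n_per_group", min = 2)
  stopifnot(is.data.frame(endpoint_params))
  needed <- c("group", "endpoint", "mean", "sd")
  if (!all(needed %in% names(endpoint_params))) {
    stop("`endpoint_params` needs columns group, endpoint, mean, sd",
         call. = FALSE)
  }
  if (any(endpoint_params$sd < 0)) {
    stop("all endpoint SDs must be >= 0", call. = FALSE)
  }
  missing_grp <- setdiff(groups, endpoint_params$group)
  if (length(missing_grp)) {
    stop("`endpoint_params` missing groups: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  lens <- c(stool = 4L, ulcer = 4L, blood = 2L, goblet = 2L, crypt = 2L,
            architecture = 3L, muscle = 3L, infiltration = 3L)
  for (g in groups) {
    probs <- ordinal_probs[[g]]
    if (is.null(probs)) {
      stop(sprintf("`ordinal_probs` has no entry for group '%s'", g),
           call. = FALSE)
    }
    for (nm in names(lens)) {
      p <- probs[[nm]]
      if (is.null(p) || length(p) != lens[[nm]] || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8) {
        stop(sprintf(
          "ordinal_probs$%s$%s must be %d non-negative probabilities summing to 1",
          g, nm, lens[[nm]]), call. = FALSE)
      }
    }
  }
  structure(
    list(groups = groups, n_per_group = as.integer(n_per_group),
         endpoint_params = tibble::as_tibble(endpoint_params),
         ordinal_probs = ordinal_probs,
         baseline_weight = baseline_weight),
    class = "study_design"
  )
}

#' Default 5-arm DSS-colitis study design
#'
#' The standard layout behind the simulation suite: healthy controls, DSS
#' alone, DSS plus each of two single agents (labelled A and B), and DSS plus
#' the combination. The combination arm's endpoint means equal the DSS mean
#' plus the sum of the two single-drug shifts plus `synergy_shift`, so a
#' shift of 0 encodes pure additivity (no synergy) and a non-zero shift
#' injects a combination effect beyond additivity. Default endpoint values
#' describe a severe acute colitis with modest, non-significant single-drug
#' effects except on MPO activity, and ordinal/histology distributions that
#' separate healthy from colitic arms.
#'
#' @param n_per_group Animals per arm (default 8, within the usual 5-10).
#' @param synergy_shift Either a single number added to every combination-arm
#'   endpoint mean, or a named vector keyed by endpoint (e.g.
#'   `c(mpo_activity = -6)`); endpoint units.
#' @return A [study_design()].
#' @export
default_design <- function(n_per_group = 8, synergy_shift = 0) {
  endpoints <- c("body_weight_change_pct", "colon_length", "colon_weight",
                 "mpo_activity")
  # rows: control, DSS means; single-drug shifts relative to DSS; SDs
  ctrl_mean <- c(body_weight_change_pct = 2,    colon_length = 9.5,
                 colon_weight = 0.25,           mpo_activity = 2)
  dss_mean  <- c(body_weight_change_pct = -12,  colon_length = 7.0,
                 colon_weight = 0.34,           mpo_activity = 8)
  shift_a   <- c(body_weight_change_pct = 1,    colon_length = 0.2,
                 colon_weight = -0.01,          mpo_activity = -1.5)
  shift_b   <- c(body_weight_change_pct = 1,    colon_length = 0.2,
                 colon_weight = -0.01,          mpo_activity = -1.5)
  sds       <- c(body_weight_change_pct = 3,    colon_length = 0.6,
                 colon_weight = 0.035,          mpo_activity = 2)

  syn <- stats::setNames(rep(0, length(endpoints)), endpoints)
  if (length(synergy_shift) == 1 && is.null(names(synergy_shift))) {
    syn[] <- synergy_shift
  } else {
    unknown <- setdiff(names(synergy_shift), endpoints)
    if (length(unknown)) {
      stop("unknown endpoint(s) in `synergy_shift`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    syn[names(synergy_shift)] <- synergy_shift
  }

  groups <- c("control", "DSS", "DSS+A", "DSS+B", "DSS+A+B")
  means <- rbind(control     = ctrl_mean,
                 `DSS`       = dss_mean,
                 `DSS+A`     = dss_mean + shift_a,
                 `DSS+B`     = dss_mean + shift_b,
                 `DSS+A+B`   = dss_mean + shift_a + shift_b + syn)
  endpoint_params <- tidyr::expand_grid(group = groups, endpoint = endpoints)
  endpoint_params$mean <- unname(means[cbind(endpoint_params$group,
                                             endpoint_params$endpoint)])
  endpoint_params$sd <- unname(sds[endpoint_params$endpoint])

  healthy <- list(
    stool = c(0.90, 0.08, 0.02, 0), ulcer = c(0.95, 0.05, 0, 0),
    blood = c(0.98, 0.02), goblet = c(0.95, 0.05), crypt = c(0.97, 0.03),
    architecture = c(0.90, 0.08, 0.02), muscle = c(0.90, 0.08, 0.02),
    infiltration = c(0.90, 0.08, 0.02))
  colitic <- list(
    stool = c(0.05, 0.15, 0.35, 0.45), ulcer = c(0.10, 0.30, 0.35, 0.25),
    blood = c(0.25, 0.75), goblet = c(0.20, 0.80), crypt = c(0.30, 0.70),
    architecture = c(0.10, 0.40, 0.50), muscle = c(0.15, 0.45, 0.40),
    infiltration = c(0.05, 0.35, 0.60))
  ordinal_probs <- stats::setNames(
    c(list(healthy), rep(list(colitic), 4)), groups)

  study_design(groups, n_per_group, endpoint_params, ordinal_probs)
}

#' @export
print.study_design <- function(x, ...) {
  cat("DSS-colitis study design:", length(x$groups), "arms x",
      x$n_per_group, "animals\n")
  cat("  arms:", paste(x$groups, collapse = ", "), "\n")
  cat("  continuous endpoints:",
      paste(unique(x$endpoint_params$endpoint), collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a study design as YAML
#'
#' @param design A [study_design()].
#' @param path File path.
#' @return `read_design_yaml()` returns a [study_design()];
#'   `write_design_yaml()` returns `path` invisibly.
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  obj <- list(
    groups = design$groups,
    n_per_group = design$n_per_group,
    endpoint_params = lapply(seq_len(nrow(design$endpoint_params)),
                             function(i) as.list(design$endpoint_params[i, ])),
    ordinal_probs = design$ordinal_probs,
    baseline_weight = as.list(design$baseline_weight)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ep <- dplyr::bind_rows(lapply(obj$endpoint_params, tibble::as_tibble))
  study_design(
    groups = unlist(obj$groups),
    n_per_group = obj$n_per_group,
    endpoint_params = ep,
    ordinal_probs = lapply(obj$ordinal_probs, function(g) lapply(g, unlist)),
    baseline_weight = unlist(obj$baseline_weight)
  )
}
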