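# Shared fixtures: built in code at test time, nothing stored on disk.

# Minimal two-arm design: control vs DSS, one continuous endpoint profile.
# Used for parameter-recovery and distributional checks where the full
# 5-arm layout is noise.
two_arm_design <- function(n_per_group = 8,
                           length_means = c(control = 10, DSS = 8),
                           length_sd = 0.6) {
  groups <- c("control", "DSS")
  ep <- tidyr::expand_grid(
    group = groups,
    endpoint = c("body_weight_change_pct", "colon_length", "colon_weight",
                 "mpo_activity"))
  base_mean <- c(body_weight_change_pct = 0, colon_length = NA,
                 colon_weight = 0.25, mpo_activity = 5)
  ep$mean <- unname(base_mean[ep$endpoint])
  ep$mean[ep$endpoint == "colon_length"] <- unname(length_means[
    ep$group[ep$endpoint == "colon_length"]])
  sds <- c(body_weight_change_pct = 3, colon_length = length_sd,
           colon_weight = 0.03, mpo_activity = 1.5)
  ep$sd <- unname(sds[ep$endpoint])
  probs <- list(
    stool = c(1, 0, 0, 0), ulcer = c(1, 0, 0, 0), blood = c(1, 0),
    goblet = c(1, 0), crypt = c(1, 0), architecture = c(1, 0, 0),
    muscle = c(1, 0, 0), infiltration = c(1, 0, 0))
  study_design(groups, n_per_group, ep,
               stats::setNames(list(probs, probs), groups))
}

# Default design altered so the combination arm's distribution on `endpoint`
# equals the DSS+A arm's: the mono-vs-combo contrast is then truly null.
null_contrast_design <- function(n_per_group = 8, endpoint = "colon_length") {
  d <- default_design(n_per_group = n_per_group)
  ep <- d$endpoint_params
  mono <- ep$mean[ep$group == "DSS+A" & ep$endpoint == endpoint]
  ep$mean[ep$group == "DSS+A+B" & ep$endpoint == endpoint] <- mono
  d$endpoint_params <- ep
  d
}

# Well-conditioned assay configuration for noisy round-trip checks: a steep
# standard curve so a 10 mU/g tissue activity produces a rate far above the
# read noise.
steep_curve <- function() standard_curve(slope = 10, intercept = 0)
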