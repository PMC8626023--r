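#' Per-group summary of one endpoint
#'
#' Mean, SD, SEM (`SD / sqrt(n)`) and n per group, the quantities behind
#' "mean +/- SEM" panels. Missing endpoint values are excluded with a
#' message reporting how many were dropped.
#'
#' @param cohort Cohort data frame with a `group` column.
#' @param endpoint Name of a numeric cohort column.
#' @return A tibble with columns `group`, `n`, `mean`, `sd`, `sem`.
#' @export
summarize_groups <- function(cohort, endpoint) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  values <- endpoint_values(cohort, endpoint)
  dropped <- sum(is.na(values))
  if (dropped > 0) {
    message(sprintf("summarize_groups: excluding %d missing '%s' value(s)",
                    dropped, endpoint))
  }
  keep <- !is.na(values)
  df <- data.frame(group = cohort$group[keep], value = values[keep])
  out <- dplyr::summarise(
    dplyr::group_by(df, group = factor(group, levels = unique(cohort$group))),
    n = dplyr::n(),
    mean = mean(value),
    sd = stats::sd(value),
    sem = stats::sd(value) / sqrt(dplyr::n()),
    .groups = "drop")
  out$group <- as.character(out$group)
  tibble::as_tibble(out)
}

endpoint_values <- function(cohort, endpoint) {
  if (!endpoint %in% names(cohort)) {
    stop(sprintf("endpoint '%s' not found in cohort", endpoint),
         call. = FALSE)
  }
  v <- cohort[[endpoint]]
  if (all(is.na(v))) {
    stop(sprintf("endpoint '%s' is missing for every animal", endpoint),
         call. = FALSE)
  }
  v
}

#' Significance stars at the conventional thresholds
#'
#' `*` for p < 0.05, `**` < 0.01, `***` < 0.001, `****` < 0.0001; empty
#' string otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", ""), right = FALSE) |>
    as.character()
}

#' Classical tests for one endpoint: normality, ANOVA, pairwise contrasts
#'
#' Runs the parametric battery standard in this field: Shapiro-Wilk
#' normality per group (a rejection warns but does not abort — the analysis
#' proceeds parametrically), one-way ANOVA across all groups, and pooled
#' -variance two-sample t-tests on the configured contrast set with
#' Bonferroni adjustment across that set. By default every non-control arm
#' is contrasted against control and every treated arm against the DSS arm.
#'
#' @param cohort Cohort data frame.
#' @param endpoint Name of a numeric cohort column.
#' @param contrasts List of length-2 character vectors `(group1, group2)`,
#'   or `NULL` for the default set described above.
#' @param alpha Significance threshold used for the flags (default 0.05).
#' @param control_group,dss_group Labels of the healthy-control and
#'   disease-control arms (defaults `"control"`, `"DSS"`).
#' @return A list with `endpoint`, `shapiro` (tibble: group, W, p),
#'   `anova_p`, and `contrasts` (tibble: group1, group2, t, df, p,
#'   p_bonferroni, stars, significant).
#' @export
run_classical_tests <- function(cohort, endpoint, contrasts = NULL,
                                alpha = 0.05, control_group = "control",
                                dss_group = "DSS") {
  values <- endpoint_values(cohort, endpoint)
  keep <- !is.na(values)
  grp <- cohort$group[keep]
  values <- values[keep]
  counts <- table(grp)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("need >= 2 groups with >= 3 animals each", call. = FALSE)
  }
  vars <- tapply(values, grp, stats::var)
  if (all(vars == 0)) {
    stop("zero within-group variance everywhere: F statistic undefined",
         call. = FALSE)
  }

  shapiro <- dplyr::bind_rows(lapply(unique(grp), function(g) {
    v <- values[grp == g]
    if (length(unique(v)) < 3) {
      return(tibble::tibble(group = g, W = NA_real_, p = NA_real_))
    }
    sw <- stats::shapiro.test(v)
    tibble::tibble(group = g, W = unname(sw$statistic), p = sw$p.value)
  }))
  bad <- shapiro$group[!is.na(shapiro$p) & shapiro$p < alpha]
  if (length(bad)) {
    warning(sprintf(
      "Shapiro-Wilk rejects normality of '%s' in group(s): %s; proceeding parametrically",
      endpoint, paste(bad, collapse = ", ")), call. = FALSE)
  }

  anova_p <- summary(stats::aov(values ~ factor(grp)))[[1]][["Pr(>F)"]][1]

  if (is.null(contrasts)) {
    contrasts <- default_contrasts(unique(cohort$group), control_group,
                                   dss_group)
  }
  rows <- lapply(contrasts, function(ct) {
    stopifnot(length(ct) == 2)
    missing_grp <- setdiff(ct, grp)
    if (length(missing_grp)) {
      stop("unknown group label(s): ", paste(missing_grp, collapse = ", "),
           call. = FALSE)
    }
    tt <- stats::t.test(values[grp == ct[1]], values[grp == ct[2]],
                        var.equal = TRUE)
    tibble::tibble(group1 = ct[1], group2 = ct[2],
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
  })
  tab <- dplyr::bind_rows(rows)
  tab$p_bonferroni <- stats::p.adjust(tab$p, method = "bonferroni")
  tab$stars <- significance_stars(tab$p_bonferroni)
  tab$significant <- tab$p_bonferroni < alpha

  list(endpoint = endpoint, shapiro = shapiro, anova_p = anova_p,
       contrasts = tab)
}

default_contrasts <- function(groups, control_group, dss_group) {
  vs_control <- lapply(setdiff(groups, control_group),
                       function(g) c(control_group, g))
  vs_dss <- lapply(setdiff(groups, c(control_group, dss_group)),
                   function(g) c(dss_group, g))
  c(vs_control, if (dss_group %in% groups) vs_dss)
}

#' Bootstrap synergy contrast: monotherapy vs combination
#'
#' Extracts the endpoint values of the monotherapy and combination arms and
#' hands them unmodified to [bootstrap_p()]; the report pairs the observed
#' absolute difference in means with its bootstrap p-value, which is how a
#' mono-vs-combo synergy claim is assessed.
#'
#' @param cohort Cohort data frame.
#' @param contrast Length-2 character vector `(monotherapy group,
#'   combination group)`.
#' @param endpoint Name of a numeric cohort column.
#' @inheritParams bootstrap_p
#' @return A `bootstrap_result` with `contrast` and `endpoint` attached.
#' @export
assess_synergy <- function(cohort, contrast, endpoint,
                           n_iterations = 10000, seed = NULL,
                           strategy = c("pooled", "per-group")) {
  stopifnot(is.data.frame(cohort), length(contrast) == 2)
  missing_grp <- setdiff(contrast, unique(cohort$group))
  if (length(missing_grp)) {
    stop("unknown group label(s): ", paste(missing_grp, collapse = ", "),
         call. = FALSE)
  }
  values <- endpoint_values(cohort, endpoint)
  a <- values[cohort$group == contrast[1]]
  b <- values[cohort$group == contrast[2]]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  res <- bootstrap_p(a, b, n_iterations = n_iterations, seed = seed,
                     strategy = match.arg(strategy))
  res$contrast <- contrast
  res$endpoint <- endpoint
  res
}

#' Default report configuration
#'
#' @param groups Cohort group labels (used to pick the synergy contrasts:
#'   each single-agent arm against the combination arm, identified as the
#'   label containing both agents).
#' @param endpoints Endpoints to analyse.
#' @param alpha,n_iterations Analysis parameters.
#' @param control_group,dss_group Arm labels.
#' @param synergy_contrasts List of `(monotherapy, combination)` pairs, or
#'   `NULL` to pair every `DSS+X` arm with `DSS+A+B`-style combination.
#' @return A named list understood by [build_report()].
#' @export
report_config <- function(groups = c("control", "DSS", "DSS+A", "DSS+B",
                                     "DSS+A+B"),
                          endpoints = c("body_weight_change_pct",
                                        "macroscopic_score", "colon_length",
                                        "colon_weight", "mpo_activity"),
                          alpha = 0.05, n_iterations = 10000,
                          control_group = "control", dss_group = "DSS",
                          synergy_contrasts = NULL) {
  if (is.null(synergy_contrasts)) {
    treated <- setdiff(groups, c(control_group, dss_group))
    combo <- treated[which.max(nchar(treated))]
    monos <- setdiff(treated, combo)
    synergy_contrasts <- lapply(monos, function(m) c(m, combo))
  }
  list(endpoints = endpoints, alpha = alpha, n_iterations = n_iterations,
       control_group = control_group, dss_group = dss_group,
       synergy_contrasts = synergy_contrasts)
}

#' Full study-style analysis report
#'
#' Orchestrates the pipeline end to end for each configured endpoint:
#' per-group mean +/- SEM summaries, Shapiro-Wilk + one-way ANOVA +
#' Bonferroni contrasts against control and DSS, and the mono-vs-combination
#' bootstrap synergy contrasts. If the cohort lacks a `macroscopic_score`
#' column it is scored first via [score_cohort()]. The run is fully
#' reproducible from (cohort, config, seed); each bootstrap contrast gets a
#' deterministic sub-seed derived from `seed`.
#'
#' @param cohort Cohort data frame ([generate_cohort()] /
#'   [read_cohort_csv()] shape).
#' @param config A [report_config()]; `NULL` uses defaults matched to the
#'   cohort's groups.
#' @param seed Integer seed driving all bootstrap resampling.
#' @return A `synergy_report`: list with `summaries`, `classical`,
#'   `synergy` (tibbles/lists keyed by endpoint), plus `config` and `seed`.
#' @export
build_report <- function(cohort, config = NULL, seed = NULL) {
  stopifnot(is.data.frame(cohort))
  config <- config %||% report_config(groups = unique(cohort$group))
  missing_grp <- setdiff(
    c(config$control_group, config$dss_group,
      unlist(config$synergy_contrasts)),
    unique(cohort$group))
  if (length(missing_grp)) {
    stop("config names group(s) absent from cohort: ",
         paste(unique(missing_grp), collapse = ", "), call. = FALSE)
  }
  if ("macroscopic_score" %in% config$endpoints &&
      !"macroscopic_score" %in% names(cohort)) {
    cohort <- score_cohort(cohort, control_group = config$control_group)
  }
  missing_ep <- setdiff(config$endpoints, names(cohort))
  if (length(missing_ep)) {
    stop("config names endpoint(s) absent from cohort: ",
         paste(missing_ep, collapse = ", "), call. = FALSE)
  }

  summaries <- lapply(config$endpoints, function(ep)
    summarize_groups(cohort, ep))
  names(summaries) <- config$endpoints

  classical <- lapply(config$endpoints, function(ep)
    run_classical_tests(cohort, ep, alpha = config$alpha,
                        control_group = config$control_group,
                        dss_group = config$dss_group))
  names(classical) <- config$endpoints

  synergy <- list()
  for (ep in config$endpoints) {
    for (ct in config$synergy_contrasts) {
      sub_seed <- if (is.null(seed)) NULL else
        (seed + 1009L * length(synergy)) %% .Machine$integer.max
      res <- assess_synergy(cohort, ct, ep,
                            n_iterations = config$n_iterations,
                            seed = sub_seed)
      synergy[[length(synergy) + 1]] <- res
    }
  }
  synergy_tab <- dplyr::bind_rows(lapply(synergy, function(r) {
    tibble::tibble(endpoint = r$endpoint, monotherapy = r$contrast[1],
                   combination = r$contrast[2],
                   observed_diff_means = r$observed_test_stat,
                   p_bootstrap = r$p_bootstrap,
                   n_iterations = r$n_iterations,
                   significant = r$p_bootstrap < config$alpha)
  }))

  structure(
    list(summaries = summaries, classical = classical,
         synergy = synergy_tab, synergy_results = synergy,
         config = config, seed = seed),
    class = "synergy_report"
  )
}

#' @export
print.synergy_report <- function(x, ...) {
  cat("DSS-colitis synergy report:", length(x$config$endpoints),
      "endpoints,", nrow(x$synergy), "bootstrap contrasts\n")
  cat("\nMonotherapy vs combination (bootstrap, ",
      x$config$n_iterations, " iterations):\n", sep = "")
  print(as.data.frame(x$synergy), digits = 4)
  invisible(x)
}

#' Serialize a synergy report
#'
#' Writes `report.json` (the whole report), `group_summaries.csv`,
#' `classical_contrasts.csv` and `synergy_contrasts.csv` into `dir`.
#'
#' @param report A [build_report()] result.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "synergy_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- dplyr::bind_rows(report$summaries, .id = "endpoint")
  classical <- dplyr::bind_rows(lapply(report$classical, function(cl) {
    tab <- cl$contrasts
    tab$endpoint <- cl$endpoint
    tab$anova_p <- cl$anova_p
    tab
  }))
  utils::write.csv(summaries, file.path(dir, "group_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(classical, file.path(dir, "classical_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(report$synergy, file.path(dir, "synergy_contrasts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summaries = summaries, classical = classical,
         synergy = report$synergy,
         config = report$config, seed = report$seed),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
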