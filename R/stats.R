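# Group comparisons of physiological parameters: Welch t-tests on
# per-patient region means (the analysis unit is the patient, not the
# pixel, to avoid pseudo-replication), with star annotation at the
# conventional strict thresholds.

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. When
#' both samples have zero variance and equal means, `t = 0`, `p = 1` by
#' convention.
#'
#' @param a,b Numeric samples, each of length >= 2, finite.
#' @param var_equal Use the pooled-variance Student variant instead.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("sample-size error: each group needs n >= 2")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("sample-size error: samples must be finite")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    df <- if (se2 > 0)
      se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    else na + nb - 2
  }
  delta <- mean(a) - mean(b)
  if (se2 == 0) {
    tt <- if (delta == 0) 0 else sign(delta) * Inf
  } else tt <- delta / sqrt(se2)
  p <- if (is.infinite(tt)) 0 else 2 * stats::pt(-abs(tt), df)
  list(t = tt, df = df, p = p)
}

#' Significance star code
#'
#' Strict thresholds: `***` for p < 0.001, `**` for p < 0.01, `*` for
#' p < 0.05, empty otherwise.
#'
#' @param p A p-value in `[0, 1]`.
#' @return One of `""`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1)
    stop("parameter error: p must be in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else ""
}

# The four panel designs compared in the physiological analysis. Each
# returns, per patient, the value entering its group (or NA).
.panel_designs <- function() {
  early <- c("T1", "T2"); late <- c("T3", "T4")
  list(
    A_stomach_vs_cancer = list(
      label = "healthy stomach vs cancer",
      a = function(s) s$tissue_class == "stomach",
      b = function(s) s$tissue_class == "cancer"),
    B_esophagus_vs_cancer = list(
      label = "healthy esophagus vs cancer",
      a = function(s) s$tissue_class == "esophagus",
      b = function(s) s$tissue_class == "cancer"),
    C_stage_cancer = list(
      label = "T1/T2 vs T3/T4 (cancer regions)",
      a = function(s) s$tissue_class == "cancer" & s$tumor_stage %in% early,
      b = function(s) s$tissue_class == "cancer" & s$tumor_stage %in% late),
    D_stage_healthy = list(
      label = "T1/T2 vs T3/T4 (healthy regions)",
      a = function(s) s$tissue_class %in% c("esophagus", "stomach") &
        s$tumor_stage %in% early,
      b = function(s) s$tissue_class %in% c("esophagus", "stomach") &
        s$tumor_stage %in% late)
  )
}

# Per-patient means of the rows selected by `pick` (healthy designs may
# select two regions per patient; they are averaged within patient first).
.patient_values <- function(summaries, pick) {
  sel <- summaries[pick(summaries), , drop = FALSE]
  if (!nrow(sel)) return(numeric(0))
  tapply(sel$mean_value, sel$patient_id, mean)
}

#' Compare physiological parameters between groups
#'
#' Runs the four panel designs -- (A) healthy stomach vs cancer, (B)
#' healthy esophagus vs cancer, (C) early vs late tumor stage within
#' cancer regions, (D) early vs late stage within healthy regions -- for
#' each physiological index, using a Welch t-test on per-patient region
#' means. Comparisons with fewer than 2 patients in either group are
#' skipped with a warning. No multiple-testing correction is applied by
#' default (`p_adjust = "holm"` to enable).
#'
#' @param summaries Region summary data frame from [summarize_cohort()] /
#'   [summarize_regions()].
#' @param var_equal Use pooled-variance Student tests.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Data frame with one row per (design, index): `index`, `design`,
#'   `design_label`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `stars`.
#' @export
compare_groups <- function(summaries, var_equal = FALSE,
                           p_adjust = "none") {
  stopifnot(is.data.frame(summaries),
            all(c("patient_id", "tissue_class", "tumor_stage", "index",
                  "mean_value") %in% names(summaries)))
  rows <- list()
  for (dname in names(.panel_designs())) {
    design <- .panel_designs()[[dname]]
    for (idx in unique(summaries$index)) {
      sub <- summaries[summaries$index == idx, , drop = FALSE]
      va <- .patient_values(sub, design$a)
      vb <- .patient_values(sub, design$b)
      if (length(va) < 2 || length(vb) < 2) {
        warning("comparison '", design$label, "' for ", idx,
                " skipped: underpowered group")
        next
      }
      tt <- welch_t_test(va, vb, var_equal = var_equal)
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, design = dname, design_label = design$label,
        n_a = length(va), n_b = length(vb),
        mean_a = mean(va), mean_b = mean(vb),
        t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(index = character(), design = character(),
                      design_label = character(), n_a = integer(),
                      n_b = integer(), mean_a = numeric(),
                      mean_b = numeric(), t = numeric(), df = numeric(),
                      p = numeric(), stars = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none"))
    out$p <- stats::p.adjust(out$p, method = p_adjust)
  out$stars <- vapply(out$p, significance_stars, "")
  out
}

#' Assemble the analysis report bundle
#'
#' Writes a single directory holding the per-patient metric rows, the
#' aggregated summary, the group-comparison table, the configuration used,
#' and (when maps are supplied) per-patient prediction and difference
#' maps. Content is byte-identical across reruns on the same inputs.
#' Missing inputs are listed in the manifest rather than failing.
#'
#' @param out_dir Output directory (created).
#' @param eval_rows Metric rows from [run_lopo()] (or NULL).
#' @param summary Output of [aggregate_report()] (or NULL).
#' @param comparisons Output of [compare_groups()] (or NULL).
#' @param config Named list of configuration objects to snapshot.
#' @param predictions Named list of prediction label matrices (or NULL).
#' @param masks Named list of annotation masks (for difference maps).
#' @return Manifest path, invisibly.
#' @export
build_report <- function(out_dir, eval_rows = NULL, summary = NULL,
                         comparisons = NULL, config = list(),
                         predictions = NULL, masks = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(files = character(0), missing = character(0))
  put_csv <- function(df, name) {
    if (is.null(df)) {
      manifest$missing <<- c(manifest$missing, name)
      return(invisible(NULL))
    }
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    manifest$files <<- c(manifest$files, name)
  }
  put_csv(eval_rows, "metrics_per_patient.csv")
  put_csv(comparisons, "group_comparisons.csv")
  if (!is.null(summary)) {
    put_csv(summary$per_class, "metrics_per_class.csv")
    put_csv(summary$macro, "metrics_macro.csv")
  } else manifest$missing <- c(manifest$missing, "metrics_per_class.csv",
                               "metrics_macro.csv")
  if (length(config)) {
    jsonlite::write_json(lapply(config, unclass),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$files <- c(manifest$files, "config.json")
  }
  if (!is.null(predictions)) {
    for (pid in names(predictions)) {
      pm <- predictions[[pid]]
      pm[is.na(pm)] <- 0L
      f <- paste0("prediction_", pid, ".png")
      write_map_png(pm, file.path(out_dir, f))
      manifest$files <- c(manifest$files, f)
      if (!is.null(masks) && pid %in% names(masks)) {
        dm <- difference_map(predictions[[pid]], masks[[pid]])
        f2 <- paste0("difference_", pid, ".png")
        write_map_png(dm$map, file.path(out_dir, f2))
        manifest$files <- c(manifest$files, f2)
      }
    }
  }
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = FALSE, pretty = TRUE)
  invisible(mpath)
}
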