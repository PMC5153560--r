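#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run: cohort source (simulate from
#' [phantom_params()] or ingest a written cohort manifest), GLCM settings,
#' feature-variant switches and statistical thresholds.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param params [phantom_params()] used in simulate mode (its `seed` drives
#'   all randomness).
#' @param manifest path to a cohort `manifest.json` for ingest mode.
#' @param n_pd,n_hc simulated cohort sizes.
#' @param Q,distance GLCM quantization levels and offset distance.
#' @param homogeneity_form,cluster_tendency_exponent texture-variant
#'   switches, see [haralick_features()].
#' @param alpha FDR level.
#' @param enter_p,remove_p stepwise selection thresholds.
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `striatex_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            params = phantom_params(), manifest = NULL,
                            n_pd = 85, n_hc = 56,
                            Q = 32L, distance = 1L,
                            homogeneity_form = "inverse_difference",
                            cluster_tendency_exponent = 4,
                            alpha = 0.05, enter_p = 0.10, remove_p = 0.05,
                            out_dir = tempfile("striatex_run_")) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(manifest))
    stop("ingest mode needs a manifest path")
  if (!(alpha > 0 && alpha < 1 && enter_p > 0 && enter_p < 1 &&
        remove_p > 0 && remove_p < 1))
    stop("alpha and stepwise thresholds must lie in (0, 1)")
  structure(list(mode = mode, params = params, manifest = manifest,
                 n_pd = n_pd, n_hc = n_hc, Q = as.integer(Q),
                 distance = as.integer(distance),
                 homogeneity_form = homogeneity_form,
                 cluster_tendency_exponent = cluster_tendency_exponent,
                 alpha = alpha, enter_p = enter_p, remove_p = remove_p,
                 out_dir = out_dir),
            class = "striatex_config")
}

#' Run the full pipeline
#'
#' Simulate (or ingest) a cohort, extract per-subject features, run the
#' association battery, and write `features.csv`, `report.csv`,
#' `report.txt`, `run.log` and a YAML provenance file to the configured
#' output directory. Identical configuration and seed give identical
#' outputs.
#'
#' The report covers the four clinical measures on the more-affected caudate
#' within patients (the primary analysis) plus the conventional putamen
#' uptake correlation with UPDRS-III with and without controls (the
#' conventional benchmark).
#'
#' @param config a [pipeline_config()].
#' @return list: `features`, `clinical`, `report`, `putamen_benchmark`,
#'   `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "striatex_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (config$mode == "simulate") {
    say("simulate mode: %d PD + %d HC, seed %d", config$n_pd, config$n_hc,
        config$params$seed)
    clinical <- stage("clinical",
                      simulate_clinical(config$params, config$n_pd, config$n_hc))
    masks <- stage("masks", make_masks(config$params))
    volumes <- NULL
    params <- config$params
  } else {
    say("ingest mode: %s", config$manifest)
    coh <- stage("ingest", read_cohort(config$manifest))
    clinical <- coh$clinical; masks <- coh$masks; volumes <- coh$volumes
    params <- coh$params
  }
  feats <- stage("features",
                 cohort_features(params, clinical = clinical,
                                 volumes = volumes, masks = masks,
                                 Q = config$Q, distance = config$distance,
                                 homogeneity_form = config$homogeneity_form,
                                 cluster_tendency_exponent =
                                   config$cluster_tendency_exponent))
  say("extracted %d feature rows for %d subjects", nrow(feats),
      length(unique(feats$subject_id)))
  report <- stage("associations",
                  association_report(feats, clinical, region = "caudate",
                                     side = "more", subset = "PD",
                                     alpha = config$alpha,
                                     enter_p = config$enter_p,
                                     remove_p = config$remove_p))
  bench <- stage("benchmark", list(
    all = analyze_measure(feats, clinical, "updrs3", region = "putamen",
                          side = "more", subset = "PD+HC",
                          alpha = config$alpha),
    pd = analyze_measure(feats, clinical, "updrs3", region = "putamen",
                         side = "more", subset = "PD",
                         alpha = config$alpha)))
  say("FDR-significant caudate metrics vs UPDRS-III: %s",
      paste(report$metric[report$measure == "updrs3" &
                            report$fdr_significant %in% TRUE],
            collapse = ", "))
  paths <- list(features = file.path(config$out_dir, "features.csv"),
                report_csv = file.path(config$out_dir, "report.csv"),
                report_txt = file.path(config$out_dir, "report.txt"),
                provenance = file.path(config$out_dir, "provenance.yaml"),
                log = logf)
  utils::write.csv(feats, paths$features, row.names = FALSE)
  utils::write.csv(as.data.frame(report), paths$report_csv, row.names = FALSE)
  writeLines(format_report(report), paths$report_txt)
  prov <- list(package = "striatex",
               version = as.character(utils::packageVersion("striatex")),
               mode = config$mode,
               seed = params$seed,
               n_pd = config$n_pd, n_hc = config$n_hc,
               glcm = list(Q = config$Q, distance = config$distance,
                           homogeneity_form = config$homogeneity_form,
                           cluster_tendency_exponent =
                             config$cluster_tendency_exponent),
               stats = list(alpha = config$alpha, enter_p = config$enter_p,
                            remove_p = config$remove_p),
               phantom = unclass(params))
  yaml::write_yaml(prov, paths$provenance)
  writeLines(log_lines, logf)
  list(features = feats, clinical = clinical, report = report,
       putamen_benchmark = bench, paths = paths)
}

#' Scatter plot of an image metric against a clinical measure
#'
#' Draws the joined per-subject values with a least-squares line, annotates
#' Pearson r and p, and distinguishes patients from controls when both
#' groups are present.
#'
#' @param features feature table from [cohort_features()].
#' @param clinical clinical table.
#' @param metric one of [ANALYSIS_METRICS].
#' @param measure one of the clinical columns (e.g. `"updrs3"`).
#' @param out output PNG path.
#' @param region,side,subset data selection as in [analyze_measure()].
#' @return `out`, invisibly.
#' @export
plot_scatter <- function(features, clinical, metric, measure, out,
                         region = "caudate", side = "more", subset = "PD") {
  if (!metric %in% ANALYSIS_METRICS)
    stop("unknown metric '", metric, "'; available: ",
         paste(ANALYSIS_METRICS, collapse = ", "))
  if (!measure %in% names(clinical))
    stop("unknown measure '", measure, "'; available: ",
         paste(setdiff(names(clinical), "subject_id"), collapse = ", "))
  rows <- features[features$region == region & features$side == side, ]
  dat <- merge(rows, clinical, by = "subject_id")
  if (subset == "PD") dat <- dat[dat$group == "PD", ]
  dat <- dat[is.finite(dat[[metric]]) & is.finite(dat[[measure]]), ]
  if (!nrow(dat)) stop("no complete cases to plot")
  ct <- pearson_corr(dat[[metric]], dat[[measure]])
  grDevices::png(out, width = 900, height = 700, res = 120)
  on.exit(grDevices::dev.off())
  col <- ifelse(dat$group == "PD", "#1f6fb4", "#e08214")
  graphics::plot(dat[[measure]], dat[[metric]], col = col, pch = 19,
                 xlab = measure, ylab = metric,
                 main = sprintf("%s %s (%s), %s vs %s", side, region, subset,
                                metric, measure))
  graphics::abline(stats::lm(dat[[metric]] ~ dat[[measure]]), lwd = 2)
  graphics::mtext(sprintf("r = %.3f, p = %.3g (n = %d)", ct$r, ct$p, ct$n),
                  side = 3, line = 0.2, cex = 0.9)
  if (length(unique(dat$group)) > 1)
    graphics::legend("topright", legend = c("PD", "HC"), pch = 19,
                     col = c("#1f6fb4", "#e08214"), bty = "n")
  invisible(out)
}
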