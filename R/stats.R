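#' Pearson correlation with t-distributed p-value
#'
#' Pairwise-complete Pearson correlation; the two-sided p-value comes from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; at least 3 complete pairs,
#'   neither constant.
#' @return list: `n`, `r`, `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Pearson correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(n = n, r = unname(ct$estimate), p = ct$p.value)
}

#' Benjamini-Hochberg step-up FDR decision
#'
#' Orders the m p-values increasingly, finds the largest k with
#' `P(k) <= (k/m) alpha`, and declares the tests carrying the k smallest
#' p-values significant (step-up: every `P(j)` with `j <= k` is included even
#' if it exceeds its own threshold). With m = 1 this reduces to the raw
#' alpha test.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha target false-discovery rate (default 0.05).
#' @return list of class `striatex_fdr`: `m`, `alpha`, `k_star`,
#'   `significant` (logical, original order), `p_sorted`, `order`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) < 1) stop("need at least one p-value")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) / m * alpha)
  k_star <- if (length(pass)) max(pass) else 0L
  sig <- logical(m)
  if (k_star > 0) sig[o[seq_len(k_star)]] <- TRUE
  structure(list(m = m, alpha = alpha, k_star = as.integer(k_star),
                 significant = sig, p_sorted = ps, order = o),
            class = "striatex_fdr")
}

#' Stepwise multivariate linear regression
#'
#' Bidirectional p-value-driven selection over ordinary least squares with
#' intercept: each forward step enters the candidate with the smallest
#' partial p-value among those below `enter_p` (ties broken by smaller p,
#' then name); each backward step removes the retained predictor with the
#' largest partial p-value if it exceeds `remove_p`. Partial p-values are
#' the two-sided t-tests on the coefficients. Selection alternates until a
#' full pass changes nothing; if a model recurs (a variable cycling in and
#' out at a p-value between the two thresholds) selection stops at the
#' post-removal model, so every retained predictor satisfies the removal
#' threshold.
#'
#' @param response numeric response vector.
#' @param candidates named list / data.frame of candidate predictors.
#' @param enter_p entry threshold on the partial p-value (default 0.10).
#' @param remove_p removal threshold (default 0.05).
#' @param max_iter cap on forward/backward sweeps (error when reached).
#' @return list of class `striatex_stepwise`: `selected` (character),
#'   `coefficients` (data.frame: term, estimate, se, p), `log` (character),
#'   `cycled` (logical), `model` (the final `lm`).
#' @export
stepwise_regression <- function(response, candidates, enter_p = 0.10,
                                remove_p = 0.05, max_iter = 50L) {
  cand <- as.data.frame(candidates, optional = TRUE)
  if (is.null(names(cand)) || any(!nzchar(names(cand))))
    stop("candidates must be named")
  y <- as.numeric(response)
  ok <- is.finite(y) & Reduce(`&`, lapply(cand, is.finite))
  y <- y[ok]; cand <- cand[ok, , drop = FALSE]
  n <- length(y)
  if (!(enter_p > 0 && enter_p < 1 && remove_p > 0 && remove_p < 1))
    stop("selection thresholds must lie in (0, 1)")
  for (nm in names(cand))
    if (stats::sd(cand[[nm]]) == 0)
      stop("candidate '", nm, "' is constant")
  nms <- names(cand)
  if (length(nms) > 1) {
    cm <- abs(stats::cor(cand))
    diag(cm) <- 0
    w <- which(cm > 1 - 1e-10, arr.ind = TRUE)
    if (nrow(w)) {
      pair <- sort(nms[w[1, ]])
      stop("collinear candidates: '", pair[1], "' and '", pair[2], "'")
    }
  }
  if (n <= 2) stop("too few complete observations")

  partial_p <- function(fit) {
    s <- summary(fit)$coefficients
    pv <- s[, "Pr(>|t|)"]
    names(pv) <- rownames(s)
    pv[setdiff(names(pv), "(Intercept)")]
  }
  fit_with <- function(vars) {
    df <- cbind(.y = y, cand[, vars, drop = FALSE])
    stats::lm(.y ~ ., data = df)
  }

  selected <- character(0)
  log <- character(0)
  seen <- character(0)
  state_key <- function(s) paste(sort(s), collapse = "|")
  cycled <- FALSE
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    # forward
    pool <- setdiff(nms, selected)
    if (length(pool) && n > length(selected) + 2) {
      ps <- vapply(pool, function(v) {
        fit <- fit_with(c(selected, v))
        pv <- partial_p(fit)
        if (!v %in% names(pv)) return(NA_real_)  # aliased/collinear in context
        pv[[v]]
      }, 0)
      ps <- ps[is.finite(ps)]
      if (length(ps) && min(ps) < enter_p) {
        best <- sort(names(ps)[ps == min(ps)])[1]
        cand_state <- state_key(c(selected, best))
        if (cand_state %in% seen) {
          cycled <- TRUE
          log <- c(log, sprintf(
            "stop: entering '%s' (p=%.4g) would revisit a previous model",
            best, min(ps)))
          break
        }
        selected <- c(selected, best)
        seen <- c(seen, state_key(selected))
        log <- c(log, sprintf("enter '%s' (p=%.4g)", best, min(ps)))
        changed <- TRUE
      }
    }
    # backward
    if (length(selected)) {
      pv <- partial_p(fit_with(selected))
      if (length(pv) && max(pv) > remove_p) {
        worst <- sort(names(pv)[pv == max(pv)])[1]
        selected <- setdiff(selected, worst)
        seen <- c(seen, state_key(selected))
        log <- c(log, sprintf("remove '%s' (p=%.4g)", worst, max(pv)))
        changed <- TRUE
      }
    }
    if (!changed) break
    if (iter == max_iter)
      stop("stepwise selection failed to settle within ", max_iter, " sweeps")
  }
  fit <- if (length(selected)) fit_with(selected) else
    stats::lm(y ~ 1, data = data.frame(y = y))
  cf <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                      se = cf[, "Std. Error"], p = cf[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(selected = selected, coefficients = coefs, log = log,
                 cycled = cycled, n = n, enter_p = enter_p,
                 remove_p = remove_p, model = fit),
            class = "striatex_stepwise")
}

#' Image-metric names used in association analyses
#'
#' Conventional normalized uptake plus the 13 texture features: the m = 14
#' family over which the FDR correction is applied per clinical measure.
#' @export
ANALYSIS_METRICS <- c("uptake", HARALICK_FEATURES)

#' Clinical measures analysed
#' @export
CLINICAL_MEASURES <- c("updrs3", "dd_diag_months", "dd_sympt_months", "moca")

#' Univariate + multivariate association analysis for one clinical measure
#'
#' Joins the feature table to the clinical table, restricts to one region x
#' side x subject subset, then (i) Pearson-correlates conventional uptake
#' and the 13 texture features against the measure, (ii) applies the BH
#' step-up FDR across those 14 tests, and (iii) runs stepwise regression of
#' the measure on all 14 metrics plus age.
#'
#' @param features output of [cohort_features()].
#' @param clinical clinical table with `subject_id`, `group`, `age` and the
#'   measure column.
#' @param measure clinical column to correlate against (see
#'   [CLINICAL_MEASURES]).
#' @param region `"caudate"` or `"putamen"`.
#' @param side `"more"` or `"less"` affected.
#' @param subset `"PD"` (patients only) or `"PD+HC"`.
#' @param alpha FDR level (default 0.05).
#' @param enter_p,remove_p stepwise thresholds (defaults 0.10 / 0.05).
#' @return data.frame of class `striatex_assoc`, one row per metric:
#'   `metric`, `n`, `r`, `p`, `fdr_significant`, `selected`,
#'   `coef`, `coef_p`; stepwise details in `attr(, "stepwise")`.
#' @export
analyze_measure <- function(features, clinical, measure,
                            region = "caudate", side = "more",
                            subset = c("PD", "PD+HC"), alpha = 0.05,
                            enter_p = 0.10, remove_p = 0.05) {
  subset <- match.arg(subset)
  for (col in c("subject_id", "group", "age", measure))
    if (!col %in% names(clinical)) stop("missing clinical column: ", col)
  rows <- features[features$region == region & features$side == side, ]
  dat <- merge(rows, clinical, by = "subject_id")
  if (subset == "PD") dat <- dat[dat$group == "PD", ]
  dat <- dat[is.finite(dat[[measure]]), ]
  dat <- dat[stats::complete.cases(dat[, c(ANALYSIS_METRICS, "age")]), ]
  if (nrow(dat) < 10)
    stop("fewer than 10 complete cases for ", measure, " (", nrow(dat), ")")
  uni <- lapply(ANALYSIS_METRICS, function(m2)
    pearson_corr(dat[[m2]], dat[[measure]]))
  res <- data.frame(metric = ANALYSIS_METRICS,
                    n = vapply(uni, `[[`, 0, "n"),
                    r = vapply(uni, `[[`, 0, "r"),
                    p = vapply(uni, `[[`, 0, "p"),
                    stringsAsFactors = FALSE)
  fdr <- bh_fdr(res$p, alpha = alpha)
  res$fdr_significant <- fdr$significant
  sw <- stepwise_regression(dat[[measure]],
                            dat[, c(ANALYSIS_METRICS, "age")],
                            enter_p = enter_p, remove_p = remove_p)
  age_row <- data.frame(metric = "age", n = nrow(dat), r = NA_real_,
                        p = pearson_corr(dat$age, dat[[measure]])$p,
                        fdr_significant = NA, stringsAsFactors = FALSE)
  res <- rbind(res, age_row)
  res$selected <- res$metric %in% sw$selected
  cf <- sw$coefficients
  res$coef <- cf$estimate[match(res$metric, cf$term)]
  res$coef_p <- cf$p[match(res$metric, cf$term)]
  res$measure <- measure
  res$region <- region
  res$side <- side
  res$subset <- subset
  attr(res, "stepwise") <- sw
  attr(res, "fdr") <- fdr
  class(res) <- c("striatex_assoc", class(res))
  res
}

#' Full association report across the four clinical measures
#'
#' Runs [analyze_measure()] for UPDRS-III, both disease durations and MoCA
#' on one region/side within patients, mirroring the univariate/multivariate
#' table layout of the analysis.
#'
#' @inheritParams analyze_measure
#' @param measures clinical measures to analyse.
#' @return data.frame: stacked [analyze_measure()] rows.
#' @export
association_report <- function(features, clinical,
                               measures = CLINICAL_MEASURES,
                               region = "caudate", side = "more",
                               subset = "PD", alpha = 0.05,
                               enter_p = 0.10, remove_p = 0.05) {
  out <- lapply(measures, function(m2)
    analyze_measure(features, clinical, m2, region = region, side = side,
                    subset = subset, alpha = alpha, enter_p = enter_p,
                    remove_p = remove_p))
  res <- do.call(rbind, lapply(out, as.data.frame))
  attr(res, "per_measure") <- out
  res
}

#' Render an association report as a fixed-width text table
#'
#' One row per metric, one univariate (p, FDR flag) and one multivariate
#' (coefficient p if retained) column pair per clinical measure.
#'
#' @param report output of [association_report()].
#' @return character vector of lines.
#' @export
format_report <- function(report) {
  measures <- unique(report$measure)
  metrics <- unique(report$metric)
  hdr <- sprintf("%-18s %s", "Metric",
                 paste(sprintf("%-22s", measures), collapse = ""))
  sub <- sprintf("%-18s %s", "",
                 paste(rep(sprintf("%-11s%-11s", "U", "M"),
                           length(measures)), collapse = ""))
  fmt_p <- function(p, flag = FALSE) {
    if (!length(p) || is.na(p)) return("-")
    s <- if (p < 0.001) "<0.001" else sprintf("%.4f", p)
    if (isTRUE(flag)) paste0(s, "*") else s
  }
  lines <- vapply(metrics, function(mt) {
    cells <- vapply(measures, function(ms) {
      row <- report[report$metric == mt & report$measure == ms, ]
      u <- fmt_p(row$p, isTRUE(row$fdr_significant))
      m2 <- if (nrow(row) && isTRUE(row$selected)) fmt_p(row$coef_p) else "-"
      sprintf("%-11s%-11s", u, m2)
    }, "")
    sprintf("%-18s %s", mt, paste(cells, collapse = ""))
  }, "")
  c(hdr, sub, strrep("-", nchar(hdr)), lines,
    "", "U: univariate Pearson p-value (* = significant after BH FDR)",
    "M: partial p-value when retained by stepwise selection")
}
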