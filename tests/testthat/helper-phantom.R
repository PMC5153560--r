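# Shared fixtures built in code.

# A tiny named single-region mask set on an arbitrary grid.
tiny_mask_set <- function(d, idx, name = "caudate_L") {
  m <- array(FALSE, dim = d)
  m[idx] <- TRUE
  region_mask_set(stats::setNames(list(m), name))
}

# Small but fully valid phantom cohort, cached per session.
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- phantom_params(seed = 7L)
      cl <- simulate_clinical(p, n_pd = 10, n_hc = 5)
      m <- make_masks(p)
      ft <- cohort_features(p, clinical = cl, masks = m)
      cache <<- list(params = p, clinical = cl, masks = m, features = ft)
    }
    cache
  }
})

# The full default 141-subject cohort used by the acceptance checks:
# simulated once, with per-region GLCM validity summaries recorded during
# the same pass as feature extraction.
acceptance_cohort <- local({
  cache <- NULL
  function(seed = 1L) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    p <- phantom_params(seed = seed)
    cl <- simulate_clinical(p, 85, 56)
    m <- make_masks(p)
    regions <- paste0(rep(c("caudate", "putamen"), each = 2), "_", c("L", "R"))
    sum_err <- 0; sym_err <- 0
    rows <- vector("list", nrow(cl))
    for (i in seq_len(nrow(cl))) {
      v <- simulate_subject(p, cl[i, ], m)
      for (rn in regions) {
        g <- build_glcm(quantize_roi(v, m$masks[[rn]], Q = 32))
        sum_err <- max(sum_err, abs(sum(g$p) - 1))
        sym_err <- max(sym_err, max(abs(g$p - t(g$p))))
      }
      f <- extract_subject_features(v, m)
      rows[[i]] <- cbind(subject_id = cl$subject_id[i], f,
                         stringsAsFactors = FALSE)
    }
    cache <<- list(seed = seed, params = p, clinical = cl, masks = m,
                   features = do.call(rbind, rows),
                   glcm_sum_err = sum_err, glcm_sym_err = sym_err)
    cache
  }
})
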