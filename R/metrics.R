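# Error metrics comparing flow-surrogate separations against a reference
# separation, and the cohort evaluation harness.

#' Compare two wave separations sharing one pressure waveform
#'
#' Percent errors are relative to the reference (measured-flow)
#' separation; both signed and absolute values are reported. Component
#' waveform differences are root-mean-squared errors; because both
#' separations share P, the forward and backward RMSEs are identical by
#' construction and both are reported as a check.
#'
#' @param ref Reference [separate_waves()] result (measured flow).
#' @param est Estimated-flow [separate_waves()] result on the same
#'   pressure waveform and grid.
#' @return One-row data.frame: `rm_ref`, `rm_est`, `rm_error_pct`,
#'   `abs_rm_error_pct`, `tr_ref`, `tr_est`, `tr_error_ms`,
#'   `tr_error_pct`, `abs_tr_error_pct`, `rmse_pf`, `rmse_pb`.
#' @export
compare_separations <- function(ref, est) {
  for (x in list(ref, est)) {
    if (!inherits(x, "separation_result")) {
      ws_stop("ref and est must be separation_result objects", "ws_invalid_input")
    }
  }
  if (!same_grid(ref$p, est$p) ||
      max(abs(ref$p$v - est$p$v)) > 1e-9 * max(1, max(abs(ref$p$v)))) {
    ws_stop("ref and est must share the pressure waveform and time grid",
            "ws_invalid_input")
  }
  rm_err <- 100 * (est$rm - ref$rm) / ref$rm
  tr_err_ms <- est$tr - ref$tr
  tr_err <- 100 * tr_err_ms / ref$tr
  data.frame(
    rm_ref = ref$rm, rm_est = est$rm,
    rm_error_pct = rm_err, abs_rm_error_pct = abs(rm_err),
    tr_ref = ref$tr, tr_est = est$tr, tr_error_ms = tr_err_ms,
    tr_error_pct = tr_err, abs_tr_error_pct = abs(tr_err),
    rmse_pf = sqrt(mean((est$pf$v - ref$pf$v)^2)),
    rmse_pb = sqrt(mean((est$pb$v - ref$pb$v)^2)))
}

#' Cohort deviation profile around a representative waveform
#'
#' Pointwise 5th-95th percentile envelope width of the normalized cohort
#' and each subject's deviation from the representative waveform, over
#' normalized time.
#'
#' @param cohort_norm List of [normalize_beat()] results on one grid.
#' @param rep A [build_representative()] result on the same grid.
#' @return Object of class `"deviation_profile"`: list with `tau`,
#'   `width` (95th minus 5th percentile, pointwise), and `deviation`
#'   (matrix, tau by subject, of `v_i - rep`).
#' @export
deviation_profile <- function(cohort_norm, rep) {
  tau <- rep$tau
  for (w in cohort_norm) {
    if (length(w$tau) != length(tau) || max(abs(w$tau - tau)) > 1e-12) {
      ws_stop("cohort and representative waveform must share one tau grid",
              "ws_invalid_input")
    }
  }
  m <- vapply(cohort_norm, function(w) w$v, numeric(length(tau)))
  qs <- apply(m, 1, stats::quantile, probs = c(0.05, 0.95), names = FALSE,
              type = 7)
  structure(list(tau = tau, width = qs[2, ] - qs[1, ],
                 deviation = m - rep$v),
            class = "deviation_profile")
}

#' @rdname deviation_profile
#' @param dp A `deviation_profile`.
#' @param tau_query Tau value at which to report (e.g. 0.75 for 75% of
#'   ejection time).
#' @return For `deviation_at`: list with the interpolated envelope
#'   `width` and the per-subject `deviation` at `tau_query`.
#' @export
deviation_at <- function(dp, tau_query) {
  if (!inherits(dp, "deviation_profile")) {
    ws_stop("dp must be a deviation_profile", "ws_invalid_input")
  }
  list(width = stats::approx(dp$tau, dp$width, tau_query)$y,
       deviation = apply(dp$deviation, 2, function(col)
         stats::approx(dp$tau, col, tau_query)$y))
}

#' Evaluate flow-surrogate methods on a simulated cohort
#'
#' Runs wave separation for each subject with the measured flow
#' (reference) and with each requested surrogate, and tabulates
#' descriptive mean and SD of the error metrics. The representative-flow
#' method is evaluated by leave-one-out cross-validation; the triangular
#' method uses each subject's measured-flow landmarks; an external
#' normalized waveform is de-normalized per subject.
#'
#' @param cohort A [simulate_cohort()] result, or a list of subjects each
#'   carrying `p` and `q` waveforms.
#' @param methods Subset of `"measured"`, `"repflow"`, `"triangle"`,
#'   `"external"`.
#' @param apex_fraction Triangle apex fraction (0.25 = Tri25).
#' @param external_path CSV path for the external normalized waveform.
#' @param grid Common tau grid for the representative construction.
#' @param smooth_span,ramp_len Passed to [build_representative()].
#' @param file Optional CSV path for the summary table.
#' @param verbose Echo per-run parameters via `message()`.
#' @return data.frame, one row per method, with mean and SD of signed and
#'   absolute RM and Tr percent errors and component RMSE.
#' @export
evaluate_methods <- function(cohort,
                             methods = c("measured", "repflow", "triangle"),
                             apex_fraction = 0.25, external_path = NULL,
                             grid = tau_grid(), smooth_span = 0.125,
                             ramp_len = 0.6, file = NULL, verbose = FALSE) {
  known <- c("measured", "repflow", "triangle", "external")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    ws_stop(paste("unknown method:", paste(bad, collapse = ", ")), "ws_usage_error")
  }
  subjects <- if (inherits(cohort, "sim_cohort")) cohort$subjects else cohort
  flows <- lapply(subjects, `[[`, "q")
  pressures <- lapply(subjects, `[[`, "p")
  n <- length(subjects)
  if (verbose) {
    message(sprintf("evaluate_methods: n=%d, methods=%s, apex=%.2f, span=%.3f, ramp=%.2f",
                    n, paste(methods, collapse = "/"), apex_fraction,
                    smooth_span, ramp_len))
  }
  refs <- mapply(function(p, q) separate_waves(p, q), pressures, flows,
                 SIMPLIFY = FALSE)
  per_method <- list()
  for (m in methods) {
    tab <- switch(m,
      measured = do.call(rbind, lapply(seq_len(n), function(i)
        compare_separations(refs[[i]], refs[[i]]))),
      repflow = loo_cross_validate(flows, pressures, grid = grid,
                                   smooth_span = smooth_span,
                                   ramp_len = ramp_len),
      triangle = do.call(rbind, lapply(seq_len(n), function(i) {
        lm_i <- detect_landmarks(flows[[i]])
        q_tri <- triangular_flow(lm_i, flows[[i]]$t, apex_fraction)
        compare_separations(refs[[i]], separate_waves(pressures[[i]], q_tri))
      })),
      external = {
        if (is.null(external_path)) {
          ws_stop("method 'external' needs external_path", "ws_usage_error")
        }
        do.call(rbind, lapply(seq_len(n), function(i) {
          lm_i <- detect_landmarks(flows[[i]])
          q_ext <- load_external_normalized(external_path, lm_i, flows[[i]]$t)
          compare_separations(refs[[i]], separate_waves(pressures[[i]], q_ext))
        }))
      })
    per_method[[m]] <- tab
  }
  summarise <- function(m, tab) {
    data.frame(method = m, n = nrow(tab),
               mean_rm_error_pct = mean(tab$rm_error_pct),
               sd_rm_error_pct = stats::sd(tab$rm_error_pct),
               mean_abs_rm_error_pct = mean(tab$abs_rm_error_pct),
               sd_abs_rm_error_pct = stats::sd(tab$abs_rm_error_pct),
               mean_tr_error_pct = mean(tab$tr_error_pct),
               sd_tr_error_pct = stats::sd(tab$tr_error_pct),
               mean_abs_tr_error_pct = mean(tab$abs_tr_error_pct),
               sd_abs_tr_error_pct = stats::sd(tab$abs_tr_error_pct),
               mean_rmse_pf = mean(tab$rmse_pf),
               sd_rmse_pf = stats::sd(tab$rmse_pf))
  }
  out <- do.call(rbind, mapply(summarise, names(per_method), per_method,
                               SIMPLIFY = FALSE))
  rownames(out) <- NULL
  attr(out, "per_subject") <- per_method
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
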