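#' Run the full WAXS pipeline: images to crystal metrics and statistics
#'
#' For every replicate: azimuthal integration, rolling-mean smoothing,
#' convex-hull baseline, deflection-point detection (used to refine the
#' standardised initial centers), pseudo-Voigt EM deconvolution and the
#' crystal report (d(200), L(200), organized-water ratio). Metrics are
#' then compared across groups (both parametric and rank-based
#' branches). A failing replicate is recorded and skipped; it never
#' aborts the run or alters other replicates.
#'
#' The q range, smoothing window, peak count and initial positions are
#' standardised across all samples of a run; every default that fills a
#' protocol gap is recorded in the run log.
#'
#' @param replicates list of replicate descriptors, each a list with
#'   `image` (a [detector_image]) or `profile` (a [qprofile]), plus
#'   `sample` and `group` labels.
#' @param geometry a [waxs_geometry] (needed when profiles are given
#'   without images, for the wavelength).
#' @param q_range baseline/fit q window, 1/Angstrom.
#' @param window rolling-mean window (odd).
#' @param init standardised peak set: list of [pv_peak] or numeric
#'   initial centers; labels default to `"110/1-10"`, `"200"`,
#'   `"water"` for 3 peaks.
#' @param q_step azimuthal bin width.
#' @param snap_init_to_deflections move each initial center to the
#'   nearest detected deflection point (within half the initial FWHM)
#'   before fitting.
#' @param max_iter,tol EM controls passed to [fit_pv_mixture()].
#' @param out_dir optional directory; when given, `metrics.csv`,
#'   `comparisons.json` and `run.log` are written there.
#' @return list of class `waxs_run`: `metrics` (one row per successful
#'   replicate), `comparisons` (per metric, when >= 2 groups succeed),
#'   `status` (per replicate), `log`.
#' @export
run_waxs_pipeline <- function(replicates, geometry,
                              q_range = c(0.5, 2.5), window = 5L,
                              init = c(1.10, 1.60, 2.00),
                              q_step = 0.001,
                              snap_init_to_deflections = TRUE,
                              max_iter = 10000L, tol = 1e-6,
                              out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("WAXS pipeline: q_range = [%g, %g], window = %d, q_step = %g",
       q_range[1L], q_range[2L], window, q_step)
  if (is.numeric(init)) {
    labels <- if (length(init) == 3L) c("110/1-10", "200", "water")
              else sprintf("peak%d", seq_along(init))
    init <- lapply(seq_along(init), function(k) {
      pv_peak(init[k], fwhm = 0.2, eta = 0.5, weight = 1 / length(init),
              label = labels[k])
    })
  }
  note("standardised peak set: %s at q = %s",
       paste(vapply(init, `[[`, "", "label"), collapse = ", "),
       paste(sprintf("%.3f", vapply(init, `[[`, 0, "mu")), collapse = ", "))
  ids <- make.unique(vapply(seq_along(replicates), function(i) {
    r <- replicates[[i]]
    as.character(r$replicate %||% r$sample %||% sprintf("replicate%d", i))
  }, ""))
  metrics <- list(); status <- list()
  for (i in seq_along(replicates)) {
    rep_i <- replicates[[i]]
    id <- ids[i]
    res <- tryCatch({
      prof <- if (!is.null(rep_i$profile)) rep_i$profile
              else integrate_azimuthal(rep_i$image, q_step = q_step)
      prof <- rolling_mean(prof, window)
      bl <- convex_hull_baseline(prof, q_range)
      init_i <- init
      if (snap_init_to_deflections) {
        defl <- tryCatch(detect_deflections(bl$profile), error = function(e) NULL)
        init_i <- snap_centers(init, defl)
      }
      fit <- fit_pv_mixture(bl$profile, init_i, max_iter = max_iter, tol = tol)
      check_peak_truncation(bl, fit)
      row <- crystal_report(fit, geometry, replicate_id = id)
      row$sample <- rep_i$sample %||% id
      row$group <- rep_i$group %||% NA_character_
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      note("replicate %s FAILED: %s", id, conditionMessage(res))
      status[[id]] <- conditionMessage(res)
    } else {
      metrics[[id]] <- res
      status[[id]] <- "ok"
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  comparisons <- list()
  if (!is.null(metrics) && length(unique(metrics$group[!is.na(metrics$group)])) >= 2L) {
    for (metric in c("d200_A", "L200_A", "water_ratio")) {
      groups <- split(metrics[[metric]], metrics$group)
      groups <- lapply(groups, function(v) v[!is.na(v)])
      groups <- groups[lengths(groups) >= 2L]
      if (length(groups) >= 2L && all(is.finite(unlist(groups)))) {
        comparisons[[metric]] <- compare_groups(groups)
      }
    }
  }
  out <- structure(list(metrics = metrics, comparisons = comparisons,
                        status = status, log = log),
                   class = "waxs_run")
  if (!is.null(out_dir)) write_waxs_run(out, out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Move each initial center to the nearest deflection point, if one lies
# within half the initial FWHM (the deflection set informs the
# deconvolution; the peak count stays fixed).
snap_centers <- function(init, defl) {
  if (is.null(defl) || nrow(defl) == 0L) return(init)
  lapply(init, function(p) {
    j <- which.min(abs(defl$q - p$mu))
    if (abs(defl$q[j] - p$mu) <= p$fwhm / 2) p$mu <- defl$q[j]
    p
  })
}

# Warn if an interior hull vertex falls inside a fitted peak's FWHM:
# the baseline is then likely truncating that peak and the q range
# should be adjusted.
check_peak_truncation <- function(bl, fit) {
  interior <- setdiff(bl$hull_vertices, c(1L, length(bl$q)))
  if (!length(interior)) return(invisible())
  qv <- bl$q[interior]
  for (p in fit$peaks) {
    hit <- abs(qv - p$mu) < p$fwhm / 2
    if (any(hit)) {
      warning(sprintf(
        "baseline hull vertex at q = %.3f lies inside the FWHM of peak %s (mu = %.3f): possible peak truncation, consider adjusting q_range",
        qv[which(hit)[1L]], p$label, p$mu), call. = FALSE)
    }
  }
  invisible()
}

write_waxs_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(run$metrics)) {
    utils::write.csv(run$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(run$comparisons, unclass),
    file.path(out_dir, "comparisons.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.waxs_run <- function(x, ...) {
  n_ok <- sum(unlist(x$status) == "ok")
  cat(sprintf("WAXS run: %d/%d replicates succeeded\n", n_ok,
              length(x$status)))
  if (!is.null(x$metrics)) print(x$metrics, digits = 5)
  for (nm in names(x$comparisons)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

#' Run the thermoporosimetry pipeline: traces to pore distributions
#'
#' For every replicate trace: isotherm segmentation and Gibbs-Thomson
#' pore partition. Per pore bin, replicates within a group are
#' summarised (mean and 95% t confidence interval, requiring >= 2
#' replicates; with a single replicate the CI is omitted with a
#' warning) and compared across groups with both parametric and
#' rank-based branches.
#'
#' @param replicates list of descriptors, each with `trace` (a
#'   [dsc_trace]), `sample`, `group`.
#' @param protocol_C ascending isotherm temperatures (C), shared by all
#'   replicates.
#' @param params a [gibbs_thomson_params].
#' @param calibration_offset_K additive temperature correction.
#' @param out_dir optional output directory (`pores.csv`,
#'   `comparisons.json`, `run.log`).
#' @return list of class `thermo_run`: `pores` (long table: replicate,
#'   group, bin, ratio), `summary` (group x bin mean and CI),
#'   `comparisons` (per bin), `status`, `log`.
#' @export
run_thermoporosity_pipeline <- function(replicates,
                                        protocol_C = default_thermo_protocol(params),
                                        params = gibbs_thomson_params(),
                                        calibration_offset_K = 0,
                                        out_dir = NULL) {
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("thermoporosimetry pipeline: protocol = %s C, offset = %g K",
       paste(sprintf("%.2f", protocol_C), collapse = ", "),
       calibration_offset_K)
  pores <- list(); status <- list()
  for (i in seq_along(replicates)) {
    rep_i <- replicates[[i]]
    id <- rep_i$sample %||% sprintf("replicate%d", i)
    res <- tryCatch({
      steps <- segment_isotherms(rep_i$trace, protocol_C)
      pd <- pore_distribution(steps, rep_i$trace, params,
                              calibration_offset_K)
      rows <- rbind(
        data.frame(bin = sprintf("%g-%g nm", pd$bins$d_lo_nm,
                                 pd$bins$d_hi_nm),
                   ratio_pct = pd$bins$freezing_water_ratio),
        data.frame(bin = c("bulk", "nonfreezing"),
                   ratio_pct = c(pd$bulk_pct, pd$nonfreezing_pct)))
      rows$sample <- id
      rows$group <- rep_i$group %||% NA_character_
      rows
    }, error = function(e) e)
    if (inherits(res, "error")) {
      note("replicate %s FAILED: %s", id, conditionMessage(res))
      status[[id]] <- conditionMessage(res)
    } else {
      pores[[id]] <- res
      status[[id]] <- "ok"
    }
  }
  pores <- if (length(pores)) do.call(rbind, pores) else NULL
  summary_tab <- NULL
  comparisons <- list()
  if (!is.null(pores)) {
    summary_tab <- do.call(rbind, lapply(
      split(pores, list(pores$group, pores$bin), drop = TRUE),
      function(d) {
        n <- nrow(d)
        m <- mean(d$ratio_pct)
        if (n >= 2L) {
          half <- stats::qt(0.975, n - 1L) * stats::sd(d$ratio_pct) / sqrt(n)
        } else {
          warning(sprintf(
            "single replicate for group %s, bin %s: confidence interval omitted",
            d$group[1L], d$bin[1L]), call. = FALSE)
          half <- NA_real_
        }
        data.frame(group = d$group[1L], bin = d$bin[1L], n = n, mean = m,
                   ci_lo = m - half, ci_hi = m + half)
      }))
    rownames(summary_tab) <- NULL
    if (length(unique(pores$group[!is.na(pores$group)])) >= 2L) {
      for (bin in unique(pores$bin)) {
        d <- pores[pores$bin == bin, ]
        groups <- split(d$ratio_pct, d$group)
        groups <- groups[lengths(groups) >= 2L]
        if (length(groups) >= 2L) comparisons[[bin]] <- compare_groups(groups)
      }
    }
  }
  out <- structure(list(pores = pores, summary = summary_tab,
                        comparisons = comparisons, status = status,
                        log = log),
                   class = "thermo_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(pores)) {
      utils::write.csv(pores, file.path(out_dir, "pores.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(lapply(comparisons, unclass),
                         file.path(out_dir, "comparisons.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.thermo_run <- function(x, ...) {
  n_ok <- sum(unlist(x$status) == "ok")
  cat(sprintf("Thermoporosimetry run: %d/%d replicates succeeded\n", n_ok,
              length(x$status)))
  if (!is.null(x$summary)) print(x$summary, digits = 4)
  for (nm in names(x$comparisons)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}
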