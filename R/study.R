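#' Study configuration
#'
#' Configuration of a full simulation study: cohort of synthetic lesions,
#' segmentation under the two initial-mask conditions, consensus fusion,
#' metrics, test-retest and statistics.
#'
#' The default cohort mirrors a 13-lesion thoracic simulation: static
#' lesion volumes log-uniform between 3.5 and 55 cm^3, heterogeneous
#' three-level uptake, and (when `motion = TRUE`) 10-bin respiratory
#' averaging with 1.5 cm diaphragm and 0.5 cm anterior-posterior
#' excursion. Each case's phantom seed derives deterministically from
#' `seed` and the case index.
#'
#' @param n_cases number of lesions in the cohort (default 13).
#' @param seed master seed for the whole study (default 1).
#' @param motion logical: include respiratory-motion averaging and
#'   evaluate against the motion-union ground truth (default `TRUE`);
#'   otherwise the static (bin-3) phantom and ground truth are used.
#' @param noise logical: apply the PET-like degradation (default `TRUE`);
#'   `FALSE` segments the noise-free activity map directly.
#' @param volume_range_cm3 range of static lesion volumes, cm^3, sampled
#'   log-uniformly (default `c(3.5, 55)`).
#' @param methods individual methods to run (default all four).
#' @param consensus_k majority-vote threshold (default 3 of 4).
#' @param shape,level_fractions,... passed to [phantom_spec()].
#' @param seg segmentation parameters, a [seg_config()].
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_cases = 13L, seed = 1L, motion = TRUE,
                         noise = TRUE, volume_range_cm3 = c(3.5, 55),
                         methods = c("MASAC", "AP", "ST", "41MAX"),
                         consensus_k = 3L,
                         shape = c(48, 200, 200),
                         level_fractions = c(1, 1, 1) / 3,
                         seg = seg_config(), ...) {
  if (n_cases < 1L) stop("'n_cases' must be >= 1")
  if (consensus_k < 1L || consensus_k > length(methods))
    stop("'consensus_k' must lie in 1..length(methods)")
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 motion = isTRUE(motion), noise = isTRUE(noise),
                 volume_range_cm3 = volume_range_cm3,
                 methods = toupper(methods),
                 consensus_k = as.integer(consensus_k),
                 shape = shape, level_fractions = level_fractions,
                 seg = seg, extra = list(...)),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d cases, seed %d, motion %s, noise %s; methods %s; k = %d\n",
              x$n_cases, x$seed, x$motion, x$noise,
              paste(x$methods, collapse = "/"), x$consensus_k))
  invisible(x)
}

# deterministic per-case seed derived from the master seed (kept < 2^31)
case_seed <- function(master, i) (as.integer(master) * 1000L + i) %% 2147483647L

#' Run the full consensus-contouring study
#'
#' For every case in the cohort: build the heterogeneous phantom (with
#' motion averaging if configured), degrade it into a PET-like image,
#' generate the rectangle and irregular initial masks, run all configured
#' methods under both masks, form the majority-vote consensus (ConSeg),
#' compute MATV/RE/DSC against the ground truth (motion-union for the
#' motion cohort, static otherwise), add the per-case metric averages
#' (AveSeg), and derive per-method test-retest (TRT) values between the
#' two mask conditions. Finally the cohort is summarized as median (IQR)
#' tables and compared across methods with the Friedman test and post hoc
#' Bonferroni-adjusted Wilcoxon signed-rank tests. Fully reproducible
#' from the configuration alone.
#'
#' @param cfg a [study_config()].
#' @param verbose print per-case progress (default `FALSE`).
#' @return An object of class `pet_study`: list with `records` (long-form
#'   per-case metrics incl. ConSeg and AveSeg), `trt` (per-case TRT
#'   values), `summary` (median/IQR per metric, method and mask
#'   condition), `trt_summary`, `stats` (Friedman + pairwise Wilcoxon per
#'   metric and mask condition), `cases` (per-case provenance), and
#'   `config`.
#' @examples
#' \donttest{
#' st <- run_study(study_config(n_cases = 2, shape = c(32, 64, 64),
#'                              volume_range_cm3 = c(4, 10)))
#' summary(st)
#' }
#' @export
run_study <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  vols <- withr::with_seed(cfg$seed,
    exp(stats::runif(cfg$n_cases, log(cfg$volume_range_cm3[1]),
                     log(cfg$volume_range_cm3[2]))))
  records <- list()
  trt_rows <- list()
  cases <- list()
  for (i in seq_len(cfg$n_cases)) {
    cs <- case_seed(cfg$seed, i)
    spec_args <- c(list(shape = cfg$shape, volume_cm3 = vols[i],
                        level_fractions = cfg$level_fractions, seed = cs),
                   cfg$extra)
    if (!cfg$motion) {
      spec_args$diaphragm_cm <- 0
      spec_args$ap_cm <- 0
    }
    spec <- do.call(phantom_spec, spec_args)
    case <- build_phantom(spec)
    if (cfg$motion) case <- apply_motion(case, spec)
    img <- if (cfg$noise) degrade(case$activity, spec, seed = cs + 1L)
           else case$activity
    gt <- if (cfg$motion) case$gt_motion else case$gt_static
    masks <- gen_masks(gt, seed = cs + 2L)
    sp <- vox_spacing(img)
    if (verbose)
      message(sprintf("case %02d: %.1f cm^3 GT, seed %d", i,
                      sum(gt) * prod(sp), cs))

    for (cond in c("rectangle", "irregular")) {
      segs <- lapply(cfg$methods, function(m)
        segment_pet(img, masks[[cond]], m, cfg$seg))
      names(segs) <- cfg$methods
      con <- majority_vote(lapply(segs, `[[`, "mask"), k = cfg$consensus_k)
      all_masks <- c(lapply(segs, `[[`, "mask"), list(ConSeg = con))
      rows <- lapply(names(all_masks), function(m) {
        sm <- all_masks[[m]]
        data.frame(case = i, method = m, mask_condition = cond,
                   MATV_cm3 = matv(sm, sp),
                   RE_pct = rel_vol_error(sm, gt, sp),
                   DSC = if (sum(sm) + sum(gt) > 0) dsc(sm, gt) else NA_real_)
      })
      ave <- data.frame(case = i, method = "AveSeg", mask_condition = cond,
                        MATV_cm3 = aveseg(vapply(rows[seq_along(cfg$methods)],
                                                 `[[`, 0, "MATV_cm3")),
                        RE_pct = aveseg(vapply(rows[seq_along(cfg$methods)],
                                               `[[`, 0, "RE_pct")),
                        DSC = aveseg(vapply(rows[seq_along(cfg$methods)],
                                            `[[`, 0, "DSC")))
      records[[length(records) + 1L]] <- do.call(rbind, c(rows, list(ave)))
    }
    cases[[i]] <- data.frame(case = i, seed = cs,
                             gt_volume_cm3 = sum(gt) * prod(sp),
                             static_volume_cm3 = sum(case$gt_static) * prod(sp))
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  # per-case TRT between the two mask conditions, per method and metric
  trt_tab <- .compute_trt(records)

  out <- structure(list(
    records = records,
    trt = trt_tab,
    summary = summarize_metrics(records),
    trt_summary = .summarize_trt(trt_tab),
    stats = .study_stats(records),
    cases = do.call(rbind, cases),
    config = cfg
  ), class = "pet_study")
  out
}

.compute_trt <- function(records) {
  wide_of <- function(metric) {
    r <- records[records$mask_condition == "rectangle", c("case", "method", metric)]
    i <- records[records$mask_condition == "irregular", c("case", "method", metric)]
    m <- merge(r, i, by = c("case", "method"), suffixes = c(".rect", ".irr"))
    data.frame(case = m$case, method = m$method, metric = metric,
               value_rectangle = m[[paste0(metric, ".rect")]],
               value_irregular = m[[paste0(metric, ".irr")]],
               TRT = trt(m[[paste0(metric, ".rect")]],
                         m[[paste0(metric, ".irr")]]))
  }
  out <- rbind(wide_of("MATV_cm3"), wide_of("RE_pct"), wide_of("DSC"))
  rownames(out) <- NULL
  out
}

.summarize_trt <- function(trt_tab) {
  agg <- function(f, nm) {
    a <- stats::aggregate(TRT ~ method + metric, data = trt_tab, FUN = f,
                          na.action = stats::na.omit)
    names(a)[3] <- nm
    a
  }
  m1 <- agg(function(v) stats::median(v), "median_TRT")
  m2 <- agg(function(v) stats::median(abs(v)), "median_abs_TRT")
  merge(m1, m2, by = c("method", "metric"))
}

# median (Q1, Q3) tables per metric x method x mask condition
#' Summarize a metrics table as median (IQR)
#'
#' @param records long-form metrics data frame with columns `case`,
#'   `method`, `mask_condition`, and metric columns `MATV_cm3`, `RE_pct`,
#'   `DSC`.
#' @return Data frame with one row per method x mask condition and, per
#'   metric, `median`, `q1` and `q3` columns.
#' @export
summarize_metrics <- function(records) {
  if (nrow(records) == 0L) stop("'records' is empty")
  metrics <- intersect(c("MATV_cm3", "RE_pct", "DSC"), names(records))
  sp <- split(records, list(records$method, records$mask_condition),
              drop = TRUE)
  rows <- lapply(sp, function(g) {
    out <- data.frame(method = g$method[1], mask_condition = g$mask_condition[1])
    for (m in metrics) {
      q <- stats::quantile(g[[m]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE, type = 7)
      out[[paste0(m, "_median")]] <- q[2]
      out[[paste0(m, "_q1")]] <- q[1]
      out[[paste0(m, "_q3")]] <- q[3]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$mask_condition, out$method), ]
}

# Friedman + pairwise Wilcoxon across methods, per metric & mask condition
.study_stats <- function(records) {
  res <- list()
  for (metric in c("MATV_cm3", "RE_pct", "DSC")) {
    for (cond in unique(records$mask_condition)) {
      g <- records[records$mask_condition == cond, ]
      wide <- stats::reshape(g[, c("case", "method", metric)],
                             idvar = "case", timevar = "method",
                             direction = "wide")
      mat <- as.matrix(wide[, -1, drop = FALSE])
      colnames(mat) <- sub(paste0("^", metric, "\\."), "", colnames(mat))
      if (nrow(mat) < 2L || any(!is.finite(mat))) next
      key <- paste(metric, cond, sep = ".")
      res[[key]] <- list(
        friedman = friedman_test(mat),
        wilcoxon = wilcoxon_bonferroni(mat)
      )
    }
  }
  res
}

#' @export
print.pet_study <- function(x, ...) {
  cat(sprintf("<pet_study> %d cases, motion %s, noise %s, methods %s + ConSeg/AveSeg\n",
              x$config$n_cases, x$config$motion, x$config$noise,
              paste(x$config$methods, collapse = "/")))
  cat("median (IQR) by method and mask condition:\n")
  s <- x$summary
  for (j in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %-9s MATV %6.2f (%6.2f, %6.2f) cm^3  RE %7.2f%%  DSC %.2f\n",
                s$mask_condition[j], s$method[j],
                s$MATV_cm3_median[j], s$MATV_cm3_q1[j], s$MATV_cm3_q3[j],
                s$RE_pct_median[j], s$DSC_median[j]))
  }
  invisible(x)
}

#' @export
summary.pet_study <- function(object, ...) {
  structure(list(summary = object$summary,
                 trt_summary = object$trt_summary,
                 stats = object$stats,
                 n_cases = object$config$n_cases),
            class = "summary.pet_study")
}

#' @export
print.summary.pet_study <- function(x, ...) {
  cat(sprintf("Consensus-contouring study over %d synthetic cases\n\n",
              x$n_cases))
  cat("Metric medians (Q1, Q3):\n")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("\nTest-retest (TRT) medians by method and metric:\n")
  print(x$trt_summary, row.names = FALSE, digits = 3)
  cat("\nFriedman omnibus p-values across methods:\n")
  for (k in names(x$stats))
    cat(sprintf("  %-20s chi-sq = %6.2f, p = %.4g\n", k,
                x$stats[[k]]$friedman$statistic, x$stats[[k]]$friedman$p.value))
  invisible(x)
}

#' Box-and-whisker plots of a study
#'
#' Draws per-method box plots of one metric (or its TRT values) in the
#' convention of the package's summaries: whiskers at 1.5 IQR, outliers
#' beyond the whiskers suppressed for display.
#'
#' @param x a `pet_study`.
#' @param metric one of `"MATV_cm3"`, `"RE_pct"`, `"DSC"`.
#' @param what `"metric"` (one panel per mask condition) or `"trt"`.
#' @param ... passed to [graphics::boxplot()].
#' @return Invisibly, `x`.
#' @export
plot.pet_study <- function(x, metric = "MATV_cm3",
                           what = c("metric", "trt"), ...) {
  what <- match.arg(what)
  if (what == "metric") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    for (cond in c("rectangle", "irregular")) {
      g <- x$records[x$records$mask_condition == cond, ]
      graphics::boxplot(g[[metric]] ~ g$method, range = 1.5, outline = FALSE,
                        xlab = "method", ylab = metric,
                        main = paste(cond, "mask"), ...)
    }
  } else {
    g <- x$trt[x$trt$metric == metric, ]
    graphics::boxplot(g$TRT ~ g$method, range = 1.5, outline = FALSE,
                      xlab = "method", ylab = paste("TRT of", metric), ...)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
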