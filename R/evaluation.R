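#' Stratify patients into quartile groups and fit a KM curve per group
#'
#' Splits at the empirical 25/50/75 percentiles of `values` (type-7
#' quantiles); ties on a cut point are assigned to the lower group, so group
#' sizes differ by at most 1 for distinct values. Typical use: quartiles of
#' individual log(KG).
#'
#' @param values per-patient numeric values (finite), e.g. log(KG)
#' @param survival data frame with `time_days`, `event`, rows aligned
#' @param variable name of the grouping variable (for reporting)
#' @return list of class `stratified_km` with `curves` (named list of
#'   `km_curve`, Q1 = lowest values), `group` (per-patient factor),
#'   `cut_points`, `variable`.
#' @export
stratify_quartiles <- function(values, survival, variable = "logKG") {
  if (any(!is.finite(values))) stop("values must be finite")
  n <- length(values)
  if (n < 4) stop("need at least 4 patients")
  stopifnot(nrow(survival) == n)
  cuts <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  grp <- factor(1 + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3]),
                levels = 1:4, labels = paste0("Q", 1:4))
  curves <- lapply(split(seq_len(n), grp), function(idx) {
    if (length(idx) == 0) return(NULL)
    km_estimate(survival$time_days[idx], survival$event[idx])
  })
  structure(list(curves = curves, group = grp, cut_points = cuts,
                 variable = variable), class = "stratified_km")
}

#' Pairwise Wilcoxon rank-sum tests of TGI metrics between tumor types
#'
#' For each metric column, every pair of groups is compared with a two-sided
#' Wilcoxon rank-sum test; p-values are Holm-adjusted across the pairs within
#' each metric. Groups with fewer than 2 values are skipped with a warning.
#'
#' @param metrics data frame of metric columns (e.g. `logKG`, `logKS`,
#'   `ttg_days`)
#' @param group group label per row (tumor type)
#' @return data frame with `metric`, `group_a`, `group_b`, `statistic`,
#'   `p_raw`, `p_adjusted`.
#' @export
pairwise_metric_tests <- function(metrics, group) {
  group <- as.character(group)
  stopifnot(nrow(metrics) == length(group))
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("skipping group(s) with < 2 values: ", paste(small, collapse = ", "))
    keep <- !(group %in% small)
    metrics <- metrics[keep, , drop = FALSE]
    group <- group[keep]
  }
  gl <- sort(unique(group))
  if (length(gl) < 2) stop("need at least 2 groups with >= 2 values")
  pairs <- utils::combn(gl, 2)
  out <- do.call(rbind, lapply(names(metrics), function(m) {
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      a <- metrics[[m]][group == pairs[1, k]]
      b <- metrics[[m]][group == pairs[2, k]]
      wt <- suppressWarnings(wilcox.test(a, b, exact = length(a) < 50 &&
                                           length(b) < 50))
      data.frame(metric = m, group_a = pairs[1, k], group_b = pairs[2, k],
                 statistic = unname(wt$statistic), p_raw = wt$p.value)
    })
    tab <- do.call(rbind, rows)
    tab$p_adjusted <- p.adjust(tab$p_raw, method = "holm")
    tab
  }))
  rownames(out) <- NULL
  out
}

#' Coverage of observed Kaplan-Meier curves by prediction bands
#'
#' For each subgroup, the fraction of grid points — up to the subgroup's last
#' observed event time — at which the observed KM curve lies inside the
#' band's `[lower, upper]` interval. Optionally writes one overlay PNG per
#' subgroup (band shaded, dashed median, solid observed KM).
#'
#' @param bands named list of `prediction_band`
#' @param observed named list of data frames with `time_days`, `event`
#'   (same names as `bands`)
#' @param grid evaluation grid; defaults to each band's own grid
#' @param dir optional output directory for overlay figures
#' @return data frame with `subgroup`, `coverage`, `n_grid_evaluated`,
#'   `last_event_day`.
#' @export
band_overlay_report <- function(bands, observed, grid = NULL, dir = NULL) {
  if (!setequal(names(bands), names(observed)))
    stop("subgroup names of bands and observed data do not match")
  rows <- lapply(names(bands), function(nm) {
    band <- bands[[nm]]
    obs <- observed[[nm]]
    g <- grid %||% band$grid
    km <- km_estimate(obs$time_days, obs$event)
    last_event <- if (length(km$event_times)) max(km$event_times) else 0
    use <- g <= last_event
    cov <- if (!any(use)) NA_real_ else {
      s <- km_survival_at(km, g[use])
      mean(s >= band$lower[use] - 1e-12 & s <= band$upper[use] + 1e-12)
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      f <- file.path(dir, paste0("band_overlay_", gsub("\\W+", "_", nm), ".png"))
      grDevices::png(f, width = 800, height = 600, res = 110)
      graphics::plot(band$grid, band$upper, type = "n", ylim = c(0, 1),
                     xlab = "days", ylab = "survival", main = nm)
      graphics::polygon(c(band$grid, rev(band$grid)),
                        c(band$upper, rev(band$lower)),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
      graphics::lines(band$grid, band$median, lty = 2, col = "steelblue4")
      graphics::lines(band$grid, km_survival_at(km, band$grid), type = "s")
      grDevices::dev.off()
    }
    data.frame(subgroup = nm, coverage = cov, n_grid_evaluated = sum(use),
               last_event_day = last_event)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Harrell's concordance index
#'
#' Censoring-aware C-index over comparable pairs: a pair is comparable when
#' the earlier time is an observed event; it is concordant when the patient
#' with the earlier event has the higher risk score (ties in score count
#' 1/2). Constant scores give 0.5 by convention.
#'
#' @param risk numeric risk scores, higher = worse prognosis
#' @param survival data frame with `time_days`, `event`
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(risk, survival) {
  stopifnot(length(risk) == nrow(survival), all(is.finite(risk)))
  t <- survival$time_days; e <- survival$event
  num <- 0; den <- 0
  for (i in which(e == 1)) {
    comp <- t > t[i] | (t == t[i] & e == 0)
    comp[i] <- FALSE
    den <- den + sum(comp)
    num <- num + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
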