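# Single-cell population statistics over lineage tables and snapshots.

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the sample mean.
#'
#' @param x numeric vector (n >= 2)
#' @return sd(x)/mean(x); `NA` with a warning when the mean is zero
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("cv needs at least two observations")
  m <- mean(x)
  if (m == 0) {
    warning("cv undefined for zero mean")
    return(NA_real_)
  }
  stats::sd(x) / m
}

#' Product-moment (Pearson) correlation coefficient
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-degenerate
#' @return correlation in [-1, 1]; `NA` with a warning if either variance
#'   is zero
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_r needs at least three pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for zero variance")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Number doubling time of a culture
#'
#' Least-squares slope of ln(count) against time; NDT = ln(2)/slope. An
#' initial transient can be discarded by count or time.
#'
#' @param t time points (min)
#' @param n cell counts (>= 2 after filtering)
#' @param min_count discard points with fewer cells than this
#' @param t_min discard points before this time
#' @return number doubling time (min)
#' @export
ndt_estimate <- function(t, n, min_count = 2, t_min = 0) {
  keep <- n >= min_count & t >= t_min
  t <- t[keep]; n <- n[keep]
  if (length(t) < 3) stop("ndt_estimate needs at least three points")
  if (all(diff(n) <= 0)) stop("counts are non-increasing; no growth to fit")
  fit <- stats::lm(log(n) ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("non-positive growth slope")
  log(2) / slope
}

#' Size-control slope from binned regression
#'
#' For each cell, x = ln(V_bir / <V_bud>) and y = mu * T_unbud. x is cut
#' into equal-count bins; a straight line is fitted to the bin means. A
#' slope near -1 indicates a strong sizer (pre-Start duration fully
#' compensates birth size); near 0, no size control. Only volume ratios
#' enter, so the slope is invariant to rescaling all volumes.
#'
#' @param v_bir birth volumes (fL)
#' @param t_unbud unbudded-phase durations (min)
#' @param mu specific growth rate (min^-1)
#' @param n_bins number of equal-count bins
#' @param v_bud_ref reference volume (default: mean budding volume of the
#'   records, supplied as `v_bud`)
#' @param v_bud budding volumes (used for the default reference)
#' @return list with `slope`, `intercept`, and the binned means
#'   (`x`, `y`)
#' @export
size_control_slope <- function(v_bir, t_unbud, mu, n_bins = 10,
                               v_bud = NULL, v_bud_ref = NULL) {
  ok <- !is.na(v_bir) & !is.na(t_unbud)
  v_bir <- v_bir[ok]; t_unbud <- t_unbud[ok]
  if (is.null(v_bud_ref)) {
    if (is.null(v_bud)) stop("supply v_bud or v_bud_ref")
    v_bud_ref <- mean(v_bud, na.rm = TRUE)
  }
  x <- log(v_bir / v_bud_ref)
  y <- mu * t_unbud
  qs <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
  bins <- cut(x, breaks = unique(qs), include.lowest = TRUE)
  bx <- tapply(x, bins, mean)
  by <- tapply(y, bins, mean)
  keep <- !is.na(bx) & !is.na(by)
  if (sum(keep) < 3) stop("fewer than 3 non-empty bins")
  fit <- stats::lm(by[keep] ~ bx[keep])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       x = unname(bx[keep]), y = unname(by[keep]))
}

#' Poisson fit of mRNA copy-number counts
#'
#' Maximum likelihood: lambda = sample mean. Reports the log-likelihood
#' and the small-sample-corrected information criterion used for model
#' choice against the two-component fit.
#'
#' @param counts non-negative integer counts (n >= 2)
#' @return list of class `yc_mixfit` with `model`, `lambda`,
#'   `loglik`, `aicc`
#' @export
fit_poisson <- function(counts) {
  stopifnot(all(counts >= 0), length(counts) >= 2)
  lambda <- mean(counts)
  ll <- sum(stats::dpois(counts, lambda, log = TRUE))
  k <- 1
  n <- length(counts)
  structure(list(model = "poisson", lambda = lambda, loglik = ll,
                 aicc = -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)),
            class = "yc_mixfit")
}

#' Two-component Poisson mixture fit by EM
#'
#' Fits w * Pois(lambda1) + (1-w) * Pois(lambda2) by
#' expectation-maximization with multiple restarts; the EM log-likelihood
#' is non-decreasing across iterations, and the mixture likelihood at the
#' optimum is at least the single-Poisson likelihood (the single Poisson is
#' nested). Convergence: log-likelihood gain below `tol`.
#'
#' @param counts non-negative integer counts (n >= 2)
#' @param restarts number of random restarts
#' @param tol convergence tolerance on the log-likelihood
#' @param max_iter iteration cap per restart (non-convergence flags the
#'   result)
#' @param seed seed for the restart draws
#' @return list of class `yc_mixfit` with `model`, `w`, `lambda1`,
#'   `lambda2` (`lambda1 <= lambda2`), `loglik`, `aicc`, `converged`,
#'   `loglik_trace` of the best restart
#' @export
fit_two_component_poisson <- function(counts, restarts = 5, tol = 1e-8,
                                      max_iter = 2000, seed = 1) {
  stopifnot(all(counts >= 0), length(counts) >= 2)
  n <- length(counts)
  best <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    m <- mean(counts)
    lam <- sort(stats::runif(2, 0.25, 2) * (m + 0.5))
    w <- stats::runif(1, 0.2, 0.8)
    ll_old <- -Inf
    trace <- numeric()
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w * stats::dpois(counts, lam[1])
      d2 <- (1 - w) * stats::dpois(counts, lam[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g <- d1 / tot
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (ll - ll_old < tol && it > 1) { converged <- TRUE; break }
      ll_old <- ll
      w <- mean(g)
      w <- min(max(w, 1e-8), 1 - 1e-8)
      lam[1] <- sum(g * counts) / max(sum(g), 1e-12)
      lam[2] <- sum((1 - g) * counts) / max(sum(1 - g), 1e-12)
      lam <- pmax(lam, 1e-8)
    }
    if (is.null(best) || ll > best$loglik) {
      ord <- order(lam)
      best <- list(w = if (ord[1] == 1) w else 1 - w,
                   lambda1 = lam[ord[1]], lambda2 = lam[ord[2]],
                   loglik = ll, converged = converged,
                   loglik_trace = trace)
    }
  }
  k <- 3
  best$model <- "two_component_poisson"
  best$aicc <- -2 * best$loglik + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  structure(best, class = "yc_mixfit")
}

#' Choose between single and two-component Poisson
#'
#' @param counts non-negative integer counts
#' @param ... passed to [fit_two_component_poisson()]
#' @return list with both fits and `preferred` (the lower-AICc model)
#' @export
compare_poisson_fits <- function(counts, ...) {
  f1 <- fit_poisson(counts)
  f2 <- fit_two_component_poisson(counts, ...)
  list(poisson = f1, mixture = f2,
       preferred = if (f2$aicc < f1$aicc) "two_component_poisson" else "poisson")
}

#' Per-cell Sic1 decay timescale
#'
#' Total Sic1 (free + all phospho-forms + Clb-bound) is followed from its
#' post-peak maximum; the decay segment, from the peak until the count
#' first reaches max(5, 1% of peak), is fitted with N(t) = N0 exp(-t/tau)
#' by least squares on log counts. Reported: tau and the half-life
#' tau*ln(2). Cells whose Sic1 never falls below half its peak are flagged
#' (`NA` timescale).
#'
#' @param time time grid
#' @param sic1 total-Sic1 count series
#' @param floor_frac decay endpoint as a fraction of the peak
#' @return list with `tau`, `half_life`, `t_onset`, `n0`; `tau = NA` when
#'   no decay segment exists
#' @export
sic1_halflife <- function(time, sic1, floor_frac = 0.01) {
  stopifnot(length(time) == length(sic1))
  # Sic1 re-accumulates in telophase; the decay of interest ends at the
  # cycle's Sic1 minimum, and its peak precedes that minimum
  imin <- which.min(sic1)
  if (imin < 3) {
    return(list(tau = NA_real_, half_life = NA_real_,
                t_onset = NA_real_, n0 = max(sic1)))
  }
  ipk <- which.max(sic1[seq_len(imin)])
  pk <- sic1[ipk]
  if (pk <= 0 || !any(sic1[ipk:imin] < pk / 2)) {
    return(list(tau = NA_real_, half_life = NA_real_,
                t_onset = NA_real_, n0 = pk))
  }
  floor_n <- max(5, floor_frac * pk)
  seg <- ipk:imin
  iend <- seg[which(sic1[seg] <= floor_n)[1]]
  if (is.na(iend)) iend <- imin
  seg <- ipk:iend
  y <- sic1[seg]
  keep <- y > 0
  if (sum(keep) < 3) {
    return(list(tau = NA_real_, half_life = NA_real_,
                t_onset = time[ipk], n0 = pk))
  }
  fit <- stats::lm(log(y[keep]) ~ time[seg][keep])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    return(list(tau = NA_real_, half_life = NA_real_,
                t_onset = time[ipk], n0 = pk))
  }
  tau <- -1 / slope
  list(tau = tau, half_life = tau * log(2), t_onset = time[ipk], n0 = pk)
}

#' Summary statistics of cell-cycle properties
#'
#' Long-format mean/sd/cv/n per variable and mother/daughter group, the
#' shape of the published per-strain tables.
#'
#' @param table a `yc_lineage`
#' @param vars variables to summarize
#' @return data.frame with `variable`, `group`, `mean`, `sd`, `cv`, `n`
#' @export
lineage_summary <- function(table,
                            vars = c("V_bir", "V_bud", "V_div", "T_unbud",
                                     "T_g1", "T_bud", "T_sg2m", "T_div",
                                     "T_whi5")) {
  done <- table[table$arrest == "none", , drop = FALSE]
  groups <- list(all = done,
                 mother = done[done$md_label != "daughter", , drop = FALSE],
                 daughter = done[done$md_label == "daughter", , drop = FALSE])
  out <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (v in vars) {
      x <- d[[v]]
      x <- x[!is.na(x)]
      if (length(x) >= 2) {
        out[[length(out) + 1L]] <- data.frame(
          variable = v, group = g, mean = mean(x), sd = stats::sd(x),
          cv = stats::sd(x) / mean(x), n = length(x))
      }
    }
  }
  do.call(rbind, out)
}

#' Asynchronous-population snapshots
#'
#' One state per extant cell at `t_stop`: per-gene mRNA count histograms
#' with means, all pairwise joint mRNA histograms, and total-protein counts
#' (free + complex-bound + phosphorylated forms summed). Fewer than 100
#' cells flags the output.
#'
#' @param net the `yc_network`
#' @param states list of [cell_state()]s sampled at the observation time
#' @return list with `mrna` (cells x genes count matrix), `protein`
#'   (cells x proteins total matrix), `mrna_means`, `joint` (named list of
#'   2-D tables), `n_cells`, `low_sample`
#' @export
population_snapshots <- function(net, states) {
  genes <- sub("^mRNA_", "", grep("^mRNA_", net$species$name, value = TRUE))
  mr <- t(vapply(states, function(s) s$counts[paste0("mRNA_", genes)],
                 numeric(length(genes))))
  colnames(mr) <- genes
  prots <- names(net$index$totals)
  pr <- t(vapply(states, function(s) {
    vapply(prots, function(p) sum(s$counts[net$index$totals[[p]]]), 0)
  }, numeric(length(prots))))
  colnames(pr) <- prots
  joint <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i < j) {
        joint[[paste(genes[i], genes[j], sep = ":")]] <-
          table(mr[, i], mr[, j])
      }
    }
  }
  list(mrna = mr, protein = pr, mrna_means = colMeans(mr), joint = joint,
       n_cells = length(states), low_sample = length(states) < 100)
}
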