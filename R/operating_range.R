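#' Fit the Gaussian temperature-response model
#'
#' Nonlinear least squares for v = v_max * exp(-(T - t_m)^2 / (2 w^2)) with
#' multi-start initialization: t_m starts at the argmax of the observed
#' rates, v_max at the maximum rate and w at a second-moment estimate of the
#' spread; additional starts perturb t_m and w over the observed temperature
#' range. The Levenberg-Marquardt optimiser is used for robustness to poor
#' starts.
#'
#' @param temperatures degrees C; >= 4 distinct values.
#' @param rates observed rates at `temperatures`; at least one positive.
#' @param n_starts number of extra random-ish starts tried on failure.
#' @return object of class `temperature_fit`: v_max, t_m, w (> 0), fwhm,
#'   r_squared, adj_r_squared (3-parameter adjustment), residuals, fitted,
#'   n_points.
#' @export
fit_gaussian <- function(temperatures, rates, n_starts = 8) {
  if (length(temperatures) != length(rates)) {
    stop("'temperatures' and 'rates' must have equal length", call. = FALSE)
  }
  if (length(unique(temperatures)) < 4L) {
    stop("need >= 4 distinct temperatures", call. = FALSE)
  }
  if (!any(rates > 0)) stop("need at least one positive rate", call. = FALSE)
  df <- data.frame(tt = temperatures, v = rates)
  i_max <- which.max(rates)
  w0 <- sqrt(sum(rates * (temperatures - temperatures[i_max])^2) / sum(rates))
  if (!is.finite(w0) || w0 <= 0) w0 <- diff(range(temperatures)) / 4
  starts <- list(c(v_max = max(rates), t_m = temperatures[i_max], w = w0))
  span <- diff(range(temperatures))
  grid_tm <- seq(min(temperatures), max(temperatures), length.out = n_starts)
  grid_w <- rep(c(span / 8, span / 3), length.out = n_starts)
  for (j in seq_len(n_starts)) {
    starts[[j + 1L]] <- c(v_max = max(rates), t_m = grid_tm[j], w = grid_w[j])
  }
  best <- NULL
  tried <- character(0)
  for (st in starts) {
    tried <- c(tried, sprintf("(v_max=%.3g, t_m=%.3g, w=%.3g)",
                              st[1], st[2], st[3]))
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ v_max * exp(-(tt - t_m)^2 / (2 * w^2)),
                        data = df, start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("Gaussian fit did not converge; starts tried: ",
         paste(tried, collapse = "; "), call. = FALSE)
  }
  cf <- stats::coef(best$fit)
  w_hat <- abs(unname(cf["w"]))
  n <- length(rates)
  p <- 3L
  ss_tot <- sum((rates - mean(rates))^2)
  r2 <- if (ss_tot > 0) 1 - best$rss / ss_tot else 1
  adj_r2 <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  structure(list(
    v_max = unname(cf["v_max"]),
    t_m = unname(cf["t_m"]),
    w = w_hat,
    fwhm = 2 * sqrt(2 * log(2)) * w_hat,
    r_squared = r2,
    adj_r_squared = adj_r2,
    fitted = as.numeric(stats::fitted(best$fit)),
    residuals = as.numeric(stats::residuals(best$fit)),
    temperatures = temperatures,
    rates = rates,
    n_points = n
  ), class = "temperature_fit")
}

#' @export
predict.temperature_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$temperatures else newdata
  gaussian_rate(tt, object$v_max, object$t_m, object$w)
}

#' Full width at half maximum of a Gaussian temperature response
#'
#' FWHM = 2 * sqrt(2 * ln 2) * w (= 2.355 w): the distance between the two
#' temperatures at which the fitted rate equals v_max / 2.
#'
#' @param x a `temperature_fit` or a numeric width parameter w.
#' @return FWHM in degrees C.
#' @export
fwhm <- function(x) {
  w <- if (inherits(x, "temperature_fit")) x$w else x
  if (any(w <= 0)) stop("'w' must be > 0", call. = FALSE)
  2 * sqrt(2 * log(2)) * w
}

#' Fit the power salt-inhibition model
#'
#' Linear regression of rate on c^-0.5 over the strictly positive
#' concentrations, exactly as the model is defined: v = k / sqrt(c) - a with
#' slope k and intercept -a. Observations with zero rate beyond complete
#' inhibition carry no information about the line (measured rates are floored
#' at zero), so zero-rate points are excluded from the regression. The
#' uninhibited rate v0 is taken from the c = 0 observation(s) (mean if
#' several). Inhibition thresholds follow from the model: complete inhibition
#' at SA0 = (k/a)^2 and onset of inhibition at SAI = (k/(v0+a))^2. A
#' non-positive fitted k or a (no inhibition signal) yields a flagged fit
#' with undefined thresholds.
#'
#' @param concentrations % w/v; must include one or more zeros (for v0) and
#'   >= 3 distinct positive values.
#' @param rates observed rates at `concentrations`.
#' @param v0 optional override for the uninhibited rate.
#' @return object of class `salt_fit`: k, a, v0, sai, sa0, r_squared,
#'   flagged, fitted, residuals (over the c > 0 points).
#' @export
fit_power <- function(concentrations, rates, v0 = NULL) {
  if (length(concentrations) != length(rates)) {
    stop("'concentrations' and 'rates' must have equal length", call. = FALSE)
  }
  pos <- concentrations > 0
  if (length(unique(concentrations[pos])) < 3L) {
    stop("need >= 3 distinct positive concentrations", call. = FALSE)
  }
  if (is.null(v0)) {
    if (!any(!pos)) {
      stop("need a c = 0 observation (or explicit 'v0') for the uninhibited rate",
           call. = FALSE)
    }
    v0 <- mean(rates[!pos])
  }
  use <- pos & rates > 0
  if (sum(use) < 2L) {
    stop("need >= 2 positive-rate observations at c > 0 to fit the line",
         call. = FALSE)
  }
  x <- 1 / sqrt(concentrations[use])
  y <- rates[use]
  fit <- stats::lm(y ~ x)
  k <- unname(stats::coef(fit)[2])
  a <- -unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  flagged <- !is.finite(k) || k <= 0 || a <= 0 || v0 <= 0
  sa0 <- if (flagged) NA_real_ else (k / a)^2
  sai <- if (flagged) NA_real_ else (k / (v0 + a))^2
  structure(list(
    k = k, a = a, v0 = v0, sai = sai, sa0 = sa0,
    r_squared = r2, flagged = flagged,
    concentrations = concentrations[use],
    rates = y,
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(stats::residuals(fit)),
    n_points = sum(use)
  ), class = "salt_fit")
}

#' @export
predict.salt_fit <- function(object, newdata = NULL, ...) {
  cc <- if (is.null(newdata)) object$concentrations else newdata
  power_rate(cc, object$k, object$a, object$v0)
}

#' Normalize a rate curve to percent of its maximum
#'
#' @param rates numeric rates; maximum must be > 0.
#' @return rates rescaled to [0, 100] with maximum exactly 100.
#' @export
normalize_rates <- function(rates) {
  m <- max(rates)
  if (!is.finite(m) || m <= 0) {
    stop("maximum rate must be > 0 to normalize", call. = FALSE)
  }
  100 * rates / m
}

# Insert-and-absorb compact letter display from a logical "significantly
# different" pairwise matrix. Returns one letter string per group.
compact_letters <- function(signif_mat, group_names) {
  n <- length(group_names)
  cols <- list(rep(TRUE, n))  # start: all groups share one letter
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!signif_mat[i, j]) next
      k <- 1L
      while (k <= length(cols)) {
        col <- cols[[k]]
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          cols[[k]] <- c1
          cols[[length(cols) + 1L]] <- c2
          # absorb: drop columns that are subsets of another
          keep <- rep(TRUE, length(cols))
          for (u in seq_along(cols)) {
            for (v in seq_along(cols)) {
              if (u != v && keep[u] && keep[v] &&
                  all(cols[[u]] <= cols[[v]]) && any(cols[[u]] < cols[[v]])) {
                keep[u] <- FALSE
              }
            }
          }
          cols <- cols[keep]
          k <- 0L
        }
        k <- k + 1L
      }
    }
  }
  # order columns by first group they contain, label a, b, c, ...
  ord <- order(vapply(cols, function(c) which(c)[1], 1))
  cols <- cols[ord]
  letters_used <- letters[seq_along(cols)]
  out <- vapply(seq_len(n), function(g) {
    paste0(letters_used[vapply(cols, function(c) c[g], TRUE)], collapse = "")
  }, "")
  stats::setNames(out, group_names)
}

#' Compare an operating-range parameter across communities
#'
#' One-way ANOVA followed by Tukey's HSD on per-replicate parameter values,
#' with a compact letter display at the chosen significance level (default
#' alpha = 0.1): communities sharing a letter do not differ at that level.
#'
#' @param values numeric parameter values (one per community x replicate).
#' @param groups community labels, same length as `values`.
#' @param alpha significance level for the letter display (default 0.1).
#' @return object of class `fit_comparison`: data.frame `summary` (group,
#'   mean, sd, n, letters), `anova_f`, `anova_p`, matrix `tukey` of pairwise
#'   adjusted p-values, `alpha`.
#' @export
compare_parameters <- function(values, groups, alpha = 0.1) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop("'values' and 'groups' must have equal length", call. = FALSE)
  }
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("need >= 2 replicates per group", call. = FALSE)
  gnames <- names(tab)
  within_var <- vapply(gnames, function(g) stats::var(values[groups == g]), 1)
  if (all(within_var == 0)) {
    stop("zero within-group variance in all groups", call. = FALSE)
  }
  f <- factor(groups, levels = gnames)
  fit <- stats::aov(values ~ f)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
  pmat <- matrix(NA_real_, length(gnames), length(gnames),
                 dimnames = list(gnames, gnames))
  for (row in rownames(tk)) {
    pair <- strsplit(row, "-", fixed = TRUE)[[1]]
    pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[row, "p adj"]
  }
  sig <- pmat < alpha
  sig[is.na(sig)] <- FALSE
  letters_out <- compact_letters(sig, gnames)
  summ <- data.frame(
    group = gnames,
    mean = vapply(gnames, function(g) mean(values[groups == g]), 1),
    sd = vapply(gnames, function(g) stats::sd(values[groups == g]), 1),
    n = as.integer(tab),
    letters = unname(letters_out),
    stringsAsFactors = FALSE
  )
  rownames(summ) <- NULL
  structure(list(summary = summ,
                 anova_f = an[["F value"]][1],
                 anova_p = an[["Pr(>F)"]][1],
                 tukey = pmat, alpha = alpha),
            class = "fit_comparison")
}
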