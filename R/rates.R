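# Bunsen solubility coefficients for N2O in pure water, tabulated every 5 C
# from standard gas-solubility references (dimensionless: volume of gas at
# STP dissolved per volume of water at 1 atm partial pressure). Salinity
# dependence ignored: the salt gradient is incubated at a single temperature.
.bunsen_n2o_table <- data.frame(
  temp_c = seq(0, 60, by = 5),
  bunsen = c(1.306, 1.065, 0.882, 0.744, 0.636, 0.550, 0.482,
             0.427, 0.382, 0.345, 0.315, 0.290, 0.270)
)

#' Bunsen solubility coefficient of N2O in water
#'
#' Linear interpolation in a 0-60 C reference table. No extrapolation:
#' temperatures outside the table range are an error.
#'
#' @param temp_c temperature(s), degrees C, within 0-60.
#' @return dimensionless Bunsen coefficient(s).
#' @export
n2o_bunsen <- function(temp_c) {
  rng <- range(.bunsen_n2o_table$temp_c)
  if (any(!is.finite(temp_c)) || any(temp_c < rng[1]) || any(temp_c > rng[2])) {
    stop(sprintf("temperature outside solubility table range [%g, %g] C",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(.bunsen_n2o_table$temp_c, .bunsen_n2o_table$bunsen,
                xout = temp_c)$y
}

#' Correct headspace N2O amounts for the dissolved fraction
#'
#' Converts measured headspace amounts to total produced amounts by
#' multiplying with (1 + beta(T) * V_liquid / V_headspace), where beta is the
#' Bunsen solubility coefficient of N2O at the incubation temperature. The
#' correction factor is constant in time, so it commutes with the linear rate
#' fit.
#'
#' @param series gas-series data.frame with columns n2o_amount,
#'   incubation_temp_c, liquid_volume_ml, headspace_volume_ml (the dialect
#'   written by [gen_gas_series()] / read by [read_gas_csv()]).
#' @return the series with n2o_amount replaced by total amounts; corrected
#'   amounts are always >= the measured ones.
#' @export
correct_dissolved <- function(series) {
  need <- c("n2o_amount", "incubation_temp_c", "liquid_volume_ml",
            "headspace_volume_ml")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("series is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  beta <- n2o_bunsen(series$incubation_temp_c)
  factor <- 1 + beta * series$liquid_volume_ml / series$headspace_volume_ml
  series$n2o_amount <- series$n2o_amount * factor
  series
}

#' Fit a linear N2O accumulation rate
#'
#' Ordinary least-squares regression of amount on time. Negative fitted
#' slopes are floored at zero with a warning (production rates are physically
#' non-negative; inhibition is carried by the response-model intercept, not
#' by negative rates).
#'
#' @param times sampling times, h; >= 3 strictly increasing non-negative
#'   values.
#' @param amounts gas amounts at `times` (any consistent unit).
#' @param warn warn when a negative slope is floored (default TRUE).
#' @return object of class `rate_estimate`: list(rate, intercept, r_squared,
#'   n_points).
#' @export
fit_linear_rate <- function(times, amounts, warn = TRUE) {
  if (length(times) != length(amounts)) {
    stop("'times' and 'amounts' must have equal length", call. = FALSE)
  }
  if (length(times) < 3L) stop("need >= 3 time points", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  xc <- times - mean(times)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("all times identical", call. = FALSE)
  slope <- sum(xc * amounts) / sxx
  intercept <- mean(amounts) - slope * mean(times)
  fitted <- intercept + slope * times
  ss_res <- sum((amounts - fitted)^2)
  ss_tot <- sum((amounts - mean(amounts))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res <= 1e-12)
  r2 <- min(max(r2, 0), 1)
  if (slope < 0) {
    if (warn) warning("negative fitted slope floored at 0", call. = FALSE)
    slope <- 0
  }
  structure(list(rate = slope, intercept = intercept, r_squared = r2,
                 n_points = length(times)),
            class = "rate_estimate")
}

#' Estimate denitrification rates for every flask in a gas-series table
#'
#' Optionally applies the dissolved-gas correction, then fits a linear rate
#' per flask. Rates can be normalized per g dry soil.
#'
#' @param gas data.frame in the [gen_gas_series()] dialect.
#' @param correct apply [correct_dissolved()] first (default TRUE).
#' @param per_gram divide rates by `soil_mass` (default FALSE).
#' @param soil_mass g soil per flask, used when `per_gram` is TRUE.
#' @return data.frame: flask_id, community, replicate, gradient_type,
#'   condition_value, rate, intercept, r_squared, n_points.
#' @export
estimate_rates <- function(gas, correct = TRUE, per_gram = FALSE, soil_mass = 8) {
  if (correct) gas <- correct_dissolved(gas)
  keys <- unique(gas[, c("flask_id", "community", "replicate",
                         "gradient_type", "condition_value")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- gas$flask_id == keys$flask_id[i]
    fit <- fit_linear_rate(gas$time_h[sel], gas$n2o_amount[sel], warn = FALSE)
    cbind(keys[i, , drop = FALSE],
          data.frame(rate = if (per_gram) fit$rate / soil_mass else fit$rate,
                     intercept = fit$intercept, r_squared = fit$r_squared,
                     n_points = fit$n_points))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
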