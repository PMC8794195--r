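#' Synthetic hospital census configuration
#'
#' The generator emulates a mid/long-stay hospital in which every discharge
#' frees a bed that is refilled by a referred admission only after a random
#' delay. Daily discharges are Poisson; each discharged slot schedules one
#' admission after a lag drawn from the configured family. The census
#' (in-patients, InP) therefore wanders: the longer the refill lag, the
#' stronger the Brownian character of the InP series, while the daily
#' admissions-minus-discharges difference (DDiAd) stays white-like.
#'
#' Defaults mirror the study conditions: 192 beds, a target census of 150,
#' 1329 consecutive daily records, 3.5 discharges/day (mean length of stay
#' 150/3.5 ~ 43 days) and a geometric refill lag with mean 150 days, the
#' scale at which the simulated census reproduces the observed structure
#' (census dimension ~1.34, difference series white).
#'
#' @param beds bed capacity (positive integer).
#' @param days number of daily records.
#' @param target_census initial/target number of in-patients (<= beds).
#' @param mean_discharges_per_day Poisson mean of daily discharges.
#' @param lag_family one of "geometric", "fixed", "uniform".
#' @param lag_mean mean refill delay in days (>= 0). For "uniform" the lag
#'   is drawn from 0..2*lag_mean; "fixed" uses the constant rounded mean.
#' @param inject_newyear_spike add impossible (>900) admission/discharge
#'   counts on the two year-boundary days the cleaning stage must repair.
#' @param inject_gap NULL or c(start_day, length): a contiguous block of
#'   missing values (0-based start day index).
#' @return a list of class `hospital_config`.
#' @export
hospital_config <- function(beds = 192L, days = 1329L, target_census = 150L,
                            mean_discharges_per_day = 3.5,
                            lag_family = c("geometric", "fixed", "uniform"),
                            lag_mean = 150,
                            inject_newyear_spike = FALSE,
                            inject_gap = NULL) {
  lag_family <- match.arg(lag_family)
  stopifnot(beds >= 1, days >= 1, mean_discharges_per_day > 0, lag_mean >= 0)
  if (target_census > beds)
    stop("infeasible config: target_census (", target_census,
         ") exceeds beds (", beds, ")")
  if (!is.null(inject_gap)) {
    stopifnot(length(inject_gap) == 2L, inject_gap[2] >= 1,
              inject_gap[1] >= 1, sum(inject_gap) <= days - 1)
  }
  structure(list(beds = as.integer(beds), days = as.integer(days),
                 target_census = as.integer(target_census),
                 mean_discharges_per_day = mean_discharges_per_day,
                 lag_family = lag_family, lag_mean = lag_mean,
                 inject_newyear_spike = isTRUE(inject_newyear_spike),
                 inject_gap = inject_gap),
            class = "hospital_config")
}

draw_lags <- function(k, family, lag_mean) {
  if (lag_mean == 0) return(integer(k))
  switch(family,
         geometric = stats::rgeom(k, 1 / (lag_mean + 1)),
         fixed     = rep.int(as.integer(round(lag_mean)), k),
         uniform   = sample.int(2 * as.integer(round(lag_mean)) + 1L, k,
                                replace = TRUE) - 1L)
}

# Day indices (0-based) standing in for Jan-1 of the two full study years;
# the real series starts May 1, so the first year boundary is day 245.
newyear_days <- function(days) {
  d <- c(245L, 610L)
  d[d < days]
}

#' Simulate a hospital census panel
#'
#' Runs the discharge/refill mechanism day by day. Within a day: scheduled
#' admissions arrive (deferred to the next day if the ward is full), then
#' discharges are drawn and each schedules a future admission after a lag
#' (a lag of 0 readmits the same day). The pending-admission pipeline is
#' pre-seeded at its stationary rate so the census starts in equilibrium
#' around `target_census`.
#'
#' @param config a `hospital_config`.
#' @param seed integer seed; the whole panel is reproducible from it.
#' @return a list of class `simulated_panel` with elements `series` (a
#'   `panel_series` data frame: day, adm, dis, inp), `true_lag_draws`
#'   (all refill delays drawn, in days) and `seed`.
#' @export
simulate_hospital <- function(config, seed = 1L) {
  stopifnot(inherits(config, "hospital_config"))
  with_seed(seed, {
    days <- config$days
    lam <- config$mean_discharges_per_day
    p_geo <- 1 / (config$lag_mean + 1)
    horizon <- days + 1L
    pend <- integer(horizon)
    # stationary pre-seed: refills of pre-study discharges arrive at rate
    # lam * P(lag >= t), geometric tail regardless of configured family
    if (config$lag_mean > 0) {
      tail_p <- lam * (1 - p_geo)^(seq_len(days) - 1)
      pend <- pend + c(stats::rpois(days, tail_p), 0L)
    }
    adm <- dis <- integer(days)
    inp <- integer(days)
    cur <- config$target_census
    carry <- 0L                      # arrivals deferred by a full ward
    all_lags <- vector("list", days)
    for (t in seq_len(days)) {
      due <- pend[t] + carry
      a <- min(due, config$beds - cur)
      carry <- due - a
      cur <- cur + a
      d <- min(stats::rpois(1, lam), cur)
      if (d > 0) {
        lags <- draw_lags(d, config$lag_family, config$lag_mean)
        all_lags[[t]] <- lags
        same_day <- sum(lags == 0L)
        cur <- cur - d
        if (same_day > 0 && cur + same_day <= config$beds) {
          a <- a + same_day
          cur <- cur + same_day
        } else if (same_day > 0) {
          carry <- carry + same_day
        }
        later <- lags[lags > 0L]
        for (L in later) {
          idx <- t + L
          if (idx <= horizon) pend[idx] <- pend[idx] + 1L
        }
      } else {
        cur <- cur - d
      }
      adm[t] <- a; dis[t] <- d; inp[t] <- cur
    }
    series <- new_panel(day = seq_len(days) - 1L, adm = adm, dis = dis,
                        inp = inp, beds = config$beds)
    if (config$inject_newyear_spike) {
      for (d0 in newyear_days(days)) {
        i <- d0 + 1L
        series$adm[i] <- series$adm[i] + 900L
        series$dis[i] <- series$dis[i] + 900L
      }
    }
    if (!is.null(config$inject_gap)) {
      i <- config$inject_gap[1] + seq_len(config$inject_gap[2])
      series$adm[i] <- NA_integer_
      series$dis[i] <- NA_integer_
      series$inp[i] <- NA_integer_
    }
    structure(list(series = series,
                   true_lag_draws = unlist(all_lags),
                   seed = as.integer(seed)),
              class = "simulated_panel")
  })
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat("Simulated hospital panel:", nrow(x$series), "days,",
      attr(x$series, "beds"), "beds, seed", x$seed, "\n")
  invisible(x)
}
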