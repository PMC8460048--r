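# Enzyme classes, rate constants, CBH processivity and lignin adhesion
# parameters.  Default rates are expressed per hour; the whole kinetics block
# can equally be read in arbitrary units since only rate ratios shape the
# dynamics up to a rescaling of time.

#' CBH processive step rate
#'
#' `k_CBH = N_steps / t`, the cellobiose release rate of an attached
#' cellobiohydrolase (about 0.56 1/s, i.e. 2000 1/h, for 50 steps in 90 s).
#'
#' @param N_steps mean number of processive steps per attachment.
#' @param t mean residence time.
#' @return rate in inverse time units of `t`.
#' @export
cbh_step_rate <- function(N_steps, t) {
  if (t <= 0) stop("t must be positive")
  N_steps / t
}

#' Draw a CBH residence time
#'
#' Normal(t_mean, sigma_t) truncated at zero (redraw); with `sigma_t = 0`
#' the draw is exactly `t_mean`.
#'
#' @param t_mean mean residence time (> 0).
#' @param sigma_t standard deviation.
#' @param n number of draws.
#' @export
draw_residence_time <- function(t_mean, sigma_t, n = 1) {
  if (t_mean <= 0) stop("t_mean must be positive")
  if (sigma_t <= 0) return(rep(t_mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, t_mean, sigma_t)
      if (x > 0) break
    }
    out[i] <- x
  }
  out
}

#' Draw the number of monolignols consumed by one adhesion event
#'
#' Normally distributed around the mean, rounded, floored at 1 and capped at
#' the remaining pool; a pool of 0 returns 0 (no binding possible).
#'
#' @param mean mean monolignols consumed per bound enzyme.
#' @param sigma standard deviation.
#' @param pool remaining monolignols available for binding.
#' @export
draw_lignols_consumed <- function(mean, sigma, pool) {
  if (pool < 0) stop("pool must be >= 0")
  if (pool == 0) return(0L)
  x <- if (sigma <= 0) mean else rnorm(1, mean, sigma)
  as.integer(min(pool, max(1, round(x))))
}

#' CBH processivity parameters
#'
#' @param N_steps mean processive steps per attachment.
#' @param t_CBH mean residence time (h by default convention; 90 s).
#' @param sigma_t residence-time SD (default 10% of `t_CBH`).
#' @param R_CBH steric radius in nm; while a CBH is attached no other
#'   digestion reaction can fire within `2 * R_CBH` of its working position.
#' @export
cbh_params <- function(N_steps = 50, t_CBH = 90 / 3600,
                       sigma_t = 0.1 * t_CBH, R_CBH = 4.25) {
  if (N_steps <= 0 || t_CBH <= 0 || sigma_t < 0 || R_CBH < 0) {
    stop("invalid CBH parameters")
  }
  structure(list(N_steps = N_steps, t_CBH = t_CBH, sigma_t = sigma_t,
                 k_CBH = cbh_step_rate(N_steps, t_CBH), R_CBH = R_CBH),
            class = "cbh_params")
}

#' Lignin adhesion parameters
#'
#' Lignin irreversibly binds randomly selected free enzymes (probability
#' proportional to each class's free count).  Every binding event consumes a
#' normally distributed number of monolignols from a finite pool initialized
#' to the total monolignol count; when the pool is exhausted no further
#' binding can occur.
#'
#' @param k_bind adhesion event rate per free enzyme.
#' @param N_lignols_bound mean monolignols consumed per bound enzyme.
#' @param sigma_lignols SD of the consumption draw (default 10% of the mean).
#' @export
lignin_adhesion <- function(k_bind = 0.1, N_lignols_bound = 50,
                            sigma_lignols = 0.1 * N_lignols_bound) {
  if (k_bind < 0 || N_lignols_bound <= 0 || sigma_lignols < 0) {
    stop("invalid lignin adhesion parameters")
  }
  structure(list(k_bind = k_bind, N_lignols_bound = N_lignols_bound,
                 sigma_lignols = sigma_lignols), class = "lignin_adhesion")
}

#' Enzyme cocktail: abundances and kinetics
#'
#' The four enzyme classes are strictly distinct: endoglucanase (EG) cuts
#' internal cellulose bonds (never the two outermost bonds at each fragment
#' end), cellobiohydrolase (CBH) attaches to exposed cellulose ends and
#' processively releases cellobiose, beta-glucosidase (BGL) cleaves cellobiose
#' into two glucose, xylanase (XYL) cuts any exposed xylan bond.  Per-bond
#' digestion rates `k_EG`/`k_XYL`, the per-cellobiose `k_BGL`, the attachment
#' rate `k_CBH_attach` and the adhesion rate `k_bind` are free parameters of
#' the model (they are what the fitting procedure optimizes); the defaults are
#' chosen so that a default medium-severity substrate is largely digested over
#' a 72 h course at the default counts.
#'
#' @param counts free enzyme counts `c(EG, CBH, BGL, XYL)`.
#' @param k_EG EG rate per accessible bond per free enzyme.
#' @param k_XYL XYL rate per accessible bond per free enzyme.
#' @param k_BGL BGL rate per cellobiose per free enzyme.
#' @param k_CBH_attach CBH attachment rate per exposed end per free enzyme
#'   (default equal in magnitude to `k_EG`).
#' @param cbh a [cbh_params()].
#' @param lignin a [lignin_adhesion()].
#' @param time_unit label for the time axis (`"h"` by default).
#' @export
cocktail <- function(counts = c(EG = 20, CBH = 52, BGL = 15, XYL = 61),
                     k_EG = 2e-3, k_XYL = 6e-3, k_BGL = 0.1,
                     k_CBH_attach = k_EG,
                     cbh = cbh_params(), lignin = lignin_adhesion(),
                     time_unit = "h") {
  counts <- as.integer(counts)
  if (length(counts) != 4 || any(counts < 0)) {
    stop("counts must be four non-negative integers (EG, CBH, BGL, XYL)")
  }
  if (any(c(k_EG, k_XYL, k_BGL, k_CBH_attach) < 0)) stop("rates must be >= 0")
  structure(list(counts = setNames(counts, c("EG", "CBH", "BGL", "XYL")),
                 k_EG = k_EG, k_XYL = k_XYL, k_BGL = k_BGL,
                 k_CBH_attach = k_CBH_attach, cbh = cbh, lignin = lignin,
                 time_unit = time_unit),
            class = "cocktail")
}

#' @export
print.cocktail <- function(x, ...) {
  cat("<cocktail> counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  k_EG=%.4g k_XYL=%.4g k_BGL=%.4g k_CBH_attach=%.4g [1/%s]\n",
              x$k_EG, x$k_XYL, x$k_BGL, x$k_CBH_attach, x$time_unit))
  cat(sprintf("  CBH: k=%.4g, t=%.4g +/- %.4g, R=%.3g nm; lignin: k_bind=%.4g, %g lignols/bind\n",
              x$cbh$k_CBH, x$cbh$t_CBH, x$cbh$sigma_t, x$cbh$R_CBH,
              x$lignin$k_bind, x$lignin$N_lignols_bound))
  invisible(x)
}
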