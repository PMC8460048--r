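# Generational hybrid random/gradient fitting of simulation parameters to
# saccharification time courses.
#
# Each generation draws a number of candidate parameter subsets uniformly
# within a fractional window Delta around the incumbent, evaluates each by
# replicate-averaged forward simulation against all experimental curves, and
# accepts the best candidate only if it improves the incumbent error.  After
# an acceptance the next generation is centred along the direction from the
# old to the new parameters (directed mode); if a directed generation fails
# to improve, the search reverts to undirected sampling around the incumbent.

#' Bounded named parameter vector
#'
#' @param values named numeric vector.
#' @param lower,upper bounds (recycled, default 0 / Inf; fraction-like
#'   parameters such as crystallinity fractions and r_c,a should be given
#'   upper bound 1).
#' @export
param_set <- function(values, lower = 0, upper = Inf) {
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("parameters must be named")
  }
  lower <- rep_len(lower, length(values))
  upper <- rep_len(upper, length(values))
  if (any(values < lower | values > upper)) stop("values outside bounds")
  structure(list(values = values, lower = setNames(lower, names(values)),
                 upper = setNames(upper, names(values))),
            class = "param_set")
}

#' Fit configuration
#'
#' @param delta fractional window: candidates lie in
#'   `[p * (1 - delta), p * (1 + delta)]` coordinate-wise.
#' @param n_subsets candidate subsets per generation.
#' @param n_replicates forward-simulation replicates per evaluation.
#' @param max_generations generation budget.
#' @param stall stop after this many consecutive generations without
#'   improvement.
#' @param seed master seed (replicate seeds are shared across the subsets of
#'   a generation so candidates are compared under common random numbers).
#' @export
fit_config <- function(delta = 0.3, n_subsets = 8, n_replicates = 3,
                       max_generations = 20, stall = 10, seed = 1) {
  if (delta <= 0) stop("delta must be > 0")
  if (n_subsets < 1 || n_replicates < 1) stop("counts must be >= 1")
  structure(list(delta = delta, n_subsets = n_subsets,
                 n_replicates = n_replicates,
                 max_generations = max_generations, stall = stall,
                 seed = seed), class = "fit_config")
}

#' Experimental (or pseudo-experimental) dataset for one condition
#'
#' @param label condition name (e.g. a pre-treatment severity).
#' @param times strictly increasing measurement times.
#' @param glucose_pct glucan-to-glucose conversion percentages.
#' @param xylose_pct xylan-to-xylose conversion percentages (or NULL).
#' @param fibril_args condition-specific substrate arguments for
#'   [microfibril()] (composition, crystallinity, ...).
#' @export
experimental_dataset <- function(label, times, glucose_pct, xylose_pct = NULL,
                                 fibril_args = list()) {
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  chk <- c(glucose_pct, xylose_pct)
  if (any(chk < 0 | chk > 100)) stop("percentages must lie in [0, 100]")
  structure(list(label = label, times = times, glucose_pct = glucose_pct,
                 xylose_pct = xylose_pct, fibril_args = fibril_args),
            class = "experimental_dataset")
}

#' Sample one generation of candidate parameter vectors
#'
#' Each coordinate is drawn uniformly in `[c - delta * |p|, c + delta * |p|]`
#' around the generation centre `c` (window width set by the incumbent `p`),
#' then clipped to the bounds.
#'
#' @param p_old incumbent [param_set()].
#' @param cfg a [fit_config()].
#' @param centre optional centre of the window (defaults to the incumbent;
#'   directed generations centre ahead of it).
#' @return list of named numeric vectors.
#' @export
sample_generation <- function(p_old, cfg, centre = NULL) {
  v <- p_old$values
  if (is.null(centre)) centre <- v
  lapply(seq_len(cfg$n_subsets), function(i) {
    w <- cfg$delta * abs(v)
    x <- runif(length(v), centre - w, centre + w)
    x <- pmin(pmax(x, p_old$lower), p_old$upper)
    setNames(x, names(v))
  })
}

# apply named parameters onto (fibril_args, cocktail) for one condition.
# Recognized names: k_EG, k_XYL, k_BGL, k_CBH_attach, k_bind,
# N_lignols_bound, frac_cellulose, frac_hemicellulose, r_ca_cellulose,
# r_ca_hemicellulose, mu_covering.
apply_params <- function(params, fibril_args, ck) {
  for (nm in names(params)) {
    val <- unname(params[nm])
    switch(nm,
      k_EG = { ck$k_EG <- val },
      k_XYL = { ck$k_XYL <- val },
      k_BGL = { ck$k_BGL <- val },
      k_CBH_attach = { ck$k_CBH_attach <- val },
      k_bind = { ck$lignin$k_bind <- val },
      N_lignols_bound = { ck$lignin$N_lignols_bound <- val },
      frac_cellulose = ,
      frac_hemicellulose = ,
      r_ca_cellulose = ,
      r_ca_hemicellulose = {
        prof <- fibril_args$crystallinity
        if (is.null(prof)) prof <- crystallinity_profile()
        prof[[nm]] <- min(1, max(0, val))
        class(prof) <- "crystallinity_profile"
        fibril_args$crystallinity <- prof
      },
      mu_covering = {
        cm <- fibril_args$covering
        if (is.null(cm)) cm <- covering_model()
        cm$mu <- min(1, max(0, val))
        class(cm) <- "covering_model"
        fibril_args$covering <- cm
      },
      stop("unknown fit parameter: ", nm))
  }
  list(fibril_args = fibril_args, ck = ck)
}

#' Combined fitting error of a parameter vector
#'
#' For each condition: run `n_replicates` forward simulations, average,
#' interpolate the mean curves at the experimental time points and take the
#' RMSE against the data, separately for the glucose and xylose curves.  The
#' combined error is the unweighted mean over all curves.  A failing
#' simulation yields `Inf` (the subset is discarded).
#'
#' @param params named numeric vector of parameter values.
#' @param datasets list of [experimental_dataset()]s.
#' @param ck base [cocktail()].
#' @param cfg a [fit_config()] (replicates).
#' @param run_cfg a [run_config()] covering the experimental time span.
#' @param seed replicate master seed.
#' @export
evaluate_error <- function(params, datasets, ck = cocktail(),
                           cfg = fit_config(), run_cfg = run_config(),
                           seed = 1) {
  errs <- c()
  for (ds in datasets) {
    res <- try({
      ap <- apply_params(params, ds$fibril_args, ck)
      reps <- simulate_replicates(cfg$n_replicates, ap$fibril_args, ap$ck,
                                  run_cfg, master_seed = seed)
      g <- interp_mean_curve(reps, ds$times, "glucan")
      e <- sqrt(mean((g - ds$glucose_pct)^2))
      if (!is.null(ds$xylose_pct)) {
        x <- interp_mean_curve(reps, ds$times, "xylan")
        e <- c(e, sqrt(mean((x - ds$xylose_pct)^2)))
      }
      e
    }, silent = TRUE)
    if (inherits(res, "try-error")) return(Inf)
    errs <- c(errs, res)
  }
  mean(errs)
}

#' Run the generational fit
#'
#' @param datasets list of [experimental_dataset()]s (fitted simultaneously).
#' @param init initial [param_set()].
#' @param cfg a [fit_config()].
#' @param ck base [cocktail()].
#' @param run_cfg forward-simulation [run_config()].
#' @return list with `best` (named vector), `best_error`, and `trace`
#'   (data frame: generation, error of the incumbent after the generation,
#'   accepted flag, search mode).
#' @export
run_fit <- function(datasets, init, cfg = fit_config(), ck = cocktail(),
                    run_cfg = run_config()) {
  stopifnot(inherits(init, "param_set"), inherits(cfg, "fit_config"))
  withr::local_seed(cfg$seed)
  p_old <- init
  err_old <- evaluate_error(p_old$values, datasets, ck, cfg, run_cfg,
                            seed = cfg$seed)
  trace <- data.frame(generation = 0L, error = err_old, accepted = NA,
                      mode = "init", stringsAsFactors = FALSE)
  mode <- "random"
  centre <- NULL
  stall <- 0L
  gen <- 0L
  while (gen < cfg$max_generations && stall < cfg$stall) {
    gen <- gen + 1L
    gen_seed <- (cfg$seed + 7919L * gen) %% .Machine$integer.max
    cand <- sample_generation(p_old, cfg, centre)
    errs <- vapply(cand, evaluate_error, numeric(1), datasets, ck, cfg,
                   run_cfg, seed = gen_seed)
    best <- which.min(errs)
    accepted <- is.finite(errs[best]) && errs[best] < err_old
    if (accepted) {
      direction <- cand[[best]] - p_old$values
      p_old$values <- cand[[best]]
      err_old <- errs[best]
      # directed mode: centre the next window ahead along the accepted step
      centre <- pmin(pmax(p_old$values + direction, p_old$lower), p_old$upper)
      mode_next <- "gradient"
      stall <- 0L
    } else {
      # failed generation: revert to undirected sampling at the incumbent
      centre <- NULL
      mode_next <- "random"
      stall <- stall + 1L
    }
    trace <- rbind(trace, data.frame(generation = gen, error = err_old,
                                     accepted = accepted, mode = mode,
                                     stringsAsFactors = FALSE))
    mode <- mode_next
  }
  list(best = p_old$values, best_error = err_old, trace = trace)
}
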