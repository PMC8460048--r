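# R-side wrapper around the compiled Gillespie engine.

#' Run configuration for the stochastic simulator
#'
#' @param t_end stop time (same unit as the cocktail rates).
#' @param record_interval spacing of the recording grid.
#' @param max_events optional event-count stopping rule.
#' @param record_dp record the cellulose DP distribution at every grid point.
#' @param dp_max largest DP bin (longer fragments land in the last bin).
#' @param seed integer seed; every run is bit-reproducible given the seed.
#' @param return_state return the full final state (bond flags, fragments,
#'   attachments, per-bond digestion weights) for inspection.
#' @param debug verify the conservation laws (glucose, xylose, enzyme
#'   headcount) after every event; stops on any violation.
#' @export
run_config <- function(t_end = 72, record_interval = 2, max_events = Inf,
                       record_dp = FALSE, dp_max = 210, seed = NULL,
                       return_state = FALSE, debug = FALSE) {
  if (!is.finite(t_end) && !is.finite(max_events)) {
    stop("at least one stopping rule (t_end, max_events) must be finite")
  }
  structure(list(t_end = t_end, record_interval = record_interval,
                 max_events = max_events, record_dp = record_dp,
                 dp_max = dp_max, seed = seed,
                 return_state = return_state, debug = debug),
            class = "run_config")
}

# flatten a microfibril into plain vectors for the C++ engine
fibril_payload <- function(fib) {
  cs <- fib$cross_section
  n_site <- nrow(cs$sites)
  nbr <- matrix(-1L, n_site, 4)
  for (i in seq_len(n_site)) {
    nb <- cs$neighbors[[i]] - 1L
    if (length(nb)) nbr[i, seq_along(nb)] <- nb
  }
  lens <- fib$chains$length
  cryst <- unlist(lapply(seq_along(lens), function(i) {
    m <- fib$crystalline[[i]]
    if (is.null(m)) m <- rep(FALSE, max(0L, lens[i] - 1L))
    m
  }), use.names = FALSE)
  cover <- unlist(lapply(seq_along(lens), function(i) {
    m <- fib$covering[[i]]
    if (is.null(m)) m <- rep(FALSE, lens[i])
    m
  }), use.names = FALSE)
  if (is.null(cryst)) cryst <- logical(0)
  if (is.null(cover)) cover <- logical(0)
  list(
    site_x = cs$sites$x, site_y = cs$sites$y, nbr = nbr,
    slots = fib$dp_bonds + 1L,
    chain_site = as.integer(fib$chains$site - 1L),
    chain_start = as.integer(fib$chains$start),
    chain_len = as.integer(lens),
    chain_kind = unname(kind_codes[fib$chains$kind]),
    cryst = cryst, cover = cover,
    structured = isTRUE(fib$structured),
    r_ca_cellulose = unname(fib$r_ca["cellulose"]),
    r_ca_hemicellulose = unname(fib$r_ca["hemicellulose"])
  )
}

cocktail_payload <- function(ck) {
  list(counts = unname(ck$counts),
       k_EG = ck$k_EG, k_XYL = ck$k_XYL, k_BGL = ck$k_BGL,
       k_CBH_attach = ck$k_CBH_attach,
       k_CBH = ck$cbh$k_CBH, t_CBH = ck$cbh$t_CBH, sigma_t = ck$cbh$sigma_t,
       R_CBH = ck$cbh$R_CBH,
       k_bind = ck$lignin$k_bind,
       N_lignols_bound = ck$lignin$N_lignols_bound,
       sigma_lignols = ck$lignin$sigma_lignols)
}

#' Simulate the saccharification of one microfibril
#'
#' Runs the Gillespie simulation until `t_end`, `max_events` or exhaustion of
#' every doable reaction.  Conversions are recorded on a uniform time grid
#' (the grid extends flat to `t_end` if the run stops early), optionally
#' together with the glucose-weighted cellulose DP distribution.
#'
#' @param fib a [microfibril()].
#' @param ck a [cocktail()].
#' @param cfg a [run_config()].
#' @return an object of class `sacch_run`: `timecourse` data frame (`time`,
#'   `glucan_pct`, `xylan_pct`, `glucose`, `cellobiose`, `xylose`), optional
#'   `dp` matrix (rows = grid times, columns = DP in monomers; DP 1 is free
#'   glucose, DP 2 cellobiose), `stop_reason`, `event_count`, final free and
#'   lignin-bound enzyme counts, and (optionally) the full final `state`.
#' @export
simulate_run <- function(fib, ck = cocktail(), cfg = run_config()) {
  stopifnot(inherits(fib, "microfibril"), inherits(ck, "cocktail"),
            inherits(cfg, "run_config"))
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  res <- cpp_run_engine(
    fibril_payload(fib), cocktail_payload(ck),
    list(t_end = cfg$t_end,
         max_events = if (is.finite(cfg$max_events)) cfg$max_events else 1e18,
         record_interval = cfg$record_interval,
         record_dp = cfg$record_dp, dp_max = as.integer(cfg$dp_max),
         return_state = cfg$return_state, debug = cfg$debug))
  tc <- data.frame(time = res$times, glucan_pct = res$glucan_pct,
                   xylan_pct = res$xylan_pct, glucose = res$glucose,
                   cellobiose = res$cellobiose, xylose = res$xylose)
  out <- list(timecourse = tc,
              dp = res$dp,
              stop_reason = res$stop_reason,
              event_count = res$event_count,
              clock = res$clock,
              init_glc = res$init_glc, init_xyl = res$init_xyl,
              pool = res$pool,
              free_counts = setNames(res$free_counts, c("EG", "CBH", "BGL", "XYL")),
              bound_counts = setNames(res$bound_counts, c("EG", "CBH", "BGL", "XYL")),
              state = res$state,
              time_unit = ck$time_unit)
  class(out) <- "sacch_run"
  out
}

#' @export
print.sacch_run <- function(x, ...) {
  n <- nrow(x$timecourse)
  cat(sprintf("<sacch_run> %d events, stop: %s at t=%.3g %s\n",
              x$event_count, x$stop_reason, x$clock, x$time_unit))
  cat(sprintf("  final conversion: glucan->glucose %.1f%%, xylan->xylose %.1f%%\n",
              x$timecourse$glucan_pct[n], x$timecourse$xylan_pct[n]))
  invisible(x)
}

#' Final conversion of a run
#'
#' 100 x free glucose / initial cellulose monomers (cellobiose does not count
#' until BGL cleaves it), and the xylose analogue.
#'
#' @param run a `sacch_run`.
#' @return `c(glucan_pct, xylan_pct)`.
#' @export
conversion <- function(run) {
  stopifnot(inherits(run, "sacch_run"))
  n <- nrow(run$timecourse)
  c(glucan_pct = run$timecourse$glucan_pct[n],
    xylan_pct = run$timecourse$xylan_pct[n])
}

#' Simulate independent replicates on a common time grid
#'
#' Each replicate rebuilds the substrate (shell arrangement, covering masks)
#' and runs the digestion with its own seed, derived from `master_seed` by a
#' fixed increment.
#'
#' @param n number of replicates.
#' @param fibril_args arguments for [microfibril()].
#' @param ck a [cocktail()].
#' @param cfg a [run_config()] (its `seed` field is ignored).
#' @param master_seed integer; replicate i uses `master_seed + i`.
#' @return an object of class `replicate_set`: `times`, matrices `glucan`
#'   and `xylan` (time x replicate), mean and SD curves.
#' @export
simulate_replicates <- function(n, fibril_args = list(), ck = cocktail(),
                                cfg = run_config(), master_seed = 1) {
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- master_seed + i
    fib <- do.call(microfibril, c(fibril_args, list(seed = seed_i)))
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    runs[[i]] <- simulate_run(fib, ck, cfg_i)
  }
  times <- runs[[1]]$timecourse$time
  glc <- vapply(runs, function(r) r$timecourse$glucan_pct, numeric(length(times)))
  xyl <- vapply(runs, function(r) r$timecourse$xylan_pct, numeric(length(times)))
  glc <- matrix(glc, nrow = length(times))
  xyl <- matrix(xyl, nrow = length(times))
  structure(list(times = times,
                 glucan = glc, xylan = xyl,
                 mean_glucan = rowMeans(glc), mean_xylan = rowMeans(xyl),
                 sd_glucan = apply(glc, 1, sd), sd_xylan = apply(xyl, 1, sd),
                 n = n, master_seed = master_seed),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  m <- length(x$times)
  cat(sprintf("<replicate_set> %d replicates, %d grid points (t in [%g, %g])\n",
              x$n, m, x$times[1], x$times[m]))
  cat(sprintf("  mean final conversion: glucan %.1f%%, xylan %.1f%%\n",
              x$mean_glucan[m], x$mean_xylan[m]))
  invisible(x)
}
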