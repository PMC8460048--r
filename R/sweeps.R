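# Parameter sweeps over lignin content and crystallinity fraction.

#' Sweep the lignin content of the substrate
#'
#' Holds the cellulose fraction fixed and trades hemicellulose for lignin,
#' recording the mean final glucan conversion at `t_end` for each lignin
#' fraction.
#'
#' @param lignin_fracs lignin monomer fractions to scan.
#' @param cellulose_frac fixed cellulose fraction.
#' @param n replicates per point.
#' @param fibril_args extra arguments for [microfibril()] (composition is set
#'   by the sweep).
#' @param ck a [cocktail()].
#' @param cfg a [run_config()].
#' @param master_seed base seed (each sweep point shifts it by 1000).
#' @return data frame (`lignin_frac`, `replicate`, `endpoint`), long format.
#' @export
sweep_lignin <- function(lignin_fracs, cellulose_frac = 0.5, n = 10,
                         fibril_args = list(), ck = cocktail(),
                         cfg = run_config(), master_seed = 1) {
  out <- list()
  for (j in seq_along(lignin_fracs)) {
    lf <- lignin_fracs[j]
    comp <- c(cellulose_frac, 1 - cellulose_frac - lf, lf)
    if (any(comp < -1e-9)) stop("infeasible composition in sweep")
    comp <- pmax(comp, 0)
    reps <- simulate_replicates(
      n, c(fibril_args, list(composition = comp)), ck, cfg,
      master_seed = master_seed + 1000 * j)
    idx <- length(reps$times)
    out[[j]] <- data.frame(lignin_frac = lf, replicate = seq_len(n),
                           endpoint = reps$glucan[idx, ])
  }
  do.call(rbind, out)
}

#' Sweep the cellulose crystallinity fraction
#'
#' @param fracs crystalline fractions of cellulose to scan.
#' @param r_ca crystalline/amorphous digestibility ratio for cellulose.
#' @param n replicates per point.
#' @param fibril_args extra arguments for [microfibril()].
#' @param ck,cfg,master_seed as in [sweep_lignin()].
#' @return data frame (`frac`, `replicate`, `endpoint`).
#' @export
sweep_crystallinity <- function(fracs, r_ca = 0.03, n = 10,
                                fibril_args = list(), ck = cocktail(),
                                cfg = run_config(), master_seed = 1) {
  out <- list()
  for (j in seq_along(fracs)) {
    prof <- crystallinity_profile(frac_cellulose = fracs[j],
                                  frac_hemicellulose = 0.23,
                                  r_ca_cellulose = r_ca,
                                  r_ca_hemicellulose = 0.043)
    reps <- simulate_replicates(
      n, c(fibril_args, list(crystallinity = prof)), ck, cfg,
      master_seed = master_seed + 1000 * j)
    idx <- length(reps$times)
    out[[j]] <- data.frame(frac = fracs[j], replicate = seq_len(n),
                           endpoint = reps$glucan[idx, ])
  }
  do.call(rbind, out)
}
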