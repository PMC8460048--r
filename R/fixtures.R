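# Severity presets, synthetic pseudo-experiments and file plumbing.

#' Pre-treatment severity presets
#'
#' Substrate composition (monomer fractions), crystallinity fractions and
#' digestibility ratios for the three steam pre-treatment severities of the
#' corn stover samples the model is calibrated against.
#'
#' @format data frame with one row per severity.
#' @export
severity_presets <- function() {
  data.frame(
    label = c("low", "medium", "high"),
    cellulose = c(0.570, 0.619, 0.627),
    hemicellulose = c(0.188, 0.095, 0.053),
    lignin = c(0.242, 0.286, 0.311),
    cryst_cellulose = c(0.52, 0.19, 0.031),
    cryst_hemicellulose = c(0.68, 0.23, 0.062),
    r_ca_cellulose = c(0.03, 0.03, 0.03),
    r_ca_hemicellulose = c(0.043, 0.043, 0.043),
    stringsAsFactors = FALSE
  )
}

#' Full simulation configuration for a severity preset
#'
#' Merges the severity's composition and crystallinity with the default
#' geometry (36 chains, 200 bonds) and the default enzyme counts
#' (EG 20, CBH 52, BGL 15, XYL 61).
#'
#' @param label `"low"`, `"medium"` or `"high"`.
#' @return list with `fibril_args` (for [microfibril()]), `cocktail` and
#'   `run` (a default 72 h [run_config()]).
#' @export
make_preset <- function(label) {
  tab <- severity_presets()
  row <- tab[tab$label == label, ]
  if (!nrow(row)) {
    stop("unknown severity label: ", label,
         "; valid labels: ", paste(tab$label, collapse = ", "))
  }
  list(
    label = label,
    fibril_args = list(
      n_chains = 36, dp_bonds = 200, n_layers = 2,
      composition = c(row$cellulose, row$hemicellulose, row$lignin) /
        sum(row$cellulose, row$hemicellulose, row$lignin),
      crystallinity = crystallinity_profile(
        frac_cellulose = row$cryst_cellulose,
        frac_hemicellulose = row$cryst_hemicellulose,
        r_ca_cellulose = row$r_ca_cellulose,
        r_ca_hemicellulose = row$r_ca_hemicellulose)),
    cocktail = cocktail(),
    run = run_config(t_end = 72, record_interval = 2)
  )
}

#' Generate a synthetic pseudo-experiment
#'
#' Simulates replicate-averaged conversion curves under a known ("truth")
#' parameter vector for one or more severity conditions, samples them on the
#' requested time grid and adds i.i.d. Gaussian noise (clipped to [0, 100]).
#' The generating truth is stored alongside the data so that fitting runs can
#' be scored by parameter recovery.
#'
#' @param truth named numeric vector of generating parameters (see
#'   [apply_params()] names); may be empty for the preset defaults.
#' @param labels severity labels to emulate.
#' @param noise_sd additive noise SD in percentage points.
#' @param time_grid sampling times.
#' @param n_replicates replicates averaged per condition.
#' @param seed master seed.
#' @param dir optional output directory; when given, one CSV per condition
#'   (`time, glucose_pct, xylose_pct`) plus a JSON truth manifest are written.
#' @param fibril_args overrides merged into every condition's substrate
#'   arguments (e.g. a smaller `dp_bonds` for quick studies).
#' @return list of [experimental_dataset()]s with attribute `truth`.
#' @export
generate_pseudo_experiment <- function(truth = c(), labels = "medium",
                                       noise_sd = 0, time_grid = seq(4, 72, 4),
                                       n_replicates = 5, seed = 1, dir = NULL,
                                       fibril_args = list()) {
  withr::local_seed(seed)
  datasets <- list()
  for (j in seq_along(labels)) {
    preset <- make_preset(labels[j])
    fa <- utils::modifyList(preset$fibril_args, fibril_args)
    ap <- apply_params(truth, fa, preset$cocktail)
    cfg <- preset$run
    cfg$t_end <- max(time_grid)
    reps <- simulate_replicates(n_replicates, ap$fibril_args, ap$ck, cfg,
                                master_seed = seed + 100000 * j)
    g <- interp_mean_curve(reps, time_grid, "glucan")
    x <- interp_mean_curve(reps, time_grid, "xylan")
    if (noise_sd > 0) {
      g <- pmin(100, pmax(0, g + rnorm(length(g), 0, noise_sd)))
      x <- pmin(100, pmax(0, x + rnorm(length(x), 0, noise_sd)))
    }
    datasets[[j]] <- experimental_dataset(labels[j], time_grid, g, x,
                                          fibril_args = fa)
  }
  attr(datasets, "truth") <- truth
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (ds in datasets) {
      write_dataset_csv(ds, file.path(dir, paste0(ds$label, ".csv")))
    }
    jsonlite::write_json(
      list(truth = as.list(truth), noise_sd = noise_sd, seed = seed,
           labels = labels, n_replicates = n_replicates),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  datasets
}

#' Write one condition's time course as CSV
#'
#' @param ds an [experimental_dataset()].
#' @param path output file.
#' @export
write_dataset_csv <- function(ds, path) {
  df <- data.frame(time = ds$times, glucose_pct = ds$glucose_pct)
  if (!is.null(ds$xylose_pct)) df$xylose_pct <- ds$xylose_pct
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a condition time course from CSV
#'
#' Expects columns `time`, `glucose_pct` and optionally `xylose_pct`;
#' validates monotone times and percentage ranges.
#'
#' @param path CSV file.
#' @param label condition label (defaults to the file name).
#' @param fibril_args substrate arguments to attach to the dataset.
#' @export
read_dataset_csv <- function(path, label = NULL,
                             fibril_args = list()) {
  df <- read.csv(path)
  if (!all(c("time", "glucose_pct") %in% names(df))) {
    stop("CSV must have columns time, glucose_pct [, xylose_pct]")
  }
  if (is.null(label)) label <- sub("\\.csv$", "", basename(path))
  experimental_dataset(label, df$time, df$glucose_pct,
                       if ("xylose_pct" %in% names(df)) df$xylose_pct,
                       fibril_args = fibril_args)
}

#' Read a simulation configuration (YAML or JSON)
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json")
}

#' Write a simulation configuration
#'
#' @param cfg a plain list.
#' @param path target file (`.yaml` or `.json`).
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(cfg, path)
  else if (grepl("\\.json$", path)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else stop("config must be .yaml/.yml or .json")
  invisible(path)
}

#' Stable hash of a configuration
#'
#' FNV-1a over the canonical JSON serialization; used in run manifests so
#' outputs can be traced to the exact configuration that produced them.
#'
#' @param cfg a plain list.
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- h - (h %% 256) + low
    # 32-bit modular multiply in two 16-bit halves (exact in doubles)
    hi <- floor(h / 65536)
    lo <- h %% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a run manifest
#'
#' Records the configuration, its hash, the seeds and the package version --
#' enough to reproduce a run bit-exactly.
#'
#' @param cfg configuration list.
#' @param seeds integer vector of seeds used.
#' @param path output JSON file.
#' @param extra optional named list of additional fields (e.g. stop reasons).
#' @export
write_manifest <- function(cfg, seeds, path, extra = list()) {
  jsonlite::write_json(
    c(list(config = cfg, config_hash = config_hash(cfg), seeds = seeds,
           package = "sacchsim",
           version = as.character(utils::packageVersion("sacchsim"))),
      extra),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
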