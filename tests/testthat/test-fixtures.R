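test_that("severity presets carry the calibrated table rows", {
  tab <- severity_presets()
  expect_equal(tab$label, c("low", "medium", "high"))
  expect_equal(tab$cellulose, c(0.570, 0.619, 0.627))
  expect_equal(tab$cryst_cellulose, c(0.52, 0.19, 0.031))
  expect_equal(tab$cryst_hemicellulose, c(0.68, 0.23, 0.062))
  expect_true(all(tab$r_ca_cellulose == 0.03))
  expect_true(all(tab$r_ca_hemicellulose == 0.043))

  p <- make_preset("medium")
  expect_equal(p$fibril_args$composition, c(0.619, 0.095, 0.286))
  expect_equal(p$fibril_args$crystallinity$frac_cellulose, 0.19)
  h <- make_preset("high")
  expect_equal(h$fibril_args$crystallinity$frac_cellulose, 0.031)
  expect_equal(sum(h$fibril_args$composition), 1)
  expect_error(make_preset("extreme"), "valid labels")
})

test_that("pseudo-experiments are deterministic and noise-faithful", {
  fa <- list(n_chains = 2, dp_bonds = 12)
  d1 <- generate_pseudo_experiment(c(), "medium", noise_sd = 0,
                                   time_grid = c(6, 12, 24), n_replicates = 2,
                                   seed = 4, fibril_args = fa)
  d2 <- generate_pseudo_experiment(c(), "medium", noise_sd = 0,
                                   time_grid = c(6, 12, 24), n_replicates = 2,
                                   seed = 4, fibril_args = fa)
  expect_identical(d1[[1]]$glucose_pct, d2[[1]]$glucose_pct)
  # zero noise equals the replicate-mean curves exactly
  p <- make_preset("medium")
  cfg <- p$run; cfg$t_end <- 24
  reps <- simulate_replicates(2, utils::modifyList(p$fibril_args, fa),
                              p$cocktail, cfg, master_seed = 4 + 100000)
  expect_equal(d1[[1]]$glucose_pct,
               interp_mean_curve(reps, c(6, 12, 24), "glucan"))
  # with noise the curves differ but stay in [0, 100]
  d3 <- generate_pseudo_experiment(c(), "medium", noise_sd = 2,
                                   time_grid = c(6, 12, 24), n_replicates = 2,
                                   seed = 4, fibril_args = fa)
  expect_false(identical(d1[[1]]$glucose_pct, d3[[1]]$glucose_pct))
  expect_true(all(d3[[1]]$glucose_pct >= 0 & d3[[1]]$glucose_pct <= 100))
})

test_that("dataset CSV files round-trip losslessly", {
  ds <- experimental_dataset("cond", c(1, 2, 4), c(10, 20, 40), c(5, 10, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(ds, path)
  back <- read_dataset_csv(path, label = "cond")
  expect_equal(back$times, ds$times)
  expect_equal(back$glucose_pct, ds$glucose_pct)
  expect_equal(back$xylose_pct, ds$xylose_pct)
  # malformed input: non-monotone times
  bad <- data.frame(time = c(2, 1), glucose_pct = c(1, 2))
  bad_path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_dataset_csv(bad_path), "increasing")
})

test_that("configs round-trip through YAML and JSON with stable hashes", {
  cfg <- list(substrate = list(n_chains = 36, dp_bonds = 200,
                               composition = c(0.619, 0.095, 0.286)),
              enzymes = list(counts = c(20, 52, 15, 61)), seed = 7)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_config(cfg, path)
    back <- read_config(path)
    expect_equal(back$substrate$n_chains, 36)
    expect_equal(unlist(back$enzymes$counts), c(20, 52, 15, 61))
    expect_identical(config_hash(back), config_hash(read_config(path)))
  }
  h1 <- config_hash(cfg)
  expect_match(h1, "^[0-9a-f]{8}$")
  cfg$seed <- 8
  expect_false(identical(h1, config_hash(cfg)))
})

test_that("manifests record enough to reproduce a run", {
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(list(a = 1), seeds = c(1, 2, 3), path,
                 extra = list(stop_reason = "t_end"))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(m$seeds, c(1, 2, 3))
  expect_equal(m$package, "sacchsim")
  expect_equal(m$stop_reason, "t_end")
  expect_match(m$config_hash, "^[0-9a-f]{8}$")
})
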