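test_that("accessibility follows the occlusion rules", {
  # fully enclosed core under a gapless hemicellulose shell: nothing on the
  # core is accessible, only the shell itself is digestible
  fib <- full_shell_fibril("hemicellulose")
  core <- which(fib$chains$kind == "cellulose")
  for (i in core) {
    for (b in 0:(fib$chains$length[i] - 2)) {
      expect_false(is_accessible(fib, i, b))
    }
  }
  # outer-layer shell chains face the open medium and are digestible
  ring2 <- which(fib$cross_section$sites$ring == 2)
  shell <- which(fib$chains$kind == "hemicellulose" & fib$chains$site %in% ring2)[1]
  expect_true(is_accessible(fib, shell, 2))

  # releasing the monomers right above a core bond opens it
  ck <- cocktail()
  state <- sacchsim:::new_state(fib, ck)
  over <- which(fib$chains$kind == "hemicellulose" &
                fib$chains$site %in% fib$cross_section$neighbors[[fib$chains$site[core[1]]]])
  state$present[[over[1]]][3:4] <- FALSE      # monomers at slots 2 and 3
  expect_true(is_accessible(fib, core[1], 2, state = state))
  expect_false(is_accessible(fib, core[1], 5, state = state))

  # an adjacent digested bond always grants access
  state2 <- sacchsim:::new_state(fib, ck)
  state2$intact[[core[1]]][4] <- FALSE        # bond 3 digested
  expect_true(is_accessible(fib, core[1], 2, state = state2))
  expect_true(is_accessible(fib, core[1], 4, state = state2))
  expect_false(is_accessible(fib, core[1], 1, state = state2))

  # covering lignin blocks permanently; non-covering lignin does not block
  lig1 <- full_shell_fibril("lignin", covering_mu = 1)
  expect_false(is_accessible(lig1, which(lig1$chains$kind == "cellulose")[1], 2))
  lig0 <- full_shell_fibril("lignin", covering_mu = 0)
  expect_true(is_accessible(lig0, which(lig0$chains$kind == "cellulose")[1], 2))

  # structure-free substrates are fully accessible
  free <- toy_fibril()
  free$structured <- FALSE
  expect_true(is_accessible(free, 1, 0))
})

test_that("EG end exclusion leaves short fragments uncuttable", {
  # a 5-bond chain has a single EG-eligible bond (the middle one)
  fib5 <- single_chain_fibril(5)
  el <- eligible_eg_bonds(fib5)
  expect_equal(nrow(el), 1)
  expect_equal(el$bond, 2)
  # a 4-bond chain has none
  fib4 <- single_chain_fibril(4)
  expect_equal(nrow(eligible_eg_bonds(fib4)), 0)
})

test_that("incremental propensities equal the from-scratch oracle", {
  ck <- cocktail(k_EG = 0.1, k_XYL = 0.2, k_BGL = 0.3, k_CBH_attach = 0.15,
                 lignin = lignin_adhesion(k_bind = 0.05, N_lignols_bound = 5,
                                          sigma_lignols = 1))
  for (seed in 1:4) {
    fib <- toy_fibril(dp_bonds = 12, seed = seed)
    for (ev in c(0, 5, 25, 80)) {
      run <- simulate_run(fib, ck, run_config(
        t_end = Inf, max_events = ev, record_interval = 1e6,
        return_state = TRUE, debug = TRUE, seed = 100 + seed))
      expect_oracle_match(fib, ck, run)
    }
  }
})

test_that("conservation laws hold throughout full default-sized runs", {
  fib <- microfibril(dp_bonds = 60, seed = 11)
  run <- simulate_run(fib, cocktail(), run_config(t_end = 72, debug = TRUE,
                                                  seed = 11))
  # debug = TRUE re-checks after every event inside the engine; verify the
  # endpoint bookkeeping here as well
  tc <- run$timecourse
  n <- nrow(tc)
  expect_true(all(diff(tc$glucan_pct) >= 0))
  expect_true(all(diff(tc$xylan_pct) >= 0))
  expect_true(all(tc$glucan_pct >= 0 & tc$glucan_pct <= 100))
  st_free <- run$free_counts + run$bound_counts
  expect_true(all(st_free <= cocktail()$counts))
})

test_that("identical seeds give bit-identical runs", {
  fib <- toy_fibril(seed = 3)
  r1 <- simulate_run(fib, cocktail(), run_config(seed = 77, record_dp = TRUE))
  r2 <- simulate_run(fib, cocktail(), run_config(seed = 77, record_dp = TRUE))
  expect_identical(r1$timecourse, r2$timecourse)
  expect_identical(r1$dp, r2$dp)
  expect_identical(r1$event_count, r2$event_count)
  r3 <- simulate_run(fib, cocktail(), run_config(seed = 78))
  expect_false(identical(r1$timecourse, r3$timecourse))
})

test_that("waiting times follow the total propensity", {
  # single channel: one EG enzyme, one eligible bond -> Exp(k_EG)
  fib <- single_chain_fibril(5)
  ck1 <- cocktail(counts = c(1, 0, 0, 0), k_EG = 2)
  ts <- vapply(1:2000, function(s) {
    simulate_run(fib, ck1, run_config(t_end = Inf, max_events = 1,
                                      record_interval = 1e6, seed = s))$clock
  }, numeric(1))
  expect_lt(abs(mean(ts) - 1 / 2), 3 * (1 / 2) / sqrt(2000))
  # doubling the enzyme count halves the mean waiting time
  ck2 <- cocktail(counts = c(2, 0, 0, 0), k_EG = 2)
  ts2 <- vapply(1:2000, function(s) {
    simulate_run(fib, ck2, run_config(t_end = Inf, max_events = 1,
                                      record_interval = 1e6, seed = s))$clock
  }, numeric(1))
  expect_lt(abs(mean(ts2) - 1 / 4), 3 * (1 / 4) / sqrt(2000))
})

test_that("equal channels are selected equally often", {
  # a 6-bond chain has two EG-eligible bonds (2 and 3) with equal propensity
  fib <- single_chain_fibril(6)
  ck <- cocktail(counts = c(1, 0, 0, 0), k_EG = 1)
  picks <- vapply(1:1000, function(s) {
    run <- simulate_run(fib, ck, run_config(t_end = Inf, max_events = 1,
                                            record_interval = 1e6,
                                            return_state = TRUE, seed = s))
    which(!run$state$intact)
  }, numeric(1))
  frac <- mean(picks == 3)   # bond index 2, 1-based position 3
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(1000))
})

test_that("CBH processivity preserves bond-count parity and boundaries", {
  # CBH alone on even-bond chains: every remaining fragment keeps an even
  # bond count (cellobiose removes two monomers at a time)
  fib <- mark_crystalline(build_core(4, 40), crystallinity_profile(0, 0, 1, 1))
  ck <- cocktail(counts = c(0, 6, 0, 0), k_CBH_attach = 0.5)
  run <- simulate_run(fib, ck, run_config(t_end = 0.5, record_interval = 0.05,
                                          return_state = TRUE, debug = TRUE,
                                          seed = 5))
  st <- run$state
  fr <- st$frags[st$frags$alive, ]
  lens <- fr$hi - fr$lo + 1
  expect_true(all((lens - 1) %% 2 == 0))
  expect_gt(run$event_count, 0)

  # a 2-monomer chain is released as one cellobiose and the CBH detaches
  fib2 <- single_chain_fibril(1)
  run2 <- simulate_run(fib2, ck, run_config(t_end = Inf, max_events = 1e9,
                                            record_interval = 1e6,
                                            debug = TRUE, seed = 6))
  expect_equal(run2$stop_reason, "exhausted")
  n <- nrow(run2$timecourse)
  expect_equal(run2$timecourse$cellobiose[n], 1)
  expect_equal(unname(run2$free_counts["CBH"]), 6)

  # BGL turns cellobiose into two glucose
  ck3 <- cocktail(counts = c(0, 6, 3, 0), k_CBH_attach = 0.5)
  run3 <- simulate_run(fib2, ck3, run_config(t_end = Inf, max_events = 1e9,
                                             record_interval = 1e6,
                                             debug = TRUE, seed = 7))
  n <- nrow(run3$timecourse)
  expect_equal(run3$timecourse$glucose[n], 2)
  expect_equal(run3$timecourse$glucan_pct[n], 100)
})

test_that("attached CBH suppresses digestion inside its steric zone", {
  # one long chain, CBH attached at the left end; EG channels within
  # 2 * R_CBH of the working position must vanish
  fib <- single_chain_fibril(40)
  ck <- cocktail(counts = c(5, 1, 0, 0), k_EG = 1e-9, k_CBH_attach = 100,
                 cbh = cbh_params(N_steps = 50, t_CBH = 1e6, sigma_t = 0))
  run <- simulate_run(fib, ck, run_config(t_end = Inf, max_events = 1,
                                          record_interval = 1e6,
                                          return_state = TRUE, seed = 8))
  st <- run$state
  att <- st$attachments[st$attachments$active, ]
  expect_equal(nrow(att), 1)
  z0 <- att$zpos
  w <- st$w_eg
  for (b in 0:38) {
    mid_in_zone <- min(abs(b - z0), abs(b + 1 - z0)) <= 2 * 4.25
    if (mid_in_zone) expect_equal(w[b + 1], 0)
  }
  # far bonds (interior, outside the zone) keep positive weight
  far <- which(seq(0, 38) > z0 + 9 & seq(0, 38) >= 2 & seq(0, 38) <= 36)
  expect_true(all(w[far] > 0))
})

test_that("lignin adhesion selects victims by abundance and respects capacity", {
  # victim class of the first binding event is multinomial in the free counts
  fib <- toy_fibril(dp_bonds = 8, composition = c(0.4, 0.1, 0.5), seed = 2)
  ck <- cocktail(counts = c(20, 52, 15, 61), k_EG = 0, k_XYL = 0, k_BGL = 0,
                 k_CBH_attach = 0,
                 lignin = lignin_adhesion(k_bind = 1, N_lignols_bound = 5,
                                          sigma_lignols = 0))
  first_victim <- vapply(1:1500, function(s) {
    run <- simulate_run(fib, ck, run_config(t_end = Inf, max_events = 1,
                                            record_interval = 1e6, seed = s))
    which(run$bound_counts == 1)
  }, integer(1))
  p_cbh <- mean(first_victim == 2)
  expect_lt(abs(p_cbh - 52 / 148), 3 * sqrt((52 / 148) * (96 / 148) / 1500))

  # pool of F * mean monolignols binds exactly F enzymes, then stops
  fib2 <- microfibril(n_chains = 2, dp_bonds = 12,
                      composition = c(26, 0, 200) / 226,
                      crystallinity = crystallinity_profile(0, 0, 1, 1),
                      covering = covering_model(0, 0), seed = 3)
  expect_equal(unname(composition_summary(fib2)["N_lign"]), 200)
  ck2 <- cocktail(counts = c(20, 52, 15, 61), k_EG = 0, k_XYL = 0, k_BGL = 0,
                  k_CBH_attach = 0,
                  lignin = lignin_adhesion(k_bind = 1, N_lignols_bound = 50,
                                           sigma_lignols = 0))
  run2 <- simulate_run(fib2, ck2, run_config(t_end = Inf, max_events = 1e9,
                                             record_interval = 1e6,
                                             debug = TRUE, seed = 4))
  expect_equal(sum(run2$bound_counts), 4)          # 200 / 50
  expect_equal(run2$pool, 0)
  expect_equal(run2$stop_reason, "exhausted")

  # lignin in large excess: every enzyme ends up bound and the run halts
  fib3 <- microfibril(n_chains = 2, dp_bonds = 12,
                      composition = c(0.15, 0, 0.85),
                      crystallinity = crystallinity_profile(0, 0, 1, 1),
                      covering = covering_model(0, 0), seed = 5)
  ck3 <- cocktail(counts = c(3, 3, 3, 3), k_EG = 1e-6, k_XYL = 0, k_BGL = 0,
                  k_CBH_attach = 0,
                  lignin = lignin_adhesion(k_bind = 10, N_lignols_bound = 5,
                                           sigma_lignols = 0))
  run3 <- simulate_run(fib3, ck3, run_config(t_end = Inf, max_events = 1e9,
                                             record_interval = 1e6,
                                             debug = TRUE, seed = 6))
  expect_equal(sum(run3$bound_counts), 12)
  expect_equal(sum(run3$free_counts), 0)
  expect_equal(run3$stop_reason, "exhausted")
})

test_that("cellulose digestion requires cellulases", {
  fib <- toy_fibril(seed = 9)
  ck <- cocktail(counts = c(0, 0, 15, 61))
  run <- simulate_run(fib, ck, run_config(seed = 9, debug = TRUE))
  expect_true(all(run$timecourse$glucan_pct == 0))
  expect_gt(max(run$timecourse$xylan_pct), 0)
})

test_that("a no-lignin substrate digests almost completely", {
  fib <- microfibril(composition = c(1, 0, 0),
                     crystallinity = crystallinity_profile(0.19, 0, 0.03, 1),
                     seed = 10)
  run <- simulate_run(fib, cocktail(), run_config(t_end = 300, seed = 10))
  n <- nrow(run$timecourse)
  expect_gt(run$timecourse$glucan_pct[n], 99)
})

test_that("crystallinity flags are inert when r_ca = 1", {
  args_flat <- list(n_chains = 18, dp_bonds = 60,
                    crystallinity = crystallinity_profile(0, 0, 1, 1))
  args_cryst <- list(n_chains = 18, dp_bonds = 60,
                     crystallinity = crystallinity_profile(0.5, 0.5, 1, 1))
  a <- simulate_replicates(15, args_flat, cocktail(), run_config(t_end = 24),
                           master_seed = 100)
  b <- simulate_replicates(15, args_cryst, cocktail(), run_config(t_end = 24),
                           master_seed = 200)
  n <- length(a$times)
  se <- sqrt(a$sd_glucan[n]^2 / 15 + b$sd_glucan[n]^2 / 15)
  expect_lt(abs(a$mean_glucan[n] - b$mean_glucan[n]), 4 * se + 0.5)
})
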