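# Small substrates and hand-built states used across the tests.

# a tiny structured fibril: 2-chain core, short chains, thin shells
toy_fibril <- function(dp_bonds = 12, composition = c(0.6, 0.2, 0.2),
                       seed = 42, ...) {
  microfibril(n_chains = 2, dp_bonds = dp_bonds, composition = composition,
              crystallinity = crystallinity_profile(0.25, 0.25, 0.5, 0.5),
              covering = covering_model(0.5, 0.2), seed = seed, ...)
}

# core completely enclosed by a gapless single-kind shell (as in the
# fully-occluded accessibility sketch)
full_shell_fibril <- function(kind = "hemicellulose", n_chains = 2,
                              dp_bonds = 6, covering_mu = 1) {
  fib <- build_core(n_chains, dp_bonds, n_layers = 2)
  shell_sites <- which(fib$cross_section$sites$ring > 0L)
  add <- data.frame(
    chain_id = nrow(fib$chains) + seq_along(shell_sites),
    kind = kind,
    site = shell_sites,
    start = 0L,
    length = dp_bonds + 1L,
    stringsAsFactors = FALSE
  )
  fib$chains <- rbind(fib$chains, add)
  fib$crystalline <- c(fib$crystalline, rep(list(NULL), nrow(add)))
  fib$covering <- c(fib$covering,
                    lapply(seq_len(nrow(add)), function(i) {
                      if (kind == "lignin") rep(covering_mu >= 1, dp_bonds + 1L)
                      else NULL
                    }))
  fib <- mark_crystalline(fib, crystallinity_profile(0, 0, 1, 1))
  # mark_crystalline resets lignin masks to FALSE bonds only; re-apply covering
  if (kind == "lignin") {
    lig <- which(fib$chains$kind == "lignin")
    for (i in lig) {
      fib$covering[[i]] <- rep(covering_mu >= 1, fib$chains$length[i])
    }
  }
  fib
}

# pure-cellulose fibril with a single chain (minimal substrates)
single_chain_fibril <- function(dp_bonds, crystallinity = crystallinity_profile(0, 0, 1, 1)) {
  fib <- build_core(1, dp_bonds, n_layers = 1)
  mark_crystalline(fib, crystallinity)
}

# match engine per-bond EG/XYL weights against the from-scratch oracle
expect_oracle_match <- function(fib, ck, run) {
  state <- sacchsim:::state_from_run(run, fib)
  tab <- propensity_table(fib, ck, state)
  st <- run$state
  lens <- fib$chains$length
  boff <- c(0L, cumsum(pmax(0L, lens - 1L)))
  # EG / XYL channels
  for (kind in c("EG_cut", "XYL_cut")) {
    w <- if (kind == "EG_cut") st$w_eg else st$w_xyl
    rate <- if (kind == "EG_cut") ck$k_EG * run$free_counts["EG"]
            else ck$k_XYL * run$free_counts["XYL"]
    eng <- data.frame(idx = which(w > 0) - 1L, p = w[w > 0] * rate)
    ora <- tab[tab$kind == kind, ]
    ora$idx <- boff[ora$chain] + ora$bond
    eng <- eng[order(eng$idx), ]
    ora <- ora[order(ora$idx), ]
    expect_equal(eng$idx, ora$idx,
                 info = paste(kind, "channel sets differ"))
    expect_equal(unname(eng$p), unname(ora$propensity), tolerance = 1e-12)
  }
  # CBH attachment: number of eligible end slots
  n_ends_engine <- sum(st$frag_weight)
  n_ends_oracle <- nrow(tab[tab$kind == "CBH_attach", ])
  expect_equal(n_ends_engine, n_ends_oracle)
  invisible(TRUE)
}
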