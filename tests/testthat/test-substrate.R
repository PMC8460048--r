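test_that("core construction places the right chains and monomer counts", {
  fib <- build_core(36, 200)
  expect_equal(nrow(fib$chains), 36)
  expect_true(all(fib$chains$length == 201))
  expect_equal(unname(composition_summary(fib)["N_glc"]), 36 * 201)  # 7236

  tiny <- build_core(1, 1)
  expect_equal(tiny$chains$length, 2)
  expect_equal(unname(composition_summary(tiny)["N_glc"]), 2)

  expect_error(build_core(7, 10), "supported layouts")
})

test_that("36-chain cross-section approximates the reported bounding box", {
  cs <- cross_section(36)
  core <- cs$sites[cs$sites$ring == 0, ]
  expect_equal(nrow(core), 36)
  width <- diff(range(core$x))
  height <- diff(range(core$y))
  expect_lt(abs(width - 5.3), 0.3)
  expect_lt(abs(height - 3.2), 0.3)
  # neighbour relation is symmetric and shells touch the previous layer
  for (i in seq_along(cs$neighbors)) {
    for (j in cs$neighbors[[i]]) expect_true(i %in% cs$neighbors[[j]])
  }
  for (k in 1:2) {
    ring_k <- which(cs$sites$ring == k)
    inner <- which(cs$sites$ring == k - 1)
    for (s in ring_k) expect_true(any(cs$neighbors[[s]] %in% inner))
  }
})

test_that("shell population realizes the composition target exactly", {
  fib <- microfibril(seed = 1)
  cnt <- composition_summary(fib)
  expect_equal(unname(cnt["N_glc"]), 7236)
  # medium severity: N_tot = 7236 / 0.619, counts from the target fractions
  n_tot <- 7236 / 0.619
  expect_equal(unname(cnt["N_xyl"]), round(0.095 * n_tot))   # ~1111
  expect_equal(unname(cnt["N_lign"]), round(0.286 * n_tot))  # ~3343
  # realized fractions within 2% relative error of the target
  fr <- cnt / sum(cnt)
  expect_lt(abs(fr[1] - 0.619) / 0.619, 0.02)
  expect_lt(abs(fr[2] - 0.095) / 0.095, 0.02)
  expect_lt(abs(fr[3] - 0.286) / 0.286, 0.02)

  # pure cellulose: no shell chains at all
  pure <- microfibril(composition = c(1, 0, 0), seed = 2)
  expect_equal(unname(composition_summary(pure)[c("N_xyl", "N_lign")]), c(0, 0))

  # half-and-half: shell is pure hemicellulose
  hh <- microfibril(composition = c(0.5, 0.5, 0), seed = 3)
  expect_equal(unname(composition_summary(hh)["N_lign"]), 0)
  expect_equal(unname(composition_summary(hh)["N_xyl"]), 7236)

  # shell chains are heterogeneous in length (gaps)
  shell_lens <- fib$chains$length[fib$chains$kind != "cellulose"]
  expect_gt(length(unique(shell_lens)), 3)

  # chains never overlap on the lattice
  occ <- paste(fib$chains$site,
               unlist(lapply(seq_len(nrow(fib$chains)), function(i) NULL)))
  slots <- lapply(seq_len(nrow(fib$chains)), function(i) {
    paste(fib$chains$site[i],
          fib$chains$start[i] + seq_len(fib$chains$length[i]))
  })
  all_slots <- unlist(slots)
  expect_equal(anyDuplicated(all_slots), 0L)
})

test_that("over-full shells raise an informative capacity error", {
  fib <- build_core(36, 50, n_layers = 1)
  expect_error(populate_shells(fib, c(0.2, 0.2, 0.6), seed = 1),
               "capacity")
})

test_that("crystalline regions are central contiguous runs of the right size", {
  fib <- microfibril(seed = 4)
  cel <- which(fib$chains$kind == "cellulose")
  for (i in cel) {
    m <- fib$crystalline[[i]]
    expect_equal(sum(m), 38)                 # 19% of 200 bonds
    runs <- rle(m)
    expect_equal(sum(runs$values), 1)        # one contiguous run
    expect_equal(runs$lengths[1], 81)        # 81 amorphous bonds on the left
    expect_equal(runs$lengths[length(runs$lengths)], 81)
  }
  # degenerate fractions
  f0 <- mark_crystalline(build_core(2, 10), crystallinity_profile(0, 0, 1, 1))
  expect_true(all(!unlist(f0$crystalline)))
  f1 <- mark_crystalline(build_core(2, 10), crystallinity_profile(1, 1, 1, 1))
  expect_true(all(unlist(f1$crystalline[1:2])))
  # hemicellulose flagged fraction tracks its target
  hemi <- which(fib$chains$kind == "hemicellulose")
  nb <- sum(fib$chains$length[hemi] - 1)
  ncr <- sum(unlist(fib$crystalline[hemi]))
  expect_lt(abs(ncr / nb - 0.23), 0.05)
})

test_that("covering masks follow the truncated-normal model", {
  fib0 <- microfibril(covering = covering_model(0, 0), seed = 5)
  expect_true(all(!unlist(fib0$covering[fib0$chains$kind == "lignin"])))
  fib1 <- microfibril(covering = covering_model(1, 0), seed = 5)
  expect_true(all(unlist(fib1$covering[fib1$chains$kind == "lignin"])))
  fib02 <- microfibril(covering = covering_model(0.2, 0), seed = 5)
  lig <- which(fib02$chains$kind == "lignin")
  for (i in lig) {
    expect_equal(sum(fib02$covering[[i]]),
                 round(0.2 * fib02$chains$length[i]))
  }
  # empirical mean of draws within 3 SE of mu for interior mu
  withr::with_seed(9, {
    draws <- sacchsim:::.rtrunc01(1000, 0.5, 0.15)
  })
  expect_lt(abs(mean(draws) - 0.5), 3 * 0.15 / sqrt(1000))
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("monomer counts are conserved by the marking passes", {
  fib <- microfibril(seed = 6)
  before <- composition_summary(fib)
  fib2 <- mark_crystalline(fib, crystallinity_profile(0.5, 0.5, 0.1, 0.1))
  fib3 <- assign_covering(fib2, covering_model(0.8, 0.05), seed = 1)
  expect_identical(composition_summary(fib3), before)
})

test_that("realized composition is reproducible and converges over seeds", {
  errs <- vapply(1:25, function(s) {
    fib <- microfibril(seed = s)
    fr <- composition_summary(fib) / sum(composition_summary(fib))
    max(abs(fr - c(0.619, 0.095, 0.286)) / c(0.619, 0.095, 0.286))
  }, numeric(1))
  expect_lt(max(errs), 0.02)
  f1 <- microfibril(seed = 123)
  f2 <- microfibril(seed = 123)
  expect_identical(f1, f2)
})

test_that("fibril snapshots can be dumped as TSV", {
  fib <- toy_fibril()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fibril_tsv(fib, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), sum(fib$chains$length))
  expect_setequal(unique(tab$kind), unique(fib$chains$kind))
})
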