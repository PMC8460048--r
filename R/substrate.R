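# Substrate construction: cellulose core, hemicellulose/lignin shells,
# crystalline regions, lignin covering masks.

# Quasi-hexagonal core layouts, given as chain counts per lattice row.
# The 36-chain cross pattern mimics the maize microfibril bundle; the small
# layouts exist for toy substrates in tests and examples.
.core_layouts <- list(
  `1`  = c(1L),
  `2`  = c(2L),
  `4`  = c(2L, 2L),
  `18` = c(3L, 6L, 6L, 3L),
  `24` = c(3L, 5L, 8L, 5L, 3L),
  `36` = c(4L, 6L, 8L, 8L, 6L, 4L)
)

kind_codes <- c(cellulose = 0L, hemicellulose = 1L, lignin = 2L)

#' Build the cross-section lattice of a microfibril
#'
#' Chains live on a rectangular lattice with 4-neighbourhood adjacency.  The
#' core is a quasi-hexagonal arrangement of cellulose positions; shell layers
#' are grown outwards as the sets of non-core sites at lattice distance
#' 1, 2, ... from the core, so every shell site of layer *k* touches layer
#' *k - 1* (or the core).  Sites on the outer boundary face the open medium.
#'
#' @param n_chains number of cellulose chains in the core (supported layouts:
#'   1, 2, 4, 18, 24, 36).
#' @param n_layers number of shell layers for hemicellulose/lignin (1-4).
#' @param pitch lattice pitch in nm, `c(x, y)`.  The default reproduces a
#'   36-chain core bounding box of roughly 5.3 nm x 3.2 nm.
#' @return a list with `sites` (data frame: `col`, `row`, `x`, `y`, `ring`;
#'   ring 0 is the core), `neighbors` (list of integer site indices) and
#'   `pitch`.
#' @export
cross_section <- function(n_chains = 36, n_layers = 2, pitch = c(0.76, 0.64)) {
  key <- as.character(n_chains)
  if (!key %in% names(.core_layouts)) {
    stop("unsupported n_chains layout: ", n_chains,
         "; supported layouts: ", paste(names(.core_layouts), collapse = ", "))
  }
  if (n_layers < 1 || n_layers > 4) stop("n_layers must be in 1..4")
  rows <- .core_layouts[[key]]
  width <- max(rows)
  core <- do.call(rbind, lapply(seq_along(rows), function(r) {
    k <- rows[r]
    off <- floor((width - k) / 2)
    cbind(col = off + seq_len(k) - 1L, row = r - 1L)
  }))
  sites <- data.frame(col = core[, "col"], row = core[, "row"], ring = 0L)
  # grow rings by lattice adjacency
  occupied <- paste(sites$col, sites$row)
  frontier <- sites
  for (k in seq_len(n_layers)) {
    cand <- unique(do.call(rbind, list(
      data.frame(col = frontier$col + 1L, row = frontier$row),
      data.frame(col = frontier$col - 1L, row = frontier$row),
      data.frame(col = frontier$col, row = frontier$row + 1L),
      data.frame(col = frontier$col, row = frontier$row - 1L)
    )))
    cand <- cand[!paste(cand$col, cand$row) %in% occupied, , drop = FALSE]
    cand <- cand[!duplicated(paste(cand$col, cand$row)), , drop = FALSE]
    cand$ring <- k
    sites <- rbind(sites, cand)
    occupied <- c(occupied, paste(cand$col, cand$row))
    frontier <- cand
  }
  rownames(sites) <- NULL
  sites$x <- sites$col * pitch[1]
  sites$y <- sites$row * pitch[2]
  keymap <- setNames(seq_len(nrow(sites)), paste(sites$col, sites$row))
  neighbors <- lapply(seq_len(nrow(sites)), function(i) {
    nb <- c(keymap[paste(sites$col[i] + 1L, sites$row[i])],
            keymap[paste(sites$col[i] - 1L, sites$row[i])],
            keymap[paste(sites$col[i], sites$row[i] + 1L)],
            keymap[paste(sites$col[i], sites$row[i] - 1L)])
    as.integer(nb[!is.na(nb)])
  })
  list(sites = sites, neighbors = neighbors, pitch = pitch)
}

#' Crystallinity profile
#'
#' Fractions of cellulose and hemicellulose bonds in the hard-to-digest
#' crystalline regions, and the crystalline/amorphous digestibility ratios
#' r_c,a = d_crystalline / d_amorphous (0 = indigestible, 1 = no difference).
#'
#' @param frac_cellulose,frac_hemicellulose crystalline fractions in [0, 1].
#' @param r_ca_cellulose,r_ca_hemicellulose digestibility ratios in [0, 1].
#' @export
crystallinity_profile <- function(frac_cellulose = 0.19,
                                  frac_hemicellulose = 0.23,
                                  r_ca_cellulose = 0.03,
                                  r_ca_hemicellulose = 0.043) {
  p <- list(frac_cellulose = frac_cellulose,
            frac_hemicellulose = frac_hemicellulose,
            r_ca_cellulose = r_ca_cellulose,
            r_ca_hemicellulose = r_ca_hemicellulose)
  bad <- vapply(p, function(v) !is.numeric(v) || v < 0 || v > 1, logical(1))
  if (any(bad)) stop("crystallinity profile fields must lie in [0, 1]")
  structure(p, class = "crystallinity_profile")
}

#' Lignin covering model
#'
#' Per lignin polymer, the fraction of monolignols that act as a physical
#' barrier over underlying bonds is drawn from Normal(mu, sigma) truncated to
#' [0, 1].  mu = 1 corresponds to linear lignin (every monolignol covers);
#' small mu mimics highly branched polymers.
#'
#' @param mu mean covering fraction in [0, 1].
#' @param sigma standard deviation of the covering fraction.
#' @export
covering_model <- function(mu = 0.5, sigma = 0.1) {
  if (mu < 0 || mu > 1 || sigma < 0) stop("invalid covering model")
  structure(list(mu = mu, sigma = sigma), class = "covering_model")
}

#' Build the cellulose core of a microfibril
#'
#' Places `n_chains` cellulose chains of `dp_bonds` glycosidic bonds
#' (`dp_bonds + 1` glucose monomers) on the core sites of the cross-section
#' lattice.  The result is a bare microfibril whose shells can be populated
#' with [populate_shells()].
#'
#' @param n_chains number of cellulose chains (see [cross_section()]).
#' @param dp_bonds bonds per cellulose chain.
#' @param n_layers shell layers to reserve around the core.
#' @return an object of class `microfibril`.
#' @export
build_core <- function(n_chains = 36, dp_bonds = 200, n_layers = 2) {
  if (n_chains < 1 || dp_bonds < 1) stop("n_chains and dp_bonds must be >= 1")
  cs <- cross_section(n_chains, n_layers)
  core_sites <- which(cs$sites$ring == 0L)
  chains <- data.frame(
    chain_id = seq_along(core_sites),
    kind = "cellulose",
    site = core_sites,
    start = 0L,
    length = dp_bonds + 1L,
    stringsAsFactors = FALSE
  )
  fib <- list(
    cross_section = cs,
    chains = chains,
    crystalline = rep(list(NULL), nrow(chains)),
    covering = rep(list(NULL), nrow(chains)),
    dp_bonds = dp_bonds,
    n_layers = n_layers,
    composition_target = c(cellulose = 1, hemicellulose = 0, lignin = 0),
    r_ca = c(cellulose = 1, hemicellulose = 1),
    structured = TRUE
  )
  class(fib) <- "microfibril"
  fib
}

# run-length shell filler; budgets are monomer counts per kind
.fill_shells <- function(fib, n_xyl, n_lign, gap_mean, run_range) {
  cs <- fib$cross_section
  slots <- fib$dp_bonds + 1L
  shell_sites <- which(cs$sites$ring > 0L)
  shell_sites <- shell_sites[order(cs$sites$ring[shell_sites])]
  capacity <- length(shell_sites) * slots
  if (n_xyl + n_lign > capacity) {
    n_tot <- sum(fib$chains$length) + n_xyl + n_lign
    stop(sprintf(
      paste0("shell capacity exceeded: need %d monomers but only %d shell ",
             "slots; maximum achievable hemicellulose+lignin fraction is %.3f"),
      n_xyl + n_lign, capacity, capacity / (sum(fib$chains$length) + capacity)))
  }
  occ <- lapply(shell_sites, function(s) rep(FALSE, slots))
  budgets <- c(hemicellulose = n_xyl, lignin = n_lign)
  new_chains <- list()
  add_chain <- function(kind, site, start, len) {
    new_chains[[length(new_chains) + 1L]] <<-
      list(kind = kind, site = site, start = start, length = len)
    budgets[kind] <<- budgets[kind] - len
  }
  pick_kind <- function() {
    tot <- sum(budgets)
    if (tot <= 0) return(NULL)
    if (runif(1) * tot < budgets["hemicellulose"]) "hemicellulose" else "lignin"
  }
  # stochastic passes: alternating gaps and runs along each shell site's axis
  for (pass in 1:2) {
    gm <- if (pass == 1) gap_mean else max(1, gap_mean / 4)
    idx <- sample(seq_along(shell_sites))
    for (j in idx) {
      if (sum(budgets) <= 0) break
      pos <- 1L
      while (pos <= slots && sum(budgets) > 0) {
        if (occ[[j]][pos]) { pos <- pos + 1L; next }
        gap <- rgeom(1, 1 / (gm + 1))
        pos <- pos + gap
        if (pos > slots) break
        free_run <- 0L
        while (pos + free_run <= slots && !occ[[j]][pos + free_run]) {
          free_run <- free_run + 1L
        }
        if (free_run < 1L) { pos <- pos + 1L; next }
        kind <- pick_kind()
        if (is.null(kind)) break
        want <- round(runif(1, run_range[1], run_range[2]))
        len <- min(free_run, want, budgets[kind])
        if (len >= 1L) {
          add_chain(kind, shell_sites[j], pos - 1L, len)
          occ[[j]][pos:(pos + len - 1L)] <- TRUE
          pos <- pos + len
        }
      }
    }
    if (sum(budgets) <= 0) break
  }
  # deterministic final pass: fill remaining free segments exactly
  if (sum(budgets) > 0) {
    for (j in seq_along(shell_sites)) {
      if (sum(budgets) <= 0) break
      pos <- 1L
      while (pos <= slots && sum(budgets) > 0) {
        if (occ[[j]][pos]) { pos <- pos + 1L; next }
        free_run <- 0L
        while (pos + free_run <= slots && !occ[[j]][pos + free_run]) {
          free_run <- free_run + 1L
        }
        # avoid stranding 1-monomer hemicellulose slivers where possible
        kind <- if (free_run == 1L && budgets["lignin"] > 0) "lignin"
                else names(budgets)[which.max(budgets)]
        len <- min(free_run, budgets[kind])
        if (len >= 1L) {
          add_chain(kind, shell_sites[j], pos - 1L, len)
          occ[[j]][pos:(pos + len - 1L)] <- TRUE
        }
        pos <- pos + free_run
      }
    }
  }
  if (sum(budgets) > 0) {
    stop("internal error: shell budget not spent (", sum(budgets), " left)")
  }
  new_chains
}

#' Populate the shell layers with hemicellulose and lignin
#'
#' Shell chains are laid down by a seeded run-length process along each shell
#' site's axis, alternating occupied runs and gaps, with the polymer kind of
#' each run drawn in proportion to the remaining hemicellulose versus lignin
#' monomer budgets.  The realized monomer counts match the composition target
#' exactly (largest-remainder rounding of the budgets); the gaps make shell
#' chains heterogeneous in length and leave parts of the core surface exposed.
#'
#' @param fib a `microfibril` from [build_core()].
#' @param composition monomer-count fractions `c(cellulose, hemicellulose,
#'   lignin)` summing to 1.
#' @param gap_mean mean gap length (monomer slots) between shell runs.
#' @param run_range uniform range for the attempted run lengths, in monomers
#'   (hemicellulose chains in nature carry roughly 50-200 monomers; runs are
#'   truncated by free space and remaining budget).
#' @param seed optional integer seed.
#' @return the populated `microfibril`.
#' @export
populate_shells <- function(fib, composition = c(0.619, 0.095, 0.286),
                            gap_mean = 8, run_range = c(30, 150),
                            seed = NULL) {
  stopifnot(inherits(fib, "microfibril"))
  composition <- unname(composition)
  if (abs(sum(composition) - 1) > 1e-9) stop("composition must sum to 1")
  if (any(composition < 0)) stop("composition fractions must be >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  n_glc <- sum(fib$chains$length[fib$chains$kind == "cellulose"])
  if (composition[1] <= 0) stop("cellulose fraction must be positive")
  n_tot <- n_glc / composition[1]
  n_xyl <- round(composition[2] * n_tot)
  n_lign <- round(composition[3] * n_tot)
  if (n_xyl + n_lign > 0) {
    new_chains <- .fill_shells(fib, n_xyl, n_lign, gap_mean, run_range)
    if (length(new_chains)) {
      add <- data.frame(
        chain_id = nrow(fib$chains) + seq_along(new_chains),
        kind = vapply(new_chains, `[[`, character(1), "kind"),
        site = vapply(new_chains, `[[`, integer(1), "site"),
        start = vapply(new_chains, function(ch) as.integer(ch$start), integer(1)),
        length = vapply(new_chains, function(ch) as.integer(ch$length), integer(1)),
        stringsAsFactors = FALSE
      )
      fib$chains <- rbind(fib$chains, add)
      fib$crystalline <- c(fib$crystalline,
                           rep(list(NULL), nrow(add)))
      fib$covering <- c(fib$covering, rep(list(NULL), nrow(add)))
    }
  }
  fib$composition_target <- c(cellulose = composition[1],
                              hemicellulose = composition[2],
                              lignin = composition[3])
  fib
}

#' Flag the crystalline regions of a microfibril
#'
#' The crystalline region of each cellulose chain is the central contiguous
#' run of `round(frac * bonds)` bonds (order between neighbouring chains
#' decays towards the microfibril ends); hemicellulose chains are flagged
#' analogously, centred within each chain's own span.
#'
#' @param fib a `microfibril`.
#' @param profile a [crystallinity_profile()].
#' @return the microfibril with per-bond crystalline masks and r_c,a values.
#' @export
mark_crystalline <- function(fib, profile = crystallinity_profile()) {
  stopifnot(inherits(fib, "microfibril"),
            inherits(profile, "crystallinity_profile"))
  central_mask <- function(nb, frac) {
    m <- rep(FALSE, nb)
    k <- round(frac * nb)
    if (k > 0) {
      s <- floor((nb - k) / 2) + 1L
      m[s:(s + k - 1L)] <- TRUE
    }
    m
  }
  for (i in seq_len(nrow(fib$chains))) {
    nb <- fib$chains$length[i] - 1L
    if (nb < 1L) { fib$crystalline[[i]] <- logical(0); next }
    fib$crystalline[[i]] <- switch(fib$chains$kind[i],
      cellulose = central_mask(nb, profile$frac_cellulose),
      hemicellulose = central_mask(nb, profile$frac_hemicellulose),
      lignin = rep(FALSE, nb))
  }
  fib$r_ca <- c(cellulose = profile$r_ca_cellulose,
                hemicellulose = profile$r_ca_hemicellulose)
  fib
}

# truncated-normal draw by redraw-until-in-range (keeps mean ~= mu for
# interior mu)
.rtrunc01 <- function(n, mu, sigma) {
  if (sigma <= 0) return(rep(min(1, max(0, mu)), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1, mu, sigma)
      if (x >= 0 && x <= 1) break
    }
    out[i] <- x
  }
  out
}

#' Assign lignin covering masks
#'
#' Each lignin chain draws an independent covering fraction from
#' Normal(mu, sigma) truncated to [0, 1]; that fraction of its monolignols
#' (chosen at random) is flagged as covering and acts as a permanent barrier
#' over underlying bonds.
#'
#' @param fib a `microfibril`.
#' @param model a [covering_model()].
#' @param seed optional integer seed.
#' @export
assign_covering <- function(fib, model = covering_model(), seed = NULL) {
  stopifnot(inherits(fib, "microfibril"), inherits(model, "covering_model"))
  if (!is.null(seed)) withr::local_seed(seed)
  lig <- which(fib$chains$kind == "lignin")
  for (i in lig) {
    len <- fib$chains$length[i]
    f <- .rtrunc01(1, model$mu, model$sigma)
    k <- round(f * len)
    mask <- rep(FALSE, len)
    if (k > 0) mask[sample.int(len, k)] <- TRUE
    fib$covering[[i]] <- mask
  }
  fib$covering_model <- model
  fib
}

#' Monomer counts by kind
#'
#' @param fib a `microfibril`.
#' @return named vector `c(N_glc, N_xyl, N_lign)`.
#' @export
composition_summary <- function(fib) {
  stopifnot(inherits(fib, "microfibril"))
  s <- function(kind) sum(fib$chains$length[fib$chains$kind == kind])
  c(N_glc = s("cellulose"), N_xyl = s("hemicellulose"), N_lign = s("lignin"))
}

#' Build a complete microfibril substrate
#'
#' One-stop constructor: core, shells, crystalline regions and lignin
#' covering masks.  With `structured = FALSE` the same polymer inventory is
#' generated but the simulation treats every bond as accessible from the
#' start (freely floating polymers, no lateral blocking and no steric
#' hindrance) -- the "no structure" scenario used when dissecting what the
#' three-dimensional arrangement contributes.
#'
#' @param n_chains,dp_bonds,n_layers core geometry (see [build_core()]).
#' @param composition monomer fractions `c(cellulose, hemicellulose, lignin)`.
#' @param crystallinity a [crystallinity_profile()].
#' @param covering a [covering_model()].
#' @param gap_mean,run_range shell generation controls ([populate_shells()]).
#' @param structured logical; `FALSE` disables all spatial accessibility rules.
#' @param seed optional integer seed for the build.
#' @export
microfibril <- function(n_chains = 36, dp_bonds = 200, n_layers = 2,
                        composition = c(0.619, 0.095, 0.286),
                        crystallinity = crystallinity_profile(),
                        covering = covering_model(),
                        gap_mean = 8, run_range = c(30, 150),
                        structured = TRUE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  fib <- build_core(n_chains, dp_bonds, n_layers)
  fib <- populate_shells(fib, composition, gap_mean, run_range)
  fib <- mark_crystalline(fib, crystallinity)
  fib <- assign_covering(fib, covering)
  fib$structured <- structured
  fib
}

#' @export
print.microfibril <- function(x, ...) {
  cnt <- composition_summary(x)
  tot <- sum(cnt)
  cat("<microfibril> ", sum(x$chains$kind == "cellulose"), " cellulose chains, ",
      x$dp_bonds, " bonds each; ", nrow(x$chains), " chains total\n", sep = "")
  cat(sprintf("  monomers: %d glucose, %d xylose, %d monolignol (%.1f/%.1f/%.1f%%)\n",
              cnt[1], cnt[2], cnt[3],
              100 * cnt[1] / tot, 100 * cnt[2] / tot, 100 * cnt[3] / tot))
  cat(sprintf("  crystallinity r_ca: cellulose %.3g, hemicellulose %.3g; %s\n",
              x$r_ca[1], x$r_ca[2],
              if (x$structured) "structured" else "structure-free"))
  invisible(x)
}

#' Dump a microfibril snapshot as TSV
#'
#' One row per monomer: chain, kind, lattice site, axial index, crystalline
#' flag of the bond starting at the monomer, covering flag (lignin).
#'
#' @param fib a `microfibril`.
#' @param path output file.
#' @export
write_fibril_tsv <- function(fib, path) {
  rows <- lapply(seq_len(nrow(fib$chains)), function(i) {
    len <- fib$chains$length[i]
    cr <- fib$crystalline[[i]]
    cv <- fib$covering[[i]]
    data.frame(
      chain_id = fib$chains$chain_id[i],
      kind = fib$chains$kind[i],
      site_x = fib$cross_section$sites$x[fib$chains$site[i]],
      site_y = fib$cross_section$sites$y[fib$chains$site[i]],
      monomer_index = fib$chains$start[i] + seq_len(len) - 1L,
      crystalline = c(if (length(cr)) cr else logical(0), FALSE)[seq_len(len)],
      covering = if (!is.null(cv)) cv else rep(FALSE, len)
    )
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
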