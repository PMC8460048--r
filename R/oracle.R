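# From-scratch enumeration of reaction channels in plain R.  This is an
# independent re-statement of the accessibility and eligibility rules used by
# the compiled engine; the two are compared bond-by-bond in the test suite.
# It is O(bonds x neighbours) per call and meant for small substrates.

# occupancy lookup: which chain owns (site, slot)?
.grid_of <- function(fib) {
  n_site <- nrow(fib$cross_section$sites)
  slots <- fib$dp_bonds + 1L
  g <- matrix(-1L, n_site, slots)
  for (i in seq_len(nrow(fib$chains))) {
    z <- fib$chains$start[i] + seq_len(fib$chains$length[i])  # 1-based slot
    g[fib$chains$site[i], z] <- i
  }
  g
}

# default fresh state for a fibril + cocktail (everything intact and free)
new_state <- function(fib, ck) {
  lens <- fib$chains$length
  cnt <- composition_summary(fib)
  list(intact = lapply(lens, function(l) rep(TRUE, max(0L, l - 1L))),
       present = lapply(lens, function(l) rep(TRUE, l)),
       free_counts = ck$counts,
       pool = unname(cnt["N_lign"]),
       cellobiose = 0,
       attachments = data.frame(chain = integer(0), zpos = integer(0)))
}

# convert an engine state dump (simulate_run(return_state = TRUE)) into the
# per-chain shape used here
state_from_run <- function(run, fib) {
  lens <- fib$chains$length
  boff <- c(0L, cumsum(pmax(0L, lens - 1L)))
  moff <- c(0L, cumsum(lens))
  st <- run$state
  att <- st$attachments
  att <- att[att$active, , drop = FALSE]
  list(intact = lapply(seq_along(lens), function(i) {
         if (lens[i] < 2) return(logical(0))
         st$intact[(boff[i] + 1L):boff[i + 1L]]
       }),
       present = lapply(seq_along(lens), function(i) {
         st$present[(moff[i] + 1L):moff[i + 1L]]
       }),
       free_counts = run$free_counts,
       pool = run$pool,
       cellobiose = tail(run$timecourse$cellobiose, 1),
       attachments = data.frame(chain = att$chain + 1L, zpos = att$zpos))
}

# fragments of one chain: maximal runs of present monomers joined by intact
# bonds; returns data.frame(lo, hi) in 0-based chain coordinates
.fragments_of <- function(intact, present) {
  len <- length(present)
  if (len == 0) return(data.frame(lo = integer(0), hi = integer(0)))
  cuts <- which(!intact)               # 1-based bond j joins monomers j-1, j
  starts <- c(0L, cuts)                # candidate spans between cuts
  ends <- c(cuts - 1L, len - 1L)
  lo <- integer(0); hi <- integer(0)
  for (k in seq_along(starts)) {
    a <- starts[k]; b <- ends[k]
    # trim released monomers off the span ends
    while (a <= b && !present[a + 1L]) a <- a + 1L
    while (b >= a && !present[b + 1L]) b <- b - 1L
    if (a <= b) { lo <- c(lo, a); hi <- c(hi, b) }
  }
  data.frame(lo = lo, hi = hi)
}

# does the monomer at (site, slot) block lateral access?
.blocks <- function(fib, state, grid, site, slot) {
  c2 <- grid[site, slot + 1L]
  if (c2 < 0) return(FALSE)
  m <- slot - fib$chains$start[c2]  # 0-based monomer index
  if (fib$chains$kind[c2] == "lignin") {
    return(isTRUE(fib$covering[[c2]][m + 1L]))
  }
  isTRUE(state$present[[c2]][m + 1L])
}

#' Is a bond accessible for digestion?
#'
#' A bond is accessible if a neighbouring lattice site (or the open medium at
#' the lattice boundary) is unoccluded at both of its axial positions, or if
#' one of its two along-chain neighbouring bonds has been digested.  Covering
#' monolignols occlude permanently (lignin is not digestible), so bonds under
#' covering lignin can only be reached via an adjacent digested bond;
#' hemicellulose occlusion lifts as soon as the occluding monomers are
#' released.  In a structure-free substrate every bond is accessible.
#'
#' @param fib a [microfibril()].
#' @param chain chain index (1-based).
#' @param bond bond index within the chain (0-based; bond i joins monomers i
#'   and i + 1).
#' @param state optional digestion state (defaults to the fresh substrate).
#' @param ck cocktail used to initialize the default state.
#' @export
is_accessible <- function(fib, chain, bond, state = NULL, ck = cocktail()) {
  if (is.null(state)) state <- new_state(fib, ck)
  grid <- .grid_of(fib)
  .accessible(fib, state, grid, chain, bond)
}

.accessible <- function(fib, state, grid, i, b) {
  if (!isTRUE(fib$structured)) return(TRUE)
  intact <- state$intact[[i]]
  nb <- length(intact)
  if (b < 0 || b > nb - 1) stop("dangling bond reference")
  if (b > 0 && !intact[b]) return(TRUE)          # bond b-1 (1-based b)
  if (b < nb - 1 && !intact[b + 2L]) return(TRUE)
  a <- fib$chains$start[i] + b
  s <- fib$chains$site[i]
  nbrs <- fib$cross_section$neighbors[[s]]
  if (length(nbrs) < 4) return(TRUE)             # open medium at the boundary
  for (nn in nbrs) {
    if (!.blocks(fib, state, grid, nn, a) && !.blocks(fib, state, grid, nn, a + 1L)) {
      return(TRUE)
    }
  }
  FALSE
}

.steric_blocked <- function(fib, state, i, b) {
  if (!isTRUE(fib$structured)) return(FALSE)
  if (nrow(state$attachments) == 0) return(FALSE)
  cs <- fib$cross_section$sites
  s <- fib$chains$site[i]
  R2 <- (2 * 4.25)^2  # default steric radius; overridden via attr if set
  if (!is.null(attr(state, "R_CBH"))) R2 <- (2 * attr(state, "R_CBH"))^2
  for (k in seq_len(nrow(state$attachments))) {
    ca <- state$attachments$chain[k]
    sa <- fib$chains$site[ca]
    dx <- cs$x[s] - cs$x[sa]
    dy <- cs$y[s] - cs$y[sa]
    za <- fib$chains$start[ca] + state$attachments$zpos[k]
    for (z in (fib$chains$start[i] + b):(fib$chains$start[i] + b + 1L)) {
      if (dx^2 + dy^2 + (z - za)^2 <= R2) return(TRUE)
    }
  }
  FALSE
}

#' Endoglucanase-eligible bonds
#'
#' Accessible, intact cellulose bonds excluding the two outermost bonds at
#' each end of every polymer or fragment.
#'
#' @inheritParams is_accessible
#' @return data frame of (chain, bond) references.
#' @export
eligible_eg_bonds <- function(fib, state = NULL, ck = cocktail()) {
  if (is.null(state)) state <- new_state(fib, ck)
  tab <- propensity_table(fib, ck, state)
  tab[tab$kind == "EG_cut" & tab$propensity > 0, c("chain", "bond")]
}

#' Enumerate all reaction channels from scratch
#'
#' Recomputes every doable reaction and its propensity directly from a
#' digestion state, without any incremental bookkeeping.  Used as the
#' independent cross-check of the compiled engine's propensity table.
#'
#' @param fib a [microfibril()].
#' @param ck a [cocktail()].
#' @param state digestion state (defaults to the fresh substrate); see
#'   [simulate_run()] with `return_state = TRUE`.
#' @return data frame with `kind` (`EG_cut`, `XYL_cut`, `BGL_cleave`,
#'   `CBH_attach`, `LIGNIN_BIND`), `chain`, `bond` and `propensity`.
#' @export
propensity_table <- function(fib, ck = cocktail(), state = NULL) {
  if (is.null(state)) state <- new_state(fib, ck)
  attr(state, "R_CBH") <- ck$cbh$R_CBH
  grid <- .grid_of(fib)
  rows <- list()
  free <- state$free_counts
  for (i in seq_len(nrow(fib$chains))) {
    kind <- fib$chains$kind[i]
    if (kind == "lignin") next
    fr <- .fragments_of(state$intact[[i]], state$present[[i]])
    if (!nrow(fr)) next
    r_ca <- unname(fib$r_ca[kind])
    for (k in seq_len(nrow(fr))) {
      lo <- fr$lo[k]; hi <- fr$hi[k]
      if (hi - lo < 1) next
      for (b in lo:(hi - 1L)) {
        if (!state$intact[[i]][b + 1L]) next
        if (!.accessible(fib, state, grid, i, b)) next
        if (.steric_blocked(fib, state, i, b)) next
        f <- if (isTRUE(fib$crystalline[[i]][b + 1L])) r_ca else 1
        if (kind == "cellulose") {
          if (b - lo >= 2 && (hi - 1L) - b >= 2) {
            rows[[length(rows) + 1L]] <- data.frame(
              kind = "EG_cut", chain = i, bond = b,
              propensity = ck$k_EG * free["EG"] * f)
          }
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            kind = "XYL_cut", chain = i, bond = b,
            propensity = ck$k_XYL * free["XYL"] * f)
        }
      }
      # exposed ends for CBH attachment (one CBH per fragment)
      if (kind == "cellulose" && hi - lo + 1 >= 2) {
        occupied <- nrow(state$attachments) > 0 &&
          any(state$attachments$chain == i &
              state$attachments$zpos >= lo & state$attachments$zpos <= hi)
        if (!occupied) {
          ends <- unique(c(lo, hi - 1L))
          for (b in ends) {
            if (.accessible(fib, state, grid, i, b)) {
              rows[[length(rows) + 1L]] <- data.frame(
                kind = "CBH_attach", chain = i, bond = b,
                propensity = ck$k_CBH_attach * free["CBH"])
            }
          }
        }
      }
    }
  }
  if (state$cellobiose > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "BGL_cleave", chain = NA_integer_, bond = NA_integer_,
      propensity = ck$k_BGL * free["BGL"] * state$cellobiose)
  }
  if (state$pool > 0 && sum(free) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "LIGNIN_BIND", chain = NA_integer_, bond = NA_integer_,
      propensity = ck$lignin$k_bind * sum(free))
  }
  if (!length(rows)) {
    return(data.frame(kind = character(0), chain = integer(0),
                      bond = integer(0), propensity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
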