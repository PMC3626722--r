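# Independent brute-force oracle: integrates the full positional-isotopomer
# ODE system (2^n states per metabolite) directly from the atom maps, without
# any EMU reduction. Only usable on small networks; used to validate the EMU
# simulator.

# isotopomer distribution of a boundary species under the feed design
oracle_feed_dist <- function(feed, met, n) {
  p <- numeric(2^n)
  entries <- feed[[met]]
  if (is.null(entries)) {
    p[1] <- 1
    return(p)
  }
  for (e in entries) {
    idx <- sum(e$pattern * 2^(seq_len(n) - 1)) + 1
    p[idx] <- p[idx] + e$fraction
  }
  p
}

# marginal distribution of a subset of positions of a metabolite state
oracle_marginal <- function(p, n, positions) {
  k <- length(positions)
  out <- numeric(2^k)
  for (s in seq_len(2^n) - 1) {
    bits <- bitwAnd(s %/% 2^(seq_len(n) - 1), 1)
    sub <- sum(bits[positions] * 2^(seq_len(k) - 1))
    out[sub + 1] <- out[sub + 1] + p[s + 1]
  }
  out
}

# full positional-isotopomer simulation; returns function(times) giving the
# fragment MIDs as a tibble matching simulate_inst output
oracle_simulate <- function(network, fluxes, pools, feed, times, fragments) {
  mets <- network$metabolites
  bal <- mets$id[!mets$is_boundary]
  nc <- stats::setNames(mets$n_carbons, mets$id)
  w <- instaflux::directed_vector(network, fluxes)

  # directed channels with oriented transitions
  chans <- list()
  for (i in seq_len(nrow(network$reactions))) {
    id <- network$reactions$id[i]
    tr <- network$transitions[[id]]
    chans[[length(chans) + 1]] <- list(w = w[[id]], subs = tr$subs,
                                       prods = tr$prods)
    if (network$reactions$reversible[i]) {
      chans[[length(chans) + 1]] <- list(w = w[[paste0(id, "_b")]],
                                         subs = tr$prods, prods = tr$subs)
    }
  }

  # state layout
  offs <- list(); off <- 0
  for (m in bal) { offs[[m]] <- off; off <- off + 2^nc[[m]] }
  y0 <- numeric(off)
  for (m in bal) y0[offs[[m]] + 1] <- 1  # all unlabeled

  get_state <- function(y, m) {
    if (m %in% bal) y[offs[[m]] + seq_len(2^nc[[m]])]
    else oracle_feed_dist(feed, m, nc[[m]])
  }

  # per channel and balanced product instance: production distribution
  prod_dist <- function(y, ch, prod_inst) {
    npz <- length(prod_inst$atoms)
    # for each product atom: which substrate instance / position
    src <- lapply(prod_inst$atoms, function(a) {
      for (si in seq_along(ch$subs)) {
        pos <- match(a, ch$subs[[si]]$atoms)
        if (!is.na(pos)) return(c(si, pos))
      }
      stop("atom not found")
    })
    sis <- vapply(src, `[`, numeric(1), 1)
    p <- numeric(2^npz)
    # marginal per substrate instance over its mapped positions
    margs <- list()
    for (si in unique(sis)) {
      sm <- ch$subs[[si]]$met
      positions <- vapply(src[sis == si], `[`, numeric(1), 2)
      margs[[as.character(si)]] <-
        oracle_marginal(get_state(y, sm), nc[[sm]], positions)
    }
    for (s in seq_len(2^npz) - 1) {
      bits <- bitwAnd(s %/% 2^(seq_len(npz) - 1), 1)
      pr <- 1
      for (si in unique(sis)) {
        sel <- which(sis == si)
        sub_bits <- bits[sel]
        idx <- sum(sub_bits * 2^(seq_along(sel) - 1))
        pr <- pr * margs[[as.character(si)]][idx + 1]
      }
      p[s + 1] <- pr
    }
    p
  }

  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    for (ch in chans) {
      if (ch$w <= 0) next
      for (pi in seq_along(ch$prods)) {
        m <- ch$prods[[pi]]$met
        if (!(m %in% bal)) next
        p <- prod_dist(y, ch, ch$prods[[pi]])
        idx <- offs[[m]] + seq_len(2^nc[[m]])
        dy[idx] <- dy[idx] + 1000 * ch$w * (p - y[idx]) / pools[[m]]
      }
    }
    list(dy)
  }
  sol <- deSolve::ode(y = y0, times = unique(c(0, times)), func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  rows <- list()
  for (tt in times) {
    y <- sol[match(tt, sol[, 1]), -1]
    for (fi in seq_len(nrow(fragments))) {
      m <- fragments$metabolite[fi]
      positions <- fragments$positions[[fi]]
      marg <- oracle_marginal(get_state(y, m), nc[[m]], positions)
      k <- length(positions)
      mid <- numeric(k + 1)
      for (s in seq_len(2^k) - 1) {
        nb <- sum(bitwAnd(s %/% 2^(seq_len(k) - 1), 1))
        mid[nb + 1] <- mid[nb + 1] + marg[s + 1]
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        fragment_id = fragments$fragment_id[fi], time_h = tt,
        mass = seq_len(k + 1) - 1L, fraction = mid)
    }
  }
  dplyr::bind_rows(rows)
}
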