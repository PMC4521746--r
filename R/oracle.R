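# Independent brute-force validators: full isotopomer-space steady-state
# simulation (damped fixed point, and a cumomer-cascade direct solver as a
# cross-check) and cumomer counting/clustering, the comparison baseline for
# the tandemer cascade.

# Precompute, per internal metabolite, the producing terms of its isotopomer
# balance: one term per (mapping entry, product occurrence), each a list of
# substrate slots with the marginalization indices needed to evaluate it.
iso_terms <- function(network, internal) {
  n_of <- stats::setNames(network$metabolites$n_atoms, network$metabolites$id)
  bm_cache <- list()
  bm_of <- function(n) {
    key <- as.character(n)
    if (is.null(bm_cache[[key]])) bm_cache[[key]] <<- bit_matrix(n)
    bm_cache[[key]]
  }
  terms <- stats::setNames(vector("list", length(internal)), internal)
  for (e in network$reactions) {
    sub_letters <- character(0); sub_slot <- integer(0); sub_pos <- integer(0)
    for (si in seq_along(e$substrates)) {
      at <- e$substrates[[si]]$atoms
      if (length(at)) {
        sub_letters <- c(sub_letters, at)
        sub_slot <- c(sub_slot, rep.int(si, length(at)))
        sub_pos <- c(sub_pos, seq_along(at))
      }
    }
    names(sub_slot) <- sub_letters; names(sub_pos) <- sub_letters
    for (po in seq_along(e$products)) {
      met <- e$products[[po]]$met
      if (!met %in% internal) next
      L <- e$products[[po]]$atoms
      if (anyNA(sub_slot[L]))
        abort_validation("reaction %s: atom %d of %s has no substrate source",
                         e$id, which(is.na(sub_slot[L]))[1L], met)
      n <- unname(n_of[met])
      bm <- bm_of(n)
      slots <- list()
      for (si in sort(unique(unname(sub_slot[L])))) {
        atoms_here <- which(sub_slot[L] == si)       # product atom indices
        q <- unname(sub_pos[L[atoms_here]])          # substrate atom indices
        ord <- order(q)
        q_sorted <- q[ord]
        a_sorted <- atoms_here[ord]
        lq <- length(q_sorted)
        idx <- as.integer(bm[, a_sorted, drop = FALSE] %*% 2^((lq - 1):0)) + 1L
        slots[[length(slots) + 1L]] <- list(
          met = e$substrates[[si]]$met, q = q_sorted, idx = idx)
      }
      terms[[met]][[length(terms[[met]]) + 1L]] <-
        list(flux_id = e$flux_id, weight = e$weight, slots = slots)
    }
  }
  terms
}

# group index for marginalizing a distribution over atoms q (sorted)
marg_index <- function(n, q) {
  bm <- bit_matrix(n)
  lq <- length(q)
  if (lq == 0L) return(rep.int(1L, 2^n))
  as.integer(bm[, q, drop = FALSE] %*% 2^((lq - 1):0)) + 1L
}

#' Brute-force isotopomer simulation
#'
#' Solves the full isotopomer balance equations of the network at isotopic
#' steady state, either by damped fixed-point iteration over all `2^n`
#' isotopomer abundances per metabolite (`method = "fixed_point"`) or by the
#' cumomer cascade (`method = "cascade"`: exact linear solves per cumomer
#' weight followed by Moebius inversion back to isotopomer space).  Both
#' routes must agree; they serve as independent oracles for
#' [simulate_tandemers()].  Intended for small networks (guarded by
#' `size_guard` on the total isotopomer count).
#'
#' @inheritParams simulate_tandemers
#' @param method `"fixed_point"` or `"cascade"`.
#' @param tol Fixed-point convergence tolerance on the maximum absolute
#'   balance violation (default 1e-12).
#' @param max_iter Fixed-point iteration cap (default 10000).
#' @param damping Fixed-point damping factor in (0, 1] (default 0.5).
#' @param size_guard Maximum allowed total isotopomer count (default 2^16).
#' @return Named list of [isotopomer_distribution()]s (media included).
#' @export
simulate_isotopomers_bruteforce <- function(network, fluxes, tracers,
                                            method = c("fixed_point", "cascade"),
                                            tol = 1e-12, max_iter = 10000L,
                                            damping = 0.5, size_guard = 2^16) {
  method <- match.arg(method)
  mets <- network$metabolites
  tracked <- mets$id[mets$n_atoms > 0L]
  total <- sum(2^mets$n_atoms[mets$n_atoms > 0L])
  if (total > size_guard)
    abort_validation("network has %d isotopomers, exceeding the size guard %d",
                     total, size_guard)
  n_of <- stats::setNames(mets$n_atoms, mets$id)
  internal <- tracked[!tracked %in% network$media]
  media <- tracked[tracked %in% network$media]

  dists <- list()
  for (m in media) {
    d <- tracers[[m]]
    if (is.null(d))
      abort_validation("no tracer distribution given for media metabolite '%s'", m)
    dists[[m]] <- as.numeric(d)
  }

  terms <- iso_terms(network, internal)
  for (m in internal) if (is.null(terms[[m]]))
    abort_validation("metabolite '%s' has no producing reaction and is not a media metabolite", m)

  P <- stats::setNames(numeric(length(internal)), internal)
  for (m in internal) for (tm in terms[[m]]) {
    v <- unname(fluxes[tm$flux_id]) * tm$weight
    if (is.na(v)) abort_validation("no flux given for reaction '%s'", tm$flux_id)
    P[m] <- P[m] + v
  }
  if (any(P <= 0))
    abort_numerical("metabolite '%s' has zero total production flux",
                    internal[which(P <= 0)[1L]])

  if (method == "fixed_point") {
    # cache marginalization group indices per (substrate, atom set)
    gi_cache <- new.env(parent = emptyenv())
    gi_of <- function(met, q) {
      key <- paste(met, paste(q, collapse = ","))
      g <- gi_cache[[key]]
      if (is.null(g)) {
        g <- marg_index(unname(n_of[met]), q)
        gi_cache[[key]] <- g
      }
      g
    }
    for (m in internal) dists[[m]] <- rep(1 / 2^n_of[m], 2^n_of[m])
    iter <- 0L
    repeat {
      iter <- iter + 1L
      resid <- 0
      nxt <- dists
      for (m in internal) {
        acc <- numeric(2^n_of[m])
        for (tm in terms[[m]]) {
          v <- unname(fluxes[tm$flux_id]) * tm$weight
          if (v == 0) next
          vec <- NULL
          for (sl in tm$slots) {
            marg <- rowsum(dists[[sl$met]], gi_of(sl$met, sl$q))[, 1L]
            vec <- if (is.null(vec)) marg[sl$idx] else vec * marg[sl$idx]
          }
          acc <- acc + v * vec
        }
        resid <- max(resid, max(abs(acc - P[m] * dists[[m]])))
        nxt[[m]] <- dists[[m]] + damping * (acc / P[m] - dists[[m]])
      }
      dists <- nxt
      if (resid < tol) break
      if (iter >= max_iter)
        abort_numerical("fixed-point iteration did not converge: residual %.3e after %d iterations",
                        resid, iter)
    }
  } else {
    dists <- c(dists, cumomer_cascade_solve(network, fluxes, dists, internal,
                                            terms, P, n_of))
  }

  out <- list()
  for (m in tracked) {
    labs <- iso_labels(unname(n_of[m]))
    out[[m]] <- structure(stats::setNames(dists[[m]], labs),
                          metabolite = m, n_atoms = unname(n_of[m]),
                          class = "isotopomer_distribution")
  }
  out
}

# zeta transform: from isotopomer probabilities (indexed by labeled-set mask)
# to cumomers y_S = P(all atoms of S labeled); mask bit for atom a is
# 2^(n - a), matching the isotopomer index convention.
zeta_transform <- function(p, n) {
  y <- p
  if (n == 0L) return(y)
  masks <- 0:(2^n - 1L)
  for (a in seq_len(n)) {
    bit <- 2^(n - a)
    lo <- which(bitwAnd(masks, bit) == 0L)
    y[lo] <- y[lo] + y[lo + bit]
  }
  y
}

mobius_transform <- function(y, n) {
  p <- y
  if (n == 0L) return(p)
  masks <- 0:(2^n - 1L)
  for (a in seq_len(n)) {
    bit <- 2^(n - a)
    lo <- which(bitwAnd(masks, bit) == 0L)
    p[lo] <- p[lo] - p[lo + bit]
  }
  p
}

# Exact solver: one linear system of cumomer balances per weight level,
# lower-weight and media cumomers known, then Moebius inversion.
cumomer_cascade_solve <- function(network, fluxes, media_dists, internal,
                                  terms, P, n_of) {
  y <- list()
  for (m in names(media_dists))
    y[[m]] <- zeta_transform(media_dists[[m]], unname(n_of[m]))
  for (m in internal) {
    y[[m]] <- rep(NA_real_, 2^n_of[m])
    y[[m]][1L] <- 1  # empty set: weight-0 cumomer is identically 1
  }
  media <- names(media_dists)

  # Direct (slot, substrate atom) map per product atom, per producing term.
  pull_terms <- stats::setNames(vector("list", length(internal)), internal)
  for (e in network$reactions) {
    sub_letters <- character(0); sub_slot <- integer(0); sub_pos <- integer(0)
    for (si in seq_along(e$substrates)) {
      at <- e$substrates[[si]]$atoms
      if (length(at)) {
        sub_letters <- c(sub_letters, at)
        sub_slot <- c(sub_slot, rep.int(si, length(at)))
        sub_pos <- c(sub_pos, seq_along(at))
      }
    }
    names(sub_slot) <- sub_letters; names(sub_pos) <- sub_letters
    for (po in seq_along(e$products)) {
      met <- e$products[[po]]$met
      if (!met %in% internal) next
      L <- e$products[[po]]$atoms
      if (anyNA(sub_slot[L]))
        abort_validation("reaction %s: atom %d of %s has no substrate source",
                         e$id, which(is.na(sub_slot[L]))[1L], met)
      pull_terms[[met]][[length(pull_terms[[met]]) + 1L]] <- list(
        flux_id = e$flux_id, weight = e$weight,
        slot_of = unname(sub_slot[L]), pos_of = unname(sub_pos[L]),
        sub_mets = vapply(e$substrates, `[[`, "", "met"))
    }
  }

  max_w <- max(n_of[internal])
  for (w in seq_len(max_w)) {
    unknown_keys <- character(0)
    unknown_met <- character(0); unknown_mask <- integer(0)
    for (m in internal) {
      n <- unname(n_of[m])
      if (w > n) next
      masks <- which(rowSums(bit_matrix(n)) == w) - 1L
      unknown_met <- c(unknown_met, rep.int(m, length(masks)))
      unknown_mask <- c(unknown_mask, masks)
      unknown_keys <- c(unknown_keys, paste0(m, "#", masks))
    }
    nu <- length(unknown_keys)
    if (nu == 0L) next
    A <- matrix(0, nu, nu)
    b <- numeric(nu)
    for (r in seq_len(nu)) {
      m <- unknown_met[r]; mask <- unknown_mask[r]
      n <- unname(n_of[m])
      atoms <- which(bitwAnd(mask, 2^(n - seq_len(n))) > 0L)
      A[r, r] <- unname(P[m])
      for (tm in pull_terms[[m]]) {
        v <- unname(fluxes[tm$flux_id]) * tm$weight
        if (v == 0) next
        slots_here <- unique(tm$slot_of[atoms])
        vals <- numeric(0); lin_key <- NULL
        for (si in slots_here) {
          sub <- tm$sub_mets[si]
          q <- tm$pos_of[atoms[tm$slot_of[atoms] == si]]
          nsub <- unname(n_of[sub])
          smask <- sum(2^(nsub - q))
          if (length(slots_here) == 1L && !sub %in% media) {
            lin_key <- paste0(sub, "#", smask)
          } else {
            yv <- y[[sub]][smask + 1L]
            if (is.na(yv))
              abort_numerical("internal error: cumomer %s#%d not yet solved", sub, smask)
            vals <- c(vals, yv)
          }
        }
        if (!is.null(lin_key)) {
          c_idx <- match(lin_key, unknown_keys)
          if (is.na(c_idx))
            abort_numerical("internal error: same-weight cumomer %s missing", lin_key)
          A[r, c_idx] <- A[r, c_idx] - v
        } else {
          b[r] <- b[r] + v * prod(vals)
        }
      }
    }
    sol <- solve(A, b)
    for (r in seq_len(nu))
      y[[unknown_met[r]]][unknown_mask[r] + 1L] <- sol[r]
  }

  out <- list()
  for (m in internal)
    out[[m]] <- mobius_transform(y[[m]], unname(n_of[m]))
  out
}

#' Oracle tandemer distributions by brute force
#'
#' Composes [simulate_isotopomers_bruteforce()] with
#' [tandemer_from_isotopomers()]: the independent reference against which the
#' cluster-cascade solver is validated.
#'
#' @inheritParams simulate_isotopomers_bruteforce
#' @param targets List of [mfp()] targets.
#' @param ... Passed to [simulate_isotopomers_bruteforce()].
#' @return Named list of `"tandemer"` matrices keyed by MFP id.
#' @export
oracle_tandemers <- function(network, fluxes, tracers, targets, ...) {
  dists <- simulate_isotopomers_bruteforce(network, fluxes, tracers, ...)
  out <- list()
  for (f in targets) {
    d <- dists[[f$metabolite]]
    if (is.null(d))
      abort_validation("target metabolite '%s' not simulated", f$metabolite)
    out[[mfp_id(f)]] <- tandemer_from_isotopomers(d, f)
  }
  out
}

#' Cumomer count and cluster report
#'
#' Reports the size of the equivalent cumomer model: the total cumomer count
#' equals the total isotopomer count, `sum(2^n)` over all metabolites with
#' tracked atoms (media included, as their cumomers are variables of the
#' classic formulation even when their values are known).  Two clustering
#' conventions are implemented, since the granularity of the cumomer cascade
#' is a convention rather than a theorem:
#'
#' * `"weight"` (default): one cluster per cumomer weight level over
#'   non-media metabolites, the unit of the classic weight-ordered cascade
#'   (one flux-matrix solve per weight); cluster `w` has
#'   `sum(choose(n, w))` cumomers.  Weight-0 cumomers (identically 1) and
#'   media cumomers (known) are excluded.
#' * `"scc"`: strongly connected components of the cumomer dependency graph
#'   restricted to same-weight linear edges, the finest decomposition
#'   (analogous to the MFP clusters).
#'
#' @param network A `"tandemer_network"`.
#' @param convention `"weight"` or `"scc"`.
#' @return List with `total_cumomers`, `convention`, `cluster_sizes`,
#'   `max_cluster_size`, and for `"weight"` a `by_weight` data.frame.
#' @export
cumomer_report <- function(network, convention = c("weight", "scc")) {
  convention <- match.arg(convention)
  mets <- network$metabolites
  tracked <- mets[mets$n_atoms > 0L, , drop = FALSE]
  total <- sum(2^tracked$n_atoms)
  internal <- tracked[!tracked$id %in% network$media, , drop = FALSE]

  if (convention == "weight") {
    max_w <- if (nrow(internal)) max(internal$n_atoms) else 0L
    sizes <- integer(0); ws <- integer(0)
    for (w in seq_len(max_w)) {
      s <- sum(choose(internal$n_atoms, w))
      if (s > 0) { sizes <- c(sizes, as.integer(s)); ws <- c(ws, w) }
    }
    return(list(total_cumomers = total, convention = "weight",
                cluster_sizes = sizes,
                max_cluster_size = if (length(sizes)) max(sizes) else 0L,
                by_weight = data.frame(weight = ws, n_cumomers = sizes)))
  }

  # SCC convention: same-weight linear dependency graph of internal cumomers
  n_of <- stats::setNames(mets$n_atoms, mets$id)
  node_names <- character(0)
  for (m in internal$id)
    node_names <- c(node_names, paste0(m, "#", seq_len(2^n_of[m] - 1L)))
  from <- character(0); to <- character(0)
  for (e in network$reactions) {
    sub_letters <- character(0); sub_slot <- integer(0); sub_pos <- integer(0)
    for (si in seq_along(e$substrates)) {
      at <- e$substrates[[si]]$atoms
      if (length(at)) {
        sub_letters <- c(sub_letters, at)
        sub_slot <- c(sub_slot, rep.int(si, length(at)))
        sub_pos <- c(sub_pos, seq_along(at))
      }
    }
    names(sub_slot) <- sub_letters; names(sub_pos) <- sub_letters
    for (po in seq_along(e$products)) {
      met <- e$products[[po]]$met
      if (!met %in% internal$id) next
      L <- e$products[[po]]$atoms
      n <- unname(n_of[met])
      bm <- bit_matrix(n)
      slot_of <- unname(sub_slot[L]); pos_of <- unname(sub_pos[L])
      slot_masks <- list(); slot_counts <- list()
      for (si in sort(unique(slot_of))) {
        sel <- slot_of == si
        nsub <- unname(n_of[e$substrates[[si]]$met])
        wvec <- numeric(n)
        wvec[sel] <- 2^(nsub - pos_of[sel])
        slot_masks[[as.character(si)]] <- as.numeric(bm %*% wvec)
        slot_counts[[as.character(si)]] <- as.integer(bm %*% as.numeric(sel))
      }
      sis <- names(slot_masks)
      cnt_mat <- do.call(cbind, slot_counts)
      nonzero <- cnt_mat > 0L
      one_slot <- rowSums(nonzero) == 1L
      for (ci in seq_along(sis)) {
        si <- as.integer(sis[ci])
        sub <- e$substrates[[si]]$met
        if (sub %in% network$media || !sub %in% internal$id) next
        rows <- which(one_slot & nonzero[, ci])
        rows <- rows[rows > 1L]  # skip the empty set
        if (length(rows)) {
          from <- c(from, paste0(sub, "#", slot_masks[[ci]][rows]))
          to <- c(to, paste0(met, "#", rows - 1L))
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = node_names, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  list(total_cumomers = total, convention = "scc",
       cluster_sizes = sizes,
       max_cluster_size = if (length(sizes)) max(sizes) else 0L)
}
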