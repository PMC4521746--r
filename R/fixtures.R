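# Shipped fixture networks and seeded random generators for property tests.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "tandemr")
  if (!nzchar(p)) abort_validation("fixture file '%s' not found", file)
  p
}

#' The five-metabolite toy network fixture
#'
#' A small network of metabolites `A` (media, 4 carbons), `B`, `C`, `D`, `E`
#' with reactions `v1`..`v6` (`v4`, `v5` reversible) plus efflux reactions,
#' whose atom maps make the tandemer distribution of `E^{1,2,3,4}_{2,3}`
#' depend on 10 fragment pairs of metabolites other than `A`, grouped into
#' three strongly connected components.  Ships with a balanced flux vector,
#' a 50% `[1,2-13C]` tracer on `A` and the default target.
#'
#' @return List with `network`, `fluxes`, `tracers`, `targets`.
#' @export
toy_network <- function() {
  network <- parse_model(fixture_path("toy_model.txt"))
  list(network = network,
       fluxes = parse_fluxes(fixture_path("toy_fluxes.csv"), network),
       tracers = parse_tracers(fixture_path("toy_tracers.csv"), network),
       targets = parse_targets(fixture_path("toy_targets.csv"), network))
}

#' The methionine-metabolism network fixture
#'
#' A synthetic reconstruction of a small model of mammalian methionine
#' metabolism (transmethylation cycle, polyamine biosynthesis and methionine
#' salvage): internal metabolites Met (5 C), SAM (15 C), SAH (14 C),
#' HCys (4 C) and MTA (11 C), with media methionine, ATP (adenine + ribose,
#' 10 C) and the 5-methyl-THF methyl carbon as media metabolites, so the
#' equivalent full isotopomer model has `sum(2^n) = 52306` states.  The
#' default targets take the intact metabolite as parent fragment with the
#' adenine group (SAM/SAH/MTA) or the four non-methyl methionine carbons
#' (Met/HCys) as product fragment.
#'
#' @return List with `network`, `fluxes`, `tracers`, `targets`.
#' @export
methionine_network <- function() {
  network <- parse_model(fixture_path("methionine_model_synthetic.txt"))
  list(network = network,
       fluxes = parse_fluxes(fixture_path("methionine_fluxes.csv"), network),
       tracers = parse_tracers(fixture_path("methionine_tracers.csv"), network),
       targets = parse_targets(fixture_path("methionine_targets.csv"), network))
}

#' Random atom-mapped network generator
#'
#' Generates small, valid, atom-conserving networks for property testing:
#' every internal metabolite is reachable from a media metabolite, carries an
#' uptake (dilution) and an efflux reaction so that a strictly positive
#' steady-state flux vector always exists, condensation (bi-substrate)
#' reactions appear with probability `bi_substrate_fraction`, and
#' `cycle_enforcement` adds a reversible interconversion between two
#' equal-size metabolites.  Atom maps are random injections, so tracked atoms
#' are conserved by construction.  Fully reproducible given `seed`.
#'
#' @param n_metabolites Number of internal metabolites (default 5).
#' @param max_atoms Maximum tracked atoms per metabolite (default 4).
#' @param n_reactions Number of core (non-uptake, non-efflux) reactions
#'   (default 8; at least `n_metabolites`).
#' @param bi_substrate_fraction Probability that an extra core reaction is a
#'   condensation (default 0.3).
#' @param cycle_enforcement Add a reversible pair guaranteeing a cycle
#'   (default TRUE).
#' @param seed Integer seed.
#' @return A `"tandemer_network"` (with uptake/efflux reactions named
#'   `upt_*` / `out_*`, media metabolites `M<n>` per atom size).
#' @export
random_network <- function(n_metabolites = 5L, max_atoms = 4L,
                           n_reactions = 8L, bi_substrate_fraction = 0.3,
                           cycle_enforcement = TRUE, seed = 0L) {
  set.seed(seed)
  n_reactions <- max(n_reactions, n_metabolites)
  mets <- paste0("X", seq_len(n_metabolites))
  n_at <- sample(seq_len(max_atoms), n_metabolites, replace = TRUE)
  if (cycle_enforcement && n_metabolites >= 2L) n_at[2L] <- n_at[1L]
  names(n_at) <- mets
  media_sizes <- integer(0)
  lines <- character(0)
  rid <- 0L
  next_id <- function() { rid <<- rid + 1L; sprintf("r%d", rid) }
  letters_for <- function(n, offset = 0L) letters[offset + seq_len(n)]
  need_media <- function(n) {
    media_sizes <<- unique(c(media_sizes, n))
    sprintf("M%d", n)
  }
  # random injective map: product of n atoms drawn from substrate letters
  draw_map <- function(sub_letters, n) sample(sub_letters, n)

  # backbone: every internal metabolite gets a producer
  for (i in seq_along(mets)) {
    tgt <- mets[i]; nt <- n_at[i]
    use_media <- i == 1L || stats::runif(1) < 0.3
    if (use_media) {
      src <- need_media(nt); ns <- nt
    } else {
      cand <- which(n_at[seq_len(i - 1L)] >= nt)
      if (length(cand)) {
        j <- if (length(cand) == 1L) cand else sample(cand, 1L)
        src <- mets[j]; ns <- n_at[j]
      } else { src <- need_media(nt); ns <- nt }
    }
    sl <- letters_for(ns)
    lines <- c(lines, sprintf("%s: %s (%s) -> %s (%s)", next_id(),
                              src, paste(sl, collapse = ""),
                              tgt, paste(draw_map(sl, nt), collapse = "")))
  }
  # extra core reactions
  for (i in seq_len(n_reactions - n_metabolites)) {
    ti <- sample(n_metabolites, 1L)
    tgt <- mets[ti]; nt <- n_at[ti]
    if (stats::runif(1) < bi_substrate_fraction && nt >= 2L) {
      # condensation: both substrates contribute at least one atom
      n1 <- sample(seq_len(nt - 1L), 1L)
      n2t <- nt - n1
      pick_sub <- function(min_n) {
        cand <- which(n_at >= min_n)
        if (stats::runif(1) < 0.25 || !length(cand)) need_media(max(min_n, 1L))
        else mets[if (length(cand) == 1L) cand else sample(cand, 1L)]
      }
      s1 <- pick_sub(n1); s2 <- pick_sub(n2t)
      ns1 <- if (startsWith(s1, "M")) as.integer(sub("M", "", s1)) else n_at[s1]
      ns2 <- if (startsWith(s2, "M")) as.integer(sub("M", "", s2)) else n_at[s2]
      l1 <- letters_for(ns1); l2 <- letters_for(ns2, ns1)
      pl <- c(draw_map(l1, n1), draw_map(l2, n2t))
      pl <- sample(pl)  # shuffle interleaving of the two halves
      lines <- c(lines, sprintf("%s: %s (%s) + %s (%s) -> %s (%s)", next_id(),
                                s1, paste(l1, collapse = ""),
                                s2, paste(l2, collapse = ""),
                                tgt, paste(pl, collapse = "")))
    } else {
      cand <- which(n_at >= nt)
      src <- mets[if (length(cand) == 1L) cand else sample(cand, 1L)]
      ns <- n_at[src]
      sl <- letters_for(ns)
      lines <- c(lines, sprintf("%s: %s (%s) -> %s (%s)", next_id(),
                                src, paste(sl, collapse = ""),
                                tgt, paste(draw_map(sl, nt), collapse = "")))
    }
  }
  if (cycle_enforcement && n_metabolites >= 2L) {
    n <- n_at[1L]
    sl <- paste(letters_for(n), collapse = "")
    lines <- c(lines, sprintf("rcyc: %s (%s) <-> %s (%s)",
                              mets[1L], sl, mets[2L], sl))
  }
  # uptake (dilution) and efflux for every internal metabolite: guarantees a
  # strictly positive steady-state flux vector exists
  for (i in seq_along(mets)) {
    n <- n_at[i]; src <- need_media(n)
    sl <- paste(letters_for(n), collapse = "")
    lines <- c(lines, sprintf("upt_%s: %s (%s) -> %s (%s)", mets[i],
                              src, sl, mets[i], sl))
    lines <- c(lines, sprintf("out_%s: %s (%s) ->", mets[i], mets[i], sl))
  }
  media <- sprintf("M%d", sort(media_sizes))
  text <- c(paste("#media", paste(media, collapse = " ")), lines)
  parse_model(text = text)
}

#' Random strictly positive steady-state flux vector
#'
#' Samples random positive fluxes and projects them onto the steady-state
#' subspace (production = consumption for every non-media tracked metabolite)
#' by alternating projections between the flux-balance affine space and the
#' box `flux >= lower`, restarting on failure.
#'
#' @param network A `"tandemer_network"`.
#' @param seed Integer seed.
#' @param lower Lower bound enforced on every flux (default 0.05).
#' @param max_iter,retries Projection iteration cap and number of restarts.
#' @return A `"flux_vector"` passing [check_steady_state()].
#' @export
random_fluxes <- function(network, seed = 0L, lower = 0.05,
                          max_iter = 500L, retries = 5L) {
  set.seed(seed)
  ids <- required_flux_ids(network)
  mets <- network$metabolites
  bal_mets <- mets$id[!mets$is_media & mets$n_atoms > 0L]
  # stoichiometric matrix over flux ids (weights/occurrences folded in)
  S <- matrix(0, length(bal_mets), length(ids),
              dimnames = list(bal_mets, ids))
  for (e in network$reactions) {
    j <- match(e$flux_id, ids)
    for (t in e$products) if (t$met %in% bal_mets)
      S[t$met, j] <- S[t$met, j] + e$weight
    for (t in e$substrates) if (t$met %in% bal_mets)
      S[t$met, j] <- S[t$met, j] - e$weight
  }
  if (length(bal_mets) == 0L) {
    v <- stats::runif(length(ids), 0.2, 2)
    names(v) <- ids
    return(structure(v, class = "flux_vector"))
  }
  sv <- svd(S)
  pos <- sv$d > max(dim(S)) * .Machine$double.eps * max(sv$d, 1)
  U <- sv$u[, pos, drop = FALSE]; D <- sv$d[pos]; V <- sv$v[, pos, drop = FALSE]
  project_null <- function(v) v - V %*% ((crossprod(U, S %*% v)) / D)
  for (try in seq_len(retries)) {
    v <- stats::runif(length(ids), 0.2, 2)
    for (it in seq_len(max_iter)) {
      v <- project_null(v)
      v <- pmax(as.numeric(v), lower)
      if (max(abs(S %*% v)) < 1e-12) break
    }
    if (max(abs(S %*% v)) < 1e-10) {
      v <- as.numeric(project_null(v))
      if (all(v >= lower / 2) && max(abs(S %*% v)) < 1e-10) {
        names(v) <- ids
        return(structure(v, class = "flux_vector"))
      }
    }
  }
  abort_numerical("could not find a strictly positive steady-state flux vector after %d retries",
                  retries)
}

#' Random tracer specification
#'
#' Draws a Dirichlet-distributed isotopomer distribution for every media
#' metabolite of the network.
#'
#' @param network A `"tandemer_network"`.
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration (default 0.5; small values give
#'   sparse, strongly informative labeling).
#' @return Named list of [isotopomer_distribution()]s.
#' @export
random_tracers <- function(network, seed = 0L, alpha = 0.5) {
  set.seed(seed)
  mets <- network$metabolites
  media <- mets[mets$is_media & mets$n_atoms > 0L, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(media))) {
    n <- media$n_atoms[r]
    g <- stats::rgamma(2^n, shape = alpha)
    while (sum(g) == 0) g <- stats::rgamma(2^n, shape = alpha)
    out[[media$id[r]]] <- isotopomer_distribution(media$id[r], n, g / sum(g))
  }
  out
}
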