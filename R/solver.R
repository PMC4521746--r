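# Cluster cascade solver: assemble and sequentially solve the per-cluster
# linear flux-balance systems A_i X_i = B_i Y_i, where each row of X_i is a
# vectorized tandemer distribution of one unknown fragment pair and Y_i
# stacks boundary / earlier-cluster distributions and Cauchy products.

#' Assemble the linear balance system of one cluster
#'
#' Builds `A X = B Y` for the unknown fragment pairs of one cluster: the
#' diagonal of `A` is minus the total production flux of each unknown's
#' metabolite; off-diagonal entries of `A` carry the fluxes of uni-substrate
#' links between unknowns of the cluster; `B` carries (negated) fluxes of
#' links to known sources, whose vectorized tandemer distributions form the
#' rows of `Y`.  Condensation links contribute a Cauchy-product row to `Y`,
#' computed once per distinct substrate pair (memoized across clusters).
#' With this sign convention `rowSums(A) == rowSums(B)` at flux steady state
#' (the production flux on the diagonal cancels against the summed link
#' fluxes), which is what guarantees solved rows summing to one without
#' renormalization.
#'
#' @param cluster_ids Character vector of unknown MFP ids (one cluster of a
#'   clustered [identify_mfps()] graph).
#' @param graph The clustered `"mfp_graph"`.
#' @param fluxes Flux vector ([parse_fluxes()]).
#' @param known Environment (or list) mapping MFP ids of boundary and
#'   earlier-cluster fragments to their `"tandemer"` matrices.
#' @param memo Environment used to memoize Cauchy products across clusters.
#' @return A `"cluster_system"`: list with `unknowns`, `A`, `B`, `Y`,
#'   `y_keys`, `n_parent`, `n_product`.
#' @export
assemble_cluster <- function(cluster_ids, graph, fluxes, known,
                             memo = new.env(parent = emptyenv())) {
  unknowns <- sort_radix(cluster_ids)
  frs <- graph$nodes[unknowns]
  if (any(vapply(frs, is.null, logical(1))))
    abort_validation("cluster contains ids absent from the graph")
  p <- length(frs[[1L]]$parent); k <- length(frs[[1L]]$product)
  for (f in frs) if (length(f$parent) != p || length(f$product) != k)
    abort_numerical("internal error: mixed fragment shapes within a cluster")
  n <- length(unknowns)
  L <- n_feasible(p, k)

  A <- matrix(0, n, n, dimnames = list(unknowns, unknowns))
  y_keys <- character(0)
  y_rows <- list()
  Bcoef <- list()  # per y-key column of B
  get_known <- function(id) {
    m <- if (is.environment(known)) known[[id]] else known[[id]]
    if (is.null(m))
      abort_numerical("internal error: source %s not yet solved (cluster ordering bug)", id)
    m
  }
  add_rhs <- function(r, key, mat, coef) {
    pos <- match(key, y_keys)
    if (is.na(pos)) {
      y_keys <<- c(y_keys, key)
      y_rows[[length(y_rows) + 1L]] <<- vectorize_tandemer(mat)
      Bcoef[[length(Bcoef) + 1L]] <<- numeric(n)
      pos <- length(y_keys)
    }
    Bcoef[[pos]][r] <<- Bcoef[[pos]][r] - coef
  }

  edges_by_target <- split(graph$edges,
                           vapply(graph$edges, `[[`, "", "target"))
  for (r in seq_len(n)) {
    id <- unknowns[r]
    total <- 0
    for (e in edges_by_target[[id]]) {
      coef <- unname(fluxes[e$flux_id]) * e$weight
      if (is.na(coef)) abort_validation("no flux given for reaction '%s'", e$flux_id)
      total <- total + coef
      if (coef == 0) next
      if (e$type == "uni") {
        src <- e$sources[1L]
        pos <- match(src, unknowns)
        if (!is.na(pos)) {
          A[r, pos] <- A[r, pos] + coef
        } else {
          add_rhs(r, src, get_known(src), coef)
        }
      } else {
        key <- paste(e$sources, collapse = " (x) ")
        conv <- memo[[key]]
        if (is.null(conv)) {
          conv <- cauchy_product(get_known(e$sources[1L]),
                                 get_known(e$sources[2L]))
          memo[[key]] <- conv
        }
        add_rhs(r, key, conv, coef)
      }
    }
    if (total <= 0)
      abort_numerical(
        "metabolite '%s' has zero total production flux; the labeling of %s is undefined at steady state",
        frs[[r]]$metabolite, id)
    # subtract (not assign): a self-loop link may already have added to the
    # diagonal
    A[r, r] <- A[r, r] - total
  }

  B <- if (length(y_keys))
    matrix(unlist(Bcoef), nrow = n, ncol = length(y_keys),
           dimnames = list(unknowns, y_keys))
  else matrix(0, n, 0L, dimnames = list(unknowns, NULL))
  Y <- if (length(y_rows))
    do.call(rbind, y_rows)
  else matrix(0, 0L, L)
  structure(list(unknowns = unknowns, fragments = frs, A = A, B = B, Y = Y,
                 y_keys = y_keys, n_parent = p, n_product = k),
            class = "cluster_system")
}

#' Solve one cluster system
#'
#' Solves `A X = B Y` by a dense LU solve (no explicit inverse).  The
#' reciprocal condition number of `A` is checked first; systems with
#' `rcond < 1e-12` are rejected as numerically rank-deficient.  Solved rows
#' are devectorized, tiny float negatives are clamped, and each row must sum
#' to 1 within 1e-9 (a consequence of flux balance, not renormalization).
#'
#' @param system A `"cluster_system"` from [assemble_cluster()].
#' @return Named list of `"tandemer"` matrices (one per unknown), with
#'   attribute `"rcond"`.
#' @export
solve_cluster <- function(system) {
  rc <- rcond(system$A)
  if (!is.finite(rc) || rc < 1e-12)
    abort_numerical("singular or ill-conditioned cluster system (rcond = %.3e) for MFPs: %s",
                    rc, paste(system$unknowns, collapse = ", "))
  rhs <- if (ncol(system$B) > 0L) system$B %*% system$Y
         else matrix(0, nrow(system$A), n_feasible(system$n_parent, system$n_product))
  X <- solve(system$A, rhs)
  out <- vector("list", length(system$unknowns))
  names(out) <- system$unknowns
  for (r in seq_along(system$unknowns)) {
    t <- devectorize_tandemer(clamp_values(X[r, ]),
                              fragment = system$fragments[[r]], check = FALSE)
    s <- sum(t$values)
    if (abs(s - 1) > 1e-9)
      abort_numerical("solved tandemer distribution of %s sums to %.12f (flux vector not at steady state?)",
                      system$unknowns[r], s)
    out[[r]] <- t
  }
  attr(out, "rcond") <- rc
  out
}

#' Simulate tandemer distributions for a set of target fragment pairs
#'
#' End-to-end driver: checks the flux vector for isotopic-steady-state
#' balance, identifies the minimal MFP set ([identify_mfps()]), clusters and
#' orders it ([cluster_and_sort()]), fixes boundary distributions by
#' marginalizing the tracer isotopomer distributions
#' ([tandemer_from_isotopomers()]), then assembles and solves the cluster
#' cascade in order.
#'
#' @param network A `"tandemer_network"`.
#' @param fluxes Flux vector ([parse_fluxes()] or named numeric covering all
#'   reactions).
#' @param tracers Named list of [isotopomer_distribution()]s for every media
#'   metabolite reachable in the closure ([parse_tracers()]).
#' @param targets List of [mfp()] targets.
#' @param all_mfps Return every identified fragment pair, not only targets.
#' @param check_balance Fail on steady-state residuals (default TRUE).
#' @param ss_tol Steady-state tolerance passed to [check_steady_state()].
#' @return A `"tandemer_simulation"`: list with `results` (named list of
#'   `"tandemer"`), `graph`, `diagnostics` (per-cluster sizes and condition
#'   estimates, model/flux hashes).
#' @export
simulate_tandemers <- function(network, fluxes, tracers, targets,
                               all_mfps = FALSE, check_balance = TRUE,
                               ss_tol = 1e-6) {
  if (check_balance) {
    ss <- check_steady_state(network, fluxes, tol = ss_tol)
    if (!attr(ss, "ok")) {
      bad <- ss[!ss$ok, , drop = FALSE]
      abort_validation("flux vector violates isotopic steady state (worst: %s, residual %.3e)",
                       bad$metabolite[which.max(abs(bad$residual))],
                       max(abs(bad$residual)))
    }
  }
  graph <- cluster_and_sort(identify_mfps(network, targets))

  known <- new.env(parent = emptyenv())
  for (id in names(graph$boundary)) {
    f <- graph$boundary[[id]]
    dist <- tracers[[f$metabolite]]
    if (is.null(dist))
      abort_validation("no tracer distribution given for media metabolite '%s'",
                       f$metabolite)
    assign(id, tandemer_from_isotopomers(dist, f), envir = known)
  }

  memo <- new.env(parent = emptyenv())
  rconds <- numeric(length(graph$clusters))
  for (ci in seq_along(graph$clusters)) {
    sys <- assemble_cluster(graph$clusters[[ci]], graph, fluxes, known, memo)
    sol <- solve_cluster(sys)
    rconds[ci] <- attr(sol, "rcond")
    for (id in names(sol)) assign(id, sol[[id]], envir = known)
  }

  want <- if (all_mfps) c(names(graph$nodes), names(graph$boundary))
          else graph$targets
  results <- stats::setNames(lapply(want, function(id) known[[id]]), want)
  structure(list(
    results = results,
    graph = graph,
    diagnostics = list(
      n_clusters = length(graph$clusters),
      cluster_sizes = lengths(graph$clusters),
      rcond = rconds,
      model_hash = text_hash(serialize_model(network)),
      flux_hash = text_hash(sprintf("%s=%.17g", names(fluxes), fluxes)))),
    class = "tandemer_simulation")
}

#' @export
print.tandemer_simulation <- function(x, ...) {
  cat(sprintf("<tandemer_simulation> %d result matrices; %d clusters (sizes: %s)\n",
              length(x$results), x$diagnostics$n_clusters,
              paste(x$diagnostics$cluster_sizes, collapse = ", ")))
  invisible(x)
}
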