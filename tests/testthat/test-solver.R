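# Cluster system assembly, the cascade solve, and solver invariants.

toy <- toy_network()

test_that("the toy cluster (I) system has the published coefficient structure", {
  g <- cluster_and_sort(identify_mfps(toy$network, toy$targets))
  # find the cluster holding B^{3,4}_{4}
  ci <- which(vapply(g$clusters, function(cl) "B^{3,4}_{4}" %in% cl, logical(1)))
  known <- new.env(parent = emptyenv())
  for (id in names(g$boundary))
    assign(id, tandemer_from_isotopomers(toy$tracers$A, g$boundary[[id]]),
           envir = known)
  sys <- assemble_cluster(g$clusters[[ci]], g, toy$fluxes, known)
  expect_identical(sys$unknowns,
                   c("B^{3,4}_{4}", "C^{1,2}_{2}", "D^{1,2}_{2}", "E^{3,4}_{4}"))
  # fixture fluxes: v1=2 v2=0.5 v3=1 v4f=1 v4b=0.5 v5f=1 v5b=1 v6=1
  # diag: -(v1+v5b), -(v2+v3+v4b), -(v2+v4f), -(v5f+v6)
  A_expected <- rbind(
    c(-3,   0,   0,   1),    # B: sources v5b * E
    c( 1,  -2,   0.5, 0),    # C: v3 * B + v4b * D
    c( 0,   1,  -1.5, 0),    # D: v4f * C
    c( 1,   1,   0,  -2))    # E: v5f * B + v6 * C (uni-demoted condensation)
  expect_equal(unname(sys$A), A_expected, tolerance = 1e-12)
  expect_identical(sys$y_keys, c("A^{3,4}_{4}", "A^{1,2}_{2}", "A^{3,4}_{3}"))
  B_expected <- rbind(c(-2, 0, 0), c(0, -0.5, 0), c(0, 0, -0.5), c(0, 0, 0))
  expect_equal(unname(sys$B), B_expected, tolerance = 1e-12)
  # flux balance under the published sign convention: the diagonal production
  # flux cancels against the summed link fluxes, row by row
  expect_equal(unname(rowSums(sys$A)), unname(rowSums(sys$B)), tolerance = 1e-12)
})

test_that("the last toy cluster couples B and E and carries the Cauchy-product row", {
  g <- cluster_and_sort(identify_mfps(toy$network, toy$targets))
  known <- new.env(parent = emptyenv())
  for (id in names(g$boundary))
    assign(id, tandemer_from_isotopomers(toy$tracers$A, g$boundary[[id]]),
           envir = known)
  memo <- new.env(parent = emptyenv())
  for (ci in seq_len(length(g$clusters) - 1L)) {
    sol <- solve_cluster(assemble_cluster(g$clusters[[ci]], g, toy$fluxes,
                                          known, memo))
    for (id in names(sol)) assign(id, sol[[id]], envir = known)
  }
  sys <- assemble_cluster(g$clusters[[3]], g, toy$fluxes, known, memo)
  expect_identical(sys$unknowns, c("B^{1,2,3,4}_{2,3}", "E^{1,2,3,4}_{2,3}"))
  expect_true("B^{3,4}_{4} (x) C^{1,2}_{1}" %in% sys$y_keys)
  # B row: production v1+v5b = 3, E row: v5f+v6 = 2
  expect_equal(unname(diag(sys$A)), c(-3, -2))
  expect_equal(unname(rowSums(sys$A)), unname(rowSums(sys$B)), tolerance = 1e-12)
})

test_that("a single-MFP cluster is the flux-weighted average of its sources", {
  net <- parse_model(text = c(
    "#media A1 A2",
    "u1: A1 (ab) -> B (ab)",
    "u2: A2 (ab) -> B (ba)",
    "bo: B (ab) ->"))
  fl <- structure(c(u1 = 3, u2 = 1, bo = 4), class = "flux_vector")
  d1 <- isotopomer_distribution("A1", 2, c("10" = 1))
  d2 <- isotopomer_distribution("A2", 2, c("01" = 0.5, "11" = 0.5))
  tr <- list(A1 = d1, A2 = d2)
  target <- mfp("B", 1:2, 1)
  sim <- simulate_tandemers(net, fl, tr, list(target))
  # closed form: (v1 * [A1^{1,2}_{1}] + v2 * [A2 mapped]) / (v1 + v2);
  # u2 maps B atoms (1,2) to A2 atoms (2,1), so K={1} pulls to A2 atom 2
  t1 <- tandemer_from_isotopomers(d1, mfp("A1", 1:2, 1))
  t2 <- tandemer_from_isotopomers(d2, mfp("A2", 1:2, 2))
  expected <- (3 * t1$values + 1 * t2$values) / 4
  expect_equal(sim$results[[mfp_id(target)]]$values, expected,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the toy solve matches both brute-force oracles", {
  sim <- simulate_tandemers(toy$network, toy$fluxes, toy$tracers, toy$targets)
  fp <- oracle_tandemers(toy$network, toy$fluxes, toy$tracers, toy$targets)
  cs <- oracle_tandemers(toy$network, toy$fluxes, toy$tracers, toy$targets,
                         method = "cascade")
  id <- "E^{1,2,3,4}_{2,3}"
  expect_lt(max(abs(sim$results[[id]]$values - fp[[id]]$values)), 1e-8)
  expect_lt(max(abs(sim$results[[id]]$values - cs[[id]]$values)), 1e-10)
  expect_equal(sum(sim$results[[id]]$values), 1, tolerance = 1e-9)
})

test_that("unlabeled media gives delta matrices; fully labeled media gives the full shift", {
  un <- list(A = isotopomer_distribution("A", 4, c("0000" = 1)))
  sim <- simulate_tandemers(toy$network, toy$fluxes, un, toy$targets,
                            all_mfps = TRUE)
  for (t in sim$results) {
    expect_equal(unname(t$values[1, 1]), 1, tolerance = 1e-12)
    expect_equal(sum(t$values), 1, tolerance = 1e-9)
  }
  full <- list(A = isotopomer_distribution("A", 4, c("1111" = 1)))
  sim2 <- simulate_tandemers(toy$network, toy$fluxes, full, toy$targets)
  v <- sim2$results[["E^{1,2,3,4}_{2,3}"]]$values
  expect_equal(unname(v[5, 3]), 1, tolerance = 1e-12)  # delta at (4, 2)
})

test_that("results are invariant to global flux rescaling", {
  sim1 <- simulate_tandemers(toy$network, toy$fluxes, toy$tracers, toy$targets)
  scaled <- toy$fluxes * 3.7
  sim2 <- simulate_tandemers(toy$network, scaled, toy$tracers, toy$targets)
  id <- "E^{1,2,3,4}_{2,3}"
  expect_equal(sim1$results[[id]]$values, sim2$results[[id]]$values,
               tolerance = 1e-12)
})

test_that("without condensations the solution is linear in the boundary labeling", {
  # Cauchy-product rows are bilinear in the boundary labeling, so tracer
  # linearity only holds when no condensation reaction lies in the closure;
  # use a condensation-free network.
  net <- chain_network()
  fl <- structure(c(c1 = 1, c2 = 1, c3 = 1), class = "flux_vector")
  d1 <- isotopomer_distribution("A", 2, c("10" = 1))
  d2 <- isotopomer_distribution("A", 2, c("01" = 0.5, "11" = 0.5))
  alpha <- 0.3
  mix <- isotopomer_distribution("A", 2, alpha * as.numeric(d1) +
                                   (1 - alpha) * as.numeric(d2))
  targets <- list(mfp("C", 1:2, 1))
  s1 <- simulate_tandemers(net, fl, list(A = d1), targets)
  s2 <- simulate_tandemers(net, fl, list(A = d2), targets)
  sm <- simulate_tandemers(net, fl, list(A = mix), targets)
  id <- "C^{1,2}_{1}"
  expect_equal(sm$results[[id]]$values,
               alpha * s1$results[[id]]$values +
                 (1 - alpha) * s2$results[[id]]$values,
               tolerance = 1e-10)
  # and the toy network, which condenses B with C, is demonstrably not linear
  toyd1 <- isotopomer_distribution("A", 4, c("1111" = 1))
  toyd2 <- isotopomer_distribution("A", 4, c("0000" = 1))
  toymix <- isotopomer_distribution("A", 4, c("1111" = 0.5, "0000" = 0.5))
  t1 <- simulate_tandemers(toy$network, toy$fluxes, list(A = toyd1), toy$targets)
  t2 <- simulate_tandemers(toy$network, toy$fluxes, list(A = toyd2), toy$targets)
  tm <- simulate_tandemers(toy$network, toy$fluxes, list(A = toymix), toy$targets)
  tid <- "E^{1,2,3,4}_{2,3}"
  expect_gt(max(abs(tm$results[[tid]]$values -
                      0.5 * (t1$results[[tid]]$values + t2$results[[tid]]$values))),
            1e-3)
})

test_that("an unbalanced flux vector is rejected before solving", {
  bad <- toy$fluxes; bad["v6"] <- 2
  expect_error(simulate_tandemers(toy$network, bad, toy$tracers, toy$targets),
               class = "tandemr_validation_error")
})

test_that("zero production flux is a hard error naming the metabolite", {
  net <- parse_model(text = c("#media A", "u: A (ab) -> B (ab)", "bo: B (ab) ->"))
  fl <- structure(c(u = 0, bo = 0), class = "flux_vector")
  tr <- list(A = isotopomer_distribution("A", 2, c("00" = 1)))
  expect_error(simulate_tandemers(net, fl, tr, list(mfp("B", 1:2, 1))),
               class = "tandemr_numerical_error")
})

test_that("split n-ary condensations simulate identically to the oracle", {
  net <- parse_model(text = c(
    "#media A B C",
    "r1: A (ab) + B (c) + C (d) -> D (acbd)",
    "ro: D (abcd) ->"), split_nary = TRUE)
  fl <- parse_fluxes(tmp_csv(c("reaction,flux", "r1,1.5", "ro,1.5")), net)
  set.seed(99)
  tr <- random_tracers(net, seed = 99)
  targets <- list(mfp("D", 1:4, c(1, 3)), mfp("D", c(2, 3), 3))
  sim <- simulate_tandemers(net, fl, tr, targets)
  ora <- oracle_tandemers(net, fl, tr, targets, method = "cascade")
  for (id in names(sim$results))
    expect_lt(max(abs(sim$results[[id]]$values - ora[[id]]$values)), 1e-10)
})
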