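# Model parsing, validation, serialization and the CSV interfaces.

test_that("uni- and bi-substrate reactions parse with correct atom bookkeeping", {
  uni <- parse_model(text = c("#media A", "v1: A (abcd) -> B (abcd)",
                              "vb: B (abcd) ->"))
  e1 <- uni$reactions[[1]]
  expect_identical(e1$substrates[[1]]$met, "A")
  expect_identical(e1$products[[1]]$atoms, c("a", "b", "c", "d"))
  net <- parse_model(text = c(
    "#media B C",
    "v6: B (ab) + C (cd) -> E (badc)",
    "ve: E (abcd) ->"))
  expect_s3_class(net, "tandemer_network")
  e6 <- net$reactions[[1]]
  # E atom 1 <- letter 'b' = B atom 2, atom 3 <- 'd' = C atom 2, etc.
  expect_identical(e6$products[[1]]$atoms, c("b", "a", "d", "c"))
  expect_identical(vapply(e6$substrates, `[[`, "", "met"), c("B", "C"))
  m <- net$metabolites
  expect_identical(m$n_atoms[m$id == "E"], 4L)
  expect_identical(m$is_media[m$id == "C"], TRUE)
})

test_that("the toy fixture expands reversible reactions to the expected ids", {
  net <- toy_network()$network
  ids <- unique(vapply(net$reactions, `[[`, "", "id"))
  expect_true(all(c("v1", "v2", "v3", "v4_f", "v4_b", "v5_f", "v5_b", "v6") %in% ids))
  expect_false("v4" %in% ids)
  expect_false("v5" %in% ids)
})

test_that("parse errors name the offending construct", {
  expect_error(parse_model(text = c("r1: A (ab) -> B (ab)",
                                    "r1: A (ab) -> B (ba)")),
               "duplicate reaction id")
  expect_error(parse_model(text = "r1: A (ab) -> B (abc)"),
               "no substrate source")
  expect_error(parse_model(text = "r1: A (ab) -> B (aa)"),
               "duplicate atom letter")
  expect_error(parse_model(text = "r1: A (a) + B (b) + C (c) -> D (abc)"),
               "more than 2 substrates")
  expect_error(parse_model(text = c("r1: A (ab) -> B (ab)",
                                    "r2: A (abc) -> C (abc)")),
               "inconsistent atom counts")
  expect_error(parse_model(text = c("#media Q", "r1: A (ab) -> B (ab)")),
               "unknown metabolite")
  # reversible reactions must conserve tracked atoms in both directions
  expect_error(parse_model(text = "r1: A (ab) <-> B (a)"),
               "conserve")
})

test_that("n-ary condensations are rejected by default and split on request", {
  txt <- c("#media A B C",
           "r1: A (a) + B (b) + C (c) -> D (abc)",
           "ro: D (abc) ->")
  expect_error(parse_model(text = txt), "split_nary")
  net <- parse_model(text = txt, split_nary = TRUE)
  ids <- vapply(net$reactions, `[[`, "", "id")
  expect_true("r1__nry1" %in% ids)
  # the auto-intermediate inherits the flux of the original reaction
  fl <- parse_fluxes(tmp_csv(c("reaction,flux", "r1,2", "ro,2")), net)
  expect_identical(unname(fl["r1"]), 2)
  ss <- check_steady_state(net, fl)
  expect_true(attr(ss, "ok"))
})

test_that("parse -> serialize -> parse round-trips to an identical network", {
  for (fx in list(toy_network()$network, methionine_network()$network)) {
    txt <- serialize_model(fx)
    again <- parse_model(text = txt)
    expect_identical(again, fx)
  }
  # mapping alternatives (molecular symmetry) survive the round trip
  net <- parse_model(text = c(
    "#media S",
    "sym: S (abcd) -> P (abcd) | S (abcd) -> P (dcba)",
    "po: P (abcd) ->"))
  expect_identical(length(net$reactions), 3L)
  expect_equal(net$reactions[[1]]$weight, 0.5)
  expect_identical(parse_model(text = serialize_model(net)), net)
})

test_that("every parsed reaction conserves tracked atoms", {
  nets <- list(toy_network()$network, methionine_network()$network,
               random_network(seed = 42))
  for (net in nets) {
    for (e in net$reactions) {
      subs <- unlist(lapply(e$substrates, `[[`, "atoms"))
      prods <- unlist(lapply(e$products, `[[`, "atoms"))
      expect_true(all(prods %in% subs))
      expect_false(anyDuplicated(prods) > 0)
    }
  }
})

test_that("flux parsing validates coverage, ids and sign", {
  net <- chain_network()
  fl <- parse_fluxes(tmp_csv(c("reaction,flux", "c1,1", "c2,1", "c3,1")), net)
  expect_equal(unname(fl[c("c1", "c2", "c3")]), c(1, 1, 1))
  expect_error(parse_fluxes(tmp_csv(c("reaction,flux", "c1,1", "c2,1")), net),
               "missing reaction")
  expect_error(parse_fluxes(tmp_csv(c("reaction,flux", "c1,1", "c2,1", "c3,1",
                                      "zz,1")), net), "unknown reaction")
  expect_error(parse_fluxes(tmp_csv(c("reaction,flux", "c1,-1", "c2,1", "c3,1")),
                            net), "non-negative")
})

test_that("tracer parsing validates membership and normalization", {
  net <- chain_network()
  tr <- parse_tracers(tmp_csv(c("metabolite,isotopomer,fraction",
                                "A,00,0.5", "A,11,0.5")), net)
  expect_equal(unname(tr$A[["11"]]), 0.5)
  expect_error(parse_tracers(tmp_csv(c("metabolite,isotopomer,fraction",
                                       "A,00,0.6", "A,11,0.5")), net),
               "sums to")
  expect_error(parse_tracers(tmp_csv(c("metabolite,isotopomer,fraction",
                                       "B,00,1.0")), net), "non-media")
  expect_error(parse_tracers(tmp_csv(c("metabolite,isotopomer,fraction",
                                       "Q,00,1.0")), net), "unknown metabolite")
  expect_error(parse_tracers(tmp_csv(c("metabolite,isotopomer,fraction",
                                       "A,000,1.0")), net), "characters")
})

test_that("target parsing builds canonical MFPs and deduplicates", {
  net <- toy_network()$network
  f <- tmp_csv(c("metabolite,parent_atoms,product_atoms",
                 'E,"1,2,3,4","2,3"',
                 'E,"4,3,2,1","3,2"',
                 'B,"3,4","4"'))
  tg <- parse_targets(f, net)
  expect_length(tg, 2L)
  expect_identical(mfp_id(tg[[1]]), "E^{1,2,3,4}_{2,3}")
  expect_error(parse_targets(tmp_csv(c("metabolite,parent_atoms,product_atoms",
                                       'E,"1,2","3"')), net), "subset")
  expect_error(parse_targets(tmp_csv(c("metabolite,parent_atoms,product_atoms",
                                       'E,"1,2,5","2"')), net), "exceeds")
})

test_that("steady-state check passes on fixtures and flags imbalance", {
  toy <- toy_network()
  ss <- check_steady_state(toy$network, toy$fluxes)
  expect_true(attr(ss, "ok"))
  expect_equal(max(abs(ss$residual)), 0)
  met <- methionine_network()
  expect_true(attr(check_steady_state(met$network, met$fluxes), "ok"))
  # all-zero fluxes balance trivially (simulation would fail later)
  zero <- toy$fluxes; zero[] <- 0
  expect_true(attr(check_steady_state(toy$network, zero), "ok"))
  bad <- toy$fluxes; bad["v1"] <- 5
  ssb <- check_steady_state(toy$network, bad)
  expect_false(attr(ssb, "ok"))
  expect_false(ssb$ok[ssb$metabolite == "B"])
})

test_that("write_results emits feasible cells only and round-trips via JSON", {
  d <- isotopomer_distribution("A", 4, c("1001" = 0.6, "0101" = 0.3, "1011" = 0.1))
  t <- tandemer_from_isotopomers(d, mfp("A", c(2, 3, 4), c(2, 3)))
  res <- stats::setNames(list(t), mfp_id(t$mfp))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  df <- write_results(res, csv, json_path = js, meta = list(seed = 1))
  expect_identical(nrow(df), 6L)
  expect_equal(df$abundance, c(0, 0.6, 0, 0.4, 0, 0))
  ondisk <- utils::read.csv(csv)
  expect_equal(ondisk$abundance, df$abundance)
  back <- read_results_json(js)
  expect_identical(back$results[[1]]$values, t$values)
  # empty results: header-only CSV
  csv2 <- tempfile(fileext = ".csv")
  write_results(list(), csv2)
  expect_identical(nrow(utils::read.csv(csv2)), 0L)
})
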