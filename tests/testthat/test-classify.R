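# Module activity calls, cell-status rules and reference-attractor matching.

test_that("module activity follows promoting/inhibiting votes with ties inactive", {
  net <- make_module_network()
  # unanimous high promoters, inhibitor low -> active (3 of 3 votes)
  ms <- module_states(c(cc1 = 0.85, cc2 = 0.85, ccI = 0.1, ap1 = 0.9), net)
  expect_equal(unname(ms["cell_cycle"]), "active")
  expect_equal(unname(ms["apoptosis"]), "active")
  # unanimous low promoters -> inactive
  ms <- module_states(c(cc1 = 0.05, cc2 = 0.05, ccI = 0.9, ap1 = 0.05), net)
  expect_equal(unname(ms["cell_cycle"]), "inactive")
  expect_equal(unname(ms["apoptosis"]), "inactive")
  # 2 promoters high, 1 inhibitor high -> active by majority (2/3)
  ms <- module_states(c(cc1 = 0.9, cc2 = 0.8, ccI = 0.9, ap1 = 0.1), net)
  expect_equal(unname(ms["cell_cycle"]), "active")
  # tie (promoter high, inhibitor high) -> inactive
  net2 <- network(data.frame(id = c("p", "i"), module = "glycolysis",
                             module_role = c("promotes", "inhibits")))
  ms <- module_states(c(p = 0.9, i = 0.9), net2)
  expect_equal(unname(ms["glycolysis"]), "inactive")
})

test_that("nodes in module 'other' are ignored and empty annotation warns", {
  net <- network(data.frame(id = c("a", "b"), module = c("other", "other")))
  expect_warning(ms <- module_states(c(a = 1, b = 1), net), "no node")
  expect_length(ms, 0)
})

test_that("the verbal cell-status definitions are reproduced", {
  expect_equal(cell_status_from_modules(c(
    cell_cycle = "active", glycolysis = "active", immune_response = "active",
    angiogenesis = "active", apoptosis = "inactive", cell_adhesion = "inactive"
  )), "proliferation")
  expect_equal(cell_status_from_modules(c(
    cell_cycle = "inactive", glycolysis = "inactive",
    immune_response = "inactive", angiogenesis = "inactive",
    apoptosis = "inactive", cell_adhesion = "active"
  )), "cell_cycle_arrest")
  expect_equal(cell_status_from_modules(c(
    cell_cycle = "inactive", glycolysis = "inactive",
    immune_response = "inactive", angiogenesis = "inactive",
    apoptosis = "active", cell_adhesion = "inactive"
  )), "apoptosis")
  # stress response: immune response active, no earlier rule fired
  expect_equal(cell_status_from_modules(c(
    cell_cycle = "inactive", glycolysis = "inactive",
    immune_response = "active", angiogenesis = "inactive",
    apoptosis = "inactive", cell_adhesion = "inactive"
  )), "stress_response")
  # all inactive -> unclassified
  expect_equal(cell_status_from_modules(stats::setNames(
    rep("inactive", 6), setdiff(functional_modules(), "other")
  )), "unclassified")
})

test_that("classification is total over partial module maps", {
  expect_equal(cell_status_from_modules(c(cell_adhesion = "active")),
               "cell_cycle_arrest")
  expect_equal(cell_status_from_modules(c(immune_response = "active",
                                          cell_cycle = "inactive")),
               "stress_response")
  # absent modules are skipped, so the proliferation rule can fire vacuously
  expect_equal(cell_status_from_modules(c(immune_response = "active",
                                          apoptosis = "inactive")),
               "proliferation")
  expect_error(cell_status_from_modules(c(not_a_module = "active")),
               "unknown module")
})

test_that("reference matching picks the nearest reference within max_dist", {
  refs <- reference_attractors(
    states = list(P2 = c(x = 1, y = 0), A1 = c(x = 0, y = 1)),
    labels = c(P2 = "proliferation", A1 = "cell_cycle_arrest")
  )
  # identical to a reference
  expect_equal(as.character(match_to_reference(c(x = 1, y = 0), refs)),
               "proliferation")
  # distances 0.08 vs 0.92 with max_dist 0.3 -> nearer label
  got <- match_to_reference(c(x = 0.92, y = 0.08), refs, max_dist = 0.3)
  expect_equal(as.character(got), "proliferation")
  expect_equal(unname(attr(got, "distance")["P2"]), 0.08)
  # farther than max_dist from all references -> unclassified
  expect_equal(as.character(match_to_reference(c(x = 0.5, y = 0.5), refs,
                                               max_dist = 0.3)),
               "unclassified")
  # exact tie -> unclassified with both candidates reported
  tied <- match_to_reference(c(x = 0.5, y = 0.5), refs, max_dist = 0.6)
  expect_equal(as.character(tied), "unclassified")
  expect_setequal(attr(tied, "candidates"), c("P2", "A1"))
  # no shared nodes -> error
  expect_error(match_to_reference(c(z = 1), refs), "no shared nodes")
})

test_that("reference attractor tables round-trip through TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("node\tA1\tP2",
               "x\t0.1\t0.9",
               "y\t0.8\t0.2",
               "cell_status\tcell_cycle_arrest\tproliferation"), path)
  refs <- read_reference_attractors(path)
  expect_equal(refs$labels,
               c(A1 = "cell_cycle_arrest", P2 = "proliferation"))
  expect_equal(refs$states$P2, c(x = 0.9, y = 0.2))
})

test_that("driver direction report counts oncogenes and TSGs as constructed", {
  net <- network(data.frame(
    id = c("o1", "o2", "o3", "t1", "t2"),
    driver_type = c("oncogene", "oncogene", "oncogene", "tsg", "tsg")
  ))
  prolif <- c(o1 = 0.8, o2 = 0.9, o3 = 0.7, t1 = 0.1, t2 = 0.9)
  arrest <- c(o1 = 0.1, o2 = 0.2, o3 = 0.1, t1 = 0.7, t2 = 0.2)
  res <- check_driver_directions(prolif, arrest, net)
  expect_equal(res$summary$consistent[res$summary$driver_type == "oncogene"], 3)
  expect_equal(res$summary$n[res$summary$driver_type == "oncogene"], 3)
  expect_equal(res$summary$consistent[res$summary$driver_type == "tsg"], 1)
  expect_equal(res$summary$n[res$summary$driver_type == "tsg"], 2)
  expect_true(res$report$higher_in_proliferation[res$report$id == "o1"])
  expect_false(res$report$higher_in_proliferation[res$report$id == "t1"])
})
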