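mk_ala <- function(predictor, chain, position, ddg,
                   convention = "positive_destabilizes", wt = "L") {
  ddg_records(predictor, chain, position, wt = wt, mut = "A", ddg = ddg,
              convention = convention)
}

test_that("alanine-scan significance uses strict per-predictor thresholds", {
  recs <- rbind(
    mk_ala("mcsm", "L", 27, -1.5),
    mk_ala("mcsm", "L", 31, -0.5),
    mk_ala("mcsm", "L", 49, 1.0),    # boundary: not greater than 1
    mk_ala("foldx", "H", 52, 6.0),
    mk_ala("foldx", "H", 57, -5.0),  # boundary: excluded
    mk_ala("foldx", "H", 59, -5.2))
  hits <- computational_alanine_hits(recs)
  expect_equal(hits$mcsm$position, 27L)
  expect_setequal(hits$foldx$position, c(52L, 59L))
  # raising a threshold never grows the hit set
  tight <- computational_alanine_hits(recs,
                                      threshold_config(mcsm_abs_threshold = 2,
                                                       foldx_abs_threshold = 7))
  expect_true(all(abmature:::pos_key(tight$mcsm) %in%
                    abmature:::pos_key(hits$mcsm)))
  expect_true(all(abmature:::pos_key(tight$foldx) %in%
                    abmature:::pos_key(hits$foldx)))
})

test_that("non-alanine mutants are rejected from alanine-scan records", {
  bad <- ddg_records("mcsm", "L", 27, "L", "Y", -1.5,
                     "positive_destabilizes")
  expect_error(computational_alanine_hits(bad), "non-alanine")
  # wild-type alanine probed as glycine is accepted
  ok <- ddg_records("mcsm", "L", 32, "A", "G", -2, "positive_destabilizes")
  expect_equal(computational_alanine_hits(ok)$mcsm$position, 32L)
})

test_that("key-residue modes implement the documented set algebra", {
  comp_m <- data.frame(chain = "L", position = c(27, 31))
  comp_f <- data.frame(chain = "L", position = c(31, 49))
  exp_h <- data.frame(chain = "L", position = c(27, 49, 90))
  inter <- derive_key_residues(comp_m, comp_f, exp_h, mode = "intersect")
  expect_setequal(inter$position, c(27, 49))
  uni <- derive_key_residues(comp_m, comp_f, exp_h, mode = "union")
  expect_setequal(uni$position, c(27, 31, 49, 90))
  expect_true(all(abmature:::pos_key(inter) %in% abmature:::pos_key(uni)))
  comp_first <- derive_key_residues(comp_m, comp_f, exp_h)
  expect_setequal(comp_first$position, c(27, 31, 49))
  expect_true(comp_first$experimental[comp_first$position == 27])
  expect_false(comp_first$experimental[comp_first$position == 31])
  # provenance: every residue carries at least one flag
  for (k in list(inter, uni, comp_first))
    expect_true(all(k$computational_mcsm | k$computational_foldx |
                      k$experimental))
  expect_warning(
    derive_key_residues(data.frame(chain = character(), position = integer()),
                        data.frame(chain = character(), position = integer()),
                        exp_h, mode = "intersect"),
    "empty")
})

test_that("the shipped experimental scan resolves to 13 distinct positions", {
  scan <- read_experimental_scan(
    system.file("extdata", "t6_experimental_alanine_scan.csv",
                package = "abmature"))
  hits <- experimental_hits(scan)
  expect_equal(nrow(hits), 13L)
  expect_equal(anyDuplicated(abmature:::pos_key(hits)), 0L)
  expect_setequal(hits$position[hits$chain == "H"], c(52, 57, 59, 99, 102, 105))
  # the wild-type-alanine entry was probed as glycine
  expect_equal(scan$mutated_to[scan$position == 32 & scan$chain == "L"], "G")
})

test_that("experimental-scan validation enforces the A/G contract", {
  bad <- data.frame(chain = "L", position = 1, wt = "K", mutated_to = "G",
                    effect = "hit")
  expect_error(validate_experimental_scan(bad), "alanine")
  bad2 <- data.frame(chain = "L", position = 1, wt = "K", mutated_to = "Y",
                     effect = "hit")
  expect_error(validate_experimental_scan(bad2), "must be to A")
})

test_that("docking-model coverage is the fraction of hits at the interface", {
  planted <- data.frame(ab_chain = c("H", "H", "L", "L"),
                        ab_resno = c(1, 2, 3, 4),
                        ag_resno = c(1, 3, 5, 7), distance = 3.0)
  s <- make_toy_complex(planted = planted, seed = 13)
  iface <- find_interface_residues(s, c("H", "L"), "A", 4.5)
  all_in <- data.frame(chain = c("H", "H", "L", "L"),
                       position = c(1, 2, 3, 4))
  expect_equal(validate_docking_model(iface, all_in), 1.0)
  half <- data.frame(chain = c("H", "H", "L", "L"),
                     position = c(1, 2, 9, 10))  # two hits off-interface
  expect_equal(validate_docking_model(iface, half), 0.5)
  expect_error(validate_docking_model(iface,
                                      data.frame(chain = character(),
                                                 position = integer())),
               "undefined")
})

test_that("coverage is monotone non-decreasing in the interface cutoff", {
  planted <- data.frame(ab_chain = c("H", "L"), ab_resno = c(2, 3),
                        ag_resno = c(2, 6), distance = c(2.5, 4.2))
  s <- make_toy_complex(planted = planted, seed = 21)
  hits <- data.frame(chain = c("H", "L"), position = c(2, 3))
  cov <- vapply(c(2.0, 3.0, 4.5, 6.0), function(cc) {
    validate_docking_model(find_interface_residues(s, c("H", "L"), "A", cc),
                           hits)
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("ddG sign conventions are explicit and normalized", {
  expect_error(ddg_records("mcsm", "L", 49, "E", "Y", 1.2, "whatever"),
               "convention")
  r <- rbind(
    ddg_records("mcsm", "L", 49, "E", "Y", 1.2, "positive_improves_binding"),
    ddg_records("geo", "L", 49, "E", "Y", -0.8, "positive_destabilizes"))
  n <- normalize_ddg(r)
  expect_equal(n$improvement, c(1.2, 0.8))
  expect_error(ddg_records("mcsm", "L", 49, "Y", "Y", 1,
                           "positive_improves_binding"),
               "wild-type == mutant")
})
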