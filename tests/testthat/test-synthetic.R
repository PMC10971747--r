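test_that("toy complexes realize planted contacts and nothing else", {
  planted <- data.frame(ab_chain = c("H", "L", "L"), ab_resno = c(3, 5, 9),
                        ag_resno = c(2, 7, 11), distance = c(3.0, 2.5, 4.0))
  s <- make_toy_complex(planted = planted, seed = 7)
  im <- find_interface_residues(s, c("H", "L"), "A", 4.5)
  expect_setequal(paste0(im$group_a$chain, im$group_a$resno),
                  paste0(planted$ab_chain, planted$ab_resno))
  expect_setequal(im$group_b$resno, planted$ag_resno)
  # realized distances within +-0.1 A of the request
  realized <- im$group_a$min_dist[match(
    paste0(planted$ab_chain, planted$ab_resno),
    paste0(im$group_a$chain, im$group_a$resno))]
  expect_true(all(abs(realized - planted$distance) <= 0.1))
  # zero planted contacts -> empty interface
  s0 <- make_toy_complex(seed = 7)
  im0 <- find_interface_residues(s0, c("H", "L"), "A", 4.5)
  expect_equal(nrow(im0$group_a) + nrow(im0$group_b), 0L)
})

test_that("generators are pure functions of their seed", {
  planted <- data.frame(ab_chain = "H", ab_resno = 2, ag_resno = 4,
                        distance = 3.1)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(make_toy_complex(planted = planted, seed = 5), f1)
  write_pdb(make_toy_complex(planted = planted, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  s3 <- make_toy_complex(planted = planted, seed = 6)
  expect_false(identical(readLines(f1),
                         {write_pdb(s3, f2); readLines(f2)}))
  # ddG and assay generators likewise
  key <- data.frame(chain = "H", position = 2)
  seqs <- list(H = "KVERI")
  t1 <- simulate_ddg_tables(key, seqs, planted = c(H2Y = 1.5),
                            predictors = list(mcsm = list(
                              noise_sd = 0.3,
                              convention = "positive_improves_binding")),
                            seed = 9)
  t2 <- simulate_ddg_tables(key, seqs, planted = c(H2Y = 1.5),
                            predictors = list(mcsm = list(
                              noise_sd = 0.3,
                              convention = "positive_improves_binding")),
                            seed = 9)
  expect_identical(t1, t2)
  d1 <- simulate_dose_response(c(x = 1), 10^seq(-2, 2, length.out = 6),
                               seed = 4)
  d2 <- simulate_dose_response(c(x = 1), 10^seq(-2, 2, length.out = 6),
                               seed = 4)
  expect_identical(d1, d2)
  # generator calls do not disturb the global RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(make_toy_complex(seed = 123))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("infeasible planted geometries are rejected", {
  expect_error(make_toy_complex(
    planted = data.frame(ab_chain = "H", ab_resno = 1, ag_resno = 1,
                         distance = 1.0), seed = 1), "1.5")
  expect_error(make_toy_complex(
    planted = data.frame(ab_chain = c("H", "H"), ab_resno = c(1, 1),
                         ag_resno = c(1, 2), distance = 3), seed = 1),
    "infeasible|distinct")
  expect_error(make_toy_complex(
    planted = data.frame(ab_chain = "H", ab_resno = 99, ag_resno = 1,
                         distance = 3), seed = 1), "range")
})

test_that("ddG conventions plant the right signs per predictor", {
  key <- data.frame(chain = "L", position = 3)
  seqs <- list(L = "KVERI")
  tabs <- simulate_ddg_tables(key, seqs, planted = c(L3Y = 1.5), seed = 2)
  mc <- tabs$mcsm; fx <- tabs$foldx; geo <- tabs$geo
  expect_equal(mc$ddg[mc$mut == "Y"], 1.5)
  expect_equal(fx$ddg[fx$mut == "Y"], -7.5)  # destabilizing convention, gain 5
  expect_equal(normalize_ddg(fx)$improvement[fx$mut == "Y"], 7.5)
  expect_equal(geo$ddg[geo$mut == "Y"], 1.5)
  expect_true(all(mc$ddg[mc$mut != "Y"] == 0))
  # alanine mode probes one mutation per site, G where wild type is A
  seqs2 <- list(L = "KAERI")
  ala <- simulate_ddg_tables(data.frame(chain = "L", position = c(2, 3)),
                             seqs2, mutants = "alanine", seed = 2)
  expect_equal(ala$mcsm$mut[ala$mcsm$position == 2], "G")
  expect_equal(ala$mcsm$mut[ala$mcsm$position == 3], "A")
})

test_that("dose-response simulation honours replicates and noise", {
  doses <- 10^seq(-1, 1, length.out = 5)
  d <- simulate_dose_response(c(x = 1), doses, noise_sd = 0.02,
                              replicates = 3, seed = 11)
  expect_equal(nrow(d), 15L)
  expect_equal(as.vector(table(d$concentration)), rep(3L, 5))
  d0 <- simulate_dose_response(c(x = 1), doses, noise_sd = 0, seed = 11)
  mu <- 0 + (1 - 0) / (1 + (doses / 1)^1)
  expect_equal(d0$response, mu)
})

test_that("two antibodies separated 3x in IC50 rank correctly across seeds", {
  doses <- 10^seq(-2, 2, length.out = 8)
  correct <- vapply(1:100, function(seed) {
    d <- simulate_dose_response(c(good = 0.5, bad = 1.5), doses,
                                noise_sd = 0.02, seed = seed)
    tbl <- fit_ic50_table(d)
    tbl$label[which.min(tbl$ic50)] == "good"
  }, logical(1))
  expect_gte(mean(correct), 0.95)
})

test_that("experimental-scan simulation applies fp/fn rates exactly at 0/1", {
  seqs <- list(H = "KVERIKVERI")
  true_key <- data.frame(chain = "H", position = c(2, 5))
  all_pos <- data.frame(chain = "H", position = 1:10)
  clean <- simulate_experimental_scan(true_key, all_pos, seqs, seed = 3)
  expect_setequal(experimental_hits(clean)$position, c(2, 5))
  none <- simulate_experimental_scan(true_key, all_pos, seqs, fn_rate = 1,
                                     seed = 3)
  expect_equal(nrow(experimental_hits(none)), 0L)
  allhit <- simulate_experimental_scan(true_key, all_pos, seqs, fp_rate = 1,
                                       seed = 3)
  expect_equal(nrow(experimental_hits(allhit)), 10L)
})

test_that("false-positive count matches its binomial expectation", {
  seqs <- list(H = paste(rep("K", 22), collapse = ""))
  true_key <- data.frame(chain = "H", position = 1:2)
  all_pos <- data.frame(chain = "H", position = 1:22)
  extra <- vapply(1:400, function(seed) {
    sc <- simulate_experimental_scan(true_key, all_pos, seqs,
                                     fp_rate = 0.1, seed = seed)
    sum(experimental_hits(sc)$position > 2)
  }, numeric(1))
  # 20 non-key positions at fp 0.1 -> mean 2, se = sqrt(20*.1*.9/400) ~ 0.067
  expect_equal(mean(extra), 2, tolerance = 0.15)
})
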