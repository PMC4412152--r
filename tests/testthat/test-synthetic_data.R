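test_that("a simulated run has the screen's plate and well structure", {
  run <- simulate_primary_run(sim_config(), seed = 9)
  rec <- run$records
  lay <- plate_layout()
  # twelve plates of 96 wells: 1 baseline + 11 odor plates
  expect_equal(length(unique(rec$plate_id)), 12L)
  counts <- table(rec$plate_id)
  expect_true(all(counts == 96L))
  for (pid in unique(rec$plate_id)) {
    plate <- rec[rec$plate_id == pid, ]
    expect_equal(sum(plate$well_index %in% lay$test_wells), 85L)
    std_ag <- plate[plate$well_index %in% lay$standard_agonist_wells, ]
    std_di <- plate[plate$well_index %in% lay$standard_diluent_wells, ]
    expect_equal(nrow(std_ag), 3L)
    expect_equal(nrow(std_di), 3L)
    expect_true(all(std_ag$receptor_id == "Olfr544"))
    expect_true(all(std_di$receptor_id == "Olfr544"))
    expect_true(all(std_ag$concentration_uM == 10))
    expect_true(all(std_di$no_odor))
    expect_equal(sum(plate$well_index %in% lay$broad_wells), 5L)
  }
  # exactly one baseline plate: all test wells no-odor with sentinel
  test_rec <- rec[rec$well_index %in% lay$test_wells, ]
  base_plates <- tapply(test_rec$no_odor, test_rec$plate_id, all)
  expect_equal(sum(base_plates), 1L)
})

test_that("the same receptor sits in the same well on all plates of a run", {
  run <- simulate_primary_run(sim_config(n_receptors = 40), seed = 10)
  maps <- split(run$records[, c("well_index", "receptor_id")],
                run$records$plate_id)
  ref <- maps[[1]][order(maps[[1]]$well_index), ]
  for (m in maps) {
    m <- m[order(m$well_index), ]
    expect_equal(m$receptor_id, ref$receptor_id)
  }
})

test_that("simulator output passes its own schema reader unchanged", {
  truth <- sim_truth(sim_config(n_receptors = 15, n_odors = 4,
                                agonist_density = 0.3), seed = 12)
  run <- simulate_primary_run(truth = truth, seed = 12)
  pairs <- truth$agonists[, c("receptor_id", "odor_id")]
  sec <- simulate_secondary(pairs, truth = truth, seed = 12)
  dose <- simulate_dose_response(pairs, truth = truth, seed = 12)
  for (kind in c("primary", "secondary", "dose")) {
    tab <- switch(kind, primary = run$records, secondary = sec, dose = dose)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_record_table(tab, path, kind)
    expect_equal(nrow(read_record_table(path, kind)), nrow(tab),
                 label = kind)
  }
})

test_that("simulation is reproducible under a seed and varies across seeds", {
  cfg <- sim_config(n_receptors = 10, n_odors = 3)
  a <- simulate_primary_run(cfg, seed = 42)
  b <- simulate_primary_run(cfg, seed = 42)
  c <- simulate_primary_run(cfg, seed = 43)
  expect_identical(a$records, b$records)
  expect_false(isTRUE(all.equal(a$records$luc_counts, c$records$luc_counts)))
  # byte-identical files under the same seed
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_record_table(a$records, fa, "primary")
  write_record_table(b$records, fb, "primary")
  expect_identical(readLines(fa), readLines(fb))
})

test_that("noise-free null screens give exactly zero deltas", {
  cfg <- sim_config(n_receptors = 20, n_odors = 5, agonist_density = 0,
                    noise_sigma = 0, rl_cv = 0)
  run <- simulate_primary_run(cfg, seed = 6)
  sc <- primary_screen_scores(run$records)
  expect_equal(max(abs(sc$delta)), 0, tolerance = 1e-12)
})

test_that("planted agonists produce rising secondary group means", {
  cfg <- sim_config(n_receptors = 5, n_odors = 2, agonist_density = 0,
                    noise_sigma = 0)
  truth <- sim_truth(cfg, seed = 14)
  truth$agonists <- tibble::tibble(receptor_id = "1001", odor_id = "3001",
                                   log_ec50 = -5, efficacy = 1)
  sec <- simulate_secondary(tibble::tibble(receptor_id = "1001",
                                           odor_id = "3001"),
                            truth = truth, seed = 14)
  expect_equal(nrow(sec), 12L)  # 4 groups x 3 replicates
  means <- tapply(sec$normalized_luc, sec$concentration_uM, mean)
  expect_true(all(diff(means[order(as.numeric(names(means)))]) > 0))
  # occupancy model arithmetic: at 10 uM and EC50 10 uM, half-maximal
  base <- truth$baselines$baseline_response[
    truth$baselines$receptor_id == "1001"]
  expect_equal(unname(means[["10"]]), base + 1 * 10 / (10 + 10),
               tolerance = 1e-12)
})

test_that("noise-free dose series are exactly recoverable; vector is flat", {
  cfg <- sim_config(n_receptors = 5, n_odors = 2, agonist_density = 0,
                    noise_sigma = 0)
  truth <- sim_truth(cfg, seed = 15)
  truth$agonists <- tibble::tibble(receptor_id = "1001", odor_id = "3001",
                                   log_ec50 = -5.5, efficacy = 0.9)
  dose <- simulate_dose_response(tibble::tibble(receptor_id = "1001",
                                                odor_id = "3001"),
                                 truth = truth, seed = 15)
  rp <- dose[dose$receptor_id == "1001", ]
  fit <- fit_sigmoid(data.frame(x = rp$concentration_log10M,
                                y = rp$normalized_luc))
  expect_equal(unname(fit$params["log_ec50"]), -5.5, tolerance = 1e-4)
  expect_equal(unname(fit$params["top"] - fit$params["bottom"]), 0.9,
               tolerance = 1e-4)
  vp <- dose[dose$receptor_id == "vector", ]
  expect_lt(diff(range(vp$normalized_luc)), 1e-9)
})

test_that("truth round-trips through agonist scoring end to end", {
  cfg <- sim_config(n_receptors = 5, n_odors = 2, agonist_density = 0)
  truth <- sim_truth(cfg, seed = 16)
  truth$agonists <- tibble::tibble(receptor_id = "1001", odor_id = "3001",
                                   log_ec50 = -5, efficacy = 1)
  dose <- simulate_dose_response(
    tibble::tibble(receptor_id = c("1001", "1002"),
                   odor_id = c("3001", "3001")),
    truth = truth, seed = 16)
  calls <- dose_response_calls(dose)
  expect_true(calls$is_agonist[calls$receptor_id == "1001"])
  expect_false(calls$is_agonist[calls$receptor_id == "1002"])
})

test_that("invalid agonist density is a config error", {
  expect_error(sim_config(agonist_density = 1.5), "config error")
})
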