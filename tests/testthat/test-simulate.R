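# Synthetic-fixture generators: determinism, ground-truth consistency,
# and recovery through the real pipeline (including file I/O).

test_that("the same fixture spec yields byte-identical files", {
  spec <- fixture_spec(seed = 99, n_compounds = 12, n_kinases = 40,
                       promiscuous_size_range = c(15, 25))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_profiles(spec, dir = d1)
  gen_profiles(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("generated S10 equals planted active count over panel size", {
  fx <- gen_profiles(fixture_spec(seed = 13, n_compounds = 30,
                                  n_kinases = 150,
                                  promiscuous_size_range = c(20, 50)))
  s10 <- compute_s10(fx$matrix)
  got <- s10$s10[match(fx$truth$compound_id, s10$compound_id)]
  expect_equal(got, fx$truth$s10_true)
  # K_D records exist only for sub-cutoff kinases
  prof <- setNames(fx$truth$active_set, fx$truth$compound_id)
  for (i in seq_len(nrow(fx$kd))) {
    expect_true(fx$kd$kinase[i] %in% prof[[fx$kd$compound[i]]])
  }
})

test_that("degenerate mixtures behave as planted", {
  all_sel <- gen_profiles(fixture_spec(seed = 2, n_compounds = 10,
                                       n_kinases = 401,
                                       fraction_selective = 1,
                                       fraction_promiscuous = 0,
                                       fraction_inactive = 0,
                                       active_size_range = c(2, 2),
                                       kd_range_nM = c(10, 50)))
  dec <- decide_inclusion(compute_s10(all_sel$matrix), all_sel$kd)
  expect_true(all(dec$passed))

  none <- gen_profiles(fixture_spec(seed = 2, n_compounds = 10,
                                    n_kinases = 60,
                                    fraction_selective = 0,
                                    fraction_promiscuous = 0,
                                    fraction_inactive = 1))
  expect_equal(nrow(filter_candidates(none$matrix, none$kd)), 0)
  expect_error(fixture_spec(n_kinases = 20, promiscuous_size_range = c(30, 60)),
               "exceeds the panel")
})

test_that("fixtures survive the file round trip into the pipeline", {
  d <- withr::local_tempdir()
  fx <- gen_profiles(fixture_spec(seed = 4, n_compounds = 15,
                                  n_kinases = 120,
                                  promiscuous_size_range = c(20, 40)),
                     dir = d)
  panel <- read_panel(fx$paths$panel)
  m <- read_poc_matrix(fx$paths$poc, panel)
  kd <- read_kd_table(fx$paths$kd)
  expect_equal(as.data.frame(m)[order(m$compound_id, m$kinase), ],
               as.data.frame(fx$matrix)[order(fx$matrix$compound_id,
                                              fx$matrix$kinase), ],
               ignore_attr = TRUE)
  cand <- filter_candidates(m, kd)
  expect_setequal(cand$compound_id,
                  fx$truth$compound_id[fx$truth$should_pass])
})

test_that("toy molecules are stable and binned as expected", {
  t1 <- toy_molecules()
  t2 <- toy_molecules()
  expect_identical(t1, t2)
  expect_true(all(smiles_is_valid(t1$smiles)))
  cat0 <- load_bin_catalog(system.file("extdata", "demo_bins.tsv",
                                       package = "kinoset"))
  expect_equal(assign_chemotypes(t1[, c("id", "smiles")], cat0)$bin,
               t1$expected_bin)
})

test_that("zero-noise growth fixtures are classified exactly as planted", {
  fx <- gen_growth_screen(fixture_spec(seed = 21, growth_noise_sd = 0))
  cls <- compute_gr(fx$records) |> classify_growth_response()
  got <- cls$response[match(fx$truth$compound_id, cls$compound_id)]
  expect_equal(got, fx$truth$class)
  # zero-effect compounds have gr exactly 1 on every line
  gr <- compute_gr(fx$records)
  inact <- fx$truth$compound_id[fx$truth$class == "inactive"]
  expect_equal(gr$gr[gr$compound_id %in% inact],
               rep(1, sum(gr$compound_id %in% inact)))
})

test_that("noisy growth fixtures are still mostly recovered", {
  fx <- gen_growth_screen(fixture_spec(seed = 22, growth_noise_sd = 0.05))
  cls <- compute_gr(fx$records) |> classify_growth_response()
  got <- cls$response[match(fx$truth$compound_id, cls$compound_id)]
  # broad and line-dependent effects are far from the thresholds at this
  # noise level; allow no more than one straggler
  expect_gte(sum(got == fx$truth$class), nrow(fx$truth) - 1)
})

test_that("zero-noise flux fixtures reproduce planted hits exactly", {
  fx <- gen_flux_screen(fixture_spec(seed = 8, flux_noise_sd = 0))
  pct <- autophagy_normalize(fx$flux)
  hits <- autophagy_hit_call(pct)
  m <- dplyr::inner_join(hits, fx$truth, by = "compound_id",
                         suffix = c("", ".true"))
  expect_equal(m$is_hit, m$is_hit.true)
  planted <- m[m$is_hit.true, ]
  expect_equal(planted$direction, planted$direction.true)
  expect_equal(planted$run_start, planted$run_start.true)
  expect_equal(planted$run_length, planted$run_length.true)
  # detection agrees with the brute-force window scan on every series
  for (cmp in unique(pct$compound_id)) {
    x <- pct$pct_flux[pct$compound_id == cmp]
    expect_equal(hits$is_hit[hits$compound_id == cmp],
                 oracle_hit_scan(x, 20, 5)$is_hit)
  }
})
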