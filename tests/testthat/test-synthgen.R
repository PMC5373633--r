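test_that("a zero labelled fraction produces no S-phase cells", {
  truth <- generate_population(
    population_params(n_cells = 1000, frac_replicating = 0, seed = 1),
    cell_cycle_params(frac_g1 = 0.8, frac_s = 0, frac_g2m = 0.2))
  expect_equal(sum(truth$phase == "S"), 0)
  expect_true(all(truth$signal_specific == 0))
})

test_that("S-cell count at n = 10,000 lies in the binomial 99% interval", {
  truth <- generate_population(population_params(n_cells = 10000, seed = 42),
                               cell_cycle_params())
  n_s <- sum(truth$phase == "S")
  # qbinom(c(0.005, 0.995), 10000, 0.44) = c(4272, 4528)
  expect_gte(n_s, 4272)
  expect_lte(n_s, 4528)
})

test_that("default population recovers its parameters within 3 SE", {
  pop <- population_params(n_cells = 10000, seed = 11)
  truth <- generate_population(pop, cell_cycle_params())
  # labelled fraction
  f_emp <- mean(truth$phase == "S")
  se_f <- sqrt(0.44 * 0.56 / 10000)
  expect_lt(abs(f_emp - 0.44), 3 * se_f)
  # mean replication signal of the S component
  s_sig <- truth$true_signal[truth$phase == "S"]
  expect_lt(abs(mean(s_sig) - pop$mu_signal_R),
            3 * stats::sd(s_sig) / sqrt(length(s_sig)))
  # phase counts conserve the population size
  expect_equal(sum(table(truth$phase)), 10000)
  # S-phase DNA content stays strictly between 2N and 4N
  s_dna <- truth$dna_content[truth$phase == "S"]
  expect_true(all(s_dna > 100 & s_dna < 200))
})

test_that("identical parameters and seed reproduce identical output", {
  p <- population_params(n_cells = 500, seed = 99)
  cyc <- cell_cycle_params()
  expect_identical(generate_population(p, cyc), generate_population(p, cyc))
  img <- imaging_params(width = 256, height = 256, seed = 5)
  t1 <- generate_population(population_params(n_cells = 30, seed = 1), cyc)
  expect_identical(render_images(t1, img), render_images(t1, img))
  expect_identical(generate_flow_events(t1, 0.1, seed = 2),
                   generate_flow_events(t1, 0.1, seed = 2))
})

test_that("mismatched replicating/S fractions are rejected with both values", {
  expect_error(
    generate_population(population_params(frac_replicating = 0.3),
                        cell_cycle_params(frac_s = 0.44)),
    "0.3.*0.44")
})

test_that("rendering an empty population gives blank images", {
  truth <- generate_population(
    population_params(n_cells = 0, frac_replicating = 0, seed = 1),
    cell_cycle_params(frac_g1 = 1, frac_s = 0, frac_g2m = 0))
  out <- render_images(truth, imaging_params(width = 64, height = 64,
                                             gaussian_noise_sd = 0))
  expect_true(all(out$dapi == 0))
  expect_true(all(out$signal == 0))
  expect_true(all(out$labels == 0L))
})

test_that("noise-free rendering of 50 cells yields 50 connected components", {
  truth <- generate_population(population_params(n_cells = 50, seed = 2),
                               cell_cycle_params())
  out <- render_images(truth, imaging_params(gaussian_noise_sd = 0, seed = 3))
  expect_equal(length(unique(out$labels[out$labels > 0])), 50)
  # connected components of the foreground agree with the label count
  comp <- EBImage::bwlabel(EBImage::Image((out$labels > 0) * 1))
  expect_equal(max(comp), 50)
})

test_that("rendered pixel intensities reproduce the truth values", {
  truth <- generate_population(
    population_params(n_cells = 1, frac_replicating = 0, seed = 1),
    cell_cycle_params(frac_g1 = 1, frac_s = 0, frac_g2m = 0))
  truth$true_signal <- 1000
  out <- render_images(truth, imaging_params(width = 128, height = 128,
                                             gaussian_noise_sd = 0, seed = 4))
  inside <- out$labels == truth$cell_id
  expect_lt(abs(mean(out$signal[inside]) - 1000), 0.5)
  # integrated DAPI equals gain * dna_content up to pixel rounding
  expect_lt(abs(sum(out$dapi[inside]) - 1000 * truth$dna_content) /
              (1000 * truth$dna_content), 0.01)
})

test_that("placement respects the overlap error contract", {
  truth <- generate_population(population_params(n_cells = 200, seed = 6),
                               cell_cycle_params())
  expect_error(
    render_images(truth, imaging_params(width = 96, height = 96, seed = 7)),
    "placed")
})

test_that("noise-free flow events equal the truth columns up to ordering", {
  truth <- generate_population(population_params(n_cells = 200, seed = 8),
                               cell_cycle_params())
  ev <- generate_flow_events(truth, noise_cv = 0, seed = 9)
  ord <- match(truth$cell_id, ev$cell_id)
  expect_equal(ev$signal[ord], truth$true_signal)
  expect_equal(ev$dna_content[ord], truth$dna_content)
})

test_that("flow measurement noise has the configured CV", {
  truth <- generate_population(
    population_params(n_cells = 10000, seed = 10),
    cell_cycle_params(dna_cv = 0))  # G1 truth content is exactly 2N
  ev <- generate_flow_events(truth, noise_cv = 0.1, seed = 11)
  g1 <- ev$dna_content[ev$cell_id %in% truth$cell_id[truth$phase == "G1"]]
  cv_emp <- stats::sd(g1) / mean(g1)
  expect_lt(abs(cv_emp - 0.1) / 0.1, 0.2)
})

test_that("washing scales only the specific signal, monotonically in time", {
  truth <- generate_population(population_params(n_cells = 500, seed = 12),
                               cell_cycle_params())
  kin <- antibody_kinetics()
  # zero-length wash leaves the table untouched
  expect_equal(apply_wash_dissociation(truth, kin, t_wash = 0), truth)
  # the 5-minute wash retains exactly 20% of the specific component
  w5 <- apply_wash_dissociation(truth, kin, t_wash = 5)
  expect_equal(w5$signal_specific, truth$signal_specific * 0.2)
  expect_equal(w5$signal_background, truth$signal_background)
  # 30 minutes: specific signal below 0.1% of initial
  w30 <- apply_wash_dissociation(truth, kin, t_wash = 30)
  expect_lt(max(w30$signal_specific / pmax(truth$signal_specific, 1e-12)),
            0.001)
  # monotone decay over a time grid
  prev <- truth
  for (t in c(1, 2, 5, 10, 30)) {
    cur <- apply_wash_dissociation(truth, kin, t_wash = t)
    expect_true(all(cur$signal_specific <= prev$signal_specific + 1e-12))
    prev <- cur
  }
  # stabilisation freezes the complex at the concentration-dependent factor
  st <- apply_wash_dissociation(truth, kin, t_wash = 30, stabilised = TRUE,
                                formaldehyde_conc = 0.05)
  expect_equal(st$signal_specific, truth$signal_specific * 0.827)
  expect_error(apply_wash_dissociation(truth, kin, t_wash = -1), "t_wash")
})
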