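test_that("receptor level to concentration conversion is a pure unit bridge", {
  expect_equal(receptors_per_cell_to_concentration(0, 1e9, 1), 0)
  one <- receptors_per_cell_to_concentration(550, 1e11, 10)
  expect_equal(receptors_per_cell_to_concentration(550, 2e11, 10), 2 * one,
               tolerance = 1e-12)
  # independent arithmetic oracle
  expect_equal(one, 550 * 1e11 / (6.02214076e23 * 10) * 1e12,
               tolerance = 1e-12)
  expect_error(receptors_per_cell_to_concentration(100, 1e9, 0), "volume")
})

test_that("receptor updates split endothelial levels across both surfaces", {
  m <- vegf_model()
  # control configuration carries the published 1100/700 levels
  ec <- m$pairs[m$pairs$cell_type == "healthy_ec", ]
  expect_equal(ec$level[ec$receptor == "VEGFR1"], c(550, 550))
  expect_equal(ec$level[ec$receptor == "VEGFR2"], c(350, 350))
  m2 <- apply_receptor_update(m, "healthy_ec", "VEGFR1", 2110)
  upd <- m2$pairs[m2$pairs$cell_type == "healthy_ec" &
                    m2$pairs$receptor == "VEGFR1", ]
  expect_equal(upd$level, c(1055, 1055))
  # abluminal surface faces normal tissue, luminal faces blood
  expect_equal(upd$compartment[order(upd$surface)], c("normal", "blood"))
  # tumor cells are wholly interstitial: no split
  m3 <- apply_receptor_update(m, "tumor_cell", "VEGFR1", 13000)
  expect_equal(m3$pairs$level[m3$pairs$pair == "tumor.VEGFR1"], 13000)
  expect_error(apply_receptor_update(m, "myocyte", "NRP1", 100), "carries no")
})

test_that("drug-free receptor steady state equals s_R / k_int", {
  m <- apply_receptor_update(vegf_model(), "healthy_ec", "VEGFR1", 2110)
  sim <- simulate_model(m, dose_schedule(amount = 0), n_out = 2)
  pairs <- m$pairs
  total <- sim$ss[paste0("R.", pairs$pair)] + sim$ss[paste0("RV.", pairs$pair)]
  expect_true(all(abs(total - pairs$s / m$config$k_int) <=
                    0.001 * pmax(pairs$s / m$config$k_int, 1e-12)))
  # with no VEGF source anywhere, the unoccupied level itself is s_R / k_int
  cfg <- m$config
  cfg$secretion[] <- 0
  m0 <- vegf_model(cfg)
  m0 <- apply_receptor_update(m0, "healthy_ec", "VEGFR1", 2110)
  sim0 <- simulate_model(m0, dose_schedule(amount = 0), n_out = 2)
  free <- sim0$ss[paste0("R.", m0$pairs$pair)]
  expect_true(all(abs(free - m0$pairs$s / cfg$k_int) <=
                    0.001 * pmax(m0$pairs$s / cfg$k_int, 1e-12)))
})

test_that("closed-compartment binding equilibrium matches the quadratic", {
  cfg <- default_model_config()
  cfg$secretion[] <- 0
  cfg$clearance_vegf <- 0; cfg$clearance_drug <- 0
  cfg$perm_flow[] <- 0; cfg$lymph_flow[] <- 0
  cfg$gag_sites[] <- 0
  cfg$k_int <- 0
  m <- vegf_model(cfg)
  V0 <- 100; R0 <- 40
  Kd <- cfg$koff[["VEGFR1"]] / cfg$kon[["VEGFR1"]]
  init <- c(V.diseased = V0, R.tumor.VEGFR1 = R0)
  sim <- simulate_model(m, dose_schedule(amount = 0, horizon = 1e6),
                        init = init, steady_state = FALSE, n_out = 5)
  expect_equal(sim$free_vegf$diseased[5],
               oracle_binding_equilibrium(V0, R0, Kd),
               tolerance = 1e-3)
})

test_that("zero sources give an identically zero VEGF trajectory", {
  cfg <- default_model_config()
  cfg$secretion[] <- 0
  m <- vegf_model(cfg)
  sim <- simulate_model(m, dose_schedule(amount = 1000, horizon = 1e5),
                        steady_state = FALSE, n_out = 5)
  expect_true(all(abs(sim$states[, c("V.normal", "V.blood", "V.diseased")]) < 1e-12))
})

test_that("an anti-VEGF bolus is mass-conservative and effective", {
  m <- vegf_model()
  sim <- simulate_model(m, dose_schedule())
  # nonnegativity of every species at every output time
  expect_true(all(sim$states >= 0))
  # treatment lowers diseased free VEGF from its pre-injection steady state
  last <- nrow(sim$free_vegf)
  expect_lt(sim$free_vegf$diseased[last], sim$ss[["V.diseased"]])
  # total drug (free + complexed, volume-weighted) never increases after t=0
  vol <- m$config$volumes
  total_drug <- sim$states[, "A.normal"] * vol[["normal"]] +
    sim$states[, "A.blood"] * vol[["blood"]] +
    sim$states[, "A.diseased"] * vol[["diseased"]] +
    sim$states[, "C.normal"] * vol[["normal"]] +
    sim$states[, "C.blood"] * vol[["blood"]] +
    sim$states[, "C.diseased"] * vol[["diseased"]]
  expect_true(all(diff(total_drug) <= 1e-6 * total_drug[1]))
})

test_that("fold change arithmetic and normalization behave as defined", {
  fake <- function(pre, post) {
    structure(list(
      ss = c(V.normal = pre[1], V.blood = pre[2], V.diseased = pre[3]),
      free_vegf = data.frame(time = c(0, 1), normal = c(pre[1], post[1]),
                             blood = c(pre[2], post[2]),
                             diseased = c(pre[3], post[3])),
      dose = dose_schedule(amount = 1, horizon = 1)
    ), class = "simulation_result")
  }
  sim <- fake(c(50, 50, 50), c(41, 60, 50))
  fc <- fold_change(sim)
  expect_equal(fc$fc, c(-0.18, 0.2, 0))
  norm <- fold_change(sim, sim)
  expect_equal(norm$fc_normalized, c(1, 1, NaN))
  expect_error(fold_change(fake(c(0, 1, 1), c(1, 1, 1))), "undefined")
})

test_that("steady-state free VEGF is monotone in the local receptor level", {
  grid <- c(500, 2000, 8000, 32000)
  m <- vegf_model()
  ss <- vapply(grid, function(level) {
    mi <- apply_receptor_update(m, "tumor_cell", "VEGFR1", level)
    simulate_model(mi, dose_schedule(amount = 0), n_out = 2)$ss[["V.diseased"]]
  }, numeric(1))
  expect_true(all(diff(ss) < 0))
})

test_that("sensitivity_scan tabulates one fold change per grid point", {
  m <- vegf_model()
  control <- simulate_model(m, dose_schedule())
  grid <- c(1e-15, 1e-14)
  scan <- sensitivity_scan(m, "insertion_rate", grid, pair = "tec_ab.VEGFR1",
                           control_sim = control)
  expect_equal(nrow(scan), length(grid) * 3)
  expect_equal(sort(unique(scan$value)), grid)
  expect_true(all(c("compartment", "pre", "post", "fc", "fc_normalized")
                  %in% names(scan)))
  expect_error(sensitivity_scan(m, "insertion_rate", 1e-14), "pair")
  expect_error(sensitivity_scan(m, "no_such_rate", 1), "unknown")
})
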