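# Workflow layer: experiment planning, the end-to-end pipeline, report
# serialization and crossover validation.

test_that("the experiment plan starts at SFL* = 1 and the branches preserve it", {
  powder <- powder_from_material(ref_mats$pvpva, 0.865)
  n0 <- rpm_to_hz(200)
  plan <- plan_experiments(powder, ref_geom, start_speed = n0)
  start <- plan[plan$branch == "start", ]
  expect_equal(kg_h_to_kg_s(start$mass_flow_kg_h),
               max_mass_flow(powder, ref_geom, n0))
  low1 <- plan[plan$branch == "low_power" & plan$step == 2L, ]
  expect_equal(low1$screw_speed_rpm, 200 * 2 / 3)
  expect_equal(low1$mass_flow_kg_h, start$mass_flow_kg_h * 2 / 3)
  # every set-point in the plan fills the feeding section exactly
  expect_equal(
    sfl_star(kg_h_to_kg_s(plan$mass_flow_kg_h), powder, ref_geom,
             rpm_to_hz(plan$screw_speed_rpm)),
    rep(1, nrow(plan)))
})

test_that("the pipeline equals the manual composition of its stages", {
  key <- "sol"
  powder_true <- powder_from_material(ref_mats[[key]], ref_slip[[key]])
  slip_pts <- simulate_feeding_experiments(powder_true, ref_geom,
                                           rpm_to_hz(seq(50, 400, by = 50)))
  obs <- simulate_autogenic_campaign(make_scenario(key))
  speeds <- rpm_to_hz(c(150, 300, 450))
  rep_ <- run_sios2(slip_pts, obs, ref_mats[[key]], ref_geom, speeds)

  # manual composition, stage by stage
  s_hat <- as.numeric(fit_slip(slip_pts, powder_from_material(ref_mats[[key]], 0),
                               ref_geom))
  powder_hat <- powder_from_material(ref_mats[[key]], s_hat)
  fit_hat <- fit_autogenic(obs, ref_geom, ref_mats[[key]])
  pred_hat <- predict_operating_point(speeds, fit_hat, ref_mats[[key]],
                                      ref_geom, sfl_max(powder_hat, ref_geom))
  expect_equal(rep_$slip, s_hat)
  expect_equal(rep_$sfl_max, sfl_max(powder_hat, ref_geom))
  expect_equal(rep_$fit$tau_extruder, fit_hat$tau_extruder)
  expect_equal(as.data.frame(rep_$predictions), as.data.frame(pred_hat))
  # and the report reproduces the scenario ground truth (noiseless inputs)
  tr <- truth_for(key)
  expect_equal(rep_$slip, ref_slip[[key]], tolerance = 1e-12)
  expect_equal(rep_$fit$tau_extruder, tr$tau, tolerance = 1e-9)
})

test_that("reports round-trip through JSON without loss of the fitted numbers", {
  obs <- simulate_autogenic_campaign(make_scenario("pvpva"))
  powder_true <- powder_from_material(ref_mats$pvpva, 0.865)
  slip_pts <- simulate_feeding_experiments(powder_true, ref_geom,
                                           rpm_to_hz(c(100, 200, 300)))
  rep_ <- run_sios2(slip_pts, obs, ref_mats$pvpva, ref_geom,
                    rpm_to_hz(c(200, 400)))
  path <- withr::local_tempfile(fileext = ".json")
  write_sios2_report(rep_, path)
  back <- read_sios2_report(path)
  expect_s3_class(back, "sios2_report")
  expect_equal(back$slip, rep_$slip)
  expect_equal(back$sfl_max, rep_$sfl_max)
  expect_equal(back$fit$tau_extruder, rep_$fit$tau_extruder)
  expect_equal(back$fit$s_extruder, rep_$fit$s_extruder)
  expect_equal(as.data.frame(back$predictions),
               as.data.frame(rep_$predictions))
})

test_that("a campaign entirely below the speed threshold fails loudly, never silently", {
  obs <- simulate_autogenic_campaign(
    make_scenario("pvpva", speeds = rpm_to_hz(c(40, 60, 80))))
  powder_true <- powder_from_material(ref_mats$pvpva, 0.865)
  slip_pts <- simulate_feeding_experiments(powder_true, ref_geom,
                                           rpm_to_hz(c(100, 200)))
  expect_error(
    run_sios2(slip_pts, obs, ref_mats$pvpva, ref_geom, rpm_to_hz(200)),
    "autogenic fitting failed")
})

test_that("schema violations in input files name the missing column", {
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(screw_speed_rpm = c(100, 200), x = 1:2),
                   bad, row.names = FALSE)
  expect_error(read_autogenic_csv(bad), "mass_flow_kg_h")
  expect_error(read_feeding_csv(bad), "max_mass_flow_kg_h")
})

test_that("crossover validation compares per point and uses the target's own bulk density", {
  donors <- c("pvpva", "sol"); target <- "bbma"
  fits <- lapply(donors, function(k) {
    fit_autogenic(simulate_autogenic_campaign(make_scenario(k)), ref_geom,
                  ref_mats[[k]])
  })
  donor_slip <- mean(ref_slip[donors])
  target_obs <- simulate_autogenic_campaign(make_scenario(target))
  xo <- crossover_validation(fits, donor_slip, target_obs,
                             ref_mats[[target]], ref_geom)
  expect_identical(nrow(xo), nrow(target_obs))
  expect_equal(xo$delta_T,
               xo$melt_temperature_pred - xo$melt_temperature_meas)
  # mass-flow prediction: donor slip with the target's bulk density
  expect_equal(
    xo$mass_flow_pred,
    max_mass_flow(powder_from_material(ref_mats[[target]], donor_slip),
                  ref_geom, target_obs$n))
  expect_equal(unique(round(xo$rel_delta_mass_flow, 12)),
               round((1 - donor_slip) / (1 - ref_slip[[target]]) - 1, 12))
})
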