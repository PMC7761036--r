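test_that("polymer templates emit the expected linkage stoichiometry", {
  # homogalacturonan of DP 100: one non-reducing terminus per chain
  hg <- template_hg(dp = 100)
  expect_equal(hg[["t-GalAp"]], 0.01)
  expect_equal(hg[["4-GalAp"]], 0.99)

  # alternating RG-I backbone at branch fraction 0.5: 2-Rhap = 2,4-Rhap
  rgi <- template_rgi(branch_fraction = 0.5)
  expect_equal(rgi[["2-Rhap"]], rgi[["2,4-Rhap"]])
  expect_equal(rgi[["4-GalAp"]], 0.5)

  # infinite cellulose is pure 4-Glcp
  ce <- template_cellulose()
  expect_equal(ce, c("4-Glcp" = 1))

  # XXXG repeat: 1 unbranched to 3 branched backbone glucoses
  xg <- template_xyloglucan(gal_fraction = 0)
  expect_equal(xg[["4,6-Glcp"]] / xg[["4-Glcp"]], 3)
  expect_equal(xg[["t-Xylp"]] / xg[["4-Glcp"]], 3)

  # every template sums to 1
  for (tpl in default_templates()) expect_equal(sum(tpl), 1)
})

test_that("simulated walls mix templates on the molar simplex", {
  wall <- generate_cell_wall(c(HG = 40, CE = 60), templates = list(
    HG = template_hg(100), CE = template_cellulose()))
  got <- stats::setNames(wall$molar_mean, wall$linkage)
  expect_equal(unname(got["4-Glcp"]), 60)
  expect_equal(unname(got["4-GalAp"]), 40 * 0.99)
  expect_equal(unname(got["t-GalAp"]), 40 * 0.01)
  expect_lt(abs(sum(wall$molar_mean) - 100), 1e-9)
  expect_error(generate_cell_wall(c(HG = 50)), "sum to 100")
  expect_error(generate_cell_wall(c(NOPE = 100)), "template")
})

test_that("noise is compositional, seed-stable and unbiased", {
  wall <- generate_cell_wall(c(HG = 30, CE = 50, AB = 20))
  # cv = 0 reproduces the input exactly
  clean <- add_noise(wall, cv = 0, n_replicates = 3, seed = 1)
  for (r in clean) expect_equal(r$molar_mean, wall$molar_mean)
  # same seed, same replicates
  a <- add_noise(wall, cv = 0.05, n_replicates = 3, seed = 99)
  b <- add_noise(wall, cv = 0.05, n_replicates = 3, seed = 99)
  expect_identical(lapply(a, `[[`, "molar_mean"),
                   lapply(b, `[[`, "molar_mean"))
  # each replicate still sums to 100
  for (r in a) expect_lt(abs(sum(r$molar_mean) - 100), 1e-9)
  # replicate means converge on the truth (3 standard errors at n = 100)
  many <- add_noise(wall, cv = 0.05, n_replicates = 100, seed = 7)
  vals <- sapply(many, `[[`, "molar_mean")
  for (i in seq_len(nrow(vals))) {
    se <- stats::sd(vals[i, ]) / sqrt(ncol(vals))
    expect_lt(abs(mean(vals[i, ]) - wall$molar_mean[i]), 3 * se + 1e-9)
  }
})

test_that("fractionation conserves mass and recreates the known enrichment", {
  comp <- c("RG-I" = 15, HG = 25, CE = 35, XG = 15, HX = 10)
  sim <- generate_fractionation(comp)
  expect_equal(attr(sim$yields, "total_yield"), 100)
  expect_equal(sum(sim$class_masses), 100)
  # pectic galacturonan dominates the chelator/carbonate extract,
  # cellulosic glucose the residue
  top_linkage <- function(p) p$linkage[which.max(p$molar_mean)]
  expect_equal(top_linkage(sim$profiles[["EDTA+Na2CO3"]]), "4-GalAp")
  expect_equal(top_linkage(sim$profiles[["Residue"]]), "4-Glcp")

  # identity matrix: each class wholly in its own fraction
  E <- diag(3)
  rownames(E) <- c("HG", "CE", "CA"); colnames(E) <- c("f1", "f2", "f3")
  pure <- generate_fractionation(c(HG = 20, CE = 30, CA = 50), extraction = E)
  expect_equal(pure$profiles[["f2"]]$linkage, "4-Glcp")
  expect_equal(pure$profiles[["f3"]]$linkage, "3-Glcp")
  expect_equal(pure$yields$yield_pct, c(20, 30, 50))

  bad <- default_extraction_matrix()
  bad["CE", ] <- c(0.5, 0.5, 0.5)
  expect_error(generate_fractionation(comp, extraction = bad),
               "summing to 1")
})

test_that("antibody plates respond linearly and reproduce under a seed", {
  abundance <- cbind(AO = c(HG = 50, XG = 50))
  affinity <- rbind(JIM5 = c(HG = 0, XG = 0))
  panel <- data.frame(mab_id = "JIM5", epitope_group = "HG backbone")
  # zero affinity: every reading is exactly the background
  plate <- generate_antibody_plate(abundance, affinity, panel,
                                   background = 0.07, noise_sd = 0, seed = 1)
  expect_true(all(plate$od == 0.07))
  expect_true(all(subtract_background(plate)$od == 0))

  affinity2 <- rbind(JIM5 = c(HG = 1, XG = 0))
  p1 <- generate_antibody_plate(abundance, affinity2, panel, noise_sd = 0.02,
                                seed = 42)
  p2 <- generate_antibody_plate(abundance, affinity2, panel, noise_sd = 0.02,
                                seed = 42)
  expect_identical(p1$od, p2$od)

  # dilution factors halve the signal, not the background
  p4 <- generate_antibody_plate(abundance, affinity2, panel, background = 0.1,
                                noise_sd = 0, n_dilutions = 2, seed = 1)
  d1 <- p4$od[p4$dilution == 1][1]; d2 <- p4$od[p4$dilution == 2][1]
  expect_equal(d1 - 0.1, 2 * (d2 - 0.1), tolerance = 1e-12)
})

test_that("simulated growth presets classify as designed", {
  curves <- generate_growth_curves(noise_sd = 0, seed = 1)
  curves <- lapply(curves, subtract_blank)
  ctrl <- curves[["glucose"]]
  expect_equal(classify_growth(curves[["NSP-moderate"]], ctrl)$label,
               "high-efficiency")
  expect_equal(classify_growth(curves[["NSP-low"]], ctrl)$label, "low")
  expect_equal(classify_growth(curves[["MM"]], ctrl)$label, "none")

  # zero growth rate keeps the curve flat at the inoculum density
  flat <- generate_growth_curves(data.frame(condition = "x", max_od = 1,
                                            rate = 0, od0 = 0.01),
                                 noise_sd = 0, seed = 1)[["x"]]
  expect_equal(unique(subtract_blank(flat)$od600), 0.01)

  noisy1 <- generate_growth_curves(noise_sd = 0.01, seed = 8)
  noisy2 <- generate_growth_curves(noise_sd = 0.01, seed = 8)
  expect_identical(noisy1[["glucose"]]$od600, noisy2[["glucose"]]$od600)
})

test_that("zero-noise round trips recover the true composition exactly", {
  comp <- c(AB = 12, "AG-I" = 4, "AG-II/ET" = 6, HX = 8, XG = 14, CA = 5,
            CE = 25, "RG-I" = 8, HG = 15, HM = 3)
  wall <- generate_cell_wall(comp)
  est <- estimate_polysaccharides(wall)
  got <- stats::setNames(est$molar_percent, est$class)
  expect_equal(got[names(comp)], comp, tolerance = 1e-9)
  expect_equal(unname(got["UA"]), 0, tolerance = 1e-12)
})
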