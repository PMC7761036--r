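make_array <- function(od, background = NULL, dilution = 1L, replicate = 1L,
                       extract = "AO") {
  df <- data.frame(
    mab_id = "LM19", epitope_group = "HG backbone",
    extract = extract, replicate = replicate, dilution = dilution, od = od
  )
  if (!is.null(background)) df$background <- background
  antibody_array(df)
}

test_that("background subtraction floors at zero and is idempotent", {
  arr <- make_array(od = c(0.8, 0.05, 0.1), background = 0.1,
                    replicate = 1:3)
  out <- subtract_background(arr)
  expect_equal(out$od, c(0.7, 0, 0))
  # already-corrected arrays pass through unchanged
  again <- subtract_background(out)
  expect_equal(again$od, out$od)
  expect_match(paste(attr(out, "log"), collapse = " "), "per-cell")
})

test_that("background modes: scalar, per-probe, per-extract", {
  df <- data.frame(
    mab_id = rep(c("LM19", "LM15"), each = 2),
    epitope_group = rep(c("HG backbone", "xyloglucan"), each = 2),
    extract = rep(c("AO", "SC"), 2),
    od = c(0.5, 0.6, 0.7, 0.8)
  )
  arr <- antibody_array(df)
  expect_equal(subtract_background(arr, 0.1)$od, c(0.4, 0.5, 0.6, 0.7))
  per_probe <- subtract_background(arr, c(LM19 = 0.1, LM15 = 0.2))
  expect_equal(per_probe$od, c(0.4, 0.5, 0.5, 0.6))
  per_extract <- subtract_background(arr, c(AO = 0.5, SC = 0.0))
  expect_equal(per_extract$od, c(0.0, 0.6, 0.2, 0.8))
  expect_error(subtract_background(arr), "background")
  expect_error(subtract_background(arr, c(nope = 1)), "match")
})

test_that("replicate averaging keeps counts and single wells pass through", {
  arr <- make_array(od = c(0.2, 0.4, 0.6), replicate = 1:3)
  avg <- average_replicates(arr)
  expect_equal(nrow(avg), 1)
  expect_equal(avg$od, 0.4)
  expect_equal(avg$n_rep, 3)

  one <- average_replicates(make_array(0.33))
  expect_equal(one$od, 0.33)
  expect_equal(one$n_rep, 1)

  flat <- average_replicates(make_array(rep(0.3, 3), replicate = 1:3))
  expect_equal(flat$od, 0.3)
})

test_that("dilution series collapse by max, mean or a named dilution", {
  arr <- make_array(od = c(0.1, 0.2, 0.4, 0.3), dilution = 1:4)
  expect_equal(collapse_dilutions(arr, "max")$od, 0.4)
  expect_equal(collapse_dilutions(arr, "mean")$od, 0.25)
  expect_equal(collapse_dilutions(arr, "2")$od, 0.2)
  expect_error(collapse_dilutions(arr, "9"), "not present")
  # single dilution: unchanged under any mode
  single <- make_array(0.5)
  expect_equal(collapse_dilutions(single, "max")$od, 0.5)
  expect_equal(collapse_dilutions(single, "mean")$od, 0.5)
})

test_that("averaging replicates commutes with mean-collapsing dilutions", {
  df <- expand.grid(replicate = 1:3, dilution = 1:4)
  df$mab_id <- "LM19"; df$epitope_group <- "HG backbone"; df$extract <- "AO"
  withr::with_seed(3, df$od <- stats::runif(nrow(df)))
  arr <- antibody_array(df)
  a <- collapse_dilutions(average_replicates(arr), "mean")
  b <- average_replicates(collapse_dilutions(arr, "mean"))
  expect_equal(a$od, b$od, tolerance = 1e-12)
})

test_that("heatmaps order rows by epitope group and columns by extract series", {
  df <- expand.grid(mab_id = c("B1", "A2", "C3", "D4"),
                    extract = c("4M KOH", "AO"), stringsAsFactors = FALSE)
  groups <- c(B1 = "xylan", A2 = "xylan", C3 = "RG-I", D4 = "RG-I")
  df$epitope_group <- groups[df$mab_id]
  df$od <- seq(0.1, 0.8, 0.1)
  arr <- antibody_array(df, group_order = c("RG-I", "xylan"))
  hm <- build_heatmap(arr)
  expect_equal(rownames(hm), c("C3", "D4", "A2", "B1"))
  expect_equal(colnames(hm), c("AO", "4M KOH"))  # ELISA series order
  expect_equal(unname(attr(hm, "groups")), c("RG-I", "RG-I", "xylan", "xylan"))

  # permuting input rows leaves the matrix unchanged
  perm <- antibody_array(df[sample(nrow(df)), ],
                         group_order = c("RG-I", "xylan"))
  expect_identical(build_heatmap(perm), hm)

  # values are the corrected means, no hidden normalisation
  expect_equal(hm["B1", "AO"], df$od[df$mab_id == "B1" & df$extract == "AO"])

  expect_error(build_heatmap(arr, group_order = "xylan"), "unknown")
  expect_error(build_heatmap(make_array(c(0.1, 0.2), replicate = 1:2)),
               "average")
})

test_that("synthetic plates put the maximum where affinity says", {
  abundance <- cbind("EDTA+Na2CO3" = c(HG = 80, CE = 20),
                     "Residue" = c(HG = 5, CE = 95))
  affinity <- rbind(JIM5 = c(HG = 1.0, CE = 0),
                    CBM3a = c(HG = 0, CE = 0.8))
  panel <- data.frame(mab_id = c("JIM5", "CBM3a"),
                      epitope_group = c("HG backbone", "cellulose"))
  plate <- generate_antibody_plate(abundance, affinity, panel,
                                   background = 0.05, noise_sd = 0,
                                   n_replicates = 3, seed = 5)
  hm <- build_heatmap(collapse_dilutions(average_replicates(
    subtract_background(plate)), "max"))
  expect_gt(hm["JIM5", "EDTA+Na2CO3"], hm["JIM5", "Residue"])
  expect_gt(hm["CBM3a", "Residue"], hm["CBM3a", "EDTA+Na2CO3"])
  # linear response: corrected OD proportional to abundance
  expect_equal(hm["JIM5", "EDTA+Na2CO3"], 0.80, tolerance = 1e-9)
  expect_equal(hm["CBM3a", "Residue"], 0.95 * 0.8, tolerance = 1e-9)
})

test_that("probes cannot sit in two epitope groups", {
  df <- data.frame(mab_id = c("X", "X"), epitope_group = c("a", "b"),
                   extract = "AO", od = c(0.1, 0.2))
  expect_error(antibody_array(df), "more than one epitope group")
})
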