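test_that("galacturonan backbone splits by rhamnose stoichiometry", {
  # no rhamnose: all 4-GalAp is homogalacturonan
  p <- linkage_profile("4-GalAp", 100)
  est <- estimate_composition(allocate_linkages(p))
  expect_equal(est$molar_percent[est$class == "HG"], 100)
  expect_equal(est$molar_percent[est$class == "RG-I"], 0)

  # alternating backbone pairs one GalA with each Rha; the rest is HG.
  # amounts 10/5/40/2 scaled onto the 100% simplex
  s <- 100 / 57
  p2 <- linkage_profile(c("2-Rhap", "2,4-Rhap", "4-GalAp", "t-GalAp"),
                        c(10, 5, 40, 2) * s)
  est2 <- estimate_composition(allocate_linkages(p2))
  expect_equal(est2$molar_percent[est2$class == "RG-I"], 30 * s)
  expect_equal(est2$molar_percent[est2$class == "HG"], 27 * s)
  expect_equal(est2$molar_percent[est2$class == "UA"], 0)
})

test_that("backbone glucose feeds xyloglucan by the XXXG ratio, rest cellulose", {
  s <- 100 / 28
  p <- linkage_profile(c("4-Glcp", "4,6-Glcp", "t-Xylp", "2-Xylp"),
                       c(10, 9, 6, 3) * s, fraction = "AIR")
  m <- allocate_linkages(p)
  # 4-Glcp row: XG gets 9/3 = 3, CE the remaining 7
  expect_equal(m["4-Glcp", "XG"], 3 * s)
  expect_equal(m["4-Glcp", "CE"], 7 * s)

  # same profile in a cellulose-suppressed fraction: remainder joins XG
  p_edta <- linkage_profile(c("4-Glcp", "4,6-Glcp", "t-Xylp", "2-Xylp"),
                            c(10, 9, 6, 3) * s, fraction = "EDTA+Na2CO3")
  m_edta <- allocate_linkages(p_edta)
  expect_equal(m_edta["4-Glcp", "CE"], 0)
  expect_equal(m_edta["4-Glcp", "XG"], 10 * s)
})

test_that("glucomannan claims backbone glucose before cellulose", {
  p <- linkage_profile(c("4-Glcp", "4-Manp", "4,6-Manp", "t-Galp"),
                       c(40, 30, 10, 20))
  m <- allocate_linkages(p)
  expect_equal(m["4-Glcp", "HM"], 10)   # 30 * 1/3
  expect_equal(m["4-Glcp", "CE"], 30)
  # t-Galp: only HM has demand (4,6-Manp = 10); AG-II and XG have none
  expect_equal(m["t-Galp", "HM"], 20)
})

test_that("shared terminals split in proportion to branch-point demand", {
  # t-Araf between arabinan (2,5-Araf demand 10) and heteroxylan
  # (3,4-Xylp demand 5): 2:1 split
  p <- linkage_profile(c("t-Araf", "2,5-Araf", "5-Araf", "3,4-Xylp", "4-Xylp"),
                       c(15, 10, 40, 5, 30))
  m <- allocate_linkages(p)
  expect_equal(m["t-Araf", "AB"], 10)
  expect_equal(m["t-Araf", "HX"], 5)
  # doubly-branched xylan counts twice in the demand
  p2 <- linkage_profile(c("t-Araf", "2,5-Araf", "2,3,4-Xylp", "4-Xylp"),
                        c(20, 10, 5, 65))
  m2 <- allocate_linkages(p2)
  expect_equal(m2["t-Araf", "AB"], 20 * 10 / 20)
  expect_equal(m2["t-Araf", "HX"], 20 * 10 / 20)
})

test_that("zero demand falls back to the first candidate in table order", {
  p <- linkage_profile("t-Araf", 100)
  m <- allocate_linkages(p)
  expect_equal(m["t-Araf", "AB"], 100)  # AB is the first t-Araf row
  p2 <- linkage_profile(c("t-Galp", "4-Xylp"), c(10, 90))
  m2 <- allocate_linkages(p2)
  expect_equal(m2["t-Galp", "AG-II/ET"], 10)
})

test_that("unmapped linkages land in UA and conservation holds row-wise", {
  p <- linkage_profile(c("2-Glcp", "4-Galp"), c(4, 96))
  m <- allocate_linkages(p)
  expect_equal(m["2-Glcp", "UA"], 4)
  est <- estimate_composition(m)
  expect_equal(est$molar_percent[est$class == "UA"], 4)
  expect_equal(est$molar_percent[est$class == "AG-I"], 96)
})

test_that("allocation conserves every row over random profiles", {
  vocab <- c(table1_vocabulary(), "2-Glcp", "6-Glcp", "3-Manp")
  withr::with_seed(7, {
    for (i in 1:100) {
      frac <- sample(c("AIR", "EDTA+Na2CO3", "4M KOH", "Residue"), 1)
      p <- random_profile(vocab, fraction = frac)
      m <- allocate_linkages(p)
      expect_lt(max(abs(rowSums(m) - p$molar_mean)), 1e-9)
      expect_true(all(m >= 0))
      est <- estimate_composition(m)
      expect_lt(abs(sum(est$molar_percent) - sum(p$molar_mean)), 1e-9)
    }
  })
})

test_that("more rhamnose weakly moves galacturonan from HG into RG-I", {
  prev_rgi <- -Inf; prev_hg <- Inf
  for (rha in c(0, 10, 25, 40)) {
    amounts <- c("2-Rhap" = rha, "4-GalAp" = 50)
    filler <- 100 - sum(amounts)
    p <- linkage_profile(c(names(amounts), "5-Araf"), c(amounts, filler))
    est <- estimate_composition(allocate_linkages(p))
    rgi <- est$molar_percent[est$class == "RG-I"]
    hg <- est$molar_percent[est$class == "HG"]
    expect_gte(rgi, prev_rgi)
    expect_lte(hg - 1e-12, prev_hg)
    prev_rgi <- rgi; prev_hg <- hg
  }
})

test_that("three-pass allocation agrees with the brute-force oracle", {
  vocab <- table1_vocabulary()
  withr::with_seed(11, {
    for (i in 1:200) {
      frac <- sample(c("AIR", "EDTA+Na2CO3", "4M KOH", "Residue"), 1)
      p <- random_profile(vocab, n_linkages = sample(1:6, 1), fraction = frac)
      est <- estimate_composition(allocate_linkages(p))
      got <- stats::setNames(est$molar_percent, est$class)
      want <- oracle_allocate(stats::setNames(p$molar_mean, p$linkage),
                              fraction = frac)
      expect_equal(got[names(want)], want, tolerance = 1e-9)
    }
  })
})

test_that("fraction comparisons produce a fixed-order long table", {
  p1 <- linkage_profile("4-GalAp", 100, fraction = "EDTA+Na2CO3")
  p2 <- linkage_profile("4-Glcp", 100, fraction = "Residue")
  comps <- list(estimate_polysaccharides(p1), estimate_polysaccharides(p2))
  rep <- compare_fractions(comps)
  expect_equal(nrow(rep), 22)  # 11 classes x 2 fractions
  expect_equal(levels(rep$class),
               c("AB", "AG-I", "AG-II/ET", "HX", "XG", "CA", "CE", "RG-I",
                 "HG", "HM", "UA"))
  expect_error(compare_fractions(list(comps[[1]], comps[[1]])), "duplicate")

  one <- compare_fractions(comps[1])
  expect_equal(one$molar_percent[one$class == "HG"], 100)
})

test_that("pectin-enriched and residue fractions order RG-I+HG vs CE as expected", {
  comp <- c("RG-I" = 20, HG = 30, CE = 40, XG = 10)
  sim <- generate_fractionation(comp)
  ests <- lapply(names(sim$profiles), function(f) {
    estimate_polysaccharides(sim$profiles[[f]], fraction = f)
  })
  names(ests) <- names(sim$profiles)
  pectin_sum <- function(est) sum(est$molar_percent[est$class %in%
                                                      c("RG-I", "HG")])
  ce_of <- function(est) est$molar_percent[est$class == "CE"]
  expect_gt(pectin_sum(ests[["EDTA+Na2CO3"]]), pectin_sum(ests[["Residue"]]))
  expect_gt(ce_of(ests[["Residue"]]), ce_of(ests[["EDTA+Na2CO3"]]))
})
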