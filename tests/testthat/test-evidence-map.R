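test_that("cross_tabulate matches a hand tally and declares empty cells", {
  ds <- toy_dataset()
  grid <- cross_tabulate(ds, "intervention", "outcome")
  # schema: intervention {CM, PSM} x outcome {QoL, AQLQ, Unknown}
  expect_equal(nrow(grid), 6)
  cell <- function(r, c) grid[grid$row_level == r & grid$col_level == c, ]
  expect_equal(cell("CM", "QoL")$n_studies, 1)      # s1
  expect_equal(cell("CM", "QoL")$n_effects, 1)
  expect_equal(cell("PSM", "QoL")$n_studies, 1)     # s2 twice
  expect_equal(cell("PSM", "QoL")$n_effects, 2)
  expect_equal(cell("CM", "Unknown")$n_effects, 1)  # s3's missing outcome
  expect_equal(cell("PSM", "AQLQ")$n_effects, 0)    # a gap, still present
  # conservation: every effect lands in exactly one cell
  expect_equal(sum(grid$n_effects), nrow(ds$effects))
  expect_error(cross_tabulate(ds, "bogus", "outcome"), "available")
})

test_that("a study spanning cells is counted in each cell's n_studies", {
  ds <- toy_dataset()  # s1 contributes to (CM,QoL) and (CM,AQLQ)
  grid <- cross_tabulate(ds, "intervention", "outcome")
  expect_equal(sum(grid$n_studies), 4)  # 3 distinct studies, s1 counted twice
  expect_gte(sum(grid$n_studies), dplyr::n_distinct(ds$effects$study_id))
})

test_that("pool_cells matches subset-refit oracles and passthrough rules", {
  ds <- toy_dataset()
  grid <- pool_cells(cross_tabulate(ds, "intervention", "outcome"), ds,
                     method = "fixed_gls", rho = 0.5)
  eff <- ds$effects
  filled <- grid[grid$n_effects > 0, ]
  for (i in seq_len(nrow(filled))) {
    inn <- eff$intervention == filled$row_level[i] &
           eff$outcome == filled$col_level[i]
    if (sum(inn) == 1) {
      expect_equal(filled$estimate[i], eff$yi[inn])
      expect_equal(filled$se[i], sqrt(eff$vi[inn]))
    } else {
      V <- build_vcv(eff$vi[inn], cluster = eff$study_id[inn], rho = 0.5)
      orc <- oracle_gls(eff$yi[inn], unclass(V))
      expect_equal(filled$estimate[i], orc$estimate, tolerance = 1e-10)
      expect_equal(filled$se[i], orc$se, tolerance = 1e-10)
    }
  }
  # empty cells report no estimate
  expect_true(all(is.na(grid$estimate[grid$n_effects == 0])))
})

test_that("a constant-effect cell pools to the constant", {
  eff <- tibble::tibble(
    study_id = c("s1", "s2", "s3"), effect_id = paste0("e", 1:3),
    yi = 0.5, vi = 0.04, g1 = "A", g2 = "B")
  ds <- evimap_dataset(eff)
  grid <- pool_cells(cross_tabulate(ds, "g1", "g2"), ds)
  expect_equal(grid$estimate, 0.5)
})

test_that("pooling the whole dataset as a 1x1 grid equals direct pooling", {
  ds <- toy_dataset()
  ds$effects$all1 <- "x"; ds$effects$all2 <- "y"
  ds <- evimap_dataset(ds$effects, moderators = c("intervention", "outcome",
                                                  "all1", "all2"))
  grid <- pool_cells(cross_tabulate(ds, "all1", "all2"), ds,
                     method = "robust", rho = 0.5)
  eff <- ds$effects
  direct <- robust_variance(eff$yi,
                            build_vcv(eff$vi, cluster = eff$study_id,
                                      rho = 0.5))
  expect_equal(grid$estimate, direct$estimate, tolerance = 1e-12)
  expect_equal(grid$se, direct$se, tolerance = 1e-12)
})

test_that("alluvial flows enumerate label tuples and conserve marginals", {
  ds <- toy_dataset()
  fl <- alluvial_flows(ds, c("intervention", "outcome"))
  expect_equal(sum(fl$n), nrow(ds$effects))
  # hand enumeration of the toy tuples
  key <- paste(fl$intervention, fl$outcome)
  expect_setequal(key, c("CM QoL", "CM AQLQ", "PSM QoL", "CM Unknown"))
  expect_equal(fl$n[key == "PSM QoL"], 2)
  # per-axis marginals agree across axes
  for (ax in c("intervention", "outcome")) {
    marg <- tapply(fl$n, fl[[ax]], sum)
    expect_equal(sum(marg), nrow(ds$effects))
  }
  expect_error(alluvial_flows(ds, "intervention"), "cross_tabulate")

  # perfectly aligned labels give diagonal flows only
  eff <- tibble::tibble(study_id = "s", effect_id = paste0("e", 1:6),
                        yi = 0, vi = 1,
                        a = rep(c("x", "y", "z"), 2),
                        b = rep(c("x2", "y2", "z2"), 2))
  fl2 <- alluvial_flows(evimap_dataset(eff), c("a", "b"))
  expect_equal(nrow(fl2), 3)
})

test_that("three-moderator flows match hand enumeration", {
  eff <- tibble::tibble(
    study_id = "s", effect_id = paste0("e", 1:4), yi = 0, vi = 1,
    a = c("a1", "a1", "a2", "a2"), b = c("b1", "b1", "b1", "b2"),
    c = c("c1", "c2", "c1", "c1"))
  fl <- alluvial_flows(evimap_dataset(eff), c("a", "b", "c"))
  expect_equal(nrow(fl), 4)
  expect_true(all(fl$n == 1))
})

test_that("geo_counts tallies countries from the bibliography", {
  ds <- toy_dataset()
  bib <- toy_bibliography()
  bib$paper_id <- c("s1", "s2", "s3")
  ds$bibliography <- bib
  gc <- geo_counts(ds, source = "bibliography")
  # US: s1 (2 effects) + s2 (2 effects); GB: s2 + s3
  expect_equal(gc$n_studies[gc$country == "US"], 2)
  expect_equal(gc$n_effects[gc$country == "US"], 4)
  expect_equal(gc$n_studies[gc$country == "GB"], 2)
  expect_equal(gc$n_effects[gc$country == "GB"], 3)
  # first-country attribution drops s2's GB
  gc1 <- geo_counts(ds, source = "bibliography", countries = "first")
  expect_equal(gc1$n_studies[gc1$country == "GB"], 1)
  # moderator source
  ds$effects$where <- c("US", "US", "DE", "DE", "DE")
  ds2 <- evimap_dataset(ds$effects,
                        moderators = c("intervention", "outcome", "where"),
                        bibliography = bib)
  gc2 <- geo_counts(ds2, source = "moderator", moderator = "where")
  expect_equal(gc2$n_effects[gc2$country == "DE"], 3)
  expect_error(geo_counts(toy_dataset()), "bibliography")
})
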