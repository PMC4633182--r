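# identification engine: printed discriminant registry and the 19-couplet key

test_that("printed-function evaluation matches independent hand arithmetic", {
  f <- printed_functions()[["D3_lichtensteini_laconicus"]]
  expect_equal(evaluate_discriminant(f, c(PoOC = 0, FRS = 0, SPST = 0)),
               3.3108, tolerance = 1e-9)
  expect_equal(evaluate_discriminant(f, c(PoOC = 200, FRS = 190, SPST = 185)),
               1.1093, tolerance = 1e-9)
  expect_equal(evaluate_discriminant("D4_crassispinus_crasecundus",
                                     c(SL = 430, SPST = 180, SPL = 95, SPWI = 190)),
               -0.5314, tolerance = 1e-9)
  # printed spelling variant of the postocular distance is accepted
  expect_equal(evaluate_discriminant(f, c(POC = 200, FRS = 190, SPST = 185)),
               1.1093, tolerance = 1e-9)
})

test_that("unknown ids and missing traits produce named errors", {
  expect_error(evaluate_discriminant("D9_nope", base_traits()), "unknown printed function")
  expect_error(evaluate_discriminant("D3_lichtensteini_laconicus",
                                     c(PoOC = 200, FRS = 190)), "SPST")
})

test_that("sign rule, published bands and ties drive classification", {
  r1 <- classify_by_function("D4_crassispinus_crasecundus",
                             c(SL = 430, SPST = 180, SPL = 95, SPWI = 190))
  expect_equal(r1$taxon, "crassispinus")

  # a specimen scoring +3.085 sits inside the laconicus 5-95% band
  f <- printed_functions()[["D3_lichtensteini_laconicus"]]
  spst <- (3.085 - 3.3108 + 0.0498 * 200 + 0.0541 * 190) / 0.0975
  r2 <- classify_by_function(f, c(PoOC = 200, FRS = 190, SPST = spst))
  expect_equal(r2$taxon, "laconicus")
  expect_equal(r2$band, "inside")

  # an exactly zero score is a tie with no class
  f0 <- discriminant_function("tiebreak", c(SPST = 1), -170, "x", "y")
  r3 <- classify_by_function(f0, c(SPST = 170))
  expect_true(r3$tie)
  expect_true(is.na(r3$taxon))
})

test_that("every printed group mean lies on its own side of the sign rule", {
  for (fn in printed_functions()) {
    if (!inherits(fn, "discriminant_function")) next
    for (i in seq_len(nrow(fn$stats))) {
      side <- if (fn$stats$mean[i] < 0) fn$negative_classes else fn$positive_classes
      expect_true(fn$stats$class[i] %in% side,
                  label = paste(fn$id, fn$stats$class[i]))
    }
  }
})

test_that("registry coefficients match the frozen printed values", {
  reg <- printed_functions()
  expect_equal(reg$D7_sordidulus_tergestinus$coefficients,
               c(SPTI = 0.0323, NOL = -0.0594, SL = 0.0859, ML = -0.0490,
                 CWb = 0.0867, EL = -0.1167, CL = -0.0414))
  expect_equal(reg$D7_sordidulus_tergestinus$intercept, -1.2164)
  expect_equal(reg$D2_subtilis_helenae$coefficients,
               c(SPST = -0.0928, ML = 0.0215))
  expect_equal(reg$D4_artvinensis_pool$intercept, 3.69209)
  expect_equal(length(reg) - 1L, 11L)   # 11 linear functions + 1 quick ratio
})

test_that("the quick FRS/SL ratio separates the narrow-frons species from its pool", {
  qd <- printed_functions()$FRS_SL_angustifrons
  r <- classify_by_ratio(qd, c(FRS = 200, SL = 500))   # 0.40
  expect_equal(r$taxon, "angustifrons")
  expect_equal(r$band, "inside")
  r2 <- classify_by_ratio(qd, 0.47)
  expect_equal(r2$taxon, "lucidus/similis/subtilis")
})

test_that("key couplet thresholds match the published values", {
  key <- nylanderi_key()
  expected <- list(`3` = c("SPST/CS", 0.384), `4` = c("SPST/CS", 0.219),
                   `5` = c("PoOC/NOH", 2.678), `6` = c("SPST/CS", 0.283),
                   `7` = c("FRS/CS", 0.334), `8` = c("ML/CS", 1.228),
                   `9` = c("SPST/CL", 0.294), `10` = c("PEH/CS", 0.402),
                   `11` = c("CL/CWb", 1.179), `13` = c("PL/CS", 0.422),
                   `14` = c("SPBA/CWb", 0.30), `15` = c("NOL/CS", 0.251),
                   `16` = c("SPBA/CS", 0.283), `17` = c("SPST/CS", 0.262),
                   `18` = c("PoOC/CL", 0.375))
  for (id in names(expected)) {
    cpl <- key$couplets[[paste0("#", id)]]
    expect_equal(cpl$feature, expected[[id]][1], label = paste("couplet", id))
    expect_equal(cpl$threshold, as.numeric(expected[[id]][2]),
                 label = paste("couplet", id))
  }
  expect_true(key$couplets[["#11"]]$range_no_unreliable)
  expect_equal(key$couplets[["#2"]]$threshold, 28.5)
  expect_equal(key$couplets[["#2"]]$threshold2, 30)
})

test_that("worked key paths follow the published couplets", {
  r1 <- classify_key(c(antennomere_count = 11))
  expect_equal(r1$taxon, "flavicornis")
  expect_equal(r1$path, 1)

  r2 <- classify_key(c(`SPST/CS` = 0.40), spine_angle_deg = 22)
  expect_equal(r2$taxon, "laconicus")
  expect_equal(r2$path, c(1, 2, 3))

  r3 <- classify_key(c(`SPST/CS` = 0.18), spine_angle_deg = 40)
  expect_equal(r3$taxon, "subtilis")
  expect_equal(r3$path, c(1, 2, 4))
})

test_that("missing features and threshold ties are surfaced, never guessed", {
  expect_error(classify_key(c(`SPST/CS` = 0.40)), "couplet 2.*spine_angle_deg")
  # exact threshold value at couplet 3 is a tie
  r <- classify_key(c(`SPST/CS` = 0.384), spine_angle_deg = 22)
  expect_true(r$tie)
  expect_true(is.na(r$taxon))
  # the printed dead zone between 28.5 and 30 degrees is ambiguous
  r2 <- classify_key(c(`SPST/CS` = 0.4), spine_angle_deg = 29)
  expect_true(r2$tie)
  # region needed at couplet 12
  expect_error(classify_key(c(`SPST/CS` = 0.25, `PoOC/NOH` = 2.4,
                              `SPST/CL` = 0.24, `CL/CWb` = 1.25),
                            spine_angle_deg = 45), "couplet 12.*region")
})

test_that("every species profile keys out to its own leaf (all leaves reachable)", {
  p <- species_profiles()
  keyed <- vapply(seq_len(nrow(p)), function(i) {
    pp <- p[i, ]
    cs <- pp$cs_mean; q <- pp$CL.CWb_mean
    tr <- c(CL = 2 * cs * q / (1 + q), CWb = 2 * cs / (1 + q))
    tr["PoOC"] <- pp$PoOC.CL_mean * tr[["CL"]]
    for (t in setdiff(trait_names(), c("CL", "CWb", "PoOC")))
      tr[t] <- pp[[paste0(t, "_mean")]] * cs
    classify_key(tr, antennomere_count = pp$antennomere_count,
                 spine_angle_deg = (pp$spine_angle_lo + pp$spine_angle_hi) / 2,
                 region = pp$region)$taxon
  }, "")
  expect_equal(keyed, p$species)
  # all 18 leaves are reached across these inputs
  expect_setequal(unique(keyed), p$species)
})

test_that("nest-level identification reports taxa and errors per nest", {
  d <- generate_morph_data(species_profiles()[c(6, 7), ], nests_per_species = 3,
                           workers_per_nest = 3, sd_scale = 0.3, seed = 3)
  nests <- aggregate_nests(d)
  out <- identify_nests(nests)
  expect_equal(nrow(out), 6)
  truth <- vapply(out$nest_id, function(id) unique(d$species[d$nest_id == id]), "")
  expect_equal(out$taxon, unname(truth))
})

test_that("single-specimen mode carries the reliability caveat", {
  r <- classify_key(c(antennomere_count = 11), single_specimen = TRUE)
  expect_match(r$caveat, "95")
})
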