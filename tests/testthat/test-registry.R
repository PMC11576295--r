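test_that("default registry matches the four-instrument pool structure", {
  reg <- default_registry()
  expect_s3_class(reg, "ipv_registry")
  expect_equal(nrow(reg), 47L)
  counts <- table(reg$instrument)
  expect_equal(as.vector(counts[c("MHC-SF", "PERMA", "FS", "WBCF")]),
               c(14L, 15L, 8L, 10L))
  facet_counts <- tapply(reg$item_id, paste(reg$instrument, reg$facet), length)
  expect_equal(as.vector(facet_counts[paste("MHC-SF", c("EWB", "SWB", "PWB"))]),
               c(3L, 5L, 6L))
  expect_true(all(facet_counts[paste("PERMA", c("P", "E", "R", "M", "A"))] == 3L))
  expect_equal(as.vector(facet_counts[c("FS FS", "WBCF PC", "WBCF PF")]),
               c(8L, 6L, 4L))
  expect_equal(reg$item_id[reg$reverse], "WBCF-PC-2")
  expect_false(anyDuplicated(reg$item_id) > 0)
  # response scales per instrument
  expect_true(all(reg$max_code[reg$instrument == "MHC-SF"] == 5L))
  expect_true(all(reg$max_code[reg$instrument == "PERMA"] == 10L))
  expect_true(all(reg$min_code[reg$instrument == "FS"] == 1L &
                  reg$max_code[reg$instrument == "FS"] == 7L))
  expect_setequal(reg$max_code[reg$instrument == "WBCF"],
                  c(4L, 3L, 10L))
})

test_that("registry configs load from YAML and JSON and validate", {
  cfg <- list(
    `MHC-SF` = list(EWB = list(items = 3, range = c(0, 5))),
    FS = list(FS = list(items = 2, range = c(1, 7))),
    WBCF = list(PC = list(items = c("WBCF-PC-1", "WBCF-PC-2"),
                          range = list(c(0, 4), c(0, 3)),
                          reverse = "WBCF-PC-2")))
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  reg <- load_registry(yml)
  expect_equal(nrow(reg), 7L)
  expect_equal(reg$item_id[reg$instrument == "MHC-SF"],
               paste0("MHC-SF-EWB-", 1:3))
  expect_equal(reg$item_id[reg$instrument == "FS"], c("FS-1", "FS-2"))
  expect_equal(reg$max_code[reg$item_id == "WBCF-PC-2"], 3L)
  expect_true(reg$reverse[reg$item_id == "WBCF-PC-2"])

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE)
  expect_equal(load_registry(jsn)$item_id, reg$item_id)

  # duplicate item id across facets
  bad <- cfg
  bad$FS$FS$items <- c("FS-1", "FS-1")
  yaml::write_yaml(bad, yml)
  expect_error(load_registry(yml), "duplicate")
  # item without range
  bad <- cfg; bad$FS$FS$range <- NULL
  yaml::write_yaml(bad, yml)
  expect_error(load_registry(yml), "range")
  # unknown instrument
  bad <- cfg; names(bad)[2] <- "NOTASCALE"
  yaml::write_yaml(bad, yml)
  expect_error(load_registry(yml), "unknown instrument")
})

test_that("response validation enforces range, completeness and recodes", {
  reg <- toy_registry()
  ok <- data.frame(`FS-1` = c(1L, 7L), `FS-2` = c(4L, 4L), `FS-3` = c(2L, 5L),
                   `WBCF-PC-1` = c(0L, 4L), `WBCF-PC-2` = c(0L, 3L),
                   check.names = FALSE)
  v <- validate_responses(ok, reg)
  expect_true(attr(v, "validated"))
  # boundary values accepted; reverse item recoded max + min - x
  expect_equal(v[["WBCF-PC-2"]], c(4L, 1L))
  # out of range
  bad <- ok; bad[["FS-1"]][1] <- 8L
  expect_error(validate_responses(bad, reg), "out-of-range")
  bad <- ok; bad[["WBCF-PC-1"]][2] <- -1L
  expect_error(validate_responses(bad, reg), "out-of-range")
  # missing cell / unknown and absent columns
  bad <- ok; bad[["FS-2"]][1] <- NA
  expect_error(validate_responses(bad, reg), "missing cells")
  expect_error(validate_responses(cbind(ok, junk = 1), reg), "unknown column")
  expect_error(validate_responses(ok[, -1], reg), "missing item")
})

test_that("reverse-coding is an involution", {
  reg <- default_registry()
  set.seed(4)
  raw <- as.data.frame(lapply(seq_len(nrow(reg)), function(i)
    sample(reg$min_code[i]:reg$max_code[i], 20, replace = TRUE)))
  names(raw) <- reg$item_id
  expect_equal(recode_reversed(recode_reversed(raw, reg), reg), raw)
  expect_false(identical(recode_reversed(raw, reg), raw))
})

test_that("subscale composites are item means, standardized on demand", {
  reg <- toy_registry()
  # constant maximum response: composite at scale max, SD 0
  dat <- data.frame(`FS-1` = rep(7L, 5), `FS-2` = rep(7L, 5),
                    `FS-3` = rep(7L, 5), `WBCF-PC-1` = c(0:4),
                    `WBCF-PC-2` = c(4L, 3L, 2L, 1L, 0L), check.names = FALSE)
  sc <- score_subscales(validate_responses(dat, reg), reg,
                        standardize_items = FALSE)
  fs_row <- sc$summary[sc$summary$facet == "FS.FS", ]
  expect_equal(fs_row$M, 7)
  expect_equal(fs_row$SD, 0)
  # hand oracle: composites are row means of the facet's items
  dat2 <- data.frame(`FS-1` = c(1L, 4L, 7L), `FS-2` = c(2L, 5L, 6L),
                     `FS-3` = c(3L, 6L, 5L), `WBCF-PC-1` = c(0L, 2L, 4L),
                     `WBCF-PC-2` = c(1L, 2L, 3L), check.names = FALSE)
  v <- validate_responses(dat2, reg)
  sc2 <- score_subscales(v, reg, standardize_items = FALSE)
  expect_equal(unname(sc2$composites[["FS.FS"]]), c(2, 5, 6))
  expect_equal(unname(sc2$composites[["WBCF.PC"]]),
               rowMeans(cbind(c(0, 2, 4), c(3, 2, 1))))
  # z-scored items average to mean ~ 0 across the sample
  sc3 <- score_subscales(v, reg, standardize_items = TRUE)
  expect_lt(abs(mean(sc3$composites[["WBCF.PC"]])), 1e-12)
  # zero-variance item cannot be standardized
  expect_error(score_subscales(validate_responses(dat, reg), reg,
                               standardize_items = TRUE), "zero-variance")
})

test_that("mixed-range facets default to standardized composites", {
  cc <- default_sim()
  reg <- cc$pop$registry
  dat <- validate_responses(cc$sim$responses, reg)
  sc <- score_subscales(dat, reg)  # per-facet default
  # WBCF facets mix 0-4/0-3/0-10 scales -> z-scored -> mean ~ 0
  expect_lt(abs(mean(sc$composites[["WBCF.PC"]])), 1e-10)
  # raw-scale facets keep their metric
  expect_true(mean(sc$composites[["FS.FS"]]) > 1)
  tab <- reliability_table(dat, reg)
  expect_equal(nrow(tab), 11L)
  # weak facets (low-loading items) are less internally consistent by
  # construction, but every facet coheres and strong facets strongly so
  expect_true(all(tab$alpha > 0.25))
  expect_gt(tab$alpha[tab$facet == "PERMA.P"], 0.75)
})

test_that("cronbach alpha matches closed forms and is shift/order invariant", {
  # two equal-variance items at sample r = 0.5: Spearman-Brown 2r/(1+r) = 2/3
  xy <- exact_corr_pair(n = 60, r = 0.5, seed = 2)
  expect_equal(cronbach_alpha(xy)$alpha, 2 * 0.5 / 1.5, tolerance = 1e-12)
  # identical columns -> alpha 1
  x <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(x, x, x))$alpha, 1, tolerance = 1e-12)
  # empirically uncorrelated equal-variance items -> alpha 0
  xy0 <- exact_corr_pair(n = 60, r = 0, seed = 3)
  expect_equal(cronbach_alpha(xy0)$alpha, 0, tolerance = 1e-12)
  # invariances
  set.seed(5)
  m <- matrix(rnorm(200), 50, 4) + rnorm(50)
  a0 <- cronbach_alpha(m)$alpha
  m2 <- m; m2[, 2] <- m2[, 2] + 100
  expect_equal(cronbach_alpha(m2)$alpha, a0, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m[, c(3, 1, 4, 2)])$alpha, a0, tolerance = 1e-12)
  # guards
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]), ">= 2 items")
  expect_error(cronbach_alpha(cbind(c(1, 1, 1), c(2, 2, 2))), "variance")
})

test_that("correlation matrix is symmetric, unit-diagonal and PSD", {
  set.seed(6)
  x <- matrix(rnorm(500), 100, 5) + rnorm(100)
  colnames(x) <- letters[1:5]
  r <- correlation_matrix(x)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_equal(unname(correlation_matrix(cbind(a = x[, 1], b = -x[, 1]))[1, 2]),
               -1)
  # hand-computed Pearson r on a 5-point toy table:
  # deviations (-2,-1,0,1,2) and (-1,-2,1,0,2): cov = 2, both vars 2.5
  toy <- cbind(p = c(1, 2, 3, 4, 5), q = c(2, 1, 4, 3, 5))
  expect_equal(unname(correlation_matrix(toy)[1, 2]), 0.8, tolerance = 1e-12)
  expect_error(correlation_matrix(cbind(a = x[1:5, 1], b = rep(1, 5))),
               "zero-variance")
})
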