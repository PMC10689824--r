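test_that("packaged fixture loads with 8 validated site means", {
  fx <- table1_fixture()
  expect_s3_class(fx, "gradient_dataset")
  expect_identical(fx$level, "site_mean")
  expect_equal(nrow(fx$samples), 8L)
  expect_setequal(unique(fx$samples$soil_type),
                  c("basalt", "shale", "ironstone", "sandstone"))
  expect_true(all(table(fx$samples$soil_type) == 2))
  # fertility grouping follows parent material
  expect_identical(
    fx$samples$fertility_class,
    ifelse(fx$samples$soil_type %in% c("basalt", "shale"),
           "fertile", "infertile"))
})

test_that("loader accepts an empty table and rejects invariant violations", {
  tmp <- tempfile(fileext = ".csv")
  df <- tiny_samples()
  utils::write.csv(df[0, ], tmp, row.names = FALSE)
  empty <- load_gradient_csv(tmp, "replicate")
  expect_equal(nrow(empty$samples), 0L)

  bad <- df; bad$nlfa_c[2] <- -1
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_gradient_csv(tmp, "replicate"), "row 2.*nlfa_c")

  bad <- df; bad$fertility_class <- c("infertile", "fertile")
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_gradient_csv(tmp, "replicate"), "fertility_class")

  bad <- df; bad$plfa_bacterial[1] <- 70
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_gradient_csv(tmp, "replicate"), "plfa_total")

  utils::write.csv(df[, setdiff(names(df), "mbc")], tmp, row.names = FALSE)
  expect_error(load_gradient_csv(tmp, "replicate"), "missing mandatory.*mbc")
})

test_that("write/read round trip preserves values exactly", {
  ds <- generate_gradient(gradient_config(seed = 11))
  tmp <- tempfile(fileext = ".csv")
  write_gradient_csv(ds, tmp)
  back <- load_gradient_csv(tmp, "replicate")
  for (nm in names(ds$samples)) {
    expect_equal(back$samples[[nm]], ds$samples[[nm]], tolerance = 1e-12,
                 label = nm)
  }
  expect_true(file.exists(sub("\\.csv$", ".json", tmp)))
})

test_that("derived indices match direct arithmetic", {
  expect_equal(mbc_from_flush(100), 264)
  expect_equal(mbc_from_flush(0), 0)
  # inverse of the basalt site-mean MBC under the standard factor
  expect_equal(mbc_from_flush(209.5), 553.08)
  expect_error(mbc_from_flush(-1), "non-negative")

  expect_equal(per_soc_normalise(22.3, 0.0428), 521.0, tolerance = 1e-3)
  expect_equal(per_soc_normalise(0, 0.04), 0)
  expect_equal(per_soc_normalise(20.5, 0.0162), 1265.4, tolerance = 1e-3)
  expect_error(per_soc_normalise(1, 0), "> 0")

  expect_equal(cp_mass_to_molar(29.4), 75.95)
  expect_equal(cp_mass_to_molar(0), 0)
  expect_equal(cp_mass_to_molar(78.7), 203.3, tolerance = 1e-3)

  expect_equal(fungal_bacterial_ratio(9.5, 42.7), 0.2225, tolerance = 1e-3)
  expect_equal(fungal_bacterial_ratio(5, 5), 1)
  expect_equal(fungal_bacterial_ratio(3.5, 7.0), 0.5)
  expect_error(fungal_bacterial_ratio(1, 0), "> 0")
})

test_that("per_soc_normalise and cp_mass_to_molar are homogeneous of degree 1", {
  for (k in c(0.5, 2, 10)) {
    expect_equal(per_soc_normalise(k * 7.3, 0.021),
                 k * per_soc_normalise(7.3, 0.021))
    expect_equal(cp_mass_to_molar(k * 13.7), k * cp_mass_to_molar(13.7))
  }
})

test_that("summarise_range reports fixture extremes with attaining sites", {
  fx <- table1_fixture()
  nl <- summarise_range(fx, "nlfa_c", "max")
  expect_equal(nl$value, 22.3)
  expect_equal(nl$sample_id, "basalt_1")
  tn <- summarise_range(fx, "total_n", "min")
  expect_equal(tn$value, 750)
  expect_equal(tn$sample_id, "ironstone_1")
  one <- gradient_dataset(tiny_samples()[1, ], "replicate")
  expect_equal(summarise_range(one, "mbc", "min")$value,
               summarise_range(one, "mbc", "max")$value)
  expect_equal(summarise_range(one, "mbc", "mean")$value, 550)
  expect_error(summarise_range(fx, "no_such_field", "max"), "unknown field")
})

test_that("storage fraction of MBC matches row arithmetic and fixture-wide mean", {
  fx <- table1_fixture()
  fr <- storage_fraction_of_mbc(fx)
  expect_equal(fr[fx$samples$sample_id == "basalt_1"],
               (22.3 + 33.4 + 0.9) / 553, tolerance = 1e-12)
  expect_equal(fr[fx$samples$sample_id == "ironstone_2"],
               (18.4 + 30.0 + 12.5) / 186, tolerance = 1e-12)
  # community storage averages ~20% of microbial biomass C across sites
  expect_gt(mean(fr), 0.15)
  expect_lt(mean(fr), 0.25)
  z <- tiny_samples(); z$nlfa_c <- z$phb_c <- z$trehalose_c <- 0
  expect_equal(storage_fraction_of_mbc(z), c(0, 0))
  # missing trehalose counts as zero storage
  z2 <- tiny_samples(); z2$trehalose_c <- NA_real_
  expect_equal(storage_fraction_of_mbc(z2),
               (z2$nlfa_c + z2$phb_c) / z2$mbc)
})

test_that("fungal:bacterial PLFA contrast between fertility classes is 2-3 fold", {
  fx <- table1_fixture()
  fb <- fungal_bacterial_ratio(sample = fx$samples)
  infert <- fx$samples$fertility_class == "infertile"
  fold <- mean(fb[infert]) / mean(fb[!infert])
  expect_gte(fold, 2)
  expect_lte(fold, 3)
})
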