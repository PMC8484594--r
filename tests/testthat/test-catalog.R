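test_that("default catalog reproduces the study's attribute space", {
  cat5 <- build_catalog()
  expect_s3_class(cat5, "attribute_catalog")
  expect_length(cat5, 5)
  expect_length(cat5$producer$levels, 5)
  expect_length(cat5$endorser$levels, 6)
  expect_length(cat5$distributor$levels, 3)
  expect_length(cat5$uptake$levels, 5)
  expect_setequal(cat5$efficacy_shown$levels, c("yes", "unspecified"))
  # baselines: unspecified for producer/efficacy/uptake, medical
  # association for endorser, health system for distributor
  expect_identical(cat5$producer$baseline, "unspecified")
  expect_identical(cat5$uptake$baseline, "unspecified")
  expect_identical(cat5$endorser$baseline, "medical_association")
  expect_identical(cat5$distributor$baseline, "healthcare_system")
  # trial efficacy rates per producer, none for the unspecified one
  expect_equal(cat5$producer$efficacy_map[["pfizer"]], 95)
  expect_equal(cat5$producer$efficacy_map[["gamaleya"]], 91)
  expect_false("unspecified" %in% names(cat5$producer$efficacy_map))
  # 19 treatment terms: 4 + 4 + 5 + 2 + 4
  expect_equal(nrow(catalog_terms(cat5)), 19)
})

test_that("catalog validation names the offending dimension", {
  bad <- default_catalog_config()
  bad$endorser$baseline <- "nobody"
  expect_error(build_catalog(bad), "endorser")
  bad2 <- default_catalog_config()
  bad2$uptake$levels <- c("1", "1", "50")
  expect_error(build_catalog(bad2), "duplicate")
  bad3 <- default_catalog_config()
  bad3$producer$efficacy_map <- c(pfizer = 95)
  expect_error(build_catalog(bad3), "efficacy_map")
  expect_error(build_catalog(list(bogus = list(levels = "x"))), "bogus")
})

test_that("omitting the unspecified producer removes its round constraint", {
  cfg <- default_catalog_config()
  cfg$producer$levels <- setdiff(cfg$producer$levels, "unspecified")
  cfg$producer$baseline <- "pfizer"
  cfg$producer$unspecified_level <- NULL
  cat4 <- build_catalog(cfg)
  expect_length(cat4$producer$levels, 4)
  expect_setequal(levels_available(cat4, "producer", 2),
                  levels_available(cat4, "producer", 1))
})

test_that("a relabeled baseline is carried through to the terms", {
  cfg <- default_catalog_config()
  cfg$producer$baseline <- "sinovac"
  cat5 <- build_catalog(cfg)
  expect_identical(cat5$producer$baseline, "sinovac")
  tt <- catalog_terms(cat5)
  expect_false("producer_sinovac" %in% tt$term)
  expect_true("producer_unspecified" %in% tt$term)
})

test_that("catalogs round-trip through JSON and YAML files", {
  cfg <- default_catalog_config()
  jf <- tempfile(fileext = ".json")
  cfg_json <- lapply(cfg, function(d) {
    for (f in c("efficacy_map", "display", "probs")) {
      if (!is.null(d[[f]])) d[[f]] <- as.list(d[[f]])
    }
    d
  })
  jsonlite::write_json(cfg_json, jf, auto_unbox = TRUE)
  yf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg_json, yf)
  cj <- read_catalog(jf)
  cy <- read_catalog(yf)
  ref <- build_catalog()
  for (cc in list(cj, cy)) {
    expect_identical(cc$producer$levels, ref$producer$levels)
    expect_identical(cc$endorser$baseline, ref$endorser$baseline)
    expect_equal(cc$producer$efficacy_map, ref$producer$efficacy_map)
  }
  expect_error(read_catalog(tempfile(fileext = ".txt")), "not found")
})

test_that("the shipped default catalog file matches the built-in default", {
  path <- system.file("extdata", "default_catalog.json",
                      package = "conjointvax")
  expect_true(nzchar(path))
  cc <- read_catalog(path)
  ref <- build_catalog()
  expect_identical(cc$producer$levels, ref$producer$levels)
  expect_identical(cc$uptake$levels, ref$uptake$levels)
  expect_equal(cc$producer$probs, ref$producer$probs)
})
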