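test_that("body surface area follows the DuBois power law", {
  expect_equal(body_surface_area(77, 176), 1.93, tolerance = 0.01)
  # weight power-law scaling at fixed height
  expect_equal(body_surface_area(4 * 70, 170) / body_surface_area(70, 170),
               4^0.425, tolerance = 1e-12)
  expect_error(body_surface_area(0, 170), class = "validation_error")
  expect_error(body_surface_area(70, -1), class = "validation_error")
})

test_that("ages outside the supported range are rejected", {
  expect_error(build_individual(0.5, "male"), class = "unsupported_age_error")
  expect_error(build_individual(101, "female"),
               class = "unsupported_age_error")
  expect_error(build_individual(30, "male", body_weight = 300, height = 150),
               class = "validation_error") # implausible BMI
})

test_that("individual construction is deterministic and self-consistent", {
  a <- build_individual(30, "male")
  b <- build_individual(30, "male")
  expect_identical(a, b)
  # organ volumes account for the body mass at ~1.05 kg/L tissue density
  expect_equal(sum(a$organs$total_volume), a$body_weight / 1.05,
               tolerance = 0.15)
})

test_that("physiological invariants hold across the age/sex sweep", {
  for (sex in c("male", "female")) {
    for (age in c(1, 2, 3.5, 5, 8, 10, 13, 15, 18, 25, 40, 60, 80, 100)) {
      ind <- build_individual(age, sex)
      org <- ind$organs
      expect_true(all(org$total_volume > 0), info = paste(sex, age))
      expect_true(all(org$plasma_flow > 0))
      expect_true(all(org$lymph_flow >= 0))
      # lymph drains a small fraction of each organ's perfusion
      expect_true(all(org$lymph_flow < org$plasma_flow +
                        1e-12), info = paste(sex, age))
      # sub-compartments fit inside the organ
      expect_true(all(org$vascular_volume + org$interstitial_volume +
                        org$endosomal_volume < org$total_volume))
      # organ plasma flows (lung excluded: in series) within cardiac
      # plasma output
      co_plasma <- ind$cardiac_output * (1 - ind$hematocrit)
      expect_lt(sum(org$plasma_flow[org$name != "lung"]), co_plasma)
      expect_equal(sum(org$total_volume), ind$body_weight / 1.05,
                   tolerance = 0.15)
      expect_true(ind$hematocrit > 0 && ind$hematocrit < 1)
    }
  }
})

test_that("reference body weight grows monotonically through childhood", {
  for (sex in c("male", "female")) {
    bw <- vapply(1:18, function(a) build_individual(a, sex)$body_weight, 0)
    expect_true(all(diff(bw) >= 0))
  }
})

test_that("population generation respects the spec and the seed", {
  spec <- population_spec(58, 0.67, c(20, 73), weight_range = c(50, 127),
                          height_range = c(151, 190), bmi_range = c(18, 50),
                          seed = 1)
  pop <- generate_population(spec)
  expect_length(pop, 58)
  for (p in pop) {
    expect_gte(p$age, 20); expect_lte(p$age, 73)
    expect_gte(p$body_weight, 50); expect_lte(p$body_weight, 127)
    expect_gte(p$height, 151); expect_lte(p$height, 190)
    bmi <- p$body_weight / (p$height / 100)^2
    expect_gte(bmi, 18); expect_lte(bmi, 50)
  }
  pop2 <- generate_population(spec)
  expect_identical(pop, pop2)
  expect_identical(generate_population(population_spec(0, seed = 1)),
                   list())
})

test_that("population moments match the sampling scheme", {
  pop <- generate_population(population_spec(400, 0.5, c(5, 9), seed = 9))
  ages <- vapply(pop, `[[`, 0, "age")
  # uniform age sampling: mean (5+9)/2, SE = width/sqrt(12 n)
  se <- 4 / sqrt(12 * 400)
  expect_lt(abs(mean(ages) - 7), 3 * se)
  sexes <- vapply(pop, `[[`, "", "sex")
  expect_lt(abs(mean(sexes == "male") - 0.5), 3 * sqrt(0.25 / 400))
  bw <- vapply(pop, `[[`, 0, "body_weight")
  ref <- (build_individual(7, "male")$body_weight +
            build_individual(7, "female")$body_weight) / 2
  expect_lt(abs(mean(bw) / ref - 1), 0.10)
})

test_that("infeasible anthropometric constraints raise an error", {
  spec <- population_spec(3, 1, c(30, 31), weight_range = c(30, 34),
                          height_range = c(180, 190), seed = 2)
  expect_error(generate_population(spec, max_attempts = 50),
               class = "infeasibility_error")
})

test_that("populations export to CSV with a JSON sidecar", {
  spec <- population_spec(4, 0.5, c(20, 40), seed = 3)
  pop <- generate_population(spec)
  path <- file.path(tempdir(), "pop.csv")
  df <- population_to_csv(pop, spec, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read.csv(path)
  expect_equal(nrow(back), 4)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 3)
  unlink(c(path, paste0(path, ".json")))
})
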