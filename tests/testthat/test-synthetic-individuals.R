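test_that("calibration closure: sample moments meet the targets at n = 1e5", {
  ind <- generate_individuals(100000, "overall", seed = 1)
  expect_equal(mean(ind$kcal_ssb), 46, tolerance = 0.5 / 46)
  expect_equal(mean(ind$bmi >= 25), 0.38, tolerance = 0.01 / 0.38)
  expect_equal(mean(ind$kcal_milk), 207, tolerance = 2 / 207)
  expect_true(all(ind$bmi >= 12 & ind$bmi <= 60))
  expect_true(all(ind$kcal_ssb >= 0))
  expect_equal(ind$bmi, ind$weight / ind$height^2, tolerance = 1e-12)
  # intake-BMI coupling has the configured rank correlation
  expect_equal(cor(ind$bmi, ind$kcal_ssb, method = "spearman"), 0.2,
               tolerance = 0.25)
})

test_that("generation is seed-reproducible and cohort labels honour the cell", {
  cell <- list(age = "25-44", sex = "F", income = "low", residence = "rural")
  a <- generate_individuals(500, cell, seed = 42)
  b <- generate_individuals(500, cell, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$sex == "F" & a$income == "low" & a$residence == "rural"))
})

test_that("a zero prevalence target yields no overweight individuals", {
  cal <- baseline_row("overall")
  cal$overweight_pct <- 0
  ind <- generate_individuals(5000, "overall", calibration = cal, seed = 2)
  expect_true(all(ind$bmi < 25))
})

test_that("infeasible prevalence targets are rejected", {
  expect_error(bmi_lognormal(1.2), "calibration error")
  expect_error(bmi_lognormal(-0.1), "calibration error")
})

test_that("cohort cells reproduce the overall margins exactly and span the design", {
  cells <- cohort_cells()
  expect_equal(nrow(cells), 24)
  expect_equal(sum(cells$weight), 1)
  expect_equal(sum(cells$weight * cells$overweight_pct), 38)
  expect_equal(sum(cells$weight * cells$diabetes_incidence), 307)
  expect_equal(sum(cells$weight * cells$ssb_kcal), 46)
  expect_equal(sum(cells$weight * cells$milk_kcal), 207)
  # full cross of the four margins
  expect_equal(nrow(unique(cells[, c("age", "sex", "income", "residence")])),
               24)
})
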