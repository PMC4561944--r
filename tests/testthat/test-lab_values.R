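test_that("blood-pressure dialects extract the printed values", {
  bp1 <- extract_blood_pressure("BP: 158/72")
  expect_equal(c(bp1$value, bp1$value2), c(158, 72))
  bp2 <- extract_blood_pressure("blood pressure 149/96")
  expect_equal(c(bp2$value, bp2$value2), c(149, 96))
  bp3 <- extract_blood_pressure("blood pressure elevated at 188/92")
  expect_equal(c(bp3$value, bp3$value2), c(188, 92))
})

test_that("range blood pressures keep the per-component maximum", {
  r <- extract_blood_pressure("120–130/88–92")
  expect_equal(c(r$value, r$value2), c(130, 92))
  r2 <- extract_blood_pressure("BP ranging 120-130/88-92 over the past month.")
  expect_equal(c(r2$value, r2$value2), c(130, 92))
})

test_that("implausible readings are discarded", {
  expect_equal(nrow(extract_blood_pressure("BP: 400/20")), 0L)
  expect_equal(nrow(extract_blood_pressure("no pressure documented")), 0L)
})

test_that("lipid and blood-test sentences yield one value per analyte", {
  lip <- extract_lipids(
    "lipid levels: total cholesterol 164, TG 145, HDL 33, and LDL 102")
  expect_equal(nrow(lip), 4L)
  expect_equal(lip$value[lip$kind == "TOTAL_CHOL"], 164)
  expect_equal(lip$value[lip$kind == "TG"], 145)
  expect_equal(lip$value[lip$kind == "HDL"], 33)
  expect_equal(lip$value[lip$kind == "LDL"], 102)
  expect_equal(extract_lipids("LDL 102")$value, 102)
  expect_equal(nrow(extract_lipids("lipids pending")), 0L)

  mb <- extract_misc_bloods("BUN is 27, creatinine is 4.7, and glucose is 79")
  expect_equal(mb$value[mb$kind == "BUN"], 27)
  expect_equal(mb$value[mb$kind == "CREATININE"], 4.7)
  expect_equal(mb$value[mb$kind == "GLUCOSE"], 79)
  expect_equal(extract_misc_bloods("A1c 8.2")$value, 8.2)
  expect_equal(nrow(extract_misc_bloods("glucose tolerance discussed")), 0L)
})

test_that("extraction is span-faithful", {
  txt <- "Exam notable for BP: 158/72 and BMI 33.1 today; A1c 8.2."
  vals <- extract_lab_values(txt)
  expect_gt(nrow(vals), 0L)
  for (i in seq_len(nrow(vals))) {
    slice <- text_slice(txt, vals$start[i], vals$end[i])
    expect_true(grepl(format(vals$value[i]), slice, fixed = TRUE))
  }
})

test_that("hypertension filter matches the brute-force threshold predicate", {
  grid <- expand.grid(s = seq(100L, 200L, by = 5L), d = seq(50L, 120L, by = 5L))
  for (i in seq_len(nrow(grid))) {
    s <- grid$s[i]; d <- grid$d[i]
    got <- filter_by_threshold(
      extract_blood_pressure(sprintf("BP: %d/%d", s, d)))
    expect_equal(nrow(got) == 1L, (s > 140) || (d > 90),
                 info = sprintf("%d/%d", s, d))
  }
})

test_that("filter promotion is monotone in the BP components", {
  base <- data.frame(kind = "BP", value = 150, value2 = 80, units = "mmHg",
                     start = 0L, end = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_threshold(base)), 1L)
  for (k in 1:20) {
    higher <- base
    higher$value <- base$value + sample.int(50L, 1L)
    higher$value2 <- base$value2 + sample.int(50L, 1L)
    expect_equal(nrow(filter_by_threshold(higher)), 1L)
  }
})

test_that("lab kinds map to their risk factors and irrelevant kinds drop", {
  th <- lab_thresholds()
  f <- filter_by_threshold(extract_blood_pressure("BP: 158/72"), th)
  expect_equal(f$risk_factor, "HYPERTENSION")
  expect_equal(f$indicator, "high blood pressure")
  expect_equal(nrow(filter_by_threshold(extract_blood_pressure("BP: 139/89"), th)), 0L)
  expect_equal(nrow(filter_by_threshold(extract_misc_bloods("glucose is 79"), th)), 0L)
  # BUN, creatinine, TG are never promoted however large
  never <- extract_misc_bloods("BUN is 270, creatinine is 40")
  never <- rbind(never, extract_lipids("TG 900"))
  expect_equal(nrow(filter_by_threshold(never, th)), 0L)
  a1c <- filter_by_threshold(extract_misc_bloods("A1c 8.2"), th)
  expect_equal(a1c$indicator, "high A1c")
  expect_equal(a1c$risk_factor, "DIABETES")
})

test_that("threshold configuration is validated", {
  expect_error(lab_thresholds(systolic_high = -1), "positive")
  custom <- lab_thresholds(ldl_high = 130)
  got <- filter_by_threshold(extract_lipids("LDL 120"), custom)
  expect_equal(nrow(got), 0L)
})
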