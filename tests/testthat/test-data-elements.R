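test_that("permitted value groups enforce their invariants", {
  g <- pvg("Size", "Size", c(large = "Large", medium = "Medium", small = "Small"))
  expect_s3_class(g, "regkit_pvg")
  expect_equal(g$values$code, c("large", "medium", "small"))
  expect_equal(nrow(g$values), 3)

  expect_error(pvg("Empty", "Empty", character()), class = "regkit_empty_pvg")
  expect_error(pvg("Dup", "Dup", c(a = "A", a = "A2")),
               class = "regkit_duplicate_value_code")
  expect_error(pvg("", "X", c(a = "A")), class = "regkit_bad_identifier")
})

test_that("element definitions accept the five datatypes and reject bad specs", {
  dob <- data_element("DOB", "Date of birth", "date")
  expect_equal(dob$datatype, "date")
  expect_false(dob$required)

  for (dt in c("integer", "float", "string", "date", "file")) {
    expect_s3_class(data_element(paste0("E", dt), datatype = dt), "regkit_de")
  }
  expect_error(data_element("B", datatype = "boolean"),
               class = "regkit_unknown_datatype")
  expect_error(data_element("Age", datatype = "integer", min = 10, max = 5),
               class = "regkit_bad_range")
  expect_error(data_element("Height", datatype = "float", pattern = "\\d+"),
               class = "regkit_bad_element")
  expect_error(data_element("S", datatype = "string", pattern = "a",
                            pvg_code = "Size"),
               class = "regkit_bad_element")
  expect_error(data_element("D", datatype = "date", min = 1),
               class = "regkit_bad_element")
  expect_error(data_element("S2", datatype = "string", pattern = "(unclosed"),
               class = "regkit_bad_element")
})

test_that("validate_value coerces, bounds and reports typed values", {
  age <- data_element("Age", datatype = "integer", min = 0, max = 120)
  tv <- validate_value(age, "42")
  expect_s3_class(tv, "regkit_typed_value")
  expect_identical(tv$value, 42)

  # integer coercion rejects fractional text
  res <- validate_value(age, "4.2")
  expect_false(is_valid_result(res))
  expect_equal(res[[1]]$rule, "type")

  res <- validate_value(age, "130")
  expect_equal(vapply(res, `[[`, character(1), "rule"), "range")

  # bounds are inclusive
  expect_true(is_valid_result(validate_value(age, "0")))
  expect_true(is_valid_result(validate_value(age, "120")))
})

test_that("pattern validation is anchored full-match (credit-card style)", {
  card <- data_element("Card", datatype = "string",
                       pattern = "\\d{4} \\d{4} \\d{4} \\d{4}")
  expect_true(is_valid_result(validate_value(card, "1234 5678 9012 3456")))
  res <- validate_value(card, "1234567890123456")
  expect_equal(res[[1]]$rule, "pattern")
  # substring matches must not pass
  expect_false(is_valid_result(validate_value(card, "x1234 5678 9012 3456x")))
})

test_that("PVG membership is enforced", {
  size <- pvg("Size", values = c(large = "Large", medium = "Medium", small = "Small"))
  de <- data_element("Sz", datatype = "string", pvg_code = "Size")
  expect_true(is_valid_result(validate_value(de, "medium", pvg = size)))
  res <- validate_value(de, "huge", pvg = size)
  expect_equal(res[[1]]$rule, "pvg")
})

test_that("dates use ISO-8601 and reject impossible calendar dates", {
  dob <- data_element("DOB", datatype = "date")
  tv <- validate_value(dob, "1980-06-15")
  expect_s3_class(tv$value, "Date")
  expect_equal(render_value(tv), "1980-06-15")
  for (bad in c("15/06/1980", "1980-13-01", "1980-02-30", "1980-6-5")) {
    expect_false(is_valid_result(validate_value(dob, bad)), label = bad)
  }
})

test_that("blank input: required elements complain, optional ones store nothing", {
  req <- data_element("R1", datatype = "string", required = TRUE)
  opt <- data_element("O1", datatype = "string")
  res <- validate_value(req, "")
  expect_equal(res[[1]]$rule, "required")
  expect_null(validate_value(opt, ""))
  expect_null(validate_value(opt, NULL))
})

test_that("render/validate round-trips typed values exactly", {
  set.seed(421)
  cases <- list(
    list(data_element("I", datatype = "integer", min = -1e6, max = 1e6),
         function() sample(-1e6:1e6, 1)),
    list(data_element("F", datatype = "float"),
         function() runif(1, -1e4, 1e4)),
    list(data_element("S", datatype = "string"),
         function() paste(sample(c(letters, " ", "-"), 12, TRUE), collapse = "")),
    list(data_element("D", datatype = "date"),
         function() as.Date("1940-01-01") + sample(0:30000, 1))
  )
  for (case in cases) {
    de <- case[[1]]
    for (i in 1:50) {
      v <- case[[2]]()
      tv <- validate_value(de, v)
      expect_true(is_valid_result(tv))
      back <- validate_value(de, render_value(tv))
      expect_identical(back$value, tv$value,
                       label = sprintf("%s round trip of %s", de$datatype,
                                       render_value(tv)))
    }
  }
})

test_that("validator agrees with an independent rule-checker on random input", {
  set.seed(99)
  eng <- registry_engine()
  for (i in 1:300) {
    de <- rand_element(eng)
    group <- if (!is.null(de$pvg_code)) eng$get_pvg(de$pvg_code) else NULL
    raw <- rand_raw(de, group)
    got <- validate_value(de, raw, pvg = group)
    expected <- oracle_violations(de, raw, pvg = group)
    if (length(expected) == 0) {
      expect_true(is_valid_result(got),
                  label = sprintf("%s (%s) should accept %s", de$code, de$datatype, raw))
    } else {
      expect_false(is_valid_result(got),
                   label = sprintf("%s (%s) should reject %s", de$code, de$datatype, raw))
      expect_setequal(vapply(got, `[[`, character(1), "rule"), unique(expected))
      # completeness: one error per independently violated rule
      expect_length(got, length(expected))
    }
  }
})

test_that("derived elements refuse entry validation and carry their inputs", {
  bmi <- derived_element("BMI", datatype = "float", expression = "W / (H * H)")
  expect_true(is_derived(bmi))
  expect_equal(bmi$inputs, c("H", "W"))
  expect_null(bmi$min)
  expect_error(validate_value(bmi, 30), class = "regkit_derived_readonly")
  expect_error(derived_element("X", datatype = "string", expression = "1"),
               class = "regkit_bad_element")
})
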