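test_that("csv loading marks missing tokens and types columns", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("a,b,y", "1,x,p", "NA,y,q", "3,z,p"), path)
  ds <- load_table(path, "csv")
  expect_equal(sum(ds$mask), 1)
  expect_true(ds$mask[2, "a"])
  expect_equal(attr_kind(ds)[["a"]], "numeric")
  expect_equal(attr_kind(ds)[["b"]], "categorical")
  expect_equal(class_attr(ds), "y")
})

test_that("csv parse -> serialize -> parse round-trips exactly", {
  df <- data.frame(a = c(1.5, NA, 3), b = c("u", "v", NA),
                   y = c("p", "q", "p"))
  ds1 <- load_table(tmp_csv(df), "csv")
  path2 <- tempfile(fileext = ".csv")
  write_table(ds1, path2)
  ds2 <- load_table(path2, "csv")
  expect_identical(ds1$values, ds2$values)
  expect_identical(ds1$mask, ds2$mask)
  expect_identical(ds1$schema, ds2$schema)
})

test_that("keel dialect reads declarations, outputs and ? tokens", {
  path <- tempfile(fileext = ".dat")
  writeLines(c(
    "@relation mammographic-style",
    "@attribute birads integer [1,6]",
    "@attribute age integer [18,96]",
    "@attribute shape integer [1,4]",
    "@attribute margin integer [1,5]",
    "@attribute density integer [1,4]",
    "@attribute severity integer [0,1]",
    "@inputs birads, age, shape, margin, density",
    "@outputs severity",
    "@data",
    "5,67,3,5,3,1",
    "4,43,1,?,?,1",
    "5,58,4,5,3,1"), path)
  ds <- load_table(path, "keel")
  expect_equal(length(predictor_attrs(ds)), 5)
  expect_equal(class_attr(ds), "severity")
  expect_true(all(attr_kind(ds) == "numeric"))
  expect_equal(sum(ds$mask), 2)
  expect_true(all(ds$mask[2, c("margin", "density")]))
})

test_that("malformed inputs raise categorized errors", {
  p1 <- tempfile(fileext = ".csv"); writeLines("a,b,y", p1)
  expect_error(load_table(p1, "csv"), "zero data rows")
  p2 <- tempfile(fileext = ".csv"); writeLines(c("a,a,y", "1,2,p"), p2)
  expect_error(load_table(p2, "csv"), "duplicate")
  p3 <- tempfile(fileext = ".dat")
  writeLines(c("@attribute a real [0,1]", "@attribute y {p,q}",
               "@outputs y", "@data", "oops,p"), p3)
  expect_error(load_table(p3, "keel"), "unparseable numeric")
})

test_that("label encoding is a bijection that preserves the mask", {
  df <- data.frame(c1 = c("a", "b", "a"), c2 = c("x", NA, "y"),
                   n1 = c(1, 2, 3), y = c("p", "q", "p"))
  ds <- dataset(df, class_attr = "y")
  enc <- encode_categoricals(ds)
  expect_equal(length(unique(enc$dataset$values$c1)), 2)
  expect_true(all(vapply(enc$dataset$values, is.numeric, logical(1))))
  expect_identical(enc$dataset$mask, ds$mask)
  expect_true(enc$dataset$mask[2, "c2"])
  dec <- decode_categoricals(enc$dataset, enc$codebook)
  expect_identical(dec$values, ds$values)
})

test_that("encoding a purely numeric dataset is the identity", {
  ds <- dataset(data.frame(a = 1:3, y = c(0, 1, 0)), class_attr = "y")
  enc <- encode_categoricals(ds)
  expect_identical(enc$dataset$values, ds$values)
  expect_length(enc$codebook, 0)
})

test_that("split_by_completeness partitions rows and preserves order", {
  df <- data.frame(a = 1:10, b = runif(10), y = rep(0:1, 5))
  df$a[c(2, 5, 10)] <- NA
  ds <- dataset(df, class_attr = "y")
  sp <- split_by_completeness(ds, "a")
  expect_equal(nrow(sp$train$values), 7)
  expect_equal(nrow(sp$test$values), 3)
  expect_equal(sp$test_rows, c(2, 5, 10))
  expect_equal(sort(c(sp$train_rows, sp$test_rows)), 1:10)
  # order preserved within parts
  expect_equal(sp$train$values$b, df$b[-c(2, 5, 10)])
  # fully observed target -> empty test part
  sp2 <- split_by_completeness(ds, "b")
  expect_equal(nrow(sp2$test$values), 0)
  expect_error(split_by_completeness(ds, "y"), "non-class")
})

test_that("the class attribute must be unique, named and complete", {
  df <- data.frame(a = c(1, NA), y = c(0, 1))
  expect_silent(dataset(df, class_attr = "y"))
  df$y[1] <- NA
  expect_error(dataset(df, class_attr = "y"), "class attribute")
  sch <- data.frame(name = c("a", "y"), kind = "numeric",
                    role = c("class", "class"))
  expect_error(dataset(data.frame(a = 1, y = 2), schema = sch),
               "exactly one")
})
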