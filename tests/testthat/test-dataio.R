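# Reading, writing and merging the supported tabular dialects.

test_that("a small tsv parses into the expected dataset", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2\tClass",
               "s1\t1.5\ta\tyes",
               "s2\t2.5\tb\tno",
               "s3\t3.5\ta\tyes"), path)
  d <- read_dataset(path)
  expect_s3_class(d, "cb_dataset")
  expect_equal(d$sample_ids, c("s1", "s2", "s3"))
  expect_equal(d$feature_names, c("f1", "f2"))
  expect_equal(d$feature_kinds, c("numeric", "categorical"))
  expect_equal(d$class_labels, c("yes", "no", "yes"))
  expect_equal(d$values$f1, c(1.5, 2.5, 3.5))
})

test_that("a table and its transposed dialect parse to identical datasets", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2\tClass",
               "s1\t1.5\ta\tyes",
               "s2\t2.5\tb\tno",
               "s3\t3.5\ta\tyes"), path)
  tpath <- withr::local_tempfile(fileext = ".tcsv")
  writeLines(c("feature,s1,s2,s3",
               "f1,1.5,2.5,3.5",
               "f2,a,b,a",
               "Class,yes,no,yes"), tpath)
  expect_equal(read_dataset(tpath), read_dataset(path))
})

test_that("missing tokens map to the canonical marker, including arff '?'", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f1,f2,Class",
               "s1,?,a,yes",
               "s2,2.5,NA,no",
               "s3,3.5,,yes"), path)
  d <- read_dataset(path)
  expect_true(is.na(d$values$f1[1]))
  expect_true(is.na(d$values$f2[2]))
  expect_true(is.na(d$values$f2[3]))
  expect_equal(d$feature_kinds, c("numeric", "categorical"))

  apath <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation test",
               "@attribute sample_id string",
               "@attribute f1 numeric",
               "@attribute Class {yes,no}",
               "@data",
               "s1,?,yes",
               "s2,2.0,no"), apath)
  a <- read_dataset(apath)
  expect_true(is.na(a$values$f1[1]))
  expect_equal(a$sample_ids, c("s1", "s2"))
  expect_equal(a$class_labels, c("yes", "no"))
})

test_that("read-write round trips are exact across all dialects", {
  withr::with_seed(101, {
    for (rep in 1:8) {
      d <- random_dataset(n = sample(3:8, 1), missing_rate = 0.15)
      for (ext in c("tsv", "csv", "ttsv", "tcsv", "arff", "tsv.gz", "arff.gz")) {
        path <- withr::local_tempfile(fileext = paste0(".", ext))
        write_dataset(d, path)
        expect_equal(read_dataset(path), d, label = ext)
      }
    }
  })
})

test_that("written files use the canonical missing token", {
  d <- cb_dataset(data.frame(f1 = c(1, NA), row.names = c("s1", "s2")),
                  class_labels = c("a", "b"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d, path)
  expect_match(readLines(path)[3], "\tNA\t")
  apath <- withr::local_tempfile(fileext = ".arff")
  write_dataset(d, apath)
  expect_true(any(grepl("^'?s2'?,\\?", readLines(apath))))
})

test_that("gz output is really gzip-compressed", {
  d <- random_dataset(n = 5)
  path <- withr::local_tempfile(fileext = ".csv.gz")
  write_dataset(d, path)
  magic <- readBin(path, "raw", 2)
  expect_equal(as.integer(magic), c(31L, 139L))
  expect_equal(read_dataset(path), d)
})

test_that("format, schema and integrity errors are distinguished", {
  d <- random_dataset(n = 4)
  expect_error(write_dataset(d, withr::local_tempfile(fileext = ".xlsx")),
               class = "cb_format_error")
  expect_error(read_dataset("nope.tsv"), class = "cb_io_error")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tLabelless", "s1\t1\tx", "s2\t2\ty"), path)
  expect_error(read_dataset(path), class = "cb_schema_error")
  expect_s3_class(read_dataset(path, require_class = FALSE), "cb_dataset")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tClass", "s1\t1\tx", "s1\t2\ty"), dup)
  expect_error(read_dataset(dup), class = "cb_integrity_error")

  ragged <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tf2\tClass", "s1\t1\tx", "s2\t2\ta\ty"), ragged)
  expect_error(read_dataset(ragged), class = "cb_parse_error")
})

test_that("class column match is case-insensitive and overridable", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\tCLASS", "s1\t1\tx", "s2\t2\ty"), path)
  expect_equal(read_dataset(path)$class_labels, c("x", "y"))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tf1\toutcome", "s1\t1\tx", "s2\t2\ty"), path2)
  expect_equal(read_dataset(path2, class_column = "outcome")$class_labels,
               c("x", "y"))
})

test_that("merging intersects samples and concatenates features", {
  a <- cb_dataset(data.frame(f1 = 1:3, row.names = c("s1", "s2", "s3")),
                  class_labels = c("x", "y", "x"))
  b <- cb_dataset(data.frame(g1 = c(10, 20, 30), g2 = c("u", "v", "w"),
                             g3 = c(0.1, 0.2, 0.3),
                             row.names = c("s1", "s2", "s4")))
  m <- merge_datasets(list(a, b))
  expect_equal(m$sample_ids, c("s1", "s2"))
  expect_equal(m$feature_names, c("f1", "g1", "g2", "g3"))
  expect_equal(m$class_labels, c("x", "y"))

  expect_equal(merge_datasets(list(a)), a)
  disjoint <- cb_dataset(data.frame(h1 = 1, row.names = "s9"))
  expect_error(merge_datasets(list(a, disjoint)), class = "cb_merge_error")
  collide <- cb_dataset(data.frame(f1 = 1, row.names = "s1"))
  expect_error(merge_datasets(list(a, collide)), class = "cb_integrity_error")
  disagree <- cb_dataset(data.frame(h1 = 1:2, row.names = c("s1", "s2")),
                         class_labels = c("x", "x"))
  expect_error(merge_datasets(list(a, disagree)), class = "cb_integrity_error")
})

test_that("merge keeps first-part sample order and is associative", {
  withr::with_seed(7, {
    a <- random_dataset(n = 6, n_cat = 0)
    b <- cb_dataset(data.frame(other1 = sample(c("u", "v"), 6, replace = TRUE),
                               row.names = paste0("s", 1:6)))
    c3 <- cb_dataset(data.frame(other2 = round(rnorm(6), 3),
                                row.names = paste0("s", 1:6)))
    left <- merge_datasets(list(merge_datasets(list(a, b)), c3))
    flat <- merge_datasets(list(a, b, c3))
    expect_equal(left, flat)
    expect_equal(flat$sample_ids, a$sample_ids)
  })
})
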