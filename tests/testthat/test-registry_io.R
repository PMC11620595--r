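test_that("address dataset read preserves fields and drops blank lines", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "id,line1,line2,n_people,over65,label",
    "a1,Sunnybank Care Home,Kirkcaldy,30,TRUE,TRUE",
    "a2,10 Glebe Street,,1,FALSE,FALSE",
    "a3,Ten Glebe St,Kirkcaldy,0,FALSE,FALSE"
  ), csv)
  ds <- read_address_dataset(csv, address_schema(lines = c("line1", "line2")))
  expect_equal(nrow(ds), 3)
  expect_equal(ds$address_id, c("a1", "a2", "a3"))
  expect_equal(ds$lines[[1]], c("Sunnybank Care Home", "Kirkcaldy"))
  expect_equal(ds$lines[[2]], "10 Glebe Street") # blank line2 dropped
  expect_equal(ds$person_count, c(30L, 1L, 0L))
  expect_equal(ds$has_over65, c(TRUE, FALSE, FALSE))
  expect_equal(ds$gold_is_care_home, c(TRUE, FALSE, FALSE))
})

test_that("header-only file gives an empty collection, bad schema errors", {
  csv <- tempfile(fileext = ".csv")
  writeLines("id,line1,line2,n_people,over65,label", csv)
  ds <- read_address_dataset(csv, address_schema(lines = c("line1", "line2")))
  expect_equal(nrow(ds), 0)
  expect_error(
    read_address_dataset(csv, address_schema(person_count = "headcount")),
    "headcount")
  expect_error(read_address_dataset(tempfile()), "not found")
})

test_that("address dataset round-trips through its CSV schema", {
  cfg <- synthetic_config(n_addresses = 60, typo_rate = 0.05,
                          abbreviation_rate = 0.3, comma_merge_rate = 0.2,
                          seed = 11)
  addr <- generate_population(cfg, generate_registry(cfg))
  path <- tempfile(fileext = ".csv")
  write_address_dataset(addr, path)
  k <- max(lengths(addr$lines))
  back <- read_address_dataset(path,
                               address_schema(lines = paste0("line", 1:k),
                                              region = "region"))
  expect_equal(back$address_id, addr$address_id)
  expect_equal(back$lines, addr$lines)
  expect_equal(back$person_count, addr$person_count)
  expect_equal(back$gold_is_care_home, addr$gold_is_care_home)
})

test_that("registry read normalizes postcodes and parses service types", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "service_id,name,address,postcode,town,service_type",
    "s1,Sunnybank Care Home,12 High St,ky1 1aa,Kirkcaldy,Care Home Service",
    "s2,Day Centre,3 Mill Rd,KY1 1AB,Kirkcaldy,Support Service"
  ), csv)
  reg <- read_care_home_registry(csv)
  expect_equal(reg$postcode, c("KY1 1AA", "KY1 1AB"))
  expect_equal(reg$service_type, c("care_home", "other_care_service"))
  # empty registry is fine
  writeLines("service_id,name,address,postcode,town,service_type", csv)
  expect_equal(nrow(read_care_home_registry(csv)), 0)
})

test_that("postcode normalization canonicalizes, rejects, and is idempotent", {
  expect_equal(normalize_postcode("ky11aa"), "KY1 1AA")
  expect_equal(normalize_postcode("KY1 1AA"), "KY1 1AA")
  expect_equal(normalize_postcode(" dd2  4rt "), "DD2 4RT")
  expect_equal(normalize_postcode("EH12 9XY"), "EH12 9XY")
  expect_true(is.na(normalize_postcode("no code here")))
  expect_true(is.na(normalize_postcode("")))
  # embedded in free text
  expect_equal(normalize_postcode("10 Glebe Street, Kirkcaldy KY2 5XY"),
               "KY2 5XY")
  set.seed(404)
  for (i in 1:200) {
    s <- random_string(0, 20, c(LETTERS[1:5], letters[1:5], 0:3, " "))
    p <- normalize_postcode(s)
    expect_identical(normalize_postcode(p), p)
  }
})

test_that("town lexicon is lowercase, deduplicated and blank-free", {
  reg <- make_registry(c("A", "B", "C"), c("1 x", "2 y", "3 z"),
                       c("KY1 1AA", "KY1 1AB", "KY1 1AC"),
                       c("Kirkcaldy", "Dundee", "Kirkcaldy"))
  expect_setequal(extract_town_lexicon(reg), c("kirkcaldy", "dundee"))
  reg$town[2] <- ""
  expect_setequal(extract_town_lexicon(reg), "kirkcaldy")
})

test_that("split is stratified, deterministic, and a partition", {
  gold <- rep(c(TRUE, FALSE), c(10, 90))
  recs <- make_addresses(as.list(paste(1:100, "High St")), gold = gold)
  sp <- split_train_validation(recs, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 70)
  expect_equal(sum(sp$train$gold_is_care_home), 7)
  expect_equal(sum(sp$validation$gold_is_care_home), 3)
  sp2 <- split_train_validation(recs, 0.7, seed = 1)
  expect_identical(sp$train$address_id, sp2$train$address_id)
  for (seed in 2:6) {
    spx <- split_train_validation(recs, 0.7, seed = seed)
    expect_setequal(c(spx$train$address_id, spx$validation$address_id),
                    recs$address_id)
    expect_length(intersect(spx$train$address_id,
                            spx$validation$address_id), 0)
  }
  expect_error(split_train_validation(recs, 1.5), "fraction")
  expect_error(split_train_validation(recs, 0), "fraction")
})
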