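test_that("registry generation is deterministic with exact type split", {
  cfg <- synthetic_config(n_addresses = 1000, n_services = 40,
                          other_service_fraction = 0.2, seed = 7)
  reg <- generate_registry(cfg)
  expect_equal(sum(reg$service_type == "care_home"), 40)
  expect_equal(sum(reg$service_type == "other_care_service"), 10)
  expect_identical(generate_registry(cfg), reg)
  cfg2 <- synthetic_config(n_addresses = 1000, n_services = 40,
                           other_service_fraction = 0.2, seed = 8)
  expect_false(identical(sort(generate_registry(cfg2)$name), sort(reg$name)))
  expect_equal(anyDuplicated(reg$postcode), 0)
})

test_that("rates outside [0,1] are rejected", {
  expect_error(synthetic_config(typo_rate = 1.2), "typo_rate")
  expect_error(synthetic_config(neighbour_rate = -0.1), "neighbour_rate")
})

test_that("perturbation is the identity at zero rates and reproducible", {
  cfg0 <- synthetic_config(seed = 1) # every noise rate 0
  lines <- c("sunnybank care home", "10 glebe street", "kirkcaldy")
  expect_identical(perturb_address(lines, cfg0, name_line = 1L), lines)
  cfg <- synthetic_config(typo_rate = 0.2, abbreviation_rate = 0.5,
                          comma_merge_rate = 0.5, line_shuffle_rate = 0.5,
                          name_drop_rate = 0.5, seed = 1)
  set.seed(99)
  a <- perturb_address(lines, cfg, name_line = 1L)
  set.seed(99)
  b <- perturb_address(lines, cfg, name_line = 1L)
  expect_identical(a, b)
  expect_true(length(a) >= 1)
})

test_that("abbreviation rewrites street words by the rule table", {
  cfg <- synthetic_config(abbreviation_rate = 1, number_spell_rate = 0,
                          seed = 1)
  expect_identical(perturb_address("10 glebe street", cfg), "10 glebe st")
  expect_identical(perturb_address("1 park avenue", cfg), "1 park ave")
  cfg_sp <- synthetic_config(number_spell_rate = 1, seed = 1)
  expect_identical(perturb_address("10 glebe street", cfg_sp),
                   "ten glebe street")
})

test_that("population allocation matches configured fractions exactly", {
  cfg <- synthetic_config(n_addresses = 10000, seed = 13)
  reg <- generate_registry(cfg)
  addr <- generate_population(cfg, reg)
  expect_equal(nrow(addr), 10000)
  expect_equal(sum(addr$gold_is_care_home), 130) # 1.3% of 10,000
  expect_equal(anyDuplicated(
    vapply(addr$lines, paste, character(1), collapse = "|")), 0)
  # regeneration is byte-identical
  expect_identical(generate_population(cfg, reg), addr)
})

test_that("care homes emit 1-5 written forms, one carrying the residents", {
  # noise-free so written forms group exactly by their service postcode
  cfg <- synthetic_config(n_addresses = 3000, seed = 17)
  reg <- generate_registry(cfg)
  addr <- generate_population(cfg, reg)
  pos <- addr[addr$gold_is_care_home, ]
  pos_pc <- normalize_postcode(vapply(pos$lines, paste, character(1),
                                      collapse = " "))
  expect_false(anyNA(pos_pc))
  per_service <- table(pos_pc)
  expect_true(all(per_service >= 1 & per_service <= 5))
  # exactly one current (inhabited) form per service
  by_pc <- tapply(pos$person_count > 0, pos_pc, sum)
  expect_true(all(by_pc == 1))
  # historical forms carry nobody and no over-65 flag
  expect_true(all(!pos$has_over65[pos$person_count == 0]))
})

test_that("neighbours share a care home postcode with a different number", {
  cfg <- synthetic_config(n_addresses = 2000, neighbour_rate = 0.05,
                          seed = 23)
  reg <- generate_registry(cfg)
  addr <- generate_population(cfg, reg)
  neg <- addr[!addr$gold_is_care_home, ]
  neg_pc <- normalize_postcode(vapply(neg$lines, paste, character(1),
                                      collapse = " "))
  ch <- reg[reg$service_type == "care_home", ]
  nb <- which(neg_pc %in% ch$postcode)
  expect_gt(length(nb), 0.8 * 0.05 * nrow(neg))
  for (i in nb) {
    svc <- ch[match(neg_pc[i], ch$postcode), ]
    nums <- clean_address(neg$lines[[i]])$numbers
    expect_false(svc$house_number %in% nums)
  }
})

test_that("more typo noise never helps validation matching (trend)", {
  cfg_run <- run_config(methods = "city_block", baselines = character(0),
                        strata = "all_ages", seed = 5)
  f1_at <- function(typo, seed) {
    cfg <- synthetic_config(n_addresses = 2500, typo_rate = typo,
                            abbreviation_rate = 0.2, name_drop_rate = 0.1,
                            seed = seed)
    corp <- generate_corpus(cfg)
    res <- run_pipeline(cfg_run, addresses = corp$addresses,
                        registry = corp$registry)
    r <- res$report
    r$f1[r$level == "address" & r$method == "city_block"]
  }
  steps <- c(0, 0.025, 0.05, 0.075, 0.1)
  med <- vapply(steps, function(tr) {
    stats::median(vapply(1:5, function(s) f1_at(tr, 100 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9),
              info = paste(round(med, 2), collapse = " "))
})
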