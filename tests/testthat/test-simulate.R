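test_that("exact count model plants round(density * size) features", {
  spec <- simulation_spec(
    seed = 1,
    samples = data.frame(sample_id = "s1", kind = "metagenome",
                         size_bp = 5e6, stringsAsFactors = FALSE),
    planted = data.frame(sample_id = "s1", ec = "3.8.1.5", density = 2.0,
                         stringsAsFactors = FALSE),
    count_model = "exact",
    background = list(n_decoys = 0L)
  )
  b <- simulate_bundle(spec, the_catalog)
  ecs <- unlist(b$tables$s1$features$ec_numbers)
  expect_equal(sum(ecs == "3.8.1.5"), 10L)
  expect_equal(b$ground_truth$counts$n_genes, 10L)
})

test_that("simulation is byte-reproducible under a fixed seed", {
  spec <- random_exact_spec(3, the_catalog)
  d1 <- tempfile()
  d2 <- tempfile()
  write_bundle(simulate_bundle(spec, the_catalog), d1)
  write_bundle(simulate_bundle(spec, the_catalog), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_true(length(files) >= 4)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
})

test_that("decoy features never perturb catalog counts", {
  mk_spec <- function(n_decoys) {
    simulation_spec(
      seed = 12,
      samples = data.frame(sample_id = "s1", kind = "metagenome",
                           size_bp = 4e6, stringsAsFactors = FALSE),
      planted = data.frame(sample_id = "s1",
                           ec = c("3.8.1.5", "1.14.19.9"),
                           density = c(8, 12) / 4,
                           stringsAsFactors = FALSE),
      count_model = "exact",
      background = list(n_decoys = n_decoys,
                        decoy_ecs = sprintf("9.9.9.%d", 1:5),
                        no_ec_fraction = 0.5)
    )
  }
  clean <- screen_sample(simulate_bundle(mk_spec(0L), the_catalog)$tables$s1,
                         the_catalog)
  noisy <- screen_sample(simulate_bundle(mk_spec(200L), the_catalog)$tables$s1,
                         the_catalog)
  expect_identical(clean$counts, noisy$counts)
})

test_that("planted ECs must exist in the catalog; decoys must not", {
  spec <- simulation_spec(
    seed = 2,
    samples = data.frame(sample_id = "s", kind = "metagenome",
                         size_bp = 1e6, stringsAsFactors = FALSE),
    planted = data.frame(sample_id = "s", ec = "7.7.7.7", density = 1,
                         stringsAsFactors = FALSE)
  )
  expect_error(simulate_bundle(spec, the_catalog), "not in catalog")

  collide <- simulation_spec(
    seed = 2,
    samples = data.frame(sample_id = "s", kind = "metagenome",
                         size_bp = 1e6, stringsAsFactors = FALSE),
    planted = data.frame(sample_id = "s", ec = "3.8.1.5", density = 1,
                         stringsAsFactors = FALSE),
    background = list(n_decoys = 5L, decoy_ecs = "3.8.1.5")
  )
  expect_error(simulate_bundle(collide, the_catalog), "collide")
})

test_that("exact-model pipeline recovery is perfect end to end", {
  spec <- study_simulation_spec(99, the_catalog)
  b <- simulate_bundle(spec, the_catalog)
  rc <- recovery_check(b, the_catalog)
  expect_equal(rc$count_agreement, 1.0)
  expect_equal(rc$max_abs_count_error, 0)
  expect_equal(rc$max_abs_density_error, 0)
  expect_equal(rc$tier_agreement, 1.0)
  expect_equal(rc$novelty_agreement, 1.0)
  # study structure: 98 MAGs, none discarded, hosts as configured
  expect_equal(nrow(b$mags), 98L)
  tiers <- tier_mags(b$mags)
  expect_equal(sum(tiers$tiers$tier == "high"), 20L)
  expect_equal(sum(tiers$tiers$tier == "medium"), 78L)
  # planted boundary MAG: completeness exactly 90 stays medium
  boundary <- b$mags[b$mags$completeness_pct == 90, ]
  expect_gte(nrow(boundary), 1L)
  expect_true(all(quality_tier(boundary$completeness_pct,
                               boundary$contamination_pct) == "medium"))
})

test_that("a decoys-only bundle recovers empty profiles", {
  spec <- simulation_spec(
    seed = 4,
    samples = data.frame(sample_id = "s1", kind = "metagenome",
                         size_bp = 2e6, stringsAsFactors = FALSE),
    planted = data.frame(sample_id = character(0), ec = character(0),
                         density = numeric(0), stringsAsFactors = FALSE),
    background = list(n_decoys = 50L)
  )
  b <- simulate_bundle(spec, the_catalog)
  prof <- screen_sample(b$tables$s1, the_catalog)
  expect_equal(prof$n_functions, 0L)
  expect_equal(recovery_check(b, the_catalog)$count_agreement, 1.0)
})

test_that("poisson counts have the planted mean (Monte Carlo)", {
  n_rep <- 200
  spec <- simulation_spec(
    seed = 2024,
    samples = data.frame(sample_id = sprintf("rep%03d", seq_len(n_rep)),
                         kind = "metagenome", size_bp = 5e6,
                         stringsAsFactors = FALSE),
    planted = data.frame(sample_id = sprintf("rep%03d", seq_len(n_rep)),
                         ec = "3.8.1.5", density = 2.0,
                         stringsAsFactors = FALSE),
    count_model = "poisson",
    background = list(n_decoys = 0L)
  )
  b <- simulate_bundle(spec, the_catalog)
  counts <- b$ground_truth$counts$n_genes
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  # recovery reports per-sample relative errors without asserting them
  rc <- recovery_check(b, the_catalog)
  expect_equal(nrow(rc$per_sample), n_rep)
  expect_true(all(is.finite(rc$per_sample$rel_density_error)))
})

test_that("simulation specs read back from JSON", {
  spec <- random_exact_spec(8, the_catalog)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(seed = spec$seed, samples = spec$samples, planted = spec$planted,
         count_model = spec$count_model, background = spec$background),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  back <- read_simulation_spec(path)
  expect_equal(back$seed, spec$seed)
  expect_equal(back$planted$density, spec$planted$density)
  b1 <- simulate_bundle(spec, the_catalog)
  b2 <- simulate_bundle(back, the_catalog)
  expect_identical(b1$ground_truth$counts, b2$ground_truth$counts)
})
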