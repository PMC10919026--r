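test_that("function densities are counts over sample size in Mbp", {
  cat <- the_catalog
  prof <- screen_sample(make_table(rep(list("3.8.1.5"), 10),
                                   size_bp = 5e6), cat)
  fd <- function_density(prof)
  expect_equal(fd$density, 2.0)
  expect_equal(fd$density_display, 2.0)

  # no matches: empty sparse output, full-length dense output of zeros
  none <- screen_sample(make_table(list("9.9.9.9")), cat)
  expect_equal(nrow(function_density(none)), 0L)
  dense <- function_density(none, cat, dense = TRUE)
  expect_equal(nrow(dense), 161L)
  expect_true(all(dense$density == 0))

  # random fixture against the division oracle
  set.seed(5)
  tab <- random_table(cat, size_bp = 3.2e6, n_features = 40)
  p <- screen_sample(tab, cat)
  fd <- function_density(p)
  expect_identical(fd$density, p$counts$n_genes / 3.2)
  expect_true(all((fd$density == 0) == (fd$n_genes == 0)))
  expect_equal(fd$density * 3.2, as.numeric(fd$n_genes), tolerance = 1e-15)
})

test_that("doubling sample size halves every density exactly", {
  set.seed(9)
  sets <- replicate(30, sample(the_catalog$functions$ec, 1),
                    simplify = FALSE)
  p1 <- screen_sample(make_table(sets, size_bp = 4e6), the_catalog)
  p2 <- screen_sample(make_table(sets, size_bp = 8e6), the_catalog)
  d1 <- function_density(p1)
  d2 <- function_density(p2)
  expect_identical(d2$density, d1$density / 2)
})

test_that("cluster densities sum member ECs and emit all clusters", {
  cat <- mini_catalog()
  # D1 = {3.8.1.5, 3.8.1.2, 2.5.1.18}: counts 3 + 2 + 0, 1 Mbp
  tab <- make_table(c(rep(list("3.8.1.5"), 3), rep(list("3.8.1.2"), 2)),
                    size_bp = 1e6)
  cd <- cluster_density(screen_sample(tab, cat), cat)
  expect_equal(nrow(cd), 3L)
  expect_equal(cd$density[cd$key == "D1"], 5.0)
  # 3.8.1.2 is shared by D1 and D2: full count contributes to both
  expect_equal(cd$n_genes[cd$key == "D2"], 2L)
  expect_equal(cd$n_genes[cd$key == "B1"], 0L)

  # all-zero profile still yields one record per cluster
  zero <- cluster_density(screen_sample(make_table(list(character(0))),
                                        the_catalog), the_catalog)
  expect_equal(nrow(zero), 32L)
  expect_true(all(zero$density == 0))
})

test_that("cluster density equals the sum of member-EC densities", {
  set.seed(21)
  for (rep in 1:5) {
    tab <- random_table(the_catalog, size_bp = 3e6, n_features = 120,
                        p_hit = 0.8)
    p <- screen_sample(tab, the_catalog)
    fd <- function_density(p, the_catalog, dense = TRUE)
    dens_of <- setNames(fd$density, fd$key)
    cd <- cluster_density(p, the_catalog)
    for (i in seq_len(nrow(the_catalog$clusters))) {
      members <- the_catalog$clusters$member_ecs[[i]]
      want <- sum(dens_of[members])
      got <- cd$density[cd$key == the_catalog$clusters$cluster_id[i]]
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("sample comparison matches brute-force set algebra", {
  cat <- the_catalog
  mk <- function(ecs, id, size = 1e6) {
    screen_sample(make_table(as.list(ecs), sample_id = id,
                             size_bp = size), cat)
  }
  ecs <- cat$functions$ec
  p1 <- mk(ecs[1:3], "s1")   # {a,b,c}
  p2 <- mk(ecs[2:4], "s2")   # {b,c,d}
  p3 <- mk(ecs[2:3], "s3")   # {b,c}
  rep3 <- compare_samples(list(p1, p2, p3), cat)
  expect_equal(length(rep3$intersection), 2L)
  expect_equal(length(rep3$union), 4L)
  expect_equal(rep3$shared_fraction, 0.5)
  expect_equal(rep3$pairwise$n_shared[rep3$pairwise$sample_a == "s1" &
                                        rep3$pairwise$sample_b == "s2"], 2L)

  expect_equal(compare_samples(list(p1, mk(ecs[1:3], "s9")),
                               cat)$shared_fraction, 1.0)
  expect_equal(compare_samples(list(p1, mk(ecs[10:12], "s9")),
                               cat)$shared_fraction, 0.0)

  set.seed(55)
  for (i in 1:20) {
    picks <- lapply(1:3, function(j) sample(ecs[1:12], sample(1:8, 1)))
    profs <- lapply(1:3, function(j) mk(picks[[j]], paste0("q", j)))
    got <- compare_samples(profs, cat)
    want <- set_algebra_oracle(lapply(profs, function(p) p$counts$ec))
    expect_equal(sort(got$intersection), want$intersection)
    expect_equal(sort(got$union), want$union)
    expect_equal(got$shared_fraction, want$shared_fraction)
    # containment invariants
    for (s in got$sets) {
      expect_true(all(got$intersection %in% s))
      expect_true(all(s %in% got$union))
    }
  }
})

test_that("comparison requires a shared catalog and >= 2 profiles", {
  p <- screen_sample(make_table(list("3.8.1.5")), the_catalog)
  q <- screen_sample(make_table(list("3.8.1.5"), sample_id = "s2"),
                     mini_catalog())
  expect_error(compare_samples(list(p), the_catalog), "at least 2")
  expect_error(compare_samples(list(p, q), the_catalog), "catalog")
})

test_that("shared-taxa normalizes labels and handles empty samples", {
  res <- shared_taxa(list(Sc = c("Proteobacteria", " Bacteroidota "),
                          At = c("proteobacteria", "Cyanobacteria"),
                          Hs = "PROTEOBACTERIA"))
  expect_equal(res$report$intersection, "proteobacteria")
  expect_equal(length(res$report$union), 3L)
  pr <- res$long[res$long$taxon == "proteobacteria" &
                   res$long$sample == "Sc", ]
  expect_equal(pr$n_samples, 3L)
  expect_equal(pr$shared_with_mask, "Sc|At|Hs")

  expect_warning(res0 <- shared_taxa(list(a = "P1", b = character(0))),
                 "empty")
  expect_equal(length(res0$report$intersection), 0L)
  expect_equal(res0$report$union, "p1")

  same <- shared_taxa(list(a = paste0("P", 1:9), b = paste0("P", 1:9),
                           c = paste0("P", 1:9)))
  expect_equal(length(same$report$intersection), 9L)
  expect_equal(same$report$shared_fraction, 1.0)
})

test_that("density matrix is keys x samples with zero fill", {
  cat <- the_catalog
  p1 <- screen_sample(make_table(list("3.8.1.5"), sample_id = "s1",
                                 size_bp = 1e6), cat)
  p2 <- screen_sample(make_table(list("1.14.19.9"), sample_id = "s2",
                                 size_bp = 2e6), cat)
  m <- density_matrix(list(function_density(p1), function_density(p2)))
  expect_equal(sort(m$key), c("1.14.19.9", "3.8.1.5"))
  expect_equal(m$s1[m$key == "3.8.1.5"], 1.0)
  expect_equal(m$s1[m$key == "1.14.19.9"], 0)
  expect_equal(m$s2[m$key == "1.14.19.9"], 0.5)
})
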