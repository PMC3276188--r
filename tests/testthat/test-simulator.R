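small_config <- function(fd, ...) {
  defaults <- list(founders = fd$founders,
                   growth = verhulst_params(12, 400, 0.4),
                   generations = 25, c = 0.01, mu = 0, sample_size = 60)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

test_that("a fixed seed reproduces the simulation bit for bit", {
  fd <- mhc_fixture()
  cfg <- small_config(fd)
  s1 <- simulate_population(cfg, seed = 99)
  s2 <- simulate_population(cfg, seed = 99)
  expect_identical(s1, s2)
  s3 <- simulate_population(cfg, seed = 100)
  expect_false(identical(s1$haplotypes, s3$haplotypes))
})

test_that("census sizes follow the rounded Verhulst trajectory", {
  fd <- mhc_fixture()
  cfg <- small_config(fd)
  sim <- simulate_population(cfg, seed = 5)
  expect_equal(sim$census,
               as.integer(round(verhulst_size(cfg$growth, 0:25))))
})

test_that("without crossovers or mutation only founder haplotypes survive", {
  fd <- mhc_fixture()
  cfg <- small_config(fd, c = 0, mu = 0)
  sim <- simulate_population(cfg, seed = 21)
  expect_true(all(sim$true_counts == 0))
  fmat <- t(vapply(fd$founders$founders,
                   function(id) founder_haplotype(fd$founders, id),
                   integer(17)))
  keys <- apply(sim$haplotypes, 1, paste, collapse = ",")
  expect_true(all(keys %in% apply(fmat, 1, paste, collapse = ",")))
  sp <- classify_population(fd$panel, fd$founders, sim$haplotypes)
  expect_equal(sum(sp$counts[-1]), 0)
})

test_that("with mu = 0 every sampled allele exists in the founder pool", {
  fd <- mhc_fixture()
  sim <- simulate_population(small_config(fd, c = 0.05), seed = 13)
  for (m in fd$panel$markers) {
    pool <- unique(unlist(lapply(fd$founders$alleles, `[[`, m)))
    expect_true(all(sim$haplotypes[, m] %in% pool))
  }
})

test_that("mutation perturbs alleles by one repeat unit", {
  fd <- mhc_fixture()
  sim <- simulate_population(small_config(fd, c = 0, mu = 0.01), seed = 31)
  for (m in fd$panel$markers) {
    pool <- unique(unlist(lapply(fd$founders$alleles, `[[`, m)))
    off <- setdiff(unique(sim$haplotypes[, m]), pool)
    if (length(off))
      expect_true(all(vapply(off, function(a)
        any(abs(a - pool) %% 2 == 0), logical(1))))
  }
  expect_gt(sum(!sim$haplotypes %in%
                  unlist(fd$founders$alleles)), 0)
})

test_that("the true crossover count bounds the parsimony count from above", {
  fd <- mhc_fixture()
  sim <- simulate_population(small_config(fd, c = 0.05, generations = 30),
                             seed = 17)
  for (i in seq_len(nrow(sim$haplotypes))) {
    h <- min_recombinations(
      build_compatibility(fd$panel, fd$founders, sim$haplotypes[i, ]))$h
    expect_lte(h, sim$true_counts[i])
  }
  expect_gt(sum(sim$true_counts), 0)
})

test_that("the true mosaic matches the founder of origin marker by marker", {
  fd <- mhc_fixture()
  sim <- simulate_population(small_config(fd, c = 0.05), seed = 23)
  fmat <- t(vapply(fd$founders$founders,
                   function(id) founder_haplotype(fd$founders, id),
                   integer(17)))
  for (i in sample(nrow(sim$haplotypes), 20))
    expect_equal(unname(sim$haplotypes[i, ]),
                 unname(fmat[cbind(sim$true_origin[i, ], 1:17)]))
})

test_that("mean accumulated crossovers per lineage is close to c * T", {
  fd <- mhc_fixture()
  cfg <- small_config(fd, c = 0.02, generations = 25,
                      growth = verhulst_params(12, 300, 0.4),
                      sample_size = 100)
  means <- vapply(1:12, function(s)
    mean(simulate_population(cfg, seed = 200 + s,
                             track_origin = FALSE)$true_counts),
    numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.02 * 25), 3 * se + 0.05)
})

test_that("sampling more animals than the final census is refused", {
  fd <- mhc_fixture()
  cfg <- small_config(fd, sample_size = 500,
                      growth = verhulst_params(12, 400, 0.4))
  expect_error(simulate_population(cfg, seed = 1), "exceeds the final census")
})

test_that("the recovery experiment recovers a zero rate exactly", {
  fd <- mhc_fixture()
  cfg <- small_config(fd, c = 0)
  rec <- recovery_experiment(cfg, replicates = 3, seed = 4)
  expect_equal(rec$lambda_hat, rep(0, 3))
  expect_equal(rec$rate_per_gen, rep(0, 3))
  expect_true(all(rec$undercount %in% NA))
})

test_that("the recovery experiment tracks detectable vs true events", {
  fd <- mhc_fixture()
  cfg <- small_config(fd, c = 0.02, generations = 25,
                      growth = verhulst_params(12, 300, 0.4),
                      sample_size = 100)
  rec <- recovery_experiment(cfg, replicates = 4, seed = 50)
  expect_equal(nrow(rec), 4L)
  expect_true(all(rec$lambda_hat <= rec$true_mean))
  expect_true(all(rec$undercount >= 0 & rec$undercount <= 1))
})
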