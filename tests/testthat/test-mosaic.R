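test_that("founders decompose with zero switches", {
  fd <- mhc_fixture()
  for (id in fd$founders$founders) {
    d <- min_recombinations(
      build_compatibility(fd$panel, fd$founders, founder_haplotype(fd$founders, id)))
    expect_equal(d$h, 0L)
    expect_true(id %in% d$segments$candidates[[1]])
  }
})

test_that("a two-founder chimera needs exactly one switch", {
  fd <- mhc_fixture()
  h1 <- founder_haplotype(fd$founders, "H1")
  h2 <- founder_haplotype(fd$founders, "H2")
  chimera <- c(h1[1:9], h2[10:17])
  cm <- build_compatibility(fd$panel, fd$founders, chimera)
  d <- min_recombinations(cm)
  expect_equal(d$h, 1L)
  expect_identical(d$segments$founder, c("H1", "H2"))
  # cross-check against enumeration on the uniquely-assignable flanks
  sub <- c(1:3, 8:12)
  sub_panel <- marker_panel(fd$panel$markers[sub])
  sub_fs <- founder_set(sub_panel, lapply(fd$founders$alleles,
                                          function(f) f[sub]))
  cm_sub <- build_compatibility(sub_panel, sub_fs, chimera[sub])
  expect_equal(min_recombinations(cm_sub)$h,
               brute_min_switches(cm_sub$matrix))
})

test_that("alleles shared by all founders give h = 0 with every candidate", {
  p <- marker_panel(c("a", "b", "c"))
  fs <- founder_set(p, list(F1 = list(10L, 20L, 30L),
                            F2 = list(10L, 20L, 30L),
                            F3 = list(10L, 20L, 30L)))
  d <- min_recombinations(build_compatibility(p, fs, c(10L, 20L, 30L)))
  expect_equal(d$h, 0L)
  expect_setequal(d$segments$candidates[[1]], c("F1", "F2", "F3"))
})

test_that("orphan policies behave as configured", {
  fd <- mhc_fixture()
  hap <- founder_haplotype(fd$founders, "H1")
  hap["D6S2892"] <- 999L  # rare allele in no founder
  cm <- build_compatibility(fd$panel, fd$founders, hap)
  expect_error(min_recombinations(cm, orphan_policy = "error"), "no founder")
  d <- min_recombinations(cm, orphan_policy = "mutation")
  expect_equal(d$h, 0L)
  expect_equal(d$orphan_markers, "D6S2892")
  expect_equal(min_recombinations(cm, orphan_policy = "wildcard")$h, 0L)
})

test_that("DP minimum agrees with brute-force enumeration on random cases", {
  set.seed(42)
  for (i in 1:60) {
    inst <- random_instance(sample(2:7, 1), sample(2:4, 1))
    cm <- build_compatibility(inst$panel, inst$founders, inst$hap)
    d <- min_recombinations(cm)
    expect_equal(d$h, brute_min_switches(cm$matrix), info = paste("case", i))
  }
})

test_that("removing a marker never increases the minimum switch count", {
  set.seed(7)
  fd <- mhc_fixture()
  for (i in 1:25) {
    # random mosaic of two founders with up to two switches
    ids <- sample(fd$founders$founders, 3)
    cuts <- sort(sample(1:16, 2))
    hap <- c(founder_haplotype(fd$founders, ids[1])[1:cuts[1]],
             founder_haplotype(fd$founders, ids[2])[(cuts[1] + 1):cuts[2]],
             founder_haplotype(fd$founders, ids[3])[(cuts[2] + 1):17])
    h_full <- min_recombinations(
      build_compatibility(fd$panel, fd$founders, hap))$h
    drop <- sample(17, 1)
    sub_panel <- marker_panel(fd$panel$markers[-drop])
    sub_fs <- founder_set(sub_panel, lapply(fd$founders$alleles,
                                            function(f) f[-drop]))
    h_sub <- min_recombinations(
      build_compatibility(sub_panel, sub_fs, hap[-drop]))$h
    expect_lte(h_sub, h_full)
  }
})

test_that("any crossover position inside a breakpoint interval is valid", {
  set.seed(11)
  fd <- mhc_fixture()
  checked <- 0
  for (i in 1:100) {
    ids <- sample(fd$founders$founders, 2)
    cut <- sample(1:16, 1)
    hap <- c(founder_haplotype(fd$founders, ids[1])[1:cut],
             founder_haplotype(fd$founders, ids[2])[(cut + 1):17])
    cm <- build_compatibility(fd$panel, fd$founders, hap)
    d <- min_recombinations(cm)
    if (d$h != 1L) next  # flanks may share all alleles
    fl <- d$segments$founder[1]; fr <- d$segments$founder[2]
    for (j in d$breakpoints$first[1]:d$breakpoints$last[1]) {
      ok <- all(cm$matrix[1:j, fl]) && all(cm$matrix[(j + 1):17, fr])
      expect_true(ok, info = sprintf("case %d, j = %d", i, j))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("classify_population tallies haplotypes and distinct types", {
  fd <- mhc_fixture()
  h1 <- founder_haplotype(fd$founders, "H1")
  h2 <- founder_haplotype(fd$founders, "H2")
  chimera <- c(h1[1:9], h2[10:17])
  haps <- rbind(h1, h1, h1, h1, chimera, chimera)
  sp <- classify_population(fd$panel, fd$founders, haps)
  expect_equal(sp$counts, c(4, 2))
  expect_equal(sp$n, 6)
  expect_equal(sp$types, c(1L, 1L))
  expect_error(classify_population(fd$panel, fd$founders,
                                   matrix(integer(0), 0, 17)), "no haplotypes")
  too_missing <- h1; too_missing[1:10] <- NA
  expect_error(classify_population(fd$panel, fd$founders,
                                   rbind(too_missing)), "missing-data")
})

test_that("flanking founder distributions follow the mosaic flanks", {
  fd <- mhc_fixture()
  h1 <- founder_haplotype(fd$founders, "H1")
  h2 <- founder_haplotype(fd$founders, "H2")
  chimera <- c(h1[1:9], h2[10:17])
  d <- min_recombinations(build_compatibility(fd$panel, fd$founders, chimera))
  dec <- rep(list(d), 10)
  tel <- flanking_founder_distribution(dec, "telomeric",
                                       founders = fd$founders$founders)
  cen <- flanking_founder_distribution(dec, "centromeric",
                                       founders = fd$founders$founders)
  expect_equal(unname(tel["H1"]), 10)
  expect_equal(sum(tel), 10)
  expect_equal(unname(cen["H2"]), 10)
  expect_error(flanking_founder_distribution(dec, "central"), "h = 2")

  # ties: fractional spreading vs dropping
  p <- marker_panel(c("a", "b"))
  fs <- founder_set(p, list(F1 = list(1L, 2L), F2 = list(1L, 3L),
                            F3 = list(5L, 9L)))
  d2 <- min_recombinations(build_compatibility(p, fs, c(1L, 9L)))
  expect_equal(d2$h, 1L)
  frac <- flanking_founder_distribution(list(d2), "telomeric",
                                        founders = c("F1", "F2", "F3"))
  expect_equal(unname(frac), c(0.5, 0.5, 0))
  drop <- flanking_founder_distribution(list(d2), "telomeric",
                                        founders = c("F1", "F2", "F3"),
                                        ties = "drop")
  expect_equal(sum(drop), 0)
})

test_that("homogeneity chi-squared matches hand computation and chisq.test", {
  r <- homogeneity_chi2(c(10, 0), c(0.5, 0.5))
  expect_equal(r$statistic, 10)
  expect_equal(r$df, 1L)

  r0 <- homogeneity_chi2(c(5, 5, 5, 5), rep(0.25, 4))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  obs <- c(20, 35, 10, 35)
  ref <- c(0.2, 0.3, 0.1, 0.4)
  r1 <- homogeneity_chi2(obs, ref)
  ct <- suppressWarnings(chisq.test(obs, p = ref))
  expect_equal(r1$statistic, unname(ct$statistic))
  expect_equal(r1$p_value, unname(ct$p.value))

  expect_error(homogeneity_chi2(c(1, 2), c(0, 1)), "zero reference")
  expect_error(homogeneity_chi2(c(1, 2, 3), c(0.5, 0.5)), "same length")
})
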