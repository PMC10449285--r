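test_that("minor allele frequency counts alleles and rejects bad coding", {
  expect_equal(minor_allele_freq(c(0, 0, 0, 0)), 0)
  expect_equal(minor_allele_freq(c(0, 1, 1, 2)), 0.5)
  expect_equal(minor_allele_freq(c(0, 1, NA, NA)), 0.25)
  expect_error(minor_allele_freq(c(NA_real_, NA_real_)), "no calls")
  expect_error(minor_allele_freq(c(2, 2, 2, 1)), "not minor-allele coded")
  expect_error(minor_allele_freq(c(0, 3, 1)), "invalid dosage")
})

test_that("MAF estimate converges on binomial dosage draws", {
  p <- 0.0836  # a realistic low minor-allele frequency
  set.seed(42)
  g <- rbinom(1000, 2, p)
  se <- sqrt(p * (1 - p) / (2 * 1000))
  expect_lt(abs(minor_allele_freq(g) - p), 3 * se)
  g2 <- rbinom(10000, 2, 0.3)
  se2 <- sqrt(0.3 * 0.7 / (2 * 10000))
  expect_lt(abs(minor_allele_freq(g2) - 0.3), 4 * se2)
})

test_that("HWE exact test matches the enumeration oracle", {
  # monomorphic: a single configuration
  expect_equal(hwe_exact_test(c(0, 0, 50)), 1.0)
  expect_equal(hwe_exact_test(c(50, 0, 0)), 1.0)
  # balanced counts agree with the oracle to near machine precision
  expect_equal(hwe_exact_test(c(25, 50, 25)), hwe_oracle(c(25, 50, 25)),
               tolerance = 1e-12)
  # extreme heterozygote deficit fails the p > 0.01 inclusion filter
  expect_lt(hwe_exact_test(c(45, 10, 45)), 0.01)
  expect_equal(hwe_exact_test(c(45, 10, 45)), hwe_oracle(c(45, 10, 45)),
               tolerance = 1e-12)
  # property: equality with the oracle across random genotype triples
  set.seed(7)
  for (i in 1:60) {
    n <- sample(3:200, 1)
    counts <- as.vector(rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(counts), hwe_oracle(counts),
                 tolerance = 1e-12,
                 label = paste("counts", paste(counts, collapse = "/")))
  }
  expect_error(hwe_exact_test(c(-1, 2, 3)), "nonnegative")
})

test_that("LD r2 is squared dosage correlation with expected invariances", {
  g <- c(0, 1, 2, 1, 0)
  expect_equal(ld_r2(g, g), 1.0)
  expect_equal(ld_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1.0)
  g1 <- c(0, 1, 2, 0, 1, 2); g2 <- c(0, 1, 0, 2, 1, 0)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)
  # symmetry and allele-orientation invariance
  set.seed(5)
  for (i in 1:20) {
    a <- rbinom(30, 2, 0.3); b <- rbinom(30, 2, 0.4)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(ld_r2(a, b), ld_r2(b, a))
    expect_equal(ld_r2(a, b), ld_r2(2 - a, b), tolerance = 1e-12)
    expect_equal(ld_r2(a, b), ld_r2(a, 2 - b), tolerance = 1e-12)
  }
  expect_error(ld_r2(c(0, 0, 0, 0), c(0, 1, 2, 1)), "undefined r2")
  expect_error(ld_r2(c(0, 1), c(1, 0)), "complete pairs")
  # pairwise-complete behaviour
  expect_equal(ld_r2(c(0, 1, 2, NA, 1), c(0, 1, 2, 0, NA)), 1.0)
})

test_that("tag-set selection partitions SNPs by LD components", {
  ids <- c("rs1", "rs2", "rs3", "rs4")
  r2 <- matrix(0.05, 4, 4, dimnames = list(ids, ids))
  diag(r2) <- 1
  r2["rs1", "rs2"] <- r2["rs2", "rs1"] <- 0.8
  sets <- select_tag_sets(r2, 0.25)
  expect_equal(sets, list(c("rs1", "rs2"), "rs3", "rs4"))
  # identity matrix: all singletons; full matrix: one set
  expect_length(select_tag_sets(diag(1, 4), 0.25), 4)
  expect_equal(select_tag_sets(matrix(1, 4, 4,
                                      dimnames = list(ids, ids)), 0.25),
               list(ids))
  # partition property + order invariance, against the igraph oracle
  skip_if_not_installed("igraph")
  set.seed(9)
  for (i in 1:20) {
    m <- sample(3:8, 1)
    nm <- paste0("s", sample(100, m))
    rr <- matrix(runif(m * m), m, m)
    rr <- (rr + t(rr)) / 2
    diag(rr) <- 1
    dimnames(rr) <- list(nm, nm)
    sets <- select_tag_sets(rr, 0.5)
    expect_setequal(unlist(sets), nm)
    expect_equal(anyDuplicated(unlist(sets)), 0L)
    g <- igraph::graph_from_adjacency_matrix(rr >= 0.5, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    oracle <- unname(lapply(split(names(comp), comp), sort))
    expect_setequal(lapply(sets, paste, collapse = "|"),
                    lapply(oracle, paste, collapse = "|"))
    # shuffling the input order changes nothing but set identity
    perm <- sample(m)
    sets2 <- select_tag_sets(rr[perm, perm], 0.5)
    expect_setequal(lapply(sets2, paste, collapse = "|"),
                    lapply(sets, paste, collapse = "|"))
  }
})

test_that("genotype coding schemes behave as declared", {
  expect_equal(code_genotype(c(0, 1, 2), "carrier"), c(0L, 1L, 1L))
  expect_equal(code_genotype(c(0, 1, 2), "additive"), c(0L, 1L, 2L))
  expect_equal(code_genotype(c(2, 2, 2), "carrier"), c(1L, 1L, 1L))
  expect_equal(code_genotype(c(0, NA, 2), "carrier"), c(0L, NA, 1L))
  expect_error(code_genotype(c(0, 1), "dominant"))
})

test_that("genotype_matrix validates its invariants and QC summarises", {
  d <- matrix(c(0, 1, 2, 0, NA, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  gm <- genotype_matrix(d)
  expect_equal(dim(gm), c(3L, 2L))
  expect_error(genotype_matrix(matrix(3, 1, 1)), "not in \\{0, 1, 2, NA\\}")
  expect_error(genotype_matrix(d, person_ids = c("a", "a", "c")),
               "unique")
  qc <- snp_qc(gm)
  expect_equal(qc$n, c(3L, 2L))
  expect_equal(qc$call_rate, c(1, 2 / 3))
  expect_equal(qc$maf, c(0.5, 1 / 4))
  expect_true(all(qc$n_hom_major + qc$n_het + qc$n_hom_minor == qc$n))
})
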