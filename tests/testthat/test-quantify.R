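makePeptides <- function(values, samples = paste0("S", 1:2)) {
  # values: named list accession -> matrix (peptides x samples)
  do.call(rbind, lapply(names(values), function(acc) {
    m <- values[[acc]]
    data.frame(accession = acc,
               peptide_id = rep(sprintf("%s_p%02d", acc, seq_len(nrow(m))),
                                ncol(m)),
               sample_id = rep(samples[seq_len(ncol(m))], each = nrow(m)),
               abundance = as.vector(m), stringsAsFactors = FALSE)
  }))
}

test_that("Top3 averages the three most abundant peptides", {
  peps <- makePeptides(list(
    A12345 = matrix(c(10, 20, 30, 1), 4, 2),   # constant across samples
    B12345 = matrix(c(4, 8), 2, 2)             # only two peptides
  ))
  pq <- top3Quantify(peps)
  expect_equal(unname(abundances(pq)["A12345", ]), c(20, 20))
  expect_equal(unname(abundances(pq)["B12345", ]), c(6, 6))
  expect_equal(unname(peptideCounts(pq)), c(4L, 2L))
})

test_that("Top3 matches the brute-force rule on random proteins", {
  set.seed(99)
  for (rep in 1:20) {
    m <- matrix(rlnorm(5 * 6), 5, 6,
                dimnames = list(paste0("A99991_p0", 1:5), paste0("S", 1:6)))
    peps <- data.frame(accession = "A99991",
                       peptide_id = rep(rownames(m), 6),
                       sample_id = rep(colnames(m), each = 5),
                       abundance = as.vector(m))
    pq <- top3Quantify(peps)
    expect_equal(unname(abundances(pq)[1, ]), unname(bruteTop3(m)))
  }
})

test_that("Top3 ignores any change in peptides ranked 4th or lower", {
  base <- matrix(c(100, 50, 25, 5, 1), 5, 3)
  perturbed <- base
  perturbed[4:5, ] <- perturbed[4:5, ] * matrix(runif(6, 0.1, 2), 2, 3)
  p1 <- top3Quantify(makePeptides(list(A00001 = base), paste0("S", 1:3)))
  p2 <- top3Quantify(makePeptides(list(A00001 = perturbed), paste0("S", 1:3)))
  expect_equal(abundances(p1), abundances(p2))
})

test_that("empty or malformed tables are rejected; all-zero proteins kept", {
  expect_error(top3Quantify(data.frame()), "columns")
  peps <- makePeptides(list(A00001 = matrix(0, 3, 2)))
  pq <- top3Quantify(peps)
  expect_equal(unname(abundances(pq)[1, ]), c(0, 0))
  dup <- rbind(peps, peps[1, ])
  expect_error(top3Quantify(dup), "unique")
})

test_that("minimum-peptide filter keeps exactly the well-quantified proteins", {
  sim <- simulatePeptideTable(simConfig(seed = 17, nProteins = 60L,
                                        nSecreted = 10L))
  pq <- top3Quantify(sim$peptides, sim$metadata)
  counts <- peptideCounts(pq)
  expect_identical(rownames(filterMinPeptides(pq, 1)), rownames(pq))
  for (k in c(2, 3, 5)) {
    kept <- filterMinPeptides(pq, k)
    expect_identical(rownames(kept), names(counts)[counts >= k])
    # bookkeeping unchanged by the column operation
    expect_identical(unname(peptideCounts(kept)),
                     unname(counts[counts >= k]))
  }
})

test_that("normalisation removes exact per-sample scalars", {
  a <- matrix(rlnorm(40, 5, 1), 10, 4,
              dimnames = list(sprintf("P%05d", 1:10), paste0("S", 1:4)))
  pq <- ProteinQuant(a, rep(3L, 10))
  # identical samples: unchanged
  m2 <- a[, c(1, 1)]
  colnames(m2) <- c("S1", "S2")
  same <- ProteinQuant(m2, rep(3L, 10))
  n0 <- normaliseAbundances(same, "all_proteins")
  expect_equal(abundances(n0), abundances(same), tolerance = 1e-12)
  # sample B = 2 x sample A: factor 1/2, columns equalised
  ab <- ProteinQuant(cbind(S1 = a[, 1], S2 = 2 * a[, 1]), rep(3L, 10))
  nab <- normaliseAbundances(ab, "all_proteins")
  expect_equal(S4Vectors::metadata(nab)$norm_factors[["S2"]], 0.5)
  expect_equal(abundances(nab)[, 1], abundances(nab)[, 2])
})

test_that("normalisation recovers planted scaling factors (oracle)", {
  set.seed(7)
  for (rep in 1:10) {
    # general random matrix: factors must match the brute-force
    # median-of-log-ratios oracle
    a <- matrix(rlnorm(200, 8, 2), 50, 4,
                dimnames = list(sprintf("P%05d", 1:50), paste0("S", 1:4)))
    pq <- ProteinQuant(a, rep(3L, 50))
    np <- normaliseAbundances(pq, "all_proteins")
    f <- S4Vectors::metadata(np)$norm_factors
    ref <- S4Vectors::metadata(np)$norm_reference_run
    expect_equal(unname(f), unname(bruteNormFactors(a, ref)),
                 tolerance = 1e-10)
    # shared protein profile with planted per-sample scalars: recovered
    # factors are the planted scalars' reciprocals up to a global constant
    base <- rlnorm(50, 8, 2)
    scal <- rlnorm(4, 0, 0.5)
    ap <- outer(base, scal)
    dimnames(ap) <- dimnames(a)
    fp <- S4Vectors::metadata(
      normaliseAbundances(ProteinQuant(ap, rep(3L, 50)),
                          "all_proteins"))$norm_factors
    expect_equal(unname(fp * scal / (fp * scal)[1]), rep(1, 4),
                 tolerance = 1e-10)
  }
})

test_that("normalisation is idempotent", {
  sim <- simulatePeptideTable(simConfig(seed = 23))
  pq <- filterMinPeptides(top3Quantify(sim$peptides, sim$metadata))
  n1 <- normaliseAbundances(pq, "reference_set", sim$reference)
  n2 <- normaliseAbundances(n1, "reference_set", sim$reference)
  expect_equal(abundances(n1), abundances(n2), tolerance = 1e-10)
})

test_that("normalisation error cases are informative", {
  a <- matrix(1, 3, 2, dimnames = list(c("P00001", "P00002", "P00003"),
                                       c("S1", "S2")))
  pq <- ProteinQuant(a, rep(3L, 3))
  expect_error(normaliseAbundances(pq, "reference_set"), "requires")
  expect_error(normaliseAbundances(pq, "reference_set", "Q99999"),
               "empty intersection")
  a2 <- a
  a2[, 2] <- 0
  pq2 <- ProteinQuant(a2, rep(3L, 3))
  expect_error(normaliseAbundances(pq2, "all_proteins"), "S2")
})

test_that("reference subsetting is plain set intersection in matrix order", {
  sim <- simulatePeptideTable(simConfig(seed = 29))
  pq <- top3Quantify(sim$peptides, sim$metadata)
  sub <- subsetReference(pq, sim$reference)
  expect_identical(rownames(sub),
                   intersect(rownames(pq), sim$reference))
  expect_identical(rownames(subsetReference(pq, rownames(pq))),
                   rownames(pq))
  expect_error(subsetReference(pq, "Z00000"), "empty intersection")
  set.seed(41)
  for (rep in 1:10) {
    ref <- sample(rownames(pq), 20)
    expect_identical(rownames(subsetReference(pq, ref)),
                     intersect(rownames(pq), ref))
  }
})

test_that("the quantification chain recovers planted fold changes exactly when noise-free", {
  # sample scaling stays on, so normalisation must do real work
  cfg <- simConfig(seed = 37, noiseCV = 0)
  sim <- simulatePeptideTable(cfg)
  sec <- secretedMatrix(sim)
  fc <- foldChanges(sec, colData(sec)$sc_level)
  planted <- cfg@plantedEffects
  got <- fc$fold_change[match(names(planted), fc$accession)]
  expect_equal(got, unname(planted), tolerance = 1e-10)
  # unplanted secreted proteins have fold change exactly 1
  rest <- fc$fold_change[!fc$accession %in% names(planted)]
  expect_equal(rest, rep(1, length(rest)), tolerance = 1e-10)
})
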