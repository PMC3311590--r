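test_that("assigned AAWS are uniform on [0, 1] and reproducible", {
  h1 <- sampleAssignedAAWS(seed = 5)
  h2 <- sampleAssignedAAWS(seed = 5)
  expect_identical(aawsWeights(h1), aawsWeights(h2))
  expect_identical(names(aawsWeights(h1)), aminoAcidAlphabet())
  expect_true(all(aawsWeights(h1) >= 0 & aawsWeights(h1) <= 1))

  # pooled draws have the uniform mean
  pooled <- unlist(lapply(1:500, function(i)
    aawsWeights(sampleAssignedAAWS(seed = i))))
  expect_lt(abs(mean(pooled) - 0.5), 0.02)
})

test_that("peptide encoding is a positional lookup into h", {
  h <- setNames(rep(0.5, 20), aminoAcidAlphabet())
  h["A"] <- 0.2
  h["C"] <- 0.9
  expect_identical(encodePeptide("AC", h), c(0.2, 0.9))
  expect_identical(encodePeptide("CA", h), c(0.9, 0.2))

  hS4 <- sampleAssignedAAWS(seed = 1)
  p <- encodePeptide("ACDEFGHIKLMNPQ", hS4)
  expect_length(p, 14)
  expect_true(all(p %in% aawsWeights(hS4)))

  # permuting the sequence permutes the encoding identically
  sq <- "WYACDK"
  perm <- c(3, 1, 6, 2, 5, 4)
  chars <- strsplit(sq, "")[[1]]
  expect_identical(encodePeptide(paste(chars[perm], collapse = ""), hS4),
                   encodePeptide(sq, hS4)[perm])

  expect_error(encodePeptide("ACZ", hS4), "Z")
})

test_that("sampled antibodies are unit-norm with symmetric signs", {
  a <- sampleAntibody(14, seed = 3)
  expect_lt(abs(sqrt(sum(a^2)) - 1), 1e-12)
  expect_identical(sampleAntibody(14, seed = 3), a)

  # l = 1: normalization forces +/-1
  expect_true(all(abs(vapply(1:20, function(i)
    sampleAntibody(1, seed = i), numeric(1))) == 1))

  # sign symmetry over many draws
  set.seed(99)
  draws <- unlist(lapply(1:2000, function(i) sampleAntibody(14)))
  expect_lt(abs(mean(draws < 0) - 0.5), 0.01)
})

test_that("binding association is the dot product with the √l bound", {
  expect_identical(bindingAssociation(c(1, 0), c(0.2, 0.9)), 0.2)
  expect_identical(bindingAssociation(c(0, 1), c(0.5, 0)), 0)
  expect_error(bindingAssociation(c(1, 0), c(1, 2, 3)), "length")

  h <- sampleAssignedAAWS(seed = 2)
  for (i in 1:25) {
    a <- sampleAntibody(14, seed = i)
    p <- encodePeptide(peptideSequences(toyLibrary(1, seed = i))[[1]], h)
    expect_lte(abs(bindingAssociation(a, p)), sqrt(14))
  }
})

test_that("association constant follows the thermodynamic closed forms", {
  th <- thermoParams()
  expect_identical(associationConstant(0, th), 1)
  expect_equal(associationConstant(1, th), exp(1), tolerance = 1e-12)

  # beta0 = RT ln 2, beta1 = 0: K = 2 whatever y is
  RT <- 8.314472 * 298.15
  th2 <- thermoParams(beta0 = RT * log(2), beta1 = 0)
  expect_equal(associationConstant(c(-3, 0, 7), th2), rep(2, 3),
               tolerance = 1e-12)

  # overflow guarded
  expect_error(associationConstant(1, thermoParams(beta1 = 1e6 * RT)),
               "overflow")
})

test_that("Langmuir signal matches hand-computed fractions", {
  # single antibody with K = 1 (all-zero h makes y = 0): S = 1/2
  lib <- PeptideLibrary(c(p1 = "AC"))
  h0 <- setNames(rep(0, 20), aminoAcidAlphabet())
  mix1 <- AntibodyMixture(matrix(c(1, 0), 1), 1)
  expect_equal(unname(profileValues(simulateSignal(lib, mix1, h0))), 0.5,
               tolerance = 1e-15)

  # two antibodies, c = (1/2, 1/2), K = (1, 3): S = 2/3
  h <- setNames(rep(0, 20), aminoAcidAlphabet())
  h["A"] <- 1                       # encode "AC" as p = (1, 0)
  thK3 <- thermoParams(beta1 = 2 * 8.314472 * 298.15)  # K = exp(2 y)
  a1 <- c(0, 1)                     # y = 0 -> K = 1
  a2 <- c(log(3) / 2, sqrt(1 - (log(3) / 2)^2))  # y = ln(3)/2 -> K = 3
  mix2 <- AntibodyMixture(rbind(a1, a2), c(0.5, 0.5))
  expect_equal(unname(profileValues(simulateSignal(lib, mix2, h, thK3))),
               2 / 3, tolerance = 1e-12)

  # dimension mismatch
  mixBad <- AntibodyMixture(matrix(sampleAntibody(3, seed = 1), 1), 1)
  expect_error(simulateSignal(lib, mixBad, h), "length")
})

test_that("simulation chain matches the step-by-step oracle to 1e-12", {
  for (case in 1:5) {
    nPep <- sample(1:5, 1)
    nAb <- sample(1:3, 1)
    l <- sample(1:3, 1)
    lib <- generateLibrary(nPep, l, seed = 100 + case)
    h <- sampleAssignedAAWS(seed = 200 + case)
    mix <- makeMixture(nAb, l, seed = 300 + case)
    got <- profileValues(simulateSignal(lib, mix, h))
    want <- oracleSignal(unname(peptideSequences(lib)), aawsWeights(h),
                         bindingSites(mix), concentrations(mix))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("Langmuir output is bounded, saturating and position-dependent", {
  sim <- toySimulation(nPep = 50, nAb = 5, seedBase = 9)
  raw <- simulateSignal(sim$lib, sim$mix, sim$h)
  expect_true(all(profileValues(raw) > 0 & profileValues(raw) < 1))

  # n_Ab = 1 reduces to K / (1 + K)
  mix1 <- makeMixture(1, 14, seed = 4)
  s1 <- profileValues(simulateSignal(sim$lib, mix1, sim$h))
  a <- bindingSites(mix1)[1, ]
  K <- exp(vapply(peptideSequences(sim$lib), function(sq)
    bindingAssociation(a, encodePeptide(sq, sim$h)), numeric(1)))
  expect_equal(unname(s1), unname(K / (1 + K)), tolerance = 1e-12)

  # S -> 1 as K -> 1e6 (beta0 tuned, beta1 = 0)
  RT <- 8.314472 * 298.15
  thBig <- thermoParams(beta0 = RT * log(1e6), beta1 = 0)
  sBig <- profileValues(simulateSignal(sim$lib, mix1, sim$h, thBig))
  expect_true(all(sBig > 1 - 2e-6))

  # position dependence: a single antibody distinguishes permuted peptides
  h <- setNames(rep(0, 20), aminoAcidAlphabet())
  h["A"] <- 1
  libPair <- PeptideLibrary(c(fwd = "AC", rev = "CA"))
  mixA <- AntibodyMixture(matrix(c(1, 0), 1), 1)
  sPair <- profileValues(simulateSignal(libPair, mixA, h))
  expect_gt(abs(sPair["fwd"] - sPair["rev"]), 0.1)
})

test_that("multiplicative noise has the declared moments and determinism", {
  prof <- BindingProfile(values = runif(1e5, 0.2, 0.8),
                         stage = "raw_fraction")
  expect_identical(applyNoise(prof, 0, seed = 1), prof)

  noisy <- applyNoise(prof, 0.01, seed = 2)
  ratio <- profileValues(noisy) / profileValues(prof) - 1
  expect_lt(abs(sd(ratio) / 0.01 - 1), 0.05)
  expect_lt(abs(mean(ratio)), 1e-3)
  expect_identical(profileValues(applyNoise(prof, 0.01, seed = 2)),
                   profileValues(noisy))
  expect_true(all(profileValues(noisy) > 0 & profileValues(noisy) < 1))

  expect_error(applyNoise(prof, -0.1), "sigma")
  normd <- normalizeSignal(prof)
  expect_error(applyNoise(normd, 0.01), "raw_fraction")
})

test_that("mixtures sit on the concentration simplex, dominance included", {
  mix4 <- makeMixture(4, 14, seed = 1)
  expect_equal(concentrations(mix4), rep(0.25, 4), tolerance = 1e-15)
  expect_true(all(abs(rowSums(bindingSites(mix4)^2) - 1) < 1e-12))

  # renormalisation: factor 3 on 2 antibodies -> (3/4, 1/4)
  mixD <- makeMixture(2, 14, seed = 1, dominanceFactor = 3)
  expect_equal(concentrations(mixD), c(0.75, 0.25), tolerance = 1e-15)

  # the printed large case: 16000 antibodies, factor 1000
  mixBig <- makeMixture(16000, 14, seed = 2, dominanceFactor = 1000)
  expect_equal(concentrations(mixBig)[1], 1000 / (1000 + 15999),
               tolerance = 1e-12)
  expect_equal(sum(concentrations(mixBig)), 1, tolerance = 1e-12)

  # supplied dominant antibody lands in row 1, unit-normalised
  dom <- c(3, rep(0, 13))
  mixS <- makeMixture(5, 14, seed = 3, dominanceFactor = 10, dominant = dom)
  expect_equal(bindingSites(mixS)[1, ], c(1, rep(0, 13)), tolerance = 1e-15)

  expect_error(makeMixture(1, 14, seed = 1, dominanceFactor = 10),
               "at least 2")
  expect_error(makeMixture(4, 14, seed = 1, dominanceFactor = 0.5), ">= 1")
})

test_that("normalization centres and scales the log signal", {
  sim <- toySimulation(nPep = 100, nAb = 20, seedBase = 3)
  v <- profileValues(sim$s)
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sd(v) - 1), 1e-9)
  expect_identical(profileStage(sim$s), "normalized")

  # normalizing the logged values gives the identical profile
  raw <- simulateSignal(sim$lib, sim$mix, sim$h)
  logged <- BindingProfile(values = log(profileValues(raw)),
                           stage = "logged")
  expect_equal(profileValues(normalizeSignal(logged)), v,
               tolerance = 1e-12)

  # constant profiles are degenerate
  flat <- BindingProfile(values = rep(0.4, 10), stage = "raw_fraction")
  expect_error(normalizeSignal(flat), "degenerate")
})
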