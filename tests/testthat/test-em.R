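test_that("structured initialization matches its defining error model", {
  cfg <- em_config(init_epsilon = 0.05, prior_p0 = 0.998)
  m <- initialize_model(learner_spec(), cfg)
  expect_equal(m$theta[1, "AA", "A"], 0.95)
  expect_equal(unname(m$theta[1, "AA", c("C", "G", "T")]), rep(0.05 / 3, 3))
  expect_equal(unname(m$theta[2, "AC", c("A", "C")]), c(0.475, 0.475))
  expect_equal(unname(m$theta[2, "AC", c("G", "T")]), c(0.025, 0.025))
  expect_equal(m$priors["G", "GG"], 0.998)
  expect_equal(unname(m$priors["G", "AA"]), 0.002 / 9)
  expect_silent(validate_model(m))
})

test_that("e_step reproduces the hand-computed noiseless Bayes posterior", {
  # one learner, error-free emissions, uniform prior, counts {A:3}:
  # q(AA) = 1/(1 + 3 * 0.125) = 8/11, each A-het 1/11, others 0
  m <- initialize_model(1L)
  for (k in seq_along(GENOTYPES)) {
    al <- genotype_alleles(k)
    row <- c(A = 0, C = 0, G = 0, T = 0)
    row[al[1]] <- row[al[1]] + 0.5
    row[al[2]] <- row[al[2]] + 0.5
    m$theta[1, k, ] <- row
  }
  m$priors[] <- 0.1
  pu <- pileups_from_counts("t", 0L, "A", matrix(c(3L, 0L, 0L, 0L), 1),
                            spec = learner_spec(0L))
  q <- e_step(pu, m)$posteriors[1, ]
  expect_equal(unname(q["AA"]), 8 / 11, tolerance = 1e-12)
  expect_equal(unname(q[c("AC", "AG", "AT")]), rep(1 / 11, 3), tolerance = 1e-12)
  expect_equal(unname(q[c("CC", "GG", "TT", "CG", "CT", "GT")]), rep(0, 6))
})

test_that("a zero-depth locus falls back to the prior row", {
  m <- initialize_model(learner_spec())
  pu <- pileups_from_counts("t", 0L, "A", matrix(0L, 1, 16))
  es <- e_step(pu, m)
  expect_equal(unname(es$posteriors[1, ]), unname(m$priors["A", ]),
               tolerance = 1e-12)
  expect_identical(es$decided, 1L)  # AA, the highest-prior class
})

test_that("posteriors are invariant to permuting learner order", {
  pu <- random_pileups(31, n_loci = 15, n_learners = 2)
  m <- initialize_model(pu$spec)
  # perturb the two learners so they differ
  m$theta[1, , ] <- (m$theta[1, , ] + 0.02) / rowSums(m$theta[1, , ] + 0.02)
  q1 <- e_step(pu, m)$posteriors
  # swap learner columns and theta slices
  pu2 <- pu
  pu2$counts <- pu$counts[, c(5:8, 1:4)]
  colnames(pu2$counts) <- colnames(pu$counts)
  m2 <- m
  m2$theta[1, , ] <- m$theta[2, , ]
  m2$theta[2, , ] <- m$theta[1, , ]
  q2 <- e_step(pu2, m2)$posteriors
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("m_step is posterior-weighted count renormalization", {
  pu <- pileups_from_counts("t", 0:1, c("A", "A"),
                            rbind(c(4L, 0L, 0L, 0L), c(2L, 2L, 0L, 0L)),
                            spec = learner_spec(0L))
  q <- matrix(0, 2, 10, dimnames = list(NULL, GENOTYPES))
  q[1, "AA"] <- 1
  q[2, "AC"] <- 1
  m <- m_step(pu, q, em_config(pseudocount = 1e-12))
  expect_equal(unname(m$theta[1, "AA", ]), c(1, 0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(m$theta[1, "AC", ]), c(0.5, 0.5, 0, 0), tolerance = 1e-9)
  # classes that received no posterior mass get the uniform smoothing row
  expect_equal(unname(m$theta[1, "GG", ]), rep(0.25, 4), tolerance = 1e-9)

  # infinite smoothing drives every row to uniform
  m_inf <- m_step(pu, q, em_config(pseudocount = 1e9))
  expect_equal(unname(m_inf$theta[1, "AA", ]), rep(0.25, 4), tolerance = 1e-6)

  # a learner with no observations at all keeps its previous rows
  pu2 <- pileups_from_counts("t", 0:1, c("A", "A"),
                             cbind(rbind(c(4L, 0L, 0L, 0L), c(2L, 2L, 0L, 0L)),
                                   matrix(0L, 2, 4)),
                             spec = learner_spec(c(0L, 20L)))
  prev <- initialize_model(pu2$spec)
  m2 <- m_step(pu2, q, em_config(), prev_model = prev)
  expect_equal(m2$theta[2, , ], prev$theta[2, , ])
})

test_that("run_em with max_iters = 1 is exactly one E+M pass", {
  pu <- random_pileups(7, n_loci = 20)
  cfg <- em_config(max_iters = 1L)
  fit <- run_em(pu, cfg, aggregate = FALSE)
  init <- initialize_model(pu$spec, cfg)
  es <- e_step(pu, init)
  manual <- m_step(pu, es$posteriors, cfg, prev_model = init)
  expect_equal(fit$posteriors, es$posteriors, tolerance = 1e-12)
  expect_equal(fit$model$theta, manual$theta, tolerance = 1e-12)
  expect_equal(fit$model$priors, manual$priors, tolerance = 1e-12)
  expect_identical(fit$n_iters, 1L)
})

test_that("the EM objective is non-decreasing and the fit is valid", {
  for (s in 1:20) {
    fit <- run_em(random_pileups(1000 + s), em_config(max_iters = 25))
    expect_true(all(diff(fit$iteration_log$objective) >= -1e-8))
    expect_equal(unname(rowSums(fit$posteriors)),
                 rep(1, nrow(fit$posteriors)), tolerance = 1e-9)
    expect_true(all(fit$entropy_bits >= 0 &
                      fit$entropy_bits <= log2(10) + 1e-12))
    expect_silent(validate_model(fit$model))
  }
})

test_that("doubling all counts preserves argmax decisions under uniform priors", {
  pu <- random_pileups(55, n_loci = 40)
  m <- initialize_model(pu$spec)
  m$priors[] <- 0.1
  pu2 <- pu
  pu2$counts <- pu$counts * 2L
  pu2$depth <- pu$depth * 2L
  es1 <- e_step(pu, m)
  es2 <- e_step(pu2, m)
  expect_identical(es1$decided, es2$decided)
  # cross-check a few loci against the independent brute-force oracle
  for (i in c(1, 10, 25)) {
    bf <- brute_force_posterior(pu2$counts[i, ], pu$ref_base[i],
                                m$theta, m$priors)
    expect_equal(unname(es2$posteriors[i, ]), bf, tolerance = 1e-10)
  }
})

test_that("pattern aggregation is exact", {
  pu <- random_pileups(8, n_loci = 60, max_depth = 3)  # many duplicates
  f1 <- run_em(pu, em_config(max_iters = 10), aggregate = TRUE)
  f2 <- run_em(pu, em_config(max_iters = 10), aggregate = FALSE)
  expect_equal(f1$posteriors, f2$posteriors, tolerance = 1e-10)
  expect_equal(f1$model$theta, f2$model$theta, tolerance = 1e-10)
  expect_identical(f1$decided, f2$decided)
})

test_that("entropy is Shannon entropy in bits with 0 log 0 = 0", {
  expect_equal(posterior_entropy(rep(0.1, 10)), log2(10))
  expect_equal(posterior_entropy(c(1, rep(0, 9))), 0)
  expect_equal(posterior_entropy(c(0.5, 0.5, rep(0, 8))), 1)
  qm <- rbind(rep(0.1, 10), c(1, rep(0, 9)))
  expect_equal(posterior_entropy(qm), c(log2(10), 0))
})

test_that("candidates are exactly the loci whose genotype leaves the reference", {
  pu <- pileups_from_counts(
    "t", 0:2, c("A", "A", "A"),
    rbind(c(20L, 0L, 0L, 0L),   # hom ref
          c(10L, 10L, 0L, 0L),  # het AC
          c(0L, 20L, 0L, 0L)),  # hom alt CC
    spec = learner_spec(0L))
  fit <- run_em(pu, em_config())
  cands <- call_candidates(pu, fit)
  expect_identical(cands$pos, c(1L, 2L))
  expect_identical(cands$genotype, c("AC", "CC"))
  expect_identical(cands$is_het, c(TRUE, FALSE))
  expect_equal(cands$alt_fraction, c(0.5, 1.0))
})

test_that("model JSON serialization round-trips", {
  fit <- run_em(random_pileups(3), em_config(max_iters = 5))
  path <- tempfile(fileext = ".json")
  write_model_json(fit$model, path, config = fit$config,
                   iteration_log = fit$iteration_log)
  m2 <- read_model_json(path)
  expect_equal(m2$theta, fit$model$theta, tolerance = 1e-15)
  expect_equal(m2$priors, fit$model$priors, tolerance = 1e-15)
})

test_that("run_em refuses empty input and non-finite likelihoods abort", {
  expect_error(run_em(pileups_from_counts("t", integer(0), character(0),
                                          matrix(0L, 0, 16))),
               "at least one")
})
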