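make_candidates <- function(n, entropy, alt_frac, depth = 30L,
                            genotype = "AC", pos = seq_len(n) - 1L) {
  gt_idx <- match(genotype, GENOTYPES)
  out <- data.frame(
    contig = "t", pos = pos, ref = "A",
    genotype = genotype, genotype_code = rep(gt_idx, length.out = n) - 1L,
    is_het = rep(genotype_is_het(gt_idx), length.out = n),
    depth = rep(depth, length.out = n),
    alt_fraction = rep(alt_frac, length.out = n),
    entropy_bits = rep(entropy, length.out = n),
    post_prob = 0.9, stringsAsFactors = FALSE)
  class(out) <- c("candidate_variants", "data.frame")
  out
}

test_that("feature extraction is a deterministic pass-through", {
  cands <- make_candidates(3, entropy = c(0, 0.5, 2), alt_frac = c(0.4, 1, 0.1))
  f <- extract_features(cands)
  expect_equal(f$alt_fraction, c(0.4, 1, 0.1))
  expect_equal(f$entropy_bits, c(0, 0.5, 2))
  expect_identical(as.character(f$genotype_code),
                   as.character(cands$genotype_code))
  expect_identical(f$is_het, as.integer(cands$is_het))
  # point-mass posterior carries zero entropy into the vector
  expect_equal(f$entropy_bits[1], 0)
})

test_that("a linearly separable training set is fit perfectly", {
  true_c <- make_candidates(30, entropy = runif(30, 0, 0.4), alt_frac = 0.5)
  false_c <- make_candidates(30, entropy = runif(30, 2.1, 3.2), alt_frac = 0.5,
                             pos = 100:129)
  cands <- rbind(true_c, false_c)
  labels <- rep(c(TRUE, FALSE), each = 30)
  model <- train_filter(extract_features(cands), labels)
  pred <- apply_filter(cands, model)
  expect_identical(pred$pos, true_c$pos)   # training accuracy 1.0
  expect_lte(model$depth, 5L)
})

test_that("tree depth never exceeds 5 regardless of training size", {
  set.seed(1)
  for (n in c(40, 400)) {
    # noisy, non-separable labels force the tree to grow as far as allowed
    ent <- runif(n, 0, 3.3)
    af <- runif(n, 0, 1)
    dp <- sample(5:60, n, TRUE)
    labels <- (ent + rnorm(n, sd = 1.2) < 1.5) & (af + rnorm(n, sd = 0.4) > 0.3)
    cands <- make_candidates(n, entropy = ent, alt_frac = af, depth = dp,
                             pos = seq_len(n) - 1L)
    if (length(unique(labels)) < 2) next
    model <- train_filter(extract_features(cands), labels)
    expect_lte(model$depth, 5L)
  }
})

test_that("apply_filter returns an ordered subset, idempotently", {
  set.seed(2)
  n <- 80
  cands <- make_candidates(n, entropy = runif(n, 0, 3.3),
                           alt_frac = runif(n, 0, 1))
  labels <- cands$entropy_bits < 1.5
  model <- train_filter(extract_features(cands), labels)
  kept <- apply_filter(cands, model)
  expect_true(all(kept$pos %in% cands$pos))
  expect_false(is.unsorted(kept$pos))
  expect_identical(apply_filter(kept, model), kept)   # idempotent
  expect_identical(apply_filter(cands, model), kept)  # deterministic
})

test_that("degenerate filter inputs behave per contract", {
  cands <- make_candidates(10, entropy = runif(10, 0, 1), alt_frac = 0.5)
  # single-class training set fails with a message
  expect_error(train_filter(extract_features(cands), rep(TRUE, 10)),
               "single class")
  model <- train_filter(extract_features(rbind(cands, cands)),
                        rep(c(TRUE, FALSE), each = 10))
  # empty candidate list -> empty output
  empty <- cands[0, , drop = FALSE]
  expect_identical(nrow(apply_filter(empty, model)), 0L)
})

test_that("a filter model persists with depth bound and metadata intact", {
  set.seed(3)
  cands <- make_candidates(60, entropy = runif(60, 0, 3.3),
                           alt_frac = runif(60, 0, 1))
  labels <- cands$entropy_bits < 1.2
  model <- train_filter(extract_features(cands), labels, seed = 77L)
  path <- tempfile(fileext = ".rds")
  write_filter_model(model, path)
  m2 <- read_filter_model(path)
  expect_lte(m2$depth, 5L)
  expect_identical(m2$seed, 77L)
  expect_identical(apply_filter(cands, m2), apply_filter(cands, model))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$depth, model$depth)
  expect_identical(unlist(meta$features), model$features)
})

test_that("filtering spiked low-confidence candidates improves the call set", {
  sim <- shared_sim()
  pu <- build_pileups(sim$sam, sim$fasta)
  fit <- run_em(pu)
  cands <- call_candidates(pu, fit)
  spiked <- spike_false_candidates(cands, n_fake = 60,
                                   genome_length = sim$config$genome_length,
                                   seed = 9)
  labels <- label_candidates(spiked, sim$truth)
  expect_identical(sum(!labels), 60L)  # exactly the spiked ones are untrue

  model <- train_filter(extract_features(spiked), labels, seed = 9L)
  kept <- apply_filter(spiked, model)
  truth_df <- data.frame(chrom = sim$config$contig_name,
                         pos = sim$truth$pos + 1L,
                         genotype = sim$truth$genotype)
  as_calls <- function(x) data.frame(chrom = x$contig, pos = x$pos + 1L,
                                     genotype = x$genotype)
  before <- evaluate_calls(as_calls(spiked), truth_df)
  after <- evaluate_calls(as_calls(kept), truth_df)
  expect_gte(after$f1, before$f1)
  expect_gte(after$precision, before$precision)
  expect_gte(after$recall, before$recall - 0.01)  # recall loss <= 1 point

  # the confidence features dominate the tree
  imp <- sort(model$importance, decreasing = TRUE)
  expect_true(all(c("entropy_bits", "alt_fraction") %in% names(imp)[1:2]))
})
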