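#' Extract filter features from SNV candidates
#'
#' The four features used to discriminate true from untrue candidates:
#' the decided genotype (encoded as its canonical class code plus a
#' heterozygosity indicator), the read depth, the fraction of reads with a
#' non-reference base, and the entropy (bits) of the genotype posterior —
#' lower entropy meaning a more confident call.
#'
#' @param candidates A `candidate_variants` data.frame.
#' @return data.frame with columns `genotype_code` (factor over 0..9),
#'   `is_het`, `depth`, `alt_fraction`, `entropy_bits`.
#' @export
extract_features <- function(candidates) {
  out <- data.frame(
    genotype_code = factor(candidates$genotype_code, levels = 0:9),
    is_het = as.integer(candidates$is_het),
    depth = as.numeric(candidates$depth),
    alt_fraction = candidates$alt_fraction,
    entropy_bits = candidates$entropy_bits)
  stopifnot(all(is.finite(out$depth)), all(is.finite(out$alt_fraction)),
            all(is.finite(out$entropy_bits)))
  out
}

#' Label candidates against a truth set
#'
#' Genotype-aware matching, consistent with [evaluate_calls()]: a candidate
#' is labeled true iff a truth variant exists at the same (contig,
#' position) with the identical genotype.
#'
#' @param candidates A `candidate_variants` data.frame (`pos` 0-based).
#' @param truth data.frame with `pos` (0-based), `genotype` (simulator
#'   truth), or a truth VCF path (1-based positions, converted).
#' @param contig Contig name assumed for data.frame truths lacking one.
#' @return Logical vector, one element per candidate.
#' @export
label_candidates <- function(candidates, truth, contig = NULL) {
  if (is.character(truth)) {
    tv <- read_snvs(truth)
    truth <- data.frame(contig = tv$chrom, pos = tv$pos - 1L,
                        genotype = tv$genotype, stringsAsFactors = FALSE)
  }
  if (is.null(truth$contig)) {
    truth$contig <- if (!is.null(contig)) contig else candidates$contig[1]
  }
  m <- match(paste(candidates$contig, candidates$pos),
             paste(truth$contig, truth$pos))
  !is.na(m) & candidates$genotype == truth$genotype[m]
}

#' Train the candidate filter (depth-limited decision tree)
#'
#' Fits a binary CART tree (Gini impurity) of depth at most 5 on the
#' candidate features, with balanced class weights so the typically rare
#' negative class is not swamped. The shallow depth is a deliberate guard
#' against overfitting.
#'
#' @param features data.frame from [extract_features()].
#' @param labels Logical vector (`TRUE` = keep / true variant).
#' @param max_depth Maximum tree depth (default 5).
#' @param seed Seed recorded in the metadata (rpart fitting is
#'   deterministic; the seed documents the provenance of training data).
#' @return A `filter_model`: the fitted `rpart` tree plus metadata
#'   (`n_pos`, `n_neg`, `depth`, `importance`, `seed`, `features`).
#' @export
train_filter <- function(features, labels, max_depth = 5L, seed = NA_integer_) {
  stopifnot(nrow(features) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; need both true and untrue candidates")
  df <- features
  df$label <- factor(ifelse(labels, "keep", "drop"), levels = c("drop", "keep"))
  n <- nrow(df)
  w <- ifelse(labels, n / (2 * sum(labels)), n / (2 * sum(!labels)))
  fit <- rpart::rpart(label ~ genotype_code + is_het + depth + alt_fraction +
                        entropy_bits,
                      data = df, weights = w, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(maxdepth = max_depth,
                                                     cp = 0, xval = 0,
                                                     minsplit = 4,
                                                     minbucket = 2))
  depth <- tree_depth(fit)
  stopifnot(depth <= max_depth)
  imp <- fit$variable.importance
  structure(list(tree = fit, depth = depth,
                 importance = imp,
                 n_pos = sum(labels), n_neg = sum(!labels),
                 seed = seed,
                 features = c("genotype_code", "is_het", "depth",
                              "alt_fraction", "entropy_bits"),
                 version = "1"),
            class = "filter_model")
}

# Depth of an rpart tree (root = depth 0).
tree_depth <- function(fit) {
  nodes <- as.integer(rownames(fit$frame))
  if (length(nodes) <= 1L) return(0L)
  as.integer(max(floor(log2(nodes))))
}

#' @export
print.filter_model <- function(x, ...) {
  cat("filter_model: depth", x$depth, "decision tree |",
      x$n_pos, "true /", x$n_neg, "untrue training candidates\n")
  if (length(x$importance))
    cat("importance:", paste(names(x$importance),
                             signif(x$importance, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Apply the filter to candidates
#'
#' Returns the ordered subset of candidates the tree predicts "keep".
#' Deterministic and idempotent: filtering a filtered set changes nothing.
#'
#' @param candidates A `candidate_variants` data.frame.
#' @param model A `filter_model` from [train_filter()].
#' @return The kept subset, original order and class preserved.
#' @export
apply_filter <- function(candidates, model) {
  stopifnot(inherits(model, "filter_model"))
  if (nrow(candidates) == 0L) return(candidates)
  feats <- extract_features(candidates)
  if (!all(model$features %in% colnames(feats)))
    stop("feature schema mismatch between candidates and filter model")
  pred <- predict(model$tree, newdata = feats, type = "class")
  out <- candidates[pred == "keep", , drop = FALSE]
  class(out) <- class(candidates)
  out
}

#' Persist / load a filter model
#'
#' The fitted tree is stored as an RDS file with a JSON metadata sidecar
#' (`<path>.json`) recording the schema version, feature names, training
#' counts, tree depth, and seed.
#'
#' @param model A `filter_model`.
#' @param path Destination RDS path.
#' @return `path`, invisibly.
#' @export
write_filter_model <- function(model, path) {
  saveRDS(model, path)
  meta <- list(version = model$version, features = model$features,
               depth = model$depth, n_pos = model$n_pos, n_neg = model$n_neg,
               seed = model$seed,
               importance = as.list(model$importance))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_filter_model
#' @export
read_filter_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "filter_model"), model$depth <= 5L)
  model
}

#' Spike synthetic low-confidence false candidates into a candidate set
#'
#' Harness for studying the filter in a controlled regime: appends `n_fake`
#' candidates that do not correspond to any true variant, drawn with high
#' posterior entropy and low alternate-base fraction — the signature of
#' marginal, untrue calls — while depth and genotype are resampled from the
#' real candidates so they carry no separating signal by construction.
#'
#' @param candidates A `candidate_variants` data.frame from a caller run.
#' @param n_fake Number of spiked false candidates.
#' @param genome_length Contig length (spiked positions drawn outside the
#'   candidate loci).
#' @param entropy_range,alt_fraction_range Uniform ranges for the spiked
#'   confidence features.
#' @param seed RNG seed.
#' @return The augmented `candidate_variants` data.frame, position-sorted,
#'   with a logical column `spiked`.
#' @export
spike_false_candidates <- function(candidates, n_fake,
                                   genome_length,
                                   entropy_range = c(1.5, log2(10)),
                                   alt_fraction_range = c(0.02, 0.35),
                                   seed = 1L) {
  with_seed(seed, {
    taken <- candidates$pos
    pool <- setdiff(seq_len(genome_length) - 1L, taken)
    pos <- sort(sample(pool, n_fake))
    ref <- sample(BASES, n_fake, replace = TRUE)
    gt_idx <- vapply(ref, function(r) {
      alt <- sample(setdiff(BASES, r), 1L)
      genotype_index(r, alt)           # spiked calls look heterozygous
    }, integer(1))
    fake <- data.frame(
      contig = rep(candidates$contig[1], n_fake),
      pos = pos, ref = ref,
      genotype = GENOTYPES[gt_idx],
      genotype_code = gt_idx - 1L,
      is_het = genotype_is_het(gt_idx),
      depth = sample(candidates$depth, n_fake, replace = TRUE),
      alt_fraction = stats::runif(n_fake, alt_fraction_range[1],
                                  alt_fraction_range[2]),
      entropy_bits = stats::runif(n_fake, entropy_range[1], entropy_range[2]),
      post_prob = stats::runif(n_fake, 0.3, 0.6),
      stringsAsFactors = FALSE)
    real <- candidates
    real$spiked <- FALSE
    fake$spiked <- TRUE
    out <- rbind(real, fake)
    out <- out[order(out$contig, out$pos), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("candidate_variants", "data.frame")
    out
  })
}

#' Default filter model trained on the packaged simulator
#'
#' Trains (once per session, cached) a depth-5 tree on a simulated
#' training regime at a fixed, documented seed: a standard caller run
#' whose candidates are labeled against the planted truth, augmented with
#' spiked low-confidence false candidates so both classes are well
#' represented. Stands in for training on a large real truth-labeled
#' dataset, which users can do via [train_filter()] on their own data.
#'
#' @return A `filter_model`.
#' @export
default_filter_model <- function() {
  if (!is.null(.emsnv_cache$default_filter)) return(.emsnv_cache$default_filter)
  model <- simulate_and_train_filter(seed = 20240601L)
  .emsnv_cache$default_filter <- model
  model
}

.emsnv_cache <- new.env(parent = emptyenv())

#' Build a labeled training regime on the simulator and fit the filter
#'
#' @param seed Master seed for the simulated training data.
#' @param genome_length,coverage Simulation scale of the training run.
#' @param n_fake Spiked false candidates added to the training set.
#' @return A `filter_model`.
#' @export
simulate_and_train_filter <- function(seed, genome_length = 50000L,
                                      coverage = 30, n_fake = 150L) {
  sim <- simulate_dataset(sim_config(seed = seed,
                                     genome_length = genome_length,
                                     coverage = coverage),
                          dir = tempfile("filtertrain"))
  pu <- build_pileups(sim$sam, sim$fasta)
  fit <- run_em(pu)
  cands <- call_candidates(pu, fit)
  cands <- spike_false_candidates(cands, n_fake = n_fake,
                                  genome_length = genome_length,
                                  seed = seed + 1L)
  labels <- label_candidates(cands, sim$truth)
  train_filter(extract_features(cands), labels, seed = seed)
}
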