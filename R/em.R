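#' EM configuration
#'
#' Hyperparameters of the unsupervised ensemble genotyper. The pseudocount
#' acts as a symmetric Dirichlet smoothing term on every confusion-matrix
#' row and prior row, keeping all probabilities strictly positive; the
#' monitored objective is therefore the Dirichlet-penalized (MAP)
#' log-likelihood, which the EM increases monotonically.
#'
#' @param max_iters Maximum EM iterations (>= 1).
#' @param tol Relative change in the objective below which EM stops.
#' @param pseudocount Dirichlet smoothing mass per cell (> 0).
#' @param init_epsilon Initial per-base miscall probability in (0, 0.5).
#' @param prior_p0 Initial prior mass on the homozygous-reference class.
#' @param seed Integer seed recorded for reproducibility metadata.
#' @return An `em_config` list.
#' @export
em_config <- function(max_iters = 50L, tol = 1e-6, pseudocount = 0.1,
                      init_epsilon = 0.05, prior_p0 = 0.998, seed = 1L) {
  stopifnot(max_iters >= 1L, tol > 0, pseudocount > 0,
            init_epsilon > 0, init_epsilon < 0.5,
            prior_p0 > 0, prior_p0 < 1)
  structure(list(max_iters = as.integer(max_iters), tol = tol,
                 pseudocount = pseudocount, init_epsilon = init_epsilon,
                 prior_p0 = prior_p0, seed = as.integer(seed)),
            class = "em_config")
}

#' Structured initialization of the learner model
#'
#' Every learner starts from the same error model: under a homozygous class
#' (x,x) the matching base has probability `1 - epsilon` and each other base
#' `epsilon / 3`; under a heterozygous class (x,y) each allele has
#' `(1 - epsilon) / 2` and each of the two remaining bases `epsilon / 2`.
#' Priors put mass `prior_p0` on the homozygous-reference class at each
#' reference base and spread the remainder uniformly over the other nine.
#'
#' @param spec A [learner_spec()] (or integer number of learners).
#' @param config An [em_config()].
#' @return A `learner_model`: `theta` (L x 10 x 4 emission array) and
#'   `priors` (4 x 10 matrix, rows indexed by reference base).
#' @export
initialize_model <- function(spec = learner_spec(), config = em_config()) {
  L <- if (inherits(spec, "learner_spec")) spec$n_learners else as.integer(spec)
  eps <- config$init_epsilon
  row10x4 <- matrix(0, 10, 4, dimnames = list(GENOTYPES, BASES))
  for (k in seq_len(10)) {
    al <- genotype_alleles(k)
    if (al[1] == al[2]) {
      row10x4[k, ] <- eps / 3
      row10x4[k, al[1]] <- 1 - eps
    } else {
      row10x4[k, ] <- eps / 2
      row10x4[k, al] <- (1 - eps) / 2
    }
  }
  theta <- array(rep(row10x4, each = L), dim = c(L, 10, 4),
                 dimnames = list(paste0("L", seq_len(L) - 1L), GENOTYPES, BASES))
  priors <- matrix((1 - config$prior_p0) / 9, 4, 10,
                   dimnames = list(BASES, GENOTYPES))
  priors[cbind(seq_len(4), hom_ref_class(BASES))] <- config$prior_p0
  structure(list(theta = theta, priors = priors, n_learners = L),
            class = "learner_model")
}

#' @export
print.learner_model <- function(x, ...) {
  cat("learner_model:", x$n_learners, "learners, 10 genotype classes\n")
  invisible(x)
}

#' Check learner-model invariants
#'
#' Each emission row and each prior row must sum to 1 within 1e-9 and all
#' entries must be strictly positive.
#'
#' @param model A `learner_model`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_model <- function(model) {
  th_sums <- apply(model$theta, c(1, 2), sum)
  if (any(abs(th_sums - 1) > 1e-9)) stop("theta rows must sum to 1")
  if (any(model$theta <= 0)) stop("theta entries must be > 0")
  pr_sums <- rowSums(model$priors)
  if (any(abs(pr_sums - 1) > 1e-9)) stop("prior rows must sum to 1")
  if (any(model$priors <= 0)) stop("prior entries must be > 0")
  invisible(TRUE)
}

# theta array -> (4L x 10) log-emission matrix whose row order matches the
# learner-major A,C,G,T count columns of locus_pileups.
theta_log_matrix <- function(model) {
  L <- model$n_learners
  out <- matrix(0, 4L * L, 10L)
  for (j in seq_len(L))
    out[(4L * (j - 1L) + 1L):(4L * j), ] <- t(log(model$theta[j, , ]))
  out
}

#' E-step: per-locus genotype posteriors
#'
#' For locus i with reference base r and counts n over (learner j, base b),
#' the posterior over the ten genotype classes is
#' `q_i(k) ~ priors[r, k] * prod_jb theta[j, k, b]^n[j, b]`,
#' computed in log space and normalized. A zero-depth locus gets the prior
#' row itself. The decided class is the argmax with deterministic
#' lowest-index tie-break.
#'
#' @param pileups A `locus_pileups` object.
#' @param model A `learner_model`.
#' @param weights Optional per-locus multiplicities (pattern aggregation).
#' @return List with `posteriors` (n x 10 matrix), `decided` (1-based class
#'   indices), `entropy_bits`, and the observed-data `loglik` (weighted).
#' @export
e_step <- function(pileups, model, weights = NULL) {
  n <- length(pileups$pos)
  lp <- log(model$priors)
  if (n == 0L)
    return(list(posteriors = matrix(numeric(0), 0, 10,
                                    dimnames = list(NULL, GENOTYPES)),
                decided = integer(0), entropy_bits = numeric(0), loglik = 0))
  lm <- theta_log_matrix(model)
  # guard the zero-probability limit: 0 * log(0) must contribute 0, and a
  # positive count against a zero emission must annihilate the class
  lm[is.infinite(lm)] <- -1e300
  logpost <- pileups$counts %*% lm + lp[match(pileups$ref_base, BASES), , drop = FALSE]
  mx <- apply(logpost, 1L, max)
  pe <- exp(logpost - mx)
  norm <- rowSums(pe)
  posteriors <- pe / norm
  colnames(posteriors) <- GENOTYPES
  w <- if (is.null(weights)) rep(1, n) else weights
  # argmax with lowest-index tie-break, robust to float noise on exact ties
  qmax <- apply(posteriors, 1L, max)
  decided <- max.col(posteriors >= qmax - 1e-12, ties.method = "first")
  list(posteriors = posteriors,
       decided = decided,
       entropy_bits = posterior_entropy(posteriors),
       loglik = sum(w * (mx + log(norm))))
}

#' M-step: re-estimate confusion matrices and priors
#'
#' Posterior-weighted count re-estimation with symmetric pseudocount
#' smoothing:
#' `theta[j,k,b] = (pc + S[j,k,b]) / (4 pc + sum_b S[j,k,b])` where
#' `S[j,k,b] = sum_i w_i q_i(k) n[i,j,b]`, and
#' `priors[r,k] = (pc + sum_{i: ref=r} w_i q_i(k)) / (10 pc + ...)`.
#' A learner with no observations at all keeps its previous emission rows.
#'
#' @param pileups A `locus_pileups` object.
#' @param posteriors n x 10 posterior matrix aligned with the pileups.
#' @param config An [em_config()] (supplies the pseudocount).
#' @param prev_model Previous `learner_model` (fallback for empty learners).
#' @param weights Optional per-locus multiplicities.
#' @return A `learner_model`.
#' @export
m_step <- function(pileups, posteriors, config = em_config(),
                   prev_model = NULL, weights = NULL) {
  L <- pileups$spec$n_learners
  pc <- config$pseudocount
  n <- length(pileups$pos)
  w <- if (is.null(weights)) rep(1, n) else weights
  wq <- posteriors * w                               # n x 10
  S <- t(pileups$counts) %*% wq                      # 4L x 10; rows (j,b)
  theta <- array(0, dim = c(L, 10, 4),
                 dimnames = list(paste0("L", seq_len(L) - 1L), GENOTYPES, BASES))
  for (j in seq_len(L)) {
    Sj <- t(S[(4L * (j - 1L) + 1L):(4L * j), , drop = FALSE])  # 10 x 4
    if (sum(Sj) == 0 && !is.null(prev_model)) {
      theta[j, , ] <- prev_model$theta[j, , ]
    } else {
      theta[j, , ] <- (pc + Sj) / (4 * pc + rowSums(Sj))
    }
  }
  priors <- matrix(pc, 4, 10, dimnames = list(BASES, GENOTYPES))
  ref_idx <- match(pileups$ref_base, BASES)
  for (r in seq_len(4)) {
    sel <- ref_idx == r
    if (any(sel))
      priors[r, ] <- priors[r, ] + colSums(wq[sel, , drop = FALSE])
  }
  priors <- priors / rowSums(priors)
  structure(list(theta = theta, priors = priors, n_learners = L),
            class = "learner_model")
}

# Dirichlet penalty term of the MAP objective.
map_penalty <- function(model, pc) {
  pc * (sum(log(model$theta)) + sum(log(model$priors)))
}

# Collapse loci with identical (ref_base, counts) into weighted patterns.
aggregate_patterns <- function(pileups) {
  n <- length(pileups$pos)
  key <- paste(pileups$ref_base,
               apply(pileups$counts, 1L, paste, collapse = ","))
  first <- which(!duplicated(key))
  map <- match(key, key[first])
  list(patterns = pileups_from_counts(pileups$contig,
                                      seq_along(first) - 1L,
                                      pileups$ref_base[first],
                                      pileups$counts[first, , drop = FALSE],
                                      pileups$spec),
       weights = as.numeric(tabulate(map, nbins = length(first))),
       map = map)
}

#' Fit the unsupervised ensemble genotyper by EM
#'
#' Alternates [e_step()] and [m_step()] until the relative change of the
#' objective (observed-data log-likelihood plus the Dirichlet smoothing
#' penalty) drops below `tol` or `max_iters` is reached. Loci with
#' identical (reference base, count pattern) are collapsed with
#' multiplicity before fitting — the likelihood is identical, and the
#' returned posteriors are re-expanded to all loci.
#'
#' @param pileups A `locus_pileups` object (at least one locus).
#' @param config An [em_config()].
#' @param model Optional starting `learner_model` (default
#'   [initialize_model()]).
#' @param aggregate Collapse duplicate patterns (default TRUE; exactness is
#'   covered by the test suite).
#' @return An `em_fit`: `model`, `posteriors` (n x 10), `decided`,
#'   `entropy_bits`, `iteration_log` (data.frame with per-iteration
#'   observed-data log-likelihood and MAP objective), `converged`,
#'   `n_iters`.
#' @export
run_em <- function(pileups, config = em_config(), model = NULL,
                   aggregate = TRUE) {
  if (length(pileups$pos) == 0L) stop("run_em requires at least one pileup")
  if (is.null(model)) model <- initialize_model(pileups$spec, config)
  validate_model(model)

  if (aggregate) {
    agg <- aggregate_patterns(pileups)
    work <- agg$patterns; weights <- agg$weights
  } else {
    work <- pileups; weights <- rep(1, length(pileups$pos))
  }

  loglik_trace <- numeric(0)
  obj_trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  for (it in seq_len(config$max_iters)) {
    es <- e_step(work, model, weights = weights)
    if (!is.finite(es$loglik)) stop("non-finite log-likelihood at iteration ", it)
    obj <- es$loglik + map_penalty(model, config$pseudocount)
    loglik_trace <- c(loglik_trace, es$loglik)
    obj_trace <- c(obj_trace, obj)
    if (it > 1L) {
      prev <- obj_trace[it - 1L]
      if (abs(obj - prev) / (abs(prev) + 1e-12) < config$tol) {
        converged <- TRUE
        break
      }
    }
    model <- m_step(work, es$posteriors, config, prev_model = model,
                    weights = weights)
  }
  validate_model(model)

  posteriors <- es$posteriors
  decided <- es$decided
  entropy <- es$entropy_bits
  if (aggregate) {
    posteriors <- posteriors[agg$map, , drop = FALSE]
    decided <- decided[agg$map]
    entropy <- entropy[agg$map]
  }
  structure(list(model = model, posteriors = posteriors, decided = decided,
                 entropy_bits = entropy,
                 iteration_log = data.frame(iter = seq_along(loglik_trace),
                                            loglik = loglik_trace,
                                            objective = obj_trace),
                 converged = converged, n_iters = length(loglik_trace),
                 config = config),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat("em_fit:", nrow(x$posteriors), "loci |", x$n_iters, "iterations |",
      if (x$converged) "converged" else "max_iters reached", "\n")
  invisible(x)
}

#' Shannon entropy of class-probability vectors, in bits
#'
#' @param probs A probability vector summing to 1, or a matrix with one
#'   such vector per row. The convention `0 * log(0) = 0` applies.
#' @return Entropy in bits (`[0, log2(10)]` for 10-class posteriors).
#' @export
posterior_entropy <- function(probs) {
  if (is.matrix(probs)) {
    pl <- probs * log2(probs)
    pl[probs == 0] <- 0
    -rowSums(pl)
  } else {
    p <- probs[probs > 0]
    -sum(p * log2(p))
  }
}

#' Mark SNV candidates from decided genotypes
#'
#' A locus is an SNV candidate when its decided genotype differs from the
#' homozygous-reference genotype in at least one allele. Each candidate
#' carries the four filter features (genotype, depth, alternate-base
#' fraction, posterior entropy) plus the posterior mass of the decided
#' class.
#'
#' @param pileups A `locus_pileups` object.
#' @param fit The matching `em_fit` from [run_em()].
#' @return A data.frame of class `candidate_variants` with columns
#'   `contig`, `pos` (0-based), `ref`, `genotype`, `genotype_code`
#'   (0-based canonical index), `is_het`, `depth`, `alt_fraction`,
#'   `entropy_bits`, `post_prob`.
#' @export
call_candidates <- function(pileups, fit) {
  stopifnot(nrow(fit$posteriors) == length(pileups$pos))
  ref_cls <- hom_ref_class(pileups$ref_base)
  is_cand <- fit$decided != ref_cls
  idx <- which(is_cand)
  af <- alt_fraction(pileups)
  out <- data.frame(
    contig = rep(pileups$contig, length(idx)),
    pos = pileups$pos[idx],
    ref = pileups$ref_base[idx],
    genotype = GENOTYPES[fit$decided[idx]],
    genotype_code = fit$decided[idx] - 1L,
    is_het = genotype_is_het(fit$decided[idx]),
    depth = pileups$depth[idx],
    alt_fraction = af[idx],
    entropy_bits = fit$entropy_bits[idx],
    post_prob = fit$posteriors[cbind(idx, fit$decided[idx])],
    stringsAsFactors = FALSE)
  class(out) <- c("candidate_variants", "data.frame")
  out
}

#' Serialize a learner model (plus config) to JSON
#'
#' Documented schema: `version`, `n_learners`, `genotypes`, `bases`,
#' `theta` (nested learner -> class -> base probabilities), `priors`
#' (ref base -> class), `config`. Round-trips through
#' [read_model_json()].
#'
#' @param model A `learner_model`.
#' @param path Output path.
#' @param config Optional [em_config()] stored alongside.
#' @param iteration_log Optional per-iteration log-likelihood data.frame.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path, config = NULL, iteration_log = NULL) {
  obj <- list(version = "1",
              n_learners = model$n_learners,
              genotypes = GENOTYPES, bases = BASES,
              theta_dim = dim(model$theta), theta = as.vector(model$theta),
              priors_dim = dim(model$priors), priors = as.vector(model$priors),
              config = unclass(config), iteration_log = iteration_log)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a learner model written by [write_model_json()]
#' @param path JSON path.
#' @return A `learner_model` (validated).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- obj$n_learners
  theta <- array(obj$theta, dim = c(L, 10, 4),
                 dimnames = list(paste0("L", seq_len(L) - 1L), GENOTYPES, BASES))
  priors <- matrix(obj$priors, 4, 10, dimnames = list(BASES, GENOTYPES))
  model <- structure(list(theta = theta, priors = priors, n_learners = L),
                     class = "learner_model")
  validate_model(model)
  model
}
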