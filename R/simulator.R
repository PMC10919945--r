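# Run code under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  force(code)
}

#' Simulation configuration
#'
#' Defines the synthetic study conditions: a uniform random reference, SNVs
#' planted at a fixed per-base rate, and error-prone reads stratified into
#' the same base-quality learners the caller uses. Defaults emulate a 30x
#' short-read whole-genome experiment with per-base substitution error at
#' or below 1\% across four quality strata.
#'
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param genome_length Reference length in bp.
#' @param contig_name Contig name used in FASTA/SAM/VCF.
#' @param snv_rate Per-base probability of planting an SNV, in (0,1).
#' @param het_fraction Probability a planted SNV is heterozygous.
#' @param coverage Mean read depth.
#' @param read_length Read length in bp.
#' @param error_rates Per-learner substitution error rates in `[0, 0.5)`.
#' @param learner_weights Mixture weights over learners (sum to 1).
#' @param baseq Representative Phred base quality per learner; encodes the
#'   learner bin in the emitted quality strings.
#' @param mapq Mapping quality written for every read.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L,
                       contig_name = "sim1", snv_rate = 0.001,
                       het_fraction = 0.67, coverage = 30,
                       read_length = 100L,
                       error_rates = c(0.01, 0.005, 0.002, 0.001),
                       learner_weights = rep(0.25, 4),
                       baseq = c(7L, 15L, 25L, 37L), mapq = 60L) {
  stopifnot(snv_rate > 0 || snv_rate == 0, snv_rate < 1,
            het_fraction >= 0, het_fraction <= 1, coverage > 0,
            all(error_rates >= 0), all(error_rates < 0.5),
            length(learner_weights) == length(error_rates),
            length(baseq) == length(error_rates),
            abs(sum(learner_weights) - 1) < 1e-9)
  if (read_length > genome_length) stop("read_length exceeds genome_length")
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 contig_name = contig_name, snv_rate = snv_rate,
                 het_fraction = het_fraction, coverage = coverage,
                 read_length = as.integer(read_length),
                 error_rates = error_rates,
                 learner_weights = learner_weights,
                 baseq = as.integer(baseq), mapq = as.integer(mapq)),
            class = "sim_config")
}

#' Simulate a reference, planted SNVs and aligned error-prone reads
#'
#' The reference is i.i.d. uniform over A,C,G,T. SNVs are planted at
#' Bernoulli(`snv_rate`) positions in the interior of the contig (at least
#' one read length from either end, where coverage is uniform), each
#' heterozygous with probability `het_fraction` and with alternate allele
#' uniform over the three non-reference bases. Reads start uniformly over
#' the contig, each drawn whole from one of the two haplotypes, assigned a
#' learner by the mixture weights, and corrupted at the learner's
#' substitution rate (uniform over the three wrong bases). Reads are
#' emitted pre-aligned — perfect placement, all-match CIGAR — in a
#' coordinate-sorted SAM whose base-quality strings encode the learner bin.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param fastq Optionally also dump reads as FASTQ (path written alongside)
#'   for use with external aligners.
#' @return List with paths `fasta`, `sam`, `truth_vcf` (and `fastq` if
#'   requested), the `truth` data.frame (`pos` 0-based, `ref`, `genotype`),
#'   the two planted `haplotypes` (strings), per-read metadata `read_info`
#'   (`start` 0-based, `learner` 0-based, `haplotype`, `n_errors`), and the
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("sim"),
                             fastq = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, {
    G <- config$genome_length
    rl <- config$read_length
    ref <- sample(BASES, G, replace = TRUE)

    # plant SNVs in the uniform-coverage interior
    lo <- min(rl, G - 1L); hi <- G - rl
    cand <- if (hi >= lo) seq.int(lo, hi) else integer(0)  # 0-based
    planted <- cand[stats::runif(length(cand)) < config$snv_rate]
    hap1 <- ref; hap2 <- ref
    truth <- data.frame(pos = integer(0), ref = character(0),
                        genotype = character(0), stringsAsFactors = FALSE)
    if (length(planted) > 0L) {
      r <- ref[planted + 1L]
      alt <- vapply(r, function(b) sample(setdiff(BASES, b), 1L), character(1))
      het <- stats::runif(length(planted)) < config$het_fraction
      gt <- ifelse(het,
                   ifelse(r < alt, paste0(r, alt), paste0(alt, r)),
                   paste0(alt, alt))
      hap2[planted + 1L] <- alt
      which_hap <- sample(1:2, length(planted), replace = TRUE)
      hom_or_h1 <- !het | which_hap == 1L
      hap1[planted[hom_or_h1] + 1L] <- alt[hom_or_h1]
      hap2[planted[het & which_hap == 1L] + 1L] <-
        r[het & which_hap == 1L]
      truth <- data.frame(pos = planted, ref = r, genotype = gt,
                          stringsAsFactors = FALSE)
    }
    hap1s <- paste(hap1, collapse = "")
    hap2s <- paste(hap2, collapse = "")

    n_reads <- max(1L, as.integer(round(config$coverage * G / rl)))
    starts <- sort(sample.int(G - rl + 1L, n_reads, replace = TRUE) - 1L)
    L <- length(config$error_rates)
    learner <- sample.int(L, n_reads, replace = TRUE,
                          prob = config$learner_weights)
    hap <- sample(1:2, n_reads, replace = TRUE)
    seqs <- ifelse(hap == 1L,
                   substring(hap1s, starts + 1L, starts + rl),
                   substring(hap2s, starts + 1L, starts + rl))

    # substitution errors, uniform among the three wrong bases
    p <- rep(config$error_rates[learner], each = rl)
    err_idx <- which(stats::runif(n_reads * rl) < p)
    n_err_read <- tabulate((err_idx - 1L) %/% rl + 1L, nbins = n_reads)
    if (length(err_idx) > 0L) {
      rd <- (err_idx - 1L) %/% rl + 1L
      off <- (err_idx - 1L) %% rl + 1L
      for (e in seq_along(err_idx)) {
        cur <- substr(seqs[rd[e]], off[e], off[e])
        substr(seqs[rd[e]], off[e], off[e]) <-
          sample(setdiff(BASES, cur), 1L)
      }
    }
    quals <- strrep(intToUtf8(config$baseq + 33L, multiple = TRUE), rl)[learner]

    fasta <- file.path(dir, "reference.fa")
    writeLines(c(paste0(">", config$contig_name),
                 substring(paste(ref, collapse = ""),
                           seq(1L, G, 70L), pmin(seq(1L, G, 70L) + 69L, G))),
               fasta)
    Rsamtools::indexFa(fasta)

    sam <- file.path(dir, "reads.sam")
    writeLines(c(
      "@HD\tVN:1.6\tSO:coordinate",
      paste0("@SQ\tSN:", config$contig_name, "\tLN:", G),
      if (n_reads > 0) paste(sprintf("r%07d", seq_len(n_reads)), 0L,
                             config$contig_name, starts + 1L, config$mapq,
                             paste0(rl, "M"), "*", 0L, 0L, seqs, quals,
                             sep = "\t")), sam)

    truth_vcf <- file.path(dir, "truth.vcf")
    write_truth_vcf(truth, truth_vcf, config$contig_name, G)

    out <- list(fasta = fasta, sam = sam, truth_vcf = truth_vcf,
                truth = truth, haplotypes = c(hap1s, hap2s),
                read_info = data.frame(start = starts,
                                       learner = learner - 1L,
                                       haplotype = hap,
                                       n_errors = n_err_read),
                config = config)
    if (isTRUE(fastq)) {
      fq <- file.path(dir, "reads.fq")
      writeLines(as.vector(rbind(paste0("@r", sprintf("%07d", seq_len(n_reads))),
                                 seqs, "+", quals)), fq)
      out$fastq <- fq
    }
    out
  })
}
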