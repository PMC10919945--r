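# Shared fixtures and independent oracles for the test suite.

# Independent brute-force genotype posterior: probability-space Bayes over
# the ten diploid genotypes, written with explicit loops and its own
# genotype table so it shares no code path with e_step().
brute_force_posterior <- function(counts, ref_base, theta, priors) {
  genotypes <- c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT", "GT")
  bases <- c("A", "C", "G", "T")
  L <- dim(theta)[1]
  r <- match(ref_base, bases)
  p <- numeric(10)
  for (k in 1:10) {
    lik <- priors[r, k]
    for (j in 1:L) {
      for (b in 1:4) {
        n <- counts[(j - 1) * 4 + b]
        if (n > 0) lik <- lik * theta[j, k, b]^n
      }
    }
    p[k] <- lik
  }
  p / sum(p)
}

# A tiny hand-written SAM + FASTA fixture with known per-column content.
# Reference: 20 bp "ACGTACGTACGTACGTACGT" on contig "t1".
# Reads (1-based start, cigar, bases, per-base qual, flag, mapq):
#   r1  pos 1  5M  ACGTA  qual 40 each          flag 0    mapq 60
#   r2  pos 1  5M  CCGTA  qual 40 each          flag 0    mapq 60
#   r3  pos 3  4M  GTAC   quals 5,15,25,35      flag 0    mapq 60
#   r4  pos 1  5M  ACGTA  qual 40 each          flag 1024 mapq 60 (duplicate)
#   r5  pos 6  5M  CGTAC  qual 40 each          flag 0    mapq 5  (low mapq)
#   r6  pos 10 3M  GTN    qual 40 each          flag 0    mapq 60 (N base)
#   r7  pos 12 2M1D2M  TACG (del at ref pos 14) qual 40   flag 0  mapq 60
#   r8  pos 16 2M2I2M  CGTTAC (ins after pos17) qual 40   flag 0  mapq 60
tiny_fixture <- function(dir = tempfile("tiny")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refseq <- "ACGTACGTACGTACGTACGT"
  fasta <- file.path(dir, "ref.fa")
  writeLines(c(">t1", refseq), fasta)
  Rsamtools::indexFa(fasta)
  q <- function(...) intToUtf8(c(...) + 33L)
  recs <- c(
    paste("r1", 0, "t1", 1, 60, "5M", "*", 0, 0, "ACGTA", q(40,40,40,40,40), sep = "\t"),
    paste("r2", 0, "t1", 1, 60, "5M", "*", 0, 0, "CCGTA", q(40,40,40,40,40), sep = "\t"),
    paste("r4", 1024, "t1", 1, 60, "5M", "*", 0, 0, "ACGTA", q(40,40,40,40,40), sep = "\t"),
    paste("r3", 0, "t1", 3, 60, "4M", "*", 0, 0, "GTAC", q(5,15,25,35), sep = "\t"),
    paste("r5", 0, "t1", 6, 5, "5M", "*", 0, 0, "CGTAC", q(40,40,40,40,40), sep = "\t"),
    paste("r6", 0, "t1", 10, 60, "3M", "*", 0, 0, "GTN", q(40,40,40), sep = "\t"),
    paste("r7", 0, "t1", 12, 60, "2M1D2M", "*", 0, 0, "TACG", q(40,40,40,40), sep = "\t"),
    paste("r8", 0, "t1", 16, 60, "2M2I2M", "*", 0, 0, "CGTTAC", q(40,40,40,40,40,40), sep = "\t"))
  sam <- file.path(dir, "reads.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:t1\tLN:20", recs), sam)
  list(dir = dir, fasta = fasta, sam = sam, refseq = refseq)
}

# Random small pileup instance for property tests.
random_pileups <- function(seed, n_loci = 30, n_learners = 2, max_depth = 10,
                           contig = "rnd") {
  set.seed(seed)
  refs <- sample(BASES, n_loci, replace = TRUE)
  counts <- matrix(0L, n_loci, 4 * n_learners)
  for (i in seq_len(n_loci)) {
    d <- sample.int(max_depth + 1L, 1L) - 1L
    if (d > 0) {
      cols <- sample.int(4 * n_learners, d, replace = TRUE)
      tb <- tabulate(cols, nbins = 4 * n_learners)
      counts[i, ] <- tb
    }
  }
  pileups_from_counts(contig, seq_len(n_loci) - 1L, refs, counts,
                      spec = learner_spec(seq(0, by = 10,
                                              length.out = n_learners)))
}

# Small simulation shared by several tests (cached per session).
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- simulate_dataset(
      sim_config(seed = 4242, genome_length = 20000, coverage = 30),
      dir = file.path(tempdir(), "emsnv_shared_sim"))
  }
  .shared$sim
}
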