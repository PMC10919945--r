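#' Read filters applied before pileup construction
#'
#' Defaults follow common short-read caller practice: discard unmapped,
#' secondary, supplementary and duplicate-flagged alignments, require
#' mapping quality >= 20, and drop individual base observations with
#' Phred base quality < 13 or base N.
#'
#' @param min_mapq Minimum mapping quality for an alignment to contribute.
#' @param min_baseq Minimum base quality for an observation to be retained.
#' @param drop_duplicates,drop_secondary,drop_supplementary Logical flags.
#' @return A `read_filter_config` list.
#' @export
read_filter_config <- function(min_mapq = 20L, min_baseq = 13L,
                               drop_duplicates = TRUE,
                               drop_secondary = TRUE,
                               drop_supplementary = TRUE) {
  structure(list(min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq),
                 drop_duplicates = isTRUE(drop_duplicates),
                 drop_secondary = isTRUE(drop_secondary),
                 drop_supplementary = isTRUE(drop_supplementary)),
            class = "read_filter_config")
}

#' A window of reference sequence
#'
#' Coordinates are 0-based half-open internally (BAM/BED convention); the
#' VCF writer converts to 1-based on output.
#'
#' @param contig Contig name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param bases Uppercase nucleotide string over A,C,G,T,N of length
#'   `end - start`.
#' @return A `reference_window` object.
#' @export
reference_window <- function(contig, start, end, bases) {
  bases <- toupper(as.character(bases))
  if (nchar(bases) != end - start)
    stop("length(bases) must equal end - start")
  if (start >= end) stop("start must be < end")
  if (grepl("[^ACGTN]", bases)) stop("bases must be over {A,C,G,T,N}")
  structure(list(contig = as.character(contig), start = as.integer(start),
                 end = as.integer(end), bases = bases),
            class = "reference_window")
}

#' Load a reference window from an indexed FASTA
#'
#' @param fasta Path to a FASTA file; a `.fai` index is created if missing.
#' @param contig Contig to load; default the first contig in the index.
#' @param start,end Optional 0-based half-open bounds (default whole contig).
#' @return A [reference_window()].
#' @export
read_reference_window <- function(fasta, contig = NULL, start = NULL, end = NULL) {
  if (!file.exists(fasta)) stop("reference FASTA not found: ", fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  si <- Rsamtools::seqinfo(fa)
  if (is.null(contig)) contig <- GenomeInfoDb::seqnames(si)[1]
  if (!contig %in% GenomeInfoDb::seqnames(si))
    stop("contig '", contig, "' absent from reference")
  clen <- GenomeInfoDb::seqlengths(si)[[contig]]
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- clen
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  seq <- Rsamtools::scanFa(fa, gr)
  reference_window(contig, start, end, as.character(seq[[1L]]))
}

#' Parse a samtools-style region string
#'
#' `"contig:start-end"` with 1-based inclusive coordinates; returns the
#' 0-based half-open equivalent. `"contig"` alone selects the whole contig.
#'
#' @param region Region string.
#' @return List with `contig`, `start`, `end` (`end` may be NULL).
#' @export
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+)(?::([0-9,]+)-([0-9,]+))?$", region))[[1]]
  if (length(m) == 0L || m[2] == "") stop("malformed region: ", region)
  if (m[3] == "") return(list(contig = m[2], start = NULL, end = NULL))
  s <- as.integer(gsub(",", "", m[3])); e <- as.integer(gsub(",", "", m[4]))
  if (s < 1L || e < s) stop("malformed region: ", region)
  list(contig = m[2], start = s - 1L, end = e)
}

# Ensure a coordinate-sorted, indexed BAM; accepts SAM or BAM input.
prepare_bam <- function(path, work_dir = tempdir()) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- file.path(work_dir, paste0(tools::file_path_sans_ext(basename(path)), "_conv"))
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  sorted <- suppressWarnings(Rsamtools::sortBam(
    path, file.path(work_dir, paste0(basename(path), "_sorted"))))
  Rsamtools::indexBam(sorted)
  sorted
}

#' Build per-locus, per-learner nucleotide pileups
#'
#' Converts aligned reads over a reference window into the EM's sufficient
#' statistics: for every covered reference position with a non-N reference
#' base, an integer count of observed A/C/G/T split by learner (base-quality
#' bin). Only read-to-reference match columns contribute; insertions are
#' skipped and deletion columns contribute no observation. Alignments
#' failing the read filters contribute nothing; observations below
#' `min_baseq` or with base N are dropped.
#'
#' @param alignments Path to a coordinate-sorted SAM or BAM file.
#' @param reference A [reference_window()] (or FASTA path, loaded whole for
#'   its first contig).
#' @param filters A [read_filter_config()].
#' @param spec A [learner_spec()].
#' @return A `locus_pileups` object: parallel vectors `pos` (0-based),
#'   `ref_base`, `depth`, and an integer `counts` matrix with one column per
#'   (learner, base) pair in learner-major A,C,G,T order.
#' @export
build_pileups <- function(alignments, reference,
                          filters = read_filter_config(),
                          spec = learner_spec()) {
  if (is.character(reference)) reference <- read_reference_window(reference)
  stopifnot(inherits(reference, "reference_window"))
  bam <- prepare_bam(alignments)

  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (filters$drop_secondary) FALSE else NA,
    isSupplementaryAlignment = if (filters$drop_supplementary) FALSE else NA,
    isDuplicate = if (filters$drop_duplicates) FALSE else NA)
  which <- GenomicRanges::GRanges(
    reference$contig,
    IRanges::IRanges(reference$start + 1L, reference$end))
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = filters$min_mapq,
                                   what = c("seq", "qual"), which = which)
  bamheader <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!reference$contig %in% names(bamheader))
    stop("contig '", reference$contig, "' absent from alignment header")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)

  if (length(aln) == 0L) return(empty_pileups(reference$contig, spec))

  seqs <- GenomicAlignments::sequenceLayer(
    S4Vectors::mcols(aln)$seq, GenomicAlignments::cigar(aln),
    from = "query", to = "reference")
  quals <- GenomicAlignments::sequenceLayer(
    Biostrings::BStringSet(S4Vectors::mcols(aln)$qual),
    GenomicAlignments::cigar(aln),
    from = "query", to = "reference", D.letter = "!", N.letter = "!")

  w <- Biostrings::width(seqs)
  pos1 <- rep.int(BiocGenerics::start(aln), w) + sequence(w) - 1L
  base <- unlist(strsplit(as.character(seqs), "", fixed = TRUE), use.names = FALSE)
  qv <- as.integer(unlist(lapply(as.character(quals), charToRaw),
                          use.names = FALSE)) - 33L

  base_idx <- match(base, BASES)                    # NA for -, N
  ref_chars <- strsplit(reference$bases, "", fixed = TRUE)[[1]]
  in_window <- pos1 > reference$start & pos1 <= reference$end
  keep <- !is.na(base_idx) & qv >= filters$min_baseq & in_window
  pos1 <- pos1[keep]; base_idx <- base_idx[keep]; qv <- qv[keep]
  ref_at <- ref_chars[pos1 - reference$start]
  keep2 <- ref_at != "N"
  pos1 <- pos1[keep2]; base_idx <- base_idx[keep2]; qv <- qv[keep2]

  if (length(pos1) == 0L) return(empty_pileups(reference$contig, spec))

  lid <- assign_learner(qv, spec = spec)            # 0-based
  col <- 4L * lid + base_idx                        # 1..4L
  dt <- data.table::data.table(pos1 = pos1, col = col)
  tallies <- dt[, .N, by = c("pos1", "col")]
  upos <- sort(unique(tallies$pos1))
  L <- spec$n_learners
  counts <- matrix(0L, nrow = length(upos), ncol = 4L * L,
                   dimnames = list(NULL, learner_base_names(spec)))
  counts[cbind(match(tallies$pos1, upos), tallies$col)] <- tallies$N

  structure(list(contig = reference$contig,
                 pos = upos - 1L,                    # back to 0-based
                 ref_base = ref_chars[upos - reference$start],
                 counts = counts,
                 depth = as.integer(rowSums(counts)),
                 spec = spec),
            class = "locus_pileups")
}

learner_base_names <- function(spec) {
  as.vector(t(outer(seq_len(spec$n_learners) - 1L, BASES,
                    function(j, b) paste0("L", j, ":", b))))
}

empty_pileups <- function(contig, spec) {
  structure(list(contig = contig, pos = integer(0), ref_base = character(0),
                 counts = matrix(0L, 0L, 4L * spec$n_learners,
                                 dimnames = list(NULL, learner_base_names(spec))),
                 depth = integer(0), spec = spec),
            class = "locus_pileups")
}

#' Construct a `locus_pileups` object from explicit counts
#'
#' Mainly for tests, harnesses and programmatic use; checks the invariants
#' (non-negative counts, depth consistency, no N reference bases).
#'
#' @param contig Contig name.
#' @param pos Integer vector of 0-based positions.
#' @param ref_base Character vector over A,C,G,T.
#' @param counts Integer matrix, one row per locus, `4 * n_learners` columns
#'   in learner-major A,C,G,T order.
#' @param spec A [learner_spec()] consistent with `ncol(counts)`.
#' @return A `locus_pileups` object.
#' @export
pileups_from_counts <- function(contig, pos, ref_base, counts,
                                spec = learner_spec()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  stopifnot(length(pos) == nrow(counts), length(ref_base) == nrow(counts),
            ncol(counts) == 4L * spec$n_learners, all(counts >= 0L),
            all(ref_base %in% BASES))
  colnames(counts) <- learner_base_names(spec)
  structure(list(contig = as.character(contig), pos = as.integer(pos),
                 ref_base = as.character(ref_base), counts = counts,
                 depth = as.integer(rowSums(counts)), spec = spec),
            class = "locus_pileups")
}

#' @export
print.locus_pileups <- function(x, ...) {
  cat("locus_pileups:", length(x$pos), "loci on", x$contig,
      "|", x$spec$n_learners, "learners | total depth", sum(x$depth), "\n")
  invisible(x)
}

#' Deterministic text dump of a pileup set
#'
#' One TSV line per locus (`contig pos ref depth count...`); identical input
#' files yield byte-identical dumps, which the test suite asserts.
#'
#' @param x A `locus_pileups` object.
#' @return Character vector of lines.
#' @export
format_pileups <- function(x) {
  if (length(x$pos) == 0L) return(character(0))
  paste(x$contig, x$pos, x$ref_base, x$depth,
        apply(x$counts, 1L, paste, collapse = ","), sep = "\t")
}

#' Fraction of non-reference observations at each locus
#'
#' @param x A `locus_pileups` object.
#' @return Numeric vector in `[0,1]`; 0 at zero-depth loci.
#' @export
alt_fraction <- function(x) {
  L <- x$spec$n_learners
  ref_idx <- match(x$ref_base, BASES)
  ref_cols <- outer(4L * (seq_len(L) - 1L), ref_idx, "+")  # L x n
  ref_counts <- vapply(seq_along(x$pos), function(i)
    sum(x$counts[i, ref_cols[, i]]), numeric(1))
  ifelse(x$depth > 0L, (x$depth - ref_counts) / x$depth, 0)
}
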