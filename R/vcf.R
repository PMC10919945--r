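# ALT field and GT string for a non-reference diploid genotype.
# Returns list(alt = "C" or "C,T", gt = "0/1" | "1/1" | "1/2").
genotype_to_alt_gt <- function(ref, genotype) {
  al <- sort(strsplit(genotype, "")[[1]])
  if (all(al == ref)) stop("genotype equals homozygous reference")
  if (al[1] == al[2]) {
    list(alt = al[1], gt = "1/1")
  } else if (ref %in% al) {
    list(alt = setdiff(al, ref), gt = "0/1")
  } else {
    list(alt = paste(al, collapse = ","), gt = "1/2")
  }
}

vcf_header <- function(sample_name, contigs, with_info = TRUE) {
  c("##fileformat=VCFv4.2",
    "##source=emsnv",
    sprintf("##contig=<ID=%s,length=%d>", contigs$name, contigs$length),
    if (with_info) c(
      '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at the locus">',
      '##INFO=<ID=AF,Number=1,Type=Float,Description="Fraction of reads with a non-reference base">',
      '##INFO=<ID=ENT,Number=1,Type=Float,Description="Shannon entropy (bits) of the 10-class genotype posterior">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
}

#' Write SNV candidates as a VCF 4.2 file
#'
#' One record per candidate; 0-based positions convert to the VCF's
#' 1-based POS. QUAL is the Phred-scaled posterior confidence
#' `-10 log10(1 - P(decided class))`, capped at 99. INFO carries depth
#' (DP), alternate-base fraction (AF) and posterior entropy in bits (ENT);
#' the single FORMAT field is GT (`0/1` het ref/alt, `1/1` hom alt, `1/2`
#' het with two alternate alleles).
#'
#' @param candidates A `candidate_variants` data.frame (from
#'   [call_candidates()]), sorted by (contig, pos).
#' @param path Output path.
#' @param sample_name Sample column name.
#' @param contigs data.frame with `name` and `length` for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(candidates, path, sample_name = "SAMPLE",
                      contigs) {
  n <- nrow(candidates)
  if (n > 1L) {
    o <- order(candidates$contig, candidates$pos)
    if (!identical(o, seq_len(n))) stop("candidates must be sorted by (contig, pos)")
  }
  lines <- vcf_header(sample_name, contigs)
  if (n > 0L) {
    ag <- lapply(seq_len(n), function(i)
      genotype_to_alt_gt(candidates$ref[i], candidates$genotype[i]))
    qual <- pmin(99, -10 * log10(pmax(1 - candidates$post_prob, 1e-10)))
    rec <- paste(candidates$contig, candidates$pos + 1L, ".",
                 candidates$ref, vapply(ag, `[[`, "", "alt"),
                 sprintf("%.4g", qual), "PASS",
                 sprintf("DP=%d;AF=%.17g;ENT=%.17g", candidates$depth,
                         candidates$alt_fraction, candidates$entropy_bits),
                 "GT", vapply(ag, `[[`, "", "gt"), sep = "\t")
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

# Minimal truth VCF (QUAL/INFO empty, GT only); used by the simulator.
write_truth_vcf <- function(truth, path, contig_name, contig_length) {
  lines <- vcf_header("TRUTH", data.frame(name = contig_name,
                                          length = contig_length),
                      with_info = FALSE)
  if (nrow(truth) > 0L) {
    ag <- lapply(seq_len(nrow(truth)), function(i)
      genotype_to_alt_gt(truth$ref[i], truth$genotype[i]))
    lines <- c(lines, paste(contig_name, truth$pos + 1L, ".", truth$ref,
                            vapply(ag, `[[`, "", "alt"), ".", "PASS", ".",
                            "GT", vapply(ag, `[[`, "", "gt"), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read the SNV records of a VCF into a genotype table
#'
#' Parses a VCF (plain or bgzipped) with `VariantAnnotation`, keeps
#' biallelic/triallelic SNV records (all alleles length 1), and resolves
#' each first-sample GT into an unordered diploid genotype. Records with
#' missing or unparseable genotypes are skipped and counted.
#'
#' @param path VCF path.
#' @return data.frame with `chrom`, `pos` (1-based), `ref`, `genotype`,
#'   plus attributes `n_skipped` (malformed/missing GT) and `n_non_snv`.
#' @export
read_snvs <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt_chr <- as(altl, "CharacterList")
  is_snv <- nchar(ref) == 1L &
    vapply(alt_chr, function(a) length(a) >= 1L && all(nchar(a) == 1L), logical(1))
  gt <- if ("GT" %in% rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf))))
    VariantAnnotation::geno(vcf)$GT[, 1L] else rep(NA_character_, length(ref))

  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  keep <- which(is_snv)
  out_chrom <- character(0); out_pos <- integer(0)
  out_ref <- character(0); out_gt <- character(0)
  n_skipped <- 0L
  for (i in keep) {
    alleles <- c(ref[i], as.character(alt_chr[[i]]))
    gti <- gt[i]
    if (is.na(gti) || !grepl("^[0-9]+[/|][0-9]+$", gti)) {
      n_skipped <- n_skipped + 1L
      next
    }
    idx <- as.integer(strsplit(gti, "[/|]")[[1]]) + 1L
    if (any(idx > length(alleles))) { n_skipped <- n_skipped + 1L; next }
    pair <- sort(alleles[idx])
    out_chrom <- c(out_chrom, chrom[i]); out_pos <- c(out_pos, pos[i])
    out_ref <- c(out_ref, ref[i])
    out_gt <- c(out_gt, paste(pair, collapse = ""))
  }
  out <- data.frame(chrom = out_chrom, pos = out_pos, ref = out_ref,
                    genotype = out_gt, stringsAsFactors = FALSE)
  info <- VariantAnnotation::info(vcf)
  for (fld in c("DP", "AF", "ENT")) {
    if (fld %in% colnames(info) && nrow(out) > 0L) {
      vals <- info[[fld]]
      m <- match(paste(out$chrom, out$pos), paste(chrom, pos))
      out[[tolower(fld)]] <- unlist(vals)[m]
    }
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_non_snv") <- sum(!is_snv)
  out
}

# Restrict a genotype table to BED regions (path or GRanges).
restrict_to_regions <- function(df, regions) {
  if (is.null(regions) || nrow(df) == 0L) return(df)
  gr <- if (is.character(regions)) rtracklayer::import(regions) else regions
  pts <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
  df[IRanges::overlapsAny(pts, gr), , drop = FALSE]
}

#' Genotype-aware precision/recall/F1 of a call set against a truth set
#'
#' Matching is at identical (chrom, pos): a call is a true positive iff its
#' genotype is identical to the truth genotype there; a call at a truth
#' locus with the wrong genotype counts as both a false positive and a
#' false negative. Precision is the fraction of calls that are true,
#' recall the fraction of truth variants called, F1 their harmonic mean.
#' With zero calls, precision is reported as 1.0 with an explicit
#' `zero_calls` flag.
#'
#' @param calls VCF path or data.frame (`chrom`, `pos` 1-based, `genotype`).
#' @param truth VCF path or data.frame in the same form.
#' @param regions Optional confident-region mask: BED path or `GRanges`
#'   (evaluation restricted to calls and truths inside it).
#' @return An `eval_report` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `zero_calls`, `n_skipped_calls`, `n_skipped_truth`.
#' @export
evaluate_calls <- function(calls, truth, regions = NULL) {
  sk_c <- 0L; sk_t <- 0L
  if (is.character(calls)) {
    calls <- read_snvs(calls); sk_c <- attr(calls, "n_skipped")
  }
  if (is.character(truth)) {
    truth <- read_snvs(truth); sk_t <- attr(truth, "n_skipped")
  }
  calls <- restrict_to_regions(calls, regions)
  truth <- restrict_to_regions(truth, regions)
  calls <- calls[!duplicated(paste(calls$chrom, calls$pos)), , drop = FALSE]
  truth <- truth[!duplicated(paste(truth$chrom, truth$pos)), , drop = FALSE]

  ckey <- paste(calls$chrom, calls$pos)
  tkey <- paste(truth$chrom, truth$pos)
  m <- match(ckey, tkey)
  tp <- sum(!is.na(m) & calls$genotype == truth$genotype[m])
  fp <- nrow(calls) - tp
  fn <- nrow(truth) - tp

  zero_calls <- (tp + fp) == 0L
  precision <- if (zero_calls) 1.0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) 1.0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, zero_calls = zero_calls,
                 n_skipped_calls = sk_c, n_skipped_truth = sk_t),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: TP=%d FP=%d FN=%d | precision=%.4f recall=%.4f f1=%.4f%s\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1,
              if (x$zero_calls) " [no calls]" else ""))
  invisible(x)
}
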