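#' Run the full two-step caller: pileup, EM genotyping, filtering, VCF
#'
#' Step 1 stratifies the reads into base-quality learners, fits the
#' unsupervised EM ensemble model per window, and marks SNV candidates
#' where the decided genotype differs from the reference. Step 2 applies
#' the depth-5 decision-tree filter to remove untrue candidates
#' (`no_filter = TRUE` stops after step 1). A JSON run manifest with the
#' resolved configuration, input checksums and per-stage wall time is
#' written next to the VCF.
#'
#' @param ref Reference FASTA path (indexed; index created if missing).
#' @param aln Coordinate-sorted SAM or BAM path.
#' @param out Output VCF path.
#' @param region Optional samtools-style region string
#'   `"contig:start-end"` (1-based inclusive).
#' @param filters A [read_filter_config()].
#' @param spec A [learner_spec()].
#' @param config An [em_config()].
#' @param no_filter Skip the decision-tree filter (EM-alone mode).
#' @param model A `filter_model`, a path to one, or NULL for
#'   [default_filter_model()].
#' @param window_size EM fitting window in bp (default 1e6).
#' @param sample_name VCF sample column name.
#' @param manifest Write the JSON run manifest (default TRUE).
#' @return List with `vcf`, `candidates` (pre-filter), `kept`
#'   (post-filter), `fits` (per-window `em_fit`s), `manifest` path.
#' @export
run_call <- function(ref, aln, out, region = NULL,
                     filters = read_filter_config(),
                     spec = learner_spec(), config = em_config(),
                     no_filter = FALSE, model = NULL,
                     window_size = 1e6, sample_name = "SAMPLE",
                     manifest = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (!file.exists(paste0(ref, ".fai"))) Rsamtools::indexFa(ref)
  fai <- Rsamtools::scanFaIndex(ref)
  contig_df <- data.frame(name = as.character(GenomeInfoDb::seqnames(fai)),
                          length = BiocGenerics::width(fai),
                          stringsAsFactors = FALSE)
  if (!is.null(region)) {
    rg <- parse_region(region)
    if (!rg$contig %in% contig_df$name)
      stop("region contig '", rg$contig, "' absent from reference")
    clen <- contig_df$length[contig_df$name == rg$contig]
    spans <- data.frame(contig = rg$contig,
                        start = if (is.null(rg$start)) 0L else rg$start,
                        end = if (is.null(rg$end)) clen else min(rg$end, clen))
  } else {
    spans <- data.frame(contig = contig_df$name, start = 0L,
                        end = contig_df$length, stringsAsFactors = FALSE)
  }

  all_cands <- list()
  fits <- list()
  t_pileup <- 0; t_em <- 0
  for (s in seq_len(nrow(spans))) {
    wstarts <- seq(spans$start[s], spans$end[s] - 1L, by = window_size)
    for (ws in wstarts) {
      we <- min(ws + window_size, spans$end[s])
      rw <- read_reference_window(ref, spans$contig[s], ws, we)
      ta <- proc.time()[["elapsed"]]
      pu <- build_pileups(aln, rw, filters = filters, spec = spec)
      tb <- proc.time()[["elapsed"]]; t_pileup <- t_pileup + (tb - ta)
      if (length(pu$pos) == 0L) next
      fit <- run_em(pu, config = config)
      t_em <- t_em + (proc.time()[["elapsed"]] - tb)
      fits[[length(fits) + 1L]] <- fit
      all_cands[[length(all_cands) + 1L]] <- call_candidates(pu, fit)
    }
  }
  candidates <- if (length(all_cands)) do.call(rbind, all_cands) else
    call_candidates(empty_pileups(spans$contig[1], spec),
                    list(posteriors = matrix(numeric(0), 0, 10),
                         decided = integer(0), entropy_bits = numeric(0)))
  candidates <- candidates[order(candidates$contig, candidates$pos), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  class(candidates) <- c("candidate_variants", "data.frame")

  if (no_filter) {
    kept <- candidates
  } else {
    fm <- if (is.null(model)) default_filter_model()
          else if (is.character(model)) read_filter_model(model)
          else model
    kept <- apply_filter(candidates, fm)
  }
  write_vcf(kept, out, sample_name = sample_name, contigs = contig_df)

  manifest_path <- NULL
  if (isTRUE(manifest)) {
    manifest_path <- paste0(out, ".manifest.json")
    jsonlite::write_json(list(
      tool = "emsnv",
      version = as.character(tryCatch(utils::packageVersion("emsnv"),
                                      error = function(e) "0.0.0")),
      config = unclass(config), filters = unclass(filters),
      learner_breaks = spec$breaks, region = region,
      window_size = window_size, no_filter = no_filter,
      inputs = as.list(tools::md5sum(c(ref = ref, aln = aln))),
      seed = config$seed,
      n_candidates = nrow(candidates), n_kept = nrow(kept),
      em_iterations = vapply(fits, function(f) f$n_iters, integer(1)),
      wall_time_sec = list(pileup = t_pileup, em = t_em,
                           total = proc.time()[["elapsed"]] - t0)),
      manifest_path, auto_unbox = TRUE, digits = NA)
  }
  list(vcf = out, candidates = candidates, kept = kept, fits = fits,
       manifest = manifest_path)
}

#' Simulate a dataset (thin wrapper used by the command line)
#'
#' @param seed Master seed.
#' @param dir Output directory.
#' @param ... Overrides passed to [sim_config()].
#' @return See [simulate_dataset()].
#' @export
run_simulate <- function(seed = 1L, dir = tempfile("sim"), ...) {
  simulate_dataset(sim_config(seed = seed, ...), dir = dir)
}

#' Train a candidate filter from an alignment and a truth VCF
#'
#' Runs step 1 of the caller on the alignment, labels the resulting
#' candidates against the truth VCF (genotype-aware), and fits the depth-5
#' tree.
#'
#' @param ref,aln Reference FASTA and SAM/BAM paths.
#' @param truth_vcf Truth VCF path.
#' @param out_model Optional path to persist the model
#'   ([write_filter_model()]).
#' @param region,filters,spec,config As in [run_call()].
#' @param seed Recorded in the model metadata.
#' @return The `filter_model`.
#' @export
run_train_filter <- function(ref, aln, truth_vcf, out_model = NULL,
                             region = NULL, filters = read_filter_config(),
                             spec = learner_spec(), config = em_config(),
                             seed = 1L) {
  res <- run_call(ref, aln, out = tempfile(fileext = ".vcf"),
                  region = region, filters = filters, spec = spec,
                  config = config, no_filter = TRUE, manifest = FALSE)
  labels <- label_candidates(res$candidates, truth_vcf)
  model <- train_filter(extract_features(res$candidates), labels, seed = seed)
  if (!is.null(out_model)) write_filter_model(model, out_model)
  model
}

#' Evaluate a call VCF against a truth VCF
#'
#' @param calls,truth VCF paths.
#' @param regions Optional confident-region BED path.
#' @param json_out Optional path for a JSON copy of the report.
#' @return An `eval_report`.
#' @export
run_eval <- function(calls, truth, regions = NULL, json_out = NULL) {
  rep <- evaluate_calls(calls, truth, regions = regions)
  if (!is.null(json_out))
    jsonlite::write_json(unclass(rep), json_out, auto_unbox = TRUE,
                         digits = NA)
  rep
}
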