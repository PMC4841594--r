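# End-to-end orchestration: one config (YAML or list) drives
# simulate -> call -> search/parse -> footprint -> enrich -> cobra ->
# profile, with per-stage outputs and a single summary JSON.

.validate_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

.one_of <- function(block, real_keys, where) {
  has_sim <- !is.null(block$simulate)
  has_real <- any(real_keys %in% names(block))
  if (has_sim && has_real) {
    stop(where, ": give either a simulate block or real inputs, not both",
         call. = FALSE)
  }
  if (!has_sim && !has_real) {
    stop(where, ": needs a simulate block or real inputs", call. = FALSE)
  }
  has_sim
}

#' A deterministic demo COBRA locus
#'
#' A 140-bp amplicon whose only CpG sits inside a GGACG context, so that
#' complete conversion of the unmethylated allele creates a FokI site
#' (GGATG) while the methylated allele retains GGACG — the textbook
#' TG-class (unmethylation-indicating) configuration.  The flanks contain
#' no cytosine, so the assayed CpG is the amplicon's only one and the
#' flanking primers are CpG-free by construction.
#'
#' @return A list: `amplicon`, `enzyme` (`"FokI"`), `forward_primer`,
#'   `reverse_primer` (annealing to the converted top strand).
#' @export
demo_cobra_locus <- function() {
  set.seed(424241L)
  bg <- function(n) paste(sample(c("A", "T", "G"), n, replace = TRUE),
                          collapse = "")
  amplicon <- paste0(bg(60L), "GGACG", bg(75L))
  conv <- bisulfite_convert(amplicon)  # flanks are C-free: unchanged
  list(amplicon = amplicon, enzyme = "FokI",
       forward_primer = substr(conv, 1, 20),
       reverse_primer = .revcomp(substr(conv, nchar(conv) - 19, nchar(conv))))
}

.stage_genomes <- function(block, params, seed, out) {
  if (.one_of(block, c("fasta_a", "fasta_b"), "genomes")) {
    sim <- .validate_keys(block$simulate,
                          c("n_elements", "element_length",
                            "element_identity", "flank_length"),
                          "genomes.simulate")
    cfg <- sim_config(seed = seed,
                      n_elements = sim$n_elements %||% 3L,
                      element_length = sim$element_length %||% 150L,
                      element_identity = sim$element_identity %||% 0.85,
                      flank_length = sim$flank_length %||% 300L)
    gp <- generate_genome_pair(cfg)
    ga <- gp$genome_a; gb <- gp$genome_b; truth <- gp$truth
  } else {
    .validate_keys(block, c("fasta_a", "fasta_b"), "genomes")
    ga <- unname(read_fasta(block$fasta_a)[1])
    gb <- unname(read_fasta(block$fasta_b)[1])
    truth <- NULL
  }
  el <- find_conserved_elements(ga, gb, params)
  hdr <- sprintf("ecrfoot %s seed=%d min_length=%d min_identity=%g",
                 as.character(packageVersion("ecrfoot")), seed,
                 params$min_length, params$min_identity)
  .write_tsv(el, file.path(out, "elements.tsv"), hdr)
  if (nrow(el)) {
    write_bed(data.frame(chrom = "ref", start = el$ref_start,
                         end = el$ref_end, name = el$id,
                         score = round(100 * el$identity)),
              file.path(out, "elements.bed"))
  }
  list(elements = el, truth = truth)
}

.stage_orthologs <- function(block, params, motif_lib, min_fp, seed, out) {
  if (.one_of(block, "dir", "orthologs")) {
    .validate_keys(block$simulate, c("compendium", "substitution_rate"),
                   "orthologs.simulate")
    comp <- synthetic_s1_compendium(
      seed = seed,
      substitution_rate = block$simulate$substitution_rate %||% 0.05)
    sets <- comp$sets
    reference <- comp$reference
  } else {
    .validate_keys(block, c("dir", "reference"), "orthologs")
    sets <- read_ortholog_sets(block$dir)
    reference <- block$reference %||% names(sets[[1]])[1]
  }
  summ <- ortholog_set_summary(sets)
  hdr <- sprintf("ecrfoot %s seed=%d",
                 as.character(packageVersion("ecrfoot")), seed)
  .write_tsv(summ$per_ecr, file.path(out, "presence.tsv"), hdr)
  # footprints on the reference-anchored alignment of each set
  fps <- list()
  for (e in names(sets)) {
    if (length(sets[[e]]) < 2 || !reference %in% names(sets[[e]])) next
    aln <- align_ortholog_set(sets[[e]], reference, params)
    fp <- find_invariant_regions(aln, min_fp)
    if (nrow(fp)) fps[[e]] <- cbind(ecr = e, fp, stringsAsFactors = FALSE)
  }
  fps <- if (length(fps)) do.call(rbind, fps) else NULL
  if (!is.null(fps)) .write_tsv(fps, file.path(out, "footprints.tsv"), hdr)
  counts <- scan_ortholog_sets(sets, motif_lib)
  mfm <- motif_frequency_matrix(counts, motif_lib)
  .write_tsv(mfm, file.path(out, "motif_matrix.tsv"), hdr)
  list(summary = summ, footprints = fps, motif_matrix = mfm, sets = sets)
}

.stage_cobra <- function(block, call_cfg, seed, out) {
  if (.one_of(block, "bands", "cobra")) {
    sim <- .validate_keys(block$simulate,
                          c("methylation_fraction", "normal_fraction",
                            "n_molecules", "noise_sd", "n_replicates"),
                          "cobra.simulate")
    locus <- demo_cobra_locus()
    assay <- cobra_assay(locus$amplicon, locus$enzyme, "demo_locus")
    nrep <- sim$n_replicates %||% 3L
    qf <- function(frac, salt) {
      vapply(seq_len(nrep), function(r) {
        gel <- generate_cobra_gel(locus$amplicon, frac, locus$enzyme,
                                  n_molecules = sim$n_molecules %||% 10000L,
                                  noise_sd = sim$noise_sd %||% 0.02,
                                  seed = derive_seed(seed, salt + r))
        quantify_methylation(gel, assay)
      }, 0)
    }
    sample_reps <- qf(sim$methylation_fraction %||% 0.6, 300L)
    normal_reps <- qf(sim$normal_fraction %||% 0.05, 400L)
  } else {
    .validate_keys(block, c("bands", "amplicon_fasta", "enzyme",
                            "normal_bands"), "cobra")
    amplicon <- unname(read_fasta(block$amplicon_fasta)[1])
    assay <- cobra_assay(amplicon, block$enzyme, "locus")
    sample_reps <- vapply(block$bands, function(p) {
      quantify_methylation(read_band_table(p), assay)
    }, 0)
    normal_reps <- vapply(block$normal_bands, function(p) {
      quantify_methylation(read_band_table(p), assay)
    }, 0)
  }
  call <- call_delta(sample_reps, normal_reps,
                     alpha = call_cfg$alpha %||% 0.05,
                     min_delta = call_cfg$min_delta %||% 10)
  rep <- data.frame(
    locus = assay$locus, enzyme = assay$enzyme, class = assay$class,
    frags_u = paste(assay$frags_u, collapse = ","),
    frags_m = paste(assay$frags_m, collapse = ","),
    sample_percent = mean(sample_reps), normal_percent = mean(normal_reps),
    delta = call$delta, p_value = call$p_value, verdict = call$verdict,
    stringsAsFactors = FALSE)
  .write_tsv(rep, file.path(out, "cobra.tsv"),
             sprintf("ecrfoot %s seed=%d alpha=%g min_delta=%g",
                     as.character(packageVersion("ecrfoot")), seed,
                     call_cfg$alpha %||% 0.05, call_cfg$min_delta %||% 10))
  list(assay = assay, sample = sample_reps, normal = normal_reps,
       call = call)
}

.stage_epigenome <- function(block, breadth_cfg, seed, out) {
  if (.one_of(block, c("ecr_bed", "track_dir"), "epigenome")) {
    sim <- .validate_keys(block$simulate, c("n_ecrs", "n_tissues"),
                          "epigenome.simulate")
    n_ecr <- sim$n_ecrs %||% 6L
    n_ts <- sim$n_tissues %||% 4L
    ecrs <- data.frame(chrom = "chr7",
                       start = 1000L + 500L * (seq_len(n_ecr) - 1L),
                       end = 1000L + 500L * (seq_len(n_ecr) - 1L) + 200L,
                       name = sprintf("ECR%d", seq_len(n_ecr)))
    set.seed(derive_seed(seed, 23L))
    states <- c("ACTIVE", "POISED", "ACETYL_ONLY", "NONE")
    assign <- expand.grid(ecr = ecrs$name,
                          tissue = sprintf("tissue%d", seq_len(n_ts)),
                          stringsAsFactors = FALSE)
    assign$state <- sample(states, nrow(assign), replace = TRUE)
    assign$hypomethylated <- assign$state %in% c("ACTIVE", "POISED") &
      runif(nrow(assign)) < 0.6
    tr <- generate_tissue_tracks(ecrs, assign, seed = seed)
    tracks <- tr$tracks
  } else {
    .validate_keys(block, c("ecr_bed", "track_dir"), "epigenome")
    ecrs <- read_bed(block$ecr_bed)
    tracks <- read_track_dir(block$track_dir)
  }
  prof <- profile_enhancers(ecrs, tracks)
  breadth <- call_breadth(prof, criterion = breadth_cfg$criterion %||% "either")
  hdr <- sprintf("ecrfoot %s seed=%d criterion=%s",
                 as.character(packageVersion("ecrfoot")), seed,
                 breadth_cfg$criterion %||% "either")
  .write_tsv(prof, file.path(out, "enhancer_states.tsv"), hdr)
  .write_tsv(breadth, file.path(out, "breadth.tsv"), hdr)
  list(profile = prof, breadth = breadth)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes the configured stages in dependency order (conserved-element
#' calling, ortholog presence + footprinting + motif enrichment, COBRA
#' methylation, enhancer profiling), writes every stage's tables into the
#' output directory with provenance headers, and aggregates a summary JSON.
#' Every stage accepts either a `simulate:` block (synthetic inputs with
#' known truth) or real input paths — never both.
#'
#' @param config Path to a YAML file, or an equivalent nested list.  Top
#'   keys: `seed`, `output_dir`, `conservation`, `footprint`, `motifs`,
#'   `cobra_call`, `breadth`, and the stage blocks `genomes`, `orthologs`,
#'   `cobra`, `epigenome` (any subset).
#' @param output_dir Overrides `config$output_dir`.
#' @return Invisibly, a list with each stage's in-memory results and
#'   `summary` (also written to `summary.json`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .validate_keys(config, c("seed", "output_dir", "conservation", "footprint",
                           "motifs", "cobra_call", "breadth", "genomes",
                           "orthologs", "cobra", "epigenome"), "config")
  out <- output_dir %||% config$output_dir %||% stop("no output_dir given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  pc <- config$conservation %||% list()
  .validate_keys(pc, c("min_length", "min_identity", "match", "mismatch",
                       "gap_open", "gap_extend", "seed_word_length",
                       "min_hit_score"), "conservation")
  params <- do.call(conservation_params, pc)
  .validate_keys(config$motifs %||% list(), c("degenerate_ebox", "library"),
                 "motifs")
  motif_lib <- if (!is.null(config$motifs$library)) {
    lib <- read.delim(config$motifs$library, stringsAsFactors = FALSE)
    stopifnot(all(c("name", "pattern") %in% names(lib)))
    lib
  } else {
    default_motif_library(isTRUE(config$motifs$degenerate_ebox))
  }
  min_fp <- (config$footprint %||% list())$min_footprint_length %||% 6L
  res <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!is.null(config$genomes)) {
    res$genomes <- run_stage("genomes", function()
      .stage_genomes(config$genomes, params, seed, out))
  }
  if (!is.null(config$orthologs)) {
    res$orthologs <- run_stage("orthologs", function()
      .stage_orthologs(config$orthologs, params, motif_lib, min_fp, seed, out))
  }
  if (!is.null(config$cobra)) {
    res$cobra <- run_stage("cobra", function()
      .stage_cobra(config$cobra, config$cobra_call %||% list(), seed, out))
  }
  if (!is.null(config$epigenome)) {
    res$epigenome <- run_stage("epigenome", function()
      .stage_epigenome(config$epigenome, config$breadth %||% list(), seed, out))
  }
  summary <- list(
    version = as.character(packageVersion("ecrfoot")),
    seed = seed,
    ecr_count = if (!is.null(res$genomes)) nrow(res$genomes$elements) else NULL,
    n_ortholog_sets = if (!is.null(res$orthologs))
      res$orthologs$summary$n_sets else NULL,
    mean_species_per_ecr = if (!is.null(res$orthologs))
      res$orthologs$summary$mean_species_per_ecr else NULL,
    n_enriched_cells = if (!is.null(res$orthologs))
      sum(res$orthologs$motif_matrix$enriched) else NULL,
    methylation_verdict = if (!is.null(res$cobra))
      res$cobra$call$verdict else NULL,
    breadth_calls = if (!is.null(res$epigenome))
      as.list(table(res$epigenome$breadth$call)) else NULL)
  summary <- summary[!vapply(summary, is.null, TRUE)]
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  res$summary <- summary
  invisible(res)
}
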