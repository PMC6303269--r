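# One-call orchestration: catalogue -> codes -> clustering -> profiles ->
# consensus -> variants -> structural coding -> reports.

#' Build a pipeline configuration
#'
#' Either point `protein_fasta` (plus optional `nt_fasta`, `metadata_tsv`,
#' `ss_fasta`) at real inputs, or set `simulate` to a
#' [simulation_config()] to run on synthetic data. The configuration is
#' serializable to YAML and a copy is written into every run's output
#' directory.
#'
#' @param protein_fasta,nt_fasta,metadata_tsv,ss_fasta Input paths
#'   (optional except `protein_fasta` when `simulate` is `NULL`).
#' @param simulate Optional [simulation_config()] replacing file inputs.
#' @param scheme A [subregion_scheme()].
#' @param metric,linkage Distance mode and linkage for the code dendrogram.
#' @param k,subk Top-level and nested cluster counts.
#' @param cluster_by `"pattern"` (default) or `"sample"`.
#' @param literal_threshold,class_threshold Consensus thresholds.
#' @param exclude_patterns Optional pattern ids excluded from consensus.
#' @param frame_prefix Untranslated prefix of the reading frame.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return Object of class `pipeline_config` (a list).
#' @export
pipeline_config <- function(protein_fasta = NULL, nt_fasta = NULL,
                            metadata_tsv = NULL, ss_fasta = NULL,
                            simulate = NULL,
                            scheme = default_subregion_scheme(),
                            metric = "id_hamming", linkage = "average",
                            k = 2L, subk = 2L, cluster_by = "pattern",
                            literal_threshold = 1, class_threshold = 1,
                            exclude_patterns = NULL, frame_prefix = 2L,
                            out_dir = "fadpat_run", seed = 1L) {
  if (is.null(protein_fasta) && is.null(simulate)) {
    stop("either 'protein_fasta' or 'simulate' must be given")
  }
  structure(list(protein_fasta = protein_fasta, nt_fasta = nt_fasta,
                 metadata_tsv = metadata_tsv, ss_fasta = ss_fasta,
                 simulate = simulate, scheme = scheme, metric = metric,
                 linkage = linkage, k = as.integer(k),
                 subk = as.integer(subk), cluster_by = cluster_by,
                 literal_threshold = literal_threshold,
                 class_threshold = class_threshold,
                 exclude_patterns = exclude_patterns,
                 frame_prefix = as.integer(frame_prefix),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments;
#'   `scheme` may be a list with `name`/`start`/`end`, `simulate` a list of
#'   [simulation_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scheme)) {
    raw$scheme <- subregion_scheme(raw$scheme$name, raw$scheme$start,
                                   raw$scheme$end)
  }
  if (!is.null(raw$simulate)) {
    raw$simulate <- do.call(simulation_config, raw$simulate)
  }
  do.call(pipeline_config, raw)
}

config_to_plain <- function(config) {
  plain <- unclass(config)
  plain$scheme <- list(name = config$scheme$name,
                       start = config$scheme$start,
                       end = config$scheme$end)
  if (!is.null(config$simulate)) {
    sim <- unclass(config$simulate)
    sim$scheme <- NULL
    sim$pool_sizes <- as.list(sim$pool_sizes)
    plain$simulate <- sim
  }
  plain
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full pattern-analysis pipeline
#'
#' Stages: input (read or simulate), pattern cataloguing, five-digit
#' encoding, code clustering with nested cut, residue/property profiling
#' and consensus per sub-region, substitution annotation (when nucleotide
#' companions exist) and structural coding/clustering (when SS profiles
#' exist). Writes catalogue TSVs, the five-digit code TSV, Newick
#' dendrograms, profile TSVs, consensus strings (text + JSON token list),
#' the substitution TSV, a machine-readable `summary.json` and a copy of
#' the configuration. Logging goes to stderr; results never do. Identical
#' config + seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()] or path to its YAML serialization.
#' @return Invisibly, the run report: list with `summary`, `paths`,
#'   `catalog`, `tree`, `assignment` and (when computed) `substitutions`
#'   and `structural`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  frame <- reading_frame(config$frame_prefix)

  # -- stage: input
  truth <- NULL
  if (!is.null(config$simulate)) {
    log_msg("stage input: simulating dataset (seed ",
            config$simulate$seed, ")")
    sim <- simulate_protein_alignment(config$simulate)
    aln <- sim$alignment
    truth <- sim$truth
    aln <- back_translate(aln, frame, seed = config$simulate$seed)
  } else {
    log_msg("stage input: reading ", config$protein_fasta)
    aln <- read_region_alignment(config$protein_fasta, config$nt_fasta,
                                 scheme_region_length(config$scheme))
    if (!is.null(config$metadata_tsv)) {
      aln <- attach_metadata(aln, config$metadata_tsv)
    }
  }

  # -- stage: catalogue + codes
  log_msg("stage catalogue: ", nrow(aln$records), " samples")
  catalog <- catalog_patterns(aln, config$scheme)
  codes <- encode_five_digit(catalog)
  paths <- c(paths, write_tables(catalog, codes, out_dir))

  # -- stage: clustering
  by <- config$cluster_by
  log_msg("stage clustering: metric ", config$metric, ", linkage ",
          config$linkage, ", by ", by)
  D <- code_distance_matrix(catalog, mode = config$metric, by = by)
  tree <- hierarchical_cluster(D, linkage = config$linkage)
  k <- min(config$k, tree$n)
  assignment <- cut_and_label(tree, k)
  subclusters <- if (config$subk > 1L &&
                     assignment$sizes[1L] >= config$subk) {
    cut_subclusters(tree, k, config$subk, cluster = 1L)
  } else {
    data.frame(item = tree$labels, cluster = unname(assignment$labels),
               subcluster = as.character(unname(assignment$labels)),
               stringsAsFactors = FALSE)
  }
  p <- file.path(out_dir, "code_dendrogram.nwk")
  writeLines(to_newick(tree), p)
  paths["code_dendrogram"] <- p
  p <- file.path(out_dir, "cluster_assignments.tsv")
  write.table(subclusters, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths["cluster_assignments"] <- p

  # -- stage: profiles + consensus (over unique patterns per sub-region)
  log_msg("stage profiles: property frequencies and consensus motifs")
  strings <- subregion_strings(catalog, by = "pattern")
  consensus <- list()
  for (r in config$scheme$name) {
    pats <- unique(strings[, r])
    prof <- compute_property_profile(pats)
    tab <- data.frame(position = seq_along(prof$n_obs),
                      t(prof$class_freq), n_obs = prof$n_obs)
    p <- file.path(out_dir, paste0("property_profile_",
                                   gsub("[^A-Za-z0-9]+", "_", r), ".tsv"))
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("profile_", r)] <- p
    motif <- derive_consensus(stats::setNames(pats, seq_along(pats)),
                              config$literal_threshold,
                              config$class_threshold,
                              exclude = config$exclude_patterns[[r]])
    consensus[[r]] <- motif
  }
  p <- file.path(out_dir, "consensus_motifs.txt")
  writeLines(vapply(names(consensus), function(r) {
    sprintf("%s\t%s\t%s", r, render_motif(consensus[[r]]),
            render_motif(consensus[[r]], trim = TRUE))
  }, character(1)), p)
  paths["consensus_txt"] <- p
  p <- file.path(out_dir, "consensus_motifs.json")
  jsonlite::write_json(
    lapply(consensus, function(m) {
      list(rendered = render_motif(m),
           trimmed = render_motif(m, trim = TRUE),
           tokens = as.data.frame(m)[, c("position", "type", "token")])
    }), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["consensus_json"] <- p

  # -- stage: variants
  substitutions <- NULL
  if (all(!is.na(aln$records$nt))) {
    log_msg("stage variants: classifying substitutions vs reference ",
            aln$records$sample_id[1L])
    substitutions <- find_and_classify_substitutions(aln, frame = frame)
    p <- file.path(out_dir, "substitutions.tsv")
    write.table(substitutions, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["substitutions"] <- p
  } else {
    log_msg("stage variants: skipped (no nucleotide companions)")
  }

  # -- stage: structural coding
  structural <- NULL
  profiles <- NULL
  if (!is.null(config$ss_fasta)) {
    log_msg("stage structural: reading SS profiles from ",
            config$ss_fasta)
    profiles <- read_ss_profiles(config$ss_fasta)
  } else if (!is.null(config$simulate)) {
    log_msg("stage structural: simulating SS profiles")
    full <- catalog$scopes$full
    pat_group <- vapply(full$groups, function(g) g[1L], character(1))
    pat_tab <- data.frame(pattern_id = full$patterns$pattern_id,
                          group = pat_group, stringsAsFactors = FALSE)
    profiles <- simulate_ss(pat_tab, config$simulate,
                            stats::setNames(full$patterns$pattern,
                                            full$patterns$pattern_id)
                            )$profiles
  }
  if (!is.null(profiles) && length(profiles) >= 2L) {
    structural <- simplify_and_cluster(profiles, k = config$k,
                                       subk = config$subk,
                                       linkage = config$linkage)
    p <- file.path(out_dir, "structural_codes.tsv")
    codes_tab <- data.frame(pattern_id = rownames(structural$codes),
                            apply(structural$codes, 1L, paste,
                                  collapse = ""),
                            stringsAsFactors = FALSE)
    names(codes_tab)[2L] <- "code"
    write.table(codes_tab, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["structural_codes"] <- p
    p <- file.path(out_dir, "structural_dendrogram.nwk")
    writeLines(to_newick(structural$tree), p)
    paths["structural_dendrogram"] <- p
  } else {
    log_msg("stage structural: skipped (no SS profiles)")
  }

  # -- summary
  rep_group <- if (by == "pattern") {
    vapply(catalog$scopes$full$groups, function(g) g[1L],
           character(1))[as.integer(tree$labels)]
  } else {
    unname(catalog$group_label[tree$labels])
  }
  cluster_groups <- lapply(split(rep_group, assignment$labels),
                           function(g) as.list(table(g)))
  summary <- list(
    n_samples = length(catalog$sample_id),
    region_length = scheme_region_length(config$scheme),
    pattern_counts = as.list(pattern_counts(catalog)),
    cluster_sizes = as.integer(assignment$sizes),
    subcluster_sizes = as.list(table(subclusters$subcluster)),
    group_composition = cluster_groups,
    consensus = lapply(consensus, render_motif, trim = TRUE),
    substitution_effects = if (!is.null(substitutions)) {
      as.list(table(substitutions$effect))
    },
    structural_cluster_sizes = if (!is.null(structural)) {
      as.integer(structural$assignment$sizes)
    }
  )
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["summary"] <- p
  p <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_plain(config), p)
  paths["config"] <- p
  log_msg("pipeline complete: ", length(paths), " outputs in ", out_dir)
  invisible(list(summary = summary, paths = paths, catalog = catalog,
                 tree = tree, assignment = assignment,
                 subclusters = subclusters,
                 substitutions = substitutions, structural = structural,
                 truth = truth))
}
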