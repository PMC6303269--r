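# Seeded synthetic datasets with the statistical structure the analysis
# assumes: group-structured sub-region patterns with invariant motif
# anchors, per-residue substitution noise, optional FAD-GG gaps,
# back-translated nucleotide companions and beta-alpha-beta SS templates.

# Invariant motif-anchor columns of a scheme: the three glycines of
# GxGxxG in the FAD sub-region (offsets 1, 3, 6) and G, G, R, T of the GG
# motif (offsets 3, 4, 5, 8).
#' Motif-anchor columns of a sub-region scheme
#'
#' Columns held invariant by the generator (and observed invariant in real
#' catalogues): the three glycines of the GxGxxG FAD-binding motif and the
#' G/G/R/T residues of the GG motif. For the default scheme these are
#' columns 6, 8, 11 (G) and 35, 36, 37, 40 (G, G, R, T).
#'
#' @param scheme A [subregion_scheme()] containing sub-regions named
#'   `"FAD"` and `"GG"`.
#' @return Named character vector: names are column numbers, values the
#'   anchored residues.
#' @export
anchor_columns <- function(scheme = default_subregion_scheme()) {
  fad <- scheme[scheme$name == "FAD", ]
  gg <- scheme[scheme$name == "GG", ]
  if (nrow(fad) != 1L || nrow(gg) != 1L) {
    stop("scheme must contain sub-regions named 'FAD' and 'GG'")
  }
  cols <- c(fad$start + c(0L, 2L, 5L), gg$start + c(2L, 3L, 4L, 7L))
  stats::setNames(c("G", "G", "G", "G", "G", "R", "T"), cols)
}

# group labels mirroring the organismal groups of a typical survey
GROUP_POOL <- c("gastropod", "mammal", "aves", "reptile",
                "actinopterygian", "other_invertebrate", "fungi",
                "bacteria")

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a small but realistic survey: 3 organismal groups of
#' 10 samples, group-private pattern pools sized like the observed
#' diversity gradient (FAD lowest, FAD-GG/aGG highest), a 2% per-residue
#' substitution noise rate, and motif-anchor columns exempt from noise
#' (matching their observed invariance in real catalogues).
#'
#' @param n_groups Number of organismal groups.
#' @param samples_per_group Samples per group.
#' @param pool_sizes Patterns per group per sub-region (scalar or one value
#'   per sub-region).
#' @param noise_rate Per-residue substitution probability in `[0, 1]`.
#' @param property_preserving Draw substitutions within the residue's
#'   biochemical property class (default `FALSE`).
#' @param gap_rate Per-residue gap probability, restricted to the FAD-GG
#'   interval (default 0).
#' @param ss_perturbation_rate Per-column SS state flip probability.
#' @param protect_anchors Exempt motif-anchor columns from noise
#'   (default `TRUE`).
#' @param scheme A [subregion_scheme()].
#' @param ss_templates Optional character vector of per-group SS template
#'   strings (H/E/C) of region length; derived from the beta-alpha-beta
#'   default when `NULL`.
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_groups = 3L, samples_per_group = 10L,
                              pool_sizes = c(bFAD = 2L, FAD = 1L,
                                             `FAD-GG` = 3L, GG = 2L,
                                             aGG = 3L),
                              noise_rate = 0.02,
                              property_preserving = FALSE,
                              gap_rate = 0, ss_perturbation_rate = 0.02,
                              protect_anchors = TRUE,
                              scheme = default_subregion_scheme(),
                              ss_templates = NULL, seed = 1L) {
  n_groups <- as.integer(n_groups)
  samples_per_group <- as.integer(samples_per_group)
  stopifnot(n_groups >= 1L, samples_per_group >= 1L)
  pool_sizes <- as.integer(rep_len(pool_sizes, nrow(scheme)))
  names(pool_sizes) <- scheme$name
  if (any(pool_sizes < 1L)) stop("pool sizes must be >= 1")
  for (r in c(noise_rate, gap_rate, ss_perturbation_rate)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  anchors <- anchor_columns(scheme)
  region_length <- scheme_region_length(scheme)
  # feasibility: total distinct strings required per sub-region
  for (i in seq_len(nrow(scheme))) {
    free <- scheme$length[i] -
      sum(as.integer(names(anchors)) >= scheme$start[i] &
          as.integer(names(anchors)) <= scheme$end[i])
    need <- n_groups * pool_sizes[i]
    if (need > 20^free) {
      stop("sub-region '", scheme$name[i], "' has ", free,
           " free column(s); cannot draw ", need, " distinct patterns")
    }
  }
  if (!is.null(ss_templates)) {
    ss_templates <- toupper(ss_templates)
    if (any(nchar(ss_templates) != region_length)) {
      stop("SS template length must equal the region length (",
           region_length, ")")
    }
    if (any(grepl("[^HEC]", ss_templates))) {
      stop("SS templates must be over the alphabet H/E/C")
    }
  }
  structure(list(n_groups = n_groups,
                 samples_per_group = samples_per_group,
                 pool_sizes = pool_sizes, noise_rate = noise_rate,
                 property_preserving = property_preserving,
                 gap_rate = gap_rate,
                 ss_perturbation_rate = ss_perturbation_rate,
                 protect_anchors = protect_anchors, scheme = scheme,
                 ss_templates = ss_templates, seed = as.integer(seed)),
            class = "simulation_config")
}

group_names <- function(n_groups) {
  if (n_groups <= length(GROUP_POOL)) GROUP_POOL[seq_len(n_groups)]
  else sprintf("group%d", seq_len(n_groups))
}

# draw n distinct random sub-region strings with anchored columns fixed
draw_pool <- function(n, length, anchor_offsets, anchor_residues) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(2L * n + 4L), function(i) {
      ch <- sample(AA20, length, replace = TRUE)
      ch[anchor_offsets] <- anchor_residues
      paste(ch, collapse = "")
    }, character(1))
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Simulate a group-structured region alignment
#'
#' Each group owns a private pool of sub-region patterns (pools are
#' disjoint across groups); every sample concatenates one draw per
#' sub-region, then receives independent per-residue substitution noise
#' and, inside the FAD-GG interval only, optional gaps. Motif-anchor
#' columns are exempt from noise unless `protect_anchors` is lifted. All
#' randomness is fixed by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `alignment` (a [region_alignment()]) and `truth`
#'   (per-sample list: `group`, `pool_choice` per sub-region,
#'   `substitutions` data frame with `column`, `from`, `to`, and `gaps`),
#'   plus `pools` (the group pattern pools).
#' @export
simulate_protein_alignment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  scheme <- config$scheme
  anchors <- anchor_columns(scheme)
  anchor_cols <- as.integer(names(anchors))
  region_length <- scheme_region_length(scheme)
  groups <- group_names(config$n_groups)
  # disjoint pools: draw all groups' patterns per sub-region at once
  pools <- vector("list", nrow(scheme))
  names(pools) <- scheme$name
  for (i in seq_len(nrow(scheme))) {
    in_sub <- anchor_cols >= scheme$start[i] & anchor_cols <= scheme$end[i]
    offs <- anchor_cols[in_sub] - scheme$start[i] + 1L
    all_pat <- draw_pool(config$n_groups * config$pool_sizes[i],
                         scheme$length[i], offs, anchors[in_sub])
    pools[[i]] <- split(all_pat,
                        rep(groups, each = config$pool_sizes[i]))
  }
  fadgg <- scheme[scheme$name == "FAD-GG", ]
  noise_cols <- setdiff(seq_len(region_length),
                        if (config$protect_anchors) anchor_cols
                        else integer(0))
  cls_of <- property_class_of()
  ids <- character(0); grp <- character(0); seqs <- character(0)
  truth <- list()
  for (g in seq_along(groups)) {
    for (s in seq_len(config$samples_per_group)) {
      id <- sprintf("%s_s%02d", groups[g], s)
      choice <- vapply(scheme$name, function(r) {
        sample.int(config$pool_sizes[r], 1L)
      }, integer(1))
      ch <- unlist(strsplit(
        vapply(scheme$name,
               function(r) pools[[r]][[groups[g]]][choice[r]],
               character(1)),
        "", fixed = TRUE), use.names = FALSE)
      subs <- list()
      hit <- noise_cols[stats::runif(length(noise_cols)) < config$noise_rate]
      for (j in hit) {
        from <- ch[j]
        to <- if (config$property_preserving) {
          resample(setdiff(PROPERTY_CLASSES[[cls_of[from]]], from))
        } else {
          resample(setdiff(AA20, from))
        }
        ch[j] <- to
        subs[[length(subs) + 1L]] <- data.frame(column = j, from = from,
                                                to = to,
                                                stringsAsFactors = FALSE)
      }
      gap_cols <- integer(0)
      if (config$gap_rate > 0 && nrow(fadgg) == 1L) {
        cand <- setdiff(seq(fadgg$start, fadgg$end), anchor_cols)
        gap_cols <- cand[stats::runif(length(cand)) < config$gap_rate]
        ch[gap_cols] <- "-"
      }
      ids <- c(ids, id); grp <- c(grp, groups[g])
      seqs <- c(seqs, paste(ch, collapse = ""))
      truth[[id]] <- list(
        group = groups[g], pool_choice = choice,
        substitutions = if (length(subs)) do.call(rbind, subs)
                        else data.frame(column = integer(0),
                                        from = character(0),
                                        to = character(0),
                                        stringsAsFactors = FALSE),
        gaps = gap_cols)
    }
  }
  aln <- region_alignment(stats::setNames(seqs, ids), group_label = grp)
  list(alignment = aln, truth = truth, pools = pools)
}

synonymous_codons <- function() {
  split(names(Biostrings::GENETIC_CODE), unname(Biostrings::GENETIC_CODE))
}

#' Back-translate a protein region alignment
#'
#' Attaches to every record a nucleotide companion of length
#' `3 * region_length + prefix`: a random untranslated prefix followed by
#' one codon per column, drawn uniformly among synonymous codons (seeded).
#' Gap columns are carried as `---`; `X` residues receive a random codon
#' (with a note). `translate_region()` of the result reproduces the amino
#' acid sequence exactly.
#'
#' @param aln A [region_alignment()].
#' @param frame A [reading_frame()] (its prefix sets the untranslated
#'   leader length).
#' @param seed Integer seed for the codon choices.
#' @return The alignment with `nt` sequences filled in.
#' @export
back_translate <- function(aln, frame = reading_frame(), seed = 1L) {
  stopifnot(inherits(aln, "region_alignment"))
  set.seed(as.integer(seed))
  syn <- synonymous_codons()
  p <- frame$untranslated_prefix
  n_x <- 0L
  nt <- vapply(aln$records$aa, function(aa) {
    ch <- strsplit(aa, "", fixed = TRUE)[[1]]
    codons <- vapply(ch, function(a) {
      if (a == "-") return("---")
      if (a == "X") {
        n_x <<- n_x + 1L
        return(resample(names(Biostrings::GENETIC_CODE)))
      }
      resample(syn[[a]])
    }, character(1))
    paste0(paste(sample(NT4, p, replace = TRUE), collapse = ""),
           paste(codons, collapse = ""))
  }, character(1), USE.NAMES = FALSE)
  if (n_x > 0L) {
    message(n_x, " 'X' residue(s) back-translated to random codons")
  }
  aln$records$nt <- normalize_nt(nt)
  aln
}

#' Default beta-alpha-beta secondary-structure template
#'
#' The canonical fold of the region: an N-terminal strand under bFAD
#' (columns 1-5), coil through the FAD motif (6-11), the central helix
#' (12-25), a short coil (26) and second strand (27-32) completing the
#' beta-alpha-beta unit within FAD-GG, and coil across the GG and aGG
#' sub-regions (33-47).
#'
#' @return A 47-character string over H/E/C.
#' @export
default_ss_template <- function() {
  paste(c(rep("E", 5), rep("C", 6), rep("H", 14), "C", rep("E", 6),
          rep("C", 15)), collapse = "")
}

derive_group_templates <- function(n_groups, region_length) {
  base <- default_ss_template()
  if (region_length != nchar(base)) {
    stop("no default SS template for region length ", region_length,
         "; supply ss_templates in the config")
  }
  vapply(seq_len(n_groups), function(g) {
    ch <- strsplit(base, "", fixed = TRUE)[[1]]
    # group-level divergence: group g extends helix into the first g-1
    # columns of the trailing coil
    if (g > 1L) {
      ext <- 33L:min(region_length, 33L + g - 2L)
      ch[ext] <- "H"
    }
    paste(ch, collapse = "")
  }, character(1))
}

#' Simulate secondary-structure profiles for a set of patterns
#'
#' Each pattern receives its group's template with independent per-column
#' perturbations (state flipped to a different H/E/C state) at
#' `ss_perturbation_rate`; columns where the protein pattern has a gap are
#' set to `-`.
#'
#' @param patterns Data frame with columns `pattern_id` and `group`.
#' @param config A [simulation_config()].
#' @param pattern_strings Optional named character vector of the protein
#'   pattern strings (used to place gaps).
#' @return List with `profiles` (an [ss_profile()]) and `truth` (the
#'   per-group templates and per-pattern perturbed columns).
#' @export
simulate_ss <- function(patterns, config = simulation_config(),
                        pattern_strings = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            all(c("pattern_id", "group") %in% names(patterns)))
  set.seed(config$seed + 1L)
  region_length <- scheme_region_length(config$scheme)
  groups <- unique(patterns$group)
  templates <- config$ss_templates
  if (is.null(templates)) {
    templates <- derive_group_templates(length(groups), region_length)
  }
  templates <- stats::setNames(rep_len(templates, length(groups)), groups)
  states <- c("H", "E", "C")
  perturbed <- list()
  profs <- character(nrow(patterns))
  for (i in seq_len(nrow(patterns))) {
    ch <- strsplit(templates[[patterns$group[i]]], "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(region_length) < config$ss_perturbation_rate)
    for (j in hit) ch[j] <- resample(setdiff(states, ch[j]))
    id <- as.character(patterns$pattern_id[i])
    if (!is.null(pattern_strings) && !is.na(pattern_strings[id])) {
      gaps <- which(strsplit(pattern_strings[[id]], "",
                             fixed = TRUE)[[1]] == "-")
      ch[gaps] <- "-"
    }
    perturbed[[id]] <- hit
    profs[i] <- paste(ch, collapse = "")
  }
  list(profiles = ss_profile(stats::setNames(profs,
                                             patterns$pattern_id)),
       truth = list(templates = templates, perturbed = perturbed))
}
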