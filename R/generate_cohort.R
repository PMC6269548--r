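#' Mutate a strain sequence
#'
#' Applies independent per-site substitutions to a DNA reference at a fixed
#' rate, returning the mutated sequence and the substitution table. Used to
#' individualize strains: unrelated individuals receive independent mutants
#' of the species reference, transmitted strains receive a low-rate mutant of
#' the maternal strain.
#'
#' @param reference DNA string over ACGT.
#' @param rate per-site substitution probability in `[0, 1]`. Each site
#'   mutates independently; a mutated site always changes to a different
#'   base (so `rate = 1` changes every site).
#' @param seed optional integer seed.
#' @return list with `sequence` (mutated string) and `substitutions`
#'   (data.frame `position`, `ref`, `alt`; positions are 1-based).
#' @export
mutate_strain <- function(reference, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (grepl("[^ACGT]", reference)) {
    stop("reference must contain only A, C, G, T")
  }
  run <- function() {
    n <- nchar(reference)
    positions <- which(runif(n) < rate)
    if (!length(positions)) {
      return(list(sequence = reference,
                  substitutions = data.frame(position = integer(0),
                                             ref = character(0),
                                             alt = character(0))))
    }
    substitute_sites(reference, positions)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Update marker amino-acid sequences given nucleotide substitutions on the
# genome. A substitution falling inside a marker interval changes the encoded
# amino acid with probability `nonsyn` (purifying selection keeps most marker
# changes synonymous).
mutate_marker_aa <- function(marker_aa, sub_positions, intervals, nonsyn) {
  if (!length(sub_positions)) return(marker_aa)
  for (i in seq_len(nrow(intervals))) {
    hits <- sub_positions[sub_positions >= intervals$start[i] &
                          sub_positions <= intervals$end[i]]
    if (!length(hits)) next
    hits <- hits[runif(length(hits)) < nonsyn]
    if (!length(hits)) next
    aa_pos <- unique((hits - intervals$start[i]) %/% 3L + 1L)
    chars <- strsplit(marker_aa[i], "")[[1]]
    for (p in aa_pos) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
    marker_aa[i] <- paste(chars, collapse = "")
  }
  marker_aa
}

# Genus names per class; recycled with a numeric suffix if a class holds
# more genomes than names. Contaminant genera are classic reagent/kitome
# organisms; one is deliberately left without a Gram label.
CLASS_GENERA <- list(
  enteric_gramneg = c("Escherichia", "Bacteroides", "Klebsiella",
                      "Enterobacter", "Citrobacter", "Proteus"),
  enteric_grampos = c("Bifidobacterium", "Enterococcus", "Lactobacillus",
                      "Clostridium"),
  skin_firmicute  = c("Staphylococcus", "Streptococcus", "Gemella"),
  contaminant     = c("Ralstonia", "Pelomonas", "Aquabacterium",
                      "Bradyrhizobium")
)
CLASS_GRAM <- c(enteric_gramneg = "negative", enteric_grampos = "positive",
                skin_firmicute = "positive", contaminant = "negative")
UNKNOWN_GRAM_GENUS <- "Aquabacterium"

fold_maf <- function(x) pmin(x, 1 - x)

perturb_freq <- function(f, sd) {
  if (!length(f)) return(f)
  plogis(qlogis(pmin(pmax(f, 1e-6), 1 - 1e-6)) + rnorm(length(f), 0, sd))
}

# Draw a within-host polymorphism table for one strain: polymorphic
# positions, alternative allele (differing from the strain consensus) and
# its frequency.
draw_polymorphism <- function(strain_seq, cfg) {
  L <- nchar(strain_seq)
  pos <- which(runif(L) < cfg$snv_density)
  if (!length(pos)) {
    return(data.frame(pos = integer(0), alt = character(0),
                      freq = numeric(0)))
  }
  cons <- substring(strain_seq, pos, pos)
  alt <- vapply(cons, function(b) sample(setdiff(DNA_ALPHABET, b), 1), "")
  maf <- fold_maf(rbeta(length(pos), cfg$within_host_maf[["shape1"]],
                        cfg$within_host_maf[["shape2"]]))
  data.frame(pos = pos, alt = unname(alt), freq = maf)
}

#' Generate a synthetic mother-neonate cohort
#'
#' Draws a complete paired cohort from a [cohort_config()]: reference
#' genomes with class-specific composition signatures, per-individual
#' strains, within-host allele-frequency spectra with a transmission
#' bottleneck and day-to-day drift in neonates, per-sample genome
#' abundances (with contaminants enriched in low-biomass samples and a
#' contaminant-only cell-culture control, and Gram-negative enteric genomes
#' enriched in vaginally delivered neonates), assembled contigs, allele-count
#' pileups, gene-to-KO hit candidates, and machine-readable ground truth for
#' evaluating every downstream stage.
#'
#' The cohort is a pure function of the configuration (including its seed):
#' the same configuration always yields a byte-identical object.
#'
#' @param config a [cohort_config()].
#' @param contigs,pileups logical; set `FALSE` to skip the corresponding
#'   (comparatively expensive) layer when it is not needed.
#' @return an object of class `synthetic_cohort`; see the package vignette
#'   for the layout.
#' @export
generate_cohort <- function(config, contigs = TRUE, pileups = TRUE) {
  validate_cohort_config(config)
  cfg <- config
  core <- with_seed(cfg$seed, build_cohort_core(cfg))
  cohort <- core
  cohort$config <- cfg
  if (contigs) {
    cohort <- emit_contigs(cohort, seed = derive_seed(cfg$seed, "contigs"))
  }
  cohort <- with_seed(derive_seed(cfg$seed, "genes"),
                      add_gene_hits(cohort))
  if (pileups) {
    cohort <- emit_pileups(cohort, seed = derive_seed(cfg$seed, "pileups"))
  }
  class(cohort) <- "synthetic_cohort"
  cohort
}

build_cohort_core <- function(cfg) {
  L <- cfg$genome_length
  ## --- genomes ---------------------------------------------------------
  classes <- rep(names(cfg$class_counts), cfg$class_counts)
  n_g <- cfg$n_genomes
  genome_id <- sprintf("g%02d", seq_len(n_g))
  genus <- character(n_g)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    pool <- CLASS_GENERA[[cl]]
    nm <- pool[((seq_along(idx) - 1) %% length(pool)) + 1]
    dup <- duplicated(nm)
    nm[dup] <- paste0(nm[dup], "_", seq_len(sum(dup)) + 1)
    genus[idx] <- nm
  }
  gram <- unname(CLASS_GRAM[classes])
  gram[genus == UNKNOWN_GRAM_GENUS] <- "unknown"
  gc <- unname(cfg$gc_by_class[classes])
  # spread GC slightly within class so genomes are individually resolvable
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    if (length(idx) > 1) {
      # contaminants stay tightly grouped so their composition never leaks
      # toward the host classes
      w <- if (cl == "contaminant") 0.015 else 0.04
      gc[idx] <- gc[idx] + seq(-w, w, length.out = length(idx))
    }
  }
  genomes <- data.frame(genome_id = genome_id, class = classes,
                        genus = genus, gram = gram, gc = gc,
                        stringsAsFactors = FALSE)

  genome_seqs <- list()
  for (i in seq_len(n_g)) {
    base <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    trans <- matrix(rep(base, each = 4), 4, 4)
    trans <- trans * matrix(exp(rnorm(16, 0, cfg$signature_sd)), 4, 4)
    trans <- trans / rowSums(trans)
    genome_seqs[[genome_id[i]]] <- random_dna_markov(L, trans)
  }

  ## --- marker genes ----------------------------------------------------
  mlen_nt <- 3L * cfg$marker_aa_length
  starts <- floor(seq(1, L - mlen_nt + 1, length.out = cfg$n_marker_families))
  marker_intervals <- data.frame(family = seq_len(cfg$n_marker_families),
                                 start = as.integer(starts),
                                 end = as.integer(starts + mlen_nt - 1L))
  marker_ref <- lapply(genome_id, function(g) {
    vapply(seq_len(cfg$n_marker_families),
           function(i) random_protein(cfg$marker_aa_length), "")
  })
  names(marker_ref) <- genome_id

  ## --- KO repertoires and pathways ------------------------------------
  ko_universe <- sprintf("K%05d", seq_len(cfg$n_kos))
  n_lps <- cfg$pathway_map_spec[["lps_biosynthesis"]]
  lps_kos <- ko_universe[seq_len(n_lps)]
  other_kos <- setdiff(ko_universe, lps_kos)
  ko_sets <- list()
  for (i in seq_len(n_g)) {
    if (genomes$class[i] == "enteric_gramneg") {
      ko_sets[[genome_id[i]]] <-
        c(lps_kos, sample(other_kos, cfg$kos_per_genome - n_lps))
    } else {
      ko_sets[[genome_id[i]]] <- sample(other_kos, cfg$kos_per_genome)
    }
  }
  pw <- cfg$pathway_map_spec
  pathway_map <- do.call(rbind, lapply(names(pw), function(p) {
    kos <- if (p == "lps_biosynthesis") lps_kos else sample(other_kos, pw[[p]])
    data.frame(pathway_id = p, ko = kos, stringsAsFactors = FALSE)
  }))

  ## --- samples ---------------------------------------------------------
  groups <- rep(COHORT_GROUPS, cfg$n_pairs_per_group[COHORT_GROUPS])
  n_pairs <- length(groups)
  pair_id <- sprintf("P%02d", seq_len(n_pairs))
  mothers <- data.frame(
    sample_id = sprintf("M%02d", seq_len(n_pairs)),
    individual_id = sprintf("M%02d", seq_len(n_pairs)),
    pair_id = pair_id, role = "mother", body_site = "faecal",
    day = NA_integer_, group = groups, stringsAsFactors = FALSE
  )
  neo <- expand.grid(pair = seq_len(n_pairs), day = cfg$days,
                     KEEP.OUT.ATTRS = FALSE)
  neo <- neo[order(neo$pair, neo$day), ]
  neonates <- data.frame(
    sample_id = sprintf("N%02d.d%d", neo$pair, neo$day),
    individual_id = sprintf("N%02d", neo$pair),
    pair_id = pair_id[neo$pair], role = "neonate", body_site = "faecal",
    day = as.integer(neo$day), group = groups[neo$pair],
    stringsAsFactors = FALSE
  )
  control <- data.frame(sample_id = "CTRL", individual_id = "CTRL",
                        pair_id = NA_character_, role = "control",
                        body_site = "cell_culture", day = NA_integer_,
                        group = NA_character_, stringsAsFactors = FALSE)
  samples <- rbind(mothers, neonates, control)
  rownames(samples) <- NULL

  ## --- carriage and transmission ---------------------------------------
  host_genomes <- genome_id[classes != "contaminant"]
  contam_genomes <- genome_id[classes == "contaminant"]
  transmitted <- data.frame(pair_id = character(0), genome_id = character(0))
  env_acquired <- data.frame(pair_id = character(0), genome_id = character(0))
  mother_carries <- matrix(FALSE, n_pairs, length(host_genomes),
                           dimnames = list(pair_id, host_genomes))
  neonate_carries <- mother_carries
  for (p in seq_len(n_pairs)) {
    for (g in host_genomes) {
      cl <- genomes$class[genomes$genome_id == g]
      p_tr <- cfg$transmission_prob[groups[p], cl]
      if (runif(1) < p_tr) {
        # transmission implies maternal carriage
        mother_carries[p, g] <- TRUE
        neonate_carries[p, g] <- TRUE
        transmitted <- rbind(transmitted,
                             data.frame(pair_id = pair_id[p], genome_id = g))
      } else {
        mother_carries[p, g] <- runif(1) < cfg$carriage_prob[cl]
        if (runif(1) < cfg$env_acquisition_prob) {
          neonate_carries[p, g] <- TRUE
          env_acquired <- rbind(env_acquired,
                                data.frame(pair_id = pair_id[p],
                                           genome_id = g))
        }
      }
    }
  }

  ## --- strains and within-host allele frequencies ----------------------
  strains <- list()
  freqs <- list()
  base_rate <- cfg$strain_divergence / 2
  mk_strain <- function(parent_seq, parent_marker, rate) {
    mut <- mutate_strain(parent_seq, rate)
    marker <- mutate_marker_aa(parent_marker, mut$substitutions$position,
                               marker_intervals, cfg$nonsyn_fraction)
    list(sequence = mut$sequence, marker_aa = marker,
         n_subs = nrow(mut$substitutions),
         sub_positions = mut$substitutions$position)
  }
  neo_days <- cfg$days
  for (p in seq_len(n_pairs)) {
    m_id <- mothers$individual_id[p]
    n_id <- sprintf("N%02d", p)
    strains[[m_id]] <- list()
    strains[[n_id]] <- list()
    for (g in host_genomes) {
      if (!mother_carries[p, g]) {
        if (neonate_carries[p, g]) {
          # environmental acquisition without maternal carriage
          st <- mk_strain(genome_seqs[[g]], marker_ref[[g]], base_rate)
          strains[[n_id]][[g]] <- st
          poly <- draw_polymorphism(st$sequence, cfg)
          f_prev <- poly$freq
          for (d in neo_days) {
            key <- paste0(g, "|", sprintf("N%02d.d%d", p, d))
            freqs[[key]] <- data.frame(pos = poly$pos, alt = poly$alt,
                                       freq = f_prev)
            f_prev <- perturb_freq(f_prev, cfg$drift_shift)
          }
        }
        next
      }
      m_strain <- mk_strain(genome_seqs[[g]], marker_ref[[g]], base_rate)
      strains[[m_id]][[g]] <- m_strain
      m_poly <- draw_polymorphism(m_strain$sequence, cfg)
      freqs[[paste0(g, "|", mothers$sample_id[p])]] <-
        data.frame(pos = m_poly$pos, alt = m_poly$alt, freq = m_poly$freq)
      if (!neonate_carries[p, g]) next
      is_transmitted <- any(transmitted$pair_id == pair_id[p] &
                            transmitted$genome_id == g)
      if (is_transmitted) {
        n_strain <- mk_strain(m_strain$sequence, m_strain$marker_aa,
                              cfg$transmission_mutation_rate)
        strains[[n_id]][[g]] <- n_strain
        # inherit the maternal polymorphism sites; drop any site where the
        # neonatal consensus itself changed
        poly <- m_poly[!(m_poly$pos %in% n_strain$sub_positions), ,
                       drop = FALSE]
        f_prev <- perturb_freq(poly$freq, cfg$bottleneck_shift)
        for (d in neo_days) {
          key <- paste0(g, "|", sprintf("N%02d.d%d", p, d))
          freqs[[key]] <- data.frame(pos = poly$pos, alt = poly$alt,
                                     freq = f_prev)
          f_prev <- perturb_freq(f_prev, cfg$drift_shift)
        }
      } else {
        st <- mk_strain(genome_seqs[[g]], marker_ref[[g]], base_rate)
        strains[[n_id]][[g]] <- st
        poly <- draw_polymorphism(st$sequence, cfg)
        f_prev <- poly$freq
        for (d in neo_days) {
          key <- paste0(g, "|", sprintf("N%02d.d%d", p, d))
          freqs[[key]] <- data.frame(pos = poly$pos, alt = poly$alt,
                                     freq = f_prev)
          f_prev <- perturb_freq(f_prev, cfg$drift_shift)
        }
      }
    }
  }

  ## --- per-sample genome abundances ------------------------------------
  load <- cfg$contaminant_load
  if (length(load) == 1) {
    load <- c(low_biomass = unname(load), high_biomass = unname(load),
              control = 1.0)
  }
  host_base <- setNames(2 ^ seq(-1, 1, length.out = length(host_genomes)),
                        host_genomes)
  abundance <- matrix(0, nrow(samples), n_g,
                      dimnames = list(samples$sample_id, genome_id))
  for (s in seq_len(nrow(samples))) {
    sm <- samples[s, ]
    if (sm$role == "control") {
      if (length(contam_genomes)) {
        w <- rlnorm(length(contam_genomes), 0, 0.3)
        abundance[s, contam_genomes] <- load[["control"]] * w / sum(w)
      }
      next
    }
    contam_frac <- if (sm$role == "mother") load[["high_biomass"]] else
      load[["low_biomass"]]
    present <- if (sm$role == "mother") {
      host_genomes[mother_carries[sm$pair_id, ]]
    } else {
      host_genomes[neonate_carries[sm$pair_id, ]]
    }
    if (length(present)) {
      w <- host_base[present] * rlnorm(length(present), 0, 0.4)
      if (sm$role == "neonate" && identical(sm$group, "VD")) {
        is_neg <- genomes$class[match(present, genomes$genome_id)] ==
          "enteric_gramneg"
        w[is_neg] <- w[is_neg] * cfg$lps_effect_size
      }
      abundance[s, present] <- (1 - contam_frac) * w / sum(w)
    } else {
      contam_frac <- 1
    }
    if (length(contam_genomes) && contam_frac > 0) {
      v <- rlnorm(length(contam_genomes), 0, 0.3)
      abundance[s, contam_genomes] <- contam_frac * v / sum(v)
    }
  }

  ## --- taxonomic profiles and truth -------------------------------------
  taxon_profiles <- t(apply(abundance, 1, function(a) {
    tapply(a, genomes$genus, sum)
  }))
  gram_table <- unique(genomes[, c("genus", "gram")])
  rownames(gram_table) <- NULL

  true_pi <- do.call(rbind, lapply(names(freqs), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    f <- freqs[[key]]$freq
    data.frame(genome_id = parts[1], sample_id = parts[2],
               pi = sum(2 * f * (1 - f)) / L, stringsAsFactors = FALSE)
  }))

  list(
    genomes = genomes, genome_seqs = genome_seqs,
    marker_intervals = marker_intervals, marker_ref = marker_ref,
    ko_sets = ko_sets, pathway_map = pathway_map,
    samples = samples, strains = strains, freqs = freqs,
    abundance = abundance, taxon_profiles = taxon_profiles,
    gram_table = gram_table,
    truth = list(
      transmitted = transmitted,
      env_acquired = env_acquired,
      contaminant_contigs = character(0),
      contig_sources = NULL,
      true_allele_freqs = freqs,
      true_pi = true_pi,
      planted_da_kos = lps_kos,
      gram_labels = gram_table
    )
  )
}

# Strain sequence of `genome` carried by the individual owning `sample`;
# contaminants always use the reference (they are identical everywhere).
strain_sequence <- function(cohort, genome, individual) {
  st <- cohort$strains[[individual]][[genome]]
  if (is.null(st)) cohort$genome_seqs[[genome]] else st$sequence
}

#' Emit assembled contigs for every sample
#'
#' Tiles each present genome's strain sequence into contigs with a lognormal
#' length distribution (source-genome substrings, as an assembler would
#' produce), attaches a per-contig coverage estimate, annotates the marker
#' proteins fully contained in each contig, and records contig provenance in
#' the ground truth. The cell-culture control receives only
#' contaminant-derived contigs. Contig identifiers are shuffled within each
#' sample and encode nothing about the source genome.
#'
#' @param cohort a `synthetic_cohort` (or the core returned during
#'   generation).
#' @param seed integer seed; defaults to a seed derived from the cohort
#'   configuration, so standalone calls reproduce the stored contigs.
#' @param median_len,sdlog,min_len contig length model; defaults come from
#'   the cohort configuration.
#' @return the cohort with `contigs`, `contig_markers` and
#'   `truth$contig_sources` / `truth$contaminant_contigs` filled in.
#' @export
emit_contigs <- function(cohort, seed = NULL,
                         median_len = cohort$config$contig_len_median,
                         sdlog = cohort$config$contig_len_sdlog,
                         min_len = cohort$config$contig_min_len) {
  cfg <- cohort$config
  seed <- seed %||% derive_seed(cfg$seed, "contigs")
  with_seed(seed, {
    L <- cfg$genome_length
    depth_mean <- cfg$depth_mean
    iv <- cohort$marker_intervals
    chunks <- list()
    marker_chunks <- list()
    for (s in seq_len(nrow(cohort$samples))) {
      sm <- cohort$samples[s, ]
      present <- colnames(cohort$abundance)[cohort$abundance[s, ] > 0]
      if (!length(present)) next
      blocks <- lapply(present, function(g) {
        seq_g <- strain_sequence(cohort, g, sm$individual_id)
        tiles <- tile_genome(L, median_len, sdlog, min_len)
        lambda <- depth_mean[[sm$body_site]] * cohort$abundance[s, g]
        data.frame(
          sample_id = sm$sample_id,
          sequence = substring(seq_g, tiles$start, tiles$end),
          genome_id = g, start = tiles$start, end = tiles$end,
          coverage = lambda * rlnorm(nrow(tiles), 0, 0.05),
          stringsAsFactors = FALSE
        )
      })
      blk <- do.call(rbind, blocks)
      blk <- blk[sample(nrow(blk)), , drop = FALSE]
      blk$contig_id <- sprintf("%s_c%03d", sm$sample_id, seq_len(nrow(blk)))
      chunks[[length(chunks) + 1]] <- blk
      # marker annotations: families fully contained in a contig carry the
      # strain's marker protein
      for (i in seq_len(nrow(blk))) {
        inside <- which(iv$start >= blk$start[i] & iv$end <= blk$end[i])
        if (!length(inside)) next
        st <- cohort$strains[[sm$individual_id]][[blk$genome_id[i]]]
        aa_set <- if (is.null(st)) cohort$marker_ref[[blk$genome_id[i]]] else
          st$marker_aa
        marker_chunks[[length(marker_chunks) + 1]] <- data.frame(
          contig_id = blk$contig_id[i], sample_id = sm$sample_id,
          family = inside,
          protein_id = sprintf("%s_f%02d", blk$contig_id[i], inside),
          aa_seq = aa_set[inside], stringsAsFactors = FALSE
        )
      }
    }
    all <- do.call(rbind, chunks)
    if (is.null(all)) {
      all <- data.frame(contig_id = character(0), sample_id = character(0),
                        sequence = character(0), genome_id = character(0),
                        start = integer(0), end = integer(0),
                        coverage = numeric(0))
    }
    contigs <- all[, c("contig_id", "sample_id", "sequence", "coverage")]
    contigs$length <- nchar(contigs$sequence)
    rownames(contigs) <- NULL
    sources <- all[, c("contig_id", "sample_id", "genome_id", "start",
                       "end")]
    rownames(sources) <- NULL
    cohort$contigs <- contigs
    cohort$contig_markers <- do.call(rbind, marker_chunks) %||%
      data.frame(contig_id = character(0), sample_id = character(0),
                 family = integer(0), protein_id = character(0),
                 aa_seq = character(0))
    rownames(cohort$contig_markers) <- NULL
    cohort$truth$contig_sources <- sources
    contam <- cohort$genomes$genome_id[cohort$genomes$class == "contaminant"]
    study <- !is.na(sources$sample_id) & sources$sample_id != "CTRL"
    cohort$truth$contaminant_contigs <-
      sources$contig_id[study & sources$genome_id %in% contam]
    cohort
  })
}

# Random tiling of [1, L] into contig-length pieces.
tile_genome <- function(L, median_len, sdlog, min_len) {
  lens <- integer(0)
  total <- 0
  while (total < L) {
    l <- max(min_len, round(rlnorm(1, log(median_len), sdlog)))
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - L)
  if (length(lens) > 1 && lens[length(lens)] < min_len) {
    lens[length(lens) - 1] <- lens[length(lens) - 1] + lens[length(lens)]
    lens <- lens[-length(lens)]
  }
  starts <- cumsum(c(1L, head(lens, -1)))
  data.frame(start = as.integer(starts),
             end = as.integer(starts + lens - 1L))
}

#' Emit allele-count pileups for every genome-sample combination
#'
#' For each host genome present in a sample, draws per-position depth as
#' Poisson(`depth_mean[body_site] * relative abundance`) and allele counts
#' as multinomial draws from the true within-host allele frequencies.
#' Positions with zero depth are omitted (this defines breadth).
#' Contaminant genomes and the control sample carry no pileups: they have no
#' within-host strain populations to profile.
#'
#' @param cohort a `synthetic_cohort`.
#' @param seed integer seed; defaults to a configuration-derived seed.
#' @return the cohort with a `pileups` list, keyed `"genome|sample"`; each
#'   element has `genome_id`, `sample_id`, `pos` (0-based covered positions)
#'   and `counts` (positions x ACGT integer matrix).
#' @export
emit_pileups <- function(cohort, seed = NULL) {
  cfg <- cohort$config
  seed <- seed %||% derive_seed(cfg$seed, "pileups")
  with_seed(seed, {
    L <- cfg$genome_length
    pileups <- list()
    for (key in names(cohort$freqs)) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      g <- parts[1]
      sid <- parts[2]
      srow <- cohort$samples[cohort$samples$sample_id == sid, ]
      lambda <- cfg$depth_mean[[srow$body_site]] * cohort$abundance[sid, g]
      if (lambda <= 0) next
      seq_g <- strain_sequence(cohort, g, srow$individual_id)
      pileups[[key]] <- simulate_pileup(
        genome_id = g, sample_id = sid, consensus = seq_g,
        poly = cohort$freqs[[key]], lambda = lambda, length = L
      )
    }
    cohort$pileups <- pileups
    cohort
  })
}

#' Simulate one allele-count pileup
#'
#' Draws a pileup for a single genome-sample combination: depth per position
#' is Poisson(`lambda`); at polymorphic positions the alternative-allele
#' count is Binomial(depth, frequency), the remainder supporting the
#' consensus base. Exposed so the popgen estimators can be exercised on
#' pileups with known allele frequencies without building a full cohort.
#'
#' @param genome_id,sample_id identifiers stored on the pileup.
#' @param consensus consensus (strain) DNA string.
#' @param poly data.frame with `pos` (1-based), `alt`, `freq`.
#' @param lambda mean per-position depth.
#' @param length genome length (defaults to `nchar(consensus)`).
#' @return a pileup: list with `genome_id`, `sample_id`, `genome_length`,
#'   `pos` (0-based) and `counts`.
#' @export
simulate_pileup <- function(genome_id, sample_id, consensus, poly, lambda,
                            length = nchar(consensus)) {
  depth <- rpois(length, lambda)
  keep <- which(depth > 0L)
  if (!length(keep)) {
    return(new_pileup(genome_id, sample_id, integer(0),
                      matrix(0L, 0, 4, dimnames = list(NULL, DNA_ALPHABET)),
                      length))
  }
  cons <- substring(consensus, keep, keep)
  counts <- matrix(0L, length(keep), 4,
                   dimnames = list(NULL, DNA_ALPHABET))
  ci <- match(cons, DNA_ALPHABET)
  counts[cbind(seq_along(keep), ci)] <- depth[keep]
  if (!is.null(poly) && nrow(poly)) {
    j <- match(poly$pos, keep)
    sel <- which(!is.na(j))
    if (length(sel)) {
      rows <- j[sel]
      alt_n <- rbinom(length(sel), depth[poly$pos[sel]], poly$freq[sel])
      ai <- match(poly$alt[sel], DNA_ALPHABET)
      cons_i <- ci[rows]
      counts[cbind(rows, cons_i)] <- counts[cbind(rows, cons_i)] - alt_n
      counts[cbind(rows, ai)] <- counts[cbind(rows, ai)] + alt_n
    }
  }
  new_pileup(genome_id, sample_id, keep - 1L, counts, length)
}

#' Construct an allele-count pileup
#'
#' The container consumed by the population-genomics functions: covered
#' positions (0-based) with their A/C/G/T read counts on one genome in one
#' sample.
#'
#' @param genome_id,sample_id identifiers.
#' @param pos integer vector of 0-based covered positions.
#' @param counts length(pos) x 4 integer matrix with columns A, C, G, T.
#' @param genome_length genome length in bp (defines breadth).
#' @return an object of class `pileup`.
#' @export
pileup <- function(genome_id, sample_id, pos, counts, genome_length) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- DNA_ALPHABET
  stopifnot(ncol(counts) == 4, nrow(counts) == length(pos),
            all(counts >= 0), genome_length >= length(pos))
  storage.mode(counts) <- "integer"
  counts <- counts[, DNA_ALPHABET, drop = FALSE]
  if (any(rowSums(counts) < 1)) stop("stored columns must have depth >= 1")
  new_pileup(genome_id, sample_id, as.integer(pos), counts,
             as.integer(genome_length))
}

new_pileup <- function(genome_id, sample_id, pos, counts, genome_length) {
  structure(
    list(genome_id = genome_id, sample_id = sample_id,
         genome_length = as.integer(genome_length),
         pos = as.integer(pos), counts = counts),
    class = "pileup"
  )
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup %s / %s: %d covered positions of %d (breadth %.2f)\n",
              x$genome_id, x$sample_id, length(x$pos), x$genome_length,
              length(x$pos) / x$genome_length))
  invisible(x)
}

# Attach per-sample gene tables and gene -> KO candidate hits.
add_gene_hits <- function(cohort) {
  cfg <- cohort$config
  ko_universe <- sprintf("K%05d", seq_len(cfg$n_kos))
  has_contigs <- !is.null(cohort$contigs)
  src <- cohort$truth$contig_sources
  gene_chunks <- list()
  cand_chunks <- list()
  for (s in seq_len(nrow(cohort$samples))) {
    sm <- cohort$samples[s, ]
    if (sm$role == "control") next
    present <- colnames(cohort$abundance)[cohort$abundance[s, ] > 0]
    if (!length(present)) next
    idx0 <- 0
    for (g in present) {
      kos <- cohort$ko_sets[[g]]
      n <- length(kos)
      gid <- sprintf("%s_gene%04d", sm$sample_id, idx0 + seq_len(n))
      idx0 <- idx0 + n
      g_contigs <- if (has_contigs) {
        src$contig_id[src$sample_id == sm$sample_id & src$genome_id == g]
      } else {
        character(0)
      }
      contig <- if (length(g_contigs)) {
        sample(g_contigs, n, replace = TRUE)
      } else {
        rep(NA_character_, n)
      }
      lambda <- cohort$abundance[s, g] * 5000 / n
      reads <- rpois(n, lambda * rlnorm(n, 0, 0.4))
      gene_chunks[[length(gene_chunks) + 1]] <- data.frame(
        sample_id = sm$sample_id, gene_id = gid, contig_id = contig,
        read_count = reads, stringsAsFactors = FALSE
      )
      weak <- runif(n) < 0.05
      sc <- ifelse(weak, runif(n, 2, 8), runif(n, 60, 300))
      cand_chunks[[length(cand_chunks) + 1]] <- data.frame(
        gene_id = gid, ko = kos, bit_score = sc, stringsAsFactors = FALSE
      )
      decoy <- which(!weak & runif(n) < 0.25)
      if (length(decoy)) {
        dk <- vapply(kos[decoy],
                     function(k) sample(setdiff(ko_universe, k), 1), "")
        cand_chunks[[length(cand_chunks) + 1]] <- data.frame(
          gene_id = gid[decoy], ko = unname(dk),
          bit_score = sc[decoy] - runif(length(decoy), 5, 40),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cohort$gene_hits <- do.call(rbind, gene_chunks) %||%
    data.frame(sample_id = character(0), gene_id = character(0),
               contig_id = character(0), read_count = integer(0))
  cohort$gene_ko_candidates <- do.call(rbind, cand_chunks) %||%
    data.frame(gene_id = character(0), ko = character(0),
               bit_score = numeric(0))
  rownames(cohort$gene_hits) <- NULL
  rownames(cohort$gene_ko_candidates) <- NULL
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic mother-neonate cohort\n")
  cat(sprintf("  %d samples (%d mothers, %d neonatal, %d control), %d genomes\n",
              nrow(x$samples), sum(x$samples$role == "mother"),
              sum(x$samples$role == "neonate"),
              sum(x$samples$role == "control"), nrow(x$genomes)))
  if (!is.null(x$contigs)) {
    cat(sprintf("  %d contigs (%d contaminant-derived in study samples)\n",
                nrow(x$contigs), length(x$truth$contaminant_contigs)))
  }
  if (!is.null(x$pileups)) {
    cat(sprintf("  %d genome-sample pileups\n", length(x$pileups)))
  }
  cat(sprintf("  %d true transmission events; seed %d\n",
              nrow(x$truth$transmitted), x$config$seed))
  invisible(x)
}
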