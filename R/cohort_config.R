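GENOME_CLASSES <- c("enteric_gramneg", "enteric_grampos", "skin_firmicute",
                    "contaminant")
COHORT_GROUPS <- c("VD", "CSD", "CSD_SGA")

#' Default mother-to-neonate transmission probabilities
#'
#' Group x genome-class matrix used by [cohort_config()]: vaginally
#' delivered neonates predominantly receive maternal enteric strains,
#' caesarean-delivered neonates more skin-associated strains; contaminants
#' are never transmitted.
#'
#' @return a 3 x 4 numeric matrix (groups x classes).
#' @export
default_transmission_prob <- function() {
  m <- rbind(
    VD      = c(enteric_gramneg = 0.80, enteric_grampos = 0.60,
                skin_firmicute = 0.10, contaminant = 0),
    CSD     = c(enteric_gramneg = 0.20, enteric_grampos = 0.30,
                skin_firmicute = 0.50, contaminant = 0),
    CSD_SGA = c(enteric_gramneg = 0.15, enteric_grampos = 0.25,
                skin_firmicute = 0.50, contaminant = 0)
  )
  m
}

#' Configuration for a synthetic mother-neonate cohort
#'
#' Bundles and validates every tunable of the synthetic-cohort generator:
#' cohort design (pairs per delivery group, sampling days), genome make-up
#' (classes, composition signatures, marker genes), the strain model
#' (between-individual divergence, transmission bottleneck, day-to-day
#' drift), sequencing depth, contaminant load, and the functional (KO /
#' pathway) layer including the Gram-negative-restricted LPS-like pathway.
#'
#' Defaults emulate a small paired cohort: mothers sampled once before
#' delivery, neonates at days 1/3/5, three delivery groups (vaginal,
#' caesarean, caesarean + small-for-gestational-age), contaminant genomes
#' enriched in low-biomass samples and a cell-culture negative control, and
#' a multiplicative enrichment of Gram-negative enteric genomes in vaginally
#' delivered neonates.
#'
#' @param n_pairs_per_group named integer vector, pairs per group
#'   (`VD`, `CSD`, `CSD_SGA`).
#' @param days neonatal sampling days, strictly increasing.
#' @param n_genomes total number of genomes; must equal `sum(class_counts)`.
#' @param class_counts named integer vector of genomes per class.
#' @param genome_length genome length in bp (>= 10000).
#' @param gc_by_class named numeric, GC fraction per genome class, in (0,1).
#' @param transmission_prob group x class matrix of mother-to-neonate
#'   transmission probabilities, all in `[0,1]`.
#' @param carriage_prob named numeric, probability that a mother carries a
#'   genome of each class.
#' @param env_acquisition_prob probability that a neonate independently
#'   acquires a non-transmitted, non-contaminant genome from the environment.
#' @param strain_divergence expected per-site nucleotide divergence between
#'   the strains of two unrelated individuals.
#' @param transmission_mutation_rate per-site substitution rate applied to a
#'   transmitted strain in the neonate (small; models within-transfer drift).
#' @param nonsyn_fraction fraction of nucleotide substitutions inside a
#'   marker gene that change the encoded amino acid (conserved single-copy
#'   markers are mostly under purifying selection).
#' @param snv_density fraction of genome positions polymorphic within a host.
#' @param within_host_maf `c(shape1, shape2)` of the Beta distribution of
#'   within-host minor-allele frequencies (folded to `[0, 0.5]`).
#' @param bottleneck_shift logit-scale s.d. of the allele-frequency
#'   perturbation applied at mother-to-neonate transmission.
#' @param drift_shift logit-scale s.d. of allele-frequency drift between
#'   consecutive neonatal sampling days.
#' @param depth_mean named numeric, mean per-genome coverage by body site
#'   (`faecal`, `vaginal`, `cell_culture`); per-genome depth is
#'   `depth_mean * relative abundance`.
#' @param contaminant_load named numeric: contaminant relative abundance in
#'   `low_biomass` samples (neonatal faecal), `high_biomass` samples
#'   (maternal faecal) and the `control` (1 = contaminants only).
#' @param n_kos size of the KO universe.
#' @param kos_per_genome KOs sampled per genome.
#' @param pathway_map_spec named integer vector pathway -> KO count; must
#'   contain `lps_biosynthesis`, whose KOs are restricted to Gram-negative
#'   genomes.
#' @param lps_effect_size multiplicative abundance enrichment of
#'   Gram-negative enteric genomes in VD neonates.
#' @param signature_sd log-scale s.d. of the per-genome perturbation of the
#'   order-1 Markov transition matrix used to synthesize genome sequences;
#'   controls how distinct genome oligonucleotide signatures are.
#' @param n_marker_families number of single-copy marker-gene families.
#' @param marker_aa_length marker protein length (amino acids).
#' @param contig_len_median,contig_len_sdlog,contig_min_len lognormal contig
#'   length model (bp) used by [emit_contigs()].
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return an object of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_pairs_per_group = c(VD = 4, CSD = 4, CSD_SGA = 4),
                          days = c(1, 3, 5),
                          n_genomes = 12,
                          class_counts = c(enteric_gramneg = 4,
                                           enteric_grampos = 3,
                                           skin_firmicute = 2,
                                           contaminant = 3),
                          genome_length = 40000,
                          gc_by_class = c(enteric_gramneg = 0.42,
                                          enteric_grampos = 0.53,
                                          skin_firmicute = 0.33,
                                          contaminant = 0.68),
                          transmission_prob = default_transmission_prob(),
                          carriage_prob = c(enteric_gramneg = 0.95,
                                            enteric_grampos = 0.90,
                                            skin_firmicute = 0.60,
                                            contaminant = 0),
                          env_acquisition_prob = 0.05,
                          strain_divergence = 0.01,
                          transmission_mutation_rate = 1e-4,
                          nonsyn_fraction = 0.25,
                          snv_density = 0.004,
                          within_host_maf = c(shape1 = 1.5, shape2 = 8),
                          bottleneck_shift = 1.5,
                          drift_shift = 0.15,
                          depth_mean = c(faecal = 300, vaginal = 150,
                                         cell_culture = 200),
                          contaminant_load = c(low_biomass = 0.15,
                                               high_biomass = 0.02,
                                               control = 1.0),
                          n_kos = 120,
                          kos_per_genome = 40,
                          pathway_map_spec = c(
                            lps_biosynthesis = 9,
                            setNames(rep(10L, 9),
                                     sprintf("pathway_%02d", 1:9))
                          ),
                          lps_effect_size = 3,
                          signature_sd = 0.5,
                          n_marker_families = 35,
                          marker_aa_length = 100,
                          contig_len_median = 5000,
                          contig_len_sdlog = 0.45,
                          contig_min_len = 500,
                          seed = 1) {
  cfg <- list(
    n_pairs_per_group = n_pairs_per_group, days = days,
    n_genomes = n_genomes, class_counts = class_counts,
    genome_length = genome_length, gc_by_class = gc_by_class,
    transmission_prob = transmission_prob, carriage_prob = carriage_prob,
    env_acquisition_prob = env_acquisition_prob,
    strain_divergence = strain_divergence,
    transmission_mutation_rate = transmission_mutation_rate,
    nonsyn_fraction = nonsyn_fraction,
    snv_density = snv_density, within_host_maf = within_host_maf,
    bottleneck_shift = bottleneck_shift, drift_shift = drift_shift,
    depth_mean = depth_mean, contaminant_load = contaminant_load,
    n_kos = n_kos, kos_per_genome = kos_per_genome,
    pathway_map_spec = pathway_map_spec, lps_effect_size = lps_effect_size,
    signature_sd = signature_sd,
    n_marker_families = n_marker_families,
    marker_aa_length = marker_aa_length,
    contig_len_median = contig_len_median,
    contig_len_sdlog = contig_len_sdlog,
    contig_min_len = contig_min_len,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks every structural invariant of a [cohort_config()]; errors name the
#' offending field.
#'
#' @param cfg a `cohort_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!all(COHORT_GROUPS %in% names(cfg$n_pairs_per_group))) {
    fail("n_pairs_per_group", "must be named for VD, CSD, CSD_SGA")
  }
  if (any(cfg$n_pairs_per_group < 0)) {
    fail("n_pairs_per_group", "counts must be non-negative")
  }
  if (length(cfg$days) < 1 || any(diff(cfg$days) <= 0)) {
    fail("days", "must be strictly increasing")
  }
  if (cfg$genome_length < 10000) fail("genome_length", "must be >= 10000 bp")
  if (!setequal(names(cfg$class_counts), GENOME_CLASSES)) {
    fail("class_counts", "must be named for the four genome classes")
  }
  if (sum(cfg$class_counts) != cfg$n_genomes) {
    fail("class_counts", "must sum to n_genomes")
  }
  if (any(cfg$gc_by_class <= 0) || any(cfg$gc_by_class >= 1)) {
    fail("gc_by_class", "GC fractions must lie in (0, 1)")
  }
  probs <- list(transmission_prob = cfg$transmission_prob,
                carriage_prob = cfg$carriage_prob,
                env_acquisition_prob = cfg$env_acquisition_prob,
                contaminant_load = cfg$contaminant_load)
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (any(v < 0) || any(v > 1)) fail(nm, "probabilities must lie in [0, 1]")
  }
  if (!all(COHORT_GROUPS %in% rownames(cfg$transmission_prob)) ||
      !all(GENOME_CLASSES %in% colnames(cfg$transmission_prob))) {
    fail("transmission_prob", "must be a group x class matrix")
  }
  if (cfg$strain_divergence < 0 || cfg$strain_divergence >= 1) {
    fail("strain_divergence", "must lie in [0, 1)")
  }
  if (cfg$snv_density < 0 || cfg$snv_density > 1) {
    fail("snv_density", "must lie in [0, 1]")
  }
  if (any(cfg$within_host_maf <= 0)) {
    fail("within_host_maf", "Beta shapes must be positive")
  }
  if (any(cfg$depth_mean < 0)) fail("depth_mean", "must be non-negative")
  if (!("lps_biosynthesis" %in% names(cfg$pathway_map_spec))) {
    fail("pathway_map_spec", "must include an 'lps_biosynthesis' pathway")
  }
  if (cfg$pathway_map_spec[["lps_biosynthesis"]] +
      sum(cfg$class_counts) > cfg$n_kos) {
    # loose sanity bound; the LPS KOs are reserved out of the universe
    fail("pathway_map_spec", "LPS pathway too large for the KO universe")
  }
  if (cfg$lps_effect_size <= 0) fail("lps_effect_size", "must be positive")
  if (cfg$n_marker_families < 1) fail("n_marker_families", "must be >= 1")
  if (cfg$n_marker_families * 3 * cfg$marker_aa_length > cfg$genome_length) {
    fail("n_marker_families", "marker genes do not fit in the genome")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  pairs: %s\n",
              paste(sprintf("%s=%d", names(x$n_pairs_per_group),
                            x$n_pairs_per_group), collapse = " ")))
  cat(sprintf("  neonatal days: %s\n", paste(x$days, collapse = ", ")))
  cat(sprintf("  genomes: %d (%s), %d bp\n", x$n_genomes,
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = " "), x$genome_length))
  cat(sprintf("  strain divergence: %.3g; bottleneck shift: %.3g; drift: %.3g\n",
              x$strain_divergence, x$bottleneck_shift, x$drift_shift))
  cat(sprintf("  KO universe: %d; LPS effect size: %.2g; seed: %d\n",
              x$n_kos, x$lps_effect_size, x$seed))
  invisible(x)
}
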