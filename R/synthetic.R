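#' Configuration for the synthetic human feeding-study generator
#'
#' Defaults mirror the longitudinal design the package targets: 17
#' subjects (11 young, 6 old) sampled at four time points (baseline W0
#' and weeks 2/4/6 of the intervention), ~1000 OTUs partitioned into 6
#' temporal co-abundance archetypes, 16S sequencing depth of 20,000 reads
#' per sample, and a plasma antioxidant phenotype (FRAP, umol/L) driven by
#' 30 signed marker OTUs (25 positive, 5 negative) through a shared latent
#' antioxidant state, with plasma glucose negatively coupled to that
#' state.
#'
#' @param n_young,n_old subjects per age group.
#' @param n_otus number of OTUs.
#' @param k_cags number of planted temporal archetypes (<= 6 distinct
#'   rank patterns are available).
#' @param timepoints ordered time-point labels.
#' @param depth reads per sample.
#' @param archetype_amplitude scales the log fold-changes of the planted
#'   trends (0 = no temporal structure).
#' @param subject_sd,noise_sd lognormal sd of the per-subject OTU effect
#'   and the per-sample residual noise.
#' @param baseline_sd sd of the log baseline abundances (rank-abundance
#'   spread).
#' @param n_markers_pos,n_markers_neg planted positive/negative marker
#'   counts.
#' @param marker_loading log-abundance loading of markers on the latent
#'   antioxidant state (0 = no phenotype signal); chosen so planted
#'   per-marker |rho| with FRAP is ~0.6 at the default noise.
#' @param frap_base,frap_scale,frap_noise_sd FRAP (umol/L) =
#'   base + scale * latent + N(0, noise_sd); defaults give
#'   cor(latent, FRAP) ~ 0.9.
#' @param glucose_base,glucose_coupling,glucose_noise_sd plasma glucose
#'   (mg/dL) = base - coupling * latent + N(0, noise_sd) (negative
#'   coupling to the antioxidant state).
#' @param crp_base mean CRP (mg/L), lognormal noise around it.
#' @param seed mandatory integer seed.
#' @return a list of class `human_config`.
#' @export
human_config <- function(n_young = 11, n_old = 6, n_otus = 1000, k_cags = 6,
                         timepoints = c("W0", "W2", "W4", "W6"),
                         depth = 20000, archetype_amplitude = 1,
                         subject_sd = 0.6, noise_sd = 0.35, baseline_sd = 1.4,
                         n_markers_pos = 25, n_markers_neg = 5,
                         marker_loading = 0.9,
                         frap_base = 900, frap_scale = 150, frap_noise_sd = 75,
                         glucose_base = 92, glucose_coupling = 6,
                         glucose_noise_sd = 4, crp_base = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(n_young >= 1, n_old >= 1, n_otus >= 2, k_cags >= 1, k_cags <= 6,
            depth >= 1, length(timepoints) >= 2)
  structure(cfg, class = "human_config")
}

## Six planted temporal archetypes. A Kendall distance on 4-point mean
## trends only sees the rank order of the four time points, so the planted
## patterns are six rank orders at pairwise Kendall (swap) distance >= 2
## (all even permutations of S4): one swap caused by noise cannot turn one
## archetype into another. Values are geometric in the rank
## (`step^(rank-1)`), so every adjacent rank contrast has the same log
## fold-change `amplitude * log(step)`.
archetype_profiles <- function(timepoints, amplitude, step = 1.75) {
  ranks <- rbind(
    rise_fall  = c(1, 3, 4, 2),   # up to W4, down (but above W0) at W6
    increase   = c(1, 2, 3, 4),   # progressive enrichment
    decrease   = c(4, 3, 2, 1),   # progressive depletion
    early_peak = c(3, 4, 1, 2),   # transient W2 bloom, then depletion
    dip        = c(4, 2, 1, 3),   # depletion with late rebound
    late_rise  = c(2, 3, 1, 4))   # flat-ish, W6 surge
  base <- step^(ranks - 1)
  if (length(timepoints) != 4)
    base <- base[, round(seq(1, 4, length.out = length(timepoints))), drop = FALSE]
  colnames(base) <- timepoints
  exp(amplitude * log(base))
}

synthetic_taxonomy <- function(otu_ids, n_genera = 30, species_frac = 0.6,
                               family_of_genus = NULL) {
  genera <- sprintf("Genus_%02d", seq_len(n_genera))
  gw <- 1 / seq_len(n_genera)             # power-law genus sizes
  g <- sample(genera, length(otu_ids), replace = TRUE, prob = gw / sum(gw))
  if (is.null(family_of_genus))
    family_of_genus <- stats::setNames(
      sprintf("Family_%02d", ((seq_len(n_genera) - 1) %% 10) + 1), genera)
  sp <- rep("", length(otu_ids))
  has_sp <- stats::runif(length(otu_ids)) < species_frac
  sp[has_sp] <- paste0(g[has_sp], "_sp", sample(1:8, sum(has_sp), replace = TRUE))
  data.frame(otu_id = otu_ids, domain = "Bacteria",
             family = unname(family_of_genus[g]), genus = g, species = sp,
             row.names = otu_ids, stringsAsFactors = FALSE)
}

#' Simulate a random rooted phylogeny over OTUs
#'
#' Coalescent-style rooted tree (exponential waiting-time branch lengths)
#' with the given OTU ids as leaves; Newick-serializable via
#' `ape::write.tree`.
#'
#' @param otu_ids >= 2 leaf labels.
#' @param seed integer seed.
#' @return a rooted `ape::phylo`.
#' @export
simulate_tree <- function(otu_ids, seed) {
  if (length(otu_ids) < 2) stop("need >= 2 OTUs")
  set.seed(derive_seed(seed, 97))
  ape::rcoal(length(otu_ids), tip.label = otu_ids)
}

#' Simulate the longitudinal human feeding-study arm
#'
#' Per subject and time point, latent log-abundances combine the OTU's
#' baseline, its CAG archetype's time-point multiplier, a subject-specific
#' effect, sample noise, and (for marker OTUs) a signed loading on a
#' latent antioxidant state; counts are drawn multinomially at the
#' configured depth. The plasma panel (FRAP, glucose, CRP) is generated at
#' every time point from the same latent state. All planted structure is
#' exported as ground truth.
#'
#' Marker OTUs are drawn from the 25th-60th percentile of the baseline
#' abundance distribution (detectable at the configured depth, but not so
#' abundant that their shared latent loading moves the compositional
#' denominator), and the negative-marker set is mass-balanced against the
#' positive set for the same reason. A warning is raised if a planted
#' marker's mean expected count falls below 1.
#'
#' @param cfg a [human_config()].
#' @return list with `counts` ([otu_table()]), `metadata` (data.frame),
#'   `taxonomy` (data.frame), `tree` (`ape::phylo`), `truth` (list:
#'   `cag` named otu -> planted label, `archetypes`, `markers_pos`,
#'   `markers_neg`, `marker_weights`, `latent`, plus the full config).
#' @export
simulate_human_study <- function(cfg) {
  stopifnot(inherits(cfg, "human_config"))
  set.seed(cfg$seed)
  tps <- cfg$timepoints
  n_subj <- cfg$n_young + cfg$n_old
  subjects <- sprintf("S%02d", seq_len(n_subj))
  age <- c(rep("young", cfg$n_young), rep("old", cfg$n_old))
  otus <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
  arch <- archetype_profiles(tps, cfg$archetype_amplitude)[seq_len(cfg$k_cags), ,
                                                           drop = FALSE]
  cag <- stats::setNames(sample(rep_len(seq_len(cfg$k_cags), cfg$n_otus)), otus)
  baseline <- stats::setNames(stats::rnorm(cfg$n_otus, 0, cfg$baseline_sd), otus)
  ## Markers are detectable but not mass-dominant taxa (25th-60th
  ## abundance percentile), and the negative-marker set is chosen so its
  ## total baseline mass matches the positive set's. Both choices keep the
  ## compositional denominator nearly invariant to the latent antioxidant
  ## state, so non-marker OTUs do not inherit spurious phenotype
  ## correlations through closure.
  ord <- names(sort(baseline, decreasing = TRUE))
  eligible <- ord[seq(max(cfg$n_otus %/% 4, 1), ceiling(cfg$n_otus * 0.6))]
  markers_pos <- sample(eligible, cfg$n_markers_pos)
  target <- log(sum(exp(baseline[markers_pos])) / max(cfg$n_markers_neg, 1))
  pool <- setdiff(otus, markers_pos)
  markers_neg <- pool[order(abs(baseline[pool] - target))][seq_len(cfg$n_markers_neg)]
  mk <- c(markers_pos, markers_neg)
  w <- stats::setNames(numeric(cfg$n_otus), otus)
  w[markers_pos] <- cfg$marker_loading
  w[markers_neg] <- -cfg$marker_loading
  subj_eff <- matrix(stats::rnorm(n_subj * cfg$n_otus, 0, cfg$subject_sd),
                     n_subj, cfg$n_otus, dimnames = list(subjects, otus))
  samples <- expand.grid(subject = subjects, timepoint = tps,
                         stringsAsFactors = FALSE)
  samples <- samples[order(samples$subject, match(samples$timepoint, tps)), ]
  sample_ids <- paste0(samples$subject, "_", samples$timepoint)
  ns <- nrow(samples)
  latent <- stats::setNames(stats::rnorm(ns), sample_ids)
  counts <- matrix(0, ns, cfg$n_otus, dimnames = list(sample_ids, otus))
  mk_expected <- stats::setNames(numeric(length(mk)), mk)
  for (s in seq_len(ns)) {
    tp <- samples$timepoint[s]
    lg <- baseline + log(arch[cag, tp]) + subj_eff[samples$subject[s], ] +
      w * latent[s] + stats::rnorm(cfg$n_otus, 0, cfg$noise_sd)
    pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
    mk_expected <- mk_expected + pr[mk] * cfg$depth / ns
    counts[s, ] <- stats::rmultinom(1, cfg$depth, pr)
  }
  if (any(mk_expected < 1))
    warning("depth too small to realize planted marker effects ",
            "(mean expected count < 1 for a planted marker OTU)")
  frap <- cfg$frap_base + cfg$frap_scale * latent +
    stats::rnorm(ns, 0, cfg$frap_noise_sd)
  glucose <- cfg$glucose_base - cfg$glucose_coupling * latent +
    stats::rnorm(ns, 0, cfg$glucose_noise_sd)
  crp <- cfg$crp_base * exp(stats::rnorm(ns, 0, 0.3))
  meta <- data.frame(sample_id = sample_ids, subject_id = samples$subject,
                     arm = "human",
                     group = age[match(samples$subject, subjects)],
                     timepoint = samples$timepoint,
                     frap = pmax(frap, 0), glucose = pmax(glucose, 0),
                     crp = crp, row.names = sample_ids,
                     stringsAsFactors = FALSE)
  taxonomy <- synthetic_taxonomy(otus)
  tree <- simulate_tree(otus, cfg$seed)
  list(counts = otu_table(counts), metadata = meta, taxonomy = taxonomy,
       tree = tree,
       truth = list(cag = stats::setNames(paste0("A", cag), otus),
                    archetypes = arch,
                    markers_pos = markers_pos, markers_neg = markers_neg,
                    marker_weights = w[mk], latent = latent, config = cfg))
}

#' Configuration for the synthetic in vitro colon-model generator
#'
#' Defaults mirror the fermenter design: five supplementation regimes
#' (ANTH/FLAV, MIX, PACs, S/A, TPP) plus an unsupplemented control, three
#' parallel vessels each, sampled at 0, 16 and 24 h. The G1 regimes
#' (ANTH/FLAV, MIX, PACs) share one post-baseline community shift and the
#' G2 regimes (S/A, TPP) another — a bloom of a designated
#' sugar-responsive (Enterobacteriaceae-like) genus.
#'
#' @param n_otus number of OTUs.
#' @param n_vessels vessels per regime.
#' @param depth reads per sample.
#' @param bloom_fold fold-increase of the G2 bloom taxa at 16/24 h (the
#'   default takes the bloom genus from a few percent of the community to
#'   roughly half of it, the scale seen for sugar-responsive
#'   Enterobacteriaceae blooms in fermenter systems)
#'   (1 = no regime effect).
#' @param g1_fold fold-increase of the G1 responder taxa at 16/24 h.
#' @param n_bloom,n_g1 number of OTUs carrying each effect.
#' @param vessel_sd,noise_sd lognormal sd of vessel effects and residual
#'   sample noise.
#' @param baseline_sd sd of log baseline abundances.
#' @param seed mandatory integer seed.
#' @return a list of class `invitro_config`.
#' @export
invitro_config <- function(n_otus = 300, n_vessels = 3, depth = 20000,
                           bloom_fold = 15, g1_fold = 3, n_bloom = 20,
                           n_g1 = 30, vessel_sd = 0.3, noise_sd = 0.3,
                           baseline_sd = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(n_otus >= n_bloom + n_g1, n_vessels >= 1, depth >= 1)
  structure(cfg, class = "invitro_config")
}

#' Simulate the in vitro colon-model arm
#'
#' @param cfg an [invitro_config()].
#' @return list with `counts`, `metadata`, `taxonomy`, `tree`, `truth`
#'   (`bloom_otus`, `g1_otus`, `partition`, config).
#' @export
simulate_invitro <- function(cfg) {
  stopifnot(inherits(cfg, "invitro_config"))
  set.seed(cfg$seed)
  regimes <- c("ANTH/FLAV", "MIX", "PACs", "S/A", "TPP", "control")
  partition <- g1_g2_partition()
  tps <- c("0h", "16h", "24h")
  otus <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
  baseline <- stats::setNames(stats::rnorm(cfg$n_otus, 0, cfg$baseline_sd), otus)
  n_detect <- max(cfg$n_otus %/% 2, cfg$n_bloom + cfg$n_g1)
  detectable <- names(sort(baseline, decreasing = TRUE))[seq_len(n_detect)]
  special <- sample(detectable, cfg$n_bloom + cfg$n_g1)
  bloom <- special[seq_len(cfg$n_bloom)]
  g1resp <- setdiff(special, bloom)
  taxonomy <- synthetic_taxonomy(otus)
  taxonomy[bloom, "genus"] <- "Genus_bloom"
  taxonomy[bloom, "family"] <- "Family_bloom"
  taxonomy[g1resp, "genus"] <- "Genus_fiber"
  taxonomy[g1resp, "family"] <- "Family_fiber"
  grid <- expand.grid(vessel = seq_len(cfg$n_vessels), timepoint = tps,
                      regime = regimes, stringsAsFactors = FALSE)
  sample_ids <- sprintf("%s_V%d_%s", gsub("[/]", ".", grid$regime),
                        grid$vessel, grid$timepoint)
  counts <- matrix(0, nrow(grid), cfg$n_otus,
                   dimnames = list(sample_ids, otus))
  vessel_eff <- array(stats::rnorm(length(regimes) * cfg$n_vessels * cfg$n_otus,
                                   0, cfg$vessel_sd),
                      dim = c(length(regimes), cfg$n_vessels, cfg$n_otus))
  for (s in seq_len(nrow(grid))) {
    rg <- grid$regime[s]
    shift <- numeric(cfg$n_otus)
    if (grid$timepoint[s] != "0h" && !is.na(partition[rg])) {
      if (partition[rg] == "G2") shift[match(bloom, otus)] <- log(cfg$bloom_fold)
      if (partition[rg] == "G1") shift[match(g1resp, otus)] <- log(cfg$g1_fold)
    }
    lg <- baseline + shift +
      vessel_eff[match(rg, regimes), grid$vessel[s], ] +
      stats::rnorm(cfg$n_otus, 0, cfg$noise_sd)
    pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
    counts[s, ] <- stats::rmultinom(1, cfg$depth, pr)
  }
  meta <- data.frame(sample_id = sample_ids,
                     subject_id = paste0("V", grid$vessel),
                     arm = "invitro", group = grid$regime,
                     timepoint = grid$timepoint, row.names = sample_ids,
                     stringsAsFactors = FALSE)
  tree <- simulate_tree(otus, cfg$seed)
  list(counts = otu_table(counts), metadata = meta, taxonomy = taxonomy,
       tree = tree,
       truth = list(bloom_otus = bloom, g1_otus = g1resp,
                    partition = partition, config = cfg))
}
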