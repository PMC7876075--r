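#' Configuration for the synthetic two-condition ceRNA cohort
#'
#' Bundles all parameters of the synthetic-data generator. Defaults describe
#' the cohort used throughout the package's own evaluation: a modest miRNA
#' universe with a sparse interaction catalog, planted mRNA-lncRNA pairs
#' that share a guaranteed number of miRNAs and are co-expressed at Pearson
#' r = `coexpression_strength` in the normal condition, and a configurable
#' fraction of planted pairs whose coupling is removed in the disease
#' condition.
#'
#' @param n_mirna,n_mrna,n_lncrna Feature counts (all >= 1).
#' @param n_samples_per_condition Samples per condition (>= 3).
#' @param catalog_density Probability that a given miRNA targets a given
#'   feature, in (0, 1].
#' @param n_planted_pairs Number of planted ceRNA pairs; pair i couples
#'   mRNA i with lncRNA i.
#' @param planted_shared_mirnas Guaranteed number of miRNAs shared by each
#'   planted pair (>= 3, the candidate-filter minimum).
#' @param coexpression_strength Target Pearson correlation of planted pairs
#'   in the normal condition, in (0, 1).
#' @param decoupling_fraction Fraction of planted pairs whose shared latent
#'   factor is removed in the disease condition, in [0, 1].
#' @param noise_sd Multiplier on the idiosyncratic (non-shared) component of
#'   each planted feature and the residual noise of background features. At
#'   the default 1 the planted-pair correlation is calibrated exactly to
#'   `coexpression_strength`; at 0 planted pairs are perfectly correlated.
#' @param repression_gain Strength of the miRNA -> target repression term;
#'   the Dicer proxy scales this term multiplicatively per sample.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_mirna = 150, n_mrna = 200, n_lncrna = 60,
                              n_samples_per_condition = 60,
                              catalog_density = 0.02,
                              n_planted_pairs = 30,
                              planted_shared_mirnas = 5,
                              coexpression_strength = 0.7,
                              decoupling_fraction = 0.5,
                              noise_sd = 1,
                              repression_gain = 0.5,
                              seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_lncrna = as.integer(n_lncrna),
              n_samples_per_condition = as.integer(n_samples_per_condition),
              catalog_density = catalog_density,
              n_planted_pairs = as.integer(n_planted_pairs),
              planted_shared_mirnas = as.integer(planted_shared_mirnas),
              coexpression_strength = coexpression_strength,
              decoupling_fraction = decoupling_fraction,
              noise_sd = noise_sd, repression_gain = repression_gain,
              seed = as.integer(seed))
  counts <- c("n_mirna", "n_mrna", "n_lncrna", "n_samples_per_condition",
              "n_planted_pairs", "planted_shared_mirnas")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("config field '", f, "' must be a count >= 1", call. = FALSE)
  if (cfg$catalog_density <= 0 || cfg$catalog_density > 1)
    stop("catalog_density must lie in (0, 1]", call. = FALSE)
  if (cfg$planted_shared_mirnas < 3L)
    stop("planted_shared_mirnas must be >= 3 (the candidate-filter minimum)",
         call. = FALSE)
  if (cfg$coexpression_strength <= 0 || cfg$coexpression_strength >= 1)
    stop("coexpression_strength must lie in (0, 1)", call. = FALSE)
  if (cfg$decoupling_fraction < 0 || cfg$decoupling_fraction > 1)
    stop("decoupling_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$n_planted_pairs > min(cfg$n_mrna, cfg$n_lncrna))
    stop("n_planted_pairs exceeds the number of mRNAs or lncRNAs",
         call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

sim_feature_ids <- function(config) {
  list(mirna = sprintf("miR-%03d", seq_len(config$n_mirna)),
       mrna = sprintf("mRNA-%04d", seq_len(config$n_mrna)),
       lncrna = sprintf("lnc-%04d", seq_len(config$n_lncrna)),
       dicer = "DICER1")
}

#' Simulate a starBase-like miRNA-target interaction catalog
#'
#' Each miRNA targets a Bernoulli(`catalog_density`) subset of mRNAs and of
#' lncRNAs; on top of that background, every planted pair (mRNA i, lncRNA i)
#' is guaranteed at least `planted_shared_mirnas` common targeting miRNAs.
#'
#' @param config A `simulation_config`.
#' @return An `interaction_catalog`.
#' @export
simulate_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$planted_shared_mirnas > config$n_mirna)
    stop("miRNA universe too small: a planted pair cannot receive ",
         config$planted_shared_mirnas, " shared miRNAs from only ",
         config$n_mirna, " miRNAs", call. = FALSE)
  ids <- sim_feature_ids(config)
  with_seed(substream_seed(config$seed, "catalog"), {
    M <- matrix(runif(config$n_mirna * config$n_mrna) < config$catalog_density,
                config$n_mirna, config$n_mrna,
                dimnames = list(ids$mirna, ids$mrna))
    L <- matrix(runif(config$n_mirna * config$n_lncrna) < config$catalog_density,
                config$n_mirna, config$n_lncrna,
                dimnames = list(ids$mirna, ids$lncrna))
    for (i in seq_len(config$n_planted_pairs)) {
      shared <- sample.int(config$n_mirna, config$planted_shared_mirnas)
      M[shared, i] <- TRUE
      L[shared, i] <- TRUE
    }
    to_edges <- function(inc) {
      w <- which(inc, arr.ind = TRUE)
      data.frame(mirna = rownames(inc)[w[, 1]],
                 target = colnames(inc)[w[, 2]],
                 stringsAsFactors = FALSE)
    }
    interaction_catalog(to_edges(M), to_edges(L))
  })
}

#' Simulate two-condition expression profiles with planted ceRNA structure
#'
#' Planted pairs draw both members from a shared standard-normal latent
#' factor with loading `sqrt(coexpression_strength)` plus an idiosyncratic
#' term, so their expected Pearson correlation equals
#' `coexpression_strength` in the normal condition (exactly so at
#' `noise_sd = 1`). A random `decoupling_fraction` of planted pairs loses
#' the shared factor in the disease condition (each member receives an
#' independent factor of the same variance). All catalog targets are
#' additionally repressed by the mean expression of their targeting miRNAs,
#' scaled per sample by a Dicer proxy feature: samples with high Dicer
#' experience stronger miRNA-mediated repression. Values live on a
#' log2-like continuous scale (baseline 8).
#'
#' @param catalog An `interaction_catalog` from [simulate_catalog()].
#' @param config The same `simulation_config` used for the catalog.
#' @return A list with components `expr` (features x samples matrix over
#'   miRNAs, mRNAs, lncRNAs and the Dicer proxy), `labels` (named condition
#'   vector, values "normal"/"disease"), `feature_type` (named vector:
#'   mirna/mrna/lncrna), and `truth` (list with `planted_pairs`,
#'   `decoupled_pairs` data.frames and `dicer_proxy_id`).
#' @export
simulate_expression <- function(catalog, config) {
  stopifnot(inherits(catalog, "interaction_catalog"),
            inherits(config, "simulation_config"))
  if (config$n_samples_per_condition < 3L)
    stop("need at least 3 samples per condition for correlations",
         call. = FALSE)
  ids <- sim_feature_ids(config)
  n <- config$n_samples_per_condition
  samples <- sprintf("S%03d", seq_len(2L * n))
  labels <- setNames(rep(c("normal", "disease"), each = n), samples)

  r <- config$coexpression_strength
  a <- sqrt(r)                      # shared-factor loading
  s <- config$noise_sd * sqrt(1 - r) # idiosyncratic scale for planted pairs

  with_seed(substream_seed(config$seed, "expression"), {
    n_tot <- 2L * n
    mir <- matrix(rnorm(config$n_mirna * n_tot), config$n_mirna, n_tot,
                  dimnames = list(ids$mirna, samples))
    dicer <- rnorm(n_tot)
    gain_scale <- 2 * stats::pnorm(dicer)  # in (0,2), mean 1, monotone in Dicer

    repression <- function(feature, class_map) {
      mir_ids <- class_map[[feature]]
      if (is.null(mir_ids) || !length(mir_ids)) return(rep(0, n_tot))
      -config$repression_gain * gain_scale *
        colMeans(mir[mir_ids, , drop = FALSE])
    }

    n_dec <- round(config$decoupling_fraction * config$n_planted_pairs)
    decoupled <- sort(sample.int(config$n_planted_pairs, n_dec))
    disease_cols <- which(labels == "disease")

    mrna <- matrix(config$noise_sd * rnorm(config$n_mrna * n_tot),
                   config$n_mrna, n_tot, dimnames = list(ids$mrna, samples))
    lnc <- matrix(config$noise_sd * rnorm(config$n_lncrna * n_tot),
                  config$n_lncrna, n_tot, dimnames = list(ids$lncrna, samples))

    for (i in seq_len(config$n_planted_pairs)) {
      z <- rnorm(n_tot)
      z_m <- z_l <- z
      if (i %in% decoupled) {
        # disease condition: members get independent factors of equal variance
        z_m[disease_cols] <- rnorm(n)
        z_l[disease_cols] <- rnorm(n)
      }
      mrna[i, ] <- a * z_m + s * rnorm(n_tot)
      lnc[i, ] <- a * z_l + s * rnorm(n_tot)
    }
    for (g in rownames(mrna))
      mrna[g, ] <- mrna[g, ] + repression(g, catalog$mirnas_by_mrna)
    for (g in rownames(lnc))
      lnc[g, ] <- lnc[g, ] + repression(g, catalog$mirnas_by_lncrna)

    expr <- rbind(mir, mrna, lnc, DICER1 = dicer) + 8
    feature_type <- setNames(
      c(rep("mirna", config$n_mirna), rep("mrna", config$n_mrna),
        rep("lncrna", config$n_lncrna), "mrna"),
      rownames(expr))
    truth <- list(
      planted_pairs = data.frame(
        mrna = ids$mrna[seq_len(config$n_planted_pairs)],
        lncrna = ids$lncrna[seq_len(config$n_planted_pairs)],
        stringsAsFactors = FALSE),
      decoupled_pairs = data.frame(
        mrna = ids$mrna[decoupled], lncrna = ids$lncrna[decoupled],
        stringsAsFactors = FALSE),
      dicer_proxy_id = ids$dicer)
    list(expr = expr, labels = labels, feature_type = feature_type,
         truth = truth)
  })
}

#' Simulate probe and transcript sequences for re-annotation fixtures
#'
#' Each transcript is a random DNA sequence carrying a known number of
#' non-overlapping exact probe substrings; decoy probes are random sequences
#' verified to match no transcript. The truth mapping allows exact
#' evaluation of the probe re-annotation stage.
#'
#' @param n_transcripts Number of transcripts.
#' @param probes_per_transcript Probes embedded per transcript; scalar or a
#'   vector of length `n_transcripts`.
#' @param probe_length Probe length in bases.
#' @param n_decoy_probes Number of decoy probes matching no transcript.
#' @param transcript_length Transcript length in bases.
#' @param seed Integer seed.
#' @return A list with `probes` and `transcripts`
#'   ([Biostrings::DNAStringSet]) and `truth` (data.frame probe ->
#'   transcript; decoys have transcript NA).
#' @export
simulate_probe_data <- function(n_transcripts, probes_per_transcript,
                                probe_length = 25, n_decoy_probes = 0,
                                transcript_length = 400, seed = 1L) {
  stopifnot(n_transcripts >= 1, probe_length >= 1)
  ppt <- rep_len(as.integer(probes_per_transcript), n_transcripts)
  if (any(ppt * probe_length > transcript_length))
    stop("cannot place ", max(ppt), " non-overlapping probes of length ",
         probe_length, " in a transcript of length ", transcript_length,
         call. = FALSE)
  if (probe_length > transcript_length)
    stop("probe_length exceeds transcript length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  with_seed(substream_seed(seed, "probes"), {
    tx <- vapply(seq_len(n_transcripts), function(i)
      paste(sample(bases, transcript_length, replace = TRUE), collapse = ""),
      character(1))
    names(tx) <- sprintf("TX%03d", seq_len(n_transcripts))
    probes <- character(0); origin <- character(0)
    for (i in seq_len(n_transcripts)) {
      if (ppt[i] == 0L) next
      # non-overlapping placement: evenly spaced block starts
      starts <- floor(seq(1, transcript_length - probe_length + 1,
                          length.out = ppt[i]))
      if (ppt[i] > 1L && any(diff(starts) < probe_length))
        starts <- seq(1, by = probe_length, length.out = ppt[i])
      p <- substring(tx[i], starts, starts + probe_length - 1L)
      names(p) <- sprintf("%s_p%02d", names(tx)[i], seq_along(p))
      probes <- c(probes, p)
      origin <- c(origin, rep(names(tx)[i], ppt[i]))
    }
    decoys <- character(0)
    attempts <- 0L
    while (length(decoys) < n_decoy_probes) {
      attempts <- attempts + 1L
      if (attempts > 100L * max(1L, n_decoy_probes))
        stop("failed to generate non-matching decoy probes", call. = FALSE)
      cand <- paste(sample(bases, probe_length, replace = TRUE), collapse = "")
      if (!any(vapply(tx, function(t) grepl(cand, t, fixed = TRUE),
                      logical(1))))
        decoys <- c(decoys, cand)
    }
    if (n_decoy_probes > 0)
      names(decoys) <- sprintf("DECOY%03d", seq_len(n_decoy_probes))
    all_probes <- c(probes, decoys)
    truth <- data.frame(
      probe = names(all_probes),
      transcript = c(origin, rep(NA_character_, n_decoy_probes)),
      stringsAsFactors = FALSE)
    list(probes = Biostrings::DNAStringSet(all_probes),
         transcripts = Biostrings::DNAStringSet(tx),
         truth = truth)
  })
}

#' Simulate a two-class marker cohort for diagnostic-panel evaluation
#'
#' Generates a cohort in which a known subset of markers carries an additive
#' mean shift between disease and normal samples while the remaining markers
#' are pure noise -- the ground truth for marker-panel recovery and for the
#' expected gain in cross-validated accuracy as informative markers are
#' combined.
#'
#' @param n_markers Total markers.
#' @param n_informative Markers with a real between-condition shift.
#' @param effect_size Mean shift (in noise-SD units) of informative markers.
#' @param n_per_condition Samples per condition.
#' @param seed Integer seed.
#' @return List with `expr` (markers x samples), `labels` (named condition
#'   vector) and `informative` (marker ids carrying signal).
#' @export
simulate_marker_cohort <- function(n_markers = 9, n_informative = 5,
                                   effect_size = 0.7, n_per_condition = 100,
                                   seed = 1L) {
  stopifnot(n_informative <= n_markers, n_per_condition >= 3)
  n_tot <- 2L * n_per_condition
  samples <- sprintf("S%03d", seq_len(n_tot))
  labels <- setNames(rep(c("normal", "disease"), each = n_per_condition),
                     samples)
  markers <- sprintf("marker-%02d", seq_len(n_markers))
  with_seed(substream_seed(seed, "markers"), {
    expr <- matrix(rnorm(n_markers * n_tot), n_markers, n_tot,
                   dimnames = list(markers, samples))
    shift <- effect_size * (labels == "disease")
    for (i in seq_len(n_informative)) expr[i, ] <- expr[i, ] + shift
    list(expr = expr + 8, labels = labels,
         informative = markers[seq_len(n_informative)])
  })
}
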