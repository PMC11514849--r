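#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a paired
#' tumor / distant-normal-tissue (DNT) cohort quantified by multi-batch
#' isobaric labeling with one internal-standard (IS) channel per batch,
#' intratumoral magnesium content measured per patient, somatic mutations,
#' and overall survival. Defaults mirror the cohort structure of a 115-patient
#' colorectal study: 27 batches of a 10-plex (9 sample channels + IS),
#' Mg content on 162-920 ug per g extracted protein, roughly a quarter of
#' proteins planted positively and a quarter negatively correlated with Mg,
#' about half of patients censored, and a small set of hypermutated samples
#' most of which carry mismatch-repair / replicative-polymerase mutations.
#'
#' Correlation planting uses a Gaussian copula: a latent standard-normal
#' patient score drives both the (rank-preserved) Mg content and the planted
#' feature abundances, with the latent Pearson correlation chosen as
#' `2*sin(pi*rho/6)` (the inverse of the Gaussian Spearman identity) and
#' inflated to compensate for measurement and IS noise, so the *observed*
#' Spearman correlation targets `target_rho`. A target that would require a
#' latent correlation above 1 after noise compensation is an error.
#'
#' @param n_patients number of patients (each contributes a tumor and a DNT
#'   sample).
#' @param n_batches number of quantification batches.
#' @param plex_size channels per batch; one channel is reserved for the IS.
#' @param n_proteins,n_phosphosites feature-space sizes.
#' @param mg_range length-2 positive range of Mg content (ug per g protein).
#' @param mg_dist `"uniform"` or `"log_uniform"` sampling of Mg on `mg_range`.
#' @param frac_pos_corr,frac_neg_corr fractions of features planted positively
#'   / negatively correlated with Mg (applied to proteins and phosphosites).
#' @param target_rho planted Spearman correlation magnitude, in (-1, 1).
#' @param missing_frac expected fraction of missing intensities (encoded as
#'   zero in the emitted tables).
#' @param missing_mechanism `"mcar"` (default) or `"mnar"`
#'   (intensity-dependent: low-abundance values go missing more often).
#' @param batch_scale_sd sd of the per-batch multiplicative log-normal scale.
#' @param n_genes number of background genes in the mutation universe.
#' @param background_mut_rate per-gene per-sample Bernoulli mutation rate.
#' @param planted_genes data.frame with columns `gene`, `freq_low_mg`,
#'   `freq_high_mg`: genes whose mutation frequency differs between Mg groups
#'   (groups defined by the true cutpoint, the midpoint of `mg_range`).
#' @param n_hypermutators number of samples with tumor mutational burden
#'   above 10 mutations/Mb.
#' @param frac_hypermut_mmr fraction of hypermutators that additionally carry
#'   a mutation in a mismatch-repair / polymerase gene (and would thus be
#'   excluded by [hypermutation_filter()]).
#' @param exome_mb captured exome size in Mb used for mutational burden.
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param log_hr_per_mg_unit log hazard ratio per standard deviation of Mg
#'   content (negative: higher Mg, better survival).
#' @param censor_rate expected fraction of patients censored.
#' @param frac_tumor_diff fraction of proteins with a planted tumor-vs-DNT
#'   abundance shift (|log2 FC| = 1).
#' @param contaminant_frac fraction of protein rows flagged as potential
#'   contaminant or reverse hits.
#' @param protein_sd,meas_noise_sd,is_noise_sd,loading_sd noise model knobs on
#'   the natural-log intensity scale: biological feature sd, per-measurement
#'   noise, IS-channel measurement noise, and per-sample loading sd.
#' @param seed integer seed; identical configs (including seed) reproduce
#'   identical cohorts.
#' @return a validated `mg_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 115,
                          n_batches = 27,
                          plex_size = 10,
                          n_proteins = 2000,
                          n_phosphosites = 600,
                          mg_range = c(162, 920),
                          mg_dist = c("uniform", "log_uniform"),
                          frac_pos_corr = 0.25,
                          frac_neg_corr = 0.24,
                          target_rho = 0.5,
                          missing_frac = 0.15,
                          missing_mechanism = c("mcar", "mnar"),
                          batch_scale_sd = 0.3,
                          n_genes = 400,
                          background_mut_rate = 0.05,
                          planted_genes = default_planted_genes(),
                          n_hypermutators = 5,
                          frac_hypermut_mmr = 0.7,
                          exome_mb = 38,
                          baseline_hazard = 0.012,
                          log_hr_per_mg_unit = -0.7,
                          censor_rate = 0.53,
                          frac_tumor_diff = 0.1,
                          contaminant_frac = 0.02,
                          protein_sd = 0.6,
                          meas_noise_sd = 0.25,
                          is_noise_sd = 0.1,
                          loading_sd = 0.2,
                          seed = 1L) {
  cfg <- list(
    n_patients = assert_count(n_patients, "n_patients", 2L),
    n_batches = assert_count(n_batches, "n_batches", 1L),
    plex_size = assert_count(plex_size, "plex_size", 2L),
    n_proteins = assert_count(n_proteins, "n_proteins", 1L),
    n_phosphosites = assert_count(n_phosphosites, "n_phosphosites", 0L),
    mg_range = mg_range,
    mg_dist = match.arg(mg_dist),
    frac_pos_corr = assert_scalar_number(frac_pos_corr, "frac_pos_corr", 0, 1),
    frac_neg_corr = assert_scalar_number(frac_neg_corr, "frac_neg_corr", 0, 1),
    target_rho = assert_scalar_number(target_rho, "target_rho", -0.999, 0.999),
    missing_frac = assert_scalar_number(missing_frac, "missing_frac", 0, 1),
    missing_mechanism = match.arg(missing_mechanism),
    batch_scale_sd = assert_scalar_number(batch_scale_sd, "batch_scale_sd", 0),
    n_genes = assert_count(n_genes, "n_genes", 1L),
    background_mut_rate = assert_scalar_number(background_mut_rate,
                                               "background_mut_rate", 0, 1),
    planted_genes = planted_genes,
    n_hypermutators = assert_count(n_hypermutators, "n_hypermutators", 0L),
    frac_hypermut_mmr = assert_scalar_number(frac_hypermut_mmr,
                                             "frac_hypermut_mmr", 0, 1),
    exome_mb = assert_scalar_number(exome_mb, "exome_mb", 1e-6),
    baseline_hazard = assert_scalar_number(baseline_hazard, "baseline_hazard",
                                           1e-12),
    log_hr_per_mg_unit = assert_scalar_number(log_hr_per_mg_unit,
                                              "log_hr_per_mg_unit"),
    censor_rate = assert_scalar_number(censor_rate, "censor_rate", 0, 0.99),
    frac_tumor_diff = assert_scalar_number(frac_tumor_diff, "frac_tumor_diff",
                                           0, 1),
    contaminant_frac = assert_scalar_number(contaminant_frac,
                                            "contaminant_frac", 0, 0.5),
    protein_sd = assert_scalar_number(protein_sd, "protein_sd", 1e-6),
    meas_noise_sd = assert_scalar_number(meas_noise_sd, "meas_noise_sd", 0),
    is_noise_sd = assert_scalar_number(is_noise_sd, "is_noise_sd", 0),
    loading_sd = assert_scalar_number(loading_sd, "loading_sd", 0),
    seed = assert_count(seed, "seed")
  )
  if (length(cfg$mg_range) != 2L || any(!is.finite(cfg$mg_range)) ||
      cfg$mg_range[1] <= 0 || diff(cfg$mg_range) <= 0)
    stopf("'mg_range' must be an increasing pair of positive values")
  if (cfg$frac_pos_corr + cfg$frac_neg_corr > 1)
    stopf("frac_pos_corr + frac_neg_corr must be <= 1")
  if (cfg$n_batches * (cfg$plex_size - 1L) < 2L * cfg$n_patients)
    stopf("batch capacity %d < %d samples (2 per patient)",
          cfg$n_batches * (cfg$plex_size - 1L), 2L * cfg$n_patients)
  if (!is.data.frame(cfg$planted_genes) ||
      !all(c("gene", "freq_low_mg", "freq_high_mg") %in%
             names(cfg$planted_genes)))
    stopf("'planted_genes' needs columns gene, freq_low_mg, freq_high_mg")
  # copula feasibility: latent Pearson needed after noise attenuation and
  # compensation of the compositional bias of equal-total normalization
  compensated_couplings(cfg, cfg$frac_pos_corr, cfg$frac_neg_corr)
  class(cfg) <- "mg_cohort_config"
  cfg
}

#' @rdname cohort_config
#' @export
default_planted_genes <- function() {
  data.frame(
    gene = c("LMG1", "LMG2", "LMG3", "LMG4", "LMG5", "HMG1", "HMG2"),
    freq_low_mg  = c(0.60, 0.55, 0.55, 0.50, 0.45, 0.20, 0.22),
    freq_high_mg = c(0.15, 0.12, 0.10, 0.10, 0.08, 0.60, 0.62),
    stringsAsFactors = FALSE
  )
}

mmr_polymerase_genes <- function() {
  c("MSH2", "MSH6", "MLH1", "PMS2", "POLD1", "POLE")
}

# Pearson correlation the latent copula must carry so that the observed
# (noise-attenuated) Spearman correlation hits rho_s.
latent_pearson_for <- function(rho_s, cfg) {
  r_tot <- 2 * sin(pi * rho_s / 6)
  atten <- cfg$protein_sd /
    sqrt(cfg$protein_sd^2 + cfg$meas_noise_sd^2 + cfg$is_noise_sd^2)
  r <- r_tot / atten
  if (abs(r) > 0.999)
    stopf(paste0("impossible copula target: |target_rho| = %.3f needs latent ",
                 "Pearson %.3f > 1 after noise compensation; lower the target ",
                 "or the noise"), abs(rho_s), abs(r))
  r
}

# Equal-total normalization followed by per-sample centering subtracts the
# feature-average Mg coupling from every feature (a compositional effect).
# The planted latent Pearson couplings r_pos / r_neg are therefore solved so
# that the *post-centering* correlation with the Mg driver hits the target
# rho_t = 2*sin(pi*rho_s/6). Writing couplings in units of the biological sd
# (relative noise tau2 = (meas^2 + is^2)/bio^2) and the signed feature-mean
# coupling m = f_pos*r_pos - f_neg*r_neg, the post-centering coupling
# s = r - m of a planted feature must satisfy
#   s / sqrt(s^2 + 1 - r^2 + tau2) = rho_t,
# a quadratic in s given m:  s^2 + 2 rho^2 m s + rho^2 (m^2 - 1 - tau2) = 0.
# m is found by fixed-point iteration over the two closed-form roots.
compensated_couplings <- function(cfg, f_pos, f_neg) {
  rho <- abs(2 * sin(pi * cfg$target_rho / 6))
  if (rho == 0 || (f_pos == 0 && f_neg == 0))
    return(list(pos = latent_pearson_for(abs(cfg$target_rho), cfg),
                neg = latent_pearson_for(abs(cfg$target_rho), cfg)))
  tau2 <- (cfg$meas_noise_sd^2 + cfg$is_noise_sd^2) / cfg$protein_sd^2
  m <- 0; r_p <- r_n <- NA_real_
  for (it in seq_len(500)) {
    disc <- rho^4 * m^2 - rho^2 * (m^2 - 1 - tau2)
    if (disc < 0)
      stopf("impossible copula target: no real coupling reaches |rho| = %.3f",
            abs(cfg$target_rho))
    r_p <- (-rho^2 * m + sqrt(disc)) + m
    r_n <- (rho^2 * m + sqrt(disc)) - m
    m_new <- f_pos * r_p - f_neg * r_n
    if (abs(m_new - m) < 1e-12) break
    m <- m_new
  }
  if (max(abs(r_p), abs(r_n)) > 0.999)
    stopf(paste0("impossible copula target: |target_rho| = %.3f needs a ",
                 "latent Pearson above 1 after compensating noise and the ",
                 "compositional bias of equal-total normalization"),
          abs(cfg$target_rho))
  list(pos = r_p, neg = r_n)
}

nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins",
    "Frame_Shift_Del", "Splice_Site", "In_Frame_Ins", "In_Frame_Del",
    "Translation_Start_Site", "Nonstop_Mutation")
}

#' Simulate a complete synthetic Mg-omics cohort
#'
#' Generates a clinical table, batched protein and phosphosite quantification
#' tables in the dialect read by [read_quant_table()], a somatic-mutation MAF
#' table, gene sets, a gene-length annotation and a truth ledger of every
#' planted effect. See [cohort_config()] for the generative model.
#'
#' @param config an `mg_cohort_config` from [cohort_config()].
#' @return an `mg_cohort` bundle: `clinical`, `batches` (per batch: `proteins`
#'   and `phospho` data.frames in the raw table dialect plus the sample ids),
#'   `maf`, `gene_sets`, `gene_lengths`, `site_map`, and `truth` (the
#'   planted-effect ledger).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "mg_cohort_config"))
    stopf("'config' must come from cohort_config()")
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  tumor_ids <- paste0(patients, "_T")
  dnt_ids <- paste0(patients, "_N")

  ## --- Mg content via Gaussian copula driver ------------------------------
  z <- stats::rnorm(n)
  u <- stats::pnorm(z)
  mg <- if (cfg$mg_dist == "uniform") {
    cfg$mg_range[1] + u * diff(cfg$mg_range)
  } else {
    exp(log(cfg$mg_range[1]) + u * diff(log(cfg$mg_range)))
  }
  mg <- round(mg, 2)
  mg_dnt <- round(mg * stats::runif(n, 0.70, 0.95), 2)

  ## --- clinical covariates and survival -----------------------------------
  side <- sample(c("right", "left"), n, replace = TRUE, prob = c(49, 66) / 115)
  gender <- sample(c("female", "male"), n, replace = TRUE,
                   prob = c(49, 66) / 115)
  age <- round(pmin(pmax(stats::rnorm(n, 52, 16), 20), 90))
  zmg <- as.numeric(scale(mg))
  rate <- cfg$baseline_hazard * exp(cfg$log_hr_per_mg_unit * zmg)
  t_event <- stats::rexp(n, rate)
  cens_rate <- cfg$baseline_hazard * cfg$censor_rate /
    max(1 - cfg$censor_rate, 1e-9)
  t_cens <- pmin(stats::rexp(n, cens_rate), 120)
  os_months <- pmax(ceiling(pmin(t_event, t_cens)), 1)
  os_event <- as.integer(t_event <= t_cens)

  clinical <- data.frame(
    patient_id = patients, tumor_sample = tumor_ids, dnt_sample = dnt_ids,
    side = side, gender = gender, age = age,
    os_months = os_months, os_event = os_event,
    mg = mg, mg_dnt = mg_dnt,
    stringsAsFactors = FALSE
  )

  ## --- planted feature structure ------------------------------------------
  proteins <- sprintf("PROT%04d", seq_len(cfg$n_proteins))
  n_pos <- round(cfg$frac_pos_corr * cfg$n_proteins)
  n_neg <- round(cfg$frac_neg_corr * cfg$n_proteins)
  pos_prot <- proteins[seq_len(n_pos)]
  neg_prot <- proteins[n_pos + seq_len(n_neg)]
  cc <- compensated_couplings(cfg, length(pos_prot) / cfg$n_proteins,
                              length(neg_prot) / cfg$n_proteins)
  r_prot <- stats::setNames(numeric(cfg$n_proteins), proteins)
  r_prot[pos_prot] <- cc$pos
  r_prot[neg_prot] <- -cc$neg

  n_flag <- round(cfg$contaminant_frac * cfg$n_proteins)
  flag_pool <- setdiff(proteins, c(pos_prot, neg_prot))
  flagged <- sort(sample(flag_pool, min(n_flag, length(flag_pool))))
  con_flag <- flagged[seq_len(floor(length(flagged) / 2))]
  rev_flag <- setdiff(flagged, con_flag)

  n_diff <- round(cfg$frac_tumor_diff * cfg$n_proteins)
  diff_pool <- setdiff(proteins, flagged)
  diff_prot <- sort(sample(diff_pool, min(n_diff, length(diff_pool))))
  diff_effect <- stats::setNames(
    sample(c(-1, 1), length(diff_prot), replace = TRUE), diff_prot)

  mu <- stats::setNames(stats::rnorm(cfg$n_proteins, 16, 1.5), proteins)
  sdp <- cfg$protein_sd

  # latent ln-abundance, tumors coupled to the Mg driver z
  lat_t <- matrix(stats::rnorm(cfg$n_proteins * n), cfg$n_proteins, n,
                  dimnames = list(proteins, tumor_ids))
  lat_t <- mu + sdp * (r_prot * matrix(z, cfg$n_proteins, n, byrow = TRUE) +
                         sqrt(1 - r_prot^2) * lat_t)
  lat_t[diff_prot, ] <- lat_t[diff_prot, ] + diff_effect[diff_prot] * log(2)
  lat_n <- mu + sdp * matrix(stats::rnorm(cfg$n_proteins * n),
                             cfg$n_proteins, n,
                             dimnames = list(proteins, dnt_ids))

  ## --- phosphosites --------------------------------------------------------
  if (cfg$n_phosphosites > 0) {
    parent <- sample(proteins, cfg$n_phosphosites, replace = TRUE)
    sites <- paste0(parent, "_S", sample(20:1500, cfg$n_phosphosites,
                                         replace = TRUE))
    dup <- duplicated(sites)
    while (any(dup)) {
      sites[dup] <- paste0(parent[dup], "_S",
                           sample(20:1500, sum(dup), replace = TRUE))
      dup <- duplicated(sites)
    }
    site_map <- stats::setNames(parent, sites)
    n_pos_s <- round(cfg$frac_pos_corr * cfg$n_phosphosites)
    n_neg_s <- round(cfg$frac_neg_corr * cfg$n_phosphosites)
    pos_sites <- sites[seq_len(n_pos_s)]
    neg_sites <- sites[n_pos_s + seq_len(n_neg_s)]
    cc_s <- compensated_couplings(
      cfg, length(pos_sites) / cfg$n_phosphosites,
      length(neg_sites) / cfg$n_phosphosites)
    r_site <- stats::setNames(numeric(cfg$n_phosphosites), sites)
    r_site[pos_sites] <- cc_s$pos
    r_site[neg_sites] <- -cc_s$neg
    mu_s <- stats::setNames(stats::rnorm(cfg$n_phosphosites, 15, 1.2), sites)

    planted_s <- r_site != 0
    eps <- matrix(stats::rnorm(cfg$n_phosphosites * n),
                  cfg$n_phosphosites, n, dimnames = list(sites, tumor_ids))
    lat_s_t <- matrix(0, cfg$n_phosphosites, n,
                      dimnames = list(sites, tumor_ids))
    # planted sites couple to Mg through their own latent, independent of the
    # parent protein; background sites track the parent protein partially
    if (any(planted_s))
      lat_s_t[planted_s, ] <- mu_s[planted_s] + sdp *
        (r_site[planted_s] * matrix(z, sum(planted_s), n, byrow = TRUE) +
           sqrt(1 - r_site[planted_s]^2) * eps[planted_s, , drop = FALSE])
    bg <- !planted_s
    parent_centered <- lat_t[parent, , drop = FALSE] -
      mu[parent]
    lat_s_t[bg, ] <- mu_s[bg] + 0.7 * parent_centered[bg, , drop = FALSE] +
      sdp * sqrt(1 - 0.7^2) * eps[bg, , drop = FALSE]
    lat_s_n <- mu_s + 0.7 * (lat_n[parent, , drop = FALSE] - mu[parent]) +
      sdp * sqrt(1 - 0.7^2) *
        matrix(stats::rnorm(cfg$n_phosphosites * n),
               cfg$n_phosphosites, n, dimnames = list(sites, dnt_ids))
    loc_prob <- round(stats::runif(cfg$n_phosphosites, 0.40, 1.00), 3)
    loc_prob[planted_s] <- round(stats::runif(sum(planted_s), 0.90, 1.00), 3)
    names(loc_prob) <- sites
  } else {
    sites <- character(0); site_map <- stats::setNames(character(0),
                                                       character(0))
    pos_sites <- neg_sites <- character(0)
    lat_s_t <- lat_s_n <- NULL; loc_prob <- numeric(0); mu_s <- numeric(0)
  }

  ## --- batch assembly ------------------------------------------------------
  all_samples <- as.character(rbind(tumor_ids, dnt_ids))  # pair-interleaved
  cap <- cfg$plex_size - 1L
  batch_of <- rep(sprintf("B%02d", seq_len(cfg$n_batches)),
                  each = cap)[seq_along(all_samples)]
  upept <- stats::setNames(
    pmax(1L, stats::rpois(cfg$n_proteins, 6L) +
           ifelse(stats::runif(cfg$n_proteins) < 0.10, -5L, 0L)),
    proteins)
  lat_all <- cbind(lat_t, lat_n)
  lat_s_all <- if (length(sites)) cbind(lat_s_t, lat_s_n) else NULL
  loading <- stats::setNames(
    exp(stats::rnorm(length(all_samples), 0, cfg$loading_sd)), all_samples)

  make_intensities <- function(latent, ids, bscale, is_noise_row) {
    m <- exp(latent[, ids, drop = FALSE] +
               matrix(stats::rnorm(nrow(latent) * length(ids),
                                   0, cfg$meas_noise_sd),
                      nrow(latent), length(ids)))
    m <- m * bscale * rep(loading[ids], each = nrow(latent))
    is_chan <- exp(is_noise_row) * bscale
    cbind(Intensity_IS = is_chan, m)
  }

  apply_missing <- function(m) {
    if (cfg$missing_frac == 0) return(m)
    sample_cols <- setdiff(colnames(m), "Intensity_IS")
    v <- m[, sample_cols, drop = FALSE]
    if (cfg$missing_mechanism == "mcar") {
      drop <- matrix(stats::runif(length(v)) < cfg$missing_frac,
                     nrow(v), ncol(v))
    } else {
      # intensity-dependent: rank within column, low intensities drop more
      pr <- apply(v, 2, function(col) {
        rk <- rank(col) / (length(col) + 1)
        p <- (1 - rk); p * cfg$missing_frac / mean(p)
      })
      drop <- matrix(stats::runif(length(v)) < pmin(pr, 1), nrow(v), ncol(v))
    }
    v[drop] <- 0
    m[, sample_cols] <- v
    m
  }

  batches <- list()
  for (b in unique(batch_of)) {
    ids <- all_samples[batch_of == b]
    bscale <- exp(stats::rnorm(1, 0, cfg$batch_scale_sd))
    ref_noise_p <- mu + stats::rnorm(cfg$n_proteins, 0, cfg$is_noise_sd)
    ip <- apply_missing(make_intensities(lat_all, ids, bscale, ref_noise_p))
    prot_tab <- data.frame(
      Protein = proteins,
      Unique_Peptides = as.integer(upept),
      Contaminant = ifelse(proteins %in% con_flag, "+", ""),
      Reverse = ifelse(proteins %in% rev_flag, "+", ""),
      stringsAsFactors = FALSE
    )
    prot_tab <- cbind(prot_tab, as.data.frame(signif(ip, 7)))
    colnames(prot_tab)[-(1:4)] <- c("Intensity_IS", paste0("Intensity_", ids))

    if (length(sites)) {
      ref_noise_s <- mu_s + stats::rnorm(cfg$n_phosphosites, 0,
                                         cfg$is_noise_sd)
      is_ <- apply_missing(make_intensities(lat_s_all, ids, bscale,
                                            ref_noise_s))
      phos_tab <- data.frame(
        Site = sites,
        Parent_Protein = unname(site_map),
        Localization_Prob = unname(loc_prob),
        Contaminant = "",
        Reverse = "",
        stringsAsFactors = FALSE
      )
      phos_tab <- cbind(phos_tab, as.data.frame(signif(is_, 7)))
      colnames(phos_tab)[-(1:5)] <- c("Intensity_IS",
                                      paste0("Intensity_", ids))
    } else phos_tab <- NULL

    batches[[b]] <- list(batch_id = b, samples = ids,
                         proteins = prot_tab, phospho = phos_tab)
  }

  ## --- somatic mutations ---------------------------------------------------
  mg_cutpoint <- mean(cfg$mg_range)
  low_mg <- mg < mg_cutpoint
  bg_genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  pg <- cfg$planted_genes
  universe <- c(bg_genes, pg$gene, mmr_polymerase_genes(), "GIANT1")
  gene_lengths <- data.frame(
    gene = universe,
    aa_length = c(sample(300:3000, cfg$n_genes, replace = TRUE),
                  sample(400:2500, nrow(pg), replace = TRUE),
                  c(934, 1360, 756, 862, 1107, 2286),  # MMR/polymerase sizes
                  5500L),
    stringsAsFactors = FALSE
  )

  spectrum_low <- c("C>A" = 0.10, "C>G" = 0.06, "C>T" = 0.22,
                    "T>A" = 0.08, "T>C" = 0.42, "T>G" = 0.12)
  spectrum_high <- c("C>A" = 0.16, "C>G" = 0.12, "C>T" = 0.30,
                     "T>A" = 0.12, "T>C" = 0.16, "T>G" = 0.14)

  mut <- list()
  add_mut <- function(smp, gene, n_rec = 1L) {
    lowg <- smp %in% tumor_ids[low_mg]
    spec <- if (lowg) spectrum_low else spectrum_high
    cls6 <- sample(names(spec), n_rec, replace = TRUE, prob = spec)
    pyr_ref <- substr(cls6, 1, 1); pyr_alt <- substr(cls6, 3, 3)
    flip <- stats::runif(n_rec) < 0.5  # emit purine strand half the time
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- ifelse(flip, comp[pyr_ref], pyr_ref)
    alt <- ifelse(flip, comp[pyr_alt], pyr_alt)
    vt <- sample(c("SNP", "INS", "DEL"), n_rec, replace = TRUE,
                 prob = c(0.85, 0.075, 0.075))
    ref[vt == "INS"] <- "-"; alt[vt == "INS"] <- "AT"
    ref[vt == "DEL"] <- "TG"; alt[vt == "DEL"] <- "-"
    vc <- sample(c(nonsilent_classes(), "Silent"), n_rec, replace = TRUE,
                 prob = c(rep(0.95 / 9, 9), 0.05))
    vc[vt == "INS"] <- "Frame_Shift_Ins"; vc[vt == "DEL"] <- "Frame_Shift_Del"
    data.frame(
      Hugo_Symbol = gene, Tumor_Sample_Barcode = smp,
      Variant_Classification = vc, Variant_Type = vt,
      Chromosome = as.character(sample(1:22, n_rec, replace = TRUE)),
      Start_Position = sample.int(2e8, n_rec),
      Reference_Allele = unname(ref), Tumor_Seq_Allele2 = unname(alt),
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_len(n)) {
    smp <- tumor_ids[i]
    hit_bg <- bg_genes[stats::runif(cfg$n_genes) < cfg$background_mut_rate]
    freq <- if (low_mg[i]) pg$freq_low_mg else pg$freq_high_mg
    hit_pl <- pg$gene[stats::runif(nrow(pg)) < freq]
    hit_gi <- if (stats::runif(1) < 0.15) "GIANT1" else character(0)
    hits <- c(hit_bg, hit_pl, hit_gi)
    if (length(hits))
      mut[[length(mut) + 1L]] <- do.call(
        rbind, lapply(hits, function(g) add_mut(smp, g)))
  }

  hyper <- sort(sample(tumor_ids, cfg$n_hypermutators))
  n_mmr <- round(cfg$frac_hypermut_mmr * cfg$n_hypermutators)
  mmr_carriers <- hyper[seq_len(n_mmr)]
  for (smp in hyper) {
    target <- ceiling(cfg$exome_mb * stats::runif(1, 12, 20))
    genes <- sample(c(bg_genes, pg$gene), target, replace = TRUE)
    tab <- table(genes)
    mut[[length(mut) + 1L]] <- do.call(
      rbind, lapply(names(tab), function(g) add_mut(smp, g, tab[[g]])))
  }
  for (smp in mmr_carriers)
    mut[[length(mut) + 1L]] <- add_mut(smp, sample(mmr_polymerase_genes(), 1))

  maf <- do.call(rbind, mut)
  maf <- maf[!duplicated(maf), , drop = FALSE]
  maf <- maf[order(maf$Tumor_Sample_Barcode, maf$Hugo_Symbol,
                   maf$Start_Position), , drop = FALSE]
  rownames(maf) <- NULL

  ## --- gene sets -----------------------------------------------------------
  gene_sets <- list()
  if (length(pos_prot) >= 5)
    gene_sets$PLANTED_POS_CORR <- sort(sample(pos_prot,
                                              min(30, length(pos_prot))))
  if (length(neg_prot) >= 5)
    gene_sets$PLANTED_NEG_CORR <- sort(sample(neg_prot,
                                              min(30, length(neg_prot))))
  for (k in seq_len(8)) {
    gene_sets[[sprintf("RANDOM_SET_%02d", k)]] <-
      sort(sample(proteins, min(sample(15:40, 1), cfg$n_proteins)))
  }

  rec_counts <- table(factor(maf$Tumor_Sample_Barcode, levels = tumor_ids))
  truth <- list(
    target_rho = cfg$target_rho,
    sample_mutation_counts = data.frame(
      sample = names(rec_counts), n_records = as.integer(rec_counts),
      stringsAsFactors = FALSE),
    pos_corr_proteins = pos_prot,
    neg_corr_proteins = neg_prot,
    pos_corr_sites = pos_sites,
    neg_corr_sites = neg_sites,
    flagged_proteins = flagged,
    diff_proteins = data.frame(protein = diff_prot,
                               effect_log2 = unname(diff_effect),
                               stringsAsFactors = FALSE),
    planted_genes = pg,
    hypermutators = hyper,
    mmr_carriers = mmr_carriers,
    mg_cutpoint = mg_cutpoint,
    log_hr_per_mg_unit = cfg$log_hr_per_mg_unit,
    snv_spectrum = list(low_mg = spectrum_low, high_mg = spectrum_high),
    planted_sets = intersect(c("PLANTED_POS_CORR", "PLANTED_NEG_CORR"),
                             names(gene_sets))
  )

  structure(
    list(config = cfg, clinical = clinical, batches = batches, maf = maf,
         gene_sets = gene_sets, gene_lengths = gene_lengths,
         site_map = site_map, truth = truth),
    class = "mg_cohort"
  )
}

#' @export
print.mg_cohort <- function(x, ...) {
  cat(sprintf(
    "<mg_cohort> %d patients | %d batches | %d proteins, %d phosphosites | %d mutation records\n",
    nrow(x$clinical), length(x$batches), x$config$n_proteins,
    x$config$n_phosphosites, nrow(x$maf)))
  invisible(x)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes the clinical CSV, one protein and one phosphosite quantification
#' TSV per batch, the MAF TSV, a GMT gene-set file, a gene-length annotation
#' TSV, a JSON truth ledger and a JSON manifest. Output is byte-stable for a
#' fixed configuration.
#'
#' @param bundle an `mg_cohort` from [simulate_cohort()].
#' @param directory output directory (created if absent).
#' @param overwrite refuse to clobber an existing manifest unless `TRUE`.
#' @return the manifest, invisibly: file paths, md5 checksums and counts.
#' @export
write_cohort <- function(bundle, directory, overwrite = FALSE) {
  if (!inherits(bundle, "mg_cohort")) stopf("'bundle' must be an mg_cohort")
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stopf("manifest already exists at %s (use overwrite = TRUE)",
          manifest_path)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)

  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  files <- list()
  p <- file.path(directory, "clinical.csv")
  utils::write.csv(bundle$clinical, p, row.names = FALSE, quote = FALSE)
  files$clinical <- p

  files$protein_batches <- character(0)
  files$phospho_batches <- character(0)
  for (b in names(bundle$batches)) {
    bp <- file.path(directory, sprintf("%s_proteins.tsv", b))
    write_tsv(bundle$batches[[b]]$proteins, bp)
    files$protein_batches <- c(files$protein_batches, bp)
    if (!is.null(bundle$batches[[b]]$phospho)) {
      sp <- file.path(directory, sprintf("%s_phospho.tsv", b))
      write_tsv(bundle$batches[[b]]$phospho, sp)
      files$phospho_batches <- c(files$phospho_batches, sp)
    }
  }
  p <- file.path(directory, "mutations.maf.tsv")
  write_tsv(bundle$maf, p); files$maf <- p
  p <- file.path(directory, "gene_sets.gmt")
  writeLines(vapply(names(bundle$gene_sets), function(nm)
    paste(c(nm, "synthetic", bundle$gene_sets[[nm]]), collapse = "\t"),
    character(1)), p)
  files$gmt <- p
  p <- file.path(directory, "gene_lengths.tsv")
  write_tsv(bundle$gene_lengths, p); files$gene_lengths <- p
  p <- file.path(directory, "truth.json")
  jsonlite::write_json(bundle$truth, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  files$truth <- p

  all_files <- unlist(files, use.names = FALSE)
  manifest <- list(
    package = "mgscreen",
    seed = bundle$config$seed,
    n_patients = bundle$config$n_patients,
    n_batches = length(bundle$batches),
    files = files,
    md5 = as.list(tools::md5sum(all_files))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
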