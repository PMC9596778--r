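#' Configuration for the multi-cohort survival simulator
#'
#' Defines the study conditions for the planted-signature experiment: K
#' cohorts of log-scale expression in which each planted signature's genes
#' are driven by a per-sample latent activity, and survival times whose
#' log-hazard is a signed linear function of the planted activities.
#' Defaults mirror a seven-cohort recurrence-free-survival study with 20
#' protective, 20 deleterious and 60 inert signatures.
#'
#' @param n_cohorts Number of cohorts K (default 7).
#' @param n_samples Samples per cohort (default 200).
#' @param n_good,n_bad,n_null Counts of planted good / bad / null
#'   signatures (defaults 20 / 20 / 60; null signatures have coherent
#'   expression structure but no survival effect).
#' @param genes_per_sig Genes per signature block; blocks are disjoint by
#'   construction (default 10).
#' @param n_background Unstructured background genes (default 200).
#' @param beta Log-hazard effect size per planted signature (default 0.8);
#'   good signatures enter with coefficient `-beta`, bad with `+beta`.
#' @param lambda Loading of the latent activity on its signature's genes
#'   (default 1).
#' @param noise_sd Gene-level Gaussian noise SD (default 1).
#' @param baseline_hazard Exponential baseline hazard h0 (default 0.1).
#' @param censor_rate Independent exponential censoring rate (default 0.05).
#' @param seed Integer seed; together with the config it fully determines
#'   the output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 7L, n_samples = 200L,
                              n_good = 20L, n_bad = 20L, n_null = 60L,
                              genes_per_sig = 10L, n_background = 200L,
                              beta = 0.8, lambda = 1, noise_sd = 1,
                              baseline_hazard = 0.1, censor_rate = 0.05,
                              seed = 1L) {
  cfg <- list(n_cohorts = as.integer(n_cohorts), n_samples = as.integer(n_samples),
              n_good = as.integer(n_good), n_bad = as.integer(n_bad),
              n_null = as.integer(n_null), genes_per_sig = as.integer(genes_per_sig),
              n_background = as.integer(n_background), beta = beta, lambda = lambda,
              noise_sd = noise_sd, baseline_hazard = baseline_hazard,
              censor_rate = censor_rate, seed = as.integer(seed))
  with(cfg, {
    if (n_cohorts < 1L || n_samples < 8L) stop("need >= 1 cohort and >= 8 samples", call. = FALSE)
    if (n_good + n_bad + n_null < 1L) stop("at least one signature required", call. = FALSE)
    if (genes_per_sig < 2L) stop("signatures need >= 2 genes", call. = FALSE)
    if (baseline_hazard <= 0 || censor_rate < 0 || noise_sd < 0)
      stop("invalid rate or noise parameter", call. = FALSE)
  })
  structure(cfg, class = "simulation_config")
}

sim_signature_plan <- function(cfg) {
  n_sig <- cfg$n_good + cfg$n_bad + cfg$n_null
  direction <- rep(c("good", "bad", "null"), c(cfg$n_good, cfg$n_bad, cfg$n_null))
  sig_names <- sprintf("SIG_%s_%02d", toupper(direction),
                       unlist(lapply(c(cfg$n_good, cfg$n_bad, cfg$n_null), seq_len)))
  n_genes <- n_sig * cfg$genes_per_sig + cfg$n_background
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  sets <- split(gene_ids[seq_len(n_sig * cfg$genes_per_sig)],
                rep(seq_len(n_sig), each = cfg$genes_per_sig))
  names(sets) <- sig_names
  list(sig_names = sig_names, direction = direction, gene_ids = gene_ids,
       sets = sets, n_sig = n_sig, n_genes = n_genes,
       d = c(good = -1, bad = 1, null = 0)[direction])
}

#' Generate multi-cohort expression + survival with planted signatures
#'
#' Per cohort and planted signature s, a latent activity
#' `a[s, j] ~ N(0, 1)` per sample j; signature genes follow
#' `x = mu_g + lambda a[s, j] + N(0, noise_sd^2)` and background genes
#' `mu_g + noise`. Survival times come from an exponential
#' proportional-hazards model by inverse-transform sampling,
#' `T = -log(U) / (h0 exp(eta))` with
#' `eta = sum_s d_s beta a[s, j]` (`d_s = -1` for good, `+1` for bad, `0`
#' for null signatures), censored by an independent Exponential(censor_rate)
#' time. Each cohort uses the substream seed `seed + cohort index`, so
#' adding cohorts never perturbs earlier ones.
#'
#' @param cfg A [simulation_config()].
#' @param n_cohorts Number of cohorts to draw (defaults to
#'   `cfg$n_cohorts`; may exceed it, e.g. to add a held-out cohort).
#' @return List with `cohorts` (list of [cohort_dataset()]), `signatures`
#'   (the planted [signature_collection()]), and `truth` (`data.frame` of
#'   per-signature direction plus per-cohort latent activities and linear
#'   predictors in `truth$latents`).
#' @export
generate_cohorts <- function(cfg, n_cohorts = cfg$n_cohorts) {
  stopifnot(inherits(cfg, "simulation_config"))
  plan <- sim_signature_plan(cfg)
  cohorts <- vector("list", n_cohorts)
  latents <- vector("list", n_cohorts)
  for (k in seq_len(n_cohorts)) {
    set.seed(cfg$seed + k)
    n <- cfg$n_samples
    sample_ids <- sprintf("C%02d_S%03d", k, seq_len(n))
    mu <- stats::rnorm(plan$n_genes, mean = 6, sd = 1)
    a <- matrix(stats::rnorm(plan$n_sig * n), nrow = plan$n_sig,
                dimnames = list(plan$sig_names, sample_ids))
    x <- matrix(mu, nrow = plan$n_genes, ncol = n) +
      matrix(stats::rnorm(plan$n_genes * n, sd = cfg$noise_sd), nrow = plan$n_genes)
    sig_of_gene <- rep(seq_len(plan$n_sig), each = cfg$genes_per_sig)
    x[seq_along(sig_of_gene), ] <- x[seq_along(sig_of_gene), ] +
      cfg$lambda * a[sig_of_gene, , drop = FALSE]
    dimnames(x) <- list(plan$gene_ids, sample_ids)

    eta <- as.numeric(crossprod(a, plan$d * cfg$beta))
    u <- stats::runif(n)
    t_event <- -log(u) / (cfg$baseline_hazard * exp(eta))
    t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate) else rep(Inf, n)
    event <- as.integer(t_event <= t_cens)
    if (mean(event) < 0.05)
      warning(sprintf("cohort %d event fraction %.1f%% (< 5%%); selection power degenerate",
                      k, 100 * mean(event)), call. = FALSE)
    surv <- survival_table(sample_ids, pmin(t_event, t_cens), event, time_unit = "months")
    cohorts[[k]] <- cohort_dataset(sprintf("SIM%02d", k),
                                   expression_matrix(x, scale_tag = "log2"), surv)
    latents[[k]] <- list(a = a, eta = eta)
  }
  names(cohorts) <- vapply(cohorts, `[[`, character(1L), "name")
  names(latents) <- names(cohorts)
  truth <- list(signatures = data.frame(signature = plan$sig_names,
                                        direction = plan$direction,
                                        beta = cfg$beta * abs(plan$d),
                                        stringsAsFactors = FALSE),
                latents = latents)
  list(cohorts = cohorts,
       signatures = signature_collection(plan$sets, source_tag = "synthetic"),
       truth = truth)
}

#' Generate single-cell counts with planted DP/DN structure
#'
#' Negative-binomial counts with cluster-specific gene means. Cells are
#' assigned DP/DN/SP classes; by default the two marker genes (ITGAE,
#' ENTPD1) are noiseless — exactly `marker_shift` counts where positive and
#' 0 where negative — so marker classification can be checked against the
#' ground truth exactly; `marker_noise = TRUE` draws them from a negative
#' binomial instead. DP cells additionally receive an up-shift on a
#' designated cytotoxic/exhausted signature block.
#'
#' @param n_cells Number of cells (default 500).
#' @param n_genes Genes beyond the two markers (default 200; the first
#'   `sig_size` form the DP-shifted block).
#' @param n_clusters Cell clusters with distinct mean profiles (default 4).
#' @param dp_fraction,dn_fraction Fractions of DP and DN cells (defaults
#'   0.462 and 0.133; the remainder are SP).
#' @param marker_shift Marker level in positive cells (default 3).
#' @param sig_shift Added NB mean on the signature block in DP cells
#'   (default 2).
#' @param sig_size Genes in the DP-shifted block (default 20).
#' @param nb_size Negative-binomial size (dispersion) parameter (default 2).
#' @param marker_noise Draw marker counts from the NB model instead of the
#'   noiseless gate.
#' @param seed Integer seed.
#' @return List with `expr` (genes x cells counts), `annotation`
#'   (`cell_id`, `cluster`, `dp_class`), `signatures` (a two-set
#'   [signature_collection()]: the DP block and a background block), and
#'   `verdicts` marking the DP block prognostically good.
#' @export
generate_single_cells <- function(n_cells = 500L, n_genes = 200L, n_clusters = 4L,
                                  dp_fraction = 0.462, dn_fraction = 0.133,
                                  marker_shift = 3, sig_shift = 2, sig_size = 20L,
                                  nb_size = 2, marker_noise = FALSE, seed = 1L) {
  if (dp_fraction < 0 || dp_fraction > 1 || dn_fraction < 0 ||
      dp_fraction + dn_fraction > 1)
    stop("dp_fraction/dn_fraction must lie in [0,1] with sum <= 1", call. = FALSE)
  set.seed(seed)
  cell_ids <- sprintf("CELL%04d", seq_len(n_cells))
  gene_ids <- c("ITGAE", "ENTPD1", sprintf("SC%04d", seq_len(n_genes)))
  n_dp <- round(dp_fraction * n_cells)
  n_dn <- round(dn_fraction * n_cells)
  cls <- sample(rep(c("DP", "DN", "SP"), c(n_dp, n_dn, n_cells - n_dp - n_dn)))
  cluster <- sample(sprintf("CL%d", seq_len(n_clusters)), n_cells, replace = TRUE)

  base_mu <- matrix(stats::rgamma(n_genes * n_clusters, shape = 2, rate = 2),
                    nrow = n_genes)
  mu <- base_mu[, match(cluster, sprintf("CL%d", seq_len(n_clusters)))]
  sig_block <- seq_len(sig_size)
  mu[sig_block, cls == "DP"] <- mu[sig_block, cls == "DP"] + sig_shift
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size),
                   nrow = n_genes)

  marker_pos <- rbind(ITGAE = cls == "DP" | (cls == "SP" & seq_len(n_cells) %% 2 == 0),
                      ENTPD1 = cls == "DP" | (cls == "SP" & seq_len(n_cells) %% 2 == 1))
  if (marker_noise) {
    markers <- matrix(stats::rnbinom(2L * n_cells, mu = ifelse(marker_pos, marker_shift, 0.01),
                                     size = nb_size), nrow = 2L)
  } else {
    markers <- ifelse(marker_pos, marker_shift, 0)
  }
  expr <- rbind(markers, counts)
  dimnames(expr) <- list(gene_ids, cell_ids)

  sigs <- signature_collection(list(
    CYTOTOX_EXHAUSTED = gene_ids[2L + sig_block],
    BACKGROUND = gene_ids[(2L + sig_size + 1L):(2L + min(n_genes, sig_size + 20L))]
  ), source_tag = "synthetic")
  verdicts <- data.frame(signature = names(sigs),
                         selected = c(TRUE, FALSE),
                         direction = c("good", "none"),
                         stringsAsFactors = FALSE)
  list(expr = expression_matrix(expr, scale_tag = "counts"),
       annotation = data.frame(cell_id = cell_ids, cluster = cluster,
                               dp_class = factor(cls, levels = c("DN", "SP", "DP")),
                               stringsAsFactors = FALSE),
       signatures = sigs, verdicts = verdicts)
}

#' Generate a synthetic cytometry frame with group-shifted cluster frequencies
#'
#' Per-sample cluster frequencies are Dirichlet draws around a group-level
#' base composition; in the `high` group the target clusters' base
#' frequencies are raised by `delta` (taken proportionally from the
#' others — a simplex violation is an error). Events are assigned to
#' clusters multinomially and marker intensities are log-normal around
#' cluster-specific centers (raw, nonnegative scale).
#'
#' @param n_high,n_low Samples per group (defaults 6 and 7).
#' @param n_clusters Number of clusters (default 8).
#' @param events_per_sample Events per sample (default 500).
#' @param delta Frequency shift added to the target clusters in the high
#'   group (default 0.15).
#' @param target_clusters Indices of shifted clusters (default 1).
#' @param concentration Dirichlet concentration (default 50; larger =
#'   tighter per-sample compositions).
#' @param n_markers Markers per event (default 10).
#' @param seed Integer seed.
#' @return List with `frame` (raw [cytometry_frame()]), `cluster` (label per
#'   event), `sample_groups` (named `high`/`low` per sample), and
#'   `base_freq` (the two group compositions).
#' @export
generate_cytometry <- function(n_high = 6L, n_low = 7L, n_clusters = 8L,
                               events_per_sample = 500L, delta = 0.15,
                               target_clusters = 1L, concentration = 50,
                               n_markers = 10L, seed = 1L) {
  set.seed(seed)
  p_low <- rep(1 / n_clusters, n_clusters)
  shift_total <- delta * length(target_clusters)
  p_high <- p_low
  p_high[target_clusters] <- p_high[target_clusters] + delta
  p_high[-target_clusters] <- p_high[-target_clusters] -
    shift_total * p_low[-target_clusters] / sum(p_low[-target_clusters])
  if (any(p_high < 0) || any(p_high > 1))
    stop("delta pushes the high-group composition off the simplex", call. = FALSE)

  centers <- matrix(stats::rgamma(n_clusters * n_markers, shape = 3, rate = 0.5),
                    nrow = n_clusters)
  samples <- c(sprintf("HI%02d", seq_len(n_high)), sprintf("LO%02d", seq_len(n_low)))
  grp <- stats::setNames(rep(c("high", "low"), c(n_high, n_low)), samples)

  rdirichlet1 <- function(alpha) { g <- stats::rgamma(length(alpha), alpha); g / sum(g) }
  ints <- NULL; sample_id <- character(0); cluster <- character(0)
  for (s in samples) {
    base <- if (grp[[s]] == "high") p_high else p_low
    freq <- rdirichlet1(concentration * base)
    cl <- sample.int(n_clusters, events_per_sample, replace = TRUE, prob = freq)
    noise <- matrix(stats::rlnorm(events_per_sample * n_markers, sdlog = 0.4),
                    nrow = events_per_sample)
    ints <- rbind(ints, centers[cl, , drop = FALSE] * noise)
    sample_id <- c(sample_id, rep(s, events_per_sample))
    cluster <- c(cluster, sprintf("T%02d", cl))
  }
  colnames(ints) <- sprintf("MK%02d", seq_len(n_markers))
  list(frame = cytometry_frame(ints, sample_id, transform_state = "raw"),
       cluster = cluster, sample_groups = grp,
       base_freq = list(high = p_high, low = p_low))
}
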