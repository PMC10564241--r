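#' Configuration for the two-species synthetic study
#'
#' Defines the simulated study: a designed two-group (diabetic-prone vs
#' control) time course for species A with replicates, an observational
#' cohort with a continuous glycemia covariate for species B, a shared
#' planted gene program (an up-regulated "angiogenesis" surrogate set and a
#' down-regulated "oxidative phosphorylation" surrogate set loading with
#' opposite signs), an optional species-A-specific second component, per-gene
#' and per-sample baselines, and i.i.d. Gaussian noise on the log scale.
#'
#' Amplitudes are in log-expression units per standardized sample-pattern
#' unit, so `amplitude / noise_sd` is the per-gene signal-to-noise ratio of
#' a program gene.
#'
#' @param n_genes_a,n_genes_b genes per species (default 2000).
#' @param n_shared_homologs one-to-one homolog pairs (default 1500; must
#'   not exceed either gene count).
#' @param timepoints ordered species-A timepoints (default weeks 4, 6, 8,
#'   16, 24).
#' @param groups_a species-A group labels, reference (diabetic-prone)
#'   first (default `c("GK", "WST")`).
#' @param replicates replicates per group x timepoint cell (default 3).
#' @param design_a sample pattern of the shared component in species A:
#'   "group_time" (default; diabetic-prone group follows a monotone time
#'   ramp, the progression design) or "group" (pure two-group contrast, the
#'   rank-1 treatment/control design).
#' @param n_samples_b species-B cohort size (default 61).
#' @param covariate_mean,covariate_sd species-B covariate distribution
#'   (default 38 and 8, mmol/mol on the HbA1c scale).
#' @param covariate_threshold value at or above which a species-B sample is
#'   flagged abnormal (default 39).
#' @param program_size genes per pole of each planted program (default 100).
#' @param amplitude_shared amplitude of the shared component (default 2).
#' @param amplitude_shared_b species-B amplitude of the shared component;
#'   defaults to `amplitude_shared`. Set 0 to plant the signal in species A
#'   only (specificity control).
#' @param amplitude_specific amplitude of the species-A-specific second
#'   component (default 1; set 0 to disable).
#' @param baseline_range range of per-gene baseline means, log-units
#'   (default c(6, 10)).
#' @param sample_shift_sd sd of per-sample baseline shifts (default 0.05).
#' @param noise_sd sd of the i.i.d. Gaussian log-scale noise (default 0.5).
#' @param n_decoys decoy gene sets per species, drawn from non-program
#'   genes (default 20).
#' @param seed integer seed; all randomness flows through it.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes_a = 2000L, n_genes_b = 2000L,
                             n_shared_homologs = 1500L,
                             timepoints = c(4, 6, 8, 16, 24),
                             groups_a = c("GK", "WST"),
                             replicates = 3L,
                             design_a = c("group_time", "group"),
                             n_samples_b = 61L,
                             covariate_mean = 38, covariate_sd = 8,
                             covariate_threshold = 39,
                             program_size = 100L,
                             amplitude_shared = 2,
                             amplitude_shared_b = NULL,
                             amplitude_specific = 1,
                             baseline_range = c(6, 10),
                             sample_shift_sd = 0.05,
                             noise_sd = 0.5,
                             n_decoys = 20L,
                             seed = 1L) {
  cfg <- list(n_genes_a = as.integer(n_genes_a),
              n_genes_b = as.integer(n_genes_b),
              n_shared_homologs = as.integer(n_shared_homologs),
              timepoints = timepoints, groups_a = groups_a,
              replicates = as.integer(replicates),
              design_a = match.arg(design_a),
              n_samples_b = as.integer(n_samples_b),
              covariate_mean = covariate_mean, covariate_sd = covariate_sd,
              covariate_threshold = covariate_threshold,
              program_size = as.integer(program_size),
              amplitude_shared = amplitude_shared,
              amplitude_shared_b = if (is.null(amplitude_shared_b)) {
                amplitude_shared
              } else amplitude_shared_b,
              amplitude_specific = amplitude_specific,
              baseline_range = baseline_range,
              sample_shift_sd = sample_shift_sd,
              noise_sd = noise_sd,
              n_decoys = as.integer(n_decoys),
              seed = as.integer(seed))
  if (cfg$n_shared_homologs > min(cfg$n_genes_a, cfg$n_genes_b)) {
    stop("n_shared_homologs must not exceed either species' gene count")
  }
  if (cfg$amplitude_shared < 0 || cfg$amplitude_shared_b < 0 ||
      cfg$amplitude_specific < 0) {
    stop("amplitudes must be >= 0")
  }
  counts <- c(cfg$n_genes_a, cfg$n_genes_b, cfg$n_shared_homologs,
              cfg$replicates, cfg$n_samples_b, cfg$program_size)
  if (any(counts < 2L)) stop("all counts must be >= 2")
  if (length(cfg$timepoints) < 2L) stop("at least 2 timepoints required")
  if (length(cfg$groups_a) != 2L) stop("species A needs exactly 2 groups")
  if (cfg$noise_sd < 0 || cfg$sample_shift_sd < 0 || cfg$covariate_sd <= 0) {
    stop("scale parameters must be non-negative (covariate_sd positive)")
  }
  if (2L * cfg$program_size > cfg$n_shared_homologs) {
    stop("shared program (2 x program_size) must fit within the homologs")
  }
  if (5L * cfg$program_size > cfg$n_genes_a ||
      3L * cfg$program_size > cfg$n_genes_b) {
    stop("gene count too small for the planted programs plus decoy pool")
  }
  structure(cfg, class = "synthetic_config")
}

# center to mean zero and scale to unit sd
standardize <- function(x) {
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Simulate the two-species expression study with planted ground truth
#'
#' Generates both species' log-scale profiles as
#' per-gene baseline + per-sample shift + planted rank-1 components +
#' i.i.d. Gaussian noise. The shared component loads +1 on the up-program
#' genes and -1 on the down-program genes (opposite signs for the two
#' surrogate sets); its sample pattern is the group-by-time interaction in
#' species A (diabetic-prone group following a monotone time ramp) and the
#' standardized covariate in species B. An optional species-A-specific
#' second component models early-stage compensation (early-vs-late contrast
#' within the diabetic-prone group). Program genes are drawn among the
#' shared homologs; the catalogs also contain decoy sets so enrichment
#' specificity has something to fail on.
#'
#' @param config a [synthetic_config()].
#' @return object of class `dual_species_simulation`: `profile_a`,
#'   `profile_b` ([expression_profile()]s), `map` ([homology_map()]),
#'   `catalogs` (list of [gene_set_catalog()]s `a`, `b`), `truth` (planted
#'   program memberships/directions, sample patterns, covariate), `config`.
#' @export
simulate_dual_species <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config")) {
    stop("`config` must be a synthetic_config")
  }
  cfg <- config
  with_seed(cfg$seed, {
    genes_a <- sprintf("rG%05d", seq_len(cfg$n_genes_a))
    genes_b <- sprintf("hG%05d", seq_len(cfg$n_genes_b))
    hom_a <- genes_a[seq_len(cfg$n_shared_homologs)]
    hom_b <- genes_b[seq_len(cfg$n_shared_homologs)]
    map <- homology_map(hom_a, hom_b)

    # shared program: up/down sets among the homologs
    hom_idx <- sample.int(cfg$n_shared_homologs, 2L * cfg$program_size)
    up_idx <- hom_idx[seq_len(cfg$program_size)]
    down_idx <- hom_idx[cfg$program_size + seq_len(cfg$program_size)]

    q_a <- numeric(cfg$n_genes_a)
    q_a[up_idx] <- 1; q_a[down_idx] <- -1
    q_b <- numeric(cfg$n_genes_b)
    q_b[up_idx] <- 1; q_b[down_idx] <- -1  # homologs share indices by construction

    # species-A-specific program among non-homolog genes
    pool_a2 <- setdiff(seq_len(cfg$n_genes_a), hom_idx)
    idx_a2 <- sample(pool_a2, 2L * cfg$program_size)
    up2 <- idx_a2[seq_len(cfg$program_size)]
    down2 <- idx_a2[cfg$program_size + seq_len(cfg$program_size)]
    q_a2 <- numeric(cfg$n_genes_a)
    q_a2[up2] <- 1; q_a2[down2] <- -1

    # species A design and sample patterns
    md_a <- expand.grid(replicate = seq_len(cfg$replicates),
                        week = cfg$timepoints,
                        group = cfg$groups_a,
                        stringsAsFactors = FALSE)
    md_a <- md_a[, c("group", "week", "replicate")]
    md_a$sample_id <- sprintf("A_%s_w%g_r%d", md_a$group, md_a$week,
                              md_a$replicate)
    s_a <- nrow(md_a)
    ramp <- match(md_a$week, cfg$timepoints)  # monotone time ramp
    p_a <- if (cfg$design_a == "group_time") {
      standardize(ifelse(md_a$group == cfg$groups_a[1L], ramp, 0))
    } else {
      standardize(ifelse(md_a$group == cfg$groups_a[1L], 1, -1))
    }
    early <- md_a$week <= stats::median(cfg$timepoints)
    p_a2 <- standardize(ifelse(md_a$group == cfg$groups_a[1L],
                               ifelse(early, 1, -1), 0))

    # species B cohort
    covariate <- stats::rnorm(cfg$n_samples_b, cfg$covariate_mean,
                              cfg$covariate_sd)
    md_b <- data.frame(sample_id = sprintf("B_s%03d", seq_len(cfg$n_samples_b)),
                       covariate = covariate,
                       abnormal = covariate >= cfg$covariate_threshold,
                       age = round(stats::rnorm(cfg$n_samples_b, 57, 10)),
                       stringsAsFactors = FALSE)
    p_b <- standardize(covariate)

    build <- function(s, g, patterns, programs, amps, sample_ids, gene_ids) {
      E <- outer(rep(1, s), stats::runif(g, cfg$baseline_range[1L],
                                         cfg$baseline_range[2L])) +
        outer(stats::rnorm(s, 0, cfg$sample_shift_sd), rep(1, g))
      for (c_ in seq_along(patterns)) {
        if (amps[c_] > 0) E <- E + amps[c_] * outer(patterns[[c_]], programs[[c_]])
      }
      if (cfg$noise_sd > 0) E <- E + matrix(stats::rnorm(s * g, 0, cfg$noise_sd), s, g)
      dimnames(E) <- list(sample_ids, gene_ids)
      E
    }

    E_a <- build(s_a, cfg$n_genes_a, list(p_a, p_a2), list(q_a, q_a2),
                 c(cfg$amplitude_shared, cfg$amplitude_specific),
                 md_a$sample_id, genes_a)
    E_b <- build(cfg$n_samples_b, cfg$n_genes_b, list(p_b), list(q_b),
                 cfg$amplitude_shared_b, md_b$sample_id, genes_b)

    profile_a <- expression_profile(E_a, species = "speciesA", metadata = md_a)
    profile_b <- expression_profile(E_b, species = "speciesB", metadata = md_b)

    make_catalog <- function(genes, programs, q) {
      sets <- programs
      pool <- setdiff(seq_along(genes), which(q != 0))
      for (d in seq_len(cfg$n_decoys)) {
        sets[[sprintf("DECOY_%02d", d)]] <-
          genes[sample(pool, cfg$program_size)]
      }
      gene_set_catalog(sets, universe = genes)
    }
    cat_a <- make_catalog(genes_a,
                          list(ANGIO_SURROGATE_UP = genes_a[up_idx],
                               OXPHOS_SURROGATE_DOWN = genes_a[down_idx],
                               SPECIFIC_A_UP = genes_a[up2],
                               SPECIFIC_A_DOWN = genes_a[down2]),
                          q_a + q_a2)
    cat_b <- make_catalog(genes_b,
                          list(ANGIO_SURROGATE_UP = genes_b[up_idx],
                               OXPHOS_SURROGATE_DOWN = genes_b[down_idx]),
                          q_b)

    truth <- list(
      shared_up_a = genes_a[up_idx], shared_down_a = genes_a[down_idx],
      shared_up_b = genes_b[up_idx], shared_down_b = genes_b[down_idx],
      specific_up_a = genes_a[up2], specific_down_a = genes_a[down2],
      program_a = q_a, program_b = q_b, program_a2 = q_a2,
      pattern_a = p_a, pattern_a2 = p_a2, pattern_b = p_b,
      covariate = covariate
    )

    structure(
      list(profile_a = profile_a, profile_b = profile_b, map = map,
           catalogs = list(a = cat_a, b = cat_b), truth = truth,
           config = cfg),
      class = "dual_species_simulation"
    )
  })
}

#' @export
print.dual_species_simulation <- function(x, ...) {
  cat("dual_species_simulation\n")
  cat(sprintf("  species A: %d samples x %d genes (designed time course)\n",
              nrow(x$profile_a$matrix), ncol(x$profile_a$matrix)))
  cat(sprintf("  species B: %d samples x %d genes (observational cohort)\n",
              nrow(x$profile_b$matrix), ncol(x$profile_b$matrix)))
  cat(sprintf("  %d homolog pairs; planted program %d up + %d down genes\n",
              nrow(x$map$pairs), x$config$program_size, x$config$program_size))
  invisible(x)
}

#' Simulate insulin/glucagon islet masks with tunable infiltration
#'
#' Emulates a stained islet micrograph reduced to channel masks. Insulin
#' pixels fill a disk (the beta-cell core plus rim). Glucagon pixels are
#' placed in two strata: a fraction `1 - infiltration` in a thin mantle
#' band (within 2 px of the disk boundary — the normal rodent core-mantle
#' arrangement) and the remainder uniformly over the disk interior
#' (alpha-cell infiltration). `infiltration = 0` is a pure core-mantle
#' islet; `infiltration = 1` is fully mixed, for which the mean
#' glucagon-to-rim distance approaches R/3 (the mean of R - r over a
#' uniform disk).
#'
#' @param radius_px disk radius in pixels (>= 10).
#' @param infiltration fraction of glucagon pixels placed uniformly in the
#'   interior, in [0, 1].
#' @param n_glucagon glucagon pixels drawn (default 2000; duplicates
#'   collapse in the mask).
#' @param n_insulin optional number of insulin pixels sampled from the
#'   disk; `NULL` (default) fills the disk.
#' @param seed integer seed.
#' @return list with `insulin`, `glucagon` (0/1 matrices of a common
#'   frame), `radius`, `infiltration`, `center`.
#' @export
simulate_islet_masks <- function(radius_px, infiltration,
                                 n_glucagon = 2000L, n_insulin = NULL,
                                 seed = 1L) {
  if (radius_px < 10) stop("radius must be >= 10 px")
  if (infiltration < 0 || infiltration > 1) {
    stop("infiltration must lie in [0, 1]")
  }
  R <- radius_px
  margin <- 5L
  n <- 2L * (ceiling(R) + margin) + 1L
  cx <- ceiling(R) + margin + 1L
  rr <- matrix(seq_len(n), n, n)          # row index
  cc <- t(rr)                             # column index
  dist_c <- sqrt((rr - cx)^2 + (cc - cx)^2)
  insulin <- (dist_c <= R) * 1L

  with_seed(seed, {
    if (!is.null(n_insulin)) {
      disk <- which(insulin == 1L)
      keep <- sample(disk, min(n_insulin, length(disk)))
      insulin <- matrix(0L, n, n)
      insulin[keep] <- 1L
    }
    glucagon <- matrix(0L, n, n)
    n_mantle <- round((1 - infiltration) * n_glucagon)
    n_core <- n_glucagon - n_mantle
    place <- function(m, accept) {
      # rejection-sample pixels until `m` accepted (criterion on the
      # rounded pixel center, so band membership is exact in pixel space)
      got <- 0L
      while (got < m) {
        k <- max(2L * (m - got), 64L)
        theta <- stats::runif(k, 0, 2 * pi)
        r <- sqrt(stats::runif(k)) * R
        px <- round(cx + r * cos(theta))
        py <- round(cx + r * sin(theta))
        d <- sqrt((px - cx)^2 + (py - cx)^2)
        ok <- accept(d)
        px <- px[ok][seq_len(min(sum(ok), m - got))]
        py <- py[ok][seq_len(min(sum(ok), m - got))]
        glucagon[cbind(py, px)] <<- 1L
        got <- got + length(px)
      }
    }
    if (n_mantle > 0L) place(n_mantle, function(d) d >= R - 2 & d <= R)
    if (n_core > 0L) place(n_core, function(d) d <= R)
  })
  list(insulin = insulin, glucagon = glucagon, radius = R,
       infiltration = infiltration, center = c(cx, cx))
}
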