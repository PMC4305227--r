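#' Configure a synthetic PBMC expression study
#'
#' The generator emulates the five-group PBMC design: healthy controls,
#' stable COPD, and exacerbation patients sampled longitudinally on
#' hospital days 1, 3 and 10 (the three AE groups share subjects). Probe
#' intensities are built additively in log2 space — gene baseline + group
#' effect + fixed per-probe offset + per-subject intercept + residual
#' noise — and exponentiated, so linear intensities are strictly positive.
#'
#' Planted signal defines the ground truth for parameter-recovery tests:
#' \describe{
#'   \item{\code{planted_copd}}{genes shifted by log2(fold) in all four
#'     disease groups relative to control (consistent in the four
#'     vs-control comparisons).}
#'   \item{\code{planted_aecopd}}{genes shifted by log2(fold) in the three
#'     AE groups relative to both control and stable (consistent in the
#'     six exacerbation comparisons).}
#'   \item{\code{planted_trajectories}}{genes stepped by log2(step_fold)
#'     from AE1 to AE3 and AE3 to AE10 following a two-step pattern.}
#' }
#'
#' @param n_subjects_per_arm subjects per arm (the study used 6).
#' @param n_genes number of genes.
#' @param probes_per_gene probes per gene (>= 1).
#' @param baseline_log2_mean,baseline_log2_sd mean and SD of gene baseline
#'   log2 intensities.
#' @param noise_sd per-sample residual SD, log2 units.
#' @param probe_offset_sd SD of the fixed per-probe affinity offsets, log2
#'   units.
#' @param subject_sd SD of per-subject random intercepts, log2 units
#'   (0 disables them).
#' @param planted_copd,planted_aecopd lists of specs
#'   \code{list(n =, fold =, direction = "up"|"down")} with fold > 1.
#' @param planted_trajectories list of specs
#'   \code{list(pattern = "up-up"|..., n =, step_fold =)} with
#'   step_fold > 1.
#' @param seed integer seed; required, every draw is reproducible from it.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_subjects_per_arm = 6, n_genes = 2000,
                              probes_per_gene = 3,
                              baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                              noise_sd = 0.25, probe_offset_sd = 0.3,
                              subject_sd = 0,
                              planted_copd = list(),
                              planted_aecopd = list(),
                              planted_trajectories = list(),
                              seed = NULL) {
  if (is.null(seed)) stop("a seed is required for a reproducible study")
  if (n_subjects_per_arm < 1 || n_genes < 1 || probes_per_gene < 1) {
    stop("subject, gene and probe counts must be positive")
  }
  if (noise_sd < 0 || probe_offset_sd < 0 || subject_sd < 0) {
    stop("standard deviations must be non-negative")
  }
  check_specs <- function(specs, fold_field) {
    for (s in specs) {
      if (s$n < 0) stop("planted gene counts must be >= 0")
      if (s[[fold_field]] <= 1) stop("planted folds must be > 1")
    }
  }
  check_specs(planted_copd, "fold")
  check_specs(planted_aecopd, "fold")
  check_specs(planted_trajectories, "step_fold")
  n_planted <- sum(vapply(c(planted_copd, planted_aecopd,
                            planted_trajectories),
                          function(s) s$n, numeric(1)))
  if (n_planted > n_genes) {
    stop("planted gene counts (", n_planted, ") exceed n_genes (", n_genes, ")")
  }
  structure(list(n_subjects_per_arm = as.integer(n_subjects_per_arm),
                 n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, probe_offset_sd = probe_offset_sd,
                 subject_sd = subject_sd,
                 planted_copd = planted_copd,
                 planted_aecopd = planted_aecopd,
                 planted_trajectories = planted_trajectories,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

traj_group_effects <- function(pattern, step_fold) {
  d <- log2(step_fold)
  s <- switch(pattern,
              "down-down" = c(0, -d, -2 * d),
              "down-up" = c(0, -d, 0),
              "up-down" = c(0, d, 0),
              "up-up" = c(0, d, 2 * d),
              stop("unknown trajectory pattern: ", pattern))
  c(CON = 0, STABLE = 0, AE1 = s[1], AE3 = s[2], AE10 = s[3])
}

#' Generate a synthetic study with planted ground truth
#'
#' @param config a [simulation_config()].
#' @return List with elements \code{probes} (linear-intensity matrix,
#'   probes x samples), \code{design} (a [study_design()]),
#'   \code{annotation} (probe_id -> gene_id), and \code{truth} (data frame
#'   \code{gene_id}, \code{label}, \code{fold}; label \code{"null"} for
#'   unplanted genes).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_subjects_per_arm
  groups <- study_groups()

  con_sub <- sprintf("CONS%02d", seq_len(n))
  sta_sub <- sprintf("STAS%02d", seq_len(n))
  ae_sub <- sprintf("AES%02d", seq_len(n))
  design <- study_design(
    sample_id = c(con_sub, sta_sub,
                  paste0(ae_sub, "_D1"), paste0(ae_sub, "_D3"),
                  paste0(ae_sub, "_D10")),
    subject_id = c(con_sub, sta_sub, ae_sub, ae_sub, ae_sub),
    group = rep(groups, each = n))

  gene_ids <- sprintf("G%05d", seq_len(config$n_genes))
  labels <- rep("null", config$n_genes)
  folds <- rep(NA_real_, config$n_genes)
  # group effect per gene, genes x groups, log2 units
  eff <- matrix(0, nrow = config$n_genes, ncol = length(groups),
                dimnames = list(gene_ids, groups))
  nxt <- 1L
  take <- function(k) {
    idx <- seq.int(nxt, length.out = k)
    nxt <<- nxt + k
    idx
  }
  for (s in config$planted_copd) {
    idx <- take(s$n)
    sgn <- if (s$direction == "up") 1 else -1
    eff[idx, c("STABLE", "AE1", "AE3", "AE10")] <- sgn * log2(s$fold)
    labels[idx] <- paste0("copd_specific_", s$direction)
    folds[idx] <- s$fold
  }
  for (s in config$planted_aecopd) {
    idx <- take(s$n)
    sgn <- if (s$direction == "up") 1 else -1
    eff[idx, c("AE1", "AE3", "AE10")] <- sgn * log2(s$fold)
    labels[idx] <- paste0("aecopd_specific_", s$direction)
    folds[idx] <- s$fold
  }
  for (s in config$planted_trajectories) {
    idx <- take(s$n)
    eff[idx, ] <- matrix(traj_group_effects(s$pattern, s$step_fold),
                         nrow = s$n, ncol = length(groups), byrow = TRUE)
    labels[idx] <- paste0("traj_", gsub("down", "d", gsub("up", "u",
                          gsub("-", "", s$pattern))))
    folds[idx] <- s$step_fold
  }

  baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  probe_ids <- paste0(rep(gene_ids, each = config$probes_per_gene), "_P",
                      rep(seq_len(config$probes_per_gene), config$n_genes))
  probe_offset <- stats::rnorm(length(probe_ids), 0, config$probe_offset_sd)
  subj_eff <- stats::rnorm(length(unique(design$subject_id)), 0,
                           config$subject_sd)
  names(subj_eff) <- unique(design$subject_id)

  gene_of_probe <- rep(seq_len(config$n_genes),
                       each = config$probes_per_gene)
  # probes x samples in log2: baseline + group effect + probe offset
  log2m <- matrix(baseline[gene_of_probe] + probe_offset,
                  nrow = length(probe_ids), ncol = nrow(design),
                  dimnames = list(probe_ids, design$sample_id))
  log2m <- log2m + eff[gene_of_probe, match(design$group, groups)]
  log2m <- sweep(log2m, 2, subj_eff[design$subject_id], `+`)
  if (config$noise_sd > 0) {
    log2m <- log2m + stats::rnorm(length(log2m), 0, config$noise_sd)
  }

  list(probes = 2^log2m,
       design = design,
       annotation = data.frame(probe_id = probe_ids,
                               gene_id = gene_ids[gene_of_probe],
                               stringsAsFactors = FALSE),
       truth = data.frame(gene_id = gene_ids, label = labels, fold = folds,
                          stringsAsFactors = FALSE))
}

#' Generate synthetic DESS clinical records
#'
#' Draws a per-sample target total from a normal around the group target
#' (clamped to [0, 256]) and raises randomly chosen components stepwise
#' (0 -> 1 -> 2 -> 4) until the target is reached, so every record is a
#' valid 64-component DESS record whose group means track the targets.
#'
#' @param design a [study_design()].
#' @param group_mean_targets named numeric vector of target mean totals per
#'   group (each in [0, 256]); every group of the design must be named.
#' @param dispersion SD of per-sample targets around the group target,
#'   score units.
#' @param seed integer seed.
#' @return Long data frame of DESS components (\code{sample_id},
#'   \code{component_id}, \code{category}, \code{level}).
#' @export
generate_dess_records <- function(design, group_mean_targets,
                                  dispersion = 10, seed) {
  if (missing(seed)) stop("a seed is required")
  if (any(group_mean_targets < 0 | group_mean_targets > 256)) {
    stop("group mean targets must lie in [0, 256]")
  }
  need <- setdiff(unique(design$group), names(group_mean_targets))
  if (length(need) > 0) {
    stop("no target for group(s): ", paste(need, collapse = ", "))
  }
  set.seed(seed)
  categories <- rep(c("symptom_sign", "biochemistry", "imaging", "other"),
                    times = c(28, 20, 8, 8))
  records <- lapply(seq_len(nrow(design)), function(i) {
    target <- stats::rnorm(1, group_mean_targets[[design$group[i]]],
                           dispersion)
    target <- round(min(max(target, 0), 256))
    levels <- integer(64)
    repeat {
      remaining <- target - sum(levels)
      if (remaining <= 0) break
      step <- ifelse(levels == 2L, 2L, 1L)
      open <- which(levels < 4L & step <= remaining)
      if (length(open) == 0) break  # only +2 raises left but 1 point to go
      j <- if (length(open) == 1) open else sample(open, 1)
      levels[j] <- if (levels[j] == 2L) 4L else levels[j] + 1L
    }
    dess_record(design$sample_id[i], levels,
                category = categories)
  })
  do.call(rbind, records)
}
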