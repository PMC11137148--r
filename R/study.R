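#' Run the full in-silico validation study
#'
#' Replicates the design of a skull observer study end to end on
#' synthetic data: a population of skull-like targets with known
#' ground truth is generated; the template is registered to every
#' skull several times with independently perturbed initialization
#' landmarks (registration reliability); several simulated observers
#' landmark every skull repeatedly (manual reliability); landmarks are
#' transferred by leave-one-out barycentric encoding (accuracy); and
#' the statistical battery is computed: RMS reliability table,
#' per-landmark Euclidean distance table, centroid-size ICCs,
#' Bland-Altman agreement, sequential ANOVA on centroid size with a
#' method factor, Procrustes shape-variance decomposition, and
#' true/gap landmark assessment.
#'
#' @param pop_spec a [population_spec()]; its seed is overridden from
#'   `seed`.
#' @param obs_spec an [observer_spec()]; its seed is overridden too.
#' @param cfg a [nonrigid_config()] for the registrations.
#' @param n_repeats registration repeats with perturbed initialization
#'   landmarks (default 3).
#' @param init_perturb_sd perturbation sd of the initialization
#'   landmarks in mm (default 2).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional directory; when given, CSV tables, QC
#'   overlays and a JSON summary are written there.
#' @param n_perm permutations for the shape variance decomposition.
#' @return object of class `validation_study` (see Details) with
#'   elements `rms_table`, `distance_table`, `icc`, `bland_altman`,
#'   `anova`, `variance`, `true_mask`, `topology`, `loo`, `automated_rms`,
#'   `intra_rms`, `inter_rms`, `seed`.
#' @export
run_validation_study <- function(pop_spec = population_spec(),
                                 obs_spec = observer_spec(),
                                 cfg = nonrigid_config(),
                                 n_repeats = 3, init_perturb_sd = 2,
                                 seed = 1, out_dir = NULL, n_perm = 199) {
  seed <- as.integer(seed)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  derive_seed <- function(mult, off)
    as.integer((as.numeric(seed) * mult) %% 2147483046) + off
  pop_spec$seed <- derive_seed(1009, 1L)
  obs_spec$seed <- derive_seed(2003, 2L)
  pop <- generate_population(pop_spec)
  mask <- pop$base
  ids <- pop$landmark_ids
  mask_lm_all <- landmark_config(mask$vertices[ids, , drop = FALSE],
                                 names(ids), frame = "template")
  init_names <- intersect(init_landmark_names(), names(ids))
  mask_init <- landmark_config(mask_lm_all$points[init_names, , drop = FALSE],
                               init_names, frame = "template")
  n_s <- length(pop$individuals)

  # --- registration repeats with perturbed initialization landmarks
  masked <- vector("list", n_s)
  with_seed(derive_seed(3001, 3L), {
    for (s in seq_len(n_s)) {
      ind <- pop$individuals[[s]]
      reps <- vector("list", n_repeats)
      for (r in seq_len(n_repeats)) {
        pts <- ind$truth_landmarks$points[init_names, , drop = FALSE] +
          matrix(rnorm(length(init_names) * 3, sd = init_perturb_sd), ncol = 3)
        # observers click on the surface, so perturbed inits are too
        pts <- cpp_closest_points(pts, ind$mesh$vertices,
                                  ind$mesh$faces)$point
        rownames(pts) <- init_names
        tgt_init <- landmark_config(pts, init_names,
                                    frame = sprintf("skull%02d", s))
        reps[[r]] <- register_mask(mask, ind$mesh, mask_init, tgt_init,
                                   cfg = cfg)$masked
      }
      masked[[s]] <- reps
    }
  })

  # automated landmarking reliability: RMS of the quasi-landmarks over
  # the registration repeats, averaged per skull
  automated_rms_per_skull <- vapply(masked, function(reps)
    rms_repeat(lapply(reps, `[[`, "quasi"))$mean, 0)
  automated_rms <- mean(automated_rms_per_skull)

  # --- simulated observers
  study <- simulate_observers(pop, obs_spec)
  n_o <- obs_spec$n_observers

  intra_per_skull <- sapply(seq_len(n_o), function(o)
    vapply(seq_len(n_s), function(s)
      rms_repeat(lapply(seq_len(obs_spec$n_rounds), function(r)
        study$landmarks[s, o, r, , ]))$mean, 0))
  colnames(intra_per_skull) <- study$observers
  inter_per_skull <- vapply(seq_len(n_s), function(s)
    rms_between(lapply(seq_len(n_o), function(o)
      observer_mean_config(study, s, o)$points))$mean, 0)

  tab_row <- function(x) c(Mean = mean(x), Std = stats::sd(x),
                           Min = min(x), Max = max(x))
  rms_table <- rbind(Automated = tab_row(automated_rms_per_skull),
                     `Inter-Observer` = tab_row(inter_per_skull))
  for (o in seq_len(n_o))
    rms_table <- rbind(rms_table, tab_row(intra_per_skull[, o]))
  rownames(rms_table)[2 + seq_len(n_o)] <-
    paste("Intra-Observer", seq_len(n_o))

  # --- leave-one-out transfer accuracy (repeat-1 registrations)
  loo_input <- lapply(seq_len(n_s), function(s) {
    lms <- lapply(seq_len(n_o), function(o) observer_mean_config(study, s, o))
    names(lms) <- study$observers
    lms$mean <- landmark_config(
      apply(study$landmarks[s, , , , , drop = FALSE], c(4, 5), mean),
      study$names, frame = sprintf("skull%02d/mean", s))
    list(masked = masked[[s]][[1]], mesh = pop$individuals[[s]]$mesh,
         landmarks = lms)
  })
  loo <- loo_evaluate(loo_input)

  # --- centroid sizes: manual (per observer mean) and automatic
  cs_manual <- sapply(seq_len(n_o), function(o)
    vapply(seq_len(n_s), function(s)
      centroid_size(observer_mean_config(study, s, o)), 0))
  cs_auto <- sapply(study$observers, function(o)
    vapply(seq_len(n_s), function(s)
      centroid_size(loo$transferred[[s]][[o]]), 0))
  cs_auto_mean <- vapply(seq_len(n_s), function(s)
    centroid_size(loo$transferred[[s]][["mean"]]), 0)
  cs_manual_mean <- vapply(seq_len(n_s), function(s)
    centroid_size(landmark_config(
      apply(study$landmarks[s, , , , , drop = FALSE], c(4, 5), mean),
      study$names)), 0)

  icc_inter <- icc(cs_manual, model = "two_way_consistency")
  icc_intra <- lapply(seq_len(n_o), function(o) {
    m <- t(vapply(seq_len(n_s), function(s)
      vapply(seq_len(obs_spec$n_rounds), function(r)
        centroid_size(study$landmarks[s, o, r, , ]), 0), numeric(obs_spec$n_rounds)))
    icc(m, model = "two_way_agreement")
  })
  names(icc_intra) <- study$observers
  icc_method <- icc(cbind(manual = cs_manual_mean, automatic = cs_auto_mean),
                    model = "two_way_agreement")
  ba <- bland_altman(cs_manual_mean, cs_auto_mean,
                     plot_path = if (!is.null(out_dir))
                       file.path(out_dir, "bland_altman.png") else NULL)

  anova_df <- rbind(
    data.frame(size = as.vector(cs_manual),
               skull = rep(seq_len(n_s), n_o),
               observer = rep(seq_len(n_o), each = n_s),
               method = "manual"),
    data.frame(size = as.vector(cs_auto[, seq_len(n_o)]),
               skull = rep(seq_len(n_s), n_o),
               observer = rep(seq_len(n_o), each = n_s),
               method = "automatic"))
  aov_tab <- anova_centroid(anova_df,
                            size ~ skull + observer + method + skull:observer)

  # --- shape variance decomposition on the manual configurations
  cfg_list <- list(); fac <- list()
  for (s in seq_len(n_s)) for (o in seq_len(n_o))
    for (r in seq_len(obs_spec$n_rounds)) {
      cfg_list[[length(cfg_list) + 1L]] <- study$landmarks[s, o, r, , ]
      fac[[length(fac) + 1L]] <- data.frame(skull = s, observer = o)
    }
  g <- gpa(cfg_list, with_scaling = TRUE)
  variance <- shape_variance_decomposition(
    g, do.call(rbind, fac), n_perm = n_perm,
    seed = derive_seed(4001, 4L))

  # --- true/gap assessment and topology fidelity (repeat 1)
  ndist <- t(vapply(seq_len(n_s), function(s)
    normal_distance(masked[[s]][[1]], pop$individuals[[s]]$mesh)$distance,
    numeric(nrow(mask$vertices))))
  pairing <- mirror_pairing(mask, max_dist = mean(edge_lengths(mask)) / 2)
  true_mask <- flag_true_landmarks(ndist, threshold = 10, pairing = pairing)
  topo <- list(mean = mean(ndist[, true_mask$flags]),
               sd = stats::sd(as.vector(ndist[, true_mask$flags])))

  out <- structure(list(
    rms_table = rms_table, automated_rms = automated_rms,
    intra_rms = colMeans(intra_per_skull), inter_rms = mean(inter_per_skull),
    loo = loo, distance_table = loo$summary,
    icc = list(inter = icc_inter, intra = icc_intra, method = icc_method),
    bland_altman = ba, anova = aov_tab, variance = variance,
    true_mask = true_mask, topology = topo,
    centroid_sizes = list(manual = cs_manual_mean, automatic = cs_auto_mean),
    masked = masked, population = pop, observer_study = study,
    seed = seed), class = "validation_study")
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

#' @export
print.validation_study <- function(x, ...) {
  cat("validation_study\n")
  cat(sprintf("  skulls: %d   seed: %d\n",
              length(x$population$individuals), x$seed))
  cat("\nRMS reliability (mm):\n")
  print(round(x$rms_table, 3))
  cat(sprintf("\nLOO transfer mean distance: %.3f mm\n", x$loo$mean))
  cat(sprintf("Inter-observer centroid-size ICC (consistency): %.4f\n",
              x$icc$inter$icc))
  cat(sprintf("Centroid-size bias (manual - automatic): %.3f mm\n",
              x$bland_altman$bias))
  cat(sprintf("True landmarks: %d / %d\n",
              sum(x$true_mask$flags), length(x$true_mask$flags)))
  cat(sprintf("Topology fidelity: %.3f +/- %.3f mm\n",
              x$topology$mean, x$topology$sd))
  invisible(x)
}

write_study_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  rt <- data.frame(Configuration = rownames(x$rms_table),
                   round(x$rms_table, 4))
  w(rt, "table1_rms.csv")
  w(cbind(x$distance_table[1],
          round(x$distance_table[-1], 4)), "table2_distances.csv")
  at <- as.data.frame(x$anova)
  names(at) <- c("Df", "Sum Sq", "Mean Sq", "F value", "Pr(>F)")
  utils::write.csv(cbind(Term = rownames(at), round(at, 4)),
                   file.path(out_dir, "table3_anova.csv"), row.names = FALSE)
  iccs <- data.frame(
    measure = c("inter_consistency",
                paste0("intra_agreement_", names(x$icc$intra)),
                "method_agreement"),
    icc = c(x$icc$inter$icc, vapply(x$icc$intra, `[[`, 0, "icc"),
            x$icc$method$icc),
    ci_low = c(x$icc$inter$ci_low, vapply(x$icc$intra, `[[`, 0, "ci_low"),
               x$icc$method$ci_low),
    ci_high = c(x$icc$inter$ci_high, vapply(x$icc$intra, `[[`, 0, "ci_high"),
                x$icc$method$ci_high))
  w(iccs, "icc.csv")
  w(data.frame(skull = seq_along(x$centroid_sizes$manual),
               manual = x$centroid_sizes$manual,
               automatic = x$centroid_sizes$automatic),
    "centroid_sizes.csv")
  w(x$variance, "shape_variance.csv")
  write_gap_ids(x$true_mask, file.path(out_dir, "gap_vertex_ids.txt"))
  qc_overlay(x$masked[[1]][[1]], x$population$individuals[[1]]$mesh,
             file.path(out_dir, "qc_skull01.png"))
  jsonlite::write_json(list(
    seed = x$seed,
    automated_rms = x$automated_rms,
    intra_rms = as.list(x$intra_rms),
    inter_rms = x$inter_rms,
    loo_mean = x$loo$mean,
    icc_inter = x$icc$inter$icc,
    centroid_bias = x$bland_altman$bias,
    n_true = sum(x$true_mask$flags),
    n_quasi = length(x$true_mask$flags),
    topology_mean = x$topology$mean,
    topology_sd = x$topology$sd),
    file.path(out_dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
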